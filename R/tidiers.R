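# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a breakpoint-graph result
#'
#' @param x A `breakpoint_graph` from [reversal_distance()] or
#'   [hp_distance()].
#' @param ... Unused.
#' @return One-row tibble with `m`, `cycles`, `hurdles`, `fortress`,
#'   `distance`.
#' @method tidy breakpoint_graph
#' @export
tidy.breakpoint_graph <- function(x, ...) {
  tibble(m = x$m, cycles = x$c, hurdles = x$h, fortress = x$f, distance = x$d)
}

#' @rdname tidy.breakpoint_graph
#' @method glance breakpoint_graph
#' @export
glance.breakpoint_graph <- function(x, ...) tidy.breakpoint_graph(x)

#' Tidy a Dollo map
#'
#' @param x A `dollo_map`.
#' @param ... Unused.
#' @return Tibble with one row per event (`gain` or `loss`) and its branch.
#' @method tidy dollo_map
#' @export
tidy.dollo_map <- function(x, ...) {
  rows <- list()
  if (!is.na(x$gain_node)) {
    rows[[1]] <- tibble(character_id = x$character_id %||% NA_character_,
                        event = "gain", node = x$gain_node,
                        branch = x$gain_label)
  }
  if (length(x$loss_nodes) > 0L) {
    rows[[length(rows) + 1L]] <- tibble(
      character_id = x$character_id %||% NA_character_,
      event = "loss", node = x$loss_nodes, branch = x$loss_labels)
  }
  if (length(rows) == 0L) {
    return(tibble(character_id = character(), event = character(),
                  node = integer(), branch = character()))
  }
  bind_rows(rows)
}

#' @rdname tidy.dollo_map
#' @return `glance`: one-row tibble with `gain_branch`, `n_losses`,
#'   `n_na_leaves`.
#' @method glance dollo_map
#' @export
glance.dollo_map <- function(x, ...) {
  tibble(character_id = x$character_id %||% NA_character_,
         gain_branch = x$gain_label, n_losses = length(x$loss_nodes),
         n_na_leaves = length(x$na_leaves))
}

#' Tidy a repeat summary
#'
#' @param x A `repeat_summary` from [mask_and_summarize()].
#' @param ... Unused.
#' @return The size-class tibble with one row per class.
#' @method tidy repeat_summary
#' @export
tidy.repeat_summary <- function(x, ...) x$size_classes

#' @rdname tidy.repeat_summary
#' @method glance repeat_summary
#' @export
glance.repeat_summary <- function(x, ...) {
  tibble(genome_length = x$genome_length, masked_bp = x$masked_bp,
         masked_percent = x$masked_percent, gc_repeat = x$gc_repeat,
         gc_unique = x$gc_unique, gc_genome = x$gc_genome,
         n_elements = x$n_elements)
}

#' Tidy an IR annotation
#'
#' @param x An `ir_annotation`.
#' @param ... Unused.
#' @return Tibble with one row per region (IRA, IRB, LSC, SSC).
#' @method tidy ir_annotation
#' @export
tidy.ir_annotation <- function(x, ...) {
  L <- x$genome_length
  tibble(region = c("IRA", "IRB", "LSC", "SSC"),
         start = c(x$ira[1], x$irb[1], x$lsc[1] %% L, x$ssc[1] %% L),
         end = c(x$ira[2], x$irb[2], x$lsc[2], x$ssc[2]),
         length = c(diff(x$ira), diff(x$irb), diff(x$lsc), diff(x$ssc)))
}

#' @rdname tidy.ir_annotation
#' @method glance ir_annotation
#' @export
glance.ir_annotation <- function(x, ...) {
  tibble(ir_len = x$ir_len, lsc_len = diff(x$lsc), ssc_len = diff(x$ssc),
         genome_length = x$genome_length)
}
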