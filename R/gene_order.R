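# Signed circular gene orders, the sidedness index, canonical adjacency pairs
# and shared-pair / gene-content matrices.
#
# A gene order is a tibble with columns `taxon`, `position` (1..n, clockwise
# from the genome origin), `symbol`, `sign` (+1/-1), carrying attribute
# `circular` (TRUE unless built otherwise). Several orders stack into one long
# tibble keyed by `taxon`.

new_gene_order <- function(df, circular = TRUE) {
  df <- as_tibble(df)
  stopifnot(all(c("taxon", "position", "symbol", "sign") %in% names(df)))
  attr(df, "circular") <- circular
  class(df) <- c("gene_order", class(df))
  df
}

is_circular_order <- function(o) isTRUE(attr(o, "circular") %||% TRUE)

#' Build a signed gene order from symbols and signs
#'
#' Convenience constructor used throughout the examples and tests.
#'
#' @param symbols Character vector in genomic order.
#' @param signs Integer vector of +1/-1 (or a character like `"+-+"`).
#' @param taxon Taxon label.
#' @param circular Is the order circular?
#' @return A `gene_order` tibble.
#' @export
gene_order <- function(symbols, signs = 1L, taxon = "g", circular = TRUE) {
  if (is.character(signs) && length(signs) == 1L) {
    signs <- ifelse(strsplit(signs, "")[[1]] == "+", 1L, -1L)
  }
  signs <- rep_len(as.integer(signs), length(symbols))
  stopifnot(all(signs %in% c(-1L, 1L)))
  new_gene_order(tibble(taxon = taxon, position = seq_along(symbols),
                        symbol = symbols, sign = signs), circular = circular)
}

#' Extract the signed gene order of a genome
#'
#' Genes are taken in genomic order (clockwise from the origin), restricted to
#' `gene_filter`, with polarity from the annotated strand. When `collapse_ir`
#' and an IR annotation are given, features inside IRB are dropped so the
#' order contains one copy of the repeat; any symbol still duplicated keeps
#' only its first occurrence clockwise from position 0 (logged).
#'
#' @param g A [plastome].
#' @param gene_filter Character vector of symbols to keep, or `"core91"`
#'   (default) for the packaged 91-gene core set, or `NULL` for all annotated
#'   standard genes.
#' @param collapse_ir Drop IRB features (default TRUE when `ir` is given).
#' @param ir Optional IR annotation from [find_inverted_repeat()].
#' @return A `gene_order` tibble.
#' @export
extract_signed_gene_order <- function(g, gene_filter = "core91",
                                      collapse_ir = !is.null(ir), ir = NULL) {
  ft <- g$features[g$features$kind %in% c("CDS", "tRNA", "rRNA"), , drop = FALSE]
  per_feat <- ft |> group_by(.data$feature_id) |>
    summarise(symbol = .data$symbol[1], strand = .data$strand[1],
              start = min(.data$start), end = max(.data$end),
              part_index = .data$part_index[1], .groups = "drop") |>
    arrange(.data$start)
  per_feat <- per_feat[per_feat$part_index == 1L, , drop = FALSE]
  if (identical(gene_filter, "core91")) gene_filter <- core91_cached()
  if (!is.null(gene_filter)) {
    per_feat <- per_feat[per_feat$symbol %in% gene_filter, , drop = FALSE]
  }
  if (collapse_ir && !is.null(ir)) {
    in_irb <- per_feat$start >= ir$irb[1] & per_feat$end <= ir$irb[2]
    per_feat <- per_feat[!in_irb, , drop = FALSE]
  }
  dup <- duplicated(per_feat$symbol)
  if (any(dup)) {
    inform(paste0(g$taxon, ": keeping first occurrence of duplicated gene(s): ",
                  paste(unique(per_feat$symbol[dup]), collapse = ", ")))
    per_feat <- per_feat[!dup, , drop = FALSE]
  }
  if (nrow(per_feat) == 0L) abort(paste0(g$taxon, ": no genes left after filtering"))
  new_gene_order(tibble(taxon = g$taxon, position = seq_len(nrow(per_feat)),
                        symbol = per_feat$symbol, sign = per_feat$strand),
                 circular = g$circular)
}

#' Sidedness index of signed gene orders
#'
#' The sidedness index is C_s = (n - n_SB) / (n - 1), where n is the number of
#' genes and n_SB the number of sided blocks, i.e. maximal runs of adjacent
#' genes on the same strand. On circular orders (the default; genomes are
#' circles) the first and last runs merge when they share a sign. C_s is 1
#' when all genes lie on one strand and 0 when strands strictly alternate on
#' a circular order.
#'
#' @param orders A `gene_order` tibble (one or several taxa stacked).
#' @param circular Count blocks circularly (default: the orders' own flag).
#' @return Tibble with one row per taxon: `taxon`, `n`, `n_sb`, `cs`.
#' @examples
#' sidedness_index(gene_order(letters[1:10], rep(1, 10)))
#' @export
sidedness_index <- function(orders, circular = NULL) {
  circ_default <- is_circular_order(orders)
  orders |> as_tibble() |> group_by(.data$taxon) |>
    summarise(res = list(sidedness1(.data$sign[order(.data$position)],
                                    circular %||% circ_default)),
              .groups = "drop") |>
    tidyr::unnest("res")
}

sidedness1 <- function(signs, circular) {
  n <- length(signs)
  if (n < 2L) abort("sidedness index needs at least 2 genes")
  n_sb <- 1L + sum(signs[-1L] != signs[-n])
  if (circular && n_sb > 1L && signs[1L] == signs[n]) n_sb <- n_sb - 1L
  tibble(n = n, n_sb = n_sb, cs = (n - n_sb) / (n - 1))
}

## ---------------------------------------------------------------------------
## Canonical adjacency pairs

signed_label <- function(symbol, sign) paste0(ifelse(sign > 0, "+", "-"), symbol)

#' Canonical form of a signed gene pair
#'
#' An adjacency read on one strand as (x, y) reads (-y, -x) on the other;
#' both renderings denote the same physical junction. The canonical form is
#' the lexicographically smaller of the two renderings, so pair identity is
#' strand-agnostic.
#'
#' @param left,right Signed labels like `"+psbA"`.
#' @return Character vector of canonical `"left|right"` pair ids.
#' @export
canonical_pair_id <- function(left, right) {
  flip <- function(x) ifelse(substr(x, 1, 1) == "+",
                             paste0("-", substr(x, 2, nchar(x))),
                             paste0("+", substr(x, 2, nchar(x))))
  a <- paste0(left, "|", right)
  b <- paste0(flip(right), "|", flip(left))
  # byte-wise comparison: locale-independent canonical form
  b_smaller <- vapply(seq_along(a), function(i) {
    a[i] != b[i] && order(c(a[i], b[i]), method = "radix")[1] == 2L
  }, logical(1))
  ifelse(b_smaller, b, a)
}

#' All adjacent signed gene pairs of gene orders
#'
#' One pair per adjacent couple: n pairs for a circular order of n genes,
#' n - 1 for a linear one, each in canonical form.
#'
#' @param orders A `gene_order` tibble.
#' @return Tibble `taxon`, `left`, `right`, `pair` (canonical id).
#' @export
canonical_pairs <- function(orders) {
  circ <- is_circular_order(orders)
  orders |> as_tibble() |> group_by(.data$taxon) |>
    summarise(res = list({
      o <- order(.data$position)
      lab <- signed_label(.data$symbol[o], .data$sign[o])
      n <- length(lab)
      idx <- if (circ) cbind(1:n, c(2:n, 1L)) else cbind(1:(n - 1L), 2:n)
      tibble(left = lab[idx[, 1]], right = lab[idx[, 2]],
             pair = canonical_pair_id(lab[idx[, 1]], lab[idx[, 2]]))
    }), .groups = "drop") |>
    tidyr::unnest("res")
}

#' Shared gene-pair presence/absence matrix
#'
#' Collects the canonical signed pairs of all taxa and keeps those present in
#' at least `min_share` taxa. A cell is 1 when the pair is present, 0 when
#' both genes exist in the taxon but are not adjacent, and NA when at least
#' one of the two genes is absent from that taxon (the gray-box case).
#'
#' @param orders A `gene_order` tibble with several taxa.
#' @param min_share Minimum number of taxa sharing a pair (default 5).
#' @return A long tibble `pair`, `taxon`, `state` of class `pair_matrix`;
#'   use [pair_matrix_wide()] for the rows-by-taxa form.
#' @export
shared_pair_matrix <- function(orders, min_share = 5L) {
  if (min_share < 2L) abort("min_share must be at least 2")
  taxa <- unique(orders$taxon)
  if (length(taxa) < 2L) abort("need at least two gene orders")
  pairs <- canonical_pairs(orders)
  keep <- pairs |> distinct(.data$taxon, .data$pair) |> count(.data$pair) |>
    filter(.data$n >= min_share) |> pull("pair")
  keep <- sort(keep)
  genes_by_taxon <- orders |> as_tibble() |>
    group_by(.data$taxon) |> summarise(genes = list(.data$symbol), .groups = "drop")
  grid <- tidyr::expand_grid(pair = keep, taxon = sort(taxa))
  present <- pairs |> distinct(.data$pair, .data$taxon) |> mutate(p = 1L)
  strip <- function(x) substr(x, 2, nchar(x))
  grid <- grid |>
    left_join(present, by = c("pair", "taxon")) |>
    left_join(genes_by_taxon, by = "taxon") |>
    mutate(
      g1 = strip(sub("\\|.*$", "", .data$pair)),
      g2 = strip(sub("^.*\\|", "", .data$pair)),
      both = purrr::map2_lgl(.data$genes, paste(.data$g1, .data$g2, sep = "\r"),
        function(gs, pp) {
          gg <- strsplit(pp, "\r", fixed = TRUE)[[1]]
          all(gg %in% gs)
        }),
      state = dplyr::case_when(!is.na(.data$p) ~ 1L, .data$both ~ 0L,
                               TRUE ~ NA_integer_)) |>
    select("pair", "taxon", "state")
  structure(grid, class = c("pair_matrix", class(grid)))
}

#' Widen a pair matrix to rows = pairs, columns = taxa
#'
#' @param pm Result of [shared_pair_matrix()].
#' @param path Optional TSV output path.
#' @return Wide tibble.
#' @export
pair_matrix_wide <- function(pm, path = NULL) {
  wide <- tidyr::pivot_wider(as_tibble(pm), names_from = "taxon",
                             values_from = "state")
  if (!is.null(path)) {
    write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wide
}

#' Core gene set shared by complete genomes
#'
#' Intersection of normalized standard-gene symbols over all complete
#' genomes; incomplete genomes are excluded with a warning.
#'
#' @param genomes A `plastome` or list of them.
#' @return Sorted character vector of shared symbols.
#' @export
core_gene_set <- function(genomes) {
  genomes <- as_plastome_list(genomes)
  complete <- vapply(genomes, function(g) isTRUE(g$complete), logical(1))
  if (any(!complete)) {
    warn(paste0("excluding incomplete genome(s): ",
                paste(names(genomes)[!complete], collapse = ", ")))
  }
  genomes <- genomes[complete]
  stopifnot(length(genomes) >= 1L)
  sets <- lapply(genomes, function(g)
    unique(g$features$symbol[g$features$kind %in% c("CDS", "tRNA", "rRNA")]))
  sort(Reduce(intersect, sets))
}

## ---------------------------------------------------------------------------
## grimm-style text IO: one block per genome, `>taxon` then signed symbols

#' Read/write gene orders in grimm-style text
#'
#' One genome per block: a `>taxon` header line followed by the signed
#' symbols in order (whitespace-separated, `-` prefix for reverse strand).
#'
#' @param path File path.
#' @param orders A `gene_order` tibble (for writing).
#' @param circular Circular flag to attach on read.
#' @return `read_grimm`: a `gene_order` tibble.
#' @export
read_grimm <- function(path, circular = TRUE) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  stopifnot(length(heads) > 0L)
  blocks <- split(lines, cumsum(grepl("^>", lines)))
  out <- lapply(blocks, function(b) {
    taxon <- sub("^>\\s*", "", b[1])
    toks <- unlist(strsplit(paste(b[-1], collapse = " "), "[[:space:]]+"))
    toks <- toks[nzchar(toks) & toks != "$"]
    sign <- ifelse(grepl("^-", toks), -1L, 1L)
    sym <- sub("^[+-]", "", toks)
    tibble(taxon = taxon, position = seq_along(sym), symbol = sym, sign = sign)
  })
  new_gene_order(bind_rows(out), circular = circular)
}

#' @rdname read_grimm
#' @export
write_grimm <- function(orders, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tx in unique(orders$taxon)) {
    o <- orders[orders$taxon == tx, , drop = FALSE]
    o <- o[order(o$position), , drop = FALSE]
    writeLines(paste0(">", tx), con)
    writeLines(paste(signed_label(o$symbol, o$sign), collapse = " "), con)
  }
  invisible(path)
}
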