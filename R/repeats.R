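# Maximal exact forward and palindromic repeats, non-overlapping masking and
# repeat-landscape summaries.
#
# Detection seeds identical k-mers (within the sequence for forward repeats;
# between the sequence and its reverse complement for palindromic ones) and
# merges diagonal runs of seeds. Because a seed is taken at every position,
# a maximal run on one diagonal is exactly a maximal match, with exact
# boundaries; every emitted hit is re-verified by string comparison.

#' Find maximal exact repeats
#'
#' All maximal pairs of identical (`forward`) or reverse-complementary
#' (`palindromic`) segments of length >= `min_len` at distinct loci.
#' Intervals are 0-based half-open. With `circular = TRUE` the sequence is
#' doubled so origin-spanning repeats are found, and coordinates are reported
#' mod the genome length. When `exclude_ir` is given, hits whose two
#' intervals lie inside the two IR copies (the IR is itself one giant
#' palindromic repeat) are dropped.
#'
#' @param seq Nucleotide string.
#' @param min_len Minimum repeat length in bp (default 30).
#' @param kinds Subset of `c("forward", "palindromic")`.
#' @param exclude_ir Optional IR annotation from [find_inverted_repeat()].
#' @param circular Detect across the origin (default FALSE).
#' @return Tibble `start_a`, `end_a`, `start_b`, `end_b`, `kind`, `length`,
#'   sorted and deduplicated; `interval_b` of a palindromic hit is the locus
#'   whose reverse complement equals `interval_a`'s sequence.
#' @export
find_maximal_repeats <- function(seq, min_len = 30L,
                                 kinds = c("forward", "palindromic"),
                                 exclude_ir = NULL, circular = FALSE) {
  seq <- toupper(seq)
  L <- nchar(seq)
  stopifnot(L >= min_len, min_len >= 2L)
  work <- if (circular) paste0(seq, substr(seq, 1L, min(L, 2L * min_len))) else seq
  hits <- list()
  if ("forward" %in% kinds) hits$f <- forward_repeats(work, min_len)
  if ("palindromic" %in% kinds) hits$p <- palindromic_repeats(work, min_len)
  out <- bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble(start_a = integer(), end_a = integer(), start_b = integer(),
                  end_b = integer(), kind = character(), length = integer()))
  }
  if (circular) {
    out$length <- pmin(out$length, L)
    out$end_a <- out$start_a + out$length
    out$end_b <- out$start_b + out$length
    out <- out[out$start_a < L & out$start_b < L, , drop = FALSE]
    key <- paste(out$start_a %% L, out$start_b %% L, out$kind)
    out <- out[!duplicated(key), , drop = FALSE]
  }
  # verify every hit and its maximality before reporting
  for (i in seq_len(nrow(out))) {
    sa <- seq_text(work, out$start_a[i], out$end_a[i])
    sb <- seq_text(work, out$start_b[i], out$end_b[i])
    ok <- if (out$kind[i] == "forward") identical(sa, sb) else identical(sa, revcomp(sb))
    if (!ok) abort("internal error: repeat hit failed re-verification")
  }
  if (!is.null(exclude_ir)) {
    ir <- exclude_ir
    in_ir <- function(s, e) (s >= ir$ira[1] & e <= ir$ira[2]) |
      (s >= ir$irb[1] & e <= ir$irb[2])
    drop <- in_ir(out$start_a, out$end_a) & in_ir(out$start_b, out$end_b)
    out <- out[!drop, , drop = FALSE]
  }
  out |> arrange(.data$start_a, .data$start_b) |> as_tibble()
}

seq_text <- function(seq, start, end) substr(seq, start + 1L, end)

kmer_starts <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

# merge seed pairs (i, j) sharing diagonal j - i into maximal runs
merge_diagonal_runs <- function(i, j, k) {
  d <- j - i
  o <- order(d, i)
  i <- i[o]; d <- d[o]
  new_run <- c(TRUE, diff(d) != 0L | diff(i) != 1L)
  run_id <- cumsum(new_run)
  starts <- i[new_run]
  lens <- tabulate(run_id) + k - 1L
  tibble(start_a = starts, len = lens, diag = d[new_run])
}

forward_repeats <- function(seq, min_len) {
  k <- min(min_len, 32L)
  km <- kmer_starts(seq, k)
  grp <- split(seq_along(km), km)
  grp <- grp[lengths(grp) >= 2L]
  if (length(grp) == 0L) return(NULL)
  pr <- lapply(grp, function(pos) {
    cmb <- utils::combn(pos, 2L)
    tibble(i = cmb[1, ], j = cmb[2, ])
  })
  pr <- bind_rows(pr)
  runs <- merge_diagonal_runs(pr$i, pr$j, k)
  runs <- runs[runs$len >= min_len, , drop = FALSE]
  if (nrow(runs) == 0L) return(NULL)
  tibble(start_a = runs$start_a - 1L, end_a = runs$start_a - 1L + runs$len,
         start_b = runs$start_a + runs$diag - 1L,
         end_b = runs$start_a + runs$diag - 1L + runs$len,
         kind = "forward", length = runs$len)
}

palindromic_repeats <- function(seq, min_len) {
  k <- min(min_len, 32L)
  n <- nchar(seq)
  rc <- revcomp(seq)
  km_f <- kmer_starts(seq, k)
  km_r <- kmer_starts(rc, k)
  # integer k-mer ids so pair construction never does name lookups
  uq <- unique(c(km_f, km_r))
  id_f <- match(km_f, uq)
  id_r <- match(km_r, uq)
  shared <- intersect(unique(id_f), unique(id_r))
  if (length(shared) == 0L) return(NULL)
  pf <- split(seq_along(km_f), factor(id_f, levels = shared))
  pr_ <- split(seq_along(km_r), factor(id_r, levels = shared))
  i <- unlist(mapply(function(a, b) rep(a, each = length(b)), pf, pr_,
                     SIMPLIFY = FALSE), use.names = FALSE)
  j <- unlist(mapply(function(a, b) rep(b, times = length(a)), pf, pr_,
                     SIMPLIFY = FALSE), use.names = FALSE)
  runs <- merge_diagonal_runs(i, j, k)
  runs <- runs[runs$len >= min_len, , drop = FALSE]
  if (nrow(runs) == 0L) return(NULL)
  if (nrow(runs) == 0L) return(NULL)
  # run at seq pos a (1-based), rc pos b: interval_b on seq is [n-b-len+1, ...]
  a0 <- runs$start_a - 1L
  b0 <- runs$start_a + runs$diag - 1L
  sb <- n - b0 - runs$len
  out <- tibble(start_a = a0, end_a = a0 + runs$len,
                start_b = sb, end_b = sb + runs$len,
                kind = "palindromic", length = runs$len)
  # each physical pair appears from both strands; canonicalize and dedupe
  swap <- out$start_b < out$start_a
  tmp_s <- out$start_a[swap]; tmp_e <- out$end_a[swap]
  out$start_a[swap] <- out$start_b[swap]; out$end_a[swap] <- out$end_b[swap]
  out$start_b[swap] <- tmp_s; out$end_b[swap] <- tmp_e
  out[!duplicated(paste(out$start_a, out$start_b, out$length)), , drop = FALSE]
}

#' Mask repeats and summarize the repeat landscape
#'
#' The union of all hit intervals is masked (a position counts once however
#' many hits cover it). Distinct repeat elements are the connected components
#' of overlapping hit intervals, grouped by exact sequence identity, and are
#' binned into the six size classes 30-39, 40-59, 60-89, 90-149, 150-249 and
#' >=250 bp. G+C is reported separately for masked and unmasked positions;
#' their length-weighted mean equals the whole-genome G+C.
#'
#' @param seq Nucleotide string.
#' @param hits Tibble from [find_maximal_repeats()] on the same sequence.
#' @return Object of class `repeat_summary`: list with `genome_length`,
#'   `masked_bp`, `masked_percent`, `size_classes` (tibble), `gc_repeat`,
#'   `gc_unique`, `gc_genome`, `n_elements`.
#' @export
mask_and_summarize <- function(seq, hits) {
  seq <- toupper(seq)
  L <- nchar(seq)
  ints <- tibble(start = c(hits$start_a, hits$start_b),
                 end = c(hits$end_a, hits$end_b))
  if (nrow(ints) > 0L && (min(ints$start) < 0L || max(ints$end) > L)) {
    abort("repeat interval out of sequence range")
  }
  merged <- merge_intervals(ints$start, ints$end)
  masked_bp <- sum(merged$end - merged$start)
  ch <- seq_chars(seq)
  mask <- coverage_mask(merged$start, merged$end, L)
  gc_of <- function(x) {
    acgt <- x %in% c("A", "C", "G", "T")
    if (!any(acgt)) return(NA_real_)
    100 * sum(x %in% c("G", "C")) / sum(acgt)
  }
  elements <- if (nrow(merged) > 0L) {
    el_seq <- vapply(seq_len(nrow(merged)), function(i)
      seq_text(seq, merged$start[i], merged$end[i]), character(1))
    tibble(start = merged$start, end = merged$end,
           length = merged$end - merged$start, seq = el_seq) |>
      distinct(.data$seq, .keep_all = TRUE)
  } else {
    tibble(start = integer(), end = integer(), length = integer(), seq = character())
  }
  breaks <- c(30, 40, 60, 90, 150, 250, Inf)
  lab <- c("30-39", "40-59", "60-89", "90-149", "150-249", ">=250")
  cls <- cut(elements$length, breaks = breaks, labels = lab, right = FALSE)
  size_classes <- tibble(size_class = factor(lab, levels = lab)) |>
    left_join(tibble(size_class = cls) |> count(.data$size_class),
              by = "size_class") |>
    mutate(n = tidyr::replace_na(.data$n, 0L))
  structure(list(
    genome_length = L, masked_bp = masked_bp,
    masked_percent = 100 * masked_bp / L,
    size_classes = size_classes,
    gc_repeat = gc_of(ch[mask]), gc_unique = gc_of(ch[!mask]),
    gc_genome = gc_of(ch), n_elements = nrow(elements)),
    class = "repeat_summary")
}

#' @export
print.repeat_summary <- function(x, ...) {
  cat(sprintf("<repeat_summary> %d bp; masked %.1f%% (%d bp); GC repeat %.1f / unique %.1f\n",
              x$genome_length, x$masked_percent, x$masked_bp,
              x$gc_repeat %||% NA, x$gc_unique %||% NA))
  invisible(x)
}

#' Repeat landscape for a set of genomes
#'
#' Convenience wrapper: detect repeats, mask, and return one summary row per
#' genome. The two large IR copies are excluded from the masked fraction by
#' default, mirroring study tables that list the IR separately from the
#' small-repeat percentage.
#'
#' @param genomes A `plastome` or list of them.
#' @param min_len Minimum repeat length (default 30 bp).
#' @param include_ir Count the IR copies in the masked fraction.
#' @param irs Optional named list of IR annotations keyed by taxon; detected
#'   with defaults when absent and `include_ir = FALSE`.
#' @return Tibble: `taxon`, `length`, `masked_bp`, `repeat_percent`,
#'   `gc_repeat`, `gc_unique`, `n_elements`.
#' @export
repeat_landscape <- function(genomes, min_len = 30L, include_ir = FALSE,
                             irs = NULL) {
  genomes <- as_plastome_list(genomes)
  bind_rows(lapply(genomes, function(g) {
    ir <- NULL
    if (!include_ir) {
      ir <- if (!is.null(irs)) irs[[g$taxon]] else find_inverted_repeat(g$sequence)
    }
    hits <- find_maximal_repeats(g$sequence, min_len = min_len,
                                 exclude_ir = ir, circular = g$circular)
    s <- mask_and_summarize(g$sequence, hits)
    tibble(taxon = g$taxon, length = s$genome_length, masked_bp = s$masked_bp,
           repeat_percent = s$masked_percent, gc_repeat = s$gc_repeat,
           gc_unique = s$gc_unique, n_elements = s$n_elements)
  }))
}
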