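# Large inverted repeat detection, quadripartite partitioning, and rDNA
# operon integrity.

#' Detect the large inverted repeat of a circular genome
#'
#' Finds the longest pair of exact, non-overlapping, reverse-complementary
#' segments of length >= `min_len` (seeded k-mer matching against the reverse
#' complement with maximal extension), and derives the quadripartite
#' partition: the longer single-copy gap is the LSC, the shorter the SSC.
#' Ties in length are broken toward the candidate containing `rrs_span`
#' (the IR typically encodes the rRNA operon) and then by leftmost IRA start.
#'
#' @param seq Nucleotide string (circular).
#' @param min_len Minimum IR length in bp (default 1000; true plastome IRs
#'   are far larger).
#' @param rrs_span Optional 0-based half-open interval of the `rrs` gene used
#'   only for tie-breaking.
#' @return `NULL` when no IR is found, otherwise an object of class
#'   `ir_annotation`: list with `ira`, `irb`, `lsc`, `ssc` (0-based half-open
#'   intervals, `lsc`/`ssc` possibly wrapping the origin with end > genome
#'   length), `ir_len` and `genome_length`. The exact reverse-complement
#'   identity of the two copies is asserted on every detection.
#' @export
find_inverted_repeat <- function(seq, min_len = 1000L, rrs_span = NULL) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L <= 2L * min_len) return(NULL)
  hits <- find_maximal_repeats(seq, min_len = min_len, kinds = "palindromic")
  if (nrow(hits) == 0L) return(NULL)
  # candidate copies must not overlap
  hits <- hits[hits$end_a <= hits$start_b | hits$end_b <= hits$start_a, , drop = FALSE]
  if (nrow(hits) == 0L) {
    inform("inverted-repeat candidates overlap; no IR annotated")
    return(NULL)
  }
  best_len <- max(hits$length)
  cand <- hits[hits$length == best_len, , drop = FALSE]
  if (nrow(cand) > 1L && !is.null(rrs_span)) {
    holds <- (cand$start_a <= rrs_span[1] & cand$end_a >= rrs_span[2]) |
      (cand$start_b <= rrs_span[1] & cand$end_b >= rrs_span[2])
    if (any(holds)) cand <- cand[holds, , drop = FALSE]
  }
  cand <- cand[order(cand$start_a), , drop = FALSE][1, , drop = FALSE]
  ira <- c(cand$start_a, cand$end_a)
  irb <- c(cand$start_b, cand$end_b)
  # single-copy gaps on the circle: between ira end and irb start, and
  # between irb end and ira start (wrapping)
  gap1 <- c(ira[2], irb[1])
  gap2 <- c(irb[2], ira[1] + L)
  if (diff(gap1) >= diff(gap2)) {
    lsc <- gap1; ssc <- gap2
  } else {
    lsc <- gap2; ssc <- gap1
  }
  ann <- structure(list(ira = ira, irb = irb, lsc = lsc, ssc = ssc,
                        ir_len = unname(diff(ira)), genome_length = L),
                   class = "ir_annotation")
  stopifnot(identical(sub0(seq, ira[1], ira[2]),
                      revcomp(sub0(seq, irb[1], irb[2]))),
            2L * ann$ir_len + diff(lsc) + diff(ssc) == L)
  ann
}

#' @export
print.ir_annotation <- function(x, ...) {
  cat(sprintf("<ir_annotation> IR %d bp: IRA [%d,%d) IRB [%d,%d); LSC %d bp, SSC %d bp\n",
              x$ir_len, x$ira[1], x$ira[2], x$irb[1], x$irb[2],
              diff(x$lsc), diff(x$ssc)))
  invisible(x)
}

# region of a 0-based interval under an ir_annotation; genes spanning an
# IR/SC junction are assigned to the single-copy side
region_of_span <- function(start, end, ir) {
  L <- ir$genome_length
  within <- function(iv, s, e) {
    s2 <- s; e2 <- e
    if (iv[2] > L) { # wrapped region: shift coordinates near origin
      if (e2 <= iv[1]) { s2 <- s + L; e2 <- e + L }
    }
    s2 >= iv[1] && e2 <= iv[2]
  }
  if (within(ir$ira, start, end) || within(ir$irb, start, end)) return("IR")
  if (within(ir$lsc, start, end)) return("LSC")
  if (within(ir$ssc, start, end)) return("SSC")
  # spans a junction: count overlap with the two single-copy regions
  ov <- function(iv) {
    s <- max(iv[1], start); e <- min(iv[2], end)
    a <- max(0L, e - s)
    if (iv[2] > L) { # also try the wrapped image
      s <- max(iv[1], start + L); e <- min(iv[2], end + L)
      a <- max(a, e - s)
    }
    a
  }
  if (ov(ir$lsc) >= ov(ir$ssc)) "LSC" else "SSC"
}

#' Load the packaged ancestral partition-side reference
#'
#' Curated table mapping standard gene symbols to their side relative to the
#' rDNA operon in ancestral-pattern (prasinophycean/streptophyte-like)
#' quadripartite plastomes.
#'
#' @return Tibble `symbol`, `side` with side in
#'   \{rdna, ssc_side, lsc_side\}.
#' @export
ancestral_sides <- function() {
  path <- system.file("extdata", "ancestral_sides.tsv", package = "plastarch")
  as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

#' Classify gene partitioning against the ancestral pattern
#'
#' Assigns each standard gene of a genome to IR, LSC or SSC from its
#' coordinates (genes spanning an IR junction go to the single-copy side),
#' looks up its ancestral side relative to the rDNA operon, and flags
#' deviations: genes observed in the single-copy region opposite their
#' ancestral side.
#'
#' @param g A [plastome] with an IR.
#' @param ir IR annotation from [find_inverted_repeat()].
#' @param reference Ancestral-side table (default [ancestral_sides()]).
#' @return Tibble `symbol`, `region`, `ancestral_side`, `deviant`. Genes
#'   absent from the reference get `ancestral_side = "unassigned"`.
#' @export
classify_partitioning <- function(g, ir, reference = ancestral_sides()) {
  stopifnot(!is.null(ir))
  ft <- g$features[g$features$kind %in% c("CDS", "tRNA", "rRNA"), , drop = FALSE]
  per_feat <- ft |> group_by(.data$feature_id) |>
    summarise(symbol = .data$symbol[1], start = min(.data$start),
              end = max(.data$end), .groups = "drop") |> arrange(.data$start)
  # one row per symbol: IR-duplicated genes keep the IRA copy
  per_feat <- per_feat[!duplicated(per_feat$symbol), , drop = FALSE]
  region <- vapply(seq_len(nrow(per_feat)), function(i)
    region_of_span(per_feat$start[i], per_feat$end[i], ir), character(1))
  out <- tibble(symbol = per_feat$symbol, region = region) |>
    left_join(reference, by = "symbol") |>
    mutate(ancestral_side = tidyr::replace_na(.data$side, "unassigned")) |>
    select(-"side")
  out$deviant <- (out$region == "LSC" & out$ancestral_side == "ssc_side") |
    (out$region == "SSC" & out$ancestral_side == "lsc_side")
  out
}

#' Check integrity and orientation of the rDNA operon
#'
#' The ancestral chloroplast rDNA operon is the cotranscribed run
#' rrs - trnI(gau) - trnA(ugc) - rrl - rrf. An internal adjacency is broken
#' when the two genes are not adjacent in the signed order, not colinear in
#' sign, or (when coordinates are supplied) separated by more than
#' `max_spacer` bp. Orientation is reported relative to the SSC when an IR
#' annotation and coordinates allow it.
#'
#' @param o A `gene_order` tibble for one taxon containing the five operon
#'   genes.
#' @param coords Optional tibble `symbol`, `start`, `end` with genomic
#'   coordinates of the operon genes.
#' @param ir Optional `ir_annotation` for orientation.
#' @param max_spacer Maximum intergenic spacer within the operon (default
#'   3000 bp).
#' @return List of class `operon_report`: `genes`, `breakpoints` (character
#'   vector of broken adjacencies like `"rrs-trnI(gau)"`), `intact`,
#'   `orientation` in \{toward_SSC, toward_LSC, mixed, not_applicable\}.
#' @export
rdna_operon_check <- function(o, coords = NULL, ir = NULL, max_spacer = 3000L) {
  operon <- c("rrs", "trnI(gau)", "trnA(ugc)", "rrl", "rrf")
  o <- o[order(o$position), , drop = FALSE]
  missing <- setdiff(operon, o$symbol)
  if (length(missing) > 0L) {
    abort(paste0("rDNA operon gene(s) missing from gene order: ",
                 paste(missing, collapse = ", ")))
  }
  n <- nrow(o)
  sym <- o$symbol; sgn <- o$sign
  circ <- is_circular_order(o)
  nxt <- function(i) if (i < n) i + 1L else if (circ) 1L else NA_integer_
  prv <- function(i) if (i > 1L) i - 1L else if (circ) n else NA_integer_
  breakpoints <- character(0)
  for (k in seq_len(length(operon) - 1L)) {
    g1 <- operon[k]; g2 <- operon[k + 1L]
    i <- match(g1, sym)
    j <- match(g2, sym)
    adjacent_fwd <- !is.na(nxt(i)) && nxt(i) == j && sgn[i] == sgn[j] && sgn[i] == 1L
    adjacent_rev <- !is.na(prv(i)) && prv(i) == j && sgn[i] == sgn[j] && sgn[i] == -1L
    ok <- adjacent_fwd || adjacent_rev
    if (ok && !is.null(coords)) {
      c1 <- coords[coords$symbol == g1, , drop = FALSE]
      c2 <- coords[coords$symbol == g2, , drop = FALSE]
      if (nrow(c1) == 1L && nrow(c2) == 1L) {
        gap <- max(c1$start, c2$start) - min(c1$end, c2$end)
        if (!is.na(gap) && gap > max_spacer) ok <- FALSE
      }
    }
    if (!ok) breakpoints <- c(breakpoints, paste0(g1, "-", g2))
  }
  orientation <- "not_applicable"
  if (length(breakpoints) == 0L) {
    op_sign <- sgn[match("rrs", sym)]
    if (!is.null(ir) && !is.null(coords)) {
      # transcription runs rrs -> rrf; toward_SSC if rrf lies closer to the
      # SSC-facing end of its IR copy than rrs does
      cr <- coords[match(c("rrs", "rrf"), coords$symbol), , drop = FALSE]
      if (all(!is.na(cr$start))) {
        d_ssc <- function(pos) circ_gap(pos, ir$ssc[1] %% ir$genome_length,
                                        ir$genome_length)
        orientation <- if (d_ssc(cr$start[2]) < d_ssc(cr$start[1]))
          "toward_SSC" else "toward_LSC"
      }
    } else {
      orientation <- if (op_sign == 1L) "forward" else "reverse"
    }
  } else if (length(breakpoints) < 4L) {
    orientation <- "mixed"
  }
  structure(list(genes = operon, breakpoints = breakpoints,
                 intact = length(breakpoints) == 0L,
                 orientation = orientation),
            class = "operon_report")
}

# clockwise circular distance from pos to target
circ_gap <- function(pos, target, L) (target - pos) %% L

#' @export
print.operon_report <- function(x, ...) {
  cat("<operon_report>", if (x$intact) "intact" else
    paste("broken at:", paste(x$breakpoints, collapse = ", ")),
    "; orientation:", x$orientation, "\n")
  invisible(x)
}

#' Annotate the IR architecture of a genome
#'
#' Bundles IR detection (with the rrs tie-break), the junction report and the
#' quadripartite partition of one genome.
#'
#' @param g A [plastome].
#' @param min_len Minimum IR length (default 1000 bp).
#' @return List with `ir` (or NULL), `junctions` (tibble of the four
#'   junction positions J_LA, J_AS, J_SB, J_BL with flanking genes) and
#'   `partition` (from [classify_partitioning()]), or NULL fields when no IR
#'   is present.
#' @export
ir_architecture <- function(g, min_len = 1000L) {
  rrs_rows <- g$features[g$features$symbol == "rrs", , drop = FALSE]
  rrs_span <- if (nrow(rrs_rows) > 0L) c(min(rrs_rows$start), max(rrs_rows$end)) else NULL
  ir <- find_inverted_repeat(g$sequence, min_len = min_len, rrs_span = rrs_span)
  if (is.null(ir)) {
    return(list(ir = NULL, junctions = NULL, partition = NULL))
  }
  L <- ir$genome_length
  jx <- tibble(
    junction = c("J_LA", "J_AS", "J_SB", "J_BL"),
    position = c(ir$ira[1], ir$ira[2], ir$irb[1], ir$irb[2]) %% L)
  ft <- g$features[g$features$kind %in% c("CDS", "tRNA", "rRNA"), , drop = FALSE]
  jx$flanking <- vapply(jx$position, function(p) {
    near <- ft[abs((ft$start + ft$end) / 2 - p) <= 5000, , drop = FALSE]
    if (nrow(near) == 0L) return("")
    paste(unique(near$symbol), collapse = ",")
  }, character(1))
  list(ir = ir, junctions = jx, partition = classify_partitioning(g, ir))
}

#' Write IR/LSC/SSC coordinates as BED
#'
#' @param ir An `ir_annotation`.
#' @param taxon Chromosome/taxon name for the BED lines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ir_bed <- function(ir, taxon, path) {
  L <- ir$genome_length
  rows <- list(c("IRA", ir$ira), c("IRB", ir$irb), c("LSC", ir$lsc), c("SSC", ir$ssc))
  lines <- vapply(rows, function(r) {
    s <- as.integer(r[2]) %% L
    e <- as.integer(r[3])
    e <- if (e > L && s + (e - as.integer(r[2])) > L) e %% L else min(e, L)
    sprintf("%s\t%d\t%d\t%s", taxon, s, if (e <= s) L else e, r[1])
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
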