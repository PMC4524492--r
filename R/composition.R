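# Nucleotide composition summaries.

#' Percent A+T of a sequence
#'
#' Computed as (A+T) / (A+C+G+T) x 100; ambiguity codes (N etc.) are excluded
#' from both numerator and denominator.
#'
#' @param seq Character scalar nucleotide sequence.
#' @return Numeric percentage in \[0, 100\].
#' @export
at_content <- function(seq) {
  stopifnot(nchar(seq) > 0L)
  ch <- seq_chars(seq)
  n_at <- sum(ch == "A" | ch == "T")
  n_acgt <- sum(ch %in% c("A", "C", "G", "T"))
  if (n_acgt == 0L) return(NA_real_)
  100 * n_at / n_acgt
}

# percent G+C, ambiguity excluded; internal twin of at_content
gc_content <- function(seq) {
  ch <- seq_chars(seq)
  n_gc <- sum(ch == "G" | ch == "C")
  n_acgt <- sum(ch %in% c("A", "C", "G", "T"))
  if (n_acgt == 0L) return(NA_real_)
  100 * n_gc / n_acgt
}

#' G+C content by codon position
#'
#' Concatenates a set of in-frame coding sequences and reports the percent G+C
#' at codon positions 1, 2 and 3. Ambiguity codes are excluded from both
#' numerator and denominator at each position.
#'
#' @param cds_list Character vector (or list) of in-frame coding sequences;
#'   every element must have length divisible by 3. Names, if present, are used
#'   in error messages.
#' @return A one-row tibble with columns `gc1`, `gc2`, `gc3` (percent) and
#'   `n_codons`.
#' @examples
#' gc_by_codon_position(c("ATGGCC"))
#' @export
gc_by_codon_position <- function(cds_list) {
  cds_list <- unlist(cds_list, use.names = TRUE)
  stopifnot(length(cds_list) >= 1L)
  bad <- which(nchar(cds_list) %% 3L != 0L)
  if (length(bad) > 0L) {
    nm <- names(cds_list)[bad[1]] %||% as.character(bad[1])
    if (is.na(nm) || nm == "") nm <- as.character(bad[1])
    abort(paste0("coding sequence length not divisible by 3: ", nm))
  }
  ch <- seq_chars(paste(cds_list, collapse = ""))
  n_codons <- length(ch) %/% 3L
  stopifnot(n_codons >= 1L)
  pos <- rep_len(1:3, length(ch))
  gc_at <- function(p) {
    x <- ch[pos == p]
    keep <- x %in% c("A", "C", "G", "T")
    if (!any(keep)) return(NA_real_)
    100 * sum(x[keep] %in% c("G", "C")) / sum(keep)
  }
  tibble(gc1 = gc_at(1), gc2 = gc_at(2), gc3 = gc_at(3), n_codons = n_codons)
}

#' Per-genome composition table
#'
#' Whole-genome A+T percent plus codon-position G+C over all annotated CDS
#' features of one or more genomes.
#'
#' @param genomes A `plastome` or list of them.
#' @param include_stops Keep annotated stop codons inside the CDS span
#'   (default TRUE).
#' @return Tibble with one row per genome: `taxon`, `at_percent`, `gc1`,
#'   `gc2`, `gc3`, `n_codons`.
#' @export
composition_table <- function(genomes, include_stops = TRUE) {
  genomes <- as_plastome_list(genomes)
  rows <- lapply(genomes, function(g) {
    cds <- cds_sequences(g)
    if (!include_stops) {
      cds <- vapply(cds, function(s) substr(s, 1L, nchar(s) - 3L), character(1))
      cds <- cds[nchar(cds) > 0L]
    }
    if (length(cds) == 0L) {
      gc <- tibble(gc1 = NA_real_, gc2 = NA_real_, gc3 = NA_real_, n_codons = 0L)
    } else {
      gc <- gc_by_codon_position(cds)
    }
    tibble(taxon = g$taxon, at_percent = at_content(g$sequence)) |>
      dplyr::bind_cols(gc)
  })
  bind_rows(rows)
}
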