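# Shared low-level helpers: sequences as plain uppercase character scalars over
# {A,C,G,T,N}; intervals are 0-based half-open [start, end).

#' Reverse complement of a nucleotide string
#'
#' @param seq Character scalar over A/C/G/T/N (case-insensitive).
#' @return Uppercase reverse-complemented string.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

# vector-of-single-characters view, uppercase
seq_chars <- function(seq) strsplit(toupper(seq), "", fixed = TRUE)[[1]]

# random sequence with a given AT fraction (percent), optionally seeded by caller
random_dna <- function(n, at_percent = 65) {
  at <- at_percent / 100
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# substring by 0-based half-open interval; no wrapping
sub0 <- function(seq, start, end) substr(seq, start + 1L, end)

# extract circular interval [start, end) mod L; end may exceed L
sub0_circ <- function(seq, start, end) {
  L <- nchar(seq)
  start <- start %% L
  len <- end - start
  if (start + len <= L) return(substr(seq, start + 1L, start + len))
  paste0(substr(seq, start + 1L, L), substr(seq, 1L, len - (L - start)))
}

# merge overlapping/adjacent 0-based half-open intervals given as a 2-col matrix
merge_intervals <- function(starts, ends) {
  if (length(starts) == 0L) {
    return(tibble(start = integer(), end = integer()))
  }
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  out_s <- starts[1]; out_e <- ends[1]; k <- 1L
  if (length(starts) > 1L) {
    for (i in 2:length(starts)) {
      if (starts[i] <= out_e[k]) {
        out_e[k] <- max(out_e[k], ends[i])
      } else {
        k <- k + 1L
        out_s[k] <- starts[i]; out_e[k] <- ends[i]
      }
    }
  }
  tibble(start = out_s, end = out_e)
}

# logical coverage vector of length L for a set of (possibly wrapped) intervals
coverage_mask <- function(starts, ends, L) {
  mask <- logical(L)
  for (i in seq_along(starts)) {
    s <- starts[i] %% L
    e <- ends[i]
    if (e <= L || s + (e - starts[i]) <= L) {
      e2 <- s + (ends[i] - starts[i])
      if (e2 <= L) {
        if (e2 > s) mask[(s + 1L):e2] <- TRUE
      } else {
        mask[(s + 1L):L] <- TRUE
        mask[1L:(e2 - L)] <- TRUE
      }
    }
  }
  mask
}

`%||%` <- function(x, y) if (is.null(x)) y else x
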