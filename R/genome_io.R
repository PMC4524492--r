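# GenBank/FASTA ingestion and the internal genome model.
#
# A `plastome` is a list with fields:
#   taxon      character scalar (nonempty)
#   accession  character scalar ("" allowed)
#   sequence   uppercase nucleotide string over A/C/G/T/N
#   circular   logical
#   complete   logical
#   features   tibble, one row per span:
#     feature_id  integer, groups spans of one feature
#     raw_name    character, name as annotated
#     symbol      character, normalized symbol
#     kind        one of CDS, tRNA, rRNA, intron, other
#     strand      +1 / -1
#     start,end   0-based half-open; origin-wrapping features are stored as
#                 two rows sharing feature_id
#     part_index  ordinal for fragmented genes sharing a symbol (>= 1)
#     intron_type "group I" / "group II" / NA

#' Construct a genome record
#'
#' @param taxon Taxon label (nonempty).
#' @param sequence Nucleotide string.
#' @param features Feature tibble (see package internals); may be empty.
#' @param accession Accession string.
#' @param circular,complete Flags.
#' @return Object of class `plastome`.
#' @export
plastome <- function(taxon, sequence, features = empty_features(),
                     accession = "", circular = TRUE, complete = TRUE) {
  stopifnot(nzchar(taxon))
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (nrow(features) > 0L) {
    stopifnot(all(features$end > features$start),
              all(features$start >= 0L), all(features$end <= L),
              all(features$part_index >= 1L))
  }
  structure(list(taxon = taxon, accession = accession, sequence = sequence,
                 circular = circular, complete = complete,
                 features = features),
            class = "plastome")
}

#' @export
print.plastome <- function(x, ...) {
  cat("<plastome> ", x$taxon,
      if (nzchar(x$accession)) paste0(" [", x$accession, "]") else "",
      "\n  length ", nchar(x$sequence), " bp; ",
      if (x$circular) "circular" else "linear", "; ",
      length(unique(x$features$feature_id)), " features\n", sep = "")
  invisible(x)
}

empty_features <- function() {
  tibble(feature_id = integer(), raw_name = character(), symbol = character(),
         kind = character(), strand = integer(), start = integer(),
         end = integer(), part_index = integer(), intron_type = character())
}

as_plastome_list <- function(genomes) {
  if (inherits(genomes, "plastome")) genomes <- list(genomes)
  stopifnot(all(vapply(genomes, inherits, logical(1), "plastome")))
  if (is.null(names(genomes))) {
    names(genomes) <- vapply(genomes, function(g) g$taxon, character(1))
  }
  genomes
}

# CDS sequences (exons spliced, strand-corrected), named by symbol
cds_sequences <- function(g) {
  ft <- g$features
  cds <- ft[ft$kind == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) return(character(0))
  ids <- unique(cds$feature_id)
  out <- vapply(ids, function(id) {
    rows <- cds[cds$feature_id == id, , drop = FALSE]
    s <- paste(vapply(seq_len(nrow(rows)), function(i)
      sub0(g$sequence, rows$start[i], rows$end[i]), character(1)), collapse = "")
    if (rows$strand[1] == -1L) s <- revcomp(s)
    s
  }, character(1))
  names(out) <- vapply(ids, function(id) cds$symbol[cds$feature_id == id][1],
                       character(1))
  # keep only in-frame CDS; partial annotations are skipped with a warning
  ok <- nchar(out) %% 3L == 0L
  if (any(!ok)) warn(paste0("dropping out-of-frame CDS: ",
                            paste(names(out)[!ok], collapse = ", ")))
  out[ok]
}

## ---------------------------------------------------------------------------
## Symbol normalization

.plastarch_env <- new.env(parent = emptyenv())

synonym_table <- function() {
  if (is.null(.plastarch_env$syn)) {
    path <- system.file("extdata", "gene_synonyms.tsv", package = "plastarch")
    .plastarch_env$syn <- read.delim(path, stringsAsFactors = FALSE)
  }
  .plastarch_env$syn
}

core91_cached <- function() {
  if (is.null(.plastarch_env$core91)) {
    path <- system.file("extdata", "core91.txt", package = "plastarch")
    .plastarch_env$core91 <- readLines(path)
  }
  .plastarch_env$core91
}

#' Normalize a gene symbol
#'
#' Maps synonym spellings (e.g. `rrn16` vs `rrs`, `trnI-GAU` vs `trnI(gau)`,
#' case variants of standard genes) to one canonical symbol. tRNA names are
#' rewritten to the `trnX(anticodon)` convention with a lowercase anticodon.
#' Unknown names pass through lowercased, so the mapping is lossless and
#' idempotent.
#'
#' @param raw_name Character vector of annotated names.
#' @return Character vector of canonical symbols.
#' @examples
#' normalize_symbol(c("rrn16", "trnI-GAU", "psbA"))
#' @export
normalize_symbol <- function(raw_name) {
  vapply(raw_name, normalize_symbol1, character(1), USE.NAMES = FALSE)
}

normalize_symbol1 <- function(x) {
  if (is.na(x) || !nzchar(x)) return("")
  x <- trimws(x)
  syn <- synonym_table()
  hit <- match(tolower(x), syn$raw)
  if (!is.na(hit)) return(syn$canonical[hit])
  # tRNA spellings: trnI-GAU, trnI_gau, trnI(gau), trnMe-CAU ...
  m <- regmatches(x, regexec("^trn([A-Za-z]{1,2})[-_(]?([AaCcGgUuTt]{3})\\)?$", x))[[1]]
  if (length(m) == 3L) {
    aa <- m[2]
    if (!aa %in% c("Me", "Mf")) aa <- toupper(substr(aa, 1, 1))
    ac <- chartr("Tt", "Uu", tolower(m[3]))
    return(paste0("trn", aa, "(", ac, ")"))
  }
  # case variants of known standard genes
  core <- core91_cached()
  hit <- match(tolower(x), tolower(core))
  if (!is.na(hit)) return(core[hit])
  tolower(x)
}

## ---------------------------------------------------------------------------
## GenBank flat-file parsing

parse_location <- function(loc, L, line_no = NA_integer_) {
  loc <- gsub("[<>]", "", gsub("[[:space:]]", "", loc))
  strand <- 1L
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  spans <- lapply(parts, function(p) {
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      se <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^\\d+$", p)) {
      se <- c(as.integer(p), as.integer(p))
    } else {
      abort(paste0("malformed GenBank location near line ", line_no, ": ", p))
    }
    c(se[1] - 1L, se[2])  # to 0-based half-open
  })
  spans <- do.call(rbind, spans)
  if (strand == -1L) spans <- spans[rev(seq_len(nrow(spans))), , drop = FALSE]
  list(strand = strand, spans = spans)
}

#' Parse a GenBank flat file
#'
#' Reads one record: LOCUS line (length, circular/linear), accession, organism,
#' the feature table (CDS, tRNA, rRNA; `gene` keys are used only when no other
#' feature covers the locus) and the ORIGIN sequence. `join(...)` and
#' `complement(...)` locations are resolved into strand plus exon spans;
#' introns are inferred between consecutive exons of multi-exon locations,
#' with the intron type taken from a `/note` qualifier when it names group I
#' or group II (never inferred from sequence). Duplicate features with
#' identical symbol and span are dropped with a warning.
#'
#' @param path Path to a GenBank flat file.
#' @return A [plastome].
#' @export
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^LOCUS", lines[1])) {
    abort(paste0("malformed GenBank record (missing LOCUS) at line 1 of ", path))
  }
  locus <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  circular <- any(tolower(locus) == "circular")
  acc <- ""
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc_line) > 0L) {
    acc <- strsplit(trimws(acc_line[1]), "[[:space:]]+")[[1]][2] %||% ""
    if (is.na(acc)) acc <- ""
  }
  taxon <- ""
  org_line <- grep("^[[:space:]]+ORGANISM", lines, value = TRUE)
  if (length(org_line) > 0L) {
    taxon <- trimws(sub("^[[:space:]]+ORGANISM[[:space:]]+", "", org_line[1]))
  }
  if (!nzchar(taxon)) {
    def <- grep("^DEFINITION", lines, value = TRUE)
    taxon <- if (length(def) > 0L) trimws(sub("^DEFINITION", "", def[1])) else "unknown"
  }

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) == 0L) abort(paste0("malformed GenBank record (no ORIGIN) in ", path))
  seq_lines <- lines[(ostart[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  L <- nchar(sequence)

  feats <- empty_features()
  if (length(fstart) > 0L) {
    flines <- lines[(fstart[1] + 1L):(ostart[1] - 1L)]
    # group continuation lines into one entry per feature
    is_key <- grepl("^ {5}[A-Za-z']", flines)
    idx <- cumsum(is_key)
    entries <- split(flines, idx)
    if (any(idx == 0L)) entries[["0"]] <- NULL
    rows <- list()
    fid <- 0L
    for (ei in seq_along(entries)) {
      e <- entries[[ei]]
      key <- strsplit(trimws(e[1]), "[[:space:]]+")[[1]][1]
      if (!key %in% c("CDS", "tRNA", "rRNA", "gene", "intron")) next
      rest <- sub(paste0("^ {5}", key, "[[:space:]]+"), "", e[1])
      qual_start <- grep("^ {21}/", e)
      loc_end <- if (length(qual_start) > 0L) qual_start[1] - 1L else length(e)
      loc_txt <- paste(c(rest, trimws(e[seq_len(loc_end)][-1])), collapse = "")
      quals <- paste(trimws(e[qual_start]), collapse = "\n")
      getq <- function(q) {
        m <- regmatches(quals, regexec(paste0("/", q, "=\"([^\"]*)\""), quals))[[1]]
        if (length(m) == 2L) m[2] else NA_character_
      }
      loc <- parse_location(loc_txt, L, line_no = ei)
      raw <- getq("gene")
      if (is.na(raw)) raw <- getq("standard_name")
      if (is.na(raw)) raw <- getq("product")
      if (is.na(raw)) raw <- getq("locus_tag")
      if (is.na(raw)) raw <- key
      note <- getq("note")
      itype <- NA_character_
      if (!is.na(note)) {
        if (grepl("group I[^I]|group I$", note)) itype <- "group I"
        if (grepl("group II", note)) itype <- "group II"
      }
      part <- 1L
      pm <- regmatches(raw, regexec("[_ ]part[_ ]?(\\d+)$", raw))[[1]]
      base_raw <- raw
      if (length(pm) == 2L) {
        part <- as.integer(pm[2])
        base_raw <- sub("[_ ]part[_ ]?\\d+$", "", raw)
      }
      fid <- fid + 1L
      spans <- loc$spans
      kind <- if (key == "gene") "gene" else key
      rows[[length(rows) + 1L]] <- tibble(
        feature_id = fid, raw_name = raw, symbol = normalize_symbol(base_raw),
        kind = kind, strand = loc$strand,
        start = spans[, 1], end = spans[, 2], part_index = part,
        intron_type = itype)
    }
    if (length(rows) > 0L) {
      feats <- bind_rows(rows)
      # drop bare `gene` keys whose locus is covered by a typed feature
      typed <- feats[feats$kind != "gene", , drop = FALSE]
      genes <- feats[feats$kind == "gene", , drop = FALSE]
      keep_gene <- !(paste(genes$symbol, genes$start) %in%
                       paste(typed$symbol, typed$start))
      genes <- genes[keep_gene, , drop = FALSE]
      if (nrow(genes) > 0L) genes$kind <- "other"
      feats <- bind_rows(typed, genes)
      feats <- infer_introns(feats, L)
      feats <- dedup_features(feats)
      feats <- feats |> arrange(.data$start, .data$feature_id) |>
        mutate(feature_id = match(.data$feature_id, unique(.data$feature_id)))
    }
  }
  if (nrow(feats) == 0L) warn(paste0("no features parsed from ", path))
  plastome(taxon = taxon, sequence = sequence, features = feats,
           accession = acc, circular = circular, complete = TRUE)
}

# add intron rows between consecutive exon spans of multi-span features
infer_introns <- function(feats, L) {
  ids <- unique(feats$feature_id[feats$kind %in% c("CDS", "tRNA", "rRNA")])
  next_id <- max(feats$feature_id) + 1L
  introns <- list()
  for (id in ids) {
    rows <- feats[feats$feature_id == id, , drop = FALSE]
    if (nrow(rows) < 2L) next
    rows <- rows[order(rows$start), , drop = FALSE]
    # a two-span feature touching both the origin and the end of a circular
    # record is an origin-wrapping span, not a spliced gene
    if (nrow(rows) == 2L && rows$start[1] == 0L && rows$end[2] == L) next
    for (i in seq_len(nrow(rows) - 1L)) {
      gap_s <- rows$end[i]; gap_e <- rows$start[i + 1L]
      if (gap_e > gap_s) {
        introns[[length(introns) + 1L]] <- tibble(
          feature_id = next_id, raw_name = rows$raw_name[1],
          symbol = rows$symbol[1], kind = "intron", strand = rows$strand[1],
          start = gap_s, end = gap_e, part_index = 1L,
          intron_type = rows$intron_type[1])
        next_id <- next_id + 1L
      }
    }
  }
  bind_rows(feats, bind_rows(introns))
}

dedup_features <- function(feats) {
  key <- paste(feats$symbol, feats$kind, feats$start, feats$end, feats$strand)
  dup_ids <- unique(feats$feature_id[duplicated(key)])
  if (length(dup_ids) > 0L) {
    warn(paste0("dropping ", length(dup_ids),
                " duplicate feature(s) with identical symbol and span"))
    feats <- feats[!feats$feature_id %in% dup_ids, , drop = FALSE]
  }
  feats
}

## ---------------------------------------------------------------------------
## GenBank writing (round-trips through parse_genbank)

#' Write a genome record as a GenBank flat file
#'
#' @param g A [plastome].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(g, path) {
  L <- nchar(g$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   PLN",
                     gsub("[^A-Za-z0-9_.]", "_", substr(g$taxon, 1, 16)), L,
                     if (g$circular) "circular" else "linear"), con)
  writeLines(paste0("DEFINITION  ", g$taxon, " chloroplast genome."), con)
  if (nzchar(g$accession)) writeLines(paste0("ACCESSION   ", g$accession), con)
  writeLines("SOURCE      synthetic", con)
  writeLines(paste0("  ORGANISM  ", g$taxon), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  ft <- g$features
  for (id in unique(ft$feature_id)) {
    rows <- ft[ft$feature_id == id, , drop = FALSE]
    kind <- rows$kind[1]
    if (kind == "intron") next  # re-inferred on parse
    key <- if (kind %in% c("CDS", "tRNA", "rRNA")) kind else "gene"
    spans <- rows[order(rows$start), c("start", "end"), drop = FALSE]
    if (rows$strand[1] == -1L) spans <- spans[rev(seq_len(nrow(spans))), , drop = FALSE]
    segs <- sprintf("%d..%d", spans$start + 1L, spans$end)
    loc <- if (length(segs) > 1L) paste0("join(", paste(segs, collapse = ","), ")") else segs
    if (rows$strand[1] == -1L) loc <- paste0("complement(", loc, ")")
    writeLines(sprintf("     %-16s%s", key, loc), con)
    nm <- rows$raw_name[1]
    if (rows$part_index[1] > 1L && !grepl("part", nm)) {
      nm <- paste0(nm, "_part", rows$part_index[1])
    }
    writeLines(sprintf("                     /gene=\"%s\"", nm), con)
    if (!is.na(rows$intron_type[1])) {
      writeLines(sprintf("                     /note=\"contains %s intron\"",
                         rows$intron_type[1]), con)
    }
  }
  writeLines("ORIGIN", con)
  starts <- seq(1L, L, by = 60L)
  for (s in starts) {
    chunk <- substr(g$sequence, s, min(s + 59L, L))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", s, tolower(paste(blocks, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read/write FASTA
#'
#' Thin wrappers over Biostrings for sequence-only stages.
#' @param path File path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Genome breakdown and fragmented genes

#' Per-position breakdown of a genome into coding / intron / intergenic
#'
#' Each position is counted once with priority coding > intron > intergenic.
#' Coding positions are those inside any exon span of a CDS/tRNA/rRNA feature;
#' positions inside inferred intron spans are intronic. Intron-encoded ORFs
#' (CDS features lying wholly within an intron span) are counted as intron
#' sequence unless `intron_orfs_as_coding = TRUE`.
#'
#' @param g A [plastome] (complete).
#' @param repeat_mask Optional tibble with `start`/`end` columns (0-based
#'   half-open) of repeat intervals; `repeat_bp` is the size of the mask
#'   intersected with the genome.
#' @param intron_orfs_as_coding Count intron-encoded ORFs as coding.
#' @return One-row tibble: `taxon`, `length`, `coding_bp`, `intron_bp`,
#'   `intergenic_bp`, `repeat_bp`, `at_percent`, `gene_count`,
#'   `groupI_count`, `groupII_count`. The three positional categories always
#'   sum to the genome length.
#' @export
genome_breakdown <- function(g, repeat_mask = NULL, intron_orfs_as_coding = FALSE) {
  stopifnot(inherits(g, "plastome"), isTRUE(g$complete))
  L <- nchar(g$sequence)
  ft <- g$features
  intron_rows <- ft[ft$kind == "intron", , drop = FALSE]
  intron_mask <- coverage_mask(intron_rows$start, intron_rows$end, L)
  coding_rows <- ft[ft$kind %in% c("CDS", "tRNA", "rRNA"), , drop = FALSE]
  if (!intron_orfs_as_coding && nrow(coding_rows) > 0L && nrow(intron_rows) > 0L) {
    inside <- vapply(seq_len(nrow(coding_rows)), function(i) {
      any(coding_rows$start[i] >= intron_rows$start &
            coding_rows$end[i] <= intron_rows$end)
    }, logical(1))
    coding_rows <- coding_rows[!inside, , drop = FALSE]
  }
  coding_mask <- coverage_mask(coding_rows$start, coding_rows$end, L)
  intron_only <- intron_mask & !coding_mask
  coding_bp <- sum(coding_mask)
  intron_bp <- sum(intron_only)
  intergenic_bp <- L - coding_bp - intron_bp
  repeat_bp <- 0L
  if (!is.null(repeat_mask) && nrow(repeat_mask) > 0L) {
    repeat_bp <- sum(coverage_mask(repeat_mask$start, repeat_mask$end, L))
  }
  n_genes <- length(unique(ft$symbol[ft$kind %in% c("CDS", "tRNA", "rRNA")]))
  stopifnot(coding_bp + intron_bp + intergenic_bp == L)
  tibble(taxon = g$taxon, length = L, coding_bp = coding_bp,
         intron_bp = intron_bp, intergenic_bp = intergenic_bp,
         repeat_bp = repeat_bp, at_percent = at_content(g$sequence),
         gene_count = n_genes,
         groupI_count = sum(intron_rows$intron_type %in% "group I"),
         groupII_count = sum(intron_rows$intron_type %in% "group II"))
}

#' Detect fragmented genes
#'
#' Reports symbols annotated as two or more separate features (distinct
#' feature ids) that are not explained by IR duplication. Copies lying inside
#' the two IR copies (when `ir` is supplied) are collapsed first.
#'
#' @param g A [plastome].
#' @param ir Optional IR annotation from [find_inverted_repeat()].
#' @return Tibble with `symbol`, `n_parts`, `contiguous` (are the parts
#'   adjacent along the genome with no other gene between them).
#' @export
detect_fragmented_genes <- function(g, ir = NULL) {
  ft <- g$features[g$features$kind %in% c("CDS", "tRNA", "rRNA"), , drop = FALSE]
  if (nrow(ft) == 0L) {
    return(tibble(symbol = character(), n_parts = integer(), contiguous = logical()))
  }
  per_feat <- ft |> group_by(.data$feature_id) |>
    summarise(symbol = .data$symbol[1], start = min(.data$start),
              end = max(.data$end), .groups = "drop")
  if (!is.null(ir)) {
    in_ira <- per_feat$start >= ir$ira[1] & per_feat$end <= ir$ira[2]
    in_irb <- per_feat$start >= ir$irb[1] & per_feat$end <= ir$irb[2]
    # drop the IRB copy of symbols present in both repeats
    dup_sym <- intersect(per_feat$symbol[in_ira], per_feat$symbol[in_irb])
    per_feat <- per_feat[!(in_irb & per_feat$symbol %in% dup_sym), , drop = FALSE]
  }
  multi <- per_feat |> count(.data$symbol) |> filter(n >= 2L)
  if (nrow(multi) == 0L) {
    return(tibble(symbol = character(), n_parts = integer(), contiguous = logical()))
  }
  ordered_syms <- per_feat$symbol[order(per_feat$start)]
  contig <- vapply(multi$symbol, function(s) {
    pos <- which(ordered_syms == s)
    all(diff(pos) == 1L)
  }, logical(1))
  tibble(symbol = multi$symbol, n_parts = multi$n, contiguous = unname(contig))
}

#' Write a per-genome summary table
#'
#' @param genomes A `plastome` or list of them.
#' @param path Optional TSV output path.
#' @param repeat_masks Optional named list of repeat-interval tibbles keyed by
#'   taxon.
#' @return The summary tibble (invisibly written to `path` if given).
#' @export
genome_summary <- function(genomes, path = NULL, repeat_masks = NULL) {
  genomes <- as_plastome_list(genomes)
  out <- bind_rows(lapply(genomes, function(g) {
    mask <- if (!is.null(repeat_masks)) repeat_masks[[g$taxon]] else NULL
    genome_breakdown(g, repeat_mask = mask) |>
      mutate(accession = g$accession, .after = "taxon")
  }))
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
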