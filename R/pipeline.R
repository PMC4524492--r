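# End-to-end orchestration over a directory of annotated genomes.

#' Run the full comparative-architecture pipeline
#'
#' Parses a set of GenBank files (or takes a list of `plastome` objects),
#' then computes per-genome summaries, IR annotations and quadripartite
#' partitions, signed gene orders and sidedness, canonical pair matrices,
#' pairwise reversal distances, Dollo maps of pair characters and IR
#' presence on the supplied tree, repeat landscapes and composition tables,
#' and writes everything as TSV plus a JSON manifest.
#'
#' @param genbank_dir Directory of `.gb`/`.gbk` files, or NULL when
#'   `genomes` is given.
#' @param genomes Optional named list of `plastome` objects.
#' @param tree Rooted `ape::phylo` or path to a Newick file; taxa must match
#'   genome names. Optional: Dollo stages are skipped when absent.
#' @param out_dir Output directory.
#' @param gene_filter `"core91"`, a character vector of symbols, or NULL.
#' @param ir_min_len Minimum IR length (bp).
#' @param repeat_min_len Minimum repeat length (bp), must be positive.
#' @param min_share Minimum taxa sharing a gene pair.
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return Invisible list of result objects; files are written to `out_dir`.
#' @export
run_pipeline <- function(genbank_dir = NULL, genomes = NULL, tree = NULL,
                         out_dir, gene_filter = "core91", ir_min_len = 1000L,
                         repeat_min_len = 30L, min_share = 5L, seed = 1L) {
  if (repeat_min_len < 1L || ir_min_len < 1L || min_share < 2L) {
    abort("invalid configuration: thresholds must be positive (min_share >= 2)")
  }
  if (is.null(genomes)) {
    stopifnot(!is.null(genbank_dir))
    paths <- list.files(genbank_dir, pattern = "\\.gbk?$", full.names = TRUE)
    if (length(paths) == 0L) abort(paste0("no GenBank files in ", genbank_dir))
    genomes <- lapply(paths, parse_genbank)
    names(genomes) <- vapply(genomes, function(g) g$taxon, character(1))
  }
  genomes <- as_plastome_list(genomes)
  if (is.character(tree)) tree <- ape::read.tree(tree)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, file) {
    p <- file.path(out_dir, file)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
    p
  }

  irs <- lapply(genomes, function(g) ir_architecture(g, min_len = ir_min_len))
  ir_tbl <- bind_rows(lapply(names(irs), function(tx) {
    ir <- irs[[tx]]$ir
    if (is.null(ir)) return(tibble(taxon = tx, ir_present = FALSE,
                                   ir_len = NA_integer_, lsc_len = NA_integer_,
                                   ssc_len = NA_integer_))
    tibble(taxon = tx, ir_present = TRUE, ir_len = ir$ir_len,
           lsc_len = diff(ir$lsc), ssc_len = diff(ir$ssc))
  }))
  emit(ir_tbl, "ir_architecture.tsv")

  summaries <- genome_summary(genomes)
  emit(summaries, "genome_summary.tsv")

  orders <- bind_rows(lapply(names(genomes), function(tx) {
    extract_signed_gene_order(genomes[[tx]], gene_filter = gene_filter,
                              collapse_ir = !is.null(irs[[tx]]$ir),
                              ir = irs[[tx]]$ir)
  }))
  orders <- new_gene_order(orders, circular = TRUE)
  emit(as_tibble(orders), "gene_orders.tsv")
  emit(sidedness_index(orders), "sidedness.tsv")

  results <- list(genomes = genomes, irs = irs, orders = orders)

  if (length(genomes) >= 2L) {
    pm <- shared_pair_matrix(orders, min_share = min(min_share, length(genomes)))
    pair_matrix_wide(pm, path = file.path(out_dir, "pair_matrix.tsv"))
    written <- c(written, file.path(out_dir, "pair_matrix.tsv"))
    D <- pairwise_distance_matrix(orders,
                                  path = file.path(out_dir, "reversal_distances.tsv"))
    written <- c(written, file.path(out_dir, "reversal_distances.tsv"))
    results$pair_matrix <- pm
    results$distances <- D
    if (!is.null(tree)) {
      ir_states <- setNames(as.integer(ir_tbl$ir_present), ir_tbl$taxon)
      ir_map <- map_ir_losses(ir_states, tree)
      chars <- as_tibble(pm) |> rename(character_id = "pair")
      maps <- dollo_map_characters(chars, tree)
      events <- branch_event_table(c(maps, list(ir_map)), tree,
                                   path = file.path(out_dir, "dollo_events.tsv"))
      written <- c(written, file.path(out_dir, "dollo_events.tsv"))
      results$ir_map <- ir_map
      results$dollo_events <- events
    }
  }

  reps <- repeat_landscape(genomes, min_len = repeat_min_len,
                           irs = lapply(irs, function(x) x$ir))
  emit(reps, "repeat_landscape.tsv")
  comp <- composition_table(genomes)
  emit(comp, "composition.tsv")
  results$repeats <- reps
  results$composition <- comp

  manifest <- list(
    package = "plastarch",
    version = as.character(utils::packageVersion("plastarch")),
    seed = seed,
    n_genomes = length(genomes),
    inputs = lapply(names(genomes), function(tx)
      list(taxon = tx, length = nchar(genomes[[tx]]$sequence),
           md5 = unname(tools::md5sum(textfile_of(genomes[[tx]]))))),
    outputs = basename(written))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

# checksum helper: serialize a genome deterministically to a temp file
textfile_of <- function(g) {
  f <- tempfile(fileext = ".gb")
  write_genbank(g, f)
  f
}
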