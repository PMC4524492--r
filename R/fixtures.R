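# Packaged study fixtures: the 38-taxon metadata table, the rooted study
# phylogeny, the 91-gene core list and the ancestral partition-side table.
# A manifest of md5 checksums guards against silent edits; structural
# invariants are asserted at load.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "plastarch")
  if (!nzchar(p)) abort(paste0("fixture not found: ", file))
  p
}

check_manifest <- function(file) {
  man <- read.delim(fixture_path("manifest.tsv"), stringsAsFactors = FALSE)
  row <- man[man$file == file, , drop = FALSE]
  if (nrow(row) == 1L) {
    got <- unname(tools::md5sum(fixture_path(file)))
    if (!identical(got, row$md5)) {
      abort(paste0("fixture checksum mismatch for ", file))
    }
  }
  invisible(TRUE)
}

#' Load a packaged study fixture
#'
#' Available fixtures:
#' \describe{
#'   \item{table1}{Per-taxon genome metadata: accession, A+T percent, genome /
#'     IR / LSC / SSC lengths, gene and intron counts, small-repeat percent,
#'     IR flags (`ir_present`: any large IR; `ir_rdna`: an rDNA-encoding IR)
#'     and completeness. Quadripartite length sums are validated for complete
#'     IR-containing rows.}
#'   \item{tree}{The rooted 38-leaf study phylogeny (`ape::phylo`), leaf names
#'     matching `table1$taxon_id`; uncertain shallow nodes are polytomies.}
#'   \item{core91}{The 91 standard genes shared by all completely sequenced
#'     study genomes.}
#'   \item{ancestral_sides}{Ancestral partition side per standard gene
#'     relative to the rDNA operon.}
#' }
#'
#' @param name One of `"table1"`, `"tree"`, `"core91"`, `"ancestral_sides"`.
#' @return A tibble, `phylo` tree, or character vector, validated at load.
#' @export
load_fixture <- function(name = c("table1", "tree", "core91", "ancestral_sides")) {
  name <- match.arg(name)
  switch(name,
    table1 = {
      check_manifest("table1.tsv")
      tb <- as_tibble(read.delim(fixture_path("table1.tsv"),
                                 stringsAsFactors = FALSE))
      stopifnot(nrow(tb) == 38L, !anyDuplicated(tb$taxon_id))
      stopifnot(all(tb$ir_present == !is.na(tb$ir_length) |
                      tb$taxon_id == "Oocystis_solitaria"))
      full <- tb[tb$complete & !is.na(tb$ir_length) & !is.na(tb$lsc_length) &
                   !is.na(tb$ssc_length), , drop = FALSE]
      stopifnot(all(2L * full$ir_length + full$lsc_length + full$ssc_length ==
                      full$genome_length))
      stopifnot(all(full$lsc_length >= full$ssc_length))
      tb
    },
    tree = {
      check_manifest("study_tree.nwk")
      tr <- ape::read.tree(fixture_path("study_tree.nwk"))
      stopifnot(ape::Ntip(tr) == 38L, ape::is.rooted(tr))
      tb <- suppressWarnings(load_fixture("table1"))
      stopifnot(setequal(tr$tip.label, tb$taxon_id))
      tr
    },
    core91 = {
      check_manifest("core91.txt")
      core <- readLines(fixture_path("core91.txt"))
      stopifnot(length(core) == 91L, !anyDuplicated(core))
      core
    },
    ancestral_sides = {
      check_manifest("ancestral_sides.tsv")
      sides <- ancestral_sides()
      stopifnot(all(sides$side %in% c("rdna", "ssc_side", "lsc_side")),
                setequal(sides$symbol[sides$side == "rdna"], operon_symbols()))
      sides
    })
}
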