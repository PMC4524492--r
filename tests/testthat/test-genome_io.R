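test_that("GenBank format semantics: strands, joins and inferred introns", {
  gb <- c(
    "LOCUS       test 6000 bp    DNA     circular   PLN",
    "DEFINITION  test record.",
    "ACCESSION   XX000001",
    "SOURCE      synthetic",
    "  ORGANISM  Testus plastidus",
    "FEATURES             Location/Qualifiers",
    "     CDS             complement(101..400)",
    "                     /gene=\"psbA\"",
    "     CDS             join(501..800,2001..2300)",
    "                     /gene=\"rbcL\"",
    "                     /note=\"contains group II intron\"",
    "     tRNA            3001..3072",
    "                     /gene=\"trnI-GAU\"",
    "     rRNA            3501..4100",
    "                     /gene=\"rrn16\"",
    "ORIGIN",
    vapply(seq(1, 6000, 60), function(s) {
      chunk <- paste(rep("acgtaagctt", 6), collapse = "")
      sprintf("%9d %s", s, chunk)
    }, character(1)),
    "//")
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, f)
  g <- parse_genbank(f)

  expect_true(g$circular)
  expect_equal(g$accession, "XX000001")
  expect_equal(nchar(g$sequence), 6000L)

  psba <- g$features[g$features$symbol == "psbA", ]
  expect_equal(psba$strand, -1L)
  expect_equal(c(psba$start, psba$end), c(100L, 400L))

  rbcl <- g$features[g$features$symbol == "rbcL" & g$features$kind == "CDS", ]
  expect_equal(nrow(rbcl), 2L)            # two exon spans, one feature
  expect_equal(length(unique(rbcl$feature_id)), 1L)
  intr <- g$features[g$features$kind == "intron", ]
  expect_equal(nrow(intr), 1L)
  expect_equal(c(intr$start, intr$end), c(800L, 2000L))
  expect_equal(intr$intron_type, "group II")

  # symbol normalization applied on parse
  expect_true("trnI(gau)" %in% g$features$symbol)
  expect_true("rrs" %in% g$features$symbol)
})

test_that("simulator GenBank fixtures round-trip to identical records", {
  truth <- sim_bundle_cached()
  g <- truth$tips$A
  f <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, f)
  g2 <- parse_genbank(f)
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$circular, g$circular)
  keep <- c("symbol", "kind", "strand", "start", "end", "part_index")
  a <- as.data.frame(g$features[order(g$features$start), keep])
  b2 <- g2$features[g2$features$kind != "intron", ]
  b <- as.data.frame(b2[order(b2$start), keep])
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("symbol normalization maps synonyms and is idempotent", {
  expect_equal(normalize_symbol("rrn16"), "rrs")
  expect_equal(normalize_symbol("23S"), "rrl")
  expect_equal(normalize_symbol("trnI-GAU"), "trnI(gau)")
  expect_equal(normalize_symbol("trnMe-CAU"), "trnMe(cau)")
  expect_equal(normalize_symbol("psbA"), "psbA")
  expect_equal(normalize_symbol("PSBA"), "psbA")
  expect_equal(normalize_symbol("unknownGene"), "unknowngene")
  raws <- c("rrn16", "trnL-UAA", "PsbA", "rpoC2", "orf123", "rrn5", "trnMf(cau)")
  once <- normalize_symbol(raws)
  expect_identical(normalize_symbol(once), once)
})

test_that("genome breakdown partitions every position once and sums to length", {
  feats <- tibble::tibble(
    feature_id = 1L, raw_name = "geneA", symbol = "genea", kind = "CDS",
    strand = 1L, start = 100L, end = 400L, part_index = 1L,
    intron_type = NA_character_)
  g <- plastome("t", strrep("AT", 500), feats)
  bd <- genome_breakdown(g)
  expect_equal(bd$coding_bp, 300L)
  expect_equal(bd$intron_bp, 0L)
  expect_equal(bd$intergenic_bp, 700L)
  expect_equal(bd$at_percent, 100)
  expect_equal(bd$coding_bp + bd$intron_bp + bd$intergenic_bp, 1000L)

  # simulator genomes: breakdown categories always close exactly
  truth <- sim_bundle_cached()
  for (g in truth$tips) {
    bd <- genome_breakdown(g)
    expect_equal(bd$coding_bp + bd$intron_bp + bd$intergenic_bp,
                 nchar(g$sequence))
  }
})

test_that("repeat mask intersects correctly in the breakdown", {
  feats <- tibble::tibble(
    feature_id = 1L, raw_name = "g1", symbol = "g1", kind = "CDS",
    strand = 1L, start = 0L, end = 300L, part_index = 1L,
    intron_type = NA_character_)
  g <- plastome("t", strrep("ACGT", 250), feats)
  mask <- tibble::tibble(start = c(100L, 900L), end = c(200L, 1000L))
  bd <- genome_breakdown(g, repeat_mask = mask)
  expect_equal(bd$repeat_bp, 200L)
})

test_that("fragmented genes are reported, IR-duplicated genes are not", {
  mk_feats <- function(rows) dplyr::bind_rows(rows)
  f1 <- mk_feats(list(
    tibble::tibble(feature_id = 1L, raw_name = "rpoB_part1", symbol = "rpoB",
                   kind = "CDS", strand = 1L, start = 0L, end = 300L,
                   part_index = 1L, intron_type = NA_character_),
    tibble::tibble(feature_id = 2L, raw_name = "rpoB_part2", symbol = "rpoB",
                   kind = "CDS", strand = 1L, start = 350L, end = 650L,
                   part_index = 2L, intron_type = NA_character_)))
  g <- plastome("t", strrep("A", 1000), f1)
  fr <- detect_fragmented_genes(g)
  expect_equal(fr$symbol, "rpoB")
  expect_equal(fr$n_parts, 2L)
  expect_true(fr$contiguous)

  # a planted 3-part gene in the simulator is recovered from the truth config
  cfg <- sim_config(n_genes = 20L, ir_gene_count = 6L, ssc_gene_count = 3L,
                    genome_length_target = 15000L, use_core_symbols = FALSE,
                    fragment = list(symbol = "g005", parts = 3L), seed = 21L,
                    rates = c(inversion = 0, ir_expand = 0, ir_contract = 0,
                              ir_loss = 0, repeat_insert = 0))
  anc <- make_ancestor(cfg)
  tr <- ape::read.tree(text = "(p,q);")
  truth <- evolve_plastomes(anc, tr, cfg)
  # with IR context, IR-duplicated genes are explained away and only the
  # planted fragmentation remains
  ir <- truth$tip_ir$p
  fr2 <- detect_fragmented_genes(truth$tips$p, ir = ir)
  expect_equal(fr2$symbol, "g005")
  expect_equal(fr2$n_parts, 3L)
  expect_false("rrs" %in% fr2$symbol)
  fr4 <- detect_fragmented_genes(truth$tips$p, ir = NULL)
  expect_true("rrs" %in% fr4$symbol)  # without IR context the copies show up
})

test_that("duplicate identical features are dropped with a warning", {
  gb_row <- tibble::tibble(feature_id = 1L, raw_name = "psbA", symbol = "psbA",
                           kind = "CDS", strand = 1L, start = 10L, end = 100L,
                           part_index = 1L, intron_type = NA_character_)
  feats <- dplyr::bind_rows(gb_row, dplyr::mutate(gb_row, feature_id = 2L))
  expect_warning(out <- plastarch:::dedup_features(feats), "duplicate")
  expect_equal(nrow(out), 1L)
})
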