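test_that("a constructed IR is recovered with exact coordinates", {
  set.seed(801)
  A <- random_dna(6000, 65)
  R <- random_dna(2000, 60)
  B <- random_dna(1500, 65)
  s <- paste0(A, R, B, revcomp(R))
  ir <- find_inverted_repeat(s, min_len = 1000)
  expect_false(is.null(ir))
  expect_equal(ir$ira, c(6000L, 8000L))
  expect_equal(ir$irb, c(9500L, 11500L))
  expect_equal(ir$ir_len, 2000L)
  # LSC is the longer gap, SSC the shorter
  expect_equal(diff(ir$lsc), 6000L)
  expect_equal(diff(ir$ssc), 1500L)
  expect_identical(substr(s, ir$ira[1] + 1, ir$ira[2]),
                   revcomp(substr(s, ir$irb[1] + 1, ir$irb[2])))
})

test_that("random sequences without a large inverted duplicate yield no IR", {
  set.seed(802)
  s <- random_dna(30000, 65)
  expect_null(find_inverted_repeat(s, min_len = 1000))
  # genomes shorter than twice the cutoff are rejected outright
  expect_null(find_inverted_repeat(random_dna(1500, 65), min_len = 1000))
})

test_that("detected IRs on simulator genomes equal the planted annotation", {
  truth <- sim_bundle_cached()
  for (tx in names(truth$tips)) {
    planted <- truth$tip_ir[[tx]]
    det <- find_inverted_repeat(truth$tips[[tx]]$sequence, min_len = 1000)
    if (is.null(planted)) {
      expect_null(det)
    } else {
      expect_equal(det$ira, planted$ira)
      expect_equal(det$irb, planted$irb)
      expect_equal(2L * det$ir_len + diff(det$lsc) + diff(det$ssc),
                   det$genome_length)
    }
  }
})

test_that("quadripartite sum invariant holds for the packaged metadata", {
  tb <- load_fixture("table1")
  pk <- tb[tb$taxon_id == "Parachlorella_kessleri", ]
  expect_equal(2 * pk$ir_length + pk$lsc_length + pk$ssc_length,
               pk$genome_length)
  expect_equal(pk$genome_length, 123994L)
})

test_that("partition classification assigns regions and flags relocations", {
  cfg <- sim_config(n_genes = 91L, genome_length_target = 70000L, seed = 41L,
                    rates = c(inversion = 0, ir_expand = 0, ir_contract = 0,
                              ir_loss = 0, repeat_insert = 0))
  anc <- make_ancestor(cfg)
  tr <- ape::read.tree(text = "(u,v);")
  truth <- evolve_plastomes(anc, tr, cfg)
  g <- truth$tips$u
  ir <- truth$tip_ir$u
  part <- classify_partitioning(g, ir)
  expect_setequal(unique(part$region), c("IR", "LSC", "SSC"))
  expect_equal(sum(duplicated(part$symbol)), 0L)
  # the rDNA operon lives in the IR
  expect_true(all(part$region[part$symbol %in%
                                c("rrs", "rrl", "rrf")] == "IR"))
  # ancestral layout: no single-copy gene on the opposite side
  lsc_dev <- part$deviant[part$region == "LSC"]
  expect_false(any(lsc_dev))

  # after two IR expansions on the LSC side those genes move into the IR
  arch2 <- plastarch:::apply_event(truth$tip_arch$u, "ir_expand",
                                   list(side = "lsc"))
  arch2 <- plastarch:::apply_event(arch2, "ir_expand", list(side = "lsc"))
  moved <- setdiff(arch2$ir$symbol, truth$tip_arch$u$ir$symbol)
  expect_length(moved, 2L)
  real2 <- plastarch:::realize_tip(arch2, cfg, 999L, taxon = "u2")
  part2 <- classify_partitioning(real2$genome, real2$ir)
  expect_true(all(part2$region[part2$symbol %in% moved] == "IR"))
})

test_that("genes straddling an IR junction are assigned to the single-copy side", {
  ir <- structure(list(ira = c(1000L, 3000L), irb = c(5000L, 7000L),
                       lsc = c(7000L, 11000L), ssc = c(3000L, 5000L),
                       ir_len = 2000L, genome_length = 10000L),
                  class = "ir_annotation")
  # spans the IRA/SSC junction at 3000
  expect_equal(plastarch:::region_of_span(2900L, 3100L, ir), "SSC")
  # spans the LSC/IRA junction at 1000
  expect_equal(plastarch:::region_of_span(900L, 1100L, ir), "LSC")
  expect_equal(plastarch:::region_of_span(1500L, 1600L, ir), "IR")
})

test_that("rDNA operon integrity and orientation reporting", {
  op <- c("rrs", "trnI(gau)", "trnA(ugc)", "rrl", "rrf")
  intact <- gene_order(c("a", op, "b"), c(1L, rep(1L, 5), 1L))
  rep0 <- rdna_operon_check(intact)
  expect_true(rep0$intact)
  expect_length(rep0$breakpoints, 0L)

  # whole operon on the other strand, read in reverse order: still intact
  flipped <- gene_order(c("a", rev(op), "b"), c(1L, rep(-1L, 5), 1L))
  repf <- rdna_operon_check(flipped)
  expect_true(repf$intact)
  expect_equal(repf$orientation, "reverse")

  # relocating trnI(gau) breaks its two adjacencies
  moved <- gene_order(c("a", "rrs", "trnA(ugc)", "rrl", "rrf", "b", "trnI(gau)"),
                      rep(1L, 7))
  repm <- rdna_operon_check(moved)
  expect_setequal(repm$breakpoints,
                  c("rrs-trnI(gau)", "trnI(gau)-trnA(ugc)"))

  # a long internal spacer breaks cotranscription even when genes are adjacent
  coords <- tibble::tibble(symbol = op,
                           start = c(0L, 5000L, 5200L, 5400L, 8400L),
                           end = c(1400L, 5072L, 5272L, 8200L, 8520L))
  repsp <- rdna_operon_check(intact, coords = coords, max_spacer = 3000L)
  expect_true("rrs-trnI(gau)" %in% repsp$breakpoints)

  expect_error(rdna_operon_check(gene_order(c("rrs", "rrl"), c(1L, 1L))),
               "missing")
})

test_that("the simulated ancestor carries an intact operon transcribed toward the SSC", {
  cfg <- sim_config(n_genes = 30L, ir_gene_count = 8L, ssc_gene_count = 4L,
                    genome_length_target = 25000L, use_core_symbols = FALSE,
                    seed = 51L,
                    rates = c(inversion = 0, ir_expand = 0, ir_contract = 0,
                              ir_loss = 0, repeat_insert = 0))
  anc <- make_ancestor(cfg)
  tr <- ape::read.tree(text = "(x,y);")
  truth <- evolve_plastomes(anc, tr, cfg)
  g <- truth$tips$x
  ir <- truth$tip_ir$x
  ft <- g$features
  coords <- dplyr::summarise(dplyr::group_by(ft, symbol),
                             start = min(start), end = max(end))
  repx <- rdna_operon_check(truth$tip_order$x, coords = coords, ir = ir)
  expect_true(repx$intact)
  expect_equal(repx$orientation, "toward_SSC")
})
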