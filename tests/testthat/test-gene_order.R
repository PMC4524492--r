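test_that("sidedness index matches its defining formula on canonical cases", {
  all_plus <- gene_order(paste0("g", 1:10), rep(1L, 10))
  expect_equal(sidedness_index(all_plus)$cs, 1)

  alternating <- gene_order(paste0("g", 1:6), rep(c(1L, -1L), 3))
  res <- sidedness_index(alternating)
  expect_equal(res$n_sb, 6L)
  expect_equal(res$cs, 0)

  # circular (+,+,-,-,+): first and last runs merge -> 2 blocks
  o <- gene_order(paste0("g", 1:5), c(1L, 1L, -1L, -1L, 1L))
  res <- sidedness_index(o)
  expect_equal(res$n_sb, 2L)
  expect_equal(res$cs, 0.75)

  # linear counting of the same signs does not merge the ends
  res_lin <- sidedness_index(o, circular = FALSE)
  expect_equal(res_lin$n_sb, 3L)
})

test_that("circular block counting agrees with brute force on random orders", {
  set.seed(401)
  for (rep in 1:300) {
    n <- sample(2:40, 1)
    signs <- sample(c(1L, -1L), n, replace = TRUE)
    o <- gene_order(paste0("g", seq_len(n)), signs)
    res <- sidedness_index(o)
    expect_equal(res$n_sb, brute_sided_blocks(signs))
    expect_gte(res$cs, 0)
    expect_lte(res$cs, 1)
    expect_equal(res$cs == 1, res$n_sb == 1L)
  }
})

test_that("flipping one gene inside a sided block strictly lowers Cs", {
  set.seed(402)
  for (rep in 1:50) {
    n <- sample(6:30, 1)
    signs <- rep(1L, n)
    # plant some opposite-strand genes but keep a block of >= 3
    k <- sample(0:(n %/% 3), 1)
    if (k > 0) signs[sample(n, k)] <- -1L
    runs <- rle(signs)
    big <- which(runs$lengths >= 3L)
    if (length(big) == 0L) next
    b <- big[1]
    pos <- sum(runs$lengths[seq_len(b - 1L)]) + 2L  # interior of the block
    cs0 <- sidedness_index(gene_order(paste0("g", 1:n), signs))$cs
    signs2 <- signs
    signs2[pos] <- -signs2[pos]
    cs1 <- sidedness_index(gene_order(paste0("g", 1:n), signs2))$cs
    expect_lt(cs1, cs0)
  }
})

test_that("canonical pairs: counts, canonicalization and reflection symmetry", {
  o <- gene_order(c("a", "b", "c"), c(1L, 1L, -1L))
  p <- canonical_pairs(o)
  expect_equal(nrow(p), 3L)  # n pairs for circular order
  expect_equal(canonical_pair_id("+b", "-a"), canonical_pair_id("+a", "-b"))
  expect_equal(canonical_pair_id("+x", "+y"),
               canonical_pair_id("-y", "-x"))

  lin <- gene_order(c("a", "b", "c"), c(1L, 1L, 1L), circular = FALSE)
  expect_equal(nrow(canonical_pairs(lin)), 2L)

  # whole-order reflection (reverse + flip signs) leaves the pair set intact
  set.seed(403)
  for (rep in 1:40) {
    n <- sample(3:20, 1)
    syms <- paste0("g", sample(1000, n))
    signs <- sample(c(1L, -1L), n, replace = TRUE)
    o1 <- gene_order(syms, signs)
    o2 <- gene_order(rev(syms), rev(-signs))
    expect_setequal(canonical_pairs(o1)$pair, canonical_pairs(o2)$pair)
    expect_equal(nrow(canonical_pairs(o1)), n)
  }
})

test_that("shared pair matrix: retention, gray cells and planted inversions", {
  o1 <- gene_order(c("a", "b", "c", "d"), c(1L, 1L, -1L, 1L), taxon = "t1")
  o2 <- gene_order(c("a", "b", "c", "d"), c(1L, 1L, -1L, 1L), taxon = "t2")
  both <- plastarch:::new_gene_order(dplyr::bind_rows(o1, o2))
  pm <- shared_pair_matrix(both, min_share = 2L)
  expect_true(all(pm$state == 1L))
  expect_equal(length(unique(pm$pair)), 4L)

  # disjoint gene sets share nothing
  o3 <- gene_order(c("x", "y", "z"), taxon = "t3")
  disj <- plastarch:::new_gene_order(dplyr::bind_rows(o1, o3))
  pm2 <- shared_pair_matrix(disj, min_share = 2L)
  expect_equal(nrow(pm2), 0L)

  # a pair whose gene is absent in one taxon is NA there, 0 when both exist
  o4 <- gene_order(c("a", "b", "d", "c"), c(1L, 1L, 1L, -1L), taxon = "t4")
  o5 <- gene_order(c("a", "b"), c(1L, 1L), taxon = "t5")
  pm3 <- shared_pair_matrix(
    plastarch:::new_gene_order(dplyr::bind_rows(o1, o2, o4, o5)),
    min_share = 2L)
  ab <- pm3[pm3$pair == canonical_pair_id("+a", "+b"), ]
  expect_true(all(ab$state == 1L))
  cd_cells <- pm3[pm3$pair == canonical_pair_id("-c", "+d"), ]
  expect_true(is.na(cd_cells$state[cd_cells$taxon == "t5"]))
  expect_equal(cd_cells$state[cd_cells$taxon == "t4"], 0L)

  expect_error(shared_pair_matrix(both, min_share = 1L), "min_share")

  # taxon input order never changes the matrix content
  pm_fwd <- shared_pair_matrix(
    plastarch:::new_gene_order(dplyr::bind_rows(o1, o2, o4)), min_share = 2L)
  pm_rev <- shared_pair_matrix(
    plastarch:::new_gene_order(dplyr::bind_rows(o4, o2, o1)), min_share = 2L)
  expect_identical(as.data.frame(pm_fwd), as.data.frame(pm_rev))
})

test_that("one planted inversion changes exactly the breakpoint-spanning pairs", {
  set.seed(404)
  n <- 20L
  syms <- paste0("g", 1:n)
  parent <- gene_order(syms, sample(c(1L, -1L), n, TRUE), taxon = "parent")
  child_df <- as.data.frame(parent)
  i <- 5L; j <- 12L
  idx <- i:j
  child_df$symbol[idx] <- rev(child_df$symbol[idx])
  child_df$sign[idx] <- -rev(child_df$sign[idx])
  child_df$taxon <- "child"
  child <- plastarch:::new_gene_order(tibble::as_tibble(child_df))
  pp <- canonical_pairs(parent)$pair
  pc <- canonical_pairs(child)$pair
  expect_equal(length(setdiff(pp, pc)), 2L)  # the two breakpoint junctions
  expect_equal(length(setdiff(pc, pp)), 2L)
})

test_that("signed order extraction collapses the IR and keeps first duplicates", {
  truth <- sim_bundle_cached()
  for (tx in names(truth$tips)) {
    g <- truth$tips[[tx]]
    ir <- truth$tip_ir[[tx]]
    o <- suppressMessages(
      extract_signed_gene_order(g, gene_filter = NULL, ir = ir))
    expect_identical(as.data.frame(o[, c("symbol", "sign")]),
                     as.data.frame(truth$tip_order[[tx]][, c("symbol", "sign")]))
    expect_false(anyDuplicated(o$symbol) > 0)
  }
  expect_error(
    extract_signed_gene_order(truth$tips$A, gene_filter = "no_such_gene"),
    "no genes")
})

test_that("core gene set is the intersection over complete genomes", {
  truth <- sim_bundle_cached()
  g1 <- truth$tips$A
  core_one <- core_gene_set(g1)
  expect_setequal(core_one,
                  unique(g1$features$symbol[g1$features$kind %in%
                                              c("CDS", "tRNA", "rRNA")]))
  # drop one gene from a second genome
  g2 <- truth$tips$B
  drop_sym <- setdiff(core_one, "rrs")[1]
  g2$features <- g2$features[g2$features$symbol != drop_sym, ]
  expect_setequal(core_gene_set(list(g1, g2)), setdiff(core_one, drop_sym))
  # incomplete genomes are excluded with a warning
  g3 <- truth$tips$C
  g3$complete <- FALSE
  expect_warning(cs <- core_gene_set(list(g1, g3)), "incomplete")
  expect_setequal(cs, core_one)
})

test_that("grimm-style text round-trips gene orders", {
  truth <- sim_bundle_cached()
  orders <- dplyr::bind_rows(lapply(truth$tip_order, tibble::as_tibble))
  f <- withr::local_tempfile(fileext = ".txt")
  write_grimm(orders, f)
  back <- read_grimm(f)
  expect_identical(as.data.frame(back), as.data.frame(orders))
})
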