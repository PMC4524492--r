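test_that("planted direct and palindromic repeats are recovered with exact coordinates", {
  set.seed(701)
  unit <- random_dna(1000, 60)
  dup <- random_dna(50, 50)
  s <- paste0(substr(unit, 1, 200), dup, substr(unit, 201, 600), dup,
              substr(unit, 601, 1000))
  h <- find_maximal_repeats(s, 30, kinds = "forward")
  expect_gte(nrow(h), 1L)
  main <- h[which.max(h$length), ]
  # the planted copies sit at 200 and 650; coincidental flank matches may
  # extend the maximal hit outward but it must contain the plant
  expect_lte(main$start_a, 200L); expect_gte(main$end_a, 250L)
  expect_lte(main$start_b, 650L); expect_gte(main$end_b, 700L)
  expect_identical(substr(s, main$start_a + 1, main$end_a),
                   substr(s, main$start_b + 1, main$end_b))

  pal <- random_dna(40, 50)
  s2 <- paste0(substr(unit, 1, 300), pal, substr(unit, 301, 700),
               revcomp(pal), substr(unit, 701, 1000))
  h2 <- find_maximal_repeats(s2, 30, kinds = "palindromic")
  expect_gte(nrow(h2), 1L)
  main2 <- h2[which.max(h2$length), ]
  expect_lte(main2$start_a, 300L); expect_gte(main2$end_a, 340L)
  expect_identical(substr(s2, main2$start_a + 1, main2$end_a),
                   revcomp(substr(s2, main2$start_b + 1, main2$end_b)))
})

test_that("seed-and-extend equals the quadratic brute-force scan", {
  set.seed(702)
  for (rep in 1:4) {
    base <- random_dna(400, 65)
    # plant one duplication and one inverted copy to make hits likely
    s <- paste0(substr(base, 1, 120), substr(base, 40, 80),
                substr(base, 121, 300), revcomp(substr(base, 200, 240)),
                substr(base, 301, 400))
    for (kind in c("forward", "palindromic")) {
      mine <- find_maximal_repeats(s, 30, kinds = kind)
      bf <- brute_force_repeats(s, 30, kind = kind)
      mine_key <- sort(paste(mine$start_a, mine$end_a, mine$start_b, mine$end_b))
      bf_key <- sort(paste(bf$start_a, bf$end_a, bf$start_b, bf$end_b))
      expect_identical(mine_key, bf_key)
    }
  }
  # clean random sequence: both report nothing
  s0 <- random_dna(800, 50)
  expect_identical(nrow(find_maximal_repeats(s0, 30)),
                   nrow(brute_force_repeats(s0, 30)) +
                     nrow(brute_force_repeats(s0, 30, "palindromic")))
})

test_that("every reported hit is maximal: one-base extension breaks identity", {
  set.seed(703)
  base <- random_dna(600, 60)
  s <- paste0(substr(base, 1, 150), substr(base, 50, 110),
              substr(base, 151, 450), revcomp(substr(base, 300, 350)),
              substr(base, 451, 600))
  h <- find_maximal_repeats(s, 30)
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  comp <- function(x) chartr("ACGT", "TGCA", x)
  for (i in seq_len(nrow(h))) {
    sa <- h$start_a[i]; ea <- h$end_a[i]; sb <- h$start_b[i]; eb <- h$end_b[i]
    if (h$kind[i] == "forward") {
      if (sa > 0 && sb > 0) expect_false(ch[sa] == ch[sb])
      if (ea < n && eb < n) expect_false(ch[ea + 1] == ch[eb + 1])
    } else {
      # extending a palindromic pair moves the two loci apart symmetrically
      if (sa > 0 && eb < n) expect_false(ch[sa] == comp(ch[eb + 1]))
      if (ea < n && sb > 0) expect_false(ch[ea + 1] == comp(ch[sb]))
    }
  }
})

test_that("masking arithmetic: union counting and GC recombination identity", {
  s <- paste0(strrep("A", 400), strrep("G", 200), strrep("T", 400))
  # one 100-bp duplicate in 1000 bp -> 200 bp masked, 20%
  hits <- tibble::tibble(start_a = 0L, end_a = 100L, start_b = 300L,
                         end_b = 400L, kind = "forward", length = 100L)
  sm <- mask_and_summarize(s, hits)
  expect_equal(sm$masked_bp, 200L)
  expect_equal(sm$masked_percent, 20)

  # no hits: nothing masked, unique GC is genome GC
  sm0 <- mask_and_summarize(s, hits[0, ])
  expect_equal(sm0$masked_percent, 0)
  expect_equal(sm0$gc_unique, sm0$gc_genome)

  # arbitrary overlapping hit sets: length-weighted GC identity to 1e-9
  set.seed(704)
  for (rep in 1:20) {
    sq <- random_dna(2000, sample(40:75, 1))
    k <- sample(1:8, 1)
    st <- sample(0:1900, k); en <- pmin(2000L, st + sample(30:300, k, TRUE))
    hh <- tibble::tibble(start_a = st, end_a = en,
                         start_b = st, end_b = en,
                         kind = "forward", length = en - st)
    smx <- mask_and_summarize(sq, hh)
    recomb <- (smx$gc_repeat * smx$masked_bp +
                 smx$gc_unique * (smx$genome_length - smx$masked_bp)) /
      smx$genome_length
    expect_equal(recomb, smx$gc_genome, tolerance = 1e-9)
  }

  expect_error(
    mask_and_summarize(s, tibble::tibble(start_a = -5L, end_a = 40L,
                                         start_b = 100L, end_b = 145L,
                                         kind = "forward", length = 45L)),
    "range")
})

test_that("size classes bin distinct elements and identical elements collapse", {
  s <- paste0(strrep("A", 50), random_dna(500, 50))
  el35 <- random_dna(35, 50); el70 <- random_dna(70, 50)
  sq <- paste0(s, el35, random_dna(80, 50), el35, random_dna(60, 50),
               el70, random_dna(90, 50), el70)
  h <- find_maximal_repeats(sq, 30, kinds = "forward")
  sm <- mask_and_summarize(sq, h)
  tab <- sm$size_classes
  expect_equal(sum(tab$n), sm$n_elements)
  expect_gte(tab$n[tab$size_class == "30-39"], 1L)
  expect_gte(tab$n[tab$size_class == "60-89"], 1L)
})

test_that("IR copies are excluded from the masked fraction by default", {
  truth <- sim_bundle_cached()
  with_ir <- names(Filter(Negate(is.null), truth$tip_ir))[1]
  g <- truth$tips[[with_ir]]
  ir <- truth$tip_ir[[with_ir]]
  rl_excl <- repeat_landscape(g, irs = setNames(list(ir), g$taxon))
  rl_incl <- repeat_landscape(g, include_ir = TRUE)
  expect_gte(rl_incl$masked_bp, rl_excl$masked_bp + 2L * ir$ir_len - 10L)
})
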