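test_that("LD measures reproduce the textbook cases and the direct formula", {
  complete <- ld_measures(c(5, 0, 0, 5))
  expect_equal(complete$dprime, 1)
  expect_equal(complete$r2, 1)
  indep <- ld_measures(c(25, 25, 25, 25))
  expect_equal(indep$D, 0)
  expect_equal(indep$r2, 0)
  # direct formula oracle on counts (40, 10, 10, 40)
  n <- 100; pA <- 0.5; pB <- 0.5
  D <- 40 / n - pA * pB
  expect_equal(ld_measures(c(40, 10, 10, 40))$r2,
               D^2 / (pA * (1 - pA) * pB * (1 - pB)))
  expect_equal(ld_measures(c(40, 10, 10, 40))$r2, 0.36)
  # monomorphic locus: undefined, flagged
  expect_false(ld_measures(c(10, 0, 5, 0))$defined)
})

test_that("r2 and D-prime stay within their bounds on random counts", {
  set.seed(31)
  for (i in 1:200) {
    cnt <- rmultinom(1, sample(10:200, 1), runif(4, 0.05, 1))[, 1]
    m <- ld_measures(cnt)
    if (!m$defined) next
    expect_gte(m$r2, -1e-9); expect_lte(m$r2, 1 + 1e-9)
    expect_gte(m$dprime, -1e-9); expect_lte(m$dprime, 1 + 1e-9)
  }
})

test_that("D-prime CI concentrates under complete LD and is wide for tiny samples", {
  big <- dprime_ci(c(500, 0, 0, 500))
  expect_gte(big[["low"]], 0.98)
  expect_equal(big[["high"]], 1.0)
  tiny <- dprime_ci(c(1, 1, 1, 1))
  expect_gte(tiny[["high"]] - tiny[["low"]], 0.5)
  expect_error(dprime_ci(c(1, 0, 0, 0)), "at least 2")
  expect_true(all(is.na(dprime_ci(c(4, 0, 4, 0)))))
})

test_that("D-prime CI endpoints match a fine-grid evaluation", {
  set.seed(32)
  cases <- list(c(30, 5, 5, 30), c(12, 3, 8, 7), c(50, 1, 2, 47),
                c(9, 9, 9, 9))
  for (i in 1:10) {
    cases[[length(cases) + 1]] <-
      rmultinom(1, sample(20:150, 1), runif(4, 0.1, 1))[, 1]
  }
  for (cnt in cases) {
    m <- ld_measures(cnt)
    if (!m$defined) next
    coarse <- dprime_ci(cnt, grid_n = 101)
    fine <- dprime_ci(cnt, grid_n = 10001)
    expect_lt(abs(coarse[["low"]] - fine[["low"]]), 0.011)
    expect_lt(abs(coarse[["high"]] - fine[["high"]]), 0.011)
    # CI brackets the point estimate (within grid resolution: the one-sided
    # inclusive tails can sit a couple of steps off a skewed likelihood)
    expect_lte(coarse[["low"]], m$dprime + 0.02 + 1e-9)
    expect_gte(coarse[["high"]], m$dprime - 0.02 - 1e-9)
  }
})

test_that("replicating the same proportions narrows the D-prime CI monotonically", {
  base <- c(12, 4, 5, 9)
  widths <- sapply(c(1, 2, 4, 8), function(k) {
    ci <- dprime_ci(base * k)
    ci[["high"]] - ci[["low"]]
  })
  expect_true(all(diff(widths) <= 1e-12))
})

test_that("Gabriel blocks recover perfect-LD panels and reject equilibrium panels", {
  # 5 markers in complete LD: two haplotypes at moderate frequency
  ph <- toy_phased(lean = rep(c("AAAAA", "GGGGG"), each = 20),
                   fat = rep(c("AAAAA", "GGGGG"), each = 20))
  pr <- ld_pairs(ph)
  b <- gabriel_blocks(pr, 5)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start_idx, b$end_idx), c(1L, 5L))
  # linkage equilibrium with a large sample: no blocks
  set.seed(33)
  h <- matrix(sample(c("A", "G"), 400 * 6, replace = TRUE), 400, 6)
  strs <- apply(h, 1, paste, collapse = "")
  ph2 <- toy_phased(lean = strs[1:200], fat = strs[201:400])
  expect_equal(nrow(gabriel_blocks(ld_pairs(ph2), 6)), 0L)
})

test_that("Gabriel blocks equal the exhaustive-span oracle on 12-marker panels", {
  set.seed(34)
  for (rep in 1:6) {
    # block-structured panel: 2 ancestral haplotypes per segment + noise
    anc <- matrix(sample(c("A", "G"), 2 * 12, replace = TRUE), 2, 12)
    pick <- sample(1:2, 60, replace = TRUE)
    h <- anc[pick, , drop = FALSE]
    flip <- matrix(runif(60 * 12) < 0.08, 60, 12)
    h[flip] <- ifelse(h[flip] == "A", "G", "A")
    # force a recombination break in the middle
    h[31:60, 7:12] <- h[sample(1:30, 30, replace = TRUE), 7:12]
    strs <- apply(h, 1, paste, collapse = "")
    ph <- toy_phased(lean = strs[1:30], fat = strs[31:60])
    pr <- ld_pairs(ph)
    got <- gabriel_blocks(pr, 12)
    want <- oracle_gabriel(pr, 12)
    expect_equal(got[, c("start_idx", "end_idx")], want)
  }
})

test_that("Gabriel blocks are invariant to allele relabelling at a marker", {
  set.seed(35)
  ph <- toy_phased(lean = rep(c("AAAA", "GGGG", "AAGG"), times = c(15, 15, 4)),
                   fat = rep(c("AAAA", "GGGG"), each = 17))
  b1 <- gabriel_blocks(ld_pairs(ph), 4)
  # swap alleles at marker 2
  hap2 <- ph$hap
  hap2[, 2] <- ifelse(hap2[, 2] == "A", "G", "A")
  ph2 <- phased_haps(hap2, ph$info, ph$map)
  b2 <- gabriel_blocks(ld_pairs(ph2), 4)
  expect_equal(b1, b2)
})

test_that("the haploview preset can withhold short blocks the plain rule accepts", {
  # a 2-marker pair with a strong but not extreme CI lower bound
  pairs <- data.frame(i = 1L, j = 2L, ci_low = 0.75, ci_high = 0.99,
                      class = "strong")
  expect_equal(nrow(gabriel_blocks(pairs, 2, preset = "plain")), 1L)
  expect_equal(nrow(gabriel_blocks(pairs, 2, preset = "haploview")), 0L)
  pairs$ci_low <- 0.85
  expect_equal(nrow(gabriel_blocks(pairs, 2, preset = "haploview")), 1L)
})

test_that("mean adjacent r2 matches per-pair recomputation", {
  ph <- toy_phased(lean = rep(c("AAAAAA", "GGGGGG"), each = 12),
                   fat = rep(c("AAAAAA", "GGGGGG"), each = 12))
  expect_equal(mean_adjacent_r2(ph), 1)
  set.seed(36)
  h <- matrix(sample(c("A", "G"), 600 * 6, replace = TRUE), 600, 6)
  strs <- apply(h, 1, paste, collapse = "")
  ph2 <- toy_phased(lean = strs[1:300], fat = strs[301:600])
  expect_lt(mean_adjacent_r2(ph2, "lean"), 0.05)
  # oracle: mean of individually recomputed adjacent pairs
  hb <- hap_binary(ph2, "lean")
  r2s <- sapply(1:5, function(i)
    ld_measures(two_locus_counts(hb[, i], hb[, i + 1]))$r2)
  expect_equal(mean_adjacent_r2(ph2, "lean"), mean(r2s))
})
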