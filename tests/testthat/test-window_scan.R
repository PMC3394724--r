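test_that("line allele frequencies count allele-1 copies over called genotypes", {
  g <- cbind(c(2L, 2L, 1L, 0L), c(2L, 2L, 2L, 2L), c(2L, NA, 0L, NA))
  ds <- toy_dataset(g, line = rep("lean", 4))
  # frequencies need both lines present in the container; add a fat row set
  g2 <- rbind(g, matrix(0L, 2, 3))
  ds <- toy_dataset(g2, line = c(rep("lean", 4), "fat", "fat"))
  p <- line_allele_freq(ds, "lean")
  expect_equal(p, c(5 / 8, 1, 0.5))
})

test_that("per-SNP AFD and expected heterozygosity follow their closed forms", {
  # lean p = 0.9, fat p = 0.2 at SNP 1; equal frequencies at SNP 2
  g_lean <- cbind(c(2L, 2L, 2L, 2L, 1L), rep(1L, 5))
  g_fat <- cbind(c(1L, 1L, 0L, 0L, 0L), rep(1L, 5))
  ds <- toy_dataset(rbind(g_lean, g_fat),
                    line = rep(c("lean", "fat"), each = 5))
  st <- snp_stats(ds)
  expect_equal(st$afd, c(0.7, 0))
  expect_equal(st$het_lean, c(2 * 0.9 * 0.1, 0.5))
  expect_equal(st$het_fat, c(2 * 0.2 * 0.8, 0.5))
  # fixed allele: het 0
  ds2 <- toy_dataset(matrix(c(2L, 2L, 0L, 0L), 2, 2),
                     line = c("lean", "fat"))
  st2 <- snp_stats(ds2)
  expect_equal(st2$het_lean, c(0, 0))
})

test_that("sliding windows tile by interval membership and drop sparse windows", {
  map <- data.frame(id = c("a", "b", "c"), chrom = "1",
                    pos_bp = c(100e3, 300e3, 600e3),
                    allele_a = "A", allele_b = "G")
  w <- sliding_windows(map, size_bp = 500e3, step_bp = 500e3, min_snps = 1)
  expect_equal(w$n_snps, c(2L, 1L))
  expect_equal(w$snp_idx[[1]], c(1L, 2L))
  # empty chromosome contributes no windows
  w0 <- sliding_windows(map[0, ], min_snps = 1)
  expect_equal(nrow(w0), 0L)
})

test_that("overlapping window membership matches a brute-force interval scan", {
  set.seed(21)
  for (rep in 1:5) {
    pos <- sort(sample(1:2e6, 120))
    map <- data.frame(id = sprintf("m%03d", 1:120), chrom = "7",
                      pos_bp = pos, allele_a = "A", allele_b = "G")
    w <- sliding_windows(map, size_bp = 500e3, step_bp = 250e3, min_snps = 3)
    # oracle: enumerate every start on the step grid and scan all markers
    start0 <- floor(min(pos) / 250e3) * 250e3
    starts <- seq(start0, max(pos), by = 250e3)
    oracle <- Filter(function(x) length(x$idx) >= 3,
                     lapply(starts, function(s)
                       list(s = s, idx = which(pos >= s & pos < s + 500e3))))
    expect_equal(nrow(w), length(oracle))
    for (k in seq_along(oracle)) {
      expect_equal(w$start_bp[k], oracle[[k]]$s)
      expect_equal(w$snp_idx[[k]], oracle[[k]]$idx)
    }
  }
})

test_that("window summaries equal independent re-summation", {
  set.seed(22)
  g <- matrix(rbinom(40 * 60, 2, runif(60, 0.2, 0.8)), 40, 60, byrow = TRUE)
  ds <- toy_dataset(g, pos = sort(sample(1:1.5e6, 60)))
  st <- snp_stats(ds)
  w <- sliding_windows(ds$map, min_snps = 1)
  ws <- window_summary(w, st)
  for (k in seq_len(nrow(ws))) {
    i <- ws$snp_idx[[k]]
    expect_equal(ws$afd_mean[k], sum(st$afd[i]) / length(i))
    expect_equal(ws$het_lean_mean[k], sum(st$het_lean[i]) / length(i))
  }
  # a single-member window's means equal that SNP's stats
  one <- which(ws$n_snps == 1)
  if (length(one)) {
    i <- ws$snp_idx[[one[1]]]
    expect_equal(ws$afd_mean[one[1]], st$afd[i])
  }
  # two SNPs with afd 0.6 and 0.8 average to 0.7
  expect_equal(mean(c(0.6, 0.8)), 0.7)
})

test_that("chromosome-wise standardization has mean 0, sd 1 and flags degenerate cases", {
  ws <- data.frame(chrom = rep(c("1", "2"), c(5, 1)),
                   start_bp = c(0, 1, 2, 3, 4, 0) * 250e3,
                   end_bp = c(0, 1, 2, 3, 4, 0) * 250e3 + 500e3,
                   n_snps = 5,
                   afd_mean = c(0.1, 0.2, 0.4, 0.3, 0.5, 0.9),
                   het_lean_mean = c(0.3, 0.3, 0.3, 0.3, 0.3, 0.1),
                   het_fat_mean = c(0.1, 0.2, 0.3, 0.2, 0.1, 0.4))
  z <- standardize_windows(ws)
  on1 <- z$chrom == "1"
  expect_equal(mean(z$z_afd[on1]), 0, tolerance = 1e-12)
  expect_equal(sd(z$z_afd[on1]), 1, tolerance = 1e-12)
  # hand calculation for the five AFD values
  x <- c(0.1, 0.2, 0.4, 0.3, 0.5)
  expect_equal(z$z_afd[on1], (x - mean(x)) / sd(x))
  # all-equal heterozygosity: non-assessable, never silently zero
  expect_true(all(is.na(z$z_lean[on1])))
  # single-window chromosome: non-assessable
  expect_true(all(is.na(z$z_afd[!on1])))
  # shift invariance
  ws2 <- ws; ws2$afd_mean <- ws2$afd_mean + 0.17
  expect_equal(standardize_windows(ws2)$z_afd[on1], z$z_afd[on1])
})

make_ws <- function(afd, z_afd, z_lean, z_fat, chrom = "1",
                    start = (seq_along(afd) - 1) * 250e3) {
  data.frame(chrom = chrom, start_bp = start, end_bp = start + 500e3,
             n_snps = 10, afd_mean = afd,
             het_lean_mean = 0.3, het_fat_mean = 0.3,
             z_afd = z_afd, z_lean = z_lean, z_fat = z_fat)
}

test_that("signature calling fires the documented threshold rules", {
  # strongest region: both AFD measures fire
  ws <- make_ws(0.75, 4.98, -3.7, -1.13)
  sg <- call_signatures(ws)
  expect_equal(nrow(sg), 1L)
  expect_true(grepl("AFD", sg$signals))
  expect_true(grepl("Z_AFD", sg$signals))
  # heterozygosity increase counted as a signal alongside AFD measures
  sg2 <- call_signatures(make_ws(0.50, 4.50, -3.58, 5.02))
  expect_true(grepl("Z_fat_up", sg2$signals))
  expect_true(sg2$het_increase)
  # fat-line heterozygosity decrease alone flags, and labels the fat line
  sg3 <- call_signatures(make_ws(0.26, 1.42, 0.76, -5.99))
  expect_equal(sg3$signals, "Z_fat_down")
  expect_equal(sg3$selected_line, "fat")
  # sub-threshold window: nothing
  expect_equal(nrow(call_signatures(make_ws(0.26, 1.42, 0.76, -1.2))), 0L)
})

test_that("flagged windows merge into disjoint sorted regions", {
  ws <- make_ws(afd = c(0.5, 0.6, 0.1, 0.1, 0.7, 0.1),
                z_afd = 0, z_lean = 0, z_fat = 0)
  sg <- call_signatures(ws)
  # windows 1-2 overlap (half-step) -> one region; window 5 separate
  expect_equal(nrow(sg), 2L)
  expect_true(all(sg$end_bp[-nrow(sg)] <= sg$start_bp[-1]))
  expect_equal(sg$peak_afd, c(0.6, 0.7))
  expect_equal(sg$n_windows, c(2L, 1L))
})

test_that("increasing member AFD never decreases the window mean", {
  set.seed(23)
  st <- data.frame(afd = runif(30), het_lean = 0.3, het_fat = 0.3)
  w <- data.frame(chrom = "1", start_bp = 0, end_bp = 1e6, n_snps = 30)
  w$snp_idx <- I(list(1:30))
  base <- window_summary(w, st)$afd_mean
  st2 <- st; st2$afd <- pmin(1, st2$afd + runif(30, 0, 0.2))
  expect_gte(window_summary(w, st2)$afd_mean, base)
})

test_that("chromosome summary counts fixed alleles exactly", {
  set.seed(24)
  n <- 30
  p_lean <- c(0, 1, runif(8, 0.1, 0.9))
  p_fat <- c(runif(9, 0.1, 0.9), 1)
  g_lean <- sapply(p_lean, function(p) rbinom(n, 2, p))
  g_fat <- sapply(p_fat, function(p) rbinom(n, 2, p))
  g_lean[, 1] <- 0L; g_lean[, 2] <- 2L       # force exact fixation
  g_fat[, 10] <- 2L
  ds <- toy_dataset(rbind(g_lean, g_fat),
                    line = rep(c("lean", "fat"), each = n))
  st <- snp_stats(ds)
  cs <- chromosome_summary(ds, st)
  # brute-force scan of the frequency vectors
  expect_equal(cs$fixed_lean, sum(st$p_lean %in% c(0, 1)))
  expect_equal(cs$fixed_fat, sum(st$p_fat %in% c(0, 1)))
  expect_gte(cs$fixed_lean, 2)
  expect_equal(cs$fixed_lean_pct, 100 * cs$fixed_lean / 10)
  expect_equal(cs$n_snps, 10L)
  expect_equal(cs$mean_spacing_bp, mean(diff(ds$map$pos_bp)))
})
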