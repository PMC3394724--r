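test_that("Bonferroni threshold arithmetic", {
  expect_equal(bonferroni_threshold(0.05, 1, 1, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 10, 1, 2), 5e-4)
  expect_equal(bonferroni_threshold(0.05, 45578, 2, 2),
               0.05 / (2 * 2 * 45578))
})

test_that("with no covariates and balanced families the adjustment removes the grand mean", {
  set.seed(61)
  fam <- rep(sprintf("f%02d", 1:10), each = 8)
  y <- rnorm(80) + rep(rnorm(10, 0, 0.7), each = 8)
  adj <- adjust_phenotypes(y, fam)
  expect_equal(adj$adjusted, y - mean(y))
})

test_that("a planted covariate effect is recovered within 3 SE", {
  set.seed(62)
  fam <- rep(sprintf("f%02d", 1:25), each = 8)
  hatch <- factor(sample(c("1", "2"), 200, replace = TRUE))
  beta_true <- 0.8
  y <- beta_true * (hatch == "2") + rep(rnorm(25, 0, 0.5), each = 8) +
    rnorm(200)
  adj <- adjust_phenotypes(y, fam, data.frame(hatch = hatch))
  est <- adj$beta[["hatch2"]]
  se_rough <- sqrt(4 / 200)   # conservative scale for this design
  expect_lt(abs(est - beta_true), 3 * se_rough)
  expect_gt(adj$sigma_f2, 0)
})

test_that("GLS reduces to ordinary least squares when the family variance is zero", {
  # family means exactly equal -> moment estimate truncates to zero
  y <- rep(c(-1, 0, 1), times = 4)
  fam <- rep(c("a", "b", "c", "d"), each = 3)
  expect_message(adj <- adjust_phenotypes(y, fam), "zero")
  expect_equal(adj$sigma_f2, 0)
  fit <- lm(y ~ 1)
  expect_equal(unname(adj$beta[1]), unname(coef(fit)[1]))
  expect_error(adjust_phenotypes(rnorm(6), rep("one", 6)), "2 families")
})

test_that("collinear covariates raise an error naming the columns", {
  fam <- rep(c("a", "b"), each = 10)
  x <- rnorm(20)
  expect_error(
    adjust_phenotypes(rnorm(20), fam, data.frame(x1 = x, x2 = 2 * x)),
    "collinear.*x2")
})

test_that("additive and dominance contrasts recover planted effects", {
  set.seed(63)
  n <- 400
  fam <- rep(sprintf("f%02d", 1:50), each = 8)
  g <- rbinom(n, 2, 0.5)
  # pure additive signal
  y_add <- 0.6 * (g - 1) + rnorm(n, 0, 0.8)
  adj <- adjust_phenotypes(y_add, fam)
  r_add <- snp_tests(adj$adjusted, g, fam, adj$sigma_f2, adj$sigma_e2)
  expect_lt(abs(r_add$add_beta - 0.6), 0.2)
  expect_lt(r_add$add_p, 1e-8)
  expect_gt(r_add$dom_p, 1e-4)
  # pure overdominance: dominance fires, additive stays null-scale
  y_dom <- 0.8 * (g == 1) + rnorm(n, 0, 0.8)
  adj2 <- adjust_phenotypes(y_dom, fam)
  r_dom <- snp_tests(adj2$adjusted, g, fam, adj2$sigma_f2, adj2$sigma_e2)
  expect_lt(r_dom$dom_p, 1e-8)
  expect_gt(r_dom$add_p, 1e-3)
})

test_that("degenerate SNPs are skipped with a reason", {
  set.seed(64)
  fam <- rep(c("a", "b", "c", "d"), each = 10)
  y <- rnorm(40)
  mono <- rep(2L, 40)
  r <- snp_tests(y, mono, fam)
  expect_equal(r$skipped, "monomorphic")
  # no heterozygotes: additive tested, dominance skipped
  g02 <- rep(c(0L, 2L), 20)
  r2 <- snp_tests(y, g02, fam)
  expect_false(is.na(r2$add_p))
  expect_true(is.na(r2$dom_p))
})

test_that("random-family and fixed-family models agree with plain regression when variance is zero", {
  set.seed(65)
  n <- 120
  fam <- rep(sprintf("f%02d", 1:12), each = 10)
  g <- rbinom(n, 2, 0.4)
  y <- 0.3 * (g - 1) + rnorm(n)
  y <- y - mean(y)
  r_gls <- snp_tests(y, g, fam, sigma_f2 = 0, sigma_e2 = var(y))
  fit <- lm(y ~ g + I(g == 1))
  p_lm <- summary(fit)$coefficients["g", 4]
  expect_equal(r_gls$add_p, p_lm, tolerance = 1e-8)
  # the fixed-family model with family in the design differs only through
  # the family columns; with balanced noise it stays close, but the exact
  # equality contract is against plain regression
  expect_equal(r_gls$add_beta,
               unname(coef(fit)["g"]), tolerance = 1e-8)
})

test_that("swapping the counted allele flips the estimate and keeps the p-value", {
  set.seed(66)
  n <- 200
  fam <- rep(sprintf("f%02d", 1:20), each = 10)
  g <- rbinom(n, 2, 0.4)
  y <- 0.4 * (g - 1) + rnorm(n)
  adj <- adjust_phenotypes(y, fam)
  r1 <- snp_tests(adj$adjusted, g, fam, adj$sigma_f2, adj$sigma_e2)
  r2 <- snp_tests(adj$adjusted, 2L - g, fam, adj$sigma_f2, adj$sigma_e2)
  expect_equal(r1$add_p, r2$add_p, tolerance = 1e-9)
  expect_equal(r1$add_beta, -r2$add_beta, tolerance = 1e-9)
})

test_that("p-values are uniform under a permutation null (KS at the 1% level)", {
  set.seed(67)
  n <- 400
  fam <- rep(sprintf("f%02d", 1:50), each = 8)
  y <- rnorm(n) + rep(rnorm(50, 0, 0.5), each = 8)
  m_per <- 2000
  pvals <- numeric(0)
  for (perm in 1:5) {
    yp <- sample(y)
    adj <- suppressMessages(adjust_phenotypes(yp, fam))
    geno <- matrix(rbinom(n * m_per, 2, runif(m_per, 0.15, 0.85)),
                   n, m_per, byrow = TRUE)
    r <- snp_tests(adj$adjusted, geno, fam, adj$sigma_f2, adj$sigma_e2)
    pvals <- c(pvals, r$add_p)
  }
  pvals <- pvals[!is.na(pvals)]
  expect_gte(length(pvals), 9900)
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("REML and moment variance components broadly agree", {
  skip_if_not_installed("lme4")
  set.seed(68)
  fam <- rep(sprintf("f%02d", 1:30), each = 8)
  y <- rep(rnorm(30, 0, 0.8), each = 8) + rnorm(240)
  a1 <- adjust_phenotypes(y, fam, method = "moment")
  a2 <- adjust_phenotypes(y, fam, method = "reml")
  expect_lt(abs(a1$sigma_f2 - a2$sigma_f2), 0.25)
  expect_lt(abs(a1$sigma_e2 - a2$sigma_e2), 0.25)
})

test_that("the genome-scan wrapper joins phenotypes and finds a planted QTL", {
  set.seed(69)
  cfg <- small_sim(seed = 70)
  res <- evolve_divergent(simulate_founders(cfg), cfg)
  dat <- sim_export(res$pop)
  a <- assoc_scan(dat$dataset, dat$phenotypes, "AFP", covariates = "hatch")
  top <- a$id[which.min(a$add_p)]
  qtl_id <- dat$dataset$map$id[dat$dataset$map$chrom == "1"][40]
  qtl_pos <- dat$dataset$map$pos_bp[dat$dataset$map$id == qtl_id]
  top_pos <- a$pos_bp[a$id == top]
  expect_true(a$chrom[a$id == top] == "1" &&
                abs(top_pos - qtl_pos) < 500e3)
})
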