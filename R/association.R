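#' Bonferroni genome-wide significance threshold
#'
#' `alpha / (n_traits * n_effects * n_snps)`: the genome-wide type-I error
#' split over every test performed (each SNP is tested for two effects,
#' additive and dominance, on each trait).
#'
#' @param alpha Genome-wide type-I error (default 0.05).
#' @param n_snps Number of SNP markers.
#' @param n_traits Number of traits tested (default 2).
#' @param n_effects Effects tested per SNP and trait (default 2: additive and
#'   dominance).
#' @return The per-test p-value threshold.
#' @examples
#' bonferroni_threshold(0.05, 45578)  # 2.74e-7
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_snps, n_traits = 2,
                                 n_effects = 2) {
  stopifnot(alpha > 0, n_snps > 0, n_traits > 0, n_effects > 0)
  alpha / (n_traits * n_effects * n_snps)
}

# Per-family whitening factors for a compound-symmetry covariance
# V_i = sigma_e^2 I + sigma_f^2 J (family i of size n_i):
# V_i^{-1/2} = (I - c_i J) / sigma_e with
# c_i = (1 - sqrt(sigma_e^2 / (sigma_e^2 + n_i sigma_f^2))) / n_i.
cs_whiten <- function(x, family, sigma_f2, sigma_e2) {
  x <- as.matrix(x)
  fam <- as.character(family)
  out <- x
  for (f in unique(fam)) {
    i <- which(fam == f)
    ni <- length(i)
    ci <- (1 - sqrt(sigma_e2 / (sigma_e2 + ni * sigma_f2))) / ni
    cm <- colMeans(x[i, , drop = FALSE])
    out[i, ] <- x[i, , drop = FALSE] -
      matrix(ci * ni * cm, ni, ncol(x), byrow = TRUE)
  }
  out / sqrt(sigma_e2)
}

# One-way ANOVA moment estimator of the family variance component
# (truncated at zero) from a response with no remaining fixed effects.
family_varcomp <- function(y, family) {
  fam <- factor(as.character(family))
  k <- nlevels(fam)
  n <- length(y)
  if (k < 2) stop("adjust_phenotypes() requires at least 2 families")
  ni <- as.numeric(table(fam))
  gm <- mean(y)
  fm <- tapply(y, fam, mean)
  ssb <- sum(ni * (fm - gm)^2)
  ssw <- sum((y - fm[as.integer(fam)])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  n0 <- (n - sum(ni^2) / n) / (k - 1)
  list(sigma_f2 = max(0, (msb - msw) / n0), sigma_e2 = msw)
}

#' Remove fixed non-genetic effects from a phenotype (GLS step)
#'
#' Two-step GLS-LS preparation: the family variance component is estimated
#' (one-way ANOVA moment estimator truncated at zero, or REML via
#' `lme4::lmer` with `method = "reml"`), fixed non-genetic covariate effects
#' are then estimated by generalized least squares under the implied
#' family-compound-symmetry covariance, and the fitted fixed effects
#' (including the intercept) are subtracted from the phenotype. When the
#' family variance estimate is zero, GLS reduces to ordinary least squares
#' (logged via message).
#'
#' @param y Numeric phenotype vector.
#' @param family Family identifier per individual (half-sib sire families).
#' @param covariates Optional data frame of fixed non-genetic covariates
#'   (e.g. hatch); factors and numerics allowed.
#' @param method Variance-component estimator: `"moment"` (default) or
#'   `"reml"` (requires lme4).
#' @return List with elements `adjusted` (centered, covariate-free
#'   phenotype), `sigma_f2`, `sigma_e2`, `beta` (fixed-effect estimates).
#' @export
adjust_phenotypes <- function(y, family, covariates = NULL,
                              method = c("moment", "reml")) {
  method <- match.arg(method)
  y <- as.numeric(y)
  X <- if (is.null(covariates)) {
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("covariate design is singular; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  if (method == "reml") {
    if (!requireNamespace("lme4", quietly = TRUE)) {
      stop("method = 'reml' requires the lme4 package")
    }
    dat <- data.frame(.y = y, .fam = factor(as.character(family)))
    Xdf <- as.data.frame(X[, -1, drop = FALSE])
    dat <- cbind(dat, Xdf)
    form <- stats::as.formula(paste(
      ".y ~", if (ncol(Xdf)) paste(c("1", colnames(Xdf)), collapse = " + ")
      else "1", "+ (1 | .fam)"))
    fit <- lme4::lmer(form, data = dat, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma_f2 <- vc$vcov[vc$grp == ".fam"]
    sigma_e2 <- vc$vcov[vc$grp == "Residual"]
    beta <- lme4::fixef(fit)
    adjusted <- y - as.numeric(X %*% beta)
    return(list(adjusted = adjusted, sigma_f2 = sigma_f2,
                sigma_e2 = sigma_e2, beta = beta))
  }
  # moment path: OLS residuals -> variance components -> GLS re-fit
  beta0 <- qr.coef(qrX, y)
  vc <- family_varcomp(y - as.numeric(X %*% beta0), family)
  if (vc$sigma_f2 == 0) {
    message("family variance component estimated at zero; ",
            "GLS reduces to ordinary least squares")
    beta <- beta0
  } else {
    Xw <- cs_whiten(X, family, vc$sigma_f2, vc$sigma_e2)
    yw <- cs_whiten(y, family, vc$sigma_f2, vc$sigma_e2)
    beta <- qr.coef(qr(Xw), yw)[, 1]
  }
  adjusted <- y - as.numeric(X %*% beta)
  list(adjusted = adjusted, sigma_f2 = vc$sigma_f2, sigma_e2 = vc$sigma_e2,
       beta = beta)
}

# 1-df Wald tests for the additive (allele-dosage trend) and dominance
# (heterozygote deviation) contrasts of a single SNP, on a possibly
# whitened response/design.
snp_test_one <- function(yw, ones_w, gw, hetw, df_extra = 0) {
  X <- cbind(ones_w, gw, if (!is.null(hetw)) hetw)
  fit <- stats::lm.fit(X, yw)
  df <- length(yw) - fit$rank - df_extra
  if (df <= 0) return(NULL)
  rss <- sum(fit$residuals^2)
  s2 <- rss / df
  R <- fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
  R[lower.tri(R)] <- 0
  XtXinv <- chol2inv(R)
  se <- sqrt(diag(XtXinv) * s2)
  beta <- fit$coefficients[seq_len(fit$rank)]
  tt <- beta / se
  p <- 2 * stats::pt(-abs(tt), df)
  list(beta = beta, p = p, df = df)
}

#' Single-SNP additive and dominance association tests
#'
#' Tests each SNP for an additive effect (linear trend over genotype codes
#' 0/1/2) and a dominance effect (heterozygote deviation) against a
#' covariate-adjusted phenotype under the model `Y = SNP + f + e` with `f` a
#' family effect. With `method = "gls-ls"` (the primary method) the family
#' effect is random: the response and design are whitened by the
#' compound-symmetry covariance implied by the variance components from
#' [adjust_phenotypes()], and 1-df F (equivalently two-sided t) tests are
#' taken from the whitened least-squares fit. With `method = "fixed-family"`
#' the family enters as fixed indicator columns (the secondary,
#' PLINK-style model).
#'
#' SNPs lacking two genotype classes with at least `min_class_n` observations
#' are skipped with a reason; the dominance test alone is skipped when there
#' are no heterozygotes.
#'
#' @param y Adjusted phenotype vector (see [adjust_phenotypes()]).
#' @param geno Genotype matrix (individuals x SNPs, codes 0/1/2/NA) or a
#'   single genotype vector.
#' @param family Family identifier per individual.
#' @param sigma_f2,sigma_e2 Variance components for the random-family
#'   covariance (from [adjust_phenotypes()]); ignored for
#'   `method = "fixed-family"`.
#' @param method `"gls-ls"` or `"fixed-family"`.
#' @param min_class_n Minimum observations per counted genotype class
#'   (default 3).
#' @return Data frame with one row per SNP: `add_beta`, `add_p`, `dom_beta`,
#'   `dom_p`, `n`, `n0`, `n1`, `n2`, `skipped` (reason or `NA`), `method`.
#' @export
snp_tests <- function(y, geno, family, sigma_f2 = 0, sigma_e2 = NULL,
                      method = c("gls-ls", "fixed-family"), min_class_n = 3) {
  method <- match.arg(method)
  if (!is.matrix(geno)) geno <- matrix(geno, ncol = 1)
  n <- length(y)
  stopifnot(nrow(geno) == n, length(family) == n)
  if (is.null(sigma_e2)) sigma_e2 <- stats::var(y)
  complete <- !is.na(y)
  whiten_all <- method == "gls-ls" && sigma_f2 > 0
  fam_chr <- as.character(family)
  # fast path (no missing genotypes): whiten response/intercept once
  if (whiten_all) {
    yw_full <- cs_whiten(y, fam_chr, sigma_f2, sigma_e2)[, 1]
    ones_full <- cs_whiten(rep(1, n), fam_chr, sigma_f2, sigma_e2)[, 1]
  } else {
    yw_full <- y
    ones_full <- rep(1, n)
  }
  fam_mm_full <- if (method == "fixed-family") {
    stats::model.matrix(~ factor(fam_chr))
  } else NULL

  m <- ncol(geno)
  res <- data.frame(add_beta = rep(NA_real_, m), add_p = NA_real_,
                    dom_beta = NA_real_, dom_p = NA_real_,
                    n = NA_integer_, n0 = NA_integer_, n1 = NA_integer_,
                    n2 = NA_integer_, skipped = NA_character_,
                    method = method)
  for (j in seq_len(m)) {
    g <- geno[, j]
    use <- complete & !is.na(g)
    gu <- g[use]
    cls <- c(n0 = sum(gu == 0), n1 = sum(gu == 1), n2 = sum(gu == 2))
    res$n[j] <- length(gu)
    res[j, c("n0", "n1", "n2")] <- as.list(as.integer(cls))
    if (sum(cls >= min_class_n) < 2) {
      res$skipped[j] <- if (sum(cls > 0) < 2) "monomorphic" else
        "insufficient_class_counts"
      next
    }
    test_dom <- cls[["n1"]] > 0
    if (all(use)) {
      yw <- yw_full; ones <- ones_full
      gw <- if (whiten_all) cs_whiten(gu, fam_chr, sigma_f2, sigma_e2)[, 1]
      else gu
      hetw <- if (test_dom) {
        hv <- as.numeric(gu == 1)
        if (whiten_all) cs_whiten(hv, fam_chr, sigma_f2, sigma_e2)[, 1] else hv
      } else NULL
      fam_mm <- fam_mm_full
    } else {
      fs <- fam_chr[use]
      if (whiten_all) {
        yw <- cs_whiten(y[use], fs, sigma_f2, sigma_e2)[, 1]
        ones <- cs_whiten(rep(1, sum(use)), fs, sigma_f2, sigma_e2)[, 1]
        gw <- cs_whiten(gu, fs, sigma_f2, sigma_e2)[, 1]
        hetw <- if (test_dom)
          cs_whiten(as.numeric(gu == 1), fs, sigma_f2, sigma_e2)[, 1]
        else NULL
      } else {
        yw <- y[use]; ones <- rep(1, sum(use)); gw <- gu
        hetw <- if (test_dom) as.numeric(gu == 1) else NULL
      }
      fam_mm <- if (method == "fixed-family")
        stats::model.matrix(~ factor(fs)) else NULL
    }
    if (method == "fixed-family") {
      dat <- data.frame(.y = yw, .fam = factor(if (all(use)) fam_chr else
        fam_chr[use]), .g = gu)
      form <- .y ~ .fam + .g
      if (test_dom) {
        dat$.het <- as.numeric(gu == 1)
        form <- .y ~ .fam + .g + .het
      }
      fit <- stats::lm(form, data = dat)
      cf <- summary(fit)$coefficients
      if (".g" %in% rownames(cf)) {
        res$add_beta[j] <- cf[".g", 1]
        res$add_p[j] <- cf[".g", 4]
      } else {
        res$skipped[j] <- "additive_aliased"
      }
      if (test_dom && ".het" %in% rownames(cf)) {
        res$dom_beta[j] <- cf[".het", 1]
        res$dom_p[j] <- cf[".het", 4]
      }
    } else {
      out <- snp_test_one(yw, ones, gw, hetw)
      if (is.null(out)) { res$skipped[j] <- "insufficient_df"; next }
      res$add_beta[j] <- out$beta[2]
      res$add_p[j] <- out$p[2]
      if (test_dom && length(out$beta) >= 3) {
        res$dom_beta[j] <- out$beta[3]
        res$dom_p[j] <- out$p[3]
      }
    }
  }
  res
}

#' Genome scan of single-SNP tests for one trait
#'
#' Convenience wrapper: [adjust_phenotypes()] then [snp_tests()] over every
#' SNP of a dataset.
#'
#' @param ds A [geno_dataset()].
#' @param phenotypes Data frame with columns `id` and the trait.
#' @param trait Trait column name (e.g. `"AFP"`).
#' @param covariates Optional covariate column names in `phenotypes`.
#' @param method `"gls-ls"` (random family; primary) or `"fixed-family"`.
#' @param vc_method Variance-component estimator for the GLS step.
#' @param min_class_n Passed to [snp_tests()].
#' @return Data frame: marker map columns plus the [snp_tests()] columns and
#'   `trait`.
#' @export
assoc_scan <- function(ds, phenotypes, trait, covariates = NULL,
                       method = c("gls-ls", "fixed-family"),
                       vc_method = c("moment", "reml"), min_class_n = 3) {
  method <- match.arg(method)
  vc_method <- match.arg(vc_method)
  stopifnot(inherits(ds, "geno_dataset"), trait %in% names(phenotypes))
  idx <- match(ds$samples$id, phenotypes$id)
  if (anyNA(idx)) stop("phenotypes missing for individual(s): ",
                       paste(ds$samples$id[is.na(idx)][1:5], collapse = ", "))
  y <- as.numeric(phenotypes[[trait]][idx])
  covs <- if (!is.null(covariates))
    phenotypes[idx, covariates, drop = FALSE] else NULL
  keep <- !is.na(y)
  adj <- adjust_phenotypes(y[keep], ds$samples$family[keep], covs[keep, ,
                           drop = FALSE], method = vc_method)
  tests <- snp_tests(adj$adjusted, ds$geno[keep, , drop = FALSE],
                     ds$samples$family[keep], adj$sigma_f2, adj$sigma_e2,
                     method = method, min_class_n = min_class_n)
  cbind(ds$map[, c("id", "chrom", "pos_bp")], trait = trait, tests)
}
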