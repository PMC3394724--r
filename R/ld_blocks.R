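#' Binary allele coding of a phased panel
#'
#' Recodes a [phased_haps()] base matrix as 1 = allele 1 (`allele_a`),
#' 0 = allele 2, `NA` = missing, optionally restricted to one line.
#'
#' @param ph A `phased_haps` object.
#' @param line `"lean"`, `"fat"`, or `NULL` for all rows.
#' @return Integer matrix with the same shape as the (possibly row-subset)
#'   haplotype matrix.
#' @export
hap_binary <- function(ph, line = NULL) {
  stopifnot(inherits(ph, "phased_haps"))
  rows <- if (is.null(line)) seq_len(nrow(ph$hap)) else
    which(as.character(ph$info$line) == line)
  h <- ph$hap[rows, , drop = FALSE]
  out <- matrix(NA_integer_, nrow(h), ncol(h))
  for (j in seq_len(ncol(h))) {
    out[h[, j] == ph$map$allele_a[j], j] <- 1L
    if (!is.na(ph$map$allele_b[j])) {
      out[h[, j] == ph$map$allele_b[j], j] <- 0L
    }
  }
  out
}

#' Two-locus haplotype counts
#'
#' Counts of the four haplotypes A1B1, A1B2, A2B1, A2B2 between two markers,
#' where allele 1 of each marker follows the [allele1()] convention. Rows with
#' a missing call at either site are excluded.
#'
#' @param x,y Binary (0/1) haplotype vectors for the two markers.
#' @return Named integer vector `c(n11, n12, n21, n22)`.
#' @export
two_locus_counts <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  c(n11 = sum(x == 1 & y == 1), n12 = sum(x == 1 & y == 0),
    n21 = sum(x == 0 & y == 1), n22 = sum(x == 0 & y == 0))
}

#' Pairwise LD measures from two-locus counts
#'
#' Standard measures: `D = p11 - pA * pB`, `D' = |D| / Dmax` with `Dmax` the
#' bound imposed by the allele frequencies given the sign of D, and
#' `r2 = D^2 / (pA (1-pA) pB (1-pB))`. A locus monomorphic in the counted
#' sample makes LD undefined (`defined = FALSE`); such pairs are excluded
#' from means and block rules.
#'
#' @param counts Two-locus counts as from [two_locus_counts()].
#' @return List with elements `D`, `dprime`, `r2`, `n`, `defined`.
#' @export
ld_measures <- function(counts) {
  n <- sum(counts)
  n11 <- counts[[1]]; n12 <- counts[[2]]; n21 <- counts[[3]]; n22 <- counts[[4]]
  pA <- (n11 + n12) / n
  pB <- (n11 + n21) / n
  if (n == 0 || pA %in% c(0, 1) || pB %in% c(0, 1)) {
    return(list(D = NA_real_, dprime = NA_real_, r2 = NA_real_, n = n,
                defined = FALSE))
  }
  D <- n11 / n - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (dmax == 0) NA_real_ else abs(D) / dmax
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  list(D = D, dprime = dprime, r2 = r2, n = n, defined = TRUE)
}

#' Likelihood-based confidence interval on D'
#'
#' Evaluates the multinomial likelihood of the four observed haplotype counts
#' on a grid of D' values in `[0, 1]`, holding the allele frequencies fixed at
#' their observed margins and the sign of D at its observed direction. After
#' normalization, the lower bound is the smallest grid value with at least
#' `tail` cumulative mass at or below it, and the upper bound the largest grid
#' value with at least `tail` mass at or above it (one-sided 5% per tail by
#' default, the convention of the Gabriel block-definition procedure; exact
#' conventions vary between implementations, so both the grid and the tails
#' are configurable).
#'
#' @param counts Two-locus counts, total at least 2.
#' @param grid_n Number of grid points on `[0, 1]` (default 101).
#' @param tail One-sided tail mass (default 0.05).
#' @return Numeric `c(low, high)`, or `c(NA, NA)` for degenerate margins.
#' @export
dprime_ci <- function(counts, grid_n = 101, tail = 0.05) {
  n <- sum(counts)
  if (n < 2) stop("dprime_ci() requires a total count of at least 2")
  n11 <- counts[[1]]; n12 <- counts[[2]]; n21 <- counts[[3]]; n22 <- counts[[4]]
  pA <- (n11 + n12) / n
  pB <- (n11 + n21) / n
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    return(c(low = NA_real_, high = NA_real_))
  }
  # orient so that observed D >= 0 by relabelling locus B's alleles
  if (n11 / n - pA * pB < 0) {
    tmp <- n11; n11 <- n12; n12 <- tmp
    tmp <- n21; n21 <- n22; n22 <- tmp
    pB <- 1 - pB
  }
  dmax <- min(pA * (1 - pB), (1 - pA) * pB)
  grid <- seq(0, 1, length.out = grid_n)
  p11 <- pA * pB + grid * dmax
  p12 <- pA - p11
  p21 <- pB - p11
  p22 <- 1 - pA - pB + p11
  ll <- vapply(seq_along(grid), function(i) {
    ps <- c(p11[i], p12[i], p21[i], p22[i])
    ps[ps < 0 & ps > -1e-12] <- 0
    ns <- c(n11, n12, n21, n22)
    if (any(ps < 0)) return(-Inf)
    if (any(ns > 0 & ps == 0)) return(-Inf)
    sum(ns[ns > 0] * log(ps[ns > 0]))
  }, numeric(1))
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  cum <- cumsum(w)
  revcum <- rev(cumsum(rev(w)))
  low <- grid[which(cum >= tail)[1]]
  high <- grid[max(which(revcum >= tail))]
  c(low = low, high = high)
}

#' Classify a marker pair from its D' confidence interval
#'
#' Gabriel-rule pair classes: "strong LD" when the CI is confidently high
#' (`low >= strong_low` and `high >= strong_high`), "strong recombination"
#' when even the upper bound is low (`high < recomb_high`), otherwise
#' uninformative.
#'
#' @param low,high D' CI bounds.
#' @param strong_low,strong_high,recomb_high Class thresholds (defaults 0.70,
#'   0.98, 0.90).
#' @return One of `"strong"`, `"recomb"`, `"uninformative"`.
#' @export
classify_ld_pair <- function(low, high, strong_low = 0.70,
                             strong_high = 0.98, recomb_high = 0.90) {
  if (is.na(low) || is.na(high)) return("uninformative")
  if (low >= strong_low && high >= strong_high) return("strong")
  if (high < recomb_high) return("recomb")
  "uninformative"
}

#' Pairwise LD table for a phased panel
#'
#' All marker pairs within `max_distance_bp` of each other, with D, D', r2,
#' the D' confidence interval and the Gabriel pair class. Computed within one
#' line when `line` is given (line-specific LD panels are how divergent-line
#' data are presented).
#'
#' @inheritParams hap_binary
#' @param max_distance_bp Maximum pair distance (default 1 Mb).
#' @param grid_n,tail Passed to [dprime_ci()].
#' @param strong_low,strong_high,recomb_high Passed to [classify_ld_pair()].
#' @return Data frame with one row per pair: `i`, `j` (marker indices),
#'   `distance_bp`, `D`, `dprime`, `r2`, `ci_low`, `ci_high`, `class`.
#' @export
ld_pairs <- function(ph, line = NULL, max_distance_bp = 1e6, grid_n = 101,
                     tail = 0.05, strong_low = 0.70, strong_high = 0.98,
                     recomb_high = 0.90) {
  h <- hap_binary(ph, line)
  pos <- ph$map$pos_bp
  m <- ncol(h)
  rows <- list()
  for (i in seq_len(max(m - 1L, 0L))) {
    for (j in (i + 1L):m) {
      if (pos[j] - pos[i] > max_distance_bp) break
      cnt <- two_locus_counts(h[, i], h[, j])
      meas <- ld_measures(cnt)
      ci <- if (meas$defined && sum(cnt) >= 2) {
        dprime_ci(cnt, grid_n, tail)
      } else c(NA_real_, NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        i = i, j = j, distance_bp = pos[j] - pos[i],
        D = meas$D, dprime = meas$dprime, r2 = meas$r2,
        ci_low = ci[1], ci_high = ci[2],
        class = classify_ld_pair(ci[1], ci[2], strong_low, strong_high,
                                 recomb_high))
    }
  }
  if (!length(rows)) {
    return(data.frame(i = integer(0), j = integer(0),
                      distance_bp = numeric(0), D = numeric(0),
                      dprime = numeric(0), r2 = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      class = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gabriel-rule haplotype blocks
#'
#' From classified marker pairs (see [ld_pairs()]), a candidate span of
#' contiguous markers is a block when the fraction of its informative pairs
#' classified strong LD is at least `min_strong_frac` (with at least one
#' strong pair). Maximal non-overlapping blocks are returned greedily in
#' descending span size. The `"haploview"` preset adds the size-stratified
#' extra requirement on short spans that the outermost pair's D' CI lower
#' bound clears a span-length-specific cutoff (0.81 / 0.78 / 0.74 for 2 / 3 /
#' 4 markers), an approximation of the Haploview defaults that produce
#' different blocks from the plain rule; the plain rule is the default.
#'
#' @param pairs Data frame with columns `i`, `j`, `ci_low`, `class` (as from
#'   [ld_pairs()]). Pairs absent from the table (e.g. beyond the distance
#'   cutoff) count as uninformative.
#' @param n_markers Number of markers in the panel.
#' @param min_strong_frac Minimum strong/informative fraction (default 0.95).
#' @param preset `"plain"` or `"haploview"`.
#' @return Data frame of blocks: `start_idx`, `end_idx`, `n_snps`,
#'   `n_strong`, `n_informative`, sorted by `start_idx`.
#' @export
gabriel_blocks <- function(pairs, n_markers, min_strong_frac = 0.95,
                           preset = c("plain", "haploview")) {
  preset <- match.arg(preset)
  class_mat <- matrix("absent", n_markers, n_markers)
  low_mat <- matrix(NA_real_, n_markers, n_markers)
  if (nrow(pairs)) {
    class_mat[cbind(pairs$i, pairs$j)] <- pairs$class
    low_mat[cbind(pairs$i, pairs$j)] <- pairs$ci_low
  }
  cand <- list()
  for (i in seq_len(max(n_markers - 1L, 0L))) {
    n_strong <- 0L; n_inform <- 0L
    for (j in (i + 1L):n_markers) {
      cl <- class_mat[i:(j - 1L), j]
      n_strong <- n_strong + sum(cl == "strong")
      n_inform <- n_inform + sum(cl %in% c("strong", "recomb"))
      if (n_inform == 0L || n_strong == 0L) next
      if (n_strong / n_inform < min_strong_frac) next
      if (preset == "haploview") {
        size <- j - i + 1L
        cut <- c(`2` = 0.81, `3` = 0.78, `4` = 0.74)[as.character(size)]
        if (!is.na(cut)) {
          outer_low <- low_mat[i, j]
          if (is.na(outer_low) || outer_low < cut) next
        }
      }
      cand[[length(cand) + 1L]] <- c(i = i, j = j)
    }
  }
  if (!length(cand)) {
    return(data.frame(start_idx = integer(0), end_idx = integer(0),
                      n_snps = integer(0), n_strong = integer(0),
                      n_informative = integer(0)))
  }
  cm <- do.call(rbind, cand)
  sizes <- cm[, "j"] - cm[, "i"] + 1L
  ord <- order(-sizes, cm[, "i"])
  taken <- rep(FALSE, n_markers)
  keep <- list()
  for (k in ord) {
    span <- cm[k, "i"]:cm[k, "j"]
    if (any(taken[span])) next
    taken[span] <- TRUE
    cl <- class_mat[span, span]
    cl <- cl[upper.tri(cl)]
    keep[[length(keep) + 1L]] <- data.frame(
      start_idx = cm[k, "i"], end_idx = cm[k, "j"],
      n_snps = length(span),
      n_strong = sum(cl == "strong"),
      n_informative = sum(cl %in% c("strong", "recomb")))
  }
  out <- do.call(rbind, keep)
  out <- out[order(out$start_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean r-squared over adjacent marker pairs
#'
#' Unweighted mean of r2 over adjacent pairs with defined LD; the chromosome
#' LD summary reported per line.
#'
#' @inheritParams hap_binary
#' @return A single numeric value, or `NA` when no pair has defined LD.
#' @export
mean_adjacent_r2 <- function(ph, line = NULL) {
  h <- hap_binary(ph, line)
  m <- ncol(h)
  if (m < 2) return(NA_real_)
  r2 <- vapply(seq_len(m - 1L), function(i) {
    ld_measures(two_locus_counts(h[, i], h[, i + 1L]))$r2
  }, numeric(1))
  if (all(is.na(r2))) NA_real_ else mean(r2, na.rm = TRUE)
}
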