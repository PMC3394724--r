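#' Per-line allele-1 frequency
#'
#' Frequency of allele 1 at each SNP among the called genotypes of one line:
#' `p = (copies of allele 1) / (2 * called individuals)`. SNPs with zero calls
#' in the line get `NA` and are excluded from window summaries. With
#' `z_hemizygous = TRUE`, females contribute a single allele copy at markers
#' on chromosome `z_chrom` (ZZ males / ZW females); heterozygous female calls
#' at such markers are impossible and are treated as missing.
#'
#' @param ds A [geno_dataset()].
#' @param line `"lean"` or `"fat"`.
#' @param z_hemizygous Count females as hemizygous on the Z chromosome
#'   (default `FALSE`: all individuals diploid, as when all measured birds are
#'   male).
#' @param z_chrom Chromosome label treated as Z (default `"Z"`).
#' @return Numeric vector of frequencies, one per SNP.
#' @export
line_allele_freq <- function(ds, line, z_hemizygous = FALSE, z_chrom = "Z") {
  stopifnot(inherits(ds, "geno_dataset"), line %in% LINE_LEVELS)
  g <- ds$geno[ds$samples$line == line, , drop = FALSE]
  copies <- matrix(2, nrow(g), ncol(g))
  if (z_hemizygous) {
    zcol <- which(ds$map$chrom == z_chrom)
    fem <- which(as.character(ds$samples$sex[ds$samples$line == line]) ==
                   "female")
    if (length(zcol) && length(fem)) {
      gz <- g[fem, zcol, drop = FALSE]
      gz[gz == 1L] <- NA_integer_          # het call impossible on hemizygous Z
      gz[gz == 2L] <- 1L
      g[fem, zcol] <- gz
      copies[fem, zcol] <- 1
    }
  }
  copies[is.na(g)] <- 0
  denom <- colSums(copies)
  p <- colSums(g * (copies > 0), na.rm = TRUE) / denom
  p[denom == 0] <- NA_real_
  unname(p)
}

#' Per-SNP line frequencies, AFD and expected heterozygosity
#'
#' For each SNP: the allele-1 frequency in each line, the allele frequency
#' difference `AFD = |p_lean - p_fat|`, and the expected heterozygosity
#' `2 p (1 - p)` of each line.
#'
#' @inheritParams line_allele_freq
#' @return Data frame with columns `id`, `chrom`, `pos_bp`, `p_lean`, `p_fat`,
#'   `afd`, `het_lean`, `het_fat`, `n_called_lean`, `n_called_fat`.
#' @export
snp_stats <- function(ds, z_hemizygous = FALSE, z_chrom = "Z") {
  stopifnot(inherits(ds, "geno_dataset"))
  p_lean <- line_allele_freq(ds, "lean", z_hemizygous, z_chrom)
  p_fat <- line_allele_freq(ds, "fat", z_hemizygous, z_chrom)
  lean_rows <- ds$samples$line == "lean"
  data.frame(
    id = ds$map$id, chrom = ds$map$chrom, pos_bp = ds$map$pos_bp,
    p_lean = p_lean, p_fat = p_fat,
    afd = abs(p_lean - p_fat),
    het_lean = 2 * p_lean * (1 - p_lean),
    het_fat = 2 * p_fat * (1 - p_fat),
    n_called_lean = colSums(!is.na(ds$geno[lean_rows, , drop = FALSE])),
    n_called_fat = colSums(!is.na(ds$geno[!lean_rows, , drop = FALSE])),
    row.names = NULL)
}

#' Sliding windows over a SNP map
#'
#' Tiles each chromosome with half-open windows `[start, start + size_bp)`
#' advanced by `step_bp`, starting from the first marker position rounded down
#' to a multiple of `step_bp`. Windows holding fewer than `min_snps` markers
#' are dropped (counted in the `dropped_windows` attribute).
#'
#' @param map SNP map data frame (`id`, `chrom`, `pos_bp`), sorted within
#'   chromosome.
#' @param size_bp Window size in bp (default 500 kb).
#' @param step_bp Step between window starts (default 250 kb: half-overlap).
#' @param min_snps Minimum markers per window (default 3).
#' @return Data frame with columns `chrom`, `start_bp`, `end_bp`, `n_snps` and
#'   a list-column `snp_idx` of member row indices into `map`.
#' @export
sliding_windows <- function(map, size_bp = 500000, step_bp = 250000,
                            min_snps = 3) {
  stopifnot(size_bp > 0, step_bp > 0, min_snps >= 1)
  out <- list(); dropped <- 0L
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pos <- map$pos_bp[idx]
    if (!length(pos)) next
    start0 <- floor(min(pos) / step_bp) * step_bp
    starts <- seq(start0, max(pos), by = step_bp)
    for (s in starts) {
      members <- idx[pos >= s & pos < s + size_bp]
      if (length(members) < min_snps) {
        dropped <- dropped + 1L
        next
      }
      out[[length(out) + 1L]] <- list(chrom = ch, start_bp = s,
                                      end_bp = s + size_bp,
                                      snp_idx = members)
    }
  }
  win <- data.frame(
    chrom = vapply(out, `[[`, character(1), "chrom"),
    start_bp = vapply(out, `[[`, numeric(1), "start_bp"),
    end_bp = vapply(out, `[[`, numeric(1), "end_bp"),
    n_snps = vapply(out, function(w) length(w$snp_idx), integer(1)))
  win$snp_idx <- I(lapply(out, `[[`, "snp_idx"))
  attr(win, "dropped_windows") <- dropped
  win
}

#' Unstandardized window summaries
#'
#' Unweighted means of per-SNP AFD and per-line expected heterozygosity over
#' each window's member SNPs (SNPs with no calls in a line are excluded).
#'
#' @param windows Output of [sliding_windows()].
#' @param stats Output of [snp_stats()] on the same map.
#' @return `windows` with columns `afd_mean`, `het_lean_mean`,
#'   `het_fat_mean` added.
#' @export
window_summary <- function(windows, stats) {
  windows$afd_mean <- vapply(windows$snp_idx, function(i)
    mean(stats$afd[i], na.rm = TRUE), numeric(1))
  windows$het_lean_mean <- vapply(windows$snp_idx, function(i)
    mean(stats$het_lean[i], na.rm = TRUE), numeric(1))
  windows$het_fat_mean <- vapply(windows$snp_idx, function(i)
    mean(stats$het_fat[i], na.rm = TRUE), numeric(1))
  windows$afd_mean[is.nan(windows$afd_mean)] <- NA_real_
  windows$het_lean_mean[is.nan(windows$het_lean_mean)] <- NA_real_
  windows$het_fat_mean[is.nan(windows$het_fat_mean)] <- NA_real_
  windows
}

# z-scores of x within groups g; NA (non-assessable) when a group has < 2
# values or zero spread.
standardize_by_group <- function(x, g) {
  z <- rep(NA_real_, length(x))
  for (gr in unique(g)) {
    i <- which(g == gr & !is.na(x))
    if (length(i) < 2L) next
    s <- stats::sd(x[i])
    if (!is.finite(s) || s == 0) next
    z[i] <- (x[i] - mean(x[i])) / s
  }
  z
}

#' Standardize window statistics per chromosome
#'
#' `Z_AFD` standardizes the window AFD means by the chromosome-wise mean and
#' sample standard deviation of AFD; `Z_lean` and `Z_fat` standardize each
#' line's window heterozygosity means using only that line's values over the
#' chromosome (within-line standardization is more conservative than pooling
#' the two lines). Chromosomes with fewer than two windows or zero spread are
#' non-assessable: their z-values stay `NA`, never silently zero.
#'
#' @param ws Output of [window_summary()].
#' @return `ws` with columns `z_afd`, `z_lean`, `z_fat` added.
#' @export
standardize_windows <- function(ws) {
  ws$z_afd <- standardize_by_group(ws$afd_mean, ws$chrom)
  ws$z_lean <- standardize_by_group(ws$het_lean_mean, ws$chrom)
  ws$z_fat <- standardize_by_group(ws$het_fat_mean, ws$chrom)
  ws
}

#' Sliding-window selection-signature scan
#'
#' Convenience wrapper: [snp_stats()] then [sliding_windows()],
#' [window_summary()] and [standardize_windows()].
#'
#' @inheritParams line_allele_freq
#' @inheritParams sliding_windows
#' @return The standardized window table, with the per-SNP statistics attached
#'   as attribute `snp_stats`.
#' @export
scan_windows <- function(ds, size_bp = 500000, step_bp = 250000, min_snps = 3,
                         z_hemizygous = FALSE, z_chrom = "Z") {
  stats <- snp_stats(ds, z_hemizygous, z_chrom)
  ws <- sliding_windows(ds$map, size_bp, step_bp, min_snps)
  ws <- standardize_windows(window_summary(ws, stats))
  attr(ws, "snp_stats") <- stats
  ws
}

window_signals <- function(ws, afd_threshold, zafd_threshold, zhet_threshold) {
  sig <- list()
  for (i in seq_len(nrow(ws))) {
    s <- character(0)
    if (!is.na(ws$afd_mean[i]) && ws$afd_mean[i] >= afd_threshold)
      s <- c(s, "AFD")
    if (!is.na(ws$z_afd[i]) && ws$z_afd[i] >= zafd_threshold)
      s <- c(s, "Z_AFD")
    if (!is.na(ws$z_lean[i])) {
      if (ws$z_lean[i] <= -zhet_threshold) s <- c(s, "Z_lean_down")
      if (ws$z_lean[i] >= zhet_threshold) s <- c(s, "Z_lean_up")
    }
    if (!is.na(ws$z_fat[i])) {
      if (ws$z_fat[i] <= -zhet_threshold) s <- c(s, "Z_fat_down")
      if (ws$z_fat[i] >= zhet_threshold) s <- c(s, "Z_fat_up")
    }
    sig[[i]] <- s
  }
  sig
}

#' Call selection signatures from standardized windows
#'
#' A window is flagged when any signal fires: `afd_mean >= afd_threshold`, or
#' `z_afd >= zafd_threshold` (one-sided: AFD is non-negative, so low extremes
#' are uninformative), or `|z_lean| >= zhet_threshold`, or
#' `|z_fat| >= zhet_threshold`. Heterozygosity increases are kept as signals
#' because a line starting from extreme allele frequencies can gain
#' heterozygosity under selection (and a p-q sweep shows no change at all).
#' Overlapping or touching flagged windows on a chromosome merge into one
#' signature region.
#'
#' The inferred selected line is the line whose heterozygosity dropped when
#' exactly one line shows a `*_down` signal; `"both"` when both do; `NA` when
#' the region was flagged by AFD measures alone.
#'
#' @param ws Output of [scan_windows()] / [standardize_windows()].
#' @param afd_threshold Window-mean AFD threshold (default 0.44).
#' @param zafd_threshold Standardized AFD threshold (default 4.0).
#' @param zhet_threshold Standardized heterozygosity threshold, applied to
#'   both signs (default 5.0).
#' @return Data frame of signature regions: `chrom`, `start_bp`, `end_bp`,
#'   `n_windows`, peak statistics, `signals` (comma-joined), `selected_line`,
#'   `het_increase`. Regions are disjoint and sorted.
#' @export
call_signatures <- function(ws, afd_threshold = 0.44, zafd_threshold = 4.0,
                            zhet_threshold = 5.0) {
  sig <- window_signals(ws, afd_threshold, zafd_threshold, zhet_threshold)
  flagged <- which(lengths(sig) > 0)
  regions <- list()
  for (ch in unique(ws$chrom)) {
    f <- flagged[ws$chrom[flagged] == ch]
    if (!length(f)) next
    f <- f[order(ws$start_bp[f])]
    cur <- f[1]; members <- f[1]
    flush <- function(members) {
      i <- members
      peak_abs <- function(v) {
        v <- v[!is.na(v)]
        if (!length(v)) return(NA_real_)
        v[which.max(abs(v))]
      }
      sigs <- sort(unique(unlist(sig[i])))
      downs <- c(lean = "Z_lean_down" %in% sigs, fat = "Z_fat_down" %in% sigs)
      selected <- if (sum(downs) == 1) names(downs)[downs] else
        if (sum(downs) == 2) "both" else NA_character_
      data.frame(
        chrom = ch,
        start_bp = min(ws$start_bp[i]), end_bp = max(ws$end_bp[i]),
        n_windows = length(i),
        peak_afd = max(ws$afd_mean[i], na.rm = TRUE),
        peak_z_afd = if (all(is.na(ws$z_afd[i]))) NA_real_ else
          max(ws$z_afd[i], na.rm = TRUE),
        z_lean_extreme = peak_abs(ws$z_lean[i]),
        z_fat_extreme = peak_abs(ws$z_fat[i]),
        signals = paste(sigs, collapse = ","),
        selected_line = selected,
        het_increase = any(grepl("_up$", sigs)))
    }
    if (length(f) > 1) {
      for (k in 2:length(f)) {
        if (ws$start_bp[f[k]] <= max(ws$end_bp[members])) {
          members <- c(members, f[k])
        } else {
          regions[[length(regions) + 1L]] <- flush(members)
          members <- f[k]
        }
      }
    }
    regions[[length(regions) + 1L]] <- flush(members)
  }
  if (!length(regions)) {
    return(data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_windows = integer(0),
                      peak_afd = numeric(0), peak_z_afd = numeric(0),
                      z_lean_extreme = numeric(0), z_fat_extreme = numeric(0),
                      signals = character(0), selected_line = character(0),
                      het_increase = logical(0)))
  }
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}

#' Per-chromosome marker and divergence summary
#'
#' For each chromosome: SNP count, mean adjacent spacing, marker density,
#' mean per-SNP AFD, and the count (and percentage) of SNPs fixed
#' (`p` exactly 0 or 1) in each line.
#'
#' @param ds A [geno_dataset()].
#' @param stats Optional precomputed [snp_stats()].
#' @return Data frame, one row per chromosome.
#' @export
chromosome_summary <- function(ds, stats = NULL) {
  if (is.null(stats)) stats <- snp_stats(ds)
  rows <- lapply(unique(ds$map$chrom), function(ch) {
    i <- which(ds$map$chrom == ch)
    pos <- ds$map$pos_bp[i]
    span_mb <- (max(pos) - min(pos)) / 1e6
    n <- length(i)
    fx_lean <- sum(stats$p_lean[i] %in% c(0, 1))
    fx_fat <- sum(stats$p_fat[i] %in% c(0, 1))
    data.frame(
      chrom = ch, n_snps = n,
      mean_spacing_bp = if (n > 1) mean(diff(pos)) else NA_real_,
      snps_per_mb = if (span_mb > 0) n / span_mb else NA_real_,
      mean_afd = mean(stats$afd[i], na.rm = TRUE),
      fixed_lean = fx_lean, fixed_lean_pct = 100 * fx_lean / n,
      fixed_fat = fx_fat, fixed_fat_pct = 100 * fx_fat / n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
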