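#' Extended haplotype homozygosity at one evaluation point
#'
#' EHH is the probability that two randomly drawn carriers of a core
#' haplotype are identical over the whole interval from the core out to the
#' evaluation marker: `EHH = sum_h e_h (e_h - 1) / (n (n - 1))` over the
#' distinct extended haplotypes `h` among the `n` carriers.
#'
#' @param ext Character vector of extended-haplotype strings (one per
#'   carrier), or a character matrix with one row per carrier.
#' @return EHH in `[0, 1]`; `NA` with fewer than 2 carriers.
#' @examples
#' ehh_at(c("AA", "AA", "AG", "AG"))  # split 2+2 -> 1/3
#' @export
ehh_at <- function(ext) {
  if (is.matrix(ext)) ext <- apply(ext, 1, paste, collapse = "")
  n <- length(ext)
  if (n < 2) return(NA_real_)
  e <- as.numeric(table(ext))
  sum(e * (e - 1)) / (n * (n - 1))
}

#' Build core regions
#'
#' Cores for EHH analysis are taken from Gabriel blocks by default, or from
#' explicit marker-index ranges.
#'
#' @param blocks Data frame with `start_idx`/`end_idx` columns (e.g. from
#'   [gabriel_blocks()]), or `NULL`.
#' @param ranges List of integer vectors `c(start_idx, end_idx)`, or `NULL`.
#' @return List of cores, each `c(start_idx, end_idx)`. Overlapping explicit
#'   ranges are an error.
#' @export
select_cores <- function(blocks = NULL, ranges = NULL) {
  if (!is.null(blocks) && !is.null(ranges)) {
    stop("give either blocks or explicit ranges, not both")
  }
  if (!is.null(blocks)) {
    return(lapply(seq_len(nrow(blocks)), function(i)
      c(blocks$start_idx[i], blocks$end_idx[i])))
  }
  if (is.null(ranges) || !length(ranges)) return(list())
  cores <- lapply(ranges, function(r) c(r[1], r[2]))
  ord <- order(vapply(cores, `[`, numeric(1), 1))
  cores <- cores[ord]
  if (length(cores) > 1) {
    for (k in 2:length(cores)) {
      if (cores[[k]][1] <= cores[[k - 1]][2]) {
        stop("core regions overlap")
      }
    }
  }
  cores
}

#' EHH decay curves from a core region
#'
#' For each core haplotype carried by at least `min_carriers` haplotype rows
#' of a line, evaluates EHH at every marker outward from the core in both
#' directions until EHH drops below `stop_threshold` or the chromosome ends.
#' Rows with a missing base inside the extension are dropped from that
#' evaluation point onward (per-point complete-case). Distances are measured
#' from the nearest core boundary marker's bp position. EHH at the core
#' boundary is 1 by construction and curves are non-increasing with distance.
#'
#' @param ph A [phased_haps()] panel.
#' @param core Integer `c(start_idx, end_idx)` of the core markers.
#' @param line `"lean"`, `"fat"`, or `NULL` for all rows.
#' @param min_carriers Minimum carriers for a core haplotype to be evaluated
#'   (default 5; curves from rarer cores are statistically meaningless).
#' @param stop_threshold Stop extending once EHH falls below this (default
#'   0.05).
#' @return Data frame with columns `core_hap`, `core_count`, `line`,
#'   `direction` (`"upstream"`/`"downstream"`), `marker_idx`, `pos_bp`,
#'   `distance_bp`, `ehh`; core haplotypes ordered by descending carrier
#'   count. Empty (with a warning) when no haplotype reaches `min_carriers`.
#' @export
ehh_decay <- function(ph, core, line = NULL, min_carriers = 5,
                      stop_threshold = 0.05) {
  stopifnot(inherits(ph, "phased_haps"))
  if (is.data.frame(core)) core <- c(core$start_idx[1], core$end_idx[1])
  m <- ncol(ph$hap)
  stopifnot(core[1] >= 1, core[2] <= m, core[1] <= core[2])
  rows <- if (is.null(line)) seq_len(nrow(ph$hap)) else
    which(as.character(ph$info$line) == line)
  h <- ph$hap[rows, , drop = FALSE]
  core_idx <- core[1]:core[2]
  core_ok <- !apply(is.na(h[, core_idx, drop = FALSE]), 1, any)
  h <- h[core_ok, , drop = FALSE]
  core_str <- apply(h[, core_idx, drop = FALSE], 1, paste, collapse = "")
  tab <- sort(table(core_str), decreasing = TRUE)
  tab <- tab[tab >= min_carriers]
  if (!length(tab)) {
    warning("no core haplotype has >= ", min_carriers, " carriers")
    return(data.frame(core_hap = character(0), core_count = integer(0),
                      line = character(0), direction = character(0),
                      marker_idx = integer(0), pos_bp = numeric(0),
                      distance_bp = numeric(0), ehh = numeric(0)))
  }
  pos <- ph$map$pos_bp
  ln_label <- if (is.null(line)) "all" else line
  curves <- list()
  for (hs in names(tab)) {
    carriers <- which(core_str == hs)
    for (dir in c("upstream", "downstream")) {
      boundary <- if (dir == "upstream") core[1] else core[2]
      step <- if (dir == "upstream") -1L else 1L
      marker_seq <- if (dir == "upstream") {
        if (core[1] > 1) seq(core[1] - 1L, 1L) else integer(0)
      } else {
        if (core[2] < m) seq(core[2] + 1L, m) else integer(0)
      }
      # boundary point: EHH = 1 at distance 0
      curves[[length(curves) + 1L]] <- data.frame(
        core_hap = hs, core_count = as.integer(tab[[hs]]), line = ln_label,
        direction = dir, marker_idx = boundary, pos_bp = pos[boundary],
        distance_bp = 0, ehh = 1)
      ext <- h[carriers, boundary, drop = TRUE]  # same base for all carriers
      grp <- rep(1L, length(carriers))
      alive <- !is.na(ext)
      for (mk in marker_seq) {
        base <- h[carriers, mk]
        alive <- alive & !is.na(base)
        if (sum(alive) < 2) break
        grp_key <- paste(grp, base, sep = "_")
        grp <- match(grp_key, unique(grp_key[alive]))
        e <- ehh_at(grp_key[alive])
        curves[[length(curves) + 1L]] <- data.frame(
          core_hap = hs, core_count = as.integer(tab[[hs]]), line = ln_label,
          direction = dir, marker_idx = mk, pos_bp = pos[mk],
          distance_bp = abs(pos[mk] - pos[boundary]), ehh = e)
        if (e < stop_threshold) break
      }
    }
  }
  out <- do.call(rbind, curves)
  rownames(out) <- NULL
  out
}

#' Area under an EHH decay curve
#'
#' Trapezoidal integral of EHH over bp distance, summed over the two
#' directions; a scalar summary of haplotype extent used to compare selection
#' pressure between lines (the more strongly selected line decays more
#' slowly).
#'
#' @param curves Data frame from [ehh_decay()]; typically filtered to one
#'   core haplotype (by default the most frequent one is used).
#' @param core_hap Core haplotype to integrate; default the one with the
#'   largest carrier count.
#' @return Numeric area in bp (EHH is unitless).
#' @export
ehh_area <- function(curves, core_hap = NULL) {
  if (!nrow(curves)) return(NA_real_)
  if (is.null(core_hap)) {
    core_hap <- curves$core_hap[which.max(curves$core_count)]
  }
  cc <- curves[curves$core_hap == core_hap, , drop = FALSE]
  total <- 0
  for (dir in unique(cc$direction)) {
    d <- cc[cc$direction == dir, , drop = FALSE]
    d <- d[order(d$distance_bp), , drop = FALSE]
    if (nrow(d) < 2) next
    total <- total + sum(diff(d$distance_bp) *
                           (utils::head(d$ehh, -1) + utils::tail(d$ehh, -1)) / 2)
  }
  total
}

#' Relative EHH of each core haplotype
#'
#' EHH of one core haplotype divided by the carrier-weighted mean EHH of all
#' other core haplotypes at the same marker. Reported for completeness; the
#' signature-calling logic reasons from raw EHH curves.
#'
#' @param curves Data frame from [ehh_decay()] (all core haplotypes of one
#'   line/direction set).
#' @return `curves` with a `rel_ehh` column added (`NA` where no other core
#'   haplotype reaches the marker).
#' @export
relative_ehh <- function(curves) {
  curves$rel_ehh <- NA_real_
  for (i in seq_len(nrow(curves))) {
    others <- curves$core_hap != curves$core_hap[i] &
      curves$direction == curves$direction[i] &
      curves$marker_idx == curves$marker_idx[i]
    if (!any(others)) next
    w <- curves$core_count[others]
    denom <- sum(w * curves$ehh[others]) / sum(w)
    if (denom > 0) curves$rel_ehh[i] <- curves$ehh[i] / denom
  }
  curves
}

#' Line-level EHH area (integrated haplotype homozygosity)
#'
#' The probability that two haplotypes drawn at random from a line are
#' identical from the core out to distance x, integrated over x: the
#' count-weighted sum over core haplotypes of each haplotype's EHH area,
#' with weights `e_h (e_h - 1) / (n (n - 1))`. At distance 0 the weighted sum
#' equals the core's haplotype homozygosity. A line swept at the core keeps
#' one high-frequency haplotype extended over long distances and scores
#' high; per-haplotype EHH alone cannot see the frequency difference, which
#' is why the line comparison uses this weighted form.
#'
#' @inheritParams ehh_decay
#' @param min_carriers Minimum carriers per included core haplotype
#'   (default 2: singletons contribute zero weight anyway).
#' @return Numeric area in bp, or `NA` when the line has no evaluable core
#'   haplotype.
#' @export
line_ehh_area <- function(ph, core, line = NULL, min_carriers = 2,
                          stop_threshold = 0.05) {
  crv <- suppressWarnings(ehh_decay(ph, core, line,
                                    min_carriers = min_carriers,
                                    stop_threshold = stop_threshold))
  if (!nrow(crv)) return(NA_real_)
  counts <- tapply(crv$core_count, crv$core_hap, max)
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  total <- 0
  for (h in names(counts)) {
    e <- counts[[h]]
    total <- total + e * (e - 1) / (n * (n - 1)) * ehh_area(crv, h)
  }
  total
}
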