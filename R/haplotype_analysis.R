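#' Hamming distance between two haplotype strings
#'
#' Number of positions at which two equal-length allele strings differ. Two
#' main haplotypes of divergently selected lines can differ at every marker
#' of a swept region (completely opposite alleles).
#'
#' @param h1,h2 Haplotype strings (e.g. `"AAGG..."`) of equal length.
#' @return Integer count of differing positions.
#' @export
hamming <- function(h1, h2) {
  if (nchar(h1) != nchar(h2)) {
    stop("hamming(): strings differ in length (", nchar(h1), " vs ",
         nchar(h2), ")")
  }
  sum(strsplit(h1, "")[[1]] != strsplit(h2, "")[[1]])
}

#' Per-line haplotype frequencies within a block
#'
#' Counts the distinct haplotype strings spanned by a block's markers in each
#' line. Rows with any missing base inside the block are dropped and counted
#' (reported in the `dropped` attribute), not imputed. Entries are ordered by
#' descending frequency, ties broken lexicographically.
#'
#' @param ph A [phased_haps()] panel.
#' @param block Integer vector `c(start_idx, end_idx)` of marker indices, or
#'   a one-row block data frame with `start_idx`/`end_idx` columns.
#' @return Data frame with columns `line`, `haplotype`, `count`, `freq`
#'   (frequencies sum to 1 within each line); attribute `dropped` gives
#'   per-line dropped-row counts, attribute `block` the marker range. A line
#'   with zero usable rows is absent from the table (with a warning).
#' @export
block_haplotype_freqs <- function(ph, block) {
  stopifnot(inherits(ph, "phased_haps"))
  if (is.data.frame(block)) block <- c(block$start_idx[1], block$end_idx[1])
  idx <- block[1]:block[2]
  stopifnot(all(idx >= 1), all(idx <= ncol(ph$hap)))
  out <- list()
  dropped <- c(lean = 0L, fat = 0L)
  for (ln in LINE_LEVELS) {
    rows <- which(as.character(ph$info$line) == ln)
    if (!length(rows)) next
    h <- ph$hap[rows, idx, drop = FALSE]
    ok <- !apply(is.na(h), 1, any)
    dropped[ln] <- sum(!ok)
    if (!any(ok)) {
      warning("no usable haplotype rows in line '", ln, "' for this block")
      next
    }
    strs <- apply(h[ok, , drop = FALSE], 1, paste, collapse = "")
    tab <- table(strs)
    df <- data.frame(line = ln, haplotype = names(tab),
                     count = as.integer(tab),
                     freq = as.numeric(tab) / sum(tab))
    df <- df[order(-df$freq, df$haplotype), , drop = FALSE]
    out[[ln]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  attr(res, "block") <- c(start_idx = block[1], end_idx = block[2])
  res
}

#' Two-block joint haplotype table
#'
#' Joint per-line frequencies of (block-1 haplotype, block-2 haplotype)
#' pairs, the object needed to examine recombination between the main
#' haplotypes of two adjacent blocks.
#'
#' @inheritParams block_haplotype_freqs
#' @param block1,block2 Marker index ranges of the two adjacent blocks.
#' @return Data frame with columns `block1`, `block2`, `count_lean`,
#'   `count_fat`, `freq_lean`, `freq_fat`, ordered by total frequency.
#' @export
joint_block_haplotypes <- function(ph, block1, block2) {
  stopifnot(inherits(ph, "phased_haps"))
  if (is.data.frame(block1)) block1 <- c(block1$start_idx[1], block1$end_idx[1])
  if (is.data.frame(block2)) block2 <- c(block2$start_idx[1], block2$end_idx[1])
  i1 <- block1[1]:block1[2]; i2 <- block2[1]:block2[2]
  h <- ph$hap[, c(i1, i2), drop = FALSE]
  ok <- !apply(is.na(h), 1, any)
  s1 <- apply(ph$hap[, i1, drop = FALSE], 1, paste, collapse = "")
  s2 <- apply(ph$hap[, i2, drop = FALSE], 1, paste, collapse = "")
  key <- paste(s1, s2, sep = "|")
  lines <- as.character(ph$info$line)
  keys <- sort(unique(key[ok]))
  cnt <- function(ln) {
    tab <- table(key[ok & lines == ln])
    v <- as.integer(tab[keys])
    v[is.na(v)] <- 0L
    v
  }
  c_lean <- cnt("lean"); c_fat <- cnt("fat")
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(
    block1 = vapply(parts, `[[`, character(1), 1),
    block2 = vapply(parts, `[[`, character(1), 2),
    count_lean = c_lean, count_fat = c_fat,
    freq_lean = if (sum(c_lean)) c_lean / sum(c_lean) else 0,
    freq_fat = if (sum(c_fat)) c_fat / sum(c_fat) else 0)
  out <- out[order(-(out$freq_lean + out$freq_fat), out$block1, out$block2), ]
  rownames(out) <- NULL
  out
}

#' Detect recombinant haplotypes between two parental haplotypes
#'
#' Given a joint two-block haplotype table and two parental haplotypes, any
#' observed haplotype equal to one parent's block-1 segment joined with the
#' other parent's block-2 segment is a recombinant (the crossover lies
#' between the blocks).
#'
#' @param joint Data frame with columns `block1`, `block2` and per-line
#'   frequency columns `freq_lean`, `freq_fat` (as from
#'   [joint_block_haplotypes()], or assembled directly from a published
#'   table).
#' @param parent1,parent2 Character vectors `c(block1_segment,
#'   block2_segment)` of the two parental haplotypes.
#' @return Data frame of recombinant rows with columns `block1`, `block2`,
#'   `parent_block1`, `parent_block2` (`"parent1"`/`"parent2"`: the donor of
#'   each segment), `freq_lean`, `freq_fat`. Empty (with a warning) when the
#'   parents are absent from the panel.
#' @export
find_recombinants <- function(joint, parent1, parent2) {
  stopifnot(length(parent1) == 2L, length(parent2) == 2L)
  key <- paste(joint$block1, joint$block2, sep = "|")
  p1 <- paste(parent1, collapse = "|")
  p2 <- paste(parent2, collapse = "|")
  if (!(p1 %in% key) || !(p2 %in% key)) {
    warning("parental haplotype(s) absent from the panel; no recombinants ",
            "reported")
    return(data.frame(block1 = character(0), block2 = character(0),
                      parent_block1 = character(0),
                      parent_block2 = character(0),
                      freq_lean = numeric(0), freq_fat = numeric(0)))
  }
  rec_defs <- list(
    list(b1 = parent1[1], b2 = parent2[2],
         donors = c("parent1", "parent2")),
    list(b1 = parent2[1], b2 = parent1[2],
         donors = c("parent2", "parent1")))
  rows <- list()
  for (rd in rec_defs) {
    k <- paste(rd$b1, rd$b2, sep = "|")
    if (k %in% c(p1, p2)) next       # degenerate: parents share a segment
    hit <- which(key == k)
    if (!length(hit)) next
    rows[[length(rows) + 1L]] <- data.frame(
      block1 = rd$b1, block2 = rd$b2,
      parent_block1 = rd$donors[1], parent_block2 = rd$donors[2],
      freq_lean = joint$freq_lean[hit], freq_fat = joint$freq_fat[hit])
  }
  if (!length(rows)) {
    return(data.frame(block1 = character(0), block2 = character(0),
                      parent_block1 = character(0),
                      parent_block2 = character(0),
                      freq_lean = numeric(0), freq_fat = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify haplotypes as line-specific, shared, or minor
#'
#' A haplotype is a line's specific main haplotype when its frequency is at
#' least `main_min` in that line and at most `absent_max` in the other
#' ("virtually line-specific"). Haplotypes common in both lines are shared;
#' the rest are minor. The thresholds are editorial defaults chosen so that
#' the qualifying haplotypes of a strongly swept region satisfy them, and are
#' configurable.
#'
#' @param tab Data frame with per-haplotype columns `freq_lean` and
#'   `freq_fat`.
#' @param absent_max Maximum frequency in the other line (default 0.02).
#' @param main_min Minimum main-haplotype frequency (default 0.40).
#' @return `tab` with a `label` column added: `"lean-specific"`,
#'   `"fat-specific"`, `"shared"` or `"minor"`.
#' @export
classify_line_specific <- function(tab, absent_max = 0.02, main_min = 0.40) {
  stopifnot(all(c("freq_lean", "freq_fat") %in% names(tab)))
  lab <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    fl <- tab$freq_lean[i]; ff <- tab$freq_fat[i]
    lab[i] <- if (fl >= main_min && ff <= absent_max) "lean-specific"
    else if (ff >= main_min && fl <= absent_max) "fat-specific"
    else if (fl > absent_max && ff > absent_max) "shared"
    else "minor"
  }
  tab$label <- lab
  tab
}

#' Widen a per-line haplotype table
#'
#' Merges the per-line rows of [block_haplotype_freqs()] into one row per
#' haplotype with `freq_lean` / `freq_fat` columns (0 when absent from a
#' line), suitable for [classify_line_specific()].
#'
#' @param tab Output of [block_haplotype_freqs()].
#' @return Data frame with columns `haplotype`, `count_lean`, `count_fat`,
#'   `freq_lean`, `freq_fat`, ordered by total frequency descending.
#' @export
hap_table_wide <- function(tab) {
  haps <- sort(unique(tab$haplotype))
  get <- function(ln, col) {
    sub <- tab[tab$line == ln, , drop = FALSE]
    v <- sub[[col]][match(haps, sub$haplotype)]
    ifelse(is.na(v), 0, v)
  }
  out <- data.frame(haplotype = haps,
                    count_lean = get("lean", "count"),
                    count_fat = get("fat", "count"),
                    freq_lean = get("lean", "freq"),
                    freq_fat = get("fat", "freq"))
  out <- out[order(-(out$freq_lean + out$freq_fat), out$haplotype), ]
  rownames(out) <- NULL
  out
}
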