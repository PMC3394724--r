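# Small builders used across test files. Everything is generated in code;
# no stored fixtures.

# genotype dataset from an explicit code matrix (one chromosome by default)
toy_dataset <- function(geno, pos = NULL, chrom = "1",
                        line = NULL, alleles = c("A", "G")) {
  geno <- as.matrix(geno)
  m <- ncol(geno); n <- nrow(geno)
  if (is.null(pos)) pos <- seq_len(m) * 10000
  if (is.null(line)) line <- rep(c("lean", "fat"), length.out = n)
  map <- data.frame(id = sprintf("s%03d", seq_len(m)),
                    chrom = rep(chrom, length.out = m), pos_bp = pos,
                    allele_a = alleles[1], allele_b = alleles[2])
  samples <- data.frame(id = sprintf("i%03d", seq_len(n)), line = line,
                        family = rep(c("famA", "famB"), length.out = n),
                        sex = "male", hatch = "1")
  geno_dataset(geno, map, samples)
}

# phased panel from per-line haplotype strings (each string = one haplotype
# row over the panel's markers)
toy_phased <- function(lean = character(0), fat = character(0),
                       pos = NULL, chrom = "1") {
  strs <- c(lean, fat)
  stopifnot(length(strs) >= 1)
  m <- nchar(strs[1])
  hap <- do.call(rbind, strsplit(strs, ""))
  if (is.null(pos)) pos <- seq_len(m) * 10000
  allele_a <- allele_b <- character(m)
  for (j in seq_len(m)) {
    obs <- sort(unique(hap[, j]))
    allele_a[j] <- obs[1]
    allele_b[j] <- if (length(obs) > 1) obs[2] else NA_character_
  }
  map <- data.frame(id = sprintf("s%03d", seq_len(m)), chrom = chrom,
                    pos_bp = pos, allele_a = allele_a, allele_b = allele_b)
  n <- length(strs)
  if (n %% 2 == 1) {  # constructor needs two rows per individual
    stop("toy_phased needs an even total number of haplotype rows")
  }
  info <- data.frame(
    individual_id = rep(sprintf("i%03d", seq_len(n / 2)), each = 2),
    hap_index = rep(1:2, n / 2),
    line = c(rep("lean", length(lean)), rep("fat", length(fat))))
  phased_haps(hap, info, map)
}

# random phased panel drawn from explicit haplotype strings with given
# per-line draw probabilities
random_phased <- function(haps, p_lean, p_fat, n_lean, n_fat, pos = NULL) {
  lean <- sample(haps, n_lean, replace = TRUE, prob = p_lean)
  fat <- sample(haps, n_fat, replace = TRUE, prob = p_fat)
  toy_phased(lean, fat, pos = pos)
}

# exhaustive-span re-implementation of the Gabriel block rule, used as the
# independent oracle (quadruple loop + the same greedy ordering)
oracle_gabriel <- function(pairs, n, frac = 0.95) {
  cls <- matrix("absent", n, n)
  if (nrow(pairs)) cls[cbind(pairs$i, pairs$j)] <- pairs$class
  cand <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      st <- 0L; inf <- 0L
      for (a in i:(j - 1)) {
        for (b in (a + 1):j) {
          if (cls[a, b] == "strong") { st <- st + 1L; inf <- inf + 1L }
          else if (cls[a, b] == "recomb") inf <- inf + 1L
        }
      }
      if (inf > 0L && st > 0L && st / inf >= frac) {
        cand[[length(cand) + 1L]] <- c(i = i, j = j)
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(start_idx = integer(0), end_idx = integer(0)))
  }
  cm <- do.call(rbind, cand)
  ord <- order(-(cm[, "j"] - cm[, "i"] + 1L), cm[, "i"])
  taken <- rep(FALSE, n)
  keep <- list()
  for (k in ord) {
    span <- cm[k, "i"]:cm[k, "j"]
    if (any(taken[span])) next
    taken[span] <- TRUE
    keep[[length(keep) + 1L]] <- data.frame(start_idx = cm[k, "i"],
                                            end_idx = cm[k, "j"])
  }
  out <- do.call(rbind, keep)
  out <- out[order(out$start_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# tiny simulation config used where a full-size genome is unnecessary
small_sim <- function(seed, ..., qtl = data.frame(chrom = 1, marker = 40,
                                                 add = 1, dom = 0)) {
  sim_config(seed = seed, n_chrom = 2, n_markers = 80, generations = 5,
             n_sires = 8, dams_per_sire = 4, offspring_per_dam = 3,
             qtl = qtl, ...)
}
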