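#' Configuration for the divergent-selection forward simulator
#'
#' Defaults emulate a two-line divergent truncation-selection breeding design
#' on a fat-content phenotype: a single base population split into two lines,
#' 11 generations of selection (high line selects upward, low line downward),
#' 25 sires each mated to 4 dams per line (25 half-sib families), and a
#' 60k-chip-like marker map with 22.5 kb mean spacing. The genome is scaled
#' to 5 chromosomes x 400 markers so that replicated simulations remain
#' desk-sized; founder haplotypes are drawn from a finite pool, which creates
#' chip-like background LD.
#'
#' @param seed Optional integer seed (set at [simulate_founders()]).
#' @param n_chrom Number of chromosomes (default 5).
#' @param n_markers Markers per chromosome (default 400).
#' @param spacing_bp Mean adjacent-marker spacing in bp (default 22500).
#' @param pool_size Founder haplotype pool size per chromosome (default 20;
#'   must be at least 2).
#' @param n_ancestral Number of ancestral haplotypes the pool is a segmental
#'   mosaic of (default 3). A recently bottlenecked grandsire line carries
#'   few distinct haplotypes in any one chromosome interval, which is what
#'   gives chip data their strong local LD; `Inf` draws every pool haplotype
#'   marker-independently instead (no local structure).
#' @param ancestral_segment_bp Mean length of the ancestral mosaic segments
#'   (default 2 Mb); switches between ancestors are placed with probability
#'   `1 - exp(-gap / ancestral_segment_bp)` per marker interval.
#' @param freq_range Range of the uniform allele-1 frequency distribution
#'   used for the ancestral haplotypes (default `c(0.15, 0.85)`, mimicking
#'   chip ascertainment against rare variants).
#' @param qtl Data frame with columns `chrom`, `marker` (index within the
#'   chromosome), `add` (additive effect a: half the difference between
#'   homozygotes) and `dom` (dominance effect d: heterozygote deviation), in
#'   phenotypic standard deviations. Default: one additive QTL of `a = 1` in
#'   the middle of chromosome 3. QTL markers get pool frequency 0.5 exactly.
#' @param h2 Narrow-sense heritability at founder frequencies (default 0.5);
#'   sets the environmental variance once, before selection.
#' @param generations Generations of selection (default 11).
#' @param n_sires Sires per line per generation (default 25).
#' @param dams_per_sire Dams mated to each sire (default 4).
#' @param offspring_per_dam Offspring per dam (default 3, i.e. 12 per
#'   half-sib family, 300 birds per line per generation).
#' @param recomb_cM_per_Mb Uniform recombination rate (default 3 cM/Mb; the
#'   chicken genome-wide average, ignoring macro/micro-chromosome
#'   differences). Crossover counts are Poisson per chromosome per meiosis.
#' @param selection Named vector giving each line's selection direction:
#'   `"down"` (select smallest phenotypes; the lean line), `"up"` (largest;
#'   the fat line) or `"none"` (random parents). Default
#'   `c(lean = "down", fat = "up")`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = NULL, n_chrom = 5, n_markers = 400,
                       spacing_bp = 22500, pool_size = 20,
                       n_ancestral = 3, ancestral_segment_bp = 2e6,
                       freq_range = c(0.15, 0.85),
                       qtl = data.frame(chrom = 3, marker = 200, add = 1,
                                        dom = 0),
                       h2 = 0.5, generations = 11, n_sires = 25,
                       dams_per_sire = 4, offspring_per_dam = 3,
                       recomb_cM_per_Mb = 3,
                       selection = c(lean = "down", fat = "up")) {
  stopifnot(pool_size >= 2, n_ancestral >= 2, ancestral_segment_bp > 0,
            h2 >= 0, h2 <= 1, generations >= 1,
            n_sires >= 1, dams_per_sire >= 1, offspring_per_dam >= 1,
            all(selection %in% c("down", "up", "none")),
            all(c("lean", "fat") %in% names(selection)))
  if (!is.null(qtl) && nrow(qtl)) {
    stopifnot(all(qtl$chrom %in% seq_len(n_chrom)),
              all(qtl$marker >= 1), all(qtl$marker <= n_markers),
              all(is.finite(qtl$add)), all(is.finite(qtl$dom)))
  }
  structure(list(seed = seed, n_chrom = n_chrom, n_markers = n_markers,
                 spacing_bp = spacing_bp, pool_size = pool_size,
                 n_ancestral = n_ancestral,
                 ancestral_segment_bp = ancestral_segment_bp,
                 freq_range = freq_range, qtl = qtl, h2 = h2,
                 generations = generations, n_sires = n_sires,
                 dams_per_sire = dams_per_sire,
                 offspring_per_dam = offspring_per_dam,
                 recomb_cM_per_Mb = recomb_cM_per_Mb,
                 selection = selection),
            class = "sim_config")
}

# Marker map for one simulated genome: positions at jittered multiples of
# spacing_bp, random biallelic pairs.
sim_map <- function(cfg) {
  maps <- lapply(seq_len(cfg$n_chrom), function(ch) {
    gaps <- pmax(1, round(stats::runif(cfg$n_markers, 0.5, 1.5) *
                            cfg$spacing_bp))
    pos <- cumsum(gaps)
    pairs <- t(vapply(seq_len(cfg$n_markers), function(i)
      sort(sample(ALLELE_ORDER, 2)), character(2)))
    data.frame(id = sprintf("chr%d_snp%04d", ch, seq_len(cfg$n_markers)),
               chrom = as.character(ch), pos_bp = pos,
               allele_a = pairs[, 1], allele_b = pairs[, 2])
  })
  do.call(rbind, maps)
}

#' Simulate the founder generation
#'
#' Draws a founder haplotype pool per chromosome and then builds the two
#' founder lines by sampling pool haplotypes with replacement: `n_sires`
#' males and `n_sires * dams_per_sire` females per line, all from the same
#' base pool (one grand population split at random). With finite
#' `n_ancestral` the pool haplotypes are segmental mosaics of a few
#' ancestral haplotypes, giving founders the strong local LD and limited
#' local haplotype diversity of a bottlenecked commercial line; with
#' `n_ancestral = Inf` pool alleles are drawn marker-independently. QTL
#' markers follow the ancestral structure: the allele-1-carrying ancestor
#' subset is chosen so the realized pool frequency is as close to 0.5 as
#' possible, so a sweep at the QTL drags its local haplotype background.
#' Monomorphic pool columns are repaired so every marker segregates.
#' Deterministic under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_population` with elements `cfg`, `map`,
#'   `haps` (per-chromosome integer matrices, 1 = allele 1; two rows per
#'   individual), `ind` (data frame: id, line, sex, family), `generation`.
#' @export
simulate_founders <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  map <- sim_map(cfg)
  pools <- lapply(seq_len(cfg$n_chrom), function(ch) {
    m <- cfg$n_markers
    p <- stats::runif(m, cfg$freq_range[1], cfg$freq_range[2])
    qtl_here <- if (is.null(cfg$qtl)) integer(0) else
      cfg$qtl$marker[cfg$qtl$chrom == ch]
    if (is.finite(cfg$n_ancestral)) {
      K <- cfg$n_ancestral
      anc <- matrix(stats::rbinom(K * m, 1, rep(p, each = K)), K, m)
      pos <- map$pos_bp[map$chrom == as.character(ch)]
      switch_p <- 1 - exp(-diff(pos) / cfg$ancestral_segment_bp)
      paths <- matrix(0L, cfg$pool_size, m)
      for (h in seq_len(cfg$pool_size)) {
        a <- sample.int(K, 1)
        sw <- stats::runif(m - 1) < switch_p
        path <- integer(m); path[1] <- a
        for (j in 2:m) {
          if (sw[j - 1]) a <- sample(seq_len(K)[-a], 1)
          path[j] <- a
        }
        paths[h, ] <- path
      }
      pool <- matrix(anc[cbind(as.vector(paths), rep(seq_len(m),
                                                     each = cfg$pool_size))],
                     cfg$pool_size, m)
      for (j in qtl_here) {
        # allele 1 carried by the ancestor subset whose realized pool
        # frequency is nearest 0.5
        anc_at <- paths[, j]
        best <- NULL; best_gap <- Inf
        for (mask in seq_len(2^K - 2)) {
          subset <- which(bitwAnd(mask, 2^(seq_len(K) - 1)) > 0)
          f <- mean(anc_at %in% subset)
          if (abs(f - 0.5) < best_gap) {
            best_gap <- abs(f - 0.5); best <- subset
          }
        }
        pool[, j] <- as.integer(anc_at %in% best)
      }
    } else {
      pool <- matrix(stats::rbinom(cfg$pool_size * m, 1,
                                   rep(p, each = cfg$pool_size)),
                     cfg$pool_size, m)
      for (j in qtl_here) {           # QTL pool frequency exactly 0.5
        pool[, j] <- rep(c(1L, 0L), length.out = cfg$pool_size)[
          sample.int(cfg$pool_size)]
      }
    }
    mono <- which(colSums(pool) %in% c(0, cfg$pool_size))
    for (j in mono) {                 # keep every marker segregating
      pool[sample.int(cfg$pool_size, 1), j] <- 1L - pool[1, j]
    }
    pool
  })
  n_per_line <- cfg$n_sires + cfg$n_sires * cfg$dams_per_sire
  n_total <- 2L * n_per_line
  haps <- lapply(pools, function(pool) {
    pool[sample.int(nrow(pool), 2L * n_total, replace = TRUE), ,
         drop = FALSE]
  })
  ind <- data.frame(
    id = sprintf("G0_%04d", seq_len(n_total)),
    line = rep(c("lean", "fat"), each = n_per_line),
    sex = rep(rep(c("male", "female"),
                  c(cfg$n_sires, cfg$n_sires * cfg$dams_per_sire)), 2),
    family = "base", stringsAsFactors = FALSE)
  structure(list(cfg = cfg, map = map, haps = haps, ind = ind,
                 generation = 0L),
            class = "sim_population")
}

# Genetic values from QTL genotypes (a = half homozygote difference,
# d = heterozygote deviation).
sim_genetic_values <- function(pop) {
  cfg <- pop$cfg
  n <- nrow(pop$ind)
  g <- numeric(n)
  if (is.null(cfg$qtl) || !nrow(cfg$qtl)) return(g)
  for (q in seq_len(nrow(cfg$qtl))) {
    ch <- cfg$qtl$chrom[q]; mk <- cfg$qtl$marker[q]
    dose <- pop$haps[[ch]][2 * seq_len(n) - 1L, mk] +
      pop$haps[[ch]][2 * seq_len(n), mk]
    g <- g + cfg$qtl$add[q] * (dose - 1) + cfg$qtl$dom[q] * (dose == 1)
  }
  g
}

sim_env_sd <- function(cfg) {
  if (is.null(cfg$qtl) || !nrow(cfg$qtl)) return(1)
  va0 <- sum(2 * 0.5 * 0.5 * cfg$qtl$add^2)   # founder QTL frequency is 0.5
  if (cfg$h2 == 0 || va0 == 0) return(1)
  sqrt(va0 * (1 - cfg$h2) / cfg$h2)
}

# One batch of gametes: parent_idx indexes individuals in `pop` (their two
# haplotype rows are 2i-1, 2i); returns a matrix with one gamete row per
# parent entry. Crossovers are Poisson with mean = map length in Morgans;
# positions uniform on the chromosome.
sim_gametes <- function(hapmat, parent_idx, pos_bp, morgans) {
  k <- length(parent_idx)
  n_x <- stats::rpois(k, morgans)
  h0 <- sample.int(2L, k, replace = TRUE) - 1L   # starting parental strand
  out <- matrix(0L, k, ncol(hapmat))
  plain <- which(n_x == 0L)
  if (length(plain)) {
    out[plain, ] <- hapmat[2L * parent_idx[plain] - 1L + h0[plain], ,
                           drop = FALSE]
  }
  span <- range(pos_bp)
  for (i in which(n_x > 0L)) {
    xpos <- sort(stats::runif(n_x[i], span[1], span[2]))
    seg <- findInterval(pos_bp, xpos)
    strand <- (h0[i] + seg) %% 2L
    r1 <- hapmat[2L * parent_idx[i] - 1L, ]
    r2 <- hapmat[2L * parent_idx[i], ]
    out[i, ] <- ifelse(strand == 0L, r1, r2)
  }
  out
}

#' Run generations of divergent truncation selection
#'
#' Each generation, within each line: offspring phenotypes are the sum of
#' QTL genotype effects and normal environmental noise (variance set once
#' from the configured heritability at founder frequencies); the best
#' `n_sires` males and `n_sires * dams_per_sire` females are selected by
#' phenotypic truncation (downward in the lean line, upward in the fat line,
#' or at random for an unselected line; ties broken by the random draw order)
#' and mated 1 sire : `dams_per_sire` dams into half-sib families; each dam
#' leaves `offspring_per_dam` offspring produced by Poisson-recombination
#' meiosis. Allele-frequency trajectories at the QTL and line phenotype
#' means are recorded per generation.
#'
#' @param pop Founders from [simulate_founders()].
#' @param cfg The same [sim_config()] (defaults to `pop$cfg`).
#' @return A list of class `sim_result`: `pop` (final generation
#'   `sim_population` with phenotypes), `truth` (list: `qtl`, `freq_traj`
#'   lean/fat x generation matrices per QTL, `pheno_means`), and `cfg`.
#' @export
evolve_divergent <- function(pop, cfg = pop$cfg) {
  stopifnot(inherits(pop, "sim_population"))
  env_sd <- sim_env_sd(cfg)
  n_dams <- cfg$n_sires * cfg$dams_per_sire
  off_per_line <- n_dams * cfg$offspring_per_dam
  morgans <- vapply(seq_len(cfg$n_chrom), function(ch) {
    pos <- pop$map$pos_bp[pop$map$chrom == as.character(ch)]
    diff(range(pos)) / 1e6 * cfg$recomb_cM_per_Mb / 100
  }, numeric(1))
  qtl <- cfg$qtl
  n_qtl <- if (is.null(qtl)) 0L else nrow(qtl)
  freq_traj <- array(NA_real_, dim = c(2, cfg$generations + 1L,
                                       max(n_qtl, 1L)),
                     dimnames = list(c("lean", "fat"), NULL, NULL))
  pheno_means <- matrix(NA_real_, 2, cfg$generations + 1L,
                        dimnames = list(c("lean", "fat"), NULL))
  qtl_freq <- function(p, line) {
    if (!n_qtl) return(NA_real_)
    rows_i <- which(p$ind$line == line)
    vapply(seq_len(n_qtl), function(q) {
      hp <- p$haps[[qtl$chrom[q]]]
      mean(hp[c(2 * rows_i - 1L, 2 * rows_i), qtl$marker[q]])
    }, numeric(1))
  }
  gv <- sim_genetic_values(pop)
  pheno <- gv + stats::rnorm(length(gv), 0, env_sd)
  for (ln in c("lean", "fat")) {
    freq_traj[ln, 1, ] <- qtl_freq(pop, ln)
    pheno_means[ln, 1] <- mean(pheno[pop$ind$line == ln])
  }

  cur <- pop
  cur_pheno <- pheno
  for (gen in seq_len(cfg$generations)) {
    new_haps <- lapply(seq_len(cfg$n_chrom), function(ch)
      matrix(0L, 2L * 2L * off_per_line, cfg$n_markers))
    new_ind <- vector("list", 2)
    row_off <- 0L
    for (li in 1:2) {
      ln <- c("lean", "fat")[li]
      cand <- which(cur$ind$line == ln)
      males <- cand[cur$ind$sex[cand] == "male"]
      females <- cand[cur$ind$sex[cand] == "female"]
      if (length(males) < cfg$n_sires || length(females) < n_dams) {
        stop("generation ", gen, ", line ", ln,
             ": not enough candidates of each sex to supply ",
             cfg$n_sires, " sires and ", n_dams, " dams")
      }
      dir <- cfg$selection[[ln]]
      rank_of <- function(idx) {
        key <- switch(dir, down = cur_pheno[idx], up = -cur_pheno[idx],
                      none = stats::runif(length(idx)))
        idx[order(key, stats::runif(length(idx)))]
      }
      sires <- rank_of(males)[seq_len(cfg$n_sires)]
      dams <- rank_of(females)[seq_len(n_dams)]
      dams <- dams[sample.int(n_dams)]             # random sire:dam pairing
      sire_of_dam <- rep(sires, each = cfg$dams_per_sire)
      dam_par <- rep(dams, each = cfg$offspring_per_dam)
      sire_par <- rep(sire_of_dam, each = cfg$offspring_per_dam)
      for (ch in seq_len(cfg$n_chrom)) {
        pos <- cur$map$pos_bp[cur$map$chrom == as.character(ch)]
        gam_s <- sim_gametes(cur$haps[[ch]], sire_par, pos, morgans[ch])
        gam_d <- sim_gametes(cur$haps[[ch]], dam_par, pos, morgans[ch])
        rows <- row_off + seq_len(2L * off_per_line)
        new_haps[[ch]][rows[c(TRUE, FALSE)], ] <- gam_s
        new_haps[[ch]][rows[c(FALSE, TRUE)], ] <- gam_d
      }
      new_ind[[li]] <- data.frame(
        id = sprintf("G%d_%s_%04d", gen, ln, seq_len(off_per_line)),
        line = ln,
        # balanced sexing (alternating within family) so small litters can
        # always supply the required sires and dams
        sex = rep(c("male", "female"), length.out = off_per_line),
        family = cur$ind$id[sire_par], stringsAsFactors = FALSE)
      row_off <- row_off + 2L * off_per_line
    }
    cur <- structure(list(cfg = cfg, map = cur$map, haps = new_haps,
                          ind = do.call(rbind, new_ind),
                          generation = gen),
                     class = "sim_population")
    gv <- sim_genetic_values(cur)
    cur_pheno <- gv + stats::rnorm(length(gv), 0, env_sd)
    for (ln in c("lean", "fat")) {
      freq_traj[ln, gen + 1L, ] <- qtl_freq(cur, ln)
      pheno_means[ln, gen + 1L] <- mean(cur_pheno[cur$ind$line == ln])
    }
  }
  cur$pheno <- cur_pheno
  truth <- list(qtl = qtl, freq_traj = freq_traj, pheno_means = pheno_means,
                env_sd = env_sd)
  structure(list(pop = cur, truth = truth, cfg = cfg), class = "sim_result")
}

#' Export a simulated population as pipeline inputs
#'
#' Converts a simulated generation into the analysis containers: a
#' [geno_dataset()], per-chromosome [phased_haps()] panels, and a phenotype
#' table with stylized fat traits: `AFP` (percent-like: a baseline plus the
#' simulated phenotype, floored at 0.05), `BW7` (7-week body weight, g) and
#' `AFW = AFP/100 * BW7` (g), plus `hatch` (two hatches at random).
#'
#' @param pop A `sim_population` (e.g. `sim_result$pop`).
#' @param afp_base Baseline AFP added to the simulated phenotype (default 3).
#' @return List with elements `dataset`, `phased` (list by chromosome),
#'   `phenotypes`.
#' @export
sim_export <- function(pop, afp_base = 3) {
  stopifnot(inherits(pop, "sim_population"))
  n <- nrow(pop$ind)
  geno <- do.call(cbind, lapply(pop$haps, function(h)
    h[2L * seq_len(n) - 1L, , drop = FALSE] +
      h[2L * seq_len(n), , drop = FALSE]))
  samples <- data.frame(id = pop$ind$id, line = pop$ind$line,
                        family = pop$ind$family, sex = pop$ind$sex,
                        hatch = sample(c("1", "2"), n, replace = TRUE),
                        stringsAsFactors = FALSE)
  ds <- geno_dataset(geno, pop$map, samples)
  phased <- lapply(seq_along(pop$haps), function(ch) {
    mp <- pop$map[pop$map$chrom == as.character(ch), , drop = FALSE]
    h01 <- pop$haps[[ch]]
    hap <- matrix(NA_character_, nrow(h01), ncol(h01))
    for (j in seq_len(ncol(h01))) {
      hap[, j] <- ifelse(h01[, j] == 1L, mp$allele_a[j], mp$allele_b[j])
    }
    info <- data.frame(
      individual_id = rep(pop$ind$id, each = 2),
      hap_index = rep(1:2, n),
      line = rep(pop$ind$line, each = 2), stringsAsFactors = FALSE)
    phased_haps(hap, info, mp)
  })
  names(phased) <- as.character(seq_along(pop$haps))
  u <- if (!is.null(pop$pheno)) pop$pheno else
    sim_genetic_values(pop) + stats::rnorm(n, 0, sim_env_sd(pop$cfg))
  afp <- pmax(0.05, afp_base + u)
  bw7 <- round(stats::rnorm(n, 2400, 220))
  phen <- data.frame(id = pop$ind$id, line = pop$ind$line,
                     family = pop$ind$family,
                     hatch = samples$hatch,
                     AFP = round(afp, 3), BW7 = bw7,
                     AFW = round(afp / 100 * bw7, 2),
                     stringsAsFactors = FALSE)
  list(dataset = ds, phased = phased, phenotypes = phen)
}

#' Construct an exact p-q sweep scenario
#'
#' A p-q sweep reverses the allele frequencies of a locus (`p_t = q_0`,
#' `q_t = p_0`), so expected heterozygosity `2pq` is unchanged while the
#' between-line allele frequency difference is `|p_0 - q_0| = |2 p_0 - 1|` —
#' the case heterozygosity-based scans are blind to and AFD-based measures
#' exist to catch. Genotype counts are constructed exactly (not evolved):
#' in the `before` dataset both lines carry frequency `p0` everywhere; in
#' the `after` dataset the fat line's markers inside the target region are
#' reversed to `1 - p0`. Background markers alternate between frequencies
#' `p0` and `1 - p0`, identical in both lines in both datasets, so expected
#' heterozygosity is constant along the whole chromosome (`2 p0 (1 - p0)`)
#' and the only between-line anomaly is the AFD of the swept region.
#'
#' @param p0 Initial allele-1 frequency of the swept region, in (0, 1) and
#'   not 0.5 (a reversal at 0.5 changes nothing and is rejected).
#' @param n_per_line Individuals per line (default 100; `2 * n_per_line * p0`
#'   must be an integer for exactness).
#' @param n_markers Markers on the single chromosome (default 201).
#' @param spacing_bp Marker spacing (default 22500).
#' @param region_bp Target region `c(start, end)` in bp; default the central
#'   500 kb.
#' @return List with elements `before` and `after` ([geno_dataset()]s),
#'   `region` (bp range) and `chrom`.
#' @export
pq_sweep_scenario <- function(p0, n_per_line = 100, n_markers = 201,
                              spacing_bp = 22500, region_bp = NULL) {
  stopifnot(p0 > 0, p0 < 1)
  if (p0 == 0.5) stop("p0 = 0.5 is degenerate: the reversal changes nothing")
  two_n <- 2L * n_per_line
  if (abs(two_n * p0 - round(two_n * p0)) > 1e-9) {
    stop("2 * n_per_line * p0 must be an integer for an exact construction")
  }
  pos <- spacing_bp * seq_len(n_markers)
  if (is.null(region_bp)) {
    mid <- pos[ceiling(n_markers / 2)]
    region_bp <- c(floor(mid / 250000) * 250000 - 250000,
                   floor(mid / 250000) * 250000 + 250000)
  }
  in_region <- pos >= region_bp[1] & pos < region_bp[2]
  map <- data.frame(id = sprintf("pq_snp%04d", seq_len(n_markers)),
                    chrom = "1", pos_bp = pos,
                    allele_a = "A", allele_b = "G")
  p_bg <- rep(c(p0, 1 - p0), length.out = n_markers)
  # exact genotype vector with allele-1 count = 2*n*p (as close to HWE
  # proportions as integers allow)
  geno_col <- function(p, n) {
    copies <- round(2 * n * p)
    n2 <- copies %/% 2L
    n1 <- copies %% 2L
    c(rep(2L, n2), rep(1L, n1), rep(0L, n - n2 - n1))
  }
  build <- function(p_lean, p_fat) {
    g <- matrix(0L, 2L * n_per_line, n_markers)
    for (j in seq_len(n_markers)) {
      g[seq_len(n_per_line), j] <- geno_col(p_lean[j], n_per_line)
      g[n_per_line + seq_len(n_per_line), j] <- geno_col(p_fat[j],
                                                         n_per_line)
    }
    samples <- data.frame(
      id = sprintf("pq_%04d", seq_len(2L * n_per_line)),
      line = rep(c("lean", "fat"), each = n_per_line),
      family = rep(sprintf("f%02d", 1:20), length.out = 2L * n_per_line),
      sex = "male", hatch = "1", stringsAsFactors = FALSE)
    geno_dataset(g, map, samples)
  }
  p_before <- ifelse(in_region, p0, p_bg)
  p_after_fat <- ifelse(in_region, 1 - p0, p_bg)
  list(before = build(p_before, p_before),
       after = build(p_before, p_after_fat),
       region = region_bp, chrom = "1",
       target_markers = which(in_region))
}
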