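#' Subset a phased panel to a marker index range
#'
#' @param ph A [phased_haps()] panel.
#' @param idx Integer marker indices (contiguous or not).
#' @return A `phased_haps` restricted to those markers.
#' @export
subset_phased <- function(ph, idx) {
  stopifnot(inherits(ph, "phased_haps"))
  phased_haps(ph$hap[, idx, drop = FALSE], ph$info,
              ph$map[idx, , drop = FALSE])
}

#' Pipeline configuration
#'
#' Collects every stage's thresholds plus either a simulation config or
#' input paths.
#'
#' @param sim A [sim_config()] to generate the data, or `NULL` to read files.
#' @param ped_path,map_path,samples_path,phased_paths,phenotype_path Input
#'   files when `sim` is `NULL`; `phased_paths` is a named list
#'   (chromosome -> file).
#' @param seed Integer seed for the whole run.
#' @param outdir Output directory for TSV tables, or `NULL` to skip writing.
#' @param window_size_bp,window_step_bp,min_snps Window-scan geometry.
#' @param afd_threshold,zafd_threshold,zhet_threshold Signature thresholds.
#' @param assoc_traits Trait columns to test (default `c("AFW", "AFP")`).
#' @param assoc_covariates Covariate columns for the GLS step (default
#'   `"hatch"`).
#' @param flank_bp Flank around a signature when looking up its most
#'   significant SNP (default 250 kb).
#' @param min_carriers,stop_threshold EHH settings.
#' @param qc Apply [apply_qc()] to the input (default `TRUE`).
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(sim = sim_config(), ped_path = NULL,
                            map_path = NULL, samples_path = NULL,
                            phased_paths = NULL, phenotype_path = NULL,
                            seed = 1L, outdir = NULL,
                            window_size_bp = 500000,
                            window_step_bp = 250000, min_snps = 3,
                            afd_threshold = 0.44, zafd_threshold = 4.0,
                            zhet_threshold = 5.0,
                            assoc_traits = c("AFW", "AFP"),
                            assoc_covariates = "hatch",
                            flank_bp = 250000, min_carriers = 5,
                            stop_threshold = 0.05, qc = TRUE) {
  if (is.null(sim)) {
    if (is.null(ped_path) || is.null(map_path) ||
        !file.exists(ped_path) || !file.exists(map_path)) {
      stop("without a simulation config, ped_path and map_path must exist")
    }
  }
  structure(as.list(environment()), class = "run_config")
}

annotate_signature <- function(sig_row, ds, phased, assoc, cfg) {
  ch <- sig_row$chrom
  reg_idx <- which(ds$map$chrom == ch &
                     ds$map$pos_bp >= sig_row$start_bp &
                     ds$map$pos_bp < sig_row$end_bp)
  out <- data.frame(n_region_snps = length(reg_idx),
                    block_found = FALSE, block_n_snps = NA_integer_,
                    main_hap_label = NA_character_,
                    ehh_area_lean = NA_real_, ehh_area_fat = NA_real_,
                    ehh_ratio_fat_lean = NA_real_)
  ph <- phased[[ch]]
  if (!is.null(ph) && length(reg_idx) >= 2) {
    chrom_idx <- which(ds$map$chrom == ch)
    local_idx <- match(reg_idx, chrom_idx)
    reg_ph <- subset_phased(ph, local_idx)
    # blocks from the combined panel; haplotype table on the largest block
    pr <- ld_pairs(reg_ph, line = NULL)
    blocks <- gabriel_blocks(pr, ncol(reg_ph$hap))
    if (nrow(blocks)) {
      big <- blocks[which.max(blocks$n_snps), ]
      out$block_found <- TRUE
      out$block_n_snps <- big$n_snps
      tab <- hap_table_wide(block_haplotype_freqs(reg_ph, big))
      tab <- classify_line_specific(tab)
      out$main_hap_label <- tab$label[1]
      core <- c(big$start_idx, big$end_idx)
    } else {
      mid <- which.min(abs(reg_ph$map$pos_bp -
                             (sig_row$start_bp + sig_row$end_bp) / 2))
      core <- c(mid, mid)
    }
    core_global <- local_idx[core]
    for (ln in c("lean", "fat")) {
      a <- tryCatch(
        line_ehh_area(ph, core_global, line = ln,
                      stop_threshold = cfg$stop_threshold),
        error = function(e) NA_real_)
      out[[paste0("ehh_area_", ln)]] <- a
    }
    if (is.finite(out$ehh_area_lean) && is.finite(out$ehh_area_fat) &&
        out$ehh_area_lean > 0) {
      out$ehh_ratio_fat_lean <- out$ehh_area_fat / out$ehh_area_lean
    }
  }
  # most significant SNP within region +/- flank, per trait
  for (tr in unique(assoc$trait)) {
    a <- assoc[assoc$trait == tr & assoc$chrom == ch &
                 assoc$pos_bp >= sig_row$start_bp - cfg$flank_bp &
                 assoc$pos_bp < sig_row$end_bp + cfg$flank_bp, ]
    pmin_val <- suppressWarnings(min(c(a$add_p, a$dom_p), na.rm = TRUE))
    best <- NA_character_
    if (is.finite(pmin_val)) {
      hit <- which(a$add_p == pmin_val | a$dom_p == pmin_val)[1]
      best <- a$id[hit]
    } else pmin_val <- NA_real_
    out[[paste0("top_snp_", tr)]] <- best
    out[[paste0("top_p_", tr)]] <- pmin_val
  }
  # refine inferred line: lower standardized heterozygosity, ties broken by
  # larger EHH area
  inferred <- sig_row$selected_line
  if (is.na(inferred)) {
    zl <- sig_row$z_lean_extreme; zf <- sig_row$z_fat_extreme
    if (!is.na(zl) && !is.na(zf) && zl != zf) {
      inferred <- if (zl < zf) "lean" else "fat"
    } else if (is.finite(out$ehh_area_lean) && is.finite(out$ehh_area_fat) &&
               out$ehh_area_lean != out$ehh_area_fat) {
      inferred <- if (out$ehh_area_fat > out$ehh_area_lean) "fat" else "lean"
    }
  }
  out$inferred_line <- inferred
  out
}

#' Run the full selection-signature pipeline
#'
#' Stages in screening order: data acquisition (simulate or read), QC, the
#' sliding-window AFD/heterozygosity scan with per-chromosome
#' standardization, signature calling, then corroboration of each flagged
#' region (Gabriel blocks, main-haplotype line-specificity, per-line EHH
#' areas) and association lookup (most significant SNP within the region
#' plus a flank, per trait), and finally report assembly. Reruns with the
#' same config and seed are identical.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `run_report`: `config` (threshold echo), `qc`,
#'   `chromosomes`, `windows`, `signatures` (annotated), `assoc`,
#'   `flagged_window_rate`, `n_windows`. Stage tables are also written as
#'   TSVs under `cfg$outdir` when set.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  if (!is.null(cfg$sim)) {
    sim <- cfg$sim
    sim$seed <- NULL              # the run seed governs; set.seed done above
    founders <- simulate_founders(sim)
    res <- evolve_divergent(founders, sim)
    dat <- sim_export(res$pop)
    ds <- dat$dataset; phased <- dat$phased; phen <- dat$phenotypes
    truth <- res$truth
  } else {
    ds <- read_genotypes(cfg$ped_path, cfg$map_path, cfg$samples_path)
    phased <- if (!is.null(cfg$phased_paths)) {
      lapply(stats::setNames(names(cfg$phased_paths),
                             names(cfg$phased_paths)), function(ch)
        read_phased(cfg$phased_paths[[ch]],
                    ds$map[ds$map$chrom == ch, , drop = FALSE]))
    } else list()
    phen <- if (!is.null(cfg$phenotype_path))
      read_phenotypes(cfg$phenotype_path) else NULL
    truth <- NULL
  }
  qc_report <- NULL
  if (isTRUE(cfg$qc)) {
    ds_qc <- apply_qc(ds)
    qc_report <- attr(ds_qc, "qc_report")
    kept <- match(ds_qc$map$id, ds$map$id)
    # keep the phased panels aligned with the surviving markers
    phased <- lapply(stats::setNames(names(phased), names(phased)),
                     function(ch) {
      keep_local <- which(ds$map$id[ds$map$chrom == ch] %in% ds_qc$map$id)
      subset_phased(phased[[ch]], keep_local)
    })
    ds <- ds_qc
  }
  ws <- scan_windows(ds, cfg$window_size_bp, cfg$window_step_bp,
                     cfg$min_snps)
  sigs <- call_signatures(ws, cfg$afd_threshold, cfg$zafd_threshold,
                          cfg$zhet_threshold)
  assoc <- NULL
  if (!is.null(phen)) {
    traits <- intersect(cfg$assoc_traits, names(phen))
    covs <- intersect(cfg$assoc_covariates, names(phen))
    if (!length(covs)) covs <- NULL
    assoc <- do.call(rbind, lapply(traits, function(tr)
      assoc_scan(ds, phen, tr, covariates = covs)))
  }
  if (nrow(sigs)) {
    ann <- do.call(rbind, lapply(seq_len(nrow(sigs)), function(i)
      annotate_signature(sigs[i, ], ds, phased,
                         if (is.null(assoc)) data.frame(trait = character(0),
                                                        chrom = character(0),
                                                        pos_bp = numeric(0),
                                                        id = character(0),
                                                        add_p = numeric(0),
                                                        dom_p = numeric(0))
                         else assoc, cfg)))
    sigs <- cbind(sigs, ann)
  }
  n_flag <- sum(lengths(window_signals(ws, cfg$afd_threshold,
                                       cfg$zafd_threshold,
                                       cfg$zhet_threshold)) > 0)
  report <- structure(list(
    config = cfg,
    qc = qc_report,
    chromosomes = chromosome_summary(ds),
    windows = ws,
    signatures = sigs,
    assoc = assoc,
    truth = truth,
    n_windows = nrow(ws),
    flagged_window_rate = if (nrow(ws)) n_flag / nrow(ws) else NA_real_),
    class = "run_report")
  if (!is.null(cfg$outdir)) {
    tabs <- list(chromosome_summary = report$chromosomes,
                 windows = ws[, setdiff(names(ws), "snp_idx")],
                 signatures = sigs)
    if (!is.null(assoc)) tabs$assoc <- assoc
    if (!is.null(qc_report)) tabs$qc_report <- qc_report
    write_report_tables(tabs, cfg$outdir)
    writeLines(report_markdown(report),
               file.path(cfg$outdir, "report.md"))
  }
  report
}

report_markdown <- function(report) {
  cfg <- report$config
  c("# Divergent-line selection signature report",
    "",
    sprintf("Seed: %d. Windows: %d (%.1f%% flagged). Thresholds: AFD >= %.2f, Z_AFD >= %.1f, |Z_het| >= %.1f.",
            cfg$seed, report$n_windows, 100 * report$flagged_window_rate,
            cfg$afd_threshold, cfg$zafd_threshold, cfg$zhet_threshold),
    "",
    sprintf("Signature regions: %d",
            if (is.null(report$signatures)) 0L else nrow(report$signatures)))
}

#' @export
print.run_report <- function(x, ...) {
  cat(report_markdown(x), sep = "\n")
  invisible(x)
}
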