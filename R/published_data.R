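#' Published haplotype table of the chicken Z-chromosome fat-content region
#'
#' Haplotype frequencies observed in the NEAUHLF lean and fat broiler lines
#' over the 0.73 Mb PC1/PCSK1 region of chromosome Z (55.43-56.16 Mb, 26
#' intronic SNP markers), split into the two haplotype blocks separated by
#' the recombination point inside FBN2. The two main haplotypes (1 in the
#' lean line, 2 in the fat line) carry opposite alleles at all 26 markers and
#' are virtually line-specific; haplotype 3 is their recombinant and has
#' nearly equal frequency in both lines. Frequencies are as published
#' (model-based phasing output, so the rarest entries are finer than one
#' haplotype count).
#'
#' @return Data frame with columns `haplotype`, `block1` (12 markers),
#'   `block2` (14 markers), `freq_lean`, `freq_fat`.
#' @export
pcsk1_region_haplotypes <- function() {
  path <- system.file("extdata", "pcsk1_region_haplotypes.tsv",
                      package = "divsig", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "character",
                                   "numeric", "numeric"))
}

#' Published phenotype summary of the NEAUHLF lines at generation 11
#'
#' Means and standard deviations of abdominal fat weight (AFW, g), abdominal
#' fat percentage (AFP, %) and 7-week body weight (BW7, g) in the lean
#' (n = 272) and fat (n = 203) NEAUHLF broiler lines after 11 generations of
#' divergent selection.
#'
#' @return Data frame with columns `trait`, `line`, `n`, `mean`, `sd`.
#' @export
neauhlf_phenotype_summary <- function() {
  path <- system.file("extdata", "neauhlf_phenotype_summary.tsv",
                      package = "divsig", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Published NEAUHLF genome-scan marker counts
#'
#' Chip, post-QC and genome-wide-significant SNP counts from the NEAUHLF 60k
#' genotyping study: 57,636 chip SNPs, 45,578 passing QC (the Bonferroni
#' denominator), 569 SNPs significant for abdominal fat traits, of which 342
#' were significant for both AFW and AFP.
#'
#' @return Named numeric vector.
#' @export
neauhlf_scan_counts <- function() {
  path <- system.file("extdata", "neauhlf_gwas_counts.tsv",
                      package = "divsig", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stats::setNames(tab$value, tab$quantity)
}
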