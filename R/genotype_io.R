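#' @keywords internal
"_PACKAGE"

ALLELE_ORDER <- c("A", "C", "G", "T")
LINE_LEVELS <- c("lean", "fat")

#' Reference allele ("allele 1") of a biallelic SNP
#'
#' For a biallelic SNP the reference allele, "allele 1", is the alphabetically
#' prior base of the pair: `A` for A/C, A/G and A/T; `C` for C/G and C/T; and
#' `G` for G/T. Genotype codes throughout the package count copies of this
#' allele, so allele-frequency differences between lines are sign-stable.
#'
#' @param a,b Character vectors of single bases (`A`, `C`, `G` or `T`); the
#'   two alleles of each SNP, in either order.
#' @return Character vector: the allele-1 base of each pair.
#' @examples
#' allele1("A", "G")        # "A"
#' allele1("G", "C")        # "C"
#' allele1(c("T", "T"), c("G", "C"))
#' @export
allele1 <- function(a, b) {
  if (length(a) != length(b)) {
    stop("allele1(): 'a' and 'b' must have the same length")
  }
  bad <- !(a %in% ALLELE_ORDER) | !(b %in% ALLELE_ORDER)
  if (any(bad)) {
    stop("allele1(): non-ACGT allele symbol in pair(s): ",
         paste(unique(paste(a[bad], b[bad], sep = "/")), collapse = ", "))
  }
  mono <- a == b
  if (any(mono)) {
    stop("allele1(): monomorphic allele pair(s): ",
         paste(unique(a[mono]), collapse = ", "))
  }
  ifelse(match(a, ALLELE_ORDER) < match(b, ALLELE_ORDER), a, b)
}

#' Construct a genotype dataset
#'
#' Bundles a genotype matrix with its SNP map and sample metadata. Genotype
#' codes count copies of allele 1 (see [allele1()]): 0, 1, 2 or `NA` for a
#' missing call. Markers are stored sorted by chromosome (in order of first
#' appearance in the map) and base-pair position, ties broken by marker id.
#'
#' @param geno Integer matrix, individuals x SNPs, entries in `{0, 1, 2, NA}`.
#' @param map Data frame with columns `id`, `chrom`, `pos_bp`, `allele_a`
#'   (allele 1) and `allele_b`; one row per SNP, in the column order of `geno`.
#'   `allele_b` may be `NA` for a SNP observed monomorphic.
#' @param samples Data frame with columns `id`, `line` (`"lean"`/`"fat"`),
#'   `family`, `sex`, `hatch`; one row per individual, in the row order of
#'   `geno`.
#' @return An object of class `geno_dataset`: a list with elements `geno`,
#'   `map` and `samples`.
#' @export
geno_dataset <- function(geno, map, samples) {
  geno <- as.matrix(geno)
  stopifnot(is.data.frame(map), is.data.frame(samples))
  req_map <- c("id", "chrom", "pos_bp", "allele_a", "allele_b")
  if (!all(req_map %in% names(map))) {
    stop("map must have columns: ", paste(req_map, collapse = ", "))
  }
  req_smp <- c("id", "line", "family")
  if (!all(req_smp %in% names(samples))) {
    stop("samples must have columns: ", paste(req_smp, collapse = ", "))
  }
  if (!"sex" %in% names(samples)) samples$sex <- NA_character_
  if (!"hatch" %in% names(samples)) samples$hatch <- NA_character_
  if (nrow(map) != ncol(geno)) {
    stop("map has ", nrow(map), " SNPs but genotype matrix has ",
         ncol(geno), " columns")
  }
  if (nrow(samples) != nrow(geno)) {
    stop("samples has ", nrow(samples), " rows but genotype matrix has ",
         nrow(geno), " rows")
  }
  if (any(map$pos_bp < 1, na.rm = TRUE)) stop("pos_bp must be >= 1")
  both <- !is.na(map$allele_a) & !is.na(map$allele_b)
  if (any(map$allele_a[both] == map$allele_b[both])) {
    stop("allele_a and allele_b must differ")
  }
  extra_lines <- setdiff(unique(as.character(samples$line)), c(LINE_LEVELS, NA))
  if (length(extra_lines)) {
    stop("line labels must be 'lean' or 'fat'; found: ",
         paste(extra_lines, collapse = ", "))
  }
  samples$line <- factor(as.character(samples$line), levels = LINE_LEVELS)
  ord <- order(match(map$chrom, unique(map$chrom)), map$pos_bp, map$id)
  map <- map[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  rownames(map) <- NULL
  rownames(samples) <- NULL
  dimnames(geno) <- list(as.character(samples$id), as.character(map$id))
  structure(list(geno = geno, map = map, samples = samples),
            class = "geno_dataset")
}

#' @export
print.geno_dataset <- function(x, ...) {
  cat("geno_dataset:", nrow(x$geno), "individuals x", ncol(x$geno), "SNPs on",
      length(unique(x$map$chrom)), "chromosome(s)\n")
  cat("  lines:", paste(sprintf("%s=%d", levels(x$samples$line),
                                table(x$samples$line)), collapse = ", "), "\n")
  cat("  missing calls:", sum(is.na(x$geno)), "\n")
  invisible(x)
}

#' Subset a genotype dataset
#'
#' @param ds A `geno_dataset`.
#' @param snps Integer/logical index into the markers, or `NULL` for all.
#' @param individuals Integer/logical index into the individuals, or `NULL`.
#' @return A `geno_dataset` restricted to the selected markers/individuals.
#' @export
subset_geno <- function(ds, snps = NULL, individuals = NULL) {
  stopifnot(inherits(ds, "geno_dataset"))
  if (is.null(snps)) snps <- seq_len(ncol(ds$geno))
  if (is.null(individuals)) individuals <- seq_len(nrow(ds$geno))
  geno_dataset(ds$geno[individuals, snps, drop = FALSE],
               ds$map[snps, , drop = FALSE],
               ds$samples[individuals, , drop = FALSE])
}

#' Read genotypes from PLINK text PED/MAP files
#'
#' Parses whitespace-delimited PED/MAP files into a [geno_dataset()]. Allele
#' pairs `0 0` (or any pair containing `0`) become missing. Genotypes are
#' coded as copies of allele 1 ([allele1()]) of the alleles observed at each
#' SNP. Line membership is taken from a sidecar sample table when given;
#' otherwise the PED phenotype column is interpreted as the line code
#' (`1`/`lean` = lean, `2`/`fat` = fat).
#'
#' @param ped_path Path to the PED file (6 leading columns: family id,
#'   individual id, father, mother, sex, phenotype/line; then two allele
#'   columns per SNP).
#' @param map_path Path to the MAP file (3 columns chrom/id/pos or 4 columns
#'   chrom/id/cM/pos).
#' @param samples Optional data frame (or path to a TSV) with columns `id`,
#'   `line`, `family`, and optionally `sex`, `hatch`; overrides PED metadata.
#' @return A `geno_dataset`.
#' @export
read_genotypes <- function(ped_path, map_path, samples = NULL) {
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = "character")
  if (ncol(map_raw) == 3L) {
    map <- data.frame(id = map_raw[[2]], chrom = map_raw[[1]],
                      pos_bp = as.integer(map_raw[[3]]))
  } else if (ncol(map_raw) == 4L) {
    map <- data.frame(id = map_raw[[2]], chrom = map_raw[[1]],
                      pos_bp = as.integer(map_raw[[4]]))
  } else {
    stop("MAP file must have 3 or 4 columns, found ", ncol(map_raw))
  }
  m <- nrow(map)
  lines_txt <- readLines(ped_path)
  lines_txt <- lines_txt[nzchar(trimws(lines_txt))]
  if (!length(lines_txt)) stop("empty PED file: ", ped_path)
  fields <- strsplit(trimws(lines_txt), "\\s+")
  lens <- lengths(fields)
  expected <- 6L + 2L * m
  bad <- which(lens != expected)
  if (length(bad)) {
    stop(sprintf(
      "PED row %d has %d fields; expected %d for the %d SNPs listed in MAP",
      bad[1], lens[bad[1]], expected, m))
  }
  ped <- do.call(rbind, fields)
  n <- nrow(ped)
  a1 <- ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(m), drop = FALSE]

  allele_a <- allele_b <- rep(NA_character_, m)
  geno <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    ua <- sort(unique(obs[obs != "0"]))
    if (length(ua) > 2L) {
      stop(sprintf("SNP %s has more than 2 observed alleles: %s",
                   map$id[j], paste(ua, collapse = ", ")))
    }
    if (length(ua) == 2L) {
      allele_a[j] <- allele1(ua[1], ua[2])
      allele_b[j] <- setdiff(ua, allele_a[j])
    } else if (length(ua) == 1L) {
      allele_a[j] <- ua
    }
    miss <- a1[, j] == "0" | a2[, j] == "0"
    code <- (a1[, j] == allele_a[j]) + (a2[, j] == allele_a[j])
    code[miss] <- NA_integer_
    geno[, j] <- as.integer(code)
  }
  map$allele_a <- allele_a
  map$allele_b <- allele_b

  smp <- data.frame(
    id = ped[, 2],
    line = unname(c("1" = "lean", "2" = "fat",
                    "lean" = "lean", "fat" = "fat")[ped[, 6]]),
    family = ped[, 1],
    sex = unname(c("1" = "male", "2" = "female")[ped[, 5]]),
    hatch = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(samples)) {
    if (is.character(samples)) {
      samples <- utils::read.table(samples, header = TRUE, sep = "\t",
                                   colClasses = "character")
    }
    idx <- match(smp$id, samples$id)
    if (anyNA(idx)) {
      stop("sample table is missing individuals: ",
           paste(smp$id[is.na(idx)], collapse = ", "))
    }
    for (col in intersect(c("line", "family", "sex", "hatch"),
                          names(samples))) {
      smp[[col]] <- samples[[col]][idx]
    }
  }
  geno_dataset(geno, map, smp)
}

#' Write a genotype dataset to PLINK text PED/MAP files
#'
#' Inverse of [read_genotypes()]: `read_genotypes(write_genotypes(ds))`
#' round-trips, including missing codes. An optional sidecar sample table
#' preserves `hatch` (which PED has no column for).
#'
#' @param ds A `geno_dataset`.
#' @param ped_path,map_path Output paths.
#' @param samples_path Optional path for a sidecar sample TSV.
#' @return Invisibly, `ds`.
#' @export
write_genotypes <- function(ds, ped_path, map_path, samples_path = NULL) {
  stopifnot(inherits(ds, "geno_dataset"))
  map_out <- data.frame(ds$map$chrom, ds$map$id, 0L, ds$map$pos_bp)
  utils::write.table(map_out, map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  n <- nrow(ds$geno); m <- ncol(ds$geno)
  aa <- ds$map$allele_a
  ab <- ifelse(is.na(ds$map$allele_b), ds$map$allele_a, ds$map$allele_b)
  al1 <- al2 <- matrix("0", n, m)
  g <- ds$geno
  for (j in seq_len(m)) {
    al1[, j] <- c("0", ab[j], aa[j], aa[j])[g[, j] + 2L]
    al2[, j] <- c("0", ab[j], ab[j], aa[j])[g[, j] + 2L]
    al1[is.na(g[, j]), j] <- "0"
    al2[is.na(g[, j]), j] <- "0"
  }
  inter <- matrix("", n, 2L * m)
  inter[, 2L * seq_len(m) - 1L] <- al1
  inter[, 2L * seq_len(m)] <- al2
  sex_code <- c(male = "1", female = "2")[as.character(ds$samples$sex)]
  sex_code[is.na(sex_code)] <- "0"
  line_code <- c(lean = "1", fat = "2")[as.character(ds$samples$line)]
  line_code[is.na(line_code)] <- "-9"
  lead <- cbind(as.character(ds$samples$family), as.character(ds$samples$id),
                "0", "0", sex_code, line_code)
  utils::write.table(cbind(lead, inter), ped_path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(samples_path)) {
    utils::write.table(ds$samples, samples_path, quote = FALSE, sep = "\t",
                       row.names = FALSE)
  }
  invisible(ds)
}

#' Apply marker and individual quality control
#'
#' Removes individuals with too many missing genotypes, then SNPs failing the
#' minor-allele-frequency or call-rate thresholds. MAF is computed on the
#' combined sample of both lines (a SNP swept to opposite fixation in the two
#' lines still passes). The individual filter runs before the final SNP filter
#' so that high-missingness individuals do not deflate SNP call rates.
#'
#' @param ds A `geno_dataset`.
#' @param maf_min Minimum combined-sample minor allele frequency (default
#'   0.05).
#' @param call_rate_min Minimum per-SNP call rate (default 0.95).
#' @param ind_miss_max Individuals with a missing-genotype fraction at or
#'   above this are removed (default 0.05).
#' @return The filtered `geno_dataset`, with a `qc_report` attribute: a data
#'   frame of counts removed per criterion. Errors if nothing survives.
#' @export
apply_qc <- function(ds, maf_min = 0.05, call_rate_min = 0.95,
                     ind_miss_max = 0.05) {
  stopifnot(inherits(ds, "geno_dataset"))
  n0 <- nrow(ds$geno); m0 <- ncol(ds$geno)
  ind_miss <- rowMeans(is.na(ds$geno))
  keep_ind <- ind_miss < ind_miss_max
  if (!any(keep_ind)) stop("QC removed all individuals (missingness filter)")
  g <- ds$geno[keep_ind, , drop = FALSE]
  call_rate <- colMeans(!is.na(g))
  called <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * called)
  maf <- pmin(p, 1 - p)
  maf[called == 0] <- 0
  keep_snp <- call_rate >= call_rate_min & !is.na(maf) & maf >= maf_min
  if (!any(keep_snp)) stop("QC removed all SNPs (MAF/call-rate filters)")
  out <- subset_geno(ds, snps = which(keep_snp),
                     individuals = which(keep_ind))
  report <- data.frame(
    criterion = c("individual_missingness", "snp_low_maf", "snp_call_rate",
                  "individuals_kept", "snps_kept"),
    threshold = c(ind_miss_max, maf_min, call_rate_min, NA, NA),
    removed = c(n0 - sum(keep_ind),
                sum(!is.na(maf) & maf < maf_min | called == 0),
                sum(call_rate < call_rate_min),
                NA, NA),
    kept = c(NA, NA, NA, sum(keep_ind), sum(keep_snp)))
  attr(out, "qc_report") <- report
  out
}

#' Construct a phased haplotype panel
#'
#' @param hap Character matrix of bases; one row per haplotype (two per
#'   diploid individual), one column per marker of a single chromosome.
#' @param info Data frame with columns `individual_id`, `hap_index` (1 or 2)
#'   and `line`; one row per haplotype row.
#' @param map SNP map for the chromosome, as in [geno_dataset()].
#' @return An object of class `phased_haps`.
#' @export
phased_haps <- function(hap, info, map) {
  hap <- as.matrix(hap)
  stopifnot(nrow(info) == nrow(hap), nrow(map) == ncol(hap))
  if (length(unique(map$chrom)) > 1L) {
    stop("a phased panel covers a single chromosome; found: ",
         paste(unique(map$chrom), collapse = ", "))
  }
  cnt <- table(info$individual_id)
  if (any(cnt %% 2L != 0L)) {
    stop("odd haplotype-row count for individual(s): ",
         paste(names(cnt)[cnt %% 2L != 0L], collapse = ", "))
  }
  for (j in seq_len(ncol(hap))) {
    ok <- hap[, j] %in% c(map$allele_a[j], map$allele_b[j]) | is.na(hap[, j])
    if (!all(ok)) {
      stop(sprintf("haplotype base '%s' at marker %s is not one of its alleles (%s/%s)",
                   hap[!ok, j][1], map$id[j], map$allele_a[j], map$allele_b[j]))
    }
  }
  info$line <- factor(as.character(info$line), levels = LINE_LEVELS)
  rownames(info) <- NULL
  rownames(map) <- NULL
  dimnames(hap) <- list(NULL, as.character(map$id))
  structure(list(hap = hap, info = info, map = map), class = "phased_haps")
}

#' @export
print.phased_haps <- function(x, ...) {
  cat("phased_haps:", nrow(x$hap), "haplotypes x", ncol(x$hap),
      "markers on chromosome", unique(x$map$chrom), "\n")
  invisible(x)
}

#' Read/write a phased haplotype table
#'
#' The file format is a TSV whose header row is `individual_id`, `hap_index`,
#' `line`, then one column per marker id; each data row is one haplotype.
#' `read_phased(write_phased(x), map)` round-trips.
#'
#' @param path File path.
#' @param map SNP map of the chromosome (supplies marker order and alleles).
#' @return `read_phased`: a [phased_haps()] object.
#' @export
read_phased <- function(path, map) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (!nrow(tab)) stop("empty phased haplotype file: ", path)
  lead <- c("individual_id", "hap_index", "line")
  if (!all(lead %in% names(tab))) {
    stop("phased file must have columns ", paste(lead, collapse = ", "))
  }
  marker_cols <- setdiff(names(tab), lead)
  if (!setequal(marker_cols, map$id)) {
    stop("phased file markers do not match the map")
  }
  hap <- as.matrix(tab[, as.character(map$id), drop = FALSE])
  hap[hap %in% c("0", "N", "")] <- NA_character_
  info <- data.frame(individual_id = tab$individual_id,
                     hap_index = as.integer(tab$hap_index),
                     line = tab$line, stringsAsFactors = FALSE)
  phased_haps(hap, info, map)
}

#' @rdname read_phased
#' @param ph A `phased_haps` object.
#' @export
write_phased <- function(ph, path) {
  stopifnot(inherits(ph, "phased_haps"))
  hap_out <- ph$hap
  hap_out[is.na(hap_out)] <- "N"
  out <- cbind(data.frame(individual_id = ph$info$individual_id,
                          hap_index = ph$info$hap_index,
                          line = as.character(ph$info$line)),
               as.data.frame(hap_out, check.names = FALSE))
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(ph)
}

#' Read a phenotype table
#'
#' Expects a TSV with a header naming at least `id`; recognised trait columns
#' are `AFW` (abdominal fat weight, g), `AFP` (abdominal fat percentage) and
#' `BW7` (7-week body weight, g), plus arbitrary covariates such as `hatch`.
#' When AFW, AFP and BW7 are all present, AFP is checked against
#' `100 * AFW / BW7` and inconsistencies beyond rounding produce a warning.
#'
#' @param path File path.
#' @return A data frame of phenotypes.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!nrow(tab)) stop("empty phenotype file: ", path)
  if (!"id" %in% names(tab)) stop("phenotype file must have an 'id' column")
  tab$id <- as.character(tab$id)
  if ("hatch" %in% names(tab)) tab$hatch <- as.character(tab$hatch)
  if ("family" %in% names(tab)) tab$family <- as.character(tab$family)
  for (tr in intersect(c("AFW", "AFP", "BW7"), names(tab))) {
    tab[[tr]] <- as.numeric(tab[[tr]])
    if (tr %in% c("AFW", "AFP") && any(tab[[tr]] < 0, na.rm = TRUE)) {
      stop(tr, " must be non-negative")
    }
  }
  if (all(c("AFW", "AFP", "BW7") %in% names(tab))) {
    full <- stats::complete.cases(tab[, c("AFW", "AFP", "BW7")])
    implied <- 100 * tab$AFW[full] / tab$BW7[full]
    off <- abs(implied - tab$AFP[full]) > pmax(0.05, 0.02 * implied)
    if (any(off)) {
      warning(sum(off), " phenotype row(s) have AFP inconsistent with ",
              "100*AFW/BW7 beyond rounding")
    }
  }
  tab
}

#' @rdname read_phenotypes
#' @param phen Data frame of phenotypes.
#' @param path File path.
#' @export
write_phenotypes <- function(phen, path) {
  utils::write.table(phen, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(phen)
}

# Write a named list of data frames as TSV report tables (deterministic
# column order as given).
#' Write report tables
#'
#' Writes each data frame in a named list as `<name>.tsv` under `dir`.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_report_tables <- function(tables, dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], p, quote = FALSE, sep = "\t",
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
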