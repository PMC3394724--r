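test_that("allele1 follows the alphabetical-precedence convention on all six pairs", {
  # A dominates any partner; C dominates G/T; G dominates T
  expect_identical(allele1("A", "C"), "A")
  expect_identical(allele1("A", "G"), "A")
  expect_identical(allele1("A", "T"), "A")
  expect_identical(allele1("C", "G"), "C")
  expect_identical(allele1("C", "T"), "C")
  expect_identical(allele1("G", "T"), "G")
  # order-independent and vectorized
  expect_identical(allele1(c("G", "T"), c("A", "C")), c("A", "C"))
  expect_error(allele1("A", "A"), "monomorphic")
  expect_error(allele1("A", "N"), "non-ACGT")
})

write_ped_map <- function(ped_lines, map_lines, dir = withr::local_tempdir(
                            .local_envir = parent.frame())) {
  ped <- file.path(dir, "toy.ped"); map <- file.path(dir, "toy.map")
  writeLines(ped_lines, ped)
  writeLines(map_lines, map)
  list(ped = ped, map = map)
}

test_that("PED/MAP parsing codes genotypes as copies of allele 1", {
  f <- write_ped_map(
    c("famA ind1 0 0 1 1  A A  A G  T T",
      "famB ind2 0 0 2 2  G G  G G  G T"),
    c("1 snp1 0 1000", "1 snp2 0 2000", "1 snp3 0 3000"))
  ds <- read_genotypes(f$ped, f$map)
  expect_equal(dim(ds$geno), c(2L, 3L))
  expect_equal(sum(is.na(ds$geno)), 0L)
  # snp1 A/G: ind1 AA -> 2, ind2 GG -> 0; snp3 G/T: TT -> 0, GT -> 1
  expect_equal(unname(ds$geno[, "snp1"]), c(2L, 0L))
  expect_equal(unname(ds$geno[, "snp3"]), c(0L, 1L))
  expect_equal(ds$map$allele_a, c("A", "A", "G"))
  expect_equal(as.character(ds$samples$line), c("lean", "fat"))
})

test_that("a '0 0' allele pair becomes exactly one missing cell", {
  f <- write_ped_map(
    c("famA ind1 0 0 1 1  A A  0 0  T T",
      "famB ind2 0 0 2 2  G G  G G  G T"),
    c("1 snp1 0 1000", "1 snp2 0 2000", "1 snp3 0 3000"))
  ds <- read_genotypes(f$ped, f$map)
  expect_equal(sum(is.na(ds$geno)), 1L)
  expect_true(is.na(ds$geno["ind1", "snp2"]))
})

test_that("PED/MAP inconsistencies are format/data errors naming the culprit", {
  f <- write_ped_map(
    c("famA ind1 0 0 1 1  A A  A G  T T"),
    c("1 snp1 0 1000", "1 snp2 0 2000", "1 snp3 0 3000", "1 snp4 0 4000"))
  expect_error(read_genotypes(f$ped, f$map), "PED row 1.*4 SNPs")
  f2 <- write_ped_map(
    c("famA ind1 0 0 1 1  A A",
      "famB ind2 0 0 2 2  C G"),
    c("1 snp1 0 1000"))
  expect_error(read_genotypes(f2$ped, f2$map), "snp1.*more than 2")
})

test_that("genotype, phased and phenotype files round-trip losslessly", {
  set.seed(11)
  g <- matrix(sample(c(0:2, NA), 40, replace = TRUE), 8, 5)
  ds <- toy_dataset(g)
  dir <- withr::local_tempdir()
  paths <- list(ped = file.path(dir, "a.ped"), map = file.path(dir, "a.map"),
                smp = file.path(dir, "a.samples.tsv"))
  write_genotypes(ds, paths$ped, paths$map, paths$smp)
  back <- read_genotypes(paths$ped, paths$map, paths$smp)
  expect_equal(back$geno, ds$geno)
  expect_equal(back$map, ds$map)
  expect_equal(back$samples, ds$samples)

  ph <- toy_phased(lean = c("AAG", "AGG"), fat = c("GAG", "GGG"))
  pf <- file.path(dir, "ph.tsv")
  write_phased(ph, pf)
  ph2 <- read_phased(pf, ph$map)
  expect_equal(ph2$hap, ph$hap)
  expect_equal(as.character(ph2$info$line), as.character(ph$info$line))

  phen <- data.frame(id = c("i1", "i2"), AFW = c(30.1, 110.3),
                     AFP = c(1.23, 4.62), BW7 = c(2447, 2387), hatch = "1")
  ppf <- file.path(dir, "phen.tsv")
  write_phenotypes(phen, ppf)
  expect_equal(read_phenotypes(ppf), phen)
})

test_that("malformed phased/phenotype inputs raise data errors", {
  ph <- toy_phased(lean = c("AAG", "AGG"), fat = c("GAG", "GGG"))
  bad_hap <- ph$hap; bad_hap[1, 1] <- "T"   # T is not an allele of marker 1
  expect_error(phased_haps(bad_hap, ph$info, ph$map), "not one of its alleles")
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty.tsv")
  writeLines("individual_id\thap_index\tline\ts001", empty)
  expect_error(read_phased(empty, ph$map[1, , drop = FALSE]), "empty")
  inc <- file.path(dir, "inc.tsv")
  writeLines(c("id\tAFW\tAFP\tBW7", "i1\t30\t9.9\t2400"), inc)
  expect_warning(read_phenotypes(inc), "inconsistent")
})

test_that("QC removes low-MAF SNPs, low call rates and high-missingness individuals", {
  set.seed(2)
  n <- 50
  g_ok <- matrix(rbinom(n * 98, 2, 0.4), n, 98)            # healthy SNPs
  g_raremaf <- integer(n)                                  # 4 copies -> MAF 0.04
  g_raremaf[1:2] <- 1L
  g_lowcall <- rbinom(n, 2, 0.5); g_lowcall[2:5] <- NA     # call rate 0.92
  g <- cbind(g_ok, g_raremaf, g_lowcall)
  g[1, ] <- NA                                             # individual 1: 100% missing
  ds <- toy_dataset(g)
  out <- apply_qc(ds)
  expect_equal(nrow(out$geno), n - 1L)
  expect_equal(ncol(out$geno), 98L)
  rep <- attr(out, "qc_report")
  expect_equal(rep$removed[rep$criterion == "individual_missingness"], 1)
  # idempotent
  out2 <- apply_qc(out)
  expect_equal(out2$geno, out$geno)
  expect_equal(out2$map, out$map)
})

test_that("QC leaves a clean dataset unchanged and errors on empty results", {
  set.seed(3)
  g <- matrix(rbinom(200, 2, 0.5), 20, 10)
  ds <- toy_dataset(g)
  out <- apply_qc(ds)
  expect_equal(out$geno, ds$geno)
  mono <- toy_dataset(matrix(2L, 10, 3))
  expect_error(apply_qc(mono), "all SNPs")
})

test_that("an individual with 6% missing genotypes is removed at the 5% rule", {
  set.seed(4)
  g <- matrix(rbinom(50 * 100, 2, 0.5), 50, 100)
  g[1, 1:6] <- NA                                          # 6% missing
  g[2, 1:4] <- NA                                          # 4% missing: kept
  ds <- toy_dataset(g)
  out <- apply_qc(ds)
  expect_false("i001" %in% out$samples$id)
  expect_true("i002" %in% out$samples$id)
})

test_that("hemizygous Z coding halves female allele copies", {
  # 4 lean individuals: 2 males coded 2, 2 females coded 2 (single Z copy)
  g <- matrix(c(2L, 2L, 2L, 0L), 4, 1)
  map <- data.frame(id = "zs1", chrom = "Z", pos_bp = 100,
                    allele_a = "A", allele_b = "G")
  smp <- data.frame(id = paste0("i", 1:4), line = "lean", family = "f",
                    sex = c("male", "male", "female", "female"), hatch = "1")
  ds <- geno_dataset(g, map, smp)
  expect_equal(line_allele_freq(ds, "lean"), 6 / 8)
  # hemizygous: males 2+2 copies of 4, females 1 and 0 of 1 each -> 5/6
  expect_equal(line_allele_freq(ds, "lean", z_hemizygous = TRUE), 5 / 6)
})
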