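---
title: "Scanning divergently selected line pairs for selection signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning divergently selected line pairs for selection signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

divsig implements the multi-signal selection-signature analysis used to map
loci under divergent artificial selection in paired lines — the design behind
the NEAUHLF broiler experiment, where two lines bred from one grandsire
population were selected up and down for abdominal fat content over 11
generations. This vignette is the package's methods account: the statistics,
the thresholds and their rationale, the simulator that stands in for the
unreleased study data, and the numerical conventions.

## The screening statistics

For two lines ("lean" and "fat") genotyped at biallelic SNPs, every statistic
is built on the per-line frequency of **allele 1**, the alphabetically prior
base of each SNP's pair (`A` before `C/G/T`, `C` before `G/T`, `G` before
`T`; `allele1()`). Coding genotypes as copies of allele 1 — rather than of
the minor allele — keeps the sign of between-line comparisons stable.

Per SNP, with `p_lean` and `p_fat` the allele-1 frequencies:

* allele frequency difference: `AFD = |p_lean - p_fat|`;
* expected heterozygosity per line: `het = 2 p (1 - p)`.

These are averaged, unweighted, over the SNPs of 0.5 Mb sliding windows
(`scan_windows()`), and the window means are standardized within each
chromosome: `Z_AFD` by the chromosome's mean and sample standard deviation of
window AFD, and `Z_lean`/`Z_fat` by each line's own chromosome-wise mean and
standard deviation. Within-line standardization is deliberately conservative
compared with pooling the two lines. Chromosomes with fewer than two windows,
or zero spread, are marked non-assessable (`NA`), never silently zero.

A window is called (`call_signatures()`) when any signal fires:

| signal | rule | default |
|---|---|---|
| AFD | `afd_mean >= t` | 0.44 |
| Z_AFD | `z_afd >= t` (one-sided; AFD is non-negative) | 4.0 |
| Z_lean / Z_fat | `|z| >= t`, both signs | 5.0 |

The thresholds are the operating point of the original genome scan.
Heterozygosity *increases* count as signals too: a line that starts from
extreme allele frequencies can gain heterozygosity under selection. The
deeper reason for carrying AFD alongside heterozygosity is the **p-q sweep**:
if selection reverses a locus's frequencies (`p_t = q_0`, `q_t = p_0`),
expected heterozygosity `2pq` is exactly unchanged and any het-based scan is
blind, while the between-line AFD is `|p_0 - q_0|`. The package constructs
this case exactly (`pq_sweep_scenario()`), and its acceptance test verifies
that the scan flags the region through AFD with no heterozygosity signal.

Overlapping flagged windows merge into one signature region. When exactly one
line shows a heterozygosity *decrease*, that line is inferred as the selected
one; the pipeline refines ties using the lower standardized heterozygosity
and then the larger line-level EHH area.

## Corroboration: LD, blocks, haplotypes, EHH

Flagged regions are corroborated, per line, from phased haplotypes (phasing
itself is out of scope; the package reads a phased table, and its simulator
emits truly phased data):

* **Pairwise LD** (`ld_pairs()`): `D`, `D' = |D|/Dmax`, `r2`, computed from
  two-locus haplotype counts.
* **D' confidence intervals** (`dprime_ci()`): the multinomial likelihood of
  the four haplotype counts is evaluated on a 101-point grid of `D'` in
  `[0, 1]` with allele frequencies fixed at their observed margins and the
  sign of D at its observed direction. After normalization, the lower bound
  is the smallest grid value with at least 5% of the mass at or below it,
  the upper bound the largest with at least 5% at or above. Conventions for
  this interval vary between implementations; the inclusive form used here
  makes a large sample in complete LD report a CI of essentially (1, 1).
  Both the grid and the tail mass are arguments. On a discrete grid the
  interval can sit up to a step or two away from the continuous point
  estimate; the tests assert bracketing within that resolution.
* **Gabriel blocks** (`gabriel_blocks()`): pairs are classed strong LD
  (`low >= 0.70`, `high >= 0.98`) or strong recombination (`high < 0.90`);
  a span of contiguous markers is a candidate block when at least 95% of its
  informative pairs are strong, and maximal non-overlapping blocks are taken
  greedily by size. A `"haploview"` preset adds approximate size-stratified
  lower-bound cutoffs for 2-4-marker spans (0.81/0.78/0.74), because the
  original study found the tool's default blocks differed from the manually
  drawn ones — both behaviours must be expressible. The plain rule is the
  default.
* **Haplotype tables** (`block_haplotype_freqs()`, `hap_table_wide()`,
  `classify_line_specific()`): per-line haplotype frequencies within a
  block, and labels `lean-specific` / `fat-specific` / `shared` / `minor`.
  The specificity thresholds (main frequency at least 0.40, at most 0.02 in
  the other line) are editorial: they are what "virtually line-specific"
  means operationally for the published Z-region table, and they are
  arguments, not constants. `find_recombinants()` identifies two-block
  haplotypes assembled from one parent's first block and the other's second.
  Rows with missing bases are dropped and counted, never imputed.
* **EHH** (`ehh_decay()`): for each core haplotype with at least 5 carriers
  (fewer make the curve meaningless), EHH at marker `x` is the probability
  that two random carriers are identical from the core boundary out to `x`,
  `sum(e_h (e_h - 1)) / (n (n - 1))`; curves extend in both directions until
  EHH < 0.05. Distances are physical (bp), as in the study's figures; no
  genetic map is assumed. Per-haplotype EHH is blind to haplotype
  *frequency*, so between-line comparisons use `line_ehh_area()`: the
  count-weighted integral, i.e. the probability that two random haplotypes
  of the line remain identical to distance x, integrated over x. A swept
  line keeps one high-frequency long haplotype and scores high.

## Association testing

`assoc_scan()` implements the two-step GLS-LS single-SNP test under
`Y = SNP + f + e`, with `f` a random half-sib family effect:

1. `adjust_phenotypes()` estimates the family variance component by the
   one-way ANOVA moment estimator truncated at zero (REML via `lme4` as an
   option), fits fixed non-genetic covariates (hatch, by default, the only
   one the design names) by GLS under the implied compound-symmetry
   covariance, and subtracts them.
2. `snp_tests()` tests each SNP for an additive contrast (trend over codes
   0/1/2) and a dominance contrast (heterozygote deviation) by whitened
   least squares, giving two 1-df tests per SNP — matching a correction for
   2 effects x 2 traits. A fixed-family variant (family indicator columns)
   is the secondary method.

When the family variance estimate is zero the GLS step collapses to ordinary
least squares (logged). The genome-wide threshold is
`bonferroni_threshold(0.05, n_snps, 2, 2)`; at the published scan size of
45,578 SNPs this is 2.74e-7. Monomorphic SNPs are skipped with a reason;
dominance is skipped only when there are no heterozygotes. Tests require two
genotype classes with at least 3 observations.

## The synthetic cohort

`sim_config()` / `simulate_founders()` / `evolve_divergent()` emulate the
breeding design so that every stage is exercisable without the study's
(undeposited) genotypes: one base population split into two lines; per line
and generation, 25 sires each mated to 4 dams (25 half-sib families), 3
offspring per dam; phenotypes are QTL genotype effects plus normal noise,
with the environmental variance fixed once from the configured heritability
(0.5) at founder frequencies; truncation selection takes the best 25 males
and 100 females (downward in the lean line, upward in the fat line; `"none"`
gives random parents); meiosis places Poisson crossovers at 3 cM/Mb, the
chicken genome-wide average, uniformly along the chromosome.

The default genome is scaled down to 5 chromosomes x 400 markers at ~22.5 kb
spacing (a 60k-chip-like density) so that 100-replicate checks stay
desk-sized; the full-size design differs only in marker count. Founder
haplotypes are drawn from a finite pool of 20 haplotypes per chromosome,
built as segmental mosaics of 3 ancestral haplotypes with ~2 Mb segments.
The mosaic structure is the load-bearing choice: a recently bottlenecked
commercial line carries few distinct haplotypes in any one interval, which
is what produces the adjacent-marker r-squared of roughly 0.25-0.3 that 60k
chip data show in these lines, and what lets a sweep drag a whole window of
hitchhikers (the published swept region had essentially two opposite
haplotypes across 0.73 Mb). Setting `n_ancestral = Inf` removes the local
structure (marker-independent pool draws) for neutral-LD checks. Ancestral
allele-1 frequencies are uniform on (0.15, 0.85), mimicking chip
ascertainment against rare variants. QTL alleles follow the ancestral
structure (the carrier subset of ancestors is chosen to put the pool
frequency as close to 0.5 as possible) — planting the QTL in linkage
equilibrium with its neighbours would silently remove hitchhiking, which is
the phenomenon under test.

What the simulator does **not** emulate: Z-linked inheritance (all simulated
chromosomes are autosomal; hemizygous Z dosage is supported on the analysis
side via `snp_stats(z_hemizygous = TRUE)`); family-based sib selection on
VLDL plus AFP (plain individual truncation is used); variable recombination
rates between macro- and micro-chromosomes; genotyping error and missing
data (QC paths are tested on constructed datasets instead); and the study's
~70-offspring G1 families. Passing tests on this cohort therefore show that
the statistics and pipeline behave correctly under a realistic bottleneck +
truncation-selection model, not that the study's exact numbers are
recovered — its genome-wide tables depend on the unreleased genotypes.

Per-generation sexes alternate within family, so every litter can supply the
required parents deterministically; ties in truncation ranking are broken by
a seeded random draw. Identical seeds give byte-identical outputs.

## Numerical conventions and edge cases

* Coordinates are 1-based; windows are half-open `[start, start + size)`,
  anchored at the first marker position rounded down to a step multiple.
  Window size 0.5 Mb is the study's; the step (250 kb, half-overlap) is this
  package's choice — the study does not state one, and flagged peaks are
  often sub-window-sized. Windows with fewer than 3 SNPs are dropped.
* Sample (n-1) standard deviations throughout.
* MAF for QC uses the combined two-line sample (`apply_qc()`), so markers
  swept to opposite fixation are retained; the individual-missingness filter
  runs before the final SNP filter so bad individuals cannot deflate call
  rates. The order is a package decision; the study does not state one.
* Monomorphic loci make LD undefined: flagged, excluded from means and
  block rules, never coerced to zero.
* All individuals are treated as diploid at Z markers by default (the
  study's measured birds were male, hence ZZ); the hemizygous option halves
  female allele copies and treats female heterozygote calls as missing.
* The association flank for "most significant SNP near a signature" is
  region plus/minus 250 kb; the study pairs signatures with nearby top SNPs
  without stating a rule.
* Reported percentages of markers above thresholds are ambiguous in unit
  (markers vs windows) in the source; the scan reports window counts and a
  flagged-window rate and does not attempt to match those percentages.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` size their computations to run on
one CPU in minutes: the permutation-null calibration uses 10,000 additive
tests (5 x 2,000 SNPs at n = 400) in the suite and 4,000 in the script;
power uses 200 and 50 replicates respectively; QTL detection uses 100
replicates of the default 5 x 400-marker genome in the suite and 20 in the
script; the EHH contrast uses 25 and 10 single-line-sweep replicates. These
sizes are the package's choices for replicated checks of a scaled-down
genome; the statistics themselves have no size limits.

## Known limitations

* The D' CI and Gabriel-rule implementation is a faithful re-derivation of
  the published procedure, not a port of any specific tool; block boundaries
  can differ from other implementations at their documented default
  settings (hence the configurable preset).
* `gabriel_blocks()` enumerates candidate spans in O(m^3); apply it to
  regions (as the pipeline does), not whole chromosomes with thousands of
  markers.
* The moment estimator of the family variance can be noticeably noisier
  than REML for very unbalanced families; use `method = "reml"` there.
* Haplotype frequencies are empirical counts; published tables produced by
  model-based phasing can contain frequencies finer than one haplotype
  count, which an empirical table cannot reproduce.
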