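---
title: "Partitioning feed-efficiency traits into host-genetic, microbiome and interaction components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning feed-efficiency traits into host-genetic, microbiome and interaction components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`hologen` analyses quantitative traits — the motivating application is feed
efficiency in commercial pigs (average daily gain ADG, average daily feed
intake ADFI, feed conversion ratio FCR = ADFI/ADG, and residual feed intake
RFI) — under a three-random-effect linear mixed model

$$y = \mathbf{1}\mu + Kc + g + m + a + e,$$

where $g \sim N(0, G\sigma_g^2)$ is the host-genetic effect with $G$ the
genomic relationship matrix (GRM), $m \sim N(0, M\sigma_m^2)$ the gut
microbiome effect with $M$ a log-standardised microbial relationship matrix
(MRM), $a \sim N(0, A\sigma_a^2)$ the genotype-by-microbiome interaction
with $A = G \circ M$ (Hadamard product), and $e \sim N(0, I\sigma_e^2)$.
Every animal contributes one record, so all incidence matrices are the
identity. $Kc$ carries the fixed covariates: sex (2 levels), pen (2
levels), onset body weight and the first three genetic principal
components.

The quantities of interest are variance ratios against
$\sigma_p^2 = \sigma_g^2 + \sigma_m^2 + \sigma_a^2 + \sigma_e^2$:
heritability $h^2 = \sigma_g^2/\sigma_p^2$, microbiability
$m^2 = \sigma_m^2/\sigma_p^2$, and the interaction fraction
$\sigma_a^2/\sigma_p^2$.

### Kernels

* **GRM** (`compute_grm()`): VanRaden-style,
  $g_{ij} = \frac{1}{N}\sum_v (x_{iv}-2\bar p_v)(x_{jv}-2\bar p_v) /
  (2\bar p_v(1-\bar p_v))$, computed on the post-QC, mean-imputed panel.
  Monomorphic SNPs must be filtered upstream (`qc_genotypes()`, thresholds
  SNP call rate > 0.95, MAF > 0.01, individual call rate > 0.95, applied in
  that order — the order is a package choice since only the thresholds are
  conventionally reported).
* **MRM** (`compute_mrm()`): a pseudo-value of 1 is added to each relative
  abundance, the natural log is taken, columns are standardised to mean 0
  and sample SD 1 ($n-1$ denominator), and $M = XX^\top/p$ with $p$ the
  number of retained taxa. Two consequences are worth knowing: the log base
  is irrelevant (standardisation absorbs it), and
  $\mathrm{tr}(M)/n = (n-1)/n$ holds exactly — the test suite asserts this
  identity. The "+1" is read literally as a pseudo-value on relative
  abundances; a `pseudo_on = "counts"` option exists for tables that arrive
  as counts (same arithmetic). Taxa constant across samples carry no
  information and are dropped with a warning.
* **Interaction** (`compute_interaction_kernel()`): the unnormalised
  elementwise product, PSD by the Schur product theorem. A
  trace-normalisation flag exists but is off by default, matching the usual
  construction of interaction kernels.

### REML

`fit_reml()` maximises the restricted likelihood with non-negativity
constraints. One kernel: the profiled likelihood is maximised exactly in
the variance ratio through a single eigendecomposition (a coarse pre-scan
guards against the rare non-unimodal profile). Two or three kernels:
average-information updates, an EM first step, step-halving, and an
active-set rule that pins components at the zero boundary while their
gradient points outward. Convergence is declared when successive restricted
log-likelihoods differ by less than 1e-8 (200-iteration cap; a
non-converged fit is returned flagged). Initialisation splits the
phenotypic variance equally across components — a neutral start.
Components are floored at $10^{-6}\hat\sigma_p^2$, which is what a "zero"
estimate looks like in the output.

Per-component significance uses the likelihood-ratio statistic against the
model with that kernel removed, referred to a 50:50 mixture of a point
mass at zero and $\chi^2_1$ — the standard reference for a variance
component tested on its boundary (the source publications do not name
their test; this is the package's choice). A statistic of 2.706 gives
p = 0.05, and the p-value never exceeds 0.5.

### Microbial traits, GWAS, and taxon association

Taxa are classified by detection rate: above 60% quantitative (encoded as
standardised log(abundance + 1)), 30–60% inclusive binary (0/1 presence),
below 30% excluded. Both boundary rates land in the binary class because
the quantitative rule is strict ("greater than 60%") while the binary range
is inclusive. Binary traits are analysed on the observed scale with the
linear model — no liability transformation, since none is conventionally
specified for this screen.

`run_lmm_gwas()` tests each SNP in the polygenic mixed model. The default
two-step mode estimates the background variance components once on the
null model and then applies per-SNP generalised least squares under that
fixed covariance (the EMMAX/P3D approximation); an exact mode re-maximises
the restricted likelihood per SNP. On cohorts of unrelated individuals the
background ratio is weakly identified, so per-SNP re-estimation moves the
extreme tail of $-\log_{10} p$ by up to ~0.15 at n = 200 while the median
concordance is ~0.001; the two-step mode is the default and the
discrepancy is bounded by a test. The tested SNP is not removed from the
background kernel (no leave-one-chromosome-out; a `loco` design was judged
out of scope because the reference analysis used a single global GRM).

The genome-wide threshold is the empirical FDR rule
$P = 0.01 \times n/i$ with $n$ the number of SNPs at p < 0.01 and $i$ the
number tested. Note this is a single fixed threshold, not a
Benjamini–Hochberg step-up; `stats::p.adjust` remains available for
comparison.

Taxon–phenotype association combines four screens on taxa detected in
more than 30% of samples: a two-part (hurdle) model — phenotype on
presence over all samples, and on standardised log abundance over present
samples only; extreme-group ANOVA (top vs bottom `floor(n * 0.10)` by
abundance — 36 animals per tail at n = 361); an extreme-group Wilcoxon
rank-sum on abundance between phenotype-ranked tails (exact null for
combined n ≤ 20 without ties, tie-corrected normal approximation
otherwise); and a Pearson screen gated at |r| > 0.1 and p < 0.05. The
consensus rule adjusts p-values per test family per trait
(Benjamini–Hochberg — the field default where the adjustment method is
unstated, configurable) and flags a pair only when all three adjusted
p-values fall below 0.05. The two-part p entering the consensus is the
minimum of the available part p-values; this is anti-conservative as a
standalone test but is only ever used inside the three-way intersection.
Ties at an extreme-group cutoff are broken by stable sample order, making
the groups deterministic.

## The synthetic cohort

Because the motivating study's data are not deposited, every stage is
verified by parameter recovery on synthetic data (`sim_config()`,
`simulate_dataset()`). The generator emulates the published cohort:

* **Genotypes** — independent biallelic SNPs, two Hardy–Weinberg draws at
  a MAF uniform on (0.05, 0.5); defaults n = 361, s = 43,580 (the post-QC
  panel size). No linkage disequilibrium and no family structure: this is
  the stated simulation model, and it matters for interpretation (below).
* **Microbiome** — latent per-taxon log-abundances = taxon baseline
  (SD 1.5 across taxa, giving a realistically skewed composition) +
  optional host-genetic value (causal SNPs rescaled to a target taxon
  heritability) + three shared community gradients carrying 25% of the
  latent variance + independent noise. Zero-inflation is applied by
  ranking: the lowest latent values are zeroed until each taxon hits its
  target detection rate exactly (up to rounding), removing a nuisance
  source of test flakiness that independent Bernoulli thinning would add.
  Rows are renormalised to sum to 1. Default: 205 taxa with detection
  rates gridded from 0.10 to 0.98, spanning the excluded/binary/
  quantitative classes.
* **Phenotypes** — drawn from the three-kernel model via eigen square
  roots (negative eigenvalues below $-10^{-8}\lambda_{max}$ are an error;
  smaller ones are clipped to zero, which rank-deficient MRMs need).
  Default variance fractions are the published RFI partition
  (0.2007/0.0304/0.5087) with $\sigma_p^2 = 0.0256$ (the squared
  phenotypic SD of RFI). Sex and pen are balanced, crossed two-level
  factors with default effects of 0.25 phenotypic SD; onset body weight is
  N(30, 2.5²) kg with a default slope of 0.05 SD/kg. Balanced assignment
  is an assumption — the study does not report the actual design.

**Why the community gradients are not optional décor.** With independent
taxa the MRM converges to $I + O(1/\sqrt{t})$ noise, and the interaction
kernel $G \circ M$ collapses towards the identity — at which point
$\sigma_a^2$ and $\sigma_e^2$ are unidentifiable at *any* sample size.
Real fecal communities co-vary along a few dominant gradients
(enterotype-like structure; the leading ordination axes of 16S surveys
typically carry 10–30% of the variance), and it is exactly this structure,
together with the heterogeneous MRM diagonal produced by zero-inflation,
that makes the three-way partition estimable. The parameters (3 gradients,
25%) were fixed on that reasoning and not revisited.

**What a green recovery test does and does not establish.** It shows the
estimation machinery is correct and approximately unbiased under the
generative model this kind of analysis assumes. It does not certify the
published point estimates: with *unrelated* simulated genotypes the
per-replicate SD of $\hat h^2$ at n = 400 / s = 5000 is ≈ 0.24 (the real
cohort, 361 pigs from one farm, surely contains close relatives, which
identifies $h^2$ far more sharply), estimates pile up on the zero
boundary in a sizeable minority of replicates, and compositional artefacts
of real 16S data (sequencing depth, taxonomic misassignment) are not
modelled. Recovery is therefore judged on replicate means: 50-replicate
means land within ±0.05 of two-kernel truths and ±0.07 of three-kernel
truths, with a small inward bias on the interaction fraction (the
diag-heavy interaction kernel leaks variance into the residual) that sits
comfortably inside those bands.

## Numerical and design choices

* Onset body weight enters as a continuous covariate. The reference
  analysis coded it as an 81-level factor, which at n = 361 would spend a
  quarter of the degrees of freedom; a divergence, made deliberately.
* RFI is the residual of ADFI regressed on onset weight and ADG with an
  intercept, so it is zero-mean by construction. The study's summary table
  reports mean RFI = 0.36, which cannot be a within-cohort OLS residual —
  possibly an external baseline; the package documents the zero-mean
  convention and does not reproduce that mean. Published CVs also disagree
  with their own rounded mean/SD at the second decimal; treated as
  rounding.
* Phenotype QC excludes values beyond mean ± 3 SD per trait, applied after
  trait derivation; with SD = 0 everything is retained. The rule is weak
  at small n — at n = 5 a 100-vs-1 outlier survives — and the tests
  document this rather than hide it.
* The Shapiro–Wilk normality check is advisory only (reported, never acted
  on).
* Seeds: each generator stage uses `config$seed` plus a small fixed offset
  (genotypes +0, microbiome +1, phenotypes +2), so a config is one
  reproducible world and stages remain individually re-runnable.
* CLI configs are JSON rather than YAML (no YAML parser is assumed on the
  target systems).

## Known limitations

* No LD, no family structure, no sequencing-depth model in the generator;
  heritability of simulated taxa refers to the latent log scale, and
  compositional renormalisation attenuates it on the observed scale.
* The two-part consensus p is a minimum over parts (see above).
* Binary microbial traits use a linear model on the 0/1 scale.
* `run_mbgwas()` emits positions only; candidate-gene annotation is out of
  scope.

## A worked example

```{r, eval = FALSE}
library(hologen)

cfg <- sim_config(n_individuals = 400, n_snps = 5000, n_taxa = 500,
                  variance_fractions = c(genetic = 0.3692,
                                         microbiome = 0.1154,
                                         interaction = 0),
                  seed = 42)
ds <- simulate_dataset(cfg)
covs <- make_covariates(ds$pheno, c("sex", "pen", "onbw"),
                        pcs = compute_pcs(ds$G, 3))
variance_partition(ds$pheno$y, covs,
                   list(genetic = ds$G, microbiome = ds$M))
```

The README shows this run with its actual printed output.
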