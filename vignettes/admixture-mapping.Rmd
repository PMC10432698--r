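---
title: "Admixture mapping in three-way admixed cohorts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Admixture mapping in three-way admixed cohorts: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Recently admixed populations — here, a Dominican community with European
(EUR), African (AFR) and Native American (NAT) continental ancestry —
carry long haplotype segments of distinct ancestral origin. When a disease
risk allele is much more frequent on one ancestral background, the local
ancestry (LA) at its locus becomes a proxy for carrying it, and a
case-control scan of LA dosage (0/1/2 copies of a given ancestry per
individual per locus) can detect risk loci that a conventional GWAS in the
same sample misses. `admixscan` implements that workflow end to end:
cohort simulation, LA summaries and QC, the dosage scan, a genome-wide
significance threshold derived from the correlation structure of local
ancestry, conditional fine-mapping to tag SNPs, and the surrounding
case-control epidemiology.

# The generative model

All statistical machinery rests on the single-pulse ("hybrid isolation")
admixture model. Each haplotype is a Markov chain along the genetic map:
ancestry switch points arrive as a Poisson process with rate $g$ per
Morgan ($g$ = generations since admixture) and the ancestry after each
switch is drawn independently from the admixture proportions
$q = (q_{EUR}, q_{AFR}, q_{NAT})$, with self-transitions collapsed. Three
standard consequences, each verified by a property test:

* tract lengths of ancestry $k$ are exponential with mean
  $1/((1-q_k)\,g)$ Morgans;
* the marginal ancestry at any locus is $q$ (stationarity);
* the correlation of LA dosage between loci at genetic distance $d$
  Morgans decays as $e^{-g d}$.

The defaults in `admixture_config()` are the study conditions the package
emulates: $n = 1813$ individuals, $q = (0.56, 0.37, 0.06)$ (the printed
medians; they sum to 0.99 from rounding and are renormalised), and
$g = 9.73$. The default genetic map has the 22 autosomes at realistic
sex-averaged lengths (~3,545 cM total) with loci every 0.2 cM, matching
LA calls pruned to one locus per RFMix window.

Genotypes are simulated conditionally on LA: each haploid allele is
Bernoulli with the ancestry-specific frequency at that haplotype's tract,
so a variant can be common on NAT tracts (e.g. 27%) and essentially
absent elsewhere (0.1%) — the architecture inferred for the reported 2q35
signal. Case status is Bernoulli-logistic; the default intercept
$\mathrm{logit}(0.135)$ reproduces the study's non-carrier anchor
prevalence, giving roughly 245 cases in 1,813. What the generator does
*not* emulate: within-ancestry linkage disequilibrium (variants are
independent given LA), genotyping error, relatedness, phasing error in
LA calls, and sex-specific maps. Passing tests therefore demonstrate the
statistical machinery under the pulse-admixture model, not robustness to
those real-data artefacts.

# The scan

Each locus and ancestry is tested with the maximum-likelihood logistic
model `status ~ LA dosage + sex + array`, Wald inference (`z = beta/se`,
two-sided normal p), exactly the printed model formula; covariates are
configurable (`scan_config()`), with global-ancestry adjustment available
as an ordinary phenotype column. The per-locus fits run in compiled code
(IRLS warm-started at the covariate-only fit, convergence `1e-8` on the
coefficient step); a test asserts agreement with `stats::glm` per locus.
Loci with fewer than 10 minor-side dosage carriers, or with perfect
separation, are skipped with machine-readable reasons rather than fitted
unstably — no Firth correction is attempted. With a single binary
predictor the fit reproduces the 2x2 closed form
($\beta = \log(ad/bc)$, $se = \sqrt{1/a+1/b+1/c+1/d}$) to six decimals.

A practical note on resolution: adjacent loci 0.2 cM apart have dosage
correlation $e^{-9.73 \times 0.002} \approx 0.98$, so the test statistics
of neighbouring loci are near-clones and the top hit localises a signal
only to its ancestry-tract neighbourhood (a few cM), not to an exact
locus. The power experiments score localisation within ±3 cM accordingly.

# The significance threshold

LA dosages are long-range correlated, so Bonferroni over ~17,700 pruned
loci x 3 ancestries would be far too strict. The family-wise threshold is
obtained by simulating the joint null of the scan statistics as a
stationary Gaussian process:

* along the map, each ancestry's statistic is an AR(1) sequence with
  coefficient $e^{-g\,\Delta d}$ between adjacent pruned loci (exact for
  Markov decay; chromosomes independent);
* across ancestries at a locus, the correlation follows the multinomial
  covariance of dosages,
  $\mathrm{corr}_{jk} = -\sqrt{q_j q_k / ((1-q_j)(1-q_k))}$ (the
  correlation matrix is singular because dosages sum to 2; its
  eigendecomposition is used with negative eigenvalues clipped at zero).

Per replicate the genome-wide maximum of $z^2$ is recorded; the cutoff is
the $\chi^2_1$ upper-tail probability of the 95th percentile of 10,000
maxima, with a Monte-Carlo CI from binomial bounds on the order statistic.
$g$ itself is estimated from the data by weighted least squares on the
binned dosage-correlation decay $\mathrm{corr}(d) = e^{-gd}$ (weights =
pair counts, pooled over ancestries, pairs within 20 cM); on noiseless
input the 1-D minimisation recovers $g$ to four decimals, and on simulated
cohorts at the study scale the estimate lands within ±0.5 of the truth.

Two limiting checks pin the simulator down: with one locus and two
ancestries the maxima are exactly $\chi^2_1$ (the two statistics are
perfectly anticorrelated), and as $g \to \infty$ the cutoff converges to
the Sidak value $1 - 0.95^{1/L}$. With the study's parameters the
computed cutoff is ~4x10^-6, the same order as the published 5.282x10^-6;
the residual gap reflects that the external implementation used by the
study is reconstructed here from its described inputs, not called.

# Conditional fine-mapping

Given a peak LA dosage and genotypes in a window (default 5 Mb), each
candidate SNP is added to `status ~ LA + SNP + tags + covariates` and the
SNP that most attenuates the LA term (largest conditional LA p) is
selected; the loop repeats with selected tags as covariates until the LA
p exceeds `p_stop` (default 0.05; the study's "fully attenuated" endpoint
of 0.4 is a configuration away) or `max_tags` is reached.

The acceptance rule for a tag is a genuine design choice. Adding *any*
covariate perturbs the LA p, and with 15+ candidates the largest
perturbation is always upward, so "conditional p exceeded the
unconditional p" cannot distinguish tagging from jitter. A tag is
therefore accepted only if it absorbs at least a fixed share (default
20%) of the current LA Wald chi-square. Empirically, ancestry-balanced
null SNPs absorb at most ~5% by chance while a planted causal SNP absorbs
over 60% even in weak cohorts, so the rule separates the two regimes
cleanly; a window with no causal variant returns an empty tag list with a
diagnostic.

Tract-stratified allele frequencies (`tract_frequency()`) use phased
haploid alleles when available (simulated data) and otherwise fall back
to ancestry-homozygous individuals, whose allele counts are unambiguous;
the fallback is labelled in the output.

# Epidemiology

Biomarkers are cleaned exactly as described for the source biobank:
sentinel entries (999999) dropped, per-individual medians over
encounters, log10 transform, Tukey fences (quartiles by linear
interpolation — fence membership can flip under other quantile
definitions, hence the explicit choice; boundary ties kept) per
sex-by-group stratum, then per-stratum z-scores. Zero-IQR strata remove
nothing and get z = 0; strata with fewer than 4 retained values get
suppressed z-scores and a flag. Prevalence tables render to one decimal
percent with chi-squared tests for discrete and Mann-Whitney for
continuous variables; the three nested risk models (1: group + age + sex;
2: + BMI; 3: + T2D + TG + TC + HDL) are fitted pairwise against the
reference group, matching the described "tested separately relative to"
design, with monotone log-likelihood across the nesting asserted by a
test. Smoking is excluded from the models (excess missingness in the
source data).

# Numerical choices and problem sizes

* Distances are carried in cM and converted to Morgans only inside the
  math; physical positions are 1-based (VCF convention).
* Seeds: one master seed per stage, sub-streams derived
  deterministically; identical seed + config gives bit-identical output.
* The test suite runs its stochastic recovery experiments on reduced maps
  (two autosomes of 75-150 cM) at the full cohort size n = 1,813:
  g-recovery over 50 cohorts, scan calibration over 500 phenotype
  permutations against a threshold computed for the same map, planted-
  locus power over 20 cohorts, and fine-mapping over 50 cohorts with a
  detectable peak (plus 30 two-SNP cohorts). The full-map threshold runs
  at the study's published configuration (10,000 replicates, ~17,700
  loci).
* Fine-mapping experiments condition on a detectable peak (LA p < 0.05 at
  the planted locus) because fine-mapping presupposes a signal; about 60%
  of cohorts qualify at these effect sizes. With two planted SNPs, one
  SNP sometimes absorbs the whole LA signal, leaving the second
  unrecoverable in ~30% of cohorts — the two-tag experiment therefore
  forces a second windowed round (as the study did) and expects a
  majority, not near-certain, recovery.

# Known limitations

* The threshold reconstructs the joint-null simulation from its described
  inputs; agreement with the published cutoff is to scale (factor ~2),
  not to printed precision.
* The Wald-based scan is anti-conservative for very sparse dosage classes;
  the minimum-carrier rule is the guard, and skipped loci are reported,
  not imputed.
* `read_msp` supports the RFMix v2 `.msp.tsv` dialect only; v1 Viterbi
  output is out of scope (the internal matrix constructor is the
  fallback).
* Autosomes only; the X chromosome is excluded throughout.
* Real cohort-level results (e.g. the published odds ratios at 2q35)
  require the original individual-level data and are represented here by
  the recovery experiments and format anchors, not reproduced.
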