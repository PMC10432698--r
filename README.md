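# admixscan

Admixture mapping of disease risk in recently admixed populations — built
around the case of peripheral artery disease (PAD) in a three-way admixed
(European/African/Native American) Dominican community cohort.

In an admixed genome, a risk allele that is common on one ancestral
background and rare on the others makes local ancestry (LA) at its locus a
proxy for carrying it. The package scans additive LA dosages (0/1/2
haplotypes of a given ancestry per individual per locus) for case-control
association, computes the genome-wide significance threshold implied by
the correlation structure of local ancestry, and fine-maps significant
peaks to tag SNPs by conditional attenuation. It is aimed at statistical
geneticists working with RFMix-style local-ancestry calls, and at anyone
who wants a fully simulated, testable stand-in for such a cohort.

## What it computes

* **Scan.** At each locus and for each ancestry `k`, the logistic model
  `PAD ~ LA_k + sex + array` with Wald inference; per-SNP GWAS with MAF
  filtering; inverse-variance fixed-effect meta-analysis across arrays;
  carrier-prevalence tables.
* **Threshold.** LA dosage correlation decays with genetic distance `d`
  (Morgans) as `exp(-g d)`, where `g` is the number of generations since
  the admixture pulse; `g` is estimated by weighted least squares on the
  observed decay. The family-wise 5% cutoff comes from 10,000 simulated
  genome-wide maxima of a Gaussian process with that along-map decay and
  cross-ancestry correlation `-sqrt(q_j q_k/((1-q_j)(1-q_k)))` from the
  multinomial covariance of dosages.
* **Fine-mapping.** Iterative windowed conditional regressions
  `PAD ~ LA + SNP + selected tags + covariates`; the SNP that absorbs the
  largest share of the LA Wald chi-square becomes the next tag, until the
  LA term is attenuated past the stop rule.
* **Cohort simulation.** Pulse-admixture tracts (Poisson(g) switches per
  Morgan, ancestries drawn from proportions `q`), ancestry-stratified
  allele frequencies, and logistic phenotypes — the study conditions
  (n = 1,813, q = 0.56/0.37/0.06, g = 9.73, ~245 cases) are the defaults.
* **Epidemiology.** Biomarker cleaning (log10 Tukey fences per
  sex-by-group stratum, z-scores), prevalence tables, and the three
  nested group-risk logistic models.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
simulated Dominican-like cohort (two 150 cM autosomes, a risk variant at
chr2:75,000,001 with allele frequency 27% on NAT tracts and 0.1%
elsewhere, per-allele OR 3.7):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_ancestry_summaries.R
Rscript analysis/03_threshold.R
Rscript analysis/04_admixture_scan.R
Rscript analysis/05_finemap.R
Rscript analysis/06_epidemiology.R
```

Selected output (seed 2027, as committed):

```
cohort: 1813 individuals, 1502 loci, 253 cases / 1560 controls
estimated generations since admixture: g = 9.739421 (truth 9.73)

top 5 admixture-mapping associations:
 chrom   pos_bp predictor   or    se        p
     2 79200001       NAT 1.99 0.174 7.81e-05
     2 72800001       NAT 1.95 0.171 8.78e-05
NAT-carrier prevalence at the peak: het 22.5% vs non-carrier 12.8%,
  OR 1.98 (95% CI 1.37-2.84)

unconditional LA p at peak: 0.00126
selected tags: risk_snp; final conditional LA p: 0.623
tract-stratified frequency of the planted risk SNP:
 ancestry n_haplotypes alt_count     freq
      EUR         2016         0 0.000000
      AFR         1386         1 0.000722
      NAT          224        60 0.267857
```

Reading this: the scan's top NAT associations cluster in the planted
locus's tract neighbourhood with odds ratios near 2; heterozygous NAT
carriers at the peak have 22.5% disease prevalence versus 12.8% in
non-carriers; conditioning on the planted SNP attenuates the LA signal
from p = 0.0013 to p = 0.62, identifying it as the tag; and its allele is
confined to NAT tracts (26.8% vs ~0%). Tables land in `results/`.

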