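# Shared study configuration for the analysis scripts. The cohort emulates
# the Dominican discovery sample: n = 1,813 (about 245 expected cases),
# three-way EUR/AFR/NAT admixture (0.56/0.37/0.06), one admixture pulse
# g = 9.73 generations ago. Two 150 cM autosomes keep the scripts quick;
# chromosome "2" carries a planted risk variant at 75 cM that is common on
# NAT tracts (27%) and rare elsewhere (0.1%), with a per-allele OR of 3.7
# -- the architecture inferred for the 2q35 signal.

library(admixscan)

study_seed <- 2027L

study_map <- default_map(chrom_cM = c("1" = 150, "2" = 150))

peak_locus <- list(chrom = "2", idx = which(study_map$chrom == "2")[376])
peak_locus$pos_bp <- study_map$pos_bp[peak_locus$idx]

study_variants <- local({
  set.seed(study_seed)
  win_lo <- peak_locus$pos_bp - 2.5e6
  win_hi <- peak_locus$pos_bp + 2.5e6
  cand <- setdiff(which(study_map$chrom == "2" &
                          study_map$pos_bp >= win_lo &
                          study_map$pos_bp <= win_hi),
                  peak_locus$idx)
  null_idx <- sort(sample(cand, 20))
  variant_model(chrom = "2",
                pos_bp = c(study_map$pos_bp[null_idx], peak_locus$pos_bp),
                id = c(sprintf("win_snp_%02d", 1:20), "risk_snp"),
                f = rbind(matrix(runif(60, 0.05, 0.5), ncol = 3),
                          c(0.001, 0.001, 0.27)),
                beta = c(rep(0, 20), log(3.7)))
})

build_cohort <- function() {
  cfg <- admixture_config(map = study_map, seed = study_seed)
  simulate_cohort(cfg, study_variants)
}

results_dir <- file.path("results")
dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)
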