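#!/usr/bin/env Rscript
# Simulate the study cohort and record its basic composition: realized
# case/control split, global ancestry proportions (with bootstrap CIs on
# the medians), and the planted variant's cohort frequency.

source(file.path("analysis", "_common.R"))

co <- build_cohort()

cat(sprintf("cohort: %d individuals, %d loci, %d cases / %d controls\n",
            n_individuals(co$la), n_loci(co$la),
            sum(co$pheno$pad_status == 1), sum(co$pheno$pad_status == 0)))

write_scan_result(co$pheno, file.path(results_dir, "phenotypes.tsv"))

props <- global_from_local(co$la)
ci <- lapply(co$la$ancestries, function(a)
  bootstrap_ci(props[[a]], statistic = median, n_boot = 10000,
               seed = study_seed))
prop_tab <- data.frame(ancestry = co$la$ancestries,
                       median = sapply(ci, `[`, "point"),
                       ci_lo = sapply(ci, `[`, "lo"),
                       ci_hi = sapply(ci, `[`, "hi"))
write_scan_result(prop_tab, file.path(results_dir, "global_ancestry.tsv"))
cat("global ancestry medians (95% bootstrap CI):\n")
print(prop_tab, row.names = FALSE, digits = 3)

maf <- co$geno$maf[["risk_snp"]]
cat(sprintf("planted risk variant cohort MAF: %.4f (expected ~ sum q_k f_k = %.4f)\n",
            maf, sum(admixture_config()$q * c(0.001, 0.001, 0.27))))
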