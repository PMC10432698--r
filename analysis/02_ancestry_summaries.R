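#!/usr/bin/env Rscript
# Local-ancestry QC and descriptive statistics: depth filter + exclusion
# regions, tract-length summaries per ancestry, and the estimate of
# generations since admixture from the decay of dosage correlation with
# genetic distance.

source(file.path("analysis", "_common.R"))

co <- build_cohort()

la_qc <- qc_la_depth(co$la)
rep <- attr(la_qc, "qc_report")
cat(sprintf("depth QC: %d loci in, %d removed (depth), %d removed (regions), %d kept\n",
            rep$n_input, rep$n_removed_depth, rep$n_removed_region, rep$n_kept))

tr <- tract_lengths(la_qc)
write_scan_result(tr$summary, file.path(results_dir, "tract_summary.tsv"))
cat("tract lengths (cM) per ancestry:\n")
print(tr$summary, row.names = FALSE, digits = 4)
cat("(expect NAT shortest, EUR longest: older, rarer NAT ancestry fragments further)\n")

pairs <- la_correlation_pairs(prune_map(la_qc, 0.2), max_d_cM = 20)
gh <- estimate_g(pairs)
cat(sprintf("estimated generations since admixture: g = %.6f (truth 9.73)\n", gh$g))
write_scan_result(data.frame(g_hat = gh$g, rss = gh$rss, n_bins = gh$n_bins),
                  file.path(results_dir, "g_estimate.tsv"))
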