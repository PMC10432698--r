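# Simulated fine-mapping scenario: a 5 Mb window holding null SNPs plus
# (optionally) causal SNPs common on NAT tracts and rare elsewhere. The
# fine-mapped peak is the planted locus, mirroring a scan-reported signal.
finemap_scenario <- function(seed, causal_beta = log(3.7), n_null = 15,
                             two_causal = FALSE, la_beta = NULL,
                             balanced_nulls = FALSE) {
  map <- default_map(chrom_cM = c("1" = 80))
  peak_idx <- 200L
  peak_bp <- map$pos_bp[peak_idx]
  win <- c(peak_bp - 2.5e6, peak_bp + 2.5e6)
  cfg <- admixture_config(map = map, seed = seed)
  set.seed(seed + 5000)
  cand <- setdiff(which(map$pos_bp >= win[1] & map$pos_bp <= win[2]),
                  c(peak_idx, peak_idx + 1L))
  null_idx <- sort(sample(cand, n_null))
  pos <- map$pos_bp[null_idx]
  ids <- sprintf("null%02d", seq_len(n_null))
  f <- if (balanced_nulls)
    matrix(rep(runif(n_null, 0.05, 0.5), 3), ncol = 3)
  else matrix(runif(3 * n_null, 0.05, 0.5), ncol = 3)
  beta <- rep(0, n_null)
  if (!is.na(causal_beta) && causal_beta != 0) {
    pos <- c(pos, peak_bp)
    ids <- c(ids, "causal1")
    f <- rbind(f, c(0.001, 0.001, 0.27))
    beta <- c(beta, causal_beta)
  }
  if (two_causal) {
    pos <- c(pos, map$pos_bp[peak_idx + 1L])
    ids <- c(ids, "causal2")
    f <- rbind(f, c(0.001, 0.001, 0.27))
    beta <- c(beta, log(2.8))
  }
  vm <- variant_model("1", pos, ids, f = f, beta = beta)
  model <- if (!is.null(la_beta))
    phenotype_model(la_effect = list(chrom = "1", pos_bp = peak_bp,
                                     ancestry = "NAT", beta = la_beta))
  else phenotype_model()
  co <- simulate_cohort(cfg, vm, model = model)
  dpk <- la_dosages(co$la, "NAT")[, peak_idx]
  base <- fit_logistic(co$pheno$pad_status,
                       cbind(la = dpk,
                             admixscan:::build_design(co$pheno,
                                                      c("sex", "array"))))
  list(co = co, peak_bp = peak_bp, dpk = dpk,
       p0 = base$coef$p[base$coef$term == "la"],
       config = finemap_config("1", win[1], win[2], peak_bp))
}

# a seed whose cohort shows a clear LA signal at the planted peak
pick_signal_seed <- function(from, ...) {
  for (s in from + 0:20) {
    sc <- finemap_scenario(s, ...)
    if (sc$p0 < 0.01) return(sc)
  }
  stop("no signal seed found")
}
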