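# Genome-wide significance for admixture mapping. Local-ancestry dosages
# are long-range correlated, so Bonferroni over loci is far too strict.
# The family-wise threshold is obtained by simulating the joint null of
# the per-locus, per-ancestry Wald statistics as a stationary Gaussian
# process whose along-map correlation decays as exp(-g d) (d in Morgans,
# g = generations since admixture, estimated from observed LA correlation)
# and whose cross-ancestry correlation at a locus follows the multinomial
# covariance of ancestry dosages. The cutoff is the chi-square(1) tail
# probability of the 95th percentile of the simulated genome-wide maxima.

#' Prune loci to a minimum genetic spacing
#'
#' Greedy left-to-right selection per chromosome: the first locus is kept,
#' then each next locus at least `spacing_cM` beyond the last kept one.
#'
#' @param la a [local_ancestry()].
#' @param spacing_cM minimum spacing (default 0.2; 0 keeps all loci).
#' @return The pruned `local_ancestry`.
#' @export
prune_map <- function(la, spacing_cM = 0.2) {
  keep <- logical(nrow(la$map))
  for (ch in unique(la$map$chrom)) {
    li <- which(la$map$chrom == ch)
    last <- -Inf
    for (i in li) {
      if (la$map$pos_cM[i] >= last + spacing_cM - 1e-9) {
        keep[i] <- TRUE
        last <- la$map$pos_cM[i]
      }
    }
  }
  local_ancestry(la$codes[, keep, drop = FALSE], la$individuals,
                 genetic_map(la$map$chrom[keep], la$map$pos_bp[keep],
                             la$map$pos_cM[keep]),
                 la$ancestries)
}

#' Binned local-ancestry dosage correlations by genetic distance
#'
#' For each ancestry, the Pearson correlation of dosage vectors for every
#' same-chromosome locus pair within `max_d_cM`, aggregated into distance
#' bins of width `bin_cM`. Pairs involving a constant dosage are skipped.
#'
#' @param la a (pruned) [local_ancestry()] with >= 2 loci per chromosome.
#' @param max_d_cM maximum pair distance in cM (default 20).
#' @param bin_cM bin width in cM (default 0.2).
#' @return data.frame with `d` (bin mean distance in Morgans), `corr`
#'   (mean pair correlation), `ancestry`, `weight` (pair count).
#' @export
la_correlation_pairs <- function(la, max_d_cM = 20, bin_cM = 0.2) {
  out <- list()
  for (a in la$ancestries) {
    D <- la_dosages(la, a)
    for (ch in unique(la$map$chrom)) {
      li <- which(la$map$chrom == ch)
      if (length(li) < 2L) next
      cm <- la$map$pos_cM[li]
      Dc <- D[, li, drop = FALSE]
      sds <- matrixStats_colSds(Dc)
      ok <- sds > 0
      if (sum(ok) < 2L) next
      Z <- scale(Dc[, ok, drop = FALSE])
      cc <- crossprod(Z) / (nrow(Z) - 1)
      cmk <- cm[ok]
      dm <- abs(outer(cmk, cmk, "-"))
      sel <- which(upper.tri(dm) & dm <= max_d_cM & dm > 0, arr.ind = TRUE)
      if (!nrow(sel)) next
      out[[length(out) + 1L]] <- data.frame(
        d_cM = dm[sel], corr = cc[sel], ancestry = a,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no usable locus pairs")
  pairs <- do.call(rbind, out)
  bin <- floor(pairs$d_cM / bin_cM + 1e-9)
  key <- paste(pairs$ancestry, bin)
  agg <- data.frame(d = as.numeric(tapply(pairs$d_cM, key, mean)) / 100,
                    corr = as.numeric(tapply(pairs$corr, key, mean)),
                    ancestry = as.character(tapply(pairs$ancestry, key, `[`, 1L)),
                    weight = as.numeric(tapply(pairs$d_cM, key, length)),
                    stringsAsFactors = FALSE)
  rownames(agg) <- NULL
  agg[order(agg$ancestry, agg$d), ]
}

#' Estimate generations since admixture from correlation decay
#'
#' Weighted least-squares fit of `corr(d) = exp(-g d)` over the pooled
#' ancestry bins (weights = pair counts), solved by 1-D minimisation.
#'
#' @param pairs data.frame from [la_correlation_pairs()] (needs >= 5 bins
#'   with finite correlations).
#' @return list with `g` (the estimate), `rss` (weighted residual sum of
#'   squares) and `n_bins`.
#' @export
estimate_g <- function(pairs) {
  ok <- is.finite(pairs$corr) & pairs$d > 0
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) < 5L) stop("need >= 5 distance bins with finite correlations")
  w <- pairs$weight / sum(pairs$weight)
  if (sum(w * pairs$corr) <= 0)
    stop("decay not exponential: non-positive correlations dominate")
  obj <- function(g) sum(w * (pairs$corr - exp(-g * pairs$d))^2)
  opt <- optimize(obj, interval = c(1e-3, 5e3), tol = 1e-10)
  list(g = opt$minimum, rss = opt$objective, n_bins = nrow(pairs))
}

#' Threshold-simulation model
#'
#' @param g generations since admixture (per-Morgan decay rate; `Inf`
#'   gives independent loci).
#' @param q ancestry proportions (length K >= 2).
#' @param map a [genetic_map()] of the pruned scan loci.
#' @param nreps null-simulation replicates (default 10,000; >= 1,000
#'   required for a reported threshold).
#' @param fwer target family-wise error rate (default 0.05).
#' @param seed integer seed.
#' @return A `threshold_model` list.
#' @export
threshold_model <- function(g, q, map, nreps = 10000, fwer = 0.05,
                            seed = 1L) {
  if (g <= 0) stop("g must be positive")
  if (length(q) < 2L) stop("need K >= 2 ancestries")
  if (abs(sum(q) - 1) > 0.02) stop("q must sum to 1")
  q <- q / sum(q)
  if (fwer <= 0 || fwer >= 1) stop("fwer must lie in (0,1)")
  structure(list(g = g, q = q, map = map, nreps = as.integer(nreps),
                 fwer = fwer, seed = as.integer(seed)),
            class = "threshold_model")
}

# Cross-ancestry correlation of dosages at one locus: dosages are
# 2 x multinomial(q), giving corr_jk = -sqrt(q_j q_k/((1-q_j)(1-q_k))).
cross_ancestry_corr <- function(q) {
  K <- length(q)
  R <- diag(K)
  for (j in seq_len(K - 1)) for (k in (j + 1):K) {
    R[j, k] <- R[k, j] <- -sqrt(q[j] * q[k] / ((1 - q[j]) * (1 - q[k])))
  }
  R
}

#' Simulate the joint null distribution of genome-wide maxima
#'
#' Per replicate, generates K correlated stationary standard-Gaussian
#' statistic sequences along the pruned map — first-order autoregression
#' between adjacent loci with coefficient `exp(-g * d)` (exact for Markov
#' decay), innovations drawn with the multinomial cross-ancestry
#' correlation — and records the maximum over all loci and ancestries of
#' the squared statistic. Chromosomes are independent.
#'
#' @param model a [threshold_model()].
#' @return numeric vector of `nreps` genome-wide maxima of `z^2`.
#' @export
simulate_null_max <- function(model) {
  stopifnot(inherits(model, "threshold_model"))
  set.seed(derive_seed(model$seed, "null_max"))
  K <- length(model$q)
  R <- cross_ancestry_corr(as.numeric(model$q))
  ev <- eigen(R, symmetric = TRUE)
  tLh <- t(ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), K))
  map <- model$map
  # AR coefficient to the previous locus; 0 at chromosome starts
  d_prev <- c(0, diff(map$pos_cM) / 100)
  newchrom <- c(TRUE, map$chrom[-1] != map$chrom[-nrow(map)])
  a <- exp(-model$g * d_prev)
  a[newchrom] <- 0
  nreps <- model$nreps
  Z <- matrix(0, nreps, K)
  maxstat <- numeric(nreps)
  for (l in seq_len(nrow(map))) {
    E <- matrix(rnorm(nreps * K), nreps, K) %*% tLh
    Z <- a[l] * Z + sqrt(1 - a[l]^2) * E
    m2 <- Z[, 1]^2
    for (k in 2:K) m2 <- pmax(m2, Z[, k]^2)
    maxstat <- pmax(maxstat, m2)
  }
  maxstat
}

#' Family-wise p-value cutoff from a max-statistic sample
#'
#' The cutoff is the upper-tail chi-square(1) probability of the
#' `(1 - fwer)` empirical quantile of the simulated maxima, with a
#' Monte-Carlo confidence interval from binomial bounds on the quantile's
#' order statistic.
#'
#' @param max_sample numeric vector of genome-wide maxima (of `z^2`).
#' @param fwer target family-wise error rate (default 0.05).
#' @param level confidence level of the Monte-Carlo interval.
#' @return list with `cutoff`, `ci` (`lo`, `hi`), and `stat_quantile`.
#' @export
compute_threshold <- function(max_sample, fwer = 0.05, level = 0.95) {
  if (!length(max_sample)) stop("empty max sample")
  n <- length(max_sample)
  s <- sort(max_sample)
  k <- max(1L, ceiling((1 - fwer) * n))
  m <- s[k]
  alpha <- (1 - level) / 2
  k_lo <- min(n, qbinom(1 - alpha, n, 1 - fwer) + 1L)
  k_hi <- max(1L, qbinom(alpha, n, 1 - fwer))
  list(cutoff = pchisq(m, df = 1, lower.tail = FALSE),
       ci = c(lo = pchisq(s[k_lo], df = 1, lower.tail = FALSE),
              hi = pchisq(s[k_hi], df = 1, lower.tail = FALSE)),
       stat_quantile = m)
}

#' End-to-end admixture-mapping significance threshold
#'
#' Convenience wrapper: simulate the joint null under `model` and convert
#' the maxima to a family-wise p-value cutoff.
#'
#' @param model a [threshold_model()].
#' @return list with `cutoff`, `ci`, `stat_quantile`, `n_loci`, `g`.
#' @export
admixture_threshold <- function(model) {
  if (model$nreps < 1000)
    stop("nreps must be >= 1000 for a reported threshold")
  mx <- simulate_null_max(model)
  th <- compute_threshold(mx, fwer = model$fwer)
  c(th, list(n_loci = nrow(model$map), g = model$g))
}
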