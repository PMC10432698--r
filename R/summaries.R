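# Descriptive statistics and QC for local-ancestry call sets: per-locus
# call-depth filtering, global ancestry proportions summed from haploid
# calls, concordance against an external estimate, tract-length summaries,
# and percentile-bootstrap confidence intervals.

#' Depth-based QC of local-ancestry loci
#'
#' Computes per-locus call depth (number of non-missing haploid calls),
#' removes loci whose depth deviates more than `sd_window` standard
#' deviations from the median depth, and removes loci inside configured
#' exclusion regions (default: the HLA region chr6:27-35 Mb, GRCh37).
#' Boundary ties are kept.
#'
#' @param la a [local_ancestry()] with at least 3 loci.
#' @param sd_window SD multiplier around the median depth (default 2).
#' @param exclude data.frame (chrom, start_bp, end_bp) of regions to drop
#'   regardless of depth; positions 1-based inclusive.
#' @return The filtered `local_ancestry` with attribute `qc_report`, a list
#'   of counts per removal reason.
#' @export
qc_la_depth <- function(la, sd_window = 2,
                        exclude = data.frame(chrom = "6",
                                             start_bp = 27e6,
                                             end_bp = 35e6)) {
  if (ncol(la$codes) < 3L) stop("need >= 3 loci for depth QC")
  depth <- colSums(!is.na(la$codes))
  med <- median(depth)
  s <- sd(depth)
  ok_depth <- if (s == 0) rep(TRUE, length(depth)) else
    abs(depth - med) <= sd_window * s
  in_excl <- rep(FALSE, nrow(la$map))
  if (!is.null(exclude) && nrow(exclude)) {
    for (r in seq_len(nrow(exclude))) {
      in_excl <- in_excl | (la$map$chrom == as.character(exclude$chrom[r]) &
                              la$map$pos_bp >= exclude$start_bp[r] &
                              la$map$pos_bp <= exclude$end_bp[r])
    }
  }
  keep <- ok_depth & !in_excl
  if (!any(keep)) stop("depth QC removed all loci")
  out <- local_ancestry(la$codes[, keep, drop = FALSE], la$individuals,
                        genetic_map(la$map$chrom[keep], la$map$pos_bp[keep],
                                    la$map$pos_cM[keep]),
                        la$ancestries)
  attr(out, "qc_report") <- list(n_input = length(depth),
                                 n_removed_depth = sum(!ok_depth & !in_excl),
                                 n_removed_region = sum(in_excl),
                                 n_kept = sum(keep),
                                 median_depth = med, sd_depth = s)
  out
}

#' Global ancestry proportions from local-ancestry calls
#'
#' Per-individual proportion of each ancestry, computed by summing haploid
#' calls over loci: `prop_k = calls_k / (2 x loci)`. Missing calls are
#' excluded from the denominator. Rows sum to 1.
#'
#' @param la a [local_ancestry()].
#' @return data.frame with `id` and one proportion column per ancestry.
#' @export
global_from_local <- function(la) {
  if (ncol(la$codes) == 0L) stop("empty local-ancestry matrix")
  K <- length(la$ancestries)
  H <- nrow(la$codes)
  n <- H / 2L
  odd <- seq(1L, H, by = 2L)
  props <- matrix(0, nrow = n, ncol = K,
                  dimnames = list(NULL, la$ancestries))
  denom <- rowSums(!is.na(la$codes[odd, , drop = FALSE])) +
    rowSums(!is.na(la$codes[odd + 1L, , drop = FALSE]))
  for (k in seq_len(K)) {
    cnt <- rowSums(la$codes[odd, , drop = FALSE] == k - 1L, na.rm = TRUE) +
      rowSums(la$codes[odd + 1L, , drop = FALSE] == k - 1L, na.rm = TRUE)
    props[, k] <- cnt / denom
  }
  data.frame(id = la$individuals, props, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Flag individuals with discordant ancestry proportions
#'
#' Compares two per-individual proportion tables (e.g. summed local-ancestry
#' calls vs. a model-based global estimate) and flags individuals whose
#' absolute difference exceeds `tol` for any ancestry.
#'
#' @param props_a,props_b data.frames as returned by [global_from_local()]
#'   (same individuals, same ancestry columns).
#' @param tol maximum tolerated absolute discordance (default 0.05).
#' @return data.frame of flagged individuals with the offending ancestry
#'   and discordance (0 rows if none).
#' @export
concordance_check <- function(props_a, props_b, tol = 0.05) {
  if (!identical(sort(props_a$id), sort(props_b$id)))
    stop("proportion tables cover different individuals")
  b <- props_b[match(props_a$id, props_b$id), , drop = FALSE]
  anc <- setdiff(names(props_a), "id")
  if (!all(anc %in% names(b))) stop("ancestry columns differ")
  d <- abs(as.matrix(props_a[anc]) - as.matrix(b[anc]))
  hit <- which(d > tol, arr.ind = TRUE)
  data.frame(id = props_a$id[hit[, 1]],
             ancestry = anc[hit[, 2]],
             discordance = d[hit],
             stringsAsFactors = FALSE)
}

#' Ancestry tracts and tract-length summaries
#'
#' A tract is a maximal run of constant ancestry along one haplotype of one
#' chromosome. Tracts tile each haplotype over the chromosome's mapped cM
#' span; internal boundaries are placed at the midpoint between the flanking
#' loci of adjacent runs. Tracts touching a chromosome end are flagged
#' censored (included in summaries).
#'
#' @param la a [local_ancestry()].
#' @return list with `tracts` (individual, haplotype, ancestry, chrom,
#'   start_cM, end_cM, length_cM, censored_left/right) and `summary`
#'   (per-ancestry n, mean and median length in cM).
#' @export
tract_lengths <- function(la) {
  out <- vector("list", 0L)
  H <- nrow(la$codes)
  for (ch in unique(la$map$chrom)) {
    li <- which(la$map$chrom == ch)
    cm <- la$map$pos_cM[li]
    span <- range(cm)
    for (h in seq_len(H)) {
      v <- la$codes[h, li]
      keep <- !is.na(v)
      if (!any(keep)) next
      r <- rle(v[keep])
      cmk <- cm[keep]
      ends_idx <- cumsum(r$lengths)
      starts_idx <- c(1L, head(ends_idx, -1L) + 1L)
      # internal boundaries at midpoints between flanking loci
      bounds <- c(span[1],
                  if (length(r$lengths) > 1L)
                    (cmk[ends_idx[-length(ends_idx)]] +
                       cmk[starts_idx[-1L]]) / 2,
                  span[2])
      out[[length(out) + 1L]] <- data.frame(
        individual = la$individuals[ceiling(h / 2)],
        haplotype = 1L + (h + 1L) %% 2L,
        ancestry = la$ancestries[r$values + 1L],
        chrom = ch,
        start_cM = bounds[-length(bounds)],
        end_cM = bounds[-1L],
        stringsAsFactors = FALSE)
    }
  }
  tracts <- do.call(rbind, out)
  tracts$length_cM <- tracts$end_cM - tracts$start_cM
  chrom_span <- tapply(la$map$pos_cM, la$map$chrom, range)
  tracts$censored_left <- tracts$start_cM ==
    vapply(chrom_span[tracts$chrom], `[`, 0, 1L)
  tracts$censored_right <- tracts$end_cM ==
    vapply(chrom_span[tracts$chrom], `[`, 0, 2L)
  smry <- do.call(rbind, lapply(split(tracts$length_cM, tracts$ancestry),
                                function(x) data.frame(n = length(x),
                                                       mean_cM = mean(x),
                                                       median_cM = median(x))))
  smry <- data.frame(ancestry = rownames(smry), smry, row.names = NULL,
                     stringsAsFactors = FALSE)
  list(tracts = tracts, summary = smry)
}

#' Percentile bootstrap confidence interval
#'
#' Nonparametric bootstrap of an arbitrary statistic with a percentile
#' interval; deterministic under `seed`.
#'
#' @param values numeric vector (length >= 2).
#' @param statistic function of a numeric vector (default [median()]).
#' @param n_boot bootstrap replicates (default 10,000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return named vector `c(point, lo, hi)`.
#' @export
bootstrap_ci <- function(values, statistic = median, n_boot = 10000,
                         level = 0.95, seed = 1L) {
  if (length(values) < 2L) stop("need >= 2 values")
  set.seed(derive_seed(seed, "bootstrap"))
  n <- length(values)
  reps <- vapply(seq_len(n_boot),
                 function(i) statistic(values[sample.int(n, n, replace = TRUE)]),
                 numeric(1))
  a <- (1 - level) / 2
  ci <- quantile(reps, c(a, 1 - a), names = FALSE, type = 7)
  c(point = statistic(values), lo = ci[1], hi = ci[2])
}
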