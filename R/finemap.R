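# Conditional fine-mapping of an admixture-mapping peak. The driver of an
# LA association is sought among SNPs in a window around the peak: each
# candidate is added to the model status ~ LA dosage + SNP + covariates,
# and the SNP whose inclusion most attenuates the LA term (largest
# conditional LA p) is selected as a tag; the loop repeats with selected
# tags as covariates until the LA signal is explained or max_tags reached.

#' Fine-mapping configuration
#'
#' @param chrom,start_bp,end_bp candidate window (default interpretation:
#'   5 Mb around the peak).
#' @param peak_bp physical position of the admixture-mapping peak locus.
#' @param p_stop stop when the conditional LA p exceeds this (default
#'   0.05).
#' @param max_tags maximum tags selected (default 5).
#' @param covariates phenotype covariates (default sex, array).
#' @param maf_min candidate MAF filter (default 0.01).
#' @param min_attenuation minimum *share* of the current LA Wald
#'   chi-square a candidate must absorb (`(z^2_before - z^2_after) /
#'   z^2_before`) to count as attenuating; default 0.2. Any irrelevant
#'   covariate jitters the LA p slightly (absorbing a few percent at
#'   most), so a bare increase in p is not evidence of tagging.
#' @return A `finemap_config` list.
#' @export
finemap_config <- function(chrom, start_bp, end_bp, peak_bp,
                           p_stop = 0.05, max_tags = 5,
                           covariates = c("sex", "array"), maf_min = 0.01,
                           min_attenuation = 0.2) {
  if (peak_bp < start_bp || peak_bp > end_bp)
    stop("window must contain the peak")
  if (p_stop <= 0 || p_stop >= 1) stop("p_stop must lie in (0,1)")
  structure(list(chrom = as.character(chrom), start_bp = start_bp,
                 end_bp = end_bp, peak_bp = peak_bp, p_stop = p_stop,
                 max_tags = as.integer(max_tags), covariates = covariates,
                 maf_min = maf_min, min_attenuation = min_attenuation),
            class = "finemap_config")
}

# Candidate variants in the window: biallelic, MAF-filtered, not yet tags.
finemap_candidates <- function(geno, config, selected) {
  v <- geno$variants
  in_win <- v$chrom == config$chrom & v$pos_bp >= config$start_bp &
    v$pos_bp <= config$end_bp
  biallelic <- !grepl(",", v$alt)
  pass <- in_win & biallelic & geno$maf >= config$maf_min &
    !(v$id %in% selected)
  which(pass)
}

#' One round of conditional scanning around an admixture peak
#'
#' For every candidate SNP in the window, fits `status ~ LA dosage + SNP +
#' selected tags + covariates` and records the LA term's conditional
#' estimate alongside the SNP's own.
#'
#' @param la_peak_dosage ancestry dosage vector (0/1/2) at the peak locus.
#' @param geno a [genotype_matrix()] covering the window.
#' @param pheno aligned phenotype data.frame.
#' @param config a [finemap_config()].
#' @param selected_tags character vector of already-selected tag SNP ids.
#' @return data.frame of attenuation records: `snp`, `pos_bp`,
#'   `la_beta`, `la_se`, `la_p`, `snp_beta`, `snp_se`, `snp_p`, `status`.
#' @export
conditional_scan <- function(la_peak_dosage, geno, pheno, config,
                             selected_tags = character(0)) {
  if (var(la_peak_dosage) == 0) stop("peak dosage is constant")
  cand <- finemap_candidates(geno, config, selected_tags)
  if (!length(cand)) stop("no candidate SNPs in window after filters")
  y <- pheno$pad_status
  covs <- build_design(pheno, config$covariates)
  tagX <- if (length(selected_tags))
    geno$dosage[, selected_tags, drop = FALSE] else NULL
  rows <- lapply(cand, function(j) {
    snp <- geno$dosage[, j]
    X <- cbind(la = la_peak_dosage, snp = snp, tagX, covs)
    rec <- data.frame(snp = geno$variants$id[j],
                      pos_bp = geno$variants$pos_bp[j],
                      la_beta = NA_real_, la_se = NA_real_, la_p = NA_real_,
                      snp_beta = NA_real_, snp_se = NA_real_,
                      snp_p = NA_real_, status = "ok",
                      stringsAsFactors = FALSE)
    if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
      rec$status <- "skipped:collinear"
      return(rec)
    }
    f <- fit_logistic(y, X)
    if (f$status != "ok") {
      rec$status <- paste0("skipped:", f$status)
      return(rec)
    }
    la_row <- f$coef[f$coef$term == "la", ]
    snp_row <- f$coef[f$coef$term == "snp", ]
    rec$la_beta <- la_row$beta; rec$la_se <- la_row$se; rec$la_p <- la_row$p
    rec$snp_beta <- snp_row$beta; rec$snp_se <- snp_row$se
    rec$snp_p <- snp_row$p
    rec
  })
  do.call(rbind, rows)
}

#' Greedy tag-SNP selection by conditional attenuation
#'
#' Each round selects the SNP maximising the conditional LA p (ties broken
#' by smaller SNP p, then lower position), adds it as a covariate, and
#' repeats until the LA p exceeds `p_stop` or `max_tags` is reached. A
#' selected SNP is only accepted if it absorbs at least
#' `config$min_attenuation` of the current LA Wald chi-square; when no
#' candidate clears that bar in the first round the tag list is empty and
#' a diagnostic is returned.
#'
#' @inheritParams conditional_scan
#' @return list with `tags` (in selection order), `trace` (one row per
#'   round: the selected record), `unconditional_la_p`, `final_la_p`, and
#'   `converged` (whether the stop rule fired before `max_tags`).
#' @export
select_tag_snps <- function(la_peak_dosage, geno, pheno, config) {
  y <- pheno$pad_status
  covs <- build_design(pheno, config$covariates)
  base <- fit_logistic(y, cbind(la = la_peak_dosage, covs))
  if (base$status != "ok") stop("baseline LA model did not fit: ", base$status)
  la_row <- base$coef[base$coef$term == "la", ]
  p0 <- la_row$p
  z2 <- la_row$z^2
  tags <- character(0)
  trace <- NULL
  la_p <- p0
  repeat {
    recs <- conditional_scan(la_peak_dosage, geno, pheno, config, tags)
    ok <- recs[recs$status == "ok" & is.finite(recs$la_p), , drop = FALSE]
    if (!nrow(ok)) break
    ord <- order(-ok$la_p, ok$snp_p, ok$pos_bp)
    best <- ok[ord[1], , drop = FALSE]
    z2_cond <- (best$la_beta / best$la_se)^2
    if (z2 - z2_cond < config$min_attenuation * z2) {
      if (!length(tags)) {
        return(list(tags = character(0), trace = NULL,
                    unconditional_la_p = p0, final_la_p = p0,
                    converged = FALSE,
                    diagnostic = "no SNP attenuates the LA signal"))
      }
      break
    }
    tags <- c(tags, best$snp)
    best$round <- length(tags)
    trace <- rbind(trace, best)
    la_p <- best$la_p
    z2 <- z2_cond
    if (la_p > config$p_stop || length(tags) >= config$max_tags) break
  }
  list(tags = tags, trace = trace, unconditional_la_p = p0,
       final_la_p = la_p, converged = la_p > config$p_stop)
}

#' Ancestry-stratified allele frequency on tracts
#'
#' Allele counts for one variant stratified by the carrying haplotype's
#' local ancestry at the variant position. Uses phased haploid alleles when
#' the genotype object carries them (simulated data); otherwise estimates
#' from individuals homozygous for ancestry at the locus, whose allele
#' counts are unambiguous.
#'
#' @param geno a [genotype_matrix()].
#' @param variant_id variant identifier in `geno`.
#' @param la a [local_ancestry()] whose map contains the variant position.
#' @return data.frame with `ancestry`, `n_haplotypes`, `alt_count`,
#'   `freq`, and attribute `method` ("phased" or "ancestry-homozygous").
#' @export
tract_frequency <- function(geno, variant_id, la) {
  j <- match(variant_id, geno$variants$id)
  if (is.na(j)) stop("unknown variant: ", variant_id)
  loc <- which(la$map$chrom == geno$variants$chrom[j] &
                 la$map$pos_bp == geno$variants$pos_bp[j])
  if (!length(loc)) stop("variant off the local-ancestry map")
  loc <- loc[1]
  K <- length(la$ancestries)
  hap <- attr(geno, "hap_alleles")
  if (!is.null(hap)) {
    anc <- la$codes[, loc]
    al <- hap[, j]
    res <- data.frame(ancestry = la$ancestries,
                      n_haplotypes = as.integer(tabulate(anc + 1L, K)),
                      alt_count = vapply(seq_len(K) - 1L,
                                         function(k) sum(al[anc == k]), 0L))
    method <- "phased"
  } else {
    odd <- seq(1L, nrow(la$codes), by = 2L)
    a1 <- la$codes[odd, loc]; a2 <- la$codes[odd + 1L, loc]
    hom <- which(a1 == a2)
    res <- do.call(rbind, lapply(seq_len(K) - 1L, function(k) {
      sel <- hom[a1[hom] == k]
      data.frame(ancestry = la$ancestries[k + 1L],
                 n_haplotypes = 2L * length(sel),
                 alt_count = as.integer(round(sum(geno$dosage[sel, j]))))
    }))
    method <- "ancestry-homozygous"
  }
  res$freq <- ifelse(res$n_haplotypes > 0, res$alt_count / res$n_haplotypes,
                     NA_real_)
  attr(res, "method") <- method
  res
}
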