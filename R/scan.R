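# The association scans: local-ancestry dosage construction, maximum-
# likelihood logistic fits with Wald inference, the per-locus admixture
# scan (case status ~ LA dosage + covariates), the per-SNP scan with MAF
# filtering, carrier-prevalence tables, and fixed-effect inverse-variance
# meta-analysis of two array-specific scans.

#' Scan configuration
#'
#' @param covariates phenotype columns entered as covariates (default sex
#'   and array, matching the admixture-mapping model; use e.g.
#'   `c("age", "sex", "PC1", ...)` for a SNP scan).
#' @param maf_min minimum minor-allele frequency for the SNP scan
#'   (default 0.01).
#' @param min_carriers minimum count of minor-side dosage carriers for a
#'   locus to be tested (default 10).
#' @return A `scan_config` list.
#' @export
scan_config <- function(covariates = c("sex", "array"), maf_min = 0.01,
                        min_carriers = 10) {
  if (maf_min < 0 || maf_min >= 0.5) stop("maf_min must lie in [0, 0.5)")
  structure(list(covariates = covariates, maf_min = maf_min,
                 min_carriers = as.integer(min_carriers)),
            class = "scan_config")
}

#' Additive local-ancestry dosage for one ancestry
#'
#' Counts, per individual and locus, how many of the two haplotypes carry
#' the given ancestry (0 = non-carrier, 1 = heterozygous, 2 = homozygous).
#'
#' @param la a [local_ancestry()].
#' @param ancestry ancestry label or 0-based code.
#' @return integer matrix `n x L` with attribute `ancestry`.
#' @export
la_dosages <- function(la, ancestry) {
  k <- if (is.character(ancestry)) match(ancestry, la$ancestries) - 1L
       else as.integer(ancestry)
  if (is.na(k) || k < 0L || k >= length(la$ancestries))
    stop("unknown ancestry: ", ancestry)
  H <- nrow(la$codes)
  odd <- seq(1L, H, by = 2L)
  d <- (la$codes[odd, , drop = FALSE] == k) +
    (la$codes[odd + 1L, , drop = FALSE] == k)
  storage.mode(d) <- "integer"
  rownames(d) <- la$individuals
  attr(d, "ancestry") <- la$ancestries[k + 1L]
  d
}

#' Maximum-likelihood logistic regression with Wald inference
#'
#' Fits a binomial GLM (logit link) with an intercept always included, and
#' reports per-column Wald statistics (`z = beta/se`, two-sided normal p).
#'
#' @param y binary response (both classes must be present).
#' @param X numeric design matrix of predictors (no intercept column;
#'   one is added).
#' @return list with `coef` (data.frame: term, beta, se, z, p, including
#'   the intercept) and `status` ("ok", "separation" or "nonconvergence";
#'   estimates are `NA` unless "ok").
#' @export
fit_logistic <- function(y, X) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("response has a single class")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  Xd <- cbind(`(Intercept)` = 1, X)
  if (nrow(Xd) < ncol(Xd) + 1L) stop("too few rows for the design")
  fit <- suppressWarnings(glm.fit(Xd, y, family = binomial(),
                                  control = list(epsilon = 1e-14,
                                                 maxit = 100)))
  eta <- Xd %*% fit$coefficients
  sep <- any(abs(eta) > 15) && any(fit$fitted.values < 1e-8 |
                                     fit$fitted.values > 1 - 1e-8)
  status <- if (!fit$converged) "nonconvergence" else if (sep) "separation"
            else "ok"
  if (status != "ok") {
    co <- data.frame(term = colnames(Xd), beta = NA_real_, se = NA_real_,
                     z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    return(list(coef = co, status = status))
  }
  w <- fit$weights
  XtWX <- crossprod(Xd * sqrt(w))
  se <- sqrt(diag(solve(XtWX)))
  beta <- fit$coefficients
  z <- beta / se
  co <- data.frame(term = colnames(Xd), beta = as.numeric(beta),
                   se = as.numeric(se), z = as.numeric(z),
                   p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  list(coef = co, status = "ok")
}

# Build the covariate design (with intercept) from a phenotype table.
# Character/factor columns with two levels are coded 0/1; numeric columns
# are used as-is. Rows with missing covariates are flagged for dropping.
build_design <- function(pheno, covariates) {
  if (!length(covariates))
    return(matrix(numeric(0), nrow = nrow(pheno), ncol = 0))
  cols <- lapply(covariates, function(v) {
    if (!v %in% names(pheno)) stop("covariate not in phenotype table: ", v)
    x <- pheno[[v]]
    if (is.character(x) || is.factor(x)) {
      lev <- sort(unique(as.character(x[!is.na(x)])))
      if (length(lev) > 2L) stop("covariate ", v, " has > 2 levels")
      as.numeric(as.character(x) == lev[length(lev)])
    } else as.numeric(x)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- covariates
  X
}

# Shared driver: scan a dosage matrix (loci in columns) against case
# status with covariates, via the compiled per-locus IRLS.
scan_dosage_matrix <- function(D, keys, pheno, config, predictor_label) {
  y <- as.numeric(pheno$pad_status)
  if (length(unique(y)) < 2L) stop("case status has a single class")
  X <- build_design(pheno, config$covariates)
  complete <- !is.na(y)
  if (ncol(X)) complete <- complete & stats::complete.cases(X)
  y <- y[complete]; X <- X[complete, , drop = FALSE]
  D <- D[complete, , drop = FALSE]
  C <- cbind(1, X)
  null_fit <- suppressWarnings(glm.fit(C, y, family = binomial()))
  beta0 <- null_fit$coefficients

  n_hi <- colSums(D > 0)
  n_lo <- colSums(D < 2)
  m <- pmin(n_hi, n_lo)
  testable <- m >= config$min_carriers & matrixStats_colSds(D) > 0
  res <- data.frame(keys, predictor = predictor_label,
                    n = length(y), n_cases = sum(y == 1),
                    n_controls = sum(y == 0),
                    beta = NA_real_, se = NA_real_, or = NA_real_,
                    p = NA_real_, status = "skipped:low_carriers",
                    stringsAsFactors = FALSE)
  res$status[matrixStats_colSds(D) == 0] <- "skipped:constant"
  if (any(testable)) {
    fit <- logistic_scan_cpp(y, D[, testable, drop = FALSE], C, beta0)
    ok <- fit$converged == 1L & is.finite(fit$se) & fit$se < 100
    idx <- which(testable)
    res$beta[idx[ok]] <- fit$beta[ok]
    res$se[idx[ok]] <- fit$se[ok]
    res$or[idx[ok]] <- exp(fit$beta[ok])
    res$p[idx[ok]] <- 2 * pnorm(-abs(fit$beta[ok] / fit$se[ok]))
    res$status[idx[ok]] <- "ok"
    res$status[idx[!ok]] <- "skipped:separation"
  }
  class(res) <- c("scan_result", "data.frame")
  res
}

# colSds without extra deps (returns 0 for constant columns)
matrixStats_colSds <- function(M) {
  mu <- colMeans(M)
  sqrt(pmax(colMeans(M^2) - mu^2, 0))
}

#' Genome-wide admixture-mapping scan
#'
#' For every ancestry and every locus passing the minimum-carrier rule,
#' fits the case-control model `status ~ LA dosage + covariates` and
#' reports the dosage term (log-odds, SE, OR, Wald p). Skipped loci carry
#' a machine-readable reason in `status`.
#'
#' @param la a QC'd [local_ancestry()].
#' @param pheno phenotype data.frame aligned to `la` (same individuals,
#'   same order; see [align_individuals()]).
#' @param config a [scan_config()].
#' @param ancestries subset of ancestry labels to scan (default all).
#' @return A `scan_result` data.frame (chrom, pos_bp, key, predictor, n,
#'   n_cases, n_controls, beta, se, or, p, status).
#' @export
admixture_scan <- function(la, pheno, config = scan_config(),
                           ancestries = la$ancestries) {
  stopifnot(identical(la$individuals, pheno$id))
  keys <- data.frame(chrom = la$map$chrom, pos_bp = la$map$pos_bp,
                     key = paste0(la$map$chrom, ":", la$map$pos_bp),
                     stringsAsFactors = FALSE)
  out <- lapply(ancestries, function(a) {
    r <- scan_dosage_matrix(la_dosages(la, a), keys, pheno, config, a)
    r
  })
  res <- do.call(rbind, out)
  if (!any(res$status == "ok")) stop("no testable loci in the scan")
  class(res) <- c("scan_result", "data.frame")
  res
}

#' Per-SNP case-control association scan
#'
#' Logistic regression of case status on alt-allele dosage for every
#' variant with MAF >= `config$maf_min`, with the configured covariates.
#'
#' @param geno a [genotype_matrix()] aligned to `pheno`.
#' @param pheno phenotype data.frame.
#' @param config a [scan_config()]; set `covariates` to include PCs when
#'   present in `pheno`.
#' @return A `scan_result` data.frame; variants failing the MAF filter are
#'   reported with status `"skipped:maf"`.
#' @export
snp_scan <- function(geno, pheno, config = scan_config()) {
  stopifnot(identical(rownames(geno$dosage), pheno$id))
  keys <- data.frame(chrom = geno$variants$chrom,
                     pos_bp = geno$variants$pos_bp,
                     key = geno$variants$id, stringsAsFactors = FALSE)
  pass <- geno$maf >= config$maf_min
  res <- scan_dosage_matrix(geno$dosage, keys, pheno, config, "SNP")
  res$status[!pass] <- "skipped:maf"
  res$beta[!pass] <- res$se[!pass] <- res$or[!pass] <- res$p[!pass] <- NA_real_
  res
}

#' Disease prevalence by carrier class
#'
#' Prevalence of case status within dosage classes 0/1/2 and the Wald
#' odds ratio (with 95% CI) of heterozygous carriers versus non-carriers
#' from the 2x2 table. Classes with fewer than `min_class` members are
#' reported but not tested.
#'
#' @param dosage vector of carrier classes in `{0, 1, 2}`.
#' @param y binary case status.
#' @param min_class minimum class size for testing (default 12).
#' @return list with `table` (class, n, cases, prevalence, tested) and
#'   `or_het` (`or`, `lo`, `hi`, `p`; `NA` when undefined).
#' @export
carrier_prevalence <- function(dosage, y, min_class = 12) {
  stopifnot(all(dosage %in% 0:2), all(y %in% 0:1))
  tab <- do.call(rbind, lapply(0:2, function(k) {
    sel <- dosage == k
    data.frame(class = k, n = sum(sel), cases = sum(y[sel]),
               prevalence = if (any(sel)) mean(y[sel]) else NA_real_)
  }))
  tab$tested <- tab$n >= min_class
  a <- tab$cases[2]; b <- tab$n[2] - tab$cases[2]
  c0 <- tab$cases[1]; d0 <- tab$n[1] - tab$cases[1]
  or_het <- c(or = NA_real_, lo = NA_real_, hi = NA_real_, p = NA_real_)
  if (all(c(a, b, c0, d0) > 0) && tab$tested[1] && tab$tested[2]) {
    lor <- log((a * d0) / (b * c0))
    se <- sqrt(1 / a + 1 / b + 1 / c0 + 1 / d0)
    or_het <- c(or = exp(lor), lo = exp(lor - 1.96 * se),
                hi = exp(lor + 1.96 * se), p = 2 * pnorm(-abs(lor / se)))
  }
  list(table = tab, or_het = or_het)
}

#' Fixed-effect inverse-variance meta-analysis of two scans
#'
#' Combines per-variant effects as `beta = sum(beta_i/se_i^2) /
#' sum(1/se_i^2)`, `se = sqrt(1/sum(1/se_i^2))`. Effects are harmonized to
#' study A's alt allele: swapped ref/alt in study B flips the sign;
#' strand-ambiguous variants (A/T, C/G) are dropped; variants present in
#' one study only are passed through with status `"single-study"`.
#'
#' @param res_a,res_b `scan_result` data.frames with columns `key`, `beta`,
#'   `se` (and optionally `ref`, `alt` for harmonization).
#' @return A meta `scan_result` with columns `key`, `beta`, `se`, `or`,
#'   `p`, `status` and attribute `log` describing drops/flips.
#' @export
meta_analyze <- function(res_a, res_b) {
  a <- res_a[!is.na(res_a$beta), , drop = FALSE]
  b <- res_b[!is.na(res_b$beta), , drop = FALSE]
  log <- list(flipped = character(0), ambiguous = character(0),
              mismatched = character(0))
  harmonize <- all(c("ref", "alt") %in% names(a)) &&
    all(c("ref", "alt") %in% names(b))
  common <- intersect(a$key, b$key)
  only_a <- setdiff(a$key, b$key); only_b <- setdiff(b$key, a$key)
  rows <- list()
  comp <- function(x) chartr("ACGT", "TGCA", x)
  for (k in common) {
    ra <- a[a$key == k, ][1, ]; rb <- b[b$key == k, ][1, ]
    bb <- rb$beta
    if (harmonize) {
      if (toupper(ra$ref) == comp(toupper(ra$alt))) {
        log$ambiguous <- c(log$ambiguous, k); next
      }
      if (ra$ref == rb$ref && ra$alt == rb$alt) {
        # aligned
      } else if (ra$ref == rb$alt && ra$alt == rb$ref) {
        bb <- -bb; log$flipped <- c(log$flipped, k)
      } else {
        log$mismatched <- c(log$mismatched, k); next
      }
    }
    w <- c(1 / ra$se^2, 1 / rb$se^2)
    beta <- sum(c(ra$beta, bb) * w) / sum(w)
    se <- sqrt(1 / sum(w))
    rows[[k]] <- data.frame(key = k, beta = beta, se = se,
                            status = "ok", stringsAsFactors = FALSE)
  }
  for (k in only_a) rows[[k]] <- data.frame(key = k, beta = a$beta[a$key == k][1],
                                            se = a$se[a$key == k][1],
                                            status = "single-study",
                                            stringsAsFactors = FALSE)
  for (k in only_b) rows[[k]] <- data.frame(key = k, beta = b$beta[b$key == k][1],
                                            se = b$se[b$key == k][1],
                                            status = "single-study",
                                            stringsAsFactors = FALSE)
  if (!length(rows)) stop("no overlapping or usable variants to meta-analyze")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$or <- exp(res$beta)
  res$p <- 2 * pnorm(-abs(res$beta / res$se))
  attr(res, "log") <- log
  class(res) <- c("scan_result", "data.frame")
  res
}
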