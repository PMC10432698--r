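# Descriptive and risk epidemiology for case-control biobank data:
# biomarker cleaning (per-individual medians, log10 Tukey fences per
# sex-by-group stratum, z-scores), Table-1-style prevalence summaries with
# chi-squared / Mann-Whitney tests, and the nested logistic risk models
# (1: group + age + sex; 2: + BMI; 3: + T2D + TG + TC + HDL) fitted
# pairwise against a reference group.

#' Clean and normalise biomarker measurements
#'
#' Per marker: rows with the invalid sentinel are dropped, the per-
#' individual median over encounters is taken, outliers are removed per
#' stratum using Tukey fences on the log10 scale (quartiles by linear
#' interpolation, boundary ties kept), and z-scores are computed per
#' stratum on the retained values. Zero-IQR strata remove nothing and get
#' z-score 0; strata with fewer than 4 retained values get suppressed
#' (`NA`) z-scores and a flag.
#'
#' @param data data.frame with columns `id`, the stratum columns, and one
#'   column per marker; multiple rows per id are treated as encounters.
#' @param markers marker column names (default hdl, tc, tg, bmi).
#' @param strata stratum column names (default sex and group), constant
#'   within id.
#' @param sentinel invalid-entry code dropped before any computation.
#' @return list with `panel` (per-id medians, log10 values and z-scores),
#'   `removed` (outliers removed per marker), and `flags` (suppressed
#'   strata).
#' @export
clean_biomarkers <- function(data, markers = c("hdl", "tc", "tg", "bmi"),
                             strata = c("sex", "group"),
                             sentinel = 999999) {
  stopifnot("id" %in% names(data), all(strata %in% names(data)))
  ids <- unique(data$id)
  meta <- data[match(ids, data$id), c("id", strata), drop = FALSE]
  panel <- meta
  removed <- setNames(integer(length(markers)), markers)
  flags <- character(0)
  stratum_of <- do.call(paste, c(meta[strata], sep = "|"))
  for (m in markers) {
    v <- data[[m]]
    keep <- !is.na(v) & v != sentinel
    if (any(v[keep] <= 0))
      stop("non-positive values in marker ", m, " (log10 undefined)")
    med <- tapply(v[keep], data$id[keep], median)
    x <- as.numeric(med[ids])
    lx <- log10(x)
    z <- rep(NA_real_, length(ids))
    out_flag <- rep(FALSE, length(ids))
    for (s in unique(stratum_of)) {
      si <- which(stratum_of == s & !is.na(lx))
      if (!length(si)) next
      qs <- quantile(lx[si], c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- qs[2] - qs[1]
      if (iqr == 0) {
        z[si] <- 0
        next
      }
      lo <- qs[1] - 1.5 * iqr
      hi <- qs[2] + 1.5 * iqr
      bad <- lx[si] > hi | lx[si] < lo
      out_flag[si[bad]] <- TRUE
      ret <- si[!bad]
      if (length(ret) < 4L) {
        flags <- c(flags, paste0(m, ":", s))
        next
      }
      z[ret] <- (lx[ret] - mean(lx[ret])) / sd(lx[ret])
    }
    removed[m] <- sum(out_flag)
    x[out_flag] <- NA; lx[out_flag] <- NA
    panel[[m]] <- x
    panel[[paste0(m, "_log10")]] <- lx
    panel[[paste0(m, "_z")]] <- z
  }
  list(panel = panel, removed = removed, flags = flags)
}

#' Prevalence of case status by group
#'
#' Per-group counts and prevalence (rendered to one decimal percent), with
#' a chi-squared test of the group-by-status table. Empty groups are
#' omitted and listed in the attribute `omitted`.
#'
#' @param pheno phenotype data.frame with `pad_status`.
#' @param group_col grouping column (default "group").
#' @return data.frame with `group`, `n`, `cases`, `controls`,
#'   `prevalence_pct`; attributes `p_value` (chi-squared across groups)
#'   and `omitted`.
#' @export
prevalence_table <- function(pheno, group_col = "group") {
  stopifnot(group_col %in% names(pheno), "pad_status" %in% names(pheno))
  g <- as.character(pheno[[group_col]])
  y <- pheno$pad_status
  groups <- unique(g[!is.na(g)])
  rows <- lapply(groups, function(gr) {
    sel <- which(g == gr & !is.na(y))
    data.frame(group = gr, n = length(sel), cases = sum(y[sel]),
               controls = sum(y[sel] == 0), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  omitted <- tab$group[tab$n == 0]
  tab <- tab[tab$n > 0, , drop = FALSE]
  tab$prevalence_pct <- round(100 * tab$cases / tab$n, 1)
  p <- if (nrow(tab) > 1L)
    suppressWarnings(chisq.test(as.matrix(tab[, c("cases", "controls")]))$p.value)
  else NA_real_
  attr(tab, "p_value") <- p
  attr(tab, "omitted") <- omitted
  tab
}

#' Case-vs-control test for a single variable
#'
#' Chi-squared for discrete variables, Mann-Whitney (Wilcoxon rank-sum)
#' for continuous ones, comparing cases and controls.
#'
#' @param pheno phenotype data.frame with `pad_status`.
#' @param var variable column name.
#' @param type `"discrete"` or `"continuous"`.
#' @return list with `n` (non-missing), `p_value`.
#' @export
case_control_test <- function(pheno, var,
                              type = c("continuous", "discrete")) {
  type <- match.arg(type)
  x <- pheno[[var]]
  y <- pheno$pad_status
  keep <- !is.na(x) & !is.na(y)
  p <- if (type == "discrete")
    suppressWarnings(chisq.test(table(x[keep], y[keep]))$p.value)
  else
    suppressWarnings(wilcox.test(x[keep] ~ y[keep])$p.value)
  list(n = sum(keep), p_value = p)
}

# Covariate sets of the three nested risk models.
risk_model_covariates <- function(model_id) {
  switch(as.character(model_id),
         "1" = c("age", "sex"),
         "2" = c("age", "sex", "bmi"),
         "3" = c("age", "sex", "bmi", "t2d", "tg", "tc", "hdl"),
         stop("model id must be 1, 2 or 3"))
}

#' Nested logistic risk models by population group
#'
#' For each non-reference group, fits `status ~ group-indicator +
#' covariates` on that group plus the reference only (pairwise, not a
#' joint multi-group model). Model 1 adjusts for age and sex; model 2
#' adds BMI; model 3 adds T2D, TG, TC and HDL. Rows with missing model
#' covariates are dropped and counted.
#'
#' @param pheno phenotype data.frame with `pad_status`, `group`, and the
#'   model covariates.
#' @param reference reference group label.
#' @param models model ids to fit (subset of 1:3).
#' @return data.frame ordered by model then group: `model`, `group`, `n`,
#'   `n_dropped`, `or`, `lo`, `hi`, `p`, `status`.
#' @export
group_risk_models <- function(pheno, reference, models = 1:3) {
  if (!reference %in% pheno$group) stop("reference group not present")
  groups <- setdiff(sort(unique(pheno$group)), reference)
  out <- list()
  for (m in models) {
    covs <- risk_model_covariates(m)
    miss <- setdiff(covs, names(pheno))
    if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
    for (gr in groups) {
      sub <- pheno[pheno$group %in% c(gr, reference), , drop = FALSE]
      X <- build_design(sub, covs)
      X <- cbind(group = as.numeric(sub$group == gr), X)
      cc <- stats::complete.cases(X) & !is.na(sub$pad_status)
      rec <- data.frame(model = m, group = gr, n = sum(cc),
                        n_dropped = sum(!cc), or = NA_real_, lo = NA_real_,
                        hi = NA_real_, p = NA_real_, status = "ok",
                        stringsAsFactors = FALSE)
      if (sum(sub$pad_status[cc] == 1 & sub$group[cc] == gr) == 0) {
        rec$status <- "skipped:no_cases_in_group"
      } else {
        f <- fit_logistic(sub$pad_status[cc], X[cc, , drop = FALSE])
        if (f$status != "ok") {
          rec$status <- paste0("skipped:", f$status)
        } else {
          co <- f$coef[f$coef$term == "group", ]
          rec$or <- exp(co$beta)
          rec$lo <- exp(co$beta - 1.96 * co$se)
          rec$hi <- exp(co$beta + 1.96 * co$se)
          rec$p <- co$p
        }
      }
      out[[length(out) + 1L]] <- rec
    }
  }
  do.call(rbind, out)
}
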