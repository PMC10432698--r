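# Log-likelihood of a fitted logistic model, reconstructed from the
# reported coefficients; used for the nesting invariant.
loglik_from_fit <- function(fit, y, X) {
  eta <- cbind(1, X) %*% fit$coef$beta
  mu <- plogis(eta)
  sum(y * log(mu) + (1 - y) * log(1 - mu))
}

test_that("Tukey fences on the log10 scale remove the hand-computed outlier", {
  d <- data.frame(id = sprintf("i%d", 1:5), sex = 1, group = "G",
                  hdl = c(10, 11, 12, 13, 1000))
  out <- clean_biomarkers(d, markers = "hdl")
  lx <- log10(c(10, 11, 12, 13))
  q <- quantile(log10(c(10, 11, 12, 13, 1000)), c(.25, .75), type = 7,
                names = FALSE)
  expect_equal(q[2] + 1.5 * (q[2] - q[1]), 1.223, tolerance = 1e-3)
  expect_equal(out$removed[["hdl"]], 1L)
  expect_true(is.na(out$panel$hdl[5]))
  expect_equal(out$panel$hdl[1:4], c(10, 11, 12, 13))
  expect_equal(mean(out$panel$hdl_z, na.rm = TRUE), 0, tolerance = 1e-10)
  expect_equal(sd(out$panel$hdl_z, na.rm = TRUE), 1, tolerance = 1e-10)
})

test_that("degenerate biomarker strata are total: zero IQR and sentinels", {
  d <- data.frame(id = sprintf("i%d", 1:6), sex = 0, group = "G",
                  tg = c(50, 50, 50, 50, 50, 999999))
  out <- clean_biomarkers(d, markers = "tg")
  expect_equal(out$removed[["tg"]], 0L)
  expect_equal(out$panel$tg_z[1:5], rep(0, 5))
  # the sentinel row contributes no encounter; id i6 has no tg median
  expect_true(is.na(out$panel$tg[out$panel$id == "i6"]))
  expect_true(is.na(out$panel$tg_z[out$panel$id == "i6"]))
})

test_that("per-individual medians pool encounters before cleaning", {
  d <- data.frame(id = rep(c("a", "b"), c(3, 2)), sex = 1, group = "G",
                  tc = c(100, 120, 140, 200, 999999))
  out <- clean_biomarkers(d, markers = "tc")
  expect_equal(out$panel$tc[out$panel$id == "a"], 120)
  expect_equal(out$panel$tc[out$panel$id == "b"], 200)
})

test_that("cleaning is invariant to input row order", {
  set.seed(31)
  d <- data.frame(id = rep(sprintf("i%02d", 1:40), each = 2),
                  sex = rep(rep(0:1, 20), each = 2),
                  group = rep(c("X", "Y"), each = 40),
                  hdl = exp(rnorm(80, 4, 0.3)))
  out1 <- clean_biomarkers(d, markers = "hdl")
  perm <- sample(nrow(d))
  out2 <- clean_biomarkers(d[perm, ], markers = "hdl")
  m1 <- out1$panel[order(out1$panel$id), ]
  m2 <- out2$panel[order(out2$panel$id), ]
  rownames(m1) <- rownames(m2) <- NULL
  expect_equal(m1, m2)
})

test_that("prevalence percentages equal round(100 c/n, 1) exactly", {
  mk <- function(n, cases, label) data.frame(
    id = paste(label, seq_len(n)), group = label,
    pad_status = rep(c(1L, 0L), c(cases, n - cases)))
  ph <- rbind(mk(1971, 227, "Dominican"), mk(5343, 608, "PuertoRican"),
              mk(2051, 35, "EastSEAsian"))
  tab <- prevalence_table(ph)
  expect_equal(tab$prevalence_pct,
               round(100 * tab$cases / tab$n, 1))
  expect_equal(tab$prevalence_pct[tab$group == "Dominican"], 11.5)
  expect_lt(attr(tab, "p_value"), 1e-10)
  # zero cases render as 0.0%
  tab0 <- prevalence_table(mk(50, 0, "Z"))
  expect_equal(tab0$prevalence_pct, 0)
})

test_that("case-control variable tests use chi-squared and rank-sum", {
  set.seed(32)
  ph <- data.frame(pad_status = rbinom(400, 1, 0.3))
  ph$age <- 50 + 10 * ph$pad_status + rnorm(400, 0, 5)
  ph$smoker <- rbinom(400, 1, 0.2 + 0.3 * ph$pad_status)
  expect_lt(case_control_test(ph, "age", "continuous")$p_value, 1e-6)
  expect_lt(case_control_test(ph, "smoker", "discrete")$p_value, 1e-3)
  ph$noise <- rnorm(400)
  expect_gt(case_control_test(ph, "noise", "continuous")$p_value, 0.001)
})

test_that("matched groups give odds ratios near one", {
  set.seed(33)
  n <- 2000
  ph <- data.frame(id = seq_len(n), pad_status = rbinom(n, 1, 0.1),
                   group = rep(c("REF", "ALT"), n / 2),
                   age = rnorm(n, 55, 8), sex = rbinom(n, 1, 0.5),
                   bmi = rnorm(n), t2d = rbinom(n, 1, 0.2), tg = rnorm(n),
                   tc = rnorm(n), hdl = rnorm(n))
  res <- group_risk_models(ph, reference = "REF")
  expect_equal(nrow(res), 3L)
  expect_true(all(res$lo < 1 & res$hi > 1))
})

test_that("group effects are recovered with nominal CI coverage", {
  cover <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    set.seed(40 + r)
    n_ref <- 3000; n_grp <- 1971
    lp <- c(rep(qlogis(0.04), n_ref), rep(qlogis(0.04) + log(3.15), n_grp))
    ph <- data.frame(id = seq_len(n_ref + n_grp),
                     pad_status = rbinom(n_ref + n_grp, 1, plogis(lp)),
                     group = rep(c("REF", "DOM"), c(n_ref, n_grp)),
                     age = rnorm(n_ref + n_grp, 55, 8),
                     sex = rbinom(n_ref + n_grp, 1, 0.5))
    res <- group_risk_models(ph, reference = "REF", models = 1)
    if (res$lo <= 3.15 && res$hi >= 3.15) cover <- cover + 1
  }
  expect_gte(cover, 16)  # nominal 95%
})

test_that("nested risk models have monotone log-likelihood", {
  co <- shared_cohort()
  ph <- co$pheno
  ph$group <- rep(c("REF", "DOM"), length.out = nrow(ph))
  rows <- ph[stats::complete.cases(ph), ]
  lls <- vapply(1:3, function(m) {
    covs <- admixscan:::risk_model_covariates(m)
    X <- cbind(group = as.numeric(rows$group == "DOM"),
               build_design(rows, covs))
    f <- fit_logistic(rows$pad_status, X)
    loglik_from_fit(f, rows$pad_status, X)
  }, numeric(1))
  expect_true(all(diff(lls) >= -1e-8))
})

test_that("a group with no cases is flagged rather than estimated", {
  ph <- data.frame(id = 1:300,
                   pad_status = c(rbinom(150, 1, 0.2), rep(0L, 150)),
                   group = rep(c("REF", "EMPTY"), each = 150),
                   age = rnorm(300, 50, 5), sex = rbinom(300, 1, 0.5))
  res <- group_risk_models(ph, reference = "REF", models = 1)
  expect_equal(res$status, "skipped:no_cases_in_group")
  expect_true(is.na(res$or))
})
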