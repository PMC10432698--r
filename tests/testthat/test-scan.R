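# Oracle for the single-binary-predictor logistic fit: the 2x2 closed form
# beta = log(ad/bc), se = sqrt(1/a + 1/b + 1/c + 1/d).
two_by_two <- function(case_exp, case_unexp, ctrl_exp, ctrl_unexp) {
  list(beta = log(case_exp * ctrl_unexp / (case_unexp * ctrl_exp)),
       se = sqrt(1 / case_exp + 1 / case_unexp + 1 / ctrl_exp +
                   1 / ctrl_unexp))
}

counts_to_data <- function(case_exp, case_unexp, ctrl_exp, ctrl_unexp) {
  y <- rep(c(1, 1, 0, 0), c(case_exp, case_unexp, ctrl_exp, ctrl_unexp))
  x <- rep(c(1, 0, 1, 0), c(case_exp, case_unexp, ctrl_exp, ctrl_unexp))
  list(y = y, x = x)
}

test_that("la_dosages counts haplotypes of the requested ancestry", {
  la <- tiny_la()
  expect_equal(unname(la_dosages(la, "NAT")[2, ]), rep(2L, 4))
  # ind A locus 3: one AFR + one AFR -> AFR 2; locus 1: EUR 1, AFR 1
  expect_equal(unname(la_dosages(la, "AFR")[1, 1]), 1L)
  expect_equal(unname(la_dosages(la, "EUR")[1, 1]), 1L)
  expect_equal(unname(la_dosages(la, "NAT")[1, 1]), 0L)
  expect_error(la_dosages(la, "XXX"), "unknown ancestry")
})

test_that("logistic fit matches the 2x2 closed form to six decimals", {
  oracle <- two_by_two(40, 60, 100, 300)
  d <- counts_to_data(40, 60, 100, 300)
  f <- fit_logistic(d$y, cbind(exposed = d$x))
  expect_equal(f$status, "ok")
  expect_equal(f$coef$beta[2], oracle$beta, tolerance = 1e-7)
  expect_equal(f$coef$se[2], oracle$se, tolerance = 1e-7)
  expect_equal(f$coef$beta[2], log(2), tolerance = 1e-7)
  expect_equal(f$coef$se[2], 0.2345208, tolerance = 1e-6)
})

test_that("degenerate responses and separation are refused or flagged", {
  expect_error(fit_logistic(rep(1, 50), cbind(rnorm(50))), "single class")
  # perfectly separated predictor
  y <- rep(c(0, 1), each = 25)
  f <- fit_logistic(y, cbind(x = y * 2 - 1))
  expect_true(f$status %in% c("separation", "nonconvergence"))
  expect_true(all(is.na(f$coef$beta)))
})

test_that("compiled scan reproduces per-locus glm fits", {
  co <- shared_cohort()
  res <- admixture_scan(co$la, co$pheno, ancestries = "AFR")
  d <- la_dosages(co$la, "AFR")
  X0 <- cbind(sex = co$pheno$sex,
              array = as.numeric(co$pheno$array == "OMNI"))
  for (j in c(3, 101, 500)) {
    f <- fit_logistic(co$pheno$pad_status, cbind(dos = d[, j], X0))
    expect_equal(res$beta[j], f$coef$beta[2], tolerance = 1e-5)
    expect_equal(res$se[j], f$coef$se[2], tolerance = 1e-5)
  }
})

test_that("null per-test p-values are uniform (KS over independent fits)", {
  set.seed(11)
  n <- 300
  y <- rbinom(n, 1, 0.3)
  D <- matrix(rbinom(n * 5000, 2, 0.3), nrow = n)
  cfg <- scan_config(covariates = character(0))
  keys <- data.frame(chrom = "1", pos_bp = seq_len(ncol(D)),
                     key = as.character(seq_len(ncol(D))))
  ph <- data.frame(id = as.character(seq_len(n)), pad_status = y)
  res <- snp_scan(genotype_matrix(`rownames<-`(D, ph$id),
                                  data.frame(chrom = "1",
                                             pos_bp = seq_len(ncol(D)),
                                             id = as.character(seq_len(ncol(D))),
                                             ref = "A", alt = "C")),
                  ph, cfg)
  p <- res$p[res$status == "ok"]
  expect_gt(length(p), 4500)
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
})

test_that("for K = 2 the two ancestry scans are mirror images", {
  cfg <- admixture_config(q = c(A = 0.5, B = 0.5), g = 8, n_individuals = 300,
                          map = default_map(chrom_cM = c("1" = 40)), seed = 12)
  la <- simulate_local_ancestry(cfg)
  ph <- simulate_phenotypes(la, model = phenotype_model(intercept = qlogis(0.3)),
                            seed = 12)
  res <- admixture_scan(la, ph)
  za <- with(res[res$predictor == "A" & res$status == "ok", ], beta / se)
  zb <- with(res[res$predictor == "B" & res$status == "ok", ], beta / se)
  expect_equal(za, -zb, tolerance = 1e-6)
})

test_that("low-carrier loci are skipped with a machine-readable reason", {
  co <- shared_cohort()
  cfg <- scan_config(min_carriers = 10)
  d <- la_dosages(co$la, "NAT")
  res <- admixture_scan(co$la, co$pheno, cfg, ancestries = "NAT")
  low <- pmin(colSums(d > 0), colSums(d < 2)) < 10
  expect_true(all(res$status[low] != "ok"))
  expect_true(all(grepl("^skipped:", res$status[low])))
  expect_true(all(res$status[!low] == "ok"))
})

test_that("monomorphic and rare variants are excluded from the SNP scan", {
  co <- shared_cohort()
  la <- co$la
  vm <- variant_model(chrom = rep("1", 2), pos_bp = la$map$pos_bp[c(10, 20)],
                      id = c("mono", "common"),
                      f = rbind(c(0, 0, 0), c(0.3, 0.3, 0.3)))
  geno <- simulate_genotypes(la, vm, seed = 13)
  res <- snp_scan(geno, co$pheno)
  expect_equal(res$status[res$key == "mono"], "skipped:maf")
  expect_equal(res$status[res$key == "common"], "ok")
})

test_that("carrier prevalence reproduces the printed 2x2 odds ratio", {
  # counts constructed to match 22.6% carrier vs 12.9% non-carrier prevalence
  dosage <- rep(c(1, 0), c(500, 1000))
  y <- rep(c(1, 0, 1, 0), c(113, 387, 129, 871))
  cp <- carrier_prevalence(dosage, y)
  expect_equal(cp$table$prevalence[2], 0.226)
  expect_equal(cp$table$prevalence[1], 0.129)
  expect_equal(unname(cp$or_het["or"]), (113 * 871) / (387 * 129),
               tolerance = 1e-10)
  expect_equal(unname(round(cp$or_het["or"], 2)), 1.97)
  expect_false(cp$table$tested[3])  # no homozygous carriers
})

test_that("carrier prevalence handles degenerate tables", {
  cp0 <- carrier_prevalence(rep(c(0, 1), each = 50), rep(0, 100))
  expect_true(all(cp0$table$prevalence[cp0$table$n > 0] == 0))
  expect_true(is.na(cp0$or_het["or"]))
  cp1 <- carrier_prevalence(rep(c(0, 1), each = 100),
                            rep(c(1, 0, 1, 0), c(20, 80, 20, 80)))
  expect_equal(unname(cp1$or_het["or"]), 1)
})

test_that("inverse-variance meta-analysis matches closed forms", {
  a <- data.frame(key = "v", beta = 0.3, se = 0.15)
  m <- meta_analyze(a, a)
  expect_equal(m$beta, 0.3)
  expect_equal(m$se, 0.15 / sqrt(2))
  b1 <- data.frame(key = "v", beta = 0.2, se = 0.1)
  b2 <- data.frame(key = "v", beta = 0.6, se = 0.2)
  m2 <- meta_analyze(b1, b2)
  expect_equal(m2$beta, 0.28, tolerance = 1e-12)
  expect_equal(m2$se, sqrt(1 / 125), tolerance = 1e-12)
  expect_equal(m2$se, 0.0894, tolerance = 1e-3)
})

test_that("meta-analysis harmonizes alleles and flags single-study variants", {
  a <- data.frame(key = c("v1", "v2", "v3"), beta = c(0.2, 0.1, 0.4),
                  se = c(0.1, 0.1, 0.1), ref = c("A", "A", "A"),
                  alt = c("G", "T", "G"))
  b <- data.frame(key = c("v1", "v2"), beta = c(-0.2, 0.1),
                  se = c(0.1, 0.1), ref = c("G", "A"), alt = c("A", "T"))
  m <- meta_analyze(a, b)
  # v1 flipped in study b: effects agree after harmonization
  expect_equal(m$beta[m$key == "v1"], 0.2)
  expect_equal(attr(m, "log")$flipped, "v1")
  # v2 is strand-ambiguous (A/T): dropped
  expect_false("v2" %in% m$key[m$status == "ok"])
  expect_equal(attr(m, "log")$ambiguous, "v2")
  expect_equal(m$status[m$key == "v3"], "single-study")
})
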