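test_that("a single ancestry yields constant haplotypes with no switches", {
  cfg <- admixture_config(q = c(ANC = 1), g = 5, n_individuals = 5,
                          map = default_map(chrom_cM = c("1" = 50)), seed = 1)
  la <- simulate_local_ancestry(cfg)
  expect_true(all(la$codes == 0L))
})

test_that("ancestry-switch density matches g(1 - sum q^2) per Morgan", {
  # 500 individuals x 2 haplotypes x 10 Morgans = 10,000 Morgans simulated
  cfg <- admixture_config(q = c(A = 0.5, B = 0.5), g = 10,
                          n_individuals = 500,
                          map = default_map(chrom_cM = c("1" = 1000)),
                          seed = 2)
  la <- simulate_local_ancestry(cfg)
  switches <- sum(apply(la$codes, 1, function(v) sum(diff(v) != 0)))
  density <- switches / (1000 * 10)
  expect_equal(density, 10 * (1 - 0.5), tolerance = 0.02)
})

test_that("marginal ancestry at loci matches q (stationarity)", {
  co <- shared_cohort()
  gp <- global_from_local(co$la)
  means <- colMeans(gp[-1])
  se <- apply(gp[-1], 2, sd) / sqrt(nrow(gp))
  expect_true(all(abs(means - co$cfg$q) < 3 * se + 0.005))
})

test_that("tract lengths are exponential with mean 1/((1-q)g) Morgans", {
  cfg <- admixture_config(q = c(A = 0.5, B = 0.5), g = 10,
                          n_individuals = 300,
                          map = default_map(chrom_cM = c("1" = 1000)),
                          seed = 3)
  la <- simulate_local_ancestry(cfg)
  tr <- tract_lengths(la)
  expect_gt(nrow(tr$tracts), 1e4)
  expect_equal(mean(tr$tracts$length_cM), 20, tolerance = 0.05)
})

test_that("genotypes follow ancestry-specific allele frequencies", {
  co <- shared_cohort()
  la <- co$la
  loc <- 200
  vm <- variant_model(chrom = la$map$chrom[loc], pos_bp = la$map$pos_bp[loc],
                      id = c("v1", "v2"),
                      f = rbind(c(1, 1, 1), c(0.001, 0.001, 0.30)))
  geno <- simulate_genotypes(la, vm, seed = 4)
  expect_true(all(geno$dosage[, "v1"] == 2))
  # stratify haploid alleles by true tract ancestry
  hap <- attr(geno, "hap_alleles")
  anc <- la$codes[, loc]
  f_nat <- mean(hap[anc == 2L, 2])
  f_eur <- mean(hap[anc == 0L, 2])
  n_nat <- sum(anc == 2L)
  expect_equal(f_nat, 0.30, tolerance = 3 * sqrt(0.3 * 0.7 / n_nat) / 0.3)
  expect_lt(f_eur, 0.01)
  # cohort-wide frequency is the mixture sum(q_k f_k)
  mix <- sum(co$cfg$q * c(0.001, 0.001, 0.30))
  expect_equal(mean(geno$dosage[, "v2"]) / 2, mix, tolerance = 0.3)
})

test_that("variant off the map is rejected", {
  la <- tiny_la()
  vm <- variant_model("1", 999, "bad", f = matrix(c(.1, .1, .1), 1))
  expect_error(simulate_genotypes(la, vm), "off-map")
})

test_that("phenotype prevalence follows the logistic intercept", {
  co <- shared_cohort()
  ph <- simulate_phenotypes(co$la, model = phenotype_model(), seed = 5)
  n <- nrow(ph)
  expect_equal(mean(ph$pad_status), 0.135,
               tolerance = 3 * sqrt(0.135 * 0.865 / n) / 0.135)
  # degenerate intercept: all controls
  ph0 <- simulate_phenotypes(co$la, model = phenotype_model(intercept = -30),
                             seed = 5)
  expect_true(all(ph0$pad_status == 0L))
})

test_that("a planted variant effect reproduces its odds ratio", {
  # large-ish cohort for a stable 2x2; carrier OR target 4.08
  cfg <- admixture_config(n_individuals = 4000,
                          map = default_map(chrom_cM = c("1" = 20)),
                          seed = 6)
  la <- simulate_local_ancestry(cfg)
  loc <- 50
  vm <- variant_model(la$map$chrom[loc], la$map$pos_bp[loc], "risk",
                      f = matrix(c(0.001, 0.001, 0.27), 1),
                      beta = log(4.08))
  geno <- simulate_genotypes(la, vm, seed = 6)
  ph <- simulate_phenotypes(la, geno,
                            model = phenotype_model(
                              variant_beta = c(risk = log(4.08))), seed = 6)
  carrier <- geno$dosage[, 1] > 0
  tab <- table(carrier, ph$pad_status)
  lor <- log(tab[2, 2] * tab[1, 1] / (tab[2, 1] * tab[1, 2]))
  se <- sqrt(sum(1 / tab))
  expect_lt(abs(lor - log(4.08)), 3 * se)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- admixture_config(n_individuals = 20,
                          map = default_map(chrom_cM = c("1" = 30)), seed = 9)
  la1 <- simulate_local_ancestry(cfg)
  la2 <- simulate_local_ancestry(cfg)
  expect_identical(la1$codes, la2$codes)
  vm <- variant_model(la1$map$chrom[10], la1$map$pos_bp[10], "v",
                      f = matrix(c(.2, .4, .6), 1))
  expect_identical(simulate_genotypes(la1, vm, seed = 9)$dosage,
                   simulate_genotypes(la2, vm, seed = 9)$dosage)
  expect_identical(simulate_phenotypes(la1, model = phenotype_model(), seed = 9),
                   simulate_phenotypes(la2, model = phenotype_model(), seed = 9))
  cfg2 <- admixture_config(n_individuals = 20,
                           map = default_map(chrom_cM = c("1" = 30)), seed = 10)
  expect_false(identical(simulate_local_ancestry(cfg2)$codes, la1$codes))
})
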