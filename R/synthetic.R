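# Synthetic admixed cohorts. The generative model is single-pulse ("hybrid
# isolation") admixture: each haplotype is a continuous-time Markov chain
# along the genetic map, with ancestry switch points arriving as a Poisson
# process of rate g per Morgan and the ancestry after each switch drawn
# independently from the admixture proportions q (self-transitions allowed
# and collapsed). This yields exponential tract lengths with mean
# 1/((1 - q_k) g) Morgans for ancestry k and exp(-g d) decay of
# local-ancestry dosage correlation with genetic distance d -- the two
# properties the threshold machinery relies on.

#' Default autosomal genetic map
#'
#' 22 autosomes with realistic sex-averaged genetic lengths (total
#' approximately 3,545 cM) and loci on a regular genetic grid, mirroring
#' local-ancestry calls pruned to one locus per 0.2 cM window. Physical
#' positions use a nominal 1 cM = 1 Mb.
#'
#' @param spacing_cM genetic distance between adjacent loci (default 0.2).
#' @param chrom_cM named numeric vector of chromosome genetic lengths in cM;
#'   default all 22 autosomes. Subset (e.g. `default_map(chrom_cM =
#'   c("1" = 150, "2" = 150))`) for smaller simulations.
#' @return A [genetic_map()].
#' @export
default_map <- function(spacing_cM = 0.2, chrom_cM = NULL) {
  if (is.null(chrom_cM)) {
    chrom_cM <- c(286.3, 268.8, 223.4, 214.6, 204.1, 192.0, 187.2, 168.0,
                  166.4, 181.1, 158.2, 174.7, 125.7, 120.2, 141.9, 134.0,
                  128.5, 117.2, 107.9, 108.3, 62.8, 74.1)
    names(chrom_cM) <- as.character(1:22)
  }
  pieces <- lapply(names(chrom_cM), function(ch) {
    cm <- seq(0, chrom_cM[[ch]], by = spacing_cM)
    data.frame(chrom = ch, pos_bp = as.integer(round(cm * 1e6)) + 1L,
               pos_cM = cm, stringsAsFactors = FALSE)
  })
  m <- do.call(rbind, pieces)
  genetic_map(m$chrom, m$pos_bp, m$pos_cM)
}

#' Admixture simulation configuration
#'
#' Defaults emulate the Dominican study cohort: three-way EUR/AFR/NAT
#' admixture with proportions (0.56, 0.37, 0.06), a single admixture pulse
#' g = 9.73 generations ago, and 1,813 individuals.
#'
#' @param q named ancestry proportions (must sum to 1).
#' @param g generations since admixture (switch intensity per Morgan).
#' @param n_individuals cohort size.
#' @param map a [genetic_map()]; default [default_map()].
#' @param seed master seed; per-stage streams are derived from it.
#' @return An `admixture_config` list.
#' @export
admixture_config <- function(q = c(EUR = 0.56, AFR = 0.37, NAT = 0.06),
                             g = 9.73, n_individuals = 1813,
                             map = default_map(), seed = 1L) {
  if (any(q < 0) || abs(sum(q) - 1) > 0.02)
    stop("q must be >= 0 and sum to 1")
  q <- q / sum(q)  # absorb printed-proportion rounding (e.g. 0.56/0.37/0.06)
  if (g <= 0) stop("g must be positive")
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  if (is.null(names(q))) names(q) <- paste0("ANC", seq_along(q))
  structure(list(q = q, g = g, n_individuals = as.integer(n_individuals),
                 map = map, seed = as.integer(seed)),
            class = "admixture_config")
}

#' Simulate local-ancestry tracts under pulse admixture
#'
#' Each haplotype on each chromosome starts from an ancestry drawn from `q`,
#' and switches ancestry at Poisson(g per Morgan) points, the new state
#' drawn from `q` (self-transitions collapsed). Deterministic given
#' `config$seed`.
#'
#' @param config an [admixture_config()].
#' @return A [local_ancestry()] object.
#' @export
simulate_local_ancestry <- function(config) {
  stopifnot(inherits(config, "admixture_config"))
  set.seed(derive_seed(config$seed, "local_ancestry"))
  map <- config$map
  K <- length(config$q)
  q <- as.numeric(config$q)
  n <- config$n_individuals
  H <- 2L * n
  codes <- matrix(NA_integer_, nrow = H, ncol = nrow(map))
  for (ch in unique(map$chrom)) {
    li <- which(map$chrom == ch)
    cm <- map$pos_cM[li]
    rel_M <- (cm - cm[1]) / 100
    L_M <- rel_M[length(rel_M)]
    n_ev <- rpois(H, config$g * L_M)
    for (h in seq_len(H)) {
      ne <- n_ev[h]
      states <- sample.int(K, ne + 1L, replace = TRUE, prob = q) - 1L
      if (ne == 0L) {
        codes[h, li] <- states
      } else {
        bp <- sort(runif(ne, 0, L_M))
        codes[h, li] <- states[findInterval(rel_M, bp) + 1L]
      }
    }
  }
  ids <- sprintf("IND%04d", seq_len(n))
  local_ancestry(codes, ids, map, names(config$q))
}

#' Define simulated variants with ancestry-specific allele frequencies
#'
#' @param chrom,pos_bp variant coordinates (must coincide with map loci of
#'   the local-ancestry matrix they are simulated on).
#' @param id variant identifiers.
#' @param f numeric matrix `V x K` of alt-allele frequencies per ancestry
#'   (columns in the ancestry order of the target cohort).
#' @param beta per-variant log-odds effect on disease (default 0).
#' @return A `variant_model` data.frame with an `f` matrix attribute.
#' @export
variant_model <- function(chrom, pos_bp, id, f, beta = 0) {
  f <- matrix(f, nrow = length(id))
  if (any(f < 0 | f > 1)) stop("allele frequencies must lie in [0,1]")
  vm <- data.frame(chrom = as.character(chrom), pos_bp = as.integer(pos_bp),
                   id = as.character(id), beta = rep_len(beta, length(id)),
                   stringsAsFactors = FALSE)
  attr(vm, "f") <- f
  class(vm) <- c("variant_model", "data.frame")
  vm
}

#' Simulate genotypes conditional on local ancestry
#'
#' Each haploid allele is Bernoulli with the frequency of that haplotype's
#' ancestry at the variant position; the diploid dosage is the sum of the
#' two draws. The returned object keeps the haploid allele matrix as
#' attribute `hap_alleles` (simulated truth used e.g. by
#' [tract_frequency()]).
#'
#' @param la a [local_ancestry()].
#' @param variants a [variant_model()]; positions must be loci of `la$map`.
#' @param seed integer seed.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(la, variants, seed = 1L) {
  set.seed(derive_seed(seed, "genotypes"))
  key_map <- paste(la$map$chrom, la$map$pos_bp)
  j <- match(paste(variants$chrom, variants$pos_bp), key_map)
  if (anyNA(j))
    stop("variant off-map: ", paste(variants$id[is.na(j)], collapse = ", "))
  f <- attr(variants, "f")
  H <- nrow(la$codes)
  n <- H / 2L
  V <- nrow(variants)
  hap <- matrix(0L, nrow = H, ncol = V)
  for (v in seq_len(V)) {
    anc <- la$codes[, j[v]]
    hap[, v] <- rbinom(H, 1L, f[v, anc + 1L])
  }
  odd <- seq(1L, H, by = 2L)
  dos <- hap[odd, , drop = FALSE] + hap[odd + 1L, , drop = FALSE]
  rownames(dos) <- la$individuals
  g <- genotype_matrix(dos, data.frame(chrom = variants$chrom,
                                       pos_bp = variants$pos_bp,
                                       id = variants$id,
                                       ref = "A", alt = "C",
                                       stringsAsFactors = FALSE))
  colnames(g$dosage) <- variants$id
  attr(g, "hap_alleles") <- hap
  attr(g, "la_locus") <- j
  g
}

#' Phenotype-generating model
#'
#' Log-odds of case status are `intercept + covariate terms + variant terms
#' + optional direct local-ancestry term`. Covariates are generated:
#' sex ~ Bernoulli(0.5), array ~ Bernoulli(0.5) (OMNI/MEGA), age ~
#' Normal(55, 10) entered as a z-score, biomarkers (bmi, tg, tc, hdl) ~
#' Normal(0, 1) z-scores, t2d ~ Bernoulli(0.2).
#'
#' @param intercept baseline log-odds (default `qlogis(0.135)`, the
#'   non-carrier anchor prevalence).
#' @param sex,array,age,bmi,t2d,tg,tc,hdl covariate log-odds effects.
#' @param variant_beta named vector of per-alt-allele log-odds, names =
#'   variant ids (overrides the `beta` column of the variant model).
#' @param la_effect optional `list(chrom, pos_bp, ancestry, beta)`: a direct
#'   log-odds effect of the ancestry dosage at one locus.
#' @return A `phenotype_model` list.
#' @export
phenotype_model <- function(intercept = qlogis(0.135), sex = 0, array = 0,
                            age = 0, bmi = 0, t2d = 0, tg = 0, tc = 0,
                            hdl = 0, variant_beta = NULL, la_effect = NULL) {
  structure(list(intercept = intercept, sex = sex, array = array, age = age,
                 bmi = bmi, t2d = t2d, tg = tg, tc = tc, hdl = hdl,
                 variant_beta = variant_beta, la_effect = la_effect),
            class = "phenotype_model")
}

#' Simulate case-control phenotypes and covariates
#'
#' @param la a [local_ancestry()].
#' @param geno a [genotype_matrix()] from [simulate_genotypes()], or `NULL`.
#' @param model a [phenotype_model()].
#' @param seed integer seed.
#' @return A phenotype data.frame (id, pad_status, sex, array, age, bmi,
#'   t2d, tg, tc, hdl, group) with attribute `prevalence`.
#' @export
simulate_phenotypes <- function(la, geno = NULL, model = phenotype_model(),
                                seed = 1L) {
  set.seed(derive_seed(seed, "phenotypes"))
  n <- length(la$individuals)
  sex <- rbinom(n, 1L, 0.5)
  array <- ifelse(rbinom(n, 1L, 0.5) == 1L, "MEGA", "OMNI")
  age <- rnorm(n, 55, 10)
  bmi <- rnorm(n); t2d <- rbinom(n, 1L, 0.2)
  tg <- rnorm(n); tc <- rnorm(n); hdl <- rnorm(n)
  lp <- model$intercept + model$sex * sex + model$array * (array == "MEGA") +
    model$age * (age - 55) / 10 + model$bmi * bmi + model$t2d * t2d +
    model$tg * tg + model$tc * tc + model$hdl * hdl
  if (!is.null(model$variant_beta)) {
    if (is.null(geno)) stop("variant effects given but no genotypes")
    vb <- model$variant_beta
    miss <- setdiff(names(vb), colnames(geno$dosage))
    if (length(miss)) stop("unknown variant in model: ", paste(miss, collapse = ", "))
    lp <- lp + as.vector(geno$dosage[, names(vb), drop = FALSE] %*% vb)
  }
  if (!is.null(model$la_effect)) {
    le <- model$la_effect
    j <- which(la$map$chrom == as.character(le$chrom) &
                 la$map$pos_bp == le$pos_bp)
    if (!length(j)) stop("la_effect locus not on map")
    k <- match(le$ancestry, la$ancestries) - 1L
    if (is.na(k)) stop("la_effect ancestry not in cohort")
    dos <- la_dosages(la, le$ancestry)
    lp <- lp + le$beta * dos[, j[1]]
  }
  y <- rbinom(n, 1L, plogis(lp))
  out <- data.frame(id = la$individuals, pad_status = y, sex = sex,
                    array = array, age = age, bmi = bmi, t2d = t2d, tg = tg,
                    tc = tc, hdl = hdl, group = "SIM",
                    stringsAsFactors = FALSE)
  attr(out, "prevalence") <- mean(y)
  out
}

#' Simulate a full cohort (ancestry, genotypes, phenotypes)
#'
#' Convenience wrapper deriving independent seeds for each stage from
#' `config$seed`.
#'
#' @param config an [admixture_config()].
#' @param variants optional [variant_model()].
#' @param model a [phenotype_model()].
#' @return list with `la`, `geno` (or NULL), `pheno`.
#' @export
simulate_cohort <- function(config, variants = NULL,
                            model = phenotype_model()) {
  la <- simulate_local_ancestry(config)
  geno <- if (!is.null(variants))
    simulate_genotypes(la, variants, seed = config$seed)
  if (is.null(model$variant_beta) && !is.null(variants) &&
      any(variants$beta != 0)) {
    vb <- variants$beta
    names(vb) <- variants$id
    model$variant_beta <- vb[vb != 0]
  }
  pheno <- simulate_phenotypes(la, geno, model, seed = config$seed)
  list(la = la, geno = geno, pheno = pheno)
}
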