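.is_psd <- function(S, tol = 1e-8) {
  S <- as.matrix(S)
  isSymmetric(S, tol = 1e-8) &&
    min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) >=
      -tol * max(1, max(abs(S)))
}

# default additive covariance of (scale, ramp, offset, decay) on natural
# units; variances follow the primiparous variance-component report, the
# offset variance is a nuisance choice, correlations are mild
.default_genetic_cov <- function() {
  s <- sqrt(c(scale_a = 7.58, ramp_b = 0.0056, offset_c = 4.0,
              decay_d = 2.228e-8))
  R <- diag(4)
  dimnames(R) <- list(names(s), names(s))
  R["scale_a", "ramp_b"] <- R["ramp_b", "scale_a"] <- 0.10
  R["scale_a", "decay_d"] <- R["decay_d", "scale_a"] <- -0.35
  R["ramp_b", "decay_d"] <- R["decay_d", "ramp_b"] <- 0.10
  diag(s) %*% R %*% diag(s) -> S
  dimnames(S) <- list(names(s), names(s))
  S
}

#' Simulation configuration for a synthetic dairy population
#'
#' Bundles and validates every knob of the synthetic-data generator:
#' population structure, marker panel, genetic architecture of the four
#' MilkBot parameters, environmental structure (herd-year-season, country,
#' age at calving acting on the curve's scale), and the test-day recording
#' scheme. Defaults emulate a pedigreed multi-herd Holstein population
#' with primiparous curve means (scale 35.57 kg/day, ramp 30.60 d, offset
#' 0 d, decay 0.00142 /day) and additive variances taken from the
#' primiparous variance-component report.
#'
#' @param n_founders,n_generations,n_per_generation pedigree structure
#'   (see [simulate_pedigree()])
#' @param n_snp,n_chromosomes,chromosome_length_bp,founder_maf_range,n_founder_haplotypes
#'   marker panel (see [drop_genotypes()])
#' @param n_qtl number of markers acting as QTL
#' @param qtl_variance_fraction fraction of each parameter's additive
#'   variance contributed by the QTL (remainder is polygenic)
#' @param trait_means primiparous means of (scale_a, ramp_b, offset_c,
#'   decay_d); `trait_means_multi` the multiparous means
#' @param genetic_covariance 4x4 additive covariance of the parameters
#' @param pe_covariance 4x4 permanent-environment covariance (shared
#'   across a cow's lactations)
#' @param te_covariance 4x4 temporary-environment covariance (drawn anew
#'   each lactation)
#' @param residual_sd_milk test-day measurement noise, kg/day
#' @param herds,years,seasons,countries contemporary-group structure
#'   (season = calendar quarter of calving: 4 levels)
#' @param hys_sd,country_sd SD of herd-year-season and country effects on
#'   the scale parameter, kg/day
#' @param age_mean,age_sd age at first calving, months
#' @param age_b1,age_b2 linear/quadratic effect of (age - age_mean) on the
#'   scale parameter, kg/day per month (and per month^2)
#' @param test_day_schedule DIM at which test-day records are taken
#' @param parity_distribution probabilities of a cow's final parity
#'   (1, 2, ...)
#' @param seed RNG seed for the whole run
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(n_founders = 200L, n_generations = 3L,
                       n_per_generation = 500L,
                       n_snp = 2000L, n_chromosomes = 5L,
                       chromosome_length_bp = 1e8,
                       founder_maf_range = c(0.05, 0.5),
                       n_founder_haplotypes = Inf,
                       n_qtl = 20L, qtl_variance_fraction = 0.3,
                       trait_means = c(scale_a = 35.57, ramp_b = 30.60,
                                       offset_c = 0, decay_d = 0.00142),
                       trait_means_multi = c(scale_a = 49.79, ramp_b = 23.27,
                                             offset_c = 0, decay_d = 0.00259),
                       genetic_covariance = .default_genetic_cov(),
                       pe_covariance = diag(c(4.85, 0.0145, 1.0, 1.143e-8)),
                       te_covariance = diag(c(30, 3.9, 2.0, 1.9e-7)),
                       residual_sd_milk = 2.0,
                       herds = 10L, years = 3L, seasons = 4L, countries = 4L,
                       hys_sd = 2.0, country_sd = 1.5,
                       age_mean = 26, age_sd = 2.5,
                       age_b1 = 0.25, age_b2 = -0.02,
                       test_day_schedule = seq(5, 305, by = 30),
                       parity_distribution = c(0.47, 0.25, 0.18, 0.10),
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(n_founders, n_generations + 1, n_per_generation, n_snp,
              n_chromosomes, herds, years, seasons, countries)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (n_qtl < 0) stop("n_qtl must be non-negative")
  stopifnot(founder_maf_range[1] > 0, founder_maf_range[2] <= 0.5,
            qtl_variance_fraction >= 0, qtl_variance_fraction <= 1)
  if (!.is_psd(genetic_covariance))
    stop("genetic_covariance must be symmetric positive semidefinite")
  if (!.is_psd(pe_covariance))
    stop("pe_covariance must be symmetric positive semidefinite")
  if (!.is_psd(te_covariance))
    stop("te_covariance must be symmetric positive semidefinite")
  stopifnot(abs(sum(parity_distribution) - 1) < 1e-8)
  structure(cfg, class = "sim_config")
}

.rmvnorm <- function(n, Sigma) {
  Sigma <- as.matrix(Sigma)
  ev <- eigen(Sigma, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(Sigma))
  matrix(stats::rnorm(n * nrow(Sigma)), n) %*% t(L)
}

#' Simulate true breeding values: QTL effects plus polygenic background
#'
#' A subset of markers act as QTL with effects drawn jointly normal across
#' traits (covariance proportional to `covariance`), rescaled so the
#' realized variance of the QTL genetic score equals `qtl_fraction` of
#' each trait's additive variance in the simulated sample. The polygenic
#' remainder is dropped through the pedigree with Mendelian-sampling
#' variance (1 - (F_s + F_d)/2)/2 times the polygenic covariance.
#'
#' @param ped ordered pedigree
#' @param genotypes `genotype_set` aligned with `ped`
#' @param covariance k x k additive covariance of the traits
#' @param qtl_fraction fraction of additive variance from QTL
#' @param n_qtl number of QTL markers
#' @param Fcoef optional precomputed inbreeding coefficients
#' @param seed optional RNG seed
#' @return list: `bv` (animals x traits), `qtl_idx` (marker indices),
#'   `qtl_effects` (n_qtl x traits, allele substitution effects),
#'   `polygenic` (animals x traits)
#' @export
simulate_breeding_values <- function(ped, genotypes, covariance,
                                     qtl_fraction = 0.3, n_qtl = 20L,
                                     Fcoef = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  covariance <- as.matrix(covariance)
  k <- nrow(covariance)
  n <- nrow(ped)
  M <- genotypes$dosage
  stopifnot(nrow(M) == n)
  qtl_part <- matrix(0, n, k)
  qtl_idx <- integer(0)
  alpha <- matrix(0, 0, k)
  if (qtl_fraction > 0 && n_qtl > 0) {
    poly_snp <- which(apply(M, 2, stats::var) > 0)
    if (length(poly_snp) < n_qtl)
      stop("not enough polymorphic markers to place ", n_qtl, " QTL")
    qtl_idx <- sort(sample(poly_snp, n_qtl))
    alpha <- .rmvnorm(n_qtl, covariance)
    Zq <- scale(M[, qtl_idx, drop = FALSE], center = TRUE, scale = FALSE)
    score <- Zq %*% alpha
    sc <- sqrt(qtl_fraction * diag(covariance) /
                 pmax(apply(score, 2, stats::var), 1e-300))
    alpha <- sweep(alpha, 2, sc, `*`)
    qtl_part <- sweep(score, 2, sc, `*`)
  }
  poly_cov <- (1 - qtl_fraction) * covariance
  if (is.null(Fcoef)) Fcoef <- diag(a_matrix(ped)) - 1
  par <- .check_ordered_pedigree(ped)
  pg <- matrix(0, n, k)
  founder_dev <- .rmvnorm(n, poly_cov)  # used where a parent is unknown
  for (i in seq_len(n)) {
    s <- par$sire[i]; d <- par$dam[i]
    if (s == 0 && d == 0) {
      pg[i, ] <- founder_dev[i, ]
    } else {
      mid <- 0.5 * ((if (s > 0) pg[s, ] else 0) + (if (d > 0) pg[d, ] else 0))
      fbar <- mean(c(if (s > 0) Fcoef[s] else 0, if (d > 0) Fcoef[d] else 0))
      ms <- .rmvnorm(1, 0.5 * (1 - fbar) * poly_cov)
      pg[i, ] <- mid + ms
    }
  }
  bv <- qtl_part + pg
  rownames(bv) <- rownames(pg) <- ped$animal
  list(bv = bv, qtl_idx = qtl_idx, qtl_effects = alpha, polygenic = pg)
}

# contemporary-group assignment shared by the trait- and lactation-level
# simulators: herds nested in countries, effects drawn once per level
.sim_environment <- function(animal, cfg) {
  n <- length(animal)
  herd <- sample.int(cfg$herds, n, replace = TRUE)
  country_of_herd <- sample.int(cfg$countries, cfg$herds, replace = TRUE)
  country <- country_of_herd[herd]
  year <- sample.int(cfg$years, n, replace = TRUE)
  season <- sample.int(cfg$seasons, n, replace = TRUE)
  hys <- interaction(herd, year, season, drop = TRUE)
  hys_eff <- stats::rnorm(nlevels(hys), 0, cfg$hys_sd)
  country_eff <- stats::rnorm(cfg$countries, 0, cfg$country_sd)
  age <- stats::rnorm(n, cfg$age_mean, cfg$age_sd)
  data.frame(animal = animal, herd = herd, year = year, season = season,
             hys = as.character(hys), country = country,
             age_calving = age,
             env_effect = hys_eff[as.integer(hys)] + country_eff[country] +
               cfg$age_b1 * (age - cfg$age_mean) +
               cfg$age_b2 * (age - cfg$age_mean)^2)
}

#' Simulate single-trait phenotypes with known variance components
#'
#' Direct simulation of one quantitative trait (e.g. 305-day milk yield)
#' on a pedigreed, genotyped population: y = mu + HYS + country +
#' b1 (age - age_mean) + b2 (age - age_mean)^2 + a + e, with the additive
#' value a built from marker QTL plus a pedigree-dropped polygenic term
#' scaled to `sigma_a2`, and e iid N(0, `sigma_e2`). Used for variance
#' component recovery studies where the trait's additive and residual
#' variances are the quantities of interest.
#'
#' @param ped ordered pedigree
#' @param genotypes `genotype_set` aligned with `ped`
#' @param sigma_a2 true additive genetic variance (trait units^2)
#' @param sigma_e2 true residual variance
#' @param phenotyped animal ids with records (default: non-founders)
#' @param mean overall mean mu
#' @param hys_sd,country_sd,age_b1,age_b2 fixed-effect magnitudes in trait
#'   units (override the curve-scale defaults in `config`)
#' @param config `sim_config` supplying structure (herds, years, seasons,
#'   countries, age distribution, QTL settings)
#' @param seed optional RNG seed
#' @return list: `phenotypes` (animal, y, herd, year, season, hys,
#'   country, age_calving), `truth` (bv per animal, qtl_idx, qtl_effects,
#'   sigma_a2, sigma_e2)
#' @export
simulate_trait_phenotypes <- function(ped, genotypes, sigma_a2, sigma_e2,
                                      phenotyped = NULL, mean = 0,
                                      hys_sd = NULL, country_sd = NULL,
                                      age_b1 = NULL, age_b2 = NULL,
                                      config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  if (!is.null(hys_sd)) cfg$hys_sd <- hys_sd
  if (!is.null(country_sd)) cfg$country_sd <- country_sd
  if (!is.null(age_b1)) cfg$age_b1 <- age_b1
  if (!is.null(age_b2)) cfg$age_b2 <- age_b2
  g <- simulate_breeding_values(ped, genotypes,
                                covariance = matrix(sigma_a2, 1, 1),
                                qtl_fraction = cfg$qtl_variance_fraction,
                                n_qtl = cfg$n_qtl)
  if (is.null(phenotyped)) {
    phenotyped <- ped$animal[ped$sire != 0 | ped$dam != 0]
    if (length(phenotyped) == 0L) phenotyped <- ped$animal
  }
  idx <- match(phenotyped, ped$animal)
  env <- .sim_environment(phenotyped, cfg)
  y <- mean + env$env_effect + g$bv[idx, 1] +
    stats::rnorm(length(idx), 0, sqrt(sigma_e2))
  phen <- cbind(data.frame(animal = phenotyped, y = y),
                env[, c("herd", "year", "season", "hys", "country",
                        "age_calving")])
  list(phenotypes = phen,
       truth = list(bv = g$bv[, 1], qtl_idx = g$qtl_idx,
                    qtl_effects = g$qtl_effects,
                    sigma_a2 = sigma_a2, sigma_e2 = sigma_e2))
}

#' Simulate test-day milk records from true MilkBot curves
#'
#' Every phenotyped cow receives true curve parameters = parity-group mean
#' + additive breeding value + permanent-environment deviate (shared
#' across her lactations) + temporary-environment deviate (new each
#' lactation); herd-year-season, country and age-at-calving effects shift
#' the scale parameter. Test-day yields are the true curve evaluated at
#' the recording schedule plus iid N(0, residual_sd_milk^2) noise;
#' negative yields are truncated at 0 and flagged. Draws violating the
#' physical constraints a > 0, b > 0, d > 0 are redrawn.
#'
#' @param ped ordered pedigree
#' @param genotypes `genotype_set` aligned with `ped`
#' @param config a [sim_config()]
#' @param phenotyped animal ids with records (default: non-founder females
#'   if sex is present, else all non-founders)
#' @return list: `records` (animal, parity, dim, milk_kg, truncated),
#'   `covariates` (one row per lactation: animal, parity, herd, year,
#'   season, hys, country, age_calving), `truth` (bv matrix, per-lactation
#'   true parameters, qtl_idx, qtl_effects, pe matrix, n_truncated)
#' @export
simulate_lactations <- function(ped, genotypes, config = sim_config(),
                                phenotyped = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  g <- simulate_breeding_values(ped, genotypes, cfg$genetic_covariance,
                                qtl_fraction = cfg$qtl_variance_fraction,
                                n_qtl = cfg$n_qtl)
  if (is.null(phenotyped)) {
    cand <- ped$sire != 0 | ped$dam != 0
    if ("sex" %in% names(ped)) cand <- cand & ped$sex == "F"
    phenotyped <- ped$animal[cand]
    if (length(phenotyped) == 0L) phenotyped <- ped$animal
  }
  idx <- match(phenotyped, ped$animal)
  n <- length(idx)
  max_parity <- sample(seq_along(cfg$parity_distribution), n, replace = TRUE,
                       prob = cfg$parity_distribution)
  pe <- .rmvnorm(n, cfg$pe_covariance)
  env <- .sim_environment(phenotyped, cfg)

  recs <- list(); covs <- list(); pars <- list()
  n_trunc <- 0L
  for (i in seq_len(n)) {
    for (par_i in seq_len(max_parity[i])) {
      mu <- if (par_i == 1) cfg$trait_means else cfg$trait_means_multi
      pe_i <- if (par_i == 1) rep(0, 4) else pe[i, ]
      for (try in 1:50) {
        te <- drop(.rmvnorm(1, cfg$te_covariance))
        p <- mu + g$bv[idx[i], ] + pe_i + te
        p[1] <- p[1] + env$env_effect[i]
        if (p[1] > 0 && p[2] > 0 && p[4] > 0) break
      }
      if (p[1] <= 0 || p[2] <= 0 || p[4] <= 0)
        stop("could not draw physical curve parameters for animal ",
             phenotyped[i])
      tt <- cfg$test_day_schedule
      yield <- .mb_eval(p[1], p[2], p[3], p[4], tt) +
        stats::rnorm(length(tt), 0, cfg$residual_sd_milk)
      trunc <- yield < 0
      n_trunc <- n_trunc + sum(trunc)
      yield[trunc] <- 0
      recs[[length(recs) + 1L]] <-
        data.frame(animal = phenotyped[i], parity = par_i, dim = tt,
                   milk_kg = yield, truncated = trunc)
      covs[[length(covs) + 1L]] <-
        data.frame(animal = phenotyped[i], parity = par_i,
                   herd = env$herd[i], year = env$year[i],
                   season = env$season[i], hys = env$hys[i],
                   country = env$country[i],
                   age_calving = env$age_calving[i] + 12 * (par_i - 1))
      pars[[length(pars) + 1L]] <-
        data.frame(animal = phenotyped[i], parity = par_i,
                   scale_a = p[1], ramp_b = p[2], offset_c = p[3],
                   decay_d = p[4])
    }
  }
  list(records = do.call(rbind, recs),
       covariates = do.call(rbind, covs),
       truth = list(bv = g$bv, true_params = do.call(rbind, pars),
                    qtl_idx = g$qtl_idx, qtl_effects = g$qtl_effects,
                    pe = pe, n_truncated = n_trunc))
}

#' Simulate a complete population: pedigree, genotypes, lactations
#'
#' Convenience wrapper running [simulate_pedigree()], [drop_genotypes()]
#' and [simulate_lactations()] under one seed.
#'
#' @param config a [sim_config()]
#' @return list: `pedigree`, `genotypes`, plus everything returned by
#'   [simulate_lactations()]
#' @export
simulate_population <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  ped <- simulate_pedigree(cfg$n_founders, cfg$n_generations,
                           cfg$n_per_generation)
  geno <- drop_genotypes(ped, n_snp = cfg$n_snp,
                         n_chromosomes = cfg$n_chromosomes,
                         chromosome_length_bp = cfg$chromosome_length_bp,
                         founder_maf_range = cfg$founder_maf_range,
                         n_founder_haplotypes = cfg$n_founder_haplotypes)
  lact <- simulate_lactations(ped, geno, cfg)
  c(list(pedigree = ped, genotypes = geno), lact)
}
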