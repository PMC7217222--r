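test_that("MME solutions equal direct GLS/BLUP on a small system", {
  set.seed(1)
  ped <- simulate_pedigree(3, 2, 2, seed = 5)
  A <- a_matrix(ped)
  n <- nrow(ped)
  sa2 <- 2; se2 <- 3
  y <- drop(t(chol(sa2 * A)) %*% rnorm(n)) + rnorm(n, 0, sqrt(se2)) + 10
  dat <- data.frame(animal = ped$animal, y = y)
  mme <- build_mme(dat, "y", h_inv = a_inv_named(ped))
  sol <- solve_mme(mme, sa2, se2, keep_inverse = TRUE)
  V <- sa2 * A + se2 * diag(n)
  X <- matrix(1, n)
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  a_blup <- drop(sa2 * A %*% Vi %*% (y - X %*% b))
  expect_equal(unname(sol$fixed), drop(b), tolerance = 1e-10)
  expect_equal(unname(sol$a), unname(a_blup), tolerance = 1e-10)
  # PEV from the direct formula: Var(a - a_hat) with P = Vi - Vi X (...)
  P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X, t(X) %*% Vi)
  pev_direct <- diag(sa2 * A - sa2 * A %*% P %*% A * sa2)
  expect_equal(unname(sol$pev), unname(pev_direct), tolerance = 1e-8)
})

test_that("vanishing additive variance reduces the MME to least squares", {
  set.seed(2)
  ped <- founder_ped(40)
  x <- rnorm(40)
  grp <- rep(c("u", "v"), 20)
  y <- 3 + 2 * x + (grp == "v") + rnorm(40)
  dat <- data.frame(animal = ped$animal, y = y, grp = grp, x = x)
  mme <- build_mme(dat, "y", fixed_effects = "grp", covariates = "x",
                   h_inv = a_inv_named(ped))
  sol <- solve_mme(mme, sigma_a2 = 1e-10, sigma_e2 = 1)
  ls <- lm(y ~ grp + I(x - mean(x)) + I((x - mean(x))^2))
  expect_equal(unname(sol$fixed), unname(coef(ls)), tolerance = 1e-4)
})

test_that("the PE block has one level per animal with records", {
  ped <- founder_ped(10)
  dat <- data.frame(animal = rep(1:6, each = 2), y = rnorm(12))
  mme <- build_mme(dat, "y", h_inv = a_inv_named(ped), pe = TRUE)
  expect_equal(mme$qp, 6)
  expect_error(build_mme(dat, "y", h_inv = a_inv_named(ped), pe = FALSE),
               "repeated records")
  dat2 <- data.frame(animal = c(1, 99), y = c(1, 2))
  expect_error(build_mme(dat2, "y", h_inv = a_inv_named(ped)), "99")
})

test_that("AI-REML reproduces the closed-form balanced one-way solution", {
  set.seed(3)
  q <- 150; reps <- 4
  an <- rep(1:q, each = reps)
  u <- rnorm(q, 0, 2)
  y <- 5 + u[an] + rnorm(q * reps, 0, sqrt(6))
  ped <- founder_ped(q)
  dat <- data.frame(animal = an, y = y)
  mme <- build_mme(dat, "y", h_inv = a_inv_named(ped), pe = TRUE)
  vc <- aireml(mme)
  av <- anova(lm(y ~ factor(an)))
  ms_b <- av$`Mean Sq`[1]; ms_w <- av$`Mean Sq`[2]
  # with unrelated animals the additive and PE terms share one between-
  # animal component; their sum is the ANOVA between-animal variance
  expect_equal(vc$sigma_a2 + vc$sigma_p2, (ms_b - ms_w) / reps,
               tolerance = 1e-4)
  expect_equal(vc$sigma_e2, ms_w, tolerance = 1e-4)
  expect_true(vc$converged)
  # accepted iterations never decrease the restricted likelihood
  expect_true(all(diff(vc$trace$loglik) > -1e-6))
})

test_that("AI-REML recovers heritability and detects its absence", {
  fit_one <- function(seed) {
    set.seed(seed)
    ped <- simulate_pedigree(80, 2, 150, seed = seed)   # 380 animals
    A <- a_matrix(ped)
    n <- nrow(ped)
    bv <- drop(t(chol(4 * A)) %*% rnorm(n))
    dat <- data.frame(animal = ped$animal,
                      y = 10 + bv + rnorm(n, 0, sqrt(6)))
    list(ped = ped, bv = bv, dat = dat,
         vc = aireml(build_mme(dat, "y", h_inv = a_inv_named(ped))))
  }
  fits <- lapply(4:6, fit_one)
  h2s <- vapply(fits, function(f) f$vc$h2, numeric(1))
  expect_true(all(vapply(fits, function(f) f$vc$converged, logical(1))))
  expect_lt(abs(mean(h2s) - 0.4), 0.1)      # true h2 = 4/10
  vc <- fits[[1]]$vc
  expect_equal(vc$h2, heritability_from_components(vc$sigma_a2, vc$sigma_p2,
                                                   vc$sigma_e2)$h2,
               tolerance = 1e-12)
  ped <- fits[[1]]$ped
  bv <- fits[[1]]$bv
  n <- nrow(ped)
  dat <- fits[[1]]$dat
  set.seed(4)

  # destroying the pedigree-phenotype link drives h2 to ~0 (larger
  # population: the boundary-constrained null estimate is O(SE) > 0)
  set.seed(7)
  ped_null <- simulate_pedigree(100, 2, 300, seed = 7)   # 700 animals
  dat_null <- data.frame(animal = ped_null$animal,
                         y = 10 + rnorm(nrow(ped_null), 0, sqrt(10)))
  vc0 <- aireml(build_mme(dat_null, "y", h_inv = a_inv_named(ped_null)))
  expect_lt(vc0$h2, 0.05)

  # near-noise-free additive data drives h2 to ~1
  dat1 <- dat
  dat1$y <- 10 + bv + rnorm(n, 0, sqrt(0.004))
  vc1 <- aireml(build_mme(dat1, "y", h_inv = a_inv_named(ped)))
  expect_gt(vc1$h2, 0.95)
})

test_that("heritability arithmetic reproduces the reported ratios", {
  # primiparous 305-day milk components
  expect_equal(round(heritability_from_components(526630, 0, 892670)$h2, 2),
               0.37)
  # multiparous 305-day milk: repeatability
  r <- heritability_from_components(685000, 414700, 1498600)$repeatability
  expect_equal(round(r, 2), 0.42)
  expect_equal(heritability_from_components(0, 0, 5)$h2, 0)
  expect_error(heritability_from_components(0, 0, 0), "zero total")
})

test_that("bivariate REML: duplicated trait has genetic correlation 1", {
  set.seed(6)
  ped <- simulate_pedigree(60, 2, 80, seed = 6)
  A <- a_matrix(ped)
  bv <- drop(t(chol(2 * A)) %*% rnorm(nrow(ped)))
  y <- 10 + bv + rnorm(nrow(ped), 0, sqrt(3))
  d <- data.frame(animal = ped$animal, t1 = y, t2 = y)
  fit <- bivariate_reml(d, c("t1", "t2"), h_inv = a_inv_named(ped))
  expect_equal(fit$genetic_correlation, 1, tolerance = 1e-3)
})

test_that("bivariate REML recovers a known genetic correlation and the null", {
  run_rg <- function(seed, rg) {
    set.seed(seed)
    ped <- simulate_pedigree(150, 2, 250, seed = seed)
    A <- a_matrix(ped)
    L <- chol(A)
    G0 <- matrix(c(4, rg * sqrt(24), rg * sqrt(24), 6), 2)
    BV <- t(L) %*% matrix(rnorm(nrow(ped) * 2), ncol = 2) %*% chol(G0)
    E <- matrix(rnorm(nrow(ped) * 2), ncol = 2) %*% diag(sqrt(c(6, 8)))
    y <- sweep(BV + E, 2, c(10, 20), `+`)
    d <- data.frame(animal = ped$animal, t1 = y[, 1], t2 = y[, 2])
    bivariate_reml(d, c("t1", "t2"),
                   h_inv = a_inv_named(ped))$genetic_correlation
  }
  est <- vapply(1:3, run_rg, numeric(1), rg = 0.8)
  expect_true(all(abs(est) <= 1))
  expect_equal(mean(est), 0.8, tolerance = 0.1)
  est0 <- vapply(4:6, run_rg, numeric(1), rg = 0)
  expect_equal(mean(est0), 0, tolerance = 0.12)
})
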