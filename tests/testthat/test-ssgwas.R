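test_that("ssGBLUP solutions match the direct V-inverse oracle", {
  set.seed(1)
  ped <- simulate_pedigree(3, 1, 2, seed = 9)  # 5 animals
  A <- a_matrix(ped)
  n <- nrow(ped)
  sa2 <- 3; se2 <- 5
  y <- 10 + drop(t(chol(sa2 * A)) %*% rnorm(n)) + rnorm(n, 0, sqrt(se2))
  dat <- data.frame(animal = ped$animal, y = y)
  mme <- build_mme(dat, "y", h_inv = a_inv_named(ped))
  sol <- solve_ssgblup(mme, list(sigma_a2 = sa2, sigma_e2 = se2))
  V <- sa2 * A + se2 * diag(n)
  X <- matrix(1, n); Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  a_blup <- drop(sa2 * A %*% Vi %*% (y - X %*% b))
  expect_equal(sol$gebv, unname(a_blup), tolerance = 1e-8)
  expect_true(all(sol$pev >= 0))
  expect_equal(sol$accuracy, sqrt(pmax(0, 1 - sol$pev / sa2)),
               tolerance = 1e-12)
})

test_that("uninformative animals get zero GEBV and zero accuracy", {
  # animal 5: no records, unrelated to every phenotyped animal
  ped <- data.frame(animal = 1:5, sire = c(0, 0, 1, 1, 0),
                    dam = c(0, 0, 2, 2, 0))
  set.seed(2)
  dat <- data.frame(animal = 1:4, y = rnorm(4, 10))
  mme <- build_mme(dat, "y", h_inv = a_inv_named(ped))
  sol <- solve_ssgblup(mme, list(sigma_a2 = 2, sigma_e2 = 3))
  expect_equal(sol$gebv[5], 0, tolerance = 1e-10)
  expect_equal(sol$accuracy[5], 0, tolerance = 1e-6)
  # shrinkage limit: tiny additive variance sends every GEBV to 0
  sol0 <- solve_ssgblup(mme, list(sigma_a2 = 1e-9, sigma_e2 = 3))
  expect_lt(max(abs(sol0$gebv)), 1e-6)
})

test_that("SNP back-solution inverts constructed genetic values", {
  set.seed(3)
  ped <- founder_ped(60)
  g <- qc_maf(drop_genotypes(ped, n_snp = 120, n_chromosomes = 2, seed = 3))
  p <- colMeans(g$dosage) / 2
  Z <- sweep(g$dosage, 2, 2 * p)
  lam <- 1 / sum(2 * p * (1 - p))
  G <- g_matrix(g)
  u_true <- rnorm(ncol(Z), 0, 0.1)
  a_g <- drop(Z %*% u_true)
  eff <- backsolve_snp_effects(a_g, G + diag(1e-8, nrow(G)), Z, lambda = lam)
  # minimum-norm preimage reproduces a_g through Z
  expect_lt(max(abs(drop(Z %*% eff$u_hat) - a_g)), 1e-6)

  # hand 3 animals x 2 SNP case vs symbolic arithmetic
  Zh <- matrix(c(1, -1, 0, 0, 1, -1), 3, 2)
  Dh <- c(2, 0.5); lamh <- 0.7
  Gh <- lamh * Zh %*% diag(Dh) %*% t(Zh) + diag(1e-10, 3)
  ah <- c(1, 0.5, -1.5)
  effh <- backsolve_snp_effects(ah, Gh, Zh, Dh, lamh)
  expect_equal(effh$u_hat,
               lamh * Dh * drop(t(Zh) %*% solve(Gh, ah)), tolerance = 1e-8)

  # doubling D doubles G; fitted genetic values Z u_hat are invariant
  eff2 <- backsolve_snp_effects(a_g, 2 * (G + diag(1e-8, nrow(G))), Z,
                                weights = rep(2, ncol(Z)), lambda = lam)
  expect_equal(drop(Z %*% eff2$u_hat), drop(Z %*% eff$u_hat),
               tolerance = 1e-6)
  expect_error(backsolve_snp_effects(a_g[-1], G, Z, lambda = lam))
})

test_that("the weighting loop normalizes weights and is unweighted at step 1", {
  set.seed(4)
  ped <- simulate_pedigree(40, 2, 80, seed = 4)
  g <- qc_maf(drop_genotypes(ped, n_snp = 200, n_chromosomes = 2, seed = 4))
  bvsim <- simulate_breeding_values(ped, g, matrix(4, 1, 1),
                                    qtl_fraction = 1, n_qtl = 50, seed = 4)
  y <- 10 + bvsim$bv[, 1] + rnorm(nrow(ped), 0, 2)
  phen <- data.frame(animal = ped$animal, y = y)
  comp <- list(sigma_a2 = 4, sigma_e2 = 4)
  scan <- iterate_weights(phen, "y", ped = ped, genotypes = g,
                          components = comp, n_iterations = 3)
  m <- ncol(g$dosage)
  expect_true(all(scan$iterations[[1]]$weights == 1))
  for (it in 2:3)
    expect_equal(sum(scan$iterations[[it]]$weights), m, tolerance = 1e-8)
  # a single-iteration run is plain unweighted ssGWAS
  scan1 <- iterate_weights(phen, "y", ped = ped, genotypes = g,
                           components = comp, n_iterations = 1)
  expect_equal(scan1$iterations[[1]]$snp_effects$u_hat,
               scan$iterations[[1]]$snp_effects$u_hat, tolerance = 1e-10)
})

test_that("with full genotyping, iteration-1 GEBVs equal direct GBLUP on G*", {
  set.seed(5)
  ped <- founder_ped(80)
  g <- qc_maf(drop_genotypes(ped, n_snp = 300, n_chromosomes = 2, seed = 5))
  bvs <- simulate_breeding_values(ped, g, matrix(4, 1, 1),
                                  qtl_fraction = 1, n_qtl = 60, seed = 5)
  y <- 10 + bvs$bv[, 1] + rnorm(80, 0, 2)
  phen <- data.frame(animal = ped$animal, y = y)
  comp <- list(sigma_a2 = 4, sigma_e2 = 4)
  scan <- iterate_weights(phen, "y", ped = ped, genotypes = g,
                          components = comp, n_iterations = 1, blend = 0.05)
  # direct GBLUP using G* alone as the relationship matrix
  Gs <- scan$iterations[[1]]$G_star
  Gi <- solve(Gs)
  dimnames(Gi) <- list(ped$animal, ped$animal)
  mme_g <- build_mme(phen, "y", h_inv = Gi)
  direct <- solve_ssgblup(mme_g, comp)
  expect_equal(scan$iterations[[1]]$gebv$gebv, direct$gebv,
               tolerance = 1e-6)
})

test_that("window variances match forcings and the brute-force oracle", {
  set.seed(6)
  ped <- founder_ped(50)
  g <- qc_maf(drop_genotypes(ped, n_snp = 80, n_chromosomes = 2, seed = 6))
  p <- colMeans(g$dosage) / 2
  Z <- sweep(g$dosage, 2, 2 * p)
  m <- ncol(Z)
  fake <- list(Z = Z, map = g$map)
  # all-zero effects
  w0 <- window_variance(fake, u_hat = rep(0, m), window_size = 10,
                        sigma_a2 = 2)
  expect_true(all(w0$pct_variance == 0))
  # single nonzero effect: only its window is nonzero, with known value
  u1 <- rep(0, m); u1[17] <- 0.8
  w1 <- window_variance(fake, u_hat = u1, window_size = 10, sigma_a2 = 2)
  hit <- w1$snp_from <= 17 & w1$snp_to >= 17
  expect_equal(sum(w1$pct_variance > 0), 1)
  expect_equal(w1$pct_variance[hit],
               100 * 0.8^2 * var(Z[, 17]) / 2, tolerance = 1e-10)
  # random effects: per-window brute-force recomputation
  u <- rnorm(m, 0, 0.3)
  w <- window_variance(fake, u_hat = u, window_size = 10, sigma_a2 = 2)
  for (k in seq_len(nrow(w))) {
    j <- w$snp_from[k]:w$snp_to[k]
    expect_equal(w$pct_variance[k],
                 100 * var(drop(Z[, j, drop = FALSE] %*% u[j])) / 2,
                 tolerance = 1e-10)
  }
  # windows tile the panel without gaps or overlap
  expect_equal(sort(unlist(Map(seq, w$snp_from, w$snp_to))), 1:m)
  # unsorted map is refused
  bad <- fake
  bad$map$bp <- rev(bad$map$bp)
  expect_error(window_variance(bad, u_hat = u, window_size = 10,
                               sigma_a2 = 2), "sorted")
})

test_that("window percentages sum to the total score variance when windows are orthogonal", {
  # orthogonal zero-mean columns: window scores are exactly uncorrelated,
  # so per-window variances partition the total score variance
  set.seed(7)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(100 * 20), 100, 20))))
  Z <- Q[, 2:21]
  colnames(Z) <- paste0("snp", 1:20)
  rownames(Z) <- 1:100
  fake <- list(Z = Z, map = data.frame(snp = 1:20, chrom = 1, bp = 1:20 * 1e3))
  u <- rnorm(20)
  w <- window_variance(fake, u_hat = u, window_size = 5, sigma_a2 = 1)
  total <- 100 * var(drop(Z %*% u)) / 1
  expect_equal(sum(w$pct_variance), total, tolerance = 1e-8)
})

test_that("candidate windows respect the strict threshold rule", {
  scan <- structure(data.frame(chrom = 1, start_bp = c(1, 2, 3) * 1e5,
                               end_bp = c(1.5, 2.5, 3.5) * 1e5,
                               snp_from = c(1, 11, 21),
                               snp_to = c(10, 20, 30), n_snp = 10,
                               pct_variance = c(0.2, 0.5, 0.9)),
                    class = c("window_scan", "data.frame"))
  flagged <- candidate_windows(scan, 0.5)
  expect_equal(nrow(flagged), 1)        # 0.5 itself is not "> 0.50%"
  expect_equal(flagged$pct_variance, 0.9)
  expect_equal(nrow(candidate_windows(scan, 0)), 3)
  low <- scan; low$pct_variance <- c(0.1, 0.2, 0.3)
  expect_equal(nrow(candidate_windows(low, 0.5)), 0)
})
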