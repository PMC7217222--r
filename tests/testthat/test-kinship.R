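test_that("MAF filter removes monomorphic and below-threshold SNP", {
  # 40 animals; columns engineered to known frequencies
  n <- 50
  dos <- cbind(rep(2L, n),                        # monomorphic
               c(rep(1L, 4), rep(0L, n - 4)),    # p = 0.04
               c(rep(1L, 6), rep(0L, n - 6)),    # p = 0.06
               c(rep(1L, 5), rep(0L, n - 5)))    # p = 0.05 (boundary kept)
  g <- make_genotypes(dos)
  gq <- qc_maf(g, 0.05)
  expect_equal(unname(which(gq$maf_mask)), c(3, 4))
  # recount oracle on a random panel
  set.seed(2)
  dos2 <- matrix(rbinom(60 * 100, 2, runif(100, 0.01, 0.5)[rep(1:100,
                                                               each = 60)]),
                 60, 100)
  g2 <- make_genotypes(dos2)
  gq2 <- qc_maf(g2, 0.05)
  p <- colMeans(dos2) / 2
  expect_equal(ncol(gq2$dosage), sum(pmin(p, 1 - p) >= 0.05 & p > 0 & p < 1))
  expect_error(qc_maf(make_genotypes(matrix(2L, 10, 3)), 0.05),
               "monomorphic")
})

test_that("tabular A matrix matches textbook forcings and the recursive oracle", {
  expect_equal(unname(a_matrix(founder_ped(4))), diag(4))
  trio <- data.frame(animal = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2))
  A <- a_matrix(trio)
  expect_equal(A["3", "1"], 0.5)
  expect_equal(A["3", "3"], 1)
  for (seed in 1:5) {
    ped <- simulate_pedigree(6, 3, 6, seed = seed)  # <= 25 animals
    expect_equal(unname(a_matrix(ped)), a_recursive(ped), tolerance = 1e-12)
  }
  disordered <- data.frame(animal = 1:2, sire = c(2, 0), dam = c(0, 0))
  expect_error(a_matrix(disordered), "ordered")
})

test_that("G matches the hand-computed case and is linear in the weights", {
  g <- make_genotypes(matrix(c(0L, 2L), 2, 1))
  G <- g_matrix(g, allele_freq = 0.5)
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(G, "denominator"), 0.5)

  set.seed(5)
  dos <- matrix(rbinom(30 * 50, 2, 0.4), 30, 50)
  gg <- make_genotypes(dos)
  gq <- qc_maf(gg, 0.01)
  G1 <- g_matrix(gq)
  G2 <- g_matrix(gq, weights = rep(2, ncol(gq$dosage)))
  expect_equal(unname(G2), unname(2 * G1), tolerance = 1e-12)
  # identical genotypes give identical rows/columns
  dos2 <- rbind(dos, dos[1, ])
  gq2 <- qc_maf(make_genotypes(dos2), 0.01)
  G3 <- g_matrix(gq2)
  expect_equal(unname(G3[31, ]), unname(G3[1, ]), tolerance = 1e-12)
})

test_that("G with identity weights has mean diagonal near 1 on founders", {
  ped <- founder_ped(120)
  g <- drop_genotypes(ped, n_snp = 5000, n_chromosomes = 5, seed = 31)
  gq <- qc_maf(g, 0.05)
  G <- g_matrix(gq)
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
})

test_that("tuning matches A22's diagonal means and solves the right 2x2", {
  ped <- simulate_pedigree(20, 2, 30, seed = 3)
  g <- qc_maf(drop_genotypes(ped, n_snp = 300, n_chromosomes = 2, seed = 4))
  A <- a_matrix(ped)
  idx <- match(rownames(g$dosage), as.character(ped$animal))
  A22 <- A[idx, idx]
  G <- g_matrix(g)
  Gs <- tune_and_blend(G, A22, blend = 0)
  off <- row(Gs) != col(Gs)
  expect_equal(mean(diag(Gs)), mean(diag(A22)), tolerance = 1e-8)
  expect_equal(mean(Gs[off]), mean(A22[off]), tolerance = 1e-8)
  # fixed point: a G already on A22's scale passes through unchanged
  Gs2 <- tune_and_blend(Gs, A22, blend = 0)
  expect_equal(unname(Gs2), unname(Gs), tolerance = 1e-8,
               ignore_attr = TRUE)
  # (alpha, beta) equal the brute-force 2x2 solution
  md_G <- mean(diag(G)); mo_G <- mean(G[off])
  ab <- solve(rbind(c(1, md_G), c(1, mo_G)),
              c(mean(diag(A22)), mean(A22[off])))
  expect_equal(attr(Gs, "alpha"), ab[1], tolerance = 1e-10)
  expect_equal(attr(Gs, "beta"), ab[2], tolerance = 1e-10)
  expect_error(tune_and_blend(matrix(1, 4, 4), diag(4)), "tune")
})

test_that("H inverse reduces to A inverse and yields a PD H", {
  ped <- simulate_pedigree(15, 2, 20, seed = 6)
  A <- a_matrix(ped)
  idx <- 30:55
  A22 <- A[idx, idx]
  # degenerate equality: G* = A22
  Hi <- h_inverse(A, A22, idx)
  expect_equal(unname(Hi), unname(solve(A)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # no genotyped animals
  Hi0 <- h_inverse(A, matrix(0, 0, 0), integer(0))
  expect_equal(unname(Hi0), unname(solve(A)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # random blended G*: H from inverting H_inv is positive definite
  g <- qc_maf(drop_genotypes(ped, n_snp = 400, n_chromosomes = 2, seed = 8))
  gidx <- match(rownames(g$dosage), as.character(ped$animal))
  Gs <- tune_and_blend(g_matrix(g), A[gidx, gidx], blend = 0.05)
  Hi2 <- h_inverse(A, Gs, gidx)
  ev <- eigen(solve(Hi2), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("build_h_system wires QC, matrices and index partition together", {
  ped <- simulate_pedigree(20, 2, 30, seed = 12)
  g <- drop_genotypes(ped, n_snp = 300, n_chromosomes = 2, seed = 12)
  keep <- sample(nrow(ped), 40)
  g$dosage <- g$dosage[keep, ]
  hs <- build_h_system(ped, g, maf_threshold = 0.05, blend = 0.05)
  expect_s3_class(hs, "h_system")
  expect_equal(length(hs$genotyped_idx), 40)
  expect_equal(dim(hs$H_inv), dim(hs$A))
  expect_equal(hs$lambda,
               1 / attr(hs$G, "denominator"), tolerance = 1e-12)
})
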