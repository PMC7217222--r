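test_that("pedigree simulation is ordered, founder-only capable, seeded", {
  ped0 <- simulate_pedigree(10, 0, seed = 1)
  expect_equal(nrow(ped0), 10)
  expect_true(all(ped0$sire == 0 & ped0$dam == 0))

  ped1 <- simulate_pedigree(20, 3, 30, seed = 5)
  ped2 <- simulate_pedigree(20, 3, 30, seed = 5)
  expect_identical(ped1, ped2)
  # parents always precede offspring (also guards against self-ancestry)
  expect_true(all(ped1$sire < ped1$animal & ped1$dam < ped1$animal))
  # relationship diagonal is always >= 1 (1 + inbreeding)
  expect_true(all(diag(a_matrix(ped1)) >= 1 - 1e-12))
  expect_error(simulate_pedigree(1, 1), "n_founders")
})

test_that("gene dropping obeys Mendelian rules and linkage", {
  ped <- simulate_pedigree(30, 2, 60, seed = 7)
  g <- drop_genotypes(ped, n_snp = 200, n_chromosomes = 2, seed = 7,
                      keep_haplotypes = TRUE)
  expect_true(all(g$dosage %in% 0:2))
  # both parents homozygous 0 forces offspring 0 at that locus
  off <- which(ped$sire != 0 & ped$dam != 0)
  for (i in off[1:20]) {
    both0 <- g$dosage[ped$sire[i], ] == 0 & g$dosage[ped$dam[i], ] == 0
    expect_true(all(g$dosage[i, both0] == 0))
    both2 <- g$dosage[ped$sire[i], ] == 2 & g$dosage[ped$dam[i], ] == 2
    expect_true(all(g$dosage[i, both2] == 2))
  }
  # complete linkage: each transmitted gamete is one parental haplotype
  trio <- data.frame(animal = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2))
  gt <- drop_genotypes(trio, n_snp = 50, n_chromosomes = 1,
                       morgans_per_bp = 0, keep_haplotypes = TRUE, seed = 9)
  expect_true(identical(gt$hap1[3, ], gt$hap1[1, ]) ||
                identical(gt$hap1[3, ], gt$hap2[1, ]))
  expect_true(identical(gt$hap2[3, ], gt$hap2[2, ]) ||
                identical(gt$hap2[3, ], gt$hap1[2, ]))
})

test_that("founder genotypes match binomial sampling and Hardy-Weinberg", {
  n <- 600
  ped <- founder_ped(n)
  g <- drop_genotypes(ped, n_snp = 60, n_chromosomes = 1,
                      founder_maf_range = c(0.5, 0.5), seed = 13)
  # mean dosage ~ 2p = 1 within 3 binomial SE
  se <- sqrt(2 * 0.5 * 0.5 / n)
  expect_true(all(abs(colMeans(g$dosage) - 1) < 3.5 * se))
  # heterozygote frequency ~ 2p(1-p) (Hardy-Weinberg)
  het <- colMeans(g$dosage == 1)
  expect_true(mean(abs(het - 0.5)) < 3 * sqrt(0.25 / n))
})

test_that("simulated founder breeding values realize the target covariance", {
  n <- 500
  ped <- founder_ped(n)
  g <- drop_genotypes(ped, n_snp = 400, n_chromosomes = 2, seed = 17)
  S <- matrix(c(4, 1.2, 1.2, 2), 2)
  bv <- simulate_breeding_values(ped, g, S, qtl_fraction = 0.3,
                                 n_qtl = 40, seed = 17)
  Shat <- stats::cov(bv$bv)
  # chi-square-style bound: sample variances of n=500 draws stay within
  # ~20% of the target
  expect_true(all(abs(diag(Shat) / diag(S) - 1) < 0.2))
  expect_lt(abs(Shat[1, 2] / S[1, 2] - 1), 0.5)
  expect_true(all(bv$qtl_idx >= 1 & bv$qtl_idx <= ncol(g$dosage)))
})

test_that("lactation records lie on the true curves when noise is zero", {
  cfg <- sim_config(n_founders = 12, n_generations = 1,
                    n_per_generation = 15, n_snp = 60, n_chromosomes = 1,
                    n_qtl = 5, residual_sd_milk = 0, seed = 3)
  ped <- simulate_pedigree(cfg$n_founders, cfg$n_generations,
                           cfg$n_per_generation)
  g <- drop_genotypes(ped, n_snp = cfg$n_snp, n_chromosomes = 1)
  sim <- simulate_lactations(ped, g, cfg)
  tp <- sim$truth$true_params
  for (k in sample(nrow(tp), 5)) {
    r <- sim$records[sim$records$animal == tp$animal[k] &
                       sim$records$parity == tp$parity[k], ]
    expect_equal(r$milk_kg,
                 pmax(0, milkbot_yield(milkbot_params(tp$scale_a[k],
                                                      tp$ramp_b[k],
                                                      tp$offset_c[k],
                                                      tp$decay_d[k]),
                                       r$dim)),
                 tolerance = 1e-10)
  }
})

test_that("zero genetic variation collapses all animals onto one curve", {
  zero4 <- matrix(0, 4, 4)
  cfg <- sim_config(n_founders = 10, n_generations = 1,
                    n_per_generation = 10, n_snp = 40, n_chromosomes = 1,
                    n_qtl = 0, qtl_variance_fraction = 0,
                    genetic_covariance = zero4, pe_covariance = zero4,
                    te_covariance = zero4, residual_sd_milk = 0,
                    hys_sd = 0, country_sd = 0, age_b1 = 0, age_b2 = 0,
                    parity_distribution = c(1), seed = 8)
  ped <- simulate_pedigree(cfg$n_founders, cfg$n_generations,
                           cfg$n_per_generation)
  g <- drop_genotypes(ped, n_snp = cfg$n_snp, n_chromosomes = 1)
  sim <- simulate_lactations(ped, g, cfg)
  ref <- milkbot_yield(milkbot_params(35.57, 30.60, 0, 0.00142),
                       cfg$test_day_schedule)
  split_recs <- split(sim$records$milk_kg, sim$records$animal)
  for (r in split_recs) expect_equal(unname(r), ref, tolerance = 1e-10)
})

test_that("the full population simulation is reproducible under one seed", {
  cfg <- sim_config(n_founders = 15, n_generations = 1,
                    n_per_generation = 20, n_snp = 50, n_chromosomes = 1,
                    n_qtl = 5, seed = 99)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(founder_maf_range = c(0, 0.5)))
  expect_error(sim_config(n_snp = 0), "positive")
  bad <- diag(4)
  bad[1, 2] <- bad[2, 1] <- 2        # eigenvalue -1: not PSD
  expect_error(sim_config(genetic_covariance = bad),
               "positive semidefinite")
})
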