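#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study population.
#
# A pedigreed multi-herd dairy population with known MilkBot-parameter
# genetics: 120 founders + 2 generations of 300 (720 animals), 1,000 SNP
# on 2 chromosomes, 20 marker QTL. Writes the raw inputs every later
# stage reads.

library(lactgwas)

outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_founders = 120, n_generations = 2,
                  n_per_generation = 300, n_snp = 1000, n_chromosomes = 2,
                  chromosome_length_bp = 2.5e7, n_founder_haplotypes = 6,
                  n_qtl = 20, herds = 6, years = 2, seed = 2024)
sim <- simulate_population(cfg)

write_pedigree(sim$pedigree, file.path(outdir, "pedigree.csv"))
write_testday(sim$records, file.path(outdir, "testday.csv"))
utils::write.csv(sim$covariates, file.path(outdir, "covariates.csv"),
                 row.names = FALSE, quote = FALSE)
write_dosage(sim$genotypes, file.path(outdir, "geno"))
write_plink(sim$genotypes, file.path(outdir, "geno"))
utils::write.csv(data.frame(animal = rownames(sim$truth$bv),
                            sim$truth$bv),
                 file.path(outdir, "truth_breeding_values.csv"),
                 row.names = FALSE, quote = FALSE)
utils::write.csv(data.frame(qtl_snp = sim$truth$qtl_idx,
                            sim$truth$qtl_effects),
                 file.path(outdir, "truth_qtl.csv"), row.names = FALSE,
                 quote = FALSE)

n_lact <- nrow(unique(sim$records[c("animal", "parity")]))
message("simulated ", nrow(sim$pedigree), " animals, ", n_lact,
        " lactations, ", ncol(sim$genotypes$dosage), " SNP (",
        sim$truth$n_truncated, " negative test-day yields truncated)")
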