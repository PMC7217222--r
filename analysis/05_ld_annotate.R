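#!/usr/bin/env Rscript
# Stage 5: LD mapping and gene annotation of the candidate windows.
# Pairwise r^2 in a 200 kb sliding window around the top region, LD
# blocks as adjacent-pair r^2 >= 0.7 runs, gene overlap against the
# bundled synthetic annotation and a hypergeometric enrichment scan.

library(lactgwas)

geno <- qc_maf(read_dosage("results/data/geno"), 0.05)
cand <- utils::read.delim("results/candidate_windows_m305.tsv")
if (nrow(cand) == 0) stop("no candidate windows; run stage 4 first")
top <- cand[1, ]
message(sprintf("top window: chr%s %d-%d (%.2f%% of additive variance)",
                top$chrom, top$start_bp, top$end_bp, top$pct_variance))

ld <- pairwise_r2(geno, chrom = top$chrom,
                  from_bp = top$start_bp - 2e5, to_bp = top$end_bp + 2e5,
                  window_bp = 2e5)
blocks <- find_blocks(ld, r2_threshold = 0.7)
utils::write.table(ld$pairs, "results/ld_pairs_top_window.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
utils::write.table(blocks, "results/ld_blocks_top_window.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
message(nrow(blocks), " LD block(s) of >= 2 SNP in the top region")
dir.create("results/figures", showWarnings = FALSE)
ggplot2::ggsave("results/figures/ld_top_window.png", plot_ld_heatmap(ld),
                width = 5, height = 4, dpi = 150)

ann <- read_gene_annotation(system.file("extdata", "synthetic_genes.gff3",
                                        package = "lactgwas"))
genes <- genes_in_windows(cand, ann, dedup = TRUE)
utils::write.table(genes, "results/candidate_genes_m305.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
message(nrow(genes), " gene(s) overlap the candidate windows")

sets <- read_gmt(system.file("extdata", "synthetic_sets.gmt",
                             package = "lactgwas"))
enr <- enrichment(genes$gene_id, sets, background = ann$gene_id,
                  min_overlap = 4)
utils::write.table(enr, "results/enrichment_m305.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
message(nrow(enr), " gene set(s) reported at overlap >= 4")
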