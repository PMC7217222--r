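#' Drop biallelic SNP genotypes through a pedigree
#'
#' Founders receive haplotypes drawn site-wise from per-SNP allele
#' frequencies sampled uniformly within `founder_maf_range`. Offspring
#' inherit one recombinant gamete from each parent: along a chromosome the
#' transmitted parental haplotype switches between markers with
#' probability given by Haldane's map function,
#' r = (1 - exp(-2 m))/2 for map distance m (Morgans), so physically
#' close markers are in linkage disequilibrium. Chromosomes segregate
#' independently.
#'
#' @param ped ordered pedigree (see [a_matrix()])
#' @param n_snp total number of SNP (split evenly across chromosomes)
#' @param n_chromosomes number of chromosomes
#' @param chromosome_length_bp physical length of each chromosome
#' @param founder_maf_range length-2 numeric in (0, 0.5]: founder allele
#'   frequencies are drawn uniformly in this interval
#' @param morgans_per_bp genetic map density (default 1e-8 = 1 cM/Mb)
#' @param map optional custom marker map data.frame (`chrom`, `bp`),
#'   sorted by (chrom, bp); overrides `n_snp`/`n_chromosomes`
#' @param n_founder_haplotypes size of the ancestral haplotype pool.
#'   `Inf` (default) draws founder alleles independently per site
#'   (linkage equilibrium in founders); a finite pool makes every
#'   founder gamete a recombinant mosaic of two pool haplotypes, which
#'   creates baseline LD that decays with map distance
#' @param keep_haplotypes retain the two haplotype matrices in the result
#' @param seed optional RNG seed
#' @return a `genotype_set`: list with `dosage` (animals x SNP matrix in
#'   \{0,1,2\}, rownames = animal ids), `map` (`snp`, `chrom`, `bp`),
#'   `allele_freq` (observed, all animals), `founder_freq` (the simulated
#'   truth), and optionally `hap1`/`hap2`
#' @export
drop_genotypes <- function(ped, n_snp = 1000L, n_chromosomes = 5L,
                           chromosome_length_bp = 1e8,
                           founder_maf_range = c(0.05, 0.5),
                           morgans_per_bp = 1e-8, map = NULL,
                           n_founder_haplotypes = Inf,
                           keep_haplotypes = FALSE, seed = NULL) {
  par <- .check_ordered_pedigree(ped)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(founder_maf_range) == 2,
            founder_maf_range[1] > 0, founder_maf_range[2] <= 0.5)
  if (is.null(map)) {
    per_chr <- rep(n_snp %/% n_chromosomes, n_chromosomes)
    per_chr[seq_len(n_snp %% n_chromosomes)] <-
      per_chr[seq_len(n_snp %% n_chromosomes)] + 1L
    map <- do.call(rbind, lapply(seq_len(n_chromosomes), function(ch) {
      m <- per_chr[ch]
      data.frame(chrom = ch,
                 bp = round(seq_len(m) * chromosome_length_bp / (m + 1)))
    }))
  }
  if (is.unsorted(order(map$chrom, map$bp)))
    map <- map[order(map$chrom, map$bp), ]
  m <- nrow(map)
  map$snp <- seq_len(m)
  map <- map[, c("snp", "chrom", "bp")]

  # per-marker switch probability; 0.5 at each chromosome start (random
  # phase), Haldane within chromosome
  d_bp <- c(0, diff(map$bp))
  new_chr <- c(TRUE, diff(map$chrom) != 0)
  sw <- 0.5 * (1 - exp(-2 * d_bp * morgans_per_bp))
  sw[new_chr] <- 0.5

  n <- nrow(ped)
  p0 <- stats::runif(m, founder_maf_range[1], founder_maf_range[2])
  pool <- NULL
  if (is.finite(n_founder_haplotypes)) {
    stopifnot(n_founder_haplotypes >= 2)
    pool <- matrix(as.integer(stats::runif(n_founder_haplotypes * m) <
                                rep(p0, each = n_founder_haplotypes)),
                   n_founder_haplotypes, m)
  }
  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  mosaic <- function(A, B) {        # recombinant of two haplotypes
    phase <- cumsum(stats::runif(m) < sw) %% 2L
    ifelse(phase == 0L, A, B)
  }
  gamete <- function(j) mosaic(H1[j, ], H2[j, ])
  founder_hap <- function() {
    if (is.null(pool)) return(as.integer(stats::runif(m) < p0))
    pick <- sample.int(nrow(pool), 2)
    mosaic(pool[pick[1], ], pool[pick[2], ])
  }
  for (i in seq_len(n)) {
    s <- par$sire[i]; d <- par$dam[i]
    H1[i, ] <- if (s > 0) gamete(s) else founder_hap()
    H2[i, ] <- if (d > 0) gamete(d) else founder_hap()
  }
  dosage <- H1 + H2
  dimnames(dosage) <- list(ped$animal, paste0("snp", map$snp))
  out <- list(dosage = dosage, map = map,
              allele_freq = colMeans(dosage) / 2, founder_freq = p0)
  if (keep_haplotypes) {
    out$hap1 <- H1
    out$hap2 <- H2
  }
  structure(out, class = "genotype_set")
}

#' Simulate a genotype panel with planted haplotype blocks
#'
#' Builds unrelated individuals whose chromosomes are mosaics of a small
#' number of ancestral haplotypes within each block, with free
#' recombination (independent sampling) between blocks. With few ancestral
#' haplotypes per block, adjacent markers inside a block are in strong LD
#' while markers in different blocks are uncorrelated - the textbook
#' haplotype-block structure used to exercise LD block callers.
#'
#' @param n_ind number of individuals
#' @param block_sizes integer vector, SNP per block
#' @param n_haplotypes ancestral haplotypes per block (default 2: maximal
#'   within-block LD)
#' @param spacing_bp distance between adjacent SNP within a block
#' @param gap_bp distance between consecutive blocks
#' @param seed optional RNG seed
#' @return a `genotype_set` (single chromosome); attribute
#'   `block_bounds` gives each block's first/last SNP index
#' @export
simulate_block_genotypes <- function(n_ind, block_sizes = c(10L, 10L),
                                     n_haplotypes = 2L, spacing_bp = 2000L,
                                     gap_bp = 50000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- sum(block_sizes)
  bp <- integer(0)
  pos <- 0L
  bounds <- matrix(0L, length(block_sizes), 2)
  k <- 0L
  for (b in seq_along(block_sizes)) {
    bounds[b, ] <- c(k + 1L, k + block_sizes[b])
    bp <- c(bp, pos + seq_len(block_sizes[b]) * spacing_bp)
    pos <- pos + block_sizes[b] * spacing_bp + gap_bp
    k <- k + block_sizes[b]
  }
  dosage <- matrix(0L, n_ind, m)
  for (b in seq_along(block_sizes)) {
    sz <- block_sizes[b]
    # ancestral haplotypes: first two complementary so every site is
    # polymorphic; extras are random
    haps <- matrix(0L, n_haplotypes, sz)
    haps[1, ] <- as.integer(stats::runif(sz) < 0.5)
    haps[2, ] <- 1L - haps[1, ]
    if (n_haplotypes > 2)
      for (h in 3:n_haplotypes)
        haps[h, ] <- as.integer(stats::runif(sz) < 0.5)
    pick <- matrix(sample.int(n_haplotypes, 2 * n_ind, replace = TRUE),
                   n_ind, 2)
    dosage[, bounds[b, 1]:bounds[b, 2]] <- haps[pick[, 1], ] + haps[pick[, 2], ]
  }
  map <- data.frame(snp = seq_len(m), chrom = 1L, bp = bp)
  dimnames(dosage) <- list(seq_len(n_ind), paste0("snp", map$snp))
  structure(list(dosage = dosage, map = map,
                 allele_freq = colMeans(dosage) / 2,
                 founder_freq = rep(NA_real_, m)),
            class = "genotype_set", block_bounds = bounds)
}
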