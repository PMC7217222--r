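# independent oracles used across test files

# additive relationship by the recursive definition (independent of the
# tabular implementation in a_matrix)
a_recursive <- function(ped) {
  n <- nrow(ped)
  s <- ped$sire
  d <- ped$dam
  f <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (i == j) return(1 + 0.5 * f(s[i], d[i]))
    if (j > i) { k <- i; i <- j; j <- k }
    0.5 * (f(s[i], j) + f(d[i], j))
  }
  outer(seq_len(n), seq_len(n), Vectorize(f))
}

# genotype container built directly from a dosage matrix
make_genotypes <- function(dosage, chrom = NULL, bp = NULL) {
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(bp)) bp <- seq_len(m) * 1000L
  if (is.null(rownames(dosage))) rownames(dosage) <- seq_len(nrow(dosage))
  colnames(dosage) <- paste0("snp", seq_len(m))
  structure(list(dosage = dosage,
                 map = data.frame(snp = seq_len(m), chrom = chrom, bp = bp),
                 allele_freq = colMeans(dosage) / 2,
                 founder_freq = rep(NA_real_, m)),
            class = "genotype_set")
}

# founders-only pedigree
founder_ped <- function(n) data.frame(animal = seq_len(n), sire = 0L, dam = 0L)

# inverse of A with dimnames, for build_mme
a_inv_named <- function(ped) {
  A <- a_matrix(ped)
  Ai <- chol2inv(chol(A))
  dimnames(Ai) <- dimnames(A)
  Ai
}

# random valid MilkBot parameter draws spanning the simulated range
random_milkbot <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(a = runif(n, 10, 60), b = runif(n, 10, 60),
             c = runif(n, -10, 10), d = runif(n, 5e-4, 5e-3))
}
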