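#' Filter SNP by minor allele frequency
#'
#' Removes markers whose minor allele frequency, computed from the
#' observed genotyped sample, falls below `threshold` (markers exactly at
#' the threshold are retained). Monomorphic markers always fail.
#'
#' @param genotypes a `genotype_set` (dosages in \{0,1,2\})
#' @param threshold MAF threshold as a fraction (default 0.05)
#' @param verbose log the number of markers removed
#' @return the filtered `genotype_set`; `maf_mask` records the retained
#'   columns of the input panel
#' @export
qc_maf <- function(genotypes, threshold = 0.05, verbose = FALSE) {
  M <- genotypes$dosage
  stopifnot(all(M %in% 0:2))
  p <- colMeans(M) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf >= threshold & maf > 0
  if (!any(keep))
    stop("no SNP pass the MAF filter (panel monomorphic or threshold ",
         "too strict)")
  if (verbose)
    message(sum(!keep), " of ", length(keep), " SNP removed at MAF < ",
            threshold)
  out <- genotypes
  out$dosage <- M[, keep, drop = FALSE]
  out$map <- genotypes$map[keep, , drop = FALSE]
  out$allele_freq <- p[keep]
  out$founder_freq <- genotypes$founder_freq[keep]
  out$maf_mask <- keep
  if (!is.null(out$hap1)) out$hap1 <- out$hap1[, keep, drop = FALSE]
  if (!is.null(out$hap2)) out$hap2 <- out$hap2[, keep, drop = FALSE]
  out
}

#' Genomic relationship matrix (VanRaden)
#'
#' G = Z D Z' / sum_i 2 p_i (1 - p_i), where Z is the dosage matrix
#' centered by twice the allele frequency, D a positive diagonal matrix
#' of per-SNP weights (identity for unweighted GBLUP), and the
#' denominator the variance-normalizing constant whose reciprocal is
#' lambda = sigma_u^2 / sigma_a^2.
#'
#' @param genotypes a `genotype_set`, ideally MAF-filtered
#' @param weights per-SNP positive weights d_i (default all 1)
#' @param allele_freq frequencies p_i used for centering and the
#'   denominator; default the observed sample frequencies
#' @return G matrix (animals x animals) with attributes `lambda`
#'   (1 / sum 2p(1-p)) and `denominator`
#' @export
g_matrix <- function(genotypes, weights = NULL, allele_freq = NULL) {
  M <- genotypes$dosage
  p <- if (is.null(allele_freq)) colMeans(M) / 2 else allele_freq
  if (any(p <= 0 | p >= 1))
    stop("monomorphic SNP present; run qc_maf() first")
  m <- ncol(M)
  if (is.null(weights)) weights <- rep(1, m)
  stopifnot(length(weights) == m, all(weights > 0))
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0) stop("zero variance denominator")
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(sweep(Z, 2, weights, `*`), Z) / denom
  dimnames(G) <- list(rownames(M), rownames(M))
  attr(G, "lambda") <- 1 / denom
  attr(G, "denominator") <- denom
  G
}

#' Tune G to the scale of A22 and blend
#'
#' Finds (alpha, beta) so that `alpha + beta * G` matches A22 in both mean
#' diagonal and mean off-diagonal (a 2x2 linear system), then blends:
#' G* = (1 - blend) * G_tuned + blend * A22. Blending guards against
#' singular G (more animals than SNP, duplicated genotypes); `blend = 0`
#' is allowed.
#'
#' @param G genomic relationship matrix
#' @param A22 pedigree relationship matrix of the genotyped animals
#' @param blend fraction of A22 mixed into the tuned G (default 0.05)
#' @return G* with attributes `alpha`, `beta`, `blend`
#' @export
tune_and_blend <- function(G, A22, blend = 0.05) {
  stopifnot(all(dim(G) == dim(A22)), blend >= 0, blend <= 1)
  n <- nrow(G)
  md_G <- mean(diag(G)); md_A <- mean(diag(A22))
  off <- row(G) != col(G)
  mo_G <- mean(G[off]); mo_A <- mean(A22[off])
  coef <- rbind(c(1, md_G), c(1, mo_G))
  if (abs(det(coef)) < 1e-12 * max(1, abs(md_G)))
    stop("cannot tune: G has equal mean diagonal and off-diagonal ",
         "(constant matrix?)")
  ab <- solve(coef, c(md_A, mo_A))
  G_tuned <- ab[1] + ab[2] * G
  G_star <- (1 - blend) * G_tuned + blend * A22
  attr(G_star, "alpha") <- ab[1]
  attr(G_star, "beta") <- ab[2]
  attr(G_star, "blend") <- blend
  G_star
}

.inv_sym <- function(S) {
  ch <- tryCatch(chol(S), error = function(e)
    stop("matrix not positive definite: ", conditionMessage(e)))
  inv <- chol2inv(ch)
  dimnames(inv) <- dimnames(S)
  inv
}

#' Inverse of the combined pedigree-genomic relationship matrix H
#'
#' H^-1 = A^-1 + [0 0; 0 G*^-1 - A22^-1] on the genotyped block, which
#' joins pedigree and genomic information so genotyped and ungenotyped
#' animals are evaluated together. When G* = A22 (or no animal is
#' genotyped) this reduces to A^-1.
#'
#' @param A full pedigree relationship matrix (all animals, ordered)
#' @param G_star tuned/blended genomic matrix for the genotyped animals
#' @param genotyped_idx positions (indices into rows of A) of the
#'   genotyped animals; may be empty
#' @param max_condition error when G*'s condition number exceeds this
#'   (remedy: increase the blend fraction)
#' @return H^-1 with attribute `genotyped_idx`
#' @export
h_inverse <- function(A, G_star, genotyped_idx, max_condition = 1e12) {
  H_inv <- .inv_sym(A)
  if (length(genotyped_idx) > 0) {
    stopifnot(length(genotyped_idx) == nrow(G_star))
    ev <- eigen(G_star, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0 || max(ev) / min(ev) > max_condition)
      stop("G* is singular or ill-conditioned (condition number ",
           format(max(ev) / max(min(ev), 1e-300), digits = 3),
           "); increase the blend fraction")
    A22 <- A[genotyped_idx, genotyped_idx, drop = FALSE]
    H_inv[genotyped_idx, genotyped_idx] <-
      H_inv[genotyped_idx, genotyped_idx] + .inv_sym(G_star) - .inv_sym(A22)
  }
  attr(H_inv, "genotyped_idx") <- genotyped_idx
  H_inv
}

#' Build the full single-step relationship system
#'
#' Convenience constructor running [a_matrix()], [qc_maf()], [g_matrix()],
#' [tune_and_blend()] and [h_inverse()], keeping every intermediate matrix
#' and the index partition.
#'
#' @param ped ordered pedigree of all animals
#' @param genotypes `genotype_set` whose rows are a subset of `ped$animal`
#' @param maf_threshold MAF filter (NULL skips QC)
#' @param weights per-SNP weights for G
#' @param blend blend fraction for [tune_and_blend()]
#' @return an `h_system`: list with `A`, `A22`, `G`, `G_star`, `H_inv`,
#'   `genotyped_idx`, `genotypes` (post-QC), `weights`, `lambda`
#' @export
build_h_system <- function(ped, genotypes, maf_threshold = 0.05,
                           weights = NULL, blend = 0.05) {
  if (!is.null(maf_threshold)) genotypes <- qc_maf(genotypes, maf_threshold)
  A <- a_matrix(ped)
  gen_ids <- rownames(genotypes$dosage)
  idx <- match(gen_ids, as.character(ped$animal))
  if (anyNA(idx))
    stop("genotyped animals absent from pedigree: ",
         paste(utils::head(gen_ids[is.na(idx)], 5), collapse = ", "))
  A22 <- A[idx, idx, drop = FALSE]
  G <- g_matrix(genotypes, weights = weights)
  G_star <- tune_and_blend(G, A22, blend = blend)
  structure(list(A = A, A22 = A22, G = G, G_star = G_star,
                 H_inv = h_inverse(A, G_star, idx),
                 genotyped_idx = idx, genotypes = genotypes,
                 weights = if (is.null(weights))
                   rep(1, ncol(genotypes$dosage)) else weights,
                 lambda = attr(G, "lambda")),
            class = "h_system")
}
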