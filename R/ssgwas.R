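#' Solve ssGBLUP: breeding values, PEV and accuracy for all animals
#'
#' Solves the mixed-model equations at fixed variance components and
#' extracts, for every animal in H (genotyped or not), the genomic
#' estimated breeding value, its prediction error variance (from the
#' additive block of the inverted coefficient matrix) and the accuracy.
#' Two accuracy conventions are reported: `accuracy` =
#' sqrt(max(0, 1 - PEV/sigma_a2)) (the conventional square-root form,
#' the default downstream) and `reliability` = 1 - PEV/sigma_a2.
#'
#' @param mme from [build_mme()]
#' @param components a `variance_components` (or list with `sigma_a2`,
#'   `sigma_e2`, optionally `sigma_p2`)
#' @return data.frame: `animal`, `gebv`, `pev`, `accuracy`, `reliability`
#' @export
solve_ssgblup <- function(mme, components) {
  sol <- solve_mme(mme, sigma_a2 = components$sigma_a2,
                   sigma_e2 = components$sigma_e2,
                   sigma_p2 = if (mme$qp > 0) components$sigma_p2 else NULL,
                   keep_inverse = TRUE)
  rel <- 1 - sol$pev / components$sigma_a2
  data.frame(animal = mme$ids, gebv = unname(sol$a), pev = unname(sol$pev),
             accuracy = sqrt(pmax(0, rel)), reliability = unname(rel))
}

#' Back-solve SNP effects from genotyped animals' breeding values
#'
#' u_hat = lambda D Z' G*^-1 a_g, the minimum-norm decomposition of the
#' genotyped animals' additive values into per-marker effects. When G* is
#' exactly Z D Z' lambda (no tuning/blending), Z u_hat reproduces a_g.
#'
#' @param a_g breeding values of the genotyped animals (in the row order
#'   of `Z`)
#' @param G_star genomic relationship used in the evaluation
#' @param Z centered dosage matrix (dosage - 2p, animals x SNP)
#' @param weights per-SNP weights d_i (diagonal of D)
#' @param lambda variance-normalizing constant 1 / sum 2p(1-p)
#' @return data.frame: `snp`, `u_hat`, `weight`
#' @export
backsolve_snp_effects <- function(a_g, G_star, Z, weights = NULL,
                                  lambda) {
  if (is.null(weights)) weights <- rep(1, ncol(Z))
  stopifnot(length(a_g) == nrow(G_star), nrow(Z) == nrow(G_star),
            length(weights) == ncol(Z))
  Ginv_a <- solve(G_star, a_g)
  u_hat <- lambda * weights * drop(crossprod(Z, Ginv_a))
  data.frame(snp = seq_len(ncol(Z)), u_hat = u_hat, weight = weights)
}

#' Iterative weighted single-step GWAS
#'
#' Runs the weighting loop: (1) D = I; (2) build G from current D, tune
#' and blend against A22; (3) solve ssGBLUP for all animals; (4) back-
#' solve SNP effects u_hat = lambda D Z' G*^-1 a_g; (5) set d_i =
#' u_hat_i^2 2 p_i (1 - p_i); (6) normalize the weights to sum to the
#' number of SNP (keeping total genetic variance constant) and loop.
#' Every iteration's SNP effects, weights and GEBV solution are retained;
#' downstream reporting defaults to iteration 2.
#'
#' @param phenotypes data.frame for [build_mme()]
#' @param response,fixed_effects,covariates,pe model specification
#' @param ped ordered pedigree of all animals
#' @param genotypes `genotype_set` (QC'd) for the genotyped subset
#' @param components variance components (fixed across iterations)
#' @param n_iterations number of loop passes (>= 1); 1 = unweighted
#'   ssGWAS
#' @param blend blend fraction for [tune_and_blend()]
#' @param tune apply diagonal/off-diagonal tuning of G to A22
#' @return object of class `wssgwas`: list with `iterations` (each:
#'   `snp_effects`, `weights`, `gebv`, `G_star`), `Z`, `lambda`,
#'   `genotyped_ids`, `map`, `components`
#' @export
iterate_weights <- function(phenotypes, response,
                            fixed_effects = character(),
                            covariates = character(), pe = FALSE,
                            ped, genotypes, components,
                            n_iterations = 3L, blend = 0.05, tune = TRUE) {
  stopifnot(n_iterations >= 1)
  M <- genotypes$dosage
  p_i <- colMeans(M) / 2
  Z <- sweep(M, 2, 2 * p_i)
  lambda <- 1 / sum(2 * p_i * (1 - p_i))
  A <- a_matrix(ped)
  gen_ids <- rownames(M)
  idx <- match(gen_ids, as.character(ped$animal))
  if (anyNA(idx)) stop("genotyped animals absent from pedigree")
  A22 <- A[idx, idx, drop = FALSE]
  A_inv <- .inv_sym(A)

  weights <- rep(1, ncol(M))
  iterations <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    G <- g_matrix(genotypes, weights = weights)
    G_star <- if (tune) tune_and_blend(G, A22, blend = blend) else
      (1 - blend) * G + blend * A22
    H_inv <- A_inv
    H_inv[idx, idx] <- H_inv[idx, idx] + .inv_sym(G_star) - .inv_sym(A22)
    dimnames(H_inv) <- dimnames(A)
    mme <- build_mme(phenotypes, response, fixed_effects, covariates,
                     h_inv = H_inv, pe = pe)
    gebv <- solve_ssgblup(mme, components)
    a_g <- gebv$gebv[match(gen_ids, gebv$animal)]
    eff <- backsolve_snp_effects(a_g, G_star, Z, weights, lambda)
    d_new <- eff$u_hat^2 * 2 * p_i * (1 - p_i)
    if (sum(d_new) <= 0) stop("SNP weights underflowed to zero")
    d_new <- d_new * length(d_new) / sum(d_new)
    iterations[[it]] <- list(snp_effects = eff, weights = weights,
                             gebv = gebv, G_star = G_star)
    weights <- d_new
  }
  structure(list(iterations = iterations, Z = Z, lambda = lambda,
                 genotyped_ids = gen_ids, map = genotypes$map,
                 allele_freq = p_i, components = components),
            class = "wssgwas")
}

# tile each chromosome into non-overlapping runs of `window_size`
# consecutive SNP (map order); the last window on a chromosome may be
# shorter. `sliding = TRUE` instead starts a window at every SNP.
.make_windows <- function(map, window_size, sliding = FALSE) {
  if (is.unsorted(order(map$chrom, map$bp)))
    stop("marker map must be sorted by (chrom, bp)")
  out <- list()
  for (ch in unique(map$chrom)) {
    pos <- which(map$chrom == ch)
    starts <- if (sliding) seq_along(pos) else
      seq(1L, length(pos), by = window_size)
    for (s in starts) {
      e <- min(s + window_size - 1L, length(pos))
      out[[length(out) + 1L]] <-
        data.frame(chrom = ch, snp_from = pos[s], snp_to = pos[e],
                   start_bp = map$bp[pos[s]], end_bp = map$bp[pos[e]],
                   n_snp = e - s + 1L)
    }
  }
  do.call(rbind, out)
}

#' Additive variance explained by windows of consecutive SNP
#'
#' For each non-overlapping window of `window_size` consecutive SNP
#' (within chromosome, map order) computes the variance across genotyped
#' individuals of the window genomic score sum_j Z_j u_hat_j, as a
#' percentage of the total additive genetic variance sigma_a2. Sample
#' variance uses denominator n - 1.
#'
#' @param scan a `wssgwas` object, or a list with `Z`, `map` and SNP
#'   effects
#' @param u_hat SNP effects to use; default: the reporting iteration's
#' @param window_size SNP per window (default 50)
#' @param sigma_a2 total additive variance; default from the scan's
#'   components
#' @param report_iteration which weighting iteration's effects to use
#'   (default 2, capped at the number available)
#' @param sliding use a sliding (per-SNP start) window instead of tiling
#' @return `window_scan` data.frame: `chrom`, `start_bp`, `end_bp`,
#'   `snp_from`, `snp_to`, `n_snp`, `pct_variance`
#' @export
window_variance <- function(scan, u_hat = NULL, window_size = 50L,
                            sigma_a2 = NULL, report_iteration = 2L,
                            sliding = FALSE) {
  if (inherits(scan, "wssgwas")) {
    it <- min(report_iteration, length(scan$iterations))
    if (is.null(u_hat)) u_hat <- scan$iterations[[it]]$snp_effects$u_hat
    if (is.null(sigma_a2)) sigma_a2 <- scan$components$sigma_a2
    Z <- scan$Z
    map <- scan$map
  } else {
    Z <- scan$Z
    map <- scan$map
    stopifnot(!is.null(u_hat), !is.null(sigma_a2))
  }
  stopifnot(length(u_hat) == ncol(Z), sigma_a2 > 0)
  win <- .make_windows(map, window_size, sliding)
  win$pct_variance <- vapply(seq_len(nrow(win)), function(w) {
    j <- win$snp_from[w]:win$snp_to[w]
    score <- Z[, j, drop = FALSE] %*% u_hat[j]
    100 * stats::var(drop(score)) / sigma_a2
  }, numeric(1))
  class(win) <- c("window_scan", "data.frame")
  win
}

#' Flag candidate windows above a variance threshold
#'
#' Windows explaining strictly more than `threshold` percent of the
#' additive genetic variance are candidate QTL regions.
#'
#' @param scan a `window_scan` from [window_variance()]
#' @param threshold percent of additive variance (default 0.50)
#' @return the flagged subset, ordered by decreasing `pct_variance`,
#'   with a `candidate` column
#' @export
candidate_windows <- function(scan, threshold = 0.50) {
  out <- scan[scan$pct_variance > threshold, , drop = FALSE]
  out <- out[order(-out$pct_variance), , drop = FALSE]
  out$candidate <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}
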