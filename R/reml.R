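#' Heritability and repeatability from variance components
#'
#' h^2 = sigma_a^2 / (sigma_a^2 + sigma_p^2 + sigma_e^2) and
#' r = (sigma_a^2 + sigma_p^2) / (sigma_a^2 + sigma_p^2 + sigma_e^2).
#'
#' @param sigma_a2 additive genetic variance
#' @param sigma_p2 permanent-environment variance (0 for single records)
#' @param sigma_e2 residual variance
#' @return list with `h2` and `repeatability`
#' @export
heritability_from_components <- function(sigma_a2, sigma_p2 = 0, sigma_e2) {
  stopifnot(sigma_a2 >= 0, sigma_p2 >= 0, sigma_e2 >= 0)
  tot <- sigma_a2 + sigma_p2 + sigma_e2
  if (tot <= 0) stop("zero total variance")
  list(h2 = sigma_a2 / tot, repeatability = (sigma_a2 + sigma_p2) / tot)
}

# restricted log-likelihood up to a constant (the constant includes
# log|H|, fixed across iterations): -2L = (n - p - q - qp) log se2 +
# q log sa2 + qp log sp2 + log|M| + y'Py
.reml_loglik <- function(mme, logdetM, yPy, sa2, se2, sp2 = NULL) {
  qp <- mme$qp
  val <- (mme$n - mme$p - mme$q - qp) * log(se2) + mme$q * log(sa2) +
    (if (qp > 0) qp * log(sp2) else 0) + logdetM + yPy
  -0.5 * val
}

#' Estimate variance components by average-information REML
#'
#' Maximizes the restricted likelihood of the animal model (optionally
#' with a permanent-environment term) by AI updates computed from the
#' inverse of the mixed-model coefficient matrix, with step-halving when
#' a proposed step leaves the parameter space or decreases the
#' likelihood, and an EM-REML step as fallback. Components are kept
#' positive by a floor at 1e-8 times the phenotypic variance.
#'
#' @param mme from [build_mme()]
#' @param start optional starting values `c(sigma_a2, [sigma_p2,]
#'   sigma_e2)`; default splits the phenotypic variance 50/50 (20% to PE
#'   when present)
#' @param max_iter maximum iterations (default 200)
#' @param tol_param relative parameter-change tolerance
#' @param tol_grad scaled-gradient (d logL / d log sigma^2) tolerance
#' @param verbose print the iteration trace
#' @return a `variance_components` list: `sigma_a2`, `sigma_p2`,
#'   `sigma_e2`, `se` (asymptotic standard errors from the inverse AI
#'   matrix), `h2`, `repeatability`, `loglik` (up to an additive
#'   constant), `converged`, `n_iter`, `trace`
#' @export
aireml <- function(mme, start = NULL, max_iter = 200L, tol_param = 1e-8,
                   tol_grad = 1e-6, verbose = FALSE) {
  has_pe <- mme$qp > 0
  vy <- stats::var(mme$y)
  floor_v <- 1e-8 * vy
  if (is.null(start)) {
    start <- if (has_pe) c(0.4, 0.2, 0.4) * vy else c(0.5, 0.5) * vy
  }
  stopifnot(all(start > 0))
  theta <- start  # (sa2, [sp2,] se2)
  k <- length(theta)
  stopifnot(k == 2L + has_pe)

  eval_point <- function(theta) {
    sa2 <- theta[1]
    sp2 <- if (has_pe) theta[2] else NULL
    se2 <- theta[k]
    la <- se2 / sa2
    lp <- if (has_pe) se2 / sp2 else NULL
    M <- .mme_matrix(mme, la, lp)
    ch <- chol(M)
    Minv <- chol2inv(ch)
    rhs <- .mme_rhs(mme, mme$y)
    sol <- drop(Minv %*% rhs)
    e <- mme$y - .mme_fitted(mme, sol)
    yPy <- (mme$blocks$yty - sum(sol * rhs)) / se2
    logdetM <- 2 * sum(log(diag(ch)))
    ll <- .reml_loglik(mme, logdetM, yPy, sa2, se2, sp2)
    list(theta = theta, sol = sol, e = e, Minv = Minv, ll = ll, ch = ch)
  }

  score_ai <- function(ev) {
    sa2 <- ev$theta[1]
    sp2 <- if (has_pe) ev$theta[2] else NULL
    se2 <- ev$theta[k]
    p <- mme$p; q <- mme$q; qp <- mme$qp
    ia <- p + seq_len(q)
    a_hat <- ev$sol[ia]
    Caa <- se2 * ev$Minv[ia, ia]
    tr_HiCaa <- sum(mme$h_inv * Caa)
    aHa <- drop(crossprod(a_hat, mme$h_inv %*% a_hat))
    trPVa <- (q - tr_HiCaa / sa2) / sa2
    g_a <- -0.5 * (trPVa - aHa / sa2^2)
    g_p <- NULL; trPVp <- 0
    if (has_pe) {
      ip <- p + q + seq_len(qp)
      p_hat <- ev$sol[ip]
      tr_Cpp <- se2 * sum(diag(ev$Minv)[ip])
      trPVp <- (qp - tr_Cpp / sp2) / sp2
      g_p <- -0.5 * (trPVp - sum(p_hat^2) / sp2^2)
    }
    trP <- (mme$n - mme$p - sa2 * trPVa -
              (if (has_pe) sp2 * trPVp else 0)) / se2
    g_e <- -0.5 * (trP - sum(ev$e^2) / se2^2)
    grad <- c(g_a, if (has_pe) g_p, g_e)

    # AI matrix via extra right-hand sides: f_i'P f_j with
    # P g = (g - fitted_g)/se2 from an MME solve on g
    F <- cbind(a_hat[mme$rec_a] / sa2,
               if (has_pe) ev$sol[p + q + mme$rec_pe] / sp2,
               ev$e / se2)
    PF <- sapply(seq_len(ncol(F)), function(j) {
      rhs_f <- .mme_rhs(mme, F[, j])
      sol_f <- drop(ev$Minv %*% rhs_f)
      (F[, j] - .mme_fitted(mme, sol_f)) / se2
    })
    AI <- 0.5 * crossprod(F, PF)
    AI <- (AI + t(AI)) / 2
    list(grad = grad, AI = AI)
  }

  em_step <- function(ev) {
    sa2 <- ev$theta[1]
    se2 <- ev$theta[k]
    p <- mme$p; q <- mme$q; qp <- mme$qp
    ia <- p + seq_len(q)
    a_hat <- ev$sol[ia]
    Caa <- se2 * ev$Minv[ia, ia]
    new_a <- (drop(crossprod(a_hat, mme$h_inv %*% a_hat)) +
                sum(mme$h_inv * Caa)) / q
    new_p <- NULL
    if (has_pe) {
      ip <- p + q + seq_len(qp)
      new_p <- (sum(ev$sol[ip]^2) + se2 * sum(diag(ev$Minv)[ip])) / qp
    }
    rhs <- .mme_rhs(mme, mme$y)
    new_e <- (mme$blocks$yty - sum(ev$sol * rhs)) / (mme$n - mme$p)
    pmax(c(new_a, if (has_pe) new_p, new_e), floor_v)
  }

  ev <- eval_point(theta)
  trace <- data.frame(iter = 0L, t(theta), loglik = ev$ll)
  converged <- FALSE
  last_sc <- NULL
  for (it in seq_len(max_iter)) {
    sc <- score_ai(ev)
    last_sc <- sc
    scaled_grad <- sqrt(sum((sc$grad * ev$theta)^2))
    delta <- tryCatch(solve(sc$AI, sc$grad), error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(delta) && all(is.finite(delta))) {
      step <- 1
      for (h in 1:12) {
        prop <- ev$theta + step * delta
        if (all(prop >= floor_v)) {
          ev_new <- tryCatch(eval_point(prop), error = function(e) NULL)
          if (!is.null(ev_new) && is.finite(ev_new$ll) &&
              ev_new$ll >= ev$ll - 1e-10) {
            accepted <- TRUE
            break
          }
        }
        step <- step / 2
      }
    }
    if (!accepted) {   # EM fallback (always increases the likelihood)
      prop <- em_step(ev)
      ev_new <- eval_point(prop)
    }
    rel_change <- max(abs(ev_new$theta - ev$theta) /
                        pmax(abs(ev$theta), floor_v))
    ev <- ev_new
    trace <- rbind(trace, data.frame(iter = it, t(ev$theta), loglik = ev$ll))
    if (verbose)
      message(sprintf("it %3d  logL %.6f  theta %s  %s", it, ev$ll,
                      paste(signif(ev$theta, 6), collapse = " "),
                      if (accepted) "AI" else "EM"))
    if (rel_change < tol_param && scaled_grad < tol_grad) {
      converged <- TRUE
      break
    }
  }
  sc <- score_ai(ev)
  se <- tryCatch(sqrt(diag(solve(sc$AI))), error = function(e)
    rep(NA_real_, k))
  sigma_a2 <- ev$theta[1]
  sigma_p2 <- if (has_pe) ev$theta[2] else 0
  sigma_e2 <- ev$theta[k]
  hr <- heritability_from_components(sigma_a2, sigma_p2, sigma_e2)
  nm <- if (has_pe) c("sigma_a2", "sigma_p2", "sigma_e2") else
    c("sigma_a2", "sigma_e2")
  structure(list(sigma_a2 = sigma_a2, sigma_p2 = sigma_p2,
                 sigma_e2 = sigma_e2,
                 se = stats::setNames(se, nm),
                 h2 = hr$h2, repeatability = hr$repeatability,
                 loglik = ev$ll, converged = converged, n_iter = it,
                 trace = trace),
            class = "variance_components")
}

#' Bivariate REML: genetic and residual covariances for two traits
#'
#' Fits the two-trait animal model on animals observed for both traits
#' (single record each): Var(vec(a)) = G0 (x) H, Var(vec(e)) = R0 (x) I.
#' The restricted likelihood is evaluated through the stacked mixed-model
#' equations and maximized over Cholesky factors of G0 and R0 (so both
#' are positive semidefinite by construction and the genetic correlation
#' lies in [-1, 1]).
#'
#' @param data data.frame with `animal`, both response columns, fixed
#'   effects and covariates (one record per animal)
#' @param responses character(2): the two trait columns
#' @param fixed_effects,covariates as in [build_mme()] (shared by both
#'   traits)
#' @param h_inv inverse relationship matrix with animal-id dimnames
#' @param max_iter optimizer iteration cap
#' @return list: `G0`, `R0` (2x2 matrices), `genetic_correlation`,
#'   `residual_correlation`, `loglik`, `converged`
#' @export
bivariate_reml <- function(data, responses, fixed_effects = character(),
                           covariates = character(), h_inv,
                           max_iter = 200L) {
  stopifnot(length(responses) == 2,
            !anyDuplicated(data$animal))
  # reuse the univariate builder for X and the record->animal index
  mme1 <- build_mme(data, responses[1], fixed_effects, covariates, h_inv)
  y1 <- data[[responses[1]]]
  y2 <- data[[responses[2]]]
  stopifnot(all(is.finite(y1)), all(is.finite(y2)))
  X <- mme1$X
  p <- ncol(X)
  q <- mme1$q
  n <- nrow(X)
  rec_a <- mme1$rec_a
  Zind <- function(v) {             # Z'v (length q)
    out <- numeric(q)
    s <- rowsum(v, rec_a)
    out[as.integer(rownames(s))] <- s
    out
  }
  counts <- tabulate(rec_a, q)
  XtX <- crossprod(X)
  ZtX <- matrix(0, q, p)
  sX <- rowsum(X, rec_a)
  ZtX[as.integer(rownames(sX)), ] <- sX
  Y <- cbind(y1, y2)
  XtY <- crossprod(X, Y)
  ZtY <- cbind(Zind(y1), Zind(y2))
  YtY <- crossprod(Y)

  dim_tot <- 2 * (p + q)
  ib <- list(seq_len(p), p + seq_len(p))
  ia <- list(2 * p + seq_len(q), 2 * p + q + seq_len(q))

  neg_loglik <- function(par) {
    Lg <- matrix(c(exp(par[1]), par[2], 0, exp(par[3])), 2, 2)
    Lr <- matrix(c(exp(par[4]), par[5], 0, exp(par[6])), 2, 2)
    G0 <- tcrossprod(Lg)
    R0 <- tcrossprod(Lr)
    Ri <- tryCatch(solve(R0), error = function(e) NULL)
    Gi <- tryCatch(solve(G0), error = function(e) NULL)
    if (is.null(Ri) || is.null(Gi)) return(1e10)
    M <- matrix(0, dim_tot, dim_tot)
    rhs <- numeric(dim_tot)
    for (s in 1:2) for (t in 1:2) {
      M[ib[[s]], ib[[t]]] <- Ri[s, t] * XtX
      M[ia[[s]], ib[[t]]] <- Ri[s, t] * ZtX
      M[ib[[s]], ia[[t]]] <- Ri[s, t] * t(ZtX)
      blk <- Gi[s, t] * h_inv
      diag(blk) <- diag(blk) + Ri[s, t] * counts
      M[ia[[s]], ia[[t]]] <- blk
      rhs[ib[[s]]] <- rhs[ib[[s]]] + Ri[s, t] * XtY[, t]
      rhs[ia[[s]]] <- rhs[ia[[s]]] + Ri[s, t] * ZtY[, t]
    }
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    sol <- drop(backsolve(ch, backsolve(ch, rhs, transpose = TRUE)))
    yRy <- sum(Ri * YtY)
    yPy <- yRy - sum(sol * rhs)
    logdetM <- 2 * sum(log(diag(ch)))
    ll <- -0.5 * (n * determinant(R0)$modulus + q * determinant(G0)$modulus +
                    logdetM + yPy)
    -as.numeric(ll)
  }

  v1 <- stats::var(y1); v2 <- stats::var(y2)
  par0 <- c(0.5 * log(0.5 * v1), 0, 0.5 * log(0.5 * v2),
            0.5 * log(0.5 * v1), 0, 0.5 * log(0.5 * v2))
  opt <- stats::nlminb(par0, neg_loglik,
                       control = list(iter.max = max_iter, eval.max = 1000))
  par <- opt$par
  Lg <- matrix(c(exp(par[1]), par[2], 0, exp(par[3])), 2, 2)
  Lr <- matrix(c(exp(par[4]), par[5], 0, exp(par[6])), 2, 2)
  G0 <- tcrossprod(Lg)
  R0 <- tcrossprod(Lr)
  list(G0 = G0, R0 = R0,
       genetic_correlation = G0[1, 2] / sqrt(G0[1, 1] * G0[2, 2]),
       residual_correlation = R0[1, 2] / sqrt(R0[1, 1] * R0[2, 2]),
       loglik = -opt$objective, converged = opt$convergence == 0)
}
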