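#' Assemble Henderson's mixed-model equations for the animal model
#'
#' Sets up the single-trait model
#' y = Xb + Za + (Wp) + e with a ~ N(0, H sigma_a^2),
#' p ~ N(0, I sigma_p^2) (permanent environment, only with repeated
#' records) and e ~ N(0, I sigma_e^2). Fixed effects are supplied as
#' factor columns (typically herd-year-season, country and, for
#' multiparous data, parity) plus linear and quadratic age-at-calving
#' covariates. Aliased fixed-effect columns are dropped so the system is
#' full rank. The incidence of records on animals is stored as an index,
#' never as a dense Z.
#'
#' @param data data.frame of phenotypes; must contain `animal`, the
#'   response, the fixed-effect and covariate columns
#' @param response name of the response column
#' @param fixed_effects character vector of factor columns (may be empty)
#' @param covariates character vector of numeric columns entered linearly
#'   and quadratically (centered first)
#' @param h_inv inverse relationship matrix for the additive term, with
#'   dimnames = animal ids (from [h_inverse()] or `solve(A)`)
#' @param pe add a permanent-environment term (one level per animal with
#'   records); required when animals have repeated records
#' @return an object of class `mme` holding the precomputed normal
#'   equation blocks
#' @export
build_mme <- function(data, response, fixed_effects = character(),
                      covariates = character(), h_inv, pe = FALSE) {
  stopifnot("animal" %in% names(data), response %in% names(data))
  ids <- rownames(h_inv)
  if (is.null(ids)) stop("h_inv must carry animal ids as dimnames")
  rec_a <- match(as.character(data$animal), ids)
  if (anyNA(rec_a))
    stop("phenotyped animals absent from the relationship matrix: ",
         paste(utils::head(unique(data$animal[is.na(rec_a)]), 5),
               collapse = ", "))
  if (!pe && anyDuplicated(data$animal))
    stop("repeated records per animal require pe = TRUE")

  y <- data[[response]]
  stopifnot(is.numeric(y), all(is.finite(y)))
  terms <- "1"
  df <- data.frame(row.names = seq_len(nrow(data)))
  for (f in fixed_effects) {
    df[[f]] <- factor(data[[f]])
    terms <- c(terms, f)
  }
  for (v in covariates) {
    df[[v]] <- data[[v]] - mean(data[[v]])
    df[[paste0(v, "_sq")]] <- df[[v]]^2
    terms <- c(terms, v, paste0(v, "_sq"))
  }
  X <- stats::model.matrix(stats::as.formula(paste("~", paste(terms,
                                                              collapse = "+"))),
                           df)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) X <- X[, qr_x$pivot[seq_len(qr_x$rank)],
                                  drop = FALSE]
  p <- ncol(X)
  n <- length(y)
  q <- nrow(h_inv)

  rec_pe <- NULL
  qp <- 0L
  pe_ids <- NULL
  if (pe) {
    pe_ids <- unique(as.character(data$animal))
    rec_pe <- match(as.character(data$animal), pe_ids)
    qp <- length(pe_ids)
  }

  agg_a <- function(v) {           # Z'v as a length-q vector
    out <- numeric(q)
    s <- rowsum(v, rec_a)
    out[as.integer(rownames(s))] <- s
    out
  }
  agg_pe <- function(v) {
    out <- numeric(qp)
    s <- rowsum(v, rec_pe)
    out[as.integer(rownames(s))] <- s
    out
  }
  ZtX <- matrix(0, q, p)
  sX <- rowsum(X, rec_a)
  ZtX[as.integer(rownames(sX)), ] <- sX
  counts_a <- tabulate(rec_a, q)
  blocks <- list(XtX = crossprod(X), Xty = crossprod(X, y),
                 ZtX = ZtX, Zty = agg_a(y), counts_a = counts_a,
                 yty = sum(y^2))
  if (pe) {
    WtX <- matrix(0, qp, p)
    sW <- rowsum(X, rec_pe)
    WtX[as.integer(rownames(sW)), ] <- sW
    ZtW <- matrix(0, q, qp)
    cross <- table(rec_a, rec_pe)
    ZtW[cbind(as.integer(rownames(cross))[row(cross)],
              as.integer(colnames(cross))[col(cross)])] <- as.numeric(cross)
    blocks <- c(blocks, list(WtX = WtX, Wty = agg_pe(y),
                             counts_pe = tabulate(rec_pe, qp), ZtW = ZtW))
  }
  structure(list(y = y, n = n, X = X, p = p, q = q, qp = qp,
                 rec_a = rec_a, rec_pe = rec_pe, ids = ids,
                 pe_ids = pe_ids, h_inv = h_inv, blocks = blocks,
                 agg_a = agg_a, agg_pe = if (pe) agg_pe else NULL),
            class = "mme")
}

# coefficient matrix in variance-ratio form:
# [X'X  X'Z        X'W      ]
# [Z'X  Z'Z+la*Hi  Z'W      ]
# [W'X  W'Z        W'W+lp*I ]
.mme_matrix <- function(mme, lambda_a, lambda_p = NULL) {
  b <- mme$blocks
  p <- mme$p; q <- mme$q; qp <- mme$qp
  dim_tot <- p + q + qp
  M <- matrix(0, dim_tot, dim_tot)
  ia <- p + seq_len(q)
  M[seq_len(p), seq_len(p)] <- b$XtX
  M[ia, seq_len(p)] <- b$ZtX
  M[seq_len(p), ia] <- t(b$ZtX)
  M[ia, ia] <- lambda_a * mme$h_inv
  diag(M)[ia] <- diag(M)[ia] + b$counts_a
  if (qp > 0) {
    ip <- p + q + seq_len(qp)
    M[ip, seq_len(p)] <- b$WtX
    M[seq_len(p), ip] <- t(b$WtX)
    M[ia, ip] <- b$ZtW
    M[ip, ia] <- t(b$ZtW)
    diag(M)[ip] <- b$counts_pe + lambda_p
  }
  M
}

.mme_rhs <- function(mme, v) {
  rhs <- c(crossprod(mme$X, v), mme$agg_a(v))
  if (mme$qp > 0) rhs <- c(rhs, mme$agg_pe(v))
  rhs
}

# record-level fitted values from a stacked solution vector
.mme_fitted <- function(mme, sol) {
  p <- mme$p; q <- mme$q
  fit <- drop(mme$X %*% sol[seq_len(p)]) + sol[p + mme$rec_a]
  if (mme$qp > 0) fit <- fit + sol[p + q + mme$rec_pe]
  fit
}

#' Solve the mixed-model equations at fixed variance components
#'
#' @param mme from [build_mme()]
#' @param sigma_a2,sigma_p2,sigma_e2 variance components (sigma_p2 ignored
#'   without a PE term)
#' @param keep_inverse retain the full inverse coefficient matrix (needed
#'   for PEV/accuracy)
#' @return list: `fixed` (named), `a` (breeding values, all animals in H),
#'   `pe`, `residuals`, `lambda_a`, `lambda_p`, and with
#'   `keep_inverse = TRUE` also `C` (sigma_e2 x inverse coefficient
#'   matrix) and `pev` (diagonal of the additive block of C)
#' @export
solve_mme <- function(mme, sigma_a2, sigma_e2, sigma_p2 = NULL,
                      keep_inverse = FALSE) {
  stopifnot(sigma_a2 > 0, sigma_e2 > 0)
  lambda_a <- sigma_e2 / sigma_a2
  lambda_p <- if (mme$qp > 0) sigma_e2 / sigma_p2 else NULL
  M <- .mme_matrix(mme, lambda_a, lambda_p)
  rhs <- .mme_rhs(mme, mme$y)
  ch <- tryCatch(chol(M), error = function(e)
    stop("singular coefficient matrix (confounded fixed effects?): ",
         conditionMessage(e)))
  sol <- drop(backsolve(ch, backsolve(ch, rhs, transpose = TRUE)))
  p <- mme$p; q <- mme$q
  out <- list(fixed = stats::setNames(sol[seq_len(p)], colnames(mme$X)),
              a = stats::setNames(sol[p + seq_len(q)], mme$ids),
              pe = if (mme$qp > 0)
                stats::setNames(sol[p + q + seq_len(mme$qp)], mme$pe_ids)
              else NULL,
              residuals = mme$y - .mme_fitted(mme, sol),
              lambda_a = lambda_a, lambda_p = lambda_p, solution = sol)
  if (keep_inverse) {
    Minv <- chol2inv(ch)
    out$C <- sigma_e2 * Minv
    out$pev <- diag(out$C)[p + seq_len(q)]
    names(out$pev) <- mme$ids
  }
  out
}
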