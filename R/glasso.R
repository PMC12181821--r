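## Graphical lasso by blockwise coordinate descent, and EBIC model selection
## over a penalty path.
##
## The estimator maximizes
##   log det(Theta) - trace(S Theta) - lambda * sum_{i != j} |Theta_ij|
## (off-diagonal penalty only, so lambda = 0 returns the unpenalized MLE
## Theta = S^{-1}). Convergence is certified through the KKT residual of
## the stationarity condition Theta^{-1} = S + lambda * sign(Theta) on the
## off-diagonal, which controls the duality gap.

## lasso subproblem by coordinate descent:
## minimize 0.5 * b' V b - s' b + lam * ||b||_1  (V positive definite)
.lasso_cd <- function(V, s, lam, b = rep(0, length(s)),
                      tol = 1e-10, max_iter = 10000L) {
  .lasso_cd_cpp(V, s, lam, b, tol, max_iter)
}

#' Graphical lasso precision-matrix estimate
#'
#' Solves the L1-penalized Gaussian log-likelihood problem for the precision
#' matrix Theta by blockwise coordinate descent (Friedman-Hastie-Tibshirani
#' scheme; the diagonal is not penalized). Returns the estimate once the
#' maximal KKT residual of the off-diagonal stationarity condition
#' Theta^{-1} = S + lambda sign(Theta) falls below \code{tol}.
#'
#' @param S covariance/correlation matrix (positive definite) or a
#'   \code{cor_matrix}.
#' @param lam penalty, lambda >= 0.
#' @param tol duality-gap tolerance (default 1e-7).
#' @param max_iter outer sweep cap.
#' @param W_init optional warm-start covariance estimate (from a neighbouring
#'   penalty on a path).
#' @return list with \code{Theta} (precision estimate), \code{W} (its
#'   inverse, the covariance estimate), \code{gap} (stationarity residual),
#'   \code{iterations}.
#' @export
graphical_lasso <- function(S, lam, tol = 1e-7, max_iter = 200L,
                            W_init = NULL, B_init = NULL) {
  if (inherits(S, "cor_matrix")) S <- S$S
  S <- as.matrix(S)
  p <- ncol(S)
  stopifnot(isTRUE(all.equal(S, t(S), tolerance = 1e-8)), lam >= 0)
  if (lam == 0) {
    Theta <- solve(S)
    W <- S
    gap <- abs(sum(diag(S %*% Theta)) - p)
    return(list(Theta = (Theta + t(Theta)) / 2, W = W, gap = gap,
                iterations = 0L))
  }
  W <- if (is.null(W_init)) S else (W_init + t(W_init)) / 2
  diag(W) <- diag(S)                       # diagonal unpenalized
  B <- if (is.null(B_init)) matrix(0, p, p) else B_init
  gap <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      V <- W[idx, idx, drop = FALSE]
      s <- S[idx, j]
      b <- .lasso_cd(V, s, lam, b = B[idx, j])
      B[idx, j] <- b
      w12 <- as.vector(V %*% b)
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    ## reconstruct Theta from the final W and regression coefficients
    Theta <- matrix(0, p, p)
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      theta_jj <- 1 / (W[j, j] - sum(W[idx, j] * B[idx, j]))
      Theta[j, j] <- theta_jj
      Theta[idx, j] <- -B[idx, j] * theta_jj
    }
    Theta <- (Theta + t(Theta)) / 2
    gap <- .kkt_residual(Theta, S, lam)
    if (gap < tol || it >= max_iter) break
  }
  if (gap >= tol)
    stop(sprintf("graphical lasso did not converge: KKT residual %.3g after %d sweeps",
                 gap, it))
  ## snap numerically-zero boundary coefficients (|.| < 1e-8) to exact zero
  ## so the edge support of the penalized solution is well defined
  zap <- abs(Theta) < 1e-8 & row(Theta) != col(Theta)
  if (any(zap)) Theta[zap] <- 0
  dimnames(Theta) <- dimnames(S)
  dimnames(W) <- dimnames(S)
  list(Theta = Theta, W = W, B = B, gap = gap, iterations = it)
}

## KKT residual of the off-diagonal stationarity conditions:
##   Theta_ij != 0:  (Theta^{-1})_ij = S_ij + lam * sign(Theta_ij)
##   Theta_ij  = 0:  |(Theta^{-1})_ij - S_ij| <= lam
.kkt_residual <- function(Theta, S, lam) {
  Winv <- tryCatch(solve(Theta), error = function(e) NULL)
  if (is.null(Winv)) return(Inf)
  R <- Winv - S
  nz <- Theta != 0
  diag(nz) <- FALSE
  z <- !nz
  diag(z) <- FALSE
  res <- 0
  if (any(nz)) res <- max(res, max(abs(R[nz] - lam * sign(Theta[nz]))))
  if (any(z)) res <- max(res, max(pmax(abs(R[z]) - lam, 0)))
  res
}

## EBIC of a fitted precision matrix:
##   -n [log det Theta - tr(S Theta)] + E log n + 4 E gamma log p
## with E the number of nonzero off-diagonal upper-triangle entries.
ebic_score <- function(Theta, S, n, gamma) {
  p <- ncol(S)
  E <- sum(Theta[upper.tri(Theta)] != 0)
  ld <- determinant(Theta, logarithm = TRUE)
  -n * (as.numeric(ld$modulus) - sum(S * Theta)) +
    E * log(n) + 4 * E * gamma * log(p)
}

#' EBIC model selection over a graphical-lasso penalty path
#'
#' Fits the graphical lasso along a log-spaced path of \code{n_lambda}
#' penalties from \code{lambda_max} (the largest absolute off-diagonal
#' correlation, where the graph is empty) down to
#' \code{lambda_max * lambda_min_ratio}, scores each fit with the extended
#' BIC, and returns the minimizing model. Ties are broken towards the
#' smallest penalty (densest candidate).
#'
#' @param S a \code{cor_matrix} (or plain matrix, in which case \code{n}
#'   must be given).
#' @param gamma EBIC hyperparameter, >= 0; gamma = 0 is plain BIC. Default
#'   0.5.
#' @param n_lambda number of penalties on the path (default 100).
#' @param lambda_min_ratio ratio of smallest to largest penalty (default
#'   0.01).
#' @param n effective sample size; defaults to \code{S$n}.
#' @return list with \code{Theta}, \code{lambda} (selected penalty),
#'   \code{path} (data frame lambda / edges / ebic), \code{gamma}.
#' @export
ebic_select <- function(S, gamma = 0.5, n_lambda = 100L,
                        lambda_min_ratio = 0.01, n = NULL) {
  if (inherits(S, "cor_matrix")) {
    if (is.null(n)) n <- S$n
    S <- S$S
  }
  stopifnot(!is.null(n), n > 1, gamma >= 0, n_lambda >= 2,
            lambda_min_ratio > 0, lambda_min_ratio < 1)
  p <- ncol(S)
  off <- abs(S[upper.tri(S)])
  lambda_max <- max(off)
  if (lambda_max == 0) {
    warning("all off-diagonal correlations are zero; returning empty network")
    Theta <- diag(1 / diag(S))
    dimnames(Theta) <- dimnames(S)
    return(list(Theta = Theta, lambda = 0,
                path = data.frame(lambda = 0, edges = 0,
                                  ebic = ebic_score(Theta, S, n, gamma)),
                gamma = gamma))
  }
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                     length.out = n_lambda))
  fits <- vector("list", n_lambda)
  ebics <- numeric(n_lambda)
  edges <- integer(n_lambda)
  W_warm <- NULL
  B_warm <- NULL
  for (i in seq_along(lambdas)) {
    fit <- graphical_lasso(S, lambdas[i], W_init = W_warm, B_init = B_warm)
    W_warm <- fit$W
    B_warm <- fit$B
    fits[[i]] <- fit$Theta
    ebics[i] <- ebic_score(fit$Theta, S, n, gamma)
    edges[i] <- sum(fit$Theta[upper.tri(fit$Theta)] != 0)
  }
  ## ties broken towards the smallest lambda: last index attaining the min
  best <- max(which(ebics <= min(ebics) + 0))
  list(Theta = fits[[best]], lambda = lambdas[best],
       path = data.frame(lambda = lambdas, edges = edges, ebic = ebics),
       gamma = gamma)
}
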