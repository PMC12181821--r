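## Two-step maximum-likelihood polychoric correlation for ordinal data.
##
## Step 1 fixes each variable's thresholds at standard-normal quantiles of
## the marginal cumulative proportions; step 2 maximizes the bivariate-normal
## cell-probability likelihood over the latent correlation.

## thresholds from marginal frequencies of one ordinal vector
polychoric_thresholds <- function(x) {
  tab <- table(factor(x))
  cum <- cumsum(tab) / sum(tab)
  stats::qnorm(cum[-length(cum)])
}

## log-likelihood of the contingency table at latent correlation rho
.polyc_loglik <- function(rho, tab, a, b) {
  ra <- c(-Inf, a, Inf)
  rb <- c(-Inf, b, Inf)
  nr <- nrow(tab); nc <- ncol(tab)
  ## CDF on the full threshold grid, then rectangle differences
  grid_h <- rep(ra, times = nc + 1L)
  grid_k <- rep(rb, each = nr + 1L)
  Phi <- matrix(pbvnorm(grid_h, grid_k, rho), nr + 1L, nc + 1L)
  P <- Phi[-1, -1, drop = FALSE] - Phi[-(nr + 1L), -1, drop = FALSE] -
       Phi[-1, -(nc + 1L), drop = FALSE] + Phi[-(nr + 1L), -(nc + 1L), drop = FALSE]
  P <- pmax(P, 1e-12)
  sum(tab * log(P))
}

#' Polychoric correlation of two ordinal variables
#'
#' @param x,y ordinal vectors (integer codes; missing values dropped
#'   pairwise).
#' @param bound optimization bound: rho is searched in (-bound, bound) and
#'   clipped there (perfectly associated variables hit the bound).
#' @return scalar correlation estimate.
#' @export
polychoric_rho <- function(x, y, bound = 0.999) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  ## category levels taken jointly so the table covers observed codes
  fx <- factor(x); fy <- factor(y)
  if (nlevels(fx) < 2) stop("variable 'x' has fewer than 2 observed categories")
  if (nlevels(fy) < 2) stop("variable 'y' has fewer than 2 observed categories")
  tab <- table(fx, fy)
  a <- polychoric_thresholds(x)
  b <- polychoric_thresholds(y)
  opt <- stats::optimize(function(r) .polyc_loglik(r, tab, a, b),
                         interval = c(-bound, bound), maximum = TRUE,
                         tol = 1e-6)
  max(-bound, min(bound, opt$maximum))
}

#' Polychoric correlation matrix of an ordinal data matrix
#'
#' Pairwise two-step estimates assembled into a matrix and, if needed,
#' repaired to positive definiteness by eigenvalue clipping at 1e-6 with
#' re-standardization to unit diagonal (pairwise polychoric matrices are not
#' guaranteed positive definite).
#'
#' @param nodes matrix or data frame of ordinal codes, one column per node.
#' @param n effective sample size recorded with the matrix (defaults to
#'   \code{nrow(nodes)}; for stacked multiply-imputed data pass the original
#'   number of participants).
#' @return object of class \code{cor_matrix}: list with \code{S} (the
#'   correlation matrix), \code{kind = "polychoric"} and \code{n}.
#' @export
polychoric_matrix <- function(nodes, n = nrow(nodes)) {
  nodes <- as.matrix(nodes)
  p <- ncol(nodes)
  labs <- colnames(nodes) %||% paste0("V", seq_len(p))
  for (j in seq_len(p)) {
    v <- nodes[, j]
    if (length(unique(v[!is.na(v)])) < 2)
      stop("node '", labs[j], "' is constant; polychoric correlation undefined")
  }
  S <- diag(1, p)
  dimnames(S) <- list(labs, labs)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      S[i, j] <- S[j, i] <- polychoric_rho(nodes[, i], nodes[, j])
    }
  }
  S <- repair_pd(S)
  structure(list(S = S, kind = "polychoric", n = n), class = "cor_matrix")
}

#' Pearson correlation matrix in the same container
#'
#' @param x numeric matrix.
#' @param n effective sample size (defaults to \code{nrow(x)}).
#' @return a \code{cor_matrix} with \code{kind = "pearson"}.
#' @export
pearson_matrix <- function(x, n = nrow(x)) {
  S <- repair_pd(stats::cor(as.matrix(x), use = "pairwise.complete.obs"))
  structure(list(S = S, kind = "pearson", n = n), class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, ...) {
  cat(sprintf("%s correlation matrix, %d variables, n = %d\n",
              x$kind, ncol(x$S), x$n))
  invisible(x)
}
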