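## Internal utilities shared across the pipeline.

#' Derive a stage-specific seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its randomness from a seed
#' derived deterministically from one global integer seed and a stage label,
#' so stages are individually reproducible even when others are toggled off.
#'
#' @param seed integer global seed.
#' @param label character stage label (e.g. "impute", "boot:17").
#' @return an integer seed in [0, 2^31 - 1).
#' @keywords internal
split_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  ## simple 32-bit FNV-1a style mix of the label bytes into the seed
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(label)) {
    h <- (h * 33 + b) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  force(seed)   # before saving state: evaluating `seed` may advance the RNG
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Repair a symmetric matrix to positive definiteness
#'
#' Eigenvalue clipping at `eps`, followed by rescaling to unit diagonal.
#' Used for polychoric correlation matrices, which are assembled pairwise and
#' are not guaranteed positive definite.
#'
#' @param S symmetric matrix with unit diagonal.
#' @param eps minimum eigenvalue after repair.
#' @return positive-definite correlation matrix.
#' @keywords internal
repair_pd <- function(S, eps = 1e-6) {
  dn <- dimnames(S)
  S <- (S + t(S)) / 2
  ee <- eigen(S, symmetric = TRUE)
  if (min(ee$values) >= eps) return(S)
  vals <- pmax(ee$values, eps)
  R <- ee$vectors %*% (vals * t(ee$vectors))
  d <- sqrt(diag(R))
  R <- R / outer(d, d)
  diag(R) <- 1
  R <- (R + t(R)) / 2
  dimnames(R) <- dn
  R
}

## precision matrix -> partial correlation matrix (zero diagonal)
prec_to_pcor <- function(K) {
  d <- sqrt(diag(K))
  P <- -K / outer(d, d)
  diag(P) <- 0
  (P + t(P)) / 2
}

## Scale a covariance/precision-derived matrix to a correlation matrix.
cov2cor_safe <- function(V) {
  d <- sqrt(diag(V))
  R <- V / outer(d, d)
  diag(R) <- 1
  (R + t(R)) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
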