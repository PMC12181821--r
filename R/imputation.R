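## Fully conditional specification multiple imputation with predictive mean
## matching (non-dichotomous variables) and logistic regression imputation
## (dichotomous variables), plus Rubin-rules pooling.

#' Imputation configuration
#'
#' @param m number of imputations (default 20).
#' @param max_iterations FCS sweeps per chain (default 10).
#' @param donor_pool PMM donor count k (default 5).
#' @param max_predictors cap on predictors per conditional model (default
#'   15): for each target the predictors are the variables with highest
#'   absolute Spearman correlation on pairwise-complete data, keeping the
#'   conditional models well below the number of observations.
#' @param seed integer seed.
#' @return an \code{imputation_config} list.
#' @export
imputation_config <- function(m = 20L, max_iterations = 10L, donor_pool = 5L,
                              max_predictors = 15L, seed = 1L) {
  stopifnot(m >= 1, max_iterations >= 1, donor_pool >= 1, max_predictors >= 1)
  structure(list(m = as.integer(m), max_iterations = as.integer(max_iterations),
                 donor_pool = as.integer(donor_pool),
                 max_predictors = as.integer(max_predictors),
                 seed = as.integer(seed)),
            class = "imputation_config")
}

#' Predictive-mean-matching imputation step
#'
#' Bayesian linear regression with posterior draws: the residual variance is
#' drawn from its scaled inverse chi-square, coefficients from the normal
#' posterior around the least-squares fit. Predicted means are computed with
#' the drawn coefficients for missing rows and with the least-squares
#' coefficients for observed rows; each missing row is matched to the
#' \code{k} observed rows with nearest predicted mean and one donor's
#' observed value is copied (type-1 matching).
#'
#' @param y_observed observed outcome values.
#' @param X_observed design matrix for observed rows (no intercept column;
#'   one is added internally).
#' @param X_missing design matrix for rows to impute.
#' @param k donor pool size.
#' @param seed integer seed.
#' @return imputed vector of length \code{nrow(X_missing)}.
#' @export
pmm_step <- function(y_observed, X_observed, X_missing, k = 5L, seed = 1L) {
  X_observed <- as.matrix(X_observed)
  X_missing <- as.matrix(X_missing)
  n <- length(y_observed)
  stopifnot(nrow(X_observed) == n, k >= 1, k <= n)
  Xo <- cbind(1, X_observed)
  Xm <- cbind(1, X_missing)
  with_seed(split_seed(seed, "pmm"), {
    qr_fit <- qr(Xo)
    if (qr_fit$rank < ncol(Xo)) {
      ## singular design: ridge fallback with a fixed small penalty
      warning("singular design in PMM step; ridge fallback applied")
      lam <- 1e-5 * n
      XtX <- crossprod(Xo) + diag(lam, ncol(Xo))
      beta_hat <- solve(XtX, crossprod(Xo, y_observed))
      XtX_inv <- solve(XtX)
    } else {
      beta_hat <- qr.coef(qr_fit, y_observed)
      XtX_inv <- chol2inv(qr_fit$qr[seq_len(ncol(Xo)), , drop = FALSE])
    }
    resid <- y_observed - as.vector(Xo %*% beta_hat)
    df <- max(n - ncol(Xo), 1)
    sigma2 <- sum(resid^2) / stats::rchisq(1, df)
    L <- chol(sigma2 * (XtX_inv + t(XtX_inv)) / 2)
    beta_star <- beta_hat + as.vector(t(L) %*% stats::rnorm(ncol(Xo)))
    yhat_obs <- as.vector(Xo %*% beta_hat)
    yhat_mis <- as.vector(Xm %*% beta_star)
    vapply(yhat_mis, function(mu) {
      d <- abs(yhat_obs - mu)
      donors <- order(d, sample.int(n))[seq_len(k)]   # random tie-break
      y_observed[donors[sample.int(k, 1)]]
    }, numeric(1))
  })
}

#' Logistic-regression imputation step for dichotomous variables
#'
#' Fits a logistic regression on the observed rows, draws coefficients from
#' the asymptotic normal posterior and imputes Bernoulli draws at the
#' implied probabilities. Complete separation (or other non-convergence)
#' falls back to a weakly ridge-penalized fit; a single observed class is
#' imputed deterministically.
#'
#' @param y_observed observed binary vector (0/1).
#' @param X_observed,X_missing design matrices (intercept added internally).
#' @param seed integer seed.
#' @return imputed 0/1 vector.
#' @export
logistic_step <- function(y_observed, X_observed, X_missing, seed = 1L) {
  X_observed <- as.matrix(X_observed)
  X_missing <- as.matrix(X_missing)
  y <- as.numeric(y_observed)
  classes <- unique(y)
  with_seed(split_seed(seed, "logistic"), {
    if (length(classes) == 1L) {
      warning("single observed class; imputing it deterministically")
      return(rep(classes, nrow(X_missing)))
    }
    Xo <- cbind(1, X_observed)
    Xm <- cbind(1, X_missing)
    fit <- suppressWarnings(
      stats::glm.fit(Xo, y, family = stats::binomial()))
    separated <- !fit$converged ||
      any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
    if (separated) {
      warning("separation detected; penalized logistic fallback applied")
      ## ridge-penalized IRLS with fixed small penalty
      beta <- rep(0, ncol(Xo))
      for (it in 1:50) {
        eta <- as.vector(Xo %*% beta)
        mu <- stats::plogis(eta)
        w <- pmax(mu * (1 - mu), 1e-8)
        z <- eta + (y - mu) / w
        H <- crossprod(Xo, w * Xo) + diag(0.1, ncol(Xo))
        beta_new <- solve(H, crossprod(Xo, w * z))
        if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
        beta <- beta_new
      }
      p_mis <- stats::plogis(as.vector(Xm %*% beta))
    } else {
      beta_hat <- fit$coefficients
      mu <- fit$fitted.values
      w <- mu * (1 - mu)
      H <- crossprod(Xo, w * Xo)
      V <- tryCatch(solve(H), error = function(e) solve(H + diag(1e-6, ncol(Xo))))
      L <- chol((V + t(V)) / 2)
      beta_star <- beta_hat + as.vector(t(L) %*% stats::rnorm(ncol(Xo)))
      p_mis <- stats::plogis(as.vector(Xm %*% beta_star))
    }
    as.numeric(stats::runif(length(p_mis)) < p_mis)
  })
}

## deterministic predictor selection: for each incomplete target, the
## max_predictors variables with highest |Spearman| on pairwise-complete data
select_predictors <- function(data, targets, max_predictors) {
  vars <- names(data)
  suppressWarnings(
    rho <- stats::cor(data.matrix(data), use = "pairwise.complete.obs",
                      method = "spearman"))
  rho[is.na(rho)] <- 0
  sets <- list()
  for (v in targets) {
    others <- setdiff(vars, v)
    ord <- others[order(-abs(rho[v, others]))]
    sets[[v]] <- utils::head(ord, max_predictors)
  }
  sets
}

#' Fully conditional specification multiple imputation
#'
#' Generates \code{m} completed copies of an incomplete item-level dataset.
#' Each chain is initialized with random draws from the observed values,
#' then swept \code{max_iterations} times in fixed left-to-right column
#' order; non-dichotomous variables are imputed by \code{\link{pmm_step}},
#' dichotomous variables by \code{\link{logistic_step}}.
#'
#' @param data data frame with missing values (numeric columns).
#' @param config an \code{\link{imputation_config}}.
#' @param dichotomous character vector naming dichotomous columns; by
#'   default, columns whose observed values take at most 2 distinct values.
#' @return object of class \code{imputation_stack}: list with
#'   \code{datasets} (m completed data frames), \code{config},
#'   \code{predictor_sets}, \code{missing_mask}.
#' @export
fcs_impute <- function(data, config = imputation_config(),
                       dichotomous = NULL) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data)
  mask <- is.na(data)
  targets <- names(data)[colSums(mask) > 0]
  for (v in targets) {
    if (all(is.na(data[[v]])))
      stop("variable '", v, "' has no observed values")
  }
  if (is.null(dichotomous)) {
    dichotomous <- names(data)[vapply(data, function(x)
      length(unique(x[!is.na(x)])) <= 2, logical(1))]
  }
  if (length(targets) == 0L) {
    return(structure(list(datasets = replicate(config$m, data,
                                               simplify = FALSE),
                          config = config, predictor_sets = list(),
                          missing_mask = mask),
                     class = "imputation_stack"))
  }
  predictor_sets <- select_predictors(data, targets, config$max_predictors)

  impute_once <- function(chain) {
    chain_seed <- split_seed(config$seed, paste0("chain", chain))
    filled <- data
    ## initialize by random draws from observed values
    with_seed(split_seed(chain_seed, "init"), {
      for (v in targets) {
        obs <- data[[v]][!mask[, v]]
        filled[[v]][mask[, v]] <- sample(obs, sum(mask[, v]), replace = TRUE)
      }
    })
    for (iter in seq_len(config$max_iterations)) {
      for (v in targets) {
        mis <- mask[, v]
        preds <- predictor_sets[[v]]
        n_obs <- sum(!mis)
        ## truncate predictor set if observed rows are too few
        if (n_obs < length(preds) + 2L) {
          warning("predictor set for '", v, "' truncated to fit ", n_obs,
                  " observed rows")
          preds <- utils::head(preds, max(n_obs - 2L, 1L))
        }
        X <- data.matrix(filled[preds])
        step_seed <- split_seed(chain_seed, paste(v, iter, sep = ":"))
        if (v %in% dichotomous) {
          obs_y <- data[[v]][!mis]
          lv <- sort(unique(obs_y))
          y01 <- as.numeric(factor(obs_y, levels = lv)) - 1
          imp <- logistic_step(y01, X[!mis, , drop = FALSE],
                               X[mis, , drop = FALSE], seed = step_seed)
          filled[[v]][mis] <- if (length(lv) == 2L) lv[imp + 1] else lv[1]
        } else {
          filled[[v]][mis] <- pmm_step(data[[v]][!mis],
                                       X[!mis, , drop = FALSE],
                                       X[mis, , drop = FALSE],
                                       k = min(config$donor_pool, n_obs),
                                       seed = step_seed)
        }
      }
    }
    filled
  }
  datasets <- lapply(seq_len(config$m), impute_once)
  structure(list(datasets = datasets, config = config,
                 predictor_sets = predictor_sets, missing_mask = mask),
            class = "imputation_stack")
}

#' @export
print.imputation_stack <- function(x, ...) {
  cat(sprintf("Imputation stack: m = %d completed datasets (%d x %d), %d cells imputed\n",
              length(x$datasets), nrow(x$datasets[[1]]),
              ncol(x$datasets[[1]]), sum(x$missing_mask)))
  invisible(x)
}

#' Pool estimates across imputations with Rubin's rules
#'
#' @param estimates per-imputation point estimates.
#' @param variances per-imputation (within-imputation) variances; defaults
#'   to zeros when pooling quantities without a variance estimate.
#' @return object of class \code{pooled_estimate}: list with \code{point},
#'   \code{within_variance}, \code{between_variance}, \code{total_variance},
#'   \code{m}.
#' @export
pool_rubin <- function(estimates, variances = rep(0, length(estimates))) {
  m <- length(estimates)
  if (m == 0) stop("no estimates to pool")
  stopifnot(length(variances) == m, all(variances >= 0))
  point <- mean(estimates)
  between <- if (m > 1) stats::var(estimates) else 0
  within <- mean(variances)
  structure(list(point = point, within_variance = within,
                 between_variance = between,
                 total_variance = within + (1 + 1 / m) * between,
                 m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled estimate %.4f (total variance %.5f over m = %d)\n",
              x$point, x$total_variance, x$m))
  invisible(x)
}

#' Pool correlations across imputations via Fisher's z
#'
#' Each correlation is z-transformed, pooled with Rubin's rules using the
#' asymptotic variance 1/(n-3), and the pooled point is back-transformed to
#' the correlation scale.
#'
#' @param correlations per-imputation correlations, each in (-1, 1).
#' @param n sample size (>= 4).
#' @return a \code{pooled_estimate} whose \code{point} is on the correlation
#'   scale (variances remain on the z scale).
#' @export
pool_correlation <- function(correlations, n) {
  stopifnot(n >= 4)
  if (any(abs(correlations) >= 1))
    stop("correlations of magnitude 1 cannot be z-transformed")
  z <- atanh(correlations)
  pooled <- pool_rubin(z, rep(1 / (n - 3), length(z)))
  pooled$point <- tanh(pooled$point)
  pooled
}
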