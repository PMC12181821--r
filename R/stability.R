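## Bootstrap stability of edges and centralities, and CS-coefficients.
##
## Interval estimation under missing data uses bootstrap-then-impute: the
## ORIGINAL incomplete data are resampled, each bootstrap sample is multiply
## imputed, and the stacked network is re-estimated per replicate.

#' Stability-analysis configuration
#'
#' @param n_boot bootstrap samples (default 1000).
#' @param m_per_boot imputations per bootstrap sample (default 20).
#' @param ci_level percentile confidence level (default 0.95).
#' @param cs_correlation correlation retained by the CS-coefficient
#'   (default 0.7).
#' @param cs_probability required probability of retaining it (default
#'   0.95).
#' @param drop_range case-dropping range as fractions of N (default
#'   0.05-0.75).
#' @param seed integer seed.
#' @export
stability_config <- function(n_boot = 1000L, m_per_boot = 20L,
                             ci_level = 0.95, cs_correlation = 0.7,
                             cs_probability = 0.95,
                             drop_range = c(0.05, 0.75), seed = 1L) {
  stopifnot(n_boot >= 1, m_per_boot >= 1,
            ci_level > 0, ci_level < 1,
            cs_correlation > 0, cs_correlation < 1,
            cs_probability > 0, cs_probability < 1,
            length(drop_range) == 2, drop_range[1] <= drop_range[2])
  structure(list(n_boot = as.integer(n_boot),
                 m_per_boot = as.integer(m_per_boot),
                 ci_level = ci_level, cs_correlation = cs_correlation,
                 cs_probability = cs_probability, drop_range = drop_range,
                 seed = as.integer(seed)),
            class = "stability_config")
}

#' Impute-then-estimate pipeline handle
#'
#' Builds the deterministic (seed-driven) data -> network handle used by
#' the bootstrap routines: multiply impute if the data contain missing
#' values, then run stacked EBIC-glasso estimation on the node table.
#'
#' @param gamma,n_lambda,lambda_min_ratio network-estimation settings.
#' @param m,max_iterations,donor_pool,max_predictors imputation settings
#'   applied when the input has missing cells.
#' @param nodes_fun maps a completed data frame to the ordinal node matrix
#'   (default \code{\link{build_node_table}}; use \code{identity}-like
#'   functions for plain node data).
#' @return function(data, seed) returning a \code{symptom_network}.
#' @export
network_pipeline <- function(gamma = 0.5, n_lambda = 100L,
                             lambda_min_ratio = 0.01, m = 20L,
                             max_iterations = 10L, donor_pool = 5L,
                             max_predictors = 15L,
                             nodes_fun = build_node_table) {
  force(nodes_fun)
  function(data, seed = 1L) {
    data <- as.data.frame(data)
    imp_cols <- setdiff(names(data), "PID")
    if (anyNA(data[imp_cols])) {
      stack <- fcs_impute(data[imp_cols],
                          imputation_config(m = m,
                                            max_iterations = max_iterations,
                                            donor_pool = donor_pool,
                                            max_predictors = max_predictors,
                                            seed = seed))
      symptom_network(stack, gamma = gamma, n_lambda = n_lambda,
                      lambda_min_ratio = lambda_min_ratio,
                      nodes_fun = nodes_fun)
    } else {
      nodes <- tryCatch(nodes_fun(data), error = function(e) data.matrix(data[imp_cols]))
      symptom_network(nodes, gamma = gamma, n_lambda = n_lambda,
                      lambda_min_ratio = lambda_min_ratio)
    }
  }
}

## TRUE when the node table implied by a (possibly incomplete) sample has a
## constant observed column, which makes polychoric estimation impossible
.has_constant_node <- function(data, nodes_fun) {
  nodes <- tryCatch(nodes_fun(as.data.frame(data)),
                    error = function(e) data.matrix(data))
  any(apply(nodes, 2, function(v) length(unique(v[!is.na(v)])) < 2))
}

#' Bootstrap edge-weight stability
#'
#' Nonparametric bootstrap of the full estimation pipeline: participants
#' are resampled with replacement from the original (incomplete) data, each
#' bootstrap sample is imputed \code{m_per_boot} times and the stacked
#' network re-estimated; percentile confidence intervals are formed from
#' the replicate edge weights. Bootstrap samples yielding a constant node
#' column are redrawn (count logged in the result).
#'
#' @param data cohort data frame (incomplete data allowed) or
#'   \code{grief_cohort}.
#' @param pipeline handle from \code{\link{network_pipeline}} (its \code{m}
#'   should equal \code{config$m_per_boot}).
#' @param config a \code{\link{stability_config}}.
#' @param nodes_fun node-table builder used for the constant-column check.
#' @return object of class \code{edge_stability}: list with
#'   \code{replicates} (n_boot x n_pairs matrix), \code{point} (full-sample
#'   edge weights), \code{ci} (data frame edge / lower / upper),
#'   \code{redraws}, \code{config}.
#' @export
bootstrap_edges <- function(data, pipeline = NULL,
                            config = stability_config(),
                            nodes_fun = build_node_table) {
  if (inherits(data, "grief_cohort")) data <- data$data
  data <- as.data.frame(data)
  if (is.null(pipeline))
    pipeline <- network_pipeline(m = config$m_per_boot, nodes_fun = nodes_fun)
  N <- nrow(data)
  full <- pipeline(data, seed = split_seed(config$seed, "full"))
  labs <- full$nodes
  pair_names <- {
    ut <- which(upper.tri(full$weights), arr.ind = TRUE)
    paste(labs[ut[, 1]], labs[ut[, 2]], sep = "--")
  }
  reps <- matrix(NA_real_, config$n_boot, length(pair_names),
                 dimnames = list(NULL, pair_names))
  redraws <- 0L
  for (b in seq_len(config$n_boot)) {
    attempt <- 0L
    repeat {
      idx <- with_seed(split_seed(config$seed, sprintf("boot%d.%d", b, attempt)),
                       sample.int(N, N, replace = TRUE))
      samp <- data[idx, , drop = FALSE]
      if (!.has_constant_node(samp[setdiff(names(samp), "PID")], nodes_fun)) break
      redraws <- redraws + 1L
      attempt <- attempt + 1L
      if (attempt > 50L) stop("could not draw a non-degenerate bootstrap sample")
    }
    net_b <- pipeline(samp, seed = split_seed(config$seed, sprintf("bootfit%d", b)))
    reps[b, ] <- net_b$weights[upper.tri(net_b$weights)]
  }
  alpha <- 1 - config$ci_level
  ci <- data.frame(edge = pair_names,
                   point = full$weights[upper.tri(full$weights)],
                   lower = apply(reps, 2, stats::quantile, probs = alpha / 2,
                                 type = 6),
                   upper = apply(reps, 2, stats::quantile,
                                 probs = 1 - alpha / 2, type = 6),
                   row.names = NULL)
  structure(list(replicates = reps, point = ci$point, ci = ci,
                 redraws = redraws, network = full, config = config),
            class = "edge_stability")
}

#' @export
print.edge_stability <- function(x, ...) {
  cat(sprintf("Edge-weight bootstrap: %d replicates, %d edges, %d redraws\n",
              nrow(x$replicates), ncol(x$replicates), x$redraws))
  invisible(x)
}

#' Case-dropping subset bootstrap for centrality stability
#'
#' For each bootstrap, a drop count k is drawn uniformly from the integer
#' range spanned by \code{drop_range} (only integer case counts are
#' meaningful), N - k participants are subsampled without replacement, the
#' impute/estimate/centrality pipeline is rerun, and the Pearson correlation
#' between subset and full-sample centralities is recorded for strength and
#' bridge strength separately. Zero-variance centrality vectors yield an NA
#' correlation (excluded from CS computation with a warning there);
#' subsets too small for estimation are skipped.
#'
#' @inheritParams bootstrap_edges
#' @return object of class \code{case_drop_result}: list with
#'   \code{records} (data frame boot / k / measure / correlation),
#'   \code{full_centrality}, \code{N}, \code{config}.
#' @export
case_dropping <- function(data, pipeline = NULL,
                          config = stability_config(),
                          nodes_fun = build_node_table) {
  if (inherits(data, "grief_cohort")) data <- data$data
  data <- as.data.frame(data)
  if (is.null(pipeline))
    pipeline <- network_pipeline(m = config$m_per_boot, nodes_fun = nodes_fun)
  N <- nrow(data)
  full <- pipeline(data, seed = split_seed(config$seed, "full"))
  cent_full <- centrality(full)
  p <- length(full$nodes)
  k_min <- max(1L, ceiling(config$drop_range[1] * N))
  k_max <- min(N - 1L, floor(config$drop_range[2] * N))
  stopifnot(k_min <= k_max)
  rec <- vector("list", config$n_boot)
  skipped <- 0L
  for (b in seq_len(config$n_boot)) {
    kb <- with_seed(split_seed(config$seed, sprintf("dropk%d", b)),
                    sample(seq.int(k_min, k_max), 1L))
    if (N - kb < p + 2L) { skipped <- skipped + 1L; next }
    idx <- with_seed(split_seed(config$seed, sprintf("drop%d", b)),
                     sample.int(N, N - kb))
    samp <- data[idx, , drop = FALSE]
    if (.has_constant_node(samp[setdiff(names(samp), "PID")], nodes_fun)) {
      skipped <- skipped + 1L
      next
    }
    net_b <- pipeline(samp, seed = split_seed(config$seed, sprintf("dropfit%d", b)))
    cent_b <- centrality(net_b)
    corr <- function(a, v) {
      if (anyNA(a) || anyNA(v) ||
          stats::sd(a) == 0 || stats::sd(v) == 0) NA_real_
      else stats::cor(a, v)
    }
    rec[[b]] <- data.frame(
      boot = b, k = kb,
      measure = c("strength", "bridge_strength"),
      correlation = c(corr(cent_full$strength, cent_b$strength),
                      corr(cent_full$bridge_strength, cent_b$bridge_strength)))
  }
  structure(list(records = do.call(rbind, rec),
                 full_centrality = cent_full, N = N, skipped = skipped,
                 config = config),
            class = "case_drop_result")
}

#' @export
print.case_drop_result <- function(x, ...) {
  nb <- length(unique(x$records$boot))
  cat(sprintf("Case-dropping bootstrap: %d replicates over N = %d (%d skipped)\n",
              nb, x$N, x$skipped))
  cs <- cs_coefficient(x)
  cat(sprintf("  CS(strength) = %.4f, CS(bridge strength) = %.4f\n",
              cs["strength"], cs["bridge_strength"]))
  invisible(x)
}

#' Correlation-stability coefficient
#'
#' CS is the largest k/N such that at every evaluated drop level k' <= k at
#' least \code{cs_probability} of the replicates retain a correlation of at
#' least \code{cs_correlation} with the full-sample centralities (0 if no
#' level qualifies). Requiring all smaller levels to pass makes the
#' definition monotone and robust to sampling flukes at single levels.
#'
#' @param result a \code{case_drop_result}.
#' @param config optional \code{\link{stability_config}} overriding the
#'   thresholds stored in the result.
#' @return named numeric vector of CS values per centrality measure.
#' @export
cs_coefficient <- function(result, config = NULL) {
  stopifnot(inherits(result, "case_drop_result"))
  config <- config %||% result$config
  rec <- result$records
  if (is.null(rec) || nrow(rec) == 0) stop("no case-dropping replicates")
  measures <- unique(rec$measure)
  out <- stats::setNames(numeric(length(measures)), measures)
  for (msr in measures) {
    r <- rec[rec$measure == msr, ]
    if (anyNA(r$correlation)) {
      warning("undefined (zero-variance) correlations excluded from CS for ",
              msr)
      r <- r[!is.na(r$correlation), ]
    }
    if (nrow(r) == 0) { out[msr] <- NA_real_; next }
    ks <- sort(unique(r$k))
    pass <- vapply(ks, function(k) {
      mean(r$correlation[r$k == k] >= config$cs_correlation) >=
        config$cs_probability
    }, logical(1))
    ok <- which(!pass)
    max_k <- if (length(ok) == 0) max(ks)
             else if (ok[1] == 1L) NA
             else ks[ok[1] - 1L]
    out[msr] <- if (is.na(max_k)) 0 else max_k / result$N
  }
  out
}
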