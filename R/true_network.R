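## Ground-truth network generation for simulation studies.
##
## A "true_network" holds a precision matrix over latent Gaussian symptom
## variables, its implied partial correlations, and per-node ordered
## thresholds that discretize the latent scale into ordinal item categories.

#' Node labels of the 13-node PGD / cPTSD symptom network
#'
#' Seven prolonged-grief symptoms (preoccupation Pr, yearning Ye, difficulty
#' accepting the loss AL, bitterness/anger BA, difficulty engaging in social
#' or other activities ML, emotional numbness Nu, feeling one has lost a part
#' of one's self PD) and six complex-PTSD symptom clusters (re-experiencing
#' Re, avoidance Av, sense of current threat Th, affective dysregulation ad,
#' negative self-concept NSC, disturbances in relationships DR).
#'
#' @export
grief_node_labels <- c("Pr", "Ye", "AL", "BA", "ML", "Nu", "PD",
                       "Re", "Av", "Th", "ad", "NSC", "DR")

#' Theoretical community assignment of the 13 symptom nodes
#'
#' The two communities used for bridge-strength centrality: the PGD symptoms
#' versus the cPTSD symptom clusters (PTSD core + disturbances in
#' self-organization together, since a cPTSD diagnosis requires both).
#'
#' @export
grief_communities <- c(Pr = "PGD", Ye = "PGD", AL = "PGD", BA = "PGD",
                       ML = "PGD", Nu = "PGD", PD = "PGD",
                       Re = "cPTSD", Av = "cPTSD", Th = "cPTSD",
                       ad = "cPTSD", NSC = "cPTSD", DR = "cPTSD")

## number of ordinal categories per network node: single TGI items have 5
## (rated 1-5), single CAPS/COPISAC items have 5 (rated 0-4), two-item sum
## clusters have 9 (0-8)
.node_categories <- c(Pr = 5, Ye = 5, AL = 5, BA = 5, ML = 5, Nu = 5, PD = 5,
                      Re = 9, Av = 9, Th = 9, ad = 5, NSC = 5, DR = 9)

## equiprobable thresholds on the latent standard-normal scale
equiprobable_thresholds <- function(n_cat) {
  stats::qnorm(seq_len(n_cat - 1) / n_cat)
}

#' Generate a ground-truth partial-correlation network
#'
#' Draws a sparse symmetric partial-correlation structure with a given edge
#' density and edge-weight range, converts it to a precision matrix, and
#' repairs positive definiteness by diagonal inflation (delta doubling from
#' 0.01 until the smallest eigenvalue is at least 1e-6) followed by
#' re-standardization to unit diagonal. Diagonal inflation preserves the
#' sparsity pattern, so the generated edge support is exact.
#'
#' @param p number of nodes (default 13, the PGD/cPTSD symptom network).
#' @param density fraction of node pairs with a nonzero edge, in [0, 1].
#' @param weight_low,weight_high edge-weight range on the partial-correlation
#'   scale, both in (-1, 1). A configurable fraction \code{prop_negative} of
#'   edges is flipped negative, mirroring the mostly-positive networks seen
#'   in symptom data.
#' @param seed integer seed.
#' @param labels node labels; defaults to \code{grief_node_labels} when
#'   \code{p = 13}.
#' @param prop_negative fraction of edges drawn with negative sign (applied
#'   on top of the [weight_low, weight_high] magnitudes when both bounds are
#'   nonnegative). Default 0.05.
#' @param thresholds optional list of per-node threshold vectors; default is
#'   equiprobable categories (\code{.node_categories} for the 13-node
#'   network, 5 categories otherwise).
#' @param max_shrink maximum number of delta-doubling repair steps.
#' @return an object of class \code{true_network} with elements
#'   \code{labels}, \code{precision}, \code{pcor}, \code{thresholds},
#'   \code{edges} (logical adjacency), \code{seed}.
#' @export
true_network <- function(p = 13, density = 0.5, weight_low = -0.04,
                         weight_high = 0.49, seed = 1,
                         labels = NULL, prop_negative = 0.05,
                         thresholds = NULL, max_shrink = 60L) {
  stopifnot(p >= 2, density >= 0, density <= 1,
            weight_low <= weight_high,
            weight_low > -1, weight_high < 1)
  if (is.null(labels)) {
    labels <- if (p == 13) grief_node_labels else paste0("V", seq_len(p))
  }
  stopifnot(length(labels) == p)

  n_pairs <- p * (p - 1L) / 2L
  n_edges <- round(density * n_pairs)
  W <- matrix(0, p, p, dimnames = list(labels, labels))
  with_seed(split_seed(seed, "true_network"), {
    idx <- sample.int(n_pairs, n_edges)
    w <- stats::runif(n_edges, weight_low, weight_high)
    if (weight_low >= 0 && prop_negative > 0 && n_edges > 0) {
      flip <- stats::runif(n_edges) < prop_negative
      w[flip] <- -w[flip]
    }
    ut <- which(upper.tri(W))
    W[ut[idx]] <- w
  })
  W <- W + t(W)

  ## precision with unit diagonal implied by the target partial correlations
  K <- -W
  diag(K) <- 1

  ## positive-definiteness repair: delta doubling, support-preserving
  delta <- 0.01
  steps <- 0L
  while (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) < 1e-6) {
    K <- K + diag(delta, p)
    delta <- delta * 2
    steps <- steps + 1L
    if (steps > max_shrink)
      stop("could not reach positive definiteness; last diagonal inflation delta = ",
           delta / 2)
  }
  ## re-standardize to unit diagonal (preserves zero pattern)
  d <- sqrt(diag(K))
  K <- K / outer(d, d)

  if (is.null(thresholds)) {
    ncat <- if (p == 13 && identical(labels, grief_node_labels))
      .node_categories else stats::setNames(rep(5L, p), labels)
    thresholds <- lapply(ncat, equiprobable_thresholds)
  }
  stopifnot(length(thresholds) == p,
            all(vapply(thresholds, function(t) all(diff(t) > 0), logical(1))))
  names(thresholds) <- labels

  structure(list(labels = labels,
                 precision = K,
                 pcor = prec_to_pcor(K),
                 thresholds = thresholds,
                 edges = W != 0,
                 seed = seed),
            class = "true_network")
}

#' @export
print.true_network <- function(x, ...) {
  p <- length(x$labels)
  ne <- sum(x$pcor[upper.tri(x$pcor)] != 0)
  cat("True partial-correlation network\n")
  cat(sprintf("  nodes: %d (%s%s)\n", p, paste(utils::head(x$labels, 6), collapse = ", "),
              if (p > 6) ", ..." else ""))
  cat(sprintf("  edges: %d of %d (density %.3f)\n", ne, p * (p - 1) / 2,
              ne / (p * (p - 1) / 2)))
  if (ne > 0) {
    w <- x$pcor[upper.tri(x$pcor)]
    w <- w[w != 0]
    cat(sprintf("  weight range: [%.3f, %.3f]\n", min(w), max(w)))
  }
  invisible(x)
}

#' Latent covariance matrix implied by a true network
#'
#' Standardized inverse of the precision matrix: the marginal correlation
#' matrix of the latent Gaussian symptom variables.
#'
#' @param net a \code{true_network}.
#' @return correlation matrix.
#' @export
latent_correlation <- function(net) {
  stopifnot(inherits(net, "true_network"))
  cov2cor_safe(solve(net$precision))
}

#' Sample ordinal symptom data from a true network
#'
#' Draws latent vectors from the multivariate normal with the network's
#' implied correlation matrix and cuts each latent variable at its node
#' thresholds, giving ordinal codes 1..(K+1) per node.
#'
#' @param n number of observations.
#' @param net a \code{true_network}.
#' @param seed integer seed.
#' @return integer matrix n x p of ordinal codes (1-based category index),
#'   columns named by node label.
#' @export
sample_ordinal <- function(n, net, seed = 1) {
  stopifnot(n >= 1, inherits(net, "true_network"))
  R <- latent_correlation(net)
  p <- ncol(R)
  ch <- tryCatch(chol(R), error = function(e)
    stop("latent correlation matrix is not positive definite"))
  Z <- with_seed(split_seed(seed, "sample_ordinal"), {
    matrix(stats::rnorm(n * p), n, p) %*% ch
  })
  X <- matrix(0L, n, p, dimnames = list(NULL, net$labels))
  for (j in seq_len(p)) {
    X[, j] <- findInterval(Z[, j], net$thresholds[[j]]) + 1L
  }
  X
}

#' @export
simulate.true_network <- function(object, nsim = 1, seed = NULL, n = 100, ...) {
  if (is.null(seed)) seed <- 1
  out <- lapply(seq_len(nsim), function(i)
    sample_ordinal(n, object, seed = split_seed(seed, paste0("sim", i))))
  if (nsim == 1) out[[1]] else out
}
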