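## Regularized partial-correlation symptom network: the central model of the
## package. symptom_network() is the fitting function; it accepts either an
## ordinal node matrix or an imputation stack (stacked estimation).

#' Build the 13-node ordinal table from instrument items
#'
#' Maps instrument items to the network nodes: the seven PGD nodes are
#' single TGI-SR+ items (1 preoccupation, 3 yearning, 5 difficulty
#' accepting, 8 bitterness/anger, 9 difficulty engaging in activities,
#' 10 emotional numbness, 21 lost part of self); four cPTSD clusters are
#' two-item sums (re-experiencing CAPS1+CAPS2, avoidance CAPS6+CAPS7,
#' current threat CAPS17+CAPS18, relationship disturbances CO3+CAPS13) and
#' two are single items (affective dysregulation CO1, negative self-concept
#' CO2).
#'
#' @param items data frame with columns named in the cohort dialect
#'   (TGI_01..TGI_22, CAPS_01.., COPISAC_CO1..CO5).
#' @return integer matrix with 13 columns labelled
#'   \code{grief_node_labels}.
#' @export
build_node_table <- function(items) {
  need <- c(paste0("TGI_", sprintf("%02d", c(1, 3, 5, 8, 9, 10, 21))),
            paste0("CAPS_", sprintf("%02d", c(1, 2, 6, 7, 13, 17, 18))),
            paste0("COPISAC_CO", 1:3))
  missing_cols <- setdiff(need, names(items))
  if (length(missing_cols))
    stop("missing constituent items: ", paste(missing_cols, collapse = ", "))
  g <- function(nm) items[[nm]]
  out <- cbind(
    Pr  = g("TGI_01"), Ye = g("TGI_03"), AL = g("TGI_05"),
    BA  = g("TGI_08"), ML = g("TGI_09"), Nu = g("TGI_10"),
    PD  = g("TGI_21"),
    Re  = g("CAPS_01") + g("CAPS_02"),
    Av  = g("CAPS_06") + g("CAPS_07"),
    Th  = g("CAPS_17") + g("CAPS_18"),
    ad  = g("COPISAC_CO1"),
    NSC = g("COPISAC_CO2"),
    DR  = g("COPISAC_CO3") + g("CAPS_13"))
  storage.mode(out) <- "integer"
  out
}

#' Fit a regularized partial-correlation symptom network
#'
#' Estimates an ordinal (polychoric) correlation matrix, runs the graphical
#' lasso over a penalty path, and selects the model with minimal extended
#' BIC. When given an imputation stack, all completed datasets are
#' concatenated and one estimation is performed with the effective sample
#' size set to the original number of participants (stacked estimation), so
#' one network is obtained rather than one per imputation.
#'
#' @param x an ordinal node matrix (participants x nodes), an
#'   \code{imputation_stack} (node tables are built from each completed
#'   dataset and stacked), or a precomputed \code{cor_matrix}.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda,lambda_min_ratio penalty-path settings.
#' @param communities named community vector; defaults to
#'   \code{grief_communities} when the node labels match.
#' @param n effective sample size override (required for a bare
#'   \code{cor_matrix} without one).
#' @param nodes_fun function applied to each completed dataset of an
#'   imputation stack to obtain the node table (default
#'   \code{build_node_table}).
#' @return object of class \code{symptom_network}: list with \code{nodes}
#'   (labels), \code{weights} (partial-correlation matrix, zero diagonal),
#'   \code{precision}, \code{lambda}, \code{gamma}, \code{path},
#'   \code{communities}, \code{S} (the \code{cor_matrix} used), \code{n}.
#' @seealso \code{\link{network_descriptives}}, \code{\link{centrality}},
#'   \code{\link{bootstrap_edges}}
#' @export
symptom_network <- function(x, gamma = 0.5, n_lambda = 100L,
                            lambda_min_ratio = 0.01, communities = NULL,
                            n = NULL, nodes_fun = build_node_table) {
  if (inherits(x, "imputation_stack")) {
    tables <- lapply(x$datasets, function(d) {
      m <- try(nodes_fun(d), silent = TRUE)
      if (inherits(m, "try-error")) as.matrix(d) else m
    })
    shapes <- vapply(tables, function(t) paste(dim(t), collapse = "x"), "")
    if (length(unique(shapes)) != 1L)
      stop("imputed datasets have inconsistent shapes")
    stacked <- do.call(rbind, tables)
    S <- polychoric_matrix(stacked, n = nrow(tables[[1]]))
  } else if (inherits(x, "cor_matrix")) {
    S <- x
    if (!is.null(n)) S$n <- n
  } else {
    x <- as.matrix(x)
    S <- polychoric_matrix(x, n = n %||% nrow(x))
  }
  sel <- ebic_select(S, gamma = gamma, n_lambda = n_lambda,
                     lambda_min_ratio = lambda_min_ratio)
  Theta <- sel$Theta
  weights <- prec_to_pcor(Theta)
  labs <- colnames(S$S) %||% paste0("V", seq_len(ncol(S$S)))
  dimnames(weights) <- list(labs, labs)
  if (is.null(communities)) {
    communities <- if (all(labs %in% names(grief_communities)))
      grief_communities[labs] else NULL
  }
  structure(list(nodes = labs, weights = weights, precision = Theta,
                 lambda = sel$lambda, gamma = gamma, path = sel$path,
                 communities = communities, S = S, n = S$n),
            class = "symptom_network")
}

#' Network descriptives: density and edge-weight summaries
#'
#' Density is the share of node pairs with a nonzero regularized partial
#' correlation. The mean edge weight is reported under both conventions
#' (over all node pairs, and over nonzero edges only); the all-pairs mean is
#' the headline figure.
#'
#' @param net a \code{symptom_network} (or plain weights matrix).
#' @return list with \code{density}, \code{mean_weight_all},
#'   \code{mean_weight_nonzero}, \code{min_weight}, \code{max_weight},
#'   \code{n_edges}, \code{n_pairs}.
#' @export
network_descriptives <- function(net) {
  W <- if (inherits(net, "symptom_network")) net$weights else as.matrix(net)
  w <- W[upper.tri(W)]
  nz <- w[w != 0]
  list(density = if (length(w)) length(nz) / length(w) else 0,
       mean_weight_all = if (length(w)) mean(w) else 0,
       mean_weight_nonzero = if (length(nz)) mean(nz) else 0,
       min_weight = if (length(nz)) min(nz) else 0,
       max_weight = if (length(nz)) max(nz) else 0,
       n_edges = length(nz), n_pairs = length(w))
}

#' @export
print.symptom_network <- function(x, ...) {
  d <- network_descriptives(x)
  cat("Regularized partial-correlation network (EBIC graphical lasso)\n")
  cat(sprintf("  nodes: %d, n = %d, gamma = %.2f, selected lambda = %.4f\n",
              length(x$nodes), x$n, x$gamma, x$lambda))
  cat(sprintf("  edges: %d of %d (density %.3f)\n", d$n_edges, d$n_pairs,
              d$density))
  if (d$n_edges > 0)
    cat(sprintf("  edge weights: mean (all pairs) %.3f, range [%.3f, %.3f]\n",
                d$mean_weight_all, d$min_weight, d$max_weight))
  invisible(x)
}

#' @export
summary.symptom_network <- function(object, ...) {
  d <- network_descriptives(object)
  cent <- centrality(object)
  out <- list(descriptives = d, centrality = cent,
              edges = edge_list(object), call_n = object$n,
              lambda = object$lambda, gamma = object$gamma)
  class(out) <- "summary.symptom_network"
  out
}

#' @export
print.summary.symptom_network <- function(x, ...) {
  cat(sprintf("EBIC graphical lasso network: %d edges, density %.3f, mean edge weight %.3f\n",
              x$descriptives$n_edges, x$descriptives$density,
              x$descriptives$mean_weight_all))
  cat(sprintf("  selected lambda %.4f (gamma %.2f), n = %d\n\n",
              x$lambda, x$gamma, x$call_n))
  cat("Strongest edges:\n")
  e <- x$edges[order(-abs(x$edges$weight)), ]
  print(utils::head(e, 5), row.names = FALSE)
  cat("\nCentrality:\n")
  print(as.data.frame(x$centrality), digits = 3)
  invisible(x)
}

#' @export
coef.symptom_network <- function(object, ...) object$weights

#' Simulate ordinal data from a fitted symptom network
#'
#' Treats the selected precision matrix and the polychoric thresholds
#' implied by equiprobable categories as a generative model and draws
#' ordinal observations from it.
#'
#' @param object a \code{symptom_network}.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param n observations per dataset.
#' @param ... unused.
#' @export
simulate.symptom_network <- function(object, nsim = 1, seed = NULL,
                                     n = object$n, ...) {
  if (is.null(seed)) seed <- 1
  p <- length(object$nodes)
  ncat <- if (all(object$nodes %in% names(.node_categories)))
    .node_categories[object$nodes] else stats::setNames(rep(5L, p), object$nodes)
  net <- structure(list(labels = object$nodes,
                        precision = object$precision,
                        pcor = object$weights,
                        thresholds = lapply(ncat, equiprobable_thresholds),
                        seed = seed),
                   class = "true_network")
  simulate.true_network(net, nsim = nsim, seed = seed, n = n)
}

#' @export
plot.symptom_network <- function(x, ...) {
  p <- length(x$nodes)
  ang <- seq(0, 2 * pi, length.out = p + 1)[-(p + 1)]
  xy <- cbind(cos(ang), sin(ang))
  graphics::plot(xy, type = "n", axes = FALSE, xlab = "", ylab = "",
                 xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25), asp = 1, ...)
  W <- x$weights
  mx <- max(abs(W))
  if (mx > 0) {
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      w <- W[i, j]
      if (w != 0)
        graphics::segments(xy[i, 1], xy[i, 2], xy[j, 1], xy[j, 2],
                           lwd = 0.5 + 4 * abs(w) / mx,
                           col = if (w > 0) grDevices::adjustcolor("steelblue", 0.8)
                                 else grDevices::adjustcolor("firebrick", 0.8))
    }
  }
  comm <- x$communities %||% stats::setNames(rep("A", p), x$nodes)
  cols <- c("lightskyblue", "sandybrown")[as.integer(factor(comm))]
  graphics::points(xy, pch = 21, bg = cols, cex = 3.5)
  graphics::text(xy[, 1], xy[, 2], x$nodes, cex = 0.7)
  invisible(x)
}

#' Long-format edge list of a network
#'
#' @param net a \code{symptom_network} or weights matrix.
#' @param nonzero_only keep only nonzero edges (default TRUE).
#' @return data frame with columns node_i, node_j, weight.
#' @export
edge_list <- function(net, nonzero_only = TRUE) {
  W <- if (inherits(net, "symptom_network")) net$weights else as.matrix(net)
  labs <- colnames(W) %||% paste0("V", seq_len(ncol(W)))
  ut <- which(upper.tri(W), arr.ind = TRUE)
  out <- data.frame(node_i = labs[ut[, 1]], node_j = labs[ut[, 2]],
                    weight = W[ut], stringsAsFactors = FALSE)
  if (nonzero_only) out <- out[out$weight != 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a network as GraphML with community attributes
#'
#' @param net a \code{symptom_network}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "symptom_network"))
  e <- edge_list(net)
  g <- igraph::graph_from_data_frame(
    e, directed = FALSE,
    vertices = data.frame(name = net$nodes,
                          community = unname(net$communities %||%
                                               rep(NA_character_,
                                                   length(net$nodes)))))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
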