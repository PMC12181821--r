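## Strength and bridge-strength centrality.

#' Node strength
#'
#' Sum over a node's incident edges; by default the absolute-value
#' convention (sum of |weight|), with a signed variant available.
#'
#' @param net a \code{symptom_network} or weights matrix.
#' @param absolute use |weight| (default TRUE).
#' @return named numeric vector.
#' @export
strength <- function(net, absolute = TRUE) {
  W <- if (inherits(net, "symptom_network")) net$weights else as.matrix(net)
  if (absolute) W <- abs(W)
  out <- rowSums(W)
  names(out) <- colnames(W) %||% paste0("V", seq_len(ncol(W)))
  out
}

#' Bridge strength over two symptom communities
#'
#' Per node, the sum of (absolute) weights of incident edges whose other
#' endpoint lies in the other community.
#'
#' @param net a \code{symptom_network} or weights matrix.
#' @param communities named character vector mapping every node to one of
#'   exactly two communities; defaults to the network's stored communities.
#' @param absolute use |weight| (default TRUE).
#' @return named numeric vector.
#' @export
bridge_strength <- function(net, communities = NULL, absolute = TRUE) {
  W <- if (inherits(net, "symptom_network")) net$weights else as.matrix(net)
  labs <- colnames(W) %||% paste0("V", seq_len(ncol(W)))
  if (is.null(communities) && inherits(net, "symptom_network"))
    communities <- net$communities
  if (is.null(communities)) stop("community assignment required")
  communities <- communities[labs]
  if (anyNA(communities))
    stop("nodes without community assignment: ",
         paste(labs[is.na(communities)], collapse = ", "))
  if (length(unique(communities)) != 2L)
    stop("bridge strength requires exactly two communities")
  if (absolute) W <- abs(W)
  cross <- outer(communities, communities, "!=")
  out <- rowSums(W * cross)
  names(out) <- labs
  out
}

#' Strength and bridge-strength centrality table
#'
#' @param net a \code{symptom_network}.
#' @param communities optional community override.
#' @param absolute absolute-value convention (default TRUE).
#' @return object of class \code{centrality_result}: data frame with node,
#'   community, strength, bridge_strength, z_strength, z_bridge.
#' @export
centrality <- function(net, communities = NULL, absolute = TRUE) {
  s <- strength(net, absolute = absolute)
  comm <- communities %||%
    (if (inherits(net, "symptom_network")) net$communities else NULL)
  b <- if (!is.null(comm)) bridge_strength(net, comm, absolute = absolute)
       else rep(NA_real_, length(s))
  zs <- function(v) {
    if (all(is.na(v)) || stats::sd(v, na.rm = TRUE) == 0)
      rep(NA_real_, length(v))
    else (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
  }
  out <- data.frame(node = names(s),
                    community = if (!is.null(comm)) unname(comm[names(s)])
                                else NA_character_,
                    strength = unname(s),
                    bridge_strength = unname(b),
                    z_strength = zs(unname(s)),
                    z_bridge = zs(unname(b)),
                    stringsAsFactors = FALSE)
  class(out) <- c("centrality_result", "data.frame")
  out
}
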