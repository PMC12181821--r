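## File dialects: cohort CSV (empty cell = missing), ground-truth JSON,
## long-format imputation-stack CSV, network/centrality/replicate exports.

.item_range <- function(col) {
  if (startsWith(col, "TGI_")) c(1, 5)
  else if (startsWith(col, "CAPS_") || startsWith(col, "COPISAC_")) c(0, 4)
  else NULL
}

validate_cohort <- function(df) {
  if (anyDuplicated(df$PID))
    stop("duplicate participant IDs: ",
         paste(unique(df$PID[duplicated(df$PID)]), collapse = ", "))
  for (cl in intersect(.cohort_item_cols, names(df))) {
    rng <- .item_range(cl)
    v <- df[[cl]]
    bad <- which(!is.na(v) & (v < rng[1] | v > rng[2]))
    if (length(bad))
      stop(sprintf("out-of-range value in column %s, row %d: %s",
                   cl, bad[1], v[bad[1]]))
  }
  if ("MONTHS_SINCE_LOSS" %in% names(df)) {
    v <- df$MONTHS_SINCE_LOSS
    if (any(!is.na(v) & v < 0)) stop("MONTHS_SINCE_LOSS must be >= 0")
  }
  invisible(df)
}

#' Write a cohort to CSV (and its ground truth to JSON)
#'
#' One row per participant; missing cells are written empty. If the cohort
#' carries a ground-truth network, it is stored alongside as
#' \code{<path>.truth.json} (precision matrix, thresholds, seed).
#'
#' @param cohort a \code{grief_cohort} or data frame.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_cohort <- function(cohort, path) {
  df <- if (inherits(cohort, "grief_cohort")) cohort$data else as.data.frame(cohort)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (inherits(cohort, "grief_cohort") && !is.null(cohort$true_network)) {
    net <- cohort$true_network
    jsonlite::write_json(
      list(labels = net$labels,
           precision = net$precision,
           thresholds = net$thresholds,
           seed = net$seed),
      paste0(path, ".truth.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a cohort CSV
#'
#' Empty cells become missing values; unknown columns are ignored with a
#' warning; duplicate participant IDs and out-of-range item values are
#' errors.
#'
#' @param path CSV path written by \code{\link{write_cohort}}.
#' @return data frame with PID, item and metadata columns.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  known <- c("PID", .cohort_item_cols, .cohort_meta_cols)
  unknown <- setdiff(names(df), known)
  if (length(unknown)) {
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "))
    df <- df[, setdiff(names(df), unknown), drop = FALSE]
  }
  validate_cohort(df)
  df
}

#' Serialize an imputation stack as one long CSV
#'
#' Long format with an \code{.imp} index column: 0 is the original data
#' with missing cells, 1..m are the completed datasets.
#'
#' @param stack an \code{imputation_stack}.
#' @param original the original incomplete data frame (optional; written as
#'   .imp = 0 when given).
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_stack <- function(stack, path, original = NULL) {
  stopifnot(inherits(stack, "imputation_stack"))
  parts <- list()
  if (!is.null(original))
    parts[[1]] <- cbind(.imp = 0L, original)
  parts <- c(parts, lapply(seq_along(stack$datasets), function(i)
    cbind(.imp = i, stack$datasets[[i]])))
  utils::write.csv(do.call(rbind, parts), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a long-format imputation stack CSV
#'
#' @param path CSV written by \code{\link{write_stack}}.
#' @return an \code{imputation_stack} (without config provenance; the
#'   original data, if present as .imp = 0, populate the missing mask).
#' @export
read_stack <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  stopifnot(".imp" %in% names(df))
  imp <- df$.imp
  df$.imp <- NULL
  orig <- if (any(imp == 0)) df[imp == 0, , drop = FALSE] else NULL
  datasets <- lapply(sort(unique(imp[imp > 0])), function(i)
    df[imp == i, , drop = FALSE])
  datasets <- lapply(datasets, function(d) { rownames(d) <- NULL; d })
  mask <- if (!is.null(orig)) is.na(orig) else
    matrix(FALSE, nrow(datasets[[1]]), ncol(datasets[[1]]))
  structure(list(datasets = datasets, config = NULL,
                 predictor_sets = NULL, missing_mask = mask),
            class = "imputation_stack")
}

#' Export network artifacts (edge list, weight matrix, EBIC path)
#'
#' @param net a \code{symptom_network}.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return character vector of written paths.
#' @export
write_network <- function(net, dir, prefix = "network") {
  stopifnot(inherits(net, "symptom_network"))
  paths <- c(
    edges = file.path(dir, paste0(prefix, "_edges.csv")),
    matrix = file.path(dir, paste0(prefix, "_matrix.csv")),
    path = file.path(dir, paste0(prefix, "_ebic_path.csv")),
    graphml = file.path(dir, paste0(prefix, ".graphml")))
  utils::write.csv(edge_list(net), paths["edges"], row.names = FALSE)
  utils::write.csv(as.data.frame(net$weights), paths["matrix"])
  utils::write.csv(net$path, paths["path"], row.names = FALSE)
  write_graphml(net, paths["graphml"])
  paths
}
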