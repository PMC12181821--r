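## End-to-end orchestration: impute -> diagnose -> network -> centrality ->
## stability, with a manifest of artifacts.

#' Run the full comorbidity / network pipeline
#'
#' Executes the analysis stages on a cohort CSV (or in-memory data frame):
#' multiple imputation of item-level data, diagnostic scoring with pooled
#' prevalence and comorbidity, stacked polychoric EBIC-glasso network
#' estimation, strength / bridge-strength centrality, and (optionally)
#' bootstrap stability. All artifacts are written under \code{out_dir} and
#' listed in a manifest JSON together with the seed and a configuration
#' hash; reruns with the same inputs and seed are identical.
#'
#' @param input cohort CSV path or data frame in the cohort dialect.
#' @param out_dir output directory (created if absent).
#' @param seed global integer seed; each stage derives its own stream.
#' @param stages character subset of
#'   \code{c("impute", "diagnose", "network", "centrality", "stability")}.
#' @param imputation an \code{\link{imputation_config}} (its seed field is
#'   replaced by the pipeline seed).
#' @param gamma,n_lambda,lambda_min_ratio network-estimation settings.
#' @param stability a \code{\link{stability_config}} used when the
#'   stability stage is enabled.
#' @param verbose print stage progress.
#' @return the manifest (named list), invisibly including loaded results.
#' @export
run_pipeline <- function(input, out_dir, seed = 1,
                         stages = c("impute", "diagnose", "network",
                                    "centrality", "stability"),
                         imputation = imputation_config(),
                         gamma = 0.5, n_lambda = 100L,
                         lambda_min_ratio = 0.01,
                         stability = stability_config(n_boot = 100L,
                                                      m_per_boot = 5L),
                         verbose = TRUE) {
  stages <- match.arg(stages, several.ok = TRUE)
  say <- function(...) if (verbose) message(...)
  data <- if (is.character(input)) read_cohort(input) else
    validate_cohort(as.data.frame(input))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  config <- list(seed = seed, stages = stages, m = imputation$m,
                 max_iterations = imputation$max_iterations,
                 donor_pool = imputation$donor_pool,
                 gamma = gamma, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio,
                 n_boot = stability$n_boot,
                 m_per_boot = stability$m_per_boot)
  config_hash <- sum(utf8ToInt(paste(deparse(config), collapse = ""))) %% 1e9
  artifacts <- list()
  results <- list()

  imp_cols <- setdiff(names(data), "PID")
  stack <- NULL
  if ("impute" %in% stages) {
    say("stage: impute (m = ", imputation$m, ")")
    imputation$seed <- split_seed(seed, "impute")
    stack <- fcs_impute(data[imp_cols], imputation)
    p <- file.path(out_dir, "imputations.csv")
    write_stack(stack, p, original = data[imp_cols])
    artifacts$imputations <- p
    results$stack <- stack
  } else if (!anyNA(data[imp_cols])) {
    stack <- structure(list(datasets = list(data[imp_cols]),
                            config = imputation_config(m = 1L),
                            predictor_sets = list(),
                            missing_mask = is.na(data[imp_cols])),
                       class = "imputation_stack")
  } else {
    stop("stage 'impute' disabled but the input contains missing values")
  }

  if ("diagnose" %in% stages) {
    say("stage: diagnose")
    prev <- prevalence_and_comorbidity(stack)
    per_imp <- lapply(seq_along(stack$datasets), function(i)
      cbind(.imp = i, diagnose_cohort(stack$datasets[[i]])))
    p1 <- file.path(out_dir, "diagnoses.csv")
    utils::write.csv(do.call(rbind, per_imp), p1, row.names = FALSE)
    omega <- mcdonald_omega(stack$datasets[[1]][.tgi_cols])
    summary_json <- list(prevalence = prev,
                         omega_tgi_total = omega$omega_total)
    p2 <- file.path(out_dir, "prevalence.json")
    jsonlite::write_json(summary_json, p2, digits = NA, auto_unbox = TRUE)
    artifacts$diagnoses <- p1
    artifacts$prevalence <- p2
    results$prevalence <- prev
    results$omega <- omega
  }

  net <- NULL
  if ("network" %in% stages) {
    say("stage: network (stacked estimation, gamma = ", gamma, ")")
    net <- symptom_network(stack, gamma = gamma, n_lambda = n_lambda,
                           lambda_min_ratio = lambda_min_ratio)
    artifacts <- c(artifacts, as.list(write_network(net, out_dir)))
    results$network <- net
  }

  if ("centrality" %in% stages) {
    if (is.null(net)) stop("centrality stage requires the network stage")
    say("stage: centrality")
    cent <- centrality(net)
    p <- file.path(out_dir, "centrality.csv")
    utils::write.csv(cent, p, row.names = FALSE)
    artifacts$centrality <- p
    results$centrality <- cent
  }

  if ("stability" %in% stages) {
    say("stage: stability (B = ", stability$n_boot, ")")
    stability$seed <- split_seed(seed, "stability")
    pipe <- network_pipeline(gamma = gamma, n_lambda = n_lambda,
                             lambda_min_ratio = lambda_min_ratio,
                             m = stability$m_per_boot,
                             max_iterations = imputation$max_iterations,
                             donor_pool = imputation$donor_pool)
    eb <- bootstrap_edges(data, pipe, stability)
    cd <- case_dropping(data, pipe, stability)
    cs <- cs_coefficient(cd)
    p1 <- file.path(out_dir, "edge_bootstrap.csv")
    utils::write.csv(eb$ci, p1, row.names = FALSE)
    p2 <- file.path(out_dir, "case_dropping.csv")
    utils::write.csv(cd$records, p2, row.names = FALSE)
    p3 <- file.path(out_dir, "cs_coefficients.json")
    jsonlite::write_json(as.list(cs), p3, digits = NA, auto_unbox = TRUE)
    artifacts$edge_bootstrap <- p1
    artifacts$case_dropping <- p2
    artifacts$cs <- p3
    results$edge_stability <- eb
    results$case_dropping <- cd
    results$cs <- cs
  }

  manifest <- list(seed = seed, config = config, config_hash = config_hash,
                   artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  manifest$results <- results
  invisible(manifest)
}
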