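## Synthetic instrument-level cohort generation.
##
## The generator emulates the data structure of a bereaved, trauma-exposed
## treatment-seeking sample: 22 TGI-SR+ items (1-5), the CAPS-5 items used
## by the ICD-11 algorithms (0-4), the five COPISAC items (0-4), plus loss
## metadata. The 13 network-node variables are driven by a latent Gaussian
## ground-truth network; the remaining items load on a general severity
## factor derived from the same latents.

.cohort_item_cols <- c(paste0("TGI_", sprintf("%02d", 1:22)),
                       paste0("CAPS_", sprintf("%02d", c(1, 2, 6, 7, 13, 17, 18, 22, 24, 25))),
                       paste0("COPISAC_CO", 1:5))
.cohort_meta_cols <- c("MONTHS_SINCE_LOSS", "BEREAVED", "TRAUMA_A")

## node -> item back-map for the single-item nodes (category index -> value)
.node_single_items <- c(Pr = "TGI_01", Ye = "TGI_03", AL = "TGI_05",
                        BA = "TGI_08", ML = "TGI_09", Nu = "TGI_10",
                        PD = "TGI_21", ad = "COPISAC_CO1", NSC = "COPISAC_CO2")
.node_sum_items <- list(Re = c("CAPS_01", "CAPS_02"),
                        Av = c("CAPS_06", "CAPS_07"),
                        Th = c("CAPS_17", "CAPS_18"),
                        DR = c("COPISAC_CO3", "CAPS_13"))

#' Cohort generator settings
#'
#' Latent mean shifts (standard-normal units) move instrument severities up
#' or down and thereby control realized prevalences; the defaults emulate a
#' treatment-seeking PTSD sample (elevated post-traumatic symptoms, less
#' frequent disturbances in self-organization). Months since the most
#' distressing loss follow a gamma distribution with mean 96 and SD 80
#' months (about 8 +/- 6.7 years).
#'
#' @param shift_tgi,shift_caps,shift_copisac latent mean shifts per
#'   instrument.
#' @param loading_extra factor loading of non-node items on the general
#'   severity factor, in [0, 1).
#' @param months_mean,months_sd gamma moments for months since loss.
#' @param prop_bereaved,prop_trauma probability of the bereaved /
#'   Criterion-A flags (inclusion-criteria style defaults of 1).
#' @param force named list of item values forced for every participant
#'   (e.g. \code{list(TGI = 5)} to force all TGI items, or individual
#'   column names); used for boundary checks.
#' @return a \code{cohort_config} list.
#' @export
cohort_config <- function(shift_tgi = 0, shift_caps = 0.8,
                          shift_copisac = -0.4, loading_extra = 0.7,
                          months_mean = 96, months_sd = 80,
                          prop_bereaved = 1, prop_trauma = 1,
                          force = NULL) {
  structure(list(shift_tgi = shift_tgi, shift_caps = shift_caps,
                 shift_copisac = shift_copisac,
                 loading_extra = loading_extra,
                 months_mean = months_mean, months_sd = months_sd,
                 prop_bereaved = prop_bereaved, prop_trauma = prop_trauma,
                 force = force),
            class = "cohort_config")
}

.instrument_shift <- function(col, config) {
  if (startsWith(col, "TGI_")) config$shift_tgi
  else if (startsWith(col, "CAPS_")) config$shift_caps
  else config$shift_copisac
}

## cut latent + shift into an ordinal value on [lo, hi] with equiprobable
## thresholds
.cut_item <- function(z, shift, lo, hi) {
  th <- equiprobable_thresholds(hi - lo + 1L)
  findInterval(z + shift, th) + lo
}

#' Generate a synthetic instrument-level cohort
#'
#' Draws latent node vectors from a ground-truth network, maps them to the
#' 13 network-node variables (two-item cluster sums are split into their
#' constituent items), and generates the remaining items from a general
#' severity factor. Emits every item needed by the diagnostic algorithms
#' plus loss metadata.
#'
#' @param n number of participants.
#' @param net a \code{\link{true_network}} over the 13 symptom nodes
#'   (default: density 0.5 with weights in [-0.04, 0.49]).
#' @param config a \code{\link{cohort_config}}.
#' @param seed integer seed.
#' @return object of class \code{grief_cohort}: list with \code{data}
#'   (data frame PID + items + metadata), \code{true_network},
#'   \code{config}, \code{seed}.
#' @export
generate_cohort <- function(n, net = true_network(), config = cohort_config(),
                            seed = 1) {
  stopifnot(n >= 1, inherits(net, "true_network"),
            identical(net$labels, grief_node_labels))
  R <- latent_correlation(net)
  ch <- chol(R)
  out <- with_seed(split_seed(seed, "cohort"), {
    Z <- matrix(stats::rnorm(n * 13), n, 13) %*% ch
    colnames(Z) <- net$labels
    df <- data.frame(PID = sprintf("P%04d", seq_len(n)))

    ## single-item nodes
    for (nd in names(.node_single_items)) {
      col <- .node_single_items[[nd]]
      lo <- if (startsWith(col, "TGI_")) 1L else 0L
      df[[col]] <- .cut_item(Z[, nd], .instrument_shift(col, config), lo, lo + 4L)
    }
    ## two-item sum nodes: cut the latent into a 0-8 sum, then split the sum
    ## uniformly over the feasible (0-4, 0-4) decompositions
    for (nd in names(.node_sum_items)) {
      cols <- .node_sum_items[[nd]]
      shift <- mean(vapply(cols, .instrument_shift, numeric(1), config = config))
      s <- .cut_item(Z[, nd], shift, 0L, 8L)
      lo1 <- pmax(0L, s - 4L); hi1 <- pmin(4L, s)
      i1 <- lo1 + floor(stats::runif(n) * (hi1 - lo1 + 1L))
      i1 <- pmin(i1, hi1)
      df[[cols[1]]] <- as.integer(i1)
      df[[cols[2]]] <- as.integer(s - i1)
    }
    ## remaining items: general severity factor + unique noise
    g <- as.vector(scale(rowMeans(Z)))
    lam <- config$loading_extra
    extra <- setdiff(.cohort_item_cols, names(df))
    for (col in extra) {
      e <- lam * g + sqrt(1 - lam^2) * stats::rnorm(n)
      lo <- if (startsWith(col, "TGI_")) 1L else 0L
      df[[col]] <- .cut_item(e, .instrument_shift(col, config), lo, lo + 4L)
    }
    ## loss / trauma metadata
    shape <- (config$months_mean / config$months_sd)^2
    rate <- shape / config$months_mean
    df$MONTHS_SINCE_LOSS <- round(stats::rgamma(n, shape = shape, rate = rate), 1)
    df$BEREAVED <- as.integer(stats::runif(n) < config$prop_bereaved)
    df$TRAUMA_A <- as.integer(stats::runif(n) < config$prop_trauma)
    df
  })
  ## forced values (boundary configurations)
  if (!is.null(config$force)) {
    for (nm in names(config$force)) {
      cols <- if (nm %in% names(out)) nm
              else grep(paste0("^", nm), names(out), value = TRUE)
      if (!length(cols)) stop("force target '", nm, "' matches no column")
      for (cl in cols) out[[cl]] <- config$force[[nm]]
    }
  }
  out <- out[, c("PID", .cohort_item_cols, .cohort_meta_cols)]
  structure(list(data = out, true_network = net, config = config,
                 seed = seed),
            class = "grief_cohort")
}

#' @export
print.grief_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants, %d item columns (seed %d)\n",
              nrow(x$data), length(.cohort_item_cols), x$seed))
  cat(sprintf("  missing cells: %d\n", sum(is.na(x$data))))
  invisible(x)
}

.scale_of <- function(col) {
  if (startsWith(col, "TGI_")) "TGI"
  else if (startsWith(col, "CAPS_")) "CAPS"
  else if (startsWith(col, "COPISAC_")) "COPISAC"
  else if (col == "MONTHS_SINCE_LOSS") "META"
  else "FLAGS"   # inclusion-criteria flags; only masked when a FLAGS rate is given
}

#' Inject missingness into a cohort
#'
#' Masks item cells per scale. Under MCAR each cell of a scale is masked
#' independently with the scale's rate; under MAR the masking probability
#' is a logistic function of a named fully observed covariate (rate gives
#' the marginal mean via an intercept offset). The pre-masking data are
#' retained in the \code{original} element for recovery checks.
#'
#' @param cohort a \code{grief_cohort} (or plain data frame).
#' @param rates named per-scale rates, e.g.
#'   \code{c(TGI = 0.03, CAPS = 0.008, COPISAC = 0.02, META = 0.057)}.
#' @param mechanism "MCAR" or "MAR".
#' @param mar_covariate column name driving MAR missingness (must itself be
#'   fully observed).
#' @param mar_slope logistic slope on the standardized covariate.
#' @param seed integer seed.
#' @return the cohort with masked \code{data}, plus \code{original} and
#'   \code{mask} elements.
#' @export
inject_missingness <- function(cohort, rates, mechanism = c("MCAR", "MAR"),
                               mar_covariate = "MONTHS_SINCE_LOSS",
                               mar_slope = 1, seed = 1) {
  mechanism <- match.arg(mechanism)
  df <- if (inherits(cohort, "grief_cohort")) cohort$data else as.data.frame(cohort)
  stopifnot(all(rates >= 0), all(rates <= 1))
  original <- df
  cols <- setdiff(names(df), "PID")
  if (mechanism == "MAR") {
    if (!mar_covariate %in% names(df))
      stop("MAR covariate '", mar_covariate, "' not found")
    if (anyNA(df[[mar_covariate]]))
      stop("MAR covariate '", mar_covariate, "' has missing values")
    x <- as.vector(scale(df[[mar_covariate]]))
    cols <- setdiff(cols, mar_covariate)
  }
  mask <- matrix(FALSE, nrow(df), length(cols), dimnames = list(NULL, cols))
  with_seed(split_seed(seed, "missingness"), {
    for (cl in cols) {
      key <- .scale_of(cl)
      rate <- if (key %in% names(rates)) rates[[key]] else 0
      if (rate <= 0) next
      if (rate >= 1) {
        mask[, cl] <- TRUE
        df[[cl]][] <- NA
        next
      }
      if (mechanism == "MCAR") {
        mask[, cl] <- stats::runif(nrow(df)) < rate
      } else {
        ## intercept chosen so the average masking probability equals rate
        a <- stats::uniroot(function(a0)
          mean(stats::plogis(a0 + mar_slope * x)) - rate,
          c(-30, 30))$root
        mask[, cl] <- stats::runif(nrow(df)) < stats::plogis(a + mar_slope * x)
      }
      df[[cl]][mask[, cl]] <- NA
    }
    df
  }) -> df
  if (inherits(cohort, "grief_cohort")) {
    cohort$data <- df
    cohort$original <- original
    cohort$mask <- mask
    cohort
  } else {
    structure(list(data = df, original = original, mask = mask,
                   true_network = NULL, config = NULL, seed = seed),
              class = "grief_cohort")
  }
}
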