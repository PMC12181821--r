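## ICD-11 diagnostic scoring: severity sums, the three diagnostic
## algorithms (PGD, PTSD, cPTSD), McDonald's omega and pooled
## prevalence/comorbidity over multiply imputed data.
##
## Item map (criterion -> item code):
##   PGD   B1 longing TGI_03 | B2 preoccupation TGI_01
##         C  TGI_02/05/08/09/10/16/19/20/21/22 | E impairment TGI_13
##         D  loss > 6 months ago
##   PTSD  B1 CAPS_01 | B2 CAPS_02 | C1 CAPS_06 | C2 CAPS_07
##         D1 CAPS_17 | D2 CAPS_18 | E CAPS_24/CAPS_25 | duration CAPS_22
##   DSO   A CO1 | B CO2 | C1 CO3 | C2 CAPS_13 | D1 CO4 | D2 CO5
## A symptom counts as present at >= 4 on the 1-5 TGI scale and >= 2 on the
## 0-4 CAPS/COPISAC scale.

.tgi_cols <- paste0("TGI_", sprintf("%02d", 1:22))
.caps_cols <- paste0("CAPS_", sprintf("%02d", c(1, 2, 6, 7, 13, 17, 18, 22, 24, 25)))
.copisac_cols <- paste0("COPISAC_CO", 1:5)
.pgd_c_items <- paste0("TGI_", sprintf("%02d", c(2, 5, 8, 9, 10, 16, 19, 20, 21, 22)))
.ptsd_items <- paste0("CAPS_", sprintf("%02d", c(1, 2, 6, 7, 17, 18)))
.dso_items_default <- paste0("COPISAC_CO", 1:3)

.need <- function(row, cols) {
  absent <- setdiff(cols, names(row))
  if (length(absent))
    stop("missing required item(s): ", paste(absent, collapse = ", "))
  vals <- unlist(row[cols], use.names = FALSE)
  names(vals) <- cols
  if (anyNA(vals)) {
    bad <- cols[is.na(vals)]
    stop("missing required item(s): ", paste(bad, collapse = ", "))
  }
  vals
}

#' Symptom severity scores
#'
#' PGD severity is the sum of all 22 TGI-SR+ items (range 22-110); PTSD
#' severity sums the six ICD-11 core items (CAPS 1, 2, 6, 7, 17, 18); DSO
#' severity sums the COPISAC DSO items (CO1-CO3 by default, optionally also
#' CAPS 13); cPTSD severity is PTSD + DSO.
#'
#' @param items one participant's item values (named list / one-row data
#'   frame).
#' @param dso_include_caps13 also add CAPS 13 to the DSO sum (default
#'   FALSE).
#' @return list with severity_pgd, severity_ptsd, severity_dso,
#'   severity_cptsd.
#' @export
score_severity <- function(items, dso_include_caps13 = FALSE) {
  tgi <- .need(items, .tgi_cols)
  ptsd <- .need(items, .ptsd_items)
  dso_cols <- c(.dso_items_default, if (dso_include_caps13) "CAPS_13")
  dso <- .need(items, dso_cols)
  list(severity_pgd = sum(tgi),
       severity_ptsd = sum(ptsd),
       severity_dso = sum(dso),
       severity_cptsd = sum(ptsd) + sum(dso))
}

#' Probable ICD-11 prolonged grief disorder
#'
#' True iff the participant is bereaved, at least one core symptom (longing
#' TGI 3 or preoccupation TGI 1) is rated >= 4, at least one accompanying
#' symptom (TGI 2, 5, 8, 9, 10, 16, 19, 20, 21, 22) is rated >= 4,
#' functional impairment (TGI 13) is rated >= 4, and the loss occurred more
#' than 6 months ago.
#'
#' @param items named item values including TGI_01..TGI_22.
#' @param months_since_loss months since the most distressing loss; must be
#'   supplied (a floor value established from other information may be
#'   passed as data, it is never assumed).
#' @param bereaved logical flag.
#' @return logical.
#' @export
diagnose_pgd <- function(items, months_since_loss, bereaved = TRUE) {
  if (is.na(months_since_loss))
    stop("months_since_loss is unknown; supply an imputed or floor value")
  tgi <- .need(items, .tgi_cols)
  isTRUE(bereaved) &&
    (tgi[["TGI_03"]] >= 4 || tgi[["TGI_01"]] >= 4) &&
    any(tgi[.pgd_c_items] >= 4) &&
    tgi[["TGI_13"]] >= 4 &&
    months_since_loss > 6
}

#' Probable ICD-11 PTSD
#'
#' True iff a Criterion-A traumatic event is present and at least one item
#' of each core cluster (re-experiencing CAPS 1/2, avoidance CAPS 6/7,
#' current threat CAPS 17/18) and impairment (CAPS 24/25) is rated >= 2,
#' with symptom duration of at least a couple of weeks (CAPS 22, consumed
#' as a duration-satisfied indicator: any value >= 1 counts, TRUE/FALSE
#' accepted).
#'
#' @param items named item values including the CAPS columns.
#' @param trauma logical Criterion-A flag (from the LEC interview).
#' @return logical.
#' @export
diagnose_ptsd_icd11 <- function(items, trauma = TRUE) {
  caps <- .need(items, .caps_cols)
  duration_ok <- as.numeric(caps[["CAPS_22"]]) >= 1
  isTRUE(trauma) &&
    (caps[["CAPS_01"]] >= 2 || caps[["CAPS_02"]] >= 2) &&
    (caps[["CAPS_06"]] >= 2 || caps[["CAPS_07"]] >= 2) &&
    (caps[["CAPS_17"]] >= 2 || caps[["CAPS_18"]] >= 2) &&
    (caps[["CAPS_24"]] >= 2 || caps[["CAPS_25"]] >= 2) &&
    duration_ok
}

#' Probable ICD-11 complex PTSD
#'
#' cPTSD requires the PTSD criteria plus all three DSO clusters: affect
#' dysregulation (CO1 >= 2), negative self-concept (CO2 >= 2), relationship
#' disturbances (CO3 >= 2 or CAPS 13 >= 2), and DSO-related impairment
#' (CO4 >= 2 or CO5 >= 2). A participant meeting cPTSD criteria does not
#' receive an additional PTSD diagnosis.
#'
#' @param items named item values including CAPS and COPISAC columns.
#' @param trauma logical Criterion-A flag.
#' @return list \code{(cptsd, ptsd_additional)}: \code{ptsd_additional} is
#'   TRUE when PTSD criteria are met but cPTSD criteria are not.
#' @export
diagnose_cptsd <- function(items, trauma = TRUE) {
  co <- .need(items, .copisac_cols)
  caps13 <- .need(items, "CAPS_13")
  ptsd <- diagnose_ptsd_icd11(items, trauma = trauma)
  cptsd <- ptsd &&
    co[["COPISAC_CO1"]] >= 2 &&
    co[["COPISAC_CO2"]] >= 2 &&
    (co[["COPISAC_CO3"]] >= 2 || caps13[["CAPS_13"]] >= 2) &&
    (co[["COPISAC_CO4"]] >= 2 || co[["COPISAC_CO5"]] >= 2)
  list(cptsd = cptsd, ptsd_additional = ptsd && !cptsd)
}

#' Apply all three diagnostic algorithms to a completed dataset
#'
#' @param data completed (no missing values) cohort data frame with item
#'   columns plus MONTHS_SINCE_LOSS, BEREAVED, TRAUMA_A.
#' @return data frame with logical columns pgd, ptsd_icd11, cptsd and the
#'   four severity scores.
#' @export
diagnose_cohort <- function(data) {
  n <- nrow(data)
  out <- data.frame(pgd = logical(n), ptsd_icd11 = logical(n),
                    cptsd = logical(n), severity_pgd = numeric(n),
                    severity_ptsd = numeric(n), severity_dso = numeric(n),
                    severity_cptsd = numeric(n))
  for (i in seq_len(n)) {
    row <- data[i, , drop = FALSE]
    sev <- score_severity(row)
    dx <- diagnose_cptsd(row, trauma = as.logical(row[["TRAUMA_A"]]))
    out$pgd[i] <- diagnose_pgd(row, row[["MONTHS_SINCE_LOSS"]],
                               bereaved = as.logical(row[["BEREAVED"]]))
    out$cptsd[i] <- dx$cptsd
    out$ptsd_icd11[i] <- dx$ptsd_additional
    out$severity_pgd[i] <- sev$severity_pgd
    out$severity_ptsd[i] <- sev$severity_ptsd
    out$severity_dso[i] <- sev$severity_dso
    out$severity_cptsd[i] <- sev$severity_cptsd
  }
  out
}

#' Pooled probable prevalence and comorbidity over an imputation stack
#'
#' Applies the three diagnostic algorithms to each completed dataset,
#' averages case counts over the m imputations and reports proportions
#' relative to the total sample and, for comorbidity, relative to the
#' pooled PGD count. Reported pooled n is the average count rounded
#' half-up.
#'
#' @param stack an \code{imputation_stack} of cohort data (each dataset must
#'   carry the metadata columns).
#' @return list with per-diagnosis pooled counts and percentages.
#' @export
prevalence_and_comorbidity <- function(stack) {
  stopifnot(inherits(stack, "imputation_stack"))
  N <- nrow(stack$datasets[[1]])
  per <- lapply(stack$datasets, diagnose_cohort)
  cnt <- function(f) mean(vapply(per, function(d) sum(f(d)), numeric(1)))
  pgd <- cnt(function(d) d$pgd)
  ptsd <- cnt(function(d) d$ptsd_icd11)
  cptsd <- cnt(function(d) d$cptsd)
  pgd_ptsd <- cnt(function(d) d$pgd & d$ptsd_icd11)
  pgd_cptsd <- cnt(function(d) d$pgd & d$cptsd)
  half_up <- function(x) floor(x + 0.5)
  pct <- function(x, base) if (base > 0) 100 * x / base else 0
  list(n_total = N, m = length(per),
       pgd = list(count = pgd, n = half_up(pgd), pct = pct(pgd, N)),
       ptsd = list(count = ptsd, n = half_up(ptsd), pct = pct(ptsd, N)),
       cptsd = list(count = cptsd, n = half_up(cptsd), pct = pct(cptsd, N)),
       comorbid_pgd_ptsd = list(count = pgd_ptsd, n = half_up(pgd_ptsd),
                                pct_total = pct(pgd_ptsd, N),
                                pct_among_pgd = pct(pgd_ptsd, pgd)),
       comorbid_pgd_cptsd = list(count = pgd_cptsd, n = half_up(pgd_cptsd),
                                 pct_total = pct(pgd_cptsd, N),
                                 pct_among_pgd = pct(pgd_cptsd, pgd)))
}

#' McDonald's omega total
#'
#' Fits a one-factor model by maximum-likelihood factor analysis on the
#' correlation matrix and returns
#' \eqn{\omega = (\sum \lambda)^2 / ((\sum \lambda)^2 + \sum \psi)}.
#' Negative uniquenesses (Heywood cases) are clipped at zero with a
#' warning.
#'
#' @param items n x k numeric matrix, k >= 3.
#' @return list with \code{omega_total}, \code{loadings},
#'   \code{error_variances}.
#' @export
mcdonald_omega <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 3) stop("omega requires at least 3 items (one-factor model is under-identified)")
  if (nrow(items) <= k) stop("need more observations than items")
  R <- stats::cor(items, use = "pairwise.complete.obs")
  fit <- tryCatch(stats::factanal(covmat = R, factors = 1, n.obs = nrow(items)),
                  error = function(e) stop("one-factor model did not converge: ",
                                           conditionMessage(e)))
  lambda <- as.vector(fit$loadings)
  psi <- fit$uniquenesses
  if (any(psi < 0)) {
    warning("Heywood case: negative uniqueness clipped at 0")
    psi <- pmax(psi, 0)
  }
  num <- sum(lambda)^2
  list(omega_total = num / (num + sum(psi)),
       loadings = lambda, error_variances = psi)
}
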