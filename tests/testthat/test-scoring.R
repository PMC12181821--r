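test_that("severity scores hit the printed scale bounds", {
  lo <- full_item_row(tgi = 1, caps = 0, copisac = 0)
  hi <- full_item_row(tgi = 5, caps = 4, copisac = 4)
  expect_equal(score_severity(lo)$severity_pgd, 22)
  expect_equal(score_severity(hi)$severity_pgd, 110)
  expect_equal(score_severity(hi)$severity_ptsd, 24)   # six items at 4
  expect_equal(score_severity(hi)$severity_dso, 12)    # CO1-CO3 at 4
  expect_equal(score_severity(hi)$severity_cptsd, 36)
  expect_equal(score_severity(hi, dso_include_caps13 = TRUE)$severity_dso, 16)
  row <- lo; row$TGI_07 <- NULL
  expect_error(score_severity(row), "TGI_07")
})

test_that("PGD algorithm follows the ICD-11 gates", {
  hi <- full_item_row(tgi = 5)
  expect_true(diagnose_pgd(hi, months_since_loss = 24, bereaved = TRUE))
  expect_false(diagnose_pgd(hi, months_since_loss = 5, bereaved = TRUE))
  expect_false(diagnose_pgd(hi, months_since_loss = 6, bereaved = TRUE))
  expect_true(diagnose_pgd(hi, months_since_loss = 6.5, bereaved = TRUE))
  expect_false(diagnose_pgd(hi, months_since_loss = 24, bereaved = FALSE))
  # core present, all accompanying symptoms below threshold
  row <- full_item_row(tgi = 3)
  row$TGI_01 <- 5; row$TGI_03 <- 5; row$TGI_13 <- 5
  expect_false(diagnose_pgd(row, 24, TRUE))
  row$TGI_16 <- 4
  expect_true(diagnose_pgd(row, 24, TRUE))
  expect_error(diagnose_pgd(hi, NA), "unknown")
})

test_that("PTSD algorithm requires every cluster gate", {
  hi <- full_item_row(caps = 4)
  expect_true(diagnose_ptsd_icd11(hi, trauma = TRUE))
  expect_false(diagnose_ptsd_icd11(hi, trauma = FALSE))
  row <- hi; row$CAPS_01 <- 1; row$CAPS_02 <- 1
  expect_false(diagnose_ptsd_icd11(row, trauma = TRUE))
  row <- hi; row$CAPS_22 <- 0
  expect_false(diagnose_ptsd_icd11(row, trauma = TRUE))
})

test_that("cPTSD supersedes PTSD and needs all DSO clusters", {
  hi <- full_item_row(tgi = 5, caps = 4, copisac = 4)
  dx <- diagnose_cptsd(hi, trauma = TRUE)
  expect_true(dx$cptsd)
  expect_false(dx$ptsd_additional)
  row <- hi; row$COPISAC_CO1 <- 1
  dx2 <- diagnose_cptsd(row, trauma = TRUE)
  expect_false(dx2$cptsd)
  expect_true(dx2$ptsd_additional)
  # relationship cluster satisfied through CAPS 13 alone
  row3 <- hi; row3$COPISAC_CO3 <- 0
  expect_true(diagnose_cptsd(row3, trauma = TRUE)$cptsd)
})

test_that("diagnoses equal brute-force truth tables on threshold grids", {
  # PGD: vary the decisive items over {3,4} with others at floor/ceiling
  vary <- c("TGI_01", "TGI_03", "TGI_02", "TGI_13")
  grid <- expand.grid(rep(list(c(3, 4)), length(vary)))
  names(grid) <- vary
  for (i in seq_len(nrow(grid))) {
    row <- full_item_row(tgi = 1)
    row[vary] <- as.list(grid[i, ])
    for (months in c(5, 24)) {
      expect_identical(diagnose_pgd(row, months, TRUE),
                       unname(oracle_pgd(row, months, TRUE)))
    }
  }
  # PTSD / cPTSD: vary cluster items over {1,2}
  vary2 <- c("CAPS_01", "CAPS_06", "CAPS_17", "CAPS_24",
             "COPISAC_CO1", "COPISAC_CO2", "COPISAC_CO3", "COPISAC_CO4")
  grid2 <- expand.grid(rep(list(c(1, 2)), length(vary2)))
  names(grid2) <- vary2
  for (i in seq_len(nrow(grid2))) {
    row <- full_item_row(caps = 1, copisac = 1)
    row$CAPS_22 <- 2
    row[vary2] <- as.list(grid2[i, ])
    expect_identical(diagnose_ptsd_icd11(row, TRUE),
                     unname(oracle_ptsd(row, TRUE)))
    dx <- diagnose_cptsd(row, TRUE)
    oracle <- oracle_cptsd(row, TRUE)
    expect_identical(dx$cptsd, unname(oracle["cptsd"]))
    expect_identical(dx$ptsd_additional, unname(oracle["ptsd_additional"]))
  }
})

test_that("mutual exclusivity and monotonicity hold on random profiles", {
  set.seed(55)
  n_profiles <- 2000
  for (i in seq_len(n_profiles)) {
    row <- full_item_row(tgi = sample(1:5, 1))
    for (nm in names(row)) {
      row[[nm]] <- if (startsWith(nm, "TGI_")) sample(1:5, 1) else sample(0:4, 1)
    }
    dx <- diagnose_cptsd(row, trauma = TRUE)
    expect_false(dx$cptsd && dx$ptsd_additional)
    # raising one random item never turns a positive diagnosis negative
    if (dx$cptsd || dx$ptsd_additional) {
      nm <- sample(names(row), 1)
      hi_val <- if (startsWith(nm, "TGI_")) 5 else 4
      row2 <- row; row2[[nm]] <- hi_val
      dx2 <- diagnose_cptsd(row2, trauma = TRUE)
      expect_true(dx2$cptsd || dx2$ptsd_additional)
      if (dx$cptsd) expect_true(dx2$cptsd)
    }
    if (i %% 4 == 0) {
      pgd <- diagnose_pgd(row, 24, TRUE)
      if (pgd) {
        nm <- sample(sprintf("TGI_%02d", 1:22), 1)
        row2 <- row; row2[[nm]] <- 5
        expect_true(diagnose_pgd(row2, 24, TRUE))
      }
    }
  }
})

test_that("pooled prevalence averages counts over imputations", {
  # two completed datasets engineered to 25 and 26 PGD cases out of 92
  mk <- function(n_cases) {
    pos <- as.data.frame(full_item_row(tgi = 5, caps = 0, copisac = 0))
    neg <- as.data.frame(full_item_row(tgi = 1, caps = 0, copisac = 0))
    df <- rbind(pos[rep(1, n_cases), ], neg[rep(1, 92 - n_cases), ])
    df$MONTHS_SINCE_LOSS <- 24
    df$BEREAVED <- 1
    df$TRAUMA_A <- 1
    rownames(df) <- NULL
    df
  }
  stack <- structure(list(datasets = list(mk(25), mk(26)),
                          config = imputation_config(m = 2),
                          predictor_sets = list(),
                          missing_mask = matrix(FALSE, 92, 1)),
                     class = "imputation_stack")
  prev <- prevalence_and_comorbidity(stack)
  expect_equal(prev$pgd$count, 25.5)
  expect_equal(prev$pgd$n, 26)              # rounded half-up
  expect_equal(prev$pgd$pct, 100 * 25.5 / 92, tolerance = 1e-12)
  expect_equal(prev$pgd$pct, 27.7173913, tolerance = 1e-6)
  expect_equal(prev$ptsd$count, 0)
  expect_equal(prev$comorbid_pgd_cptsd$pct_among_pgd, 0)
  # identical datasets pool to the single-dataset counts
  stack2 <- stack; stack2$datasets <- list(mk(25), mk(25))
  expect_equal(prevalence_and_comorbidity(stack2)$pgd$count, 25)
})

test_that("McDonald's omega matches the one-factor closed form", {
  set.seed(66)
  n <- 5000; k <- 10; lambda <- 0.8
  f <- rnorm(n)
  items <- sapply(seq_len(k), function(j) lambda * f + sqrt(1 - lambda^2) * rnorm(n))
  res <- mcdonald_omega(items)
  omega_pop <- (k * lambda)^2 / ((k * lambda)^2 + k * (1 - lambda^2))
  expect_lt(abs(res$omega_total - omega_pop), 0.02)
  # uncorrelated items: omega near zero
  noise <- matrix(rnorm(n * 6), n, 6)
  expect_lte(mcdonald_omega(noise)$omega_total, 0.1)
  expect_error(mcdonald_omega(items[, 1:2]), "at least 3")
})
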