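test_that("generated items respect their declared response ranges", {
  co <- generate_cohort(150, seed = 41)
  d <- co$data
  for (cl in grep("^TGI_", names(d), value = TRUE))
    expect_true(all(d[[cl]] >= 1 & d[[cl]] <= 5))
  for (cl in grep("^(CAPS|COPISAC)", names(d), value = TRUE))
    expect_true(all(d[[cl]] >= 0 & d[[cl]] <= 4))
  expect_true(all(d$MONTHS_SINCE_LOSS >= 0))
  expect_true(all(d$BEREAVED %in% 0:1))
  # two-item cluster sums decompose consistently
  expect_true(all(d$CAPS_01 + d$CAPS_02 <= 8))
  # same seed regenerates the identical cohort
  expect_identical(d, generate_cohort(150, seed = 41)$data)
})

test_that("node table of a generated cohort reproduces the latent node categories", {
  net <- true_network(seed = 43)
  co <- generate_cohort(3000, net = net, seed = 44)
  nodes <- build_node_table(co$data)
  # marginals of single-item nodes should be near-equiprobable at zero shift
  tab <- table(nodes[, "Pr"]) / 3000
  expect_lt(max(abs(tab - 0.2)), 0.05)
  # polychoric correlations recover the latent structure
  R <- latent_correlation(net)
  est <- polychoric_matrix(nodes)$S
  pgd_nodes <- c("Pr", "Ye", "AL", "BA", "ML", "Nu", "PD")
  expect_lt(max(abs(est[pgd_nodes, pgd_nodes] - R[pgd_nodes, pgd_nodes])), 0.08)
})

test_that("forced boundary configurations drive the diagnoses deterministically", {
  co_hi <- generate_cohort(40, seed = 45,
                           config = cohort_config(force = list(TGI = 5, MONTHS_SINCE_LOSS = 24)))
  d <- diagnose_cohort(co_hi$data)
  expect_true(all(d$pgd))
  co_lo <- generate_cohort(40, seed = 46,
                           config = cohort_config(force = list(TGI = 1, CAPS = 0, COPISAC = 0)))
  d2 <- diagnose_cohort(co_lo$data)
  expect_false(any(d2$pgd | d2$ptsd_icd11 | d2$cptsd))
})

test_that("realized prevalence matches the latent-threshold integral", {
  # single-item gate: P(TGI_13 >= 4) with shift s is 1 - Phi(qnorm(3/5) - s)
  for (s in c(0, 0.5)) {
    co <- generate_cohort(20000, seed = 47,
                          config = cohort_config(shift_tgi = s))
    p_hat <- mean(co$data$TGI_13 >= 4)
    p_true <- 1 - pnorm(qnorm(3 / 5) - s)
    expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / 20000) + 0.01)
  }
})

test_that("missingness injection is exact at the trivial rates", {
  co <- generate_cohort(50, seed = 48)
  m0 <- inject_missingness(co, c(TGI = 0, CAPS = 0, COPISAC = 0, META = 0),
                           seed = 1)
  expect_identical(m0$data, co$data)
  m1 <- inject_missingness(co, c(TGI = 1), seed = 1)
  tgi <- grep("^TGI_", names(m1$data), value = TRUE)
  expect_true(all(is.na(m1$data[tgi])))
  expect_false(anyNA(m1$data[grep("^CAPS_", names(m1$data), value = TRUE)]))
})

test_that("MCAR realized rate is within binomial error and masks only targets", {
  co <- generate_cohort(92, seed = 49)
  m <- inject_missingness(co, c(TGI = 0.057), seed = 50)
  tgi <- grep("^TGI_", names(m$data), value = TRUE)
  n_cells <- 92 * 22
  rate_hat <- sum(is.na(m$data[tgi])) / n_cells
  se <- sqrt(0.057 * (1 - 0.057) / n_cells)
  expect_lt(abs(rate_hat - 0.057), 3 * se)
  # non-masked cells identical to the original
  for (cl in tgi) {
    keep <- !is.na(m$data[[cl]])
    expect_identical(m$data[[cl]][keep], m$original[[cl]][keep])
  }
})

test_that("MAR missingness depends on the named covariate", {
  co <- generate_cohort(4000, seed = 51)
  m <- inject_missingness(co, c(TGI = 0.2), mechanism = "MAR",
                          mar_covariate = "MONTHS_SINCE_LOSS",
                          mar_slope = 2, seed = 52)
  mis_count <- rowSums(is.na(m$data[grep("^TGI_", names(m$data))]))
  months <- m$data$MONTHS_SINCE_LOSS
  hi <- months > median(months)
  expect_gt(mean(mis_count[hi]), mean(mis_count[!hi]))
  expect_lt(abs(mean(is.na(m$data[grep("^TGI_", names(m$data))])) - 0.2), 0.03)
  # a covariate with missing values is rejected
  co2 <- inject_missingness(co, c(META = 0.5), seed = 53)
  expect_error(
    inject_missingness(co2$data, c(TGI = 0.1), mechanism = "MAR",
                       mar_covariate = "MONTHS_SINCE_LOSS", seed = 54),
    "missing values")
})
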