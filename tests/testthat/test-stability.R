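# fast pipeline for stability machinery: plain node data, shortened penalty
# path (the algorithms are identical at full scale)
fast_pipe <- function() network_pipeline(n_lambda = 25L, m = 1L,
                                         nodes_fun = function(d) data.matrix(d))

test_that("CS-coefficient reproduces hand-constructed tables exactly", {
  mk_result <- function(records, N) {
    structure(list(records = records, N = N,
                   config = stability_config(n_boot = 10)),
              class = "case_drop_result")
  }
  # all correlations 1 at all levels: CS is the largest evaluated fraction
  rec <- expand.grid(boot = 1:20, k = c(5, 10, 20, 42))
  rec$measure <- "strength"
  rec$correlation <- 1
  expect_equal(cs_coefficient(mk_result(rec, 92))[["strength"]], 42 / 92)
  # all correlations 0.5: CS = 0
  rec$correlation <- 0.5
  expect_equal(cs_coefficient(mk_result(rec, 92))[["strength"]], 0)
  # levels pass up to k = 42, fail at k = 43: CS = 42/92 (the printed
  # 45.65% granularity at N = 92)
  rec2 <- expand.grid(boot = 1:40, k = c(10, 21, 42, 43, 60))
  rec2$measure <- "strength"
  rec2$correlation <- ifelse(rec2$k <= 42, 0.9, 0.3)
  expect_equal(cs_coefficient(mk_result(rec2, 92))[["strength"]], 42 / 92,
               tolerance = 1e-12)
  expect_equal(42 / 92, 0.4565, tolerance = 1e-4)
  # 21/92 gives the second printed granularity
  rec3 <- rec2
  rec3$correlation <- ifelse(rec3$k <= 21, 0.9, 0.3)
  expect_equal(cs_coefficient(mk_result(rec3, 92))[["strength"]], 21 / 92)
  expect_equal(21 / 92, 0.2283, tolerance = 1e-3)
  # a failing intermediate level caps CS even if later levels pass
  rec4 <- rec2
  rec4$correlation <- ifelse(rec4$k == 21, 0.3, 0.9)
  expect_equal(cs_coefficient(mk_result(rec4, 92))[["strength"]], 10 / 92)
})

test_that("CS is non-increasing in its thresholds", {
  set.seed(61)
  rec <- expand.grid(boot = 1:50, k = c(5, 15, 30, 45, 60))
  rec$measure <- "strength"
  rec$correlation <- pmin(1, pmax(-1, 1 - rec$k / 80 + rnorm(nrow(rec), 0, 0.1)))
  res <- structure(list(records = rec, N = 92,
                        config = stability_config()),
                   class = "case_drop_result")
  cs_vals <- sapply(c(0.5, 0.7, 0.9), function(thr)
    cs_coefficient(res, stability_config(cs_correlation = thr))[["strength"]])
  expect_true(all(diff(cs_vals) <= 1e-12))
  cs_p <- sapply(c(0.8, 0.9, 0.95), function(pr)
    cs_coefficient(res, stability_config(cs_probability = pr))[["strength"]])
  expect_true(all(diff(cs_p) <= 1e-12))
})

test_that("zero-variance centralities are excluded from CS with a warning", {
  rec <- data.frame(boot = 1:10, k = 5, measure = "strength",
                    correlation = c(rep(1, 8), NA, NA))
  res <- structure(list(records = rec, N = 92,
                        config = stability_config()),
                   class = "case_drop_result")
  expect_warning(cs <- cs_coefficient(res), "zero-variance")
  expect_equal(cs[["strength"]], 5 / 92)
})

test_that("degenerate bootstrap reduces to the plain percentile bootstrap", {
  # identity pipeline whose single edge is the sample mean: percentile CIs
  # must match the textbook normal-theory interval within MC tolerance
  set.seed(62)
  x <- rnorm(150, mean = 5, sd = 1)
  mean_pipe <- function(data, seed = 1) {
    W <- matrix(0, 2, 2, dimnames = list(c("m", "z"), c("m", "z")))
    W[1, 2] <- W[2, 1] <- mean(data$x)
    structure(list(nodes = c("m", "z"), weights = W, precision = diag(2),
                   communities = NULL, n = nrow(data)),
              class = "symptom_network")
  }
  res <- bootstrap_edges(data.frame(x = x, y = rnorm(150)),
                         pipeline = mean_pipe,
                         config = stability_config(n_boot = 400, m_per_boot = 1,
                                                   seed = 63),
                         nodes_fun = function(d) data.matrix(d))
  ci <- res$ci[res$ci$edge == "m--z", ]
  se <- sd(x) / sqrt(150)
  expect_lt(abs(ci$lower - (mean(x) - 1.96 * se)), 3 * se / sqrt(2))
  expect_lt(abs(ci$upper - (mean(x) + 1.96 * se)), 3 * se / sqrt(2))
  expect_lte(ci$lower, median(res$replicates[, "m--z"]))
  expect_lte(median(res$replicates[, "m--z"]), ci$upper)
})

test_that("single-replicate bootstrap collapses the CI to that replicate", {
  X <- as.data.frame(sample_ordinal(100, true_network(seed = 64), seed = 65))
  res <- bootstrap_edges(X, fast_pipe(),
                         stability_config(n_boot = 1, m_per_boot = 1, seed = 66),
                         nodes_fun = function(d) data.matrix(d))
  expect_equal(res$ci$lower, res$ci$upper)
  expect_equal(res$ci$lower, as.vector(res$replicates[1, ]))
})

test_that("resampling is reproducible under a fixed seed", {
  X <- as.data.frame(sample_ordinal(80, true_network(seed = 67), seed = 68))
  cfg <- stability_config(n_boot = 3, m_per_boot = 1, seed = 69)
  r1 <- bootstrap_edges(X, fast_pipe(), cfg, nodes_fun = function(d) data.matrix(d))
  r2 <- bootstrap_edges(X, fast_pipe(), cfg, nodes_fun = function(d) data.matrix(d))
  expect_identical(r1$replicates, r2$replicates)
})

test_that("case-dropping records correlations that degrade with larger drops", {
  net <- true_network(density = 0.5, weight_low = 0.15, weight_high = 0.45,
                      seed = 70, prop_negative = 0)
  X <- as.data.frame(sample_ordinal(250, net, seed = 71))
  res <- case_dropping(X, fast_pipe(),
                       stability_config(n_boot = 24, m_per_boot = 1, seed = 72),
                       nodes_fun = function(d) data.matrix(d))
  rec <- res$records[res$records$measure == "strength", ]
  expect_true(all(rec$correlation >= -1 & rec$correlation <= 1, na.rm = TRUE))
  small <- rec$correlation[rec$k <= median(rec$k)]
  large <- rec$correlation[rec$k > median(rec$k)]
  expect_gte(median(small, na.rm = TRUE), median(large, na.rm = TRUE))
  # drop counts stay within the configured range
  expect_true(all(rec$k >= ceiling(0.05 * 250) & rec$k <= floor(0.75 * 250)))
})
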