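test_that("complete data pass through imputation unchanged", {
  df <- data.frame(a = rnorm(30), b = rnorm(30), c = rbinom(30, 1, 0.5))
  stack <- fcs_impute(df, imputation_config(m = 3, seed = 1))
  for (d in stack$datasets) expect_identical(d, df)
})

test_that("observed cells are never modified and PMM stays in support", {
  set.seed(2)
  n <- 120
  df <- data.frame(x = rnorm(n), y = rnorm(n), z = rnorm(n))
  df$y <- df$x + rnorm(n, sd = 0.3)
  mis <- sample(n, 25)
  truth <- df$y
  df$y[mis] <- NA
  stack <- fcs_impute(df, imputation_config(m = 4, max_iterations = 3, seed = 3))
  obs_idx <- setdiff(seq_len(n), mis)
  for (d in stack$datasets) {
    expect_identical(d$y[obs_idx], truth[obs_idx])
    expect_identical(d$x, df$x)
    expect_false(anyNA(d))
    # donor property: every imputed value is an observed value of y
    expect_true(all(d$y[mis] %in% df$y[obs_idx]))
    expect_true(all(d$y[mis] >= min(df$y[obs_idx]) &
                      d$y[mis] <= max(df$y[obs_idx])))
  }
})

test_that("PMM with one donor and a monotone predictor copies the nearest neighbour", {
  x_obs <- seq(1, 20)
  y_obs <- 2 * x_obs + 1          # noiseless linear relation
  x_mis <- c(3.2, 11.9, 17.4)
  imp <- pmm_step(y_obs, cbind(x_obs), cbind(x_mis), k = 1, seed = 5)
  # brute-force nearest-neighbour oracle in predictor space
  oracle <- vapply(x_mis, function(x) y_obs[which.min(abs(x_obs - x))],
                   numeric(1))
  expect_equal(imp, oracle)
})

test_that("constant predictors make PMM a uniform draw from observed values", {
  y_obs <- c(1, 2, 3, 4, 5)
  X_obs <- matrix(1, 5, 1)
  draws <- replicate(300, {
    suppressWarnings(pmm_step(y_obs, X_obs, matrix(1, 1, 1), k = 5,
                              seed = sample.int(1e6, 1)))
  })
  expect_true(all(draws %in% y_obs))
  tab <- table(factor(draws, levels = y_obs))
  expect_gt(min(tab), 0)   # every donor reachable
  expect_lt(max(abs(tab / 300 - 0.2)), 3 * sqrt(0.2 * 0.8 / 300) + 0.02)
})

test_that("logistic step handles degenerate and balanced cases", {
  X <- cbind(rnorm(50))
  expect_warning(
    imp <- logistic_step(rep(1, 50), X, cbind(rnorm(10)), seed = 1),
    "single observed class")
  expect_true(all(imp == 1))
  # balanced outcome independent of X: imputed class fraction near 1/2
  set.seed(9)
  n <- 400
  y <- rep(0:1, n / 2)
  Xo <- cbind(rnorm(n))
  imp2 <- logistic_step(y, Xo, cbind(rnorm(600)), seed = 2)
  expect_lt(abs(mean(imp2) - 0.5), 3 * sqrt(0.25 / 600) + 0.05)
})

test_that("strong separation imputes the fitted side of the boundary", {
  set.seed(4)
  x <- c(rnorm(60, -3), rnorm(60, 3))
  y <- as.numeric(x > 0)
  x_mis <- c(rnorm(50, -3), rnorm(50, 3))
  expect_warning(imp <- logistic_step(y, cbind(x), cbind(x_mis), seed = 7),
                 "separation")
  agreement <- mean(imp == as.numeric(x_mis > 0))
  expect_gte(agreement, 0.95)
})

test_that("Rubin pooling matches the textbook formulas", {
  p <- pool_rubin(c(0.4, 0.4, 0.4), c(0.01, 0.01, 0.01))
  expect_equal(p$point, 0.4)
  expect_equal(p$between_variance, 0)
  expect_equal(p$total_variance, 0.01)
  p2 <- pool_rubin(c(0, 1), c(0, 0))
  expect_equal(p2$point, 0.5)
  expect_equal(p2$between_variance, 0.5)
  expect_equal(p2$total_variance, 0.75)
  set.seed(11)
  for (i in 1:20) {
    est <- rnorm(7); v <- rexp(7)
    p3 <- pool_rubin(est, v)
    expect_equal(p3$point, mean(est), tolerance = 1e-12)
    expect_equal(p3$within_variance, mean(v), tolerance = 1e-12)
    expect_equal(p3$between_variance, sum((est - mean(est))^2) / 6,
                 tolerance = 1e-12)
    expect_equal(p3$total_variance, mean(v) + (1 + 1 / 7) * p3$between_variance,
                 tolerance = 1e-12)
  }
  expect_error(pool_rubin(numeric(0)), "no estimates")
})

test_that("correlation pooling works on the Fisher-z scale", {
  expect_equal(pool_correlation(rep(0.23, 5), n = 92)$point, 0.23,
               tolerance = 1e-12)
  expect_equal(pool_correlation(c(0.5, -0.5), n = 92)$point, 0,
               tolerance = 1e-12)
  r <- c(0.2, 0.3, 0.4)
  expect_equal(pool_correlation(r, n = 92)$point, tanh(mean(atanh(r))),
               tolerance = 1e-12)
  expect_equal(pool_correlation(r, n = 92)$within_variance, 1 / 89,
               tolerance = 1e-12)
  expect_error(pool_correlation(c(0.2, 1), n = 92), "magnitude 1")
})

test_that("MCAR imputation recovers complete-data item means", {
  co <- tiny_cohort(n = 200, seed = 21)
  complete <- co$data
  com <- inject_missingness(co, c(TGI = 0.05, CAPS = 0.05, COPISAC = 0.05,
                                  META = 0.05), seed = 22)
  stack <- fcs_impute(com$data[setdiff(names(com$data), "PID")],
                      imputation_config(m = 5, max_iterations = 5, seed = 23))
  item_cols <- grep("^(TGI|CAPS|COPISAC)", names(complete), value = TRUE)
  pooled_means <- sapply(item_cols, function(cl)
    mean(sapply(stack$datasets, function(d) mean(d[[cl]]))))
  expect_lt(max(abs(pooled_means - colMeans(complete[item_cols]))), 0.1)
})

test_that("a fully missing variable fails by name", {
  df <- data.frame(a = rnorm(10), b = NA_real_)
  expect_error(fcs_impute(df, imputation_config(m = 1)), "'b'")
})

test_that("imputation is reproducible under a fixed seed", {
  co <- tiny_cohort(n = 60, seed = 31)
  com <- inject_missingness(co, c(TGI = 0.05), seed = 32)
  cfg <- imputation_config(m = 2, max_iterations = 2, seed = 33)
  d <- com$data[setdiff(names(com$data), "PID")]
  s1 <- fcs_impute(d, cfg)
  s2 <- fcs_impute(d, cfg)
  expect_identical(s1$datasets, s2$datasets)
})
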