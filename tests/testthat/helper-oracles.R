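# Independent oracles used across the suite. Each deliberately avoids the
# package's own code path for the quantity it checks.

# bivariate normal CDF by univariate quadrature of the conditional normal
pbvn_oracle <- function(h, k, r) {
  if (r == 0) return(pnorm(h) * pnorm(k))
  stats::integrate(function(x) dnorm(x) * pnorm((k - r * x) / sqrt(1 - r^2)),
                   -Inf, h, rel.tol = 1e-12)$value
}

# ADMM solver for the graphical lasso objective (off-diagonal penalty);
# an independent convex solver used to certify the coordinate-descent path
admm_glasso <- function(S, lam, rho = 1, iters = 20000, tol = 1e-11) {
  p <- ncol(S)
  Z <- diag(p)
  U <- matrix(0, p, p)
  soft <- function(A, t) {
    R <- sign(A) * pmax(abs(A) - t, 0)
    diag(R) <- diag(A)
    R
  }
  for (i in seq_len(iters)) {
    ee <- eigen(rho * (Z - U) - S, symmetric = TRUE)
    xv <- (ee$values + sqrt(ee$values^2 + 4 * rho)) / (2 * rho)
    X <- ee$vectors %*% (xv * t(ee$vectors))
    Znew <- soft(X + U, lam / rho)
    r1 <- max(abs(X - Znew))
    r2 <- max(abs(rho * (Znew - Z)))
    Z <- Znew
    U <- U + X - Z
    if (r1 < tol && r2 < tol) break
  }
  Z
}

glasso_objective <- function(Theta, S, lam) {
  -as.numeric(determinant(Theta, logarithm = TRUE)$modulus) +
    sum(S * Theta) + lam * (sum(abs(Theta)) - sum(abs(diag(Theta))))
}

# grid-search oracle for the two-step polychoric likelihood
polychoric_grid_oracle <- function(x, y, grid = seq(-0.99, 0.99, by = 0.01)) {
  tab <- table(factor(x), factor(y))
  a <- qnorm(cumsum(table(factor(x))) / length(x))
  a <- a[-length(a)]
  b <- qnorm(cumsum(table(factor(y))) / length(y))
  b <- b[-length(b)]
  ll <- vapply(grid, function(r) {
    ra <- c(-Inf, a, Inf)
    rb <- c(-Inf, b, Inf)
    nr <- nrow(tab); nc <- ncol(tab)
    Phi <- matrix(griefnet::pbvnorm(rep(ra, times = nc + 1),
                                    rep(rb, each = nr + 1), r),
                  nr + 1, nc + 1)
    P <- Phi[-1, -1] - Phi[-(nr + 1), -1] - Phi[-1, -(nc + 1)] +
      Phi[-(nr + 1), -(nc + 1)]
    sum(tab * log(pmax(P, 1e-12)))
  }, numeric(1))
  grid[which.max(ll)]
}

# independently coded diagnostic truth tables (straight transcriptions of
# the ICD-11 algorithms, structured differently from the package's code)
oracle_pgd <- function(items, months, bereaved) {
  core <- items[["TGI_03"]] >= 4 | items[["TGI_01"]] >= 4
  acc <- FALSE
  for (i in c(2, 5, 8, 9, 10, 16, 19, 20, 21, 22))
    acc <- acc | items[[sprintf("TGI_%02d", i)]] >= 4
  bereaved & core & acc & (items[["TGI_13"]] >= 4) & (months > 6)
}
oracle_ptsd <- function(items, trauma) {
  gates <- c(items[["CAPS_01"]] >= 2 | items[["CAPS_02"]] >= 2,
             items[["CAPS_06"]] >= 2 | items[["CAPS_07"]] >= 2,
             items[["CAPS_17"]] >= 2 | items[["CAPS_18"]] >= 2,
             items[["CAPS_24"]] >= 2 | items[["CAPS_25"]] >= 2,
             items[["CAPS_22"]] >= 1)
  trauma & all(gates)
}
oracle_cptsd <- function(items, trauma) {
  ptsd <- oracle_ptsd(items, trauma)
  dso <- items[["COPISAC_CO1"]] >= 2 & items[["COPISAC_CO2"]] >= 2 &
    (items[["COPISAC_CO3"]] >= 2 | items[["CAPS_13"]] >= 2) &
    (items[["COPISAC_CO4"]] >= 2 | items[["COPISAC_CO5"]] >= 2)
  c(cptsd = ptsd & dso, ptsd_additional = ptsd & !dso)
}

# complete participant item row (all instruments) with a given fill value
full_item_row <- function(tgi = 1, caps = 0, copisac = 0) {
  row <- as.list(c(
    setNames(rep(tgi, 22), sprintf("TGI_%02d", 1:22)),
    setNames(rep(caps, 10), sprintf("CAPS_%02d", c(1, 2, 6, 7, 13, 17, 18, 22, 24, 25))),
    setNames(rep(copisac, 5), paste0("COPISAC_CO", 1:5))))
  row
}

# small complete cohort for pipeline-level tests
tiny_cohort <- function(n = 60, seed = 5, density = 0.5) {
  net <- griefnet::true_network(density = density, seed = seed)
  griefnet::generate_cohort(n, net = net, seed = seed)
}
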