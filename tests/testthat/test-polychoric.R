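# Threshold estimation and polychoric correlation.

test_that("thresholds are inverse-normal quantiles of cumulative proportions", {
  x <- rep(1:5, each = 1000)  # exact fifths
  expect_equal(estimate_thresholds(x, 5), qnorm(c(0.2, 0.4, 0.6, 0.8)),
               tolerance = 1e-12)
  expect_equal(estimate_thresholds(rep(1:2, 50), 2), 0)
  expect_warning(th <- estimate_thresholds(rep(1L, 30), 5), "degenerate")
  expect_true(all(th == Inf))
})

test_that("identical columns hit the upper clip", {
  set.seed(1)
  x <- sample(1:5, 400, replace = TRUE)
  expect_equal(polychoric_pair(x, x, n_categories = 5), 0.999)
})

test_that("polychoric pair recovers the generating latent correlation", {
  thr <- qnorm(c(0.2, 0.4, 0.6, 0.8))
  set.seed(2024)
  n <- 100000
  z1 <- rnorm(n)
  for (rho in c(0, 0.5)) {
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    x <- findInterval(z1, thr) + 1L
    y <- findInterval(z2, thr) + 1L
    expect_equal(polychoric_pair(x, y, n_categories = 5), rho,
                 tolerance = 0.02)
  }
})

test_that("polychoric pair is symmetric and monotone in the latent correlation", {
  thr <- qnorm(c(0.2, 0.4, 0.6, 0.8))
  set.seed(7)
  n <- 50000
  z1 <- rnorm(n)
  ests <- vapply(c(0, 0.3, 0.6, 0.9), function(rho) {
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    x <- findInterval(z1, thr) + 1L
    y <- findInterval(z2, thr) + 1L
    est <- polychoric_pair(x, y, n_categories = 5)
    expect_equal(polychoric_pair(y, x, n_categories = 5), est,
                 tolerance = 1e-6)
    est
  }, numeric(1))
  expect_true(all(diff(ests) > 0))
})

test_that("polychoric matrix is symmetric, unit-diagonal and row-order invariant", {
  spec <- planted_optimum_spec(c(f1 = 3, f2 = 3), c(f1 = 2, f2 = 2),
                               n_obs = 300, seed = 5)
  resp <- generate_responses(spec)
  r <- polychoric_matrix(resp, 5)
  expect_true(isSymmetric(unname(r)))
  expect_equal(unname(diag(r)), rep(1, 6))
  expect_true(all(abs(r[upper.tri(r)]) <= 0.999))
  expect_false(attr(r, "smoothing_applied"))
  perm <- polychoric_matrix(resp[sample(nrow(resp)), ], 5)
  expect_equal(unname(r), unname(perm), tolerance = 1e-6)
})

test_that("polychoric matrix reconstructs the generating structure", {
  spec <- adbs_like_spec(n_obs = 2000, seed = 31)
  resp <- generate_responses(spec)
  r <- polychoric_matrix(resp, 5)
  L <- spec$loadings
  truth <- outer(seq_along(L), seq_along(L), function(i, j) {
    phi <- ifelse(spec$factor_of[names(L)[i]] == spec$factor_of[names(L)[j]],
                  1, spec$factor_corr[1, 2])
    L[i] * L[j] * phi
  })
  off <- upper.tri(truth)
  err <- abs(r[off] - truth[off])
  # per-pair sampling SE at N = 2000 is ~0.03, so the bulk must sit inside
  # +/-0.05 while the maximum over 325 estimates may reach ~3 SE
  expect_lt(mean(err), 0.03)
  expect_lt(stats::median(err), 0.05)
  expect_lt(max(err), 0.12)
})

test_that("degenerate columns are fatal with the item named", {
  spec <- planted_optimum_spec(c(f1 = 3, f2 = 3), c(f1 = 2, f2 = 2),
                               n_obs = 50, seed = 5)
  resp <- generate_responses(spec)
  resp[, "f1_i01"] <- 3L
  expect_error(polychoric_matrix(resp, 5), "f1_i01")
})

test_that("eigenvalue clipping restores positive definiteness and flags it", {
  # an indefinite 'correlation' pattern (two near-duplicates disagreeing
  # about a third variable)
  bad <- matrix(c(1, 0.999, 0.999,
                  0.999, 1, 0.05,
                  0.999, 0.05, 1), 3, byrow = TRUE)
  sm <- smooth_correlation(bad)
  expect_true(attr(sm, "smoothing_applied"))
  ev <- eigen(sm, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_equal(unname(diag(sm)), rep(1, 3))
  expect_true(isSymmetric(unname(sm)))
  # an already-PD matrix passes through untouched
  ok <- diag(3)
  expect_false(attr(smooth_correlation(ok), "smoothing_applied"))
  # and a clean polychoric matrix is not flagged
  spec <- planted_optimum_spec(c(f1 = 3, f2 = 3), c(f1 = 2, f2 = 2),
                               n_obs = 200, seed = 2)
  expect_false(attr(polychoric_matrix(generate_responses(spec), 5),
                    "smoothing_applied"))
})

test_that("bivariate normal CDF agrees with mvtnorm across regimes", {
  skip_if_not_installed("mvtnorm")
  set.seed(3)
  for (rho in c(-0.999, -0.6, 0, 0.5, 0.9, 0.99)) {
    h <- runif(20, -3, 3)
    k <- runif(20, -3, 3)
    ref <- vapply(seq_along(h), function(i)
      mvtnorm::pmvnorm(upper = c(h[i], k[i]),
                       corr = matrix(c(1, rho, rho, 1), 2),
                       algorithm = mvtnorm::TVPACK())[1], numeric(1))
    expect_equal(acoscale:::pbvnorm(h, k, rho), ref, tolerance = 1e-8)
  }
})
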