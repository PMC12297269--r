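# Ant-colony search mechanics.

make_fixture <- function(n_obs = 300, seed = 5) {
  spec <- planted_optimum_spec(c(f1 = 5, f2 = 5), c(f1 = 3, f2 = 3),
                               n_obs = n_obs, seed = seed)
  resp <- generate_responses(spec)
  scale <- scale_from_spec(spec, attr(spec, "quota"))
  full <- scale_from_spec(spec)
  corr <- polychoric_matrix(resp, 5)
  ref <- reference_fit(resp, full, corr)
  list(spec = spec, resp = resp, scale = scale, corr = corr, ref = ref)
}

test_that("pheromone-proportional sampling respects concentration and symmetry", {
  sc <- scale_definition(list(f = sprintf("f_i%02d", 1:6)), c(f = 3))
  # concentrated pheromone: the three heavy items are all but certain
  tau <- init_pheromone(sc, 1e-6)
  heavy <- c("f_i01", "f_i03", "f_i05")
  tau[heavy] <- 1
  set.seed(10)
  hits <- sum(vapply(1:1000, function(i)
    identical(sample_subset(tau, sc)$f, sort(heavy)), logical(1)))
  expect_gte(hits / 1000, 0.999)
  # uniform pheromone: marginal selection frequency ~ k/n = 0.5
  tau <- init_pheromone(sc)
  set.seed(11)
  picks <- unlist(lapply(1:10000, function(i) sample_subset(tau, sc)$f))
  marg <- table(picks) / 10000
  expect_true(all(abs(marg - 0.5) < 0.03))
  # determinism under a fixed seed
  set.seed(3); s1 <- sample_subset(tau, sc)
  set.seed(3); s2 <- sample_subset(tau, sc)
  expect_identical(s1, s2)
})

test_that("pheromone update composes decay, deposit and flooring", {
  sc <- toy_scale(3, 2)
  tau <- init_pheromone(sc)
  best <- structure(list(items = c("a01", "a02", "b01", "b02"),
                         components = list(phi_total = 2)),
                    class = "subset_evaluation")
  tau2 <- update_pheromone(tau, best, evaporation = 0.5)
  expect_equal(unname(tau2[c("a01", "b02")]), c(2.5, 2.5))
  expect_equal(unname(tau2[c("a03", "b03")]), c(0.5, 0.5))
  # a degenerate iteration (phi = 0) is pure decay
  best$components$phi_total <- 0
  expect_equal(unname(update_pheromone(tau, best, 0.5)), rep(0.5, 6))
  # repeated decay bottoms out at the floor
  for (i in 1:40) tau <- update_pheromone(tau, NULL, 0.5)
  expect_equal(unname(tau), rep(1e-6, 6))
})

test_that("evaluating the full pool against itself is a fixed point", {
  fx <- make_fixture()
  full_scale <- scale_from_spec(fx$spec)
  ev <- evaluate_subset(full_scale$factors, fx$resp, fx$corr, fx$ref)
  expect_equal(unname(ev$sum_score_cor), c(1, 1))
  expect_equal(ev$fc_diff, 0)
  expect_equal(ev$components$phi_corr, 1 / (1 + exp(-15)))
})

test_that("infeasible fits zero out the pheromone with a reason", {
  fx <- make_fixture(n_obs = 60, seed = 2)
  # two-item factors routinely go Heywood / non-convergent at tiny N; force
  # the infeasibility path via an impossible correlation structure instead
  corr <- fx$corr
  corr["f1_i01", "f1_i02"] <- corr["f1_i02", "f1_i01"] <- 0.999
  corr["f1_i01", "f1_i03"] <- corr["f1_i03", "f1_i01"] <- 0.999
  corr["f1_i02", "f1_i03"] <- corr["f1_i03", "f1_i02"] <- 0.05
  ev <- evaluate_subset(list(f1 = c("f1_i01", "f1_i02", "f1_i03"),
                             f2 = c("f2_i01", "f2_i02", "f2_i03")),
                        fx$resp, corr, fx$ref)
  if (!is.null(ev$reason)) {
    expect_equal(ev$components$phi_total, 0)
  } else {
    succeed("structure was still admissible")
  }
})

test_that("the planted subset dominates random alternatives", {
  spec <- planted_optimum_spec(c(f1 = 6, f2 = 6), c(f1 = 3, f2 = 3),
                               n_obs = 2000, seed = 13)
  resp <- generate_responses(spec)
  scale <- scale_from_spec(spec, attr(spec, "quota"))
  corr <- polychoric_matrix(resp, 5)
  ref <- reference_fit(resp, scale_from_spec(spec), corr)
  planted <- attr(spec, "planted")
  planted_ev <- evaluate_subset(
    split(planted, sub("_.*", "", planted)), resp, corr, ref)
  set.seed(99)
  tau <- init_pheromone(scale)
  worse <- vapply(1:100, function(i) {
    sub <- sample_subset(tau, scale)
    if (identical(sort(unlist(sub)), sort(planted))) return(TRUE)
    ev <- evaluate_subset(sub, resp, corr, ref)
    ev$components$phi_total < planted_ev$components$phi_total
  }, logical(1))
  expect_true(all(worse))
})

test_that("runs are deterministic per seed with non-decreasing best-so-far", {
  fx <- make_fixture()
  cfg <- aco_config(n_ants = 15, max_iterations = 12, patience = 4, seed = 42)
  r1 <- run_aco(fx$resp, fx$scale, cfg, corr = fx$corr, reference = fx$ref)
  r2 <- run_aco(fx$resp, fx$scale, cfg, corr = fx$corr, reference = fx$ref)
  expect_identical(r1$best$items, r2$best$items)
  expect_equal(vapply(r1$trace, `[[`, numeric(1), "best_so_far_phi"),
               vapply(r2$trace, `[[`, numeric(1), "best_so_far_phi"))
  bsf <- vapply(r1$trace, `[[`, numeric(1), "best_so_far_phi")
  expect_true(all(diff(bsf) >= 0))
  ib <- vapply(r1$trace, `[[`, numeric(1), "iteration_best_phi")
  expect_true(all(bsf >= ib | abs(bsf - ib) < 1e-12))
})

test_that("patience zero executes exactly one iteration", {
  fx <- make_fixture()
  cfg <- aco_config(n_ants = 5, max_iterations = 20, patience = 0, seed = 1)
  r <- run_aco(fx$resp, fx$scale, cfg, corr = fx$corr, reference = fx$ref)
  expect_identical(r$iterations_executed, 1L)
  expect_true(r$converged_early)
})

test_that("with evaporation 1 and no feasible deposits sampling stays stationary", {
  sc <- toy_scale(3, 2)
  tau <- init_pheromone(sc)
  for (i in 1:10)
    tau <- update_pheromone(
      tau, structure(list(items = c("a01", "b01"),
                          components = list(phi_total = 0)),
                     class = "subset_evaluation"), evaporation = 1)
  expect_equal(unname(tau), rep(1, 6))
})

test_that("multi-run seeds are base + run index and reproducible", {
  fx <- make_fixture()
  cfg <- aco_config(n_ants = 10, max_iterations = 6, patience = 2,
                    seed = 100, n_runs = 3)
  runs <- run_aco_many(fx$resp, fx$scale, cfg, corr = fx$corr,
                       reference = fx$ref)
  expect_equal(vapply(runs, `[[`, integer(1), "seed"), c(101L, 102L, 103L))
  solo <- run_aco(fx$resp, fx$scale,
                  aco_config(10, 6, 0.5, 2, seed = 102),
                  corr = fx$corr, reference = fx$ref)
  expect_identical(runs[[2]]$best$items, solo$best$items)
})
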