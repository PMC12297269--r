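# Shared fixtures: published ADBS short-form loading solutions (used as
# frozen worked-example inputs), small scale builders, and the exhaustive
# search oracle.

# Standardized loadings of the published German ADBS solutions, by scale.
adbs_published <- list(
  full_pros = c(0.83, 0.77, 0.86, 0.83, 0.71, 0.74, 0.86, 0.69, 0.94, 0.92,
                0.82, 0.70, 0.56),
  full_cons = c(0.79, 0.82, 0.61, 0.85, 0.76, 0.70, 0.25, 0.31, 0.78, 0.88,
                0.74, 0.43, 0.55),
  acop_pros = c(0.77, 0.86, 0.87, 0.73, 0.68),
  acop_cons = c(0.85, 0.97, 0.93, 0.74, 0.47),
  acoc_pros = c(0.79, 0.75, 0.87, 0.83, 0.80),
  acoc_cons = c(0.68, 0.88, 0.97, 0.92, 0.82, 0.49),
  loading_scale_pros = c(0.85, 0.89, 0.84, 0.79, 0.85),
  loading_scale_cons = c(0.85, 0.89, 0.96, 0.92, 0.82))

# A tiny two-factor scale definition.
toy_scale <- function(n_per = 3, select = 2) {
  scale_definition(
    factors = list(a = sprintf("a%02d", seq_len(n_per)),
                   b = sprintf("b%02d", seq_len(n_per))),
    select = c(a = select, b = select))
}

# Model-implied correlation matrix for a two-factor simple structure.
implied_corr <- function(loadings, factor_idx, phi12) {
  p <- length(loadings)
  L <- matrix(0, p, 2)
  L[cbind(seq_len(p), factor_idx)] <- loadings
  Phi <- matrix(c(1, phi12, phi12, 1), 2)
  S <- tcrossprod(L %*% Phi, L)
  diag(S) <- 1
  S
}

# Independent exhaustive-search oracle: evaluates every admissible subset
# through the same evaluation pipeline and returns the best by phi_total
# (ties toward the lexicographically smallest item tuple).
exhaustive_best <- function(responses, scale, corr, reference) {
  per_factor <- lapply(names(scale$factors), function(f)
    utils::combn(scale$factors[[f]], scale$select_counts[[f]],
                 simplify = FALSE))
  grid <- expand.grid(lapply(per_factor, seq_along))
  best <- NULL
  best_key <- ""
  for (i in seq_len(nrow(grid))) {
    subset <- lapply(seq_along(per_factor), function(j)
      per_factor[[j]][[grid[i, j]]])
    names(subset) <- names(scale$factors)
    ev <- evaluate_subset(subset, responses, corr, reference)
    key <- paste(ev$items, collapse = "|")
    if (is.null(best) ||
        ev$components$phi_total > best$components$phi_total ||
        (ev$components$phi_total == best$components$phi_total &&
           key < best_key)) {
      best <- ev
      best_key <- key
    }
  }
  best
}

# Mock aco_run objects from bare item sets (for consensus-logic tests).
mock_runs <- function(item_sets, phis = rep(1, length(item_sets))) {
  lapply(seq_along(item_sets), function(i) {
    structure(list(
      best = structure(list(items = sort(item_sets[[i]]),
                            subset = list(all = sort(item_sets[[i]])),
                            components = list(phi_total = phis[[i]])),
                       class = "subset_evaluation"),
      trace = list(), iterations_executed = 1L, converged_early = TRUE,
      seed = i), class = "aco_run")
  })
}
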