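# Ant-colony search over item subsets: pheromone-proportional sampling,
# CFA-based evaluation against the full-pool reference, iteration-best
# deposit with multiplicative evaporation, stagnation-based convergence.

.TAU_MIN <- 1e-6

#' ACO run configuration
#'
#' Defaults sit inside the regions where the search is reported to behave
#' consistently: 60 ants, up to 50 iterations, evaporation (pheromone
#' retention) 0.5.
#'
#' @param n_ants subsets sampled per iteration (default 60).
#' @param max_iterations iteration cap (default 50).
#' @param evaporation pheromone retention factor in `(0, 1]` applied each
#'   iteration before the deposit (default 0.5); larger values make past
#'   solutions persist longer.
#' @param patience stop after this many iterations without best-so-far
#'   improvement (default 15); `patience = 0` executes exactly one iteration.
#' @param seed integer seed of a single run; in [run_aco_many()] run `r`
#'   uses `seed + r`.
#' @param n_runs number of independent runs for consensus building
#'   (default 5).
#' @return object of class `"aco_config"`.
#' @export
aco_config <- function(n_ants = 60L, max_iterations = 50L, evaporation = 0.5,
                       patience = 15L, seed = 1L, n_runs = 5L) {
  stopifnot(n_ants >= 1, max_iterations >= 1,
            evaporation > 0, evaporation <= 1,
            patience >= 0, n_runs >= 1)
  structure(list(n_ants = as.integer(n_ants),
                 max_iterations = as.integer(max_iterations),
                 evaporation = evaporation, patience = as.integer(patience),
                 seed = as.integer(seed), n_runs = as.integer(n_runs)),
            class = "aco_config")
}

#' Initialize per-item pheromone levels
#'
#' All items start at the same level, so the first iteration samples
#' uniformly at random within each factor.
#'
#' @param scale a [scale_definition()].
#' @param value initial level (default 1).
#' @return named numeric vector of pheromone levels tau.
#' @export
init_pheromone <- function(scale, value = 1) {
  stats::setNames(rep(value, length(scale$item_ids)), scale$item_ids)
}

#' Sample a candidate subset proportional to pheromone
#'
#' For each factor independently, draws the factor's quota of items
#' sequentially without replacement, each draw with probability proportional
#' to the remaining items' pheromone levels.
#'
#' @param tau named pheromone vector (see [init_pheromone()]).
#' @param scale a [scale_definition()].
#' @return named list (factor -> sorted character vector of item IDs).
#' @export
sample_subset <- function(tau, scale) {
  sel <- lapply(names(scale$factors), function(f) {
    pool <- scale$factors[[f]]
    k <- scale$select_counts[[f]]
    if (k == length(pool)) return(sort(pool))
    sort(sample(pool, k, prob = tau[pool]))
  })
  stats::setNames(sel, names(scale$factors))
}

.subset_key <- function(subset) paste(sort(unlist(subset)), collapse = "|")

#' Fit the full-pool reference model
#'
#' Fits the CFA to the complete item pool and stores the per-factor
#' unit-weighted full-scale sum scores; candidate subsets are scored against
#' this reference (sum-score correlation, factor-correlation drift).
#'
#' @param responses response matrix.
#' @param scale a [scale_definition()].
#' @param corr optional precomputed [polychoric_matrix()] of `responses`.
#' @return object of class `"reference_fit"`: list with `fit` (a
#'   `"cfa_fit"`), `sum_scores` (N x factors matrix), `scale`.
#' @export
reference_fit <- function(responses, scale, corr = NULL) {
  if (is.null(corr)) corr <- polychoric_matrix(responses, scale$n_categories)
  fit <- fit_cfa(corr, scale, nrow(responses))
  if (!fit$converged)
    stop("reference (full-pool) CFA did not converge")
  ss <- vapply(names(scale$factors), function(f)
    rowSums(responses[, scale$factors[[f]], drop = FALSE]),
    numeric(nrow(responses)))
  structure(list(fit = fit, sum_scores = ss, scale = scale),
            class = "reference_fit")
}

#' Evaluate a candidate subset
#'
#' Fits the subset CFA on the subset's rows/columns of the polychoric
#' matrix, computes per-factor McDonald's omega, the Pearson correlations
#' between short-form and full-form unit-weighted sum scores on the raw
#' responses, and the factor-correlation drift versus the reference, then
#' assembles the pheromone components. A non-converged or Heywood fit yields
#' `phi_total = 0` with the reason recorded.
#'
#' @param subset named list (factor -> item IDs) or character vector of
#'   item IDs.
#' @param responses response matrix.
#' @param corr full-pool [polychoric_matrix()].
#' @param reference a [reference_fit()] on the same data.
#' @return object of class `"subset_evaluation"`: list with `subset`,
#'   `items`, `fit`, `components`, `sum_score_cor`, `fc_diff`, `reason`.
#' @export
evaluate_subset <- function(subset, responses, corr, reference) {
  scale <- reference$scale
  items <- sort(unlist(subset, use.names = FALSE))
  sub_scale <- restrict_scale(scale, items)
  fit <- tryCatch(
    withCallingHandlers(fit_cfa(corr, sub_scale, nrow(responses)),
                        warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) e)
  if (inherits(fit, "error") || !fit$converged || fit$heywood) {
    reason <- if (inherits(fit, "error")) conditionMessage(fit)
              else if (!fit$converged) "non-convergence" else "Heywood case"
    ev <- list(subset = subset, items = items,
               fit = if (inherits(fit, "error")) NULL else fit,
               components = pheromone_components(NA, NA, NA, NA, NA,
                                                 feasible = FALSE),
               sum_score_cor = NULL, fc_diff = NA_real_, reason = reason)
    return(structure(ev, class = "subset_evaluation"))
  }
  facs <- names(sub_scale$factors)
  ss_cor <- vapply(facs, function(f) {
    short <- rowSums(responses[, sub_scale$factors[[f]], drop = FALSE])
    full <- reference$sum_scores[, f]
    if (stats::sd(short) == 0 || stats::sd(full) == 0) return(0)
    stats::cor(short, full)
  }, numeric(1))
  fc_diff <- if (length(facs) < 2) 0 else {
    ut <- upper.tri(diag(length(facs)))
    max(abs(fit$factor_corr[facs, facs][ut] -
              reference$fit$factor_corr[facs, facs][ut]))
  }
  comp <- pheromone_components(fit$cfi, fit$rmsea, fit$omega_by_factor,
                               ss_cor, fc_diff)
  structure(list(subset = subset, items = items, fit = fit,
                 components = comp, sum_score_cor = ss_cor,
                 fc_diff = fc_diff, reason = NULL),
            class = "subset_evaluation")
}

#' Evaporate and deposit pheromone
#'
#' Every item's level is first multiplied by the evaporation (retention)
#' factor; the iteration-best subset's items then receive a deposit equal to
#' its total pheromone value; levels are floored at `1e-6`.
#'
#' @param tau named pheromone vector.
#' @param iteration_best a [evaluate_subset()] result (the iteration's best).
#' @param evaporation retention factor in `(0, 1]`.
#' @return updated pheromone vector.
#' @export
update_pheromone <- function(tau, iteration_best, evaporation) {
  tau <- tau * evaporation
  if (!is.null(iteration_best)) {
    phi <- iteration_best$components$phi_total
    tau[iteration_best$items] <- tau[iteration_best$items] + phi
  }
  pmax(tau, .TAU_MIN)
}

#' Run one ant-colony search
#'
#' Repeats: sample `n_ants` subsets, evaluate the distinct ones (evaluations
#' are cached by sorted item set), update the best-so-far solution (strict
#' improvement only; ties broken toward the lexicographically smallest item
#' tuple), deposit from the iteration best, and stop when the best-so-far
#' value has not improved for `patience` iterations or the iteration cap is
#' reached.
#'
#' @param responses response matrix (from [read_responses()] or
#'   [generate_responses()]).
#' @param scale a [scale_definition()].
#' @param config an [aco_config()]; `config$seed` seeds this run.
#' @param corr optional precomputed [polychoric_matrix()].
#' @param reference optional precomputed [reference_fit()].
#' @param cache optional environment memoizing evaluations by item set; pass
#'   a shared environment to reuse evaluations across runs on the same data.
#' @param verbose print per-iteration progress.
#' @return object of class `"aco_run"`: list with `best` (a
#'   `"subset_evaluation"`), `trace` (list of per-iteration records),
#'   `iterations_executed`, `converged_early`, `seed`.
#' @export
run_aco <- function(responses, scale, config = aco_config(), corr = NULL,
                    reference = NULL, cache = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "aco_config"))
  if (is.null(corr)) corr <- polychoric_matrix(responses, scale$n_categories)
  if (is.null(reference)) reference <- reference_fit(responses, scale, corr)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  tau <- init_pheromone(scale)
  best <- NULL; best_key <- ""
  stagnation <- 0L
  trace <- vector("list", config$max_iterations)
  iterations <- 0L; converged_early <- FALSE

  for (iter in seq_len(config$max_iterations)) {
    iterations <- iter
    subsets <- replicate(config$n_ants, sample_subset(tau, scale),
                         simplify = FALSE)
    keys <- vapply(subsets, .subset_key, character(1))
    uniq <- !duplicated(keys)
    evals <- lapply(which(uniq), function(i) {
      k <- keys[i]
      if (!is.null(cache[[k]])) return(cache[[k]])
      e <- evaluate_subset(subsets[[i]], responses, corr, reference)
      cache[[k]] <- e
      e
    })
    ukeys <- keys[uniq]
    phis <- vapply(evals, function(e) e$components$phi_total, numeric(1))
    ord <- order(-phis, ukeys)
    iter_best <- evals[[ord[1]]]
    iter_key <- ukeys[ord[1]]

    # best-so-far replaced only on strict improvement; equal-value subsets
    # take over only when lexicographically smaller (no stagnation reset)
    if (is.null(best) ||
        iter_best$components$phi_total > best$components$phi_total) {
      best <- iter_best; best_key <- iter_key
      stagnation <- 0L
    } else {
      if (iter_best$components$phi_total == best$components$phi_total &&
          iter_key < best_key) {
        best <- iter_best; best_key <- iter_key
      }
      stagnation <- stagnation + 1L
    }

    tau <- update_pheromone(tau, iter_best, config$evaporation)
    trace[[iter]] <- list(iteration = iter,
                          iteration_best_phi = iter_best$components$phi_total,
                          best_so_far_phi = best$components$phi_total,
                          items = best$items)
    if (verbose)
      message(sprintf("iter %3d: best %.4f | best-so-far %.4f", iter,
                      iter_best$components$phi_total,
                      best$components$phi_total))
    if (stagnation >= config$patience) { converged_early <- TRUE; break }
  }
  structure(list(best = best, trace = trace[seq_len(iterations)],
                 iterations_executed = iterations,
                 converged_early = converged_early, seed = config$seed),
            class = "aco_run")
}

#' Run several independent ant-colony searches
#'
#' Executes `config$n_runs` runs; run `r` is seeded with `config$seed + r`,
#' making each run reproducible independently. The polychoric matrix,
#' reference fit and evaluation cache are shared across runs (evaluation is
#' deterministic given the data, so sharing changes no result).
#'
#' @inheritParams run_aco
#' @return list of `"aco_run"` objects of length `config$n_runs`.
#' @export
run_aco_many <- function(responses, scale, config = aco_config(),
                         corr = NULL, reference = NULL, verbose = FALSE) {
  if (is.null(corr)) corr <- polychoric_matrix(responses, scale$n_categories)
  if (is.null(reference)) reference <- reference_fit(responses, scale, corr)
  cache <- new.env(parent = emptyenv())
  lapply(seq_len(config$n_runs), function(r) {
    cfg <- config; cfg$seed <- config$seed + r
    run_aco(responses, scale, cfg, corr = corr, reference = reference,
            cache = cache, verbose = verbose)
  })
}

#' @export
print.aco_run <- function(x, ...) {
  cat(sprintf("ACO run (seed %d): %d iteration(s)%s, best phi = %.4f\n",
              x$seed, x$iterations_executed,
              if (x$converged_early) " (converged early)" else "",
              x$best$components$phi_total))
  cat("best subset:", paste(x$best$items, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.subset_evaluation <- function(x, ...) {
  cat("subset:", paste(x$items, collapse = ", "), "\n")
  if (!is.null(x$reason)) cat("infeasible:", x$reason, "\n")
  print(x$components)
  invisible(x)
}
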