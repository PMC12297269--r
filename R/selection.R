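# Aggregation of multiple ACO runs into final scales (best-pheromone and
# consensus) plus comparison baselines.

#' Best-pheromone (ACO-P) scale across runs
#'
#' Returns the per-run best subset with the overall highest total pheromone;
#' ties are broken toward the lexicographically smallest sorted item tuple.
#'
#' @param run_results list of `"aco_run"` objects (see [run_aco_many()]).
#' @return the winning subset: named list (factor -> item IDs) with
#'   attributes `"phi_total"` and `"run_index"`.
#' @export
select_aco_p <- function(run_results) {
  stopifnot(length(run_results) >= 1)
  phis <- vapply(run_results, function(r) r$best$components$phi_total,
                 numeric(1))
  if (all(phis == 0))
    stop("all runs ended infeasible (phi_total = 0); no ACO-P scale")
  keys <- vapply(run_results, function(r) paste(r$best$items, collapse = "|"),
                 character(1))
  win <- order(-phis, keys)[1]
  structure(run_results[[win]]$best$subset, phi_total = phis[win],
            run_index = win)
}

#' Consensus (ACO-C) scale across runs
#'
#' All items selected in at least `threshold` of the runs' best solutions.
#' The consensus is a union rule: it may yield unequal factor sizes and need
#' not respect the per-factor quotas.
#'
#' @param run_results list of `"aco_run"` objects (>= 2).
#' @param threshold minimum selection fraction (default 0.6).
#' @return sorted character vector of consensus items with attribute
#'   `"frequency"` (named selection counts over all items ever selected).
#' @export
select_aco_c <- function(run_results, threshold = 0.6) {
  stopifnot(length(run_results) >= 2, threshold > 0, threshold <= 1)
  picks <- unlist(lapply(run_results, function(r) r$best$items))
  freq <- table(picks)
  keep <- sort(names(freq)[freq / length(run_results) >= threshold])
  if (length(keep) == 0)
    warning("empty consensus at threshold ", threshold)
  structure(keep, frequency = stats::setNames(as.integer(freq), names(freq)))
}

#' Highest-loading baseline selection
#'
#' The traditional comparison strategy: per factor, take the quota items with
#' the highest full-pool standardized loadings (ties toward the
#' lexicographically smallest item ID).
#'
#' @param reference a [reference_fit()].
#' @param scale a [scale_definition()] carrying the quotas.
#' @return named list (factor -> sorted item IDs).
#' @export
baseline_top_loadings <- function(reference, scale) {
  stopifnot(inherits(reference, "reference_fit"))
  lam <- reference$fit$loadings
  sel <- lapply(names(scale$factors), function(f) {
    pool <- scale$factors[[f]]
    ord <- pool[order(-lam[pool], pool)]
    sort(ord[seq_len(scale$select_counts[[f]])])
  })
  stats::setNames(sel, names(scale$factors))
}

#' Evaluate a fixed item subset
#'
#' Runs the same evaluation pipeline as the ACO ants on an externally given
#' subset (e.g. a legacy short scale), enabling like-for-like comparisons.
#' A bare character vector is split into factors via the scale definition.
#'
#' @param subset named list (factor -> item IDs) or character vector.
#' @param responses response matrix.
#' @param corr full-pool [polychoric_matrix()].
#' @param reference a [reference_fit()].
#' @return a `"subset_evaluation"`.
#' @export
evaluate_fixed_subset <- function(subset, responses, corr, reference) {
  if (!is.list(subset)) {
    fo <- reference$scale$factor_of[as.character(subset)]
    if (anyNA(fo))
      stop("unknown item(s): ",
           paste(subset[is.na(fo)], collapse = ", "))
    subset <- lapply(split(names(fo), fo), sort)
  }
  evaluate_subset(subset, responses, corr, reference)
}

#' Comparison table across candidate scales
#'
#' One row per labeled evaluation with the discrepancy statistic, df, CFI,
#' RMSEA, per-factor omega, loading mean/min/max and the factor correlation
#' (single value for two factors). Values are carried unrounded; rounding
#' happens only in the print method.
#'
#' @param evaluations named list of `"subset_evaluation"` objects.
#' @return data frame of class `"comparison_report"`.
#' @export
comparison_report <- function(evaluations) {
  stopifnot(length(evaluations) >= 1, !is.null(names(evaluations)))
  rows <- lapply(names(evaluations), function(lab) {
    ev <- evaluations[[lab]]
    fit <- ev$fit
    if (is.null(fit))
      return(data.frame(scale = lab, n_items = length(ev$items),
                        stat = NA_real_, df = NA_integer_, cfi = NA_real_,
                        rmsea = NA_real_, phi_total = 0))
    row <- data.frame(scale = lab, n_items = length(fit$loadings),
                      stat = fit$stat_T, df = fit$df, cfi = fit$cfi,
                      rmsea = fit$rmsea,
                      phi_total = ev$components$phi_total)
    for (f in names(fit$omega_by_factor))
      row[[paste0("omega_", f)]] <- fit$omega_by_factor[[f]]
    ls <- loading_summary(fit)
    row$loading_mean <- ls[["mean"]]
    row$loading_min <- ls[["min"]]
    row$loading_max <- ls[["max"]]
    row$factor_corr <- if (nrow(fit$factor_corr) == 2)
      fit$factor_corr[1, 2] else NA_real_
    row
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' @export
print.comparison_report <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' @param report a [comparison_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
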