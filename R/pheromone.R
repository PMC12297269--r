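# The pheromone objective: sigmoid transforms of the optimization criteria.
# Each sigmoid is centred next to its criterion cut-off (CFI >= 0.96,
# RMSEA <= 0.06, omega >= 0.90, scale correlation >= 0.85, factor-correlation
# drift < 0.03) and maps the criterion onto (0, 1); the total pheromone is
# the sum of the four criterion components and lives in (0, 4).

#' Pheromone components
#'
#' @name pheromone
#' @rdname pheromone
NULL

#' @describeIn pheromone model-fit reward from the CFI:
#'   `1 / (1 + exp(95 - 100 cfi))`; 0.5 at CFI = 0.95.
#' @param cfi comparative fit index in `[0, 1]`.
#' @export
phi_cfi <- function(cfi) 1 / (1 + exp(95 - 100 * cfi))

#' @describeIn pheromone model-fit reward from the RMSEA:
#'   `1 - 1 / (1 + exp(5 - 100 rmsea))`; 0.5 at RMSEA = 0.05.
#' @param rmsea root mean square error of approximation, `>= 0`.
#' @export
phi_rmsea <- function(rmsea) 1 - 1 / (1 + exp(5 - 100 * rmsea))

#' @describeIn pheromone equally weighted model-fit pheromone:
#'   arithmetic mean of the CFI and RMSEA components.
#' @param cfi_component,rmsea_component values of [phi_cfi()] / [phi_rmsea()].
#' @export
phi_fit <- function(cfi_component, rmsea_component)
  (cfi_component + rmsea_component) / 2

#' @describeIn pheromone reliability reward from McDonald's omega:
#'   per factor `1 / (1 + exp(9 - 10 omega))` (0.5 at omega = 0.90),
#'   aggregated over factors by the arithmetic mean.
#' @param omegas numeric vector of per-factor omega values.
#' @export
phi_rel <- function(omegas) mean(1 / (1 + exp(9 - 10 * omegas)))

#' @describeIn pheromone full-versus-short sum-score correlation reward:
#'   `1 / (1 + exp(85 - 100 cor))` (0.5 at cor = 0.85) applied to the
#'   minimum correlation across factors, so every subscale must track its
#'   full-length counterpart.
#' @param correlations numeric vector of per-factor correlations in `[-1, 1]`.
#' @export
phi_corr <- function(correlations)
  1 / (1 + exp(85 - 100 * min(correlations)))

#' @describeIn pheromone factor-correlation preservation reward:
#'   `1 - 1 / (1 + exp(3 - 100 d))` where `d` is the maximum absolute
#'   difference between full-scale and short-scale factor correlations;
#'   0.5 at d = 0.03.
#' @param max_abs_diff maximum absolute factor-correlation difference, `>= 0`.
#' @export
phi_fc <- function(max_abs_diff) 1 - 1 / (1 + exp(3 - 100 * max_abs_diff))

#' Assemble the pheromone components of a candidate subset
#'
#' Computes the four criterion components (model fit, reliability, sum-score
#' correlation, factor-correlation preservation) and their sum. An infeasible
#' candidate (non-converged or Heywood CFA) receives `phi_total = 0` and `NA`
#' components, so it can never displace a feasible solution.
#'
#' @param cfi,rmsea model fit indices of the subset CFA.
#' @param omegas per-factor McDonald's omega values.
#' @param correlations per-factor correlations between short-form and
#'   full-form sum scores.
#' @param fc_diff maximum absolute difference between the subset's and the
#'   full pool's factor correlations (0 for a single factor).
#' @param feasible logical; `FALSE` marks a failed/inadmissible fit.
#' @param extra optional additional criterion component in `(0, 1)` added to
#'   the total (hook for user-defined criteria).
#' @return object of class `"pheromone_components"`: list with `phi_cfi`,
#'   `phi_rmsea`, `phi_fit`, `phi_rel`, `phi_corr`, `phi_fc`, `phi_total`.
#' @export
pheromone_components <- function(cfi, rmsea, omegas, correlations, fc_diff,
                                 feasible = TRUE, extra = NULL) {
  if (!feasible) {
    comp <- list(phi_cfi = NA_real_, phi_rmsea = NA_real_, phi_fit = NA_real_,
                 phi_rel = NA_real_, phi_corr = NA_real_, phi_fc = NA_real_,
                 phi_total = 0)
    return(structure(comp, class = "pheromone_components"))
  }
  pc <- phi_cfi(cfi)
  pr <- phi_rmsea(rmsea)
  comp <- list(phi_cfi = pc, phi_rmsea = pr, phi_fit = phi_fit(pc, pr),
               phi_rel = phi_rel(omegas), phi_corr = phi_corr(correlations),
               phi_fc = phi_fc(fc_diff))
  comp$phi_total <- comp$phi_fit + comp$phi_rel + comp$phi_corr + comp$phi_fc
  if (!is.null(extra)) {
    stopifnot(is.numeric(extra), length(extra) == 1, extra > 0, extra < 1)
    comp$phi_total <- comp$phi_total + extra
    comp$phi_extra <- extra
  }
  structure(comp, class = "pheromone_components")
}

#' @export
print.pheromone_components <- function(x, ...) {
  cat(sprintf(
    "pheromone: total = %.4f (fit %.4f | rel %.4f | corr %.4f | fc %.4f)\n",
    x$phi_total, x$phi_fit, x$phi_rel, x$phi_corr, x$phi_fc))
  invisible(x)
}
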