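# Simple-structure CFA fitted to a (polychoric) correlation matrix by
# minimizing the ML discrepancy F = log|Sigma| - log|S| + tr(S Sigma^-1) - p
# over standardized loadings and factor correlations, with residual variances
# fixed at 1 - lambda^2 (correlation-structure parameterization).

#' Degrees of freedom of a simple-structure correlation CFA
#'
#' `p(p-1)/2` unique correlations minus `p` loadings minus `q` free factor
#' correlations.
#'
#' @param p number of items (>= 3).
#' @param q number of free factor correlations (`F(F-1)/2` for F factors).
#' @return integer degrees of freedom.
#' @examples
#' model_df(26, 1)  # 298
#' model_df(10, 1)  # 34
#' @export
model_df <- function(p, q) {
  stopifnot(p >= 3, q >= 0)
  df <- p * (p - 1) / 2 - p - q
  if (df < 0) stop("under-identified model: negative degrees of freedom")
  as.integer(df)
}

#' CFI and RMSEA from test statistics
#'
#' `cfi = 1 - max(T - df, 0) / max(Tb - dfb, T - df, 0)` (1 when the
#' denominator is 0; 0 when the baseline fits better than the model), and
#' `rmsea = sqrt(max(T - df, 0) / (df * (N - 1)))`.
#'
#' @param stat_T model discrepancy test statistic.
#' @param df model degrees of freedom (> 0).
#' @param baseline_T,baseline_df independence-model statistic and df.
#' @param n_obs sample size N.
#' @return named list with `cfi` and `rmsea`.
#' @export
fit_indices <- function(stat_T, df, baseline_T, baseline_df, n_obs) {
  stopifnot(df > 0, baseline_df >= df, n_obs > 1)
  num <- max(stat_T - df, 0)
  den <- max(baseline_T - baseline_df, stat_T - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  rmsea <- sqrt(max(stat_T - df, 0) / (df * (n_obs - 1)))
  list(cfi = cfi, rmsea = rmsea)
}

#' McDonald's omega from standardized loadings
#'
#' Factor-saturation reliability of a unit-weighted sum score:
#' `omega = (sum lambda)^2 / ((sum lambda)^2 + sum(1 - lambda^2))`.
#'
#' @param loadings numeric vector of standardized loadings for one factor,
#'   all strictly inside `(-1, 1)`.
#' @return scalar omega in `[0, 1]`.
#' @examples
#' omega(c(0.77, 0.86, 0.87, 0.73, 0.68))
#' @export
omega <- function(loadings) {
  if (any(abs(loadings) >= 1))
    stop("omega undefined: |loading| >= 1 (Heywood case)")
  s <- sum(loadings)^2
  s / (s + sum(1 - loadings^2))
}

#' Fit a simple-structure CFA to a correlation matrix
#'
#' Each item loads on exactly one factor (its factor in `scale`); factor
#' correlations are free; residual variances are fixed at `1 - lambda^2`.
#' The maximum-likelihood discrepancy is minimized with bounded quasi-Newton
#' (analytic gradient), starting from loadings 0.7 and factor correlations
#' 0.5, with up to 3 jittered restarts on failure. The test statistic is
#' `(N - 1)` times the minimized discrepancy; the baseline model sets all
#' correlations to zero. Loadings at the `+/-0.999` bound raise the
#' `heywood` flag and the fit is treated as inadmissible downstream.
#'
#' @param corr correlation matrix (e.g. from [polychoric_matrix()]) whose
#'   dimnames cover the items of `scale`.
#' @param scale a [scale_definition()]; only its items are used, so pass a
#'   restricted definition (see [restrict_scale()]) to fit a subset.
#' @param n_obs sample size behind `corr`.
#' @return object of class `"cfa_fit"`: list with `loadings` (named),
#'   `factor_corr` (matrix), `stat_T`, `df`, `baseline_T`, `baseline_df`,
#'   `cfi`, `rmsea`, `omega_by_factor`, `converged`, `heywood`, `n_obs`.
#' @export
fit_cfa <- function(corr, scale, n_obs) {
  items <- scale$item_ids
  if (!all(items %in% rownames(corr)))
    stop("correlation matrix does not cover items: ",
         paste(setdiff(items, rownames(corr)), collapse = ", "))
  S <- corr[items, items, drop = FALSE]
  p <- length(items)
  factors <- names(scale$select_counts)
  nf <- length(factors)
  fidx <- match(scale$factor_of[items], factors)
  sizes <- tabulate(fidx, nf)
  if (any(sizes < 2L))
    stop("factor(s) with fewer than 2 items: ",
         paste(factors[sizes < 2L], collapse = ", "))
  if (any(sizes == 2L) && nf >= 2L)
    warning("factor(s) with only 2 items; identification anchored by the ",
            "remaining factors")
  if (any(sizes < 3L) && nf == 1L)
    stop("a single-factor model needs at least 3 items")
  q <- nf * (nf - 1L) / 2L
  df <- model_df(p, q)

  logdetS <- determinant(S, logarithm = TRUE)$modulus[1]
  low <- upper.tri(diag(nf))
  obj <- function(par) {
    lam <- par[seq_len(p)]
    Phi <- diag(nf); Phi[low] <- par[-seq_len(p)]; Phi <- Phi + t(Phi) - diag(nf)
    L <- matrix(0, p, nf); L[cbind(seq_len(p), fidx)] <- lam
    Sigma <- tcrossprod(L %*% Phi, L); diag(Sigma) <- 1
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(list(f = 1e8, gr = rep(0, length(par))))
    A <- chol2inv(ch)
    f <- 2 * sum(log(diag(ch))) - logdetS + sum(S * A) - p
    M <- A - A %*% S %*% A
    MLP <- M %*% L %*% Phi
    glam <- 2 * (MLP[cbind(seq_len(p), fidx)] - lam * diag(M))
    gphi <- if (q > 0) 2 * (t(L) %*% M %*% L)[low] else numeric(0)
    list(f = f, gr = c(glam, gphi))
  }
  fn <- function(par) obj(par)$f
  gr <- function(par) obj(par)$gr

  lower <- c(rep(-0.999, p), rep(-0.995, q))
  upper <- -lower
  start <- c(rep(0.7, p), rep(0.5, q))
  fit <- NULL
  for (attempt in 0:3) {
    par0 <- if (attempt == 0) start else
      pmin(pmax(start + stats::runif(length(start), -0.2, 0.2), lower), upper)
    res <- tryCatch(
      stats::optim(par0, fn, gr, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (!is.null(res) && res$convergence == 0) { fit <- res; break }
    if (!is.null(res) && (is.null(fit) || res$value < fit$value)) fit <- res
  }
  if (is.null(fit)) stop("CFA optimization failed to produce any solution")
  converged <- fit$convergence == 0

  lam <- fit$par[seq_len(p)]
  Phi <- diag(nf); Phi[low] <- fit$par[-seq_len(p)]
  Phi <- Phi + t(Phi) - diag(nf)
  # resolve sign indeterminacy: each factor's loading sum positive
  for (g in seq_len(nf)) {
    if (sum(lam[fidx == g]) < 0) {
      lam[fidx == g] <- -lam[fidx == g]
      Phi[g, -g] <- -Phi[g, -g]; Phi[-g, g] <- -Phi[-g, g]
    }
  }
  heywood <- any(abs(lam) >= 0.999 - 1e-8)
  lam <- pmin(pmax(lam, -0.999), 0.999)
  names(lam) <- items
  dimnames(Phi) <- list(factors, factors)

  stat_T <- max((n_obs - 1) * fit$value, 0)
  baseline_T <- max((n_obs - 1) * (-logdetS + sum(diag(S)) - p), 0)
  baseline_df <- p * (p - 1L) / 2L
  fi <- fit_indices(stat_T, df, baseline_T, baseline_df, n_obs)
  omegas <- if (heywood) stats::setNames(rep(NA_real_, nf), factors) else
    vapply(factors, function(f) omega(lam[scale$factor_of[items] == f]),
           numeric(1))
  structure(list(loadings = lam, factor_corr = Phi, stat_T = stat_T, df = df,
                 baseline_T = baseline_T, baseline_df = baseline_df,
                 cfi = fi$cfi, rmsea = fi$rmsea, omega_by_factor = omegas,
                 converged = converged, heywood = heywood, n_obs = n_obs),
            class = "cfa_fit")
}

#' Mean, minimum and maximum standardized loading
#'
#' @param fit a `"cfa_fit"` object, or a bare numeric vector of loadings.
#' @return named numeric vector `c(mean, min, max)`.
#' @export
loading_summary <- function(fit) {
  lam <- if (inherits(fit, "cfa_fit")) fit$loadings else as.numeric(fit)
  c(mean = mean(lam), min = min(lam), max = max(lam))
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("CFA fit: %d items, T = %.2f (df = %d), CFI = %.3f, RMSEA = %.3f\n",
              length(x$loadings), x$stat_T, x$df, x$cfi, x$rmsea))
  cat("omega:", paste(sprintf("%s = %.3f", names(x$omega_by_factor),
                              x$omega_by_factor), collapse = ", "), "\n")
  if (nrow(x$factor_corr) == 2)
    cat(sprintf("factor correlation: %.3f\n", x$factor_corr[1, 2]))
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  if (x$heywood) cat("WARNING: Heywood case (|loading| at bound)\n")
  invisible(x)
}
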