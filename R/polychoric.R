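# Polychoric correlation of ordinal Likert responses: two-step maximum
# likelihood (thresholds from marginal frequencies, rho by 1-D optimization
# of the bivariate-normal contingency likelihood with thresholds fixed).

#' Estimate latent-normal thresholds for one ordinal item
#'
#' Threshold k is the standard-normal quantile of the cumulative proportion of
#' responses in categories `<= k`. An interior cumulative proportion of 0 or 1
#' (an empty boundary run of categories) yields a `-Inf`/`Inf` sentinel with a
#' warning; downstream matrix estimation treats such items as degenerate.
#'
#' @param column integer vector of responses in `1..n_categories`.
#' @param n_categories number of response categories C (>= 2).
#' @return numeric vector of C-1 non-decreasing thresholds.
#' @examples
#' estimate_thresholds(rep(1:5, each = 20), 5)
#' @export
estimate_thresholds <- function(column, n_categories) {
  stopifnot(n_categories >= 2)
  column <- as.integer(column)
  if (anyNA(column) || any(column < 1L | column > n_categories))
    stop("responses must be integers in 1..", n_categories)
  counts <- tabulate(column, nbins = n_categories)
  cum <- cumsum(counts)[-n_categories] / length(column)
  th <- stats::qnorm(cum)
  if (any(!is.finite(th)))
    warning("degenerate column: some categories empty at the boundary; ",
            "infinite threshold sentinels returned")
  th
}

#' Polychoric correlation of two ordinal items
#'
#' Maximizes the bivariate-normal contingency-table likelihood over the latent
#' correlation, holding the item thresholds fixed at their univariate
#' estimates. The estimate is clipped to `[-0.999, 0.999]`.
#'
#' @param x,y integer response vectors of equal length, categories `1..C`.
#' @param tx,ty optional threshold vectors (defaults: estimated from `x`, `y`).
#' @param n_categories number of categories C; default inferred as
#'   `max(length(tx), length(ty)) + 1` when thresholds are given, else
#'   `max(x, y)`.
#' @return scalar correlation estimate in `[-0.999, 0.999]`.
#' @examples
#' set.seed(1)
#' z <- rnorm(500)
#' x <- findInterval(z, c(-1, 0, 1)) + 1
#' y <- findInterval(0.8 * z + 0.6 * rnorm(500), c(-1, 0, 1)) + 1
#' polychoric_pair(x, y, n_categories = 4)
#' @export
polychoric_pair <- function(x, y, tx = NULL, ty = NULL, n_categories = NULL) {
  stopifnot(length(x) == length(y))
  if (is.null(n_categories))
    n_categories <- if (!is.null(tx) || !is.null(ty))
      max(length(tx), length(ty)) + 1L else max(x, y)
  if (is.null(tx)) tx <- estimate_thresholds(x, n_categories)
  if (is.null(ty)) ty <- estimate_thresholds(y, n_categories)
  tab <- table(factor(x, levels = seq_len(n_categories)),
               factor(y, levels = seq_len(n_categories)))
  nll <- .polychoric_nll_factory(tab, tx, ty)
  opt <- stats::optimize(nll, interval = c(-0.999, 0.999), tol = 1e-6)
  rho <- opt$minimum
  # optimize() never lands exactly on a bound; snap when the bound is better
  for (b in c(-0.999, 0.999)) if (nll(b) < nll(rho)) rho <- b
  rho
}

# Negative log-likelihood of a CxC contingency table as a function of rho,
# cell probabilities via finite differences of the CDF on the threshold grid.
.polychoric_nll_factory <- function(tab, tx, ty) {
  cx <- length(tx) + 1L
  cy <- length(ty) + 1L
  gx <- c(-Inf, tx, Inf)
  gy <- c(-Inf, ty, Inf)
  hh <- rep(gx, times = cy + 1L)
  kk <- rep(gy, each = cx + 1L)
  tabv <- as.vector(tab)
  keep <- tabv > 0
  function(rho) {
    cdf <- matrix(pbvnorm(hh, kk, rho), nrow = cx + 1L)
    p <- cdf[-1, -1] - cdf[-(cx + 1L), -1] - cdf[-1, -(cy + 1L)] +
      cdf[-(cx + 1L), -(cy + 1L)]
    -sum(tabv[keep] * log(pmax(p[keep], 1e-12)))
  }
}

#' Polychoric correlation matrix
#'
#' All pairwise polychoric correlations of a response matrix, with optional
#' eigenvalue-clipping smoothing to restore positive definiteness: if the
#' smallest eigenvalue falls below `1e-8`, eigenvalues are clipped at `1e-8`
#' and the matrix is rescaled back to a unit diagonal. The
#' `"smoothing_applied"` attribute records whether smoothing was needed, so
#' callers can reject smoothed matrices.
#'
#' @param responses integer matrix (respondents x items) with column names;
#'   typically from [read_responses()] or [generate_responses()].
#' @param n_categories number of categories C (default: `attr(responses,
#'   "n_categories")`, falling back to `max(responses)`).
#' @return symmetric p x p correlation matrix with item-ID dimnames and
#'   attributes `smoothing_applied` (logical) and `thresholds` (list).
#' @export
polychoric_matrix <- function(responses, n_categories = NULL) {
  stopifnot(is.matrix(responses), !is.null(colnames(responses)))
  if (is.null(n_categories))
    n_categories <- attr(responses, "n_categories") %||% max(responses)
  p <- ncol(responses)
  items <- colnames(responses)
  thr <- lapply(seq_len(p), function(j)
    withCallingHandlers(
      estimate_thresholds(responses[, j], n_categories),
      warning = function(w) invokeRestart("muffleWarning")))
  names(thr) <- items
  bad <- vapply(thr, function(t) any(!is.finite(t)) || any(diff(t) <= 0),
                logical(1))
  # a column observed in a single category cannot enter a polychoric matrix
  deg <- vapply(seq_len(p), function(j)
    length(unique(responses[, j])) < 2L, logical(1))
  if (any(deg))
    stop("degenerate item(s): ", paste(items[deg], collapse = ", "),
         " (fewer than two observed categories)")
  r <- diag(p)
  for (i in seq_len(p - 1L)) {
    for (j in seq.int(i + 1L, p)) {
      r[i, j] <- r[j, i] <- polychoric_pair(
        responses[, i], responses[, j], thr[[i]], thr[[j]], n_categories)
    }
  }
  dimnames(r) <- list(items, items)
  r <- smooth_correlation(r)
  structure(r, thresholds = thr)
}

#' Eigenvalue-clipping smoothing of a correlation matrix
#'
#' If the smallest eigenvalue falls below `1e-8`, eigenvalues are clipped at
#' `1e-8` and the matrix rescaled to a unit diagonal; otherwise the input is
#' returned unchanged. The `"smoothing_applied"` attribute records which
#' branch was taken.
#'
#' @param r symmetric correlation matrix.
#' @return positive-definite correlation matrix with attribute
#'   `smoothing_applied`.
#' @export
smooth_correlation <- function(r) {
  dn <- dimnames(r)
  ev <- eigen(r, symmetric = TRUE)
  if (min(ev$values) >= 1e-8)
    return(structure(r, smoothing_applied = FALSE))
  vals <- pmax(ev$values, 1e-8)
  r <- ev$vectors %*% (vals * t(ev$vectors))
  d <- sqrt(diag(r))
  r <- r / tcrossprod(d)
  diag(r) <- 1
  r <- (r + t(r)) / 2
  dimnames(r) <- dn
  structure(r, smoothing_applied = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
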