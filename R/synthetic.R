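# Ordinal factor-model simulator: multivariate-normal factor scores, linear
# item model with standardized loadings, threshold discretization into
# Likert categories.

#' Specify an ordinal factor-model generator
#'
#' @param loadings named numeric vector of standardized loadings, one per
#'   item, all `|lambda| < 1`.
#' @param factor_of named character vector mapping each item ID to its factor.
#' @param factor_corr factor correlation matrix (unit diagonal, positive
#'   definite) with factor labels as dimnames; a scalar is accepted for two
#'   factors.
#' @param n_obs number of respondents to simulate.
#' @param seed integer seed; the generator is deterministic per seed.
#' @param thresholds per-item list of strictly increasing threshold vectors,
#'   or the name of a preset: `"quintile"` (equal-probability categories, the
#'   default) or `"skewed"` (mass concentrated in the low categories, as is
#'   typical of symptom/importance ratings).
#' @param n_categories number of Likert categories C (default 5).
#' @return object of class `"generator_spec"`.
#' @export
generator_spec <- function(loadings, factor_of, factor_corr, n_obs, seed,
                           thresholds = "quintile", n_categories = 5L) {
  stopifnot(!is.null(names(loadings)), all(abs(loadings) < 1),
            setequal(names(loadings), names(factor_of)), n_obs >= 1)
  items <- names(loadings)
  flabs <- unique(unname(factor_of[items]))
  if (is.matrix(factor_corr)) {
    Phi <- factor_corr
    if (is.null(dimnames(Phi))) dimnames(Phi) <- list(flabs, flabs)
  } else {
    stopifnot(length(flabs) == 2L, length(factor_corr) == 1L)
    Phi <- matrix(c(1, factor_corr, factor_corr, 1), 2,
                  dimnames = list(flabs, flabs))
  }
  stopifnot(all(diag(Phi) == 1), isSymmetric(unname(Phi)),
            min(eigen(Phi, symmetric = TRUE, only.values = TRUE)$values) > 0)
  n_categories <- as.integer(n_categories)
  if (is.character(thresholds))
    thresholds <- rep(list(likert_thresholds(n_categories, thresholds)),
                      length(items))
  if (is.null(names(thresholds))) names(thresholds) <- items
  stopifnot(setequal(names(thresholds), items),
            all(vapply(thresholds, function(t)
      length(t) == n_categories - 1L && all(diff(t) > 0), logical(1))))
  structure(list(loadings = loadings, factor_of = factor_of,
                 factor_corr = Phi, thresholds = thresholds[items],
                 n_obs = as.integer(n_obs), seed = as.integer(seed),
                 n_categories = n_categories),
            class = "generator_spec")
}

#' Threshold presets for Likert items
#'
#' `"quintile"` gives equal-probability categories; `"skewed"` concentrates
#' responses in the low categories (cumulative probabilities 0.45, 0.70,
#' 0.85, 0.95 for C = 5, interpolated for other C).
#'
#' @param n_categories number of categories C.
#' @param type `"quintile"` or `"skewed"`.
#' @return numeric vector of C-1 thresholds on the standard-normal scale.
#' @export
likert_thresholds <- function(n_categories, type = c("quintile", "skewed")) {
  type <- match.arg(type)
  k <- seq_len(n_categories - 1L)
  cum <- switch(type,
    quintile = k / n_categories,
    skewed = {
      base <- c(0.45, 0.70, 0.85, 0.95)
      if (n_categories == 5L) base else
        stats::approx(seq(0, 1, length.out = 5), c(0, base),
                      xout = k / n_categories)$y
    })
  stats::qnorm(cum)
}

#' Generate ordinal responses from a factor model
#'
#' Draws factor scores from `N(0, Phi)`, forms each latent item response
#' `y* = lambda f + sqrt(1 - lambda^2) e` with independent standard-normal
#' errors (items processed in item-ID order, factor scores drawn first, which
#' pins determinism), and discretizes by the item's thresholds into
#' categories `1..C`.
#'
#' @param spec a [generator_spec()].
#' @return integer response matrix (`n_obs` x items) with item-ID column
#'   names and an `n_categories` attribute, reproducible per seed.
#' @export
generate_responses <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  items <- names(spec$loadings)
  flabs <- rownames(spec$factor_corr)
  n <- spec$n_obs
  Z <- matrix(stats::rnorm(n * length(flabs)), n)
  Fsc <- Z %*% chol(spec$factor_corr)
  colnames(Fsc) <- flabs
  out <- matrix(0L, n, length(items), dimnames = list(NULL, items))
  for (it in items) {
    lam <- spec$loadings[[it]]
    y <- lam * Fsc[, spec$factor_of[[it]]] +
      sqrt(1 - lam^2) * stats::rnorm(n)
    out[, it] <- findInterval(y, spec$thresholds[[it]]) + 1L
  }
  structure(out, n_categories = spec$n_categories)
}

#' Scale definition matching a generator spec
#'
#' @param spec a [generator_spec()].
#' @param select named per-factor quota (default: the full pool per factor).
#' @return a [scale_definition()].
#' @export
scale_from_spec <- function(spec, select = NULL) {
  factors <- split(names(spec$factor_of), spec$factor_of)
  factors <- factors[rownames(spec$factor_corr)]
  if (is.null(select)) select <- stats::setNames(lengths(factors), names(factors))
  scale_definition(factors, select, spec$n_categories)
}

# Full-pool standardized loadings of the 26-item German ADBS (pros/cons
# decisional-balance pool): loadings span 0.25-0.94, factor correlation 0.56.
.adbs_loadings <- c(
  item01 = 0.83, item02 = 0.77, item03 = 0.79, item04 = 0.86, item05 = 0.82,
  item06 = 0.61, item07 = 0.83, item08 = 0.85, item09 = 0.71, item10 = 0.76,
  item11 = 0.70, item12 = 0.25, item13 = 0.31, item14 = 0.74, item15 = 0.78,
  item16 = 0.86, item17 = 0.69, item18 = 0.88, item19 = 0.94, item20 = 0.92,
  item21 = 0.74, item22 = 0.82, item23 = 0.70, item24 = 0.43, item25 = 0.55,
  item26 = 0.56)
.adbs_factor_of <- c(
  item01 = "pros", item02 = "pros", item03 = "cons", item04 = "pros",
  item05 = "cons", item06 = "cons", item07 = "pros", item08 = "cons",
  item09 = "pros", item10 = "cons", item11 = "cons", item12 = "cons",
  item13 = "cons", item14 = "pros", item15 = "cons", item16 = "pros",
  item17 = "pros", item18 = "cons", item19 = "pros", item20 = "pros",
  item21 = "cons", item22 = "pros", item23 = "pros", item24 = "cons",
  item25 = "cons", item26 = "pros")

#' ADBS-like two-factor generator spec
#'
#' A 26-item pool (13 pros, 13 cons of drinking) on a 5-point scale with the
#' loading profile reported for the full German Alcohol Decisional Balance
#' Scale (loadings 0.25 to 0.94, mean 0.72) and a pros-cons factor
#' correlation of 0.56. Default sample size 1834 matches the scale's
#' validation sample.
#'
#' @param n_obs number of respondents (default 1834).
#' @param seed integer seed.
#' @param thresholds threshold preset or list, see [generator_spec()].
#' @return a [generator_spec()].
#' @export
adbs_like_spec <- function(n_obs = 1834, seed = 1, thresholds = "quintile") {
  generator_spec(.adbs_loadings, .adbs_factor_of, factor_corr = 0.56,
                 n_obs = n_obs, seed = seed, thresholds = thresholds)
}

#' Generator spec with a planted optimal subset
#'
#' Gives `quota` items per factor a high loading and the remaining items a
#' low loading, so that at large N the high-loading subset is the known best
#' solution of the pheromone objective; used as a search oracle fixture.
#'
#' @param pool_sizes integer vector of per-factor pool sizes (names become
#'   factor labels; defaults `f1`, `f2`, ...).
#' @param quota per-factor number of planted (high-loading) items.
#' @param lambda_high,lambda_low loadings of planted and filler items.
#' @param n_obs number of respondents.
#' @param seed integer seed.
#' @param factor_corr factor correlation (scalar for two factors) or matrix.
#' @return a [generator_spec()] with attribute `"planted"` (character vector
#'   of the planted item IDs) and `"quota"` (named per-factor quota).
#' @export
planted_optimum_spec <- function(pool_sizes = c(f1 = 6, f2 = 6),
                                 quota = c(f1 = 3, f2 = 3),
                                 lambda_high = 0.9, lambda_low = 0.3,
                                 n_obs = 500, seed = 1, factor_corr = 0.5) {
  if (is.null(names(pool_sizes)))
    names(pool_sizes) <- paste0("f", seq_along(pool_sizes))
  quota <- quota[names(pool_sizes)]
  stopifnot(all(quota >= 1), all(quota <= pool_sizes))
  loadings <- c(); factor_of <- c(); planted <- character()
  for (f in names(pool_sizes)) {
    ids <- sprintf("%s_i%02d", f, seq_len(pool_sizes[[f]]))
    lam <- rep(lambda_low, pool_sizes[[f]])
    lam[seq_len(quota[[f]])] <- lambda_high
    planted <- c(planted, ids[seq_len(quota[[f]])])
    loadings <- c(loadings, stats::setNames(lam, ids))
    factor_of <- c(factor_of, stats::setNames(rep(f, length(ids)), ids))
  }
  Phi <- if (is.matrix(factor_corr)) factor_corr else {
    nf <- length(pool_sizes)
    m <- matrix(factor_corr, nf, nf,
                dimnames = list(names(pool_sizes), names(pool_sizes)))
    diag(m) <- 1
    m
  }
  spec <- generator_spec(loadings, factor_of, Phi, n_obs = n_obs, seed = seed)
  attr(spec, "planted") <- planted
  attr(spec, "quota") <- quota
  spec
}
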