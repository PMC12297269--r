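# Scale definitions: item pool, factor membership, per-factor selection quota.

#' Define a multi-factor scale and its selection quotas
#'
#' @param factors named list mapping each factor label to the character vector
#'   of item IDs assigned to it. Every item belongs to exactly one factor.
#' @param select named integer vector/list: how many items to select per
#'   factor (`1 <= select[f] <=` pool size of `f`).
#' @param n_categories number of Likert response categories C (default 5).
#' @return object of class `"scale_definition"`: list with `item_ids`
#'   (ordered as listed), `factor_of` (named character), `select_counts`
#'   (named integer) and `n_categories`.
#' @examples
#' scale_definition(
#'   factors = list(pros = c("p1", "p2", "p3"), cons = c("c1", "c2", "c3")),
#'   select = c(pros = 2, cons = 2))
#' @export
scale_definition <- function(factors, select, n_categories = 5L) {
  stopifnot(is.list(factors), length(factors) >= 1, !is.null(names(factors)))
  factors <- lapply(factors, as.character)
  items <- unlist(factors, use.names = FALSE)
  if (anyDuplicated(items))
    stop("item(s) assigned to more than one factor: ",
         paste(unique(items[duplicated(items)]), collapse = ", "))
  select <- unlist(select)
  if (!setequal(names(select), names(factors)))
    stop("'select' must name exactly the factors of the pool")
  select <- as.integer(select[names(factors)])
  names(select) <- names(factors)
  pool <- lengths(factors)
  if (any(select < 1L) || any(select > pool))
    stop("selection quota out of range for factor(s): ",
         paste(names(factors)[select < 1L | select > pool], collapse = ", "))
  if (length(factors) == 1L && select[[1L]] < 3L)
    stop("a single-factor short form needs a quota of at least 3 items")
  n_categories <- as.integer(n_categories)
  stopifnot(n_categories >= 2L)
  factor_of <- stats::setNames(
    rep(names(factors), pool), items)
  structure(list(item_ids = items, factor_of = factor_of,
                 select_counts = select, n_categories = n_categories,
                 factors = factors),
            class = "scale_definition")
}

#' Restrict a scale definition to an item subset
#'
#' Keeps only the given items, sets each factor's quota to the number of
#' surviving items, and drops emptied factors. Used to fit a CFA to a
#' candidate short form.
#'
#' @param scale a [scale_definition()].
#' @param items character vector of item IDs (subset of the pool).
#' @return a new `"scale_definition"`.
#' @export
restrict_scale <- function(scale, items) {
  stopifnot(inherits(scale, "scale_definition"))
  unknown <- setdiff(items, scale$item_ids)
  if (length(unknown))
    stop("items not in the pool: ", paste(unknown, collapse = ", "))
  kept <- lapply(scale$factors, function(f) f[f %in% items])
  kept <- kept[lengths(kept) > 0]
  scale_definition(kept, stats::setNames(lengths(kept), names(kept)),
                   scale$n_categories)
}

#' Read a scale definition from YAML or JSON
#'
#' The file must contain `factors` (map: factor label -> list of item IDs)
#' and `select` (map: factor label -> count); `n_categories` is optional
#' (default 5). Format is chosen by extension (`.json` vs `.yaml`/`.yml`).
#'
#' @param path file path.
#' @return a [scale_definition()].
#' @export
read_scale_definition <- function(path) {
  if (!file.exists(path)) stop("scale definition file not found: ", path)
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE) else
    yaml::read_yaml(path)
  if (is.null(spec$factors) || is.null(spec$select))
    stop("scale definition must contain 'factors' and 'select'")
  scale_definition(spec$factors, spec$select,
                   spec$n_categories %||% 5L)
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("Scale: %d items, %d factor(s), %d categories\n",
              length(x$item_ids), length(x$factors), x$n_categories))
  for (f in names(x$factors))
    cat(sprintf("  %s: %d items, select %d\n", f, length(x$factors[[f]]),
                x$select_counts[[f]]))
  invisible(x)
}
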