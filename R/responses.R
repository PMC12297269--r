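# Reading and validating Likert response matrices.

#' Read a Likert response matrix from CSV
#'
#' The CSV must have a header row of item IDs and one respondent per row.
#' Columns are re-aligned to the order of the scale definition (surplus
#' columns are ignored). Rows containing any missing, non-integer or
#' out-of-range value are removed (listwise deletion) and the count of
#' dropped rows is reported via `message()` and stored in the `"n_dropped"`
#' attribute.
#'
#' @param path CSV file path.
#' @param scale a [scale_definition()]; supplies the item set, column order
#'   and the valid category range `1..n_categories`.
#' @return integer matrix (respondents x items) with item-ID column names and
#'   attributes `n_dropped` and `n_categories`.
#' @export
read_responses <- function(path, scale) {
  stopifnot(inherits(scale, "scale_definition"))
  if (!file.exists(path)) stop("response file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(scale$item_ids, names(raw))
  if (length(missing_cols))
    stop("response file lacks column(s): ", paste(missing_cols, collapse = ", "))
  raw <- raw[, scale$item_ids, drop = FALSE]
  m <- suppressWarnings(vapply(raw, function(col) as.numeric(as.character(col)),
                               numeric(nrow(raw))))
  if (nrow(raw) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(raw)))
  C <- scale$n_categories
  ok <- rowSums(is.na(m) | m < 1 | m > C | m != round(m)) == 0
  dropped <- sum(!ok)
  if (dropped > 0)
    message(dropped, " row(s) dropped by listwise deletion")
  m <- m[ok, , drop = FALSE]
  if (nrow(m) == 0L) stop("no complete rows left after listwise deletion")
  storage.mode(m) <- "integer"
  colnames(m) <- scale$item_ids
  structure(m, n_dropped = dropped, n_categories = C)
}

#' Write a response matrix to CSV
#'
#' @param responses integer response matrix with item-ID column names.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(as.data.frame(responses), path, row.names = FALSE)
  invisible(path)
}
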