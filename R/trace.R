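# JSON-lines traces of ACO iterations.

#' Write an iteration trace as JSON lines
#'
#' One JSON object per iteration with fields `iteration`,
#' `iteration_best_phi`, `best_so_far_phi` and `items`. An empty record list
#' produces an empty file.
#'
#' @param records list of per-iteration records (as found in an
#'   [run_aco()] result's `$trace`).
#' @param path output file path.
#' @param append append to an existing file instead of overwriting.
#' @return `path`, invisibly.
#' @export
write_trace <- function(records, path, append = FALSE) {
  con <- tryCatch(file(path, open = if (append) "a" else "w"),
                  error = function(e) stop("cannot open trace path: ", path))
  on.exit(close(con))
  for (rec in records) {
    writeLines(jsonlite::toJSON(
      list(iteration = rec$iteration,
           iteration_best_phi = rec$iteration_best_phi,
           best_so_far_phi = rec$best_so_far_phi,
           items = as.list(rec$items)),
      auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read a JSON-lines iteration trace
#'
#' @param path trace file written by [write_trace()].
#' @return list of records with the same fields, field-for-field equal to
#'   what was written.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  lines <- readLines(path)
  lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    rec$items <- as.character(unlist(rec$items))
    rec
  })
}
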