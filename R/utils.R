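# Internal helpers: classed errors, seeded evaluation, TSV I/O.

kf_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "kf_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

kf_validation_error   <- function(msg, ...) kf_stop("kf_validation_error", msg, ...)
kf_lookup_error       <- function(msg, ...) kf_stop("kf_lookup_error", msg, ...)
kf_construction_error <- function(msg, ...) kf_stop("kf_construction_error", msg, ...)
kf_placement_error    <- function(msg, ...) kf_stop("kf_placement_error", msg, ...)
kf_io_error           <- function(msg, ...) kf_stop("kf_io_error", msg, ...)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`,
#' restoring the previous RNG state afterwards so callers never leak global
#' random state. All stochastic functions in the package take explicit seeds
#' and route through this helper.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    kf_validation_error("seed must be a single number, got %s", deparse(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

#' Write a measurement table to TSV
#'
#' @param table A measurement table (see [generate_measurement_table()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(table, path) {
  cols <- c("chromosome_id", "pair_index", "long_arm", "short_arm", "unit")
  missing <- setdiff(cols, names(table))
  if (length(missing))
    kf_validation_error("measurement table lacks columns: %s",
                        paste(missing, collapse = ", "))
  utils::write.table(table[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a measurement table from TSV
#'
#' @param path TSV with columns chromosome_id, pair_index, long_arm,
#'   short_arm, unit.
#' @return A `data.frame` measurement table.
#' @export
read_measurement_table <- function(path) {
  if (!file.exists(path)) kf_io_error("no such file: %s", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  validate_measurement_table(tab)
  tab
}

validate_measurement_table <- function(table) {
  cols <- c("chromosome_id", "long_arm", "short_arm")
  missing <- setdiff(cols, names(table))
  if (length(missing))
    kf_validation_error("measurement table lacks columns: %s",
                        paste(missing, collapse = ", "))
  if (nrow(table) == 0) return(invisible(table))
  if (any(!is.finite(table$long_arm)) || any(!is.finite(table$short_arm)) ||
      any(table$long_arm <= 0) || any(table$short_arm <= 0))
    kf_validation_error("invariant violated: all arm lengths strictly positive")
  if (anyDuplicated(table$chromosome_id))
    kf_validation_error("invariant violated: chromosome ids unique")
  invisible(table)
}
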