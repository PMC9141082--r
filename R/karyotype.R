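# Karyotype analytics: Levan centromere classes, relative lengths, karyotype
# formula, interchromosomal (longest/shortest) ratio and Stebbins cytotype.

#' Per-chromosome arm ratio
#'
#' The Levan arm ratio of one chromosome: long arm over short arm,
#' orientation-invariant (arguments may be swapped), always >= 1.
#'
#' @param long_arm,short_arm Arm lengths (same unit, > 0). Vectorized.
#' @return Numeric ratio(s) >= 1.
#' @examples
#' arm_ratio(3, 1)  # 3
#' arm_ratio(1, 3)  # 3
#' @export
arm_ratio <- function(long_arm, short_arm) {
  if (any(!is.finite(long_arm)) || any(!is.finite(short_arm)) ||
      any(long_arm <= 0) || any(short_arm <= 0))
    kf_validation_error("arm lengths must be positive and finite")
  pmax(long_arm, short_arm) / pmin(long_arm, short_arm)
}

#' Levan centromere classification
#'
#' Maps an arm ratio to the Levan centromere-position class using the
#' conventional bands: metacentric (m) for ratios up to 1.70, submetacentric
#' (sm) up to 3.00, subtelocentric (st) up to 7.00, telocentric (t) above.
#' Band boundaries are inclusive toward the more symmetric class, so a ratio
#' of exactly 1.70 is metacentric.
#'
#' @param ratio Arm ratio(s) >= 1 (see [arm_ratio()]).
#' @return Factor-free character vector in `c("m", "sm", "st", "t")`.
#' @examples
#' classify_levan(c(1.3, 2.2, 4.0, 8.0))  # "m" "sm" "st" "t"
#' classify_levan(1.70)                   # "m" (boundary)
#' @export
classify_levan <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio < 1))
    kf_validation_error("arm ratio must be >= 1")
  cls <- character(length(ratio))
  cls[ratio <= 1.70] <- "m"
  cls[ratio > 1.70 & ratio <= 3.00] <- "sm"
  cls[ratio > 3.00 & ratio <= 7.00] <- "st"
  cls[ratio > 7.00] <- "t"
  cls
}

#' Relative chromosome lengths
#'
#' Each chromosome's total length as a percentage of the whole diploid
#' complement's summed length; values sum to 100.
#'
#' @param table Measurement table with `long_arm`, `short_arm`.
#' @return Numeric vector of percentages, one per row.
#' @export
relative_lengths <- function(table) {
  if (is.null(table) || nrow(table) == 0)
    kf_validation_error("relative_lengths requires a non-empty table")
  tot <- table$long_arm + table$short_arm
  100 * tot / sum(tot)
}

#' Augment a measurement table with derived descriptors
#'
#' Adds `total_length`, `arm_ratio`, `levan_class`, and `relative_length`
#' columns.
#'
#' @param table Measurement table.
#' @return The table with derived columns appended.
#' @export
karyotype_descriptors <- function(table) {
  validate_measurement_table(table)
  if (nrow(table) == 0) kf_validation_error("empty measurement table")
  table$total_length <- table$long_arm + table$short_arm
  table$arm_ratio <- arm_ratio(table$long_arm, table$short_arm)
  table$levan_class <- classify_levan(table$arm_ratio)
  table$relative_length <- relative_lengths(table)
  table
}

#' Order a measurement table from longest to shortest chromosome
#'
#' Rows are sorted by strictly non-increasing total length; ties are broken
#' by ascending arm ratio and then by chromosome id, making the ordering
#' deterministic and idempotent.
#'
#' @param table Measurement table.
#' @return The reordered table (with derived descriptors).
#' @export
order_by_length <- function(table) {
  if (nrow(table) == 0) return(table)
  tab <- karyotype_descriptors(table)
  ord <- order(-tab$total_length, tab$arm_ratio, tab$chromosome_id)
  out <- tab[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair homologous chromosomes
#'
#' Sorts the complement by length and pairs adjacent chromosomes, the
#' standard diploid karyogram arrangement. When a `signals` data frame is
#' supplied (columns `chromosome_id`, `channel`, and optionally `category`),
#' adjacent candidates whose lengths agree within `length_tol` (relative)
#' are locally re-paired to maximize signal-pattern agreement within pairs.
#'
#' @param table Measurement table with an even number of rows.
#' @param signals Optional detected-signal table used to refine ambiguous
#'   pairings.
#' @param length_tol Relative length tolerance within which chromosomes are
#'   considered exchangeable candidates (default 0.05).
#' @return The ordered table with a `pair_index` column; each index appears
#'   exactly twice.
#' @export
pair_homologs <- function(table, signals = NULL, length_tol = 0.05) {
  if (nrow(table) %% 2 != 0)
    kf_validation_error(
      "diploid complement expected: even row count, got %d", nrow(table))
  tab <- order_by_length(table)
  n <- nrow(tab)
  tab$pair_index <- rep(seq_len(n / 2), each = 2)
  if (is.null(signals) || n < 4) return(tab)

  sig_key <- function(id) {
    s <- signals[signals$chromosome_id == id, , drop = FALSE]
    if (nrow(s) == 0) return("")
    parts <- s$channel
    if (!is.null(s$category)) parts <- paste(parts, s$category, sep = ":")
    paste(sort(parts), collapse = ",")
  }
  keys <- vapply(tab$chromosome_id, sig_key, "")
  # local swap pass: for consecutive quadruples of near-equal length, choose
  # the pairing with more within-pair signal agreement
  agree <- function(i, j) as.integer(keys[i] == keys[j])
  for (p in seq_len(n / 2 - 1)) {
    i <- 2 * p - 1
    lens <- tab$total_length[i:(i + 3)]
    if ((max(lens) - min(lens)) / max(lens) > length_tol) next
    base <- agree(i, i + 1) + agree(i + 2, i + 3)
    sw13 <- agree(i, i + 2) + agree(i + 1, i + 3)
    sw14 <- agree(i, i + 3) + agree(i + 1, i + 2)
    best <- which.max(c(base, sw13, sw14))
    if (best == 2) tab[c(i + 1, i + 2), ] <- tab[c(i + 2, i + 1), ]
    if (best == 3) tab[c(i + 1, i + 3), ] <- tab[c(i + 3, i + 1), ]
    keys <- vapply(tab$chromosome_id, sig_key, "")
  }
  tab$pair_index <- rep(seq_len(n / 2), each = 2)
  rownames(tab) <- NULL
  tab
}

#' Karyotype formula string
#'
#' Builds the conventional formula, e.g. `"2n = 2x = 14m + 12sm + 2st"`,
#' listing Levan classes in the fixed order m, sm, st, t and omitting
#' zero counts.
#'
#' @param table Measurement table (classes computed if absent).
#' @param ploidy Ploidy level x (default 2).
#' @return A list with `formula_string`, `class_counts`, `two_n`.
#' @export
karyotype_formula <- function(table, ploidy = 2) {
  tab <- karyotype_descriptors(table)
  counts <- vapply(CLASS_ORDER,
                   function(k) sum(tab$levan_class == k), integer(1))
  counts <- counts[counts > 0]
  list(
    formula_string = sprintf("2n = %dx = %s", ploidy,
                             paste(sprintf("%d%s", counts, names(counts)),
                                   collapse = " + ")),
    class_counts = counts,
    two_n = nrow(tab)
  )
}

#' Interchromosomal (longest/shortest) length ratio
#'
#' Ratio of the longest chromosome's total length to the shortest's; the
#' quantity driving the Stebbins asymmetry column.
#'
#' @param table Measurement table.
#' @return A single number >= 1.
#' @export
interchromosomal_ratio <- function(table) {
  if (is.null(table) || nrow(table) == 0)
    kf_validation_error("interchromosomal_ratio requires a non-empty table")
  tot <- table$long_arm + table$short_arm
  max(tot) / min(tot)
}

#' Stebbins asymmetry cytotype
#'
#' Two-way Stebbins (1971) category. The column is set by the
#' longest/shortest chromosome ratio: A below 2, B from 2 to 4 (inclusive),
#' C above 4. The row is set by the proportion `p` of chromosomes whose arm
#' ratio exceeds 2: row 1 for `p = 0`, row 2 for `0 < p <= 0.5`, row 3 for
#' `0.5 < p < 1`, row 4 for `p = 1`. A proportion of exactly one half stays
#' in row 2 and a length ratio of exactly 2 stays in column B.
#'
#' @param table Measurement table.
#' @return List with `stebbins_row` (integer), `stebbins_col` (character),
#'   `cytotype` (their concatenation, e.g. `"2B"`), `ls_ratio`, and
#'   `prop_ratio_gt2`.
#' @export
stebbins_cytotype <- function(table) {
  tab <- karyotype_descriptors(table)
  ls <- interchromosomal_ratio(tab)
  col <- if (ls < 2) "A" else if (ls <= 4) "B" else "C"
  p <- mean(tab$arm_ratio > 2)
  row <- if (p == 0) 1L else if (p <= 0.5) 2L else if (p < 1) 3L else 4L
  list(stebbins_row = row, stebbins_col = col,
       cytotype = paste0(row, col), ls_ratio = ls, prop_ratio_gt2 = p)
}

#' Full karyotype analysis of a measurement table
#'
#' Convenience wrapper combining [karyotype_formula()],
#' [interchromosomal_ratio()] and [stebbins_cytotype()] into one
#' `karyotype_result`.
#'
#' @param table Measurement table.
#' @param species_id Label carried into the result (defaults to the table's
#'   `species_id` attribute).
#' @param ploidy Ploidy level x.
#' @return A list of class `karyotype_result` with fields `species_id`,
#'   `formula_string`, `class_counts`, `ls_ratio`, `stebbins_row`,
#'   `stebbins_col`, `cytotype`.
#' @export
analyze_karyotype <- function(table, species_id = NULL, ploidy = 2) {
  if (is.null(species_id))
    species_id <- attr(table, "species_id") %||% "unknown"
  form <- karyotype_formula(table, ploidy)
  steb <- stebbins_cytotype(table)
  structure(list(
    species_id = species_id,
    formula_string = form$formula_string,
    class_counts = form$class_counts,
    two_n = form$two_n,
    ls_ratio = steb$ls_ratio,
    stebbins_row = steb$stebbins_row,
    stebbins_col = steb$stebbins_col,
    cytotype = steb$cytotype
  ), class = "karyotype_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.karyotype_result <- function(x, ...) {
  cat(sprintf("<karyotype_result> %s\n  %s   cytotype %s   longest/shortest %.4f\n",
              x$species_id, x$formula_string, x$cytotype, x$ls_ratio))
  invisible(x)
}
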