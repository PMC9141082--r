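#' Packaged species identifiers
#'
#' The five Fabaceae taxa whose karyotype and 5S rDNA signal patterns ship
#' with the package as ground-truth fixtures: three *Robinia pseudoacacia*
#' taxa (the type, the cultivar 'idaho', and f. *decaisneana*),
#' *Styphnolobium japonicum*, and *Amorpha fruticosa*.
#'
#' @return Character vector of species ids accepted by
#'   [load_species_fixture()].
#' @export
species_ids <- function() {
  c("robinia_pseudoacacia",
    "robinia_pseudoacacia_idaho",
    "robinia_pseudoacacia_decaisneana",
    "styphnolobium_japonicum",
    "amorpha_fruticosa")
}

#' Load a karyotype fixture
#'
#' A karyotype fixture encodes one species' ground truth: diploid chromosome
#' number `two_n`, Levan class counts (the karyotype formula), the
#' longest/shortest chromosome length ratio `ls_ratio`, the expected Stebbins
#' cytotype, a haploid length-decay model, representative within-class arm
#' ratios, and the 5S rDNA signal assignments per homolog pair.
#'
#' @param species_id One of [species_ids()], or a path to a user fixture
#'   JSON file with the same schema.
#' @return A list of class `karyotype_fixture`, validated against the
#'   fixture invariants.
#' @examples
#' fx <- load_species_fixture("robinia_pseudoacacia")
#' fx$two_n            # 22
#' fx$class_counts     # m = 20, sm = 2
#' @export
load_species_fixture <- function(species_id) {
  if (!is.character(species_id) || length(species_id) != 1)
    kf_validation_error("species_id must be a single string")
  if (species_id %in% species_ids()) {
    path <- system.file("extdata", "fixtures",
                        paste0(species_id, ".json"), package = "karyofish")
  } else if (file.exists(species_id)) {
    path <- species_id
  } else {
    kf_lookup_error(
      "unknown species_id '%s'; packaged ids: %s",
      species_id, paste(species_ids(), collapse = ", "))
  }
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  fx <- structure(raw, class = "karyotype_fixture")
  fx$class_counts <- unlist(fx$class_counts)
  validate_fixture(fx)
  fx
}

#' Validate a karyotype fixture
#'
#' Checks the fixture invariants and raises a validation error naming the
#' first violated invariant.
#'
#' @param fx A `karyotype_fixture`.
#' @return `fx`, invisibly, if valid.
#' @export
validate_fixture <- function(fx) {
  need <- c("species_id", "two_n", "ploidy", "class_counts", "ls_ratio",
            "signal_pairs", "length_profile")
  missing <- setdiff(need, names(fx))
  if (length(missing))
    kf_validation_error("fixture lacks fields: %s",
                        paste(missing, collapse = ", "))
  cc <- unlist(fx$class_counts)
  if (sum(cc) != fx$two_n)
    kf_validation_error(
      "invariant violated: sum of class_counts (%d) != two_n (%d)",
      sum(cc), fx$two_n)
  if (fx$two_n %% 2 != 0)
    kf_validation_error("invariant violated: two_n must be even, got %d",
                        fx$two_n)
  if (fx$two_n %% fx$ploidy != 0)
    kf_validation_error(
      "invariant violated: two_n / ploidy must be an integer (%d / %d)",
      fx$two_n, fx$ploidy)
  if (fx$ls_ratio < 1)
    kf_validation_error("invariant violated: ls_ratio >= 1, got %g",
                        fx$ls_ratio)
  unknown <- setdiff(names(cc), c("m", "sm", "st", "t"))
  if (length(unknown))
    kf_validation_error("unknown Levan classes in class_counts: %s",
                        paste(unknown, collapse = ", "))
  n_pairs <- fx$two_n / 2
  for (sp in fx$signal_pairs) {
    if (sp$pair_index < 1 || sp$pair_index > n_pairs)
      kf_validation_error(
        "invariant violated: signal pair_index %d outside [1, %d]",
        sp$pair_index, n_pairs)
    if (sp$position_fraction < 0 || sp$position_fraction > 1)
      kf_validation_error(
        "invariant violated: position_fraction %g outside [0, 1]",
        sp$position_fraction)
    if (!sp$channel %in% c("FAM", "TAMRA"))
      kf_validation_error("unknown channel '%s'", sp$channel)
    if (!sp$zygosity %in% c("both-homologs", "one-homolog"))
      kf_validation_error("unknown zygosity '%s'", sp$zygosity)
  }
  # one-homolog entries only legal as strong/weak heteromorphic pairs
  oh <- Filter(function(sp) identical(sp$zygosity, "one-homolog"),
               fx$signal_pairs)
  if (length(oh)) {
    key <- vapply(oh, function(sp)
      paste(sp$pair_index, sp$channel, sep = "/"), "")
    for (k in unique(key)) {
      ints <- vapply(oh[key == k], `[[`, "", "intensity")
      if (length(unique(ints)) < 2)
        kf_validation_error(
          "invariant violated: one-homolog assignments on pair %s must differ in intensity between homologs",
          k)
    }
  }
  invisible(fx)
}

#' @export
print.karyotype_fixture <- function(x, ...) {
  cc <- x$class_counts
  cat(sprintf("<karyotype_fixture> %s (%s)\n", x$species_id, x$species_name))
  cat(sprintf("  2n = %d (%dx); %s; longest/shortest = %.4f\n",
              x$two_n, x$ploidy,
              paste(sprintf("%d%s", cc, names(cc)), collapse = " + "),
              x$ls_ratio))
  cat(sprintf("  5S assignments: %d entries on %d homolog pair(s)\n",
              length(x$signal_pairs),
              length(unique(vapply(x$signal_pairs, `[[`, 1, "pair_index")))))
  invisible(x)
}
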