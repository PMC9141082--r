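# Synthetic measurement tables: the deterministic karyotype geometry plus a
# multiplicative measurement-noise model.

DEFAULT_CLASS_ARM_RATIO <- c(m = 1.3, sm = 2.2, st = 4.0, t = 8.0)
CLASS_ORDER <- c("m", "sm", "st", "t")

#' Generate a chromosome measurement table from a karyotype fixture
#'
#' Builds the diploid complement implied by a fixture: `two_n / 2` homolog
#' pairs whose haploid total lengths follow a geometric decay from the
#' longest chromosome down to the shortest, with the decay rate fixed so the
#' longest/shortest ratio equals `fixture$ls_ratio` exactly. Within a pair
#' the two homologs are identical (at `noise_cv = 0`). Each pair carries the
#' arm ratio representative of its Levan class (fixture field
#' `arm_ratio_by_class`), so classifying the noise-free table reproduces the
#' fixture's class counts exactly. Pairs are assigned classes longest-first
#' in the order m, sm, st, t.
#'
#' Measurement noise is an independent multiplicative Gaussian perturbation
#' per arm, `arm * (1 + noise_cv * z)` with `z` standard normal truncated at
#' three standard deviations (keeping lengths positive for any
#' `noise_cv < 1/3`).
#'
#' @param fixture A `karyotype_fixture` (see [load_species_fixture()]).
#' @param seed Integer seed for the noise draws; ignored when
#'   `noise_cv = 0`, in which case the table is fully deterministic.
#' @param noise_cv Coefficient of variation of the per-arm noise
#'   (dimensionless, >= 0).
#' @return A `data.frame` with columns `chromosome_id`, `pair_index`,
#'   `long_arm`, `short_arm`, `unit` (micrometres), plus attributes
#'   `species_id` and `provenance = "fixture-generated"`.
#' @examples
#' fx <- load_species_fixture("styphnolobium_japonicum")
#' tab <- generate_measurement_table(fx, seed = 1, noise_cv = 0)
#' nrow(tab)  # 28
#' @export
generate_measurement_table <- function(fixture, seed = 1L, noise_cv = 0) {
  validate_fixture(fixture)
  if (!is.numeric(noise_cv) || length(noise_cv) != 1 || is.na(noise_cv) ||
      noise_cv < 0)
    kf_validation_error("noise_cv must be a single non-negative number")

  two_n <- fixture$two_n
  n_pairs <- two_n / 2
  cc <- fixture$class_counts
  if (any(cc %% 2 != 0))
    kf_construction_error(
      "class_counts must be even per class (homolog pairs share a class)")
  if (n_pairs == 1 && abs(fixture$ls_ratio - 1) > 1e-12)
    kf_construction_error(
      "single homolog pair is incompatible with ls_ratio %g != 1",
      fixture$ls_ratio)

  longest <- fixture$length_profile$longest_um
  if (is.null(longest)) longest <- 4.0
  # geometric decay: lengths[1] / lengths[n_pairs] == ls_ratio exactly
  lengths <- if (n_pairs == 1) longest else
    longest * fixture$ls_ratio^(-(seq_len(n_pairs) - 1) / (n_pairs - 1))

  ratios <- DEFAULT_CLASS_ARM_RATIO
  if (!is.null(fixture$arm_ratio_by_class)) {
    ov <- unlist(fixture$arm_ratio_by_class)
    ratios[names(ov)] <- ov
  }
  pair_class <- rep(CLASS_ORDER,
                    times = ifelse(CLASS_ORDER %in% names(cc),
                                   cc[CLASS_ORDER] / 2, 0))
  pair_ratio <- ratios[pair_class]
  if (any(pair_ratio < 1) || any(!is.finite(pair_ratio)))
    kf_construction_error("within-class arm ratios must be finite and >= 1")

  long0  <- lengths * pair_ratio / (1 + pair_ratio)
  short0 <- lengths / (1 + pair_ratio)

  idx <- rep(seq_len(n_pairs), each = 2)
  hom <- rep(c("a", "b"), n_pairs)
  long_arm  <- long0[idx]
  short_arm <- short0[idx]

  if (noise_cv > 0) {
    rtrunc3 <- function(n) {
      z <- stats::rnorm(n)
      bad <- abs(z) > 3
      while (any(bad)) {
        z[bad] <- stats::rnorm(sum(bad))
        bad <- abs(z) > 3
      }
      z
    }
    perturb <- with_seed(seed, matrix(rtrunc3(2L * two_n), ncol = 2))
    long_arm  <- long_arm  * (1 + noise_cv * perturb[, 1])
    short_arm <- short_arm * (1 + noise_cv * perturb[, 2])
    # noise can invert the generated arm orientation; keep long >= short
    lo <- pmax(long_arm, short_arm)
    sh <- pmin(long_arm, short_arm)
    long_arm <- lo
    short_arm <- sh
  }

  tab <- data.frame(
    chromosome_id = sprintf("chr%02d%s", idx, hom),
    pair_index = idx,
    long_arm = long_arm,
    short_arm = short_arm,
    unit = "um",
    stringsAsFactors = FALSE
  )
  attr(tab, "species_id") <- fixture$species_id
  attr(tab, "provenance") <- "fixture-generated"
  attr(tab, "true_class") <- pair_class[idx]
  validate_measurement_table(tab)
  tab
}
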