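# Species-level 5S rDNA signal profiles, their pseudometric, and phenetic
# clustering of the five taxa.

POSITION_CATEGORIES <- c("centromeric", "interstitial",
                         "proximal-telomeric", "telomeric")

#' Map an arm position fraction to a position category
#'
#' Positions are fractions of arm length measured from the centromere toward
#' the telomere. Thresholds: centromeric up to 0.15; interstitial up to
#' 0.70 (exclusive); proximal-telomeric up to 0.90 (exclusive); telomeric
#' from 0.90.
#'
#' @param position_fraction Numeric in `[0, 1]`. Vectorized.
#' @return Character vector over
#'   `c("centromeric", "interstitial", "proximal-telomeric", "telomeric")`.
#' @examples
#' position_category(c(0, 0.3, 0.8, 0.95))
#' @export
position_category <- function(position_fraction) {
  if (any(!is.finite(position_fraction)) ||
      any(position_fraction < 0) || any(position_fraction > 1))
    kf_validation_error("position_fraction must lie in [0, 1]")
  out <- character(length(position_fraction))
  out[position_fraction <= 0.15] <- "centromeric"
  out[position_fraction > 0.15 & position_fraction < 0.70] <- "interstitial"
  out[position_fraction >= 0.70 & position_fraction < 0.90] <- "proximal-telomeric"
  out[position_fraction >= 0.90] <- "telomeric"
  out
}

#' Construct a signal profile
#'
#' @param species_id Label.
#' @param n_pairs_5S Number of 5S-bearing homolog pairs.
#' @param category_counts Named counts of 5S sites per position category
#'   (missing categories filled with zero).
#' @param heteromorphic_pairs Number of pairs with one strong and one weak
#'   homolog signal.
#' @return A list of class `signal_profile`.
#' @export
signal_profile <- function(species_id, n_pairs_5S, category_counts,
                           heteromorphic_pairs = 0L) {
  cc <- stats::setNames(integer(length(POSITION_CATEGORIES)),
                        POSITION_CATEGORIES)
  if (length(category_counts)) {
    unknown <- setdiff(names(category_counts), POSITION_CATEGORIES)
    if (length(unknown))
      kf_validation_error("unknown position categories: %s",
                          paste(unknown, collapse = ", "))
    cc[names(category_counts)] <- as.integer(category_counts)
  }
  if (any(cc < 0) || n_pairs_5S < 0 || heteromorphic_pairs < 0)
    kf_validation_error("signal profile counts must be non-negative")
  if (sum(cc) < n_pairs_5S)
    kf_validation_error(
      "invariant violated: total site count (%d) < n_pairs_5S (%d)",
      sum(cc), n_pairs_5S)
  structure(list(species_id = species_id,
                 n_pairs_5S = as.integer(n_pairs_5S),
                 category_counts = cc,
                 heteromorphic_pairs = as.integer(heteromorphic_pairs)),
            class = "signal_profile")
}

#' Signal profile straight from a karyotype fixture
#'
#' Encodes the fixture's 5S assignments without rendering or measuring any
#' image: pairs are counted once each; sites are counted per bearing
#' homolog (two for both-homolog assignments, one per one-homolog entry);
#' heteromorphic pairs are pairs carrying one-homolog entries of differing
#' intensity.
#'
#' @param fixture A `karyotype_fixture`.
#' @return A `signal_profile`.
#' @export
fixture_signal_profile <- function(fixture) {
  validate_fixture(fixture)
  sp <- Filter(function(s) identical(s$channel, "TAMRA"), fixture$signal_pairs)
  if (!length(sp))
    return(signal_profile(fixture$species_id, 0L, integer(0), 0L))
  pair_idx <- vapply(sp, `[[`, 1, "pair_index")
  zyg <- vapply(sp, `[[`, "", "zygosity")
  cats <- position_category(vapply(sp, `[[`, 1, "position_fraction"))
  mult <- ifelse(zyg == "both-homologs", 2L, 1L)
  cc <- tapply(mult, cats, sum)
  het <- length(unique(pair_idx[zyg == "one-homolog"]))
  signal_profile(fixture$species_id,
                 n_pairs_5S = length(unique(pair_idx)),
                 category_counts = cc,
                 heteromorphic_pairs = het)
}

#' Signal profile from measured chromosomes and detected sites
#'
#' The image-analysis route to a species profile: homolog pairs come from
#' [pair_homologs()]; a pair bears 5S if at least one homolog carries a
#' TAMRA site; each bearing homolog contributes its sites to the category
#' counts; a pair is heteromorphic when one homolog's sites are all strong
#' and the other's all weak.
#'
#' @param table Measurement table (even row count).
#' @param sites Data frame of detected sites with columns `chromosome_id`,
#'   `channel`, `position_fraction` (or `category`), `intensity`.
#' @param species_id Label for the profile.
#' @return A `signal_profile`.
#' @export
encode_signal_profile <- function(table, sites, species_id = NULL) {
  if (is.null(species_id))
    species_id <- attr(table, "species_id") %||% "unknown"
  tam <- sites[sites$channel == "TAMRA", , drop = FALSE]
  if (nrow(tam) == 0)
    return(signal_profile(species_id, 0L, integer(0), 0L))
  unknown <- setdiff(tam$chromosome_id, table$chromosome_id)
  if (length(unknown))
    kf_validation_error("sites reference unknown chromosomes: %s",
                        paste(unknown, collapse = ", "))
  paired <- pair_homologs(table, signals = tam)
  tam$pair <- paired$pair_index[match(tam$chromosome_id,
                                      paired$chromosome_id)]
  if (is.null(tam$category))
    tam$category <- position_category(tam$position_fraction)

  bearing_pairs <- unique(tam$pair)
  cc <- table(factor(tam$category, levels = POSITION_CATEGORIES))
  het <- 0L
  for (p in bearing_pairs) {
    homs <- paired$chromosome_id[paired$pair_index == p]
    ints <- lapply(homs, function(h) tam$intensity[tam$chromosome_id == h])
    if (all(lengths(ints) > 0) &&
        ((all(ints[[1]] == "strong") && all(ints[[2]] == "weak")) ||
         (all(ints[[1]] == "weak") && all(ints[[2]] == "strong"))))
      het <- het + 1L
  }
  signal_profile(species_id, length(bearing_pairs), c(cc), het)
}

#' Dissimilarity between two signal profiles
#'
#' A weighted L1 pseudometric on profile summaries:
#' `d = w_n |dn| + w_c L1(category counts) + w_h |dh|`, where `dn` is the
#' difference in 5S-bearing pair counts, the middle term sums absolute
#' per-category site-count differences, and `dh` is the difference in
#' heteromorphic pair counts. Symmetric, zero exactly on identical
#' profiles, and triangle-inequality compliant (it is a weighted L1 norm on
#' concatenated count vectors).
#'
#' @param p,q `signal_profile` objects.
#' @param weights Named numeric vector `c(w_n, w_c, w_h)`, all >= 0.
#' @return Non-negative number.
#' @export
profile_dissimilarity <- function(p, q,
                                  weights = c(w_n = 1.0, w_c = 0.5,
                                              w_h = 0.25)) {
  if (any(weights < 0) || any(!is.finite(weights)))
    kf_validation_error("dissimilarity weights must be non-negative")
  w <- c(w_n = 1.0, w_c = 0.5, w_h = 0.25)
  w[names(weights)] <- weights
  cats <- union(names(p$category_counts), names(q$category_counts))
  pc <- stats::setNames(numeric(length(cats)), cats)
  qc <- pc
  pc[names(p$category_counts)] <- p$category_counts
  qc[names(q$category_counts)] <- q$category_counts
  unname(w["w_n"] * abs(p$n_pairs_5S - q$n_pairs_5S) +
         w["w_c"] * sum(abs(pc - qc)) +
         w["w_h"] * abs(p$heteromorphic_pairs - q$heteromorphic_pairs))
}

#' Pairwise dissimilarity matrix over signal profiles
#'
#' @param profiles List of `signal_profile` objects.
#' @param weights Passed to [profile_dissimilarity()].
#' @return Symmetric matrix with species ids as dimnames.
#' @export
dissimilarity_matrix <- function(profiles,
                                 weights = c(w_n = 1.0, w_c = 0.5,
                                             w_h = 0.25)) {
  n <- length(profiles)
  ids <- vapply(profiles, `[[`, "", "species_id")
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- profile_dissimilarity(profiles[[i]], profiles[[j]], weights)
  D
}

#' Agglomerative clustering of signal profiles
#'
#' Standard hierarchical clustering (single or average linkage) on the
#' profile dissimilarity matrix, with deterministic handling of ties
#' (profiles keep their input order). The result is a phenetic similarity
#' dendrogram over signal patterns, not a phylogeny estimate.
#'
#' @param profiles List of at least two `signal_profile` objects.
#' @param linkage `"average"` (default) or `"single"`.
#' @param weights Passed to [profile_dissimilarity()].
#' @param newick_path Optional path; when given, the tree is written in
#'   Newick format with branch lengths derived from merge heights.
#' @return A list of class `signal_dendrogram` with elements `hclust` (the
#'   merge tree), `dist` (the matrix), `phylo` (an [ape::as.phylo()] tree),
#'   and `join_order` (for each species, the index of the merge at which it
#'   first enters a cluster).
#' @export
cluster_profiles <- function(profiles, linkage = c("average", "single"),
                             weights = c(w_n = 1.0, w_c = 0.5, w_h = 0.25),
                             newick_path = NULL) {
  linkage <- match.arg(linkage)
  if (length(profiles) < 2)
    kf_validation_error("clustering requires at least 2 profiles")
  D <- dissimilarity_matrix(profiles, weights)
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  if (any(diff(hc$height) < -1e-9))
    kf_construction_error("merge heights must be non-decreasing")
  phy <- ape::as.phylo(hc)
  join <- vapply(seq_along(hc$labels), function(i) {
    which(apply(hc$merge == -i, 1, any))[1]
  }, numeric(1))
  names(join) <- hc$labels
  if (!is.null(newick_path))
    ape::write.tree(phy, file = newick_path)
  structure(list(hclust = hc, dist = D, phylo = phy, join_order = join,
                 linkage = linkage, weights = weights),
            class = "signal_dendrogram")
}

#' Leaf membership of every merge in a dendrogram
#'
#' @param hc An `hclust` object.
#' @return List of character vectors: the leaf labels united at each merge.
#' @export
merge_members <- function(hc) {
  members <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    grab <- function(v) if (v < 0) hc$labels[-v] else members[[v]]
    members[[k]] <- sort(c(grab(hc$merge[k, 1]), grab(hc$merge[k, 2])))
  }
  members
}

#' @export
print.signal_dendrogram <- function(x, ...) {
  cat(sprintf("<signal_dendrogram> %d taxa, %s linkage\n",
              length(x$hclust$labels), x$linkage))
  mm <- merge_members(x$hclust)
  for (k in seq_along(mm))
    cat(sprintf("  merge %d @ %.3f: {%s}\n", k, x$hclust$height[k],
                paste(mm[[k]], collapse = ", ")))
  invisible(x)
}
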