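# Shared helpers: seeded spread rendering and a minimal toy fixture builder.

render_species <- function(species_id, seed = 3L, noise_cv = 0,
                           params = render_params()) {
  fx <- load_species_fixture(species_id)
  tab <- generate_measurement_table(fx, seed = seed, noise_cv = noise_cv)
  img <- render_metaphase_image(tab, fx$signal_pairs, seed = seed,
                                params = params)
  list(fixture = fx, table = tab, image = img)
}

measured_spread <- function(img) {
  masks <- segment_chromosomes(img)
  ms <- measure_spread(masks, img$pixel_size)
  sites <- detect_signals(img, masks, measurements = ms$measurements)
  list(masks = masks, measurements = ms$measurements, table = ms$table,
       sites = sites)
}

toy_fixture <- function(two_n = 2, class_counts = c(m = 2), ls_ratio = 1,
                        arm_ratio_by_class = list(m = 1.0),
                        signal_pairs = list()) {
  structure(list(
    species_id = "toy", species_name = "toy",
    two_n = two_n, ploidy = 2,
    class_counts = unlist(class_counts), ls_ratio = ls_ratio,
    expected_cytotype = NA,
    length_profile = list(model = "geometric", longest_um = 3.0),
    arm_ratio_by_class = arm_ratio_by_class,
    signal_pairs = signal_pairs
  ), class = "karyotype_fixture")
}

# match segmented masks to ground-truth chromosomes by nearest centroid
match_masks_to_truth <- function(masks, img) {
  gt <- img$ground_truth$chromosomes
  gtc <- t(vapply(gt, function(g) unname(g$centroid), numeric(2)))
  cent <- t(vapply(masks, `[[`, numeric(2), "centroid"))
  vapply(seq_along(masks), function(i)
    which.min((gtc[, 1] - cent[i, 1])^2 + (gtc[, 2] - cent[i, 2])^2),
    integer(1))
}

random_profile <- function(id) {
  cats <- c("centromeric", "interstitial", "proximal-telomeric", "telomeric")
  cc <- stats::setNames(sample(0:4, 4, replace = TRUE), cats)
  n <- sample(0:min(4, sum(cc)), 1)
  signal_profile(id, n, cc, heteromorphic_pairs = sample(0:2, 1))
}
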