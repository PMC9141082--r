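test_that("an empty TAMRA channel yields zero TAMRA sites", {
  fx <- toy_fixture(two_n = 4, class_counts = c(m = 4), ls_ratio = 1.2)
  tab <- generate_measurement_table(fx, noise_cv = 0)
  img <- render_metaphase_image(tab, NULL, seed = 2)  # no 5S assignments
  masks <- segment_chromosomes(img)
  sites <- detect_signals(img, masks)
  expect_equal(sum(sites$channel == "TAMRA"), 0)
})

test_that("a requested absent channel is an error naming the channel", {
  img <- render_metaphase_image(NULL, NULL, seed = 1)
  img$channels$TAMRA <- NULL
  expect_error(detect_signals(img, list(), channels = "TAMRA"), "TAMRA",
               class = "kf_validation_error")
})

test_that("detected TAMRA-bearing chromosomes match the published counts", {
  expected <- c(robinia_pseudoacacia = 8, robinia_pseudoacacia_idaho = 6,
                robinia_pseudoacacia_decaisneana = 8,
                styphnolobium_japonicum = 2, amorpha_fruticosa = 4)
  for (spid in names(expected)) {
    sp <- render_species(spid, seed = 5)
    masks <- segment_chromosomes(sp$image)
    sites <- detect_signals(sp$image, masks)
    bearing <- unique(sites$chromosome_id[sites$channel == "TAMRA"])
    expect_equal(length(bearing), unname(expected[spid]), label = spid)
  }
})

test_that("every chromosome carries exactly two detected FAM sites", {
  sp <- render_species("amorpha_fruticosa", seed = 7)
  masks <- segment_chromosomes(sp$image)
  sites <- detect_signals(sp$image, masks)
  fam <- table(sites$chromosome_id[sites$channel == "FAM"])
  expect_equal(length(fam), length(masks))
  expect_true(all(fam == 2))
  expect_equal(nrow(attr(sites, "unassigned")), 0)
})

test_that("the heteromorphic weak signal is classed weak by the intensity rule", {
  sp <- render_species("robinia_pseudoacacia_idaho", seed = 4)
  masks <- segment_chromosomes(sp$image)
  sites <- detect_signals(sp$image, masks)
  tam <- sites[sites$channel == "TAMRA", ]
  expect_equal(sum(tam$intensity == "weak"), 1)
  expect_equal(sum(tam$intensity == "strong"), 5)
})

test_that("signal positions project to the correct arm categories", {
  sp <- render_species("robinia_pseudoacacia", seed = 6)
  m <- measured_spread(sp$image)
  tam <- m$sites[m$sites$channel == "TAMRA", ]
  # fixture: 1 centromeric pair, 2 telomeric pairs, 1 proximal-telomeric
  got <- sort(table(tam$category), decreasing = TRUE)
  expect_equal(sum(tam$category %in% c("telomeric", "proximal-telomeric")), 6)
  expect_equal(sum(tam$category == "centromeric"), 2)
  # telomere positions are well-defined where the centromere is interior;
  # on the stubbiest chromosomes (near-terminal constriction) the arm split
  # itself is ill-posed, so restrict to chromosomes >= 1.8 um
  fam <- m$sites[m$sites$channel == "FAM", ]
  tot <- m$table$long_arm + m$table$short_arm
  long_enough <- m$table$chromosome_id[tot >= 1.8]
  fam_le <- fam[fam$chromosome_id %in% long_enough, ]
  expect_gte(nrow(fam_le), 24)
  expect_true(all(fam_le$category %in% c("telomeric", "proximal-telomeric")))
  expect_true(all(fam$position_fraction >= 0.5))
})

test_that("position categories follow the documented thresholds", {
  expect_equal(position_category(0), "centromeric")
  expect_equal(position_category(0.15), "centromeric")
  expect_equal(position_category(0.30), "interstitial")
  expect_equal(position_category(0.80), "proximal-telomeric")
  expect_equal(position_category(0.90), "telomeric")
  expect_equal(position_category(0.95), "telomeric")
  expect_error(position_category(1.2), class = "kf_validation_error")
  expect_equal(locate_signal_on_arm(list(position_fraction = 0.95)),
               "telomeric")
  expect_equal(locate_signal_on_arm(list(position_fraction = 0.0)),
               "centromeric")
  expect_error(locate_signal_on_arm(list(position_fraction = NA)),
               class = "kf_validation_error")
})
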