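test_that("noise-free tables are deterministic and reproduce fixture geometry", {
  for (sp in species_ids()) {
    fx <- load_species_fixture(sp)
    t1 <- generate_measurement_table(fx, seed = 1, noise_cv = 0)
    t2 <- generate_measurement_table(fx, seed = 99, noise_cv = 0)
    expect_identical(t1, t2)  # seed-independent at zero noise
    expect_equal(nrow(t1), fx$two_n)
    # homologs of a pair identical
    a <- t1[seq(1, nrow(t1), 2), c("long_arm", "short_arm")]
    b <- t1[seq(2, nrow(t1), 2), c("long_arm", "short_arm")]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b)
    # longest/shortest total-length ratio equals ls_ratio to 1e-9
    expect_equal(interchromosomal_ratio(t1), fx$ls_ratio, tolerance = 1e-9)
    # Levan classification reproduces class_counts exactly (round trip)
    cls <- classify_levan(arm_ratio(t1$long_arm, t1$short_arm))
    got <- table(cls)
    expect_equal(c(got[names(fx$class_counts)]),
                 stats::setNames(as.integer(fx$class_counts),
                                 names(fx$class_counts)))
  }
})

test_that("S. japonicum classification agrees with a direct threshold oracle", {
  fx <- load_species_fixture("styphnolobium_japonicum")
  tab <- generate_measurement_table(fx, noise_cv = 0)
  r <- pmax(tab$long_arm, tab$short_arm) / pmin(tab$long_arm, tab$short_arm)
  oracle <- ifelse(r <= 1.70, "m",
                   ifelse(r <= 3.00, "sm", ifelse(r <= 7.00, "st", "t")))
  expect_identical(classify_levan(r), oracle)
  expect_equal(sum(oracle == "m"), 14)
  expect_equal(sum(oracle == "sm"), 12)
  expect_equal(sum(oracle == "st"), 2)
})

test_that("a single metacentric pair yields two identical chromosomes with ratio 1", {
  fx <- toy_fixture(two_n = 2, class_counts = c(m = 2), ls_ratio = 1,
                    arm_ratio_by_class = list(m = 1.0))
  tab <- generate_measurement_table(fx, noise_cv = 0)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$long_arm[1], tab$long_arm[2])
  expect_equal(arm_ratio(tab$long_arm, tab$short_arm), c(1, 1))
})

test_that("infeasible fixture constraints raise construction errors", {
  expect_error(
    generate_measurement_table(
      toy_fixture(two_n = 2, class_counts = c(m = 2), ls_ratio = 1.5)),
    class = "kf_construction_error")
  expect_error(
    generate_measurement_table(
      toy_fixture(two_n = 4, class_counts = c(m = 3, sm = 1),
                  ls_ratio = 1.2)),
    class = "kf_construction_error")
  expect_error(
    generate_measurement_table(load_species_fixture("amorpha_fruticosa"),
                               noise_cv = -0.1),
    class = "kf_validation_error")
})

test_that("measurement noise is seeded, truncated, and perturbs per arm", {
  fx <- load_species_fixture("robinia_pseudoacacia")
  n1 <- generate_measurement_table(fx, seed = 5, noise_cv = 0.05)
  n2 <- generate_measurement_table(fx, seed = 5, noise_cv = 0.05)
  n3 <- generate_measurement_table(fx, seed = 6, noise_cv = 0.05)
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
  base <- generate_measurement_table(fx, noise_cv = 0)
  expect_false(any(n1$long_arm == base$long_arm))
  # +-3 SD truncation bounds every arm
  expect_true(all(abs(n1$long_arm / base$long_arm - 1) <= 0.15 + 1e-12))
  # even extreme noise keeps arms positive
  big <- generate_measurement_table(fx, seed = 2, noise_cv = 0.3)
  expect_true(all(big$long_arm > 0 & big$short_arm > 0))
})

test_that("measurement tables round-trip through TSV", {
  fx <- load_species_fixture("styphnolobium_japonicum")
  tab <- generate_measurement_table(fx, noise_cv = 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_measurement_table(tab, path)
  back <- read_measurement_table(path)
  expect_equal(back$chromosome_id, tab$chromosome_id)
  expect_equal(back$long_arm, tab$long_arm, tolerance = 1e-12)
})
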