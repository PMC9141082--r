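test_that("arm_ratio is orientation-invariant and validates input", {
  expect_equal(arm_ratio(2.0, 2.0), 1.0)
  expect_equal(arm_ratio(3.0, 1.0), 3.0)
  expect_equal(arm_ratio(1.0, 3.0), 3.0)
  expect_error(arm_ratio(0, 1), class = "kf_validation_error")
  expect_error(arm_ratio(1, -2), class = "kf_validation_error")
})

test_that("Levan classification follows the band boundaries", {
  expect_identical(classify_levan(c(1, 1.3, 1.70, 1.7000001, 2.2, 3.00,
                                    3.0001, 7.00, 7.01)),
                   c("m", "m", "m", "sm", "sm", "sm", "st", "st", "t"))
  expect_error(classify_levan(0.9), class = "kf_validation_error")
})

test_that("Levan classification is monotone in the arm ratio", {
  set.seed(42)
  r <- sort(runif(200, 1, 10))
  cls <- classify_levan(r)
  rank <- match(cls, c("m", "sm", "st", "t"))
  expect_true(all(diff(rank) >= 0))
})

test_that("relative lengths are normalized percentages", {
  t2 <- data.frame(chromosome_id = c("a", "b"), long_arm = c(1, 1),
                   short_arm = c(1, 1))
  expect_equal(relative_lengths(t2), c(50, 50))
  t3 <- data.frame(chromosome_id = c("a", "b"), long_arm = c(2, 0.6),
                   short_arm = c(1, 0.4))
  expect_equal(relative_lengths(t3), c(75, 25))
  set.seed(7)
  for (i in 1:5) {
    n <- sample(4:40, 1)
    tr <- data.frame(chromosome_id = as.character(seq_len(n)),
                     long_arm = runif(n, 0.5, 3),
                     short_arm = runif(n, 0.2, 2))
    expect_equal(sum(relative_lengths(tr)), 100, tolerance = 1e-6)
  }
  expect_error(relative_lengths(t3[0, ]), class = "kf_validation_error")
})

test_that("length ordering is longest-first, deterministic, and idempotent", {
  tab <- data.frame(chromosome_id = c("a", "b", "c"),
                    long_arm = c(0.6, 2, 1.2), short_arm = c(0.4, 1, 0.8))
  ord <- order_by_length(tab)
  expect_equal(ord$total_length, c(3, 2, 1))
  expect_identical(order_by_length(ord)[, names(ord)], ord)
  # ties broken by arm ratio then id
  ties <- data.frame(chromosome_id = c("z", "y", "x"),
                     long_arm = c(1.5, 1.2, 1.2),
                     short_arm = c(0.5, 0.8, 0.8))
  o2 <- order_by_length(ties)
  expect_equal(o2$chromosome_id, c("x", "y", "z"))
})

test_that("homolog pairing recovers the generator's pairs for all fixtures", {
  for (sp in species_ids()) {
    tab <- generate_measurement_table(load_species_fixture(sp),
                                      noise_cv = 0)
    paired <- pair_homologs(tab)
    expect_true(all(table(paired$pair_index) == 2))
    # compare partitions (within-pair order is arbitrary for identical homologs)
    truth <- split(tab$chromosome_id, tab$pair_index)
    got <- split(paired$chromosome_id, paired$pair_index)
    expect_setequal(
      unname(vapply(got, function(x) paste(sort(x), collapse = "|"), "")),
      unname(vapply(truth, function(x) paste(sort(x), collapse = "|"), "")))
  }
})

test_that("pairing rejects odd complements and handles a single pair", {
  tab <- data.frame(chromosome_id = c("a", "b", "c"),
                    long_arm = c(1, 1, 1), short_arm = c(1, 1, 1))
  expect_error(pair_homologs(tab), "diploid",
               class = "kf_validation_error")
  two <- data.frame(chromosome_id = c("a", "b"), long_arm = c(1, 1),
                    short_arm = c(0.9, 0.9))
  expect_equal(pair_homologs(two)$pair_index, c(1, 1))
})

test_that("karyotype formulas match the published strings", {
  af <- generate_measurement_table(load_species_fixture("amorpha_fruticosa"),
                                   noise_cv = 0)
  expect_equal(karyotype_formula(af)$formula_string, "2n = 2x = 38m + 2sm")
  sj <- generate_measurement_table(
    load_species_fixture("styphnolobium_japonicum"), noise_cv = 0)
  expect_equal(karyotype_formula(sj)$formula_string,
               "2n = 2x = 14m + 12sm + 2st")
  toy <- generate_measurement_table(
    toy_fixture(two_n = 2, class_counts = c(m = 2), ls_ratio = 1,
                arm_ratio_by_class = list(m = 1.0)), noise_cv = 0)
  expect_equal(karyotype_formula(toy)$formula_string, "2n = 2x = 2m")
})

test_that("interchromosomal ratio matches the published Arm Ratio column", {
  ida <- generate_measurement_table(
    load_species_fixture("robinia_pseudoacacia_idaho"), noise_cv = 0)
  expect_equal(interchromosomal_ratio(ida), 1.8997, tolerance = 1e-9)
  rp <- generate_measurement_table(
    load_species_fixture("robinia_pseudoacacia"), noise_cv = 0)
  expect_equal(interchromosomal_ratio(rp), 3.4821, tolerance = 1e-9)
  eq <- data.frame(chromosome_id = c("a", "b"), long_arm = c(1, 1),
                   short_arm = c(1, 1))
  expect_equal(interchromosomal_ratio(eq), 1.0)
  expect_error(interchromosomal_ratio(eq[0, ]),
               class = "kf_validation_error")
})

test_that("Stebbins cytotype handles published and boundary cases", {
  ida <- generate_measurement_table(
    load_species_fixture("robinia_pseudoacacia_idaho"), noise_cv = 0)
  expect_equal(stebbins_cytotype(ida)$cytotype, "1A")
  sj <- generate_measurement_table(
    load_species_fixture("styphnolobium_japonicum"), noise_cv = 0)
  ssj <- stebbins_cytotype(sj)
  expect_equal(ssj$cytotype, "2B")
  expect_equal(ssj$prop_ratio_gt2, 0.5)  # 14/28 borderline stays row 2
  toy <- data.frame(chromosome_id = c("a", "b"), long_arm = c(1, 1),
                    short_arm = c(1, 1))
  expect_equal(stebbins_cytotype(toy)$cytotype, "1A")
  # longest/shortest exactly 2 stays column B
  edge <- data.frame(chromosome_id = c("a", "b"), long_arm = c(1.0, 0.5),
                     short_arm = c(1.0, 0.5))
  expect_equal(stebbins_cytotype(edge)$stebbins_col, "B")
})

test_that("all descriptors are invariant under a global length rescaling", {
  set.seed(11)
  for (sp in c("robinia_pseudoacacia", "styphnolobium_japonicum")) {
    tab <- generate_measurement_table(load_species_fixture(sp),
                                      seed = 4, noise_cv = 0.03)
    for (scale in c(0.1, 3.7)) {
      sc <- tab
      sc$long_arm <- sc$long_arm * scale
      sc$short_arm <- sc$short_arm * scale
      expect_equal(arm_ratio(sc$long_arm, sc$short_arm),
                   arm_ratio(tab$long_arm, tab$short_arm))
      expect_equal(relative_lengths(sc), relative_lengths(tab))
      expect_equal(interchromosomal_ratio(sc), interchromosomal_ratio(tab))
      r1 <- analyze_karyotype(sc); r0 <- analyze_karyotype(tab)
      expect_equal(r1$formula_string, r0$formula_string)
      expect_equal(r1$cytotype, r0$cytotype)
    }
  }
})

test_that("formula and cytotype are robust to 2% measurement noise", {
  # threshold (>= 8 of 10 replicates) is a test parameter, not a claim of
  # the underlying study
  for (sp in species_ids()) {
    fx <- load_species_fixture(sp)
    expect_r <- analyze_karyotype(generate_measurement_table(fx, noise_cv = 0))
    hits <- 0
    for (s in 1:10) {
      r <- analyze_karyotype(generate_measurement_table(fx, seed = s,
                                                        noise_cv = 0.02))
      if (r$formula_string == expect_r$formula_string &&
          r$cytotype == expect_r$cytotype) hits <- hits + 1
    }
    expect_gte(hits, 8)
  }
})
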