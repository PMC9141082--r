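test_that("fixture signal profiles encode the published 5S pair counts", {
  rp <- fixture_signal_profile(load_species_fixture("robinia_pseudoacacia"))
  expect_equal(rp$n_pairs_5S, 4)
  expect_equal(rp$heteromorphic_pairs, 0)
  ida <- fixture_signal_profile(
    load_species_fixture("robinia_pseudoacacia_idaho"))
  expect_equal(ida$n_pairs_5S, 3)
  expect_equal(ida$heteromorphic_pairs, 1)
  sj <- fixture_signal_profile(
    load_species_fixture("styphnolobium_japonicum"))
  expect_equal(sj$n_pairs_5S, 1)
  af <- fixture_signal_profile(load_species_fixture("amorpha_fruticosa"))
  expect_equal(af$n_pairs_5S, 2)
  expect_equal(unname(af$category_counts["centromeric"]), 4L)
  expect_equal(sum(af$category_counts), 4L)
})

test_that("profiles from measured spreads agree with fixture profiles", {
  for (spid in c("robinia_pseudoacacia", "robinia_pseudoacacia_idaho")) {
    sp <- render_species(spid, seed = 6)
    m <- measured_spread(sp$image)
    prof <- encode_signal_profile(m$table, m$sites, species_id = spid)
    ref <- fixture_signal_profile(sp$fixture)
    expect_equal(prof$n_pairs_5S, ref$n_pairs_5S, label = spid)
    expect_equal(prof$heteromorphic_pairs, ref$heteromorphic_pairs,
                 label = spid)
  }
})

test_that("an empty site table gives an empty profile, unknown ids an error", {
  tab <- generate_measurement_table(
    load_species_fixture("amorpha_fruticosa"), noise_cv = 0)
  none <- encode_signal_profile(tab, empty <- data.frame(
    chromosome_id = character(0), channel = character(0),
    position_fraction = numeric(0), intensity = character(0)))
  expect_equal(none$n_pairs_5S, 0)
  expect_true(all(none$category_counts == 0))
  bad <- data.frame(chromosome_id = "nope", channel = "TAMRA",
                    position_fraction = 0.5, intensity = "strong")
  expect_error(encode_signal_profile(tab, bad),
               class = "kf_validation_error")
})

test_that("packaged profile dissimilarities match hand-computed values", {
  profs <- lapply(species_ids(),
                  function(s) fixture_signal_profile(load_species_fixture(s)))
  names(profs) <- species_ids()
  rp <- profs$robinia_pseudoacacia
  dec <- profs$robinia_pseudoacacia_decaisneana
  af <- profs$amorpha_fruticosa
  # hand evaluation of d = 1*|dn| + 0.5*L1(categories) + 0.25*|dh|:
  # rp {c2,t4,pt2} vs dec {c4,t2,pt2}: 0 + 0.5*(2+2+0) = 2
  expect_equal(profile_dissimilarity(rp, dec), 2.0)
  # rp vs af {c4}: 2 + 0.5*(2+4+2) = 6
  expect_equal(profile_dissimilarity(rp, af), 6.0)
  expect_lt(profile_dissimilarity(rp, dec), profile_dissimilarity(rp, af))
  expect_error(profile_dissimilarity(rp, dec, weights = c(w_n = -1)),
               class = "kf_validation_error")
})

test_that("the dissimilarity is a pseudometric on random profiles", {
  set.seed(99)
  profs <- lapply(seq_len(60), function(i) random_profile(paste0("s", i)))
  # identity and symmetry over ~1000 sampled pairs
  for (rep in seq_len(1000)) {
    ij <- sample(60, 2)
    p <- profs[[ij[1]]]; q <- profs[[ij[2]]]
    d <- profile_dissimilarity(p, q)
    expect_gte(d, 0)
    expect_identical(d, profile_dissimilarity(q, p))
  }
  for (p in profs) expect_identical(profile_dissimilarity(p, p), 0)
  # triangle inequality over sampled triples
  for (rep in seq_len(300)) {
    ijk <- sample(60, 3)
    d_ij <- profile_dissimilarity(profs[[ijk[1]]], profs[[ijk[2]]])
    d_jk <- profile_dissimilarity(profs[[ijk[2]]], profs[[ijk[3]]])
    d_ik <- profile_dissimilarity(profs[[ijk[1]]], profs[[ijk[3]]])
    expect_lte(d_ik, d_ij + d_jk + 1e-12)
  }
})

test_that("clustering handles identical profiles and conserves leaves", {
  p1 <- signal_profile("a", 2, c(centromeric = 4))
  p2 <- signal_profile("b", 2, c(centromeric = 4))
  dend <- cluster_profiles(list(p1, p2))
  expect_equal(dend$hclust$height, 0)
  profs <- lapply(species_ids(),
                  function(s) fixture_signal_profile(load_species_fixture(s)))
  nwk <- withr::local_tempfile(fileext = ".nwk")
  dend5 <- cluster_profiles(profs, newick_path = nwk)
  expect_setequal(dend5$phylo$tip.label, species_ids())
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, species_ids())
  expect_error(cluster_profiles(profs[1]), class = "kf_validation_error")
})

test_that("the three Robinia taxa cluster together before any other taxon joins", {
  profs <- lapply(species_ids(),
                  function(s) fixture_signal_profile(load_species_fixture(s)))
  dend <- cluster_profiles(profs)
  mm <- merge_members(dend$hclust)
  robinia <- c("robinia_pseudoacacia", "robinia_pseudoacacia_idaho",
               "robinia_pseudoacacia_decaisneana")
  expect_identical(mm[[1]],
                   sort(c("robinia_pseudoacacia",
                          "robinia_pseudoacacia_decaisneana")))
  expect_identical(mm[[2]], sort(robinia))
})
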