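test_that("topology wiring tables match the four designs", {
  expect_equal(make_topology("M1")$dephosphorylation_map,
               list(MKKK = "Phos1", MKK = "Phos2", MK = "Phos3"))
  expect_equal(make_topology("M2")$dephosphorylation_map,
               list(MKKK = "Phos1", MKK = "Phos1", MK = "Phos2"))
  expect_equal(make_topology("M3")$dephosphorylation_map,
               list(MKKK = "Phos1", MKK = "Phos2", MK = "Phos2"))
  expect_equal(make_topology("M4")$dephosphorylation_map,
               list(MKKK = "Phos1", MKK = c("Phos1", "Phos2"), MK = "Phos2"))
  # MKKK is always served by Phos1 alone; only M4 has a shared layer
  for (tp in all_topologies) {
    topo <- make_topology(tp)
    expect_equal(topo$dephosphorylation_map$MKKK, "Phos1")
    n_shared <- sum(lengths(topo$dephosphorylation_map) > 1)
    expect_equal(n_shared, if (tp == "M4") 1L else 0L)
  }
  expect_error(make_topology("M5"), "valid names.*M1")
  expect_error(make_topology(1), "valid names")
})

test_that("species inventories have the counts implied by the wiring", {
  # K1/K2_QSS: the five phosphoforms only
  for (tp in all_topologies) {
    m <- default_model(tp, "K1", "USEQ")
    expect_equal(list_species(m),
                 c("MKKK_P", "MKK_P", "MKK_PP", "MK_P", "MK_PP"))
  }
  # K2: 8 kinase forms + enzymes + one complex per conversion
  # (+ one sequestration complex per layer-terminal dephosphorylation)
  for (tp in all_topologies) {
    n_conv <- expected_conversions(tp)
    n_enz <- length(make_topology(tp)$phosphatases) + 1L   # + Sig
    useq <- default_model(tp, "K2", "USEQ")
    expect_length(list_species(useq), 8L + n_enz + n_conv)
    pseq <- default_model(tp, "K2", "PSEQ")
    n_pairs <- nrow(mapkdesign:::k2_seq_pairs(make_topology(tp)))
    expect_length(list_species(pseq), 8L + n_enz + n_conv + n_pairs)
  }
  # spot values: M1 22/25 species, M4 USEQ 23 species
  expect_length(list_species(default_model("M1", "K2", "USEQ")), 22L)
  expect_length(list_species(default_model("M1", "K2", "PSEQ")), 25L)
  expect_length(list_species(default_model("M4", "K2", "USEQ")), 23L)
})

test_that("conserved_totals recovers the configured pools", {
  m <- default_model("M1", "K1", "USEQ")
  state <- c(MKKK_P = 30, MKK_P = 0, MKK_PP = 0, MK_P = 0, MK_PP = 0)
  pools <- conserved_totals(state, m)
  expect_equal(pools[["MKKK_total"]], m$totals$MKKK_total)
  free <- mapkdesign:::free_kinase_forms(state, m)
  expect_equal(free[["MKKK"]], m$totals$MKKK_total - 30)

  m2 <- default_model("M3", "K2", "PSEQ")
  y0 <- mapkdesign:::initial_state(m2, sig = 7)
  pools0 <- conserved_totals(y0, m2)
  expect_equal(pools0[["MKK_total"]], m2$totals$MKK_total)
  expect_equal(pools0[["Phos2_total"]], m2$totals$Phos2_total)
  expect_equal(pools0[["Sig_total"]], 7)
  expect_error(conserved_totals(y0[-1], m2), "match")
})

test_that("conserved pools are constant along simulated trajectories", {
  prot <- signal_protocol(10)
  for (case in list(c("M2", "K1", "PSEQ"), c("M4", "K2", "PSEQ"))) {
    m <- default_model(case[1], case[2], case[3])
    traj <- simulate_cascade(m, prot, 800, n_out = 40)
    pools <- t(apply(traj$species, 1, conserved_totals, model = m))
    drift <- apply(pools, 2, function(p) diff(range(p)) / max(p[1], 1e-12))
    expect_lt(max(drift), 1e-6)
  }
})

test_that("model construction validates scheme/parameter pairings", {
  ref1 <- reference_parameters("M1", "K1")
  ref2 <- reference_parameters("M1", "K2")
  expect_error(mapk_model("M1", "K2", "USEQ", ref1$params, ref1$totals),
               "k2_parameters")
  expect_error(mapk_model("M1", "K1", "USEQ", ref2$params, ref2$totals),
               "k1_parameters")
  # K2_QSS accepts a K2 set and derives the Michaelis-Menten parameters
  m <- mapk_model("M1", "K2_QSS", "PSEQ", ref2$params, ref2$totals)
  expect_s3_class(m$params, "k1_parameters")
  # Phos3 exists iff M1
  expect_error(mapk_model("M2", "K1", "USEQ",
                          reference_parameters("M2", "K1")$params,
                          ref1$totals), "Phos3")
})
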