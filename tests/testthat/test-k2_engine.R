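test_that("network sizes follow from the construction rules", {
  # 3 elementary reactions per conversion; PSEQ adds 2 per pair
  cases <- list(
    list("M1", "USEQ", conv = 10L, rxn = 30L, sp = 22L),
    list("M1", "PSEQ", conv = 10L, rxn = 36L, sp = 25L),
    list("M4", "USEQ", conv = 12L, rxn = 36L, sp = 23L),
    list("M4", "PSEQ", conv = 12L, rxn = 44L, sp = 27L))
  for (cs in cases) {
    expect_equal(expected_conversions(cs[[1]]), cs$conv)
    nw <- build_k2_network(default_model(cs[[1]], "K2", cs[[2]]))
    expect_equal(nrow(nw$reactions), cs$rxn)
    expect_length(nw$species, cs$sp)
  }
  expect_error(build_k2_network(default_model("M1", "K1", "USEQ")),
               "scheme K2")
})

test_that("mass-action rates follow the law of mass action", {
  nw <- build_k2_network(default_model("M1", "K2", "USEQ"))
  rhs <- mass_action_rhs(nw)
  y <- setNames(numeric(length(nw$species)), nw$species)
  expect_equal(max(abs(rhs(y))), 0)          # empty state, zero derivative
  # single active binding reaction: Sig + MKKK -> Sig complex
  y["Sig"] <- 4; y["MKKK"] <- 3
  a <- nw$reactions$rate_constant[nw$reactions$id == "bind_Sig:MKKK"]
  dy <- rhs(y)
  expect_equal(dy[["MKKK.Sig"]], a * 4 * 3)
  expect_equal(dy[["Sig"]], -a * 4 * 3)
  expect_error(rhs(y - 1), "negative")
})

test_that("conservation pools are left-null vectors of the stoichiometry", {
  for (tp in all_topologies) for (sq in c("USEQ", "PSEQ")) {
    m <- default_model(tp, "K2", sq)
    nw <- build_k2_network(m)
    # indicator of each pool over the species (1 if the species contains
    # a member of the pool): analytic time derivative must vanish
    pools <- names(conserved_totals(mapkdesign:::initial_state(m), m))
    for (pool in pools) {
      ind <- vapply(nw$species, function(sp) {
        parts <- strsplit(sp, ".", fixed = TRUE)[[1]]
        as.numeric(pool %in% vapply(parts, mapkdesign:::.pool_of, ""))
      }, numeric(1))
      expect_equal(max(abs(ind %*% nw$stoichiometry)), 0)
    }
  }
})

test_that("USEQ networks contain no sequestration complexes", {
  for (tp in all_topologies) {
    sp <- list_species(default_model(tp, "K2", "USEQ"))
    complexes <- grep(".", sp, fixed = TRUE, value = TRUE)
    left <- sub("\\..*$", "", complexes)
    # every complex carries a phosphorylated substrate or the enzyme Sig
    # bound to MKKK; no unphosphorylated kinase-phosphatase pair exists
    phosphatase_bound <- complexes[grepl("Phos", complexes)]
    expect_true(all(grepl("_P", sub("\\..*$", "", phosphatase_bound))))
    expect_false(any(left %in% c("MKKK", "MKK", "MK") &
                       grepl("Phos", complexes)))
  }
})

test_that("PSEQ reroutes only the layer-terminal dephosphorylations", {
  nw <- build_k2_network(default_model("M4", "K2", "PSEQ"))
  rxn <- nw$reactions
  # MKK-PP -> MKK-P catalysis releases free MKK-P
  j <- which(rxn$id == "cat_Phos1:MKK_PP")
  expect_equal(sort(na.omit(c(rxn$product1[j], rxn$product2[j]))),
               sort(c("Phos1", "MKK_P")))
  # MKK-P -> MKK catalysis yields the bound sequestration complex
  j <- which(rxn$id == "cat_Phos1:MKK_P")
  expect_equal(na.omit(c(rxn$product1[j], rxn$product2[j]))[[1]],
               "MKK.Phos1")
  # and the complex is reversibly released
  expect_true(all(c("seqrel_MKK.Phos1", "seqbind_MKK.Phos1") %in% rxn$id))
})

test_that("mass-action steady state approaches the QSS reduction when
          enzyme pools are far below substrate pools", {
  prot <- signal_protocol(1)
  for (tp in all_topologies) {
    ref <- qss_regime(tp)
    full <- mapk_model(tp, "K2", "USEQ", ref$params, ref$totals)
    reduced <- mapk_model(tp, "K2_QSS", "USEQ",
                          derive_qss_params(ref$params), ref$totals)
    s_full <- steady_state(full, prot)[["MK_PP"]]
    s_red <- steady_state(reduced, prot)[["MK_PP"]]
    expect_lt(abs(s_full - s_red) / s_full, 0.05)
  }
})

test_that("compiled and reference derivative paths agree", {
  prot <- signal_protocol(10, t_off = 300)
  for (case in list(c("M4", "K1", "PSEQ"), c("M2", "K2", "PSEQ"))) {
    m <- default_model(case[1], case[2], case[3])
    tc <- simulate_cascade(m, prot, 900, n_out = 60, compiled = TRUE)
    tr <- simulate_cascade(m, prot, 900, n_out = 60, compiled = FALSE)
    expect_lt(max(abs(tc$species - tr$species)) / max(tr$species), 1e-6)
  }
})
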