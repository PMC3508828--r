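test_that("competitive Michaelis-Menten flux matches hand arithmetic", {
  # half saturation: kcat * E / 2
  expect_equal(mm_competitive_flux(1, 10, 5, 5), 5)
  # one competitor sitting at its own Km adds 1 to the denominator
  expect_equal(mm_competitive_flux(1, 10, 5, 5,
                                   competitors = data.frame(conc = 3, Km = 3)),
               10 / 3)
  # one sequestration term with kinase at Kse adds another 1
  expect_equal(mm_competitive_flux(1, 10, 5, 5,
                                   competitors = data.frame(conc = 3, Km = 3),
                                   sequestration_terms =
                                     data.frame(conc = 2, Kse = 2)),
               2.5)
  expect_equal(mm_competitive_flux(1, 10, 0, 5), 0)
  expect_error(mm_competitive_flux(1, 10, 5, 0), "positive")
  expect_error(mm_competitive_flux(1, 10, 5, 5,
                                   sequestration_terms =
                                     data.frame(conc = 1, Kse = -1)),
               "Kse")
})

test_that("no signal and no phosphoforms is a fixed point", {
  for (tp in all_topologies) for (sq in c("USEQ", "PSEQ")) {
    rhs <- build_k1_rhs(default_model(tp, "K1", sq))
    expect_equal(unname(rhs(rep(0, 5), sig = 0)), rep(0, 5))
  }
})

test_that("M1 steady MKKK-P matches a scalar root-finding oracle", {
  m <- default_model("M1", "K1", "USEQ")
  p <- m$params; t <- m$totals; sig <- 10
  # the MKKK layer of M1 is autonomous: Sig*k1*(MKKK/K1)/(1+MKKK/K1)
  # = Phos1*k2*(P/K2)/(1+P/K2) with MKKK = MKKK_total - P
  f <- function(P) {
    mkkk <- t$MKKK_total - P
    sig * p[["k1"]] * (mkkk / p[["K1"]]) / (1 + mkkk / p[["K1"]]) -
      t$Phos1_total * p[["k2"]] * (P / p[["K2"]]) / (1 + P / p[["K2"]])
  }
  oracle <- uniroot(f, c(1e-9, t$MKKK_total - 1e-9), tol = 1e-12)$root
  ss <- steady_state(m, signal_protocol(sig))
  expect_equal(ss[["MKKK_P"]], oracle, tolerance = 1e-6)
})

test_that("assembled M4 MKK-PP derivative matches a literal transcription", {
  m <- default_model("M4", "K1", "USEQ")
  rhs <- build_k1_rhs(m)
  p <- as.list(unclass(m$params)); t <- m$totals; sig <- t$Sig
  # hand-coded arithmetic for dMKK-PP/dt in the M4 design:
  # phosphorylation by MKKK-P minus dephosphorylation by Phos1 (pooled
  # with MKKK-P and MKK-P) and by Phos2 (pooled with MKK-P, MK-PP, MK-P)
  oracle <- function(s) {
    mkk <- t$MKK_total - s[["MKK_P"]] - s[["MKK_PP"]]
    v4 <- p$k4 * s[["MKKK_P"]] * (s[["MKK_P"]] / p$K4) /
      (1 + mkk / p$K3 + s[["MKK_P"]] / p$K4)
    v5a <- p$k5a * t$Phos1_total * (s[["MKK_PP"]] / p$K5a) /
      (1 + s[["MKK_PP"]] / p$K5a + s[["MKK_P"]] / p$K6a +
         s[["MKKK_P"]] / p$K2a)
    v5b <- p$k5b * t$Phos2_total * (s[["MKK_PP"]] / p$K5b) /
      (1 + s[["MKK_PP"]] / p$K5b + s[["MKK_P"]] / p$K6b +
         s[["MK_PP"]] / p$K9b + s[["MK_P"]] / p$K10b)
    v4 - v5a - v5b
  }
  set.seed(41)
  for (i in 1:20) {
    s <- random_k1_state(t)
    expect_equal(rhs(s, sig = sig)[["MKK_PP"]], oracle(s),
                 tolerance = 1e-12)
  }
})

test_that("quasi-steady-state map reduces mass-action rates correctly", {
  k2 <- k2_parameters("M2", a = 1, d = 0.5, kcat = 0.5,
                      kf_seq = 1, kr_seq = 0.06)
  k1 <- derive_qss_params(k2)
  expect_equal(unname(k1[["K1"]]), 1)          # (0.5 + 0.5) / 1
  expect_equal(unname(k1[["k1"]]), 0.5)        # kcat carried over
  expect_equal(unname(k1[["Kse1"]]), 0.06)     # kr_seq / kf_seq
  expect_equal(unname(k1[["Kse2"]]), 0.06)
  # kcat -> 0 limit: Km -> d/a (pure binding)
  k2b <- k2_parameters("M2", a = 2, d = 1, kcat = 1e-12)
  expect_equal(unname(derive_qss_params(k2b)[["K5"]]), 0.5,
               tolerance = 1e-9)
  # M4 gets the full a/b-suffixed MKK-layer duplication
  k4 <- derive_qss_params(reference_parameters("M4", "K2")$params)
  expect_true(all(c("k5a", "K5a", "k6b", "K10b", "K2a") %in% names(k4)))
})

test_that("K2_QSS right-hand side equals the K1 engine for mapped params", {
  set.seed(17)
  for (tp in all_topologies) for (sq in c("USEQ", "PSEQ")) {
    ref <- reference_parameters(tp, "K2")
    qss <- mapk_model(tp, "K2_QSS", sq, ref$params, ref$totals)
    k1m <- mapk_model(tp, "K1", sq, derive_qss_params(ref$params),
                      ref$totals)
    rhs_qss <- build_k1_rhs(qss)
    rhs_k1 <- build_k1_rhs(k1m)
    for (i in 1:5) {
      s <- random_k1_state(ref$totals)
      expect_equal(rhs_qss(s), rhs_k1(s), tolerance = 1e-14)
    }
  }
})

test_that("sequestration strictly decreases every dephosphorylation flux", {
  set.seed(23)
  for (tp in c("M2", "M4")) {
    ref <- reference_parameters(tp, "K1")
    useq <- mapk_model(tp, "K1", "USEQ", ref$params, ref$totals)
    pseq <- mapk_model(tp, "K1", "PSEQ", ref$params, ref$totals)
    rhs_u <- build_k1_rhs(useq); rhs_p <- build_k1_rhs(pseq)
    for (i in 1:5) {
      s <- random_k1_state(ref$totals)
      s["MKKK_P"] <- min(s[["MKKK_P"]], 0.9 * ref$totals$MKKK_total)
      # with phosphorylation fluxes identical, weaker dephosphorylation
      # means d(MKKK-P)/dt can only grow
      expect_gt(rhs_p(s)[["MKKK_P"]], rhs_u(s)[["MKKK_P"]])
    }
  }
})

test_that("the M1 MKKK layer is decoupled from downstream pools", {
  ref <- reference_parameters("M1", "K1")
  base <- steady_state(mapk_model("M1", "K1", "USEQ", ref$params,
                                  ref$totals), signal_protocol(10))
  t2 <- ref$totals
  t2$Phos2_total <- 999; t2$Phos3_total <- 3; t2$MKK_total <- 432
  t2$MK_total <- 2111
  alt <- steady_state(mapk_model("M1", "K1", "USEQ", ref$params, t2),
                      signal_protocol(10))
  expect_equal(alt[["MKKK_P"]], base[["MKKK_P"]], tolerance = 1e-7)
})
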