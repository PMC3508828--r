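test_that("total parameter variation is the absolute log10 fold sum", {
  ref <- c(1, 2, 3)
  expect_equal(total_parameter_variation(ref, ref), 0)
  expect_equal(total_parameter_variation(c(10, 2, 3), ref), 1)
  expect_equal(total_parameter_variation(c(0.1, 20, 3), ref), 2)
  expect_error(total_parameter_variation(c(1, -1, 1), ref), "positive")
  expect_error(total_parameter_variation(1:2, 1:3), "equal-length")
})

test_that("robustness coefficient matches its defining arithmetic", {
  expect_equal(as.numeric(robustness_coefficient(rep(2, 10), 2)), 0)
  expect_equal(as.numeric(robustness_coefficient(rep(20, 10), 2)), -1)
  # over- and under-shoots do not cancel under the absolute value
  expect_equal(as.numeric(robustness_coefficient(c(0.2, 20), 2)), -1)
  expect_error(robustness_coefficient(1, 0), "positive")
  r <- robustness_coefficient(c(1e-15, 1), 1)
  expect_equal(attr(r, "n_floored"), 1L)
})

test_that("robustness difference reproduces the reported arithmetic", {
  expect_equal(robustness_difference(-0.4, -4.55), 4.15)
  expect_equal(robustness_difference(-0.61, -7.86), 7.25)
  expect_equal(robustness_difference(-1, -1), 0)
})

test_that("the stratified sample respects its grid and seed contract", {
  ref <- c(a = 2, b = 50)
  spec <- perturbation_spec("kinases", n_strata = 2000,
                            n_simulations = 400, seed = 5)
  s <- lhs_sample(spec, ref)
  expect_equal(dim(s), c(400L, 2L))
  for (nm in names(ref)) {
    grid <- seq(0.1 * ref[[nm]], 10 * ref[[nm]], length.out = 2000)
    expect_true(all(s[, nm] >= 0.1 * ref[[nm]] - 1e-12))
    expect_true(all(s[, nm] <= 10 * ref[[nm]] + 1e-12))
    expect_true(all(vapply(s[, nm], function(x)
      min(abs(grid - x)) < 1e-9 * ref[[nm]], logical(1))))
  }
  # two-point grid
  spec2 <- perturbation_spec("kinases", fold_range = c(1, 10),
                             n_strata = 2, n_simulations = 100, seed = 1)
  s2 <- lhs_sample(spec2, c(x = 1))
  expect_true(all(s2 %in% c(1, 10)))
  expect_true(all(c(1, 10) %in% s2))
  # reproducibility
  expect_identical(lhs_sample(spec, ref), lhs_sample(spec, ref))
  spec_alt <- perturbation_spec("kinases", n_strata = 2000,
                                n_simulations = 400, seed = 6)
  expect_false(identical(lhs_sample(spec, ref), lhs_sample(spec_alt, ref)))
  # the caller's RNG stream is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(lhs_sample(spec, ref)); after <- runif(1)
  expect_identical(before, after)
})

test_that("zero-width perturbation gives a robustness of exactly zero", {
  m <- default_model("M2", "K1", "USEQ")
  spec <- perturbation_spec("kinases", fold_range = c(1, 1),
                            n_strata = 1, n_simulations = 5, seed = 3)
  r <- run_robustness(m, spec)
  expect_equal(r$robustness_coefficient, 0, tolerance = 1e-6)
  expect_equal(r$tpv, rep(0, 5))
})

test_that("perturbation magnitude widens the robustness coefficient", {
  m <- default_model("M2", "K1", "USEQ")
  R <- vapply(list(c(0.5, 2), c(0.2, 5), c(0.1, 10)), function(fr) {
    run_robustness(m, perturbation_spec(
      "phosphatases", fold_range = fr, n_simulations = 60,
      seed = 8))$robustness_coefficient
  }, numeric(1))
  expect_true(all(diff(R) < 0))       # strictly more negative
  expect_true(all(R <= 0))
})

test_that("kinetic-parameter variation spans all rates but not Kse", {
  m1 <- default_model("M2", "K1", "PSEQ")
  ref <- mapkdesign:::varied_reference(m1, perturbation_spec("kinetic"))
  expect_false(any(grepl("Kse", names(ref))))
  expect_true(all(c("k1", "K1", "k10", "K10") %in% names(ref)))
  ref_kse <- mapkdesign:::varied_reference(
    m1, perturbation_spec("kinetic", include_kse = TRUE))
  expect_true(any(grepl("Kse", names(ref_kse))))
  m2 <- default_model("M1", "K2", "PSEQ")
  ref2 <- mapkdesign:::varied_reference(m2, perturbation_spec("kinetic"))
  expect_length(ref2, 3 * 10)         # (a, d, kcat) per conversion
  expect_false(any(grepl("seq", names(ref2))))
})

test_that("reduced-N robustness agrees with large-N within Monte-Carlo error", {
  m <- default_model("M1", "K1", "USEQ")
  big <- run_robustness(m, perturbation_spec("kinases",
                                             n_simulations = 5000, seed = 2))
  small <- run_robustness(m, perturbation_spec("kinases",
                                               n_simulations = 500, seed = 3))
  logs <- abs(log10(big$output_ratio))
  se <- sd(logs) / sqrt(500)
  expect_lt(abs(small$robustness_coefficient - big$robustness_coefficient),
            3 * se)
})

test_that("kinetic perturbation runs end to end on both engines", {
  for (case in list(c("M2", "K1"), c("M1", "K2"))) {
    m <- default_model(case[1], case[2], "USEQ")
    r <- run_robustness(m, small_spec("kinetic", n = 20))
    expect_lte(r$robustness_coefficient, 0)
    expect_equal(r$n_failed, 0)
    expect_length(r$tpv, 20)
  }
})
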