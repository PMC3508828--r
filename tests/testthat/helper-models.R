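# shared fixtures: all built in code, no stored data

all_topologies <- c("M1", "M2", "M3", "M4")

# expected number of enzymatic conversions from the wiring table alone
# (5 phosphorylation steps + one dephosphorylation conversion per
# (phosphatase, phosphoform) pair), independent of k2_conversions()
expected_conversions <- function(topology_name) {
  forms_per_layer <- c(MKKK = 1L, MKK = 2L, MK = 2L)
  topo <- make_topology(topology_name)
  5L + sum(vapply(names(topo$dephosphorylation_map), function(layer)
    length(topo$dephosphorylation_map[[layer]]) * forms_per_layer[[layer]],
    integer(1)))
}

# a small perturbation spec for smoke tests
small_spec <- function(vary, n = 30, seed = 101, ...)
  perturbation_spec(vary, n_simulations = n, seed = seed, ...)

# random valid K1 phosphoform state within the conservation totals
random_k1_state <- function(totals) {
  mkkk_p <- runif(1, 0, totals$MKKK_total)
  mkk <- diff(c(0, sort(runif(2, 0, totals$MKK_total)), totals$MKK_total))
  mk <- diff(c(0, sort(runif(2, 0, totals$MK_total)), totals$MK_total))
  c(MKKK_P = mkkk_p, MKK_P = mkk[1], MKK_PP = mkk[2],
    MK_P = mk[1], MK_PP = mk[2])
}

# the hierarchical-concentration regime in which the quasi-steady-state
# reduction of the mass-action model is expected to be accurate
# (enzyme pools well below their substrate pools)
qss_regime <- function(topology_name) {
  ref <- reference_parameters(topology_name, "K2")
  ref$totals <- cascade_concentrations(
    MKKK_total = 5, MKK_total = 50, MK_total = 500,
    Phos1_total = 5, Phos2_total = 5,
    Phos3_total = if (topology_name == "M1") 5 else NULL, Sig = 1)
  ref
}
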