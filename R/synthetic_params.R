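#' Packaged reference parameter sets
#'
#' Deterministic, versioned default parameter sets and total
#' concentrations for every topology and kinetic scheme, emulating the
#' Huang-Ferrell-type regime of in-vitro MAPK reconstitution: the MKKK
#' pool is much smaller than the MKK and MK pools, phosphatase totals are
#' comparable to the kinase totals, and all rates and Michaelis/
#' elementary constants lie within a few orders of magnitude of each
#' other (nM and seconds throughout).
#'
#' The K1 and K2 defaults are independent sets; the K2_QSS defaults are
#' derived from the K2 set through [derive_qss_params()], which puts the
#' quasi-steady-state sequestration constant at
#' `Kse = kr_seq / kf_seq = 0.06 nM` -- four orders of magnitude below
#' the dephosphorylation Michaelis constants, so K2_QSS PSEQ models are
#' very strongly sequestrated.
#'
#' @param topology a `mapk_topology` or topology name.
#' @param scheme `"K1"`, `"K2"` or `"K2_QSS"`.
#' @return A list with `params` (a [k1_parameters()] or
#'   [k2_parameters()] set as appropriate) and `totals`
#'   (a [cascade_concentrations()] object).
#' @export
reference_parameters <- function(topology, scheme = c("K1", "K2", "K2_QSS")) {
  if (!inherits(topology, "mapk_topology")) topology <- make_topology(topology)
  scheme <- match.arg(scheme)
  # phosphatase totals are comparable to the kinase totals; the K2 set
  # keeps them below the MKKK pool so that stoichiometric sequestration
  # (Kse = 0.06 nM) shields the phosphatases without locking away the
  # entire MKKK pool at rest
  phos_total <- if (scheme == "K1") 150 else 60
  totals <- cascade_concentrations(
    MKKK_total = 100, MKK_total = 1200, MK_total = 1200,
    Phos1_total = phos_total, Phos2_total = phos_total,
    Phos3_total = if (topology$name == "M1") phos_total else NULL,
    Sig = 10)

  if (scheme == "K1") {
    kcat_sig <- 2.5     # signal-layer catalytic rate, 1/s
    kcat_phos <- 1      # cascade kinase catalytic rates, 1/s
    kcat_deph <- 0.25   # MKKK/MKK-layer phosphatase catalytic rates, 1/s
    kcat_mk <- 1        # MK-layer phosphatase catalytic rate, 1/s
    Km <- 300           # Michaelis constants, nM
    Km_mk <- 1200       # MK-layer dephosphorylation Michaelis constant, nM
    kse <- 10           # K1 sequestration equilibrium constant, nM
    v <- c(k1 = kcat_sig, K1 = Km, k3 = kcat_phos, K3 = Km,
           k4 = kcat_phos, K4 = Km, k7 = kcat_phos, K7 = Km,
           k8 = kcat_phos, K8 = Km, k2 = kcat_deph)
    v <- if (topology$name == "M4") {
      c(v, K2a = Km, k5a = kcat_deph, K5a = Km, k6a = kcat_deph, K6a = Km,
        k5b = kcat_deph, K5b = Km, k6b = kcat_deph, K6b = Km,
        k9 = kcat_mk, K9b = Km_mk, k10 = kcat_mk, K10b = Km_mk)
    } else {
      c(v, K2 = Km, k5 = kcat_deph, K5 = Km, k6 = kcat_deph, K6 = Km,
        k9 = kcat_mk, K9 = Km_mk, k10 = kcat_mk, K10 = Km_mk)
    }
    kse_names <- if (topology$name == "M1") c("Kse1", "Kse2", "Kse3")
                 else c("Kse1", "Kse2")
    v <- c(v, stats::setNames(rep(kse, length(kse_names)), kse_names))
    params <- do.call(k1_parameters, c(list(topology = topology), as.list(v)))
    return(list(params = params, totals = totals))
  }

  # K2 / K2_QSS: shared within kind for parsimony -- phosphorylation
  # conversions get one (a, d, kcat) triple, dephosphorylation another
  conv <- k2_conversions(topology)
  mk_deph <- conv$kind == "dephosphorylation" &
    conv$substrate %in% c("MK_P", "MK_PP")
  pick <- function(phos_val, deph_val, mk_val)
    stats::setNames(ifelse(conv$kind == "phosphorylation", phos_val,
                           ifelse(mk_deph, mk_val, deph_val)), conv$id)
  k2 <- k2_parameters(
    topology,
    a = pick(0.01, 0.005, 0.005), # 1/(nM s): Km 300 / 600 / 1200 nM
    d = pick(1, 2, 2),            # 1/s
    kcat = pick(2, 1, 4),         # 1/s
    kf_seq = 1, kr_seq = 0.06)    # Kse = 0.06 nM under QSS
  if (scheme == "K2") return(list(params = k2, totals = totals))
  list(params = derive_qss_params(k2, topology), totals = totals)
}

#' Convenience constructor for a default model instance
#'
#' @param topology,scheme,sequestration as in [mapk_model()].
#' @return A `mapk_model` built from [reference_parameters()].
#' @export
default_model <- function(topology, scheme = "K1", sequestration = "USEQ") {
  ref <- reference_parameters(topology, scheme)
  mapk_model(topology, scheme, sequestration, ref$params, ref$totals)
}

#' Random parameter sets within stated ranges
#'
#' Draws `n` log-uniform parameter vectors within per-quantity bounds,
#' reproducibly by seed. Used by property-style tests to exercise model
#' invariants across random parameterisations.
#'
#' @param ranges named list of `c(low, high)` bounds (all positive).
#' @param n number of draws.
#' @param seed integer seed.
#' @return A data.frame with `n` rows, one column per quantity.
#' @export
sample_parameters <- function(ranges, n, seed) {
  stopifnot(is.list(ranges), length(ranges) > 0, n >= 0)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2])
      stop("range '", nm, "' must be c(low, high) with 0 < low <= high",
           call. = FALSE)
  }
  rng <- function() {
    cols <- lapply(ranges, function(r)
      exp(stats::runif(n, log(r[1]), log(r[2]))))
    as.data.frame(cols)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rng()
}

# save/restore the global RNG state so seeded helpers do not perturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
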