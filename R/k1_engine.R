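#' Competitive Michaelis-Menten flux with enzyme sequestration
#'
#' Evaluates the quasi-steady-state flux of one enzymatic conversion in
#' the presence of competing substrates of the same enzyme and, in PSEQ
#' mode, of unphosphorylated kinases that sequester the enzyme:
#'
#' \deqn{v = \frac{k_{cat} \, E \, S/K_S}
#'   {1 + S/K_S + \sum_i S_i/K_i + \sum_j Kin_j/Kse_j}}
#'
#' @param kcat catalytic rate (1/s).
#' @param enzyme_conc free enzyme (total) concentration (nM).
#' @param substrate_conc substrate concentration (nM).
#' @param substrate_Km Michaelis constant of the substrate (nM).
#' @param competitors optional two-column matrix or data.frame with
#'   columns `conc` and `Km` for competing substrates.
#' @param sequestration_terms optional two-column matrix or data.frame
#'   with columns `conc` (kinase, nM) and `Kse` (sequestration
#'   equilibrium constant, nM).
#' @return Flux in nM/s (nonnegative; 0 when the substrate is 0).
#' @examples
#' mm_competitive_flux(1, 10, 5, 5)          # half saturation: 5 nM/s
#' @export
mm_competitive_flux <- function(kcat, enzyme_conc, substrate_conc,
                                substrate_Km, competitors = NULL,
                                sequestration_terms = NULL) {
  if (substrate_Km <= 0) stop("substrate_Km must be positive", call. = FALSE)
  den <- 1 + substrate_conc / substrate_Km
  if (!is.null(competitors) && NROW(competitors) > 0) {
    competitors <- as.data.frame(competitors)
    if (any(competitors$Km <= 0))
      stop("competitor Km values must be positive", call. = FALSE)
    den <- den + sum(competitors$conc / competitors$Km)
  }
  if (!is.null(sequestration_terms) && NROW(sequestration_terms) > 0) {
    sequestration_terms <- as.data.frame(sequestration_terms)
    if (any(sequestration_terms$Kse <= 0))
      stop("Kse values must be positive", call. = FALSE)
    den <- den + sum(sequestration_terms$conc / sequestration_terms$Kse)
  }
  kcat * enzyme_conc * (substrate_conc / substrate_Km) / den
}

# --- flux-group tables ------------------------------------------------
#
# The K1 right-hand side is assembled from "flux groups": one enzyme
# acting on one or more substrates that share a competitive denominator.
# Each member is (substrate, Km name, kcat name, stoichiometry over the
# five phosphoform states). PSEQ adds (kinase, Kse name) entries to the
# dephosphorylation groups.
#
# state order: MKKK_P, MKK_P, MKK_PP, MK_P, MK_PP

.k1_states <- c("MKKK_P", "MKK_P", "MKK_PP", "MK_P", "MK_PP")

.delta <- function(...) {
  d <- stats::setNames(numeric(5), .k1_states)
  args <- list(...)
  for (nm in names(args)) d[nm] <- args[[nm]]
  d
}

# phosphorylation groups are identical in all four designs
.k1_phospho_groups <- function() {
  list(
    list(enzyme = "Sig", members = list(
      list(sub = "MKKK", Km = "K1", kcat = "k1", delta = .delta(MKKK_P = 1)))),
    list(enzyme = "MKKK_P", members = list(
      list(sub = "MKK", Km = "K3", kcat = "k3", delta = .delta(MKK_P = 1)),
      list(sub = "MKK_P", Km = "K4", kcat = "k4",
           delta = .delta(MKK_P = -1, MKK_PP = 1)))),
    list(enzyme = "MKK_PP", members = list(
      list(sub = "MK", Km = "K7", kcat = "k7", delta = .delta(MK_P = 1)),
      list(sub = "MK_P", Km = "K8", kcat = "k8",
           delta = .delta(MK_P = -1, MK_PP = 1))))
  )
}

# member describing the dephosphorylation of one phosphoform, with the
# Km/kcat parameter names resolved per topology
.dephos_member <- function(form, Km, kcat) {
  delta <- switch(form,
    MKKK_P = .delta(MKKK_P = -1),
    MKK_PP = .delta(MKK_PP = -1, MKK_P = 1),
    MKK_P  = .delta(MKK_P = -1),
    MK_PP  = .delta(MK_PP = -1, MK_P = 1),
    MK_P   = .delta(MK_P = -1))
  list(sub = form, Km = Km, kcat = kcat, delta = delta)
}

# dephosphorylation groups: one per phosphatase; the denominator pools
# every phospho-substrate that phosphatase serves in the topology
.k1_dephos_groups <- function(topology) {
  name <- topology$name
  m <- function(...) .dephos_member(...)
  groups <- switch(name,
    M1 = list(
      Phos1 = list(m("MKKK_P", "K2", "k2")),
      Phos2 = list(m("MKK_PP", "K5", "k5"), m("MKK_P", "K6", "k6")),
      Phos3 = list(m("MK_PP", "K9", "k9"), m("MK_P", "K10", "k10"))),
    M2 = list(
      Phos1 = list(m("MKKK_P", "K2", "k2"),
                   m("MKK_PP", "K5", "k5"), m("MKK_P", "K6", "k6")),
      Phos2 = list(m("MK_PP", "K9", "k9"), m("MK_P", "K10", "k10"))),
    M3 = list(
      Phos1 = list(m("MKKK_P", "K2", "k2")),
      Phos2 = list(m("MKK_PP", "K5", "k5"), m("MKK_P", "K6", "k6"),
                   m("MK_PP", "K9", "k9"), m("MK_P", "K10", "k10"))),
    M4 = list(
      Phos1 = list(m("MKKK_P", "K2a", "k2"),
                   m("MKK_PP", "K5a", "k5a"), m("MKK_P", "K6a", "k6a")),
      Phos2 = list(m("MKK_PP", "K5b", "k5b"), m("MKK_P", "K6b", "k6b"),
                   m("MK_PP", "K9b", "k9"), m("MK_P", "K10b", "k10"))))
  lapply(names(groups), function(ph) {
    kse <- paste0("Kse", substring(ph, 5))
    list(enzyme = ph, members = groups[[ph]],
         seq_kinases = .base_form[layers_served(topology, ph)],
         Kse = kse)
  })
}

#' Build the Michaelis-Menten right-hand side of a model
#'
#' Assembles the coupled phosphoform ODEs of a K1 or K2_QSS model from
#' competitive Michaelis-Menten fluxes: within each layer the two
#' phosphoforms compete for their shared kinase, each phosphatase's
#' denominator pools every phospho-substrate it serves in the topology,
#' and in PSEQ mode each dephosphorylation denominator additionally
#' gains a `kinase/Kse` term per unphosphorylated kinase of the layers
#' that phosphatase serves. Free kinases are eliminated through the
#' conservation relations.
#'
#' @param model a `mapk_model` with scheme `"K1"` or `"K2_QSS"`.
#' @return A function `f(state, sig = model$totals$Sig)` returning
#'   `d(state)/dt` over the five phosphoforms (named numeric vector).
#'   `sig` is the instantaneous signal concentration, so transient
#'   protocols can switch it.
#' @export
build_k1_rhs <- function(model) {
  totals <- model$totals
  tabs <- .k1_tables(model)
  compiled <- tabs$compiled
  neg_tol <- tabs$neg_tol
  t1 <- totals$MKKK_total; t2 <- totals$MKK_total; t3 <- totals$MK_total

  function(state, sig = totals$Sig) {
    y <- unname(state)
    val <- c(y, t1 - y[1], t2 - y[2] - y[3], t3 - y[4] - y[5])
    if (val[6] < neg_tol || val[7] < neg_tol || val[8] < neg_tol)
      stop("state exceeds kinase conservation totals", call. = FALSE)
    dy <- numeric(5)
    for (g in compiled) {
      E <- if (g$is_sig) sig
           else if (!is.na(g$phos_total)) g$phos_total
           else val[g$enzyme_idx]
      s_over_K <- val[g$subs] / g$Km
      den <- 1 + sum(s_over_K)
      if (!is.na(g$kse)) den <- den + sum(val[g$seq_idx]) / g$kse
      dy <- dy + as.numeric(g$delta %*% (g$kcat * E * s_over_K / den))
    }
    names(dy) <- .k1_states
    dy
  }
}

# flux tables of a K1/K2_QSS model, precompiled with integer indices
# into the flat value vector c(MKKK_P, MKK_P, MKK_PP, MK_P, MK_PP,
# MKKK, MKK, MK); shared by the R closure and the compiled evaluator
.k1_tables <- function(model) {
  stopifnot(inherits(model, "mapk_model"))
  if (model$scheme == "K2")
    stop("build_k1_rhs applies to schemes K1 and K2_QSS only", call. = FALSE)
  p <- model$params
  totals <- model$totals
  pseq <- model$sequestration == "PSEQ"
  groups <- c(.k1_phospho_groups(), .k1_dephos_groups(model$topology))
  value_names <- c(.k1_states, "MKKK", "MKK", "MK")
  compiled <- lapply(groups, function(g) {
    kcat <- unname(p[vapply(g$members, `[[`, "", "kcat")])
    Km <- unname(p[vapply(g$members, `[[`, "", "Km")])
    subs <- match(vapply(g$members, `[[`, "", "sub"), value_names)
    delta <- vapply(g$members, `[[`, numeric(5), "delta")  # 5 x n
    seq_kin <- if (pseq && !is.null(g$seq_kinases)) g$seq_kinases else
      character(0)
    kse <- if (length(seq_kin)) unname(p[g$Kse]) else NA_real_
    list(enzyme_idx = match(g$enzyme, value_names),     # NA for Sig/Phos
         is_sig = g$enzyme == "Sig",
         kcat = kcat, Km = Km, subs = subs, delta = delta,
         seq_idx = match(seq_kin, value_names), kse = kse,
         phos_total = if (g$enzyme %in% c("Phos1", "Phos2", "Phos3"))
           totals[[paste0(g$enzyme, "_total")]] else NA_real_)
  })
  list(compiled = compiled,
       neg_tol = -1e-4 * max(totals$MKKK_total, totals$MKK_total,
                             totals$MK_total))
}

#' Quasi-steady-state parameter map from mass-action rates
#'
#' Reduces a mass-action (K2) parameter set to the Michaelis-Menten
#' parameters of the corresponding K2_QSS model: per conversion
#' `Km = (d + kcat) / a` with the catalytic rate carried over, and per
#' sequestration pair `Kse = kr_seq / kf_seq`. The flux equations of the
#' resulting model are identical to the K1 engine's.
#'
#' @param k2 a [k2_parameters()] set.
#' @param topology the topology the set was built for (defaults to the
#'   one recorded in the set).
#' @return A [k1_parameters()] set.
#' @export
derive_qss_params <- function(k2, topology = k2$topology) {
  stopifnot(inherits(k2, "k2_parameters"))
  if (!inherits(topology, "mapk_topology")) topology <- make_topology(topology)
  if (topology$name != k2$topology)
    stop("k2 parameter set was built for ", k2$topology, call. = FALSE)
  if (any(k2$a <= 0) || any(k2$kf_seq <= 0))
    stop("association and sequestration binding rates must be positive",
         call. = FALSE)
  Km <- (k2$d + k2$kcat) / k2$a
  kcat <- k2$kcat

  # conversion id -> (kcat name, Km name) per topology
  conv_map <- list(
    "Sig:MKKK" = c("k1", "K1"), "MKKK_P:MKK" = c("k3", "K3"),
    "MKKK_P:MKK_P" = c("k4", "K4"), "MKK_PP:MK" = c("k7", "K7"),
    "MKK_PP:MK_P" = c("k8", "K8"))
  if (topology$name == "M4") {
    conv_map <- c(conv_map, list(
      "Phos1:MKKK_P" = c("k2", "K2a"),
      "Phos1:MKK_PP" = c("k5a", "K5a"), "Phos1:MKK_P" = c("k6a", "K6a"),
      "Phos2:MKK_PP" = c("k5b", "K5b"), "Phos2:MKK_P" = c("k6b", "K6b"),
      "Phos2:MK_PP" = c("k9", "K9b"), "Phos2:MK_P" = c("k10", "K10b")))
  } else {
    dephos <- k2_conversions(topology)
    dephos <- dephos[dephos$kind == "dephosphorylation", ]
    base_map <- c("MKKK_P" = "2", "MKK_PP" = "5", "MKK_P" = "6",
                  "MK_PP" = "9", "MK_P" = "10")
    for (i in seq_len(nrow(dephos))) {
      n <- base_map[[dephos$substrate[i]]]
      conv_map[[dephos$id[i]]] <- c(paste0("k", n), paste0("K", n))
    }
  }

  out <- list()
  for (id in names(conv_map)) {
    nm <- conv_map[[id]]
    out[[nm[1]]] <- unname(kcat[id])
    out[[nm[2]]] <- unname(Km[id])
  }
  for (ph in topology$phosphatases) {
    kse_name <- paste0("Kse", substring(ph, 5))
    out[[kse_name]] <- unname(k2$kr_seq[ph] / k2$kf_seq[ph])
  }
  do.call(k1_parameters, c(list(topology = topology), out))
}
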