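# Internal integration engine: serialises the flux tables / reaction
# network into the flat parameter vectors consumed by the compiled
# derivative evaluators in src/cascade_deriv.c, with the pure-R
# closures from build_k1_rhs() / mass_action_rhs() as fallback.
#
# K1 parameter vector layout (1-based R indices):
#   [1] Sig, [2:4] kinase totals, [5] negative-free tolerance,
#   [6] n_groups, then per flux group:
#     e_kind (0 = Sig, 1 = state-indexed enzyme, 2 = fixed total),
#     e_ref (state index into c(y, free) or the total), Kse (0 = none),
#     n_seq, seq indices..., n_members, then per member:
#     kcat, Km, substrate index, 5 stoichiometry entries.
#
# K2 parameter vector layout:
#   [1] sig_off flag, [2] Sig species index, [3] n_rxn,
#   k[n_rxn], reactant1[n_rxn], reactant2[n_rxn] (0 = unimolecular),
#   n_triplets, rows, cols, values of the sparse stoichiometry.

.PARMS_MAX <- 4096L

.pad_parms <- function(v) {
  out <- numeric(.PARMS_MAX)
  out[seq_along(v)] <- v
  out
}

.k1_parms_vector <- function(model) {
  tabs <- .k1_tables(model)
  t <- model$totals
  v <- c(0, t$MKKK_total, t$MKK_total, t$MK_total, tabs$neg_tol,
         length(tabs$compiled))
  for (g in tabs$compiled) {
    e_kind <- if (g$is_sig) 0 else if (!is.na(g$enzyme_idx)) 1 else 2
    e_ref <- if (e_kind == 1) g$enzyme_idx else
             if (e_kind == 2) g$phos_total else 0
    kse <- if (is.na(g$kse)) 0 else g$kse
    mem <- as.numeric(rbind(g$kcat, g$Km, g$subs, g$delta))
    v <- c(v, e_kind, e_ref, kse, length(g$seq_idx), g$seq_idx,
           length(g$kcat), mem)
  }
  v
}

.k2_parms_vector <- function(network) {
  rxn <- network$reactions
  species <- network$species
  i1 <- match(rxn$reactant1, species)
  i2 <- match(rxn$reactant2, species)
  i2[is.na(i2)] <- 0
  trip <- which(network$stoichiometry != 0, arr.ind = TRUE)
  vals <- network$stoichiometry[trip]
  c(0, match("Sig", species), nrow(rxn),
    rxn$rate_constant, i1, i2,
    nrow(trip), trip[, 1], trip[, 2], vals)
}

# engine = everything needed to integrate a model fast
.engine <- function(model) {
  if (model$scheme == "K2") {
    network <- build_k2_network(model)
    rhs <- mass_action_rhs(network)
    r_deriv <- function(t, y, parms) {
      if (isTRUE(parms$sig_off)) y[["Sig"]] <- 0
      dy <- rhs(y)
      if (isTRUE(parms$sig_off)) dy[["Sig"]] <- 0
      list(dy)
    }
    list(type = "k2", species = network$species,
         base = .k2_parms_vector(network), r_deriv = r_deriv,
         n_rxn = nrow(network$reactions))
  } else {
    rhs <- build_k1_rhs(model)
    r_deriv <- function(t, y, parms) list(rhs(y, sig = parms$sig))
    list(type = "k1", species = .k1_states,
         base = .k1_parms_vector(model), r_deriv = r_deriv)
  }
}

# one lsoda call over `times`, either through the compiled evaluator or
# the R closure; returns the deSolve matrix with named columns
.engine_ode <- function(engine, y, times, sig = 0, sig_off = FALSE,
                        rtol = .default_rtol, atol = .default_atol,
                        compiled = TRUE, base = engine$base) {
  if (compiled) {
    parms <- base
    parms[1] <- if (engine$type == "k1") sig else as.numeric(sig_off)
    sol <- deSolve::ode(y = unname(y), times = times,
                        func = paste0("cascade_derivs_", engine$type),
                        parms = .pad_parms(parms),
                        dllname = "mapkdesign", initfunc = "cascade_initmod",
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = 50000)
  } else {
    parms <- if (engine$type == "k1") list(sig = sig)
             else list(sig_off = sig_off)
    sol <- deSolve::ode(y = unname(y), times = times,
                        func = engine$r_deriv, parms = parms,
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = 50000)
  }
  colnames(sol) <- c("time", engine$species)
  sol
}

# derivative of a state through the engine's R-level closure
.engine_deriv <- function(engine, y, sig = 0, sig_off = FALSE) {
  parms <- if (engine$type == "k1") list(sig = sig) else
    list(sig_off = sig_off)
  engine$r_deriv(0, y, parms)[[1]]
}
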