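#' Construct a cascade model instance
#'
#' A model instance binds a topology (M1-M4), a kinetic scheme, a
#' sequestration mode and a parameter set:
#'
#' * `scheme = "K1"`: Michaelis-Menten fluxes with competitive
#'   denominators; state variables are the five phosphoforms, the free
#'   kinases are eliminated through the conservation relations, and `Sig`
#'   and the phosphatase totals enter as constants.
#' * `scheme = "K2"`: elementary mass-action reaction network over all
#'   free forms, enzymes and complexes (requires a [k2_parameters()]
#'   set).
#' * `scheme = "K2_QSS"`: the quasi-steady-state reduction of K2; its
#'   flux equations are identical to K1's, so it carries a
#'   [k1_parameters()] set -- either given directly or derived from a
#'   [k2_parameters()] set via [derive_qss_params()].
#'
#' In PSEQ mode the unphosphorylated kinases sequester the phosphatases
#' of the layers those phosphatases serve: K1/K2_QSS dephosphorylation
#' denominators gain `kinase/Kse` terms, while K2 reroutes each
#' layer-terminal dephosphorylation through a reversible
#' kinase-phosphatase complex.
#'
#' @param topology a `mapk_topology` or topology name.
#' @param scheme `"K1"`, `"K2"` or `"K2_QSS"`.
#' @param sequestration `"USEQ"` or `"PSEQ"`.
#' @param params a [k1_parameters()] set (K1/K2_QSS) or
#'   [k2_parameters()] set (K2; also accepted for K2_QSS, where it is
#'   mapped through [derive_qss_params()]).
#' @param totals a [cascade_concentrations()] object.
#' @return An object of class `mapk_model`.
#' @examples
#' ref <- reference_parameters("M1", "K1")
#' m <- mapk_model("M1", "K1", "USEQ", ref$params, ref$totals)
#' list_species(m)
#' @export
mapk_model <- function(topology, scheme = c("K1", "K2", "K2_QSS"),
                       sequestration = c("USEQ", "PSEQ"),
                       params, totals) {
  if (!inherits(topology, "mapk_topology")) topology <- make_topology(topology)
  scheme <- match.arg(scheme)
  sequestration <- match.arg(sequestration)
  if (!inherits(totals, "cascade_concentrations"))
    stop("'totals' must be a cascade_concentrations object", call. = FALSE)
  if (topology$name == "M1" && is.null(totals$Phos3_total))
    stop("topology M1 requires Phos3_total", call. = FALSE)
  if (topology$name != "M1" && !is.null(totals$Phos3_total))
    stop("Phos3_total is defined only for topology M1", call. = FALSE)

  if (scheme == "K2") {
    if (!inherits(params, "k2_parameters"))
      stop("scheme K2 requires a k2_parameters set", call. = FALSE)
  } else {
    if (inherits(params, "k2_parameters")) {
      if (scheme == "K1")
        stop("scheme K1 requires a k1_parameters set", call. = FALSE)
      params <- derive_qss_params(params, topology)
    }
    if (!inherits(params, "k1_parameters"))
      stop("scheme ", scheme, " requires a k1_parameters set", call. = FALSE)
  }
  if (!is.null(attr(params, "topology")) &&
      attr(params, "topology") != topology$name ||
      inherits(params, "k2_parameters") && params$topology != topology$name)
    stop("parameter set was built for topology ",
         if (inherits(params, "k2_parameters")) params$topology
         else attr(params, "topology"),
         ", not ", topology$name, call. = FALSE)

  structure(
    list(topology = topology, scheme = scheme,
         sequestration = sequestration, params = params, totals = totals),
    class = "mapk_model"
  )
}

#' @export
print.mapk_model <- function(x, ...) {
  cat(sprintf("<mapk_model> %s^%s, %s\n", x$topology$name, x$scheme,
              x$sequestration))
  cat("  species:", length(list_species(x)), "\n")
  invisible(x)
}

#' Ordered species inventory of a model
#'
#' The state variables integrated by the kinetic engines, in a
#' deterministic order: for K1/K2_QSS the five phosphoforms
#' (`MKKK_P`, `MKK_P`, `MKK_PP`, `MK_P`, `MK_PP`); for K2 the kinase
#' forms top-down by layer and phosphorylation count, then the enzymes
#' (`Sig`, phosphatases), then the enzyme-substrate complexes in
#' construction order and finally (PSEQ) the sequestration complexes.
#' Complexes are named `substrate.enzyme`.
#'
#' @param model a `mapk_model`.
#' @return Character vector of species names.
#' @export
list_species <- function(model) {
  stopifnot(inherits(model, "mapk_model"))
  if (model$scheme != "K2")
    return(c("MKKK_P", "MKK_P", "MKK_PP", "MK_P", "MK_PP"))
  conv <- k2_conversions(model$topology)
  base <- c("MKKK", "MKKK_P", "MKK", "MKK_P", "MKK_PP", "MK", "MK_P", "MK_PP")
  enzymes <- c("Sig", model$topology$phosphatases)
  complexes <- paste(conv$substrate, conv$enzyme, sep = ".")
  if (model$sequestration == "PSEQ")
    complexes <- c(complexes, k2_seq_pairs(model$topology)$id)
  c(base, enzymes, complexes)
}

# pool membership of an elementary species name (no complexes):
# the kinase layer it belongs to, the phosphatase it is, or Sig
.pool_of <- function(sp) {
  if (sp %in% c("MKKK", "MKKK_P")) "MKKK_total"
  else if (sp %in% c("MKK", "MKK_P", "MKK_PP")) "MKK_total"
  else if (sp %in% c("MK", "MK_P", "MK_PP")) "MK_total"
  else if (sp == "Sig") "Sig_total"
  else paste0(sp, "_total")
}

#' Conserved pools of a model state
#'
#' Sums each conserved pool over the free forms plus every complex
#' containing that species (counted once per complex). For K1/K2_QSS
#' states the free kinases are first recovered from the conservation
#' relations, so the kinase pools equal the configured totals by
#' construction (an error is raised if a pool is overdrawn).
#'
#' @param state named numeric vector matching `list_species(model)`.
#' @param model a `mapk_model`.
#' @return Named numeric vector of pool values (nM): `MKKK_total`,
#'   `MKK_total`, `MK_total`, plus (K2) `Sig_total` and the phosphatase
#'   totals.
#' @export
conserved_totals <- function(state, model) {
  species <- list_species(model)
  if (is.null(names(state))) {
    if (length(state) != length(species))
      stop("state length ", length(state), " does not match the ",
           length(species), " model species", call. = FALSE)
    names(state) <- species
  } else if (!setequal(names(state), species)) {
    stop("state names do not match list_species(model)", call. = FALSE)
  }
  state <- state[species]
  if (model$scheme != "K2") {
    free <- free_kinase_forms(state, model)
    return(c(
      MKKK_total = unname(free["MKKK"] + state["MKKK_P"]),
      MKK_total  = unname(free["MKK"] + state["MKK_P"] + state["MKK_PP"]),
      MK_total   = unname(free["MK"] + state["MK_P"] + state["MK_PP"])
    ))
  }
  pools <- unique(vapply(
    c("MKKK", "MKK", "MK", "Sig", model$topology$phosphatases),
    .pool_of, character(1)))
  out <- stats::setNames(numeric(length(pools)), pools)
  for (sp in species) {
    parts <- strsplit(sp, ".", fixed = TRUE)[[1]]
    for (member in unique(vapply(parts, .pool_of, character(1))))
      out[member] <- out[member] + state[[sp]]
  }
  out
}

# free (unphosphorylated) kinases of a K1/K2_QSS state via the
# conservation relations; negative values indicate an inconsistent state
free_kinase_forms <- function(state, model) {
  t <- model$totals
  free <- c(
    MKKK = t$MKKK_total - state[["MKKK_P"]],
    MKK  = t$MKK_total - state[["MKK_P"]] - state[["MKK_PP"]],
    MK   = t$MK_total - state[["MK_P"]] - state[["MK_PP"]]
  )
  if (any(free < -1e-4 * max(t$MKKK_total, t$MKK_total, t$MK_total)))
    stop("state exceeds kinase conservation totals (negative free ",
         paste(names(free)[free < 0], collapse = ", "), ")", call. = FALSE)
  # tiny negative excursions from the solver are kept as-is: the flux
  # terms are smooth through zero and push the state back
  free
}

# initial state of a model: everything unphosphorylated / unbound.
# sig gives the free signal concentration placed in the K2 state.
initial_state <- function(model, sig = 0) {
  species <- list_species(model)
  y <- stats::setNames(numeric(length(species)), species)
  if (model$scheme == "K2") {
    t <- model$totals
    y["MKKK"] <- t$MKKK_total
    y["MKK"] <- t$MKK_total
    y["MK"] <- t$MK_total
    y["Sig"] <- sig
    for (ph in model$topology$phosphatases)
      y[ph] <- t[[paste0(ph, "_total")]]
  }
  y
}
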