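#' Build the elementary mass-action reaction network of a K2 model
#'
#' Every phosphorylation/dephosphorylation conversion implied by the
#' topology (see [k2_conversions()]) is expanded into the three
#' elementary reactions `E + S <-> E.S -> E + P` (binding, dissociation,
#' catalysis). In PSEQ mode each layer-terminal dephosphorylation is
#' rewired so that catalysis yields the bound kinase-phosphatase complex
#' (the sequestrated fraction), and a reversible release
#' `kinase.phosphatase <-> kinase + phosphatase` is added (2 extra
#' reactions per sequestration pair).
#'
#' @param model a `mapk_model` with scheme `"K2"`.
#' @return An object of class `k2_network`: a list with `species`,
#'   `reactions` (data.frame with reactants, products, rate constant and
#'   kind) and the sparse `stoichiometry` matrix (species x reactions).
#' @export
build_k2_network <- function(model) {
  stopifnot(inherits(model, "mapk_model"))
  if (model$scheme != "K2")
    stop("build_k2_network requires scheme K2", call. = FALSE)
  p <- model$params
  conv <- k2_conversions(model$topology)
  pseq <- model$sequestration == "PSEQ"
  species <- list_species(model)

  rx <- list()
  add <- function(id, r1, r2, p1, p2, k, kind) {
    rx[[length(rx) + 1L]] <<- data.frame(
      id = id, reactant1 = r1, reactant2 = r2, product1 = p1, product2 = p2,
      rate_constant = k, kind = kind, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(conv))) {
    cid <- conv$id[i]
    E <- conv$enzyme[i]; S <- conv$substrate[i]; P <- conv$product[i]
    C <- paste(S, E, sep = ".")
    add(paste0("bind_", cid), E, S, C, NA, p$a[[cid]], "binding")
    add(paste0("diss_", cid), C, NA, E, S, p$d[[cid]], "dissociation")
    if (pseq && conv$terminal[i]) {
      # catalysis keeps the phosphatase bound to the dephosphorylated
      # kinase: the product is the sequestration complex
      seqC <- paste(P, E, sep = ".")
      add(paste0("cat_", cid), C, NA, seqC, NA, p$kcat[[cid]], "catalysis")
    } else {
      add(paste0("cat_", cid), C, NA, E, P, p$kcat[[cid]], "catalysis")
    }
  }
  if (pseq) {
    pairs <- k2_seq_pairs(model$topology)
    for (i in seq_len(nrow(pairs))) {
      kin <- pairs$kinase[i]; ph <- pairs$phosphatase[i]
      seqC <- pairs$id[i]
      add(paste0("seqrel_", seqC), seqC, NA, kin, ph,
          p$kr_seq[[ph]], "seq_release")
      add(paste0("seqbind_", seqC), kin, ph, seqC, NA,
          p$kf_seq[[ph]], "seq_bind")
    }
  }
  reactions <- do.call(rbind, rx)

  stoich <- matrix(0, nrow = length(species), ncol = nrow(reactions),
                   dimnames = list(species, reactions$id))
  for (j in seq_len(nrow(reactions))) {
    for (r in stats::na.omit(c(reactions$reactant1[j],
                               reactions$reactant2[j])))
      stoich[r, j] <- stoich[r, j] - 1
    for (pr in stats::na.omit(c(reactions$product1[j],
                                reactions$product2[j])))
      stoich[pr, j] <- stoich[pr, j] + 1
  }
  structure(list(model = model, species = species, reactions = reactions,
                 stoichiometry = stoich),
            class = "k2_network")
}

#' @export
print.k2_network <- function(x, ...) {
  cat(sprintf("<k2_network> %s^K2 %s: %d species, %d elementary reactions\n",
              x$model$topology$name, x$model$sequestration,
              length(x$species), nrow(x$reactions)))
  invisible(x)
}

#' Mass-action derivative function of a reaction network
#'
#' Returns the time derivative `d(state)/dt = S %*% v(state)` where `S`
#' is the stoichiometry matrix and each reaction rate is the rate
#' constant times the product of its reactant concentrations.
#'
#' @param network a `k2_network` from [build_k2_network()].
#' @return A function `f(state)` mapping a named/ordered species vector
#'   to its derivative (named numeric vector, nM/s).
#' @export
mass_action_rhs <- function(network) {
  stopifnot(inherits(network, "k2_network"))
  rxn <- network$reactions
  species <- network$species
  i1 <- match(rxn$reactant1, species)
  i2 <- match(rxn$reactant2, species)          # NA for unimolecular
  bi <- !is.na(i2)
  k <- rxn$rate_constant
  S <- network$stoichiometry
  function(state) {
    if (any(state < -1e-6))
      stop("negative concentrations beyond tolerance in mass-action state",
           call. = FALSE)
    rates <- k * state[i1]
    rates[bi] <- rates[bi] * state[i2[bi]]
    stats::setNames(as.numeric(S %*% rates), species)
  }
}
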