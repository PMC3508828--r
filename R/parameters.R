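#' Total concentrations of the cascade proteins and the input signal
#'
#' All concentrations are in nM. `Phos3_total` exists only for topology
#' M1 (the only design with a third phosphatase); `Sig` is the input
#' signal concentration used for sustained protocols.
#'
#' @param MKKK_total,MKK_total,MK_total total kinase concentrations (nM).
#' @param Phos1_total,Phos2_total total phosphatase concentrations (nM).
#' @param Phos3_total total Phos3 concentration (nM), M1 only; `NULL`
#'   otherwise.
#' @param Sig input signal concentration (nM).
#' @return An object of class `cascade_concentrations` (a named list).
#' @export
cascade_concentrations <- function(MKKK_total, MKK_total, MK_total,
                                   Phos1_total, Phos2_total,
                                   Phos3_total = NULL, Sig = 10) {
  x <- list(MKKK_total = MKKK_total, MKK_total = MKK_total,
            MK_total = MK_total, Phos1_total = Phos1_total,
            Phos2_total = Phos2_total, Phos3_total = Phos3_total,
            Sig = Sig)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.null(v)) next
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("concentration '", nm, "' must be a single nonnegative number",
           call. = FALSE)
  }
  structure(x, class = "cascade_concentrations")
}

# required Michaelis-Menten parameter names for a topology.
# M4 duplicates the MKK-layer dephosphorylation parameters with the
# "a" (Phos1) and "b" (Phos2) suffixes; its MK-layer Michaelis constants
# carry the "b" suffix because Phos2's pooled denominator is distinct
# from the M1-M3 one.
k1_param_names <- function(topology) {
  name <- if (inherits(topology, "mapk_topology")) topology$name else topology
  phosphorylation <- c("k1", "K1", "k3", "K3", "k4", "K4",
                       "k7", "K7", "k8", "K8")
  core <- if (name == "M4") {
    c("k2", "K2a",
      "k5a", "K5a", "k6a", "K6a",
      "k5b", "K5b", "k6b", "K6b",
      "k9", "K9b", "k10", "K10b")
  } else {
    c("k2", "K2", "k5", "K5", "k6", "K6", "k9", "K9", "k10", "K10")
  }
  kse <- if (name == "M1") c("Kse1", "Kse2", "Kse3") else c("Kse1", "Kse2")
  c(phosphorylation, core, kse)
}

#' Michaelis-Menten (K1 / K2_QSS) parameter set
#'
#' Catalytic rates `k1..k10` are in 1/s, Michaelis constants `K1..K10` in
#' nM. For topology M4 the MKK-layer dephosphorylation parameters are
#' duplicated with suffixes `a` (Phos1) and `b` (Phos2): `k5a, k6a, K2a,
#' K5a, K6a` and `k5b, k6b, K5b, K6b, K9b, K10b`. Sequestration
#' equilibrium constants `Kse1`, `Kse2` (and `Kse3` for M1) are in nM and
#' enter the model only in PSEQ mode.
#'
#' @param topology a `mapk_topology` or topology name.
#' @param ... named parameter values; must cover exactly
#'   `k1_param_names(topology)`.
#' @return An object of class `k1_parameters` (a named numeric vector with
#'   a `topology` attribute).
#' @seealso [reference_parameters()] for packaged defaults,
#'   [derive_qss_params()] for the quasi-steady-state map from a
#'   mass-action parameter set.
#' @export
k1_parameters <- function(topology, ...) {
  if (!inherits(topology, "mapk_topology")) topology <- make_topology(topology)
  vals <- c(...)
  required <- k1_param_names(topology)
  missing <- setdiff(required, names(vals))
  if (length(missing))
    stop("missing K1 parameter(s) for ", topology$name, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(vals), required)
  if (length(extra))
    stop("unknown K1 parameter(s) for ", topology$name, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  vals <- vals[required]
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad))
    stop("K1 parameter(s) must be positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(vals, topology = topology$name, class = "k1_parameters")
}

#' Enzymatic conversions implied by a topology
#'
#' Enumerates every phosphorylation and dephosphorylation conversion of
#' the mass-action (K2) reaction scheme: 5 phosphorylation conversions
#' (identical in all designs) plus one dephosphorylation conversion per
#' (phosphatase, phospho-substrate) pair of the wiring table.
#'
#' @param topology a `mapk_topology` or topology name.
#' @return A data.frame with columns `id`, `enzyme`, `substrate`,
#'   `product`, `kind` (`"phosphorylation"`/`"dephosphorylation"`), and
#'   `terminal` (`TRUE` for the dephosphorylation step producing the
#'   fully dephosphorylated kinase -- the step rewired under PSEQ).
#' @export
k2_conversions <- function(topology) {
  if (!inherits(topology, "mapk_topology")) topology <- make_topology(topology)
  conv <- data.frame(
    enzyme    = c("Sig", "MKKK_P", "MKKK_P", "MKK_PP", "MKK_PP"),
    substrate = c("MKKK", "MKK", "MKK_P", "MK", "MK_P"),
    product   = c("MKKK_P", "MKK_P", "MKK_PP", "MK_P", "MK_PP"),
    kind      = "phosphorylation",
    terminal  = FALSE,
    stringsAsFactors = FALSE
  )
  for (layer in .layers) {
    forms <- rev(.phosphoforms[[layer]])          # PP -> P, then P -> base
    targets <- c(forms[-1], .base_form[[layer]])
    for (ph in topology$dephosphorylation_map[[layer]]) {
      conv <- rbind(conv, data.frame(
        enzyme = ph, substrate = forms, product = targets,
        kind = "dephosphorylation",
        terminal = targets == .base_form[[layer]],
        stringsAsFactors = FALSE
      ))
    }
  }
  conv$id <- paste(conv$enzyme, conv$substrate, sep = ":")
  rownames(conv) <- NULL
  conv[, c("id", "enzyme", "substrate", "product", "kind", "terminal")]
}

# sequestration pairs (unphosphorylated kinase, phosphatase): one per
# layer-terminal dephosphorylation of the topology
k2_seq_pairs <- function(topology) {
  if (!inherits(topology, "mapk_topology")) topology <- make_topology(topology)
  conv <- k2_conversions(topology)
  term <- conv[conv$terminal, ]
  data.frame(kinase = term$product, phosphatase = term$enzyme,
             id = paste(term$product, term$enzyme, sep = "."),
             stringsAsFactors = FALSE)
}

#' Elementary mass-action (K2) parameter set
#'
#' One `(a, d, kcat)` triple per enzymatic conversion of the topology:
#' association rate `a` in 1/(nM*s), dissociation rate `d` in 1/s,
#' catalytic rate `kcat` in 1/s. Sequestration pairs (one per
#' phosphatase) carry a binding rate `kf_seq` (1/(nM*s)) and a release
#' rate `kr_seq` (1/s); they are used only in PSEQ mode.
#'
#' Scalars are recycled over all conversions; alternatively pass named
#' vectors keyed by the conversion ids of [k2_conversions()] (for
#' `a`/`d`/`kcat`) or by phosphatase name (for `kf_seq`/`kr_seq`).
#'
#' @param topology a `mapk_topology` or topology name.
#' @param a,d,kcat association, dissociation and catalytic rates.
#' @param kf_seq,kr_seq sequestration binding/release rates per
#'   phosphatase.
#' @return An object of class `k2_parameters`.
#' @export
k2_parameters <- function(topology, a, d, kcat, kf_seq = 1, kr_seq = 0.06) {
  if (!inherits(topology, "mapk_topology")) topology <- make_topology(topology)
  conv <- k2_conversions(topology)
  expand <- function(x, keys, what) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- rep(x, length(keys)); names(x) <- keys
    }
    missing <- setdiff(keys, names(x))
    if (length(missing))
      stop("missing '", what, "' rate(s) for: ",
           paste(missing, collapse = ", "), call. = FALSE)
    x <- x[keys]
    if (any(!is.finite(x) | x <= 0))
      stop("'", what, "' rates must be positive", call. = FALSE)
    x
  }
  phs <- topology$phosphatases
  structure(
    list(topology = topology$name,
         a = expand(a, conv$id, "a"),
         d = expand(d, conv$id, "d"),
         kcat = expand(kcat, conv$id, "kcat"),
         kf_seq = expand(kf_seq, phs, "kf_seq"),
         kr_seq = expand(kr_seq, phs, "kr_seq")),
    class = "k2_parameters"
  )
}

#' Read a parameter/concentration configuration file
#'
#' Accepts JSON or YAML (decided by file extension). The file may contain
#' the keys `concentrations` (fields of [cascade_concentrations()]),
#' `k1_parameters` (named scalars) and/or `k2_parameters` (with fields
#' `a`, `d`, `kcat`, `kf_seq`, `kr_seq`). Unknown or malformed keys are
#' reported by name.
#'
#' @param path file path.
#' @param topology a `mapk_topology` or topology name, used to validate
#'   the parameter blocks.
#' @return A list with any of `concentrations`, `k1_parameters`,
#'   `k2_parameters` that the file defines, validated.
#' @export
read_parameter_file <- function(path, topology) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported parameter file extension '", ext,
         "' (use .json or .yaml)", call. = FALSE))
  allowed <- c("concentrations", "k1_parameters", "k2_parameters")
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- list()
  if (!is.null(raw$concentrations))
    out$concentrations <- do.call(cascade_concentrations,
                                  as.list(raw$concentrations))
  if (!is.null(raw$k1_parameters))
    out$k1_parameters <- do.call(
      k1_parameters, c(list(topology = topology),
                       as.list(unlist(raw$k1_parameters))))
  if (!is.null(raw$k2_parameters)) {
    kp <- raw$k2_parameters
    out$k2_parameters <- k2_parameters(
      topology,
      a = unlist(kp$a), d = unlist(kp$d), kcat = unlist(kp$kcat),
      kf_seq = if (is.null(kp$kf_seq)) 1 else unlist(kp$kf_seq),
      kr_seq = if (is.null(kp$kr_seq)) 0.06 else unlist(kp$kr_seq))
  }
  out
}
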