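# SBML Level 2 Version 4 export/import built on xml2.
#
# K2 models export as full reaction networks with mass-action kinetic
# laws; K1/K2_QSS models export the five phosphoform rate rules as
# explicit MathML expressions, with the free kinases as assignment
# rules over the conservation totals. A package annotation on the
# <model> element records topology/scheme/sequestration so that imports
# of our own exports reconstruct the model instance exactly; files
# following the M<i>_K<j>_<SEQ> stem naming convention
# (M<i>_K<j>[_QSS]_<USEQ|PSEQ>*.xml) are recognised best-effort.

.SBML_NS <- "http://www.sbml.org/sbml/level2/version4"
.ANN_NS <- "https://mapkdesign.r-pkg/annotation"

.sbml_num <- function(x) sprintf("%.17g", x)

# SBML ids must be SIds: conversion/complex ids use "__" separators,
# which is unambiguous because plain species names never contain "__"
.sid_species <- function(x) gsub(".", "__", x, fixed = TRUE)
.sid_rxn <- function(id) gsub(":", "__", gsub(".", "__", sub("_", "__", id),
                                              fixed = TRUE))

# --- minimal MathML builders (strings) --------------------------------
.mml_ci <- function(x) paste0("<ci> ", x, " </ci>")
.mml_cn <- function(x) paste0("<cn> ", .sbml_num(x), " </cn>")
.mml_apply <- function(op, ...) paste0("<apply><", op, "/>",
                                       paste0(..., collapse = ""),
                                       "</apply>")
.mml_math <- function(body)
  paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">", body,
         "</math>")

# MathML for one flux group of the K1 tables: returns per-member flux
# expressions (list) sharing the group's competitive denominator
.k1_group_mathml <- function(g, value_names) {
  E <- if (g$is_sig) .mml_ci("Sig")
       else if (!is.na(g$enzyme_idx)) .mml_ci(value_names[g$enzyme_idx])
       else .mml_ci(g$phos_name)
  den_terms <- c("<cn> 1 </cn>",
                 mapply(function(s, K) .mml_apply(
                   "divide", .mml_ci(value_names[s]), .mml_ci(K)),
                   g$subs, g$Km_names))
  if (length(g$seq_idx))
    den_terms <- c(den_terms, vapply(g$seq_idx, function(s) .mml_apply(
      "divide", .mml_ci(value_names[s]), .mml_ci(g$Kse_name)), ""))
  den <- .mml_apply("plus", paste0(den_terms, collapse = ""))
  lapply(seq_along(g$subs), function(m) .mml_apply(
    "divide",
    paste0(.mml_apply("times", .mml_ci(g$kcat_names[m]), E,
                      .mml_apply("divide", .mml_ci(value_names[g$subs[m]]),
                                 .mml_ci(g$Km_names[m]))),
           ""),
    den))
}

#' Export a cascade model to SBML
#'
#' Writes an SBML Level 2 Version 4 document: K2 models as elementary
#' reaction networks with mass-action kinetic laws, K1/K2_QSS models
#' with explicit rate-rule expressions for the five phosphoforms and
#' assignment rules recovering the free kinases from the conservation
#' totals. A package annotation records the model coordinates so the
#' document round-trips through [import_sbml()] to an equivalent model
#' instance.
#'
#' @param model a `mapk_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(model, path) {
  stopifnot(inherits(model, "mapk_model"))
  t <- model$totals
  model_id <- sprintf("%s_%s_%s", model$topology$name,
                      sub("K2_QSS", "K2_QSS", model$scheme),
                      model$sequestration)
  xml <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<sbml xmlns=\"%s\" level=\"2\" version=\"4\">", .SBML_NS),
    sprintf("<model id=\"%s\">", model_id),
    "<annotation>",
    sprintf(paste0("<mapkdesign:model xmlns:mapkdesign=\"%s\" ",
                   "topology=\"%s\" scheme=\"%s\" sequestration=\"%s\"/>"),
            .ANN_NS, model$topology$name, model$scheme, model$sequestration),
    "</annotation>",
    "<listOfCompartments>",
    "<compartment id=\"cell\" size=\"1\"/>",
    "</listOfCompartments>")

  param_line <- function(id, value, constant = TRUE)
    sprintf("<parameter id=\"%s\" value=\"%s\" constant=\"%s\"/>",
            id, .sbml_num(value), if (constant) "true" else "false")
  totals_params <- c(
    param_line("MKKK_total", t$MKKK_total),
    param_line("MKK_total", t$MKK_total),
    param_line("MK_total", t$MK_total),
    param_line("Phos1_total", t$Phos1_total),
    param_line("Phos2_total", t$Phos2_total),
    if (!is.null(t$Phos3_total)) param_line("Phos3_total", t$Phos3_total),
    param_line("Sig_total", t$Sig))

  if (model$scheme == "K2") {
    network <- build_k2_network(model)
    y0 <- initial_state(model, sig = t$Sig)
    species_lines <- vapply(network$species, function(sp) sprintf(
      "<species id=\"%s\" compartment=\"cell\" initialConcentration=\"%s\"/>",
      .sid_species(sp), .sbml_num(y0[[sp]])), "")
    p <- model$params
    rate_params <- c(
      vapply(names(p$a), function(id) param_line(
        .sid_rxn(paste0("a_", id)), p$a[[id]]), ""),
      vapply(names(p$d), function(id) param_line(
        .sid_rxn(paste0("d_", id)), p$d[[id]]), ""),
      vapply(names(p$kcat), function(id) param_line(
        .sid_rxn(paste0("kcat_", id)), p$kcat[[id]]), ""),
      vapply(names(p$kf_seq), function(ph) param_line(
        paste0("kf_seq__", ph), p$kf_seq[[ph]]), ""),
      vapply(names(p$kr_seq), function(ph) param_line(
        paste0("kr_seq__", ph), p$kr_seq[[ph]]), ""))
    rxn <- network$reactions
    rxn_lines <- unlist(lapply(seq_len(nrow(rxn)), function(j) {
      reac <- stats::na.omit(c(rxn$reactant1[j], rxn$reactant2[j]))
      prod <- stats::na.omit(c(rxn$product1[j], rxn$product2[j]))
      kin <- .mml_math(.mml_apply("times", paste0(
        c(.mml_ci(.k2_rate_param_id(rxn$id[j], model)),
          vapply(reac, function(s) .mml_ci(.sid_species(s)), "")),
        collapse = "")))
      c(sprintf("<reaction id=\"%s\" reversible=\"false\">", .sid_rxn(rxn$id[j])),
        "<listOfReactants>",
        vapply(reac, function(s) sprintf(
          "<speciesReference species=\"%s\"/>", .sid_species(s)), ""),
        "</listOfReactants>",
        "<listOfProducts>",
        vapply(prod, function(s) sprintf(
          "<speciesReference species=\"%s\"/>", .sid_species(s)), ""),
        "</listOfProducts>",
        paste0("<kineticLaw>", kin, "</kineticLaw>"),
        "</reaction>")
    }))
    xml <- c(xml,
             "<listOfSpecies>", species_lines, "</listOfSpecies>",
             "<listOfParameters>", totals_params, rate_params,
             "</listOfParameters>",
             "<listOfReactions>", rxn_lines, "</listOfReactions>")
  } else {
    tabs <- .k1_tables(model)
    value_names <- c(.k1_states, "MKKK", "MKK", "MK")
    # reattach parameter names for MathML generation
    groups <- c(.k1_phospho_groups(), .k1_dephos_groups(model$topology))
    for (i in seq_along(tabs$compiled)) {
      g <- groups[[i]]
      tabs$compiled[[i]]$kcat_names <- vapply(g$members, `[[`, "", "kcat")
      tabs$compiled[[i]]$Km_names <- vapply(g$members, `[[`, "", "Km")
      tabs$compiled[[i]]$Kse_name <- g$Kse
      tabs$compiled[[i]]$phos_name <- paste0(g$enzyme, "_total")
      if (model$sequestration != "PSEQ") tabs$compiled[[i]]$seq_idx <-
        integer(0)
    }
    species_lines <- c(
      vapply(.k1_states, function(sp) sprintf(
        "<species id=\"%s\" compartment=\"cell\" initialConcentration=\"0\"/>",
        sp), ""),
      vapply(c("MKKK", "MKK", "MK"), function(sp) sprintf(
        paste0("<species id=\"%s\" compartment=\"cell\" ",
               "boundaryCondition=\"true\"/>"), sp), ""))
    par_lines <- c(totals_params,
                   param_line("Sig", t$Sig),
                   vapply(names(model$params), function(nm) param_line(
                     nm, model$params[[nm]]), ""))
    # d(state)/dt as signed sums of the group fluxes
    terms <- vector("list", 5)
    for (g in tabs$compiled) {
      fluxes <- .k1_group_mathml(g, value_names)
      for (m in seq_along(fluxes)) {
        for (s in seq_len(5)) {
          d <- g$delta[s, m]
          if (d == 0) next
          term <- if (d == 1) fluxes[[m]] else
            .mml_apply("times", .mml_cn(d), fluxes[[m]])
          terms[[s]] <- c(terms[[s]], term)
        }
      }
    }
    rule_lines <- unlist(lapply(seq_len(5), function(s) sprintf(
      "<rateRule variable=\"%s\">%s</rateRule>", .k1_states[s],
      .mml_math(.mml_apply("plus", paste0(terms[[s]], collapse = ""))))))
    assign_rules <- c(
      sprintf("<assignmentRule variable=\"MKKK\">%s</assignmentRule>",
              .mml_math(.mml_apply("minus", .mml_ci("MKKK_total"),
                                   .mml_ci("MKKK_P")))),
      sprintf("<assignmentRule variable=\"MKK\">%s</assignmentRule>",
              .mml_math(.mml_apply("minus", .mml_ci("MKK_total"),
                                   .mml_apply("plus", .mml_ci("MKK_P"),
                                              .mml_ci("MKK_PP"))))),
      sprintf("<assignmentRule variable=\"MK\">%s</assignmentRule>",
              .mml_math(.mml_apply("minus", .mml_ci("MK_total"),
                                   .mml_apply("plus", .mml_ci("MK_P"),
                                              .mml_ci("MK_PP"))))))
    xml <- c(xml,
             "<listOfSpecies>", species_lines, "</listOfSpecies>",
             "<listOfParameters>", par_lines, "</listOfParameters>",
             "<listOfRules>", assign_rules, rule_lines, "</listOfRules>")
  }
  xml <- c(xml, "</model>", "</sbml>")
  doc <- xml2::read_xml(paste0(xml, collapse = ""))
  xml2::write_xml(doc, path)
  invisible(path)
}

.k2_rate_param_id <- function(rxn_id, model) {
  kind <- sub("_.*$", "", rxn_id)
  rest <- sub("^[a-z]+_", "", rxn_id)
  switch(kind,
    bind = .sid_rxn(paste0("a_", rest)),
    diss = .sid_rxn(paste0("d_", rest)),
    cat = .sid_rxn(paste0("kcat_", rest)),
    seqrel = paste0("kr_seq__", sub("^.*\\.", "", rest)),
    seqbind = paste0("kf_seq__", sub("^.*\\.", "", rest)))
}

#' Import a cascade model from SBML
#'
#' Reconstructs a `mapk_model` from an SBML file. The package's own
#' exports are recognised through their annotation; other files are
#' handled best-effort by parsing the file stem for the
#' `M<i>_K<j>[_QSS]_<USEQ|PSEQ>` naming convention and reading the
#' parameter list. For K2 documents the reaction list is validated
#' against the network implied by the topology; a missing or unknown
#' reaction is reported by its conversion.
#'
#' @param path SBML file path.
#' @return A `mapk_model`.
#' @export
import_sbml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse failure in '", path, "': ", conditionMessage(e),
         call. = FALSE))
  ns <- c(s = .SBML_NS, ann = .ANN_NS)
  model_node <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(model_node, "xml_missing"))
    stop("no <model> element found (is this an SBML level 2 file?)",
         call. = FALSE)
  known <- c("annotation", "notes", "listOfCompartments", "listOfSpecies",
             "listOfParameters", "listOfReactions", "listOfRules",
             "listOfUnitDefinitions")
  kids <- unique(xml2::xml_name(xml2::xml_children(model_node)))
  unknown <- setdiff(kids, known)
  if (length(unknown))
    stop("unsupported SBML construct(s): ",
         paste0("<", unknown, ">", collapse = ", "), call. = FALSE)

  ann <- xml2::xml_find_first(model_node, ".//ann:model", ns)
  if (!inherits(ann, "xml_missing")) {
    topology <- xml2::xml_attr(ann, "topology")
    scheme <- xml2::xml_attr(ann, "scheme")
    sequestration <- xml2::xml_attr(ann, "sequestration")
  } else {
    stem <- sub("\\.xml$", "", basename(path), ignore.case = TRUE)
    m <- regmatches(stem, regexec(
      "^(M[1-4])_(K1|K2_QSS|K2)_(USEQ|PSEQ)", stem))[[1]]
    if (length(m) == 0)
      stop("cannot identify the model: no package annotation and the file ",
           "stem '", stem, "' does not follow the M<i>_K<j>_<SEQ> convention",
           call. = FALSE)
    topology <- m[2]; scheme <- m[3]; sequestration <- m[4]
  }

  pnodes <- xml2::xml_find_all(model_node, ".//s:parameter", ns)
  pvals <- stats::setNames(
    as.numeric(xml2::xml_attr(pnodes, "value")),
    xml2::xml_attr(pnodes, "id"))
  topo <- make_topology(topology)
  totals <- cascade_concentrations(
    MKKK_total = pvals[["MKKK_total"]], MKK_total = pvals[["MKK_total"]],
    MK_total = pvals[["MK_total"]], Phos1_total = pvals[["Phos1_total"]],
    Phos2_total = pvals[["Phos2_total"]],
    Phos3_total = if ("Phos3_total" %in% names(pvals))
      pvals[["Phos3_total"]] else NULL,
    Sig = pvals[["Sig_total"]])

  if (scheme == "K2") {
    conv <- k2_conversions(topo)
    get_rate <- function(prefix) {
      ids <- .sid_rxn(paste0(prefix, "_", conv$id))
      missing <- conv$id[!ids %in% names(pvals)]
      if (length(missing))
        stop("missing ", prefix, " rate for conversion(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      stats::setNames(pvals[ids], conv$id)
    }
    phs <- topo$phosphatases
    kf <- stats::setNames(pvals[paste0("kf_seq__", phs)], phs)
    kr <- stats::setNames(pvals[paste0("kr_seq__", phs)], phs)
    if (anyNA(kf)) kf <- 1
    if (anyNA(kr)) kr <- 0.06
    params <- k2_parameters(topo, a = get_rate("a"), d = get_rate("d"),
                            kcat = get_rate("kcat"),
                            kf_seq = kf, kr_seq = kr)
    model <- mapk_model(topo, "K2", sequestration, params, totals)
    # validate the document's reactions against the implied network
    expected <- .sid_rxn(build_k2_network(model)$reactions$id)
    found <- xml2::xml_attr(
      xml2::xml_find_all(model_node, ".//s:reaction", ns), "id")
    missing <- setdiff(expected, found)
    if (length(missing))
      stop("SBML document is missing reaction(s) required by the ",
           topology, " ", sequestration, " network: ",
           paste(missing, collapse = ", "), call. = FALSE)
    extra <- setdiff(found, expected)
    if (length(extra))
      stop("SBML document contains reaction(s) not in the ", topology,
           " ", sequestration, " network: ",
           paste(extra, collapse = ", "), call. = FALSE)
    return(model)
  }

  wanted <- k1_param_names(topo)
  missing <- setdiff(wanted, names(pvals))
  if (length(missing))
    stop("missing K1 parameter(s) in SBML document: ",
         paste(missing, collapse = ", "), call. = FALSE)
  params <- do.call(k1_parameters,
                    c(list(topology = topo), as.list(pvals[wanted])))
  mapk_model(topo, scheme, sequestration, params, totals)
}
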