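#' Cascade wiring tables for the four kinase-phosphatase designs
#'
#' The three-tier MAPK cascade (MKKK -> MKK -> MK) always uses the same
#' kinase-kinase interactions, but the four designs M1-M4 differ in which
#' phosphatase dephosphorylates which tier:
#'
#' \describe{
#'   \item{M1}{one dedicated phosphatase per tier: Phos1 (MKKK),
#'     Phos2 (MKK), Phos3 (MK).}
#'   \item{M2}{Phos1 shared by MKKK and MKK; Phos2 on MK.}
#'   \item{M3}{Phos1 on MKKK; Phos2 shared by MKK and MK.}
#'   \item{M4}{Phos1 on MKKK and MKK; Phos2 on MKK and MK -- the middle
#'     tier is served by both phosphatases.}
#' }
#'
#' @param name one of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#'
#' @return An object of class `mapk_topology`: a list with `name`,
#'   `dephosphorylation_map` (named list mapping layer `MKKK`/`MKK`/`MK`
#'   to a character vector of phosphatases) and `phosphatases` (all
#'   phosphatases present in the design).
#' @examples
#' make_topology("M4")$dephosphorylation_map$MKK
#' @export
make_topology <- function(name) {
  maps <- list(
    M1 = list(MKKK = "Phos1", MKK = "Phos2",               MK = "Phos3"),
    M2 = list(MKKK = "Phos1", MKK = "Phos1",               MK = "Phos2"),
    M3 = list(MKKK = "Phos1", MKK = "Phos2",               MK = "Phos2"),
    M4 = list(MKKK = "Phos1", MKK = c("Phos1", "Phos2"),   MK = "Phos2")
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(maps)) {
    stop("unknown topology ", deparse(name),
         "; valid names are: ", paste(names(maps), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(
      name = name,
      dephosphorylation_map = maps[[name]],
      phosphatases = sort(unique(unlist(maps[[name]])))
    ),
    class = "mapk_topology"
  )
}

#' @export
print.mapk_topology <- function(x, ...) {
  cat("MAPK cascade topology", x$name, "\n")
  for (layer in names(x$dephosphorylation_map)) {
    cat(sprintf("  %-4s dephosphorylated by %s\n", layer,
                paste(x$dephosphorylation_map[[layer]], collapse = " + ")))
  }
  invisible(x)
}

# layers served by a given phosphatase, in cascade order
layers_served <- function(topology, phosphatase) {
  layers <- names(topology$dephosphorylation_map)
  layers[vapply(topology$dephosphorylation_map,
                function(p) phosphatase %in% p, logical(1))]
}

# kinase layer names in cascade order; phosphoforms per layer
.layers <- c("MKKK", "MKK", "MK")
.phosphoforms <- list(
  MKKK = "MKKK_P",
  MKK  = c("MKK_P", "MKK_PP"),
  MK   = c("MK_P", "MK_PP")
)
# fully dephosphorylated (free) kinase of each layer
.base_form <- c(MKKK = "MKKK", MKK = "MKK", MK = "MK")
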