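#' Steady MKKK-P amplitude as a function of Phos2 concentration
#'
#' Sweeps the total Phos2 concentration and records the steady-state
#' MKKK-P amplitude under a sustained signal, all other parameters
#' fixed. In the M4 design this exposes the implicit negative feedback
#' from Phos2 to the MKKK layer (Phos2 never touches MKKK physically;
#' the coupling is mediated by Phos1/Phos2 competition for the
#' MKK-layer substrates). In M1-M3 the MKKK layer is decoupled from
#' Phos2 and the sweep leaves the amplitude unchanged.
#'
#' @param model a `mapk_model` (any topology; M4 is the design of
#'   interest).
#' @param phos2_grid Phos2 totals to sweep (nM); default 30 log-spaced
#'   points on \[1, 2000\].
#' @param protocol sustained [signal_protocol()] (default: the model's
#'   `Sig`).
#' @param amplitude_species species whose steady amplitude is recorded
#'   (default `"MKKK_P"`).
#' @return A data.frame of class `sweep_result` with columns
#'   `Phos2_total` and `amplitude`, plus a `config` attribute recording
#'   the full run configuration.
#' @export
phos2_amplitude_sweep <- function(model,
                                  phos2_grid = 10^seq(0, log10(2000),
                                                      length.out = 30),
                                  protocol = signal_protocol(model$totals$Sig),
                                  amplitude_species = "MKKK_P") {
  stopifnot(inherits(model, "mapk_model"))
  phos2_grid <- sort(phos2_grid)
  amp <- vapply(phos2_grid, function(p2) {
    m <- model
    m$totals$Phos2_total <- p2
    steady_state(m, protocol)[[amplitude_species]]
  }, numeric(1))
  res <- data.frame(Phos2_total = phos2_grid, amplitude = amp)
  attr(res, "config") <- list(
    model = sprintf("%s^%s_%s", model$topology$name, model$scheme,
                    model$sequestration),
    amplitude_species = amplitude_species, Sig = protocol$strength)
  class(res) <- c("sweep_result", "data.frame")
  res
}

#' Implicit-feedback strength versus sequestration strength
#'
#' For each sequestration strength in the grid, computes the difference
#' in steady MKKK-P amplitude between a low and a high Phos2
#' concentration (default 5 and 1000 nM), all other parameters fixed.
#' For K1/K2_QSS models the sequestration strength is the equilibrium
#' constant `Kse` applied to every sequestration term (smaller `Kse` =
#' stronger sequestration); for K2 models it is the sequestration
#' binding rate `kf_seq` (larger = stronger).
#'
#' @param model an M4 `mapk_model` in PSEQ mode.
#' @param kseq_grid sequestration strengths: `Kse` values (nM) for
#'   K1/K2_QSS (default 20 log-spaced points on \[1e-2, 1e4\]), binding
#'   rates (1/(nM s)) for K2 (default 20 log-spaced points on
#'   \[1e-4, 1e2\]).
#' @param phos2_low,phos2_high the two Phos2 totals compared (nM).
#' @param protocol sustained [signal_protocol()].
#' @return A data.frame of class `sweep_result` with columns
#'   `seq_strength`, `amp_low`, `amp_high`, `amp_difference`.
#' @export
kseq_feedback_sweep <- function(model, kseq_grid = NULL, phos2_low = 5,
                                phos2_high = 1000,
                                protocol = signal_protocol(model$totals$Sig)) {
  stopifnot(inherits(model, "mapk_model"))
  if (model$sequestration != "PSEQ")
    stop("kseq_feedback_sweep requires a PSEQ model", call. = FALSE)
  if (phos2_low >= phos2_high)
    stop("phos2_low must be below phos2_high", call. = FALSE)
  k2 <- model$scheme == "K2"
  if (is.null(kseq_grid))
    kseq_grid <- if (k2) 10^seq(-4, 2, length.out = 20)
                 else 10^seq(-2, 4, length.out = 20)
  set_strength <- function(m, s) {
    if (k2) {
      m$params$kf_seq[] <- s
    } else {
      p <- unclass(m$params)
      p[grepl("^Kse", names(p))] <- s
      m$params <- do.call(k1_parameters,
                          c(list(topology = m$topology), as.list(p)))
    }
    m
  }
  one <- function(s, p2) {
    m <- set_strength(model, s)
    m$totals$Phos2_total <- p2
    steady_state(m, protocol)[["MKKK_P"]]
  }
  amp_low <- vapply(kseq_grid, one, numeric(1), p2 = phos2_low)
  amp_high <- vapply(kseq_grid, one, numeric(1), p2 = phos2_high)
  res <- data.frame(seq_strength = kseq_grid, amp_low = amp_low,
                    amp_high = amp_high,
                    amp_difference = amp_low - amp_high)
  attr(res, "config") <- list(
    model = sprintf("%s^%s_%s", model$topology$name, model$scheme,
                    model$sequestration),
    strength_is = if (k2) "kf_seq (1/(nM s), larger = stronger)"
                  else "Kse (nM, smaller = stronger)",
    phos2_low = phos2_low, phos2_high = phos2_high, Sig = protocol$strength)
  class(res) <- c("sweep_result", "data.frame")
  res
}

# simulate a transient run, extending the horizon until the output has
# relaxed below its memory threshold (or the horizon cap is reached)
.simulate_relaxed <- function(model, protocol, output_species = "MK_PP",
                              baseline_fraction = 0.01, t_cap = 2e6,
                              n_out = 800) {
  t_end <- max(4 * protocol$t_off, protocol$t_off + 600)
  repeat {
    traj <- simulate_cascade(model, protocol, t_end, n_out = n_out)
    m <- output_metrics(traj, output_species, baseline_fraction)
    if (!m$censored || t_end >= t_cap) return(list(traj = traj, metrics = m))
    t_end <- min(t_end * 4, t_cap)
  }
}

#' Output memory under a transient signal
#'
#' Subjects each requested cascade design, in both USEQ and PSEQ
#' conditions, to a signal of identical strength and duration, and
#' tabulates the output metrics of MK-PP: peak amplitude, duration, and
#' memory (total time taken after signal removal for the output to
#' return to its unstimulated level).
#'
#' @param topologies topology names (default all four).
#' @param scheme kinetic scheme for all runs (default `"K1"`).
#' @param strength signal strength (nM, default 10).
#' @param duration signal duration (s, default 600).
#' @param sequestration conditions to include (default both).
#' @param baseline_fraction threshold fraction for the memory/duration
#'   metrics.
#' @param models optional list of pre-built `mapk_model` objects; if
#'   given, `topologies`/`scheme`/`sequestration` are ignored.
#' @return A data.frame with one row per model: `topology`, `scheme`,
#'   `sequestration`, `peak_amplitude`, `duration`, `memory`,
#'   `censored`.
#' @export
transient_memory_experiment <- function(topologies = c("M1", "M2", "M3", "M4"),
                                        scheme = "K1", strength = 10,
                                        duration = 600,
                                        sequestration = c("USEQ", "PSEQ"),
                                        baseline_fraction = 0.01,
                                        models = NULL) {
  if (is.null(models)) {
    grid <- expand.grid(topology = topologies, seq = sequestration,
                        stringsAsFactors = FALSE)
    models <- Map(function(tp, sq) default_model(tp, scheme, sq),
                  grid$topology, grid$seq)
  }
  protocol <- signal_protocol(strength, t_on = 0, t_off = duration)
  rows <- lapply(models, function(m) {
    if (strength == 0) {
      return(data.frame(topology = m$topology$name, scheme = m$scheme,
                        sequestration = m$sequestration, peak_amplitude = 0,
                        duration = 0, memory = 0, censored = FALSE))
    }
    res <- .simulate_relaxed(m, protocol,
                             baseline_fraction = baseline_fraction)
    data.frame(topology = m$topology$name, scheme = m$scheme,
               sequestration = m$sequestration,
               peak_amplitude = res$metrics$peak_amplitude,
               duration = res$metrics$duration,
               memory = res$metrics$memory,
               censored = res$metrics$censored)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- list(strength = strength, duration = duration,
                              baseline_fraction = baseline_fraction)
  out
}

#' Dose-response of output amplitude and duration
#'
#' Applies transient signals of varying strength but fixed duration and
#' records the peak amplitude and duration of the MK-PP output per
#' dose. The activation threshold (smallest strength whose amplitude
#' exceeds `threshold_fraction` of the saturation amplitude) is
#' attached as an attribute.
#'
#' @param model a `mapk_model`.
#' @param strength_grid signal strengths (nM); at least 3 points.
#' @param duration signal duration (s, default 600).
#' @param baseline_fraction threshold fraction for the duration metric.
#' @param threshold_fraction fraction of the saturation amplitude
#'   defining the activation threshold (default 0.05).
#' @param measure `"both"` (default) integrates each dose until the
#'   output has relaxed, yielding exact durations; `"amplitude"` stops
#'   shortly after signal removal and reports in-horizon durations only
#'   (sufficient for activation thresholds, much cheaper for strongly
#'   sequestrated models).
#' @return A data.frame of class `sweep_result` with columns `strength`,
#'   `peak_amplitude`, `duration`; attributes `activation_threshold` and
#'   `config`.
#' @export
dose_response <- function(model, strength_grid, duration = 600,
                          baseline_fraction = 0.01,
                          threshold_fraction = 0.05,
                          measure = c("both", "amplitude")) {
  stopifnot(inherits(model, "mapk_model"))
  measure <- match.arg(measure)
  if (length(strength_grid) < 3)
    stop("strength_grid needs at least 3 points", call. = FALSE)
  strength_grid <- sort(strength_grid)
  rows <- lapply(strength_grid, function(s) {
    if (s == 0)
      return(data.frame(strength = 0, peak_amplitude = 0, duration = 0))
    protocol <- signal_protocol(s, t_on = 0, t_off = duration)
    res <- if (measure == "amplitude") {
      traj <- simulate_cascade(model, protocol, t_end = duration * 2)
      list(metrics = output_metrics(traj, "MK_PP", baseline_fraction))
    } else {
      .simulate_relaxed(model, protocol,
                        baseline_fraction = baseline_fraction)
    }
    data.frame(strength = s, peak_amplitude = res$metrics$peak_amplitude,
               duration = res$metrics$duration)
  })
  res <- do.call(rbind, rows)
  sat <- max(res$peak_amplitude)
  thr_idx <- which(res$peak_amplitude > threshold_fraction * sat)
  attr(res, "activation_threshold") <-
    if (length(thr_idx)) res$strength[min(thr_idx)] else NA_real_
  attr(res, "config") <- list(
    model = sprintf("%s^%s_%s", model$topology$name, model$scheme,
                    model$sequestration),
    duration = duration, threshold_fraction = threshold_fraction)
  class(res) <- c("sweep_result", "data.frame")
  res
}
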