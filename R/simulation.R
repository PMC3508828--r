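#' Signal protocol
#'
#' The input signal `Sig` is applied at constant strength from `t_on`
#' until `t_off`; `t_off = Inf` gives a sustained signal. In K1/K2_QSS
#' models the signal is a piecewise-constant parameter; in K2 models it
#' is a species placed in the free state at `t_on` and clamped to zero at
#' `t_off` (bound signal in complexes runs to completion, mimicking
#' ligand removal).
#'
#' @param strength signal concentration (nM).
#' @param t_on onset time (s), default 0.
#' @param t_off removal time (s), `Inf` for sustained.
#' @return An object of class `signal_protocol`.
#' @export
signal_protocol <- function(strength, t_on = 0, t_off = Inf) {
  if (!is.numeric(strength) || strength < 0)
    stop("signal strength must be nonnegative", call. = FALSE)
  if (is.finite(t_off) && t_off <= t_on)
    stop("t_off must exceed t_on", call. = FALSE)
  structure(list(strength = strength, t_on = t_on, t_off = t_off,
                 sustained = !is.finite(t_off)),
            class = "signal_protocol")
}

.default_rtol <- 1e-8
.default_atol <- 1e-10

#' Integrate a cascade model under a signal protocol
#'
#' Uses a stiff solver (`deSolve::ode`, lsoda) with the integration
#' restarted at the signal-on and signal-off discontinuities so the
#' events are handled exactly.
#'
#' @param model a `mapk_model`.
#' @param protocol a [signal_protocol()].
#' @param t_end end of the integration (s).
#' @param n_out approximate number of output grid points.
#' @param rtol,atol solver tolerances.
#' @param y0 optional initial state (defaults to the fully
#'   unphosphorylated, unbound state).
#' @param compiled use the compiled derivative evaluator (default); the
#'   pure-R right-hand sides are used when `FALSE`.
#' @return An object of class `cascade_trajectory`: list with `time`,
#'   `species` (time x species matrix, nM), `model`, `protocol`,
#'   `solver`.
#' @export
simulate_cascade <- function(model, protocol, t_end,
                             n_out = 600, rtol = .default_rtol,
                             atol = .default_atol, y0 = NULL,
                             compiled = TRUE) {
  stopifnot(inherits(model, "mapk_model"), inherits(protocol, "signal_protocol"))
  if (t_end <= protocol$t_on)
    stop("t_end must exceed the signal onset time", call. = FALSE)
  engine <- .engine(model)
  k2 <- model$scheme == "K2"
  if (is.null(y0)) y0 <- initial_state(model)

  # segment boundaries at the protocol discontinuities
  bounds <- unique(sort(c(0, protocol$t_on,
                          if (is.finite(protocol$t_off))
                            min(protocol$t_off, t_end), t_end)))
  bounds <- bounds[bounds <= t_end]
  times_all <- numeric(0); out_all <- NULL
  y <- y0
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    sig_on <- a >= protocol$t_on &&
      (is.infinite(protocol$t_off) || a < protocol$t_off)
    sig_off <- FALSE
    if (k2) {
      if (a == protocol$t_on) y[["Sig"]] <- y[["Sig"]] + protocol$strength
      sig_off <- is.finite(protocol$t_off) && a >= protocol$t_off
      if (sig_off) y[["Sig"]] <- 0
    }
    npt <- max(20L, ceiling(n_out * (b - a) / t_end))
    times <- seq(a, b, length.out = npt + 1L)
    sol <- .engine_ode(engine, y, times,
                       sig = if (sig_on) protocol$strength else 0,
                       sig_off = sig_off, rtol = rtol, atol = atol,
                       compiled = compiled)
    if (attr(sol, "istate")[1] < 0)
      stop("solver failure in [", a, ", ", b, "] s; last state: ",
           paste(signif(y, 4), collapse = ", "), call. = FALSE)
    y <- stats::setNames(sol[nrow(sol), -1], engine$species)
    keep <- if (i == 1L) seq_len(nrow(sol)) else -1L
    times_all <- c(times_all, sol[keep, 1])
    out_all <- rbind(out_all, sol[keep, -1, drop = FALSE])
  }
  if (min(out_all) < -1e3 * atol - 1e-12)
    warning("negative concentration excursion: min = ", min(out_all))
  colnames(out_all) <- list_species(model)
  structure(list(time = times_all, species = out_all, model = model,
                 protocol = protocol,
                 solver = list(method = "lsoda", rtol = rtol, atol = atol)),
            class = "cascade_trajectory")
}

#' @export
print.cascade_trajectory <- function(x, ...) {
  cat(sprintf("<cascade_trajectory> %s^%s %s, t in [%g, %g] s, %d species\n",
              x$model$topology$name, x$model$scheme, x$model$sequestration,
              min(x$time), max(x$time), ncol(x$species)))
  invisible(x)
}

#' Steady state of a model under a sustained signal
#'
#' Integrates in doubling time chunks until the maximal derivative
#' magnitude falls below `tol`, then (for the five-variable K1/K2_QSS
#' schemes) polishes the state with a damped Newton iteration on the
#' right-hand side. Conservation pools are preserved throughout.
#'
#' @param model a `mapk_model`.
#' @param protocol a sustained [signal_protocol()].
#' @param tol convergence tolerance on `max |d/dt|` (nM/s).
#' @param t_chunk initial integration chunk length (s).
#' @param max_time total integration budget (s of model time).
#' @param rtol,atol solver tolerances.
#' @param y0 optional initial state.
#' @param compiled use the compiled derivative evaluator (default).
#' @return Named numeric vector: the steady species state, with
#'   attributes `max_deriv` and `t_reached`.
#' @export
steady_state <- function(model, protocol, tol = 1e-9, t_chunk = 2000,
                         max_time = 2e6, rtol = .default_rtol,
                         atol = .default_atol, y0 = NULL, compiled = TRUE) {
  stopifnot(inherits(protocol, "signal_protocol"))
  if (!protocol$sustained)
    stop("steady_state requires a sustained protocol", call. = FALSE)
  engine <- .engine(model)
  k2 <- model$scheme == "K2"
  if (is.null(y0)) {
    y <- initial_state(model)
    if (k2) y[["Sig"]] <- y[["Sig"]] + protocol$strength
  } else y <- y0

  sig <- protocol$strength
  maxd <- function(y) max(abs(.engine_deriv(engine, y, sig = sig)))
  t_now <- 0; chunk <- t_chunk
  while (maxd(y) >= tol) {
    if (t_now >= max_time)
      stop("steady state not reached within ", max_time,
           " s of model time (max |d/dt| = ", signif(maxd(y), 3), ")",
           call. = FALSE)
    sol <- .engine_ode(engine, y, c(t_now, t_now + chunk), sig = sig,
                       rtol = rtol, atol = atol, compiled = compiled)
    if (attr(sol, "istate")[1] < 0)
      stop("solver failure during steady-state search", call. = FALSE)
    y <- stats::setNames(sol[nrow(sol), -1], engine$species)
    t_now <- t_now + chunk
    chunk <- chunk * 2
  }
  if (!k2)
    y <- .newton_polish(y, function(v) .engine_deriv(engine, v, sig = sig),
                        tol)
  structure(y, max_deriv = maxd(y), t_reached = t_now)
}

# damped Newton with forward-difference Jacobian; returns the input
# unchanged if no step improves the residual
.newton_polish <- function(y, f, tol, max_iter = 8L) {
  n <- length(y)
  for (iter in seq_len(max_iter)) {
    r <- f(y)
    if (max(abs(r)) < tol * 1e-3) break
    J <- matrix(0, n, n)
    h <- pmax(abs(y), 1) * 1e-7
    for (j in seq_len(n)) {
      yp <- y; yp[j] <- yp[j] + h[j]
      J[, j] <- (f(yp) - r) / h[j]
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1; improved <- FALSE
    for (k in 1:6) {
      y_try <- y + lambda * step
      ok <- tryCatch(max(abs(f(y_try))) < max(abs(r)), error = function(e) FALSE)
      if (ok) { y <- y_try; improved <- TRUE; break }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  y
}

# total time a series spends above a threshold, with linear
# interpolation at the crossings
.time_above <- function(time, y, thr) {
  above <- y > thr
  if (!any(above)) return(0)
  total <- 0
  n <- length(time)
  for (i in seq_len(n - 1L)) {
    a <- above[i]; b <- above[i + 1L]
    dt <- time[i + 1L] - time[i]
    if (a && b) total <- total + dt
    else if (a != b) {
      frac <- (thr - y[i]) / (y[i + 1L] - y[i])
      total <- total + if (a) frac * dt else (1 - frac) * dt
    }
  }
  total
}

# last time a series is above a threshold (interpolated); -Inf if never
.last_time_above <- function(time, y, thr) {
  above <- y > thr
  if (!any(above)) return(-Inf)
  i <- max(which(above))
  if (i == length(time)) return(time[i])
  frac <- (thr - y[i]) / (y[i + 1L] - y[i])
  time[i] + frac * (time[i + 1L] - time[i])
}

#' Output metrics of a simulated trajectory
#'
#' Extracts the amplitude, duration and memory of an output species:
#' * `peak_amplitude`: maximum over the trajectory (nM);
#' * `steady_amplitude`: value at the end of the trajectory (the steady
#'   output of a sustained run);
#' * `duration`: total time the output exceeds
#'   `baseline_fraction * peak`;
#' * `memory` (bounded protocols only): the total time taken after
#'   signal removal for the output to return to its unstimulated level,
#'   measured as the last time the output exceeds
#'   `unstimulated + baseline_fraction * peak`, minus `t_off`, floored
#'   at 0.
#'
#' @param traj a `cascade_trajectory`.
#' @param output_species output species name (default `"MK_PP"`).
#' @param baseline_fraction relative threshold defining "unstimulated"
#'   (default 0.01, i.e. within 1% of the peak above baseline).
#' @return A list of class `output_metrics` with fields
#'   `peak_amplitude`, `steady_amplitude`, `duration`, `memory` (NA for
#'   sustained protocols), `baseline_fraction`, and `censored` (`TRUE`
#'   if the output was still above threshold at the end of the
#'   trajectory, i.e. `memory` is a lower bound).
#' @export
output_metrics <- function(traj, output_species = "MK_PP",
                           baseline_fraction = 0.01) {
  stopifnot(inherits(traj, "cascade_trajectory"))
  if (!output_species %in% colnames(traj$species))
    stop("species '", output_species, "' not in trajectory", call. = FALSE)
  y <- pmax(traj$species[, output_species], 0)
  time <- traj$time
  peak <- max(y)
  baseline <- y[1]
  thr <- baseline + baseline_fraction * peak
  p <- traj$protocol
  out <- list(
    peak_amplitude = peak,
    steady_amplitude = y[length(y)],
    duration = if (peak > 0) .time_above(time, y, baseline_fraction * peak)
               else 0,
    memory = NA_real_,
    baseline_fraction = baseline_fraction,
    censored = FALSE
  )
  if (!p$sustained) {
    last <- .last_time_above(time, y, thr)
    out$memory <- max(0, last - p$t_off)
    out$censored <- is.finite(last) && last >= time[length(time)] - 1e-9
  }
  structure(out, class = "output_metrics")
}

#' @export
print.output_metrics <- function(x, ...) {
  cat(sprintf(paste0("output metrics: peak %.4g nM, steady %.4g nM, ",
                     "duration %.4g s, memory %s s%s\n"),
              x$peak_amplitude, x$steady_amplitude, x$duration,
              if (is.na(x$memory)) "NA" else sprintf("%.4g", x$memory),
              if (x$censored) " (censored)" else ""))
  invisible(x)
}
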