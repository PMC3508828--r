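#' Total parameter variation
#'
#' Sum of absolute log10 fold-changes of the perturbed parameters
#' relative to their reference values:
#' \deqn{TPV = \sum_{n=1}^{L} |\log_{10}(k_n / k_{n0})|}
#'
#' @param perturbed,reference positive numeric vectors of equal length.
#' @return TPV (dimensionless, >= 0).
#' @export
total_parameter_variation <- function(perturbed, reference) {
  if (length(perturbed) != length(reference) || length(perturbed) < 1)
    stop("perturbed and reference must be equal-length, nonempty",
         call. = FALSE)
  if (any(perturbed <= 0) || any(reference <= 0))
    stop("parameters must be positive", call. = FALSE)
  sum(abs(log10(perturbed / reference)))
}

#' Robustness coefficient of a model output
#'
#' Minus the mean absolute log10 ratio of perturbed to reference output
#' over N perturbation simulations:
#' \deqn{R = -\frac{1}{N}\sum_{p=1}^{N} |\log_{10}(f_p / f_0)|}
#' R is nonpositive; values closer to zero indicate a more robust
#' system. Outputs that collapse below `floor` are floored to keep the
#' logarithm finite; the number of floored simulations is recorded in
#' the `"n_floored"` attribute.
#'
#' @param f_perturbed outputs under perturbation (nM).
#' @param f_reference output of the unperturbed system (nM, > 0).
#' @param floor lower floor applied to `f_perturbed` (nM).
#' @return R (dimensionless, <= 0) with attribute `n_floored`.
#' @export
robustness_coefficient <- function(f_perturbed, f_reference, floor = 1e-12) {
  if (length(f_reference) != 1 || !is.finite(f_reference) || f_reference <= 0)
    stop("f_reference must be a single positive number", call. = FALSE)
  if (length(f_perturbed) < 1)
    stop("need at least one perturbed output", call. = FALSE)
  n_floored <- sum(f_perturbed < floor)
  f <- pmax(f_perturbed, floor)
  structure(-mean(abs(log10(f / f_reference))), n_floored = n_floored)
}

#' Robustness difference between sequestrated and unsequestrated runs
#'
#' `R_pseq - R_useq` for the same perturbation experiment; positive
#' values mean the sequestrated condition is the more robust one.
#'
#' @param R_pseq,R_useq robustness coefficients (<= 0).
#' @return The difference (dimensionless).
#' @examples
#' robustness_difference(-0.4, -4.55)   # 4.15
#' @export
robustness_difference <- function(R_pseq, R_useq) {
  R_pseq - R_useq
}

#' Perturbation specification for robustness analysis
#'
#' Defines which quantities are varied and how the Latin-hypercube
#' sample is drawn: each varied quantity gets a grid of `n_strata`
#' equidistant values spanning `fold_range` times its reference value,
#' and each of the `n_simulations` perturbed parameter sets draws one
#' grid value per quantity uniformly at random.
#'
#' @param vary one of `"kinases"`, `"phosphatases"`, `"kinases+sig"`,
#'   `"phosphatases+sig"`, `"kinetic"`.
#' @param fold_range `c(low, high)` multipliers (default `c(0.1, 10)`).
#' @param n_strata number of equidistant strata (default 2000).
#' @param n_simulations number of perturbed simulations (default 5000).
#' @param seed integer seed for reproducible sampling.
#' @param include_kse whether `"kinetic"` variation also perturbs the
#'   sequestration constants/rates (default `FALSE`).
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(vary = c("kinases", "phosphatases",
                                       "kinases+sig", "phosphatases+sig",
                                       "kinetic"),
                              fold_range = c(0.1, 10), n_strata = 2000,
                              n_simulations = 5000, seed = 1,
                              include_kse = FALSE) {
  vary <- match.arg(vary)
  if (length(fold_range) != 2 || fold_range[1] > fold_range[2] ||
      any(fold_range <= 0))
    stop("fold_range must be c(low, high) with 0 < low <= high",
         call. = FALSE)
  if (n_strata < 1 || n_simulations < 1)
    stop("n_strata and n_simulations must be positive", call. = FALSE)
  structure(list(vary = vary, fold_range = fold_range, n_strata = n_strata,
                 n_simulations = n_simulations, seed = as.integer(seed),
                 include_kse = include_kse),
            class = "perturbation_spec")
}

# reference values of the quantities a spec varies, for a given model
varied_reference <- function(model, spec) {
  t <- model$totals
  conc <- switch(sub("\\+sig$", "", spec$vary),
    kinases = c(MKKK_total = t$MKKK_total, MKK_total = t$MKK_total,
                MK_total = t$MK_total),
    phosphatases = {
      v <- c(Phos1_total = t$Phos1_total, Phos2_total = t$Phos2_total)
      if (!is.null(t$Phos3_total)) v <- c(v, Phos3_total = t$Phos3_total)
      v
    },
    kinetic = NULL)
  if (spec$vary == "kinetic") {
    if (model$scheme == "K2") {
      p <- model$params
      ref <- c(stats::setNames(p$a, paste0("a.", names(p$a))),
               stats::setNames(p$d, paste0("d.", names(p$d))),
               stats::setNames(p$kcat, paste0("kcat.", names(p$kcat))))
      if (spec$include_kse)
        ref <- c(ref,
                 stats::setNames(p$kf_seq, paste0("kf_seq.", names(p$kf_seq))),
                 stats::setNames(p$kr_seq, paste0("kr_seq.", names(p$kr_seq))))
      return(ref)
    }
    p <- unclass(model$params)
    if (!spec$include_kse) p <- p[!grepl("^Kse", names(p))]
    return(p)
  }
  if (grepl("\\+sig$", spec$vary)) conc <- c(conc, Sig = t$Sig)
  conc
}

#' Latin-hypercube sample of perturbed parameter vectors
#'
#' For each varied quantity, builds a grid of `n_strata` equidistant
#' values (linear spacing) on `fold_range * reference` and draws, for
#' each of the `n_simulations` simulations, one grid value per quantity
#' uniformly at random. The draw is reproducible by `spec$seed` and
#' leaves the caller's RNG stream untouched.
#'
#' @param spec a [perturbation_spec()].
#' @param reference named vector of positive reference values.
#' @return A `n_simulations` x `length(reference)` matrix with the
#'   reference names as column names.
#' @export
lhs_sample <- function(spec, reference) {
  stopifnot(inherits(spec, "perturbation_spec"), length(reference) >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_simulations
  out <- vapply(reference, function(ref) {
    grid <- if (spec$n_strata == 1L) (spec$fold_range[1] +
                                        spec$fold_range[2]) / 2 * ref
            else seq(spec$fold_range[1] * ref, spec$fold_range[2] * ref,
                     length.out = spec$n_strata)
    grid[sample.int(length(grid), n, replace = TRUE)]
  }, numeric(n))
  if (n == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL,
                                                            names(reference)))
  out
}

# apply a named vector of perturbed quantities to a model, returning the
# perturbed model (totals and/or parameters replaced)
apply_perturbation <- function(model, values) {
  t <- model$totals
  p <- model$params
  for (nm in names(values)) {
    v <- unname(values[[nm]])
    if (nm %in% names(t)) {
      t[[nm]] <- v
    } else if (model$scheme == "K2") {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      key <- paste(parts[-1], collapse = ".")
      p[[parts[1]]][[key]] <- v
    } else {
      p[[nm]] <- v
    }
  }
  model$totals <- t
  model$params <- p
  model
}

#' Run a robustness experiment
#'
#' Computes the reference steady-state output `f_0` under a sustained
#' signal, then the perturbed outputs `f_p` for `n_simulations`
#' Latin-hypercube draws, and summarises them as the robustness
#' coefficient. The per-simulation total parameter variation (TPV) and
#' output ratios are returned alongside. Failed integrations are retried
#' once with a larger time budget, then excluded; more than 1% failures
#' aborts the run.
#'
#' @param model a `mapk_model`.
#' @param spec a [perturbation_spec()].
#' @param output output species (default `"MK_PP"`).
#' @param steady_tol steady-state tolerance passed to the integrator
#'   (max |d/dt|, nM/s).
#' @param floor output floor forwarded to [robustness_coefficient()].
#' @return An object of class `robustness_result`: list with
#'   `robustness_coefficient`, `tpv`, `output_ratio`, `f_reference`,
#'   `n_failed`, `n_floored`, `spec`, and `model_id`.
#' @export
run_robustness <- function(model, spec, output = "MK_PP",
                           steady_tol = 1e-6, floor = 1e-12,
                           rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(model, "mapk_model"), inherits(spec, "perturbation_spec"))
  reference <- varied_reference(model, spec)
  draws <- lhs_sample(spec, reference)
  evaluate <- .steady_output_evaluator(model, output, steady_tol, rtol, atol)
  f0 <- evaluate(reference)
  if (!is.finite(f0) || f0 <= 0)
    stop("reference steady output is not positive; robustness undefined",
         call. = FALSE)
  fp <- rep(NA_real_, nrow(draws))
  for (i in seq_len(nrow(draws))) {
    v <- draws[i, ]
    fp[i] <- tryCatch(evaluate(v), error = function(e) NA_real_)
    if (is.na(fp[i]))
      fp[i] <- tryCatch(evaluate(v, retry = TRUE), error = function(e)
        NA_real_)
  }
  failed <- is.na(fp)
  if (mean(failed) > 0.01)
    stop(sum(failed), " of ", length(fp),
         " perturbed simulations failed to converge", call. = FALSE)
  R <- robustness_coefficient(fp[!failed], f0, floor = floor)
  tpv <- apply(draws, 1, total_parameter_variation, reference = reference)
  structure(
    list(robustness_coefficient = as.numeric(R),
         tpv = tpv, output_ratio = fp / f0, f_reference = f0,
         n_failed = sum(failed), n_floored = attr(R, "n_floored"),
         spec = spec,
         model_id = sprintf("%s^%s_%s", model$topology$name, model$scheme,
                            model$sequestration)),
    class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("robustness of %s under %s variation: R = %.4g (N = %d%s)\n",
              x$model_id, x$spec$vary, x$robustness_coefficient,
              length(x$tpv) - x$n_failed,
              if (x$n_floored > 0) paste0(", ", x$n_floored, " floored")
              else ""))
  invisible(x)
}

# returns function(values, retry = FALSE) -> steady output under the
# perturbation given by the named vector `values`. For K2 the reaction
# network and its compiled parameter vector are built once; only rate
# constants and initial conditions are patched per draw.
.steady_output_evaluator <- function(model, output, steady_tol, rtol, atol) {
  protocol_for <- function(m) signal_protocol(m$totals$Sig)
  if (model$scheme != "K2") {
    return(function(values, retry = FALSE) {
      m <- apply_perturbation(model, values)
      ss <- steady_state(m, protocol_for(m), tol = steady_tol,
                         t_chunk = if (retry) 20000 else 2000,
                         max_time = if (retry) 2e7 else 2e6,
                         rtol = rtol, atol = atol)
      ss[[output]]
    })
  }
  engine <- .engine(model)
  network <- build_k2_network(model)
  rxn <- network$reactions
  species <- network$species
  i1 <- match(rxn$reactant1, species)
  i2 <- match(rxn$reactant2, species)
  bi <- !is.na(i2)
  S <- network$stoichiometry
  k0 <- rxn$rate_constant
  # reaction id -> underlying parameter name ("a.<conv>", "kf_seq.<ph>", ...)
  conv <- k2_conversions(model$topology)
  par_of_rxn <- character(nrow(rxn))
  par_of_rxn[match(paste0("bind_", conv$id), rxn$id)] <-
    paste0("a.", conv$id)
  par_of_rxn[match(paste0("diss_", conv$id), rxn$id)] <-
    paste0("d.", conv$id)
  par_of_rxn[match(paste0("cat_", conv$id), rxn$id)] <-
    paste0("kcat.", conv$id)
  if (model$sequestration == "PSEQ") {
    pairs <- k2_seq_pairs(model$topology)
    par_of_rxn[match(paste0("seqrel_", pairs$id), rxn$id)] <-
      paste0("kr_seq.", pairs$phosphatase)
    par_of_rxn[match(paste0("seqbind_", pairs$id), rxn$id)] <-
      paste0("kf_seq.", pairs$phosphatase)
  }
  out_idx <- match(output, species)
  n_rxn <- nrow(rxn)
  deriv_max <- function(y, k) {
    rates <- k * y[i1]
    rates[bi] <- rates[bi] * y[i2[bi]]
    max(abs(S %*% rates))
  }
  function(values, retry = FALSE) {
    k <- k0
    kin_nms <- intersect(names(values), names(model$totals))
    par_nms <- setdiff(names(values), kin_nms)
    if (length(par_nms)) {
      idx <- match(par_of_rxn, par_nms)
      hit <- !is.na(idx)
      k[hit] <- values[par_nms][idx[hit]]
    }
    base <- engine$base
    base[3 + seq_len(n_rxn)] <- k
    y <- initial_state(model)
    t <- model$totals
    for (nm in kin_nms) t[[nm]] <- unname(values[[nm]])
    y["MKKK"] <- t$MKKK_total; y["MKK"] <- t$MKK_total; y["MK"] <- t$MK_total
    for (ph in model$topology$phosphatases)
      y[ph] <- t[[paste0(ph, "_total")]]
    y["Sig"] <- t$Sig
    t_now <- 0; chunk <- if (retry) 20000 else 2000
    max_time <- if (retry) 2e7 else 2e6
    while (deriv_max(y, k) >= steady_tol) {
      if (t_now >= max_time)
        stop("steady state not reached", call. = FALSE)
      sol <- .engine_ode(engine, y, c(t_now, t_now + chunk),
                         rtol = rtol, atol = atol, base = base)
      if (attr(sol, "istate")[1] < 0)
        stop("solver failure", call. = FALSE)
      y <- sol[nrow(sol), -1]
      t_now <- t_now + chunk
      chunk <- chunk * 2
    }
    y[[out_idx]]
  }
}
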