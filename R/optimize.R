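#' Chi-squared divergence between two current traces
#'
#' Mean squared pointwise difference, \eqn{\chi^2 = N^{-1}\sum_k (a_k -
#' b_k)^2}, normalized to the number of sampling points. Symmetric,
#' non-negative, zero iff the traces are identical.
#'
#' @param a,b [current_trace()] objects or numeric vectors of equal length.
#' @return Scalar divergence.
#' @export
#' @examples
#' chi2_divergence(c(1, 2), c(1, 4))
chi2_divergence <- function(a, b) {
  av <- if (is.list(a)) a$samples else as.numeric(a)
  bv <- if (is.list(b)) b$samples else as.numeric(b)
  if (length(av) != length(bv)) stop("traces have different lengths")
  mean((av - bv)^2)
}

#' Model-discrimination cost of a coefficient set
#'
#' Synthesizes the candidate waveform, enforces the peak-to-peak amplitude
#' bound, simulates both models from equilibrium at the holding potential,
#' and returns the chi-squared divergence of the two predicted currents.
#' This is the quantity the genetic algorithm maximizes for protocol design.
#'
#' @param coeffs A [wavelet_coeffs()].
#' @param model_a,model_b [channel_model()]s sharing the simulation settings.
#' @param v_hold Holding potential (mV); also the synthesis offset, so the
#'   pulse fluctuates about the hold.
#' @param v_rev Reversal potential (mV).
#' @param dt Sample interval (ms).
#' @param max_pp Peak-to-peak bound (mV).
#' @param thermal_voltage kT/e (mV).
#' @param quantum Propagator cache quantum (mV).
#' @return Scalar divergence (to maximize).
#' @export
divergence_cost <- function(coeffs, model_a, model_b, v_hold = -90,
                            v_rev = -90, dt = 0.01, max_pp = 200,
                            thermal_voltage = waveclamp::thermal_voltage(),
                            quantum = 0.001) {
  wf <- enforce_amplitude(synthesize(coeffs, dt = dt, offset = v_hold), max_pp)
  sa <- simulate_current(model_a, wf, v_hold, v_rev, thermal_voltage,
                         keep_trajectory = FALSE, quantum = quantum)
  sb <- simulate_current(model_b, wf, v_hold, v_rev, thermal_voltage,
                         keep_trajectory = FALSE, quantum = quantum)
  chi2_divergence(sa$current, sb$current)
}

#' Kinetic-focusing cost of a coefficient set
#'
#' Time-averaged occupancy of a chosen conformational state over a time
#' window, under the synthesized (amplitude-constrained) waveform. Maximizing
#' it designs pulses that focus the channel ensemble into that state.
#'
#' @param coeffs A [wavelet_coeffs()].
#' @param model A [channel_model()].
#' @param target_state State label to focus into.
#' @param window Length-2 numeric, time window in ms (relative to the pulse
#'   start); must have positive length. `NULL` averages over the whole pulse.
#' @inheritParams divergence_cost
#' @return Mean occupancy in \[0, 1\].
#' @export
occupancy_cost <- function(coeffs, model, target_state, window = NULL,
                           v_hold = -90, dt = 0.01, max_pp = 200,
                           thermal_voltage = waveclamp::thermal_voltage(),
                           quantum = 0.001) {
  if (!target_state %in% model$states) stop("unknown target state")
  wf <- enforce_amplitude(synthesize(coeffs, dt = dt, offset = v_hold), max_pp)
  p0 <- equilibrium(model, v_hold, thermal_voltage)
  traj <- propagate(model, wf, p0, thermal_voltage, quantum)
  t <- time_axis(wf) - wf$t0
  keep <- if (is.null(window)) rep(TRUE, length(t)) else {
    if (length(window) != 2L || diff(window) <= 0) stop("window must have positive length")
    t >= window[1L] & t < window[2L]
  }
  if (!any(keep)) stop("window contains no samples")
  mean(traj[match(target_state, model$states), keep])
}

#' Multiplicative mutation of a coefficient set
#'
#' Produces one daughter set by perturbing every coefficient independently:
#' \eqn{T \to T\,(1 + E_0\, e^{-Rn} (X - 1/2))} with X ~ Uniform(0,1) drawn
#' per coefficient from the current R RNG stream, n the generation index.
#' The perturbation envelope shrinks geometrically with generations, so the
#' search narrows as it converges.
#'
#' @param parent A [wavelet_coeffs()].
#' @param generation Generation index n >= 0.
#' @param E0 Initial perturbation range.
#' @param R Narrowing rate per generation.
#' @param mutate_coarse Perturb the coarse term too? (Default: details only.)
#' @param levels Optional integer vector of levels to perturb (for
#'   level-by-level optimization); `NULL` perturbs all.
#' @return A daughter [wavelet_coeffs()].
#' @export
mutate_coeffs <- function(parent, generation, E0 = 0.5, R = 0.0004,
                          mutate_coarse = FALSE, levels = NULL) {
  stopifnot(generation >= 0, E0 > 0, R >= 0)
  env <- E0 * exp(-R * generation)
  detail <- parent$detail
  which_levels <- if (is.null(levels)) seq_len(parent$n_levels) else levels
  for (m in which_levels) {
    d <- detail[[m]]
    detail[[m]] <- d * (1 + env * (runif(length(d)) - 0.5))
  }
  coarse <- parent$coarse
  if (mutate_coarse)
    coarse <- coarse * (1 + env * (runif(length(coarse)) - 0.5))
  wavelet_coeffs(detail, coarse, parent$family, parent$n_samples)
}

#' Genetic-algorithm search over wavelet coefficients
#'
#' Generic engine: per generation, `n_daughters` candidates are produced from
#' the incumbent parent by [mutate_coeffs()]; the candidate maximizing
#' `cost_fn` becomes the next parent. With `elitism = TRUE` the incumbent
#' parent competes too, so the best cost is monotone non-decreasing; with
#' `elitism = FALSE` selection is among the daughters only (the literal
#' published scheme) and the cost may fluctuate. Fully reproducible for a
#' fixed `seed`.
#'
#' @param initial A [wavelet_coeffs()] starting point.
#' @param cost_fn Function `wavelet_coeffs -> scalar` to maximize.
#' @param n_generations Number of generations.
#' @param n_daughters Daughters per generation (2..64).
#' @param E0,R Perturbation schedule, see [mutate_coeffs()].
#' @param elitism Keep the parent in the candidate pool?
#' @param mode `"all"` perturbs every level each generation;
#'   `"by-level"` cycles through the levels, one per generation.
#' @param mutate_coarse Perturb the coarse term too?
#' @param seed Integer seed; if `NULL` the current RNG state is used.
#' @return An object of class `ga_result`: `best_coeffs`, `best_cost`,
#'   `cost_history` (per-generation best), `n_evaluations`, and the
#'   configuration.
#' @export
run_ga <- function(initial, cost_fn, n_generations = 500, n_daughters = 16,
                   E0 = 0.5, R = 0.0004, elitism = TRUE,
                   mode = c("all", "by-level"), mutate_coarse = FALSE,
                   seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(initial, "wavelet_coeffs"),
            n_daughters >= 2, n_daughters <= 64, n_generations >= 1)
  if (!is.null(seed)) set.seed(seed)
  parent <- initial
  parent_cost <- tryCatch(cost_fn(parent), error = function(e)
    stop("cost functional failed on the initial coefficients: ",
         conditionMessage(e)))
  history <- numeric(n_generations)
  n_eval <- 1L
  for (gen in seq_len(n_generations)) {
    levels <- if (mode == "by-level")
      ((gen - 1L) %% initial$n_levels) + 1L else NULL
    best_cost <- if (elitism) parent_cost else -Inf
    best <- if (elitism) parent else NULL
    for (d in seq_len(n_daughters)) {
      cand <- mutate_coeffs(parent, gen - 1L, E0, R, mutate_coarse, levels)
      cost <- tryCatch(cost_fn(cand), error = function(e)
        stop(sprintf("cost functional failed at generation %d, daughter %d: %s",
                     gen, d, conditionMessage(e))))
      n_eval <- n_eval + 1L
      if (cost > best_cost) { best_cost <- cost; best <- cand }
    }
    parent <- best
    parent_cost <- best_cost
    history[gen] <- best_cost
  }
  structure(list(best_coeffs = parent, best_cost = parent_cost,
                 cost_history = history, n_evaluations = n_eval,
                 config = list(n_generations = n_generations,
                               n_daughters = n_daughters, E0 = E0, R = R,
                               elitism = elitism, mode = mode,
                               mutate_coarse = mutate_coarse),
                 seed = seed),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> %d generations x %d daughters, best cost %.6g\n",
              x$config$n_generations, x$config$n_daughters, x$best_cost))
  invisible(x)
}

#' Design an optimized voltage-clamp protocol
#'
#' The package's main entry point. Starting from random wavelet coefficients,
#' a genetic algorithm tunes the coefficient set so that the synthesized,
#' amplitude-constrained voltage pulse either (objective `"divergence"`)
#' maximizes the chi-squared divergence between the currents predicted by two
#' competing gating models — yielding a stimulus that discriminates between
#' them — or (objective `"occupancy"`) maximizes the occupancy of a chosen
#' conformational state (kinetic focusing).
#'
#' @param model_a A [channel_model()].
#' @param model_b Second model (divergence objective only).
#' @param objective `"divergence"` or `"occupancy"`.
#' @param target_state,window Occupancy objective: state label and time
#'   window in ms (see [occupancy_cost()]).
#' @param family Wavelet family, `"haar"` or `"db8"`.
#' @param n_levels Number of dyadic levels in the pulse (8-10 typical).
#' @param n_samples Pulse length in samples; power of two >= `2^n_levels`.
#' @param dt Sample interval in ms.
#' @param v_hold Holding potential (mV): equilibration point and pulse
#'   baseline.
#' @param v_rev Reversal potential (mV).
#' @param max_pp Peak-to-peak amplitude bound (mV).
#' @param init_scale Half-width of the initial uniform coefficient draw.
#' @param n_generations,n_daughters,E0,R,elitism,mode GA settings, see
#'   [run_ga()].
#' @param seed Integer seed for full reproducibility.
#' @param thermal_voltage kT/e in mV.
#' @param quantum Propagator cache quantum (mV).
#' @return An object of class `protocol_design`: the optimized waveform
#'   (`waveform`), its coefficients (`coeffs`, also via [coef()]), the cost
#'   history, the final cost, and the full configuration.
#' @export
#' @examples
#' \donttest{
#' a <- shaker_model("zha_a"); d <- shaker_model("zha_d")
#' des <- design_protocol(a, d, n_levels = 4, n_samples = 16, dt = 0.1,
#'                        n_generations = 20, seed = 1)
#' print(des)
#' }
design_protocol <- function(model_a, model_b = NULL,
                            objective = c("divergence", "occupancy"),
                            target_state = NULL, window = NULL,
                            family = c("db8", "haar"), n_levels = 8,
                            n_samples = 2^10, dt = 0.01,
                            v_hold = -90, v_rev = -90, max_pp = 200,
                            init_scale = 100, n_generations = 500,
                            n_daughters = 16, E0 = 0.5, R = 0.0004,
                            elitism = TRUE, mode = c("all", "by-level"),
                            seed = NULL,
                            thermal_voltage = waveclamp::thermal_voltage(),
                            quantum = 0.001) {
  objective <- match.arg(objective)
  family <- match.arg(family)
  mode <- match.arg(mode)
  if (objective == "divergence" && is.null(model_b))
    stop("the divergence objective needs two models")
  if (objective == "occupancy" && is.null(target_state))
    stop("the occupancy objective needs a target state")
  if (!is.null(seed)) set.seed(seed)
  initial <- random_coeffs(family, n_levels, n_samples, scale = init_scale)
  cost_fn <- if (objective == "divergence") {
    function(coeffs) divergence_cost(coeffs, model_a, model_b, v_hold, v_rev,
                                     dt, max_pp, thermal_voltage, quantum)
  } else {
    function(coeffs) occupancy_cost(coeffs, model_a, target_state, window,
                                    v_hold, dt, max_pp, thermal_voltage,
                                    quantum)
  }
  ga <- run_ga(initial, cost_fn, n_generations, n_daughters, E0, R, elitism,
               mode, seed = NULL)  # RNG already seeded above
  wf <- enforce_amplitude(synthesize(ga$best_coeffs, dt = dt, offset = v_hold),
                          max_pp)
  structure(list(objective = objective,
                 models = c(model_a$name, if (!is.null(model_b)) model_b$name),
                 target_state = target_state,
                 coeffs = ga$best_coeffs, waveform = wf,
                 best_cost = ga$best_cost, cost_history = ga$cost_history,
                 peak_to_peak = peak_to_peak(wf),
                 config = c(ga$config,
                            list(family = family, n_levels = n_levels,
                                 n_samples = n_samples, dt = dt,
                                 v_hold = v_hold, v_rev = v_rev,
                                 max_pp = max_pp, init_scale = init_scale,
                                 thermal_voltage = thermal_voltage)),
                 seed = seed),
            class = "protocol_design")
}

#' @export
print.protocol_design <- function(x, ...) {
  cat(sprintf("<protocol_design> %s%s\n", x$objective,
              if (x$objective == "divergence")
                sprintf(" (%s vs %s)", x$models[1L], x$models[2L])
              else sprintf(" (%s, state %s)", x$models[1L], x$target_state)))
  cat(sprintf("  %s wavelets, %d levels, %d samples @ %g ms\n",
              x$config$family, x$config$n_levels, x$config$n_samples,
              x$config$dt))
  cat(sprintf("  final cost %.6g after %d generations; pulse peak-to-peak %.1f mV\n",
              x$best_cost, x$config$n_generations, x$peak_to_peak))
  invisible(x)
}

#' @export
summary.protocol_design <- function(object, ...) {
  print(object)
  h <- object$cost_history
  cat(sprintf("  cost history: start %.4g, median %.4g, final %.4g\n",
              h[1L], stats::median(h), h[length(h)]))
  cat(sprintf("  seed: %s\n", if (is.null(object$seed)) "none" else object$seed))
  invisible(object)
}

#' @export
coef.protocol_design <- function(object, ...) object$coeffs

#' @export
plot.protocol_design <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(seq_along(x$cost_history), x$cost_history, type = "l",
       xlab = "generation", ylab = "best cost", main = "GA convergence")
  plot(x$waveform, main = "optimized pulse")
  invisible(x)
}
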