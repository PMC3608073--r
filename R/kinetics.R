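#' Thermal voltage kT/e
#'
#' The voltage scale of gating-charge movement, \eqn{V_T = kT/e}, in mV.
#' Recordings of the shipped models are anchored at 12 degrees C, for which
#' \eqn{V_T \approx 24.57} mV; this is the package default wherever a
#' `thermal_voltage` argument appears.
#'
#' @param temp_c Temperature in degrees Celsius.
#' @return Thermal voltage in mV.
#' @export
#' @examples
#' thermal_voltage(12)
thermal_voltage <- function(temp_c = 12) {
  0.08617333262 * (273.15 + temp_c)   # k_B/e in mV/K
}

#' Evaluate a voltage-dependent rate
#'
#' \eqn{\alpha(V) = \alpha(0)\,\exp(qV/V_T)}.
#'
#' @param law A [rate_law()].
#' @param V Membrane potential(s) in mV.
#' @param thermal_voltage kT/e in mV.
#' @return Rate(s) in 1/ms; strictly positive.
#' @export
#' @examples
#' rate_at(rate_law(0.1219, 0.6232), 0)
rate_at <- function(law, V, thermal_voltage = waveclamp::thermal_voltage()) {
  stopifnot(inherits(law, "rate_law"), all(is.finite(V)), thermal_voltage > 0)
  law$amplitude * exp(law$charge * V / thermal_voltage)
}

#' Transition-rate generator matrix at a fixed voltage
#'
#' Assembles the generator W(V) of the master equation dP/dt = W P: the
#' off-diagonal entry (j, i) is the multiplicity-weighted rate of the i -> j
#' transition, and each diagonal entry is minus the total rate leaving that
#' state, so every column sums to zero.
#'
#' @param model A [channel_model()].
#' @param V Membrane potential in mV (scalar).
#' @param thermal_voltage kT/e in mV.
#' @return n x n numeric matrix in 1/ms, with state labels as dimnames.
#' @export
transition_matrix <- function(model, V, thermal_voltage = waveclamp::thermal_voltage()) {
  stopifnot(inherits(model, "channel_model"), length(V) == 1L, is.finite(V))
  n <- length(model$states)
  W <- matrix(0, n, n, dimnames = list(model$states, model$states))
  tr <- model$transitions
  rates <- tr$multiplicity * tr$scale * tr$amplitude *
    exp(tr$charge * V / thermal_voltage)
  for (k in seq_len(nrow(tr)))
    W[tr$to[k], tr$from[k]] <- W[tr$to[k], tr$from[k]] + rates[k]
  diag(W) <- diag(W) - colSums(W)
  W
}

#' Stationary distribution at a fixed voltage
#'
#' The equilibrium probability vector P satisfying W(V) P = 0, sum(P) = 1.
#' Unique because the gating chains are irreducible. Used as the initial
#' condition of every simulation (ensemble equilibrated at the holding
#' potential).
#'
#' @inheritParams transition_matrix
#' @return Named probability vector (entries >= 0, summing to 1).
#' @export
equilibrium <- function(model, V, thermal_voltage = waveclamp::thermal_voltage()) {
  W <- transition_matrix(model, V, thermal_voltage)
  n <- nrow(W)
  A <- rbind(W[-n, , drop = FALSE], rep(1, n))
  p <- tryCatch(solve(A, c(rep(0, n - 1L), 1)),
                error = function(e) stop("singular generator: model disconnected or degenerate rates"))
  p[p < 0 & p > -1e-12] <- 0
  if (any(p < 0)) stop("negative stationary probability; generator ill-conditioned")
  p <- p / sum(p)
  names(p) <- model$states
  p
}

#' Sampled voltage waveform
#'
#' A uniformly sampled membrane-potential trace.
#'
#' @param samples Potentials in mV.
#' @param dt Sample interval in ms (default 0.01 ms = 100 kHz).
#' @param t0 Start time in ms.
#' @return An object of class `voltage_waveform`.
#' @export
voltage_waveform <- function(samples, dt = 0.01, t0 = 0) {
  samples <- as.numeric(samples)
  stopifnot(length(samples) >= 1L, all(is.finite(samples)), dt > 0)
  structure(list(samples = samples, dt = dt, t0 = t0), class = "voltage_waveform")
}

#' @export
print.voltage_waveform <- function(x, ...) {
  cat(sprintf("<voltage_waveform> %d samples @ dt = %g ms (%.3g ms), range [%.4g, %.4g] mV\n",
              length(x$samples), x$dt, length(x$samples) * x$dt,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
plot.voltage_waveform <- function(x, ...) {
  t <- x$t0 + (seq_along(x$samples) - 1L) * x$dt
  plot(t, x$samples, type = "l", xlab = "time (ms)", ylab = "V (mV)", ...)
  invisible(x)
}

#' Time axis of a waveform or current trace
#' @param x A `voltage_waveform` or `current_trace`.
#' @return Numeric vector of sample times in ms.
#' @export
time_axis <- function(x) x$t0 + (seq_along(x$samples) - 1L) * x$dt

#' Peak-to-peak amplitude
#' @param x A `voltage_waveform` or numeric vector.
#' @return max - min of the samples.
#' @export
peak_to_peak <- function(x) {
  v <- if (is.list(x)) x$samples else x
  max(v) - min(v)
}

#' Current trace
#'
#' Whole-cell current samples aligned with a driving voltage waveform.
#' Units are arbitrary but consistent with the model's g0 scale.
#'
#' @param samples Current values.
#' @param dt Sample interval in ms.
#' @param t0 Start time in ms.
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(samples, dt = 0.01, t0 = 0) {
  samples <- as.numeric(samples)
  stopifnot(length(samples) >= 1L, all(is.finite(samples)), dt > 0)
  structure(list(samples = samples, dt = dt, t0 = t0), class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %d samples @ dt = %g ms, range [%.4g, %.4g]\n",
              length(x$samples), x$dt, min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
plot.current_trace <- function(x, ...) {
  t <- x$t0 + (seq_along(x$samples) - 1L) * x$dt
  plot(t, x$samples, type = "l", xlab = "time (ms)", ylab = "current (a.u.)", ...)
  invisible(x)
}

#' Propagate the master equation under a sampled waveform
#'
#' Iterates \eqn{P(t_{i+1}) = \exp(W(V_i)\,dt)\,P(t_i)} with the voltage held
#' at the sample value across each interval. The matrix exponential is exact
#' (scaling-and-squaring, computed in compiled code) and cached per distinct
#' voltage, quantized to `quantum` mV, since fluctuating waveforms revisit
#' values.
#'
#' @param model A [channel_model()].
#' @param waveform A [voltage_waveform()].
#' @param p0 Initial probability vector (length n, entries >= 0, sum 1).
#' @param thermal_voltage kT/e in mV.
#' @param quantum Voltage quantum for propagator caching, in mV.
#' @return n x n_samples matrix of state probabilities; column 1 is `p0`.
#' @export
propagate <- function(model, waveform, p0,
                      thermal_voltage = waveclamp::thermal_voltage(),
                      quantum = 0.001) {
  stopifnot(inherits(model, "channel_model"), inherits(waveform, "voltage_waveform"))
  n <- length(model$states)
  p0 <- as.numeric(p0)
  if (length(p0) != n) stop("p0 length does not match the model")
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-9) stop("p0 is not a probability vector")
  tr <- model$transitions
  traj <- cpp_propagate(as.integer(tr$from), as.integer(tr$to),
                        tr$amplitude, tr$charge,
                        as.numeric(tr$multiplicity * tr$scale),
                        n, waveform$samples, waveform$dt, thermal_voltage,
                        p0, quantum)
  rownames(traj) <- model$states
  traj
}

poly_eval <- function(coeffs, V) {
  # coeffs ordered degree 5 .. constant
  out <- 0
  for (c_k in coeffs) out <- out * V + c_k
  out
}

#' Whole-cell current from a state trajectory
#'
#' Ohm's law for the ensemble:
#' \eqn{i(t) = g_0\, g(V(t))\, (V(t) - V_r)\, O\!\cdot\!P(t)}, where
#' \eqn{O\cdot P} is the summed probability of the conducting states and
#' g(V) the degree-5 conductance polynomial of the model.
#'
#' @param model A [channel_model()].
#' @param waveform Driving [voltage_waveform()].
#' @param trajectory State-probability matrix from [propagate()].
#' @param v_rev Reversal potential in mV.
#' @return A [current_trace()] aligned with the waveform.
#' @export
ohmic_current <- function(model, waveform, trajectory, v_rev = -90) {
  stopifnot(ncol(trajectory) == length(waveform$samples))
  open_p <- colSums(trajectory[model$states %in% model$open_states, , drop = FALSE])
  V <- waveform$samples
  i <- model$g0 * poly_eval(model$gV_coeffs, V) * (V - v_rev) * open_p
  current_trace(i, dt = waveform$dt, t0 = waveform$t0)
}

#' Simulate the whole-cell current response to a waveform
#'
#' Equilibrates the ensemble at the holding potential, propagates the master
#' equation under the waveform, and converts the open-state occupancy to
#' current. Deterministic for fixed inputs.
#'
#' @param model A [channel_model()].
#' @param waveform A [voltage_waveform()].
#' @param v_hold Holding potential in mV, at which P(0) is the equilibrium
#'   distribution.
#' @param v_rev Reversal potential in mV.
#' @param thermal_voltage kT/e in mV.
#' @param keep_trajectory Keep the full state-probability matrix (n x T)?
#' @param quantum Propagator cache quantum in mV, see [propagate()].
#' @return An object of class `channel_sim` with components `model_name`,
#'   `waveform`, `current` (a [current_trace()]), `open_probability`, and
#'   optionally `trajectory`.
#' @export
#' @examples
#' m <- shaker_model("zha_a")
#' wf <- steps_to_waveform(list(step_segment(-90, 2), step_segment(42, 10)), dt = 0.05)
#' sim <- simulate_current(m, wf)
#' print(sim)
simulate_current <- function(model, waveform, v_hold = -90, v_rev = -90,
                             thermal_voltage = waveclamp::thermal_voltage(),
                             keep_trajectory = TRUE, quantum = 0.001) {
  p0 <- equilibrium(model, v_hold, thermal_voltage)
  traj <- propagate(model, waveform, p0, thermal_voltage, quantum)
  cur <- ohmic_current(model, waveform, traj, v_rev)
  open_p <- colSums(traj[model$states %in% model$open_states, , drop = FALSE])
  structure(list(model_name = model$name, waveform = waveform, current = cur,
                 open_probability = open_p,
                 trajectory = if (keep_trajectory) traj else NULL,
                 v_hold = v_hold, v_rev = v_rev),
            class = "channel_sim")
}

#' @export
print.channel_sim <- function(x, ...) {
  cat(sprintf("<channel_sim> %s: %d samples @ dt = %g ms\n", x$model_name,
              length(x$current$samples), x$current$dt))
  cat(sprintf("  peak |current| %.4g (a.u.), max open probability %.4f\n",
              max(abs(x$current$samples)), max(x$open_probability)))
  invisible(x)
}

#' @export
plot.channel_sim <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(x$waveform, main = "")
  plot(x$current, main = "")
  invisible(x)
}
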