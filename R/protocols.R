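#' Constant-voltage segment
#'
#' @param level Command potential in mV.
#' @param duration Segment duration in ms (> 0).
#' @return An object of class `step_segment`.
#' @export
step_segment <- function(level, duration) {
  stopifnot(is.finite(level), duration > 0)
  structure(list(level = level, duration = duration), class = "step_segment")
}

#' Sample a piecewise-constant protocol
#'
#' Concatenates constant segments into one sampled waveform. Each segment is
#' rounded to at least one sample, so the total duration is conserved within
#' one `dt` per segment.
#'
#' @param segments Non-empty list of [step_segment()]s.
#' @param dt Sample interval in ms.
#' @return A [voltage_waveform()].
#' @export
#' @examples
#' steps_to_waveform(list(step_segment(-90, 1), step_segment(42, 2)), dt = 0.1)
steps_to_waveform <- function(segments, dt = 0.01) {
  if (dt <= 0) stop("dt must be positive")
  if (length(segments) == 0L) stop("need at least one segment")
  samples <- unlist(lapply(segments, function(s) {
    stopifnot(inherits(s, "step_segment"))
    rep(s$level, max(1L, round(s$duration / dt)))
  }))
  voltage_waveform(samples, dt = dt)
}

#' Activation protocol
#'
#' The standard family of step protocols probing channel opening: from the
#' holding potential, one depolarizing test step per sweep, the test level
#' running from `start` to `stop` in increments of `step` (defaults: -70 mV
#' to +42 mV in 8 mV increments from a -90 mV hold, giving 15 sweeps). The
#' pre- and test-segment durations are package choices, not measured
#' quantities.
#'
#' @param hold Holding potential in mV.
#' @param start,stop,step Test-level grid in mV (`step` > 0, `stop >= start`).
#' @param pre_ms Duration at the holding potential before the test step, ms.
#' @param test_ms Test-step duration, ms.
#' @param dt Sample interval in ms.
#' @return List of [voltage_waveform()]s, one per sweep, named by test level;
#'   attribute `levels` holds the level grid.
#' @export
activation_protocol <- function(hold = -90, start = -70, stop = 42, step = 8,
                                pre_ms = 10, test_ms = 50, dt = 0.01) {
  if (step <= 0) stop("step must be positive")
  if (stop < start) stop("stop must be >= start")
  levels <- seq(start, stop, by = step)
  sweeps <- lapply(levels, function(v)
    steps_to_waveform(list(step_segment(hold, pre_ms),
                           step_segment(v, test_ms)), dt = dt))
  names(sweeps) <- sprintf("%+d mV", as.integer(round(levels)))
  attr(sweeps, "levels") <- levels
  sweeps
}

#' Tail (deactivation) protocol
#'
#' Probes channel closing: every sweep applies a fixed depolarizing prepulse
#' (default +32 mV for 30 ms) that opens channels, followed by one
#' repolarizing tail step per sweep, the tail level running from `start` to
#' `stop` in increments of `step` (defaults: -120 mV to +48 mV in 12 mV
#' steps, 15 sweeps).
#'
#' @param hold Holding potential in mV.
#' @param prepulse_mV,prepulse_ms Prepulse level (mV) and duration (ms).
#' @param start,stop,step Tail-level grid in mV.
#' @param pre_ms Duration at the holding potential before the prepulse, ms.
#' @param tail_ms Tail-step duration, ms.
#' @param dt Sample interval in ms.
#' @return List of [voltage_waveform()]s with attribute `levels`.
#' @export
tail_protocol <- function(hold = -90, prepulse_mV = 32, prepulse_ms = 30,
                          start = -120, stop = 48, step = 12,
                          pre_ms = 10, tail_ms = 50, dt = 0.01) {
  if (step <= 0) stop("step must be positive")
  if (stop < start) stop("stop must be >= start")
  levels <- seq(start, stop, by = step)
  sweeps <- lapply(levels, function(v)
    steps_to_waveform(list(step_segment(hold, pre_ms),
                           step_segment(prepulse_mV, prepulse_ms),
                           step_segment(v, tail_ms)), dt = dt))
  names(sweeps) <- sprintf("%+d mV", as.integer(round(levels)))
  attr(sweeps, "levels") <- levels
  sweeps
}
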