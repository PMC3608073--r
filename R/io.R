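#' Write current traces as delimited text
#'
#' Writes one or more aligned current traces to a tab-separated file with a
#' `time_ms` column followed by one column per sweep, plus a JSON sidecar
#' (`<path>.json`) recording `dt`, units and sweep labels. This is the
#' package's interchange format for "recorded" currents.
#'
#' @param traces A [current_trace()] or list of them (equal length and dt).
#' @param path Output file path.
#' @param labels Optional sweep labels.
#' @param meta Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_current_traces <- function(traces, path, labels = NULL, meta = list()) {
  if (inherits(traces, "current_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L)
  dt <- traces[[1L]]$dt
  n <- length(traces[[1L]]$samples)
  for (tr in traces)
    if (length(tr$samples) != n || tr$dt != dt)
      stop("all sweeps must share length and dt")
  if (is.null(labels)) labels <- paste0("sweep", seq_along(traces))
  df <- data.frame(time_ms = traces[[1L]]$t0 + (seq_len(n) - 1L) * dt,
                   lapply(traces, function(tr) tr$samples))
  names(df) <- c("time_ms", labels)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  sidecar <- modifyList(list(dt_ms = dt, n_samples = n, units = "a.u.",
                             sweeps = as.list(labels)), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read current traces from delimited text
#'
#' @param path File written by [write_current_traces()] (or any delimited
#'   file with a time column followed by sweep columns).
#' @return Named list of [current_trace()]s; attribute `meta` carries the
#'   sidecar contents when present.
#' @export
read_current_traces <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (ncol(df) < 2L || nrow(df) == 0L) stop("empty or malformed current file")
  t <- df[[1L]]
  dt <- if (nrow(df) > 1L) stats::median(diff(t)) else 0.01
  out <- lapply(df[-1L], function(col) current_trace(col, dt = dt, t0 = t[1L]))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(out, "meta") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  out
}

#' Write a voltage waveform
#'
#' `write_waveform_text()` writes `time_ms` / `V_mV` columns;
#' `write_waveform_binary()` writes raw little-endian float32 samples (the
#' common stimulus-hardware import format) with a JSON sidecar recording
#' `dt`, units and length.
#'
#' @param waveform A [voltage_waveform()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_waveform_text <- function(waveform, path) {
  df <- data.frame(time_ms = time_axis(waveform), V_mV = waveform$samples)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform_text
#' @export
write_waveform_binary <- function(waveform, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(waveform$samples), con, size = 4L, endian = "little")
  jsonlite::write_json(list(dt_ms = waveform$dt, units = "mV",
                            n_samples = length(waveform$samples),
                            encoding = "float32-le"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a voltage waveform from delimited text
#'
#' @param path File written by [write_waveform_text()].
#' @return A [voltage_waveform()].
#' @export
read_waveform_text <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (nrow(df) == 0L) stop("empty waveform file")
  dt <- if (nrow(df) > 1L) stats::median(diff(df[[1L]])) else 0.01
  voltage_waveform(df[[2L]], dt = dt, t0 = df[[1L]][1L])
}

#' Serialize wavelet coefficients to JSON
#'
#' @param coeffs A [wavelet_coeffs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coeffs_json <- function(coeffs, path) {
  jsonlite::write_json(list(family = coeffs$family, n_levels = coeffs$n_levels,
                            n_samples = coeffs$n_samples,
                            detail = coeffs$detail, coarse = coeffs$coarse),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coeffs_json
#' @export
read_coeffs_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  detail <- x$detail
  if (!is.list(detail)) detail <- list(as.numeric(detail))
  wavelet_coeffs(lapply(detail, as.numeric), as.numeric(x$coarse),
                 x$family, x$n_samples)
}

#' Generate a synthetic "recorded" current
#'
#' Emulates an experimental whole-cell recording as a model current plus
#' i.i.d. Gaussian noise, for testing model-recovery workflows. The generator
#' parameters are embedded in the sidecar when written to disk.
#'
#' @param model A [channel_model()] (the generating truth).
#' @param waveform Driving [voltage_waveform()].
#' @param noise_sd Standard deviation of the additive Gaussian noise, in
#'   current units.
#' @param seed Integer seed.
#' @param path Optional output path (text + sidecar via
#'   [write_current_traces()]).
#' @param ... Passed to [simulate_current()].
#' @return A [current_trace()]; attribute `model_name` records the truth.
#' @export
make_fixture <- function(model, waveform, noise_sd = 0, seed = 1L,
                         path = NULL, ...) {
  sim <- simulate_current(model, waveform, keep_trajectory = FALSE, ...)
  set.seed(seed)
  noisy <- sim$current
  if (noise_sd > 0)
    noisy$samples <- noisy$samples + rnorm(length(noisy$samples), 0, noise_sd)
  attr(noisy, "model_name") <- model$name
  if (!is.null(path))
    write_current_traces(noisy, path,
                         meta = list(generator = "waveclamp::make_fixture",
                                     model = model$name, noise_sd = noise_sd,
                                     seed = seed, synthetic = TRUE))
  noisy
}

#' Rank gating models against an observed current
#'
#' Simulates each candidate model under the waveform that produced the
#' observed current and ranks the models by chi-squared divergence from the
#' observation (ascending: best first). Exact ties are flagged.
#'
#' @param observed A [current_trace()] (e.g. a recording or
#'   [make_fixture()] output).
#' @param models Named list of [channel_model()]s.
#' @param waveform The [voltage_waveform()] the observation was recorded
#'   under.
#' @param ... Passed to [simulate_current()].
#' @return An object of class `model_comparison`: a data frame with columns
#'   `model` and `chi2`, sorted ascending, with attributes `best` and `tie`.
#' @export
compare_models <- function(observed, models, waveform, ...) {
  stopifnot(length(models) >= 1L)
  if (is.null(names(models)))
    names(models) <- vapply(models, function(m) m$name, "")
  obs <- if (is.list(observed)) observed$samples else as.numeric(observed)
  if (length(obs) != length(waveform$samples))
    stop("observed current and waveform lengths differ")
  chi2 <- vapply(models, function(m) {
    sim <- simulate_current(m, waveform, keep_trajectory = FALSE, ...)
    chi2_divergence(obs, sim$current)
  }, 0)
  out <- data.frame(model = names(models), chi2 = unname(chi2))
  out <- out[order(out$chi2), ]
  rownames(out) <- NULL
  attr(out, "best") <- out$model[1L]
  attr(out, "tie") <- nrow(out) > 1L && isTRUE(all.equal(out$chi2[1L], out$chi2[2L]))
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model ranking by chi-squared divergence from the observed current:\n")
  print.data.frame(x, row.names = FALSE)
  if (isTRUE(attr(x, "tie")))
    cat("NOTE: tie between the top-ranked models\n")
  else
    cat(sprintf("Best model: %s\n", attr(x, "best")))
  invisible(x)
}
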