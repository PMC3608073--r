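#' Haar mother wavelet
#'
#' The simplest orthonormal mother wavelet: +1 on \[0, 1/2), -1 on \[1/2, 1),
#' 0 elsewhere. It has zero mean and unit energy, and its dilates/translates
#' \eqn{\psi_{m,n}(t) = 2^{-m/2}\psi(2^{-m}t - n)} form the dyadic Haar basis.
#'
#' @param t Dimensionless argument (vectorized).
#' @return Wavelet value(s).
#' @export
#' @examples
#' haar_psi(c(0.25, 0.75, 1.5))
haar_psi <- function(t) {
  ifelse(t >= 0 & t < 0.5, 1, ifelse(t >= 0.5 & t < 1, -1, 0))
}

# Orthonormal analysis filters (low/high pass). The Daubechies-8
# extremal-phase filter has 16 taps and 8 vanishing moments; its taps are the
# standard published constants. Sign convention chosen so that a unit detail
# coefficient at the finest Haar level synthesizes to (+, -)/sqrt(2).
wavelet_filters <- function(family = c("haar", "db8")) {
  family <- match.arg(family)
  lo <- switch(family,
    haar = rep(1 / sqrt(2), 2),
    db8 = c(0.05441584224310401,    0.31287159091429995,   0.6756307362972898,
            0.5853546836542067,    -0.015829105256349306, -0.2840155429615469,
            0.0004724845739132828,  0.12874742662047847,  -0.017369301001807547,
           -0.044088253930794755,   0.013981027917398282,  0.008746094047405777,
           -0.004870352993451574,  -0.00039174037337694705,
            0.0006754494064505693, -0.00011747678412476953))
  L <- length(lo)
  # quadrature-mirror highpass: hi[k] = (-1)^k lo[L-1-k]
  hi <- rev(lo) * (-1)^(seq_len(L) - 1L)
  list(lo = lo, hi = hi, length = L)
}

# One analysis step of the periodic pyramid: x (length N, N even) ->
# approximation a and detail d (length N/2). a[k] = sum_j lo[j] x[2k+j] with
# circular indexing; the synthesis step below is the exact transpose, so the
# pair is orthonormal for orthogonal filter banks.
.analyze_step <- function(x, f) {
  N <- length(x)
  half <- N / 2L
  a <- numeric(half); d <- numeric(half)
  base <- 2L * (seq_len(half) - 1L)
  for (j in seq_len(f$length)) {
    idx <- (base + (j - 1L)) %% N + 1L
    a <- a + f$lo[j] * x[idx]
    d <- d + f$hi[j] * x[idx]
  }
  list(a = a, d = d)
}

.synthesize_step <- function(a, d, f) {
  half <- length(a)
  N <- 2L * half
  x <- numeric(N)
  base <- 2L * (seq_len(half) - 1L)
  for (j in seq_len(f$length)) {
    idx <- (base + (j - 1L)) %% N + 1L
    x[idx] <- x[idx] + f$lo[j] * a + f$hi[j] * d
  }
  x
}

#' Dyadic wavelet coefficient set
#'
#' Coefficients T(m, n) of a signal in the periodic orthonormal dyadic
#' wavelet basis, plus the scaling-function (coarse approximation) term at
#' the coarsest level. Level m = 1 is the finest scale; level m holds
#' `n_samples / 2^m` detail coefficients.
#'
#' @param detail List of numeric vectors, one per level, finest first.
#' @param coarse Numeric vector of scaling coefficients at the coarsest
#'   level (length `n_samples / 2^n_levels`).
#' @param family Wavelet family, `"haar"` or `"db8"`.
#' @param n_samples Target signal length; a power of two >= `2^n_levels`.
#' @return An object of class `wavelet_coeffs`.
#' @export
wavelet_coeffs <- function(detail, coarse, family = c("haar", "db8"),
                           n_samples = 2L * length(detail[[1L]])) {
  family <- match.arg(family)
  n_levels <- length(detail)
  if (n_levels < 1L || n_levels > 12L) stop("n_levels must be in 1..12")
  if (bitwAnd(n_samples, n_samples - 1L) != 0L)
    stop("n_samples must be a power of two")
  if (n_samples < 2^n_levels) stop("n_samples too short for n_levels")
  for (m in seq_len(n_levels)) {
    if (length(detail[[m]]) != n_samples / 2^m)
      stop(sprintf("level %d must hold %d coefficients", m, n_samples / 2^m))
    if (!all(is.finite(detail[[m]]))) stop("non-finite detail coefficients")
  }
  if (length(coarse) != n_samples / 2^n_levels)
    stop("coarse term has the wrong length")
  if (!all(is.finite(coarse))) stop("non-finite coarse coefficients")
  structure(list(detail = detail, coarse = as.numeric(coarse), family = family,
                 n_levels = n_levels, n_samples = as.integer(n_samples)),
            class = "wavelet_coeffs")
}

#' @export
print.wavelet_coeffs <- function(x, ...) {
  cat(sprintf("<wavelet_coeffs> %s, %d levels, %d samples, energy %.4g\n",
              x$family, x$n_levels, x$n_samples, coeff_energy(x)))
  invisible(x)
}

#' Coefficient energy
#'
#' Sum of squared coefficients (details plus coarse term). By Parseval's
#' identity this equals the energy of the synthesized fluctuation.
#'
#' @param coeffs A [wavelet_coeffs()].
#' @return Scalar energy.
#' @export
coeff_energy <- function(coeffs) {
  sum(vapply(coeffs$detail, function(d) sum(d^2), 0)) + sum(coeffs$coarse^2)
}

#' Flatten / rebuild wavelet coefficients
#'
#' `coeff_vector()` concatenates all coefficients (details finest-first, then
#' the coarse term) into one numeric vector; `coeff_restore()` is its inverse
#' given a template.
#'
#' @param coeffs,template A [wavelet_coeffs()].
#' @param x Numeric vector from `coeff_vector()`.
#' @return A numeric vector, or a rebuilt `wavelet_coeffs`.
#' @export
coeff_vector <- function(coeffs) {
  c(unlist(coeffs$detail, use.names = FALSE), coeffs$coarse)
}

#' @rdname coeff_vector
#' @export
coeff_restore <- function(x, template) {
  lens <- vapply(template$detail, length, 0L)
  detail <- vector("list", length(lens))
  pos <- 0L
  for (m in seq_along(lens)) {
    detail[[m]] <- x[pos + seq_len(lens[m])]
    pos <- pos + lens[m]
  }
  coarse <- x[pos + seq_len(length(template$coarse))]
  wavelet_coeffs(detail, coarse, template$family, template$n_samples)
}

#' Discrete wavelet transform of a waveform
#'
#' Analyzes a sampled signal into its periodic orthonormal dyadic wavelet
#' coefficients by the cascading pyramid: at each level the running
#' approximation splits into a half-length approximation and detail. Exact
#' inverse of [synthesize()]; energy is preserved (Parseval).
#'
#' @param waveform A [voltage_waveform()] (or numeric vector) whose length is
#'   a power of two >= `2^n_levels`. Non-power-of-two lengths are rejected,
#'   not padded.
#' @param family `"haar"` or `"db8"`.
#' @param n_levels Number of decomposition levels.
#' @param offset Constant removed from the samples before analysis (e.g. the
#'   holding potential); the same value is supplied back to [synthesize()].
#' @return A [wavelet_coeffs()].
#' @export
#' @examples
#' wf <- voltage_waveform(sin(2 * pi * (0:255) / 64), dt = 0.01)
#' tc <- dwt(wf, "haar", 4)
#' max(abs(synthesize(tc, dt = 0.01)$samples - wf$samples))
dwt <- function(waveform, family = c("haar", "db8"), n_levels, offset = 0) {
  x <- if (inherits(waveform, "voltage_waveform")) waveform$samples else as.numeric(waveform)
  family <- match.arg(family)
  N <- length(x)
  if (N < 2L || bitwAnd(N, N - 1L) != 0L)
    stop("waveform length must be a power of two")
  if (N < 2^n_levels) stop("waveform too short for n_levels")
  f <- wavelet_filters(family)
  x <- x - offset
  detail <- vector("list", n_levels)
  a <- x
  for (m in seq_len(n_levels)) {
    st <- .analyze_step(a, f)
    detail[[m]] <- st$d
    a <- st$a
  }
  wavelet_coeffs(detail, a, family, N)
}

#' Synthesize a voltage waveform from wavelet coefficients
#'
#' Inverse discrete wavelet transform: reconstructs the signal as the
#' superposition \eqn{x(t) = \sum_{m,n} T(m,n)\,\psi_{m,n}(t)} plus the
#' coarse scaling term, then adds a constant offset (typically the holding
#' potential). Linear in the coefficients; exact inverse of [dwt()].
#'
#' @param coeffs A [wavelet_coeffs()].
#' @param dt Sample interval in ms.
#' @param offset Constant baseline added to the reconstruction, in mV.
#' @param t0 Start time in ms.
#' @return A [voltage_waveform()] of length `coeffs$n_samples`.
#' @export
synthesize <- function(coeffs, dt = 0.01, offset = 0, t0 = 0) {
  stopifnot(inherits(coeffs, "wavelet_coeffs"))
  f <- wavelet_filters(coeffs$family)
  a <- coeffs$coarse
  for (m in rev(seq_len(coeffs$n_levels)))
    a <- .synthesize_step(a, coeffs$detail[[m]], f)
  voltage_waveform(a + offset, dt = dt, t0 = t0)
}

#' Enforce a peak-to-peak amplitude bound
#'
#' Voltage excursions beyond about 200 mV peak-to-peak destroy the gigaseal,
#' so synthesized pulses are constrained: if the waveform's peak-to-peak
#' amplitude exceeds `max_pp` its fluctuation about the mean is linearly
#' rescaled so the peak-to-peak equals `max_pp` exactly (mean preserved);
#' otherwise the waveform is returned unchanged. Idempotent.
#'
#' @param waveform A [voltage_waveform()].
#' @param max_pp Maximum allowed peak-to-peak amplitude in mV.
#' @param action `"rescale"` (default) or `"reject"` (error when violated).
#' @return A [voltage_waveform()].
#' @export
enforce_amplitude <- function(waveform, max_pp = 200,
                              action = c("rescale", "reject")) {
  action <- match.arg(action)
  stopifnot(inherits(waveform, "voltage_waveform"), max_pp > 0)
  pp <- peak_to_peak(waveform)
  if (pp <= max_pp) return(waveform)
  if (action == "reject")
    stop(sprintf("peak-to-peak %.3g mV exceeds the %.3g mV bound", pp, max_pp))
  mu <- mean(waveform$samples)
  voltage_waveform(mu + (waveform$samples - mu) * (max_pp / pp),
                   dt = waveform$dt, t0 = waveform$t0)
}

#' Random wavelet coefficients
#'
#' Draws every detail coefficient from Uniform(-scale, scale), redrawing
#' exact zeros (multiplicative mutation cannot escape an exactly-zero
#' coefficient). The coarse term is zero by default so the DC level is
#' carried by the synthesis offset.
#'
#' @param family `"haar"` or `"db8"`.
#' @param n_levels Number of levels.
#' @param n_samples Signal length (power of two).
#' @param scale Half-width of the uniform draw, in mV-equivalent units.
#' @param random_coarse Draw the coarse term too (default: zeros).
#' @return A [wavelet_coeffs()]. Uses the current R RNG stream; seed with
#'   [set.seed()] for reproducibility.
#' @export
random_coeffs <- function(family = c("haar", "db8"), n_levels = 8L,
                          n_samples = 2L^n_levels, scale = 100,
                          random_coarse = FALSE) {
  family <- match.arg(family)
  draw <- function(k) {
    x <- runif(k, -scale, scale)
    while (any(x == 0)) x[x == 0] <- runif(sum(x == 0), -scale, scale)
    x
  }
  detail <- lapply(seq_len(n_levels), function(m) draw(n_samples / 2^m))
  nc <- n_samples / 2^n_levels
  coarse <- if (random_coarse) draw(nc) else numeric(nc)
  wavelet_coeffs(detail, coarse, family, n_samples)
}
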