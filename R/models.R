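#' Voltage-dependent transition rate
#'
#' A single gating transition rate with exponential voltage dependence
#' \eqn{\alpha(V) = \alpha(0)\,e^{qV/V_T}}, where \eqn{\alpha(0)} is the rate
#' at 0 mV and \eqn{q} the gating charge in units of the elementary charge.
#'
#' @param amplitude Rate at 0 mV, in 1/ms. Must be positive.
#' @param charge Gating charge in units of e. May be zero or negative
#'   (backward transitions of activation steps usually carry negative charge).
#' @return An object of class `rate_law`.
#' @seealso [rate_at()]
#' @export
#' @examples
#' rate_law(0.1219, 0.6232)
rate_law <- function(amplitude, charge) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, is.finite(amplitude),
            amplitude > 0,
            is.numeric(charge), length(charge) == 1L, is.finite(charge))
  structure(list(amplitude = amplitude, charge = charge), class = "rate_law")
}

#' @export
print.rate_law <- function(x, ...) {
  cat(sprintf("<rate_law> %.4g ms^-1 at 0 mV, q = %.4g e\n", x$amplitude, x$charge))
  invisible(x)
}

#' Abbreviated subunit gating scheme
#'
#' Describes the gating of one channel subunit as a linear chain of
#' `n_subunit_states` conformations, plus the number of identical subunits in
#' the channel. Tetrameric Shaker schemes use `n_subunits = 4`.
#'
#' @param transitions List of length `n_subunit_states - 1`; element `i` is a
#'   list with components `fwd` and `bwd`, both [rate_law()] objects, for the
#'   transition between subunit states `i` and `i + 1`.
#' @param n_subunit_states Number of conformations of one subunit (>= 2).
#' @param n_subunits Number of identical subunits (>= 1).
#' @return An object of class `subunit_scheme`.
#' @seealso [expand_subunits()]
#' @export
subunit_scheme <- function(transitions, n_subunit_states = length(transitions) + 1L,
                           n_subunits = 4L) {
  n_subunit_states <- as.integer(n_subunit_states)
  n_subunits <- as.integer(n_subunits)
  if (n_subunit_states < 2L) stop("a subunit needs at least 2 states")
  if (n_subunits < 1L) stop("n_subunits must be >= 1")
  if (length(transitions) != n_subunit_states - 1L)
    stop("need exactly n_subunit_states - 1 transitions")
  for (tr in transitions) {
    if (!inherits(tr$fwd, "rate_law") || !inherits(tr$bwd, "rate_law"))
      stop("each transition must carry 'fwd' and 'bwd' rate_law objects")
  }
  structure(list(transitions = transitions,
                 n_subunit_states = n_subunit_states,
                 n_subunits = n_subunits),
            class = "subunit_scheme")
}

# All compositions (k_1,...,k_s) of n identical subunits over s subunit states,
# ordered by activation progress sum((i-1)*k_i), ties broken lexicographically
# with resting-state counts first. This ordering puts the fully resting
# composition first and the fully activated one last, so linear schemes come
# out most-closed -> open with no permutation.
compositions <- function(n, s) {
  if (s == 1L) return(matrix(n, 1L, 1L))
  out <- list()
  for (k in n:0) {
    rest <- compositions(n - k, s - 1L)
    out[[length(out) + 1L]] <- cbind(k, rest, deparse.level = 0L)
  }
  m <- do.call(rbind, out)
  score <- as.vector(m %*% (seq_len(s) - 1L))
  ord <- do.call(order, c(list(score), lapply(seq_len(s), function(j) -m[, j])))
  m[ord, , drop = FALSE]
}

#' Expand a subunit scheme into composition states
#'
#' Expands an abbreviated scheme of `n` identical, independent subunits into
#' the full channel topology whose states are the multisets (compositions) of
#' subunit conformations. A transition connects two compositions that differ
#' by moving exactly one subunit along one subunit transition, and its
#' multiplicity is the number of subunits able to make that move. For the
#' classical two-state (resting/activated) tetramer this yields the familiar
#' C1-C2-C3-C4-O chain with forward multiplicities 4, 3, 2, 1.
#'
#' @param scheme A [subunit_scheme()].
#' @return A list with components `states` (matrix of composition vectors,
#'   one row per state), `labels`, `transitions` (data frame with columns
#'   `from`, `to`, `amplitude`, `charge`, `multiplicity`; both directions
#'   listed), and `open_index`, the row of the unique all-activated
#'   composition (the activation endpoint).
#' @export
#' @examples
#' rl <- function(a, q) rate_law(a, q)
#' sch <- subunit_scheme(list(list(fwd = rl(0.12, 0.62), bwd = rl(0.03, -0.02))))
#' frag <- expand_subunits(sch)
#' frag$labels
expand_subunits <- function(scheme) {
  stopifnot(inherits(scheme, "subunit_scheme"))
  s <- scheme$n_subunit_states
  n <- scheme$n_subunits
  comp <- compositions(n, s)
  n_states <- nrow(comp)
  key <- apply(comp, 1L, paste, collapse = ",")
  lookup <- structure(seq_len(n_states), names = key)

  rows <- list()
  for (i in seq_len(n_states)) {
    k <- comp[i, ]
    for (j in seq_len(s - 1L)) {
      if (k[j] > 0L) {            # one subunit moves j -> j+1
        k2 <- k; k2[j] <- k2[j] - 1L; k2[j + 1L] <- k2[j + 1L] + 1L
        tgt <- lookup[[paste(k2, collapse = ",")]]
        tr <- scheme$transitions[[j]]
        rows[[length(rows) + 1L]] <- data.frame(
          from = i, to = tgt,
          amplitude = tr$fwd$amplitude, charge = tr$fwd$charge,
          multiplicity = k[j])
        rows[[length(rows) + 1L]] <- data.frame(
          from = tgt, to = i,
          amplitude = tr$bwd$amplitude, charge = tr$bwd$charge,
          multiplicity = k2[j + 1L])
      }
    }
  }
  trans <- unique(do.call(rbind, rows))
  open_key <- paste(c(rep(0L, s - 1L), n), collapse = ",")
  list(states = comp,
       labels = paste0("(", key, ")"),
       transitions = trans,
       open_index = lookup[[open_key]])
}

#' Discrete-state Markov channel model
#'
#' Container for a full (expanded) gating scheme: state labels, the directed
#' transition list with voltage-dependent rates and multiplicities, the set of
#' conducting states, and the conductance parameters used to convert open
#' probability to whole-cell current via Ohm's law,
#' \eqn{i(t) = g_0\, g(V) (V - V_r)\, O\!\cdot\!P(t)}.
#'
#' @param name Model identifier.
#' @param states Character vector of state labels.
#' @param transitions Data frame with columns `from`, `to` (state indices),
#'   `amplitude` (1/ms at 0 mV), `charge` (e) and `multiplicity` (>= 1), plus
#'   an optional `scale` column (> 0, default 1) of voltage-independent
#'   cooperativity factors applied on top of the base rate (so a scaled
#'   transition still counts its base rate once as a free parameter).
#'   Every directed edge must have a reverse partner and the graph must be
#'   connected.
#' @param open_states Labels (or indices) of the conducting states; non-empty.
#' @param g0 Overall conductance scale (dimensionless; absorbs channel count
#'   and unitary conductance).
#' @param gV_coeffs Numeric vector of 6 polynomial coefficients for the
#'   voltage-dependent part of the conductance g(V), ordered degree 5 down to
#'   the constant term; V in mV.
#' @param extras Named list of additional scalar parameters.
#' @return An object of class `channel_model`.
#' @export
channel_model <- function(name, states, transitions, open_states,
                          g0 = 1, gV_coeffs = c(0, 0, 0, 0, 0, 1),
                          extras = list()) {
  states <- as.character(states)
  n <- length(states)
  stopifnot(n >= 2L, !anyDuplicated(states))
  req <- c("from", "to", "amplitude", "charge", "multiplicity")
  if (!all(req %in% names(transitions))) stop("transitions missing columns")
  if (is.null(transitions$scale)) transitions$scale <- 1
  if (any(transitions$scale <= 0)) stop("scale factors must be positive")
  if (any(transitions$from < 1L | transitions$from > n |
          transitions$to < 1L | transitions$to > n))
    stop("transition indices out of range")
  if (any(transitions$from == transitions$to)) stop("self-transitions not allowed")
  if (any(transitions$amplitude <= 0)) stop("rate amplitudes must be positive")
  if (any(transitions$multiplicity < 1L)) stop("multiplicities must be >= 1")
  # reversibility: each directed edge has a partner in the other direction
  fwd <- paste(transitions$from, transitions$to)
  bwd <- paste(transitions$to, transitions$from)
  if (!all(fwd %in% bwd)) stop("every transition needs a reverse partner")
  # connectivity
  adj <- matrix(FALSE, n, n)
  adj[cbind(transitions$from, transitions$to)] <- TRUE
  reach <- logical(n); reach[1L] <- TRUE
  repeat {
    new <- reach | apply(adj[reach, , drop = FALSE], 2L, any)
    if (identical(new, reach)) break
    reach <- new
  }
  if (!all(reach)) stop("transition graph is not connected")
  if (is.numeric(open_states)) open_states <- states[open_states]
  if (length(open_states) == 0L || !all(open_states %in% states))
    stop("open_states must be a non-empty subset of states")
  if (length(gV_coeffs) != 6L) stop("gV_coeffs must have 6 entries (degree 5 .. constant)")
  structure(list(name = name, states = states,
                 transitions = transitions[order(transitions$from, transitions$to), ],
                 open_states = open_states, g0 = g0,
                 gV_coeffs = as.numeric(gV_coeffs), extras = extras),
            class = "channel_model")
}

#' @export
print.channel_model <- function(x, ...) {
  cat(sprintf("<channel_model> %s: %d states, %d directed transitions, open: %s\n",
              x$name, length(x$states), nrow(x$transitions),
              paste(x$open_states, collapse = ", ")))
  invisible(x)
}

#' @export
summary.channel_model <- function(object, ...) {
  cat(sprintf("Markov gating model %s\n", object$name))
  cat(sprintf("  states            : %d\n", length(object$states)))
  cat(sprintf("  directed edges    : %d\n", nrow(object$transitions)))
  cat(sprintf("  free rate params  : %d\n", n_parameters(object)))
  cat(sprintf("  open states       : %s\n", paste(object$open_states, collapse = ", ")))
  cat(sprintf("  g0                : %.4f\n", object$g0))
  if (length(object$extras))
    cat(sprintf("  extras            : %s\n",
                paste(names(object$extras), unlist(object$extras),
                      sep = " = ", collapse = ", ")))
  invisible(object)
}

#' Count free rate parameters of a model
#'
#' Counts the distinct nonzero scalars among the rate amplitudes and gating
#' charges of a model's transition list (amplitude/charge pairs are
#' deduplicated, so the expanded topology counts each underlying subunit rate
#' once; structurally-zero gating charges are not counted as free parameters).
#'
#' @param model A [channel_model()].
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "channel_model"))
  pairs <- unique(model$transitions[, c("amplitude", "charge")])
  sum(pairs$amplitude != 0) + sum(pairs$charge != 0)
}

#' Load the Shaker model parameter registry
#'
#' Reads the packaged registry of published rate amplitudes (1/ms at 0 mV),
#' gating charges (units of e), conductance scales g0, conductance polynomial
#' coefficients and additional parameters for the four Shaker K+ gating
#' schemes ZHA A, ZHA D, BPS and SS.
#'
#' @param path Optional path to an alternative registry JSON file.
#' @return Named list, one entry per model, each with components `rates`
#'   (named list of `amplitude`/`charge` pairs), `g0`, `gV_coeffs` (degree 5
#'   down to constant) and `extras`.
#' @export
shaker_parameters <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "shaker_params.json", package = "waveclamp",
                        mustWork = TRUE)
  reg <- jsonlite::read_json(path, simplifyVector = FALSE)
  models <- reg$models
  for (m in names(models)) {
    models[[m]]$gV_coeffs <- as.numeric(unlist(models[[m]]$gV_coeffs))
    for (r in names(models[[m]]$rates)) {
      amp <- models[[m]]$rates[[r]]$amplitude
      if (is.null(amp) || amp <= 0)
        stop(sprintf("registry entry %s/%s has non-positive amplitude", m, r))
    }
  }
  models
}

get_rl <- function(params, model, rate, negate_charge = FALSE) {
  entry <- params[[model]]$rates[[rate]]
  if (is.null(entry)) stop(sprintf("missing parameter '%s' for model %s", rate, model))
  q <- entry$charge
  rate_law(entry$amplitude, if (negate_charge) -q else q)
}

#' Build the ZHA A gating model
#'
#' The simplest tetramer scheme: four identical subunits, each with a single
#' resting-to-activated transition; the channel conducts when all four
#' subunits are activated. Expansion yields the linear chain C1-C2-C3-C4-O
#' with multiplicities 4, 3, 2, 1 forward and 1, 2, 3, 4 backward.
#'
#' @param params Parameter registry, see [shaker_parameters()].
#' @return A 5-state [channel_model()].
#' @export
build_zha_a <- function(params = shaker_parameters()) {
  sch <- subunit_scheme(list(list(fwd = get_rl(params, "zha_a", "alpha"),
                                  bwd = get_rl(params, "zha_a", "beta"))),
                        n_subunits = 4L)
  frag <- expand_subunits(sch)
  labels <- c(paste0("C", 1:4), "O")
  channel_model("ZHA A", labels, frag$transitions, open_states = "O",
                g0 = params$zha_a$g0, gV_coeffs = params$zha_a$gV_coeffs)
}

#' Build the ZHA D gating model
#'
#' Four identical subunits, each a linear chain of two resting states and one
#' activated state (rates alpha/beta then gamma/delta), expanded into 15
#' composition states, plus an extra closed state Cf reachable from the open
#' state only (rates k_alpha/k_beta). The cooperativity factor theta scales
#' the final activation step (by default: forward rate multiplied, backward
#' divided). 16 states in total.
#'
#' @param params Parameter registry.
#' @param theta_mode Where the cooperativity factor theta acts:
#'   `"final_step"` (default) scales the last activation step into the open
#'   state; `"cf"` scales the Cf transitions instead (Cf -> O multiplied,
#'   O -> Cf divided).
#' @param cf_forward Direction convention for the Cf attachment:
#'   `"k_alpha_to_open"` (default) uses k_alpha for Cf -> O and k_beta for
#'   O -> Cf; `"k_alpha_to_cf"` swaps them.
#' @return A 16-state [channel_model()].
#' @export
build_zha_d <- function(params = shaker_parameters(),
                        theta_mode = c("final_step", "cf"),
                        cf_forward = c("k_alpha_to_open", "k_alpha_to_cf")) {
  theta_mode <- match.arg(theta_mode)
  cf_forward <- match.arg(cf_forward)
  p <- function(r, neg = FALSE) get_rl(params, "zha_d", r, neg)
  sch <- subunit_scheme(list(list(fwd = p("alpha"), bwd = p("beta")),
                             list(fwd = p("gamma"), bwd = p("delta"))),
                        n_subunits = 4L)
  frag <- expand_subunits(sch)
  theta <- params$zha_d$extras$theta
  trans <- frag$transitions
  trans$scale <- 1
  open_i <- frag$open_index
  cf_scale <- 1
  if (theta_mode == "final_step") {
    # last step into the fully activated composition: theta speeds opening
    trans$scale[trans$to == open_i] <- theta
    trans$scale[trans$from == open_i] <- 1 / theta
  } else {
    cf_scale <- theta   # Cf -> O multiplied, O -> Cf divided
  }
  ka <- p("k_alpha"); kb <- p("k_beta")
  if (cf_forward == "k_alpha_to_cf") { tmp <- ka; ka <- kb; kb <- tmp }
  n <- nrow(frag$states)
  cf <- n + 1L
  trans <- rbind(trans,
                 data.frame(from = open_i, to = cf, amplitude = kb$amplitude,
                            charge = kb$charge, multiplicity = 1L,
                            scale = 1 / cf_scale),
                 data.frame(from = cf, to = open_i, amplitude = ka$amplitude,
                            charge = ka$charge, multiplicity = 1L,
                            scale = cf_scale))
  labels <- frag$labels
  labels[open_i] <- "O"
  labels <- c(labels, "Cf")
  channel_model("ZHA D", labels, trans, open_states = "O",
                g0 = params$zha_d$g0, gV_coeffs = params$zha_d$gV_coeffs,
                extras = list(theta = theta, theta_mode = theta_mode))
}

#' Build the BPS gating model
#'
#' A linear chain of 8 states (7 closed, 1 open) with 5 independent rate
#' pairs: the chain uses pairs alpha0/beta0, then alpha1/beta1 three times,
#' then alpha2/beta2, alpha3/beta3 and alpha4/beta4. Forward rates carry the
#' published gating charges q0..q4; backward rates carry charge -delta0..
#' -delta4 (the published deltas are positive-magnitude backward charges).
#'
#' @param params Parameter registry.
#' @return An 8-state [channel_model()].
#' @export
build_bps <- function(params = shaker_parameters()) {
  pair_idx <- c(0L, 1L, 1L, 1L, 2L, 3L, 4L)
  rows <- list()
  for (k in seq_along(pair_idx)) {
    i <- pair_idx[k]
    f <- get_rl(params, "bps", paste0("alpha", i))
    b <- get_rl(params, "bps", paste0("beta", i))
    # delta_i stored positive in the registry -> negative backward charge
    rows[[length(rows) + 1L]] <- data.frame(
      from = k, to = k + 1L, amplitude = f$amplitude, charge = f$charge,
      multiplicity = 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      from = k + 1L, to = k, amplitude = b$amplitude, charge = -abs(b$charge),
      multiplicity = 1L)
  }
  labels <- c(paste0("C", 1:7), "O")
  channel_model("BPS", labels, do.call(rbind, rows), open_states = "O",
                g0 = params$bps$g0, gV_coeffs = params$bps$gV_coeffs)
}

#' Build the SS gating model
#'
#' Four identical subunits, each a linear chain of four conformations (rates
#' alpha/beta, gamma/delta, epsilon/zeta), expanded into 35 composition
#' states. From the fully activated composition two concerted transitions
#' (alphaN1/betaN1 then alphaN/betaN) lead through one intermediate closed
#' state to the open state. Three inactivated states are reachable from the
#' open state only (default: a chain O-I1-I2-I3 with pairs c/d, c1/d1,
#' c2/d2). 40 states in total.
#'
#' @param params Parameter registry.
#' @param inactivation `"chain"` (default) attaches I1, I2, I3 in series
#'   behind the open state; `"parallel"` attaches each directly to it. The
#'   state count is 40 either way.
#' @return A 40-state [channel_model()].
#' @export
build_ss <- function(params = shaker_parameters(),
                     inactivation = c("chain", "parallel")) {
  inactivation <- match.arg(inactivation)
  p <- function(r) get_rl(params, "ss", r)
  sch <- subunit_scheme(list(list(fwd = p("alpha"), bwd = p("beta")),
                             list(fwd = p("gamma"), bwd = p("delta")),
                             list(fwd = p("epsilon"), bwd = p("zeta"))),
                        n_subunits = 4L)
  frag <- expand_subunits(sch)
  n <- nrow(frag$states)                       # 35 composition states
  top <- frag$open_index
  cN <- n + 1L; open_i <- n + 2L
  i1 <- n + 3L; i2 <- n + 4L; i3 <- n + 5L
  edge <- function(a, b, rl) data.frame(from = a, to = b,
                                        amplitude = rl$amplitude,
                                        charge = rl$charge, multiplicity = 1L)
  trans <- rbind(frag$transitions,
                 edge(top, cN, p("alphaN1")), edge(cN, top, p("betaN1")),
                 edge(cN, open_i, p("alphaN")), edge(open_i, cN, p("betaN")))
  inact <- if (inactivation == "chain") {
    rbind(edge(open_i, i1, p("c")),  edge(i1, open_i, p("d")),
          edge(i1, i2, p("c1")),     edge(i2, i1, p("d1")),
          edge(i2, i3, p("c2")),     edge(i3, i2, p("d2")))
  } else {
    rbind(edge(open_i, i1, p("c")),  edge(i1, open_i, p("d")),
          edge(open_i, i2, p("c1")), edge(i2, open_i, p("d1")),
          edge(open_i, i3, p("c2")), edge(i3, open_i, p("d2")))
  }
  labels <- c(frag$labels, "CN", "O", "I1", "I2", "I3")
  channel_model("SS", labels, rbind(trans, inact), open_states = "O",
                g0 = params$ss$g0, gV_coeffs = params$ss$gV_coeffs,
                extras = list(inactivation = inactivation))
}

#' Build a shipped Shaker gating model by name
#'
#' @param name One of `"zha_a"`, `"zha_d"`, `"bps"`, `"ss"`.
#' @param params Parameter registry.
#' @param ... Passed to the individual builder.
#' @return A [channel_model()].
#' @export
#' @examples
#' m <- shaker_model("zha_a")
#' summary(m)
shaker_model <- function(name = c("zha_a", "zha_d", "bps", "ss"),
                         params = shaker_parameters(), ...) {
  name <- match.arg(name)
  switch(name,
         zha_a = build_zha_a(params),
         zha_d = build_zha_d(params, ...),
         bps = build_bps(params),
         ss = build_ss(params, ...))
}
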