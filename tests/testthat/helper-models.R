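# Shared fixtures and independent oracles, all built in code.

VT <- thermal_voltage(12)

# Minimal two-state gating model C <-> O with arbitrary rate laws; admits
# closed-form equilibrium and relaxation, used as the kinetics oracle.
two_state_model <- function(a_amp = 0.5, a_q = 1, b_amp = 0.2, b_q = -0.5,
                            g0 = 1) {
  channel_model("toy2",
                states = c("C", "O"),
                transitions = data.frame(
                  from = c(1L, 2L), to = c(2L, 1L),
                  amplitude = c(a_amp, b_amp), charge = c(a_q, b_q),
                  multiplicity = 1L),
                open_states = "O", g0 = g0)
}

# Independent brute-force expansion oracle: enumerate every subunit
# configuration vector (one entry per subunit), merge by multiset
# equivalence, and count single-subunit moves between multisets (per
# representative configuration). Deliberately avoids the package's
# composition generator.
brute_force_expand <- function(n_subunit_states, n_subunits) {
  configs <- as.matrix(expand.grid(rep(list(seq_len(n_subunit_states)),
                                       n_subunits)))
  multiset_key <- apply(configs, 1L, function(cfg)
    paste(tabulate(cfg, nbins = n_subunit_states), collapse = ","))
  states <- unique(multiset_key)
  moves <- integer(0)
  for (key in states) {
    cfg <- as.integer(strsplit(key, ",")[[1L]])      # counts per subunit state
    rep_cfg <- rep(seq_len(n_subunit_states), cfg)   # one representative
    for (su in seq_along(rep_cfg)) {
      for (dir in c(1L, -1L)) {
        tgt_state <- rep_cfg[su] + dir
        if (tgt_state < 1L || tgt_state > n_subunit_states) next
        cfg2 <- rep_cfg; cfg2[su] <- tgt_state
        key2 <- paste(tabulate(cfg2, nbins = n_subunit_states), collapse = ",")
        id <- paste(key, key2, sep = "|")
        moves[id] <- (if (id %in% names(moves)) moves[[id]] else 0L) + 1L
      }
    }
  }
  list(states = states, moves = moves)
}

# Brute-force sampled dyadic Haar basis vector at level m, translation n
# (0-based), over N samples: 2^{-m/2} psi(2^{-m} k - n).
haar_basis_vector <- function(m, n, N) {
  k <- 0:(N - 1L)
  2^(-m / 2) * haar_psi(2^(-m) * k - n)
}

all_shaker_models <- function() {
  params <- shaker_parameters()
  list(zha_a = build_zha_a(params), zha_d = build_zha_d(params),
       bps = build_bps(params), ss = build_ss(params))
}
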