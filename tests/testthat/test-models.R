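test_that("two-state tetramer expands to the canonical 5-state chain", {
  sch <- subunit_scheme(list(list(fwd = rate_law(0.1219, 0.6232),
                                  bwd = rate_law(0.0342, -0.0207))),
                        n_subunits = 4L)
  frag <- expand_subunits(sch)
  expect_equal(nrow(frag$states), 5L)
  expect_equal(frag$open_index, 5L)
  tr <- frag$transitions
  fwd <- tr[tr$from < tr$to, ]
  fwd <- fwd[order(fwd$from), ]
  bwd <- tr[tr$from > tr$to, ]
  bwd <- bwd[order(-bwd$from), ]
  expect_equal(fwd$multiplicity, c(4, 3, 2, 1))
  expect_equal(rev(bwd$multiplicity), c(1, 2, 3, 4))
})

test_that("single-subunit expansion is the identity scheme", {
  sch <- subunit_scheme(list(list(fwd = rate_law(1, 0), bwd = rate_law(2, 0))),
                        n_subunits = 1L)
  frag <- expand_subunits(sch)
  expect_equal(nrow(frag$states), 2L)
  expect_true(all(frag$transitions$multiplicity == 1))
})

test_that("three-state tetramer has choose(6, 2) = 15 composition states", {
  sch <- subunit_scheme(list(list(fwd = rate_law(1, 0), bwd = rate_law(1, 0)),
                             list(fwd = rate_law(1, 0), bwd = rate_law(1, 0))),
                        n_subunits = 4L)
  expect_equal(nrow(expand_subunits(sch)$states), 15L)
})

test_that("expansion agrees with brute-force multiset enumeration (<= 12 slots)", {
  grid <- expand.grid(s = 2:4, n = 1:6)
  grid <- grid[grid$s * grid$n <= 12, ]
  for (r in seq_len(nrow(grid))) {
    s <- grid$s[r]; n <- grid$n[r]
    trans <- lapply(seq_len(s - 1L), function(j)
      list(fwd = rate_law(j, 0.1 * j), bwd = rate_law(j + 0.5, -0.1 * j)))
    frag <- expand_subunits(subunit_scheme(trans, n_subunits = n))
    oracle <- brute_force_expand(s, n)
    pkg_keys <- apply(frag$states, 1L, paste, collapse = ",")
    expect_setequal(pkg_keys, oracle$states)
    # edge sets and multiplicities agree exactly
    tr <- frag$transitions
    pkg_edges <- structure(tr$multiplicity,
                           names = paste(pkg_keys[tr$from], pkg_keys[tr$to],
                                         sep = "|"))
    expect_setequal(names(pkg_edges), names(oracle$moves))
    expect_equal(unname(pkg_edges[names(oracle$moves)]),
                 unname(as.numeric(oracle$moves)),
                 info = sprintf("s=%d n=%d", s, n))
  }
})

test_that("expansion rejects degenerate schemes", {
  expect_error(subunit_scheme(list(), n_subunit_states = 1L))
  expect_error(subunit_scheme(list(list(fwd = rate_law(1, 0),
                                        bwd = rate_law(1, 0))),
                              n_subunits = 0L))
})

test_that("the four gating models have the published state and parameter counts", {
  mods <- all_shaker_models()
  expect_equal(length(mods$zha_a$states), 5L)
  expect_equal(length(mods$zha_d$states), 16L)
  expect_equal(length(mods$bps$states), 8L)
  expect_equal(length(mods$ss$states), 40L)
  expect_equal(n_parameters(mods$zha_a), 4L)
  expect_equal(n_parameters(mods$zha_d), 12L)
  expect_equal(n_parameters(mods$bps), 20L)
  expect_equal(n_parameters(mods$ss), 28L)
})

test_that("every built model is reversible as a graph and connected", {
  for (m in all_shaker_models()) {
    tr <- m$transitions
    expect_setequal(paste(tr$from, tr$to), paste(tr$to, tr$from))
    # channel_model() constructor enforces connectivity; rebuild to confirm
    expect_s3_class(channel_model(m$name, m$states, tr, m$open_states,
                                  m$g0, m$gV_coeffs), "channel_model")
  }
})

test_that("ZHA D: Cf hangs off the open state only", {
  m <- build_zha_d()
  cf <- match("Cf", m$states)
  o <- match("O", m$states)
  touching <- m$transitions$from == cf | m$transitions$to == cf
  expect_true(all(m$transitions$from[touching] %in% c(cf, o)))
  expect_true(all(m$transitions$to[touching] %in% c(cf, o)))
})

test_that("SS: 35 composition states; inactivation hangs off the open state", {
  p <- shaker_parameters()
  sch <- subunit_scheme(list(list(fwd = rate_law(p$ss$rates$alpha$amplitude, 0),
                                  bwd = rate_law(p$ss$rates$beta$amplitude, 0)),
                             list(fwd = rate_law(p$ss$rates$gamma$amplitude, 0),
                                  bwd = rate_law(p$ss$rates$delta$amplitude, 0)),
                             list(fwd = rate_law(p$ss$rates$epsilon$amplitude, 0),
                                  bwd = rate_law(p$ss$rates$zeta$amplitude, 0))),
                        n_subunits = 4L)
  expect_equal(nrow(expand_subunits(sch)$states), 35L)

  m <- build_ss()
  inact <- match(c("I1", "I2", "I3"), m$states)
  o <- match("O", m$states)
  touching <- m$transitions$from %in% inact | m$transitions$to %in% inact
  allowed <- c(inact, o)
  expect_true(all(m$transitions$from[touching] %in% allowed))
  expect_true(all(m$transitions$to[touching] %in% allowed))
  # parallel topology keeps the state count
  expect_equal(length(build_ss(inactivation = "parallel")$states), 40L)
})

test_that("BPS chain uses the published 5 rate pairs in chain order", {
  m <- build_bps()
  tr <- m$transitions
  fwd <- tr[tr$from < tr$to, ]
  fwd <- fwd[order(fwd$from), ]
  expect_equal(fwd$amplitude,
               c(0.2761, 1.6095, 1.6095, 1.6095, 1.6809, 2.0483, 1.8216))
  expect_equal(length(unique(paste(tr$amplitude, tr$charge))), 10L)
  bwd <- tr[tr$from > tr$to, ]
  expect_true(all(bwd$charge < 0))  # backward charges are negative by convention
})

test_that("parameter registry is complete and digit-faithful", {
  params <- shaker_parameters()
  expect_setequal(names(params), c("zha_a", "zha_d", "bps", "ss"))
  for (m in params) {
    for (r in m$rates) expect_gt(r$amplitude, 0)
    expect_length(m$gV_coeffs, 6L)
  }
  expect_equal(params$zha_a$rates$alpha$amplitude, 0.1219)
  expect_equal(params$zha_a$rates$alpha$charge, 0.6232)
  expect_equal(params$zha_a$g0, 0.9717)
  expect_equal(params$zha_a$gV_coeffs[6], 0.07696)
  expect_equal(params$zha_d$extras$theta, 8.8660)
  expect_equal(params$ss$rates$d2$amplitude, 9.9927)
})

test_that("model constructor rejects malformed inputs", {
  tr <- data.frame(from = 1L, to = 2L, amplitude = 1, charge = 0,
                   multiplicity = 1L)
  expect_error(channel_model("bad", c("A", "B"), tr, "B"),
               "reverse partner")
  tr2 <- rbind(tr, data.frame(from = 2L, to = 1L, amplitude = -1, charge = 0,
                              multiplicity = 1L))
  expect_error(channel_model("bad", c("A", "B"), tr2, "B"), "positive")
  tr3 <- rbind(tr, data.frame(from = 2L, to = 1L, amplitude = 1, charge = 0,
                              multiplicity = 1L))
  expect_error(channel_model("bad", c("A", "B"), tr3, "C"), "open_states")
  expect_error(channel_model("bad", c("A", "B", "Cx"), tr3, "B"),
               "not connected")
})
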