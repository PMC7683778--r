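test_that("the LTP right-hand side has the committed structure", {
  p <- plasticity_params()
  expect_identical(ltp_rhs(0, p, B = 0), 0)
  expect_error(ltp_rhs(-0.1, p), "L")

  # g = 0: linear decay with a single stable equilibrium at eta B / delta
  p0 <- plasticity_params(g0 = 0, delta = 2, eta = 1)
  eq <- ltp_equilibria(p0, B = 1)
  expect_equal(nrow(eq), 1L)
  expect_equal(eq$L, 0.5, tolerance = 1e-9)
  expect_true(eq$stable)

  # saturation bound: rhs < 0 above (g + eta B)/delta
  p <- plasticity_params(cgrp = 1.5)
  expect_lt(ltp_rhs((p$g + 1) / p$delta + 0.1, p, B = 1), 0)

  expect_error(plasticity_params(hill = 1), "hill")
  expect_error(plasticity_params(delta = 0), "delta")
})

test_that("equilibria match a dense-scan oracle", {
  cases <- list(list(cgrp = 0, B = 0.42),    # inside the bistable window
                list(cgrp = 0, B = 0),
                list(cgrp = 1.5, B = 0),     # irreversible: 3 equilibria
                list(cgrp = 1.5, B = 1))     # far above B_on: high only
  for (cs in cases) {
    p <- plasticity_params(cgrp = cs$cgrp)
    eq <- ltp_equilibria(p, B = cs$B)
    oracle <- scan_equilibria(p$delta, p$g, p$K, p$hill, p$eta, cs$B)
    expect_equal(eq$L, oracle, tolerance = 1e-8)
    # stability alternates along the line for a scalar flow
    if (nrow(eq) == 3) expect_identical(eq$stable, c(TRUE, FALSE, TRUE))
  }
  p <- plasticity_params(cgrp = 0)
  expect_equal(nrow(ltp_equilibria(p, B = 0.42)), 3L)
  expect_equal(nrow(ltp_equilibria(p, B = 2)), 1L)
})

test_that("bifurcation scan finds the three regimes and the saddle-nodes", {
  expect_identical(bifurcation_scan(plasticity_params(g0 = 0))$regime,
                   "monostable")

  bi <- bifurcation_scan(plasticity_params())
  expect_identical(bi$regime, "reversible_bistable")
  expect_true(0 < bi$B_off && bi$B_off < bi$B_on)
  # saddle-node inputs against the analytic fold oracle
  p <- plasticity_params()
  folds <- fold_inputs(p$delta, p$g, p$K, p$hill, p$eta)
  expect_equal(bi$B_off, folds[1], tolerance = 1e-6)
  expect_equal(bi$B_on, folds[2], tolerance = 1e-6)

  hi <- bifurcation_scan(plasticity_params(cgrp = 1.5))
  expect_identical(hi$regime, "irreversible")
  st0 <- hi$equilibria_at_zero
  expect_gte(sum(st0$stable), 2)
  expect_gt(max(st0$L[st0$stable]), 1)
})

test_that("regime is monotone in loop strength with g_bi < g_irr", {
  # analytic thresholds for delta = K = eta = 1, n = 4:
  # folds exist iff g >= min_L (1+L^4)^2 / (4 L^3); the high state exists
  # at B = 0 iff g >= min_L (1+L^4)/L^3 = 4/3^(3/4)
  g_bi <- stats::optimize(function(L) (1 + L^4)^2 / (4 * L^3),
                          c(0.3, 3))$objective
  g_irr <- 4 / 3^(3 / 4)
  expect_lt(g_bi, g_irr)
  regime_at <- function(g)
    bifurcation_scan(plasticity_params(g0 = g), B_range = c(0, 2))$regime
  expect_identical(regime_at(g_bi - 0.05), "monostable")
  expect_identical(regime_at((g_bi + g_irr) / 2), "reversible_bistable")
  expect_identical(regime_at(g_irr + 0.05), "irreversible")
  # committed defaults sit in the intended regimes
  expect_gt(1.2, g_bi); expect_lt(1.2, g_irr)
  expect_gt(1.2 * (1 + 1.5), g_irr)
})

test_that("hysteresis traces agree with the bifurcation scan", {
  # monostable: up and down sweeps coincide
  p0 <- plasticity_params(g0 = 0.5)
  hy0 <- hysteresis_trace(p0, B_max = 1)
  up <- hy0[hy0$direction == "up", ]
  dn <- hy0[hy0$direction == "down", ]
  expect_equal(up$L, rev(dn$L), tolerance = 1e-6)

  # reversible bistable: branches split between B_off and B_on, and the
  # jump locations match the scan within one quasi-static step
  p <- plasticity_params()
  bi <- bifurcation_scan(p)
  step <- 0.015
  hy <- hysteresis_trace(p, B_max = 1.5, step = step, relax_time = 60)
  up <- hy[hy$direction == "up", ]
  dn <- hy[hy$direction == "down", ]       # B descending
  mid <- up$B > bi$B_off + step & up$B < bi$B_on - step
  expect_true(all(abs(up$L[mid] - rev(dn$L)[mid]) > 0.1))
  # jump locations: where the trace crosses between the branches
  jump_up <- up$B[which(up$L > 1)[1]]
  jump_dn <- dn$B[which(dn$L < 0.5)[1]]
  expect_lte(abs(jump_up - bi$B_on), step + 1e-9)
  expect_lte(abs(jump_dn - bi$B_off), step + 1e-9)

  # irreversible: after the pulse returns to zero, L stays high
  pirr <- plasticity_params(cgrp = 1.5)
  hyi <- hysteresis_trace(pirr, B_max = 1.5)
  L_end <- hyi$L[nrow(hyi)]
  eq0 <- ltp_equilibria(pirr, 0)
  L_high <- max(eq0$L[eq0$stable])
  expect_lt(abs(L_end - L_high) / L_high, 0.05)
})

test_that("the LTP-to-weights coupling is monotone, bounded and anchored", {
  map <- coupling_map()
  base <- weight_scheme(1, 10, 10)
  expect_identical(ltp_to_weights(0, map, base)$w_inh, base$w_inh)
  expect_identical(ltp_to_weights(0, map, base)$w_exc, base$w_exc)

  Ls <- sort(stats::runif(20, 0, 10))
  wi <- vapply(Ls, function(L) ltp_to_weights(L, map, base)$w_inh, numeric(1))
  expect_true(all(diff(wi) >= 0))
  expect_true(all(wi <= base$w_inh * (1 + map$lambda)))

  # the high-LTP state lands in the high-inhibition regime (>~ 40)
  eq <- ltp_equilibria(plasticity_params(cgrp = 1.5), 0)
  L_high <- max(eq$L[eq$stable])
  expect_gte(ltp_to_weights(L_high, map, base)$w_inh, 40)

  # inhibition-only coupling leaves the excitatory weight untouched
  g_only <- coupling_map(couple_excitatory = FALSE)
  expect_identical(ltp_to_weights(3, g_only, base)$w_exc, base$w_exc)
})
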