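test_that("free network dynamics honour decay, equilibria and bounds", {
  net0 <- rate_network(matrix(0, 4, 4), decay = c(1, 2, 0.5, 1))
  x0 <- c(1, -0.5, 0.25, 2)
  tr <- simulate(net0, x0 = x0, t_end = 5, dt = 0.25)
  for (i in c(5, 11, 21)) {
    expect_equal(unname(as.numeric(tr[i, 2:5])),
                 x0 * exp(-net0$decay * tr$t[i]), tolerance = 1e-6)
  }

  # the origin is a fixed point of the free dynamics
  net <- rate_network(network_weights(weight_scheme(1, 1, 2)))
  tr0 <- simulate(net, x0 = rep(0, 4), t_end = 10, dt = 0.5)
  expect_true(all(abs(as.matrix(tr0[, 2:5])) < 1e-12))

  # boundedness under strong drive, even for an unstable weight matrix
  netu <- rate_network(network_weights(weight_scheme(1, 10, 20)))
  tru <- simulate(netu, x0 = rep(0.1, 4), t_end = 50, dt = 0.05,
                  input = function(t) 2 * sin(t))
  bound <- (max(rowSums(abs(netu$W))) + max(abs(netu$input_gain)) * 2) /
    min(netu$decay)
  expect_true(all(abs(as.matrix(tru[, 2:5])) <= bound + 1e-6))
})

test_that("linearisation is exact at the origin and guards its precondition", {
  W <- network_weights(weight_scheme(1, 1.5, 3))
  net <- rate_network(W, decay = c(1, 2, 2, 1), slope = 1)
  J <- linearize(net)
  expect_equal(J, -diag(net$decay) + W, ignore_attr = TRUE)
  expect_identical(unname(sign(J))[W != 0], canonical_signs()[W != 0])

  net2 <- rate_network(W, slope = 2)
  expect_equal(linearize(net2), -diag(4) + 2 * W, ignore_attr = TRUE)

  expect_error(linearize(net, state = c(0.3, 0, 0, 0)), "not an equilibrium")
})

test_that("small-signal trajectories match the linear propagator", {
  skip_if_not_installed("Matrix")
  W <- network_weights(weight_scheme(1, 2, 4))
  net <- rate_network(W)
  J <- linearize(net)
  x0 <- c(0.004, -0.003, 0.002, -0.001)
  tr <- simulate(net, x0 = x0, t_end = 10, dt = 0.5)
  for (i in seq(3, 21, by = 6)) {
    xe <- as.numeric(Matrix::expm(J * tr$t[i]) %*% x0)
    xn <- unname(as.numeric(tr[i, 2:5]))
    expect_lt(sqrt(sum((xn - xe)^2)) / sqrt(sum(xe^2)), 0.01)
  }
})

test_that("oscillation descriptors recover constructed signals", {
  t <- seq(0, 200, 0.1)
  x <- exp(-0.1 * t) * sin(2 * pi * 0.25 * t)
  d <- detect_oscillation(x, dt = 0.1)
  expect_equal(d$dominant_frequency, 0.25, tolerance = 0.02)
  expect_identical(d$damping_label, "decaying")
  expect_equal(d$envelope_rate, -0.1, tolerance = 0.1)

  dc <- detect_oscillation(rep(2, 500), dt = 0.1)
  expect_identical(dc$dominant_frequency, 0)

  expect_error(detect_oscillation(x[1:20], dt = 0.1), "too short")

  # linear simulation of an unstable-oscillatory matrix: growing, at the
  # eigenfrequency (eigendecomposition oracle)
  J <- rbind(c(0.05, -2 * pi * 0.3, 0, 0), c(2 * pi * 0.3, 0.05, 0, 0),
             c(0, 0, -1, 0), c(0, 0, 0, -1))
  sol <- deSolve::ode(c(1e-3, 0, 1e-3, 1e-3), seq(0, 150, 0.05),
                      function(t, x, p) list(drop(J %*% x)), NULL)
  dg <- detect_oscillation(sol[, 2], dt = 0.05)
  expect_identical(dg$damping_label, "growing")
  expect_equal(dg$dominant_frequency, 0.3, tolerance = 0.05)
})

test_that("entrainment locks to the drive and releases into free dynamics", {
  net <- rate_network(network_weights(weight_scheme(1, 1, 2)))

  # zero amplitude: driven run identical to the free run
  en0 <- entrain(net, amplitude = 0, t_on = 5, t_off = 50, t_end = 100,
                 dt = 0.1, x0 = c(0.01, 0, 0, 0))
  free <- simulate(net, x0 = c(0.01, 0, 0, 0), t_end = 100, dt = 0.1)
  expect_equal(en0$trajectory$x1, free$x1, tolerance = 1e-10)

  # stable weights: driven at 0.25 Hz, decaying afterwards
  en <- entrain(net, f_drive = 0.25, amplitude = 0.5, t_on = 10,
                t_off = 200, t_end = 320, dt = 0.05)
  expect_equal(en$during$dominant_frequency, 0.25, tolerance = 0.02)
  expect_identical(en$after$damping_label, "decaying")

  # weakly unstable weights: sustained post-drive oscillation near the
  # linearisation's eigenfrequency
  netu <- rate_network(network_weights(weight_scheme(1, 1.25, 4.06)))
  ev <- eigen(linearize(netu), only.values = TRUE)$values
  f_pred <- max(Im(ev)[Re(ev) > 0]) / (2 * pi)
  enu <- entrain(netu, f_drive = 0.25, amplitude = 0.3, t_on = 5,
                 t_off = 40, t_end = 400, dt = 0.02)
  expect_identical(enu$after$damping_label, "sustained")
  expect_equal(enu$after$dominant_frequency, f_pred, tolerance = 0.05)

  expect_error(entrain(net, t_on = 10, t_off = 5, t_end = 100), "t_on")
})

test_that("spectral classification predicts nonlinear steady behaviour", {
  set.seed(33)
  n <- 200
  agree <- 0
  for (k in seq_len(n)) {
    wi <- exp(stats::runif(1, log(1), log(30)))
    we <- exp(stats::runif(1, log(1), log(30)))
    net <- rate_network(network_weights(weight_scheme(1, we, wi)))
    spec_osc <- classify_spectrum(linearize(net))$category ==
      "unstable_oscillatory"
    x0 <- stats::rnorm(4, sd = 0.001)
    if (nonlinear_oscillates(net, x0) == spec_osc) agree <- agree + 1
  }
  expect_gte(agree / n, 0.95)
})
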