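test_that("sample_jacobian respects structure, scale and seed", {
  st <- canonical_structure()

  # zero off-diagonal scaling annihilates everything but the diagonal
  set.seed(1)
  J <- sample_jacobian(st, weight_scheme(1, 0, 0))
  expect_true(all(J[row(J) != col(J)] == 0))
  expect_true(all(diag(J) <= 0 & diag(J) >= -1))

  # determinism under a fixed seed
  set.seed(42); J1 <- sample_jacobian(st, weight_scheme(1, 10, 30))
  set.seed(42); J2 <- sample_jacobian(st, weight_scheme(1, 10, 30))
  expect_identical(J1, J2)

  # moment check: entry (1,2) is +u * w_exc, mean w_exc/2 (uniform oracle)
  set.seed(7)
  n <- 2e4
  v <- replicate(n, sample_jacobian(st, weight_scheme(1, 10, 1))[1, 2])
  se <- (10 / sqrt(12)) / sqrt(n)
  expect_lt(abs(mean(v) - 5), 3 * se)

  # fixed diagonal option
  set.seed(3)
  Jf <- sample_jacobian(st, weight_scheme(2, 1, 1), random_diagonal = FALSE)
  expect_equal(unname(diag(Jf)), rep(-2, 4))

  expect_error(sample_jacobian(st, weight_scheme(1, -1, 1)))
})

test_that("classify_spectrum matches closed-form spectra", {
  expect_equal(classify_spectrum(-diag(4))$category, "stable_nonoscillatory")
  expect_false(classify_spectrum(-diag(4))$oscillatory)

  J <- rbind(c(0.1, -1, 0, 0), c(1, 0.1, 0, 0),
             c(0, 0, -1, 0), c(0, 0, 0, -1))
  cs <- classify_spectrum(J)
  expect_true(cs$oscillatory)
  expect_equal(cs$category, "unstable_oscillatory")
  expect_equal(sort(Re(cs$eigenvalues)), c(-1, -1, 0.1, 0.1))
  expect_equal(sort(abs(Im(cs$eigenvalues))), c(0, 0, 1, 1))

  cs2 <- classify_spectrum(diag(c(1, -1, -1, -1)))
  expect_false(cs2$oscillatory)
  expect_equal(cs2$category, "unstable_nonoscillatory")

  expect_equal(classify_spectrum(rbind(c(-0.1, -1, 0, 0), c(1, -0.1, 0, 0),
                                       c(0, 0, -1, 0), c(0, 0, 0, -1)))$category,
               "stable_oscillatory")

  expect_error(classify_spectrum(matrix(1, 2, 3)), "square")
  expect_error(classify_spectrum(matrix(NA_real_, 4, 4)), "finite")
})

test_that("oscillation probability is exact in degenerate cases and reproducible", {
  # diagonal negative matrices: real negative eigenvalues, never oscillatory
  est <- oscillation_probability(weight_scheme(1, 0, 0), n_samples = 1000,
                                 seed = 5)
  expect_identical(est$p_osc, 0)

  e1 <- oscillation_probability(weight_scheme(1, 1, 30), n_samples = 5000,
                                seed = 11)
  e2 <- oscillation_probability(weight_scheme(1, 1, 30), n_samples = 5000,
                                seed = 11)
  e3 <- oscillation_probability(weight_scheme(1, 1, 30), n_samples = 5000,
                                seed = 12)
  expect_identical(e1$p_osc, e2$p_osc)
  expect_false(identical(e1$p_osc, e3$p_osc))
  expect_gte(e1$p_osc, 0); expect_lte(e1$p_osc, 1)
  expect_equal(e1$se, sqrt(e1$p_osc * (1 - e1$p_osc) / 5000))
  expect_error(oscillation_probability(weight_scheme(), n_samples = 0), "n_samples")
})

test_that("estimates agree with an independent larger rerun and order by inhibition", {
  small <- oscillation_probability(weight_scheme(1, 1, 1), n_samples = 2e4,
                                   seed = 21)
  big <- oscillation_probability(weight_scheme(1, 1, 1), n_samples = 1e5,
                                 seed = 9937)       # different stream
  expect_lt(abs(small$p_osc - big$p_osc),
            3 * sqrt(small$se^2 + big$se^2))

  lo <- oscillation_probability(weight_scheme(1, 1, 1), n_samples = 1e4,
                                seed = 31)
  hi <- oscillation_probability(weight_scheme(1, 1, 30), n_samples = 1e4,
                                seed = 32)
  expect_gt(hi$p_osc - lo$p_osc, 3 * sqrt(lo$se^2 + hi$se^2))
})

test_that("sweeps reproduce pointwise estimates and are deterministic", {
  sw <- sweep_oscillation(w_inh = 7, w_exc = 3, w_self = 1,
                          n_samples = 2000, seed = 17)
  expect_equal(nrow(sw), 1L)
  pt <- oscillation_probability(weight_scheme(1, 3, 7), n_samples = 2000,
                                seed = sw$seed[1])
  expect_identical(sw$p_osc[1], pt$p_osc)

  sw1 <- sweep_oscillation(w_inh = c(1, 10), w_exc = c(1, 100),
                           n_samples = 1000, seed = 8)
  sw2 <- sweep_oscillation(w_inh = c(1, 10), w_exc = c(1, 100),
                           n_samples = 1000, seed = 8)
  expect_identical(sw1, sw2)
  expect_equal(nrow(sw1), 4L)

  # p = 0 exactly when both couplings vanish
  z <- sweep_oscillation(w_inh = 0, w_exc = 0, w_self = 1,
                         n_samples = 500, seed = 1)
  expect_identical(z$p_osc, 0)

  expect_error(sweep_oscillation(w_inh = numeric(0)), "non-empty")
  expect_error(sweep_oscillation(w_inh = -1), "weights")
})

test_that("standard sweep grids match their published layout", {
  sw <- inhibition_sweep(n_samples = 50, step = 25, seed = 2)
  expect_setequal(unique(sw$w_inh), c(1, 25, 50, 75, 100))
  expect_setequal(unique(sw$w_exc), c(1, 10, 100))
  expect_true(all(sw$w_self == 1))

  sc <- self_inhibition_sweep(n_samples = 50, step = 10, seed = 2)
  expect_setequal(unique(sc$w_inh), c(1, 10, 20, 30))
  expect_setequal(unique(sc$w_self), c(0.1, 1, 10))
  expect_equal(nrow(sc), 4 * 3 * 3)
})
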