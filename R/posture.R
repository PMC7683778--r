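#' Postural control model with an internal-model adaptation loop
#'
#' A unit-inertia linearised inverted pendulum
#' `theta'' = omega_u^2 theta + u_C + u_A + d(t)` under two feedback loops:
#' the stabilising proportional-derivative reflex
#' `u_C = -Kp theta - Kd theta'`, and an adaptation loop whose output `u_A`
#' comes from a second-order resonant compensator
#' `z'' + 2 rho omega_c z' + omega_c^2 z = k_a e` (error `e = -theta`,
#' `u_A = z'`), the internal model of a sinusoidal disturbance. With
#' `rho = 0` and `omega_c` matched to the disturbance frequency the closed
#' loop has a transmission zero at that frequency: the disturbance is
#' cancelled exactly (Internal Model Principle). After the disturbance is
#' removed the compensator rings at `omega_c` with envelope
#' `exp(-rho omega_c t)`: damped ringing (`rho > 0`) is the transient
#' mal-de-debarquement state, and `rho = 0` a permanent oscillator (MdDS).
#'
#' @param omega_u Unstable-pole rate of the pendulum (1/s); default
#'   `sqrt(9.81)`, i.e. gravity over a 1 m effective pendulum.
#' @param Kp,Kd PD gains; `Kp > omega_u^2` and `Kd > 0` are required for
#'   the stabilising loop alone to be stable.
#' @param omega_c Compensator centre frequency (rad/s); default matches a
#'   0.25 Hz wave.
#' @param rho Compensator damping ratio, `>= 0`; `0` is the permanent
#'   oscillator.
#' @param k_a Adaptation gain (`0` disables loop A). The full closed loop
#'   must be stable; this is verified at construction.
#' @return An object of class `posture_model`.
#' @examples
#' posture_model(rho = 0.05)
#' @export
posture_model <- function(omega_u = sqrt(9.81), Kp = 20, Kd = 8,
                          omega_c = 2 * pi * 0.25, rho = 0.05, k_a = 2) {
  vals <- c(omega_u = omega_u, Kp = Kp, Kd = Kd, omega_c = omega_c,
            rho = rho, k_a = k_a)
  if (any(!is.finite(vals)))
    stop("all parameters must be finite", call. = FALSE)
  if (Kp <= omega_u^2 || Kd <= 0)
    stop("stabilising loop unstable: need Kp > omega_u^2 and Kd > 0",
         call. = FALSE)
  if (omega_c <= 0 || rho < 0 || k_a < 0)
    stop("need omega_c > 0, rho >= 0, k_a >= 0", call. = FALSE)
  m <- structure(as.list(vals), class = "posture_model")
  rts <- closed_loop_poles(m)
  if (any(Re(rts) > -1e-9))
    stop("closed loop unstable for these gains (max Re pole ",
         format(max(Re(rts)), digits = 3), ")", call. = FALSE)
  m
}

# Roots of (s^2 + Kd s + Kp - omega_u^2)(s^2 + 2 rho w_c s + w_c^2) + k_a s
closed_loop_poles <- function(m) {
  kp <- m$Kp - m$omega_u^2
  a <- c(kp * m$omega_c^2,
         m$Kd * m$omega_c^2 + 2 * m$rho * m$omega_c * kp + m$k_a,
         kp + m$omega_c^2 + 2 * m$rho * m$omega_c * m$Kd,
         m$Kd + 2 * m$rho * m$omega_c,
         1)
  polyroot(a)
}

#' @export
print.posture_model <- function(x, ...) {
  cat(sprintf(
    "Posture model: omega_u %.3g, PD (Kp %.3g, Kd %.3g), compensator omega_c %.4g rad/s, rho %.3g, k_a %.3g\n",
    x$omega_u, x$Kp, x$Kd, x$omega_c, x$rho, x$k_a))
  cat("Slowest closed-loop pole Re:",
      format(max(Re(closed_loop_poles(x))), digits = 3), "\n")
  invisible(x)
}

#' Disturbance specification
#'
#' Describes the passive-motion disturbance applied to posture while
#' aboard: a pure sinusoid (regular sea waves), a sinusoid plus Gaussian
#' noise, or dominance-free broadband noise (road travel). Pure sinusoids
#' must put essentially all spectral power at the nominal frequency
#' (dominance ratio >= 0.99); broadband series must stay below 0.2.
#'
#' @param kind `"pure_sine"`, `"sine_plus_noise"` or `"broadband"`.
#' @param amplitude Disturbance amplitude `D` (rad/s^2 equivalent on the
#'   normalised pendulum); default 0.05.
#' @param frequency Nominal frequency (Hz), inside the 0.2-0.3 Hz band
#'   typical of sea travel; must be below Nyquist (`1/(2 dt)`).
#' @param noise_level Noise standard deviation relative to `amplitude`.
#' @param t_aboard,t_ashore Phase durations (s).
#' @param dt Sampling/output step (s).
#' @param seed Seed for the noise (ignored for `pure_sine`).
#' @return An object of class `disturbance_spec`.
#' @examples
#' disturbance_spec("pure_sine", frequency = 0.25)
#' @export
disturbance_spec <- function(kind = c("pure_sine", "sine_plus_noise",
                                      "broadband"),
                             amplitude = 0.05, frequency = 0.25,
                             noise_level = 0.3, t_aboard = 300,
                             t_ashore = 400, dt = 0.05, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (frequency >= 1 / (2 * dt))
    stop("'frequency' must be below the Nyquist frequency 1/(2 dt)",
         call. = FALSE)
  if (amplitude < 0 || noise_level < 0 || t_aboard <= 0 || t_ashore < 0)
    stop("invalid disturbance parameters", call. = FALSE)
  structure(list(kind = kind, amplitude = amplitude, frequency = frequency,
                 noise_level = noise_level, t_aboard = t_aboard,
                 t_ashore = t_ashore, dt = dt, seed = seed),
            class = "disturbance_spec")
}

#' Generate a disturbance time series
#'
#' Realises the series described by a [disturbance_spec()] on the aboard
#' phase `[0, t_aboard]`. Reproducible from the spec's seed; the caller's
#' RNG state is preserved.
#'
#' @param spec A [disturbance_spec()].
#' @return A data frame `(t, d)` with the spec attached as an attribute.
#' @examples
#' d <- make_disturbance(disturbance_spec("broadband", seed = 1))
#' spectral_dominance(d$d, dt = 0.05, frequency = 0.25)
#' @export
make_disturbance <- function(spec) {
  stopifnot(inherits(spec, "disturbance_spec"))
  t <- seq(0, spec$t_aboard, by = spec$dt)
  d <- switch(spec$kind,
    pure_sine = spec$amplitude * sin(2 * pi * spec$frequency * t),
    sine_plus_noise = with_preserved_seed(spec$seed,
      spec$amplitude * sin(2 * pi * spec$frequency * t) +
        stats::rnorm(length(t), sd = spec$noise_level * spec$amplitude)),
    broadband = with_preserved_seed(spec$seed, {
      w <- stats::rnorm(length(t))
      x <- as.numeric(stats::filter(w, 0.9, method = "recursive"))
      spec$amplitude * x / stats::sd(x)
    }))
  out <- data.frame(t = t, d = d)
  attr(out, "spec") <- spec
  out
}

#' Spectral dominance ratio
#'
#' Fraction of total periodogram power within one bin of the nominal
#' frequency: near 1 for a pure tone, small for broadband noise.
#'
#' @param x Numeric series (uniformly sampled).
#' @param dt Sampling interval (s).
#' @param frequency Nominal frequency (Hz); when `NULL` the peak bin is
#'   used.
#' @return A number in `[0, 1]`.
#' @export
spectral_dominance <- function(x, dt, frequency = NULL) {
  if (!is.null(frequency)) {
    # trim to an integer number of nominal cycles so the tone falls on a
    # Fourier bin (otherwise leakage spreads a pure tone over many bins)
    cycles <- floor(length(x) * dt * frequency)
    if (cycles >= 1) x <- x[seq_len(round(cycles / (frequency * dt)))]
  }
  sp <- stats::spec.pgram(stats::ts(x - mean(x), deltat = dt), taper = 0,
                          plot = FALSE, detrend = TRUE, fast = FALSE)
  k <- if (is.null(frequency)) which.max(sp$spec)
       else which.min(abs(sp$freq - frequency))
  idx <- max(1, k - 1):min(length(sp$spec), k + 1)
  sum(sp$spec[idx]) / sum(sp$spec)
}

#' Simulate posture aboard and after disembarkation
#'
#' Integrates the posture model through two phases. Aboard, the full
#' closed loop runs: the PD reflex plus the error-driven internal-model
#' compensator, forced by the disturbance. Ashore, the disturbance and the
#' entraining error drive are gone; the compensator rings freely from its
#' aboard exit state and feeds its output `u_A` into the stabilising loop
#' (the phantom-motion signal). Integration uses `deSolve::lsoda` with
#' tolerances 1e-9.
#'
#' @param model A [posture_model()].
#' @param dist A [disturbance_spec()] (or a `(t, d)` data frame from
#'   [make_disturbance()]).
#' @param theta0 Initial posture angle (rad).
#' @return A data frame of class `posture_trajectory` with columns `t`,
#'   `phase` (`"aboard"`/`"ashore"`), `theta`, `theta_dot`, `u_C`, `u_A`,
#'   `d`; model and spec attached as attributes.
#' @examples
#' tr <- simulate_posture(posture_model(rho = 0),
#'                        disturbance_spec(t_aboard = 100, t_ashore = 120))
#' @export
simulate_posture <- function(model, dist = disturbance_spec(),
                             theta0 = 0) {
  stopifnot(inherits(model, "posture_model"))
  if (is.data.frame(dist)) {
    spec <- attr(dist, "spec")
    if (is.null(spec)) stop("data-frame 'dist' must come from make_disturbance()",
                            call. = FALSE)
    dser <- dist
  } else {
    stopifnot(inherits(dist, "disturbance_spec"))
    spec <- dist
    dser <- make_disturbance(spec)
  }
  d_fun <- if (spec$kind == "pure_sine") {
    function(t) spec$amplitude * sin(2 * pi * spec$frequency * t)
  } else {
    stats::approxfun(dser$t, dser$d, rule = 2)
  }
  kp <- model$Kp - model$omega_u^2
  rhs_aboard <- function(t, y, p) {
    list(c(y[2],
           -kp * y[1] - model$Kd * y[2] + y[4] + d_fun(t),
           y[4],
           -model$omega_c^2 * y[3] -
             2 * model$rho * model$omega_c * y[4] - model$k_a * y[1]))
  }
  rhs_ashore <- function(t, y, p) {
    list(c(y[2],
           -kp * y[1] - model$Kd * y[2] + y[4],
           y[4],
           -model$omega_c^2 * y[3] -
             2 * model$rho * model$omega_c * y[4]))
  }
  t_ab <- seq(0, spec$t_aboard, by = spec$dt)
  sol1 <- deSolve::ode(c(theta0, 0, 0, 0), t_ab, rhs_aboard, NULL,
                       method = "lsoda", rtol = 1e-9, atol = 1e-9)
  t_as <- seq(0, spec$t_ashore, by = spec$dt)
  sol2 <- deSolve::ode(sol1[nrow(sol1), -1], t_as, rhs_ashore, NULL,
                       method = "lsoda", rtol = 1e-9, atol = 1e-9)
  sol2 <- sol2[-1, , drop = FALSE]
  out <- data.frame(
    t = c(sol1[, 1], sol2[, 1] + spec$t_aboard),
    phase = rep(c("aboard", "ashore"), c(nrow(sol1), nrow(sol2))),
    theta = c(sol1[, 2], sol2[, 2]),
    theta_dot = c(sol1[, 3], sol2[, 3]),
    u_A = c(sol1[, 5], sol2[, 5]),
    d = c(vapply(sol1[, 1], d_fun, numeric(1)), numeric(nrow(sol2))))
  out$u_C <- -model$Kp * out$theta - model$Kd * out$theta_dot
  out <- out[, c("t", "phase", "theta", "theta_dot", "u_C", "u_A", "d")]
  attr(out, "model") <- model
  attr(out, "spec") <- spec
  attr(out, "dt") <- spec$dt
  class(out) <- c("posture_trajectory", "data.frame")
  out
}

#' Steady-state posture residual aboard
#'
#' Half peak-to-peak amplitude of the posture angle over the last `window`
#' seconds of the aboard phase, after the closed loop has settled. With a
#' matched undamped compensator this residual is essentially zero
#' (semi-perfect adaptation).
#'
#' @param traj A [posture_trajectory][simulate_posture].
#' @param window Window length (s) at the end of the aboard phase.
#' @return Residual amplitude (rad).
#' @export
steady_state_residual <- function(traj, window = 40) {
  stopifnot(inherits(traj, "posture_trajectory"))
  ab <- traj[traj$phase == "aboard", ]
  t_end <- max(ab$t)
  if (window <= 0 || window > t_end)
    stop("'window' must lie within the aboard phase", call. = FALSE)
  th <- ab$theta[ab$t >= t_end - window]
  (max(th) - min(th)) / 2
}

#' Post-disembarkation ringing analysis
#'
#' Characterises the adaptation-loop output `u_A` after the disturbance is
#' removed: ringing frequency (from zero-crossing spacing), exponential
#' decay time constant `tau` (log-linear envelope fit; `Inf` when the
#' envelope does not decay), and the regime: `"persistent_MdDS"` when the
#' amplitude drifts by less than 1% over the last 50 cycles, otherwise
#' `"recovering_MdD"`. For the free compensator `tau = 1/(rho omega_c)`.
#'
#' @param traj A [posture_trajectory][simulate_posture] whose ashore phase
#'   covers at least 20 compensator periods.
#' @return A list with `ringing_frequency` (Hz), `tau` (s), `regime` and
#'   `drift_per_50_cycles`.
#' @export
post_removal_response <- function(traj) {
  stopifnot(inherits(traj, "posture_trajectory"))
  model <- attr(traj, "model")
  as <- traj[traj$phase == "ashore", ]
  period <- 2 * pi / model$omega_c
  if (nrow(as) == 0 || diff(range(as$t)) < 20 * period)
    stop("ashore phase must cover at least 20 compensator periods",
         call. = FALSE)
  dt <- attr(traj, "dt")
  tv <- as$t - min(as$t)
  f <- crossing_frequency(as$u_A, dt)
  rate <- envelope_rate(as$u_A, tv)
  if (is.na(rate)) rate <- 0
  tau <- if (rate < -1e-12) -1 / rate else Inf
  # drift over the trailing 50 ringing cycles
  span <- 50 / max(f, 1e-6)
  tail_idx <- tv >= max(tv) - span
  rate_tail <- envelope_rate(as$u_A[tail_idx], tv[tail_idx])
  if (is.na(rate_tail)) rate_tail <- 0
  drift <- abs(expm1(rate_tail * span))
  regime <- if (drift < 0.01) "persistent_MdDS" else "recovering_MdD"
  list(ringing_frequency = f, tau = tau, regime = regime,
       drift_per_50_cycles = drift)
}

#' Phantom self-motion signal
#'
#' The adaptation-loop output `u_A` restricted to the ashore phase: the
#' undesired input that keeps driving the stabilising loop after
#' disembarkation and is perceived as bobbing/rocking/swaying.
#'
#' @param traj A [posture_trajectory][simulate_posture].
#' @return A data frame `(t, u_A)` with the sampling step as attribute.
#' @export
phantom_motion_signal <- function(traj) {
  stopifnot(inherits(traj, "posture_trajectory"))
  as <- traj[traj$phase == "ashore", ]
  if (nrow(as) == 0) stop("no ashore phase present", call. = FALSE)
  out <- data.frame(t = as$t, u_A = as$u_A)
  attr(out, "dt") <- attr(traj, "dt")
  out
}

#' Closed-form disturbance-to-posture frequency response
#'
#' Gain `|theta| / |d|` of the closed loop at each frequency, computed from
#' the transfer function
#' `theta/d = N_c(s) / (P_c(s) N_c(s) + k_a s)` with
#' `N_c = s^2 + 2 rho omega_c s + omega_c^2` (compensator denominator) and
#' `P_c = s^2 + Kd s + Kp - omega_u^2` (PD loop). The response has a notch
#' at `omega_c` whose depth grows without bound as `rho` approaches 0 (an
#' exact transmission zero at `rho = 0`); far above the notch it approaches
#' the PD-only gain `1/|P_c|`.
#'
#' @param model A [posture_model()].
#' @param f Frequencies (Hz) at which to evaluate.
#' @return A data frame with columns `f`, `gain` and `gain_pd` (the
#'   PD-only gain).
#' @examples
#' frequency_response(posture_model(rho = 0), f = c(0.1, 0.25, 2))
#' @export
frequency_response <- function(model, f = seq(0.01, 2, by = 0.01)) {
  stopifnot(inherits(model, "posture_model"))
  s <- 2i * pi * f
  kp <- model$Kp - model$omega_u^2
  Nc <- s^2 + 2 * model$rho * model$omega_c * s + model$omega_c^2
  Pc <- s^2 + model$Kd * s + kp
  data.frame(f = f,
             gain = Mod(Nc / (Pc * Nc + model$k_a * s)),
             gain_pd = 1 / Mod(Pc))
}

#' @export
plot.posture_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  t_split <- max(x$t[x$phase == "aboard"])
  graphics::plot(x$t, x$theta, type = "l", xlab = "time (s)",
                 ylab = "posture angle (rad)", ...)
  graphics::abline(v = t_split, lty = 2, col = "grey40")
  graphics::plot(x$t, x$u_A, type = "l", col = "firebrick",
                 xlab = "time (s)", ylab = "adaptation output u_A", ...)
  graphics::abline(v = t_split, lty = 2, col = "grey40")
  invisible(x)
}
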