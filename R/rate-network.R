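#' Connection matrix from a weight scheme
#'
#' Realises a numeric 4x4 connection matrix for the loop network.
#' `"midscale"` sets each non-zero entry to `sign * w_class`
#' (deterministic); `"random"` draws one frozen sample `sign * u * w_class`
#' with `u ~ U[0, 1]` from the current RNG.
#'
#' @inheritParams sample_jacobian
#' @param method Either `"midscale"` or `"random"`.
#' @return A 4x4 numeric matrix with the structure's sign pattern.
#' @export
network_weights <- function(scheme = weight_scheme(),
                            structure = canonical_structure(),
                            method = c("midscale", "random")) {
  method <- match.arg(method)
  scheme <- as_weight_scheme(scheme)
  w <- class_weights(structure, scheme)
  if (method == "midscale") structure$sign_pattern * w
  else sample_jacobian(structure, scheme)
}

#' Nonlinear firing-rate network
#'
#' A saturating firing-rate realisation of the vestibulocerebellar loop
#' circuit, `dx_i/dt = -d_i x_i + sum_j W_ij tanh(s x_j) + u_i(t)`. Its
#' linearisation at the origin is `J = -D + s W`, which carries the
#' canonical sign pattern, so the spectral analysis of the random-Jacobian
#' ensemble predicts this model's local behaviour. The tanh nonlinearity
#' keeps all states bounded by `(sum_j |W_ij| + max|u|) / min(d_i)`.
#'
#' @param W 4x4 connection matrix; its sign pattern must match
#'   [canonical_structure()] wherever non-zero (see [network_weights()]).
#' @param decay Positive decay rate(s) `d_i` (scalar or length 4).
#' @param slope Positive activation slope `s` of the tanh nonlinearity.
#' @param input_gain Per-node input gain (scalar or length 4); the drive
#'   signal `u(t)` enters node `i` as `input_gain[i] * u(t)`.
#' @return An object of class `rate_network`.
#' @examples
#' net <- rate_network(network_weights(weight_scheme(1, 1, 2)))
#' @export
rate_network <- function(W, decay = 1, slope = 1,
                         input_gain = c(0, 1, -1, 0)) {
  stopifnot(is.matrix(W), all(dim(W) == c(4, 4)), all(is.finite(W)))
  ref <- canonical_structure()$sign_pattern
  if (any(sign(W)[W != 0] != ref[W != 0]))
    stop("sign pattern of 'W' conflicts with the canonical loop structure",
         call. = FALSE)
  decay <- rep_len(decay, 4)
  input_gain <- rep_len(input_gain, 4)
  if (any(!is.finite(decay)) || any(decay <= 0))
    stop("'decay' must be positive and finite", call. = FALSE)
  if (!is.finite(slope) || slope <= 0)
    stop("'slope' must be positive and finite", call. = FALSE)
  structure(list(W = W, decay = decay, slope = slope,
                 input_gain = input_gain),
            class = "rate_network")
}

#' @export
print.rate_network <- function(x, ...) {
  cat("Firing-rate loop network (4 nodes: PJ_A, VN_A, VN_B, PJ_B)\n")
  cat(sprintf("decay: %s; slope: %g\n",
              paste(format(x$decay), collapse = ", "), x$slope))
  cat("State bound:", format(state_bound(x), digits = 4), "(free dynamics)\n")
  invisible(x)
}

state_bound <- function(net, u_max = 0) {
  (max(rowSums(abs(net$W))) + max(abs(net$input_gain)) * u_max) /
    min(net$decay)
}

#' Simulate the firing-rate network
#'
#' Integrates the network ODE with `deSolve` (adaptive `lsoda`, relative
#' tolerance 1e-8, absolute 1e-10).
#'
#' @param object A [rate_network()].
#' @param nsim,seed Unused (present for the [stats::simulate()] generic).
#' @param x0 Initial state (length 4).
#' @param t_end End time (s); the trajectory is reported on a uniform grid.
#' @param dt Output time step (s), `> 0`.
#' @param input Drive signal: `NULL` (free dynamics), a function of time
#'   returning a scalar, or a two-column data frame `(t, u)` interpolated
#'   linearly. The signal enters node `i` scaled by the network's
#'   `input_gain[i]`.
#' @param ... Unused.
#' @return A data frame of class `network_trajectory` with columns `t`,
#'   `x1`..`x4`, `u`, carrying `dt` and the network as attributes.
#' @examples
#' net <- rate_network(network_weights(weight_scheme(1, 1, 2)))
#' tr <- simulate(net, x0 = c(0.01, 0, 0, 0), t_end = 20, dt = 0.05)
#' @export
simulate.rate_network <- function(object, nsim = 1, seed = NULL,
                                  x0 = rep(0, 4), t_end = 100, dt = 0.1,
                                  input = NULL, ...) {
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  u_fun <- drive_function(input)
  times <- seq(0, t_end, by = dt)
  rhs <- function(t, x, p) {
    u <- u_fun(t)
    list(-object$decay * x +
           drop(object$W %*% tanh(object$slope * x)) +
           object$input_gain * u)
  }
  sol <- deSolve::ode(y = as.numeric(x0), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  out <- data.frame(t = sol[, 1], x1 = sol[, 2], x2 = sol[, 3],
                    x3 = sol[, 4], x4 = sol[, 5],
                    u = vapply(sol[, 1], u_fun, numeric(1)))
  attr(out, "dt") <- dt
  attr(out, "network") <- object
  class(out) <- c("network_trajectory", "data.frame")
  out
}

drive_function <- function(input) {
  if (is.null(input)) return(function(t) 0)
  if (is.function(input)) return(input)
  if (is.data.frame(input) && ncol(input) >= 2) {
    f <- stats::approxfun(input[[1]], input[[2]], rule = 2)
    return(f)
  }
  stop("'input' must be NULL, a function of time, or a (t, u) data frame",
       call. = FALSE)
}

#' Linearise the firing-rate network at an equilibrium
#'
#' Returns the Jacobian `J_ij = -d_i delta_ij + W_ij s sech^2(s x*_j)` of
#' the network at an equilibrium `x*`. At the origin this is `-D + s W`,
#' whose sign pattern equals the canonical loop structure.
#'
#' @param network A [rate_network()].
#' @param state Equilibrium state; the free-dynamics right-hand side must
#'   vanish there (within `tol`).
#' @param tol Residual tolerance for the equilibrium check.
#' @return A 4x4 Jacobian matrix.
#' @examples
#' net <- rate_network(network_weights(weight_scheme(1, 1, 2)))
#' linearize(net)   # equals -diag(decay) + slope * W
#' @export
linearize <- function(network, state = rep(0, 4), tol = 1e-8) {
  stopifnot(inherits(network, "rate_network"), length(state) == 4)
  res <- -network$decay * state +
    drop(network$W %*% tanh(network$slope * state))
  if (sqrt(sum(res^2)) > tol)
    stop(sprintf("'state' is not an equilibrium (residual norm %.3g > %.3g)",
                 sqrt(sum(res^2)), tol), call. = FALSE)
  s <- network$slope
  -diag(network$decay) + network$W * rep(s / cosh(s * state)^2, each = 4)
}

#' Oscillation descriptor of a trajectory
#'
#' Measures the dominant frequency (periodogram peak with quadratic
#' interpolation, after discarding an initial transient) and the
#' exponential envelope rate (log-linear fit on peak magnitudes) of the
#' most active state series, and labels the motion `"decaying"`,
#' `"sustained"` or `"growing"` by the sign of the per-cycle envelope slope
#' with a dead-band.
#'
#' @param traj A `network_trajectory`, or a numeric vector (then `dt` must
#'   be given).
#' @param transient_fraction Fraction of the record discarded as transient.
#' @param dt Sampling interval when `traj` is a bare numeric vector.
#' @param dead_band Per-cycle envelope-slope dead-band for the
#'   `"sustained"` label.
#' @return An object of class `oscillation_descriptor`: list with
#'   `dominant_frequency` (Hz), `damping_label`, `envelope_rate` (1/s) and
#'   `amplitude` (half peak-to-peak over the analysis window).
#' @examples
#' t <- seq(0, 200, 0.1)
#' x <- exp(-0.1 * t) * sin(2 * pi * 0.25 * t)
#' detect_oscillation(x, dt = 0.1)
#' @export
detect_oscillation <- function(traj, transient_fraction = 0.25, dt = NULL,
                               dead_band = 1e-3) {
  if (inherits(traj, "network_trajectory")) {
    dt <- attr(traj, "dt")
    sub <- traj[-seq_len(floor(nrow(traj) * transient_fraction)), ]
    xs <- as.matrix(sub[, c("x1", "x2", "x3", "x4")])
    x <- xs[, which.max(apply(xs, 2, stats::var))]
    tv <- sub$t
  } else {
    if (is.null(dt)) stop("'dt' is required for a bare series", call. = FALSE)
    x <- as.numeric(traj)
    x <- x[-seq_len(floor(length(x) * transient_fraction))]
    tv <- seq_along(x) * dt
  }
  if (length(x) < 64)
    stop("trajectory too short for oscillation analysis", call. = FALSE)
  x <- x - mean(x)
  amp <- (max(x) - min(x)) / 2
  if (amp < 1e-12) {
    return(structure(list(dominant_frequency = 0,
                          damping_label = "sustained",
                          envelope_rate = 0, amplitude = 0),
                     class = "oscillation_descriptor"))
  }
  f <- dominant_frequency(x, dt)
  rate <- envelope_rate(x, tv)
  if (is.na(rate)) rate <- 0
  per_cycle <- if (f > 0) rate / f else rate
  label <- if (per_cycle > dead_band) "growing"
    else if (per_cycle < -dead_band) "decaying" else "sustained"
  structure(list(dominant_frequency = f, damping_label = label,
                 envelope_rate = rate, amplitude = amp),
            class = "oscillation_descriptor")
}

#' @export
print.oscillation_descriptor <- function(x, ...) {
  cat(sprintf(
    "Oscillation: %.4g Hz, %s (envelope rate %.3g 1/s, amplitude %.3g)\n",
    x$dominant_frequency, x$damping_label, x$envelope_rate, x$amplitude))
  invisible(x)
}

#' Entrain the network with a periodic vestibular drive
#'
#' Applies a sinusoidal drive in antiphase to the two vestibular-nuclei
#' nodes (the side-to-side stimulation experienced aboard) during
#' `[t_on, t_off]` and simulates through `t_end`, then summarises the
#' driven window and the free dynamics after release.
#'
#' @inheritParams simulate.rate_network
#' @param network A [rate_network()]; its `input_gain` should be the
#'   antiphase pattern `c(0, 1, -1, 0)` (the default).
#' @param f_drive Drive frequency (Hz); sea-travel entrainment is around
#'   0.2-0.3 Hz.
#' @param amplitude Drive amplitude (activity units).
#' @param t_on,t_off,t_end Drive onset, offset and simulation end (s),
#'   `0 < t_on < t_off < t_end`.
#' @return A list with `trajectory`, `during` and `after` (both
#'   [oscillation descriptors][detect_oscillation]).
#' @examples
#' net <- rate_network(network_weights(weight_scheme(1, 1, 2)))
#' en <- entrain(net, f_drive = 0.25, amplitude = 0.5,
#'               t_on = 5, t_off = 120, t_end = 200, dt = 0.1)
#' en$during$dominant_frequency
#' @export
entrain <- function(network, f_drive = 0.25, amplitude = 1,
                    t_on = 10, t_off = 200, t_end = 400, dt = 0.05,
                    x0 = rep(0, 4)) {
  if (!(0 < t_on && t_on < t_off && t_off < t_end))
    stop("need 0 < t_on < t_off < t_end", call. = FALSE)
  drive <- function(t) {
    ifelse(t >= t_on & t <= t_off,
           amplitude * sin(2 * pi * f_drive * (t - t_on)), 0)
  }
  traj <- simulate(network, x0 = x0, t_end = t_end, dt = dt, input = drive)
  seg <- function(lo, hi, tf) {
    sub <- traj[traj$t > lo & traj$t <= hi, ]
    class(sub) <- class(traj)
    attr(sub, "dt") <- dt
    detect_oscillation(sub, transient_fraction = tf)
  }
  list(trajectory = traj,
       during = seg(t_on, t_off, 0.3),
       after = seg(t_off, t_end, 0.1))
}

#' @export
plot.network_trajectory <- function(x, ...) {
  graphics::matplot(x$t, as.matrix(x[, c("x1", "x2", "x3", "x4")]),
                    type = "l", lty = 1, xlab = "time (s)",
                    ylab = "activity (a.u.)", ...)
  graphics::legend("topright", legend = c("PJ_A", "VN_A", "VN_B", "PJ_B"),
                   col = 1:4, lty = 1, bty = "n")
  invisible(x)
}
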