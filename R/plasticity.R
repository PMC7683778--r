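#' Parameters of the bistable LTP switch
#'
#' The one-variable positive-feedback model of synaptic long-term
#' potentiation: `dL/dt = -delta L + g L^n / (K^n + L^n) + eta B`, with
#' `L` the LTP level, `B` the BDNF stimulus, and loop strength
#' `g = g0 (1 + cgrp)` scaled by the CGRP factor (CGRP is an LTP promoter;
#' it enters only as this multiplicative factor). Decay plus sigmoidal
#' self-activation plus additive input is the minimal model exhibiting a
#' saddle-node bifurcation, hysteresis, and irreversibility once the lower
#' saddle-node crosses `B = 0`. All quantities are in arbitrary units.
#'
#' @param delta LTP decay rate, `> 0`.
#' @param g0 Base positive-loop strength, `>= 0`.
#' @param cgrp CGRP scaling factor `c >= 0`; effective strength
#'   `g = g0 (1 + c)`.
#' @param hill Hill exponent, integer `>= 2` (sigmoidal activation is
#'   required for bistability).
#' @param K Half-activation constant, `> 0`.
#' @param eta Input gain, `> 0`.
#' @return An object of class `plasticity_params` (with the effective `g`
#'   precomputed).
#' @examples
#' plasticity_params(cgrp = 1.5)   # high-CGRP: irreversible regime
#' @export
plasticity_params <- function(delta = 1, g0 = 1.2, cgrp = 0, hill = 4,
                              K = 1, eta = 1) {
  if (!all(is.finite(c(delta, g0, cgrp, hill, K, eta))))
    stop("all parameters must be finite", call. = FALSE)
  if (delta <= 0 || g0 < 0 || cgrp < 0 || K <= 0 || eta <= 0)
    stop("need delta > 0, g0 >= 0, cgrp >= 0, K > 0, eta > 0",
         call. = FALSE)
  if (hill != round(hill) || hill < 2)
    stop("'hill' must be an integer >= 2", call. = FALSE)
  structure(list(delta = delta, g0 = g0, cgrp = cgrp, hill = as.integer(hill),
                 K = K, eta = eta, g = g0 * (1 + cgrp)),
            class = "plasticity_params")
}

#' @export
print.plasticity_params <- function(x, ...) {
  cat(sprintf(
    "LTP switch: delta %g, g0 %g, CGRP factor %g (effective g %g), Hill n %d, K %g, eta %g\n",
    x$delta, x$g0, x$cgrp, x$g, x$hill, x$K, x$eta))
  invisible(x)
}

#' Right-hand side of the LTP switch
#'
#' @param L LTP level(s), `>= 0`.
#' @param params A [plasticity_params()].
#' @param B BDNF input, `>= 0`.
#' @return `dL/dt` (same length as `L`).
#' @examples
#' ltp_rhs(0, plasticity_params(), B = 0)   # 0: L = 0 is an equilibrium
#' @export
ltp_rhs <- function(L, params, B = 0) {
  stopifnot(inherits(params, "plasticity_params"))
  if (any(L < 0)) stop("'L' must be >= 0", call. = FALSE)
  Ln <- L^params$hill
  -params$delta * L + params$g * Ln / (params$K^params$hill + Ln) +
    params$eta * B
}

# d(rhs)/dL, for stability classification
ltp_rhs_deriv <- function(L, params) {
  n <- params$hill
  Kn <- params$K^n
  Ln <- L^n
  -params$delta + params$g * n * Kn * ifelse(L > 0, L^(n - 1), 0) /
    (Kn + Ln)^2
}

#' Equilibria of the LTP switch
#'
#' Finds all roots of [ltp_rhs()] on `[0, (g + eta B)/delta + margin]` by
#' sign-change bracketing on a dense grid followed by `uniroot` polishing,
#' and classifies their stability from the sign of the derivative of the
#' right-hand side. Generic parameter sets have 1, 2 or 3 equilibria.
#'
#' @inheritParams ltp_rhs
#' @param grid_n Number of bracketing grid points.
#' @return A data frame with columns `L` and `stable`.
#' @examples
#' ltp_equilibria(plasticity_params(cgrp = 1.5), B = 0)  # 3 equilibria
#' @export
ltp_equilibria <- function(params, B = 0, grid_n = 4000) {
  stopifnot(inherits(params, "plasticity_params"))
  upper <- (params$g + params$eta * B) / params$delta + 1
  grid <- seq(0, upper, length.out = grid_n)
  f <- ltp_rhs(grid, params, B)
  roots <- numeric(0)
  exact <- which(f == 0)
  roots <- c(roots, grid[exact])
  sgn <- sign(f)
  ch <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in ch) {
    r <- stats::uniroot(function(L) ltp_rhs(L, params, B),
                        c(grid[i], grid[i + 1]), tol = 1e-12)
    roots <- c(roots, r$root)
  }
  roots <- sort(unique(roots))
  if (length(roots) > 1)    # merge numerically coincident roots
    roots <- roots[c(TRUE, diff(roots) > 1e-9 * upper)]
  data.frame(L = roots, stable = ltp_rhs_deriv(roots, params) < 0)
}

#' Bifurcation scan of the LTP switch over the BDNF input
#'
#' Follows the equilibrium branches over a BDNF range and locates the
#' saddle-node inputs: `B_on`, above which the low-LTP branch disappears
#' (up-switch), and `B_off`, below which the high-LTP branch disappears
#' (down-switch). Saddle-node locations are refined by bisection on the
#' equilibrium count. The regime is `"monostable"` (no bistable window in
#' the scanned range), `"reversible_bistable"` (`0 < B_off < B_on`), or
#' `"irreversible"` (a stable high-LTP equilibrium exists at `B = 0`, so
#' LTP persists after the stimulus returns to zero; the down-switch would
#' require a negative input, reported as `NA` unless the scan range covers
#' it).
#'
#' @inheritParams ltp_rhs
#' @param B_range Scanned input interval; must contain 0.
#' @param resolution Number of scan points. If the grid is too coarse to
#'   bracket both saddle-nodes a refined rescan is performed (with a
#'   warning).
#' @return An object of class `bifurcation_result`: list with `regime`,
#'   `B_on`, `B_off`, `equilibria_at_zero`, and `branches` (data frame
#'   `B, L_low, L_unstable, L_high`, `NA` where a branch is absent).
#' @examples
#' bifurcation_scan(plasticity_params())$regime       # reversible_bistable
#' bifurcation_scan(plasticity_params(cgrp = 1.5))$regime  # irreversible
#' @export
bifurcation_scan <- function(params, B_range = c(0, 1.5),
                             resolution = 601) {
  stopifnot(inherits(params, "plasticity_params"))
  if (B_range[1] > 0 || B_range[2] < 0)
    stop("'B_range' must contain 0", call. = FALSE)
  Bs <- seq(B_range[1], B_range[2], length.out = resolution)
  eq_list <- lapply(Bs, function(B) ltp_equilibria(params, B))
  n_stable <- vapply(eq_list, function(e) sum(e$stable), integer(1))
  bistable <- n_stable >= 2
  if (any(bistable) && sum(bistable) < 3) {
    warning("bistable window barely resolved; rescanning at finer resolution")
    return(bifurcation_scan(params, B_range, resolution * 4))
  }
  branches <- data.frame(B = Bs, L_low = NA_real_, L_unstable = NA_real_,
                         L_high = NA_real_)
  last_low <- NA_real_
  last_high <- NA_real_
  for (i in seq_along(Bs)) {
    e <- eq_list[[i]]
    st <- e$L[e$stable]
    un <- e$L[!e$stable]
    if (length(st) >= 2) {
      branches$L_low[i] <- last_low <- min(st)
      branches$L_high[i] <- last_high <- max(st)
    } else if (length(st) == 1) {
      # attach a single stable equilibrium to the nearer branch seen so
      # far (continuity); with no history it is the low branch
      to_high <- !is.na(last_high) &&
        (is.na(last_low) || abs(st - last_high) < abs(st - last_low))
      if (to_high) branches$L_high[i] <- last_high <- st
      else branches$L_low[i] <- last_low <- st
    }
    if (length(un)) branches$L_unstable[i] <- max(un)
  }
  # saddle-node refinement: bisection on the stable-equilibrium count
  refine <- function(B_lo, B_hi, count_lo) {
    for (k in 1:60) {
      mid <- (B_lo + B_hi) / 2
      cnt <- sum(ltp_equilibria(params, mid)$stable)
      if (cnt == count_lo) B_lo <- mid else B_hi <- mid
      if (B_hi - B_lo < 1e-10) break
    }
    (B_lo + B_hi) / 2
  }
  B_on <- NA_real_
  B_off <- NA_real_
  if (any(bistable)) {
    i_last <- max(which(bistable))
    i_first <- min(which(bistable))
    if (i_last < length(Bs))
      B_on <- refine(Bs[i_last], Bs[i_last + 1], 2L)
    if (i_first > 1)
      B_off <- refine(Bs[i_first - 1], Bs[i_first], 1L)
  }
  eq0 <- ltp_equilibria(params, 0)
  st0 <- eq0$L[eq0$stable]
  regime <- if (length(st0) >= 2) "irreversible"
    else if (any(bistable)) "reversible_bistable" else "monostable"
  if (regime == "irreversible" && min(Bs) == 0) B_off <- NA_real_
  structure(list(regime = regime, B_on = B_on, B_off = B_off,
                 equilibria_at_zero = eq0, branches = branches,
                 params = params),
            class = "bifurcation_result")
}

#' @export
print.bifurcation_result <- function(x, ...) {
  cat("LTP switch regime:", x$regime, "\n")
  cat(sprintf("B_on %s, B_off %s\n",
              format(x$B_on, digits = 6), format(x$B_off, digits = 6)))
  cat("Equilibria at B = 0:\n")
  print(x$equilibria_at_zero)
  invisible(x)
}

#' @export
plot.bifurcation_result <- function(x, ...) {
  br <- x$branches
  graphics::plot(NA, xlim = range(br$B), ylim = c(0, max(br, na.rm = TRUE)),
                 xlab = "BDNF input B (a.u.)", ylab = "LTP level L (a.u.)",
                 main = paste("regime:", x$regime), ...)
  graphics::lines(br$B, br$L_low, lwd = 2, col = "steelblue")
  graphics::lines(br$B, br$L_high, lwd = 2, col = "firebrick")
  graphics::lines(br$B, br$L_unstable, lty = 2, col = "grey40")
  invisible(x)
}

#' Quasi-static hysteresis trace
#'
#' Sweeps the BDNF input from 0 up to `B_max` and back, relaxing the LTP
#' level to the nearest stable equilibrium at each step by a short ODE
#' integration. The up-sweep jumps to the high branch at `B_on`, the
#' down-sweep returns at `B_off` (never, within the sweep, if the switch
#' is irreversible); the enclosed loop area is positive iff the switch is
#' bistable in the swept range.
#'
#' @inheritParams ltp_rhs
#' @param B_max Upper end of the sweep.
#' @param step Quasi-static step; default 1% of `B_max`. A step wider than
#'   the bistable window can skip the jumps (warning).
#' @param relax_time Relaxation time per step, default `20/delta`.
#' @return A data frame of class `hysteresis_trace` with columns
#'   `direction` (`"up"`/`"down"`), `B`, `L`.
#' @examples
#' hy <- hysteresis_trace(plasticity_params(), B_max = 1)
#' @export
hysteresis_trace <- function(params, B_max = 1.5, step = NULL,
                             relax_time = NULL) {
  stopifnot(inherits(params, "plasticity_params"))
  if (is.null(step)) step <- 0.01 * B_max
  if (is.null(relax_time)) relax_time <- 20 / params$delta
  bi <- bifurcation_scan(params, c(0, B_max))
  if (!is.na(bi$B_on) && !is.na(bi$B_off) && step > (bi$B_on - bi$B_off))
    warning("quasi-static step exceeds the bistable window; jumps may be skipped")
  relax <- function(L0, B) {
    sol <- deSolve::ode(y = L0, times = c(0, relax_time),
                        func = function(t, L, p)
                          list(ltp_rhs(max(L, 0), params, B)),
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
    max(sol[nrow(sol), 2], 0)
  }
  up_B <- seq(0, B_max, by = step)
  down_B <- rev(up_B)
  L <- min(ltp_equilibria(params, 0)$L)
  up_L <- numeric(length(up_B))
  for (i in seq_along(up_B)) up_L[i] <- L <- relax(L, up_B[i])
  down_L <- numeric(length(down_B))
  for (i in seq_along(down_B)) down_L[i] <- L <- relax(L, down_B[i])
  out <- data.frame(direction = rep(c("up", "down"),
                                    c(length(up_B), length(down_B))),
                    B = c(up_B, down_B), L = c(up_L, down_L))
  attr(out, "params") <- params
  class(out) <- c("hysteresis_trace", "data.frame")
  out
}

#' Coupling from LTP level to connection weights
#'
#' Saturating map `m(L) = 1 + lambda L / (L + K_m)` applied as a
#' multiplier to the connection weights of a [weight_scheme()]: always to
#' the inhibitory weight (excess LTP in GABAergic fibres strengthens the
#' inhibitory vestibulocerebellar connections), and by default also to the
#' excitatory weight. Strengthening both classes tracks the ensemble's
#' oscillation-probability surface along its monotone direction -- the
#' tendency to oscillate is highest when both inhibitory and excitatory
#' connections are strong -- whereas strengthening inhibition alone at
#' fixed moderate excitation leaves the high-inhibition plateau, where the
#' probability slowly declines. `m` is monotone nondecreasing, `m(0) = 1`,
#' bounded by `1 + lambda`.
#'
#' @param lambda Maximal extra gain; the default (6) carries a base
#'   inhibitory weight of 10 into the high-inhibition regime (above ~40)
#'   at the high-LTP state.
#' @param K_m Half-saturation LTP level.
#' @param couple_excitatory Also multiply the excitatory weight
#'   (default `TRUE`).
#' @return An object of class `coupling_map` (callable via
#'   [ltp_to_weights()]).
#' @export
coupling_map <- function(lambda = 6, K_m = 1, couple_excitatory = TRUE) {
  stopifnot(is.finite(lambda), lambda >= 0, is.finite(K_m), K_m > 0)
  structure(list(lambda = lambda, K_m = K_m,
                 couple_excitatory = couple_excitatory),
            class = "coupling_map")
}

#' @rdname coupling_map
#' @param L LTP level, `>= 0`.
#' @param map A [coupling_map()].
#' @param base Base [weight_scheme()].
#' @return `ltp_to_weights()`: the rescaled [weight_scheme()].
#' @examples
#' ltp_to_weights(3, coupling_map(), weight_scheme(1, 10, 10))
#' @export
ltp_to_weights <- function(L, map = coupling_map(),
                           base = weight_scheme(1, 10, 10)) {
  stopifnot(inherits(map, "coupling_map"), length(L) == 1, L >= 0)
  base <- as_weight_scheme(base)
  m <- 1 + map$lambda * L / (L + map$K_m)
  weight_scheme(w_self = base$w_self,
                w_exc = if (map$couple_excitatory) base$w_exc * m
                        else base$w_exc,
                w_inh = base$w_inh * m)
}
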