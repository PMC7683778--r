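# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: dense-grid scans with hand-rolled bisection for
# the plasticity equilibria, analytic fold conditions for the saddle-nodes,
# and direct nonlinear simulation for oscillation decisions.

# All roots of the LTP right-hand side by dense scan + bisection.
scan_equilibria <- function(delta, g, K, n, eta, B, grid_n = 1e4) {
  f <- function(L) -delta * L + g * L^n / (K^n + L^n) + eta * B
  upper <- (g + eta * B) / delta + 1
  grid <- seq(0, upper, length.out = grid_n)
  fv <- f(grid)
  roots <- grid[fv == 0]
  sgn <- sign(fv)
  ch <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in ch) {
    lo <- grid[i]; hi <- grid[i + 1]
    for (k in 1:200) {
      mid <- (lo + hi) / 2
      if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
      if (hi - lo < 1e-14) break
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  sort(unique(roots))
}

# Saddle-node (fold) inputs from the parametrisation B(L) along rhs = 0:
# B(L) = (delta L - g L^n/(K^n + L^n)) / eta; folds are its interior
# stationary points. Returns sorted fold inputs (length 0 when monostable).
fold_inputs <- function(delta, g, K, n, eta, grid_n = 2e4) {
  B_of_L <- function(L) (delta * L - g * L^n / (K^n + L^n)) / eta
  L <- seq(1e-6, g / delta + 1, length.out = grid_n)
  B <- B_of_L(L)
  dB <- diff(B)
  turn <- which(dB[-1] * dB[-length(dB)] < 0) + 1
  vapply(turn, function(i) {
    o <- stats::optimize(B_of_L, c(L[i - 1], L[i + 1]),
                         maximum = dB[i - 1] > 0, tol = 1e-12)
    if (dB[i - 1] > 0) o$maximum else o$minimum
  }, numeric(1)) -> Lf
  sort(B_of_L(Lf))
}

# Does the free nonlinear network reach a sustained oscillation from a
# small perturbation? Adaptive horizon: keep extending while the amplitude
# is still in the undecided band (slowly growing or slowly decaying).
nonlinear_oscillates <- function(net, x0, t_max = 960) {
  t_end <- 60
  repeat {
    tr <- simulate(net, x0 = x0, t_end = t_end, dt = 0.02)
    tail_amp <- max(abs(as.matrix(tr[tr$t > 0.75 * t_end, 2:5])))
    if (tail_amp < 1e-4) return(FALSE)              # decayed
    if (tail_amp > 0.05 || t_end >= t_max) {
      dsc <- detect_oscillation(tr, transient_fraction = 0.5)
      return(dsc$damping_label %in% c("sustained", "growing") &&
               dsc$dominant_frequency > 0 && tail_amp > 0.01)
    }
    t_end <- t_end * 2                              # still undecided
  }
}

canonical_signs <- function() {
  matrix(c(-1,  1, -1,  0,
           -1, -1, -1,  0,
            0, -1, -1, -1,
            0, -1,  1, -1), 4, 4, byrow = TRUE)
}
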