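#' Derive a per-stage RNG seed from a master seed
#'
#' Stable key-derivation for independent, individually reproducible RNG
#' streams: two rounds of the Lehmer multiplicative congruential map modulo
#' 2^31 - 1, keyed by the stage index. Deterministic across platforms and
#' always in `[1, 2^31 - 2]`.
#'
#' @param master Master seed (coerced to integer).
#' @param stage Stage index (non-negative integer).
#' @return A single integer-valued seed.
#' @examples
#' derive_seed(42, 1); derive_seed(42, 2)
#' @export
derive_seed <- function(master, stage) {
  m <- 2147483647                       # 2^31 - 1 (prime)
  a <- 48271                            # a * m < 2^53: exact in doubles
  x <- as.numeric(master) %% m
  x <- (a * x + as.numeric(stage)) %% m
  x <- (a * x + 1) %% m
  if (x < 1) x <- 1
  x
}

# Evaluate `expr` under `seed` (if non-NULL) and restore the caller's RNG
# state afterwards.
with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Dominant frequency of a uniformly sampled series by raw periodogram, with
# quadratic interpolation around the peak bin. Returns 0 when the series has
# (numerically) no power.
dominant_frequency <- function(x, dt) {
  x <- x - mean(x)
  n <- length(x)
  if (n < 8 || sqrt(mean(x^2)) < 1e-12) return(0)
  sp <- stats::spec.pgram(stats::ts(x, deltat = dt), taper = 0, plot = FALSE,
                          detrend = TRUE, fast = TRUE)
  k <- which.max(sp$spec)
  f <- sp$freq[k]
  if (k > 1 && k < length(sp$spec)) {        # quadratic peak refinement
    y1 <- log(sp$spec[k - 1] + 1e-300)
    y2 <- log(sp$spec[k] + 1e-300)
    y3 <- log(sp$spec[k + 1] + 1e-300)
    denom <- y1 - 2 * y2 + y3
    if (is.finite(denom) && abs(denom) > 1e-12) {
      shift <- 0.5 * (y1 - y3) / denom
      shift <- max(-0.5, min(0.5, shift))
      f <- f + shift * (sp$freq[2] - sp$freq[1])
    }
  }
  f
}

# Frequency from mean spacing of upward zero crossings (precise for clean
# near-sinusoidal series); falls back to the periodogram estimate.
crossing_frequency <- function(x, dt) {
  x <- x - mean(x)
  s <- sign(x)
  up <- which(s[-1] > 0 & s[-length(s)] <= 0)
  if (length(up) < 3) return(dominant_frequency(x, dt))
  1 / (mean(diff(up)) * dt)
}

# Local maxima of |x| (peak magnitudes and their times) for envelope fits.
envelope_peaks <- function(x, t) {
  a <- abs(x)
  n <- length(a)
  if (n < 3) return(data.frame(t = numeric(0), a = numeric(0)))
  idx <- which(a[2:(n - 1)] > a[1:(n - 2)] & a[2:(n - 1)] >= a[3:n]) + 1
  idx <- idx[a[idx] > 1e-300]
  data.frame(t = t[idx], a = a[idx])
}

# Exponential envelope rate (1/s) by log-linear regression on peak
# magnitudes; NA when there are too few peaks. Peaks below 1% of the
# largest are dropped: far down the decay the finite-window DC offset of
# the series pollutes |x| and would flatten the fit.
envelope_rate <- function(x, t) {
  pk <- envelope_peaks(x, t)
  pk <- pk[pk$a > max(pk$a, 0) * 1e-2, ]
  if (nrow(pk) < 4) return(NA_real_)
  stats::coef(stats::lm(log(a) ~ t, data = pk))[[2]]
}

sign_changes <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}
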