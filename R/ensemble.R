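#' Sample a structured random Jacobian
#'
#' Draws one Jacobian matrix for the loop network: every non-zero entry is
#' `sign * u * w`, with `u` an independent uniform draw on `[0, 1]` and `w`
#' the weight of the entry's connection class under `scheme`. Absent entries
#' are exactly zero. Uses R's global RNG; call [set.seed()] for
#' reproducibility.
#'
#' @param structure A [loop_structure][canonical_structure] object.
#' @param scheme A [weight_scheme()] (or numeric `c(w_self, w_exc, w_inh)`).
#' @param random_diagonal If `FALSE` the diagonal entries are fixed at
#'   `-w_self` instead of carrying their own random factor.
#' @return A 4x4 numeric matrix.
#' @examples
#' set.seed(1)
#' sample_jacobian(canonical_structure(), weight_scheme(1, 10, 30))
#' @export
sample_jacobian <- function(structure = canonical_structure(),
                            scheme = weight_scheme(),
                            random_diagonal = TRUE) {
  scheme <- as_weight_scheme(scheme)
  w <- class_weights(structure, scheme)
  s <- structure$sign_pattern
  J <- matrix(0, 4, 4, dimnames = dimnames(s))
  nz <- which(s != 0 & w != 0)             # column-major order
  u <- stats::runif(length(nz))
  J[nz] <- s[nz] * u * w[nz]
  if (!random_diagonal) diag(J) <- diag(s) * diag(w)
  J
}

#' Spectral classification of a Jacobian
#'
#' Computes the eigenvalues of a square matrix and flags it as oscillatory
#' when at least one eigenvalue has real part above `tol_re` and imaginary
#' part above `tol_im` in magnitude (both tolerances are relative to the
#' matrix scale `max(1, max|J|)`). Such eigenvalues correspond to growing
#' oscillations of the linear dynamics `dx/dt = J x`. Matrices whose only
#' unstable eigenvalues are real are unstable but not oscillatory.
#'
#' @param J A finite square numeric matrix.
#' @param tol_re,tol_im Relative tolerances for the strict inequalities.
#' @return An object of class `spectral_class`: list with `eigenvalues`
#'   (complex), `oscillatory` (logical) and `category` (one of
#'   `"stable_nonoscillatory"`, `"stable_oscillatory"`,
#'   `"unstable_oscillatory"`, `"unstable_nonoscillatory"`).
#' @examples
#' classify_spectrum(-diag(4))                      # stable, no rotation
#' classify_spectrum(rbind(c(0.1, -1, 0, 0), c(1, 0.1, 0, 0),
#'                         c(0, 0, -1, 0), c(0, 0, 0, -1)))
#' @export
classify_spectrum <- function(J, tol_re = 1e-9, tol_im = 1e-9) {
  if (!is.matrix(J) || nrow(J) != ncol(J))
    stop("'J' must be a square matrix", call. = FALSE)
  if (!all(is.finite(J)))
    stop("'J' must be finite", call. = FALSE)
  scale <- max(1, max(abs(J)))
  ev <- eigen(J, only.values = TRUE)$values
  unst <- Re(ev) > tol_re * scale
  cplx <- abs(Im(ev)) > tol_im * scale
  oscillatory <- any(unst & cplx)
  category <- if (oscillatory) "unstable_oscillatory"
    else if (any(unst)) "unstable_nonoscillatory"
    else if (any(cplx)) "stable_oscillatory"
    else "stable_nonoscillatory"
  structure(list(eigenvalues = ev, oscillatory = oscillatory,
                 category = category, tol_re = tol_re, tol_im = tol_im),
            class = "spectral_class")
}

#' @export
print.spectral_class <- function(x, ...) {
  cat("Spectral classification:", x$category, "\n")
  cat("Eigenvalues:", paste(format(x$eigenvalues, digits = 4),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Monte-Carlo oscillation probability of the loop ensemble
#'
#' Estimates the probability that a randomly sampled Jacobian (see
#' [sample_jacobian()]) has a complex eigenvalue with positive real part,
#' i.e. that the linearised loop network supports growing oscillations.
#'
#' @inheritParams sample_jacobian
#' @param n_samples Number of matrices to draw (>= 1).
#' @param seed Optional integer seed; the estimate is reproducible from it.
#'   The caller's RNG state is preserved.
#' @param tol_re,tol_im Passed to the spectral classification.
#' @return An object of class `osc_estimate`: list with `p_osc`, `se`
#'   (binomial standard error `sqrt(p(1-p)/n)`), `n_samples`, `seed` and
#'   `counts` (tally of the four spectral categories).
#' @examples
#' oscillation_probability(weight_scheme(1, 1, 30), n_samples = 2000, seed = 1)
#' @export
oscillation_probability <- function(scheme = weight_scheme(),
                                    n_samples = 1e5, seed = NULL,
                                    structure = canonical_structure(),
                                    tol_re = 1e-9, tol_im = 1e-9,
                                    random_diagonal = TRUE) {
  scheme <- as_weight_scheme(scheme)
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L)
    stop("'n_samples' must be >= 1", call. = FALSE)
  w <- class_weights(structure, scheme)
  counts <- with_preserved_seed(seed, {
    cpp_ensemble_tally(structure$sign_pattern, w, n_samples,
                       tol_re, tol_im, random_diagonal)
  })
  names(counts) <- c("stable_nonoscillatory", "stable_oscillatory",
                     "unstable_oscillatory", "unstable_nonoscillatory")
  p <- counts[["unstable_oscillatory"]] / n_samples
  structure(list(p_osc = p, se = sqrt(p * (1 - p) / n_samples),
                 n_samples = n_samples, seed = seed, counts = counts,
                 scheme = scheme),
            class = "osc_estimate")
}

#' @export
print.osc_estimate <- function(x, ...) {
  cat(sprintf(
    "Oscillation probability: %.4f (se %.4f, n = %d)\n  scheme: self %g, exc %g, inh %g\n",
    x$p_osc, x$se, x$n_samples, x$scheme$w_self, x$scheme$w_exc,
    x$scheme$w_inh))
  invisible(x)
}

#' Oscillation-probability sweep over connection weights
#'
#' Estimates the oscillation probability on the Cartesian grid of the three
#' weight vectors. Each grid point uses its own RNG stream derived from the
#' master seed, so individual points are independently reproducible.
#'
#' @param w_inh,w_exc,w_self Numeric vectors of class weights (the grid is
#'   their Cartesian product; all non-negative, none empty).
#' @param n_samples Matrices per grid point.
#' @param seed Master seed (integer). Per-point seeds are derived with
#'   [derive_seed()].
#' @inheritParams oscillation_probability
#' @return A data frame of class `osc_sweep` with columns `w_inh`, `w_exc`,
#'   `w_self`, `n_samples`, `p_osc`, `se`, `seed` (the per-point seed).
#' @examples
#' sw <- sweep_oscillation(w_inh = c(1, 30), w_exc = c(1, 100),
#'                         n_samples = 1000, seed = 7)
#' sw
#' @seealso [inhibition_sweep()], [self_inhibition_sweep()]
#' @export
sweep_oscillation <- function(w_inh, w_exc = 1, w_self = 1,
                              n_samples = 1e5, seed = 1,
                              structure = canonical_structure(),
                              tol_re = 1e-9, tol_im = 1e-9,
                              random_diagonal = TRUE) {
  if (length(w_inh) < 1 || length(w_exc) < 1 || length(w_self) < 1)
    stop("weight grids must be non-empty", call. = FALSE)
  if (any(c(w_inh, w_exc, w_self) < 0) || !all(is.finite(c(w_inh, w_exc, w_self))))
    stop("weights must be finite and >= 0", call. = FALSE)
  grid <- expand.grid(w_inh = w_inh, w_exc = w_exc, w_self = w_self,
                      KEEP.OUT.ATTRS = FALSE)
  out <- grid
  out$n_samples <- as.integer(n_samples)
  out$p_osc <- NA_real_
  out$se <- NA_real_
  out$seed <- vapply(seq_len(nrow(grid)), function(i) derive_seed(seed, i),
                     numeric(1))
  for (i in seq_len(nrow(grid))) {
    est <- oscillation_probability(
      weight_scheme(grid$w_self[i], grid$w_exc[i], grid$w_inh[i]),
      n_samples = n_samples, seed = out$seed[i], structure = structure,
      tol_re = tol_re, tol_im = tol_im, random_diagonal = random_diagonal)
    out$p_osc[i] <- est$p_osc
    out$se[i] <- est$se
  }
  attr(out, "master_seed") <- seed
  class(out) <- c("osc_sweep", "data.frame")
  out
}

#' Standard sweep experiments over inhibitory strength
#'
#' `inhibition_sweep()` varies the inhibitory weight over 1-100 for
#' excitatory weights \{1, 10, 100\} at unit self-inhibition; it exposes the
#' three regimes of the loop network (low inhibition: oscillation tendency
#' decreases with excitation; intermediate, roughly 20-40: high tendency
#' nearly independent of excitation; high, 40-100: the effect of excitation
#' reverses). `self_inhibition_sweep()` varies inhibition over 1-30 with
#' self-inhibitory weight in \{0.1, 1, 10\}, showing that oscillations are
#' more likely when self-inhibition is weak.
#'
#' @param n_samples Matrices per grid point (100,000 reproduces the
#'   reference curves; smaller values trade precision for speed).
#' @param step Grid step for the inhibitory weight; the grid always starts
#'   at 1 (`unique(c(1, seq(step, max, step)))`).
#' @param w_exc Excitatory weights (one curve each).
#' @param seed Master seed.
#' @param ... Passed to [sweep_oscillation()].
#' @return An `osc_sweep` data frame.
#' @examples
#' sw <- inhibition_sweep(n_samples = 500, step = 25, seed = 3)
#' @export
inhibition_sweep <- function(n_samples = 1e5, step = 1,
                             w_exc = c(1, 10, 100), seed = 1, ...) {
  stopifnot(step >= 1)
  w_inh <- unique(c(1, seq(step, 100, by = step)))
  sweep_oscillation(w_inh = w_inh, w_exc = w_exc, w_self = 1,
                    n_samples = n_samples, seed = seed, ...)
}

#' @rdname inhibition_sweep
#' @param w_self Self-inhibitory weights (one curve family each).
#' @export
self_inhibition_sweep <- function(n_samples = 1e5, step = 1,
                                  w_exc = c(1, 10, 100),
                                  w_self = c(0.1, 1, 10), seed = 1, ...) {
  stopifnot(step >= 1)
  w_inh <- unique(c(1, seq(step, 30, by = step)))
  sweep_oscillation(w_inh = w_inh, w_exc = w_exc, w_self = w_self,
                    n_samples = n_samples, seed = seed, ...)
}

#' @export
plot.osc_sweep <- function(x, ...) {
  selfs <- sort(unique(x$w_self))
  excs <- sort(unique(x$w_exc))
  cols <- grDevices::hcl.colors(max(3L, length(excs)), "Dark 3")
  op <- graphics::par(mfrow = c(length(selfs), 1),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (ws in selfs) {
    sub <- x[x$w_self == ws, ]
    graphics::plot(NA, xlim = range(sub$w_inh), ylim = c(0, 1),
                   xlab = "inhibitory weight (a.u.)",
                   ylab = "oscillation probability",
                   main = sprintf("self-inhibitory weight d = %g", ws), ...)
    for (k in seq_along(excs)) {
      s2 <- sub[sub$w_exc == excs[k], ]
      s2 <- s2[order(s2$w_inh), ]
      graphics::lines(s2$w_inh, s2$p_osc, col = cols[k], lwd = 2)
    }
    graphics::legend("bottomright", legend = sprintf("w_exc = %g", excs),
                     col = cols[seq_along(excs)], lwd = 2, bty = "n")
  }
  invisible(x)
}
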