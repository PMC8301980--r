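# Independent oracles, kept deliberately separate from the implementation:
# power-series Bessel evaluation, bisection root finding, and brute-force
# pixel loops. These converge/enumerate rather than reusing package code.

# Modified Bessel function of the first kind by its power series
# sum_k (x/2)^{2k+nu} / (k! (k+nu)!); adequate in double precision for the
# moderate arguments the oracle is used at (x <= ~30).
bessel_series <- function(x, nu, terms = 80L) {
  k <- 0:(terms - 1L)
  sum((x / 2)^(2 * k + nu) / (factorial(k) * gamma(k + nu + 1)))
}

# High-precision series/quadrature evaluation of the disk recovery fraction.
oracle_f <- function(t, tau) {
  x <- 2 * tau / t
  exp(-x) * (bessel_series(x, 0) + bessel_series(x, 1))
}

# Plain bisection, independent of stats::uniroot.
bisect <- function(fn, lo, hi, tol = 1e-12, maxit = 200L) {
  flo <- fn(lo)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- fn(mid)
    if (abs(hi - lo) < tol) break
    if (sign(fm) == sign(flo)) {
      lo <- mid
      flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# Brute-force per-pixel ROI mean: explicit double loop over pixel centers.
pixel_loop_roi_mean <- function(frame, center, radius) {
  acc <- 0
  n <- 0L
  for (i in seq_len(nrow(frame))) {
    for (j in seq_len(ncol(frame))) {
      if ((i - center[1L])^2 + (j - center[2L])^2 <= radius^2) {
        acc <- acc + frame[i, j]
        n <- n + 1L
      }
    }
  }
  acc / n
}

# Shared fixture: the default acquisition geometry.
default_geom <- function() bleach_geometry()

# Simulated noiseless trace for a given parameter triple (uses the public
# model on an explicit time grid; the fitting round-trip target).
model_trace <- function(a, b, tau_d, n = 100L, dt = 0.5) {
  t <- (seq_len(n) - 0.5) * dt
  recovery_trace(t, recovery_model(t, a, b, tau_d))
}
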