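# Shared fixtures and independent oracles for the test suite.

# Standard dynamic time grid: 90 frames at 8 s, injection at 120 s.
std_times <- (0:89) * 8
std_aif <- function() aif_template(std_times, 120)

# Small fast phantom for module-level tests.
small_phantom <- function(noise = list(model = "none", sigma = 0, snr = NULL),
                          seed = 1L) {
  simulate_dataset(default_tbi_spec(grid = c(32, 32, 2), noise = noise,
                                    seed = seed))
}

# Independent O(n^2) trapezoid evaluation of the exponential-weighted
# convolution integral (oracle for the recursive implementation).
conv_direct <- function(cp, times, kep_s) {
  vapply(seq_along(times), function(i) {
    if (i == 1) return(0)
    w <- cp[1:i] * exp(-kep_s * (times[i] - times[1:i]))
    pracma::trapz(times[1:i], w)
  }, numeric(1))
}

# Brute-force SSE over a (ktrans, vp) grid for the irreversible model;
# returns the grid minimum. Rates in min^-1.
brute_sse_model2 <- function(y, cp, times, kt_grid, vp_grid) {
  x2 <- conv_direct(cp, times, 0)
  a <- sum(cp^2); d <- sum(x2^2); b <- sum(cp * x2)
  p <- sum(cp * y); q <- sum(x2 * y); yy <- sum(y^2)
  kt_s <- kt_grid / 60
  sse <- outer(vp_grid, kt_s, function(vp, kt)
    yy - 2 * vp * p - 2 * kt * q + vp^2 * a + kt^2 * d + 2 * vp * kt * b)
  min(sse)
}

# Brute-force SSE over a (ktrans, vp, kep) grid for the reversible model.
brute_sse_model3 <- function(y, cp, times, kt_grid, vp_grid, kep_grid) {
  best <- Inf
  a <- sum(cp^2); yy <- sum(y^2); p <- sum(cp * y)
  for (kep in kep_grid) {
    x2 <- conv_direct(cp, times, kep / 60)
    d <- sum(x2^2); b <- sum(cp * x2); q <- sum(x2 * y)
    kt_s <- kt_grid / 60
    sse <- outer(vp_grid, kt_s, function(vp, kt)
      yy - 2 * vp * p - 2 * kt * q + vp^2 * a + kt^2 * d + 2 * vp * kt * b)
    best <- min(best, min(sse))
  }
  best
}
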