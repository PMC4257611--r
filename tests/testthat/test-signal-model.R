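# SPGR signal physics: forward model, R1 inversion, dynamic series, T2 fit.

test_that("spgr_signal matches independently evaluated closed-form values", {
  # frozen from an independent numpy evaluation of the Ernst equation
  expect_equal(spgr_signal(1, 30, 1 / 1.8, 0.064), 0.10635027773592623,
               tolerance = 1e-12)
  expect_equal(spgr_signal(1, 30, 1 / 1.8, 0.200), 0.2336422047882564,
               tolerance = 1e-12)
  # full-recovery limit: tr*r1 -> Inf gives m0 * sin(alpha)
  expect_equal(spgr_signal(2.5, 40, 1, 1e4), 2.5 * sin(40 * pi / 180),
               tolerance = 1e-12)
  # domain errors
  expect_error(spgr_signal(1, 0, 1, 0.064))
  expect_error(spgr_signal(1, 90, 1, 0.064))
  expect_error(spgr_signal(1, 30, -1, 0.064))
  expect_error(spgr_signal(1, 30, 1, 0))
})

test_that("spgr_signal is strictly increasing in r1", {
  r1 <- seq(0.05, 8, length.out = 400)
  for (a in c(5, 15, 30, 45, 75, 89)) {
    for (tr in c(0.064, 0.2, 3)) {
      expect_true(all(diff(spgr_signal(1, a, r1, tr)) > 0))
    }
  }
})

test_that("invert_r1 round-trips spgr_signal to the conditioning limit of doubles", {
  grid <- expand.grid(alpha = seq(5, 85, by = 10),
                      tr = c(0.064, 0.2, 3.0),
                      r1 = c(0.2, 0.5556, 1, 2.3, 5))
  s <- spgr_signal(1, grid$alpha, grid$r1, grid$tr)
  r1_back <- invert_r1(s, 1, grid$alpha, grid$tr)
  rel <- abs(r1_back / grid$r1 - 1)
  # amplification of the signal's representation error through the inverse:
  # kappa = (1-E)(1-cE)/(tr*r1*E*(1-c)); at deep saturation (TR*R1 = 15) even
  # exact inversion of the rounded forward signal errs ~3e-9
  a <- grid$alpha * pi / 180
  E <- exp(-grid$tr * grid$r1)
  kappa <- (1 - E) * (1 - cos(a) * E) / (grid$tr * grid$r1 * E * (1 - cos(a)))
  bound <- pmax(1e-11, 64 * .Machine$double.eps * kappa)
  expect_true(all(rel < bound))
  # away from saturation the identity is essentially exact
  expect_lt(max(rel[grid$tr * grid$r1 <= 6]), 1e-12)
  # worked example: signal 0.1063 at 64 ms inverts near 1/1.8
  expect_equal(invert_r1(0.1063503, 1, 30, 0.064), 1 / 1.8, tolerance = 1e-4)
})

test_that("invert_r1 flags inconsistent signals instead of erroring", {
  # signal >= m0 sin(alpha): saturation factor out of range
  expect_true(is.na(invert_r1(0.51, 1, 30, 0.064)))
  expect_true(is.na(invert_r1(0.5, 1, 30, 0.064)))
  # zero or negative signal cannot arise from positive R1
  expect_true(is.na(invert_r1(0, 1, 30, 0.064)))
  expect_true(is.na(invert_r1(-0.05, 1, 30, 0.064)))
  # vectorized: valid and invalid mixed
  out <- invert_r1(c(0.10635027773592623, 0.9), 1, 30, 0.064)
  expect_false(is.na(out[1]))
  expect_true(is.na(out[2]))
})

test_that("compute_r1_series recovers a known r1(t) and averages 15 baseline frames", {
  d <- c(4, 4, 2)
  acq <- acq_params(n_slices = 2, matrix = c(4, 4))
  m0 <- array(runif(prod(d), 50, 150), d)
  alpha <- array(runif(prod(d), 15, 45), d)
  r1_true <- array(0, c(d, 90))
  dyn <- array(0, c(d, 90))
  base_r1 <- array(runif(prod(d), 0.4, 0.7), d)
  for (t in 1:90) {
    bump <- if (std_times[t] >= 120) 0.2 * (1 - exp(-(std_times[t] - 120) / 100)) else 0
    r1_true[, , , t] <- base_r1 + bump
    dyn[, , , t] <- spgr_signal(m0, alpha, r1_true[, , , t], acq$tr_dynamic)
  }
  r1s <- compute_r1_series(dce_series(dyn, std_times, 120), m0, alpha, acq)
  expect_equal(r1s$n_baseline, 15L)  # 2 min baseline at 8 s/frame
  expect_true(all(r1s$valid_mask))
  expect_lt(max(abs(r1s$r1 / r1_true - 1)), 1e-8)
  expect_lt(max(abs(r1s$baseline_r1 / base_r1 - 1)), 1e-8)
  expect_equal(r1s$delta_r1, r1s$r1 - as.vector(r1s$baseline_r1),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a contrast-free series yields identically zero delta_r1", {
  d <- c(4, 4, 1)
  acq <- acq_params(n_slices = 1, matrix = c(4, 4))
  m0 <- array(100, d); alpha <- array(30, d)
  fr <- spgr_signal(m0, alpha, array(0.5556, d), acq$tr_dynamic)
  dyn <- array(fr, c(d, 90))
  r1s <- compute_r1_series(dce_series(dyn, std_times, 120), m0, alpha, acq)
  expect_lt(max(abs(r1s$delta_r1)), 1e-12)
})

test_that("compute_r1_series errors when no frame precedes the injection", {
  d <- c(2, 2, 1)
  acq <- acq_params(n_slices = 1, matrix = c(2, 2))
  dyn <- array(1, c(d, 90))
  expect_error(
    compute_r1_series(dce_series(dyn, std_times + 500, 500),
                      array(100, d), array(30, d), acq),
    "baseline")
})

test_that("fit_t2_map recovers T2 exactly from noiseless multi-echo data", {
  tes <- c(0.018, 0.054, 0.090, 0.126)
  d <- c(5, 5, 1)
  t2_true <- array(runif(prod(d), 0.03, 0.12), d)
  echoes <- lapply(tes, function(te) exp(-te / t2_true))
  fit <- fit_t2_map(echoes, tes)
  expect_true(all(fit$valid))
  expect_lt(max(abs(fit$t2 / t2_true - 1)), 1e-10)
})

test_that("fit_t2_map flags zero-decay and non-positive voxels without failing", {
  tes <- c(0.018, 0.054, 0.090, 0.126)
  d <- c(2, 2, 1)
  flat <- lapply(tes, function(te) array(1, d))
  fit <- fit_t2_map(flat, tes)
  expect_true(all(!fit$valid))
  expect_true(all(is.infinite(fit$t2)))
  neg <- lapply(tes, function(te) array(c(-1, 1, 1, 1), d) * exp(-te / 0.06))
  fit2 <- fit_t2_map(neg, tes)
  expect_true(is.na(fit2$t2[1, 1, 1]))
  expect_false(fit2$valid[1, 1, 1])
  expect_true(all(fit2$valid[-1]))
})

test_that("fit_t2_map is accurate in the median under realistic noise", {
  tes <- c(0.018, 0.054, 0.090, 0.126)
  d <- c(500, 1, 1)
  t2_true <- 0.060
  set.seed(7)
  echoes <- lapply(tes, function(te)
    array(exp(-te / t2_true) + rnorm(prod(d), sd = 1 / 50), d))
  fit <- fit_t2_map(echoes, tes)
  med <- median(fit$t2[fit$valid])
  expect_lt(abs(med / t2_true - 1), 0.05)
})
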