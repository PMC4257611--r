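# Extended Kety forward model, model-2/model-3 fits, F-selection.

test_that("kety_forward limits: zero parameters, irreversible reduction", {
  aif <- std_aif()
  expect_true(all(kety_forward(kinetic_params(0, 0, 0), aif) == 0))
  # kep = 0 reduces exactly to vp*Cp + ktrans * cumulative trapezoid of Cp
  p <- kinetic_params(0.03, 0.015, 0)
  expected <- 0.015 * aif$values +
    (0.03 / 60) * as.numeric(pracma::cumtrapz(std_times, aif$values))
  expect_equal(kety_forward(p, aif), expected, tolerance = 1e-12)
})

test_that("kety_forward matches the constant-input closed form within 0.1%", {
  cc <- 2.0
  cp <- rep(cc, length(std_times))
  # trapezoid discretization error scales as (kep*dt)^2/12, so the 0.1% claim
  # holds across the physiological BBB-leakage range (kep well below 1 min^-1)
  for (kep in c(0.1, 0.3, 0.5)) {
    p <- kinetic_params(0.05, 0, kep)
    got <- kety_forward(p, cp, std_times)
    cf <- (0.05 / 60) * cc / (kep / 60) * (1 - exp(-(kep / 60) * std_times))
    expect_lt(max(abs(got[-1] / cf[-1] - 1)), 1e-3)
  }
})

test_that("the recursive convolution agrees with direct trapezoid evaluation", {
  aif <- std_aif()
  for (kep in c(0.01, 0.2, 1, 5)) {
    p <- kinetic_params(1, 0, kep)
    direct <- conv_direct(aif$values, std_times, kep / 60) / 60
    expect_equal(kety_forward(p, aif), direct, tolerance = 1e-12)
  }
})

test_that("fit_model2 is exact when the curve lies in the model span", {
  aif <- std_aif()
  y <- kety_forward(kinetic_params(0.01, 0.01, 0), aif)
  f <- fit_model2(y, aif)
  expect_lt(abs(f$params$ktrans / 0.01 - 1), 1e-8)
  expect_lt(abs(f$params$vp / 0.01 - 1), 1e-8)
  expect_lt(f$sse, 1e-16)
  expect_identical(f$model_id, 2L)
  # the zero curve fits with zero parameters and zero residual
  f0 <- fit_model2(rep(0, 90), aif)
  expect_equal(f0$params$ktrans, 0)
  expect_equal(f0$params$vp, 0)
  expect_equal(f0$sse, 0)
  # a rank-deficient design (all-zero AIF) is flagged, not crashed
  fbad <- fit_model2(y, rep(0, 90), std_times)
  expect_false(fbad$valid)
})

test_that("fit_model2 attains the brute-force grid optimum", {
  aif <- std_aif()
  set.seed(21)
  for (i in 1:5) {
    y <- kety_forward(kinetic_params(runif(1, 0.002, 0.05),
                                     runif(1, 0.002, 0.03), 0), aif) +
      rnorm(90, sd = 0.003)
    f <- fit_model2(y, aif)
    gmin <- brute_sse_model2(y, aif$values, std_times,
                             seq(0, 0.08, length.out = 120),
                             seq(0, 0.05, length.out = 100))
    expect_lte(f$sse, gmin + 1e-12)
  }
})

test_that("fit_model3 recovers reversible parameters from clean curves", {
  aif <- std_aif()
  f <- fit_model3(kety_forward(kinetic_params(0.05, 0.01, 0.2), aif), aif)
  expect_lt(abs(f$params$ktrans / 0.05 - 1), 1e-4)
  expect_lt(abs(f$params$vp / 0.01 - 1), 1e-4)
  expect_lt(abs(f$params$kep / 0.2 - 1), 1e-4)
  expect_identical(f$model_id, 3L)
})

test_that("model 3 nests model 2: kep = 0 truth gives identical SSE", {
  aif <- std_aif()
  set.seed(22)
  y <- kety_forward(kinetic_params(0.01, 0.01, 0), aif) + rnorm(90, sd = 0.002)
  f2 <- fit_model2(y, aif)
  f3 <- fit_model3(y, aif)
  expect_lte(f3$sse, f2$sse)
  # clean kep=0 curve: the kep=0 candidate wins and ties model 2 exactly
  yc <- kety_forward(kinetic_params(0.01, 0.01, 0), aif)
  f3c <- fit_model3(yc, aif)
  expect_identical(f3c$sse, fit_model2(yc, aif)$sse)
  expect_equal(f3c$params$kep, 0)
})

test_that("variable projection beats a dense 3-D brute-force grid on random voxels", {
  aif <- std_aif()
  set.seed(23)
  n_vox <- 20
  for (i in seq_len(n_vox)) {
    kt <- runif(1, 0.003, 0.06); vp <- runif(1, 0.002, 0.03)
    kep <- sample(c(0, runif(1, 0.05, 1)), 1)
    y <- kety_forward(kinetic_params(kt, vp, kep), aif) + rnorm(90, sd = 0.004)
    f3 <- fit_model3(y, aif)
    gmin <- brute_sse_model3(y, aif$values, std_times,
                             seq(0, 0.09, length.out = 60),
                             seq(0, 0.05, length.out = 40),
                             c(0, exp(seq(log(1e-3), log(2), length.out = 30))))
    expect_lte(f3$sse, gmin + 1e-12)
  }
})

test_that("f_statistic implements the nested-model formula with its sentinels", {
  mk <- function(sse, id, n = 90) structure(
    list(params = kinetic_params(0, 0, 0), sse = sse, n = n,
         model_id = id, valid = TRUE), class = "model_fit")
  expect_equal(f_statistic(mk(2, 2), mk(1, 3)), 87)   # (2-1)/(1/87)
  expect_equal(f_statistic(mk(1, 2), mk(1, 3)), 0)
  expect_identical(f_statistic(mk(1, 2), mk(0, 3)), Inf)
  expect_identical(f_statistic(mk(0, 2), mk(0, 3)), 0)  # perfect tie keeps model 2
  expect_error(f_statistic(mk(1, 2, n = 3), mk(0.5, 3, n = 3)))
})

test_that("select_and_combine stitches maps by the F threshold", {
  fits2 <- list(ktrans = c(1, 2, 3), vp = c(.1, .2, .3), kep = c(0, 0, 0),
                sse = c(2, 2, 2), n = 90)
  fits3 <- list(ktrans = c(10, 20, 30), vp = c(.5, .6, .7), kep = c(1, 1, 1),
                sse = c(2, 1.6, 0.5), n = 90)
  # voxel 1: F = 0; voxel 2: F moderate; voxel 3: F large. Setting the
  # threshold to voxel 2's own F checks that an exact tie keeps model 2.
  f_all <- select_and_combine(fits2, fits3, f0 = 1e9)$f_stat
  sel <- select_and_combine(fits2, fits3, f0 = f_all[2])
  expect_equal(sel$mask3, c(FALSE, FALSE, TRUE))
  expect_equal(sel$ktrans_final, c(1, 2, 30))
  expect_equal(sel$kep_final, c(0, 0, 1))
  # all-zero F keeps the model-2 map exactly
  fits3b <- list(ktrans = c(9, 9, 9), vp = c(0, 0, 0), kep = c(1, 1, 1),
                 sse = fits2$sse, n = 90)
  selb <- select_and_combine(fits2, fits3b, 10)
  expect_true(all(!selb$mask3))
  expect_equal(selb$ktrans_final, fits2$ktrans)
})

test_that("F is non-negative and invariant under joint rescaling of curve and AIF", {
  aif <- std_aif()
  set.seed(24)
  Y <- sapply(1:30, function(i)
    kety_forward(kinetic_params(runif(1, 0, 0.05), runif(1, 0, 0.03),
                                sample(c(0, 0.3), 1)), aif) +
      rnorm(90, sd = 0.003))
  f1 <- fit_curves(Y, aif)
  expect_true(all(f1$model3$sse <= f1$model2$sse + 1e-14))
  expect_true(all(f1$f_stat >= 0))
  for (c0 in c(0.5, 3)) {
    scaled <- aif; scaled$values <- c0 * aif$values
    f2 <- fit_curves(c0 * Y, scaled)
    expect_equal(f2$f_stat, f1$f_stat, tolerance = 1e-6)
  }
})

test_that("fit_volume recovers regional truth on the noiseless phantom and is deterministic", {
  ph <- small_phantom()
  cal <- calibrate(ph$prescans, ph$masks$brain, ph$spec$acq)
  r1s <- compute_r1_series(ph$dynamic, cal$m0, cal$alpha_smooth, ph$spec$acq)
  maps <- fit_volume(r1s, ph$truth$aif, mask = ph$masks$brain)
  expect_true(all(ph$masks$brain == maps$fitted_mask))
  err <- abs(maps$ktrans_final - ph$truth$ktrans)[maps$fitted_mask]
  expect_lt(max(err), 1e-3)
  maps2 <- fit_volume(r1s, ph$truth$aif, mask = ph$masks$brain)
  expect_identical(maps$ktrans_final, maps2$ktrans_final)
  expect_identical(maps$f_stat, maps2$f_stat)
})
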