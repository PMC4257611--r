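# Voxelwise extended Kety modeling in delta-R1 units: forward convolution,
# irreversible (model 2) and reversible (model 3) fits by variable projection,
# nested-model F-statistic selection, and final K-trans map assembly.
#
# Unit bookkeeping: K-trans and k_ep are expressed in min^-1 at every
# interface; integration runs on the seconds time grid internally. Because
# tissue and plasma curves share delta-R1 units, K-trans carries no relaxivity
# conversion.

#' Kinetic parameter triple
#'
#' @param ktrans Volume transfer coefficient, min^-1.
#' @param vp Plasma volume fraction (dimensionless).
#' @param kep Reversible back-flux rate, min^-1 (0 for the irreversible model).
#' @return Object of class `kinetic_params`.
#' @export
kinetic_params <- function(ktrans, vp, kep = 0) {
  stopifnot(is.finite(ktrans), is.finite(vp), is.finite(kep), kep >= 0)
  structure(list(ktrans = ktrans, vp = vp, kep = kep), class = "kinetic_params")
}

# Exponential-weighted running convolution
#   I(t_i) = int_0^{t_i} cp(tau) exp(-kep (t_i - tau)) dtau
# by the recursive trapezoid identity
#   I_i = E_i I_{i-1} + dt_i/2 (E_i cp_{i-1} + cp_i),  E_i = exp(-kep dt_i),
# which is algebraically the full-grid trapezoid of the sampled integrand but
# O(n) and immune to exp overflow. `kep_s` (s^-1) may be a vector: one column
# of the result per rate.
.conv_exp <- function(cp, times, kep_s) {
  n <- length(times); V <- length(kep_s)
  out <- matrix(0, n, V)
  prev <- numeric(V)
  for (i in 2:n) {
    dt <- times[i] - times[i - 1]
    E <- exp(-kep_s * dt)
    prev <- prev * E + dt / 2 * (cp[i - 1] * E + cp[i])
    out[i, ] <- prev
  }
  out
}

#' Forward extended Kety model
#'
#' Tissue delta-R1 predicted from a plasma input:
#' \deqn{\Delta R_1(t) = v_p C_p(t) +
#'       K^{trans} \int_0^t C_p(\tau) e^{-k_{ep}(t-\tau)} d\tau,}
#' evaluated by trapezoidal discretization on the frame grid. With
#' `kep = 0` this reduces exactly to the irreversible-leakage model
#' `vp * Cp + ktrans * cumtrapz(Cp)`.
#'
#' @param p A [kinetic_params()] (rates in min^-1).
#' @param aif An `aif_curve` giving `Cp(t)` in s^-1, or a numeric vector on
#'   `times`.
#' @param times Frame times in seconds (defaults to the curve's own grid).
#' @return Numeric tissue delta-R1 curve, s^-1.
#' @export
kety_forward <- function(p, aif, times = NULL) {
  stopifnot(inherits(p, "kinetic_params"))
  if (inherits(aif, "aif_curve")) {
    if (is.null(times)) times <- aif$times
    cp <- aif$values
  } else cp <- as.numeric(aif)
  stopifnot(length(cp) == length(times))
  conv <- .conv_exp(cp, times, p$kep / 60)[, 1]
  p$vp * cp + (p$ktrans / 60) * conv
}

# Two-regressor least squares with a shared design [cp, x2] for all columns of
# Y (n x V). Returns vp, kt_s (s^-1) and sse per column. Rank-deficient
# designs (e.g. an all-zero AIF) yield valid = FALSE.
.ls_shared <- function(Y, cp, x2) {
  a <- sum(cp * cp); b <- sum(cp * x2); d <- sum(x2 * x2)
  det <- a * d - b * b
  scale <- max(a, d)
  if (!is.finite(det) || scale <= 0 || det <= .Machine$double.eps * scale^2) {
    V <- ncol(Y)
    return(list(vp = rep(NA_real_, V), kt_s = rep(NA_real_, V),
                sse = rep(NA_real_, V), valid = rep(FALSE, V)))
  }
  p <- colSums(cp * Y); q <- colSums(x2 * Y)
  vp <- (d * p - b * q) / det
  kt <- (a * q - b * p) / det
  R <- Y - tcrossprod(cp, vp) - tcrossprod(x2, kt)
  list(vp = vp, kt_s = kt, sse = colSums(R * R), valid = rep(TRUE, ncol(Y)))
}

# Same but with a per-column second regressor X2 (n x V), column j pairing
# with Y[, j].
.ls_percol <- function(Y, cp, X2) {
  a <- sum(cp * cp)
  b <- colSums(cp * X2)
  d <- colSums(X2 * X2)
  p <- colSums(cp * Y)
  q <- colSums(X2 * Y)
  det <- a * d - b * b
  bad <- !is.finite(det) | det <= .Machine$double.eps * pmax(a, d)^2
  det[bad] <- 1
  vp <- (d * p - b * q) / det
  kt <- (a * q - b * p) / det
  R <- Y - tcrossprod(cp, vp) - X2 * rep(kt, each = nrow(Y))
  sse <- colSums(R * R)
  vp[bad] <- NA_real_; kt[bad] <- NA_real_; sse[bad] <- NA_real_
  list(vp = vp, kt_s = kt, sse = sse, valid = !bad)
}

#' Default k_ep search grid
#'
#' Log-spaced candidates for the variable-projection search over the
#' reversible rate, plus the exact `kep = 0` candidate that makes model 3 nest
#' model 2.
#'
#' @param n Number of log-spaced points (default 50).
#' @param lo,hi Bounds in min^-1 (defaults 1e-3 and 10).
#' @return Sorted numeric vector of k_ep candidates in min^-1, starting at 0.
#' @export
default_kep_grid <- function(n = 50, lo = 1e-3, hi = 10) {
  c(0, exp(seq(log(lo), log(hi), length.out = n)))
}

# Core fitting engine: fits models 2 and 3 to every column of Y (n x V).
# Model 3 uses variable projection over the kep grid followed by iterative
# 5-point bracket refinement between the grid neighbours of the minimum; the
# kep = 0 candidate guarantees sse3 <= sse2 (identical arithmetic path).
.fit_kinetics_engine <- function(Y, cp, times, kep_grid = default_kep_grid(),
                                 refine = TRUE, zoom_iter = 14L) {
  n <- nrow(Y); V <- ncol(Y)
  stopifnot(length(cp) == n, length(times) == n, n > 3)
  kgs <- sort(unique(c(0, kep_grid))) / 60   # s^-1
  K <- length(kgs)

  cum_cp <- .conv_exp(cp, times, 0)[, 1]     # cumulative trapezoid of Cp
  fit2 <- .ls_shared(Y, cp, cum_cp)

  best <- list(sse = fit2$sse, vp = fit2$vp, kt = fit2$kt_s,
               kep = numeric(V), idx = rep(1L, V))
  for (k in 2:K) {
    x2 <- .conv_exp(cp, times, kgs[k])[, 1]
    f <- .ls_shared(Y, cp, x2)
    upd <- is.finite(f$sse) & (!is.finite(best$sse) | f$sse < best$sse)
    best$sse[upd] <- f$sse[upd]; best$vp[upd] <- f$vp[upd]
    best$kt[upd] <- f$kt_s[upd]; best$kep[upd] <- kgs[k]; best$idx[upd] <- k
  }

  if (refine && V > 0) {
    lo <- kgs[pmax(best$idx - 1L, 1L)]
    hi <- kgs[pmin(best$idx + 1L, K)]
    act <- which(fit2$valid & hi > lo & best$idx > 1L)  # kep=0 winners stay exact
    if (length(act)) {
      Ya <- Y[, act, drop = FALSE]
      loa <- lo[act]; hia <- hi[act]
      for (z in seq_len(zoom_iter)) {
        sse5 <- matrix(NA_real_, length(act), 5)
        par5 <- vector("list", 5)
        for (j in 1:5) {
          kc <- loa + (hia - loa) * (j - 1) / 4
          X2 <- .conv_exp(cp, times, kc)
          f <- .ls_percol(Ya, cp, X2)
          sse5[, j] <- f$sse
          par5[[j]] <- list(kep = kc, vp = f$vp, kt = f$kt_s)
        }
        sse5[!is.finite(sse5)] <- .Machine$double.xmax
        m <- max.col(-sse5, ties.method = "first")
        for (j in 1:5) {
          sel <- which(m == j & is.finite(sse5[, j]))
          if (!length(sel)) next
          gi <- act[sel]
          better <- sse5[sel, j] < best$sse[gi]
          gi <- gi[better]; sel <- sel[better]
          best$sse[gi] <- sse5[sel, j]
          best$kep[gi] <- par5[[j]]$kep[sel]
          best$vp[gi] <- par5[[j]]$vp[sel]
          best$kt[gi] <- par5[[j]]$kt[sel]
        }
        width <- (hia - loa) / 4
        ctr <- loa + width * (m - 1)
        loa <- pmax(ctr - width, lo[act])
        hia <- pmin(ctr + width, hi[act])
      }
    }
  }

  list(model2 = list(ktrans = fit2$kt_s * 60, vp = fit2$vp, kep = numeric(V),
                     sse = fit2$sse, valid = fit2$valid, n = n, model_id = 2L),
       model3 = list(ktrans = best$kt * 60, vp = best$vp, kep = best$kep * 60,
                     sse = best$sse, valid = fit2$valid & is.finite(best$sse),
                     n = n, model_id = 3L))
}

.as_model_fit <- function(f, i = 1L) {
  structure(list(params = kinetic_params(ifelse(is.na(f$ktrans[i]), 0, f$ktrans[i]),
                                         ifelse(is.na(f$vp[i]), 0, f$vp[i]),
                                         ifelse(is.na(f$kep[i]), 0, f$kep[i])),
                 sse = f$sse[i], n = f$n, model_id = f$model_id,
                 valid = f$valid[i]),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> model %d: ktrans=%.4g min^-1, vp=%.4g, kep=%.4g min^-1, sse=%.3g (n=%d)%s\n",
              x$model_id, x$params$ktrans, x$params$vp, x$params$kep, x$sse,
              x$n, if (x$valid) "" else " [invalid]"))
  invisible(x)
}

.curve_inputs <- function(curve, aif, times) {
  if (inherits(aif, "aif_curve")) {
    if (is.null(times)) times <- aif$times
    cp <- aif$values
  } else cp <- as.numeric(aif)
  stopifnot(length(curve) == length(cp), length(cp) == length(times))
  list(Y = matrix(curve, ncol = 1), cp = cp, times = times)
}

#' Fit the irreversible extended Kety model (model 2) to one voxel
#'
#' With `kep = 0` the model is linear in `(vp, ktrans)` with regressors
#' `Cp(t)` and its running integral; the exact least-squares minimizer is
#' computed in closed form (no iterative search).
#'
#' @param curve Tissue delta-R1 curve, s^-1.
#' @param aif An `aif_curve` or numeric plasma curve.
#' @param times Frame times, seconds (defaults to the AIF grid).
#' @return A `model_fit` (model id 2, `kep` fixed at 0). `valid = FALSE`
#'   flags a rank-deficient design (e.g. all-zero AIF).
#' @export
fit_model2 <- function(curve, aif, times = NULL) {
  ci <- .curve_inputs(curve, aif, times)
  if (nrow(ci$Y) < 4) stop("model 2 requires at least 4 frames")
  f <- .fit_kinetics_engine(ci$Y, ci$cp, ci$times, kep_grid = 0, refine = FALSE)
  .as_model_fit(f$model2)
}

#' Fit the reversible extended Kety model (model 3) to one voxel
#'
#' Variable projection: for each candidate `kep` the conditionally linear
#' `(vp, ktrans)` pair is solved in closed form; the `kep` profile is searched
#' on a log grid and refined by bracketed subdivision around the grid minimum.
#' The `kep = 0` candidate is always included, so the model-3 SSE can never
#' exceed the model-2 SSE.
#'
#' @inheritParams fit_model2
#' @param kep_grid Candidate rates, min^-1 (default [default_kep_grid()]).
#' @param refine Refine `kep` between the bracketing grid points (default TRUE).
#' @return A `model_fit` (model id 3).
#' @export
fit_model3 <- function(curve, aif, times = NULL, kep_grid = default_kep_grid(),
                       refine = TRUE) {
  ci <- .curve_inputs(curve, aif, times)
  if (nrow(ci$Y) < 5) stop("model 3 requires at least 5 frames")
  f <- .fit_kinetics_engine(ci$Y, ci$cp, ci$times, kep_grid, refine)
  .as_model_fit(f$model3)
}

.f_stat_values <- function(sse2, sse3, n) {
  if (any(n <= 3)) stop("F-statistic requires n > 3 frames")
  num <- sse2 - sse3
  ifelse(sse3 > 0, num / (sse3 / (n - 3)),
         ifelse(num > 0, Inf, 0))
}

#' Nested-model F-statistic for model 2 versus model 3
#'
#' Models 2 and 3 differ by the single extra parameter `kep`, giving
#' \deqn{F = \frac{SSE_2 - SSE_3}{SSE_3 / (N - 3)}}
#' with degrees of freedom (1, N-3). A perfect model-3 fit with a worse
#' model-2 fit returns `Inf`; two perfect fits tie at 0 (the simpler model is
#' then kept by the selection rule).
#'
#' @param fit2,fit3 `model_fit` objects for the same voxel (same `n`).
#' @return Scalar F value, >= 0 whenever the nesting holds.
#' @export
f_statistic <- function(fit2, fit3) {
  stopifnot(inherits(fit2, "model_fit"), inherits(fit3, "model_fit"),
            fit2$model_id == 2, fit3$model_id == 3)
  if (fit2$n != fit3$n) stop("fits compare different numbers of frames")
  .f_stat_values(fit2$sse, fit3$sse, fit2$n)
}

#' Combine per-model fits into the final K-trans map
#'
#' The irreversible model is kept unless the reversible model fits
#' significantly better: `mask3 = F > f0` (ties at the threshold keep
#' model 2). Final maps stitch the model-3 parameters inside `mask3` and the
#' model-2 parameters elsewhere; `kep` is 0 outside `mask3`.
#'
#' @param fits2,fits3 Per-voxel fit maps as produced by [fit_volume()]
#'   internals: lists with `ktrans`, `vp`, `kep`, `sse` arrays and scalar `n`.
#' @param f0 F-statistic threshold; default 10.
#' @return Object of class `selection_result`: `f_stat`, `mask3`,
#'   `ktrans_final`, `vp_final`, `kep_final`.
#' @export
select_and_combine <- function(fits2, fits3, f0 = 10) {
  stopifnot(f0 > 0, fits2$n == fits3$n)
  f <- .f_stat_values(fits2$sse, fits3$sse, fits2$n)
  mask3 <- !is.na(f) & f > f0
  pick <- function(a3, a2) ifelse(mask3, a3, a2)
  structure(list(f_stat = f, mask3 = mask3,
                 ktrans_final = pick(fits3$ktrans, fits2$ktrans),
                 vp_final = pick(fits3$vp, fits2$vp),
                 kep_final = ifelse(mask3, fits3$kep, 0),
                 f0 = f0),
            class = "selection_result")
}

#' Fit both kinetic models to a batch of tissue curves
#'
#' Vectorized fitting of models 2 and 3 plus F-statistic selection for a
#' matrix of tissue delta-R1 curves (one column per voxel/replicate). This is
#' the engine behind [fit_volume()], exposed directly for Monte-Carlo
#' parameter-recovery and operating-characteristic studies.
#'
#' @param Y Numeric matrix, frames x curves.
#' @param aif An `aif_curve` or numeric plasma curve.
#' @param times Frame times, seconds (defaults to the AIF grid).
#' @param f0 Selection threshold (default 10).
#' @param kep_grid Candidate `kep` grid, min^-1.
#' @param refine Refine the `kep` minimum between grid points.
#' @return List: `model2` and `model3` (each with per-curve `ktrans`, `vp`,
#'   `kep`, `sse`, `valid`), `f_stat`, `mask3`, `ktrans_final`, `vp_final`,
#'   `kep_final`, and `n` (frames per curve).
#' @export
fit_curves <- function(Y, aif, times = NULL, f0 = 10,
                       kep_grid = default_kep_grid(), refine = TRUE) {
  if (inherits(aif, "aif_curve")) {
    if (is.null(times)) times <- aif$times
    cp <- aif$values
  } else cp <- as.numeric(aif)
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == length(cp), length(cp) == length(times))
  eng <- .fit_kinetics_engine(Y, cp, times, kep_grid, refine)
  sel <- select_and_combine(eng$model2, eng$model3, f0)
  c(list(model2 = eng$model2, model3 = eng$model3), unclass(sel),
    list(n = nrow(Y)))
}

#' Voxelwise kinetic fitting over a volume
#'
#' Fits models 2 and 3 to every valid voxel of a delta-R1 series, applies the
#' F-statistic selection, and assembles the per-model and final parameter
#' maps. Fitting is deterministic: no randomness, voxels independent, no
#' spatial regularization.
#'
#' @param r1s An `r1_series` from [compute_r1_series()].
#' @param aif An `aif_curve` (the scaled plasma input).
#' @param mask Optional logical 3-D array further restricting the fit
#'   (default: the series' own valid mask).
#' @param f0 Selection threshold (default 10).
#' @param kep_grid Candidate `kep` grid, min^-1.
#' @param refine Refine the `kep` minimum between grid points.
#' @return Object of class `ktrans_maps`: 3-D arrays `ktrans_final`,
#'   `vp_final`, `kep_final`, `f_stat`, `mask3`, `fitted_mask`, plus
#'   `model2` and `model3` sub-lists with their `ktrans`, `vp`, `kep`, `sse`
#'   maps, and scalar `n`.
#' @export
fit_volume <- function(r1s, aif, mask = NULL, f0 = 10,
                       kep_grid = default_kep_grid(), refine = TRUE) {
  stopifnot(inherits(r1s, "r1_series"), inherits(aif, "aif_curve"))
  d <- dim(r1s$delta_r1)
  stopifnot(length(aif$values) == d[4])
  use <- r1s$valid_mask
  if (!is.null(mask)) use <- use & mask
  M <- matrix(r1s$delta_r1, prod(d[1:3]), d[4])
  idx <- which(as.vector(use) & apply(is.finite(M), 1, all))
  if (!length(idx)) stop("no valid voxels to fit")
  Y <- t(M[idx, , drop = FALSE])

  eng <- .fit_kinetics_engine(Y, aif$values, r1s$times, kep_grid, refine)
  to_map <- function(v) { a <- array(NA_real_, d[1:3]); a[idx] <- v; a }
  maps2 <- list(ktrans = to_map(eng$model2$ktrans), vp = to_map(eng$model2$vp),
                kep = to_map(eng$model2$kep), sse = to_map(eng$model2$sse),
                n = d[4])
  maps3 <- list(ktrans = to_map(eng$model3$ktrans), vp = to_map(eng$model3$vp),
                kep = to_map(eng$model3$kep), sse = to_map(eng$model3$sse),
                n = d[4])
  sel <- select_and_combine(maps2, maps3, f0)
  fitted <- array(FALSE, d[1:3]); fitted[idx] <- eng$model2$valid
  sel$mask3 <- sel$mask3 & fitted
  structure(list(ktrans_final = sel$ktrans_final, vp_final = sel$vp_final,
                 kep_final = sel$kep_final, f_stat = sel$f_stat,
                 mask3 = sel$mask3, fitted_mask = fitted,
                 model2 = maps2, model3 = maps3, n = d[4], f0 = f0),
            class = "ktrans_maps")
}

#' @export
print.ktrans_maps <- function(x, ...) {
  cat(sprintf("<ktrans_maps> %d voxels fit (n=%d frames, F0=%.3g); model 3 selected in %d (%.1f%%)\n",
              sum(x$fitted_mask), x$n, x$f0, sum(x$mask3),
              100 * sum(x$mask3) / max(1, sum(x$fitted_mask))))
  invisible(x)
}
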