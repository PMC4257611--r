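# Pre-scan calibration for a surface transceiver coil: flip-angle (B1+) map
# from the dual-TR FLASH pair, spatial smoothing, and M0 from the long-TR scan.

#' Dual-TR SPGR magnitude ratio
#'
#' Ratio of SPGR magnitudes at a long and a short TR for unit M0. M0, receive
#' sensitivity and sin(alpha) cancel, leaving a quantity that depends strongly
#' on the flip angle but only weakly on T1 — the basis of dual-TR B1 mapping
#' with a single assumed tissue T1.
#'
#' @param alpha Flip angle, degrees (vectorized).
#' @param t1 Longitudinal relaxation time, seconds.
#' @param tr_long,tr_short The two repetition times, seconds.
#' @return Dimensionless ratio, strictly increasing in `alpha` on (0, 90).
#' @export
flip_ratio <- function(alpha, t1, tr_long = 0.200, tr_short = 0.064) {
  stopifnot(t1 > 0, tr_long > tr_short, tr_short > 0)
  spgr_signal(1, alpha, 1 / t1, tr_long) / spgr_signal(1, alpha, 1 / t1, tr_short)
}

# Grid check that the ratio is strictly monotone in alpha -- precondition for
# bisection; run once per call (cheap) rather than cached.
.check_ratio_monotone <- function(t1, tr_long, tr_short) {
  g <- seq(1, 89, by = 0.5)
  if (any(diff(flip_ratio(g, t1, tr_long, tr_short)) <= 0))
    stop("dual-TR ratio is not monotone in alpha for these TRs/T1")
}

#' Raw flip-angle map from the dual-TR pre-scan pair
#'
#' Inverts the per-voxel magnitude ratio long-TR/short-TR for the flip angle
#' by bisection on \[1, 89\] degrees, assuming a single tissue T1 (brain-tissue
#' T1 is narrowly distributed, so the ratio is dominated by the flip angle).
#' Ratios outside the attainable range (1, ratio(89 deg)\] are flagged `NA`.
#'
#' @param m_long,m_short Magnitude volumes at the long (default 200 ms) and
#'   short (64 ms) TR, same grid.
#' @param t1_assumed Assumed tissue T1 in seconds (default 1.8).
#' @param mask Logical 3-D array restricting the fit (default: all voxels with
#'   positive short-TR signal).
#' @param tr_long,tr_short Repetition times, seconds.
#' @param tol Bisection tolerance, degrees.
#' @return 3-D flip-angle map in degrees, `NA` outside mask or where invalid.
#' @export
estimate_alpha_raw <- function(m_long, m_short, t1_assumed = 1.8, mask = NULL,
                               tr_long = 0.200, tr_short = 0.064, tol = 1e-9) {
  stopifnot(identical(dim(m_long), dim(m_short)))
  .check_ratio_monotone(t1_assumed, tr_long, tr_short)
  if (is.null(mask)) mask <- is.finite(m_short) & m_short > 0
  ratio <- ifelse(mask & m_short > 0, m_long / m_short, NA_real_)
  rmax <- flip_ratio(89, t1_assumed, tr_long, tr_short)
  ratio[!is.finite(ratio) | ratio <= 1 | ratio > rmax] <- NA_real_

  idx <- which(is.finite(ratio))
  out <- array(NA_real_, dim(m_long))
  if (length(idx)) {
    r <- ratio[idx]
    lo <- rep(1, length(idx)); hi <- rep(89, length(idx))
    n_it <- ceiling(log2(88 / tol))
    for (k in seq_len(n_it)) {
      mid <- (lo + hi) / 2
      up <- flip_ratio(mid, t1_assumed, tr_long, tr_short) < r
      lo[up] <- mid[up]; hi[!up] <- mid[!up]
    }
    out[idx] <- (lo + hi) / 2
  }
  out
}

#' Smooth a raw flip-angle map
#'
#' The transmit field of a surface coil varies smoothly with depth, so the raw
#' voxelwise map is replaced by a smooth spatial surrogate. The default fits a
#' low-order 2-D polynomial surface per slice over the valid voxels and
#' evaluates it across the whole mask; Gaussian normalized-convolution
#' smoothing is available as an alternative and as the automatic fallback when
#' the polynomial system is rank-deficient or has too few (< 20) valid voxels.
#' The polynomial fit is robust (Tukey-bisquare IRLS): voxels whose raw angle
#' is locally biased — e.g. tissue whose true T1 deviates from the assumed
#' value — are downweighted against the smooth majority surface.
#' Output is clipped to \[1, 89\] degrees (clips are messaged).
#'
#' @param alpha_raw 3-D raw flip-angle map, degrees; `NA` marks invalid voxels.
#' @param mask Logical 3-D array: where the smooth map is evaluated.
#' @param method `"poly_surface"` (default) or `"gaussian"`.
#' @param order Polynomial surface order (default 3).
#' @param sigma Gaussian kernel standard deviation in voxels (default 3).
#' @param weights Optional non-negative per-voxel fit weights (3-D array).
#' @return Smoothed 3-D flip-angle map, degrees (`NA` outside mask).
#' @export
smooth_alpha <- function(alpha_raw, mask, method = c("poly_surface", "gaussian"),
                         order = 3, sigma = 3, weights = NULL) {
  method <- match.arg(method)
  stopifnot(identical(dim(alpha_raw), dim(mask)))
  d <- dim(alpha_raw)
  out <- array(NA_real_, d)
  for (z in seq_len(d[3])) {
    msk <- mask[, , z]
    if (!any(msk)) next
    sl <- alpha_raw[, , z]
    w <- if (is.null(weights)) NULL else weights[, , z]
    out[, , z] <- if (method == "poly_surface")
      .smooth_slice_poly(sl, msk, order, sigma, w)
    else
      .smooth_slice_gauss(sl, msk, sigma)
  }
  n_clip <- sum(out < 1 | out > 89, na.rm = TRUE)
  if (n_clip > 0) message(n_clip, " smoothed flip-angle voxels clipped to [1, 89] deg")
  out[out < 1] <- 1; out[out > 89] <- 89
  out
}

.poly_design <- function(x, y, order) {
  cols <- list()
  for (i in 0:order) for (j in 0:(order - i)) cols[[length(cols) + 1]] <- x^i * y^j
  do.call(cbind, cols)
}

# Robust per-slice polynomial surface: iteratively reweighted least squares
# with Tukey bisquare weights, so that voxels whose raw angle is locally
# biased (e.g. tissue whose T1 deviates from the assumed value) are
# downweighted against the smooth majority surface. The scale floor keeps the
# noiseless case (residuals ~ machine precision) well conditioned.
.smooth_slice_poly <- function(sl, msk, order, sigma, w, irls_iter = 10) {
  valid <- msk & is.finite(sl)
  nterms <- (order + 1) * (order + 2) / 2
  if (sum(valid) < max(20, nterms)) {
    message("too few valid voxels for polynomial surface; falling back to gaussian")
    return(.smooth_slice_gauss(sl, msk, sigma))
  }
  d <- dim(sl)
  xs <- (row(sl) - (d[1] + 1) / 2) / (d[1] / 2)
  ys <- (col(sl) - (d[2] + 1) / 2) / (d[2] / 2)
  X <- .poly_design(xs[valid], ys[valid], order)
  yv <- sl[valid]
  w0 <- if (is.null(w)) rep(1, length(yv)) else pmax(w[valid], 0)
  wr <- rep(1, length(yv))
  coefs <- NULL
  for (it in seq_len(irls_iter)) {
    fit <- stats::lm.wfit(X, yv, w0 * wr)
    if (fit$rank < ncol(X)) {
      message("rank-deficient polynomial surface; falling back to gaussian")
      return(.smooth_slice_gauss(sl, msk, sigma))
    }
    coefs <- fit$coefficients
    r <- yv - X %*% coefs
    scale <- max(1.4826 * stats::median(abs(r)), 1e-6)
    u <- abs(r) / (4.685 * scale)
    wr <- as.numeric(ifelse(u < 1, (1 - u^2)^2, 0))
    if (sum(wr > 0) < nterms) { wr <- rep(1, length(yv)); break }
  }
  out <- rep(NA_real_, length(sl))
  out[msk] <- .poly_design(xs[msk], ys[msk], order) %*% coefs
  array(out, d)
}

# Normalized convolution: gaussian-smooth value*validity / validity so that
# invalid voxels contribute nothing rather than dragging the estimate.
.smooth_slice_gauss <- function(sl, msk, sigma) {
  valid <- msk & is.finite(sl)
  v <- ifelse(valid, sl, 0)
  wt <- valid * 1.0
  k <- stats::dnorm(seq(-ceiling(3 * sigma), ceiling(3 * sigma)), sd = sigma)
  conv1 <- function(m, along) {
    if (along == 2) m <- t(m)
    res <- apply(m, 2, function(col)
      stats::convolve(col, rev(k), type = "open")[(length(k) - 1) / 2 + seq_along(col)])
    if (along == 2) t(res) else res
  }
  num <- conv1(conv1(v, 1), 2)
  den <- conv1(conv1(wt, 1), 2)
  out <- ifelse(den > 1e-12 & msk, num / den, NA_real_)
  array(out, dim(sl))
}

#' M0 map from the long-TR pre-scan
#'
#' At a long TR (3 s versus tissue T1 of roughly 1.4-2.1 s) the SPGR magnitude
#' depends primarily on sin(alpha), so `m0 = m_long / sin(alpha)`. The residual
#' saturation factor `(1 - E1)/(1 - cos(alpha) E1)` at finite TR is accepted,
#' not corrected (see [m0_saturation_factor()]); the resulting map therefore
#' underestimates the true M0 by that known factor. Voxels with
#' `sin(alpha) < 0.1` are flagged invalid.
#'
#' @param m_long Magnitude volume at the long TR (3000 ms).
#' @param alpha_smooth Smoothed flip-angle map, degrees.
#' @param mask Logical 3-D array.
#' @return 3-D M0 map in scanner units (`NA` outside mask / where invalid).
#' @export
estimate_m0 <- function(m_long, alpha_smooth, mask) {
  stopifnot(identical(dim(m_long), dim(alpha_smooth)))
  s <- sin(alpha_smooth * pi / 180)
  ok <- mask & is.finite(s) & s >= 0.1 & is.finite(m_long)
  out <- array(NA_real_, dim(m_long))
  out[ok] <- m_long[ok] / s[ok]
  out
}

#' Residual saturation factor of the long-TR M0 estimate
#'
#' The exact SPGR factor `(1 - E1)/(1 - cos(alpha) E1)` by which the long-TR
#' M0 estimate falls short of the true M0. Exposed so the documented bias can
#' be quantified and logged.
#'
#' @param alpha Flip angle, degrees.
#' @param r1 Longitudinal rate, s^-1.
#' @param tr Long repetition time, seconds (default 3).
#' @return Dimensionless factor in (0, 1\].
#' @export
m0_saturation_factor <- function(alpha, r1, tr = 3.0) {
  spgr_signal(1, alpha, r1, tr) / sin(alpha * pi / 180)
}

#' Saturation-corrected M0 from the short/long TR scan pair
#'
#' At a known flip angle the ratio `M_long / M_short` of the two pre-scan
#' magnitudes is a strictly decreasing function of the baseline R1, so the
#' pair determines (M0, baseline R1) jointly: R1 is found by bisection on the
#' ratio, and `m0 = m_long / (sin(alpha) * f)` with `f` the exact SPGR
#' saturation factor at the long TR. This removes the residual long-TR
#' saturation bias of [estimate_m0()] (exact on noiseless data); the cost is
#' sensitivity to the short-TR scan's noise, which is mild because both
#' pre-scans are high-SNR averages.
#'
#' @param m_short,m_long Magnitude volumes at the short (64 ms) and long
#'   (3000 ms) TR.
#' @param alpha_smooth Smoothed flip-angle map, degrees.
#' @param mask Logical 3-D array.
#' @param tr_short,tr_long Repetition times, seconds.
#' @param r1_range Bisection bracket for baseline R1, s^-1.
#' @param tol Bisection tolerance on R1, s^-1.
#' @return List with 3-D maps `m0` (scanner units) and `r1_baseline` (s^-1);
#'   `NA` flags voxels whose ratio is outside the attainable range.
#' @export
estimate_m0_corrected <- function(m_short, m_long, alpha_smooth, mask,
                                  tr_short = 0.064, tr_long = 3.0,
                                  r1_range = c(0.02, 50), tol = 1e-12) {
  stopifnot(identical(dim(m_short), dim(m_long)), tr_long > tr_short)
  sina <- sin(alpha_smooth * pi / 180)
  ok <- mask & is.finite(alpha_smooth) & sina >= 0.1 &
        is.finite(m_short) & m_short > 0 & is.finite(m_long) & m_long > 0
  ratio <- array(NA_real_, dim(m_short))
  ratio[ok] <- m_long[ok] / m_short[ok]
  tr_ratio <- function(r1, a)
    spgr_signal(1, a, r1, tr_long) / spgr_signal(1, a, r1, tr_short)
  a_ok <- alpha_smooth
  idx <- which(is.finite(ratio))
  m0 <- array(NA_real_, dim(m_short)); r1b <- array(NA_real_, dim(m_short))
  if (length(idx)) {
    av <- a_ok[idx]; rv <- ratio[idx]
    att <- rv < tr_ratio(r1_range[1], av) & rv > tr_ratio(r1_range[2], av)
    idx <- idx[att]; av <- av[att]; rv <- rv[att]
    lo <- rep(r1_range[1], length(idx)); hi <- rep(r1_range[2], length(idx))
    n_it <- ceiling(log2(diff(r1_range) / tol))
    for (k in seq_len(n_it)) {
      mid <- (lo + hi) / 2
      dn <- tr_ratio(mid, av) > rv     # ratio decreasing in R1
      lo[dn] <- mid[dn]; hi[!dn] <- mid[!dn]
    }
    r1v <- (lo + hi) / 2
    r1b[idx] <- r1v
    m0[idx] <- m_long[idx] / spgr_signal(1, av, r1v, tr_long)
  }
  list(m0 = m0, r1_baseline = r1b)
}

#' Full pre-scan calibration
#'
#' Convenience wrapper: raw flip-angle map from the 200/64 ms pair, smoothing,
#' and M0 from the pre-scan magnitudes. The default M0 path
#' (`"sat_corrected"`) solves (M0, baseline R1) jointly from the 64/3000 ms
#' pair via [estimate_m0_corrected()]; `"long_tr"` uses the plain
#' `M_3000/sin(alpha)` estimator of [estimate_m0()] with its documented
#' residual-saturation bias.
#'
#' @param prescans List with elements `m64`, `m200`, `m3000` (3-D arrays).
#' @param mask Logical brain mask (3-D).
#' @param acq An [acq_params()].
#' @param t1_assumed Assumed tissue T1, seconds.
#' @param smooth_method,smooth_order,smooth_sigma Passed to [smooth_alpha()].
#' @param alpha_tol Bisection tolerance in degrees.
#' @param m0_method `"sat_corrected"` (default) or `"long_tr"`.
#' @return Object of class `calibration_maps`: `alpha_raw`, `alpha_smooth`,
#'   `m0`, `r1_baseline` (NULL for `"long_tr"`), `brain_mask`, `t1_assumed`,
#'   `m0_method`.
#' @export
calibrate <- function(prescans, mask, acq = acq_params(), t1_assumed = 1.8,
                      smooth_method = "poly_surface", smooth_order = 3,
                      smooth_sigma = 3, alpha_tol = 1e-9,
                      m0_method = c("sat_corrected", "long_tr")) {
  stopifnot(all(c("m64", "m200", "m3000") %in% names(prescans)))
  m0_method <- match.arg(m0_method)
  alpha_raw <- estimate_alpha_raw(prescans$m200, prescans$m64, t1_assumed,
                                  mask, tr_long = acq$tr_prescan[2],
                                  tr_short = acq$tr_prescan[1], tol = alpha_tol)
  alpha_smooth <- smooth_alpha(alpha_raw, mask, method = smooth_method,
                               order = smooth_order, sigma = smooth_sigma)
  if (m0_method == "sat_corrected") {
    mm <- estimate_m0_corrected(prescans$m64, prescans$m3000, alpha_smooth,
                                mask, tr_short = acq$tr_prescan[1],
                                tr_long = acq$tr_prescan[3])
    m0 <- mm$m0; r1b <- mm$r1_baseline
  } else {
    m0 <- estimate_m0(prescans$m3000, alpha_smooth, mask)
    r1b <- NULL
  }
  structure(list(alpha_raw = alpha_raw, alpha_smooth = alpha_smooth, m0 = m0,
                 r1_baseline = r1b, brain_mask = mask, t1_assumed = t1_assumed,
                 m0_method = m0_method),
            class = "calibration_maps")
}

#' @export
print.calibration_maps <- function(x, ...) {
  rng <- range(x$alpha_smooth, na.rm = TRUE)
  cat(sprintf("<calibration_maps> %d voxels in mask; smoothed flip angle %.1f-%.1f deg (assumed T1 %.2f s)\n",
              sum(x$brain_mask), rng[1], rng[2], x$t1_assumed))
  invisible(x)
}
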