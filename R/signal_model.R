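# Spoiled-gradient-echo (SPGR/FLASH) signal physics: forward synthesis,
# closed-form R1 inversion, dynamic delta-R1 series, mono-exponential T2 fit.
# Angles are degrees at every interface and radians internally.

#' Acquisition parameters for the pre-scan + dynamic FLASH protocol
#'
#' Bundles the repetition times, echo time, nominal flip angle and dynamic
#' timing of the two-part acquisition: a three-scan calibration pre-scan
#' (short/medium/long TR) followed by a fast T1-weighted dynamic series.
#'
#' @param tr_prescan Repetition times of the three pre-scans, seconds.
#'   Defaults to 64, 200 and 3000 ms.
#' @param tr_dynamic Repetition time of the dynamic scan, seconds.
#' @param te Echo time, seconds. Carried as metadata only: the sequence uses a
#'   minimum-TE single echo so the T2*-decay factor is treated as exactly 1.
#' @param nominal_flip_deg Nominal (prescribed) flip angle, degrees.
#' @param frame_interval Temporal resolution of the dynamic scan, seconds.
#' @param n_frames Number of dynamic frames.
#' @param baseline_duration Duration of the pre-injection baseline, seconds.
#' @param n_slices,matrix Grid geometry (slices; in-plane rows x cols).
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(tr_prescan = c(0.064, 0.200, 3.000),
                       tr_dynamic = 0.064,
                       te = 0.002,
                       nominal_flip_deg = 30,
                       frame_interval = 8,
                       n_frames = 90,
                       baseline_duration = 120,
                       n_slices = 5,
                       matrix = c(64, 64)) {
  stopifnot(length(tr_prescan) == 3, all(tr_prescan > 0), tr_dynamic > 0,
            te > 0, frame_interval > 0, n_frames > 1,
            nominal_flip_deg > 0, nominal_flip_deg < 90)
  if (baseline_duration >= n_frames * frame_interval)
    stop("baseline_duration must be shorter than the dynamic scan")
  structure(list(tr_prescan = tr_prescan, tr_dynamic = tr_dynamic, te = te,
                 nominal_flip_deg = nominal_flip_deg,
                 frame_interval = frame_interval, n_frames = n_frames,
                 baseline_duration = baseline_duration,
                 n_slices = n_slices, matrix = matrix),
            class = "acq_params")
}

#' Dynamic image series
#'
#' @param data 4-D numeric array (row, col, slice, frame) of scanner-unit
#'   magnitudes, or a list of 3-D frames of a common grid.
#' @param times Frame times in seconds from scan start, strictly increasing.
#' @param injection_time Contrast injection time, seconds (default 120).
#' @return Object of class `dce_series` with elements `data`, `times`,
#'   `injection_time`.
#' @export
dce_series <- function(data, times, injection_time = 120) {
  if (is.list(data)) data <- simplify2array(data)
  stopifnot(length(dim(data)) == 4, dim(data)[4] == length(times))
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  if (injection_time < times[1]) stop("injection precedes the first frame")
  if (any(!is.finite(data)))
    stop("magnitudes must be finite")
  structure(list(data = data, times = as.numeric(times),
                 injection_time = injection_time),
            class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dce_series> %dx%dx%d grid, %d frames (%.0f..%.0f s), injection at %.0f s\n",
              d[1], d[2], d[3], d[4], x$times[1], x$times[length(x$times)],
              x$injection_time))
  invisible(x)
}

#' Steady-state SPGR (FLASH) signal
#'
#' Closed-form spoiled gradient-echo amplitude
#' \deqn{S = M_0 \sin\alpha \, (1 - E_1) / (1 - \cos\alpha \, E_1),
#'       \quad E_1 = e^{-TR \cdot R_1}.}
#' The echo-time decay factor is treated as exactly 1 (minimum-TE single-echo
#' acquisition).
#'
#' @param m0 Equilibrium magnetization (scanner units), >= 0.
#' @param alpha Flip angle in degrees, in (0, 90).
#' @param r1 Longitudinal relaxation rate 1/T1, s^-1, > 0.
#' @param tr Repetition time, seconds, > 0.
#' @return Signal magnitude in scanner units; vectorized over all arguments.
#' @export
spgr_signal <- function(m0, alpha, r1, tr) {
  if (any(alpha <= 0 | alpha >= 90)) stop("alpha must lie in (0, 90) degrees")
  if (any(tr <= 0)) stop("tr must be positive")
  if (any(r1 <= 0)) stop("r1 must be positive")
  if (any(m0 < 0)) stop("m0 must be non-negative")
  a <- alpha * pi / 180
  e1 <- exp(-tr * r1)
  m0 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

#' Invert the SPGR equation for R1
#'
#' Solves the closed-form SPGR equation for the longitudinal relaxation rate
#' given the signal, M0, flip angle and TR. Voxels whose normalized signal is
#' inconsistent with the model (saturation factor outside (0, 1), e.g. from
#' noise) return `NA` rather than raising an error, so a single corrupted
#' voxel never aborts a volume.
#'
#' @param signal Measured magnitude, scanner units.
#' @param m0 Equilibrium magnetization, > 0.
#' @param alpha Flip angle, degrees in (0, 90).
#' @param tr Repetition time, seconds.
#' @return R1 in s^-1; `NA_real_` flags an invalid (non-invertible) voxel.
#' @export
invert_r1 <- function(signal, m0, alpha, tr) {
  if (any(alpha <= 0 | alpha >= 90, na.rm = TRUE))
    stop("alpha must lie in (0, 90) degrees")
  if (any(tr <= 0)) stop("tr must be positive")
  if (any(m0 <= 0, na.rm = TRUE)) stop("m0 must be positive")
  a <- alpha * pi / 180
  s <- signal / (m0 * sin(a))
  # E1 = (1-s)/(1-s cos a) rearranged as u/((1-cos a) + u cos a) with
  # u = 1-s and 1-cos a = 2 sin^2(a/2), minimizing cancellation near full
  # recovery. Accuracy is then limited only by the conditioning of the
  # forward model (error ~ eps * exp(tr*r1)/(tr*r1) at deep saturation).
  u <- 1 - s
  one_m_c <- 2 * sin(a / 2)^2
  e1 <- u / (one_m_c + u * cos(a))
  bad <- !is.finite(e1) | e1 <= 0 | e1 >= 1
  e1[bad] <- NA_real_
  -log(e1) / tr
}

#' Dynamic R1 and delta-R1 series from a calibrated dynamic scan
#'
#' Applies [invert_r1()] per voxel and frame with the calibrated flip-angle
#' and M0 maps, averages the pre-injection frames into a baseline R1 and
#' subtracts it to give the contrast-induced delta-R1 series (linearly related
#' to tissue contrast-agent concentration).
#'
#' Baseline frames are those acquired strictly before the injection time and
#' within `params$baseline_duration` of scan start. A voxel is marked invalid
#' if any of its baseline frames fails inversion; later-frame failures remain
#' `NA` in that frame only.
#'
#' @param dyn A [dce_series()].
#' @param m0_map,alpha_map 3-D calibration maps on the series grid (M0 in
#'   scanner units, flip angle in degrees).
#' @param params An [acq_params()]; `tr_dynamic` and `baseline_duration` are
#'   used.
#' @return Object of class `r1_series`: `r1` (4-D, s^-1), `baseline_r1` (3-D),
#'   `delta_r1` (4-D), `valid_mask` (3-D logical), `times`, `injection_time`.
#' @export
compute_r1_series <- function(dyn, m0_map, alpha_map, params) {
  stopifnot(inherits(dyn, "dce_series"), inherits(params, "acq_params"))
  d <- dim(dyn$data)
  if (!identical(d[1:3], dim(m0_map)) || !identical(d[1:3], dim(alpha_map)))
    stop("calibration maps and dynamic frames must share one grid")
  nt <- d[4]
  base_idx <- which(dyn$times < dyn$injection_time &
                    dyn$times < params$baseline_duration)
  if (length(base_idx) == 0)
    stop("no frame lies in the pre-injection baseline window")

  ok <- is.finite(m0_map) & m0_map > 0 &
        is.finite(alpha_map) & alpha_map > 0 & alpha_map < 90
  a <- ifelse(ok, alpha_map, 45) * pi / 180    # placeholder angle, masked out below
  m0v <- ifelse(ok, m0_map, 1)
  sin_a <- sin(a); cos_a <- cos(a)

  one_m_c <- 2 * sin(a / 2)^2
  r1 <- array(NA_real_, d)
  for (t in seq_len(nt)) {
    s <- array(dyn$data[, , , t], d[1:3]) / (m0v * sin_a)
    u <- 1 - s
    e1 <- u / (one_m_c + u * cos_a)
    bad <- !ok | !is.finite(e1) | e1 <= 0 | e1 >= 1
    e1[bad] <- NA_real_
    r1[, , , t] <- -log(e1) / params$tr_dynamic
  }

  rmat <- matrix(r1, prod(d[1:3]), nt)
  baseline <- rowMeans(rmat[, base_idx, drop = FALSE])
  valid <- apply(is.finite(rmat[, base_idx, drop = FALSE]), 1, all)
  baseline[!valid] <- NA_real_
  delta <- array(rmat - baseline, d)

  structure(list(r1 = r1,
                 baseline_r1 = array(baseline, d[1:3]),
                 delta_r1 = delta,
                 valid_mask = array(valid, d[1:3]),
                 times = dyn$times,
                 injection_time = dyn$injection_time,
                 n_baseline = length(base_idx)),
            class = "r1_series")
}

#' @export
print.r1_series <- function(x, ...) {
  d <- dim(x$r1)
  cat(sprintf("<r1_series> %dx%dx%d grid, %d frames, %d baseline frames, %d valid voxels\n",
              d[1], d[2], d[3], d[4], x$n_baseline, sum(x$valid_mask)))
  invisible(x)
}

#' Mono-exponential T2 map from a multi-echo acquisition
#'
#' Fits `S(TE) = S0 * exp(-TE / T2)` per voxel by log-linear least squares
#' across the echo images. Voxels with any non-positive echo are flagged
#' invalid; voxels with zero decay (all echoes equal) receive the `Inf`
#' sentinel and an invalid flag. Per-voxel failures never abort the fit.
#'
#' @param echo_volumes List of 3-D magnitude arrays, one per echo (>= 3).
#' @param tes Echo times in seconds, one per volume.
#' @return List with `t2` (3-D array, seconds), `s0`, and `valid` (logical).
#' @export
fit_t2_map <- function(echo_volumes, tes) {
  stopifnot(length(echo_volumes) == length(tes), length(tes) >= 3)
  d <- dim(echo_volumes[[1]])
  Y <- vapply(echo_volumes, as.numeric, numeric(prod(d)))  # voxels x echoes
  valid <- apply(is.finite(Y) & Y > 0, 1, all)
  logY <- log(pmax(Y, .Machine$double.xmin))
  tc <- tes - mean(tes)
  w <- tc / sum(tc^2)
  slope <- as.numeric(logY %*% w)          # d logS / d TE = -1/T2
  icept <- rowMeans(logY) - slope * mean(tes)
  t2 <- ifelse(slope < 0, -1 / slope, Inf)
  valid <- valid & slope < 0
  t2[!valid & slope >= 0] <- Inf
  t2[!apply(is.finite(Y) & Y > 0, 1, all)] <- NA_real_
  list(t2 = array(t2, d), s0 = array(exp(icept), d), valid = array(valid, d))
}
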