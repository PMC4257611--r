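# Arterial input function: configurable population template, scaling against
# a no-leakage reference region, and venous-curve extraction for QC.

#' Parameters of the bi-exponential population AIF template
#'
#' A population-average plasma curve shape: zero before injection, a linear
#' bolus rise, then a bi-exponential washout `A1 exp(-m1 tau) + A2 exp(-m2 tau)`
#' (tau = time since peak). Defaults are typical small-molecule gadolinium
#' kinetics in the rat (fast distribution phase, slow renal elimination); the
#' template's absolute level is irrelevant because it is rescaled against the
#' reference region before use.
#'
#' @param bolus_rise Bolus rise time, seconds.
#' @param A1,A2 Amplitudes of the fast and slow components, s^-1 (delta-R1
#'   equivalent units).
#' @param m1,m2 Decay rates, s^-1; must satisfy `m1 > m2 > 0`.
#' @return Object of class `aif_template_params`.
#' @export
aif_template_params <- function(bolus_rise = 16, A1 = 4.0, m1 = 0.007,
                                A2 = 1.5, m2 = 4e-4) {
  stopifnot(bolus_rise > 0, A1 >= 0, A2 >= 0)
  if (!(m1 > m2 && m2 > 0)) stop("decay rates must satisfy m1 > m2 > 0")
  structure(list(bolus_rise = bolus_rise, A1 = A1, m1 = m1, A2 = A2, m2 = m2),
            class = "aif_template_params")
}

.new_aif <- function(times, values, injection_time, scale_factor, source) {
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 injection_time = injection_time, scale_factor = scale_factor,
                 source = source),
            class = "aif_curve")
}

#' @export
print.aif_curve <- function(x, ...) {
  cat(sprintf("<aif_curve> source=%s, %d frames, peak %.3g s^-1, scale %.4g\n",
              x$source, length(x$times), max(x$values), x$scale_factor))
  invisible(x)
}

#' Evaluate the population AIF template on the dynamic time grid
#'
#' @param times Frame times, seconds.
#' @param injection_time Injection time, seconds.
#' @param p An [aif_template_params()].
#' @return An `aif_curve` (source `"template"`, scale factor 1). Values are 0
#'   before injection, rise linearly to the peak `A1 + A2` over `bolus_rise`
#'   seconds, and decay bi-exponentially afterwards.
#' @export
aif_template <- function(times, injection_time, p = aif_template_params()) {
  stopifnot(inherits(p, "aif_template_params"))
  peak_t <- injection_time + p$bolus_rise
  v <- numeric(length(times))
  rise <- times >= injection_time & times < peak_t
  v[rise] <- (times[rise] - injection_time) / p$bolus_rise * (p$A1 + p$A2)
  dec <- times >= peak_t
  tau <- times[dec] - peak_t
  v[dec] <- p$A1 * exp(-p$m1 * tau) + p$A2 * exp(-p$m2 * tau)
  .new_aif(times, v, injection_time, 1, "template")
}

# Trapezoidal time-average of per-frame values over frames whose
# post-injection time falls in the half-open window [w1, w2).
.window_mean <- function(times, values, injection_time, window) {
  sel <- which(times - injection_time >= window[1] &
               times - injection_time < window[2])
  if (length(sel) < 2) stop("AIF scaling window contains fewer than 2 frames")
  tt <- times[sel]
  pracma::trapz(tt, values[sel]) / (tt[length(tt)] - tt[1])
}

#' Scale the population AIF against a no-leakage reference region
#'
#' Under the assumptions that the reference region (contralesional
#' caudate-putamen) has no BBB leakage and a plasma volume fraction `vp_ref`,
#' its tissue delta-R1 equals `vp_ref * Cp(t)`. Averaging both the reference
#' curve and the template over a late window (default 3-9 min post injection,
#' where the bolus shape is slowly varying) gives the scale factor
#' `k = mean(ref) / (vp_ref * mean(template))`; the scaled AIF is
#' `k * template`.
#'
#' @param template An `aif_curve` (the population template).
#' @param ref_delta_r1 Per-frame mean delta-R1 over the reference ROI, s^-1
#'   (same grid as the template; see [reference_curve()]).
#' @param window Averaging window in seconds post injection, half-open
#'   `[start, end)`; default `c(180, 540)`.
#' @param vp_ref Assumed reference-region plasma volume fraction; default 0.01.
#' @return An `aif_curve` with `source = "scaled"` and the applied
#'   `scale_factor` recorded.
#' @export
scale_aif <- function(template, ref_delta_r1, window = c(180, 540),
                      vp_ref = 0.01) {
  stopifnot(inherits(template, "aif_curve"),
            length(ref_delta_r1) == length(template$times),
            vp_ref > 0, window[2] > window[1])
  mt <- .window_mean(template$times, template$values, template$injection_time,
                     window)
  mr <- .window_mean(template$times, ref_delta_r1, template$injection_time,
                     window)
  if (mt <= 0) stop("window mean of the AIF template is not positive")
  if (mr <= 0) stop("window mean of the reference-region curve is not positive")
  k <- mr / (vp_ref * mt)
  .new_aif(template$times, k * template$values, template$injection_time,
           k * template$scale_factor, "scaled")
}

#' Mean delta-R1 curve of a reference ROI
#'
#' Per-frame mean of the delta-R1 series over a mask, excluding voxels flagged
#' invalid by the R1 inversion.
#'
#' @param r1s An `r1_series` from [compute_r1_series()].
#' @param mask Logical 3-D ROI mask.
#' @return Numeric per-frame vector, s^-1.
#' @export
reference_curve <- function(r1s, mask) {
  stopifnot(inherits(r1s, "r1_series"), identical(dim(mask), dim(r1s$valid_mask)))
  use <- mask & r1s$valid_mask
  if (!any(use)) stop("reference ROI contains no valid voxels")
  d <- dim(r1s$delta_r1)
  m <- matrix(r1s$delta_r1, prod(d[1:3]), d[4])[as.vector(use), , drop = FALSE]
  colMeans(m, na.rm = TRUE)
}

#' Extract a venous input function from a single voxel
#'
#' Returns the delta-R1 time course of one voxel (typically the center of the
#' superior sagittal sinus, chosen to minimize partial-volume effects) for
#' cross-validation of the scaled AIF.
#'
#' @param r1s An `r1_series`.
#' @param voxel_index Integer vector `c(row, col, slice)`.
#' @return An `aif_curve` with `source = "venous"`.
#' @export
extract_vif <- function(r1s, voxel_index) {
  stopifnot(inherits(r1s, "r1_series"), length(voxel_index) == 3)
  d <- dim(r1s$delta_r1)
  if (any(voxel_index < 1) || any(voxel_index > d[1:3]))
    stop("voxel index outside the image grid")
  v <- r1s$delta_r1[voxel_index[1], voxel_index[2], voxel_index[3], ]
  if (!r1s$valid_mask[voxel_index[1], voxel_index[2], voxel_index[3]] ||
      any(!is.finite(v)))
    stop("requested voxel is flagged invalid in at least one frame")
  .new_aif(r1s$times, v, r1s$injection_time, 1, "venous")
}

#' Write / read an input-function curve as two-column CSV
#'
#' @param aif An `aif_curve`.
#' @param path CSV path (columns `time_s`, `value_s1`).
#' @return `read_aif_csv` returns an `aif_curve` (source `"template"` unless
#'   stored otherwise in the optional attributes row comment is absent).
#' @export
write_aif_csv <- function(aif, path) {
  utils::write.csv(data.frame(time_s = aif$times, value_s1 = aif$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_aif_csv
#' @param injection_time Injection time in seconds for the curve read back.
#' @export
read_aif_csv <- function(path, injection_time = 120) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "value_s1") %in% names(df)))
  .new_aif(df$time_s, df$value_s1, injection_time, 1, "template")
}
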