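# File I/O (NIfTI-1, CSV, YAML config, JSON manifest), QC metrics, and the
# end-to-end pipeline driver.

#' Read / write a 3-D volume as NIfTI-1
#'
#' Thin wrappers over RNifti preserving values, grid and voxel dimensions.
#' Masks are written as byte volumes (0/1) and read back as logical.
#'
#' @param x Numeric 3-D array (or logical for `write_mask_nifti`).
#' @param path File path (`.nii` / `.nii.gz`).
#' @param voxel_size Voxel edge lengths in mm, length 3.
#' @return Read functions return the array (logical for masks).
#' @export
write_volume_nifti <- function(x, path, voxel_size = c(0.172, 0.172, 1)) {
  img <- RNifti::asNifti(x, pixdim = voxel_size)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  array(as.numeric(arr), dim(arr))
}

#' @rdname write_volume_nifti
#' @export
write_mask_nifti <- function(x, path, voxel_size = c(0.172, 0.172, 1)) {
  img <- RNifti::asNifti(array(as.integer(x), dim(x)), pixdim = voxel_size,
                         datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_mask_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  array(arr != 0, dim(arr))
}

#' Dice overlap coefficient of two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`. Two empty masks return 1 by convention
#' (messaged).
#'
#' @param mask_a,mask_b Logical arrays on one grid.
#' @return Scalar in \[0, 1\].
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) stop("masks are on different grids")
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    message("both masks empty; Dice = 1 by convention")
    return(1)
  }
  2 * sum(a & b) / denom
}

# In-plane 4-neighbour erosion of a label map: a voxel survives if its four
# in-plane neighbours carry the same label (brain-edge exclusion).
.erode_labels <- function(labels, iterations = 1) {
  for (k in seq_len(iterations)) {
    d <- dim(labels)
    out <- labels
    for (z in seq_len(d[3])) {
      sl <- labels[, , z]
      same <- function(sh) {
        p <- matrix(NA, d[1], d[2])
        if (sh == "up")    p[-1, ] <- sl[-d[1], ]
        if (sh == "down")  p[-d[1], ] <- sl[-1, ]
        if (sh == "left")  p[, -1] <- sl[, -d[2]]
        if (sh == "right") p[, -d[2]] <- sl[, -1]
        !is.na(p) & p == sl
      }
      keep <- same("up") & same("down") & same("left") & same("right")
      sl[!keep] <- NA
      out[, , z] <- sl
    }
    labels <- out
  }
  labels
}

#' Per-ROI summary of a parameter map
#'
#' Mean and standard error of the mean per labeled region, optionally after
#' eroding each region by one or more voxels in-plane to exclude edge voxels
#' (brain-boundary hyperintensities are a known artifact).
#'
#' @param value_map Numeric 3-D array.
#' @param labels Integer 3-D label array (`NA` or 0 = unlabeled) or a named
#'   list of logical masks.
#' @param erode Number of 1-voxel in-plane erosions applied to the labels
#'   before summarizing (default 0).
#' @param level_names Optional names for integer labels.
#' @return Data frame with `region`, `n`, `mean`, `sem`.
#' @export
roi_summary <- function(value_map, labels, erode = 0, level_names = NULL) {
  if (is.list(labels)) {
    lab <- array(NA_integer_, dim(value_map))
    for (i in seq_along(labels)) lab[labels[[i]]] <- i
    level_names <- names(labels)
    labels <- lab
  }
  stopifnot(identical(dim(value_map), dim(labels)))
  labels[labels == 0] <- NA
  if (erode > 0) labels <- .erode_labels(labels, erode)
  levs <- sort(unique(labels[!is.na(labels)]))
  rows <- lapply(levs, function(l) {
    v <- value_map[!is.na(labels) & labels == l]
    v <- v[is.finite(v)]
    if (!length(v)) {
      warning("region ", l, " is empty after erosion/validity filtering")
      return(data.frame(region = l, n = 0L, mean = NA_real_, sem = NA_real_))
    }
    data.frame(region = l, n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)))
  })
  out <- do.call(rbind, rows)
  if (!is.null(level_names)) out$region <- level_names[out$region]
  out
}

#' Default pipeline configuration
#'
#' All tunable keys of the processing chain with their defaults, overridable
#' per call or from a YAML file via [read_pipeline_config()].
#'
#' @param ... Named overrides.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(t1_assumed = 1.8,
              smooth_method = "poly_surface", smooth_order = 3,
              smooth_sigma = 3, alpha_tol = 1e-9,
              m0_method = "sat_corrected",
              vp_ref = 0.01, window_start_s = 180, window_end_s = 540,
              f0 = 10, kep_grid_n = 50, kep_min = 1e-3, kep_max = 10,
              refine_kep = TRUE)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file whose keys override the defaults.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage [%s]: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full K-trans pipeline
#'
#' Orchestrates calibration (flip-angle + M0), dynamic R1 inversion, AIF
#' scaling against the reference region, voxelwise model fitting with
#' F-statistic selection, and QC. Deterministic: identical inputs give
#' identical outputs.
#'
#' @param prescans List with `m64`, `m200`, `m3000` 3-D arrays (or NIfTI
#'   paths).
#' @param dynamic A [dce_series()].
#' @param brain_mask,ref_mask Logical 3-D arrays: fitting mask and no-leakage
#'   reference ROI (required for AIF scaling).
#' @param aif_template An `aif_curve` population template on the dynamic grid.
#' @param acq An [acq_params()].
#' @param config A [pipeline_config()] list.
#' @param sinus_voxel Optional `c(row, col, slice)` of a venous voxel for
#'   AIF/VIF QC.
#' @param labels Optional ROI label array for the summary table.
#' @return Object of class `ktrans_pipeline`: `calibration`, `r1`, `aif`,
#'   `maps` (a `ktrans_maps`), `qc` (list), `config`.
#' @export
run_pipeline <- function(prescans, dynamic, brain_mask, ref_mask,
                         aif_template, acq = acq_params(),
                         config = pipeline_config(), sinus_voxel = NULL,
                         labels = NULL) {
  if (is.null(ref_mask))
    stop("pipeline stage [aif-scaling]: a reference-ROI mask is required to scale the AIF")
  if (is.character(prescans)) prescans <- lapply(prescans, read_volume_nifti)

  cal <- .stage("calibration",
    calibrate(prescans, brain_mask, acq, t1_assumed = config$t1_assumed,
              smooth_method = config$smooth_method,
              smooth_order = config$smooth_order,
              smooth_sigma = config$smooth_sigma,
              alpha_tol = config$alpha_tol, m0_method = config$m0_method))
  r1s <- .stage("r1-mapping",
    compute_r1_series(dynamic, cal$m0, cal$alpha_smooth, acq))
  aif <- .stage("aif-scaling", {
    refc <- reference_curve(r1s, ref_mask)
    scale_aif(aif_template, refc,
              window = c(config$window_start_s, config$window_end_s),
              vp_ref = config$vp_ref)
  })
  maps <- .stage("kinetic-fitting",
    fit_volume(r1s, aif, mask = brain_mask, f0 = config$f0,
               kep_grid = default_kep_grid(config$kep_grid_n,
                                           config$kep_min, config$kep_max),
               refine = config$refine_kep))

  qc <- list(dice_final_vs_model2 = dice_coefficient(maps$fitted_mask & !maps$mask3,
                                                     maps$fitted_mask),
             model3_fraction = sum(maps$mask3) / max(1, sum(maps$fitted_mask)))
  if (!is.null(sinus_voxel)) {
    vif <- .stage("qc", extract_vif(r1s, sinus_voxel))
    qc$vif_correlation <- stats::cor(aif$values, vif$values)
  }
  if (!is.null(labels))
    qc$roi_table <- roi_summary(maps$ktrans_final, labels, erode = 1)

  structure(list(calibration = cal, r1 = r1s, aif = aif, maps = maps,
                 qc = qc, config = config),
            class = "ktrans_pipeline")
}

#' @export
print.ktrans_pipeline <- function(x, ...) {
  print(x$maps)
  if (!is.null(x$qc$vif_correlation))
    cat(sprintf("  AIF/VIF correlation: %.4f\n", x$qc$vif_correlation))
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes the parameter maps and selection mask as NIfTI, the scaled AIF as
#' CSV, the ROI table (if present) as CSV, and a JSON manifest (package
#' version, configuration, AIF scale factor, QC scalars).
#'
#' @param result A `ktrans_pipeline`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "ktrans_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- result$maps
  vols <- list(ktrans_final = m$ktrans_final, ktrans_model2 = m$model2$ktrans,
               ktrans_model3 = m$model3$ktrans, vp = m$vp_final,
               kep = m$kep_final, f_stat = m$f_stat)
  for (nm in names(vols)) {
    v <- vols[[nm]]; v[!is.finite(v)] <- 0
    write_volume_nifti(v, file.path(dir, paste0(nm, ".nii.gz")))
  }
  write_mask_nifti(m$mask3, file.path(dir, "mask_model3.nii.gz"))
  write_mask_nifti(m$fitted_mask, file.path(dir, "mask_fitted.nii.gz"))
  write_aif_csv(result$aif, file.path(dir, "aif_scaled.csv"))
  if (!is.null(result$qc$roi_table))
    utils::write.csv(result$qc$roi_table, file.path(dir, "roi_summary.csv"),
                     row.names = FALSE)
  manifest <- list(package = "ktransmap",
                   version = as.character(utils::packageVersion("ktransmap")),
                   config = result$config,
                   aif_scale_factor = result$aif$scale_factor,
                   qc = result$qc[setdiff(names(result$qc), "roi_table")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
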