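#' Rescale a map's geometry about its center
#'
#' Multiplies the voxel size by `factor` and moves the origin so the
#' geometric center of the grid is a fixed point of the rescaling. Grid
#' values are untouched: "pixel size" is treated as metadata, the way
#' map-fitting tools treat it, so the experimental densities are preserved
#' bit-exactly. Center-fixing minimizes drift of a centered particle.
#'
#' @param map a `density_map`.
#' @param factor positive scale factor.
#' @return a `density_map` with rescaled geometry.
#' @export
rescale_geometry <- function(map, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0) {
    stop("factor must be a positive scalar", call. = FALSE)
  }
  g <- map_geometry(map)
  new_voxel <- map$voxel_size * factor
  new_origin <- g$center - (g$dim_xyz - 1) / 2 * new_voxel
  density_map(map$grid, voxel_size = new_voxel, origin = new_origin,
              identifier = map$identifier)
}

#' Fraction of model atoms inside a map's footprint
#'
#' A quick docking sanity check: a model that is supposed to be positioned
#' inside the experimental map should have an overlap fraction near 1.
#'
#' @param model an atomic model tibble.
#' @param map a `density_map`.
#' @return fraction in `[0, 1]` of heavy atoms whose coordinates fall
#'   inside the map's world-coordinate bounding box.
#' @export
model_map_overlap <- function(model, map) {
  m <- canonical_conformer(model)
  g <- map_geometry(map)
  lo <- g$origin - g$voxel_size / 2
  hi <- g$origin + (g$dim_xyz - 0.5) * g$voxel_size
  xyz <- coords_matrix(m)
  inside <- xyz[, 1] >= lo[1] & xyz[, 1] <= hi[1] &
    xyz[, 2] >= lo[2] & xyz[, 2] <= hi[2] &
    xyz[, 3] >= lo[3] & xyz[, 3] <= hi[3]
  mean(inside)
}

new_calibration_curve <- function(curve, nominal_voxel, optimum_voxel,
                                  optimum_mode, optimum_correlation,
                                  corr_mode) {
  structure(
    list(curve = curve, nominal_voxel = nominal_voxel,
         optimum_voxel = optimum_voxel, optimum_mode = optimum_mode,
         optimum_correlation = optimum_correlation, corr_mode = corr_mode),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> nominal %.4g A/px, optimum %.4g A/px (%s, corr %.4f)\n",
    x$nominal_voxel, x$optimum_voxel, x$optimum_mode, x$optimum_correlation))
  print(x$curve)
  invisible(x)
}

# parabola through the argmax and its two neighbours; vertex clamped to the
# sweep range. Falls back to the argmax at a boundary or for a degenerate fit.
parabolic_vertex <- function(xs, ys) {
  i <- which.max(ys)
  if (i == 1 || i == length(ys)) return(xs[i])
  x <- xs[(i - 1):(i + 1)]; y <- ys[(i - 1):(i + 1)]
  denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) /
    denom
  b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) +
          x[1]^2 * (y[2] - y[3])) / denom
  if (a >= 0) return(xs[i])
  min(max(-b / (2 * a), min(xs)), max(xs))
}

#' Build a calibration curve from precomputed correlations
#'
#' Useful when the sweep correlations come from an external source (for
#' example a published table): selects the argmax and, optionally, the
#' sub-step parabolic optimum.
#'
#' @param candidate_voxels strictly increasing candidate pixel sizes,
#'   Angstrom/pixel.
#' @param correlations correlation values, same length, in `[-1, 1]`.
#' @param nominal_voxel the pixel size recorded in the map header.
#' @param refine logical; refine the optimum with a parabola through the
#'   top three points.
#' @return a `calibration_curve`.
#' @export
calibration_curve <- function(candidate_voxels, correlations, nominal_voxel,
                              refine = FALSE) {
  stopifnot(length(candidate_voxels) == length(correlations),
            length(candidate_voxels) >= 2,
            all(diff(candidate_voxels) > 0),
            all(abs(correlations) <= 1))
  curve <- tibble::tibble(candidate_voxel = candidate_voxels,
                          correlation = correlations)
  i <- which.max(correlations)
  opt <- if (refine) parabolic_vertex(candidate_voxels, correlations)
         else candidate_voxels[i]
  new_calibration_curve(curve, nominal_voxel, opt,
                        if (refine) "parabolic" else "argmax",
                        correlations[i], corr_mode = "external")
}

#' Calibrate the pixel size of an experimental map by a correlation sweep
#'
#' For each candidate pixel size `s`, the experimental map's geometry is
#' rescaled by `s / nominal` about the map center (metadata only — the
#' experimental densities are never interpolated), a map simulated from
#' the docked model is resampled onto that geometry, and the two are
#' correlated. The optimum is the argmax over candidates; with
#' `refine = TRUE` a parabola through the top three points gives a
#' sub-step optimum clamped to the sweep range.
#'
#' @param exp_map experimental `density_map`, with the model already
#'   positioned (docked) in its coordinate frame.
#' @param model the docked atomic model.
#' @param sweep numeric `c(min, max, step)` in Angstrom/pixel; endpoints
#'   inclusive (1.047-1.087 step 0.01 yields exactly 5 candidates).
#' @param sim_params see [simulation_params()]; the simulation voxel size
#'   defaults to half the nominal pixel size for faithful resampling.
#' @param corr_mode `"about_zero"` (default, the common default of
#'   map-fitting tools) or `"about_mean"`.
#' @param mask_threshold mask cutoff applied to the simulated map.
#' @param refine logical; parabolic sub-step refinement.
#' @param nominal override for the nominal pixel size; defaults to the
#'   map's header voxel size (useful when a deposited header already
#'   carries a corrected value).
#' @param min_overlap fail loudly if fewer than this fraction of model
#'   atoms fall inside the map footprint (mis-docked input).
#' @return a `calibration_curve`; `tidy()` gives the per-candidate table,
#'   `glance()` the one-row optimum summary, `autoplot()` the curve.
#' @export
calibrate_pixel_size <- function(exp_map, model, sweep,
                                 sim_params = NULL,
                                 corr_mode = c("about_zero", "about_mean"),
                                 mask_threshold = 0,
                                 refine = FALSE,
                                 nominal = NULL,
                                 min_overlap = 0.5) {
  corr_mode <- match.arg(corr_mode)
  stopifnot(length(sweep) == 3)
  if (!(sweep[1] < sweep[2]) || sweep[3] <= 0) {
    stop("sweep must satisfy min < max and step > 0", call. = FALSE)
  }
  candidates <- seq(sweep[1], sweep[2] + sweep[3] * 1e-9, by = sweep[3])
  if (length(candidates) < 2) {
    stop("sweep produces fewer than 2 candidates", call. = FALSE)
  }
  if (is.null(nominal)) {
    nominal <- exp_map$voxel_size[1]
  }
  if (is.null(sim_params)) {
    sim_params <- simulation_params(voxel_size = nominal / 2)
  }
  ov <- model_map_overlap(model, exp_map)
  if (ov < min_overlap) {
    stop(sprintf(
      "only %.0f%% of model atoms fall inside the map footprint; is the model docked?",
      100 * ov), call. = FALSE)
  }
  sim <- simulate_map(model, sim_params)
  correlations <- vapply(candidates, function(s) {
    resc <- rescale_geometry(exp_map, s / nominal)
    sim_on_grid <- resample_map(sim, resc)
    if (!any(sim_on_grid$grid > mask_threshold)) {
      return(NA_real_)
    }
    correlate_maps(resc, sim_on_grid, mode = corr_mode,
                   mask_threshold = mask_threshold)
  }, numeric(1))
  if (all(is.na(correlations))) {
    stop("model outside the map footprint at every candidate scale",
         call. = FALSE)
  }
  correlations[is.na(correlations)] <- -1
  curve <- tibble::tibble(candidate_voxel = candidates,
                          correlation = correlations)
  i <- which.max(correlations)
  opt <- if (refine) parabolic_vertex(candidates, correlations)
         else candidates[i]
  new_calibration_curve(curve, nominal, opt,
                        if (refine) "parabolic" else "argmax",
                        correlations[i], corr_mode)
}
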