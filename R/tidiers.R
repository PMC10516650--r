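#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a calibration curve into its per-candidate table
#'
#' @param x a `calibration_curve`.
#' @param ... unused.
#' @return a tibble with `candidate_voxel` and `correlation`.
#' @export
tidy.calibration_curve <- function(x, ...) {
  x$curve
}

#' One-row summary of a calibration curve
#'
#' @param x a `calibration_curve`.
#' @param ... unused.
#' @return a tibble with `nominal_voxel`, `optimum_voxel`, `optimum_mode`,
#'   `optimum_correlation`, `corr_mode`, `n_candidates`.
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(
    nominal_voxel = x$nominal_voxel,
    optimum_voxel = x$optimum_voxel,
    optimum_mode = x$optimum_mode,
    optimum_correlation = x$optimum_correlation,
    corr_mode = x$corr_mode,
    n_candidates = nrow(x$curve)
  )
}

#' Plot a calibration sweep
#'
#' @param object a `calibration_curve`.
#' @param ... unused.
#' @return a ggplot: correlation versus candidate pixel size with the
#'   nominal (dashed) and optimum (solid) pixel sizes marked.
#' @export
autoplot.calibration_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$candidate_voxel,
                               y = .data$correlation)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$nominal_voxel,
                        linetype = "dashed", color = "grey60") +
    ggplot2::geom_vline(xintercept = object$optimum_voxel,
                        color = "firebrick") +
    ggplot2::labs(
      x = "candidate pixel size (Å/px)",
      y = sprintf("map-model correlation (%s)", object$corr_mode),
      title = sprintf("Pixel-size calibration: optimum %.4g Å/px",
                      object$optimum_voxel)
    ) +
    ggplot2::theme_minimal()
}

#' Tidy a motion report
#'
#' @param x a `motion_report`.
#' @param ... unused.
#' @return a long tibble of the report's scalar quantities.
#' @export
tidy.motion_report <- function(x, ...) {
  vals <- c(
    angle_deg = x$angle_deg,
    axis_x = x$mobile_motion$axis[1],
    axis_y = x$mobile_motion$axis[2],
    axis_z = x$mobile_motion$axis[3],
    mobile_rmsd = x$mobile_motion$rmsd,
    reference_rmsd = x$body_alignment$rmsd,
    n_reference_pairs = x$n_reference_pairs,
    n_mobile_pairs = x$n_mobile_pairs
  )
  if (!is.null(x$swivel_deg)) {
    vals <- c(vals, swivel_deg = x$swivel_deg, tilt_deg = x$tilt_deg,
              swivel_signed_deg = x$swivel_signed_deg)
  }
  tibble::tibble(quantity = names(vals), value = unname(vals))
}

#' One-row summary of a motion report
#'
#' @param x a `motion_report`.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.motion_report <- function(x, ...) {
  tibble::tibble(
    angle_deg = x$angle_deg,
    swivel_deg = if (is.null(x$swivel_deg)) NA_real_ else x$swivel_deg,
    tilt_deg = if (is.null(x$tilt_deg)) NA_real_ else x$tilt_deg,
    reference_rmsd = x$body_alignment$rmsd,
    mobile_rmsd = x$mobile_motion$rmsd,
    n_reference_pairs = x$n_reference_pairs,
    n_mobile_pairs = x$n_mobile_pairs
  )
}

#' Tidy a burial report into its per-atom SASA table
#'
#' @param x a `burial_report`.
#' @param ... unused.
#' @return the per-atom tibble with `sasa` and `isolated_area` columns.
#' @export
tidy.burial_report <- function(x, ...) {
  tibble::as_tibble(x$per_atom)
}

#' One-row summary of a burial report
#'
#' @param x a `burial_report`.
#' @param ... unused.
#' @return a one-row tibble of the burial counts and total SASA.
#' @export
glance.burial_report <- function(x, ...) {
  tibble::tibble(
    hydrophobic_atom_count = x$hydrophobic_atom_count,
    buried_hydrophobic_count = x$buried_hydrophobic_count,
    hydrophobic_residue_count = x$hydrophobic_residue_count,
    buried_hydrophobic_residue_count = x$buried_hydrophobic_residue_count,
    total_sasa = x$total_sasa
  )
}

#' Plot the per-atom SASA distribution of a burial report
#'
#' @param object a `burial_report`.
#' @param ... unused.
#' @return a ggplot histogram of per-atom SASA, hydrophobic counted atoms
#'   highlighted, with the burial threshold marked.
#' @export
autoplot.burial_report <- function(object, ...) {
  pa <- tibble::as_tibble(object$per_atom)
  pa$counted <- polymer_class(pa$resname) == "protein" &
    toupper(pa$resname) %in% object$params$hydrophobic_residues &
    pa$element %in% object$params$counted_elements
  thr <- object$params$burial_threshold
  ggplot2::ggplot(pa, ggplot2::aes(x = .data$sasa, fill = .data$counted)) +
    ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "steelblue"),
                               name = "hydrophobic C/S") +
    ggplot2::labs(x = "per-atom SASA (Å²)", y = "atoms") +
    ggplot2::theme_minimal()
}

#' Plot per-residue displacements
#'
#' @param displacements a tibble from
#'   `displacement(..., statistic = "per_residue")`.
#' @return a ggplot of displacement versus residue number, by chain.
#' @export
plot_displacement <- function(displacements) {
  ggplot2::ggplot(displacements,
                  ggplot2::aes(x = .data$resnum, y = .data$displacement,
                               color = .data$chain)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "residue", y = "displacement (Å)") +
    ggplot2::theme_minimal()
}
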