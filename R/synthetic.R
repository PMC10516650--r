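#' Specification for synthetic test data
#'
#' One integer seed drives a single pseudo-random stream; two runs with an
#' equal spec produce bit-identical models and maps. Defaults are sized so
#' every analysis runs in seconds: two helical domains of 60 residues, a
#' map mislabelled from a true 1.057 Angstrom/pixel to the 1.087 nominal
#' recorded by the microscope.
#'
#' @param n_domains number of domains (currently 2: body and head).
#' @param atoms_per_domain residues per helical domain.
#' @param head_rotation_deg applied head rotation, degrees. Ignored when
#'   `head_swivel_deg`/`head_tilt_deg` are given.
#' @param head_axis rotation axis of the head motion; with a swivel/tilt
#'   split this is the swivel (twist) axis.
#' @param head_swivel_deg,head_tilt_deg optional split of the head motion
#'   into a swivel about `head_axis` followed by a tilt about `tilt_axis`
#'   (`R = R_tilt %*% R_swivel`).
#' @param tilt_axis axis of the tilt component (orthogonalized against
#'   `head_axis` internally).
#' @param head_translation translation of the head domain, Angstrom.
#' @param coordinate_noise_sigma per-coordinate Gaussian noise, Angstrom.
#' @param true_voxel true pixel size of generated maps, Angstrom/pixel.
#' @param labelled_voxel pixel size written to the map header.
#' @param map_noise_sigma map noise, as a fraction of the peak density.
#' @param resolution simulated-map resolution, Angstrom.
#' @param seed integer seed.
#' @return a list (class `toy_spec`).
#' @export
toy_spec <- function(n_domains = 2, atoms_per_domain = 60,
                     head_rotation_deg = 18, head_axis = c(0, 0, 1),
                     head_swivel_deg = NULL, head_tilt_deg = NULL,
                     tilt_axis = c(1, 0, 0),
                     head_translation = c(0, 0, 0),
                     coordinate_noise_sigma = 0,
                     true_voxel = 1.057, labelled_voxel = 1.087,
                     map_noise_sigma = 0, resolution = 3.5, seed = 1L) {
  structure(
    list(n_domains = n_domains, atoms_per_domain = atoms_per_domain,
         head_rotation_deg = head_rotation_deg,
         head_axis = head_axis / sqrt(sum(head_axis^2)),
         head_swivel_deg = head_swivel_deg, head_tilt_deg = head_tilt_deg,
         tilt_axis = tilt_axis / sqrt(sum(tilt_axis^2)),
         head_translation = head_translation,
         coordinate_noise_sigma = coordinate_noise_sigma,
         true_voxel = true_voxel, labelled_voxel = labelled_voxel,
         map_noise_sigma = map_noise_sigma, resolution = resolution,
         seed = as.integer(seed)),
    class = "toy_spec"
  )
}

# run code under a local, seeded RNG without touching global state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate an ideal helical trace model
#'
#' Protein alpha helix: 1.5 Angstrom rise and 100 degrees twist per
#' residue on a 2.3 Angstrom radius, CA atoms, residues alternating
#' LEU/ALA. RNA A-form phosphate trace: 2.81 Angstrom rise, 32.7 degrees
#' twist, 8.8 Angstrom radius, P atoms, residues alternating A/U. Real
#' residue and atom names are used so selection and burial logic runs
#' unmodified on fixtures.
#'
#' @param n_residues number of residues (>= 1).
#' @param kind `"protein_alpha_helix"` or `"rna_P_trace"`.
#' @param chain_id chain identifier.
#' @param start_resnum first residue number.
#' @param origin helix start position, Angstrom.
#' @return an atomic model tibble; the helix axis is +z.
#' @export
make_helix_model <- function(n_residues,
                             kind = c("protein_alpha_helix", "rna_P_trace"),
                             chain_id = "A", start_resnum = 1L,
                             origin = c(0, 0, 0)) {
  kind <- match.arg(kind)
  stopifnot(n_residues >= 1)
  if (kind == "protein_alpha_helix") {
    rise <- 1.5; twist <- 100; radius <- 2.3
    atom_name <- "CA"; element <- "C"
    resnames <- rep(c("LEU", "ALA"), length.out = n_residues)
  } else {
    rise <- 2.81; twist <- 32.7; radius <- 8.8
    atom_name <- "P"; element <- "P"
    resnames <- rep(c("A", "U"), length.out = n_residues)
  }
  i <- seq_len(n_residues) - 1
  th <- i * twist * pi / 180
  atoms <- tibble::tibble(
    serial = as.integer(i + 1),
    name = atom_name, element = element, resname = resnames,
    chain = chain_id,
    resnum = as.integer(start_resnum + i),
    inscode = "", alt = "",
    x = origin[1] + radius * cos(th),
    y = origin[2] + radius * sin(th),
    z = origin[3] + i * rise,
    occupancy = 1, bfactor = 30, hetero = FALSE
  )
  new_atomic_model(atoms, identifier = paste0("helix-", kind))
}

#' Generate a two-domain conformational pair with known head motion
#'
#' Model A has a "body" (chain A) and a "head" (chain B) helical domain,
#' emulating the 30S body/head geometry at toy scale. Model B applies the
#' specified head rotation about `head_axis` through the head centroid
#' plus the specified translation, then optional coordinate noise; the
#' body is untouched (up to noise). The applied motion is returned as
#' ground truth for recovery tests.
#'
#' @param spec a [toy_spec()].
#' @return list with `model_a`, `model_b`, and `truth` (a list with
#'   `angle_deg`, `axis`, `swivel_deg`, `tilt_deg` relative to the spec's
#'   head axis, and the selections for body and head).
#' @export
make_two_domain_pair <- function(spec = toy_spec()) {
  # each domain is a 4-helix bundle: a thin single helix has almost no
  # lever arm about its own axis, while a real ribosomal domain is tens of
  # Angstrom wide; the bundle gives rotation recovery a realistic footprint
  bundle <- function(chain_id, z0) {
    offsets <- list(c(-9, -9), c(9, -9), c(-9, 9), c(9, 9))
    parts <- lapply(seq_along(offsets), function(k) {
      make_helix_model(spec$atoms_per_domain, "protein_alpha_helix",
                       chain_id = chain_id,
                       start_resnum = (k - 1L) * (spec$atoms_per_domain + 10L) + 1L,
                       origin = c(offsets[[k]][1], offsets[[k]][2], z0))
    })
    out <- do.call(rbind, parts)
    out$serial <- seq_len(nrow(out))
    out
  }
  body <- bundle("A", 0)
  head <- bundle("B", spec$atoms_per_domain * 1.5 + 6)
  head$serial <- head$serial + max(body$serial)
  model_a <- new_atomic_model(rbind(body, head), identifier = "toy-pair-a")

  centroid <- colMeans(coords_matrix(head))
  if (!is.null(spec$head_swivel_deg) || !is.null(spec$head_tilt_deg)) {
    sw <- spec$head_swivel_deg %||% 0
    ti <- spec$head_tilt_deg %||% 0
    # orthogonalize the tilt axis against the swivel axis
    ta <- spec$tilt_axis - sum(spec$tilt_axis * spec$head_axis) * spec$head_axis
    if (sqrt(sum(ta^2)) < 1e-12) {
      stop("tilt_axis is parallel to head_axis", call. = FALSE)
    }
    ta <- ta / sqrt(sum(ta^2))
    R <- axis_angle_matrix(ta, ti) %*% axis_angle_matrix(spec$head_axis, sw)
    truth_angle <- rotation_to_axis_angle(R)$angle
    truth_swivel <- sw
    truth_tilt <- ti
  } else {
    R <- axis_angle_matrix(spec$head_axis, spec$head_rotation_deg)
    truth_angle <- spec$head_rotation_deg
    dec <- swivel_tilt_decompose(R, spec$head_axis)
    truth_swivel <- dec$swivel_deg
    truth_tilt <- dec$tilt_deg
  }
  head_b <- transform_model(head, rotation = R,
                            translation = spec$head_translation,
                            about = centroid)
  model_b <- new_atomic_model(rbind(body, head_b), identifier = "toy-pair-b")
  if (spec$coordinate_noise_sigma > 0) {
    model_b <- with_local_seed(spec$seed, {
      xyz <- coords_matrix(model_b)
      set_coords(model_b, xyz + matrix(
        stats::rnorm(length(xyz), sd = spec$coordinate_noise_sigma),
        ncol = 3))
    })
  }
  list(
    model_a = model_a, model_b = model_b,
    truth = list(
      angle_deg = truth_angle,
      swivel_deg = truth_swivel,
      tilt_deg = truth_tilt,
      rotation = R,
      axis = spec$head_axis,
      body_selection = list(chains = "A", atoms = "CA"),
      head_selection = list(chains = "B", atoms = "CA")
    )
  )
}

#' Generate a density map with a mislabelled pixel size
#'
#' Simulates a map from the model at the spec's true pixel size, then
#' relabels the whole geometry at the labelled pixel size about the map
#' center — emulating a map whose header records the nominal microscope
#' pixel size while the physical magnification differs. Optional Gaussian
#' voxel noise is added at `map_noise_sigma` times the peak density,
#' driven by the spec's seed.
#'
#' @param model an atomic model tibble.
#' @param spec a [toy_spec()].
#' @return a `density_map` whose header claims `labelled_voxel`; running
#'   [calibrate_pixel_size()] with the model should recover `true_voxel`.
#' @export
make_mislabelled_map <- function(model, spec = toy_spec()) {
  stopifnot(spec$true_voxel > 0, spec$labelled_voxel > 0)
  sim <- simulate_map(model, simulation_params(
    resolution = spec$resolution, voxel_size = spec$true_voxel, padding = 5))
  if (spec$map_noise_sigma > 0) {
    peak <- max(sim$grid)
    sim$grid <- with_local_seed(spec$seed, {
      sim$grid + array(
        stats::rnorm(length(sim$grid), sd = spec$map_noise_sigma * peak),
        dim = dim(sim$grid))
    })
  }
  mislabelled <- rescale_geometry(sim, spec$labelled_voxel / spec$true_voxel)
  mislabelled$identifier <- sprintf("mislabelled(%.4g as %.4g)",
                                    spec$true_voxel, spec$labelled_voxel)
  mislabelled
}
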