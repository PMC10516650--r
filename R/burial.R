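#' Parameters for solvent-accessible surface area and burial counting
#'
#' @param probe_radius probe sphere radius, Angstrom (1.4, the water probe).
#' @param n_sphere_points number of quasi-uniform test points per atom
#'   sphere (default 960; deterministic golden-section spiral, so results
#'   are bit-reproducible).
#' @param radius_set optional named numeric vector of van der Waals radii
#'   overriding the shipped table (see [element_data()]).
#' @param burial_threshold an atom is buried when its SASA falls below
#'   this value; Angstrom^2 in absolute mode, a fraction of the isolated
#'   sphere area in relative mode.
#' @param burial_mode `"absolute"` (default; threshold in Angstrom^2) or
#'   `"relative"` (threshold as a fraction, e.g. 0.05).
#' @param hydrophobic_residues residue names whose atoms are counted.
#' @param counted_elements elements counted within those residues
#'   (default carbon and sulfur).
#' @return a list of parameters.
#' @export
sasa_params <- function(probe_radius = 1.4, n_sphere_points = 960,
                        radius_set = NULL, burial_threshold = 0.1,
                        burial_mode = c("absolute", "relative"),
                        hydrophobic_residues = c("ALA", "VAL", "LEU", "ILE",
                                                 "PRO", "PHE", "MET", "TRP"),
                        counted_elements = c("C", "S")) {
  burial_mode <- match.arg(burial_mode)
  stopifnot(probe_radius >= 0, n_sphere_points >= 16, burial_threshold >= 0)
  list(probe_radius = probe_radius, n_sphere_points = n_sphere_points,
       radius_set = radius_set, burial_threshold = burial_threshold,
       burial_mode = burial_mode,
       hydrophobic_residues = toupper(hydrophobic_residues),
       counted_elements = toupper(counted_elements))
}

# deterministic golden-section spiral on the unit sphere
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' For each heavy atom, `n_sphere_points` test points are placed on the
#' expanded sphere of radius `r_vdw + probe`; a point is accessible iff it
#' lies outside every neighbor's expanded sphere, and the accessible
#' fraction times the expanded sphere area gives the SASA. Hydrogens are
#' excluded and alternate locations collapsed before computation; waters
#' (`HOH`) are excluded as occluders. The neighbor search is an exact
#' radius cutoff, so results are identical to an all-pairs scan.
#'
#' @param model an atomic model tibble.
#' @param params see [sasa_params()].
#' @return the heavy-atom model tibble with columns `sasa` (Angstrom^2)
#'   and `isolated_area` (the atom's full expanded-sphere area) appended.
#' @export
sasa <- function(model, params = sasa_params()) {
  m <- canonical_conformer(model)
  m <- m[toupper(m$resname) != "HOH", , drop = FALSE]
  if (nrow(m) == 0) stop("model has no heavy atoms", call. = FALSE)
  radii <- vdw_radius(m$element, params$radius_set) + params$probe_radius
  xyz <- coords_matrix(m)
  n <- nrow(m)
  pts <- sphere_points(params$n_sphere_points)
  npts <- nrow(pts)
  rmax <- max(radii)

  # cell list on a grid of the maximum interaction distance
  cell_w <- 2 * rmax
  ci <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell_w)
  ckey <- paste(ci[, 1], ci[, 2], ci[, 3], sep = ",")
  cells <- split(seq_len(n), ckey)
  cell_of <- match(ckey, names(cells))
  neigh_offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))

  areas <- numeric(n)
  for (i in seq_len(n)) {
    # candidate neighbors from the 27 surrounding cells
    base <- ci[i, ]
    cand_keys <- paste(base[1] + neigh_offsets[, 1],
                       base[2] + neigh_offsets[, 2],
                       base[3] + neigh_offsets[, 3], sep = ",")
    cand <- unlist(cells[cand_keys], use.names = FALSE)
    cand <- cand[cand != i]
    if (length(cand)) {
      dvec <- sweep(xyz[cand, , drop = FALSE], 2, xyz[i, ])
      d2 <- rowSums(dvec^2)
      keep <- d2 < (radii[i] + radii[cand])^2
      cand <- cand[keep]
    }
    if (!length(cand)) {
      areas[i] <- 4 * pi * radii[i]^2
      next
    }
    p <- sweep(pts * radii[i], 2, xyz[i, ], `+`)
    accessible <- rep(TRUE, npts)
    for (j in cand) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      accessible <- accessible & dj2 >= radii[j]^2
      if (!any(accessible)) break
    }
    areas[i] <- mean(accessible) * 4 * pi * radii[i]^2
  }
  m$sasa <- areas
  m$isolated_area <- 4 * pi * radii^2
  m
}

#' Count buried hydrophobic atoms of a model
#'
#' Computes SASA in the context of the full model (rRNA and heteroatoms,
#' waters excluded, act as occluders) and counts carbon/sulfur atoms of
#' hydrophobic protein residues whose SASA falls below the burial
#' threshold. rRNA atoms occlude but are never counted: the statistic is
#' over the ribosomal proteins.
#'
#' @param model an atomic model tibble (full assembly).
#' @param params see [sasa_params()].
#' @return a `burial_report` list: `per_atom` (the SASA table),
#'   `hydrophobic_atom_count`, `buried_hydrophobic_count`,
#'   `hydrophobic_residue_count`, `buried_hydrophobic_residue_count`
#'   (a residue counts as buried when every counted atom of it is buried),
#'   `total_sasa` and the parameters used.
#' @export
count_buried_hydrophobic <- function(model, params = sasa_params()) {
  per_atom <- sasa(model, params)
  is_protein <- polymer_class(per_atom$resname) == "protein"
  if (!any(is_protein)) {
    stop("model contains no protein residues; the burial statistic is over r-proteins",
         call. = FALSE)
  }
  counted <- is_protein &
    toupper(per_atom$resname) %in% params$hydrophobic_residues &
    per_atom$element %in% params$counted_elements
  thr <- if (params$burial_mode == "absolute") {
    rep(params$burial_threshold, nrow(per_atom))
  } else {
    params$burial_threshold * per_atom$isolated_area
  }
  buried <- counted & per_atom$sasa < thr
  res_key <- paste(per_atom$chain, per_atom$resnum, per_atom$inscode,
                   sep = "\r")
  counted_res <- unique(res_key[counted])
  buried_res <- vapply(counted_res, function(k) {
    idx <- counted & res_key == k
    all(per_atom$sasa[idx] < thr[idx])
  }, logical(1))
  structure(
    list(
      per_atom = per_atom,
      hydrophobic_atom_count = sum(counted),
      buried_hydrophobic_count = sum(buried),
      hydrophobic_residue_count = length(counted_res),
      buried_hydrophobic_residue_count = sum(buried_res),
      total_sasa = sum(per_atom$sasa),
      params = params
    ),
    class = "burial_report"
  )
}

#' @export
print.burial_report <- function(x, ...) {
  cat(sprintf(
    "<burial_report> %d/%d hydrophobic atoms buried (%d/%d residues), total SASA %.0f A^2\n",
    x$buried_hydrophobic_count, x$hydrophobic_atom_count,
    x$buried_hydrophobic_residue_count, x$hydrophobic_residue_count,
    x$total_sasa))
  invisible(x)
}

#' Percent excess of buried hydrophobic atoms between two models
#'
#' `100 * (a - b) / baseline`. The natural reading ("a buries x% more
#' than b") uses `baseline = "b"`; `baseline = "a"` expresses the same
#' difference as a fraction of the larger count, a convention that also
#' appears in the literature, so both are available.
#'
#' @param report_a,report_b `burial_report`s, or bare counts.
#' @param baseline `"b"` (default) or `"a"`.
#' @return percent difference.
#' @export
burial_excess <- function(report_a, report_b, baseline = c("b", "a")) {
  baseline <- match.arg(baseline)
  ca <- if (inherits(report_a, "burial_report"))
    report_a$buried_hydrophobic_count else as.numeric(report_a)
  cb <- if (inherits(report_b, "burial_report"))
    report_b$buried_hydrophobic_count else as.numeric(report_b)
  denom <- if (baseline == "b") cb else ca
  if (denom <= 0) stop("baseline buried count is zero", call. = FALSE)
  100 * (ca - cb) / denom
}
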