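#' Rigid transforms
#'
#' A `rigid_transform` holds a proper rotation matrix, a translation, the
#' axis-angle form of the rotation, and the fit statistics of the
#' superposition that produced it.
#'
#' @name rigid_transform
NULL

new_rigid_transform <- function(rotation, translation, rmsd = NA_real_,
                                n_atoms = NA_integer_) {
  aa <- rotation_to_axis_angle(rotation)
  structure(
    list(rotation = rotation, translation = as.numeric(translation),
         angle = aa$angle, axis = aa$axis,
         rmsd = rmsd, n_atoms = as.integer(n_atoms)),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> angle %.3f deg about (%.3f, %.3f, %.3f), |t| %.3f A, rmsd %.3f A over %s atoms\n",
    x$angle, x$axis[1], x$axis[2], x$axis[3],
    sqrt(sum(x$translation^2)), x$rmsd,
    ifelse(is.na(x$n_atoms), "?", x$n_atoms)))
  invisible(x)
}

#' Convert a rotation matrix to axis and angle
#'
#' Robust near 0 deg (axis defaults to +z) and near 180 deg (axis from the
#' dominant eigenvector of `(R + I)/2`).
#'
#' @param rotation 3x3 proper rotation matrix.
#' @return list with `angle` (degrees, in `[0, 180]`) and `axis` (unit
#'   3-vector).
#' @export
rotation_to_axis_angle <- function(rotation) {
  tr <- sum(diag(rotation))
  cs <- (tr - 1) / 2
  skew <- c(rotation[3, 2] - rotation[2, 3],
            rotation[1, 3] - rotation[3, 1],
            rotation[2, 1] - rotation[1, 2])
  sn <- sqrt(sum(skew^2)) / 2
  angle <- atan2(sn, cs)           # precise near 0, unlike acos
  if (angle < 1e-12) {
    return(list(angle = 0, axis = c(0, 0, 1)))
  }
  if (angle < pi - 1e-6) {
    ax <- skew / (2 * sin(angle))
  } else {
    # near 180 deg: axis is the eigenvector of R with eigenvalue +1
    B <- (rotation + diag(3)) / 2
    ax <- B[, which.max(diag(B))]
    ax <- ax / sqrt(sum(ax^2))
  }
  list(angle = angle * 180 / pi, axis = ax / sqrt(sum(ax^2)))
}

#' Build a rotation matrix from axis and angle
#'
#' @param axis 3-vector (normalized internally).
#' @param angle_deg rotation angle, degrees.
#' @return 3x3 rotation matrix (Rodrigues formula).
#' @export
axis_angle_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Optimal rigid superposition of paired coordinates (Kabsch)
#'
#' Finds the least-squares rotation and translation mapping `coords_b`
#' onto `coords_a` by SVD of the covariance matrix, with the reflection
#' corrected to a proper rotation by a sign flip of the smallest singular
#' direction.
#'
#' @param coords_a,coords_b n x 3 matrices of paired coordinates.
#' @return a `rigid_transform` such that
#'   `coords_b %*% t(rotation) + translation` approximates `coords_a` with
#'   the reported `rmsd`.
#' @export
kabsch <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  stopifnot(ncol(coords_a) == 3, ncol(coords_b) == 3,
            nrow(coords_a) == nrow(coords_b))
  n <- nrow(coords_a)
  if (n < 3) stop("need at least 3 paired atoms", call. = FALSE)
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A0 <- sweep(coords_a, 2, ca); B0 <- sweep(coords_b, 2, cb)
  # collinearity check: rank of the centred point cloud
  sv_a <- svd(A0, nu = 0, nv = 0)$d
  if (sv_a[2] < 1e-8 * max(sv_a[1], 1)) {
    stop("degenerate (collinear) point set", call. = FALSE)
  }
  H <- t(B0) %*% A0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_vec <- ca - as.vector(R %*% cb)
  fitted <- B0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - A0)^2)))
  new_rigid_transform(R, t_vec, rmsd = rmsd, n_atoms = n)
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 matrix.
#' @param transform a `rigid_transform`.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, transform) {
  sweep(as.matrix(xyz) %*% t(transform$rotation), 2,
        transform$translation, `+`)
}

# quaternion helpers (w, x, y, z) -------------------------------------------

quat_from_matrix <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / sqrt(sum(q^2))
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

quat_mult <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_angle_deg <- function(q) {
  2 * atan2(sqrt(sum(q[2:4]^2)), abs(q[1])) * 180 / pi
}

#' Twist-swing decomposition of a rotation about a reference axis
#'
#' Splits a rotation into a twist about `swivel_axis` (the swivel
#' component) and a residual swing about an axis orthogonal to it (the
#' tilt component), using the quaternion swing-twist decomposition. The
#' two recompose exactly: `R = R_swing %*% R_twist`.
#'
#' @param rotation 3x3 rotation matrix, or a `rigid_transform`.
#' @param swivel_axis unit 3-vector defining the swivel direction.
#' @return list with `swivel_deg` and `tilt_deg` (non-negative magnitudes),
#'   `swivel_signed_deg` (sign relative to `swivel_axis` by the right-hand
#'   rule), and the `twist`/`swing` rotation matrices.
#' @export
swivel_tilt_decompose <- function(rotation, swivel_axis) {
  R <- if (inherits(rotation, "rigid_transform")) rotation$rotation else rotation
  u <- swivel_axis / sqrt(sum(swivel_axis^2))
  q <- quat_from_matrix(R)
  proj <- sum(q[2:4] * u)
  tw <- c(q[1], proj * u)
  nt <- sqrt(sum(tw^2))
  if (nt < 1e-12) {
    # 180-degree swing exactly orthogonal to the axis: no twist component
    twist_q <- c(1, 0, 0, 0)
  } else {
    twist_q <- tw / nt
  }
  # swing = q * conj(twist)
  swing_q <- quat_mult(q, c(twist_q[1], -twist_q[2:4]))
  swivel_signed <- 2 * atan2(proj, q[1]) * 180 / pi
  if (swivel_signed > 180) swivel_signed <- swivel_signed - 360
  if (swivel_signed < -180) swivel_signed <- swivel_signed + 360
  list(
    swivel_deg = abs(swivel_signed),
    tilt_deg = quat_angle_deg(swing_q),
    swivel_signed_deg = swivel_signed,
    twist = quat_to_matrix(twist_q),
    swing = quat_to_matrix(swing_q)
  )
}

#' Pair atoms of two models by identity
#'
#' Atoms are matched by (chain, residue number, insertion code, atom name)
#' after collapsing alternate locations and dropping hydrogens
#' ([canonical_conformer()]); unmatched atoms are dropped. Where insertion
#' codes disagree but exactly one candidate exists on each side of a
#' (chain, residue, name) key, the pair is still accepted; ambiguous keys
#' are dropped.
#'
#' @param model_a,model_b atomic model tibbles.
#' @param ... selection arguments passed to [select_atoms()] (applied to
#'   both models).
#' @return list with `coords_a`, `coords_b` (paired n x 3 matrices in a
#'   common order), `n_pairs` and a `pairs` tibble of the matched keys.
#' @export
pair_atoms <- function(model_a, model_b, ...) {
  a <- canonical_conformer(select_atoms(model_a, ...))
  b <- canonical_conformer(select_atoms(model_b, ...))
  key_full <- function(m) paste(m$chain, m$resnum, m$inscode, m$name,
                                sep = "\r")
  key_loose <- function(m) paste(m$chain, m$resnum, m$name, sep = "\r")
  ka <- key_full(a); kb <- key_full(b)
  ia <- match(ka, kb)
  matched_a <- which(!is.na(ia))
  used_b <- ia[matched_a]
  # second pass ignoring insertion codes, only for uniquely keyed leftovers
  rest_a <- setdiff(seq_len(nrow(a)), matched_a)
  rest_b <- setdiff(seq_len(nrow(b)), used_b)
  if (length(rest_a) && length(rest_b)) {
    la <- key_loose(a)[rest_a]; lb <- key_loose(b)[rest_b]
    ua <- rest_a[la %in% names(which(table(la) == 1))]
    ub_keys <- names(which(table(lb) == 1))
    la2 <- key_loose(a)[ua]
    hit <- match(la2, lb)
    ok <- !is.na(hit) & la2 %in% ub_keys
    matched_a <- c(matched_a, ua[ok])
    used_b <- c(used_b, rest_b[hit[ok]])
  }
  ord <- order(matched_a)
  matched_a <- matched_a[ord]; used_b <- used_b[ord]
  n <- length(matched_a)
  if (n < 3) stop("fewer than 3 atom pairs matched", call. = FALSE)
  list(
    coords_a = coords_matrix(a[matched_a, , drop = FALSE]),
    coords_b = coords_matrix(b[used_b, , drop = FALSE]),
    n_pairs = n,
    pairs = tibble::tibble(
      chain = a$chain[matched_a], resnum = a$resnum[matched_a],
      inscode = a$inscode[matched_a], name = a$name[matched_a]
    )
  )
}

#' Quantify the rotation of a mobile domain between two conformations
#'
#' `model_b` is globally superposed onto `model_a` using the reference
#' selection (for ribosome work: 16S body phosphates when measuring head
#' motion, 23S phosphates when measuring whole-subunit motion); the
#' residual Kabsch fit of the mobile selection then gives the domain
#' motion as a rotation angle, axis and RMSD. With `swivel_axis` given the
#' motion is additionally split into swivel (twist) and tilt (swing)
#' components.
#'
#' @param model_a,model_b atomic model tibbles (two conformations).
#' @param reference list of [select_atoms()] arguments naming the frame
#'   domain (e.g. `list(chains = "A", residues = c(1, 929), atoms = "P")`).
#' @param mobile list of selection arguments naming the moving domain.
#' @param swivel_axis optional unit 3-vector (in `model_a`'s frame) about
#'   which the swivel component is measured.
#' @return a `motion_report` list: `body_alignment` and `mobile_motion`
#'   (`rigid_transform`s), `angle_deg`, and when `swivel_axis` is given
#'   `swivel_deg`, `tilt_deg`, `swivel_signed_deg`. `tidy()`/`glance()`
#'   return tibbles.
#' @export
domain_rotation <- function(model_a, model_b, reference, mobile,
                            swivel_axis = NULL) {
  ref_pairs <- do.call(pair_atoms, c(list(model_a, model_b), reference))
  body_alignment <- kabsch(ref_pairs$coords_a, ref_pairs$coords_b)
  mob_pairs <- do.call(pair_atoms, c(list(model_a, model_b), mobile))
  b_aligned <- apply_transform(mob_pairs$coords_b, body_alignment)
  # motion carrying a's mobile domain onto (aligned) b's
  mobile_motion <- kabsch(b_aligned, mob_pairs$coords_a)
  out <- list(
    reference = reference, mobile = mobile,
    body_alignment = body_alignment,
    mobile_motion = mobile_motion,
    angle_deg = mobile_motion$angle,
    n_reference_pairs = ref_pairs$n_pairs,
    n_mobile_pairs = mob_pairs$n_pairs
  )
  if (!is.null(swivel_axis)) {
    dec <- swivel_tilt_decompose(mobile_motion$rotation, swivel_axis)
    out$swivel_axis <- swivel_axis / sqrt(sum(swivel_axis^2))
    out$swivel_deg <- dec$swivel_deg
    out$tilt_deg <- dec$tilt_deg
    out$swivel_signed_deg <- dec$swivel_signed_deg
  }
  class(out) <- "motion_report"
  out
}

#' @export
print.motion_report <- function(x, ...) {
  cat(sprintf(
    "<motion_report> mobile rotation %.2f deg (axis %.3f, %.3f, %.3f), rmsd %.3f A, %d/%d ref/mobile pairs\n",
    x$angle_deg, x$mobile_motion$axis[1], x$mobile_motion$axis[2],
    x$mobile_motion$axis[3], x$mobile_motion$rmsd,
    x$n_reference_pairs, x$n_mobile_pairs))
  if (!is.null(x$swivel_deg)) {
    cat(sprintf("  swivel %.2f deg (signed %+.2f), tilt %.2f deg\n",
                x$swivel_deg, x$swivel_signed_deg, x$tilt_deg))
  }
  invisible(x)
}

#' Per-atom displacement of a selection between two conformations
#'
#' After superposing `model_b` onto `model_a` on the `align_on` selection,
#' reports Euclidean distances between paired atoms of the `measure`
#' selection.
#'
#' @param model_a,model_b atomic model tibbles.
#' @param measure list of selection arguments for the measured atoms.
#' @param align_on list of selection arguments for the alignment frame.
#' @param statistic `"mean"`, `"max"` or `"per_residue"`.
#' @return a single value in Angstrom, or for `"per_residue"` a tibble
#'   with columns `chain`, `resnum`, `displacement` (mean over the
#'   residue's paired atoms).
#' @export
displacement <- function(model_a, model_b, measure, align_on,
                         statistic = c("mean", "max", "per_residue")) {
  statistic <- match.arg(statistic)
  ref_pairs <- do.call(pair_atoms, c(list(model_a, model_b), align_on))
  fit <- kabsch(ref_pairs$coords_a, ref_pairs$coords_b)
  mp <- do.call(pair_atoms, c(list(model_a, model_b), measure))
  b_aligned <- apply_transform(mp$coords_b, fit)
  d <- sqrt(rowSums((mp$coords_a - b_aligned)^2))
  switch(statistic,
    mean = mean(d),
    max = max(d),
    per_residue = mp$pairs |>
      dplyr::mutate(displacement = d) |>
      dplyr::group_by(.data$chain, .data$resnum) |>
      dplyr::summarise(displacement = mean(.data$displacement),
                       .groups = "drop")
  )
}

#' Minimum heavy-atom distance between two selections of one model
#'
#' @param model an atomic model tibble.
#' @param sel_a,sel_b lists of [select_atoms()] arguments.
#' @return minimum pairwise distance, Angstrom.
#' @export
min_distance <- function(model, sel_a, sel_b) {
  a <- canonical_conformer(do.call(select_atoms, c(list(model), sel_a)))
  b <- canonical_conformer(do.call(select_atoms, c(list(model), sel_b)))
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("empty selection in min_distance", call. = FALSE)
  }
  xa <- coords_matrix(a); xb <- coords_matrix(b)
  # blockwise cross-distance keeps memory bounded for large selections
  best <- Inf
  step <- 2000L
  for (i0 in seq(1, nrow(xa), by = step)) {
    ii <- i0:min(i0 + step - 1, nrow(xa))
    d2 <- outer(rowSums(xa[ii, , drop = FALSE]^2), rowSums(xb^2), `+`) -
      2 * xa[ii, , drop = FALSE] %*% t(xb)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}
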