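test_that("atom pairing matches identity keys and survives shuffling", {
  m <- mixed_model_fixture()
  p <- pair_atoms(m, m)
  expect_equal(p$n_pairs, nrow(canonical_conformer(m)))
  expect_equal(p$coords_a, p$coords_b)
  # removing residues removes exactly their atoms from the pairing
  m2 <- m[!(m$chain == "B" & m$resnum %in% 10:12), ]
  m2 <- cryoquant:::new_atomic_model(m2)
  p2 <- pair_atoms(m, m2)
  expect_equal(p$n_pairs - p2$n_pairs, 3)
  # shuffled atom order gives the same pairs as unshuffled (oracle: keys)
  shuf <- withr::with_seed(9, m[sample(nrow(m)), ])
  shuf <- cryoquant:::new_atomic_model(shuf)
  p3 <- pair_atoms(m, shuf)
  expect_equal(p3$n_pairs, p$n_pairs)
  key <- function(t) sort(paste(t$chain, t$resnum, t$name))
  expect_equal(key(p3$pairs), key(p$pairs))
  # pairs are aligned: distances all zero
  expect_lt(max(abs(p3$coords_a - p3$coords_b)), 1e-12)
  expect_error(pair_atoms(m, m, chains = "Z"), "pairs|match")
})

test_that("Kabsch recovers applied transforms exactly and handles noise", {
  xyz <- as.matrix(random_model(50, 1)[, c("x", "y", "z")])
  # identity
  fit0 <- kabsch(xyz, xyz)
  expect_equal(fit0$angle, 0)
  expect_lt(fit0$rmsd, 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-12)
  # 30 degrees about z plus a translation: exact recovery
  R <- axis_angle_matrix(c(0, 0, 1), 30)
  moved <- sweep(xyz %*% t(R), 2, c(5, -3, 2), `+`)
  fit <- kabsch(moved, xyz)
  expect_equal(fit$angle, 30, tolerance = 1e-9)
  expect_equal(abs(fit$axis[3]), 1, tolerance = 1e-9)
  expect_lt(fit$rmsd, 1e-9)
  # orthogonality and properness invariants
  expect_equal(fit$rotation %*% t(fit$rotation), diag(3), tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  # Rodrigues consistency of the axis-angle report
  expect_equal(axis_angle_matrix(fit$axis, fit$angle), fit$rotation,
               tolerance = 1e-6)
  # noisy case: 25 degrees, sigma 0.3 A, n = 200
  xyz2 <- as.matrix(random_model(200, 2, spread = 20)[, c("x", "y", "z")])
  R25 <- axis_angle_matrix(c(1, 2, 0.5), 25)
  noisy <- withr::with_seed(3, xyz2 %*% t(R25) +
                              matrix(rnorm(600, sd = 0.3), ncol = 3))
  fitn <- kabsch(noisy, xyz2)
  expect_lt(abs(fitn$angle - 25), 0.5)
  expect_lt(abs(fitn$rmsd - 0.3 * sqrt(3)), 0.15)
  # collinear points are degenerate
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch(line, line), "collinear|degenerate")
})

test_that("cross-check: Kabsch agrees with bio3d's superposition", {
  xyz <- as.matrix(random_model(40, 7)[, c("x", "y", "z")])
  R <- axis_angle_matrix(c(2, -1, 1), 17)
  moved <- withr::with_seed(8, sweep(xyz %*% t(R), 2, c(1, 2, 3), `+`) +
                              matrix(rnorm(120, sd = 0.2), ncol = 3))
  fit <- kabsch(xyz, moved)
  ours <- apply_transform(moved, fit)
  ref <- suppressWarnings(bio3d::fit.xyz(
    fixed = as.vector(t(xyz)), mobile = as.vector(t(moved))))
  ref <- matrix(ref, ncol = 3, byrow = TRUE)
  expect_lt(max(abs(ours - ref)), 1e-6)
})

test_that("domain rotation recovers a constructed head motion", {
  spec <- toy_spec(head_rotation_deg = 18, seed = 4)
  pair <- make_two_domain_pair(spec)
  rep <- domain_rotation(pair$model_a, pair$model_b,
                         reference = pair$truth$body_selection,
                         mobile = pair$truth$head_selection)
  expect_equal(rep$angle_deg, 18, tolerance = 1e-9)
  expect_lt(rep$body_alignment$rmsd, 1e-12)
  # both domains untouched: zero everywhere
  rep0 <- domain_rotation(pair$model_a, pair$model_a,
                          reference = pair$truth$body_selection,
                          mobile = pair$truth$head_selection)
  expect_equal(rep0$angle_deg, 0, tolerance = 1e-9)
})

test_that("domain rotation is antisymmetric and frame-invariant", {
  spec <- toy_spec(head_rotation_deg = 12, head_axis = c(0.3, 0.2, 1),
                   seed = 6)
  pair <- make_two_domain_pair(spec)
  fwd <- domain_rotation(pair$model_a, pair$model_b,
                         reference = pair$truth$body_selection,
                         mobile = pair$truth$head_selection)
  rev <- domain_rotation(pair$model_b, pair$model_a,
                         reference = pair$truth$body_selection,
                         mobile = pair$truth$head_selection)
  expect_equal(fwd$angle_deg, rev$angle_deg, tolerance = 1e-6)
  expect_equal(fwd$mobile_motion$axis, -rev$mobile_motion$axis,
               tolerance = 1e-6)
  # a global rigid transform of both models changes nothing
  G <- axis_angle_matrix(c(1, 1, 1), 40)
  ga <- transform_model(pair$model_a, G, translation = c(10, 5, -3))
  gb <- transform_model(pair$model_b, G, translation = c(10, 5, -3))
  moved <- domain_rotation(ga, gb,
                           reference = pair$truth$body_selection,
                           mobile = pair$truth$head_selection)
  expect_equal(moved$angle_deg, fwd$angle_deg, tolerance = 1e-6)
})

test_that("twist-swing decomposition splits swivel from tilt", {
  z <- c(0, 0, 1)
  # pure rotation about the swivel axis
  d1 <- swivel_tilt_decompose(axis_angle_matrix(z, 10), z)
  expect_equal(d1$swivel_deg, 10, tolerance = 1e-9)
  expect_equal(d1$tilt_deg, 0, tolerance = 1e-9)
  # pure rotation about an orthogonal axis
  d2 <- swivel_tilt_decompose(axis_angle_matrix(c(1, 0, 0), 7), z)
  expect_equal(d2$swivel_deg, 0, tolerance = 1e-9)
  expect_equal(d2$tilt_deg, 7, tolerance = 1e-9)
  # zero rotation
  d0 <- swivel_tilt_decompose(diag(3), z)
  expect_equal(c(d0$swivel_deg, d0$tilt_deg), c(0, 0))
  # random rotations: R = swing %*% twist within 1e-6, tilt axis orthogonal
  for (seed in 1:10) {
    R <- withr::with_seed(seed, axis_angle_matrix(rnorm(3), runif(1, 1, 170)))
    axis <- withr::with_seed(seed + 100, {
      a <- rnorm(3); a / sqrt(sum(a^2))
    })
    d <- swivel_tilt_decompose(R, axis)
    expect_lt(max(abs(d$swing %*% d$twist - R)), 1e-6)
    swing_axis <- rotation_to_axis_angle(d$swing)$axis
    if (d$tilt_deg > 1e-6) {
      expect_lt(abs(sum(swing_axis * axis)), 1e-6)
    }
  }
})

test_that("a composed swivel+tilt generator motion is recovered component-wise", {
  spec <- toy_spec(head_swivel_deg = 6, head_tilt_deg = 5, seed = 12)
  pair <- make_two_domain_pair(spec)
  rep <- domain_rotation(pair$model_a, pair$model_b,
                         reference = pair$truth$body_selection,
                         mobile = pair$truth$head_selection,
                         swivel_axis = spec$head_axis)
  expect_equal(rep$swivel_deg, 6, tolerance = 1e-6)
  expect_equal(rep$tilt_deg, 5, tolerance = 1e-6)
  expect_equal(rep$angle_deg, pair$truth$angle_deg, tolerance = 1e-6)
})

test_that("displacements reproduce constructed shifts and a distance oracle", {
  m <- mixed_model_fixture()
  # identical models: zero for every statistic
  expect_equal(displacement(m, m, measure = list(chains = "B"),
                            align_on = list(chains = "A")), 0,
               tolerance = 1e-12)
  # translate the measured chain by exactly 5 A
  m2 <- m
  shift <- m2$chain == "B"
  m2$x[shift] <- m2$x[shift] + 3
  m2$y[shift] <- m2$y[shift] + 4
  m2 <- cryoquant:::new_atomic_model(m2)
  expect_equal(displacement(m, m2, measure = list(chains = "B"),
                            align_on = list(chains = "A")), 5,
               tolerance = 1e-9)
  expect_equal(displacement(m, m2, measure = list(chains = "B"),
                            align_on = list(chains = "A"),
                            statistic = "max"), 5, tolerance = 1e-9)
  # per-residue values match a brute-force distance computation
  per_res <- displacement(m, m2, measure = list(chains = "B"),
                          align_on = list(chains = "A"),
                          statistic = "per_residue")
  expect_equal(nrow(per_res), 13)
  expect_true(all(abs(per_res$displacement - 5) < 1e-9))
})

test_that("minimum distance equals the exhaustive scan", {
  # two single atoms 4.2 A apart
  two <- cryoquant:::new_atomic_model(tibble::tibble(
    serial = 1:2, name = "CA", element = "C", resname = "ALA",
    chain = c("A", "B"), resnum = 1L, inscode = "", alt = "",
    x = c(0, 4.2), y = 0, z = 0, occupancy = 1, bfactor = 0, hetero = FALSE))
  expect_equal(min_distance(two, list(chains = "A"), list(chains = "B")),
               4.2, tolerance = 1e-12)
  # overlapping selections share atoms: distance 0
  expect_equal(min_distance(two, list(chains = c("A", "B")),
                            list(chains = "B")), 0)
  # 50-atom random fixture against the O(n^2) oracle
  m <- random_model(50, 13, spread = 15)
  m$chain <- rep(c("A", "B"), 25)
  m <- cryoquant:::new_atomic_model(m)
  got <- min_distance(m, list(chains = "A"), list(chains = "B"))
  xa <- as.matrix(m[m$chain == "A", c("x", "y", "z")])
  xb <- as.matrix(m[m$chain == "B", c("x", "y", "z")])
  expect_equal(got, min_distance_oracle(xa, xb), tolerance = 1e-12)
  expect_error(min_distance(m, list(chains = "Z"), list(chains = "B")),
               "empty")
})

test_that("shipped 16S domain boundaries load and select disjoint domains", {
  all_schemes <- domain_definitions()
  expect_true(all(c("Ecoli-16S", "Sac-16S") %in% all_schemes$scheme))
  head_rng <- domain_definitions("Ecoli-16S", "head")
  body_rng <- domain_definitions("Ecoli-16S", "body")
  expect_equal(head_rng, list(c(930, 1390)))
  # sibling domains within one scheme are disjoint
  in_any <- function(rngs, x) {
    Reduce(`|`, lapply(rngs, function(r) x >= r[1] & x <= r[2]))
  }
  xs <- 1:1542
  expect_false(any(in_any(head_rng, xs) & in_any(body_rng, xs)))
  # Sac boundaries are the E. coli head shifted by the stated -31 offset
  expect_equal(domain_definitions("Sac-16S", "head"),
               list(c(930 - 31, 1390 - 31)))
  # ranges plug straight into selections
  r <- make_helix_model(40, "rna_P_trace", start_resnum = 920L)
  head_sel <- select_atoms(r, residues = head_rng)
  expect_equal(range(head_sel$resnum), c(930, 959))
  expect_error(domain_definitions("nope"), "unknown numbering scheme")
})
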