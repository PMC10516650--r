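# helper to write a raw MRC file with explicit nstart / ORIGIN / axis order
write_raw_mrc <- function(path, grid_xyz, voxel = 1, nstart = c(0, 0, 0),
                          origin = c(0, 0, 0), axis_order = c(1, 2, 3)) {
  dims <- dim(grid_xyz)                     # (nx, ny, nz) world dims
  perm <- axis_order                        # world axis of col, row, sec
  file_arr <- aperm(grid_xyz, perm)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dim(file_arr)); wi(2); wi(nstart); wi(dims)
  wf(dims * voxel); wf(c(90, 90, 90)); wi(axis_order)
  wf(c(min(grid_xyz), max(grid_xyz), mean(grid_xyz)))
  wi(0); wi(0); wi(rep(0, 25)); wf(origin)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(sd(grid_xyz)); wi(0); writeBin(raw(800), con)
  wf(as.vector(file_arr))
  path
}

test_that("MRC write/read round trip preserves grid and geometry", {
  m <- make_helix_model(8)
  mp <- simulate_map(m, simulation_params(voxel_size = 1.2))
  f <- tempfile(fileext = ".mrc")
  write_map(mp, f)
  back <- read_map(f)
  expect_equal(dim(back$grid), dim(mp$grid))
  expect_lt(max(abs(back$grid - mp$grid)), 1e-5)
  expect_equal(back$voxel_size, mp$voxel_size, tolerance = 1e-6)
  expect_equal(back$origin, mp$origin, tolerance = 1e-4)
})

test_that("header origin rules: nstart fallback and ORIGIN precedence", {
  g <- array(as.numeric(1:27), dim = c(3, 3, 3))
  # zero ORIGIN: origin comes from nstart * voxel
  f1 <- write_raw_mrc(tempfile(), g, voxel = 1, nstart = c(-2, -2, -2))
  m1 <- read_map(f1)
  expect_equal(m1$origin, c(-2, -2, -2))
  # nonzero ORIGIN wins over nstart
  f2 <- write_raw_mrc(tempfile(), g, voxel = 1, nstart = c(5, 5, 5),
                      origin = c(3.5, 0, 0))
  m2 <- read_map(f2)
  expect_equal(m2$origin, c(3.5, 0, 0))
})

test_that("non-standard axis order is normalized on read", {
  g <- array(stats::rnorm(24), dim = c(2, 3, 4))  # (nx, ny, nz)
  f_std <- write_raw_mrc(tempfile(), g, axis_order = c(1, 2, 3))
  f_prm <- write_raw_mrc(tempfile(), g, axis_order = c(3, 1, 2))
  expect_equal(read_map(f_prm)$grid, read_map(f_std)$grid)
})

test_that("unsupported data modes are refused by name", {
  f <- tempfile()
  g <- array(1, dim = c(2, 2, 2))
  write_raw_mrc(f, g)
  con <- file(f, "r+b"); seek(con, 12, rw = "write")
  writeBin(4L, con, size = 4, endian = "little"); close(con)
  expect_error(read_map(f), "mode 4")
})

test_that("simulated density peaks at the atom and follows the Gaussian kernel", {
  # one carbon; voxel chosen so a voxel center sits exactly sigma away
  sigma <- 0.225 * 3.5
  v <- sigma / 3
  atom <- cryoquant:::new_atomic_model(tibble::tibble(
    serial = 1L, name = "C", element = "C", resname = "ALA", chain = "A",
    resnum = 1L, inscode = "", alt = "", x = 0, y = 0, z = 0,
    occupancy = 1, bfactor = 0, hetero = FALSE))
  mp <- simulate_map(atom, simulation_params(
    resolution = 3.5, voxel_size = v, padding = 20 * v))
  peak_idx <- which(mp$grid == max(mp$grid), arr.ind = TRUE)[1, ]
  g <- map_geometry(mp)
  peak_world <- unname(g$origin +
    (c(peak_idx[3], peak_idx[2], peak_idx[1]) - 1) * g$voxel_size)
  expect_equal(peak_world, c(0, 0, 0), tolerance = 1e-9)
  peak_val <- max(mp$grid)
  # three voxels along +x is exactly one sigma
  at_sigma <- mp$grid[peak_idx[1], peak_idx[2], peak_idx[3] + 3]
  expect_equal(at_sigma / peak_val, exp(-1 / 2), tolerance = 1e-9)
  # amplitude scales with atomic number
  expect_equal(peak_val, 6, tolerance = 1e-9)
})

test_that("map simulation is linear in the atom set", {
  a <- make_helix_model(6, chain_id = "A")
  b <- make_helix_model(6, chain_id = "B", origin = c(6, 0, 0))
  b$serial <- b$serial + 100L
  ab <- cryoquant:::new_atomic_model(rbind(a, b))
  geom <- map_geometry(simulate_map(ab, simulation_params(voxel_size = 1)))
  sim_ab <- simulate_map(ab, geometry = geom)
  sim_a <- simulate_map(a, geometry = geom)
  sim_b <- simulate_map(b, geometry = geom)
  expect_lt(max(abs(sim_ab$grid - (sim_a$grid + sim_b$grid))), 1e-10)
})

test_that("map integral is invariant under rigid transformation of the model", {
  m <- make_helix_model(10)
  R <- axis_angle_matrix(c(1, 1, 0), 35)
  mt <- transform_model(m, R, translation = c(3, -2, 1))
  p <- simulation_params(voxel_size = 0.8)
  i1 <- sum(simulate_map(m, p)$grid)
  i2 <- sum(simulate_map(mt, p)$grid)
  expect_lt(abs(i1 - i2) / i1, 0.01)
})

test_that("resampling: identity, constants, and exact linear interpolation", {
  m <- make_helix_model(6)
  mp <- simulate_map(m, simulation_params(voxel_size = 1))
  same <- resample_map(mp, mp)
  expect_lt(max(abs(same$grid - mp$grid)), 1e-9)
  # constant map stays constant strictly inside its support
  cmap <- density_map(array(7, dim = c(6, 6, 6)), 1, origin = c(0, 0, 0))
  inner <- density_map(array(0, dim = c(3, 3, 3)), 1.2,
                       origin = c(0.7, 0.9, 1.1))
  expect_true(all(abs(resample_map(cmap, inner)$grid - 7) < 1e-12))
  # linear ramp f(x) = x: half-voxel offsets give exact midpoint values
  nx <- 8
  ramp <- density_map(
    array(rep(0:(nx - 1), each = 16), dim = c(4, 4, nx)),  # value = x coord
    voxel_size = 1, origin = c(0, 0, 0))
  target <- density_map(array(0, dim = c(2, 2, nx - 1)), 1,
                        origin = c(0.5, 0.5, 0.5))
  got <- resample_map(ramp, target)
  expect_equal(got$grid[1, 1, ], seq(0.5, nx - 1.5, by = 1))
})

test_that("out-of-bounds resampling yields zero, not an error", {
  src <- density_map(array(1, dim = c(3, 3, 3)), 1, origin = c(0, 0, 0))
  far <- density_map(array(0, dim = c(2, 2, 2)), 1, origin = c(100, 0, 0))
  expect_true(all(resample_map(src, far)$grid == 0))
})

test_that("correlation matches hand arithmetic and its invariances", {
  # self-correlation is 1 in both modes
  m <- make_helix_model(6)
  mp <- simulate_map(m, simulation_params(voxel_size = 1))
  expect_equal(correlate_maps(mp, mp, "about_zero"), 1)
  expect_equal(correlate_maps(mp, mp, "about_mean"), 1)
  # Pearson mode is invariant to a constant offset of one operand
  shifted <- mp; shifted$grid <- mp$grid + 3
  expect_equal(correlate_maps(shifted, mp, "about_mean"), 1, tolerance = 1e-12)
  # hand-specified 2x2x2 grids against an explicit loop oracle
  a <- density_map(array(c(1, 2, 3, 4, 5, 6, 7, 8), dim = c(2, 2, 2)), 1)
  b <- density_map(array(c(2, 1, 0, 3, 1, 4, 2, 2), dim = c(2, 2, 2)), 1)
  num <- 0; da <- 0; db <- 0
  for (i in 1:8) {
    av <- a$grid[i]; bv <- b$grid[i]
    if (bv > 0) { num <- num + av * bv; da <- da + av^2; db <- db + bv^2 }
  }
  expect_equal(correlate_maps(a, b, "about_zero"), num / sqrt(da * db))
  # |r| <= 1 on random fixtures; symmetry under a fixed mask operand
  for (seed in 1:5) {
    withr::with_seed(seed, {
      ga <- density_map(array(stats::rnorm(64), dim = c(4, 4, 4)), 1)
      gb <- density_map(array(stats::rnorm(64), dim = c(4, 4, 4)), 1)
    })
    r <- correlate_maps(ga, gb, "about_zero", mask_threshold = -Inf)
    expect_lte(abs(r), 1)
    expect_equal(
      correlate_maps(ga, gb, "about_zero", mask_threshold = -Inf),
      correlate_maps(gb, ga, "about_zero", mask_threshold = -Inf))
  }
})

test_that("degenerate correlation inputs raise errors", {
  z <- density_map(array(0, dim = c(2, 2, 2)), 1)
  o <- density_map(array(1, dim = c(2, 2, 2)), 1)
  expect_error(correlate_maps(o, z, "about_zero"), "mask")
  expect_error(correlate_maps(o, o, "about_mean"), "variance")
  small <- density_map(array(1, dim = c(3, 3, 3)), 1)
  expect_error(correlate_maps(small, z, "about_zero"), "dimensions")
})
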