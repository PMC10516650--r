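#' Density map objects
#'
#' A `density_map` holds a 3-D scalar grid indexed `[z, y, x]` (section,
#' row, column — file order), the voxel size in Angstrom per pixel for the
#' (x, y, z) axes, and the world coordinate (Angstrom) of the center of
#' voxel (1,1,1). The world coordinate of voxel `(i, j, k)` (z, y, x
#' indices, 1-based) is `origin + ((k-1)*vx, (j-1)*vy, (i-1)*vz)`.
#'
#' @param grid 3-D numeric array in `[z, y, x]` order.
#' @param voxel_size Angstrom/pixel; scalar (isotropic) or length-3 (x,y,z).
#' @param origin length-3 numeric (x,y,z), Angstrom.
#' @param identifier string label.
#' @return an object of class `density_map`.
#' @export
density_map <- function(grid, voxel_size, origin = c(0, 0, 0),
                        identifier = "") {
  stopifnot(length(dim(grid)) == 3)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0),
            length(origin) == 3)
  if (!all(is.finite(grid))) stop("grid values must be finite", call. = FALSE)
  structure(
    list(grid = grid, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin), identifier = identifier),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf(
    "<density_map %s> %d x %d x %d (nx,ny,nz), voxel %.4g/%.4g/%.4g A, origin (%.4g, %.4g, %.4g) A\n",
    x$identifier, d[3], d[2], d[1],
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Map geometry: dimensions, voxel centers and world extent
#'
#' @param map a `density_map`.
#' @return a list with `dim_xyz` (nx, ny, nz), `voxel_size`, `origin` and
#'   `center` (world coordinate of the geometric center of the grid).
#' @export
map_geometry <- function(map) {
  d <- dim(map$grid)
  dim_xyz <- c(d[3], d[2], d[1])
  center <- map$origin + (dim_xyz - 1) / 2 * map$voxel_size
  list(dim_xyz = dim_xyz, voxel_size = map$voxel_size,
       origin = map$origin, center = center)
}

# ---------------------------------------------------------------------------
# MRC2014 I/O (hand-written: no installed R package reads MRC/CCP4 volumes)
# ---------------------------------------------------------------------------

#' Read an MRC2014/CCP4 density map
#'
#' The grid is returned in `[z, y, x]` order after applying the header's
#' axis-order mapping (mapc/mapr/maps). The voxel size comes from
#' `cella / (mx, my, mz)`. The origin is taken from the ORIGIN header when
#' any component is nonzero, otherwise from `nstart * voxel_size`.
#' Data modes 0 (int8), 1 (int16) and 2 (float32) are supported.
#'
#' @param path path to an `.mrc`/`.map` file.
#' @return a `density_map`.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  seek(con, 208)
  magic <- rawToChar(readBin(con, "raw", n = 4))
  if (!(substr(magic, 1, 3) %in% c("MAP"))) {
    stop("not an MRC2014 file (missing MAP magic): ", path, call. = FALSE)
  }
  nc <- hdr_int[1]; nr <- hdr_int[2]; ns <- hdr_int[3]
  mode <- hdr_int[4]
  nstart <- hdr_int[5:7]              # along column, row, section axes
  mxyz <- hdr_int[8:10]
  cella <- hdr_num[11:13]
  mapc <- hdr_int[17]; mapr <- hdr_int[18]; maps_ <- hdr_int[19]
  nsymbt <- hdr_int[24]
  origin_hdr <- hdr_num[50:52]        # words 50-52: ORIGIN x,y,z
  axmap <- c(mapc, mapr, maps_)       # world axis of (column, row, section)
  if (!setequal(axmap, 1:3)) stop("invalid mapc/mapr/maps axis mapping",
                                  call. = FALSE)
  n <- nc * nr * ns
  seek(con, 1024 + nsymbt)
  data <- switch(
    as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    stop("unsupported MRC data mode ", mode,
         " (modes 0, 1, 2 supported)", call. = FALSE)
  )
  if (length(data) < n) stop("truncated MRC data block", call. = FALSE)
  arr <- array(data, dim = c(nc, nr, ns))  # fastest = columns
  # permute file axes (col,row,sec) onto world axes, then to internal (z,y,x)
  perm <- match(1:3, axmap)                # world x,y,z <- which file axis
  arr_xyz <- aperm(arr, perm)              # dims now (nx, ny, nz)
  grid <- aperm(arr_xyz, c(3, 2, 1))       # internal (z, y, x)
  voxel <- cella / mxyz                    # per world axis
  nstart_world <- nstart[perm]
  origin <- if (any(origin_hdr != 0)) origin_hdr else nstart_world * voxel
  density_map(grid, voxel_size = voxel, origin = origin,
              identifier = basename(path))
}

#' Write a density map as MRC2014 mode 2 (float32)
#'
#' Axis order is written as the standard x-fastest layout
#' (mapc=1, mapr=2, maps=3); `voxel_size` goes to `cella/mx,my,mz` and
#' `origin` to the ORIGIN header words, so a round trip preserves geometry.
#'
#' @param map a `density_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  g <- map_geometry(map)
  nxyz <- g$dim_xyz
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  data <- as.vector(aperm(map$grid, c(3, 2, 1)))  # x fastest
  wi(nxyz)                       # nx ny nz (columns, rows, sections)
  wi(2)                          # mode 2 float32
  wi(c(0, 0, 0))                 # nstart
  wi(nxyz)                       # mx my mz
  wf(nxyz * g$voxel_size)        # cella
  wf(c(90, 90, 90))              # cellb
  wi(c(1, 2, 3))                 # mapc mapr maps
  wf(c(min(data), max(data), mean(data)))
  wi(0)                          # ispg
  wi(0)                          # nsymbt
  wi(rep(0, 25))                 # extra
  wf(g$origin)                   # ORIGIN x y z
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(data))
  wi(0)                          # nlabl
  writeBin(raw(800), con)        # labels
  wf(data)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Map simulation from atoms
# ---------------------------------------------------------------------------

#' Parameters for simulating a density map from atoms
#'
#' Each heavy atom contributes an isotropic Gaussian of standard deviation
#' `sigma = 0.225 * resolution`, the convention under which the Fourier
#' transform of the kernel falls to 1/e of its maximum at spatial frequency
#' `1/resolution` — the convention of the molmap-style simulators used for
#' map-model fitting.
#'
#' @param resolution target resolution in Angstrom (default 3.5).
#' @param voxel_size grid spacing, Angstrom/pixel (default 1.0).
#' @param padding margin beyond the model bounding box, Angstrom (default 5).
#' @param amplitude_mode `"atomic_number"` (amplitude proportional to Z) or
#'   `"unit"`.
#' @return a list of simulation parameters.
#' @export
simulation_params <- function(resolution = 3.5, voxel_size = 1.0, padding = 5,
                              amplitude_mode = c("atomic_number", "unit")) {
  amplitude_mode <- match.arg(amplitude_mode)
  stopifnot(resolution > 0, voxel_size > 0, padding >= 0)
  list(resolution = resolution, voxel_size = voxel_size, padding = padding,
       amplitude_mode = amplitude_mode)
}

#' Simulate a density map from an atomic model
#'
#' Sums one Gaussian per heavy atom (hydrogens excluded, alternate
#' locations collapsed to one conformer) on a grid covering the model
#' bounding box plus padding. The contribution of a union of atom sets is
#' the sum of their contributions (linearity).
#'
#' @param model an atomic model tibble.
#' @param params see [simulation_params()].
#' @param geometry optional target geometry (a `density_map` or the result
#'   of [map_geometry()]); when given, the map is evaluated on that grid
#'   and `voxel_size`/`padding` in `params` are ignored.
#' @return a `density_map`.
#' @export
simulate_map <- function(model, params = simulation_params(), geometry = NULL) {
  m <- canonical_conformer(model)
  if (nrow(m) == 0) stop("model has no non-hydrogen atoms", call. = FALSE)
  sigma <- 0.225 * params$resolution
  xyz <- coords_matrix(m)
  amp <- if (params$amplitude_mode == "atomic_number") {
    as.numeric(atomic_number(m$element))
  } else rep(1, nrow(m))

  if (is.null(geometry)) {
    v <- rep(params$voxel_size, 3)
    lo <- apply(xyz, 2, min) - params$padding
    hi <- apply(xyz, 2, max) + params$padding
    dim_xyz <- pmax(2L, as.integer(floor((hi - lo) / v)) + 1L)
    origin <- lo
  } else {
    g <- if (inherits(geometry, "density_map")) map_geometry(geometry) else geometry
    v <- g$voxel_size
    dim_xyz <- g$dim_xyz
    origin <- g$origin
  }
  grid <- array(0, dim = c(dim_xyz[3], dim_xyz[2], dim_xyz[1]))
  cut <- 4 * sigma
  xs <- origin[1] + (seq_len(dim_xyz[1]) - 1) * v[1]
  ys <- origin[2] + (seq_len(dim_xyz[2]) - 1) * v[2]
  zs <- origin[3] + (seq_len(dim_xyz[3]) - 1) * v[3]
  inv2s2 <- 1 / (2 * sigma^2)
  for (a in seq_len(nrow(m))) {
    p <- xyz[a, ]
    ix <- which(abs(xs - p[1]) <= cut)
    iy <- which(abs(ys - p[2]) <= cut)
    iz <- which(abs(zs - p[3]) <= cut)
    if (!length(ix) || !length(iy) || !length(iz)) next
    gx <- exp(-(xs[ix] - p[1])^2 * inv2s2)
    gy <- exp(-(ys[iy] - p[2])^2 * inv2s2)
    gz <- exp(-(zs[iz] - p[3])^2 * inv2s2)
    # separable kernel: outer product ordered (z, y, x)
    block <- amp[a] * (gz %o% gy %o% gx)
    grid[iz, iy, ix] <- grid[iz, iy, ix] + block
  }
  density_map(grid, voxel_size = v, origin = origin,
              identifier = paste0("sim:", attr(model, "identifier")))
}

# ---------------------------------------------------------------------------
# Resampling and correlation
# ---------------------------------------------------------------------------

#' Resample a map onto another grid geometry by trilinear interpolation
#'
#' Values at target voxel centers outside the source grid are 0; in a
#' calibration sweep these edge voxels fall outside the simulated-map mask
#' and never enter the correlation.
#'
#' @param map source `density_map`.
#' @param geometry target geometry: a `density_map` or a [map_geometry()]
#'   list.
#' @return a `density_map` on the target geometry.
#' @export
resample_map <- function(map, geometry) {
  g <- if (inherits(geometry, "density_map")) map_geometry(geometry) else geometry
  sdim <- dim(map$grid)                      # (nz, ny, nx)
  nx <- g$dim_xyz[1]; ny <- g$dim_xyz[2]; nz <- g$dim_xyz[3]
  # fractional source indices (0-based) of all target voxel centers
  tx <- (g$origin[1] + (seq_len(nx) - 1) * g$voxel_size[1] - map$origin[1]) /
    map$voxel_size[1]
  ty <- (g$origin[2] + (seq_len(ny) - 1) * g$voxel_size[2] - map$origin[2]) /
    map$voxel_size[2]
  tz <- (g$origin[3] + (seq_len(nz) - 1) * g$voxel_size[3] - map$origin[3]) /
    map$voxel_size[3]
  FX <- array(rep(tx, each = nz * ny), dim = c(nz, ny, nx))
  FY <- array(rep(rep(ty, each = nz), times = nx), dim = c(nz, ny, nx))
  FZ <- array(rep(tz, times = ny * nx), dim = c(nz, ny, nx))
  x0 <- floor(FX); y0 <- floor(FY); z0 <- floor(FZ)
  fx <- FX - x0; fy <- FY - y0; fz <- FZ - z0
  inside <- x0 >= 0 & x0 <= sdim[3] - 1 & y0 >= 0 & y0 <= sdim[2] - 1 &
    z0 >= 0 & z0 <= sdim[1] - 1
  # clamp the upper corner so points exactly on the far face interpolate
  x1 <- pmin(x0 + 1, sdim[3] - 1); y1 <- pmin(y0 + 1, sdim[2] - 1)
  z1 <- pmin(z0 + 1, sdim[1] - 1)
  out <- array(0, dim = c(nz, ny, nx))
  if (any(inside)) {
    idx <- function(zi, yi, xi) zi + 1 + sdim[1] * (yi + sdim[2] * xi)
    gvec <- as.vector(map$grid)
    w <- which(inside)
    X0 <- x0[w]; X1 <- x1[w]; Y0 <- y0[w]; Y1 <- y1[w]
    Z0 <- z0[w]; Z1 <- z1[w]
    Fx <- fx[w]; Fy <- fy[w]; Fz <- fz[w]
    c000 <- gvec[idx(Z0, Y0, X0)]; c100 <- gvec[idx(Z0, Y0, X1)]
    c010 <- gvec[idx(Z0, Y1, X0)]; c110 <- gvec[idx(Z0, Y1, X1)]
    c001 <- gvec[idx(Z1, Y0, X0)]; c101 <- gvec[idx(Z1, Y0, X1)]
    c011 <- gvec[idx(Z1, Y1, X0)]; c111 <- gvec[idx(Z1, Y1, X1)]
    out[w] <-
      c000 * (1 - Fx) * (1 - Fy) * (1 - Fz) +
      c100 * Fx * (1 - Fy) * (1 - Fz) +
      c010 * (1 - Fx) * Fy * (1 - Fz) +
      c110 * Fx * Fy * (1 - Fz) +
      c001 * (1 - Fx) * (1 - Fy) * Fz +
      c101 * Fx * (1 - Fy) * Fz +
      c011 * (1 - Fx) * Fy * Fz +
      c111 * Fx * Fy * Fz
  }
  density_map(out, voxel_size = g$voxel_size, origin = g$origin,
              identifier = map$identifier)
}

#' Cross-correlate two density maps on the same grid
#'
#' The mask is taken where `map_b` exceeds `mask_threshold` (in map-model
#' work `map_b` is the simulated map, so the mask follows the model
#' footprint). `about_zero` returns `sum(ab)/sqrt(sum(a^2) sum(b^2))` over
#' masked voxels; `about_mean` subtracts the masked means first (Pearson).
#'
#' @param map_a,map_b `density_map`s with identical grid dimensions
#'   (resample first otherwise).
#' @param mode `"about_zero"` or `"about_mean"`.
#' @param mask_threshold scalar; mask is `map_b > mask_threshold`.
#' @return correlation in `[-1, 1]`.
#' @export
correlate_maps <- function(map_a, map_b,
                           mode = c("about_zero", "about_mean"),
                           mask_threshold = 0) {
  mode <- match.arg(mode)
  if (!identical(dim(map_a$grid), dim(map_b$grid))) {
    stop("maps have different grid dimensions; resample first", call. = FALSE)
  }
  mask <- map_b$grid > mask_threshold
  if (!any(mask)) stop("empty correlation mask", call. = FALSE)
  a <- map_a$grid[mask]; b <- map_b$grid[mask]
  if (mode == "about_mean") {
    a <- a - mean(a); b <- b - mean(b)
    if (sum(a^2) == 0 || sum(b^2) == 0) {
      stop("zero variance under mask in about_mean mode", call. = FALSE)
    }
  } else if (sum(a^2) == 0 || sum(b^2) == 0) {
    stop("zero norm under mask", call. = FALSE)
  }
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
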