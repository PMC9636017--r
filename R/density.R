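#' Model-based density synthesis
#'
#' Each atom contributes an isotropic 3D Gaussian whose integral equals the
#' element's electron count. The width is resolution-dependent:
#' `sigma = 0.425 * resolution`, i.e. the kernel's full width at half
#' maximum equals the nominal resolution, which reproduces the visual blob
#' width of experimental maps at that resolution. The constant is held
#' fixed; any smooth resolution-dependent kernel preserves the behaviour of
#' the docking and rebuilding machinery, which only ever compares densities
#' generated with the same kernel.
#'
#' @param model A `dr_model`.
#' @param resolution nominal resolution in Angstrom (> 0).
#' @param template a `dr_map` providing the output grid geometry.
#' @return A `dr_map` with the template's geometry.
#' @export
synthesize_map <- function(model, resolution, template) {
  stopifnot(resolution > 0, inherits(template, "dr_map"))
  xyz <- model_coords(model)
  z <- element_electrons(model$atoms$element)
  sigma <- gaussian_sigma(resolution)
  accumulate_gaussians(xyz, z, sigma, template)
}

# FWHM of the atom kernel equals the nominal resolution
gaussian_sigma <- function(resolution) 0.425 * resolution

element_electrons <- function(element) {
  tab <- c(H = 1, C = 6, N = 7, O = 8, S = 16, P = 15, SE = 34, FE = 26,
           MG = 12, ZN = 30, CA = 20, MN = 25, "NA" = 11, K = 19, CL = 17)
  z <- tab[toupper(element)]
  z[is.na(z)] <- 6
  unname(z)
}

# add normalized Gaussians (integral = weight) onto the template grid;
# contributions beyond cutoff_sigma standard deviations are dropped
accumulate_gaussians <- function(xyz, weight, sigma, template,
                                 cutoff_sigma = 3.5) {
  d <- dim(template$grid)
  vx <- template$voxel
  out <- array(0, d)
  cutoff <- cutoff_sigma * sigma
  amp <- weight / ((2 * pi)^1.5 * sigma^3)
  fi <- map_frac_index(template, xyz)
  lo <- template$origin - 10
  hi <- template$origin + (d - 1) * vx + 10
  far <- xyz[, 1] < lo[1] | xyz[, 2] < lo[2] | xyz[, 3] < lo[3] |
         xyz[, 1] > hi[1] | xyz[, 2] > hi[2] | xyz[, 3] > hi[3]
  if (any(far))
    warning(sum(far), " atom(s) more than 10 A outside the grid; ",
            "their density contribution is clipped")
  nw <- ceiling(cutoff / vx)
  for (a in seq_len(nrow(xyz))) {
    i0 <- max(1L, ceiling(fi[a, 1] - nw[1])); i1 <- min(d[1], floor(fi[a, 1] + nw[1]))
    j0 <- max(1L, ceiling(fi[a, 2] - nw[2])); j1 <- min(d[2], floor(fi[a, 2] + nw[2]))
    k0 <- max(1L, ceiling(fi[a, 3] - nw[3])); k1 <- min(d[3], floor(fi[a, 3] + nw[3]))
    if (i0 > i1 || j0 > j1 || k0 > k1) next
    gx <- exp(-((i0:i1 - fi[a, 1]) * vx[1])^2 / (2 * sigma^2))
    gy <- exp(-((j0:j1 - fi[a, 2]) * vx[2])^2 / (2 * sigma^2))
    gz <- exp(-((k0:k1 - fi[a, 3]) * vx[3])^2 / (2 * sigma^2))
    out[i0:i1, j0:j1, k0:k1] <-
      out[i0:i1, j0:j1, k0:k1, drop = FALSE] + amp[a] * (gx %o% gy %o% gz)
  }
  map_new(out, voxel = vx, origin = template$origin,
          resolution_hint = template$resolution_hint)
}

#' Trilinear interpolation of map values at arbitrary points
#'
#' Points outside the grid return the map minimum and are flagged in the
#' `outside` attribute of the result.
#'
#' @param map A `dr_map`.
#' @param points n x 3 matrix (or length-3 vector) of Cartesian positions.
#' @return Numeric vector of interpolated values with attribute `outside`
#'   (logical vector).
#' @export
interpolate_density <- function(map, points) {
  if (is.null(dim(points))) points <- matrix(points, 1, 3)
  stopifnot(all(is.finite(points)))
  d <- dim(map$grid)
  fi <- map_frac_index(map, points)
  outside <- fi[, 1] < 1 | fi[, 1] > d[1] | fi[, 2] < 1 | fi[, 2] > d[2] |
             fi[, 3] < 1 | fi[, 3] > d[3]
  fi[, 1] <- pmin(pmax(fi[, 1], 1), d[1])
  fi[, 2] <- pmin(pmax(fi[, 2], 1), d[2])
  fi[, 3] <- pmin(pmax(fi[, 3], 1), d[3])
  i0 <- pmin(floor(fi[, 1]), d[1] - 1); fx <- fi[, 1] - i0
  j0 <- pmin(floor(fi[, 2]), d[2] - 1); fy <- fi[, 2] - j0
  k0 <- pmin(floor(fi[, 3]), d[3] - 1); fz <- fi[, 3] - k0
  g <- map$grid
  idx <- function(i, j, k) g[cbind(i, j, k)]
  v <- idx(i0,     j0,     k0    ) * (1 - fx) * (1 - fy) * (1 - fz) +
       idx(i0 + 1, j0,     k0    ) * fx       * (1 - fy) * (1 - fz) +
       idx(i0,     j0 + 1, k0    ) * (1 - fx) * fy       * (1 - fz) +
       idx(i0,     j0,     k0 + 1) * (1 - fx) * (1 - fy) * fz       +
       idx(i0 + 1, j0 + 1, k0    ) * fx       * fy       * (1 - fz) +
       idx(i0 + 1, j0,     k0 + 1) * fx       * (1 - fy) * fz       +
       idx(i0,     j0 + 1, k0 + 1) * (1 - fx) * fy       * fz       +
       idx(i0 + 1, j0 + 1, k0 + 1) * fx       * fy       * fz
  v[outside] <- min(g)
  attr(v, "outside") <- outside
  v
}

#' Masked map-model correlation
#'
#' Pearson correlation between the experimental map and a synthetic map
#' computed from the model, evaluated over the union of spheres of
#' `mask_radius` about the model's atoms (a single-radius analogue of the
#' CC_mask statistic). Per-atom B-values are ignored in the synthesis; the
#' B column of predicted models carries confidence, not displacement.
#'
#' @param map experimental `dr_map`.
#' @param model A `dr_model` with at least one atom inside the map.
#' @param resolution nominal resolution, Angstrom.
#' @param mask_radius sphere radius about each atom, Angstrom (default 2.5).
#' @return A list of class `dr_cc` with fields `cc`, `n_voxels`,
#'   `mask_radius`.
#' @export
map_model_cc <- function(map, model, resolution, mask_radius = 2.5) {
  mask <- atom_mask(map, model_coords(model), mask_radius)
  if (!any(mask)) stop("empty mask: no map voxels within ", mask_radius,
                       " A of any atom")
  synth <- synthesize_map(model, resolution, map)
  a <- map$grid[mask]; b <- synth$grid[mask]
  cc <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance region inside mask; cc defined as 0")
    0
  } else stats::cor(a, b)
  structure(list(cc = cc, n_voxels = sum(mask), mask_radius = mask_radius),
            class = "dr_cc")
}

#' @export
print.dr_cc <- function(x, ...) {
  cat(sprintf("<dr_cc> cc = %.4f over %d voxels (mask radius %.1f A)\n",
              x$cc, x$n_voxels, x$mask_radius))
  invisible(x)
}

# logical grid of voxels within `radius` of any of the given atom positions
atom_mask <- function(map, xyz, radius) {
  d <- dim(map$grid)
  vx <- map$voxel
  mask <- array(FALSE, d)
  fi <- map_frac_index(map, xyz)
  nw <- ceiling(radius / vx)
  r2 <- radius^2
  for (a in seq_len(nrow(xyz))) {
    i0 <- max(1L, ceiling(fi[a, 1] - nw[1])); i1 <- min(d[1], floor(fi[a, 1] + nw[1]))
    j0 <- max(1L, ceiling(fi[a, 2] - nw[2])); j1 <- min(d[2], floor(fi[a, 2] + nw[2]))
    k0 <- max(1L, ceiling(fi[a, 3] - nw[3])); k1 <- min(d[3], floor(fi[a, 3] + nw[3]))
    if (i0 > i1 || j0 > j1 || k0 > k1) next
    dx2 <- ((i0:i1 - fi[a, 1]) * vx[1])^2
    dy2 <- ((j0:j1 - fi[a, 2]) * vx[2])^2
    dz2 <- ((k0:k1 - fi[a, 3]) * vx[3])^2
    within <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r2
    mask[i0:i1, j0:j1, k0:k1] <-
      mask[i0:i1, j0:j1, k0:k1, drop = FALSE] | within
  }
  mask
}

#' Outlier threshold for per-residue density values
#'
#' Discards the lower half of the values (below the median; values equal to
#' the median are kept), then returns `mean(upper) - sd_ratio * sd(upper)`.
#' Residues whose smoothed CA density falls below this threshold are
#' treated as poorly fitting the map.
#'
#' @param values per-residue density values (>= 4).
#' @param sd_ratio number of standard deviations below the upper-half mean
#'   (default 3).
#' @return The threshold value.
#' @export
density_outlier_threshold <- function(values, sd_ratio = 3) {
  stopifnot(length(values) >= 4)
  upper <- values[values >= stats::median(values)]
  s <- stats::sd(upper)
  if (is.na(s) || s == 0) {
    if (length(unique(values)) == 1L)
      warning("all density values identical; threshold equals that value")
    s <- 0
  }
  mean(upper) - sd_ratio * s
}

# low-pass filter a map to an approximate target resolution by extra
# Gaussian blurring in Fourier space (used by iterative-resolution refinement)
map_lowpass <- function(map, from_resolution, to_resolution) {
  if (to_resolution <= from_resolution) return(map)
  s_extra <- sqrt(gaussian_sigma(to_resolution)^2 - gaussian_sigma(from_resolution)^2)
  d <- dim(map$grid)
  fg <- stats::fft(map$grid)
  att <- lapply(1:3, function(ax) {
    freq <- c(0:(d[ax] %/% 2), -((d[ax] - d[ax] %/% 2 - 1):1)) / (d[ax] * map$voxel[ax])
    exp(-2 * pi^2 * s_extra^2 * freq^2)
  })
  fg <- fg * (att[[1]] %o% att[[2]] %o% att[[3]])
  map_new(Re(stats::fft(fg, inverse = TRUE)) / prod(d), map$voxel, map$origin,
          map$resolution_hint)
}

# crop a map to a bounding box around coordinates (+pad A); returns dr_map
map_crop <- function(map, xyz, pad = 5) {
  d <- dim(map$grid)
  fi <- map_frac_index(map, xyz)
  lo <- pmax(1L, floor(apply(fi, 2, min) - pad / map$voxel))
  hi <- pmin(d, ceiling(apply(fi, 2, max) + pad / map$voxel))
  lo <- pmin(lo, d - 1L); hi <- pmax(hi, lo + 1L)
  map_new(map$grid[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
          map$voxel, map$origin + (lo - 1L) * map$voxel, map$resolution_hint)
}
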