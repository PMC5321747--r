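# Geometric and spectral manipulation of density maps.

#' Resample a map onto a new grid
#'
#' Trilinear interpolation onto a grid with the requested voxel size and
#' shape.  The rotation/Fourier centre voxel (floor(N/2), 0-based) of the
#' target grid is placed on the centre voxel of the source grid, so that
#' maps resampled between grids stay centred; constant fields map to
#' constant fields.
#'
#' @param m a [density_map()].
#' @param target_voxel target voxel size in Angstrom (> 0).
#' @param target_shape target grid dimensions; default keeps the physical
#'   extent of the source.
#' @return a [density_map()] on the new grid.
#' @export
resample_map <- function(m, target_voxel, target_shape = NULL) {
  stopifnot(inherits(m, "density_map"))
  if (target_voxel <= 0) stop("`target_voxel` must be positive")
  d <- dim(m$values)
  target_shape <- as.integer(target_shape %||%
                               round(d * m$voxel_size / target_voxel))
  if (any(target_shape < 1)) stop("requested target grid is empty")
  if (identical(target_shape, d) &&
      isTRUE(all.equal(target_voxel, m$voxel_size, tolerance = 1e-12)))
    return(m)
  cs <- grid_center(d)
  ct <- grid_center(target_shape)
  # target voxel centres expressed in source voxel coordinates
  co <- grid_coords(target_shape)
  scale <- target_voxel / m$voxel_size
  xyz <- cbind((co[, 1] - ct[1]) * scale + cs[1],
               (co[, 2] - ct[2]) * scale + cs[2],
               (co[, 3] - ct[3]) * scale + cs[3])
  inside <- xyz[, 1] >= 1 & xyz[, 1] <= d[1] &
    xyz[, 2] >= 1 & xyz[, 2] <= d[2] &
    xyz[, 3] >= 1 & xyz[, 3] <= d[3]
  if (!any(inside))
    stop("requested grid does not overlap the source map support")
  v <- trilinear(m$values, xyz, fill = 0)
  density_map(array(v, target_shape), voxel_size = target_voxel,
              origin = m$origin, label = m$label)
}

# Radial raised-cosine low-pass transfer function on the unshifted Fourier
# grid.  Unity up to 1/R - w/2, cosine falloff to zero at 1/R + w/2, with
# w spanning `width_voxels` Fourier voxels.  DC is always untouched.
lowpass_transfer <- function(d, voxel_size, resolution, width_voxels = 2) {
  f <- fft_radius(d) / (d[1] * voxel_size)       # 1/A (cubic grids)
  fc <- 1 / resolution
  w <- width_voxels / (d[1] * voxel_size)
  h <- array(0, d)
  h[f <= fc - w / 2] <- 1
  tz <- f > fc - w / 2 & f < fc + w / 2
  h[tz] <- 0.5 * (1 + cos(pi * (f[tz] - (fc - w / 2)) / w))
  h[1, 1, 1] <- 1
  h
}

#' Low-pass filter a map to a target resolution
#'
#' Fourier-space filter with a raised-cosine edge: the transfer function is
#' 1 up to 1/R - w/2 and falls as a half-cosine to 0 at 1/R + w/2, with the
#' rolloff width w spanning 2 Fourier voxels.  The soft edge suppresses the
#' real-space ringing a sharp cutoff would inject into difference maps.
#' The DC term is untouched, so the map mean is preserved.
#'
#' @param m a [density_map()].
#' @param resolution target resolution in Angstrom; must be at least twice
#'   the voxel size (Nyquist).
#' @return the filtered [density_map()].
#' @export
lowpass_filter <- function(m, resolution) {
  stopifnot(inherits(m, "density_map"))
  if (resolution < 2 * m$voxel_size)
    stop(sprintf(
      "resolution %.3g A is below Nyquist (%.3g A) for voxel size %.3g A",
      resolution, 2 * m$voxel_size, m$voxel_size))
  d <- dim(m$values)
  h <- lowpass_transfer(d, m$voxel_size, resolution)
  v <- Re(stats::fft(stats::fft(m$values) * h, inverse = TRUE)) / prod(d)
  density_map(array(v, d), m$voxel_size, m$origin, m$label)
}

#' Normalize a map to zero mean and unit standard deviation
#'
#' The mean and population standard deviation are computed over the voxels
#' selected by `region` (mask value > 0.5); the same affine transform is
#' then applied to every voxel of the map, including those outside the
#' region.
#'
#' @param m a [density_map()].
#' @param region a [volume_mask()] or `NULL` for the whole box.
#' @return the normalized [density_map()].
#' @export
normalize_map <- function(m, region = NULL) {
  stopifnot(inherits(m, "density_map"))
  v <- m$values
  sel <- if (is.null(region)) rep(TRUE, length(v)) else
    as.vector(map_values(region) > 0.5)
  if (sum(sel) < 2) stop("normalization region selects fewer than 2 voxels")
  mu <- mean(v[sel])
  sdp <- sqrt(mean((v[sel] - mu)^2))        # population sd
  if (sdp == 0) stop("zero variance in normalization region")
  density_map(array((v - mu) / sdp, dim(v)), m$voxel_size, m$origin, m$label)
}
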