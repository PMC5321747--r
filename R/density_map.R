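#' 3D density map
#'
#' The universal currency of the pipeline: a 3D scalar field on a regular
#' grid with an isotropic voxel size in Angstrom and an origin giving the
#' position of voxel (0,0,0) in Angstrom.  Values are stored in an R array
#' indexed `[x, y, z]` with x fastest in memory, which matches the on-disk
#' MRC section order (z slowest).
#'
#' @param values numeric 3D array.
#' @param voxel_size voxel edge length in Angstrom (> 0).
#' @param origin numeric length-3, position of voxel (0,0,0) in Angstrom.
#' @param label free-text provenance string.
#' @return an object of class `density_map`.
#' @export
density_map <- function(values, voxel_size = 1, origin = c(0, 0, 0),
                        label = "") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number")
  if (any(!is.finite(values)))
    stop("density map contains non-finite values")
  storage.mode(values) <- "double"
  structure(
    list(values = values, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin), label = as.character(label)[1]),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_map> %d x %d x %d voxels @ %.4g A/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g, sd %.4g\n",
              min(x$values), max(x$values), mean(x$values),
              stats::sd(x$values)))
  if (nzchar(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}

#' @export
dim.density_map <- function(x) dim(x$values)

#' @export
summary.density_map <- function(object, ...) {
  c(summary(as.vector(object$values)),
    voxel_size = object$voxel_size)
}

#' Plot a central slice of a density map
#'
#' @param x a `density_map`.
#' @param axis slicing axis, 1 (x), 2 (y) or 3 (z).
#' @param index slice index; defaults to the central voxel.
#' @param col colour palette.
#' @param ... passed to [graphics::image()].
#' @export
plot.density_map <- function(x, axis = 3, index = NULL,
                             col = grDevices::gray.colors(128), ...) {
  d <- dim(x$values)
  index <- index %||% grid_center(d)[axis]
  sl <- switch(axis,
               x$values[index, , ],
               x$values[, index, ],
               x$values[, , index])
  graphics::image(seq_len(nrow(sl)) * x$voxel_size,
                  seq_len(ncol(sl)) * x$voxel_size,
                  sl, asp = 1, xlab = "A", ylab = "A", col = col, ...)
  invisible(x)
}

#' Volume mask
#'
#' A 3D grid of weights in \[0, 1\] sharing the geometry of the map it is
#' applied to.  `role` records the intended use: a `focus` mask restricts
#' classification or scoring to a subregion, an `exclusion` mask removes a
#' region from difference analysis, an `analysis` mask delimits the voxels
#' over which statistics are computed.
#'
#' @param values numeric 3D array with values in \[0, 1\].
#' @param voxel_size voxel edge length in Angstrom.
#' @param role one of `"focus"`, `"exclusion"`, `"analysis"`.
#' @return an object of class `volume_mask`.
#' @export
volume_mask <- function(values, voxel_size = 1,
                        role = c("focus", "exclusion", "analysis")) {
  role <- match.arg(role)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (any(values < -1e-9 | values > 1 + 1e-9))
    stop("mask values must lie in [0, 1]")
  storage.mode(values) <- "double"
  values[values < 0] <- 0; values[values > 1] <- 1
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 role = role),
            class = "volume_mask")
}

#' @export
print.volume_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_mask> role=%s, %d x %d x %d, coverage %.1f%%\n",
              x$role, d[1], d[2], d[3], 100 * mean(x$values > 0.5)))
  invisible(x)
}

#' Spherical focus mask around a point
#'
#' Convenience constructor used to focus classification or difference
#' analysis on one subunit region.
#'
#' @param dim grid dimensions (length 3).
#' @param center_ang sphere centre in Angstrom (grid coordinates, origin at
#'   voxel 0).
#' @param radius_ang sphere radius in Angstrom.
#' @param voxel_size voxel size in Angstrom.
#' @param soft_edge_ang width of a cosine-tapered edge (0 = hard mask).
#' @param role mask role, see [volume_mask()].
#' @return a `volume_mask`.
#' @export
sphere_mask <- function(dim, center_ang, radius_ang, voxel_size = 1,
                        soft_edge_ang = 0, role = "focus") {
  co <- grid_coords(dim)
  r <- sqrt(colSums((t(co) - 1 - center_ang / voxel_size)^2)) * voxel_size
  v <- numeric(length(r))
  v[r <= radius_ang] <- 1
  if (soft_edge_ang > 0) {
    edge <- r > radius_ang & r < radius_ang + soft_edge_ang
    v[edge] <- 0.5 * (1 + cos(pi * (r[edge] - radius_ang) / soft_edge_ang))
  }
  volume_mask(array(v, dim), voxel_size, role = role)
}

# Coerce a density_map or bare array to a plain array.
map_values <- function(m) {
  if (inherits(m, "density_map") || inherits(m, "volume_mask")) m$values
  else if (is.array(m) && length(dim(m)) == 3L) m
  else stop("expected a density_map, volume_mask or 3D array")
}
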