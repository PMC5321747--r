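# Normalized difference-density mapping and sigma-significance
# localization of missing components between two density maps.
#
# Pipeline (fixed order): low-pass both maps to a common resolution ->
# resample the second onto the first map's grid -> optional rigid fit ->
# optional exclusion mask -> normalize both to zero mean / unit sd over
# the analysis region -> subtract -> express the difference in units of
# its own standard deviation (sigma) over the analysis region.

#' Rigid-body fit of one map onto another
#'
#' Exhaustive local search maximizing the real-space correlation over a
#' ZYZ Euler grid within `angular_range`, with the translation found by
#' FFT cross-correlation at each orientation.  Identical maps return the
#' identity.
#'
#' @param a reference [density_map()].
#' @param b moving [density_map()] (same grid as `a`).
#' @param angular_range search half-range in degrees per Euler angle.
#' @param step grid step in degrees.
#' @param max_shift translation bound in voxels.
#' @return list with `transform` (a [rigid_transform()] to apply to `b`)
#'   and `correlation`.
#' @export
rigid_fit_maps <- function(a, b, angular_range = 8, step = 2,
                           max_shift = 6) {
  stopifnot(inherits(a, "density_map"), inherits(b, "density_map"))
  if (!identical(dim(a$values), dim(b$values)))
    stop("maps must share a grid; resample first")
  angs <- seq(-angular_range, angular_range, by = step)
  grid <- list()
  for (p in angs) for (t in angs) for (s in angs)
    grid[[length(grid) + 1L]] <- rigid_transform(p, t, s)
  al <- align_pair(subtomo(b), a, angular_step = step, max_shift = max_shift,
                   angles = grid, refine = 0, subpixel = TRUE)
  list(transform = al$transform, correlation = al$score)
}

#' Normalized difference-density map between two maps
#'
#' Both maps are low-pass filtered to `resolution`, brought onto the grid
#' of `a`, optionally rigidly fitted, optionally restricted by an
#' exclusion mask (for heterogeneous regions such as variable OST
#' occupancy), normalized to zero mean and unit standard deviation over
#' the analysis region, and subtracted (a - b).  The difference is
#' expressed in sigma units: its own standard deviation over the analysis
#' region.  Super-threshold connected components are tabulated with
#' [sigma_components()].
#'
#' @param a reference [density_map()] (its grid is the common frame).
#' @param b comparison [density_map()].
#' @param resolution common filtering resolution in Angstrom.
#' @param exclusion optional [volume_mask()] of the region to exclude
#'   from both maps (mask value > 0.5 excluded).
#' @param prealigned if `TRUE` (maps share an averaging frame) the rigid
#'   fit is skipped.
#' @param threshold component threshold in sigma units (default 5).
#' @param sign which differences to tabulate: `"reduction"` (negative
#'   values of a - b: density missing from `a` relative to `b`),
#'   `"gain"` (positive values), or `"both"`.  Pass the deficient map as
#'   `a` and the reference as `b` to localize missing subunits as
#'   reductions.
#' @param min_volume minimum component size in voxels; default the number
#'   of voxels in a (1.5 nm)^3 cube at the working voxel size.
#' @param connectivity 26 (default) or 6.
#' @param localization_limit bounding-box diagonal (nm) below which a
#'   component is flagged "localized" (default 8 nm).
#' @return a `difference_result`: `diff_map` ([density_map()], sigma
#'   units), `sigma` (in normalized-intensity units), `analysis_mask`,
#'   `components` (see [sigma_components()]), `params`, and flags
#'   (`identical_maps`).
#' @export
difference_map <- function(a, b, resolution, exclusion = NULL,
                           prealigned = TRUE, threshold = 5,
                           sign = c("reduction", "gain", "both"),
                           min_volume = NULL, connectivity = 26,
                           localization_limit = 8) {
  stopifnot(inherits(a, "density_map"), inherits(b, "density_map"))
  sign <- match.arg(sign)
  if (resolution < 2 * a$voxel_size || resolution < 2 * b$voxel_size)
    stop("resolution is below the Nyquist limit of the inputs")
  af <- lowpass_filter(a, resolution)
  bf <- lowpass_filter(b, resolution)
  resampled <- FALSE
  if (!identical(dim(bf$values), dim(af$values)) ||
      abs(bf$voxel_size - af$voxel_size) > 1e-9 * af$voxel_size) {
    bf <- resample_map(bf, af$voxel_size, dim(af$values))
    resampled <- TRUE
  }
  fit <- NULL
  if (!prealigned) {
    fit <- rigid_fit_maps(af, bf)
    bf <- apply_transform(bf, fit$transform)
  }
  d <- dim(af$values)
  analysis <- array(TRUE, d)
  if (!is.null(exclusion)) {
    ev <- map_values(exclusion)
    stopifnot(identical(dim(ev), d))
    analysis <- analysis & (ev <= 0.5)
  }
  if (sum(analysis) < 100) stop("analysis region below 100 voxels")
  amask <- volume_mask(array(as.numeric(analysis), d), af$voxel_size,
                       role = "analysis")
  va <- af$values; vb <- bf$values
  norm_region <- function(v) {
    mu <- mean(v[analysis])
    sdp <- sqrt(mean((v[analysis] - mu)^2))
    if (sdp == 0) stop("zero variance in analysis region")
    (v - mu) / sdp
  }
  na <- norm_region(va); nb <- norm_region(vb)
  D <- na - nb
  mu_d <- mean(D[analysis])
  sigma <- sqrt(mean((D[analysis] - mu_d)^2))
  # after normalization both inputs have unit sd over the region, so a
  # sigma at rounding-noise level means the maps are affinely identical
  identical_maps <- sigma < 1e-8
  if (identical_maps) {
    dm <- density_map(array(0, d), af$voxel_size, af$origin,
                      label = "difference map (sigma units)")
    res <- structure(list(
      diff_map = dm, sigma = 0, analysis_mask = amask,
      components = empty_component_table(),
      fit = fit,
      params = list(resolution = resolution, threshold = threshold,
                    sign = sign, connectivity = connectivity,
                    min_volume = min_volume, resampled = resampled,
                    localization_limit = localization_limit),
      identical_maps = TRUE), class = "difference_result")
    return(res)
  }
  D[!analysis] <- 0
  dm <- density_map(array((D - mu_d) / sigma * analysis, d), af$voxel_size,
                    af$origin, label = "difference map (sigma units)")
  min_volume <- min_volume %||% max(1L, round((15 / af$voxel_size)^3))
  res <- structure(list(
    diff_map = dm, sigma = sigma, analysis_mask = amask,
    components = NULL, fit = fit,
    params = list(resolution = resolution, threshold = threshold,
                  sign = sign, connectivity = connectivity,
                  min_volume = min_volume, resampled = resampled,
                  localization_limit = localization_limit),
    identical_maps = FALSE), class = "difference_result")
  res$components <- sigma_components(res, k_sigma = threshold, sign = sign,
                                     min_volume = min_volume,
                                     connectivity = connectivity,
                                     localization_limit = localization_limit)
  res
}

empty_component_table <- function() {
  data.frame(component = integer(0), peak_sigma = numeric(0),
             volume_voxels = integer(0), volume_nm3 = numeric(0),
             cx = numeric(0), cy = numeric(0), cz = numeric(0),
             bbox_diameter_nm = numeric(0), localized = logical(0))
}

# 3D connected-component labelling (6 or 26 connectivity) of a logical
# array, by breadth-first flood fill over the selected voxels only.
label_components <- function(sel, connectivity = 26) {
  d <- dim(sel)
  idx <- which(sel)
  labels <- integer(length(idx))
  if (!length(idx)) return(list(labels = labels, idx = idx, n = 0L))
  pos <- arrayInd(idx, d)
  key <- (pos[, 3] - 1) * (d[1] * d[2]) + (pos[, 2] - 1) * d[1] + pos[, 1]
  lookup <- new.env(parent = emptyenv())
  for (j in seq_along(key)) assign(as.character(key[j]), j, envir = lookup)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  else if (connectivity != 26)
    stop("connectivity must be 6 or 26")
  n <- 0L
  for (j in seq_along(idx)) {
    if (labels[j] != 0L) next
    n <- n + 1L
    queue <- j
    labels[j] <- n
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      p <- pos[cur, ]
      for (o in seq_len(nrow(offs))) {
        q <- p + c(offs$dx[o], offs$dy[o], offs$dz[o])
        if (any(q < 1) || any(q > d)) next
        kk <- as.character((q[3] - 1) * (d[1] * d[2]) + (q[2] - 1) * d[1] + q[1])
        m <- lookup[[kk]]
        if (!is.null(m) && labels[m] == 0L) {
          labels[m] <- n
          queue <- c(queue, m)
        }
      }
    }
  }
  list(labels = labels, idx = idx, n = n)
}

#' Tabulate super-threshold connected components of a difference map
#'
#' Thresholds the sigma-unit difference map at -k (density reductions,
#' i.e. material missing from the comparison map), +k (gains) or both,
#' labels connected components, drops components smaller than
#' `min_volume`, and flags components whose bounding-box diagonal is
#' within the localization limit.
#'
#' @param d a `difference_result` from [difference_map()], or a
#'   [density_map()] already in sigma units.
#' @param k_sigma significance threshold in sigma units (> 0).
#' @param sign `"reduction"`, `"gain"` or `"both"`.
#' @param min_volume minimum component volume in voxels.
#' @param connectivity 26 (default) or 6.
#' @param localization_limit bounding-box diagonal limit in nm for the
#'   `localized` flag.
#' @return data.frame sorted by descending |peak sigma|: component id,
#'   `peak_sigma` (signed), `volume_voxels`, `volume_nm3`, centroid
#'   (`cx`, `cy`, `cz`, Angstrom in grid coordinates), `bbox_diameter_nm`,
#'   `localized`.
#' @export
sigma_components <- function(d, k_sigma = 5,
                             sign = c("reduction", "gain", "both"),
                             min_volume = 1, connectivity = 26,
                             localization_limit = 8) {
  sign <- match.arg(sign)
  if (k_sigma <= 0) stop("k_sigma must be positive")
  dm <- if (inherits(d, "difference_result")) d$diff_map else d
  stopifnot(inherits(dm, "density_map"))
  v <- dm$values
  vs <- dm$voxel_size
  sel <- switch(sign,
                reduction = v <= -k_sigma,
                gain = v >= k_sigma,
                both = abs(v) >= k_sigma)
  lab <- label_components(sel, connectivity)
  if (lab$n == 0) return(empty_component_table())
  pos <- arrayInd(lab$idx, dim(v))
  rows <- lapply(seq_len(lab$n), function(ci) {
    sub <- lab$labels == ci
    if (sum(sub) < min_volume) return(NULL)
    p <- pos[sub, , drop = FALSE]
    vals <- v[lab$idx[sub]]
    peak <- vals[which.max(abs(vals))]
    bb <- apply(p, 2, range)
    diam <- sqrt(sum(((bb[2, ] - bb[1, ] + 1) * vs)^2)) / 10   # nm
    data.frame(component = ci, peak_sigma = peak,
               volume_voxels = sum(sub),
               volume_nm3 = sum(sub) * (vs / 10)^3,
               cx = mean(p[, 1] - 1) * vs, cy = mean(p[, 2] - 1) * vs,
               cz = mean(p[, 3] - 1) * vs,
               bbox_diameter_nm = diam,
               localized = diam <= localization_limit)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_component_table())
  out <- out[order(-abs(out$peak_sigma)), , drop = FALSE]
  out$component <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' @export
print.difference_result <- function(x, ...) {
  cat("<difference_result>\n")
  if (isTRUE(x$identical_maps)) {
    cat("  identical maps: difference is identically zero\n")
    return(invisible(x))
  }
  cat(sprintf("  filtered to %.3g A, sigma = %.4g (normalized units)\n",
              x$params$resolution, x$sigma))
  cat(sprintf("  %d component(s) beyond %.3g sigma (%s, min %d voxels)\n",
              nrow(x$components), x$params$threshold, x$params$sign,
              x$params$min_volume))
  if (nrow(x$components)) {
    df <- x$components
    for (i in seq_len(nrow(df)))
      cat(sprintf(
        "    #%d: peak %+.2f sigma, %d vox (%.2f nm^3), centroid (%.0f, %.0f, %.0f) A, %s\n",
        df$component[i], df$peak_sigma[i], df$volume_voxels[i],
        df$volume_nm3[i], df$cx[i], df$cy[i], df$cz[i],
        if (df$localized[i]) "localized" else "extended"))
  }
  invisible(x)
}

#' @export
summary.difference_result <- function(object, ...) {
  list(sigma = object$sigma,
       n_components = nrow(object$components),
       peak_sigma = if (nrow(object$components))
         object$components$peak_sigma[1] else NA_real_,
       identical_maps = object$identical_maps)
}

#' Plot the central slice of a difference map
#'
#' @param x a `difference_result`.
#' @param axis,index slice selection as in [plot.density_map()].
#' @param ... passed to [graphics::image()].
#' @export
plot.difference_result <- function(x, axis = 3, index = NULL, ...) {
  plot(x$diff_map, axis = axis, index = index,
       col = grDevices::hcl.colors(128, "Blue-Red 2"), ...)
}

#' Write a component table as TSV
#'
#' @param res a `difference_result`.
#' @param path output path.
#' @export
write_components <- function(res, path) {
  write_tsv_exact(res$components, path)
}
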