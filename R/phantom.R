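# Translocon-like phantom: an analytic ground-truth density built from
# isotropic Gaussian blobs plus a membrane slab.
#
# The default geometry is a deliberate caricature of the ER membrane-
# associated ribosome: a large globular body (the ribosome) sitting on the
# cytosolic side of a membrane slab, with small blobs for the Sec61
# channel in the membrane, the TRAP subunits (alpha/beta lumenal, gamma
# cytosolic, delta at the OST-facing periphery) and the OST complex.  It
# makes no claim of structural fidelity; its purpose is a ground truth
# whose components can be switched on and off.

#' Phantom specification
#'
#' @param box_size cubic box edge in voxels.
#' @param voxel_size voxel size in Angstrom.
#' @param components data.frame with columns `name`, `x`, `y`, `z`
#'   (centre in Angstrom relative to the box centre), `sd` (Gaussian sd in
#'   Angstrom) and `amplitude`.  `NULL` selects the default
#'   translocon-like geometry.
#' @param membrane list with `z` (slab centre in Angstrom relative to the
#'   box centre), `thickness` (Angstrom) and `amplitude`; `NULL` disables
#'   the slab.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(box_size = 48, voxel_size = 5,
                         components = NULL, membrane = list(
                           z = -55, thickness = 40, amplitude = 0.6)) {
  if (is.null(components)) {
    ext <- box_size * voxel_size   # 240 A at the defaults
    components <- data.frame(
      name = c("ribosome", "sec61", "trap_ab", "trap_gamma", "trap_delta",
               "ost"),
      # x/y/z in Angstrom relative to the box centre; membrane at z ~ -55
      x = c(0, 0, 35, 55, 62, 45),
      y = c(0, 0, 30, 42, -8, -42),
      z = c(30, -52, -75, -30, -68, -60),
      sd = c(60, 14, 13, 12, 11, 18),
      amplitude = c(1, 1, 1, 1, 1, 1),
      stringsAsFactors = FALSE
    )
    half <- ext / 2 - 2 * voxel_size
    stopifnot(all(abs(components$x) < half), all(abs(components$y) < half),
              all(abs(components$z) < half))
  }
  stopifnot(is.data.frame(components),
            all(c("name", "x", "y", "z", "sd", "amplitude") %in%
                  names(components)))
  if (any(components$amplitude < 0)) stop("component amplitudes must be >= 0")
  if (any(components$sd <= 0)) stop("component sds must be positive")
  half_ext <- box_size * voxel_size / 2
  if (any(abs(components$x) >= half_ext | abs(components$y) >= half_ext |
            abs(components$z) >= half_ext))
    stop("all component centres must lie inside the box")
  structure(list(box_size = as.integer(box_size),
                 voxel_size = as.numeric(voxel_size),
                 components = components, membrane = membrane),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d^3 voxels @ %.3g A, %d components%s\n",
              x$box_size, x$voxel_size, nrow(x$components),
              if (is.null(x$membrane)) "" else " + membrane slab"))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Build a phantom density map
#'
#' Evaluates the sum of the analytic component Gaussians (optionally
#' restricted to a subset of components) plus the membrane slab on the
#' grid.  Construction is linear: omitting a component subtracts exactly
#' that component's field.
#'
#' @param spec a [phantom_spec()].
#' @param present character vector of component names to include, or
#'   `NULL` for all.  Unknown names are an error.
#' @param membrane include the membrane slab?
#' @return a [density_map()].
#' @export
build_phantom <- function(spec, present = NULL, membrane = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  comp <- spec$components
  if (!is.null(present)) {
    unknown <- setdiff(present, comp$name)
    if (length(unknown))
      stop("unknown component(s): ", paste(unknown, collapse = ", "))
    comp <- comp[comp$name %in% present, , drop = FALSE]
  }
  n <- spec$box_size
  d <- c(n, n, n)
  cc <- grid_center(d)
  ax <- (seq_len(n) - cc[1]) * spec$voxel_size   # Angstrom, centre at 0
  v <- array(0, d)
  for (i in seq_len(nrow(comp))) {
    gx <- exp(-(ax - comp$x[i])^2 / (2 * comp$sd[i]^2))
    gy <- exp(-(ax - comp$y[i])^2 / (2 * comp$sd[i]^2))
    gz <- exp(-(ax - comp$z[i])^2 / (2 * comp$sd[i]^2))
    v <- v + comp$amplitude[i] * outer(outer(gx, gy), gz)
  }
  if (membrane && !is.null(spec$membrane)) {
    mz <- spec$membrane
    # soft-edged slab: error-function profile with a 1-voxel edge
    prof <- mz$amplitude *
      (stats::pnorm((ax - (mz$z - mz$thickness / 2)) / spec$voxel_size) -
         stats::pnorm((ax - (mz$z + mz$thickness / 2)) / spec$voxel_size))
    v <- v + outer(array(1, c(n, n)), prof)
  }
  density_map(v, spec$voxel_size,
              label = "tomowedge synthetic phantom")
}

#' Focus mask around named phantom components
#'
#' A spherical (union of spheres) mask centred on the listed components,
#' with radius `k_sd` times each component's Gaussian sd.
#'
#' @param spec a [phantom_spec()].
#' @param names component names.
#' @param k_sd sphere radius in units of component sd (default 2.5).
#' @param soft_edge_ang cosine edge width in Angstrom.
#' @return a [volume_mask()] with role `"focus"`.
#' @export
component_mask <- function(spec, names, k_sd = 2.5, soft_edge_ang = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  comp <- spec$components
  unknown <- setdiff(names, comp$name)
  if (length(unknown))
    stop("unknown component(s): ", paste(unknown, collapse = ", "))
  n <- spec$box_size
  d <- c(n, n, n)
  cc <- grid_center(d)
  acc <- array(0, d)
  for (nm in names) {
    i <- match(nm, comp$name)
    ctr_ang <- c(comp$x[i], comp$y[i], comp$z[i]) +
      (cc - 1) * spec$voxel_size
    m <- sphere_mask(d, ctr_ang, k_sd * comp$sd[i], spec$voxel_size,
                     soft_edge_ang = soft_edge_ang)
    acc <- pmax(acc, m$values)
  }
  volume_mask(acc, spec$voxel_size, role = "focus")
}

# Centre of a named component in 1-based voxel coordinates.
component_center_voxel <- function(spec, name) {
  comp <- spec$components
  i <- match(name, comp$name)
  if (is.na(i)) stop("unknown component: ", name)
  cc <- grid_center(rep(spec$box_size, 3))
  c(comp$x[i], comp$y[i], comp$z[i]) / spec$voxel_size + cc
}
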