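# Missing-wedge geometry of single-axis tomography.
#
# A tilt series from tilt_min to tilt_max samples, for each tilt, a central
# plane of Fourier space perpendicular to the beam (z).  The union over the
# tilt range leaves a wedge-shaped unsampled region around the beam axis;
# for the default +/-60 degree range the missing wedge is 1/3 of Fourier
# space (measured within the Nyquist sphere).

#' Tilt-scheme specification
#'
#' @param tilt_min,tilt_max tilt range in degrees (default -60, +60).
#' @param increment angular increment between projections in degrees
#'   (default 2; recorded for provenance, the continuous-union wedge
#'   support depends only on the range).
#' @param tilt_axis `"y"` or `"x"`; the beam is along z.
#' @return an object of class `wedge_spec`.
#' @export
wedge_spec <- function(tilt_min = -60, tilt_max = 60, increment = 2,
                       tilt_axis = "y") {
  if (tilt_min >= tilt_max) stop("tilt_min must be below tilt_max")
  tilt_axis <- match.arg(tilt_axis, c("y", "x"))
  structure(list(tilt_min = as.numeric(tilt_min),
                 tilt_max = as.numeric(tilt_max),
                 increment = as.numeric(increment),
                 tilt_axis = tilt_axis),
            class = "wedge_spec")
}

#' @export
print.wedge_spec <- function(x, ...) {
  cat(sprintf("<wedge_spec> %+.1f to %+.1f deg, increment %.1f deg, axis %s\n",
              x$tilt_min, x$tilt_max, x$increment, x$tilt_axis))
  invisible(x)
}

#' Binary Fourier support induced by a tilt scheme
#'
#' A Fourier voxel is sampled iff some tilt in the range produces a central
#' plane through it.  With tilt axis y and beam z, the voxel (kx, ky, kz)
#' is sampled iff the in-plane angle of (kx, kz) measured from the kx axis
#' falls inside the (centro-symmetrized) tilt range; ky is unconstrained.
#' DC is always sampled.  The support is returned in the unshifted FFT
#' layout (DC at index \[1,1,1\]).
#'
#' @param w a [wedge_spec()] or `NULL` for full support.
#' @param box grid dimensions (scalar for cubic grids or length-3).
#' @return a logical 3D array.
#' @export
wedge_support <- function(w, box) {
  d <- if (length(box) == 1) rep(as.integer(box), 3) else as.integer(box)
  if (any(d < 8)) stop("box must be at least 8 voxels")
  if (is.null(w)) return(array(TRUE, d))
  stopifnot(inherits(w, "wedge_spec"))
  g <- fft_freq_grid(d)
  ku <- if (w$tilt_axis == "y") g$kx else g$ky   # in-plane axis
  kz <- g$kz
  # fold the direction into (-90, 90] using Friedel symmetry
  ang <- atan2(kz, ku) * 180 / pi
  ang[ang > 90] <- ang[ang > 90] - 180
  ang[ang <= -90] <- ang[ang <= -90] + 180
  # the plane acquired at tilt theta lies at in-plane angle -theta
  lo <- -w$tilt_max; hi <- -w$tilt_min
  inside <- (ang >= lo & ang <= hi) | (ang - 180 >= lo & ang - 180 <= hi) |
    (ang + 180 >= lo & ang + 180 <= hi)
  # Friedel closure: k is known whenever -k was measured.  Only the
  # self-aliased Nyquist planes of even-sized grids can be asymmetric here.
  inside <- inside | inside[c(1, d[1]:2), c(1, d[2]:2), c(1, d[3]:2)]
  inside[1, 1, 1] <- TRUE
  inside
}

#' Apply a Fourier support (wedge filter) to a map
#'
#' Multiplies the spectrum by the support and transforms back.  Applying
#' the same binary support twice equals applying it once (projection).
#'
#' @param m a [density_map()] or 3D array.
#' @param support logical or numeric 3D array in the unshifted FFT layout.
#' @return filtered map, same class as `m`.
#' @export
apply_wedge <- function(m, support) {
  vol <- map_values(m)
  d <- dim(vol)
  stopifnot(identical(dim(support), d))
  v <- Re(stats::fft(stats::fft(vol) * as.numeric(support),
                     inverse = TRUE)) / prod(d)
  v <- array(v, d)
  if (inherits(m, "density_map")) density_map(v, m$voxel_size, m$origin, m$label)
  else v
}

# Rotate a binary Fourier support into another frame.  The support is
# centred (DC to floor(N/2)), rotated with trilinear interpolation about
# the same centre, centro-symmetrized and re-binarized at 0.5.
rotate_support <- function(support, t) {
  d <- dim(support)
  s <- fftshift3(array(as.numeric(support), d))
  r <- apply_transform(s, rigid_transform(t$euler[1], t$euler[2], t$euler[3]))
  r <- fftshift3(r, inverse = TRUE)
  # Friedel symmetrization: in the unshifted layout -k lives at N+2-i (i>1)
  r <- (r + r[c(1, d[1]:2), c(1, d[2]:2), c(1, d[3]:2)]) / 2
  out <- r >= 0.5
  out[1, 1, 1] <- TRUE
  out
}

#' Fraction of Fourier space missing from a support
#'
#' Counted within the Nyquist sphere (|k| <= N/2), where the analytic
#' single-axis result for a symmetric +/-t tilt range is (90 - t) / 90,
#' i.e. 1/3 for +/-60 degrees.  DC is excluded from the count.
#'
#' @param support logical 3D array (unshifted layout).
#' @return missing fraction in \[0, 1\].
#' @export
missing_fraction <- function(support) {
  d <- dim(support)
  r <- fft_radius(d)
  inside <- r <= min(d) / 2 & r > 0
  mean(!support[inside])
}
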