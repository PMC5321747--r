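# Fourier shell correlation (FSC) resolution estimation.
#
# Two conventions are supported: half-set FSC between maps averaged from
# the two halves of a dataset (resolution read at FSC = 0.5) and Fourier
# shell cross-resolution against an external reference (read at 0.33).

#' Fourier shell correlation of two maps
#'
#' Per shell s of width `shell_width` Fourier voxels:
#' FSC(s) = Re(sum F_a conj(F_b)) / sqrt(sum |F_a|^2 sum |F_b|^2),
#' over the coefficients whose radius falls in the shell.
#'
#' @param a,b [density_map()] objects of identical shape and voxel size.
#' @param shell_width shell width in Fourier voxels (default 1).
#' @return an `fsc_curve` data.frame with columns `freq` (shell centre in
#'   1/Angstrom), `fsc`, `n_coef`; attributes `voxel_size` and
#'   `thresholds` (0.5 half-set, 0.33 cross).
#' @export
fsc <- function(a, b, shell_width = 1) {
  stopifnot(inherits(a, "density_map"), inherits(b, "density_map"))
  if (!identical(dim(a$values), dim(b$values)))
    stop("maps differ in shape")
  if (abs(a$voxel_size - b$voxel_size) > 1e-6 * a$voxel_size)
    stop("maps differ in voxel size")
  d <- dim(a$values)
  A <- stats::fft(a$values); B <- stats::fft(b$values)
  r <- fft_radius(d)
  nyq <- min(d) / 2
  shell <- floor(r / shell_width + 0.5)          # shell index, 0 = DC
  smax <- floor(nyq / shell_width)
  keep <- shell <= smax
  num <- Re(A * Conj(B))
  pa <- abs(A)^2; pb <- abs(B)^2
  grp <- factor(shell[keep], levels = 0:smax)   # numeric level order
  sn <- as.vector(tapply(num[keep], grp, sum))
  sa <- as.vector(tapply(pa[keep], grp, sum))
  sb <- as.vector(tapply(pb[keep], grp, sum))
  nc <- as.vector(table(grp))
  corr <- ifelse(sa > 0 & sb > 0, sn / sqrt(sa * sb), NA_real_)
  out <- data.frame(
    freq = (0:smax) * shell_width / (d[1] * a$voxel_size),
    fsc = corr,
    n_coef = nc
  )
  attr(out, "voxel_size") <- a$voxel_size
  attr(out, "thresholds") <- c(half_set = 0.5, cross = 0.33)
  class(out) <- c("fsc_curve", "data.frame")
  out
}

#' Resolution at an FSC threshold
#'
#' Locates the first crossing of the curve below `threshold` by linear
#' interpolation in frequency and reports 1/frequency in Angstrom.  The DC
#' shell is ignored.  If the curve never drops below the threshold the
#' Nyquist resolution (2 x voxel size) is returned with attribute
#' `crossed = FALSE`.
#'
#' @param curve an `fsc_curve` from [fsc()].
#' @param threshold FSC threshold in (0, 1); 0.5 for half-set maps, 0.33
#'   for cross-resolution against an external reference.
#' @return resolution in Angstrom, with attribute `crossed`.
#' @export
resolution_at <- function(curve, threshold = 0.5) {
  stopifnot(inherits(curve, "fsc_curve"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  cv <- curve[curve$freq > 0 & is.finite(curve$fsc), , drop = FALSE]
  if (nrow(cv) == 0) stop("empty FSC curve")
  vs <- attr(curve, "voxel_size")
  below <- which(cv$fsc < threshold)
  if (length(below) == 0)
    return(structure(2 * vs, crossed = FALSE))
  i <- below[1]
  if (i == 1) {
    f <- cv$freq[1]
  } else {
    f0 <- cv$freq[i - 1]; f1 <- cv$freq[i]
    y0 <- cv$fsc[i - 1]; y1 <- cv$fsc[i]
    f <- f0 + (y0 - threshold) / (y0 - y1) * (f1 - f0)
  }
  structure(1 / f, crossed = TRUE)
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("<fsc_curve> %d shells to %.4g 1/A\n", nrow(x) - 1,
              max(x$freq)))
  r05 <- resolution_at(x, 0.5); r033 <- resolution_at(x, 0.33)
  cat(sprintf("  resolution: %.3g A (FSC=0.5%s), %.3g A (FSC=0.33%s)\n",
              r05, if (attr(r05, "crossed")) "" else ", no crossing",
              r033, if (attr(r033, "crossed")) "" else ", no crossing"))
  invisible(x)
}

#' Plot an FSC curve
#'
#' @param x an `fsc_curve`.
#' @param thresholds horizontal guide lines.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fsc_curve <- function(x, thresholds = c(0.5, 0.33), ...) {
  graphics::plot(x$freq, x$fsc, type = "l", xlab = "spatial frequency (1/A)",
                 ylab = "FSC", ylim = c(min(0, min(x$fsc, na.rm = TRUE)), 1),
                 ...)
  graphics::abline(h = thresholds, lty = 3, col = "grey40")
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}

#' Write an FSC curve as TSV
#'
#' @param curve an `fsc_curve`.
#' @param path output path.
#' @export
write_fsc <- function(curve, path) {
  write_tsv_exact(as.data.frame(curve), path)
}

#' Split particles into half sets
#'
#' Deterministic even/odd split after a seeded shuffle; the two halves
#' differ in size by at most one particle.
#'
#' @param n number of particles (>= 2), or a list whose length is used.
#' @param seed integer seed.
#' @return list with integer index vectors `even` and `odd`.
#' @export
halfset_split <- function(n, seed = 1) {
  if (is.list(n) || length(n) > 1) n <- length(n)
  if (n < 2) stop("need at least 2 particles to split")
  perm <- with_seed(seed, sample.int(n))
  list(even = sort(perm[seq(1, n, by = 2)]),
       odd = sort(perm[seq(2, n, by = 2)]))
}
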