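# Wedge-aware scoring, exhaustive rigid alignment, wedge-compensated
# averaging and template matching.

# Raised-cosine band-pass transfer on the unshifted Fourier grid.
# `band` = c(low_res_A, high_res_A): frequencies between 1/low_res and
# 1/high_res pass; each edge rolls off over 2 Fourier voxels.  Inf on the
# low-resolution side keeps everything down to (but excluding) DC.
bandpass_transfer <- function(d, voxel_size, band) {
  if (is.null(band)) return(array(1, d))
  f <- fft_radius(d) / (d[1] * voxel_size)
  w <- 2 / (d[1] * voxel_size)
  h <- array(1, d)
  if (is.finite(band[1])) {          # high-pass edge at 1/low_res
    fl <- 1 / band[1]
    h[f <= fl - w / 2] <- 0
    tz <- f > fl - w / 2 & f < fl + w / 2
    h[tz] <- 0.5 * (1 - cos(pi * (f[tz] - (fl - w / 2)) / w))
  }
  fh <- 1 / band[2]                  # low-pass edge at 1/high_res
  tz <- f > fh - w / 2 & f < fh + w / 2
  h[tz] <- h[tz] * 0.5 * (1 + cos(pi * (f[tz] - (fh - w / 2)) / w))
  h[f >= fh + w / 2] <- 0
  h
}

#' Constrained cross-correlation of two volumes
#'
#' Pearson-type correlation restricted to the Fourier coefficients inside
#' the intersection of the two sampling supports (the region both volumes
#' have actually measured), after real-space masking.  The mean is removed
#' by excluding the DC coefficient of the masked volumes; the variances
#' are the Fourier power inside the intersection.  With full supports and
#' a unit mask this equals the plain Pearson correlation of voxel values.
#' The score is invariant to affine intensity changes a*x + b (a > 0) of
#' either input.
#'
#' @param a,b [density_map()] objects or 3D arrays of equal shape.
#' @param support_a,support_b logical Fourier supports (unshifted layout)
#'   or `NULL` for full sampling.
#' @param mask real-space [volume_mask()] or array, or `NULL`.
#' @return correlation in \[-1, 1\].
#' @export
constrained_cc <- function(a, b, support_a = NULL, support_b = NULL,
                           mask = NULL) {
  va <- map_values(a); vb <- map_values(b)
  if (!identical(dim(va), dim(vb))) stop("volumes differ in shape")
  d <- dim(va)
  if (!is.null(mask)) {
    mv <- map_values(mask)
    stopifnot(identical(dim(mv), d))
    va <- va * mv; vb <- vb * mv
  }
  va <- va - mean(va); vb <- vb - mean(vb)
  S <- if (is.null(support_a)) array(TRUE, d) else support_a
  if (!is.null(support_b)) S <- S & support_b
  S[1, 1, 1] <- FALSE                       # DC carries no contrast
  if (!any(S)) stop("disjoint wedge supports: empty Fourier intersection")
  A <- stats::fft(va); B <- stats::fft(vb)
  num <- sum(Re(A * Conj(B))[S])
  den <- sqrt(sum(abs(A[S])^2) * sum(abs(B[S])^2))
  if (den == 0) stop("zero power inside the constrained support")
  max(-1, min(1, num / den))
}

# Euler-angle grid covering SO(3) at roughly `step` degrees, as a list of
# zero-shift rigid transforms.  For theta in {0, 180} the (phi, psi) pair
# is degenerate and psi is fixed at 0.  `inplane = TRUE` restricts to
# rotations about z.
euler_grid <- function(step, inplane = FALSE) {
  phis <- seq(0, 360 - step, by = step)
  if (inplane)
    return(lapply(phis, function(p) rigid_transform(phi = p)))
  thetas <- seq(0, 180, by = step)
  out <- list()
  for (th in thetas) {
    psis <- if (th %in% c(0, 180)) 0 else seq(0, 360 - step, by = step)
    for (ph in phis) for (ps in psis)
      out[[length(out) + 1L]] <- rigid_transform(ph, th, ps)
  }
  out
}

# Local grid around transform t0: all +/- {0, step} offsets on each angle.
local_euler_grid <- function(t0, step) {
  offs <- c(0, -step, step)
  out <- list()
  for (dp in offs) for (dt in offs) for (ds in offs)
    out[[length(out) + 1L]] <- rigid_transform(
      t0$euler[1] + dp, max(0, min(180, t0$euler[2] + dt)), t0$euler[3] + ds)
  out
}

# Signed wrapped shift values for each FFT index of axis length n.
shift_values <- function(n) fft_freq_int(n)

# FFT of the reference rotated by `rot`, memoized in `cache` (an
# environment) keyed by the Euler triple.  Shared across particles during
# averaging, where every particle scores the same orientation grid.
rotated_ref_fft <- function(vref, rot, cache = NULL, cache_max = 256L) {
  if (is.null(cache)) {
    vr <- apply_transform(vref, rot)
    return(stats::fft(vr - mean(vr)))
  }
  key <- sprintf("%.4f_%.4f_%.4f", rot$euler[1] %% 360, rot$euler[2],
                 rot$euler[3] %% 360)
  got <- cache[[key]]
  if (!is.null(got)) return(got)
  vr <- apply_transform(vref, rot)
  R <- stats::fft(vr - mean(vr))
  if (length(ls(cache)) < cache_max) cache[[key]] <- R
  R
}

# Score one candidate orientation: reference rotated by `rot`, filtered to
# the particle's measured domain, FFT cross-correlation over shifts.
# Returns the best in-range shift and its normalized score.
score_orientation <- function(P, vref, rot, filt, d, max_shift,
                              shift_ok, subpixel = TRUE, cache = NULL) {
  R <- rotated_ref_fft(vref, rot, cache) * filt
  pw <- sqrt(sum(abs(P)^2) * sum(abs(R)^2))
  if (pw == 0) return(list(score = -Inf, shift = c(0, 0, 0)))
  cc <- Re(stats::fft(P * Conj(R), inverse = TRUE)) / prod(d)
  cc <- array(cc, d) / pw * prod(d)
  cc[!shift_ok] <- -Inf
  i <- which.max(cc)                       # ties: lowest linear index
  idx <- arrayInd(i, d)
  sx <- shift_values(d[1])[idx[1]]; sy <- shift_values(d[2])[idx[2]]
  sz <- shift_values(d[3])[idx[3]]
  sh <- c(sx, sy, sz)
  if (subpixel) {
    # parabolic peak interpolation per axis (wrapped neighbours)
    for (ax in 1:3) {
      im <- idx; ip <- idx
      im[ax] <- (idx[ax] - 2) %% d[ax] + 1
      ip[ax] <- idx[ax] %% d[ax] + 1
      y0 <- cc[idx[1], idx[2], idx[3]]
      ym <- cc[im[1], im[2], im[3]]; yp <- cc[ip[1], ip[2], ip[3]]
      den <- ym - 2 * y0 + yp
      if (is.finite(ym) && is.finite(yp) && den < 0)
        sh[ax] <- sh[ax] + 0.5 * (ym - yp) / den
    }
  }
  list(score = cc[i], shift = sh)
}

#' Align one subtomogram against a reference
#'
#' Exhaustive search over an orientation grid; for each orientation the
#' reference is rotated, restricted to the particle's wedge support and
#' band-pass, and the translation is found by FFT cross-correlation
#' limited to `max_shift` voxels per axis.  The coarse grid is followed by
#' `refine` local half-step refinements.  Deterministic: exact score ties
#' resolve to the lowest grid index.
#'
#' @param s a [subtomo()] (or bare [density_map()], full wedge assumed).
#' @param ref reference [density_map()].
#' @param angular_step coarse grid step in degrees.
#' @param max_shift maximum translation per axis in voxels.
#' @param bandpass c(low_res_A, high_res_A) band limits; `NULL` for none.
#' @param angles optional explicit list of [rigid_transform()] candidate
#'   rotations replacing the built-in coarse grid.
#' @param inplane restrict the built-in grid to rotations about z.
#' @param refine number of local half-step refinement passes.
#' @param subpixel parabolic sub-voxel peak interpolation of the shift.
#' @param ref_cache optional environment memoizing rotated-reference
#'   spectra across particles (used internally by [iterative_average()]).
#' @return list with `transform` (a [rigid_transform()] mapping the
#'   particle frame to the reference frame) and `score`.
#' @export
align_pair <- function(s, ref, angular_step = 20, max_shift = 6,
                       bandpass = NULL, angles = NULL, inplane = FALSE,
                       refine = 2, subpixel = TRUE, ref_cache = NULL) {
  if (inherits(s, "density_map")) s <- subtomo(s)
  stopifnot(inherits(s, "subtomo"), inherits(ref, "density_map"))
  if (angular_step <= 0) stop("angular_step must be positive")
  d <- dim(s$map$values)
  vs <- s$map$voxel_size
  W <- if (is.null(s$wedge)) array(TRUE, d) else wedge_support(s$wedge, d)
  filt <- as.numeric(W) * bandpass_transfer(d, vs, bandpass)
  dim(filt) <- d
  filt[1, 1, 1] <- 0                       # remove DC
  vp <- s$map$values - mean(s$map$values)
  P <- stats::fft(vp) * filt
  shift_ok <- outer(outer(abs(shift_values(d[1])) <= max_shift,
                          abs(shift_values(d[2])) <= max_shift),
                    abs(shift_values(d[3])) <= max_shift)
  grid <- angles %||% euler_grid(angular_step, inplane = inplane)
  best <- list(score = -Inf, rot = grid[[1]], shift = c(0, 0, 0))
  for (g in grid) {
    r <- score_orientation(P, ref$values, g, filt, d, max_shift, shift_ok,
                           subpixel, cache = ref_cache)
    if (r$score > best$score)
      best <- list(score = r$score, rot = g, shift = r$shift)
  }
  step <- angular_step
  for (k in seq_len(refine)) {
    step <- step / 2
    for (g in local_euler_grid(best$rot, step)) {
      r <- score_orientation(P, ref$values, g, filt, d, max_shift, shift_ok,
                             subpixel, cache = ref_cache)
      if (r$score > best$score)
        best <- list(score = r$score, rot = g, shift = r$shift)
    }
  }
  gen <- rigid_transform(best$rot$euler[1], best$rot$euler[2],
                         best$rot$euler[3], best$shift)
  list(transform = invert_transform(gen), score = max(-1, min(1, best$score)))
}

# Rotate each particle (and its wedge support) into the reference frame.
# Returns real-space maps and binary supports as n x Nvox matrices.
align_stack <- function(subtomos, poses) {
  n <- length(subtomos)
  d <- dim(subtomos[[1]]$map$values)
  nv <- prod(d)
  real <- matrix(0, n, nv)
  supp <- matrix(FALSE, n, nv)
  for (i in seq_len(n)) {
    s <- subtomos[[i]]
    p <- poses[[i]]
    real[i, ] <- as.vector(apply_transform(s$map$values, p))
    W <- if (is.null(s$wedge)) array(TRUE, d) else wedge_support(s$wedge, d)
    supp[i, ] <- as.vector(
      if (is.null(s$wedge) ||
          all(abs(p$euler) < 1e-9)) W else rotate_support(W, p))
  }
  list(real = real, supp = supp, dim = d)
}

# Wedge-compensated Fourier-space average of pose-aligned particles:
# A = sum_i F_i / max(sum_i W_i, eps), eps = eps_frac * n.
wedge_average <- function(subtomos, poses, eps_frac = 0.1) {
  stk <- align_stack(subtomos, poses)
  wedge_average_stack(stk, eps_frac)
}

wedge_average_stack <- function(stk, eps_frac = 0.1, rows = NULL) {
  rows <- rows %||% seq_len(nrow(stk$real))
  d <- stk$dim
  n <- length(rows)
  Fsum <- array(0 + 0i, d)
  Wsum <- array(0, d)
  for (i in rows) {
    Fsum <- Fsum + stats::fft(array(stk$real[i, ], d))
    Wsum <- Wsum + stk$supp[i, ]
  }
  A <- Fsum / pmax(Wsum, eps_frac * n)
  array(Re(stats::fft(A, inverse = TRUE)) / prod(d), d)
}

#' Iterative alignment and wedge-compensated averaging
#'
#' Classic subtomogram averaging loop: in each iteration every particle is
#' aligned to the current reference ([align_pair()]), then a new reference
#' is formed as the wedge-compensated Fourier average
#' A = sum_i R_i(F_i) / max(sum_i R_i(W_i), 0.1 n), where R_i rotates
#' particle i (and its wedge support W_i) into the reference frame.
#'
#' @param subtomos non-empty list of [subtomo()].
#' @param ref0 starting reference [density_map()].
#' @param n_iter number of iterations.
#' @param angular_schedule numeric vector of coarse grid steps per
#'   iteration (recycled), or `NULL` to keep the particles' current poses
#'   (average-only).
#' @param max_shift,bandpass,inplane,refine,subpixel passed to
#'   [align_pair()].
#' @return list with `average` ([density_map()]), `poses`, `scores`,
#'   and `score_history` (mean score per iteration).
#' @export
iterative_average <- function(subtomos, ref0, n_iter = 3,
                              angular_schedule = 20, max_shift = 6,
                              bandpass = NULL, inplane = FALSE, refine = 1,
                              subpixel = TRUE) {
  if (length(subtomos) == 0) stop("empty particle list")
  n <- length(subtomos)
  d <- dim(subtomos[[1]]$map$values)
  ref <- ref0
  poses <- lapply(subtomos, function(s) s$pose)
  scores <- rep(NA_real_, n)
  hist <- numeric(0)
  for (it in seq_len(n_iter)) {
    if (!is.null(angular_schedule)) {
      step <- angular_schedule[(it - 1) %% length(angular_schedule) + 1]
      cache <- new.env(parent = emptyenv())
      for (i in seq_len(n)) {
        a <- align_pair(subtomos[[i]], ref, angular_step = step,
                        max_shift = max_shift, bandpass = bandpass,
                        inplane = inplane, refine = refine,
                        subpixel = subpixel, ref_cache = cache)
        poses[[i]] <- a$transform
        scores[i] <- a$score
      }
      hist <- c(hist, mean(scores))
    }
    avg <- wedge_average(subtomos, poses)
    ref <- density_map(avg, subtomos[[1]]$map$voxel_size,
                       label = sprintf("wedge-compensated average (n=%d)", n))
  }
  list(average = ref, poses = poses, scores = scores, score_history = hist)
}

#' Template matching in a tomogram
#'
#' Locally normalized, wedge-filtered cross-correlation of a template over
#' all positions and a grid of orientations.  For every position the best
#' orientation is kept; peaks are extracted after non-maximum suppression
#' with an exclusion radius equal to the template radius.
#'
#' @param tomogram [density_map()] to search.
#' @param template [density_map()], not larger than the tomogram.
#' @param w [wedge_spec()] applied to the template, or `NULL`.
#' @param angles list of candidate rotations (default: identity only).
#' @param n_peaks number of peaks to return.
#' @return a data.frame (`peak_list`): x, y, z (1-based voxel position of
#'   the particle centre), phi, theta, psi, score; sorted by descending
#'   score.
#' @export
template_match <- function(tomogram, template, w = NULL, angles = NULL,
                           n_peaks = 10) {
  stopifnot(inherits(tomogram, "density_map"), inherits(template, "density_map"))
  D <- dim(tomogram$values); dt <- dim(template$values)
  if (any(dt > D)) stop("template larger than tomogram")
  angles <- angles %||% list(rigid_transform())
  tv <- tomogram$values
  N <- prod(D)
  Tf <- stats::fft(tv)
  T2f <- stats::fft(tv^2)
  # spherical correlation mask of the template footprint
  rt <- min(dt) / 2
  ct <- grid_center(dt)
  co <- grid_coords(dt)
  msk <- sqrt(colSums((t(co) - ct)^2)) <= rt
  n_m <- sum(msk)
  mask_t <- array(0, dt); mask_t[msk] <- 1
  embed <- function(block) {
    # place the template block with its centre voxel at index (1,1,1),
    # wrapping negative offsets (ifftshift-style embedding)
    out <- array(0, D)
    ix <- ((seq_len(dt[1]) - ct[1]) %% D[1]) + 1L
    iy <- ((seq_len(dt[2]) - ct[2]) %% D[2]) + 1L
    iz <- ((seq_len(dt[3]) - ct[3]) %% D[3]) + 1L
    out[ix, iy, iz] <- block
    out
  }
  Mf <- stats::fft(embed(mask_t))
  # local mean and sd of the tomogram under the mask footprint
  locmean <- Re(stats::fft(Tf * Conj(Mf), inverse = TRUE)) / N / n_m
  locvar <- Re(stats::fft(T2f * Conj(Mf), inverse = TRUE)) / N / n_m -
    locmean^2
  locsd <- sqrt(pmax(locvar, 0))
  Wt <- if (is.null(w)) NULL else wedge_support(w, dt)
  best_score <- array(-Inf, D)
  best_ang <- array(1L, D)
  for (ai in seq_along(angles)) {
    tt <- apply_transform(template$values, angles[[ai]])
    if (!is.null(Wt)) tt <- apply_wedge(tt, Wt)
    tt[!msk] <- 0
    tt[msk] <- tt[msk] - mean(tt[msk])
    nrm <- sqrt(sum(tt^2))
    if (nrm == 0) next
    tt <- tt / nrm
    num <- Re(stats::fft(Tf * Conj(stats::fft(embed(tt))), inverse = TRUE)) / N
    sc <- num / (sqrt(n_m) * pmax(locsd, 1e-12))
    upd <- sc > best_score
    best_score[upd] <- sc[upd]
    best_ang[upd] <- ai
  }
  ord <- order(best_score, decreasing = TRUE)
  picked <- integer(0)
  pos <- arrayInd(ord, D)
  for (j in seq_along(ord)) {
    if (length(picked) >= n_peaks) break
    p <- pos[j, ]
    if (length(picked)) {
      prev <- pos[picked, , drop = FALSE]
      dd <- sqrt(rowSums(sweep(prev, 2, p)^2))
      if (any(dd < rt)) next
    }
    picked <- c(picked, j)
  }
  sel <- ord[picked]
  ang <- t(sapply(best_ang[sel], function(ai) angles[[ai]]$euler))
  out <- data.frame(
    x = pos[picked, 1], y = pos[picked, 2], z = pos[picked, 3],
    phi = ang[, 1], theta = ang[, 2], psi = ang[, 3],
    score = best_score[sel]
  )
  rownames(out) <- NULL
  class(out) <- c("peak_list", "data.frame")
  out
}
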