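# Internal numerical helpers shared across the pipeline.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded internals
#' (noise draws, k-means restarts, half-set shuffles) never perturb the
#' global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and an index, staying inside the
# 32-bit signed range.  Simple LCG-style mixing; collisions across distinct
# (seed, index) pairs are astronomically unlikely at the scales used here.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) * 2654435761 + as.double(index) * 40503) %% 2147483629
  as.integer(s %/% 1)
}

# Integer DFT sample frequencies for axis length n (cycles per full axis),
# in the unshifted FFT layout: 0, 1, ..., then the negative branch.
fft_freq_int <- function(n) {
  q <- seq_len(n) - 1L
  q[q > n %/% 2] <- q[q > n %/% 2] - n
  # for even n the single Nyquist element sits at -n/2
  if (n %% 2 == 0) q[n %/% 2 + 1L] <- -(n %/% 2)
  q
}

# Three arrays of integer frequencies on a dim-`d` grid (unshifted layout).
fft_freq_grid <- function(d) {
  qx <- fft_freq_int(d[1]); qy <- fft_freq_int(d[2]); qz <- fft_freq_int(d[3])
  list(
    kx = array(rep(qx, times = d[2] * d[3]), dim = d),
    ky = array(rep(rep(qy, each = d[1]), times = d[3]), dim = d),
    kz = array(rep(qz, each = d[1] * d[2]), dim = d)
  )
}

# Radial frequency magnitude in cycles per full axis (cubic grids).
fft_radius <- function(d) {
  g <- fft_freq_grid(d)
  sqrt(g$kx^2 + g$ky^2 + g$kz^2)
}

# Centre a spectrum (DC moved to floor(N/2), 0-based) or undo it.
fftshift3 <- function(a, inverse = FALSE) {
  d <- dim(a)
  idx <- lapply(d, function(n) {
    h <- n %/% 2
    if (inverse) c((h + 1L):n, 1:h) else c((n - h + 1L):n, 1:(n - h))
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# Trilinear interpolation of volume `vol` at fractional 1-based coordinates
# `xyz` (m x 3 matrix).  Points outside the grid get `fill`.
trilinear <- function(vol, xyz, fill = 0) {
  d <- dim(vol)
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  # clamp the base cell so the gather is always valid; on the upper
  # boundary the fractional part becomes 1, interpolating to the edge
  x0c <- pmin(pmax(floor(x), 1), d[1] - 1)
  y0c <- pmin(pmax(floor(y), 1), d[2] - 1)
  z0c <- pmin(pmax(floor(z), 1), d[3] - 1)
  fxc <- ifelse(ok, x - x0c, 0)
  fyc <- ifelse(ok, y - y0c, 0)
  fzc <- ifelse(ok, z - z0c, 0)
  nxy <- d[1] * d[2]
  i000 <- x0c + (y0c - 1) * d[1] + (z0c - 1) * nxy
  v000 <- vol[i000];          v100 <- vol[i000 + 1]
  v010 <- vol[i000 + d[1]];   v110 <- vol[i000 + d[1] + 1]
  v001 <- vol[i000 + nxy];    v101 <- vol[i000 + nxy + 1]
  v011 <- vol[i000 + d[1] + nxy]; v111 <- vol[i000 + d[1] + nxy + 1]
  w <- (1 - fxc) * (1 - fyc) * (1 - fzc) * v000 +
    fxc * (1 - fyc) * (1 - fzc) * v100 +
    (1 - fxc) * fyc * (1 - fzc) * v010 +
    fxc * fyc * (1 - fzc) * v110 +
    (1 - fxc) * (1 - fyc) * fzc * v001 +
    fxc * (1 - fyc) * fzc * v101 +
    (1 - fxc) * fyc * fzc * v011 +
    fxc * fyc * fzc * v111
  w[!ok] <- fill
  w
}

# 1-based voxel coordinates of the rotation centre: floor(N/2) in 0-based
# indexing on each axis.
grid_center <- function(d) floor(d / 2) + 1

# Cartesian product of 1-based voxel indices as an m x 3 double matrix.
grid_coords <- function(d) {
  cbind(
    rep(seq_len(d[1]), times = d[2] * d[3]),
    rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    rep(seq_len(d[3]), each = d[1] * d[2])
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
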