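# Simulation of tilt-limited, noisy subtomograms with known ground truth.
#
# Particles are simulated directly in the subtomogram frame:
# rotate/shift the phantom, impose the missing-wedge Fourier support, add
# white Gaussian noise at a controlled SNR.  The SNR is defined as signal
# variance over noise variance, with the signal variance measured inside
# the particle region (voxels above 10% of the wedge-filtered signal
# maximum) so that empty box padding does not deflate it.

#' Subtomogram
#'
#' A density map plus its acquisition wedge and mutable alignment state.
#'
#' @param map a [density_map()].
#' @param wedge a [wedge_spec()] (or `NULL` for full sampling).
#' @param pose current pose estimate, a [rigid_transform()] mapping the
#'   particle frame to the reference frame.
#' @param score last alignment score in \[-1, 1\], or `NA`.
#' @param class_label optional class id.
#' @return an object of class `subtomo`.
#' @export
subtomo <- function(map, wedge = NULL, pose = rigid_transform(),
                    score = NA_real_, class_label = NA_integer_) {
  stopifnot(inherits(map, "density_map"))
  if (!is.na(score) && (score < -1 - 1e-9 || score > 1 + 1e-9))
    stop("score must lie in [-1, 1]")
  structure(list(map = map, wedge = wedge, pose = pose, score = score,
                 class_label = class_label),
            class = "subtomo")
}

#' @export
print.subtomo <- function(x, ...) {
  d <- dim(x$map$values)
  cat(sprintf("<subtomo> %d^3 voxels, score %s, class %s\n", d[1],
              format(x$score, digits = 3), format(x$class_label)))
  invisible(x)
}

#' Dataset specification
#'
#' @param n_particles number of particles.
#' @param occupancy named numeric vector of presence probabilities per
#'   phantom component; components not listed are always present.
#' @param snr signal-variance / noise-variance ratio (> 0; `Inf` disables
#'   noise).
#' @param seed integer master seed; a fixed seed reproduces the dataset
#'   bit-exactly.
#' @param rotations `"so3"` for uniform orientations, `"inplane"` for
#'   rotations about z only (membrane-attached geometry), `"none"`.
#' @param max_shift translations drawn uniformly in +/- `max_shift` voxels
#'   per axis.
#' @return an object of class `dataset_spec`.
#' @export
dataset_spec <- function(n_particles, occupancy = c(ost = 0.58),
                         snr = 0.7, seed = 1, rotations = c("so3", "inplane",
                                                            "none"),
                         max_shift = 3) {
  rotations <- match.arg(rotations)
  if (any(occupancy < 0 | occupancy > 1))
    stop("occupancy probabilities must lie in [0, 1]")
  if (snr <= 0) stop("snr must be positive")
  structure(list(n_particles = as.integer(n_particles),
                 occupancy = occupancy, snr = snr,
                 seed = as.integer(seed), rotations = rotations,
                 max_shift = as.numeric(max_shift)),
            class = "dataset_spec")
}

#' Simulate one subtomogram
#'
#' Applies the rigid transform to the phantom, filters with the missing
#' wedge support, and adds white Gaussian noise with variance equal to the
#' in-particle signal variance divided by `snr`.
#'
#' @param phantom a [density_map()] (the noise-free particle).
#' @param t a [rigid_transform()] taking the reference (phantom) frame to
#'   the particle frame.
#' @param w a [wedge_spec()] or `NULL` for full sampling.
#' @param snr signal/noise variance ratio; `Inf` disables noise.
#' @param seed integer noise seed.
#' @return a [subtomo()]; its `pose` is the identity (unaligned), the
#'   generating transform is the caller's to record.
#' @export
simulate_subtomogram <- function(phantom, t = rigid_transform(), w = NULL,
                                 snr = Inf, seed = 0) {
  stopifnot(inherits(phantom, "density_map"))
  if (snr <= 0) stop("snr must be positive")
  d <- dim(phantom$values)
  sig <- apply_transform(phantom, t)
  if (!is.null(w)) sig <- apply_wedge(sig, wedge_support(w, d))
  v <- sig$values
  if (is.finite(snr)) {
    region <- abs(v) > 0.1 * max(abs(v))
    svar <- if (any(region)) stats::var(v[region]) else stats::var(as.vector(v))
    noise_sd <- sqrt(svar / snr)
    v <- v + with_seed(seed, array(stats::rnorm(prod(d), sd = noise_sd), d))
  }
  subtomo(density_map(v, phantom$voxel_size, phantom$origin,
                      label = sprintf("simulated particle (seed %d)", seed)),
          wedge = w)
}

#' Generate a synthetic subtomogram dataset
#'
#' Draws per-particle component presence flags (independent Bernoulli per
#' component), rigid poses and noise seeds from the master seed, and
#' simulates each particle.  A fixed seed reproduces the dataset
#' bit-exactly, and each particle can be regenerated alone from its
#' recorded row.
#'
#' @param spec a [dataset_spec()].
#' @param phantom_spec a [phantom_spec()].
#' @param w a [wedge_spec()] or `NULL`.
#' @return a list with `subtomos` (list of [subtomo()]) and
#'   `ground_truth` (data.frame: particle, phi, theta, psi, dx, dy, dz,
#'   one logical column `present_<name>` per component, noise_seed).
#' @export
generate_dataset <- function(spec, phantom_spec, w = wedge_spec()) {
  stopifnot(inherits(spec, "dataset_spec"), inherits(phantom_spec, "phantom_spec"))
  n <- spec$n_particles
  comp_names <- phantom_spec$components$name
  occ <- rep(1, length(comp_names)); names(occ) <- comp_names
  if (length(spec$occupancy)) {
    unknown <- setdiff(names(spec$occupancy), comp_names)
    if (length(unknown))
      stop("occupancy for unknown component(s): ",
           paste(unknown, collapse = ", "))
    occ[names(spec$occupancy)] <- spec$occupancy
  }
  if (n == 0) {
    gt <- data.frame(particle = integer(0), phi = numeric(0),
                     theta = numeric(0), psi = numeric(0), dx = numeric(0),
                     dy = numeric(0), dz = numeric(0), noise_seed = integer(0))
    for (nm in comp_names) gt[[paste0("present_", nm)]] <- logical(0)
    return(list(subtomos = list(), ground_truth = gt))
  }
  draws <- with_seed(spec$seed, {
    pres <- sapply(comp_names, function(nm)
      stats::runif(n) < occ[nm])
    pres <- matrix(pres, nrow = n,
                   dimnames = list(NULL, comp_names))
    rots <- switch(spec$rotations,
                   so3 = random_rotations(n),
                   inplane = lapply(stats::runif(n, 0, 360), function(a)
                     rigid_transform(phi = a)),
                   none = replicate(n, rigid_transform(), simplify = FALSE))
    shifts <- matrix(stats::runif(3 * n, -spec$max_shift, spec$max_shift),
                     ncol = 3)
    if (spec$max_shift == 0) shifts[] <- 0
    seeds <- sapply(seq_len(n), function(i) derive_seed(spec$seed, i))
    list(pres = pres, rots = rots, shifts = shifts, seeds = seeds)
  })
  # memoize phantoms per distinct presence pattern
  cache <- new.env(parent = emptyenv())
  get_phantom <- function(flags) {
    key <- paste(as.integer(flags), collapse = "")
    if (is.null(cache[[key]]))
      cache[[key]] <- build_phantom(phantom_spec,
                                    present = comp_names[flags])
    cache[[key]]
  }
  subtomos <- vector("list", n)
  for (i in seq_len(n)) {
    t_i <- rigid_transform(draws$rots[[i]]$euler[1], draws$rots[[i]]$euler[2],
                           draws$rots[[i]]$euler[3], draws$shifts[i, ])
    subtomos[[i]] <- simulate_subtomogram(get_phantom(draws$pres[i, ]), t_i,
                                          w, spec$snr, draws$seeds[i])
  }
  gt <- data.frame(
    particle = seq_len(n),
    phi = sapply(draws$rots, function(r) r$euler[1]),
    theta = sapply(draws$rots, function(r) r$euler[2]),
    psi = sapply(draws$rots, function(r) r$euler[3]),
    dx = draws$shifts[, 1], dy = draws$shifts[, 2], dz = draws$shifts[, 3],
    noise_seed = as.integer(draws$seeds)
  )
  for (nm in comp_names) gt[[paste0("present_", nm)]] <- draws$pres[, nm]
  list(subtomos = subtomos, ground_truth = gt)
}

#' Write / read a ground-truth table as TSV
#'
#' Numeric columns are serialized with full precision (`format = "%.17g"`)
#' so the table round-trips unchanged.
#'
#' @param gt ground-truth data.frame as returned by [generate_dataset()].
#' @param path TSV file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_ground_truth <- function(gt, path) {
  write_tsv_exact(gt, path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

# Deterministic TSV writer: full-precision numerics, no locale dependence.
write_tsv_exact <- function(df, path) {
  fmt <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  })
  out <- do.call(paste, c(fmt, sep = "\t"))
  con <- file(path, "wb")   # binary: fixed "\n" across platforms
  on.exit(close(con), add = TRUE)
  writeLines(c(paste(names(df), collapse = "\t"), out), con, sep = "\n")
  invisible(path)
}

#' Write a dataset to disk (one MRC per particle + ground-truth TSV)
#'
#' @param ds dataset as returned by [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ds$subtomos))
    write_mrc(ds$subtomos[[i]]$map,
              file.path(dir, sprintf("particle_%04d.mrc", i)))
  write_ground_truth(ds$ground_truth, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}
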