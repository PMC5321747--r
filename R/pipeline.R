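# Orchestration: configuration handling and the two end-to-end workflows
# (synthetic ground-truth run; reproduction run on user-supplied EMDB maps).

default_config <- function() {
  list(
    seed = 1,
    phantom = list(box_size = 48, voxel_size = 5),
    wedge = list(tilt_min = -60, tilt_max = 60, increment = 2),
    dataset = list(n_particles = 200, snr = 0.7,
                   occupancy = list(ost = 0.58, trap_ab = 1, trap_gamma = 1,
                                    trap_delta = 1),
                   trap_occupancy_among_ost = 0.76,
                   rotations = "inplane", max_shift = 3),
    align = list(n_iter = 2, angular_step = 15, max_shift = 5,
                 bandpass = c(50, 15), inplane = TRUE, refine = 1),
    classify = list(k = 2, n_components = 4, focus_k_sd = 2.5),
    fsc = list(shell_width = 1),
    diffmap = list(resolution = 15, threshold = 5, connectivity = 26,
                   min_volume = NULL),
    output = list(write_particles = FALSE)
  )
}

# Validate a user config against the default schema: unknown keys are
# rejected, known keys override defaults.
merge_config <- function(user, defaults = default_config(), path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section '", path, "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(if (nzchar(path)) paste0(path, "."), unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      merge_config(user[[k]], defaults[[k]],
                   if (nzchar(path)) paste(path, k, sep = ".") else k)
    else user[[k]]
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), validates it against the known
#' schema -- unknown keys are rejected -- and fills unset values from the
#' defaults.
#'
#' @param config path to a YAML file, a list, or `NULL` for defaults.
#' @return validated config list.
#' @export
load_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  merge_config(config)
}

write_resolved_config <- function(cfg, dir) {
  p <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, p)
  hash <- unname(tools::md5sum(p))
  writeLines(hash, file.path(dir, "config.md5"))
  hash
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the synthetic end-to-end workflow
#'
#' Generates a translocon-like dataset with known occupancy mixture,
#' aligns the particles by iterative wedge-compensated averaging,
#' classifies them in two focused rounds (OST presence, then TRAP
#' presence among the OST-containing class), averages the relevant
#' classes, estimates half-set and cross resolutions, and computes the
#' sigma-thresholded difference map between the TRAP-lacking and
#' TRAP-containing class averages.  Fully reproducible from the seed:
#' identical seeds give byte-identical output tables.
#'
#' @param config a config list / YAML path (see [load_config()]).
#' @param dir run directory for outputs (created; default a tempdir).
#' @return (invisibly) a list with the dataset ground truth, poses,
#'   classification, FSC curves, difference result and the run directory.
#' @export
run_synthetic_end_to_end <- function(config = NULL, dir = tempfile("tomorun")) {
  cfg <- load_config(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_resolved_config(cfg, dir)
  logf <- file(file.path(dir, "run.log"), "w")
  on.exit(close(logf), add = TRUE)
  stage <- "setup"
  result <- list(dir = dir)
  tryCatch({
    stage <- "simulate"
    pspec <- phantom_spec(cfg$phantom$box_size, cfg$phantom$voxel_size)
    w <- wedge_spec(cfg$wedge$tilt_min, cfg$wedge$tilt_max,
                    cfg$wedge$increment)
    occ <- unlist(cfg$dataset$occupancy)
    dspec <- dataset_spec(cfg$dataset$n_particles, occupancy = occ,
                          snr = cfg$dataset$snr, seed = cfg$seed,
                          rotations = cfg$dataset$rotations,
                          max_shift = cfg$dataset$max_shift)
    ds <- generate_trap_dataset(dspec, pspec, w,
                                cfg$dataset$trap_occupancy_among_ost)
    write_ground_truth(ds$ground_truth, file.path(dir, "ground_truth.tsv"))
    if (isTRUE(cfg$output$write_particles))
      write_dataset(ds, file.path(dir, "particles"))
    log_line(logf, "simulate: %d particles, snr %.3g, occupancy ost=%.2f",
             length(ds$subtomos), cfg$dataset$snr, occ[["ost"]])
    n <- length(ds$subtomos)

    stage <- "align"
    ref0 <- lowpass_filter(build_phantom(pspec), 50)
    av <- iterative_average(ds$subtomos, ref0, n_iter = cfg$align$n_iter,
                            angular_schedule = cfg$align$angular_step,
                            max_shift = cfg$align$max_shift,
                            bandpass = cfg$align$bandpass,
                            inplane = identical(cfg$dataset$rotations,
                                                "inplane"),
                            refine = cfg$align$refine)
    poses <- av$poses
    pose_df <- data.frame(
      particle = seq_len(n),
      phi = sapply(poses, function(p) p$euler[1]),
      theta = sapply(poses, function(p) p$euler[2]),
      psi = sapply(poses, function(p) p$euler[3]),
      dx = sapply(poses, function(p) p$shift[1]),
      dy = sapply(poses, function(p) p$shift[2]),
      dz = sapply(poses, function(p) p$shift[3]),
      score = av$scores
    )
    write_tsv_exact(pose_df, file.path(dir, "poses.tsv"))
    write_mrc(av$average, file.path(dir, "average_all.mrc"))
    log_line(logf, "align: %d iterations, mean score %.4f", cfg$align$n_iter,
             mean(av$scores))

    stage <- "classify"
    rounds <- list(
      list(focus = component_mask(pspec, "ost", cfg$classify$focus_k_sd),
           k = cfg$classify$k, keep = "present",
           n_components = cfg$classify$n_components),
      list(focus = component_mask(pspec, c("trap_ab", "trap_gamma",
                                           "trap_delta"),
                                  cfg$classify$focus_k_sd),
           k = cfg$classify$k, keep = "present",
           n_components = cfg$classify$n_components)
    )
    cl <- classify_pipeline(ds$subtomos, poses, rounds,
                            seed = derive_seed(cfg$seed, 1001))
    write_classification(cl, n, file.path(dir, "classes.tsv"))
    r1 <- cl$rounds[[1]]
    r2 <- if (length(cl$rounds) >= 2) cl$rounds[[2]] else NULL
    if (isTRUE(cl$degenerate) || is.null(r2) || is.null(r2$result)) {
      log_line(logf,
               "classify: degenerate (too few particles for a full two-round sort)")
    } else {
      log_line(logf,
               "classify: round1 OST+ %.1f%% (n=%d), round2 TRAP- %.1f%% (n=%d)",
               100 * r1$present_fraction, length(r1$classified),
               100 * (1 - r2$present_fraction), length(r2$classified))
    }

    stage <- "average"
    trap_plus <- cl$final
    trap_minus <- if (is.null(r2)) integer(0) else
      setdiff(r2$classified, cl$final)
    stk <- align_stack(ds$subtomos, poses)
    vs <- cfg$phantom$voxel_size
    avg_plus <- density_map(wedge_average_stack(stk, rows = trap_plus), vs,
                            label = "class average: OST+ TRAP+")
    write_mrc(avg_plus, file.path(dir, "average_trap_plus.mrc"))
    avg_minus <- if (length(trap_minus) >= 1) {
      am <- density_map(wedge_average_stack(stk, rows = trap_minus), vs,
                        label = "class average: OST+ TRAP-")
      write_mrc(am, file.path(dir, "average_trap_minus.mrc"))
      am
    } else NULL
    log_line(logf, "average: TRAP+ n=%d, TRAP- n=%d", length(trap_plus),
             length(trap_minus))

    stage <- "fsc"
    curve <- NULL; res05 <- NA_real_
    if (length(trap_plus) >= 2) {
      hs <- halfset_split(trap_plus, seed = derive_seed(cfg$seed, 2002))
      h1 <- density_map(wedge_average_stack(stk, rows = trap_plus[hs$even]), vs)
      h2 <- density_map(wedge_average_stack(stk, rows = trap_plus[hs$odd]), vs)
      curve <- fsc(h1, h2, shell_width = cfg$fsc$shell_width)
      write_fsc(curve, file.path(dir, "fsc_halfset.tsv"))
      grDevices::png(file.path(dir, "fsc_halfset.png"), 600, 480)
      plot(curve, main = "half-set FSC (TRAP+ class)")
      grDevices::dev.off()
      res05 <- resolution_at(curve, 0.5)
    }
    phant <- build_phantom(pspec)
    cross <- fsc(avg_plus, phant, shell_width = cfg$fsc$shell_width)
    write_fsc(cross, file.path(dir, "fsc_cross.tsv"))
    res033 <- resolution_at(cross, 0.33)
    log_line(logf, "fsc: half-set %.3g A (FSC=0.5), cross %.3g A (FSC=0.33)",
             res05, res033)

    stage <- "diffmap"
    diff <- NULL
    if (!is.null(avg_minus)) {
      diff <- difference_map(avg_minus, avg_plus,
                             resolution = cfg$diffmap$resolution,
                             prealigned = TRUE,
                             threshold = cfg$diffmap$threshold,
                             sign = "reduction",
                             min_volume = cfg$diffmap$min_volume,
                             connectivity = cfg$diffmap$connectivity)
      write_mrc(diff$diff_map, file.path(dir, "diff_sigma.mrc"))
      write_components(diff, file.path(dir, "diff_components.tsv"))
      grDevices::png(file.path(dir, "diff_sigma.png"), 600, 600)
      plot(diff, main = "difference map (sigma units), central slice")
      grDevices::dev.off()
      log_line(logf, "diffmap: %d component(s) beyond %.3g sigma, peak %.2f",
               nrow(diff$components), cfg$diffmap$threshold,
               if (nrow(diff$components)) diff$components$peak_sigma[1] else NA)
    } else {
      log_line(logf, "diffmap: skipped (TRAP- class empty)")
    }

    result <- list(dir = dir, config = cfg, ground_truth = ds$ground_truth,
                   poses = poses, scores = av$scores, classification = cl,
                   average = av$average, average_trap_plus = avg_plus,
                   average_trap_minus = avg_minus,
                   fsc_halfset = curve, resolution_halfset = res05,
                   fsc_cross = cross, resolution_cross = res033,
                   difference = diff)
    invisible(result)
  }, error = function(e) {
    log_line(logf, "FAILED at stage '%s': %s", stage, conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Generate the two-level occupancy dataset used by the synthetic workflow
#'
#' OST presence is Bernoulli(`occupancy["ost"]`); among OST-containing
#' particles the whole TRAP complex (alpha/beta, gamma, delta blobs
#' jointly) is present with probability `trap_among_ost`, emulating a
#' translocon population that loses TRAP as a unit.  OST-lacking
#' particles keep TRAP.
#'
#' @param spec a [dataset_spec()]; its `occupancy` entry for `ost` is
#'   used, TRAP components are driven by `trap_among_ost`.
#' @param phantom_spec a [phantom_spec()].
#' @param w a [wedge_spec()].
#' @param trap_among_ost probability that an OST-containing particle also
#'   has TRAP.
#' @return as [generate_dataset()].
#' @export
generate_trap_dataset <- function(spec, phantom_spec, w = wedge_spec(),
                                  trap_among_ost = 0.76) {
  ds <- generate_dataset(spec, phantom_spec, w)
  n <- spec$n_particles
  if (n == 0) return(ds)
  trap_cols <- intersect(c("present_trap_ab", "present_trap_gamma",
                           "present_trap_delta"), names(ds$ground_truth))
  ost <- ds$ground_truth$present_ost
  trap_present <- with_seed(derive_seed(spec$seed, 999),
                            stats::runif(n) < trap_among_ost)
  trap_present[!ost] <- TRUE
  for (cl in trap_cols) ds$ground_truth[[cl]] <- trap_present
  # re-simulate the particles whose composition changed
  comp_names <- phantom_spec$components$name
  trap_names <- c("trap_ab", "trap_gamma", "trap_delta")
  for (i in which(!trap_present)) {
    row <- ds$ground_truth[i, ]
    flags <- sapply(comp_names, function(nm) row[[paste0("present_", nm)]])
    t_i <- rigid_transform(row$phi, row$theta, row$psi,
                           c(row$dx, row$dy, row$dz))
    ph <- build_phantom(phantom_spec,
                        present = setdiff(comp_names[flags], character(0)))
    ds$subtomos[[i]] <- simulate_subtomogram(ph, t_i, w, spec$snr,
                                             row$noise_seed)
  }
  ds
}

#' Difference-map reproduction on user-supplied EMDB maps
#'
#' Runs the normalized difference-density procedure on two downloaded
#' maps (no network access inside the tool): filter both to a common
#' resolution, resample onto the first map's grid (logged when voxel
#' sizes differ), optionally exclude a region (e.g. the heterogeneous OST
#' lobe), normalize and subtract, and report super-threshold components.
#'
#' @param map_a path to the query map (e.g. a subunit-deficient average).
#' @param map_b path to the reference map.
#' @param resolution common filtering resolution in Angstrom (default 15).
#' @param exclusion_mask optional path to an MRC mask to exclude.
#' @param threshold sigma threshold (default 5).
#' @param prealigned skip the rigid fit (default FALSE).
#' @param dir output directory, or `NULL` for no files.
#' @return the `difference_result`.
#' @export
run_emdb_reproduction <- function(map_a, map_b, resolution = 15,
                                  exclusion_mask = NULL, threshold = 5,
                                  prealigned = FALSE, dir = NULL) {
  missing_files <- c(map_a, map_b)[!file.exists(c(map_a, map_b))]
  if (length(missing_files))
    stop("map file(s) not found: ", paste(missing_files, collapse = ", "),
         " (download the required EMDB accessions first)")
  a <- read_mrc(map_a)
  b <- read_mrc(map_b)
  if (abs(a$voxel_size - b$voxel_size) > 1e-6)
    message(sprintf("voxel sizes differ (%.4g vs %.4g A): resampling onto %s",
                    a$voxel_size, b$voxel_size, basename(map_a)))
  excl <- if (!is.null(exclusion_mask)) {
    em <- read_mrc(exclusion_mask)
    volume_mask(pmin(pmax(em$values, 0), 1), em$voxel_size,
                role = "exclusion")
  } else NULL
  res <- difference_map(a, b, resolution = resolution, exclusion = excl,
                        prealigned = prealigned, threshold = threshold,
                        sign = "reduction")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_mrc(res$diff_map, file.path(dir, "diff_sigma.mrc"))
    write_components(res, file.path(dir, "diff_components.tsv"))
  }
  print(res)
  invisible(res)
}
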