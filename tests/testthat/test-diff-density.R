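# Normalized difference-density mapping and sigma-component analysis.

test_that("difference map localizes a planted deletion to one component", {
  spec <- fx_spec()
  full <- build_phantom(spec)
  dless <- build_phantom(spec,
                         present = setdiff(spec$components$name, "trap_delta"))
  res <- difference_map(dless, full, resolution = 15, threshold = 5)
  expect_equal(nrow(res$components), 1)
  expect_lt(res$components$peak_sigma[1], -5)
  expect_true(res$components$localized[1])
  ctr_true <- tomowedge:::component_center_voxel(spec, "trap_delta")
  ctr_found <- c(res$components$cx[1], res$components$cy[1],
                 res$components$cz[1]) / spec$voxel_size + 1
  expect_lt(sqrt(sum((ctr_found - ctr_true)^2)), 1)
  # sigma-unit construction: sd of the map over the analysis region is 1
  expect_equal(sd(as.vector(res$diff_map$values)), 1, tolerance = 1e-3)
})

test_that("difference map is antisymmetric and affine-invariant", {
  spec <- fx_spec_small()
  a <- build_phantom(spec)
  b <- build_phantom(spec, present = setdiff(spec$components$name, "ost"))
  r_ab <- difference_map(a, b, resolution = 20, sign = "both")
  r_ba <- difference_map(b, a, resolution = 20, sign = "both")
  expect_lt(max(abs(r_ab$diff_map$values + r_ba$diff_map$values)), 1e-6)

  aff <- density_map(0.3 * a$values - 40, a$voxel_size)
  r_id <- difference_map(aff, a, resolution = 20)
  expect_true(r_id$identical_maps)
  expect_true(all(r_id$diff_map$values == 0))
  expect_equal(nrow(r_id$components), 0)
})

test_that("exclusion masks remove a region from the analysis", {
  spec <- fx_spec()
  full <- build_phantom(spec)
  # b lacks both Sec61 and TRAP-delta (well separated); masking out the
  # Sec61 region leaves only the TRAP-delta reduction
  b <- build_phantom(spec, present = setdiff(spec$components$name,
                                             c("sec61", "trap_delta")))
  r_unmasked <- difference_map(b, full, resolution = 15, threshold = 5)
  expect_gte(nrow(r_unmasked$components), 2)
  excl <- component_mask(spec, "sec61", k_sd = 2.5)
  excl <- volume_mask(excl$values, excl$voxel_size, role = "exclusion")
  r_masked <- difference_map(b, full, resolution = 15, threshold = 5,
                             exclusion = excl)
  expect_equal(nrow(r_masked$components), 1)
  ctr_true <- tomowedge:::component_center_voxel(spec, "trap_delta")
  ctr_found <- c(r_masked$components$cx[1], r_masked$components$cy[1],
                 r_masked$components$cz[1]) / spec$voxel_size + 1
  expect_lt(sqrt(sum((ctr_found - ctr_true)^2)), 1.5)
})

test_that("sigma thresholding is monotone and sorts by significance", {
  v <- array(0, c(24, 24, 24))
  v[4:6, 4:6, 4:6] <- -8      # strong compact reduction
  v[18:20, 18:20, 4:6] <- -6  # weaker one, 20+ voxels away
  dm <- density_map(v, 5)
  tb <- sigma_components(dm, k_sigma = 5, sign = "reduction", min_volume = 1)
  expect_equal(nrow(tb), 2)
  expect_equal(tb$peak_sigma, c(-8, -6))
  expect_true(all(tb$localized))

  # zero map -> empty table; threshold above extremum -> empty table
  expect_equal(nrow(sigma_components(density_map(array(0, c(16, 16, 16)), 5),
                                     5)), 0)
  expect_equal(nrow(sigma_components(dm, k_sigma = 9, min_volume = 1)), 0)

  # lowering the threshold never decreases the captured voxel count
  vox <- sapply(c(7, 5, 3, 1), function(k)
    sum(sigma_components(dm, k_sigma = k, min_volume = 1)$volume_voxels))
  expect_true(all(diff(vox) >= 0))

  # connectivity: corner-touching blocks merge under 26 but not 6
  v2 <- array(0, c(16, 16, 16))
  v2[4:5, 4:5, 4:5] <- -7
  v2[6:7, 6:7, 6:7] <- -7
  d2 <- density_map(v2, 5)
  expect_equal(nrow(sigma_components(d2, 5, min_volume = 1,
                                     connectivity = 26)), 1)
  expect_equal(nrow(sigma_components(d2, 5, min_volume = 1,
                                     connectivity = 6)), 2)

  # min_volume drops small speckle
  v3 <- array(0, c(16, 16, 16)); v3[8, 8, 8] <- -10
  expect_equal(nrow(sigma_components(density_map(v3, 5), 5, min_volume = 2)),
               0)
})

test_that("rigid map fitting recovers small planted rotations", {
  ph <- fx_phantom_small()
  f0 <- rigid_fit_maps(ph, ph, angular_range = 2, step = 2)
  expect_equal(f0$correlation, 1, tolerance = 1e-6)
  expect_lt(max(abs(f0$transform$shift)), 0.5)

  rot <- rigid_transform(phi = 4)
  b <- apply_transform(ph, rot)
  fit <- rigid_fit_maps(ph, b, angular_range = 6, step = 1, max_shift = 3)
  # transform maps b back onto a: about -4 degrees about z
  recovered <- -fit$transform$euler[["phi"]] %% 360
  expect_lt(min(abs(c(recovered - 4, recovered - 364))), 1.01)
})

test_that("independent noise alone does not produce significant components", {
  spec <- fx_spec_small()
  full <- build_phantom(spec)
  w <- fx_wedge()
  violations <- 0
  for (i in 1:20) {
    s1 <- simulate_subtomogram(full, rigid_transform(), w, 2, 5000 + i)
    s2 <- simulate_subtomogram(full, rigid_transform(), w, 2, 6000 + i)
    r <- difference_map(s1$map, s2$map, resolution = 20, threshold = 5,
                        sign = "both", min_volume = 27)
    if (nrow(r$components) > 0) violations <- violations + 1
  }
  expect_lte(violations, 1)
})

test_that("planted-deletion significance decays with snr", {
  spec <- fx_spec_small()
  full <- build_phantom(spec)
  dless <- build_phantom(spec,
                         present = setdiff(spec$components$name, "trap_delta"))
  w <- fx_wedge()
  peak_at_snr <- function(snr) {
    mean(sapply(1:5, function(i) {
      n <- 8
      subs_f <- lapply(seq_len(n), function(j)
        simulate_subtomogram(full, rigid_transform(), w, snr,
                             10000 + 100 * i + j)$map$values)
      subs_d <- lapply(seq_len(n), function(j)
        simulate_subtomogram(dless, rigid_transform(), w, snr,
                             20000 + 100 * i + j)$map$values)
      af <- density_map(Reduce(`+`, subs_f) / n, spec$voxel_size)
      ad <- density_map(Reduce(`+`, subs_d) / n, spec$voxel_size)
      r <- difference_map(ad, af, resolution = 20, threshold = 3,
                          sign = "reduction", min_volume = 1)
      if (nrow(r$components)) -min(r$components$peak_sigma) else 0
    }))
  }
  peaks <- sapply(c(8, 1, 0.125), peak_at_snr)
  expect_true(all(diff(peaks) < 0))
})
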