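# Constrained correlation, pairwise alignment, wedge-compensated
# averaging and template matching.

test_that("constrained correlation reduces to Pearson at full support", {
  set.seed(10)
  for (i in 1:200) {
    a <- array(rnorm(512), c(8, 8, 8))
    b <- array(rnorm(512), c(8, 8, 8))
    expect_equal(constrained_cc(a, b), cor(as.vector(a), as.vector(b)),
                 tolerance = 1e-6)
  }
  a <- array(rnorm(512), c(8, 8, 8))
  expect_equal(constrained_cc(a, a), 1, tolerance = 1e-6)
  expect_equal(constrained_cc(a, -a), -1, tolerance = 1e-6)
})

test_that("constrained correlation is affine-invariant and wedge-aware", {
  set.seed(11)
  a <- array(rnorm(24^3), c(24, 24, 24))
  b <- array(rnorm(24^3), c(24, 24, 24))
  r0 <- constrained_cc(a, b)
  expect_equal(constrained_cc(2.7 * a + 3, b), r0, tolerance = 1e-9)
  expect_equal(constrained_cc(a, 0.4 * b - 11), r0, tolerance = 1e-9)

  # disjoint supports error
  d <- c(16, 16, 16)
  s1 <- array(FALSE, d); s1[2, 1, 1] <- TRUE
  s2 <- array(FALSE, d); s2[1, 2, 1] <- TRUE
  expect_error(constrained_cc(a[1:16, 1:16, 1:16], b[1:16, 1:16, 1:16],
                              s1, s2), "disjoint")

  # restricting to a support only uses those coefficients: correlation of
  # a map with its wedge-filtered self is 1 inside the wedge
  ph <- fx_phantom_small()
  sup <- wedge_support(fx_wedge(), dim(ph$values)[1])
  wph <- apply_wedge(ph, sup)
  expect_equal(constrained_cc(ph, wph, sup, sup), 1, tolerance = 1e-6)
})

test_that("alignment recovers planted shifts exactly and poses within a step", {
  blob <- fx_blob()
  w <- fx_wedge()
  # noiseless integer shifts, compact object: exact recovery
  for (sh in list(c(3, -2, 5), c(-4, 0, 2))) {
    s <- simulate_subtomogram(blob, rigid_transform(shift = sh), w, Inf, 1)
    al <- align_pair(s, blob, angles = list(rigid_transform()),
                     max_shift = 6, refine = 0, subpixel = FALSE)
    expect_identical(-al$transform$shift, as.numeric(sh))
    expect_gt(al$score, 0.99)
  }

  # noiseless copy, identity truth on the grid
  ph <- fx_phantom_small()
  s0 <- simulate_subtomogram(ph, rigid_transform(), w, Inf, 1)
  al0 <- align_pair(s0, ph, angular_step = 30, inplane = TRUE, refine = 0,
                    max_shift = 2, subpixel = FALSE)
  expect_equal(al0$transform$euler[["phi"]] %% 360, 0)
  expect_equal(al0$transform$shift, c(0, 0, 0))

  # aligning against a rotated reference returns the composed transform
  rot <- rigid_transform(phi = 60)
  ref_rot <- apply_transform(ph, rot)
  s1 <- simulate_subtomogram(ph, rigid_transform(phi = 15), w, Inf, 1)
  al1 <- align_pair(s1, ref_rot, angular_step = 15, inplane = TRUE,
                    refine = 0, max_shift = 2)
  # particle frame -> rotated-ref frame should be ~ +45 degrees about z
  expect_equal(al1$transform$euler[["phi"]] %% 360, 45, tolerance = 1e-6)
})

test_that("scores are invariant to affine intensity changes of the input", {
  ph <- fx_phantom_small()
  w <- fx_wedge()
  s <- simulate_subtomogram(ph, rigid_transform(phi = 30, shift = c(1, 0, -1)),
                            w, 1, 5)
  al_a <- align_pair(s, ph, angular_step = 30, inplane = TRUE, refine = 0)
  s2 <- s
  s2$map$values <- 3 * s$map$values + 17
  al_b <- align_pair(s2, ph, angular_step = 30, inplane = TRUE, refine = 0)
  expect_equal(al_b$score, al_a$score, tolerance = 1e-9)
  expect_equal(al_b$transform$euler, al_a$transform$euler)
})

test_that("wedge-compensated averaging satisfies its limiting cases", {
  ph <- fx_phantom_small()
  w <- fx_wedge()
  # single noiseless particle, identity pose: average equals the particle
  s <- simulate_subtomogram(ph, rigid_transform(), w, Inf, 1)
  av1 <- iterative_average(list(s), ph, n_iter = 1, angular_schedule = NULL)
  expect_lt(max(abs(av1$average$values - s$map$values)) /
              max(abs(s$map$values)), 1e-5)

  # identical wedges + identity poses: equals plain mean in the pass band
  ds <- generate_dataset(dataset_spec(6, occupancy = c(), snr = 1, seed = 3,
                                      rotations = "none", max_shift = 0),
                         fx_spec_small(), w)
  poses <- replicate(6, rigid_transform(), simplify = FALSE)
  avg <- tomowedge:::wedge_average(ds$subtomos, poses)
  plain <- Reduce(`+`, lapply(ds$subtomos, function(x) x$map$values)) / 6
  sup <- wedge_support(w, dim(ph$values)[1])
  inband <- apply_wedge(plain, sup)
  expect_lt(max(abs(apply_wedge(avg, sup) - inband)), 1e-8 * max(abs(inband)))
})

test_that("averaging more particles does not hurt agreement with the truth", {
  ph <- fx_phantom_small()
  ds <- generate_dataset(dataset_spec(32, occupancy = c(), snr = 0.5,
                                      seed = 9, rotations = "so3",
                                      max_shift = 2),
                         fx_spec_small(), fx_wedge())
  poses <- gt_poses(ds$ground_truth)
  avg16 <- tomowedge:::wedge_average(ds$subtomos[1:16], poses[1:16])
  avg32 <- tomowedge:::wedge_average(ds$subtomos, poses)
  singles <- sapply(1:16, function(i)
    constrained_cc(apply_transform(ds$subtomos[[i]]$map$values, poses[[i]]),
                   ph$values))
  cc16 <- constrained_cc(avg16, ph$values)
  cc32 <- constrained_cc(avg32, ph$values)
  expect_gt(cc16, max(singles))          # averaging gain
  expect_gte(cc32, cc16 - 0.01)          # no loss when doubling n
  r16 <- resolution_at(fsc(density_map(avg16, 7.5), ph), 0.33)
  r32 <- resolution_at(fsc(density_map(avg32, 7.5), ph), 0.33)
  expect_lte(r32, r16 + 1e-9)            # cross-resolution monotone in n
})

test_that("alignment score improves from a blurred start and then stabilizes", {
  ds <- generate_dataset(dataset_spec(8, occupancy = c(), snr = 1, seed = 21,
                                      rotations = "inplane", max_shift = 2),
                         fx_spec_small(), fx_wedge())
  # de-novo start: average of unaligned particles (blurred reference)
  ref0 <- density_map(
    Reduce(`+`, lapply(ds$subtomos, function(s) s$map$values)) / 8, 7.5)
  av <- iterative_average(ds$subtomos, ref0, n_iter = 3,
                          angular_schedule = 30, max_shift = 3,
                          bandpass = c(200, 20), inplane = TRUE, refine = 1)
  h <- av$score_history
  expect_true(all(diff(h) > -1e-3))
})

test_that("template matching finds planted particles and rejects pure noise", {
  blob <- fx_blob()
  tmpl <- resample_map(blob, 7.5, c(16, 16, 16))
  D <- c(48, 48, 48)
  truth <- rbind(c(12, 12, 12), c(36, 14, 30), c(24, 38, 22), c(38, 38, 38),
                 c(12, 30, 34))
  plant <- function(noise_sd, seed) {
    set.seed(seed)
    tomo <- array(rnorm(prod(D), sd = noise_sd), D)
    tv <- tmpl$values
    ct <- floor(dim(tv) / 2) + 1
    for (r in seq_len(nrow(truth))) {
      for (i in 1:16) for (j in 1:16) for (k in 1:16) {
        q <- truth[r, ] + c(i, j, k) - ct
        if (all(q >= 1 & q <= D))
          tomo[q[1], q[2], q[3]] <- tomo[q[1], q[2], q[3]] + tv[i, j, k]
      }
    }
    density_map(tomo, 7.5)
  }
  # clean planted match: exact position, score ~ 1
  pk0 <- template_match(plant(1e-6, 1), tmpl, n_peaks = 1)
  top0 <- as.numeric(pk0[1, c("x", "y", "z")])
  expect_true(any(apply(truth, 1, function(p) all(p == top0))))
  expect_gt(pk0$score[1], 0.98)

  # snr ~ 1: all five planted particles within 2 voxels
  sig_sd <- sd(tmpl$values)
  pk <- template_match(plant(sig_sd, 2), tmpl, w = fx_wedge(), n_peaks = 5)
  found <- sapply(seq_len(nrow(truth)), function(r)
    min(sqrt(colSums((t(as.matrix(pk[, c("x", "y", "z")])) - truth[r, ])^2))))
  expect_true(all(found <= 2))

  # pure noise scores strictly below the planted case (paired seed)
  set.seed(2)
  noise_only <- density_map(array(rnorm(prod(D), sd = sig_sd), D), 7.5)
  pk_noise <- template_match(noise_only, tmpl, w = fx_wedge(), n_peaks = 1)
  expect_lt(pk_noise$score[1], pk$score[1])
})
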