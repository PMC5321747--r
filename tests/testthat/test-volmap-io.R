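# MRC input/output and geometric map operations.

test_that("MRC write/read round-trips volumes losslessly", {
  d <- c(16, 16, 16)
  m0 <- density_map(array(0, d), voxel_size = 2.62)
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(m0, f)
  r0 <- read_mrc(f)
  expect_identical(r0$values, m0$values)
  expect_equal(r0$voxel_size, 2.62, tolerance = 1e-4)

  # arbitrary float values: exact after one float32 truncation
  set.seed(1)
  m1 <- density_map(array(rnorm(prod(d)), d), voxel_size = 3.42,
                    origin = c(-10, 5.5, 0))
  write_mrc(m1, f)
  r1 <- read_mrc(f)
  expect_lt(max(abs(r1$values - m1$values)), 1e-6 * max(abs(m1$values)))
  expect_equal(r1$origin, m1$origin, tolerance = 1e-4)
  # second round trip through float32 is bit-exact
  f2 <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(r1, f2)
  expect_identical(read_mrc(f2)$values, r1$values)

  # rectangular grids round-trip unchanged
  mr <- density_map(array(seq_len(8 * 10 * 12), c(8, 10, 12)), 4)
  write_mrc(mr, f)
  expect_identical(dim(read_mrc(f)$values), c(8L, 10L, 12L))
})

test_that("gzipped MRC files are read transparently", {
  m <- density_map(array(rnorm(16^3), c(16, 16, 16)), 2.62)
  f <- withr::local_tempfile(fileext = ".mrc")
  fgz <- paste0(f, ".gz")
  write_mrc(m, f)
  con <- gzfile(fgz, "wb")
  writeBin(readBin(f, "raw", file.size(f)), con)
  close(con)
  r <- read_mrc(fgz)
  expect_equal(r$voxel_size, 2.62, tolerance = 1e-4)
  expect_lt(max(abs(r$values - m$values)), 1e-6)
})

test_that("malformed MRC files raise format errors, not partial maps", {
  m <- density_map(array(rnorm(12^3), c(12, 12, 12)), 2)
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(m, f)
  # truncate mid-data
  raw <- readBin(f, "raw", file.size(f))
  ft <- withr::local_tempfile(fileext = ".mrc")
  writeBin(raw[1:(1024 + 1000)], ft)
  expect_error(read_mrc(ft), "truncated data")
  # unsupported mode
  raw2 <- raw
  raw2[13] <- as.raw(1)   # mode word (byte 13-16) -> 1 (int16)
  fm <- withr::local_tempfile(fileext = ".mrc")
  writeBin(raw2, fm)
  expect_error(read_mrc(fm), "mode")
  expect_error(read_mrc(withr::local_tempfile()), "not found")
})

test_that("our MRC writer agrees with an independent reader (gemmi)", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  has_gemmi <- suppressWarnings(system2(
    "python", c("-c", shQuote("import gemmi")),
    stdout = FALSE, stderr = FALSE)) == 0
  skip_if(!has_gemmi, "python gemmi not importable")
  set.seed(7)
  m <- density_map(array(rnorm(12^3), c(12, 12, 12)), voxel_size = 2.62)
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(m, f)
  code <- paste0(
    "import gemmi\n",
    "import numpy as np\n",
    "g = gemmi.read_ccp4_map(r'", f, "')\n",
    "a = np.array(g.grid, copy=False)\n",
    "print(round(g.grid.spacing[0], 5))\n",
    "print(a.shape)\n",
    "print(float(a.sum()))\n")
  py <- withr::local_tempfile(fileext = ".py")
  writeLines(code, py)
  out <- system2("python", py, stdout = TRUE)
  expect_equal(as.numeric(out[1]), 2.62, tolerance = 1e-4)
  expect_equal(out[2], "(12, 12, 12)")
  expect_equal(as.numeric(out[3]), sum(m$values), tolerance = 1e-5)
})

test_that("resample_map preserves constants, identity and smooth content", {
  cm <- density_map(array(5, c(16, 16, 16)), 3.42)
  r <- resample_map(cm, 2.62, c(20, 20, 20))
  inner <- r$values[4:17, 4:17, 4:17]
  expect_true(all(abs(inner - 5) < 1e-9))

  ph <- fx_phantom_small()
  ident <- resample_map(ph, ph$voxel_size, dim(ph$values))
  expect_lt(max(abs(ident$values - ph$values)), 1e-6)

  # 3.42 -> 2.62 -> 3.42 A round trip on a smooth phantom
  up <- resample_map(ph, 2.62, round(dim(ph$values) * 7.5 / 2.62))
  back <- resample_map(up, 7.5, dim(ph$values))
  core <- 5:28   # away from the border where the grids stop overlapping
  expect_gt(cor(as.vector(back$values[core, core, core]),
                as.vector(ph$values[core, core, core])), 0.99)

  # volume integral conserved within 1% for a smooth, border-free map
  blob <- fx_blob()
  vol0 <- sum(blob$values) * blob$voxel_size^3
  bl_up <- resample_map(blob, 3, round(dim(blob$values) * 7.5 / 3))
  vol1 <- sum(bl_up$values) * 3^3
  expect_lt(abs(vol1 - vol0) / abs(vol0), 0.01)

  expect_error(resample_map(ph, 1e6), "overlap|empty")
})

test_that("low-pass filter matches its analytic raised-cosine response", {
  vs <- 2.62
  n <- 48
  cm <- density_map(array(7, c(n, n, n)), vs)
  expect_lt(max(abs(lowpass_filter(cm, 15)$values - 7)), 1e-9)

  set.seed(3)
  wn <- density_map(array(rnorm(n^3), c(n, n, n)), vs)
  expect_lt(var(as.vector(lowpass_filter(wn, 15)$values)),
            var(as.vector(wn$values)))

  # impulse response FWHM vs 1D quadrature of the analytic transfer:
  # h(r) = int H(f) sinc(2 pi f r) 4 pi f^2 df for the raised cosine
  R <- 15
  H <- function(f) {
    w <- 2 / (n * vs); fc <- 1 / R
    ifelse(f <= fc - w / 2, 1,
           ifelse(f >= fc + w / 2, 0,
                  0.5 * (1 + cos(pi * (f - (fc - w / 2)) / w))))
  }
  psf <- function(r) sapply(r, function(ri) {
    integrand <- function(f) {
      s <- ifelse(f * ri == 0, 1, sin(2 * pi * f * ri) / (2 * pi * f * ri))
      H(f) * s * 4 * pi * f^2
    }
    stats::integrate(integrand, 0, 1 / (2 * vs), rel.tol = 1e-8)$value
  })
  rg <- seq(0, 20, by = 0.01)
  pv <- psf(rg)
  fwhm_analytic <- 2 * rg[which(pv < pv[1] / 2)[1]]

  imp <- density_map(array(0, c(n, n, n)), vs)
  ctr <- floor(n / 2) + 1
  imp$values[ctr, ctr, ctr] <- 1
  prof <- lowpass_filter(imp, R)$values[, ctr, ctr]
  hm <- max(prof) / 2
  above <- which(prof >= hm)
  lo <- approx(prof[c(min(above) - 1, min(above))],
               c(min(above) - 1, min(above)), xout = hm)$y
  hi <- approx(prof[c(max(above), max(above) + 1)],
               c(max(above), max(above) + 1), xout = hm)$y
  fwhm_measured <- (hi - lo) * vs
  expect_lt(abs(fwhm_measured - fwhm_analytic) / fwhm_analytic, 0.2)

  # idempotence on the pass band
  ph <- fx_phantom()
  once <- lowpass_filter(ph, 20)
  twice <- lowpass_filter(once, 20)
  passband <- lowpass_filter(ph, 25)  # strictly inside the pass band
  expect_lt(max(abs(lowpass_filter(passband, 20)$values -
                      lowpass_filter(lowpass_filter(passband, 20), 20)$values)),
            1e-5 * max(abs(passband$values)))

  expect_error(lowpass_filter(ph, 2 * ph$voxel_size - 1), "Nyquist")
})

test_that("normalize_map applies the region affine map to the whole box", {
  v <- array(0, c(8, 8, 8))
  v[1, 1, 1] <- 1; v[2, 1, 1] <- 3
  reg <- array(0, c(8, 8, 8)); reg[1:2, 1, 1] <- 1
  m <- normalize_map(density_map(v, 1), volume_mask(reg, 1, role = "analysis"))
  expect_equal(m$values[1, 1, 1], -1)
  expect_equal(m$values[2, 1, 1], 1)
  expect_equal(m$values[3, 3, 3], (0 - 2) / 1)

  set.seed(5)
  g <- density_map(array(rnorm(16^3, 4, 3), c(16, 16, 16)), 1)
  n1 <- normalize_map(g)
  expect_lt(abs(mean(n1$values)), 1e-12)
  expect_lt(abs(sqrt(mean(n1$values^2)) - 1), 1e-12)
  n2 <- normalize_map(density_map(2.5 * g$values + 7, 1))
  expect_lt(max(abs(n2$values - n1$values)), 1e-9)

  expect_error(normalize_map(density_map(array(1, c(8, 8, 8)), 1)),
               "variance")
})
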