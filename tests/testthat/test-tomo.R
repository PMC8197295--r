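test_that("frame tiling round-trips through sub-image extraction", {
  cfg <- paper_config()
  g <- lenslet_grid(cfg)
  va <- viewing_angles(g)
  n <- 12
  set.seed(21)
  tiles <- lapply(seq_len(nrow(va)), function(q) matrix(stats::runif(n * n), n))
  frame <- matrix(0, 6 * n, 6 * n)
  ms <- sort(unique(g$m)); ns <- sort(unique(g$n))
  for (q in seq_len(nrow(va))) {
    i <- match(va$n[q], ns); j <- match(va$m[q], ms)
    frame[(i - 1) * n + 1:n, (j - 1) * n + 1:n] <- tiles[[q]]
  }
  ps <- extract_lenslet_subimages(frame, g, cfg, subimage_px = n)
  for (q in seq_len(nrow(va)))
    expect_identical(ps$subimages[[q]], tiles[[q]])
  expect_equal(ps$angles$alpha_rad, va$alpha_rad)
  # an all-zero frame extracts to all-zero tiles
  ps0 <- extract_lenslet_subimages(matrix(0, 6 * n, 6 * n), g, cfg,
                                   subimage_px = n)
  expect_true(all(vapply(ps0$subimages, function(x) all(x == 0), TRUE)))
  # a frame too small for the tiling is rejected
  expect_error(extract_lenslet_subimages(matrix(0, 6 * n, 6 * n - 1), g, cfg,
                                         subimage_px = n), "too small")
  expect_error(extract_lenslet_subimages(frame, g, cfg, subimage_px = n,
                                         origin = c(0, 1)), "too small")
})

test_that("sub-image peak displacement tracks the viewing direction for defocused points", {
  cfg <- paper_config()
  vox <- pixel_resolution_at_sample(cfg)
  n <- 48
  dens <- array(0, dim = c(n, n, n))
  ctr <- floor(n / 2) + 1
  dz <- 6                                  # defocus: 6 voxels above centre
  dens[ctr, ctr, ctr + dz] <- 1
  ph <- phantom(dens, vox)
  va <- viewing_angles(lenslet_grid(cfg))
  for (q in c(1, 4, 7, nrow(va))) {
    p <- project_phantom(ph, va$alpha_rad[q], va$beta_rad[q])
    pk <- arrayInd(which.max(p), dim(p))
    # a point above focus shifts against the viewing slope
    expect_equal(pk[2] - ctr, -round(tan(va$alpha_rad[q]) * dz))
    expect_equal(pk[1] - ctr, -round(tan(va$beta_rad[q]) * dz))
  }
})

test_that("Richardson-Lucy is identity under a delta PSF and conserves flux", {
  set.seed(31)
  img <- matrix(0, 48, 48)
  img[20:28, 18:26] <- stats::runif(81, 1, 3)
  delta_psf <- spotfts:::psf_delta(0.27)
  expect_identical(richardson_lucy(img, delta_psf, 7), img)
  psf <- psf_model(1.23, 0.27)
  blurred <- spotfts:::.fft_conv2(img, psf$kernel)
  out <- richardson_lucy(blurred, psf, 10)
  expect_true(all(out >= 0))
  expect_lt(abs(sum(out) - sum(blurred)) / sum(blurred), 0.001)
  expect_error(richardson_lucy(img - 5, psf, 3), "non-negative")
})

test_that("Richardson-Lucy sharpens a diffraction-blurred point by at least 25%", {
  n <- 64
  img <- matrix(0, n, n); img[33, 33] <- 1
  psf <- psf_model(1.23, 0.27)
  blurred <- spotfts:::.fft_conv2(img, psf$kernel)
  dec <- richardson_lucy(blurred, psf, 20)
  f_b <- crossing_fwhm(blurred[33, ])
  f_d <- crossing_fwhm(dec[33, ])
  expect_lt(f_d, 0.75 * f_b)
})

test_that("normal-incidence insertion fills exactly the kz = 0 plane and is linear", {
  n <- 16
  set.seed(5)
  proj <- matrix(stats::runif(n * n), n)
  vol <- fourier_volume(n, 1)
  vol <- fourier_slice_insert(vol, proj, 0, 0)
  P2 <- stats::fft(proj)
  expect_equal(vol$values[, , 1], P2)
  expect_true(all(vol$weight[, , 1] == 1))
  expect_true(all(vol$weight[, , -1] == 0))
  # inserting twice doubles values and weights
  vol2 <- fourier_slice_insert(vol, proj, 0, 0)
  expect_equal(vol2$values[, , 1], 2 * P2)
  expect_equal(vol2$weight[, , 1], matrix(2, n, n))
  expect_error(fourier_slice_insert(vol, proj, pi / 2, 0), "90")
})

test_that("projection transforms equal tilted central slices of the 3D DFT", {
  set.seed(42)
  n <- 16
  vol <- array(stats::runif(n^3), c(n, n, n))
  for (ang in list(c(0.4, -0.25), c(-0.3, 0.3), c(0.55, 0.1))) {
    P2 <- stats::fft(project_phantom(vol, ang[1], ang[2], voxel_um = 1))
    oracle <- tilted_slice_oracle(vol, ang[1], ang[2])
    expect_lt(max(Mod(P2 - oracle)) / max(Mod(oracle)), 0.02)
    # and exact away from the Nyquist edge of the lateral grid
    keep <- c(1:(n / 2), (n / 2 + 2):n)
    expect_lt(max(Mod(P2[keep, keep] - oracle[keep, keep])) /
                max(Mod(oracle)), 1e-10)
  }
})

test_that("single-view inversion back-projects along z and localizes with many views", {
  n <- 32
  ctr <- floor(n / 2) + 1
  dens <- array(0, dim = c(n, n, n)); dens[ctr, ctr, ctr] <- 1
  p <- project_phantom(dens, 0, 0, voxel_um = 1)
  vol <- fourier_volume(n, 1)
  expect_error(invert_fourier_volume(vol), "no projection")
  vol <- fourier_slice_insert(vol, p, 0, 0)
  tomo <- invert_fourier_volume(vol)
  # constant along z through the point's (x, y)
  expect_lt(diff(range(tomo$intensity[ctr, ctr, ])), 1e-10)
  expect_lt(max(abs(tomo$intensity[ctr + 5, ctr + 3, ])), 1e-10)
  # a spread of views localizes the point to its voxel
  angs <- expand.grid(a = c(-0.5, -0.2, 0.2, 0.5), b = c(-0.4, -0.1, 0.3))
  vol <- fourier_volume(n, 1)
  for (q in seq_len(nrow(angs))) {
    pq <- project_phantom(dens, angs$a[q], angs$b[q], voxel_um = 1)
    vol <- fourier_slice_insert(vol, pq, angs$a[q], angs$b[q])
  }
  tomo <- invert_fourier_volume(vol)
  pk <- arrayInd(which.max(tomo$intensity), dim(tomo$intensity))
  expect_true(all(abs(pk - ctr) <= 1))
})

test_that("positivity refinement clips, fixes non-negative fully-measured volumes, and tightens residuals", {
  n <- 16
  ctr <- floor(n / 2) + 1
  # iterations = 0 returns the clipped input
  dens <- array(stats::rnorm(n^3), c(n, n, n))
  vol <- fourier_volume(n, 1)
  vol <- fourier_slice_insert(vol, matrix(1, n, n), 0, 0)
  out0 <- positivity_refine(tomogram(dens, 1), vol, 0)
  expect_equal(out0$intensity, pmax(dens, 0), tolerance = 1e-12)
  # a non-negative object with every Fourier cell measured is a fixed point
  x0 <- array(stats::runif(n^3), c(n, n, n))
  pz <- exp(-2i * pi * (seq_len(n) - 1) * floor(n / 2) / n)
  volf <- fourier_volume(n, 1)
  volf$weight[] <- 1
  volf$values <- sweep(stats::fft(x0), 3, Conj(pz), "*")
  outf <- positivity_refine(tomogram(x0, 1), volf, 5)
  expect_equal(outf$intensity, x0, tolerance = 1e-9)
  # partial measurement: measured-plane residual is non-increasing
  dens <- array(0, dim = c(n, n, n)); dens[ctr, ctr, ctr + 2] <- 1
  vol <- fourier_volume(n, 1)
  for (a in c(-0.4, 0, 0.4)) {
    p <- project_phantom(dens, a, 0, voxel_um = 1)
    vol <- fourier_slice_insert(vol, p, a, 0)
  }
  tomo <- invert_fourier_volume(vol)
  ref <- positivity_refine(tomo, vol, 30)
  res <- attr(ref, "residuals")
  expect_true(all(diff(res) <= 1e-9 * res[1]))
  expect_true(all(ref$intensity >= 0))
})

test_that("positivity refinement reduces axial elongation of a shell reconstruction", {
  n <- 32
  sh <- make_shell_bead(3, 0.6, voxel_um = 0.27, n = n)
  angs <- expand.grid(a = c(-0.35, 0, 0.35), b = c(-0.35, 0, 0.35))
  vol <- fourier_volume(n, 0.27)
  for (q in seq_len(nrow(angs))) {
    p <- project_phantom(sh, atan(angs$a[q]), atan(angs$b[q]))
    p[p < 0] <- 0
    vol <- fourier_slice_insert(vol, p, atan(angs$a[q]), atan(angs$b[q]))
  }
  raw <- invert_fourier_volume(vol)
  ref <- positivity_refine(raw, vol, 50)
  clip <- raw; clip$intensity[clip$intensity < 0] <- 0
  elong <- function(tm) {
    ctr <- floor(n / 2) + 1
    zp <- apply(tm$intensity, 3, max)
    xp <- apply(tm$intensity, 2, max)
    crossing_fwhm(zp) / crossing_fwhm(xp)
  }
  expect_lt(elong(ref), elong(clip))
})

test_that("reconstruction is linear before positivity and equivariant under the index flip", {
  n <- 32
  ctr <- floor(n / 2) + 1
  dens <- array(0, dim = c(n, n, n))
  dens[ctr + 3, ctr - 2, ctr + 4] <- 1
  dens[ctr - 5, ctr + 1, ctr - 2] <- 0.5
  ph <- phantom(dens, 1)
  angs <- data.frame(m = c(0.5, -0.5, 0.5, -0.5), n = c(0.5, 0.5, -0.5, -0.5),
                     alpha_rad = atan(c(0.4, -0.4, 0.4, -0.4)),
                     beta_rad = atan(c(0.4, 0.4, -0.4, -0.4)))
  imgs <- lapply(seq_len(4), function(q)
    project_phantom(ph, angs$alpha_rad[q], angs$beta_rad[q]))
  ps1 <- projection_set(imgs, angs, 1)
  ps3 <- projection_set(lapply(imgs, function(x) 3 * x), angs, 1)
  t1 <- reconstruct_tomogram(ps1, NULL, positivity_iterations = 0)
  t3 <- reconstruct_tomogram(ps3, NULL, positivity_iterations = 0)
  expect_equal(t3$intensity, 3 * t1$intensity, tolerance = 1e-9)
  # (m,n) -> (-m,-n) with mirrored images yields the mirrored tomogram
  mir <- c(1, n:2)
  angsf <- angs
  angsf$alpha_rad <- -angs$alpha_rad; angsf$beta_rad <- -angs$beta_rad
  psf_set <- projection_set(lapply(imgs, function(x) x[mir, mir]), angsf, 1)
  tf <- reconstruct_tomogram(psf_set, NULL, positivity_iterations = 0)
  expect_equal(tf$intensity, t1$intensity[mir, mir, ], tolerance = 1e-9)
  # fewer than two distinct angles is rejected
  expect_error(reconstruct_tomogram(projection_set(imgs[c(1, 1)],
                                                   angs[c(1, 1), ], 1), NULL),
               "distinct")
})

test_that("Gaussian-fit FWHM is exact on Gaussian blobs and scale invariant", {
  n <- 33
  ctr <- 17
  ax <- seq_len(n) - ctr
  g1 <- exp(-outer(outer(ax^2, ax^2 / 1.5^2, "+"), ax^2 / 4, "+") / 2)
  tm <- tomogram(g1, voxel_um = 0.5)
  expect_equal(measure_fwhm_3d(tm, "y"), 2.3548 * 1 * 0.5, tolerance = 1e-3)
  expect_equal(measure_fwhm_3d(tm, "x"), 2.3548 * 1.5 * 0.5, tolerance = 1e-3)
  expect_equal(measure_fwhm_3d(tm, "z"), 2.3548 * 2 * 0.5,
               tolerance = 1e-3)
  tm2 <- tomogram(40 * g1, voxel_um = 0.5)
  expect_equal(measure_fwhm_3d(tm2, "z"), measure_fwhm_3d(tm, "z"),
               tolerance = 1e-9)
  expect_error(measure_fwhm_3d(tomogram(array(1, c(4, 4, 4)), 1), "x"), "flat")
})
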