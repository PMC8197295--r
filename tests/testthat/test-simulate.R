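test_that("shell-bead phantoms carry the analytic shell volume and symmetry", {
  vox <- 0.27
  ph <- make_shell_bead(6, 0.54, voxel_um = vox, n = 65)
  R <- 3; t <- 0.54
  expect_equal(sum(ph$density > 0), 4 * pi * R^2 * t / vox^3,
               tolerance = 0.15)
  ctr <- 33
  expect_equal(ph$density[ctr, ctr, ctr], 0)           # hollow
  # mirror symmetry about all three mid-planes
  expect_identical(ph$density, ph$density[65:1, , ])
  expect_identical(ph$density, ph$density[, 65:1, ])
  expect_identical(ph$density, ph$density[, , 65:1])
  expect_error(make_shell_bead(6, 0.5, voxel_um = 0.27, n = 17), "larger")
  expect_error(make_shell_bead(1, 0.6), "2 \\* shell_thickness")
})

test_that("point-bead phantoms integrate to the ball volume at the right centroid", {
  vox <- 0.27
  ph <- make_point_bead(0.5, voxel_um = vox, n = 33)
  expect_equal(sum(ph$density) * vox^3, 4 / 3 * pi * 0.25^3,
               tolerance = 0.05)
  w <- ph$density
  ctr <- 17
  for (d in 1:3) {
    idx <- slice.index(w, d)
    expect_equal(sum(w * idx) / sum(w), ctr, tolerance = 1e-9)
  }
  # projections at any angle are unimodal (above the ringing floor)
  for (ang in list(c(0, 0), c(0.5, -0.3), c(-0.7, 0.7))) {
    p <- project_phantom(ph, ang[1], ang[2])
    prof <- p[17, ]
    prof[prof < 0.01 * max(prof)] <- 0
    nmax <- sum(diff(sign(diff(prof))) == -2)
    expect_lte(nmax, 1)
  }
})

test_that("projections preserve chord profiles and total intensity", {
  n <- 48
  ball <- smooth_ball(n, 9)
  p <- project_phantom(ball, 0, 0, voxel_um = 1)
  ctr <- floor(n / 2) + 1
  r <- seq_len(n) - ctr
  inside <- abs(r) <= 6
  # analytic line integral of the soft-edged ball by fine quadrature
  zq <- seq(0, 14, by = 0.005)
  chord <- vapply(r, function(x) {
    rho <- pmin(1, pmax(0, 9.5 - sqrt(x^2 + zq^2)))
    2 * sum(rho) * 0.005
  }, 0)
  expect_lt(max(abs(p[ctr, inside] - chord[inside])) / max(chord), 0.03)
  # line-integral conservation: total projected intensity is angle independent
  s0 <- sum(project_phantom(ball, 0, 0, voxel_um = 1))
  for (ang in list(c(0.4, 0.2), c(-0.5, 0.5), c(0.3, -0.6)))
    expect_equal(sum(project_phantom(ball, ang[1], ang[2], voxel_um = 1)) / s0,
                 1, tolerance = 0.01)
  # bilinear shear path agrees with the spectral path away from edges
  p2 <- project_phantom(ball, 0.3, -0.2, voxel_um = 1, method = "linear")
  p1 <- project_phantom(ball, 0.3, -0.2, voxel_um = 1)
  expect_lt(max(abs(p1 - p2)) / max(p1), 0.05)
  # too-steep shears are rejected
  expect_error(project_phantom(ball, 1.5, 0, voxel_um = 1), "steep")
})

test_that("shell projections are centrally filled while the phantom is hollow", {
  cfg <- paper_config()
  vox <- pixel_resolution_at_sample(cfg)
  sh <- make_shell_bead(6, 0.54, voxel_um = vox, n = 64)
  psf <- psf_model(lenslet_diffraction_limit(cfg, "width"), vox)
  p <- project_phantom(sh, 0, 0, psf)
  ctr <- floor(64 / 2) + 1
  # no ring: the centre does not dip towards zero
  expect_gt(p[ctr, ctr] / max(p), 0.35)
  # while the phantom's own mid-plane is hollow at the centre
  expect_equal(sh$density[ctr, ctr, ctr], 0)
})

test_that("snapshot frames tile projections and scale linearly with density", {
  cfg <- paper_config()
  g <- lenslet_grid(cfg)
  vox <- pixel_resolution_at_sample(cfg)
  pb <- make_point_bead(0.5, voxel_um = vox, n = 24)
  frame <- render_snapshot(pb, g, cfg)
  ps <- extract_lenslet_subimages(frame, g, cfg, subimage_px = 24)
  va <- viewing_angles(g)
  for (q in c(1, 8, nrow(va)))
    expect_equal(ps$subimages[[q]],
                 pmax(project_phantom(pb, va$alpha_rad[q], va$beta_rad[q]), 0),
                 tolerance = 1e-12)
  # dark phantom -> dark frame
  dark <- phantom(array(0, dim = c(24, 24, 24)), vox)
  expect_true(all(render_snapshot(dark, g, cfg) == 0))
  # linear in the density
  pb2 <- phantom(2.5 * pb$density, vox)
  expect_equal(render_snapshot(pb2, g, cfg), 2.5 * frame, tolerance = 1e-12)
})

test_that("OPD axes are uniform without jitter and carry the requested nonlinearity", {
  ax <- sample_opd_axis(2000, 200, 0)
  expect_equal(ax$positions_um, seq(-100, 100, length.out = 2000))
  ax2 <- sample_opd_axis(2000, 200, 0.01, seed = 8)
  # mean step is span/(n-1) regardless of jitter (endpoints pinned)
  expect_equal(mean(diff(ax2$positions_um)), 200 / 1999)
  jit <- ax2$positions_um - seq(-100, 100, length.out = 2000)
  expect_equal(sqrt(mean(jit^2)), 0.01, tolerance = 0.1)
  expect_error(sample_opd_axis(50, 10, 5, seed = 1), "increasing")
})

test_that("interferograms obey the two-beam model for known spectra", {
  opd <- opd_axis(seq(-40, 40, length.out = 801))
  delta <- opd$positions_um
  # monochromatic: I(delta) = 1 + cos(2 pi sigma0 delta) exactly
  st <- synth_interferograms(list(brightness = matrix(1, 1, 1),
                                  spectrum = emission_line(632.8)), opd)
  expect_equal(st$intensities[, 1, 1],
               1 + cos(2 * pi * delta / 0.6328), tolerance = 1e-12)
  # band spectrum: I(0) = 2B and bounded by [0, 2B]
  band <- emission_band()
  stb <- synth_interferograms(list(brightness = matrix(3, 1, 1),
                                   spectrum = band), opd)
  i0 <- which.min(abs(delta))
  expect_equal(stb$intensities[i0, 1, 1], 2 * 3, tolerance = 1e-6)
  expect_true(all(stb$intensities >= -1e-9 &
                    stb$intensities <= 6 + 1e-9))
  # Gaussian band of sigma-domain std s -> envelope std 1/(2 pi s)
  s_cm <- 300
  sig <- seq(18868 - 4 * s_cm, 18868 + 4 * s_cm, length.out = 401)
  gsp <- emission_spectrum(sig, exp(-(sig - 18868)^2 / (2 * s_cm^2)))
  stg <- synth_interferograms(list(brightness = matrix(1, 1, 1),
                                   spectrum = gsp), opd)
  osc <- stg$intensities[, 1, 1] - mean(stg$intensities[, 1, 1])
  env <- upper_envelope(osc - mean(osc), opd)
  sd_fit <- spotfts:::.gaussian_fwhm_1d(env) / 2.3548 * opd$nominal_step_um
  expect_equal(sd_fit, 1 / (2 * pi * s_cm * 1e-4), tolerance = 0.02)
})

test_that("acquisitions are reproducible bit-for-bit under a fixed seed", {
  cfg <- paper_config()
  g <- lenslet_grid(cfg)
  vox <- pixel_resolution_at_sample(cfg)
  pb <- make_point_bead(1, voxel_um = vox, n = 16)
  opd <- sample_opd_axis(64, 20, 0.01, seed = 13)
  nm <- noise_model(peak_photons = 500, seed = 99)
  s1 <- simulate_acquisition(pb, g, cfg, opd, noise = nm)
  s2 <- simulate_acquisition(pb, g, cfg, opd, noise = nm)
  expect_identical(s1$intensities, s2$intensities)
  # noiseless monochromatic phantom: every lit pixel is an offset cosine
  pb$spectra <- list(emission_line(530))
  s3 <- simulate_acquisition(pb, g, cfg, opd)
  lit <- which(apply(s3$intensities, c(2, 3), max) > 0, arr.ind = TRUE)
  pix <- s3$intensities[, lit[1, 1], lit[1, 2]]
  model <- 1 + cos(2 * pi * opd$positions_um / 0.530)
  B <- sum(pix * model) / sum(model^2)   # least-squares brightness
  expect_equal(pix, B * model, tolerance = 1e-9)
})

test_that("two-compartment phantoms separate spectrally in the processed cube", {
  cfg <- paper_config()
  g <- lenslet_grid(cfg)
  vox <- pixel_resolution_at_sample(cfg)
  po <- make_pollen_phantom(core_diameter_um = 2.2, envelope_diameter_um = 5.4,
                            envelope_thickness_um = 0.8,
                            voxel_um = vox, n = 40)
  opd <- sample_opd_axis(256, 25.5, 0, seed = 2)
  st <- simulate_acquisition(po, g, cfg, opd)
  grid <- seq(1e7 / 680, 1e7 / 500, length.out = 160)
  # a handful of faint limb pixels may fail envelope centering; their
  # spectra are zeroed by design
  cube <- suppressWarnings(process_stack(st, "norton_beer_medium", grid))
  # reconstruct both wavelength planes: the 540 nm tomogram localizes to
  # the solid core, the 620 nm tomogram to the hollow envelope
  ctr <- floor(40 / 2) + 1
  tomos <- lapply(c(540, 620), function(lam) {
    plane <- cube_plane(cube, lam)
    ps <- extract_lenslet_subimages(plane, g, cfg, subimage_px = 40)
    reconstruct_tomogram(ps, NULL, positivity_iterations = 20)
  })
  mid540 <- tomos[[1]]$intensity[, , ctr]
  mid620 <- tomos[[2]]$intensity[, , ctr]
  expect_gt(mid540[ctr, ctr] / max(mid540), 0.5)   # filled core
  expect_lt(mid620[ctr, ctr] / max(mid620), 0.3)   # hollow shell
  # the 620 nm ring peak sits out near the envelope radius (2.7 um)
  prof <- mid620[ctr, ]
  pk2 <- which.max(prof)
  expect_gt(abs(pk2 - ctr) * po$voxel_um, 1.8)
})
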