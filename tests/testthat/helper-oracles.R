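# Independent oracles and small builders used across the suite.

# brute-force nonuniform discrete Fourier transform (the NUFFT oracle)
nudft_oracle <- function(series, delta_um, sigma_cm1) {
  as.vector(exp(-2i * pi * outer(sigma_cm1 * 1e-4, delta_um)) %*% series)
}

# brute-force tilted central slice of the 3D DFT of `vol`, z measured
# from the centre slice (the Fourier-slice oracle)
tilted_slice_oracle <- function(vol, alpha_rad, beta_rad) {
  n <- dim(vol)[1]
  a <- tan(alpha_rad); b <- tan(beta_rad)
  f <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1)) / n
  ex <- exp(-2i * pi * outer(seq_len(n) - 1, seq_len(n) - 1) / n)
  kz <- -(a * matrix(f, n, n, byrow = TRUE) + b * matrix(f, n, n))
  z0 <- floor(n / 2) + 1
  out <- matrix(0 + 0i, n, n)
  for (z in seq_len(n)) {
    Fz <- ex %*% vol[, , z] %*% t(ex)
    out <- out + Fz * exp(-2i * pi * kz * (z - z0))
  }
  out
}

# model-free FWHM of a 1D profile by linear interpolation at half max
crossing_fwhm <- function(prof, step = 1) {
  p <- which.max(prof)
  half <- prof[p] / 2
  il <- p; while (il > 1 && prof[il - 1] >= half) il <- il - 1
  ir <- p; while (ir < length(prof) && prof[ir + 1] >= half) ir <- ir + 1
  xl <- il - 1 + (half - prof[il - 1]) / (prof[il] - prof[il - 1])
  xr <- ir + (half - prof[ir]) / (prof[ir + 1] - prof[ir])
  (xr - xl) * step
}

# smooth-edged uniform ball (1-voxel linear ramp) for chord-profile tests
smooth_ball <- function(n, radius_vox) {
  ctr <- floor(n / 2) + 1
  ax <- seq_len(n) - ctr
  r <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  array(pmin(1, pmax(0, radius_vox + 0.5 - r)), dim = c(n, n, n))
}

paper_config <- function() spot_config()

# projection set of a phantom over all valid in-pupil lenslets
project_all <- function(ph, cfg = paper_config(), psf = NULL) {
  va <- viewing_angles(lenslet_grid(cfg))
  imgs <- lapply(seq_len(nrow(va)), function(q)
    project_phantom(ph, va$alpha_rad[q], va$beta_rad[q], psf))
  projection_set(imgs, va, ph$voxel_um)
}
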