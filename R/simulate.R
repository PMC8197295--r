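# evaluate code with a temporary RNG state derived from `seed`
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fluorophore emission spectrum
#'
#' Spectral density on a wavenumber grid. A single-point grid represents
#' a monochromatic (laser) line. Band spectra are normalized to unit
#' integral so that an emitter of brightness B produces a zero-OPD
#' interferogram intensity of exactly 2B.
#'
#' @param wavenumber_cm1 Ascending positive wavenumbers (cm^-1); length
#'   1 for a monochromatic line.
#' @param density Non-negative spectral density, same length.
#' @return An `emission_spectrum` object.
#' @export
emission_spectrum <- function(wavenumber_cm1, density) {
  if (any(wavenumber_cm1 <= 0)) stop("wavenumbers must be positive")
  if (length(wavenumber_cm1) > 1 && any(diff(wavenumber_cm1) <= 0))
    stop("wavenumber grid must be ascending")
  if (length(density) != length(wavenumber_cm1) || any(density < 0))
    stop("density must be non-negative and match the grid")
  out <- list(wavenumber_cm1 = wavenumber_cm1, density = density)
  class(out) <- "emission_spectrum"
  out
}

#' @rdname emission_spectrum
#' @param wavelength_nm Line wavelength for a monochromatic source.
#' @export
emission_line <- function(wavelength_nm) {
  emission_spectrum(1e7 / wavelength_nm, 1)
}

#' @rdname emission_spectrum
#' @param peak_nm Band peak wavelength (nm).
#' @param cut_low_nm,cut_high_nm Bandpass filter edges (nm); density is
#'   zero outside. Defaults are the 512-545 nm emission-filter window of
#'   the green dye band peaking at 530 nm.
#' @param width_nm Gaussian width (standard deviation, nm) of the
#'   underlying band.
#' @param n Grid points across the band.
#' @export
emission_band <- function(peak_nm = 530, cut_low_nm = 512, cut_high_nm = 545,
                          width_nm = 20, n = 201) {
  stopifnot(cut_low_nm < cut_high_nm, width_nm > 0)
  lam <- seq(cut_low_nm, cut_high_nm, length.out = n)
  dens <- exp(-(lam - peak_nm)^2 / (2 * width_nm^2))
  sig <- rev(1e7 / lam)                     # ascending in wavenumber
  dens <- rev(dens)
  w <- .trapezoid_weights(sig)
  emission_spectrum(sig, dens / sum(w * dens))
}

.trapezoid_weights <- function(x) {
  n <- length(x)
  if (n == 1) return(1)
  w <- numeric(n)
  w[1] <- (x[2] - x[1]) / 2
  w[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  w
}

# integral of S over its grid (1 for normalized bands, S for lines)
.spectrum_integral <- function(spec) {
  sum(.trapezoid_weights(spec$wavenumber_cm1) * spec$density)
}

# c(delta) = integral S(sigma) (1 + cos(2 pi sigma delta)) dsigma
.interferogram_kernel <- function(spec, delta_um) {
  w <- .trapezoid_weights(spec$wavenumber_cm1) * spec$density
  tot <- sum(w)
  tot + as.vector(cos(2 * pi * outer(delta_um, spec$wavenumber_cm1 * 1e-4)) %*% w)
}

#' Camera noise model
#'
#' Signal-dependent (scaled-Poisson) shot noise plus additive Gaussian
#' read noise, fully reproducible from the seed. The photon budget is
#' stated relative to the brightest pixel of the dataset: the data are
#' scaled so the peak corresponds to `peak_photons` detected photon
#' equivalents, Poisson counts are drawn, and the result is scaled back;
#' read noise is `read_noise_photons` on the same scale. Defaults
#' emulate a cooled EMCCD frame with a few thousand photons at the peak.
#'
#' @param peak_photons Photon equivalents at the brightest pixel
#'   (0 disables shot noise).
#' @param read_noise_photons Read-noise standard deviation in photon
#'   equivalents.
#' @param seed Integer RNG seed.
#' @return A `noise_model` object.
#' @export
noise_model <- function(peak_photons = 2000, read_noise_photons = 2, seed = 1) {
  stopifnot(peak_photons >= 0, read_noise_photons >= 0)
  out <- list(peak_photons = peak_photons,
              read_noise_photons = read_noise_photons, seed = seed)
  class(out) <- "noise_model"
  out
}

.apply_noise <- function(x, noise) {
  if (is.null(noise)) return(x)
  .with_seed(noise$seed, {
    x[x < 0] <- 0
    mx <- max(x)
    if (mx > 0) {
      scale <- mx / max(noise$peak_photons, 1)
      if (noise$peak_photons > 0)
        x[] <- scale * stats::rpois(length(x), x / scale)
      if (noise$read_noise_photons > 0)
        x[] <- x + stats::rnorm(length(x), 0, noise$read_noise_photons * scale)
    }
    x[x < 0] <- 0
    x
  })
}

#' Labelled fluorophore phantom
#'
#' A 3D non-negative fluorophore concentration on an isotropic voxel
#' grid, with an integer label map assigning each non-background voxel
#' an emission spectrum.
#'
#' @param density 3D non-negative array (y, x, z).
#' @param voxel_um Isotropic voxel size (micrometres).
#' @param labels Integer array of the same shape; 0 marks background.
#'   Defaults to `density > 0`.
#' @param spectra List of [emission_spectrum()]s indexed by label.
#' @return A `phantom` object.
#' @export
phantom <- function(density, voxel_um,
                    labels = NULL, spectra = list(emission_band())) {
  stopifnot(length(dim(density)) == 3, voxel_um > 0)
  if (min(density) < 0) stop("density must be non-negative")
  if (is.null(labels)) labels <- array(as.integer(density > 0), dim(density))
  if (!all(dim(labels) == dim(density))) stop("labels must match density shape")
  used <- setdiff(unique(as.vector(labels)), 0L)
  if (length(used) && max(used) > length(spectra))
    stop("labels reference undefined spectra")
  out <- list(density = density, voxel_um = voxel_um, labels = labels,
              spectra = spectra)
  class(out) <- "phantom"
  out
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$density)
  cat(sprintf("Phantom: %d x %d x %d voxels of %g um, %d label(s), total intensity %.4g\n",
              d[1], d[2], d[3], x$voxel_um,
              length(setdiff(unique(as.vector(x$labels)), 0L)),
              sum(x$density)))
  invisible(x)
}

# radius map (um) from the grid centre voxel floor(n/2)+1
.radius_um <- function(n, voxel_um) {
  ctr <- floor(n / 2) + 1
  ax <- (seq_len(n) - ctr) * voxel_um
  r2 <- outer(ax^2, ax^2, "+")
  sqrt(outer(as.vector(r2), ax^2, "+")) |>
    array(dim = c(n, n, n))
}

#' Surface-stained bead phantom (spherical shell)
#'
#' Emulates a polystyrene bead whose outer layer is stained with dye:
#' unit density on the spherical shell of nominal diameter
#' `diameter_um`, zero elsewhere (hollow). The stained layer is centred
#' on the nominal surface radius with the given thickness.
#'
#' @param diameter_um Bead diameter (default 6).
#' @param shell_thickness_um Stained-layer thickness; must satisfy
#'   `diameter > 2 * thickness > 0`.
#' @param spectrum The shell's [emission_spectrum()].
#' @param voxel_um Voxel size (default 0.27, the camera pixel referred
#'   to the sample).
#' @param n Grid side in voxels; must contain the bead.
#' @return A `phantom`.
#' @export
make_shell_bead <- function(diameter_um = 6, shell_thickness_um = 0.54,
                            spectrum = emission_band(), voxel_um = 0.27,
                            n = 65) {
  stopifnot(diameter_um > 2 * shell_thickness_um, shell_thickness_um > 0)
  R <- diameter_um / 2
  if (R + shell_thickness_um / 2 >= n / 2 * voxel_um)
    stop("phantom larger than the grid")
  r <- .radius_um(n, voxel_um)
  dens <- array(0, dim = c(n, n, n))
  dens[abs(r - R) <= shell_thickness_um / 2] <- 1
  phantom(dens, voxel_um, spectra = list(spectrum))
}

#' Point-like bead phantom (solid sub-resolution ball)
#'
#' A solid fluorescent ball of the given diameter with partial-volume
#' anti-aliasing (each voxel carries the fraction of its volume inside
#' the ball, estimated on a 4x4x4 sub-grid), centred on the grid.
#'
#' @param diameter_um Ball diameter (default 0.5, sub-resolution).
#' @param spectrum The bead's [emission_spectrum()].
#' @param voxel_um Voxel size.
#' @param n Grid side in voxels.
#' @return A `phantom`.
#' @export
make_point_bead <- function(diameter_um = 0.5, spectrum = emission_band(),
                            voxel_um = 0.27, n = 65) {
  stopifnot(diameter_um > 0)
  R <- diameter_um / 2
  if (R >= n / 2 * voxel_um) stop("phantom larger than the grid")
  ctr <- floor(n / 2) + 1
  half <- ceiling(R / voxel_um) + 1
  sub <- (seq_len(4) - 2.5) / 4
  dens <- array(0, dim = c(n, n, n))
  idx <- seq(-half, half)
  for (dz in idx) for (dx in idx) for (dy in idx) {
    frac <- 0
    for (sz in sub) {
      zz <- (dz + sz) * voxel_um
      xy <- outer((dy + sub)^2, (dx + sub)^2, "+") * voxel_um^2
      frac <- frac + sum(xy + zz^2 <= R^2)
    }
    dens[ctr + dy, ctr + dx, ctr + dz] <- frac / 64
  }
  phantom(dens, voxel_um, spectra = list(spectrum))
}

#' Two-compartment pollen-like phantom
#'
#' A solid core with one emission spectrum inside a concentric spherical
#' envelope with another, emulating a pollen grain whose core and wall
#' fluoresce in different bands.
#'
#' @param core_diameter_um,envelope_diameter_um Core and outer
#'   diameters.
#' @param envelope_thickness_um Envelope shell thickness.
#' @param core_spectrum,envelope_spectrum [emission_spectrum()]s of the
#'   two compartments (defaults peak at 540 and 620 nm).
#' @param voxel_um Voxel size.
#' @param n Grid side in voxels.
#' @return A `phantom` with labels 1 (core) and 2 (envelope).
#' @export
make_pollen_phantom <- function(core_diameter_um = 4, envelope_diameter_um = 8,
                                envelope_thickness_um = 0.8,
                                core_spectrum = emission_band(540, 520, 560),
                                envelope_spectrum = emission_band(620, 600, 640),
                                voxel_um = 0.27, n = 65) {
  stopifnot(core_diameter_um < envelope_diameter_um)
  Re_ <- envelope_diameter_um / 2
  if (Re_ + envelope_thickness_um / 2 >= n / 2 * voxel_um)
    stop("phantom larger than the grid")
  r <- .radius_um(n, voxel_um)
  dens <- array(0, dim = c(n, n, n))
  lab <- array(0L, dim = c(n, n, n))
  core <- r <= core_diameter_um / 2
  env <- abs(r - Re_) <= envelope_thickness_um / 2
  dens[core] <- 1; lab[core] <- 1L
  dens[env] <- 1; lab[env] <- 2L
  phantom(dens, voxel_um, labels = lab,
          spectra = list(core_spectrum, envelope_spectrum))
}

#' Parallel projection of a phantom along a viewing direction
#'
#' Line integrals of the density along the direction with slopes
#' `(tan alpha, tan beta, 1)`: each z slice is laterally shifted by
#' `(-tan alpha, -tan beta) * (z - z0)` (z0 the centre slice) and the
#' slices are summed, then scaled by the voxel size to approximate the
#' continuous integral, and optionally blurred with the lenslet kernel.
#' Shifts are applied in the Fourier domain (exact for band-limited,
#' interior-supported volumes) or by bilinear interpolation.
#'
#' @param obj A `phantom` or a 3D array (then `voxel_um` must be given).
#' @param alpha_rad,beta_rad Viewing angle components.
#' @param psf Optional [psf_model()] blur.
#' @param method `"fourier"` (default) or `"linear"`.
#' @param voxel_um Voxel size when `obj` is a bare array.
#' @return 2D projection matrix (y, x), same side as the volume.
#' @export
project_phantom <- function(obj, alpha_rad = 0, beta_rad = 0, psf = NULL,
                            method = c("fourier", "linear"), voxel_um = NULL) {
  method <- match.arg(method)
  if (inherits(obj, "phantom")) {
    vol <- obj$density; voxel_um <- obj$voxel_um
  } else {
    vol <- obj
    if (is.null(voxel_um)) stop("voxel_um required for a bare array")
  }
  d <- dim(vol)
  a <- tan(alpha_rad); b <- tan(beta_rad)
  nz <- d[3]; z0 <- floor(nz / 2) + 1
  lit <- which(apply(vol != 0, 3, any))
  if (!length(lit)) return(matrix(0, d[1], d[2]))
  maxshift <- max(abs(a), abs(b)) * max(abs(lit - z0))
  if (maxshift > min(d[1], d[2]) / 2)
    stop("viewing angle too steep: shear exceeds the lateral grid")
  if (method == "fourier") {
    f1 <- .fftfreq(d[1]); f2 <- .fftfreq(d[2])
    fy <- matrix(f1, d[1], d[2]); fx <- matrix(f2, d[1], d[2], byrow = TRUE)
    acc <- matrix(0 + 0i, d[1], d[2])
    for (z in lit) {
      zc <- z - z0
      ph <- exp(2i * pi * (fx * (a * zc) + fy * (b * zc)))
      acc <- acc + stats::fft(vol[, , z]) * ph
    }
    p <- Re(stats::fft(acc, inverse = TRUE)) / (d[1] * d[2])
  } else {
    p <- matrix(0, d[1], d[2])
    for (z in lit) {
      zc <- z - z0
      p <- p + .bilinear_shift(vol[, , z], b * zc, a * zc)
    }
  }
  p <- p * voxel_um
  if (!is.null(psf) && psf$fwhm_um > 0) p <- .fft_conv2(p, psf$kernel)
  p
}

# sample img at (y + dy, x + dx), scalar shifts, bilinear, zero outside
.bilinear_shift <- function(img, dy, dx) {
  d <- dim(img)
  y0 <- floor(dy); x0 <- floor(dx)
  wy <- dy - y0; wx <- dx - x0
  pick <- function(oy, ox) {
    m <- matrix(0, d[1], d[2])
    ri <- seq_len(d[1]) + oy; ci <- seq_len(d[2]) + ox
    keep_r <- ri >= 1 & ri <= d[1]; keep_c <- ci >= 1 & ci <= d[2]
    m[keep_r, keep_c] <- img[ri[keep_r], ci[keep_c]]
    m
  }
  (1 - wy) * (1 - wx) * pick(y0, x0) +
    (1 - wy) * wx * pick(y0, x0 + 1) +
    wy * (1 - wx) * pick(y0 + 1, x0) +
    wy * wx * pick(y0 + 1, x0 + 1)
}

#' Render one snapshot camera frame
#'
#' Tiles the per-lenslet projections of a phantom (one per valid
#' in-pupil lenslet, at its grid position) into a single camera frame.
#' Tiles of excluded lenslets stay dark. The tile side equals the
#' phantom's lateral side, i.e. the phantom voxel size is taken to be
#' the camera pixel referred to the sample plane.
#'
#' @param phantom A [phantom()].
#' @param grid A [lenslet_grid()].
#' @param config A [spot_config()].
#' @param psf Optional [psf_model()] applied to every projection.
#' @param density Optional override 3D array projected instead of the
#'   phantom's density (used for per-label rendering).
#' @return Numeric frame matrix of side `6 * n`.
#' @export
render_snapshot <- function(phantom, grid, config = attr(grid, "config"),
                            psf = NULL, density = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(grid, "lenslet_grid"))
  vol <- if (is.null(density)) phantom$density else density
  n <- dim(vol)[1]
  ang <- viewing_angles(grid, config)
  ms <- sort(unique(grid$m)); ns <- sort(unique(grid$n))
  frame <- matrix(0, length(ns) * n, length(ms) * n)
  for (q in seq_len(nrow(ang))) {
    i <- match(ang$n[q], ns); j <- match(ang$m[q], ms)
    p <- project_phantom(vol, ang$alpha_rad[q], ang$beta_rad[q], psf,
                         voxel_um = phantom$voxel_um)
    frame[(i - 1) * n + seq_len(n), (j - 1) * n + seq_len(n)] <- p
  }
  frame[frame < 0] <- 0   # clip numerical ringing; intensities are physical
  frame
}

#' Sample an OPD axis with stage nonlinearity
#'
#' Nominally uniform positions over the span, with seeded Gaussian
#' jitter of the given RMS on the interior points emulating the slight
#' nonlinearity of the translation stage. Endpoints are kept fixed, so
#' the mean step is exactly `span / (n - 1)` for any jitter.
#'
#' @param n Number of positions (2000 for the reference acquisition).
#' @param span_um Total OPD span (200), centred on zero.
#' @param nonlinearity_rms_um Jitter RMS in micrometres (0 = exactly
#'   uniform).
#' @param seed RNG seed for the jitter.
#' @return An [opd_axis()]. Jitter large enough to break monotonicity is
#'   an error.
#' @export
sample_opd_axis <- function(n = 2000, span_um = 200, nonlinearity_rms_um = 0,
                            seed = 1) {
  stopifnot(n >= 8, span_um > 0, nonlinearity_rms_um >= 0)
  pos <- seq(-span_um / 2, span_um / 2, length.out = n)
  if (nonlinearity_rms_um > 0) {
    jit <- .with_seed(seed, stats::rnorm(n - 2, 0, nonlinearity_rms_um))
    pos[2:(n - 1)] <- pos[2:(n - 1)] + jit
  }
  if (any(diff(pos) <= 0))
    stop("stage nonlinearity too large: OPD positions not strictly increasing")
  opd_axis(pos)
}

#' Synthesize interferogram frames from per-pixel emitters
#'
#' For an incoherent emitter of brightness B and normalized spectral
#' density S, the two-beam interferogram is
#' `I(delta) = B * integral S(sigma) (1 + cos(2 pi sigma delta)) dsigma`,
#' so `I(0) = 2B` and the large-OPD mean is B. Emitters with different
#' spectra add linearly. Optional camera noise is applied frame-wise.
#'
#' @param emitters A list of components, each a list with `brightness`
#'   (H x W matrix, or scalar) and `spectrum` (an
#'   [emission_spectrum()]); or a single such component.
#' @param opd An [opd_axis()].
#' @param noise Optional [noise_model()].
#' @return An [interferogram_stack()].
#' @export
synth_interferograms <- function(emitters, opd, noise = NULL) {
  opd <- opd_axis(opd)
  if (!is.null(emitters$brightness)) emitters <- list(emitters)
  br <- lapply(emitters, function(e) as.matrix(e$brightness))
  d <- dim(br[[1]])
  N <- length(opd$positions_um)
  out <- array(0, dim = c(N, d[1], d[2]))
  for (l in seq_along(emitters)) {
    ker <- .interferogram_kernel(emitters[[l]]$spectrum, opd$positions_um)
    out <- out + outer(ker, br[[l]])
  }
  out <- .apply_noise(out, noise)
  interferogram_stack(out, opd)
}

#' Simulate a full SPOT-FTS acquisition
#'
#' End-to-end synthetic dataset: the phantom is projected through every
#' valid lenslet into a snapshot frame, separately per spectral label
#' (projected spectra mix linearly along rays, as incoherent
#' fluorescence adds), and each pixel's interferogram is synthesized
#' over the OPD sweep with optional camera noise. With a fixed seed the
#' output is bit-identical across runs.
#'
#' @param phantom A [phantom()].
#' @param grid A [lenslet_grid()].
#' @param config A [spot_config()].
#' @param opd An [opd_axis()].
#' @param psf Optional [psf_model()] per-lenslet blur.
#' @param noise Optional [noise_model()].
#' @return An [interferogram_stack()] of snapshot frames.
#' @export
simulate_acquisition <- function(phantom, grid, config = attr(grid, "config"),
                                 opd = sample_opd_axis(), psf = NULL,
                                 noise = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  labs <- setdiff(sort(unique(as.vector(phantom$labels))), 0L)
  emitters <- lapply(labs, function(l) {
    dens <- phantom$density * (phantom$labels == l)
    list(brightness = render_snapshot(phantom, grid, config, psf,
                                      density = dens),
         spectrum = phantom$spectra[[l]])
  })
  st <- synth_interferograms(emitters, opd, noise)
  st$metadata$phantom_dim <- dim(phantom$density)
  st
}
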