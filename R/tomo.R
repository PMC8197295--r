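# FFT frequency axis in cycles per sample, FFT bin order
.fftfreq <- function(n) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / n
}

# circular 2D convolution via FFT; kernel given centered, any odd size
.fft_conv2 <- function(img, kernel, conjugate = FALSE) {
  n <- dim(img)
  kp <- matrix(0, n[1], n[2])
  kc <- dim(kernel)
  ci <- floor(kc / 2)
  ri <- ((seq_len(kc[1]) - 1 - ci[1]) %% n[1]) + 1
  cj <- ((seq_len(kc[2]) - 1 - ci[2]) %% n[2]) + 1
  kp[ri, cj] <- kp[ri, cj] + kernel
  K <- stats::fft(kp)
  if (conjugate) K <- Conj(K)
  Re(stats::fft(stats::fft(img) * K, inverse = TRUE)) / (n[1] * n[2])
}

#' Blur kernel of a single lenslet image
#'
#' The per-lenslet blur is modeled as an isotropic kernel whose FWHM
#' equals the lenslet diffraction limit at the working wavelength:
#' a Gaussian by default, or the separable sinc^2 pattern of the square
#' lenslet aperture. The kernel is non-negative and normalized to unit
#' sum.
#'
#' @param fwhm_um Kernel FWHM in micrometres (typically
#'   [lenslet_diffraction_limit()]).
#' @param pixel_um Image pixel pitch at the sample plane in micrometres.
#' @param shape `"gaussian"` or `"sinc2"`.
#' @param radius_fwhm Kernel support half-width in FWHM units.
#' @return A `psf_model`: list with the `kernel` matrix (odd side),
#'   `fwhm_um`, `pixel_um`, `shape`.
#' @export
psf_model <- function(fwhm_um, pixel_um, shape = c("gaussian", "sinc2"),
                      radius_fwhm = 3) {
  shape <- match.arg(shape)
  stopifnot(fwhm_um > 0, pixel_um > 0)
  r <- max(1L, ceiling(radius_fwhm * fwhm_um / pixel_um))
  x <- seq(-r, r) * pixel_um
  if (shape == "gaussian") {
    s <- fwhm_um / 2.3548200450309493
    k1 <- exp(-x^2 / (2 * s^2))
  } else {
    # sinc^2 with its own FWHM scaled to fwhm_um (sinc^2 half max at 0.4429/a)
    a <- 0.88589 / fwhm_um
    k1 <- (sinc <- function(u) ifelse(u == 0, 1, sin(pi * u) / (pi * u)))(a * x)^2
  }
  kern <- outer(k1, k1)
  kern <- kern / sum(kern)
  out <- list(kernel = kern, fwhm_um = fwhm_um, pixel_um = pixel_um,
              shape = shape)
  class(out) <- "psf_model"
  out
}

# delta kernel convenience (no blur)
psf_delta <- function(pixel_um = 1) {
  out <- list(kernel = matrix(1, 1, 1), fwhm_um = 0, pixel_um = pixel_um,
              shape = "delta")
  class(out) <- "psf_model"
  out
}

#' Split a raw camera frame into per-lenslet sub-images
#'
#' Each raw frame is a tiling of the projection images formed by the
#' individual lenslets. The frame is cut on the regular lenslet grid
#' (row = n index, column = m index, ascending), anchored at a
#' configurable origin, and each tile is paired with its viewing angle.
#' Only valid in-pupil lenslets are kept.
#'
#' @param frame Numeric matrix (rows = y = camera rows).
#' @param grid A [lenslet_grid()].
#' @param config A [spot_config()].
#' @param subimage_px Side of one tile in pixels; defaults to
#'   `floor(mla_pitch_um * relay2_mag / camera_pixel_um)` (about 153 for
#'   the default configuration).
#' @param origin Pixel (row, col) of the top-left corner of the first
#'   tile, 1-based.
#' @return A `projection_set`: list of square `subimages` in grid-row
#'   order, matching data.frame `angles` (m, n, alpha_rad, beta_rad),
#'   and `pixel_um`, the sub-image pixel pitch at the sample plane.
#' @export
extract_lenslet_subimages <- function(frame, grid, config = attr(grid, "config"),
                                      subimage_px = NULL, origin = c(1, 1)) {
  stopifnot(is.matrix(frame), inherits(grid, "lenslet_grid"))
  if (is.null(subimage_px))
    subimage_px <- floor(config$mla_pitch_um * config$relay2_mag /
                           config$camera_pixel_um)
  ms <- sort(unique(grid$m)); ns <- sort(unique(grid$n))
  need <- c(length(ns), length(ms)) * subimage_px + origin - 1
  if (origin[1] < 1 || origin[2] < 1 || any(need > dim(frame)))
    stop(sprintf("frame %d x %d too small for %d x %d tiles of %d px at origin (%d, %d)",
                 nrow(frame), ncol(frame), length(ns), length(ms),
                 subimage_px, origin[1], origin[2]))
  ang <- viewing_angles(grid, config)
  subimages <- vector("list", nrow(ang))
  for (q in seq_len(nrow(ang))) {
    i <- match(ang$n[q], ns); j <- match(ang$m[q], ms)
    r0 <- origin[1] + (i - 1) * subimage_px
    c0 <- origin[2] + (j - 1) * subimage_px
    subimages[[q]] <- frame[r0:(r0 + subimage_px - 1), c0:(c0 + subimage_px - 1)]
  }
  projection_set(subimages, ang, pixel_um = pixel_resolution_at_sample(config))
}

#' Projection set container
#'
#' @param subimages List of equal-sized square numeric matrices, one
#'   parallel-projection image per lenslet, in sample-plane coordinates.
#' @param angles Data.frame with columns `m`, `n`, `alpha_rad`,
#'   `beta_rad`, one row per sub-image.
#' @param pixel_um Pixel pitch at the sample plane (micrometres).
#' @return A `projection_set` object.
#' @export
projection_set <- function(subimages, angles, pixel_um) {
  stopifnot(length(subimages) == nrow(angles), pixel_um > 0)
  dims <- vapply(subimages, function(x) dim(as.matrix(x)), integer(2))
  if (length(subimages) && (any(dims != dims[1, 1])))
    stop("all sub-images must be square and of identical size")
  if (any(abs(angles$alpha_rad) >= pi / 2) || any(abs(angles$beta_rad) >= pi / 2))
    stop("viewing angles must be below 90 degrees")
  out <- list(subimages = lapply(subimages, as.matrix), angles = angles,
              pixel_um = pixel_um)
  class(out) <- "projection_set"
  out
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("Projection set: %d sub-images of %d px, pixel %.3g um, max angle %.1f deg\n",
              length(x$subimages), nrow(x$subimages[[1]]), x$pixel_um,
              max(abs(c(x$angles$alpha_rad, x$angles$beta_rad))) * 180 / pi))
  invisible(x)
}

#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative Richardson-Lucy update for incoherent
#' imaging: `e <- e * corr(img / conv(e, h), h)`, starting from a flat
#' estimate. The update conserves total flux and preserves
#' non-negativity. Convolutions are circular (FFT-based); objects should
#' be supported away from the frame boundary.
#'
#' @param image Non-negative numeric matrix.
#' @param psf A [psf_model()].
#' @param iterations Number of updates (>= 1).
#' @return Deconvolved matrix, non-negative.
#' @export
richardson_lucy <- function(image, psf, iterations = 10) {
  stopifnot(is.matrix(image), inherits(psf, "psf_model"), iterations >= 1)
  if (min(image) < -1e-12 * max(abs(image)))
    stop("image must be non-negative; clip or offset before deconvolving")
  image[image < 0] <- 0   # floating-point dust only, given the check above
  if (psf$fwhm_um == 0 || all(dim(psf$kernel) == 1)) return(image)
  est <- matrix(mean(image), nrow(image), ncol(image))
  eps <- .Machine$double.eps * max(image)
  for (it in seq_len(iterations)) {
    denom <- .fft_conv2(est, psf$kernel)
    ratio <- image / pmax(denom, eps)
    est <- est * .fft_conv2(ratio, psf$kernel, conjugate = TRUE)
    est[est < 0] <- 0
  }
  est
}

#' Empty Fourier volume for slice accumulation
#'
#' Holds the 3D spatial-frequency samples accumulated from the 2D
#' transforms of the projection images, together with per-voxel gridding
#' weights for later normalization.
#'
#' @param n Cubic grid side (voxels).
#' @param voxel_um Isotropic voxel size in micrometres.
#' @return A `fourier_volume`: complex `values` array, numeric `weight`
#'   array, `n`, `voxel_um`.
#' @export
fourier_volume <- function(n, voxel_um) {
  stopifnot(n >= 2, voxel_um > 0)
  out <- list(values = array(0 + 0i, dim = c(n, n, n)),
              weight = array(0, dim = c(n, n, n)),
              n = as.integer(n), voxel_um = voxel_um)
  class(out) <- "fourier_volume"
  out
}

#' Insert a projection into the Fourier volume (Fourier slice theorem)
#'
#' For a parallel projection along the direction with slopes
#' `(tan alpha, tan beta, 1)`, the 2D Fourier transform of the
#' projection image equals the central plane
#' `kz = -(kx tan alpha + ky tan beta)` of the object's 3D transform --
#' the plane through the origin with normal parallel to the viewing
#' direction. Each 2D sample lands on its exact `(kx, ky)` column and is
#' spread linearly over the two neighbouring `kz` planes; values and
#' interpolation weights are accumulated for later normalization.
#'
#' @param volume A [fourier_volume()].
#' @param projection Square numeric matrix (rows = y), same pixel pitch
#'   as the volume voxel size.
#' @param alpha_rad,beta_rad Viewing angle components (|angle| < pi/2).
#' @return The updated `fourier_volume`.
#' @export
fourier_slice_insert <- function(volume, projection, alpha_rad, beta_rad) {
  stopifnot(inherits(volume, "fourier_volume"), is.matrix(projection))
  n <- volume$n
  if (!all(dim(projection) == n))
    stop("projection must match the volume grid side")
  if (abs(alpha_rad) >= pi / 2 || abs(beta_rad) >= pi / 2)
    stop("viewing angle magnitude must be below 90 degrees")
  a <- tan(alpha_rad); b <- tan(beta_rad)
  P2 <- stats::fft(projection)          # dim (y, x) = (ky, kx) bins
  f <- .fftfreq(n)
  ky <- matrix(f, n, n); kx <- matrix(f, n, n, byrow = TRUE)
  kz <- -(a * kx + b * ky)              # cycles per voxel
  iz <- kz * n                          # fractional kz bin
  i0 <- floor(iz)
  w1 <- iz - i0
  iy <- matrix(seq_len(n), n, n); ix <- matrix(seq_len(n), n, n, byrow = TRUE)
  id0 <- cbind(as.vector(iy), as.vector(ix), as.vector((i0 %% n) + 1))
  id1 <- cbind(as.vector(iy), as.vector(ix), as.vector(((i0 + 1) %% n) + 1))
  v <- as.vector(P2); w0v <- as.vector(1 - w1); w1v <- as.vector(w1)
  volume$values[id0] <- volume$values[id0] + v * w0v
  volume$values[id1] <- volume$values[id1] + v * w1v
  volume$weight[id0] <- volume$weight[id0] + w0v
  volume$weight[id1] <- volume$weight[id1] + w1v
  volume
}

#' Invert an accumulated Fourier volume
#'
#' Normalizes the accumulated samples by their gridding weights (cells
#' never touched by any projection plane -- the missing cone -- stay
#' zero) and takes the real part of the 3D inverse Fourier transform.
#' The projection model measures z from the centre slice, so the result
#' is circularly shifted to put the z origin at slice `floor(n/2) + 1`.
#'
#' @param volume A [fourier_volume()] with at least one inserted plane.
#' @return A `tomogram`: list with 3D `intensity` array (y, x, z),
#'   `voxel_um`, and optional `wavelength_nm` tag.
#' @export
invert_fourier_volume <- function(volume) {
  stopifnot(inherits(volume, "fourier_volume"))
  if (sum(volume$weight) == 0) stop("no projection planes have been inserted")
  F <- volume$values
  pos <- volume$weight > 0
  F[pos] <- F[pos] / volume$weight[pos]
  F[!pos] <- 0
  n <- volume$n
  x <- Re(stats::fft(F, inverse = TRUE)) / n^3
  z0 <- floor(n / 2) + 1
  x <- x[, , ((seq_len(n) - z0) %% n) + 1, drop = FALSE]
  tomogram(x, volume$voxel_um)
}

#' Tomogram container
#'
#' @param intensity 3D numeric array (y, x, z).
#' @param voxel_um Isotropic voxel size in micrometres.
#' @param wavelength_nm Optional wavelength tag.
#' @return A `tomogram` object.
#' @export
tomogram <- function(intensity, voxel_um, wavelength_nm = NA_real_) {
  stopifnot(length(dim(intensity)) == 3, voxel_um > 0)
  if (any(!is.finite(intensity))) stop("tomogram intensities must be finite")
  out <- list(intensity = intensity, voxel_um = voxel_um,
              wavelength_nm = wavelength_nm)
  class(out) <- "tomogram"
  out
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("Tomogram: %d x %d x %d voxels of %.3g um%s\n", d[1], d[2], d[3],
              x$voxel_um,
              if (is.na(x$wavelength_nm)) "" else
                sprintf(" at %g nm", x$wavelength_nm)))
  invisible(x)
}

#' Positivity refinement of a limited-angle reconstruction
#'
#' Alternating projections between the physical constraint (fluorescence
#' intensity is non-negative) and the data constraint (the measured
#' Fourier planes are kept): clip negatives in real space, transform,
#' restore the weight-normalized measured samples where gridding weight
#' is positive, transform back, repeat. This partially fills the missing
#' cone and reduces the axial elongation of the reconstruction. Iterates
#' until `iterations` or until the negativity energy falls below
#' `tol` times the total energy.
#'
#' @param tomo A [tomogram()] (typically from
#'   [invert_fourier_volume()]).
#' @param volume The [fourier_volume()] holding the measured planes.
#' @param iterations Maximum iterations (>= 0); 0 returns the
#'   non-negativity-clipped input.
#' @param tol Early-stop threshold on the negativity energy fraction.
#' @return The refined `tomogram`, non-negative everywhere, with the
#'   per-iteration measured-plane residuals in attribute `"residuals"`.
#' @export
positivity_refine <- function(tomo, volume, iterations = 50, tol = 1e-4) {
  stopifnot(inherits(tomo, "tomogram"), inherits(volume, "fourier_volume"),
            iterations >= 0)
  n <- volume$n
  pos <- volume$weight > 0
  Fmeas <- volume$values
  Fmeas[pos] <- Fmeas[pos] / volume$weight[pos]
  # tomograms carry the z origin at slice floor(n/2)+1 (see
  # invert_fourier_volume); express the measured planes in that frame
  pz <- exp(-2i * pi * (seq_len(n) - 1) * (floor(n / 2)) / n)
  Fmeas <- sweep(Fmeas, 3, pz, "*")
  x <- tomo$intensity
  resid <- numeric(0)
  for (it in seq_len(iterations)) {
    x[x < 0] <- 0
    X <- stats::fft(x)
    resid <- c(resid, sqrt(sum(Mod(X[pos] - Fmeas[pos])^2)))
    X[pos] <- Fmeas[pos]
    x <- Re(stats::fft(X, inverse = TRUE)) / n^3
    neg <- sum(x[x < 0]^2)
    if (neg <= tol * sum(x^2)) break
  }
  x[x < 0] <- 0
  out <- tomogram(x, tomo$voxel_um, tomo$wavelength_nm)
  attr(out, "residuals") <- resid
  out
}

#' Reconstruct a tomogram from a set of lenslet projections
#'
#' The full inverse pipeline: Richardson-Lucy deconvolution of each
#' sub-image with the lenslet blur, insertion of each deconvolved
#' projection's 2D Fourier transform onto its tilted central plane,
#' weight-normalized 3D inversion, and positivity refinement. The
#' reconstruction grid is an isotropic cube with side equal to the
#' sub-image side and voxel size equal to the sub-image pixel pitch.
#'
#' @param projections A [projection_set()] with at least two distinct
#'   viewing angles.
#' @param psf A [psf_model()] for the deconvolution, or `NULL` to skip
#'   deconvolution.
#' @param rl_iterations Richardson-Lucy iterations (default 10).
#' @param positivity_iterations Positivity iterations (default 50).
#' @param wavelength_nm Optional wavelength tag for the output.
#' @return A `tomogram`.
#' @export
reconstruct_tomogram <- function(projections, psf = NULL, rl_iterations = 10,
                                 positivity_iterations = 50,
                                 wavelength_nm = NA_real_) {
  stopifnot(inherits(projections, "projection_set"))
  ang <- projections$angles
  if (nrow(unique(ang[, c("alpha_rad", "beta_rad")])) < 2)
    stop("reconstruction needs at least two distinct viewing angles")
  n <- nrow(projections$subimages[[1]])
  vol <- fourier_volume(n, projections$pixel_um)
  for (q in seq_along(projections$subimages)) {
    img <- projections$subimages[[q]]
    img[img < 0] <- 0   # amplitude data; simulated projections may ring
    if (!is.null(psf))
      img <- richardson_lucy(img, psf, rl_iterations)
    vol <- fourier_slice_insert(vol, img, ang$alpha_rad[q], ang$beta_rad[q])
  }
  tomo <- invert_fourier_volume(vol)
  tomo <- positivity_refine(tomo, vol, positivity_iterations)
  tomo$wavelength_nm <- wavelength_nm
  tomo
}

#' Gaussian-fit FWHM of a blob along one axis
#'
#' Extracts the 1D intensity profile through the maximum-intensity voxel
#' along the requested axis, fits a Gaussian (amplitude, centre, sigma,
#' baseline) by least squares, and returns `2.3548 * sigma` in
#' micrometres.
#'
#' @param tomo A [tomogram()] with a single dominant blob.
#' @param axis `"x"`, `"y"`, or `"z"`.
#' @return FWHM in micrometres.
#' @export
measure_fwhm_3d <- function(tomo, axis = c("x", "y", "z")) {
  stopifnot(inherits(tomo, "tomogram"))
  axis <- match.arg(axis)
  arr <- tomo$intensity
  pk <- arrayInd(which.max(arr), dim(arr))
  prof <- switch(axis,
                 y = arr[, pk[2], pk[3]],
                 x = arr[pk[1], , pk[3]],
                 z = arr[pk[1], pk[2], ])
  .gaussian_fwhm_1d(prof) * tomo$voxel_um
}

# least-squares Gaussian fit of a 1D profile; returns FWHM in samples
.gaussian_fwhm_1d <- function(prof) {
  n <- length(prof)
  x <- seq_len(n)
  i0 <- which.max(prof)
  amp0 <- max(prof) - min(prof)
  if (amp0 <= 0) stop("profile is flat; Gaussian fit failed")
  # moment start for sigma
  w <- pmax(prof - min(prof), 0)
  s0 <- sqrt(sum(w * (x - sum(w * x) / sum(w))^2) / sum(w))
  obj <- function(p) {
    mu <- p[1]; lsig <- p[2]; amp <- p[3]; base <- p[4]
    sum((base + amp * exp(-(x - mu)^2 / (2 * exp(2 * lsig))) - prof)^2)
  }
  fit <- stats::optim(c(i0, log(max(s0, 0.5)), amp0, min(prof)), obj,
                      method = "BFGS", control = list(maxit = 500))
  if (!is.finite(fit$value)) stop("Gaussian fit failed")
  2.3548200450309493 * exp(fit$par[2])
}
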