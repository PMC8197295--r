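#' Optical system configuration
#'
#' Bundles the parameters of the SPOT optical train: infinity-corrected
#' objective, demagnifying relay onto the objective back focal plane (BFP)
#' where the micro-lens array (MLA) sits, a second relay stage, and the
#' camera. The objective focal length is derived from the manufacturer
#' reference tube length, `f1 = reference_tube_focal_mm / objective_magnification`.
#'
#' @param objective_magnification Nominal objective magnification (60).
#' @param objective_na Objective numerical aperture (1.4, oil immersion).
#' @param reference_tube_focal_mm Manufacturer tube-lens reference focal
#'   length in mm (200 for the Nikon convention); configurable for other
#'   manufacturers.
#' @param relay_demag Demagnification of the relay that images the pupil
#'   onto the MLA plane (2.86).
#' @param mla_pitch_um Micro-lens pitch in micrometres (500).
#' @param mla_focal_mm Micro-lens focal length in mm (13.8); the MLA acts
#'   as the tube lens.
#' @param relay2_mag Magnification of the second relay stage (4).
#' @param camera_pixel_um Physical camera pixel size in micrometres (13).
#' @param design_wavelength_nm Design wavelength in nm used for
#'   diffraction-limit calculations (530).
#' @param immersion_index Refractive index of the immersion medium; the
#'   numerical aperture must not exceed it.
#'
#' @return An object of class `spot_config` (a named list) with the
#'   supplied fields plus the derived objective focal length
#'   `objective_focal_mm`.
#' @examples
#' cfg <- spot_config()
#' overall_magnification(cfg)
#' @export
spot_config <- function(objective_magnification = 60,
                        objective_na = 1.4,
                        reference_tube_focal_mm = 200,
                        relay_demag = 2.86,
                        mla_pitch_um = 500,
                        mla_focal_mm = 13.8,
                        relay2_mag = 4,
                        camera_pixel_um = 13,
                        design_wavelength_nm = 530,
                        immersion_index = 1.518) {
  vals <- c(objective_magnification, objective_na, reference_tube_focal_mm,
            relay_demag, mla_pitch_um, mla_focal_mm, relay2_mag,
            camera_pixel_um, design_wavelength_nm, immersion_index)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all spot_config parameters must be positive and finite")
  if (objective_na >= immersion_index)
    stop("objective_na must be below the immersion refractive index")
  cfg <- list(
    objective_magnification = objective_magnification,
    objective_na = objective_na,
    reference_tube_focal_mm = reference_tube_focal_mm,
    relay_demag = relay_demag,
    mla_pitch_um = mla_pitch_um,
    mla_focal_mm = mla_focal_mm,
    relay2_mag = relay2_mag,
    camera_pixel_um = camera_pixel_um,
    design_wavelength_nm = design_wavelength_nm,
    immersion_index = immersion_index,
    objective_focal_mm = reference_tube_focal_mm / objective_magnification
  )
  class(cfg) <- "spot_config"
  cfg
}

#' @export
print.spot_config <- function(x, ...) {
  cat("SPOT system configuration\n")
  cat(sprintf("  objective: %gx / NA %g (f1 = %.4g mm)\n",
              x$objective_magnification, x$objective_na, x$objective_focal_mm))
  cat(sprintf("  MLA: pitch %g um, focal %g mm; relay demag %g; relay2 x%g\n",
              x$mla_pitch_um, x$mla_focal_mm, x$relay_demag, x$relay2_mag))
  cat(sprintf("  camera pixel %g um; design wavelength %g nm\n",
              x$camera_pixel_um, x$design_wavelength_nm))
  cat(sprintf("  overall magnification %.4g, FOV %.4g um, pixel at sample %.4g um\n",
              overall_magnification(x), field_of_view(x),
              pixel_resolution_at_sample(x)))
  invisible(x)
}

#' Lenslet grid behind the objective pupil
#'
#' The MLA tiles the (relayed) back focal plane with square lenslets on a
#' 6x6 grid indexed by half-integers `m, n` in {-2.5, ..., 2.5}; lenslet
#' (m, n) is centred at (m p, n p) where `p` is the pitch referred to the
#' BFP (`mla_pitch_um * relay_demag`). A lenslet is flagged `in_pupil`
#' when its centre radius stays inside the pupil radius `NA * f1`, and
#' `valid` when additionally the viewing-angle formula is defined for it
#' (centre radius below `f1`, see [viewing_angles()]).
#'
#' @param config A [spot_config()].
#' @param indices Optional two-column matrix or data.frame of (m, n)
#'   half-integer indices; defaults to the full 6x6 grid.
#' @return A `lenslet_grid` object: data.frame with columns `m`, `n`,
#'   `in_pupil`, `valid`, and attributes `pitch_at_bfp_um`, `config`.
#' @export
lenslet_grid <- function(config = spot_config(), indices = NULL) {
  if (is.null(indices)) {
    half <- seq(-2.5, 2.5, by = 1)
    indices <- expand.grid(m = half, n = half)
  }
  indices <- as.data.frame(indices)
  names(indices)[1:2] <- c("m", "n")
  p_mm <- config$mla_pitch_um * config$relay_demag / 1000
  f1 <- config$objective_focal_mm
  r_mm <- sqrt(indices$m^2 + indices$n^2) * p_mm
  pupil_mm <- config$objective_na * f1
  g <- data.frame(m = indices$m, n = indices$n,
                  in_pupil = r_mm <= pupil_mm,
                  valid = (r_mm <= pupil_mm) & (r_mm < f1))
  attr(g, "pitch_at_bfp_um") <- p_mm * 1000
  attr(g, "config") <- config
  class(g) <- c("lenslet_grid", "data.frame")
  g
}

#' Viewing angles of the lenslet projections
#'
#' Each lenslet records a parallel projection of the sample along a
#' direction set by its position in the pupil. The projection of the
#' viewing direction onto the x-z plane makes the angle
#' `alpha_m = atan(m p / sqrt(f1^2 - (m^2 + n^2) p^2))` with the optical
#' axis, and `beta_n` analogously with `n p`, where `p` is the lenslet
#' pitch referred to the objective BFP and `f1` the objective focal
#' length. Lenslets whose centre radius reaches `f1` have no defined
#' direction under this model and are excluded, as are lenslets outside
#' the pupil.
#'
#' @param grid A [lenslet_grid()].
#' @param config A [spot_config()]; defaults to the grid's own.
#' @return A data.frame with columns `m`, `n`, `alpha_rad`, `beta_rad`,
#'   one row per valid in-pupil lenslet, in the order of the grid rows.
#' @examples
#' va <- viewing_angles(lenslet_grid())
#' range(va$alpha_rad) * 180 / pi
#' @export
viewing_angles <- function(grid, config = attr(grid, "config")) {
  stopifnot(inherits(grid, "lenslet_grid"))
  p_mm <- attr(grid, "pitch_at_bfp_um") / 1000
  f1 <- config$objective_focal_mm
  keep <- grid$valid
  m <- grid$m[keep]; n <- grid$n[keep]
  den <- sqrt(f1^2 - (m^2 + n^2) * p_mm^2)
  out <- data.frame(m = m, n = n,
                    alpha_rad = atan2(m * p_mm, den),
                    beta_rad = atan2(n * p_mm, den))
  if (!nrow(out)) stop("no valid in-pupil lenslets for this configuration")
  out
}

#' Overall lateral magnification of the optical train
#'
#' `M = (mla_focal / f1) * relay_demag * relay2_mag` with
#' `f1 = reference_tube_focal / objective_magnification`: the MLA acts as
#' the tube lens of the infinity-corrected objective, the pupil relay
#' demagnification enlarges the image by the same factor, and the second
#' relay magnifies again.
#'
#' @param config A [spot_config()].
#' @return Dimensionless magnification (about 47.4 for the default
#'   configuration).
#' @export
overall_magnification <- function(config = spot_config()) {
  (config$mla_focal_mm / config$objective_focal_mm) *
    config$relay_demag * config$relay2_mag
}

#' Field of view of one lenslet sub-image at the sample plane
#'
#' One lenslet sub-image covers `mla_pitch * relay2_mag` at the camera;
#' referred back to the sample it spans
#' `mla_pitch_um * relay2_mag / M` micrometres.
#'
#' @param config A [spot_config()].
#' @return Field of view in micrometres (about 42 um by default).
#' @export
field_of_view <- function(config = spot_config()) {
  config$mla_pitch_um * config$relay2_mag / overall_magnification(config)
}

#' Camera pixel size referred to the sample plane
#'
#' @param config A [spot_config()].
#' @return `camera_pixel_um / M` in micrometres (about 0.27 um by default).
#' @export
pixel_resolution_at_sample <- function(config = spot_config()) {
  config$camera_pixel_um / overall_magnification(config)
}

#' Diffraction limit of a single lenslet
#'
#' A lenslet uses only a patch of the pupil, so its effective numerical
#' aperture is the aperture extent referred to the BFP over twice the
#' objective focal length: `NA_lenslet = (extent * relay_demag / 2) / f1`,
#' with extent the lenslet pitch (`aperture = "width"`) or `pitch * sqrt(2)`
#' (`aperture = "diagonal"` of the square aperture). The transverse
#' resolution is then `lambda / (2 NA_lenslet)`.
#'
#' @param config A [spot_config()].
#' @param aperture `"width"` or `"diagonal"`.
#' @param wavelength_nm Wavelength in nm; defaults to the design
#'   wavelength.
#' @return Resolution in micrometres (1.24 um width / 0.87 um diagonal at
#'   530 nm for the default configuration).
#' @export
lenslet_diffraction_limit <- function(config = spot_config(),
                                      aperture = c("width", "diagonal"),
                                      wavelength_nm = config$design_wavelength_nm) {
  aperture <- match.arg(aperture)
  if (wavelength_nm <= 0) stop("wavelength must be positive")
  extent_um <- config$mla_pitch_um * if (aperture == "diagonal") sqrt(2) else 1
  f1_um <- config$objective_focal_mm * 1000
  na_lenslet <- (extent_um * config$relay_demag / 2) / f1_um
  if (na_lenslet >= config$objective_na)
    stop("lenslet aperture exceeds the objective pupil (NA_lenslet >= NA)")
  (wavelength_nm / 1000) / (2 * na_lenslet)
}
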