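# Canonical on-disk layout: multi-page 32-bit TIFF for the array data
# (pages normalized to [0,1] as the format requires) plus a YAML sidecar
# next to it carrying axes, normalization scale/offset and metadata.
.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".yaml")

.write_pages <- function(pages, path) {
  lo <- min(vapply(pages, min, 0)); hi <- max(vapply(pages, max, 0))
  scale <- if (hi > lo) hi - lo else 1
  norm <- lapply(pages, function(p) (p - lo) / scale)
  tiff::writeTIFF(norm, path, bits.per.sample = 32L)
  list(offset = lo, scale = scale)
}

.read_pages <- function(path, norm) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) p * norm$scale + norm$offset)
}

#' Write / read an interferogram stack
#'
#' The stack is stored as a multi-page 32-bit TIFF (one page per OPD
#' frame, in OPD order) with a YAML sidecar (same basename, `.yaml`)
#' holding the OPD positions in micrometres, the intensity
#' normalization, and any metadata. Units are embedded in the sidecar
#' field names.
#'
#' @param stack An [interferogram_stack()].
#' @param path Output TIFF path.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns
#'   the validated [interferogram_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "interferogram_stack"))
  d <- dim(stack$intensities)
  pages <- lapply(seq_len(d[1]), function(j) stack$intensities[j, , ])
  norm <- .write_pages(pages, path)
  side <- list(format = "spotfts-stack-1",
               opd_um = as.numeric(stack$opd$positions_um),
               offset = norm$offset, scale = norm$scale,
               metadata = stack$metadata)
  yaml::write_yaml(side, .sidecar_path(path), precision = 15L)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  side <- yaml::read_yaml(.sidecar_path(path))
  pages <- .read_pages(path, side)
  if (length(pages) != length(side$opd_um))
    stop(sprintf("frame count (%d) does not match OPD count (%d)",
                 length(pages), length(side$opd_um)))
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (j in seq_along(pages)) arr[j, , ] <- pages[[j]]
  interferogram_stack(arr, opd_axis(side$opd_um),
                      metadata = if (is.null(side$metadata)) list() else side$metadata)
}

#' Write / read a hyperspectral cube
#'
#' One TIFF page per wavelength plane plus a YAML sidecar with the
#' wavenumber axis (cm^-1) at full precision and the signal mask.
#'
#' @param cube A `spectral_cube` from [process_stack()].
#' @param path Output TIFF path.
#' @return `write_cube` returns `path` invisibly; `read_cube` the
#'   restored `spectral_cube`.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$amplitudes)
  pages <- lapply(seq_len(d[1]), function(j) cube$amplitudes[j, , ])
  norm <- .write_pages(pages, path)
  side <- list(format = "spotfts-cube-1",
               wavenumber_cm1 = as.numeric(cube$wavenumber_cm1),
               offset = norm$offset, scale = norm$scale,
               mask = as.integer(cube$mask), mask_dim = dim(cube$mask),
               apodization = cube$apodization,
               failed_pixels = cube$failed_pixels)
  yaml::write_yaml(side, .sidecar_path(path), precision = 15L)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  side <- yaml::read_yaml(.sidecar_path(path))
  pages <- .read_pages(path, side)
  if (length(pages) != length(side$wavenumber_cm1))
    stop("page count does not match the wavenumber axis")
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (j in seq_along(pages)) arr[j, , ] <- pages[[j]]
  arr[arr < 0] <- 0
  out <- list(amplitudes = arr,
              wavenumber_cm1 = as.numeric(side$wavenumber_cm1),
              wavelength_nm = 1e7 / as.numeric(side$wavenumber_cm1),
              mask = array(as.logical(side$mask), unlist(side$mask_dim)),
              failed_pixels = side$failed_pixels,
              apodization = side$apodization,
              source_dim = NULL)
  class(out) <- "spectral_cube"
  out
}

#' Write / read a tomogram
#'
#' One TIFF page per z slice plus a YAML sidecar with voxel size and
#' wavelength tag.
#'
#' @param tomo A [tomogram()].
#' @param path Output TIFF path.
#' @return `write_tomogram` returns `path` invisibly; `read_tomogram`
#'   the restored [tomogram()].
#' @export
write_tomogram <- function(tomo, path) {
  stopifnot(inherits(tomo, "tomogram"))
  d <- dim(tomo$intensity)
  pages <- lapply(seq_len(d[3]), function(z) tomo$intensity[, , z])
  norm <- .write_pages(pages, path)
  side <- list(format = "spotfts-tomo-1",
               voxel_um = tomo$voxel_um,
               wavelength_nm = tomo$wavelength_nm,
               offset = norm$offset, scale = norm$scale)
  yaml::write_yaml(side, .sidecar_path(path), precision = 15L)
  invisible(path)
}

#' @rdname write_tomogram
#' @export
read_tomogram <- function(path) {
  side <- yaml::read_yaml(.sidecar_path(path))
  pages <- .read_pages(path, side)
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- pages[[z]]
  tomogram(arr, side$voxel_um,
           if (is.null(side$wavelength_nm)) NA_real_ else side$wavelength_nm)
}

.config_fields <- c("objective_magnification", "objective_na",
                    "reference_tube_focal_mm", "relay_demag", "mla_pitch_um",
                    "mla_focal_mm", "relay2_mag", "camera_pixel_um",
                    "design_wavelength_nm", "immersion_index")

#' Write / read a system configuration as YAML
#'
#' The configuration is a flat mapping of the [spot_config()] fields.
#' Unknown keys in a file are rejected rather than ignored, so typos do
#' not silently fall back to defaults.
#'
#' @param config A [spot_config()].
#' @param path YAML file path.
#' @return `write_spot_config` returns `path` invisibly;
#'   `read_spot_config` a validated [spot_config()].
#' @export
write_spot_config <- function(config, path) {
  stopifnot(inherits(config, "spot_config"))
  yaml::write_yaml(config[.config_fields], path, precision = 15L)
  invisible(path)
}

#' @rdname write_spot_config
#' @export
read_spot_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), .config_fields)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(spot_config, vals)
}
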