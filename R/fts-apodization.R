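# Norton-Beer apodization family: A(u) = sum_i c_i (1 - u^2)^i on u in
# [-1, 1], with the literature-standard coefficient sets. The
# coefficients of each kind sum to one so that the weight at zero OPD is
# exactly 1.
.norton_beer_coefs <- list(
  boxcar             = c(1),
  norton_beer_weak   = c(0.384093, -0.087577, 0.703484),
  norton_beer_medium = c(0.152442, -0.136176, 0.983734),
  norton_beer_strong = c(0.045335, 0, 0.554883, 0, 0.399782)
)

#' Apodization (interferogram taper) specification
#'
#' Apodization multiplies the interferogram by a weighting function
#' before the Fourier transform, trading spectral resolution for
#' suppression of the sinc sidelobes of plain truncation. The supported
#' family is Norton-Beer, `A(u) = sum_i c_i (1 - u^2)^i` with
#' `u = delta / delta_max` the OPD normalised to the half-span; `boxcar`
#' is the identity taper (no apodization).
#'
#' @param kind One of `"boxcar"`, `"norton_beer_weak"`,
#'   `"norton_beer_medium"`, `"norton_beer_strong"`. Hyphens may be used
#'   instead of underscores.
#' @return An `apodization` object with fields `kind` and `coefficients`.
#' @examples
#' sum(apodization("norton_beer_medium")$coefficients)  # exactly 1
#' @export
apodization <- function(kind = c("norton_beer_medium", "boxcar",
                                 "norton_beer_weak", "norton_beer_strong")) {
  if (inherits(kind, "apodization")) return(kind)
  kind <- gsub("-", "_", kind[1])
  kind <- match.arg(kind)
  out <- list(kind = kind, coefficients = .norton_beer_coefs[[kind]])
  class(out) <- "apodization"
  out
}

#' Evaluate an apodization window
#'
#' @param spec An [apodization()] (or a kind name).
#' @param u Normalised OPD, `delta / delta_max`; values with `|u| > 1`
#'   get weight 0.
#' @return Weights in `[0, 1]`, same length as `u`.
#' @export
apodization_window <- function(spec, u) {
  spec <- apodization(spec)
  w <- rep(0, length(u))
  inside <- abs(u) <= 1
  g <- 1 - u[inside]^2
  acc <- 0
  for (i in seq_along(spec$coefficients))
    acc <- acc + spec$coefficients[i] * g^(i - 1)
  w[inside] <- acc
  w
}

#' Apodize a centered interferogram
#'
#' Element-wise product of the series with the window evaluated at
#' `delta / delta_max`, where `delta_max = max(|delta|)` over the
#' (centered) OPD axis. Boxcar returns the input unchanged.
#'
#' @param series Numeric interferogram samples.
#' @param opd An [opd_axis()] whose positions straddle zero (centered).
#' @param spec An [apodization()] or kind name.
#' @return Weighted series, same length as the input.
#' @export
apodize <- function(series, opd, spec = apodization()) {
  spec <- apodization(spec)
  opd <- opd_axis(opd)
  delta <- opd$positions_um
  if (length(series) != length(delta))
    stop("series length must match the OPD axis")
  if (min(delta) > 0 || max(delta) < 0)
    stop("OPD axis must be centered (zero inside the span) before apodizing")
  if (spec$kind == "boxcar") return(series)
  series * apodization_window(spec, delta / max(abs(delta)))
}
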