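#' Optical configuration of the off-axis DHM system
#'
#' Bundles the physical constants of the holographic microscope that every
#' synthesis, reconstruction and fitting step needs: laser wavelength, buffer
#' refractive index, object-space pixel size, sensor geometry, the spatial
#' carrier frequency of the tilted off-axis reference wave, and the intensity
#' noise scale used when synthesizing holograms.
#'
#' Defaults describe a 532 nm laser with cells suspended in PBS-like buffer
#' (`n_medium = 1.337`, an Abbe-refractometer figure for the measurement
#' buffer) imaged at 0.1 um/px, which projects a typical lymphocyte
#' (radius 3.7 um) onto roughly 73 pixels so the sphere-model fit sees
#' several thousand in-mask pixels.
#'
#' @param wavelength Laser wavelength in um. Default 0.532.
#' @param n_medium Refractive index of the surrounding buffer medium.
#'   Default 1.337.
#' @param pixel_scale Object-space size of one pixel in um. Default 0.1.
#' @param image_shape Integer vector `c(rows, cols)`; both at least 64.
#' @param carrier_freq Spatial frequency of the off-axis carrier fringes in
#'   cycles per pixel, `c(f_row, f_col)`. Each component must lie strictly
#'   between 0 and 0.5 (the Nyquist limit) in absolute value.
#' @param noise_sigma Standard deviation of additive Gaussian intensity noise
#'   applied by [synthesize_hologram()], in units of the unit-amplitude
#'   interference intensity (which spans roughly 0 to 4). Default 0.01.
#'
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config()
#' cfg$wavelength
#' @export
optical_config <- function(wavelength = 0.532,
                           n_medium = 1.337,
                           pixel_scale = 0.1,
                           image_shape = c(128L, 128L),
                           carrier_freq = c(0.25, 0.25),
                           noise_sigma = 0.01) {
  stopifnot(
    is.numeric(wavelength), length(wavelength) == 1L, wavelength > 0,
    is.numeric(n_medium), length(n_medium) == 1L, n_medium > 1,
    is.numeric(pixel_scale), length(pixel_scale) == 1L, pixel_scale > 0,
    is.numeric(image_shape), length(image_shape) == 2L,
    is.numeric(carrier_freq), length(carrier_freq) == 2L,
    is.numeric(noise_sigma), length(noise_sigma) == 1L, noise_sigma >= 0
  )
  image_shape <- as.integer(image_shape)
  if (any(image_shape < 64L)) {
    stop("`image_shape` must be at least 64 x 64 pixels", call. = FALSE)
  }
  if (any(abs(carrier_freq) >= 0.5) || all(carrier_freq == 0)) {
    stop("`carrier_freq` components must lie in (0, 0.5) cycles/px in absolute value",
         call. = FALSE)
  }
  structure(
    list(
      wavelength = wavelength,
      n_medium = n_medium,
      pixel_scale = pixel_scale,
      image_shape = image_shape,
      carrier_freq = carrier_freq,
      noise_sigma = noise_sigma
    ),
    class = "optical_config"
  )
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  wavelength:   %.4g um\n", x$wavelength))
  cat(sprintf("  n_medium:     %.4f\n", x$n_medium))
  cat(sprintf("  pixel_scale:  %.4g um/px\n", x$pixel_scale))
  cat(sprintf("  image_shape:  %d x %d px\n", x$image_shape[1], x$image_shape[2]))
  cat(sprintf("  carrier_freq: (%.3f, %.3f) cycles/px\n",
              x$carrier_freq[1], x$carrier_freq[2]))
  cat(sprintf("  noise_sigma:  %.4g\n", x$noise_sigma))
  invisible(x)
}
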