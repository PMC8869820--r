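#' Complex object field
#'
#' The demodulated object wave of an off-axis hologram: a complex-valued
#' matrix plus the optical metadata needed for numerical propagation.
#'
#' @param field Complex matrix.
#' @param pixel_scale Object-space pixel size in um/px.
#' @param wavelength Wavelength in um.
#' @param n_medium Refractive index of the immersion/buffer medium.
#'
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(field, pixel_scale, wavelength, n_medium = 1.337) {
  stopifnot(is.matrix(field), is.complex(field) || is.numeric(field),
            pixel_scale > 0, wavelength > 0, n_medium >= 1)
  structure(
    list(field = as.complex(field) |> matrix(nrow(field), ncol(field)),
         pixel_scale = pixel_scale, wavelength = wavelength,
         n_medium = n_medium),
    class = "complex_field"
  )
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d px @ %.3g um/px, lambda %.4g um\n",
              nrow(x$field), ncol(x$field), x$pixel_scale, x$wavelength))
  invisible(x)
}

#' Numerical refocusing by angular-spectrum propagation
#'
#' Propagates a complex field along the optical axis by multiplying its
#' spectrum with the angular-spectrum kernel
#' \eqn{\exp(2\pi i z \sqrt{(n/\lambda)^2 - f_x^2 - f_y^2})}.  Evanescent
#' components (negative radicand) are suppressed.  For fields whose energy
#' lives entirely in the propagating band, propagation conserves energy and
#' `refocus(refocus(f, z), -z)` restores the input to numerical precision.
#'
#' @param field A [complex_field()].
#' @param distance Propagation distance in um (positive or negative).
#'
#' @return A [complex_field()] at the new focal plane.
#' @examples
#' f <- complex_field(matrix(complex(modulus = 1, argument = 0), 64, 64),
#'                    pixel_scale = 0.1, wavelength = 0.532)
#' g <- refocus(f, 5)
#' @export
refocus <- function(field, distance) {
  stopifnot(inherits(field, "complex_field"),
            is.numeric(distance), length(distance) == 1L, is.finite(distance))
  if (distance == 0) return(field)
  nr <- nrow(field$field)
  nc <- ncol(field$field)
  fy <- fft_freq(nr) / field$pixel_scale      # cycles / um, row direction
  fx <- fft_freq(nc) / field$pixel_scale      # cycles / um, column direction
  f2 <- outer(fy^2, rep(1, nc)) + outer(rep(1, nr), fx^2)
  rad <- (field$n_medium / field$wavelength)^2 - f2
  prop <- rad > 0
  kernel <- matrix(0 + 0i, nr, nc)
  kernel[prop] <- exp(2i * pi * distance * sqrt(rad[prop]))
  spec <- fft(field$field) * kernel
  out <- fft(spec, inverse = TRUE) / length(spec)
  complex_field(out, field$pixel_scale, field$wavelength, field$n_medium)
}

#' Autofocus search over a range of propagation distances
#'
#' For a pure phase object the in-focus amplitude image is maximally flat;
#' defocus converts phase structure into amplitude contrast.  The sharpness
#' criterion used here is therefore the standard deviation of the field
#' amplitude, which is minimal at best focus.
#'
#' @param field A [complex_field()].
#' @param distances Numeric vector of candidate propagation distances (um).
#'
#' @return A tibble with columns `distance` and `amplitude_sd`, plus
#'   attribute `best` (the distance minimizing `amplitude_sd`).
#' @export
autofocus <- function(field, distances) {
  stopifnot(inherits(field, "complex_field"), length(distances) >= 1)
  sharp <- vapply(distances, function(d) sd(Mod(refocus(field, d)$field)),
                  numeric(1))
  out <- tibble::tibble(distance = distances, amplitude_sd = sharp)
  attr(out, "best") <- distances[which.min(sharp)]
  out
}
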