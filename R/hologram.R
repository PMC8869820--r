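#' Synthesize an off-axis hologram from a phase image
#'
#' Interferes the object wave \eqn{O = \exp(i\varphi)} with a tilted plane
#' reference wave \eqn{R = \exp(2\pi i (f_r y + f_c x))} and records the
#' intensity \eqn{|O + R|^2 = 2 + 2\cos(\varphi - 2\pi(f_r y + f_c x))},
#' i.e. carrier fringes at the configured spatial frequency, locally bent by
#' the cell-induced phase.  Optional additive Gaussian intensity noise
#' models sensor noise; negative intensities are clipped at zero as a real
#' sensor would.
#'
#' @param phase A [phase_image()] (or bare matrix of radians).
#' @param config An [optical_config()]; supplies `carrier_freq` and the
#'   default `noise_sigma`.
#' @param noise_sigma Override for the intensity noise SD; `NULL` uses
#'   `config$noise_sigma`.
#' @param seed Optional seed for the noise draw.
#'
#' @return An object of class `hologram`: list with `intensity` matrix and
#'   the `optical_config` used.
#' @examples
#' cfg <- optical_config()
#' ph <- phantom_population(1, 3.675, 0, seed = 1)
#' holo <- synthesize_hologram(render_phase_image(ph, cfg), cfg)
#' @export
synthesize_hologram <- function(phase, config, noise_sigma = NULL, seed = NULL) {
  stopifnot(inherits(config, "optical_config"))
  phi <- as_phase_matrix(phase)
  if (!all(dim(phi) == config$image_shape)) {
    stop("phase image shape does not match `config$image_shape`", call. = FALSE)
  }
  check_carrier_separability(config)
  if (is.null(noise_sigma)) noise_sigma <- config$noise_sigma
  nr <- nrow(phi)
  nc <- ncol(phi)
  fr <- config$carrier_freq[1]
  fc <- config$carrier_freq[2]
  ramp <- 2 * pi * (outer((seq_len(nr) - 1) * fr, rep(1, nc)) +
                      outer(rep(1, nr), (seq_len(nc) - 1) * fc))
  intensity <- 2 + 2 * cos(phi - ramp)
  if (noise_sigma > 0) {
    intensity <- with_seed(seed, intensity + rnorm(length(intensity), 0, noise_sigma))
    intensity <- pmax(intensity, 0)
  }
  structure(list(intensity = intensity, config = config), class = "hologram")
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("<hologram> %d x %d px, carrier (%.3f, %.3f) cycles/px\n",
              nrow(x$intensity), ncol(x$intensity),
              x$config$carrier_freq[1], x$config$carrier_freq[2]))
  invisible(x)
}

# The carrier must sit far enough from DC that the +1 sideband can be cut
# out without touching the object band around DC.  A minimum carrier
# magnitude of 0.08 cycles/px keeps at least ~10 bins of clearance on a
# 128 px field.
check_carrier_separability <- function(config) {
  if (sqrt(sum(config$carrier_freq^2)) < 0.08) {
    stop("carrier frequency too close to DC for sideband separation",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Signed FFT bin frequencies in cycles per sample.
fft_freq <- function(n) {
  k <- 0:(n - 1)
  ((k + floor(n / 2)) %% n - floor(n / 2)) / n
}
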