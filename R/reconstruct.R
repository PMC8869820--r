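#' Reconstruct a quantitative phase image from an off-axis hologram
#'
#' Standard single-shot Fourier demodulation: the hologram spectrum is
#' computed with a 2-D FFT, the +1-order sideband is located as the
#' strongest peak outside the DC region (or nearest the configured
#' carrier), isolated with a Butterworth window, re-centred at zero
#' frequency, and transformed back to give the complex object wave.  Its
#' argument is unwrapped ([unwrap_phase()]) and a low-order polynomial
#' background, fitted to cell-free pixels, is subtracted so the cell-free
#' region has median phase close to zero.  Cells are denser than the buffer
#' and must carry positive phase; a reconstruction with predominantly
#' negative in-cell phase is sign-flipped and flagged.
#'
#' @param holo A `hologram` from [synthesize_hologram()] (or a list with
#'   elements `intensity` and `config`).
#' @param window_radius Butterworth window radius in cycles/px; default
#'   0.4 times the detected carrier magnitude.
#' @param window_order Butterworth order (default 5).
#' @param background_degree Degree of the polynomial background model
#'   (default 2, i.e. tilt plus curvature).
#' @param return_field If `TRUE`, the demodulated [complex_field()] is
#'   attached as attribute `"field"` (useful for [refocus()]).
#'
#' @return A [phase_image()] with provenance `"reconstructed"` and
#'   attributes `carrier_detected` (cycles/px), `sign_flipped` (logical).
#' @examples
#' cfg <- optical_config()
#' ph <- phantom_population(1, 3.675, 0, seed = 1)
#' truth <- render_phase_image(ph, cfg)
#' rec <- reconstruct_hologram(synthesize_hologram(truth, cfg, noise_sigma = 0))
#' max(abs(rec$phase - truth$phase))
#' @export
reconstruct_hologram <- function(holo,
                                 window_radius = NULL,
                                 window_order = 5,
                                 background_degree = 2,
                                 return_field = FALSE) {
  intensity <- holo$intensity
  config <- holo$config
  stopifnot(is.matrix(intensity), inherits(config, "optical_config"))
  nr <- nrow(intensity)
  nc <- ncol(intensity)

  spec <- fft(intensity)
  mag <- Mod(spec)
  fr <- fft_freq(nr)
  fc <- fft_freq(nc)
  fr_g <- outer(fr, rep(1, nc))
  fc_g <- outer(rep(1, nr), fc)
  dist_dc <- sqrt(fr_g^2 + fc_g^2)

  cand <- dist_dc > 0.05
  if (!any(cand)) stop("image too small to host a sideband", call. = FALSE)
  noise_floor <- median(mag[cand])
  peak_idx <- which(cand)[which.max(mag[cand])]
  if (mag[peak_idx] < 10 * noise_floor) {
    stop("no sideband peak above the noise floor: not an off-axis hologram",
         call. = FALSE)
  }
  q <- c(fr_g[peak_idx], fc_g[peak_idx])

  if (is.null(window_radius)) window_radius <- 0.4 * sqrt(sum(q^2))
  if (sqrt(sum(q^2)) - window_radius < 0.02) {
    stop("sideband window would overlap DC; carrier below separability bound",
         call. = FALSE)
  }

  # Butterworth window centred on the detected peak (wrap-around metric).
  dq <- sqrt(wrap_freq(fr_g - q[1])^2 + wrap_freq(fc_g - q[2])^2)
  win <- 1 / (1 + (dq / window_radius)^(2 * window_order))

  # Re-centre the sideband at DC by a circular shift of the spectrum.
  pr <- ((peak_idx - 1) %% nr)        # 0-based row of the peak
  pc <- ((peak_idx - 1) %/% nr)       # 0-based column
  shifted <- circular_shift(spec * win, -pr, -pc)
  field <- fft(shifted, inverse = TRUE) / length(shifted)

  phase <- unwrap_phase(Arg(field))
  bg <- fit_background(phase, degree = background_degree)
  phase <- phase - bg
  phase <- phase - median(phase)

  # Sign convention: cells are phase-positive, so most of the excursion
  # energy away from the (already zeroed) background must be positive.
  sign_flipped <- FALSE
  if (sum(pmax(-phase, 0)^2) > sum(pmax(phase, 0)^2)) {
    phase <- -phase
    sign_flipped <- TRUE
    q <- -q
  }
  # Re-zero the cell-free region after a potential flip.
  mask <- positive_phase_mask(phase)
  if (any(!mask)) phase <- phase - median(phase[!mask])

  out <- phase_image(phase, config$pixel_scale, "reconstructed")
  attr(out, "carrier_detected") <- canonical_carrier(q)
  attr(out, "sign_flipped") <- sign_flipped
  if (return_field) {
    attr(out, "field") <- complex_field(field, config$pixel_scale,
                                        config$wavelength, config$n_medium)
  }
  out
}

#' Locate the off-axis carrier frequency of a hologram
#'
#' Finds the strongest non-DC peak of the hologram spectrum and reports its
#' frequency in cycles/px, canonicalized so the first non-zero component is
#' positive (the +1/-1 sidebands are conjugate mirror images).
#'
#' @param holo A `hologram`.
#' @return Numeric length-2 vector `c(f_row, f_col)` in cycles/px.
#' @export
detect_carrier <- function(holo) {
  intensity <- holo$intensity
  nr <- nrow(intensity)
  nc <- ncol(intensity)
  mag <- Mod(fft(intensity))
  fr_g <- outer(fft_freq(nr), rep(1, nc))
  fc_g <- outer(rep(1, nr), fft_freq(nc))
  cand <- sqrt(fr_g^2 + fc_g^2) > 0.05
  peak_idx <- which(cand)[which.max(mag[cand])]
  canonical_carrier(c(fr_g[peak_idx], fc_g[peak_idx]))
}

canonical_carrier <- function(q) {
  if (q[1] < 0 || (q[1] == 0 && q[2] < 0)) q <- -q
  q
}

wrap_freq <- function(f) {
  (f + 0.5) %% 1 - 0.5
}

circular_shift <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- ((seq_len(nr) - 1 - dr) %% nr) + 1
  ci <- ((seq_len(nc) - 1 - dc) %% nc) + 1
  m[ri, ci, drop = FALSE]
}

# Iteratively trimmed least-squares polynomial surface fit: pixels with
# large residuals (cells) are progressively excluded so the polynomial
# tracks the cell-free background only.
fit_background <- function(phase, degree = 2, n_iter = 3, keep = 0.6) {
  nr <- nrow(phase)
  nc <- ncol(phase)
  x <- rep((seq_len(nc) - 1) / (nc - 1) * 2 - 1, each = nr)
  y <- rep((seq_len(nr) - 1) / (nr - 1) * 2 - 1, times = nc)
  X <- poly_design(x, y, degree)
  z <- as.vector(phase)

  # subsample for speed on large images (deterministic stride)
  n <- length(z)
  idx <- if (n > 8192) seq(1L, n, by = max(1L, n %/% 8192L)) else seq_len(n)
  # anchor on the median level first: the background is the majority phase
  res <- abs(z[idx] - median(z[idx]))
  use <- idx[res <= stats::quantile(res, keep)]
  fit <- NULL
  for (i in seq_len(n_iter)) {
    fit <- stats::lm.fit(X[use, , drop = FALSE], z[use])
    res <- abs(z[idx] - X[idx, , drop = FALSE] %*% fit$coefficients)
    use <- idx[res <= stats::quantile(res, keep)]
  }
  matrix(X %*% fit$coefficients, nr, nc)
}

poly_design <- function(x, y, degree) {
  cols <- list(rep(1, length(x)))
  for (d in seq_len(degree)) {
    for (i in 0:d) cols[[length(cols) + 1L]] <- x^(d - i) * y^i
  }
  do.call(cbind, cols)
}

# Binary mask of likely cell pixels: Otsu threshold on the positive phase
# histogram with an absolute floor of 0.1 rad.
positive_phase_mask <- function(phase, floor_rad = 0.1) {
  strong <- abs(phase) > floor_rad
  if (!any(strong)) return(matrix(FALSE, nrow(phase), ncol(phase)))
  pos <- pmax(phase, 0)
  mx <- max(pos)
  if (mx <= floor_rad) {
    neg <- pmax(-phase, 0)
    return(neg > max(floor_rad, EBImage::otsu(neg / max(neg)) * max(neg)))
  }
  thr <- tryCatch(EBImage::otsu(pos / mx) * mx, error = function(e) mx / 2)
  pos > max(floor_rad, thr)
}
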