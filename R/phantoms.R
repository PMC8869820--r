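#' Generate a population of ground-truth cell phantoms
#'
#' Draws spherical (or in-plane elongated spheroidal) cell phantoms whose
#' radius and integral refractive index follow truncated normal
#' distributions.  Phantoms are the ground truth against which phase
#' rendering, hologram synthesis and the sphere-model fit are validated:
#' lymphocyte-like defaults (`radius_mean = 3.675` um) give a population
#' mean volume of about 208 um^3, monocyte-like radii
#' (`radius_mean = 4.533` um) about 390 um^3.
#'
#' Truncation enforces physically meaningful draws: radii must be positive
#' and the cell must be optically denser than the buffer
#' (`n_cell > n_cell_min`).  If the requested distribution cannot satisfy
#' that after repeated resampling, an error is raised.
#'
#' @param n Number of phantoms (>= 1).
#' @param radius_mean,radius_sd Mean and SD of the cell radius in um.
#' @param n_cell_mean,n_cell_sd Mean and SD of the integral cellular
#'   refractive index.
#' @param n_cell_min Lower truncation bound for `n_cell`; defaults to the
#'   buffer index 1.337.
#' @param label Cell type tag, `"lymphocyte"` or `"monocyte"` (free text is
#'   allowed).
#' @param shape `"sphere"` or `"spheroid"`; spheroids are elongated in the
#'   image plane by `axis_ratio` along `orientation`.
#' @param axis_ratio In-plane major/minor axis ratio (>= 1); ignored for
#'   spheres.
#' @param orientation Major-axis angle in radians; ignored for spheres.
#' @param center Optional `c(x, y)` position in um applied to all phantoms;
#'   `NULL` leaves placement to the renderer (field centre).
#' @param seed Optional integer seed; a fixed seed makes the population
#'   reproducible.
#'
#' @return A tibble with one row per phantom and columns `cell_id`, `label`,
#'   `shape`, `x_um`, `y_um`, `radius_um`, `n_cell`, `axis_ratio`,
#'   `orientation`, `volume_um3` (ground-truth volume \eqn{(4/3)\pi R^3}).
#' @examples
#' ph <- phantom_population(5, radius_mean = 3.675, radius_sd = 0.05, seed = 1)
#' mean(ph$volume_um3)
#' @export
phantom_population <- function(n,
                               radius_mean,
                               radius_sd,
                               n_cell_mean = 1.3497,
                               n_cell_sd = 5e-4,
                               n_cell_min = 1.337,
                               label = "lymphocyte",
                               shape = c("sphere", "spheroid"),
                               axis_ratio = 1,
                               orientation = 0,
                               center = NULL,
                               seed = NULL) {
  shape <- match.arg(shape)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  stopifnot(radius_mean > 0, radius_sd >= 0, n_cell_sd >= 0, axis_ratio >= 1)

  ar <- if (shape == "sphere") 1 else axis_ratio
  ori <- if (shape == "sphere") 0 else orientation
  with_seed(seed, {
    radius <- rtruncnorm(n, radius_mean, radius_sd, lower = .Machine$double.eps)
    n_cell <- rtruncnorm(n, n_cell_mean, n_cell_sd, lower = n_cell_min)
    tibble::tibble(
      cell_id = seq_len(n),
      label = label,
      shape = shape,
      x_um = if (is.null(center)) NA_real_ else center[1],
      y_um = if (is.null(center)) NA_real_ else center[2],
      radius_um = radius,
      n_cell = n_cell,
      axis_ratio = ar,
      orientation = ori,
      volume_um3 = (4 / 3) * pi * radius^3
    )
  })
}

# Normal draws truncated below by resampling; errors out if the acceptance
# region is essentially unreachable.
rtruncnorm <- function(n, mean, sd, lower) {
  if (sd == 0) {
    if (mean <= lower) {
      stop("degenerate distribution violates the truncation bound", call. = FALSE)
    }
    return(rep(mean, n))
  }
  if (stats::pnorm(lower, mean, sd) > 1 - 1e-6) {
    stop("distribution cannot satisfy the truncation bound", call. = FALSE)
  }
  out <- rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- out <= lower
    if (!any(bad)) break
    out[bad] <- rnorm(sum(bad), mean, sd)
  }
  if (any(out <= lower)) {
    stop("truncation failed after repeated resampling", call. = FALSE)
  }
  out
}

#' Render the quantitative phase image of a single phantom
#'
#' Projects a phantom's optical thickness onto the sensor grid and converts
#' it to phase delay \deqn{\Delta\varphi(x, y) = (2\pi/\lambda)\, d(x, y)\,
#' (n_{cell} - n_{medium})} with the spherical thickness profile
#' \eqn{d(x, y) = 2\sqrt{\max(0, R^2 - \rho^2)}}, \eqn{\rho} being the
#' in-plane distance from the cell centre.  The phase is evaluated at pixel
#' centres (0-based convention, x = column) and is zero outside the
#' projected disk; its peak value at the centre is
#' \eqn{(2\pi/\lambda)\,2R\,(n_{cell} - n_{medium})}.
#'
#' @param phantom A single-row tibble from [phantom_population()] (or a list
#'   with the same fields).
#' @param config An [optical_config()].
#'
#' @return A [phase_image()] with provenance `"synthetic"`.
#' @examples
#' cfg <- optical_config()
#' ph <- phantom_population(1, 3.675, 0, seed = 1)
#' img <- render_phase_image(ph, cfg)
#' max(img$phase)  # ~1.10 rad for the lymphocyte defaults
#' @export
render_phase_image <- function(phantom, config) {
  stopifnot(inherits(config, "optical_config"))
  ph <- as.list(phantom)
  if (length(ph$radius_um) != 1L) {
    stop("`phantom` must describe exactly one cell", call. = FALSE)
  }
  nr <- config$image_shape[1]
  nc <- config$image_shape[2]
  px <- config$pixel_scale

  cx <- ph$x_um
  cy <- ph$y_um
  if (is.null(cx) || is.na(cx)) cx <- (nc - 1) / 2 * px
  if (is.null(cy) || is.na(cy)) cy <- (nr - 1) / 2 * px

  r_um <- ph$radius_um
  ar <- if (is.null(ph$axis_ratio) || is.na(ph$axis_ratio)) 1 else ph$axis_ratio
  th <- if (is.null(ph$orientation) || is.na(ph$orientation)) 0 else ph$orientation
  a <- r_um * sqrt(ar)   # in-plane semi-major axis
  b <- r_um / sqrt(ar)   # in-plane semi-minor axis

  if (r_um / px < 3) {
    stop("projected radius below 3 px; pixel scale too coarse for a meaningful fit",
         call. = FALSE)
  }
  margin <- 2 * px
  if (cx - a < margin || cy - a < margin ||
      cx + a > (nc - 1) * px - margin || cy + a > (nr - 1) * px - margin) {
    stop("phantom does not fit inside the field of view with a 2 px margin",
         call. = FALSE)
  }

  x <- (seq_len(nc) - 1) * px
  y <- (seq_len(nr) - 1) * px
  dx <- outer(rep(1, nr), x - cx)   # nr x nc
  dy <- outer(y - cy, rep(1, nc))
  # rotate into the spheroid frame
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  # thickness of a spheroid with in-plane semi-axes (a, b) and out-of-plane
  # semi-axis equal to the nominal radius (a sphere when axis_ratio = 1)
  arg <- 1 - (u / a)^2 - (v / b)^2
  d <- 2 * r_um * sqrt(pmax(arg, 0))
  phase <- (2 * pi / config$wavelength) * d * (ph$n_cell - config$n_medium)
  phase_image(phase, px, "synthetic")
}
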