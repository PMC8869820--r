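#' Settings for the sphere-model Gauss-Newton fit
#'
#' @param max_iterations Maximum Gauss-Newton iterations (default 60).
#' @param tol Convergence tolerance on the relative parameter step
#'   (default 1e-10).
#' @param lambda0 Initial Levenberg damping factor (default 0; damping is
#'   switched on automatically when a step fails).
#' @param boundary_exclude_px Width in pixels of the mask boundary ring
#'   excluded from the residual.  The sphere thickness derivative is
#'   singular at the cell edge and edge diffraction corrupts measured
#'   phase there; default 2.
#'
#' @return An object of class `fit_settings`.
#' @export
fit_settings <- function(max_iterations = 60L,
                         tol = 1e-10,
                         lambda0 = 0,
                         boundary_exclude_px = 2L) {
  stopifnot(max_iterations >= 1, tol > 0, lambda0 >= 0, boundary_exclude_px >= 0)
  structure(
    list(max_iterations = as.integer(max_iterations), tol = tol,
         lambda0 = lambda0, boundary_exclude_px = as.integer(boundary_exclude_px)),
    class = "fit_settings"
  )
}

#' Fit the sphere-projection phase model to a segmented cell
#'
#' Retrieves the integral cellular refractive index and radius from a
#' single-cell phase image by minimizing
#' \deqn{\sum_{(x,y)} \left[\varphi(x,y) - \frac{2\pi}{\lambda}\,
#'   2\sqrt{\max(0, R^2 - \rho^2)}\,(n_{cell} - n_{medium})\right]^2}
#' over \eqn{(x_0, y_0, R, n_{cell})} with a damped Gauss-Newton
#' iteration and analytic Jacobian; \eqn{\rho} is the distance from the
#' candidate centre.  Because the model couples thickness and index only
#' through their product at each radius, sampling many radii across the
#' projected disk decouples the two.  Initialization: centre at the mask
#' centroid, \eqn{R_0 = \sqrt{A/\pi}} from the mask area, and
#' \eqn{n_0 = n_{medium} + \lambda\varphi_{peak}/(4\pi R_0)} from the peak
#' phase.  A boundary ring (default 2 px) is excluded from the residual.
#'
#' @param phase A [phase_image()] or matrix of radians.
#' @param mask Logical matrix marking the cell's pixels.
#' @param config An [optical_config()].
#' @param settings A [fit_settings()].
#'
#' @return An object of class `sphere_fit`: list with `x0_um`, `y0_um`,
#'   `R_um`, `n_cell`, `V_um3`, `DM_pg`, `residual_rms` (rad),
#'   `iterations`, `converged`, `fit_failed`, `n_pixels`.
#'   Use [tidy()] for a tibble row.
#' @examples
#' cfg <- optical_config()
#' ph <- phantom_population(1, 3.675, 0, seed = 1)
#' img <- render_phase_image(ph, cfg)
#' seg <- segment_cells(img, 10, 400)
#' fit <- fit_sphere_model(img, seg$mask[[1]], cfg)
#' c(fit$R_um, fit$n_cell)
#' @export
fit_sphere_model <- function(phase, mask, config, settings = fit_settings()) {
  stopifnot(inherits(config, "optical_config"), inherits(settings, "fit_settings"))
  phi <- as_phase_matrix(phase)
  stopifnot(is.matrix(mask), all(dim(mask) == dim(phi)))
  px <- if (inherits(phase, "phase_image")) phase$pixel_scale else config$pixel_scale

  if (sum(mask) < 25) {
    return(failed_fit("mask below 25 pixels"))
  }

  fit_mask <- erode_mask(mask, settings$boundary_exclude_px)
  if (sum(fit_mask) < 10) fit_mask <- mask

  idx <- which(fit_mask, arr.ind = TRUE)
  xs <- (idx[, 2] - 1) * px
  ys <- (idx[, 1] - 1) * px
  obs <- phi[fit_mask]

  # initialization from mask geometry and peak phase
  A_px <- sum(mask)
  R0 <- sqrt(A_px / pi) * px
  if (R0 / px < 3) return(failed_fit("projected radius below 3 px"))
  midx <- which(mask, arr.ind = TRUE)
  x0 <- (mean(midx[, 2]) - 1) * px
  y0 <- (mean(midx[, 1]) - 1) * px
  phi_peak <- max(phi[mask])
  lambda_um <- config$wavelength
  nm <- config$n_medium
  n0 <- nm + lambda_um * phi_peak / (4 * pi * R0)
  if (!is.finite(n0) || n0 <= nm || phi_peak <= 0) {
    return(failed_fit("no usable index contrast in mask"))
  }

  k <- 4 * pi / lambda_um  # phase = k * sqrt(R^2 - rho^2) * (n - nm), factor 2 folded in
  theta <- c(x0, y0, R0, n0)
  model_sse <- function(th) {
    s2 <- th[3]^2 - (xs - th[1])^2 - (ys - th[2])^2
    s <- sqrt(pmax(s2, 0))
    m <- k * s * (th[4] - nm)
    r <- obs - m
    list(s = s, resid = r, sse = sum(r^2))
  }

  cur <- model_sse(theta)
  lambda <- settings$lambda0
  converged <- FALSE
  iter <- 0L
  field_um <- max(dim(phi)) * px
  for (iter in seq_len(settings$max_iterations)) {
    s <- cur$s
    dn <- theta[4] - nm
    inside <- s > 1e-9
    inv_s <- ifelse(inside, 1 / pmax(s, 1e-9), 0)
    J <- cbind(
      k * dn * (xs - theta[1]) * inv_s,   # d/dx0
      k * dn * (ys - theta[2]) * inv_s,   # d/dy0
      k * dn * theta[3] * inv_s * inside, # d/dR
      k * s                               # d/dn
    )
    g <- crossprod(J, cur$resid)
    H <- crossprod(J)
    step_ok <- FALSE
    for (try in 1:12) {
      Hd <- H + lambda * diag(diag(H) + 1e-12)
      delta <- tryCatch(solve(Hd, g), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta + as.vector(delta)
        if (cand[3] > 0 && cand[3] < field_um) {
          new <- model_sse(cand)
          if (is.finite(new$sse) && new$sse <= cur$sse * (1 + 1e-12)) {
            rel <- max(abs(delta) / (abs(theta) + 1e-9))
            theta <- cand
            cur <- new
            lambda <- lambda / 4
            step_ok <- TRUE
            if (rel < settings$tol) converged <- TRUE
            break
          }
        }
      }
      lambda <- max(lambda * 10, 1e-6)
    }
    if (!step_ok || converged) break
  }

  if (theta[3] <= 0 || theta[3] >= field_um || theta[4] <= nm) {
    return(failed_fit("parameters left the admissible region"))
  }

  V <- compute_volume(theta[3])
  structure(
    list(
      x0_um = theta[1], y0_um = theta[2], R_um = theta[3], n_cell = theta[4],
      V_um3 = V,
      DM_pg = compute_dry_mass(V, theta[4], nm),
      residual_rms = sqrt(cur$sse / length(obs)),
      iterations = iter,
      converged = converged || iter < settings$max_iterations,
      fit_failed = FALSE,
      failure_reason = NA_character_,
      n_pixels = length(obs)
    ),
    class = "sphere_fit"
  )
}

failed_fit <- function(reason) {
  structure(
    list(x0_um = NA_real_, y0_um = NA_real_, R_um = NA_real_,
         n_cell = NA_real_, V_um3 = NA_real_, DM_pg = NA_real_,
         residual_rms = NA_real_, iterations = 0L, converged = FALSE,
         fit_failed = TRUE, failure_reason = reason, n_pixels = 0L),
    class = "sphere_fit"
  )
}

#' @export
print.sphere_fit <- function(x, ...) {
  if (x$fit_failed) {
    cat("<sphere_fit> FAILED:", x$failure_reason, "\n")
  } else {
    cat(sprintf(
      "<sphere_fit> R = %.4f um, n_cell = %.5f, V = %.1f um^3, DM = %.2f pg (rms %.4g rad, %d px)\n",
      x$R_um, x$n_cell, x$V_um3, x$DM_pg, x$residual_rms, x$n_pixels))
  }
  invisible(x)
}

#' @export
tidy.sphere_fit <- function(x, ...) {
  tibble::tibble(
    x0_um = x$x0_um, y0_um = x$y0_um, R_um = x$R_um, n_cell = x$n_cell,
    V_um3 = x$V_um3, DM_pg = x$DM_pg, residual_rms = x$residual_rms,
    fit_failed = x$fit_failed
  )
}

#' @export
glance.sphere_fit <- function(x, ...) {
  tibble::tibble(
    iterations = x$iterations, converged = x$converged,
    n_pixels = x$n_pixels, residual_rms = x$residual_rms,
    fit_failed = x$fit_failed
  )
}

#' Cell volume from the fitted radius
#'
#' \eqn{V = (4/3)\pi R^3}.
#'
#' @param R Radius in um (vectorized, >= 0).
#' @return Volume in um^3.
#' @examples
#' compute_volume(3.675)  # ~207.9
#' @export
compute_volume <- function(R) {
  if (any(R < 0)) stop("negative radius", call. = FALSE)
  (4 / 3) * pi * R^3
}

#' Cellular dry mass from volume and refractive index
#'
#' \eqn{DM = (V/\alpha)(n_{cell} - n_{medium})} with the refractive index
#' increment \eqn{\alpha = 0.2} mL/g, which in the um/pg unit system equals
#' 0.2 um^3/pg, so volumes in um^3 give dry mass in pg.
#'
#' @param V Volume in um^3 (>= 0).
#' @param n_cell Integral cellular refractive index.
#' @param n_medium Buffer refractive index.
#' @param alpha Refractive index increment in um^3/pg (default 0.2).
#' @return Dry mass in pg.
#' @examples
#' compute_dry_mass(212, 1.3497, 1.337)  # ~13.5 pg
#' @export
compute_dry_mass <- function(V, n_cell, n_medium = 1.337, alpha = 0.2) {
  if (any(V < 0)) stop("negative volume", call. = FALSE)
  if (alpha <= 0) stop("`alpha` must be positive", call. = FALSE)
  (V / alpha) * (n_cell - n_medium)
}

# Binary erosion with a (2k+1) square structuring element.
erode_mask <- function(mask, k) {
  if (k <= 0) return(mask)
  m <- EBImage::erode(EBImage::Image(mask * 1),
                      EBImage::makeBrush(2 * k + 1, shape = "box"))
  EBImage::imageData(m) > 0.5
}
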