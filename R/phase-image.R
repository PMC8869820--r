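#' Quantitative phase image
#'
#' A 2-D map of the cell-induced phase delay in radians, relative to the
#' surrounding buffer, together with the object-space pixel size.  Phase
#' images are the unit of all morphometric analysis: synthetic ones come
#' from [render_phase_image()], reconstructed ones from
#' [reconstruct_hologram()].
#'
#' @param phase Numeric matrix of phase values in radians.
#' @param pixel_scale Object-space pixel size in um/px.
#' @param provenance Either `"synthetic"` or `"reconstructed"`.
#'
#' @return An object of class `phase_image`: a list with elements `phase`,
#'   `pixel_scale` and `provenance`.
#' @export
phase_image <- function(phase, pixel_scale, provenance = c("synthetic", "reconstructed")) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(phase), is.numeric(phase), all(is.finite(phase)),
            is.numeric(pixel_scale), length(pixel_scale) == 1L, pixel_scale > 0)
  structure(
    list(phase = phase, pixel_scale = pixel_scale, provenance = provenance),
    class = "phase_image"
  )
}

#' @export
print.phase_image <- function(x, ...) {
  cat(sprintf("<phase_image> %d x %d px @ %.3g um/px (%s)\n",
              nrow(x$phase), ncol(x$phase), x$pixel_scale, x$provenance))
  cat(sprintf("  phase range: [%.4f, %.4f] rad\n",
              min(x$phase), max(x$phase)))
  invisible(x)
}

#' @describeIn phase_image Render a phase image as a `ggplot2` raster.
#' @param object A `phase_image`.
#' @param ... Unused.
#' @export
autoplot.phase_image <- function(object, ...) {
  df <- expand.grid(
    x = (seq_len(ncol(object$phase)) - 1) * object$pixel_scale,
    y = (seq_len(nrow(object$phase)) - 1) * object$pixel_scale
  )
  df$phase <- as.vector(t(object$phase))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$phase)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "phase (rad)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (\u00b5m)", y = "y (\u00b5m)") +
    ggplot2::theme_minimal()
}

as_phase_matrix <- function(phase) {
  if (inherits(phase, "phase_image")) phase$phase else phase
}
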