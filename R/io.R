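#' Read and write phase images and holograms as 32-bit float TIFF
#'
#' Single-channel float TIFF I/O.  The underlying TIFF writer stores
#' samples on a \[0, 1\] scale, so values are mapped affinely into that
#' range and back: phase images use the fixed range \[-4 pi, 4 pi\]
#' radians, holograms \[0, 16\] intensity units.  32-bit samples keep the
#' quantization below 1e-8 rad.
#'
#' @param phase A [phase_image()].
#' @param path Output file path.
#' @name phase_tiff
#' @return `write_phase_tiff()` returns `path` invisibly;
#'   `read_phase_tiff()` returns a [phase_image()].
NULL

PHASE_TIFF_RANGE <- c(-4 * pi, 4 * pi)
HOLO_TIFF_RANGE <- c(0, 16)

#' @rdname phase_tiff
#' @export
write_phase_tiff <- function(phase, path) {
  stopifnot(inherits(phase, "phase_image"))
  m <- scale_to_unit(phase$phase, PHASE_TIFF_RANGE)
  tiff::writeTIFF(m, path, bits.per.sample = 32L, compression = "none")
  invisible(path)
}

#' @rdname phase_tiff
#' @param pixel_scale Pixel size in um/px to attach on read.
#' @param provenance Provenance tag to attach on read.
#' @export
read_phase_tiff <- function(path, pixel_scale, provenance = "reconstructed") {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  phase_image(unscale_from_unit(m, PHASE_TIFF_RANGE), pixel_scale, provenance)
}

#' @rdname phase_tiff
#' @param holo A `hologram`.
#' @export
write_hologram_tiff <- function(holo, path) {
  m <- scale_to_unit(holo$intensity, HOLO_TIFF_RANGE)
  tiff::writeTIFF(m, path, bits.per.sample = 32L, compression = "none")
  invisible(path)
}

#' @rdname phase_tiff
#' @param config The [optical_config()] of the recording.
#' @export
read_hologram_tiff <- function(path, config) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  structure(list(intensity = unscale_from_unit(m, HOLO_TIFF_RANGE),
                 config = config),
            class = "hologram")
}

scale_to_unit <- function(m, range) {
  out <- (m - range[1]) / (range[2] - range[1])
  if (any(out < 0 | out > 1)) {
    stop(sprintf("values outside the storable range [%g, %g]",
                 range[1], range[2]), call. = FALSE)
  }
  out
}

unscale_from_unit <- function(m, range) {
  m * (range[2] - range[1]) + range[1]
}

#' Write / read a cohort table as CSV
#'
#' One row per patient x timepoint x cell type; the column dictionary is
#' the [simulate_cohort()] return layout.  Timepoint factor levels are
#' restored on read from their order of first appearance unless given.
#'
#' @param cohort A cohort table.
#' @param path CSV file path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a cohort tibble.
#' @name cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(dplyr::mutate(cohort,
                                 timepoint = as.character(.data$timepoint)),
                   path)
  invisible(path)
}

#' @rdname cohort_csv
#' @param timepoints Optional ordered timepoint labels.
#' @export
read_cohort_csv <- function(path, timepoints = NULL) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (is.null(timepoints)) timepoints <- unique(out$timepoint)
  out$timepoint <- factor(out$timepoint, levels = timepoints)
  class(out) <- c("cohort_table", class(out))
  out
}
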