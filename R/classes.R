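# Lightweight S3 containers for the pipeline's intermediate products.

#' Construct a microvessel intensity image
#'
#' A nonnegative 2-D intensity image of enhanced vasculature on a regular
#' grid, together with its physical pixel size and a processing provenance
#' list (filter ranks, scales, windows) that downstream stages append to.
#'
#' @param data numeric matrix (row = axial/depth, col = lateral), values >= 0.
#' @param pixel_size_mm physical size of one pixel in mm.
#' @param provenance named list describing how the image was produced.
#' @return An object of class `microvessel_image`.
#' @export
microvessel_image <- function(data, pixel_size_mm, provenance = list()) {
  data <- as_matrix(data)
  stopifnot_scalar_pos(pixel_size_mm, "pixel_size_mm")
  if (any(!is.finite(data))) stop("image contains non-finite values", call. = FALSE)
  if (any(data < 0)) stop("microvessel image values must be >= 0", call. = FALSE)
  structure(
    list(data = data, pixel_size_mm = pixel_size_mm, provenance = provenance),
    class = "microvessel_image"
  )
}

#' @export
print.microvessel_image <- function(x, ...) {
  cat(sprintf("<microvessel_image> %d x %d px @ %.4g mm/px, range [%.3g, %.3g]\n",
              nrow(x$data), ncol(x$data), x$pixel_size_mm,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a lesion ROI mask
#'
#' Binary region-of-interest mask on the image grid.  `kind` records whether
#' the mask is the original manual/simulated segmentation or its perilesional
#' dilation.
#'
#' @param data logical (or 0/1) matrix.
#' @param pixel_size_mm physical pixel size in mm.
#' @param kind `"original"` or `"dilated"`.
#' @param dilation_mm dilation radius applied, in mm (0 for original masks).
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(data, pixel_size_mm, kind = "original", dilation_mm = 0) {
  data <- as_matrix(data) != 0
  stopifnot_scalar_pos(pixel_size_mm, "pixel_size_mm")
  kind <- match.arg(kind, c("original", "dilated"))
  structure(
    list(data = data, pixel_size_mm = pixel_size_mm, kind = kind,
         dilation_mm = dilation_mm),
    class = "lesion_mask"
  )
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %d x %d px (%s, dilation %.1f mm), %d px in ROI\n",
              nrow(x$data), ncol(x$data), x$kind, x$dilation_mm, sum(x$data)))
  invisible(x)
}

#' Construct a slow-time IQ ensemble
#'
#' Complex beamformed data cube (rows x cols x frames) with spatial and
#' temporal sampling metadata; the input to clutter filtering.
#'
#' @param data complex array with `dim = c(rows, cols, frames)`, frames >= 2.
#' @param pixel_size_mm physical pixel size in mm.
#' @param frame_rate_hz slow-time sampling rate (pulse repetition frequency).
#' @return An object of class `iq_ensemble`.
#' @export
iq_ensemble <- function(data, pixel_size_mm, frame_rate_hz = 1000) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a rows x cols x frames array", call. = FALSE)
  }
  if (dim(data)[3] < 2L) stop("an IQ ensemble needs at least 2 frames", call. = FALSE)
  if (any(!is.finite(Re(data))) || any(!is.finite(Im(data)))) {
    stop("ensemble contains non-finite values", call. = FALSE)
  }
  stopifnot_scalar_pos(pixel_size_mm, "pixel_size_mm")
  stopifnot_scalar_pos(frame_rate_hz, "frame_rate_hz")
  storage.mode(data) <- "complex"
  structure(
    list(data = data, pixel_size_mm = pixel_size_mm, frame_rate_hz = frame_rate_hz),
    class = "iq_ensemble"
  )
}

#' @export
print.iq_ensemble <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<iq_ensemble> %d x %d px, %d frames @ %.4g mm/px, %.5g Hz\n",
              d[1], d[2], d[3], x$pixel_size_mm, x$frame_rate_hz))
  invisible(x)
}

#' Construct a binary vessel map
#'
#' Binary segmentation of the vessel lumen on the image grid, with the
#' threshold and cleanup parameters that produced it.
#'
#' @param data logical (or 0/1) matrix.
#' @param pixel_size_mm physical pixel size in mm.
#' @param threshold threshold used during binarization (recorded, may be NA).
#' @param params named list of cleanup parameters.
#' @return An object of class `binary_vessel_map`.
#' @export
binary_vessel_map <- function(data, pixel_size_mm, threshold = NA_real_,
                              params = list()) {
  data <- as_matrix(data) != 0
  stopifnot_scalar_pos(pixel_size_mm, "pixel_size_mm")
  structure(
    list(data = data, pixel_size_mm = pixel_size_mm, threshold = threshold,
         params = params),
    class = "binary_vessel_map"
  )
}

#' @export
print.binary_vessel_map <- function(x, ...) {
  cat(sprintf("<binary_vessel_map> %d x %d px, %d foreground px (threshold %s)\n",
              nrow(x$data), ncol(x$data), sum(x$data),
              format(x$threshold, digits = 3)))
  invisible(x)
}
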