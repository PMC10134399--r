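# Lesion-ROI handling: perilesional dilation and restriction of images to
# the analysis region.

#' Dilate a lesion mask to include perilesional vascularity
#'
#' Morphological dilation with a Euclidean disk of radius
#' `round(dilation_mm / pixel_size_mm)` pixels (default 10 mm, applied
#' identically to every lesion).  The result is clipped to the image
#' bounds, so masks near the image border simply use as much of the image
#' as is available.
#'
#' @param mask a [lesion_mask()].
#' @param dilation_mm dilation radius in mm (0 = identity).
#' @return A [lesion_mask()] with `kind = "dilated"`.
#' @export
dilate_mask <- function(mask, dilation_mm = 10) {
  if (dilation_mm < 0) stop("`dilation_mm` must be >= 0", call. = FALSE)
  if (is.null(mask$pixel_size_mm)) stop("mask has no pixel size", call. = FALSE)
  r_px <- round(dilation_mm / mask$pixel_size_mm)
  out <- mask$data
  if (r_px >= 1) {
    brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
    out <- as_matrix(EBImage::dilate(mask$data * 1, brush)) != 0
  }
  lesion_mask(out, mask$pixel_size_mm, kind = "dilated",
              dilation_mm = dilation_mm)
}

#' Restrict an image to the analysis ROI
#'
#' Sets pixels outside the mask to zero and records the ROI pixel count
#' (the denominator of vessel density) in the image provenance.
#'
#' @param image a [microvessel_image()].
#' @param mask a [lesion_mask()] on the same grid.
#' @return A [microvessel_image()] with provenance fields `roi_px` and
#'   `roi_area_mm2`.
#' @export
apply_roi <- function(image, mask) {
  if (!all(dim(image$data) == dim(mask$data))) {
    stop("image and mask shapes differ", call. = FALSE)
  }
  d <- image$data
  d[!mask$data] <- 0
  n_roi <- sum(mask$data)
  microvessel_image(d, image$pixel_size_mm,
                    provenance = c(image$provenance,
                                   list(roi_px = n_roi,
                                        roi_area_mm2 = n_roi * image$pixel_size_mm^2,
                                        roi_kind = mask$kind)))
}
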