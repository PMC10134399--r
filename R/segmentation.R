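# Vessel segmentation: thresholding, morphological cleanup and
# topology-preserving thinning of the enhanced microvessel image.

#' Binarize a microvessel image
#'
#' Foreground is every pixel with intensity `>= threshold`.  The image must
#' already be normalized to \[0, 1\] (see [normalize_image()]).
#' `threshold = "otsu"` uses the standard between-class-variance maximizer
#' as a reproducible stand-in for a manually tuned threshold.
#'
#' @param image a [microvessel_image()] with values in \[0, 1\].
#' @param threshold numeric in \[0, 1\], or `"otsu"`.
#' @param roi optional [lesion_mask()]; when given, Otsu's threshold is
#'   computed from ROI pixels only and foreground is restricted to the ROI.
#' @return A [binary_vessel_map()].
#' @export
binarize <- function(image, threshold = "otsu", roi = NULL) {
  if (max(image$data) > 1 + 1e-9 || min(image$data) < 0) {
    stop("image must be normalized to [0, 1] before binarization",
         call. = FALSE)
  }
  if (identical(threshold, "otsu")) {
    vals <- if (is.null(roi)) image$data else image$data[roi$data]
    thr <- EBImage::otsu(matrix(vals), range = c(0, 1), levels = 256L)
  } else {
    thr <- threshold
    if (!is.numeric(thr) || length(thr) != 1L || thr < 0 || thr > 1) {
      stop("`threshold` must be in [0, 1] or \"otsu\"", call. = FALSE)
    }
  }
  fg <- image$data >= thr
  if (!is.null(roi)) fg <- fg & roi$data
  binary_vessel_map(fg, image$pixel_size_mm, threshold = thr)
}

#' Morphological cleanup of a binary vessel map
#'
#' Removes 8-connected foreground components smaller than `min_object_px`
#' and fills 4-connected background holes of at most `max_hole_px` pixels.
#' Idempotent: a second application changes nothing.
#'
#' @param map a [binary_vessel_map()].
#' @param min_object_px minimum object size kept, pixels.
#' @param max_hole_px largest hole filled, pixels.
#' @return A [binary_vessel_map()].
#' @export
cleanup_map <- function(map, min_object_px = 20L, max_hole_px = 10L) {
  if (min_object_px < 0 || max_hole_px < 0) {
    stop("cleanup sizes must be >= 0", call. = FALSE)
  }
  fg <- map$data
  if (min_object_px > 0 && any(fg)) {
    lab <- label8(fg)
    sizes <- tabulate(lab[lab > 0L])
    fg[lab > 0L & sizes[pmax(lab, 1L)] < min_object_px] <- FALSE
  }
  if (max_hole_px > 0 && any(fg)) {
    bg <- !fg
    lab <- as_matrix(EBImage::bwlabel(bg * 1))  # 4-connected background
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border <- border[border > 0L]
    sizes <- tabulate(lab)
    hole <- lab > 0L & !(lab %in% border) & sizes[pmax(lab, 1L)] <= max_hole_px
    fg[hole] <- TRUE
  }
  binary_vessel_map(fg, map$pixel_size_mm, threshold = map$threshold,
                    params = c(map$params,
                               list(min_object_px = min_object_px,
                                    max_hole_px = max_hole_px)))
}

#' Convert mm^2 cleanup sizes to pixels
#'
#' @param area_mm2 area in mm^2.
#' @param pixel_size_mm pixel size in mm.
#' @return Integer pixel count.
#' @export
area_mm2_to_px <- function(area_mm2, pixel_size_mm) {
  as.integer(round(area_mm2 / pixel_size_mm^2))
}

#' Thin a binary vessel map to a one-pixel skeleton
#'
#' Zhang-Suen iterative thinning: pixels are peeled from alternating sides
#' until only a 1-px-wide, 8-connected medial line remains.  Connectivity
#' is preserved, so the skeleton has the same number of connected
#' components as the input map.
#'
#' @param map a [binary_vessel_map()].
#' @return Logical skeleton matrix (same shape as the map).
#' @export
skeletonize_map <- function(map) {
  if (!any(map$data)) {
    warning("empty vessel map: skeleton is empty", call. = FALSE)
    return(map$data)
  }
  nr <- nrow(map$data); nc <- ncol(map$data)
  # zero-padded image as a flat vector; neighbors are fixed index offsets
  nrp <- nr + 2L
  v <- integer(nrp * (nc + 2L))
  pad <- matrix(0L, nrp, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- map$data * 1L
  v <- as.integer(pad)
  idx_fg <- which(v == 1L)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      i <- idx_fg
      p2 <- v[i - 1L];        p3 <- v[i - 1L + nrp]
      p4 <- v[i + nrp];       p5 <- v[i + 1L + nrp]
      p6 <- v[i + 1L];        p7 <- v[i + 1L - nrp]
      p8 <- v[i - nrp];       p9 <- v[i - 1L - nrp]
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (step == 1L) {
        del <- B >= 2L & B <= 6L & A == 1L &
          p2 * p4 * p6 == 0L & p4 * p6 * p8 == 0L
      } else {
        del <- B >= 2L & B <= 6L & A == 1L &
          p2 * p4 * p8 == 0L & p2 * p6 * p8 == 0L
      }
      if (any(del)) {
        v[i[del]] <- 0L
        idx_fg <- i[!del]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # parallel Zhang-Suen can leave 2-px-wide diagonal staircases; a
  # sequential pass deleting 8-simple points (Yokoi connectivity number
  # equal to 1, endpoints kept) reduces them to minimal 1-px chains
  # without changing topology
  repeat {
    removed <- FALSE
    for (i in which(v == 1L)) {
      # x1..x8 = E, NE, N, NW, W, SW, S, SE
      x <- c(v[i + nrp], v[i - 1L + nrp], v[i - 1L], v[i - 1L - nrp],
             v[i - nrp], v[i + 1L - nrp], v[i + 1L], v[i + 1L + nrp])
      B <- sum(x)
      if (B < 2L) next
      xb <- 1L - x
      xc <- c(xb, xb[1:2])
      nc8 <- sum(vapply(c(1L, 3L, 5L, 7L), function(k) {
        xc[k] - xc[k] * xc[k + 1L] * xc[k + 2L]
      }, integer(1)))
      if (nc8 == 1L) {
        v[i] <- 0L
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  out <- matrix(v == 1L, nrp, nc + 2L)
  out[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
}
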