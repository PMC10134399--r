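# Microvessel image formation: Casorati rearrangement, SVD clutter
# filtering, power-Doppler integration, background equalization and
# multiscale Hessian vessel enhancement.

#' Casorati matrix of an IQ ensemble
#'
#' Rearranges the rows x cols x frames data cube into a (pixels x frames)
#' matrix: column t is frame t flattened in R's fixed column-major order.
#' [casorati_inverse()] undoes the rearrangement exactly.
#'
#' @param ensemble an [iq_ensemble()].
#' @return Complex matrix with `prod(dim)[1:2]` rows and one column per frame.
#' @export
casorati <- function(ensemble) {
  d <- dim(ensemble$data)
  matrix(ensemble$data, nrow = d[1] * d[2], ncol = d[3])
}

#' Invert the Casorati rearrangement
#'
#' @param mat complex (pixels x frames) matrix.
#' @param ensemble the source [iq_ensemble()] supplying grid shape and
#'   metadata.
#' @return An [iq_ensemble()] with the same shape as `ensemble`.
#' @export
casorati_inverse <- function(mat, ensemble) {
  d <- dim(ensemble$data)
  iq_ensemble(array(mat, dim = d), ensemble$pixel_size_mm,
              ensemble$frame_rate_hz)
}

#' SVD clutter filter
#'
#' Zeroes singular components `1..rank_low` (tissue clutter) and
#' `rank_high+1..n_frames` (noise) of the Casorati matrix, then reshapes
#' back to an ensemble.  With `rank_low = 0` and `rank_high = n_frames` the
#' filter is the identity; it is a projection, so applying it twice with
#' the same ranks equals applying it once.
#'
#' @param ensemble an [iq_ensemble()].
#' @param rank_low number of leading singular components to remove.
#' @param rank_high last singular component kept (default: all).
#' @return A filtered [iq_ensemble()].
#' @export
svd_clutter_filter <- function(ensemble, rank_low = 1L, rank_high = NULL) {
  nf <- dim(ensemble$data)[3]
  if (is.null(rank_high)) rank_high <- nf
  rank_low <- as.integer(rank_low); rank_high <- as.integer(rank_high)
  if (rank_low < 0L || rank_low > rank_high || rank_high > nf) {
    stop("need 0 <= rank_low <= rank_high <= n_frames", call. = FALSE)
  }
  X <- casorati(ensemble)
  s <- svd(X)
  d <- s$d
  keep <- rep(FALSE, length(d))
  if (rank_high > rank_low) keep[(rank_low + 1L):rank_high] <- TRUE
  d[!keep] <- 0
  Y <- s$u %*% (d * Conj(t(s$v)))
  casorati_inverse(Y, ensemble)
}

#' Power-Doppler image of an ensemble
#'
#' Per-pixel mean of the squared signal magnitude across slow-time frames;
#' proportional to moving-blood signal energy after clutter filtering.
#'
#' @param ensemble an [iq_ensemble()].
#' @return A [microvessel_image()].
#' @export
power_doppler <- function(ensemble) {
  d <- dim(ensemble$data)
  p <- matrix(rowMeans(matrix(Mod(ensemble$data)^2, nrow = d[1] * d[2])),
              d[1], d[2])
  microvessel_image(p, ensemble$pixel_size_mm,
                    provenance = list(stage = "power_doppler",
                                      n_frames = d[3]))
}

#' Normalize image intensities to [0, 1]
#'
#' Divides by the image maximum (identity on all-zero images), so the
#' binarization threshold is a fraction of peak intensity and transfers
#' across simulated cohorts.
#'
#' @param image a [microvessel_image()].
#' @return A [microvessel_image()].
#' @export
normalize_image <- function(image) {
  m <- max(image$data)
  d <- if (m > 0) image$data / m else image$data
  microvessel_image(d, image$pixel_size_mm,
                    provenance = c(image$provenance, list(normalized_by = m)))
}

#' Morphological background equalization (white top-hat)
#'
#' Subtracts the grayscale opening of the image with a disk of radius
#' `window_mm` and clips at 0: flat or slowly varying background is removed
#' while curvilinear structures narrower than the window are preserved.
#'
#' @param image a [microvessel_image()].
#' @param window_mm opening-disk radius in mm (must be at least one pixel).
#' @return A [microvessel_image()].
#' @export
background_equalize <- function(image, window_mm = 1) {
  stopifnot_scalar_pos(window_mm, "window_mm")
  r_px <- round(window_mm / image$pixel_size_mm)
  if (r_px < 1) {
    stop("`window_mm` is smaller than one pixel at this pixel size",
         call. = FALSE)
  }
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  op <- as_matrix(EBImage::opening(image$data, brush))
  microvessel_image(pmax(image$data - op, 0), image$pixel_size_mm,
                    provenance = c(image$provenance,
                                   list(equalize_window_mm = window_mm)))
}

# gaussian second-derivative kernels at scale sigma (pixels); the support
# is capped so the kernel never exceeds the image
hessian_kernels <- function(sigma, max_half = Inf) {
  h <- max(2L, min(ceiling(3 * sigma), max_half))
  x <- -h:h
  g <- outer(x, x, function(y, x) exp(-(x^2 + y^2) / (2 * sigma^2)))
  g <- g / sum(g)
  X <- outer(x, x, function(y, x) x)   # column offset
  Y <- outer(x, x, function(y, x) y)   # row offset
  gxx <- g * (X^2 / sigma^4 - 1 / sigma^2)
  gyy <- g * (Y^2 / sigma^4 - 1 / sigma^2)
  # truncation leaves a tiny nonzero kernel sum; remove it so constant
  # images produce exactly zero second derivatives
  gxx <- gxx - mean(gxx)
  gyy <- gyy - mean(gyy)
  list(gxx = gxx, gyy = gyy, gxy = g * X * Y / sigma^4)
}

#' Multiscale Hessian vessel enhancement
#'
#' Frangi-style line filter for bright curvilinear structures: at each
#' scale the scale-normalized Hessian eigenvalues (|l1| <= |l2|) feed a
#' blobness term `exp(-(l1/l2)^2 / (2 beta^2))` and a structure term
#' `1 - exp(-S^2 / (2 c^2))` (S = Frobenius norm, `c` set to half the
#' maximum S at that scale); the response is zero where `l2 >= 0` and the
#' final image is the maximum over scales.  Invariant to adding a global
#' constant; zero on constant images.
#'
#' @param image a [microvessel_image()].
#' @param scales_mm positive vessel-radius scales in mm
#'   (default spans roughly 0.15-1.2 mm, bracketing the 300-micron
#'   smallest resolvable vessels).
#' @param beta blobness sensitivity (default 0.5).
#' @return A [microvessel_image()].
#' @export
vessel_enhance <- function(image, scales_mm = c(0.15, 0.3, 0.6, 1.2),
                           beta = 0.5) {
  if (length(scales_mm) == 0L || any(scales_mm <= 0)) {
    stop("`scales_mm` must be a non-empty vector of positive scales",
         call. = FALSE)
  }
  img <- image$data
  best <- matrix(0, nrow(img), ncol(img))
  for (s_mm in scales_mm) {
    sigma <- max(s_mm / image$pixel_size_mm, 0.8)
    kk <- hessian_kernels(sigma, max_half = (min(dim(img)) - 1L) %/% 2L)
    # scale-normalized second derivatives (multiply by sigma^2)
    hxx <- sigma^2 * as_matrix(EBImage::filter2(img, kk$gxx, boundary = "replicate"))
    hyy <- sigma^2 * as_matrix(EBImage::filter2(img, kk$gyy, boundary = "replicate"))
    hxy <- sigma^2 * as_matrix(EBImage::filter2(img, kk$gxy, boundary = "replicate"))
    tmp <- sqrt((hxx - hyy)^2 + 4 * hxy^2)
    l_a <- (hxx + hyy + tmp) / 2
    l_b <- (hxx + hyy - tmp) / 2
    # order by magnitude: |l1| <= |l2|
    swap <- abs(l_a) > abs(l_b)
    l1 <- ifelse(swap, l_b, l_a)
    l2 <- ifelse(swap, l_a, l_b)
    S2 <- l1^2 + l2^2
    c2 <- max(sqrt(S2)) / 2
    if (c2 <= 1e-10 * max(abs(img), 1e-12)) next
    rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c2^2)))
    v[l2 >= 0] <- 0
    best <- pmax(best, v)
  }
  microvessel_image(best, image$pixel_size_mm,
                    provenance = c(image$provenance,
                                   list(vesselness_scales_mm = scales_mm,
                                        vesselness_beta = beta)))
}
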