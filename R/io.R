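# Readers and writers for the pipeline's standard formats: single-channel
# TIFF/PNG images and masks, CSV metric tables, JSON provenance sidecars,
# and RDS-serialized IQ ensembles.

#' Write a microvessel image as single-channel float TIFF
#'
#' Intensities are stored as 32-bit float; pixel size goes into a JSON
#' sidecar (`<path>.json`).
#'
#' @param image a [microvessel_image()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  tiff::writeTIFF(image$data, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_size_mm = image$pixel_size_mm, provenance = image$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a grayscale image (TIFF or PNG) as a microvessel image
#'
#' Multi-channel files are averaged to one channel; a JSON sidecar (if
#' present) supplies the pixel size, otherwise it must be given.  With
#' `normalize = TRUE` intensities are rescaled to \[0, 1\] by the maximum.
#'
#' @param path `.tif`/`.tiff` or `.png` file.
#' @param pixel_size_mm pixel size in mm (overrides any sidecar).
#' @param normalize rescale to \[0, 1\]?
#' @return A [microvessel_image()].
#' @export
read_image <- function(path, pixel_size_mm = NULL, normalize = FALSE) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    "tif" = , "tiff" = tiff::readTIFF(path),
    "png" = png::readPNG(path),
    stop(sprintf("unsupported image format '%s'", ext), call. = FALSE))
  if (length(dim(m)) == 3L) m <- apply(m, c(1, 2), mean)
  sidecar <- paste0(path, ".json")
  if (is.null(pixel_size_mm) && file.exists(sidecar)) {
    pixel_size_mm <- jsonlite::read_json(sidecar)$pixel_size_mm
  }
  if (is.null(pixel_size_mm)) {
    stop("pixel size unknown: give `pixel_size_mm` or provide a JSON sidecar",
         call. = FALSE)
  }
  img <- microvessel_image(m, pixel_size_mm,
                           provenance = list(source = basename(path)))
  if (normalize) img <- normalize_image(img) else {
    if (max(img$data) > 1) img$data <- img$data / max(img$data)
  }
  img
}

#' Write a lesion mask as uint8 PNG (0/255)
#' @param mask a [lesion_mask()].
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask$data * 1, path)
  jsonlite::write_json(
    list(pixel_size_mm = mask$pixel_size_mm, kind = mask$kind,
         dilation_mm = mask$dilation_mm),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a lesion mask (any nonzero pixel is foreground)
#' @param path `.png` or `.tif` file.
#' @param pixel_size_mm pixel size in mm (sidecar used when `NULL`).
#' @return A [lesion_mask()].
#' @export
read_mask <- function(path, pixel_size_mm = NULL) {
  img <- read_image(path, pixel_size_mm = pixel_size_mm %||% 1)
  sidecar <- paste0(path, ".json")
  kind <- "original"; dil <- 0
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (is.null(pixel_size_mm)) pixel_size_mm <- meta$pixel_size_mm
    kind <- meta$kind %||% "original"
    dil <- meta$dilation_mm %||% 0
  }
  if (is.null(pixel_size_mm)) {
    stop("pixel size unknown for mask", call. = FALSE)
  }
  lesion_mask(img$data != 0, pixel_size_mm, kind = kind, dilation_mm = dil)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an IQ ensemble
#'
#' Ensembles are serialized as RDS (a list holding the complex data cube
#' and its sampling metadata); the round trip is bit-exact.
#'
#' @param ensemble an [iq_ensemble()].
#' @param path output `.rds` path.
#' @return `path` (write) or an [iq_ensemble()] (read).
#' @export
write_ensemble <- function(ensemble, path) {
  saveRDS(unclass(ensemble), path)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  x <- readRDS(path)
  iq_ensemble(x$data, x$pixel_size_mm, x$frame_rate_hz)
}

#' Write / read a biomarker metric table
#'
#' CSV with one row per lesion in the fixed column order `lesion_id`,
#' `label`, `VD`, `D_mean_mm`, `MD_mean`, `FD`, `NB`, `NV`, `tau_mean`,
#' `tau_max`, `BA_mean_deg` (plus any extra columns).  Numeric values are
#' written with full precision so a rerun under the same configuration is
#' byte-identical.
#'
#' @param table metric data frame.
#' @param path output `.csv` path.
#' @return `path` (write) or a data frame (read).
#' @export
write_metrics_csv <- function(table, path) {
  lead <- intersect(c("lesion_id", "label", metric_names(), "roi_area_mm2"),
                    names(table))
  table <- table[c(lead, setdiff(names(table), lead))]
  num <- vapply(table, is.numeric, logical(1))
  out <- table
  out[num] <- lapply(table[num], function(v) {
    ifelse(is.na(v), "", formatC(v, digits = 15, format = "g"))
  })
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (mt in intersect(c(metric_names(), "roi_area_mm2"), names(tab))) {
    tab[[mt]] <- as.numeric(tab[[mt]])
  }
  tab
}

#' Write a provenance JSON sidecar
#'
#' @param x named list of provenance fields (config, seed, versions).
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(x, path) {
  x$package_version <- as.character(utils::packageVersion("microvasq"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
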