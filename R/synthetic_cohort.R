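# Two-group cohort emulation: image-level cohorts (synthetic trees whose
# morphology differs between benign-like and malignant-like groups) and
# metric-level cohorts (biomarker draws matched to published group moments).

metric_names <- function() {
  c("VD", "D_mean_mm", "MD_mean", "FD", "NB", "NV",
    "tau_mean", "tau_max", "BA_mean_deg")
}

#' Reference biomarker group moments
#'
#' Mean/SD pairs per biomarker for benign (n = 10) and malignant (n = 19)
#' hepatic lesions, as reported for contrast-free HDMI morphometry of liver
#' masses.  Used as the default moments of the metric-level cohort
#' generator.
#'
#' @return Named list of data frames (`benign`, `malignant`), each with
#'   columns `metric`, `mean`, `sd`.
#' @export
reference_group_moments <- function() {
  m <- metric_names()
  list(
    benign = data.frame(
      metric = m,
      mean = c(0.045, 1.641, 0.350, 1.161, 1.700, 5.400, 1.020, 1.048, 95.808),
      sd   = c(0.026, 0.356, 0.081, 0.080, 2.057, 2.716, 0.007, 0.027, 4.214)
    ),
    malignant = data.frame(
      metric = m,
      mean = c(0.074, 1.555, 0.351, 1.295, 11.263, 24.894, 1.035, 1.192, 102.783),
      sd   = c(0.058, 0.378, 0.101, 0.153, 12.520, 22.439, 0.018, 0.192, 13.177)
    )
  )
}

#' Specify a two-group synthetic cohort
#'
#' Image-level mode draws a synthetic vascular tree per lesion from
#' group-specific tree parameters: malignant-like trees have more roots,
#' deeper branching, larger tortuosity amplitude and a wider, larger
#' bifurcation-angle distribution than benign-like trees, so true NV, NB,
#' tortuosity and fractal dimension are stochastically larger in the
#' malignant group.  Metric-level mode draws each biomarker from a
#' log-normal matched to the supplied mean/SD (biomarkers with a hard floor
#' of 1 — tortuosity, fractal dimension — are drawn as 1 + log-normal on
#' the excess).
#'
#' @param n_benign,n_malignant group sizes (defaults mirror a 10 vs 19
#'   benign/malignant study design).
#' @param mode `"image"` or `"metrics"`.
#' @param benign_tree,malignant_tree [vessel_tree_spec()] templates for
#'   image-level mode.
#' @param moments group moments for metric-level mode
#'   (default [reference_group_moments()]).
#' @param background_level,noise_sd image-level background model.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_benign = 10L, n_malignant = 19L,
                        mode = c("image", "metrics"),
                        benign_tree = vessel_tree_spec(
                          n_roots = 1L, depth = 2L,
                          tortuosity_amplitude_mm = 0.12,
                          tortuosity_cycles = 1L,
                          branch_angle_deg_mean = 76,
                          branch_angle_deg_sd = 5,
                          segment_length_mm_mean = 3.6,
                          segment_length_mm_sd = 0.5
                        ),
                        malignant_tree = vessel_tree_spec(
                          n_roots = 2L, depth = 3L,
                          tortuosity_amplitude_mm = 0.45,
                          tortuosity_cycles = 2L,
                          branch_angle_deg_mean = 88,
                          branch_angle_deg_sd = 12,
                          segment_length_mm_mean = 3.0,
                          segment_length_mm_sd = 0.5
                        ),
                        moments = reference_group_moments(),
                        background_level = 0.08, noise_sd = 0.04,
                        seed = 1L) {
  mode <- match.arg(mode)
  if (n_benign < 1L || n_malignant < 1L) {
    stop("group sizes must be >= 1", call. = FALSE)
  }
  for (g in names(moments)) {
    if (any(moments[[g]]$sd <= 0)) {
      stop("metric-level moments require positive SDs", call. = FALSE)
    }
  }
  structure(
    list(n_benign = as.integer(n_benign), n_malignant = as.integer(n_malignant),
         mode = mode, benign_tree = benign_tree,
         malignant_tree = malignant_tree, moments = moments,
         background_level = background_level, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# lognormal parameters matched to an arithmetic mean/SD pair
lognormal_params <- function(m, s) {
  sdlog2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

draw_metric <- function(n, metric, m, s) {
  floor1 <- metric %in% c("tau_mean", "tau_max", "FD")
  if (floor1) {
    p <- lognormal_params(max(m - 1, 1e-6), s)
    x <- 1 + stats::rlnorm(n, p$meanlog, p$sdlog)
  } else {
    p <- lognormal_params(m, s)
    x <- stats::rlnorm(n, p$meanlog, p$sdlog)
  }
  if (metric %in% c("NV", "NB")) x <- round(x)
  if (metric == "VD") x <- pmin(x, 1)
  if (metric == "FD") x <- pmin(x, 2)
  if (metric == "BA_mean_deg") x <- pmin(x, 180)
  x
}

#' Generate a labeled two-group cohort
#'
#' @param spec a [cohort_spec()].
#' @param seed optional integer overriding `spec$seed`.
#' @return Image-level mode: list with class `cohort_images`, element
#'   `lesions` — one entry per lesion with `lesion_id`, `label`, `image`
#'   (a [microvessel_image()]), `mask` (a [lesion_mask()] covering the full
#'   field of view), and `truth` (generator ground truth).  Metric-level
#'   mode: a data frame (one row per lesion) in the morphometrics CSV
#'   schema.
#' @export
generate_cohort <- function(spec, seed = NULL) {
  if (is.null(seed)) seed <- spec$seed
  labels <- c(rep("benign", spec$n_benign), rep("malignant", spec$n_malignant))
  if (spec$mode == "metrics") {
    return(with_seed(seed, {
      rows <- lapply(seq_along(labels), function(i) {
        g <- if (labels[i] == "benign") "benign" else "malignant"
        mom <- spec$moments[[g]]
        vals <- vapply(seq_len(nrow(mom)), function(k) {
          draw_metric(1L, mom$metric[k], mom$mean[k], mom$sd[k])
        }, numeric(1))
        names(vals) <- mom$metric
        data.frame(lesion_id = sprintf("L%03d", i), label = labels[i],
                   t(vals))
      })
      tab <- do.call(rbind, rows)
      rownames(tab) <- NULL
      tab
    }))
  }
  # image-level mode: per-lesion seed derived deterministically
  lesion_seeds <- with_seed(seed, sample.int(.Machine$integer.max / 2,
                                             length(labels)))
  lesions <- lapply(seq_along(labels), function(i) {
    base <- if (labels[i] == "benign") spec$benign_tree else spec$malignant_tree
    tg <- generate_vessel_tree(base, seed = lesion_seeds[i])
    img <- add_background(rasterize_tree(tg$tree)$image,
                          noise_sd = spec$noise_sd,
                          background_level = spec$background_level,
                          seed = lesion_seeds[i] + 1L)
    mask <- lesion_mask(matrix(TRUE, nrow(img$data), ncol(img$data)),
                        img$pixel_size_mm, kind = "dilated",
                        dilation_mm = 0)
    list(lesion_id = sprintf("L%03d", i), label = labels[i],
         image = img, mask = mask, truth = tg$truth)
  })
  structure(list(lesions = lesions, seed = seed), class = "cohort_images")
}
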