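# Slow-time IQ ensemble simulator: rank-limited tissue clutter + vessel-
# confined decorrelating blood signal + white complex noise, with stated
# power ratios.  Makes SVD clutter separation provably effective and lets
# the filter be checked against an explicit clutter subspace.

# smooth unit-power spatial field (gaussian-blurred white noise); the blur
# kernel is capped so tiny grids remain valid
smooth_field <- function(nr, nc, sigma_px = 8) {
  f <- matrix(stats::rnorm(nr * nc), nr, nc)
  sigma_px <- min(sigma_px, (min(nr, nc) - 1) / 6.5)
  if (sigma_px >= 0.5) f <- as_matrix(EBImage::gblur(f, sigma = sigma_px))
  f <- f - mean(f)
  f / sqrt(mean(f^2))
}

#' Simulate a slow-time IQ ensemble over a vessel mask
#'
#' The ensemble is the sum of three components: (1) tissue clutter — a
#' rank-`clutter_rank` sum of outer products of smooth spatial fields and
#' slowly varying unit-modulus temporal envelopes, scaled to
#' `clutter_to_blood_db` above the blood signal; (2) blood — a per-pixel
#' complex AR(1) process (coefficient `blood_ar`, unit power) confined to
#' `vessel_mask`; (3) white complex noise at `noise_db` relative to blood.
#' Power ratios are set analytically, not estimated, so the simulator is a
#' pure function of its arguments and seed.
#'
#' @param vessel_mask logical matrix of vessel support.
#' @param n_frames number of slow-time frames (>= 2).
#' @param clutter_to_blood_db clutter power per pixel relative to blood
#'   power per vessel pixel, dB. `-Inf` disables clutter.
#' @param noise_db noise power relative to blood, dB. `-Inf` disables noise.
#' @param seed integer seed.
#' @param clutter_rank number of clutter components (default 1).
#' @param blood_ar AR(1) coefficient of the blood signal (short coherence).
#' @param pixel_size_mm,frame_rate_hz grid and sampling metadata.
#' @param components when `TRUE`, also return the separate clutter, blood
#'   and noise cubes (for oracle checks of the clutter filter).
#' @return An [iq_ensemble()]; with `components = TRUE`, a list
#'   `(ensemble, clutter, blood, noise)`.
#' @export
simulate_iq_ensemble <- function(vessel_mask, n_frames = 64L,
                                 clutter_to_blood_db = 40,
                                 noise_db = -20, seed = 1L,
                                 clutter_rank = 1L, blood_ar = 0.3,
                                 pixel_size_mm = 0.1,
                                 frame_rate_hz = 1000,
                                 components = FALSE) {
  vessel_mask <- as_matrix(vessel_mask) != 0
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) {
    stop("`n_frames` must be >= 2 (clutter filtering is undefined otherwise)",
         call. = FALSE)
  }
  nr <- nrow(vessel_mask); nc <- ncol(vessel_mask)
  parts <- with_seed(seed, {
    blood <- array(0 + 0i, dim = c(nr, nc, n_frames))
    clutter <- array(0 + 0i, dim = c(nr, nc, n_frames))
    noise <- array(0 + 0i, dim = c(nr, nc, n_frames))
    # blood: complex AR(1), unit stationary power, inside the mask only
    idx <- which(vessel_mask)
    if (length(idx)) {
      b <- complex(real = stats::rnorm(length(idx), 0, sqrt(0.5)),
                   imaginary = stats::rnorm(length(idx), 0, sqrt(0.5)))
      innov_sd <- sqrt((1 - blood_ar^2) / 2)
      for (t in seq_len(n_frames)) {
        if (t > 1L) {
          b <- blood_ar * b +
            complex(real = stats::rnorm(length(idx), 0, innov_sd),
                    imaginary = stats::rnorm(length(idx), 0, innov_sd))
        }
        frame <- matrix(0 + 0i, nr, nc)
        frame[idx] <- b
        blood[, , t] <- frame
      }
    }
    # clutter: rank-limited, common spatial structure, slow temporal drift
    if (is.finite(clutter_to_blood_db)) {
      amp_c <- sqrt(10^(clutter_to_blood_db / 10) / clutter_rank)
      tt <- seq_len(n_frames) / n_frames
      for (k in seq_len(clutter_rank)) {
        sp <- smooth_field(nr, nc, sigma_px = max(4, min(nr, nc) / 8))
        drift <- 2 * pi * (0.2 * k) * tt + 0.3 * sin(2 * pi * tt * k / 2)
        env <- exp(1i * drift)
        for (t in seq_len(n_frames)) {
          clutter[, , t] <- clutter[, , t] + amp_c * sp * env[t]
        }
      }
    }
    # white complex noise
    if (is.finite(noise_db)) {
      amp_n <- sqrt(10^(noise_db / 10) / 2)
      noise <- array(complex(real = stats::rnorm(nr * nc * n_frames, 0, amp_n),
                             imaginary = stats::rnorm(nr * nc * n_frames, 0, amp_n)),
                     dim = c(nr, nc, n_frames))
    }
    list(clutter = clutter, blood = blood, noise = noise)
  })
  ens <- iq_ensemble(parts$clutter + parts$blood + parts$noise,
                     pixel_size_mm, frame_rate_hz)
  if (components) {
    return(list(ensemble = ens, clutter = parts$clutter,
                blood = parts$blood, noise = parts$noise))
  }
  ens
}
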