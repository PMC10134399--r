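# Synthetic vascular-tree generator: the ground-truth source for every
# downstream stage (rasterization, segmentation, skeleton morphometry).

#' Specify a synthetic vascular tree
#'
#' Parameters of the recursive binary branching generator.  Daughter
#' diameters at each bifurcation satisfy the generalized Murray relation
#' `d_p^k = d_1^k + d_2^k` (k = `murray_exponent`) exactly before
#' multiplicative noise of relative SD `murray_noise` is applied.  Each
#' segment centerline is a straight chord plus a windowed sinusoidal
#' transverse perturbation `a * sin(2*pi*c*t) * sin(pi*t)^2` whose value and
#' slope vanish at both segment ends, so bifurcation geometry is controlled
#' by the chord directions alone.
#'
#' @param n_roots number of independent root vessels.
#' @param depth branching generations per root (0 = unbranched root only).
#' @param root_diameter_mm diameter of each root segment, mm.
#' @param murray_exponent branching exponent k (3 = Murray-compliant).
#' @param murray_noise relative SD of multiplicative daughter-diameter noise.
#' @param tortuosity_amplitude_mm peak transverse centerline perturbation, mm.
#' @param tortuosity_cycles sinusoid cycles per segment.
#' @param branch_angle_deg_mean,branch_angle_deg_sd mean/SD of the
#'   daughter-daughter opening angle at a bifurcation, degrees.
#' @param segment_length_mm_mean,segment_length_mm_sd mean/SD of segment
#'   chord length, mm.
#' @param field_of_view_mm numeric length-2 `(width, height)` in mm.
#' @param pixel_size_mm rasterization pixel size, mm.
#' @param seed integer seed making the generator a pure function of its spec.
#' @return An object of class `vessel_tree_spec`.
#' @export
vessel_tree_spec <- function(n_roots = 1L,
                             depth = 2L,
                             root_diameter_mm = 1.2,
                             murray_exponent = 3,
                             murray_noise = 0,
                             tortuosity_amplitude_mm = 0.3,
                             tortuosity_cycles = 1L,
                             branch_angle_deg_mean = 70,
                             branch_angle_deg_sd = 8,
                             segment_length_mm_mean = 4,
                             segment_length_mm_sd = 0.6,
                             field_of_view_mm = c(19.2, 19.2),
                             pixel_size_mm = 0.1,
                             seed = 1L) {
  spec <- list(
    n_roots = as.integer(n_roots), depth = as.integer(depth),
    root_diameter_mm = root_diameter_mm, murray_exponent = murray_exponent,
    murray_noise = murray_noise,
    tortuosity_amplitude_mm = tortuosity_amplitude_mm,
    tortuosity_cycles = tortuosity_cycles,
    branch_angle_deg_mean = branch_angle_deg_mean,
    branch_angle_deg_sd = branch_angle_deg_sd,
    segment_length_mm_mean = segment_length_mm_mean,
    segment_length_mm_sd = segment_length_mm_sd,
    field_of_view_mm = as.numeric(field_of_view_mm),
    pixel_size_mm = pixel_size_mm, seed = as.integer(seed)
  )
  validate_tree_spec(spec)
  structure(spec, class = "vessel_tree_spec")
}

validate_tree_spec <- function(spec) {
  if (spec$n_roots < 1L) stop("`n_roots` must be >= 1", call. = FALSE)
  if (spec$depth < 0L) stop("`depth` must be >= 0", call. = FALSE)
  stopifnot_scalar_pos(spec$root_diameter_mm, "root_diameter_mm")
  stopifnot_scalar_pos(spec$murray_exponent, "murray_exponent")
  if (spec$murray_noise < 0) stop("`murray_noise` must be >= 0", call. = FALSE)
  if (spec$tortuosity_amplitude_mm < 0) {
    stop("`tortuosity_amplitude_mm` must be >= 0", call. = FALSE)
  }
  stopifnot_scalar_pos(spec$segment_length_mm_mean, "segment_length_mm_mean")
  if (spec$segment_length_mm_sd < 0) {
    stop("`segment_length_mm_sd` must be >= 0", call. = FALSE)
  }
  if (length(spec$field_of_view_mm) != 2L || any(spec$field_of_view_mm <= 0)) {
    stop("`field_of_view_mm` must be two positive numbers", call. = FALSE)
  }
  stopifnot_scalar_pos(spec$pixel_size_mm, "pixel_size_mm")
  invisible(spec)
}

# densified centerline: chord from p0 along unit vector u for length L,
# plus windowed-sinusoid transverse offset (zero value/slope at both ends)
segment_centerline <- function(p0, u, L, amp, cycles, step_mm = 0.02) {
  n <- max(25L, ceiling(L / step_mm) + 1L)
  t <- seq(0, 1, length.out = n)
  offset <- amp * sin(2 * pi * cycles * t) * sin(pi * t)^2
  nrm <- c(-u[2], u[1])
  cbind(
    p0[1] + L * t * u[1] + offset * nrm[1],
    p0[2] + L * t * u[2] + offset * nrm[2]
  )
}

#' Generate a synthetic vascular tree with exact ground truth
#'
#' Recursive binary branching for `depth` generations from each root.  The
#' returned ground truth records exact segment and branch-point counts,
#' per-segment arc/chord tortuosity computed on the dense centerline,
#' per-bifurcation parent/daughter diameters and opening angles, and the
#' rasterized vessel mask.
#'
#' @param spec a [vessel_tree_spec()].
#' @param seed optional integer overriding `spec$seed`.
#' @return A list with elements `tree` (class `vessel_tree`: `segments`,
#'   `bifurcations`) and `truth` (class `vessel_ground_truth`: `true_NV`,
#'   `true_NB`, `tortuosity`, `bifurcations`, `vessel_mask`, `total_length_mm`).
#' @examples
#' tg <- generate_vessel_tree(vessel_tree_spec(depth = 2, seed = 7))
#' tg$truth$true_NV  # 7 segments for a depth-2 binary tree
#' @export
generate_vessel_tree <- function(spec, seed = NULL) {
  validate_tree_spec(spec)
  if (is.null(seed)) seed <- spec$seed
  with_seed(seed, {
    fov <- spec$field_of_view_mm
    segments <- list()
    bifs <- list()
    sign_pool <- c(-1, 1)
    root_x <- seq(0.25, 0.75, length.out = max(spec$n_roots, 2L)) * fov[1]
    if (spec$n_roots == 1L) root_x <- fov[1] / 2
    # obstacle cloud for collision avoidance: centerline samples with
    # radius and owning-segment id
    obst <- matrix(numeric(0), 0L, 4L)
    clearance <- 4.5 * spec$pixel_size_mm

    draw_len <- function() {
      max(0.8, stats::rnorm(1, spec$segment_length_mm_mean,
                            spec$segment_length_mm_sd))
    }

    sample_path <- function(path, step = 0.12) {
      arc <- polyline_length(path)
      n <- max(3L, ceiling(arc / step) + 1L)
      s <- seq(0, 1, length.out = n)
      t0 <- seq(0, 1, length.out = nrow(path))
      cbind(stats::approx(t0, path[, 1], xout = s)$y,
            stats::approx(t0, path[, 2], xout = s)$y)
    }

    # obstacle rows relevant to a daughter growing from junction p0:
    # segments in `family_ids` (parent/grandparent, which legitimately meet
    # the path at the junction) are exempt within `excl_mm` of p0 only
    relevant_obst <- function(p0, excl_mm, family_ids, extra = NULL,
                              reach = Inf) {
      ob <- rbind(obst, extra)
      if (nrow(ob) == 0L) return(ob)
      if (is.finite(reach)) {
        near <- abs(ob[, 1] - p0[1]) <= reach & abs(ob[, 2] - p0[2]) <= reach
        ob <- ob[near, , drop = FALSE]
        if (nrow(ob) == 0L) return(ob)
      }
      d_junc <- sqrt((ob[, 1] - p0[1])^2 + (ob[, 2] - p0[2])^2)
      ob[!(ob[, 4] %in% family_ids & d_junc <= excl_mm), , drop = FALSE]
    }

    # per-sample clearance violations of a candidate path against an
    # obstacle set and the field-of-view border (so generated topology is
    # never clipped); thresholding squared distances avoids sqrt and
    # row-minimum passes
    path_viol <- function(q, r, ob) {
      viol <- pmin(q[, 1], q[, 2], fov[1] - q[, 1], fov[2] - q[, 2]) - r <=
        clearance
      if (nrow(ob) > 0L) {
        d2 <- outer(q[, 1], ob[, 1], "-")^2 + outer(q[, 2], ob[, 2], "-")^2
        thr <- (clearance + r + ob[, 3])^2
        viol <- viol | rowSums(d2 <= matrix(thr, nrow(q), nrow(ob),
                                            byrow = TRUE)) > 0L
      }
      viol
    }

    # arc position just before the first clearance violation (Inf if clear)
    cut_arc <- function(q, viol) {
      k <- which(viol)
      if (length(k) == 0L) return(Inf)
      arc_q <- c(0, cumsum(sqrt(rowSums(diff(q)^2))))
      arc_q[k[1L]] - 0.3
    }

    # shorten a path to the given arc length (a vessel terminating short of
    # another vessel rather than crossing it)
    apply_cut <- function(path, cut) {
      if (!is.finite(cut)) return(path)
      arc_p <- c(0, cumsum(sqrt(rowSums(diff(path)^2))))
      keep <- arc_p <= cut
      if (sum(keep) < 2L) keep[1:2] <- TRUE
      path[keep, , drop = FALSE]
    }

    new_segment <- function(path, theta, diam, gen, parent) {
      id <- length(segments) + 1L
      segments[[id]] <<- list(
        id = id, parent = parent, generation = gen, path = path,
        diameter_mm = diam,
        chord_mm = sqrt(sum((path[nrow(path), ] - path[1L, ])^2)),
        theta = theta,
        arc_mm = polyline_length(path)
      )
      q <- sample_path(path)
      obst <<- rbind(obst, cbind(q, diam / 2, id))
      id
    }

    # propose a daughter centerline; direction theta (rad from +y toward +x)
    propose <- function(p0, theta, diam, len_scale = 1) {
      L <- draw_len() * len_scale
      amp <- spec$tortuosity_amplitude_mm * sample(sign_pool, 1L)
      path <- segment_centerline(p0, c(sin(theta), cos(theta)), L, amp,
                                 spec$tortuosity_cycles)
      list(path = path, L = L, theta = theta)
    }

    grow <- function(seg_id, gen) {
      if (gen > spec$depth) return(invisible())
      par <- segments[[seg_id]]
      p_end <- par$path[nrow(par$path), ]
      k <- spec$murray_exponent
      d_sym <- par$diameter_mm * 2^(-1 / k)
      d1 <- d_sym; d2 <- d_sym
      if (spec$murray_noise > 0) {
        d1 <- d1 * max(0.2, 1 + stats::rnorm(1, 0, spec$murray_noise))
        d2 <- d2 * max(0.2, 1 + stats::rnorm(1, 0, spec$murray_noise))
      }
      excl <- max(1, 1.5 * par$diameter_mm)
      family <- c(seg_id, par$parent)
      # resample the daughter pair's geometry until both stay clear of the
      # rest of the tree (keeps rasterized topology equal to the generated
      # topology); if no clear geometry is found, the final candidates are
      # truncated so each daughter terminates before its first collision
      got <- NULL
      reach <- spec$segment_length_mm_mean + 4 * spec$segment_length_mm_sd +
        spec$tortuosity_amplitude_mm + 2
      ob1 <- relevant_obst(p_end, excl, family, reach = reach)
      for (attempt in 1:40) {
        open_angle <- stats::rnorm(1, spec$branch_angle_deg_mean,
                                   spec$branch_angle_deg_sd)
        open_angle <- min(max(open_angle, 10), 170)
        half <- open_angle / 2 * pi / 180
        len_scale <- if (attempt > 20) 0.75 else 1
        c1 <- propose(p_end, par$theta - half, d1, len_scale)
        c2 <- propose(p_end, par$theta + half, d2, len_scale)
        q1 <- sample_path(c1$path)
        g1 <- path_viol(q1, d1 / 2, ob1)
        q2 <- sample_path(c2$path)
        got <- list(c1 = c1, c2 = c2, open_angle = open_angle,
                    q1 = q1, g1 = g1, q2 = q2, excl = excl)
        if (any(g1)) next
        # the sibling is exempt near the junction like the parent (id -1)
        ob2 <- relevant_obst(p_end, excl, c(family, -1),
                             extra = cbind(q1, d1 / 2, -1), reach = reach)
        g2 <- path_viol(q2, d2 / 2, ob2)
        if (!any(g2)) break
      }
      cut1 <- cut_arc(got$q1, got$g1)
      if (is.finite(cut1)) {
        got$c1$path <- apply_cut(got$c1$path, max(cut1, 1.5))
        got$q1 <- sample_path(got$c1$path)
      }
      ob2 <- relevant_obst(p_end, excl, c(family, -1),
                           extra = cbind(got$q1, d1 / 2, -1),
                           reach = reach)
      cut2 <- cut_arc(got$q2, path_viol(got$q2, d2 / 2, ob2))
      if (is.finite(cut2)) got$c2$path <- apply_cut(got$c2$path,
                                                   max(cut2, 1.5))
      # no room for two viable daughters: the parent terminates instead of
      # bifurcating, and the ground truth records that topology
      if (min(cut1, cut2) < 1.5) return(invisible())
      id1 <- new_segment(got$c1$path, got$c1$theta, d1, gen, seg_id)
      id2 <- new_segment(got$c2$path, got$c2$theta, d2, gen, seg_id)
      # ground-truth opening angle between the actual daughter chords
      # (equals the drawn angle unless a daughter was truncated)
      chord_dir <- function(id) {
        p <- segments[[id]]$path
        v <- p[nrow(p), ] - p[1L, ]
        v / sqrt(sum(v^2))
      }
      u1 <- chord_dir(id1); u2 <- chord_dir(id2)
      actual_angle <- acos(min(max(sum(u1 * u2), -1), 1)) * 180 / pi
      bifs[[length(bifs) + 1L]] <<- data.frame(
        parent = seg_id, daughter1 = id1, daughter2 = id2,
        x_mm = p_end[1], y_mm = p_end[2],
        d_p = par$diameter_mm, d_1 = d1, d_2 = d2,
        angle_deg = actual_angle
      )
      # a daughter truncated too short to host a clean downstream junction
      # terminates instead of branching (the generated topology, recorded
      # in the ground truth, is what the skeleton stage must recover)
      if (segments[[id1]]$arc_mm >= 1.8) grow(id1, gen + 1L)
      if (segments[[id2]]$arc_mm >= 1.8) grow(id2, gen + 1L)
    }

    for (r in seq_len(spec$n_roots)) {
      p0 <- c(root_x[r], 0.08 * fov[2])
      cand <- NULL
      for (attempt in 1:40) {
        tilt <- stats::rnorm(1, 0, 5) * pi / 180
        cand <- propose(p0, tilt, spec$root_diameter_mm)
        q <- sample_path(cand$path)
        g <- path_viol(q, spec$root_diameter_mm / 2,
                       relevant_obst(p0, 0, integer(0)))
        if (!any(g)) break
        if (attempt == 40L) {
          cand$path <- apply_cut(cand$path, max(cut_arc(q, g), 1.5))
        }
      }
      rid <- new_segment(cand$path, cand$theta,
                         spec$root_diameter_mm, 0L, NA_integer_)
      grow(rid, 1L)
    }

    bif_df <- if (length(bifs)) do.call(rbind, bifs) else
      data.frame(parent = integer(), daughter1 = integer(),
                 daughter2 = integer(), x_mm = numeric(), y_mm = numeric(),
                 d_p = numeric(), d_1 = numeric(), d_2 = numeric(),
                 angle_deg = numeric())

    tree <- structure(
      list(segments = segments, bifurcations = bif_df, spec = spec),
      class = "vessel_tree"
    )
    ras <- rasterize_tree(tree, spec$pixel_size_mm, fov)
    tort <- vapply(segments, function(s) s$arc_mm / s$chord_mm, numeric(1))
    truth <- structure(
      list(
        true_NV = length(segments),
        true_NB = nrow(bif_df),
        tortuosity = tort,
        bifurcations = bif_df,
        vessel_mask = ras$vessel_mask,
        total_length_mm = sum(vapply(segments, `[[`, numeric(1), "arc_mm")),
        diameters_mm = vapply(segments, `[[`, numeric(1), "diameter_mm")
      ),
      class = "vessel_ground_truth"
    )
    list(tree = tree, truth = truth)
  })
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree> %d segments, %d bifurcations\n",
              length(x$segments), nrow(x$bifurcations)))
  invisible(x)
}

#' Rasterize a vascular tree onto a pixel grid
#'
#' Each segment is painted as its dense centerline dilated to the segment
#' diameter: a pixel is foreground when its center lies within
#' `diameter / 2` of the centerline.  Intensity is 1 inside vessels and 0
#' outside; the mask is the exact painted support.  Geometry extending past
#' the field of view is clipped (recorded in provenance).
#'
#' @param tree a `vessel_tree`.
#' @param pixel_size_mm pixel size in mm.
#' @param field_of_view_mm numeric `(width, height)` in mm.
#' @return List with `image` (a [microvessel_image()]) and `vessel_mask`
#'   (logical matrix).
#' @export
rasterize_tree <- function(tree, pixel_size_mm = tree$spec$pixel_size_mm,
                           field_of_view_mm = tree$spec$field_of_view_mm) {
  stopifnot_scalar_pos(pixel_size_mm, "pixel_size_mm")
  nc <- max(2L, round(field_of_view_mm[1] / pixel_size_mm))
  nr <- max(2L, round(field_of_view_mm[2] / pixel_size_mm))
  mask <- matrix(FALSE, nr, nc)
  clipped <- FALSE
  min_d <- Inf
  for (seg in tree$segments) {
    min_d <- min(min_d, seg$diameter_mm)
    # resample centerline at sub-pixel spacing
    path <- seg$path
    arc <- polyline_length(path)
    n <- max(2L, ceiling(arc / (pixel_size_mm / 3)) + 1L)
    s <- seq(0, 1, length.out = n)
    t0 <- seq(0, 1, length.out = nrow(path))
    px <- stats::approx(t0, path[, 1], xout = s)$y / pixel_size_mm  # 0-based col
    py <- stats::approx(t0, path[, 2], xout = s)$y / pixel_size_mm  # 0-based row
    r_px <- (seg$diameter_mm / 2) / pixel_size_mm
    rad <- ceiling(r_px)
    dr <- rep(-rad:rad, times = 2L * rad + 1L)
    dc <- rep(-rad:rad, each = 2L * rad + 1L)
    # stamp all samples at once: candidate pixels = rounded centers + disk
    # offsets, kept where the pixel center falls inside the tube
    rr <- outer(round(py), dr, "+")
    cc <- outer(round(px), dc, "+")
    inside <- (rr - py)^2 + (cc - px)^2 <= r_px^2
    rr <- rr[inside]; cc <- cc[inside]
    keep <- rr >= 0 & rr <= nr - 1 & cc >= 0 & cc <= nc - 1
    if (any(!keep)) clipped <- TRUE
    mask[cbind(rr[keep] + 1L, cc[keep] + 1L)] <- TRUE
  }
  if (is.finite(min_d) && min_d <= pixel_size_mm) {
    warning("smallest vessel diameter is at or below one pixel; ",
            "sub-pixel vessels will rasterize poorly", call. = FALSE)
  }
  img <- microvessel_image(mask * 1, pixel_size_mm,
                           provenance = list(stage = "rasterize",
                                             clipped = clipped))
  list(image = img, vessel_mask = mask)
}

#' Add constant background and Gaussian noise to an image
#'
#' @param image a [microvessel_image()].
#' @param noise_sd Gaussian noise SD (intensity units).
#' @param background_level constant background added everywhere.
#' @param seed integer seed.
#' @return A [microvessel_image()]; values are clipped at 0.
#' @export
add_background <- function(image, noise_sd = 0.05, background_level = 0.1,
                           seed = 1L) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (background_level < 0) stop("`background_level` must be >= 0", call. = FALSE)
  out <- with_seed(seed, {
    d <- image$data + background_level
    if (noise_sd > 0) {
      d <- d + matrix(stats::rnorm(length(d), 0, noise_sd),
                      nrow(d), ncol(d))
    }
    pmax(d, 0)
  })
  microvessel_image(out, image$pixel_size_mm,
                    provenance = c(image$provenance,
                                   list(background_level = background_level,
                                        noise_sd = noise_sd, noise_seed = seed)))
}
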