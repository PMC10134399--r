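# The nine vessel-morphometry biomarkers computed from a skeleton graph and
# binary vessel map: VD, NV, NB, tau_mean, tau_max, D_mean, FD, MD_mean,
# BA_mean.

#' Vessel density within an ROI
#'
#' Fraction of ROI pixels occupied by binarized vessels.
#'
#' @param map a [binary_vessel_map()].
#' @param roi a [lesion_mask()] on the same grid (non-empty).
#' @return A fraction in \[0, 1\].
#' @export
vessel_density <- function(map, roi) {
  if (!all(dim(map$data) == dim(roi$data))) {
    stop("map and ROI shapes differ", call. = FALSE)
  }
  n_roi <- sum(roi$data)
  if (n_roi == 0L) stop("empty ROI: vessel density undefined", call. = FALSE)
  sum(map$data & roi$data) / n_roi
}

#' Count vessel segments (NV)
#' @param graph a `skeleton_graph`.
#' @return Integer edge count.
#' @export
count_segments <- function(graph) length(graph$edges)

#' Count branch points (NB)
#' @param graph a `skeleton_graph`.
#' @return Integer count of nodes with degree >= 3.
#' @export
count_branch_points <- function(graph) sum(graph$nodes$degree >= 3L)

#' Distance-metric tortuosity of a path
#'
#' Arc length of the polyline divided by the straight-line distance between
#' its endpoints; 1 for a straight vessel.
#'
#' @param path n x 2 coordinate matrix (any consistent units).
#' @return Dimensionless tortuosity >= 1, or `NA` for a closed path
#'   (coincident endpoints).
#' @export
tortuosity_dm <- function(path) {
  path <- as.matrix(path)
  if (nrow(path) < 2L) stop("path needs at least 2 points", call. = FALSE)
  chord <- sqrt(sum((path[nrow(path), ] - path[1L, ])^2))
  if (chord <= 0) return(NA_real_)
  polyline_length(path) / chord
}

# per-edge tortuosity on the smoothed pixel path
edge_tortuosity <- function(e) {
  if (e$chord_mm <= 0) return(NA_real_)
  e$length_mm / e$chord_mm
}

#' Aggregate segment tortuosity (tau_mean, tau_max)
#'
#' Distance-metric tortuosity per segment, aggregated over segments longer
#' than `min_segment_mm`; closed loops are excluded.
#'
#' @param graph a `skeleton_graph`.
#' @param min_segment_mm minimum segment length entering the aggregate.
#' @return List with `tau_mean`, `tau_max`, `per_segment`, `n_used`.
#' @export
tortuosity_summary <- function(graph, min_segment_mm = 0.3) {
  if (length(graph$edges) == 0L) {
    return(list(tau_mean = NA_real_, tau_max = NA_real_,
                per_segment = numeric(0), n_used = 0L))
  }
  tau <- vapply(graph$edges, edge_tortuosity, numeric(1))
  len <- vapply(graph$edges, `[[`, numeric(1), "length_mm")
  use <- !is.na(tau) & len >= min_segment_mm
  if (!any(use)) {
    return(list(tau_mean = NA_real_, tau_max = NA_real_,
                per_segment = tau, n_used = 0L))
  }
  # a measured polyline can undershoot its chord by sub-pixel jitter;
  # tortuosity is >= 1 by definition
  tt <- pmax(tau[use], 1)
  list(tau_mean = mean(tt), tau_max = max(tt), per_segment = tau,
       n_used = sum(use))
}

#' Mean vessel diameter (D_mean)
#'
#' Per-segment mean of twice the distance-transform radius along the
#' segment's skeleton pixels (junction-trimmed); D_mean averages over
#' segments.
#'
#' @param graph a `skeleton_graph` (radii attached by [build_graph()]).
#' @return Mean diameter in mm, or `NA` for an empty graph.
#' @export
mean_diameter <- function(graph) {
  if (length(graph$edges) == 0L) return(NA_real_)
  mean(vapply(graph$edges, `[[`, numeric(1), "diameter_mm"))
}

#' Box-counting fractal dimension
#'
#' Counts occupied boxes N(s) over dyadic box sizes s and fits
#' log N(s) ~ log s by least squares; FD is minus the slope.  The two
#' extreme sizes (single-pixel boxes and the whole-image box) are excluded
#' from the fit by default.
#'
#' @param mask logical matrix of foreground (vessel map restricted to ROI).
#' @param drop_extremes how many sizes to drop at each end of the dyadic
#'   ladder (default 1).
#' @return FD (dimensionless), or `NA` when fewer than 3 scales remain.
#' @export
fractal_dimension <- function(mask, drop_extremes = 1L) {
  mask <- as_matrix(mask) != 0
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0L) return(NA_real_)
  # crop to the foreground bounding box so box origins are data-defined
  r0 <- min(pts[, 1L]); c0 <- min(pts[, 2L])
  r <- pts[, 1L] - r0; co <- pts[, 2L] - c0     # 0-based
  extent <- max(max(r), max(co)) + 1L
  k_max <- floor(log2(extent))
  sizes <- 2^(0:k_max)
  if (length(sizes) < 3L) return(NA_real_)
  counts <- vapply(sizes, function(s) {
    length(unique((r %/% s) * (max(co %/% s) + 1L) + (co %/% s)))
  }, numeric(1))
  keep <- seq_along(sizes)
  if (drop_extremes > 0L) {
    keep <- keep[keep > drop_extremes & keep <= length(sizes) - drop_extremes]
  }
  if (length(keep) < 3L) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, log(sizes[keep])), log(counts[keep]))
  -unname(fit$coefficients[2L])
}

#' Murray's-law deviation at bifurcations (MD_mean)
#'
#' At each degree-3 node the parent is the incident segment with the
#' largest mean diameter (ties: longest segment, then lowest node id) and
#' the cube-law relative deviation is
#' `|d_p^3 - (d_1^3 + d_2^3)| / d_p^3`: zero exactly when Murray's law
#' holds, and invariant under uniform scaling of all diameters.  Nodes with
#' four or more incident segments are excluded (counted in the result).
#'
#' @param graph a `skeleton_graph`.
#' @return List with `MD_mean`, `per_bifurcation` (data frame `node`, `d_p`,
#'   `d_1`, `d_2`, `MD`), `n_excluded`.  `MD_mean` is `NA` when the graph
#'   has no degree-3 bifurcation.
#' @export
murray_deviation <- function(graph) {
  res <- bifurcation_table(graph)
  if (nrow(res$tab) == 0L) {
    return(list(MD_mean = NA_real_,
                per_bifurcation = data.frame(node = integer(), d_p = numeric(),
                                             d_1 = numeric(), d_2 = numeric(),
                                             MD = numeric()),
                n_excluded = res$n_excluded))
  }
  tab <- res$tab
  md <- abs(tab$d_p^3 - (tab$d_1^3 + tab$d_2^3)) / tab$d_p^3
  list(MD_mean = mean(md),
       per_bifurcation = cbind(tab[c("node", "d_p", "d_1", "d_2")], MD = md),
       n_excluded = res$n_excluded)
}

# shared parent/daughter resolution at degree-3 nodes
bifurcation_table <- function(graph) {
  deg <- graph$nodes$degree
  bif_nodes <- which(deg >= 3L)
  n_excluded <- sum(deg >= 4L)
  rows <- list()
  for (nid in bif_nodes[deg[bif_nodes] == 3L]) {
    inc <- which(vapply(graph$edges, function(e) nid %in% e$nodes, logical(1)))
    if (length(inc) != 3L) next
    es <- graph$edges[inc]
    d <- vapply(es, `[[`, numeric(1), "diameter_mm")
    len <- vapply(es, `[[`, numeric(1), "length_mm")
    other <- vapply(es, function(e) e$nodes[e$nodes != nid][1L], numeric(1))
    ord <- order(-d, -len, other)
    parent <- ord[1L]; dgt <- ord[2:3]
    rows[[length(rows) + 1L]] <- data.frame(
      node = nid, d_p = d[parent], d_1 = d[dgt[1L]], d_2 = d[dgt[2L]],
      parent_edge = inc[parent], daughter_edges = I(list(inc[dgt]))
    )
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = integer(), d_p = numeric(), d_1 = numeric(),
               d_2 = numeric())
  list(tab = tab, n_excluded = n_excluded)
}

# outward tangent of an edge path leaving node nid.  Skeleton pixels
# inside the junction ball (arc distance below the node's distance-
# transform radius) trace thinning geometry, not the vessel centerline,
# so the fit window starts just beyond that radius; x(s) and y(s) are then
# fit as quadratics in arc length over `window_mm` (a straight-line fit
# would be biased by within-window curvature of tortuous daughters) and
# the tangent is the derivative at the window start.
edge_tangent_at <- function(e, nid, window_mm, psz, nodes = NULL) {
  p <- e$path_px
  r <- e$radius_mm
  if (e$nodes[2L] == nid && e$nodes[1L] != nid) {
    p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    r <- rev(r)
  }
  # infinite window: whole-segment direction (robust on tortuous segments,
  # akin to the node-to-node convention of several vessel-analysis tools):
  # principal axis of the path beyond the junction ball, which averages
  # pixel jitter and, for a symmetric bow, coincides with the chord.  The
  # junction ball is excluded because the node centroid and the skeleton
  # inside the crotch would widen the angle systematically.
  if (!is.finite(window_mm)) {
    steps0 <- c(0, cumsum(sqrt(rowSums(diff(p)^2)))) * psz
    skip0 <- min(2 * r[1L] + 2 * psz, 0.3 * steps0[length(steps0)])
    q <- p[steps0 >= skip0, , drop = FALSE]
    if (nrow(q) >= 3L) {
      q0 <- sweep(q, 2, colMeans(q))
      v <- eigen(crossprod(q0), symmetric = TRUE)$vectors[, 1L]
      if (sum(v * (q[nrow(q), ] - q[1L, ])) < 0) v <- -v
      return(v)
    }
  }
  p <- smooth_path(p, 5L)
  steps <- c(0, cumsum(sqrt(rowSums(diff(p)^2)))) * psz
  total <- steps[length(steps)]
  skip <- min(2 * r[1L] + 2 * psz, 0.4 * total)
  w <- min(window_mm, total - skip)
  sel <- steps >= skip - 1e-9 & steps <= skip + w + 1e-9
  if (sum(sel) < 2L) sel <- steps <= max(steps[2L], skip + w)
  q <- p[sel, , drop = FALSE]
  s <- steps[sel]
  if (nrow(q) < 5L) {
    v <- q[nrow(q), ] - q[1L, ]
  } else {
    X <- cbind(1, s, s^2)
    fy <- stats::lm.fit(X, q[, 1L])$coefficients
    fx <- stats::lm.fit(X, q[, 2L])$coefficients
    s0 <- s[1L]
    v <- c(fy[2L] + 2 * fy[3L] * s0, fx[2L] + 2 * fx[3L] * s0)
    if (sum(v * (colMeans(q) - q[1L, ])) < 0) v <- -v
  }
  n <- sqrt(sum(v^2))
  if (n == 0) return(c(1, 0))
  v / n
}

#' Bifurcation angles (BA_mean)
#'
#' At each degree-3 node, the angle between the two daughter segments'
#' outgoing directions (parent = largest-diameter incident segment).
#' With the default infinite window each daughter's direction is the chord
#' from this node's centroid to its far node's centroid, which is exact on
#' straight vessels and robust on tortuous ones.  A finite
#' `tangent_window_mm` switches to a local tangent: a quadratic fit in arc
#' length over that window, starting beyond the junction ball.  Values in
#' \[0, 180\] degrees.
#'
#' @param graph a `skeleton_graph`.
#' @param tangent_window_mm tangent-fit window in mm (default `Inf` =
#'   segment-chord convention).
#' @return List with `BA_mean` (degrees, `NA` if no degree-3 bifurcation)
#'   and `per_bifurcation` (data frame `node`, `angle_deg`).
#' @export
bifurcation_angle <- function(graph, tangent_window_mm = Inf) {
  res <- bifurcation_table(graph)
  if (nrow(res$tab) == 0L) {
    return(list(BA_mean = NA_real_,
                per_bifurcation = data.frame(node = integer(),
                                             angle_deg = numeric())))
  }
  psz <- graph$pixel_size_mm
  ang <- vapply(seq_len(nrow(res$tab)), function(i) {
    nid <- res$tab$node[i]
    dedges <- res$tab$daughter_edges[[i]]
    t1 <- edge_tangent_at(graph$edges[[dedges[1L]]], nid, tangent_window_mm,
                          psz, graph$nodes)
    t2 <- edge_tangent_at(graph$edges[[dedges[2L]]], nid, tangent_window_mm,
                          psz, graph$nodes)
    acos(pmin(pmax(sum(t1 * t2), -1), 1)) * 180 / pi
  }, numeric(1))
  list(BA_mean = mean(ang),
       per_bifurcation = data.frame(node = res$tab$node, angle_deg = ang))
}

#' Assemble the full biomarker record for one lesion
#'
#' Computes all nine biomarkers from a binary vessel map, its ROI and the
#' skeleton graph, and enforces the record invariants: `tau_max >=
#' tau_mean >= 1`, `VD` in \[0, 1\], and `MD_mean`/`BA_mean` missing if and
#' only if the graph has no branch point.
#'
#' @param map a [binary_vessel_map()].
#' @param roi a [lesion_mask()].
#' @param graph a `skeleton_graph`.
#' @param lesion_id,label identifiers copied into the record.
#' @param min_segment_mm tortuosity aggregation floor.
#' @param tangent_window_mm bifurcation-angle tangent window.
#' @return One-row data frame with columns `lesion_id`, `label`, `VD`,
#'   `D_mean_mm`, `MD_mean`, `FD`, `NB`, `NV`, `tau_mean`, `tau_max`,
#'   `BA_mean_deg`, `roi_area_mm2`.
#' @export
quantify <- function(map, roi, graph, lesion_id = "lesion", label = NA_character_,
                     min_segment_mm = 0.3, tangent_window_mm = Inf) {
  vd <- vessel_density(map, roi)
  nv <- count_segments(graph)
  nb <- count_branch_points(graph)
  tau <- tortuosity_summary(graph, min_segment_mm)
  fd <- fractal_dimension(map$data & roi$data)
  md <- if (nb >= 1L) murray_deviation(graph)$MD_mean else NA_real_
  ba <- if (nb >= 1L) bifurcation_angle(graph, tangent_window_mm)$BA_mean else NA_real_
  data.frame(
    lesion_id = lesion_id, label = label,
    VD = vd, D_mean_mm = mean_diameter(graph), MD_mean = md, FD = fd,
    NB = nb, NV = nv, tau_mean = tau$tau_mean, tau_max = tau$tau_max,
    BA_mean_deg = ba,
    roi_area_mm2 = sum(roi$data) * map$pixel_size_mm^2
  )
}
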