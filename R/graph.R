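# Skeleton-graph construction: classify skeleton pixels by neighbor count,
# merge adjacent branch pixels into nodes, trace segments between nodes,
# attach distance-transform radii, and prune sub-resolution spurs.

# moving-average smoothing of a pixel polyline (endpoints fixed); reduces
# the staircase bias of 8-connected chain lengths
smooth_path <- function(p, w = 5L) {
  n <- nrow(p)
  if (n <= 4L || w < 3L) return(p)
  half <- w %/% 2L
  out <- p
  for (i in 2:(n - 1L)) {
    a <- max(1L, i - half); b <- min(n, i + half)
    out[i, ] <- colMeans(p[a:b, , drop = FALSE])
  }
  out
}

#' Build a segment/branch-point graph from a skeleton
#'
#' Skeleton pixels are classified by 8-neighbor count (1 = endpoint,
#' >= 3 = branch-point candidate); adjacent branch candidates are merged
#' into a single node at their centroid (thinning leaves branch-pixel
#' clusters that would otherwise inflate the branch-point count).  Edges
#' are traced between nodes as ordered 8-connected pixel paths; each path
#' pixel carries a radius estimate from the Euclidean distance transform of
#' the binary map.  Spur edges (one endpoint terminus) shorter than
#' `min_segment_mm` are pruned and any node thereby reduced to degree 2 is
#' dissolved, so sub-resolution thinning artifacts do not contribute
#' segments or branch points.
#'
#' @param skeleton logical skeleton matrix from [skeletonize_map()].
#' @param map the [binary_vessel_map()] the skeleton came from.
#' @param min_segment_mm spur-pruning threshold in mm (default 0.3 mm, the
#'   resolution floor of the imaging method).
#' @param smooth_window path-smoothing window (pixels) used when measuring
#'   segment length and tangents.
#' @return An object of class `skeleton_graph`: `nodes` (data frame: `id`,
#'   `row`, `col`, `type`, `degree`), `edges` (list: `path_px` k x 2 matrix
#'   of (row, col), `nodes` length-2 id vector, `length_mm`, `chord_mm`,
#'   `radius_mm` per path pixel, `diameter_mm` junction-trimmed mean),
#'   `pixel_size_mm`, `skeleton`, `n_dropped_cycles`.
#' @export
build_graph <- function(skeleton, map, min_segment_mm = 0.3,
                        smooth_window = 5L) {
  psz <- map$pixel_size_mm
  sk <- as_matrix(skeleton) != 0
  nr <- nrow(sk); nc <- ncol(sk)
  dt <- as_matrix(EBImage::distmap(map$data * 1))
  empty <- structure(
    list(nodes = data.frame(id = integer(), row = numeric(), col = numeric(),
                            type = character(), degree = integer()),
         edges = list(), pixel_size_mm = psz, skeleton = sk,
         n_dropped_cycles = 0L),
    class = "skeleton_graph"
  )
  if (!any(sk)) return(empty)

  nb <- neighbor_count8(sk)
  node_px <- sk & (nb != 2)            # endpoints, isolated px, branch clusters
  interior <- sk & (nb == 2) & !node_px

  # --- node clusters -------------------------------------------------------
  nlab <- label8(node_px)
  n_nodes <- max(nlab)
  node_rows <- node_cols <- numeric(n_nodes)
  node_type <- character(n_nodes)
  node_members <- vector("list", n_nodes)
  if (n_nodes > 0L) {
    idx <- which(nlab > 0L)
    lab <- nlab[idx]
    r <- (idx - 1L) %% nr + 1L
    co <- (idx - 1L) %/% nr + 1L
    for (k in seq_len(n_nodes)) {
      sel <- lab == k
      node_rows[k] <- mean(r[sel]); node_cols[k] <- mean(co[sel])
      node_members[[k]] <- idx[sel]
      node_type[k] <- if (any(nb[idx[sel]] >= 3)) "branch" else "endpoint"
    }
  }

  # pixel -> node-cluster lookup
  node_of <- integer(nr * nc)
  node_of[which(nlab > 0L)] <- nlab[nlab > 0L]

  neighbors8 <- function(i) {
    r <- (i - 1L) %% nr + 1L; co <- (i - 1L) %/% nr + 1L
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    rr <- r + dr; cc <- co + dc
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    (cc[ok] - 1L) * nr + rr[ok]
  }

  # --- trace edges through interior components ----------------------------
  ilab <- label8(interior)
  n_int <- max(ilab)
  edges <- list()
  n_cycles <- 0L
  used_pairs <- character(0)
  int_idx_all <- which(ilab > 0L)
  comp_members <- split(int_idx_all, ilab[int_idx_all])

  for (comp in comp_members) {
    # order the component into a path by walking from a terminal pixel
    in_comp <- logical(nr * nc); in_comp[comp] <- TRUE
    nbrs <- lapply(comp, function(i) {
      nn <- neighbors8(i); nn[in_comp[nn]]
    })
    names(nbrs) <- as.character(comp)
    deg <- lengths(nbrs)
    terminals <- comp[deg <= 1L]
    if (length(terminals) == 0L) {  # pure cycle, no attached node
      n_cycles <- n_cycles + 1L
      next
    }
    start <- terminals[1L]
    path <- integer(length(comp))
    path[1L] <- start
    visited <- logical(nr * nc); visited[start] <- TRUE
    i <- 1L
    while (i <= length(comp)) {
      nxt <- nbrs[[as.character(path[i])]]
      nxt <- nxt[!visited[nxt]]
      if (length(nxt) == 0L) break
      path[i + 1L] <- nxt[1L]
      visited[nxt[1L]] <- TRUE
      i <- i + 1L
    }
    path <- path[path > 0L]
    # attach node clusters adjacent to the two path ends
    attach_node <- function(px, exclude = 0L) {
      nn <- neighbors8(px)
      cand <- node_of[nn]
      cand <- cand[cand > 0L]
      if (length(cand) == 0L) return(NA_integer_)
      if (any(cand != exclude)) cand <- cand[cand != exclude]
      cand[1L]
    }
    a <- attach_node(path[1L])
    b <- attach_node(path[length(path)],
                     exclude = if (length(path) == 1L) a else 0L)
    if (length(path) == 1L && (is.na(b) || identical(a, b))) {
      # single interior pixel bridging one cluster twice: tiny loop, skip
      nn <- neighbors8(path[1L]); cand <- unique(node_of[nn][node_of[nn] > 0L])
      if (length(cand) >= 2L) { a <- cand[1L]; b <- cand[2L] } else next
    }
    if (is.na(a) || is.na(b)) { n_cycles <- n_cycles + 1L; next }
    # prepend/append the nearest member pixel of each attached cluster
    near_member <- function(cluster, px) {
      mem <- node_members[[cluster]]
      r0 <- (px - 1L) %% nr + 1L; c0 <- (px - 1L) %/% nr + 1L
      rm_ <- (mem - 1L) %% nr + 1L; cm <- (mem - 1L) %/% nr + 1L
      mem[which.min((rm_ - r0)^2 + (cm - c0)^2)]
    }
    full <- c(near_member(a, path[1L]), path,
              near_member(b, path[length(path)]))
    edges[[length(edges) + 1L]] <- list(pixels = full, nodes = c(a, b))
  }

  # --- direct node-node adjacencies (no interior pixels between) ----------
  if (n_nodes > 1L) {
    for (k in seq_len(n_nodes)) {
      for (px in node_members[[k]]) {
        for (nn in neighbors8(px)) {
          k2 <- node_of[nn]
          if (k2 > k) {
            key <- paste(k, k2)
            if (!(key %in% used_pairs)) {
              used_pairs <- c(used_pairs, key)
              edges[[length(edges) + 1L]] <- list(pixels = c(px, nn),
                                                  nodes = c(k, k2))
            }
          }
        }
      }
    }
  }

  idx_to_rc <- function(i) cbind((i - 1L) %% nr + 1L, (i - 1L) %/% nr + 1L)

  nodes_df <- data.frame(id = seq_len(n_nodes), row = node_rows,
                         col = node_cols, type = node_type, degree = 0L)
  edges <- lapply(edges, function(e) {
    rc <- idx_to_rc(e$pixels)
    e$path_px <- rc
    e$radius_mm <- dt[rc] * psz
    e$pixels <- NULL
    remeasure_edge(e, nodes_df, psz, smooth_window)
  })

  graph <- structure(
    list(nodes = nodes_df, edges = edges, pixel_size_mm = psz,
         skeleton = sk, n_dropped_cycles = n_cycles),
    class = "skeleton_graph"
  )
  graph <- recompute_degrees(graph)
  prune_graph(graph, min_segment_mm)
}

# (re)compute an edge's geometric summaries: the measurement polyline runs
# from node centroid to node centroid through the (lightly smoothed) pixel
# path, which removes most of the staircase bias of 8-connected chains
remeasure_edge <- function(e, nodes, psz, smooth_window = 5L) {
  a <- e$nodes[1L]; b <- e$nodes[2L]
  p <- rbind(c(nodes$row[a], nodes$col[a]),
             e$path_px,
             c(nodes$row[b], nodes$col[b]))
  sm <- smooth_path(p, smooth_window)
  e$length_mm <- polyline_length(sm) * psz
  e$chord_mm <- sqrt(sum((sm[nrow(sm), ] - sm[1L, ])^2)) * psz
  # junction-trimmed mean diameter: drop path pixels inside the junction
  # ball at either terminus (their distance-transform values reflect the
  # junction, not the vessel); the 0.1 px subtraction removes the small
  # mean overshoot of the grid distance transform at the vessel boundary
  rad <- e$radius_mm
  steps <- c(0, cumsum(sqrt(rowSums(diff(e$path_px)^2)))) * psz
  len_px <- if (length(steps)) steps[length(steps)] else 0
  trim_a <- min(rad[1L], 0.25 * len_px)
  trim_b <- min(rad[length(rad)], 0.25 * len_px)
  keep <- steps >= trim_a & steps <= (len_px - trim_b)
  if (!any(keep)) keep <- rep(TRUE, length(rad))
  e$diameter_mm <- max(mean(2 * rad[keep]) - 0.1 * psz, psz)
  e
}

recompute_degrees <- function(graph) {
  deg <- integer(nrow(graph$nodes))
  for (e in graph$edges) {
    deg[e$nodes[1L]] <- deg[e$nodes[1L]] + 1L
    deg[e$nodes[2L]] <- deg[e$nodes[2L]] + 1L
  }
  graph$nodes$degree <- deg
  graph
}

# remove short spur edges, dissolve the degree-2 nodes this creates, and
# drop isolated nodes; iterate to a fixed point
prune_graph <- function(graph, min_segment_mm) {
  repeat {
    graph <- recompute_degrees(graph)
    deg <- graph$nodes$degree
    spur <- vapply(graph$edges, function(e) {
      # junction-scale self-loops are thinning artifacts (a ring no larger
      # than the junction blob itself); real anastomoses are far longer
      if (e$nodes[1L] == e$nodes[2L]) {
        return(e$length_mm < pi * max(e$diameter_mm, min_segment_mm))
      }
      is_spur_end <- deg[e$nodes[1L]] == 1L || deg[e$nodes[2L]] == 1L
      is_spur_end && e$length_mm < min_segment_mm &&
        # keep a lone edge: an isolated short vessel is not a spur
        (deg[e$nodes[1L]] > 1L || deg[e$nodes[2L]] > 1L)
    }, logical(1))
    changed <- any(spur)
    graph$edges <- graph$edges[!spur]
    graph <- recompute_degrees(graph)

    # dissolve nodes of degree 2 joining exactly two distinct edges
    deg <- graph$nodes$degree
    for (nid in which(deg == 2L)) {
      inc <- which(vapply(graph$edges, function(e) nid %in% e$nodes,
                          logical(1)))
      if (length(inc) != 2L) next
      e1 <- graph$edges[[inc[1L]]]; e2 <- graph$edges[[inc[2L]]]
      if (identical(sort(e1$nodes), sort(e2$nodes)) &&
          e1$nodes[1L] == e1$nodes[2L]) next
      # orient both paths so they meet at nid
      p1 <- e1$path_px; r1 <- e1$radius_mm; n1 <- e1$nodes
      if (n1[1L] == nid) {
        p1 <- p1[rev(seq_len(nrow(p1))), , drop = FALSE]
        r1 <- rev(r1); n1 <- rev(n1)
      }
      p2 <- e2$path_px; r2 <- e2$radius_mm; n2 <- e2$nodes
      if (n2[2L] == nid) {
        p2 <- p2[rev(seq_len(nrow(p2))), , drop = FALSE]
        r2 <- rev(r2); n2 <- rev(n2)
      }
      merged <- list(nodes = c(n1[1L], n2[2L]))
      merged$path_px <- rbind(p1, p2[-1L, , drop = FALSE])
      merged$radius_mm <- c(r1, r2[-1L])
      merged <- remeasure_edge(merged, graph$nodes, graph$pixel_size_mm)
      # the dissolved node's junction-inflated radii should not enter the
      # diameter; reuse the two parts' junction-trimmed estimates instead
      merged$diameter_mm <- stats::weighted.mean(
        c(e1$diameter_mm, e2$diameter_mm),
        c(e1$length_mm, e2$length_mm))
      graph$edges[[inc[1L]]] <- merged
      graph$edges <- graph$edges[-inc[2L]]
      changed <- TRUE
      break  # degrees changed; restart scan
    }
    if (!changed) break
  }
  recompute_degrees(graph)
}

#' @export
print.skeleton_graph <- function(x, ...) {
  nb <- sum(x$nodes$degree >= 3L)
  cat(sprintf("<skeleton_graph> %d segments, %d branch points, %d nodes\n",
              length(x$edges), nb, nrow(x$nodes)))
  invisible(x)
}
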