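# Shared fixtures, built in code at test time.

# rasterize a tree spec and return the binary map + ground truth
raster_truth <- function(..., seed = 1L) {
  tg <- generate_vessel_tree(vessel_tree_spec(...), seed = seed)
  map <- binary_vessel_map(tg$truth$vessel_mask,
                           list(...)$pixel_size_mm %||% 0.1)
  list(map = map, truth = tg$truth, tree = tg$tree)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# graph of a clean rasterized tree
graph_of <- function(rt) build_graph(skeletonize_map(rt$map), rt$map)

# hand-built three-armed star graph with prescribed diameters and daughter
# directions (degrees, measured like image angles); used for Murray / angle
# unit oracles independent of the raster pipeline
make_star_graph <- function(d_p, d_1, d_2, dir_p = 180, dir_1 = 0, dir_2 = 90,
                            arm_px = 40L, psz = 0.1) {
  center <- c(60, 60)
  mk_path <- function(dir_deg) {
    th <- dir_deg * pi / 180
    t(sapply(0:arm_px, function(k) center + k * c(sin(th), cos(th))))
  }
  arm <- function(dir_deg, d, a, b) {
    p <- mk_path(dir_deg)
    list(nodes = c(a, b), path_px = p,
         radius_mm = rep(d / 2, nrow(p)),
         diameter_mm = d,
         length_mm = arm_px * psz, chord_mm = arm_px * psz)
  }
  edges <- list(arm(dir_p, d_p, 1L, 2L), arm(dir_1, d_1, 1L, 3L),
                arm(dir_2, d_2, 1L, 4L))
  ends <- lapply(list(dir_p, dir_1, dir_2), function(dd) {
    th <- dd * pi / 180
    center + arm_px * c(sin(th), cos(th))
  })
  nodes <- data.frame(
    id = 1:4,
    row = c(center[1], ends[[1]][1], ends[[2]][1], ends[[3]][1]),
    col = c(center[2], ends[[1]][2], ends[[2]][2], ends[[3]][2]),
    type = c("branch", "endpoint", "endpoint", "endpoint"),
    degree = c(3L, 1L, 1L, 1L)
  )
  structure(list(nodes = nodes, edges = edges, pixel_size_mm = psz,
                 skeleton = NULL, n_dropped_cycles = 0L),
            class = "skeleton_graph")
}

# independent trapezoid-rule arc length of the generator's centerline
# model: chord L plus transverse offset a*sin(2*pi*c*t)*sin(pi*t)^2
oracle_arc_length <- function(L, a, cycles, n = 20000L) {
  t <- seq(0, 1, length.out = n)
  dp <- a * (2 * pi * cycles * cos(2 * pi * cycles * t) * sin(pi * t)^2 +
               sin(2 * pi * cycles * t) * pi * sin(2 * pi * t))
  f <- sqrt(L^2 + dp^2)
  sum((f[-1] + f[-n]) / 2) * (1 / (n - 1))
}

# order-n Sierpinski triangle on a 2^n grid via the bit trick
sierpinski_mask <- function(order = 7L) {
  n <- 2L^order
  outer(0:(n - 1L), 0:(n - 1L), function(i, j) bitwAnd(i, j) == 0L)
}
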