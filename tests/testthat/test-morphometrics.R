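test_that("vessel density is the foreground fraction of the ROI", {
  full <- binary_vessel_map(matrix(TRUE, 10, 10), 0.1)
  roi <- lesion_mask(matrix(TRUE, 10, 10), 0.1)
  expect_equal(vessel_density(full, roi), 1.0)
  empty <- binary_vessel_map(matrix(FALSE, 10, 10), 0.1)
  expect_equal(vessel_density(empty, roi), 0.0)

  m <- matrix(FALSE, 100, 100); m[sample.int(10000, 450)] <- TRUE
  expect_equal(vessel_density(binary_vessel_map(m, 0.1),
                              lesion_mask(matrix(TRUE, 100, 100), 0.1)),
               0.045)
  expect_error(vessel_density(full, lesion_mask(matrix(FALSE, 10, 10), 0.1)),
               "ROI")
})

test_that("distance-metric tortuosity matches analytic and numeric oracles", {
  straight <- cbind(seq(0, 5, length.out = 50), rep(1, 50))
  expect_equal(tortuosity_dm(straight), 1.0, tolerance = 1e-12)

  th <- seq(0, pi, length.out = 300)
  semi <- cbind(cos(th), sin(th))
  expect_equal(tortuosity_dm(semi), pi / 2, tolerance = 0.01 * pi / 2)

  x <- seq(0, 2 * pi, length.out = 4000)
  sine <- cbind(x, sin(x))
  # independent numerical arc-length oracle for one sine period
  f <- sqrt(1 + cos(x)^2)
  arc <- sum((f[-1] + f[-length(x)]) / 2) * diff(x[1:2])
  expect_equal(tortuosity_dm(sine), arc / (2 * pi), tolerance = 1e-3)

  # closed path is excluded
  loop <- rbind(straight, straight[rev(seq_len(50)), ])
  expect_true(is.na(tortuosity_dm(loop)))
  expect_error(tortuosity_dm(straight[1, , drop = FALSE]), "2 points")
})

test_that("mean diameter reflects bar widths through the distance transform", {
  bar <- matrix(FALSE, 30, 110); bar[11:20, 6:105] <- TRUE  # 10 px wide
  mp <- binary_vessel_map(bar, 0.1)
  g <- build_graph(skeletonize_map(mp), mp)
  expect_lt(abs(mean_diameter(g) - 1.0) / 1.0, 0.1)

  two <- matrix(FALSE, 70, 110)
  two[11:20, 6:105] <- TRUE   # 10 px
  two[41:60, 6:105] <- TRUE   # 20 px
  mp2 <- binary_vessel_map(two, 0.1)
  g2 <- build_graph(skeletonize_map(mp2), mp2)
  expect_equal(count_segments(g2), 2L)
  expect_lt(abs(mean_diameter(g2) - 1.5) / 1.5, 0.1)

  # rasterized tree: per-segment estimates within 15% of ground truth
  rt <- raster_truth(depth = 2, seed = 6)
  g3 <- graph_of(rt)
  est <- sort(vapply(g3$edges, `[[`, numeric(1), "diameter_mm"))
  expect_true(all(abs(est - sort(rt$truth$diameters_mm)) /
                    sort(rt$truth$diameters_mm) < 0.15))
})

test_that("box-counting dimension matches line, plane and Sierpinski oracles", {
  line <- matrix(FALSE, 520, 520); line[260, 5:516] <- TRUE
  fd_line <- fractal_dimension(line)
  expect_gte(fd_line, 0.95); expect_lte(fd_line, 1.08)

  square <- matrix(TRUE, 512, 512)
  fd_sq <- fractal_dimension(square)
  expect_gte(fd_sq, 1.85); expect_lte(fd_sq, 2.0)

  fd_sp <- fractal_dimension(sierpinski_mask(7L))
  expect_lt(abs(fd_sp - log(3) / log(2)), 0.06)

  expect_true(is.na(fractal_dimension(matrix(FALSE, 8, 8))))
})

test_that("Murray deviation follows the cube-law formula and its symmetries", {
  # exactly Murray-compliant bifurcation
  g0 <- make_star_graph(d_p = 2^(1 / 3), d_1 = 1, d_2 = 1)
  expect_lt(murray_deviation(g0)$MD_mean, 1e-12)

  # degenerate daughter of zero caliber
  gd <- make_star_graph(d_p = 1, d_1 = 1, d_2 = 0)
  expect_lt(murray_deviation(gd)$MD_mean, 1e-12)

  # equal calibers: |1 - 2| / 1 = 1
  ge <- make_star_graph(d_p = 1, d_1 = 1, d_2 = 1)
  expect_equal(murray_deviation(ge)$MD_mean, 1.0)

  # invariant under uniform diameter scaling
  g1 <- make_star_graph(d_p = 1.3, d_1 = 1.05, d_2 = 0.8)
  g2 <- make_star_graph(d_p = 3.7 * 1.3, d_1 = 3.7 * 1.05, d_2 = 3.7 * 0.8)
  expect_equal(murray_deviation(g1)$MD_mean, murray_deviation(g2)$MD_mean,
               tolerance = 1e-12)
})

test_that("bifurcation angles follow the daughter-daughter convention", {
  # parent pointing up; daughters along 0 and 90 degrees
  g90 <- make_star_graph(1.3, 1, 1, dir_p = 180, dir_1 = 0, dir_2 = 90)
  expect_equal(bifurcation_angle(g90)$BA_mean, 90, tolerance = 0.5)

  # collinear opposite daughters
  g180 <- make_star_graph(1.3, 1, 1, dir_p = 270, dir_1 = 0, dir_2 = 180)
  expect_equal(bifurcation_angle(g180)$BA_mean, 180, tolerance = 0.5)

  # clean symmetric raster Y with a 120-degree opening
  rt <- raster_truth(depth = 1, tortuosity_amplitude_mm = 0,
                     branch_angle_deg_mean = 120, branch_angle_deg_sd = 0,
                     seed = 5)
  g <- graph_of(rt)
  expect_lt(abs(bifurcation_angle(g)$BA_mean - 120), 2)
})

test_that("quantify assembles records that honor the biomarker invariants", {
  rt <- raster_truth(depth = 0, tortuosity_amplitude_mm = 0, seed = 3)
  roi <- lesion_mask(matrix(TRUE, nrow(rt$map$data), ncol(rt$map$data)), 0.1)
  rec <- quantify(rt$map, roi, graph_of(rt), lesion_id = "one", label = "benign")
  expect_equal(rec$NV, 1L)
  expect_equal(rec$NB, 0L)
  expect_equal(rec$tau_mean, 1.0, tolerance = 5e-3)
  expect_equal(rec$tau_max, rec$tau_mean)
  expect_true(is.na(rec$MD_mean))
  expect_true(is.na(rec$BA_mean_deg))

  rt2 <- raster_truth(depth = 2, seed = 4)
  rec2 <- quantify(rt2$map, roi, graph_of(rt2), "two", "malignant")
  expect_equal(rec2$NV, 7L)
  expect_equal(rec2$NB, 3L)
  expect_gte(rec2$tau_max, rec2$tau_mean)
  expect_gte(rec2$tau_mean, 1)
  expect_true(rec2$VD > 0 && rec2$VD < 1)

  # CSV round trip preserves the record
  path <- tempfile(fileext = ".csv")
  write_metrics_csv(rbind(rec, rec2), path)
  back <- read_metrics_csv(path)
  expect_equal(back$NV, c(1L, 7L))
  expect_equal(back$tau_max, c(rec$tau_max, rec2$tau_max), tolerance = 1e-12)
  expect_equal(back$BA_mean_deg[1], NA_real_)
})

test_that("Murray deviation stays small end-to-end on well-resolved Murray trees", {
  md <- vapply(1:6, function(s) {
    rt <- raster_truth(depth = 2, tortuosity_amplitude_mm = 0,
                       pixel_size_mm = 0.05, seed = s)
    murray_deviation(graph_of(rt))$MD_mean
  }, numeric(1))
  expect_lt(mean(md), 0.05)
})

test_that("tortuosity and counts respond monotonically to generator knobs", {
  # generator truth: larger perturbation amplitude raises median tortuosity
  med_tau <- vapply(c(0.1, 0.3, 0.5), function(a) {
    median(vapply(1:20, function(s) {
      mean(generate_vessel_tree(vessel_tree_spec(
        depth = 1, tortuosity_amplitude_mm = a, seed = s))$truth$tortuosity)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_tau) > 0))

  # measured: deeper trees have more segments and branch points
  g2 <- graph_of(raster_truth(depth = 1, seed = 8))
  g3 <- graph_of(raster_truth(depth = 3, seed = 8))
  expect_gt(count_segments(g3), count_segments(g2))
  expect_gt(count_branch_points(g3), count_branch_points(g2))

  # measured per-segment tortuosity within 2% of ground truth
  rt <- raster_truth(depth = 2, seed = 10)
  g <- graph_of(rt)
  tau_m <- sort(vapply(g$edges, function(e) e$length_mm / e$chord_mm,
                       numeric(1)))
  expect_true(all(abs(tau_m - sort(rt$truth$tortuosity)) /
                    sort(rt$truth$tortuosity) < 0.02))
})
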