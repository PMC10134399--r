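test_that("branching produces the expected topology and ground truth counts", {
  t0 <- generate_vessel_tree(vessel_tree_spec(depth = 0, n_roots = 1, seed = 1))
  expect_equal(t0$truth$true_NV, 1L)
  expect_equal(t0$truth$true_NB, 0L)

  t2 <- generate_vessel_tree(vessel_tree_spec(depth = 2, seed = 7))
  expect_equal(t2$truth$true_NV, 7L)
  expect_equal(t2$truth$true_NB, 3L)

  # single-root strictly binary trees satisfy NV = 2 NB + 1 even when
  # crowded geometry suppresses a bifurcation
  for (s in 1:8) {
    tg <- generate_vessel_tree(vessel_tree_spec(depth = 3, seed = s))
    expect_equal(tg$truth$true_NV, 2L * tg$truth$true_NB + 1L)
  }
})

test_that("daughter diameters satisfy the Murray relation before noise", {
  tg <- generate_vessel_tree(vessel_tree_spec(depth = 3, murray_noise = 0,
                                              murray_exponent = 3, seed = 4))
  b <- tg$truth$bifurcations
  expect_true(all(abs(b$d_p^3 - (b$d_1^3 + b$d_2^3)) < 1e-12))

  # generalized exponent
  tk <- generate_vessel_tree(vessel_tree_spec(depth = 2, murray_noise = 0,
                                              murray_exponent = 2.2, seed = 4))
  bk <- tk$truth$bifurcations
  expect_true(all(abs(bk$d_p^2.2 - (bk$d_1^2.2 + bk$d_2^2.2)) < 1e-12))

  # with noise the relation is perturbed but diameters stay positive
  tn <- generate_vessel_tree(vessel_tree_spec(depth = 2, murray_noise = 0.15,
                                              seed = 4))
  expect_true(all(tn$truth$diameters_mm > 0))
})

test_that("recorded tortuosity matches an independent numerical arc-length oracle", {
  spec <- vessel_tree_spec(depth = 1, tortuosity_amplitude_mm = 0.4,
                           tortuosity_cycles = 1L,
                           field_of_view_mm = c(40, 40), seed = 11)
  tg <- generate_vessel_tree(spec)
  for (i in seq_along(tg$tree$segments)) {
    seg <- tg$tree$segments[[i]]
    oracle <- oracle_arc_length(seg$chord_mm, 0.4, 1L) / seg$chord_mm
    expect_equal(tg$truth$tortuosity[i], oracle, tolerance = 1e-3)
  }

  # tortuosity is 1 exactly iff the perturbation amplitude is 0
  t0 <- generate_vessel_tree(vessel_tree_spec(depth = 2,
                                              tortuosity_amplitude_mm = 0,
                                              seed = 3))
  expect_true(all(abs(t0$truth$tortuosity - 1) < 1e-9))
  t1 <- generate_vessel_tree(vessel_tree_spec(depth = 2,
                                              tortuosity_amplitude_mm = 0.3,
                                              seed = 3))
  expect_true(all(t1$truth$tortuosity > 1))
})

test_that("the generator is a pure function of (spec, seed)", {
  spec <- vessel_tree_spec(depth = 2, seed = 21)
  a <- generate_vessel_tree(spec)
  b <- generate_vessel_tree(spec)
  expect_identical(a$truth$vessel_mask, b$truth$vessel_mask)
  expect_identical(a$truth$tortuosity, b$truth$tortuosity)
  c <- generate_vessel_tree(spec, seed = 22)
  expect_false(identical(a$truth$vessel_mask, c$truth$vessel_mask))
})

test_that("invalid geometry parameters are rejected", {
  expect_error(vessel_tree_spec(root_diameter_mm = -1), "root_diameter")
  expect_error(vessel_tree_spec(pixel_size_mm = 0), "pixel_size")
  expect_error(vessel_tree_spec(murray_exponent = 0), "murray_exponent")
  expect_error(vessel_tree_spec(depth = -1), "depth")
  expect_error(vessel_tree_spec(segment_length_mm_sd = -0.1), "segment_length")
})

test_that("rasterization paints centerlines at the prescribed thickness", {
  # single horizontal segment, 10 mm long, 1 mm wide, 0.1 mm/px
  path <- cbind(seq(2, 12, length.out = 200), rep(8, 200))
  tree <- structure(list(segments = list(list(path = path, diameter_mm = 1)),
                         bifurcations = NULL),
                    class = "vessel_tree")
  ras <- rasterize_tree(tree, 0.1, c(16, 16))
  cols_occupied <- sum(colSums(ras$vessel_mask) > 0)
  widths <- rowSums(t(ras$vessel_mask))
  widths <- colSums(ras$vessel_mask[, colSums(ras$vessel_mask) > 0, drop = FALSE])
  # the tube is painted with rounded end caps, adding ~one radius per end
  expect_gte(cols_occupied, 99)
  expect_lte(cols_occupied, 112)
  expect_true(all(abs(widths[5:95] - 10) <= 1))

  # empty tree rasterizes to an all-zero image
  empty <- structure(list(segments = list(), bifurcations = NULL),
                     class = "vessel_tree")
  expect_equal(sum(rasterize_tree(empty, 0.1, c(5, 5))$vessel_mask), 0)
})

test_that("painted area matches the analytic length-times-diameter oracle", {
  set.seed(42)
  for (rep in 1:5) {
    L <- runif(1, 6, 10); d <- runif(1, 0.8, 1.4)
    y <- runif(1, 4, 8)
    path <- cbind(seq(2, 2 + L, length.out = 300), rep(y, 300))
    tree <- structure(list(segments = list(list(path = path, diameter_mm = d)),
                           bifurcations = NULL),
                      class = "vessel_tree")
    ras <- rasterize_tree(tree, 0.1, c(16, 16))
    expected_px <- (L * d + pi * (d / 2)^2) / 0.01  # tube + end caps
    expect_lt(abs(sum(ras$vessel_mask) - expected_px) / expected_px, 0.1)
  }
})

test_that("background model adds the stated offset and seeded noise", {
  img <- microvessel_image(matrix(0, 50, 50), 0.1)
  # zero noise, zero background: identity
  same <- add_background(img, noise_sd = 0, background_level = 0, seed = 1)
  expect_equal(same$data, img$data)
  # all-zero image with background b becomes the constant image b
  bg <- add_background(img, noise_sd = 0, background_level = 0.3, seed = 1)
  expect_true(all(bg$data == 0.3))
  # CLT bound on the noise-region mean
  nz <- add_background(img, noise_sd = 0.05, background_level = 0.5, seed = 2)
  expect_lt(abs(mean(nz$data) - 0.5), 3 * 0.05 / sqrt(2500))
  # seeded reproducibility
  nz2 <- add_background(img, noise_sd = 0.05, background_level = 0.5, seed = 2)
  expect_identical(nz$data, nz2$data)
})
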