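test_that("exact rank-sum p-values match full enumeration", {
  expect_equal(wilcoxon_rank_sum(1:3, 4:6, mode = "exact")$p, 0.1)
  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2), mode = "exact")$p, 1.0)

  # cross-check against the independent exact implementation in stats
  set.seed(31)
  for (i in 1:40) {
    m <- sample(3:7, 1); n <- sample(3:7, 1)
    x <- rnorm(m); y <- rnorm(n, 0.4)
    expect_equal(wilcoxon_rank_sum(x, y, "exact")$p,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("the normal approximation tracks the exact test closely", {
  set.seed(17)
  worst <- 0
  for (i in 1:100) {
    m <- sample(3:7, 1); n <- sample(3:7, 1)
    x <- rnorm(m); y <- rnorm(n, 0.5)
    pe <- wilcoxon_rank_sum(x, y, "exact")$p
    pa <- wilcoxon_rank_sum(x, y, "approx")$p
    worst <- max(worst, abs(pe - pa))
  }
  expect_lte(worst, 0.02)
})

test_that("the test is symmetric and invariant to monotone transforms", {
  set.seed(5)
  x <- rnorm(8); y <- rnorm(11, 1)
  expect_equal(wilcoxon_rank_sum(x, y)$p, wilcoxon_rank_sum(y, x)$p)
  mono <- function(v) exp(3 * v) + 2
  expect_equal(wilcoxon_rank_sum(x, y)$p,
               wilcoxon_rank_sum(mono(x), mono(y))$p)
  expect_equal(wilcoxon_rank_sum(x, y, "approx")$p,
               wilcoxon_rank_sum(mono(x), mono(y), "approx")$p)
})

test_that("group summaries use available cases and the n-1 denominator", {
  tab <- data.frame(
    lesion_id = sprintf("L%02d", 1:6),
    label = c("benign", "benign", "benign", "HCC", "HCC", "CCA"),
    NV = c(3, 5, 7, 20, 30, 10),
    MD_mean = c(0.3, NA, 0.4, 0.5, NA, 0.2)
  )
  s <- summarize_groups(tab, "benign_vs_malignant", metrics = c("NV", "MD_mean"))
  expect_equal(s$mean_a[s$metric == "NV"], 5)
  expect_equal(s$sd_a[s$metric == "NV"], sd(c(3, 5, 7)))
  expect_equal(s$n_a[s$metric == "MD_mean"], 2)
  expect_equal(s$mean_b[s$metric == "MD_mean"], mean(c(0.5, 0.2)))

  # single-value group: mean kept, SD missing
  one <- data.frame(label = c("benign", "HCC"), NV = c(4, 9))
  s1 <- summarize_groups(one, "benign_vs_hcc", metrics = "NV")
  expect_equal(s1$mean_a, 4)
  expect_true(is.na(s1$sd_a))

  # constant group: SD is zero
  cst <- data.frame(label = rep(c("benign", "HCC"), each = 3),
                    NV = c(4, 4, 4, 9, 9, 9))
  expect_equal(summarize_groups(cst, "benign_vs_hcc", metrics = "NV")$sd_a, 0)

  # independent two-pass oracle on a random cohort
  set.seed(2)
  rnd <- data.frame(label = rep(c("benign", "malignant"), c(10, 19)),
                    FD = runif(29, 1, 2))
  sr <- summarize_groups(rnd, "benign_vs_malignant", metrics = "FD")
  xs <- rnd$FD[rnd$label == "benign"]
  expect_equal(sr$mean_a, sum(xs) / 10, tolerance = 1e-12)
  expect_equal(sr$sd_a, sqrt(sum((xs - mean(xs))^2) / 9), tolerance = 1e-12)
})

test_that("the significance screen flags strictly below alpha", {
  set.seed(3)
  tab <- generate_cohort(cohort_spec(mode = "metrics", seed = 12))
  res <- significance_screen(tab, "benign_vs_malignant", alpha = 0.05)
  expect_true(all(res$significant == (res$p < 0.05)))

  # a p-value equal to alpha is not significant
  p_obs <- res$p[res$metric == "NV"]
  res_at <- significance_screen(tab, "benign_vs_malignant", alpha = p_obs)
  expect_false(res_at$significant[res_at$metric == "NV"])

  # empty metric list yields an empty result
  empty <- significance_screen(tab, metrics = character(0))
  expect_equal(nrow(empty), 0L)

  # the Holm column never drives the flag
  expect_true(all(res$p_holm >= res$p))
})

test_that("metric-level cohorts reproduce the requested group structure", {
  tab <- generate_cohort(cohort_spec(n_benign = 10, n_malignant = 19,
                                     mode = "metrics", seed = 77))
  expect_equal(nrow(tab), 29L)
  expect_equal(sum(tab$label == "benign"), 10L)
  expect_equal(sum(tab$label == "malignant"), 19L)
  expect_true(all(tab$tau_mean >= 1))
  expect_true(all(tab$tau_max >= 1))
  expect_true(all(tab$VD >= 0 & tab$VD <= 1))
  expect_true(all(tab$NV == round(tab$NV)))

  # seeded determinism
  tab2 <- generate_cohort(cohort_spec(n_benign = 10, n_malignant = 19,
                                      mode = "metrics", seed = 77))
  expect_identical(tab, tab2)

  # degenerate spec with identical group distributions: group means agree
  # within 3 pooled standard errors in most seeded draws
  mom <- reference_group_moments()
  mom$malignant <- mom$benign
  hits <- 0L
  for (s in 1:20) {
    t0 <- generate_cohort(cohort_spec(mode = "metrics", moments = mom,
                                      seed = s))
    nv_a <- t0$NV[t0$label == "benign"]; nv_b <- t0$NV[t0$label == "malignant"]
    se <- sqrt(var(nv_a) / 10 + var(nv_b) / 19)
    if (abs(mean(nv_a) - mean(nv_b)) < 3 * se) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})
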