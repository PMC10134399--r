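# Two-group statistics: mean +/- SD summaries and two-sided Wilcoxon
# rank-sum screening at alpha = 0.05, with exact enumeration for small
# samples and a tie-corrected normal approximation otherwise.

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact mode enumerates all `choose(m + n, m)` group assignments of the
#' pooled midranks and doubles the smaller tail (capped at 1).  Approximate
#' mode uses the normal approximation with tie-corrected variance and a
#' continuity correction.  `auto` picks exact when `m + n <= 20`.
#'
#' @param x,y numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return List with `p` (two-sided), `statistic` (rank sum of `x`),
#'   `mode` actually used.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L) stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    return(list(p = 1, statistic = m * (m + n + 1) / 2, mode = "degenerate"))
  }
  rk <- rank(pooled)               # midranks for ties
  w <- sum(rk[seq_len(m)])
  if (mode == "auto") mode <- if (m + n <= 20L) "exact" else "approx"
  if (mode == "exact") {
    combs <- utils::combn(m + n, m)
    ws <- colSums(matrix(rk[combs], nrow = m))
    eps <- 1e-9
    p_le <- mean(ws <= w + eps)
    p_ge <- mean(ws >= w - eps)
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    # Edgeworth-corrected normal approximation with continuity correction.
    # W is the sum of an m-subset drawn without replacement from the
    # midrank population, so its exact variance and fourth central moment
    # follow from finite-population sampling formulas (valid under ties);
    # the kurtosis term sharpens the tails at small sample sizes.
    N <- m + n
    b <- rk - mean(rk)
    S2 <- sum(b^2); S4 <- sum(b^4)
    e_w <- m * (N + 1) / 2
    v_w <- m * (N - m) / (N * (N - 1)) * S2
    if (v_w <= 0) return(list(p = 1, statistic = w, mode = mode))
    g2 <- 0
    if (N > 3) {
      den <- N * (N - 1) * (N - 2) * (N - 3)
      A <- m * (N - m) * (N^2 - 6 * N * m + N + 6 * m^2) / den
      B <- 3 * m * (N - m) * (m - 1) * (N - m - 1) / den
      g2 <- (A * S4 + B * S2^2) / v_w^2 - 3
    }
    F_edge <- function(z) {
      stats::pnorm(z) - stats::dnorm(z) * (g2 / 24) * (z^3 - 3 * z)
    }
    p_le <- F_edge((w + 0.5 - e_w) / sqrt(v_w))
    p_ge <- 1 - F_edge((w - 0.5 - e_w) / sqrt(v_w))
    p <- min(1, max(0, 2 * min(p_le, p_ge)))
  }
  list(p = p, statistic = w, mode = mode)
}

# resolve a named contrast into two label sets
contrast_groups <- function(contrast) {
  malignant_labels <- c("malignant", "HCC", "CCA", "metastatic")
  switch(
    contrast,
    "benign_vs_malignant" = list(a = "benign", b = malignant_labels),
    "benign_vs_hcc" = list(a = "benign", b = "HCC"),
    "hcc_vs_other_malignant" = list(a = "HCC", b = c("CCA", "metastatic")),
    stop(sprintf("unknown contrast '%s'", contrast), call. = FALSE)
  )
}

#' Per-group mean and SD summaries for a contrast
#'
#' Available-case analysis: missing values are excluded per metric, with
#' the non-missing counts reported.  SD uses the n - 1 denominator and is
#' `NA` for groups with fewer than 2 non-missing values.
#'
#' @param table cohort data frame (morphometrics schema with a `label`
#'   column).
#' @param contrast `"benign_vs_malignant"`, `"benign_vs_hcc"` or
#'   `"hcc_vs_other_malignant"`.
#' @param metrics metric columns to summarize.
#' @return Data frame: `metric`, `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`,
#'   `n_b` (group a = first-named group of the contrast).
#' @export
summarize_groups <- function(table, contrast = "benign_vs_malignant",
                             metrics = metric_names()) {
  gr <- contrast_groups(contrast)
  a <- table[table$label %in% gr$a, , drop = FALSE]
  b <- table[table$label %in% gr$b, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("both contrast groups must be non-empty", call. = FALSE)
  }
  one <- function(v) {
    v <- v[!is.na(v)]
    c(mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
      n = length(v))
  }
  rows <- lapply(metrics, function(mt) {
    sa <- one(a[[mt]]); sb <- one(b[[mt]])
    data.frame(metric = mt, mean_a = sa["mean"], sd_a = sa["sd"],
               n_a = sa["n"], mean_b = sb["mean"], sd_b = sb["sd"],
               n_b = sb["n"], row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Wilcoxon significance screen over the biomarkers
#'
#' Runs the two-sided rank-sum test per biomarker for the given contrast
#' and flags p strictly below `alpha` (a p-value equal to `alpha` is not
#' significant).  No multiplicity adjustment drives the flag; a
#' Holm-adjusted column is reported alongside for transparency.
#'
#' @param table cohort data frame (morphometrics schema).
#' @param contrast contrast name (see [summarize_groups()]).
#' @param alpha significance level (default 0.05).
#' @param mode rank-sum mode passed to [wilcoxon_rank_sum()].
#' @param metrics metric columns to screen.
#' @return Data frame: the [summarize_groups()] columns plus `p`,
#'   `p_holm`, `significant`.
#' @export
significance_screen <- function(table, contrast = "benign_vs_malignant",
                                alpha = 0.05, mode = "auto",
                                metrics = metric_names()) {
  metrics <- intersect(metrics, names(table))
  if (length(metrics) == 0L) {
    return(data.frame(metric = character(), p = numeric(),
                      p_holm = numeric(), significant = logical()))
  }
  summ <- summarize_groups(table, contrast, metrics)
  gr <- contrast_groups(contrast)
  a <- table[table$label %in% gr$a, , drop = FALSE]
  b <- table[table$label %in% gr$b, , drop = FALSE]
  p <- vapply(metrics, function(mt) {
    xa <- a[[mt]][!is.na(a[[mt]])]
    xb <- b[[mt]][!is.na(b[[mt]])]
    if (length(xa) == 0L || length(xb) == 0L) return(NA_real_)
    wilcoxon_rank_sum(xa, xb, mode = mode)$p
  }, numeric(1))
  summ$p <- unname(p)
  summ$p_holm <- stats::p.adjust(summ$p, method = "holm")
  summ$significant <- !is.na(summ$p) & summ$p < alpha
  summ
}
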