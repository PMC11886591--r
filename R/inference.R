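#' Two-proportion z-test (pooled)
#'
#' Compares two independent proportions with the pooled-variance z statistic
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))`, `p = (x1+x2)/(n1+n2)`, and a
#' two-sided p-value from the standard normal. When the pooled proportion is
#' 0 or 1 the statistic is undefined (both samples are constant and equal);
#' the test degenerates to no evidence of a difference and is reported as
#' `z = NA`, `p = 1` with `degenerate = TRUE`.
#'
#' @param x1,n1 Successes and trials in the first sample.
#' @param x2,n2 Successes and trials in the second sample.
#' @return A list: `z`, `p_value`, `degenerate`.
#' @examples
#' two_proportion_ztest(90, 100, 80, 100)
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2) {
  check_counts(x1, n1)
  check_counts(x2, n2)
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) {
    return(list(z = NA_real_, p_value = 1, degenerate = TRUE))
  }
  z <- (x1 / n1 - x2 / n2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  list(z = z, p_value = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

#' One-proportion z-test against a fixed benchmark
#'
#' Tests an observed proportion `x/n` against a null value `p0` with
#' `z = (x/n - p0) / sqrt(p0 (1 - p0) / n)` and a two-sided normal p-value.
#' Used to compare an observer's accuracy with the probabilistic-guessing
#' benchmark (see [always_normal_benchmark()]).
#'
#' @param x,n Successes and trials.
#' @param p0 Null proportion, strictly inside (0, 1).
#' @return A list: `z`, `p_value`, `degenerate` (always `FALSE`).
#' @examples
#' one_proportion_ztest(900, 1000, 0.84)
#' @export
one_proportion_ztest <- function(x, n, p0) {
  check_counts(x, n)
  if (p0 <= 0 || p0 >= 1) {
    rs_abort("benchmark proportion must lie strictly inside (0, 1)",
             "readerstudy_degenerate_error")
  }
  z <- (x / n - p0) / sqrt(p0 * (1 - p0) / n)
  list(z = z, p_value = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

check_counts <- function(x, n) {
  if (n <= 0 || x < 0 || x > n) {
    rs_abort("counts must satisfy 0 <= x <= n, n > 0",
             "readerstudy_value_error")
  }
}

#' Bonferroni adjustment
#'
#' Multiplies each raw p-value by the family size and caps at 1, controlling
#' the family-wise error rate across the family of comparisons.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param m Family size; defaults to `length(p)` and must be at least that.
#' @return Adjusted p-values, `pmin(1, m * p)`.
#' @examples
#' bonferroni(c(0.004, 0.2), m = 11)
#' @export
bonferroni <- function(p, m = length(p)) {
  if (length(p) < 1 || m < length(p)) {
    rs_abort("family size m must be >= length(p) >= 1",
             "readerstudy_value_error")
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    rs_abort("p-values must lie in [0, 1]", "readerstudy_value_error")
  }
  pmin(1, m * p)
}

signif_stars <- function(p_adj) {
  dplyr::case_when(
    is.na(p_adj) ~ "",
    p_adj < 0.01 ~ "***",
    p_adj < 0.05 ~ "**",
    p_adj < 0.1 ~ "*",
    .default = ""
  )
}

metric_counts <- function(metrics, metric) {
  switch(metric,
         accuracy = list(x = metrics$tp + metrics$tn, n = metrics$total),
         sensitivity = list(x = metrics$tp, n = metrics$tp + metrics$fn),
         specificity = list(x = metrics$tn, n = metrics$tn + metrics$fp))
}

#' Compare every human observer with the AI on each metric
#'
#' Runs one pooled two-proportion z-test per human vs. the AI, per metric,
#' using each observer's own micro-averaged numerator and denominator. The
#' Bonferroni family is the set of human-vs-AI comparisons within one metric
#' (and, when called per stratum, within that stratum): humans whose metric
#' is undefined are skipped and shrink the family. Stars mark adjusted
#' p-values below 0.1 / 0.05 / 0.01.
#'
#' @param metrics A metrics tibble from [observer_metrics()] containing the
#'   AI row.
#' @param ai_observer Observer id of the AI.
#' @param metrics_to_test Character vector of metric names to compare.
#' @param alpha Significance level on the adjusted scale (default 0.05).
#' @return A tibble `metric, observer_id, x1, n1, x2, n2, z, p_raw, m,
#'   p_adj, significant, stars`.
#' @export
compare_humans_vs_ai <- function(metrics, ai_observer,
                                 metrics_to_test = c("accuracy", "sensitivity",
                                                     "specificity"),
                                 alpha = 0.05) {
  stopifnot(ai_observer %in% metrics$observer_id)
  ai <- metrics[metrics$observer_id == ai_observer, ]
  humans <- metrics[metrics$observer_id != ai_observer, ]
  out <- lapply(metrics_to_test, function(metric) {
    if (is.na(ai[[metric]])) return(NULL)
    defined <- humans[!is.na(humans[[metric]]), ]
    if (nrow(defined) == 0) return(NULL)
    hc <- metric_counts(defined, metric)
    ac <- metric_counts(ai, metric)
    tests <- lapply(seq_len(nrow(defined)), function(i) {
      two_proportion_ztest(hc$x[i], hc$n[i], ac$x, ac$n)
    })
    m <- nrow(defined)
    tibble::tibble(
      metric = metric,
      observer_id = defined$observer_id,
      x1 = hc$x, n1 = hc$n, x2 = ac$x, n2 = ac$n,
      z = vapply(tests, `[[`, numeric(1), "z"),
      p_raw = vapply(tests, `[[`, numeric(1), "p_value"),
      m = m
    ) |>
      dplyr::mutate(p_adj = bonferroni(.data$p_raw, m[1]))
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(significant = .data$p_adj < alpha,
                  stars = signif_stars(.data$p_adj))
}

#' Compare each observer's accuracy with the guessing benchmark
#'
#' One-proportion z-test of each observer's accuracy against the accuracy of
#' always guessing "normal" (`p0` = prevalence of consensus-normal), on the
#' observer's own denominator.
#'
#' @param metrics A metrics tibble from [observer_metrics()].
#' @param p0 Benchmark accuracy, from [always_normal_benchmark()].
#' @param adjust Apply a Bonferroni correction over the observers tested
#'   (default `TRUE`).
#' @param alpha Significance level (default 0.05).
#' @return A tibble `observer_id, x, n, p0, z, p_raw, m, p_adj, significant`.
#' @export
compare_vs_benchmark <- function(metrics, p0, adjust = TRUE, alpha = 0.05) {
  cc <- metric_counts(metrics, "accuracy")
  tests <- lapply(seq_len(nrow(metrics)), function(i) {
    one_proportion_ztest(cc$x[i], cc$n[i], p0)
  })
  m <- if (adjust) nrow(metrics) else 1L
  tibble::tibble(
    observer_id = metrics$observer_id,
    x = cc$x, n = cc$n, p0 = p0,
    z = vapply(tests, `[[`, numeric(1), "z"),
    p_raw = vapply(tests, `[[`, numeric(1), "p_value"),
    m = m
  ) |>
    dplyr::mutate(p_adj = bonferroni(.data$p_raw, m[1]),
                  significant = .data$p_adj < alpha)
}
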