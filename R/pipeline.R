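#' Options for the full reader-study pipeline
#'
#' @param exclude_ai_from_consensus Drop the AI's votes when building the
#'   consensus truth (default `FALSE`: the AI is an observer like any other).
#' @param min_observers Minimum panel size per finding for a consensus
#'   (default 5).
#' @param variance_reference Reference for the assessment variance,
#'   `"consensus"` (default) or `"mean"`; see [assessment_variance()].
#' @param median_scope Scope of the median used to split low from high
#'   ambiguity, `"finding"` (default) or `"observation"`; see [stratify()].
#' @param alpha Significance level on the Bonferroni-adjusted scale
#'   (default 0.05).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(exclude_ai_from_consensus = FALSE,
                            min_observers = 5L,
                            variance_reference = c("consensus", "mean"),
                            median_scope = c("finding", "observation"),
                            alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, min_observers >= 2)
  structure(
    list(exclude_ai_from_consensus = isTRUE(exclude_ai_from_consensus),
         min_observers = as.integer(min_observers),
         variance_reference = match.arg(variance_reference),
         median_scope = match.arg(median_scope),
         alpha = alpha),
    class = "pipeline_config"
  )
}

#' Run the full reader-study analysis
#'
#' End-to-end, deterministic pipeline: impute unmentioned findings as normal,
#' build the consensus truth, compute per-finding assessment variances and
#' the ambiguity strata, then for each subsample (all findings, no
#' unanimity, low ambiguity, high ambiguity) tally per-observer outcome
#' counts, micro-averaged metrics sorted by accuracy descending, and
#' Bonferroni-corrected human-vs-AI z-tests. Also computes the
#' probabilistic-guessing benchmark and one-proportion tests against it, and
#' a run log (excluded findings, imputed fraction, at-median count).
#'
#' @param x A [finding_table()] (imputation is applied internally; passing an
#'   already-imputed table is fine — imputation is idempotent).
#' @param config A [pipeline_config()].
#' @return A list of class `report_bundle`: `summary`, `distribution`,
#'   `benchmark` (`p0` and per-observer tests), `tables` (per-subsample
#'   metrics), `tests` (per-subsample human-vs-AI comparisons), `strata`,
#'   `consensus`, `run_log`.
#' @export
run_pipeline <- function(x, config = pipeline_config()) {
  stopifnot(inherits(x, "finding_table"), inherits(config, "pipeline_config"))
  x <- impute_unmentioned(x)
  consensus <- build_consensus_table(
    x, exclude_ai = config$exclude_ai_from_consensus,
    min_observers = config$min_observers
  )
  if (nrow(consensus) == 0) {
    rs_abort("consensus stage: no finding reached the minimum panel size",
             "readerstudy_empty_error")
  }
  strata <- stratify(
    variance_table(x, reference = config$variance_reference,
                   min_observers = config$min_observers),
    median_scope = config$median_scope
  )

  subsamples <- c("all", "non_unanimous", "low", "high")
  metric_tables <- list()
  test_tables <- list()
  for (s in subsamples) {
    keys <- stratum_keys(strata, s)
    if (nrow(keys) == 0) {
      metric_tables[[s]] <- NULL
      next
    }
    counts <- outcome_counts(x, consensus, keys = keys)
    if (nrow(counts) == 0) next
    mt <- observer_metrics(counts) |>
      dplyr::mutate(is_ai = !is.na(x$ai_observer) &
                      .data$observer_id == x$ai_observer) |>
      dplyr::arrange(dplyr::desc(.data$accuracy))
    metric_tables[[s]] <- mt
    if (!is.na(x$ai_observer) && x$ai_observer %in% mt$observer_id &&
        nrow(mt) > 1) {
      test_tables[[s]] <- compare_humans_vs_ai(
        mt, ai_observer = x$ai_observer, alpha = config$alpha
      ) |>
        dplyr::mutate(subsample = s, .before = 1)
    }
  }

  p0 <- always_normal_benchmark(consensus, x)
  benchmark_tests <- if (p0 > 0 && p0 < 1) {
    compare_vs_benchmark(metric_tables[["all"]], p0, alpha = config$alpha)
  }

  excluded <- attr(consensus, "excluded")
  run_log <- tibble::tibble(
    n_findings_excluded = nrow(excluded),
    imputed_fraction = mean(!x$records$mentioned),
    n_at_median = sum(strata$stratum == "AT_MEDIAN"),
    n_unanimous = sum(strata$stratum == "UNANIMOUS"),
    median_variance = attr(strata, "median_v") %||% NA_real_
  )

  structure(
    list(summary = design_summary(x),
         distribution = distribution_table(x, consensus, strata),
         benchmark = list(p0 = p0, tests = benchmark_tests),
         tables = metric_tables,
         tests = dplyr::bind_rows(test_tables),
         strata = strata,
         consensus = consensus,
         run_log = run_log,
         config = config,
         table = x),
    class = "report_bundle"
  )
}

#' Render a metrics table for display
#'
#' Formats a per-subsample metrics table the way reader-study reports print
#' them: observers sorted by accuracy descending, three decimal places,
#' undefined metrics shown as `"-"`, significance stars from the adjusted
#' human-vs-AI tests, and the AI row flagged.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param subsample One of `"all"`, `"non_unanimous"`, `"low"`, `"high"`.
#' @return A character-column tibble ready for printing.
#' @export
format_metric_table <- function(bundle, subsample = "all") {
  mt <- bundle$tables[[subsample]]
  if (is.null(mt)) {
    rs_abort(paste0("no metrics table for subsample '", subsample, "'"),
             "readerstudy_empty_error")
  }
  tests <- bundle$tests
  star_of <- function(obs, metric) {
    if (is.null(tests) || nrow(tests) == 0) return(rep("", length(obs)))
    vapply(obs, function(o) {
      row <- tests[tests$subsample == subsample & tests$metric == metric &
                     tests$observer_id == o, ]
      if (nrow(row) == 1) row$stars else ""
    }, character(1))
  }
  fmt <- function(v, stars) {
    ifelse(is.na(v), "-", paste0(sprintf("%.3f", v), stars))
  }
  tibble::tibble(
    observer = ifelse(mt$is_ai, paste0("*", mt$observer_id, "*"),
                      mt$observer_id),
    accuracy = fmt(mt$accuracy, star_of(mt$observer_id, "accuracy")),
    sensitivity = fmt(mt$sensitivity, star_of(mt$observer_id, "sensitivity")),
    specificity = fmt(mt$specificity, star_of(mt$observer_id, "specificity"))
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n\nDesign\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  cat("\nDistribution of findings (consensus labels, observer level)\n")
  print(as.data.frame(x$distribution), row.names = FALSE, digits = 4)
  cat(sprintf("\nAlways-normal benchmark accuracy: %.4f\n", x$benchmark$p0))
  for (s in names(x$tables)) {
    cat("\nMetrics (", s, ")\n", sep = "")
    print(as.data.frame(format_metric_table(x, s)), row.names = FALSE)
  }
  cat("\nRun log\n")
  print(as.data.frame(x$run_log), row.names = FALSE)
  invisible(x)
}

#' Write a report bundle to a directory of CSV files
#'
#' Emits `distribution.csv`, `consensus.csv`, `strata.csv`,
#' `metrics_<subsample>.csv`, `tests.csv`, `benchmark.csv`, `run_log.csv`,
#' plus the imputed table's explicit records (`findings.csv`, `design.csv`,
#' `observers.yaml`) so the whole run can be reproduced from its own output.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if needed).
#' @return `bundle`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(bundle$distribution, file.path(dir, "distribution.csv"))
  write_consensus(bundle$consensus, file.path(dir, "consensus.csv"))
  readr::write_csv(
    dplyr::mutate(bundle$strata, stratum = as.character(.data$stratum)),
    file.path(dir, "strata.csv")
  )
  for (s in names(bundle$tables)) {
    readr::write_csv(bundle$tables[[s]],
                     file.path(dir, paste0("metrics_", s, ".csv")))
  }
  if (!is.null(bundle$tests) && nrow(bundle$tests) > 0) {
    readr::write_csv(bundle$tests, file.path(dir, "tests.csv"))
  }
  if (!is.null(bundle$benchmark$tests)) {
    readr::write_csv(bundle$benchmark$tests, file.path(dir, "benchmark.csv"))
  }
  readr::write_csv(bundle$run_log, file.path(dir, "run_log.csv"))
  write_findings(bundle$table,
                 file.path(dir, "findings.csv"),
                 file.path(dir, "design.csv"),
                 file.path(dir, "observers.yaml"))
  invisible(bundle)
}
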