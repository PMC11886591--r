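#' Pooled outcome counts per observer
#'
#' Tallies TP/TN/FP/FN for each observer over exactly the findings that
#' observer assessed (explicitly or by imputation), that have a consensus
#' label, and that pass an optional finding filter. Pooling counts before
#' dividing (micro-averaging) matches the summation form of the study
#' metrics; each observer's denominator reflects only the studies they read.
#'
#' @param x An imputed [finding_table()].
#' @param consensus Consensus tibble from [build_consensus_table()].
#' @param observers Optional character vector restricting to some observers.
#' @param keys Optional data frame with columns `study_id`, `finding_code`
#'   restricting the tally to those findings (e.g. one ambiguity stratum).
#' @return A tibble `observer_id, tp, tn, fp, fn, total`, one row per
#'   observer with at least one counted finding.
#' @export
outcome_counts <- function(x, consensus, observers = NULL, keys = NULL) {
  stopifnot(inherits(x, "finding_table"))
  rec <- x$records
  if (!is.null(observers)) {
    unknown <- setdiff(observers, unique(x$design$observer_id))
    if (length(unknown) > 0) {
      rs_abort(paste0("unknown observer(s): ", paste(unknown, collapse = ", ")),
               "readerstudy_lookup_error")
    }
    rec <- dplyr::filter(rec, .data$observer_id %in% observers)
  }
  if (!is.null(keys)) {
    rec <- dplyr::semi_join(rec, keys, by = c("study_id", "finding_code"))
  }
  rec |>
    dplyr::inner_join(
      consensus[, c("study_id", "finding_code", "consensus")],
      by = c("study_id", "finding_code")
    ) |>
    dplyr::mutate(outcome = classify_outcome(.data$assessment, .data$consensus)) |>
    dplyr::summarise(
      tp = sum(.data$outcome == "TP"),
      tn = sum(.data$outcome == "TN"),
      fp = sum(.data$outcome == "FP"),
      fn = sum(.data$outcome == "FN"),
      .by = "observer_id"
    ) |>
    dplyr::mutate(total = .data$tp + .data$tn + .data$fp + .data$fn) |>
    dplyr::arrange(.data$observer_id)
}

#' Micro-averaged diagnostic metrics from outcome counts
#'
#' Computes accuracy `(tp+tn)/total`, sensitivity `tp/(tp+fn)` and
#' specificity `tn/(tn+fp)`. A metric whose denominator is zero — e.g.
#' sensitivity for an observer whose read studies contained no
#' consensus-abnormal finding in the stratum — is *undefined* and reported as
#' `NA`, never as 0: the observer made no classification of that kind, right
#' or wrong.
#'
#' @param counts A tibble of counts as returned by [outcome_counts()] (or any
#'   data frame with columns `tp`, `tn`, `fp`, `fn`).
#' @return The input with columns `accuracy`, `sensitivity`, `specificity`
#'   appended (`NA` when undefined) and `total` recomputed.
#' @examples
#' observer_metrics(data.frame(tp = 8, tn = 80, fp = 10, fn = 2))
#' @export
observer_metrics <- function(counts) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("tp", "tn", "fp", "fn") %in% names(counts)))
  counts <- dplyr::mutate(counts,
                          total = .data$tp + .data$tn + .data$fp + .data$fn)
  if (any(counts$total == 0)) {
    rs_abort("observer with zero counted findings", "readerstudy_empty_error")
  }
  dplyr::mutate(
    counts,
    accuracy = (.data$tp + .data$tn) / .data$total,
    sensitivity = dplyr::if_else(.data$tp + .data$fn > 0,
                                 .data$tp / (.data$tp + .data$fn),
                                 NA_real_),
    specificity = dplyr::if_else(.data$tn + .data$fp > 0,
                                 .data$tn / (.data$tn + .data$fp),
                                 NA_real_)
  )
}

#' Best, median and worst human observer for one metric
#'
#' Ranks the human observers (the AI, if named, is excluded) on one metric,
#' re-determined per metric: the best reader on accuracy need not be the best
#' on sensitivity. Observers whose metric is undefined are excluded from that
#' metric's ranking. With `h` defined values sorted descending, the median is
#' the element at position `ceiling(h/2)` (the 6th of 11).
#'
#' @param metrics A tibble from [observer_metrics()] with `observer_id`.
#' @param metric One of `"accuracy"`, `"sensitivity"`, `"specificity"`.
#' @param ai_observer Observer id to exclude from ranking, or `NA`.
#' @return A tibble with rows `best`, `median`, `worst`: rank label,
#'   observer id and metric value.
#' @export
rank_humans <- function(metrics, metric = c("accuracy", "sensitivity",
                                            "specificity"),
                        ai_observer = NA_character_) {
  metric <- match.arg(metric)
  humans <- metrics
  if (!is.na(ai_observer)) {
    humans <- dplyr::filter(humans, .data$observer_id != ai_observer)
  }
  humans <- humans[!is.na(humans[[metric]]), ]
  if (nrow(humans) == 0) {
    rs_abort(paste0("no human observer with defined ", metric),
             "readerstudy_empty_error")
  }
  ord <- order(humans[[metric]], decreasing = TRUE)
  h <- length(ord)
  idx <- c(best = ord[1], median = ord[ceiling(h / 2)], worst = ord[h])
  tibble::tibble(
    rank = names(idx),
    observer_id = humans$observer_id[idx],
    value = humans[[metric]][idx]
  )
}

#' Accuracy of the probabilistic-guessing benchmark
#'
#' A reader who guesses "normal" for every finding attains an accuracy equal
#' to the prevalence of consensus-normal findings among the observer-level
#' observations — with a heavily normal case mix, a deceptively high bar that
#' any real observer must beat to demonstrate skill.
#'
#' @param x An imputed [finding_table()], used to weight each finding by the
#'   number of observers who assessed it; or `NULL` to weight by the
#'   consensus table's own `n_observers`.
#' @param consensus Consensus tibble from [build_consensus_table()].
#' @return The benchmark accuracy, a proportion in `[0, 1]`; it equals
#'   `1 - abnormal prevalence` by construction.
#' @export
always_normal_benchmark <- function(consensus, x = NULL) {
  if (nrow(consensus) == 0) {
    rs_abort("empty consensus table", "readerstudy_empty_error")
  }
  if (is.null(x)) {
    w <- consensus$n_observers
    return(sum(w * (consensus$consensus == 0L)) / sum(w))
  }
  stopifnot(inherits(x, "finding_table"))
  joined <- dplyr::inner_join(
    x$records, consensus[, c("study_id", "finding_code", "consensus")],
    by = c("study_id", "finding_code")
  )
  mean(joined$consensus == 0L)
}
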