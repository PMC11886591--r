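#' Consensus label for one finding
#'
#' With no external reference standard, the true state of a finding is
#' proxied by the consensus of the observers who assessed it: the finding is
#' called abnormal when at least half of the assessments are abnormal
#' (indicator of mean >= 0.5), i.e. the median assessment with exact ties
#' resolved to abnormal. The rule requires at least `min_observers`
#' assessments (default 5) to be considered meaningful.
#'
#' @param assessments Integer vector of binary assessments (0 normal,
#'   1 abnormal).
#' @param min_observers Minimum panel size for a consensus (default 5).
#' @return A list with `n_observers`, `mean_assessment` and `consensus`
#'   (0 or 1).
#' @examples
#' consensus_label(c(1, 1, 1, 0, 0))          # majority abnormal
#' consensus_label(c(1, 1, 1, 0, 0, 0))       # exact tie -> abnormal
#' @export
consensus_label <- function(assessments, min_observers = 5L) {
  assessments <- as.integer(assessments)
  if (length(assessments) < min_observers) {
    rs_abort(
      paste0("consensus requires at least ", min_observers,
             " assessments, got ", length(assessments)),
      "readerstudy_insufficient_observers_error"
    )
  }
  stopifnot(all(assessments %in% c(0L, 1L)))
  m <- mean(assessments)
  list(
    n_observers = length(assessments),
    mean_assessment = m,
    consensus = as.integer(m >= 0.5)
  )
}

#' Classify an assessment against the consensus truth
#'
#' Each observer-level assessment of a finding falls into one of four
#' outcomes relative to the finding's consensus label: true positive (both
#' abnormal), true negative (both normal), false positive (called abnormal,
#' consensus normal) or false negative (called normal, consensus abnormal).
#'
#' @param assessment,consensus Binary vectors (recycled to common length).
#' @return A character vector with values in `c("TP", "TN", "FP", "FN")`.
#' @examples
#' classify_outcome(c(1, 0, 1, 0), c(1, 0, 0, 1))
#' @export
classify_outcome <- function(assessment, consensus) {
  stopifnot(all(assessment %in% c(0, 1)), all(consensus %in% c(0, 1)))
  dplyr::case_when(
    assessment == 1 & consensus == 1 ~ "TP",
    assessment == 0 & consensus == 0 ~ "TN",
    assessment == 1 & consensus == 0 ~ "FP",
    .default = "FN"
  )
}

#' Build the consensus table for a finding table
#'
#' Computes, per unique finding, the number of assessing observers, the mean
#' assessment and the consensus label (see [consensus_label()]). Findings
#' assessed by fewer than `min_observers` observers carry no meaningful
#' consensus; they are excluded from the returned table and reported in the
#' `excluded` attribute so a run log can account for them.
#'
#' @param x An imputed [finding_table()] (run [impute_unmentioned()] first so
#'   silent readers contribute their implicit normal votes).
#' @param exclude_ai Drop the AI observer's assessments from the consensus
#'   (default `FALSE`: the AI is an observer like any other and votes).
#' @param min_observers Minimum panel size per finding (default 5).
#' @return A tibble `study_id, finding_code, n_observers, mean_assessment,
#'   consensus`, with attribute `excluded`: the sub-threshold findings and
#'   their observer counts.
#' @export
build_consensus_table <- function(x, exclude_ai = FALSE, min_observers = 5L) {
  stopifnot(inherits(x, "finding_table"))
  rec <- x$records
  if (exclude_ai && !is.na(x$ai_observer)) {
    rec <- dplyr::filter(rec, .data$observer_id != x$ai_observer)
  }
  all_findings <- rec |>
    dplyr::summarise(
      n_observers = dplyr::n(),
      mean_assessment = mean(.data$assessment),
      .by = c("study_id", "finding_code")
    ) |>
    dplyr::mutate(consensus = as.integer(.data$mean_assessment >= 0.5))
  keep <- all_findings$n_observers >= min_observers
  out <- all_findings[keep, ]
  attr(out, "excluded") <- all_findings[!keep,
                                        c("study_id", "finding_code",
                                          "n_observers")]
  out
}

#' Write/read a consensus table as CSV
#'
#' @param consensus A consensus tibble from [build_consensus_table()].
#' @param path Output path.
#' @return The input (write) or the parsed tibble (read).
#' @export
write_consensus <- function(consensus, path) {
  readr::write_csv(
    consensus[, c("study_id", "finding_code", "n_observers",
                  "mean_assessment", "consensus")],
    path
  )
  invisible(consensus)
}

#' @rdname write_consensus
#' @export
read_consensus <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      study_id = "c", finding_code = "c", n_observers = "i",
      mean_assessment = "d", consensus = "i"
    )
  )
}
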