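#' Inter-observer assessment variance of one finding
#'
#' Disagreement about a finding is quantified as the mean squared deviation
#' of the observers' binary assessments from a reference. The default
#' reference is the finding's binarised consensus label, under which the
#' variance is exactly the minority fraction: 0 when all observers agree, up
#' to 0.5 at an even split. An alternative reference, the mean assessment,
#' gives the population variance `m(1 - m)`; it is provided because the two
#' conventions genuinely differ for split panels and published analyses are
#' not always explicit about which was used.
#'
#' @param assessments Integer vector of binary assessments.
#' @param reference `"consensus"` (default) or `"mean"`.
#' @return A non-negative variance; 0 iff all observers agree.
#' @examples
#' assessment_variance(c(1, 1, 1, 0, 0))                    # 2/5 minority
#' assessment_variance(c(1, 1, 1, 0, 0, 0), "mean")         # 0.25
#' @export
assessment_variance <- function(assessments,
                                reference = c("consensus", "mean")) {
  reference <- match.arg(reference)
  assessments <- as.integer(assessments)
  if (length(assessments) == 0) {
    rs_abort("no assessments", "readerstudy_empty_error")
  }
  stopifnot(all(assessments %in% c(0L, 1L)))
  m <- mean(assessments)
  ref <- switch(reference, consensus = as.numeric(m >= 0.5), mean = m)
  mean((assessments - ref)^2)
}

#' Per-finding variance table
#'
#' @param x An imputed [finding_table()].
#' @param reference Variance reference, see [assessment_variance()].
#' @param min_observers Findings with fewer observers are dropped, matching
#'   the consensus gate.
#' @return A tibble `study_id, finding_code, n_observers, v`.
#' @export
variance_table <- function(x, reference = c("consensus", "mean"),
                           min_observers = 5L) {
  stopifnot(inherits(x, "finding_table"))
  reference <- match.arg(reference)
  x$records |>
    dplyr::summarise(
      n_observers = dplyr::n(),
      mean_assessment = mean(.data$assessment),
      .by = c("study_id", "finding_code")
    ) |>
    dplyr::filter(.data$n_observers >= min_observers) |>
    dplyr::mutate(
      ref = switch(reference,
                   consensus = as.numeric(.data$mean_assessment >= 0.5),
                   mean = .data$mean_assessment),
      # for binary data mean((a - ref)^2) reduces to a closed form in
      # (mean, ref): m - 2*ref*m + ref^2
      v = .data$mean_assessment - 2 * .data$ref * .data$mean_assessment +
        .data$ref^2
    ) |>
    dplyr::select("study_id", "finding_code", "n_observers", "v")
}

#' Stratify findings by ambiguity
#'
#' Findings on which all observers agreed (variance 0) are `UNANIMOUS`.
#' Among the non-unanimous findings, the median variance splits low from
#' high ambiguity with *strict* inequalities: strictly below the median is
#' `LOW`, strictly above is `HIGH`, and findings exactly at the median are
#' `AT_MEDIAN` — members of neither stratum, reported separately. This strict
#' split is why the low- and high-ambiguity observation counts need not sum
#' to the non-unanimous total.
#'
#' @param variances A tibble from [variance_table()].
#' @param median_scope `"finding"` (default): the median is taken over unique
#'   findings; `"observation"`: over observer-level observations, i.e. each
#'   finding's variance weighted by its observer count.
#' @return The input with a `stratum` factor appended
#'   (`UNANIMOUS`, `LOW`, `HIGH`, `AT_MEDIAN`).
#' @export
stratify <- function(variances, median_scope = c("finding", "observation")) {
  median_scope <- match.arg(median_scope)
  pos <- variances$v > 0
  med <- if (!any(pos)) {
    NA_real_
  } else if (median_scope == "finding") {
    median(variances$v[pos])
  } else {
    median(rep(variances$v[pos], variances$n_observers[pos]))
  }
  stratum <- dplyr::case_when(
    variances$v == 0 ~ "UNANIMOUS",
    variances$v < med ~ "LOW",
    variances$v > med ~ "HIGH",
    .default = "AT_MEDIAN"
  )
  variances$stratum <- factor(stratum,
                              levels = c("UNANIMOUS", "LOW", "HIGH",
                                         "AT_MEDIAN"))
  attr(variances, "median_v") <- med
  variances
}

#' Finding keys of one subsample
#'
#' @param strata A stratified variance tibble from [stratify()].
#' @param which `"all"`, `"non_unanimous"`, `"low"`, `"high"`, `"unanimous"`
#'   or `"at_median"`.
#' @return A tibble of `study_id, finding_code` keys.
#' @export
stratum_keys <- function(strata, which = c("all", "non_unanimous", "low",
                                           "high", "unanimous", "at_median")) {
  which <- match.arg(which)
  keep <- switch(
    which,
    all = rep(TRUE, nrow(strata)),
    non_unanimous = strata$stratum != "UNANIMOUS",
    low = strata$stratum == "LOW",
    high = strata$stratum == "HIGH",
    unanimous = strata$stratum == "UNANIMOUS",
    at_median = strata$stratum == "AT_MEDIAN"
  )
  strata[keep, c("study_id", "finding_code")]
}

#' Distribution of normal and abnormal findings across subsamples
#'
#' Observer-level counts and consensus-label percentages for the subsamples
#' all findings / no unanimity / low ambiguity / high ambiguity, the usual
#' first table of a reader-study report.
#'
#' @param x An imputed [finding_table()].
#' @param consensus Consensus tibble.
#' @param strata Stratified variance tibble from [stratify()].
#' @return A tibble `subsample, n_findings, normal_pct, abnormal_pct` where
#'   `n_findings` counts observer-level observations.
#' @export
distribution_table <- function(x, consensus, strata) {
  stopifnot(inherits(x, "finding_table"))
  joined <- x$records |>
    dplyr::inner_join(consensus[, c("study_id", "finding_code", "consensus")],
                      by = c("study_id", "finding_code")) |>
    dplyr::inner_join(strata[, c("study_id", "finding_code", "stratum")],
                      by = c("study_id", "finding_code"))
  one <- function(df, label) {
    tibble::tibble(
      subsample = label,
      n_findings = nrow(df),
      normal_pct = if (nrow(df) == 0) NA_real_ else
        100 * mean(df$consensus == 0L),
      abnormal_pct = if (nrow(df) == 0) NA_real_ else
        100 * mean(df$consensus == 1L)
    )
  }
  dplyr::bind_rows(
    one(joined, "All"),
    one(joined[joined$stratum != "UNANIMOUS", ], "No unanimity"),
    one(joined[joined$stratum == "LOW", ], "Low ambiguity"),
    one(joined[joined$stratum == "HIGH", ], "High ambiguity")
  )
}
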