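#' Finding tables: observer-level assessments plus the reading design
#'
#' A `finding_table` is the central relation of the pipeline: one row per
#' (study, finding code, observer) assessment, together with the reading
#' design (which observer produced a report for which study) and an observer
#' registry naming the AI observer, if any. A *finding* is one codable
#' observation within one study, labelled `0` (normal) or `1` (abnormal).
#' Findings an observer did not mention are treated as implicitly normal and
#' are materialised by [impute_unmentioned()] with `mentioned = FALSE`.
#'
#' @param records A data frame with columns `study_id`, `finding_code`,
#'   `observer_id`, `assessment` (0/1 or "normal"/"abnormal") and optionally
#'   `mentioned` (logical; defaults to `TRUE`, i.e. explicitly stated).
#' @param design A data frame with columns `observer_id`, `study_id`: one row
#'   per report an observer produced.
#' @param ai_observer Identifier of the AI observer within the design, or
#'   `NA` if the panel is all-human.
#'
#' @return An object of class `finding_table`: a list with elements
#'   `records` (tibble), `design` (tibble) and `ai_observer`.
#'
#' @details Validation enforces the structural invariants the downstream
#' stages rely on: assessments are binary, at most one record exists per
#' (study, code, observer), every record's (observer, study) pair appears in
#' the reading design, and imputed records are always normal.
#'
#' @examples
#' recs <- data.frame(
#'   study_id = "S1", finding_code = c("C1", "C1"),
#'   observer_id = c("A", "B"), assessment = c(1, 0)
#' )
#' des <- data.frame(observer_id = c("A", "B"), study_id = "S1")
#' ft <- finding_table(recs, des)
#' ft
#' @export
finding_table <- function(records, design, ai_observer = NA_character_) {
  records <- parse_records(records)
  design <- parse_design(design)
  x <- structure(
    list(records = records, design = design,
         ai_observer = as.character(ai_observer)[1]),
    class = "finding_table"
  )
  validate_finding_table(x)
}

parse_records <- function(records) {
  records <- tibble::as_tibble(records)
  required <- c("study_id", "finding_code", "observer_id", "assessment")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    rs_abort(
      paste0("findings table lacks column(s): ", paste(missing, collapse = ", ")),
      "readerstudy_format_error"
    )
  }
  if (!"mentioned" %in% names(records)) records$mentioned <- TRUE
  records$mentioned <- as.logical(records$mentioned)
  records |>
    dplyr::mutate(
      study_id = as.character(.data$study_id),
      finding_code = as.character(.data$finding_code),
      observer_id = as.character(.data$observer_id),
      assessment = parse_assessment(.data$assessment)
    ) |>
    dplyr::select(dplyr::all_of(c(required, "mentioned")))
}

parse_design <- function(design) {
  design <- tibble::as_tibble(design)
  missing <- setdiff(c("observer_id", "study_id"), names(design))
  if (length(missing) > 0) {
    rs_abort(
      paste0("design table lacks column(s): ", paste(missing, collapse = ", ")),
      "readerstudy_format_error"
    )
  }
  design |>
    dplyr::transmute(
      observer_id = as.character(.data$observer_id),
      study_id = as.character(.data$study_id)
    ) |>
    dplyr::distinct()
}

#' Parse normal/abnormal labels to binary assessments
#'
#' @param x A vector of assessments coded `0`/`1` or `"normal"`/`"abnormal"`
#'   (case-insensitive).
#' @return An integer vector in \{0, 1\}.
#' @keywords internal
parse_assessment <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- dplyr::case_match(x, "0" ~ 0L, "normal" ~ 0L, "1" ~ 1L, "abnormal" ~ 1L)
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    rs_abort(
      paste0("assessment value(s) outside {0, 1, normal, abnormal}: ",
             paste(head(bad, 5), collapse = ", ")),
      "readerstudy_value_error"
    )
  }
  out
}

validate_finding_table <- function(x) {
  r <- x$records
  if (any(!r$mentioned & r$assessment != 0L)) {
    rs_abort("imputed (unmentioned) records must be normal (assessment 0)",
             "readerstudy_value_error")
  }
  dup <- r |>
    dplyr::count(.data$study_id, .data$finding_code, .data$observer_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    rs_abort(
      paste0("duplicate assessment for (study, code, observer), e.g. (",
             dup$study_id[1], ", ", dup$finding_code[1], ", ",
             dup$observer_id[1], ")"),
      "readerstudy_design_error"
    )
  }
  off <- dplyr::anti_join(
    dplyr::distinct(r, .data$observer_id, .data$study_id),
    x$design,
    by = c("observer_id", "study_id")
  )
  if (nrow(off) > 0) {
    rs_abort(
      paste0("assessment by observer '", off$observer_id[1], "' for study '",
             off$study_id[1], "' outside the reading design"),
      "readerstudy_design_error"
    )
  }
  if (!is.na(x$ai_observer) &&
      !x$ai_observer %in% unique(x$design$observer_id)) {
    rs_abort(paste0("ai_observer '", x$ai_observer, "' absent from the design"),
             "readerstudy_design_error")
  }
  x
}

#' @export
print.finding_table <- function(x, ...) {
  cat("<finding_table>\n")
  cat("  studies:   ", dplyr::n_distinct(x$design$study_id), "\n", sep = "")
  cat("  observers: ", dplyr::n_distinct(x$design$observer_id),
      if (!is.na(x$ai_observer)) paste0(" (AI: ", x$ai_observer, ")") else "",
      "\n", sep = "")
  cat("  records:   ", nrow(x$records), " (",
      sum(!x$records$mentioned), " imputed)\n", sep = "")
  invisible(x)
}

#' Read assessments and reading design from CSV
#'
#' The findings file has header `study_id,finding_code,observer_id,assessment`
#' with assessments in \{0, 1, normal, abnormal\}, one row per explicit
#' statement by an observer. The design file has header
#' `observer_id,study_id`. The optional observer registry is a YAML file with
#' a single key `ai_observer` naming the AI observer's id.
#'
#' @param findings Path to the findings CSV.
#' @param design Path to the design CSV.
#' @param observers Path to the observer-registry YAML, an AI observer id
#'   given directly as a string, or `NULL` for an all-human panel.
#' @return A [finding_table()].
#' @seealso [write_findings()] for the inverse.
#' @export
read_findings <- function(findings, design, observers = NULL) {
  for (p in c(findings, design)) {
    if (!file.exists(p)) {
      rs_abort(paste0("file not found: ", p), "readerstudy_format_error")
    }
  }
  rec <- readr::read_csv(findings, col_types = readr::cols(.default = "c"))
  des <- readr::read_csv(design, col_types = readr::cols(.default = "c"))
  ai <- NA_character_
  if (!is.null(observers)) {
    ai <- if (file.exists(observers)) {
      reg <- yaml::read_yaml(observers)
      as.character(reg$ai_observer %||% NA_character_)
    } else {
      as.character(observers)
    }
  }
  finding_table(rec, des, ai_observer = ai)
}

#' Write a finding table's explicit records and design to CSV
#'
#' Only explicitly mentioned records are written (one row per explicit
#' statement); imputed normals are reproducible from the design via
#' [impute_unmentioned()] and are therefore not materialised.
#'
#' @param x A [finding_table()].
#' @param findings,design Output CSV paths.
#' @param observers Optional path for the observer-registry YAML (written
#'   only when the table names an AI observer).
#' @return `x`, invisibly.
#' @export
write_findings <- function(x, findings, design, observers = NULL) {
  stopifnot(inherits(x, "finding_table"))
  x$records |>
    dplyr::filter(.data$mentioned) |>
    dplyr::select("study_id", "finding_code", "observer_id", "assessment") |>
    readr::write_csv(findings)
  readr::write_csv(x$design, design)
  if (!is.null(observers) && !is.na(x$ai_observer)) {
    yaml::write_yaml(list(ai_observer = x$ai_observer), observers)
  }
  invisible(x)
}

#' Impute unmentioned findings as normal
#'
#' Reading reports are sparse: an observer only writes down what they judged
#' worth stating. Following the standard coding rule for such studies, an
#' observation raised by *any* reader of a study but unmentioned by another
#' reader of the same study is taken as judged normal by the silent reader.
#' The finding universe is per-study: the union of finding codes mentioned by
#' any observer who read that study. No records are created for observers who
#' did not read the study.
#'
#' @param x A [finding_table()].
#' @return A `finding_table` in which, for every study, each reader of the
#'   study has exactly one record per code in that study's universe; added
#'   records carry `assessment = 0` and `mentioned = FALSE`. Idempotent.
#' @examples
#' recs <- data.frame(study_id = "S1", finding_code = "C1",
#'                    observer_id = "A", assessment = 1)
#' des <- data.frame(observer_id = c("A", "B"), study_id = "S1")
#' impute_unmentioned(finding_table(recs, des))$records
#' @export
impute_unmentioned <- function(x) {
  stopifnot(inherits(x, "finding_table"))
  universe <- dplyr::distinct(x$records, .data$study_id, .data$finding_code)
  full <- dplyr::inner_join(x$design, universe, by = "study_id",
                            relationship = "many-to-many")
  added <- full |>
    dplyr::anti_join(x$records,
                     by = c("study_id", "finding_code", "observer_id")) |>
    dplyr::mutate(assessment = 0L, mentioned = FALSE)
  x$records <- dplyr::bind_rows(x$records, added) |>
    dplyr::arrange(.data$study_id, .data$finding_code, .data$observer_id)
  x
}

#' Summarise a reading design and its assessment table
#'
#' @param x A [finding_table()], normally after [impute_unmentioned()].
#' @return A one-row tibble: number of studies and observers, mean and range
#'   of reports per observer, total observer-level findings (records), unique
#'   findings, prevalence of abnormal assessments among all records, and the
#'   imputed fraction.
#' @export
design_summary <- function(x) {
  stopifnot(inherits(x, "finding_table"))
  if (nrow(x$records) == 0) {
    rs_abort("finding table has no records", "readerstudy_empty_error")
  }
  reports <- dplyr::count(x$design, .data$observer_id)
  tibble::tibble(
    n_studies = dplyr::n_distinct(x$design$study_id),
    n_observers = dplyr::n_distinct(x$design$observer_id),
    reports_per_observer_mean = mean(reports$n),
    reports_per_observer_min = min(reports$n),
    reports_per_observer_max = max(reports$n),
    n_observer_findings = nrow(x$records),
    n_unique_findings = nrow(dplyr::distinct(x$records, .data$study_id,
                                             .data$finding_code)),
    abnormal_assessment_rate = mean(x$records$assessment == 1L),
    imputed_fraction = mean(!x$records$mentioned)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
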