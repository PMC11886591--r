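#' Default human observer operating points
#'
#' Eleven heterogeneous (sensitivity, specificity) pairs spanning the range
#' typically seen for board-certified radiologists reading small-animal
#' radiographs: sensitivities from about 0.64 to 0.95 and specificities from
#' about 0.80 to 0.94, with the usual trade-off (the most sensitive readers
#' are the least specific).
#'
#' @return A tibble `observer_id, sensitivity, specificity` with 11 rows.
#' @export
default_human_profiles <- function() {
  tibble::tibble(
    observer_id = paste0("R", 1:11),
    sensitivity = c(0.779, 0.784, 0.643, 0.824, 0.824, 0.860,
                    0.784, 0.865, 0.898, 0.826, 0.948),
    specificity = c(0.936, 0.921, 0.926, 0.899, 0.899, 0.878,
                    0.883, 0.861, 0.852, 0.861, 0.798)
  )
}

#' Configuration of a synthetic reader panel
#'
#' Describes a multi-reader multi-case study design: a set of studies, each
#' with a random number of codable findings, read by a panel of human
#' observers (each reading a random subset of the studies) plus an AI
#' observer that reads everything. Defaults emulate a 50-study, 11-radiologist
#' panel with roughly 51 findings per study, half the studies per human
#' (about 25 reports each), 16% abnormal prevalence, and the operating points
#' of [default_human_profiles()] — which together yield on the order of
#' 16,000 observer-level findings.
#'
#' @param n_studies Number of radiographic studies (default 50).
#' @param findings_per_study Mean findings per study (default 51).
#' @param findings_dist `"poisson"` (default) draws each study's finding
#'   count from Poisson(`findings_per_study`) truncated at 1; `"fixed"` uses
#'   the value exactly.
#' @param n_humans Number of human observers (default 11).
#' @param human_read_fraction Probability a human reads any given study
#'   (default 0.5).
#' @param ai_reads_all Include an AI observer reading every study
#'   (default `TRUE`).
#' @param abnormal_prevalence Probability a finding is truly abnormal
#'   (default 0.16).
#' @param human_profiles Tibble `observer_id, sensitivity, specificity`, one
#'   row per human; recycled/truncated to `n_humans`.
#' @param ai_profile Named vector `c(sensitivity=, specificity=)` for the AI
#'   observer (default a high-specificity, lower-sensitivity operating point,
#'   0.688 / 0.944).
#' @param difficulty Per-finding difficulty `d` in `[0, 1]`: with probability
#'   `1 - d` the observer applies their own operating point, with probability
#'   `d` they flip a fair coin. Either a single number (constant difficulty)
#'   or a list `list(p_zero=, min=, max=)`: `d = 0` with probability
#'   `p_zero`, else Uniform(min, max). Default `list(p_zero = 0.5,
#'   min = 0.1, max = 0.6)`, giving a unanimous / low / high ambiguity mix.
#' @param mention_prob_normal Probability an observer explicitly records a
#'   finding they judged normal (default 0.3); abnormal judgements are always
#'   recorded. Unrecorded normals are left to [impute_unmentioned()].
#' @param min_readers Minimum readers per study; human reading sets are
#'   redrawn for deficient studies (default 5, the consensus gate).
#' @param seed Optional RNG seed stored in the config and used by
#'   [generate_panel()].
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_studies = 50L,
                             findings_per_study = 51,
                             findings_dist = c("poisson", "fixed"),
                             n_humans = 11L,
                             human_read_fraction = 0.5,
                             ai_reads_all = TRUE,
                             abnormal_prevalence = 0.16,
                             human_profiles = default_human_profiles(),
                             ai_profile = c(sensitivity = 0.688,
                                            specificity = 0.944),
                             difficulty = list(p_zero = 0.5, min = 0.1,
                                               max = 0.6),
                             mention_prob_normal = 0.3,
                             min_readers = 5L,
                             seed = NULL) {
  findings_dist <- match.arg(findings_dist)
  stopifnot(
    n_studies >= 1, findings_per_study >= 1, n_humans >= 1,
    human_read_fraction >= 0, human_read_fraction <= 1,
    abnormal_prevalence >= 0, abnormal_prevalence <= 1,
    mention_prob_normal >= 0, mention_prob_normal <= 1
  )
  human_profiles <- tibble::as_tibble(human_profiles)
  if (nrow(human_profiles) < n_humans) {
    idx <- rep_len(seq_len(nrow(human_profiles)), n_humans)
    human_profiles <- human_profiles[idx, ]
    human_profiles$observer_id <- paste0("R", seq_len(n_humans))
  }
  human_profiles <- human_profiles[seq_len(n_humans), ]
  n_readers_possible <- n_humans + as.integer(ai_reads_all)
  if (n_readers_possible < min_readers) {
    rs_abort(
      paste0("design cannot reach ", min_readers, " readers per study with ",
             n_humans, " humans",
             if (ai_reads_all) " + AI" else ""),
      "readerstudy_config_error"
    )
  }
  if (n_humans * human_read_fraction + as.integer(ai_reads_all) <
      min_readers) {
    warn(paste0("expected readers per study (",
                round(n_humans * human_read_fraction +
                        as.integer(ai_reads_all), 2),
                ") is below the min_readers gate (", min_readers,
                "); many redraws may be needed"))
  }
  structure(
    list(n_studies = as.integer(n_studies),
         findings_per_study = findings_per_study,
         findings_dist = findings_dist,
         n_humans = as.integer(n_humans),
         human_read_fraction = human_read_fraction,
         ai_reads_all = isTRUE(ai_reads_all),
         abnormal_prevalence = abnormal_prevalence,
         human_profiles = human_profiles,
         ai_profile = ai_profile,
         difficulty = difficulty,
         mention_prob_normal = mention_prob_normal,
         min_readers = as.integer(min_readers),
         seed = seed),
    class = "synthetic_config"
  )
}

draw_difficulty <- function(n, difficulty) {
  if (is.numeric(difficulty) && length(difficulty) == 1) {
    return(rep(difficulty, n))
  }
  zero <- runif(n) < difficulty$p_zero
  d <- runif(n, difficulty$min, difficulty$max)
  d[zero] <- 0
  d
}

#' Probability a simulated assessment is correct
#'
#' Under the difficulty-mixture observer model, an observer with
#' class-conditional accuracy `q` (their sensitivity on truly abnormal
#' findings, specificity on truly normal ones) assessing a finding of
#' difficulty `d` is correct with probability `(1 - d) q + d/2`: with
#' probability `d` the finding is ambiguous enough that the call is a coin
#' flip.
#'
#' @param q Class-conditional accuracy (sensitivity or specificity).
#' @param d Difficulty in `[0, 1]`.
#' @return The per-assessment probability of a correct call.
#' @examples
#' expected_assessment_accuracy(0.9, 0)
#' expected_assessment_accuracy(0.95, 0.4)
#' @export
expected_assessment_accuracy <- function(q, d) {
  stopifnot(all(q >= 0 & q <= 1), all(d >= 0 & d <= 1))
  (1 - d) * q + d * 0.5
}

#' Generate a synthetic reader panel with latent truth
#'
#' Simulates the full study: latent true states per finding, per-finding
#' difficulty, a reading design (AI reads everything, humans read random
#' subsets, deficient studies redrawn until every study clears the
#' `min_readers` gate), per-observer assessments under the difficulty-mixture
#' model of [expected_assessment_accuracy()], and selective reporting
#' (abnormal calls always written down, normal calls only with probability
#' `mention_prob_normal`). Truth is returned separately so the analysis
#' pipeline never sees it.
#'
#' @param config A [synthetic_config()].
#' @param seed RNG seed; defaults to the config's own. The same seed
#'   reproduces the identical panel.
#' @return A list with `table` (a [finding_table()], explicit records only —
#'   run [impute_unmentioned()] before analysis) and `truth` (a tibble
#'   `study_id, finding_code, truth, difficulty`).
#' @export
generate_panel <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)

  study_ids <- sprintf("S%03d", seq_len(config$n_studies))
  k <- switch(config$findings_dist,
              poisson = pmax(1L, rpois(config$n_studies,
                                       config$findings_per_study)),
              fixed = rep(as.integer(config$findings_per_study),
                          config$n_studies))
  truth <- tibble::tibble(
    study_id = rep(study_ids, k),
    finding_code = unlist(lapply(k, function(m) sprintf("F%03d", seq_len(m)))),
    truth = rbinom(sum(k), 1L, config$abnormal_prevalence),
    difficulty = draw_difficulty(sum(k), config$difficulty)
  )

  humans <- config$human_profiles$observer_id
  ai_id <- if (config$ai_reads_all) "AI" else NA_character_
  reads <- matrix(runif(config$n_humans * config$n_studies) <
                    config$human_read_fraction,
                  nrow = config$n_humans)
  base <- as.integer(config$ai_reads_all)
  for (iter in seq_len(10000)) {
    deficient <- which(colSums(reads) + base < config$min_readers)
    if (length(deficient) == 0) break
    reads[, deficient] <- runif(config$n_humans * length(deficient)) <
      config$human_read_fraction
  }
  if (any(colSums(reads) + base < config$min_readers)) {
    rs_abort("could not satisfy the min_readers gate; check read fraction",
             "readerstudy_config_error")
  }
  design <- dplyr::bind_rows(
    tibble::tibble(
      observer_id = rep(humans, times = rowSums(reads)),
      study_id = unlist(lapply(seq_len(config$n_humans),
                               function(i) study_ids[reads[i, ]]))
    ),
    if (config$ai_reads_all) {
      tibble::tibble(observer_id = "AI", study_id = study_ids)
    }
  )

  profiles <- config$human_profiles
  if (config$ai_reads_all) {
    profiles <- dplyr::bind_rows(
      profiles,
      tibble::tibble(observer_id = "AI",
                     sensitivity = unname(config$ai_profile["sensitivity"]),
                     specificity = unname(config$ai_profile["specificity"]))
    )
  }

  pairs <- dplyr::inner_join(design, truth, by = "study_id",
                             relationship = "many-to-many") |>
    dplyr::inner_join(profiles, by = "observer_id") |>
    dplyr::mutate(
      q = dplyr::if_else(.data$truth == 1L, .data$sensitivity,
                         .data$specificity),
      p_correct = expected_assessment_accuracy(.data$q, .data$difficulty),
      correct = runif(dplyr::n()) < .data$p_correct,
      assessment = dplyr::if_else(.data$correct, .data$truth, 1L - .data$truth),
      mentioned = .data$assessment == 1L |
        runif(dplyr::n()) < config$mention_prob_normal
    )

  records <- pairs |>
    dplyr::filter(.data$mentioned) |>
    dplyr::select("study_id", "finding_code", "observer_id", "assessment") |>
    dplyr::mutate(mentioned = TRUE)

  list(
    table = finding_table(records, design, ai_observer = ai_id),
    truth = truth
  )
}

#' Write a generated panel to CSV (findings, design, truth)
#'
#' @param panel A list from [generate_panel()].
#' @param dir Output directory (created if needed).
#' @return The panel, invisibly. Files: `findings.csv`, `design.csv`,
#'   `observers.yaml`, `truth.csv`.
#' @export
write_panel <- function(panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_findings(panel$table,
                 file.path(dir, "findings.csv"),
                 file.path(dir, "design.csv"),
                 file.path(dir, "observers.yaml"))
  readr::write_csv(panel$truth, file.path(dir, "truth.csv"))
  invisible(panel)
}
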