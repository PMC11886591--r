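# fixtures are built in code: small hand-written tables and parameterised
# synthetic panels

# finding_table from a records data frame; design defaults to the distinct
# (observer, study) pairs present in the records
ft <- function(records, design = NULL, ai = NA_character_) {
  records <- tibble::as_tibble(records)
  if (is.null(design)) {
    design <- dplyr::distinct(records, observer_id, study_id)
  }
  finding_table(records, design, ai_observer = ai)
}

# one study, `k` codes, every observer assesses every code explicitly
complete_study <- function(observers, assessments_by_code,
                           study = "S1", ai = NA_character_) {
  codes <- names(assessments_by_code)
  recs <- do.call(rbind, lapply(codes, function(code) {
    data.frame(study_id = study, finding_code = code,
               observer_id = observers,
               assessment = assessments_by_code[[code]])
  }))
  ft(recs, ai = ai)
}

# homogeneous panel config: every human reads every study, fixed finding
# count, constant difficulty
uniform_config <- function(n_studies, findings_per_study, n_humans,
                           se, sp, ai_reads_all = TRUE,
                           ai_se = se, ai_sp = sp,
                           prevalence = 0.16, difficulty = 0,
                           mention_prob_normal = 1, seed = NULL) {
  synthetic_config(
    n_studies = n_studies,
    findings_per_study = findings_per_study,
    findings_dist = "fixed",
    n_humans = n_humans,
    human_read_fraction = 1,
    ai_reads_all = ai_reads_all,
    abnormal_prevalence = prevalence,
    human_profiles = tibble::tibble(
      observer_id = paste0("R", seq_len(n_humans)),
      sensitivity = se, specificity = sp
    ),
    ai_profile = c(sensitivity = ai_se, specificity = ai_sp),
    difficulty = difficulty,
    mention_prob_normal = mention_prob_normal,
    seed = seed
  )
}

# brute-force consensus oracle: sort, take the median position(s), resolve an
# exact tie to abnormal
consensus_oracle <- function(assessments) {
  s <- sort(assessments)
  n <- length(s)
  lo <- s[ceiling(n / 2)]
  hi <- s[ceiling((n + 1) / 2)]
  if (lo == hi) lo else 1L
}
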