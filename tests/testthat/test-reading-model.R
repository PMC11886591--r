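test_that("CSV round-trip preserves a valid table and parses labels", {
  recs <- data.frame(
    study_id = c("S1", "S1", "S2"),
    finding_code = c("C1", "C2", "C1"),
    observer_id = c("A", "B", "A"),
    assessment = c("abnormal", "normal", "1")
  )
  des <- data.frame(observer_id = c("A", "B", "A"),
                    study_id = c("S1", "S1", "S2"))
  tab <- finding_table(recs, des, ai_observer = "A")
  expect_equal(nrow(tab$records), 3)
  expect_equal(tab$records$assessment, c(1L, 0L, 1L))

  dir <- withr::local_tempdir()
  f <- file.path(dir, "f.csv"); d <- file.path(dir, "d.csv")
  o <- file.path(dir, "o.yaml")
  write_findings(tab, f, d, o)
  back <- read_findings(f, d, o)
  expect_equal(back$records, tab$records)
  expect_equal(dplyr::arrange(back$design, observer_id, study_id),
               dplyr::arrange(tab$design, observer_id, study_id))
  expect_equal(back$ai_observer, "A")
})

test_that("malformed input is rejected with classed errors", {
  des <- data.frame(observer_id = "A", study_id = "S1")
  # duplicate (study, code, observer)
  dup <- data.frame(study_id = "S1", finding_code = "C1",
                    observer_id = "A", assessment = c(1, 0))
  expect_error(finding_table(dup, des), class = "readerstudy_design_error")
  # missing column
  expect_error(
    finding_table(data.frame(study_id = "S1", finding_code = "C1",
                             assessment = 1), des),
    class = "readerstudy_format_error"
  )
  # assessment outside the vocabulary
  expect_error(
    finding_table(data.frame(study_id = "S1", finding_code = "C1",
                             observer_id = "A", assessment = "maybe"), des),
    class = "readerstudy_value_error"
  )
  # record for a study the observer did not read
  expect_error(
    finding_table(data.frame(study_id = "S2", finding_code = "C1",
                             observer_id = "A", assessment = 1), des),
    class = "readerstudy_design_error"
  )
  # imputed records must be normal
  expect_error(
    finding_table(data.frame(study_id = "S1", finding_code = "C1",
                             observer_id = "A", assessment = 1,
                             mentioned = FALSE), des),
    class = "readerstudy_value_error"
  )
})

test_that("silent readers gain imputed-normal records, per-study universe", {
  recs <- data.frame(study_id = "S1", finding_code = "C1",
                     observer_id = "A", assessment = 1)
  des <- data.frame(observer_id = c("A", "B", "D"),
                    study_id = c("S1", "S1", "S2"))
  out <- impute_unmentioned(finding_table(recs, des))
  added <- dplyr::filter(out$records, !mentioned)
  expect_equal(nrow(added), 1)
  expect_equal(added$observer_id, "B")
  expect_equal(added$assessment, 0L)
  # D read only S2, which has an empty universe: nothing imputed for D
  expect_false("D" %in% out$records$observer_id)
})

test_that("imputation is idempotent, conservative and completing", {
  panel <- generate_panel(synthetic_config(
    n_studies = 6, findings_per_study = 8, n_humans = 8, seed = 42
  ))
  tab <- panel$table
  once <- impute_unmentioned(tab)
  twice <- impute_unmentioned(once)
  expect_identical(once$records, twice$records)

  # explicit records are untouched
  expect_equal(
    dplyr::semi_join(once$records, tab$records,
                     by = c("study_id", "finding_code", "observer_id")),
    dplyr::arrange(tab$records, study_id, finding_code, observer_id)
  )

  # |records for study j| = |universe(j)| x |readers(j)|
  per_study <- dplyr::count(once$records, study_id)
  universe <- dplyr::count(dplyr::distinct(once$records, study_id,
                                           finding_code), study_id,
                           name = "codes")
  readers <- dplyr::count(tab$design, study_id, name = "readers")
  joined <- dplyr::inner_join(universe, readers, by = "study_id")
  expect_equal(per_study$n,
               joined$codes[match(per_study$study_id, joined$study_id)] *
                 joined$readers[match(per_study$study_id, joined$study_id)])
})

test_that("design_summary counts studies, observers and findings", {
  # 2 studies x 5 codes x 6 observers, everyone reads everything
  obs <- paste0("O", 1:6)
  recs <- expand.grid(study_id = c("S1", "S2"),
                      finding_code = paste0("C", 1:5),
                      observer_id = obs, stringsAsFactors = FALSE)
  recs$assessment <- 0
  recs$assessment[1] <- 1
  s <- design_summary(ft(recs))
  expect_equal(s$n_observer_findings, 60)
  expect_equal(s$n_unique_findings, 10)
  expect_equal(s$n_studies, 2)
  expect_equal(s$n_observers, 6)

  single <- ft(data.frame(study_id = "S1", finding_code = paste0("C", 1:3),
                          observer_id = "A", assessment = 0))
  expect_equal(design_summary(single)$n_observer_findings, 3)

  empty <- ft(recs[0, ], design = data.frame(observer_id = "A",
                                             study_id = "S1"))
  expect_error(design_summary(empty), class = "readerstudy_empty_error")
})

test_that("default panel emulates the target study scale", {
  # Monte-Carlo mean over 20 seeds: ~50 studies, 12 observers, on the order
  # of 16.4k observer-level findings and ~25 reports per radiologist
  sums <- lapply(1:20, function(s) {
    panel <- generate_panel(synthetic_config(seed = s))
    design_summary(impute_unmentioned(panel$table))
  })
  sums <- dplyr::bind_rows(sums)
  expect_equal(unique(sums$n_studies), 50)
  expect_equal(unique(sums$n_observers), 12)
  expect_lt(abs(mean(sums$n_observer_findings) - 16434) / 16434, 0.10)
  human_reports <- (sums$reports_per_observer_mean * 12 - 50) / 11
  expect_lt(abs(mean(human_reports) - 24.8) / 24.8, 0.10)
})
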