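test_that("assessment variance is zero iff observers are unanimous", {
  for (ref in c("consensus", "mean")) {
    expect_equal(assessment_variance(rep(1, 7), ref), 0)
    expect_equal(assessment_variance(rep(0, 5), ref), 0)
    expect_gt(assessment_variance(c(1, 1, 1, 0, 0), ref), 0)
  }
  expect_error(assessment_variance(integer(0)),
               class = "readerstudy_empty_error")
})

test_that("variance equals the minority fraction under the consensus reference", {
  expect_equal(assessment_variance(c(1, 1, 1, 0, 0)), 2 / 5)
  expect_equal(assessment_variance(c(1, 1, 1, 0, 0, 0), "mean"), 0.25)
  # tie: consensus is abnormal, so half the panel is the "minority"
  expect_equal(assessment_variance(c(1, 1, 1, 0, 0, 0)), 0.5)

  # brute-force oracle on every length-6 vector, both reference modes
  grid <- expand.grid(rep(list(0:1), 6))
  for (i in seq_len(nrow(grid))) {
    v <- as.integer(grid[i, ])
    m <- mean(v)
    cons <- as.numeric(m >= 0.5)
    expect_equal(assessment_variance(v), mean((v - cons)^2))
    expect_equal(assessment_variance(v, "mean"), mean((v - m)^2))
    # minority-fraction identity
    expect_equal(assessment_variance(v), 1 - max(m, 1 - m))
  }
})

test_that("strict median split yields UNANIMOUS/LOW/HIGH/AT_MEDIAN", {
  vt <- tibble::tibble(
    study_id = "S1", finding_code = paste0("C", 1:5),
    n_observers = 6L, v = c(0, 0.2, 0.2, 0.4, 0.4)
  )
  s <- stratify(vt)
  expect_equal(as.character(s$stratum),
               c("UNANIMOUS", "LOW", "LOW", "HIGH", "HIGH"))
  expect_equal(attr(s, "median_v"), 0.3)

  at <- stratify(tibble::tibble(study_id = "S1",
                                finding_code = paste0("C", 1:3),
                                n_observers = 6L, v = c(0.2, 0.3, 0.4)))
  expect_equal(as.character(at$stratum), c("LOW", "AT_MEDIAN", "HIGH"))

  allz <- stratify(dplyr::mutate(vt, v = 0))
  expect_true(all(allz$stratum == "UNANIMOUS"))

  # observation-scope median weights each finding by its observer count
  wt <- tibble::tibble(study_id = "S1", finding_code = paste0("C", 1:3),
                       n_observers = c(10L, 1L, 1L), v = c(0.1, 0.3, 0.5))
  s2 <- stratify(wt, median_scope = "observation")
  expect_equal(attr(s2, "median_v"), 0.1)
  expect_equal(as.character(s2$stratum), c("AT_MEDIAN", "HIGH", "HIGH"))
})

test_that("strata partition the non-unanimous findings on random panels", {
  for (seed in 1:5) {
    panel <- generate_panel(synthetic_config(
      n_studies = 10, findings_per_study = 15, n_humans = 8, seed = seed
    ))
    tab <- impute_unmentioned(panel$table)
    for (scope in c("finding", "observation")) {
      s <- stratify(variance_table(tab), median_scope = scope)
      n_non <- sum(s$v > 0)
      expect_equal(sum(s$stratum == "LOW") + sum(s$stratum == "HIGH") +
                     sum(s$stratum == "AT_MEDIAN"), n_non)
      expect_equal(sum(s$stratum == "UNANIMOUS"), sum(s$v == 0))
    }
  }
})

test_that("harder findings show more inter-observer variance", {
  # bimodal difficulty: half the findings d = 0, half d = 0.5
  cfg <- uniform_config(
    n_studies = 50, findings_per_study = 100, n_humans = 6,
    se = 0.9, sp = 0.9,
    difficulty = list(p_zero = 0.5, min = 0.5, max = 0.5),
    seed = 31
  )
  panel <- generate_panel(cfg)
  tab <- impute_unmentioned(panel$table)
  vt <- dplyr::inner_join(variance_table(tab), panel$truth,
                          by = c("study_id", "finding_code"))
  mean_v <- tapply(vt$v, vt$difficulty > 0, mean)
  expect_gt(mean_v[["TRUE"]], mean_v[["FALSE"]])
})

test_that("stratification ignores key labels and observer order", {
  panel <- generate_panel(synthetic_config(
    n_studies = 8, findings_per_study = 12, n_humans = 9, seed = 99
  ))
  tab <- impute_unmentioned(panel$table)
  s1 <- stratify(variance_table(tab))

  shuffled <- tab
  shuffled$records <- shuffled$records[sample(nrow(shuffled$records)), ]
  relabel <- function(x) paste0("X", x)
  shuffled$records$study_id <- relabel(shuffled$records$study_id)
  shuffled$design$study_id <- relabel(shuffled$design$study_id)
  s2 <- stratify(variance_table(shuffled))
  s2$study_id <- sub("^X", "", s2$study_id)

  merged <- dplyr::inner_join(
    s1, s2, by = c("study_id", "finding_code"), suffix = c("", ".2")
  )
  expect_equal(nrow(merged), nrow(s1))
  expect_equal(merged$v, merged$v.2)
  expect_equal(as.character(merged$stratum), as.character(merged$stratum.2))
})
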