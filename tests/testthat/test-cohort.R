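# Eligibility, index-visit selection, exclusions, cohort assembly.

test_that("eligible intervals require a BMI-bearing index with 1-year spacing", {
  d0 <- as.Date("2010-01-01")
  iv <- find_eligible_intervals(d0 + c(0, 400, 800), c(25, 26, 27))
  expect_equal(nrow(iv), 1)
  expect_equal(iv$index_date, d0 + 400)
  expect_equal(iv$prior_visit_date, d0)
  expect_equal(iv$followup_visit_date, d0 + 800)

  expect_equal(nrow(find_eligible_intervals(d0 + c(0, 200, 400),
                                            c(25, 26, 27))), 0)

  iv <- find_eligible_intervals(d0 + c(0, 400, 800, 1200), rep(25, 4))
  expect_equal(nrow(iv), 2)
  expect_equal(iv$index_date, d0 + c(400, 800))

  # no BMI at the middle visit: not a candidate index
  iv <- find_eligible_intervals(d0 + c(0, 400, 800), c(25, NA, 27))
  expect_equal(nrow(iv), 0)
  # boundary: exactly 365 days on both sides qualifies
  iv <- find_eligible_intervals(d0 + c(0, 365, 730), c(NA, 25, NA))
  expect_equal(nrow(iv), 1)
})

test_that("index selection is deterministic per (seed, patient) and uniform", {
  d0 <- as.Date("2010-01-01")
  iv <- find_eligible_intervals(d0 + c(0, 400, 800, 1200), rep(25, 4))
  s1 <- select_index_visit(iv, seed = 1, patient_id = "P1")
  s2 <- select_index_visit(iv, seed = 1, patient_id = "P1")
  expect_identical(s1, s2)
  one <- select_index_visit(iv[1, ], seed = 99, patient_id = "P1")
  expect_equal(one$index_date, iv$index_date[1])
  expect_error(select_index_visit(iv[0, ], 1, "P1"), "eligible")

  # across many patients the two intervals are chosen ~uniformly
  picks <- vapply(sprintf("P%05d", 1:10000), function(pid) {
    select_index_visit(iv, seed = 4, patient_id = pid)$index_date == d0 + 400
  }, logical(1))
  expect_lt(abs(mean(picks) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("exclusions: any matching code at any date, or registry membership", {
  diag <- data.frame(
    patient_id = c("a", "b", "d"),
    date = as.Date(c("2005-03-01", "2015-06-01", "2012-01-01")),
    code = c("Z34.9", "C509", "E119")
  )
  out <- apply_exclusions(c("a", "b", "c", "d"), diag,
                          registry_ids = "c",
                          exclusion_code_sets = list(
                            pregnancy = c("Z34", "V22"),
                            cancer = c("C50", "174")))
  expect_setequal(out$retained, "d")
  expect_equal(out$audit$reason[out$audit$patient_id == "a"], "pregnancy")
  expect_equal(out$audit$reason[out$audit$patient_id == "b"], "cancer")
  expect_equal(out$audit$reason[out$audit$patient_id == "c"], "registry")
  # partition: excluded + retained = input
  expect_equal(nrow(out$audit) + length(out$retained), 4)
  expect_error(apply_exclusions("a", diag,
                                exclusion_code_sets = list(pregnancy = character(0))),
               "empty code set")
})

test_that("build_cohort applies the hand-derived fixture rules", {
  d0 <- as.Date("2010-01-01")
  mkv <- function(id, offs, h = 67, w = 170) {
    data.frame(patient_id = id, date = d0 + offs, height = h, weight = w)
  }
  visits <- rbind(
    mkv("ok1", c(0, 400, 800)),
    mkv("ok2", c(0, 500, 1000)),
    mkv("ok3", c(10, 410, 820)),
    mkv("sp1", c(0, 100, 200)),      # no 1-year spacing
    mkv("sp2", c(0, 400)),           # only two visits
    mkv("ex1", c(0, 400, 800))       # excluded by pregnancy code
  )
  diagnoses <- data.frame(patient_id = c("ex1", "ok1"),
                          date = d0 + c(50, 450),
                          code = c("Z34.0", "E11.9"))
  demographics <- data.frame(
    patient_id = c("ok1", "ok2", "ok3", "sp1", "sp2", "ex1"),
    birth_date = as.Date("1970-06-15"),
    sex = c("female", "male", "female", "male", "female", "female"),
    race_ethnicity = "White-NH", insurance = "commercial", smoking = "non"
  )
  built <- build_cohort(visits, diagnoses, demographics,
                        code_sets = list(t2dm = code_set("t2dm", "E11")),
                        seed = 1)
  expect_setequal(built$cohort$patient_id, c("ok1", "ok2", "ok3"))
  expect_equal(built$cohort$baseline_bmi, rep(703 * 170 / 67^2, 3))
  # ok1's E11 code 50 days after its day-400 index: incident
  expect_equal(built$cohort$status_t2dm[built$cohort$patient_id == "ok1"],
               "incident")
  expect_equal(built$cohort$status_t2dm[built$cohort$patient_id == "ok2"],
               "free")
  expect_true("ex1" %in% built$exclusion_audit$patient_id)

  # the window property holds for every cohort row
  for (i in seq_len(nrow(built$cohort))) {
    vd <- visits$date[visits$patient_id == built$cohort$patient_id[i]]
    idx <- built$cohort$index_date[i]
    expect_true(any(vd <= idx - 365) && any(vd >= idx + 365))
  }
})

test_that("patients outside 18-75 at index are filtered", {
  d0 <- as.Date("2010-01-01")
  visits <- data.frame(patient_id = "old", date = d0 + c(0, 400, 800),
                       height = 67, weight = 170)
  demographics <- data.frame(patient_id = "old",
                             birth_date = as.Date("1931-01-01"),
                             sex = "female", race_ethnicity = "White-NH",
                             insurance = "commercial", smoking = "non")
  expect_warning(
    built <- build_cohort(visits, data.frame(patient_id = character(0),
                                             date = as.Date(character(0)),
                                             code = character(0)),
                          demographics),
    "zero rows")
  expect_equal(nrow(built$cohort), 0)
  expect_equal(built$exclusion_audit$reason, "age")
})

test_that("cohort construction is invariant to input row order", {
  cfg <- ehr_config(n_patients = 300)
  sim <- simulate_ehr(cfg, seed = 41)
  cs <- lapply(cfg$comorbidities, function(s) code_set(s$name, s$code_prefixes))
  b1 <- build_cohort(sim$visits, sim$diagnoses, sim$demographics,
                     sim$registry_ids, code_sets = cs, seed = 2)
  set.seed(1)
  shuf <- function(df) df[sample(nrow(df)), , drop = FALSE]
  b2 <- build_cohort(shuf(sim$visits), shuf(sim$diagnoses),
                     shuf(sim$demographics), sim$registry_ids,
                     code_sets = cs, seed = 2)
  o1 <- b1$cohort[order(b1$cohort$patient_id), ]
  o2 <- b2$cohort[order(b2$cohort$patient_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})
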