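# Anthropometric cleaning: plausibility bounds, dispersion rules,
# imputation, BMI.

test_that("height rules: absolute bounds and per-patient SD rule", {
  r <- clean_heights(c(95, 70, 70))
  expect_equal(r$reason, c("abs_bound_high", "none", "none"))
  expect_equal(r$valid, c(FALSE, TRUE, TRUE))

  r <- clean_heights(c(40, 70, 70))
  expect_equal(r$reason[1], "abs_bound_low")

  # zero variance: SD = 0 <= 2.5% of mean, rule never fires
  expect_true(all(clean_heights(c(70, 70, 70))$valid))

  # hand-computed: mean 67.5, sample SD 5.0 > 1.6875 = 2.5% of mean;
  # |60 - 67.5| = 7.5 > 5 removed, 70s (2.5 <= 5) kept
  r <- clean_heights(c(60, 70, 70, 70))
  expect_equal(r$reason, c("sd_rule", "none", "none", "none"))

  # dispersion statistics are computed on absolute-bound survivors
  r <- clean_heights(c(200, 70, 70, 70))
  expect_equal(r$reason, c("abs_bound_high", "none", "none", "none"))

  # boundary at exactly 1 SD is kept (strict inequality)
  h <- c(64, 70, 76) # mean 70, sd 6 > 1.75; |64-70| = 6, not > 6
  expect_true(all(clean_heights(h)$valid))

  expect_error(clean_heights(c(-5, 70)), "positive")
  expect_equal(nrow(clean_heights(numeric(0))), 0)
})

test_that("weight rules: absolute bounds, range rule, SD rule", {
  r <- clean_weights(c(1200, 180))
  expect_equal(r$reason, c("abs_bound_high", "none"))
  expect_equal(clean_weights(c(30, 180))$reason[1], "abs_bound_low")

  # hand-computed: range 250 >= 50, mean 212.5, 0.7*range = 175;
  # 400 removed (187.5 > 175), 150s kept (62.5 <= 175, <= SD 125)
  r <- clean_weights(c(150, 150, 150, 400))
  expect_equal(r$valid, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(r$reason[4], "range_rule")

  # range 5 < 50 and SD below 20% of mean: both kept
  expect_true(all(clean_weights(c(160, 165))$valid))

  # SD rule alone: [100, 150, 150, 150]: range 50 triggers range rule too;
  # use range < 50 with high SD: [100, 140]: range 40 < 50, mean 120,
  # sd 28.3 > 24; |100-120| = 20 <= 28.3 so still kept
  expect_true(all(clean_weights(c(100, 140))$valid))

  expect_error(clean_weights(c(0, 100)), "positive")
})

test_that("missing heights are imputed forward then backward", {
  r <- impute_heights(c(70, NA, NA))
  expect_equal(r$height, c(70, 70, 70))
  expect_equal(r$imputed, c(FALSE, TRUE, TRUE))

  r <- impute_heights(c(NA, 68, NA, 69))
  expect_equal(r$height, c(68, 68, 68, 69))
  expect_equal(r$imputed, c(TRUE, FALSE, TRUE, FALSE))

  # imputation only uses valid measurements
  r <- impute_heights(c(95, NA, 70), valid = c(FALSE, NA, TRUE))
  expect_equal(r$height, c(70, 70, 70))
  expect_equal(r$imputed, c(TRUE, TRUE, FALSE))

  r <- impute_heights(c(NA_real_, NA_real_))
  expect_true(all(is.na(r$height)))
  expect_false(any(r$imputed))
})

test_that("BMI follows the imperial conversion and propagates missingness", {
  expect_equal(compute_bmi(70, 180), 703 * 180 / 4900, tolerance = 1e-12)
  expect_true(is.na(compute_bmi(NA, 180)))
  expect_error(compute_bmi(64, 0), "positive")
  # linear in weight
  expect_equal(compute_bmi(66, 300), 2 * compute_bmi(66, 150))
})

test_that("cleaning is idempotent on its output when triggers are stable", {
  set.seed(11)
  for (i in 1:50) {
    h <- round(rnorm(sample(3:12, 1), 67, runif(1, 0.2, 6)), 1)
    h <- h[h > 0]
    r1 <- clean_heights(h)
    surv <- h[!is.na(r1$valid) & r1$valid]
    if (length(surv) < 2) next
    m <- mean(surv); s <- sd(surv)
    r2 <- clean_heights(surv)
    if (s <= 0.025 * m) {
      expect_true(all(r2$valid), info = paste(h, collapse = ","))
    }
  }
})

test_that("values within bounds and within 1 SD of the mean are never removed", {
  set.seed(12)
  for (i in 1:50) {
    m <- runif(1, 55, 75)
    h <- round(runif(sample(3:10, 1), m - 1, m + 1), 1)
    if (any(abs(h - mean(h)) > sd(h))) next
    expect_true(all(clean_heights(h)$valid))
    w <- round(runif(sample(3:10, 1), 150, 160), 1)
    if (any(abs(w - mean(w)) > sd(w))) next
    expect_true(all(clean_weights(w)$valid))
  }
})

test_that("table-level cleaning audits removals and drops no patient", {
  visits <- data.frame(
    patient_id = c("a", "a", "a", "b", "b", "c"),
    date = as.Date("2010-01-01") + c(0, 100, 200, 0, 100, 0),
    height = c(70, NA, 95, 64, 64, NA),
    weight = c(180, 185, 1200, 130, 132, 150)
  )
  out <- clean_visits(visits)
  expect_setequal(unique(out$visits$patient_id), c("a", "b", "c"))
  expect_true("abs_bound_high" %in% out$audit$removal_reason)
  # patient a: missing height imputed from the valid 70; BMI present where
  # weight valid
  a <- out$visits[out$visits$patient_id == "a", ]
  expect_equal(a$height_used, c(70, 70, 70))
  expect_equal(a$bmi[1], 703 * 180 / 4900)
  expect_true(is.na(a$bmi[3])) # weight 1200 removed
  # patient c has no height at all: BMI stays missing
  expect_true(is.na(out$visits$bmi[out$visits$patient_id == "c"]))
})

test_that("table-level cleaning agrees with the per-patient reference rules", {
  set.seed(33)
  rows <- list()
  for (p in 1:40) {
    k <- sample(1:12, 1)
    h <- round(rnorm(k, 66, 2), 1)
    h[runif(k) < 0.3] <- NA
    bad_h <- runif(k) < 0.05
    h[bad_h] <- round(runif(sum(bad_h), 95, 200))
    w <- round(rnorm(k, 170, 25), 1)
    bad_w <- runif(k) < 0.05
    w[bad_w] <- round(runif(sum(bad_w), 300, 1200))
    rows[[p]] <- data.frame(patient_id = sprintf("p%02d", p),
                            date = as.Date("2010-01-01") + sort(sample(0:3000, k)),
                            height = h, weight = pmax(w, 20))
  }
  visits <- do.call(rbind, rows)
  out <- clean_visits(visits)$visits
  for (p in unique(visits$patient_id)) {
    vi <- visits[visits$patient_id == p, ]
    vi <- vi[order(vi$date), ]
    oi <- out[out$patient_id == p, ]
    ch <- clean_heights(vi$height)
    cw <- clean_weights(vi$weight)
    im <- impute_heights(vi$height, valid = !is.na(ch$valid) & ch$valid)
    expect_identical(oi$height_valid, ch$valid)
    expect_identical(oi$weight_valid, cw$valid)
    expect_identical(oi$height_used, im$height)
    expect_identical(oi$height_imputed, im$imputed)
  }
})

test_that("cleaning removes injected gross errors but spares real values", {
  cfg <- ehr_config(n_patients = 1500,
                    errors = error_spec(p_missing_height = 0.25,
                                        p_height_typo = 0.01,
                                        p_weight_typo = 0.01))
  sim <- simulate_ehr(cfg, seed = 31)
  out <- clean_visits(sim$visits)
  v <- out$visits
  # stable (patient, date) sort puts the uncorrupted table in the same row
  # order clean_visits() uses
  u <- sim$truth$visits_uncorrupted
  u <- u[order(u$patient_id, u$date), ]
  expect_equal(paste(v$patient_id, v$date), paste(u$patient_id, u$date))
  h_typo <- !is.na(v$height) & v$height != u$height
  w_typo <- v$weight != u$weight
  # recovery of gross typos
  expect_gt(mean(!v$height_valid[h_typo]), 0.90)
  expect_gt(mean(!v$weight_valid[w_typo]), 0.90)
  # collateral loss on uncorrupted measurements
  clean_h <- !is.na(v$height) & !h_typo
  clean_w <- !w_typo
  expect_lt(mean(!v$height_valid[clean_h]), 0.02)
  expect_lt(mean(!v$weight_valid[clean_w]), 0.02)
})
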