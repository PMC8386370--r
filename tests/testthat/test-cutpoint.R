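# ROC, AUROC, Youden maximization, gate, subgroup and bootstrap machinery.

test_that("youden_index is Se + Sp - 1 with range validation", {
  expect_equal(youden_index(1, 1), 1)
  expect_equal(youden_index(0.5, 0.5), 0)
  expect_equal(round(youden_index(0.72, 0.666), 3), 0.386)
  expect_error(youden_index(1.2, 0.5), "\\[0, 1\\]")
  expect_error(youden_index(0.5, -0.1), "\\[0, 1\\]")
})

test_that("roc_curve matches exhaustive threshold enumeration", {
  # perfect separation
  r <- roc_curve(c(40, 41, 20, 21), c(1, 1, 0, 0))
  at40 <- r[r$threshold == 40, ]
  expect_equal(at40$sensitivity, 1)
  expect_equal(at40$specificity, 1)
  expect_equal(r$sensitivity[1], 1) # -Inf endpoint
  expect_equal(r$specificity[1], 0)
  expect_equal(r$sensitivity[nrow(r)], 0) # +Inf endpoint

  set.seed(5)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    b <- round(runif(n, 20, 40), sample(0:1, 1)) # ties likely
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0 || sum(y) == n) next
    r <- roc_curve(b, y)
    obs <- r[is.finite(r$threshold), ]
    o <- oracle_roc(b, y, obs$threshold)
    expect_equal(obs$sensitivity, o$sensitivity)
    expect_equal(obs$specificity, o$specificity)
    # monotonicity along ascending thresholds
    expect_true(all(diff(r$sensitivity) <= 1e-12))
    expect_true(all(diff(r$specificity) >= -1e-12))
  }
})

test_that("trapezoidal AUROC equals pairwise concordance and pROC agrees", {
  expect_equal(auroc(c(40, 41, 20, 21), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(25, 10), rep(c(0, 1), 5)), 0.5) # all ties

  set.seed(6)
  for (i in 1:30) {
    n <- sample(8:150, 1)
    b <- round(runif(n, 18, 45), 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.6))
    if (sum(y) == 0 || sum(y) == n) next
    a <- auroc(b, y)
    expect_equal(a, oracle_auroc(b, y), tolerance = 1e-12)
    expect_equal(a, bmicutpoints:::.auroc_rank(b, y), tolerance = 1e-12)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(7)
    b <- round(rnorm(300, 29, 6), 1)
    y <- rbinom(300, 1, plogis(-2 + 0.1 * (b - 29)))
    expect_equal(auroc(b, y),
                 as.numeric(pROC::auc(y, b, direction = "<", quiet = TRUE)),
                 tolerance = 1e-10)
  }
  expect_error(auroc(1:5, rep(1, 5)), "single-class")
})

test_that("cut point maximizes Youden with smallest-BMI tie break", {
  # cases {2,4}, controls {1,3}: J = 0.5 at thresholds 2 and 4, tie to 2
  fit <- find_cutpoint(c(2, 4, 1, 3), c(1, 1, 0, 0))
  expect_true(fit$defined)
  expect_equal(fit$cutpoint, 2)
  expect_equal(fit$youden, 0.5)
  expect_equal(fit$youden, fit$sensitivity + fit$specificity - 1,
               tolerance = 1e-12)

  # J at the cut point must dominate every other observed threshold
  set.seed(8)
  b <- round(c(rnorm(150, 27, 4), rnorm(60, 33, 4)), 1)
  y <- rep(c(0, 1), c(150, 60))
  fit <- cutpoint_model(b, y)
  expect_true(fit$cutpoint %in% b) # always an observed value
  r <- fit$roc[is.finite(fit$roc$threshold), ]
  expect_true(all(fit$youden >= r$sensitivity + r$specificity - 1 - 1e-12))
  # smallest BMI among all J-maximizing thresholds
  jmax <- r$threshold[abs(r$sensitivity + r$specificity - 1 - fit$youden)
                      < 1e-12]
  expect_equal(fit$cutpoint, min(jmax))
})

test_that("the AUROC gate is strict and controls `defined`", {
  set.seed(9)
  b <- rnorm(800, 29, 6)
  y <- rbinom(800, 1, 0.2) # labels independent of BMI: AUROC near 0.5
  fit <- cutpoint_model(b, y)
  expect_false(fit$defined)
  expect_true(is.na(fit$cutpoint))
  expect_lt(abs(fit$auroc - 0.5), 3 * sqrt(1 / (12 * sum(y))))
  # same data passes a barely-lower gate
  fit2 <- cutpoint_model(b, y, gate = 0.501)
  expect_identical(fit2$defined, fit2$auroc > 0.501)
  expect_error(cutpoint_model(b, y, gate = 0.4), "gate")
})

test_that("fit methods: coef, predict, summary, formula interface", {
  df <- data.frame(bmi = c(2, 4, 1, 3), incident = c(1, 1, 0, 0))
  fit <- cutpoint_model(incident ~ bmi, data = df)
  expect_equal(unname(coef(fit)["cutpoint"]), 2)
  expect_equal(as.character(predict(fit, c(1.9, 2.1))),
               c("negative", "positive"))
  s <- summary(fit)
  expect_equal(s$n_incident, 2)
  expect_output(print(fit), "cut point")
})

test_that("subgroup cut points recover ordered sex-specific thresholds", {
  spec_f <- true_model_spec("x", "X1", incidence_threshold = 28,
                            incidence_effect = 3, incidence_base_rate = 0.02,
                            age_slope = 0)
  spec_m <- true_model_spec("x", "X1", incidence_threshold = 32,
                            incidence_effect = 3, incidence_base_rate = 0.02,
                            age_slope = 0)
  sf <- simulate_screening_sample(spec_f, 6000, seed = 21)
  sm <- simulate_screening_sample(spec_m, 6000, seed = 22)
  cohort <- data.frame(
    baseline_bmi = c(sf$bmi, sm$bmi),
    sex = rep(c("female", "male"), each = 6000),
    status_x = ifelse(c(sf$label, sm$label) == 1, "incident", "free"),
    stringsAsFactors = FALSE
  )
  sg <- subgroup_cutpoints(cohort, "x", "sex")
  expect_equal(sg$stratum, c("female", "male"))
  expect_true(all(sg$defined))
  expect_lt(sg$cutpoint[sg$stratum == "female"],
            sg$cutpoint[sg$stratum == "male"])
  expect_lt(abs(sg$cutpoint[1] - 28), 1.5)
  expect_lt(abs(sg$cutpoint[2] - 32), 1.5)

  # degenerate stratum: no incident cases
  cohort2 <- cohort
  cohort2$status_x[cohort2$sex == "male"] <- "free"
  sg2 <- subgroup_cutpoints(cohort2, "x", "sex")
  expect_false(sg2$defined[sg2$stratum == "male"])
  expect_match(sg2$reason[sg2$stratum == "male"], "single class")

  # a single-stratum cohort reproduces the overall fit
  one <- cohort[cohort$sex == "female", ]
  sg3 <- subgroup_cutpoints(one, "x", "sex")
  overall <- find_cutpoint(one$baseline_bmi,
                           as.integer(one$status_x == "incident"))
  expect_equal(sg3$cutpoint, overall$cutpoint)
})

test_that("bootstrap comparison is seeded, calibrated in sign, and powered", {
  spec <- true_model_spec("x", "X1", incidence_threshold = 30,
                          incidence_effect = 3, incidence_base_rate = 0.03,
                          age_slope = 0)
  s <- simulate_screening_sample(spec, 4000, seed = 23)
  cmp1 <- bootstrap_compare_cutpoints(s$bmi, s$label, s$bmi, s$label,
                                      n_resamples = 200, seed = 5)
  cmp2 <- bootstrap_compare_cutpoints(s$bmi, s$label, s$bmi, s$label,
                                      n_resamples = 200, seed = 5)
  expect_identical(cmp1$p_value, cmp2$p_value) # determinism
  expect_gte(cmp1$p_value, 0.5) # identical samples: no signal

  spec_b <- true_model_spec("x", "X1", incidence_threshold = 36,
                            incidence_effect = 3, incidence_base_rate = 0.03,
                            age_slope = 0)
  sb <- simulate_screening_sample(spec_b, 8000, seed = 24)
  sa <- simulate_screening_sample(spec, 8000, seed = 25)
  cmp3 <- bootstrap_compare_cutpoints(sa$bmi, sa$label, sb$bmi, sb$label,
                                      n_resamples = 200, seed = 6)
  expect_lt(cmp3$p_value, 0.05)
  expect_lt(cmp3$cutpoint_a, cmp3$cutpoint_b)
  expect_error(bootstrap_compare_cutpoints(s$bmi, s$label, s$bmi, s$label,
                                           n_resamples = 0), "at least 1")
})

test_that("prevalence-based cut point uses prevalent vs non-prevalent", {
  spec <- true_model_spec("x", "X1", incidence_threshold = 30,
                          incidence_effect = 3, incidence_base_rate = 0.03,
                          age_slope = 0)
  s <- simulate_screening_sample(spec, 8000, seed = 26)
  cohort <- data.frame(baseline_bmi = s$bmi,
                       status_x = ifelse(s$label == 1, "prevalent", "free"),
                       stringsAsFactors = FALSE)
  fit <- prevalence_cutpoint(cohort, "x")
  expect_true(fit$defined)
  expect_lt(abs(fit$cutpoint - 30), 1.5)
  cohort$status_x <- "free"
  expect_error(prevalence_cutpoint(cohort, "x"), "single-class")
})

test_that("incidence above the cut point exceeds incidence below for a step model", {
  spec <- true_model_spec("x", "X1", incidence_threshold = 30,
                          incidence_effect = 2, incidence_base_rate = 0.02,
                          age_slope = 0)
  s <- simulate_screening_sample(spec, 20000, seed = 27)
  cohort <- data.frame(baseline_bmi = s$bmi,
                       status_x = ifelse(s$label == 1, "incident", "free"),
                       stringsAsFactors = FALSE)
  rab <- rates_above_below(cohort, "x", 30)
  below <- rab$rate_per_100py[rab$stratum == "below"]
  above <- rab$rate_per_100py[rab$stratum == "above"]
  # implied rates: 100*plogis(qlogis(0.02)) below, 100*plogis(qlogis(0.02)+2)
  p_lo <- 0.02
  p_hi <- plogis(qlogis(0.02) + 2)
  n_lo <- rab$n_at_risk[rab$stratum == "below"]
  n_hi <- rab$n_at_risk[rab$stratum == "above"]
  expect_lt(abs(below - 100 * p_lo), 3 * 100 * sqrt(p_lo * (1 - p_lo) / n_lo))
  expect_lt(abs(above - 100 * p_hi), 3 * 100 * sqrt(p_hi * (1 - p_hi) / n_hi))
  expect_gt(above, below)
  expect_error(rates_above_below(cohort, "x", NA), "not defined")
  # empty stratum yields an undefined-rate marker
  rab2 <- rates_above_below(cohort, "x", min(cohort$baseline_bmi))
  expect_true(is.na(rab2$rate_per_100py[rab2$stratum == "below"]))
})
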