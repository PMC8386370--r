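# Synthetic longitudinal EHR generator.
#
# Emits the three tables the analysis consumes (visits with raw imperial
# anthropometrics, dated diagnosis codes, demographics) plus a bariatric-
# registry id list, together with a ground-truth object (latent BMI model,
# true onset dates, injected-corruption counts) so that every downstream
# stage can be checked against known parameters. The disease model is a
# per-year logistic with a step in the log-odds at a configurable BMI
# threshold, so a true cut point exists by construction.

#' Ground-truth disease model for one comorbidity
#'
#' Baseline prevalence follows a logistic model in BMI and age; one-year
#' incidence among disease-free patients follows
#' `logit(p) = logit(base_rate) + effect * step(BMI - threshold)
#'  + age_slope * (age - 45) + modifiers`,
#' with a hard step by default and a smoothed (logistic ramp) alternative.
#'
#' @param name comorbidity name (used for `status_` columns downstream).
#' @param code_prefixes ICD code prefixes emitted for this comorbidity and
#'   consumed by the classification stage.
#' @param baseline_prevalence_logit_intercept intercept of the baseline
#'   prevalence model (log-odds at BMI 25, age 45).
#' @param prevalence_bmi_slope prevalence log-odds per kg/m^2 above 25.
#' @param incidence_base_rate one-year incidence probability below the
#'   threshold (at age 45), in (0, 1).
#' @param incidence_threshold true BMI threshold theta in kg/m^2 (15-60).
#' @param incidence_effect log-odds step delta at the threshold (>= 0).
#' @param age_slope incidence log-odds per year of age.
#' @param sex_modifier log-odds added for male patients.
#' @param smooth use a logistic ramp of scale `smooth_scale` instead of a
#'   hard step.
#' @param smooth_scale ramp scale in kg/m^2.
#' @return object of class `"true_model_spec"`.
#' @export
true_model_spec <- function(name, code_prefixes,
                            baseline_prevalence_logit_intercept = -3,
                            prevalence_bmi_slope = 0.08,
                            incidence_base_rate = 0.02,
                            incidence_threshold = 30,
                            incidence_effect = 1.5,
                            age_slope = 0.02,
                            sex_modifier = 0,
                            smooth = FALSE,
                            smooth_scale = 2) {
  if (!is.numeric(incidence_base_rate) || incidence_base_rate <= 0 ||
      incidence_base_rate >= 1) {
    stop("configuration error: `incidence_base_rate` must be in (0, 1)",
         call. = FALSE)
  }
  if (incidence_threshold < 15 || incidence_threshold > 60) {
    stop("configuration error: `incidence_threshold` must be a plausible ",
         "BMI (15-60 kg/m^2)", call. = FALSE)
  }
  if (incidence_effect < 0) {
    stop("configuration error: `incidence_effect` must be >= 0", call. = FALSE)
  }
  structure(list(
    name = name, code_prefixes = as.character(code_prefixes),
    baseline_prevalence_logit_intercept = baseline_prevalence_logit_intercept,
    prevalence_bmi_slope = prevalence_bmi_slope,
    incidence_base_rate = incidence_base_rate,
    incidence_threshold = incidence_threshold,
    incidence_effect = incidence_effect,
    age_slope = age_slope, sex_modifier = sex_modifier,
    smooth = smooth, smooth_scale = smooth_scale
  ), class = "true_model_spec")
}

# Log-odds contribution of BMI for one comorbidity spec.
.bmi_effect <- function(spec, bmi) {
  if (spec$smooth) {
    spec$incidence_effect *
      stats::plogis((bmi - spec$incidence_threshold) / spec$smooth_scale)
  } else {
    spec$incidence_effect * as.numeric(bmi >= spec$incidence_threshold)
  }
}

#' Measurement-corruption model
#'
#' Heights go missing with probability `p_missing_height`; recorded
#' non-missing heights and weights receive a gross data-entry error with
#' probabilities `p_height_typo` / `p_weight_typo`. An error is a unit
#' confusion with probability `p_unit_confusion` (a height entered in
#' centimetres, a weight entered in kilograms) and otherwise a
#' transposition of the first two digits of the integer part.
#'
#' @param p_missing_height,p_height_typo,p_weight_typo probabilities.
#' @param p_unit_confusion probability a typo is a unit confusion.
#' @return object of class `"error_spec"`.
#' @export
error_spec <- function(p_missing_height = 0.30, p_height_typo = 0.005,
                       p_weight_typo = 0.005, p_unit_confusion = 0.5) {
  .assert_prob(p_missing_height, "p_missing_height")
  .assert_prob(p_height_typo, "p_height_typo")
  .assert_prob(p_weight_typo, "p_weight_typo")
  .assert_prob(p_unit_confusion, "p_unit_confusion")
  structure(list(p_missing_height = p_missing_height,
                 p_height_typo = p_height_typo,
                 p_weight_typo = p_weight_typo,
                 p_unit_confusion = p_unit_confusion),
            class = "error_spec")
}

.default_comorbidities <- function() {
  list(
    t2dm = true_model_spec(
      "t2dm", c("E11", "250"),
      baseline_prevalence_logit_intercept = -3.2,
      prevalence_bmi_slope = 0.10,
      incidence_base_rate = 0.012, incidence_threshold = 31,
      incidence_effect = 1.6, age_slope = 0.03),
    hypertension = true_model_spec(
      "hypertension", c("I10", "401"),
      baseline_prevalence_logit_intercept = -2.2,
      prevalence_bmi_slope = 0.08,
      incidence_base_rate = 0.025, incidence_threshold = 28.5,
      incidence_effect = 1.2, age_slope = 0.04),
    osa = true_model_spec(
      "osa", c("G4733", "32723"),
      baseline_prevalence_logit_intercept = -3.8,
      prevalence_bmi_slope = 0.12,
      incidence_base_rate = 0.008, incidence_threshold = 30,
      incidence_effect = 2.0, age_slope = 0.02, sex_modifier = 0.4),
    anxiety = true_model_spec(
      "anxiety", c("F41", "3000"),
      baseline_prevalence_logit_intercept = -1.9,
      prevalence_bmi_slope = 0.0,
      incidence_base_rate = 0.03, incidence_threshold = 30,
      incidence_effect = 0, age_slope = -0.01)
  )
}

#' Generator configuration
#'
#' Bundles everything [simulate_ehr()] needs: cohort size, observation
#' window, visit process, demographic mixture, anthropometric model,
#' per-comorbidity ground-truth disease models, the corruption model and
#' the exclusion process. Defaults emulate a 10.5-year adult primary-care
#' population: lognormal baseline BMI (mean ~29, SD ~7 kg/m^2),
#' sex-specific heights, about 1.5 visits per patient-year.
#'
#' @param n_patients number of patients (>= 0).
#' @param window_start,window_end observation window (ISO dates).
#' @param visit_rate mean visits per patient-year (Poisson).
#' @param comorbidities named list of [true_model_spec()] objects.
#' @param errors an [error_spec()].
#' @param demographics list: `p_female`, named `race`, `insurance`,
#'   `smoking` probability vectors, `age_mean`, `age_sd`, `age_range`
#'   (age at the start of the window).
#' @param anthro list: `height_mean` (named, by sex, inches), `height_sd`,
#'   `height_noise_sd`, `bmi_meanlog`, `bmi_sdlog`, `bmi_drift_sd`
#'   (kg/m^2 per year), `bmi_noise_sd`.
#' @param exclusions list: `pregnancy_prefixes`, `cancer_prefixes`,
#'   `p_pregnancy` (among female patients), `p_cancer`, `p_registry`.
#' @return object of class `"ehr_config"`.
#' @export
ehr_config <- function(n_patients = 1000,
                       window_start = "2008-06-01",
                       window_end = "2018-12-31",
                       visit_rate = 1.5,
                       comorbidities = .default_comorbidities(),
                       errors = error_spec(),
                       demographics = list(),
                       anthro = list(),
                       exclusions = list()) {
  if (!is.numeric(n_patients) || n_patients < 0) {
    stop("configuration error: `n_patients` must be >= 0", call. = FALSE)
  }
  window_start <- .as_date(window_start)
  window_end <- .as_date(window_end)
  if (!(window_end > window_start)) {
    stop("configuration error: `window_end` must be after `window_start`",
         call. = FALSE)
  }
  if (!is.numeric(visit_rate) || visit_rate <= 0) {
    stop("configuration error: `visit_rate` must be positive", call. = FALSE)
  }
  stopifnot(inherits(errors, "error_spec"),
            all(vapply(comorbidities, inherits, logical(1),
                       "true_model_spec")))
  dem <- utils::modifyList(list(
    p_female = 0.549,
    race = c("White-NH" = 0.887, "Black-NH" = 0.039, "Asian-NH" = 0.027,
             "Native-American-NH" = 0.005, "Hispanic" = 0.031,
             "other/unspecified" = 0.011),
    insurance = c(commercial = 0.788, Medicare = 0.131, Medicaid = 0.025,
                  "other/unspecified" = 0.056),
    smoking = c(active = 0.141, former = 0.264, passive = 0.011,
                non = 0.584),
    age_mean = 46.8, age_sd = 15.3, age_range = c(18, 85)
  ), demographics)
  an <- utils::modifyList(list(
    height_mean = c(female = 63.8, male = 69.3),
    height_sd = c(female = 2.7, male = 2.9),
    height_noise_sd = 0.3,
    bmi_meanlog = log(29.1) - 0.5 * log(1 + (7 / 29.1)^2),
    bmi_sdlog = sqrt(log(1 + (7 / 29.1)^2)),
    bmi_drift_sd = 0.15,
    bmi_noise_sd = 0.5
  ), anthro)
  exc <- utils::modifyList(list(
    pregnancy_prefixes = c("Z34", "V22"),
    cancer_prefixes = c("C50", "174"),
    p_pregnancy = 0.03, p_cancer = 0.02, p_registry = 0.002
  ), exclusions)
  .assert_prob(exc$p_pregnancy, "p_pregnancy")
  .assert_prob(exc$p_cancer, "p_cancer")
  .assert_prob(exc$p_registry, "p_registry")
  .assert_prob(dem$p_female, "p_female")
  structure(list(
    n_patients = as.integer(n_patients),
    window_start = window_start, window_end = window_end,
    visit_rate = visit_rate, comorbidities = comorbidities,
    errors = errors, demographics = dem, anthro = an, exclusions = exc
  ), class = "ehr_config")
}

# Swap the first two digits of the integer part; returns the original value
# when the swap is a no-op (caller falls back to unit confusion).
.transpose_digits <- function(x) {
  ip <- floor(abs(x))
  frac <- abs(x) - ip
  s <- formatC(ip, format = "d")
  swapped <- vapply(s, function(si) {
    if (nchar(si) < 2L) return(si)
    paste0(substr(si, 2, 2), substr(si, 1, 1), substr(si, 3, nchar(si)))
  }, character(1), USE.NAMES = FALSE)
  sign(x) * (as.numeric(swapped) + frac)
}

#' Simulate a synthetic EHR
#'
#' Generates demographics, visit and diagnosis tables plus a registry id
#' list and a ground-truth object. Identical `(config, seed)` pairs
#' reproduce identical output.
#'
#' Each patient has a constant true height, a latent BMI trajectory
#' (random intercept + linear drift + visit-level noise), and Poisson
#' visits at uniform dates strictly inside the window. Recorded weights
#' derive from the latent BMI; heights and weights are then corrupted per
#' the [error_spec()]. Baseline-prevalent disease emits a code early in
#' the window; incident disease is simulated year by year from the
#' [true_model_spec()] step model, emitting a code at (or shortly after)
#' onset.
#'
#' @param config an [ehr_config()].
#' @param seed integer seed.
#' @return object of class `"synthetic_ehr"`: list with `demographics`,
#'   `visits`, `diagnoses`, `registry_ids`, `truth` (class `"ehr_truth"`)
#'   and `config`.
#' @export
simulate_ehr <- function(config = ehr_config(), seed = 1) {
  stopifnot(inherits(config, "ehr_config"))
  .with_seed(seed, .simulate_ehr_impl(config))
}

.simulate_ehr_impl <- function(config) {
  n <- config$n_patients
  ws <- config$window_start
  we <- config$window_end
  span_days <- as.numeric(we - ws)
  years <- span_days / 365.25
  dem <- config$demographics
  an <- config$anthro
  empty <- function() {
    list(
      demographics = data.frame(patient_id = character(0),
                                birth_date = as.Date(character(0)),
                                sex = character(0),
                                race_ethnicity = character(0),
                                insurance = character(0),
                                smoking = character(0)),
      visits = data.frame(patient_id = character(0),
                          date = as.Date(character(0)),
                          height = numeric(0), weight = numeric(0)),
      diagnoses = data.frame(patient_id = character(0),
                             date = as.Date(character(0)),
                             code = character(0)),
      registry_ids = character(0),
      truth = structure(list(
        patients = data.frame(), onsets = data.frame(),
        visits_uncorrupted = data.frame(),
        corruption = c(missing_height = 0L, height_typo = 0L,
                       weight_typo = 0L),
        model = config$comorbidities), class = "ehr_truth"),
      config = config
    )
  }
  if (n == 0L) {
    out <- empty()
    class(out) <- "synthetic_ehr"
    return(out)
  }

  id <- sprintf("P%06d", seq_len(n))
  sex <- ifelse(stats::runif(n) < dem$p_female, "female", "male")
  race <- sample(names(dem$race), n, replace = TRUE, prob = dem$race)
  insurance <- sample(names(dem$insurance), n, replace = TRUE,
                      prob = dem$insurance)
  smoking <- sample(names(dem$smoking), n, replace = TRUE,
                    prob = dem$smoking)
  # truncated normal age at window start via inverse CDF
  lo <- stats::pnorm(dem$age_range[1], dem$age_mean, dem$age_sd)
  hi <- stats::pnorm(dem$age_range[2], dem$age_mean, dem$age_sd)
  age0 <- stats::qnorm(stats::runif(n, lo, hi), dem$age_mean, dem$age_sd)
  birth_date <- ws - round(age0 * 365.25)

  height_true <- stats::rnorm(n, an$height_mean[sex], an$height_sd[sex])
  bmi0 <- pmin(pmax(stats::rlnorm(n, an$bmi_meanlog, an$bmi_sdlog), 16), 65)
  drift <- stats::rnorm(n, 0, an$bmi_drift_sd)

  n_visits <- stats::rpois(n, config$visit_rate * years)
  vid <- rep(id, n_visits)
  vpat <- rep(seq_len(n), n_visits)
  # strictly inside the window
  vdate <- ws + floor(stats::runif(length(vid), 1, span_days))
  ord <- order(vpat, vdate)
  vid <- vid[ord]; vpat <- vpat[ord]; vdate <- vdate[ord]
  t_years <- as.numeric(vdate - ws) / 365.25
  bmi_visit <- bmi0[vpat] + drift[vpat] * t_years +
    stats::rnorm(length(vpat), 0, an$bmi_noise_sd)
  bmi_visit <- pmax(bmi_visit, 13)
  h_rec <- round((height_true[vpat] +
                  stats::rnorm(length(vpat), 0, an$height_noise_sd)) * 2) / 2
  w_rec <- round(bmi_visit * height_true[vpat]^2 / 703, 1)

  visits_clean <- data.frame(patient_id = vid, date = vdate,
                             height = h_rec, weight = w_rec,
                             stringsAsFactors = FALSE)

  # --- corruption -----------------------------------------------------
  err <- config$errors
  nv <- nrow(visits_clean)
  h <- visits_clean$height
  w <- visits_clean$weight
  miss <- stats::runif(nv) < err$p_missing_height
  typo_h <- !miss & stats::runif(nv) < err$p_height_typo
  typo_w <- stats::runif(nv) < err$p_weight_typo
  unit_h <- stats::runif(nv) < err$p_unit_confusion
  unit_w <- stats::runif(nv) < err$p_unit_confusion
  h_cor <- h
  if (any(typo_h)) {
    tr <- .transpose_digits(h[typo_h])
    use_unit <- unit_h[typo_h] | tr == h[typo_h]
    h_cor[typo_h] <- ifelse(use_unit, round(h[typo_h] * 2.54), tr)
  }
  w_cor <- w
  if (any(typo_w)) {
    tr <- .transpose_digits(w[typo_w])
    use_unit <- unit_w[typo_w] | tr == w[typo_w]
    w_cor[typo_w] <- ifelse(use_unit, round(w[typo_w] / 2.2046, 1), tr)
  }
  h_cor[miss] <- NA_real_
  visits <- visits_clean
  visits$height <- h_cor
  visits$weight <- w_cor
  # .transpose_digits no-ops fall back to unit confusion, so every injected
  # typo changes the recorded value and is recoverable by diffing tables
  corruption <- c(missing_height = sum(miss),
                  height_typo = sum(typo_h),
                  weight_typo = sum(typo_w))

  # --- disease processes ----------------------------------------------
  cms <- config$comorbidities
  onset_list <- list()
  diag_rows <- list()
  for (cm in names(cms)) {
    spec <- cms[[cm]]
    sex_term <- spec$sex_modifier * as.numeric(sex == "male")
    lp_prev <- spec$baseline_prevalence_logit_intercept +
      spec$prevalence_bmi_slope * (bmi0 - 25) +
      spec$age_slope * (age0 - 45) + sex_term
    prevalent <- stats::runif(n) < stats::plogis(lp_prev)
    onset <- rep(as.Date(NA), n)
    onset[prevalent] <- ws - floor(stats::runif(sum(prevalent), 1, 3 * 365))
    at_risk <- !prevalent
    yrs <- floor(years)
    onset_year <- rep(NA_real_, n)
    for (y in seq_len(yrs) - 1L) {
      if (!any(at_risk)) break
      bmi_y <- bmi0 + drift * (y + 0.5)
      lp <- stats::qlogis(spec$incidence_base_rate) +
        .bmi_effect(spec, bmi_y) +
        spec$age_slope * (age0 + y + 0.5 - 45) + sex_term
      hit <- at_risk & stats::runif(n) < stats::plogis(lp)
      onset_year[hit] <- y + stats::runif(sum(hit))
      at_risk <- at_risk & !hit
    }
    inc <- !is.na(onset_year)
    onset[inc] <- ws + floor(onset_year[inc] * 365.25)
    onset_list[[cm]] <- data.frame(patient_id = id, comorbidity = cm,
                                   prevalent_at_start = prevalent,
                                   onset_date = onset,
                                   stringsAsFactors = FALSE)
    has <- prevalent | inc
    if (any(has)) {
      code_date <- rep(as.Date(NA), n)
      code_date[prevalent] <- ws + floor(stats::runif(sum(prevalent), 0, 300))
      code_date[inc] <- pmin(onset[inc] +
                               floor(stats::runif(sum(inc), 0, 30)), we)
      pref <- sample(spec$code_prefixes, sum(has), replace = TRUE)
      dotted <- stats::runif(sum(has)) < 0.5
      code <- paste0(pref, ifelse(dotted, ".", ""),
                     sample(0:9, sum(has), replace = TRUE))
      diag_rows[[cm]] <- data.frame(patient_id = id[has],
                                    date = code_date[has], code = code,
                                    stringsAsFactors = FALSE)
    }
  }

  # --- exclusions ------------------------------------------------------
  exc <- config$exclusions
  preg <- sex == "female" & stats::runif(n) < exc$p_pregnancy
  canc <- stats::runif(n) < exc$p_cancer
  if (any(preg)) {
    diag_rows[["pregnancy"]] <- data.frame(
      patient_id = id[preg],
      date = ws + floor(stats::runif(sum(preg), 0, span_days)),
      code = paste0(sample(exc$pregnancy_prefixes, sum(preg), replace = TRUE),
                    sample(0:9, sum(preg), replace = TRUE)),
      stringsAsFactors = FALSE)
  }
  if (any(canc)) {
    diag_rows[["cancer"]] <- data.frame(
      patient_id = id[canc],
      date = ws + floor(stats::runif(sum(canc), 0, span_days)),
      code = paste0(sample(exc$cancer_prefixes, sum(canc), replace = TRUE),
                    sample(0:9, sum(canc), replace = TRUE)),
      stringsAsFactors = FALSE)
  }
  registry_ids <- id[stats::runif(n) < exc$p_registry]

  diagnoses <- if (length(diag_rows)) do.call(rbind, diag_rows) else
    data.frame(patient_id = character(0), date = as.Date(character(0)),
               code = character(0))
  diagnoses <- diagnoses[order(diagnoses$patient_id, diagnoses$date,
                               diagnoses$code), , drop = FALSE]
  rownames(diagnoses) <- NULL

  demographics <- data.frame(patient_id = id, birth_date = birth_date,
                             sex = sex, race_ethnicity = race,
                             insurance = insurance, smoking = smoking,
                             stringsAsFactors = FALSE)
  onsets <- do.call(rbind, onset_list)
  rownames(onsets) <- NULL
  truth <- structure(list(
    patients = data.frame(patient_id = id, sex = sex, age_at_start = age0,
                          height_true = height_true, bmi_intercept = bmi0,
                          bmi_drift = drift, stringsAsFactors = FALSE),
    onsets = onsets,
    visits_uncorrupted = visits_clean,
    corruption = corruption,
    model = cms
  ), class = "ehr_truth")

  out <- list(demographics = demographics, visits = visits,
              diagnoses = diagnoses, registry_ids = registry_ids,
              truth = truth, config = config)
  class(out) <- "synthetic_ehr"
  out
}

#' @export
print.synthetic_ehr <- function(x, ...) {
  cat("Synthetic EHR:", nrow(x$demographics), "patients,",
      nrow(x$visits), "visits,", nrow(x$diagnoses), "diagnosis events\n")
  cat("  window:", format(x$config$window_start), "to",
      format(x$config$window_end), "\n")
  cat("  comorbidities:", paste(names(x$config$comorbidities),
                                collapse = ", "), "\n")
  invisible(x)
}

#' True BMI threshold of the generator
#'
#' Accessor for the generator's ground-truth threshold theta, used in
#' parameter-recovery tests.
#'
#' @param truth a `"synthetic_ehr"`, `"ehr_truth"`, `"ehr_config"` object
#'   or a named list of [true_model_spec()]s.
#' @param comorbidity comorbidity name.
#' @return theta in kg/m^2.
#' @export
true_cutpoint <- function(truth, comorbidity) {
  model <- if (inherits(truth, "synthetic_ehr")) truth$config$comorbidities
  else if (inherits(truth, "ehr_truth")) truth$model
  else if (inherits(truth, "ehr_config")) truth$comorbidities
  else truth
  if (!comorbidity %in% names(model)) {
    stop("unknown comorbidity `", comorbidity, "`; known: ",
         paste(names(model), collapse = ", "), call. = FALSE)
  }
  model[[comorbidity]]$incidence_threshold
}

#' Draw a cross-sectional screening sample from the ground-truth model
#'
#' Samples baseline BMI from the generator's latent BMI distribution and a
#' one-year incident label from the [true_model_spec()] step model at a
#' fixed age (so the age term vanishes at `age = 45`). This is the same
#' disease model the full longitudinal generator uses, without the visit
#' process, and is convenient for simulation studies of the cut-point
#' estimator itself.
#'
#' @param spec a [true_model_spec()].
#' @param n sample size.
#' @param seed integer seed.
#' @param age common patient age in years.
#' @param anthro optional anthropometric parameter list as in
#'   [ehr_config()] (only `bmi_meanlog`/`bmi_sdlog` are used).
#' @return data.frame with columns `bmi`, `label`.
#' @export
simulate_screening_sample <- function(spec, n, seed = 1, age = 45,
                                      anthro = NULL) {
  stopifnot(inherits(spec, "true_model_spec"))
  an <- utils::modifyList(list(
    bmi_meanlog = log(29.1) - 0.5 * log(1 + (7 / 29.1)^2),
    bmi_sdlog = sqrt(log(1 + (7 / 29.1)^2))
  ), if (is.null(anthro)) list() else anthro)
  .with_seed(seed, {
    bmi <- pmin(pmax(stats::rlnorm(n, an$bmi_meanlog, an$bmi_sdlog), 16), 65)
    lp <- stats::qlogis(spec$incidence_base_rate) + .bmi_effect(spec, bmi) +
      spec$age_slope * (age - 45)
    data.frame(bmi = bmi,
               label = as.integer(stats::runif(n) < stats::plogis(lp)))
  })
}
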