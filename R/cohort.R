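# Cohort construction: eligibility, index-visit selection, exclusions.
#
# An eligible index visit carries a computable BMI and has some visit at
# least 365 days before it and some visit at least 365 days after it (which
# also guarantees >= 3 visits spanning >= 2 years). Patients with several
# candidate index visits have one chosen uniformly at random from a
# per-patient stream keyed on (seed, patient_id), so cohort membership does
# not depend on input row order.

#' Enumerate eligible index-visit intervals for one patient
#'
#' @param dates visit dates for one patient, date-ordered.
#' @param bmi BMI at each visit (`NA` when not computable).
#' @param window_days minimum spacing in days on each side (default 365).
#' @return data.frame with one row per candidate index visit: `index_date`,
#'   `prior_visit_date` (latest visit at least `window_days` before),
#'   `followup_visit_date` (earliest visit at least `window_days` after),
#'   `index_bmi`. Zero rows when the patient is ineligible.
#' @export
find_eligible_intervals <- function(dates, bmi, window_days = 365) {
  dates <- .as_date(dates)
  stopifnot(length(dates) == length(bmi))
  o <- order(dates)
  dates <- dates[o]; bmi <- bmi[o]
  out <- data.frame(index_date = as.Date(character(0)),
                    prior_visit_date = as.Date(character(0)),
                    followup_visit_date = as.Date(character(0)),
                    index_bmi = numeric(0))
  if (length(dates) < 3L) return(out)
  d <- as.numeric(dates)
  for (i in seq_along(dates)) {
    if (is.na(bmi[i])) next
    before <- which(d <= d[i] - window_days)
    after <- which(d >= d[i] + window_days)
    if (length(before) && length(after)) {
      out <- rbind(out, data.frame(
        index_date = dates[i],
        prior_visit_date = dates[max(before)],
        followup_visit_date = dates[min(after)],
        index_bmi = bmi[i]))
    }
  }
  rownames(out) <- NULL
  out
}

#' Select the index visit among a patient's eligible intervals
#'
#' Uniform random choice from a per-patient substream derived from
#' `(seed, patient_id)`: the same pair always selects the same interval,
#' independent of row order elsewhere in the data.
#'
#' @param intervals data.frame from [find_eligible_intervals()].
#' @param seed integer analysis seed.
#' @param patient_id the patient's identifier.
#' @return the selected row of `intervals`.
#' @export
select_index_visit <- function(intervals, seed, patient_id) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    stop("no eligible interval to select from", call. = FALSE)
  }
  intervals <- intervals[order(intervals$index_date), , drop = FALSE]
  k <- nrow(intervals)
  pick <- if (k == 1L) 1L else {
    u <- .substream_unif(seed, patient_id)
    as.integer(floor(u * k)) + 1L
  }
  intervals[min(pick, k), , drop = FALSE]
}

#' Apply diagnosis-code and registry exclusions
#'
#' A patient is excluded when any diagnosis code at any date matches an
#' exclusion category's prefixes, or when the patient appears in the
#' registry id list. The audit records the first triggering reason, with
#' categories checked in their configured order and the registry last.
#'
#' @param patient_ids character vector of candidate patient ids.
#' @param diagnoses diagnosis table (`patient_id`, `date`, `code`).
#' @param registry_ids ids excluded by registry membership.
#' @param exclusion_code_sets named list of prefix vectors (or
#'   [code_set()]s), one per category.
#' @return list with `retained` (ids) and `audit` (data.frame
#'   `patient_id`, `reason` for each excluded patient).
#' @export
apply_exclusions <- function(patient_ids, diagnoses, registry_ids = character(0),
                             exclusion_code_sets = list()) {
  patient_ids <- as.character(patient_ids)
  reason <- rep(NA_character_, length(patient_ids))
  for (cat_name in names(exclusion_code_sets)) {
    set <- exclusion_code_sets[[cat_name]]
    prefixes <- if (inherits(set, "code_set")) set$prefixes
                else normalize_code(set)
    if (length(prefixes) == 0L || !any(nzchar(prefixes))) {
      stop("configuration error: exclusion category `", cat_name,
           "` has an empty code set", call. = FALSE)
    }
    if (nrow(diagnoses) == 0L) next
    hit_rows <- match_codes(diagnoses$code, prefixes)
    hit_ids <- unique(as.character(diagnoses$patient_id[hit_rows]))
    newly <- is.na(reason) & patient_ids %in% hit_ids
    reason[newly] <- cat_name
  }
  newly <- is.na(reason) & patient_ids %in% as.character(registry_ids)
  reason[newly] <- "registry"
  list(
    retained = patient_ids[is.na(reason)],
    audit = data.frame(patient_id = patient_ids[!is.na(reason)],
                       reason = reason[!is.na(reason)],
                       stringsAsFactors = FALSE)
  )
}

#' Build the analysis cohort
#'
#' Runs the full front end: anthropometric cleaning and BMI computation,
#' eligibility enumeration, random index-visit selection, code/registry
#' exclusions, the age filter at the index visit, covariate assembly and
#' per-comorbidity prevalent/incident/free classification. Deterministic
#' given `(inputs, seed)`.
#'
#' @param visits raw visit table (`patient_id`, `date`, `height`, `weight`).
#' @param diagnoses diagnosis table (`patient_id`, `date`, `code`).
#' @param demographics demographics table (`patient_id`, `birth_date`,
#'   `sex`, `race_ethnicity`, `insurance`, `smoking`).
#' @param registry_ids registry exclusion id list.
#' @param code_sets named list of [code_set()]s, one per comorbidity.
#' @param exclusion_code_sets named list of exclusion prefix sets.
#' @param seed integer seed driving index-visit selection.
#' @param window_days eligibility/incidence window (days).
#' @param age_range inclusive age bounds at the index visit.
#' @return list of class `"ehr_cohort"` with `cohort` (one row per
#'   retained patient: index date, baseline BMI, covariates and one
#'   `status_<comorbidity>` column per code set), `exclusion_audit`,
#'   `cleaning_audit` and `n_input_patients`.
#' @export
build_cohort <- function(visits, diagnoses, demographics,
                         registry_ids = character(0),
                         code_sets = list(),
                         exclusion_code_sets = list(
                           pregnancy = c("Z34", "V22"),
                           cancer = c("C50", "174")),
                         seed = 1, window_days = 365,
                         age_range = c(18, 75)) {
  cleaned <- clean_visits(visits)
  v <- cleaned$visits
  ids_in <- unique(as.character(v$patient_id))

  # candidate index visits, vectorized over the (patient-sorted) table
  ok_bmi <- !is.na(v$bmi)
  id <- as.character(v$patient_id)
  dnum <- as.numeric(v$date)
  first_d <- .grp_apply(dnum, id, min)
  last_d <- .grp_apply(dnum, id, max)
  cand <- ok_bmi & (dnum - first_d >= window_days) &
    (last_d - dnum >= window_days)

  cand_ids <- id[cand]
  cand_dates <- dnum[cand]
  cand_bmi <- v$bmi[cand]
  # order by (patient, date) so the k-th candidate is well defined
  o <- order(cand_ids, cand_dates)
  cand_ids <- cand_ids[o]; cand_dates <- cand_dates[o]; cand_bmi <- cand_bmi[o]
  grp <- split(seq_along(cand_ids), cand_ids)
  eligible_ids <- names(grp)
  if (length(eligible_ids)) {
    k <- lengths(grp)
    u <- .substream_unif(seed, eligible_ids)
    pick_in_grp <- pmin(as.integer(floor(u * k)) + 1L, k)
    pick <- vapply(seq_along(grp), function(i) grp[[i]][pick_in_grp[i]],
                   integer(1))
    index_date <- as.Date(cand_dates[pick], origin = "1970-01-01")
    baseline_bmi <- cand_bmi[pick]
  } else {
    index_date <- as.Date(character(0))
    baseline_bmi <- numeric(0)
  }

  excl <- apply_exclusions(eligible_ids, diagnoses, registry_ids,
                           exclusion_code_sets)
  keep <- eligible_ids %in% excl$retained

  cohort <- data.frame(patient_id = eligible_ids[keep],
                       index_date = index_date[keep],
                       baseline_bmi = baseline_bmi[keep],
                       stringsAsFactors = FALSE)

  dm <- demographics
  dm$patient_id <- as.character(dm$patient_id)
  m <- match(cohort$patient_id, dm$patient_id)
  cohort$sex <- dm$sex[m]
  cohort$race_ethnicity <- dm$race_ethnicity[m]
  cohort$insurance <- dm$insurance[m]
  cohort$smoking <- dm$smoking[m]
  cohort$age_at_index <-
    as.numeric(cohort$index_date - .as_date(dm$birth_date[m])) / 365.25

  in_age <- !is.na(cohort$age_at_index) &
    cohort$age_at_index >= age_range[1] & cohort$age_at_index <= age_range[2]
  age_audit <- data.frame(patient_id = cohort$patient_id[!in_age],
                          reason = rep("age", sum(!in_age)),
                          stringsAsFactors = FALSE)
  cohort <- cohort[in_age, , drop = FALSE]

  for (cm in names(code_sets)) {
    cohort[[paste0("status_", cm)]] <- .classify_all(
      diagnoses, cohort$patient_id, cohort$index_date, code_sets[[cm]],
      window_days = window_days)
  }
  rownames(cohort) <- NULL
  if (nrow(cohort) == 0L) {
    warning("cohort has zero rows", call. = FALSE)
  }
  structure(list(cohort = cohort,
                 exclusion_audit = rbind(excl$audit, age_audit),
                 cleaning_audit = cleaned$audit,
                 n_input_patients = length(ids_in)),
            class = "ehr_cohort")
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat("EHR analysis cohort:", nrow(x$cohort), "patients retained of",
      x$n_input_patients, "with visits\n")
  if (nrow(x$exclusion_audit)) {
    tb <- table(x$exclusion_audit$reason)
    cat("  exclusions:", paste(sprintf("%s=%d", names(tb), tb),
                               collapse = ", "), "\n")
  }
  cat("  measurements removed in cleaning:", nrow(x$cleaning_audit), "\n")
  invisible(x)
}
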