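# End-to-end seeded pipeline: inputs (or generator) -> cleaning audit,
# cohort, incidence table, median contrasts, cut-point tables, subgroup
# comparisons, incidence-vs-prevalence comparison, baseline-characteristic
# summaries, plus a JSON manifest of everything written.

#' Pipeline configuration
#'
#' @param input_dir directory holding `visits.csv`, `diagnoses.csv`,
#'   `demographics.csv`, `registry_ids.csv`; `NULL` to simulate instead.
#' @param generator an [ehr_config()] used when `input_dir` is `NULL`.
#' @param code_sets named list of [code_set()]s; defaults to the
#'   generator's comorbidity code prefixes.
#' @param exclusion_code_sets named list of exclusion prefix sets.
#' @param gate AUROC gate in (0.5, 1).
#' @param n_resamples bootstrap resamples for comparisons and CIs.
#' @param window_days eligibility/incidence window in days.
#' @param age_range inclusive age bounds at the index visit.
#' @param seed top-level seed; every stage derives its randomness from it.
#' @param output_dir where `run_pipeline()` writes its files.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input_dir = NULL, generator = ehr_config(),
                            code_sets = NULL,
                            exclusion_code_sets = list(
                              pregnancy = c("Z34", "V22"),
                              cancer = c("C50", "174")),
                            gate = 0.6, n_resamples = 1000,
                            window_days = 365, age_range = c(18, 75),
                            seed = 1, output_dir = tempfile("ehr_out")) {
  if (!is.numeric(gate) || gate <= 0.5 || gate >= 1) {
    stop("configuration error: `gate` must lie in (0.5, 1)", call. = FALSE)
  }
  if (!is.numeric(n_resamples) || n_resamples < 1) {
    stop("configuration error: `n_resamples` must be >= 1", call. = FALSE)
  }
  if (is.null(code_sets) && !is.null(generator)) {
    code_sets <- lapply(generator$comorbidities, function(s) {
      code_set(s$name, s$code_prefixes)
    })
  }
  structure(list(input_dir = input_dir, generator = generator,
                 code_sets = code_sets,
                 exclusion_code_sets = exclusion_code_sets,
                 gate = gate, n_resamples = n_resamples,
                 window_days = window_days, age_range = age_range,
                 seed = seed, output_dir = output_dir),
            class = "pipeline_config")
}

#' Cut-point table across comorbidities
#'
#' One row per comorbidity: AUROC, Youden index, sensitivity, specificity
#' and cut point, with `NA` entries when the AUROC gate fails.
#'
#' @param cohort cohort data.frame.
#' @param comorbidities names (default: every `status_` column).
#' @param gate AUROC gate.
#' @return data.frame in the shape of a cut-points-by-comorbidity table.
#' @export
cutpoint_table <- function(cohort, comorbidities = NULL, gate = 0.6) {
  if (is.null(comorbidities)) {
    comorbidities <- sub("^status_", "",
                         grep("^status_", names(cohort), value = TRUE))
  }
  rows <- lapply(comorbidities, function(cm) {
    st <- as.character(cohort[[paste0("status_", cm)]])
    at_risk <- st != "prevalent"
    y <- as.integer(st[at_risk] == "incident")
    b <- cohort$baseline_bmi[at_risk]
    if (length(unique(y)) < 2L) {
      return(data.frame(comorbidity = cm, n_at_risk = length(y),
                        n_incident = sum(y), auroc = NA_real_,
                        defined = FALSE, youden = NA_real_,
                        sensitivity = NA_real_, specificity = NA_real_,
                        cutpoint = NA_real_, stringsAsFactors = FALSE))
    }
    core <- .cutpoint_core(b, y, gate = gate)
    data.frame(comorbidity = cm, n_at_risk = length(y), n_incident = sum(y),
               auroc = core$auroc, defined = core$defined,
               youden = core$youden, sensitivity = core$sensitivity,
               specificity = core$specificity, cutpoint = core$cutpoint,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Subgroup table with bootstrap p-values against a reference stratum
# (male vs female; each race/ethnicity vs White-NH).
.subgroup_table <- function(cohort, comorbidities, stratifier, ref_stratum,
                            gate, n_resamples, seed) {
  rows <- list()
  for (cm in comorbidities) {
    sg <- subgroup_cutpoints(cohort, cm, stratifier, gate = gate)
    st_col <- paste0("status_", cm)
    at_risk <- cohort[cohort[[st_col]] != "prevalent", , drop = FALSE]
    ref_def <- sg$defined[sg$stratum == ref_stratum]
    for (i in seq_len(nrow(sg))) {
      p <- NA_real_
      s <- sg$stratum[i]
      if (s != ref_stratum && isTRUE(sg$defined[i]) &&
          length(ref_def) == 1L && isTRUE(ref_def)) {
        sub_a <- at_risk[as.character(at_risk[[stratifier]]) == s, ]
        sub_b <- at_risk[as.character(at_risk[[stratifier]]) == ref_stratum, ]
        cmp <- bootstrap_compare_cutpoints(
          sub_a$baseline_bmi, as.integer(sub_a[[st_col]] == "incident"),
          sub_b$baseline_bmi, as.integer(sub_b[[st_col]] == "incident"),
          n_resamples = n_resamples, gate = gate,
          seed = (.str_hash(paste(cm, s)) + seed) %% 2147483647)
        p <- cmp$p_value
      }
      rows[[length(rows) + 1L]] <- cbind(sg[i, , drop = FALSE],
                                         p_vs_reference = p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Baseline characteristics by incident status
#'
#' For the at-risk set of one comorbidity, summarizes baseline
#' characteristics of patients who developed the disease within one year
#' versus those who did not: mean (SD) age and BMI, counts and percentages
#' of sex, race/ethnicity and smoking categories, and the prevalence of
#' the other comorbidities at the index visit.
#'
#' @param cohort cohort data.frame.
#' @param comorbidity comorbidity name.
#' @param require_cutpoint only produce the table when the comorbidity has
#'   a defined cut point (default), mirroring the analysis design.
#' @param gate AUROC gate used by `require_cutpoint`.
#' @return data.frame with columns `characteristic`, `level`,
#'   `incident_value`, `reference_value` (formatted summaries) plus
#'   numeric helper columns.
#' @export
baseline_comparison_table <- function(cohort, comorbidity,
                                      require_cutpoint = TRUE, gate = 0.6) {
  st_col <- paste0("status_", comorbidity)
  stopifnot(st_col %in% names(cohort))
  at_risk <- cohort[cohort[[st_col]] != "prevalent", , drop = FALSE]
  y <- at_risk[[st_col]] == "incident"
  if (require_cutpoint) {
    if (length(unique(y)) < 2L ||
        !.cutpoint_core(at_risk$baseline_bmi, as.integer(y),
                        gate = gate)$defined) {
      stop("no defined cut point for `", comorbidity,
           "`; set require_cutpoint = FALSE to force the table",
           call. = FALSE)
    }
  }
  grp <- list(incident = at_risk[y, , drop = FALSE],
              reference = at_risk[!y, , drop = FALSE])
  mean_sd <- function(x) {
    if (length(x) == 0L) return(NA_character_)
    sprintf("%.1f (%.1f)", mean(x), stats::sd(x))
  }
  n_pct <- function(f, lev) {
    if (length(f) == 0L) return(NA_character_)
    k <- sum(f == lev)
    sprintf("%d (%.1f%%)", k, 100 * k / length(f))
  }
  rows <- list(
    data.frame(characteristic = "n", level = "",
               incident_value = as.character(nrow(grp$incident)),
               reference_value = as.character(nrow(grp$reference))),
    data.frame(characteristic = "age, mean (SD)", level = "",
               incident_value = mean_sd(grp$incident$age_at_index),
               reference_value = mean_sd(grp$reference$age_at_index)),
    data.frame(characteristic = "BMI, mean (SD)", level = "",
               incident_value = mean_sd(grp$incident$baseline_bmi),
               reference_value = mean_sd(grp$reference$baseline_bmi))
  )
  for (col in c("sex", "race_ethnicity", "smoking")) {
    for (lev in sort(unique(as.character(at_risk[[col]])))) {
      rows[[length(rows) + 1L]] <- data.frame(
        characteristic = col, level = lev,
        incident_value = n_pct(as.character(grp$incident[[col]]), lev),
        reference_value = n_pct(as.character(grp$reference[[col]]), lev))
    }
  }
  others <- setdiff(sub("^status_", "",
                        grep("^status_", names(cohort), value = TRUE)),
                    comorbidity)
  for (cm in others) {
    oc <- paste0("status_", cm)
    rows[[length(rows) + 1L]] <- data.frame(
      characteristic = paste0("prevalent ", cm), level = "",
      incident_value = n_pct(as.character(grp$incident[[oc]]), "prevalent"),
      reference_value = n_pct(as.character(grp$reference[[oc]]), "prevalent"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Reads (or simulates) the input tables, builds the cohort, and writes
#' every output table as CSV plus a JSON manifest listing each file with
#' its row count and MD5 hash. Rerunning with the same configuration and
#' seed reproduces byte-identical files.
#'
#' Outputs: `cleaning_audit.csv`, `exclusion_audit.csv`, `cohort.csv`,
#' `incidence.csv`, `median_contrasts.csv`, `cutpoints.csv`,
#' `cutpoints_by_sex.csv`, `cutpoints_by_race.csv`,
#' `incidence_vs_prevalence.csv`, `rates_above_below.csv`, and
#' `baseline_<comorbidity>.csv` for each comorbidity with a defined cut
#' point.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage log lines (sent to `message()`).
#' @return invisibly, the manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  if (!is.null(config$input_dir)) {
    need <- file.path(config$input_dir,
                      c("visits.csv", "diagnoses.csv", "demographics.csv"))
    if (!all(file.exists(need))) {
      stop("missing input files: ",
           paste(need[!file.exists(need)], collapse = ", "), call. = FALSE)
    }
    visits <- read_visit_csv(need[1])
    diagnoses <- read_diagnosis_csv(need[2])
    demographics <- read_demographics_csv(need[3])
    reg_path <- file.path(config$input_dir, "registry_ids.csv")
    registry_ids <- if (file.exists(reg_path)) read_registry_csv(reg_path)
                    else character(0)
    say("read inputs from %s (%d visits)", config$input_dir, nrow(visits))
  } else {
    sim <- simulate_ehr(config$generator, seed = config$seed)
    visits <- sim$visits; diagnoses <- sim$diagnoses
    demographics <- sim$demographics; registry_ids <- sim$registry_ids
    say("simulated %d patients, %d visits", nrow(demographics), nrow(visits))
  }

  built <- build_cohort(visits, diagnoses, demographics, registry_ids,
                        code_sets = config$code_sets,
                        exclusion_code_sets = config$exclusion_code_sets,
                        seed = config$seed,
                        window_days = config$window_days,
                        age_range = config$age_range)
  cohort <- built$cohort
  say("cohort: %d rows (%d excluded) [%.1fs]", nrow(cohort),
      nrow(built$exclusion_audit), proc.time()[["elapsed"]] - t0)

  cms <- names(config$code_sets)
  inc_tab <- incidence_table(cohort, cms)
  contrasts <- do.call(rbind, lapply(cms, function(cm) {
    do.call(rbind, lapply(c(FALSE, TRUE), function(adj) {
      mc <- median_bmi_difference(cohort, cm, adjusted = adj,
                                  seed = config$seed,
                                  n_boot = config$n_resamples)
      data.frame(comorbidity = cm,
                 model = if (adj) "adjusted" else "unadjusted",
                 estimate = mc$estimate, ci_low = mc$ci_low,
                 ci_high = mc$ci_high, n_incident = mc$n_incident,
                 n_reference = mc$n_reference, stringsAsFactors = FALSE)
    }))
  }))
  say("median contrasts done [%.1fs]", proc.time()[["elapsed"]] - t0)

  cp_tab <- cutpoint_table(cohort, cms, gate = config$gate)
  by_sex <- .subgroup_table(cohort, cms, "sex", "female", config$gate,
                            config$n_resamples, config$seed)
  by_race <- .subgroup_table(cohort, cms, "race_ethnicity", "White-NH",
                             config$gate, config$n_resamples, config$seed)
  say("cut points done [%.1fs]", proc.time()[["elapsed"]] - t0)

  ivp <- list(); rab <- list(); baseline_files <- character(0)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cp_tab))) {
    cm <- cp_tab$comorbidity[i]
    if (!isTRUE(cp_tab$defined[i])) next
    rab[[cm]] <- cbind(comorbidity = cm,
                       rates_above_below(cohort, cm, cp_tab$cutpoint[i]))
    st_col <- paste0("status_", cm)
    st <- as.character(cohort[[st_col]])
    prev_fit <- tryCatch(prevalence_cutpoint(cohort, cm, gate = config$gate),
                         error = function(e) NULL)
    p <- NA_real_; prev_cut <- NA_real_
    if (!is.null(prev_fit) && prev_fit$defined) {
      prev_cut <- prev_fit$cutpoint
      at_risk <- st != "prevalent"
      cmp <- tryCatch(bootstrap_compare_cutpoints(
        cohort$baseline_bmi[at_risk],
        as.integer(st[at_risk] == "incident"),
        cohort$baseline_bmi, as.integer(st == "prevalent"),
        n_resamples = config$n_resamples, gate = config$gate,
        seed = (.str_hash(paste("ivp", cm)) + config$seed) %% 2147483647),
        error = function(e) NULL)
      if (!is.null(cmp)) p <- cmp$p_value
    }
    ivp[[cm]] <- data.frame(comorbidity = cm,
                            incidence_cutpoint = cp_tab$cutpoint[i],
                            prevalence_cutpoint = prev_cut,
                            p_value = p, stringsAsFactors = FALSE)
    bl <- baseline_comparison_table(cohort, cm, require_cutpoint = FALSE)
    f <- file.path(config$output_dir, paste0("baseline_", cm, ".csv"))
    .write_csv(bl, f)
    baseline_files <- c(baseline_files, f)
  }
  say("comparisons done [%.1fs]", proc.time()[["elapsed"]] - t0)

  files <- list(
    cleaning_audit = built$cleaning_audit,
    exclusion_audit = built$exclusion_audit,
    cohort = cohort,
    incidence = inc_tab,
    median_contrasts = contrasts,
    cutpoints = cp_tab,
    cutpoints_by_sex = by_sex,
    cutpoints_by_race = by_race,
    incidence_vs_prevalence = if (length(ivp)) do.call(rbind, ivp) else
      data.frame(comorbidity = character(0)),
    rates_above_below = if (length(rab)) do.call(rbind, rab) else
      data.frame(comorbidity = character(0))
  )
  paths <- character(0)
  for (nm in names(files)) {
    f <- file.path(config$output_dir, paste0(nm, ".csv"))
    .write_csv(files[[nm]], f)
    paths <- c(paths, f)
  }
  paths <- c(paths, baseline_files)
  manifest <- list(
    seed = config$seed, gate = config$gate,
    n_resamples = config$n_resamples,
    files = lapply(paths, function(f) {
      list(file = basename(f),
           rows = length(readLines(f)) - 1L,
           md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(config$output_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("wrote %d files to %s [%.1fs]", length(paths) + 1L,
      config$output_dir, proc.time()[["elapsed"]] - t0)
  invisible(manifest)
}
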