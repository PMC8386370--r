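# Prevalent / incident classification from dated diagnosis codes, and
# fixed-window one-year incidence rates.
#
# Conventions: the prevalence boundary is closed at the index date ("at or
# before"); the incidence window is half-open (index, index + 365 days].
# Every at-risk patient contributes exactly one person-year (the design
# guarantees a follow-up visit at least one year after index), so the rate
# per 100 person-years equals the one-year cumulative incidence times 100.

.WINDOW_DAYS <- 365

#' Construct a comorbidity code set
#'
#' A code set is a named list of ICD-9/ICD-10 code prefixes; `"E11"`
#' matches any code beginning `E11`. Prefixes are case-insensitive and
#' dot-insensitive (`"E11.9"` and `"E119"` are equivalent).
#'
#' @param name comorbidity name.
#' @param prefixes non-empty character vector of code prefixes.
#' @return object of class `"code_set"`.
#' @export
code_set <- function(name, prefixes) {
  prefixes <- normalize_code(prefixes)
  prefixes <- prefixes[nzchar(prefixes)]
  if (length(prefixes) == 0L) {
    stop("configuration error: code set `", name, "` has no prefixes",
         call. = FALSE)
  }
  structure(list(name = name, prefixes = prefixes), class = "code_set")
}

#' Read comorbidity code sets from YAML
#'
#' The file maps comorbidity names to lists of code prefixes:
#' `t2dm: ["E11", "250"]`.
#'
#' @param path YAML file path.
#' @return named list of [code_set()] objects.
#' @export
read_code_sets <- function(path) {
  raw <- yaml::read_yaml(path)
  stats::setNames(
    lapply(names(raw), function(nm) code_set(nm, unlist(raw[[nm]]))),
    names(raw)
  )
}

#' Match diagnosis codes against a code set
#'
#' @param codes character vector of ICD code strings.
#' @param set a [code_set()] (or bare character vector of prefixes).
#' @param exact match codes exactly instead of by prefix (default `FALSE`).
#' @return logical vector: which codes match.
#' @export
match_codes <- function(codes, set, exact = FALSE) {
  prefixes <- if (inherits(set, "code_set")) set$prefixes
              else normalize_code(set)
  codes <- normalize_code(codes)
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) {
    hit <- hit | if (exact) codes == p else startsWith(codes, p)
  }
  hit
}

#' Classify disease status relative to an index visit
#'
#' A patient is `prevalent` with any matching code dated at or before the
#' index date; otherwise `incident` with a matching code in the year
#' following the index date (half-open window `(index, index + 365]`);
#' otherwise `free`.
#'
#' @param dates diagnosis event dates for one patient (may be empty).
#' @param codes corresponding ICD code strings.
#' @param index_date the patient's index visit date.
#' @param set a [code_set()].
#' @param window_days incidence window length in days (default 365).
#' @param exact exact code matching instead of prefixes.
#' @return one of `"prevalent"`, `"incident"`, `"free"`.
#' @export
classify_disease_status <- function(dates, codes, index_date, set,
                                    window_days = .WINDOW_DAYS,
                                    exact = FALSE) {
  index_date <- .as_date(index_date)
  if (length(dates) == 0L) return("free")
  dates <- .as_date(dates)
  hit <- match_codes(codes, set, exact = exact)
  if (!any(hit)) return("free")
  first <- min(dates[hit])
  if (first <= index_date) "prevalent"
  else if (first <= index_date + window_days) "incident"
  else "free"
}

# Vectorized classification for a whole cohort: returns a character vector
# aligned with `index_dates` (named by patient id).
.classify_all <- function(diagnoses, patient_ids, index_dates, set,
                          window_days = .WINDOW_DAYS, exact = FALSE) {
  status <- rep("free", length(patient_ids))
  names(status) <- patient_ids
  if (nrow(diagnoses) == 0L) return(status)
  hit <- match_codes(diagnoses$code, set, exact = exact)
  d <- diagnoses[hit, , drop = FALSE]
  if (nrow(d) == 0L) return(status)
  first <- tapply(as.numeric(.as_date(d$date)), as.character(d$patient_id), min)
  idx <- match(names(first), patient_ids)
  ok <- !is.na(idx)
  first <- first[ok]; idx <- idx[ok]
  ref <- as.numeric(.as_date(index_dates))[idx]
  status[idx[first <= ref]] <- "prevalent"
  inc <- first > ref & first <= ref + window_days
  status[idx[inc]] <- "incident"
  status
}

#' One-year incidence rate per 100 person-years
#'
#' Removes prevalent cases from the chosen subset; each remaining (at-risk)
#' patient contributes one person-year, so the rate is
#' `100 * incident / at-risk`.
#'
#' @param cohort cohort data.frame with a `status_<comorbidity>` column.
#' @param comorbidity comorbidity name.
#' @param subset logical vector selecting cohort rows (default all).
#' @return object of class `"incidence_result"`: `comorbidity`,
#'   `n_at_risk`, `n_incident`, `rate` (`NA` when no patient is at risk).
#' @export
incidence_rate <- function(cohort, comorbidity, subset = NULL) {
  st_col <- paste0("status_", comorbidity)
  stopifnot(st_col %in% names(cohort))
  if (is.null(subset)) subset <- rep(TRUE, nrow(cohort))
  st <- as.character(cohort[[st_col]])[subset]
  at_risk <- st != "prevalent"
  n_at_risk <- sum(at_risk)
  n_incident <- sum(st == "incident")
  rate <- if (n_at_risk == 0L) NA_real_ else 100 * n_incident / n_at_risk
  structure(list(comorbidity = comorbidity, n_at_risk = n_at_risk,
                 n_incident = n_incident, rate = rate),
            class = "incidence_result")
}

#' @export
print.incidence_result <- function(x, ...) {
  cat(sprintf("%s: %d incident / %d at risk = %s per 100 person-years\n",
              x$comorbidity, x$n_incident, x$n_at_risk,
              if (is.na(x$rate)) "undefined" else sprintf("%.2f", x$rate)))
  invisible(x)
}

#' Incidence table across comorbidities
#'
#' @param cohort cohort data.frame.
#' @param comorbidities character vector of comorbidity names (defaults to
#'   every `status_` column).
#' @return data.frame: comorbidity, n at risk, n incident, rate per 100
#'   person-years.
#' @export
incidence_table <- function(cohort, comorbidities = NULL) {
  if (is.null(comorbidities)) {
    comorbidities <- sub("^status_", "",
                         grep("^status_", names(cohort), value = TRUE))
  }
  rows <- lapply(comorbidities, function(cm) {
    r <- incidence_rate(cohort, cm)
    data.frame(comorbidity = cm, n_at_risk = r$n_at_risk,
               n_incident = r$n_incident, rate_per_100py = r$rate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
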