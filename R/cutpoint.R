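# ROC / Youden cut-point estimation.
#
# BMI is treated as a screening test for one-year comorbidity incidence:
# a patient screens positive when BMI >= threshold. A comorbidity has a cut
# point only when the AUROC exceeds a discrimination gate (default 0.6,
# strict); the cut point is then the observed BMI value maximizing the
# Youden index J = sensitivity + specificity - 1, ties broken toward the
# smaller BMI (earlier screening).

#' Youden index
#'
#' `J = sensitivity + specificity - 1`: 0 for a chance-level test, 1 for a
#' perfect one.
#'
#' @param sensitivity,specificity fractions in `[0, 1]`.
#' @return numeric, the Youden index.
#' @examples
#' youden_index(0.72, 0.666)
#' @export
youden_index <- function(sensitivity, specificity) {
  if (any(is.na(sensitivity)) || any(is.na(specificity)) ||
      any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1)) {
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  }
  sensitivity + specificity - 1
}

.check_two_class <- function(label) {
  label <- as.integer(label)
  if (any(is.na(label)) || !all(label %in% c(0L, 1L))) {
    stop("labels must be binary 0/1 without missing values", call. = FALSE)
  }
  if (sum(label) == 0L || sum(label) == length(label)) {
    stop("both classes must be present: AUROC is undefined for a ",
         "single-class sample", call. = FALSE)
  }
  label
}

# Shared threshold sweep. Returns per-threshold sensitivity/specificity at
# the unique observed values (ascending), with -Inf/+Inf sentinels giving
# the (1,0) and (0,1) endpoints. O(n log n).
.roc_points <- function(bmi, label) {
  o <- order(bmi)
  b <- bmi[o]
  y <- label[o]
  n1 <- sum(y)
  n0 <- length(y) - n1
  new_val <- !duplicated(b)
  g <- cumsum(new_val)
  cases_g <- unname(rowsum(as.numeric(y), g, reorder = TRUE)[, 1])
  ctrls_g <- unname(rowsum(as.numeric(1 - y), g, reorder = TRUE)[, 1])
  u <- b[new_val]
  # at threshold u[k]: positives are BMI >= u[k]
  se <- (n1 - c(0, cumsum(cases_g))[seq_along(u)]) / n1
  sp <- c(0, cumsum(ctrls_g))[seq_along(u)] / n0
  list(
    thresholds = c(-Inf, u, Inf),
    sensitivity = c(1, se, 0),
    specificity = c(0, sp, 1),
    n_case = n1, n_control = n0
  )
}

#' ROC curve over observed BMI thresholds
#'
#' For each unique observed BMI value `t` (plus `-Inf`/`Inf` sentinels),
#' computes sensitivity `P(BMI >= t | case)` and specificity
#' `P(BMI < t | non-case)` for the screening rule "positive when
#' BMI >= t".
#'
#' @param bmi numeric vector of BMI values.
#' @param label binary vector (1 = incident case, 0 = reference).
#' @return object of class `"roc_points"`: a data.frame with columns
#'   `threshold`, `sensitivity`, `specificity`.
#' @export
roc_curve <- function(bmi, label) {
  label <- .check_two_class(label)
  stopifnot(length(bmi) == length(label), !any(is.na(bmi)))
  p <- .roc_points(bmi, label)
  out <- data.frame(threshold = p$thresholds, sensitivity = p$sensitivity,
                    specificity = p$specificity)
  class(out) <- c("roc_points", "data.frame")
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the curve of [roc_curve()]; equal to the
#' Mann-Whitney concordance `P(BMI_case > BMI_ref) + P(tie)/2`.
#'
#' @inheritParams roc_curve
#' @return AUROC as a fraction in `[0, 1]`.
#' @export
auroc <- function(bmi, label) {
  label <- .check_two_class(label)
  stopifnot(length(bmi) == length(label), !any(is.na(bmi)))
  p <- .roc_points(bmi, label)
  fpr <- 1 - p$specificity
  se <- p$sensitivity
  # thresholds ascend so (fpr, se) runs from (1,1) down to (0,0)
  sum((fpr[-length(fpr)] - fpr[-1]) * (se[-length(se)] + se[-1]) / 2)
}

# Rank-based AUROC (midranks give the ties-1/2 convention); used in the
# bootstrap loops where speed matters. Identical to auroc() by construction;
# the equality is exercised in the test suite.
.auroc_rank <- function(bmi, label) {
  n1 <- sum(label)
  n0 <- length(label) - n1
  r <- rank(bmi)
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Fast core: gate + Youden maximization over observed values. Returns a
# plain list; no validation (callers validate).
.cutpoint_core <- function(bmi, label, gate = 0.6) {
  a <- .auroc_rank(bmi, label)
  if (!(a > gate)) {
    return(list(auroc = a, defined = FALSE, cutpoint = NA_real_,
                youden = NA_real_, sensitivity = NA_real_,
                specificity = NA_real_))
  }
  p <- .roc_points(bmi, label)
  k <- seq(2L, length(p$thresholds) - 1L) # observed values only
  j <- p$sensitivity[k] + p$specificity[k] - 1
  best <- k[which.max(j)] # which.max takes the first maximum = smallest BMI
  list(auroc = a, defined = TRUE, cutpoint = p$thresholds[best],
       youden = p$sensitivity[best] + p$specificity[best] - 1,
       sensitivity = p$sensitivity[best], specificity = p$specificity[best])
}

#' Fit a BMI cut-point screening model
#'
#' The central estimator: computes the ROC curve and AUROC for BMI as a
#' screening test of a binary outcome, applies the AUROC gate (strictly
#' greater than `gate`; default 0.6), and, when the gate passes, returns
#' the observed BMI value maximizing the Youden index. When two thresholds
#' tie on the Youden index the smaller BMI is reported.
#'
#' @param bmi numeric vector of baseline BMI values, or a one-sided or
#'   two-sided formula `label ~ bmi` evaluated in `data`.
#' @param label binary outcome (1 = case); ignored when `bmi` is a formula.
#' @param data optional data.frame for the formula interface.
#' @param gate AUROC value that must be strictly exceeded for a cut point
#'   to be defined (default 0.6).
#' @param comorbidity optional label carried into printouts.
#' @param subset_label optional label for the subset analysed.
#' @return object of class `"cutpoint_fit"` with components `auroc`,
#'   `defined`, `cutpoint`, `youden`, `sensitivity`, `specificity`,
#'   `n_at_risk`, `n_incident`, `roc`, `gate`, `bmi`, `label`.
#' @examples
#' set.seed(1)
#' b <- c(rnorm(200, 27, 4), rnorm(50, 33, 4))
#' y <- rep(c(0, 1), c(200, 50))
#' fit <- cutpoint_model(b, y)
#' fit
#' coef(fit)
#' @export
cutpoint_model <- function(bmi, label = NULL, data = NULL, gate = 0.6,
                           comorbidity = NULL, subset_label = "all") {
  if (inherits(bmi, "formula")) {
    mf <- stats::model.frame(bmi, data = data, na.action = stats::na.omit)
    label <- mf[[1L]]
    bmi <- mf[[2L]]
  }
  if (!is.numeric(gate) || length(gate) != 1L || gate <= 0.5 || gate >= 1) {
    stop("`gate` must lie in (0.5, 1)", call. = FALSE)
  }
  keep <- !is.na(bmi) & !is.na(label)
  bmi <- as.numeric(bmi[keep])
  label <- .check_two_class(label[keep])
  core <- .cutpoint_core(bmi, label, gate = gate)
  fit <- c(core, list(
    n_at_risk = length(label),
    n_incident = sum(label),
    gate = gate,
    comorbidity = comorbidity,
    subset_label = subset_label,
    roc = roc_curve(bmi, label),
    bmi = bmi,
    label = label
  ))
  class(fit) <- "cutpoint_fit"
  fit
}

#' Find the BMI cut point for a case/reference sample
#'
#' Convenience wrapper around [cutpoint_model()] returning the same fitted
#' object.
#'
#' @inheritParams cutpoint_model
#' @return a `"cutpoint_fit"` object; see [cutpoint_model()].
#' @export
find_cutpoint <- function(bmi, label, gate = 0.6, comorbidity = NULL,
                          subset_label = "all") {
  cutpoint_model(bmi, label, gate = gate, comorbidity = comorbidity,
                 subset_label = subset_label)
}

#' @export
print.cutpoint_fit <- function(x, digits = 3, ...) {
  hdr <- if (is.null(x$comorbidity)) "BMI cut-point screening model"
         else paste0("BMI cut-point screening model: ", x$comorbidity)
  cat(hdr, " (subset: ", x$subset_label, ")\n", sep = "")
  cat(sprintf("  n at risk: %d, incident: %d\n", x$n_at_risk, x$n_incident))
  cat(sprintf("  AUROC: %.*f (gate > %.2f)\n", digits, x$auroc, x$gate))
  if (x$defined) {
    cat(sprintf("  cut point: %.*f kg/m^2\n", 1, x$cutpoint))
    cat(sprintf("  Youden J: %.*f (Se %.1f%%, Sp %.1f%%)\n", digits,
                x$youden, 100 * x$sensitivity, 100 * x$specificity))
  } else {
    cat("  cut point: not defined (AUROC below gate)\n")
  }
  invisible(x)
}

#' @export
summary.cutpoint_fit <- function(object, ...) {
  out <- data.frame(
    comorbidity = if (is.null(object$comorbidity)) NA_character_
                  else object$comorbidity,
    subset = object$subset_label,
    n_at_risk = object$n_at_risk,
    n_incident = object$n_incident,
    auroc = object$auroc,
    defined = object$defined,
    cutpoint = object$cutpoint,
    youden = object$youden,
    sensitivity = object$sensitivity,
    specificity = object$specificity,
    stringsAsFactors = FALSE
  )
  class(out) <- c("summary.cutpoint_fit", "data.frame")
  out
}

#' @export
print.summary.cutpoint_fit <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.cutpoint_fit <- function(object, ...) {
  c(cutpoint = object$cutpoint, auroc = object$auroc,
    youden = object$youden, sensitivity = object$sensitivity,
    specificity = object$specificity)
}

#' @export
predict.cutpoint_fit <- function(object, newdata = NULL, ...) {
  if (!object$defined) {
    stop("no cut point is defined for this fit (AUROC below gate)",
         call. = FALSE)
  }
  b <- if (is.null(newdata)) object$bmi
       else if (is.data.frame(newdata)) newdata$bmi
       else as.numeric(newdata)
  factor(ifelse(b >= object$cutpoint, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Plot a fitted cut-point model
#'
#' `type = "roc"` draws the ROC curve with the Youden-optimal operating
#' point; `type = "incidence"` draws empirical incidence against binned BMI
#' with the cut point marked.
#'
#' @param x a `"cutpoint_fit"` object.
#' @param type `"roc"` or `"incidence"`.
#' @param bin_width BMI bin width for `type = "incidence"` (kg/m^2).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.cutpoint_fit <- function(x, type = c("roc", "incidence"),
                              bin_width = 2, ...) {
  type <- match.arg(type)
  if (type == "roc") {
    graphics::plot(1 - x$roc$specificity, x$roc$sensitivity, type = "l",
                   xlab = "1 - specificity", ylab = "sensitivity",
                   main = sprintf("AUROC %.3f", x$auroc), ...)
    graphics::abline(0, 1, lty = 3)
    if (x$defined) {
      graphics::points(1 - x$specificity, x$sensitivity, pch = 19)
      graphics::text(1 - x$specificity, x$sensitivity,
                     sprintf("  cut %.1f", x$cutpoint), adj = 0)
    }
  } else {
    br <- seq(floor(min(x$bmi)), ceiling(max(x$bmi)) + bin_width, bin_width)
    bin <- cut(x$bmi, br, include.lowest = TRUE)
    inc <- tapply(x$label, bin, mean)
    mid <- (br[-1] + br[-length(br)]) / 2
    graphics::plot(mid, 100 * as.numeric(inc), type = "b",
                   xlab = "baseline BMI (kg/m^2)",
                   ylab = "incidence per 100 person-years", ...)
    if (x$defined) graphics::abline(v = x$cutpoint, lty = 2)
  }
  invisible(x)
}

#' Cut points within strata of a cohort
#'
#' Runs [cutpoint_model()] independently within each level of a
#' stratifying covariate (for example sex or race/ethnicity). Strata in
#' which the AUROC gate fails, or which lack incident cases or references
#' after removing prevalent patients, are reported as not defined with a
#' reason rather than dropped.
#'
#' @param cohort cohort data.frame (see [build_cohort()]).
#' @param comorbidity comorbidity name; `status_<comorbidity>` must be a
#'   column of `cohort`.
#' @param stratifier column name to stratify on, e.g. `"sex"` or
#'   `"race_ethnicity"`.
#' @param gate AUROC gate.
#' @return data.frame with one row per stratum: stratum label, counts,
#'   AUROC, defined flag, cut point, Youden, sensitivity, specificity,
#'   reason.
#' @export
subgroup_cutpoints <- function(cohort, comorbidity, stratifier, gate = 0.6) {
  stopifnot(stratifier %in% names(cohort))
  st_col <- paste0("status_", comorbidity)
  stopifnot(st_col %in% names(cohort))
  at_risk <- cohort[cohort[[st_col]] != "prevalent", , drop = FALSE]
  strata <- sort(unique(as.character(at_risk[[stratifier]])))
  rows <- lapply(strata, function(s) {
    sub <- at_risk[as.character(at_risk[[stratifier]]) == s, , drop = FALSE]
    y <- as.integer(sub[[st_col]] == "incident")
    base <- data.frame(stratum = s, n_at_risk = nrow(sub),
                       n_incident = sum(y), auroc = NA_real_,
                       defined = FALSE, cutpoint = NA_real_,
                       youden = NA_real_, sensitivity = NA_real_,
                       specificity = NA_real_, reason = "",
                       stringsAsFactors = FALSE)
    if (sum(y) == 0L || sum(y) == length(y)) {
      base$reason <- "single class"
      return(base)
    }
    core <- .cutpoint_core(sub$baseline_bmi, y, gate = gate)
    base$auroc <- core$auroc
    base$defined <- core$defined
    base$cutpoint <- core$cutpoint
    base$youden <- core$youden
    base$sensitivity <- core$sensitivity
    base$specificity <- core$specificity
    base$reason <- if (core$defined) "" else "AUROC below gate"
    base
  })
  out <- do.call(rbind, rows)
  out$comorbidity <- comorbidity
  out[, c("comorbidity", setdiff(names(out), "comorbidity"))]
}

#' Bootstrap comparison of two cut points
#'
#' Compares the cut points of two independent case/reference samples by
#' resampling patients with replacement in each sample, recomputing both
#' cut points per resample, and forming the difference `cut_a - cut_b`.
#' The two-sided p-value uses the add-one correction
#' `2 * min(count(d <= 0) + 1, count(d >= 0) + 1) / (B + 1)` over the `B`
#' usable resamples. Resamples in which either side fails the AUROC gate
#' (or loses a class) are redrawn up to `max_redraw` times and then counted
#' as missing with a warning.
#'
#' @param bmi_a,label_a sample A (BMI values, binary incident labels).
#' @param bmi_b,label_b sample B.
#' @param n_resamples number of bootstrap resamples (default 1000).
#' @param seed integer seed; the same seed reproduces the same p-value.
#' @param gate AUROC gate applied to every resample.
#' @param stratified resample within outcome classes (preserving class
#'   counts) instead of over all patients; default `FALSE`.
#' @param max_redraw redraw budget per resample before it is declared
#'   missing.
#' @return object of class `"cutpoint_boot"`: observed cut points, their
#'   difference, `p_value`, `n_resamples`, `n_missing`, the resampled
#'   differences, and the seed.
#' @export
bootstrap_compare_cutpoints <- function(bmi_a, label_a, bmi_b, label_b,
                                        n_resamples = 1000, seed = 1,
                                        gate = 0.6, stratified = FALSE,
                                        max_redraw = 20) {
  if (!is.numeric(n_resamples) || n_resamples < 1) {
    stop("`n_resamples` must be at least 1", call. = FALSE)
  }
  label_a <- .check_two_class(label_a)
  label_b <- .check_two_class(label_b)
  obs_a <- .cutpoint_core(bmi_a, label_a, gate = gate)
  obs_b <- .cutpoint_core(bmi_b, label_b, gate = gate)
  if (!obs_a$defined || !obs_b$defined) {
    stop("both samples must pass the AUROC gate on the observed data",
         call. = FALSE)
  }
  resample_cut <- function(b, y) {
    n <- length(y)
    for (try in seq_len(max_redraw + 1L)) {
      if (stratified) {
        i1 <- which(y == 1L); i0 <- which(y == 0L)
        idx <- c(sample(i1, length(i1), replace = TRUE),
                 sample(i0, length(i0), replace = TRUE))
      } else {
        idx <- sample.int(n, n, replace = TRUE)
      }
      yy <- y[idx]
      s <- sum(yy)
      if (s == 0L || s == n) next
      core <- .cutpoint_core(b[idx], yy, gate = gate)
      if (core$defined) return(core$cutpoint)
    }
    NA_real_
  }
  d <- .with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      ca <- resample_cut(bmi_a, label_a)
      cb <- resample_cut(bmi_b, label_b)
      ca - cb
    }, numeric(1))
  })
  n_missing <- sum(is.na(d))
  if (n_missing > 0) {
    warning(n_missing, " resample(s) failed the AUROC gate after redraws ",
            "and were counted as missing", call. = FALSE)
  }
  du <- d[!is.na(d)]
  B <- length(du)
  p <- if (B == 0L) NA_real_ else {
    min(1, 2 * min(sum(du <= 0) + 1, sum(du >= 0) + 1) / (B + 1))
  }
  out <- list(cutpoint_a = obs_a$cutpoint, cutpoint_b = obs_b$cutpoint,
              difference = obs_a$cutpoint - obs_b$cutpoint,
              p_value = p, n_resamples = as.integer(n_resamples),
              n_missing = n_missing, differences = d, seed = seed,
              gate = gate, stratified = stratified)
  class(out) <- "cutpoint_boot"
  out
}

#' @export
print.cutpoint_boot <- function(x, ...) {
  cat("Bootstrap comparison of BMI cut points\n")
  cat(sprintf("  cut point A: %.2f, cut point B: %.2f (difference %.2f)\n",
              x$cutpoint_a, x$cutpoint_b, x$difference))
  cat(sprintf("  two-sided p = %.4g (%d resamples, %d missing)\n",
              x$p_value, x$n_resamples, x$n_missing))
  invisible(x)
}

#' Prevalence-based cut point
#'
#' Re-runs the cut-point analysis with prevalent disease at the index
#' visit as the positive class and all non-prevalent cohort members
#' (including later incident cases) as the reference, using baseline BMI.
#'
#' @inheritParams subgroup_cutpoints
#' @return a `"cutpoint_fit"` object.
#' @export
prevalence_cutpoint <- function(cohort, comorbidity, gate = 0.6) {
  st_col <- paste0("status_", comorbidity)
  stopifnot(st_col %in% names(cohort))
  y <- as.integer(cohort[[st_col]] == "prevalent")
  cutpoint_model(cohort$baseline_bmi, y, gate = gate,
                 comorbidity = comorbidity, subset_label = "prevalence")
}

#' One-year incidence above and below a cut point
#'
#' Splits the at-risk cohort at the cut point (below: BMI < cut point;
#' above: BMI >= cut point) and computes the one-year incidence per 100
#' person-years in each stratum.
#'
#' @inheritParams subgroup_cutpoints
#' @param cutpoint BMI threshold in kg/m^2; must be defined (non-missing).
#' @return data.frame with rows `below` and `above`: n at risk, incident
#'   count and rate per 100 person-years (`NA` rate for an empty stratum).
#' @export
rates_above_below <- function(cohort, comorbidity, cutpoint) {
  if (is.null(cutpoint) || is.na(cutpoint)) {
    stop("cut point is not defined", call. = FALSE)
  }
  below <- incidence_rate(cohort, comorbidity,
                          subset = cohort$baseline_bmi < cutpoint)
  above <- incidence_rate(cohort, comorbidity,
                          subset = cohort$baseline_bmi >= cutpoint)
  data.frame(
    stratum = c("below", "above"),
    cutpoint = cutpoint,
    n_at_risk = c(below$n_at_risk, above$n_at_risk),
    n_incident = c(below$n_incident, above$n_incident),
    rate_per_100py = c(below$rate, above$rate),
    stringsAsFactors = FALSE
  )
}
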