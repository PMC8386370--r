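# Longitudinal anthropometric cleaning.
#
# Recorded heights and weights in EHRs carry data-entry errors (unit
# confusion, transposed digits). Cleaning is per patient and single pass:
# absolute plausibility bounds first, then dispersion rules computed once on
# the survivors of the absolute bounds. Patients are never dropped, only
# individual measurements.

.H_MAX <- 90   # inches
.H_MIN <- 44
.W_MAX <- 1000 # pounds
.W_MIN <- 55

#' Clean one patient's height series
#'
#' Flags biologically implausible heights. Heights above 90 or below 44
#' inches are removed on absolute bounds. On the surviving values the
#' per-patient mean and sample SD are computed once; when the SD exceeds
#' 2.5% of the mean, values more than 1 SD from the mean are removed.
#' The pass is single: the dispersion statistics are not recomputed after
#' removals. Missing values pass through unflagged (they are handled by
#' [impute_heights()]).
#'
#' @param height numeric vector of recorded heights in inches for a single
#'   patient, in visit order; may contain `NA`.
#' @return data.frame with columns `height`, `valid` (logical; `NA` for
#'   missing input) and `reason` (one of `"none"`, `"abs_bound_high"`,
#'   `"abs_bound_low"`, `"sd_rule"`).
#' @seealso [clean_weights()], [impute_heights()]
#' @examples
#' clean_heights(c(95, 70, 70))   # 95 removed on the absolute bound
#' clean_heights(c(60, 70, 70, 70)) # 60 removed by the SD rule
#' @export
clean_heights <- function(height) {
  height <- as.numeric(height)
  if (any(!is.na(height) & height <= 0)) {
    stop("malformed input: heights must be positive", call. = FALSE)
  }
  n <- length(height)
  reason <- rep("none", n)
  reason[!is.na(height) & height > .H_MAX] <- "abs_bound_high"
  reason[!is.na(height) & height < .H_MIN] <- "abs_bound_low"
  surv <- !is.na(height) & reason == "none"
  if (sum(surv) >= 2L) {
    m <- mean(height[surv])
    s <- stats::sd(height[surv])
    if (s > 0.025 * m) {
      reason[surv & abs(height - m) > s] <- "sd_rule"
    }
  }
  valid <- ifelse(is.na(height), NA, reason == "none")
  data.frame(height = height, valid = valid, reason = reason,
             stringsAsFactors = FALSE)
}

#' Clean one patient's weight series
#'
#' Weights above 1000 or below 55 pounds are removed on absolute bounds.
#' On the survivors the per-patient mean, range and sample SD are computed
#' once: when the range is at least 50 pounds, values more than 70% of the
#' range from the mean are removed (`range_rule`); when the SD exceeds 20%
#' of the mean, values more than 1 SD from the mean are removed
#' (`sd_rule`). A value failing both conditional rules is attributed to the
#' range rule. Single pass, strict inequalities: a value exactly at a rule
#' boundary is kept.
#'
#' @param weight numeric vector of recorded weights in pounds for a single
#'   patient, in visit order; may contain `NA`.
#' @return data.frame with columns `weight`, `valid`, `reason` (one of
#'   `"none"`, `"abs_bound_high"`, `"abs_bound_low"`, `"range_rule"`,
#'   `"sd_rule"`).
#' @examples
#' clean_weights(c(1200, 180))          # 1200 removed on the absolute bound
#' clean_weights(c(150, 150, 150, 400)) # 400 removed by the range rule
#' @export
clean_weights <- function(weight) {
  weight <- as.numeric(weight)
  if (any(!is.na(weight) & weight <= 0)) {
    stop("malformed input: weights must be positive", call. = FALSE)
  }
  n <- length(weight)
  reason <- rep("none", n)
  reason[!is.na(weight) & weight > .W_MAX] <- "abs_bound_high"
  reason[!is.na(weight) & weight < .W_MIN] <- "abs_bound_low"
  surv <- !is.na(weight) & reason == "none"
  if (sum(surv) >= 2L) {
    w <- weight[surv]
    m <- mean(w)
    rng <- max(w) - min(w)
    s <- stats::sd(w)
    bad_sd <- if (s > 0.20 * m) abs(weight - m) > s else rep(FALSE, n)
    bad_rng <- if (rng >= 50) abs(weight - m) > 0.70 * rng else rep(FALSE, n)
    reason[surv & bad_sd] <- "sd_rule"
    reason[surv & bad_rng] <- "range_rule" # range rule reported when both fire
  }
  valid <- ifelse(is.na(weight), NA, reason == "none")
  data.frame(weight = weight, valid = valid, reason = reason,
             stringsAsFactors = FALSE)
}

#' Impute missing heights within one patient
#'
#' Missing (or invalid) heights are filled with the most recent previous
#' valid height; any still missing are filled with the most recent
#' subsequent valid height. Patients with no valid height at all keep
#' missing values. Records must be in date order.
#'
#' @param height numeric vector of heights in inches, date-ordered.
#' @param valid logical vector: which entries are valid measurements
#'   (defaults to non-missing entries of `height`).
#' @return data.frame with columns `height` (filled), `imputed` (logical).
#' @export
impute_heights <- function(height, valid = !is.na(height)) {
  height <- as.numeric(height)
  n <- length(height)
  valid <- !is.na(valid) & valid & !is.na(height)
  out <- ifelse(valid, height, NA_real_)
  if (n == 0L || !any(valid)) {
    return(data.frame(height = out, imputed = rep(FALSE, n)))
  }
  idx <- seq_len(n)
  filled <- out
  # forward fill: last valid index at or before each position (0 = none yet)
  last <- cummax(ifelse(valid, idx, 0L))
  need <- !valid & last > 0L
  filled[need] <- height[last[need]]
  # backward fill for positions before the first valid measurement
  nxt <- rev(cummin(rev(ifelse(valid, idx, n + 1L))))
  need_b <- is.na(filled) & nxt <= n
  filled[need_b] <- height[nxt[need_b]]
  data.frame(height = filled, imputed = !valid & !is.na(filled))
}

#' Body mass index from imperial units
#'
#' BMI in kg/m^2 from height in inches and weight in pounds:
#' `703 * weight / height^2`. Missing inputs yield missing BMI.
#'
#' @param height numeric, inches.
#' @param weight numeric, pounds.
#' @return numeric vector of BMI values.
#' @examples
#' compute_bmi(70, 180) # 25.82449
#' @export
compute_bmi <- function(height, weight) {
  height <- as.numeric(height)
  weight <- as.numeric(weight)
  if (any(!is.na(height) & height <= 0) || any(!is.na(weight) & weight <= 0)) {
    stop("malformed input: heights and weights must be positive", call. = FALSE)
  }
  703 * weight / height^2
}

# Vectorized group machinery for clean_visits(): identical rules to the
# per-patient functions above, applied across contiguous integer group ids
# without per-group R calls. The equivalence is asserted in the test suite.

.gsum <- function(x, gi, ng) {
  out <- numeric(ng)
  if (length(x)) {
    t <- rowsum(x, gi)
    out[as.integer(rownames(t))] <- t[, 1]
  }
  out
}

.clean_heights_vec <- function(h, gi, ng) {
  reason <- rep("none", length(h))
  nonmiss <- !is.na(h)
  reason[nonmiss & h > .H_MAX] <- "abs_bound_high"
  reason[nonmiss & h < .H_MIN] <- "abs_bound_low"
  surv <- nonmiss & reason == "none"
  cnt <- tabulate(gi[surv], ng)
  m <- .gsum(h[surv], gi[surv], ng) / pmax(cnt, 1)
  ss <- .gsum((h[surv] - m[gi[surv]])^2, gi[surv], ng)
  sd_g <- sqrt(ss / pmax(cnt - 1, 1))
  fire <- cnt >= 2 & sd_g > 0.025 * m
  flag <- surv & fire[gi] & abs(h - m[gi]) > sd_g[gi]
  reason[flag] <- "sd_rule"
  list(valid = ifelse(nonmiss, reason == "none", NA), reason = reason)
}

.clean_weights_vec <- function(w, gi, ng) {
  reason <- rep("none", length(w))
  nonmiss <- !is.na(w)
  reason[nonmiss & w > .W_MAX] <- "abs_bound_high"
  reason[nonmiss & w < .W_MIN] <- "abs_bound_low"
  surv <- nonmiss & reason == "none"
  cnt <- tabulate(gi[surv], ng)
  m <- .gsum(w[surv], gi[surv], ng) / pmax(cnt, 1)
  ss <- .gsum((w[surv] - m[gi[surv]])^2, gi[surv], ng)
  sd_g <- sqrt(ss / pmax(cnt - 1, 1))
  # group min/max of survivors via one sort
  gmin <- rep(Inf, ng); gmax <- rep(-Inf, ng)
  sel <- which(surv)
  if (length(sel)) {
    o <- sel[order(gi[sel], w[sel])]
    gs <- gi[o]
    f <- !duplicated(gs)
    l <- rev(!duplicated(rev(gs)))
    gmin[gs[f]] <- w[o[f]]
    gmax[gs[l]] <- w[o[l]]
  }
  rng <- gmax - gmin
  fire_sd <- cnt >= 2 & sd_g > 0.20 * m
  fire_rng <- cnt >= 2 & rng >= 50
  dev <- abs(w - m[gi])
  reason[surv & fire_sd[gi] & dev > sd_g[gi]] <- "sd_rule"
  reason[surv & fire_rng[gi] & dev > 0.70 * rng[gi]] <- "range_rule"
  list(valid = ifelse(nonmiss, reason == "none", NA), reason = reason)
}

# LOCF-then-NOCB over contiguous groups in one pass.
.impute_heights_vec <- function(h, valid, gi) {
  n <- length(h)
  idx <- seq_len(n)
  valid <- !is.na(valid) & valid & !is.na(h)
  filled <- ifelse(valid, h, NA_real_)
  if (n == 0L) return(list(height = filled, imputed = logical(0)))
  gstart <- idx[!duplicated(gi)][gi]
  gend <- rev(rev(idx)[!duplicated(rev(gi))])[gi]
  last <- cummax(ifelse(valid, idx, 0L))
  f_ok <- !valid & last >= gstart
  filled[f_ok] <- h[last[f_ok]]
  nxt <- rev(cummin(rev(ifelse(valid, idx, n + 1L))))
  b_ok <- is.na(filled) & nxt <= gend
  filled[b_ok] <- h[nxt[b_ok]]
  list(height = filled, imputed = !valid & !is.na(filled))
}

#' Clean a visit table and compute BMI
#'
#' Applies [clean_heights()] and [clean_weights()] within each patient,
#' imputes missing heights per [impute_heights()], and computes BMI where a
#' valid-or-imputed height and a valid weight coexist. No patient is ever
#' removed: cleaning acts on measurements only.
#'
#' @param visits data.frame with columns `patient_id`, `date`, `height`
#'   (inches, may be `NA`), `weight` (pounds, may be `NA`).
#' @return list with `visits`: the input rows (sorted by patient and date)
#'   plus `height_valid`, `weight_valid`, `height_imputed`, `height_used`,
#'   `bmi` columns; and `audit`: one row per removed measurement
#'   (`patient_id`, `date`, `field`, `value`, `removal_reason`).
#' @export
clean_visits <- function(visits) {
  stopifnot(all(c("patient_id", "date", "height", "weight") %in% names(visits)))
  visits$date <- .as_date(visits$date)
  ord <- order(visits$patient_id, visits$date)
  v <- visits[ord, , drop = FALSE]
  rownames(v) <- NULL
  if (nrow(v) == 0L) {
    v$height_valid <- logical(0); v$weight_valid <- logical(0)
    v$height_imputed <- logical(0); v$height_used <- numeric(0)
    v$bmi <- numeric(0)
    audit <- data.frame(patient_id = character(0), date = as.Date(character(0)),
                        field = character(0), value = numeric(0),
                        removal_reason = character(0))
    return(list(visits = v, audit = audit))
  }
  id <- as.character(v$patient_id)
  if (any(!is.na(v$height) & v$height <= 0) ||
      any(!is.na(v$weight) & v$weight <= 0)) {
    stop("malformed input: heights and weights must be positive",
         call. = FALSE)
  }
  gi <- cumsum(!duplicated(id)) # contiguous after the (id, date) sort
  ng <- gi[length(gi)]
  ch <- .clean_heights_vec(v$height, gi, ng)
  cw <- .clean_weights_vec(v$weight, gi, ng)
  imp <- .impute_heights_vec(v$height, ch$valid, gi)
  hreason <- ch$reason
  wreason <- cw$reason
  wv <- cw$valid
  v$height_valid <- ch$valid
  v$weight_valid <- wv
  v$height_imputed <- imp$imputed
  v$height_used <- imp$height
  hused <- imp$height
  wt <- ifelse(!is.na(wv) & wv, v$weight, NA_real_)
  v$bmi <- ifelse(!is.na(hused) & !is.na(wt), 703 * wt / hused^2, NA_real_)

  rem_h <- which(hreason != "none")
  rem_w <- which(wreason != "none")
  audit <- rbind(
    data.frame(patient_id = id[rem_h], date = v$date[rem_h],
               field = rep("height", length(rem_h)),
               value = v$height[rem_h], removal_reason = hreason[rem_h],
               stringsAsFactors = FALSE),
    data.frame(patient_id = id[rem_w], date = v$date[rem_w],
               field = rep("weight", length(rem_w)),
               value = v$weight[rem_w], removal_reason = wreason[rem_w],
               stringsAsFactors = FALSE)
  )
  rownames(audit) <- NULL
  list(visits = v, audit = audit)
}
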