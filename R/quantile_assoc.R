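# Median (tau = 0.5) quantile regression and incident-vs-reference median
# BMI contrasts.
#
# The fitter minimizes the check loss sum_i rho_0.5(y_i - x_i' beta),
# rho_0.5(u) = |u| / 2, by iteratively reweighted least squares on a
# smoothed |u|, followed, for small problems, by an exact vertex-polishing
# step: an optimum of the check loss is attained at a coefficient vector
# interpolating p observations, so the best-fitting p-subsets among the
# smallest IRLS residuals are solved exactly and the loss-minimizing vertex
# returned. Tie rule: the first vertex (in index order) attaining the
# minimal loss.

.check_loss <- function(r, tau = 0.5) {
  sum(r * (tau - (r < 0)))
}

#' Median regression by check-loss minimization
#'
#' Fits `y = X beta + e` at the median (tau = 0.5). The design must
#' include an intercept column and be of full column rank.
#'
#' @param y numeric response.
#' @param X design matrix (with intercept column).
#' @param tol IRLS convergence tolerance on the coefficient change.
#' @param max_iter IRLS iteration cap.
#' @param polish enumerate exact vertex solutions near the IRLS optimum;
#'   by default only for small problems (`n <= 2000`, `p <= 6`).
#' @return object of class `"median_fit"`: `coefficients`, `fitted.values`,
#'   `residuals`, `loss` (the minimized check loss).
#' @examples
#' fit_median_regression(c(1, 2, 9), cbind(1, c(0, 0, 0)))
#' @export
fit_median_regression <- function(y, X, tol = 1e-10, max_iter = 200,
                                  polish = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n)
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    bad <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1L, p)]]
    if (is.null(bad)) bad <- paste("column", qr_x$pivot[seq(qr_x$rank + 1L, p)])
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(polish)) polish <- (n <= 2000 && p <= 6)

  beta <- qr.coef(qr_x, y)
  eps <- 1e-8
  for (it in seq_len(max_iter)) {
    r <- y - X %*% beta
    w <- 1 / pmax(abs(r), eps)
    fit <- stats::lm.wfit(X, y, as.numeric(w))
    new_beta <- fit$coefficients
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  beta <- as.numeric(beta)
  best_loss <- .check_loss(y - X %*% beta)

  if (polish && n >= p) {
    r <- abs(y - X %*% beta)
    m <- min(n, 2L * p + 6L)
    cand <- order(r)[seq_len(m)]
    subsets <- utils::combn(cand, p)
    for (j in seq_len(ncol(subsets))) {
      ix <- subsets[, j]
      Xi <- X[ix, , drop = FALSE]
      qi <- qr(Xi)
      if (qi$rank < p) next
      b <- qr.coef(qi, y[ix])
      loss <- .check_loss(y - X %*% b)
      if (loss < best_loss - 1e-12) {
        best_loss <- loss
        beta <- as.numeric(b)
      }
    }
  }
  names(beta) <- colnames(X)
  fitted <- as.numeric(X %*% beta)
  structure(list(coefficients = beta, fitted.values = fitted,
                 residuals = y - fitted, loss = .check_loss(y - fitted),
                 n = n, p = p),
            class = "median_fit")
}

#' @export
print.median_fit <- function(x, digits = 5, ...) {
  cat("Median (tau = 0.5) regression, n =", x$n, "\n")
  print(round(x$coefficients, digits))
  cat("check loss:", format(x$loss, digits = digits), "\n")
  invisible(x)
}

#' @export
coef.median_fit <- function(object, ...) object$coefficients

#' @export
residuals.median_fit <- function(object, ...) object$residuals

# Reference-coded model matrix for the adjusted contrast. Reference
# levels: female sex, White-NH race/ethnicity, non-smoker.
.adjusted_design <- function(df) {
  sex <- factor(df$sex, levels = c("female", "male"))
  race_lv <- c("White-NH", "Black-NH", "Asian-NH", "Native-American-NH",
               "Hispanic", "other/unspecified")
  race <- factor(df$race_ethnicity,
                 levels = c(race_lv, setdiff(unique(df$race_ethnicity),
                                             race_lv)))
  race <- droplevels(race)
  smoke <- factor(df$smoking, levels = c("non", "active", "former",
                                         "passive"))
  smoke <- droplevels(smoke)
  mm <- stats::model.matrix(
    ~ incident + age + sex + race + smoke,
    data = data.frame(incident = df$incident, age = df$age_at_index,
                      sex = sex, race = race, smoke = smoke))
  # drop constant indicator columns (single-level factors after droplevels
  # never reach here, but guard against all-equal covariates)
  keep <- c(TRUE, apply(mm[, -1, drop = FALSE], 2,
                        function(cc) stats::var(cc) > 0))
  mm[, keep, drop = FALSE]
}

#' Median BMI contrast between incident and reference patients
#'
#' The analysis set is the cohort minus prevalent cases of the
#' comorbidity. Unadjusted, the estimate is the median baseline BMI of
#' incident cases minus the median of patients who did not develop the
#' disease (an algebraic identity of the two-group median regression).
#' Adjusted, it is the incidence-indicator coefficient of a median
#' regression with age (linear), sex, race/ethnicity and smoking status as
#' reference-coded covariates. The 95% CI is a seeded percentile bootstrap
#' over patients.
#'
#' @param cohort cohort data.frame (see [build_cohort()]).
#' @param comorbidity comorbidity name.
#' @param adjusted fit the covariate-adjusted model.
#' @param seed integer seed for the bootstrap.
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level.
#' @return object of class `"median_contrast"`: `estimate`, `ci_low`,
#'   `ci_high`, `n_incident`, `n_reference`, `adjusted`, `comorbidity`.
#' @export
median_bmi_difference <- function(cohort, comorbidity, adjusted = FALSE,
                                  seed = 1, n_boot = 1000, conf = 0.95) {
  st_col <- paste0("status_", comorbidity)
  stopifnot(st_col %in% names(cohort))
  df <- cohort[cohort[[st_col]] != "prevalent", , drop = FALSE]
  df$incident <- as.integer(df[[st_col]] == "incident")
  n1 <- sum(df$incident)
  n0 <- sum(df$incident == 0L)
  if (n1 == 0L || n0 == 0L) {
    out <- list(comorbidity = comorbidity, adjusted = adjusted,
                estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n_incident = n1, n_reference = n0, defined = FALSE)
    class(out) <- "median_contrast"
    return(out)
  }
  est_fun <- if (!adjusted) {
    function(d) stats::median(d$baseline_bmi[d$incident == 1L]) -
      stats::median(d$baseline_bmi[d$incident == 0L])
  } else {
    function(d) {
      mm <- .adjusted_design(d)
      fit <- fit_median_regression(d$baseline_bmi, mm, polish = FALSE)
      unname(fit$coefficients[colnames(mm) == "incident"])
    }
  }
  est <- est_fun(df)
  boots <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      d <- df[sample.int(nrow(df), nrow(df), replace = TRUE), , drop = FALSE]
      if (sum(d$incident) == 0L || sum(d$incident) == nrow(d)) {
        return(NA_real_)
      }
      est_fun(d)
    }, numeric(1))
  })
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  out <- list(comorbidity = comorbidity, adjusted = adjusted,
              estimate = est, ci_low = qs[1], ci_high = qs[2],
              n_incident = n1, n_reference = n0, defined = TRUE,
              n_boot = n_boot, seed = seed)
  class(out) <- "median_contrast"
  out
}

#' @export
print.median_contrast <- function(x, ...) {
  cat(sprintf("Median BMI difference (%s, %s): ", x$comorbidity,
              if (x$adjusted) "adjusted" else "unadjusted"))
  if (!isTRUE(x$defined)) {
    cat("undefined (empty incident or reference group)\n")
  } else {
    cat(sprintf("%.2f kg/m^2 (95%% CI %.2f to %.2f); n=%d vs %d\n",
                x$estimate, x$ci_low, x$ci_high, x$n_incident,
                x$n_reference))
  }
  invisible(x)
}
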