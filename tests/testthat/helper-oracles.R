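# Independent brute-force oracles and small fixtures used across tests.

# O(n^2) pairwise-concordance AUROC with ties counted 1/2.
oracle_auroc <- function(bmi, label) {
  b1 <- bmi[label == 1]
  b0 <- bmi[label == 0]
  tot <- 0
  for (x in b1) tot <- tot + sum(x > b0) + 0.5 * sum(x == b0)
  tot / (length(b1) * length(b0))
}

# Exhaustive threshold enumeration of sensitivity/specificity for the
# screening rule "positive when bmi >= t".
oracle_roc <- function(bmi, label, thresholds) {
  b1 <- bmi[label == 1]
  b0 <- bmi[label == 0]
  data.frame(
    threshold = thresholds,
    sensitivity = vapply(thresholds, function(t) mean(b1 >= t), numeric(1)),
    specificity = vapply(thresholds, function(t) mean(b0 < t), numeric(1))
  )
}

# Exact check-loss minimum by full enumeration of p-point interpolating
# vertex solutions (an optimum of the tau = 0.5 check loss is attained at
# one of them).
oracle_median_loss <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  loss <- function(b) sum(abs(y - X %*% b)) / 2
  best <- Inf
  for (ix in utils::combn(n, p, simplify = FALSE)) {
    Xi <- X[ix, , drop = FALSE]
    if (qr(Xi)$rank < p) next
    b <- qr.coef(qr(Xi), y[ix])
    best <- min(best, loss(b))
  }
  best
}

# Small cohort-shaped data frame for contrast / cut-point level tests.
make_toy_cohort <- function(n1, n0, bmi1, bmi0, status_name = "t2dm",
                            seed = 42) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  withr_seed({
    n <- n1 + n0
    df <- data.frame(
      patient_id = sprintf("T%04d", seq_len(n)),
      index_date = as.Date("2012-01-01"),
      baseline_bmi = c(bmi1, bmi0),
      sex = sample(c("female", "male"), n, replace = TRUE),
      race_ethnicity = sample(c("White-NH", "Black-NH", "Asian-NH"), n,
                              replace = TRUE, prob = c(0.8, 0.1, 0.1)),
      insurance = "commercial",
      smoking = sample(c("non", "active", "former"), n, replace = TRUE),
      age_at_index = round(runif(n, 25, 70), 1),
      stringsAsFactors = FALSE
    )
    df[[paste0("status_", status_name)]] <- rep(c("incident", "free"),
                                                c(n1, n0))
    df
  })
}
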