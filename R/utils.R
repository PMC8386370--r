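# Internal helpers: seeded substreams, code normalization, small checks.

# 31-bit polynomial string hash (Lehmer-mixed). Multipliers are small
# enough that every product stays below 2^53, keeping double arithmetic
# exact; result is in [0, 2^31 - 1).
.str_hash <- function(x) {
  m <- 2147483647 # 2^31 - 1
  vapply(x, function(s) {
    h <- 40503
    for (code in utf8ToInt(as.character(s))) {
      h <- (h * 69621 + code) %% m
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Deterministic uniform in (0,1) for a (seed, key) pair, independent of the
# global RNG state. One splitmix-style scrambling round on top of the string
# hash; used for per-patient decisions so results do not depend on row order.
.substream_unif <- function(seed, key) {
  m <- 2147483647
  h <- (.str_hash(key) + (as.numeric(seed) %% m) * 48271) %% m
  h <- (h * 69621 + 1013904223) %% m
  h <- (h * 40692 + 12345) %% m
  (h + 0.5) / m
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. The seed argument is forced before the
# caller's state is saved: a seed drawn from the global RNG must advance
# that RNG, not be rolled back with the restore.
.with_seed <- function(seed, expr) {
  seed <- as.integer(as.numeric(seed) %% 2147483647)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Normalize an ICD code or code prefix
#'
#' Uppercases and removes dots so that dotted and undotted spellings of the
#' same code ("E11.9" and "E119") compare equal.
#'
#' @param x character vector of codes or prefixes.
#' @return character vector of normalized codes.
#' @export
normalize_code <- function(x) {
  gsub(".", "", toupper(trimws(as.character(x))), fixed = TRUE)
}

.assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop("configuration error: `", name, "` must be a probability in [0, 1]",
         call. = FALSE)
  }
  invisible(x)
}

.as_date <- function(x) {
  if (inherits(x, "Date")) x else as.Date(x)
}

# Per-group means/SDs/etc. for a numeric vector split by a grouping id,
# returned aligned to the elements of x. split() is C-level and fast enough
# for the table sizes this package targets.
.grp_apply <- function(x, g, fun) {
  g <- as.character(g)
  res <- vapply(split(x, g), fun, numeric(1))
  res[g]
}
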