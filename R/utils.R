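# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never disturb the
# session RNG.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic per-stage seed derived from a master seed and a stage name,
# kept below 2^31 so it is always a valid R integer.
derive_seed <- function(master_seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 48271 + h) %% 2147483563) + 1L
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    abort(sprintf("`%s` must be supplied", name))
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  }
  if (integer && x != round(x)) {
    abort(sprintf("`%s` must be a whole number, got %s", name, x))
  }
  invisible(x)
}

# Lower-triangle vector of a symmetric matrix (used by Mantel machinery).
lower_vec <- function(m) m[lower.tri(m)]

is_symmetric_zero_diag <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m)), na.rm = TRUE) <= tol &&
    all(abs(diag(m)) <= tol, na.rm = TRUE)
}
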