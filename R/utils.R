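# Internal validation helpers. Errors always name the offending field so CLI
# users see which config key to fix.

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, lower = -Inf, upper = Inf,
                         integer = FALSE, closed_lower = TRUE,
                         closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (integer && x != round(x))
    stop_field(field, "must be an integer")
  ok_lo <- if (closed_lower) x >= lower else x > lower
  ok_hi <- if (closed_upper) x <= upper else x < upper
  if (!ok_lo || !ok_hi) {
    lo <- if (closed_lower) "[" else "("
    hi <- if (closed_upper) "]" else ")"
    stop_field(field, sprintf("must lie in %s%g, %g%s, got %g",
                              lo, lower, upper, hi, x))
  }
  if (integer) as.integer(x) else as.numeric(x)
}

check_prob_vector <- function(p, field, tol = 1e-12) {
  if (!is.numeric(p) || length(p) < 1L || anyNA(p))
    stop_field(field, "must be a numeric vector without NA")
  if (any(p < 0))
    stop_field(field, "entries must be non-negative")
  if (abs(sum(p) - 1) > tol)
    stop_field(field, sprintf("must sum to 1 within %g (sum = %.15g)",
                              tol, sum(p)))
  stats::setNames(as.numeric(p), names(p))
}

# One global seed feeds named substreams so that adding a module or
# reordering evaluations does not perturb the draws of another module.
# Substream seeds are derived by hashing (seed, label) into [0, 2^31).
substream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(paste0(label, ":", seed))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
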