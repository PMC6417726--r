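# internal validation helpers -------------------------------------------------

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) abort(sprintf(msg, ...), class = "beecuticle_error")
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  stop_if_not(is.numeric(x) && length(x) == 1L && is.finite(x),
              "`%s` must be a single finite number", name)
  stop_if_not(x >= min && x <= max,
              "`%s` must be in [%s, %s], got %s", name, min, max, x)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_number(x, name, min = min)
  stop_if_not(x == as.integer(x), "`%s` must be a whole number", name)
  as.integer(x)
}

# run `expr` under `seed` without disturbing the caller's RNG state
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# derive a reproducible child seed (kept well below .Machine$integer.max)
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 48271L + k * 1009L) %% 2147483562L
}
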