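#' @keywords internal
"_PACKAGE"

# Seed derivation: every stochastic stage takes a seed derived from the master
# seed through this mixer, so one integer reproduces a whole experiment.
# Lehmer-style multiplicative mixing modulo the Mersenne prime 2^31 - 1;
# results stay in [1, 2^31 - 2] and are valid set.seed() inputs.
derive_seed <- function(seed, ...) {
  salts <- c(...)
  x <- (abs(as.numeric(seed)) %% 2147483647)
  if (x == 0) x <- 1
  for (s in salts) {
    x <- (x * 48271 + abs(as.numeric(s)) + 1) %% 2147483647
    if (x == 0) x <- 1
  }
  as.integer(x)
}

# Run an expression under a locally set RNG seed without clobbering the
# caller's RNG state. seed = NULL uses the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_if_not_count <- function(x, name, zero_ok = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != round(x) ||
      x < if (zero_ok) 0 else 1) {
    stop(sprintf("`%s` must be a single %s integer", name,
                 if (zero_ok) "non-negative" else "positive"), call. = FALSE)
  }
  invisible(as.integer(x))
}

check_probs <- function(p, name, n = NULL, tol = 1e-9) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0)) {
    stop(sprintf("`%s` must be non-negative probabilities", name),
         call. = FALSE)
  }
  if (!is.null(n) && length(p) != n) {
    stop(sprintf("`%s` must have length %d", name, n), call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("`%s` must sum to 1 (got %.12f)", name, sum(p)),
         call. = FALSE)
  }
  invisible(p)
}
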