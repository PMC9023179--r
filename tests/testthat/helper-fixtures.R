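# Shared fixtures, all generated in code under fixed seeds.

make_view <- function(n, seed = 1, system = "surgery", effect_size = 1.5,
                      ...) {
  cohort <- generate_cohort(cohort_spec(n_cases = n, seed = seed,
                                        effect_size = effect_size, ...))
  system_view(cohort, system)
}

# Independent brute-force oracle for the balancing multiple: argmin over
# positive integers of |m * n_i - n_max|, ties resolved to the larger m.
brute_force_multiple <- function(n_i, n_max, m_max = n_max + 1) {
  errs <- abs(seq_len(m_max) * n_i - n_max)
  max(which(errs == min(errs)))
}

# A small linearly separable encoded fixture: class-conditional means on a
# 4-point grid, tight noise.
tiny_encoded <- function(n = 200, d = 24, seed = 42, sep = 1) {
  set.seed(seed)
  cls <- sample.int(4, n, replace = TRUE)
  x <- matrix(stats::rnorm(n * d, sd = 0.05), n, d) +
    outer(cls, rep(1, d)) * sep / 10
  encoded_dataset(x, cls)
}

# A view with exact per-class record counts (for balancing arithmetic):
# overwrites durations so the surgery classes tabulate as requested.
view_with_class_counts <- function(counts, seed = 9) {
  stopifnot(length(counts) == 4)
  v <- make_view(sum(counts), seed = seed)
  mids <- c(30, 90, 150, 210)
  v$duration_minutes <- rep(mids, counts)
  v
}
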