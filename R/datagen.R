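# Synthetic perioperative cohorts.
#
# No public perioperative dataset with this attribute set exists, so the
# package ships a seeded generator that emulates the statistical structure the
# pipeline assumes: 24 preoperative attributes (patient physiology, ASA class,
# anesthesia type, clinician title/seniority/age, surgical grade), an
# imbalanced 4-class surgery-duration outcome, and an anesthesia-emergence
# duration that depends stochastically and monotonically on the surgery
# duration class.

# Physiological reference ranges (adult, resting) used as truncation bounds
# for the continuous attributes. Units follow common Chinese hospital lab
# conventions (HB g/L, PLT 10^9/L, electrolytes mmol/L, times in seconds).
periop_ranges <- function() {
  list(
    bmi         = c(15,   40),
    sbp         = c(90,  180),
    dbp         = c(50,  110),
    pr          = c(50,  120),
    rr          = c(10,   30),
    temperature = c(35.8, 37.8),
    rbc         = c(3.0,  6.5),
    hb          = c(90,  175),
    hct         = c(0.28, 0.54),
    plt         = c(80,  450),
    k           = c(3.0,  5.8),
    na          = c(130, 152),
    cl          = c(95,  112),
    aptt        = c(20,   45),
    pt          = c(9,    15),
    tt          = c(13,   22)
  )
}

# Default conditional law of the emergence class given the surgery class.
# Rows are surgery classes 1..4, columns emergence classes 1..4. The row means
# increase with the surgery class (stochastic monotonicity), reflecting that
# longer surgeries under general anesthesia take longer to emerge from.
default_emergence_dependence <- function() {
  m <- rbind(
    c(0.900, 0.080, 0.015, 0.005),
    c(0.060, 0.880, 0.050, 0.010),
    c(0.010, 0.060, 0.880, 0.050),
    c(0.005, 0.015, 0.080, 0.900)
  )
  dimnames(m) <- list(surgery = 1:4, emergence = 1:4)
  m
}

#' Specification of a synthetic perioperative cohort
#'
#' Bundles and validates the parameters of [generate_cohort()]. The defaults
#' describe a deliberately imbalanced cohort (most surgeries finish within two
#' hours) with a moderate class signal in the continuous physiology
#' attributes, so that the balancing stage of the preprocessing algorithm is
#' exercised non-trivially.
#'
#' @param n_cases Number of cases to generate (non-negative integer).
#' @param class_probs Length-4 probability vector over surgery-duration
#'   classes 1–4 (1 = up to 1 h, ..., 4 = 3–4 h). Must sum to 1 within `1e-9`.
#' @param effect_size Separation, in within-class standard deviations, between
#'   the class-conditional means of adjacent surgery classes for the 16
#'   continuous physiology attributes. `0` removes the signal entirely.
#' @param emergence_dependence 4 x 4 row-stochastic matrix; row `i` is the
#'   distribution of the emergence class given surgery class `i`.
#' @param grade_concordance Probability that the recorded surgical grade (A24
#'   of the surgery system) equals the surgery-duration class; otherwise it is
#'   drawn uniformly. Grade is the strongest single predictor in practice.
#' @param seed Integer seed; identical specs generate identical cohorts.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [system_view()]
#' @export
#' @examples
#' spec <- cohort_spec(n_cases = 100, seed = 7)
#' cohort <- generate_cohort(spec)
#' table(bin_duration(cohort$surgery_minutes, surgery_bins()))
cohort_spec <- function(n_cases = 2000,
                        class_probs = c(0.40, 0.30, 0.20, 0.10),
                        effect_size = 1.5,
                        emergence_dependence = default_emergence_dependence(),
                        grade_concordance = 0.8,
                        seed = 1L) {
  stop_if_not_count(n_cases, "n_cases", zero_ok = TRUE)
  check_probs(class_probs, "class_probs", n = 4)
  if (!is.numeric(effect_size) || length(effect_size) != 1 ||
      is.na(effect_size) || effect_size < 0) {
    stop("`effect_size` must be a single non-negative number", call. = FALSE)
  }
  if (!is.matrix(emergence_dependence) ||
      !all(dim(emergence_dependence) == c(4, 4))) {
    stop("`emergence_dependence` must be a 4 x 4 matrix", call. = FALSE)
  }
  for (i in 1:4) check_probs(emergence_dependence[i, ],
                             sprintf("emergence_dependence[%d, ]", i))
  if (grade_concordance < 0 || grade_concordance > 1) {
    stop("`grade_concordance` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_cases = as.integer(n_cases),
         class_probs = as.numeric(class_probs),
         effect_size = as.numeric(effect_size),
         emergence_dependence = emergence_dependence,
         grade_concordance = grade_concordance,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Truncated-normal draws by inverse-CDF; exact, vectorised and seedable.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  pmin(pmax(stats::qnorm(u, mean, sd), lo), hi)
}

#' Generate a synthetic perioperative cohort
#'
#' Draws `spec$n_cases` cases. The surgery-duration class is sampled from
#' `spec$class_probs`; continuous physiology attributes are truncated normals
#' whose class-conditional means are shifted by `effect_size` within-class
#' standard deviations per class step; the emergence class is drawn from
#' `spec$emergence_dependence` conditioned on the surgery class. Durations are
#' emitted in minutes (surgery in (0, 240], emergence in (0, 60]); binning
#' them into classes is the preprocessing stage's job.
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame` of class `periop_cohort`, one row per case, with a
#'   `case_id` column, the shared attribute columns, `surgery_minutes` and
#'   `emergence_minutes`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    stop("`spec` must be a cohort_spec", call. = FALSE)
  }
  n <- spec$n_cases
  ranges <- periop_ranges()
  empty <- function() numeric(0)
  if (n == 0) {
    cols <- c("case_id", "gender", names(ranges), "heart_class", "asa",
              "anesthesia_binary", "anesthesia_general", "title", "seniority",
              "clinician_age", "surgical_grade", "surgery_minutes",
              "emergence_minutes")
    out <- as.data.frame(stats::setNames(rep(list(empty()), length(cols)),
                                         cols))
    class(out) <- c("periop_cohort", class(out))
    return(out)
  }

  with_seed(spec$seed, {
    z <- sample.int(4, n, replace = TRUE, prob = spec$class_probs)

    cont <- lapply(names(ranges), function(a) {
      r <- ranges[[a]]
      mid <- mean(r)
      # sd chosen as 1/20 of the reference range so that class shifts of up to
      # +/- 1.5 * effect_size sd stay well inside the truncation bounds.
      sd <- diff(r) / 20
      mu <- mid + spec$effect_size * sd * (z - 2.5)
      rtruncnorm(n, mu, sd, r[1], r[2])
    })
    names(cont) <- names(ranges)

    gender <- sample.int(2, n, replace = TRUE)
    heart_class <- sample.int(3, n, replace = TRUE, prob = c(0.70, 0.25, 0.05))
    asa <- sample.int(3, n, replace = TRUE, prob = c(0.45, 0.45, 0.10))
    anesthesia_binary <- sample.int(2, n, replace = TRUE, prob = c(0.3, 0.7))
    anesthesia_general <- sample.int(4, n, replace = TRUE,
                                     prob = c(0.40, 0.35, 0.15, 0.10))
    title <- sample.int(4, n, replace = TRUE, prob = c(0.25, 0.35, 0.25, 0.15))
    seniority <- pmax(1, pmin(38, round(title * 7 + stats::rnorm(n, 0, 3))))
    clinician_age <- pmax(27, pmin(65, round(24 + seniority +
                                               stats::rnorm(n, 0, 2))))

    concordant <- stats::runif(n) < spec$grade_concordance
    surgical_grade <- ifelse(concordant, z, sample.int(4, n, replace = TRUE))

    s_edges <- surgery_bins()$edges
    surgery_minutes <- stats::runif(n, s_edges[z] + 0.5, s_edges[z + 1])

    e <- vapply(z, function(zi) {
      sample.int(4, 1, prob = spec$emergence_dependence[zi, ])
    }, integer(1))
    e_edges <- emergence_bins()$edges
    emergence_minutes <- stats::runif(n, e_edges[e] + 0.25, e_edges[e + 1])

    out <- data.frame(case_id = seq_len(n), gender = gender,
                      cont, heart_class = heart_class, asa = asa,
                      anesthesia_binary = anesthesia_binary,
                      anesthesia_general = anesthesia_general,
                      title = title, seniority = seniority,
                      clinician_age = clinician_age,
                      surgical_grade = surgical_grade,
                      surgery_minutes = surgery_minutes,
                      emergence_minutes = emergence_minutes)
    class(out) <- c("periop_cohort", class(out))
    out
  })
}

#' Extract the 24-attribute view of one prediction system
#'
#' The surgery and emergence systems share attributes A1–A19 and A21–A23 but
#' differ in A20 and A24: the surgery system uses the binary local/general
#' anesthesia type and the surgical grade, while the emergence system uses the
#' 4-level general-anesthesia subtype and the (true) surgery-duration class
#' obtained by binning `surgery_minutes`.
#'
#' @param cohort A `periop_cohort` from [generate_cohort()].
#' @param system `"surgery"` or `"emergence"`.
#' @return A `data.frame` with columns `case_id`, `A1`..`A24` (numeric codes)
#'   and `duration_minutes` (the system's outcome, in minutes).
#' @export
system_view <- function(cohort, system = c("surgery", "emergence")) {
  system <- match.arg(system)
  shared <- c("gender", "bmi", "sbp", "dbp", "pr", "rr", "temperature",
              "heart_class", "rbc", "hb", "hct", "plt", "k", "na", "cl",
              "aptt", "pt", "tt", "asa")
  x <- cohort[, shared, drop = FALSE]
  if (system == "surgery") {
    x$a20 <- cohort$anesthesia_binary
    a24 <- cohort$surgical_grade
    outcome <- cohort$surgery_minutes
  } else {
    x$a20 <- cohort$anesthesia_general
    a24 <- if (nrow(cohort) > 0) {
      bin_duration(cohort$surgery_minutes, surgery_bins())
    } else integer(0)
    outcome <- cohort$emergence_minutes
  }
  x$title <- cohort$title
  x$seniority <- cohort$seniority
  x$clinician_age <- cohort$clinician_age
  x$a24 <- a24
  names(x) <- paste0("A", seq_len(24))
  cbind(data.frame(case_id = cohort$case_id), x,
        data.frame(duration_minutes = outcome))
}

#' Worked-example category counts for the balancing rule
#'
#' The fixture used throughout the documentation and tests of the automatic
#' balancing rule: category 1 holds 60 records, category 2 holds 30, and the
#' largest category holds 100. Feeding it to [build_balance_plan()] yields
#' replication multiples (2, 3, 1).
#'
#' @return A [category_counts()] object with `n_i = c(60, 30, 100)`.
#' @export
#' @examples
#' build_balance_plan(worked_example_counts())
worked_example_counts <- function() {
  category_counts(c(`1` = 60L, `2` = 30L, `3` = 100L))
}

#' Write or read a cohort as CSV
#'
#' @param cohort A `periop_cohort`.
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly; `read_cohort_csv()`
#'   returns a `periop_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("periop_cohort", class(out))
  out
}
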