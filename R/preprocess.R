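# Intelligent data preprocessing: cleaning, min-max normalization to
# [0.1, 0.9], duration binning into 4 classes, one-hot output coding,
# automatic class balancing by integer replication, bounded-noise
# augmentation, and the 60/20/20 partition.

#' Duration binning schemes
#'
#' Right-closed interval edges, in minutes, for the two prediction targets.
#' Surgery durations are binned hourly up to 4 h; emergence durations into
#' up-to-15, 15–40, 40–50 and 50–60 minute classes. Exactly 60 minutes of
#' surgery falls in class 1 ("up to one hour"); the right-closed convention
#' is applied uniformly.
#'
#' @return A `binning_scheme`: list with `edges` (length 5, strictly
#'   increasing, first element 0), `cap` (the last edge) and `labels`.
#' @export
#' @examples
#' bin_duration(c(30, 60, 61, 240), surgery_bins())
surgery_bins <- function() {
  structure(list(edges = c(0, 60, 120, 180, 240), cap = 240,
                 labels = c("<=1h", "1-2h", "2-3h", "3-4h")),
            class = "binning_scheme")
}

#' @rdname surgery_bins
#' @export
emergence_bins <- function() {
  structure(list(edges = c(0, 15, 40, 50, 60), cap = 60,
                 labels = c("<=15min", "15-40min", "40-50min", "50-60min")),
            class = "binning_scheme")
}

#' Bin durations into 4 ordered classes
#'
#' @param minutes Numeric vector of durations, each in `(0, cap]`.
#' @param scheme A [surgery_bins()] or [emergence_bins()] scheme.
#' @return Integer class indices in 1..4.
#' @export
bin_duration <- function(minutes, scheme) {
  if (!inherits(scheme, "binning_scheme")) {
    stop("`scheme` must be a binning_scheme", call. = FALSE)
  }
  if (length(minutes) == 0) return(integer(0))
  if (any(!is.finite(minutes)) || any(minutes <= 0) ||
      any(minutes > scheme$cap)) {
    stop(sprintf("durations must lie in (0, %g]; run clean() first",
                 scheme$cap), call. = FALSE)
  }
  findInterval(minutes, scheme$edges, left.open = TRUE)
}

#' Clean a system view of raw records
#'
#' Inspection and exclusion, the first stage of the preprocessing algorithm:
#' drops records whose categorical attributes fall outside their declared
#' level sets, whose continuous attributes are non-finite, or whose outcome
#' duration is outside `(0, cap)` for the system (surgeries lasting 4 h or
#' more, emergences of 1 h or more). An interquartile-range outlier rule on
#' the continuous attributes is available but off by default, since only the
#' duration caps are prescriptive.
#'
#' @param view A system view from [system_view()] (columns `A1`..`A24`,
#'   `duration_minutes`).
#' @param system `"surgery"` or `"emergence"` (sets the duration cap and the
#'   A20 level set).
#' @param iqr_rule If `TRUE`, additionally exclude records with any continuous
#'   attribute outside `[Q1 - k IQR, Q3 + k IQR]`.
#' @param iqr_k Multiplier for the IQR rule (default 3, a conservative fence).
#' @return A list with `records` (the retained rows), `n_removed`, and
#'   `removed_by_rule` (named integer vector of per-rule removal counts; a
#'   record failing several rules is counted under each).
#' @export
clean <- function(view, system = c("surgery", "emergence"),
                  iqr_rule = FALSE, iqr_k = 3) {
  system <- match.arg(system)
  req <- c("case_id", paste0("A", 1:24), "duration_minutes")
  missing_cols <- setdiff(req, names(view))
  if (length(missing_cols) > 0) {
    stop("view is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cap <- if (system == "surgery") 240 else 60
  a20_levels <- if (system == "surgery") 1:2 else 1:4
  level_sets <- list(A1 = 1:2, A8 = 1:3, A19 = 1:3, A20 = a20_levels,
                     A21 = 1:4, A24 = 1:4)
  cont_cols <- paste0("A", c(2:7, 9:18, 22, 23))

  n <- nrow(view)
  if (n == 0) {
    return(list(records = view, n_removed = 0L,
                removed_by_rule = c(level_set = 0L, non_finite = 0L,
                                    duration_cap = 0L, iqr_outlier = 0L)))
  }

  bad_level <- rep(FALSE, n)
  for (a in names(level_sets)) {
    bad_level <- bad_level | !(view[[a]] %in% level_sets[[a]])
  }
  bad_finite <- rowSums(!is.finite(as.matrix(view[, cont_cols]))) > 0
  d <- view$duration_minutes
  bad_duration <- !is.finite(d) | d <= 0 | d >= cap

  bad_iqr <- rep(FALSE, n)
  if (iqr_rule) {
    for (a in cont_cols) {
      q <- stats::quantile(view[[a]], c(0.25, 0.75), na.rm = TRUE)
      iqr <- q[2] - q[1]
      bad_iqr <- bad_iqr |
        (view[[a]] < q[1] - iqr_k * iqr | view[[a]] > q[2] + iqr_k * iqr)
    }
  }

  drop <- bad_level | bad_finite | bad_duration | bad_iqr
  list(records = view[!drop, , drop = FALSE],
       n_removed = sum(drop),
       removed_by_rule = c(level_set = sum(bad_level),
                           non_finite = sum(bad_finite),
                           duration_cap = sum(bad_duration),
                           iqr_outlier = sum(bad_iqr)))
}

#' Fit and apply min-max normalization to \[0.1, 0.9\]
#'
#' Every attribute (categorical codes included) is mapped affinely so that the
#' minimum observed on the fitting set lands on 0.1 and the maximum on 0.9:
#' `x -> 0.1 + 0.8 (x - min) / (max - min)`. A constant attribute maps to the
#' interval midpoint 0.5. Values outside the fitted range map outside
#' \[0.1, 0.9\]; no clipping is applied.
#'
#' @param x A numeric `data.frame`/matrix of attributes (rows = records).
#' @return `fit_normalization()` returns a `normalization_params` object;
#'   `apply_normalization()` and `invert_normalization()` return matrices.
#' @export
#' @examples
#' p <- fit_normalization(data.frame(a = c(0, 5, 10)))
#' apply_normalization(data.frame(a = c(0, 5, 10)), p)
fit_normalization <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("cannot fit normalization on 0 records",
                         call. = FALSE)
  if (!is.numeric(x)) stop("attributes must be numeric", call. = FALSE)
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max),
                 lo = 0.1, hi = 0.9),
            class = "normalization_params")
}

#' @rdname fit_normalization
#' @param params A fitted `normalization_params` object.
#' @export
apply_normalization <- function(x, params) {
  x <- as.matrix(x)
  if (!all(colnames(x) %in% names(params$min))) {
    stop("attributes absent from normalization params: ",
         paste(setdiff(colnames(x), names(params$min)), collapse = ", "),
         call. = FALSE)
  }
  mn <- params$min[colnames(x)]
  mx <- params$max[colnames(x)]
  rng <- mx - mn
  out <- sweep(sweep(x, 2, mn, "-"), 2, ifelse(rng == 0, 1, rng), "/")
  out <- params$lo + (params$hi - params$lo) * out
  # a constant attribute carries no information; park it at the midpoint
  if (any(rng == 0)) {
    out[, rng == 0] <- (params$lo + params$hi) / 2
  }
  out
}

#' @rdname fit_normalization
#' @export
invert_normalization <- function(x, params) {
  x <- as.matrix(x)
  mn <- params$min[colnames(x)]
  mx <- params$max[colnames(x)]
  rng <- mx - mn
  out <- sweep(sweep(x, 2, params$lo, "-") / (params$hi - params$lo),
               2, rng, "*")
  sweep(out, 2, mn, "+")
}

#' One-hot output coding
#'
#' Duration classes are coded as 4-bit rows 1000, 0100, 0010, 0001; the
#' position of the 1 is the class index.
#'
#' @param idx Integer class indices in 1..4.
#' @param y A one-hot matrix (rows with exactly one 1).
#' @return `one_hot()` an `n x 4` 0/1 matrix; `un_hot()` integer indices.
#' @export
#' @examples
#' one_hot(c(1, 4))
#' un_hot(one_hot(1:4))
one_hot <- function(idx) {
  if (length(idx) > 0 &&
      (any(is.na(idx)) || any(idx != round(idx)) || any(idx < 1 | idx > 4))) {
    stop("class indices must be integers in 1..4", call. = FALSE)
  }
  y <- matrix(0L, nrow = length(idx), ncol = 4)
  y[cbind(seq_along(idx), as.integer(idx))] <- 1L
  y
}

#' @rdname one_hot
#' @export
un_hot <- function(y) {
  y <- as.matrix(y)
  if (ncol(y) != 4 || any(!(y %in% c(0, 1))) || any(rowSums(y) != 1)) {
    stop("`y` must be a matrix of 4-bit rows with exactly one 1",
         call. = FALSE)
  }
  max.col(y, ties.method = "first")
}

#' Per-class record counts
#'
#' @param x Either a named vector of per-class counts, or an integer vector of
#'   class labels to tabulate.
#' @param tabulate If `TRUE`, treat `x` as class labels and count them.
#' @return A `category_counts` object: list with `n_i` (named counts) and
#'   `n_max`.
#' @export
category_counts <- function(x, tabulate = FALSE) {
  if (tabulate) {
    n_i <- table(factor(x, levels = sort(unique(x))))
    n_i <- stats::setNames(as.integer(n_i), names(n_i))
  } else {
    if (any(x < 0) || any(x != round(x))) {
      stop("counts must be non-negative integers", call. = FALSE)
    }
    n_i <- stats::setNames(as.integer(x),
                           if (is.null(names(x))) seq_along(x) else names(x))
  }
  structure(list(n_i = n_i, n_max = max(n_i)), class = "category_counts")
}

#' Automatic replication multiple for class balancing
#'
#' The balancing rule assigns a minority class of size `n_i` the integer
#' replication multiple `m = (k - 1)/2` whose bracket
#' `2 n_max / (k - 2) >= n_i > 2 n_max / k` (k odd) contains `n_i` — the
#' multiple that brings `m * n_i` closest to the majority size `n_max`.
#' An exact tie `|m n_i - n_max| = |(m+1) n_i - n_max|` resolves to the
#' larger multiple, as forced by the interval bounds. The largest class
#' always gets `m = 1`.
#'
#' @param n_i Class size(s), `1 <= n_i <= n_max` (vectorised).
#' @param n_max Size of the largest class.
#' @return Integer multiple(s) `m >= 1`.
#' @export
#' @examples
#' compute_balance_multiple(60, 100)  # 2: 120 is closer to 100 than 60 is
#' compute_balance_multiple(30, 100)  # 3: 90 beats 120
compute_balance_multiple <- function(n_i, n_max) {
  if (length(n_max) != 1 || n_max < 1 || n_max != round(n_max)) {
    stop("`n_max` must be a single positive integer", call. = FALSE)
  }
  if (length(n_i) == 0) return(integer(0))
  if (any(n_i != round(n_i)) || any(n_i < 1) || any(n_i > n_max)) {
    stop("`n_i` must satisfy 1 <= n_i <= n_max", call. = FALSE)
  }
  # smallest m with n_i > 2 n_max / (2m + 1), in exact integer arithmetic:
  # m > (2 n_max - n_i) / (2 n_i)
  as.integer((2 * n_max - n_i) %/% (2 * n_i) + 1)
}

#' Build and apply a balancing plan
#'
#' `build_balance_plan()` computes a replication multiple per class from its
#' counts; `apply_balance()` duplicates every record of class `i` so that it
#' appears `m_i` times (the `m_i - 1` copies are exact and tagged
#' `"balanced-replica"`). Noise is *not* added here; balancing and noise
#' enhancement are separate stages. A class with zero records is skipped with
#' a warning (its multiple is undefined).
#'
#' @param counts A [category_counts()] object.
#' @return A `balance_plan`: list with `m_i` (named multiples) and the counts.
#' @export
#' @examples
#' plan <- build_balance_plan(worked_example_counts())
#' plan$m_i                       # 2, 3, 1
#' plan$m_i * worked_example_counts()$n_i  # balanced sizes 120, 90, 100
build_balance_plan <- function(counts) {
  if (!inherits(counts, "category_counts")) {
    stop("`counts` must be a category_counts object", call. = FALSE)
  }
  m <- rep(1L, length(counts$n_i))
  names(m) <- names(counts$n_i)
  nonzero <- counts$n_i > 0
  if (any(!nonzero)) {
    warning("class(es) with zero records skipped: ",
            paste(names(counts$n_i)[!nonzero], collapse = ", "))
  }
  m[nonzero] <- compute_balance_multiple(counts$n_i[nonzero], counts$n_max)
  structure(list(m_i = m, counts = counts), class = "balance_plan")
}

#' @rdname build_balance_plan
#' @param dataset An [encoded_dataset()].
#' @param plan A `balance_plan` built from this dataset's class counts.
#' @export
apply_balance <- function(dataset, plan) {
  stopifnot(inherits(dataset, "encoded_dataset"),
            inherits(plan, "balance_plan"))
  classes <- as.integer(names(plan$m_i))
  extra <- integer(0)
  for (j in seq_along(classes)) {
    reps <- plan$m_i[j] - 1L
    if (reps > 0) {
      extra <- c(extra, rep(which(dataset$class == classes[j]), reps))
    }
  }
  if (length(extra) == 0) return(dataset)
  encoded_dataset(
    x = rbind(dataset$x, dataset$x[extra, , drop = FALSE]),
    class = c(dataset$class, dataset$class[extra]),
    provenance = c(dataset$provenance, rep("balanced-replica", length(extra)))
  )
}

#' Augmentation settings
#'
#' @param multiple Total enrichment multiple `M >= 1`: the augmented set holds
#'   the originals plus `M - 1` noisy copies of each record. The pipeline uses
#'   `M = 3` for architecture screening and `M = 10` for the final models.
#' @param noise Half-width of the uniform input noise (default 0.03, on the
#'   normalized \[0.1, 0.9\] scale).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return An `augmentation_config` object.
#' @export
augmentation_config <- function(multiple = 3, noise = 0.03, seed = NULL) {
  stop_if_not_count(multiple, "multiple")
  if (noise < 0) stop("`noise` must be non-negative", call. = FALSE)
  structure(list(multiple = as.integer(multiple), noise = noise, seed = seed),
            class = "augmentation_config")
}

#' Enrich a dataset with bounded-noise copies
#'
#' Generates new samples by adding independent uniform noise on
#' `[-noise, +noise]` to every input cell of `multiple - 1` copies of each
#' record, keeping the output class unchanged. Inputs are expected to be
#' normalized already; noisy values are not clipped.
#'
#' @param dataset An [encoded_dataset()].
#' @param config An [augmentation_config()].
#' @return An enlarged `encoded_dataset` with the copies tagged `"augmented"`.
#' @export
augment <- function(dataset, config) {
  stopifnot(inherits(dataset, "encoded_dataset"),
            inherits(config, "augmentation_config"))
  m <- config$multiple
  if (m == 1) return(dataset)
  n <- nrow(dataset$x)
  with_seed(config$seed, {
    idx <- rep(seq_len(n), m - 1L)
    noisy <- dataset$x[idx, , drop = FALSE] +
      matrix(stats::runif(length(idx) * ncol(dataset$x),
                          -config$noise, config$noise),
             nrow = length(idx))
    encoded_dataset(
      x = rbind(dataset$x, noisy),
      class = c(dataset$class, dataset$class[idx]),
      provenance = c(dataset$provenance, rep("augmented", length(idx)))
    )
  })
}

#' Split settings for the train/test/validation partition
#'
#' @param ratios Length-3 positive vector `(train, test, validation)` summing
#'   to 1; default `c(0.6, 0.2, 0.2)`.
#' @param seed Integer seed, or `NULL`.
#' @param mode `"paper_faithful"` balances and augments the whole dataset
#'   before partitioning (replicas of one source record may land in different
#'   splits, an optimistic-bias risk); `"leakage_safe"` partitions the
#'   original records first and then balances/augments the training split
#'   only. See the methods vignette.
#' @return A `split_spec` object.
#' @export
split_spec <- function(ratios = c(0.6, 0.2, 0.2), seed = NULL,
                       mode = c("paper_faithful", "leakage_safe")) {
  mode <- match.arg(mode)
  if (length(ratios) != 3 || any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-9) {
    stop("`ratios` must be 3 positive numbers summing to 1", call. = FALSE)
  }
  structure(list(ratios = ratios, seed = seed, mode = mode),
            class = "split_spec")
}

#' Partition a dataset into train/test/validation
#'
#' Disjoint, exhaustive, uniformly random under the seed. Sizes are
#' `floor(r1 n)` and `floor(r2 n)`, with the remainder going to validation.
#'
#' @param dataset An [encoded_dataset()].
#' @param spec A [split_spec()].
#' @return A named list of three `encoded_dataset`s: `train`, `test`,
#'   `validation`.
#' @export
partition <- function(dataset, spec = split_spec()) {
  stopifnot(inherits(dataset, "encoded_dataset"),
            inherits(spec, "split_spec"))
  n <- nrow(dataset$x)
  if (n == 0) stop("cannot partition an empty dataset", call. = FALSE)
  with_seed(spec$seed, {
    ord <- sample.int(n)
    n_train <- floor(spec$ratios[1] * n)
    n_test <- floor(spec$ratios[2] * n)
    take <- function(i) encoded_dataset(
      x = dataset$x[i, , drop = FALSE],
      class = dataset$class[i],
      provenance = dataset$provenance[i]
    )
    list(train = take(ord[seq_len(n_train)]),
         test = take(ord[n_train + seq_len(n_test)]),
         validation = take(ord[setdiff(seq_len(n), seq_len(n_train + n_test))]))
  })
}

#' Encoded dataset container
#'
#' The numeric representation consumed by the network: an input matrix
#' (nominally on the \[0.1, 0.9\] scale after normalization), the integer
#' class labels, the equivalent one-hot target matrix, and a provenance tag
#' per row (`"original"`, `"balanced-replica"` or `"augmented"`).
#'
#' @param x Numeric input matrix.
#' @param class Integer class labels in 1..4, one per row of `x`.
#' @param provenance Character tags, one per row (default all `"original"`).
#' @return An `encoded_dataset` object with elements `x`, `y` (one-hot),
#'   `class`, `provenance`.
#' @export
encoded_dataset <- function(x, class,
                            provenance = rep("original", length(class))) {
  x <- as.matrix(x)
  if (nrow(x) != length(class) || length(class) != length(provenance)) {
    stop("row counts of x, class and provenance must agree", call. = FALSE)
  }
  structure(list(x = x, y = one_hot(class), class = as.integer(class),
                 provenance = provenance),
            class = "encoded_dataset")
}

#' @export
print.encoded_dataset <- function(x, ...) {
  cat(sprintf("<encoded_dataset> %d records x %d attributes\n",
              nrow(x$x), ncol(x$x)))
  cat("  classes:    ", paste(sprintf("%d:%d", sort(unique(x$class)),
                                      tabulate(x$class, 4)[sort(unique(x$class))]),
                              collapse = "  "), "\n")
  cat("  provenance: ", paste(names(table(x$provenance)),
                              table(x$provenance), sep = "=",
                              collapse = "  "), "\n")
  invisible(x)
}

#' Run the full preprocessing pipeline on raw records
#'
#' Composes the stages of the preprocessing algorithm. In `paper_faithful`
#' mode (the default, mirroring the original flow) the order is clean ->
#' encode -> normalize -> balance -> augment -> partition; in `leakage_safe`
#' mode the partition happens right after normalization and only the training
#' split is balanced and augmented, so no replica or noisy copy of a record
#' can cross a split boundary.
#'
#' @param view A system view from [system_view()].
#' @param system `"surgery"` or `"emergence"`.
#' @param multiple Enrichment multiple `M` (total-size convention; see
#'   [augment()]).
#' @param spec A [split_spec()] carrying the ratios, seed and mode.
#' @param balance If `FALSE`, skip the balancing stage (all multiples 1).
#' @param noise Noise half-width for augmentation.
#' @param iqr_rule Passed to [clean()].
#' @return A list of class `preprocessed_data`: `train`, `test`, `validation`
#'   (encoded datasets), `norm` (fitted [fit_normalization()] params), `plan`
#'   (the balance plan, or `NULL`), `scheme`, and `report` — a data.frame of
#'   record counts after every stage.
#' @export
preprocess_pipeline <- function(view, system = c("surgery", "emergence"),
                                multiple = 3, spec = split_spec(seed = 1L),
                                balance = TRUE, noise = 0.03,
                                iqr_rule = FALSE) {
  system <- match.arg(system)
  scheme <- if (system == "surgery") surgery_bins() else emergence_bins()
  report <- list(raw = nrow(view))

  cleaned <- clean(view, system, iqr_rule = iqr_rule)
  report$cleaned <- nrow(cleaned$records)
  if (nrow(cleaned$records) == 0) {
    stop("no records survive cleaning", call. = FALSE)
  }

  xraw <- cleaned$records[, paste0("A", 1:24), drop = FALSE]
  cls <- bin_duration(cleaned$records$duration_minutes, scheme)
  norm <- fit_normalization(xraw)
  ds <- encoded_dataset(apply_normalization(xraw, norm), cls)
  report$encoded <- nrow(ds$x)

  aug_seed <- if (is.null(spec$seed)) NULL else derive_seed(spec$seed, 101)
  part_spec <- split_spec(spec$ratios,
                          if (is.null(spec$seed)) NULL
                          else derive_seed(spec$seed, 202),
                          spec$mode)
  plan <- NULL
  balance_augment <- function(d) {
    if (balance) {
      counts <- category_counts(tabulate(d$class, 4))
      plan <<- build_balance_plan(counts)
      d <- apply_balance(d, plan)
    }
    augment(d, augmentation_config(multiple, noise, aug_seed))
  }

  if (spec$mode == "paper_faithful") {
    ds <- balance_augment(ds)
    report$balanced_augmented <- nrow(ds$x)
    splits <- partition(ds, part_spec)
  } else {
    splits <- partition(ds, part_spec)
    splits$train <- balance_augment(splits$train)
    report$balanced_augmented <- nrow(splits$train$x) +
      nrow(splits$test$x) + nrow(splits$validation$x)
  }
  report$train <- nrow(splits$train$x)
  report$test <- nrow(splits$test$x)
  report$validation <- nrow(splits$validation$x)

  structure(list(train = splits$train, test = splits$test,
                 validation = splits$validation,
                 norm = norm, plan = plan, scheme = scheme, system = system,
                 mode = spec$mode, multiple = multiple,
                 clean_report = cleaned$removed_by_rule,
                 report = data.frame(stage = names(report),
                                     records = unlist(report),
                                     row.names = NULL)),
            class = "preprocessed_data")
}

#' @export
print.preprocessed_data <- function(x, ...) {
  cat(sprintf("<preprocessed_data> system=%s mode=%s M=%d\n",
              x$system, x$mode, x$multiple))
  print(x$report, row.names = FALSE)
  invisible(x)
}
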