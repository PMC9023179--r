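# Unit and property tests for the preprocessing algorithm.

test_that("clean drops out-of-cap durations and malformed records", {
  v <- make_view(100, seed = 3)
  v$duration_minutes[1] <- 250           # 4 h 10 min: over the surgery cap
  v$duration_minutes[2] <- -5
  v$A1[3] <- 9                           # gender outside its level set
  v$A2[4] <- NA_real_
  res <- clean(v, "surgery")
  expect_equal(nrow(res$records), 96)
  expect_equal(res$n_removed, 4)
  expect_equal(unname(res$removed_by_rule[c("duration_cap", "level_set",
                                            "non_finite")]),
               c(2, 1, 1))
})

test_that("clean on an emergence fixture retains exactly the in-cap records", {
  v <- make_view(100, seed = 21, system = "emergence")
  over <- sample(seq_len(100), 7)
  v$duration_minutes[over] <- runif(7, 61, 120)
  res <- clean(v, "emergence")
  expect_equal(nrow(res$records), 93)  # direct filter on the fixture
  expect_equal(res$n_removed, 7)
})

test_that("clean of an empty view is an empty no-op", {
  v <- make_view(10, seed = 1)[0, ]
  res <- clean(v, "surgery")
  expect_equal(nrow(res$records), 0)
  expect_equal(res$n_removed, 0)
})

test_that("normalization maps the fitted range onto [0.1, 0.9] linearly", {
  p <- fit_normalization(data.frame(a = c(0, 5, 10)))
  out <- apply_normalization(data.frame(a = c(0, 5, 10)), p)
  expect_equal(unname(out[, "a"]), c(0.1, 0.5, 0.9))
  # constant attribute parks at the midpoint
  pc <- fit_normalization(data.frame(a = c(3, 3, 3)))
  expect_equal(unname(apply_normalization(data.frame(a = 3), pc)[, "a"]), 0.5)
  # unknown attribute is a schema error
  expect_error(apply_normalization(data.frame(zz = 1), p), "absent")
})

test_that("normalization is order-preserving and affinely invertible", {
  set.seed(8)
  x <- as.data.frame(matrix(rnorm(10000), ncol = 10))
  p <- fit_normalization(x)
  z <- apply_normalization(x, p)
  expect_true(all(z >= 0.1 - 1e-12 & z <= 0.9 + 1e-12))
  expect_equal(unname(apply(z, 2, min)), rep(0.1, 10))
  expect_equal(unname(apply(z, 2, max)), rep(0.9, 10))
  for (j in 1:10) {
    expect_identical(order(z[, j]), order(x[, j]))
  }
  back <- invert_normalization(z, p)
  expect_lt(max(abs(back - as.matrix(x))), 1e-9)
})

test_that("duration binning uses right-closed hourly and emergence intervals", {
  expect_equal(bin_duration(c(30, 60, 61, 120.5, 240), surgery_bins()),
               c(1, 1, 2, 3, 4))
  expect_equal(bin_duration(c(15, 45, 55), emergence_bins()), c(1, 3, 4))
  expect_error(bin_duration(241, surgery_bins()), "clean")
  expect_error(bin_duration(0, surgery_bins()), "clean")
})

test_that("one-hot coding is the 1000/0100/0010/0001 scheme and inverts", {
  expect_equal(one_hot(1)[1, ], c(1, 0, 0, 0))
  expect_equal(one_hot(4)[1, ], c(0, 0, 0, 1))
  expect_equal(un_hot(one_hot(c(3, 1, 4, 2, 2))), c(3, 1, 4, 2, 2))
  expect_error(un_hot(matrix(c(1, 1, 0, 0), 1)), "exactly one 1")
  expect_error(one_hot(5), "1..4")
})

test_that("balancing multiples reproduce the worked examples", {
  expect_identical(compute_balance_multiple(60, 100), 2L)
  expect_identical(compute_balance_multiple(30, 100), 3L)
  expect_identical(compute_balance_multiple(100, 100), 1L)
  # exact tie |2*40-100| = |3*40-100| resolves to the larger multiple
  expect_identical(compute_balance_multiple(40, 100), 3L)
  expect_error(compute_balance_multiple(0, 100), "n_i")
  expect_error(compute_balance_multiple(101, 100), "n_i")
})

test_that("the rule agrees with the brute-force argmin on sampled cases", {
  set.seed(14)
  for (rep in 1:300) {
    n_max <- sample(1:200, 1)
    n_i <- sample(n_max, 1)
    expect_identical(as.integer(compute_balance_multiple(n_i, n_max)),
                     as.integer(brute_force_multiple(n_i, n_max)),
                     label = sprintf("n_i=%d n_max=%d", n_i, n_max))
  }
})

test_that("balance plans replicate classes toward n_max", {
  counts <- worked_example_counts()
  plan <- build_balance_plan(counts)
  expect_equal(unname(plan$m_i * counts$n_i), c(120, 90, 100))
  # |m_i n_i - n_max| minimal over all positive integers
  for (j in seq_along(counts$n_i)) {
    errs <- abs((1:200) * counts$n_i[j] - counts$n_max)
    expect_equal(abs(plan$m_i[j] * counts$n_i[j] - counts$n_max),
                 min(errs), ignore_attr = TRUE)
  }
  # perfectly balanced input: identity plan
  even <- build_balance_plan(category_counts(c(50, 50, 50, 50)))
  expect_equal(unname(even$m_i), rep(1, 4))
  expect_warning(build_balance_plan(category_counts(c(10, 0, 5))),
                 "zero records")
})

test_that("apply_balance duplicates exactly and preserves labels", {
  ds <- tiny_encoded(n = 190, seed = 6)
  # force counts 60/30/100/0-free: relabel deterministically
  ds$class <- rep(c(1L, 2L, 3L, 4L), c(60, 30, 80, 20))
  ds$y <- one_hot(ds$class)
  counts <- category_counts(tabulate(ds$class, 4))
  plan <- build_balance_plan(counts)
  out <- apply_balance(ds, plan)
  expect_equal(tabulate(out$class, 4), unname(plan$m_i * counts$n_i))
  expect_equal(sum(out$provenance == "balanced-replica"),
               nrow(out$x) - nrow(ds$x))
  # replicas are exact copies: every balanced row exists among the originals
  expect_true(all(duplicated(rbind(ds$x, out$x))[-(1:nrow(ds$x))] |
                    out$provenance == "original"))
  # identity plan leaves the dataset untouched
  even <- ds
  even$class <- rep(1:4, length.out = 190)
  even$y <- one_hot(even$class)
  plan2 <- build_balance_plan(category_counts(tabulate(even$class, 4)))
  expect_identical(apply_balance(even, plan2)$x, even$x)
})

test_that("augmentation scales counts exactly and obeys the noise bound", {
  ds <- tiny_encoded(n = 10, seed = 3)
  out <- augment(ds, augmentation_config(multiple = 3, seed = 11))
  expect_equal(nrow(out$x), 30)
  expect_equal(sum(out$provenance == "augmented"), 20)
  expect_identical(out$class, c(ds$class, rep(ds$class, 2)))
  src <- rbind(ds$x, ds$x)
  expect_lte(max(abs(out$x[11:30, ] - src)), 0.03)
  # M = 1 is the identity
  expect_identical(augment(ds, augmentation_config(1)), ds)
  expect_error(augmentation_config(0), "positive")
  # seeded reproducibility
  out2 <- augment(ds, augmentation_config(multiple = 3, seed = 11))
  expect_identical(out, out2)
})

test_that("partition yields floor-rule sizes, disjoint and exhaustive", {
  ds <- tiny_encoded(n = 1000, seed = 2)
  sp <- partition(ds, split_spec(seed = 4))
  expect_equal(vapply(sp, function(d) nrow(d$x), numeric(1)),
               c(train = 600, test = 200, validation = 200))
  # conservation: multiset of rows is preserved
  all_rows <- rbind(sp$train$x, sp$test$x, sp$validation$x)
  expect_equal(dim(all_rows), dim(ds$x))
  expect_equal(sort(all_rows[, 1]), sort(ds$x[, 1]))
  one <- partition(tiny_encoded(n = 1), split_spec(seed = 1))
  expect_equal(vapply(one, function(d) nrow(d$x), numeric(1)),
               c(train = 0, test = 0, validation = 1))
  expect_error(split_spec(ratios = c(0.5, 0.2, 0.2)), "summing to 1")
})

test_that("pipeline reproduces the worked-example balancing arithmetic", {
  v <- view_with_class_counts(c(60, 30, 100, 0))
  expect_warning(
    prep <- preprocess_pipeline(v, "surgery", multiple = 1,
                                spec = split_spec(seed = 1)),
    "zero records")
  rep_counts <- setNames(prep$report$records, prep$report$stage)
  expect_equal(unname(rep_counts["balanced_augmented"]), 310)  # 120+90+100
  expect_equal(unname(plan <- prep$plan$m_i)[1:3], c(2, 3, 1))
  # with M = 3 the 310 become 930, split 558/186/186 by the floor rule
  expect_warning(
    prep3 <- preprocess_pipeline(v, "surgery", multiple = 3,
                                 spec = split_spec(seed = 1)),
    "zero records")
  rep3 <- setNames(prep3$report$records, prep3$report$stage)
  expect_equal(unname(rep3[c("balanced_augmented", "train", "test",
                             "validation")]),
               c(930, 558, 186, 186))
})

test_that("identity configuration reduces the pipeline to a pure split", {
  v <- make_view(200, seed = 15)
  prep <- preprocess_pipeline(v, "surgery", multiple = 1,
                              spec = split_spec(seed = 2), balance = FALSE)
  expect_equal(nrow(prep$train$x) + nrow(prep$test$x) +
                 nrow(prep$validation$x), 200)
  expect_true(all(c(prep$train$provenance, prep$test$provenance,
                    prep$validation$provenance) == "original"))
})

test_that("leakage_safe mode keeps replicas inside the training split", {
  v <- make_view(400, seed = 16)
  prep <- preprocess_pipeline(v, "surgery", multiple = 3,
                              spec = split_spec(seed = 3,
                                                mode = "leakage_safe"))
  expect_true(all(prep$test$provenance == "original"))
  expect_true(all(prep$validation$provenance == "original"))
  expect_true(any(prep$train$provenance != "original"))
  # the three splits partition the 400 original records
  expect_equal(sum(prep$train$provenance == "original") +
                 nrow(prep$test$x) + nrow(prep$validation$x), 400)
})

test_that("augmentation and balancing never change a record's target", {
  ds <- tiny_encoded(n = 60, seed = 19)
  plan <- build_balance_plan(category_counts(tabulate(ds$class, 4)))
  bal <- apply_balance(ds, plan)
  aug <- augment(bal, augmentation_config(4, seed = 5))
  n0 <- nrow(bal$x)
  idx <- rep(seq_len(n0), 3)
  expect_identical(aug$class[(n0 + 1):nrow(aug$x)], bal$class[idx])
  expect_identical(aug$y, one_hot(aug$class))
})
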