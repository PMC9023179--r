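# Grid search, t-test comparison, the accuracy-then-runtime selection rule,
# and the follow-up experiments.

fabricate_grid <- function(spec_means, runtimes, n_rep = 10, sd = 0.01,
                           seed = 1) {
  # spec_means: named list arch -> mean testing accuracy
  set.seed(seed)
  rows <- do.call(rbind, lapply(names(spec_means), function(a) {
    lw <- as.integer(strsplit(a, "-")[[1]])
    acc <- pmin(pmax(rnorm(n_rep, spec_means[[a]], sd), 0), 1)
    data.frame(arch = a, layers = lw[1], width = lw[2], replicate = 1:n_rep,
               acc_test = acc, acc_train = acc, acc_validation = acc,
               loss_test = 1 - acc, loss_train = 1 - acc,
               loss_validation = 1 - acc,
               time_s = runtimes[[a]] / n_rep)
  }))
  grid_result(rows)
}

test_that("a toy grid runs deterministically with coherent summaries", {
  v <- make_view(250, seed = 17, effect_size = 3)
  prep <- preprocess_pipeline(v, "surgery", multiple = 1,
                              spec = split_spec(seed = 2))
  gs <- grid_spec(layers = c(1, 2), widths = c(8, 16), replicates = 2,
                  config = train_config(epochs = 2))
  gr <- run_grid(gs, prep, seed = 21)
  expect_equal(nrow(gr$summary), 4)  # |layers| x |widths|
  expect_equal(nrow(gr$results), 8)
  expect_true(all(gr$summary$acc_test_min <= gr$summary$acc_test_mean &
                    gr$summary$acc_test_mean <= gr$summary$acc_test_max))
  expect_true(all(gr$summary$acc_test_std >= 0))
  gr2 <- run_grid(gs, prep, seed = 21)
  expect_equal(gr$summary[, -1], gr2$summary[, -1], tolerance = 1e-12,
               ignore_attr = TRUE)
  # summary recomputed from the raw replicate rows matches exactly
  re <- grid_result(gr$results)
  expect_equal(re$summary, gr$summary)
  expect_equal(re$runtimes, gr$runtimes)
})

test_that("the one-tailed pooled t-test matches stats::t.test", {
  set.seed(2)
  a <- rnorm(10, 0.9, 0.01)
  b <- rnorm(10, 0.5, 0.01)
  mine <- compare_t_test(a, b)
  ref <- t.test(a, b, var.equal = TRUE, alternative = "greater")
  expect_equal(mine$p, unname(ref$p.value), tolerance = 1e-12)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(mine$p, 0.001)
  expect_true(mine$significant)
  # Welch variant
  w <- compare_t_test(a, b, var_equal = FALSE)
  refw <- t.test(a, b, alternative = "greater")
  expect_equal(w$p, unname(refw$p.value), tolerance = 1e-12)
  # one-sided symmetry under swapping
  expect_equal(compare_t_test(b, a)$p, 1 - mine$p, tolerance = 1e-12)
})

test_that("degenerate and identical samples give p = 0.5", {
  a <- rep(0.8, 5)
  res <- compare_t_test(a, a)
  expect_equal(res$p, 0.5)
  expect_true(res$degenerate)
  expect_false(res$significant)
  jittered <- c(0.8, 0.80001, 0.79999)
  expect_equal(compare_t_test(jittered, jittered)$p, 0.5, tolerance = 1e-6)
  expect_error(compare_t_test(1, c(1, 2)), "at least 2")
})

test_that("runtime-saving arithmetic reproduces the printed 67.66%", {
  expect_equal(round(runtime_saving(1806.50, 584.24), 2), 67.66)
  expect_equal(runtime_saving(100, 100), 0)
})

test_that("a dominating architecture is selected with an all-significant trace", {
  gr <- fabricate_grid(list(`3-64` = 0.60, `3-128` = 0.70,
                            `4-64` = 0.65, `4-128` = 0.92),
                       list(`3-64` = 100, `3-128` = 200,
                            `4-64` = 120, `4-128` = 260),
                       sd = 0.005)
  sel <- select_architecture(gr)
  expect_equal(sel$label, "4-128")
  expect_true(all(sel$trace$significant))
  expect_true(all(sel$trace$action == "keep"))
})

test_that("an indistinguishable but cheaper width is demoted to", {
  # deterministic replicate vectors: identical jitter about means 0.7254 and
  # 0.7252, so the top pair is statistically indistinguishable while the
  # cheaper width saves 67.66% runtime
  jitter <- seq(-0.009, 0.009, length.out = 10)
  mk <- function(arch, layers, width, mean_acc, time_total) {
    data.frame(arch = arch, layers = layers, width = width, replicate = 1:10,
               acc_test = mean_acc + jitter, acc_train = mean_acc + jitter,
               acc_validation = mean_acc + jitter,
               loss_test = 1 - mean_acc, loss_train = 1 - mean_acc,
               loss_validation = 1 - mean_acc, time_s = time_total / 10)
  }
  gr <- grid_result(rbind(mk("3-64", 3, 64, 0.60, 100),
                          mk("3-128", 3, 128, 0.65, 200),
                          mk("3-256", 3, 256, 0.7252, 584.24),
                          mk("3-512", 3, 512, 0.7254, 1806.50)))
  sel <- select_architecture(gr)
  expect_equal(sel$label, "3-256")
  demo <- sel$trace[sel$trace$action == "demote", ]
  expect_equal(nrow(demo), 1)
  expect_false(demo$significant)
  expect_equal(round(demo$saving_pct, 2), 67.66)
})

test_that("dropout experiment shares seeds with the baseline and summarises", {
  v <- make_view(250, seed = 23, effect_size = 3)
  prep <- preprocess_pipeline(v, "surgery", multiple = 1,
                              spec = split_spec(seed = 2))
  arch <- mlp_architecture(1, 8)
  de <- dropout_experiment(arch, prep, p_values = c(0, 0.3), replicates = 2,
                           config = train_config(epochs = 3), seed = 31)
  expect_equal(nrow(de$summary), 2)
  expect_true(all(c("acc_test_mean", "acc_test_std", "acc_test_max",
                    "acc_test_min") %in% names(de$summary)))
  # the p = 0 row equals a dropout-free run with the same derived seeds
  cfg <- train_config(epochs = 3)
  cfg$seed <- periopnet:::derive_seed(31, 900, 1)
  base <- run_trial(arch, prep, cfg)
  expect_equal(de$results$acc_test[de$results$dropout == 0][1],
               base$acc_test)
})

test_that("enrichment scales the training set by M and null settings agree", {
  v <- make_view(300, seed = 29, effect_size = 3)
  arch <- mlp_architecture(1, 8)
  ee <- enrichment_experiment(arch, v, "surgery",
                              settings = list(c(multiple = 1, epochs = 2),
                                              c(multiple = 1, epochs = 2),
                                              c(multiple = 3, epochs = 2)),
                              replicates = 2, seed = 41)
  # identical settings give identical results (null enrichment)
  expect_equal(ee$results$acc_test[ee$results$arch == "M1-E2"],
               rep(ee$results$acc_test[ee$results$arch == "M1-E2"][1:2], 2))
  expect_equal(unname(ee$mean_acc_test[1]), unname(ee$mean_acc_test[2]))
  # total record count scales exactly by M at a fixed preprocessing seed
  s <- periopnet:::derive_seed(41, 50)
  tot <- function(m) {
    p <- preprocess_pipeline(v, "surgery", multiple = m,
                             spec = split_spec(seed = s))
    nrow(p$train$x) + nrow(p$test$x) + nrow(p$validation$x)
  }
  expect_equal(tot(3), 3 * tot(1))
})

test_that("grid_spec rejects degenerate settings", {
  expect_error(grid_spec(replicates = 1), ">= 2")
  expect_error(grid_spec(layers = integer(0)), "nonempty")
})
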