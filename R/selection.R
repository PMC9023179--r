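# Architecture selection: replicate grid search over layer-count x width
# combinations, Mean/Std/Max/Min summaries per split, pairwise one-tailed
# t-tests on testing accuracy, runtime accounting, and the
# accuracy-then-runtime selection rule, plus the dropout and
# enrichment/longer-training follow-up experiments.

#' Grid-search specification
#'
#' @param layers Hidden-layer counts to screen (default 3–6).
#' @param widths Hidden widths to screen (default 64, 128, 256, 512).
#' @param replicates Independently seeded training replicates per
#'   architecture (default 10; at least 2, since the t-tests need variance).
#' @param config Base [train_config()] shared by every cell (its seed is
#'   replaced by derived per-replicate seeds).
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(layers = c(3, 4, 5, 6), widths = c(64, 128, 256, 512),
                      replicates = 10, config = train_config()) {
  if (length(layers) == 0 || length(widths) == 0) {
    stop("grid must be nonempty", call. = FALSE)
  }
  stop_if_not_count(replicates, "replicates")
  if (replicates < 2) stop("`replicates` must be >= 2", call. = FALSE)
  structure(list(layers = as.integer(layers), widths = as.integer(widths),
                 replicates = as.integer(replicates), config = config),
            class = "grid_spec")
}

#' Assemble a grid result from raw replicate rows
#'
#' Computes the Mean/Std/Max/Min summary (per architecture and split, for
#' accuracy and loss) and the per-architecture total runtime from a
#' data.frame of per-replicate results. [run_grid()] returns this class;
#' constructing it directly is useful for analysing externally produced
#' replicate tables.
#'
#' @param results data.frame with columns `arch`, `layers`, `width`,
#'   `replicate`, `acc_test`, `acc_train`, `acc_validation`, `loss_test`,
#'   `loss_train`, `loss_validation`, `time_s`.
#' @return A `grid_result`: list with `results` (raw rows), `summary` (one
#'   row per architecture), `runtimes` (arch, total seconds).
#' @export
grid_result <- function(results) {
  req <- c("arch", "layers", "width", "acc_test", "acc_train",
           "acc_validation", "loss_test", "loss_train", "loss_validation",
           "time_s")
  if (!all(req %in% names(results))) {
    stop("results is missing columns: ",
         paste(setdiff(req, names(results)), collapse = ", "), call. = FALSE)
  }
  archs <- unique(results$arch)
  stat_cols <- c("acc_test", "acc_train", "acc_validation",
                 "loss_test", "loss_train", "loss_validation")
  summ <- do.call(rbind, lapply(archs, function(a) {
    r <- results[results$arch == a, ]
    row <- data.frame(arch = a, layers = r$layers[1], width = r$width[1],
                      n_replicates = nrow(r))
    for (cc in stat_cols) {
      v <- r[[cc]]
      row[[paste0(cc, "_mean")]] <- mean(v)
      row[[paste0(cc, "_std")]] <- stats::sd(v)
      row[[paste0(cc, "_max")]] <- max(v)
      row[[paste0(cc, "_min")]] <- min(v)
    }
    row
  }))
  runtimes <- data.frame(
    arch = archs,
    time_s = vapply(archs,
                    function(a) sum(results$time_s[results$arch == a]),
                    numeric(1))
  )
  structure(list(results = results, summary = summ, runtimes = runtimes),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %d architectures x %d replicate rows\n",
              nrow(x$summary), nrow(x$results)))
  cols <- c("arch", "acc_test_mean", "acc_test_std", "acc_test_max",
            "acc_test_min")
  print(x$summary[, cols], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Run the replicate grid search
#'
#' Trains `replicates` independently seeded models for every layer-count x
#' width combination on the prepared splits. Replicate seeds derive
#' deterministically from the master seed, so a rerun with the same seed
#' reproduces the whole grid.
#'
#' @param grid A [grid_spec()].
#' @param data A `preprocessed_data` (train/test/validation splits).
#' @param seed Master seed.
#' @param dropout Dropout probability applied to every cell (default 0).
#' @param verbose Print a line per completed cell.
#' @return A [grid_result()].
#' @export
run_grid <- function(grid, data, seed = 1L, dropout = 0, verbose = FALSE) {
  stopifnot(inherits(grid, "grid_spec"))
  cells <- expand.grid(width = grid$widths, layers = grid$layers)
  rows <- vector("list", nrow(cells) * grid$replicates)
  k <- 0
  for (i in seq_len(nrow(cells))) {
    arch <- mlp_architecture(cells$layers[i], cells$width[i],
                             dropout = dropout)
    for (r in seq_len(grid$replicates)) {
      cfg <- grid$config
      cfg$seed <- derive_seed(seed, i, r)
      k <- k + 1
      res <- run_trial(arch, data, cfg)
      attr(res, "model") <- NULL
      res$replicate <- r
      rows[[k]] <- res
    }
    if (verbose) {
      message(sprintf("grid cell %s done (%d/%d)", format(arch), i,
                      nrow(cells)))
    }
  }
  grid_result(do.call(rbind, rows))
}

#' One-tailed two-sample t-test for model comparison
#'
#' Tests the directional hypothesis "mean(a) > mean(b)" on replicate testing
#' accuracies, by default with the pooled-variance statistic. When both
#' samples are constant and equal the statistic is undefined; the comparison
#' is then flagged degenerate with `p = 0.5` (the symmetric-null convention).
#'
#' @param a,b Numeric replicate vectors (length >= 2 each).
#' @param alpha Significance level (default 0.05).
#' @param var_equal Pooled variance (default) or Welch.
#' @param two_sided If `TRUE`, report the two-sided p instead.
#' @return A `t_test_result`: list with `t`, `df`, `p`, `significant`,
#'   `direction` (+1 if `mean(a) > mean(b)`), `degenerate`.
#' @export
#' @examples
#' compare_t_test(c(0.9, 0.91, 0.89), c(0.5, 0.52, 0.48))
compare_t_test <- function(a, b, alpha = 0.05, var_equal = TRUE,
                           two_sided = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    stop("both samples need at least 2 values", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  degenerate <- FALSE
  if (va == 0 && vb == 0) {
    if (ma == mb) {
      t_stat <- 0; df <- na + nb - 2; p <- 0.5
      degenerate <- TRUE
    } else {
      t_stat <- sign(ma - mb) * Inf; df <- na + nb - 2
      p <- if (ma > mb) 0 else 1
    }
  } else if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t_stat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
    p <- stats::pt(t_stat, df, lower.tail = FALSE)
  } else {
    se2 <- va / na + vb / nb
    t_stat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- stats::pt(t_stat, df, lower.tail = FALSE)
  }
  if (two_sided && !degenerate) p <- 2 * min(p, 1 - p)
  structure(list(t = t_stat, df = df, p = p,
                 significant = is.finite(p) && p < alpha,
                 direction = sign(ma - mb), degenerate = degenerate,
                 alpha = alpha),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("one-tailed t = %.4f, df = %.1f, p = %.4f (%s)%s\n",
              x$t, x$df, x$p,
              if (x$significant) "significant" else "not significant",
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' Percentage runtime saving of the faster of two architectures
#'
#' `100 * (slow - fast) / slow`.
#'
#' @param slow,fast Runtimes in seconds (`slow >= fast`).
#' @return Percentage saving.
#' @export
#' @examples
#' runtime_saving(1806.50, 584.24)  # 67.66
runtime_saving <- function(slow, fast) {
  if (slow <= 0) stop("`slow` must be positive", call. = FALSE)
  100 * (slow - fast) / slow
}

# One elimination round over candidate architectures ordered by mean testing
# accuracy: keep the leader unless a cheaper candidate is statistically
# indistinguishable (not significantly worse at alpha) and saves runtime, in
# which case demote to it and continue. Returns the winner and trace rows.
select_round <- function(cands, results, runtimes, alpha, stage) {
  acc <- function(a) results$acc_test[results$arch == a]
  rt <- function(a) runtimes$time_s[runtimes$arch == a]
  ord <- cands[order(-vapply(cands, function(a) mean(acc(a)), numeric(1)))]
  winner <- ord[1]
  trace <- list()
  for (a in ord[-1]) {
    tt <- compare_t_test(acc(winner), acc(a), alpha = alpha)
    cheaper <- rt(a) < rt(winner)
    demote <- !tt$significant && cheaper
    trace[[length(trace) + 1]] <- data.frame(
      stage = stage, leader = winner, challenger = a,
      p = tt$p, significant = tt$significant,
      leader_time_s = rt(winner), challenger_time_s = rt(a),
      saving_pct = if (cheaper) runtime_saving(rt(winner), rt(a)) else NA_real_,
      action = if (demote) "demote" else "keep")
    if (demote) winner <- a
  }
  list(winner = winner, trace = do.call(rbind, trace))
}

#' Select the final architecture from a grid result
#'
#' Two-stage rule: within each hidden-layer count, the width with the highest
#' mean testing accuracy wins unless a cheaper width is not significantly
#' worse (one-tailed t-test at `alpha`) and saves runtime, in which case the
#' cheaper width is taken; the per-layer winners then compete under the same
#' rule. Every comparison (p-value, runtimes, runtime saving, keep/demote) is
#' recorded in the decision trace.
#'
#' @param gr A [grid_result()].
#' @param alpha Significance level (default 0.05).
#' @return An `architecture_selection`: list with `arch` (the winning
#'   [mlp_architecture()]), `label`, `per_layer_winners`, and `trace`.
#' @export
select_architecture <- function(gr, alpha = 0.05) {
  stopifnot(inherits(gr, "grid_result"))
  layer_counts <- sort(unique(gr$summary$layers))
  traces <- list()
  winners <- character(0)
  for (L in layer_counts) {
    cands <- gr$summary$arch[gr$summary$layers == L]
    round <- select_round(cands, gr$results, gr$runtimes, alpha,
                          stage = sprintf("width@%d-layers", L))
    winners <- c(winners, round$winner)
    traces[[length(traces) + 1]] <- round$trace
  }
  final <- select_round(winners, gr$results, gr$runtimes, alpha,
                        stage = "layers")
  traces[[length(traces) + 1]] <- final$trace
  trace <- do.call(rbind, traces[!vapply(traces, is.null, logical(1))])
  row <- gr$summary[gr$summary$arch == final$winner, ]
  structure(list(arch = mlp_architecture(row$layers, row$width),
                 label = final$winner, per_layer_winners = winners,
                 trace = trace, alpha = alpha,
                 n_comparisons = if (is.null(trace)) 0L else nrow(trace)),
            class = "architecture_selection")
}

#' @export
print.architecture_selection <- function(x, ...) {
  cat(sprintf("<architecture_selection> final architecture: %s\n", x$label))
  cat("per-layer winners:", paste(x$per_layer_winners, collapse = ", "), "\n")
  cat(sprintf("%d pairwise comparisons at alpha = %g (no multiplicity correction)\n",
              x$n_comparisons, x$alpha))
  if (!is.null(x$trace)) print(x$trace, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Dropout follow-up experiment
#'
#' Re-trains the selected architecture at each dropout probability with
#' `replicates` seeded replicates and summarises accuracy/loss per split.
#' Overfitting is absent in this regime, so dropout is expected not to help;
#' the result records whether mean testing accuracy is non-increasing in `p`.
#'
#' @param arch The selected [mlp_architecture()].
#' @param data A `preprocessed_data`.
#' @param p_values Dropout probabilities (default 0, 0.1, 0.2, 0.3).
#' @param replicates Replicates per setting.
#' @param config Base [train_config()].
#' @param seed Master seed.
#' @return A `dropout_experiment` result: `summary` (one row per `p`, with
#'   Mean/Std/Max/Min columns per split), `results` (raw rows), and
#'   `monotone_nonincreasing` (mean testing accuracy never rises with `p`).
#' @export
dropout_experiment <- function(arch, data, p_values = c(0, 0.1, 0.2, 0.3),
                               replicates = 10, config = train_config(),
                               seed = 1L) {
  rows <- list()
  for (i in seq_along(p_values)) {
    arch_p <- mlp_architecture(arch$hidden_layers, arch$width,
                               dropout = p_values[i],
                               activation = arch$activation)
    for (r in seq_len(replicates)) {
      cfg <- config
      # replicate seeds shared across p settings so p = 0 reproduces the
      # dropout-free baseline exactly
      cfg$seed <- derive_seed(seed, 900, r)
      res <- run_trial(arch_p, data, cfg)
      attr(res, "model") <- NULL
      res$replicate <- r
      rows[[length(rows) + 1]] <- res
    }
  }
  results <- do.call(rbind, rows)
  results$arch <- sprintf("%s-p%g", results$arch, results$dropout)
  gr <- grid_result(results)
  means <- vapply(p_values, function(p) {
    mean(results$acc_test[results$dropout == p])
  }, numeric(1))
  structure(list(summary = cbind(dropout = p_values,
                                 gr$summary[match(sprintf("%d-%d-p%g",
                                                          arch$hidden_layers,
                                                          arch$width,
                                                          p_values),
                                                  gr$summary$arch), ]),
                 results = results,
                 monotone_nonincreasing = all(diff(means) <= 1e-12)),
            class = "dropout_experiment")
}

#' Enrichment and longer-training follow-up experiment
#'
#' Re-runs preprocessing at each enrichment multiple `M` and training at each
#' epoch count `E`, for the selected architecture, and summarises the
#' replicate accuracies. The canonical settings ladder is
#' `(M=3, E=200) -> (M=10, E=200) -> (M=10, E=1000)`.
#'
#' @param arch The selected [mlp_architecture()].
#' @param view A raw system view (re-preprocessed per setting).
#' @param system `"surgery"` or `"emergence"`.
#' @param settings A list of `c(multiple = , epochs = )` pairs.
#' @param replicates Replicates per setting.
#' @param config Base [train_config()] (epochs overridden per setting).
#' @param seed Master seed (also seeds the per-setting preprocessing, so the
#'   underlying partition is shared across settings).
#' @param mode Pipeline ordering mode, see [split_spec()].
#' @return An `enrichment_experiment` result: `summary` (one row per
#'   setting), `results`, and `mean_acc_test` in settings order.
#' @export
enrichment_experiment <- function(arch, view, system,
                                  settings = list(c(multiple = 3, epochs = 200),
                                                  c(multiple = 10, epochs = 200),
                                                  c(multiple = 10, epochs = 1000)),
                                  replicates = 10, config = train_config(),
                                  seed = 1L, mode = "paper_faithful") {
  rows <- list()
  labels <- vapply(settings, function(s) {
    sprintf("M%d-E%d", s[["multiple"]], s[["epochs"]])
  }, character(1))
  for (i in seq_along(settings)) {
    s <- settings[[i]]
    prep <- preprocess_pipeline(view, system, multiple = s[["multiple"]],
                                spec = split_spec(seed = derive_seed(seed, 50),
                                                  mode = mode))
    for (r in seq_len(replicates)) {
      cfg <- config
      cfg$epochs <- as.integer(s[["epochs"]])
      cfg$seed <- derive_seed(seed, 800, r)
      res <- run_trial(arch, prep, cfg)
      attr(res, "model") <- NULL
      res$arch <- labels[i]
      res$replicate <- r
      rows[[length(rows) + 1]] <- res
    }
  }
  results <- do.call(rbind, rows)
  gr <- grid_result(results)
  means <- vapply(labels, function(l) {
    mean(results$acc_test[results$arch == l])
  }, numeric(1))
  structure(list(summary = cbind(setting = labels,
                                 gr$summary[match(labels, gr$summary$arch), ]),
                 results = results, mean_acc_test = means),
            class = "enrichment_experiment")
}
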