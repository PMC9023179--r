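# The serial (final combination) system: the predicted surgery-duration class
# from stage 1 replaces input A24 of the stage-2 anesthesia-emergence
# predictor. Stage 2 is trained on TRUE surgery classes; the cascade is an
# evaluation-time wiring, so the predicted class must be pushed through the
# same fitted normalization map as the true class it replaces.

#' Inner-join two cohort samples on case identifier
#'
#' The surgery and emergence systems are fitted on different eligibility
#' windows (all anesthesia types vs general anesthesia only); the cascade is
#' evaluated on their intersection. Duplicate identifiers in either input are
#' a join error.
#'
#' @param surgery,emergence data.frames carrying a `case_id` column (cohorts
#'   or system views).
#' @return A list with `surgery` and `emergence`: the rows of each input
#'   restricted to the shared identifiers, in matching order.
#' @export
intersect_cohorts <- function(surgery, emergence) {
  for (nm in c("surgery", "emergence")) {
    d <- get(nm)
    if (!"case_id" %in% names(d)) {
      stop(sprintf("`%s` has no case_id column", nm), call. = FALSE)
    }
    if (anyDuplicated(d$case_id)) {
      stop(sprintf("duplicate case_id values in `%s`: %s", nm,
                   paste(utils::head(unique(d$case_id[duplicated(d$case_id)]), 5),
                         collapse = ", ")), call. = FALSE)
    }
  }
  ids <- intersect(surgery$case_id, emergence$case_id)
  list(surgery = surgery[match(ids, surgery$case_id), , drop = FALSE],
       emergence = emergence[match(ids, emergence$case_id), , drop = FALSE],
       n = length(ids))
}

#' The two-stage serial prediction system
#'
#' Bundles the trained stage-1 (surgery) and stage-2 (emergence) classifiers
#' with the normalization parameters each was fitted with. Stage-1 output
#' classes and the stage-2 A24 level set are both 1..4 by construction.
#'
#' @param surgery_model Stage-1 classifier (an `mlp_model`, or any object
#'   with a [predict_classes()] method).
#' @param emergence_model Stage-2 classifier.
#' @param surgery_norm,emergence_norm The `normalization_params` fitted by
#'   each stage's preprocessing run.
#' @return A `serial_system` object.
#' @export
serial_system <- function(surgery_model, emergence_model,
                          surgery_norm, emergence_norm) {
  stopifnot(inherits(surgery_norm, "normalization_params"),
            inherits(emergence_norm, "normalization_params"))
  structure(list(surgery_model = surgery_model,
                 emergence_model = emergence_model,
                 surgery_norm = surgery_norm,
                 emergence_norm = emergence_norm),
            class = "serial_system")
}

# Normalize a raw 24-attribute view with stored params.
normalize_view <- function(view, norm) {
  apply_normalization(view[, paste0("A", 1:24), drop = FALSE], norm)
}

#' Predict emergence classes through the serial cascade
#'
#' Stage 1 predicts a surgery-duration class from the surgery view of each
#' joined record; that class index replaces A24 of the emergence view, is
#' normalized with the stage-2 fitted parameters, and stage 2 predicts the
#' emergence class.
#'
#' @param system A [serial_system()].
#' @param joined A joined sample pair from [intersect_cohorts()] of system
#'   views (surgery view and emergence view).
#' @return A list with `emergence_pred`, `surgery_pred`, and `oracle_pred`
#'   (stage-2 predictions when fed the TRUE surgery class).
#' @export
serial_predict <- function(system, joined) {
  stopifnot(inherits(system, "serial_system"))
  sx <- normalize_view(joined$surgery, system$surgery_norm)
  surgery_pred <- predict_classes(system$surgery_model, sx)

  oracle_view <- joined$emergence
  ex_oracle <- normalize_view(oracle_view, system$emergence_norm)
  oracle_pred <- predict_classes(system$emergence_model, ex_oracle)

  cascade_view <- joined$emergence
  cascade_view$A24 <- surgery_pred
  ex <- normalize_view(cascade_view, system$emergence_norm)
  emergence_pred <- predict_classes(system$emergence_model, ex)

  list(emergence_pred = emergence_pred, surgery_pred = surgery_pred,
       oracle_pred = oracle_pred)
}

#' Evaluate the serial system three ways
#'
#' Computes (i) the oracle accuracy of the emergence predictor fed the true
#' surgery class, (ii) the stage-1 surgery accuracy, (iii) the combined
#' accuracy of the cascade fed the predicted class, and the oracle-minus-
#' combined gap.
#'
#' @param system A [serial_system()].
#' @param joined A joined pair of system views from [intersect_cohorts()];
#'   both views must carry `duration_minutes` (the true outcomes).
#' @return A `serial_result`: list with `oracle_accuracy`,
#'   `surgery_accuracy`, `combined_accuracy`, `gap`, `n`, and the per-sample
#'   prediction vectors.
#' @export
evaluate_serial <- function(system, joined) {
  if (joined$n == 0) stop("empty join: nothing to evaluate", call. = FALSE)
  true_surgery <- bin_duration(joined$surgery$duration_minutes, surgery_bins())
  true_emergence <- bin_duration(joined$emergence$duration_minutes,
                                 emergence_bins())
  pred <- serial_predict(system, joined)
  oracle <- mean(pred$oracle_pred == true_emergence)
  combined <- mean(pred$emergence_pred == true_emergence)
  structure(list(oracle_accuracy = oracle,
                 surgery_accuracy = mean(pred$surgery_pred == true_surgery),
                 combined_accuracy = combined,
                 gap = oracle - combined,
                 n = joined$n, predictions = pred),
            class = "serial_result")
}

#' @export
print.serial_result <- function(x, ...) {
  cat(sprintf("<serial_result> on %d joined samples\n", x$n))
  tab <- data.frame(
    `Prediction system` = c("Anesthesia emergence (true surgery class)",
                            "Surgery duration",
                            "Final combination (predicted class)"),
    Accuracy = c(x$oracle_accuracy, x$surgery_accuracy, x$combined_accuracy),
    check.names = FALSE)
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("oracle - combined gap: %.4f\n", x$gap))
  invisible(x)
}

#' Train a complete serial system on a synthetic cohort
#'
#' Convenience builder: preprocesses the surgery and emergence views of one
#' cohort, trains one model per stage (stage 2 on true surgery classes), and
#' wires them into a [serial_system()].
#'
#' @param cohort A `periop_cohort`.
#' @param arch An [mlp_architecture()] shared by both stages.
#' @param config A [train_config()].
#' @param multiple Enrichment multiple for both preprocessing runs.
#' @param seed Master seed.
#' @param mode Pipeline ordering mode.
#' @return A list: `system` (the [serial_system()]), and per-stage
#'   `preprocessed` data and trial summaries.
#' @export
train_serial_system <- function(cohort, arch = mlp_architecture(4, 256),
                                config = train_config(), multiple = 3,
                                seed = 1L, mode = "paper_faithful") {
  prep <- list()
  models <- list()
  trials <- list()
  for (sys in c("surgery", "emergence")) {
    view <- system_view(cohort, sys)
    prep[[sys]] <- preprocess_pipeline(view, sys, multiple = multiple,
                                       spec = split_spec(seed = derive_seed(seed, 10),
                                                         mode = mode))
    cfg <- config
    cfg$seed <- derive_seed(seed, if (sys == "surgery") 1 else 2)
    trials[[sys]] <- run_trial(arch, prep[[sys]], cfg)
    models[[sys]] <- attr(trials[[sys]], "model")
    attr(trials[[sys]], "model") <- NULL
  }
  list(system = serial_system(models$surgery, models$emergence,
                              prep$surgery$norm, prep$emergence$norm),
       preprocessed = prep, trials = trials)
}
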