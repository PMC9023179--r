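# Orchestration: a declarative experiment runner tying the stages together
# (simulate -> preprocess -> grid/select -> refine -> serial), a JSON run
# manifest for reproducibility, and a small subcommand CLI.

#' Default experiment configuration
#'
#' Returns the full nested configuration with the canonical settings: a
#' skewed 4-class cohort, enrichment multiple 3 for screening, the 16-cell
#' 3–6 x 64–512 grid with 10 replicates of 200 epochs, dropout probes at
#' 0/0.1/0.2/0.3, the (M=3,E=200)/(M=10,E=200)/(M=10,E=1000) enrichment
#' ladder, and the serial combination. Any subset can be overridden via
#' `modifyList()`-style nesting in [run_experiment()].
#'
#' @return A nested list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "periopnet-run",
    stages = c("simulate", "preprocess", "grid", "select", "refine", "serial"),
    simulate = list(n_cases = 2000, class_probs = c(0.40, 0.30, 0.20, 0.10),
                    effect_size = 1.5),
    preprocess = list(system = "surgery", multiple = 3,
                      mode = "paper_faithful"),
    grid = list(layers = c(3, 4, 5, 6), widths = c(64, 128, 256, 512),
                replicates = 10, epochs = 200, batch_size = 100),
    refine = list(dropout = c(0, 0.1, 0.2, 0.3),
                  enrichment = list(c(multiple = 3, epochs = 200),
                                    c(multiple = 10, epochs = 200),
                                    c(multiple = 10, epochs = 1000)),
                  replicates = 10),
    serial = list(arch = c(layers = 4, width = 256), epochs = 200,
                  multiple = 3)
  )
}

deep_merge <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- deep_merge(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run a declared experiment end to end
#'
#' Executes the stages named in `config$stages`, in canonical order, writing
#' every artifact (cohort CSV, stage summaries, decision trace, serial
#' report) plus a JSON run manifest into `config$out_dir`. Identical config
#' and seed reproduce every artifact.
#'
#' @param config A nested list overriding [default_config()], or a path to a
#'   JSON file containing such overrides.
#' @param quiet Suppress stage banners.
#' @return The run manifest (invisibly), a list with the config snapshot,
#'   seed, stage-by-stage record counts and wall-clock, and artifact paths.
#' @export
run_experiment <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- deep_merge(default_config(), config)
  seed <- as.integer(cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("periopnet")),
                   seed = seed, config = cfg, stages = list(),
                   artifacts = character(0))
  say <- function(...) if (!quiet) message(sprintf(...))
  add_artifact <- function(path) {
    manifest$artifacts <<- c(manifest$artifacts, path)
  }
  stage_timer <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- expr
    manifest$stages[[name]]$seconds <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  cohort <- NULL
  prep <- NULL
  gr <- NULL
  sel <- NULL

  if ("simulate" %in% cfg$stages) {
    cohort <- stage_timer("simulate", {
      spec <- cohort_spec(n_cases = cfg$simulate$n_cases,
                          class_probs = cfg$simulate$class_probs,
                          effect_size = cfg$simulate$effect_size,
                          seed = derive_seed(seed, 1))
      generate_cohort(spec)
    })
    path <- file.path(cfg$out_dir, "cohort.csv")
    write_cohort_csv(cohort, path)
    add_artifact(path)
    manifest$stages$simulate$n_cases <- nrow(cohort)
    say("[simulate] %d cases -> %s", nrow(cohort), path)
  }

  if ("preprocess" %in% cfg$stages) {
    if (is.null(cohort)) {
      path <- file.path(cfg$out_dir, "cohort.csv")
      if (!file.exists(path)) stop("preprocess needs a cohort; run simulate",
                                   call. = FALSE)
      cohort <- read_cohort_csv(path)
    }
    prep <- stage_timer("preprocess", {
      view <- system_view(cohort, cfg$preprocess$system)
      preprocess_pipeline(view, cfg$preprocess$system,
                          multiple = cfg$preprocess$multiple,
                          spec = split_spec(seed = derive_seed(seed, 2),
                                            mode = cfg$preprocess$mode))
    })
    path <- file.path(cfg$out_dir, "preprocess_report.csv")
    utils::write.csv(prep$report, path, row.names = FALSE)
    add_artifact(path)
    manifest$stages$preprocess$counts <- stats::setNames(
      as.list(prep$report$records), prep$report$stage)
    say("[preprocess] %s", paste(prep$report$stage, prep$report$records,
                                 sep = "=", collapse = " "))
  }

  if ("grid" %in% cfg$stages) {
    if (is.null(prep)) stop("grid needs preprocessed data", call. = FALSE)
    gr <- stage_timer("grid", {
      run_grid(grid_spec(layers = cfg$grid$layers, widths = cfg$grid$widths,
                         replicates = cfg$grid$replicates,
                         config = train_config(epochs = cfg$grid$epochs,
                                               batch_size = cfg$grid$batch_size)),
               prep, seed = derive_seed(seed, 3), verbose = !quiet)
    })
    for (piece in c("summary", "results", "runtimes")) {
      path <- file.path(cfg$out_dir, sprintf("grid_%s.csv", piece))
      utils::write.csv(gr[[piece]], path, row.names = FALSE)
      add_artifact(path)
    }
    manifest$stages$grid$cells <- nrow(gr$summary)
    say("[grid] %d cells x %d replicates", nrow(gr$summary),
        cfg$grid$replicates)
  }

  if ("select" %in% cfg$stages) {
    if (is.null(gr)) stop("select needs grid results", call. = FALSE)
    sel <- stage_timer("select", select_architecture(gr))
    path <- file.path(cfg$out_dir, "selection_trace.csv")
    utils::write.csv(sel$trace, path, row.names = FALSE)
    add_artifact(path)
    manifest$stages$select$final <- sel$label
    say("[select] final architecture %s", sel$label)
  }

  if ("refine" %in% cfg$stages) {
    if (is.null(prep) || is.null(cohort)) {
      stop("refine needs preprocessed data", call. = FALSE)
    }
    arch <- if (!is.null(sel)) sel$arch else {
      mlp_architecture(cfg$serial$arch[["layers"]], cfg$serial$arch[["width"]])
    }
    refined <- stage_timer("refine", {
      de <- dropout_experiment(arch, prep, p_values = cfg$refine$dropout,
                               replicates = cfg$refine$replicates,
                               config = train_config(epochs = cfg$grid$epochs),
                               seed = derive_seed(seed, 4))
      ee <- enrichment_experiment(arch,
                                  system_view(cohort, cfg$preprocess$system),
                                  cfg$preprocess$system,
                                  settings = cfg$refine$enrichment,
                                  replicates = cfg$refine$replicates,
                                  seed = derive_seed(seed, 5),
                                  mode = cfg$preprocess$mode)
      list(dropout = de, enrichment = ee)
    })
    for (piece in c("dropout", "enrichment")) {
      path <- file.path(cfg$out_dir, sprintf("refine_%s.csv", piece))
      utils::write.csv(refined[[piece]]$summary, path, row.names = FALSE)
      add_artifact(path)
    }
    say("[refine] dropout monotone non-increasing: %s; enrichment means: %s",
        refined$dropout$monotone_nonincreasing,
        paste(round(refined$enrichment$mean_acc_test, 4), collapse = " -> "))
  }

  if ("serial" %in% cfg$stages) {
    if (is.null(cohort)) stop("serial needs a cohort", call. = FALSE)
    res <- stage_timer("serial", {
      arch <- if (!is.null(sel)) sel$arch else {
        mlp_architecture(cfg$serial$arch[["layers"]],
                         cfg$serial$arch[["width"]])
      }
      fit <- train_serial_system(cohort, arch,
                                 config = train_config(epochs = cfg$serial$epochs),
                                 multiple = cfg$serial$multiple,
                                 seed = derive_seed(seed, 6))
      joined <- intersect_cohorts(system_view(cohort, "surgery"),
                                  system_view(cohort, "emergence"))
      evaluate_serial(fit$system, joined)
    })
    path <- file.path(cfg$out_dir, "serial_report.csv")
    utils::write.csv(data.frame(
      system = c("emergence_oracle", "surgery", "combined", "gap"),
      accuracy = c(res$oracle_accuracy, res$surgery_accuracy,
                   res$combined_accuracy, res$gap)), path, row.names = FALSE)
    add_artifact(path)
    manifest$stages$serial <- c(manifest$stages$serial,
                                list(oracle = res$oracle_accuracy,
                                     surgery = res$surgery_accuracy,
                                     combined = res$combined_accuracy,
                                     gap = res$gap))
    say("[serial] oracle %.4f surgery %.4f combined %.4f gap %.4f",
        res$oracle_accuracy, res$surgery_accuracy, res$combined_accuracy,
        res$gap)
  }

  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  say("[done] manifest -> %s", manifest_path)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommand dispatcher backing the `inst/cli/periopnet` script. Supported
#' subcommands: `simulate`, `run` (full or partial experiment via
#' `--stages`), each accepting `--seed`, `--config <json>`, `--out <dir>`,
#' and simulate additionally `--n`.
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return The manifest from [run_experiment()], invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    stop("usage: periopnet <simulate|run> [--n N] [--seed S] ",
         "[--stages a,b,c] [--config file.json] [--out dir]", call. = FALSE)
  }
  cmd <- args[1]
  opts <- list()
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  config <- if (!is.null(opts$config)) {
    jsonlite::read_json(opts$config, simplifyVector = TRUE)
  } else list()
  if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
  if (!is.null(opts$out)) config$out_dir <- opts$out
  if (cmd == "simulate") {
    config$stages <- "simulate"
    if (!is.null(opts$n)) {
      config$simulate <- deep_merge(list(n_cases = as.integer(opts$n)),
                                    as.list(config$simulate))
    }
  } else if (cmd == "run") {
    if (!is.null(opts$stages)) {
      config$stages <- strsplit(opts$stages, ",")[[1]]
    }
  } else {
    stop("unknown subcommand: ", cmd, call. = FALSE)
  }
  run_experiment(config)
}
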