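#' Validate a pipeline configuration
#'
#' The configuration is a YAML (or equivalent list) with a master `seed`,
#' a `simulate` block (`n_lpp`, `n_hpp`, `sampling_rate_hz`,
#' `bout_duration_s`, optional `activities`, `missing_fraction`), an
#' optional `featurize` block (`window_s`), an optional `run` block
#' (`tasks`, `outer_k`, `inner_k`, `reduced_grid`) and an optional
#' `transfer` block (`mode`, `train_group`, `test_group`, `repeats`,
#' `task_kind`, `positive_class`). Missing required fields raise an error
#' naming the field.
#'
#' @param config list (parsed YAML).
#' @return the validated config with defaults filled in.
#' @export
validate_config <- function(config) {
  require_field <- function(block, field, where) {
    if (is.null(block[[field]])) {
      stop(sprintf("config error: missing field '%s' in '%s'", field, where))
    }
    block[[field]]
  }
  if (is.null(config$seed)) stop("config error: missing field 'seed'")
  sim <- config$simulate
  if (is.null(sim)) stop("config error: missing block 'simulate'")
  for (f in c("n_lpp", "n_hpp", "sampling_rate_hz", "bout_duration_s")) {
    require_field(sim, f, "simulate")
  }
  config$featurize <- config$featurize %||% list()
  config$featurize$window_s <- config$featurize$window_s %||% 60
  config$run <- config$run %||% list()
  config$run$tasks <- config$run$tasks %||% "all"
  config$run$outer_k <- config$run$outer_k %||% 5
  config$run$inner_k <- config$run$inner_k %||% 5
  config$run$reduced_grid <- config$run$reduced_grid %||% TRUE
  if (!config$run$tasks %in% c("all", "type", "intensity", "multiclass", "ee")) {
    stop("config error: run.tasks must be one of all/type/intensity/multiclass/ee")
  }
  config
}

select_tasks <- function(which) {
  tasks <- enumerate_model_configs()
  kind <- switch(which,
    all = NULL, type = "binary_type", intensity = "binary_intensity",
    multiclass = "multiclass_activity", ee = "regression_ee"
  )
  if (is.null(kind)) tasks else tasks[tasks$task_kind == kind, , drop = FALSE]
}

activity_slug <- function(name) gsub("[^A-Z0-9]+", "-", canonical_activity_name(name))

#' Run the full analysis pipeline from a config file
#'
#' Executes simulate -> featurize -> run (-> transfer) with plain-file
#' handoffs between stages, so any stage can be re-run from the previous
#' stage's artifacts alone. Writes `results.csv` (one row per task x outer
#' fold), `importance.csv`, `transfer.csv` when requested, and a
#' `manifest.yaml` recording config, seed, package version and md5 digests
#' of all outputs. Deterministic: identical config and seed reproduce
#' byte-identical results files.
#'
#' @param config_path YAML config file, or a config list.
#' @param out output directory (default: `out` field of the config).
#' @param stages character subset of
#'   `c("simulate", "featurize", "run", "transfer", "report")`.
#' @param seed optional override of the config's seed.
#' @return invisibly, a list of stage outputs and the manifest.
#' @export
pipeline <- function(config_path, out = NULL,
                     stages = c("simulate", "featurize", "run"), seed = NULL) {
  config <- if (is.character(config_path)) yaml::read_yaml(config_path) else config_path
  config <- validate_config(config)
  if (!is.null(seed)) config$seed <- seed
  out <- out %||% config$out
  if (is.null(out)) stop("config error: missing field 'out' (or pass out=)")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(out, "data")
  res <- list()

  if ("simulate" %in% stages) {
    sim <- config$simulate
    cfg <- cohort_config(
      n_lpp = sim$n_lpp, n_hpp = sim$n_hpp, seed = config$seed,
      sampling_rate_hz = sim$sampling_rate_hz,
      bout_duration_s = sim$bout_duration_s,
      activities = sim$activities,
      missing_fraction = sim$missing_fraction %||% 0
    )
    cohort <- simulate_cohort(cfg)
    write_cohort(cohort, data_dir)
    res$simulate <- data_dir
  }

  if ("featurize" %in% stages) {
    acc_dir <- file.path(data_dir, "accelerometry")
    if (!dir.exists(acc_dir)) stop("featurize: no simulated data under ", data_dir)
    catalog <- activity_catalog()
    slug_map <- setNames(catalog$activity_name, activity_slug(catalog$activity_name))
    files <- sort(list.files(acc_dir, pattern = "\\.csv$", full.names = TRUE))
    bouts <- lapply(files, function(fp) {
      base <- sub("\\.csv$", "", basename(fp))
      subject <- sub("_.*$", "", base)
      act <- slug_map[[sub("^[^_]+_", "", base)]]
      read_bout(fp, subject_id = subject, activity_name = act)
    })
    feats <- extract_feature_table(bouts, catalog, window_s = config$featurize$window_s)
    write_feature_table(feats, file.path(out, "features.csv"))
    cal_dir <- file.path(data_dir, "calorimetry")
    mets <- NULL
    if (dir.exists(cal_dir)) {
      cal_files <- sort(list.files(cal_dir, pattern = "\\.csv$", full.names = TRUE))
      mets <- do.call(rbind, lapply(cal_files, function(fp) {
        base <- sub("\\.csv$", "", basename(fp))
        dat <- read.csv(fp)
        br <- breath_series(dat$time_s, dat$vo2_mlkgmin,
          subject_id = sub("_.*$", "", base),
          activity_name = slug_map[[sub("^[^_]+_", "", base)]]
        )
        ss <- steady_state_vo2(br)
        data.frame(
          subject_id = br$subject_id, activity_name = br$activity_name,
          mets = ss$mets, stringsAsFactors = FALSE
        )
      }))
      write.csv(mets, file.path(out, "mets.csv"), row.names = FALSE)
    }
    res$featurize <- file.path(out, "features.csv")
  }

  if ("run" %in% stages) {
    feats <- read_feature_table(file.path(out, "features.csv"))
    subjects <- read.csv(file.path(data_dir, "subjects.csv"), stringsAsFactors = FALSE)
    mets_path <- file.path(out, "mets.csv")
    mets <- if (file.exists(mets_path)) read.csv(mets_path, stringsAsFactors = FALSE) else NULL
    runres <- run_all_tasks(
      feats, subjects, mets,
      tasks = select_tasks(config$run$tasks), seed = config$seed,
      outer_k = config$run$outer_k, inner_k = config$run$inner_k,
      reduced_grid = isTRUE(config$run$reduced_grid)
    )
    write.csv(runres$results, file.path(out, "results.csv"), row.names = FALSE)
    if (!is.null(runres$importance)) {
      write.csv(runres$importance, file.path(out, "importance.csv"), row.names = FALSE)
    }
    confs <- lapply(names(runres$evals), function(nm) {
      cf <- runres$evals[[nm]]$confusion
      if (is.null(cf)) return(NULL)
      df <- as.data.frame(as.table(as.matrix(cf)), stringsAsFactors = FALSE)
      names(df) <- c("observed", "predicted", "count")[seq_len(ncol(df))]
      df$task <- nm
      df
    })
    confs <- Filter(Negate(is.null), confs)
    if (length(confs)) {
      write.csv(do.call(rbind, confs), file.path(out, "confusion.csv"), row.names = FALSE)
    }
    res$run <- runres$results
  }

  if ("transfer" %in% stages) {
    tr <- config$transfer
    if (is.null(tr)) stop("config error: missing block 'transfer'")
    feats <- read_feature_table(file.path(out, "features.csv"))
    subjects <- read.csv(file.path(data_dir, "subjects.csv"), stringsAsFactors = FALSE)
    task <- task_spec(
      tr$task_kind %||% "binary_type", tr$positive_class %||% "Locomotion",
      "boosted_trees", "ALL"
    )
    mode <- tr$mode %||% "loo"
    tres <- if (identical(mode, "loo")) {
      run_loo(feats, subjects, task, tr$train_group %||% "LPP",
        tr$test_group %||% "HPP",
        seed = config$seed, reduced_grid = TRUE
      )
    } else {
      run_lpo(feats, subjects, task, tr$train_group %||% "LPP",
        tr$test_group %||% "HPP",
        repeats = tr$repeats %||% 10,
        seed = config$seed, reduced_grid = TRUE
      )
    }
    write.csv(
      data.frame(
        mode = tres$mode, task = format(tres$task),
        train_group = tres$train_group, test_group = tres$test_group,
        repeat_index = seq_along(tres$scores), metric = tres$metric,
        score = tres$scores
      ),
      file.path(out, "transfer.csv"),
      row.names = FALSE
    )
    res$transfer <- tres
  }

  if ("report" %in% stages) {
    res_path <- file.path(out, "results.csv")
    if (!file.exists(res_path)) stop("report: no results.csv under ", out)
    results <- read.csv(res_path, stringsAsFactors = FALSE)
    results$task <- paste(results$task_kind, results$positive_class,
      results$algorithm, results$cohort,
      sep = "/"
    )
    agg <- do.call(rbind, lapply(split(results, results$task), function(d) {
      data.frame(
        task = d$task[1],
        folds = nrow(d),
        f1_mean = mean(d$f1), f1_sd = stats::sd(d$f1),
        auc_mean = mean(d$auc),
        balanced_accuracy_mean = mean(d$balanced_accuracy),
        accuracy_mean = mean(d$accuracy),
        rmse_mean = mean(d$rmse),
        stringsAsFactors = FALSE
      )
    }))
    rownames(agg) <- NULL
    write.csv(agg, file.path(out, "summary.csv"), row.names = FALSE)
    res$report <- agg
  }

  manifest <- list(
    package = "wristfunc",
    version = as.character(utils::packageVersion("wristfunc")),
    seed = config$seed,
    stages = stages,
    config = config,
    created = format(Sys.time(), tz = "UTC"),
    digests = as.list(tools::md5sum(sort(list.files(out,
      pattern = "\\.csv$",
      recursive = FALSE, full.names = TRUE
    ))))
  )
  names(manifest$digests) <- basename(names(manifest$digests))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  res$manifest <- manifest
  invisible(res)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `featurize`, `run`, `transfer`, `pipeline`
#' (all stages). Flags: `--config PATH` (required), `--out DIR`,
#' `--seed N`.
#'
#' @param args character vector (default: command-line arguments).
#' @return exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: wristfunc <simulate|featurize|run|transfer|pipeline> --config FILE [--out DIR] [--seed N]"
  if (length(args) < 1L) {
    message(usage)
    return(invisible(2L))
  }
  cmd <- args[1L]
  get_flag <- function(flag) {
    i <- which(args == flag)
    if (length(i) && i[1L] < length(args)) args[i[1L] + 1L] else NULL
  }
  config <- get_flag("--config")
  if (is.null(config)) {
    message("missing --config\n", usage)
    return(invisible(2L))
  }
  out <- get_flag("--out")
  seed <- get_flag("--seed")
  seed <- if (is.null(seed)) NULL else as.integer(seed)
  stages <- switch(cmd,
    simulate = "simulate",
    featurize = "featurize",
    run = "run",
    transfer = "transfer",
    report = "report",
    pipeline = c("simulate", "featurize", "run", "report"),
    {
      message("unknown command: ", cmd, "\n", usage)
      return(invisible(2L))
    }
  )
  status <- tryCatch(
    {
      pipeline(config, out = out, stages = stages, seed = seed)
      0L
    },
    error = function(e) {
      message("error: ", conditionMessage(e))
      1L
    }
  )
  invisible(status)
}
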