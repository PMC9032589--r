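#' Build a design matrix for one modeling task
#'
#' Filters the feature table to the task's cohort, constructs the target
#' (binary one-vs-rest indicator, multiclass activity label, or
#' steady-state METs for the regression task) and attaches class weights
#' inversely proportional to class frequency, `w_c = N / (K * N_c)`;
#' regression rows get unit weights.
#'
#' @param feature_table table from [extract_feature_table()] (one row per
#'   window, 49 features plus label columns).
#' @param task a [task_spec()].
#' @param subjects data.frame with `subject_id`, `group` (and typically
#'   `sppb_score`).
#' @param mets for `regression_ee`: data.frame `subject_id`,
#'   `activity_name`, `mets` (steady-state METs per bout).
#' @return list with `x` (matrix), `y`, `weights`, `subject_id`, `group`,
#'   `task`.
#' @export
build_design <- function(feature_table, task, subjects, mets = NULL) {
  stopifnot(inherits(task, "task_spec"))
  need <- c(feature_names(), "subject_id", "activity_name")
  missing_cols <- setdiff(need, names(feature_table))
  if (length(missing_cols)) stop("feature table lacks: ", paste(missing_cols, collapse = ", "))
  grp <- subjects$group[match(feature_table$subject_id, subjects$subject_id)]
  if (anyNA(grp)) stop("feature table contains subjects missing from the subject table")
  keep <- if (task$cohort == "ALL") rep(TRUE, nrow(feature_table)) else grp == task$cohort
  tab <- feature_table[keep, , drop = FALSE]
  grp <- grp[keep]
  if (nrow(tab) == 0L) stop("no rows left after cohort filter ", task$cohort)
  x <- as.matrix(tab[, feature_names()])
  if (any(!is.finite(x))) stop("non-finite feature values in design")
  weights <- rep(1, nrow(tab))
  if (task$task_kind == "regression_ee") {
    if (is.null(mets)) stop("regression_ee requires a mets table")
    key <- paste(tab$subject_id, canonical_activity_name(tab$activity_name))
    mkey <- paste(mets$subject_id, canonical_activity_name(mets$activity_name))
    y <- mets$mets[match(key, mkey)]
    if (anyNA(y)) stop("missing steady-state METs for some bouts")
  } else {
    if (task$task_kind == "binary_type") {
      cats <- tab$type_category
      if (!task$positive_class %in% TYPE_LEVELS) stop("unknown positive_class")
    } else if (task$task_kind == "binary_intensity") {
      cats <- tab$intensity_category
      if (!task$positive_class %in% INTENSITY_LEVELS) stop("unknown positive_class")
    } else {
      cats <- NULL
    }
    if (!is.null(cats)) {
      y <- factor(ifelse(cats == task$positive_class, "pos", "neg"), levels = c("neg", "pos"))
    } else {
      y <- factor(canonical_activity_name(tab$activity_name))
    }
    if (nlevels(droplevels(y)) < 2L) {
      stop("single-class cohort after filtering for ", format(task))
    }
    counts <- table(y)
    counts <- counts[counts > 0]
    k <- length(counts)
    w_class <- length(y) / (k * counts)
    weights <- as.numeric(w_class[as.character(y)])
  }
  list(
    x = x, y = y, weights = weights,
    subject_id = as.character(tab$subject_id), group = grp, task = task
  )
}

#' Subject-level cross-validation folds
#'
#' Assigns each subject (never each window) to one of `k` folds. When a
#' group label is given the assignment is stratified by group so the
#' LPP/HPP mixture stays stable across folds.
#'
#' @param subject_ids character vector of unique subject ids.
#' @param k number of folds.
#' @param seed RNG seed for the shuffle.
#' @param group optional group label per subject for stratification.
#' @return named integer vector: fold per subject.
#' @export
make_subject_folds <- function(subject_ids, k, seed = 1, group = NULL) {
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stop("subject_ids must be unique")
  if (length(subject_ids) < k) {
    stop(sprintf("need >= %d subjects for %d folds, have %d", k, k, length(subject_ids)))
  }
  folds <- integer(length(subject_ids))
  names(folds) <- subject_ids
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  strata <- if (is.null(group)) rep("all", length(subject_ids)) else as.character(group)
  offset <- 0L
  for (s in unique(strata)) {
    ids <- sample(subject_ids[strata == s])
    folds[ids] <- ((seq_along(ids) - 1L + offset) %% k) + 1L
    offset <- offset + length(ids)
  }
  folds
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

assert_disjoint_subjects <- function(train_ids, test_ids) {
  overlap <- intersect(unique(train_ids), unique(test_ids))
  if (length(overlap)) {
    stop("subject leakage between train and test: ", paste(overlap, collapse = ", "))
  }
  invisible(TRUE)
}

design_rows <- function(design, rows) {
  list(
    x = design$x[rows, , drop = FALSE],
    y = if (is.factor(design$y)) droplevels(design$y[rows]) else design$y[rows],
    weights = design$weights[rows],
    subject_id = design$subject_id[rows],
    group = design$group[rows],
    task = design$task
  )
}

fit_task_model <- function(design, params) {
  if (design$task$algorithm == "boosted_trees") {
    fit_boosted_trees(
      design$x, design$y, design$weights,
      max_depth = params$max_depth %||% 6,
      nrounds = params$nrounds %||% 100,
      eta = params$eta %||% 0.1
    )
  } else {
    fit_l1_linear(design$x, design$y, design$weights, lambda = params$lambda)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

score_task_model <- function(model, design, positive = "pos") {
  kind <- task_metric_kind(design$task)
  if (kind == "regression") {
    pred <- predict(model, design$x)
    compute_metrics(design$y, pred, kind = "regression")
  } else if (kind == "binary") {
    y <- factor(design$y, levels = c("neg", "pos"))
    score <- predict(model, design$x, type = "response")
    pred <- factor(ifelse(score >= 0.5, "pos", "neg"), levels = c("neg", "pos"))
    compute_metrics(y, pred, score, kind = "binary", positive = positive)
  } else {
    prob <- predict(model, design$x, type = "response")
    pred <- colnames(prob)[max.col(prob, ties.method = "first")]
    compute_metrics(design$y, pred, prob, kind = "multiclass")
  }
}

task_metric_kind <- function(task) {
  switch(task$task_kind,
    regression_ee = "regression",
    multiclass_activity = "multiclass",
    "binary"
  )
}

default_grid_for <- function(task, reduced = FALSE) {
  if (task$algorithm == "boosted_trees") {
    if (task$task_kind == "multiclass_activity" && reduced) {
      default_gbt_grid(reduced = TRUE)[1L] # one-vs-rest fits are costly
    } else {
      default_gbt_grid(reduced = reduced)
    }
  } else {
    default_lasso_grid(n_lambda = if (reduced) 8 else 20)
  }
}

# Inner-loop hyperparameter selection: mean validation F1 (classification)
# or RMSE (regression) over subject-wise inner folds. For the L1 path the
# full regularization path is fitted once per fold and every penalty is
# scored from it.
select_hyperparams <- function(design, grid, inner_k, seed) {
  if (length(grid) == 1L) return(grid[[1L]])
  kind <- task_metric_kind(design$task)
  maximize <- kind != "regression"
  metric_name <- if (kind == "regression") "rmse" else "f1"
  sub_ids <- unique(design$subject_id)
  inner_k <- min(inner_k, length(sub_ids)) # cannot have more folds than subjects
  if (inner_k < 2L) return(grid[[1L]])
  sub_group <- design$group[match(sub_ids, design$subject_id)]
  folds <- make_subject_folds(sub_ids, inner_k, seed = seed, group = sub_group)
  scores <- matrix(NA_real_, nrow = inner_k, ncol = length(grid))
  for (fi in seq_len(inner_k)) {
    val_subjects <- names(folds)[folds == fi]
    tr_rows <- !(design$subject_id %in% val_subjects)
    assert_disjoint_subjects(design$subject_id[tr_rows], design$subject_id[!tr_rows])
    d_tr <- design_rows(design, which(tr_rows))
    d_val <- design_rows(design, which(!tr_rows))
    if (is.factor(design$y)) {
      d_tr$y <- factor(d_tr$y, levels = levels(design$y))
      d_val$y <- factor(d_val$y, levels = levels(design$y))
      if (nlevels(droplevels(d_tr$y)) < 2L) next
    }
    if (design$task$algorithm == "l1_linear") {
      lambdas <- vapply(grid, `[[`, numeric(1), "lambda")
      path <- fit_l1_linear(d_tr$x, d_tr$y, d_tr$weights,
        lambda = NULL, lambda_grid = lambdas
      )
      for (gi in seq_along(grid)) {
        path$lambda <- lambdas[gi]
        scores[fi, gi] <- score_task_model(path, d_val)[[metric_name]]
      }
    } else {
      for (gi in seq_along(grid)) {
        m <- fit_task_model(d_tr, grid[[gi]])
        scores[fi, gi] <- score_task_model(m, d_val)[[metric_name]]
      }
    }
  }
  mean_scores <- colMeans(scores, na.rm = TRUE)
  best <- if (maximize) which.max(mean_scores) else which.min(mean_scores)
  grid[[best]]
}

#' Nested cross-validation for one task
#'
#' Outer folds estimate generalization, inner folds select hyperparameters;
#' both partition subjects, never windows, so no subject contributes to
#' both training and evaluation anywhere. The selected configuration is
#' refitted on the full outer-training set and scored once on the held-out
#' outer fold; the result aggregates the outer scores as mean and SD and
#' carries a pooled confusion summary plus an importance ranking averaged
#' over the outer refits.
#'
#' @param design from [build_design()].
#' @param outer_k,inner_k fold counts (study configuration: 5 and 5).
#' @param seed master seed; all fold assignments derive from it.
#' @param grid hyperparameter grid (list of parameter lists); default
#'   depends on the task's algorithm.
#' @param reduced_grid use the small default grid (desk-scale runs).
#' @return an `eval_result` list.
#' @export
nested_cv <- function(design, outer_k = 5, inner_k = 5, seed = 1,
                      grid = NULL, reduced_grid = FALSE) {
  task <- design$task
  if (is.null(grid)) grid <- default_grid_for(task, reduced = reduced_grid)
  sub_ids <- unique(design$subject_id)
  if (length(sub_ids) < outer_k) {
    stop(sprintf("need >= %d subjects, have %d", outer_k, length(sub_ids)))
  }
  sub_group <- design$group[match(sub_ids, design$subject_id)]
  strat <- if (task$cohort == "ALL") sub_group else NULL
  folds <- make_subject_folds(sub_ids, outer_k, seed = seed, group = strat)
  kind <- task_metric_kind(task)
  per_fold <- list()
  confusion <- NULL
  importances <- list()
  best_params <- list()
  for (fo in seq_len(outer_k)) {
    test_subjects <- names(folds)[folds == fo]
    tr_rows <- which(!(design$subject_id %in% test_subjects))
    te_rows <- which(design$subject_id %in% test_subjects)
    assert_disjoint_subjects(design$subject_id[tr_rows], design$subject_id[te_rows])
    d_tr <- design_rows(design, tr_rows)
    d_te <- design_rows(design, te_rows)
    if (is.factor(design$y)) {
      d_tr$y <- factor(d_tr$y, levels = levels(design$y))
      d_te$y <- factor(d_te$y, levels = levels(design$y))
    }
    params <- select_hyperparams(d_tr, grid, inner_k, seed = seed * 1000L + fo)
    model <- fit_task_model(d_tr, params)
    met <- score_task_model(model, d_te)
    per_fold[[fo]] <- met
    best_params[[fo]] <- params
    if (!is.null(met$confusion)) {
      confusion <- if (is.null(confusion)) met$confusion else confusion + met$confusion
    }
    imp <- tryCatch(
      suppressWarnings(rank_importance(model, top_k = ncol(design$x))),
      error = function(e) NULL
    )
    importances[[fo]] <- imp
  }
  metric_names <- if (kind == "regression") "rmse" else c("f1", "auc", "balanced_accuracy", "accuracy")
  summarize <- function(nm) {
    v <- vapply(per_fold, function(m) as.numeric(m[[nm]][1L]), numeric(1))
    c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
  }
  summary_tab <- vapply(metric_names, summarize, numeric(2))
  imp_agg <- aggregate_importance(importances)
  structure(
    list(
      task = task, per_fold = per_fold, metrics = summary_tab,
      confusion = confusion, importance = imp_agg,
      best_params = best_params, outer_k = outer_k, inner_k = inner_k,
      seed = seed
    ),
    class = "eval_result"
  )
}

aggregate_importance <- function(importances) {
  importances <- Filter(Negate(is.null), importances)
  if (length(importances) == 0L) return(NULL)
  allf <- unique(unlist(lapply(importances, `[[`, "feature")))
  acc <- setNames(numeric(length(allf)), allf)
  for (imp in importances) acc[imp$feature] <- acc[imp$feature] + imp$importance
  acc <- acc / length(importances)
  if (sum(acc) > 0) acc <- acc / sum(acc)
  ord <- order(acc, decreasing = TRUE)
  data.frame(
    feature = names(acc)[ord], importance = unname(acc[ord]),
    rank = seq_along(acc), stringsAsFactors = FALSE
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat("<eval_result> ", format(x$task), "\n", sep = "")
  print(round(x$metrics, 4))
  invisible(x)
}

#' Leave-one-group-out transfer evaluation
#'
#' Trains on all subjects of one performance group (hyperparameters tuned
#' by subject-wise inner cross-validation within that group only) and
#' evaluates once on all subjects of the other group.
#'
#' @param feature_table window-level feature table.
#' @param subjects subject table with `group`.
#' @param task a [task_spec()] (its cohort field is ignored; groups come
#'   from the arguments).
#' @param train_group,test_group "LPP" or "HPP", distinct.
#' @param seed master seed.
#' @param inner_k inner folds for tuning.
#' @param grid hyperparameter grid.
#' @param mets METs table for regression tasks.
#' @param reduced_grid use the small default grid.
#' @return a `transfer_result`.
#' @export
run_loo <- function(feature_table, subjects, task, train_group, test_group,
                    seed = 1, inner_k = 5, grid = NULL, mets = NULL,
                    reduced_grid = FALSE) {
  if (identical(train_group, test_group)) {
    stop("train and test groups must differ (use nested_cv for within-group)")
  }
  design <- build_design(feature_table, retarget_cohort(task, "ALL"), subjects, mets)
  tr_rows <- which(design$group == train_group)
  te_rows <- which(design$group == test_group)
  if (!length(tr_rows) || !length(te_rows)) stop("empty train or test group")
  assert_disjoint_subjects(design$subject_id[tr_rows], design$subject_id[te_rows])
  if (is.null(grid)) grid <- default_grid_for(task, reduced = reduced_grid)
  d_tr <- design_rows(design, tr_rows)
  d_te <- design_rows(design, te_rows)
  if (is.factor(design$y)) {
    d_tr$y <- factor(d_tr$y, levels = levels(design$y))
    d_te$y <- factor(d_te$y, levels = levels(design$y))
  }
  params <- select_hyperparams(d_tr, grid, inner_k, seed = seed)
  model <- fit_task_model(d_tr, params)
  met <- score_task_model(model, d_te)
  kind <- task_metric_kind(task)
  score <- if (kind == "regression") met$rmse else met$f1
  structure(
    list(
      mode = "LOO", task = task, train_group = train_group,
      test_group = test_group, repeats = 1L, scores = score,
      mean = score, metric = if (kind == "regression") "rmse" else "f1",
      detail = list(met), params = params, seed = seed
    ),
    class = "transfer_result"
  )
}

retarget_cohort <- function(task, cohort) {
  task$cohort <- cohort
  task
}

#' Leave-partial-group-out transfer evaluation
#'
#' Per repeat, the `split_group` subjects are randomly halved at the
#' subject level; the model is trained on all of `full_group` plus one
#' half, tuned by subject-wise inner cross-validation on that composite,
#' and evaluated on the held-out half. The mean score over repeats is
#' reported.
#'
#' @inheritParams run_loo
#' @param full_group group included in training in its entirety.
#' @param split_group group that is split between training and test.
#' @param frac fraction of `split_group` subjects added to training,
#'   in (0, 1).
#' @param repeats number of random splits (study configuration: 10).
#' @return a `transfer_result`.
#' @export
run_lpo <- function(feature_table, subjects, task, full_group, split_group,
                    frac = 0.5, repeats = 10, seed = 1, inner_k = 5,
                    grid = NULL, mets = NULL, reduced_grid = FALSE) {
  if (frac <= 0 || frac >= 1) stop("frac must be in (0, 1)")
  if (identical(full_group, split_group)) stop("groups must differ")
  design <- build_design(feature_table, retarget_cohort(task, "ALL"), subjects, mets)
  split_subjects <- unique(design$subject_id[design$group == split_group])
  if (length(split_subjects) < 2L) stop("split_group needs >= 2 subjects")
  if (is.null(grid)) grid <- default_grid_for(task, reduced = reduced_grid)
  kind <- task_metric_kind(task)
  scores <- numeric(repeats)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    shuffled <- sample(split_subjects)
    n_in <- round(frac * length(shuffled))
    n_in <- max(1L, min(length(shuffled) - 1L, n_in))
    in_train <- shuffled[seq_len(n_in)]
    held_out <- setdiff(shuffled, in_train)
    tr_rows <- which(design$group == full_group | design$subject_id %in% in_train)
    te_rows <- which(design$subject_id %in% held_out)
    assert_disjoint_subjects(design$subject_id[tr_rows], design$subject_id[te_rows])
    d_tr <- design_rows(design, tr_rows)
    d_te <- design_rows(design, te_rows)
    if (is.factor(design$y)) {
      d_tr$y <- factor(d_tr$y, levels = levels(design$y))
      d_te$y <- factor(d_te$y, levels = levels(design$y))
    }
    params <- select_hyperparams(d_tr, grid, inner_k, seed = seed * 100L + r)
    model <- fit_task_model(d_tr, params)
    met <- score_task_model(model, d_te)
    scores[r] <- if (kind == "regression") met$rmse else met$f1
  }
  structure(
    list(
      mode = "LPO", task = task, train_group = full_group,
      test_group = split_group, frac = frac, repeats = repeats,
      scores = scores, mean = mean(scores),
      metric = if (kind == "regression") "rmse" else "f1", seed = seed
    ),
    class = "transfer_result"
  )
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf(
    "<transfer_result> %s %s: train %s -> test %s, %d repeat(s), mean %s = %.4f\n",
    x$mode, format(x$task), x$train_group, x$test_group, x$repeats,
    x$metric, x$mean
  ))
  invisible(x)
}

#' Run every configuration of the experiment grid
#'
#' Enumerates the 51 model configurations and evaluates each with
#' [nested_cv()], returning one row per task and outer fold.
#'
#' @param feature_table window-level feature table.
#' @param subjects subject table.
#' @param mets METs table for the regression tasks (if NULL, regression
#'   tasks are skipped with a message).
#' @param tasks task grid (default [enumerate_model_configs()]).
#' @param seed master seed.
#' @param outer_k,inner_k fold counts.
#' @param reduced_grid use small hyperparameter grids.
#' @return list: `results` (data.frame, task x fold x metrics),
#'   `importance` (per-task ranking), `evals` (raw `eval_result`s).
#' @export
run_all_tasks <- function(feature_table, subjects, mets = NULL,
                          tasks = enumerate_model_configs(), seed = 1,
                          outer_k = 5, inner_k = 5, reduced_grid = FALSE) {
  rows <- list()
  imps <- list()
  evals <- list()
  for (ti in seq_len(nrow(tasks))) {
    task <- task_spec(
      tasks$task_kind[ti],
      if (is.na(tasks$positive_class[ti])) NA_character_ else tasks$positive_class[ti],
      tasks$algorithm[ti], tasks$cohort[ti]
    )
    if (task$task_kind == "regression_ee" && is.null(mets)) {
      message("skipping ", format(task), ": no METs table")
      next
    }
    design <- build_design(feature_table, task, subjects, mets)
    ev <- nested_cv(design,
      outer_k = outer_k, inner_k = inner_k,
      seed = seed + ti, reduced_grid = reduced_grid
    )
    evals[[format(task)]] <- ev
    for (fo in seq_along(ev$per_fold)) {
      m <- ev$per_fold[[fo]]
      rows[[length(rows) + 1L]] <- data.frame(
        task_kind = task$task_kind,
        positive_class = task$positive_class,
        algorithm = task$algorithm,
        cohort = task$cohort,
        fold = fo,
        f1 = if (!is.null(m$f1)) as.numeric(m$f1[1L]) else NA_real_,
        auc = if (!is.null(m$auc)) as.numeric(m$auc[1L]) else NA_real_,
        balanced_accuracy = if (!is.null(m$balanced_accuracy)) m$balanced_accuracy else NA_real_,
        accuracy = if (!is.null(m$accuracy)) m$accuracy else NA_real_,
        rmse = if (!is.null(m$rmse)) m$rmse else NA_real_,
        stringsAsFactors = FALSE
      )
    }
    if (!is.null(ev$importance)) {
      imp <- ev$importance
      imp$task <- format(task)
      imps[[length(imps) + 1L]] <- imp
    }
  }
  list(
    results = do.call(rbind, rows),
    importance = if (length(imps)) do.call(rbind, imps) else NULL,
    evals = evals
  )
}
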