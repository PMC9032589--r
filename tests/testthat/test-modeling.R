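# Modeling tests run on a cached 20-subject cohort with 120 s bouts at
# 50 Hz (2 windows per bout) so the whole file stays desk-scale.

bundle_modeling <- function() {
  small_cohort_bundle(
    seed = 2024, n_lpp = 8, n_hpp = 12, bout_s = 120, rate = 50,
    activities = c(
      "LEISURE WALK", "RAPID WALK", "TV WATCHING", "COMPUTER WORK",
      "STRETCHING YOGA", "STRENGTH EXERCISE CHEST PRESS",
      "MOPPING", "WASHING DISHES"
    )
  )
}

test_that("build_design: targets, inverse-frequency weights, cohort filter", {
  b <- bundle_modeling()
  task <- task_spec("binary_type", "Locomotion", "boosted_trees", "ALL")
  d <- build_design(b$features, task, b$subjects)
  expect_equal(ncol(d$x), 49)
  expect_s3_class(d$y, "factor")
  expect_equal(levels(d$y), c("neg", "pos"))
  # w_c = N / (K * N_c): ratio of weights = inverse ratio of counts
  n_pos <- sum(d$y == "pos")
  n_neg <- sum(d$y == "neg")
  w_pos <- unique(d$weights[d$y == "pos"])
  w_neg <- unique(d$weights[d$y == "neg"])
  expect_length(w_pos, 1)
  expect_equal(w_pos / w_neg, n_neg / n_pos)
  expect_equal(w_pos, length(d$y) / (2 * n_pos))

  # synthetic 90/10 check of the weight formula
  ft_toy <- b$features[1:100, ]
  ft_toy$type_category <- rep(c("Lifestyle", "Locomotion"), c(90, 10))
  subj_all <- b$subjects
  d_toy <- build_design(ft_toy, task, subj_all)
  expect_equal(
    unique(d_toy$weights[ft_toy$type_category == "Locomotion"]) /
      unique(d_toy$weights[ft_toy$type_category == "Lifestyle"]),
    9
  )

  d_lpp <- build_design(b$features, task_spec("binary_type", "Locomotion", cohort = "LPP"),
    b$subjects)
  expect_true(all(d_lpp$group == "LPP"))
  expect_lt(nrow(d_lpp$x), nrow(d$x))

  expect_error(
    build_design(b$features, task_spec("regression_ee"), b$subjects),
    "mets"
  )
  # single-class cohort after filtering errors out
  ft_one <- b$features[b$features$type_category == "Locomotion", ]
  expect_error(build_design(ft_one, task, b$subjects), "single-class")
})

test_that("compute_metrics matches hand-computed values", {
  perfect <- compute_metrics(
    factor(c("neg", "pos", "pos"), levels = c("neg", "pos")),
    factor(c("neg", "pos", "pos"), levels = c("neg", "pos")),
    c(0.1, 0.9, 0.8),
    kind = "binary"
  )
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$balanced_accuracy, 1)

  # TP=8 FP=2 FN=4 TN=6 -> precision .8, recall 2/3, F1 = 8/11
  y_true <- factor(rep(c("pos", "neg"), c(12, 8)), levels = c("neg", "pos"))
  y_pred <- factor(c(rep("pos", 8), rep("neg", 4), rep("pos", 2), rep("neg", 6)),
    levels = c("neg", "pos")
  )
  m <- compute_metrics(y_true, y_pred, kind = "binary")
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 8 / 11)
  expect_equal(m$accuracy, 14 / 20)
  expect_equal(m$balanced_accuracy, (2 / 3 + 6 / 8) / 2)

  expect_equal(compute_metrics(c(1, 2, 3), c(1.5, 2.5, 3.5), kind = "regression")$rmse, 0.5)
  expect_error(compute_metrics(numeric(0), numeric(0), kind = "regression"), "empty")

  # F1 invariant to duplicating every sample
  m2 <- compute_metrics(rep(y_true, 2), rep(y_pred, 2), kind = "binary")
  expect_equal(m2$f1, m$f1)

  # rank-based AUC with ties equals midrank formula
  is_pos <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  sc <- c(0.9, 0.5, 0.5, 0.1, 0.3)
  # pairwise: 4 wins + 1 tie (0.5) + 1 loss over 6 pos/neg pairs = 4.5/6
  expect_equal(roc_auc(is_pos, sc), 4.5 / 6)
})

test_that("boosted trees: determinism, planted feature, null AUC", {
  set.seed(21)
  n <- 300
  x <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("f", 1:10)))
  y <- factor(ifelse(x[, 4] > 0, "pos", "neg"), levels = c("neg", "pos"))
  m1 <- fit_boosted_trees(x, y, nrounds = 30, max_depth = 3)
  m2 <- fit_boosted_trees(x, y, nrounds = 30, max_depth = 3)
  expect_identical(predict(m1, x), predict(m2, x))
  expect_equal(rank_importance(m1, top_k = 1)$feature, "f4")
  expect_gt(rank_importance(m1, top_k = 1)$importance, 0.8)

  # pure-noise labels: held-out AUC near 0.5
  y_noise <- factor(sample(c("neg", "pos"), n, TRUE), levels = c("neg", "pos"))
  tr <- 1:200
  mn <- fit_boosted_trees(x[tr, ], y_noise[tr], nrounds = 30, max_depth = 3)
  auc <- roc_auc(y_noise[-tr] == "pos", predict(mn, x[-tr, ]))
  expect_gt(auc, 0.3)
  expect_lt(auc, 0.7)

  # regression objective
  yr <- 2 * x[, 1] - x[, 2] + rnorm(n, 0, 0.1)
  mr <- fit_boosted_trees(x, yr, nrounds = 150, max_depth = 3, eta = 0.2)
  expect_lt(sqrt(mean((predict(mr, x) - yr)^2)), 0.5)

  expect_error(fit_boosted_trees(cbind(x, NA), y), "non-finite")

  # multiclass one-vs-rest
  y3 <- factor(c("a", "b", "c")[1 + (x[, 1] > 0) + (x[, 2] > 0)])
  m3 <- fit_boosted_trees(x, y3, nrounds = 30, max_depth = 3)
  pr <- predict(m3, x)
  expect_equal(dim(pr), c(n, 3))
  expect_equal(rowSums(pr), rep(1, n))
  expect_gt(mean(predict(m3, x, type = "class") == y3), 0.9)
})

test_that("l1 linear: shrinkage limits, unpenalized oracle, support recovery", {
  set.seed(31)
  n <- 200
  x <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("f", 1:8)))
  beta <- c(2, -1.5, 1, 0, 0, 0, 0, 0)
  y <- drop(x %*% beta) + rnorm(n, 0, 0.3)

  # huge penalty: all slopes zero, prediction = mean
  m_big <- fit_l1_linear(x, y, lambda = 1e4, lambda_grid = 1e4)
  expect_equal(unname(coef(m_big)[-1]), rep(0, 8))
  expect_equal(unique(round(predict(m_big, x), 10)), round(mean(y), 10))

  # lambda ~ 0 matches the least-squares oracle
  m0 <- fit_l1_linear(x, y, lambda = 1e-6, lambda_grid = c(1, 0.1, 1e-6))
  ls <- coef(lm(y ~ x))
  expect_equal(unname(coef(m0)[-1]), unname(ls[-1]), tolerance = 1e-2)

  # moderate penalty keeps the planted support
  m_mid <- fit_l1_linear(x, y, lambda = 0.1)
  cf <- coef(m_mid)[-1]
  expect_true(all(abs(cf[1:3]) > 0.5))
  expect_true(all(abs(cf[4:8]) < 0.2))

  # constant columns dropped with warning
  xc <- cbind(x, const = 1)
  expect_warning(mc <- fit_l1_linear(xc, y, lambda = 0.1), "constant")
  expect_equal(unname(coef(mc)["const"]), 0)

  # binomial path
  yb <- factor(ifelse(x[, 1] + rnorm(n, 0, 0.5) > 0, "pos", "neg"), levels = c("neg", "pos"))
  mb <- fit_l1_linear(x, yb, lambda = 0.01)
  expect_gt(roc_auc(yb == "pos", predict(mb, x)), 0.9)
  expect_warning(rank_importance(mb), "coefficient")
})

test_that("nested_cv: subject-exclusive folds, separable task, permutation null", {
  b <- bundle_modeling()
  task <- task_spec("binary_type", "Locomotion", "boosted_trees", "ALL")
  d <- build_design(b$features, task, b$subjects)
  ev <- nested_cv(d, outer_k = 5, inner_k = 3, seed = 1,
    grid = default_gbt_grid(reduced = TRUE))
  expect_s3_class(ev, "eval_result")
  expect_length(ev$per_fold, 5)
  expect_true(all(is.finite(ev$metrics["mean", ])))
  # separable by construction: locomotion signatures are distinct
  expect_gte(ev$metrics["mean", "f1"], 0.95)
  expect_false(is.null(ev$importance))
  expect_equal(sum(ev$importance$importance), 1, tolerance = 1e-8)

  # labels shuffled within subjects -> chance-level AUC
  d_null <- d
  set.seed(5)
  d_null$y <- sample(d$y)
  ev_null <- nested_cv(d_null, outer_k = 5, inner_k = 3, seed = 2,
    grid = default_gbt_grid(reduced = TRUE)[1])
  expect_gt(ev_null$metrics["mean", "auc"], 0.35)
  expect_lt(ev_null$metrics["mean", "auc"], 0.65)

  # too few subjects
  keep <- d$subject_id %in% unique(d$subject_id)[1:3]
  few <- wristfunc:::design_rows(d, which(keep))
  expect_error(nested_cv(few, outer_k = 5), "subjects")
})

test_that("make_subject_folds partitions subjects and stratifies groups", {
  ids <- sprintf("S%02d", 1:20)
  grp <- rep(c("LPP", "HPP"), each = 10)
  folds <- make_subject_folds(ids, 5, seed = 3, group = grp)
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(as.integer(table(folds)), rep(4L, 5))
  for (f in 1:5) {
    expect_equal(sum(grp[match(names(folds)[folds == f], ids)] == "LPP"), 2)
  }
  expect_identical(folds, make_subject_folds(ids, 5, seed = 3, group = grp))
  expect_error(make_subject_folds(ids[1:3], 5), "subjects")
})

test_that("LOO and LPO transfer obey their partition contracts", {
  b <- bundle_modeling()
  task <- task_spec("binary_type", "Locomotion", "boosted_trees", "ALL")
  grid1 <- default_gbt_grid(reduced = TRUE)[1]

  loo <- run_loo(b$features, b$subjects, task, "LPP", "HPP", seed = 1, grid = grid1)
  expect_equal(loo$repeats, 1L)
  expect_true(is.finite(loo$mean))
  expect_error(run_loo(b$features, b$subjects, task, "LPP", "LPP"), "differ")

  lpo <- run_lpo(b$features, b$subjects, task, "LPP", "HPP",
    repeats = 3, seed = 1, grid = grid1)
  expect_length(lpo$scores, 3)
  expect_equal(lpo$mean, mean(lpo$scores))
  lpo2 <- run_lpo(b$features, b$subjects, task, "LPP", "HPP",
    repeats = 3, seed = 1, grid = grid1)
  expect_identical(lpo$scores, lpo2$scores) # same master seed, same splits
  expect_error(
    run_lpo(b$features, b$subjects, task, "LPP", "HPP", frac = 1.2),
    "frac"
  )
})

test_that("rank_importance normalizes, clips top_k, flags linear models", {
  set.seed(41)
  x <- matrix(rnorm(600), 100, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- factor(ifelse(x[, 2] > 0, "pos", "neg"), levels = c("neg", "pos"))
  m <- fit_boosted_trees(x, y, nrounds = 20, max_depth = 2)
  imp <- rank_importance(m, top_k = 100)
  expect_equal(nrow(imp), 6) # clipped to available features
  expect_equal(sum(imp$importance), 1)
  expect_equal(imp$feature[1], "f2")
  expect_equal(attr(imp, "basis"), "gain")
})
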