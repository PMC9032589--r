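test_that("subject SPPB draws respect group ranges and the clipped-normal mean", {
  cfg <- cohort_config(n_lpp = 2, n_hpp = 2, seed = 1, bout_duration_s = 120)
  set.seed(101)
  lpp <- replicate(2000, simulate_subject(cfg, "LPP")$sppb_score)
  hpp <- replicate(2000, simulate_subject(cfg, "HPP")$sppb_score)
  expect_true(all(lpp >= 0 & lpp <= 9))
  expect_true(all(hpp %in% 10:12))
  # analytic oracle for E[clip(round(N(7.7, 1.8)), 0, 9)]
  ks <- 0:9
  pk <- pnorm(ks + 0.5, 7.7, 1.8) - pnorm(ks - 0.5, 7.7, 1.8)
  pk[1] <- pnorm(0.5, 7.7, 1.8)
  pk[10] <- 1 - pnorm(8.5, 7.7, 1.8)
  mu_oracle <- sum(ks * pk)
  expect_equal(mean(lpp), mu_oracle, tolerance = 0.03) # MC/analytic agreement
  expect_lt(abs(mean(lpp) - 7.7), 0.35) # shift from clipping stays modest
  expect_lt(abs(mean(hpp) - 11.3), 0.25)
})

test_that("simulate_bout: sedentary quietness, locomotion df loop-back, determinism", {
  sig <- activity_signatures()
  ge <- default_group_effects()
  subj <- data.frame(
    subject_id = "S1", sppb_score = 11L, group = "HPP",
    met_effect = 0.3, stringsAsFactors = FALSE
  )

  sed <- sig[sig$activity_name == "COMPUTER WORK", ]
  sb <- simulate_bout(subj, sed, ge$HPP, duration_s = 120, rate_hz = 50, seed = 5)
  f_sed <- suppressWarnings(extract_features(segment_windows(sb$bout)[[1]]))
  expect_lt(f_sed[["sdvm"]], 0.05)
  expect_equal(f_sed[["mvm"]], 1, tolerance = 0.05)

  walk <- sig[sig$activity_name == "LEISURE WALK", ]
  for (grp in c("HPP", "LPP")) {
    wb <- simulate_bout(subj, walk, ge[[grp]], duration_s = 120, rate_hz = 50, seed = 6)
    f_walk <- extract_features(segment_windows(wb$bout)[[1]])
    expect_equal(f_walk[["df"]], walk$f0_hz * ge[[grp]]$freq_scale, tolerance = 1 / 60 + 1e-9)
    expect_gt(f_walk[["p625"]], 0.5)
  }

  b1 <- simulate_bout(subj, walk, ge$HPP, duration_s = 120, rate_hz = 50, seed = 7)
  b2 <- simulate_bout(subj, walk, ge$HPP, duration_s = 120, rate_hz = 50, seed = 7)
  expect_identical(b1$bout$z, b2$bout$z)
  expect_identical(b1$breaths$vo2, b2$breaths$vo2)
  expect_identical(b1$met_target, b2$met_target)

  expect_error(simulate_bout(subj, walk, ge$HPP, duration_s = 60), ">= 120")
})

test_that("simulate_cohort: counts, missingness, determinism", {
  cfg <- cohort_config(
    n_lpp = 2, n_hpp = 2, seed = 3, sampling_rate_hz = 20,
    bout_duration_s = 120, activities = c("LEISURE WALK", "TV WATCHING")
  )
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh$subjects), 4)
  expect_length(coh$bouts, 8) # subjects x activities
  expect_equal(coh$subjects$group, c("LPP", "LPP", "HPP", "HPP"))
  expect_equal(nrow(coh$ground_truth), 8)
  expect_true(all(coh$ground_truth$met_target >= 0.5))

  coh2 <- simulate_cohort(cfg)
  expect_identical(coh$bouts[[5]]$x, coh2$bouts[[5]]$x)
  expect_identical(coh$subjects, coh2$subjects)

  cfg_miss <- cohort_config(
    n_lpp = 5, n_hpp = 5, seed = 4, sampling_rate_hz = 20,
    bout_duration_s = 120, activities = c("LEISURE WALK", "TV WATCHING", "MOPPING"),
    missing_fraction = 0.3
  )
  cm <- simulate_cohort(cfg_miss)
  n_expected <- 30
  expect_lt(length(cm$bouts), n_expected)
  expect_gt(length(cm$bouts), n_expected * 0.4)
  # downstream still runs on the incomplete cohort
  ft <- extract_feature_table(cm$bouts)
  expect_gt(nrow(ft), 0)
})

test_that("steady-state estimator recovers generator MET targets (loop-back)", {
  cfg <- cohort_config(
    n_lpp = 2, n_hpp = 2, seed = 11, sampling_rate_hz = 20,
    bout_duration_s = 480,
    activities = c("LEISURE WALK", "COMPUTER WORK", "DIGGING")
  )
  coh <- simulate_cohort(cfg)
  mets <- cohort_mets(coh)
  rel_err <- abs(mets$mets - coh$ground_truth$met_target) / coh$ground_truth$met_target
  expect_lt(max(rel_err), 0.05)
})

test_that("group effects separate extracted gait frequency (LPP slower)", {
  bundle <- small_cohort_bundle(
    seed = 77, n_lpp = 10, n_hpp = 10, bout_s = 120, rate = 25,
    activities = c("LEISURE WALK", "RAPID WALK", "WALKING AT RPE 1")
  )
  ft <- bundle$features
  grp <- bundle$subjects$group[match(ft$subject_id, bundle$subjects$subject_id)]
  df_lpp <- mean(ft$df[grp == "LPP"])
  df_hpp <- mean(ft$df[grp == "HPP"])
  expect_lt(df_lpp, df_hpp)
  expect_equal(df_lpp / df_hpp, 0.79 / 1.05, tolerance = 0.1)
})

test_that("cohort writer emits the plain-file layout the readers accept", {
  cfg <- cohort_config(
    n_lpp = 1, n_hpp = 1, seed = 9, sampling_rate_hz = 20,
    bout_duration_s = 120, activities = c("LEISURE WALK", "TV WATCHING")
  )
  coh <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "subjects.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  acc <- list.files(file.path(dir, "accelerometry"), full.names = TRUE)
  expect_length(acc, 4)
  b <- read_bout(acc[1], subject_id = "S001", activity_name = "LEISURE WALK")
  expect_equal(b$sampling_rate_hz, 20, tolerance = 1e-6)
  expect_length(b$x, 2400)
})
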