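#' Load the per-activity signal signatures
#'
#' Each of the 33 activities gets a static wrist orientation (unit gravity
#' vector), a dominant movement frequency, an oscillation amplitude,
#' a broadband noise level, and a mean/SD for steady-state METs. The
#' shipped defaults place Sedentary activities at ~1.1-1.5 METs with
#' near-zero movement, SFE and light Lifestyle activities at 1.6-2.9 METs
#' with slow low-amplitude motion, and Locomotion at 3.0-5.0 METs with
#' 1.2-2.2 Hz gait-band periodicity, so the generated labels agree with
#' the catalog categories under conventional MET cut-points.
#'
#' @param path optional alternative CSV with the same columns.
#' @return data.frame, one row per activity; gravity weights renormalized
#'   to unit length.
#' @export
activity_signatures <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "activity_signatures.csv", package = "wristfunc")
  }
  sig <- read.csv(path, stringsAsFactors = FALSE)
  sig$activity_name <- canonical_activity_name(sig$activity_name)
  nrm <- sqrt(sig$grav_x^2 + sig$grav_y^2 + sig$grav_z^2)
  sig$grav_x <- sig$grav_x / nrm
  sig$grav_y <- sig$grav_y / nrm
  sig$grav_z <- sig$grav_z / nrm
  stopifnot(all(sig$f0_hz >= 0), all(sig$amp_g >= 0), all(sig$met_mu > 0))
  sig
}

#' Conventional MET cut-points for intensity (generator ground truth only)
#'
#' Low < 1.6 METs, Light 1.6-2.9, Moderate >= 3.0. Used only to sanity-check
#' that generator MET targets agree with the catalog's printed intensity
#' categories; the catalog remains the authoritative label source.
#'
#' @param mets numeric METs.
#' @return character intensity category.
#' @export
met_intensity <- function(mets) {
  ifelse(mets < 1.6, "Low", ifelse(mets < 3.0, "Light", "Moderate"))
}

#' Default group effects on movement
#'
#' The low-performance group moves slower and more variably: its movement
#' frequencies are scaled by the study's LPP/HPP walk-speed ratio
#' 0.79 / 1.05 ~= 0.752 and its within-bout amplitude jitter is inflated
#' 1.5x. MET offsets default to zero for both groups.
#'
#' @return named list of per-group effect lists
#'   (`freq_scale`, `variability_scale`, `met_shift`).
#' @export
default_group_effects <- function() {
  list(
    LPP = list(freq_scale = 0.79 / 1.05, variability_scale = 1.5, met_shift = 0),
    HPP = list(freq_scale = 1.0, variability_scale = 1.0, met_shift = 0)
  )
}

#' Configuration for a synthetic cohort
#'
#' Defaults reproduce the study's stated world: 91 LPP + 156 HPP
#' subjects, all 33 activities, 100 Hz accelerometry, 480 s bouts
#' (the 8-10 min protocol), VO2 rise time constant 30 s. Note that the
#' full default cohort is large (~100 GB of raw samples if materialized at
#' once); desk-scale analyses pass smaller `n_lpp`/`n_hpp` and/or shorter
#' bouts.
#'
#' @param n_lpp,n_hpp subjects per group.
#' @param seed master seed; all cohort randomness derives from it.
#' @param sampling_rate_hz accelerometer rate.
#' @param bout_duration_s bout length, seconds (>= 120 for a plateau).
#' @param activities subset of catalog activity names (default all).
#' @param group_effects per-group effect lists, see
#'   [default_group_effects()].
#' @param missing_fraction fraction of subject-activity bouts absent
#'   (emulates incomplete visits), in \[0, 1).
#' @param vo2_noise_sd breath-level VO2 noise SD, mL min^-1 kg^-1.
#' @param tau_s VO2 on-kinetics time constant, seconds.
#' @param jitter_sd baseline SD of the slow amplitude-modulation process.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_lpp = 91, n_hpp = 156, seed = 1,
                          sampling_rate_hz = 100, bout_duration_s = 480,
                          activities = NULL,
                          group_effects = default_group_effects(),
                          missing_fraction = 0, vo2_noise_sd = 0.3,
                          tau_s = 30, jitter_sd = 0.2) {
  stopifnot(n_lpp >= 0, n_hpp >= 0, n_lpp + n_hpp >= 2)
  if (bout_duration_s < 120) stop("bout_duration_s must be >= 120 to allow a plateau")
  if (missing_fraction < 0 || missing_fraction >= 1) stop("missing_fraction in [0, 1)")
  for (g in names(group_effects)) {
    ge <- group_effects[[g]]
    if (ge$freq_scale <= 0 || ge$variability_scale <= 0) {
      stop("group-effect multipliers must be > 0")
    }
  }
  structure(
    list(
      n_lpp = n_lpp, n_hpp = n_hpp, seed = seed,
      sampling_rate_hz = sampling_rate_hz,
      bout_duration_s = bout_duration_s, activities = activities,
      group_effects = group_effects, missing_fraction = missing_fraction,
      vo2_noise_sd = vo2_noise_sd, tau_s = tau_s, jitter_sd = jitter_sd
    ),
    class = "cohort_config"
  )
}

#' Draw one synthetic subject
#'
#' SPPB scores are discretized, range-clipped normal draws per group
#' (LPP: mean 7.7, SD 1.8, clipped to 0-9; HPP: mean 11.3, SD 0.8, clipped
#' to 10-12, the study's group means). The group label is re-derived from
#' the drawn score via [assign_group()] and must agree. Age, walk speed
#' and BMI use the study's group-level summaries. Also draws a standard
#' normal subject-level random effect that scales the per-activity MET SD.
#' Uses the current RNG state.
#'
#' @param config a [cohort_config()].
#' @param group "LPP" or "HPP".
#' @param subject_id identifier.
#' @return one-row data.frame subject profile.
#' @export
simulate_subject <- function(config, group, subject_id = "S1") {
  group <- match.arg(group, GROUP_LEVELS)
  if (group == "LPP") {
    sppb <- pmin(9L, pmax(0L, as.integer(round(rnorm(1, 7.7, 1.8)))))
    age <- rnorm(1, 75.9, 6.6)
    walk <- max(0.2, rnorm(1, 0.79, 0.15))
    bmi <- max(15, rnorm(1, 30.8, 8.8))
  } else {
    sppb <- pmin(12L, pmax(10L, as.integer(round(rnorm(1, 11.3, 0.8)))))
    age <- rnorm(1, 70.3, 6.6)
    walk <- max(0.2, rnorm(1, 1.05, 0.17))
    bmi <- max(15, rnorm(1, 27.5, 4.8))
  }
  stopifnot(identical(assign_group(sppb), group))
  data.frame(
    subject_id = subject_id, sppb_score = sppb, group = group,
    age_years = age, walk_speed_mps = walk, bmi = bmi,
    met_effect = rnorm(1), stringsAsFactors = FALSE
  )
}

# Slowly varying multiplicative amplitude envelope: normal knots every 2 s,
# linear interpolation, floored at 0.05 so the envelope stays positive.
amplitude_envelope <- function(t, jitter_sd, variability_scale) {
  knots_t <- seq(0, t[length(t)] + 2, by = 2)
  knots_v <- 1 + variability_scale * jitter_sd * rnorm(length(knots_t))
  pmax(0.05, stats::approx(knots_t, knots_v, xout = t, rule = 2)$y)
}

#' Simulate one bout of accelerometry plus calorimetry
#'
#' Acceleration per axis is the static gravity projection of the wrist
#' orientation, plus a sinusoidal movement component at the signature
#' frequency (scaled by the group's `freq_scale`) whose amplitude is
#' modulated by a slow jitter envelope (inflated by `variability_scale`),
#' distributed over the axes along a direction orthogonal to gravity, plus
#' Gaussian broadband noise. Breath-by-breath VO2 rises exponentially
#' (time constant `tau_s`) to the plateau 3.5 x MET target with additive
#' noise; breaths arrive every 2-4 s. The MET target is the signature mean
#' plus the subject random effect times the signature SD plus the group
#' MET offset, floored at 0.5.
#'
#' @param subject one-row profile from [simulate_subject()].
#' @param signature one row of [activity_signatures()].
#' @param group_effect effect list for the subject's group.
#' @param duration_s bout duration, >= 120 s.
#' @param rate_hz sampling rate.
#' @param vo2_noise_sd,tau_s,jitter_sd calorimetry and envelope parameters.
#' @param seed optional seed for a self-contained reproducible bout; by
#'   default the current RNG state is used (cohort-level seeding).
#' @return list with `bout` ([triaxial_bout()]), `breaths`
#'   ([breath_series()]) and `met_target`.
#' @export
simulate_bout <- function(subject, signature, group_effect,
                          duration_s = 480, rate_hz = 100,
                          vo2_noise_sd = 0.3, tau_s = 30, jitter_sd = 0.2,
                          seed = NULL) {
  if (duration_s < 120) stop("duration_s must be >= 120")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  gw <- c(signature$grav_x, signature$grav_y, signature$grav_z)
  # Movement direction: partially aligned with gravity. The along-gravity
  # component puts vector-magnitude power at the movement frequency itself
  # (a purely orthogonal oscillation would only show up at twice f0 via the
  # quadratic term of |g + m|), matching how real wrist motion reads out.
  v <- rnorm(3)
  perp <- v - sum(v * gw) * gw
  if (sqrt(sum(perp^2)) < 1e-8) perp <- c(gw[2], -gw[1], 0)
  perp <- perp / sqrt(sum(perp^2))
  align <- runif(1, 0.5, 0.85)
  mv <- align * gw + sqrt(1 - align^2) * perp
  f_mov <- signature$f0_hz * group_effect$freq_scale
  phase <- runif(1, 0, 2 * pi)
  if (f_mov > 0 && signature$amp_g > 0) {
    env <- amplitude_envelope(t, jitter_sd, group_effect$variability_scale)
    osc <- signature$amp_g * env * sin(2 * pi * f_mov * t + phase)
  } else {
    osc <- numeric(n)
  }
  noise_sd <- signature$noise_g
  ax <- gw[1] + mv[1] * osc + rnorm(n, 0, noise_sd)
  ay <- gw[2] + mv[2] * osc + rnorm(n, 0, noise_sd)
  az <- gw[3] + mv[3] * osc + rnorm(n, 0, noise_sd)
  bout <- triaxial_bout(ax, ay, az, rate_hz,
    subject_id = subject$subject_id, activity_name = signature$activity_name
  )
  met_target <- max(
    0.5,
    signature$met_mu + subject$met_effect * signature$met_sigma + group_effect$met_shift
  )
  n_breaths_max <- ceiling(duration_s / 2) + 1L
  gaps <- runif(n_breaths_max, 2, 4)
  bt <- cumsum(gaps)
  bt <- bt[bt <= duration_s]
  vo2 <- pmax(0, 3.5 * met_target * (1 - exp(-bt / tau_s)) + rnorm(length(bt), 0, vo2_noise_sd))
  breaths <- breath_series(bt, vo2,
    subject_id = subject$subject_id,
    activity_name = signature$activity_name
  )
  list(bout = bout, breaths = breaths, met_target = met_target)
}

#' Simulate a full synthetic cohort
#'
#' Draws all subjects, then one bout (accelerometry + calorimetry) per
#' subject-activity pair, optionally dropping a random fraction of bouts
#' to emulate incomplete visits. Fully deterministic given the config's
#' seed.
#'
#' @param config a [cohort_config()].
#' @param signatures signature table (default shipped signatures).
#' @return list: `subjects` (data.frame), `bouts` (list of
#'   [triaxial_bout()]), `breaths` (list of [breath_series()]),
#'   `ground_truth` (data.frame with `met_target` per bout), `config`.
#' @export
simulate_cohort <- function(config, signatures = activity_signatures()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$activities)) {
    want <- canonical_activity_name(config$activities)
    missing_acts <- setdiff(want, signatures$activity_name)
    if (length(missing_acts)) stop("no signature for: ", paste(missing_acts, collapse = ", "))
    signatures <- signatures[signatures$activity_name %in% want, , drop = FALSE]
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n_tot <- config$n_lpp + config$n_hpp
  ids <- sprintf("S%03d", seq_len(n_tot))
  groups <- c(rep("LPP", config$n_lpp), rep("HPP", config$n_hpp))
  subjects <- do.call(rbind, lapply(seq_len(n_tot), function(i) {
    simulate_subject(config, groups[i], ids[i])
  }))
  bouts <- list()
  breaths <- list()
  gt <- list()
  for (i in seq_len(n_tot)) {
    ge <- config$group_effects[[groups[i]]]
    for (a in seq_len(nrow(signatures))) {
      if (config$missing_fraction > 0 && runif(1) < config$missing_fraction) next
      sim <- simulate_bout(
        subjects[i, ], signatures[a, ], ge,
        duration_s = config$bout_duration_s,
        rate_hz = config$sampling_rate_hz,
        vo2_noise_sd = config$vo2_noise_sd,
        tau_s = config$tau_s, jitter_sd = config$jitter_sd
      )
      key <- length(bouts) + 1L
      bouts[[key]] <- sim$bout
      breaths[[key]] <- sim$breaths
      gt[[key]] <- data.frame(
        subject_id = ids[i],
        activity_name = signatures$activity_name[a],
        met_target = sim$met_target, stringsAsFactors = FALSE
      )
    }
  }
  list(
    subjects = subjects, bouts = bouts, breaths = breaths,
    ground_truth = do.call(rbind, gt), config = config
  )
}

#' Estimate steady-state METs for every bout of a cohort
#'
#' Runs [steady_state_vo2()] on each breath series and returns the METs
#' table the regression task consumes.
#'
#' @param cohort from [simulate_cohort()].
#' @param plateau_s plateau duration passed through.
#' @return data.frame `subject_id`, `activity_name`, `mets`, `vo2_ss`.
#' @export
cohort_mets <- function(cohort, plateau_s = 120) {
  rows <- lapply(cohort$breaths, function(b) {
    ss <- steady_state_vo2(b, plateau_s = plateau_s)
    data.frame(
      subject_id = b$subject_id, activity_name = b$activity_name,
      mets = ss$mets, vo2_ss = ss$vo2_ss, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a cohort to disk in the pipeline's plain-file formats
#'
#' Emits one accelerometer CSV and one calorimetry CSV per bout, plus
#' `subjects.csv` and `ground_truth.csv`.
#'
#' @param cohort from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  acc_dir <- file.path(dir, "accelerometry")
  cal_dir <- file.path(dir, "calorimetry")
  dir.create(acc_dir, showWarnings = FALSE)
  dir.create(cal_dir, showWarnings = FALSE)
  slug <- function(b) paste0(b$subject_id, "_", gsub("[^A-Z0-9]+", "-", b$activity_name))
  for (i in seq_along(cohort$bouts)) {
    b <- cohort$bouts[[i]]
    write_bout(b, file.path(acc_dir, paste0(slug(b), ".csv")))
    br <- cohort$breaths[[i]]
    write.csv(
      data.frame(time_s = br$timestamps_s, vo2_mlkgmin = br$vo2),
      file.path(cal_dir, paste0(slug(br), ".csv")),
      row.names = FALSE
    )
  }
  write.csv(cohort$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}
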