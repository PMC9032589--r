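# Shared fixtures: window constructors, a cached small cohort (built once
# per test run), and independent naive-formula oracles for the features.

make_window <- function(x, y, z, rate = 100) {
  structure(
    list(
      subject_id = "S1", activity_name = "TEST", window_index = 0L,
      duration_s = length(x) / rate, sampling_rate_hz = rate,
      x = x, y = y, z = z
    ),
    class = "signal_window"
  )
}

random_window <- function(n = 300, rate = 5) {
  make_window(rnorm(n, 0.4, 0.3), rnorm(n, 0.7, 0.2), rnorm(n, 0.5, 0.25), rate)
}

# Bout with a sinusoidal tone riding on gravity along z.
tone_bout <- function(freqs, amps = rep(0.1, length(freqs)), duration = 60,
                      rate = 100, subject = "S1", activity = "LEISURE WALK") {
  t <- (0:(duration * rate - 1)) / rate
  z <- rep(1, length(t))
  for (i in seq_along(freqs)) z <- z + amps[i] * sin(2 * pi * freqs[i] * t)
  triaxial_bout(rep(0, length(t)), rep(0, length(t)), z, rate,
    subject_id = subject, activity_name = activity
  )
}

# --- independent naive oracles (plain-loop formulas) -----------------------

oracle_time_features <- function(w) {
  vm <- sqrt(w$x^2 + w$y^2 + w$z^2)
  chans <- list(vm = vm, x = w$x, y = w$y, z = w$z)
  per_chan <- list()
  for (nm in names(chans)) {
    v <- chans[[nm]]
    n <- length(v)
    mu <- sum(v) / n
    s <- sqrt(sum((v - mu)^2) / (n - 1))
    m2 <- sum((v - mu)^2) / n
    m3 <- sum((v - mu)^3) / n
    m4 <- sum((v - mu)^4) / n
    cv <- if (abs(mu) < 1e-12) 0 else 100 * s / mu
    skew <- if (m2 < 1e-24) 0 else m3 / m2^1.5
    kurt <- if (m2 < 1e-24) 0 else m4 / m2^2
    sv <- sort(v)
    qq <- function(p) { # type-7 linear interpolation
      h <- (n - 1) * p + 1
      lo <- floor(h)
      sv[lo] + (h - lo) * (sv[min(n, lo + 1)] - sv[lo])
    }
    per_chan[[nm]] <- c(mu, s, cv, min(v), max(v), qq(0.25), qq(0.75), m3, m4, skew, kurt)
  }
  # family-major: statistic 1 for all channels, then statistic 2, ...
  as.numeric(t(do.call(cbind, per_chan)))
}

oracle_angles <- function(w) {
  vm <- sqrt(w$x^2 + w$y^2 + w$z^2)
  ang <- ifelse(vm == 0, 0, asin(pmax(-1, pmin(1, w$x / vm))))
  c(mean(ang), sqrt(sum((ang - mean(ang))^2) / (length(ang) - 1)))
}

# Direct DFT summation (O(n^2)), independent of stats::fft.
oracle_spectral <- function(w, band = c(0.6, 2.5), use_fft_for_speed = FALSE) {
  vm <- sqrt(w$x^2 + w$y^2 + w$z^2)
  v <- vm - mean(vm)
  n <- length(v)
  kmax <- n %/% 2
  if (use_fft_for_speed) {
    mod <- Mod(stats::fft(v))[2:(kmax + 1)]
  } else {
    mod <- vapply(1:kmax, function(k) {
      ang <- -2 * pi * k * (0:(n - 1)) / n
      sqrt(sum(v * cos(ang))^2 + sum(v * sin(ang))^2)
    }, numeric(1))
  }
  freq <- (1:kmax) * w$sampling_rate_hz / n
  if (sum(mod^2) < 1e-24) return(c(0, freq[1], 0))
  idx <- which(mod == max(mod))[1]
  c(
    sum(mod[freq >= band[1] & freq <= band[2]]^2) / sum(mod^2),
    freq[idx],
    mod[idx] / sum(mod)
  )
}

oracle_all_features <- function(w) {
  c(oracle_time_features(w), oracle_angles(w), oracle_spectral(w, use_fft_for_speed = TRUE))
}

# --- cached small cohort ---------------------------------------------------

.fixture_env <- new.env(parent = emptyenv())

# 20-subject cohort with short bouts; used by modeling and acceptance tests.
small_cohort_bundle <- function(seed = 2024, n_lpp = 8, n_hpp = 12,
                                bout_s = 120, rate = 50, activities = NULL,
                                group_effects = default_group_effects(),
                                gap_s = 0) {
  key <- paste("cohort", seed, n_lpp, n_hpp, bout_s, rate, gap_s,
    paste(activities, collapse = "|"),
    paste(unlist(group_effects), collapse = "|"),
    sep = "_"
  )
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  cfg <- cohort_config(
    n_lpp = n_lpp, n_hpp = n_hpp, seed = seed, sampling_rate_hz = rate,
    bout_duration_s = bout_s, activities = activities,
    group_effects = group_effects
  )
  cohort <- simulate_cohort(cfg)
  bundle <- list(
    cohort = cohort,
    features = extract_feature_table(cohort$bouts, gap_s = gap_s),
    subjects = cohort$subjects
  )
  .fixture_env[[key]] <- bundle
  bundle
}
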