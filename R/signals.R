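#' Construct a tri-axial accelerometer bout
#'
#' A bout is one continuous subject-activity recording of wrist
#' acceleration, in units of g, sampled at a fixed rate (100 Hz in the
#' study configuration).
#'
#' @param x,y,z numeric acceleration per axis, equal lengths >= 1.
#' @param sampling_rate_hz positive sampling rate.
#' @param subject_id,activity_name identifiers carried through the pipeline.
#' @param t0 optional start timestamp.
#' @return a `triaxial_bout`.
#' @export
triaxial_bout <- function(x, y, z, sampling_rate_hz = 100,
                          subject_id = NA_character_,
                          activity_name = NA_character_, t0 = NULL) {
  n <- length(x)
  if (n < 1L || length(y) != n || length(z) != n) {
    stop("axes must have equal length >= 1")
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be > 0")
  }
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z))) {
    stop("bout contains non-finite samples")
  }
  structure(
    list(
      subject_id = subject_id,
      activity_name = if (is.na(activity_name)) activity_name else canonical_activity_name(activity_name),
      sampling_rate_hz = sampling_rate_hz,
      x = as.numeric(x), y = as.numeric(y), z = as.numeric(z), t0 = t0
    ),
    class = "triaxial_bout"
  )
}

#' @export
print.triaxial_bout <- function(x, ...) {
  cat(sprintf(
    "<triaxial_bout> %s / %s: %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$activity_name, length(x$x), x$sampling_rate_hz,
    length(x$x) / x$sampling_rate_hz
  ))
  invisible(x)
}

#' Read a bout from a delimited file
#'
#' Accepts either a 4-column file (`time`/`timestamp`, `x`, `y`, `z`) or a
#' 3-column file (`x`, `y`, `z`) with the sampling rate declared by the
#' caller. Rows containing NaN/Inf are dropped with a warning that reports
#' the count.
#'
#' @param path CSV file.
#' @param sampling_rate_hz rate used for 3-column files; for 4-column files
#'   the rate is inferred from the median time step when not supplied.
#' @param subject_id,activity_name identifiers attached to the bout.
#' @return a [triaxial_bout()].
#' @export
read_bout <- function(path, sampling_rate_hz = NULL,
                      subject_id = NA_character_, activity_name = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e))
  )
  if (nrow(dat) == 0L) stop("empty bout file: ", path)
  nm <- tolower(names(dat))
  time_col <- which(nm %in% c("time", "timestamp", "time_s", "t"))
  if (!all(c("x", "y", "z") %in% nm)) {
    stop("bout file needs columns x, y, z (optionally a leading time column): ", path)
  }
  xi <- dat[[which(nm == "x")[1]]]
  yi <- dat[[which(nm == "y")[1]]]
  zi <- dat[[which(nm == "z")[1]]]
  if (length(time_col)) {
    tt <- dat[[time_col[1]]]
    keep <- is.finite(tt) & is.finite(xi) & is.finite(yi) & is.finite(zi)
  } else {
    tt <- NULL
    keep <- is.finite(xi) & is.finite(yi) & is.finite(zi)
  }
  n_bad <- sum(!keep)
  if (n_bad > 0L) {
    warning(sprintf("dropped %d non-finite row(s) from %s", n_bad, path))
    xi <- xi[keep]; yi <- yi[keep]; zi <- zi[keep]
    if (!is.null(tt)) tt <- tt[keep]
  }
  if (length(xi) == 0L) stop("no valid samples in ", path)
  if (!is.null(tt)) {
    if (is.unsorted(tt, strictly = TRUE)) stop("non-monotone time column in ", path)
    if (is.null(sampling_rate_hz)) {
      if (length(tt) < 2L) stop("cannot infer rate from a single sample; supply sampling_rate_hz")
      sampling_rate_hz <- 1 / stats::median(diff(tt))
    }
  } else if (is.null(sampling_rate_hz)) {
    stop("3-column file requires an explicit sampling_rate_hz")
  }
  triaxial_bout(xi, yi, zi, sampling_rate_hz,
    subject_id = subject_id, activity_name = activity_name,
    t0 = if (is.null(tt)) NULL else tt[1]
  )
}

#' Write a bout to CSV (timestamp, x, y, z)
#'
#' @param bout a [triaxial_bout()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bout <- function(bout, path) {
  stopifnot(inherits(bout, "triaxial_bout"))
  n <- length(bout$x)
  tt <- (seq_len(n) - 1) / bout$sampling_rate_hz
  write.csv(
    data.frame(time = tt, x = bout$x, y = bout$y, z = bout$z),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' Cut a bout into fixed-duration feature windows
#'
#' Windows tile the bout from its start without overlap; an optional
#' inter-window gap can be configured and a trailing partial window is
#' dropped, so the count is `floor(n / ((window_s + gap_s) * rate))`-ish
#' (exactly `floor` with `gap_s = 0`). An optional `trim_s` discards the
#' bout's first and last seconds before windowing (transition guard,
#' default off).
#'
#' @param bout a [triaxial_bout()].
#' @param window_s window duration in seconds (60 in the study design).
#' @param gap_s gap between consecutive windows, seconds.
#' @param trim_s seconds trimmed from both bout ends before windowing.
#' @return list of `signal_window` objects (possibly empty).
#' @export
segment_windows <- function(bout, window_s = 60, gap_s = 0, trim_s = 0) {
  stopifnot(inherits(bout, "triaxial_bout"))
  if (window_s <= 0) stop("window_s must be > 0")
  if (gap_s < 0 || trim_s < 0) stop("gap_s and trim_s must be >= 0")
  rate <- bout$sampling_rate_hz
  n <- length(bout$x)
  trim_n <- round(trim_s * rate)
  lo <- trim_n + 1L
  hi <- n - trim_n
  if (hi < lo) return(list())
  win_n <- round(window_s * rate)
  gap_n <- round(gap_s * rate)
  out <- list()
  start <- lo
  k <- 0L
  while (start + win_n - 1L <= hi) {
    idx <- start:(start + win_n - 1L)
    out[[k + 1L]] <- structure(
      list(
        subject_id = bout$subject_id,
        activity_name = bout$activity_name,
        window_index = k,
        duration_s = window_s,
        sampling_rate_hz = rate,
        x = bout$x[idx], y = bout$y[idx], z = bout$z[idx]
      ),
      class = "signal_window"
    )
    k <- k + 1L
    start <- start + win_n + gap_n
  }
  out
}

#' @export
print.signal_window <- function(x, ...) {
  cat(sprintf(
    "<signal_window> %s / %s #%d: %d samples @ %g Hz\n",
    x$subject_id, x$activity_name, x$window_index, length(x$x), x$sampling_rate_hz
  ))
  invisible(x)
}

#' Construct a breath-by-breath VO2 series
#'
#' @param timestamps_s strictly increasing breath times, seconds.
#' @param vo2 oxygen uptake per breath, mL min^-1 kg^-1, each >= 0.
#' @param subject_id,activity_name identifiers.
#' @return a `breath_series`.
#' @export
breath_series <- function(timestamps_s, vo2, subject_id = NA_character_,
                          activity_name = NA_character_) {
  if (length(timestamps_s) != length(vo2)) stop("timestamps and vo2 lengths differ")
  if (length(vo2) == 0L) stop("empty breath series")
  if (any(!is.finite(timestamps_s)) || any(!is.finite(vo2))) stop("non-finite breath data")
  if (is.unsorted(timestamps_s, strictly = TRUE)) stop("timestamps must be strictly increasing")
  if (any(vo2 < 0)) stop("vo2 must be >= 0")
  structure(
    list(
      timestamps_s = as.numeric(timestamps_s), vo2 = as.numeric(vo2),
      subject_id = subject_id,
      activity_name = if (is.na(activity_name)) activity_name else canonical_activity_name(activity_name)
    ),
    class = "breath_series"
  )
}

#' Smooth a breath series with a centered running average
#'
#' Each output value is the mean of all breaths whose timestamps fall in the
#' centered interval `[t - span_s/2, t + span_s/2]`; timestamps are
#' unchanged. Centered (rather than trailing) averaging is used to avoid
#' phase distortion with irregular breath spacing.
#'
#' @param series a [breath_series()].
#' @param span_s averaging span, seconds (30 in the study configuration).
#' @return smoothed [breath_series()].
#' @export
smooth_vo2 <- function(series, span_s = 30) {
  stopifnot(inherits(series, "breath_series"))
  if (span_s <= 0) stop("span_s must be > 0")
  tt <- series$timestamps_s
  v <- series$vo2
  half <- span_s / 2
  lo <- findInterval(tt - half, tt, left.open = TRUE) + 1L
  hi <- findInterval(tt + half, tt)
  cs0 <- c(0, cumsum(v))
  out <- (cs0[hi + 1L] - cs0[lo]) / (hi - lo + 1L)
  breath_series(tt, out, series$subject_id, series$activity_name)
}

#' Estimate steady-state VO2 and METs for a bout
#'
#' Smooths the series, then selects the contiguous interval of
#' `plateau_s` seconds with the smallest within-interval standard deviation
#' of smoothed VO2 — an automated surrogate for the study's manual plateau
#' reading. Candidates are restricted to the second half of the bout by
#' default so the initial metabolic rise is excluded. Steady-state VO2 is
#' the mean over the chosen interval; METs are VO2 / 3.5.
#'
#' @param series a [breath_series()].
#' @param plateau_s plateau duration, seconds (~2 min in the study).
#' @param span_s smoothing span passed to [smooth_vo2()].
#' @param second_half_only restrict candidate starts to the bout's second
#'   half (default TRUE).
#' @return a `steady_state_met` list with `vo2_ss`, `mets`,
#'   `plateau_interval_s`.
#' @export
steady_state_vo2 <- function(series, plateau_s = 120, span_s = 30,
                             second_half_only = TRUE) {
  stopifnot(inherits(series, "breath_series"))
  tt <- series$timestamps_s
  duration <- tt[length(tt)] - tt[1]
  if (duration < plateau_s) {
    stop(sprintf("series spans %.1f s < plateau_s = %.1f s", duration, plateau_s))
  }
  sm <- smooth_vo2(series, span_s)$vo2
  t_min <- if (second_half_only) tt[1] + duration / 2 else tt[1]
  starts <- which(tt >= t_min & tt + plateau_s <= tt[length(tt)] + 1e-9)
  if (length(starts) == 0L) starts <- which(tt + plateau_s <= tt[length(tt)] + 1e-9)
  if (length(starts) == 0L) starts <- 1L
  best <- NULL
  best_sd <- Inf
  for (i in starts) {
    j <- findInterval(tt[i] + plateau_s, tt)
    idx <- i:j
    s <- if (length(idx) > 1L) stats::sd(sm[idx]) else 0
    if (s < best_sd - 1e-15) {
      best_sd <- s
      best <- idx
    }
  }
  vo2_ss <- mean(sm[best])
  structure(
    list(
      subject_id = series$subject_id,
      activity_name = series$activity_name,
      vo2_ss = vo2_ss,
      mets = vo2_to_mets(vo2_ss),
      plateau_interval_s = c(tt[best[1]], tt[best[length(best)]]),
      plateau_sd = best_sd
    ),
    class = "steady_state_met"
  )
}

#' Convert VO2 to metabolic equivalents
#'
#' Divides mass-normalized oxygen uptake (mL min^-1 kg^-1) by the resting
#' convention of 3.5.
#'
#' @param vo2 numeric, >= 0.
#' @return METs.
#' @export
vo2_to_mets <- function(vo2) {
  if (any(!is.finite(vo2)) || any(vo2 < 0)) stop("vo2 must be finite and >= 0")
  vo2 / 3.5
}
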