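#' Names of the 49 window features, in canonical order
#'
#' Eleven summary-statistic families over four channels (vector magnitude,
#' x, y, z), the two forearm-angle features, and three spectral features of
#' the vector-magnitude series.
#'
#' @return character vector of length 49.
#' @export
feature_names <- function() {
  fam <- function(vm, ax) c(vm, paste0(ax, c("x", "y", "z")))
  c(
    fam("mvm", "mean_"),
    fam("sdvm", "sd_"),
    fam("cv_vm", "cv_"),
    fam("min_vm", "min_"),
    fam("max_vm", "max_"),
    c("lower_vm_25", "lower_x_25", "lower_y_25", "lower_z_25"),
    c("upper_vm_75", "upper_x_75", "upper_y_75", "upper_z_75"),
    fam("third_vm", "third_"),
    fam("fourth_vm", "fourth_"),
    fam("skewness_vm", "skewness_"),
    fam("kurtosis_vm", "kurtosis_"),
    c("mangle", "sdangle"),
    c("p625", "df", "fpdf")
  )
}

#' Per-sample vector magnitude
#'
#' Euclidean norm sqrt(x^2 + y^2 + z^2) of the three acceleration axes.
#'
#' @param window a `signal_window` (or any list with x, y, z).
#' @return numeric series, same length as the axes.
#' @export
vector_magnitude <- function(window) {
  sqrt(window$x^2 + window$y^2 + window$z^2)
}

# Summary statistics for one channel. Conventions: sample (n-1) SD;
# population central moments m2..m4; skewness m3/m2^1.5 and non-excess
# kurtosis m4/m2^2, both 0 under the zero-variance guard; cv in percent
# with a near-zero-mean guard; type-7 (linear interpolation) quantiles.
channel_stats <- function(v, eps = 1e-12) {
  n <- length(v)
  mu <- mean(v)
  s <- if (n > 1L) stats::sd(v) else 0
  d <- v - mu
  m2 <- mean(d^2)
  m3 <- mean(d^3)
  m4 <- mean(d^4)
  if (abs(mu) < eps) {
    warning("near-zero channel mean; cv set to 0")
    cv <- 0
  } else {
    cv <- 100 * s / mu
  }
  if (m2 < eps^2) {
    skew <- 0
    kurt <- 0
  } else {
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2
  }
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  c(
    mean = mu, sd = s, cv = cv, min = min(v), max = max(v),
    q25 = q[1], q75 = q[2], third = m3, fourth = m4,
    skewness = skew, kurtosis = kurt
  )
}

#' Time-domain features of a window
#'
#' The 44 statistics: for each of the four channels (vector magnitude, x,
#' y, z) the mean, sample SD, coefficient of variation (100 * SD / mean),
#' min, max, 25% and 75% quantiles, third and fourth central moments,
#' skewness and kurtosis.
#'
#' @param window a `signal_window`.
#' @return named numeric vector of length 44.
#' @export
time_domain_features <- function(window) {
  if (length(window$x) < 1L) stop("zero-length window")
  vm <- vector_magnitude(window)
  st <- cbind(
    vm = channel_stats(vm), x = channel_stats(window$x),
    y = channel_stats(window$y), z = channel_stats(window$z)
  )
  nm <- feature_names()[1:44]
  out <- as.numeric(t(st))
  names(out) <- nm
  out
}

#' Forearm-angle features of a window
#'
#' Per sample, the angle between the x axis and the acceleration vector is
#' asin(x / VM) in radians (the established convention for this wrist
#' feature); samples with VM = 0 get angle 0 with a warning. Returns the
#' sample mean and sample SD of the angle series.
#'
#' @param window a `signal_window`.
#' @param degrees return degrees instead of radians.
#' @return named numeric vector `c(mangle, sdangle)`.
#' @export
angle_features <- function(window, degrees = FALSE) {
  vm <- vector_magnitude(window)
  ratio <- ifelse(vm > 0, pmin(1, pmax(-1, window$x / ifelse(vm > 0, vm, 1))), 0)
  if (any(vm == 0)) warning("window contains zero-magnitude samples; angle set to 0")
  ang <- asin(ratio)
  if (degrees) ang <- ang * 180 / pi
  c(
    mangle = mean(ang),
    sdangle = if (length(ang) > 1L) stats::sd(ang) else 0
  )
}

#' Spectral features of a window
#'
#' From the discrete Fourier transform of the mean-removed vector-magnitude
#' series, over positive frequencies only (the DC bin is excluded so the
#' gravity offset cannot dominate):
#' * `p625` — fraction of power (squared moduli) in the human-movement band
#'   0.6--2.5 Hz (endpoints inclusive);
#' * `df` — frequency with the largest modulus, ties broken toward the
#'   lowest frequency;
#' * `fpdf` — modulus at `df` divided by the sum of moduli over all
#'   positive frequencies.
#' An all-constant window has an empty spectrum: `p625 = fpdf = 0` and
#' `df` is the lowest positive frequency, with a warning.
#'
#' @param window a `signal_window`.
#' @param band lower/upper band edges, Hz.
#' @return named numeric vector `c(p625, df, fpdf)`.
#' @export
spectral_features <- function(window, band = c(0.6, 2.5)) {
  vm <- vector_magnitude(window)
  n <- length(vm)
  if (n < 2L) stop("window too short for spectral features")
  rate <- window$sampling_rate_hz
  sp <- stats::fft(vm - mean(vm))
  kmax <- n %/% 2L
  mod <- Mod(sp[2:(kmax + 1L)])
  freq <- (1:kmax) * rate / n
  tot_pow <- sum(mod^2)
  if (tot_pow < 1e-24) {
    warning("flat vector-magnitude series; zero spectrum")
    return(c(p625 = 0, df = freq[1], fpdf = 0))
  }
  in_band <- freq >= band[1] & freq <= band[2]
  p625 <- sum(mod[in_band]^2) / tot_pow
  # lowest frequency among (numerically) tied maxima; the relative
  # tolerance keeps analytically equal tones deterministic under fft
  # round-off
  i_dom <- which(mod >= max(mod) * (1 - 1e-9))[1L]
  c(p625 = p625, df = freq[i_dom], fpdf = mod[i_dom] / sum(mod))
}

#' Extract the full 49-feature vector for one window
#'
#' @param window a `signal_window`.
#' @return named numeric vector, length 49, names from [feature_names()].
#' @export
extract_features <- function(window) {
  out <- c(
    time_domain_features(window),
    angle_features(window),
    spectral_features(window)
  )
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Build a feature table from bouts
#'
#' Segments every bout into windows, extracts the 49 features per window,
#' and joins the activity-type and intensity labels from the catalog. One
#' row per window.
#'
#' @param bouts list of [triaxial_bout()] objects.
#' @param catalog catalog data.frame from [activity_catalog()].
#' @param window_s window duration, seconds.
#' @param ... passed to [segment_windows()].
#' @return data.frame: `subject_id`, `activity_name`, `window_index`,
#'   49 feature columns, `type_category`, `intensity_category`.
#' @export
extract_feature_table <- function(bouts, catalog = activity_catalog(),
                                  window_s = 60, ...) {
  rows <- list()
  for (bout in bouts) {
    wins <- segment_windows(bout, window_s = window_s, ...)
    for (w in wins) {
      rows[[length(rows) + 1L]] <- c(
        list(
          subject_id = w$subject_id, activity_name = w$activity_name,
          window_index = w$window_index
        ),
        as.list(extract_features(w))
      )
    }
  }
  if (length(rows) == 0L) stop("no windows produced; bouts shorter than window_s?")
  tab <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  lab <- map_activity(tab$activity_name, catalog)
  tab$type_category <- lab$type_category
  tab$intensity_category <- lab$intensity_category
  rownames(tab) <- NULL
  tab
}

#' Write / read a feature table as CSV
#'
#' @param table feature table from [extract_feature_table()].
#' @param path CSV file.
#' @return `path` (writer) or the table (reader).
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(feature_names(), names(tab))
  if (length(missing_cols)) {
    stop("feature table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  tab
}
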