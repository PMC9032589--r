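test_that("vector magnitude is the per-sample Euclidean norm", {
  w <- make_window(c(0, 1, 3), c(0, 2, 0), c(1, 2, 4), rate = 1)
  expect_equal(vector_magnitude(w), c(1, 3, 5))
  set.seed(11)
  rw <- random_window(50)
  expect_equal(
    vector_magnitude(rw),
    vapply(1:50, function(i) sqrt(rw$x[i]^2 + rw$y[i]^2 + rw$z[i]^2), numeric(1))
  )
})

test_that("time-domain features: hand-computed and degenerate cases", {
  # constant gravity along z
  n <- 100
  w <- suppressWarnings(extract_features(make_window(rep(0, n), rep(0, n), rep(1, n))))
  expect_equal(unname(w["mvm"]), 1)
  expect_equal(unname(w["mean_z"]), 1)
  expect_equal(unname(w[c("sdvm", "sd_z", "skewness_z", "kurtosis_z", "third_z", "fourth_z")]),
    rep(0, 6))
  expect_equal(unname(w["lower_z_25"]), 1)
  expect_equal(unname(w["upper_z_75"]), 1)

  # {1,2,3,4}: mean 2.5, sample SD sqrt(5/3), symmetric -> m3 = 0
  w4 <- make_window(c(1, 2, 3, 4), rep(0, 4), rep(0, 4), rate = 1)
  f4 <- suppressWarnings(time_domain_features(w4))
  expect_equal(unname(f4["mean_x"]), 2.5)
  expect_equal(unname(f4["sd_x"]), sqrt(5 / 3))
  expect_equal(unname(f4["third_x"]), 0)
  expect_equal(unname(f4["skewness_x"]), 0)
  expect_equal(unname(f4["cv_x"]), 100 * sqrt(5 / 3) / 2.5)
  expect_equal(unname(f4["lower_x_25"]), 1.75) # type-7 quantile
  expect_equal(unname(f4["upper_x_75"]), 3.25)
  expect_equal(unname(f4["fourth_x"]), mean((c(1, 2, 3, 4) - 2.5)^4))
})

test_that("angle features follow the asin(x / VM) convention", {
  n <- 10
  pure_x <- angle_features(make_window(rep(1, n), rep(0, n), rep(0, n)))
  expect_equal(unname(pure_x["mangle"]), pi / 2)
  expect_equal(unname(pure_x["sdangle"]), 0)
  no_x <- angle_features(make_window(rep(0, n), rep(1, n), rep(0, n)))
  expect_equal(unname(no_x["mangle"]), 0)
  diag_xz <- angle_features(make_window(rep(1 / sqrt(2), n), rep(0, n), rep(1 / sqrt(2), n)))
  expect_equal(unname(diag_xz["mangle"]), pi / 4)
  # zero-magnitude guard
  expect_warning(
    zm <- angle_features(make_window(c(0, 1), c(0, 0), c(0, 0))),
    "zero-magnitude"
  )
  expect_equal(unname(zm["mangle"]), mean(c(0, pi / 2)))
  # degrees toggle
  deg <- angle_features(make_window(rep(1, n), rep(0, n), rep(0, n)), degrees = TRUE)
  expect_equal(unname(deg["mangle"]), 90)
})

test_that("spectral features: tones, band edges, tie-break, flat guard", {
  rate <- 100
  t <- (0:(60 * rate - 1)) / rate
  zeros <- rep(0, length(t))
  in_band <- make_window(zeros, zeros, 1 + 0.1 * sin(2 * pi * 2 * t), rate)
  sf <- spectral_features(in_band)
  expect_equal(unname(sf["df"]), 2.0)
  expect_gt(sf["p625"], 0.999)
  expect_gt(sf["fpdf"], 0.99)

  out_band <- make_window(zeros, zeros, 1 + 0.1 * sin(2 * pi * 5 * t), rate)
  sf5 <- spectral_features(out_band)
  expect_equal(unname(sf5["df"]), 5.0)
  expect_lt(sf5["p625"], 0.001)

  # two equal tones: lowest-frequency tie-break, fpdf ~ 0.5
  two <- make_window(zeros, zeros, 1 + 0.1 * sin(2 * pi * 1 * t) + 0.1 * sin(2 * pi * 2 * t), rate)
  sf2 <- spectral_features(two)
  expect_equal(unname(sf2["df"]), 1.0)
  expect_gt(sf2["p625"], 0.999)
  expect_equal(unname(sf2["fpdf"]), 0.5, tolerance = 0.01)

  flat <- make_window(zeros, zeros, rep(1, length(t)), rate)
  expect_warning(sf0 <- spectral_features(flat), "flat")
  expect_equal(unname(sf0["p625"]), 0)
  expect_equal(unname(sf0["fpdf"]), 0)
  expect_equal(unname(sf0["df"]), rate / length(t))
})

test_that("every feature matches the independent naive oracle", {
  set.seed(42)
  for (i in 1:20) {
    w <- random_window(n = 300, rate = 5)
    got <- suppressWarnings(extract_features(w))
    want <- suppressWarnings(oracle_all_features(w))
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
  }
  # one window checked against the O(n^2) direct DFT summation as well
  set.seed(43)
  w <- random_window(n = 240, rate = 4)
  expect_equal(
    unname(suppressWarnings(extract_features(w))[c("p625", "df", "fpdf")]),
    oracle_spectral(w),
    tolerance = 1e-10
  )
})

test_that("feature vector properties: names, scale equivariance, reversal", {
  set.seed(9)
  w <- random_window(n = 200, rate = 4)
  f <- suppressWarnings(extract_features(w))
  expect_length(f, 49)
  expect_identical(names(f), feature_names())
  expect_true(all(is.finite(f)))
  expect_true(f["p625"] >= 0 && f["p625"] <= 1)
  expect_true(f["fpdf"] >= 0 && f["fpdf"] <= 1)
  expect_true(f["df"] > 0 && f["df"] <= w$sampling_rate_hz / 2)
  for (ch in c("vm", "x", "y", "z")) {
    sep <- if (ch == "vm") "" else "_"
    lower <- if (ch == "vm") "lower_vm_25" else paste0("lower_", ch, "_25")
    upper <- if (ch == "vm") "upper_vm_75" else paste0("upper_", ch, "_75")
    mn <- if (ch == "vm") "min_vm" else paste0("min_", ch)
    mx <- if (ch == "vm") "max_vm" else paste0("max_", ch)
    expect_true(f[mn] <= f[lower] && f[lower] <= f[upper] && f[upper] <= f[mx])
  }

  # scale equivariance under k > 0
  k <- 2.7
  wk <- make_window(k * w$x, k * w$y, k * w$z, w$sampling_rate_hz)
  fk <- suppressWarnings(extract_features(wk))
  for (nm in c("mvm", "sdvm", "min_x", "max_y", "lower_z_25", "upper_vm_75")) {
    expect_equal(unname(fk[nm]), unname(k * f[nm]), tolerance = 1e-12)
  }
  expect_equal(unname(fk["third_vm"]), unname(k^3 * f["third_vm"]), tolerance = 1e-10)
  expect_equal(unname(fk["fourth_x"]), unname(k^4 * f["fourth_x"]), tolerance = 1e-10)
  for (nm in c("cv_vm", "skewness_x", "kurtosis_y", "mangle", "sdangle", "p625", "fpdf", "df")) {
    expect_equal(unname(fk[nm]), unname(f[nm]), tolerance = 1e-10)
  }

  # time reversal leaves time-domain features and modulus spectrum alone
  wr <- make_window(rev(w$x), rev(w$y), rev(w$z), w$sampling_rate_hz)
  fr <- suppressWarnings(extract_features(wr))
  expect_equal(unname(fr[1:46]), unname(f[1:46]), tolerance = 1e-12)
  expect_equal(unname(fr["p625"]), unname(f["p625"]), tolerance = 1e-10)
  expect_equal(unname(fr["df"]), unname(f["df"]))

  # p625 + out-of-band fraction = 1
  vm <- vector_magnitude(w)
  sp <- Mod(fft(vm - mean(vm)))[2:(length(vm) %/% 2 + 1)]
  freq <- (1:(length(vm) %/% 2)) * w$sampling_rate_hz / length(vm)
  out_frac <- sum(sp[freq < 0.6 | freq > 2.5]^2) / sum(sp^2)
  expect_equal(unname(f["p625"]) + out_frac, 1, tolerance = 1e-12)
})

test_that("feature table writer/reader round-trips values", {
  b <- tone_bout(1.5, duration = 120)
  tab <- suppressWarnings(extract_feature_table(list(b))) # x = y = 0 trips the cv guard
  expect_equal(nrow(tab), 2)
  expect_equal(tab$type_category, rep("Locomotion", 2))
  expect_equal(tab$intensity_category, rep("Moderate", 2))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, tmp)
  back <- read_feature_table(tmp)
  expect_equal(as.matrix(back[, feature_names()]), as.matrix(tab[, feature_names()]),
    tolerance = 1e-12)
})
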