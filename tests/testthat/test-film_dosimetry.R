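test_that("net optical density follows the log10 attenuation identities", {
  expect_equal(net_od(40000, 40000), 0)
  expect_equal(net_od(40000, 20000), log10(2))
  expect_equal(net_od(40000, 4000), 1)
  # additive in cascaded attenuations
  expect_equal(net_od(40000, 23000) + net_od(23000, 9100),
               net_od(40000, 9100), tolerance = 1e-12)
  # strictly decreasing in the exposed pixel value
  pv <- seq(35000, 5000, by = -1500)
  expect_true(all(diff(net_od(40000, pv)) > 0))
  # negative values flagged, not rejected
  flagged <- net_od(40000, c(41000, 20000))
  expect_equal(attr(flagged, "flagged_negative"), 1L)
  expect_error(net_od(0, 100), "> 0")
})

test_that("calibration fit recovers known parameters exactly without noise", {
  pts <- calibration_fixture(n_points = 10)
  for (ch in c("red", "green")) {
    fit <- fit_calibration(pts, ch)
    truth <- true_calibration(ch)
    expect_equal(fit$n, truth$n)
    expect_lt(abs(fit$b / truth$b - 1), 1e-6)
    expect_lt(abs(fit$c / truth$c - 1), 1e-6)
    expect_equal(unname(predict(fit, 0)), 0)
  }
})

test_that("calibration fit tolerates measurement noise in dose recovery", {
  # 1% netOD noise on 10 points: node-dose recovery errors stay in the
  # few-percent range; an occasional seed flips the exponent choice, which
  # costs a few percent more but never an order of magnitude
  clean <- calibration_fixture(n_points = 10)
  worst <- vapply(1:5, function(s) {
    pts <- calibration_fixture(n_points = 10, noise_sd = 0.01, seed = s)
    fit <- fit_calibration(pts, "red")
    max(abs(predict(fit, clean$netod_red[-1]) / clean$dose_cGy[-1] - 1))
  }, 0)
  expect_lt(stats::median(worst), 0.03)
  expect_lt(max(worst), 0.08)
})

test_that("degenerate calibration inputs are refused", {
  pts <- calibration_fixture(n_points = 4)
  expect_error(fit_calibration(pts, "red"), "at least 5")
  bad <- calibration_fixture(n_points = 8)
  bad$netod_red[5] <- bad$netod_red[3]   # netOD no longer increasing
  expect_error(fit_calibration(bad, "red"), "monotone")
  expect_error(calibration_points(c(1, 2), c(0, 0.1), c(0, 0.1)), "dose 0")
})

test_that("channel selection switches at the 10 Gy boundary", {
  expect_identical(select_channel(400), "red")
  expect_identical(select_channel(999.99), "red")
  expect_identical(select_channel(1000), "green")
  expect_identical(select_channel(1500), "green")
  expect_error(select_channel(0), "> 0")
})

test_that("dose -> synthetic scan -> dose is the identity over the calibration span", {
  fit_r <- fit_calibration(calibration_fixture(), "red")
  fit_g <- fit_calibration(calibration_fixture(), "green")
  # span 0-19 Gy on one grid (green channel covers the high range)
  doses <- matrix(seq(0, 1900, length.out = 144), 12, 12)
  grid <- dose_grid(doses, spacing = 0.1, medium = "ABS")
  back <- scan_to_dose(synthesize_scan(grid, fit_g), fit_g)
  expect_lt(max(abs(back$values - grid$values)), 1e-8)
  # low-dose map through the red channel
  low <- dose_grid(doses / 4, spacing = 0.1)
  back_r <- scan_to_dose(synthesize_scan(low, fit_r), fit_r)
  expect_lt(max(abs(back_r$values - low$values)), 1e-8)
  # unexposed scan maps to zero dose
  blank <- film_scan(list(red = matrix(40000, 5, 5)), 0.1,
                     c(red = 40000))
  expect_true(all(scan_to_dose(blank, fit_r)$values == 0))
})

test_that("scan-to-dose handles noise, saturation and missing channels", {
  fit <- fit_calibration(calibration_fixture(), "red")
  plan <- hdr_plan(40700, list(dwell_point(0, dwell_time_for_dose(
    40700, tiny_source(), 400))), tiny_source())
  truth <- dose_plane(plan, grid_spec(extent = c(3, 3), spacing = 0.15),
                      cf = abs_conversion_curve())
  scan <- synthesize_scan(truth, fit)
  set.seed(99)
  noisy <- scan
  noisy$channels$red <- pmin(noisy$channels$red *
    (1 + matrix(rnorm(length(noisy$channels$red), sd = 0.005),
                nrow(noisy$channels$red))), 65535)
  got <- scan_to_dose(noisy, fit)
  sel <- truth$values > 50
  rel <- abs(got$values[sel] / truth$values[sel] - 1)
  # 0.5% pixel noise propagates to 1-3% dose noise (worst at the lowest
  # doses, where the calibration slope is shallow)
  expect_lt(stats::median(rel), 0.015)
  expect_gt(mean(rel < 0.03), 0.90)
  expect_gt(mean(rel < 0.05), 0.97)
  # saturated scan: every pixel far beyond the calibrated netOD range
  sat <- film_scan(list(red = matrix(1, 4, 4)), 0.1, c(red = 40000))
  expect_error(scan_to_dose(sat, fit), "saturated")
  green_only <- film_scan(list(green = matrix(30000, 4, 4)), 0.1,
                          c(green = 40000))
  expect_error(scan_to_dose(green_only, fit), "no red channel")
})

test_that("film scans and calibration tables round-trip through text files", {
  fit <- fit_calibration(calibration_fixture(), "red")
  grid <- dose_grid(matrix(seq(0, 800, length.out = 36), 6, 6), spacing = 0.2)
  scan <- synthesize_scan(grid, fit)
  paths <- c(red = tempfile(fileext = ".txt"))
  write_film_scan(scan, paths)
  back <- read_film_scan(paths)
  expect_equal(back$channels$red, scan$channels$red, tolerance = 1e-9)
  expect_equal(back$spacing, scan$spacing)
  expect_equal(back$unexposed[["red"]], 40000)

  pts <- calibration_fixture()
  cp <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(pts), cp, row.names = FALSE)
  back_pts <- read_calibration_points(cp)
  expect_equal(back_pts$dose_cGy, pts$dose_cGy)
})
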