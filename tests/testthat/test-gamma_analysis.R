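test_that("gamma of a distribution against itself is identically zero", {
  pair <- gamma_pair("smooth", seed = 11)
  res <- gamma_map(pair$ref, pair$ref)
  expect_true(all(res$gamma[!is.nan(res$gamma)] < 1e-12))
  expect_equal(res$passing_rate, 100)
  expect_equal(res$n_passed, res$n_evaluated)
})

test_that("uniform dose offsets give the closed-form gamma", {
  ref <- dose_grid(matrix(100, 15, 15), spacing = 0.2)
  up2 <- gamma_map(ref, dose_grid(matrix(102, 15, 15), spacing = 0.2))
  expect_equal(unique(as.numeric(up2$gamma)), 2 / 3, tolerance = 1e-9)
  expect_equal(up2$passing_rate, 100)
  up4 <- gamma_map(ref, dose_grid(matrix(104, 15, 15), spacing = 0.2))
  expect_equal(unique(as.numeric(up4$gamma)), 4 / 3, tolerance = 1e-9)
  expect_equal(up4$passing_rate, 0)
  # symmetric in sign for a uniform field
  dn2 <- gamma_map(ref, dose_grid(matrix(98, 15, 15), spacing = 0.2))
  expect_equal(unique(as.numeric(dn2$gamma)), 2 / 3, tolerance = 1e-9)
})

test_that("a sub-DTA rigid shift of a gradient field passes everywhere", {
  # dose ramp f(u); evaluated grid holds f shifted by +2 mm and extends past
  # the reference on both sides so every reference point can find its match
  sp <- 0.1
  f <- function(u) 50 + 30 * u
  ev_u <- seq(0.1, 2.5, by = sp)
  ev <- dose_grid(matrix(rep(f(ev_u - 0.2), 25), 25, 25),
                  spacing = sp, origin = c(0.1, 0.1))
  ref_u <- seq(0.5, 2.1, by = sp)
  ref <- dose_grid(matrix(rep(f(ref_u), 17), 17, 17),
                   spacing = sp, origin = c(0.5, 0.5))
  res <- gamma_map(ref, ev)
  expect_equal(res$passing_rate, 100)
  # pure 2 mm spatial residual against a 3 mm DTA
  expect_true(all(res$gamma[!is.nan(res$gamma)] <= 2 / 3 + 0.02))
})

test_that("loosening criteria never lowers the passing rate", {
  for (kind in c("smooth", "random")) {
    pair <- gamma_pair(kind, seed = 21)
    base <- gamma_map(pair$ref, pair$eval, gamma_criteria(2, 1))
    wider_dose <- gamma_map(pair$ref, pair$eval, gamma_criteria(3, 1))
    wider_dta <- gamma_map(pair$ref, pair$eval, gamma_criteria(2, 2))
    expect_gte(wider_dose$passing_rate, base$passing_rate)
    expect_gte(wider_dta$passing_rate, base$passing_rate)
  }
})

test_that("global-normalization gamma is invariant under common rescaling", {
  pair <- gamma_pair("smooth", seed = 31)
  res1 <- gamma_map(pair$ref, pair$eval)
  ref2 <- dose_grid(pair$ref$values * 7.3, spacing = pair$ref$spacing,
                    origin = pair$ref$origin)
  ev2 <- dose_grid(pair$eval$values * 7.3, spacing = pair$eval$spacing,
                   origin = pair$eval$origin)
  res2 <- gamma_map(ref2, ev2)
  expect_equal(res2$gamma, res1$gamma, tolerance = 1e-9)
})

test_that("local normalization and low-dose threshold behave as specified", {
  # smooth gradient with a uniform +2% evaluated offset: under local 3% the
  # zero-shift dose term is 2/3 at every point, and shifting can only lower
  # gamma further
  n <- 15
  vals <- matrix(rep(seq(50, 150, length.out = n), n), n, n)
  ref <- dose_grid(vals, spacing = 0.2)
  ev <- dose_grid(vals * 1.02, spacing = 0.2)
  loc <- gamma_map(ref, ev, gamma_criteria(normalization = "local"))
  g <- loc$gamma[!is.nan(loc$gamma)]
  expect_true(all(g <= 2 / 3 + 1e-9))
  # at the reference minimum the evaluated field exceeds it by >= 2% of the
  # local dose everywhere, so no shift can beat the zero-offset dose term
  expect_equal(loc$gamma[1, 1], 2 / 3, tolerance = 1e-9)
  # threshold counting: points below 10% of the maximum are excluded
  mixed <- dose_grid(matrix(c(rep(5, 25), rep(100, 200)), n, n),
                     spacing = 0.2)
  thr <- gamma_map(mixed, mixed, gamma_criteria())
  expect_equal(thr$n_evaluated, 200)
  all_in <- gamma_map(mixed, mixed, gamma_criteria(low_dose_threshold = 0))
  expect_equal(all_in$n_evaluated, 225)
})

test_that("disjoint grids and zero normalization are rejected", {
  a <- dose_grid(matrix(1, 5, 5), spacing = 0.1, origin = c(0, 0))
  b <- dose_grid(matrix(1, 5, 5), spacing = 0.1, origin = c(10, 10))
  expect_error(gamma_map(a, b), "overlap")
  z <- dose_grid(matrix(0, 5, 5), spacing = 0.1)
  expect_error(gamma_map(z, a), "normalization dose")
  big <- dose_grid(matrix(1, 220, 5), spacing = 0.1)
  expect_error(gamma_oracle(big, big), "200 x 200")
})

test_that("gamma_map matches the exhaustive oracle on structured pairs", {
  kinds <- c("smooth", "gradient", "random", "uniform")
  for (i in seq_along(kinds)) {
    pair <- gamma_pair(kinds[i], seed = 100 + i)
    m <- gamma_map(pair$ref, pair$eval)
    o <- gamma_oracle(pair$ref, pair$eval)
    expect_lt(max(abs(m$gamma - o$gamma), na.rm = TRUE), 0.01)
    expect_equal(m$n_evaluated, o$n_evaluated)
  }
  # also across differing grid spacings
  pair <- gamma_pair("smooth", seed = 140)
  ev <- dose_grid(pair$eval$values, spacing = 0.13)
  m <- gamma_map(pair$ref, ev)
  o <- gamma_oracle(pair$ref, ev)
  expect_lt(max(abs(m$gamma - o$gamma), na.rm = TRUE), 0.01)
})

test_that("gamma reports serialize with criteria and counts", {
  pair <- gamma_pair("smooth", seed = 51)
  res <- gamma_map(pair$ref, pair$eval)
  p <- tempfile(fileext = ".txt")
  write_gamma_report(res, p)
  txt <- readLines(p)
  expect_true(any(grepl("passing_rate_percent", txt)))
  expect_true(any(grepl("3%/3 mm", txt)))
  expect_equal(length(txt) - 8, nrow(res$gamma))
})
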