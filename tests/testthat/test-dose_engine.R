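test_that("line-source geometry factor matches closed forms and limits", {
  # on-axis closed form at r = 1, L = 0.35: 1 / (1 - L^2/4)
  expect_equal(geometry_factor_line(1, 0, 0.35), 1 / (1 - 0.030625))
  expect_equal(geometry_factor_line(1, 180, 0.35), 1 / (1 - 0.030625))
  # transverse axis: beta = 2 atan(L / 2r)
  expect_equal(geometry_factor_line(1, 90, 0.35), 2 * atan(0.175) / 0.35)
  # point-source limit at r >> L
  expect_lt(abs(geometry_factor_line(10, 90, 0.35) * 100 - 1), 1e-3)
  expect_lt(abs(geometry_factor_line(8, 37, 0.35) * 64 - 1), 1e-3)
  # inside the source segment on axis
  expect_error(geometry_factor_line(0.1, 0, 0.35), "inside the source")
})

test_that("geometry factor agrees with the quadrature oracle over an (r, theta) lattice", {
  for (r in c(0.5, 1, 2, 5, 10))
    for (th in c(5, 30, 60, 90, 120, 155, 175)) {
      expect_lt(abs(geometry_factor_line(r, th, 0.35) /
                      quadrature_geometry_factor(r, th, 0.35) - 1),
                1e-6)
    }
})

test_that("dose rate at the reference point reduces to S_K * Lambda", {
  spec <- tiny_source()
  expect_equal(dose_rate_point(1, spec, 1, 90), spec$dose_rate_constant)
  expect_equal(dose_rate_point(40700, spec, 1, 90), 40700 * 1.109)
  # linearity in S_K anywhere
  expect_equal(dose_rate_point(2, spec, 2.3, 40),
               2 * dose_rate_point(1, spec, 2.3, 40))
  # medium conversion multiplies in CF(r)
  cv <- abs_conversion_curve()
  expect_equal(dose_rate_point(1, spec, 1, 90, cf = cv),
               spec$dose_rate_constant * 0.932)
})

test_that("dose_plane superposes dwells like the explicit summation oracle", {
  spec <- tiny_source()
  plan <- hdr_plan(40700,
                   list(dwell_point(-0.5, 10), dwell_point(0, 25),
                        dwell_point(0.7, 40)),
                   spec, label = "3 dwells")
  gs <- grid_spec(offset = 1, extent = c(3, 3), spacing = 0.3)
  got <- dose_plane(plan, gs)
  # oracle: loop over dwells and grid nodes, reconstructing the geometry
  u <- plan$dwells[[1]]$position + got$origin[1] +
    (seq_len(nrow(got$values)) - 1) * got$spacing
  v <- got$origin[2] + (seq_len(ncol(got$values)) - 1) * got$spacing
  expected <- matrix(0, length(u), length(v))
  for (dw in plan$dwells)
    for (i in seq_along(u))
      for (j in seq_along(v)) {
        du <- u[i] - dw$position
        r <- sqrt(du^2 + v[j]^2 + 1)
        th <- acos(du / r) * 180 / pi
        expected[i, j] <- expected[i, j] +
          dose_rate_point(40700, spec, r, th) * dw$time / 3600
      }
  expect_equal(got$values, expected, tolerance = 1e-12)
})

test_that("dose_plane is linear in dwell time and mirror-symmetric for symmetric plans", {
  spec <- tiny_source()
  gs <- grid_spec(extent = c(2, 2), spacing = 0.25)
  p1 <- hdr_plan(100, list(dwell_point(-0.5, 20), dwell_point(0.5, 20)), spec)
  p2 <- hdr_plan(100, list(dwell_point(-0.5, 40), dwell_point(0.5, 40)), spec)
  g1 <- dose_plane(p1, gs)
  g2 <- dose_plane(p2, gs)
  expect_equal(g2$values, 2 * g1$values, tolerance = 1e-12)
  # mirror symmetry about the v-axis through the pattern center
  expect_equal(g1$values, g1$values[nrow(g1$values):1, ], tolerance = 1e-9)
})

test_that("single-dwell grids record radii and satisfy water/ABS consistency", {
  spec <- tiny_source()
  cv <- abs_conversion_curve()
  plan <- hdr_plan(40700, list(dwell_point(0, 30)), spec)
  gs <- grid_spec(extent = c(3, 3), spacing = 0.3)
  water <- dose_plane(plan, gs)
  solid <- dose_plane(plan, gs, cf = cv)
  expect_identical(water$medium, "water")
  expect_identical(solid$medium, "ABS")
  radii <- attr(water, "radii")
  expect_false(is.null(radii))
  expect_equal(solid$values / water$values,
               matrix(cf_at(cv, as.numeric(radii)), nrow(water$values)),
               tolerance = 1e-12)
  # apply_cf on the recorded radii reproduces the engine's own conversion
  expect_equal(apply_cf(water, cv)$values, solid$values, tolerance = 1e-12)
})

test_that("dwell_time_for_dose normalizes the reference point dose", {
  spec <- tiny_source()
  tm <- dwell_time_for_dose(40700, spec, 400)
  plan <- hdr_plan(40700, list(dwell_point(0, tm)), spec)
  expect_equal(point_dose(plan), 400, tolerance = 1e-12)
  # the grid node directly under the dwell carries the prescription
  g <- dose_plane(plan, grid_spec(extent = c(2, 2), spacing = 0.1))
  i <- round(-g$origin[1] / g$spacing) + 1
  j <- round(-g$origin[2] / g$spacing) + 1
  expect_equal(g$values[i, j], 400, tolerance = 1e-9)
})

test_that("plan and dose-grid files round-trip", {
  spec_path <- write_source_fixture(tempfile(fileext = ".txt"))
  src <- read_source_spec(spec_path)
  plan <- hdr_plan(12345.5, list(dwell_point(-0.25, 12.5), dwell_point(1, 3)),
                   src, label = "io test")
  pp <- tempfile(fileext = ".plan")
  write_plan(plan, pp, source_path = spec_path)
  back <- read_plan(pp)
  expect_equal(back$air_kerma_strength, plan$air_kerma_strength)
  expect_equal(vapply(back$dwells, `[[`, 0, "time"),
               vapply(plan$dwells, `[[`, 0, "time"))
  expect_equal(back$label, "io test")

  g <- dose_plane(plan, grid_spec(extent = c(2, 2), spacing = 0.4))
  gp <- tempfile(fileext = ".txt")
  write_dose_grid(g, gp)
  gb <- read_dose_grid(gp)
  expect_equal(gb$values, g$values, tolerance = 1e-9)
  expect_equal(gb$origin, g$origin)
  expect_identical(gb$medium, "water")
  expect_error(read_plan(tempfile()), "not found")
})

test_that("empty or invalid plans are rejected", {
  spec <- tiny_source()
  expect_error(hdr_plan(100, list(), spec), "at least one dwell")
  expect_error(hdr_plan(-1, list(dwell_point(0, 1)), spec), "positive")
  expect_error(dwell_point(0, -5), ">= 0")
})
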