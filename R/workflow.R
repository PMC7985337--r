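# Sum of per-dwell dose rates (cGy/h per unit time weight) at the plane
# point 1 cm below the dwell-pattern centroid, used for plan normalization
# and reference-point doses.
.point_rate <- function(air_kerma_strength, source, positions, offset = 1,
                        cf = NULL, at = mean(positions)) {
  du <- at - positions
  r <- sqrt(du^2 + offset^2)
  theta <- acos(pmin(pmax(du / r, -1), 1)) * 180 / pi
  dose_rate_point(air_kerma_strength, source, r, theta, cf = cf)
}

#' Build a standard verification test case
#'
#' The three planar QA cases: a single dwell (feasibility of the medium
#' conversion and the whole chain), an elliptical dose distribution from
#' equal dwell times at 5 mm pitch, and a concave-elliptical distribution
#' from a monotone dwell-time ramp over the same positions (illustrative
#' weights 1..N; the ramp shape is a package choice, not a reproduction of
#' any clinical plan). Dwell times are normalized so the water-formalism dose
#' at the point 1 cm below the dwell-pattern centroid equals the
#' prescription; for the single dwell this is the TG-43 reference point
#' (r = 1 cm, theta = 90 deg) exactly.
#'
#' @param case_id `"single_dwell"`, `"elliptical"` or `"concave"`.
#' @param prescription prescribed water dose at the normalization point, cGy.
#' @param source a [source_spec()] (default: the packaged synthetic source).
#' @param air_kerma_strength \eqn{S_K}, U; default 40700 U (a nominal 10 Ci
#'   Ir-192 source).
#' @param n_dwells number of dwells for the multi-dwell cases (default 7).
#' @param pitch dwell spacing, cm (default 0.5, the 5 mm step).
#' @return an [hdr_plan()].
#' @examples
#' plan <- make_case("single_dwell", 400)
#' @export
make_case <- function(case_id = c("single_dwell", "elliptical", "concave"),
                      prescription, source = packaged_source(),
                      air_kerma_strength = 40700, n_dwells = 7L,
                      pitch = 0.5) {
  case_id <- match.arg(case_id)
  if (!is.numeric(prescription) || length(prescription) != 1L ||
      !is.finite(prescription) || prescription <= 0)
    stop("make_case: prescription must be a single positive dose (cGy)")
  if (case_id == "single_dwell") {
    tm <- dwell_time_for_dose(air_kerma_strength, source, prescription)
    return(hdr_plan(air_kerma_strength, list(dwell_point(0, tm)), source,
                    label = sprintf("single_dwell_%gcGy", prescription)))
  }
  n_dwells <- as.integer(n_dwells)
  if (n_dwells < 2L) stop("make_case: multi-dwell cases need >= 2 dwells")
  positions <- (seq_len(n_dwells) - (n_dwells + 1) / 2) * pitch
  weights <- if (case_id == "elliptical") rep(1, n_dwells)
             else seq_len(n_dwells)   # documented monotone time ramp
  rates <- .point_rate(air_kerma_strength, source, positions)
  scale <- 3600 * prescription / sum(weights * rates)
  dwells <- lapply(seq_len(n_dwells), function(i)
    dwell_point(positions[i], scale * weights[i]))
  hdr_plan(air_kerma_strength, dwells, source,
           label = sprintf("%s_%gcGy", case_id, prescription))
}

#' Point dose at the plan reference point
#'
#' Analytic (not grid-sampled) dose at the plane point 1 cm below the
#' dwell-pattern centroid, in water (`cf = NULL`) or in the solid phantom.
#'
#' @param plan an [hdr_plan()].
#' @param cf optional [conversion_curve()].
#' @param offset perpendicular plane offset, cm (default 1).
#' @return dose in cGy.
#' @export
point_dose <- function(plan, cf = NULL, offset = 1) {
  stopifnot(inherits(plan, "hdr_plan"))
  positions <- vapply(plan$dwells, `[[`, 0, "position")
  times <- vapply(plan$dwells, `[[`, 0, "time")
  rates <- .point_rate(plan$air_kerma_strength, plan$source, positions,
                       offset = offset, cf = cf)
  sum(rates * times) / 3600
}

#' Synthesize a measured dose distribution
#'
#' Stands in for a film measurement: the truth grid is rigidly shifted
#' (bilinear resampling, edge-clamped) and then perturbed with multiplicative
#' Gaussian noise. Deterministic under a fixed seed; the caller's RNG state
#' is left untouched.
#'
#' @param truth a [dose_grid()].
#' @param noise_sd_fraction standard deviation of the multiplicative noise
#'   as a fraction of the local dose (>= 0).
#' @param shift rigid (u, v) shift in mm applied to the truth before
#'   sampling.
#' @param seed integer seed for the noise.
#' @return a [dose_grid()] on the same lattice as `truth`.
#' @export
simulate_measurement <- function(truth, noise_sd_fraction = 0,
                                 shift = c(0, 0), seed = 1L) {
  stopifnot(inherits(truth, "dose_grid"))
  if (!is.finite(noise_sd_fraction) || noise_sd_fraction < 0)
    stop("simulate_measurement: noise must be >= 0")
  shift <- rep_len(as.numeric(shift), 2L) / 10   # mm -> cm
  vals <- truth$values
  if (any(shift != 0)) {
    nu <- nrow(vals); nv <- ncol(vals)
    # sample the shifted truth on the original lattice (edge-clamped)
    ai <- seq_len(nu) - shift[1L] / truth$spacing
    bj <- seq_len(nv) - shift[2L] / truth$spacing
    ai <- pmin(pmax(ai, 1), nu); bj <- pmin(pmax(bj, 1), nv)
    i0 <- pmin(floor(ai), nu - 1L); ti <- ai - i0
    j0 <- pmin(floor(bj), nv - 1L); tj <- bj - j0
    rows <- vals[i0, , drop = FALSE] * (1 - ti) +
      vals[i0 + 1L, , drop = FALSE] * ti
    vals <- rows[, j0, drop = FALSE] * rep(1 - tj, each = nu) +
      rows[, j0 + 1L, drop = FALSE] * rep(tj, each = nu)
  }
  if (noise_sd_fraction > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    vals <- vals * (1 + stats::rnorm(length(vals), sd = noise_sd_fraction))
    vals <- matrix(pmax(vals, 0), nrow(truth$values))
  }
  dose_grid(vals, spacing = truth$spacing, origin = truth$origin,
            medium = truth$medium)
}

#' End-to-end dosimetric verification
#'
#' Runs the whole QA chain for one plan: the water-formalism plane (the
#' TPS-like calculation, which assumes all dose is deposited in water), the
#' solid-phantom plane (the independent calculation with CF(r) applied per
#' dwell contribution), a measured plane (supplied, or synthesized from the
#' solid-phantom plane), point doses at the reference point 1 cm below the
#' dwell-pattern centroid, and gamma analyses of both calculations against
#' the measurement.
#'
#' @param plan an [hdr_plan()].
#' @param cf a [conversion_curve()] for the phantom medium (required: the
#'   measurement lives in the solid phantom).
#' @param measurement a measured [dose_grid()], or `NULL` to synthesize one
#'   from the solid-phantom plane via [simulate_measurement()].
#' @param grid a [grid_spec()].
#' @param criteria a [gamma_criteria()].
#' @param noise_sd_fraction,shift,seed passed to [simulate_measurement()]
#'   when `measurement` is `NULL`.
#' @param pass_threshold verification passes when the solid-phantom
#'   calculation's gamma passing rate reaches this percentage (default 95).
#' @return an object of class `"verification_report"`.
#' @examples
#' \donttest{
#' rep <- run_verification(make_case("single_dwell", 400),
#'                         cf = abs_conversion_curve(),
#'                         grid = grid_spec(extent = c(4, 4), spacing = 0.2))
#' rep$point_doses
#' }
#' @export
run_verification <- function(plan, cf, measurement = NULL,
                             grid = grid_spec(),
                             criteria = gamma_criteria(),
                             noise_sd_fraction = 0, shift = c(0, 0),
                             seed = 1L, pass_threshold = 95) {
  stopifnot(inherits(plan, "hdr_plan"))
  if (!inherits(cf, "conversion_curve"))
    stop("run_verification: a conversion curve is required (the measurement ",
         "medium is the solid phantom); pass cf = abs_conversion_curve()")
  water <- dose_plane(plan, grid, cf = NULL)
  solid <- dose_plane(plan, grid, cf = cf)
  if (is.null(measurement))
    measurement <- simulate_measurement(solid, noise_sd_fraction, shift, seed)
  if (!inherits(measurement, "dose_grid"))
    stop("run_verification: measurement must be a dose_grid or NULL")

  pd <- c(tps_water = point_dose(plan, cf = NULL, offset = grid$offset),
          calc_abs = point_dose(plan, cf = cf, offset = grid$offset),
          measured = .grid_value_at(measurement,
                                    mean(vapply(plan$dwells, `[[`, 0,
                                                "position")) -
                                      plan$dwells[[1L]]$position, 0))
  g_tps <- gamma_map(measurement, water, criteria)
  g_calc <- gamma_map(measurement, solid, criteria)
  structure(list(label = plan$label, point_doses = pd,
                 gamma_tps = g_tps, gamma_calc = g_calc,
                 criteria = criteria,
                 water = water, solid = solid, measurement = measurement,
                 pass_threshold = pass_threshold,
                 passed = g_calc$passing_rate >= pass_threshold),
            class = "verification_report")
}

# Nearest-lattice-point value of a dose grid at plane coordinates (u, v).
.grid_value_at <- function(grid, u, v) {
  i <- round((u - grid$origin[1L]) / grid$spacing) + 1L
  j <- round((v - grid$origin[2L]) / grid$spacing) + 1L
  if (i < 1L || i > nrow(grid$values) || j < 1L || j > ncol(grid$values))
    stop("reference point lies outside the measured grid")
  grid$values[i, j]
}

#' @export
print.verification_report <- function(x, ...) {
  cat("Dosimetric verification:", x$label, "\n")
  cat(sprintf("  point dose 1 cm below source: water %.2f / phantom-corrected %.2f / measured %.2f cGy\n",
              x$point_doses[["tps_water"]], x$point_doses[["calc_abs"]],
              x$point_doses[["measured"]]))
  cat(sprintf("  gamma (%g%%/%g mm, %s): water-calc vs measured %.2f%%, corrected-calc vs measured %.2f%%\n",
              x$criteria$dose_difference, x$criteria$dta,
              x$criteria$normalization,
              x$gamma_tps$passing_rate, x$gamma_calc$passing_rate))
  cat(sprintf("  verdict: %s (threshold %.1f%% on the corrected calculation)\n",
              if (x$passed) "PASS" else "FAIL", x$pass_threshold))
  invisible(x)
}

#' Write a verification report
#'
#' Human-readable summary plus a delimited point-dose table; dose and gamma
#' grids are written alongside when `artifacts = TRUE`.
#'
#' @param report a `verification_report`.
#' @param path output file for the summary.
#' @param artifacts also write the water/solid/measured grids and both gamma
#'   maps next to `path`.
#' @return `path`, invisibly.
#' @export
write_verification_report <- function(report, path, artifacts = FALSE) {
  stopifnot(inherits(report, "verification_report"))
  lines <- c("# brachyqa verification report v1",
             sprintf("# generated: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             sprintf("label: %s", report$label),
             sprintf("criteria: %g%%/%g mm %s, threshold %g%%",
                     report$criteria$dose_difference, report$criteria$dta,
                     report$criteria$normalization,
                     report$criteria$low_dose_threshold),
             "point_doses_cGy:",
             sprintf("  tps_water: %.4f", report$point_doses[["tps_water"]]),
             sprintf("  calc_abs: %.4f", report$point_doses[["calc_abs"]]),
             sprintf("  measured: %.4f", report$point_doses[["measured"]]),
             sprintf("gamma_passing_tps_percent: %.4f",
                     report$gamma_tps$passing_rate),
             sprintf("gamma_passing_calc_percent: %.4f",
                     report$gamma_calc$passing_rate),
             sprintf("verdict: %s", if (report$passed) "PASS" else "FAIL"))
  writeLines(lines, path)
  if (artifacts) {
    stem <- sub("\\.[^.]*$", "", path)
    write_dose_grid(report$water, paste0(stem, "_water.txt"))
    write_dose_grid(report$solid, paste0(stem, "_solid.txt"))
    write_dose_grid(report$measurement, paste0(stem, "_measured.txt"))
    write_gamma_report(report$gamma_tps, paste0(stem, "_gamma_tps.txt"))
    write_gamma_report(report$gamma_calc, paste0(stem, "_gamma_calc.txt"))
  }
  invisible(path)
}
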