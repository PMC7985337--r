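#' Water-to-solid-phantom conversion curve CF(r)
#'
#' Doses computed with the TG-43 formalism are doses to water in a water
#' phantom. Measurements in a plastic (ABS) phantom see a different scatter
#' and attenuation environment, so a radial conversion factor
#' \eqn{CF(r) = D_{ABS}(r) / D_{water}(r)} is applied per source
#' contribution. A `conversion_curve` holds Monte-Carlo-derived anchor points
#' and evaluates CF by piecewise-linear interpolation: below the first anchor
#' the first value is held (no near-source physics is invented); above the
#' last anchor CF is exactly 1, the difference being treated as negligible
#' there.
#'
#' @param radii anchor radii in cm, strictly increasing, all positive.
#' @param cf conversion factor at each anchor, all positive.
#' @param medium_pair label for the media ratio, e.g. `"ABS/water"`.
#' @return an object of class `"conversion_curve"`.
#' @examples
#' cv <- abs_conversion_curve()
#' cf_at(cv, c(0.5, 2.1, 6, 8))
#' @export
conversion_curve <- function(radii, cf, medium_pair = "ABS/water") {
  radii <- as.numeric(radii)
  cf <- as.numeric(cf)
  if (length(radii) < 2L || length(radii) != length(cf))
    stop("conversion curve: need >= 2 (radius, cf) anchors of equal length")
  if (any(!is.finite(radii)) || any(radii <= 0) || any(diff(radii) <= 0))
    stop("conversion curve: radii must be positive and strictly increasing")
  if (any(!is.finite(cf)) || any(cf <= 0))
    stop("conversion curve: all cf values must be finite and > 0")
  structure(list(radii = radii, cf = cf,
                 medium_pair = as.character(medium_pair)[1L],
                 valid_range = range(radii)),
            class = "conversion_curve")
}

#' @export
print.conversion_curve <- function(x, ...) {
  cat("Medium conversion curve", x$medium_pair, "\n")
  cat(sprintf("  %d anchors on [%.2f, %.2f] cm; CF = 1 above %.2f cm\n",
              length(x$radii), x$valid_range[1L], x$valid_range[2L],
              x$valid_range[2L]))
  print(data.frame(r_cm = x$radii, cf = x$cf), row.names = FALSE)
  invisible(x)
}

#' Evaluate a conversion curve
#'
#' Piecewise-linear in r between the anchors; clamped to the first anchor
#' below the valid range; exactly 1 above it.
#'
#' @param curve a [conversion_curve()].
#' @param r radial distance(s), cm (> 0).
#' @return numeric vector of conversion factors.
#' @export
cf_at <- function(curve, r) {
  stopifnot(inherits(curve, "conversion_curve"))
  r <- as.numeric(r)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("cf_at: r must be finite and > 0")
  out <- stats::approx(curve$radii, curve$cf, xout = r, rule = 2)$y
  out[r > curve$valid_range[2L]] <- 1
  out
}

#' Read a conversion-factor table file
#'
#' Two-column delimited text (`r_cm, cf`) with `#` comment lines; a comment
#' of the form `# medium_pair: ABS/water` names the media.
#'
#' @param path path to the CF table.
#' @return a [conversion_curve()].
#' @export
read_cf_curve <- function(path) {
  if (!file.exists(path)) stop("CF table not found: ", path)
  raw <- readLines(path, warn = FALSE)
  mp <- grep("^#\\s*medium_pair\\s*:", raw, value = TRUE)
  medium_pair <- if (length(mp))
    trimws(sub("^#\\s*medium_pair\\s*:", "", mp[1L])) else "ABS/water"
  dat <- sub("#.*$", "", raw)
  dat <- trimws(dat)
  dat <- dat[nzchar(dat)]
  rows <- lapply(dat, .split_numeric)
  if (any(lengths(rows) != 2L) || anyNA(unlist(rows)))
    stop("CF table: rows must be 'r_cm, cf' pairs")
  m <- do.call(rbind, rows)
  conversion_curve(m[, 1L], m[, 2L], medium_pair = medium_pair)
}

#' Packaged ABS/water conversion curve
#'
#' The curve anchored at (0.5 cm, 0.88), (1.0 cm, 0.932), (2.1 cm, 1.00),
#' (6.0 cm, 1.08) and (8.0 cm, 1.04): the ABS phantom under-responds close
#' to the source (scatter deficit), crosses unity at 2.1 cm, over-responds
#' up to 6 cm and converges back toward 1 by 8 cm, beyond which the
#' difference is negligible and CF is taken as exactly 1.
#'
#' @return a [conversion_curve()].
#' @export
abs_conversion_curve <- function() {
  read_cf_curve(system.file("extdata", "cf_abs_water.txt",
                            package = "brachyqa", mustWork = TRUE))
}

#' ABS percentage dose at a radial distance
#'
#' The percentage-dose profile in the ABS phantom normalized to the water
#' dose at 1 cm: 100 * CF(r) * g-weighted water percentage. Evaluated at the
#' 1 cm normalization point itself this is simply 100 * CF(1 cm), the
#' ABS dose as a percentage of the water reference dose.
#'
#' @param curve a [conversion_curve()].
#' @param r radial distance(s), cm.
#' @param water_percent water percentage dose at `r` relative to the 1 cm
#'   normalization point (default 100 at r = 1 cm scale, i.e. the caller
#'   supplies the water profile; for the normalization point leave default).
#' @return percentage dose in ABS (%).
#' @export
abs_percent_dose <- function(curve, r, water_percent = 100) {
  cf_at(curve, r) * water_percent
}

#' Apply a conversion curve to a single-dwell dose grid
#'
#' Multiplies a water-medium planar dose grid point-by-point by CF evaluated
#' at each point's radial distance to the (single) dwell that produced it.
#' The grid must carry per-point radii, which [dose_plane()] records when the
#' plan has exactly one dwell; for multi-dwell plans CF must be applied per
#' dwell contribution inside the superposition, i.e. call
#' `dose_plane(plan, grid, cf = curve)` instead.
#'
#' @param grid a [dose_grid()] with a `radii` attribute (single-dwell).
#' @param curve a [conversion_curve()].
#' @return a [dose_grid()] with medium `"ABS"`.
#' @export
apply_cf <- function(grid, curve) {
  stopifnot(inherits(grid, "dose_grid"), inherits(curve, "conversion_curve"))
  radii <- attr(grid, "radii")
  if (is.null(radii))
    stop("apply_cf: grid carries no per-point radii (multi-dwell or imported ",
         "grid); recompute with dose_plane(plan, grid, cf = curve) so CF is ",
         "applied per dwell contribution")
  out <- grid
  out$values <- grid$values * matrix(cf_at(curve, as.numeric(radii)),
                                     nrow = nrow(grid$values))
  out$medium <- "ABS"
  attr(out, "radii") <- radii
  out
}
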