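#' Net optical density
#'
#' Standard radiochromic-film definition:
#' \eqn{netOD = \log_{10}(PV_{unexposed} / PV_{exposed})}. Negative values
#' (exposed pixel brighter than the unexposed reference, i.e. noise) are
#' permitted; their indices are recorded in the `"flagged_negative"`
#' attribute.
#'
#' @param pv_unexposed unexposed-film pixel value(s), > 0.
#' @param pv_exposed exposed-film pixel value(s), > 0.
#' @return net optical density, dimensionless.
#' @examples
#' net_od(40000, 20000)  # log10(2)
#' @export
net_od <- function(pv_unexposed, pv_exposed) {
  if (any(!is.finite(pv_unexposed)) || any(pv_unexposed <= 0) ||
      any(!is.finite(pv_exposed)) || any(pv_exposed <= 0))
    stop("net_od: pixel values must be finite and > 0")
  out <- log10(pv_unexposed / pv_exposed)
  neg <- which(out < 0)
  if (length(neg)) attr(out, "flagged_negative") <- neg
  out
}

#' Film calibration point set
#'
#' Doses (cGy, strictly increasing, starting at 0) with the measured net
#' optical density of the red and green scanner channels at each dose, as
#' obtained by irradiating film pieces over the calibration range (0-19 Gy
#' with a 6 MV beam in the reference protocol).
#'
#' @param doses delivered doses, cGy; strictly increasing, first value 0.
#' @param netod_red,netod_green net optical densities per channel.
#' @return an object of class `"calibration_points"` (a data frame).
#' @export
calibration_points <- function(doses, netod_red, netod_green) {
  doses <- as.numeric(doses)
  if (length(doses) < 2L || any(!is.finite(doses)) || any(diff(doses) <= 0))
    stop("calibration points: doses must be finite and strictly increasing")
  if (doses[1L] != 0)
    stop("calibration points: the point set must include dose 0")
  if (length(netod_red) != length(doses) ||
      length(netod_green) != length(doses))
    stop("calibration points: one netOD per channel per dose required")
  df <- data.frame(dose_cGy = doses, netod_red = as.numeric(netod_red),
                   netod_green = as.numeric(netod_green))
  class(df) <- c("calibration_points", "data.frame")
  df
}

#' Read a film calibration CSV
#'
#' Columns `dose_cGy, netod_red, netod_green`; `#` comment lines allowed.
#'
#' @param path CSV path.
#' @return a [calibration_points()] set.
#' @export
read_calibration_points <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("dose_cGy", "netod_red", "netod_green")
  if (!all(need %in% names(df)))
    stop("calibration file: need columns ", paste(need, collapse = ", "))
  calibration_points(df$dose_cGy, df$netod_red, df$netod_green)
}

#' Fit a dose-versus-netOD calibration curve
#'
#' Fits the standard radiochromic response
#' \eqn{D(netOD) = b \cdot netOD + c \cdot netOD^n} by least squares in
#' (b, c), with the exponent n chosen from a fixed grid \{1.5, 2, 2.5, 3\}
#' by minimum residual sum of squares. Residuals are relative (weighted by
#' 1/dose), since the calibration spans two decades of dose and accuracy is
#' needed in percent, not cGy; the zero-dose point is honoured by
#' construction (both basis terms vanish at netOD 0). The fitted curve must
#' be strictly increasing over the calibrated netOD range.
#'
#' @param points a [calibration_points()] set with at least 5 points.
#' @param channel `"red"` or `"green"`.
#' @return an object of class `"film_calibration"` with `print`, `coef`,
#'   `predict` and `residuals` methods. `predict(curve, netod)` returns dose
#'   in cGy; [netod_for_dose()] inverts the curve.
#' @examples
#' nod <- seq(0, 0.6, length.out = 8)
#' pts <- calibration_points(600 * nod + 2600 * nod^2.5, nod, nod / 2)
#' fit <- fit_calibration(pts, "red")
#' coef(fit)
#' @export
fit_calibration <- function(points, channel = c("red", "green")) {
  stopifnot(inherits(points, "calibration_points"))
  channel <- match.arg(channel)
  x <- points[[paste0("netod_", channel)]]
  d <- points$dose_cGy
  if (length(d) < 5L)
    stop("fit_calibration: at least 5 calibration points are required")
  if (any(diff(x) <= 0))
    stop("fit_calibration: netOD must be strictly increasing with dose ",
         "(non-monotone calibration data)")
  grid_n <- c(1.5, 2, 2.5, 3)
  pos <- d > 0
  best <- NULL
  for (n in grid_n) {
    X <- cbind(x[pos], x[pos]^n) / d[pos]   # relative least squares
    fit <- stats::lm.fit(X, rep(1, sum(pos)))
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss)
      best <- list(n = n, b = fit$coefficients[[1L]],
                   c = fit$coefficients[[2L]], rss = rss,
                   residuals = fit$residuals * d[pos])
  }
  # monotonicity of the fitted curve over the calibrated range
  xs <- seq(max(min(x), 1e-6), max(x), length.out = 200L)
  deriv <- best$b + best$n * best$c * xs^(best$n - 1)
  if (any(deriv <= 0))
    stop("fit_calibration: fitted curve is not strictly increasing over the ",
         "calibrated netOD range; calibration data are unusable as given")
  structure(list(channel = channel, b = best$b, c = best$c, n = best$n,
                 residuals = best$residuals,
                 dose_range = range(d), netod_range = range(x)),
            class = "film_calibration")
}

#' @export
print.film_calibration <- function(x, ...) {
  cat(sprintf("Film calibration (%s channel): D = %.4g netOD + %.4g netOD^%g\n",
              x$channel, x$b, x$c, x$n))
  cat(sprintf("  valid: netOD %.4g-%.4g, dose %.4g-%.4g cGy; RMS residual %.3g cGy\n",
              x$netod_range[1L], x$netod_range[2L],
              x$dose_range[1L], x$dose_range[2L],
              sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' @export
coef.film_calibration <- function(object, ...)
  c(b = object$b, c = object$c, n = object$n)

#' @export
residuals.film_calibration <- function(object, ...) object$residuals

#' @export
predict.film_calibration <- function(object, netod, ...) {
  x <- pmax(as.numeric(netod), 0)   # negative netOD is noise around zero dose
  object$b * x + object$c * x^object$n
}

#' Invert a calibration curve
#'
#' Solves \eqn{b \cdot netOD + c \cdot netOD^n = D} for netOD (bisection
#' followed by Newton polishing; the curve is strictly increasing).
#'
#' @param curve a `film_calibration`.
#' @param dose dose(s), cGy, >= 0.
#' @return net optical density value(s).
#' @export
netod_for_dose <- function(curve, dose) {
  stopifnot(inherits(curve, "film_calibration"))
  dose <- as.numeric(dose)
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("netod_for_dose: dose must be finite and >= 0")
  f <- function(x) curve$b * x + curve$c * x^curve$n
  fp <- function(x) curve$b + curve$n * curve$c * x^(curve$n - 1)
  vapply(dose, function(d) {
    if (d == 0) return(0)
    hi <- max(curve$netod_range[2L], 0.1)
    while (f(hi) < d) hi <- hi * 2
    x <- stats::uniroot(function(x) f(x) - d, c(0, hi), tol = 1e-12)$root
    for (i in 1:3) x <- x - (f(x) - d) / fp(x)   # polish to machine precision
    x
  }, 0)
}

#' Colour-channel selection by dose range
#'
#' The red channel of EBT3-type film is the more sensitive below 10 Gy; the
#' green channel extends the usable range to high doses. The boundary dose
#' (exactly 10 Gy) is assigned to green.
#'
#' @param max_expected_dose maximum expected dose in the measurement, cGy.
#' @return `"red"` or `"green"`.
#' @examples
#' select_channel(400)   # "red"
#' select_channel(1500)  # "green"
#' @export
select_channel <- function(max_expected_dose) {
  if (!is.finite(max_expected_dose) || max_expected_dose <= 0)
    stop("select_channel: max expected dose must be > 0")
  if (max_expected_dose < 1000) "red" else "green"
}

#' Film scan container
#'
#' Per-channel pixel-value grids on a 16-bit scale with the unexposed
#' reference pixel value per channel. Scans are accepted as delimited-text
#' channel grids ([read_film_scan()]); no scanner-specific corrections are
#' applied.
#'
#' @param channels named list of numeric pixel matrices (names among
#'   `"red"`, `"green"`); all values in (0, 65535].
#' @param spacing pixel spacing, cm.
#' @param unexposed named numeric vector of unexposed-film pixel values,
#'   one per channel present.
#' @return an object of class `"film_scan"`.
#' @export
film_scan <- function(channels, spacing, unexposed) {
  if (!is.list(channels) || !length(channels) ||
      is.null(names(channels)) ||
      !all(names(channels) %in% c("red", "green")))
    stop("film scan: channels must be a named list with names in red/green")
  for (ch in names(channels)) {
    m <- channels[[ch]]
    if (!is.matrix(m) || any(!is.finite(m)) || any(m <= 0) || any(m > 65535))
      stop("film scan: ", ch, " channel pixel values must lie in (0, 65535]")
    if (!(ch %in% names(unexposed)) || !is.finite(unexposed[[ch]]) ||
        unexposed[[ch]] <= 0 || unexposed[[ch]] > 65535)
      stop("film scan: missing or invalid unexposed reference for ", ch)
  }
  if (!is.finite(spacing) || spacing <= 0)
    stop("film scan: spacing must be > 0")
  structure(list(channels = channels, spacing = spacing,
                 unexposed = unexposed),
            class = "film_scan")
}

#' Convert a film scan to a planar dose map
#'
#' Per-pixel netOD against the channel's unexposed reference, then evaluation
#' of the calibration curve. The result is tagged as ABS medium (the film
#' sits inside the solid phantom). Pixels whose netOD exceeds the calibrated
#' range are flagged in the `"out_of_range"` attribute.
#'
#' @param scan a [film_scan()].
#' @param curve a `film_calibration` whose channel is present in the scan.
#' @return a [dose_grid()] in cGy, medium `"ABS"`.
#' @export
scan_to_dose <- function(scan, curve) {
  stopifnot(inherits(scan, "film_scan"), inherits(curve, "film_calibration"))
  ch <- curve$channel
  if (!ch %in% names(scan$channels))
    stop("scan_to_dose: scan has no ", ch, " channel")
  pv <- scan$channels[[ch]]
  nod <- matrix(log10(scan$unexposed[[ch]] / pv), nrow(pv), ncol(pv))
  if (all(nod > curve$netod_range[2L]))
    stop("scan_to_dose: scan is saturated (every pixel beyond the calibrated ",
         "netOD range)")
  dose <- matrix(predict(curve, nod), nrow(pv), ncol(pv))
  out <- dose_grid(pmax(dose, 0), spacing = scan$spacing,
                   origin = c(-(nrow(pv) - 1L) / 2, -(ncol(pv) - 1L) / 2) *
                     scan$spacing,
                   medium = "ABS")
  oor <- which(nod > curve$netod_range[2L])
  if (length(oor)) attr(out, "out_of_range") <- oor
  out
}

#' Synthesize a film scan from a dose map
#'
#' Inverts the calibration curve per pixel and converts netOD to pixel
#' values against the unexposed reference:
#' \eqn{PV = PV_0 \cdot 10^{-netOD(D)}}. Pixel values are kept continuous
#' (not quantized to integers) so the noiseless round trip through
#' [scan_to_dose()] is exact to numerical precision.
#'
#' @param grid a [dose_grid()].
#' @param curve a `film_calibration`.
#' @param unexposed unexposed-film pixel value (default 40000).
#' @return a [film_scan()] with the curve's channel.
#' @export
synthesize_scan <- function(grid, curve, unexposed = 40000) {
  stopifnot(inherits(grid, "dose_grid"), inherits(curve, "film_calibration"))
  nod <- matrix(netod_for_dose(curve, as.numeric(grid$values)),
                nrow(grid$values), ncol(grid$values))
  pv <- unexposed * 10^(-nod)
  chans <- list(pv)
  names(chans) <- curve$channel
  unexp <- unexposed
  names(unexp) <- curve$channel
  film_scan(chans, spacing = grid$spacing, unexposed = unexp)
}

#' Read and write film scans as delimited-text channel grids
#'
#' Each channel is one text file in the planar-grid dialect with `#` headers
#' `spacing_cm` and `unexposed_pv`.
#'
#' @param scan a [film_scan()].
#' @param paths named character vector of file paths, one per channel.
#' @return `read_film_scan()` returns a [film_scan()]; `write_film_scan()`
#'   returns `paths` invisibly.
#' @export
write_film_scan <- function(scan, paths) {
  stopifnot(inherits(scan, "film_scan"))
  for (ch in names(scan$channels)) {
    if (!ch %in% names(paths)) stop("write_film_scan: no path for ", ch)
    hdr <- c("# brachyqa film channel grid v1",
             sprintf("# channel: %s", ch),
             sprintf("# spacing_cm: %.17g", scan$spacing),
             sprintf("# unexposed_pv: %.17g", scan$unexposed[[ch]]))
    body <- apply(scan$channels[[ch]], 1L, function(row)
      paste(sprintf("%.10g", row), collapse = " "))
    writeLines(c(hdr, body), paths[[ch]])
  }
  invisible(paths)
}

#' @rdname write_film_scan
#' @export
read_film_scan <- function(paths) {
  if (is.null(names(paths)) || !all(names(paths) %in% c("red", "green")))
    stop("read_film_scan: paths must be named by channel (red/green)")
  chans <- list(); unexp <- numeric(0); spacing <- NULL
  for (ch in names(paths)) {
    raw <- readLines(paths[[ch]], warn = FALSE)
    hdr <- grep("^#", raw, value = TRUE)
    getn <- function(key) {
      ln <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
      if (!length(ln)) stop("film scan file: missing header '", key, "'")
      as.numeric(trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", ln[1L])))
    }
    body <- raw[!grepl("^#", raw)]
    body <- body[nzchar(trimws(body))]
    rows <- lapply(body, .split_numeric)
    if (length(unique(lengths(rows))) != 1L || anyNA(unlist(rows)))
      stop("film scan file: ragged or non-numeric pixel matrix")
    chans[[ch]] <- do.call(rbind, rows)
    unexp[ch] <- getn("unexposed_pv")
    sp <- getn("spacing_cm")
    if (!is.null(spacing) && abs(sp - spacing) > 1e-12)
      stop("read_film_scan: channel files disagree on pixel spacing")
    spacing <- sp
  }
  film_scan(chans, spacing = spacing, unexposed = unexp)
}
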