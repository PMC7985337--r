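#' Gamma-index comparison criteria
#'
#' The gamma index of Low et al. combines a dose-difference criterion with a
#' distance-to-agreement (DTA) criterion: a reference point passes when some
#' nearby evaluated dose lies within the combined ellipsoid, i.e.
#' \eqn{\gamma = \min \sqrt{(\Delta d / \Delta D)^2 + (\Delta r / DTA)^2}
#' \le 1}. The clinical default here is the 3%/3 mm criterion with global
#' normalization.
#'
#' @param dose_difference dose-difference criterion, percent (default 3).
#' @param dta distance to agreement, mm (default 3).
#' @param normalization `"global"` (percent of a single normalization dose)
#'   or `"local"` (percent of the local reference dose).
#' @param norm_dose normalization dose in cGy for global normalization;
#'   `NULL` (default) uses the maximum of the reference distribution.
#' @param low_dose_threshold reference points below this percentage of the
#'   normalization dose are excluded from analysis (default 10).
#' @param search_radius spatial search radius, mm; default 3 * dta, beyond
#'   which the distance term alone already gives gamma > 3.
#' @return an object of class `"gamma_criteria"`.
#' @export
gamma_criteria <- function(dose_difference = 3, dta = 3,
                           normalization = c("global", "local"),
                           norm_dose = NULL, low_dose_threshold = 10,
                           search_radius = 3 * dta) {
  normalization <- match.arg(normalization)
  if (!is.finite(dose_difference) || dose_difference <= 0)
    stop("gamma criteria: dose_difference must be > 0")
  if (!is.finite(dta) || dta <= 0) stop("gamma criteria: dta must be > 0")
  if (!is.finite(low_dose_threshold) || low_dose_threshold < 0 ||
      low_dose_threshold >= 100)
    stop("gamma criteria: low_dose_threshold must lie in [0, 100)")
  if (!is.finite(search_radius) || search_radius < dta)
    stop("gamma criteria: search_radius must be >= dta")
  if (!is.null(norm_dose) && (!is.finite(norm_dose) || norm_dose <= 0))
    stop("gamma criteria: norm_dose must be > 0 when given")
  structure(list(dose_difference = dose_difference, dta = dta,
                 normalization = normalization, norm_dose = norm_dose,
                 low_dose_threshold = low_dose_threshold,
                 search_radius = search_radius),
            class = "gamma_criteria")
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("Gamma criteria: %g%%/%g mm, %s normalization, %g%% threshold\n",
              x$dose_difference, x$dta, x$normalization,
              x$low_dose_threshold))
  invisible(x)
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("Gamma analysis (%g%%/%g mm, %s): %d/%d points pass, %.2f%%\n",
              x$criteria$dose_difference, x$criteria$dta,
              x$criteria$normalization, x$n_passed, x$n_evaluated,
              x$passing_rate))
  invisible(x)
}

# Shared setup for gamma_map / gamma_oracle: resolves units (criteria are in
# mm, grids in cm), the normalization dose, the dose criterion per reference
# point and the analysis mask.
.gamma_setup <- function(reference, evaluated, criteria) {
  stopifnot(inherits(reference, "dose_grid"), inherits(evaluated, "dose_grid"),
            inherits(criteria, "gamma_criteria"))
  ur <- .grid_u(reference); vr <- .grid_v(reference)
  ue <- .grid_u(evaluated); ve <- .grid_v(evaluated)
  if (min(ur) > max(ue) || max(ur) < min(ue) ||
      min(vr) > max(ve) || max(vr) < min(ve))
    stop("gamma: reference and evaluated grids do not overlap spatially")
  norm <- if (is.null(criteria$norm_dose)) max(reference$values)
          else criteria$norm_dose
  if (!is.finite(norm) || norm <= 0)
    stop("gamma: normalization dose is zero; nothing to compare")
  refdose <- as.numeric(reference$values)
  dcrit <- if (criteria$normalization == "global")
    rep_len(criteria$dose_difference / 100 * norm, length(refdose))
  else criteria$dose_difference / 100 * refdose
  mask <- refdose >= criteria$low_dose_threshold / 100 * norm & dcrit > 0
  list(ur = ur, vr = vr, ue = ue, ve = ve, refdose = refdose,
       dcrit = dcrit, mask = mask,
       dta_cm = criteria$dta / 10,
       radius_cm = criteria$search_radius / 10)
}

# Bilinear upsampling of a matrix by integer factor k per axis (separable).
.upsample_bilinear <- function(mat, k) {
  if (k == 1L) return(mat)
  nr <- nrow(mat); nc <- ncol(mat)
  ri <- 1 + (0:((nr - 1L) * k)) / k
  ci <- 1 + (0:((nc - 1L) * k)) / k
  i0 <- pmin(floor(ri), nr - 1L); ti <- ri - i0
  j0 <- pmin(floor(ci), nc - 1L); tj <- ci - j0
  rows <- mat[i0, , drop = FALSE] * (1 - ti) + mat[i0 + 1L, , drop = FALSE] * ti
  rows[, j0, drop = FALSE] * rep(1 - tj, each = length(ri)) +
    rows[, j0 + 1L, drop = FALSE] * rep(tj, each = length(ri))
}

.gamma_result <- function(g, reference, criteria, mask) {
  gmap <- matrix(NaN, nrow(reference$values), ncol(reference$values))
  gmap[mask] <- g
  n_eval <- sum(mask)
  n_pass <- sum(g <= 1)
  structure(list(gamma = gmap, passing_rate = 100 * n_pass / max(n_eval, 1L),
                 n_evaluated = n_eval, n_passed = n_pass,
                 criteria = criteria, spacing = reference$spacing,
                 origin = reference$origin),
            class = "gamma_result")
}

#' Gamma-index map between two planar dose grids
#'
#' For every reference point above the low-dose threshold, searches the
#' evaluated distribution — bilinearly upsampled to at most DTA/10 sampling —
#' within the criteria's search radius for the position minimizing the
#' combined dose-difference / distance measure. Offsets are visited in order
#' of increasing spatial distance so the search can stop as soon as the
#' distance term alone exceeds every point's current minimum.
#'
#' @param reference the reference [dose_grid()] (conventionally the
#'   measurement).
#' @param evaluated the evaluated [dose_grid()] (conventionally the
#'   calculation).
#' @param criteria a [gamma_criteria()].
#' @return an object of class `"gamma_result"`: the gamma map (NaN below
#'   threshold), pass/evaluated counts and the passing rate in percent.
#' @examples
#' g <- dose_grid(matrix(100, 12, 12), spacing = 0.2)
#' e <- dose_grid(matrix(102, 12, 12), spacing = 0.2)
#' gamma_map(g, e, gamma_criteria())$passing_rate  # 100; gamma = 2/3
#' @export
gamma_map <- function(reference, evaluated, criteria = gamma_criteria()) {
  s <- .gamma_setup(reference, evaluated, criteria)
  k <- max(1L, as.integer(ceiling(evaluated$spacing / (s$dta_cm / 10))))
  h <- evaluated$spacing / k
  E <- .upsample_bilinear(evaluated$values, k)
  nfr <- nrow(E); nfc <- ncol(E)

  # reference-point coordinates in fine-lattice (fractional) index space
  A <- (rep(s$ur, times = length(s$vr)) - s$ue[1L]) / h + 1
  B <- (rep(s$vr, each = length(s$ur)) - s$ve[1L]) / h + 1
  A <- A[s$mask]; B <- B[s$mask]
  d0 <- s$refdose[s$mask]
  dc <- s$dcrit[s$mask]
  i0 <- round(A); j0 <- round(B)

  m <- as.integer(ceiling(s$radius_cm / h)) + 1L
  off <- expand.grid(di = -m:m, dj = -m:m)
  odist <- sqrt(off$di^2 + off$dj^2)
  keep <- (odist - sqrt(2)) * h <= s$radius_cm
  off <- off[keep, ]; odist <- odist[keep]
  ord <- order(odist)
  off <- off[ord, ]; odist <- odist[ord]
  # lower bound on the true candidate distance for each offset (the rounded
  # base index is within sqrt(1/2) fine cells of the true position)
  dlow <- pmax(0, (odist - sqrt(0.5)) * h)

  g2 <- rep(Inf, length(A))
  r2max <- s$radius_cm^2
  for (t in seq_len(nrow(off))) {
    if ((dlow[t] / s$dta_cm)^2 >= max(g2)) break
    ri <- i0 + off$di[t]
    cj <- j0 + off$dj[t]
    d2 <- ((ri - A)^2 + (cj - B)^2) * h^2
    valid <- ri >= 1L & ri <= nfr & cj >= 1L & cj <= nfc & d2 <= r2max
    if (!any(valid)) next
    idx <- (cj[valid] - 1L) * nfr + ri[valid]
    cand <- ((E[idx] - d0[valid]) / dc[valid])^2 + d2[valid] / s$dta_cm^2
    g2[valid] <- pmin(g2[valid], cand)
  }
  .gamma_result(sqrt(g2), reference, criteria, s$mask)
}

#' Exhaustive-search gamma oracle
#'
#' Independent reference implementation for validating [gamma_map()]: the
#' evaluated grid is upsampled to 10 samples per DTA and, for every reference
#' point, all fine-grid positions within the search radius are enumerated by
#' brute force. Quadratic cost; refuses grids larger than 200 x 200.
#'
#' @inheritParams gamma_map
#' @return an object of class `"gamma_result"`.
#' @export
gamma_oracle <- function(reference, evaluated, criteria = gamma_criteria()) {
  s <- .gamma_setup(reference, evaluated, criteria)
  if (nrow(reference$values) > 200L || ncol(reference$values) > 200L ||
      nrow(evaluated$values) > 200L || ncol(evaluated$values) > 200L)
    stop("gamma oracle: grids larger than 200 x 200 are not supported")
  k <- max(1L, as.integer(ceiling(10 * evaluated$spacing / s$dta_cm)))
  h <- evaluated$spacing / k
  ne_u <- nrow(evaluated$values); ne_v <- ncol(evaluated$values)
  fu <- s$ue[1L] + (seq_len((ne_u - 1L) * k + 1L) - 1L) * h
  fv <- s$ve[1L] + (seq_len((ne_v - 1L) * k + 1L) - 1L) * h
  # independent bilinear upsample: direct evaluation at every fine node
  iu <- pmin(findInterval(fu, s$ue), ne_u - 1L)
  tv <- pmin(findInterval(fv, s$ve), ne_v - 1L)
  wu <- (fu - s$ue[iu]) / evaluated$spacing
  wv <- (fv - s$ve[tv]) / evaluated$spacing
  Ez <- evaluated$values
  Fgrid <- outer(seq_along(fu), seq_along(fv), function(i, j)
    (1 - wu[i]) * (1 - wv[j]) * Ez[cbind(iu[i], tv[j])] +
      wu[i] * (1 - wv[j]) * Ez[cbind(iu[i] + 1L, tv[j])] +
      (1 - wu[i]) * wv[j] * Ez[cbind(iu[i], tv[j] + 1L)] +
      wu[i] * wv[j] * Ez[cbind(iu[i] + 1L, tv[j] + 1L)])

  pts_u <- rep(s$ur, times = length(s$vr))[s$mask]
  pts_v <- rep(s$vr, each = length(s$ur))[s$mask]
  d0 <- s$refdose[s$mask]
  dc <- s$dcrit[s$mask]
  g <- numeric(length(d0))
  r2max <- s$radius_cm^2
  for (p in seq_along(d0)) {
    du2 <- (fu - pts_u[p])^2
    dv2 <- (fv - pts_v[p])^2
    usel <- which(du2 <= r2max)
    vsel <- which(dv2 <= r2max)
    if (!length(usel) || !length(vsel)) { g[p] <- Inf; next }
    d2 <- outer(du2[usel], dv2[vsel], `+`)
    inr <- d2 <= r2max
    if (!any(inr)) { g[p] <- Inf; next }
    gg <- ((Fgrid[usel, vsel, drop = FALSE] - d0[p]) / dc[p])^2 +
      d2 / s$dta_cm^2
    g[p] <- sqrt(min(gg[inr]))
  }
  .gamma_result(g, reference, criteria, s$mask)
}

#' Write a gamma report
#'
#' Delimited-text gamma map preceded by a `#` summary block (criteria,
#' counts, passing rate).
#'
#' @param result a `gamma_result` from [gamma_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gamma_report <- function(result, path) {
  stopifnot(inherits(result, "gamma_result"))
  hdr <- c("# brachyqa gamma report v1",
           sprintf("# criteria: %g%%/%g mm, %s normalization, threshold %g%%",
                   result$criteria$dose_difference, result$criteria$dta,
                   result$criteria$normalization,
                   result$criteria$low_dose_threshold),
           sprintf("# evaluated: %d", result$n_evaluated),
           sprintf("# passed: %d", result$n_passed),
           sprintf("# passing_rate_percent: %.4f", result$passing_rate),
           sprintf("# spacing_cm: %.17g", result$spacing),
           sprintf("# origin_u_cm: %.17g", result$origin[1L]),
           sprintf("# origin_v_cm: %.17g", result$origin[2L]))
  body <- apply(result$gamma, 1L, function(row)
    paste(sprintf("%.6g", row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
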