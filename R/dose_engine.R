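#' Dwell points and treatment plans
#'
#' A plan is an air-kerma strength \eqn{S_K} plus an ordered set of dwell
#' points along one straight catheter. Dwell positions are signed distances
#' (cm) along the catheter axis from the plan origin; dwell times are in
#' seconds. The source long axis is fixed to the catheter axis.
#'
#' @param position signed position along the catheter axis, cm.
#' @param time dwell time, seconds (>= 0).
#' @return `dwell_point()` returns a list with class `"dwell_point"`.
#' @export
dwell_point <- function(position, time) {
  if (!is.finite(position)) stop("dwell point: position must be finite")
  if (!is.finite(time) || time < 0)
    stop("dwell point: time must be finite and >= 0")
  structure(list(position = as.numeric(position), time = as.numeric(time)),
            class = "dwell_point")
}

#' @rdname dwell_point
#' @param air_kerma_strength \eqn{S_K} in U = cGy cm^2 h^-1 (> 0).
#' @param dwells list of [dwell_point()]s, or a 2-column matrix / data frame
#'   of (position_cm, time_s) rows.
#' @param source a [source_spec()].
#' @param label plan label.
#' @return `hdr_plan()` returns an object of class `"hdr_plan"`.
#' @examples
#' plan <- hdr_plan(40700, list(dwell_point(0, 30)), packaged_source())
#' @export
hdr_plan <- function(air_kerma_strength, dwells, source, label = "plan") {
  if (!is.numeric(air_kerma_strength) || length(air_kerma_strength) != 1L ||
      !is.finite(air_kerma_strength) || air_kerma_strength <= 0)
    stop("plan: air-kerma strength must be a single positive number (U)")
  if (is.matrix(dwells) || is.data.frame(dwells)) {
    m <- as.matrix(dwells)
    dwells <- lapply(seq_len(nrow(m)),
                     function(i) dwell_point(m[i, 1L], m[i, 2L]))
  }
  if (!length(dwells)) stop("plan: at least one dwell is required")
  ok <- vapply(dwells, inherits, TRUE, what = "dwell_point")
  if (!all(ok)) stop("plan: dwells must be dwell_point objects")
  if (!inherits(source, "source_spec"))
    stop("plan: source must be a source_spec")
  structure(list(air_kerma_strength = air_kerma_strength,
                 dwells = dwells, source = source,
                 label = as.character(label)[1L]),
            class = "hdr_plan")
}

#' @export
print.hdr_plan <- function(x, ...) {
  cat("HDR plan:", x$label, "\n")
  cat(sprintf("  S_K = %.1f U, source '%s', %d dwell(s)\n",
              x$air_kerma_strength, x$source$name, length(x$dwells)))
  pos <- vapply(x$dwells, `[[`, 0, "position")
  tm <- vapply(x$dwells, `[[`, 0, "time")
  print(data.frame(position_cm = pos, time_s = tm), row.names = FALSE)
  invisible(x)
}

#' TG-43 line-source geometry factor
#'
#' \eqn{G_L(r,\theta) = \beta / (L r \sin\theta)} where \eqn{\beta} is the
#' angle subtended at the calculation point by the active length \eqn{L};
#' on the long axis (\eqn{\sin\theta = 0}) the closed form
#' \eqn{(r^2 - L^2/4)^{-1}} applies. Vectorized over `r` and `theta`.
#'
#' @param r distance from the source center, cm.
#' @param theta polar angle from the source long axis, degrees in [0, 180].
#' @param L active source length, cm.
#' @return geometry factor in cm^-2.
#' @examples
#' geometry_factor_line(1, 90, 0.35)
#' geometry_factor_line(1, 0, 0.35)  # 1 / (1 - 0.35^2/4)
#' @export
geometry_factor_line <- function(r, theta, L) {
  n <- max(length(r), length(theta))
  r <- rep_len(as.numeric(r), n)
  theta <- rep_len(as.numeric(theta), n)
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("geometry factor: L must be a single positive number (cm)")
  if (any(!is.finite(r)) || any(r <= 0))
    stop("geometry factor: r must be finite and > 0")
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > 180))
    stop("geometry factor: theta must lie in [0, 180] degrees")
  th <- theta * pi / 180
  s <- sin(th)
  z <- r * cos(th)          # coordinate along the source axis
  y <- r * s                # perpendicular distance to the axis
  on_axis <- s < 1e-12
  if (any(on_axis & (r <= L / 2)))
    stop("geometry factor: on-axis point lies inside the source segment ",
         "(r <= L/2)")
  out <- numeric(n)
  if (any(!on_axis)) {
    yy <- y[!on_axis]
    zz <- z[!on_axis]
    beta <- atan((L / 2 - zz) / yy) + atan((L / 2 + zz) / yy)
    out[!on_axis] <- beta / (L * yy)
  }
  if (any(on_axis))
    out[on_axis] <- 1 / (r[on_axis]^2 - L^2 / 4)
  out
}

#' TG-43 line-source dose rate at a point
#'
#' \eqn{\dot D(r,\theta) = S_K \Lambda
#' \frac{G_L(r,\theta)}{G_L(r_0,\theta_0)} g_L(r) F(r,\theta) CF(r)}
#' with the reference point \eqn{(r_0, \theta_0)} = (1 cm, 90 deg) and
#' \eqn{CF \equiv 1} in water (`cf = NULL`).
#'
#' @param air_kerma_strength \eqn{S_K}, U.
#' @param source a [source_spec()].
#' @param r,theta evaluation point, cm / degrees (vectorized).
#' @param cf optional [conversion_curve()]; `NULL` for water.
#' @return dose rate in cGy/h.
#' @examples
#' src <- packaged_source()
#' dose_rate_point(1, src, 1, 90) / src$dose_rate_constant  # = 1
#' @export
dose_rate_point <- function(air_kerma_strength, source, r, theta, cf = NULL) {
  stopifnot(inherits(source, "source_spec"))
  if (!is.null(cf) && !inherits(cf, "conversion_curve"))
    stop("dose_rate_point: cf must be NULL or a conversion_curve")
  L <- source$active_length
  g_ref <- geometry_factor_line(1, 90, L)
  d <- air_kerma_strength * source$dose_rate_constant *
    geometry_factor_line(r, theta, L) / g_ref *
    radial_dose(source, r) * anisotropy(source, r, theta)
  if (!is.null(cf)) d <- d * cf_at(cf, r)
  d
}

#' Planar grid specification
#'
#' The measurement plane is parallel to the catheter axis at a perpendicular
#' offset (default 1 cm, the "1 cm below the source" geometry). Plane
#' coordinates are u along the catheter axis and v transverse to it; the
#' (u, v) origin is the foot of the perpendicular from the first dwell.
#'
#' @param offset perpendicular distance from catheter axis to plane, cm.
#' @param extent numeric length-2, full extent of the grid (u, v), cm.
#' @param spacing grid spacing, cm (default 0.1, i.e. 1 mm).
#' @return an object of class `"grid_spec"`.
#' @export
grid_spec <- function(offset = 1, extent = c(8, 8), spacing = 0.1) {
  extent <- rep_len(as.numeric(extent), 2L)
  if (!is.finite(offset) || offset <= 0)
    stop("grid spec: offset must be > 0 (plane through the source axis is ",
         "not supported)")
  if (any(!is.finite(extent)) || any(extent <= 0))
    stop("grid spec: extent must be positive in both axes")
  if (!is.finite(spacing) || spacing <= 0)
    stop("grid spec: spacing must be > 0")
  structure(list(offset = offset, extent = extent, spacing = spacing),
            class = "grid_spec")
}

#' Planar dose grid
#'
#' A 2D planar dose distribution: matrix of doses (cGy) on a regular (u, v)
#' lattice. `values[i, j]` is the dose at
#' u = origin[1] + (i-1) * spacing, v = origin[2] + (j-1) * spacing.
#'
#' @param values numeric matrix of doses, cGy, all finite and >= 0.
#' @param spacing lattice spacing, cm.
#' @param origin numeric length-2, (u, v) of `values[1, 1]`, cm.
#' @param medium `"water"` or `"ABS"`.
#' @return an object of class `"dose_grid"`.
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0), medium = "water") {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("dose grid: values must be finite and >= 0")
  if (!is.finite(spacing) || spacing <= 0)
    stop("dose grid: spacing must be > 0")
  origin <- rep_len(as.numeric(origin), 2L)
  medium <- match.arg(medium, c("water", "ABS"))
  structure(list(values = values, spacing = spacing, origin = origin,
                 medium = medium),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("Planar dose grid (%s): %d x %d points, %.2f mm spacing\n",
              x$medium, nrow(x$values), ncol(x$values), 10 * x$spacing))
  cat(sprintf("  u: %.2f to %.2f cm, v: %.2f to %.2f cm\n",
              x$origin[1L], x$origin[1L] + (nrow(x$values) - 1L) * x$spacing,
              x$origin[2L], x$origin[2L] + (ncol(x$values) - 1L) * x$spacing))
  cat(sprintf("  dose: %.2f to %.2f cGy\n", min(x$values), max(x$values)))
  invisible(x)
}

# u / v coordinate vectors of a dose grid or (nu, nv, origin, spacing) set
.grid_u <- function(g) g$origin[1L] + (seq_len(nrow(g$values)) - 1L) * g$spacing
.grid_v <- function(g) g$origin[2L] + (seq_len(ncol(g$values)) - 1L) * g$spacing

#' Superpose a plan onto a planar grid
#'
#' Computes, at every grid point, the sum over dwells of the TG-43
#' line-source dose rate times the dwell time (seconds, converted to hours
#' inside). The radial distance and polar angle for each contribution are
#' measured from that dwell, with the source axis along the catheter; the
#' conversion factor, when given, is evaluated at each contribution's own
#' radius, i.e. inside the per-dwell sum.
#'
#' @param plan an [hdr_plan()].
#' @param grid a [grid_spec()].
#' @param cf optional [conversion_curve()] for the solid-phantom medium;
#'   `NULL` computes water dose.
#' @return a [dose_grid()] (medium `"ABS"` when `cf` is given). For a
#'   single-dwell plan the per-point radii are recorded in the `"radii"`
#'   attribute so [apply_cf()] can be used afterwards.
#' @examples
#' plan <- hdr_plan(40700, list(dwell_point(0, 30)), packaged_source())
#' dw <- dose_plane(plan, grid_spec(extent = c(4, 4), spacing = 0.2))
#' @export
dose_plane <- function(plan, grid, cf = NULL) {
  stopifnot(inherits(plan, "hdr_plan"), inherits(grid, "grid_spec"))
  if (!is.null(cf) && !inherits(cf, "conversion_curve"))
    stop("dose_plane: cf must be NULL or a conversion_curve")
  sp <- grid$spacing
  nu <- floor(grid$extent[1L] / sp) + 1L
  nv <- floor(grid$extent[2L] / sp) + 1L
  pos <- vapply(plan$dwells, `[[`, 0, "position")
  # lattice is centered on the dwell-pattern centroid; plane coordinates are
  # expressed relative to the foot of the perpendicular from the first dwell
  centroid <- mean(pos)
  u <- centroid + (seq_len(nu) - 1L - (nu - 1L) / 2) * sp  # axis coordinates
  v <- (seq_len(nv) - 1L - (nv - 1L) / 2) * sp
  U <- matrix(u, nu, nv)
  V <- matrix(v, nu, nv, byrow = TRUE)
  d2_perp <- V^2 + grid$offset^2          # squared distance to catheter axis
  total <- matrix(0, nu, nv)
  radii1 <- NULL
  for (dw in plan$dwells) {
    du <- U - dw$position
    r <- sqrt(du^2 + d2_perp)
    theta <- acos(pmin(pmax(du / r, -1), 1)) * 180 / pi
    rate <- dose_rate_point(plan$air_kerma_strength, plan$source,
                            as.numeric(r), as.numeric(theta), cf = cf)
    total <- total + matrix(rate, nu, nv) * (dw$time / 3600)
    if (length(plan$dwells) == 1L) radii1 <- r
  }
  out <- dose_grid(total, spacing = sp,
                   origin = c(u[1L] - pos[1L], v[1L]),
                   medium = if (is.null(cf)) "water" else "ABS")
  if (!is.null(radii1)) attr(out, "radii") <- radii1
  out
}

#' Dwell time delivering a prescribed water dose at the reference point
#'
#' Returns the dwell time (seconds) for which a single dwell of the given
#' plan strength delivers `dose` cGy in water at (r = 1 cm, theta = 90 deg),
#' where all normalized TG-43 factors equal one and the dose rate is simply
#' \eqn{S_K \Lambda}.
#'
#' @param air_kerma_strength \eqn{S_K}, U.
#' @param source a [source_spec()].
#' @param dose prescribed water dose at the reference point, cGy (> 0).
#' @return time in seconds.
#' @export
dwell_time_for_dose <- function(air_kerma_strength, source, dose) {
  if (!is.finite(dose) || dose <= 0)
    stop("dwell_time_for_dose: dose must be > 0")
  rate <- dose_rate_point(air_kerma_strength, source, 1, 90)  # cGy/h
  3600 * dose / rate
}

#' Read and write planar dose grids
#'
#' Delimited-text format: `#` header lines carry `spacing_cm`, `origin_u_cm`,
#' `origin_v_cm`, `medium` and `units` (always cGy); the body is a
#' whitespace-separated matrix, rows indexing u and columns indexing v.
#'
#' @param grid a [dose_grid()].
#' @param path file path.
#' @return `read_dose_grid()` returns a [dose_grid()];
#'   `write_dose_grid()` returns `path` invisibly.
#' @export
write_dose_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  hdr <- c("# brachyqa dose grid v1",
           sprintf("# spacing_cm: %.17g", grid$spacing),
           sprintf("# origin_u_cm: %.17g", grid$origin[1L]),
           sprintf("# origin_v_cm: %.17g", grid$origin[2L]),
           sprintf("# medium: %s", grid$medium),
           "# units: cGy")
  body <- apply(grid$values, 1L, function(row)
    paste(sprintf("%.10g", row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  if (!file.exists(path)) stop("dose grid file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  hdr <- grep("^#", raw, value = TRUE)
  getn <- function(key) {
    ln <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (!length(ln)) stop("dose grid file: missing header '", key, "'")
    as.numeric(trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", ln[1L])))
  }
  medium_ln <- grep("^#\\s*medium\\s*:", hdr, value = TRUE)
  medium <- if (length(medium_ln))
    trimws(sub("^#\\s*medium\\s*:", "", medium_ln[1L])) else "water"
  body <- raw[!grepl("^#", raw)]
  body <- body[nzchar(trimws(body))]
  rows <- lapply(body, .split_numeric)
  if (length(unique(lengths(rows))) != 1L || anyNA(unlist(rows)))
    stop("dose grid file: ragged or non-numeric matrix body")
  dose_grid(do.call(rbind, rows), spacing = getn("spacing_cm"),
            origin = c(getn("origin_u_cm"), getn("origin_v_cm")),
            medium = medium)
}

#' Read and write plan files
#'
#' Structured text: `key: value` header lines (`label`, `source` file path or
#' `packaged`, `air_kerma_strength_U`) followed by a `[DWELLS]` block of
#' `position_cm, time_s` rows.
#'
#' @param plan an [hdr_plan()].
#' @param path file path.
#' @param source_path value written to the `source` header (default
#'   `"packaged"`, meaning the packaged synthetic source).
#' @return `read_plan()` returns an [hdr_plan()]; `write_plan()` returns
#'   `path` invisibly.
#' @export
write_plan <- function(plan, path, source_path = "packaged") {
  stopifnot(inherits(plan, "hdr_plan"))
  pos <- vapply(plan$dwells, `[[`, 0, "position")
  tm <- vapply(plan$dwells, `[[`, 0, "time")
  writeLines(c("# brachyqa plan v1",
               sprintf("label: %s", plan$label),
               sprintf("source: %s", source_path),
               sprintf("air_kerma_strength_U: %.17g", plan$air_kerma_strength),
               "[DWELLS]",
               sprintf("%.17g, %.17g", pos, tm)),
             path)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  if (!file.exists(path)) stop("plan file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", raw)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  split_at <- match("[DWELLS]", toupper(raw))
  if (is.na(split_at)) stop("plan file: missing [DWELLS] block")
  hdr <- raw[seq_len(split_at - 1L)]
  kv <- strsplit(hdr, ":[[:space:]]*")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- vapply(kv, function(x) trimws(paste(x[-1L], collapse = ":")), "")
  getv <- function(key) {
    i <- match(tolower(key), keys)
    if (is.na(i)) stop("plan file: missing header '", key, "'")
    vals[i]
  }
  sk <- suppressWarnings(as.numeric(getv("air_kerma_strength_U")))
  src_ref <- getv("source")
  src <- if (identical(src_ref, "packaged")) packaged_source()
         else read_source_spec(src_ref)
  rows <- lapply(raw[-seq_len(split_at)], .split_numeric)
  if (!length(rows) || any(lengths(rows) != 2L) || anyNA(unlist(rows)))
    stop("plan file: [DWELLS] rows must be 'position_cm, time_s' pairs")
  dwells <- lapply(rows, function(x) dwell_point(x[1L], x[2L]))
  label <- if ("label" %in% keys) getv("label") else basename(path)
  hdr_plan(sk, dwells, src, label = label)
}
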