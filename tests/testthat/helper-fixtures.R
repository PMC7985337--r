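# Small in-code fixtures shared across tests.

# A compact TG-43 source with hand-checkable tables: g_L linear segments and
# an F grid small enough for manual bilinear arithmetic.
tiny_source <- function() {
  g <- radial_dose_table(c(0.5, 1, 2, 5), c(0.996, 1, 1.004, 0.990))
  f <- anisotropy_table(
    radii = c(0.5, 1, 2, 5),
    angles = c(0, 30, 60, 90, 120, 150, 180),
    values = rbind(
      c(0.64, 0.89, 0.98, 1, 0.98, 0.89, 0.64),
      c(0.66, 0.90, 0.97, 1, 0.97, 0.90, 0.66),
      c(0.68, 0.91, 0.98, 1, 0.98, 0.91, 0.68),
      c(0.72, 0.92, 0.98, 1, 0.98, 0.92, 0.72)))
  source_spec(0.35, 1.109, g, f, name = "tiny test source")
}

# Calibration ground truth used to synthesize film data: the same functional
# family the fitter assumes, with per-channel parameters in a realistic
# EBT3-like range (red saturating earlier than green).
true_calibration <- function(channel = "red") {
  if (channel == "red") list(b = 600, c = 2620, n = 2.5)
  else list(b = 1200, c = 8000, n = 3)
}

# netOD producing dose d under the true response of a channel
true_netod <- function(d, channel) {
  p <- true_calibration(channel)
  vapply(d, function(di) {
    if (di == 0) return(0)
    stats::uniroot(function(x) p$b * x + p$c * x^p$n - di, c(0, 2),
                   tol = 1e-13)$root
  }, 0)
}

# One shared irradiation series (0 to max_dose cGy) read out on both
# channels, with optional multiplicative netOD measurement noise.
calibration_fixture <- function(n_points = 10, noise_sd = 0, seed = NULL,
                                max_dose = 1900) {
  if (!is.null(seed)) set.seed(seed)
  doses <- seq(0, max_dose, length.out = n_points)
  nod_r <- true_netod(doses, "red")
  nod_g <- true_netod(doses, "green")
  if (noise_sd > 0) {
    nod_r <- nod_r * (1 + c(0, stats::rnorm(n_points - 1, sd = noise_sd)))
    nod_g <- nod_g * (1 + c(0, stats::rnorm(n_points - 1, sd = noise_sd)))
  }
  calibration_points(doses, nod_r, nod_g)
}

# Independent quadrature oracle for the line-source geometry factor:
# (1/L) * integral over the active length of the inverse-square distance.
quadrature_geometry_factor <- function(r, theta, L) {
  th <- theta * pi / 180
  z0 <- r * cos(th); y0 <- r * sin(th)
  f <- function(l) 1 / ((z0 - l)^2 + y0^2)
  stats::integrate(f, -L / 2, L / 2, rel.tol = 1e-10)$value / L
}

# Deterministic structured/random dose-grid pairs for gamma validation.
gamma_pair <- function(kind, seed, n = 20, spacing = 0.1) {
  set.seed(seed)
  u <- seq_len(n)
  base <- switch(kind,
    smooth = 100 + 40 * sin(outer(u, u, `+`) / 4) + 20 * cos(outer(u, u, `-`) / 6),
    gradient = matrix(rep(20 + 8 * u, n), n, n),
    random = {
      m <- matrix(stats::rnorm(n * n), n, n)
      sm <- stats::filter(rbind(m, m), rep(1 / 5, 5), circular = TRUE)[1:n, ]
      100 + 25 * sm
    },
    uniform = matrix(100, n, n))
  base <- pmax(base, 1)
  pert <- switch(kind,
    smooth = base * (1 + matrix(stats::rnorm(n * n, sd = 0.02), n, n)),
    gradient = base * 1.01 + 2,
    random = base + matrix(stats::rnorm(n * n, sd = 3), n, n),
    uniform = base * (1 + stats::runif(1, -0.05, 0.05)))
  list(ref = dose_grid(base, spacing = spacing),
       eval = dose_grid(pmax(pert, 0), spacing = spacing))
}

# Write a minimal valid source file, optionally mutated, for parser tests.
write_source_fixture <- function(path, drop_block = NULL,
                                 unsorted_angles = FALSE, break_f90 = FALSE) {
  f_vals <- c("0.5, 0.66, 0.90, 1.0, 0.90, 0.66",
              "2.0, 0.68, 0.91, 1.0, 0.91, 0.68")
  angles <- if (unsorted_angles) "angles, 0, 45, 30, 135, 180"
            else "angles, 0, 45, 90, 135, 180"
  if (break_f90) f_vals[1] <- "0.5, 0.66, 0.90, 0.95, 0.90, 0.66"
  blocks <- list(
    SOURCE = c("[SOURCE]", "name, fixture", "active_length_cm, 0.35",
               "dose_rate_constant, 1.109"),
    GL = c("[GL]", "0.5, 0.996", "1.0, 1.0", "2.0, 1.004"),
    F = c("[F]", angles, f_vals))
  if (!is.null(drop_block)) blocks[[drop_block]] <- NULL
  writeLines(unlist(blocks), path)
  path
}
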