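#' Beam model configuration
#'
#' Bundles the coefficients of the analytic single-spot dose model: the
#' Bragg-curve parameterization of the integral depth dose (IDD), the
#' range-energy power law, the in-air spot size table, and the
#' double-Gaussian lateral kernel. All coefficients are explicit model
#' inputs, configurable per machine; the defaults describe a generic
#' synchrotron pencil beam in water.
#'
#' @param p,alpha Range-energy power law \eqn{R = \alpha E^p} (R in cm,
#'   E in MeV). Defaults `p = 1.77`, `alpha = 0.0022`.
#' @param beta Slope parameter (1/cm) of the fluence-reduction term in the
#'   Bragg curve.
#' @param gamma Fraction of locally absorbed energy released in nonelastic
#'   nuclear interactions.
#' @param epsilon Fraction of primary fluence contributing to the low-lying
#'   "tail" of the spectrum.
#' @param energy_spread Relative intrinsic energy spread (sigma_E / E) of
#'   the incident beam, dimensionless.
#' @param sigma_air_table Data frame with columns `range_cm`, `sigma_mm`
#'   mapping beam range to the in-air spot sigma at isocenter (linear
#'   interpolation, clamped at the table ends). The machine envelope
#'   restricts sigma to 3-6 mm.
#' @param sigma_air_limits Length-2 numeric, the allowed envelope for the
#'   in-air sigma (mm).
#' @param w Weight of the secondary (halo) Gaussian, in 0-0.2.
#' @param k Sigma ratio of the secondary to primary Gaussian, in (1, 10].
#' @param scat_coeff,scat_power Growth law of the multiple-scattering
#'   sigma with depth: `sigma_scat(z) = scat_coeff * R * (z/R)^scat_power`
#'   (cm), a power-law fit of Moliere-theory growth in water.
#' @param trunc_factor Lateral kernel truncation half-width, in units of
#'   `k * sigma1(z)`.
#' @param idd_peak Calibration of absolute dose: integral depth dose at
#'   the Bragg peak, cGy cm^2 per MU. Sets the scale of optimized spot
#'   weights (chosen so a clinical-scale plan totals on the order of
#'   1e2 MU, the regime in which the 0.002-0.02 MU repainting caps are
#'   meaningful).
#' @param distal_margin Depth beyond the range (cm) for which the lateral
#'   model remains evaluable.
#' @return An object of class `beam_config`.
#' @export
beam_config <- function(p = 1.77, alpha = 0.0022, beta = 0.012,
                        gamma = 0.6, epsilon = 0.1,
                        energy_spread = 0.008,
                        sigma_air_table = data.frame(
                          range_cm = c(5, 32), sigma_mm = c(6, 3)),
                        sigma_air_limits = c(3, 6),
                        w = 0.05, k = 3,
                        scat_coeff = 0.0224, scat_power = 1.7,
                        trunc_factor = 5,
                        idd_peak = 450,
                        distal_margin = 2) {
  check_scalar(p, "p"); check_scalar(alpha, "alpha")
  check_scalar(energy_spread, "energy_spread", positive = FALSE)
  if (energy_spread < 0) stop_domain("energy_spread must be >= 0")
  if (!is.numeric(w) || w < 0 || w > 0.2)
    stop_domain("secondary Gaussian weight w must lie in [0, 0.2]")
  if (!is.numeric(k) || k <= 1 || k > 10)
    stop_domain("sigma ratio k must lie in (1, 10]")
  check_scalar(trunc_factor, "trunc_factor")
  check_scalar(idd_peak, "idd_peak")
  structure(list(p = p, alpha = alpha, beta = beta, gamma = gamma,
                 epsilon = epsilon, energy_spread = energy_spread,
                 sigma_air_table = sigma_air_table,
                 sigma_air_limits = sigma_air_limits,
                 w = w, k = k, scat_coeff = scat_coeff,
                 scat_power = scat_power, trunc_factor = trunc_factor,
                 idd_peak = idd_peak, distal_margin = distal_margin),
            class = "beam_config")
}

#' Energy/range conversion
#'
#' Power-law range-energy relation \eqn{R = \alpha E^p} for protons in
#' water.
#'
#' @param energy Energy in MeV.
#' @param range Range in cm.
#' @param config A [beam_config()].
#' @return Range in cm / energy in MeV.
#' @export
energy_to_range <- function(energy, config = beam_config()) {
  if (any(energy <= 0)) stop_domain("energy must be > 0")
  config$alpha * energy^config$p
}

#' @rdname energy_to_range
#' @export
range_to_energy <- function(range, config = beam_config()) {
  if (any(range <= 0)) stop_domain("range must be > 0")
  (range / config$alpha)^(1 / config$p)
}

sigma_air_for_range <- function(range_cm, config) {
  tab <- config$sigma_air_table
  s <- approx(tab$range_cm, tab$sigma_mm, xout = range_cm, rule = 2)$y
  s
}

#' Single-energy beam model
#'
#' Builds the dose model for one beam energy: range, straggling width,
#' in-air sigma, and normalized Bragg-curve shape. The depth-dose shape
#' is the analytic power-law Bragg curve
#' \eqn{(R-z)^{1/p-1} + b\,(R-z)^{1/p}} convolved with a Gaussian range
#' spectrum of width sigma (range straggling plus the contribution of the
#' intrinsic energy spread), evaluated by fixed-order Gauss-Legendre
#' quadrature of the convolution integral. The curve is normalized so its
#' peak equals `config$idd_peak` (cGy cm^2 / MU).
#'
#' @param energy Nominal beam energy (MeV). Exactly one of `energy`,
#'   `range` must be given.
#' @param range Range in water (cm).
#' @param config A [beam_config()].
#' @param sigma_air In-air spot sigma at isocenter (mm); defaults to the
#'   configured range -> sigma table. Must lie within the machine envelope.
#' @return An object of class `beam_energy_model`.
#' @export
beam_energy_model <- function(energy = NULL, range = NULL,
                              config = beam_config(), sigma_air = NULL) {
  if (is.null(energy) && is.null(range))
    stop_domain("one of energy or range is required")
  if (is.null(range)) range <- energy_to_range(energy, config)
  if (is.null(energy)) energy <- range_to_energy(range, config)
  check_scalar(range, "range")
  if (is.null(sigma_air)) sigma_air <- sigma_air_for_range(range, config)
  lim <- config$sigma_air_limits
  if (sigma_air < lim[1] || sigma_air > lim[2])
    stop_domain(sprintf(
      "sigma_air = %.3g mm outside the machine envelope [%g, %g] mm",
      sigma_air, lim[1], lim[2]))

  # width of the Gaussian range spectrum: straggling + energy spread
  sigma_mono <- 0.012 * range^0.935
  sigma_es <- config$alpha * config$p * energy^(config$p - 1) *
    (config$energy_spread * energy)
  sigma_z <- sqrt(sigma_mono^2 + sigma_es^2)

  m <- structure(list(energy = energy, range = range,
                      sigma_air = sigma_air, sigma_z = sigma_z,
                      config = config, r0 = range, u_peak = 1,
                      z_peak = range),
                 class = "beam_energy_model")
  # `range` is the Bragg-peak depth; the convolved peak of the analytic
  # curve sits ~0.9 sigma_z upstream of the monoenergetic endpoint r0,
  # so solve for r0 placing the peak at the nominal range
  for (it in 1:8) {
    opt <- optimize(function(z) idd_shape(m, z),
                    interval = c(max(0, m$r0 - 6 * sigma_z - 0.5),
                                 m$r0 + 2 * sigma_z),
                    maximum = TRUE, tol = 1e-9)
    shift <- range - opt$maximum
    if (abs(shift) < 1e-6) break
    m$r0 <- m$r0 + shift
  }
  m$z_peak <- opt$maximum
  m$u_peak <- opt$objective
  m
}

#' @export
print.beam_energy_model <- function(x, ...) {
  cat(sprintf(
    "<beam_energy_model> E = %.1f MeV, R = %.2f cm (peak at %.2f cm)\n",
    x$energy, x$range, x$z_peak))
  cat(sprintf("  sigma_air = %.2f mm, range-spectrum sigma = %.3f cm\n",
              x$sigma_air, x$sigma_z))
  invisible(x)
}

# Unnormalized straggled Bragg-curve shape at depths z (vectorized).
# u(z) = E_sigma[ (R'-z)^(a-1) + b (R'-z)^a ],  R' ~ N(R, sigma_z^2)
#      = (1/sqrt(2pi)) [ s^(a-1) I(a-1, zeta) + b s^a I(a, zeta) ]
# with zeta = (R - z)/s and I(nu, zeta) = int_0^inf t^nu exp(-(t-zeta)^2/2) dt.
idd_shape <- function(model, z) {
  cfg <- model$config
  a <- 1 / cfg$p
  b <- cfg$beta + cfg$gamma * cfg$beta * cfg$p +
    cfg$epsilon * cfg$p / model$r0
  s <- model$sigma_z
  zeta <- (model$r0 - z) / s
  vapply(zeta, function(zt) {
    if (zt < -6) return(0)
    (s^(a - 1) * gauss_power_moment(a - 1, zt) +
       b * s^a * gauss_power_moment(a, zt)) / sqrt(2 * pi)
  }, numeric(1))
}

# I(nu, zeta) = int_0^inf t^nu exp(-(t - zeta)^2 / 2) dt, for nu > -1.
# For zeta >= 9 the window excludes the origin and the integrand is smooth;
# otherwise the integrable singularity at t = 0 (nu < 0) is removed by the
# substitution t = u^(1/(nu+1)).
gauss_power_moment <- function(nu, zeta) {
  hi <- max(zeta, 0) + 8.5
  if (zeta >= 9) {
    return(gl_quad(function(t) t^nu * exp(-(t - zeta)^2 / 2),
                   zeta - 8.5, hi))
  }
  if (nu >= 0) {
    return(gl_quad(function(t) t^nu * exp(-(t - zeta)^2 / 2), 0, hi))
  }
  q <- nu + 1  # in (0, 1): substitution removes the singularity
  gl_quad(function(u) exp(-(u^(1 / q) - zeta)^2 / 2) / q, 0, hi^q)
}

#' Integral depth dose
#'
#' Laterally integrated dose per MU at depth `z` on the central axis
#' (cGy cm^2 / MU). Evaluated analytically (quadrature of the smooth
#' convolution integral), not from a lookup table, so the curve is free
#' of grid artifacts.
#'
#' @param model A [beam_energy_model()].
#' @param z Depth(s) in water, cm; must be >= 0.
#' @return Numeric vector of IDD values.
#' @export
depth_dose <- function(model, z) {
  stopifnot(inherits(model, "beam_energy_model"))
  if (any(!is.finite(z)) || any(z < 0))
    stop_domain("depth z must be finite and >= 0")
  model$config$idd_peak * idd_shape(model, z) / model$u_peak
}

#' Source geometry
#'
#' Virtual-source geometry used for the beam-divergence term of the
#' lateral spread.
#'
#' @param sad Source-to-isocenter distance, cm (default 245).
#' @param isocenter_depth Depth of isocenter in the phantom, cm
#'   (default 15).
#' @return An object of class `source_geometry`.
#' @export
source_geometry <- function(sad = 245, isocenter_depth = 15) {
  check_scalar(sad, "sad"); check_scalar(isocenter_depth, "isocenter_depth")
  if (sad <= isocenter_depth)
    stop_domain("sad must exceed isocenter_depth")
  structure(list(sad = sad, isocenter_depth = isocenter_depth),
            class = "source_geometry")
}

#' Primary lateral sigma at depth
#'
#' Sigma of the primary Gaussian of the lateral kernel at depth `z`, in
#' mm: the quadrature sum of the in-air sigma scaled geometrically by
#' divergence from the source and a multiple-scattering term growing as
#' a power law in `z/R`. Strictly increasing in depth.
#'
#' @param model A [beam_energy_model()].
#' @param geometry A [source_geometry()].
#' @param z Depth(s) in cm, within `[0, R + distal_margin]`.
#' @return Sigma in mm.
#' @export
lateral_sigma <- function(model, geometry, z) {
  stopifnot(inherits(model, "beam_energy_model"),
            inherits(geometry, "source_geometry"))
  cfg <- model$config
  if (any(!is.finite(z)) || any(z < 0) ||
      any(z > model$range + cfg$distal_margin))
    stop_domain("depth z outside [0, R + distal_margin]")
  div <- model$sigma_air *
    (geometry$sad - geometry$isocenter_depth + z) / geometry$sad
  scat <- 10 * cfg$scat_coeff * model$range *
    (z / model$range)^cfg$scat_power
  sqrt(div^2 + scat^2)
}

#' Dose grid
#'
#' A 3D dose grid in the target frame. Axis convention: `x` is the fast
#' raster scan axis, `y` the orthogonal step axis, `z` the beam depth
#' axis. `origin` holds the coordinates (cm) of the first voxel center;
#' voxel values are dose (cGy) at voxel centers.
#'
#' @param origin Numeric 3-vector, cm.
#' @param spacing Numeric 3-vector (or scalar), cm per voxel.
#' @param dim Integer 3-vector of voxel counts.
#' @param values Optional array of initial values (default all zero).
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(origin, spacing, dim, values = NULL) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop_config("grid spacing must be > 0")
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L))
    stop_config("dim must be three positive voxel counts")
  if (is.null(values)) values <- array(0, dim = dim)
  stopifnot(all(dim(values) == dim))
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dim = dim, values = values),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d x %d voxels @ %.3g cm, max %.3g cGy\n",
              x$dim[1], x$dim[2], x$dim[3], x$spacing[1], max(x$values)))
  invisible(x)
}

#' Grid axis coordinates
#'
#' @param grid A [dose_grid()].
#' @return List of numeric vectors `x`, `y`, `z` (voxel centers, cm).
#' @export
grid_axes <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$dim[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(grid$dim[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(grid$dim[3]) - 1) * grid$spacing[3])
}

# Per-slice IDD (cGy cm^2/MU) and primary sigma (cm) for one beam model
# on a grid's depth axis. Slices beyond the evaluable/contributing depth
# window get zero IDD and are skipped by the rasterizer.
layer_slice_tables <- function(model, geometry, grid) {
  z <- grid_axes(grid)$z
  zmax <- model$range + model$config$distal_margin
  ok <- z >= 0 & z <= zmax
  idd <- numeric(length(z))
  sig <- rep(1e-3, length(z))
  idd[ok] <- depth_dose(model, z[ok])
  sig[ok] <- lateral_sigma(model, geometry, z[ok]) / 10
  idd[idd < 1e-9 * model$config$idd_peak] <- 0
  list(idd = idd, sigma_cm = sig)
}

#' Rasterize one spot onto a dose grid
#'
#' Adds the analytic dose of a single spot delivery to a grid:
#' `MU * IDD(z) * [(1-w) G2(sigma1(z)) + w G2(k sigma1(z))]` evaluated at
#' voxel centers, with the lateral offset measured from the displaced
#' spot axis (`position - displacement`, i.e. dose is scored in the
#' target frame). The kernel is truncated at `trunc_factor * k * sigma1`
#' per lateral axis.
#'
#' @param model A [beam_energy_model()].
#' @param geometry A [source_geometry()].
#' @param grid A [dose_grid()]; returned with the contribution added.
#' @param position Spot (x, y) at the isocenter plane, mm.
#' @param mu Monitor units, >= 0.
#' @param displacement Target displacement (dx, dy, dz), mm.
#' @return The updated `dose_grid`.
#' @export
rasterize_spot <- function(model, geometry, grid, position, mu,
                           displacement = c(0, 0, 0)) {
  if (!is.finite(mu) || mu < 0) stop_domain("mu must be >= 0")
  if (any(!is.finite(position)) || any(!is.finite(displacement)))
    stop_domain("spot position and displacement must be finite")
  st <- layer_slice_tables(model, geometry, grid)
  cfg <- model$config
  # explicit copy: the C kernel accumulates in place
  vals <- array(grid$values, dim = grid$dim)
  cpp_rasterize_events(vals, grid$dim, grid$origin, grid$spacing,
                       position[1] / 10 - displacement[1] / 10,
                       position[2] / 10 - displacement[2] / 10,
                       mu, st$sigma_cm, st$idd, cfg$w, cfg$k,
                       cfg$trunc_factor)
  grid$values <- vals
  grid
}
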