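#' Optical configuration for the striped-background measurement
#'
#' The deposited strut acts as a plano-convex cylindrical lens lying on a
#' diagonally striped background. Seen from below (orthographic view), the
#' lens magnifies the background across the strut axis, which rotates the
#' apparent stripe direction inside the strut. The model is paraxial and
#' thin: only the vertex curvature enters, and all unmodelled interfaces
#' (flat strut bottom, substrate plate) are folded into an effective
#' optical distance `z_bg`, so the product `z_bg * (n_strut - n_medium)`
#' acts as a single lumped calibration constant.
#'
#' @param n_strut refractive index of the ink (default 1.34, dilute
#'   aqueous hydrogel).
#' @param n_medium refractive index of the surrounding medium (default 1,
#'   air).
#' @param z_bg effective optical distance from the strut base to the
#'   background pattern plane, in mm.
#' @param pattern_angle_deg true stripe angle vs. the strut axis, degrees,
#'   strictly between 0 and 90.
#' @param pattern_pitch stripe spacing in mm.
#' @param lumped_zdn optional direct override of the calibration constant
#'   `z_bg * (n_strut - n_medium)` in mm; when given it takes precedence.
#' @return A list of class `optical_config`.
#' @export
optical_config <- function(n_strut = 1.34, n_medium = 1.0, z_bg = 0.5,
                           pattern_angle_deg = 45, pattern_pitch = 0.8,
                           lumped_zdn = NULL) {
  if (n_strut <= n_medium || n_medium < 1)
    stopf("need n_strut > n_medium >= 1")
  check_positive(z_bg, "z_bg")
  check_positive(pattern_pitch, "pattern_pitch")
  if (pattern_angle_deg <= 0 || pattern_angle_deg >= 90)
    stopf("pattern_angle_deg must be in (0, 90)")
  if (!is.null(lumped_zdn)) check_positive(lumped_zdn, "lumped_zdn")
  structure(list(n_strut = n_strut, n_medium = n_medium, z_bg = z_bg,
                 pattern_angle_deg = pattern_angle_deg,
                 pattern_pitch = pattern_pitch, lumped_zdn = lumped_zdn),
            class = "optical_config")
}

# the lumped lens constant z_bg * delta_n in mm
lens_constant <- function(config) {
  config$lumped_zdn %||% (config$z_bg * (config$n_strut - config$n_medium))
}

#' Apparent stripe rotation produced by a strut of given vertex curvature
#'
#' Forward paraxial model: a cylindrical lens of vertex curvature `rho`
#' magnifies the across-strut background coordinate by
#' \deqn{M = \frac{1}{1 - z_{bg}\,\rho\,\Delta n}}
#' so a stripe at true angle \eqn{\theta} to the strut axis appears at
#' \eqn{\tan\theta' = \tan\theta / M}. A flat strut (`rho = 0`) leaves the
#' pattern untouched.
#'
#' @param rho vertex curvature in 1/mm (>= 0).
#' @param config an [optical_config()].
#' @return A list of class `pattern_observation` with `apparent_angle_deg`
#'   and `magnification`.
#' @export
apparent_rotation <- function(rho, config) {
  check_nonneg(rho, "rho")
  stopifnot(inherits(config, "optical_config"))
  zdn <- lens_constant(config)
  f <- zdn * rho
  if (f >= 1)
    stopf("beyond-focus condition: z_bg * rho * dn = %.3f >= 1 (background inverted; measurement invalid)", f)
  M <- 1 / (1 - f)
  theta <- deg2rad(config$pattern_angle_deg)
  pattern_observation(rad2deg(atan(tan(theta) / M)), M)
}

#' Record a measured stripe observation
#'
#' @param apparent_angle_deg measured stripe angle inside the strut,
#'   degrees in (0, 90).
#' @param magnification across-strut background magnification (> 0).
#' @return A list of class `pattern_observation`.
#' @export
pattern_observation <- function(apparent_angle_deg, magnification = NA_real_) {
  if (apparent_angle_deg <= 0 || apparent_angle_deg >= 90)
    stopf("apparent_angle_deg must be in (0, 90)")
  structure(list(apparent_angle_deg = apparent_angle_deg,
                 magnification = magnification),
            class = "pattern_observation")
}

#' Vertex curvature from an observed stripe rotation
#'
#' Algebraic inverse of [apparent_rotation()]:
#' \deqn{\rho = \frac{1 - \tan\theta'/\tan\theta}{z_{bg}\,\Delta n}.}
#' An apparent angle larger than the true pattern angle is not produced by
#' the lens model and is rejected as an inconsistent observation.
#'
#' @param observation a [pattern_observation()].
#' @param config an [optical_config()].
#' @return Vertex curvature in 1/mm (0 when the stripes are unrotated).
#' @export
invert_curvature <- function(observation, config) {
  stopifnot(inherits(observation, "pattern_observation"),
            inherits(config, "optical_config"))
  theta <- deg2rad(config$pattern_angle_deg)
  thetap <- deg2rad(observation$apparent_angle_deg)
  if (thetap > theta + 1e-9)
    stopf("inconsistent observation: apparent angle %.3f deg exceeds pattern angle %.3f deg",
          observation$apparent_angle_deg, config$pattern_angle_deg)
  (1 - tan(min(thetap, theta)) / tan(theta)) / lens_constant(config)
}

#' Full strut reconstruction from a stripe observation and measured width
#'
#' Combines the optical curvature inversion with a width measured from the
#' strut edge contours in the same image: `H = rho * a^2 / 8`.
#'
#' @inheritParams invert_curvature
#' @param width_a strut width in mm measured in the same image.
#' @return A [parabolic_strut()]; a degenerate flat film (`rho = 0`) is
#'   returned as a list with `H = 0` and the given width rather than a
#'   strut object.
#' @export
strut_from_pattern <- function(observation, width_a, config) {
  check_positive(width_a, "width_a")
  rho <- invert_curvature(observation, config)
  if (rho <= 0)
    return(structure(list(H = 0, a = width_a), class = "flat_film"))
  parabolic_strut(H = rho * width_a^2 / 8, a = width_a)
}
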