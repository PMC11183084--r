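#' Parabolic strut model
#'
#' A deposited strut (printed strand) is described as a parabolic cap
#' \deqn{h(x) = H \left(1 - \left(\frac{2x}{a}\right)^2\right)}
#' with vertex height `H` and width `a`, both in mm. The lateral
#' coordinate `x` runs from `-a/2` to `a/2`.
#'
#' @param H vertex height in mm (> 0).
#' @param a strut width in mm (> 0).
#' @return An object of class `parabolic_strut` with fields `H` and `a`.
#' @examples
#' s <- parabolic_strut(H = 0.15, a = 0.6)
#' height_profile(s, 0)       # 0.15 at the vertex
#' vertex_curvature(s)        # 8 H / a^2
#' cross_section_area(s)      # 2/3 H a
#' @export
parabolic_strut <- function(H, a) {
  check_positive(H, "H")
  check_positive(a, "a")
  structure(list(H = H, a = a), class = "parabolic_strut")
}

#' @export
print.parabolic_strut <- function(x, ...) {
  cat(sprintf("parabolic strut: H = %.4g mm, a = %.4g mm\n", x$H, x$a))
  cat(sprintf("  vertex curvature rho = %.4g 1/mm, cross-section kappa = %.4g mm^2\n",
              vertex_curvature(x), cross_section_area(x)))
  invisible(x)
}

#' Height of the parabolic strut at a lateral position
#'
#' @param strut a [parabolic_strut()].
#' @param x lateral position(s) in mm; must satisfy `|x| <= a/2`.
#' @return Height(s) in mm; `H` at `x = 0`, zero at the edges `x = +-a/2`.
#' @export
height_profile <- function(strut, x) {
  stopifnot(inherits(strut, "parabolic_strut"))
  if (any(abs(x) > strut$a / 2 + 1e-12))
    stopf("|x| must be <= a/2 = %.4g mm", strut$a / 2)
  strut$H * (1 - (2 * x / strut$a)^2)
}

#' Curvature at the strut vertex
#'
#' The magnitude of the second derivative of the parabolic profile at its
#' apex, \eqn{\rho = 8H/a^2}. The profile is concave down, so the signed
#' second derivative is \eqn{-8H/a^2}; the positive magnitude is reported,
#' as is conventional for the lens curvature.
#'
#' @inheritParams height_profile
#' @return Curvature in 1/mm.
#' @export
vertex_curvature <- function(strut) {
  stopifnot(inherits(strut, "parabolic_strut"))
  8 * strut$H / strut$a^2
}

#' Cross-sectional area of the strut
#'
#' The definite integral of the parabolic profile over its width,
#' \eqn{\kappa = \frac{2}{3} H a}.
#'
#' @inheritParams height_profile
#' @return Area in mm^2.
#' @export
cross_section_area <- function(strut) {
  stopifnot(inherits(strut, "parabolic_strut"))
  2 / 3 * strut$H * strut$a
}

#' Reconstruct a strut from its optically observable quantities
#'
#' Inverts the curvature and cross-section relations:
#' `a = (12 kappa / rho)^(1/3)`, `H = rho a^2 / 8`. This is the algebraic
#' back-door used when `rho` comes from the stripe-rotation optics and
#' `kappa` from a throughput constraint.
#'
#' @param rho vertex curvature in 1/mm (> 0).
#' @param kappa cross-section area in mm^2 (> 0).
#' @return A [parabolic_strut()].
#' @export
strut_from_observables <- function(rho, kappa) {
  check_positive(rho, "rho")
  check_positive(kappa, "kappa")
  a <- (12 * kappa / rho)^(1 / 3)
  parabolic_strut(H = rho * a^2 / 8, a = a)
}

#' Volumetric throughput of a deposited strut
#'
#' `Q = kappa * v_p`: the cross-section swept at the print speed. Used for
#' closed-loop throughput monitoring during printing.
#'
#' @param kappa cross-section area in mm^2 (>= 0).
#' @param v_p print speed in mm/s (> 0).
#' @return Throughput in mm^3/s.
#' @export
throughput <- function(kappa, v_p) {
  check_nonneg(kappa, "kappa")
  check_positive(v_p, "v_p")
  kappa * v_p
}

#' Summarise strut geometry for a given print speed
#'
#' @inheritParams height_profile
#' @param v_p print speed in mm/s.
#' @return A list of class `strut_geometry_report` with `H_mm`, `a_mm`,
#'   `rho_per_mm`, `kappa_mm2` and `Q_mm3_per_s`, serialisable to JSON.
#' @export
strut_geometry_report <- function(strut, v_p) {
  kappa <- cross_section_area(strut)
  structure(list(
    H_mm = strut$H, a_mm = strut$a,
    rho_per_mm = vertex_curvature(strut),
    kappa_mm2 = kappa,
    Q_mm3_per_s = throughput(kappa, v_p)
  ), class = "strut_geometry_report")
}

#' Print conditions of an extrusion run
#'
#' Bundles the process quantities needed by the trajectory force balance.
#' Note the deliberate naming: `density` is the bulk ink mass density
#' (kg/m^3), distinct from the vertex curvature `rho` (1/mm) of the
#' deposited strut — the two never share a symbol in this package.
#'
#' @param v_p print speed in mm/s.
#' @param Q volumetric throughput in mm^3/s.
#' @param density bulk ink density in kg/m^3 (default 1000, dilute aqueous
#'   inks).
#' @param g gravitational acceleration in m/s^2.
#' @param gamma surface tension in N/m; 0 means surface tension neglected.
#' @param nozzle_od nozzle outer diameter in mm (default 0.82, a 21G
#'   needle, used for image scale calibration).
#' @return A list of class `print_conditions`.
#' @export
print_conditions <- function(v_p, Q, density = 1000, g = 9.81,
                             gamma = 0, nozzle_od = 0.82) {
  check_positive(v_p, "v_p")
  check_positive(Q, "Q")
  check_positive(density, "density")
  check_positive(g, "g")
  check_nonneg(gamma, "gamma")
  check_positive(nozzle_od, "nozzle_od")
  structure(list(v_p = v_p, Q = Q, density = density, g = g,
                 gamma = gamma, nozzle_od = nozzle_od),
            class = "print_conditions")
}
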