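#' Generate a synthetic spreading series with known ground truth
#'
#' Samples either spreading law on a time grid and adds i.i.d. Gaussian
#' width noise (clipped positive). Defaults emulate typical bottom-view
#' spreading measurements: times up to 12 s, widths 0.4-1.1 mm, width
#' noise of order 10 um.
#'
#' @param model `"complete"` or `"partial"`.
#' @param params list of generating parameters: `K`, `t0` for complete
#'   wetting; `a_s`, `B`, `t0` for partial wetting.
#' @param t_grid time grid in s (default 24 points on 0.5-12 s).
#' @param noise_sd width noise SD in mm (default 0.01).
#' @param seed RNG seed; fixed seed gives identical output.
#' @return A list with `series` (a [spreading_series()]) and `truth` (the
#'   generating parameters, model and seed).
#' @export
gen_spreading_series <- function(model = c("complete", "partial"), params,
                                 t_grid = seq(0.5, 12, length.out = 24),
                                 noise_sd = 0.01, seed = 1) {
  model <- match.arg(model)
  check_nonneg(noise_sd, "noise_sd")
  a0 <- if (model == "complete") {
    eval_complete_wetting(params$K, params$t0 %||% 0, t_grid)
  } else {
    eval_partial_wetting(params$a_s, params$B, params$t0 %||% 0, t_grid)
  }
  set.seed(seed)
  a <- pmax(a0 + rnorm(length(t_grid), 0, noise_sd), 1e-6)
  list(series = spreading_series(t_grid, a),
       truth = c(params, list(model = model, noise_sd = noise_sd, seed = seed)))
}

#' Generate a synthetic hanging-strut trajectory with known viscosity
#'
#' Builds a trajectory from the closed-form models the analysis assumes:
#' linear pitch angle `alpha(x) = alpha0 + m x` (so `s(x)` follows from
#' integrating `ds = dx / cos(alpha)`) and exponential diameter decay
#' `d(s) = d_inf + (d0 - d_inf) exp(-s/s_c)`. The true elongational
#' viscosity curve is computed analytically from the force balance with
#' the same closed forms; Gaussian pixel jitter (`noise_px * scale`) is
#' added to the sampled diameters.
#'
#' @param cond a [print_conditions()]; supplies `Q`, `density`, `g`,
#'   `gamma`.
#' @param d0 nozzle-exit diameter, mm.
#' @param d_inf asymptotic diameter, mm (`0 < d_inf < d0`).
#' @param s_c decay length, mm.
#' @param alpha0 pitch angle at the nozzle exit, rad.
#' @param m pitch-angle slope dalpha/dx, rad/mm (>= 1e-3; smaller slopes
#'   make the force balance degenerate).
#' @param s_max trajectory length, mm.
#' @param n_points number of samples (>= 8).
#' @param noise_px diameter jitter SD in pixels (default 0).
#' @param scale mm per pixel for the jitter (default 0.025).
#' @param seed RNG seed.
#' @return A list with `traj` (a [strut_trajectory()]), `truth`
#'   (parameters plus the noiseless `eta_true` data.frame with `s`,
#'   `eps_dot`, `eta_E`).
#' @export
gen_trajectory <- function(cond, d0 = 0.8, d_inf = 0.3, s_c = 3,
                           alpha0 = 0.1, m = 0.08, s_max = 8,
                           n_points = 160, noise_px = 0, scale = 0.025,
                           seed = 1) {
  stopifnot(inherits(cond, "print_conditions"))
  if (!(d0 > d_inf && d_inf > 0)) stopf("need d0 > d_inf > 0")
  if (m < 1e-3) stopf("pitch-angle slope m below 1e-3 rad/mm: viscosity diverges, refusing")
  if (n_points < 8) stopf("n_points must be >= 8")
  # fine x grid; alpha linear in x; s by integrating sec(alpha)
  xf <- seq(0, 2 * s_max, length.out = 20000)
  af <- alpha0 + m * xf
  if (any(af >= pi / 2 - 1e-3)) {
    xf <- xf[af < pi / 2 - 1e-3]
    af <- af[af < pi / 2 - 1e-3]
  }
  sf <- as.numeric(cumtrapz(xf, 1 / cos(af)))
  if (max(sf) < s_max)
    stopf("pitch angle reaches 90 deg before s_max = %g mm", s_max)
  s <- seq(0, s_max, length.out = n_points)
  x <- approx(sf, xf, s)$y
  alpha <- alpha0 + m * x
  d_true <- d_inf + (d0 - d_inf) * exp(-s / s_c)
  set.seed(seed)
  d <- pmax(d_true + rnorm(n_points, 0, noise_px * scale), 1e-4)
  eps <- strain_rate_closed_form(s, d0, d_inf, s_c, cond$Q)
  eta <- (cond$density * cond$g / (m * 1000) - 2 * cond$gamma / (d_true / 1000)) / eps
  list(traj = strut_trajectory(s, x, alpha, d),
       truth = list(d0 = d0, d_inf = d_inf, s_c = s_c, alpha0 = alpha0,
                    m = m, noise_px = noise_px, scale = scale, seed = seed,
                    eta_true = data.frame(s = s, eps_dot = eps, eta_E = eta)))
}

#' Synthetic trajectory with a prescribed power-law elongational viscosity
#'
#' Prescribes `eta_E = C * eps_dot^(n-1)` (elongational thinning for
#' `n < 1`) together with the exponential diameter decay, and derives the
#' pitch-angle profile the force balance then requires:
#' `dalpha/dx = rho_m g / (C eps_dot(s)^n)` (surface tension neglected),
#' integrated along the arc with `dx/ds = cos(alpha)`. Note a strictly
#' linear pitch angle always implies `eta_E ~ 1/eps_dot`; a genuine
#' power-law exponent needs this curved profile, and its analysis needs
#' `dalpha = "local"` in [elongational_viscosity()].
#'
#' @inheritParams gen_trajectory
#' @param C power-law consistency, Pa s^n.
#' @param n_exp power-law exponent `n` (< 1 for thinning).
#' @return As [gen_trajectory()]; `truth` additionally carries `C` and
#'   `n_exp`.
#' @export
gen_trajectory_power_law <- function(cond, C = 300, n_exp = 0.4,
                                     d0 = 0.8, d_inf = 0.3, s_c = 3,
                                     alpha0 = 0.1, s_max = 8, n_points = 160,
                                     noise_px = 0, scale = 0.025, seed = 1) {
  stopifnot(inherits(cond, "print_conditions"))
  if (!(d0 > d_inf && d_inf > 0)) stopf("need d0 > d_inf > 0")
  check_positive(C, "C")
  grav <- cond$density * cond$g
  rhs <- function(s, y, parms) {
    eps <- strain_rate_closed_form(s, d0, d_inf, s_c, cond$Q)
    dadx_mm <- grav / (C * eps^n_exp) / 1000   # rad/mm
    list(c(alpha = dadx_mm * cos(y[["alpha"]]), x = cos(y[["alpha"]])))
  }
  s <- seq(0, s_max, length.out = n_points)
  sol <- ode(c(alpha = alpha0, x = 0), s, rhs, NULL, method = "ode45")
  alpha <- sol[, "alpha"]; x <- sol[, "x"]
  if (any(alpha >= pi / 2 - 1e-3))
    stopf("pitch angle reaches 90 deg before s_max; reduce s_max or increase C")
  d_true <- d_inf + (d0 - d_inf) * exp(-s / s_c)
  set.seed(seed)
  d <- pmax(d_true + rnorm(n_points, 0, noise_px * scale), 1e-4)
  eps <- strain_rate_closed_form(s, d0, d_inf, s_c, cond$Q)
  list(traj = strut_trajectory(s, x, alpha, d),
       truth = list(C = C, n_exp = n_exp, d0 = d0, d_inf = d_inf, s_c = s_c,
                    alpha0 = alpha0, noise_px = noise_px, scale = scale,
                    seed = seed,
                    eta_true = data.frame(s = s, eps_dot = eps,
                                          eta_E = C * eps^(n_exp - 1))))
}
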