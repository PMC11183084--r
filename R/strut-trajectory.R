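#' Hanging-strut trajectory record
#'
#' Geometry of the strand hanging from the nozzle during printing,
#' discretised along its centerline: arc length `s` from the nozzle exit,
#' horizontal coordinate `x`, pitch angle `alpha` against the x-axis
#' (radians; positive sagging downward) and local diameter `d`. The
#' kinematic identity `cos(alpha) = dx/ds` must hold up to discretisation
#' error.
#'
#' @param s arc length in mm, strictly increasing, length >= 8.
#' @param x horizontal coordinate in mm.
#' @param alpha pitch angle in radians.
#' @param d local diameter in mm, > 0.
#' @return A data.frame of class `strut_trajectory`.
#' @export
strut_trajectory <- function(s, x, alpha, d) {
  n <- length(s)
  if (n < 8 || length(x) != n || length(alpha) != n || length(d) != n)
    stopf("s, x, alpha, d must have equal length >= 8")
  if (any(diff(s) <= 0)) stopf("s must be strictly increasing")
  check_positive(d, "d")
  structure(data.frame(s = s, x = x, alpha = alpha, d = d),
            class = c("strut_trajectory", "data.frame"))
}

#' Read/write a trajectory as CSV
#'
#' CSV columns: `s_mm`, `x_mm`, `alpha_deg`, `d_mm` (angles stored in
#' degrees externally, radians internally).
#'
#' @param path file path.
#' @return [read_trajectory_csv()] returns a [strut_trajectory()].
#' @export
read_trajectory_csv <- function(path) {
  d <- read.csv(path)
  need <- c("s_mm", "x_mm", "alpha_deg", "d_mm")
  if (!all(need %in% names(d))) stopf("CSV must have columns %s", paste(need, collapse = ", "))
  strut_trajectory(d$s_mm, d$x_mm, deg2rad(d$alpha_deg), d$d_mm)
}

#' @rdname read_trajectory_csv
#' @param traj a [strut_trajectory()].
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(data.frame(s_mm = traj$s, x_mm = traj$x,
                       alpha_deg = rad2deg(traj$alpha), d_mm = traj$d),
            path, row.names = FALSE)
  invisible(path)
}

#' Axial velocity and cross-section from the diameter profile
#'
#' Volume continuity along the strand:
#' \deqn{v(s) = \frac{Q}{A(s)} = \frac{4Q}{\pi d(s)^2}}
#' with `A = pi d^2 / 4`.
#'
#' @param d local diameter(s) in mm, > 0.
#' @param Q volumetric throughput in mm^3/s.
#' @return A list of class `kinematics_profile` with `v` (mm/s), `A`
#'   (mm^2) and `Q`.
#' @export
velocity_profile <- function(d, Q) {
  check_positive(d, "d")
  check_positive(Q, "Q")
  A <- pi * d^2 / 4
  structure(list(v = Q / A, A = A, Q = Q), class = "kinematics_profile")
}

#' Strain rate along the strand
#'
#' \eqn{\dot\varepsilon = dv/ds}, by central finite differences on the
#' given grid. When the diameter follows the fitted exponential law the
#' closed form [strain_rate_closed_form()] should be preferred.
#'
#' @param profile a [velocity_profile()] computed on the same `s` grid.
#' @param s arc-length grid in mm, length >= 3.
#' @return Strain rate in 1/s at each grid point.
#' @export
strain_rate <- function(profile, s) {
  stopifnot(inherits(profile, "kinematics_profile"))
  if (length(s) < 3) stopf("need >= 3 points for numeric differentiation")
  v <- profile$v
  n <- length(s)
  e <- numeric(n)
  e[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (s[3:n] - s[1:(n - 2)])
  e[1] <- (v[2] - v[1]) / (s[2] - s[1])
  e[n] <- (v[n] - v[n - 1]) / (s[n] - s[n - 1])
  e
}

#' Closed-form strain rate for the fitted exponential diameter profile
#'
#' With `d(s) = d_inf + (d0 - d_inf) exp(-s/s_c)` and `v = 4Q/(pi d^2)`,
#' \deqn{\dot\varepsilon(s) = \frac{8Q}{\pi d(s)^3}\,
#' \frac{d_0 - d_\infty}{s_c}\, e^{-s/s_c}.}
#'
#' @param s arc length(s) in mm.
#' @param d0 diameter at the nozzle exit, mm.
#' @param d_inf asymptotic diameter, mm.
#' @param s_c decay length, mm.
#' @param Q throughput, mm^3/s.
#' @return Strain rate in 1/s.
#' @export
strain_rate_closed_form <- function(s, d0, d_inf, s_c, Q) {
  d <- d_inf + (d0 - d_inf) * exp(-s / s_c)
  8 * Q / (pi * d^3) * (d0 - d_inf) / s_c * exp(-s / s_c)
}

#' Fit an exponential decay to the diameter profile
#'
#' `d(s) = d_inf + (d0 - d_inf) exp(-s/s_c)` over the viscous-stretching
#' regime. The offset form is used because strand diameters decay to a
#' finite value, not to zero.
#'
#' @param traj a [strut_trajectory()].
#' @param regime `c(s_start, s_end)` in mm; defaults to the full range.
#' @return A list of class `diameter_fit` with `d0`, `d_inf`, `s_c`,
#'   standard errors, `rss` and `decaying` (FALSE flags a non-decaying
#'   profile, e.g. the elastic recovery region).
#' @export
fit_diameter_profile <- function(traj, regime = range(traj$s)) {
  stopifnot(inherits(traj, "strut_trajectory"))
  keep <- traj$s >= regime[1] & traj$s <= regime[2]
  if (sum(keep) < 5) stopf("regime must contain >= 5 points")
  dat <- data.frame(s = traj$s[keep], d = traj$d[keep])
  trend <- coef(lm(d ~ s, dat))[2]
  decaying <- trend < 0
  if (!decaying)
    warning("diameter profile is non-decaying over the regime", call. = FALSE)
  d0i <- max(dat$d); dinfi <- max(min(dat$d) * 0.9, 1e-6)
  fit <- tryCatch(
    nlsLM(d ~ d_inf + (d0 - d_inf) * exp(-s / s_c), data = dat,
          start = list(d0 = d0i, d_inf = dinfi, s_c = diff(range(dat$s)) / 3),
          lower = c(1e-9, 0, 1e-9),
          control = nls.lm.control(ftol = 1e-12, ptol = 1e-12, maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    if (!decaying) {
      # non-decaying diagnostic: no exponential decay to report
      return(structure(list(d0 = NA_real_, d_inf = NA_real_, s_c = NA_real_,
                            se_d0 = NA_real_, se_d_inf = NA_real_,
                            se_s_c = NA_real_, rss = NA_real_,
                            decaying = FALSE, regime = regime),
                       class = "diameter_fit"))
    }
    stopf("diameter fit failed to converge: %s", conditionMessage(fit))
  }
  co <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 3), names(co)))
  structure(list(d0 = unname(co["d0"]), d_inf = unname(co["d_inf"]),
                 s_c = unname(co["s_c"]),
                 se_d0 = unname(se["d0"]), se_d_inf = unname(se["d_inf"]),
                 se_s_c = unname(se["s_c"]),
                 rss = sum(resid(fit)^2), decaying = decaying,
                 regime = regime),
            class = "diameter_fit")
}

#' Slope of the pitch angle against the horizontal coordinate
#'
#' Ordinary least squares of `alpha` on `x` over the regime; the slope
#' `m = dalpha/dx` (rad/mm) is the denominator of the force-balance
#' viscosity formula.
#'
#' @inheritParams fit_diameter_profile
#' @return A list with `m` (rad/mm), `se_m`, `intercept` and `regime`.
#' @export
fit_pitch_angle <- function(traj, regime = range(traj$s)) {
  stopifnot(inherits(traj, "strut_trajectory"))
  keep <- traj$s >= regime[1] & traj$s <= regime[2]
  if (sum(keep) < 3) stopf("regime must contain >= 3 points")
  x <- traj$x[keep]
  if (diff(range(x)) < 1e-9) stopf("degenerate x-range in regime")
  fit <- lm(traj$alpha[keep] ~ x)
  list(m = unname(coef(fit)[2]), se_m = summary(fit)$coefficients[2, 2],
       intercept = unname(coef(fit)[1]), regime = regime)
}

#' Select the viscous-stretching regime of a diameter profile
#'
#' Strand diameter profiles are typically "parabolic-like": a viscous
#' stretching phase (diameter decreasing) near the nozzle followed by
#' elastic recovery (diameter increasing). The analysis is restricted to
#' the stretching phase: the regime ends at the minimum of the
#' median-smoothed profile and starts after a short nozzle-exit exclusion
#' zone (die swell / attachment region).
#'
#' @param traj a [strut_trajectory()].
#' @param exclude_points number of initial grid points excluded at the
#'   nozzle exit (default 2).
#' @param smooth_window running-median window for minimum detection
#'   (default 5, must be odd).
#' @return `c(s_start, s_end)` in mm.
#' @export
select_viscous_regime <- function(traj, exclude_points = 2, smooth_window = 5) {
  stopifnot(inherits(traj, "strut_trajectory"))
  dsm <- runmed(traj$d, smooth_window, endrule = "median")
  imin <- which.min(dsm)
  if (imin <= exclude_points + 2) {
    if (all(diff(dsm) >= 0))
      stopf("regime selection failed: diameter profile is monotone increasing")
    stopf("regime selection failed: no viscous stretching regime found")
  }
  c(traj$s[exclude_points + 1], traj$s[imin])
}

# local dalpha/dx by Savitzky-Golay differentiation of alpha against index,
# divided by the local dx per index step
local_dalpha_dx <- function(traj) {
  n <- nrow(traj)
  win <- min(11, if (n %% 2 == 1) n else n - 1)
  if (win < 5) stopf("too few points for local dalpha/dx")
  da <- sgolayfilt(traj$alpha, p = 2, n = win, m = 1)
  dx <- sgolayfilt(traj$x, p = 2, n = win, m = 1)
  da / dx
}

#' Elongational viscosity from the hanging-strut force balance
#'
#' A force balance on infinitesimal cylindrical elements of the hanging
#' strand — elongational stresses at both faces plus gravity — yields,
#' with surface tension \eqn{\gamma} included,
#' \deqn{\eta_E = \left(\frac{\rho_m g}{d\alpha/dx}
#' - \frac{2\gamma}{d(s)}\right)\frac{1}{dv/ds}}
#' against the horizontal coordinate (`axis = "x"`), or equivalently
#' \deqn{\eta_E = \frac{\rho_m g \cos\alpha(s)}{(d\alpha/ds)(dv/ds)}
#' - \frac{2\gamma}{d(s)\,(dv/ds)}}
#' along the arc (`axis = "s"`), where \eqn{\rho_m} is the ink mass
#' density. Derivatives come from the fitted parametric models (the
#' exponential diameter decay and the linear pitch angle); all inputs are
#' converted to SI at this boundary so the result emerges in Pa s.
#'
#' @param traj a [strut_trajectory()].
#' @param diam_fit a [fit_diameter_profile()] result.
#' @param pitch_fit a [fit_pitch_angle()] result (used when
#'   `dalpha = "linear"`).
#' @param cond a [print_conditions()]; `cond$gamma` supplies the surface
#'   tension.
#' @param include_gamma include the surface-tension term (default `TRUE`;
#'   with `cond$gamma = 0` both settings give identical curves).
#' @param axis `"x"` (default) or `"s"`.
#' @param regime `c(s_start, s_end)` in mm; defaults to
#'   [select_viscous_regime()].
#' @param dalpha `"linear"` (slope from `pitch_fit`, the standard
#'   procedure) or `"local"` (pointwise smoothed derivative, for profiles
#'   whose pitch angle is visibly non-linear).
#' @return A data.frame of class `viscosity_curve` with columns `s` (mm),
#'   `eps_dot` (1/s) and `eta_E` (Pa s), plus attribute `negative_flag`
#'   set TRUE if any viscosity came out negative (reported, not dropped).
#' @export
elongational_viscosity <- function(traj, diam_fit, pitch_fit, cond,
                                   include_gamma = TRUE, axis = c("x", "s"),
                                   regime = NULL, dalpha = c("linear", "local")) {
  axis <- match.arg(axis)
  dalpha <- match.arg(dalpha)
  stopifnot(inherits(traj, "strut_trajectory"), inherits(diam_fit, "diameter_fit"),
            inherits(cond, "print_conditions"))
  if (is.null(regime)) regime <- select_viscous_regime(traj)
  keep <- traj$s >= regime[1] & traj$s <= regime[2]
  s <- traj$s[keep]
  d_mm <- diam_fit$d_inf + (diam_fit$d0 - diam_fit$d_inf) * exp(-s / diam_fit$s_c)
  eps <- strain_rate_closed_form(s, diam_fit$d0, diam_fit$d_inf, diam_fit$s_c, cond$Q)
  if (any(eps <= 0)) stopf("dv/ds <= 0 inside the regime: not a stretching flow")

  dadx_per_mm <- if (dalpha == "linear") {
    if (pitch_fit$m <= 0) stopf("pitch-angle slope m <= 0: force balance invalid")
    rep(pitch_fit$m, length(s))
  } else {
    interp_strict(traj$s, local_dalpha_dx(traj), s)
  }
  if (any(dadx_per_mm <= 0)) stopf("local dalpha/dx <= 0 inside the regime")

  # SI conversion at this boundary only
  dadx_si <- dadx_per_mm * 1000        # rad/m
  d_si <- d_mm / 1000                  # m
  gamma <- if (include_gamma) cond$gamma else 0
  grav <- cond$density * cond$g        # N/m^3

  eta <- if (axis == "x") {
    (grav / dadx_si - 2 * gamma / d_si) / eps
  } else {
    alpha_s <- interp_strict(traj$s, traj$alpha, s)
    dads_si <- dadx_si * cos(alpha_s)  # dalpha/ds = dalpha/dx * dx/ds
    grav * cos(alpha_s) / (dads_si * eps) - 2 * gamma / (d_si * eps)
  }
  neg <- any(eta < 0)
  if (neg) warning("negative elongational viscosities in the regime", call. = FALSE)
  out <- data.frame(s = s, eps_dot = eps, eta_E = eta)
  class(out) <- c("viscosity_curve", "data.frame")
  attr(out, "negative_flag") <- neg
  out
}

#' Write a viscosity curve as CSV
#'
#' Columns: `eps_dot_per_s`, `eta_E_Pa_s`, `s_mm`.
#'
#' @param curve a `viscosity_curve`.
#' @param path file path.
#' @export
write_viscosity_csv <- function(curve, path) {
  write.csv(data.frame(eps_dot_per_s = curve$eps_dot,
                       eta_E_Pa_s = curve$eta_E, s_mm = curve$s),
            path, row.names = FALSE)
  invisible(path)
}

#' Log-log slope of a viscosity curve
#'
#' Least-squares slope of `log(eta_E)` against `log(eps_dot)`; for a
#' power-law fluid `eta_E = C eps_dot^(n-1)` this returns `n - 1`.
#' Negative slopes indicate elongational thinning.
#'
#' @param curve a `viscosity_curve` with positive viscosities.
#' @return The dimensionless slope.
#' @export
thinning_slope <- function(curve) {
  ok <- curve$eta_E > 0 & curve$eps_dot > 0
  if (sum(ok) < 3) stopf("too few positive points for a log-log slope")
  unname(coef(lm(log(eta_E) ~ log(eps_dot), curve[ok, ]))[2])
}
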