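#' Time-resolved strut width series
#'
#' A spreading measurement: strut width `a` (mm) as a function of elapsed
#' time `t` (s) since deposition, optionally with per-point width
#' uncertainties used as weights in the fits.
#'
#' @param t elapsed times in s; strictly increasing, nonnegative, length
#'   >= 3.
#' @param a strut widths in mm, positive, same length as `t`.
#' @param sigma_a optional per-point width standard deviation in mm.
#' @return A data.frame of class `spreading_series` with columns `t`, `a`
#'   and (if given) `sigma_a`.
#' @export
spreading_series <- function(t, a, sigma_a = NULL) {
  if (length(t) != length(a) || length(t) < 3)
    stopf("t and a must have equal length >= 3")
  if (any(diff(t) <= 0) || any(t < 0)) stopf("t must be strictly increasing and >= 0")
  check_positive(a, "a")
  out <- data.frame(t = t, a = a)
  if (!is.null(sigma_a)) {
    check_positive(sigma_a, "sigma_a")
    out$sigma_a <- rep_len(sigma_a, length(t))
  }
  class(out) <- c("spreading_series", "data.frame")
  out
}

#' Read/write a spreading series as CSV
#'
#' CSV columns: `t_s`, `a_mm`, optional `sigma_mm`.
#'
#' @param path file path.
#' @return [read_spreading_csv()] returns a [spreading_series()].
#' @export
read_spreading_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("t_s", "a_mm") %in% names(d)))
    stopf("CSV must have columns t_s, a_mm")
  spreading_series(d$t_s, d$a_mm, if ("sigma_mm" %in% names(d)) d$sigma_mm)
}

#' @rdname read_spreading_csv
#' @param series a [spreading_series()].
#' @export
write_spreading_csv <- function(series, path) {
  d <- data.frame(t_s = series$t, a_mm = series$a)
  if (!is.null(series$sigma_a)) d$sigma_mm <- series$sigma_a
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Complete-wetting spreading law
#'
#' Width of a strut spreading without bound,
#' \deqn{a(t) = K \left(\frac{t + t_0}{\mathrm{s}}\right)^{1/7}}
#' where the division by the unit second makes the prefactor `K` carry mm.
#'
#' @param K prefactor in mm.
#' @param t0 delay time in s.
#' @param t elapsed time(s) in s; `t + t0` must be nonnegative.
#' @return Width(s) in mm.
#' @export
eval_complete_wetting <- function(K, t0, t) {
  check_positive(K, "K")
  if (any(t + t0 < 0)) stopf("t + t0 must be >= 0")
  K * (t + t0)^(1 / 7)
}

#' Partial-wetting spreading law
#'
#' Width of a strut saturating at a final width `a_s`,
#' \deqn{a(t) = a_s \left(1 - e^{-B (t + t_0)}\right)^{1/7}.}
#'
#' @param a_s final strut width in mm.
#' @param B rate constant in 1/s.
#' @param t0 delay time in s.
#' @param t elapsed time(s) in s; `t + t0` must be nonnegative.
#' @return Width(s) in mm.
#' @export
eval_partial_wetting <- function(a_s, B, t0, t) {
  check_positive(a_s, "a_s")
  check_positive(B, "B")
  if (any(t + t0 < 0)) stopf("t + t0 must be >= 0")
  a_s * (1 - exp(-B * (t + t0)))^(1 / 7)
}

series_weights <- function(series) {
  if (!is.null(series$sigma_a)) 1 / series$sigma_a^2 else rep(1, nrow(series))
}

fit_report <- function(fit, series, par_names, k) {
  co <- coef(fit)
  se <- tryCatch({
    cm <- summary(fit)$coefficients
    setNames(cm[, "Std. Error"], rownames(cm))
  }, error = function(e) setNames(rep(NA_real_, length(co)), names(co)))
  rss <- sum(resid(fit)^2)
  list(coef = co, se = se, rss = rss, n = nrow(series),
       aicc = aicc_from_rss(rss, nrow(series), k))
}

degenerate_series <- function(series) {
  sd(series$a) / mean(series$a) < 1e-3
}

#' Fit the complete-wetting law to a spreading series
#'
#' Least-squares fit of \eqn{a = K((t+t_0)/\mathrm{s})^{1/7}} by
#' Levenberg-Marquardt with positivity bounds. By default the delay time
#' is fixed at zero: in practice its fitted value is consistently smaller
#' than its own standard error, so the free parameter adds nothing but
#' variance; the free-`t0` mode is retained for diagnostics.
#'
#' @param series a [spreading_series()].
#' @param fix_t0 fix the delay `t0 = 0` (default `TRUE`).
#' @return A list of class `complete_wetting_fit`: `K`, `t0`, `se_K`,
#'   `se_t0`, `rss`, `aicc`, `n`, `t0_fixed`, `degenerate`.
#' @export
fit_complete_wetting <- function(series, fix_t0 = TRUE) {
  stopifnot(inherits(series, "spreading_series"))
  if (nrow(series) < if (fix_t0) 2L else 3L) stopf("too few points to fit")
  w <- series_weights(series)
  # closed-form start for K (linear in K at t0 = 0)
  b <- series$t^(1 / 7)
  K0 <- sum(w * series$a * b) / sum(w * b^2)
  if (fix_t0) {
    fit <- nlsLM(a ~ K * t^(1 / 7), data = series, weights = w,
                 start = list(K = K0), lower = 1e-9,
                 control = nls.lm.control(ftol = 1e-12, ptol = 1e-12, maxiter = 200))
    r <- fit_report(fit, series, "K", k = 1)
    t0 <- 0; se_t0 <- NA_real_
  } else {
    fit <- nlsLM(a ~ K * (t + t0)^(1 / 7), data = series, weights = w,
                 start = list(K = K0, t0 = 0.01), lower = c(1e-9, 0),
                 control = nls.lm.control(ftol = 1e-12, ptol = 1e-12, maxiter = 200))
    r <- fit_report(fit, series, c("K", "t0"), k = 2)
    t0 <- unname(r$coef["t0"]); se_t0 <- unname(r$se["t0"])
  }
  structure(list(K = unname(r$coef["K"]), t0 = t0,
                 se_K = unname(r$se["K"]), se_t0 = se_t0,
                 rss = r$rss, aicc = r$aicc, n = r$n, t0_fixed = fix_t0,
                 degenerate = degenerate_series(series)),
            class = "complete_wetting_fit")
}

#' Fit the partial-wetting law to a spreading series
#'
#' Least-squares fit of \eqn{a = a_s(1 - e^{-B(t+t_0)})^{1/7}}.
#' Initialisation: `a_s = 1.05 * max(a)`; `B` from the time at which the
#' width reaches \eqn{(1-e^{-1})^{1/7} a_s}.
#'
#' @inheritParams fit_complete_wetting
#' @return A list of class `partial_wetting_fit`: `a_s`, `B`, `t0`,
#'   standard errors, `rss`, `aicc`, `n`, `t0_fixed`, `degenerate`.
#' @export
fit_partial_wetting <- function(series, fix_t0 = TRUE) {
  stopifnot(inherits(series, "spreading_series"))
  if (nrow(series) < if (fix_t0) 3L else 4L) stopf("too few points to fit")
  w <- series_weights(series)
  as0 <- 1.05 * max(series$a)
  a_at_tau <- (1 - exp(-1))^(1 / 7) * as0
  i <- which(series$a >= a_at_tau)[1]
  B0 <- if (is.na(i)) 1 / max(series$t) else 1 / max(series$t[i], min(diff(series$t)))
  ctl <- nls.lm.control(ftol = 1e-12, ptol = 1e-12, maxiter = 500)
  if (fix_t0) {
    fit <- nlsLM(a ~ a_s * (1 - exp(-B * t))^(1 / 7), data = series, weights = w,
                 start = list(a_s = as0, B = B0), lower = c(1e-9, 1e-9), control = ctl)
    r <- fit_report(fit, series, c("a_s", "B"), k = 2)
    t0 <- 0; se_t0 <- NA_real_
  } else {
    fit <- nlsLM(a ~ a_s * (1 - exp(-B * (t + t0)))^(1 / 7), data = series,
                 weights = w, start = list(a_s = as0, B = B0, t0 = 0.01),
                 lower = c(1e-9, 1e-9, 0), control = ctl)
    r <- fit_report(fit, series, c("a_s", "B", "t0"), k = 3)
    t0 <- unname(r$coef["t0"]); se_t0 <- unname(r$se["t0"])
  }
  structure(list(a_s = unname(r$coef["a_s"]), B = unname(r$coef["B"]), t0 = t0,
                 se_a_s = unname(r$se["a_s"]), se_B = unname(r$se["B"]),
                 se_t0 = se_t0, rss = r$rss, aicc = r$aicc, n = r$n,
                 t0_fixed = fix_t0, degenerate = degenerate_series(series)),
            class = "partial_wetting_fit")
}

#' Initial-spreading prefactor of a partial-wetting fit
#'
#' First-order expansion of the partial-wetting law for small `B(t+t0)`
#' gives \eqn{a(t) \approx a_s B^{1/7} (t/\mathrm{s})^{1/7}}, so the
#' product \eqn{a_s B^{1/7}} (mm) is directly comparable with the
#' complete-wetting prefactor `K`. Used to compare early-time spreading
#' speed between solvents (e.g. PBS-based vs. water-based inks).
#'
#' @param fit a [fit_partial_wetting()] result, or a list with `a_s` (mm)
#'   and `B` (1/s).
#' @return Prefactor in mm.
#' @export
initial_prefactor <- function(fit) {
  check_positive(fit$a_s, "a_s")
  check_positive(fit$B, "B")
  fit$a_s * fit$B^(1 / 7)
}

#' Material parameters entering the full spreading prefactor
#'
#' @param gamma_L surface tension in N/m.
#' @param eta ink viscosity in Pa s.
#' @param eta_S solvent viscosity in Pa s.
#' @param intrinsic_viscosity intrinsic viscosity in reciprocal
#'   concentration units matching `c`.
#' @param c polymer concentration (same basis as `intrinsic_viscosity`,
#'   e.g. % w/v).
#' @param lambda_const dimensionless universal constant of the wetting
#'   theory; no published numeric value, must be supplied by the user for
#'   absolute prefactor computations.
#' @return A list of class `material_params`.
#' @export
material_params <- function(gamma_L = NULL, eta = NULL, eta_S = NULL,
                            intrinsic_viscosity = NULL, c = NULL,
                            lambda_const = NULL) {
  for (nm in c("gamma_L", "eta", "eta_S", "intrinsic_viscosity", "lambda_const")) {
    v <- get(nm)
    if (!is.null(v)) check_positive(v, nm)
  }
  if (!is.null(c)) check_nonneg(c, "c")
  structure(list(gamma_L = gamma_L, eta = eta, eta_S = eta_S,
                 intrinsic_viscosity = intrinsic_viscosity, c = c,
                 lambda_const = lambda_const), class = "material_params")
}

#' Dilute-solution viscosity from polymer concentration
#'
#' \deqn{\eta(c) = \eta_S \left(1 + \frac{[\eta] c}{3}\right)^3}
#' the typical low-concentration dependency of a polymer solution.
#'
#' @param params a [material_params()] with `eta_S`,
#'   `intrinsic_viscosity` and `c` set.
#' @return Viscosity in the units of `eta_S`.
#' @export
viscosity_from_concentration <- function(params) {
  stopifnot(inherits(params, "material_params"))
  if (is.null(params$eta_S) || is.null(params$intrinsic_viscosity) || is.null(params$c))
    stopf("eta_S, intrinsic_viscosity and c must all be set")
  params$eta_S * (1 + params$intrinsic_viscosity * params$c / 3)^3
}

#' Viscosity scaling of the complete-wetting prefactor
#'
#' At fixed surface tension and cross-section, \eqn{K \sim \eta^{-1/7}},
#' so `K2/K1 = (eta1/eta2)^(1/7)`.
#'
#' @param eta1,eta2 viscosities (any common unit).
#' @return The dimensionless prefactor ratio `K2/K1`.
#' @export
prefactor_ratio_from_viscosity <- function(eta1, eta2) {
  check_positive(eta1, "eta1")
  check_positive(eta2, "eta2")
  (eta1 / eta2)^(1 / 7)
}

#' Full-form complete-wetting prefactor
#'
#' \deqn{K = \left(\frac{\gamma_L \cdot 18 \cdot 7 \cdot \kappa^3}
#' {\lambda\,\eta}\right)^{1/7}}
#' evaluated at `t` in seconds, with `gamma_L` in N/m, `eta` in Pa s and
#' `kappa` in mm^2 (the ratio `gamma_L/eta`, m/s, is converted to mm/s so
#' `K` emerges in mm). Mainly useful for scaling checks — the universal
#' constant `lambda` has no published value.
#'
#' @param params a [material_params()] with `gamma_L`, `eta` and
#'   `lambda_const` set.
#' @param kappa strut cross-section area in mm^2.
#' @return Prefactor `K` in mm.
#' @export
full_form_prefactor <- function(params, kappa) {
  stopifnot(inherits(params, "material_params"))
  if (is.null(params$lambda_const)) stopf("lambda required: lambda_const is unset")
  if (is.null(params$gamma_L) || is.null(params$eta)) stopf("gamma_L and eta must be set")
  check_positive(kappa, "kappa")
  speed_mm_s <- params$gamma_L / params$eta * 1000
  (speed_mm_s * 18 * 7 * kappa^3 / params$lambda_const)^(1 / 7)
}

#' Choose between complete- and partial-wetting models
#'
#' Fits both laws with `t0` fixed at zero and compares them by
#' small-sample corrected AIC. Water-based inks typically spread without
#' bound (complete wetting), PBS-based inks saturate (partial wetting);
#' the information criterion generalises that empirical dichotomy to
#' arbitrary series. A difference below `tie_margin` is reported as a tie.
#'
#' @param series a [spreading_series()] with >= 4 points.
#' @param tie_margin AICc difference below which the models are declared
#'   indistinguishable (default 2).
#' @return A list of class `spreading_model_selection` with `model`
#'   (`"complete"`, `"partial"` or `"tie"`), both fits, and both AICc
#'   values.
#' @export
model_selection <- function(series, tie_margin = 2) {
  stopifnot(inherits(series, "spreading_series"))
  if (nrow(series) < 4) stopf("need >= 4 points for model selection")
  fc <- fit_complete_wetting(series, fix_t0 = TRUE)
  fp <- fit_partial_wetting(series, fix_t0 = TRUE)
  d <- fc$aicc - fp$aicc
  model <- if (abs(d) < tie_margin) "tie" else if (d < 0) "complete" else "partial"
  structure(list(model = model, complete = fc, partial = fp,
                 aicc = c(complete = fc$aicc, partial = fp$aicc)),
            class = "spreading_model_selection")
}

#' Free-exponent power-law fit of a spreading series
#'
#' Diagnostic fit of `a = K (t/s)^p` with the exponent free; on data
#' following the complete-wetting law the exponent returns 1/7.
#'
#' @param series a [spreading_series()] with all `t > 0`.
#' @return A list with `K` (mm), `exponent`, and `rss`.
#' @export
spreading_exponent <- function(series) {
  stopifnot(inherits(series, "spreading_series"))
  if (any(series$t <= 0)) stopf("all t must be > 0 for a free-exponent fit")
  lf <- lm(log(a) ~ log(t), data = series)
  fit <- nlsLM(a ~ K * t^p, data = series,
               start = list(K = unname(exp(coef(lf)[1])), p = unname(coef(lf)[2])),
               control = nls.lm.control(ftol = 1e-14, ptol = 1e-14, maxiter = 500))
  list(K = unname(coef(fit)["K"]), exponent = unname(coef(fit)["p"]),
       rss = sum(resid(fit)^2))
}

#' Volume fraction occupied by suspended cells
#'
#' `fraction_percent = density * mean_volume * 1e-12 * 100`
#' (1 ml = 1e12 um^3). Used to judge whether a cell loading can plausibly
#' alter the bulk rheology of a bioink.
#'
#' @param density cell density in cells/ml.
#' @param mean_volume mean single-cell volume in um^3.
#' @return Volume fraction in percent.
#' @export
cell_volume_fraction <- function(density, mean_volume) {
  check_nonneg(density, "density")
  check_nonneg(mean_volume, "mean_volume")
  density * mean_volume * 1e-12 * 100
}

#' JSON report for a spreading fit
#'
#' @param fit a complete- or partial-wetting fit.
#' @param path optional file to write.
#' @return The report list, invisibly if written to file.
#' @export
spreading_fit_report <- function(fit, path = NULL) {
  rep <- if (inherits(fit, "complete_wetting_fit")) {
    list(model = "complete", K_mm = fit$K, t0_s = fit$t0, se_K = fit$se_K,
         se_t0 = fit$se_t0, rss = fit$rss, aicc = fit$aicc, n_points = fit$n)
  } else if (inherits(fit, "partial_wetting_fit")) {
    list(model = "partial", a_s_mm = fit$a_s, B_per_s = fit$B, t0_s = fit$t0,
         se_a_s = fit$se_a_s, se_B = fit$se_B, se_t0 = fit$se_t0,
         rss = fit$rss, aicc = fit$aicc, n_points = fit$n)
  } else stopf("not a spreading fit")
  if (!is.null(path)) {
    write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
    return(invisible(rep))
  }
  rep
}
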