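test_that("complete-wetting evaluator follows the 1/7 power law", {
  expect_equal(eval_complete_wetting(0.566, 0, 1), 0.566)
  expect_equal(eval_complete_wetting(0.566, 0, 128), 1.132)  # 128^(1/7) = 2
  expect_equal(eval_complete_wetting(0.5, 0, 0), 0)
  t <- seq(0, 12, by = 0.25)
  expect_true(all(diff(eval_complete_wetting(0.566, 0, t)) >= 0))
  # log-log slope is exactly 1/7 for t0 = 0
  lt <- log(c(1, 2, 5, 10)); la <- log(eval_complete_wetting(0.7, 0, exp(lt)))
  expect_equal(unname(coef(lm(la ~ lt))[2]), 1 / 7, tolerance = 1e-12)
  expect_error(eval_complete_wetting(0.5, -1, 0.5), "t0")
})

test_that("partial-wetting evaluator saturates at a_s", {
  expect_equal(eval_partial_wetting(0.83, 0.25, 0, 1e9), 0.83)
  expect_equal(eval_partial_wetting(0.83, 0.25, 0, 0), 0)
  expect_equal(eval_partial_wetting(0.83, 0.25, 0, 4),
               0.83 * (1 - exp(-1))^(1 / 7), tolerance = 1e-12)
  expect_equal(round(eval_partial_wetting(0.83, 0.25, 0, 4), 3), 0.777)
  t <- seq(0, 40, by = 0.5)
  expect_true(all(diff(eval_partial_wetting(0.83, 0.25, 0, t)) >= 0))
})

test_that("partial wetting matches its small-time expansion to ~x/14", {
  a_s <- 0.83; B <- 0.25
  for (x in c(0.01, 0.005, 0.001)) {
    t <- x / B
    full <- eval_partial_wetting(a_s, B, 0, t)
    first_order <- a_s * B^(1 / 7) * t^(1 / 7)
    expect_equal(full / first_order, 1, tolerance = x / 7)  # ~x/14 predicted
  }
})

test_that("noiseless fits recover generating parameters exactly", {
  t <- seq(0.5, 12, length.out = 24)
  sc <- spreading_series(t, eval_complete_wetting(0.566, 0, t))
  fc <- fit_complete_wetting(sc)
  expect_equal(fc$K, 0.566, tolerance = 1e-8)
  expect_lt(fc$rss, 1e-12)
  sp <- spreading_series(t, eval_partial_wetting(0.83, 0.25, 0, t))
  fp <- fit_partial_wetting(sp)
  expect_equal(fp$a_s, 0.83, tolerance = 1e-6)
  expect_equal(fp$B, 0.25, tolerance = 1e-6)
})

test_that("noisy fits are nearly unbiased (short simulation)", {
  Ks <- as_ <- Bs <- numeric(20)
  for (i in 1:20) {
    g1 <- gen_spreading_series("complete", list(K = 0.558, t0 = 0),
                               noise_sd = 0.01, seed = 100 + i)
    Ks[i] <- fit_complete_wetting(g1$series)$K
    g2 <- gen_spreading_series("partial", list(a_s = 0.83, B = 0.25, t0 = 0),
                               noise_sd = 0.01, seed = 200 + i)
    f2 <- fit_partial_wetting(g2$series)
    as_[i] <- f2$a_s; Bs[i] <- f2$B
  }
  expect_lt(abs(mean(Ks) / 0.558 - 1), 0.01)
  expect_lt(abs(mean(as_) / 0.83 - 1), 0.01)
  # B scatters ~10% per replicate; the 5% bias bound is asserted over 100
  # replicates in the end-to-end suite
  expect_lt(abs(mean(Bs) / 0.25 - 1), 0.1)
})

test_that("free-t0 fit on t0 = 0 data returns t0 smaller than its own error", {
  t0s <- se0s <- numeric(10)
  for (i in 1:10) {
    g <- gen_spreading_series("complete", list(K = 0.566, t0 = 0),
                              noise_sd = 0.01, seed = 30 + i)
    f <- fit_complete_wetting(g$series, fix_t0 = FALSE)
    t0s[i] <- f$t0; se0s[i] <- f$se_t0
  }
  expect_gte(mean(se0s), mean(abs(t0s)))
})

test_that("degenerate constant-width series is flagged", {
  s <- spreading_series(1:5, rep(0.8, 5))
  f <- fit_complete_wetting(s)
  expect_true(f$degenerate)
})

test_that("initial prefactor a_s B^(1/7) is comparable with K", {
  p <- initial_prefactor(list(a_s = 0.83, B = 0.25))
  expect_equal(p, 0.83 * 0.25^(1 / 7), tolerance = 1e-12)
  expect_equal(round(p, 3), 0.681)
  expect_equal(initial_prefactor(list(a_s = 0.77, B = 1)), 0.77)
  # PBS-vs-water comparison: ~20% above the water prefactor
  expect_equal(p / 0.566, 1.203, tolerance = 1e-3)
})

test_that("viscosity-concentration law and prefactor scaling", {
  mp <- function(ivc) material_params(eta_S = 0.001, intrinsic_viscosity = ivc, c = 1)
  expect_equal(viscosity_from_concentration(mp(1e-9)), 0.001, tolerance = 1e-6)
  expect_equal(viscosity_from_concentration(mp(3)), 0.008)    # (1+1)^3
  # [eta] c = 1.5 -> eta_S (1 + 0.5)^3 = 3.375 eta_S
  expect_equal(viscosity_from_concentration(mp(1.5)), 0.001 * 3.375)
  expect_equal(prefactor_ratio_from_viscosity(1, 1), 1)
  expect_equal(prefactor_ratio_from_viscosity(1, 2), 2^(-1 / 7))
  expect_equal(prefactor_ratio_from_viscosity(1, 128), 0.5)
})

test_that("full-form prefactor obeys the theoretical scalings", {
  mp <- function(eta) material_params(gamma_L = 0.07, eta = eta, lambda_const = 50)
  K1 <- full_form_prefactor(mp(1), kappa = 0.05)
  expect_equal(full_form_prefactor(mp(2), 0.05) / K1, 2^(-1 / 7), tolerance = 1e-12)
  expect_equal(full_form_prefactor(mp(1), 0.10) / K1, 2^(3 / 7), tolerance = 1e-12)
  # consistency with the partial-wetting rate: K^7 / (B a_s^7) = 7/4
  gamma <- 0.07; eta <- 1; lambda <- 50; kappa <- 0.05; a_s <- 0.9
  B <- 4 * (gamma / eta * 1000) * 18 * kappa^3 / (lambda * a_s^7)
  expect_equal(K1^7 / (B * a_s^7), 7 / 4, tolerance = 1e-12)
  expect_error(full_form_prefactor(material_params(gamma_L = 0.07, eta = 1), 0.05),
               "lambda")
})

test_that("model selection distinguishes the spreading regimes", {
  gc <- gen_spreading_series("complete", list(K = 0.566, t0 = 0),
                             noise_sd = 0.005, seed = 3)
  expect_equal(model_selection(gc$series)$model, "complete")
  gp <- gen_spreading_series("partial", list(a_s = 0.83, B = 0.3, t0 = 0),
                             noise_sd = 0.005, seed = 3)
  expect_equal(model_selection(gp$series)$model, "partial")
  # both fits are always returned; a wide tie margin reports a tie
  sel <- model_selection(gc$series, tie_margin = 1e6)
  expect_equal(sel$model, "tie")
  expect_s3_class(sel$complete, "complete_wetting_fit")
  expect_s3_class(sel$partial, "partial_wetting_fit")
})

test_that("free-exponent fit on exact data returns 1/7", {
  g <- gen_spreading_series("complete", list(K = 0.566, t0 = 0),
                            noise_sd = 0, seed = 1)
  ex <- spreading_exponent(g$series)
  expect_equal(ex$exponent, 1 / 7, tolerance = 1e-7)
})

test_that("cell volume fraction arithmetic", {
  expect_equal(cell_volume_fraction(1e6, 3440.68), 0.344068)
  expect_equal(cell_volume_fraction(1e6, 1949.12), 0.194912)
  expect_equal(cell_volume_fraction(0, 3000), 0)
})

test_that("series CSV and fit report round-trip", {
  g <- gen_spreading_series("complete", list(K = 0.6, t0 = 0), seed = 5)
  f <- tempfile(fileext = ".csv")
  write_spreading_csv(g$series, f)
  s2 <- read_spreading_csv(f)
  expect_equal(s2$t, g$series$t)
  expect_equal(s2$a, g$series$a)
  jf <- tempfile(fileext = ".json")
  spreading_fit_report(fit_complete_wetting(s2), jf)
  rep <- jsonlite::read_json(jf)
  expect_equal(rep$model, "complete")
  expect_true(is.numeric(rep$K_mm))
})
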