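test_that("scale calibration from the nozzle silhouette", {
  img <- nozzle_image(width_px = 33)
  sc <- calibrate_scale(img, nozzle_od_mm = 0.82)
  expect_equal(as.numeric(sc), 0.82 / 33, tolerance = 0.02 / 33 * 2)  # 2-px accuracy
  expect_equal(attr(sc, "width_px"), 33, tolerance = 2)
  # anti-aliased fractional width
  img2 <- nozzle_image(width_px = 32.8)
  expect_equal(attr(calibrate_scale(img2), "width_px"), 32.8, tolerance = 2)
  expect_error(calibrate_scale(matrix(0.9, 100, 100)), "calibration")
})

test_that("contours and centerline of two parallel bands", {
  img <- parallel_band_image(y_top = 50, y_bot = 70)
  co <- extract_contours(img)
  expect_s3_class(co, "contour_pair")
  tr <- centerline_and_diameter(co, scale = 0.025)
  # dark rows 50..70: edges at 49.5 / 70.5 px -> d = 21 px = 0.525 mm
  expect_equal(median(tr$d), 21 * 0.025, tolerance = 0.02)
  expect_lt(max(abs(tr$alpha)), 0.01)
  expect_error(extract_contours(matrix(0.5, 80, 80)), "extraction")
})

test_that("side-view extraction recovers diameter within 2 px (interior)", {
  cond <- default_conditions()
  g <- gen_trajectory(cond, d0 = 0.8, d_inf = 0.3, s_c = 3, alpha0 = 0.15,
                      m = 0.08, s_max = 8, noise_px = 0)
  sc <- render_side_view(g$traj, seed = 2)
  cal <- calibrate_scale(sc$img)
  scale <- as.numeric(cal)
  nz <- attr(cal, "center_px")
  roi <- list(x = c(ceiling(nz + 0.5 * 0.82 / scale) + 3, ncol(sc$img)),
              y = c(1, nrow(sc$img)))
  co <- extract_contours(sc$img, roi)
  tr <- centerline_and_diameter(co, scale)
  xg <- (co$upper$x - sc$truth$exit_px["x"]) * scale
  keep <- which(xg <= max(g$traj$x))
  trim <- 8
  idx <- keep[trim:(length(keep) - trim)]
  dtrue <- approx(g$traj$x, g$traj$d, xg[idx])$y
  expect_lt(max(abs(tr$d[idx] - dtrue)) / 0.025, 2)
  # pitch angle tracks the truth
  atrue <- approx(g$traj$x, g$traj$alpha, xg[idx])$y
  expect_lt(max(abs(tr$alpha[idx] - atrue)), 1 * pi / 180)
  # kinematic consistency cos(alpha) = dx/ds within 2%
  dxds <- diff(tr$x[idx]) / diff(tr$s[idx])
  expect_lt(max(abs(cos(tr$alpha[idx][-1]) - dxds)), 0.02)
})

test_that("stripe-angle measurement on plain and refracted patterns", {
  img <- stripe_image(45, pitch_px = 32)
  obs <- stripe_angle_in_strut(img, roi = list(x = c(20, 280), y = c(20, 280)),
                               config = default_optics())
  expect_equal(obs$apparent_angle_deg, 45, tolerance = 0.5)
  expect_error(stripe_angle_in_strut(matrix(0.5, 200, 200),
                                     roi = list(x = c(20, 180), y = c(20, 180)),
                                     config = default_optics()),
               "orientation|uniform")
})

test_that("rendered strut rotates stripes to the predicted apparent angle", {
  sc <- straight_bottom_scene(rho = 2, a = 2)
  yc_px <- 5 / 0.025 + 1
  roi_in <- list(x = c(round(4 / 0.025), round(10 / 0.025)),
                 y = c(round(yc_px - 30), round(yc_px + 30)))
  obs <- stripe_angle_in_strut(sc$img, roi_in, default_optics())
  predicted <- apparent_rotation(2, default_optics())$apparent_angle_deg
  expect_equal(obs$apparent_angle_deg, predicted, tolerance = 1)
})

test_that("snapshot width series re-fits the generating prefactor", {
  ms <- meander_scene(K = 0.566, row_length = 20, n_rows = 3)
  series <- width_series_from_snapshot(ms$scene$img, ms$path, ms$v_p, ms$scale,
                                       station_step = 2)
  expect_gte(nrow(series), 10)
  st <- attr(series, "stations")
  keep <- series$t >= ms$t_floor
  f <- fit_complete_wetting(spreading_series(series$t[keep], series$a[keep]))
  expect_lt(abs(f$K / ms$K - 1), 0.03)
  # per-station width against the generating law (sub-pixel dips on a
  # striped background: a few percent per station, unbiased on average)
  atrue <- ms$K * pmax(st$t, ms$t_floor)^(1 / 7)
  expect_lt(max(abs(st$a - atrue) / atrue), 0.05)
  expect_lt(abs(mean(st$a / atrue) - 1), 0.01)
})

test_that("degenerate snapshot inputs fail loudly", {
  # constant-width strand: series extracted but the fit flags degeneracy
  sc <- straight_bottom_scene(rho = 1, a = 1, len_mm = 14, corner_margin = 1)
  path <- data.frame(x_mm = c(0, 14), y_mm = c(5, 5))
  series <- width_series_from_snapshot(sc$img, path, v_p = 5, scale = 0.025,
                                       station_step = 2)
  expect_true(fit_complete_wetting(series)$degenerate)
  # giant station step -> too few stations
  expect_error(width_series_from_snapshot(sc$img, path, 5, 0.025,
                                          station_step = 7), "station")
})

test_that("in-gel strut mask recovers the band area within 3%", {
  sc <- straight_bottom_scene(rho = 2, a = 1.5, len_mm = 16, y_mm = 4,
                              edge_depth = 0, corner_margin = 0)
  mask <- in_gel_strut_mask(sc$img)
  ymm <- (seq_len(nrow(sc$img)) - 1) * 0.025
  xmm <- (seq_len(ncol(sc$img)) - 1) * 0.025
  colsel <- xmm >= 2 & xmm <= 14
  truth_rows <- abs(ymm - 4) <= 0.75
  area <- sum(mask[, colsel])
  truth <- sum(truth_rows) * sum(colsel)
  expect_lt(abs(area - truth) / truth, 0.03)
  expect_equal(attr(mask, "background_angle_deg"), 45, tolerance = 0.5)
})

test_that("image IO preserves intensities and reduces RGB by luminance", {
  img <- stripe_image(30, 16, nx = 60, ny = 50)
  f <- tempfile(fileext = ".png")
  write_image(img, f)
  back <- read_image(f)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 255 + 1e-9)  # 8-bit quantisation only
  rgb <- array(c(img, img, img), dim = c(dim(img), 3))
  frgb <- tempfile(fileext = ".png")
  png::writePNG(rgb, frgb)
  expect_equal(read_image(frgb), back, tolerance = 1 / 255)
})
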