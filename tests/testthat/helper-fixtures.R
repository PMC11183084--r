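# shared fixture builders (all synthetic, generated at test time)

# a minimal side-view-like frame with only a nozzle bar at the top
nozzle_image <- function(width_px = 33, center = 100, nx = 200, ny = 120,
                         tip_row = 40) {
  img <- matrix(0.95, ny, nx)
  hw <- width_px / 2
  cov <- pmin(pmax(hw - abs(seq_len(nx) - center) + 0.5, 0), 1)
  img[seq_len(tip_row), ] <- sweep(img[seq_len(tip_row), , drop = FALSE], 2, cov,
                                   function(v, c) v * (1 - c) + 0.08 * c)
  img
}

# two horizontal dark bands (a straight horizontal strut silhouette)
parallel_band_image <- function(y_top = 50, y_bot = 70, nx = 300, ny = 120) {
  img <- matrix(0.95, ny, nx)
  img[y_top:y_bot, ] <- 0.2
  img
}

# plain diagonal stripes, no strut
stripe_image <- function(angle_deg = 45, pitch_px = 32, nx = 300, ny = 300) {
  th <- angle_deg * pi / 180
  xx <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  yy <- matrix(rep(0:(ny - 1), nx), ny, nx)
  0.75 + 0.2 * cos(2 * pi * (xx * sin(th) - yy * cos(th)) / pitch_px)
}

default_conditions <- function(gamma = 0) {
  print_conditions(v_p = 5, Q = 0.25, density = 1000, g = 9.81, gamma = gamma)
}

default_optics <- function() {
  optical_config(pattern_angle_deg = 45, pattern_pitch = 0.8, lumped_zdn = 0.17)
}

# straight single-strut bottom-view scene with constant width/curvature
straight_bottom_scene <- function(rho, a = 2, len_mm = 14, y_mm = 5,
                                  noise_sd = 0.01, seed = 5, edge_depth = 0.55,
                                  corner_margin = 1) {
  kappa <- rho * a^3 / 12
  path <- data.frame(x_mm = c(0, len_mm), y_mm = c(y_mm, y_mm))
  stations <- data.frame(p_mm = c(0, len_mm), a_mm = c(a, a))
  sc <- render_bottom_view(stations, path, default_optics(), kappa,
                           scale = 0.025, noise_sd = noise_sd, seed = seed,
                           pad_mm = 5, edge_depth = edge_depth,
                           corner_margin = corner_margin)
  sc$kappa <- kappa
  sc
}

# meander spreading scene generated from the complete-wetting law
meander_scene <- function(K = 0.566, v_p = 5, scale = 0.025, row_length = 40,
                          n_rows = 7, seed = 7, t_floor = 0.45) {
  path <- serpentine_path(row_length, n_rows, row_spacing_mm = 4, margin_mm = 4)
  cum <- c(0, cumsum(sqrt(diff(path$x_mm)^2 + diff(path$y_mm)^2)))
  L <- max(cum)
  p <- seq(0, L, by = 1)
  stations <- data.frame(p_mm = p,
                         a_mm = K * pmax((L - p) / v_p, t_floor)^(1 / 7))
  sc <- render_bottom_view(stations, path, default_optics(), kappa = 0.05,
                           scale = scale, noise_sd = 0.01, seed = seed,
                           pad_mm = 4)
  list(scene = sc, path = path, L = L, K = K, v_p = v_p, scale = scale,
       kappa = 0.05, t_floor = t_floor)
}
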