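# Synthetic scene rendering. Scenes are deterministic under a fixed seed
# and every render can be written together with a machine-readable
# ground-truth sidecar (JSON), so end-to-end tests consume only the
# render and compare only against the sidecar.

#' Serpentine (meander) print path
#'
#' Horizontal rows of equal length connected by short vertical moves, the
#' standard pattern for the strut-spreading test. Coordinates are in mm
#' with the origin at the image's top-left pixel centre.
#'
#' @param row_length_mm length of each horizontal row.
#' @param n_rows number of horizontal rows.
#' @param row_spacing_mm vertical spacing between rows.
#' @param margin_mm offset of the first vertex from the origin.
#' @return A data.frame with `x_mm`, `y_mm` vertices in print order.
#' @export
serpentine_path <- function(row_length_mm, n_rows, row_spacing_mm = 3,
                            margin_mm = 3) {
  xs <- ys <- numeric(0)
  for (i in seq_len(n_rows)) {
    y <- margin_mm + (i - 1) * row_spacing_mm
    xx <- if (i %% 2 == 1) c(margin_mm, margin_mm + row_length_mm)
          else c(margin_mm + row_length_mm, margin_mm)
    if (i == 1) { xs <- xx; ys <- c(y, y) }
    else { xs <- c(xs, xx[2]); ys <- c(ys, y) }
    if (i < n_rows) { xs <- c(xs, xx[2]); ys <- c(ys, y + row_spacing_mm) }
  }
  data.frame(x_mm = xs, y_mm = ys)
}

#' Render a bottom-view snapshot of a printed strand on a striped plate
#'
#' Draws diagonal sinusoidal stripes of the configured pitch and angle
#' over the whole frame, then, inside the strut band of every horizontal
#' path segment, remaps the across-strut background coordinate through
#' the paraxial lens forward model ([apparent_rotation()]): a background
#' point at offset `dy` from the strut axis is displayed from
#' `M(x) * dy`, with the local magnification following from the local
#' vertex curvature `rho = 12 kappa / a(x)^3` (cross-section `kappa`
#' conserved along the strand). Faint edge darkening marks `+-a/2`.
#' Corner zones (within `corner_margin` of segment ends) and vertical
#' connector segments are left as plain background.
#'
#' @param stations data.frame with `p_mm` (arc position along the path)
#'   and `a_mm` (strut width there); widths are interpolated linearly in
#'   between.
#' @param path print path (see [serpentine_path()]).
#' @param optics an [optical_config()].
#' @param kappa conserved cross-section area in mm^2.
#' @param scale mm per pixel (default 0.025).
#' @param noise_sd additive Gaussian pixel noise SD (default 0.01).
#' @param seed RNG seed.
#' @param corner_margin unrendered zone at segment ends, mm (default 1).
#' @param pad_mm frame padding beyond the path bounding box (default 3).
#' @param edge_depth,edge_width_px darkening amplitude and Gaussian width
#'   of the strut edge lines.
#' @return A list with `img` (matrix) and `truth` (all generating
#'   parameters, JSON-serialisable).
#' @export
render_bottom_view <- function(stations, path, optics, kappa,
                               scale = 0.025, noise_sd = 0.01, seed = 1,
                               corner_margin = 1, pad_mm = 3,
                               edge_depth = 0.55, edge_width_px = 1.5) {
  stopifnot(inherits(optics, "optical_config"))
  check_positive(kappa, "kappa")
  nx <- ceiling((max(path$x_mm) + pad_mm) / scale)
  ny <- ceiling((max(path$y_mm) + pad_mm) / scale)
  xmm <- (seq_len(nx) - 1) * scale
  ymm <- (seq_len(ny) - 1) * scale
  theta <- deg2rad(optics$pattern_angle_deg)
  stripe_at <- function(x, y) {
    0.75 + 0.2 * cos(2 * pi * (x * sin(theta) - y * cos(theta)) / optics$pattern_pitch)
  }
  img <- outer(ymm, xmm, function(y, x) stripe_at(x, y))

  cum <- path_arclength(path)
  zdn <- lens_constant(optics)
  for (i in seq_len(nrow(path) - 1)) {
    if (abs(path$y_mm[i + 1] - path$y_mm[i]) > 1e-9) next  # connector
    y_c <- path$y_mm[i]
    x0 <- path$x_mm[i]; x1 <- path$x_mm[i + 1]
    dir <- sign(x1 - x0)
    lo <- min(x0, x1) + corner_margin; hi <- max(x0, x1) - corner_margin
    cols <- which(xmm >= lo & xmm <= hi)
    if (!length(cols)) next
    for (cx in cols) {
      p <- cum[i] + abs(xmm[cx] - x0)
      a <- approx(stations$p_mm, stations$a_mm, p, rule = 2)$y
      if (a / 2 > max(y_c, max(ymm) - y_c))
        stopf("strut wider than image at station %.1f mm", p)
      rho <- 12 * kappa / a^3
      f <- zdn * rho
      if (f >= 1) stopf("beyond-focus curvature in render (z*rho*dn = %.2f)", f)
      M <- 1 / (1 - f)
      rows <- which(abs(ymm - y_c) <= a / 2 + 4 * edge_width_px * scale)
      dy <- ymm[rows] - y_c
      inside <- abs(dy) <= a / 2
      vals <- img[rows, cx]
      vals[inside] <- stripe_at(xmm[cx], y_c + M * dy[inside])
      vals <- vals * (1 - edge_depth *
                        exp(-(abs(dy) - a / 2)^2 / (2 * (edge_width_px * scale)^2)))
      img[rows, cx] <- vals
    }
  }
  set.seed(seed)
  img <- pmin(pmax(img + rnorm(length(img), 0, noise_sd), 0), 1)
  list(img = img,
       truth = list(stations = stations, path = path, kappa = kappa,
                    scale = scale, noise_sd = noise_sd, seed = seed,
                    optics = unclass(optics)[!vapply(unclass(optics), is.null, TRUE)],
                    corner_margin = corner_margin))
}

#' Render a side view of the hanging strut at the nozzle
#'
#' Draws the nozzle as a dark vertical bar of the stated outer diameter
#' (so [calibrate_scale()] works on the render) and the strut silhouette
#' as the centerline offset by half the local diameter along the local
#' normal, anti-aliased over one pixel, plus additive Gaussian noise.
#' Gravity points down the image (+y), matching the physical geometry of
#' a strand sagging from a horizontally moving nozzle.
#'
#' @param traj a [strut_trajectory()] (x must span the strut; the first
#'   sample is the nozzle exit).
#' @param nozzle_od nozzle outer diameter in mm (default 0.82).
#' @param scale mm per pixel (default 0.025).
#' @param noise_sd additive pixel noise SD (default 0.01).
#' @param seed RNG seed.
#' @return A list with `img` and `truth` (trajectory table, nozzle od,
#'   scale, seed, pixel origin of the nozzle exit).
#' @export
render_side_view <- function(traj, nozzle_od = 0.82, scale = 0.025,
                             noise_sd = 0.01, seed = 1) {
  stopifnot(inherits(traj, "strut_trajectory"))
  if (nrow(traj) < 2) stopf("blank trajectory")
  y_mm <- as.numeric(cumtrapz(traj$x, tan(traj$alpha)))
  pad_x <- ceiling(nozzle_od / scale) + 20
  pad_y <- 40                                    # nozzle length above the tip
  nx <- pad_x + ceiling(max(traj$x) / scale) + ceiling(max(traj$d) / scale) + 20
  ny <- pad_y + ceiling(max(y_mm) / scale) + ceiling(max(traj$d) / scale) + 20
  img <- matrix(0.95, ny, nx)
  x0_px <- pad_x; y0_px <- pad_y                 # nozzle exit pixel
  # strut silhouette, column by column (x is strictly increasing)
  cols <- which((seq_len(nx) - x0_px) * scale >= 0 &
                  (seq_len(nx) - x0_px) * scale <= max(traj$x))
  yy <- seq_len(ny)
  for (cx in cols) {
    xm <- (cx - x0_px) * scale
    yc <- y0_px + approx(traj$x, y_mm, xm, rule = 2)$y / scale
    al <- approx(traj$x, traj$alpha, xm, rule = 2)$y
    dd <- approx(traj$x, traj$d, xm, rule = 2)$y
    h <- dd / (2 * cos(al)) / scale              # vertical half-thickness, px
    cov <- pmin(pmax(h - abs(yy - yc) + 0.5, 0), 1)
    img[, cx] <- img[, cx] - 0.75 * cov
  }
  # nozzle bar
  hw <- nozzle_od / 2 / scale
  covn <- pmin(pmax(hw - abs(seq_len(nx) - x0_px) + 0.5, 0), 1)
  rows_n <- seq_len(floor(y0_px))
  img[rows_n, ] <- sweep(img[rows_n, , drop = FALSE], 2, covn,
                         function(v, c) v * (1 - c) + 0.08 * c)
  set.seed(seed)
  img <- pmin(pmax(img + rnorm(length(img), 0, noise_sd), 0), 1)
  list(img = img,
       truth = list(traj = as.data.frame(traj), nozzle_od = nozzle_od,
                    scale = scale, noise_sd = noise_sd, seed = seed,
                    exit_px = c(x = x0_px, y = y0_px)))
}

#' Write a rendered scene with its ground-truth sidecar
#'
#' @param scene a list with `img` and `truth` (from a render function).
#' @param prefix output path prefix; writes `<prefix>.png` and
#'   `<prefix>.json`.
#' @return The two paths, invisibly.
#' @export
write_scene <- function(scene, prefix) {
  png_path <- paste0(prefix, ".png")
  json_path <- paste0(prefix, ".json")
  write_image(scene$img, png_path)
  write_json(scene$truth, json_path, auto_unbox = TRUE, digits = NA,
             dataframe = "columns", null = "null")
  invisible(c(png_path, json_path))
}
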