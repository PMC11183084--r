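#' Calibrate the pixel scale from the nozzle silhouette
#'
#' The nozzle is the darkest vertical structure at the top of a side-view
#' frame; its measured pixel width against the known outer diameter sets
#' the mm-per-pixel scale (a 21G needle, 0.82 mm, by default). Edges are
#' located to sub-pixel precision by linear interpolation of the
#' column-intensity profile at the half-contrast level.
#'
#' @param img image matrix (see [read_image()]).
#' @param nozzle_od_mm nozzle outer diameter in mm (default 0.82).
#' @param top_frac fraction of image rows (from the top) averaged for the
#'   column profile (default 0.15).
#' @return Scale in mm per pixel, with attributes `width_px` and
#'   `center_px` (column of the nozzle axis).
#' @export
calibrate_scale <- function(img, nozzle_od_mm = 0.82, top_frac = 0.15) {
  check_positive(nozzle_od_mm, "nozzle_od_mm")
  rows <- seq_len(max(2L, floor(nrow(img) * top_frac)))
  prof <- colMeans(img[rows, , drop = FALSE])
  lo <- min(prof); hi <- max(prof)
  if (hi - lo < 0.2)
    stopf("calibration error: no nozzle detected (column contrast %.3f < 0.2); supply a manual scale", hi - lo)
  thr <- (lo + hi) / 2
  dark <- prof < thr
  # widest dark run
  r <- rle(dark)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  di <- which(r$values)
  if (!length(di)) stopf("calibration error: no dark run found")
  j <- di[which.max(r$lengths[di])]
  i0 <- starts[j]; i1 <- ends[j]
  # sub-pixel crossings of the profile at thr
  left <- if (i0 > 1) (i0 - 1) + (prof[i0 - 1] - thr) / (prof[i0 - 1] - prof[i0]) else i0
  right <- if (i1 < length(prof)) i1 + (prof[i1] - thr) / (prof[i1] - prof[i1 + 1]) else i1
  width_px <- right - left
  if (width_px < 3) stopf("calibration error: nozzle run too narrow (%.1f px)", width_px)
  structure(nozzle_od_mm / width_px, width_px = width_px,
            center_px = (left + right) / 2)
}

#' Canny-style edge contours of a single strand
#'
#' Gaussian-smoothed derivative-of-Gaussian gradients, Otsu-anchored
#' hysteresis thresholding (low/high as fractions of the Otsu level of
#' the gradient magnitude) and connected-component linking, followed by
#' per-column extraction of the upper and lower boundary of the dominant
#' strand, each refined to sub-pixel by a parabolic fit of the gradient
#' magnitude across the edge.
#'
#' @param img image matrix.
#' @param roi optional region of interest `list(x = c(x0, x1), y =
#'   c(y0, y1))` in pixel indices; default full frame.
#' @param sigma Gaussian pre-smoothing SD in px (default 2).
#' @param low_frac,high_frac hysteresis thresholds as fractions of the
#'   Otsu level of the gradient magnitude (defaults 0.5, 1.0).
#' @param min_coverage minimum fraction of ROI columns that must carry
#'   both an upper and a lower edge (default 0.5).
#' @return A list of class `contour_pair` with data.frames `upper` and
#'   `lower` (columns `x`, `y` in full-image pixel coordinates, upper =
#'   smaller y), both x-monotone.
#' @export
extract_contours <- function(img, roi = NULL, sigma = 2, low_frac = 0.5,
                             high_frac = 1.0, min_coverage = 0.5) {
  if (is.null(roi)) roi <- list(x = c(1, ncol(img)), y = c(1, nrow(img)))
  sub <- img[roi$y[1]:roi$y[2], roi$x[1]:roi$x[2], drop = FALSE]
  g <- grad_xy(sub, sigma)
  mag <- sqrt(g$gx^2 + g$gy^2)
  mx <- max(mag)
  if (mx < 1e-4) stopf("extraction error: no edges found (blank image?)")
  th_high <- high_frac * EBImage::otsu(mag / mx, range = c(0, 1)) * mx
  th_low <- low_frac * th_high
  strong <- mag >= th_high
  weak <- mag >= th_low
  lab <- EBImage::bwlabel(weak)
  keep_lab <- unique(lab[strong])
  keep_lab <- keep_lab[keep_lab > 0]
  if (!length(keep_lab)) stopf("extraction error: no edge chains above threshold")
  edge <- matrix(lab %in% keep_lab, nrow(sub), ncol(sub))

  nc <- ncol(sub)
  up <- lo <- rep(NA_real_, nc)
  for (cx in seq_len(nc)) {
    ys <- which(edge[, cx])
    if (length(ys) < 2) next
    # split into runs; topmost run -> upper edge, bottommost -> lower
    runs <- split(ys, cumsum(c(1, diff(ys) > 2)))
    if (length(runs) < 2) next
    up[cx] <- refine_edge(mag[, cx], runs[[1]])
    lo[cx] <- refine_edge(mag[, cx], runs[[length(runs)]])
  }
  ok <- !is.na(up) & !is.na(lo) & up < lo
  if (mean(ok) < min_coverage)
    stopf("extraction error: fewer than two x-monotone chains cover the ROI (coverage %.0f%%)",
          100 * mean(ok))
  xs <- which(ok)
  structure(list(
    upper = data.frame(x = xs + roi$x[1] - 1, y = up[xs] + roi$y[1] - 1),
    lower = data.frame(x = xs + roi$x[1] - 1, y = lo[xs] + roi$y[1] - 1)),
    class = "contour_pair")
}

# sub-pixel edge position: gradient-magnitude peak within a run of edge
# rows, refined parabolically
refine_edge <- function(mag_col, run) {
  i <- run[which.max(mag_col[run])]
  if (i <= 1 || i >= length(mag_col)) return(i)
  i + parabolic_vertex(mag_col[i - 1], mag_col[i], mag_col[i + 1])
}

#' Centerline, pitch angle and local diameter from a contour pair
#'
#' The centerline is the pointwise mean of the two contours on their
#' common pixel abscissa; the local diameter at each centerline point is
#' the nearest-neighbour distance to the upper contour plus the
#' nearest-neighbour distance to the lower contour; the pitch angle is
#' the arctangent of a Savitzky-Golay-smoothed centerline tangent
#' (local quadratic, 11-point window); arc length accumulates from the
#' first (nozzle-exit) point.
#'
#' @param contours a [extract_contours()] result.
#' @param scale mm per pixel.
#' @return A [strut_trajectory()] (s, x in mm; alpha in rad, positive
#'   downward; d in mm).
#' @export
centerline_and_diameter <- function(contours, scale) {
  stopifnot(inherits(contours, "contour_pair"))
  check_positive(scale, "scale")
  u <- contours$upper; l <- contours$lower
  if (any(u$y >= l$y)) stopf("contour crossing detected")
  xs <- u$x
  yc <- (u$y + l$y) / 2
  n <- length(xs)
  win <- min(11, if (n %% 2 == 1) n else n - 1)
  slope <- sgolayfilt(yc, p = 2, n = win, m = 1) / sgolayfilt(xs, p = 2, n = win, m = 1)
  alpha <- atan(slope)   # image y is downward = physical sag direction
  # nearest-neighbour diameter (px), vectorised over contour points
  d_px <- vapply(seq_len(n), function(i) {
    du <- sqrt((u$x - xs[i])^2 + (u$y - yc[i])^2)
    dl <- sqrt((l$x - xs[i])^2 + (l$y - yc[i])^2)
    min(du) + min(dl)
  }, numeric(1))
  ds <- sqrt(diff(xs)^2 + diff(yc)^2)
  s <- c(0, cumsum(ds)) * scale
  # enforce strictly increasing s (duplicate columns cannot occur, but
  # guard against degenerate smoothing output)
  strut_trajectory(s = s, x = (xs - xs[1]) * scale, alpha = alpha, d = d_px * scale)
}

# dominant orientation (degrees vs x-axis, in (0, 90)) of a striped
# region by the structure tensor of derivative-of-Gaussian gradients
structure_tensor_angle <- function(img, roi, sigma = 2, margin = NULL) {
  if (is.null(margin)) margin <- ceiling(4 * sigma) + 2
  sub <- img[roi$y[1]:roi$y[2], roi$x[1]:roi$x[2], drop = FALSE]
  g <- grad_xy(sub, sigma)
  nr <- nrow(sub); nc <- ncol(sub)
  if (nr <= 2 * margin + 2 || nc <= 2 * margin + 2)
    stopf("ROI too small for orientation analysis")
  ry <- (margin + 1):(nr - margin); rx <- (margin + 1):(nc - margin)
  gx <- g$gx[ry, rx]; gy <- g$gy[ry, rx]
  jxx <- sum(gx^2); jyy <- sum(gy^2); jxy <- sum(gx * gy)
  energy <- jxx + jyy
  if (energy < 1e-6) stopf("no dominant orientation: uniform region")
  coherence <- sqrt((jxx - jyy)^2 + 4 * jxy^2) / energy
  if (coherence < 0.2)
    stopf("no dominant orientation: coherence %.2f < 0.2", coherence)
  phi <- 0.5 * atan2(2 * jxy, jxx - jyy)  # gradient orientation
  stripe <- phi + pi / 2                  # stripes are normal to the gradient
  ang <- abs(rad2deg(atan(tan(stripe))))  # fold into (0, 90)
  structure(ang, coherence = coherence)
}

#' Measure the apparent stripe angle inside a strut
#'
#' Dominant stripe orientation from the structure tensor of the image
#' gradients inside the strut region; the reference (true) angle is taken
#' from a region outside the strut when given, else from the optical
#' configuration. The across-strut magnification is inferred as
#' `tan(theta_ref) / tan(theta_apparent)`.
#'
#' @param img image matrix.
#' @param roi strut region `list(x = c(x0, x1), y = c(y0, y1))` (pixel
#'   indices); should lie inside the strut band.
#' @param config an [optical_config()] (supplies the reference angle if
#'   `roi_reference` is `NULL`).
#' @param roi_reference optional background region outside the strut.
#' @param sigma gradient scale in px (default 2).
#' @return A [pattern_observation()] with attribute `reference_angle_deg`.
#' @export
stripe_angle_in_strut <- function(img, roi, config, roi_reference = NULL,
                                  sigma = 2) {
  stopifnot(inherits(config, "optical_config"))
  ang_in <- structure_tensor_angle(img, roi, sigma)
  ang_ref <- if (!is.null(roi_reference)) {
    as.numeric(structure_tensor_angle(img, roi_reference, sigma))
  } else config$pattern_angle_deg
  obs <- pattern_observation(as.numeric(ang_in),
                             magnification = tan(deg2rad(ang_ref)) /
                               tan(deg2rad(as.numeric(ang_in))))
  attr(obs, "reference_angle_deg") <- ang_ref
  obs
}

# arc-length parameterisation of a polyline path (mm)
path_arclength <- function(path) {
  c(0, cumsum(sqrt(diff(path$x_mm)^2 + diff(path$y_mm)^2)))
}

# position and unit tangent at arc position p along the path
path_point <- function(path, cum, p) {
  i <- max(1, min(findInterval(p, cum, rightmost.closed = TRUE), nrow(path) - 1))
  seg <- c(path$x_mm[i + 1] - path$x_mm[i], path$y_mm[i + 1] - path$y_mm[i])
  len <- sqrt(sum(seg^2))
  tang <- seg / len
  f <- (p - cum[i]) / len
  list(x = path$x_mm[i] + f * seg[1], y = path$y_mm[i] + f * seg[2],
       tangent = tang, seg_index = i,
       dist_to_corner = min(p - cum[i], cum[i + 1] - p))
}

#' Strut-width time series from an end-of-print snapshot
#'
#' At the moment printing ends the strand near the nozzle is freshly
#' extruded while the far end has been spreading for the whole print, so
#' a single snapshot yields a width-versus-time series: at stations
#' spaced along the print path, the width is measured perpendicular to
#' the local path direction, and the elapsed time per station is the
#' remaining path distance to the print end divided by the print speed.
#' Stations falling within `corner_margin` of a path corner are skipped
#' (logged in the `skipped` attribute).
#'
#' The width at a station is found from the two edge-darkening dips of
#' the perpendicular intensity profile (averaged over +-3 px along the
#' path), each refined to sub-pixel by a parabolic fit.
#'
#' @param img snapshot image matrix.
#' @param path print path as a data.frame with `x_mm`, `y_mm` (origin at
#'   the image's top-left pixel centre).
#' @param v_p print speed in mm/s.
#' @param scale mm per pixel.
#' @param station_step station spacing along the path in mm (default 2).
#' @param corner_margin exclusion zone around path corners in mm
#'   (default 2).
#' @param max_halfwidth_mm half-width of the perpendicular search profile
#'   (default 1.2 mm).
#' @param min_dip minimum edge-dip depth below the local background to
#'   accept a station (default 0.15 intensity units).
#' @return A [spreading_series()] sorted by time, with attribute
#'   `stations` (data.frame of arc position, x, y, t, a) and `skipped`.
#' @export
width_series_from_snapshot <- function(img, path, v_p, scale,
                                       station_step = 2, corner_margin = 2,
                                       max_halfwidth_mm = 1.2, min_dip = 0.15) {
  check_positive(v_p, "v_p"); check_positive(scale, "scale")
  check_positive(station_step, "station_step")
  cum <- path_arclength(path)
  L <- cum[length(cum)]
  ps <- seq(station_step, L - station_step / 2, by = station_step)
  if (!length(ps)) stopf("path too short for any station")
  hw_px <- ceiling(max_halfwidth_mm / scale)
  res <- list(); skipped <- character()
  for (p in ps) {
    pt <- path_point(path, cum, p)
    seg_len <- cum[pt$seg_index + 1] - cum[pt$seg_index]
    if (pt$dist_to_corner <= corner_margin || seg_len < 3 * corner_margin) {
      skipped <- c(skipped, sprintf("station %.1f mm: within %.1f mm of a corner", p, corner_margin))
      next
    }
    nrm <- c(-pt$tangent[2], pt$tangent[1])
    uu <- seq(-hw_px, hw_px)           # px steps along the normal
    prof <- rep(0, length(uu))
    offs <- -3:3                        # +-3 px averaging along the path
    for (o in offs) {
      cx <- (pt$x + o * scale * pt$tangent[1]) / scale + 1 + uu * nrm[1]
      cy <- (pt$y + o * scale * pt$tangent[2]) / scale + 1 + uu * nrm[2]
      prof <- prof + sample_bilinear(img, cx, cy)
    }
    prof <- prof / length(offs)
    w <- width_from_profile(prof, uu, min_dip)
    if (is.na(w)) {
      skipped <- c(skipped, sprintf("station %.1f mm: no edge dips found", p))
      next
    }
    res[[length(res) + 1]] <- data.frame(p = p, x = pt$x, y = pt$y,
                                         t = (L - p) / v_p, a = w * scale)
  }
  if (length(res) < 3) stopf("fewer than 3 usable stations")
  st <- do.call(rbind, res)
  st <- st[order(st$t), ]
  out <- spreading_series(st$t, st$a)
  attr(out, "stations") <- st
  attr(out, "skipped") <- skipped
  out
}

# width (px) between the two strongest edge dips of a perpendicular
# intensity profile; NA if the dips are too shallow
width_from_profile <- function(prof, uu, min_dip) {
  bg <- quantile(prof, 0.75)
  mid <- which.min(abs(uu))
  find_dip <- function(idx) {
    i <- idx[which.min(prof[idx])]
    if (bg - prof[i] < min_dip) return(NA_real_)
    if (i <= 1 || i >= length(prof)) return(NA_real_)
    uu[i] + parabolic_vertex(prof[i - 1], prof[i], prof[i + 1])
  }
  u_left <- find_dip(seq_len(mid - 2))
  u_right <- find_dip((mid + 2):length(prof))
  if (is.na(u_left) || is.na(u_right)) return(NA_real_)
  u_right - u_left
}

#' Strut mask from local stripe-orientation deviation (in-gel imaging)
#'
#' When a strut is embedded in a support gel there is no intensity step
#' at its boundary; the strut is only visible because the stripes inside
#' it are displaced and rotated by refraction. The local stripe
#' orientation (structure tensor) deviates from the background
#' orientation inside the strut, and the phase discontinuity at the strut
#' boundary produces a sharp spike of the deviation field. The mask is
#' built column by column between the two outermost deviation spikes
#' (each refined to sub-pixel by a parabolic fit), for struts running
#' along the image x-axis.
#'
#' @param img image matrix.
#' @param sigma gradient scale in px (default 1.5).
#' @param sigma_w tensor-averaging window SD in px (default 2).
#' @param min_dev_deg minimum peak deviation (degrees) for a column to
#'   count as crossing the strut (default 10).
#' @param border_px image-border zone excluded from the analysis, where
#'   replicate-boundary filtering corrupts orientations (default 15).
#' @return A logical matrix of the strut mask, with attribute
#'   `background_angle_deg`.
#' @export
in_gel_strut_mask <- function(img, sigma = 1.5, sigma_w = 2,
                              min_dev_deg = 10, border_px = 15) {
  g <- grad_xy(img, sigma)
  gw <- gauss_kernel(sigma_w); K <- outer(gw, gw)
  jxx <- EBImage::filter2(g$gx^2, K, boundary = "replicate")
  jyy <- EBImage::filter2(g$gy^2, K, boundary = "replicate")
  jxy <- EBImage::filter2(g$gx * g$gy, K, boundary = "replicate")
  if (sum(jxx) + sum(jyy) < 1e-6) stopf("uniform image: no stripes to segment")
  phi <- 0.5 * atan2(2 * jxy, jxx - jyy)
  phi_bg <- median(phi)   # background dominates the scene
  dev <- rad2deg(abs(atan(tan(phi - phi_bg))))
  bm <- border_px
  dev[c(seq_len(bm), (nrow(dev) - bm + 1):nrow(dev)), ] <- 0
  dev[, c(seq_len(bm), (ncol(dev) - bm + 1):ncol(dev))] <- 0
  mask <- matrix(FALSE, nrow(img), ncol(img))
  for (cx in seq_len(ncol(img))) {
    dv <- runmed(dev[, cx], 3)
    mx <- max(dv); b <- median(dv)
    if (mx < min_dev_deg) next
    # edge spikes: outermost local maxima clearly above the background
    thr <- b + pmax(0.8 * min_dev_deg, 0.3 * (mx - b))
    n <- length(dv)
    is_peak <- c(FALSE, dv[2:(n - 1)] >= dv[1:(n - 2)] &
                   dv[2:(n - 1)] >= dv[3:n], FALSE) & dv > thr
    pk <- which(is_peak)
    if (length(pk) < 2 || max(pk) - min(pk) < 3) next
    top <- refine_edge(dv, min(pk) + (-1:1))
    bot <- refine_edge(dv, max(pk) + (-1:1))
    mask[ceiling(top):floor(bot), cx] <- TRUE
  }
  structure(mask,
            background_angle_deg = abs(rad2deg(atan(tan(phi_bg + pi / 2)))))
}
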