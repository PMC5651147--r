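# Synthetic scoliotic spine phantom: geometry generation, radiograph
# rendering, and marker-based ground-truth slope recovery.
#
# Conventions used throughout the package:
#  * images are numeric matrices, rows = y (top to bottom), cols = x,
#    intensities in [0, 255]; pixel indices are 1-based
#  * a vertebral slope is the angle (degrees) of the endplate direction
#    versus horizontal; positive = right end of the superior endplate
#    higher than the left (counterclockwise with x right, y down)

#' Run code with a private RNG state
#'
#' Seeds the RNG, runs `code`, and restores the caller's RNG state so that
#' package functions never leak random-state side effects.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Fixed phantom geometry (pixels, in the 1000-px standardized frame).
# The marker offset, vertebra pitch and detection window are chosen jointly
# so that a detection window centred on one vertebra always contains that
# vertebra's two markers and never a neighbour's, up to the maximum slope.
phantom_geometry <- function() {
  list(
    height         = 1000,  # standardized image height
    y_top          = 96,    # centre of the topmost vertebra
    y_bottom       = 904,   # centre of the lowest vertebra
    body_halfwidth = 42,
    body_halfheight = 18,
    corner_radius  = 6,
    endplate_band  = 3,     # thickness of the darker endplate edge band
    marker_offset  = 20,    # distance of each pedicle marker from the centre
    marker_radius  = 3.5,
    bg_base        = 55,
    bg_gradient    = 25,    # added linearly top -> bottom
    body_delta     = 80,    # body intensity above background
    edge_delta     = -35,   # endplate band relative to body
    marker_delta   = 150,   # markers above body
    blur_sigma     = 1
  )
}

vertebra_labels <- function(n) {
  if (n == 17L) c(paste0("T", 1:12), paste0("L", 1:5)) else paste0("V", seq_len(n))
}

# Normalized midline derivative g(t) for each curve family, evaluated at the
# vertebra stations t in [0, 1]: lateral deviation x(t) proportional to
# sin(pi t) (single, C-shaped) or sin(2 pi t) (double, S-shaped).
curve_shape_deriv <- function(t, curve_family) {
  switch(curve_family,
    single_curve = pi * cos(pi * t),
    double_curve = 2 * pi * cos(2 * pi * t),
    stop("unknown curve_family: ", curve_family)
  )
}

# Mean absolute vertebral slope (degrees) produced by a spec whose maximum
# absolute slope is M degrees: slopes_i = atan(tan(M) * g_i / max|g|).
mean_abs_slope_given_max <- function(M, g_rel) {
  mean(atan(tan(M * pi / 180) * abs(g_rel))) * 180 / pi
}

# Calibrate the exponent of the maximum-slope law M(u) = lo + (hi-lo) u^gamma
# (u uniform) so that the population mean absolute vertebral slope equals
# `target` degrees.  Solved once per generator call by root finding over a
# quadrature grid; deterministic.
calibrate_max_slope_exponent <- function(lo, hi, target, g_rel) {
  u <- (seq_len(512) - 0.5) / 512
  pop_mean <- function(log_gamma) {
    M <- lo + (hi - lo) * u^exp(log_gamma)
    mean(vapply(M, mean_abs_slope_given_max, numeric(1), g_rel = g_rel)) - target
  }
  f_lo <- mean_abs_slope_given_max(lo, g_rel)
  f_hi <- mean_abs_slope_given_max(hi, g_rel)
  if (pop_mean(6) >= 0 || pop_mean(-6) <= 0) {
    stop("mean_magnitude ", target,
         " not attainable with slope range [", lo, ", ", hi, "]",
         sprintf(" (attainable mean-slope band approx (%.2f, %.2f))",
                 f_lo, f_hi))
  }
  stats::uniroot(pop_mean, interval = c(-6, 6), tol = 1e-10)$root
}

#' Generate the geometric specification of a phantom scoliotic spine
#'
#' Draws a smooth lateral-deviation midline (a single C-shaped or double
#' S-shaped sinusoidal curve), places `n_vertebrae` vertebrae at equal
#' vertical spacing in the 1000-px standardized frame, and assigns each
#' vertebra the slope of the midline tangent at its centre.  The maximum
#' absolute slope of each spine is drawn from a law calibrated so that, over
#' many spines, every maximum falls inside `slope_magnitude_range` and the
#' grand mean absolute vertebral slope equals `mean_magnitude`.
#'
#' @param n_vertebrae number of vertebrae (default 17: T1-T12, L1-L5).
#' @param slope_magnitude_range numeric length-2, degrees; the per-spine
#'   maximum absolute slope is confined to this interval (default 5-50).
#' @param mean_magnitude target population mean absolute vertebral slope in
#'   degrees (default 15).
#' @param curve_family `"single_curve"` or `"double_curve"`.
#' @param image_width width in pixels of the frame the spine must fit
#'   (with a 75-px patch margin); default 900.
#' @param seed integer; the spec is fully determined by it.
#' @return An object of class `spine_spec`: a list with `vertebrae` (a
#'   data.frame of label, centre, size, slope and marker coordinates),
#'   `curve_params`, and `seed`.
#' @examples
#' spec <- generate_spine_spec(seed = 1)
#' head(spec$vertebrae)
#' @export
generate_spine_spec <- function(n_vertebrae = 17L,
                                slope_magnitude_range = c(5, 50),
                                mean_magnitude = 15,
                                curve_family = c("single_curve", "double_curve"),
                                image_width = 900L,
                                seed = 1L) {
  curve_family <- match.arg(curve_family)
  lo <- slope_magnitude_range[1]; hi <- slope_magnitude_range[2]
  if (length(slope_magnitude_range) != 2L || !is.finite(lo) || !is.finite(hi) ||
      lo >= hi || lo < 0 || hi > 89) {
    stop("invalid slope_magnitude_range: need 0 <= low < high <= 89, got [",
         lo, ", ", hi, "]")
  }
  if (n_vertebrae < 2L) stop("n_vertebrae must be >= 2, got ", n_vertebrae)

  geom <- phantom_geometry()
  t_i <- (seq_len(n_vertebrae) - 1) / (n_vertebrae - 1)
  y_i <- geom$y_top + t_i * (geom$y_bottom - geom$y_top)
  g <- curve_shape_deriv(t_i, curve_family)
  g_rel <- g / max(abs(g))

  gamma <- exp(calibrate_max_slope_exponent(lo, hi, mean_magnitude, g_rel))

  with_seed(seed, {
    u <- stats::runif(1)
    max_slope <- lo + (hi - lo) * u^gamma
    direction <- sample(c(-1, 1), 1)
  })

  # amplitude such that dx/dy at the steepest vertebra equals tan(max_slope)
  span <- geom$y_bottom - geom$y_top
  slope_tan <- direction * tan(max_slope * pi / 180) * g_rel
  slope_deg <- atan(slope_tan) * 180 / pi
  shape <- switch(curve_family,
    single_curve = sin(pi * t_i),
    double_curve = sin(2 * pi * t_i)
  )
  amp <- direction * tan(max_slope * pi / 180) * span / max(abs(g))
  x_i <- image_width / 2 + amp * shape

  th <- slope_deg * pi / 180
  d <- geom$marker_offset
  vert <- data.frame(
    label     = vertebra_labels(n_vertebrae),
    center_x  = x_i,
    center_y  = y_i,
    width     = 2 * geom$body_halfwidth,
    height    = 2 * geom$body_halfheight,
    slope_deg = slope_deg,
    marker_lx = x_i - d * cos(th),
    marker_ly = y_i + d * sin(th),
    marker_rx = x_i + d * cos(th),
    marker_ry = y_i - d * sin(th),
    stringsAsFactors = FALSE
  )

  structure(
    list(
      vertebrae = vert,
      curve_params = list(
        family = curve_family, amplitude = amp, max_slope = max_slope,
        direction = direction, gamma = gamma,
        slope_magnitude_range = c(lo, hi), mean_magnitude = mean_magnitude,
        image_width = image_width
      ),
      seed = seed
    ),
    class = "spine_spec"
  )
}

#' @export
print.spine_spec <- function(x, ...) {
  cat("Phantom spine spec:", nrow(x$vertebrae), "vertebrae,",
      x$curve_params$family, "\n")
  cat(sprintf("  max |slope| %.1f deg, mean |slope| %.1f deg, seed %d\n",
              max(abs(x$vertebrae$slope_deg)),
              mean(abs(x$vertebrae$slope_deg)), x$seed))
  invisible(x)
}

validate_spine_spec <- function(spec) {
  stopifnot(inherits(spec, "spine_spec"))
  v <- spec$vertebrae
  if (any(diff(v$center_y) <= 0)) {
    stop("spine_spec invalid: vertebra centres not strictly increasing in y")
  }
  ang <- atan2(-(v$marker_ry - v$marker_ly), v$marker_rx - v$marker_lx) * 180 / pi
  if (max(abs(ang - v$slope_deg)) > 1e-8) {
    stop("spine_spec invalid: marker segment angle inconsistent with slope")
  }
  invisible(spec)
}

# signed distance to a rounded rectangle of half extents (a, b), corner
# radius r, in the rectangle's own frame; negative inside
rounded_rect_sdf <- function(p, q, a, b, r) {
  qx <- abs(p) - (a - r)
  qy <- abs(q) - (b - r)
  sqrt(pmax(qx, 0)^2 + pmax(qy, 0)^2) + pmin(pmax(qx, qy), 0) - r
}

#' Render a phantom radiograph from a spine specification
#'
#' Produces a grayscale image (1000 px high) in which each vertebra appears
#' as a rotated rounded rectangle of elevated intensity with darker endplate
#' edge bands and two bright pedicle-marker disks, over a smooth background
#' gradient, with Gaussian blur and optional additive Gaussian noise.
#'
#' @param spec a [generate_spine_spec()] result.
#' @param image_width canvas width in pixels; defaults to the width the spec
#'   was generated for.
#' @param noise_level standard deviation of additive Gaussian noise in
#'   intensity units (0-255 scale); default 5.
#' @param seed integer seed for the noise.
#' @return An object of class `phantom_radiograph`: list with `image`
#'   (matrix, rows = y), `truth` (the spec), `noise_level`, `seed`.
#' @export
render_radiograph <- function(spec, image_width = NULL, noise_level = 5,
                              seed = 1L) {
  validate_spine_spec(spec)
  geom <- phantom_geometry()
  H <- geom$height
  W <- as.integer(if (is.null(image_width)) spec$curve_params$image_width
                  else image_width)
  v <- spec$vertebrae

  # every 150x150 patch centred on a vertebra must fit in the canvas
  bad <- which(v$center_x - 75 < 1 | v$center_x + 74 > W |
               v$center_y - 75 < 1 | v$center_y + 74 > H)
  if (length(bad)) {
    stop("patch window out of bounds for vertebra index ", bad[1],
         " (", v$label[bad[1]], "): increase image_width")
  }

  img <- matrix(geom$bg_base, nrow = H, ncol = W) +
    matrix(geom$bg_gradient * (seq_len(H) - 1) / (H - 1), nrow = H, ncol = W)

  a <- geom$body_halfwidth; b <- geom$body_halfheight
  r <- geom$corner_radius; band <- geom$endplate_band
  half <- ceiling(sqrt(a^2 + b^2)) + 3L
  for (i in seq_len(nrow(v))) {
    cx <- v$center_x[i]; cy <- v$center_y[i]
    th <- v$slope_deg[i] * pi / 180
    rows <- max(1L, floor(cy) - half):min(H, ceiling(cy) + half)
    cols <- max(1L, floor(cx) - half):min(W, ceiling(cx) + half)
    dx <- outer(rep(1, length(rows)), cols - cx)
    dy <- outer(rows - cy, rep(1, length(cols)))
    # rotate into the vertebra frame (p along endplate, q along spine axis)
    p <-  dx * cos(th) - dy * sin(th)
    q <-  dx * sin(th) + dy * cos(th)
    sdf <- rounded_rect_sdf(p, q, a, b, r)
    cov <- pmin(pmax(0.5 - sdf, 0), 1)  # anti-aliased edge coverage
    band_cov <- pmin(pmax(abs(q) - (b - band) + 0.5, 0), 1)
    img[rows, cols] <- img[rows, cols] +
      geom$body_delta * cov + geom$edge_delta * band_cov * cov
  }

  # pedicle markers: small bright disks
  mr <- geom$marker_radius
  marker_xy <- rbind(cbind(v$marker_lx, v$marker_ly),
                     cbind(v$marker_rx, v$marker_ry))
  for (m in seq_len(nrow(marker_xy))) {
    mx <- marker_xy[m, 1]; my <- marker_xy[m, 2]
    rows <- max(1L, floor(my - mr - 1)):min(H, ceiling(my + mr + 1))
    cols <- max(1L, floor(mx - mr - 1)):min(W, ceiling(mx + mr + 1))
    dd <- outer((rows - my)^2, rep(1, length(cols))) +
          outer(rep(1, length(rows)), (cols - mx)^2)
    cov <- pmin(pmax(mr + 0.5 - sqrt(dd), 0), 1)  # anti-aliased disk
    img[rows, cols] <- img[rows, cols] + geom$marker_delta * cov
  }

  img <- eb_gblur(img, geom$blur_sigma)
  if (noise_level > 0) {
    noise <- with_seed(seed,
      matrix(stats::rnorm(H * W, 0, noise_level), nrow = H))
    img <- img + noise
  }
  img[img < 0] <- 0
  img[img > 255] <- 255

  structure(
    list(image = img, truth = spec, noise_level = noise_level, seed = seed),
    class = "phantom_radiograph"
  )
}

#' @export
print.phantom_radiograph <- function(x, ...) {
  cat(sprintf("Phantom radiograph %d x %d px, noise sd %.1f, %d vertebrae\n",
              nrow(x$image), ncol(x$image), x$noise_level,
              nrow(x$truth$vertebrae)))
  invisible(x)
}

# isotropic Gaussian blur via EBImage (x = columns first there, so transpose)
eb_gblur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(img)), sigma = sigma)))
}

#' Recover a vertebra's slope from its rendered pedicle markers
#'
#' Thresholds the brightest pixels in a square window centred on the
#' vertebra, labels connected components, takes the two largest blobs as the
#' pedicle markers, and returns the angle of the segment joining their
#' intensity-weighted centroids versus horizontal.  On noise-free phantom
#' renders this recovers the specified slope to within a small fraction of a
#' degree; it is the phantom analogue of reading lead markers off a
#' radiograph to establish ground truth.
#'
#' @param image grayscale matrix (rows = y).
#' @param vertebra_center numeric (x, y) centre of the vertebra, 1-based.
#' @param window odd window side length in pixels (default 55, sized to
#'   exclude neighbouring vertebrae's markers).
#' @param percentile intensity quantile used as the blob threshold.  The
#'   default 0.97 admits the whole of both marker disks (about 2.5% of the
#'   window area), so centroids average over full anti-aliased blobs; higher
#'   thresholds keep only the saturated plateau tops and lose sub-pixel
#'   accuracy.
#' @return slope in degrees (positive = right marker higher).
#' @export
detect_markers_and_slope <- function(image, vertebra_center, window = 55L,
                                     percentile = 0.97) {
  stopifnot(is.matrix(image), length(vertebra_center) == 2)
  half <- (as.integer(window) - 1L) %/% 2L
  cx <- round(vertebra_center[1]); cy <- round(vertebra_center[2])
  rows <- max(1L, cy - half):min(nrow(image), cy + half)
  cols <- max(1L, cx - half):min(ncol(image), cx + half)
  win <- image[rows, cols, drop = FALSE]

  if (max(win) - min(win) < 1e-9) {
    stop("markers not found: featureless window at (", cx, ", ", cy, ")")
  }
  # inclusive threshold: saturated (clipped) marker cores form plateaus at
  # the window maximum, which a strict > would exclude entirely.  The
  # mid-range floor keeps the threshold out of flat backgrounds, where the
  # upper quantile can coincide with the background level and select
  # everything.
  thr <- max(stats::quantile(win, percentile, names = FALSE),
             min(win) + 0.5 * (max(win) - min(win)))
  bw <- win >= thr
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(bw * 1)))))
  sizes <- tabulate(lab[lab > 0])
  min_area <- 4  # reject isolated bright noise pixels
  keep <- which(sizes >= min_area)
  if (length(keep) < 2) {
    stop("markers not found: fewer than two blobs above threshold at (",
         cx, ", ", cy, ")")
  }
  ord <- keep[order(sizes[keep], decreasing = TRUE)]
  if (length(ord) > 2 && sizes[ord[3]] >= 0.5 * sizes[ord[2]]) {
    stop("ambiguous markers: ", length(ord),
         " similar-size blobs in window at (", cx, ", ", cy, "); sizes ",
         paste(sizes[ord], collapse = ", "))
  }
  centroid <- function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    w <- win[idx] - thr + 0.5  # >= 0.5 on plateaus, intensity-weighted above
    c(x = sum((cols[idx[, 2]]) * w) / sum(w),
      y = sum((rows[idx[, 1]]) * w) / sum(w))
  }
  c1 <- centroid(ord[1]); c2 <- centroid(ord[2])
  left <- if (c1["x"] <= c2["x"]) c1 else c2
  right <- if (c1["x"] <= c2["x"]) c2 else c1
  unname(atan2(-(right["y"] - left["y"]), right["x"] - left["x"]) * 180 / pi)
}

#' Ground-truth Cobb angle of a spine specification
#'
#' Applies the end-vertebra selection and sum-of-absolute-slopes rule
#' directly to the exact specified slopes.
#' @param spec a `spine_spec`.
#' @return Cobb angle in degrees.
#' @export
true_cobb_angle <- function(spec) {
  cobb_angle(spec$vertebrae$slope_deg)
}
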