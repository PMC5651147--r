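# Cobb angle from vertebral slopes: end-vertebra selection and the
# sum-of-absolute-slopes rule.

#' Select the end-vertebrae from a list of slopes
#'
#' The end-vertebrae of a curve are the two most tilted vertebrae inclined
#' in opposite directions: the maximum positive slope and the most negative
#' slope.  Zero slopes are sign-neutral and may pair with either sign,
#' contributing nothing to the angle.  When every slope has the same strict
#' sign (e.g. the user clicked only half of a curve) there is no opposite
#' pair: with `strict = TRUE` this is an error; by default the extreme pair
#' (max and min) is returned with a `degenerate` flag so the tilt difference
#' can still be reported.
#'
#' Ties in absolute slope resolve to the lowest list index.  The returned
#' pair is ordered by list position (`upper` = smaller index).
#'
#' @param slopes numeric vector of slopes in degrees, length >= 2.
#' @param strict error on same-sign degenerate input instead of flagging.
#' @return list with `upper_index`, `lower_index`, and logical `degenerate`.
#' @examples
#' select_end_vertebrae(c(5, -10, 3))  # indices 1 and 2
#' @export
select_end_vertebrae <- function(slopes, strict = FALSE) {
  if (length(slopes) < 2) {
    stop("need at least 2 slopes to select end-vertebrae, got ",
         length(slopes))
  }
  if (anyNA(slopes)) stop("slopes contain missing values")
  i_max <- which.max(slopes)   # lowest index on ties
  i_min <- which.min(slopes)
  s_max <- slopes[i_max]; s_min <- slopes[i_min]
  degenerate <- FALSE
  if (s_max > 0 && s_min < 0) {
    pair <- c(i_max, i_min)
  } else if (s_max == 0 || s_min == 0) {
    # zeros are sign-neutral: pair the extreme with the first zero
    zero <- which(slopes == 0)[1]
    extreme <- if (s_max > 0) i_max else i_min
    if (extreme == zero) zero <- which(slopes == 0)[min(2, sum(slopes == 0))]
    pair <- c(extreme, zero)
  } else {
    if (strict) {
      stop("degenerate curve: all slopes tilt the same way (extremes at ",
           i_max, " and ", i_min, ")")
    }
    degenerate <- TRUE
    pair <- c(i_max, i_min)
  }
  if (pair[1] == pair[2]) {
    # all slopes zero: any two distinct positions
    pair <- c(1L, 2L)
    degenerate <- FALSE
  }
  list(upper_index = min(pair), lower_index = max(pair),
       degenerate = degenerate)
}

#' Cobb angle from vertebral slopes
#'
#' The Cobb angle is the sum of the absolute values of the two end-vertebra
#' slopes.  For degenerate same-sign input (see
#' [select_end_vertebrae()]) the tilt difference `max - min` is returned
#' with a warning, unless `strict = TRUE`.
#'
#' @inheritParams select_end_vertebrae
#' @return angle in degrees (>= 0), with attribute `degenerate` when the
#'   same-sign fallback was used.
#' @examples
#' cobb_angle(c(5, -10))  # 15
#' @export
cobb_angle <- function(slopes, strict = FALSE) {
  sel <- select_end_vertebrae(slopes, strict = strict)
  s1 <- slopes[sel$upper_index]; s2 <- slopes[sel$lower_index]
  if (sel$degenerate) {
    warning("all slopes tilt the same way; reporting tilt difference ",
            "max - min instead of a Cobb angle")
    ang <- max(slopes) - min(slopes)
  } else {
    ang <- abs(s1) + abs(s2)
  }
  structure(ang, degenerate = if (sel$degenerate) TRUE else NULL)
}

#' Measure the Cobb angle on a radiograph from user clicks
#'
#' Standardizes the image, predicts the slope of the vertebra at each
#' clicked point with the trained network, selects the end-vertebrae among
#' the clicked set, and computes the Cobb angle.  Clicks are interpreted in
#' the standardized (1000-px-high) frame.
#'
#' @param image grayscale matrix.
#' @param clicks list of numeric (x, y) pairs, or an n x 2 matrix/data.frame
#'   with columns x, y; at least 2 clicks.
#' @param model trained `dnn_parameters`.
#' @param strict propagate the same-sign degenerate case as an error.
#' @return An object of class `measurement_record`: list with `clicks`,
#'   `slopes`, `upper_index`, `lower_index`, `cobb_angle`, `degenerate`.
#' @export
measure <- function(image, clicks, model, strict = FALSE) {
  if (is.data.frame(clicks)) clicks <- as.matrix(clicks[, c("x", "y")])
  if (is.matrix(clicks)) {
    clicks <- lapply(seq_len(nrow(clicks)), function(i) clicks[i, ])
  }
  if (length(clicks) < 2) {
    stop("need at least 2 clicked vertebrae, got ", length(clicks))
  }
  img <- standardize_image(image)
  slopes <- vapply(seq_along(clicks), function(i) {
    tryCatch(predict_slope(model, img, as.numeric(clicks[[i]])),
             error = function(e) stop("click ", i, ": ", conditionMessage(e),
                                      call. = FALSE))
  }, numeric(1))
  sel <- select_end_vertebrae(slopes, strict = strict)
  ang <- if (sel$degenerate) max(slopes) - min(slopes) else
    abs(slopes[sel$upper_index]) + abs(slopes[sel$lower_index])
  structure(
    list(clicks = clicks, slopes = slopes,
         upper_index = sel$upper_index, lower_index = sel$lower_index,
         cobb_angle = ang, degenerate = sel$degenerate),
    class = "measurement_record"
  )
}

#' @export
print.measurement_record <- function(x, ...) {
  cat(sprintf("Cobb angle: %.1f deg%s\n", x$cobb_angle,
              if (x$degenerate) " (degenerate: same-sign tilt difference)" else ""))
  cat(sprintf("  end-vertebrae: clicks %d (%.1f deg) and %d (%.1f deg) of %d\n",
              x$upper_index, x$slopes[x$upper_index],
              x$lower_index, x$slopes[x$lower_index], length(x$slopes)))
  invisible(x)
}
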