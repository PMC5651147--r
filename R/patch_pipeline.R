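# Preprocessing pipeline: image standardization, 150x150 patch extraction
# around vertebra centres, 3x3 block-average downsampling to 50x50, and
# jittered training-patch sampling.

PATCH_SIZE <- 150L
PATCH_DOWN <- 50L

#' Standardize a radiograph to the 1000-pixel reference height
#'
#' Rescales an image so its height is exactly 1000 pixels, preserving the
#' aspect ratio, using bilinear resampling.  An image already 1000 px high
#' is returned unchanged (standardization is idempotent).
#'
#' @param image grayscale matrix (rows = y), intensities in \[0, 255\].
#' @return matrix with 1000 rows.
#' @examples
#' img <- matrix(runif(2000 * 800, 0, 255), nrow = 2000)
#' dim(standardize_image(img))  # 1000 x 400
#' @export
standardize_image <- function(image) {
  if (!is.matrix(image) || nrow(image) == 0 || ncol(image) == 0) {
    stop("standardize_image needs a non-empty 2-D image matrix")
  }
  target_h <- 1000L
  if (nrow(image) == target_h) return(image)
  # EBImage stores x (width) first: transpose in and out
  eb <- EBImage::Image(t(image))
  out <- EBImage::resize(eb, h = target_h, filter = "bilinear")
  t(EBImage::imageData(out))
}

#' Extract the 150x150 patch centred on a point
#'
#' The window for integer centre `c` spans rows/columns `(c - 75):(c + 74)`
#' (a 150-pixel half-open window); the whole window must lie inside the
#' image.
#'
#' @param image grayscale matrix.
#' @param center numeric (x, y), 1-based pixel coordinates; rounded to the
#'   nearest integer pixel.
#' @return 150 x 150 matrix.
#' @export
extract_patch <- function(image, center) {
  stopifnot(is.matrix(image), length(center) == 2)
  half <- PATCH_SIZE %/% 2L  # 75
  cx <- as.integer(round(center[1])); cy <- as.integer(round(center[2]))
  if (cy - half < 1L || cy + half - 1L > nrow(image) ||
      cx - half < 1L || cx + half - 1L > ncol(image)) {
    stop(sprintf(paste0(
      "patch window out of bounds at centre (%d, %d): need x in [%d, %d], ",
      "y in [%d, %d]"), cx, cy, half + 1L, ncol(image) - half + 1L,
      half + 1L, nrow(image) - half + 1L))
  }
  image[(cy - half):(cy + half - 1L), (cx - half):(cx + half - 1L)]
}

#' Downsample a 150x150 patch to a 2500-element feature vector
#'
#' Reduces the patch by a factor of three with non-overlapping 3x3 block
#' averaging (150/3 = 50), flattens the 50x50 result row-major, and rescales
#' intensities from \[0, 255\] to \[0, 1\].
#'
#' @param patch150 a 150 x 150 matrix with intensities in \[0, 255\].
#' @return numeric vector of length 2500 with values in \[0, 1\].
#' @export
downsample_patch <- function(patch150) {
  if (!is.matrix(patch150) || !all(dim(patch150) == PATCH_SIZE)) {
    stop("downsample_patch needs a 150x150 matrix, got ",
         paste(dim(patch150), collapse = "x"))
  }
  K <- kronecker(diag(PATCH_DOWN), matrix(1 / 3, 1, 3))  # 50 x 150 averaging
  ds <- K %*% patch150 %*% t(K)
  as.vector(t(ds)) / 255
}

# extract + downsample in one step (patch vector for a click)
patch_vector_at <- function(image, center) {
  downsample_patch(extract_patch(image, center))
}

#' Sample labeled training patches from phantom radiographs
#'
#' For every vertebra of every radiograph, draws `patches_per_vertebra`
#' patch centres uniformly in the disk of radius `jitter_radius` around the
#' true vertebra centre, extracts and downsamples each patch, and labels it
#' with the vertebra's exact ground-truth slope (labels come from the spine
#' specification and are untouched by image noise).  Draws that would push
#' the 150x150 window out of bounds are rejected and redrawn (at most 100
#' attempts per patch).
#'
#' @param radiographs list of [render_radiograph()] results.
#' @param patches_per_vertebra patches sampled per vertebra (the reference
#'   training protocol uses 100).
#' @param jitter_radius maximum displacement of a patch centre from the
#'   vertebra centre, pixels (default 15).
#' @param seed integer seed; the sample is fully determined by it.
#' @param vectors if `FALSE`, skip pixel extraction and return only the
#'   sampling metadata (centres, offsets, labels); useful for auditing the
#'   sampling protocol at scales where the patch matrix would not fit in
#'   memory.
#' @return An object of class `patch_set`: list with `vectors` (N x 2500
#'   matrix, or NULL), `meta` (data.frame: radiograph, vertebra, label,
#'   center_x, center_y, dx, dy, slope label), and `sampling_config`.
#' @export
sample_training_patches <- function(radiographs, patches_per_vertebra = 100L,
                                    jitter_radius = 15, seed = 1L,
                                    vectors = TRUE) {
  if (inherits(radiographs, "phantom_radiograph")) radiographs <- list(radiographs)
  stopifnot(length(radiographs) >= 1, patches_per_vertebra >= 1)

  meta_list <- vector("list", length(radiographs))
  vec_list <- if (vectors) vector("list", length(radiographs)) else NULL

  with_seed(seed, {
    for (r in seq_along(radiographs)) {
      rg <- radiographs[[r]]
      img <- rg$image
      v <- rg$truth$vertebrae
      n_v <- nrow(v)
      n_p <- n_v * patches_per_vertebra
      cxs <- numeric(n_p); cys <- numeric(n_p)
      dxs <- numeric(n_p); dys <- numeric(n_p)
      labs <- numeric(n_p); verts <- integer(n_p)
      k <- 0L
      for (i in seq_len(n_v)) {
        for (j in seq_len(patches_per_vertebra)) {
          ok <- FALSE
          for (attempt in seq_len(100L)) {
            if (jitter_radius > 0) {
              # uniform in the disk: sqrt-radius times random angle
              rad <- jitter_radius * sqrt(stats::runif(1))
              ang <- stats::runif(1, 0, 2 * pi)
              dx <- round(rad * cos(ang)); dy <- round(rad * sin(ang))
            } else {
              dx <- 0; dy <- 0
            }
            cx <- round(v$center_x[i]) + dx; cy <- round(v$center_y[i]) + dy
            if (cy - 75 >= 1 && cy + 74 <= nrow(img) &&
                cx - 75 >= 1 && cx + 74 <= ncol(img)) { ok <- TRUE; break }
          }
          if (!ok) {
            stop("could not place patch window for vertebra ", i, " (",
                 v$label[i], ") of radiograph ", r,
                 " after 100 draws; jitter_radius too large for the canvas")
          }
          k <- k + 1L
          cxs[k] <- cx; cys[k] <- cy; dxs[k] <- dx; dys[k] <- dy
          labs[k] <- v$slope_deg[i]; verts[k] <- i
        }
      }
      meta_list[[r]] <- data.frame(
        radiograph = r, vertebra = verts, label = labs,
        center_x = cxs, center_y = cys, dx = dxs, dy = dys
      )
      if (vectors) {
        m <- matrix(0, nrow = n_p, ncol = PATCH_DOWN^2)
        for (k in seq_len(n_p)) {
          m[k, ] <- patch_vector_at(img, c(cxs[k], cys[k]))
        }
        vec_list[[r]] <- m
      }
    }
  })

  structure(
    list(
      vectors = if (vectors) do.call(rbind, vec_list) else NULL,
      meta = do.call(rbind, meta_list),
      sampling_config = list(patches_per_vertebra = patches_per_vertebra,
                             jitter_radius = jitter_radius, seed = seed)
    ),
    class = "patch_set"
  )
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf(
    "Patch set: %d patches (%d radiographs, %d per vertebra, jitter %g px)%s\n",
    nrow(x$meta), length(unique(x$meta$radiograph)),
    x$sampling_config$patches_per_vertebra, x$sampling_config$jitter_radius,
    if (is.null(x$vectors)) " [metadata only]" else ""))
  invisible(x)
}

#' Number of patches in a patch set
#' @param patch_set a `patch_set`.
#' @return integer count.
#' @export
n_patches <- function(patch_set) nrow(patch_set$meta)
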