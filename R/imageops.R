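# Shared low-level raster operations. EBImage does the heavy lifting
# (Gaussian filtering, grayscale morphology, CLAHE, distance transform,
# watershed); ridge/spot enhancement and shape measurement are implemented
# here because their exact definitions are part of the analysis contract.

as_pixels <- function(image) {
  if (inherits(image, "field_image")) image$pixels else as.matrix(image)
}

eb_mat <- function(x) {
  m <- EBImage::imageData(x)
  matrix(as.numeric(m), nrow(m), ncol(m))
}

#' Rolling-ball style background subtraction
#'
#' Estimates the smooth background as the grayscale morphological opening of
#' the image with a disc structuring element of the given radius and
#' subtracts it, flooring at zero. Used as the universal pre-processing step
#' to correct illumination heterogeneity; the structuring radius must exceed
#' the scale of genuine foreground objects.
#'
#' @param image A [field_image()] or matrix.
#' @param ball_radius_px Structuring-element radius in pixels (>= 1).
#' @return Same type as the input, background-subtracted.
#' @export
subtract_background <- function(image, ball_radius_px = 25) {
  if (!is.numeric(ball_radius_px) || ball_radius_px < 1) {
    stop("`ball_radius_px` must be >= 1.", call. = FALSE)
  }
  px <- as_pixels(image)
  r <- as.integer(round(ball_radius_px))
  off <- -r:r
  brush <- 1 * (outer(off^2, off^2, "+") <= r^2 + 1e-9)
  bg <- eb_mat(EBImage::opening(px, brush))
  out <- pmax(px - bg, 0)
  if (inherits(image, "field_image")) {
    field_image(out, channel = image$channel, pixel_size = image$pixel_size)
  } else {
    out
  }
}

gaussian_blur <- function(px, sigma_px) {
  if (sigma_px <= 0) return(px)
  eb_mat(EBImage::gblur(px, sigma = sigma_px))
}

conv3 <- function(px, k) {
  # 3x3 correlation with replicate padding (no spurious edge gradients)
  n <- nrow(px); m <- ncol(px)
  p <- matrix(0, n + 2, m + 2)
  p[2:(n + 1), 2:(m + 1)] <- px
  p[1, 2:(m + 1)] <- px[1, ]; p[n + 2, 2:(m + 1)] <- px[n, ]
  p[2:(n + 1), 1] <- px[, 1]; p[2:(n + 1), m + 2] <- px[, m]
  p[1, 1] <- px[1, 1]; p[1, m + 2] <- px[1, m]
  p[n + 2, 1] <- px[n, 1]; p[n + 2, m + 2] <- px[n, m]
  out <- matrix(0, n, m)
  for (di in -1:1) for (dj in -1:1) {
    w <- k[di + 2, dj + 2]
    if (w != 0) out <- out + w * p[(2 + di):(n + 1 + di), (2 + dj):(m + 1 + dj)]
  }
  out
}

log_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  xs <- -r:r
  g <- exp(-xs^2 / (2 * sigma^2))
  gx <- outer(g, g)
  x2 <- outer(xs^2, rep(1, length(xs))) + outer(rep(1, length(xs)), xs^2)
  k <- (x2 - 2 * sigma^2) / sigma^4 * gx
  k - mean(k) # zero-sum so flat regions give zero response
}

#' Laplacian-of-Gaussian spot response
#'
#' Convolves with a zero-sum LoG kernel and negates the response so that
#' bright, punctate structures become positive maxima.
#'
#' @param image A [field_image()] or matrix.
#' @param sigma_px Smoothing scale in pixels.
#' @return Matrix of spot responses (bright puncta positive).
#' @export
log_response <- function(image, sigma_px) {
  px <- as_pixels(image)
  k <- log_kernel(sigma_px)
  -eb_mat(EBImage::filter2(px, k, boundary = "replicate"))
}

#' Local contrast enhancement (CLAHE)
#'
#' Tile-based contrast-limited adaptive histogram equalization. The tile
#' size is given in micrometres and converted to pixels; the image is padded
#' by replication so its dimensions are tile multiples, then cropped back.
#'
#' @param image A [field_image()] or matrix.
#' @param block_um Tile size in micrometres (default 1.8).
#' @param slope Clip limit (default 3).
#' @param pixel_size Pixel size um/px (taken from a `field_image` input).
#' @return Matrix of enhanced intensities in `[0, 1]`.
#' @export
local_contrast_enhance <- function(image, block_um = 1.8, slope = 3,
                                   pixel_size = default_pixel_size()) {
  px <- as_pixels(image)
  if (inherits(image, "field_image")) pixel_size <- image$pixel_size
  tile <- max(4L, as.integer(round(um_to_px(block_um, pixel_size))))
  n <- nrow(px); m <- ncol(px)
  pn <- ceiling(n / tile) * tile
  pm <- ceiling(m / tile) * tile
  pad <- px
  if (pn > n) pad <- rbind(pad, pad[rep(n, pn - n), , drop = FALSE])
  if (pm > m) pad <- cbind(pad, pad[, rep(m, pm - m), drop = FALSE])
  sc <- max(pad)
  if (sc <= 0) return(px)
  enh <- eb_mat(EBImage::clahe(pad / sc, nx = pn / tile, ny = pm / tile,
                               limit = slope, keep.range = FALSE))
  enh[seq_len(n), seq_len(m)]
}

#' Hessian ridge ("tubeness") filter
#'
#' Enhances bright curvilinear structures: after Gaussian smoothing at the
#' given scale, the response is `max(-lambda_min, 0) * sigma^2`, where
#' `lambda_min` is the smaller eigenvalue of the local Hessian. Flat regions
#' and dark lines give zero.
#'
#' @param image A [field_image()] or matrix.
#' @param sigma_px Scale of the filter in pixels.
#' @return Matrix of ridge responses (>= 0).
#' @export
tubeness <- function(image, sigma_px = 3) {
  px <- as_pixels(image)
  g <- gaussian_blur(px, sigma_px)
  kxx <- matrix(c(0, 0, 0, 1, -2, 1, 0, 0, 0), 3, 3, byrow = TRUE)
  kyy <- t(kxx)
  kxy <- matrix(c(0.25, 0, -0.25, 0, 0, 0, -0.25, 0, 0.25), 3, 3, byrow = TRUE)
  ixx <- conv3(g, kxx)
  iyy <- conv3(g, kyy)
  ixy <- conv3(g, kxy)
  tr2 <- (ixx + iyy) / 2
  disc <- sqrt(((ixx - iyy) / 2)^2 + ixy^2)
  lambda_min <- tr2 - disc
  pmax(-lambda_min, 0) * sigma_px^2
}

#' Label connected foreground components (8-connected)
#'
#' @param mask Logical matrix.
#' @param pixel_size Pixel size um/px.
#' @return A [label_map()] with contiguous positive labels.
#' @export
label_components <- function(mask, pixel_size = default_pixel_size()) {
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  lab <- eb_mat(EBImage::bwlabel(mask * 1)) # 4-connected
  merge_diagonal_labels(lab, pixel_size)
}

merge_diagonal_labels <- function(lab, pixel_size) {
  n <- nrow(lab); m <- ncol(lab)
  if (max(lab) > 0 && n > 1 && m > 1) {
    a1 <- lab[-n, -m]; b1 <- lab[-1, -1]   # \ diagonal
    a2 <- lab[-1, -m]; b2 <- lab[-n, -1]   # / diagonal
    keep1 <- a1 > 0 & b1 > 0 & a1 != b1
    keep2 <- a2 > 0 & b2 > 0 & a2 != b2
    pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                          cbind(a2[keep2], b2[keep2])))
    if (nrow(pairs)) {
      parent <- seq_len(max(lab))
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (r in seq_len(nrow(pairs))) {
        ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_along(parent), find, numeric(1))
      lab[lab > 0] <- roots[lab[lab > 0]]
    }
  }
  relabel_contiguous(lab, pixel_size)
}

relabel_contiguous <- function(lab, pixel_size) {
  ids <- sort(setdiff(unique(as.vector(lab)), 0))
  if (length(ids)) {
    remap <- integer(max(ids))
    remap[ids] <- seq_along(ids)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  label_map(lab, pixel_size)
}

# Weighted-contour perimeter estimator (border pixels classified by their
# 3x3 neighborhood; straight edges ~1, diagonal steps ~sqrt(2), corners
# intermediate). Operates on a single binary object mask.
perimeter_px <- function(mask) {
  mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (!sum(mask)) return(0)
  # outside the image counts as background
  z <- matrix(0L, nrow(mask) + 2, ncol(mask) + 2)
  z[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  mask <- z
  k4 <- matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
  neigh <- conv3(mask, k4)
  eroded <- as.integer(mask == 1 & neigh == 5)
  border <- mask - matrix(eroded, nrow(mask), ncol(mask))
  code <- conv3(border, matrix(c(10, 2, 10, 2, 1, 2, 10, 2, 10), 3, 3))
  w <- numeric(50)
  w[c(5, 7, 15, 17, 25, 27) + 1] <- 1
  w[c(21, 33) + 1] <- sqrt(2)
  w[c(13, 23) + 1] <- (1 + sqrt(2)) / 2
  idx <- code[border == 1] + 1
  idx <- idx[idx >= 1 & idx <= 50]
  sum(w[idx])
}

#' Measure labelled particles
#'
#' Computes calibrated area, perimeter (weighted contour estimation),
#' circularity `4 * pi * area / perimeter^2` (clipped to `[0, 1]`; a particle
#' too small to have a measurable contour counts as maximally compact),
#' centroid, and mean intensity in any supplied channel.
#'
#' @param lm A [label_map()].
#' @param intensity_images Named list of [field_image()] objects or matrices;
#'   one `mean_<name>` column is added per entry.
#' @return A tibble (class `particle_set`) with one row per particle:
#'   `label`, `area_um2`, `perimeter_um`, `circularity`, `x`, `y`.
#' @export
measure_particles <- function(lm, intensity_images = list()) {
  stopifnot(inherits(lm, "label_map"))
  lab <- lm$labels
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (!length(ids)) {
    out <- tibble::tibble(label = integer(), area_um2 = numeric(),
                          perimeter_um = numeric(), circularity = numeric(),
                          x = numeric(), y = numeric())
    for (nm in names(intensity_images)) out[[paste0("mean_", nm)]] <- numeric()
    class(out) <- c("particle_set", class(out))
    return(out)
  }
  pos <- which(lab > 0, arr.ind = TRUE)
  labv <- lab[lab > 0]
  area_px <- as.numeric(tabulate(labv, nbins = max(ids))[ids])
  cy <- tapply(pos[, 1], labv, mean)[as.character(ids)]
  cx <- tapply(pos[, 2], labv, mean)[as.character(ids)]
  perim <- vapply(ids, function(id) {
    sel <- pos[labv == id, , drop = FALSE]
    r0 <- range(sel[, 1]); c0 <- range(sel[, 2])
    crop <- matrix(0L, r0[2] - r0[1] + 3, c0[2] - c0[1] + 3)
    crop[cbind(sel[, 1] - r0[1] + 2, sel[, 2] - c0[1] + 2)] <- 1L
    perimeter_px(crop)
  }, numeric(1))
  circ <- ifelse(perim > 0,
                 pmin(1, 4 * pi * area_px / perim^2), 1)
  out <- tibble::tibble(
    label = as.integer(ids),
    area_um2 = px_area_to_um2(area_px, lm$pixel_size),
    perimeter_um = px_to_um(perim, lm$pixel_size),
    circularity = circ,
    x = as.numeric(cx),
    y = as.numeric(cy)
  )
  for (nm in names(intensity_images)) {
    px <- as_pixels(intensity_images[[nm]])
    stopifnot(all(dim(px) == dim(lab)))
    means <- tapply(px[lab > 0], labv, mean)[as.character(ids)]
    out[[paste0("mean_", nm)]] <- as.numeric(means)
  }
  class(out) <- c("particle_set", class(out))
  out
}
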