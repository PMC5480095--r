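# Fixed-image analysis: cytotoxicity, neurite density, synapse density,
# tubulin intensity ratios / colocalization, and fibrillar-Tau load.

#' Segment nuclei from a counterstain image
#'
#' Gaussian smoothing (radius given in micrometres), a fixed intensity
#' threshold, distance-transform watershed separation of touching nuclei,
#' then removal of debris below a minimum area. The fixed threshold is a
#' required, documented configuration value relative to the image's dynamic
#' range; it is never auto-chosen.
#'
#' @param nuc_image A [field_image()] of the nuclear counterstain.
#' @param fixed_threshold Intensity threshold applied to the smoothed image.
#' @param min_area_um2 Minimum nucleus area in um^2 (default 90).
#' @param blur_radius_um Gaussian smoothing radius in um (default 1.75).
#' @param watershed_tolerance Minimum height of an object's distance-map
#'   maximum relative to its neighbours for a split (default 1).
#' @return A [label_map()]; one label per nucleus. A blank image yields an
#'   empty map. The attribute `px_params` records the pixel-space values
#'   actually used.
#' @export
segment_nuclei <- function(nuc_image, fixed_threshold,
                           min_area_um2 = 90, blur_radius_um = 1.75,
                           watershed_tolerance = 1) {
  stopifnot(inherits(nuc_image, "field_image"))
  ps <- nuc_image$pixel_size
  sigma_px <- um_to_px(blur_radius_um, ps)
  min_px <- area_um2_to_px(min_area_um2, ps)
  sm <- gaussian_blur(nuc_image$pixels, sigma_px)
  mask <- sm > fixed_threshold
  if (!any(mask)) {
    out <- label_map(matrix(0L, nrow(mask), ncol(mask)), ps)
    attr(out, "px_params") <- list(sigma_px = sigma_px, min_area_px = min_px)
    return(out)
  }
  dm <- EBImage::distmap(mask * 1)
  ws <- eb_mat(EBImage::watershed(dm, tolerance = watershed_tolerance))
  ws <- matrix(as.integer(round(ws)), nrow(ws), ncol(ws))
  # watershed conserves the thresholded foreground: every mask pixel labelled
  full <- relabel_contiguous(ws, ps)
  keep_labels <- which(tabulate(full$labels[full$labels > 0]) >= min_px)
  lab <- full$labels
  lab[!(lab %in% keep_labels)] <- 0L
  out <- relabel_contiguous(lab, ps)
  attr(out, "px_params") <- list(sigma_px = sigma_px, min_area_px = min_px)
  attr(out, "unfiltered") <- full
  out
}

#' Percentage of PI-positive (dead) nuclei
#'
#' A nucleus counts as dead when its mean intensity in the propidium-iodide
#' channel exceeds a fixed threshold.
#'
#' @param nuclei A [label_map()] from [segment_nuclei()].
#' @param pi_image A [field_image()] of the PI channel (same geometry).
#' @param pi_threshold Fixed intensity threshold on the per-nucleus mean.
#' @return One-row tibble: `n_nuclei`, `n_pi_positive`, `pct_pi_positive`
#'   (percent; `NA` when the field contains no nuclei — an undefined
#'   percentage, not zero).
#' @export
classify_pi_positive <- function(nuclei, pi_image, pi_threshold) {
  stopifnot(inherits(nuclei, "label_map"), inherits(pi_image, "field_image"))
  lab <- nuclei$labels
  if (!all(dim(lab) == dim(pi_image$pixels))) {
    stop("PI image and nucleus labels must share geometry.", call. = FALSE)
  }
  n <- n_objects(nuclei)
  if (n == 0) {
    return(tibble::tibble(n_nuclei = 0L, n_pi_positive = NA_integer_,
                          pct_pi_positive = NA_real_))
  }
  means <- tapply(pi_image$pixels[lab > 0], lab[lab > 0], mean)
  npos <- sum(means > pi_threshold)
  tibble::tibble(n_nuclei = n, n_pi_positive = as.integer(npos),
                 pct_pi_positive = 100 * npos / n)
}

#' Dual-mask segmentation of the neurite network
#'
#' Two masks are combined: mask 1 captures the high-intensity network core by
#' Isodata thresholding of the (background-subtracted) input; mask 2 recovers
#' faint, fine processes by local contrast enhancement (CLAHE tiles of
#' `clahe_block_um`, clip `clahe_slope`) followed by Laplacian edge
#' enhancement (`image + alpha * |LoG response|`), again Isodata-thresholded.
#' The network ROI is their union.
#'
#' @param tub_image A background-subtracted [field_image()] of a cytoskeletal
#'   marker (e.g. beta-III-tubulin, MAP2).
#' @param clahe_block_um CLAHE tile size in um (default 1.8).
#' @param clahe_slope CLAHE clip limit (default 3).
#' @param laplace_alpha Weight of the edge-enhancement term (default 1).
#' @param laplace_sigma_px LoG scale for edge enhancement in px (default 1).
#' @param denoise_sigma_px Gaussian pre-smoothing applied before the local
#'   contrast enhancement only, suppressing read noise that small-tile
#'   equalization would otherwise amplify (default 0.8 px; 0 disables).
#' @return A [neurite_mask()]; attributes `mask1` and `mask2` keep the two
#'   components for inspection. A constant image yields an empty mask with a
#'   warning.
#' @export
segment_neurites <- function(tub_image, clahe_block_um = 1.8, clahe_slope = 3,
                             laplace_alpha = 1, laplace_sigma_px = 1,
                             denoise_sigma_px = 0.8) {
  stopifnot(inherits(tub_image, "field_image"))
  px <- tub_image$pixels
  ps <- tub_image$pixel_size
  if (diff(range(px)) <= 0) {
    warning("Constant image: empty neurite mask.", call. = FALSE)
    return(neurite_mask(matrix(FALSE, nrow(px), ncol(px)), ps))
  }
  mask1 <- px > auto_threshold(px, "isodata")
  base <- if (denoise_sigma_px > 0) gaussian_blur(px, denoise_sigma_px) else px
  enh <- local_contrast_enhance(base, block_um = clahe_block_um,
                                slope = clahe_slope, pixel_size = ps)
  edge <- enh + laplace_alpha * abs(log_response(enh, laplace_sigma_px))
  mask2 <- edge > auto_threshold(edge, "isodata")
  out <- neurite_mask(mask1 | mask2, ps)
  attr(out, "mask1") <- mask1
  attr(out, "mask2") <- mask2
  out
}

#' Mean intensity ratio inside a mask
#'
#' Ratio of the mean numerator intensity over the mean denominator intensity,
#' both taken over the pixels of the network mask (e.g. acetylated
#' alpha-tubulin over beta-III-tubulin, or AT8 over total Tau).
#'
#' @param numerator,denominator [field_image()] objects of equal geometry.
#' @param mask A [neurite_mask()].
#' @return The ratio, or `NA` (with attribute `reason`) for an empty mask or
#'   a non-positive denominator mean.
#' @export
intensity_ratio <- function(numerator, denominator, mask) {
  stopifnot(inherits(mask, "neurite_mask"))
  a <- as_pixels(numerator); b <- as_pixels(denominator)
  m <- mask$mask
  if (!any(m)) {
    out <- NA_real_; attr(out, "reason") <- "empty mask"; return(out)
  }
  den <- mean(b[m])
  if (!is.finite(den) || den <= 0) {
    out <- NA_real_; attr(out, "reason") <- "non-positive denominator mean"
    return(out)
  }
  mean(a[m]) / den
}

#' Pearson colocalization coefficient
#'
#' Sample Pearson correlation of two channels over the pixels of a mask
#' (whole image when no mask is given). Symmetric and invariant to affine
#' intensity rescaling with positive gain.
#'
#' @param a,b [field_image()] objects or matrices of equal geometry.
#' @param mask Optional [neurite_mask()] or logical matrix restricting the
#'   pixel domain.
#' @return Correlation in `[-1, 1]`, or `NA` (attribute `reason`) when a
#'   channel is constant on the domain or the domain has < 2 pixels.
#' @export
pearson_colocalization <- function(a, b, mask = NULL) {
  pa <- as_pixels(a); pb <- as_pixels(b)
  stopifnot(all(dim(pa) == dim(pb)))
  if (is.null(mask)) {
    m <- matrix(TRUE, nrow(pa), ncol(pa))
  } else if (inherits(mask, "neurite_mask")) {
    m <- mask$mask
  } else {
    m <- matrix(as.logical(mask), nrow(pa), ncol(pa))
  }
  va <- pa[m]; vb <- pb[m]
  if (length(va) < 2 || stats::sd(va) == 0 || stats::sd(vb) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "constant channel or degenerate domain"
    return(out)
  }
  stats::cor(va, vb)
}

#' Fibrillar-Tau particle segmentation and load
#'
#' Enhances curvilinear structures in the amyloid-dye channel with a Hessian
#' ridge filter, thresholds with the Triangle criterion, and keeps particles
#' of at least `min_area_um2` whose circularity falls inside `circ_range`
#' (elongated structures only). The fibril load is the summed calibrated
#' area of kept-particle pixels that fall inside the microtubule-network
#' mask (pixel intersection; set `mode = "centroid"` to instead count whole
#' particles whose centroid lies inside the mask).
#'
#' @param pftaa A [field_image()] of the fibril dye channel.
#' @param mt_mask A [neurite_mask()] delimiting the MT network.
#' @param tubeness_sigma Ridge-filter scale (default 3, in px; set
#'   `sigma_in_um = TRUE` to interpret it in um).
#' @param min_area_um2 Minimum particle size (default 15 um^2).
#' @param circ_range Circularity interval kept (default `c(0, 0.30)`).
#' @param mode `"pixel"` (default) or `"centroid"` mask intersection.
#' @param sigma_in_um Interpret `tubeness_sigma` in micrometres.
#' @return List: `particles` (kept [measure_particles()] tibble),
#'   `fibril_load_um2`, `all_particles` (pre-filter tibble).
#' @export
segment_fibrils <- function(pftaa, mt_mask, tubeness_sigma = 3,
                            min_area_um2 = 15, circ_range = c(0, 0.30),
                            mode = c("pixel", "centroid"),
                            sigma_in_um = FALSE) {
  stopifnot(inherits(pftaa, "field_image"), inherits(mt_mask, "neurite_mask"))
  mode <- match.arg(mode)
  ps <- pftaa$pixel_size
  sigma_px <- if (sigma_in_um) um_to_px(tubeness_sigma, ps) else tubeness_sigma
  tube <- tubeness(pftaa$pixels, sigma_px)
  if (diff(range(tube)) <= 1e-9 * max(1, max(abs(tube)))) {
    empty <- measure_particles(label_map(matrix(0L, nrow(tube), ncol(tube)), ps))
    return(list(particles = empty, fibril_load_um2 = 0, all_particles = empty))
  }
  mask <- tube > auto_threshold(tube, "triangle")
  lm <- label_components(mask, ps)
  all_particles <- measure_particles(lm)
  keep <- all_particles$area_um2 >= min_area_um2 &
    all_particles$circularity >= circ_range[1] &
    all_particles$circularity <= circ_range[2]
  kept <- all_particles[keep, , drop = FALSE]
  lab <- lm$labels
  if (mode == "pixel") {
    inside <- lab %in% kept$label & mt_mask$mask
    load <- px_area_to_um2(sum(inside), ps)
  } else {
    cin <- kept$label[mt_mask$mask[cbind(round(kept$y), round(kept$x))]]
    load <- sum(kept$area_um2[kept$label %in% cin])
  }
  list(particles = kept, fibril_load_um2 = load, all_particles = all_particles)
}

#' Detect synaptic puncta
#'
#' Laplacian-of-Gaussian filtering at the stated smoothing scale (response
#' signed so bright puncta are maxima), Triangle thresholding, and particle
#' size filtering.
#'
#' @param syn_image A background-subtracted [field_image()] of a presynaptic
#'   marker (e.g. synaptophysin-I).
#' @param laplace_scale_um LoG smoothing scale in um (default 0.35).
#' @param min_area_um2 Minimum spot area (default 0.75 um^2).
#' @return A `particle_set` tibble of kept spots (attribute `n_rejected`
#'   counts sub-size particles).
#' @export
detect_synapse_spots <- function(syn_image, laplace_scale_um = 0.35,
                                 min_area_um2 = 0.75) {
  stopifnot(inherits(syn_image, "field_image"))
  ps <- syn_image$pixel_size
  resp <- log_response(syn_image$pixels, um_to_px(laplace_scale_um, ps))
  if (diff(range(resp)) <= 1e-9 * max(1, max(abs(resp)))) {
    return(measure_particles(label_map(matrix(0L, nrow(resp), ncol(resp)), ps)))
  }
  mask <- resp > auto_threshold(resp, "triangle")
  lm <- label_components(mask, ps)
  spots <- measure_particles(lm)
  kept <- spots[spots$area_um2 >= min_area_um2, , drop = FALSE]
  attr(kept, "n_rejected") <- nrow(spots) - nrow(kept)
  kept
}

#' Synapse density
#'
#' Number of presynaptic puncta per square micrometre of neurite area.
#'
#' @param spots A `particle_set` from [detect_synapse_spots()], or a spot
#'   count.
#' @param neurites A [neurite_mask()].
#' @return Spots per um^2, or `NA` (attribute `reason`) when the neurite
#'   area is zero.
#' @export
synapse_density <- function(spots, neurites) {
  stopifnot(inherits(neurites, "neurite_mask"))
  n <- if (is.numeric(spots)) spots else nrow(spots)
  if (neurites$area_um2 <= 0) {
    out <- NA_real_; attr(out, "reason") <- "zero neurite area"; return(out)
  }
  n / neurites$area_um2
}
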