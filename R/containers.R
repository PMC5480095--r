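#' Calibrated single-channel image
#'
#' A 2D non-negative intensity image with its channel name and pixel
#' calibration. Matrices are stored in standard R orientation (rows = y,
#' columns = x); point coordinates elsewhere in the package are `(x, y)`
#' pixel positions, 1-based at pixel centres.
#'
#' @param pixels Numeric matrix of non-negative finite intensities.
#' @param channel Channel name (e.g. `"dapi"`, `"tubulin"`).
#' @param pixel_size Pixel size in um/px.
#' @return A `field_image` object.
#' @export
field_image <- function(pixels, channel = "unknown",
                        pixel_size = default_pixel_size()) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix.", call. = FALSE)
  }
  if (anyNA(pixels) || any(!is.finite(pixels)) || any(pixels < 0)) {
    stop("Image intensities must be finite and non-negative.", call. = FALSE)
  }
  check_pixel_size(pixel_size)
  structure(
    list(pixels = pixels, channel = as.character(channel)[1],
         pixel_size = pixel_size),
    class = "field_image"
  )
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("<field_image> channel '%s', %d x %d px @ %.4g um/px\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$pixel_size))
  invisible(x)
}

#' @export
dim.field_image <- function(x) dim(x$pixels)

#' Multi-channel z-stack for one field of view
#'
#' Stores the voxel data of one imaging field as a 4D array
#' `(z, y, x, channel)` together with channel names and spatial calibration.
#'
#' @param voxels 4D numeric array `(z, y, x, channel)`, or a 3D array
#'   `(z, y, x)` for a single channel.
#' @param channel_names Character vector naming the channel axis.
#' @param pixel_size Lateral pixel size, um/px.
#' @param z_spacing Axial plane spacing, um.
#' @return A `field_stack` object.
#' @export
field_stack <- function(voxels, channel_names, pixel_size = default_pixel_size(),
                        z_spacing = 1) {
  if (length(dim(voxels)) == 3) {
    voxels <- array(voxels, dim = c(dim(voxels), 1))
  }
  if (length(dim(voxels)) != 4) {
    stop("`voxels` must be a (z, y, x, channel) array.", call. = FALSE)
  }
  if (anyNA(voxels) || any(!is.finite(voxels)) || any(voxels < 0)) {
    stop("Voxel intensities must be finite and non-negative.", call. = FALSE)
  }
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(voxels)[4]) {
    stop("`channel_names` length must match the channel axis.", call. = FALSE)
  }
  check_pixel_size(pixel_size)
  if (!is.numeric(z_spacing) || z_spacing <= 0) {
    stop("`z_spacing` must be positive (um).", call. = FALSE)
  }
  structure(
    list(voxels = voxels, channel_names = channel_names,
         pixel_size = pixel_size, z_spacing = z_spacing),
    class = "field_stack"
  )
}

#' @export
print.field_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<field_stack> %d z x %d y x %d x px, channels: %s\n",
              d[1], d[2], d[3], paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' Well-level 5D dataset (fields x channels x z)
#'
#' Bundles the field stacks of one well (default layout: 16 fields on a 4 x 4
#' grid) with the well's plate-layout entry. Fields remain independent units
#' of analysis; no stitching is performed.
#'
#' @param well_id Well identifier (e.g. `"B03"`).
#' @param fields List of [field_stack()] objects sharing channel set and
#'   calibration.
#' @param layout Optional one-row tibble from [read_plate_layout()].
#' @param missing_fields Optional character vector describing fields that were
#'   expected but not found; kept as a warning record.
#' @return A `well_dataset` object.
#' @export
well_dataset <- function(well_id, fields, layout = NULL,
                         missing_fields = character()) {
  if (length(fields) < 1) stop("A well needs at least one field.", call. = FALSE)
  if (!all(vapply(fields, inherits, logical(1), "field_stack"))) {
    stop("`fields` must be a list of field_stack objects.", call. = FALSE)
  }
  chans <- lapply(fields, `[[`, "channel_names")
  if (length(unique(vapply(chans, paste, character(1), collapse = "|"))) != 1) {
    stop("All fields of a well must share the same channel set.", call. = FALSE)
  }
  px <- vapply(fields, `[[`, numeric(1), "pixel_size")
  if (diff(range(px)) > 1e-12) {
    stop("All fields of a well must share the same pixel calibration.",
         call. = FALSE)
  }
  structure(
    list(well_id = as.character(well_id)[1], fields = fields,
         layout = layout, missing_fields = missing_fields),
    class = "well_dataset"
  )
}

#' @export
print.well_dataset <- function(x, ...) {
  cat(sprintf("<well_dataset> well %s: %d field(s), channels: %s\n",
              x$well_id, length(x$fields),
              paste(x$fields[[1]]$channel_names, collapse = ", ")))
  if (length(x$missing_fields)) {
    cat("  missing fields:", paste(x$missing_fields, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Integer-labelled segmentation map
#'
#' @param labels Integer matrix; 0 is background, objects are labelled with
#'   contiguous positive integers.
#' @param pixel_size Pixel size um/px.
#' @return A `label_map` object.
#' @export
label_map <- function(labels, pixel_size = default_pixel_size()) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix.", call. = FALSE)
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  if (any(labels < 0)) stop("Labels must be >= 0.", call. = FALSE)
  check_pixel_size(pixel_size)
  structure(list(labels = labels, pixel_size = pixel_size),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d object(s), %d x %d px\n",
              n_objects(x), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Number of labelled objects in a label map
#' @param x A `label_map`.
#' @return Integer count.
#' @export
n_objects <- function(x) {
  stopifnot(inherits(x, "label_map"))
  length(setdiff(unique(as.vector(x$labels)), 0L))
}

#' Binary neurite-network mask with calibrated area
#'
#' @param mask Logical matrix (TRUE = neurite).
#' @param pixel_size Pixel size um/px.
#' @return A `neurite_mask` object whose `area_um2` equals the TRUE-pixel
#'   count times `pixel_size^2`.
#' @export
neurite_mask <- function(mask, pixel_size = default_pixel_size()) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix.", call. = FALSE)
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  check_pixel_size(pixel_size)
  structure(
    list(mask = mask, pixel_size = pixel_size,
         area_um2 = px_area_to_um2(sum(mask), pixel_size)),
    class = "neurite_mask"
  )
}

#' @export
print.neurite_mask <- function(x, ...) {
  cat(sprintf("<neurite_mask> area %.1f um^2 (%d px)\n", x$area_um2,
              sum(x$mask)))
  invisible(x)
}
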