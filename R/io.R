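#' Read a plate layout table
#'
#' The layout CSV maps wells to treatment groups. Required columns: `well`
#' (unique id), `treatment`, `dose` (numeric, unit in `dose_unit` or implied
#' by the experiment), `n_b` (biological replicate index) and `n_w` (well
#' replicate index).
#'
#' @param path CSV file path.
#' @return A tibble with columns `well_id`, `treatment`, `dose`, `n_b`, `n_w`.
#' @export
read_plate_layout <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("well", "treatment", "dose", "n_b", "n_w")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    stop("Plate layout is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    well_id = as.character(tbl$well),
    treatment = as.character(tbl$treatment),
    dose = as.numeric(tbl$dose),
    n_b = as.integer(tbl$n_b),
    n_w = as.integer(tbl$n_w)
  )
  if (anyDuplicated(out$well_id)) {
    stop("Plate layout well ids must be unique.", call. = FALSE)
  }
  if (any(out$n_b < 1, na.rm = TRUE) || any(out$n_w < 1, na.rm = TRUE)) {
    stop("Replicate counts must be >= 1.", call. = FALSE)
  }
  out
}

#' Quantize intensities to a 16-bit grid
#'
#' Images are written as 16-bit grayscale TIFF. Quantizing in memory before
#' any file round trip guarantees that load -> write -> load is bit-exact.
#' Intensities are clipped to `[0, 1]` first.
#'
#' @param x Numeric matrix or array.
#' @return The input snapped to multiples of `1/65535` in `[0, 1]`.
#' @export
quantize_16bit <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  round(x * 65535) / 65535
}

#' Write / read a multi-page 16-bit grayscale TIFF
#'
#' `write_stack_tiff()` writes a list of 2D matrices (or a 3D array sliced
#' along its first axis) as one multi-page TIFF. `read_stack_tiff()` reads all
#' pages back as a list of matrices.
#'
#' @param pages A list of numeric matrices in `[0, 1]`, or a 3D array
#'   `(page, y, x)`.
#' @param path Output file path.
#' @return `write_stack_tiff()`: the path, invisibly. `read_stack_tiff()`: a
#'   list of matrices.
#' @export
write_stack_tiff <- function(pages, path) {
  if (is.array(pages) && length(dim(pages)) == 3) {
    pages <- lapply(seq_len(dim(pages)[1]), function(i) pages[i, , ])
  }
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, quantize_16bit)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  if (!file.exists(path)) {
    stop("Cannot read TIFF: file not found: ", path, call. = FALSE)
  }
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE),
    error = function(e) stop("Unreadable TIFF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1] # tolerate RGB-expanded pages
    p
  })
}

#' Default file naming convention for well datasets
#'
#' One multi-page TIFF per field and channel, named
#' `"<well>_f<FF>_<channel>.tif"` (pages = z planes), plus an optional sidecar
#' `"<well>_meta.json"` holding `pixel_size` and `z_spacing`. The convention
#' is configurable because microscope export schemes vary.
#'
#' @param pattern `sprintf`-style pattern with `%s` (well), `%02d` (field
#'   index) and `%s` (channel).
#' @param n_fields Number of fields expected per well.
#' @param pixel_size_default Calibration used when the sidecar is absent.
#' @param z_spacing_default Axial spacing used when the sidecar is absent.
#' @return A naming-convention list.
#' @export
naming_convention <- function(pattern = "%s_f%02d_%s.tif",
                              n_fields = 16,
                              pixel_size_default = default_pixel_size(),
                              z_spacing_default = 1) {
  list(pattern = pattern, n_fields = n_fields,
       pixel_size_default = pixel_size_default,
       z_spacing_default = z_spacing_default)
}

#' Load one well's 5D dataset from disk
#'
#' Reads every field stack of a well (all channels), using the file naming
#' convention. Missing fields are reported in the returned object's
#' `missing_fields` record, never silently dropped. When no metadata sidecar
#' is present the default calibration of the convention is used and the
#' provenance is flagged in the `calibration_source` attribute.
#'
#' @param root_path Directory containing the TIFF files.
#' @param well_id Well to load.
#' @param channels Character vector of channel names to read.
#' @param convention A [naming_convention()] list.
#' @return A [well_dataset()].
#' @export
load_well_dataset <- function(root_path, well_id, channels,
                              convention = naming_convention()) {
  if (!dir.exists(root_path)) {
    stop("Dataset directory not found: ", root_path, call. = FALSE)
  }
  meta_path <- file.path(root_path, paste0(well_id, "_meta.json"))
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    pixel_size <- meta$pixel_size
    z_spacing <- meta$z_spacing
    calibration_source <- "metadata"
  } else {
    pixel_size <- convention$pixel_size_default
    z_spacing <- convention$z_spacing_default
    calibration_source <- "config-default"
  }
  fields <- list()
  missing <- character()
  for (f in seq_len(convention$n_fields)) {
    paths <- vapply(channels, function(ch)
      file.path(root_path, sprintf(convention$pattern, well_id, f, ch)),
      character(1))
    if (!any(file.exists(paths))) {
      missing <- c(missing, sprintf("field %02d", f))
      next
    }
    if (!all(file.exists(paths))) {
      stop("Field ", f, " of well ", well_id,
           " has an inconsistent channel set (missing: ",
           paste(channels[!file.exists(paths)], collapse = ", "), ").",
           call. = FALSE)
    }
    per_channel <- lapply(paths, read_stack_tiff)
    nz <- vapply(per_channel, length, integer(1))
    if (length(unique(nz)) != 1) {
      stop("Field ", f, " of well ", well_id,
           " has differing z-plane counts across channels.", call. = FALSE)
    }
    d <- dim(per_channel[[1]][[1]])
    vox <- array(0, dim = unname(c(nz[1], d[1], d[2], length(channels))))
    for (ci in seq_along(channels)) {
      for (zi in seq_len(nz[1])) {
        vox[zi, , , ci] <- per_channel[[ci]][[zi]]
      }
    }
    fields[[length(fields) + 1]] <- field_stack(
      vox, channel_names = channels,
      pixel_size = pixel_size, z_spacing = z_spacing
    )
  }
  if (!length(fields)) {
    stop("No fields found for well ", well_id, " in ", root_path, call. = FALSE)
  }
  if (length(missing)) {
    warning("Well ", well_id, ": expected ", convention$n_fields,
            " fields, missing ", length(missing), " (",
            paste(missing, collapse = ", "), ").", call. = FALSE)
  }
  wd <- well_dataset(well_id, fields, missing_fields = missing)
  attr(wd, "calibration_source") <- calibration_source
  wd
}

#' Write a well dataset to disk under the naming convention
#'
#' @param wd A [well_dataset()].
#' @param root_path Output directory (created if needed).
#' @param convention A [naming_convention()].
#' @return `root_path`, invisibly.
#' @export
write_well_dataset <- function(wd, root_path,
                               convention = naming_convention()) {
  dir.create(root_path, recursive = TRUE, showWarnings = FALSE)
  channels <- wd$fields[[1]]$channel_names
  for (f in seq_along(wd$fields)) {
    st <- wd$fields[[f]]
    for (ci in seq_along(channels)) {
      pages <- lapply(seq_len(dim(st$voxels)[1]),
                      function(zi) st$voxels[zi, , , ci])
      write_stack_tiff(
        pages,
        file.path(root_path,
                  sprintf(convention$pattern, wd$well_id, f, channels[ci]))
      )
    }
  }
  jsonlite::write_json(
    list(pixel_size = wd$fields[[1]]$pixel_size,
         z_spacing = wd$fields[[1]]$z_spacing),
    file.path(root_path, paste0(wd$well_id, "_meta.json")),
    auto_unbox = TRUE, digits = NA
  )
  invisible(root_path)
}

#' Maximum-intensity projection of one channel
#'
#' Each output pixel is the maximum of the voxel column over z. This is the
#' only projection offered; downstream analysis operates on projections.
#'
#' @param stack A [field_stack()].
#' @param channel Channel name to project.
#' @return A [field_image()] with the stack's calibration.
#' @export
max_project <- function(stack, channel) {
  stopifnot(inherits(stack, "field_stack"))
  ci <- match(channel, stack$channel_names)
  if (is.na(ci)) {
    stop("Unknown channel '", channel, "'. Available: ",
         paste(stack$channel_names, collapse = ", "), call. = FALSE)
  }
  vox <- stack$voxels[, , , ci, drop = FALSE]
  proj <- apply(vox[, , , 1, drop = FALSE], c(2, 3), max)
  field_image(proj, channel = channel, pixel_size = stack$pixel_size)
}
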