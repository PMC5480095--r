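# EB3 comet velocimetry: kymograph construction along a user polyline and
# velocity from track slope (manual endpoints, plus an automatic streak
# detector for batch validation).

bilinear_sample <- function(frame, x, y) {
  n <- nrow(frame); m <- ncol(frame)
  x <- pmin(pmax(x, 1), m); y <- pmin(pmax(y, 1), n)
  x0 <- pmin(floor(x), m - 1); y0 <- pmin(floor(y), n - 1)
  fx <- x - x0; fy <- y - y0
  frame[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    frame[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    frame[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    frame[cbind(y0 + 1, x0 + 1)] * fx * fy
}

resample_polyline <- function(polyline, step = 1) {
  seg <- sqrt(rowSums(diff(polyline)^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  s <- seq(0, total, by = step)
  i <- pmin(findInterval(s, arc, all.inside = TRUE), nrow(polyline) - 1)
  w <- (s - arc[i]) / pmax(arc[i + 1] - arc[i], 1e-12)
  pts <- polyline[i, , drop = FALSE] * (1 - w) +
    polyline[i + 1, , drop = FALSE] * w
  # unit tangents for perpendicular sampling
  tang <- rbind(pts[2, , drop = FALSE] - pts[1, , drop = FALSE],
                (pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]))
  tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
  list(points = pts, tangents = tang, length_px = total)
}

#' Kymograph container
#'
#' @param map Positions x frames intensity matrix.
#' @param pixel_size Pixel size along the path, um/px.
#' @param frame_interval_s Seconds between frames.
#' @param line_width_px Averaging width used at construction.
#' @return A `kymograph` object; warns when the path is shorter than the
#'   20 um segment criterion.
#' @export
kymograph <- function(map, pixel_size, frame_interval_s, line_width_px = 3) {
  stopifnot(is.matrix(map))
  check_pixel_size(pixel_size)
  path_length_um <- px_to_um(nrow(map), pixel_size)
  if (path_length_um < 20) {
    warning(sprintf("Path length %.1f um is below the 20 um segment criterion.",
                    path_length_um), call. = FALSE)
  }
  structure(
    list(map = map, pixel_size = pixel_size,
         frame_interval_s = frame_interval_s,
         path_length_um = path_length_um, line_width_px = line_width_px),
    class = "kymograph"
  )
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d positions x %d frames, %.1f um path\n",
              nrow(x$map), ncol(x$map), x$path_length_um))
  invisible(x)
}

#' Build a kymograph along a polyline
#'
#' The polyline is resampled at 1 px arclength steps; each kymograph pixel is
#' the mean of `width_px` bilinear samples taken perpendicular to the path at
#' that position, per frame (rows = positions, columns = frames).
#'
#' @param movie 3D array `(y, x, frame)`.
#' @param polyline Matrix of ordered `(x, y)` pixel coordinates (>= 2 rows).
#' @param width_px Averaging width perpendicular to the path (default 3).
#' @param pixel_size Pixel size um/px.
#' @param frame_interval_s Seconds per frame.
#' @return A [kymograph()].
#' @export
build_kymograph <- function(movie, polyline, width_px = 3,
                            pixel_size = default_pixel_size(),
                            frame_interval_s = 2) {
  d <- dim(movie)
  if (length(d) != 3) stop("`movie` must be (y, x, frame).", call. = FALSE)
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2) stop("Polyline needs >= 2 points.", call. = FALSE)
  if (any(polyline[, 1] < 1) || any(polyline[, 1] > d[2]) ||
      any(polyline[, 2] < 1) || any(polyline[, 2] > d[1])) {
    stop("Polyline lies outside the movie bounds.", call. = FALSE)
  }
  rp <- resample_polyline(polyline)
  offs <- seq_len(width_px) - (width_px + 1) / 2
  normals <- cbind(-rp$tangents[, 2], rp$tangents[, 1])
  map <- matrix(0, nrow(rp$points), d[3])
  for (fr in seq_len(d[3])) {
    frame <- movie[, , fr]
    acc <- 0
    for (o in offs) {
      xs <- rp$points[, 1] + o * normals[, 1]
      ys <- rp$points[, 2] + o * normals[, 2]
      acc <- acc + bilinear_sample(frame, xs, ys)
    }
    map[, fr] <- acc / width_px
  }
  kymograph(map, pixel_size, frame_interval_s, width_px)
}

#' Comet velocity from kymograph tracks
#'
#' Manual mode reproduces the classic workflow: the user supplies the two
#' endpoints of a streak and the velocity follows from the slope,
#' `|delta position| * pixel_size / (delta frame * frame_interval)`.
#' Automatic mode (an extension for batch validation) thresholds the
#' kymograph (Triangle), labels streaks, and fits a line through each
#' streak's per-frame intensity-weighted centroid.
#'
#' @param kym A [kymograph()].
#' @param track Either a 2 x 2 matrix `rbind(c(position_px, frame), ...)` for
#'   manual mode, or `"auto"`.
#' @param min_track_px Minimum pixel count of an automatic streak
#'   (default 10).
#' @param min_span_frames Minimum frame span of an automatic streak
#'   (default 3).
#' @return Tibble (class `comet_tracks`): one row per track with
#'   `track`, `velocity_um_s`, `n_px`, `frame_span`; attribute
#'   `mean_velocity_um_s`.
#' @export
measure_velocity <- function(kym, track = "auto", min_track_px = 10,
                             min_span_frames = 3) {
  stopifnot(inherits(kym, "kymograph"))
  if (is.matrix(track)) {
    dpos <- abs(track[2, 1] - track[1, 1])
    dframe <- abs(track[2, 2] - track[1, 2])
    if (dframe < 1) stop("Track endpoints must span >= 1 frame.", call. = FALSE)
    v <- px_to_um(dpos, kym$pixel_size) / (dframe * kym$frame_interval_s)
    out <- tibble::tibble(track = 1L, velocity_um_s = v,
                          n_px = NA_integer_,
                          frame_span = as.integer(dframe))
    attr(out, "mean_velocity_um_s") <- v
    class(out) <- c("comet_tracks", class(out))
    return(out)
  }
  if (!identical(track, "auto")) {
    stop("`track` must be a 2x2 endpoint matrix or \"auto\".", call. = FALSE)
  }
  m <- kym$map
  if (diff(range(m)) <= 0) {
    stop("Kymograph is constant; no detectable streak.", call. = FALSE)
  }
  mask <- m > auto_threshold(m, "triangle")
  lm <- label_components(mask, kym$pixel_size)
  lab <- lm$labels
  ids <- seq_len(n_objects(lm))
  rows <- list()
  for (id in ids) {
    sel <- which(lab == id, arr.ind = TRUE)
    if (nrow(sel) < min_track_px) next
    frames <- sort(unique(sel[, 2]))
    if (length(frames) < min_span_frames) next
    cent <- vapply(frames, function(fr) {
      p <- sel[sel[, 2] == fr, 1]
      w <- m[cbind(p, rep(fr, length(p)))]
      sum(p * w) / sum(w)
    }, numeric(1))
    fit <- stats::lm.fit(cbind(1, frames), cent)
    slope <- abs(fit$coefficients[2]) # px / frame
    rows[[length(rows) + 1]] <- tibble::tibble(
      track = id,
      velocity_um_s = px_to_um(slope, kym$pixel_size) / kym$frame_interval_s,
      n_px = nrow(sel),
      frame_span = as.integer(diff(range(frames)) + 1)
    )
  }
  if (!length(rows)) {
    stop("No streak satisfied the detection criteria.", call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  out$track <- seq_len(nrow(out))
  attr(out, "mean_velocity_um_s") <- mean(out$velocity_um_s)
  class(out) <- c("comet_tracks", class(out))
  out
}
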