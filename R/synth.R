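# Synthetic-data generators. Every input the pipeline consumes can be
# rendered with known ground truth: nuclei/PI fields, neurite + synapse +
# acetylation channels with tunable colocalization, fibril fields, bursting
# calcium recordings with a terminal glutamate epoch, and EB3 comet movies.
# Identical parameters and seed give bit-identical outputs.

with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("`seed` must be a single integer.", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop("`", name, "` must be a single value in [0, 1].", call. = FALSE)
  }
  x
}

# Stamp a filled ellipse (axes a, b px, rotation theta) into a logical matrix.
stamp_ellipse <- function(mask, cx, cy, a, b, theta = 0) {
  n <- nrow(mask); m <- ncol(mask)
  r <- ceiling(max(a, b)) + 1
  ys <- max(1, floor(cy - r)):min(n, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(m, ceiling(cx + r))
  if (!length(ys) || !length(xs)) return(mask)
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  hit <- (u / a)^2 + (v / b)^2 <= 1
  mask[ys, xs] <- mask[ys, xs] | hit
  mask
}

stamp_disc <- function(mask, cx, cy, r) stamp_ellipse(mask, cx, cy, r, r, 0)

# Gaussian read noise plus Poisson-like shot noise; clipped and snapped to
# the 16-bit grid so file round trips are exact.
apply_noise <- function(px, noise_sd, photons = 400) {
  if (is.finite(photons) && photons > 0) {
    px <- matrix(stats::rpois(length(px), pmax(px, 0) * photons) / photons,
                 nrow(px), ncol(px))
  }
  if (noise_sd > 0) {
    px <- px + matrix(stats::rnorm(length(px), 0, noise_sd), nrow(px), ncol(px))
  }
  quantize_16bit(px)
}

#' Synthetic nuclei + propidium-iodide field
#'
#' Renders `n_cells` smoothed elliptical nuclei with Poisson-like shot noise
#' and Gaussian read noise. Exactly `round(dead_fraction * n_cells)` nuclei
#' carry a high PI signal. With `crowding > 0`, a corresponding fraction of
#' nuclei is placed as touching pairs (watershed test cases).
#'
#' @param n_cells Number of nuclei (>= 0).
#' @param dead_fraction Fraction of PI-positive nuclei in `[0, 1]`.
#' @param mean_area_um2 Mean nucleus area (default 140 um^2, comfortably
#'   above the 90 um^2 debris cut).
#' @param crowding Fraction of nuclei placed in touching pairs, `[0, 1]`.
#' @param seed Random seed (determinism contract).
#' @param size_px Field edge length in pixels (default 1024).
#' @param pixel_size Pixel size um/px.
#' @param noise_sd Gaussian read-noise SD; set 0 (with `photons = Inf`) for a
#'   noiseless render.
#' @param photons Photon scale of the shot noise; `Inf` disables it.
#' @return List: `nuclei` and `pi` ([field_image()]s) and `truth` (list with
#'   a per-nucleus tibble `nuclei` (`id, x, y, area_um2, is_dead`), `seed`,
#'   and the noiseless label ground truth `labels`).
#' @export
synth_nuclei_field <- function(n_cells, dead_fraction = 0,
                               mean_area_um2 = 140, crowding = 0, seed = 1,
                               size_px = 1024,
                               pixel_size = default_pixel_size(),
                               noise_sd = 0.01, photons = 400) {
  stopifnot(n_cells >= 0)
  check_fraction(dead_fraction, "dead_fraction")
  check_fraction(crowding, "crowding")
  with_seed(seed, {
    rbar <- um_to_px(sqrt(mean_area_um2 / pi), pixel_size)
    margin <- 2.5 * rbar
    n_pairs <- floor(round(crowding * n_cells) / 2)
    centers <- matrix(numeric(0), ncol = 2)
    place <- function(min_sep, near = NULL) {
      for (try in 1:400) {
        if (is.null(near)) {
          p <- stats::runif(2, margin, size_px - margin)
        } else {
          ang <- stats::runif(1, 0, 2 * pi)
          p <- near + 1.7 * rbar * c(cos(ang), sin(ang))
        }
        if (any(p < margin / 2) || any(p > size_px - margin / 2)) next
        if (!nrow(centers) ||
            min(sqrt(rowSums((centers - matrix(p, nrow(centers), 2,
                                               byrow = TRUE))^2))) >= min_sep) {
          return(p)
        }
      }
      p
    }
    ids <- seq_len(n_cells)
    pts <- matrix(0, n_cells, 2)
    i <- 1
    pair_left <- n_pairs
    while (i <= n_cells) {
      if (pair_left > 0 && i < n_cells) {
        p1 <- place(3.2 * rbar)
        centers <- rbind(centers, p1)
        p2 <- place(0, near = p1)
        centers <- rbind(centers, p2)
        pts[i, ] <- p1; pts[i + 1, ] <- p2
        i <- i + 2
        pair_left <- pair_left - 1
      } else {
        p <- place(2.6 * rbar)
        centers <- rbind(centers, p)
        pts[i, ] <- p
        i <- i + 1
      }
    }
    dead <- rep(FALSE, n_cells)
    if (n_cells > 0) {
      dead[sample.int(n_cells, round(dead_fraction * n_cells))] <- TRUE
    }
    labels <- matrix(0L, size_px, size_px)
    areas <- numeric(n_cells)
    for (j in ids) {
      area <- max(0.5 * mean_area_um2,
                  stats::rnorm(1, mean_area_um2, 0.12 * mean_area_um2))
      r <- um_to_px(sqrt(area / pi), pixel_size)
      ecc <- stats::runif(1, 0.9, 1.15)
      th <- stats::runif(1, 0, pi)
      obj <- stamp_ellipse(matrix(FALSE, size_px, size_px),
                           pts[j, 1], pts[j, 2], r * ecc, r / ecc, th)
      areas[j] <- px_area_to_um2(sum(obj), pixel_size)
      labels[obj] <- j
    }
    nuc <- matrix(0.0, size_px, size_px)
    int_per <- stats::rnorm(n_cells, 0.7, 0.05)
    for (j in ids) nuc[labels == j] <- int_per[j]
    nuc <- gaussian_blur(nuc, 1) + 0.02
    pi_img <- matrix(0.0, size_px, size_px)
    for (j in ids[dead]) pi_img[labels == j] <- 0.8
    pi_img <- gaussian_blur(pi_img, 1) + 0.02
    truth <- list(
      seed = seed,
      nuclei = tibble::tibble(id = ids, x = pts[, 1], y = pts[, 2],
                              area_um2 = areas, is_dead = dead),
      labels = labels,
      n_dead = sum(dead)
    )
    list(
      nuclei = field_image(apply_noise(nuc, noise_sd, photons),
                           "nuclei", pixel_size),
      pi = field_image(apply_noise(pi_img, noise_sd, photons),
                       "pi", pixel_size),
      truth = truth
    )
  })
}

random_walk_path <- function(size_px, n_steps, step = 2, wiggle = 0.18,
                             margin = 10) {
  p <- stats::runif(2, margin, size_px - margin)
  dir <- stats::runif(1, 0, 2 * pi)
  out <- matrix(0, n_steps, 2)
  for (i in seq_len(n_steps)) {
    dir <- dir + stats::rnorm(1, 0, wiggle)
    p2 <- p + step * c(cos(dir), sin(dir))
    if (p2[1] < margin || p2[1] > size_px - margin) dir <- pi - dir
    if (p2[2] < margin || p2[2] > size_px - margin) dir <- -dir
    p <- p + step * c(cos(dir), sin(dir))
    p <- pmin(pmax(p, margin / 2), size_px - margin / 2)
    out[i, ] <- p
  }
  out
}

#' Synthetic neurite field with co-varying acetylation and synapse channels
#'
#' Neurites are rendered as random-walk tubes in two intensity tiers: bright
#' trunks and faint fine branches (exercising the dual-mask segmentation).
#' The "acetylated" channel is constructed inside the true neurite mask as a
#' mixture of the rendered tubulin channel and independent noise calibrated
#' so the within-mask sample Pearson correlation approaches `coloc_rho`.
#' Synaptic puncta are placed on the mask at the requested density.
#'
#' @param total_neurite_length_um Total drawn path length (default 2000 um).
#' @param synapse_density_true Planted puncta density, spots/um^2 of neurite
#'   mask area.
#' @param coloc_rho Target within-mask Pearson correlation, `[-1, 1]`.
#' @param seed Random seed.
#' @param size_px Field edge length (default 1024).
#' @param pixel_size Pixel size um/px.
#' @param trunk_frac Fraction of path length drawn as bright trunk.
#' @param trunk_width_px,branch_width_px Tube widths (bright / faint tier).
#' @param spot_area_um2 Planted puncta area (default 1.5 um^2).
#' @param noise_sd Read-noise SD.
#' @return List: `tubulin`, `acetylated`, `synaptophysin` ([field_image()]s)
#'   and `truth` (neurite mask, tier masks, spot table, planted density and
#'   correlation).
#' @export
synth_neurite_field <- function(total_neurite_length_um = 2000,
                                synapse_density_true = 0.05,
                                coloc_rho = 0.9, seed = 1, size_px = 1024,
                                pixel_size = default_pixel_size(),
                                trunk_frac = 0.6, trunk_width_px = 4,
                                branch_width_px = 2, spot_area_um2 = 1.5,
                                noise_sd = 0.015) {
  stopifnot(synapse_density_true >= 0, total_neurite_length_um >= 0)
  if (coloc_rho < -1 || coloc_rho > 1) {
    stop("`coloc_rho` must be in [-1, 1].", call. = FALSE)
  }
  with_seed(seed, {
    step <- 2
    total_px <- um_to_px(total_neurite_length_um, pixel_size)
    draw_tier <- function(target_px, width_px) {
      tier <- matrix(FALSE, size_px, size_px)
      drawn <- 0
      while (drawn < target_px) {
        len <- min(stats::runif(1, 150, 400), (target_px - drawn) / step * step)
        n_steps <- max(2, round(len / step))
        path <- random_walk_path(size_px, n_steps, step = step)
        for (i in seq_len(nrow(path))) {
          tier <- stamp_disc(tier, path[i, 1], path[i, 2], width_px / 2)
        }
        drawn <- drawn + n_steps * step
      }
      tier
    }
    trunk <- draw_tier(total_px * trunk_frac, trunk_width_px)
    branch <- draw_tier(total_px * (1 - trunk_frac), branch_width_px)
    mask <- trunk | branch
    tub <- matrix(0, size_px, size_px)
    tub[branch] <- 0.22
    tub[trunk] <- 0.75
    tub <- gaussian_blur(tub, 0.8) + 0.03
    tub <- apply_noise(tub, noise_sd)
    # acetylated channel: mixture of the final tubulin image and independent
    # noise, standardized within the truth mask so the sample correlation
    # there approaches coloc_rho
    z <- tub[mask]
    z <- (z - mean(z)) / stats::sd(z)
    eps <- stats::rnorm(length(z))
    mix <- coloc_rho * z + sqrt(1 - coloc_rho^2) * eps
    acet <- matrix(0, size_px, size_px)
    acet[!mask] <- 0.03 + stats::rnorm(sum(!mask), 0, noise_sd)
    acet[mask] <- 0.45 + 0.1 * mix
    acet <- quantize_16bit(acet)
    mask_area_um2 <- px_area_to_um2(sum(mask), pixel_size)
    n_spots <- round(synapse_density_true * mask_area_um2)
    spot_r <- um_to_px(sqrt(spot_area_um2 / pi), pixel_size)
    idx <- which(mask, arr.ind = TRUE)
    placed <- matrix(numeric(0), ncol = 2)
    syn <- matrix(0, size_px, size_px)
    min_sep <- 5 * spot_r
    for (s in seq_len(n_spots)) {
      for (try in 1:200) {
        cand <- idx[sample.int(nrow(idx), 1), ]
        pt <- c(cand[2], cand[1]) # (x, y)
        ok <- !nrow(placed) ||
          min(sqrt(rowSums((placed - matrix(pt, nrow(placed), 2,
                                            byrow = TRUE))^2))) >= min_sep
        if (ok || try == 200) {
          placed <- rbind(placed, pt)
          syn <- stamp_disc(syn > 0, pt[1], pt[2], spot_r) * 0.8
          break
        }
      }
    }
    syn <- matrix(as.numeric(syn), size_px, size_px)
    syn <- gaussian_blur(syn, 0.6) + 0.02
    syn <- apply_noise(syn, noise_sd)
    truth <- list(
      seed = seed, mask = mask, trunk = trunk, branch = branch,
      mask_area_um2 = mask_area_um2,
      spots = if (nrow(placed)) {
        tibble::tibble(x = placed[, 1], y = placed[, 2])
      } else tibble::tibble(x = numeric(), y = numeric()),
      n_spots = nrow(placed),
      synapse_density_true = synapse_density_true,
      coloc_rho = coloc_rho
    )
    list(
      tubulin = field_image(tub, "tubulin", pixel_size),
      acetylated = field_image(acet, "acetylated", pixel_size),
      synaptophysin = field_image(syn, "synaptophysin", pixel_size),
      truth = truth
    )
  })
}

#' Synthetic fibrillar-Tau field
#'
#' Fibrils are curved rods (area >= 15 um^2 and circularity < 0.30 by
#' construction); round blobs with circularity > 0.6 serve as negative
#' controls for the shape filter. Truth lists each particle's rendered area
#' and circularity.
#'
#' @param n_fibrils Number of rods.
#' @param n_round_blobs Number of compact discs.
#' @param seed Random seed.
#' @param size_px Field edge length (default 1024).
#' @param pixel_size Pixel size um/px.
#' @param rod_width_um Rod stroke width (default 2 um).
#' @param rod_length_um Range of rod lengths (default 25-45 um).
#' @param disc_radius_um Blob radius (default 2.8 um).
#' @param noise_sd Read-noise SD.
#' @return List: `pftaa` ([field_image()]), `mask` (rod-pixel truth), and
#'   `truth` (per-particle tibble with `type`, `area_um2`, `circularity`).
#' @export
synth_fibril_field <- function(n_fibrils, n_round_blobs = 0, seed = 1,
                               size_px = 1024,
                               pixel_size = default_pixel_size(),
                               rod_width_um = 2,
                               rod_length_um = c(25, 45),
                               disc_radius_um = 2.8, noise_sd = 0.015) {
  stopifnot(n_fibrils >= 0, n_round_blobs >= 0)
  with_seed(seed, {
    w_px <- um_to_px(rod_width_um, pixel_size)
    occupied <- matrix(FALSE, size_px, size_px)
    particles <- list()
    stamp_rod <- function() {
      for (try in 1:80) {
        len_px <- um_to_px(stats::runif(1, rod_length_um[1], rod_length_um[2]),
                           pixel_size)
        n_steps <- max(3, round(len_px))
        margin <- 20
        p <- stats::runif(2, margin, size_px - margin)
        dir <- stats::runif(1, 0, 2 * pi)
        kappa <- stats::runif(1, -0.02, 0.02)
        obj <- matrix(FALSE, size_px, size_px)
        ok <- TRUE
        for (i in seq_len(n_steps)) {
          dir <- dir + kappa
          p <- p + c(cos(dir), sin(dir))
          if (any(p < 5) || any(p > size_px - 5)) { ok <- FALSE; break }
          obj <- stamp_disc(obj, p[1], p[2], w_px / 2)
        }
        if (!ok) next
        grown <- eb_mat(EBImage::dilate(obj * 1,
                                        EBImage::makeBrush(31, "disc"))) > 0
        if (any(grown & occupied)) next
        circ <- min(1, 4 * pi * sum(obj) / perimeter_px(obj)^2)
        if (circ >= 0.30) next
        return(list(obj = obj, circ = circ))
      }
      NULL
    }
    stamp_blob <- function() {
      r_px <- um_to_px(disc_radius_um, pixel_size)
      for (try in 1:80) {
        p <- stats::runif(2, 20, size_px - 20)
        obj <- stamp_disc(matrix(FALSE, size_px, size_px), p[1], p[2], r_px)
        grown <- eb_mat(EBImage::dilate(obj * 1,
                                        EBImage::makeBrush(31, "disc"))) > 0
        if (any(grown & occupied)) next
        circ <- min(1, 4 * pi * sum(obj) / perimeter_px(obj)^2)
        if (circ <= 0.6) next
        return(list(obj = obj, circ = circ))
      }
      NULL
    }
    img <- matrix(0, size_px, size_px)
    rod_mask <- matrix(FALSE, size_px, size_px)
    for (i in seq_len(n_fibrils)) {
      s <- stamp_rod()
      if (is.null(s)) next
      occupied <- occupied | s$obj
      rod_mask <- rod_mask | s$obj
      img[s$obj] <- stats::runif(1, 0.7, 0.85)
      pos <- which(s$obj, arr.ind = TRUE)
      particles[[length(particles) + 1]] <- tibble::tibble(
        type = "fibril", area_um2 = px_area_to_um2(sum(s$obj), pixel_size),
        circularity = s$circ, x = mean(pos[, 2]), y = mean(pos[, 1])
      )
    }
    for (i in seq_len(n_round_blobs)) {
      s <- stamp_blob()
      if (is.null(s)) next
      occupied <- occupied | s$obj
      img[s$obj] <- stats::runif(1, 0.7, 0.85)
      pos <- which(s$obj, arr.ind = TRUE)
      particles[[length(particles) + 1]] <- tibble::tibble(
        type = "blob", area_um2 = px_area_to_um2(sum(s$obj), pixel_size),
        circularity = s$circ, x = mean(pos[, 2]), y = mean(pos[, 1])
      )
    }
    img <- gaussian_blur(img, 0.7) + 0.02
    truth_tbl <- if (length(particles)) {
      dplyr::bind_rows(particles)
    } else {
      tibble::tibble(type = character(), area_um2 = numeric(),
                     circularity = numeric(), x = numeric(), y = numeric())
    }
    list(
      pftaa = field_image(apply_noise(img, noise_sd), "pftaa", pixel_size),
      mask = rod_mask,
      truth = list(seed = seed, particles = truth_tbl,
                   fibril_area_um2 = sum(truth_tbl$area_um2[
                     truth_tbl$type == "fibril"]))
    )
  })
}

#' Synthetic bursting calcium recording
#'
#' Population burst times are drawn as a Poisson process; each active neuron
#' joins each burst with probability `sync_prob`. Transients have an
#' instantaneous rise and exponential decay (`tau_s`). All neurons - and only
#' neurons - receive a sustained response during the terminal glutamate
#' window; non-neuronal cells stay flat apart from noise.
#'
#' @param n_cells Number of cells.
#' @param neuron_fraction,active_fraction Fractions in `[0, 1]`.
#' @param burst_rate_per_min Poisson rate of population bursts.
#' @param sync_prob Per-burst participation probability of an active neuron.
#' @param duration_s Recording length (default 260 s).
#' @param fps Frame rate (default 2 Hz).
#' @param glut_window_s Terminal stimulation window (default 20 s).
#' @param noise_sd Additive noise SD on the fluorescence traces.
#' @param seed Random seed.
#' @param amplitude Mean transient amplitude in dF/F0 units (default 0.5).
#' @param tau_s Transient decay constant (default 1.5 s).
#' @param glut_factor Glutamate step height as a multiple of `amplitude`.
#' @return List: `recording` (a [calcium_recording()]) and `truth`
#'   (per-cell tibble `cells` with `is_neuron`, `is_active`, `n_events`;
#'   `burst_times_s`; per-cell event times `events`).
#' @export
synth_calcium_recording <- function(n_cells = 50, neuron_fraction = 0.8,
                                    active_fraction = 0.6,
                                    burst_rate_per_min = 3, sync_prob = 0.9,
                                    duration_s = 260, fps = 2,
                                    glut_window_s = 20, noise_sd = 0.03,
                                    seed = 1, amplitude = 0.5, tau_s = 1.5,
                                    glut_factor = 3) {
  check_fraction(neuron_fraction, "neuron_fraction")
  check_fraction(active_fraction, "active_fraction")
  check_fraction(sync_prob, "sync_prob")
  n_frames <- round(duration_s * fps)
  if (n_frames < 10) stop("Recording must span >= 10 frames.", call. = FALSE)
  with_seed(seed, {
    stim_start <- n_frames - round(glut_window_s * fps) + 1L
    stim_window <- c(stim_start, n_frames)
    t_s <- (seq_len(n_frames) - 1) / fps
    spont_T <- duration_s - glut_window_s
    neurons <- sort(sample.int(n_cells, round(neuron_fraction * n_cells)))
    is_neuron <- seq_len(n_cells) %in% neurons
    n_active <- round(active_fraction * length(neurons))
    active <- sort(sample(neurons, n_active))
    is_active <- seq_len(n_cells) %in% active
    n_bursts <- stats::rpois(1, burst_rate_per_min * spont_T / 60)
    burst_times <- sort(stats::runif(n_bursts, 2, max(2.5, spont_T - 4)))
    events <- vector("list", n_cells)
    dff <- matrix(0, n_cells, n_frames)
    for (ci in active) {
      join <- stats::runif(length(burst_times)) < sync_prob
      te <- burst_times[join] + abs(stats::rnorm(sum(join), 0, 0.1))
      events[[ci]] <- te
      for (tt in te) {
        amp <- max(0.1, stats::rnorm(1, amplitude, 0.1 * amplitude))
        on <- t_s >= tt
        dff[ci, on] <- dff[ci, on] + amp * exp(-(t_s[on] - tt) / tau_s)
      }
    }
    for (ci in neurons) {
      dff[ci, stim_start:n_frames] <- dff[ci, stim_start:n_frames] +
        glut_factor * amplitude
    }
    f0 <- stats::runif(n_cells, 0.8, 1.2)
    traces <- f0 * (1 + dff) +
      matrix(stats::rnorm(n_cells * n_frames, 0, noise_sd), n_cells, n_frames)
    rec <- calcium_recording(traces, fps = fps, duration_s = duration_s,
                             stim_window = stim_window)
    truth <- list(
      seed = seed,
      cells = tibble::tibble(
        cell = seq_len(n_cells), is_neuron = is_neuron, is_active = is_active,
        n_events = vapply(events, length, integer(1))
      ),
      burst_times_s = burst_times,
      events = events,
      sync_prob = sync_prob,
      burst_rate_per_min = burst_rate_per_min
    )
    list(recording = rec, truth = truth)
  })
}

#' Synthetic EB3 comet movie
#'
#' Bright Gaussian comets advance along a gently curved polyline at constant
#' velocity with staggered starts.
#'
#' @param n_comets Number of comets.
#' @param velocity_um_s Comet velocity (>= 0).
#' @param path_length_um Polyline length (default 25 um; the kymograph module
#'   warns below 20 um).
#' @param frame_interval_s Seconds between frames (default 2).
#' @param n_frames Number of frames (default 31, i.e. one minute).
#' @param seed Random seed.
#' @param pixel_size Pixel size um/px (default 0.25, high-magnification
#'   regime).
#' @param movie_px Movie edge length (default 128).
#' @param noise_sd Read-noise SD.
#' @return List: `movie` (array `y` x `x` x `frame`), `polyline` (matrix of
#'   `(x, y)` px), `pixel_size`, `frame_interval_s`, `truth` (per-comet
#'   velocities and start offsets).
#' @export
synth_comet_movie <- function(n_comets = 10, velocity_um_s = 0.2,
                              path_length_um = 25, frame_interval_s = 2,
                              n_frames = 31, seed = 1, pixel_size = 0.25,
                              movie_px = 128, noise_sd = 0.02) {
  if (velocity_um_s < 0) stop("`velocity_um_s` must be >= 0.", call. = FALSE)
  with_seed(seed, {
    len_px <- um_to_px(path_length_um, pixel_size)
    # gently curved path from one margin toward the opposite corner
    tpar <- seq(0, 1, length.out = 400)
    amp <- stats::runif(1, 5, 12)
    start <- c(12, stats::runif(1, 30, movie_px - 30))
    dir <- c(1, stats::runif(1, -0.3, 0.3))
    dir <- dir / sqrt(sum(dir^2))
    nrm <- c(-dir[2], dir[1])
    raw <- cbind(start[1] + tpar * (movie_px - 24) * dir[1] +
                   amp * sin(pi * tpar) * nrm[1],
                 start[2] + tpar * (movie_px - 24) * dir[2] +
                   amp * sin(pi * tpar) * nrm[2])
    seg <- sqrt(rowSums(diff(raw)^2))
    arc <- c(0, cumsum(seg))
    keep <- arc <= len_px
    poly <- raw[keep, , drop = FALSE]
    arc <- arc[keep]
    pos_at <- function(s) {
      s <- min(max(s, 0), arc[length(arc)])
      i <- findInterval(s, arc, all.inside = TRUE)
      w <- (s - arc[i]) / max(arc[i + 1] - arc[i], 1e-9)
      poly[i, ] * (1 - w) + poly[i + 1, ] * w
    }
    v_px_frame <- um_to_px(velocity_um_s, pixel_size) * frame_interval_s
    f0 <- sample.int(max(1, floor(n_frames / 3)), n_comets, replace = TRUE) - 1
    s0 <- stats::runif(n_comets, 0, max(1, arc[length(arc)] * 0.35))
    movie <- array(0, dim = c(movie_px, movie_px, n_frames))
    sig <- 1.2
    for (fr in seq_len(n_frames)) {
      frame <- matrix(0, movie_px, movie_px)
      for (ci in seq_len(n_comets)) {
        if (fr - 1 < f0[ci]) next
        s <- s0[ci] + v_px_frame * (fr - 1 - f0[ci])
        if (s > arc[length(arc)]) next
        p <- pos_at(s)
        xs <- max(1, floor(p[1] - 4)):min(movie_px, ceiling(p[1] + 4))
        ys <- max(1, floor(p[2] - 4)):min(movie_px, ceiling(p[2] + 4))
        g <- 0.9 * exp(-(outer((ys - p[2])^2, (xs - p[1])^2, "+")) /
                         (2 * sig^2))
        frame[ys, xs] <- pmax(frame[ys, xs], g)
      }
      movie[, , fr] <- apply_noise(frame + 0.02, noise_sd)
    }
    list(
      movie = movie,
      polyline = poly,
      pixel_size = pixel_size,
      frame_interval_s = frame_interval_s,
      truth = list(seed = seed,
                   velocities_um_s = rep(velocity_um_s, n_comets),
                   start_frame = f0, start_offset_px = s0,
                   path_length_um = px_to_um(arc[length(arc)], pixel_size))
    )
  })
}
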