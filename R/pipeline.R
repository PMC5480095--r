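# End-to-end workflow wiring: synthetic plate -> per-field analysis ->
# per-well aggregation -> group statistics, with a serialized configuration
# and a manifest so every numeric output is traceable to config + seed.

`%||%` <- rlang::`%||%`

#' Build a pipeline run configuration
#'
#' The configuration fully determines a run: plate layout, per-treatment
#' generator conditions, every analysis parameter, field geometry and the
#' master seed. It is serialized (YAML) into the output directory so results
#' are reproducible from the record alone.
#'
#' @param out_dir Output directory.
#' @param seed Master seed; all per-field seeds derive from it.
#' @param layout Plate-layout tibble as from [read_plate_layout()]. Default:
#'   two treatments x 4 wells.
#' @param conditions Named list (by treatment) of generator settings; each
#'   entry may set `dead_fraction`, `synapse_density`, `coloc_rho`,
#'   `active_fraction`, `sync_prob`, `burst_rate_per_min`, `n_fibrils`,
#'   `comet_velocity_um_s`.
#' @param n_fields Fields per well (default 8).
#' @param field_px Field edge length in px used by the generators.
#' @param n_cells_per_field Nuclei per cytotoxicity field.
#' @param control Control treatment label (for the Steel post-hoc).
#' @param params Overrides for analysis parameters (see defaults in the
#'   returned object).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1, layout = NULL, conditions = NULL,
                       n_fields = 8, field_px = 256, n_cells_per_field = 8,
                       control = NULL, params = list()) {
  if (is.null(layout)) {
    layout <- tibble::tibble(
      well_id = sprintf("%s%02d", rep(c("A", "B"), each = 4), rep(1:4, 2)),
      treatment = rep(c("control", "treated"), each = 4),
      dose = rep(c(0, 1), each = 4),
      n_b = 1L, n_w = rep(1:4, 2)
    )
  }
  if (is.null(conditions)) {
    conditions <- list(
      control = list(dead_fraction = 0.05, synapse_density = 0.05,
                     coloc_rho = 0.9, active_fraction = 0.6,
                     sync_prob = 0.9, burst_rate_per_min = 3, n_fibrils = 0,
                     comet_velocity_um_s = 0.2),
      treated = list(dead_fraction = 0.3, synapse_density = 0.02,
                     coloc_rho = 0.5, active_fraction = 0.3,
                     sync_prob = 0.5, burst_rate_per_min = 1.5, n_fibrils = 6,
                     comet_velocity_um_s = 0.2)
    )
  }
  missing_cond <- setdiff(unique(layout$treatment), names(conditions))
  if (length(missing_cond)) {
    stop("No generator conditions for treatment(s): ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  defaults <- list(
    pixel_size = default_pixel_size(),
    nucleus_threshold = 0.1, pi_threshold = 0.3,
    min_nucleus_area_um2 = 90, blur_radius_um = 1.75,
    ball_radius_px = 25,
    clahe_block_um = 1.8, clahe_slope = 3,
    laplace_scale_um = 0.35, min_spot_area_um2 = 0.75,
    tubeness_sigma = 3, min_fibril_area_um2 = 15, circ_max = 0.30,
    response_factor = 5, baseline_percentile = 10, k_mad = 5,
    min_prominence = 0.05, bin_s = 1, participation_frac = 0.5,
    n_cells_calcium = 50, neuron_fraction = 0.8,
    n_comets = 10, steel_n_perm = 10000, alpha = 0.05
  )
  params <- utils::modifyList(defaults, params)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), layout = layout,
         conditions = conditions, n_fields = as.integer(n_fields),
         field_px = as.integer(field_px),
         n_cells_per_field = as.integer(n_cells_per_field),
         control = control %||% layout$treatment[1], params = params),
    class = "run_config"
  )
}

field_seed <- function(config, well_idx, field, stage_offset) {
  base <- (as.numeric(config$seed) * 97 + stage_offset) * 1e5 +
    well_idx * 257 + field
  as.integer(base %% .Machine$integer.max)
}

stage_names <- function() {
  c("synth", "cytotox", "neurite", "synapse", "coloc", "fibril",
    "calcium", "kymo", "stats")
}

#' Run the full analysis pipeline on a synthetic plate
#'
#' Runs the selected stages in dependency order: the synthetic generators
#' produce each well's raw data under the per-treatment conditions of the
#' configuration, the per-field analyses extract the morphology, calcium and
#' velocimetry readouts, fields are averaged per well, and the group
#' statistics layer compares treatments. Outputs: one per-field CSV per
#' metric family, a per-well summary CSV, a statistics CSV and a
#' machine-readable manifest (config hash, seed, package version). Reruns
#' with the same configuration and seed are bit-identical.
#'
#' @param config A [run_config()].
#' @param stages Subset of
#'   `c("synth", "cytotox", "neurite", "synapse", "coloc", "fibril",
#'   "calcium", "kymo", "stats")`. `"all"` selects everything. Analysis
#'   stages need `synth`; `stats` needs at least one analysis stage; the
#'   plan is validated before any work.
#' @return Invisibly, a list with the per-field table, the well summary and
#'   the statistics table (also written under `config$out_dir`).
#' @export
run_pipeline <- function(config, stages = "all") {
  stopifnot(inherits(config, "run_config"))
  if (identical(stages, "all")) stages <- stage_names()
  unknown <- setdiff(stages, stage_names())
  if (length(unknown)) {
    stop("Unknown stage(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  analysis <- setdiff(stages, c("synth", "stats"))
  # plan validation happens before any computation
  if (length(analysis) && !"synth" %in% stages) {
    stop("Plan error: analysis stage(s) ", paste(analysis, collapse = ", "),
         " require the 'synth' stage.", call. = FALSE)
  }
  if ("stats" %in% stages && !length(analysis)) {
    stop("Plan error: 'stats' requires at least one analysis stage to ",
         "produce well summaries.", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  rows <- list()
  for (wi in seq_len(nrow(config$layout))) {
    well <- config$layout$well_id[wi]
    trt <- config$layout$treatment[wi]
    cond <- config$conditions[[trt]]
    for (f in seq_len(config$n_fields)) {
      row <- tibble::tibble(well_id = well, field = f, treatment = trt)
      if ("cytotox" %in% stages) {
        sn <- synth_nuclei_field(
          n_cells = config$n_cells_per_field,
          dead_fraction = cond$dead_fraction %||% 0,
          seed = field_seed(config, wi, f, 1),
          size_px = config$field_px, pixel_size = p$pixel_size
        )
        nuclei <- segment_nuclei(sn$nuclei, p$nucleus_threshold,
                                 p$min_nucleus_area_um2, p$blur_radius_um)
        cy <- classify_pi_positive(nuclei, sn$pi, p$pi_threshold)
        row$n_nuclei <- cy$n_nuclei
        row$pct_pi_positive <- cy$pct_pi_positive
      }
      if (any(c("neurite", "synapse", "coloc") %in% stages)) {
        nf <- synth_neurite_field(
          total_neurite_length_um = 500 * (config$field_px / 256),
          synapse_density_true = cond$synapse_density %||% 0.05,
          coloc_rho = cond$coloc_rho %||% 0.9,
          seed = field_seed(config, wi, f, 2),
          size_px = config$field_px, pixel_size = p$pixel_size
        )
        tub_bs <- subtract_background(nf$tubulin, p$ball_radius_px)
        mask <- segment_neurites(tub_bs, p$clahe_block_um, p$clahe_slope)
        if ("neurite" %in% stages) row$neurite_area_um2 <- mask$area_um2
        if ("synapse" %in% stages) {
          spots <- detect_synapse_spots(
            subtract_background(nf$synaptophysin, p$ball_radius_px),
            p$laplace_scale_um, p$min_spot_area_um2)
          row$synapse_count <- nrow(spots)
          row$synapse_density <- synapse_density(spots, mask)
        }
        if ("coloc" %in% stages) {
          row$coloc_pcc <- pearson_colocalization(nf$acetylated, nf$tubulin,
                                                  mask)
          row$acet_ratio <- intensity_ratio(nf$acetylated, nf$tubulin, mask)
        }
      }
      if ("fibril" %in% stages) {
        ff <- synth_fibril_field(
          n_fibrils = cond$n_fibrils %||% 0, n_round_blobs = 2,
          seed = field_seed(config, wi, f, 3),
          size_px = config$field_px, pixel_size = p$pixel_size
        )
        # the generator's rod-support mask plays the role of the MT-network
        # mask: load counts only fibril pixels on the network
        mt <- neurite_mask(ff$mask, p$pixel_size)
        fib <- segment_fibrils(ff$pftaa, mt, p$tubeness_sigma,
                               p$min_fibril_area_um2, c(0, p$circ_max))
        row$fibril_load_um2 <- fib$fibril_load_um2
      }
      if ("calcium" %in% stages) {
        cr <- synth_calcium_recording(
          n_cells = p$n_cells_calcium,
          neuron_fraction = p$neuron_fraction,
          active_fraction = cond$active_fraction %||% 0.6,
          burst_rate_per_min = cond$burst_rate_per_min %||% 3,
          sync_prob = cond$sync_prob %||% 0.9,
          seed = field_seed(config, wi, f, 4)
        )
        nm <- network_metrics(cr$recording,
                              bin_s = p$bin_s,
                              participation_frac = p$participation_frac,
                              baseline_percentile = p$baseline_percentile,
                              k_mad = p$k_mad,
                              min_prominence = p$min_prominence)
        row$pct_active <- nm$pct_active
        row$burst_frequency <- nm$burst_frequency
        row$burst_correlation <- nm$burst_correlation
        row$nd_flag <- nm$nd_flag
      }
      if ("kymo" %in% stages) {
        cm <- synth_comet_movie(
          n_comets = p$n_comets,
          velocity_um_s = cond$comet_velocity_um_s %||% 0.2,
          seed = field_seed(config, wi, f, 5)
        )
        kym <- build_kymograph(cm$movie, cm$polyline,
                               pixel_size = cm$pixel_size,
                               frame_interval_s = cm$frame_interval_s)
        tr <- measure_velocity(kym, "auto")
        row$comet_velocity_um_s <- attr(tr, "mean_velocity_um_s")
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  field_tbl <- dplyr::bind_rows(rows)
  out <- list(fields = field_tbl)
  readr::write_csv(field_tbl, file.path(config$out_dir, "fields.csv"))
  layout_min <- config$layout[, c("well_id", "treatment", "dose",
                                  "n_b", "n_w")]
  if (length(analysis)) {
    wells <- aggregate_per_well(field_tbl, layout = layout_min)
    out$wells <- wells
    readr::write_csv(wells, file.path(config$out_dir, "wells.csv"))
  }
  if ("stats" %in% stages) {
    stat_rows <- list()
    usable <- out$wells |>
      dplyr::filter(is.finite(.data$mean), .data$metric != "nd_flag")
    for (m in unique(usable$metric)) {
      dat <- usable[usable$metric == m, ]
      if (length(unique(dat$treatment)) < 2) next
      set.seed(config$seed)
      gc_res <- compare_groups(dat, mean, treatment,
                               control = config$control,
                               alpha = p$alpha, metric = m,
                               n_perm = p$steel_n_perm)
      stat_rows[[m]] <- dplyr::left_join(
        generics::glance(gc_res)[, c("metric", "kruskal_h", "kruskal_p",
                                     "posthoc_performed")],
        if (nrow(generics::tidy(gc_res))) generics::tidy(gc_res)
        else tibble::tibble(metric = m),
        by = "metric")
    }
    stats_tbl <- dplyr::bind_rows(stat_rows)
    out$stats <- stats_tbl
    readr::write_csv(stats_tbl, file.path(config$out_dir, "stats.csv"))
  }
  manifest <- list(
    package = "neurohcs",
    version = as.character(utils::packageVersion("neurohcs")),
    seed = config$seed,
    stages = stages,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    n_wells = nrow(config$layout),
    n_fields = config$n_fields
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- config
  cfg$layout <- as.data.frame(config$layout)
  yaml::write_yaml(unclass(cfg), file.path(config$out_dir, "config.yaml"))
  invisible(out)
}
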