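#' Default pipeline configuration
#'
#' Builds the nested configuration consumed by [run_pipeline()]: stage
#' toggles, per-stage parameter blocks, paths and the global seed. Every
#' stage derives its own seed from the global one by a fixed offset so
#' stages are individually reproducible.
#'
#' @param output_dir run directory (created if needed)
#' @param seed global seed
#' @param n_per_group plaques simulated per genotype
#' @param stages named logical toggles (simulate, detect, reconstruct,
#'   measure, compare)
#' @param simulate,detect,reconstruct,measure,compare per-stage overrides
#'   merged over the defaults
#' @return list of class `run_config`
#' @export
run_config <- function(output_dir, seed = 1L, n_per_group = 4L,
                       stages = NULL, simulate = NULL, detect = NULL,
                       reconstruct = NULL, measure = NULL, compare = NULL) {
  cfg <- list(
    output_dir = output_dir,
    seed = as.integer(seed),
    stages = list(simulate = TRUE, detect = TRUE, reconstruct = TRUE,
                  measure = TRUE, compare = TRUE),
    simulate = list(n_per_group = as.integer(n_per_group),
                    genotypes = c("control", "pkp2cko"),
                    noise_sd = 0.04, background_texture_scale_nm = 200,
                    length_range_nm = c(1200, 2000),
                    n_slices_range = c(5L, 8L)),
    detect = list(diameter_range_nm = c(10, 20), response_threshold = 0.12,
                  min_separation_nm = 12),
    reconstruct = list(link_distance_nm = 150, min_beads = 6),
    measure = list(max_gap_nm = 120, min_run_beads = 3,
                   min_run_length_nm = 100),
    compare = list(group_col = "genotype",
                   metrics = c("avg_area_per_length_nm", "max_width_nm",
                               "hemiplaque_fraction_pct"),
                   stratify_by_ventricle = FALSE))
  for (nm in names(cfg$stages)) {
    if (!is.null(stages[[nm]])) cfg$stages[[nm]] <- isTRUE(stages[[nm]])
  }
  for (blk in c("simulate", "detect", "reconstruct", "measure", "compare")) {
    ov <- get(blk)
    if (!is.null(ov)) for (nm in names(ov)) cfg[[blk]][[nm]] <- ov[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#' @param path YAML file with any subset of the [run_config()] fields
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(output_dir = y$output_dir %||% dirname(path),
             seed = y$seed %||% 1L,
             n_per_group = y$simulate$n_per_group %||% 4L,
             stages = y$stages, simulate = y$simulate, detect = y$detect,
             reconstruct = y$reconstruct, measure = y$measure,
             compare = y$compare)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the simulate -> detect -> reconstruct -> measure -> compare pipeline
#'
#' Executes the enabled stages in order, each consuming the previous
#' stage's standard outputs from the run directory, and writes a manifest
#' (config snapshot, per-file MD5 checksums, package version, timestamps).
#' Disabled stages must have left their outputs in place from an earlier
#' run, otherwise the dependency check aborts naming the missing input.
#'
#' @param config a [run_config()]
#' @return the manifest, invisibly (also written to `manifest.json`)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages

  if (st$simulate) .stage_simulate(config)
  if (st$detect) {
    .require_input(file.path(out, "cohort.csv"), "detect", "simulate")
    .stage_detect(config)
  }
  if (st$reconstruct) {
    .require_input(file.path(out, "detections.csv"), "reconstruct", "detect")
    .stage_reconstruct(config)
  }
  if (st$measure) {
    .require_input(file.path(out, "detections.csv"), "measure", "detect")
    .stage_measure(config)
  }
  if (st$compare) {
    .require_input(file.path(out, "morphometrics_per_plaque.csv"),
                   "compare", "measure")
    .stage_compare(config)
  }

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("plaquemorph")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    checksums = as.list(tools::md5sum(sort(files))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.require_input <- function(path, stage, producer) {
  if (!file.exists(path)) {
    stop(sprintf("stage '%s' requires '%s' (produced by stage '%s')",
                 stage, basename(path), producer))
  }
}

.stage_simulate <- function(config) {
  out <- config$output_dir
  sc <- config$simulate
  cohort <- sample_cohort(n_per_group = sc$n_per_group,
                          seed = config$seed,
                          length_range_nm = sc$length_range_nm,
                          n_slices_range = sc$n_slices_range)
  meta <- list()
  for (i in seq_along(cohort)) {
    entry <- cohort[[i]]
    r <- generate_stack(list(entry$spec), entry$geometry,
                        noise_sd = sc$noise_sd,
                        background_texture_scale_nm = sc$background_texture_scale_nm,
                        seed = config$seed + 100L + i)
    tif <- file.path(out, sprintf("%s.tif", entry$plaque_id))
    write_stack(r$stack, tif)
    write_truth(r$truth, file.path(out, sprintf("%s_truth.json", entry$plaque_id)))
    meta[[i]] <- data.frame(stack_id = entry$plaque_id,
                            genotype = entry$genotype,
                            ventricle = entry$ventricle,
                            tiff = basename(tif))
  }
  utils::write.csv(do.call(rbind, meta), file.path(out, "cohort.csv"),
                   row.names = FALSE)
}

.stage_detect <- function(config) {
  out <- config$output_dir
  cohort <- utils::read.csv(file.path(out, "cohort.csv"), stringsAsFactors = FALSE)
  dp <- do.call(detection_params, config$detect)
  dets <- lapply(seq_len(nrow(cohort)), function(i) {
    stack <- read_stack(file.path(out, cohort$tiff[i]))
    d <- detect_beads(stack, dp)
    if (nrow(d)) d$stack_id <- cohort$stack_id[i]
    d
  })
  dets <- do.call(rbind, dets[vapply(dets, nrow, integer(1)) > 0])
  utils::write.csv(dets, file.path(out, "detections.csv"), row.names = FALSE)
}

.read_detections <- function(config) {
  utils::read.csv(file.path(config$output_dir, "detections.csv"),
                  stringsAsFactors = FALSE)
}

.reconstruct_all <- function(config) {
  out <- config$output_dir
  cohort <- utils::read.csv(file.path(out, "cohort.csv"), stringsAsFactors = FALSE)
  dets <- .read_detections(config)
  rc <- config$reconstruct
  recs <- list()
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$stack_id[i]
    d <- dets[dets$stack_id == id, , drop = FALSE]
    if (!nrow(d)) next
    meta <- yaml::read_yaml(file.path(out, paste0(cohort$tiff[i], ".meta.yaml")))
    g <- voxel_geometry(meta$n_rows, meta$n_cols, meta$n_slices,
                        meta$dx_nm, meta$dy_nm, meta$dz_nm)
    recs[[id]] <- suppressWarnings(
      reconstruct_plaques(d, g, link_distance_nm = rc$link_distance_nm,
                          min_beads = rc$min_beads))
  }
  recs
}

.stage_reconstruct <- function(config) {
  recs <- .reconstruct_all(config)
  for (id in names(recs)) {
    write_reconstruction(recs[[id]],
                         file.path(config$output_dir,
                                   sprintf("%s_reconstruction.json", id)))
  }
}

.stage_measure <- function(config) {
  out <- config$output_dir
  cohort <- utils::read.csv(file.path(out, "cohort.csv"), stringsAsFactors = FALSE)
  recs <- .reconstruct_all(config)
  mc <- config$measure
  planes <- list(); plaques <- list(); segs <- list()
  for (id in names(recs)) {
    rec <- measure_plaques(recs[[id]], max_gap_nm = mc$max_gap_nm,
                           min_run_beads = mc$min_run_beads,
                           min_run_length_nm = mc$min_run_length_nm)
    lab <- cohort[cohort$stack_id == id, c("genotype", "ventricle")]
    for (nm in c("per_plane", "per_plaque", "hemiplaque_segments")) {
      if (is.null(rec[[nm]])) next
      t <- rec[[nm]]
      t$stack_id <- id
      t$genotype <- lab$genotype; t$ventricle <- lab$ventricle
      if (nm == "per_plane") planes[[id]] <- t
      if (nm == "per_plaque") plaques[[id]] <- t
      if (nm == "hemiplaque_segments") segs[[id]] <- t
    }
  }
  utils::write.csv(do.call(rbind, unname(planes)),
                   file.path(out, "morphometrics_per_plane.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, unname(plaques)),
                   file.path(out, "morphometrics_per_plaque.csv"), row.names = FALSE)
  seg_tab <- if (length(segs)) do.call(rbind, unname(segs)) else
    data.frame(side = character(0), s_start_nm = numeric(0),
               length_nm = numeric(0), n_beads = integer(0),
               slice = integer(0), plaque_id = character(0),
               stack_id = character(0), genotype = character(0),
               ventricle = character(0))
  utils::write.csv(seg_tab, file.path(out, "hemiplaque_segments.csv"),
                   row.names = FALSE)
  pp <- do.call(rbind, unname(plaques))
  utils::write.csv(cohort_hemiplaque_stats(pp),
                   file.path(out, "hemiplaque_group_stats.csv"), row.names = FALSE)
}

.stage_compare <- function(config) {
  out <- config$output_dir
  cc <- config$compare
  pp <- utils::read.csv(file.path(out, "morphometrics_per_plaque.csv"),
                        stringsAsFactors = FALSE)
  cmp <- compare_metric_table(pp, cc$metrics, group_col = cc$group_col)
  tabs <- list(pooled = cmp)
  if (isTRUE(cc$stratify_by_ventricle)) {
    for (v in sort(unique(pp$ventricle))) {
      tabs[[v]] <- compare_metric_table(pp[pp$ventricle == v, , drop = FALSE],
                                        cc$metrics, group_col = cc$group_col)
    }
  }
  all_cmp <- do.call(rbind, lapply(names(tabs), function(nm) {
    t <- tabs[[nm]]; t$stratum <- nm; t
  }))
  utils::write.csv(all_cmp, file.path(out, "comparisons.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_comparisons = nrow(all_cmp), comparisons = all_cmp),
    file.path(out, "comparisons.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
}

#' Build a named fixture: config plus simulated data on disk
#'
#' `control_like`: plaques with narrow, constant gaps and no orphan runs;
#' `pkp2cko_like`: bulged gaps with orphan runs (hemiplaques); `tiny`: one
#' short control plaque over 5 slices, sized so a full pipeline run
#' completes in seconds.
#'
#' @param name one of "control_like", "pkp2cko_like", "tiny"
#' @param dir output directory
#' @param seed global seed
#' @param n_plaques plaques to simulate (ignored for "tiny")
#' @return the [run_config()] used, with the simulate stage already run
#' @export
make_fixture <- function(name = c("control_like", "pkp2cko_like", "tiny"),
                         dir, seed = 1L, n_plaques = 4L) {
  name <- match.arg(name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (name == "tiny") {
    cfg <- run_config(dir, seed = seed, n_per_group = 1L,
                      simulate = list(length_range_nm = c(700, 900),
                                      n_slices_range = c(5L, 5L)),
                      stages = list(compare = FALSE))
    # tiny keeps one plaque per genotype so downstream stages still run
  } else {
    gt <- if (name == "control_like") "control" else "pkp2cko"
    cfg <- run_config(dir, seed = seed, n_per_group = n_plaques,
                      stages = list(compare = FALSE))
    cfg$simulate$genotypes <- gt
    cfg$fixture_genotype <- gt
  }
  .fixture_simulate(cfg)
  cfg$stages$simulate <- FALSE    # data already on disk; re-running the
                                  # pipeline consumes it as-is
  yaml::write_yaml(.config_to_yaml(cfg), file.path(dir, "config.yaml"))
  cfg
}

# simulate honouring a single-genotype restriction
.fixture_simulate <- function(config) {
  if (is.null(config$fixture_genotype)) {
    .stage_simulate(config)
    return(invisible())
  }
  out <- config$output_dir
  sc <- config$simulate
  set.seed(config$seed)
  meta <- list()
  for (i in seq_len(sc$n_per_group)) {
    id <- sprintf("%s_%02d", config$fixture_genotype, i)
    pl <- sample_plaque(genotype = config$fixture_genotype, plaque_id = id,
                        length_range_nm = sc$length_range_nm,
                        n_slices_range = sc$n_slices_range)
    r <- generate_stack(list(pl$spec), pl$geometry, noise_sd = sc$noise_sd,
                        background_texture_scale_nm = sc$background_texture_scale_nm,
                        seed = config$seed + 100L + i)
    tif <- file.path(out, sprintf("%s.tif", id))
    write_stack(r$stack, tif)
    write_truth(r$truth, file.path(out, sprintf("%s_truth.json", id)))
    meta[[i]] <- data.frame(stack_id = id, genotype = config$fixture_genotype,
                            ventricle = if (i %% 2 == 0) "LV" else "RV",
                            tiff = basename(tif))
  }
  utils::write.csv(do.call(rbind, meta), file.path(out, "cohort.csv"),
                   row.names = FALSE)
}

.config_to_yaml <- function(cfg) {
  x <- unclass(cfg)
  x$simulate$length_range_nm <- as.numeric(x$simulate$length_range_nm)
  x
}

#' Write per-slice QC overlays of detections
#'
#' One PNG per slice: the grayscale slice with detection centroids marked;
#' intended for visual quality control of a run.
#' @param stack an `em_stack`
#' @param detections data.frame from [detect_beads()]
#' @param dir output directory
#' @param stack_id file-name prefix
#' @return written paths, invisibly
#' @export
write_qc_overlays <- function(stack, detections, dir, stack_id = "stack") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- stack$geometry
  paths <- character(0)
  for (k in seq_len(g$n_slices) - 1L) {
    p <- file.path(dir, sprintf("%s_slice%03d.png", stack_id, k))
    grDevices::png(p, width = g$n_cols, height = g$n_rows)
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot(NA, xlim = c(0, g$n_cols), ylim = c(g$n_rows, 0),
                   xaxs = "i", yaxs = "i", axes = FALSE, xlab = "", ylab = "")
    graphics::rasterImage(stack$intensities[, , k + 1L], 0, g$n_rows, g$n_cols, 0)
    d <- detections[detections$slice == k, , drop = FALSE]
    if (nrow(d)) {
      graphics::points(d$x_nm / g$dx_nm, d$y_nm / g$dy_nm, col = "red",
                       cex = 1.2, lwd = 1.5)
    }
    grDevices::dev.off()
    paths <- c(paths, p)
  }
  invisible(paths)
}
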