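#' Write a stack as a multi-page grayscale TIFF with a metadata sidecar
#'
#' One TIFF page per slice, values quantized at the stack's bit depth. The
#' physical voxel sizes are written both into the TIFF description tag and
#' to a structured YAML sidecar (`<path>.meta.yaml`), which is the
#' authoritative record on reading.
#'
#' @param stack an `em_stack`
#' @param path output TIFF path
#' @return the TIFF path, invisibly
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "em_stack"))
  g <- stack$geometry
  pages <- lapply(seq_len(g$n_slices), function(k) stack$intensities[, , k])
  desc <- sprintf("dx_nm=%g dy_nm=%g dz_nm=%g bit_depth=%d",
                  g$dx_nm, g$dy_nm, g$dz_nm, stack$bit_depth)
  pages[[1]] <- structure(pages[[1]], description = desc)
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                  compression = "none", reduce = FALSE)
  meta <- list(dx_nm = g$dx_nm, dy_nm = g$dy_nm, dz_nm = g$dz_nm,
               n_rows = g$n_rows, n_cols = g$n_cols, n_slices = g$n_slices,
               bit_depth = stack$bit_depth)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a stack written by [write_stack()]
#' @param path TIFF path (the `<path>.meta.yaml` sidecar must exist)
#' @return an `em_stack`
#' @export
read_stack <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(meta$n_rows, meta$n_cols, meta$n_slices))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  g <- voxel_geometry(meta$n_rows, meta$n_cols, meta$n_slices,
                      meta$dx_nm, meta$dy_nm, meta$dz_nm)
  structure(list(intensities = arr, geometry = g,
                 bit_depth = as.integer(meta$bit_depth)), class = "em_stack")
}

# plaque_spec <-> plain list for JSON round-trips
.spec_to_list <- function(sp) {
  list(plaque_id = sp$plaque_id,
       control_points_nm = unname(apply(sp$control_points, 1, as.list)),
       slice_start = sp$slice_start, n_slices = sp$n_slices,
       gap_baseline_nm = sp$gap_baseline_nm,
       bulges = sp$bulges, bead_spacing_nm = sp$bead_spacing_nm,
       bead_spacing_jitter_nm = sp$bead_spacing_jitter_nm,
       bead_diameter_range_nm = as.list(sp$bead_diameter_range_nm),
       orphan_runs = sp$orphan_runs,
       side_registration = sp$side_registration,
       bead_registration_jitter_nm = sp$bead_registration_jitter_nm,
       bead_contrast = sp$bead_contrast,
       membrane_on_orphan = sp$membrane_on_orphan, seed = sp$seed)
}

.list_to_spec <- function(x) {
  cp <- do.call(rbind, lapply(x$control_points_nm, unlist))
  plaque_spec(control_points = cp, slice_start = x$slice_start,
              n_slices = x$n_slices, gap_baseline_nm = x$gap_baseline_nm,
              bulges = if (!is.null(x$bulges) && length(x$bulges)) as.data.frame(x$bulges) else NULL,
              bead_spacing_nm = x$bead_spacing_nm,
              bead_spacing_jitter_nm = x$bead_spacing_jitter_nm,
              bead_diameter_range_nm = unlist(x$bead_diameter_range_nm),
              orphan_runs = if (!is.null(x$orphan_runs) && length(x$orphan_runs)) as.data.frame(x$orphan_runs) else NULL,
              side_registration = x$side_registration %||% "paired",
              bead_registration_jitter_nm = x$bead_registration_jitter_nm %||% 5,
              bead_contrast = x$bead_contrast,
              membrane_on_orphan = isTRUE(x$membrane_on_orphan),
              seed = x$seed, plaque_id = x$plaque_id)
}

#' Write ground truth: JSON (specs + geometry) and a bead CSV
#'
#' @param truth a `ground_truth`
#' @param json_path path of the JSON file; the bead table is written next
#'   to it as `<stem>_beads.csv` with columns plaque_id, side, slice, s_nm,
#'   x_nm, y_nm, diameter_nm
#' @return `json_path`, invisibly
#' @export
write_truth <- function(truth, json_path) {
  g <- truth$geometry
  payload <- list(
    geometry = list(dx_nm = g$dx_nm, dy_nm = g$dy_nm, dz_nm = g$dz_nm,
                    n_rows = g$n_rows, n_cols = g$n_cols,
                    n_slices = g$n_slices),
    plaques = lapply(truth$plaques, function(p) .spec_to_list(p$spec)))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  beads <- truth_beads(truth)
  utils::write.csv(beads, sub("\\.json$", "_beads.csv", json_path),
                   row.names = FALSE)
  invisible(json_path)
}

#' Read ground truth written by [write_truth()]
#' @param json_path path of the JSON file
#' @param seed seed used to resample the bead tables deterministically
#' @return a `ground_truth`
#' @export
read_truth <- function(json_path, seed = 1L) {
  x <- jsonlite::read_json(json_path)
  g <- x$geometry
  geom <- voxel_geometry(g$n_rows, g$n_cols, g$n_slices,
                         g$dx_nm, g$dy_nm, g$dz_nm)
  specs <- lapply(x$plaques, .list_to_spec)
  truth <- truth_from_specs(specs, geom, seed = seed, beads = FALSE)
  # attach the stored bead table (authoritative; resampling would need the
  # exact original stream position)
  beads <- utils::read.csv(sub("\\.json$", "_beads.csv", json_path),
                           stringsAsFactors = FALSE)
  for (id in names(truth$plaques)) {
    truth$plaques[[id]]$beads <- beads[beads$plaque_id == id, , drop = FALSE]
  }
  truth
}

#' Write a reconstruction as nested JSON
#'
#' Plaques -> slices -> midline/side polylines (nm) and bead assignments.
#' @param reconstruction a `plaque_reconstruction`
#' @param path JSON output path
#' @export
write_reconstruction <- function(reconstruction, path) {
  payload <- lapply(reconstruction$plaques, function(p) {
    list(plaque_id = p$plaque_id,
         slices = lapply(unname(p$slices), function(sl) list(
           slice = sl$slice,
           midline_nm = unname(apply(sl$midline[seq(1, nrow(sl$midline), by = 25), ,
                                                drop = FALSE], 1, as.list)),
           side_A_nm = if (is.null(sl$side_A)) NULL else
             unname(apply(sl$side_A, 1, as.list)),
           side_B_nm = if (is.null(sl$side_B)) NULL else
             unname(apply(sl$side_B, 1, as.list)),
           beads = sl$beads,
           area_nm2 = if (is.null(sl$segment)) NULL else sl$segment$area_nm2)))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write a morphometrics record as CSV tables
#' @param record a `morphometrics_record`
#' @param dir output directory
#' @param prefix file-name prefix
#' @return character vector of written paths
#' @export
write_morphometrics <- function(record, dir, prefix = "morphometrics") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (nm in c("per_plane", "per_plaque", "hemiplaque_segments")) {
    if (is.null(record[[nm]])) next
    p <- file.path(dir, sprintf("%s_%s.csv", prefix, nm))
    utils::write.csv(record[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  paths
}
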