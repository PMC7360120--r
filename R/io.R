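# Serialization: scenes as JSON + CSV point tables, image stacks as
# multi-page TIFF with a JSON pixel-size sidecar, annotated events as CSV,
# tidy result tables, and run manifests for provenance.

#' Write a tidy result table
#'
#' Deterministic CSV writer (fixed column order, no row names) so repeated
#' runs with the same inputs are byte-identical.
#'
#' @param df data.frame of results.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write / read an EM scene directory
#'
#' A scene is stored as `vesicles.csv` (`id`, `x_nm`, `y_nm`,
#' `diameter_nm`), `endosomes.csv`, `scene.json` (axon segment, membranes,
#' bouton table) and, when given, `truth.json`.
#'
#' @param scene an `em_scene` (see [gen_em_scene()]).
#' @param dir output directory (created if needed).
#' @param truth optional `ground_truth` to store alongside.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(scene$vesicles, file.path(dir, "vesicles.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$endosomes, file.path(dir, "endosomes.csv"),
                   row.names = FALSE)
  meta <- list(
    axon_segment = list(centerline = scene$axon_segment$centerline,
                        width = scene$axon_segment$width,
                        length = scene$axon_segment$length),
    membranes = lapply(scene$membranes, function(m)
      list(plasma_membrane = m$plasma_membrane, psd_span = m$psd_span)),
    boutons = scene$boutons)
  jsonlite::write_json(meta, file.path(dir, "scene.json"), digits = NA,
                       auto_unbox = TRUE)
  if (!is.null(truth)) {
    jsonlite::write_json(list(params = truth$params,
                              vesicle_labels = truth$vesicle_labels),
                         file.path(dir, "truth.json"), digits = NA,
                         auto_unbox = TRUE)
  }
  invisible(dir)
}

#' @rdname write_scene
#' @return `read_scene`: the `em_scene` rebuilt from disk.
#' @export
read_scene <- function(dir) {
  ves <- utils::read.csv(file.path(dir, "vesicles.csv"))
  need <- c("id", "x_nm", "y_nm", "diameter_nm")
  if (!all(need %in% names(ves))) {
    stop(sprintf("%s: vesicles.csv must have columns %s", dir,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(ves$id)) {
    stop(sprintf("%s: duplicate vesicle ids in vesicles.csv", dir),
         call. = FALSE)
  }
  endo <- utils::read.csv(file.path(dir, "endosomes.csv"))
  meta <- jsonlite::read_json(file.path(dir, "scene.json"),
                              simplifyVector = TRUE)
  seg <- axon_segment(matrix(unlist(meta$axon_segment$centerline),
                             ncol = 2),
                      width = meta$axon_segment$width,
                      length = meta$axon_segment$length)
  # jsonlite simplifies the homogeneous membrane list into a data.frame of
  # matrix-lists; rebuild one list entry per bouton either way
  mm <- meta$membranes
  n_mem <- if (is.data.frame(mm)) nrow(mm) else length(mm)
  membranes <- lapply(seq_len(n_mem), function(i) {
    m <- if (is.data.frame(mm)) {
      list(plasma_membrane = mm$plasma_membrane[[i]],
           psd_span = mm$psd_span[[i]])
    } else mm[[i]]
    list(plasma_membrane = matrix(as.numeric(unlist(m$plasma_membrane)),
                                  ncol = 2),
         psd_span = matrix(as.numeric(unlist(m$psd_span)), ncol = 2))
  })
  structure(list(vesicles = ves, axon_segment = seg, membranes = membranes,
                 boutons = as.data.frame(meta$boutons), endosomes = endo),
            class = "em_scene")
}

#' Write / read an image stack as multi-page TIFF with a pixel-size sidecar
#'
#' Intensities are stored as 32-bit float TIFF pages; the physical pixel
#' size (and optional frame interval) is written to `<path>.json`, since it
#' cannot be embedded by the TIFF writer used here. `read_stack` refuses to
#' guess: without a sidecar or an explicit `pixel_size` it errors.
#'
#' @param frames list of matrices (or a single matrix).
#' @param path output `.tif` path.
#' @param pixel_size pixel size, nm.
#' @param frame_interval optional frame interval, s.
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, path, pixel_size, frame_interval = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  mx <- max(1e-12, max(unlist(lapply(frames, max))))
  tiff::writeTIFF(lapply(frames, function(f) f / mx), path,
                  bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(pixel_size_nm = pixel_size, scale = mx,
               n_frames = length(frames))
  if (!is.null(frame_interval)) meta$frame_interval_s <- frame_interval
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @param pixel_size_override explicit pixel size, nm, used when no sidecar
#'   is present.
#' @return `read_stack`: list with `frames`, `pixel_size`, and
#'   `frame_interval` when stored.
#' @export
read_stack <- function(path, pixel_size_override = NULL) {
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else NULL
  if (is.null(meta$pixel_size_nm) && is.null(pixel_size_override)) {
    stop(sprintf(paste0("%s carries no pixel-size metadata; pass an ",
                        "explicit pixel_size_override"), path),
         call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  scale <- if (!is.null(meta$scale)) meta$scale else 1
  frames <- lapply(pages, function(f) f * scale)
  list(frames = frames,
       pixel_size = if (!is.null(meta$pixel_size_nm)) meta$pixel_size_nm
         else pixel_size_override,
       frame_interval = meta$frame_interval_s)
}

#' Read / write annotated movement events
#'
#' Events are exchanged as long-format CSV with columns `event_id`, `t_s`,
#' `x_um` and `segment_label` (the label of the interval starting at that
#' vertex; the last vertex of an event carries `NA`). Hand-annotated paths
#' in this format enter the statistics identically to traced ones.
#'
#' @param events list of [track_event()]s.
#' @param path CSV path.
#' @return `path` / list of `track_event`s.
#' @export
write_events <- function(events, path) {
  rows <- lapply(seq_along(events), function(i) {
    ev <- events[[i]]
    data.frame(event_id = i, t_s = ev$t, x_um = ev$x,
               segment_label = c(ev$labels, NA))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  need <- c("event_id", "t_s", "x_um", "segment_label")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: events CSV must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  lapply(split(df, df$event_id), function(sub) {
    sub <- sub[order(sub$t_s), , drop = FALSE]
    track_event(sub$t_s, sub$x_um,
                labels = sub$segment_label[-nrow(sub)])
  })
}

#' Write a run manifest
#'
#' Records the parameters, seed and package version that produced a result
#' directory; contains nothing time- or host-dependent, so repeated runs
#' are byte-identical.
#'
#' @param params parameter object or list.
#' @param path output JSON path.
#' @param module module name recorded for provenance.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(params, path, module = "presyncapture") {
  jsonlite::write_json(
    list(module = module, parameters = unclass(params),
         package = "presyncapture",
         version = as.character(utils::packageVersion("presyncapture"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
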