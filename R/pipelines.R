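# End-to-end pipeline runners. Each generates (or accepts) a scene, applies
# the full quantification for its modality, and writes deterministic CSV
# result tables plus a JSON run manifest: the same parameters and seed give
# byte-identical outputs.

#' Run the EM quantification pipeline
#'
#' Generates a synthetic EM scene (or analyzes a provided one), clusters
#' boutons, counts docked vesicles per bouton, classifies endosomes and
#' axonal vesicles, and writes `boutons.csv`, `axonal.csv` and
#' `manifest.json`.
#'
#' @param params an [em_scene_params()] object.
#' @param out_dir output directory; NULL skips writing.
#' @param scene optional pre-built `em_scene` to analyze instead of
#'   generating one.
#' @param contact_eps docking contact tolerance, nm (recorded in the
#'   output).
#' @return list with `boutons` and `axonal` data.frames (invisibly when
#'   writing).
#' @export
run_em_pipeline <- function(params, out_dir = NULL, scene = NULL,
                            contact_eps = 2) {
  if (is.null(scene)) scene <- gen_em_scene(params)$scene
  boutons <- cluster_boutons(scene$vesicles)
  endo <- classify_endosomes(scene$endosomes, boutons = scene$boutons)
  bouton_rows <- lapply(seq_along(boutons), function(i) {
    b <- boutons[[i]]
    # match the annotation bouton whose center is nearest the cluster mean
    mem <- scene$vesicles[scene$vesicles$id %in% b$member_ids, ]
    cx <- mean(mem$x_nm)
    ann <- which.min(abs(scene$boutons$center_x_nm - cx))
    n_d <- if (length(scene$membranes) >= ann) {
      count_docked(b, scene$vesicles, scene$membranes[[ann]],
                   contact_eps = contact_eps)
    } else NA_integer_
    fr <- if (!is.null(endo$fractions) && nrow(endo$fractions) >= ann) {
      endo$fractions$fraction[ann]
    } else NA_real_
    data.frame(bouton = i, n_vesicles = b$n_vesicles, n_docked = n_d,
               area_um2 = scene$boutons$area_um2[ann],
               endosome_fraction = fr, contact_eps_nm = contact_eps)
  })
  bouton_df <- if (length(bouton_rows)) do.call(rbind, bouton_rows) else
    data.frame(bouton = integer(), n_vesicles = integer(),
               n_docked = integer(), area_um2 = numeric(),
               endosome_fraction = numeric(), contact_eps_nm = numeric())
  ax <- classify_axonal_vesicles(scene$vesicles, boutons,
                                 scene$axon_segment)
  ax_df <- data.frame(
    segment_length_um = scene$axon_segment$length,
    n_axonal = nrow(ax),
    density_per_um = axonal_vesicle_density(ax, scene$axon_segment))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(bouton_df, file.path(out_dir, "boutons.csv"))
    write_results(ax_df, file.path(out_dir, "axonal.csv"))
    write_manifest(params, file.path(out_dir, "manifest.json"), "em_quant")
  }
  invisible(list(boutons = bouton_df, axonal = ax_df))
}

#' Run the mitochondrial tethering pipeline
#'
#' @param params a [mito_scene_params()] object.
#' @param out_dir output directory; NULL skips writing.
#' @return data.frame with the tethered count and its 3-um-perimeter
#'   normalization.
#' @export
run_mito_pipeline <- function(params, out_dir = NULL) {
  out <- gen_mito_scene(params)
  teth <- count_tethered(out$scene$mito, out$scene$vesicles,
                         dist_max = params$tether_distance_max)
  df <- data.frame(perimeter_um = out$scene$mito$perimeter,
                   n_tethered = teth$count, per_3um = teth$per_3um)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(df, file.path(out_dir, "mito.csv"))
    write_manifest(params, file.path(out_dir, "manifest.json"), "em_quant")
  }
  invisible(df)
}

#' Run the STED side-view profile pipeline
#'
#' Generates a synthetic side-view stack, runs bar placement, profile
#' extraction and alignment, and writes `per_synapse.csv` (target peak
#' position and intensity per synapse) and `mean_profile.csv`.
#'
#' @param params a [sideview_params()] object.
#' @param out_dir output directory; NULL skips writing.
#' @param normalize divide each target profile by its own maximum.
#' @return list as [analyze_sideview_stack()] (invisibly when writing).
#' @export
run_sted_pipeline <- function(params, out_dir = NULL, normalize = TRUE) {
  stack <- gen_sideview_stack(params)
  res <- analyze_sideview_stack(stack$synapses, normalize = normalize)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(res$per_synapse, file.path(out_dir, "per_synapse.csv"))
    write_results(res$mean_profile, file.path(out_dir, "mean_profile.csv"))
    write_manifest(params, file.path(out_dir, "manifest.json"),
                   "sted_quant")
  }
  invisible(res)
}

#' Run the axonal-transport motility pipeline
#'
#' Generates a time-lapse movie, builds the 3-pixel line-scan kymograph,
#' detects stationary objects and their synaptic fraction (against SV2A
#' puncta confirmed in both pre and post frames), traces moving paths, and
#' computes flux and speeds. Writes `events.csv` and `summary.csv`.
#'
#' @param params a [motility_params()] object.
#' @param out_dir output directory; NULL skips writing.
#' @return list with `events`, `speeds` (per event), `summary` data.frame.
#' @export
run_motility_pipeline <- function(params, out_dir = NULL) {
  out <- gen_timelapse(params)
  movie <- out$movie
  kymo <- build_kymograph(movie)
  stat <- detect_stationary(kymo)
  syn <- confirm_synapse_objects(movie$sv2a_pre, movie$sv2a_post)
  syn_profile <- path_mask_profile(syn$mask, movie$path)
  sf <- synaptic_fraction(stat, syn_profile)
  events <- trace_moving_paths(kymo)
  speeds <- do.call(rbind, lapply(seq_along(events), function(i) {
    sp <- event_speeds(events[[i]])
    data.frame(event = i, instant_speed = sp$instant_speed,
               net_speed = sp$net_speed,
               n_moving_segments = sp$n_moving_segments,
               pause_time_s = sp$pause_time)
  }))
  if (is.null(speeds)) {
    speeds <- data.frame(event = integer(), instant_speed = numeric(),
                         net_speed = numeric(),
                         n_moving_segments = integer(),
                         pause_time_s = numeric())
  }
  summary <- data.frame(
    axon_length_um = movie$axon_length,
    duration_min = params$duration / 60,
    n_events = length(events),
    flux_per_100um_min = compute_flux(events, movie$axon_length,
                                      params$duration / 60),
    n_stationary = stat$count,
    stationary_per_10um = stat$density_per_10um,
    synaptic_fraction = sf$fraction,
    mean_instant_speed = if (nrow(speeds)) {
      mean(speeds$instant_speed, na.rm = TRUE)
    } else NA_real_,
    mean_net_speed = if (nrow(speeds)) mean(speeds$net_speed) else NA_real_)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_events(events, file.path(out_dir, "events.csv"))
    write_results(speeds, file.path(out_dir, "speeds.csv"))
    write_results(summary, file.path(out_dir, "summary.csv"))
    write_manifest(params, file.path(out_dir, "manifest.json"), "motility")
  }
  invisible(list(events = events, speeds = speeds, summary = summary,
                 stationary = stat, kymograph = kymo))
}
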