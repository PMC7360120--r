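# Parameter objects for the synthetic-scene generators. Each constructor
# validates its arguments once; the generators then trust the object.

#' Parameters for synthetic EM scenes
#'
#' Describes a single ultrathin-section scene: an axon shaft carrying en
#' passant boutons (dense synaptic-vesicle clusters), sparse axonal transport
#' vesicles, docked vesicles at the PSD-opposed membrane and endosomes.
#'
#' @param axon_length axon segment length, um.
#' @param axon_width axon shaft width, um (must lie in 0.2--0.75, the validity
#'   range for analyzable axon segments).
#' @param n_boutons number of boutons placed along the axon.
#' @param vesicles_per_bouton mean vesicle count per bouton (Poisson, floored
#'   at the 20-vesicle bouton minimum).
#' @param bouton_nn_spacing target nearest-neighbor spacing inside a cluster,
#'   nm; must be <= 100 so a generated cluster satisfies the bouton rule.
#' @param axonal_vesicle_rate expected axonal vesicles per um of axon
#'   (Poisson along the shaft, thinned near boutons).
#' @param vesicle_diameter_mean,vesicle_diameter_sd vesicle diameter
#'   distribution, nm (normal truncated to > 10 nm).
#' @param docked_fraction fraction of each bouton's vesicles placed in
#'   membrane contact on the PSD span.
#' @param endosome_rate expected endosomes per bouton (Poisson).
#' @param seed integer seed; the same seed and parameters give a
#'   byte-identical scene.
#' @return an object of class `em_scene_params`.
#' @seealso [gen_em_scene()]
#' @export
em_scene_params <- function(axon_length = 10, axon_width = 0.4,
                            n_boutons = 2, vesicles_per_bouton = 100,
                            bouton_nn_spacing = 60,
                            axonal_vesicle_rate = 1,
                            vesicle_diameter_mean = 40,
                            vesicle_diameter_sd = 5,
                            docked_fraction = 0.05,
                            endosome_rate = 1,
                            seed = 1L) {
  .check_num(axon_length, "axon_length", lower = 1)
  .check_num(axon_width, "axon_width", lower = 0.2, upper = 0.75)
  .check_count(n_boutons, "n_boutons")
  .check_num(vesicles_per_bouton, "vesicles_per_bouton", lower = 0)
  .check_num(bouton_nn_spacing, "bouton_nn_spacing", lower = 10, upper = 100)
  .check_num(axonal_vesicle_rate, "axonal_vesicle_rate", lower = 0)
  .check_num(vesicle_diameter_mean, "vesicle_diameter_mean", lower = 10)
  .check_num(vesicle_diameter_sd, "vesicle_diameter_sd", lower = 0)
  .check_num(docked_fraction, "docked_fraction", lower = 0, upper = 1)
  .check_num(endosome_rate, "endosome_rate", lower = 0)
  .check_count(seed, "seed")
  structure(list(axon_length = axon_length, axon_width = axon_width,
                 n_boutons = as.integer(n_boutons),
                 vesicles_per_bouton = vesicles_per_bouton,
                 bouton_nn_spacing = bouton_nn_spacing,
                 axonal_vesicle_rate = axonal_vesicle_rate,
                 vesicle_diameter_mean = vesicle_diameter_mean,
                 vesicle_diameter_sd = vesicle_diameter_sd,
                 docked_fraction = docked_fraction,
                 endosome_rate = endosome_rate,
                 seed = as.integer(seed)),
            class = "em_scene_params")
}

#' Parameters for synthetic two-color STED side-view synapses
#'
#' Each synthetic synapse has three registered channels: a synaptic-vesicle
#' cloud imaged at confocal resolution, an active-zone/PSD marker that appears
#' as a bar at one edge of the cloud imaged at STED resolution, and a target
#' channel displaced from the bar center along the bar normal.
#'
#' @param n_synapses number of synapses to generate.
#' @param pixel_size pixel size in nm (14.2 by default; 22.7 is the coarser
#'   acquisition setting).
#' @param bar_length,bar_width physical extent of the AZ/PSD marker bar, nm.
#' @param target_offset signed displacement of the target channel's center
#'   along the bar normal, nm; negative values point toward the presynaptic
#'   (vesicle-cloud) side.
#' @param target_spread Gaussian spread of the target distribution before PSF
#'   blurring, nm.
#' @param psf_sigma_confocal,psf_sigma_sted Gaussian PSF sigmas, nm; the STED
#'   sigma must be smaller than the confocal one.
#' @param snr peak signal-to-noise ratio of the rendered channels (Poisson
#'   shot noise plus Gaussian read noise).
#' @param seed integer seed.
#' @return an object of class `sideview_params`.
#' @seealso [gen_sideview_stack()]
#' @export
sideview_params <- function(n_synapses = 50, pixel_size = 14.2,
                            bar_length = 400, bar_width = 100,
                            target_offset = 0, target_spread = 60,
                            psf_sigma_confocal = 110, psf_sigma_sted = 40,
                            snr = 10, seed = 1L) {
  .check_count(n_synapses, "n_synapses", lower = 1)
  .check_num(pixel_size, "pixel_size", lower = 1)
  .check_num(bar_length, "bar_length", lower = 50)
  .check_num(bar_width, "bar_width", lower = 10)
  .check_num(target_offset, "target_offset", lower = -400, upper = 400)
  .check_num(target_spread, "target_spread", lower = 1)
  .check_num(psf_sigma_confocal, "psf_sigma_confocal", lower = 1)
  .check_num(psf_sigma_sted, "psf_sigma_sted", lower = 1)
  if (psf_sigma_sted >= psf_sigma_confocal) {
    stop("psf_sigma_sted must be smaller than psf_sigma_confocal",
         call. = FALSE)
  }
  .check_num(snr, "snr", lower = 0.5)
  .check_count(seed, "seed")
  structure(list(n_synapses = as.integer(n_synapses), pixel_size = pixel_size,
                 bar_length = bar_length, bar_width = bar_width,
                 target_offset = target_offset, target_spread = target_spread,
                 psf_sigma_confocal = psf_sigma_confocal,
                 psf_sigma_sted = psf_sigma_sted, snr = snr,
                 seed = as.integer(seed)),
            class = "sideview_params")
}

#' Parameters for synthetic axonal-transport time-lapse movies
#'
#' Emulates a 2-min, 1-frame/s wide-field recording of a fluorescent cargo
#' along a straight axon: stationary puncta persist for the whole movie (a
#' stated fraction sitting on synapses, rendered in separate pre/post synapse-
#' marker frames), while moving particles enter as a Poisson process and
#' alternate constant-speed runs with exponential pauses.
#'
#' @param axon_length axon length, um.
#' @param duration movie duration, s.
#' @param frame_interval time between frames, s; `duration / frame_interval`
#'   must be an integer.
#' @param entry_rate moving-particle entries per 100 um of axon per minute.
#' @param run_speed run speed, um/s.
#' @param pause_rate rate of entering a pause while running, per s
#'   (exponential run lengths); 0 disables pausing.
#' @param pause_duration_mean mean pause duration, s (exponential).
#' @param n_stationary number of stationary puncta.
#' @param stationary_synaptic_fraction fraction of stationary puncta that sit
#'   on a synapse-marker punctum.
#' @param pixel_size pixel size, nm.
#' @param psf_sigma Gaussian PSF sigma, nm.
#' @param snr peak signal-to-noise ratio of rendered frames.
#' @param seed integer seed.
#' @return an object of class `motility_params`.
#' @seealso [gen_timelapse()]
#' @export
motility_params <- function(axon_length = 50, duration = 120,
                            frame_interval = 1, entry_rate = 8,
                            run_speed = 0.5, pause_rate = 0.05,
                            pause_duration_mean = 8, n_stationary = 5,
                            stationary_synaptic_fraction = 0.8,
                            pixel_size = 160, psf_sigma = 200, snr = 20,
                            seed = 1L) {
  .check_num(axon_length, "axon_length", lower = 5)
  .check_num(duration, "duration", lower = 2)
  .check_num(frame_interval, "frame_interval", lower = 0.01)
  if (abs(duration / frame_interval - round(duration / frame_interval)) >
      1e-9) {
    stop("duration must be an integer multiple of frame_interval",
         call. = FALSE)
  }
  .check_num(entry_rate, "entry_rate", lower = 0)
  .check_num(run_speed, "run_speed", lower = 0)
  .check_num(pause_rate, "pause_rate", lower = 0)
  .check_num(pause_duration_mean, "pause_duration_mean", lower = 0.1)
  .check_count(n_stationary, "n_stationary")
  .check_num(stationary_synaptic_fraction, "stationary_synaptic_fraction",
             lower = 0, upper = 1)
  .check_num(pixel_size, "pixel_size", lower = 10)
  .check_num(psf_sigma, "psf_sigma", lower = 10)
  .check_num(snr, "snr", lower = 0.5)
  .check_count(seed, "seed")
  structure(list(axon_length = axon_length, duration = duration,
                 frame_interval = frame_interval, entry_rate = entry_rate,
                 run_speed = run_speed, pause_rate = pause_rate,
                 pause_duration_mean = pause_duration_mean,
                 n_stationary = as.integer(n_stationary),
                 stationary_synaptic_fraction = stationary_synaptic_fraction,
                 pixel_size = pixel_size, psf_sigma = psf_sigma, snr = snr,
                 seed = as.integer(seed)),
            class = "motility_params")
}

#' Parameters for synthetic mitochondrion-tethering scenes
#'
#' A single mitochondrion polygon with surface-tethered vesicles (membrane-to-
#' membrane distance at most `tether_distance_max`) and untethered background
#' vesicles placed strictly beyond the tether distance so ground-truth labels
#' are unambiguous.
#'
#' @param perimeter mitochondrion perimeter, um (3 um is the average observed
#'   mitochondrial perimeter and the normalization unit).
#' @param tethered_density tethered vesicles per 3 um of perimeter.
#' @param background_density background vesicles per um^2 in the surrounding
#'   field.
#' @param tether_distance_max maximal membrane-to-surface distance of a
#'   tethered vesicle, nm.
#' @param vesicle_diameter_mean,vesicle_diameter_sd vesicle diameters, nm.
#' @param seed integer seed.
#' @return an object of class `mito_scene_params`.
#' @seealso [gen_mito_scene()]
#' @export
mito_scene_params <- function(perimeter = 3, tethered_density = 4,
                              background_density = 2,
                              tether_distance_max = 70,
                              vesicle_diameter_mean = 40,
                              vesicle_diameter_sd = 5, seed = 1L) {
  .check_num(perimeter, "perimeter", lower = 0.5)
  .check_num(tethered_density, "tethered_density", lower = 0)
  .check_num(background_density, "background_density", lower = 0)
  .check_num(tether_distance_max, "tether_distance_max", lower = 1)
  .check_num(vesicle_diameter_mean, "vesicle_diameter_mean", lower = 10)
  .check_num(vesicle_diameter_sd, "vesicle_diameter_sd", lower = 0)
  .check_count(seed, "seed")
  structure(list(perimeter = perimeter, tethered_density = tethered_density,
                 background_density = background_density,
                 tether_distance_max = tether_distance_max,
                 vesicle_diameter_mean = vesicle_diameter_mean,
                 vesicle_diameter_sd = vesicle_diameter_sd,
                 seed = as.integer(seed)),
            class = "mito_scene_params")
}
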