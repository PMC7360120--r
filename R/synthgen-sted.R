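# Synthetic two-resolution side-view synapse images. Channels are rendered
# analytically (Gaussian-convolved primitives) so the noiseless limit has a
# closed-form intensity field, then degraded with Poisson shot noise plus
# Gaussian read noise.

#' Generate a stack of synthetic side-view synapses
#'
#' Each synapse carries three registered channels on a common pixel grid:
#' `vesicle` (synaptic-vesicle cloud, confocal PSF), `marker` (AZ/PSD marker
#' bar, STED PSF) and `target` (test protein, STED PSF) whose intensity
#' center is displaced from the bar center by `target_offset` along the bar
#' normal; negative offsets point toward the presynaptic (vesicle-cloud)
#' side. Ground truth records each synapse's bar center, signed normal axis
#' and true offset.
#'
#' @param params a [sideview_params()] object.
#' @return list with `synapses` (list of `sideview_synapse`, each holding
#'   three [image_channel()]s) and `truth` (data.frame of per-synapse bar
#'   geometry plus the generating parameters).
#' @export
gen_sideview_stack <- function(params) {
  stopifnot(inherits(params, "sideview_params"))
  withr::with_seed(params$seed, .gen_sideview_impl(params))
}

.gen_sideview_impl <- function(p) {
  ps <- p$pixel_size
  npx <- ceiling(2200 / ps)            # 2.2 um field of view
  ctr_nm <- npx * ps / 2
  # pixel-center coordinates in nm
  coord <- (seq_len(npx) - 0.5) * ps
  X <- matrix(coord, npx, npx, byrow = TRUE)   # column index -> x
  Y <- matrix(coord, npx, npx, byrow = FALSE)  # row index -> y

  synapses <- vector("list", p$n_synapses)
  truth_rows <- vector("list", p$n_synapses)
  for (s in seq_len(p$n_synapses)) {
    cx <- ctr_nm + stats::runif(1, -100, 100)
    cy <- ctr_nm + stats::runif(1, -100, 100)
    phi <- stats::runif(1, 0, 2 * pi)
    tangent <- c(cos(phi), sin(phi))          # along the marker bar
    normal <- c(-sin(phi), cos(phi))          # profile axis
    # vesicle cloud sits on the presynaptic side = negative normal direction
    cloud <- c(cx, cy) - 250 * normal

    U <- (X - cx) * tangent[1] + (Y - cy) * tangent[2]
    V <- (X - cx) * normal[1] + (Y - cy) * normal[2]

    sig_cloud <- sqrt(200^2 + p$psf_sigma_confocal^2)
    img_ves <- exp(-((X - cloud[1])^2 + (Y - cloud[2])^2) / (2 * sig_cloud^2))

    ss <- p$psf_sigma_sted
    img_mark <- (stats::pnorm((U + p$bar_length / 2) / ss) -
                   stats::pnorm((U - p$bar_length / 2) / ss)) *
      (stats::pnorm((V + p$bar_width / 2) / ss) -
         stats::pnorm((V - p$bar_width / 2) / ss))

    sig_u <- p$bar_length / 2.5
    sig_v <- sqrt(p$target_spread^2 + ss^2)
    img_tgt <- exp(-U^2 / (2 * sig_u^2) -
                     (V - p$target_offset)^2 / (2 * sig_v^2))

    synapses[[s]] <- structure(list(
      channels = list(
        vesicle = image_channel(.add_noise(img_ves, p$snr), ps,
                                "vesicle", "confocal"),
        marker = image_channel(.add_noise(img_mark, p$snr), ps,
                               "marker", "sted"),
        target = image_channel(.add_noise(img_tgt, p$snr), ps,
                               "target", "sted"))),
      class = "sideview_synapse")
    truth_rows[[s]] <- data.frame(
      synapse = s, center_x_nm = cx, center_y_nm = cy,
      axis_x = normal[1], axis_y = normal[2],
      target_offset_nm = p$target_offset)
  }
  truth <- structure(list(params = unclass(p),
                          synapses = do.call(rbind, truth_rows)),
                     class = "ground_truth")
  list(synapses = synapses, truth = truth)
}

# Poisson shot noise + Gaussian read noise at a stated peak SNR. The clean
# field is scaled so its maximum is snr^2 expected counts (shot-noise SNR at
# the peak then equals `snr`), with a small additive read-noise floor.
.add_noise <- function(img, snr) {
  A <- snr^2
  read_sd <- max(0.5, 0.02 * A)
  counts <- stats::rpois(length(img), as.vector(img) * A) +
    stats::rnorm(length(img), 0, read_sd)
  matrix(pmax(counts, 0), nrow(img), ncol(img))
}
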