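---
title: "Quantifying presynaptic cargo capture: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying presynaptic cargo capture: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presyncapture)
```

This vignette is the package's own account of the measurement procedures it
implements, the assumptions behind them, and the design choices made where
the operational definitions left room.

## The measurement problem

Nerve terminals receive membranous cargo delivered along the axon and must
capture it. The readouts implemented here quantify that capture from four
kinds of data: (1) electron micrographs of ultrathin sections, where failed
capture shows up as small vesicles accumulating in the axon shaft instead
of in boutons; (2) two-color STED images of "side-view" synapses, where the
axial position of a protein relative to the active zone/PSD marker is read
from aligned line profiles; (3) time-lapse movies of fluorescent cargo
moving along axons, summarized on kymographs; and (4) an ectopic-capture
assay in which the tethering machinery is mistargeted to mitochondria and
capture is read out as vesicles accumulating at the mitochondrial surface.

All geometry is 2-D in nanometers with x rightward and y downward (raster
convention), because every quantity is defined per section or per image.
Pixel indexing is 0-based with pixel centers at `(i + 0.5) * pixel_size`.

## EM classification rules

The rules are deliberately operational, so they can be applied to point and
polygon annotations without access to image texture:

* **Bouton**: ≥ 20 vesicles in which every member's nearest neighbor within
  the group is ≤ 100 nm away (center-to-center). We formalize this as
  connected components of the graph joining vesicle pairs ≤ 100 nm apart,
  keeping components with ≥ 20 members: this is the unique graph
  formalization under which the nearest-neighbor condition holds for all
  members of a maximal group. A distance of exactly 100 nm counts as
  connected.
* **Axonal vesicle**: diameter ≤ 50 nm, center inside a *valid* axon
  segment (length ≥ 1 μm, width within 0.2–0.75 μm), and ≥ 150 nm from the
  center of every bouton vesicle. The 150-nm exclusion is center-to-center
  and inclusive: exactly 150 nm qualifies. Both cut-offs are exposed as
  parameters because inclusivity at equality is a convention, not a
  measurement.
* **Docked vesicle**: "no visible white space" between vesicle and the
  PSD-opposed plasma membrane is a visual criterion; we operationalize it
  as circle-edge-to-membrane gap ≤ `contact_eps` (default 2 nm,
  configurable and recorded in the output) with the vesicle center
  projecting perpendicularly onto the PSD span.
* **Endosome**: diameter strictly > 50 nm *and* a clear lumen. Lumen
  clarity cannot be computed from point annotations, so it is an input
  flag, set by the annotator or the generator.
* **Tethered vesicle** (mitochondria assay): diameter ≤ 50 nm and
  membrane-to-surface distance ≤ 70 nm, inclusive. The distance is
  measured vesicle edge to polygon boundary because tethers connect
  membranes; a center-to-boundary variant is available
  (`measure = "center"`). Counts are normalized per 3 μm of mitochondrial
  perimeter, the average mitochondrial perimeter in this preparation and
  hence the natural reporting unit.

Degenerate inputs error early: polygons need ≥ 3 vertices and nonzero
perimeter, axon segments failing the validity window refuse to classify,
missing PSD spans stop docked counting.

## STED side-view profiling

A synapse qualifies as side-view when the AZ/PSD marker forms a bar at one
edge of the vesicle cloud. The original selection is manual; the automated
stand-in here accepts a synapse when the marker object's principal-axis
ratio (square root of the eigenvalue ratio of its intensity-weighted second
moments) is ≥ 2. This anisotropy test is a pragmatic proxy, not a
reconstruction of the original visual judgment — synapses it rejects can
still be supplied as manual bar annotations.

The profile bar is 0.2 × 1.0 μm, centered on the marker's intensity-
weighted centroid and oriented along the marker's *minor* principal axis
(perpendicular to the bar). Its sign convention makes negative positions
point toward the presynaptic side, identified by the vesicle-channel
centroid. Intensities are sampled along the axis at one-pixel steps with
bilinear interpolation (sampling at the native pixel pitch avoids
resampling artifacts at STED pixel sizes of 14.2 or 22.7 nm), averaged
across the 200-nm width, then smoothed with a rolling average of three
consecutive values; only positions with a full window are kept, so each
profile loses one sample at each end.

Profiles are aligned per synapse by shifting positions so the marker peak
is at 0. The peak is the argmax of the smoothed profile; ties are broken
toward the presynaptic (negative) side and flagged. Because shifts are
whole pixels, aligned profiles share a common grid and the mean ± SEM
profile is computed positionwise; positions covered by fewer than half the
synapses are dropped. Each target profile is divided by its own maximum
before averaging by default (`normalize = TRUE`): peak *positions* are
unaffected, and it keeps bright synapses from dominating the mean shape;
the toggle exists because intensity-preserving averages are needed when
absolute levels are compared.

## Motility statistics

Kymographs are 3-pixel-wide line scans: at each path sample the intensity
is the mean across the normal. A stationary object must appear as a
vertical bar in *every* frame (within ±1 position step); an object present
in 119 of 120 frames is not stationary. Stationary density is reported per
10 μm of axon. The synaptic fraction counts stationary objects whose
footprint overlaps, by more than zero positions, a synapse-marker punctum
present in both the pre- and post-movie marker frames (both thresholded at
the first frame's Otsu threshold).

Moving-path events are defined on `track_event` vertex lists — whether
traced automatically or annotated by hand — as one outlined path from
appearance to disappearance including pauses. The automated tracer is a
convenience for synthetic and high-SNR data: stationary background is
removed per position (temporal median), per-frame peaks above a
per-position noise threshold (5 robust SDs from temporal differences) are
localized by centroid, and detections are linked with velocity-predictive
nearest-neighbor gating (1.2 μm per frame by default). Fragments whose
endpoints are each other's *unique* gated continuation are rejoined —
segments between pauses are not independent events — while competing
candidates stay separate and are flagged `ambiguous`. Fragments ending at
the axon boundary are exits and never merged across. Tracks shorter than
5 detections or spanning under 1 μm are not movement events. Events
touching the movie's first or last frame are kept and flagged `censored`.

Pauses are intervals with |slope| < 0.05 μm/s for ≥ 3 consecutive frames;
the original criterion is visual and unquantified, so both numbers are
parameters. Instant speed pools an event's moving segments time-weighted
(sum of |segment displacement| over summed segment time; a per-segment
table can be derived from the labels), net speed divides the
appearance-to-disappearance displacement by total time including pauses,
so net ≤ instant always. Flux is events per 100 μm of axon per minute.

## Shared statistics

`pearson` wraps the product-moment correlation with its two-sided test and
refuses degenerate input. `ddct_ratio` averages ΔCt (target minus
reference Ct) across replicates within each condition before differencing,
then reports 2^−ΔΔCt; replicate pairing across conditions is not assumed.
`normalize_western` divides each band by its loading control, normalizes
within culture to the control-condition mean, and only then averages across
cultures — the within-culture-first order keeps blot-to-blot gain out of
the comparison. `window_compare` restricts aligned profiles to a 200-nm
window centered on the peak and delegates the two-way ANOVA
(condition × position with interaction) to `stats::aov`; the bespoke
content is the alignment and windowing upstream, not the ANOVA itself.
Holm-adjusted per-position tests are optional.

## What the generators emulate — and what they do not

The generators reproduce the *data-generating processes* the measurements
assume, with full ground truth:

* `gen_em_scene`: a straight axon shaft (default width 0.4 μm) with en
  passant boutons. Cluster members are placed sequentially within one
  nearest-neighbor spacing (default 60 nm) of an existing member, which
  guarantees the bouton rule holds by construction; axonal vesicles are a
  Poisson process along the shaft (default 1 per μm) thinned of points
  within 150 nm of bouton vesicles; docked vesicles touch the membrane on
  the PSD span; vesicle diameters are normal (mean 40 nm, SD 5 nm)
  truncated to > 10 nm — the rules only bound diameters, so the
  distribution is a documented, configurable choice.
* `gen_sideview_stack`: three registered channels rendered analytically —
  vesicle cloud at confocal resolution (PSF σ 110 nm), marker bar and
  offset target at STED resolution (σ 40 nm) — then degraded with Poisson
  shot noise plus Gaussian read noise at a stated peak SNR (default 10).
  The noiseless field has a closed form, which the profile tests exploit.
* `gen_timelapse`: 2 min at 1 frame/s on a 50-μm axon; movers enter as a
  Poisson process (default 8 per 100 μm per min) and alternate
  constant-speed runs (default 0.5 μm/s, exponential lengths at pause rate
  0.05 /s) with exponential pauses (mean 8 s) — the simplest memoryless
  run-and-pause kinetics consistent with kymograph appearance; stationary
  puncta persist throughout, 80% on synapse-marker puncta by default, and
  the pre/post marker frames carry independent noise plus transient
  distractors so the pre/post confirmation rule is exercised non-trivially.
* `gen_mito_scene`: an elliptical mitochondrion scaled to the requested
  perimeter (default 3 μm), tethered vesicles placed within the 70-nm
  shell at a stated density per 3 μm, and background vesicles strictly
  beyond it, so tether labels are exact by construction.

Not emulated: 3-D structure, EM texture (membranes are analytic polylines,
vesicles circles), photobleaching, stage drift, chromatic offsets between
channels, and crowding artifacts of dense neuropil. Passing recovery tests
therefore demonstrates that the *measurement chain* is correct under the
stated noise and geometry models; it does not certify performance on real
micrographs, where annotation quality and selection criteria dominate.

## Problem sizes and numerical choices

The validation suite checks oracle equivalence of the clustering and
filtering rules on 100 random scenes of up to 300 vesicles against
brute-force O(n²) implementations; density-ratio recovery uses 50 segments
per condition; STED offset recovery uses 50 synapses per offset at the
default SNR for offsets 0 to −150 nm (tolerance ±15 nm, about one pixel);
speed recovery uses pause-free kinetics at 0.2–1.0 μm/s (tolerance 5%) and
entry-rate recovery 30 movies (tolerance 10%). These sizes were chosen so
Monte-Carlo error sits well below each tolerance. Determinism is enforced
end to end: generators draw from a seed-scoped RNG (`withr::with_seed`),
pipeline runners write fixed-format CSVs, and manifests contain no
timestamps, so repeat runs are byte-identical.

Two practical notes. TIFF stacks are written with a JSON sidecar carrying
the physical pixel size, and `read_stack` refuses to guess when neither a
sidecar nor an explicit pixel size is given. And the package's interface is
its functions and pipeline runners (`run_em_pipeline`, `run_sted_pipeline`,
`run_motility_pipeline`, `run_mito_pipeline`) rather than a shell
executable; the runners are what scripts should call.

## Known limitations

* The anisotropy criterion for side-view selection is stricter than a
  trained eye; borderline synapses should be annotated manually.
* The tracer is built for sparse, high-SNR kymographs. Dense traffic with
  frequent crossings will trigger the ambiguity rule often, and the
  resulting fragments — correctly — stay separate events, biasing flux
  upward; hand annotation remains the reference workflow there.
* Instant speed on traced events is biased low by one partial frame at
  each moving-segment boundary (about 2–3% at the default frame rate);
  the bias vanishes for hand-annotated vertices placed at true change
  points.
* Endosome area fractions require bouton areas from annotation polygons;
  without them the fraction is reported absent rather than guessed.
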