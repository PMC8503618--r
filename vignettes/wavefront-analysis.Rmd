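---
title: "Time-averaged wavefront analysis of atrial fibrillation basket recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-averaged wavefront analysis of atrial fibrillation basket recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afpathways)
```

## The problem and the method

Atrial fibrillation (AF) looks chaotic on a beat-to-beat basis, yet local
activation may favour particular pathways when watched for long enough.
This package implements a time-averaged wavefront analysis for 64-electrode
basket-catheter recordings that makes those preferential pathways visible
and quantifies activation flowing from the pulmonary-vein (PV) antra into
the left-atrial body — the signature of PV-driven AF in patients whose AF
terminates acutely under pulmonary vein isolation (PVI).

The pipeline is:

1. **Electrogram processing** (`subtract_qrs()`, `derivative_chain()`).
   Unipolar electrograms are cleansed of the ventricular far field by
   average-beat template subtraction, differentiated, band-passed
   (40–250 Hz), rectified, low-passed (20 Hz) and min–max normalised per
   channel to give the *normalised filtered derivative* in [0, 1], whose
   peaks mark local activation. Cycle lengths (`cycle_lengths()`) are mean
   inter-peak intervals.
2. **Grid arrangement** (`arrange_grid()`, `interpolate_grid()`). The 8
   splines × 8 electrodes are laid out as a 2D anatomical grid — rows are
   splines, top row the anterior mitral-valve spline, columns run from the
   lateral/left-PV side to the septal/right-PV side. The valve spline is
   duplicated at the opposite edge (9×8) so wavefronts crossing the valve
   orifice stay contiguous, then the grid is linearly refined, two points
   per gap (9×8 → 25×22), with original node values preserved exactly.
   Out-of-contact electrodes are excluded from the interpolation support
   rather than bridged.
3. **Optical flow** (`horn_schunck()`, `flow_sequence()`). Classical
   Horn–Schunck flow between frames 40 samples apart (≈20 ms at
   2034.5 kHz), enough displacement to measure while staying within the
   differential regime.
4. **Wavefront averaging** (`detect_wavefronts()`, `average_flow()`).
   Wavefronts are the leading-edge boundary pixels of the 0.9 super-level
   set of the normalised derivative, in 8-connected components of more
   than three pixels. Flow vectors at wavefront pixels are summed over the
   10 s window and divided by the number of analysed frames, so the
   averaged magnitude encodes *directional repeatability*: repeated
   directions accumulate, incoherent ones cancel.
5. **Streamlines** (`build_streamlines()`). The averaged field is
   visualised by streamlines seeded at the centroids of a triangulation of
   the recording points, integrated both ways with 0.25 px Euler steps,
   stopped by an angular criterion of 0.7 rad, and greedily retained in
   order of decreasing length subject to a 0.5 px spacing rule.
6. **PV activation flow metric** (`tag_pv_vectors()`). In boxes adjacent
   to the left and right PV edges, a vector is tagged as PV-to-body flow
   when its magnitude exceeds the array mean and its direction lies in a
   90° cone about the inward axis. Each box reports the tagged percentage
   of its valid pixels; the headline metric is the maximum of the two.
7. **Cohort statistics** (`compare_groups()`): Wilcoxon rank-sum p-value,
   rank-based AUC, and sensitivity/specificity at the Youden-optimal
   threshold (always reported alongside).

## The synthetic activation generator

No clinical basket recordings can be redistributed, so the package ships a
kinematic generator (`synth_scene()`, `activation_times()`,
`render_movie()`, `render_electrograms()`) that produces ground-truth
activation "movies" and basket-sampled unipolar electrograms for four
driver archetypes: planar waves, rotors (spiral phase maps), repetitive
focal sources, and multi-wavelet regimes built from Poisson-seeded,
short-lived focal bursts (lifetime about two cycles). Waves propagate at a
configurable conduction speed with closed-form activation times, so every
downstream estimate can be checked against exact ground truth.

Defaults are chosen to emulate persistent-AF basket data: an 8×8 electrode
grid (≈7 mm pitch on a 50 mm basket), 2034.5 Hz sampling, cycle lengths
near 180 ms, conduction 0.1 px/ms (≈0.7 m/s), activation pulses of 10 ms
SD, and additive noise at 5% of signal amplitude. Movie noise is
band-limited (Gaussian knots every 25 ms, linearly interpolated) because
the movie emulates the normalised derivative *after* the 20 Hz low-pass;
white per-sample noise would put spurious sign flips into the temporal
derivative that no filtered signal exhibits. Electrograms are biphasic
deflections (difference of Gaussians, 5 and 8 ms widths, negative lobe
dominant) plus an optional common-mode "QRS" artifact and noise.

Driver placement follows the anatomy of the problem. The basket does not
map the veins themselves, so PV drivers live at or beyond the grid edge
and only their radiating far field is recorded: PV *triggers* are focal
sources up to one pixel beyond the edge, while PV *re-entry* is modelled
as a rotor circulating a 2 px core (the ostium) sitting 4–5 px behind the
edge. The deeper placement compensates for the spiral tilt of a rotating
wavefront — the angle between propagation and the radial axis is
atan(v·CL/2πr), so a core too close to the mapped field fills the PV box
with tangential near-field flow that no PV-driven patient shows. With
these placements the two PV archetypes yield statistically
indistinguishable metrics, reproducing the physiological equivalence of
triggers and rotational drivers as seen from LA-body recordings, while
functional (point) rotors in the body and multi-wavelet regimes score near
zero.

What the generator does *not* emulate: fibrotic conduction slowing and
break-up, secondary wavelets shed by a primary driver, anisotropy, atrial
geometry beyond the flat grid, far-field electrogram morphology, and
electrode motion. Synthetic non-responders therefore score almost exactly
0% PV flow, whereas clinical and monodomain non-responders show small but
nonzero values; passing tests demonstrate that the *analysis* recovers
known kinematics, not that the generator reproduces clinical signal
complexity.

## Worked example

```{r example, eval = FALSE}
library(afpathways)

scene <- synth_scene(
  grid_shape = c(8, 8), duration = 11,
  drivers = driver_spec("rotor", origin = c(4.5, 13.5), period = 180,
                        chirality = 1L, core_radius = 2),
  conduction_speed = 0.1, noise_sd = 0.05, seed = 42)

res <- pv_flow_from_scene(scene)
res
#> <pv_flow_result> left 0.0%, right 35.0%, metric 35.0%
```

A rotor behind the right PV produces right-sided PV-to-body flow; a
multi-wavelet scene under the same analysis scores 0%.

## Numerical and design choices

* **Filter chain identity.** The canonical pre-dominant-frequency chain
  (band-pass 40–250 Hz on the derivative, rectify, low-pass 20 Hz) with
  2nd-order zero-phase (forward–backward) Butterworth filters; zero-phase
  because filter lag would bias activation timing and hence flow
  direction. All cutoffs sit in `analysis_config()`.
* **Normalisation** is per channel over the analysis window; channels with
  range below 1e-9 are flagged flat and excluded, since the 0.9 isoline
  presumes peaks near 1.
* **Peak detection** uses a 50 ms minimum separation (below any plausible
  AF cycle length, above the pulse width) and a 0.5 minimum height on the
  normalised signal.
* **Horn–Schunck** uses the original 4-point cube derivative stencils,
  weighted 8-neighbour smoothing (1/6 edges, 1/12 diagonals), α = 1 and
  100 Jacobi iterations from zero — the regime of the original method;
  both knobs are exposed because the source methodology does not state
  them. Invalid pixels carry zero flow and are dropped from neighbourhood
  averages with weight renormalisation (a Neumann condition, also applied
  at grid borders). The compiled kernel is verified against a direct
  pure-R re-implementation to 1e-12.
* **Leading edge.** The wavefront/wave-back discriminator is the sign of
  the one-sample temporal derivative at the analysed frame. It must not be
  taken across the 40-sample flow increment: at physiological speeds the
  wave travels farther than the width of the 0.9 band in 20 ms, so the
  pair difference is negative on the true leading edge.
* **Averaging normalisation.** Vector sums are divided by the number of
  analysed frames, not by each pixel's contribution count; dividing by
  contributions would erase the "how often is this direction repeated"
  information that streamline thickness and the magnitude threshold rely
  on. The PV metric is invariant to any global rescaling of the field, so
  this choice affects interpretation, not the metric.
* **Streamline integration** uses fixed 0.25 px Euler steps on the
  normalised direction field. The angular stopping criterion (0.7 rad) is
  evaluated over one pixel of arc length rather than between consecutive
  0.25 px steps: bilinear interpolation unfolds even a discontinuous 90°
  corner over about one pixel, so a strictly consecutive-step test could
  never fire at sub-pixel step sizes; with steps of 1 px or more the two
  definitions coincide. Selection ties (equal lengths) break by ascending
  seed id, making the retained set deterministic and order-independent.
* **PV boxes** default to the outer 20% of columns and central 60% of rows
  per side, inward direction along the column axis; the source material
  fixes the 90° cone width but not the box extents, so both are
  configurable and echoed into every result artifact. Each box uses its
  own valid-pixel denominator (a pooled variant is available), which makes
  "the maximum of the left and right metrics" meaningful.
* **Statistics.** Two independent groups of unequal size admit no
  signed-rank pairing, so group comparison is the Wilcoxon rank-sum
  (Mann–Whitney) test; AUC is the normalised U statistic, cross-checked in
  tests against brute-force pair enumeration and an independent ROC
  implementation.
* **Degenerate inputs.** Empty wavefront masks are allowed (zero averaged
  vectors); a zero field at a streamline seed yields an empty polyline; a
  PV box with no valid pixels reports `NA`, and only both boxes empty is
  an error; fully tied group comparisons report p = 1.

## Known limitations

* The 0.9 isoline with the >3-connected-pixel rule needs crests wider than
  roughly half the electrode pitch. At slow conduction (≲0.35 m/s at 7 mm
  pitch) diagonal planar wavefronts reduce to isolated sub-4-pixel blobs
  and are discarded — direction recovery degrades not because of the flow
  estimator but because no wavefronts survive the component filter. The
  bundled direction tests therefore run at 0.56–1.05 m/s, the normal
  atrial range.
* Dropout handling excludes regions around missing electrodes (pixels
  without full valid interpolation support are masked) rather than
  inpainting across gaps; with heavy dropout the PV boxes lose pixels and
  the metric becomes coarse-grained before it becomes wrong.
* Problem sizes in the test-suite: unit tests run 2 s windows on 8×8
  scenes; the end-to-end property tests use the full 10 s windows, 20+20
  scene cohorts, and three dropout seed batches. These sizes were chosen
  to make the whole suite a few minutes long while keeping every assertion
  at the published thresholds.
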