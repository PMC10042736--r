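---
title: "Methods: quantifying nuclear expulsion from time-lapse movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying nuclear expulsion from time-lapse movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The phenotype and the measurement model

Apoptotic tumor cells expressing an H2B chromatin reporter can, in a
Padi4-dependent manner, expel their nuclear contents: after the usual
apoptotic condensation (and sometimes fragmentation into apoptotic bodies),
the chromatin signal decondenses and spreads rapidly, several-fold beyond
its baseline area. `nucexpel` operationalizes this as a per-cell statistic
on the *area of thresholdable chromatin signal*:

1. segment nuclei per frame and link them over time into per-cell traces;
2. normalize each cell's area trace by its own pre-treatment baseline,
   `e(t) = area(t) / baseline_area` (dimensionless fold-change);
3. score each cell by the maximum forward gradient of `e` over a grid of
   interval widths `W`:
   `score = max_{t, w ∈ W} [e(t + w) − e(t)] / w` (fold per frame);
4. calibrate a score threshold by ROC between a whole known-positive
   condition (wild-type) and a whole known-negative condition (knockout),
   and call `score > threshold` as nuclear expulsion.

The statistic assumes that expulsion manifests as a *fast, sustained* area
increase, whereas apoptosis alone only shrinks or fragments the signal; slow
drifts of segmentation area contribute small gradients at every interval
width and are absorbed by the calibrated threshold.

Key assumptions inherited from the assay: a single imaging plane; no cell
division during the movie (cells are serum-starved and drug-treated); every
cell's baseline is observed before treatment takes effect.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `intervals` | {1, 2, 4, 8} | frames | a dyadic grid spans fast (ionophore-like) and slow (Raptinal-like) expansion kinetics; the interval set is deliberately exposed because no canonical choice exists |
| `baseline_window` | frames 0–4 | frames | "before drug addition"; for the simulator this predates every condensation onset |
| `smoothing_sigma` | 1 | px | suppresses shot noise without moving edges |
| `min_area` | 20 | px² | rejects noise specks below any plausible nucleus |
| `merge_radius` | 2 × median equivalent radius at frame 0 | px | apoptotic bodies land within about two baseline radii of the parent centroid, neighbouring cells farther apart |
| `max_link_distance` | 15 | px | several times the per-frame drift of starved cells |
| `max_gap` | 2 | frames | bridges single-frame segmentation dropouts |
| `spike_fold`, `min_run` | 1.5, 2 | fold, frames | calcium spikes are several-fold; two consecutive frames reject single-frame blips |

The expulsion "onset" used for calcium timing is derived from the score's
own gradient field: the earliest window start whose gradient is within 10%
of the maximum (`onset_time`). The strict argmax start (`argmax_time`) is
also reported, but it is a biased onset estimator: on a noisy, nearly
linear expansion ramp every full-ramp window has almost the same slope, so
noise places the argmax anywhere along the ramp (typically one or two
frames late), whereas the earliest near-maximal start pins the onset to
the foot of the rise. The assay itself never defines an onset; both
quantities come from the gradients the scoring algorithm already computes,
so no separate change-point detector (with its own parameters) is
introduced. Whether expansion should be normalized per cell (as here) or
reported as absolute area is equally unspecified in the assay; per-cell
normalization is the default because it makes cells of different sizes
comparable, and reports always carry the threshold and rule used.

## Segmentation: why log-domain Otsu plus half-max refinement

Total chromatin intensity is conserved while its area grows, so an expanded
nucleus is about `expansion_fold`-fold dimmer than at baseline and
many-fold dimmer than a condensed one. A global Otsu threshold on raw
intensities settles between the background and the *bright* nuclei and
silently deletes exactly the phenotype being measured. Two measures address
this:

* the detection threshold is computed by Otsu's method on
  log1p-transformed smoothed intensities (the log compresses the bright
  mode, keeping the background/dim-signal split dominant); a robust
  background alternative (median + k·MAD) and a fixed threshold are also
  available;
* each detected object is then *refined to its own half-maximum*: pixels
  above halfway between the frame background (median) and the object's
  peak. The measured area of a smooth-edged nucleus therefore corresponds
  to its half-maximum contour regardless of its brightness, which is what
  makes area fold-changes comparable between bright condensed and dim
  expanded states.

Touching nuclei can optionally be split by watershed on the distance
transform (`split_touching`); it is off by default because the pipeline's
intended density keeps nuclei resolvable, and during expansion the mask is
deliberately whatever the threshold covers — no convex hull, since the
quantity of interest is the area of chromatin signal, halo included.

Degenerate inputs are defined, not errors: a blank or constant frame yields
zero regions; an empty frame sequence or an empty score set is an input
error; a trace with no baseline overlap is excluded and tallied, not
crashed on; a trace too short for every interval is flagged unscorable and
leaves the percent-expulsion denominator.

## Tracking and fragment merging

Linking is greedy: the globally closest (track, detection) pair within
`max_link_distance` is linked first. Exact ties break by smaller area
difference, then lower detection label, then lower track id, making the
result deterministic. At the low motility of starved cells the greedy
assignment coincides with the optimal one (the suite checks this against a
permutation-search oracle).

`merge_fragments()` merges regions whose centroids chain within
`merge_radius` (single-linkage closure), so a fragmented nucleus counts as
one cell's chromatin — the assay never states whether apoptotic bodies were
tracked as one object, so this is explicit and configurable. The closure is
iterated to a fixed point because merged centroids can themselves fall
within the radius of one another; a single pass would not be idempotent.

## ROC calibration

Whole conditions are the calibration classes: every wild-type cell is a
positive even though a sizeable minority never expels, and that label noise
is precisely why moderate false-positive operating points are expected when
thresholding real data. The AUC is computed by trapezoid over the curve
evaluated at every distinct score (strict-inequality calls), which equals
the Mann–Whitney pair statistic with ties counted one half — the suite
checks this identity to 1e-12 against explicit pair counting. Youden's J is
the default operating rule because the assay states ROC thresholding but
not the operating point; `fixed_fpr(α)` is provided for
bounded-false-positive regimes, and `fixed` passes an external threshold
through. The Youden threshold is returned as the midpoint between the
optimal score and the next higher distinct score, so that perfectly
separated populations get a mid-gap threshold rather than a population
score.

## What the simulator emulates — and what it does not

`simulate_movie()` renders nuclei as anisotropic, smooth-edged elliptical
blobs: a flat core with a logistic radial falloff of relative width
`edge_sharpness` (default 0.1), so the half-maximum contour encloses
exactly the ground-truth ellipse area. A pure Gaussian profile was rejected
deliberately: its thresholded area varies with log(amplitude/threshold), so
no threshold-based segmentation can report areas consistent with ground
truth across an intensity-conserving expansion, whereas the logistic edge
keeps thresholding non-trivial (diffuse edges, dim expanded states) while
making "the area of the rendered mask" well defined.

The generator's event model follows the assay's phenotype: per-cell
condensation onset uniform in a configurable window, area shrinking to
`condensation_fold` (0.6) over a few frames with intensity rising
conservatively; optional fragmentation into 2–4 bodies placed within two
baseline radii; for expelling cells, monotone area growth to
`expansion_fold` (3.0) times baseline over `expansion_duration` (6) frames
with total intensity conserved (chromatin decondenses, it is not
synthesized), bodies coalescing at expulsion; a sustained calcium step of
`calcium_spike_fold` starting `calcium_spike_lead` frames before expulsion
onset (knockout-like apoptotic cells spike too — calcium is upstream of
Padi4, so spiking without expulsion is the expected negative-control
behaviour). Noise is Poisson photon noise (gain `photon_scale`) plus
Gaussian read noise on a constant background. Default geometry: 480 × 480
px fields, 48 frames at 3-minute intervals, baseline radius 8 ± 1 px,
nuclear peak ≈ 1500 counts over a background of 100 — typical of widefield
imaging at 10–20× of cell-line monolayers; the assay's own magnification
and intervals vary between experiments, so these are realistic free
parameters, not calibrated constants.

Cells are placed on a jittered grid (pitch five baseline radii) and do not
divide, die away, or arrive mid-movie. Determinism is strict: all per-cell
parameters come from per-cell substreams derived from the master seed by
counter (adding cells leaves earlier cells' realizations untouched), and
noise from a per-channel derived stream, so identical config and seed give
bit-identical movies.

What it does *not* emulate — and what passing tests therefore cannot show
about real movies: out-of-focus light and z-drift, photobleaching,
illumination gradients, cell crowding with genuinely touching nuclei,
motile cells, debris, and segmentation-adversarial textures. The
false-positive rate of the negative condition in the synthetic benchmark is
consequently far below what real knockout movies show; the synthetic
benchmark validates the *algorithmic* chain (segmentation → tracking →
scoring → calibration recovers known fates), not robustness to microscopy
artifacts.

## Problem sizes and numerical choices

The standard benchmark used by the test suite and the acceptance script is
2,000 cells per condition per seed, split into fields of 144 cells
(filling the default frame's placement grid), three seeds, paired
wild-type/knockout cohorts — large enough for stable percentages at a cost
of minutes per seed on one CPU. Calcium-lead recovery uses 20 seeded
16-cell movies per lead value (4, 8, 16 frames). Oracle checks run on
1,000 random traces (exact equality for the score) and 200 random score
sets (1e-12 for the AUC identity).

Floating-point ties in the score are resolved by earliest time then
smallest interval; candidate thresholds are the distinct scores with
infinite endpoints; percent-expulsion denominators exclude unscorable
cells but reports carry their count. TIFF output quantizes counts to
16-bit integers.

## Known limitations

* Greedy linking has no motion model; fast or crowded cells need a real
  tracker upstream, after which the scoring and calibration layers apply
  unchanged.
* The expulsion score is scale-free but not robust to baseline
  mis-estimation: a cell first observed after treatment has no baseline
  and is excluded rather than guessed at.
* Expulsion onset (`argmax_time`) is quantized to the frame grid and can
  precede the visible area take-off by up to one interval width for slow
  expansions.
* Calcium is measured inside the chromatin mask only; nuclear versus
  cytosolic compartments are not distinguished.
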