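---
title: "Template-based cluster calling at desk scale: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based cluster calling at desk scale: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(templateseq)
```

templateseq is a desk-scale re-implementation of the image-analysis pipeline
of sequencing-by-synthesis instruments, built to make one failure mode and
its fix reproducible without a sequencer: libraries with *low initial
sequence diversity* (reads sharing a 5' barcode) break cluster detection
during template generation, and extending the template window — the Long
Template Protocol — repairs it. This vignette documents the generative
model, the pipeline's algorithms, every tunable that matters, the design
decisions taken where the underlying instrument behaviour is undisclosed,
and what the simulations can and cannot say about real flowcells.

## The generative model

A tile is a `tile_width_px` x `tile_height_px` patch of flowcell imaged in
four channels (one per base) once per cycle. Clusters are placed as a
homogeneous spatial Poisson process; an optional minimum-distance thinning
(`exclusion_radius_px`) is available for constructing well-separated
fixtures but is off by default, since published data give no cluster-spacing
statistics. Each cluster carries:

* a sequence of length `n_cycles`, built from the library description —
  either a `lowdiv_fraction` of clusters carrying a fixed 5' prefix (the two
  11 nt BLESS barcodes by default) with a random suffix, or an explicit
  sample sheet with per-sample prefixes, reference sequences to copy insert
  bases from, and multiplexing indices read in the final `index_cycles`
  cycles;
* a log-normal amplitude (mean `amplitude_mean` = 8000 ADU, CV
  `amplitude_cv` = 0.35) — the integrated photon signal of the spot; and
* an independent log-normal amplitude for the index cycles, modelling the
  index read's separate priming and imaging: relative cluster brightness is
  not preserved between the insert read and the index read.

Rendering a cycle places an isotropic Gaussian spot (sigma `psf_sigma_px`)
with integrated intensity equal to the amplitude into the channel of the
cluster's base at that cycle, mixes channels through a row-stochastic
crosstalk matrix (identity by default), adds a constant background
(400 ADU) and Gaussian read noise (SD 30 ADU), optionally Poisson shot
noise (off by default so closed-form oracles hold exactly), and clamps to
the 16-bit range. Cycles after the first are translated by a uniform stage
drift in [-2, 2] px; cycle 1 is the reference frame. Runs are bit-for-bit
reproducible from the seed.

### Choice of optical scale

Two scales govern everything: the PSF width sigma and the mean
nearest-neighbour spacing (0.5 / sqrt(density)). On the instrument, optimal
cluster density places clusters roughly 2.5-3 sigma apart — dense enough
that same-channel neighbours routinely coalesce — while the detector can
still separate clusters that land in *different* channels. A desk-scale
detector working on 1 px pixels has a hard cross-channel resolution floor of
about 1.5 px (local maxima on an integer grid, plus the spot-merge radius),
so the PSF must be wide enough that the same-channel coalescence scale
(about 2 sigma) sits clearly above that floor. We therefore use sigma =
2 px and an optimal density of 0.0085 clusters/px^2 (mean spacing about
5.4 px, i.e. 2.7 sigma): same-channel pairs merge out to about 4 px while
different-channel pairs separate down to about 1.5 px. A narrower PSF
(e.g. 1.2 px) collapses these two scales onto the pixel grid and the
diversity effect — the phenomenon under study — becomes unobservable at any
Poisson density.

## The pipeline

**Spot detection** (`detect_spots()`) runs per channel: local maxima above
`background + detection_threshold_sd x noise SD` (median and MAD of the
channel; 4 SDs by default), sub-pixel refinement by an intensity-weighted
centroid over a 5x5 window of the same channel, then three guards —

* *flux confirmation*: the background-subtracted 3x3 sum around the peak
  must also exceed the threshold scaled to the 9-pixel noise SD, rejecting
  single-pixel noise excursions;
* *shoulder suppression*: a maximum with a brighter same-channel maximum
  within 3.5 px (just under the 2-sigma coalescence scale) is discarded —
  inside that scale a genuine second cluster of the same base cannot
  produce a separate maximum, so whatever did is noise on the first spot's
  wing;
* *cross-channel merge*: the pooled per-channel lists are merged by single
  linkage at `merge_radius_px` (1.5 px), collapsing crosstalk duplicates
  and genuinely unresolvable pairs to an intensity-weighted centroid.

Detecting per channel rather than on the max-over-channels image is what
real detectors do, and it is essential here: with log-normal amplitudes a
bright cluster's wing dominates a dim neighbour's peak on the max image even
when they occupy different channels, which would erase the diversity benefit
being studied.

**Template generation** (`build_template()`) detects spots in each of the
first `template_cycle_count` cycles (default 4; larger values are the Long
Template Protocol), names the cycle with the most spots *golden* and the
second best *silver* (ties to the earlier cycle), registers the silver list
onto the golden one (exhaustive integer shift maximising matches, refined by
the mean displacement of matched pairs), and combines the two by a
*max-resolution union*: pooled spots are grouped by single linkage at
`dedup_radius_px`, and each group keeps the spots of the cycle that resolved
it into more maxima (ties favour golden). A plain union was tried first and
produces a characteristic artifact — a pair merged in the golden cycle but
resolved in silver leaves the stale merged centroid *plus* the two resolving
spots, three positions for two clusters, and the stale centroid then emits
mixed reads. The template is immutable from this point on; nothing
downstream corrects it.

**Registration** (`register_offset()`) is translation-only, consistent with
per-cycle stage drift: the background-subtracted max-channel image is
sampled at the template positions over all integer shifts within
`max_shift_px`, and the best shift is refined by quadratic interpolation of
the score surface. Registration subsamples at most 500 template positions;
the score is an average over hundreds of spots and loses nothing.

**Extraction and calling** (`extract_intensities()`, `call_bases()`)
estimate per-channel amplitudes with a PSF-matched filter over a 3-sigma
window at each offset-corrected template position (background-subtracted,
negatives clamped), call the argmax channel, and compute per-cycle
*chastity* I1/(I1+I2) from the two brightest channels; an all-zero vector
gives an `N` with chastity 0.25. The purity filter passes a read when at
most one of the first 25 cycles (or the whole insert, if shorter) has
chastity below 0.6 — threshold and window are conventional values, since
the instrument's are not published, and both are parameters.

**Quality** is a documented convention, not an instrument model: Phred
scores map piecewise-linearly from chastity (0.5 -> Q2, 1.0 -> Q40,
monotone, flat at Q2 below 0.5). Downstream, the high-quality read filter
retains reads with at least 34 consecutive bases strictly above Q20, and
barcode matching is exact prefix equality (0 mismatches = "intact") with
trimming.

**Bleeding measurement** (`bleeding_lane()`, `cross_map()`) simulates a
multiplexed lane — a barcoded low-diversity sample and a diverse control,
each with its own 6 nt index read in dedicated index cycles — calls it at
two template lengths, demultiplexes by exact index match, quality-filters,
and counts reads that map (0 mismatches, either strand, exact substring
search) only to the other sample's reference. Expected bleeding under the
binomial index-morphing null is `index_morph_prob()`: the upper binomial
tail P(X >= d) for an n nt index at per-base error p reproduces the printed
null rates; a stricter specific-substitution mode, (p/3)^d (1-p)^(n-d), is
provided for sensitivity analysis. Exact substring search against ~30 kb
synthetic references stands in for genome alignment; it preserves the
0-mismatch criterion at desk scale.

**Memory model** (`estimate_template_memory()`): template generation holds
all channel images of the template window in RAM, so memory is linear in
template length — four 2048 x 160000 16-bit images are ~2.6 decimal GB per
cycle, and `max_template_length()` is the floor of available RAM over the
~4 GB/cycle empirical slope. Decimal GB (1e9 bytes) matches the convention
of the instrument documentation these figures come from.

## What the simulations show — and what they cannot

The test suite (all sizes chosen as the package's own desk-scale study
conditions) verifies, among others:

* exactness oracles: noiseless isolated clusters are detected to < 0.5 px,
  called identically to ground truth, and pass every filter; applied
  integer offsets are recovered exactly and half-pixel offsets to 0.25 px;
  the binomial null agrees with brute-force convolution to 1e-12 for all
  index lengths up to 8;
* the diversity mechanism, on 512 px tiles at the reference density
  (~2200 clusters, seeds 1-5): with a 100% low-diversity library carrying a
  5 nt prefix, 7-cycle (barcode+2) templates recover at least 95% of true
  clusters while 4-cycle templates recover under 80%, and the purity-pass
  intact-barcode yield is strictly higher for the long template in every
  seed;
* sample bleeding on 12 seeded multiplexed lanes: the long template's
  per-lane median bleeding is at most half the standard protocol's, and the
  pooled cross-mapped rate is strictly lower.

Two honest caveats. First, desk-scale lanes yield only a handful of
cross-mapped reads each, so the per-lane median is a degenerate statistic
(it is zero for both protocols in most seed sets); the pooled rate is the
informative number, and it reproduces the *direction* of the
template-length effect, not the instrument-scale magnitude. On a real
flowcell the standard protocol's template failure at 100% low diversity is
catastrophic (percent-level usable reads), a regime a 1 px-pixel detector
cannot reach while still resolving clusters at all; the bleeding reduction
measured here is correspondingly milder than the several-fold reduction
achievable on the instrument. Second, the quality model is a convention:
absolute Q30 fractions and absolute bleeding rates from this simulator are
not predictions for any instrument, and are not compared against published
absolute values anywhere in the package — only ratios, bounds and
directions are.

The generator also deliberately omits instrument physics that the template
mechanism does not depend on: bridge-amplification chemistry, phasing and
pre-phasing, colour-matrix estimation from data, lane/swath camera
mechanics beyond per-cycle translation, and alignment with mismatches.

## Numerical and degenerate-input choices

* Coordinates are 0-based, x along columns, y along rows; cluster centres
  are real-valued; offsets translate whole cycle images.
* Local-maximum ties on plateaus break by comparing strictly against the
  N/W/NW/SW neighbours and non-strictly against the rest, so a flat
  plateau yields exactly one deterministic peak.
* `rank_cycles()` ties break to the earlier cycle.
* All-zero images detect zero spots (not an error); empty templates are
  errors for registration and extraction.
* Positions whose extraction window leaves the image are flagged and read
  as `N`; they are excluded from yield metrics.
* Ratios in summary tables round half away from zero.
* The high-quality filter reads "above Q20" strictly (Q >= 21), documented
  and configurable.
* Sub-pixel registration refinement is clamped to half a pixel around the
  best integer shift; a non-concave score triple falls back to the integer
  optimum.
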