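---
title: "Methods: from multichannel sEMG grids to task-discriminating activation maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from multichannel sEMG grids to task-discriminating activation maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

High-density surface EMG (HD-EMG) records monopolar potentials from a 2-D
array of closely spaced electrodes (10 mm pitch here) over a muscle. The
pixel-wise RMS of those channels forms an *activation map* whose intensity
and spatial distribution carry information about which muscles are active,
how strongly, and where — information a single bipolar channel cannot
provide. This vignette explains the models and procedures the package
implements, the choices behind its defaults, and what its synthetic tests do
and do not demonstrate about real recordings.

## The processing chain

For every recording the pipeline runs, in order:

1. **Detection features.** Each channel's 3 s analysis window is split into
   six non-overlapping 500 ms epochs. Per epoch we compute the relative
   spectral power below 12 Hz (`p_lt`), the relative power at the mains
   frequency and its first four harmonics (`p_linet`, 50–250 Hz, ±2 Hz per
   line), and the RMS amplitude; features are epoch means. The PSD estimator
   is the magnitude-squared FFT of the rectangularly windowed epoch
   (2 Hz resolution at 2048 Hz / 1024 samples). A dead (all-zero) channel
   gets spectral fractions of 0 rather than `NaN`, so the amplitude rule —
   not the spectral rules — is what flags it.
2. **Channel quality control.** A threshold expert system (below).
3. **Activation map.** Channels are band-pass filtered 12–350 Hz with an
   order-4 Butterworth applied forward and backward (zero net phase), then
   the map pixel is the mean of the six epoch RMS values. Flagged channels
   are replaced by Delaunay-based bicubic surface interpolation over the
   remaining electrodes; cells outside the convex hull of valid electrodes
   take the nearest valid neighbour's value.
4. **Segmentation.** The h-dome transform (grayscale reconstruction of
   `I - h` under `I`, subtracted from `I`) keeps every dome at least `h`
   above its surroundings, merging multiple local maxima — produced on real
   arrays by electrode-to-electrode impedance differences — into one global
   active region. A grayscale opening with a radius-1 disc (the 5-pixel
   cross) then removes isolated single-electrode peaks. Connected components
   of the strictly positive residue are the candidate regions; the selected
   region is the one containing (or nearest to) a seed electrode, by default
   the anatomical reference electrode of the grid.
5. **Geometry and features.** Map coordinates are normalised to fractions of
   limb circumference (x) and segment length (y) about the reference
   electrode; maps from different subjects are resampled by separable cubic
   splines onto a common grid (twice the densest source resolution over the
   intersection of ranges, so nothing is extrapolated) and averaged, with a
   pixel-wise variability map (sd / mean). Each condition is summarised by
   the mean map intensity over the selected region (`rms_av_hd`), the RMS of
   one differential channel pair 10 mm apart along the fibre direction
   (`rms_av_bip`), and the medians `mu_x`, `mu_y` of the per-axis maxima
   profiles of the segmented map.
6. **Statistics.** Blocked and repeated-measures Friedman tests,
   Bonferroni-corrected decisions, Wilcoxon signed-rank pairwise
   comparisons, and leave-one-out linear discriminant classification of
   tasks (4 classes) or task × effort conditions (12 classes) with
   micro-averaged accuracy/sensitivity/specificity/precision.

## The channel-quality expert system

Thresholds are derived from a *reference* subset of channels whose `p_lt`
and `p_linet` both lie within 1.5 interquartile ranges of the set medians
(median and IQR because of their robustness to the very outliers being
hunted; a zero IQR degrades the comparison to equality). The spectral
thresholds are

- `thresh_lt = k1 * median(p_lt, ref) + 1.5 * IQR(p_lt, ref)`, default
  `k1 = 11.2`;
- `thresh_linet = min(0.85, k_line * median(p_linet, ref) + 1.5 *
  IQR(p_linet, ref))`, default `k_line = 2.5` — a channel with more than
  85% of its power in the mains lines is always an artifact.

The constants multiply only the median term; a configuration switch
(`k_scales_whole_expression`) provides the alternative parse, which changes
little in practice because the IQR term is small for clean sets.

The amplitude rule is local. Around channel (i, j), three opposite-neighbour
pairs are formed — longitudinal (i±1, j) and the two diagonals — and the
neighbourhood threshold is `min(pair means) + k2 * max(pair sds)` (default
`k2 = 0.2`; the sd of a two-element pair uses the n−1 convention,
`|a−b|/√2`). Missing border neighbours are mirror-padded. Opposite pairs make
the means first-order insensitive to the spatial gradient of the map, so the
threshold tracks the local activation level.

One decision here deviates from the bare formula and deserves its
rationale. Comparing the channel RMS directly against that threshold flags
any channel that happens to fall below the *minimum* pair mean plus a small
margin — on homogeneous or smoothly varying regions that is close to a coin
flip (we measured ~80% of clean channels flagged on smooth synthetic sets),
because the threshold sits *above* the local level by construction. What
identifies the motivating artifact — an isolated electrode with poor contact
— is a channel *much* lower than its neighbourhood, not marginally lower.
`classify_channels` therefore requires a genuine deficit: a channel is
flagged by the RMS rule when its RMS falls below `rms_deficit_frac` (default
0.5) of the neighbourhood threshold. Setting `rms_deficit_frac = 1` recovers
the literal comparison. The default direction is `below` (low outliers); the
`both` direction adds a symmetric test for abnormally high channels. This
gate preserves the distinction the rule exists for: an isolated low channel
inside an active region is flagged, while an equally low channel whose
neighbours are also low (an inactive region or innervation zone) is not.

The constants `k1` and `k2` are tuned on labelled sets by grid search,
pooling confusion counts across sets, under either the ROC criterion
(minimum distance to (0, 1) in (1−specificity, sensitivity) space) or the
precision–recall criterion (minimum distance to (1, 1) in (specificity,
precision) space); ties break to higher accuracy, then smaller constants.
PR tuning is the default for offline map cleaning: false positives are
costly there because wrongly discarded channels impoverish the surface
interpolation. Expert-label utilities (odd-rater majority vote and Fleiss'
kappa) support building such labelled sets.

## Segmentation choices

- **Dome height `h`.** No universally correct value exists; the default is
  relative, `h = 0.25 · (max − median)` of the map, which scales across
  effort levels without per-map tuning. An absolute mode is available. In
  the full pipeline (`process_recording`) the fraction escalates (0.25 →
  0.5 → 0.75) if the opening erases every region — on small or very peaked
  maps the top slab of a dome can be thinner than the structuring element.
- **Flat maps.** When a map's total relief is below an absolute `h`, no dome
  of height `h` exists; the transform's residue would be a meaningless
  whole-grid slab, so segmentation reports "no region" instead. With the
  fractional default this situation cannot arise, but purely noise-driven
  maps will still segment *something*; the seed-based region selection and
  the opening are what keep inactive arrays from contributing spurious
  regions.
- **Connectivity** is 8-connected by default (MUAP spread on a 10 mm grid is
  not axis-aligned); the disc of radius 1 is the city-block cross, with a
  3×3 square available.
- Region labels are ordered by decreasing peak dome height; note that after
  the transform, a *broader* dome can out-peak a taller-but-narrower one,
  so selection should use the seed, not the label order.

## The synthetic-data generator

No public HD-EMG grid dataset accompanies the method, so the package ships a
generator whose defaults are the study conditions used by every test:

- **Signal model.** Channels are independent Gaussian noise shaped to the
  15–350 Hz EMG band (order-6 band-pass magnitude skirt, keeping ≥95% of
  power inside 10–400 Hz) and scaled so each channel's RMS equals a spatial
  profile: a sum of 2-D Gaussian blobs plus a 0.01 floor. Downstream stages
  use only band powers and RMS values, which is why a noise model suffices;
  no motor-unit action-potential trains, conduction velocity or force
  dynamics are simulated.
- **Spatial realism.** Blob widths (sd 25–45 mm) are set so the activation
  profile is bell-shaped along the fibre direction across the full array —
  arrays are placed over muscle bellies — which is the regime in which the
  neighbourhood RMS rule attains its high specificity.
- **Artifacts.** Three classes with ground truth: drift (sinusoids below
  5 Hz), power-line (50 Hz and four harmonics), both parameterised by the
  added-RMS/channel-RMS ratio (3–8 by default), and isolated amplitude
  anomalies (gain 0.02–0.1 by default — the low-contact case the `below`
  rule targets; high-gain anomalies are available explicitly). Prevalence
  per recording is uniform on 0–13%, the range reported for real arrays;
  the class mix is configurable because no per-class breakdown is reported.
- **Task/effort/subject structure.** Five muscle arrays (two 8×15 upper-arm,
  three 6×17 forearm), a co-activation weight per (muscle, task) chosen to
  mimic agonist/antagonist load sharing at the elbow, a linear effort gain
  reaching the weight at 50% MVC, log-normal inter-subject multipliers
  (sdlog 0.25, putting pixel variability in the 10–30% range typical of
  between-subject map studies), an effort-dependent lateral shift of the
  activation centre (0/2.5/5 mm at 10/30/50% MVC), and a per-(subject,
  muscle) electrode-placement jitter (sd 5 mm) that penalises
  position-sensitive features — the mechanism by which single bipolar
  channels lose classification accuracy relative to map features.

Passing tests on these data show that the pipeline's machinery — detection
rules, morphology, interpolation, geometry, statistics — is implemented
correctly and behaves as intended under controlled conditions. They do not
certify performance on real recordings, where channels are spatially
correlated, artifact classes are messier, activation is non-Gaussian in
space and nonstationary in time, and expert labels are imperfect.

## Numerical conventions

- Epochs are `round(epoch_ms · fs / 1000)` samples; the PSD excludes the DC
  bin; band membership is inclusive on both edges.
- The projection median interpolates the cumulative mass linearly with each
  coordinate's mass centred on it, so a symmetric profile yields the exact
  centre and a delta profile its own coordinate; the discrete equal-area
  identity rarely holds exactly on a grid.
- Friedman tests rank all `reps × k` values of a block jointly with
  midranks; the statistic uses the empirical rank variance per block, which
  reproduces the textbook tie correction exactly at `reps = 1` and equals
  `n(k−1)` under unanimous strict rankings.
- LDA uses pooled within-class covariance and uniform priors (the simulated
  design is balanced); a singular pooled covariance falls back to a small
  ridge (`1e-6` of the mean diagonal), with a message.
- Steady-window selection minimises force variance over a 100 ms-stride
  sliding search, earliest window on ties.
- Problem sizes in the shipped checks: 20 labelled sets for detector tuning,
  100 random 8×12 grids for the morphology oracles, 12 simulated subjects ×
  4 tasks × 3 efforts × 5 arrays for classification, 1000 replicates for
  test size.

## Known limitations

- Channels are generated independently; real monopolar neighbours share
  most of their signal. Features that depend only on per-channel RMS and
  band power are unaffected, but the bipolar difference RMS is larger
  relative to the monopolar level than on real skin.
- The generator's lateral shifts and co-activation weights are stylised;
  they create discriminable structure but no claim of physiological
  fidelity.
- EDF import is not provided; recordings exchange as delimited text or flat
  float32 plus a JSON sidecar.
- The watershed alternative to h-dome segmentation is intentionally out of
  scope, as are spatial (Laplacian) filtering, innervation-zone localisation
  and fatigue indices.
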