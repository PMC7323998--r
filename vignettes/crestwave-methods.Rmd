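---
title: "Models and methods behind crestwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crestwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(crestwave)
```

`crestwave` analyses 4D live-imaging data of the two cranial neural crest
(NC) waves that colonise the zebrafish eye, and ships a synthetic-embryo
generator that emulates the study conditions so that every downstream stage
can be validated against known ground truth. This vignette explains the
models, the defaults and why they were chosen, the numerical choices, and
what the synthetic validation does and does not establish about real data.

## Geometry

The embryo frame is right-handed with `axis_ap = +x` (anterior),
`axis_ml = +y` (lateral, toward the tracked eye) and `axis_dv = +z`
(dorsal); coordinates are micrometres, times are hours post fertilisation
(hpf). The eye is a sphere (default radius 50 µm) with the lens at its
lateral pole; the proximodistal unit vector is
`u = normalize(lens_center − eye_center)`, so `(p − c)·u > 0` is the
distal, lens-facing hemisphere and `(p − c)·u < 0` the proximal,
brain-facing one. A *mirrored* flag models the contralateral eye by
flipping `u` along the mediolateral axis. Cells "in the eye" are those in
a spherical shell of half-thickness 6 µm around the eye surface — the
ocular NC cells of interest crawl on the optic cup rather than inside it.

## The two-population simulator

Each founder cell belongs to one population with its own schedule:

* **1NC** (default 90 founders) delaminates at 12–14 hpf from a lateral
  stripe zone, migrates at 0.8 µm/min toward a random target on the
  proximal hemisphere (targets with proximodistal coordinate between
  −0.95 R and −0.15 R), and settles there. Settled cells are clamped to
  the shell and to the proximal side of the equator. After 22 hpf settled
  1NC cells creep slowly (0.25 µm/min) in a horizontal direction 55° from
  anterior toward the distal side, stalling at a per-cell random depth
  short of the equator. The creep direction and its magnitude are a
  qualitative calibration to the modest distal-ward drift observed for the
  proximal group after 22 hpf; the per-cell stall depth
  keeps the sheet spread over the hemisphere instead of piling up at the
  equator.
* **2NC** (default 22 founders) appears at 16–17 hpf in a mediodorsal zone
  at the diencephalon/mesencephalon level, is attracted to a dorsal
  periocular cluster centre (mean-reverting Ornstein–Uhlenbeck attraction
  with stationary spread 9 µm, reversion 1/h), and is kept outside the
  ocular shell until the entry phase. From 22 hpf cells leave the cluster
  (staggered departures over ~0.9 h), cross a dorsal-rim waypoint and then
  crawl over the eye surface (great-circle steps at 1.5 µm/min) to a
  target on the distal cap (proximodistal coordinate 0.5–0.95 R), where
  they settle. With defaults, all 2NC founder lineages are programmed
  distal, which places 20–30 cells in the distal eye by the end of the
  entry window (22–28 hpf) — the calibration the generator is held to.

Positional jitter is diffusive, 0.3 µm per √minute per axis; settled cells
are quiescent (40 % of that), reflecting the epithelial arrangement of
settled ocular NC. Speeds and the division rate are free parameters — the
study reports behaviour, not dynamics — set to values typical of cranial NC
migration.

**Divisions** are a per-cell Poisson process (default 0.05/h) active during
12–22 hpf; divisions cease at cluster dissolution, when the entering cells
shift to differentiation. Sister nuclei start ~1.5 µm apart and separate
over ~25 min of post-mitotic drift to 7 µm — one nuclear diameter, the
closest physically meaningful arrangement (an instantaneous large
displacement would be artefactual, and sisters closer than the PSF could
not be resolved anyway).

**Mixed lineages.** With probability `mixing_fraction` (default 0.09,
echoing the observed 9 %) a founder lineage is programmed
mixed-destination: at its first division the second daughter's subtree is
assigned the opposite hemisphere programme. Because divergent daughter
fates can only be realised at a division, mixed-programmed lineages are
guaranteed at least one division; without this the recovered mixing
fraction would be biased low by the lineages that happen never to divide.
A consequence worth noting: under wildtype defaults a few 1NC-derived
cells legitimately end distal (the study's ~3.6 %), so the schedule
property "no 1NC cell in the distal hemisphere" and the defect call on
wildtype hold for `mixing_fraction = 0`, and the strict defect criterion
(`max_1nc_distal = 0`) is best applied to genotype screens simulated
without mixing.

**Genotypes.** `pax6b_null` keeps the 2NC cluster periocular (no distal
entry); `pax6_double_null` additionally releases 1NC cells across the
equator (half of the founders draw distal targets). These are behaviour
switches only — no attempt is made to model mutant anatomy such as the
missing lens.

**Reporters.** The sox10-driven green pool follows
`dG/dt = k_syn·a(t) − k_deg·G` with `a(t)` a hard promoter switch (on from
birth until 16 hpf for 1NC, 20 hpf for 2NC), `k_syn = 1` AU/h and a 12-h
half-life chosen so converted red fluorescence persists to ~48 hpf.
Photoconversion at time `t` sets `R ← R + G, G ← 0` for every live cell
and re-integrates forward; daughters inherit the parent's pools. With
conversion at 17 hpf, the green fraction `G/(G+R)` at any later time
separates the populations exactly — by construction of the hard switches —
which is why the classification property demands zero errors. Wnt-reporter
intensity is the sum of two Gaussian waves in time (peaks 14 and 21 hpf,
amplitudes 30 and 150 AU); the second wave is carried by a random half of
the 2NC lineages (`wnt_wave2_fraction = 0.5`).

The frame interval defaults to 20.4 s so that a 10-frame stride equals
3 min 24 s, the stride used for angle sampling; it is configurable because
acquisition series at 26 s exist as well.

## Rendering and detection

Each cell contributes a separable anisotropic Gaussian blob
(σ = FWHM/2.355; FWHM 1.5 µm lateral, 6.6 µm axial) scaled by
`gain × pool`, on a constant background, with Poisson shot noise plus
Gaussian read noise. Detection smooths at the PSF scale (FFT-based
separable convolution in voxel units derived from physical µm — anisotropy
is mandatory metadata, never assumed away), computes a negated
finite-difference Laplacian with physical spacings, and takes local maxima
above `median + k·MAD` (k = 5) of the response. Two guards matter in
practice: the threshold has a relative floor (2 % of the response peak) so
noise-free frames do not promote numerical ripple, and candidates within
one PSF σ of the array faces are discarded (boundary artifacts of circular
smoothing). Sub-voxel positions come from an intensity-weighted centre of
mass over a 3-voxel-radius neighbourhood of the background-subtracted
frame; on noiseless frames the localisation error is well under half a
voxel per axis. At the study-like density (~1 cell per 17-µm box) and
peak ≈ 10× background, detection F1 is 1.0 on the tested fields
(60 nuclei in a 120 × 120 × 48 µm stack).

## Tracking

Frame-to-frame linking solves a gated linear assignment problem per frame
pair: candidate pairs within `gate_um` cost their squared distance, and
every detection can stay unmatched at cost `gate_um²` (padded square LAP,
solved exactly by the Hungarian method via `clue`). The matching therefore
maximises gated links while minimising total squared displacement, and is
verified in tests against exhaustive enumeration for up to 7 points per
side. Unmatched next-frame detections within 1.5× the gate of a
once-matched predecessor are attached as second children; among eligible
predecessors the one closest to the midpoint of the two would-be sisters
wins (at cytokinesis the mother lies between her daughters), with
competing orphans resolved by a second small assignment. Track ends may be
re-joined across ≤ 2 skipped frames with a per-frame cost penalty. The
forest is obtained by contracting linear chains; children are ordered by
planar angle, then id, for reproducibility.

Tracking fidelity is evaluated on a 1-minute sampling of the default
embryo (~170 cells, 1200 frames, detection jitter 0.3 µm): edge F1 ≈ 0.99
and division recall ≥ 0.9. The sampling interval matters: at 4-minute
sampling the cluster's diffusive jitter produces frame-to-frame jumps
comparable to the sister separation, and cluster divisions become
genuinely ambiguous for any nearest-neighbour linker — the acquisitions
this pipeline emulates ran at 20–26 s precisely to avoid that regime.
Note that mid-movie delaminations are indistinguishable from divisions
without appearance information, so newly appearing founders near existing
cells can create spurious division events; edge scores are insensitive to
this, and the exact closed-loop property is therefore tested on a fixture
without mid-movie appearances.

## Fate analysis

Selections are geometric predicates (half-spaces about the equatorial
plane, the ocular shell, boxes, spheres, and boolean combinations)
evaluated at a reference stage; backward propagation follows unique
ancestor paths, forward propagation collects descendants, mirroring the
17 → 11 hpf and 17 → 31 hpf tracking strategy. Destination labels at
`t_eval` (default 30 hpf): inside the shell, distal/proximal by the sign
of the proximodistal projection with a configurable margin (default 0;
the exact-equator tie breaks proximal, a documented convention); outside
the shell, periocular; dead terminals, unlabelled. Lineage homogeneity
uses only proximal/distal terminals — the published dichotomy — with
periocular terminals ignored and label-free lineages excluded from the
denominator but counted. Percentages round half-away-from-zero, matching
the published "39 % (9/23)" style (7/8 → 88 %).

## Circular statistics

Angles are sampled every `stride` frames from horizontal-plane
displacements, measured from anterior toward the tracked eye's distal
side, in [0, 360); steps shorter than 0.5 µm are discarded to suppress
stationary jitter. **This convention is load-bearing**: median directions
are only comparable between analyses using the same reference and sign.
The circular median minimises the summed wrap-around distance
`d(a,b) = min(|a−b|, 360−|a−b|)`; the objective is piecewise linear with
valleys exactly at data angles, so the data-point minimiser (ties → the
smallest angle) is also the global one — the property tests exploit this
by comparing against a 1° grid on integer samples. The Wallraff test
reduces each angle to its circular distance from its own group's median
and applies a two-sided Mann–Whitney test with midranks: exact permutation
enumeration for `nA + nB ≤ 12`, otherwise the tie-corrected normal
approximation without continuity correction — the within-group median
estimation already makes the procedure slightly conservative, and the test
is used at large n (null rejection ≈ 0.042–0.049 at 0.05 in the 2 000-run
calibration at n = 100 per group). p-value floors ("< 2.2e-16") exist
only in formatted output.

On wildtype simulations the distal-destined group's median direction
exceeds the proximal group's (echoing the published 83.6° > 56.5°); the
medians themselves are realisation-dependent and are reported, not
asserted.

## Reporter statistics

Background subtraction removes the per-slice median and clips at zero;
colocalization is the pixelwise product of background-subtracted channels
(the ImageJ "Multiply" idiom) with per-cell mean-product scores; reporter
positivity defaults to `median + 3·MAD` of the per-cell intensities;
intensity profiles are unsmoothed per-timepoint means with the cell count
alongside (the published profile's normalisation is unspecified, so none
is applied). Welch's t from `mean ± SD (n)` summaries uses sample SDs
(n−1) — required to reproduce printed t/df from printed summaries — with
Welch–Satterthwaite degrees of freedom.

## Problem sizes and what the tests show

The default test and acceptance runs use: the full default embryo at
4-minute sampling for fate/penetrance/photoconversion checks (~240
segments), the native 20.4-s grid for angle statistics, a 1-minute
sampling for tracking fidelity, 220 founder lineages for mixing-fraction
recovery (at 0, 0.09 and 0.5, each within its 95 % binomial interval),
and 2 000 replicates for rank-test calibration. All randomness flows from
the single config seed; identical config and seed reproduce bit-identical
exports.

Passing these checks shows the pipeline is internally correct — detection
recovers rendered nuclei, the linker reconstructs known lineages, the
statistics match their oracles and the published worked examples. It does
not certify performance on real DSLM data, where nuclei deform and touch,
intensity varies with depth, optics drift, and manual curation remains
part of any honest lineage analysis. The simulator also simplifies
biology: hard promoter switches, Gaussian reporter waves, straight-line or
great-circle guidance instead of cue-driven migration, and no tissue
mechanics; mutant modes switch behaviour without modelling anatomy.

## Known limitations

* The detector is a stand-in validated only against synthetic truth; no
  deconvolution, fusion or bleaching correction.
* Delamination vs division is undecidable from positions alone (see
  above).
* Whether published mixed-lineage counts enumerate lineages or cells is
  ambiguous; the simulator programmes mixing per lineage and documents
  that choice.
* Destination fractions are evaluated at a single `t_eval`; windowed
  occupancy would need a different estimator.
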