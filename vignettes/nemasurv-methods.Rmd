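---
title: "Methods: automated killing-assay analysis in microfluidic chambers"
author: "nemasurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated killing-assay analysis in microfluidic chambers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemasurv)
```

## The problem

A killing assay tracks how many *C. elegans* survive as a function of time
after exposure to a pathogen. Performed in a sealed microfluidic chamber and
imaged every hour, the assay can be scored entirely from the images: worms
are confined (none are ever lost, so no censoring is needed), they appear
much darker than the background in bright-field, and a dead worm degrades
within hours into a faint cuticle trace. `nemasurv` implements the full
image-analysis chain for such assays — masking worm pixels, splitting
clusters of touching worms into individuals, scoring each worm dead or
alive from its opacity, quantifying per-worm fluorescence and motility, and
building survival curves — together with a ground-truthed synthetic scene
generator that makes every stage testable without a microscope.

Pixel units throughout correspond to a low-magnification (~2.5x) view in
which a young adult worm is roughly 100 px long and 10 px wide. Darkness is
defined as `1 - normalized intensity`, so "darker" is always the larger
number.

## Worm masking and the single-worm area model

Worm pixels are found by comparing each pixel's darkness with a local
background estimate: a median filter whose window (default radius 31 px,
about three worm widths) is too large for a worm to bias, so pillar shading
and illumination gradients stay in the background. Pixels exceeding the
background by `max(k * sigma_bg, contrast_floor)` are worm candidates;
`sigma_bg` is a robust (MAD) estimate of the residual noise and the
contrast floor (default 0.2) keeps faint stationary structure — pillar
disks in particular — out of the mask when the noise is very low. Holes are
filled (the gut interior can be brighter than the cuticle) and components
below a debris cutoff are dropped, which removes eggs and progeny small
enough to pass the chamber's worm filters.

Each 8-connected component of the mask is one worm or several touching
worms. Because single-worm components are the most abundant in a chamber,
the single-worm area is estimated from the component-area distribution: a
histogram with bin width 0.25x the median component area locates the
dominant mode among areas below 1.6x the median, and an iterated windowed
mean (areas within [0.5, 1.55]x the running estimate, three iterations)
then estimates the mean single-worm area. The windowed mean matters:
worm-to-worm size variation makes the raw mode a biased estimator of the
mean area, and it is the mean that calibrates worm counting
(`round(component area / single-worm area)`, clamped to at least 1).
Components near the single-worm area also calibrate the single-worm
skeleton length (the "length ruler") and trunk width (an upper quantile of
the medial half-width, since the taper toward the tips would bias a median
low).

## Separating touching worms

The chamber is shallow enough that worms cannot cross over each other, so
any apparent overlap is side contact. This makes the separation problem
solvable from silhouette geometry alone:

1. **Body parts.** The component is skeletonized (Zhang–Suen thinning,
   after pruning short spur branches) and the distance transform gives the
   local half-width along the skeleton. Skeleton stretches whose half-width
   is at most 1.6x the single-worm half-width are single-worm *body parts*;
   thicker stretches and branch points are *junctions* where worms touch.
   The narrowness factor is deliberately tolerant — worms sampled at width
   10 ± 2 px vary enough that a tight cut (e.g. 1.3x) shatters wide worms'
   trunks — and contacts still register as junctions through skeleton
   branch points even when the contact zone is not much thicker than one
   body.
2. **Turn-angle prohibition.** The signed turn angle along the component
   boundary (angle between 5 px chords) is small on a genuine worm
   silhouette, whose bending radius is limited by body stiffness; turns
   sharper than 70° mark worm–worm contact points. Each boundary arc
   connecting two part endpoints across a junction is scanned: if it
   contains a sharp turn, connecting those two parts is prohibited
   (symmetrically).
3. **Junction resolution.** Among the remaining pairings, endpoints are
   matched to maximize geometric continuity: a weighted sum of tangent
   continuity (cosine between one part's incoming medial tangent and the
   reversed tangent of the other, weight 0.3) and positional alignment
   (cosine between the tangents and the endpoint-to-endpoint direction,
   weight 0.7). The positional term carries more weight because the
   hardest junctions are parallel-lying worms, where all tangents agree
   and only position disambiguates. Matching is exhaustive (junction
   degree is small); endpoints may stay unmatched, and pairs with
   non-positive continuity are never forced. When crowded contacts leave
   *every* pairing prohibited, near-straight continuations (score > 0.5)
   are still admitted; a junction where even that fails is flagged
   unresolved. Large junctions that no pairing traverses — for example the
   middle animal of a three-worm parallel bundle, whose entire body is
   "thick" — are kept as low-confidence worm candidates of their own.
4. **Chain splitting.** Matched parts merge into chains. Worms touching
   end-to-end produce one long chain that no junction can split; it is cut
   into `round(length / ruler)` pieces. Where the body-width profile along
   the chain shows pronounced interior dips (two tapered tips meeting), the
   dips refine the cut positions and can justify one more worm than the
   average-length ruler alone — worm length varies, the ruler is a
   population mean. Without dips the cuts are equally spaced, which is
   unbiased when the true contact point is unknown.
5. **Pixel assignment.** Every component pixel is assigned to the nearest
   final medial path by breadth-first search *inside the mask* (geodesic
   distance), so pixels never leak across a worm lying in between.

A component reports itself fully resolved only when every junction was
matched *and* the resulting worm tally agrees with the component's
area-based count; two independent counts disagreeing is reported as
unresolved residue even if each junction looked consistent. The final
count itself comes from the chains: enforcing the area quotient was tried
and discarded, because under realistic size variation the quotient is the
noisier of the two counts and forcing it measurably reduced the fraction
of correctly recovered worms.

On 200 random synthetic clusters of 2–5 worms with mixed side- and
end-contacts, 81–84% of clustered worms are recovered with at least 0.7
intersection-over-union against ground truth (see
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`). The
residual failures are dominated by parallel bundles of three or more worms
and by pairs of unusually small worms whose combined area rounds to one.

## Dead or alive

A worm's opacity is the mean darkness over its pixels. Live worms are
opaque (dark gut granules); a cadaver degrades rapidly, leaving a faint
trace within a few hours. The dead/alive threshold is the mean darkness of
a ring-shaped neighborhood around the worm (one worm width wide, excluding
all worm pixels) plus a multiple (default 1) of the darkness standard
deviation of the image. Two details matter:

- **The sd term is frozen at the assay's first frame by default**
  (`viability$sd_scope = "assay"`). The per-frame sd collapses late in the
  assay as the cohort dies and cadavers fade, which would silently lower
  the bar for "alive"; freezing the term keeps one fixed threshold per
  assay while the neighborhood mean still adapts to local shading. A
  per-frame mode (`"frame"`) and a fixed scalar mode are available.
- **Equality counts as dead** (opacity <= threshold), making the dead set
  closed and the call deterministic.

Because the post-mortem opacity drop is fast — the default synthetic decay
is an immediate drop to 40% of the live excess followed by exponential
decay with a 1 h half-life, leaving ~1.5% by 4 h — the precise threshold is
uncritical: across sd multipliers spanning [0.75, 2], estimated times of
death move by at most 2 h, less than the resolution of a manually scored
assay. Multipliers below ~0.75 are not sensible: the threshold then
approaches the residual darkness of a two-hour-old cadaver, and death
calls drift later than the 1 h imaging interval can support.

The time of death is the first frame at which the dead call holds and
persists to the end of the series; a dead call followed by re-emergence is
logged as a segmentation anomaly and the last alive-to-dead transition is
used. Worms are not tracked across frames (identity tracking is out of
scope); survival counting is population-based — the number of alive worms
per frame — which is exact because worms cannot leave the chamber.

## Per-worm quantities

- **Fluorescence**: sum over the worm's pixels of
  `max(0, intensity - background)`, background being the median intensity
  of non-worm pixels; additive over any split of the pixel set.
- **Motility**: two bright-field frames ~1.3 s apart; motility is the
  fraction of the worm's pixels in the later frame not covered by worm
  pixels in the earlier frame (0 = still, 1 = fully displaced). The
  later-frame area is the denominator, implementing the definition
  literally; the measurement is absent — never silently 0 — when the
  earlier frame is missing.
- **Population summaries**: per-time empirical CDFs, means and standard
  deviations, and pairwise two-sample Kolmogorov–Smirnov tests between
  time points. The CDFs matter because infection broadens distributions
  in ways the mean hides; time points with fewer than 3 worms are flagged
  low-n.

## Survival curves

In a sealed chamber no worm is lost, so the survival curve is the plain
alive fraction `S(t) = alive(t) / n0` with binomial standard errors
(Greenwood's formula reduces to exactly this without censoring). Isotonic
(pool-adjacent-violators) correction repairs occasional count increases
caused by segmentation jitter, and is logged when applied. Death times are
interval-censored by the 1 h imaging interval; events are assigned to the
right endpoint, the frame at which the dead call first holds.

For plate-style records, where 10–20% of worms are typically lost and must
be censored, `kaplanMeier()` provides the product-limit estimator with
Greenwood standard errors (delegating to the survival package; the
identity between Kaplan–Meier without censoring and the chamber estimator
is a test invariant). `compareCurves()` reports median survival times
(linear interpolation within the bracketing step; beyond-range medians are
`Inf`), pointwise differences, and the log-rank test when records are
available. Both binomial and Greenwood standard errors are thus available,
since published error bars rarely state which was used.

## The synthetic scene generator

The generator emulates the statistical and geometric structure the
analysis relies on, not photorealism:

- **Worms** are smooth midlines whose heading follows a damped sinusoid
  (random phase, amplitude up to ~0.7 rad), swept with a tapered width
  profile and rasterized; length 100 ± 15 px and width 10 ± 2 px by
  default. Midlines that would self-intersect are rejected and re-drawn.
- **Clusters** are built by sliding a new worm toward the group until the
  silhouettes first touch, then backing off one pixel — contact without
  overlap, exactly the constraint the chamber height imposes. Side contact
  places the newcomer parallel (with an independent posture) or obliquely
  against a member's flank; end contact continues beyond a member's tip
  with angular jitter. Every cluster is verified to be one connected
  component.
- **Scene**: darkness 0.1 background, 0.7 live worms, a hexagonal lattice
  of slightly dark (0.25) pillar disks of radius 5 px at 45 px pitch, and
  additive Gaussian noise (sd 0.02). Worms may occlude pillars — a worm
  crawling past a pillar base covers it in projection — rather than being
  placed around them, which would make placement of 100 px worms
  infeasible in a bounded number of retries.
- **Death** drops a worm's darkness excess immediately to 40% of the live
  value, then halves it every hour: cadavers are dramatically fainter than
  live worms within 4 h, matching the rapid degradation the method relies
  on.
- **Time lapse**: hourly frame pairs ~1.3 s apart; live worms displace
  between pair frames with per-worm speeds (0–8 px/s by default), dead
  worms stop; per-worm fluorescence is deposited uniformly over the body.
  Worm positions are otherwise held fixed between hours — real worms
  relocate, but since no stage of the analysis links identities across
  frames, hourly repositioning would only slow the tests without
  exercising any additional code path.
- Everything is deterministic given the `SceneSpec` (including its seed);
  ground truth (label image, per-worm areas, midlines, viability,
  deposited fluorescence) is exact.

What passing tests on these scenes do *not* show: robustness to uneven
illumination beyond what the median-filter background absorbs, to thick
opaque bacterial lawns, to worms pressed against chamber walls, or to
optical blur — real bright-field point-spread structure is absent, so the
synthetic contrast between worm and background is cleaner than reality.
The separation benchmark should therefore be read as an upper bound of
what the same configuration achieves on real frames.

## Problem sizes and numerical choices

The shipped tests run the whole chain at desk scale: 560–760 px scenes,
30-worm calibration chambers, 200-cluster separation benchmarks, 50-worm
time-of-death sweeps, 50-seed survival simulations. Tie-breaks and
degenerate inputs are handled explicitly: matching ties fall to the first
enumeration order (deterministic); components thinner than 2 px everywhere
are treated as a single part; contours shorter than three turn-angle
windows are an error; empty masks yield empty component lists; a
single-worm component passes through separation with its exact pixel set
and confidence `"isolated"`. All randomness flows from a single integer
seed per scene or per pipeline run, and a pipeline rerun with the same
configuration and seed is byte-identical in its measurement tables.

## Known limitations

- Worm identity is not maintained across frames; per-worm time series in
  the tests use ground-truth labels, and real longitudinal phenotyping
  would need a tracking layer on top.
- Dense clumps (say six or more worms in one component, or three worms
  lying in a parallel bundle) often defeat junction resolution; the
  affected components are flagged rather than guessed.
- Two small touching worms whose combined area rounds to one worm are
  genuinely ambiguous under area-based counting and are usually merged.
- The plate-assay path (Kaplan–Meier, lost-worm courses) expects tabulated
  records; scoring plate photographs is out of scope.
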