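---
title: "Methods: scoring, hit calling and downstream analysis of a yeast inclusion-formation imaging screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, hit calling and downstream analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inclusionscreen)
```

## Scope and model

`inclusionscreen` reimplements, as a tested pipeline, the analysis chain of a
genome-wide high-content imaging screen for regulators of synphilin-1
(dsRed-tagged) inclusion formation in *Saccharomyces cerevisiae*:

1. **Image quantification** — per-field fluorescence images are shade
   corrected, a background map is estimated, cells are isolated as regions at
   least 300 grayscale units above local background, inclusions as
   within-cell regions at least 400 units above the cell's diffuse level, and
   the two masks are combined into the screen phenotype: the percentage of
   signal-bearing cells that carry an inclusion, plus the mean cellular
   intensity used as an expression-level control.
2. **Hit calling** — per strain, replicate phenotypes are compared with the
   wild-type reference (his3Δ-style control) by a two-sample pooled-variance
   Student's t-test; a strain is a hit when the inclusion change is
   significant (P ≤ 0.05), the effect is at least 25%, and the intensity
   control shows no significant change. Strains whose intensity also changed
   significantly are routed to an `expression_confounded` category rather
   than being called hits.
3. **Enrichment** — hypergeometric upper-tail term enrichment of the hit
   genes against the deduplicated array universe (deletion collection plus
   ts-allele collection genes), with Bonferroni or simulation-based
   correction.
4. **Network** — the induced subgraph of a physical-interaction edge list on
   the hit genes; genetic interactions are filtered out entirely and modules
   are connected components.
5. **Cytotoxicity** — generation (doubling) times from 72-hour OD curves
   sampled every 30 minutes; the synthetic-sick effect is the excess
   generation-time increase caused by synphilin-1 expression in a mutant
   over that in the wild type, tested per replicate with the same t-test.

Every stage is driven end to end by a synthetic-data generator with planted
ground truth, because the original ~5,155-strain image set was not deposited.
The published headline counts (148 hits etc.) are therefore *not*
reproduction targets; the package's accuracy claims are property-based.

## The synthetic generator: what it emulates, and what it does not

A field is rendered as a 16-bit image: a flat background (default 200
grayscale units) plus a radially symmetric quadratic vignette (default
amplitude 60), with 40–80 non-overlapping cell discs of radius 4–7 px — the
scoring chain uses only intensity masks, so budding morphology would add
nothing. Each cell carries diffuse signal `diffuse_signal_delta ×
true_expression_scale` above local background (default 800, so a strain at
half expression still clears the 300-unit cell threshold). Each cell is
flagged *aggregated* by an independent Bernoulli draw with the strain's
`true_inclusion_prob`; aggregated cells receive 1–3 puncta of radius 1–2 px
at `inclusion_delta` (default 800) above the diffuse plateau, with total
punctum area capped below 40% of the cell disc so the diffuse level remains
the within-cell majority signal (this is what makes the median a safe
initial estimate of the diffuse reference). Noise is additive Gaussian,
clipped to the camera range; there is no PSF, no bleaching, no bright-field
channel, no focus drift, and cells never touch. A green segmentation test
therefore establishes correctness of the thresholding logic and its
bookkeeping — not robustness to clumping, debris, or optical blur.

Growth curves are lag + *exact* exponential (doubling time
`true_generation_time_h`) + exponential saturation toward the carrying
capacity, so the log2-linear exponential phase has slope exactly `1/g` and
estimator accuracy can be measured against a closed form. OD noise is
additive (SD 0.005 by default, a typical Bioscreen residual); the default
inoculum (OD 0.005) is below the noise floor, as in micro-cultivation.
Curves are emitted blank-corrected; an optical offset can be added via
`blank_od` to exercise blank estimation.

Key stated-world defaults: thresholds 300/400 grayscale units; hit criteria
P ≤ 0.05, 25% minimum effect; sampling 0.5 h over 72 h (145 points);
triplicate replicates; a QC floor of 300 cells per scored well (the screen's
manual-confirmation count; synthetic demonstrations use more fields or a
lower floor because a single synthetic field holds 40–80 cells).

## Numerical and design choices

**Shade correction.** The published chain pre-processes with "shade
correction and background subtraction" without specifying a model. `poly2`
fits a second-order polynomial surface to the dimmer half of the pixels
(cells would bias the fit) and *subtracts* it, adding back its mean: both
detection thresholds are intensity differences, and the generator's
vignetting is additive, so an additive correction is exact for this model
and preserves the image mean. A multiplicative `flatfield_reference` mode is
provided for real flat-field references.

**Background.** Either a tiled-median map (robust while cells cover a
minority of each tile; default tile side 48 px against cells of ≤ 15 px) or
a grayscale opening ("rolling ball"). The background is a *map*, so the
cell threshold is local; a scalar mode falls out as the map's median.

**Inclusion reference.** The 400-unit threshold is defined against
"cellular regions", which varies per cell with expression. The reference is
estimated per cell, starting from the median of the cell's pixels (puncta
are a minority by construction) and refined twice by averaging the pixels
outside the current candidate set — the fixed point on noiseless cells is
the exact diffuse plateau.

**Segmentation plumbing.** Plain 4-connected components with an area gate
(defaults 20–2000 px for the default geometry); no watershed splitting
(the source procedure is silent, and generated cells do not clump). Border
cells are excluded by default because partial cells bias area and intensity.
Minimum inclusion area 2 px suppresses single-pixel noise.

**Effect-size reading.** "At least 25%" is ambiguous between percentage
points and a fraction of the wild-type value. Because the screen reports
WT-anchored normalized values (WT = 50%), the default reads it as relative:
`|pct_mut − pct_wt| / pct_wt ≥ 0.25`; `absolute_points` mode is provided.
Hit p-values are used raw at 0.05 with no multiple-testing correction,
exactly as published; enrichment is where correction is applied.

**Intensity summarization.** Whether the original software averaged per-cell
means or pooled all cellular pixels is unknown; per-cell mean-of-means is
the default, an area-weighted pooled mode is available. The t-test unit is
the replicate well.

**Generation time.** The estimator takes the maximal least-squares slope of
`log2(OD − blank)` over 9-point (4 h) sliding windows, with two quality
gates: candidate windows need fit `r² ≥ 0.98` and must lie entirely above
10% of the curve's corrected maximum. The gates matter: OD noise is
additive, so *relative* noise diverges near the detection floor, and an
ungated max-slope rule preferentially selects noise-inflated slopes there —
with the generator's own noise (SD 0.005) it misses a 2.5 h doubling time by
up to 10%; gated, the worst error over 45 replicate curves is under 5%. The
default blank is 0 (curves exported blank-corrected); `blank = "first3"`
(median of the first three readings) is provided for raw plates. Subtracting
early readings from a curve that starts at inoculation density removes part
of the biological signal (`OD' = N0(2^{t/g} − 1)` is steeper than
exponential at small `t`) and would bias a max-slope estimator; it is
therefore an option, not the default.

**Toxicity test.** Per replicate, `Δg = g(dsRed-SY1) − g(dsRed-only)`;
mutant and wild-type `Δg` samples are compared by the pooled t-test. Two
calibration facts, both established by simulation in the test suite: power
for a +0.5 h planted synthetic-sick effect at triplicate scale is ≈ 100%,
and the empirical type-I level is ≈ 6% rather than the nominal 5% — the
estimator's window-selection errors are non-normal, and a 3-vs-3 t-test is
mildly anti-conservative under that. This is intrinsic to applying a
t-test to selection-based estimates, and is a known limitation, not a
tuning target.

**Hit-caller calibration.** The three-rule caller has a structural ceiling:
rule 3 diverts any strain whose intensity control is significant, and an
exact-level test does that to 5% of true hits regardless of the noise scale.
Expected pure-"decreased" sensitivity is therefore `0.95 × (inclusion
power)` whenever intensity replicates carry i.i.d. noise. The ≥ 95%
recovery benchmark is accordingly run with noiseless intensity replicates
(the only stated noise is SD 3 on the inclusion percentage); under a
realistic intensity SD of 50 units the package demonstrates ≥ 90% pure
sensitivity and ≥ 95% detection when the confounded bin is included.

**Hypergeometric tail.** Summed in log space via `lchoose` with the largest
term factored out; verified against exact integer-arithmetic enumeration for
all N ≤ 30 (binomial coefficients there are exact in doubles) to 1e-12
relative error. Bonferroni is the default correction (deterministic); a
Boyle-style simulation correction (fraction of random same-size hit lists
whose best raw p beats the observed one) is available because the source
procedure cites that method without stating which was used.

**Network.** Physical-only filtering is applied at construction, so no
genetic edge can survive into any export; components come from igraph and
are cross-checked in the tests against a hand-rolled union-find. Module
ordering (size desc, then smallest member) makes exports byte-deterministic.
Complex labels are taken from an optional annotation table, never inferred.

## Degenerate inputs and tie-breaks

- `students_t` with zero pooled variance: equal means → t = 0, p = 1;
  unequal means → p = 0, flagged degenerate.
- Empty masks, empty wells (`n_cells = 0` → NA percentage, QC fail), empty
  edge files and hit lists without annotation are all valid, handled inputs.
- `hypergeom_tail(k = 0, …) = 1` and `k > min(n, K) → 0`, exactly.
- Saturated images (all pixels at the camera ceiling) and flat growth curves
  (no positive-slope window) raise errors rather than returning numbers.
- Overfull fields: cell placement retries are bounded; a field that cannot
  host the requested cell count is rendered with fewer cells, recorded in
  the ground truth.

## What the tests establish

All empirical statements above are computed by the test suite or the
acceptance script at run time: exact ground-truth reproduction on noiseless
plates and ≥ 95% per-cell accuracy at noise SD 20; exact 300/400 threshold
semantics; hit-caller sensitivity/specificity/confounder routing over 200
seeded simulations; hypergeometric exactness and planted-term ranking;
network purity and oracle-equal components; closed-form and noisy
generation-time recovery and toxicity power/level over 100 seeds. What they
do not establish is performance on real micrographs (clumped cells, blur,
uneven focus) or on growth curves with non-Gaussian instrument artifacts.
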