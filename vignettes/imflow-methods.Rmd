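---
title: "Methods: simulation and morphometric analysis of dual-view flow-cytometry frames"
author: "imflow developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and morphometric analysis of dual-view flow-cytometry frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Circulating tumour cells (CTCs) and especially CTC *clusters* are rare,
label-variable objects in blood, which makes antibody-based detection
fragile. An alternative is morphometry: image every particle in a
focused microfluidic stream and describe it by *imaging biomarkers* —
bright-field (BF) cross-sectional area, perimeter, aspect ratio and an
apparent cell count, plus nucleus count and total nucleus area from a
simultaneously acquired fluorescence (FL) view of a DNA stain. Because
both views land on halves of one sensor, a nucleus appears at the same
pixel coordinates as its parent cell, and "has this object at least two
nuclei?" becomes a cheap, label-free cluster test. Size bands then
carry the biology: red-cell debris around 10–30 µm², single leukocytes
around 50–70 µm², large single cells at 90–130 µm², and clusters from
150 µm² upward (270 µm² and larger for three or more cells). Objects
with *no* nucleus are debris whatever their size — the single most
effective filter against false clusters.

`imflow` implements that computational core end to end: a synthetic
paired-frame generator with exact ground truth, the BF/FL feature
extractors, the band classifier, a virtual sort-trigger/routing model,
and distribution analytics. There is no public dataset for this
instrument; the generator is therefore a first-class, tested module and
every quantitative claim in the package is made *about the stated
synthetic world*, never about real blood.

## The synthetic world

Objects are unions of disks; nuclei are smaller disks strictly inside
their parent cell. This is deliberately the simplest geometry whose
area and perimeter have closed forms, so every measurement has an
analytic oracle.

Default optics: 0.5 µm/pixel (not stated by the instrument description;
chosen so the 50-µm channel is 100 px wide), one 100 × 400 px view per
channel, BF background 180 with object contrast −60, FL background 8
with nucleus peak +80, Gaussian sensor noise sd 2 (8-bit units). The FL
peak is far above the 16/256 recognition floor, as in the real system,
where nuclei are dim relative to BF but comfortably above the lower
4 bits. Stream defaults: 200 frames/s, Poisson arrivals at 2 objects
per frame, a centre lane with 2 µm jitter and 35 µm minimum
centre-to-centre spacing (the hydrodynamic-focusing guarantees:
centred, spaced, aligned).

Mixtures (calibrated fixtures — the source system reports bands and a
qualitative time course, not component weights):

| component | area model (µm²) | nuclei | control | positive day 11 |
|---|---|---|---|---|
| rbc_debris | lognormal, median 20, trunc [10,30) | 0 | 0.45 | 0.423 |
| wbc | median 60, trunc [50,70) | 1 (≈20 µm²) | 0.50 | 0.47 |
| debris_agg | median 60, broad, 2–3 subunits | 0 | 0.05 | 0.047 |
| large_single | median 110, trunc [90,130) | 1–2 (≈30 µm²) | — | 0.04 |
| cluster | per-cell median 100, trunc [88,250] | 1–2 per cell | — | 0.02 |

Cluster cells (2–6, weights 0.40/0.25/0.18/0.10/0.07) are packed at
1.2 r centre spacing; the cluster's area is the emergent union area
(≥ 0.857 × Σ cell areas), which keeps every 2-cell cluster at or above
the 150-µm² band floor. On earlier study days the tumour components are
ramped down (cluster weight 0.002/0.006/0.010/0.015/0.020 for days
2/4/7/9/11) so that clusters cross the "1% of leukocytes" level around
day 4 and roughly double between days 7 and 11. Ground truth is exact
by construction: the recorded true area *is* the rasterised union, so
generator-vs-measurement discrepancies isolate the analysis pipeline.

What the generator does **not** emulate: point-spread blur, motion
blur, depth-of-field loss, illumination drift, intensity texture,
non-circular cell shapes, overlapping neighbours (hydrodynamic spacing
is enforced, as in the chip), or any electrokinetics. A green test
therefore establishes correctness of the *algorithms under the stated
geometry and noise*, not instrument-level performance on blood.

## Feature extraction

**Binarisation.** The BF rule "threshold based on the average
intensity" is under-specified in the source description; we read it as
foreground iff |frame − background| > k·mean(|frame − background|) over
the whole frame, k = 3 by default and exposed in the config. Per-cell
subwindow thresholding is the plausible alternative reading; whole-frame
was chosen for determinism and is flagged as the one deliberate
interpretation in the package. The FL channel uses the fixed 16/256
floor instead — its background is dark, so a mean-relative rule would
be noise-driven.

**Blobs.** 8-connected components, interior holes filled before
measurement (BF cell interiors can be bright), components under 10 µm²
discarded — the area histograms start at 10 µm², so nothing below that
is an object. Nuclei: 8-connected FL components ≥ 4 µm²; touching
nuclei merge (known undercount risk for dense clusters, mirrored by the
area-based estimator below).

**Perimeter** uses the 4-direction Cauchy–Crofton estimate
P = (π/8)(T₀ + T₉₀ + (T₄₅+T₁₃₅)/√2)·pixel size, where T are boundary
transition counts along the sampling directions. It is essentially
unbiased on disks and ≈5% low on squares; a naive boundary-pixel count
would be ≈27% high on disks, which is why "actual perimeter" needs a
calibrated estimator.

**Aspect ratio** is the side ratio of the minimum-area *rotated*
rectangle (rotating calipers over the convex hull of pixel-square
corners). An axis-aligned box would be biased by flow alignment.
Pixel corners, not centres, are used so a 40 × 10 px bar reads 4.0, not
39/9.

**BF cell count.** Local maxima of the exact Euclidean distance
transform, greedily thinned to ≥ 6 µm separation, seed a priority-flood
watershed; segments under 10 µm² are dropped and the count is never
below 1. The source system itself reports this BF counter as its least
reliable biomarker (debris attachment); accordingly the classifier
never consumes it — cluster calls use nucleus counts.

**Matching.** A nucleus belongs to the blob whose mask, dilated by
2 px (Chebyshev), contains its registration-corrected centroid;
ambiguity resolves to the nearest blob pixel; unmatched nuclei are kept
and flagged. Total nucleus area divided by a 20-µm² reference (the
first peak of the nucleus-area distribution) gives the alternative cell
count, rounded to the nearest integer with a floor of 1 for positive
totals — the neutral choice given the known multinucleate
overestimation risk.

## Classification, trigger, routing

Bands (µm²): [10,30) rbc_debris, [30,50) unclassified_small, [50,70)
wbc, [70,90) intermediate, [90,150) large_single, [150,270)
cluster_2plus, [270,∞) cluster_3plus. The gap bands are named rather
than forced into neighbours. Zero matched nuclei ⇒ debris, overriding
any band; cluster bands additionally require ≥ 2 (resp. ≥ 3) nuclei,
otherwise the object is a debris aggregate. Both decision boundaries of
the sorter are strict, anchored to the instrument's wording: trigger
iff area > 300 µm² ("exceeded"), collection iff displacement > 8.3 µm
("more than"). The pulse (40 V, 100 µs) produces a single configurable
displacement (default 10 µm — enough to cross 8.3); no electrophoretic
force model is attempted, because the contract under test is the
routing logic, not the physics. The 5-ms real-time budget is logged as
metadata and never enforced.

## Distribution analytics

Histograms use half-open fixed-width bins: area 20 µm² from 10,
aspect ratio 0.2 from 1, perimeter 10 µm from 0; frequencies are
percent of N and sum to exactly 100. Values below the origin fall
outside the binned range by convention (the pipeline floors areas at
10 µm² anyway). Peak detection — absent from the source, which reads
peaks by eye — takes local maxima of the frequencies with a
topographic-prominence threshold of 0.2 percentage points; an optional
moving average (zero-padded beyond the range) is exposed but defaults
to *off*. The reason is structural: at 20-µm² bins the red-cell and
leukocyte peaks occupy bins two apart ([10,30) and [50,70)), and a
centred window of three or more always merges two peaks separated by a
single low bin — and likewise buries the 90–130 µm² peak under the
dominant leukocyte flank. With any such window the domain's band peaks
are unresolvable no matter the mixture, so the unsmoothed default is
the one that preserves the discriminative structure the method exists
to read. Peak *checks* in the acceptance suite run on pooled
10,000-object samples because sub-percent sampling noise at small n
can fake bumps in the debris tail; the claim under test concerns the
population's modes. Distribution shift is summarised
by total-variation distance, TV = ½Σ|pᵢ−qᵢ|, an extension chosen for
its direct "mass moved" reading; the per-band deltas are reported
alongside. The irregular-cell fraction is clusters as a percentage of
WBC-band objects and is flagged undefined when the WBC band is empty.

## Numerical choices and degenerate inputs

Strict inequalities at every stated boundary (16-step FL floor
included); half-open bins; 8-connectivity everywhere; watershed ties
broken deterministically (FIFO at equal height); empty frames, empty
masks, zero-object streams and zero-nucleus objects all return empty
but well-formed results rather than errors; an object that cannot be
placed in view raises a placement error. All randomness flows through
R's global RNG via explicit seeds; a fixed seed reproduces frames
bit-identically.

## Scale of the stated checks

Replicate-stability and peak-direction checks run the full
simulate→analyze pipeline at 5,000 objects per replicate (two seeds per
condition) — a desk-scale stand-in for one 50-µL assay — and the pooled
20,000 objects feed the headline analogues (cluster fraction of the WBC
band ≥ 1%; ≥ 90% of aspect ratios ≤ 1.4). The acceptance script uses
20,000 objects per population. These sizes were fixed before the
thresholds were evaluated and are not tuned.

## Known limitations

The generator's realism gap (above) is the main one. The BF cell
counter undercounts tightly packed small-cell clusters (seed separation
6 µm exceeds their centre spacing) — the same failure mode the
instrument reports, handled the same way: trust nuclei. Touching nuclei
merge; multinucleate cells can push the area-based count high. The
classifier downgrades a ≥ 270 µm² object with exactly two nuclei to
debris (by the stated rule), although a two-cell cluster of very large
cells is conceivable; at the default mixtures this configuration has
negligible probability. TIFF output is not provided (no TIFF codec in
the target environment); the combined-frame PNG carries the same
8-bit payload.
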