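---
title: "Knowledge-driven image segmentation and reasoning with knowseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-driven image segmentation and reasoning with knowseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knowseg)
```

## The model

`knowseg` treats image understanding as matching an image against an explicit,
human-readable knowledge base rather than as a single black-box prediction. The
knowledge base is a *semantic network*: each node is a concept (an organ, a
device, a landmark, a decision about a scene) and each node's attributes state
what is expected of it — an intensity range, a size prior, a spatial relation
to another node ("left of the spine, typically 50–100 mm"), or a decision rule
("the tube tip must lie inside the safe zone"). Applying the knowledge base to
an image means recognizing each node: generating candidate regions, scoring
them against the expectations, and keeping the best candidate or — importantly
— *nothing* when no candidate is acceptable.

Recognition is organized around a **blackboard**, a shared working memory with
one *Solution Element* per node. Autonomous agents collaborate only through
the blackboard:

* a *knowledge agent* translates attributes into feature expectations with
  fuzzy priors,
* a *scheduling agent* repeatedly picks the pending element with the highest
  fraction of computable features (references already resolved), so a missing
  object reorders processing without hard-coded exception rules,
* *segmentation agents* produce candidate regions (intensity thresholding into
  connected components, morphology, derived boxes, or an external predictor
  hook where a trained model plugs in),
* *reasoning agents* infer spatial search areas from relations to
  already-recognized objects, score candidates, select or reject, evaluate
  decision rules, and cross-check duplicate estimates of the same structure.

Exactly one agent activates per iteration — the one with the highest
activation score — and the loop ends when all scores are zero. Every
activation is recorded, so a completed blackboard is also an explanation of
what the system did and why.

## Fuzzy expectations

Every scalar expectation is a piecewise-linear membership function mapping a
feature value to a confidence in $[0,1]$, evaluated with flat extrapolation
beyond the first and last vertex. Printed ranges $[a,b]$ become trapezoids
with full confidence on $[a,b]$ and linear shoulders of width $0.2\,(b-a)$ on
each side; tolerance expectations ("within 30 mm") hold confidence 1 up to the
tolerance and fall to 0 at 1.2 times it. The 20 % relative shoulder is a
design choice: the knowledge sources state typical ranges without stating how
sharply confidence should fall outside them, and a fixed relative shoulder
keeps the construction scale-free. It is exposed per node (`SearchShoulder`),
and a node that needs a crisp region (the tube safe zone) sets it to 0.

A candidate's aggregate score is the **product** of its memberships.
Product rather than minimum is again a deliberate choice: it penalizes a
candidate that is mediocre on several criteria below one that fails slightly
on a single criterion, and any single violated expectation (membership 0)
vetoes the candidate. Expectations whose reference object was not found are
*non-informative* and contribute 1 — an absent object must not block
recognition of its neighbours. Selection is the arg-max of the score when it
exceeds the node's acceptance threshold (default 0, i.e. any strictly
positive score); ties go to the larger region, then the first found.

## Coordinates, units and conventions

Rasters are stored as R arrays, `[x, y]` in 2D and `[x, y, z]` in 3D, with
1-based indices; the physical position of a voxel is `(index - 1) * spacing`
mm. The craniocaudal axis is z in 3D ("above" = larger z, the superior
direction) and y in 2D ("above" = smaller y, the row convention of
radiograph rasters). Laterality follows radiological display: "patient-left"
is larger x. The orientation tag is stored with every image. Knowledge-base
scalars default to millimetres; `cm`, `cm2` and `cm3` suffixes are converted
at parse time, so "5–10 cm" and "50–100 mm" express the same fact.

Connected components use the full neighbourhood (8-connectivity in 2D, 26 in
3D) and the minimum candidate size defaults to 1 voxel — the most permissive
settings, because rejecting implausible candidates is the reasoning layer's
job, not the segmenter's. Morphological radii are physical (mm), converted to
per-axis voxel extents through the spacing, and are applied to the foreground
mask *before* component labeling so that, for example, a closing can
reconnect a region split by an overlying structure (the trachea band split by
a bright tube). Hole filling fills background components not connected to the
raster border (face connectivity).

## The tunable-parameter genome

Any numeric knowledge-base parameter can be exposed to optimization by
appending a value-encoding operator `{bit_start, bit_end, lower, upper}`.
The designated bits of a binary chromosome are read as an unsigned index into
$2^{n}$ equidistant values between the bounds: all-zeros decodes to the lower
bound, all-ones to the upper. Bit positions are taken as 0-based inclusive
indices into the chromosome; only absolute gene placement depends on this
reading, never the decoded values. Unused bits between genes are permitted
and ignored, and overlapping bit claims are a validation error.

The learn module co-optimizes all encoded parameters with a seeded genetic
algorithm: random initial population, fitness evaluation of every chromosome
through a distributor (sequential reference backend; a local process-pool
backend with the same order-independent contract), elitism, binary
tournament selection, single-point crossover and per-bit mutation. Defaults:
population 30, 10 generations, elitism 2, crossover probability 0.8,
mutation 1/length per bit. Selection scheme and rates are standard GA
practice — the method this package implements names the operators but not
their rates — and all of them sit in `ga_config()`. Fitness is the weighted
per-node performance (Dice, sensitivity, specificity, precision/recall, or a
landmark metric) averaged over the tuning cases; a node that is not found
scores 0, and a degenerate parameter set that makes a whole run fail scores
0 rather than raising, because the optimizer must be able to traverse bad
regions of the search space. Landmark error is mapped into $[0,1]$ as
$1/(1+(d/s)^2)$ with scale $s = 10$ mm, so 10 mm of error halves the
fitness. Fitness evaluations are memoized per chromosome within a run — the
fitness is a deterministic function of the bit string — and elitism makes
the best-so-far trajectory non-decreasing by construction.

## Decisions and consistency

Decision nodes turn recognition into explainable boolean findings:
`InsideZone` tests a landmark against a zone mask and, when violated, reports
*which way* it is violated (tip too low / too high); `PathWithin` requires a
fraction of a path's voxels (default 0.9, tolerating raster discretization of
a crisp "must be within" statement) to lie inside a reference region;
`DecisionAnd` conjoins sub-decisions. Any operand that was not found makes
the decision *indeterminate* rather than silently false. `ConsistentWith`
cross-checks two independent estimates of the same structure: centroids
within the stated tolerance (10 mm in the shipped tube knowledge base) fuse
to a refined estimate (midpoint for points, intersection for regions), and
estimates further apart mark the fused node *unreliable* — the system
reports that it cannot identify the structure instead of guessing.

## The phantom generators

All tests and demonstrations run on deterministic synthetic phantoms, so the
package needs no external data. The abdominal phantom emulates the geometry
that the kidney knowledge base describes: a soft-tissue body, a spine at
bone intensity (1400) running the full craniocaudal extent, two kidney
ellipsoids (400, within the 300–2000 soft-tissue window) placed 55–95 mm
lateral of the spine at the same level within ±20 mm, an optional stray
distractor blob at kidney intensity 125–160 mm out (outside the admissible
40–110 mm search band), and an optional low-intensity (250) blob adhering to
a kidney pole, used to give threshold optimization a unique optimum.
Gaussian noise (sd 20) is seeded. The default field is 100×44×36 voxels at
4.5 mm — coarse, but several voxels finer than every tolerance the
knowledge base states, which is what the spatial reasoning needs; unit tests
that check volumes against analytic geometry use a finer grid. The tube
phantom emulates a chest radiograph fragment at 0.5 mm: a dark trachea band
ending at the carina, with a bright two-pixel tube descending inside it to a
configurable height above (or below) the carina.

What the phantoms deliberately do **not** emulate: anatomical shape
variation, intensity inhomogeneity (bias fields), imaging artifacts, or any
texture a trained segmenter would rely on. Passing tests therefore
demonstrate that the reasoning, scheduling, decision and optimization
machinery behaves as specified — not that any particular clinical
segmentation accuracy would be reached on real data, which depends on the
quality of the plugged-in predictors and of the knowledge base itself.

## Numerical choices and edge cases

* Knowledge-base scalars are written back with the shortest decimal
  representation that round-trips the double exactly, so
  `parse(write(net))` is the identity on parsed structures.
* Blackboard JSON uses full-precision numbers; reading restores scalar
  fields bit-exactly and masks voxel-exactly.
* An empty search area, an empty threshold result, or a reference that was
  not found all yield `not_found` statuses, never errors; the activation
  loop is bounded at `100 × (nodes + 1)` activations and reports the stuck
  element if ever exceeded.
* Degenerate normalization (constant image) maps to 0 rather than dividing
  by zero; centile clipping defaults to the 2–98 percentiles.
* Erosion treats the region outside the image as background, so structures
  touching the border shrink there; closing is dilation followed by erosion
  with the same element.
* The scheduler counts `not_found` and `unreliable` references as resolved
  when computing the computable-feature fraction: an absent prerequisite
  changes the order and the informativeness of expectations, but never
  blocks an element.
* Exactly one candidate is selected per node (no merging); a node that
  should aggregate several components expresses that through a dependent
  node over the candidate union.

## Problem sizes used by the test suite

The shipped checks run at desk scale by design: 200 seeded abdominal
phantoms for the stray-rejection and Hausdorff properties, 100 random
dependency graphs for the scheduler oracle, 20 seeded GA runs (population
30, 10 generations over a 3-bit gene, memoized fitness) for threshold
recovery, and single runs for the tube-decision scenarios. The full suite
and the acceptance script each complete in a couple of minutes on one CPU.

## Limitations

The external-predictor hook is the seam for trained models; the package
ships no learned weights and the bias-field step is an identity unless a
hook is registered. Only sequential and local process-pool distribution
backends are provided. The blackboard file layout is this package's own
JSON dialect. The knowledge-base grammar is single-line-per-attribute;
multi-line attributes and quoting are not supported.
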