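# knowseg

Knowledge-network driven medical image segmentation and reasoning in R.

Data-driven segmenters — neural networks included — make *obvious* mistakes:
a stray disconnected region far from the organ, a tube "detected" in the
esophagus, a silently wrong landmark. `knowseg` is for researchers and tool
builders who want to wrap explicit, human-readable anatomical knowledge
around such segmenters (or around plain thresholding): review candidate
regions, keep only those in plausible locations, cross-check independent
estimates, and turn the result into explainable findings — or into an honest
"not found" instead of a confident error.

## The model in brief

A knowledge base is a **semantic network** stored as plain text: one
`node_list` file plus one attribute file per node. Node attributes state
expected characteristics as **fuzzy membership functions** (piecewise-linear
maps from a feature value to a confidence in [0, 1]) and **spatial
relations** with typical ranges:

```
# kidney_left_init
PartOf kidney_cnn
NotPartOf dense_bone
LeftOf spine 50 100
SameLevelAs kidney_right_init 3cm
```

A **blackboard** multi-agent loop applies the knowledge base to an image:
one Solution Element per node, a scheduler that always processes the element
with the highest fraction of computable features, segmentation agents that
generate candidate connected components (thresholding, morphology, derived
boxes, or an external predictor hook), and reasoning agents that derive
spatial search areas, score each candidate as the product of its fuzzy
memberships, select the best candidate (or none), evaluate decision rules
and flag inconsistent duplicate estimates as *unreliable*.

Any numeric parameter can be exposed to optimization with a value-encoding
operator — `IntensityRange 300 {0, 2, 100, 800} 2000` puts the window low
bound on chromosome bits 0–2 over an 8-value grid from 100 to 800 — and a
seeded genetic algorithm (population 30, tournament selection, single-point
crossover, elitism) co-optimizes all exposed parameters against a tuning set
scored by Dice, confusion-matrix or landmark metrics.

Deterministic phantom generators (an abdominal-CT-like volume with spine,
kidneys and a stray distractor blob; a chest-radiograph-like image with a
trachea, carina and tube) supply every input with ground truth, so nothing
needs downloading.

## Worked example

```r
library(knowseg)
net <- parse_network(example_kb("kidney"))
ph  <- sample_abdominal_phantom(seed = 7)   # image + ground truth
bb  <- run_think(net, ph$image)
print(bb)
```

```
<blackboard> 8 solution elements, 33 agent activations
  abdomen                  recognized  (75780 voxels, score 0.816)
  dense_bone               recognized  (1332 voxels, score 1.000)
  spine                    recognized  (1332 voxels, score 1.000)
  kidney_cnn               recognized  (1332 voxels, score 1.000)
  kidney_right_init        recognized  (438 voxels, score 1.000)
  kidney_left_init         recognized  (434 voxels, score 1.000)
  kidney_right             recognized  (438 voxels, score 1.000)
  kidney_left              recognized  (434 voxels, score 1.000)
```

Every node was recognized; the abdomen's score 0.816 is the fuzzy confidence
of its mean cross-sectional area (427 cm² on this phantom, on a prior rising
from 0 at 100 cm² to 1 at 500 cm²). The selected left kidney:

```r
sel <- bb$elements$kidney_left$selected
m <- array(FALSE, dim(ph$image$data)); m[sel$idx] <- TRUE
dice_coefficient(m, ph$truth$kidney_left)          # 1.000
length(intersect(sel$idx, which(ph$truth$stray)))  # 0
```

The raw threshold output (`kidney_cnn`) contains four components — spine,
both kidneys and the stray blob — but the reasoning layer's lateral band
("left of the spine, 50–100 mm") and bone exclusion reject everything except
the true left kidney: Dice 1.000 against truth and zero stray voxels.

A command-line wrapper with `think`, `learn`, `summarize` and `fixtures`
subcommands is installed at `inst/cli/knowseg`; see `?cmd_think` for the
YAML configuration fields. The methods vignette
(`vignettes/knowledge-driven-segmentation.Rmd`) documents the model,
conventions and design choices in detail.

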