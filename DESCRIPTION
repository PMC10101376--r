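Package: knowseg
Title: Knowledge-Network Driven Medical Image Segmentation and Reasoning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Cognitive-AI style environment for knowledge-based image
    understanding. A human-readable semantic-network knowledge base (nodes
    with fuzzy attribute expectations and spatial relations) drives a
    blackboard multi-agent engine: segmentation agents generate candidate
    regions (intensity thresholding, connected components, morphology,
    derived boxes, external predictor hooks) and machine-reasoning agents
    score candidates against fuzzy expectations, infer spatial search
    areas, select or reject candidates, and evaluate explainable decision
    rules (safe zones, path containment, cross-estimate consistency).
    Tunable knowledge-base parameters are exposed through a value-encoding
    operator and co-optimized by a seeded genetic algorithm over a tuning
    set. Deterministic abdominal-CT-like and chest-radiograph-like phantom
    generators provide self-contained inputs with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    RNifti,
    png,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
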