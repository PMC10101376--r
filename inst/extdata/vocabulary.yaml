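# Default attribute vocabulary for knowseg knowledge bases.
#
# Each entry defines an attribute: its name, the agent-facing category, and
# the ordered parameter arity. Parameter types:
#   node      - name of another node in the network (creates a graph edge)
#   scalar    - numeric value; mm by default, `cm`/`cm2`/`cm3` suffixes are
#               converted at parse time; may carry a {start, end, lo, hi}
#               value-encoding group making it tunable
#   word      - bare identifier (hook names, step names, directions)
#   fuzzy     - trailing alternating value/confidence vertex pairs
#   varscalar - trailing optional numeric values
#   varnode   - trailing node names (two or more)
#
# Categories map to agent families:
#   segmentation  -> segmentation agents (candidate generation, morphology)
#   unary         -> reasoning agents (fuzzy scoring of unary features)
#   relational    -> reasoning agents (search areas + fuzzy relational scoring)
#   decision      -> reasoning agents (boolean decisions, consistency fusion)
#   preprocessing -> segmentation agents (channel construction for predictors)
#   learning      -> learning module only (no runtime agent)
#
# Users may extend this vocabulary with their own file.

- name: IntensityRange
  category: segmentation
  params: [scalar, scalar]        # low, high (native intensity units, e.g. HU)
- name: ExternalPredictor
  category: segmentation
  params: [word]                  # registered predictor hook name
- name: Box
  category: segmentation
  params: [node, scalar, scalar, scalar, scalar, word]
  # reference, in-plane width mm, in-plane height mm, offset low mm,
  # offset high mm, direction (above|below) relative to reference center slice
- name: BottomOf
  category: segmentation
  params: [node]                  # landmark: lowest point of the reference
- name: MinSize
  category: segmentation
  params: [scalar]                # minimum candidate size, voxels
- name: FillHoles
  category: segmentation
  params: []
- name: MorphOpen
  category: segmentation
  params: [scalar]                # structuring radius, mm
- name: MorphClose
  category: segmentation
  params: [scalar]                # structuring radius, mm
- name: PartOf
  category: relational
  params: [node]
- name: NotPartOf
  category: relational
  params: [node]
- name: InsideOf
  category: relational
  params: [node]
- name: LeftOf
  category: relational
  params: [node, scalar, scalar]  # reference, expected distance range mm
- name: RightOf
  category: relational
  params: [node, scalar, scalar]
- name: Above
  category: relational
  params: [node, scalar, scalar]
- name: Below
  category: relational
  params: [node, scalar, scalar]
- name: SameLevelAs
  category: relational
  params: [node, scalar]          # reference, craniocaudal tolerance mm
- name: SearchShoulder
  category: relational
  params: [scalar]                # relative soft-shoulder width for this node
- name: AcceptThreshold
  category: relational
  params: [scalar]                # minimum score for candidate acceptance
- name: Area
  category: unary
  params: [fuzzy]                 # 2D area, mm^2
- name: Volume
  category: unary
  params: [fuzzy]                 # 3D volume, mm^3
- name: CrossSectionalArea
  category: unary
  params: [fuzzy]                 # mean per-slice area, mm^2
- name: MeanIntensity
  category: unary
  params: [fuzzy]
- name: InsideZone
  category: decision
  params: [node, node]            # tip/landmark node, zone node
- name: PathWithin
  category: decision
  params: [node, node, varscalar] # path node, region node, containment frac
- name: DecisionAnd
  category: decision
  params: [varnode]
- name: ConsistentWith
  category: decision
  params: [node, node, scalar]    # estimate a, estimate b, tolerance mm
- name: HistogramSource
  category: preprocessing
  params: [node]                  # region supplying normalization histogram
- name: PreprocChannel
  category: preprocessing
  params: [scalar, word, varscalar]
  # channel index, step (biasfield|minmax|centile_clip|clip_histeq), step args
- name: NeuralNet_LearningRate
  category: learning
  params: [scalar, scalar]        # base, exponent (rate = base * 10^exponent)
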