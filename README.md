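# cadaSeg

Context-aware delayed agglomeration for electron-microscopy segmentation.

Connectomics pipelines segment EM images in two steps: a pixel classifier
predicts class probabilities (cell boundary, cytoplasm, mitochondria,
mitochondria boundary), a watershed over-segments the image into
superpixels, and the superpixels are then merged back into whole cells.
cadaSeg implements the merging step for researchers building or evaluating
such pipelines: a region-adjacency-graph engine with exactly mergeable
boundary/region statistics, two agglomeration policies, a two-phase
context-aware pipeline, split error metrics, and a seeded synthetic-scene
generator so everything can be developed and benchmarked without imaging
data.

## The method

Given superpixels \(S_1,\dots,S_N\) and a boundary-confidence function
\(h(e)\in[0,1]\) on RAG edges, agglomeration repeatedly dissolves the
cheapest face while \(\min_e h(e)\le\delta\).

* **Standard agglomeration** re-queues the merged body's faces
  immediately, so faces whose confidence just dropped are acted on first.
* **Delayed agglomeration** flags a face `DELAY` whenever its recomputed
  confidence did not increase, defers it until no `ACTIVE` face remains
  mergeable, then reactivates all in-range deferred faces in one batch and
  starts a new round — decisions on newly formed bodies are made with more
  context.
* **Context-aware two-phase merging (CADA)** splits regions into putative
  mitochondria (mean mitochondria probability > 0.5) and cytoplasm.
  Phase 1 clusters cytoplasm faces only, with a random-forest boundary
  classifier \(h_c\) (depth-limited to 20, trained in a single pass;
  mitochondria–cytoplasm borders are labelled as true boundaries).
  Phase 2 absorbs each mitochondrion into the neighbour holding the
  largest share of its boundary: with overlap ratio
  \(\rho(\{S_m,S_c\}) = \mathrm{face}(\{S_m,S_c\}) / \sum_i
  \mathrm{face}(\{S_m,S_i\})\), the confidence is
  \(h_m = 1-\rho\), mitochondria–mitochondria faces are never candidates,
  and each merged body is re-tagged cytoplasm so stacked blobs are
  absorbed chain-wise.

Segmentations are scored against ground truth by split variation of
information, \(VI_{OE} = -\sum_{ij}\frac{|g_i\cap r_j|}{Z}
\log\frac{|g_i\cap r_j|}{|g_i|}\) (false splits) and its mirror image
\(VI_{UE}\) (false merges), and by split Rand error, the fractions of
pixel pairs falsely split and falsely merged.

## Worked example

```r
library(cadaSeg)

train <- generateScene(sceneSpec(seed = 1))   # 256x256, 15 cells, noise 0.15
test  <- generateScene(sceneSpec(seed = 2))
test
#> Scene: 256 x 256, 15 cells, 26 mitochondria, 139 superpixels (seed 2)

hc <- trainSceneClassifier(train, maxDepth = 20, seed = 1)
hc
#> ConfidencePredictor: CLASSIFIER (99 features)

res <- cadaSegment(test@superpixels, test@probs, hc,
                   deltaC = 0.14, deltaM = 0.5)
res$phase1$merges; res$phase1$rounds   # 98 cytoplasm merges in 4 rounds
res$phase2$merges                      # all 26 mitochondria absorbed

splitMetrics(test@gtCells, res$labels)
#> SplitMetrics: VI_OE = 0.0000, VI_UE = 0.0000 nats; RE_OE = 0, RE_UE = 0
```

At the default mild noise the pipeline recovers the ground truth exactly:
the 139 superpixels collapse to the 15 true cells with zero split error in
both directions. On a harder scene (`noiseSigma = 0.3, gapPerCell = 2`,
membrane gaps emulating detector misses) the same classifier yields

```r
#> SplitMetrics: VI_OE = 0.2226, VI_UE = 0.1639 nats; RE_OE = 0.00656, RE_UE = 0.0113
```

i.e. a few tenths of a nat of residual fragmentation and fusion. The
`benchmarkSuite()`, `compareEnginesFalseMerges()` and
`compareContextAware()` harnesses run these comparisons across seeded
scene pairs and threshold sweeps; a command-line wrapper for every stage
is in `inst/cli/cadaseg.R`, and `runPipeline()` drives the whole chain
from one YAML config.

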