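---
title: "Predicting drug-drug interaction effects from similarity profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-drug interaction effects from similarity profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Co-prescribed drugs can interact, and the *type* of the interaction matters
clinically: one pair may prolong the QTc interval, another may potentiate
anticoagulation. Given a catalogue of known drug-drug interactions (DDIs)
labeled with effect types, the task is to predict the effect type of new
drug pairs from what is known about each drug: its chemical structure, its
target genes, and the biological processes those targets participate in.

ddiprofiler frames each drug as three *similarity profiles* over the drug
universe, and each ordered pair as the concatenation of the two drugs'
profiles. A per-modality autoencoder compresses each profile pair; a deep
feed-forward network classifies the concatenated codes into DDI types.

## The three similarity measures

**Structural (SSP).** The Tanimoto coefficient between binary molecular
fingerprints, $|a \cap b| / |a \cup b|$ over set bits. The SSP of drug $A$
is the vector $\{SS_{AA}, SS_{AB}, \dots\}$ over all drugs, so its length
equals the universe size and $SS_{AA} = 1$.

**Target (TSP).** For target-gene sets $G_A$, $G_B$ and hop distance
$d(x,y)$ on a functional-interaction (FI) gene network,

$$TS_{AB} = \frac{|\{(x,y) \in G_A \times G_B \mid d(x,y) \le t_A\}|}
                {|G_A \times G_B|},
  \qquad t_A = \max\{d(x,y) \mid x, y \in G_A\}.$$

The threshold $t_A$ is drug $A$'s own intra-set diameter, which makes the
measure asymmetric: $TS_{AB} \ne TS_{BA}$ in general, while $TS_{AA} = 1$
always. Both quantifiers range over the full Cartesian product, so $x = y$
pairs count and a single-target drug has $t_A = 0$.

**GO-term (GSP).** The same statistic with gene sets replaced by GO-term
sets (the union of biological-process annotations of the drug's targets)
and the FI network replaced by the GO graph, whose `is_a`/`part_of` edges
are treated as undirected for hop distances.

### Numerical and degenerate-input choices

* Two all-zero fingerprints have an empty union; their Tanimoto
  coefficient is defined as 0, with a warning. The self-similarity of a
  drug is pinned to 1 regardless.
* Unreachable node pairs (disconnected graphs) fail $d(x,y) \le t_A$ and
  are skipped when computing the max in $t_A$. This keeps both statistics
  well defined on disconnected graphs without inventing a finite penalty
  distance.
* Genes or terms absent from the graph are dropped from a drug's set with
  a warning; a drug whose set becomes empty is excluded from that profile,
  mirroring the dataset rule that drugs without target information are
  excluded.
* Hop distances are computed by per-source breadth-first search, cached,
  so repeated queries are identical and cheap.
* A drug's GO-term set uses direct annotations by default. Ancestor
  propagation along the term graph is available behind
  `drug_go_terms(propagate = TRUE)`; direct annotation is the default
  because propagation inflates every set with the same shallow ancestors,
  which compresses the dynamic range of $t_A$.
* Fingerprints computed from SMILES use ChemmineR's atom-pair-derived
  1024-bit binary fingerprints, the established Bioconductor route; any
  fixed-length binary fingerprint can be supplied directly, and the
  synthetic generator does so.

## The model

Per selected modality an autoencoder with layer sizes
$2N \to 1000 \to 200 \to 1000 \to 2N$ (sigmoid activations; $N$ = universe
size, so $2N = 3194$ for a 1597-drug universe) reduces each concatenated
profile pair to a 200-unit bottleneck code. The codes are concatenated
(600 units for three modalities) and classified by a feed-forward network
with six 2000-unit ReLU hidden layers and one sigmoid output per DDI type.
Training labels are one-hot; the classification cost is per-type binary
cross-entropy, matching the multi-label reading of the sigmoid outputs
(the evaluation treats a score of at least 0.5 for *any* type as a
positive prediction of that type). The reconstruction cost is mean squared
error by default — profile values live in $[0,1]$, matching the sigmoid
output layer — with binary cross-entropy behind a flag.

Each epoch has two phases. First every autoencoder takes
reconstruction-only minibatch steps (RMSprop, learning rate 0.001). Then a
joint pass minimizes the *unweighted sum* of all reconstruction costs and
the classification cost (classifier steps via Adam, learning rate 0.0001),
with gradients flowing from the classifier into the encoders — so the
autoencoders are trained twice per epoch and the codes are shaped for
classification, not just reconstruction. Batch size is 256; hidden layers
use batch normalization (applied between the affine map and the
activation) and dropout 0.3; the output layer and each encoder's
bottleneck layer use neither, so the code fed to the classifier is a plain
activation. The joint-cost weights are configurable but default to 1,
reflecting the plain-sum objective.

All randomness — weight initialization (Glorot uniform), batch shuffling,
dropout masks, fold assignment — flows through R's RNG from a single
integer seed, so a fixed seed reproduces bit-identical cost histories on
the same platform. Training aborts with a diagnostic if any cost becomes
non-finite. Both phases share the same per-epoch shuffling; reusing the
minibatches between phases is a simplification the two-phase schedule
leaves open, and it keeps one pass over the data per phase.

The reference setting (850 epochs, 1000/200/1000 and 6x2000 hidden sizes)
is for a DrugBank-scale universe. The package's own experiments run at
synthetic scale, where a ~60-drug universe makes profile pairs ~120-long:
there the tests use proportionally smaller networks (e.g. 96/48/96
autoencoders, two 256-unit classifier layers), a few hundred epochs, a
classifier learning rate of 0.001 (at a few thousand samples the reference
rate of 0.0001 is needlessly conservative), and an autoencoder learning
rate of 0.0001. The lower autoencoder rate matters: once reconstruction
has converged, RMSprop's normalized steps stop shrinking with the
gradient, so at the reference rate the encoder weights keep wandering and
the classifier chases drifting features — visible as held-out accuracy
*decreasing* with further epochs on small worlds. These sizes are stated
in the tests and in `scripts/acceptance.R`; the defaults remain the
reference values.

## Evaluation protocol

* **Filtering.** Drugs without target genes are excluded, DDIs touching an
  excluded drug are dropped, and types left with fewer than five records
  are dropped; the rules are iterated to a fixed point and logged.
  "Fewer than five" is strict: a type with exactly five records survives.
* **Cross-validation.** Five folds by default; the split unit is the
  labeled ordered pair, so a drug may appear on both sides of a fold
  boundary — this matches the protocol the headline numbers come from and
  is deliberately not a cold-start split. Folds are stratified by type
  when a type has at least `k` records (avoiding empty-type test folds);
  rarer types are assigned at random. Any reducer (autoencoder or PCA) is
  fitted on the training folds only.
* **Metrics.** Accuracy is the fraction of samples whose true-type score
  is at least 0.5. Macro recall/precision average per-type ratios (a type
  with a zero denominator contributes 0, with a warning); micro versions
  pool the counts first. Precision/recall curves use step-wise
  interpolation for the area, which avoids the optimistic bias of
  trapezoidal interpolation; AUPRC is reported both per type and
  micro-averaged (pooling all type-sample scores), since either averaging
  convention is defensible for a headline number.
* **Baselines.** PCA to the same 200-dimension budget feeds the same
  feed-forward classifier; SVM and random forest run on the *unreduced*
  concatenated profiles. The random forest uses Gini splitting, 10 trees,
  minimum node size 1. The SVM baseline uses a linear kernel with cost 1
  and Platt-scaled probabilities, which supplies the $[0,1]$ per-type
  scores the metrics need.
* **Novel-DDI report.** Among cross-validated *true positives* (true-type
  score at least 0.5), every other type scoring at least 0.5 is reported as
  a putative additional effect, sorted by score.

## The synthetic world generator

Real inputs (DrugBank-scale DDI catalogues, BioGrid networks, the GO) are
large and license-encumbered, so the package ships a generator that plants
the statistical structure the method assumes, at desk scale:

* drugs belong to latent clusters; fingerprints are cluster prototypes
  with 5% per-bit flip noise;
* the gene network is a planted-partition graph whose communities align
  with the clusters (within-community edge probability targets mean degree
  8, sparse between-community links, bridged into one component so the
  distance oracle is total); target sets draw from the drug's community
  with 90% fidelity;
* the GO graph is a rooted tree with one subtree per annotation block
  plus ~5% `part_of` shortcut edges; every gene is annotated with 2-4
  terms from its block, so term sets inherit the block signal through the
  targets;
* the DDI type of an ordered pair is a seeded, balanced lookup table over
  the ordered cluster pair — direction matters by construction — and a
  `noise_rate` fraction of labels is resampled *to a different type*, so
  the disagreement rate with the planted rule estimates the noise rate
  directly;
* every type is checked to end with at least five pairs (the filtering
  threshold), and configurations that cannot honor that error out with a
  suggestion.

`split_signal()` draws *independent* per-modality latent factors instead
of one shared cluster, with level counts allocated so each modality's
log-capacity is proportional to its weight
($k_m \approx K^{w_m/\sum w}$). The planted table then lives on the
composite code, so a single-modality learner observes only its own factor
and is capped below the all-modality ceiling, and a zero-weight modality
(one level) carries no signal at all. This is the package's testbed for
the claim that target and GO information add predictive signal beyond
structure alone.

What the generator does *not* emulate: chemically valid fingerprints, the
heavy-tailed type distribution of real DDI catalogues, hub structure of
real interaction networks, or annotation depth bias in the GO. Passing
tests on synthetic worlds therefore demonstrate that the implementation
recovers plantable signal under the model's assumptions — not that the
reported real-data performance transfers to any particular catalogue.

## Problem sizes used by the tests and acceptance script

The shipped experiments use worlds of 60 drugs, 300 genes, 200 terms,
10 types and 2000-3000 labeled pairs with label noise 0.1 — the smallest
sizes at which the planted-rule recovery is comfortably above the
filtering and stratification constraints (>= 5 pairs per type, >= k per
type per fold) while whole-pipeline runs stay in the minutes range.
Dimensional-identity checks instantiate the reference 1597-drug geometry
directly. The split-signal acceptance world uses equal modality weights,
the package's neutral choice when no modality is privileged.

## Known limitations

* The joint training schedule reuses the same minibatch partition in both
  phases of an epoch; the alternative (independent draws) is a one-line
  change but would double shuffling cost for no observed benefit.
* Batch normalization precedes the activation; the post-activation
  variant is not implemented.
* The SVM baseline is a linear-kernel C-SVC with Platt scaling, not a
  squared-hinge liblinear model; at the package's problem sizes the
  difference is immaterial for the comparisons made.
* No GPU path and no hyper-parameter search: the reference values are
  taken as given, and users with different data scales should re-tune by
  cross-validation.
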