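---
title: "Predicting kinase–cancer relations from literature embeddings: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting kinase–cancer relations from literature embeddings: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`kce` turns a corpus of concept-annotated biomedical abstracts plus curated
drug–target and clinical-trial tables into a ranking of candidate protein
kinase (PK) / cancer pairs. This vignette is the package's account of the
model, its assumptions, the tunable parameters, the synthetic-data design,
and the numerical decisions a maintainer would want to know about.

## The model and its assumptions

The working hypothesis is distributional: if inhibiting a kinase is relevant
to treating a cancer, the literature written *before* any trial already
places the two concepts in similar contexts. The pipeline operationalizes
this in three steps.

**Concept-aware corpus.** Multi-word medical concepts are collapsed to
single tokens before embedding (`non-small-cell lung carcinoma` →
`meshd002289`), so that a concept gets one vector rather than a bag of word
fragments. Mentions of the human species (NCBI taxon 9606) are deliberately
*not* collapsed: words like *patient*, *woman* or *boy* carry age and gender
information that is medically meaningful context. Relevance filtering keeps
articles with an abstract that are tagged with (or keyword-matched to) a
descriptor inside the MeSH closure of the search set; everything else
contributes nothing but noise to the embedding space.

**Skip-gram negative sampling.** Token vectors are trained from scratch by
mini-batch gradient ascent on the per-pair objective
$\log\sigma(u_o \cdot v_c) + \sum_{i=1}^{K}\log\sigma(-u_{n_i} \cdot v_c)$.
The served map $f(\cdot)$ is the input-vector table; output vectors exist
only for training. An important property, verified by the test suite on a
planted-co-occurrence corpus: input–input similarity tracks *shared
contexts* (paradigmatic similarity), not raw adjacency. Two tokens that
always co-occur end up close because they also share neighborhoods, which is
what real co-mentions in topical text do.

**Difference-vector classification.** A candidate pair is represented by
$f(\mathrm{PK}) - f(\mathrm{cancer})$, and a random forest learns the region
of difference space occupied by historically validated pairs. Labels come
from clinical-trial evidence: a phase-IV (post-approval) trial of an
inhibitor of the kinase against the cancer is treated as proof of
therapeutic relevance; training positives therefore use phase IV only,
regardless of how the test set is defined. Negatives are sampled uniformly
from pairs with no trial evidence — the assumption, necessarily unprovable
from the literature, is that the vast majority of arbitrary pairs are not
therapeutically related.

## Parameters that matter

| parameter | default | unit / range | why |
|---|---|---|---|
| `affinity_max_um` | 0.03 | μM | activity below this threshold is what makes a kinase a plausible mechanism of the drug |
| `n_pk` | 5 | kinases/drug | promiscuous inhibitors would otherwise flood the evidence with weak targets; "top" = lowest affinity |
| `window` | 5 | tokens | standard skip-gram radius; fixed, not shrinking (a dynamic-window toggle exists, off) |
| `min_count` | 5 | occurrences | below this, vectors are mostly initialization noise |
| `dim` | 100 | — | the feature dimension of the classifier |
| `negatives` | 20 | samples/pair | noise contrast; drawn from unigram$^{0.75}$ |
| `batch_size` | 128 | pairs | update granularity of the mini-batch ascent |
| `epochs`, `learning_rate` | 5, 0.025 | — | conventional word2vec-style defaults with linear decay to $10^{-4}\times$; configurable |
| `neg_ratio` | 10 | — | class imbalance of the splits; the class prior is exactly 1/11 |
| `iterations`, `cv_folds` | 100, 5 | — | randomized-search budget; configurations are drawn without replacement, so a grid of ≤ `iterations` points is scanned exhaustively |

Threshold selection offers two criteria — the geometric mean
$\sqrt{\mathrm{TPR}(1-\mathrm{FPR})}$ on the ROC curve and the F1 optimum on
the PR curve — and is computed on whatever evaluation the caller supplies;
which dataset's curve to use is a caller policy, not hard-coded.

## The synthetic study

Real inputs at full scale (millions of abstracts) are outside what a package
check can run, so `kce` ships a generator whose output exercises every stage
under a planted ground truth. Defaults: 30 kinases × 30 cancers, 40 planted
pairs, 60 relation documents per pair, 3000 background documents, background
vocabulary of 600 words, ~30 tokens per document, 50 inhibitors, 3 trials
per planted pair, trial years 2001–2020, seed 7. At this scale the full
pipeline (corpus → embedding → catalog → split → forest → evaluation) runs
in about a minute on one CPU; the test suite and the acceptance script both
use it.

The signal mechanism was designed around what difference-vector
classification can actually learn, and two failure modes discovered during
development are worth recording:

* *Proximity alone is not enough.* If each planted pair only shares a
  private context cluster, the two vectors converge and the difference is
  small in norm — but an axis-aligned forest trained on ~20 positives cannot
  learn "small norm in 100 dimensions" unless positives' per-dimension
  spread is roughly half the negatives'. Relational structure is required,
  not just closeness.
* *Globally shared relation vocabulary is too much.* If all planted pairs
  share one "inhibition/remission" word set, a kinase from one planted pair
  combined with the cancer of *another* is indistinguishable from a true
  pair.

The final design gives every concept its own signature vocabulary. A
background mention is flanked by the concept's own signature (every real
gene or disease has a literature of its own — this keeps unrelated vectors
apart). A relation document flanks *both* mentions with the **union** of the
two concepts' signatures, so the members of a true pair see near-identical
context distributions — even when a concept participates in two pairs —
while mismatched combinations share nothing. Planted pairs are sampled with
a per-concept multiplicity cap of 2, mirroring the moderate promiscuity of
curated drug–target tables; unbounded multiplicity smears a concept's vector
across many clusters. Background mentions are allocated mainly to concepts
outside planted pairs, reflecting that the heavily studied concepts'
literature is mostly about the relation. A light one-sided flavour (one
inhibition word near the kinase, one response word near the cancer) and
occasional decoy mentions (15% of relation documents) keep the corpus from
being unrealistically clean.

**What the generator does not emulate:** real English syntax, realistic
affinity or citation distributions, temporal drift of vocabulary, annotation
errors, and negatives that are semantically close to positives. Passing the
end-to-end test therefore shows that the machinery is correct and that a
planted distributional signal of realistic shape is recoverable — it does
not certify performance on PubMed-scale data.

**Evaluation protocol of the end-to-end check.** The target year defaults to
the median phase-IV year of the planted pairs, so roughly half train and
half are held out as "future" trials. Recovery is measured under the
phase-IV test protocol: only planted pairs ever receive phase-IV trials, so
the held-out positives are exactly the planted pairs beyond the target year.
(Under the all-phases protocol the generator's decoy phase I–II trials —
deliberately signal-free — enter the test positives; the acceptance script
reports that number too, and it is expectedly lower.) The permutation
control re-scores the same predictions against 20 random relabelings and
should sit at AUROC ≈ 0.5; the average over 20 permutations is reported
because a single permutation at ~190 test pairs has a standard deviation of
about 0.07. Note that the co-occurrence baseline is artificially strong on
synthetic data (planted pairs co-occur in ≥ 60 documents by construction);
its value lies in the oracle-checked counting and sweep machinery, not in a
fair comparison against the forest.

## Numerical choices

* **Mini-batch semantics.** Gradients inside a batch are computed at the
  batch-start parameters and applied summed, each scaled by the current
  (linearly decaying) learning rate. Training is single-threaded with an
  internal splitmix64 generator, so identical seeds give bit-identical
  vectors.
* **Initialization.** Input vectors uniform in $[-0.5/\mathrm{dim},
  0.5/\mathrm{dim}]$, output vectors zero — the standard word2vec scheme;
  noise draws equal to the positive context are redrawn (up to 100 times).
* **Loss reporting.** The mean negative objective per epoch is returned; on
  toy corpora with a suitable learning rate it is non-increasing (the test
  tolerates ≤ 1% upticks, since the reported quantity is itself stochastic
  through the noise draws).
* **Ties.** Vocabulary indices: descending frequency, then token string.
  Target lists: ascending affinity, then kinase symbol. Thresholds: the
  smallest threshold among maximizers. Rankings: descending score, then
  (pk, cancer). Overlapping annotations: longest span, then leftmost, then
  lexicographic concept id, applied right-to-left so offsets stay valid.
* **Curve conventions.** ROC curves are threshold sweeps over distinct
  scores, prepended with (0,0); AUROC is the trapezoidal area and equals
  pairwise concordance with half-credit for ties (oracle-checked). Average
  precision is the step sum $\sum_k (R_k - R_{k-1}) P_k$, never an
  interpolated area.
* **Degenerate inputs.** Empty abstracts are excluded by filtering; an empty
  annotation list is an identity replacement; F1 is defined as 0 when
  precision and recall are both 0; single-class label vectors are an error,
  not an NaN.

## Design decisions on open points

* **Offset base.** Annotation offsets are interpreted against
  `title + " " + abstract` as one offset space; this is a documented
  convention of the input dialect.
* **Trial year.** All year cutoffs use the trial's start year — the closest
  observable stand-in for "registered by"-style cutoffs in the record
  dialect consumed here.
* **Combined phase labels** ("Phase 1/Phase 2") normalize to the higher
  phase. This is conservative where it matters most: nothing becomes
  phase-IV training evidence unless a label actually says phase 4.
* **Negative-set hygiene.** The negative test sampler explicitly excludes
  the negative training pairs rather than relying on chance disjointness.
* **Any-affinity exclusion.** The test-set exclusion uses a *separate,
  unfiltered* target map (no affinity cutoff, no per-drug cap), so a pair is
  never a test positive merely because a weak-affinity association was
  filtered out of the training evidence.
* **Candidate universe.** Pairs whose concept tokens lack embeddings cannot
  be featurized and are dropped with a message; the split drivers therefore
  restrict the universe to identifiers with vectors.
* **Forest backend.** The search space maps onto `ranger`: trees, `mtry`
  (max features), `max.depth`, `min.node.size`, `replace` (bootstrap). The
  minimum-node-size knob covers the leaf-size control; a separate
  "minimum samples to split" parameter has no equivalent there and is not
  exposed.
* **Lemmatizer contract.** Any dictionary lemmatizer that maps plural nouns
  to singulars and comparatives to base forms satisfies the module; the
  shipped one is suffix rules plus an exception table, and tests assert only
  specific inflected→base pairs.
* **Acronym fixed point.** Because acronyms are preserved through stop-word
  removal and lowercasing happens last, a token like `ALL` legitimately
  yields `all` in the output corpus. Re-running the punctuation and
  lowercasing stages on their own output is an exact fixed point; re-running
  stop-word removal would additionally strip those acronym-derived tokens.
  The property test pins exactly this behavior.

## Known limitations

Difference vectors are direction-sensitive but scale-naive: concept
frequency affects vector norms, and the forest partially keys on norm
structure. Negative sampling of pairs is uniform, not degree-matched, so
hub kinases are easier negatives than they should be. Phase-IV evidence is a
conservative proxy for efficacy (not all effective drugs get phase-IV
trials), and trial registries capture only part of worldwide trials — on
real data both biases shrink the positive sets. Finally, the classifier's
scores are tree-vote fractions, not calibrated probabilities; thresholds
chosen by the geometric-mean criterion should be re-derived on any new
corpus rather than reused.
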