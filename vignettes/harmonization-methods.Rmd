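---
title: "Methods: semantic harmonization of SDOH survey items"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semantic harmonization of SDOH survey items}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdohmap)
```

## The problem

Clinical intake forms from different sites ask about the same
social determinants of health (SDOH) — education, housing, employment,
legal history — in syntactically different ways.  The same question may
appear verbatim under different section headings ("economic/Education/"
versus "Educational Data/"), or as a paraphrase ("What Is The Highest
Grade You Have Completed" versus "Highest grade attained").  Analyses
that join such data need the items grouped by meaning, not wording.

`sdohmap` implements that grouping as a pipeline: question records are
deduplicated under an explicit key; texts are embedded as unit vectors;
the embedding space is reduced with locally linear embedding (LLE);
items are clustered with spherical k-means under the cosine distance;
cluster reproducibility is validated with the In-Group Proportion (IGP)
statistic over independent train/test partitions; and the resulting
categories are mapped onto a reference taxonomy (e.g. the PhenX SDOH
protocol names) by thresholded cosine similarity.

## Question records and distinctness

A record is one form field: the verbatim question text (`field_name`)
plus its slash-separated section hierarchy (`field_path`, `""` or
terminated by `"/"`).  Records come from delimited text, JSON lines, or
from a depth-first traversal of a JSON-Schema form definition, where
nested objects encode the section hierarchy and each non-object leaf is
a question (enumerated leaves become `choice`, array leaves
`multi_answer`).

Distinctness is counted under two keys: `path_and_text` (section path
plus question text) and `text_only`.  Both keys normalize by collapsing
whitespace and case-folding, with no stemming and no punctuation
stripping — title-cased duplicates collapse, while every substantive
wording difference is preserved, keeping the rule auditable.  Raw
records are never discarded: deduplication happens at the analysis
boundary so provenance is preserved.

```{r dedup}
recs <- question_records(
  form_id = c("F1", "F2", "F3"),
  field_path = c("economic/Education/", "Educational Data/",
                 "social/Education History/"),
  field_name = c("What Is The Highest Grade You Have Completed",
                 "What Is The Highest Grade You Have Completed",
                 "Highest grade attained"))
distinct_questions(recs, "path_and_text")$count  # 3
distinct_questions(recs, "text_only")$count      # 2
```

## Embedding

The encoder contract is pluggable: any function mapping texts to matrix
rows can be used (for instance a pretrained 768-dimensional sentence
transformer), and all rows are L2-normalized on ingestion so that
downstream cosine similarity is a plain dot product.  No fine-tuning of
any external model is performed or supported.

The built-in backend is a deterministic hashed character n-gram
encoder: n-grams of sizes 3–5 of the normalized string are counted into
4,096 hash buckets and projected to `dim` dimensions (default 256) with
a seeded Gaussian matrix.  Two properties matter here: it is bitwise
reproducible from its seed with no model download, and strings sharing
wording overlap in n-grams and therefore land close on the sphere.  It
is a lexical encoder, not a semantic one: paraphrases with disjoint
vocabulary ("Highest grade attained") will not be close to their
semantic siblings the way a transformer embedding places them.  Tests
that need semantic closeness therefore construct corpora whose
within-category items share wording, and conclusions about real
transformer embeddings rest on the geometry being the same (unit-norm
vectors, cosine similarity), not on the fallback's lexical behavior.

## Locally linear embedding

LLE assumes the data lie near a low-dimensional manifold that is
locally linear.  Each point is reconstructed from its `K` nearest
Euclidean neighbors with weights summing to one; the embedded
coordinates `Y` minimize the same reconstruction residual

$$\Phi(Y) = \sum_i \bigl\lVert Y_i - \textstyle\sum_j W_{ij} Y_j \bigr\rVert^2,$$

obtained from the bottom `d + 1` eigenvectors of
$(I - W)^\top (I - W)$, discarding the constant eigenvector.

Numerical choices:

* **Local Gram regularization.** The local Gram matrix is conditioned
  with a ridge of `reg * trace(G) / K`, `reg = 1e-3` by default — the
  standard LLE conditioning for duplicated or locally coplanar
  neighborhoods; duplicated points are thereby resolved rather than
  fatal.
* **Ties.** Neighbor ties break toward the lowest row index, making the
  neighbor graph deterministic.
* **Eigen-solver.** The dense symmetric solver is used; the corpus
  scales this package targets (a few thousand items) fit comfortably.
* **Sign convention.** Each embedding column's largest-magnitude entry
  is made positive so runs are comparable.
* **Degenerate regimes.** When the ambient dimension is at most `K`,
  any point is an exact affine combination of its neighbors and
  $\Phi$ collapses to eigensolver noise near machine zero; comparisons
  of $\Phi$ between implementations are then meaningless.  The
  package's correctness fixtures therefore live in a 10-dimensional
  ambient space with ambient noise, where $\Phi \approx 10^{-4}$ — a
  genuinely nonzero quantity of the magnitude seen on real question
  corpora.

The dimension sweep refits LLE on `replications` random subsamples
(without replacement) and aggregates $\Phi$ per candidate `d`; since
the weight matrix and eigensystem depend only on the subsample and `K`,
one decomposition per replication serves the entire `d` grid.
Dimension selection is **manual by default**: on real data the
$\Phi(d)$ curve can increase with `d`, in which case no automatic rule
recovers a practitioner's choice, and pretending otherwise would
overclaim.  A `knee` mode (maximum perpendicular distance to the chord
joining the curve's endpoints) is provided for curves with a genuine
bend.

## Spherical k-means

Points and centroids live on the unit sphere; the dissimilarity is the
cosine distance $1 - \cos(x, c)$.  Assignment takes the nearest
centroid (ties to the lowest index); the update renormalizes the member
mean.  Iteration stops when labels stabilize or after `max_iter`
sweeps (default 10); among `restarts` seeded initializations the model
with lowest inertia wins.  Within a run the inertia descends
monotonically, which the test suite asserts per iteration.

Initialization defaults to `cosine_plus_plus`, k-means++ seeding
adapted to the cosine distance.  A `similar_cut_like` option implements
the fast farthest-first idea (each new seed is the point whose maximum
similarity to the chosen seeds is smallest); it is an approximation of
the similarly named initializer in the document-clustering literature,
not a port.  An empty cluster is repaired deterministically by
reseeding it with the point farthest from its centroid, and the event
is logged in the model object.

A `minimum_df_factor` sparsity option zeroes centroid coordinates
supported by fewer than that fraction of member documents — meaningful
for non-negative term-frequency inputs.  On dense coordinates (such as
LLE output, which has negative entries) the projection has no sensible
interpretation, so it is a warning-level no-op rather than a guess.

Model selection reports, per candidate `k`, the inertia (elbow curve),
the Calinski-Harabasz index, and the mean cosine silhouette from the
same fitted model; the elbow knee uses the same distance-to-chord rule
as dimension selection, with manual override supported.

## In-Group Proportion validation

IGP connects reproducibility to prediction: cluster the training half,
assign the held-out test half to the fitted centroids, and ask — for
each cluster — what proportion of its test points have a nearest test
neighbor with the same assignment.  Values near 1 mean the structure
found in training data reappears in independent data.

Conventions: the metric defaults to cosine, consistent with the
spherical geometry of the clustering stage; `one_minus_pearson` (the
correlation distance used by correlation-based reproducibility tools)
is available for cross-checking.  A cluster with fewer than two
assigned test points has an ill-defined proportion and is reported as
`NA`, excluded from summaries, and counted in `undefined_clusters` so
totals reconcile.  Replicated validation draws a fresh partition per
run, each with a seed derived from the master seed, and emits one
summary row per run (`Median`, `IQR`, `Mean`, `SD`, `Q1`, `Q3`,
`Range`, over the defined per-cluster values, using
linear-interpolation quantiles throughout).  By default validation runs
in the reduced space; passing the raw embedding matrix validates the
un-reduced space instead.

## Taxonomy mapping

Each taxonomy row is concatenated — category, up to three
subcategories, then the definition, joined with `", "` — and embedded
with the same encoder as the reference names.  All pairwise cosine
similarities form one distribution; the mapping threshold is its
boxplot upper hinge

$$Q_3 + 1.5 \times (Q_3 - Q_1),$$

and a category maps to a reference name when their similarity is
**strictly greater** than the threshold (equality excluded).  One
category may map to several references.  Coverage is the percentage of
categories with at least one edge, and it is monotonically
non-increasing in the threshold — a property the test suite checks.

Quantiles use linear interpolation between order statistics (the
mainstream numerical default); strict Tukey hinges differ slightly and
can be selected via `quantile_type = 2`.  The convention in use is
recorded in the run manifest.  Node keys are the category plus its
subcategory path, so rows sharing a top-level category remain distinct
nodes.  The package bundles the 36-row SDOH category taxonomy as a
fixture; reference name lists (such as PhenX protocol names) are
user-supplied.

## Synthetic data: what it emulates, and what it does not

Two generators make every stage testable offline:

* **Planted spherical mixtures.** Components are von Mises–Fisher
  (vMF) distributions: means drawn uniformly on the sphere subject to a
  maximum pairwise cosine (default 0.7), points drawn with the
  Ulrich/Wood rejection sampler.  vMF is the natural planted model for
  a pipeline whose geometry is cosine-on-the-unit-sphere.  The
  corpus-scale stress test uses n = 3,582 with a 1,937/1,645
  train/test split, k = 38 clusters in d = 35 — the scale of a real
  multi-site question corpus — with κ = 200, chosen so the
  within-cluster spread (mean cosine to the component mean ≈ 0.915 at
  d = 35) sits well inside the separation constraint: "well-separated"
  by construction.  On such data per-run mean IGP is expected high
  (the acceptance checks use 0.85 as the bar), and on a uniform-sphere
  null it must drop materially.
* **Template corpora.** Question records are generated from a
  paraphrase bank keyed to the bundled taxonomy's top-level categories,
  with randomized section paths, varied lead-in phrasings, and injected
  exact duplicates under different paths — reproducing the structures
  the corpus module must handle (path variation, case/whitespace
  noise, duplicate inflation).

What the generators do **not** emulate: real clinical wording
diversity, imbalanced category sizes beyond multinomial fluctuation,
non-vMF cluster shapes, and the semantic (rather than lexical)
closeness of true paraphrases.  Passing tests therefore demonstrate
the pipeline's statistical machinery — recovery, reproducibility,
thresholding, determinism — under a favorable generative model, not
performance on any real corpus.

## Reproducibility

Every stochastic step takes an explicit seed and restores the caller's
RNG state.  `run_pipeline()` fans a master seed out as
`stage_seed = master_seed + 1000 * stage_index`, so stages can be
re-run independently.  The manifest records, per stage, the
parameters, the seed, and MD5 content hashes of inputs and outputs;
re-running with an identical config must reproduce identical hashes
for every deterministic stage, which both the test suite and the
end-to-end acceptance check assert.  Expert relabels
(`apply_sme_relabels()`) are applied on top of algorithmic labels with
a before/after audit log and a reported override fraction, keeping the
manual step of the workflow inspectable.

## Problem sizes and limitations

The test suite exercises small instances (n ≤ 600) for oracle
equivalence and recovery, and one corpus-scale IGP calibration
(n = 3,582, 10 runs).  Dense-eigen LLE is O(n³) in the decomposition;
beyond roughly 5,000 items an iterative solver would be the next step
and is not implemented.  The elbow and knee rules are heuristics: on
curves without a clear bend (including overlapping planted clusters)
they can return neighboring values of the true count, which is why
manual selection remains the default for dimension choice and an
explicit option for k.  The built-in encoder's lexical nature is the
main gap between synthetic validation and real-corpus behavior; with
an external sentence encoder plugged in, every downstream stage runs
unchanged.
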