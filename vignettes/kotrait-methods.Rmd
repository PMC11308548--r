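---
title: "Predicting microbial traits from KO profiles: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting microbial traits from KO profiles: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
pieces are designed the way they are.  It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The model

A functional trait (a FAPROTAX-style functional group: methanogenesis,
cellulolysis, sulfate respiration, ...) is treated as a binary property of a
genome.  The working assumption, inherited from the curated taxon–function
databases this package consumes, is that **every organism inside an
affiliated taxon can perform the associated function**.  Labels therefore
propagate strictly *downward* through the taxonomy: a genome is positive for
a function when its own taxid, or any ancestor on its lineage, is a matched
member taxon of that function's group.  Nothing ever propagates upward.

Features are KEGG-ortholog (KO) **copy numbers**: the number of genes in the
genome annotated with each K number.  A gene listing $n$ KOs contributes one
copy to each of the $n$ (not $1/n$ fractionally) — the simplest reading of
"copy number" that keeps counting deterministic and integer-valued.

Each class gets its own one-vs-rest binary classifier.  Joint multi-label
models are deliberately out of scope: classes overlap heavily and their
positive sets differ by orders of magnitude, so per-class models with
per-class standardization are both simpler and easier to audit.

## Database parsing and set algebra

The flat-text database dialect is: a group starts at a non-indented header
line `name<TAB>annotation`; member lines are asterisk-delimited taxonomic
paths (`*Genus species*`); directive lines are `add_group:NAME`,
`subtract_group:NAME`, `intersect_group:NAME`.  Unknown line types are
skipped with a warning, never silently.  The canonical identity of a taxon
strips the leading/trailing wildcards and keeps interior level boundaries as
`;`; case is preserved, because case-folding belongs to the name-matching
stage, not to identity.

Resolution starts from a group's literal members and applies its directives
in file order (union, difference, intersection), with referenced groups
resolved first in topological order.  Cycles are a hard error naming the
cycle.  Taxa subtracted out of every group are dropped from the
taxon × function matrix: rows represent function-bearing taxa.

## Taxonomy matching

Names are matched against an NCBI-style dump with a fixed cascade: exact
scientific name ("perfect"), then case-insensitive scientific name, then
exact match against any name class (synonyms, equivalent names), then match
after stripping bracketed qualifiers, collapsing whitespace and
case-folding (all "imperfect").  The first successful stage wins.  A name
that hits more than one taxid at its first successful stage is returned
**unmatched** with a logged ambiguity: curated links should be supplied by a
human, not invented by string matching.

Genome selection applies a per-species cap (default 30, grouped on the
species-rank ancestor): complete assemblies are kept first, the remaining
slots filled by seeded uniform sampling without replacement.  The quality
gate keeps genomes with completeness ≥ 90% and contamination ≤ 5%, both
boundaries inclusive; records missing either value are rejected as
`unscored`.

## Training

Per class, in order:

* **Stratified 80/20 split.**  Each label stratum is sampled separately, so
  the positive proportion in the two splits differs from the overall one by
  at most one genome.  Classes with fewer than 2 positives (or negatives)
  are unstratifiable and are skipped with a logged reason.
* **Standardization.**  Feature means and *population* standard deviations
  (divisor $n$) are fit on the training split only; a column $(2,4,6)$ maps
  to $(-1.2247, 0, 1.2247)$.  Constant training columns store a standard
  deviation of 1 and hence map to 0.  Scalers are per-class even though the
  feature space is shared, so a stored classifier is self-contained.
* **Nested cross-validated grid search** (logistic regression, random
  forest, SVM).  Three stratified outer folds; within each outer-train
  portion, a three-fold inner grid search picks the hyperparameter
  combination with the highest inner mean MCC (ties go to the first
  combination in grid order); the winner is refit on the outer-train portion
  and scored on the outer fold.  The final combination is the fold winner
  with the highest outer MCC, ties broken by inner mean, then grid order.
  The nesting keeps hyperparameter tuning out of the generalization
  estimate.
* **Neural-network tuning** is repeated-restart rather than nested: the
  grid is scored on a stratified validation slice of the *training* split,
  the search is restarted 5 times, and the best (combination, restart) pair
  wins.  The held-out test split is never touched during NN tuning — model
  selection for every algorithm sees the test split exactly once, at final
  scoring.
* **Selection.**  Every algorithm's chosen configuration is refit on the
  full training split and scored by MCC on the test split; the argmax
  becomes the class's stored classifier.  Exact ties break by the fixed
  order LR > SVM > RF > NN, preferring models whose importances are
  directly interpretable.

MCC is computed as
$(TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}$, with
the convention that a zero factor in the denominator yields 0.  The test
suite verifies it against the Pearson correlation of the expanded binary
vectors to $10^{-12}$ over 1,000 random confusion tables.

### Backends and hyperparameter grids

| algorithm | backend | tuned dimensions | default grid |
|---|---|---|---|
| LR  | glmnet | C, penalty | C ∈ {0.01, 0.1, 1, 10, 100} × {l1, l2} |
| RF  | ranger | trees, feature-subset rule | {100, 300, 500} × {sqrt, log2} |
| SVM | e1071  | kernel, C | {linear, rbf} × {0.1, 1, 10} |
| NN  | nnet   | hidden units, weight decay | {2, 8, 16} × {0.001, 0.01, 0.1} |

All grids are config-overridable (`trait_config(grids = ...)`).  The
logistic-regression C maps to glmnet's $\lambda = 1/(C\,n)$, which makes the
two objectives identical up to scaling.  The neural network is a single
dense hidden layer with logistic output trained under cross-entropy; its
regularizer is **weight decay rather than dropout**, because the
full-batch quasi-Newton optimizer behind `nnet` has no stochastic
forward passes to drop units from.  The same optimizer stores a quadratic
approximation of the Hessian, so network size is capped (20,000 weights);
wide hidden layers on large KO spaces are out of reach of this backend and
the default units grid is kept small accordingly.

## Prediction, evaluation, importance

Query genomes are aligned to the registry's feature order: training KOs
absent from the query are zero-filled, query KOs outside the training space
are dropped with a logged count, and input order is irrelevant.  Each class
then applies its own scaler and model (decision threshold 0.5 for
probabilistic models).

Evaluation reports per-class confusion counts and MCC.  For classes with
zero truth positives the MCC is reported as `NA` alongside the confusion
matrix — the statistic is uninformative there — with `strict_zero = TRUE`
available for compatibility with tools that report 0.  Superclass scores
pool member-class confusion counts first and compute one MCC on the pooled
table.

Importance extraction is model-dependent: logistic-regression coefficients,
random-forest impurity importances, linear-SVM hyperplane weights.  Two
surrogates are used and always flagged in `source_algorithm`: an RBF-kernel
SVM gets a linear-kernel SVM retrained on the same training split, and a
neural network gets the class's second-best classical model retrained
likewise.  Zero scores are filtered.  Tables larger than 1,000 rows keep
only the top and bottom 10% of the signed-score ranking (the threshold is a
package choice, config-exposed; the extremes always survive truncation).

A consequence worth knowing: an l1-penalized logistic model may be selected
for a class and legitimately keep only a small subset of nonzero
coefficients.  When several informative genes carry redundant signal, the
l1 optimum uses a few of them and zeroes the rest, so the importance table
of such a class lists a *sparse subset* of the truly associated genes — the
parameter-recovery check in the acceptance suite shows exactly this
behavior on one of its five planted classes.

## Simulated genome fragmentation

Incompleteness of MAGs is emulated by removing random segments from the
assembled sequence: removal lengths are drawn from a truncated
Normal(5,000 bp, 1,500 bp) (defaults chosen as a plausible contig-scale
loss; config-exposed and recorded in the manifest), the contig is chosen
with probability proportional to its length, the start position uniformly,
and the excised span splits the contig in two.  Removal stops once the
retained length is at most `target × reference_size × (1 + tolerance)`
(tolerance 1%), and the last removal is clipped to the excess, so the
achieved completeness always lands in `[target, target × 1.01]`.
Completeness is **length-based** against a reference genome size (the
genome's own length by default), so gene content is affected only through
what the removed segments happened to contain.  Output headers record the
parent contig and 0-based half-open coordinates; length conservation is
exact and every output contig is a verbatim substring of its parent.

To study classifier robustness without running a gene caller, the fixture
generator can lay a genome's KO complement onto synthetic contigs as
fixed-length genes with known coordinates; after fragmentation, a gene
survives if its interval is fully contained in a retained fragment, and the
surviving copies form the degraded KO vector.  This emulates re-annotation
under the simplification that genes are uniformly spaced and never
truncated mid-gene into a still-callable fragment.

## Class refinement

`build_refined_dataset()` rebuilds one class from curated genomes with
three guarantees: previous positives of the class become negatives; a
provided genome already present in the base is removed from the base rows
and re-enters only as a positive (a genome is never both a positive and a
negative example of the refined class); holdout genomes are removed from
every row.  New KOs from the provided genomes extend the feature space with
zeros elsewhere.  Provided genomes default to label 0 for every *other*
class — conservative, since nothing is known about their other traits — and
a message points at the default so a label override can be supplied.

## The synthetic-data generators

The generators define the study conditions for every test:

* `synth_dataset()` plants per-class informative KO sets: positives draw
  those counts from Poisson(effect = 5), negatives from Poisson(0.1);
  background KOs are Poisson(0.5) for everyone; every cell is redrawn from
  the background with probability `noise_rate`.  The Poisson model matches
  the non-negative-integer nature of copy numbers; effect 5 against a 0.5
  background is a strong, clearly recoverable signal.
* The default study scale — 200 genomes × ~600 KOs × 5 classes of 40
  positives, noise 0.05 — keeps the full suite and the acceptance script in
  the minutes range on one CPU while leaving the learning problem
  non-trivial.
* `synth_taxonomy()` builds a five-level tree (root/phylum/genus/species/
  strain) with one merged-id redirect and one synonym per run, exercising
  the redirect and cascade paths.
* `synth_genome_fasta()` draws i.i.d. bases at a target GC.

What the generators do **not** emulate: phylogenetic correlation among
genomes (relatives sharing background gene content), annotation error
structure, contamination, or the heavy class-size skew of real databases.
Passing tests therefore demonstrate correctness of the machinery and
recoverability of planted signal — not field performance on real genome
corpora, which depends on those unmodeled properties.

## Numerical choices and degenerate inputs

* MCC zero-denominator convention: 0; zero-truth-positive evaluation: `NA`
  by default, 0 in strict mode.
* Scaler: population standard deviation; constant columns map to 0.
* Grid-search ties: first combination in grid order (deterministic).
* Seeds: one config seed drives the split, the CV folds, the forest
  bootstrap and the NN restarts; fragmentation derives per-genome,
  per-level seeds from a master seed, all below $2^{31}$.
* Empty inputs error early with named messages (empty nodes table,
  unstratifiable class, empty grid, genome already below the fragmentation
  target, corrupted registry artifact).

## Known limitations

* The nnet-backed neural network cannot scale to the tens of thousands of
  KO features of a full corpus; at that scale a minibatch framework is the
  right backend, and the classical three algorithms are the practical
  default here.
* Name matching resolves ambiguity by refusing to guess; heavily curated
  legacy names will need a user-supplied override table.
* The fragmentation gene-survival emulation ignores partial genes and
  operon structure.
* Importance scores are model-relative, not causal: redundant features can
  be arbitrarily shared (l2) or pruned (l1) without affecting predictions.
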