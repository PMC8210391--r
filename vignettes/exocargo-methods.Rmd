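---
title: "Predicting exosome luminal cargo from sequence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting exosome luminal cargo from sequence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exocargo)
```

## The prediction problem

Exosomes are 30–100 nm extracellular vesicles that carry proteins in their
lumen and release them from the cell without a classical secretion signal.
A protein that reaches the extracellular space this way is *leaderless*: it
has no N-terminal signal peptide and no transmembrane anchor, so the usual
ER/Golgi-pathway predictors say nothing about it. `exocargo` asks the
complementary question: given only an amino-acid sequence, can a random
forest tell exosome luminal cargo apart from proteins that are not secreted
by exosomes?

The package covers the full workflow around that question — dataset
curation, sequence encodings, cross-validated model selection, evaluation
metrics, and a gated prediction report — so the pieces are documented here
together with the design decisions each one embeds.

## Sequence encodings

Every classifier input is a fixed-length numeric vector computed from the
sequence alone. Five schemes are available:

* **AA** — amino-acid composition: 20 proportions, one per canonical
  residue, in the fixed order `ACDEFGHIKLMNPQRSTVWY`. Sums to 1.
* **DP** — dipeptide composition: the 400 ordered residue pairs, counted
  over the N−1 overlapping windows of a length-N sequence and divided by
  N−1, in row-major order over the same residue order. The N−1 denominator
  makes the block a probability distribution, which the tests assert to
  1e−9; composition definitions that normalize by N instead would break
  that invariant for every sequence.
* **PCP** — physico-chemical profile: for each of 11 residue property
  scales \(i\), the per-sequence average
  \(P_i = \frac{1}{N}\sum_{n=1}^{N} p_i(a_n)\),
  where \(p_i(a)\) is the scale's normalized value for residue \(a\).
* **PCP_AA** and **PCP_AA_DP** — exact concatenations of the blocks above
  (PCP first, then AA, then DP), of lengths 31 and 431. Combined encodings
  are byte-identical to their standalone blocks, a property the tests check
  directly.

### The 11 property scales

Ten scales are taken at run time from the AAindex compilation bundled with
the `seqinr` package: average flexibility (BHAR880101), residue volume
(GOLD730102), relative mutability (JOND920102), net charge (KLEP840101),
optimized side-chain interaction parameter (OOBM850105), polarity
(GRAR740102), α-helix and β-sheet propensities derived from designed
sequences (KOEP990101/2), amphiphilicity index (MITS020101) and the
modified Kyte–Doolittle hydrophobicity scale (JURD980101). The eleventh,
aromaticity, has no canonical published scale, so it is a binary indicator:
1 for F, W and Y, 0 otherwise. Histidine is deliberately not counted as
aromatic — its ring is protonatable and its hydrophobicity profile sits
apart from the three canonical aromatics; treating it as aromatic is the
minority convention.

"Normalized" is taken to mean min–max scaling to [0, 1] within each scale
(the minimum residue maps to 0, the maximum to 1). This bounds every PCP
feature in [0, 1], makes constant-scale unit tests exact, and is invariant
to the affine freedom with which published scales are reported. Scales with
different raw values but the same ordering and spacing therefore produce
identical features. A custom table can be supplied via `read_scale_set()`;
the row order of the table defines the feature order.

Exact numeric equality with any particular historical software stack is not
claimed: another AAindex transcription, or different scale choices for the
loosely named properties, would shift PCP features slightly. Everything
downstream (forest training, metrics) is agnostic to that choice.

## Sanitization policy

The 20-letter canonical alphabet is enforced everywhere. Ambiguity codes
(B, J, O, U, X, Z) are handled asymmetrically on purpose: when *building a
dataset* the default drops any record containing them (training purity —
an imputed residue in a training sequence is invisible noise), while at
*prediction time* the default maps U→C and O→K and deletes the rest, so a
user query is never silently refused. Both policies are idempotent and
logged; `strict` mode turns any non-canonical residue into an error naming
the residue and position.

## Identity statistics and redundancy reduction

Pairwise similarity uses Needleman–Wunsch global alignment (Biostrings)
with BLOSUM62 and affine gap cost 10 + 0.5 per gap position — the default
parameterization of the widely used `needle` tool. Two conventions are
fixed and documented because they change the number reported:

* **Identity denominator** — identical columns divided by the *full
  alignment length including gap columns*. This is the most conservative
  of the common definitions (alternatives divide by the shorter sequence
  length, which can only raise the value).
* **Terminal gaps are penalized** (pure global alignment). Ends-free
  variants give slightly different alignments for length-mismatched pairs;
  one convention has to be picked, and the fully penalized one is the
  mathematically standard Needleman–Wunsch recurrence.

For co-optimal alignments the reported identity is that of the optimal path
the aligner returns; between implementations this can differ by a point or
two on essentially unrelated pairs (identity ~10–15%), which is why the
cross-implementation agreement tests use clearly related pairs whose
optimum is unique.

Dataset-level summaries align every pair once and count it twice, matching
the ordered-pair bookkeeping in which N sequences yield N×(N−1) alignments;
a dataset of identical copies has mean identity 100 and standard deviation
exactly 0. Because full summaries are quadratic, datasets beyond 2000
sequences require either explicit consent (`allow_large = TRUE`) or a
seeded `sample_pairs` budget.

Redundancy reduction is greedy longest-first clustering: sort by decreasing
length, walk the list, join the first representative exceeded in identity,
otherwise found a new cluster. This mirrors the ordering heuristic of the
standard clustering tool for this job (CD-HIT) but replaces its k-mer
pre-filters with true global-alignment identity — exact semantics are worth
more than speed at the scale this package targets, and the retained-set
guarantee (*no retained pair above the threshold*) is asserted by an
exhaustive post-hoc scan in the tests. Note that CD-HIT's own identity
definition divides by the shorter sequence; the needle-style definition
used here is the stricter of the two, so a threshold of 80 removes at least
as much as CD-HIT would.

## Random-forest training and model selection

The classifier is a probability forest (`ranger`) with the common defaults
for this model family: `mtry = sqrt(p)` features per split and unlimited
tree depth. A record's score is the forest's class-probability estimate for
the positive class; the Y/N call applies a decision threshold of 0.5, the
probability analogue of the forest's modal vote. Training is exactly
reproducible: the master seed deterministically derives every fold shuffle
and every per-fit seed, and all fits run single-threaded, so two runs of
the same configuration are bitwise identical.

Model selection sweeps the number of trees over a 31-value grid (100 to
1000 in steps of 50, 1500 to 6000 in steps of 500, then 8000 and 10000)
under stratified tenfold cross-validation repeated 10 times. Design choices
worth stating:

* **Stratification** — folds preserve the class ratio to within one record.
  With near-balanced classes this is almost free, and it stabilizes
  fold-level MCC, which degrades badly in accidentally unbalanced folds.
* **Fold-level aggregation** — performance is reported as mean ± sd over
  the `n_repeats × n_folds` fold-level metric values (e.g. 100 values for
  10×10). Reporting a dispersion requires per-fold values; pooling
  predictions first would hide fold-to-fold variance.
* **Encoding before splitting** — feature vectors are strictly
  per-sequence, so encoding the whole dataset once cannot leak information
  across folds; the no-leakage property is still asserted via id
  bookkeeping in the tests.
* **Tie-breaking in selection** — the winning (scheme, trees) cell
  maximizes the chosen criterion; ties prefer fewer trees (cheaper, less
  variance) and then the simpler scheme in the fixed order
  PCP < AA < PCP_AA < DP < PCP_AA_DP.

Accuracy as a function of tree count typically climbs and then flattens
around 1000–2000 trees; `autoplot()` on a sweep result shows exactly this
curve per scheme.

## Evaluation metrics

With TP/FN/TN/FP the confusion counts at a threshold:

$$SE = \frac{TP}{TP+FN},\qquad SP = \frac{TN}{TN+FP},\qquad
ACC = 100\cdot\frac{TP+TN}{TP+FP+TN+FN}$$

$$MCC = \frac{TP\cdot TN - FP\cdot FN}
{\sqrt{(TN+FN)(TP+FN)(TN+FP)(TP+FP)}}$$

The Matthews coefficient uses the standard cross-product numerator
\(TP\cdot TN - FP\cdot FN\); that is the only form consistent with its
advertised behaviour (−1 for an all-wrong prediction, +1 for a perfect
one), which the tests pin down on enumerated tables. Any metric whose
denominator is zero is reported as `NA` with no error, so fold aggregation
can skip undefined cells and count them.

AUC is the area under the ROC curve (SE against 1−SP over all thresholds).
The default implementation is exact Mann–Whitney pair counting via
midranks — tied scores count one half — and a trapezoidal integration of
the threshold-swept curve is implemented independently; the two agree to
1e−9 on randomized instances with deliberate ties, and both are
cross-checked against the `pROC` package.

## The gated prediction report

The secretion model is only meaningful for the population it was trained
on: vertebrate proteins with no signal peptide and no transmembrane region.
The report therefore gates every query: a protein failing any of the three
conditions gets `NA` in the secretion column and no score, and the tests
fuzz this over randomized annotation combinations to show no scored record
ever violates the gate.

Missing external evidence is handled asymmetrically, mirroring curation:

* **Dataset building** (conservative): a record whose vertebrate/SP/TM
  status is unknown is dropped and counted under its own log category.
* **Prediction** (permissive): unknown vertebrate status still gets a
  score (reported as `unknown`, with `uniprot_id` "not found"); unknown
  SP/TM flags default to "no" via the `unknown_is` policy flag, which can
  be flipped to gate instead.

The package consumes annotations from a TSV table rather than running the
external annotators (taxonomy lookups, signal-peptide and transmembrane
predictors) itself: the science here begins downstream of those tools, and
a table keeps every run reproducible. The annotation booleans are
deliberately tri-state (yes/no/unknown); collapsing unknown into no at
parse time would make the two policies above indistinguishable.

## The synthetic-data generator

`generate_synthetic()` emulates the *shape* of a curated two-class training
set — balanced classes, protein-like lengths (default 50–400 residues), a
tunable amount of compositional signal, and an annotation table with a
configurable fraction of disqualifying flags. Two signal constructions:

* **`aa_bias`** — classes draw residues i.i.d. from two distributions
  built by mixing a Dirichlet-drawn base distribution with class-preferred
  half-alphabets; the total-variation distance between the classes equals
  `bias_strength`, so 0 is an exact null and 1 gives disjoint alphabets
  (trivially separable — useful as a positive control).
* **`dipeptide_bias`** — first-order Markov chains whose transition
  matrices are mixtures of the uniform kernel with class-specific
  residue-cycle permutations. Both chains have the *uniform* stationary
  distribution, so single-residue composition carries no class signal
  while transition (dipeptide) structure does. This isolates the added
  value of the DP encoding in a verifiable way: in the tests the DP scheme
  beats the AA scheme by a wide margin on such data, while AA hovers near
  chance.

What the generator does **not** emulate: real exosome cargo biology
(sorting motifs, domain content, disorder), homology structure between
sequences, database annotation bias, or class imbalance. Passing tests on
synthetic data therefore demonstrate that the machinery is correct — not
that any particular accuracy will be reached on biological data.

## Numerical choices and test-scale parameters

* Composition blocks are asserted to sum to 1 within 1e−9; analytic
  feature cases (two-residue averages) to 1e−12.
* Statistical assertions are sized to their sampling noise: the null-AUC
  band 0.5 ± 0.02 at n = 10,000 is ~7 standard errors wide; the
  marginal-matching bound for `dipeptide_bias` (total variation < 0.01)
  is checked at 500 sequences per class where sampling alone contributes
  about 0.006.
* Cross-validation tests run on a few hundred synthetic records with
  short tree grids (≤ 300 trees); these sizes are where the separable
  constructions already saturate, and nothing in the code depends on them.
* Degenerate inputs fail loudly and early: single-class labels, sequences
  shorter than 2 under DP, classes smaller than the fold count, duplicate
  ids in a prediction batch, constant property scales.

## Known limitations

* The bundled property scales are one reasonable transcription of the 11
  named properties; other transcriptions shift PCP features slightly.
* Redundancy reduction is quadratic in the number of alignments; for
  datasets in the tens of thousands an external clustering tool is the
  right choice, and the cluster-map format here was chosen to be
  interoperable with that workflow.
* The identity summary's standard deviation follows the ordered-pair
  convention (each unordered pair counted twice); the mean is unaffected,
  the sd differs from the unordered convention by a factor
  \(\sqrt{(2m-1)/(2m-2)}\) at m unordered pairs — negligible beyond toy
  sizes, but worth knowing when comparing against other tools.
* Forest probability estimates are terminal-node class frequencies
  averaged over trees; they are well-ordered but not calibrated, so the
  0.5 threshold is a vote boundary, not a calibrated probability.
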