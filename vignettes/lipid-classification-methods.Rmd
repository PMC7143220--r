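---
title: "Predicting lipid categories from elemental molecular formulas: methods and design"
author: "lipidForest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lipid categories from elemental molecular formulas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidForest)
```

## The problem

Untargeted FT-MS assignment tools can attach non-adducted elemental
molecular formulas (EMFs) to observed spectral features without consulting
metabolite databases, but downstream lipidomics questions are usually posed
at the level of lipid *categories* (the eight top-level LIPIDMAPS groups:
fatty acyls, glycerolipids, glycerophospholipids, sphingolipids, sterol
lipids, prenol lipids, saccharolipids, polyketides) and *classes* (their
subdivisions). An EMF alone carries no structure, so category membership
must be inferred from composition. lipidForest treats this as supervised
classification: Random Forest models learn the mapping from
formula-derived features to lipid labels using curated databases (or, in
this package's tests and examples, a synthetic stand-in with known ground
truth).

## The feature vector

Every model consumes the same descriptor, a pure function of the formula
(`featurize()`):

* the atom count of each CHONPS element and the summed count of all other
  elements;
* the theoretical monoisotopic mass, recomputed from a bundled, versioned
  table of most-abundant-isotope masses (`isotopeMassTable()`), so that
  observed-mass error cannot leak into classification;
* the hydrogen deficit due to unsaturation, `2C + 2 + N + P - H`, i.e.
  twice the ring-plus-double-bond-equivalent count under the fixed valence
  convention C=4, N=3, P=3, O/S divalent. The deficit may be negative for
  non-chemical formulas; hull enumeration produces such formulas and they
  must remain featurizable rather than raise;
* the first `k` fractional digits of the mass. The mass is *rounded* to
  `k` decimal places before the digits are read (truncation would differ
  only in rare borderline cases; rounding is the documented choice).

`k = 4` by default: four fractional digits resolve roughly 0.1 mDa, which
comfortably encodes the mass-defect signal that distinguishes, say,
phosphorus-rich from oxygen-rich compositions, and matches the ~1 ppm
digital resolution of modern FT-MS instruments at 1000 Da. Only the
fractional digits are expanded -- the integer part is already present as
the mass feature itself. Features deliberately sit on different scales;
Random Forest is scale-free, so no normalization is applied.

## Training sets

Lipid records arrive from LMSD-style (tag-field SDF or TSV) and
LMISSD-style (TSV) exports, non-lipids from HMDB-style XML or TSV with
entries of the lipid super-class removed and everything else labeled with
the extra category/class `non_lipid`. Because lipid isomerism is rampant,
records are de-duplicated *by formula*: each distinct element-count map
becomes one record carrying the union of every category and class observed
for it. Identity is the exact count map -- isomers collapse, isobars do
not. A formula appearing both as a lipid and as a non-lipid keeps only the
lipid labels, consistent with how known lipids are removed from the
non-lipid source in the first place; this conflict rule is a design choice
of this package, not something the source databases prescribe. Field maps
for SDF tags and XML paths are configuration, because export dialects
drift across database versions.

## Model organizations

Two organizations are implemented:

* **Hierarchical** (`trainHierarchy()`): one binary one-vs-rest forest per
  category (positives: records carrying the label; negatives: everything
  else), and one per class, with class models evaluated *only* for inputs
  whose parent category model fired. Gating guarantees the reported class
  labels are always consistent with the reported categories, and each
  model learns a single decision boundary.
* **Monolithic** (`trainMonolithic()`): one multiclass forest over all
  categories and one over all classes, trained on the identical feature
  matrix. Multi-label records are replicated once per label -- the
  simplest defensible way to feed a multi-label record to a single
  multiclass learner, and a documented choice since nothing canonical
  exists. Category and class vote independently, so contradictions are
  possible; that weakness is the point of keeping this baseline around.

Forests use 500 trees by default and otherwise standard Random Forest
hyperparameters. A label fires when its positive vote fraction reaches
the threshold (default 0.5, majority vote -- the threshold is exposed
because no canonical value exists). Labels with fewer than 10 positive
records are skipped with a prominent warning rather than trained into
degenerate forests. Training is deterministic given (data, seed, tree
count): each forest draws from a seed derived from the user seed and the
label index.

## Evaluation

`evaluateOob()` reports, per label, out-of-bag accuracy (each training
record scored only by trees that did not sample it) and precision
`tp/(tp+fp)` from out-of-bag votes. Out-of-bag estimation is used
*instead of* k-fold cross-validation: bagging already provides an
internal held-out estimate, and k-fold CV would only shrink the training
data for these unbalanced label sets. Accuracy is one-vs-rest accuracy
over *all* records (not restricted to the label's positives); this
interpretation is implemented consistently and stated here because the
alternative reading exists. Precision with zero positive predictions is
reported as `NA`, never 0 or 1.

## Convex-hull generalization testing

To probe behavior on plausible-but-unseen formulas, `buildHull()` treats
each CHONPS formula as a point in a 6-D integer lattice, keeps generator
points below 1600 Da, and builds the convex hull; `enumerateLattice()`
yields every lattice point inside; `classifyHull()` streams them through
the classifier into a per-label tally. Implementation notes:

* The hull is computed with an incremental beneath-beyond algorithm in
  the affine subspace actually spanned by the points, so rank-deficient
  generator sets (all points sharing a coordinate) become explicit
  equality constraints rather than failures.
* Membership tolerance is `1e-9` scaled by the facet offset, so boundary
  lattice points -- including the hull's own generators -- count as
  inside.
* Enumeration scans the bounding box in lexicographic order with interval
  pruning derived from the facet inequalities. Pruning changes cost only;
  tests verify the output set equals an unpruned scan with an independent
  membership oracle, and 2-D counts match Pick's theorem.
* The mass filter applies to generator points only. Enumerated interior
  formulas are *not* mass-filtered unless `massLimitEnumerated` is given,
  since either convention is defensible; both are provided.

Desk-scale hulls (tens of generators, thousands of lattice points) are the
intended regime here; the full hull over a curated metabolome contains
~10^8 formulas and is explicitly out of scope.

## Assignment correspondence

Correct assignments recur across the samples of a dataset; artifactual
ones mostly do not. `assignmentCorrespondence()` filters per-sample
assignment records at an E-value cutoff (records with `e_value <= cutoff`
are retained, matching the conventional "<= 0.1" and "<= 0.01" usage),
optionally keeps only lipid-classified formulas, and counts distinct
samples per formula. A formula's representative m/z is the median of its
retained peak m/z values (a documented choice; nothing canonical exists).
`correspondenceHistogram()` bins formulas into 400-wide m/z bins up to
1600 -- the four panels conventionally used for this analysis -- and
`compareShifted()` contrasts a calibrated table against a miscalibrated
one, reporting per-bin means, maxima, counts above a correspondence floor
and the signed corroboration gap (unshifted mean minus shifted mean).
Histograms count formulas (distinct-sample counts), not formula-peak
pairs. Empty bins contribute a mean of zero, so the gap over an empty
shifted bin equals the unshifted mean.

## The synthetic study

`generateLabeledFormulas()` fabricates labeled records from per-category
composition rules: fatty acyls are C8-30 chains with 1-7 unsaturations
and 2-4 oxygens; glycerolipids are a glycerol backbone plus 1-3 acyl
condensations (each adding CnH2n-2O, n = 8-22); glycerophospholipids add
a phosphate and optionally a nitrogen to that core; sphingolipids are
large (C30-48) nitrogenous formulas with optional phosphate; sterols are
C27-30 with 5-8 unsaturations; prenols are isoprene multiples (C = 5m,
H = 8m-2d with d = 0-3 and up to two oxygens, the unstated ranges fixed
here once); saccharolipids are an oxygen-rich sugar core (C20-40, O
10-16) bearing two acyl arms, which is what pushes their masses toward
1450 Da as real saccharolipids reach; polyketides are C10-30 with an
O/C ratio of 0.2-0.5; non-lipids are small CHNOPS formulas under 350 Da.

These rules are caricatures engineered for separability comparable to
curated databases, not chemical truth: they reproduce the coarse
compositional signatures (phosphorus in glycerophospholipids, nitrogen in
sphingolipids, oxygen richness in saccharolipids) but none of the
fine structure, biosynthetic constraints, or real mass/composition
distributions of LIPIDMAPS. Passing tests on this study therefore
demonstrates that the pipeline recovers separable category structure at
realistic scale and label imbalance -- not that any particular real
database would yield the same per-category numbers. An `overlap`
parameter injects boundary-straddling records to stress precision, and
the rules naturally emit isomeric collisions that exercise the
multi-label union semantics of de-duplication.

`generateAssignments()` emulates multi-sample assignment lists: true
formulas are lipid-labeled records sampled stratified across the four m/z
bins (so every bin of the correspondence analysis is populated, as a full
FT-MS peak list would be), each appearing in a sample with probability
`recurrence` (default 0.8 over 10 samples) at log-normal E-values with a
low mode (median 0.02); decoys are per-sample random CHONPS formulas at a
higher mode (median 0.25), lipid-labeled 35% of the time. The shifted
variant models gross miscalibration by dropping true-formula recurrence
to one sample each and inflating the decoy count by 5% -- within the
3-6% growth in assignments that a +21 m/z shift produces in practice.
The miscalibration is emulated at the assignment-table level; re-running
an assignment engine on shifted peaks is out of scope.

## Study sizes and determinism

The default study is 400 records per label over 9 category labels (3600
records, ~2000 unique formulas after de-duplication) with 500 trees per
forest; at these sizes training the full hierarchy takes well under a
minute and every category model reaches out-of-bag accuracy at or above
0.90 with precision at or above 0.83 -- the recovery bar asserted in the
test suite. Hull demonstrations use generator sets of under a hundred
formulas (a few thousand lattice points). All randomness flows through
explicit integer seeds; identical seeds yield byte-identical generator
output and identical forests and predictions.

## Known limitations

* Formula-only features cannot resolve categories whose members are
  compositional twins; multi-category output (or none) is the honest
  answer there, and the classifier reports exactly what fired.
* The monolithic baseline can emit contradictory category/class pairs by
  construction.
* The synthetic generator's caricature rules overstate separability
  relative to real curated databases at the class level, where real
  classes overlap heavily in composition.
* Adducts, charges, isotope labels and isotopologue patterns are outside
  the formula dialect: inputs are non-adducted neutral EMFs.
* Hull enumeration cost grows quickly with generator spread; the
  implementation streams and prunes but is meant for desk-scale studies,
  not exhaustive metabolome hulls.
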