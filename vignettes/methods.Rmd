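---
title: "Methods: curation, chemical space, cliffs and rules in ureascape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation, chemical space, cliffs and rules in ureascape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ureascape analyses heterogeneous enzyme-inhibition bioassay collections —
the motivating system is urease, a nickel metalloenzyme targeted in both
antimicrobial and agricultural programs — where potency values (IC50, Ki)
come from many laboratories, species and decades, with inconsistent
controls, duplicated structures and qualitative "inactive" reports. The
package turns such a table into a curated compound set and profiles its
chemical space, activity landscape and interpretable activity rules. This
vignette records the models, conventions and numerical choices behind each
stage, in the order the pipeline runs them.

## Curation model

Activity is made comparable across assays by normalizing each value against
the control of its own assay: `ratio = activity / control`, both in µM.
When a publication reports no control, a fallback of 20 µM is used — a
typical IC50 of thiourea, the usual jack-bean urease control — applied
globally and configurable (`default_control_um`). Compounds described only
as "inactive", with no measured value, receive an excess value of 1000 µM
*before* normalization. A compound is classified **active** when its ratio
is strictly below 1 (more potent than the control); the boundary ratio 1.0
is inactive. IC50 and Ki records are pooled on the ratio scale; the
activity type is kept for provenance only.

Structures are standardized in three documented steps: OpenBabel
canonicalization; salt stripping (of the dot-separated fragments, the
largest carbon-containing fragment is kept, ties broken lexically);
and charge neutralization. Tautomers are *not* canonicalized — two
tautomeric spellings can map to different InChIKeys, a known limitation
shared with most fast standardizers. Metal complexes (any element outside
H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I remaining after counterion
stripping — a deliberately conservative list, overridable via
`allowed_elements`) and mixtures (two or more distinct organic fragments)
are rejected with reasons; nothing is dropped silently, and the record
accounting `sum(n_merged) + rejects = raw records` is asserted in the test
suite.

Duplicates are merged by InChIKey, keeping the most potent record (minimum
ratio). Potency ties break on the lexicographically smallest reference id —
determinism over arbitrary choice. "Most potent" is compared on the
normalized ratio rather than the raw value, since when two assays used
different controls the ratio is the scale on which classification happens.
Species labels are unioned and the earliest year kept, so per-species views
are derived rather than stored; cross-species concordance therefore runs on
the pre-merge record table.

## Fingerprints and similarity

Similarity everywhere is the Tanimoto coefficient over 1024-bit circular
(Morgan-type, radius 2) fingerprints. The fingerprint is implemented in the
package: initial atom invariants are (element, heavy-atom degree, total
hydrogen count, formal charge, ring membership); identifiers are iteratively
refined over sorted (bond order, neighbor identifier) lists and every
identifier at radii 0–2 is hashed onto 1024 bits. Two conventions matter:

* aromatic ring bonds contribute order 1.5, which makes the bit vector
  independent of the kekulé structure the SMILES writer happened to choose;
* the Tanimoto of two all-zero vectors is defined as 0 (this can only occur
  for molecules with no hashed environments).

Bit collisions at 1024 bits are accepted as-is; no count vectors are used.
Fingerprints must be computed on *standardized* SMILES — canonicalization
is what guarantees two spellings of one molecule agree.

Murcko scaffolds are computed by iteratively deleting terminal atoms
attached through single bonds, so ring systems, linkers and exocyclic
multiple bonds (e.g. a ring ketone's oxygen) are retained; acyclic
molecules yield an empty scaffold.

## Clustering

Two deliberately different clusterings are used:

* **Spontaneous clustering** quantifies raw diversity: complete-linkage
  agglomeration on Tanimoto distance (1 − Tc), cut at height 0.6, which
  guarantees every intra-cluster pairwise distance is at most 0.6. The
  *number* of clusters is the diversity statistic. The cut semantics
  (per-cluster maximum distance, the natural reading of a "maximum Tanimoto
  distance threshold") are verified against a brute-force agglomeration
  oracle in the tests.
* **Family clustering** builds a fixed number *k* of structural families
  with Ward linkage (`ward.D2`, the Euclidean-Ward formulation used by
  scikit-learn's `ward`) on the raw 0/1 bit vectors; no transformation is
  applied to the bits.

Choosing *k* by eye is codified in `select_k`: among candidate *k* whose
smallest cluster has ≥ 3 members, pick the one maximizing the number of
cohesive clusters (minimum intra-cluster Tc ≥ 0.5), ties to the smallest
*k*. The full per-*k* diagnostics table is returned, and an override flag
restores the human choice — the heuristic exists so the selection is
deterministic and testable, not because it is better than inspection.

Each family is summarized by its minimum and median pairwise intra-cluster
similarity (singletons use the convention min = median = 1.0) and by its
maximum common substructure. The MCS is a connected induced common subgraph
maximizing atom count, searched by label-constrained backtracking in which
ring atoms match only ring atoms and bond orders must agree (aromatic =
1.5). The search is exact but time-capped (default 60 s per cluster); on
expiry the cluster reports an empty, flagged scaffold rather than blocking
the pipeline. The result is rendered as SMARTS with per-atom
`[#element;R]`/`[#element;!R]` constraints and order-agnostic `~` bonds:
the search is strict, the rendering permissive, so the guarantee that the
SMARTS matches every member survives kekulization differences in the
matcher. For multi-molecule clusters the MCS is folded pairwise from the
smallest member, a standard approximation that is exact for two molecules.

## Chemical-space map and reference comparison

`embed_2d` is an exact (O(n²)) t-SNE implementation: conditional
affinities from a per-point binary search to the target perplexity
(default 30, capped at (n−1)/3), symmetrized; 500 gradient iterations with
early exaggeration 12 for the first 100, learning rate 200, momentum
0.5→0.8. Coordinates are deterministic given the seed but axes are
arbitrary: they are for reporting only and never feed downstream
statistics. Reference-library comparison counts exact overlaps (InChIKey
equality after standardization) and near neighbors (maximum Tc strictly
above 0.6, excluding exact overlaps), e.g. against an approved-drug SMILES
file supplied by the user.

## Activity cliffs

All unordered pairs with Tc *strictly* above 0.6 (the stricter end of the
usual 0.5–0.55 practice) are enumerated all-vs-all — at a few thousand
compounds this is desk-scale and needs no indexing shortcut — and
allocated to three groups: both active, both inactive (linear SAR pairs)
or opposite classes (activity cliff). The three counts partition the pair
set. A pair's activity contrast is the fold change of normalized ratios,
so cross-assay pairs compare on the control-adjusted scale. A compound's
cliff degree is its number of opposite-class partners; actives with ≥ 10
(configurable; the lower end of the published hub range) inactive partners
are **dead ends**, inactives with ≥ 10 active partners **safe bets**. Top
cliffs rank by fold change with ties broken by Tc, then pair key — stable
and deterministic.

## Rule extraction

A gini decision tree over the descriptor vector, depth-capped at 10 and
otherwise memorization-friendly (cp = 0, minimum split 2, no surrogate
splits — mirroring the defaults of the reference scikit-learn
implementation), is fit to the full curated set. It is a pattern-extraction
device, not a predictor, and is never exposed for prediction on new
compounds.

Rules are extracted anchor-style: every compound's root-to-leaf path is a
candidate IF-THEN rule, then greedily pruned — repeatedly dropping the
condition whose removal best preserves empirical precision on the dataset,
for as long as precision stays ≥ 0.80. This deterministic
evaluate-on-the-data variant reproduces published count/precision semantics
exactly and is fully testable; the published Anchors algorithm's
perturbation sampling is deliberately out of scope. Dropping a condition
can only widen coverage (asserted as a property test). Duplicate rules are
merged and ranked by coverage. Leaf paths that never reach the precision
threshold are kept but flagged `below_threshold` — impure leaves produce
printed-style rules below 80% and silently dropping them would misstate
the tree. Conditions on integer count descriptors are rendered in count
style ("fr_hdrzine > 0", "fr_NH1 = 0"): a path condition "count < 0.5" and
"= 0" are the same statement.

Precision is reported as the percentage of covered compounds in the rule's
predicted class, to one decimal, halves rounded up (the reporting
convention used for all percentages in the package).

Feature relevance is summarized by Friedman's one-vs-all H statistic: the
variance of (centered full partial dependence minus its additive
decomposition into the feature term and the rest term), normalized by the
variance of the full partial dependence and clipped to [0, 1]; constant
predictions define H = 0. Partial dependences are evaluated over the
empirical distribution with an n ≤ 500 subsample cap, since the evaluation
costs O(n²) model calls per feature.

## Descriptors, filters, alert catalogs

The descriptor vector combines OpenBabel bulk properties (MW, logP, TPSA,
molar refractivity), Lipinski-convention H-bond donor (N/O with H) and
acceptor (N + O) counts, rotatable bonds, aromatic ring count, a
Bertz-style graph-complexity score (bond-connection information content
plus an element-distribution term), a Delaney-style ESOL solubility
estimate, and SMARTS-defined functional-group counts (`fr_*`). The
rule-of-5 filter treats values exactly at a limit as compliant and defaults
to the strict zero-violation reading; the common ≤ 1-violation variant is a
flag, since published analyses rarely state which convention they used.

PAINS- and Brenk-style alert catalogs are plain tab-separated SMARTS files
under `inst/extdata/alerts/`, loaded and validated at run time. The bundled
files are compact defaults written from the published alert descriptions —
they cover the classic unwanted moieties (thiocarbonyl, catechol, nitro,
Michael acceptors, N–O single bonds, …) and the most frequent
pan-assay-interference families — not verbatim copies of any reference
catalog. Catalogs are data, not code: users can pin a full catalog version
by pointing at their own file. The same holds for the functional-group
census map (`default_group_map()`), whose family definitions ("urea
analogues", "long carbon chains" = more than six consecutive acyclic
methylenes, …) are documented, editable SMARTS.

## The synthetic-data generator

`generate_library` emulates the *structure* of a literature-curated
bioassay table, with planted ground truth for every downstream stage:

* **Compounds**: 10 aryl cores × 30 substituents = 300 compounds. Cores
  are deliberately mixed in cohesion — large amide/urea scaffolds whose
  analogue pairs clear Tc 0.6, and small bicyclics forming loose families —
  because both regimes occur in real libraries.
* **Activity**: simulated on the log-ratio scale, `value = control ·
  exp(log_ratio + noise)`, so the planted class (log-ratio < 0) maps
  exactly onto the downstream ratio < 1 cutoff. Family base log-ratios are
  small (|·| ≤ 0.3) and substituent shifts dominate (0.6–1.2, alternating
  sign along the substituent list so activity tracks substituent identity
  rather than any monotone physicochemical trend). Hydrazine-type
  substituents are forced strongly activating (−2.0): they carry the
  planted rule `fr_hdrzine > 0 ⇒ active`.
* **Cliffs**: 5% of compounds (never rule-bearing ones, so the planted
  rule stays exact) have their log-ratio sign flipped with a minimum
  magnitude of 0.5; the planted cliff-pair list is the same-family
  opposite-class pairs whose Tanimoto similarity, recomputed at generation
  time, exceeds 0.6 — so the truth is verified by construction.
* **Provenance mess**: references of ~10 compounds with their own controls
  (15–25 µM, 15% missing), 10% duplicated records with perturbed values,
  qualitative "inactive" reports (5%, only for truly inactive compounds, so
  the 1000 µM imputation cannot contradict the truth), mixed µM/nM units,
  species labels drawn with literature-like weights, years 1990–2021.

What it does **not** emulate: real structural diversity (300 enumerated
analogues versus thousands of bespoke structures), tautomer and salt-form
ambiguity, correlated assay batch effects, censored values ("> 100 µM"),
or any real structure–activity relationship. Passing recovery tests
therefore demonstrates that the pipeline's machinery is correct and
internally consistent — not that its thresholds are optimal for any real
library.

Test problem sizes: unit tests run on the 300-compound default or small
fixtures (≤ 60 compounds); recovery under noise uses 5 seeds at noise sd
0.3 log-ratio units. These sizes were chosen to exercise every code path at
interactive turnaround.

## Numerical conventions and degenerate inputs

* Percentages: one decimal, round half up.
* Seeds: one master seed; per-stage seeds derived by hashing the stage name
  (recorded in the pipeline report), all below 2³¹.
* Ties: dedup → smallest reference id; `select_k` → smallest k;
  `top_cliffs` → Tc then pair key; tree splits → rpart's column-order
  behavior with a fixed seed.
* Degenerate inputs: empty reference libraries warn and return zeros;
  single-compound similarity matrices cluster trivially; singleton clusters
  report cohesion 1.0; empty rule coverage flags precision as undefined
  (NA) rather than 0; MCS timeouts flag rather than fail.

## Known limitations

Tautomer-sensitive deduplication; approximate multi-way MCS (pairwise
fold); hash-collision sensitivity of 1024-bit fingerprints; the exact
t-SNE's O(n²) memory (fine to a few thousand compounds); alert catalogs
that are representative rather than exhaustive; and tree-based rules that
describe this dataset rather than predict new compounds — the package
refuses to present them otherwise.
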