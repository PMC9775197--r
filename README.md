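# ureascape

Chemical-space and activity-landscape analysis for enzyme-inhibition
bioassay collections, built for urease inhibitors.

Urease inhibition data accumulates across decades, species and
laboratories: potencies are reported as IC50 or Ki against different
controls, structures are duplicated between references, and weak compounds
are often reported only as "inactive". Before any chemical-space question
can be asked — how diverse is the explored space? which scaffolds are
saturated? which modifications flip activity? — that mess has to be
curated into one comparable compound set. ureascape implements the whole
chain as a reusable, tested R pipeline:

* **Curation** — activities normalized against the assay control
  (`ratio = activity / control`, 20 µM fallback; 1000 µM excess value for
  qualitative inactives), `ratio < 1` ⇒ active; structures standardized
  (canonicalization, salt stripping, neutralization) and deduplicated by
  InChIKey keeping the most potent record; metal complexes and mixtures
  rejected with reasons.
* **Chemical space** — 1024-bit radius-2 circular (Morgan) fingerprints and
  Tanimoto similarity \(T_c = |A \cap B| / |A \cup B|\); Murcko scaffolds;
  exact t-SNE maps; comparison against a user-supplied reference library
  (e.g. approved drugs).
* **Clustering** — "spontaneous" complete-linkage clustering on 1 − Tc cut
  at 0.6 (the cluster count is the diversity statistic) and Ward family
  clustering at fixed k, with per-cluster cohesion statistics and
  maximum-common-substructure scaffolds (ring atoms match ring atoms only).
* **Activity cliffs** — all pairs with Tc > 0.6 split into linear SAR pairs
  vs cliffs; "dead ends" (actives losing activity under many small edits)
  and "safe bets" (inactives gaining it) profiled by cliff degree.
* **Rules** — a depth-10 gini decision tree on 2-D descriptors, distilled
  into anchor-style conjunctive IF-THEN rules at a 0.80 precision
  threshold, plus Friedman one-vs-all interaction scores.
* **Synthetic libraries** — a generator that plants scaffold families,
  activity cliffs and a descriptor rule into a realistic raw bioassay
  table, so every stage is testable against known truth.

## Worked example

```r
library(ureascape)

gl  <- generate_library(synth_config(seed = 42))   # raw table + planted truth
cur <- curate_bioassay(gl$records)
cur
#> Curated bioassay compound set
#>   300 compounds from 335 records (0 rejected)
#>   active: 155  inactive: 145
```

335 raw records (duplicates, qualitative reports, mixed nM/µM units)
collapse to 300 unique compounds, none rejected — the generator plants
only valid structures.

```r
pairs <- enumerate_similar_pairs(cur, threshold = 0.6)
#> 982 similar pairs (Tc > 0.6): 313 both-active, 162 both-inactive, 507 cliffs
```

Of the 982 structurally similar pairs, 507 are activity cliffs — pairs of
near-analogues sitting on opposite sides of the activity cutoff, the
regions where structure–activity intuition fails.

```r
classes <- setNames(cur$compounds$activity_class, cur$compounds$inchikey)
head(cliff_profiles(pairs, classes, min_degree = 10), 3)
#>                     inchikey     role cliff_degree
#>  MQYMKWNLXXZZBH-UHFFFAOYSA-N safe_bet           17
#>  ZSUJAABHVRZUSO-UHFFFAOYSA-N safe_bet           17
#>  LOWPYBLMLJDXJS-UHFFFAOYSA-N safe_bet           16
```

These are inactive compounds forming cliffs with 16–17 active analogues:
small modifications usually *gain* activity, making them attractive
starting points.

```r
desc  <- compute_descriptors(cur$compounds$canonical_smiles)
tree  <- train_activity_tree(desc, cur$compounds$activity_class)
rules <- extract_rules(tree, desc, cur$compounds$activity_class)
head(subset(as.data.frame(rules), !below_threshold)
     [, c("conditions", "predicted_class", "n_total", "precision_pct")], 3)
#>                                  conditions predicted_class n_total precision_pct
#>                 fr_halogen > 0; mw <= 228.2        inactive      23          82.6
#>  fr_NH2 = 0; fr_halogen > 0; log_s > -4.036        inactive      21          85.7
#>                      fr_NH2 > 0; mw > 228.2          active      21          90.5
```

Each rule is a sufficient condition at ≥ 80% empirical precision: e.g. the
first covers 23 compounds of which 82.6% are inactive. Because the truth is
planted, recovery can be verified exactly —
`evaluate_recovery(list(curated = cur, pairs = pairs, rules = rules),
gl$truth)` reports perfect class recovery, cliff recall 1.0 and the planted
hydrazine rule recovered verbatim at noise 0.

A shell entry point wrapping the same functions ships in
`inst/scripts/ureascape` (`synth`, `curate`, `run --config pipeline.yaml`),
and `run_pipeline()` executes all stages with one config, writing stage
CSVs plus `report.json`.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) records the models,
conventions, defaults and numerical choices of every stage — including
what the synthetic generator does and does not emulate, and therefore what
passing tests do and do not demonstrate about real bioassay data.
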