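---
title: "Proteochemometric screening with data-driven target selection: models and methods"
author: "pcmscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteochemometric screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A proteochemometric (PCM) model regresses bioactivity on concatenated
compound and protein descriptors, so one model covers a set of related
targets and can extrapolate across them. For a target whose known ligands
are chemically monotonous — the norepinephrine transporter (NET/SLC6A2) is
the motivating case — a single-target model sees too narrow a chemical
space to rank novel chemotypes. The remedy is to add training data from
related proteins. The question this package operationalizes is *which*
related proteins to add: it treats the inclusion radius as a tunable,
data-scored quantity rather than a fixed family annotation.

The pipeline has five stages, each usable on its own:

1. **Curation** (`curate_dataset`): raw activity tables (ChEMBL-shaped:
   SMILES, target id, activity type, pChEMBL value, year) are reduced to
   one record per (standardized compound, target) pair. Within a pair,
   only the best-ranked activity type is kept (Ki > IC50 > EC50 > Kd);
   surviving duplicates are averaged.
2. **Descriptors** (`compound_block_ecfp`, `physchem_block`,
   `protein_block_zscale_acc`, `protein_block_composition`,
   `assemble_features`): compound and protein descriptor *blocks*
   concatenated into a feature matrix. No cross-terms are computed;
   nonlinear learners are left to discover compound-protein interplay.
3. **Target selection** (`select_training_set`): similarity networks and
   phylogenetic layers propose nested protein sets around the seed
   target; each candidate's records are scored with a fixed
   out-of-the-box random forest, and the largest comparably scoring set
   wins.
4. **Modeling** (`pcm_stack`, `grid_search`, `stepwise_block_selection`):
   random-forest and gradient-boosting bases whose out-of-fold
   predictions (mean and fold spread) feed a partial-least-squares meta
   learner.
5. **Screening and assay analysis** (`screen_library`, `novelty_filter`,
   `cluster_hits`, `tract_analyze`): affinity- and novelty-filtered
   library scoring with density-based clustering of hits, and
   impedance-trace analysis into pIC50 values for follow-up validation.

## Curation conventions

Activity values are pChEMBL units, $-\log_{10}$ of a molar concentration
(100 nM $\equiv$ 7.0). Compound standardization is delegated to Open
Babel: keep the largest fragment, apply a pH 7.0 protonation model,
neutralize residual $\pm 1$ charges, emit canonical SMILES. The result is
a neutral canonical parent; stereochemistry annotations are passed
through unaltered. The operation is idempotent, which makes curation of
an already curated table the identity — a property the tests enforce.

When one pair carries measurements at several priority levels, the
lower-priority measurements are *discarded*, not averaged in: the ranking
is a choice of the single most trustworthy assay readout, not a weight.
For merged duplicates the earliest publication year is kept, so a
temporal split can never leak a compound that was already known early
into the future-facing test side.

## Descriptor blocks

* **ECFP fingerprints**: extended-connectivity fingerprints (radius 3 =
  ECFP-6 by default) hashed and folded to 1,024 bits, computed by Open
  Babel. Tanimoto similarity is intersection-over-union of set bits; two
  all-zero fingerprints are defined as similarity 1 (both featureless).
* **Physicochemical block**: molecular weight, logP, H-bond donors and
  acceptors, rotatable bonds, TPSA, ring count, heavy atoms.
* **Z-scale autocross-correlation (ACC)**: each residue maps to the
  five-dimensional Z-scales; for property pair $(j,k)$ and lag
  $l \in 1..L$ the block emits
  $\frac{1}{n-l}\sum_i \tilde z_{i,j}\, \tilde z_{i+l,k}$ over centered
  per-position values, giving a fixed $25L$-length vector independent of
  sequence length. The default $L = 3$ keeps the block compact (75
  columns) while covering local correlation structure; no alignment is
  needed. Gap characters encode as the all-zero neutral vector.
* **Composition block**: residue (20) and dipeptide (400) frequencies, an
  alignment-free stand-in for coarse sequence-level descriptors.

The ACC lag count and the residue scale are configurable; the shipped
defaults (lag 3, five Z-scales) were chosen once as the compact standard
configuration and are not data-tuned.

## Target selection

All-versus-all protein similarity uses Smith-Waterman local alignment
under BLOSUM62 with gap open 11 / extend 1 (BLAST-like defaults), raw
score symmetrized by the larger of the two orders. A similarity network
at threshold $t$ connects pairs scoring $\ge t$; the connected component
containing the seed is the candidate set, and a descending threshold
sweep yields a nested chain. Thresholds are score-scheme-specific and
therefore user-supplied; the conventional raw-BLAST values
850/650/550/350/100 are kept as documented defaults, while the synthetic
benchmark uses 850/500/150, matched to its planted tiers.

Phylogenetic layers come from a neighbor-joining tree over pairwise
global-alignment fractional-identity distances (a deliberate,
deterministic simplification of a progressive-MSA guide-tree pipeline;
for point-mutant families the two agree). The tree is rooted at the leaf
farthest from the seed so the seed sits at maximal depth; layer $k$ is
the leaf set under the seed's $k$-th ancestor, starting from the seed
itself and ending at all leaves. Network components and tree layers that
contain exactly the same proteins are evaluated once.

Each candidate layer is scored by fitting the *fixed* out-of-the-box
random forest (100 trees, mtry $=\sqrt p$, minimum node size 1, no depth
cap) under seeded 5-fold cross-validation — deliberately not tuned per
layer, so the score reflects the data, not the optimizer. Selection then
takes, among layers with cross-validated $R^2$ within `r2_tolerance`
(default 0.01) of the best, the one with the most records: more data at
comparable quality. $R^2$ is always the coefficient of determination
$1 - SS_{res}/SS_{tot}$, never squared Pearson.

## Stacked modeling

`pcm_stack` is the package's central fitting function. For each base
learner, $k = 10$ fold models are trained on a shared fold assignment.
The meta-feature matrix has two columns per base: the **mean** column is
the out-of-fold prediction (for a training row, from the one fold model
that never saw it — leakage-free), and the **sd** column is the spread of
that row's predictions across all $k$ fold models, a cheap uncertainty
signal. At inference both statistics are taken across all fold models.
The meta learner (PLS by default, on 2 components) is fit on these
columns. The std column does see in-fold models at training time; this
caveat is accepted because the mean — the dominant signal — stays
unleaked, and the convention is applied identically at train and test
time.

PLS is excluded from the default base set: without cross-term features a
linear model cannot express compound-protein interplay, and it
underperforms the tree ensembles; it remains available by configuration.
Hyperparameter grids replicate the conventional search space (trees
100-1000; mtry sqrt/log2/10-50-90%; node sizes 1/5/7; depths 5/7/none;
boosting rounds, learning rate, gamma, depth, subsampling; PLS component
counts), and `grid_search` scores the full Cartesian grid by 5-fold CV,
logging failed cells as $-\infty$ rather than aborting. Stepwise forward
selection over descriptor blocks runs for at most 25 iterations with
patience 3, accepting a block only when 5-fold CV $R^2$ improves; feature
selection runs before the grid, and both trajectories are retained.

Validation splits: random hold-out (10-30%), temporal (train before
2010, test 2010 onward; missing years train), and target-based 70/30 —
proteins clustered by K-means ($k = \max(2, \lceil\sqrt p\rceil)$) on the
principal components covering 90% of protein-descriptor variance, whole
clusters assigned greedily to the training side until its record share
reaches 70%, with a final swap of the crossing cluster to land nearest
the target share. No protein ever appears on both sides.

## Screening

`screen_library` streams a SMILES file (plain or gzipped) in batches, so
memory is bounded in the deck size; a streamed pass is bit-identical to
an in-memory pass. Compounds predicted at or better than 100 nM
(pChEMBL $\ge 7.0$; the boundary is kept) survive. The novelty filter
then computes each survivor's Tanimoto similarity to its nearest
training compound and keeps the open band $0.5 < s < 0.9$: at or above
0.9 the compound is not novel, at or below 0.5 the model is outside its
applicability domain. Filtering runs *before* clustering — the filter is
per-compound, so order does not change the kept set, but filtering first
keeps the clustering honest to the reportable chemical space.

Survivors are clustered with HDBSCAN on fingerprint Jaccard distance
(never on a 2D embedding; density clustering on embeddings is unstable).
The implementation is the package's own: single linkage over
mutual-reachability distances (core distance = distance to the
`min_cluster_size`-th neighbor), a condensed tree at the minimum cluster
size, and excess-of-mass cluster selection, with noise labelled 0. The
root is selectable only when the hierarchy never splits, so a single
homogeneous clump of at least the minimum size is one cluster rather
than noise. Per non-noise cluster, the hit with the best predicted
affinity (ties: higher training similarity, then SMILES order) is
flagged as the representative for follow-up. The exact $O(n^2)$ t-SNE in
`embed_2d` exists for reporting layouts only.

## Impedance assay analysis

The transport-activity assay reads inhibitor potency off a
substrate-induced cellular impedance response. Per well:
$CI = (Z - Z_0)/15\,\Omega$ with $Z_0$ the well's first recorded
impedance; normalized CI divides by the last sample at or before
substrate addition (a ratio, not a subtraction — the instrument-software
convention, and the choice that makes the chain invariant to consistent
unit rescaling); the mean double-vehicle trace is subtracted pointwise;
the net AUC is the signed trapezoid over the 30 minutes after
stimulation. Percent response anchors substrate-only wells at 0% and
saturating reference-inhibitor wells at 100%.

The dose-response model is
$resp = bottom + (top - bottom)\,/\,(1 + 10^{-(pIC_{50} + \log_{10} c)})$
with the pseudo-Hill slope fixed at 1. The sign convention makes the
response *increase* with inhibitor concentration (blocking reuptake
enhances the substrate response) and puts the half-maximal response at
$c = IC_{50}$ exactly. Fitting is Levenberg-Marquardt with multi-start
over a log-spaced pIC50 grid spanning the tested concentrations ± 1 log
unit; flat response vectors are rejected as "no concentration
dependence" rather than fitted. Replicate wells are averaged per
concentration within a plate before fitting; plates are fit
independently and reported as mean ± SEM across experiments.

## The synthetic world

Everything is testable offline against generators with known truth
(`generate_world` bundles them; all are pure functions of their seeds).

* **Protein family**: 12 proteins in 3 tiers around a length-200 seed.
  Each tier descends from a tier ancestor (70% of the tier substitution
  rate seed→ancestor, 30% ancestor→member), so tiers form clades like
  real paralog subfamilies. Tier rates 0.03/0.25/0.65 put tier scores
  cleanly on opposite sides of the benchmark sweep thresholds
  850/500/150.
* **Compounds**: SMILES from a ~30-fragment grammar (secondary-amine
  linkers, aromatic and saturated rings, small caps). Valid and
  standardizable by construction; no claim of property realism.
* **Bioactivities**: 2,000 records over the 400-compound × 12-protein
  grid. Shared tiers (1-2) follow a sparse linear signal on 40 ECFP-4
  bits plus small protein offsets (SD 0.15), an optional per-protein
  interaction on a second bit pattern, and Gaussian noise calibrated so
  signal variance is 80% of total. Distant-tier records carry *no*
  feature-linked component: pure noise at twice the shared tiers' total
  SD, modeling unrelated targets whose activity determinants lie outside
  the descriptor space and whose assay distributions are broader. This
  is the planted structure target selection must recover: pooling
  distant records dilutes, pooling mid-tier records helps. A tenth of
  the pairs is re-emitted under a lower-priority activity type to
  exercise the unit-ranking rule.
* **Impedance plates**: three plates, duplicate wells per concentration
  (7 concentrations, 10 pM-10 µM), double-vehicle, substrate-only and
  reference wells; response amplitudes follow the fixed-slope logistic
  with Gaussian amplitude noise at 5% of the vehicle-reference span. At
  zero noise the analysis chain recovers the planted pIC50 to ±0.01.

What passing these tests shows — and what it does not: the synthetic
world has equal-length mutant proteins, a linear latent activity model,
grammar-generated near-drug-like compounds, and homoscedastic noise.
Real bioactivity data adds assay heterogeneity, indels and domain
structure, activity cliffs, and census bias that the generators do not
emulate; results on the benchmark demonstrate the machinery is correct
and the selection logic sound, not that any particular real target will
yield a given $R^2$.

## Numerical choices and degenerate inputs

* Fold assignments, forests, boosting, K-means, t-SNE and the
  generators all run from explicit seeds (default 12345) on one thread;
  every stochastic stage is bit-reproducible.
* Grid cells and CV folds that fail (e.g. PLS components exceeding the
  data rank) score $-\infty$ and are logged, never silently dropped.
* `tanimoto` of two empty fingerprints is 1; `hdbscan_labels` with fewer
  points than the minimum cluster size returns all noise; identical
  points collapse to a single cluster.
* Zero cell index at the normalization reference flags the well instead
  of propagating an infinity; dose-response fits require ≥ 4 distinct
  concentrations spanning ≥ 2 log units.
* Problem sizes in tests and the acceptance script (12 proteins, 400
  compounds, 2,000 records, 10k-compound decks, 200 assay simulations
  per pIC50 level, 20 selection replicates) are the package's standard
  benchmark configuration.

## Known limitations

* Chemistry is Open Babel's: fingerprint hashing, logP and pH model
  differ in detail from other toolkits; fingerprints are comparable only
  within one toolkit.
* The phylogenetic layering uses pairwise-identity NJ trees, not a full
  progressive MSA; for deeply gapped families a dedicated aligner would
  be preferable.
* The HDBSCAN and t-SNE implementations are exact and $O(n^2)$ — ample
  for post-filter hit sets (thousands), not for millions of compounds.
* Target selection scores layers with a single fixed learner; a layer
  that only a tuned model could exploit would be missed, which is the
  accepted price of an honest, optimizer-free comparison.
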