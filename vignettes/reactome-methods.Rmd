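---
title: "Methods: extracting a reactome from HTE data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extracting a reactome from HTE data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its statistical machinery: the
models, the assumptions they lean on, the tunable parameters and why their
defaults are what they are, what the synthetic campaign generator does and
does not emulate, and the design decisions that were genuinely open.

## The problem

An HTE dataset is a table of reaction conditions and measured outcomes
accumulated across many campaigns. It is not a designed experiment: the
sampled combinations are a sparse, chemist-chosen subset of the reagent
cross; substrates differ enormously in intrinsic reactivity; yields are often
uncalibrated UV-ratio estimates; a substantial fraction of wells yield
exactly 0%; and reagent availability drifts over the years. The question the
package answers is not "predict the yield" but "what relationships between
components and outcome does this dataset actually support?" — its
*reactome*.

## Subreactomes and the inclusion rule

All analysis is per *subreactome*: a slice by reaction class (e.g.
Buchwald–Hartwig vs Ullmann coupling, which differ mechanistically) and
substrate subclass. Coupling subclasses are the cross of reacting-halide type
(ArI/ArBr/ArCl) and nucleophile class (amide, aromatic N–H, primary or
secondary amine, primary or secondary alcohol), assigned by ordered SMARTS
rules shipped as an editable CSV. Two conventions deserve note:

* **Multi-halogenated electrophiles** are classed by I > Br > Cl priority, a
  proxy for the reacting C–X bond (oxidative-addition reactivity follows the
  same order). When an explicit reacting-site annotation is absent this is a
  guess, and it is implemented as a rule so users with annotations can
  override it.
* **Amide N–H outranks amine** when both patterns match, keeping amides a
  separate class.

A subreactome is analysed only when it has **strictly more than 80 reactions
and at least 2 unique reacting pairs**. The reaction bound keeps the
per-level group sizes in Tukey territory; the pair bound guarantees the
Z-score normalization (below) has at least two substrate contexts, without
which reagent and substrate effects are confounded. Excluded slices are
reported with reasons, never silently dropped.

## Branch 1: Z-score / ANOVA / Tukey ranking

Outcomes are normalized within a grouping unit, by default the unique
reacting pair: \(z = (y - \bar y_g)/s_g\) with the sample (n−1) standard
deviation. Singleton and zero-variance groups map to z = 0, which keeps
sparse substrates in the analysis at the cost of shrinking them toward "no
evidence" — preferable to dropping them or letting a single well carry a
pseudo-effect.

The grouping unit is the single most consequential open choice in the whole
framework: plate, target product, or reacting pair are all defensible. The
package defaults to the reacting pair because the ranking's stated purpose is
to detangle reagent effects from substrate reactivity, and the pair is the
finest unit that captures "same chemistry, different conditions". The choice
is a config parameter (`grouping`), not a constant.

Each variable category (catalyst metal, ligand, base, solvent, additive,
temperature binned to its observed set points) is then tested by classic
one-way fixed-effects ANOVA on z. The assumptions are the textbook ones —
independent observations, roughly equal within-group variance, approximate
normality of residuals — and the Z-scoring does part of the work of making
within-group variances comparable across substrates. In ANOVA-significant
categories (α = 0.05), all pairwise levels are compared by Tukey's HSD
(Tukey–Kramer under unbalance). A level is an *outlier* when it has at least
one significant adjusted comparison; outliers with positive mean z are
best-in-class, negative worst-in-class; everything else is neutral. Levels
observed fewer than `min_level_n = 5` times are reported as "insufficient
data" — studentized-range comparisons on smaller groups are noise.

Numerical edge cases are handled explicitly rather than left to the fitting
routine: zero within-group variance with unequal means is reported as p = 0
with a `degenerate` flag (and degenerate Tukey p-values of 0/1 by mean
equality); fewer than two populated levels is "not testable", not an error.
Ties in mean z are broken by larger n, then level name, so rankings are
deterministic. "Average Z-score" averages over reactions, not over per-pair
means; with strongly unbalanced pair usage the two differ, and the
per-reaction mean was chosen because it weights evidence by the data that
exist.

## Branch 2: random-forest variable importance

A regression forest (100 trees, library-default hyperparameters, recorded in
the report) is fitted on the one-hot design matrix of reactant *and* reagent
identities. Forests were chosen over linear models because reagent effects
in HTE data are routinely non-linear and interaction-laden, and because the
design is sparse and non-combinatorial. The forest target defaults to the
Z-scored outcome, consistent with the ranking branch (raw yield is a config
option); the out-of-bag R² is the accuracy measure for a continuous target,
reported verbatim — a low or negative value flags a subreactome offering
"low mechanistic insight" rather than being hidden. Importances are
impurity-based, normalized to sum 1, and gated by the per-category ANOVA:
features of non-significant categories stay in the table but are marked, so
headline plots can exclude them.

Before fitting, indicator columns with |Pearson r| ≥ 0.85 (the phi
coefficient, on binary columns) are merged over the connected components of
the threshold graph, making the result independent of column order. Within a
component, members positively correlated with the component's reference are
unioned by logical OR; anti-correlated members are *absorbed* instead of
OR'd, because the OR of an indicator with its own complement is a constant —
the common case being the two levels of a binary category, where either
level alone already carries all the information. Absolute correlation is
used because anti-correlated indicators are equally redundant. Merging is
idempotent and records full provenance in `merged_from`. Correlation merging
is applied per analysed subreactome, not globally: co-occurrence structure
is itself subclass-specific, and a global merge would let one dominant
subclass dictate the encoding of all others.

## Branch 3: chemical space

Ligand identifiers are resolved to structures through the same alias
dictionary the cleanup uses (unresolvable ligands are listed, not dropped)
and encoded as Morgan-type circular fingerprints. The hashing (element,
heavy-atom degree, bond-order-sum invariants, iteratively rehashed over
sorted neighbour environments, folded modulo the bit length) is implemented
in the package on top of ChemmineR connectivity tables; it is deterministic
across runs and platforms for fixed parameters but not bit-compatible with
other toolkits. Defaults are 2048 bits and radius 2 — the de facto community
standard radius, exposed as config since reasonable analyses use 2 or 3.

The embedding is centered PCA on the *deduplicated* fingerprint matrix:
duplicates map to identical coordinates and never enter the covariance, so
an over-screened ligand cannot dominate the axes (frequency weighting would
be a different, also defensible, choice; deduplication was picked because
the plot depicts ligand *scope*). PCA is used instead of t-SNE/UMAP
deliberately: the axes keep their highest-variance / second-highest-variance
interpretation. Best/worst labels from the ranking branch are painted onto
the embedding; Tanimoto matrices (with hierarchical leaf ordering recorded
for reproducibility) summarize reactant diversity.

## Dataset curation

The cleanup applies, in order: string temperature set points resolved
through a small dictionary ("rt" → 25 °C) *before* the missing-temperature
filter; rows without temperature removed; exact duplicates removed —
"duplicate" means identical on every field except the reaction identifier,
because replicate wells that differ in outcome are real data and only
byte-identical rows are export artifacts; reagent identifiers that neither
parse as SMILES nor appear in the alias dictionary flagged as nonsensical
(removed only under `strict = TRUE`, since deciding whether "Pd(0Ac)2" is a
typo is a human call); and couplings missing a catalyst or base flagged for
review. Cleaning is idempotent and conserves records
(input = output + removals, asserted on every run). Precatalysts are split
into (metal source, ligand) through an editable lookup table; unknown
precatalysts pass through as bare metal sources with a warning, never
guessed.

## The synthetic campaign generator

The generator exists so that every branch can be tested against known ground
truth. Its yield model is deliberately the simplest structure that
reproduces the documented features of real HTE exports:

\[ y = \mathrm{clip}\bigl(\text{baseline(pair)} + \textstyle\sum_c
\text{effect}(\text{level}_c) + \varepsilon,\; 0, 100\bigr), \qquad
\varepsilon \sim N(0, \sigma) \]

with probability `failure_rate` the outcome replaced by exactly 0. It
emulates: sparse designs (a seeded fraction of the reagent cross per pair),
substrate-dependent baselines, additive reagent main effects, yield noise
(default σ = 10 points, a realistic scale for uncalibrated UV-ratio yields),
the 0% point mass, and temporal drift in level availability. Replicate wells
receive distinct dates so generated tables contain no byte-identical rows.
It does **not** emulate: reagent × substrate interactions beyond what
clipping induces, heteroscedastic noise, calibration bias, plate-position
effects, or any quantitative match to a real dataset's distributions. A
pipeline that passes on these campaigns is therefore shown to recover
*planted additive effects under realistic sparsity and failure structure* —
not to be robust to everything real data can do.

Preset fixtures mirror the canonical campaign shapes: `buchwald_like` (wide
but shallow: 29 unique reacting pairs across ~10 coupling subclasses, one of
which deliberately fails the inclusion rule), `ullmann_like` (narrow but
deep: 9 pairs, 4 subclasses, planted solvent effects), `hydrogenation_like`
(transformation-typed substrates, planted catalyst and additive effects),
`temporal_drift` (a ligand available only in the second screening period),
and `high_failure`. The last is constructed so that baselines sit just above
0 and the planted worst ligand (−30 points, σ = 10) drives its wells to 0 by
clipping on top of a 30% unconditional failure rate: in this regime the 0%
records *are* the evidence for the worst-in-class label, which is exactly
the mechanism the zero-yield ablation probes — removing the zeros censors
the worst level's distribution upward and starves it of observations.
Planted levels with |effect| ≥ 1.5σ are the intended best/worst; every
category keeps a zero-effect reference level.

## Ablations

`ablate_zero_yield()` re-runs the pipeline after dropping all 0% records
(mimicking a literature-style successes-only dataset) and reports every
label change. `temporal_split()` re-runs it independently per time period —
inclusion rule re-applied per period — and tabulates label drift, with
"absent" marking levels unused in a period.

## Problem sizes and determinism

The shipped test and acceptance workloads use campaigns of roughly 300–2,600
reactions, 100-seed replicate loops for recovery rates, 2,000 simulated
datasets for the type-I calibration of the ANOVA gate, and 50–100 seeded
forest fits; these sizes give stable rate estimates (binomial standard error
≤ 0.05) while keeping a full run in the minutes range on one core. All
randomness — design subsampling, noise, failures, dates, forest bootstraps —
is seeded; identical config plus seed gives byte-identical reports.

## Known limitations

* One-way analyses only: no interaction terms or multi-way ANOVA, so a
  reagent that is good only on one substrate class within a subreactome
  appears diluted.
* The best/worst rule labels *every* outlier by the sign of its mean z; in
  strongly separated categories even mid-pack levels can acquire a label
  because they differ significantly from the extremes. Ranks and mean z
  should be read together.
* Impurity importances are biased toward high-frequency indicators;
  permutation importances were deliberately left out of scope.
* The circular fingerprint is structurally faithful but not bit-compatible
  with other toolkits; Tanimoto values are comparable within the package
  only.
* Identity encoding only — no continuous (steric/electronic) descriptors, so
  "why" a ligand is best is outside the model; the chemical-space plot is
  the interpretive aid.
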