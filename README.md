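# hitea

Statistical reactome analysis of high-throughput experimentation (HTE) data.

HTE campaigns — parallel miniaturized reaction screens run in well plates —
accumulate thousands of reaction-condition/outcome rows over years of
medicinal- and process-chemistry work. Buried in those tables is what this
package calls the dataset's **reactome**: the statistically supported
relationships between reaction components (catalysts, ligands, bases,
solvents, additives, temperature, substrates) and the measured outcome. The
data are awkward on purpose: sparse non-combinatorial designs, substrates of
wildly different intrinsic reactivity, uncalibrated yields, a large point mass
of 0% failures, and reagent usage that drifts over time. `hitea` extracts the
reactome anyway, for bench chemists planning the next screen and for data
scientists auditing a dataset before training models on it.

## The method

Three orthogonal branches are run on every analysable *subreactome* — a slice
of the dataset by reaction class and substrate subclass (e.g. "ArBr + primary
amine"), kept when it has **more than 80 reactions and at least 2 unique
reacting pairs**:

1. **Which variables matter?** A regression random forest (standard
   hyperparameters, 100 trees) is fitted to the one-hot encoded reaction
   conditions; indicator columns with pairwise |Pearson r| ≥ 0.85 are merged
   first. Impurity importances (normalized to sum 1) are reported with the
   out-of-bag R² as the accuracy measure, and gated by per-category one-way
   ANOVA at α = 0.05.

2. **Which reagents are best/worst in class?** Outcomes are Z-score
   normalized within each unique reacting pair, z = (y − ȳ_pair)/s_pair,
   detangling reagent effects from substrate reactivity. Each variable
   category is tested by one-way ANOVA; in significant categories, Tukey's
   honest-significant-difference test (Tukey–Kramer for unbalanced groups)
   identifies outlier levels, which are ranked by mean Z-score: positive
   outliers are *best-in-class*, negative ones *worst-in-class*.

3. **How do the reagents populate chemical space?** Ligands are encoded as
   2048-bit radius-2 Morgan-type circular fingerprints, embedded by centered
   PCA (axes keep their highest-variance reading), and colored by the
   best/worst labels from branch 2. Tanimoto similarity matrices summarize
   reactant diversity.

Around the statistics sits the full curation pipeline: CSV schema mapping,
SMILES canonicalization, the cleanup rules (missing-temperature removal,
exact-duplicate removal, nonsensical-reagent flagging, reaction-profile
review flags), precatalyst → (metal source, ligand) splitting, and subclass
assignment from editable SMARTS rules. A seeded synthetic campaign generator
with planted ground truth makes every branch testable end to end, and two
ablations mirror common dataset pathologies: dropping 0%-yield records and
temporal segregation.

## Worked example

```r
library(hitea)

camp <- preset_campaign("ullmann_like", seed = 1)   # 1,188 reactions, 9 pairs
res  <- hitea(camp$records, hitea_config(seed = 1))
print(res)
#> HTE reactome analysis: 1188 reactions, 4 analysable subreactome(s), 0 skipped
#>   ullmann / ArBr + primary alcohol: 264 reactions, 2 pairs, OOB R^2 = 0.37
#>   ullmann / ArI + aromatic nitrogen: 396 reactions, 3 pairs, OOB R^2 = 0.58
#>   ullmann / ArI + primary alcohol: 264 reactions, 2 pairs, OOB R^2 = 0.33
#>   ullmann / ArI + secondary alcohol: 264 reactions, 2 pairs, OOB R^2 = 0.54

r <- res$subreactomes[["ullmann / ArI + aromatic nitrogen"]]
print(r$rankings$solvent)
#> Reagent ranking [solvent]
#> One-way ANOVA [solvent]: F(2, 393) = 118.1, p = 7.017e-41 *
#>    level   n mean_z class n_significant_pairs
#>  dioxane 132  0.701  best                   2
#>     DMAc 140  0.060  best                   2
#>  toluene 124 -0.814 worst                   2

print(r$importance, n = 5)
#> Random-forest importance report (100 trees, seed 1)
#>   OOB R^2 = 0.579
#>                feature category importance anova_significant
#>        solvent=toluene  solvent     0.2831              TRUE
#>        solvent=dioxane  solvent     0.2035              TRUE
#>  ligand=phenanthroline   ligand     0.1676              TRUE
#>           ligand=DMPAO   ligand     0.1420              TRUE
#>           solvent=DMAc  solvent     0.0642              TRUE
```

Reading it: within the ArI + aromatic-nitrogen subreactome, solvent choice is
statistically decisive (ANOVA p ≈ 1e-40); dioxane is best-in-class and
toluene worst-in-class by mean Z-score, each supported by 2 significant Tukey
comparisons; the forest agrees, putting the solvent indicators at the top of
the importances with a moderate OOB R² of 0.58 — all matching the effects this
synthetic campaign was generated with. `plot(res)` draws the importance bars
and the labelled ligand PCA; `write_hitea_report(res, "out/")` emits the
JSON + markdown report bundle. `ablate_zero_yield()` and `temporal_split()`
run the two ablations. A command-line wrapper with verbs
`simulate | clean | analyze | ablate | temporal | report` ships at
`inst/cli/hitea.R`.

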