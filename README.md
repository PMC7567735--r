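# klse

Individual brain metabolic connectomes from parcellated FDG-PET, by
Kullback-Leibler divergence similarity estimation.

## The problem

FDG-PET measures regional glucose metabolism, and metabolic *networks* —
which regions covary — carry information about neurodegeneration that
regional uptake alone misses. The conventional network estimator (Pearson
correlation of regional means across subjects) only exists at the group
level, so it cannot say anything about one patient. This package builds a
network for a **single scan**: each atlas region's voxel-intensity
distribution is estimated by Gaussian kernel density estimation, and the
edge between regions *i* and *j* is

```
KLS(P, Q) = exp( -D(P‖Q) ),   D(P‖Q) = ∫ ( P log P/Q + Q log Q/P ) dx
```

the exponentiated symmetric Kullback-Leibler divergence between the two
densities: 1 for identical distributions, near 0 for disjoint ones. At the
standard 90-region AAL parcellation this yields a 90 × 90 similarity matrix
per subject.

On top of the matrix the package implements the full analysis chain used to
validate and apply such connectomes in predicting conversion from mild
cognitive impairment (MCI) to Alzheimer's dementia:

* edge-wise group difference patterns (Welch t on Fisher-Z weights,
  Benjamini-Hochberg FDR over the 4005 unique edges), with lobe-wise
  alteration fractions;
* inter-subject network similarity (mean pairwise Spearman correlation) and
  regional inter-individual dissimilarity with Z-normalised maps;
* 457 weighted graph-theory properties per subject (7 global: clustering,
  characteristic path length, small-worldness, global efficiency,
  transitivity, assortativity, modularity; 5 per region: betweenness,
  strength, local efficiency, vulnerability, local clustering);
* the prognostic pipeline: LASSO-selected **metabolic connectome
  expression** (MCE), ROC/AUC, Cox proportional-hazards models with Efron
  tie handling (per-SD hazard ratios), Harrell's C-index, and Kaplan-Meier
  stratification by median prognostic index;
* a fully seeded synthetic-cohort generator (known regional distributions,
  injected group effects, proportional-hazards conversion times) so every
  stage is testable without imaging data, plus NIfTI fixture writing and a
  reader for real template-space volumes.

Intended users: imaging methodologists and neuro-PET researchers who want
subject-level metabolic networks, and anyone needing a fully synthetic,
reproducible testbed for connectome-based prognosis pipelines.

## Worked example

A complete synthetic run — cohort, networks, statistics, features, MCE,
Cox models, Kaplan-Meier — in one call:

```r
library(klse)
res <- run_demo(seed = 1, out_dir = "klse_demo")

res$c_index_test
#>   clinical connectome    pattern   combined
#>  0.5631579  0.6263158  0.6184211  0.6289474

round(res$auc_test, 4)
#> [1] 0.8267

tidy(res$mce_model)
#> # A tibble: 5 × 2
#>   feature                  coefficient
#> 1 global__char_path_length      0.604
#> 2 degree__4                    -0.225
#> 3 local_efficiency__12         -0.0131
#> 4 vulnerability__6             -0.0662
#> 5 local_clustering__4          -0.456
```

Reading the output: the demo simulates 30 stable and 30 progressive
subjects whose conversion hazard is driven mainly by the strengths of four
hypometabolic regions. The LASSO picks network properties that separate
the groups (test-set AUC 0.83), and on the held-out half the combined Cox
model (clinical covariates + MCE) ranks conversion times better
(C-index 0.63) than the clinical-only model (0.56) — the qualitative
ordering the connectome score is supposed to add. `autoplot(res$km)` draws
the Kaplan-Meier curves of the two risk strata; every artifact (networks,
feature table, survival table, fitted model, manifest with MD5 hashes) is
written under `out_dir`, and identical seeds reproduce it bit for bit.

For real data the entry points are `load_parcellation(pet, atlas)` →
`global_normalize()` → `klse_connectome()` → `network_features()`, with
`group_pearson_network()` as the group-level comparator. A thin
command-line wrapper lives at `inst/cli/klse.R`
(`demo | extract | network | features`).

The methods vignette (`vignettes/klse-methods.Rmd`) documents the model,
the numerical choices (bandwidths, grids, the density floor), what the
synthetic cohorts do and do not emulate, and the accuracy envelope of the
divergence estimator.

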