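# loopmorph

3D geometric morphometrics for species discrimination from complex
curved skeletal structures — built around the long loop (brachidium) of
terebratellidine brachiopods, the calcified support of the lophophore
whose geometry carries most of the taxonomic signal in this group.
Species in these genera were historically named from qualitative
morphology; `loopmorph` provides the quantitative machinery to test
whether such named species are actually distinguishable in shape space.

The package implements the full workflow:

* **Landmark I/O** — long/wide/TPS landmark tables, YAML scheme and
  slider definitions, metadata joins; built-in bilateral (41-point) and
  trabecular (36-point) loop schemes sharing 15 fixed landmarks and
  three curves with 21 sliding semilandmarks.
* **Superimposition** — generalized Procrustes analysis (`gpa()`):
  centering, unit-centroid-size scaling and iterative rotation onto the
  consensus, with curve semilandmarks slid along their tangents to
  minimize thin-plate-spline bending energy
  (E(y) = Σ_d y_dᵀ B y_d, B the bending-energy matrix of the consensus
  with 3D kernel U(r) = −r); a minimized-Procrustes-distance sliding
  criterion is available as an alternative.
* **Ordination** — shape PCA (`shape_pca()`, with back-transformation
  of scores to configurations) and canonical variate analysis
  (`shape_cva()`): PC-reduced subspace, between- vs pooled within-group
  generalized eigenproblem, Mahalanobis distances
  d(i,j) = √((mᵢ−mⱼ)ᵀ W⁻¹ (mᵢ−mⱼ)), and leave-one-out cross-validated
  classification with equal priors.
* **Procrustes ANOVA** (`procrustes_anova()`,
  `common_allometry_test()`) — sequential decomposition of Procrustes
  sums of squares over size (log centroid size), group and their
  interaction, with residual-randomization permutation p-values
  (p = (1 + #{F\* ≥ F})/(n_perm + 1)).
* **LaSEC** (`lasec()`) — the landmark sampling evaluation curve:
  random landmark subsets grown from 3 to p, each scored against the
  full-data ordination by 1 − PSS after ordinary Procrustes alignment
  of score matrices.
* **Synthetic data** (`simulate_dataset()`, `simulation_preset()`) —
  a ground-truthed generator of species-structured loop datasets
  (smooth TPS mean deformations, allometric vectors in tangent shape
  space, rigid nuisance transforms) so every stage runs and is testable
  without external data.

## A worked example

Simulate the "hard" trabecular scenario (two overlapping congeners plus
one distant genus, n = 18 in groups of 8/5/5), superimpose with sliding,
and run the discrimination analyses:

```r
library(loopmorph)
ds <- simulate_dataset(simulation_preset("trabecular"), seed = 202)
al <- gpa(ds, sliders = build_slider_table(ds$scheme))
print(al)
#> Generalized Procrustes fit: 18 specimens x 36 points
#>   sliding semilandmarks: yes; iterations: 22
#>   centroid size range: 8.795 - 23.1

shape_pca(al)
#> Shape PCA: 18 specimens, 17 positive components
#>   variance explained (%): PC1=94.27, PC2=0.87, PC3=0.67, PC4=0.60, PC5=0.57

summary(shape_cva(al))
#> CVA summary (2 PCs retained)
#> Mahalanobis distances:
#>        spF    spG    spH
#> spF  0.000  1.588 55.303
#> spG  1.588  0.000 53.829
#> spH 55.303 53.829  0.000
#>
#> Leave-one-out confusion (rows = true group):
#>      predicted
#> true  spF spG spH
#>   spF   3   5   0
#>   spG   1   4   0
#>   spH   0   0   5
#>
#> Per-group accuracy (%):
#>   spF   spG   spH
#>  37.5  80.0 100.0
#> Overall accuracy: 66.67%

procrustes_anova(al, terms = c("size", "group"), n_perm = 999, seed = 2)
#> Procrustes ANOVA (rrpp permutation, 999 permutations, seed 2)
#>           Df       SS        MS     F     p
#> size       1 0.133970 0.1339700  45.2 0.002
#> group      2 0.648760 0.3243800 109.4 0.001
#> Residuals 14 0.041494 0.0029639    NA    NA
#> Total     17 0.824220        NA    NA    NA
```

Read: the first principal component (94% of variance) is the genus
separation. The distant genus (spH) classifies perfectly and sits ~55
Mahalanobis units from both congeners, while the two congeners are only
1.6 units apart and trade misassignments (37.5% / 80% accuracy, 66.67%
overall) — yet the permutation ANOVA still finds species a significant
factor (p = 0.001): overlap in cross-validated assignment and
statistical distinguishability are different questions. `plot(...)`
methods draw the morphospace, canonical variates and sampling curve;
`run_pipeline(analysis_config(...))` executes the whole workflow and
writes CSV/JSON tables plus a manifest.

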