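# gconnect

Genetic connectedness across management units, for quantitative
geneticists and breeding-program designers. When animals are raised in
different herds, flocks or cages, their BLUP breeding values can only be
compared fairly if genetic links (shared relatives) tie the units
together; `gconnect` quantifies that, end to end:

* **Relationship kernels** — pedigree `A` (tabular method), VanRaden
  genomic `G`, base-frequency-0.5 `G0.5`, min–max scaled `Gs`, and the
  single-step hybrid `H` for partly genotyped populations.
* **Prediction error structure** — for the animal model
  `y = Xb + Zu + e` with unit fixed effects, the prediction error
  (co)variance `PEV = (Z'MZ + K⁻¹λ)⁻¹ σ²ε` via absorption of the fixed
  effects (`M = I − X(X'X)⁻X'`), with a full-MME-inverse route as an
  independent cross-check. `λ = (1 − h²)/h²` under standardized
  phenotypes.
* **Connectedness statistics** — pairwise and across-unit PEVD
  (`λ(C²²ᵢᵢ + C²²ⱼⱼ − 2C²²ᵢⱼ)`, small = connected), CD
  (`1 − λ x'C²²x / x'Kx`, the reliability of the predicted difference)
  and prediction error correlation `r = PEC/√(PEVᵢ·PEVⱼ)`; contrast,
  pair-average and group-ratio summaries; full-sib stratification; PCA
  of pairwise connectedness matrices.
* **Designed scenarios** — k-medoid clustering of kinship (exact on
  small instances, BUILD+SWAP beyond) with silhouette-based selection
  of k, and four cluster-to-unit allocation scenarios spanning
  completely disconnected to fully mixed.
* **Simulators** — a full-sib/cage design, a multi-generation pedigree
  with closed lines and a genotyped recent subset, gene-drop genotypes
  (so `E[G] = A`), and phenotypes, making the whole pipeline runnable
  with no external data.

## Worked example

Two full-sib families, each spread over two cages — so cage pairs of
the same family are genetically linked and cross-family pairs are not:

```r
library(gconnect)

cfg <- sim_config(n_families = 2, sibs_per_family = 6,
                  cages_per_family = 2, n_markers = 1000, seed = 7)
md  <- simulate_mice_design(cfg)
A   <- numerator_relationship(md$ped)

des <- build_design(md$units)
vm  <- variance_model_from_h2(0.8)          # lambda = 0.25
pev <- pev_absorption(des, A, vm)

pevd <- summarize_across_units(pevd_pairwise(pev), md$units)
pevd$unit_matrix
#>           F001_C1   F001_C2   F002_C1   F002_C2
#> F001_C1        NA 0.3333333 1.3333333 1.3333333
#> F001_C2 0.3333333        NA 1.3333333 1.3333333
#> F002_C1 1.3333333 1.3333333        NA 0.3333333
#> F002_C2 1.3333333 1.3333333 0.3333333        NA

stratify_by_fullsibs(pevd, md$ped, md$units)[1:2]
#> $overall_no_fullsib
#> [1] 1.333333
#>
#> $overall_with_fullsib
#> [1] 0.3333333
```

The within-family cage pairs (PEVD = 0.33) are an order of magnitude
better connected than the cross-family ones (1.33, the prior contrast
variance — the fully disconnected ceiling). Swapping `A` for a genomic
kernel (`vanraden_G()` on gene-dropped or real genotypes) and rerunning
the same three lines measures how marker data changes the picture.

## Analysis workflow

The `analysis/` drivers reproduce the package's reference analyses on
the full-sized simulated designs and write tables under `results/`:

1. `01_simulate_designs.R` — generates both designs (1859 offspring in
   507 cages with a 10,946-marker panel; 1929 animals over six
   generations, 35% genotyped) and their QC'd genotypes.
2. `02_cage_connectedness.R` — PEVD/CD/r across cages for A, G, G0.5,
   Gs at h² = 0.8 and 0.2, with full-sib stratification.
3. `03_line_scenarios.R` — kinship clustering, scenarios 1–4, and the
   connectedness sweep under A and H.
4. `04_pca_views.R` — principal-component views of pairwise CD for the
   extreme scenarios.

Run them in order from the repository root with `Rscript`.

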