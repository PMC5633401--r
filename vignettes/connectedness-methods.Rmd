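---
title: "Measuring genetic connectedness across management units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring genetic connectedness across management units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gconnect)
```

## The problem

Breeding values estimated by BLUP are only comparable across herds,
flocks or cages — *management units*, fitted as fixed effects — to the
extent that genetic links tie the units together. When units share no
relatives, the genetic difference between their animals is confounded
with the difference in unit effects, and ranking animals across units is
unsafe. *Genetic connectedness* quantifies this risk. `gconnect`
implements the machinery end to end: relationship kernels, the
prediction-error structure of the mixed model equations, the three
standard connectedness statistics and their across-unit summaries, a
clustering-based generator of designed (dis)connectedness, and
simulators that make every stage testable without external data.

## Model and statistics

The animal model is $y = Xb + Zu + \epsilon$ with $u \sim N(0, K
\sigma_u^2)$ and $\epsilon \sim N(0, I \sigma_\epsilon^2)$, where $X$ is
the one-hot incidence of management units (no intercept; units are the
only fixed effects), $Z$ relates records to individuals (the identity
when each individual has one record) and $K$ is a relationship kernel.
Phenotypes are taken standardized, so for heritability $h^2$ we use
$\sigma_u^2 = h^2$, $\sigma_\epsilon^2 = 1 - h^2$ and the variance ratio
$\lambda = (1 - h^2)/h^2$; explicit components (e.g. REML estimates) can
be supplied instead via `variance_model()`. Variance-component
estimation itself is out of scope.

Prediction error (co)variances come from the random-effect block of the
inverted coefficient matrix:
$\mathrm{PEV} = (Z'MZ + K^{-1}\lambda)^{-1}\sigma_\epsilon^2 =
C^{22}\sigma_\epsilon^2$, where $M = I - X(X'X)^{-}X'$ absorbs the fixed
effects. `pev_absorption()` is the production route;
`pev_full_mme()` inverts the full coefficient matrix (Moore–Penrose)
and is kept as an independent cross-check — the two agree to $10^{-8}$
relative error on randomized instances in the test suite. PEV depends
only on $X$, $Z$, $K$ and $\lambda$: phenotype values are never
consumed.

Three statistics summarize connectedness between individuals $i$ and
$j$:

* **PEVD** $= (C^{22}_{ii} + C^{22}_{jj} - 2C^{22}_{ij})
  \sigma_\epsilon^2$, reported scaled by $\sigma_u^2$ (so it equals
  $\lambda\, x'C^{22}x$ on a difference contrast and is invariant to the
  absolute variance scale). Small PEVD = well connected. For a fully
  disconnected pair it equals the prior contrast variance $x'Kx$, which
  is why pedigree-based across-unit averages barely move with $h^2$ in
  disconnected designs.
* **CD** $= 1 - \lambda\, x'C^{22}x / x'Kx$: the reliability of the
  predicted difference. It is 0 exactly for a fully uninformed contrast
  and penalizes "connectedness" obtained by comparing near-identical
  groups (the scenario-4 drop below). Pairs with $x'Kx = 0$ are
  undefined and excluded from summaries with a warning.
* **r** $= \mathrm{PEC}_{ij}/\sqrt{\mathrm{PEV}_i\,\mathrm{PEV}_j}$:
  the prediction-error correlation, zero when no information flows
  between the individuals. Although often described as bounded in
  $[0, 1]$, negative values occur with genomic kernels (negative PECs)
  and are reported as-is; the true contract is $[-1, 1]$.

Across-unit summaries (`summarize_across_units()`): PEVD and CD default
to the mean-difference **contrast** form per unit pair; r defaults to
**pair averaging** over cross-unit individual pairs, because the
group-ratio form (summed PECs over root summed PEVs) degenerates for
genomic kernels with exactly two units — `r_group_summary()` warns in
that configuration. All three modes are available for comparison. The
overall value is the unweighted mean over distinct unit pairs; whether
the historical tables averaged unit pairs or individual pairs is not
documented, so both readings are one switch apart.
`stratify_by_fullsibs()` partitions unit pairs by whether a full-sib
pair straddles them — in family-structured designs that is where the
genetic links live.

## Relationship kernels

* `numerator_relationship()` builds **A** by the tabular recursion over
  a topological ordering; unknown parents are unrelated, non-inbred
  founders. The tabular method is used (rather than inverse-A rules)
  because the statistics need A itself and $n$ is moderate.
* `vanraden_G()` builds **G** from allele counts standardized at
  observed frequencies, $G = WW'/m$; with `freqs = 0.5` it builds
  **G0.5**, centered and scaled at base frequency one-half, which
  avoids the negative entries that observed-frequency centering
  produces. Monomorphic markers are a hard error for observed
  frequencies (filter first) and harmless for G0.5.
* `minmax_scale()` maps the global extremes of G onto $[0, 2]$ (the
  range of A) — **Gs**. The map is affine over all entries including
  the diagonal, hence order-preserving with correlation exactly 1.
* `hybrid_H()` combines pedigree and genomic information for partly
  genotyped populations by conditioning ungenotyped genetic values on
  genotyped ones (the single-step **H**).
* `ensure_invertible()` adds diagonal jitter (default
  $10^{-6}\times$ mean diagonal) only when the smallest eigenvalue is
  near zero — G is rank-deficient whenever $m < n$ — and records the
  amount. The PEV routines apply it automatically.

Genotype QC: `impute_missing()` replaces each missing genotype by the
sum of two Bernoulli draws at the marker's observed allele frequency
(allele-level sampling, consistent with the HWE assumption behind G),
then recomputes frequencies; `filter_maf()` drops markers with minor
allele frequency strictly below the threshold (default 0.05). Filtering
is applied after imputation; at realistic missing rates the order is
immaterial.

## Clustering and designed scenarios

To emulate chosen levels of connectedness, individuals are clustered on
kinship and clusters are allocated to units.
`relationship_dissimilarity()` uses $D = \max(A) - A$ with the diagonal
forced to zero (k-medoids requires self-dissimilarity zero; the affine
transform is otherwise order-preserving). `pam_cluster()` solves small
instances (at most 5000 candidate medoid sets) exactly by enumeration
and uses BUILD+SWAP (via the `cluster` package) above that; BUILD+SWAP
is a 1-interchange local search that can miss the optimum on tiny
instances where exhaustive search is free, so paying for exactness
there is the better trade. Ties go to the lowest-index medoid set, so
both routes are deterministic. `choose_k_silhouette()` scans $k$ in
2..min(15, n−1) by default and keeps the largest average silhouette
width, preferring smaller $k$ on ties.

`assign_scenario()` produces four designs: (1) one unit per cluster —
completely disconnected; (2) clusters split into two units;
(3) flanking thirds to units 1 and 2 with the middle clusters'
individuals divided between both as links; (4) every cluster divided
between the two units. Clusters are ordered by decreasing size (ties by
medoid id) and consecutive-group cuts are chosen to balance individual
counts, since the historical design kept unit sizes approximately equal
and fixed its cluster-to-unit map only by enumeration for one dataset.
Within-cluster splits are seeded, near-equal random halves.

## Synthetic data: what it emulates, and what it does not

`simulate_mice_design()` emulates a heterogeneous-stock-style mouse
population: 169 full-sib families of ~11 sibs, each family's offspring
spread over 3 cages, only offspring phenotyped. Cages are single-family
by default, so within-cage relatedness is exactly 0.5 and cross-family
relatedness 0; connectedness across cages is carried entirely by full
sibs housed apart. `share_fraction` merges a fraction of adjacent
families' cages to create two-family units. Founders are non-inbred and
unrelated, so the real population's background inbreeding (within-cage
average 0.49 rather than 0.5) and, importantly, its cross-family
genomic relatedness from a shared 8-strain base are *not* emulated.

`simulate_cattle_design()` emulates a six-generation pedigree of 1929
animals with the recent three generations (35%) genotyped, bred in 8
closed lines (founders split evenly, seeded random sire–dam pairs
within line). The lines plant the cluster-structured relatedness that
the kinship clustering step is meant to recover; base-generation
founders are mutually unrelated and form a low-relatedness "blob" that
clustering may keep as its own group — the real data showed the same
phenomenon (one cluster of distant relatives) — so the selected $k$
need not equal the number of lines on the full pedigree.

`gene_drop_genotypes()` drops founder alleles (frequencies uniform on
the configured MAF range, mirrored to both halves of the spectrum)
down the pedigree by independent Mendelian transmission, no linkage.
Unlinked markers make $E[G] = A$ at the generating frequencies — a
provable calibration target the tests exploit — while real LD
structure, which the connectedness statistics do not consume, is
deliberately absent. `simulate_phenotypes()` draws $u \sim N(0, K h^2)$
via eigendecomposition, adds unit effects (sd 0.3 before
standardization; the PEV-based statistics are unaffected by this
choice) and residuals, and standardizes $y$.

Two consequences of these choices matter when reading test results.
First, with unrelated founders the genomic kernel equals A only in
expectation; its Mendelian-sampling noise acts as weak information, so
G strengthens measured connectedness relative to A clearly at high
heritability (the headline direction), while at $h^2 = 0.2$ the
noise-information effect and the small contrast-inflation bias of
observed-frequency centering nearly cancel and the PEVD direction is
not reproducible — reproducing the large real-data gap would require
the cross-family relatedness the generator deliberately omits. Second,
CD rises from scenario 1 to 3 but falls again in scenario 4: with both
units containing the same clusters, the contrast has little relatedness
variability left, and CD treats that as reduced connectedness — a
property of the statistic, not an artifact.

## Numerical choices

Symmetric solves use Cholesky with an eigendecomposition fallback;
results are symmetrized (averaged with their transpose) to $10^{-10}$.
$(X'X)^{-}$ uses the Moore–Penrose pseudo-inverse (exact when X has
full column rank, which the one-hot construction guarantees). CD pairs
with kernel denominators below $10^{-12}$ are treated as undefined.
Seeded routines save and restore the caller's RNG state; every
generator is bit-reproducible given its seed.

## Problem sizes used by the checks

The test suite runs the full statistics on reduced designs (e.g. 40
families × 8 sibs with 3000 markers; six generations of 60/40 with 800
markers) and randomized small instances for the oracle equivalences;
the acceptance script and the analysis drivers run the full-sized
designs (1859 phenotyped offspring in 507 cages with a 10,946-marker
panel; 1929 animals with 7250 markers). These sizes are the package's
own choice of scale for its reference runs.

## Known limitations

REML/Gibbs variance estimation, repeated records per individual,
multi-trait models, LD-aware simulation and imputation, dominance or
epistatic kernels, and gene-flow-based connectedness statistics are out
of scope. Group-ratio r is provided for comparison but is not a
default for genomic kernels. Real-data values from the motivating
studies are not bundled; the simulators provide structurally analogous
inputs instead.
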