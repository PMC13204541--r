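# hdbn — group comparison of streamline-count brain networks

`hdbn` is an R package for comparing structural connectomes between two
cohorts of mice — wild-type (WT) versus knockout (KO) — where each
animal's network is a symmetric region-by-region matrix of diffusion
tractography streamline counts over a bilateral parcellation (72 regions,
36 per hemisphere). It is aimed at small-animal imaging groups who export
connectivity matrices from tractography software and need a tested,
reproducible statistical pipeline downstream of the imaging.

The package covers, end to end:

* **Parcellation** — a bilateral region table with homolog pairing and
  composite ROIs (the hippocampus as CA1+CA2+CA3+DG, and nine other
  predetermined regions of interest), user-overridable via TSV.
* **Connectome views** — normalization of count matrices to maximum 1,
  weight extraction at threshold 0.001, ipsilateral / contralateral
  hemisphere blocks, composite-ROI merging, chord-diagram edge tables.
* **Weighted graph measures** — density; Onnela clustering coefficient
  and transitivity; characteristic path length and global/local
  efficiency with edge length 1/weight; strength assortativity;
  rich-club coefficients; and small-worldness
  σ = (C/C_rand)/(L/L_rand) against degree-preserving Maslov–Sneppen
  rewired surrogates with shuffled weights (σ > 1 = small-world).
* **Edgewise statistics** — for all n(n−1)/2 = 630 region pairs of a
  36-region view: exclusion of pairs with >50% zero observations,
  log(x+1) transform, pooled two-sample t-tests
  (df = n_WT + n_KO − 2), Benjamini–Hochberg FDR at 5%, and symmetric
  *signed* adjusted-p matrices (positive = KO > WT, negative = WT > KO)
  with light/dark display bins.
* **Region and parameter tests** — per-region streamline totals and
  per-metric network-parameter comparisons; FA/MD/AD/RD diffusivity
  scalars from tensor eigenvalues (FA in the standard
  √(3/2)·‖λ−MD‖/‖λ‖ form) with region-wise signed-p maps.
* **Circuits** — hypothesis-driven comparison of the fear-conditioning
  and temporal-lobe-epilepsy pathways, ipsilaterally and
  contralaterally, each circuit BH-adjusted as its own family.
* **Simulation** — a zero-inflated rounded-lognormal cohort generator
  with planted group effects, so the entire pipeline is testable with no
  imaging data.

## Worked example

Simulate a study-sized cohort (8 WT, 12 KO) with the amygdala–thalamus
connection planted six-fold stronger in KO animals in both hemispheres,
then run the edgewise pipeline on the ipsilateral view:

```r
library(hdbn)
tab <- load_region_table()
coa <- resolve_composite(tab, composite_roi("COA", "COA"), "L")
th  <- resolve_composite(tab, composite_roi("TH", "TH"), "L")
cfg <- sim_config(
  planted_edges = list(
    list(pair = c(coa, th), effect = 6),
    list(pair = c(homolog_of(tab, coa), homolog_of(tab, th)), effect = 6)),
  seed = 42)
cohort <- simulate_cohort(cfg)
ew <- edgewise_compare(cohort, mode = "ipsilateral")
ew
#> edgewise_result (ipsilateral): 630 pairs, 623 included, 1 discoveries at FDR 0.05
subset(ew$edges, discovery, select = c(pair, t, df, p_adj, sign, bin))
#>       pair        t df       p_adj sign  bin
#> 177 COA~TH -6.59179 18 0.002138273    1 dark
```

Of the 630 unordered region pairs, 623 survive the >50%-zero filter and
exactly the planted amygdala–thalamus pair is discovered: its pooled t
(WT − KO) is −6.6 on 18 degrees of freedom, the BH-adjusted p of 0.002
falls in the dark (<0.01) display bin, and the sign +1 records that the
KO group has the stronger connection. `ew$signed_p` holds the same
information as a symmetric signed matrix for heat-map display.

Small-worldness of a ring lattice with 10% shortcuts (36 nodes, degree
4), against 100 degree-preserving rewired nulls:

```r
g <- ring_lattice_graph(n = 36, k = 4, p = 0.1, seed = 1)
sw <- small_worldness(g, n_null = 100, seed = 1)
sprintf("sigma = %.2f (C/Crand = %.2f, L/Lrand = %.2f)",
        sw$sigma, sw$c_ratio, sw$l_ratio)
#> "sigma = 4.10 (C/Crand = 5.76, L/Lrand = 1.41)"
```

Clustering sits far above the rewired nulls while path length is only
modestly longer, so σ ≈ 4: the hallmark small-world signature.

## Analysis workflow

The `analysis/` directory holds numbered driver scripts that run the full
study workflow over a simulated cohort and write tidy TSV tables under
`results/`:

```sh
Rscript analysis/01_simulate.R            # cohort matrices + manifest
Rscript analysis/02_network_metrics.R     # per-animal graph measures + group tests
Rscript analysis/03_edgewise_comparison.R # signed-FDR edgewise matrices
Rscript analysis/04_circuits.R            # fear / TLE circuit comparisons
Rscript analysis/05_diffusivity.R         # FA/MD/AD/RD region tests
```

Each script states what it found on stdout; `run_pipeline()` performs the
same stages as one deterministic call (identical config + seed gives a
byte-identical output tree).

## Vignette

`vignettes/hdbn-methods.Rmd` documents the statistical model and every
convention choice: the generator's assumptions, the t-test and BH
details, the graph-measure definitions, the null model for σ, degenerate
-input policies, and known limitations.
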