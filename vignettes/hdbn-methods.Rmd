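---
title: "Methods: group comparison of streamline-count connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group comparison of streamline-count connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdbn)
```

## What the package computes

`hdbn` compares structural brain networks between two cohorts of mice — a
wild-type (WT) group and a knockout (KO) group — where each animal's
network is a symmetric region-by-region matrix of diffusion-tractography
streamline counts over a bilateral parcellation (72 regions, 36 per
hemisphere by default). Three kinds of questions are answered:

1. **Edgewise**: which individual region-pair connections differ between
   groups, with the false discovery rate controlled?
2. **Topological**: do summary measures of network organization (density,
   clustering, efficiency, small-worldness, ...) differ, for the whole
   brain or for the subnetwork around a region of interest?
3. **Hypothesis-driven**: do the connections of a named circuit — the
   fear-conditioning pathway or the temporal-lobe-epilepsy circuitry —
   differ, within hemispheres or across them?

Alongside the network analysis, tensor-eigenvalue diffusivity scalars
(FA, MD, AD, RD) are computed per region and compared between groups.

Raw imaging is out of scope: the package consumes count matrices (and
eigenvalue tables) and ships a cohort simulator so that every stage is
testable end-to-end without any imaging data.

## Data model

A `region_table` holds the parcellation: 36 abbreviation stems per
hemisphere, hemisphere encoded by a leading `L`/`R` character, and a
homolog map pairing each region with its mirror twin (an involution that
always crosses hemispheres). The packaged default names every region the
analysis addresses (CA1--CA3, DG, EC, TH, ICtx, COA, SS, MO, SUC, HY, CB,
MY, CC, IC, PIR, TT, RHP, MB, P, ...) and pads each hemisphere to 36 with
clearly marked synthetic placeholder parcels; any other parcellation can
be supplied as a TSV. The placeholder padding is a deliberate choice: the
downstream mathematics depends only on the cardinality and labels of the
table, so nothing is gained — and silent mismatches are risked — by
guessing unpublished region memberships.

Ten predetermined composite ROIs are built in (cerebellum, entorhinal
cortex, hippocampus, hypothalamus, medulla, somatomotor cortex,
somatosensory cortex, superior colliculus, thalamus, visual cortex). The
hippocampus is the union of CA1, CA2, CA3 and DG; the isocortex region
stands in for the visual cortex.

A `connectome` is one animal's count matrix: symmetric, nonnegative, zero
diagonal. Asymmetric input (counts from A-to-B seeding versus B-to-A
seeding differ only by where the seeds were placed) is symmetrized by the
elementwise maximum, with a warning — the graphs are undirected.

Graph analysis never runs on raw counts. A *weight view* is a slice of
the matrix — whole brain, within-hemisphere (ipsilateral) block, or
cross-hemisphere (contralateral) block — normalized so its maximum entry
is exactly 1 and pruned at the extraction threshold 0.001: entries
strictly below the threshold become 0, entries at the threshold are kept
(so a threshold of 0 is the identity). Normalization makes every
downstream measure invariant to uniform rescaling of raw counts.
The contralateral block is not symmetric in stem space
(counts(L~i~, R~j~) ≠ counts(L~j~, R~i~)), so for graph measures the two
orientations are summed into one symmetric stem-by-stem matrix, and the
homotopic diagonal is dropped.

## The synthetic cohort generator

The generator (`sim_config()`, `simulate_cohort()`) emulates exactly the
statistical structure the comparison machinery assumes:

* Per present edge, counts are **rounded lognormal**: `round(exp(N(mu,
  sigma)))` with `mu = baseline_log_mean` (default 4, i.e. counts around
  55) and `sigma = baseline_log_sd` (default 0.5, a realistic
  between-animal spread for tract counts on the log scale).
* **Structural zeros** are drawn once per cohort at the edge level
  (probability `zero_prob`, default 0.15) and shared by every animal: a
  missing tract is a property of the wiring, not of one mouse. This keeps
  every included edge purely lognormal across animals, so after the
  pipeline's `log(x + 1)` transform the pooled t-test's normality
  assumption is recoverable by construction — which is what makes the
  false-discovery-rate acceptance checks clean.
* **Planted effects** multiply the KO-group lognormal mean of chosen
  edges; planted diffusivity effects multiply the KO mean of a chosen
  scalar (AD scales the first eigenvalue, RD the second and third, MD all
  three).
* Cohort sizes default to 8 WT and 12 KO, the study design the analysis
  is built around.

Reproducibility: one master seed expands into deterministic per-animal
substreams (an arithmetic hash of the seed and the animal index), so the
same configuration is bit-identical regardless of iteration order.

What the generator does **not** emulate: spatial autocorrelation between
edges, distance-dependent connection probability, scanner or registration
artefacts, and any coupling between an animal's edges. Passing tests
therefore demonstrate the correctness and calibration of the statistics
under the generator's idealized model, not robustness to the full
messiness of real tractography data.

Eigenvalue triples for the diffusivity records are drawn on the log scale
around a mildly anisotropic baseline (1.0, 0.55, 0.45) × 10^-3^ mm²/s and
sorted, guaranteeing λ1 ≥ λ2 ≥ λ3 > 0.

## Diffusivity scalars

From a sorted eigenvalue triple: axial diffusivity AD = λ1, radial
diffusivity RD = (λ2 + λ3)/2, mean diffusivity MD = (λ1 + λ2 + λ3)/3, and
fractional anisotropy in the standard tensor form

$$\mathrm{FA} = \sqrt{\tfrac{3}{2}}\;
\frac{\lVert \lambda - \mathrm{MD} \rVert}{\lVert \lambda \rVert},$$

which runs from 0 (isotropic) to 1 (a single nonzero eigenvalue). FA is
only described qualitatively in the source study; the
Basser–Pierpaoli definition above is the universal convention in the DTI
literature and is what the package uses. FA values are clipped to 1 only
against floating-point overshoot below 10^-12^; anything larger raises an
error.

## The edgewise comparison

For a chosen view, every unordered region pair (630 pairs for 36 regions)
is processed as:

1. **Zero filter**: a pair is excluded when *strictly more than* 50% of
   its per-animal observations are zero (exactly half is kept).
2. **Log transform**: natural `log(x + 1)`. The base is not specified by
   the source analysis; it only rescales all values identically and
   leaves every t statistic unchanged.
3. **Pooled t-test**: Student's pooled-variance two-sample t with
   `df = n_WT + n_KO - 2`, computed from the samples actually supplied.
   (The source text prints df = 17 alongside group sizes of 8 and 12,
   which give 18; the package always derives df from the data and treats
   the printed value as an inconsistency to be surfaced, never
   hard-coded.) Welch's t is available as an option.
4. **BH adjustment**: one Benjamini–Hochberg step-up family across all
   included pairs of that view, FDR 5%; a discovery is `p_adj <= q`
   (the standard BH convention for the boundary).
5. **Signs and bins**: adjusted p-values carry an artificial sign,
   positive where the KO mean exceeds the WT mean, negative otherwise,
   and are assembled into a symmetric signed p matrix (NA where
   filtered). Display bins: light for 0.01 ≤ |p| < 0.05, dark for
   |p| < 0.01. The source's figure legends use 0.005–0.01 for the dark
   bin while its text says 0–0.01; the text convention is the default and
   the legend convention is available via `dark_convention = "legend"`.

The ipsilateral view averages each animal's L-L and R-R blocks (the two
hemispheres were examined separately in the source workflow and then
combined after proving comparable); the contralateral view sums the two
cross-hemisphere orientations per stem pair. The contralateral family
omits the 36 homotopic pairs so both views test the same 630-pair family.
Ipsilateral and contralateral families are adjusted separately, since
they are presented as separate analyses; pooling them into one family is
possible by running the `"whole"` mode over a custom table.

Degenerate cases are explicit: identical group means give p = 1 and sign
0; two constant groups with different constants give the smallest
representable p with a degeneracy flag.

The "two-step adjusted p values with signs" of the source are read as
(1) BH adjustment, (2) sign attachment — not as a two-stage FDR
procedure, because only the Benjamini–Hochberg procedure is named in its
methods.

Region-level totals (all streamlines touching a region, i.e. row sums of
the count matrix) are compared on the raw scale — the source does not
state a log transform for this comparison — with BH across regions.

## Graph measures

The source defers formulas to the brain-connectivity-toolbox
implementations; the package states and implements one convention per
measure, each isolated behind one function so alternates can be swapped:

* **Density**: nonzero upper-triangle entries over N(N−1)/2.
* **Clustering** (Onnela): geometric-mean triangle intensity,
  C~i~ = Σ(w~ij~ w~ih~ w~jh~)^1/3^ / (k~i~(k~i~−1)), zero for degree < 2;
  the mean includes the zeros.
* **Transitivity**: the global ratio form, ΣΣ(w w w)^1/3^ / Σ k(k−1).
  A star graph has 2-paths but no triangles, so its transitivity is 0;
  the undefined (NA) case is a graph with no node of degree ≥ 2.
* **Path length**: shortest paths with edge length 1/weight;
  characteristic path length is the mean over ordered *reachable* pairs,
  with a warning when the graph is disconnected. Distances are computed
  by a vectorized Floyd–Warshall — at N ≤ 72 the O(N³) sweep is faster
  than building graph objects per call, and it is cross-checked against
  an independent graph library in the tests.
* **Global efficiency**: mean of 1/d over ordered pairs with 1/∞ = 0, so
  disconnection needs no special casing.
* **Local efficiency**: per node, the global efficiency of the weighted
  subgraph induced on its neighbors; 0 for degree < 2.
* **Assortativity**: Pearson correlation of endpoint strengths (weighted
  degrees) over the edge list, both orientations per edge; NA when the
  strengths have zero variance (regular graphs).
* **Rich club**: on the binarized graph, edge density among nodes of
  degree > k; NA when fewer than two nodes survive.

Statistically undefined values are returned as NA so cohort tables stay
rectangular; structural impossibilities (empty graph, single node) raise
errors.

### Small-worldness

σ = (C/C~rand~)/(L/L~rand~), where C~rand~ and L~rand~ are means over an
ensemble of degree-preserving surrogates: Maslov–Sneppen double-edge
swaps (default 10 attempts per edge) on the binarized topology, with the
original weight multiset shuffled onto the rewired edges. Defaults are
100 surrogates; the ensemble (rather than a single random graph) was
chosen because it makes σ's null variability measurable, and the null
means, standard deviations and configuration are returned with the
value. σ is bit-reproducible given (graph, n_null, swaps_per_edge,
seed). A complete graph cannot be rewired, so its σ is exactly 1; a
ring lattice with shortcuts gives σ well above 1; a density-matched
random graph is its own null and fluctuates around 1.

## Circuits

A circuit is a set of composite nodes (e.g. `Hipp` = CA1+CA2+CA3+DG) and
a list of node pairs. Per animal, a pair's strength is the summed count
between the two resolved region sets: ipsilaterally the mean of the L-L
and R-R sums, contralaterally the sum of both cross-hemisphere
orientations. Strength is additive over ROI members (splitting a
composite and summing reproduces the original — a tested conservation
law). Pairs are compared on the raw strength scale (the source presents
group-averaged streamline counts per pair), with BH across that circuit's
pairs only: each circuit figure is its own family. Two circuits are
built in: the fear-conditioning pathway (6 pairs) and the
temporal-lobe-epilepsy circuitry (7 pairs, including the
hippocampal-thalamic projection).

## Numerical and design choices

| Parameter | Default | Meaning |
|---|---|---|
| extraction threshold | 0.001 | minimum normalized weight kept (strictly-below removed) |
| FDR level `q` | 0.05 | BH discovery level per family |
| `n_null` | 100 | surrogates for σ |
| `swaps_per_edge` | 10 | Maslov–Sneppen attempts per edge |
| `baseline_log_mean` | 4 | log mean of simulated edge counts |
| `baseline_log_sd` | 0.5 | log-scale noise sd of simulated counts |
| `zero_prob` | 0.15 | structural-zero probability per edge |
| `n_wt`, `n_ko` | 8, 12 | cohort sizes |
| `lambda_base` | (1.0, 0.55, 0.45)·10⁻³ mm²/s | baseline eigenvalues |

Tie-breaks and degenerate inputs are all explicit: threshold boundary
kept, zero-filter boundary kept, BH boundary is a discovery, exact mean
ties give sign 0 and p 1, constant-versus-constant differences give the
smallest representable p with a flag, and undefined graph measures are NA
rather than errors.

## Statistical power at the study's design size

With 8 vs 12 animals and log-scale noise sd 0.5, a doubled edge mean
(effect 2.0) has a t noncentrality of about 3.0 — roughly 82% power for a
*single* test at α = 0.05, but only ~7% power once BH across 630 pairs
demands |t| ≈ 5.1 for an isolated effect. Reliable single-edge recovery
after correction at this design size needs effects of roughly 4× or
noise nearer 0.25; region-level totals and circuit sums, which aggregate
many edges, reach high power at much smaller effects. The test suite's
recovery checks therefore plant strong effects (×6–×8) where they assert
reliable detection, and the calibration (false-discovery-rate) checks,
which do not depend on power, run at the study conditions themselves.

## Problem sizes used by the test suite

The suite verifies every measure against brute-force enumeration on ≥100
random graphs with N ≤ 8, BH against the reference implementation on
1,000 random p-vectors, false-discovery-rate calibration on 200 replicate
cohorts at the study design (8 vs 12, 36 regions, 630 pairs), and
small-worldness on 100 lattice seeds with 100 surrogates each. These
sizes were chosen so the whole suite completes in a few minutes while the
Monte-Carlo error of each calibration check stays a few percentage
points.

## Known limitations

* The packaged region table pads to 72 with placeholder parcels; analyses
  that depend on the identity of unnamed regions need a user table.
* The simulator's independence across edges means network-level metrics
  on simulated data have no planted "truth" beyond what edge effects
  induce; σ calibration is validated on constructed graphs instead.
* Streamline counts are a proxy for connectivity; nothing in the package
  corrects for region volume, seeding density, or tract length biases.
* Edgewise inference is mass-univariate; no spatial or cluster-level
  statistic is offered.
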