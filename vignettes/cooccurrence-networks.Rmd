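---
title: "Correlation-based co-occurrence networks for microbial communities"
author: "micronet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-based co-occurrence networks for microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Amplicon surveys of lakes and other aquatic habitats yield OTU count
tables for bacterioplankton (16S) and microeukaryotes (18S) across a
handful of samples per site. Which taxa co-occur, which exclude one
another, how modular those association networks are, and how the modules
track nutrient gradients are the questions this package addresses. It
implements the standard correlation-threshold pipeline used for such
studies — from counts to a signed co-occurrence network, its topology
against random-network nulls, taxon-level co-occurrence enrichment,
node roles, and module-environment associations — together with a
synthetic community generator so that every stage can be validated
end to end without sequencing data.

# The pipeline and its assumptions

## From counts to a network

1. **Prevalence filter.** Within each sample group (zone), only OTUs
   detected in at least `minPrevalence` samples are kept (default 8, for
   designs with 10 samples per zone). Rarely observed OTUs cannot support
   a rank correlation over so few samples and mostly contribute noise.
2. **Relative abundances.** Counts are divided by the per-sample total
   *within each kingdom block*: 16S and 18S are separate amplicons whose
   depths are not comparable, so each is closed independently
   (`toRelative()`); inter-kingdom tables concatenate two closed
   compositions (`combineKingdoms()`).
3. **Spearman screen.** All OTU pairs are tested with Spearman rank
   correlation (average ranks, tie-corrected), two-sided p-values from
   the t approximation with n − 2 degrees of freedom
   (`spearmanScreen()`). With n = 10 samples this approximation is the
   de-facto standard; an exact-permutation option exists for small n.
   Constant profiles have no rank signal: their pairs carry `rho = NA`,
   are excluded from the multiple-testing pool, and can never be edges.
4. **False-discovery control.** Storey q-values with the smoother pi0
   estimate over the grid lambda = 0.05, ..., 0.95 (`storeyQvalues()`);
   Benjamini-Hochberg is available as `qMethod = "BH"`. Q-values are
   computed over all testable pairs (the standard usage), not only the
   pairs passing the p threshold.
5. **Thresholding.** An edge requires `|rho| >= 0.9`, `p < 0.01` and
   `q < 0.05` simultaneously (`buildNetwork()`). The sign of rho is kept
   on the edge (co-occurrence vs co-exclusion), and each edge is tagged
   intra- or inter-kingdom. Nodes without any surviving edge are
   dropped. Edges are canonically oriented by the lexicographic order of
   OTU ids, making outputs byte-reproducible.

## Topology, nulls, and downstream statistics

* **Modules** come from fast greedy modularity optimization on the
  unweighted, sign-blind graph (`detectModules()`). The cut along the
  merge path with maximal Newman Q is used; when several cuts tie
  numerically (e.g. a complete graph), the one with fewer modules wins,
  so a structureless graph collapses to a single module at Q = 0.
* **Indices** (`networkIndices()`): modularity (MD), average local
  clustering (CC), average path length over connected pairs (APL),
  diameter (ND), average degree (AD = 2E/N), density
  (GD = 2E/(N(N−1))). Path statistics average over *connected* pairs
  because thresholded networks are usually disconnected.
* **Clustering convention.** Nodes of degree < 2 have no defined local
  clustering. The default (`ccMode = "exclude"`) drops them from the
  average — the convention under which the expected CC of a uniform
  G(n,m) graph equals its density, which is the signature that published
  random-network CC columns display; `ccMode = "zero"` counts them as
  zero instead.
* **Null ensembles** (`randomEnsemble()`): uniform G(N, E) graphs
  (default) or degree-preserving double-edge swaps, with fast greedy
  re-run per replicate; observed indices are compared by Z-tests
  (`zTest()`). The G(n,m) default follows from the CC-equals-density
  signature above.
* **O/R ratios** (`orRatio()`): the observed share of same-sign edges
  joining two phyla (Proteobacteria resolved to class level by default)
  over its mean share in the random ensemble, with node labels held
  fixed. Random edges carry no sign, so the random incidence is shared
  between signs. Empirical p-values use the add-one correction.
* **Node roles** (`ziPi()`, `classifyRoles()`): within-module degree
  standardized within each module (population SD; Zi = 0 when the SD is
  0, avoiding infinities) and the among-module participation
  Pi = 1 − Σ (k_is / k_i)². Roles use the conventional thresholds
  Zi = 2.5 and Pi = 0.62 with inclusive lower boundaries: peripheral,
  connector, module hub, network hub.
* **Environment** (`envEdges()`, `moduleEigengene()`,
  `eigengeneEnvCorrelations()`): OTU-environment edges at
  `|rho| >= 0.6`, `p < 0.05` (unadjusted — FDR control is applied only
  to the species-species screen); module eigengenes are the first right
  singular vector of the member-standardized profile matrix, oriented to
  correlate non-negatively with the module mean profile, with modules
  under 4 members skipped by default (matching the usual figure
  convention of hiding tiny modules). Member profiles are standardized
  before the decomposition, the usual eigengene definition.

## Comparing two zones

A single network per zone yields one number per index, so "is AD higher
in zone B?" needs a resampling notion of variability.
`compareZones()` defaults to a permutation test: zone labels are
shuffled across the pooled samples, the entire pipeline is re-run on
both permuted groups, and the two-sided p-value is the add-one-corrected
fraction of permutations whose absolute index difference reaches the
observed one. This is calibrated by construction under exchangeability;
measured on identical-parameter synthetic zones (50 seeds, 99
permutations), the rejection rate at alpha = 0.05 is ~0.02–0.04 for the
edge-driven indices (slightly conservative for MD and ND, whose
differences are coarse). Bootstrap alternatives are kept as options:
`"bootstrap_se"` (observed difference over combined bootstrap SDs) is
strongly over-conservative here because resampling 10 columns with
replacement creates heavy rank ties, and `"welch"` (a t-test treating
bootstrap replicates as observations) is strongly anticonservative; we
document both rather than recommend them.

# The synthetic community generator

`simulateDataset()` emulates the study design the pipeline expects: two
zones of 10 samples, a few thousand to a few hundred OTUs, sequencing
depth 20,000 reads per sample and amplicon, and planted correlated
modules. Per zone and module, a latent per-sample factor drives the
log-abundance of member OTUs as `mu_i + loading * s_i * f_m + noise`,
with a quarter of members carrying negative loadings (`s_i = −1`) so
networks contain co-exclusion edges; proportions are the per-kingdom
softmax and counts a multinomial draw, making the data compositional
like real amplicon counts. The default per-zone loadings (0.5, 0.95)
emulate a weak-structure versus strong-structure contrast; with
noise SD 0.3, a loading of 0.95 puts the true member correlation at
0.95²/(0.95² + 0.3²) ≈ 0.91, deliberately close to the 0.9 edge
threshold. Modules can be tied to environmental variables
(`envLink`; by default module 1 to TN, module 2 to TP), in which case
the variable is an affine transform of the planted factor, leaving rank
correlations intact.

Three generator choices are ours and deserve explanation:

* **Background mass.** Baseline log-abundances have SD 0.4 and
  background (unstructured) OTUs are shifted +1.6, so background taxa
  carry most of the reads. This matches real surveys — network OTUs are
  a small minority of the community — and it keeps the compositional
  denominator stable; without it, denominator fluctuations induced by
  the planted modules attenuate negative correlations below the edge
  threshold and split modules by loading sign.
* **Factor decorrelation.** With only 10 samples, independently drawn
  module factors are frequently rank-correlated by chance (|rho| up to
  ~0.7), which makes the planted truth itself unidentifiable. Factors
  are therefore orthogonalized within each zone; marginally they remain
  standard normal-like, but distinct modules stay distinguishable.
* **Sub-seeding.** One global seed governs everything; each zone draws
  from a seed derived from it, so zone A's data do not depend on how
  many zones follow.

What the generator does *not* emulate: read-level error and chimeras,
OTU-picking artifacts, overdispersion beyond multinomial sampling,
phylogenetic correlation structure, temporal dynamics, and genuine
ecological interaction mechanisms. Passing the validation experiments
therefore shows that the pipeline recovers planted *statistical*
structure from compositional counts at realistic sample sizes — not
that inferred edges in real data are ecological interactions.

# Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` re-run these experiments at
the following sizes, chosen to exercise the study design at desk scale:

* closed-form density/degree identities at the published network sizes
  (N up to 485);
* G(n,m) ensembles of 1000 replicates at (N = 329, E = 436) and
  (N = 353, E = 1443), whose mean CC reproduces the published random
  clustering values 0.008 and 0.023 under the default clustering
  convention;
* a 6-node two-phylum fixture whose random co-occurrence incidence has
  an exact hypergeometric expectation (O/R = 5), matched within
  Monte-Carlo error at 1000 replicates;
* module recovery on 120 OTUs with four planted 20-OTU modules at
  loading 0.95 (adjusted Rand index ≥ 0.8 in ≥ 9 of 10 seeds);
* zone-test calibration over 50 seeds at 99 permutations; eigengene
  factor recovery (|rho| ≥ 0.9); truncated-power-law model selection
  over 50 simulated degree sequences;
* brute-force oracles (explicit-rank Spearman, per-node Zi/Pi recount,
  hand-evaluated Newman Q) agreeing to 1e-12 on ≤ 12-node fixtures.

# Degenerate inputs and numerical conventions

* Constant OTU rows: `rho = NA`, `p = 1`, never edges, excluded from the
  q-value pool.
* Empty sign classes in O/R: flagged (`no_edges`), not zero-filled.
* Degenerate ensembles (SD = 0): Z undefined; p = 1 if the observed
  value equals the null mean, else 0, with a `degenerate` flag.
* Zero within-module degree SD: Zi = 0 for the whole module.
* Single-member modules: the eigengene is the standardized profile,
  flagged `single_member`.
* Fewer than 3 distinct degrees: the degree-distribution fit is skipped
  with a warning.
* All randomness flows through explicit seeds; a fixed seed reproduces
  counts, ensembles and pipeline TSVs bit-identically.

# Known limitations

Plain proportion-based Spearman correlation is subject to compositional
bias: closure induces spurious negative dependence, and common-factor
denominator variation attenuates true negative correlations. The
package deliberately mirrors the conventional pipeline rather than
compositionality-aware estimators (SparCC, SpiecEasi), which are out of
scope. The `r >= 0.9` threshold at n = 10 sits close to the null tail,
so single-zone networks have both missed edges and a nonzero
false-positive floor; conclusions should rest on the null-model
comparisons, not on individual edges. The two published
bacterioplankton average-degree values (2.63, 8.21) are inconsistent
with 2E/N at the printed node/edge counts; the package implements the
closed form and flags those two cells rather than guessing the
variant used.

# A minimal session

```{r example}
library(micronet)

cfg <- syntheticConfig(seed = 1)
tab <- simulateDataset(cfg)

zoneB <- tab[, zones(tab) == "zoneB"]
rel <- toRelative(prevalenceFilter(zoneB, "zoneB", minPrevalence = 8))
net <- buildNetwork(spearmanScreen(rel), rel)
part <- detectModules(net)
networkIndices(net, part)

ens <- randomEnsemble(net, n = 1000, seed = 1)
zTest(networkIndices(net, part)[["CC"]], ens, "CC")

roles <- classifyRoles(ziPi(net, part))
table(roles$role)
```
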