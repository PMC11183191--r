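---
title: "Methods: co-occurrence networks, cohesion, and life-history strategy along nitrogen gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence networks, cohesion, and life-history strategy along nitrogen gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngradnet)
```

## The scientific question

Long-term nitrogen (N) enrichment reorganizes soil bacterial
communities. Two community-level syndromes are commonly reported: the
co-occurrence network simplifies (fewer nodes and edges, lower degree
and clustering), and the community's life-history composition shifts
toward copiotrophs — fast-growing, resource-demanding taxa with high
ribosomal operon (*rrn*) copy numbers and high genomic GC content —
at the expense of oligotrophs. The analytical question this package
addresses is *which* of two correlated candidate drivers better
explains the loss of network complexity: the decline in bacterial
richness, or the shift in life-history strategy. The pipeline
assembles the statistics needed to ask that question — signed
correlation networks with a complexity score, null-corrected cohesion,
community-weighted trait indices, and a piecewise structural equation
model — and a synthetic data generator that encodes the hypothesized
causal structure so that every stage can be tested against known
ground truth.

## Statistical components

### Signed co-occurrence networks and the complexity score

For each N level, all pairwise Spearman correlations among taxa are
computed across that level's replicate samples, with two-sided
p-values from the t approximation on $n - 2$ degrees of freedom and
Benjamini–Hochberg q-values over the upper triangle. An edge joins two
taxa when $|r| \ge r_{\min}$ (default 0.6) and $q < \alpha$ (default
0.05); its sign is the correlation sign. Seven topology parameters are
computed per network: node and edge counts, average degree $2E/N$,
density $2E/N(N-1)$, mean local clustering (degree-$<2$ nodes
contribute 0), modularity of a deterministic greedy partition on the
unsigned weighted graph, and mean shortest-path length on the largest
connected component. The seven metrics are z-standardized across
networks and summarized by their first principal component, oriented
so that the average-degree loading is non-negative — higher PC1 means
a more complex network. Constant metric columns are dropped with a
note.

Spearman was chosen as the default estimator because OTU relative
abundances are closed, heavy-tailed compositions; Pearson is available
by configuration. One network per treatment level keeps the
construction faithful to how gradient studies present their networks;
with the default ten replicate plots per level the per-level
correlation tests retain enough power for BH-significant edges (at
five replicates the smallest achievable p-value is already too large
to survive the correction, which is why the generator's default design
uses ten).

### Null-corrected cohesion

Cohesion summarizes how strongly a sample's community is built from
taxa that covary with others. Per taxon pair the observed correlation
is corrected by the mean correlation under a *taxa-shuffle* null:
each draw permutes one taxon's abundance vector across samples, both
orientations contributing `n_iter` draws (default 200). A taxon's
positive (negative) *connectedness* is the mean of its positive
(negative) corrected correlations; a sample's positive (negative)
*cohesion* is the relative-abundance-weighted sum of connectedness
over taxa. Total cohesion is the positive part plus the magnitude of
the negative part, and the negative:positive ratio indexes the
balance of competitive versus cooperative association.

Two deliberate defaults in the pipeline differ from the original
construction and are worth stating plainly. First, connectedness is
estimated *jointly* from all samples rather than within N levels:
with ten samples per level, the mean over sign-partitioned
correlations has a noise floor of roughly $\pm 0.25$ (the expected
magnitude of a null correlation at $n = 10$ is about $0.26$), which
swallows realistic association signals; at $n = 80$ the floor drops
to $\pm 0.09$. A per-level mode remains available via the `group`
argument. Second, the pipeline's observed correlations inside cohesion
are Spearman rather than Pearson. On closed, roughly lognormal
abundances, the Pearson correlation of two negatively coupled taxa is
bounded near zero (the familiar asymmetry that $\mathrm{corr}(e^X,
e^Y)$ cannot be very negative when the log-scale variances are large),
so a Pearson-based cohesion is structurally blind to exactly the
competitive associations the statistic is meant to quantify. The
low-level function keeps Pearson as its default, faithful to the
original method; the pipeline overrides it.

### Life-history trait indices

Per sample, the copiotroph/oligotroph ratio is the quotient of summed
relative abundances of the two guilds (unclassified taxa excluded);
community-weighted means (CWMs) of *rrn* copy number and GC content
are abundance-weighted averages over annotated taxa, renormalized over
the annotated subset. The composite r/K-strategy axis is the first
principal component of the log ratio and the two CWMs (the ratio is
logged because ratios are scale-asymmetric), oriented so the log-ratio
loading is non-negative: higher scores mean a more copiotrophic,
r-selected community. The ratio is abundance-weighted rather than
richness-based, matching its use alongside CWM traits; a richness
split by guild is computed separately. No 16S copy-number correction
is applied to abundances before the CWMs; practice varies and the
choice is stated rather than hidden.

### Gradient trends, partial correlations, and piecewise SEM

All dose regressions are ordinary least squares on
$\log_2(N + 1)$ — the application rates are doublings, so the
transform makes the design approximately uniform. Partial
correlations residualize both variables on the controls by OLS and
test the correlation of residuals on $n - k - 2$ degrees of freedom.

The piecewise structural equation model fits one OLS per endogenous
variable on its parents and evaluates global fit through the
d-separation basis set: for every non-adjacent variable pair
(deduplicated, ordered topologically) the model claims conditional
independence given the union of both variables' parents; each claim is
tested by regressing the later variable on the earlier plus the
conditioning set, and Fisher's
$C = -2\sum_i \ln p_i \sim \chi^2_{2k}$ aggregates the $k$ claim
p-values. The union-of-parents conditioning convention is stated
because conventions differ. The default DAG is

```
n_dose -> din            n_dose -> ph        n_dose -> plant_richness
din    -> rk_pc1         ph     -> rk_pc1
rk_pc1 -> richness       rk_pc1 -> total_cohesion
richness -> total_cohesion      plant_richness -> total_cohesion
```

which encodes the hypothesis chain — N reaches the community through
soil chemistry, soil chemistry drives the life-history shift, and the
life-history shift (not richness, not plant richness) drives
cohesion — while keeping the competing richness paths in the model so
the data can contradict the hypothesis. All component models are plain
OLS; a block/plot grouping hook is left out because the synthetic
design has no spatial structure.

## The synthetic gradient generator

`sim_config()` / `simulate_dataset()` generate an OTU count table,
trait table, and plot metadata with known effect directions. The
design is 8 N levels (0–64 g N m⁻² y⁻¹, doublings) × 10 replicate
plots, 60 taxa, expected sequencing depth 20,000 with
negative-binomial counts (size 15). The environment responds linearly
in dose: DIN rises, pH and plant richness fall, each with plot-level
Gaussian noise. Nitrogen reaches the community *only* through the
realized DIN and pH values, so the SEM's environmental paths are the
true generative channels.

Latent log-abundance per taxon combines:

* a per-taxon baseline (log-normal abundance spectrum, sd 0.8);
* guild responses to the standardized environment — copiotrophs
  follow DIN and additionally benefit from acidification (acid-tolerant
  opportunists), oligotrophs decline modestly with pH — so the
  copiotroph share rises along the gradient mostly through the
  oligotroph collapse, as trait studies describe;
* module-level cooperation factors: oligotrophs form large, tight
  modules (~18 taxa, high loadings) and copiotrophs small, loose
  associations (~4 taxa, lower loadings) — the "copiotroph
  independence" end of the cooperation spectrum;
* an antagonistic coupling between paired oligotroph modules: the
  second module of a pair loads on the first module's factor with
  opposite sign, and the coupling rotates away linearly with the
  DIN-implied dose. The rotation is zero-sum — taxon variances are
  unchanged as competition is released — so the negative correlation
  block decays with N without distorting the positive modules;
* residual Gaussian noise.

Oligotroph local extinction is gated by the realized
abundance-weighted copiotroph dominance of each sample (competitive
exclusion: the same quantity the r/K axis measures) and falls
preferentially on rare taxa. Rarity targeting matters twice over:
rare taxa carry the richness and network-node decline, but almost no
abundance mass, so the correlations that cohesion depends on are
spared; and because the dropout gate is a function of what `rk_pc1`
measures, richness is conditionally independent of N given the r/K
axis — the default SEM DAG is (approximately) the true generative
graph and Fisher's C is calibrated for it.

Several sketches that look natural were tried and rejected during
design, and the reasons are scientific rather than cosmetic.
Guild-wide cooperation factors are cancelled by compositional closure
for whichever guild dominates abundance, and the closure of a
collapsing guild hands coherent rank rises to the other guild — so
correlation structure must live in modules small relative to total
mass. A single guild-wide competition factor inflates every taxon's
variance exactly where the networks need clean modules. And with
negative structure only *between* guilds, the per-sample
negative:positive cohesion ratio and total cohesion cannot both
decline — the cross-guild block contributes symmetrically to both
guilds' negative connectedness, which is why the generator places the
decaying antagonism *within* the oligotroph guild (between its
modules) and leaves between-guild negativity to the gradient itself.

### What the generator does and does not emulate

It reproduces the statistical skeleton of a multilevel fertilization
experiment: a monotone environmental gradient with noise, a
guild-structured composition shift, modular positive co-occurrence
with decaying competition, rarity-biased species loss, and
overdispersed compositional counts. It does not simulate reads or
sequencing error, spatial (Latin-square) autocorrelation, temporal
dynamics, phylogenetic trait conservatism, or taxon-specific
interaction networks beyond the module/antagonist structure. Passing
the directional tests therefore shows the *pipeline* recovers known
effects embedded in realistic compositional noise — not that any
field system behaves this way.

## Numerical choices and degenerate inputs

Zero-variance taxa get $r = 0$, $p = 1$ against all partners and zero
corrected correlations. Empty networks are returned flagged, with all
topology metrics zero, rather than as errors. Constant columns are
dropped (with a record) before either PCA, and PC1 orientation is
anchored (average degree for networks; log ratio for the r/K axis)
with a deterministic tie-break. The negative:positive cohesion ratio
is flagged undefined when positive cohesion is exactly zero, and such
samples propagate as missing into the complete-case SEM. A claim
p-value of exactly zero is surfaced as an error rather than an
infinite Fisher's C. All stochastic stages draw from stage-local
seeds derived from one master seed, so adding a stage never perturbs
another stage's stream and end-to-end runs are byte-reproducible.

## Problem sizes used by the test-suite simulations

Unit tests run the generator at 16 taxa × 32 samples with shallow
depth; the null-calibration study uses 100 seeds of a fully null
configuration at 30 taxa × 40 samples; the directional-recovery and
SEM-recovery studies use 50 seeds of the full default design (60 taxa
× 80 samples, 200 null-model draws per orientation). The exhaustive
cohesion oracle enumerates all 720 permutations per orientation on a
4 × 6 instance and compares against 50,000 Monte-Carlo draws.

## Known limitations

* The per-sample cohesion trends are emergent properties of the whole
  design, and two of them sit near their recovery targets: across
  50 generator seeds the complexity-PC1 and negative:positive ratio
  trends come out negative in roughly 85–90% of realizations rather
  than all of them. The remaining seeds are genuine statistical
  losses (the race between the positive and negative cohesion
  declines, and per-level network noise), not bugs; they are reported
  as-is by the test suite.
* Bacterial richness and the r/K axis are strongly collinear proxies
  of the same gradient. In roughly a third of realizations the SEM's
  conditional credit assignment lets richness cross $\alpha = 0.05$
  on the cohesion model (often with a suppressor sign). With one
  field dataset one would see a single draw from this distribution;
  the package reports the full distribution instead.
* Guild annotation is taken from the user's trait table. The shipped
  phylum-level lookup (`default_guild_map()`) is a coarse heuristic;
  trophic strategy varies within phyla.
* Cohesion p-values are not computed (the statistic is used
  descriptively and inside regressions, as in common practice); no
  compositional network inference (SparCC-style) is attempted.

## A compact end-to-end run

```{r example, eval = FALSE}
library(ngradnet)

cfg <- analysis_config(seed = 101)
run_full_pipeline(cfg, "runs/demo")
summarize_report("runs/demo")

# or stage by stage:
b <- simulate_dataset(sim_config(rng_seed = 101))
bun <- validate_bundle(filter_taxa(b$counts), b$metadata, b$traits)
rel <- to_relative_abundance(bun$counts)
coh <- compute_cohesion(rel, n_iter = 200, seed = 101,
                        method = "spearman")
idx <- rk_strategy_pc1(trait_indices(rel, bun$traits))
plot_trait_trends(idx, bun$metadata)
```
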