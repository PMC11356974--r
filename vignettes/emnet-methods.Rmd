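---
title: "Methods: linking EM fungal diversity to neighboring plant richness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking EM fungal diversity to neighboring plant richness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific setting

Ectomycorrhizal (EM) fungi colonize the root tips of host trees and trade
soil nutrients for plant carbon. How strongly the EM fungal community of a
*focal* tree reflects the richness of its *neighboring* plant community —
rather than just its host — is the question this package operationalizes.
The study design it targets is a three-way forest-type comparison: pure
oak stands (PF), oak–pine mixtures (QPF), and oak–broadleaf mixtures
(QBF), each sampled in six plots, every plot yielding one composite
root-tip sample (18 samples in all) plus rhizosphere soil, litter
chemistry, and a full census of neighboring plant richness.

`emnet` implements the complete analysis chain over such data: diversity
estimation, Sørensen beta-diversity partitioning, signed co-occurrence
networks with per-sample subnetwork complexity, Zi–Pi node-role
classification, log response ratios across forest types, interaction
mixed models, random-forest contribution estimates, and a partial
least-squares path model — all driven, for testing and demonstration, by
a synthetic-data generator with known ground truth.

# Diversity estimation

`alpha_diversity()` reports the five standard indicators. Shannon entropy
is $-\sum_i p_i \ln p_i$ (nats) and Simpson diversity defaults to the
Gini–Simpson form $1 - \sum_i p_i^2$; because "Simpson" is ambiguous in
the literature, the concentration $\lambda$ and the inverse form are
available through the `simpson` argument and the variant used is recorded
in the result's attributes. Chao1 uses the bias-corrected estimator
$S_{obs} + F_1(F_1 - 1)/(2(F_2 + 1))$, which stays defined when no
doubletons exist; the classic $S_{obs} + F_1^2/(2F_2)$ is available via
`chao1 = "classic"`. ACE splits taxa at 10 individuals (the conventional
cutoff, settable), uses the coverage estimate $C = 1 - F_1/N_{rare}$, and
truncates the coefficient of variation at zero; when every rare taxon is
a singleton ($C = 0$), ACE is undefined and the function falls back to
Chao1. Counts are used as given: no rarefaction is applied, and the
per-sample sequencing depth is reported alongside so users can judge
depth effects themselves.

`beta_partition()` derives presence/absence from counts and partitions
pairwise Sørensen dissimilarity into turnover and nestedness:
$\beta_{sor} = (b+c)/(2a+b+c)$, $\beta_{sim} = \min(b,c)/(a+\min(b,c))$,
$\beta_{sne} = \beta_{sor} - \beta_{sim}$, with the matching
multiple-site forms over all samples. Additivity is exact and is enforced
in the tests to $10^{-12}$. Because a regression of "beta diversity" per
plot needs one value per plot and there is no single canonical reduction,
two are provided and labeled: the default mean pairwise dissimilarity of
a plot to all others, and local contributions to beta diversity (LCBD,
the squared-deviation decomposition of the Gower-centred matrix;
non-Euclidean dissimilarities can produce tiny negative diagonal terms,
which are clamped at zero before normalization).

# Co-occurrence networks

Networks are built from Spearman correlations on taxa that pass an
overall relative-abundance filter (default 0.01% of the grand total).
Edges require $|\rho| \ge 0.6$ at $p \le 0.001$ within the fungal
community and $|\rho| \ge 0.6$ at $p \le 0.05$ for the joint
fungal–bacterial (cross-kingdom) network; both correlations' signs are
kept, since negative edges are read as putative competition. The
correlation threshold is applied to $|\rho|$, not $\rho$, precisely so
that negative edges exist. P-values use the two-sided t approximation on
tie-corrected $\rho$; an exact null distribution is offered for very
small designs (`p_method = "exact"`, $n \le 10$). No multiple-testing
correction is applied by default — the raw-threshold convention of the
field — but Benjamini–Hochberg adjustment is one argument away
(`adjust_p = "BH"`). A known limitation worth stating plainly: at
$n = 18$ the t approximation is slightly liberal in the extreme tail
(the true two-sided rate at nominal $p = 0.001$ is roughly 0.0013), so
with several hundred taxa a network built from pure noise still shows
about one spurious edge on average.

Whole-network topology (`network_topology()`) is computed on the
unsigned graph except for the positive/negative tally: node and edge
numbers, average degree, average shortest-path distance over reachable
pairs, density, degree assortativity, and mean betweenness, degree, and
eigenvector centrality (the latter on the largest connected component).
"Betweenness centrality of a network" is reduced to the mean of
normalized node values by default; Freeman centralization is the
alternative. Undefined quantities — the ratio when no negative edge
exists, assortativity on degree-regular graphs, path metrics on empty
graphs — are `NA` and listed in an attribute rather than silently
dropped.

Each sample then receives its own topology through the induced subgraph
on the taxa present in it (`sample_subnetworks()`,
`sample_subnetwork_topology()`). The multi-complexity index
(`multi_net()`) is the mean of the z-standardized subnetwork node
number, edge number, and betweenness; standardization pools all 18
samples across forest types, because the downstream response ratios
compare forest types on a common scale and per-type standardization
would erase exactly the differences of interest. A metric that is
constant across samples is given z-score 0 everywhere and flagged.

Node roles (`zi_pi()`) use modules from greedy modularity maximization
on the unsigned graph — chosen because it is deterministic, making runs
reproducible without seed bookkeeping; seeded Louvain is available.
Within-module degree $Z_i$ and participation $P_i = 1 - \sum_m
(k_{im}/k_i)^2$ are thresholded at 2.5 and 0.62 (peripheral / connector
/ module hub / network hub), with boundary values assigned to the lower
category and $Z_i = 0$ (flagged) in modules with no degree spread.
Non-peripheral nodes form the keystone set whose relative abundances are
correlated with the diversity indicators
(`keystone_diversity_correlations()`).

One structural fact discovered while validating this module deserves
record: if module detection recovers exactly two modules, the
participation coefficient is bounded by $1 - 1/2 = 0.5 < 0.62$, so
*connectors cannot exist in a two-module graph*. Connector status
requires edges spread over at least three modules. In planted two-block
validation data, bridge taxa can therefore only be classified connectors
if they are numerous and mutually correlated enough to form a third
detected module — and greedy modularity absorbs such a group into a
block whenever its cross-edges are dense enough to give $P_i > 0.62$. A
design-stage grid search over bridge counts (4–6), block loadings
(0.45–0.7), and own-factor loadings (0–0.7) found no configuration that
yields reliable connector classification at $n = 18$, while within-block
edge enrichment and module recovery (adjusted Rand index $\approx 0.99$)
are essentially perfect. Tests of this package assert the attainable
properties; reliable connector detection in two-block data is recorded
here as unattainable rather than papered over.

# Forest-type effects and association models

`log_response_ratio()` implements the standard meta-analytic effect
size $\ln R = \ln \bar{X}_E - \ln \bar{X}_C$ with variance
$v = SD_E^2/(n_E \bar{X}_E^2) + SD_C^2/(n_C \bar{X}_C^2)$, the percent
change $(e^{\ln R} - 1) \times 100$ (identical to the raw percentage
difference of means), and a normal-approximation z-test; because the
test behind significance stars on such figures is often unstated, the
table wrapper also reports the one-way ANOVA p across all groups, and
both are labeled.

`fit_diversity_regressions()` regresses log metric on log plant
richness, overall and within forest type. Metrics spanning zero (the
multi-complexity index) cannot be logged: the default keeps them on the
raw scale and records that; a signed shifted log
($\mathrm{sign}(x)\log(1+|x|)$) is available. `anova_duncan()` pairs the
one-way ANOVA with Duncan's multiple range test: the critical range for
a span of $p$ ordered means uses the studentized range quantile at the
protection level $(1-\alpha)^{p-1}$ with the harmonic mean group size,
and letters come from an insert-and-absorb algorithm, so shared letters
are always contiguous runs over the sorted means.

Covariates are screened by `collinearity_filter()` before modelling:
while any pair has $|r| \ge 0.6$, the member of the worst pair with the
larger mean absolute correlation to everything else is dropped, and the
dropped list with reasons is returned. `fit_interaction_lmm()` fits
$y \sim \mathrm{plant} + \mathrm{env} + \mathrm{plant}\times\mathrm{env}
+ (1|\mathrm{site})$ by REML with Satterthwaite-based Wald tests;
predictors are z-scored by default so intercept and slope effects are
comparable across covariates (disable with `standardize = FALSE`).
Boundary fits (site variance 0) are reported as zero and flagged, in
which case fixed effects coincide with OLS — an identity the test suite
checks to $10^{-6}$. `rf_contributions()` uses 500 trees with
$mtry = \lceil p/3 \rceil$ and reports scaled permutation importance;
model significance comes from refitting on permuted responses (999 by
default), which at these sample sizes is the only honest test. The
"relationship between plant and EM communities" has no standard
operational response variable, so the EM metric itself is the target and
the output says so.

# The PLS path model

`fit_plspm()` is a from-first-principles implementation of
Lohmöller-style alternating least squares: standardized indicators,
mode-A (reflective) outer estimation, and the path inner scheme
(regression weights toward predecessors, correlations toward
successors), iterated until the largest absolute outer-weight change
falls below $10^{-7}$ (cap 300 iterations; non-convergence is an error,
not a warning). The latent blocks follow the study's four-group layout:
plant diversity (richness), abiotic factors (SOC, TN, LC, LP), biotic
factors (assortativity, average distance, eigenvector centrality of the
cross-kingdom subnetworks), and EM diversity (alpha indices, the first
two ordination axes of the community matrix, and subnetwork topology
including multi-complexity). For the beta-diversity indicators the
default is principal coordinates of the Bray–Curtis matrix —
`pca_axes()` performs PCoA when handed a dissimilarity matrix and PCA
when handed a data table, with axis signs anchored by the
largest-magnitude loading (or score) so repeated runs cannot flip.

Path coefficients are OLS fits of each endogenous latent on its
predecessors; $GoF = \sqrt{\overline{\mathrm{communality}} \times
\overline{R^2}}$ averages communalities over blocks with more than one
indicator (single-indicator blocks have communality 1 by construction
and would inflate the index). Effects decompose exactly: the indirect
effect is the sum over directed paths of products of coefficients,
computed by the nilpotent power series of the path matrix, and
`total = direct + indirect` holds to machine precision. Inference is a
seeded nonparametric bootstrap (500 resamples) with percentile CIs; a
small-sample continuity term is added to percentile p-values so they are
never exactly zero. Missing values are a hard error: with 18 samples
there is no imputation worth defending silently.

# The synthetic generator and what it does (not) show

`simulate_dataset()` draws study-shaped data under `sim_params()`. The
defaults are the study conditions where those are known — 6 plots per
forest type, 18 composite samples — and field-realistic choices
elsewhere, fixed once: mean plant richness 15 (PF), 24 (QPF), 30 (QBF)
species per plot (mixtures richer than pure stands, in the range of
warm-temperate secondary forests); sequencing depth 10\,000 reads;
symmetric Dirichlet concentration 1 for fungal relative abundances; EM
pool elasticity `coupling_beta = 0.5` on log plant richness around a
base pool of 40 taxa; site intercepts with SD 0.1 and residual SD 0.2 on
the log scale; bacterial pool of 400 taxa with three planted
co-occurrence blocks (25/20/15) at within-block latent correlation 0.7,
the first block tied to plant richness; soil covariates generated at
stated correlations to richness (SOC 0.6, TN 0.5, LC 0.4, LP 0.3, pH
−0.2, mineral N ~0.1) through a shared habitat factor. Fungal counts are
Dirichlet-multinomial; the realized EM pool is drawn from a ranked
species pool with decaying inclusion weights so communities share a core
and beta diversity is non-trivial.

The generator emulates the *coupling structure* the analysis is meant to
recover; it does not emulate ITS read error, phylogenetic signal,
spatial autocorrelation between plots, or compositional bias-aware
truth. Passing tests therefore demonstrate that the pipeline recovers
known coupling, calibrated nulls, and planted network structure under
these idealized conditions — not that any particular field dataset
satisfies them. The focused two-block generator
(`simulate_planted_blocks()`) uses Poisson counts on absolute latent
abundances rather than multinomial closure, deliberately: closure
depresses cross-taxon rank correlations, and this fixture's job is to
validate edge detection against clean ground truth, while
compositionality-aware inference (SparCC and kin) is explicitly outside
this package's scope.

# Validation problem sizes and numerical conventions

The test suite validates formulas against independent brute-force
oracles (direct summation, set arithmetic, eigendecomposition, explicit
path enumeration), calibrates null behavior (1000-replicate type-I error
for OLS and ANOVA at $\alpha = 0.05$; 100 white-noise tables of 40 taxa
for spurious edges), and measures parameter recovery (200 simulated
studies for the richness-coupling elasticity; 20 designs for the mixed
model interaction; 200 runs of a four-latent chain at $n = 500$ for PLS
paths; $10^4$ replicates for response-ratio bias). These sizes keep the
whole suite within a few minutes on one core while leaving Monte-Carlo
error well inside the asserted tolerances. End-to-end determinism is
checked by running the full pipeline twice at the same seed and
comparing output files byte for byte.

Conventions worth knowing when extending the package: boundary Zi/Pi
values classify downward; Spearman correlations involving zero-variance
series are `NA` and flagged rather than zero; empty subnetworks score
zero; constant indicators are dropped from PLS blocks by the pipeline
(with a record) but are an error in `fit_plspm()` itself; all
randomness flows from a single integer seed per entry point.

# Known limitations

Per-forest-type networks built from only six samples at $p \le 0.001$
are extremely sparse — near-perfect monotone relationships are the only
survivors — so per-sample subnetwork metrics within forest types are
coarse, and keystone detection on the pooled network varies with the
seed. The t-approximation tail issue quantified above means
raw-threshold networks on hundreds of taxa carry roughly one spurious
edge. The PLS path model treats a heterogeneous EM-diversity block
(alpha, ordination axes, topology) as reflective because that mirrors
the study layout it reproduces; a formative specification would be a
defensible alternative and is not implemented.
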