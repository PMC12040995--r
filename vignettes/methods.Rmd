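---
title: "Methods: individual-based host–ectoparasite network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual-based host-ectoparasite network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ectonet` analyses individual-based bipartite networks between host
individuals and ectoparasite species: per-host position indices, null-model
standardized network structure, module-based host roles, permutation tests
for female–male differences, and comparative (phylogenetic) models that ask
whether sex differences in position translate into differences in network
structure. This vignette documents the models, their assumptions, the
tunable parameters, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## The data model

A network couples the parasitized individuals of one host species in one
region to one parasite group (fleas or gamasid mites). Entries `a_ij` are
counts of parasite individuals of species *j* on host *i*. Hosts carrying no
parasite of the focal group are excluded at assembly: every position index
below is undefined for an isolated node, and a survey records interactions,
not absences. For the same reason the cohort selection rule — at least
`min_per_sex = 20` parasitized individuals of each sex, the conventional
threshold for these surveys — counts parasitized individuals only.
All-zero parasite columns are dropped; duplicate (host, parasite) records
are summed rather than rejected, which tolerates long-format exports;
sampling sites are pooled within a region and retained as metadata only.

## Position indices

*Individual strength* `s_i = Σ_j a_ij / A_j` sums the dependencies of every
parasite species on host *i*; strengths add up to the number of parasite
species exactly, which the tests assert at 1e-9 on random matrices.

*Nested rank* places each host in the matrix arrangement that maximizes
nestedness and normalizes the rank to [0, 1] (0 = most generalist). The
arrangement used is the decreasing binary-degree sort with ties broken by
decreasing row total and then input order. This is deterministic,
O(S log S), and coincides with the nested arrangement whenever one exists;
a search-based ordering (optimizing NODF directly) would be slower and
non-deterministic under ties, and the ordering function is pluggable if a
different convention is wanted.

*Specialization d′* is the Kullback–Leibler divergence of the host's
interaction frequencies `p_ij = a_ij / A_i` from the parasite marginals
`q_j = A_j / m`, normalized by the real-valued range `[0, ln(m / A_i)]` and
clamped to [0, 1]. The original formulation normalizes by
integer-constrained extremes; the real-valued relaxation is simpler and
smooth, but the two scales genuinely differ at small totals — the
integer-constrained maximum can even exceed `ln(m / A_i)`, since piling all
of `A_i` onto the rarest parasite achieves `ln(m / min_j A_j)`. The test
suite quantifies this against an exhaustive allocation oracle on matrices
with `m ≤ 12` and freezes the observed discreteness bounds; at survey-scale
totals the gap is immaterial for rank-based comparisons between sexes.
Weighted interactions are assumed throughout (counts are available).

*Eigenvector centrality* is computed on the unipartite host–host
projection. The default projection weights an edge by
`Σ_{shared j} (a_gj + a_hj)`; a binary (shared-species count) and a
degree-discounted variant (`Σ_j 1/(n_j − 1)`) are selectable, since the
upstream convention is a named function argument rather than a fixed
method. Centrality is the principal eigenvector of the symmetric weight
matrix, rescaled to max = 1. It is found by power iteration (tolerance
1e-12, at most 10,000 iterations, uniform start) on the shifted matrix
`W + cI` with `c` = the maximum row sum: shifting leaves eigenvectors
unchanged but makes the principal eigenvalue strictly dominant, which
matters because projections of modular networks can have nearly bipartite
spectra on which unshifted power iteration oscillates. Agreement with a
dense eigendecomposition is asserted at 1e-8.

## Network structure and the null model

*NODF* is the classic binary paired-overlap / decreasing-fill index
(0–100): a pair of rows (or columns) with unequal fill contributes
`100 · overlap / fill_lesser`, equal-fill pairs contribute 0, and NODF is
the mean over all pairs. It is invariant to row and column permutations.
The weighted NODF variant is out of scope.

*H2′* standardizes the two-dimensional Shannon entropy of the interaction
frequencies between an independence upper bound (entropy of the
outer-product expectation) and a lower bound obtained by greedily packing
the marginals into as few cells as possible (always loading the cell of the
currently largest remaining row and column totals). The greedy packing
approximates the integer-constrained minimum from above, which biases H2′
upward by a small amount; the endpoints (0 for an exact outer product, 1
for an equal-total diagonal) are exact and tested.

Because networks differ in size, fill and totals, raw indices are not
comparable across networks; both indices are therefore standardized as
Z-scores against a constrained null model. Each null draw preserves the
grand total `m`, the number of filled cells `L`, and leaves no row or
column empty, with cell selection and event placement proportional to the
product of the observed marginals: phase 1 selects `L` distinct cells,
phase 2 places one interaction in each and distributes the remaining
`m − L` events over them with replacement. Phase 1 first tries whole-draw
rejection (sample `L` cells, retry if some row or column is uncovered); on
matrices whose size or marginal skew makes full coverage vanishingly rare
in a single draw, it falls back to a coverage-first construction that draws
cells lying in still-uncovered rows or columns one at a time by the same
probabilities. The fallback biases selection slightly towards low-marginal
rows; the alternative — unbounded rejection — simply does not terminate on
realistic matrices. Either way the m / L / coverage invariants hold
exactly, and the ensemble's mean marginals track the observed totals
approximately and proportionally (this null-model family does not fix
marginals exactly, so the tests compare ensemble means against the
per-draw spread, not against the vanishing standard error of the mean).
Z-scores use the sample (n−1) standard deviation; a zero-variance ensemble
yields Z = 0 with a warning. The default ensemble size is 1000; every
stochastic operation takes an explicit seed and records it in its result.

The comparative stage uses the Z-scores as structure responses by default
(`response_scale = "zscore"`); the raw indices are selectable, since
standardization is what makes networks of different sizes comparable but
either choice is defensible.

## Modules and roles

Modules maximize Barber's bipartite modularity
`Q = (1/m) Σ_ij (a_ij − A_i A_j / m) δ(g_i, h_j)` using weighted label
propagation: starting from distinct row labels, columns adopt the label
with the largest modularity contribution, then rows, until Q stops
improving, followed by a greedy module-merging pass; the best of
`n_restarts = 10` seeded restarts is kept. If nothing beats the
single-module baseline, the single module (Q = 0) is returned, so reported
Q is never negative. Simulated-annealing optimizers for the same objective
are slower and no more deterministic; label propagation with restarts
recovers planted two-block partitions (within-block density 0.8, between
0.05) with adjusted Rand index 1 in at least 95 of 100 seeded runs, which
the tests assert.

Within-module degree `z_i` standardizes a host's links into its own module
against the hosts of that module (0 where the module's spread is zero);
the participation coefficient `c_i = 1 − Σ_t (k_it / k_i)²` measures how
evenly links spread over modules. Both use binary degrees by default (the
upstream convention), with a weighted variant behind a flag. Role
thresholds are the empirical 95th percentiles of the network's own z and c
distributions — pooled over both sexes, since the per-network threshold
describes the network, not a sex — with linear-interpolation percentiles
(the common default; percentile conventions differ enough to matter, so
the choice is fixed and documented). "High" means strictly above the
threshold, so an all-equal network classifies every host peripheral rather
than promoting ties. The classic fixed thresholds (z = 2.5, c = 0.62) are
available as options, not defaults: they were calibrated for large
metabolic networks, not for networks of tens of hosts.

## Within-network sex comparisons

Counts of parasite individuals are compared between sexes by
negative-binomial (NB2, log link, ML dispersion) regression and species
richness by Poisson regression, both reporting the Wald z for the sex
coefficient — Wald rather than likelihood-ratio inference because z
statistics are the reporting convention for these models.

The four position indices jointly enter a distance-based MANOVA: Euclidean
(Pythagorean) distances, the one-way decomposition
`SST = (1/N) Σ_{i<j} d²`, `SSW = Σ_g (1/n_g) Σ_{i<j∈g} d²`, and
`pseudo-F = ((SST − SSW)/(g−1)) / (SSW/(N−g))`, with p-values from 10,000
random permutations of the sex labels and the `(1 + b)/(1 + nperm)`
convention (p can never be 0, and `nperm = 1` puts p on the {0.5, 1}
grid). Index columns are centred and scaled by default before the
distance: strength is unbounded while the other three live in [0, 1], so
an unstandardized distance would be dominated by whichever index happens
to have the largest variance. The toggle exists for sensitivity analysis.
On univariate input the pseudo-F reduces to the classical one-way ANOVA F
exactly (asserted at 1e-10), and the permutation null makes no normality
assumption. Univariate permutation ANOVAs per index (same permutation
scheme, full label randomization — equivalent to residual randomization
under the intercept-only reduced model for this one-factor design) report
which index drives a multivariate difference, alongside per-sex means and
standard errors. No multiplicity adjustment is applied anywhere; readers
who prefer family-wise control can apply it to the reported p-values.

## Across-network comparative models

Per network, the sex difference in each index is the natural log of the
larger of the two mean ratios, `ln max(mean_M/mean_F, mean_F/mean_M)` —
non-negative, symmetric, zero only at equality. Role-proportion differences
are modelled by a beta GLMM (logit mean link, constant precision φ,
Gaussian species random intercept, Laplace-approximate ML via glmmTMB);
proportions are nudged off the boundary by exactly ±1e-7 first, because
the beta likelihood excludes 0 and 1. If the random-intercept variance
collapses, the model refits as fixed-effects beta regression and flags the
collapse. The default fixed structure pools the four roles with a role
fixed effect (one sex coefficient per parasite group); modelling one
role's proportions alone is the `include_role = FALSE` variant — the
marginal per-role and pooled analyses answer slightly different questions
and both are exposed, neither treated as ground truth. A compositional
joint model of all four proportions is deliberately out of scope.

Structure responses are regressed on the four sex-difference predictors by
phylogenetic GLS under plain Brownian motion:
`β̂ = (XᵀC⁻¹X)⁻¹XᵀC⁻¹y` with `C` the shared branch-length matrix, ML
variance `σ̂² = RSS/n`, exact multivariate-normal log-likelihood, and
`AIC = −2 logL + 2(p + 2)` counting the intercept and σ². No Pagel's λ or
other transformation is estimated: with ~20 tips per group there is little
information to estimate a transformation parameter on top of four
candidate slopes, and ML (never REML) keeps AICs comparable across fixed
effects. All 16 predictor subsets (including intercept-only) are fitted
and ranked; ties break towards fewer predictors, then lexicographically.
The whole-model F reported with the best model is the GLS F-test of all
slopes jointly zero, the natural analogue of a whole-model p alongside
AIC. A species occurring in both regions enters as two unit-length sister
tips (a cherry replaces the original tip), and `unit_branches = TRUE` sets
every edge to 1 — the convention that treats regional populations as
exchangeable sister taxa; a species-level response sharing one tip across
regions would make C singular.

## The synthetic-data generator

The generator emulates the statistical skeleton of a multi-species,
two-region ectoparasite survey: per host, a total load drawn from a
negative binomial with mean `nb_mean` (5 by default — a typical flea
burden) and dispersion 1 (strongly overdispersed, as real burdens are),
multiplied by `male_abundance_mult` for males; the load is allocated over
`n_parasites = 15` species by a multinomial whose baseline follows a
geometric rank-abundance profile (ratio 0.7 — a few common and many rare
species, which is what makes nestedness non-trivial); and when
`male_composition_shift > 0` each sex uses its own Dirichlet perturbation
of the baseline. Load and composition are controlled separately so that
abundance and composition effects can be switched on independently —
per-species independent negative binomials would entangle them.
Unparasitized draws are redrawn so that exactly `hosts_per_sex = 30`
parasitized individuals per sex enter each network (comfortably above the
≥ 20 rule; the assembly stage would drop zero-load hosts anyway).
Collections add a Yule (pure-birth) tree over species and per-species
effect sizes drawn uniformly from configured ranges. With all effects off
the sexes are exchangeable by construction, which is what makes the
type-I calibration of the downstream tests meaningful.

What the generator does **not** emulate: spatial and temporal structure
(sites and sampling periods are labels, not processes), parasite-parasite
interactions within hosts, aggregation of parasites beyond the negative
binomial, phylogenetic signal in the effect sizes themselves, and
host-species differences in parasite faunas (all species share one
rank-abundance skeleton). Passing tests therefore show that the pipeline's
statistics are correct and calibrated under a faithful null — not that
real surveys satisfy these assumptions.

## Problem sizes and determinism

The test suite and the acceptance script run everything at desk scale,
chosen so the full battery exercises every stage on one core in minutes:
type-I calibration uses 1000 replicates of 25 hosts per sex with 999
permutations; effect-size recovery uses 200 replicates each for the
negative-binomial (n = 200 per sex) and beta-GLMM (20 species) layers and
500 Brownian replicates on a 100-tip tree for PGLS; the packaged demo
collection is 21 species × 2 regions × 2 parasite groups with 200 null
matrices and 999 permutations per network. Production settings (1000
nulls, 10,000 permutations) are the package defaults. Every stochastic
operation takes an explicit seed, per-network streams are derived
deterministically from the master seed, and rerunning any configuration
reproduces its outputs bit for bit.
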