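# ectonet

Individual-based host–ectoparasite network analysis in R.

`ectonet` asks a question from parasite ecology: **do female and male hosts
occupy different positions, and play different roles, in individual-based
host–parasite networks — and do those differences shape the structure of the
network as a whole?** Its model system is ectoparasites (fleas and gamasid
mites) on small mammals sampled in two regions, but any survey that records
parasite counts per host individual fits the data model.

An individual-based network is a bipartite graph: one mode is host
*individuals*, the other parasite *species*, and the edge weight
`a_ij` is the number of parasite individuals of species *j* recorded on host
*i*. For each host species × region × parasite group with at least 20
parasitized individuals of each sex, the package computes:

- **Per-host position indices** — individual strength
  `s_i = Σ_j a_ij / A_j` (summed dependencies of the parasite community on
  the host); normalized **nested rank** (position in the maximally nested
  arrangement, 0 = most generalist, 1 = most specialized); the
  **specialization index d′** (Kullback–Leibler divergence of the host's
  interaction frequencies from the parasite marginals, normalized to
  [0, 1]); and **eigenvector centrality** on the weighted unipartite
  projection.
- **Network structure** — **NODF** nestedness (paired overlap, decreasing
  fill) and **H2′** network-level specialization (standardized
  two-dimensional Shannon entropy), both Z-standardized against 1000
  constrained null matrices that preserve the grand total, the number of
  filled cells, and approximately proportional marginals.
- **Module-based roles** — Barber bipartite modularity maximized by
  weighted label propagation with restarts; within-module degree *z* and
  participation coefficient `c = 1 − Σ_t (k_it/k_i)²`; hosts classified as
  peripheral / connector / module hub / network hub at per-network 95th
  percentile thresholds.
- **Within-network sex comparisons** — negative-binomial regression of
  parasite counts and Poisson regression of species richness on sex;
  distance-based MANOVA (pseudo-F on Euclidean distances over the four
  indices, 10,000 label permutations); univariate permutation ANOVAs per
  index.
- **Across-network comparative models** — beta GLMMs (logit link, species
  random intercept) of role proportions on sex; phylogenetic GLS of NODF /
  H2′ Z-scores on the four log mean-ratio sex-difference predictors
  (`dNR`, `dSS`, `dEC`, `dDP`), with all-subsets AIC model selection under a
  Brownian-motion covariance from a Newick tree (species present in both
  regions enter as unit-length sister tips).

A seeded synthetic-data generator (negative-binomial loads, geometric
rank-abundance parasite pools, controllable male abundance and composition
biases, Yule host tree) makes the entire pipeline testable without field
data.

## Worked example

```r
library(ectonet)

cfg <- pipeline_config(
  simulate = simulation_config(n_species = 4, hosts_per_sex = 22, seed = 11),
  n_null = 50, nperm = 199, seed = 11
)
res <- run_pipeline(cfg)
head(res$tables$db_manova, 4)
#>   parasite_group   region species  pseudo_F    p
#> 1           flea  Siberia    sp01 0.7048052 0.47
#> 2           mite  Siberia    sp01 2.1896194 0.11
#> 3           flea Slovakia    sp01 3.1352648 0.09
#> 4           mite Slovakia    sp01 0.4031146 0.62
res$tables$pgls_best
#>       model                      equation              t                  p_c
#> 1 flea_nodf +5.56*dNR -1.61*dSS +2.65*dDP 3, -2.28, 1.88 0.0399, 0.085, 0.133
#> 2   flea_h2            -4.58*dNR -4.7*dDP   -2.92, -3.98        0.033, 0.0105
#> 3 mite_nodf                   (intercept)           <NA>                 <NA>
#> 4   mite_h2                     +3.72*dEC            1.5                0.184
#>          R2         F         p_m      AIC
#> 1 0.7856249  4.886295 0.079739831 14.11814
#> 2 0.8722479 17.069142 0.005833384 12.15184
#> 3 0.0000000        NA          NA 30.53192
#> 4 0.2729626  2.252671 0.184057379 25.62870
res$comparative$structure_correlation$rho
#> [1] -0.8382353
```

Read this as: for each simulated network the db-MANOVA pseudo-F tests
whether the sexes separate in the four-index position space; the PGLS table
lists the AIC-best model of each structure response per parasite group with
slope estimates, t and per-coefficient p (here, flea-network specialization
is best explained by the nested-rank and d′ sex differences, R² = 0.87);
and nestedness and specialization Z-scores are strongly negatively
correlated across networks (Spearman ρ = −0.84). With the null generator
settings every db-MANOVA p is uniform — significant rows appear at the
nominal 5% rate.

A packaged demo configuration
(`inst/extdata/demo_config.yaml`: 21 species × 2 regions × 2 parasite
groups, per-species effect sizes drawn from configured ranges) can be run
from a shell:

```sh
Rscript inst/scripts/run_pipeline.R --config inst/extdata/demo_config.yaml --out demo_out
```

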