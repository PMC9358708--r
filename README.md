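# ecoassembly

Community-assembly analysis for bacterial 16S surveys: who is abundant, who
is rare, and which ecological processes — selection, dispersal, drift —
shaped each subcommunity.

Given a rarefied OTU count table, a phylogeny (or a taxon distance matrix
from which a neighbor-joining tree is built) and per-sample environmental
metadata, the package

1. partitions taxa into **abundant** (relative abundance ≥ 0.1%),
   **rare** (< 0.01%) and intermediate classes, locally and regionally;
2. quantifies taxonomic turnover (Bray–Curtis) and phylogenetic turnover
   (abundance-weighted **βMNTD**,
   `0.5 [ Σ_{i∈k} w_i min_{j∈m} d_ij + Σ_{j∈m} w_j min_{i∈k} d_ij ]`);
3. infers assembly processes per sample pair with two null models, each on
   999 permutations:
   **βNTI** = (βMNTD_obs − mean βMNTD_null) / sd βMNTD_null from tip
   shuffles on the phylogeny, and **RC_Bray** = 2(P − 0.5) where P is the
   probability that a null community pair (richness and read totals fixed;
   taxa drawn ∝ occupancy, reads ∝ regional abundance) is less dissimilar
   than observed. Pairs are classified as heterogeneous selection
   (βNTI > +2), homogeneous selection (βNTI < −2), dispersal limitation
   (RC > 0.95), homogenizing dispersal (RC < −0.95) or undominated;
4. relates diversity and assembly to the environment with Mantel
   permutation tests, Spearman correlations and Wilcoxon rank-sum
   comparisons.

A synthetic metacommunity generator with tunable selection strength, niche
breadth, dispersal decay and drift — and phylogenetically conserved niches
from Brownian traits on a simulated tree — provides ground truth for
validating the whole chain by parameter recovery. The methods vignette
(`vignettes/community-assembly.Rmd`) documents the model, every tunable
parameter, and the design decisions, including one deliberate red flag:
under strong drift the RC_Bray metric misattributes drift to dispersal
limitation, which the validation keeps visible instead of hiding.

## Worked example

```r
library(ecoassembly)

# a 44-sample survey-scale metacommunity with known generative parameters
sim <- simulate_metacommunity(synthetic_scenario(
  n_taxa = 1000, n_samples = 44, depth = 24251,
  s = 2, omega = 0.5, lambda = 2, theta = 200, seed = 11))

regional <- classify_regional(sim$otu)
table(regional$labels)
#> abundant intermediate         rare
#>      272          339          389

cs <- category_summary(sim$otu, classify_local(sim$otu))
subset(cs$means, category != "intermediate")
# abundant taxa average 53.9% of observed richness but 95.4% of the reads;
# rare taxa 13.3% of richness and 0.2% of the reads

rare <- subset_subcommunity(sim$otu, regional, "rare")
abund <- subset_subcommunity(sim$otu, regional, "abundant")
bc_ab <- bray_curtis_matrix(abund); bc_ra <- bray_curtis_matrix(rare)
rank_sum_test(bc_ab[lower.tri(bc_ab)], bc_ra[lower.tri(bc_ra)])
#> abundant mean Bray-Curtis 0.612 vs rare 0.970, p ~ 0
#> (the rare subcommunity turns over far more between lakes)

cfg <- null_model_config(n_null = 999, seed = 11)
bn <- bnti_matrix(abund, patristic_distances(sim$tree), cfg)
rc <- rc_bray_matrix(abund, cfg)
classify_assembly(bn, rc, cfg)
#> assembly process fractions (946 pairs):
#> heterogeneous_selection 0.412 | homogeneous_selection 0.002
#> dispersal_limitation 0.582 | homogenizing_dispersal 0.000
#> undominated 0.003   (deterministic 0.414 | stochastic 0.586)
```

Running the same classification on the rare subcommunity
(`analysis/03_assembly_processes.R`) gives het 0.174, dispersal limitation
0.017 and undominated 0.781 — under this generative scenario the abundant
subcommunity carries the selection and dispersal signal while the rare one
is mostly unresolved, and 9 of 27 Mantel tests against the spatial and
environmental divergences are significant at p < 0.05.

```r
```

The numbered drivers under `analysis/` run this end to end and write their
tables beneath `results/`: `01_simulate_scenarios.R` (datasets),
`02_partition_diversity.R` (partition, Spearman panel, rank-sum
contrasts), `03_assembly_processes.R` (the full `run_pipeline()` with
βNTI/RC_Bray for abundant, rare and all taxa plus Mantel panels; about a
quarter hour), `04_regime_recovery.R` (classification of the neutral,
selection and dispersal-limited calibration datasets).

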