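# coaldelim

Coalescent-based species delimitation for single-locus (mitochondrial)
data, built around three lines of evidence that field herpetologists and
other organismal biologists combine when deciding whether allopatric
populations deserve species rank:

1. **Divergence screening** — pairwise uncorrected p-distances (pairwise
   deletion of gaps/ambiguities) against the 3–5% thresholds that separate
   intra- from interspecific 16S divergence in amphibians. Non-conspecific
   pairs below the band are candidates for *lumping*; conspecific pairs
   above it are candidates for *splitting*; pairs touching the band are
   reported as grey zone.
2. **Two-population multispecies-coalescent (MSC) inference** — Bayesian
   estimation of the divergence time τ and the mutation-scaled population
   sizes θ_A, θ_B, θ_root (all in expected substitutions/site) under
   inverse-gamma priors IG(α, β) with mean m = β/(α−1), by
   Metropolis-within-Gibbs MCMC over the genealogy and parameters (JC69
   likelihood, Felsenstein pruning in C++). Priors come either from a
   ten-set sensitivity grid (diffuse α = 3 vs informative α = 21, means
   spanning two orders of magnitude) or from empirical calibration:
   nucleotide diversity for θ, guide-tree MRCA height for τ. A
   reversible-jump sampler moves between the merged (one-θ) and split
   models and reports the posterior probability of the split, with support
   bands pp ≥ 0.95 (high), 0.90 ≤ pp < 0.95 (moderate), pp < 0.90 (weak).
3. **The genealogical divergence index** —
   `gdi = 1 − exp(−2τ/θ)`, computed per posterior draw in both directions
   (θ_A and θ_B) and summarised as mean ± SD; means above 0.7 indicate
   distinct species, below 0.2 the same species, anything else ambiguous.

A coalescent simulator (`simulate_msc_dataset()`) generates datasets with
known truth at the study's scale, so the whole pipeline is testable without
downloading anything. `run_pipeline()` chains the stages per candidate pair
and writes screening, prior-sensitivity and evidence-summary tables; a thin
CLI over the same functions ships in `inst/scripts/coaldelim.R`.

## Worked example

Simulate a deeply diverged pair (τ = 0.03, θ = 0.002, 10 + 10 samples,
1000 bp), screen it, calibrate empirical priors, fit the MSC, and combine
the evidence:

```r
library(coaldelim)

sim <- simulate_msc_dataset(tau = 0.03, theta_a = 0.002, theta_b = 0.002,
                            theta_root = 0.002, n_a = 10, n_b = 10,
                            length = 1000, seed = 42)
dm  <- p_distance_matrix(sim$locus)
tax <- data.frame(population_a = "A", population_b = "B", conspecific = TRUE)
screen_candidates(dm, sim$popmap, tax, lower = 3, upper = 5)
#> Candidate screen: 1 pairs (1 flagged)
#>  population_a population_b conspecific d_min d_max d_mean        category
#>             A            B        TRUE  5.90  6.30   6.03 split_candidate
```

The pair is conspecific under current taxonomy but 5.9–6.3% divergent —
above the 5% threshold, so it is flagged for splitting. Calibrate priors
from the data (θ from within-population diversity; τ from a two-tip guide
tree at half the mean between-population distance) and fit:

```r
h     <- between_population_summary(dm, sim$popmap, "A", "B")[["d_mean"]] / 200
tree  <- guide_tree(ape::read.tree(text = sprintf("(A:%g,B:%g);", h, h)))
priors <- prior_set(empirical_theta_prior(sim$locus, sim$popmap),
                    empirical_tau_prior(tree, c("A", "B")), "empirical")
priors
#> Prior set 'empirical': theta ~ IG(3, 0.00415556), tau ~ IG(3, 0.0603)

fit <- fit_msc_pair(sim$locus, sim$popmap, priors,
                    settings = mcmc_settings(2000, 1000, 5),
                    n_runs = 4, seed = 1)
summary(fit)
#> Posterior summary (4 runs pooled), pair (A, B):
#>                mean       sd     2.5%      50%    97.5%
#> tau        0.029597 0.004241 0.021409 0.029591 0.037759
#> theta_a    0.001399 0.000647 0.000579 0.001258 0.003079
#> theta_b    0.001852 0.000839 0.000769 0.001683 0.003999
#> theta_root 0.002181 0.002107 0.000589 0.001593 0.007574
```

The generating values (τ = 0.03, θ = 0.002) sit inside every 95% interval,
and the four runs agree (R-hat ≈ 1, ESS > 1000 for every parameter). The
gdi and the split-model probability then both point the same way:

```r
g <- gdi(fit, "both")
g$a
#> gdi A vs B (2*tau/theta_A): 1.00 ± 0.00  -> distinct

d <- delimit_pair(sim$locus, sim$popmap, priors,
                  settings = mcmc_settings(2000, 1000, 5),
                  n_runs = 4, seed = 1)
d
#> Split-vs-merge delimitation, pair (A, B):
#>   pp(split) = 1.000  [high support]
#>   per-run: 1.000, 1.000, 1.000, 1.000 (spread 0.000)

summarize_evidence(d$pp_split, g$a, g$b)$verdict
#> [1] "split supported"
```

`plot(fit)` shows traces and posterior densities; `plot(g$a)` the gdi
density against the 0.2/0.7 bands. `run_pipeline()` does all of the above
for every flagged pair and writes TSV reports plus per-pair trace files.

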