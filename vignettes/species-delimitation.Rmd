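---
title: "Coalescent species delimitation with coaldelim: models, priors and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent species delimitation with coaldelim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`coaldelim` implements a three-stage workflow for deciding whether allopatric
populations sampled for a single mitochondrial locus should be treated as one
species or two: (1) uncorrected p-distance screening against
amphibian-calibrated divergence thresholds, (2) Bayesian inference under the
two-population multispecies coalescent (MSC), including trans-model
split-versus-merge comparison, and (3) the genealogical divergence index
(gdi). This vignette explains the models, every tunable that matters, the
numerical decisions, and what the simulation-based tests do and do not
establish about real data.

## Stage 1: threshold screening

For every pair of sequences the uncorrected p-distance is the fraction of
mismatches among *comparable* sites: positions where both sequences carry an
unambiguous A/C/G/T. Gaps and IUPAC ambiguity codes are dropped pairwise
rather than fractionally matched — the convention of "uncorrected p-distance
with pairwise deletion", chosen because it is reproducible and matches what
distance programs report by default. `U` is normalised to `T` and `?` to `N`
on input, since rRNA GenBank records mix conventions.

Candidate pairs are screened with two thresholds, by default 3% and 5% in
percent divergence, the range shown to separate intra- from interspecific
16S divergence in amphibians. Writing `[lower, upper]` for the band:

* a **non-conspecific** pair whose whole divergence range lies strictly below
  `lower` is a *lump candidate*;
* a **conspecific** pair whose whole range lies strictly above `upper` is a
  *split candidate*;
* any pair whose range touches the band (boundary values included) is
  reported as *grey zone* and analysed but not auto-acted on — the band is a
  reporting device, not a decision rule.

Conspecificity always comes from a user-supplied taxonomy table; the package
never infers it. Between-population summaries report the min, max and mean
over all cross-population sequence pairs (printed to two decimals in percent;
full precision is kept internally).

## Stage 2: the two-population MSC model

Populations A and B diverged at time `tau` (expected substitutions per site)
from an ancestral population. Each population has a mutation-scaled size
`theta` (`theta_A`, `theta_B`, `theta_root`): within a population carrying
`k` gene lineages, every pair coalesces at rate `2/theta` (total rate
`k(k-1)/theta`). Below `tau` lineages may only coalesce within their own
population; at `tau` the survivors enter the ancestral population. Sequences
evolve on the resulting genealogy under JC69 with equal base frequencies —
the conventional default when no substitution model is stated for the
coalescent engine; the locus is treated as haploid with heredity scalar 1,
appropriate for mtDNA.

Priors on `tau` and on every `theta` are inverse gamma, IG(alpha, beta), with
mean `beta/(alpha - 1)` for `alpha > 2`. Two routes supply them:

* **Sensitivity grid** (`prior_grid()`): ten prior sets crossing a diffuse
  shape `alpha = 3` and an informative shape `alpha = 21` with means spanning
  two orders of magnitude — five theta priors {IG(3, 0.0002), IG(3, 0.002),
  IG(3, 0.02), IG(21, 0.02), IG(21, 0.2)} against the central tau prior
  IG(3, 0.004), and five tau priors {IG(3, 0.0004), IG(3, 0.04),
  IG(21, 0.004), IG(21, 0.04), IG(21, 0.4)} against the central theta prior
  IG(3, 0.002).
* **Empirical calibration**: `beta = m (alpha - 1)` with `m` set from the
  data — mean within-population nucleotide diversity for theta, and the
  pair's MRCA height on an ultrametric guide tree (heights in expected
  substitutions per site) for tau. The default `alpha = 3` keeps the prior
  heavy-tailed, so the calibration fixes the scale without pretending to
  know the spread. When every population is a singleton, or observed
  diversity is exactly zero, the mean is uncalibratable and a configured
  fallback prior is used with a warning (calibrating to zero would make the
  prior degenerate).

### The sampler

`fit_msc_pair()` is Metropolis-within-Gibbs over the genealogy and the
parameters. One sweep performs:

* a uniform age-slide for every internal node inside its valid window
  (between its children's ages — raised to `tau` for nodes joining the two
  populations — and its parent's age); the root age moves by a
  multiplicative proposal;
* two constrained nearest-neighbour exchanges and two random subtree swaps
  (symmetric selection; moves violating the `tau` constraint have zero
  posterior density and are rejected);
* a multiplicative random walk on `tau`, bounded above by the youngest node
  joining the two populations;
* exact Gibbs draws of every `theta` from its conditional
  IG(alpha + c, beta + S), where `c` counts coalescences in that population
  and `S = sum k(k-1) dt` over its intervals — the conjugacy that the
  coalescent factor `(2/theta)^c exp(-S/theta)` induces;
* one joint rescaling of all node ages, `tau` and every `theta`, which
  decorrelates the overall time scale.

Step sizes are tuned during burn-in toward a 0.2–0.4 acceptance rate and
frozen afterwards so detailed balance holds for every recorded draw. Each of
the `n_runs` (default 4) independent runs derives its seed as
`seed + run - 1` and starts from a genealogy simulated at the prior means.
Default chain settings are 100000 recorded samples, burn-in 10000, one
record every 5 sweeps.

The likelihood kernel collapses the alignment to unique site patterns and
runs Felsenstein pruning in C++ with per-pattern rescaling; ambiguity codes
contribute a partial likelihood of 1 over their compatible states. With the
low diversity typical of this scale (tens of variable sites in ~1 kb), the
pattern count is small and a full-tree pruning per proposal is cheap.

### Split versus merge

`delimit_pair()` estimates the posterior probability of the two-species
model by reversible-jump MCMC between the merged model (one panmictic
population, a single `theta`) and the split model, with equal prior model
probabilities by default (exposed as `prior_split_prob`; no convention for
this prior is universal, so it is explicit). The jump proposes `tau` from
its prior truncated at the youngest node joining the two populations, and
every `theta` from its conditional inverse-gamma posterior given the
genealogy. Because that conditional is exactly proportional to the prior
times the coalescent factor, the theta terms cancel analytically and the
acceptance ratio reduces to a ratio of theta-integrated genealogy densities
— the jump is near-Gibbs in everything but the genealogy itself. Proposing
the thetas from their raw priors instead is valid but essentially never
accepts once each population carries more than a handful of lineages.

The genealogy remains the slow direction: a chain in the split state holds
two-cluster trees that the merged model finds improbable, and vice versa.
Runs therefore alternate between a split-model and a merged-model start, and
the across-run spread in the split probability doubles as a mixing
diagnostic: spreads above 0.05 raise a convergence warning (never an error).
With informative data the two starts agree quickly; in the no-data
(prior-only) regime cross-model mixing degrades with sample size, which is
why the prior-recovery property of the trans-model sampler is exercised at
small sample sizes, where transitions are frequent.

Support bands follow the usual reading: `pp >= 0.95` high, `0.90 <= pp <
0.95` moderate, below that weak.

### Convergence diagnostics

`convergence_check()` computes, per parameter, the largest across-run
difference in posterior means (in pooled-SD units), rank-normalised
split-chain R-hat, and an effective sample size from Geyer's initial
monotone sequence on the split, rank-normalised chains. Parameters with
R-hat above 1.05 or ESS below 200 are flagged. Note that split-chain R-hat
of two *identical* stationary chains is near, not exactly, 1 (the two halves
of one chain differ); the tests assert closeness accordingly.

## Stage 3: the genealogical divergence index

`gdi = 1 - exp(-2 tau / theta)` is the probability that two lineages
sampled in one population coalesce before the divergence event, looking
backward. It is computed *per posterior draw* — direction A-vs-B uses
`theta_A`, B-vs-A uses `theta_B` — and then summarised as mean ± SD, because
published tables report exactly that and plug-in values at posterior means
understate the uncertainty. Classification uses the posterior mean with
strict thresholds: above 0.7 distinct species, below 0.2 same species,
anything else (including the boundaries) ambiguous. Both directions are
always computed, and the pipeline flags pairs where they disagree in
classification, since a single published value rarely states its direction.
Density summaries use a Gaussian kernel with Silverman bandwidth restricted
to [0, 1]. At extreme `tau/theta` the draw saturates to 1 in double
precision; the limit is approached, never attained, analytically.

## Evidence synthesis

`summarize_evidence()` encodes the joint reading of the support band and the
two gdi directions: *split supported* requires a high band and at least one
distinct direction; *lump supported* requires a weak band and both
directions same; everything else is *ambiguous*. This is deliberately the
most mechanical reading of the combined-evidence table format — narrative
judgements (holding taxonomic changes in abeyance, case-by-case grey-zone
treatment) stay with the user.

## The synthetic-data generator

`simulate_msc_dataset()` produces exactly the data-generating process the
inference assumes: a two-population coalescent genealogy (`tau = 0` giving
the panmictic null), i.i.d. JC69 sites from a uniform root state, gap-free,
single-locus, haploid. Defaults mirror the scale of a 16S study — 10 + 10
samples, 1000 bp, `tau` and `theta` of order 10^-3 – 10^-2. Truth parameters
travel with the dataset and a plain-text sidecar.

Because generator and model coincide, passing tests establish *internal*
correctness: the sampler targets its posterior, intervals cover truth at
nominal rates, the trans-model sampler is calibrated. They do not establish
robustness to what real 16S data add: alignment gaps and ambiguity codes
(handled by the likelihood but not simulated), substitution-model
misspecification, rate variation across sites, selection on mtDNA,
migration after divergence, or multi-locus discordance. The gap between
"one mitochondrial locus supports a split" and "these are species" is
scientific, not computational, and the package keeps it visible by reporting
bands and classifications rather than verdict probabilities alone.

Distributional checks of the simulator test against closed forms — pair
coalescence ages against Exp(2/theta), the (1,1) cross pair against a
shifted exponential, expected p-distance against `3/4 (1 - exp(-4d/3))` —
which is sharper than comparing against another stochastic simulator.

## Numerical choices and degenerate inputs

* Site patterns are compressed once per fit; pruning rescales a pattern's
  partials whenever the maximum falls below 1e-100.
* The ultrametricity tolerance for guide trees is 1e-8 on the tip-height
  spread; tip heights are then treated as exactly zero.
* A genealogy violating the `tau` constraint has log-density `-Inf` and the
  violating node is reported in an attribute rather than by raising an
  error, since samplers must be able to evaluate and reject such states.
* Zero comparable sites between two sequences is an error naming the pair;
  an all-singleton or zero-diversity dataset falls back to the configured
  theta prior with a warning (or errors without one).
* `tau = 0` is a valid simulation input (panmixia) but not a valid split
  model parameter; the merged model carries that case.
* Ties in node ages have probability zero under the continuous model; the
  implementation uses strict comparisons (`age < tau` within populations,
  `age >= tau` ancestral).

## Problem sizes used by the tests

The test-suite experiments run at the study's scale but with chain lengths
chosen for a laptop-class budget: parameter recovery uses 20 replicates of
10 + 10 samples and 1000 bp with 1500 recorded draws after 1000 burn-in
sweeps; calibration uses the same with two runs per dataset (one start per
model); prior-reproduction uses 10^4 draws thinned every 40 sweeps so the
Kolmogorov–Smirnov test's independence assumption is honest. The default
`mcmc_settings()` remain the full-length protocol; the short chains are a
test-budget choice, and the conjugate and prior-reproduction checks confirm
the sampler is exact at any length.

## Known limitations

* Only the two-population core is implemented: multi-population joint
  species-tree estimation is out of scope, and multi-pair analyses iterate
  over pairs independently.
* Single locus, no migration, no recombination, JC69 only (configurability
  is deliberately deferred).
* Cross-model rjMCMC mixing in data-poor regimes depends on initialisation;
  the alternating starts and the 0.05 spread warning surface this rather
  than hide it.
* Exact replication of published tables from GenBank data requires
  downloading the original alignments; the package validates against
  closed forms and simulations instead, and documents the replication
  recipe in the README.
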