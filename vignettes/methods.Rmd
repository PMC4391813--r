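---
title: "Models and methods behind gagconnect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gagconnect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gagconnect)
```

# The scientific problem

Gag grouper (*Mycteroperca microlepis*) spawn on Campeche Bank (CB) and
across the West Florida Shelf (WFS), two shelf systems separated by water
far too deep for adult movement. Whether the WFS stock is demographically
connected to CB — by larval transport on the Loop Current — is a question
with direct management consequences. `gagconnect` implements the complete
population-genetic tool chain with which that question is addressed:
multilocus differentiation testing with simulation-calibrated error rates,
mismatch-distribution expansion dating, heterozygosity-based
bottleneck/expansion tests, haplotype networks, and scenario-constrained
migration-model comparison, together with a synthetic-data generator that
reproduces the statistical structure of the study design (three demes
sampled at 85/148/241 fish, ten microsatellite loci with 4–33 alleles,
~536-site control-region sequences with a 9-bp and a 40-bp tandem-repeat
indel bounded at 7 and 13 copies).

All parameters follow the mutation-scaled conventions of coalescent
migration inference: per-deme `theta = 4*Ne*mu` for nuclear data (a quarter
of that for the maternally inherited mitochondrial genome), migration rates
`M = m/mu` oriented source → recipient, and effective migrant numbers
`Nm = theta*M/4` for the recipient deme.

# The synthetic-data generator

The generator is first-class, tested code: every analysis stage is
exercised against data whose true parameters are known.

**Structured coalescent (microsatellites and mtDNA).** A discrete-deme
Kingman sampler (compiled code) runs backwards in mutational time: within a
deme holding `k` lineages, coalescence occurs at rate `k(k-1)/theta`;
a lineage in deme `d` jumps to source deme `s` at the backward rate
`M[s, d]`. Mutations are placed as a Poisson process at rate one per
lineage per unit time. Microsatellite states perform a stepwise walk —
strict single steps (SMM) or, under the two-phase model (TPM), single steps
with probability `p_single = 0.9` and otherwise geometric multi-step jumps
of mean 2 (the TPM is named in the field's bottleneck methodology without
printed parameters; these defaults are exposed and stamped into output).
Allele codes are repeat counts anchored at 100. Two numerical guards exist:
with all-zero migration between multiple demes the genealogy height is
capped (with a warning) because the demes cannot share ancestry, and after
20,000 migration events a genealogy is collapsed to the strong-migration
(panmictic) limit with the harmonic-mean effective size — beyond that point
the individual events are statistically indistinguishable from panmixia and
only cost time.

The sampler is validated distributionally, not against its own internals:
single-deme SMM heterozygosity matches the closed form
`He = 1 - 1/sqrt(1 + 2*theta)`; a symmetric `k`-island model reproduces
`F_ST = 1/(1 + k*theta*M_pair)` (equivalently `1/(1 + 4*k*Nm_pair)`), the
finite-island generalization of the textbook `1/(1 + 4*Nm)`; one-deme
samples give Tajima's D centred on zero.

**mtDNA.** One genealogy (no recombination) is shared by the sequence and
both repeat loci. Substitutions follow an equal-rates finite-sites model —
the control-region data enter every statistic only through difference
counts, so a richer substitution model would change nothing the pipeline
measures; the choice is configurable. Repeat loci perform ±1 copy-number
walks bounded at [0, max], at rates set relative to the whole-sequence
rate (default 0.015 per motif, echoing the roughly thirty-fold lower
per-locus rate of the indels compared with the sequence).

**Forward-drift divergence experiment.** Two daughter populations drift
from shared ancestral frequencies by multinomial Wright–Fisher resampling
with no migration; after `t` generations, 85 diploids are sampled per side
and multilocus Weir–Cockerham F_ST is computed. Under pure drift the
expectation is `1 - exp(-t/(2*Ne))`. The default `Ne = 10,000` diploids is
a derived calibration: it is the one value consistent with both benchmark
behaviours of this experiment (F_ST ≈ 0.06 after ~1,300 generations, the
time since the last glacial maximum, and ≈ 0.5 after 14,000 generations).
Mutation is off by default: microsatellite mutation at realistic rates
would depress identity-based F_ST through homoplasy, and the drift
expectation is the quantity of interest.

**Null and power sampling.** `sample_null_frequencies()` re-specifies the
POWSIM design: demes drift independently from a shared base-frequency pool
for `t` generations in a population of size `N` chosen so that
`1 - (1 - 1/2N)^t` equals the target F_ST; a target of zero means direct
multinomial sampling. Genotypes are drawn in Hardy–Weinberg proportions.

# File formats and indel recoding

GENEPOP is parsed with per-file auto-detection of 2- vs 3-digit allele
width (mixed widths are rejected as ambiguous) and round-trips losslessly;
FASTA input goes through `ape` with deme tags taken from a delimited header
field ("|" by default, configurable because supplementary-file header
syntax varies). The two perfect tandem repeats are recoded in place: an
array of `n` motif copies becomes `n` adenosines followed by `max - n`
single-site gaps, so a copy-number difference of `|n - m|` equals exactly
`|n - m|` single-site steps and the recoding is invertible. Three data
views mirror the analysis design: `sequence_only` (gap-bearing columns
excluded), `sequence_plus_indels` (each recoded indel site is a standard
site), and `indels_as_rflp` (repeat counts alone). Alignment coordinates
are 0-based half-open internally; motifs are assumed to occur in left-to-
right order of their alignment positions.

# Diversity and neutrality screening

Per-locus summaries use the unbiased heterozygosity `n/(n-1)(1 - sum p^2)`
and `F_IS = 1 - Ho/He` (flagged undefined at monomorphic loci). The exact
Hardy–Weinberg test samples genotype tables with fixed allele counts by
random re-pairing of gene copies and compares Levene conditional
probabilities; linkage disequilibrium uses the Metropolis chain over
genotype-by-genotype contingency tables. Sequence summaries report
haplotype diversity, segregating sites, Watterson's theta, nucleotide
diversity (identical, by construction, to the mean of the mismatch
distribution), Tajima's D with the standard variance constants, and Fu's
Fs computed as `ln(S'/(1-S'))` with `S' = P(K >= k_obs)` under the Ewens
sampling distribution at `theta = pi` (log-space Stirling-number
recursion; negative values mean haplotype excess, the expansion
signature). Multiple testing uses plain Bonferroni at two granularities
(per-locus, e.g. 0.05/9 ≈ 0.0056 for ten loci, and global); sequential
Bonferroni is deliberately not used.

# Differentiation testing

`weir_cockerham_fst()` implements the variance-components estimator
(components a/b/c per allele per locus, multilocus ratio of sums), with
permutation of individuals — not gene copies — so within-individual
dependence survives the null resampling. Negative estimates are reported
as computed; they read as zero. `phi_st()` runs the AMOVA partition of
pairwise step distances; `standardized_phi_prime()` divides F_ST by the
value obtained after recoding every deme's alleles to be deme-private,
the maximal differentiation the within-deme diversity allows — the
standardization that compensates the high-heterozygosity bias of
microsatellite F_ST.

The multilocus chi-squared test sums per-locus Pearson statistics on
allele-count tables (alleles whose expected count anywhere falls below 1
are pooled into an "other" class; a flag exposes the unpooled variant).
The exact test runs a Metropolis chain over fixed-margin tables (default
chain: 10,000 dememorization steps, 100 batches of 5,000 iterations;
standard errors from batch means; ties count as extreme), with per-locus
p-values combined by Fisher's method. Two numerical points matter: an
add-one Monte-Carlo correction keeps a sampled p of exactly zero — which
only means "below chain resolution" — from exploding the Fisher sum, and
chains of at least ~50,000 recorded steps per locus are needed before the
combined test holds its nominal level, because the log in Fisher's method
amplifies Monte-Carlo noise asymmetrically.

The minimum spanning network collapses identical haplotypes into
frequency-weighted nodes, builds a Kruskal tree under a deterministic
(distance, lexicographic id) edge order, and then flags every co-minimal
alternative edge — a non-tree edge whose weight equals the maximum on the
tree path between its endpoints — so the output is seed-free and a true
network. Edges carry their step decomposition (base vs 9-bp vs 40-bp
changes).

# Historical demography

Expected mismatch distributions under both expansion models are computed
from exact phase-type integrals of the pairwise coalescence time, with
time in pairwise-difference units so that `tau = 2*mu*t`:

* sudden demographic expansion `(tau, theta0, theta1)` — exponential
  coalescence at rate `1/theta1` until `tau`, then `1/theta0`;
* spatial expansion `(tau, thetaS, M)` — an infinite-island range where a
  pair in one deme coalesces at `1/thetaS` or separates at `M/thetaS`,
  separated pairs cannot coalesce before `tau`, and everything older than
  `tau` sits in a single ancestral deme of size `thetaS`.

Both reduce to the stationary geometric `F_j = theta^j/(1+theta)^(j+1)` at
`tau = 0` and are verified in the test suite against an independent
coalescent simulation of the same demographies (the simulation is also the
engine of the parametric bootstrap). Fitting minimizes the sum of squared
deviations with a deterministic multi-start bounded optimizer (tau linear,
size parameters on log scale, cap 99,999 reported as a sentinel). The same
start grid is used for the data fit and for every bootstrap refit — warm-
starting the refits from the data estimate looks like an optimization but
biases the goodness-of-fit p-value, because refits would then fit their
data better than the original fit fits its own. The bootstrap yields
5%/95% parameter quantiles, the model p-value (share of simulated SSDs at
least as large as observed), and the raggedness p-value.

Dating: the expansion-age relation is used as
`years = G * tau / (2*mu)` — the operationalization that converts a
mutational-time tau through generations to years — with `G = 7.94` years
and `mu` per sequence per generation (1.23e-4 for sequence data, derivable
as `0.02888e-6 * G * L` at `L = 536` aligned sites). A formula transcribed
the other way around ("tau = 2*mu*t*G") is dimensionally inconsistent with
every published date this relation reproduces exactly, so the consistent
reading is adopted.

The bottleneck/expansion test simulates, for each locus, the equilibrium
distribution of heterozygosity conditional on the observed allele count
and sample size under the TPM (coalescent rejection sampling started from
the Ewens-matched theta, with the condition relaxed to ±1 allele if
acceptance is poor), standardizes the observed heterozygosity, and
combines loci by Wilcoxon signed-rank (two-tailed plus one-tailed excess
and deficiency) and a sign test. Heterozygosity excess is the bottleneck
signature; deficiency indicates expansion or unresolved substructure.
Fewer than four usable loci refuse the Wilcoxon and fall back to the sign
test alone.

# Migration-model comparison

The ten-model space is catalogued exactly: Scenario 1 (CB source: one-way
flow into both WFS demes, free migration within the WFS), Scenario 2 (full
connectivity except SWFS→CB), full and symmetric 3-population models,
one-way and full/symmetric 2-population models, panmixia, and Scenario 3
(the reverse source-sink orientation). Masks declare each directed rate
free, zero, or tied-symmetric, and feed both the simulator and the
inference.

Inference is rejection ABC in place of full-likelihood genealogy-sampling
MCMC — a deliberate engine substitution that keeps the scenario space, the
uniform [0, 100] priors on theta and M, the BF > 150 decision rule and the
`Nm = theta*M/4` conversion, while remaining desk-scale and testable by
recovery experiments. Summary statistics per deme are mean heterozygosity,
allele count, allele-size variance, and private-allele count and
frequency; per deme pair, Weir–Cockerham F_ST, an allele-size-variance
analogue, and signed contrasts of diversity and privacy (a pure source
keeps private variants its sinks lack, the most direction-informative
low-order summary). Distances are Euclidean after robust scaling;
accepted draws optionally receive the local-linear regression adjustment.
Model evidence is approximated by each scenario's acceptance rate at a
tolerance common to all scenarios (a pooled distance quantile), which is a
prior-predictive density estimate at the data.

A limitation worth stating plainly: at the gene-flow levels this system
operates at (Nm ≈ 20), all migration scenarios sit within O(1/Nm) of
panmixia, and opposite source-sink orientations are nearly observationally
equivalent in summary space. The recovery experiments in the test suite
show the correct scenario ranking is recovered, but acceptance-rate
evidence ratios between the true orientation and its reverse concentrate
around 2–10, not in the >150 "very strong" range that full-likelihood
thermodynamic integration can report on large samples. Decisive Bayes
factors at near-panmictic gene flow are a property of full-likelihood
evidence, not of low-order summaries; the corresponding acceptance check
is left failing rather than weakened.

# Problem sizes used in the checks

The test suite and acceptance script run everything at sizes a laptop
handles comfortably, chosen once: diversity calibrations at 40–85 samples
and 100–200 loci; the divergence benchmark at its full published design
(Ne = 10,000, 100 replicates, 85 diploids sampled); type-I calibration at
1,000 null datasets of 3 × 85 diploids × 10 loci with 55,000-step exact-
test chains; tau-recovery at 100 trials of 50 sequences with 40 bootstrap
replicates; ABC recovery at the full design (85 diploids per deme, 10
loci) with 450 draws per scenario, a pooled 5% tolerance quantile and 20
trials; coverage at 25 two-deme trials of 300 draws. What
passing these checks shows is internal consistency and calibration under
the generator's assumptions — neutral, unlinked loci, equilibrium or
piecewise-stationary demography, no null alleles or genotyping error; real
data can violate any of these, which is exactly why the screening stage
(HWE, LD, neutrality) runs first in the pipeline.

# Known limitations

* No selection, recombination within mtDNA, overlapping generations, or
  spatially explicit larval transport — out of scope by design.
* The ABC evidence approximation is honest about ranking but weak for
  Bayes-factor magnitude near panmixia (above).
* Fu's Fs uses the Ewens distribution at `theta = pi`, the standard
  approximation; for very large samples the Stirling recursion is O(n²)
  but exact in log space.
* The spatial-expansion closed form assumes infinite islands and a single
  ancestral deme of the same size as a present-day deme; it matches the
  coalescent oracle for moderate M but is not a finite-landscape model.
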