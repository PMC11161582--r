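---
title: "Methods: population genetics and private-allele tracing of a traded pangolin"
author: "pangotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genetics and private-allele tracing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangotrace)
```

# The problem

The white-bellied pangolin (*Phataginus tricuspis*) is among the most
trafficked mammals in the world. Carcasses reach large urban bushmeat
markets from a network of rural source areas, and seizures surface at
international borders. Two molecular data types carry complementary
information about this trade: a 402-bp cytochrome-*b* fragment separates
deeply divergent maternal lineages (in western Central Africa, the WCA and
Gab clades), while a panel of 20 species-specific microsatellite loci
resolves individuals and populations within a lineage. `pangotrace`
implements the full analysis chain over both marker types — diversity and
equilibrium statistics, forensic identity indices, a private-allele
rarefaction protocol that assigns market and seizure animals to candidate
source populations, a coalescent bottleneck test, and the mitochondrial
haplotype/mismatch workflow — together with a synthetic-data generator
that reproduces the statistical structure of such a study, because real
trade genotypes are rarely public.

The package is organised as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers over the functions documented
here, writing their tables under `results/`.

# Synthetic data generator

`simulate_model()` builds per-population allele frequencies by Dirichlet
perturbation of a shared ancestral vector: population frequencies are drawn
`Dirichlet(c * p_anc)` with concentration `c`, so every allele has
among-population variance `p(1-p)/(c+1)` and the Weir–Cockerham theta
estimand is exactly `1/(c+1)` (`expected_fst()`). This gives the generator
a closed-form differentiation dial that estimator-recovery tests can be
scored against. Spatial structure (`ibd_strength` in [0, 1]) tilts each
population's target along a geographic gradient between two endpoint
vectors, which produces a positive Mantel correlation between chord and
great-circle distances without a full stepping-stone model.

The default scenario (`simulate_scenario()`) defines the emulated study
design:
ten reference populations of 5–45 diploid individuals at 20 loci;
per-population inbreeding/Wahlund coefficients spanning 0.11–0.22; Dirichlet
concentration 40 (pairwise theta centred near 0.024, within the low
within-lineage range of 0.006–0.048); eight strictly-private alleles
injected at frequency 0.15 in eight populations; two urban markets of 84
and 248 animals drawing from four and six source populations; one
10-animal seizure; 2% duplicated individuals (the same animal sampled
twice) and 5% missing calls, after which the 75% completeness filter is
applied as in the field protocol. Allele codes sit on a 2-bp ladder from
100, mimicking dinucleotide repeats; injected private alleles use odd
codes off the ladder so their privacy is structural, not accidental.

Two mechanisms produce the heterozygote deficit. The default draws, per
call, an identical-by-descent homozygote with probability `f`; it is exactly
controllable and is what the recovery tests use. The alternative
(`mechanism = "wahlund"`) splits each population into cryptic demes
differentiated to a between-deme theta of about `f` and samples
Hardy–Weinberg within demes, mimicking the usual interpretation of a
positive F~IS~ with low F~ST~ — pooled structure rather than inbreeding.

What the generator does *not* emulate: allele-size homoplasy and binning
error, genotyping dropout that is correlated within multiplexes, family
structure within populations, and market mixtures whose weights drift over
time. Tests passing on this generator therefore certify the estimators and
the protocol logic, not robustness to those field artefacts.

# Diversity and F-statistics

Per population, `diversity()` reports the mean number of alleles (Na),
observed heterozygosity (Ho), expected heterozygosity `He = 1 - sum p_i^2`,
and the unbiased `uHe = 2n/(2n-1) He` (n = typed genotypes). Allelic
richness is hypergeometric rarefaction to `g` gene copies,
`A_R = sum_i [1 - C(N-N_i, g)/C(N, g)]`, with `g` defaulting to the
smallest non-zero gene-copy count over population-locus cells (the FSTAT
convention).

F~IS~ and pairwise F~ST~ use the Weir–Cockerham (1984) variance components,
summed over alleles and loci with complete-case treatment per locus.
Significance comes from randomization: gene copies re-paired among
individuals within populations for F~IS~ (one-tailed for deficit),
individuals shuffled between the two populations for each pairwise theta.
All permutation p-values use the add-one rule `(b+1)/(m+1)`, so they are
never zero. Defaults are the conventional field-protocol settings: 10,000
permutations
for F~ST~ and Mantel, 1,000 randomizations for linkage disequilibrium,
Bonferroni correction across multiple tests.

Isolation by distance is tested at the individual level: the
Cavalli-Sforza–Edwards chord distance on allele-dosage profiles, averaged
over mutually typed loci, against great-circle distance in km (WGS84). The
field description of geographic distance as "Euclidean" leaves projection
unstated; both a haversine great-circle (default) and a planar option are
provided, and at the ~1,000-km scale of such studies the choice moves the
Mantel r only marginally.

Hardy–Weinberg tests default to the chi-square goodness of fit
(`df = k(k-1)/2`), with a Monte-Carlo exact variant that re-pairs the
observed gene copies. Null alleles are estimated from the heterozygote
deficit (Chakraborty's `(He-Ho)/(He+Ho)` and Brookfield-1
`(He-Ho)/(1+He)`) with a Micro-Checker-style homozygote-excess Monte-Carlo
p-value; the size-class binning of the original program is simplified to
per-allele expected homozygosity, a documented divergence.

# Identity and forensic indices

`find_matches()` compares canonical (sorted) genotype pairs at all
mutually typed loci; missing data never count as mismatches, and a
mismatch budget accommodates genotyping error. `pgen()` gives the
multilocus genotype probability with an inbreeding adjustment
(`p^2 + f p(1-p)` for homozygotes, `2pq(1-f)` for heterozygotes); alleles
unseen in the reference table receive a floor frequency `1/(2N+1)` so
market genotypes are never assigned probability zero. `psex()` is the
probability of encountering the genotype more than once among n animals,
`1 - (1-pgen)^(n-1)`, computed via `expm1`/`log1p` because 20-locus
genotype probabilities underflow the naive form.

Per-locus identity indices: `PI = sum p_i^4 + sum_{i<j} (2 p_i p_j)^2`,
the sibling bound `PIsibs = 1/4 + a_2/2 + a_2^2/2 - a_4/4`, and the
unbiased estimator

uPI = [n³(2a₂² − a₄) − 2n²(a₃ + 2a₂) + n(9a₂ + 2) − 6] / [(n−1)(n−2)(n−3)],

where `a_k = sum p_i^k` and **n counts sampled gene copies**. Two
conventions circulate for this formula (n as individuals with an extra
factor of n in the denominator, or n as gene copies); we fixed ours by a
Monte-Carlo unbiasedness experiment — with the form above,
`E[uPI(p_hat)] = PI(p_true)` to within Monte-Carlo error at n as small as
20, and `uPI -> PI` as n grows, which the alternative transcription fails.
`min_loci_for_pi()` sorts loci by informativeness and reports how many are
needed to push the cumulative PI under a threshold (the conventional
forensic bar is 0.01).

# Tracing by private-allele rarefaction

The tracing signal unit is the private allele: one observed in exactly one
reference population. Raw private-allele counts are dominated by sample
size, so the protocol rarefies. For a set S of populations, the expected
number of distinct alleles of population j in a subsample of g gene copies
is `sum_i [1 - C(N_j - N_ji, g)/C(N_j, g)]`, and the expected number of
*private* alleles multiplies each term by the probability that every other
population's subsample of g copies misses that allele. The implementation
is exact (log-scale binomial coefficients) and is tested against full
enumeration of all `C(N, g)` subsets on small instances. One subtlety the
enumeration makes vivid: an allele shared between populations still
contributes to a population's expected private count whenever the other
subsamples can miss it; the contribution vanishes only at full sample
size.

Locus selection follows the protocol: keep (locus, population) pairs whose
expected private-allele count at `g* = 5` individuals exceeds 0.4 and whose
curve has plateaued or is still rising there. "Plateau or increasing" is
quantified as a last-step slope of at least `-slope_tolerance` (default
0.01); the protocol as practised gives no numeric rule, so the tolerance is a
package choice, configurable. The rarefaction unit defaults to individuals
(g individuals = 2g gene copies), matching the "rarefied from 2 to 5
individuals" usage; a gene-copy mode is provided.

Candidates are then cross-filtered against the private alleles actually
observed. Beyond the locus-level screen, `build_panel()` screens each
allele on its own merits: it must be observed at least twice, and its
individual rarefied private expectation at g* must clear the same 0.4
threshold. This guards against sampling-noise privates — alleles that are
genuinely present in several populations but happen to be unobserved in
the other (small) reference samples. Without the allele-level screen such
alleles enter the panel and produce false assignments; with it, assignment
precision against generator truth is 1.0 across the seeds we examined for
the default scenario. The residual risk cannot be eliminated: an allele at
a few percent frequency in several populations can look strictly private
to samples of 5–45 individuals, and at some generator seeds one such
allele passes both screens (one master seed of the analysis drivers yields
precision 0.83). This is the in-silico face of the protocol's published
caveat — inference quality is bounded by the representativeness of the
reference sampling — and is why assignments are reported with their
per-locus evidence rather than as bare labels.

Assignment itself is deliberately simple, mirroring the manual screening
it automates: an animal is assigned to source P if it carries at least one
panel allele of P; animals with evidence for several sources are kept but
flagged as conflicted, and the chord-diagram-ready market-by-source
summary counts non-conflicted assignments only. Missing genotypes at panel
loci contribute nothing; there is no imputation and no likelihood model —
likelihood-based assignment is out of scope by design.

# Bottleneck test

The heterozygosity-excess test compares, per locus, the unbiased
heterozygosity with the distribution expected at mutation–drift
equilibrium given the observed allele count k. Equilibrium samples come
from a coalescent simulator (compiled code) with stepwise mutation: SMM
moves one repeat unit per mutation; TPM adds, with probability
`1 - p_smm`, a multi-step geometric jump. TPM defaults are
`p_smm = 0.95`, geometric variance 12 — the conventional settings for this
class of test — and TPM with
`p_smm = 1` reduces exactly to SMM. Theta is tuned per locus by bisection
until the pilot mean allele count matches k (tolerance 0.25 alleles, 500
pilot replicates), then replicates are retained conditional on exactly k
alleles.

Two calibration choices deserve emphasis, both made after measuring the
test's size on equilibrium data and both deviating from the textbook
recipe:

* **Quantile scoring.** The conditional Heq distribution is left-skewed,
  so the sign of `He - mean(Heq)` is positive about 61% of the time *at
  equilibrium*, and a Wilcoxon on mean-centred differences rejects a true
  null at roughly 0.14 instead of 0.05. Each locus is therefore scored by
  its conditional quantile `u = P(Heq <= He)` (mid-rank, add-one
  smoothed), which is uniform under the null, and the Wilcoxon signed-rank
  (exact for <= 25 loci) is applied to `u - 1/2`. Mean-based standardized
  differences are still reported per locus for inspection.
* **Theta-window conditioning.** Plugging in a single tuned theta
  understates the uncertainty of the mutation parameter given one locus's
  allele count and leaves the quantiles overdispersed; each
  rejection-sampling attempt therefore draws theta log-uniformly in
  `[theta/3, 3*theta]`. With both choices the measured type-I error is
  0.053 ± 0.009 over 600 equilibrium replicates.

The calibrated test pays for its honesty with power: across declining-
population scenarios (10-fold decline, varied timing, up to 100
individuals and 20 loci) the one-tailed excess test rejects at best in
roughly 44% of replicates. Users should read a non-significant excess test
as weak evidence, not absence of a bottleneck.

# Mitochondrial workflow

Haplotype collapsing is strict by default — sequences containing anything
but unambiguous A/C/G/T are removed, matching the usual "remove sequences
with missing data" practice — and identical survivors are grouped.
Diversity statistics are the standard S (polymorphic sites), h (haplotype
number), `Hd = n/(n-1)(1 - sum p_i^2)` and nucleotide diversity pi (mean
pairwise differences per site).

Distances are Kimura 2-parameter with pairwise deletion,
`d = -1/2 log((1-2P-Q) sqrt(1-2Q))`; saturated pairs (non-positive log
argument) are flagged infinite rather than silently truncated. Trees are
Saitou–Nei neighbor joining via `ape`, with support from resampling
alignment columns; our K2P implementation is cross-checked against
`ape::dist.dna(model = "K80")` in the tests, keeping implementation and
oracle separate. Lineage assignment walks from each query tip toward the
root of the combined NJ tree and adopts the lineage of the first
reference-containing clade if that clade is pure; mixed first clades yield
an explicit tie/paraphyly diagnostic, and queries with fewer than 100
unambiguous sites are not assigned. On synthetic two-lineage data with 23
fixed differences — the divergence observed between the WCA and Gab
clades — assignment is error-free.

The mismatch analysis fits the sudden-expansion model. We derived the
expected pairwise-difference distribution in closed form via regularized
incomplete gamma functions: with coalescence hazard `1/theta1` more
recently than tau (in mutational time units) and `1/theta0` beyond,

F_j = (1/θ₁) a^-(j+1) P(j+1, aτ) + e^{τ(1/θ₀−1/θ₁)} (1/θ₀) b^-(j+1) Q(j+1, bτ),

with `a = 1 + 1/θ₁`, `b = 1 + 1/θ₀`; at `tau = 0` this reduces exactly to
the geometric equilibrium curve `θ^j/(1+θ)^{j+1}`, which the tests assert.
Parameters are fitted by least squares on the relative frequencies
(Nelder–Mead on a transformed scale enforcing `τ >= 0`,
`θ₁ >= θ₀ >= 0`, four starts). The raggedness statistic uses the pinned
convention `r = sum (x_i - x_{i-1})^2` over classes `0 .. d_max + 1` with
zero classes appended at both ends (a one-class distribution has r = 2);
conventions differ between sources, so ours is stated and tested.
P-values are a parametric bootstrap: coalescent samples are simulated
under the fitted expansion (piecewise-exponential coalescence times,
infinite-sites mutations at rate 1/2 per lineage per unit), refitted, and
compared on SSD and raggedness with the add-one rule. The
spatial-expansion mismatch model is not implemented; only the sudden
demographic form is.

# Problem sizes and reproducibility

Every stochastic function takes an explicit seed and restores the caller's
RNG state; `derive_seeds()` spawns per-stage streams from one master seed,
and rerunning any driver or the pipeline with the same configuration
produces byte-identical artifacts (hash-checked in the tests). The test
suite and the acceptance script scale their simulation sizes to desk
scale: identity-index oracles use 10^6 simulated pairs, calibration
studies use 300–1000 null replicates with 99–150 permutations or
conditional replicates inside each, and the bottleneck power study was
pinned from a 50-replicate run; the package defaults
(10,000 permutations/replications) remain the study-scale conventions.

# Known limitations

* Tracing precision is conditional on strict privacy of the panel
  alleles; quasi-private alleles occasionally survive both screens (see
  above), so assignments are hypotheses about origin, not proof.
* The bottleneck test's power against a 10-fold decline is modest once
  honestly calibrated, and TPM parameters are conventions, not estimates.
* The mismatch bootstrap refits each replicate with the same least-squares
  criterion; generalized-least-squares internals of other programs are not
  replicated, so SSD p-values can differ from theirs in the tails.
* No R~ST~, AMOVA, jackknife confidence intervals, Bayesian assignment or
  skyline reconstruction; the out-of-scope list of the protocol is final
  here.
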