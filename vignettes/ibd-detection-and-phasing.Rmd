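---
title: "Phase-aware IBD detection and IBD-driven phasing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-aware IBD detection and IBD-driven phasing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdphase)
```

This vignette is the package's own account of the science it implements:
the two hidden Markov models for pairwise identity-by-descent (IBD)
detection, the link-based phase updater, the simulator that provides
ground truth, the numerical and design choices that were genuinely open,
and what the tests do and do not establish.

## Observation models

All models work locus by locus on biallelic SNPs with allele A frequency
$p$ (and $q = 1-p$), assumed known or estimated from the panel, and treat
observations at different loci as independent given the hidden IBD state.
That last assumption means SNPs should be in approximate linkage
equilibrium; no LD correction is applied (see *Limitations*).

**Genotype emissions (2 states).** For a pair of samples the unordered
genotype pair falls in one of six classes with emission probabilities

| observation | NO IBD | IBD | $\mathrm{lev}_G$ |
|---|---|---|---|
| {AA, AA} | $p^4$ | $p^3$ | $\log_2 p$ |
| {AA, AB} | $4p^3q$ | $2p^2q$ | $1+\log_2 p$ |
| {AA, BB} | $2p^2q^2$ | $0 \to 2p^2q^2\,2^{-\gamma}$ | $\gamma$ |
| {AB, AB} | $4p^2q^2$ | $pq$ | $2+\log_2 pq$ |
| {AB, BB} | $4pq^3$ | $2pq^2$ | $1+\log_2 q$ |
| {BB, BB} | $q^4$ | $q^3$ | $\log_2 q$ |

$\mathrm{lev}_G$ is the per-locus log-evidence (bits) in favour of NO IBD.
The incompatible observation {AA, BB} is impossible under IBD, so its
evidence would be infinite; since in practice it frequently reflects a
genotyping artefact (e.g. apparent homozygosity from a hemizygous
deletion), its evidence is capped at a constant $\gamma$ by emitting
$2^{-\gamma}$ times the NO-IBD probability. Each emission column sums to
one over observations ($(p+q)^4$ and $(p+q)^3$ expansions) before the
$\gamma$ adjustment; after it the IBD column exceeds one by
$2p^2q^2 2^{-\gamma}$, an accepted and deliberate weighting rather than a
probability model of the error process.

**Phased-genotype emissions (5 states).** With ordered calls — `AB` puts
allele A on the arbitrary-but-consistent "left" autosome — the hidden
state refines IBD into `LL`, `LR`, `RL`, `RR`: which autosome of sample 1
shares with which autosome of sample 2. Each of the 16 ordered observation
pairs has probability (shared allele) × (two free alleles) under the
matching states and 0 under states contradicted by the phase; e.g.
`(AB, AB)` emits $pq^2$ under `LL` (shared A on both left autosomes),
$p^2q$ under `RR`, and 0 under `LR`/`RL`. Every column again sums to one.

**Haplotype emissions.** When actual haploid sequences are compared, the
two-state model emits $p^2 / 2pq / q^2$ under NO IBD and $p / 0 / q$ under
IBD. Its per-locus evidence under IBD averages $\log_2 p$-scale values
around $-1$ bit at $p=1/2$, versus $-1/4$ bit for the genotype model:
`sigma_omega_moments()` computes these means and variances exactly by
summation over the emission tables, quantifying how much more detection
power haplotypes carry (the mean-to-sd ratio of the evidence collected
against a false IBD call is several times more negative for the haplotype
model).

```{r moments}
sigma_omega_moments(0.5, gamma = 8)[, c("variable", "condition", "mean", "sd")]
```

## Transitions and the switch mechanism

Both chains are symmetric with transition probability
$\varepsilon = 2^{-\delta}$ between NO IBD and IBD (split as
$\varepsilon/4$ towards each of the four phased IBD states, and
$\varepsilon$ back). We deliberately read $\delta$ as a *cost*, not an
estimate of relatedness: raising it demands longer runs of compatible
evidence, suppressing false positives at the price of missing short
segments. The minimum detectable segment length grows roughly linearly in
$\delta$. Note that raising $\delta$ does not shrink the decoded locus set
pointwise — strong segments *extend* at their flanks because leaving the
IBD state becomes costlier, while short segments vanish; the per-pair
tests assert exactly this behaviour.

The phased model's key device is heterozygosity-triggered switching.
Between locus $t$ and $t+1$ the within-IBD transition matrix is chosen by
which samples are heterozygous at the *next* observation: sample 1
heterozygous allows `LL`↔`RL` and `LR`↔`RR` with weight $\lambda$; sample
2 allows `LL`↔`LR` and `RL`↔`RR` with weight $\mu$; both heterozygous,
the two switches act independently (double switch $\lambda\mu$, single
switches $\lambda(1-\mu)$, $(1-\lambda)\mu$). Homozygous loci permit no
switch — the phase of a homozygote carries no information, so an
"incorrect" phase there is meaningless. The chain is therefore
time-inhomogeneous, with four templates selected per locus.

Two limits pin the construction down. At $\lambda=\mu=0$ no switching is
allowed: with correct phase the model behaves like the haplotype model run
on the shared pair of autosomes (up to the $\varepsilon/4$ entry split).
At $\lambda=\mu=1/2$ the phase is treated as a fair coin and the summed
IBD posterior coincides *exactly* with the genotype model's posterior on
the collapsed genotypes, for any phase configuration. `theorem1_check()`
verifies this equivalence empirically; the test suite holds it below
$10^{-9}$ across hundreds of random panels and re-phasings, which is also
the strongest available check that the transition construction is right.

**Discount modes.** The $\gamma$ cap extends to the phased model in three
selectable ways (`gamma_discount` in `hmm_params()`): `"all"` (default)
discounts every structurally-zero IBD cell, including the phase-only
zeros such as `(AB, AB)` under `LR`, which is the robust choice for
detection on imperfect phase; `"incompat"` discounts only the
genotype-incompatible rows `(AA, BB)`/`(BB, AA)`. The distinction matters
for the equivalence above: discounting phase-only zeros perturbs the
phased/genotype likelihood ratio by order $2^{-\gamma}$, so the
$\lambda=\mu=1/2$ equivalence is exact only under `"incompat"` (both
models' incompatible cells then scale identically), and
`theorem1_check()` uses that mode. `"none"` reproduces the literal
emission table.

**Initial distributions.** The genotype chain starts from $(1/2, 1/2)$
and the phased chain from $(1/2, 1/8, 1/8, 1/8, 1/8)$ — the projection
compatible with the equivalence limit. Both are configurable; results on
panels of realistic length are insensitive to them.

## Decoding

Scaled forward–backward recursions (per-locus normalisation constants,
implemented in C++; the per-locus scaling is the standard alternative to
log-space and keeps the posterior exact to machine precision) yield
per-locus state posteriors. A locus is IBD when its posterior IBD
probability — for the phased model the sum over the four IBD states —
*strictly* exceeds $1/2$; exact ties decode as NOT IBD. Maximal runs form
half-open, 0-based segments; a phased segment is labelled by the majority
per-locus argmax among `LL`/`LR`/`RL`/`RR` (ties broken in that fixed
order). Missing observations and masked loci (monomorphic or without a
valid frequency) emit probability one in every state: they are simply
uninformative, never evidence. This treatment of missingness is a package
choice; so is masking rather than clamping monomorphic frequencies, which
avoids $\log 0$ without inventing pseudo-counts.

The forward–backward implementation is verified against exhaustive
enumeration over all hidden-state paths on short panels (both models,
agreement to $10^{-10}$), and posterior rows sum to one within $10^{-12}$.

## Phase inference from IBD segments

Within a detected segment, consider the target sample's heterozygous loci
$t_1 < \dots < t_m$ and the subsequence at which the source sample is
homozygous. Consecutive pairs in that subsequence are *links*: the shared
haplotype must carry the source's homozygous allele at both loci, so equal
source alleles force the target's heterozygous alleles onto the same
autosome, different alleles onto opposite autosomes. Each segment
contributes its links twice, once per role assignment. Links accumulate as
$\pm 1$ votes in a sparse matrix $L$ over het-locus ordinals (conflicting
votes cancel), and with phase bits $y_i \in \{0, 1\}$ (0 = `AB`) the
objective

$$\sum_{(i,j):\,L(i,j)\neq 0} L(i,j)\,(+1 \text{ if } y_i = y_j
  \text{ else } -1)$$

counts satisfied minus unsatisfied links. Some links are unsatisfiable in
any configuration — genotype errors, false-positive segments,
recombination inside a segment, double sharing on both homologous pairs
(typical for siblings) — so the objective is maximised, never solved. The
increment rule (equal source alleles → $+1$) is the unique
phase-independent convention under which the objective has this
satisfied-minus-unsatisfied reading; a configuration that requires the IBD
pattern to switch autosomes between the linked loci scores $-1$ there.

The search works on relative coefficients $z_i = y_i \oplus y_{i+1}$,
because links overwhelmingly join nearby heterozygous loci and a global
autosome flip is unobservable (the objective is invariant under it). For
every window position, all $2^s$ flip patterns that include the window's
first coefficient are evaluated against the bookkeeping vector of current
per-link signs; a pattern is accepted only on *strict* improvement
(equal-gain patterns keep the current configuration, which guarantees
termination without cycling), and sweeps repeat until none fires. The
default window $s = 4$ balances cost ($2^s$ patterns per position) against
reach; on chain-structured instances any $s \ge 1$ is exact, and on random
general instances with $m = 12$ the search matches the exhaustive
$2^{m-1}$ optimum in nearly all cases (the suite requires $\ge 95\%$ of
the optimum on average). `brute_force_phase()` is retained as the test
oracle.

## The simulator and what it stands for

`simulate_family()` emulates genotype data from a large interbred family:

1. **Stage 1** — a pool of $2N$ haplotypes (default 800) evolves for $T$
   (default 10) Wright–Fisher generations: each offspring haplotype
   recombines two uniformly chosen parents with a Poisson($L/100$)
   crossover count placed uniformly in genetic distance (Haldane model, no
   interference), random mating with replacement including selfing.
2. **Stage 2** — $2n$ haplotypes are sampled as *family founders*, each
   its own ancestry source, and evolve as a closed population for $t$
   (default 4) generations; the final haplotypes pair into $n$ diploid
   samples.

Founder haplotypes are synthetic: allele frequencies drawn uniformly from
$[0.05, 0.95]$, alleles independent across loci (an optional Markov
copying knob, `ld_copy`, induces block LD when realism demands it; it is
off by default and off in all tests). SNP density defaults to 30 per cM,
the order of a genome-wide 100k array. Per-locus founder ancestry defines
ground truth: a locus is truth-IBD for a pair when haplotypes of both
samples descend from the same stage-2 founder there. Sharing *between*
founders themselves (created by stage 1) is deliberately not counted —
which is also why detectors legitimately report false positives above
what the truth labels concede.

What the simulator does **not** reproduce: real LD structure and allele
frequency spectra, genotyping error, missingness patterns, mutation, gene
conversion, sex-specific maps, interference. Tests that pass on these
panels therefore establish the *mechanics* and the *direction* of the
claims (phase information lowers false negatives; phasing from IBD beats
an uninformed baseline; sharing dilutes with family size) — not
field-calibrated error rates on array data.

## Evaluation metrics

`switch_error_rate()` compares relative phase between consecutive
heterozygous loci only (homozygous and missing loci carry no phase) and is
invariant to relabelling either sample's autosomes; the canonical 6-locus
example with one wrong relative phase out of three comparisons scores
exactly 33%. `ibd_accuracy()` pools over pairs and loci —
false-negative and false-positive counts are both expressed relative to
the total truth-IBD count, so FP% can exceed 100% when truth sharing is
scarce. Pooling by locus counts (not averaging per pair) is the package's
reading of "relative to total shared loci"; per-pair tables can be built
from `truth_ibd()` directly if wanted.

## The iteration loop

`run_pipeline()` seeds segments with the genotype model (or the
equivalent $\lambda=\mu=1/2$ phased model), then alternates: collect
links → sliding-window phase update per sample → phased-model detection
with per-iteration $(\delta, \lambda, \mu)$ schedules. Convergence is
declared when no phase bit changes between iterations — an exact integer
comparison, safe where floating-point criteria are not. The phase
objective never decreases within an update step; the detected IBD
fraction typically rises across iterations as the recovered phase exposes
segments below the genotype model's detection threshold. All-pairs
computation is quadratic in sample count by design; no sub-quadratic
indexing is attempted.

## Problem sizes and parameter defaults used in the tests

The suite exercises panels of 40–300 SNPs and families of 5–200 samples;
the directional accuracy experiments use $n \in \{50, 100\}$ at
$L \in \{2, 10\}$ cM (so 60–300 SNPs at the default density) with
$\delta = 20$, $\gamma = 8$ — a transition cost proportionate to panels
of a few hundred loci, chosen via the $\delta$–segment-length relation.
The iteration-loop experiment keeps $\delta = 40$, $\gamma = 8$,
$\lambda = \mu = 1/4$, the parameterisation appropriate to the
highly-inbred-family regime the loop targets. Default family depth
$t = 4$ and stage-1 depth $T = 10$ are fixed once as realistic for a
large interbred family; none of these values are fitted quantities.

## Limitations

- Linkage equilibrium between loci is assumed given the hidden state;
  on real dense arrays LD inflates evidence and the effective $\delta$
  needed.
- Only one shared pair of autosomes is modelled: the 3-, 9- and 15-state
  refinements for double sharing (relevant for siblings and selfing) are
  out of scope, and double sharing instead surfaces as unsatisfiable
  links.
- Allele frequencies are treated as known; estimating them from a small
  related panel biases them towards the family's founders.
- Genotyping error enters only through the $\gamma$ cap, not as an
  explicit error model.
- The phase updater is a local search; it inherits MAX-2-SAT hardness and
  offers no approximation guarantee, only the empirical near-optimality
  the tests document.
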