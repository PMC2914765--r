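# ibdphase

Pairwise identity-by-descent (IBD) detection from SNP genotypes, with
phase-aware refinement and IBD-driven haplotype phasing.

## The problem

In family-based genetic studies — large pedigrees with uncertain structure,
isolated populations, inbred families — mapping a phenotype means finding
the chromosome segments that affected relatives share *identical by
descent*: identical because they were inherited from a recent common
ancestor, not merely identical in state. With dense biallelic SNP panels,
IBD segments reveal themselves as long stretches free of *incompatible*
loci (one sample `AA`, the other `BB`) whose allele frequencies make chance
sharing unlikely. Haplotype (phased) data makes much shorter segments
detectable, but phase estimates are never fully accurate, and a single
phase switch error can cut a true segment in two. `ibdphase` implements a
detection model that exploits phase information exactly to the degree it
deserves to be trusted, plus the converse operation: using detected IBD
segments to infer the phase itself. Alternating the two recovers IBD that
genotype data alone cannot.

## The models

**Genotype HMM.** A two-state chain (`NO IBD`, `IBD`) along the loci of a
sample pair. Emissions depend on the frequency *p* of allele A (*q* = 1 −
*p*): e.g. the unordered pair {AA, AB} emits 4*p*³*q* under NO IBD and
2*p*²*q* under IBD; the incompatible pair {AA, BB} emits 2*p*²*q*² under NO
IBD and is impossible under IBD. To stay robust to genotyping error the
incompatible observation is discounted to 2^−γ times its NO-IBD
probability, capping its log-evidence against IBD at γ bits. Transitions
are symmetric with probability ε = 2^−δ; δ acts as a *cost*, and the
minimum detectable segment length grows roughly linearly with it. Posterior
state probabilities come from exact scaled forward–backward decoding, and a
locus is called IBD when its posterior exceeds 1/2.

**Phased-genotype HMM.** Five states: `NO` plus `LL`, `LR`, `RL`, `RR`,
recording which autosome ("left"/"right") of each sample carries the shared
haplotype. Ordered emissions distinguish `AB` (allele A on the left
autosome) from `BA`. Whenever the *next* observation is heterozygous for
sample 1, the shared segment may switch autosomes in sample 1 (`LL`↔`RL`,
`LR`↔`RR`) with weight λ; heterozygous for sample 2, switch with weight μ;
both, the switches act independently. λ = μ = 0 trusts the phase
completely; λ = μ = 1/2 treats it as noise, and the model then reproduces
the genotype HMM exactly (a property the test suite verifies to 1e−9).
Intermediate values (the default is 1/4) exploit imperfect phase while
remaining robust to its errors.

**Phase from IBD.** Inside a detected segment, two consecutive
heterozygous loci of a *target* sample at which the *source* sample is
homozygous are *linked*: if the source is homozygous for the same allele at
both, the target's heterozygous alleles must lie on the same autosome;
different alleles, opposite autosomes. Each link casts a ±1 vote in a
sparse matrix `L`, and the phase vector *y* (one bit per heterozygous
locus) is chosen to maximise

    sum over links of L(i, j) * (+1 if y_i = y_j else -1)

— satisfied minus unsatisfied links, a special MAX 2-SAT instance. The
optimiser works on relative phase coefficients *z_i* = *y_i* ⊕ *y_{i+1}*
with a sliding-window local search that tests all flip patterns within a
window and accepts strict improvements until a full sweep changes nothing.

**Evaluation and simulation.** A two-stage Wright–Fisher simulator (large
population, then a sampled family evolved for a few more generations)
tracks founder ancestry per locus, giving ground-truth pairwise IBD.
Metrics are the switch error rate (share of consecutive-heterozygous-locus
pairs with wrong relative phase) and pooled false-negative/false-positive
IBD percentages relative to total truth IBD.

## Worked example

```r
library(ibdphase)

sim <- simulate_family(sim_config(n = 20, L = 10), seed = 1)
#> <family_sim> n=20 samples, s=300 loci, L=10 cM, t=4 family generations

params <- hmm_params(delta = 20, gamma = 8, lam = 0.25, mu = 0.25)
pl <- run_pipeline(sim$genotypes, params, iterations = 3)
tidy(pl)
#>   iteration    model n_segments mean_ibd_fraction total_objective phase_changes
#> 1         0 genotype         59         0.2834386              NA            NA
#> 2         1   phased         84         0.3957193            3666           810
#> 3         2   phased         88         0.4080702            6216            58
#> 4         3   phased         88         0.4080702            6508             0
```

Iteration 0 detects IBD from genotypes alone (28.3% of pair–locus
combinations). Each iteration then phases every sample from the current
segments (the link objective climbs from 3666 to 6508 as phase errors are
ironed out) and re-detects with the phased model, which finds the shorter
segments the genotype model missed — the mean IBD fraction rises to 40.8%
and the loop converges when no phase bit changes.

Against the simulator's ground truth:

```r
switch_error_rate(sim$haplotypes, pl$phased, pooled = TRUE)
#>   n_het_pairs n_incorrect     rate
#> 1        1602         131 8.177278

tm  <- truth_ibd_matrix(sim)
ids <- samples(sim$haplotypes); prs <- attr(tm, "pairs")
ibd_accuracy(tm, segments_to_loci(pl$segments, n_loci(sim$genotypes),
                                  cbind(ids[prs[, 1]], ids[prs[, 2]])))
#>   n_truth n_detected   fn_pct   fp_pct
#> 1   22717      23260 1.558304 3.948585
```

8.2% of relative phases wrong (against a ~50% uninformed baseline) and
98.4% of truth-IBD loci recovered. Single pairs can be inspected with
`pair_posterior()` / `decode_segments()` / `autoplot()`, and panels
exchanged as phased VCF (`read_vcf()`, `write_vcf()`) or a plain tabular
format. A command-line wrapper with `simulate`, `detect`, `phase`,
`iterate` and `evaluate` subcommands is installed under `exec/`.

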