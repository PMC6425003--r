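---
title: "Methods: f-statistics, admixture modeling and the synthetic validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: f-statistics, admixture modeling and the synthetic validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixfit)
```

## Scope and data model

`admixfit` infers population relationships from biallelic SNP allele
frequencies, the regime of ancient-DNA studies where each individual
contributes a low-coverage pseudo-haploid genotype (one sampled allele
per site, coded as a homozygous 0/2 call). The central container,
`genotype_dataset`, stores alt-allele counts with SNP and individual
metadata. Two conventions matter:

* **EIGENSTRAT coding.** The text EIGENSTRAT geno digit counts copies
  of the *reference* allele; internally we store *alt*-allele counts
  (`g = 2 − digit`). One unambiguous internal convention prevents sign
  errors in f-statistics; the mapping is applied symmetrically at the
  I/O boundary so read/write is the identity.
* **Pseudo-haploid allele counting.** A pseudo-haploid genotype is one
  sampled allele despite its 0/2 coding, so it contributes one
  observation to the allele count (a diploid contributes two).
  Double-counting would understate the variance of small-sample
  frequencies.

Merging intersects SNPs on (chromosome, position), flips genotypes when
the allele pair is swapped, and drops (never fails on) incompatible
allele pairs, logging them for audit. Strand-ambiguous A/T and C/G
SNPs are kept by default — they are only a hazard when strands can
differ between sources, which the caller can assert with
`drop_strand_ambiguous = TRUE`.

## f-statistics and the block jackknife

For per-site frequencies the package computes

* `f2 = mean (a − b)^2`, `f3(t; a, b) = mean (t − a)(t − b)`,
  `f4(a, b; c, d) = mean (a − b)(c − d)`, and
* `D = Σ (w − x)(y − z) / Σ (w + x − 2wx)(y + z − 2yz)`,

each over its own complete-case SNP set (sites with at least one
observed allele in every population of that statistic, not a global
intersection — this matches how per-statistic overlap counts are
reported in practice). Frequencies are plain sample frequencies: D and
f4 are unbiased under within-population sampling noise because the
noise terms of disjoint population pairs are independent; f2/f3 would
need a heterozygosity correction to be unbiased, which we deliberately
do not apply silently (the uncorrected forms are used as diagnostics
and covariance building blocks only).

Standard errors come from the **weighted delete-one-block jackknife**.
SNPs are grouped greedily into blocks spanning at most 0.05 morgans
(the convention of the reference tools), with a 5 Mb physical fallback
when the genetic map is absent or degenerate; blocks never cross
chromosome boundaries. With block weights $m_j$ (usable SNP counts),
$n = \sum m_j$, $h_j = n/m_j$, whole-data ratio $\hat\theta$ and
leave-one-out ratios $\theta_{(-j)}$,

$$\hat\sigma^2 = \frac{1}{g}\sum_j \frac{(\tau_j - \theta_J)^2}{h_j-1},
\qquad \tau_j = h_j\hat\theta - (h_j - 1)\theta_{(-j)},$$

with $\theta_J = g\hat\theta - \sum_j (1 - m_j/n)\theta_{(-j)}$. Under
equal weights this reduces exactly to the textbook unweighted delete-1
jackknife, which the tests assert to 1e-12. The point estimate is
always the whole-data ratio. A statistic whose denominator sums to
zero (no shared polymorphism) is an error, not a 0/0. Statistics based
on ≤ 30,000 usable SNPs carry a soft `below_threshold` flag rather
than being suppressed, so the library still returns values for
inspection while reports can apply the conventional filter.

Whether to restrict to transversions is left to the caller (subset the
dataset first); all sites are used by default.

## Permutation nulls

Two individual-label permutation schemes validate D statistics for
small groups: exhaustive leave-one (each first-group individual takes
the single second-position individual's place in turn, with a variant
excluding that anchor entirely to probe within-group variation), and
random re-splits of the pooled individuals preserving group sizes
(drawn without replacement within a permutation; repeats across
permutations are allowed, keeping the null exact). The empirical
P-value is identity-inclusive,

$$P = \frac{1 + \#\{D_{perm} \ge D_{obs}\}}{n_{perm} + 1},$$

counting the observed statistic as one permutation in both numerator
and denominator: with 1000 random permutations the denominator is
1001, P is never zero, and ties count toward significance ("equal to
or greater"). The convention is recorded in the result object.

## qpWave rank test and qpAdm weights

The f4 matrix $X_{ij} = f4(l_1, l_{i+1}; r_1, r_{j+1})$ is computed,
by default, on the single SNP set usable in *all* left and right
populations — the conservative classic behaviour of the reference
tools (an all-available per-cell mode exists but is off by default).
Its vectorized jackknife covariance $Q$ uses the same weighted scheme
as the scalar statistics; the tests check that its diagonal matches
the per-statistic jackknife variances.

The rank-r test minimizes $(\mathrm{vec}(X - AB))' Q^{-1}
(\mathrm{vec}(X - AB))$ over factorizations $A B$ by alternating
generalized least squares (each half-step is a linear GLS via a
Kronecker design; convergence tolerance 1e-10 relative, max 2000
iterations, SVD initialization, error with diagnostics on
non-convergence). The statistic is chi-square with
$(n_l - 1 - r)(n_r - 1 - r)$ dof. When $Q$ is numerically singular —
routine with tiny panels or duplicated populations — a ridge of
$10^{-5} \times$ mean diagonal is added with a warning rather than
failing silently.

A k-source qpAdm fit sets left = (target, sources…) and fits rank
k − 1. Under the admixture model the weight vector annihilates the
fitted matrix from the left, so the weights are the left null vector
of the fitted matrix rescaled to sum to one; infeasible weights
(outside [0, 1]) are reported with a flag, never clipped. Weight SEs
re-estimate the whole weight vector on every delete-one-block
replicate (full jackknife rather than linearization — more robust and
consistent with the jackknife-everywhere architecture; the full-data
factorization warm-starts each replicate). The base populations
(left 1 = target, right 1 = first outgroup) are fixed and documented;
the rank-test chi-square is checked invariant to reordering the
remaining right populations. With one source the fit degenerates to
the rank-0 cladality test of (target, source) against the outgroups.

**Basal Eurasian α.** No unadmixed Basal Eurasian proxy exists, so α
is estimated indirectly: a two-source fit of the target from a deeply
diverging African proxy plus a non-basal source, against outgroups
that are all crown Eurasians (eastern non-Africans and Upper
Paleolithic genomes), none African, none carrying basal ancestry.
Both the proxy and the basal lineage branch off before every such
outgroup, so the proxy weight identifies the basal fraction.
`compose_alpha()` multiplies a source proportion by the α within that
source and propagates the SE by the first-order delta method assuming
independence — a documented simplification justified by the two
estimates coming from different fits.

## PCA projection

`fit_pca()` uses the reference normalization: center by the mean
genotype, scale by $\sqrt{\hat p(1 - \hat p)}$ with
$\hat p = \text{mean}/2$, drop monomorphic SNPs, mean-impute residual
missingness in the fitting panel, and eigendecompose. `lsq_project()`
solves the least-squares fit of a sample's normalized non-missing
genotypes onto the loadings restricted to those SNPs; complete-data
panel members project exactly onto their own scores. No shrinkage
correction for projection bias is applied (a documented limitation of
plain least-squares projection).

## The synthetic-data generator

Frequencies evolve on an explicit admixture graph under
**Balding–Nichols drift**: along an edge with parameter F the child
frequency is Beta with mean p and variance p(1 − p)F; admixture nodes
mix their parents per SNP. We simulate frequencies rather than
coalescent genealogies because frequencies are the sufficient
statistics for every estimator in the package — orders of magnitude
faster, with exactly testable moments. Root frequencies are uniform on
(0.05, 0.95), truncated away from fixation so small-F edges stay
informative. Genotypes are Binomial(2, p); pseudo-haploid individuals
then have one allele of the pair drawn at random and coded 0/2;
missingness is Bernoulli with P(missing) = exp(−coverage), the zero
class of a Poisson read-count model. The synthetic map spreads SNPs
evenly over 22 chromosomes of 0.5 morgans each (1 cM/Mb), giving ~220
jackknife blocks at the default block size — enough resolution for
stable variance estimation at desk scale.

What the generator does *not* emulate: linkage disequilibrium within
blocks, ascertainment of the capture panel, reference bias, residual
DNA damage, and contamination. Passing tests therefore demonstrate the
correctness and calibration of the estimators under the drift model,
not robustness to those real-data artifacts.

### Shipped scenarios

`sim_scenario()` encodes the admixture-model ledger as generative
graphs with the published point estimates as true proportions: AAF =
0.897 AHG + 0.103 Iran_N; ACF = 0.787 AAF + 0.213 Levant_N; Iron
Gates = 0.258 AHG + 0.629 WHG + 0.113 EHG (two chained two-parent
events whose proportions compose exactly); and a Basal Eurasian graph
with α = 0.248 (AHG) and 0.385 (Natufian), where the basal branch
diverges from the Eurasian stem before all crown outgroups and the
African proxy before that — the geometry that makes the proxy-based
estimator exact in expectation. Sample sizes mirror the study design
(1 AHG, 5 AAF, 25 ACF; pseudo-haploid ancients with coverages in the
0.16–2.9× regime; diploid complete moderns). Drift parameters were
chosen once for realism — ~0.15 for the African/non-African split,
0.03–0.06 for deep Eurasian structure and long terminal ancient
branches, ≤ 0.01 between each source and the true mixing parent — and
give outgroup sets that genuinely distinguish the sources (the qpWave
prerequisite). With only 1e5 independent SNPs and single-individual
source populations the scenario standard errors (5–15%) are larger
than published ones, as expected at desk scale; what the tests check
is calibration (estimates within 3 SE of truth in ≥95% of replicates)
and the absence of material bias, not the published precision.

## Numerical and design choices

* Degenerate inputs: zero usable SNPs, all-missing populations,
  non-distinguishing outgroups (degenerate null space) and unknown
  labels are errors with named messages; below-threshold SNP counts
  and infeasible weights are flags.
* The sex-typing thresholds (y-rate ≥ 0.3 with x-rate ≤ 0.8 for male;
  y-rate ≤ 0.1 with x-rate ≥ 0.8 for female) are configurable package
  defaults in line with shotgun practice; the contract is the
  normalized ratio computation. Relatedness is screened against the
  within-group mismatch distribution (z-scores), not an absolute
  cutoff.
* Pileup bases matching neither allele at a site are emitted as
  missing; upstream tools' behaviour for that case is not documented,
  and missing is the conservative choice.
* The orchestration layer (`run_analysis()`) derives one sub-seed per
  stage from the single mandatory seed via a stable string hash, so
  stages are independently reproducible and a rerun with the same
  config and seed is byte-identical. No multiple-testing correction is
  applied across D-statistic batches (raw Z and empirical P are the
  convention being reproduced); the run log says so.
* Problem sizes in the test suite — 1e4-SNP oracle comparisons, 1e5-SNP
  scenario recoveries with 100 replicates, 200-replicate calibration
  checks with 99 permutations — were chosen as the smallest scales at
  which the stochastic acceptance bands are statistically meaningful.

## Known limitations

Weight SEs assume the fixed-Q approximation across jackknife
replicates (Q is not re-estimated per replicate). `compose_alpha`
assumes independence of its two inputs. The rank-test chi-square
relies on the asymptotic normality of f4 cells, which degrades below a
few dozen blocks. The simulator's independent-SNP assumption makes
jackknife blocks exchangeable, so block-level variance estimation is
mildly conservative relative to LD-correlated real data.
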