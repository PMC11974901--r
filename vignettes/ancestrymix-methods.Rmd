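---
title: "Models and methods in ancestrymix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ancestrymix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ancestrymix infers the ancestry composition of individuals whose genotypes
come from sparse, error-prone call sets — typically SNPs recovered from
scRNA-seq reads — against a labelled reference panel, and quantifies how
trustworthy that inference is under a given panel size, missingness, and
genotype-error rate. This vignette records the models, the parameter
choices and why they were made, what the synthetic data generator does and
does not emulate, and the numerical decisions that make results exactly
reproducible.

## The admixture model

An individual $i$ has ancestry proportions $q_{i\cdot}$ on the $K$-simplex
over predefined ancestry groups; group $k$ has ALT-allele frequency
$f_{kj}$ at SNP $j$. Each of the two allele copies at a SNP independently
originates from group $k$ with probability $q_{ik}$ and is then ALT with
probability $f_{kj}$, so a dosage $g_{ij} \in \{0,1,2\}$ is
$\mathrm{Binomial}(2, \sum_k q_{ik} f_{kj})$ and the log-likelihood is

$$\ell = \sum_{ij}\left[ g_{ij}\,\log\!\Big(\sum_k q_{ik} f_{kj}\Big)
 + (2 - g_{ij})\,\log\!\Big(\sum_k q_{ik} (1 - f_{kj})\Big)\right],$$

with missing dosages contributing nothing. The assumptions are the usual
ones: Hardy–Weinberg equilibrium within ancestral groups, independent SNPs
(hence the LD pruning upstream), and genotypes observed without error —
the last assumption matters and is revisited under *Limitations*.

**Supervised fitting.** `fit_supervised_admixture()` freezes every
reference individual's $q$ to the one-hot vector of its labelled group and
starts queries at $1/K$. Ancestral frequencies start at the observed group
frequencies, clamped to $[10^{-6}, 1-10^{-6}]$ so that a discordant
genotype cannot produce $\log 0$. By default $F$ is informed by the
reference rows only; because the reference labels are one-hot, the observed
group frequencies are a fixed point of the $F$ update, so $F$ stays put and
only query proportions move. This is the stable choice when queries are few
and error-prone. `update_F_with_queries = TRUE` instead re-estimates $F$
jointly from reference and query rows each step, the behaviour of classical
supervised admixture software; with tens of queries against hundreds of
reference samples the two give nearly identical answers.

**EM and acceleration.** `em_step()` implements the plain EM update:
allele-copy responsibilities proportional to $q_{ik} f_{kj}$ (ALT) and
$q_{ik}(1-f_{kj})$ (REF), $q$ re-estimated as the mean attribution over the
$2M_i$ observed copies, $f$ as the attributed ALT fraction; both updates
use the same responsibilities, so $\ell$ never decreases. Plain EM,
however, converges sublinearly when components of $q$ approach the simplex
boundary — precisely the common case of a nearly unadmixed query — and can
need tens of thousands of iterations to move $|\Delta\ell|$ below a tight
tolerance. The compiled fitting loop therefore wraps the plain update in a
monotonicity-guarded squared extrapolation (SQUAREM-style): each cycle
takes two EM steps, extrapolates, and falls back to the plain double step
whenever the extrapolated point is infeasible or would lower the
likelihood. Two details matter:

* the extrapolated point is projected to the simplex, but never by clipping
  a positive proportion to zero — an exact zero is absorbing under the
  multiplicative EM update and can trap a query at a wrong boundary
  stationary point. The step instead backtracks toward the plain EM step
  until all proportions stay positive;
* the recorded `loglik_trace` holds the likelihood at the start of every
  cycle and is non-decreasing by construction, so the plain-EM monotonicity
  contract survives the acceleration. Stationary points are those of the
  likelihood either way, which the tests verify against an independent
  quasi-Newton maximization.

Convergence is declared when $|\Delta\ell| < 10^{-6}$ (default `tol`)
between cycles, capped at `max_iter = 2000`; at the package's study scales
fits converge in 10–30 cycles.

## PCA projection and the two geometric classifiers

`fit_reference_pca()` standardizes reference dosages SNP-wise by
$\mathrm{mean} = 2\hat p$ and $\mathrm{scale} = \sqrt{2\hat p(1-\hat p)}$
(unit variance under HWE — the package's choice of the standard
population-structure scaling), mean-imputes missing cells (standardized 0),
excludes monomorphic SNPs, and takes the top right-singular vectors as SNP
loadings; five components by default, the depth at which continental-scale
structure is normally captured. Queries are projected by least squares onto
the loadings with the *reference* means and scales; SNPs absent from a
query count as missing, which shrinks scores toward the origin rather than
inventing genotypes. No projection-bias (shrinkage) correction is applied.
A fixed sign convention — the largest-magnitude loading entry of each
component is positive — plus deterministic tie-breaks make the model
invariant to sample order.

`centroid_classify()` assigns each query to the ancestry group whose
reference-score centroid is nearest in Euclidean distance over all
components; the reported per-group values are normalized inverse distances,
a ranking device for a uniform output shape, *not* probabilities.
`rf_classify()` trains a 100-tree random forest on the labelled reference
scores (fixed seed, probabilities by tree-vote averaging). Everywhere,
assignment is the argmax with exact ties broken lexicographically by group
label — determinism is worth more than any pretence of randomized
fairness.

## QC and LD pruning

Filters follow strict inequalities: SNPs are kept when their **reference
panel** MAF exceeds 0.05 (a query set is never allowed to define
commonness), SNPs with missingness above 10% are removed first, then
samples above 10% over the remaining SNPs. A SNP or sample at exactly the
threshold survives.

Pruning thins each chromosome so that no pair of retained SNPs within 50
consecutive retained SNPs has squared dosage correlation above 0.1
(`prune_params()`: window 50 SNPs, step 10, r² 0.1 — the common
`--indep-pairwise 50 10 0.1` setting). r² is the squared Pearson
correlation of unstandardized dosages over pairwise-complete entries,
defined as 0 for constant vectors or fewer than two complete pairs. The
removal rule is fully deterministic: windows slide by the step over the
retained sequence and are cleaned greedily — worst pair first; of the pair,
the SNP with the smaller reference MAF is removed, ties broken by the
larger position. Because removals create new adjacencies across window
boundaries, passes repeat to a fixed point, and a final sweep over every
window offset removes any residual violating pair by the same rule; the
post-condition is then exact rather than approximate, which is what the
property tests assert. The procedure is idempotent. One practical caveat:
with small reference panels (tens of samples) the null sampling
distribution of r² routinely exceeds 0.1, so pruning legitimately discards
much of the panel; the evaluation design keeps per-fold references in the
hundreds for this reason.

## The synthetic data generator

`make_scenario()` is the stand-in for a harmonized global reference panel
plus scRNA-seq-genotyped donors. It draws ancestral frequencies uniformly
on $[0.05, 0.95]$ (mirroring a common-SNP panel), group frequencies by the
Balding–Nichols model $f_{kj} \sim \mathrm{Beta}(p_j(1-F)/F,
(1-p_j)(1-F)/F)$ at $F_{\mathrm{ST}} = 0.1$ between groups, and a second
nested Balding–Nichols layer at $F_{\mathrm{ST}} = 0.01$ for populations
within groups — the continental vs within-continental differentiation
scale of human panels, and the structure needed for
leave-one-population-out evaluation with intact same-group populations.
Genotypes are HWE binomial draws; admixed queries draw each allele copy's
population of origin from $q$, exactly the likelihood's generative process.

Default study conditions: 6 ancestry groups × 3 populations × 20 samples
(360 individuals), 3,000 SNPs — the scale of common SNPs recoverable from
scRNA-seq reads — with 5% per-cell missingness. The missingness default
sits deliberately *below* the 10% QC exclusion threshold: at a uniform 10%
cell rate, sampling noise would push half the SNPs over the per-SNP cutoff
and QC would discard half the panel, which is not what partially observed
real panels look like. Genotype errors replace a called genotype, with
probability `rate`, by one of the two *other* values of $\{0,1,2\}$
uniformly — so the injected rate equals the expected discordance against
the original calls, matching how the 8% scRNA-seq error figure is measured
against arrays; whether real errors hit heterozygous and homozygous calls
symmetrically is unknown, and this uniform choice is the package's stated
interpretation. All generators are pure functions of `(parameters, seed)`;
a single scenario seed is expanded into labelled sub-streams
(`derive_seed()`) so that, for example, changing the error rate of a sweep
cannot perturb the panel itself.

What the generator does **not** emulate: linkage disequilibrium between
SNPs (draws are independent, so pruning on synthetic panels mostly removes
structure-induced correlation), coalescent genealogy, read-level artefacts
of scRNA-seq variant calling (allelic expression imbalance, coverage-driven
non-random missingness), or error rates that depend on genotype class or
expression level. Passing tests therefore demonstrate correctness of the
estimators and the evaluation machinery under the stated statistical
model — not that real scRNA-seq call sets satisfy that model.

## Evaluation procedures

`leave_one_population_out()` removes one population at a time, rebuilds the
reference honestly on the remainder (MAF filter, missingness filter,
pruning, then PCA or group frequencies, all recomputed per fold — strict
leave-out, no leakage), classifies the held-out individuals, and tallies a
confusion matrix with per-group and overall error rates. Error injection in
the `sc_snps_error` condition touches only the held-out individuals'
genotypes, since that is where scRNA-seq-derived genotypes would sit.
Confidence intervals are 95% Wilson score intervals — chosen because the
interesting error rates are at or near zero, where Wald intervals collapse;
the $k=0$ and $k=n$ bounds are returned exactly as 0 and 1.
`error_rate_sweep()` reuses the folds and fold seeds so that only the error
injection varies across rates and rate 0 reproduces the error-free result
bit for bit. `within_group_inference()` asks the finer question of
separating populations inside one ancestry group; there the held-out unit
is the individual rather than the population (removing a whole population
would remove its class), a documented interpretation rather than a claim
about how such analyses must be done.

`admixture_recovery()` regresses estimated on gold-standard proportions by
OLS with intercept and reports the slope and Pearson r;
`gold_standard_selection()` implements the strictly-more-than-1/8 rule for
picking admixed individuals whose estimated minority ancestry is large
enough to serve as a gold standard. `simulate_admixture_recovery()`
packages the full synthetic recovery experiment: K = 3 groups at
$F_{\mathrm{ST}} = 0.1$, 5,000 SNPs, 100 reference samples per group, 50
queries with $q \sim \mathrm{Dirichlet}(1,1,1)$.

Problem sizes used by the test suite — 360-sample panels at 3,000 SNPs for
leave-one-population-out, the recovery design above, smaller panels for
unit tests — are the package's chosen desk-scale study conditions:
large enough that between-group signal dominates sampling noise, small
enough to iterate on.

## Numerical choices and degenerate inputs

* Frequencies clamped to $[10^{-6}, 1-10^{-6}]$; proportions non-negative,
  rows renormalized to sum to one at every update.
* A group with no non-missing call at a SNP takes the panel-wide frequency
  (with a warning); an SNP column with a zero EM denominator keeps its
  previous frequency.
* All-missing SNPs get `NA` MAF and are flagged; all-missing query rows
  keep their current proportions.
* Ties: argmax ties lexicographic by label; pruning ties by smaller MAF,
  then larger position, then larger column index; PCA signs by the
  largest-magnitude loading entry.
* Allele harmonization matches SNPs on `(chrom, pos)` — identifiers are not
  trusted across call sets — counts the ALT allele of the reference panel
  after reconciliation, flips swapped REF/ALT dosages as $g \to 2-g$, and
  drops A/T and C/G SNPs (strand-unresolvable) plus any allele pair that
  neither matches nor swaps.
* Empty results (all SNPs or samples filtered away, empty matrices on
  write) are errors, not silent empties.

## Limitations

* **Unmodelled genotype error attenuates admixture estimates.** The
  likelihood assumes error-free genotypes. Injecting 8% uniform genotype
  error attenuates the regression slope of estimated on true proportions to
  roughly 0.7 in the package's recovery experiment, even though assignment
  to the majority group and the correlation structure remain excellent
  (r ≈ 0.99). This is a property of the estimator class, not of the
  implementation: an oracle refit with an error-adjusted frequency matrix
  restores slopes near 1. Proportion estimates from error-prone panels
  should be read as systematically shrunk toward uniform, while *rankings*
  and classifications remain reliable at these error rates.
* Classification accuracy claims transfer to real data only to the extent
  that real reference panels are as differentiated as the Balding–Nichols
  conditions above and real errors resemble uniform substitution.
* PCA projection applies no shrinkage correction; query scores are mildly
  attenuated relative to reference scores, which the centroid classifier
  partly absorbs but does not remove.
* Estimated reference frequencies carry sampling noise (hundreds of
  chromosomes per group), which attenuates recovery slopes by a few percent
  relative to oracle frequencies.
* Only biallelic SNVs with hard-called diploid genotypes are supported; no
  dosage/phased input, no multiallelic sites.
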