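---
title: "Pleiotropy versus linkage: model, simulator, and mapping methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pleiotropy versus linkage: model, simulator, and mapping methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiolink)
```

## The question

Two quantitative traits can be genetically correlated either because single
loci affect both traits (pleiotropy) or because loci affecting different
traits are physically linked and held in linkage disequilibrium (LD) by
correlational selection. The two architectures are indistinguishable in
classical equilibrium theory under Gaussian assumptions, yet they differ in
one crucial respect: a pleiotropic locus changes both traits with a single
mutation (probability $\mu$ per copy per generation), whereas a linked pair
needs two mutations (probability $\mu^2$) to produce joint variation.
`pleiolink` provides an individual-based forward simulator, closed-form
equilibrium expectations, and a downstream association-mapping stage to
quantify when the two architectures diverge and how that affects the
detection of true and spurious pleiotropy in genome-wide association
analyses (GWAA).

## Model

**Traits and selection.** Two fully heritable additive traits
$z = (z_1, z_2)$ are the sums of allelic values over all loci affecting
each trait (no environmental effects, no dominance or epistasis). Viability
selection is Gaussian: an offspring survives with probability
$$w(z) = \exp\left(-\tfrac12 (z-\theta)^\top \Omega^{-1} (z-\theta)\right),
\qquad
\Omega = \omega^2 \begin{pmatrix} 1 & \rho_\omega \\ \rho_\omega & 1
\end{pmatrix},$$
where $\theta$ is the vector of local optima, $\omega^2$ the
stabilizing-selection variance (smaller = stronger selection) and
$\rho_\omega$ the correlational-selection coefficient favoring
combinations of trait values along the diagonal.

**Mutation.** A mutation has effect vector
$a(\cos\theta_m, \sin\theta_m)^\top$ with magnitude $a \sim N(0, \alpha^2)$.
At a pleiotropic locus the direction $\theta_m$ is free, giving a bivariate
Gaussian $N_2(0, \alpha^2 I)$ with no mutational correlation; at a
nonpleiotropic locus $\theta_m$ is pinned to a trait axis
($\{0, \pi\}$ or $\{\pi/2, 3\pi/2\}$), so the joint mutational input of a
linked pair is a cross-shaped axis mixture, with both components
simultaneously nonzero only at rate $\mu^2$. Effects add to the standing
allelic value (continuum of alleles); the biallelic QTN mode instead fixes
one magnitude per locus and lets mutation flip the allele's sign.

**Analytic expectations.** Under the Gaussian regime the per-locus
equilibrium covariance matrix $C$ solves $C\,\Omega^{-1} C = \mu\alpha^2 I$,
i.e. $C = \sqrt{\mu\alpha^2}\,\Omega^{1/2}$, giving
$$c = \sqrt{\left(1+\sqrt{1-\rho_\omega^2}\right)\frac{\omega^2\mu\alpha^2}{2}},
\qquad b = \frac{\rho_\omega\,\omega^2\mu\alpha^2}{2c}, \qquad
r = \frac{b}{c} = \frac{\rho_\omega}{1+\sqrt{1-\rho_\omega^2}},$$
implemented in `lande_equilibrium()`. The equilibrium correlation $r$ is
independent of $\mu$, $\alpha^2$, $\omega^2$ — the package's tests assert
this exactly. The house-of-cards single-locus G-matrix,
$G = 2\mu\, a a^\top / (a^\top \Omega^{-1} a)$, and its trigonometric
closed form are both implemented (`hoc_gmatrix()`) and must agree to
machine precision; for axis-bound directions its off-diagonal vanishes —
nonpleiotropic mutations generate no genetic covariance directly.
`classify_regime()` separates the Gaussian ($\mu \gg \alpha^2/\omega^2$)
and house-of-cards ($\mu \ll \alpha^2/\omega^2$) regimes with a
factor-of-10 margin on each side of $\mu = \alpha^2/\omega^2$; the margin
is a package choice, since only the asymptotic inequalities are defined.

## The simulator

`run_simulation()` evolves $N$ diploid hermaphrodites (default 5000) with
nonoverlapping generations for a configured number of generations (default
50,000), starting monomorphic with every phenotype exactly at the optimum.
Each new generation is built by rejection sampling: draw two parents
uniformly with replacement (selfing permitted, so the selfing rate is
$1/N$), form one recombined and mutated gamete per parent, and accept the
offspring with probability $w(z)$ until $N$ survivors are collected. This
soft-selection scheme keeps $N$ constant, matching the model's fixed
carrying capacity; the exact regulation scheme is a design choice since
fitness is defined as a juvenile survival probability. If the running mean
fitness over rejection attempts falls below $10^{-12}$ the engine aborts
with an error rather than looping forever.

**Recombination.** Map distances are in centiMorgans with Haldane's map
function (no interference): crossovers on a chromosome are a Poisson
process with rate (map length)/100, which reproduces the per-interval
Haldane fractions exactly and gives $r = 10^{-6}$ for the 0.0001 cM
marker spacing used in the mapping panels. Chromosomes assort
independently. In the linkage architectures the two members of a pair are
placed trait-1 locus first; by symmetry of the model the order is
immaterial.

**Migration.** Two-deme runs are unidirectional (island-mainland): with
probability $m$ both parents of a focal-deme offspring are drawn from the
source deme, which matches the backward-rate definition (expected fraction
of new individuals with source parentage) and is verified against the
realized migrant fraction. The source deme evolves concurrently under its
own regime. Both demes are burnt in independently before migration starts.
The source optimum sits 10 phenotypic units from the focal optimum along
the diagonal, $\theta_{src} = \theta_{focal} + (10/\sqrt2)(1,1)$; an
explicit `optima` argument supports any other placement, including a
literal $(50, 50)$.

**QTN initialization.** In biallelic mode each causal locus receives a
fixed magnitude per affected trait — drawn once as $|N(0,\alpha^2)|$, or
equal to $\sqrt{\alpha^2}$ with `qtn_equal_magnitudes` (the reference
design does not pin this down, so both are options) — and a random initial
sign shared by all copies. A non-evolving basal value absorbs the residual
$\theta_k - \sum \text{effects}$ so that selection pressure at generation
zero is nil, exactly as in the continuum mode.

**Implementation.** The per-generation loop (gamete formation, mutation,
viability selection) is in C++ (Rcpp) as is usual for forward simulators;
mutation counts per gamete are drawn binomially with Floyd sampling of
locus indices, so runtime scales with the genome size only through the
haplotype copy. All randomness goes through R's RNG: a seeded run is
bit-reproducible, which the tests assert. The R-level mutation and fitness
functions (`apply_mutations()`, `fitness()`) expose the same model for
direct use and property testing.

## Summary statistics

With no environmental variance, phenotypic (co)variances equal genetic
(co)variances, so `g_matrix()` estimates G directly from phenotypes
(denominator $n-1$; the correlation is defined as 0 and flagged when a
variance is 0). `genic_gametic_covariance()` splits the cross-trait
covariance of haplotype effect sums into the locus-by-locus (genic)
part — nonzero only with pleiotropy — and the between-locus LD part; the
decomposition is exact by construction. `multiallelic_r2()` implements
$r^2 = \sum_{ij} D_{ij}^2 / [(1-\sum_i p_i^2)(1-\sum_j q_j^2)]$ over
haplotype frequencies, which reduces to the squared Pearson correlation of
allele indicators for diallelic loci; the statistic's name is standard but
its formula had to be chosen, and this normalization keeps it in $[0,1]$.
Continuum-of-alleles loci are treated as multiallelic by exact value
identity, which is well defined because mutation is additive from a
monomorphic start. `allelic_kurtosis()` uses population moments (no
small-sample correction). A reported equilibrium correlation of a run is
the mean of the recorded statistic over a trailing window of records
(default: final record), averaged over replicates.

## Association mapping

The mapping stage mirrors a standard mixed-model GWAA pipeline on the
simulator's samples (default 1000 individuals): a centered genetic
relatedness matrix $K = M^{-1}\sum_m (g_m-\bar g_m)(g_m - \bar g_m)^\top$
over markers with MAF $\ge 0.001$; univariate simple-regression scans per
trait with Benjamini–Hochberg correction at FDR 0.1; and a two-trait
linear mixed model with random polygenic covariance $K \otimes V_g$ plus
residual $I \otimes V_e$. The 2×2 components $V_g, V_e$ are estimated once
by REML on the eigenbasis of $K$ under the no-marker null and then held
fixed for all markers, each tested by a 2-df likelihood ratio; this
plug-in scan matches common mixed-model GWAS practice and keeps the scan
$O(M)$ after one eigendecomposition — exact per-marker REML refits are
deliberately out of scope. P-values become Storey q-values ($\pi_0$ from
the usual $\lambda$-grid with a df-3 cubic smoother, clamped to $(0,1]$;
$\pi_0 = 1$ reproduces BH exactly, an identity the tests check).

`discovery_metrics()` scores scans against the simulator's truth table: a
segregating causal locus counts as discovered when a significant marker
lies within 0.05 cM on the same chromosome (inclusive window). The
univariate pair reports the both-trait (pleiotropy) discovery rate, the
single-trait rate, and the count of markers significant in both scans;
QTN scans report the spurious-pleiotropy FPR of nonpleiotropic QTNs and
the FNR of pleiotropic QTNs, adjusted over segregating QTNs only. For the
LD statistic a significant marker is paired with the nearest segregating
causal locus in cM (a `max_ld` option pairs it with the highest-$r^2$
locus instead; nearest-in-cM is the default because the window criterion
is positional). The multivariate joint test yields one p-value per
marker; a q-significant marker is counted as associated with both traits.

## Problem sizes and what the tests show

Full-scale runs ($N = 5000$, 50,000 generations, 120 loci per trait, up to
120,000 neutral markers, 10–50 replicates per cell) are cluster-scale.
The package's test suite and acceptance script therefore run a documented
desk scale chosen once: $N = 500$, 60 loci per trait, 5000 generations and
6–8 replicates for equilibrium correlations; 2000 + 3000 generations for
the two-deme migration runs; and 20 chromosomes × 100 neutral markers,
8000 generations, samples of 500 for the mapping experiments. The
neutral-marker mutation rate at desk scale is $10^{-5}$ rather than the
full-scale $10^{-6}$, preserving the population-scaled input
$4N\mu = 0.02$ so that marker diversity is comparable — a standard
rescaling. At this scale the package reproduces the study's directional
results: higher equilibrium correlation for pleiotropy than for fully
linked pairs under house-of-cards mutation, correlations increasing with
the mutation rate and with tighter between-pair linkage, decreasing with
within-pair map distance, and a mapping advantage (higher discovery rate
and more joint associations) for pleiotropic architectures.

Quantitatively, the high-mutation linkage condition
($\mu = 10^{-3}, \alpha^2 = 0.1, \rho_\omega = 0.9$, 0 cM) approaches the
analytic equilibrium $r = 0.627$ from below as $N$ grows: drift pulls the
G-matrix toward the diagonal mutational covariance, giving means near
0.40 at $N = 500$ and near 0.48 at $N = 1000$. The acceptance band is
therefore wide ($[0.4, 0.8]$, asserted on the $N = 1000$ runs together
with the improvement over $N = 500$), and the comparison with a matched
pleiotropy run is a Welch test at the 1% level on the $N = 500$
replicates.

The migration experiments carry a desk-scale caveat. With only ~6
segregating house-of-cards loci at $N = 500$, the focal deme's standing
variance (~0.03 per trait) is tiny relative to the phenotypic
displacement of migrant families (~7 units per trait), so the covariance
contributed by the resident/migrant-descendant mixture dominates the
genetic *correlation* already at $m = 0.001$; at $m = 0.1$ the deme
becomes fully admixed, its mean reaches migration–selection balance near
the source optimum, and the focal regime (no correlational selection)
reshapes the standing variation, so the measured correlation *falls*
rather than rises with $m$. The robust desk-scale contrast — a
correlated source maintains a higher focal correlation than an
uncorrelated one — reproduces; the increase of the correlation with the
migration rate is a property of the full-scale conditions (larger
standing variance relative to the migrant displacement) that this scale
does not recover, and the corresponding directional check is expected to
fail at desk scale.

## What the generator does and does not emulate

The synthetic data are faithful to the model: polygenic additive traits,
Gaussian stabilizing/correlational viability selection, continuum or
biallelic mutation, diallelic neutral markers, Haldane recombination,
unidirectional migration. They do not include environmental variance,
dominance or epistasis, interference, sequence-level mutation spectra,
population growth, or structured mating — so passing tests demonstrate
correctness of the method under the model's assumptions, not robustness
of GWAA conclusions to features of real data outside them.

## Numerical choices and degenerate inputs

Monomorphic markers are skipped in scans with a recorded reason; a
monomorphic sample makes the genetic correlation 0 with a flag rather
than NaN. MAF ties at 0.5 are broken toward allele "1". The REML
optimizer uses a log-Cholesky parameterization (BFGS, bounded away from
overflow); non-PSD kinship matrices are rejected, eigenvalues are clipped
at zero. The fitness floor ($10^{-12}$ mean fitness per generation)
converts a non-terminating regulation loop into an error. `omega2 = Inf`
turns selection off exactly, which the drift tests use to recover neutral
Wright–Fisher behavior.

## Worked example

```{r example, eval = FALSE}
sel <- build_selection(100, 0.9, c(10, 10))
arch <- build_architecture("linkage", 60, within_pair_cM = 0)
cfg <- sim_config(arch, mutation_params(1e-5, 0.1), sel,
                  N = 500, generations = 5000, sample_size = 400, seed = 1)
sim <- run_simulation(cfg)
equilibrium_gcor(sim, window = 10)
g_matrix(sim)
genic_gametic_covariance(sim$population)
```

## Known limitations

The mixed-model scan fixes variance components across markers (plug-in
LRT); sample sizes and replicate counts at desk scale leave wide
Monte-Carlo bands, so quantitative agreement with full-scale reference
values is directional; LD statistics for externally imported PLINK data
are unavailable because phase is unknown; and the Gaussian
mutation–selection–drift expectation for finite populations is not
implemented (only the infinite-population equilibrium), so drift-induced
shortfalls of the correlation are observed, not predicted.
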