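---
title: "Methods: coalescent scenario choice and gorget color analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coalescent scenario choice and gorget color analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

`scenabc` reconstructs the demographic history of a set of structured
populations — the motivating system is a Mesoamerican cloud-forest
hummingbird sampled in four mountain-range groups (labelled TMVB, SMO, SMS
and CHIS) on either side of the Isthmus of Tehuantepec — from two marker
classes measured on overlapping sets of individuals: a concatenated
mitochondrial sequence alignment (751 bp in the motivating data) and
diploid microsatellite genotypes (8 loci, 126 individuals). Three competing
backward-time histories are compared by approximate Bayesian computation
(ABC):

* **Sc1** (isolation split 1): TMVB joins SMO at `t1`, SMO joins SMS at
  `t2`, SMS joins CHIS at `t3`.
* **Sc2** (isolation split 2): SMS joins TMVB at `t1`, TMVB joins SMO at
  `t2`, SMO joins CHIS at `t3`.
* **Sc3** (isolation with admixture): SMS is an admixture pulse of TMVB
  (weight `r`) and SMO at `t1`; TMVB joins SMO at `t2`, SMO joins CHIS at
  `t3`.

A second, independent component analyses reflectance spectra of the
iridescent throat patch (gorget) in avian tetrahedral color space and
quantifies color-volume overlap between plumage groups.

# The coalescent simulator

The simulator is a standard structured coalescent with piecewise-constant
population sizes, population merges, and one optional admixture pulse.
Within a population of diploid census-effective size $N$, $k$ lineages
coalesce at rate $\binom{k}{2}/(2N)$ per generation for autosomal markers.
For mtDNA the effective gene-copy number is $N/2$ (haploid, maternally
inherited, even sex ratio), i.e. one quarter of the autosomal $2N$; this is
the community default and matters because the paper-scale data mix both
marker classes. All times are in generations; multiplying by a generation
time $T$ (default 3 years for scenario work; $T = a + s/(1-s)$ from age at
maturity $a$ and adult survival $s$ is provided for rate conversions)
yields years.

Sequences mutate by an HKY process: mutation counts per branch are
Poisson$(\mu L \cdot \text{len})$, each mutation hits a uniform site and
substitutes with probability proportional to the target base frequency,
scaled by $\kappa$ (default 8) for transitions. Microsatellites follow a
generalized stepwise model (GSM): step sizes are geometric,
$P(G = g) = (1-P)P^{g-1}$, with fair sign; the allele ladder has 40
contiguous states and steps that would leave it are *reflected*. Reflection
(rather than discarding or truncating) keeps the mutation rate honest at
the boundary; the root allele is the ladder midpoint. These boundary
choices are stated here because the source analyses leave them to the
internals of the ABC software they used.

## Priors

All priors are uniform: effective sizes on [10, 100000]; split times
`t1`, `t2`, `t3` on [100, 50000] generations with `t1 < t2 < t3` enforced
by rejection on the time triple; admixture rate on (0.001, 0.999). Mean
mutation rates are not stated in the source analyses; we use
$\mu_\text{seq} \sim U[10^{-9}, 10^{-7}]$ per site per generation and
$\mu_\text{ms} \sim U[10^{-4}, 10^{-2}]$ per locus per generation, with
per-locus microsatellite rates drawn from a Gamma (shape 2) around the
mean, and the GSM parameter $P \sim U[0.1, 0.3]$ (the default range of the
DIYABC-family tools). All ranges are configurable; the defaults are the
package's stated world and are not adjusted per analysis.

A note on scale: the mitochondrial posterior mean rate printed by the
source study (0.000187) is interpretable as a *per-locus* rate; read
per-site it would exceed the upper end of the sequence prior. The prior
here is a deliberately conventional per-site range, and the ambiguity is
flagged rather than resolved.

## Parameter vectors and the reference table

The three scenarios share one rectangular parameter vector
(`N_TMVB, N_SMO, N_SMS, N_CHIS, N5, N6, N7, t1, t2, t3, r, mu_seq, mu_ms,
P_gsm`); parameters a scenario does not use (`r` for Sc1/Sc2, `N7` for
Sc3) are still drawn so reference-table rows all have the same width.
Every row derives its own sub-seed from the master seed and the global row
counter by a fixed affine-mod-$2^{31}$ scheme, so tables are bit-identical
under any batching or checkpoint/resume pattern.

# Summary statistics

The ABC summary vector follows the source design exactly: per group the
mean number of alleles, mean genic diversity, mean allele-size variance
(microsatellites) and the number of haplotypes, segregating sites and mean
pairwise differences (sequences); per group pair the combined (pooled)
genic diversity, Weir–Cockerham $\theta$, combined segregating sites and
$N_{ST}$. For four groups that is $6 \cdot 4 + 4 \cdot 6 = 48$ statistics
in a fixed documented order. Two conventions were genuinely open and are
fixed as follows: the pairwise "FST" uses the microsatellite
Weir–Cockerham estimator (sequence $\Phi_{ST}$ is computed and reported
separately, not in the vector), and "combined" statistics pool the two
samples rather than averaging per-sample values.

Other conventions:

* Ambiguous sites (`N`, `-`) are excluded *pairwise*; haplotype identity
  compares sequences over sites unambiguous in both, closed transitively.
* Gene diversity $h = \frac{n}{n-1}(1 - \sum p_i^2)$ with Nei's variance;
  nucleotide diversity is the mean per-pair proportion of differences.
* Microsatellite expected heterozygosity uses the small-sample correction
  $\frac{2n}{2n-1}(1 - \sum p^2)$; allele-size variance uses the
  population (divide-by-$n$) convention; allelic richness uses
  hypergeometric rarefaction.
* $N_{ST} = 1 - \pi_S/\pi_T$ on TN93 distances, with within-group means
  weighted by pair counts (the pooled-pair convention; the
  sample-size weighting of Pons & Petit differs negligibly at these sizes).
* TN93 distances use empirical base frequencies estimated from each pair;
  saturated pairs (log-domain failure) are flagged infinite.

## Neutrality tests and the mismatch distribution

Tajima's $D$ uses the standard constants. Fu's $F_s$ is
$\ln(S'/(1-S'))$ with $S' = P(K \ge K_\text{obs})$ under the Ewens
sampling formula at $\theta = \bar{k}$; the pmf of $K$ is built by the
probabilistic recursion $K_n = K_{n-1} + \text{Bernoulli}(\theta/(\theta +
n - 1))$, which is algebraically the unsigned-Stirling closed form but
cannot overflow. $F_s$ is flagged undefined (rather than $\pm\infty$)
when $K = n$, $K = 1$ or $S' \in \{0, 1\}$. p-values for both tests are
lower-tail fractions over `n_sim` constant-size neutral coalescent
simulations at $\theta = \bar{k}$, with the $(b+1)/(m+1)$ correction used
for every permutation/bootstrap p-value in the package (no exact zeros).

The mismatch analysis fits the sudden-expansion expectation (Li 1977;
Rogers & Harpending) for $(\tau, \theta_0, \theta_1)$ by bounded
least squares with a coarse multistart grid (tolerance $10^{-8}$,
$\theta_0 \le \theta_1$ enforced by parametrizing the increment).
Harpending's raggedness pads the relative frequencies with zero classes
below class 0 and above the last class, so a two-class histogram
$(0.5, 0.5)$ scores $0.5$; the source tables do not state a convention, so
this one is documented and covered by direct-arithmetic tests. p-values
come from a parametric bootstrap: data re-simulated under the fitted
expansion (two-epoch haploid coalescent in mutational units), refitted
with a reduced multistart, statistic compared with $\ge$.

## AMOVA

Variance components follow the squared-distance sums-of-squares
decomposition on TN93-corrected numbers of differences, one- or two-level.
When the design has one population per group, the among-populations-
within-groups stratum is structurally empty and its component is fixed at
zero rather than divided by zero. Negative components are reported as
estimated; percentages floor components at zero first (flagged). The three
fixation indices use their own permutation schemes (individuals among all
populations for $F_{ST}$; individuals among populations within groups for
$F_{SC}$; whole populations among groups for $F_{CT}$).

# The ABC engine

Rejection standardizes each statistic by its reference-table median
absolute deviation (SD fallback for zero MAD; statistics constant in both
table and observation are dropped with a log), takes the
$\lceil \delta n \rceil$ Euclidean-closest rows (default $\delta = 0.01$),
and weights them with an Epanechnikov kernel in distance.

Model choice reports both the weighted vote share ("direct") and a
weighted multinomial logistic regression of the scenario indicator,
evaluated at zero offset (the observed point). The standardized statistic
differences are first projected onto the $k-1$ Fisher discriminant axes
of the accepted rows and scaled to unit variance — the same preprocessing
the standard ABC model-choice tools apply, and necessary here because a
raw 48-feature regression on a few hundred accepted rows overfits into
overconfident posteriors. No multinomial fitter is assumed in the
environment, so the package implements weighted
Newton–Raphson with a small ridge ($10^{-6}$) and monotone step-halving;
95% CIs come from the delta method on the softmax using the observed-
information covariance of the intercepts. Complete separation (or a
singular fit) falls back to the direct estimate with a warning — on
strongly separated problems the direct estimate is itself near-degenerate,
so nothing is lost. The POD selection rule is argmax of the logistic
posterior, ties broken by the direct estimate, then scenario order.

Parameter estimation is Beaumont-style local-linear adjustment: each
parameter is logit-transformed to its prior range (guaranteeing adjusted
draws respect the bounds), regressed on the standardized statistic
differences with the rejection weights, adjusted by subtracting the fitted
systematic part, and back-transformed. A noiseless identity mapping
collapses the posterior onto the observed value up to the local curvature
of the range-logit link — exactly zero spread is not attainable under the
bounded transform, and the tests assert a collapse tolerance accordingly.
Singular designs fall back to a ridge solve ($10^{-6}$).

Model checking simulates summary vectors from posterior draws, projects
prior, posterior-predictive and observed vectors onto the PCA of the
standardized prior simulations, and reports two-sided tail probabilities
per statistic with the $(b+1)/(m+1)$ correction.

# Color space

Spectra are LOESS-smoothed (local quadratic, tricube weights, span 0.25 —
the span the source analysis states) on the input grid; negative smoothed
reflectance is clipped at zero with a count kept. Hue is extracted as the
argmax wavelength in two windows (UV/blue 300–500 nm; red beyond 600 nm),
flagging boundary argmaxes as non-peaks. Quantum catches integrate
reflectance × illuminant × cone sensitivity by the trapezoid rule over
300–700 nm only: the red gorget peak near 715/780 nm is deliberately
*outside* the visual integration range (it still drives the hue metric),
because avian photoreception is capped near 700 nm.

The default visual model is an idealized tetrachromat — Gaussian cone
sensitivities peaking at 372, 456, 544, 609 nm (SD 40 nm), flat
illuminant, each curve normalized to unit integral — because the source
analysis does not name its cone template and results must be reproducible
without proprietary sensitivity data; any user-supplied curves are
accepted. The tetrahedral mapping places the achromatic point at the
origin with the four unit-stimulation vertices at distance 0.75;
`r_max` is computed by exact ray–face intersection, so
`r_achieved = r_vec/r_max` is exactly 1 at a vertex.

Color volumes are 3-D convex hulls (an in-package quickhull;
no qhull binding is available in the environment), and the intersection
volume uses seeded Monte-Carlo sampling over the intersection of bounding
boxes with half-space membership tests (default $10^6$ points, ~1%
relative tolerance) — the documented fallback in place of exact half-space
intersection. Overlap is reported both as intersection/union and
intersection/smaller, because the source's "0.73% of the tetrahedral
color volume" does not name its denominator.

# The synthetic-data generator

`make_popgen_fixture()` writes FASTA/GenePop/map files simulated under a
scenario preset at the study's layout: 751-bp sequences with group copies
(SMO 70, TMVB 19, SMS 37, CHIS 27) and 126 diploids at 8 loci split
proportionally (58/16/30/22); `make_spectra_fixture()` writes two-Gaussian
spectra (UV peak 420 nm; red peak 715 nm for amethyst-like groups, 780 nm
for the blue group; per-specimen peak jitter SD 8 nm; heteroscedastic
noise). What the generator does *not* emulate: recombination,
null alleles and genotyping dropout, within-group substructure,
iridescence angle dependence, and the real study's allele-frequency
spectra. A green test on these fixtures therefore establishes that the
*machinery* is correct and calibrated under its own model, not that the
historical inference for the real bird is right.

# Scaling choices in the test suite

The source analyses use $10^6$ simulations per scenario, 500 PODs, and
10000 permutations. The offline test suite must finish in minutes on one
CPU, so calibration tests run the same code at reduced scale: reference
tables of ~600–1200 rows per scenario, a reduced sample configuration
(25 sequences / 20 diploids across the four groups, 4 loci), tens of PODs,
and $\delta$ raised so that a few hundred rows are accepted. The
acceptance thresholds (e.g. "generating scenario recovered in ≥ 80% of
replicates", "true `t3` inside the 90% interval in ≥ 80% of replicates")
are unchanged; only the Monte-Carlo sizes shrink. Recovery tests use
well-separated truth parameters (clear time ordering, moderate sizes)
as their stated world.

# Known limitations

* No recombination, continuous migration, or selection; the admixture
  pulse is instantaneous.
* The weighted multinomial likelihood treats Epanechnikov weights as case
  weights; its delta-method CIs are approximate in the same way the
  standard ABC tooling's are.
* Monte-Carlo hull intersection has ~1% error at the default sample size;
  exact half-space intersection is not implemented.
* TN93 distances saturate (flagged `Inf`) for extremely divergent pairs;
  downstream statistics propagate the flag rather than guessing.
* Real-data reproduction of the motivating study requires its archived
  alignments and genotypes, which this package does not download.
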