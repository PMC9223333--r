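---
title: "Dating founder events from allele-sharing correlation decay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating founder events from allele-sharing correlation decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A founder event — the formation of a population from few individuals, or a
transient collapse in effective size — leaves a distinctive signature in
genotype data: pairs of individuals co-inherit long chromosomal segments
from the small founding pool, so the number of alleles two individuals
share identical-by-state (IBS) becomes correlated between nearby SNPs, and
that correlation decays with genetic distance as recombination breaks the
segments up.

`ascendr` measures this decay and inverts it. For each pair of individuals
$(a,b)$ and SNP $i$ we record $N_{a,b,i} \in \{0,1,2\}$, the number of IBS
alleles; a heterozygous genotype in either individual counts as one shared
allele regardless of phase, which is what frees the method from phasing and
makes it applicable to unphased diploid and pseudo-haploid data. The
*within-population allele-sharing correlation* at genetic distance $d$ is

$$ z_w(d) = \frac{1}{|S_d|} \sum_{(i,j) \in S_d} r(N_{\cdot,i}, N_{\cdot,j}), $$

the mean over SNP pairs $(i,j)$ at distance $d$ of the Pearson correlation
of their sharing vectors across individual pairs. Ancestral sharing common
to all populations is removed by subtracting the same statistic computed
across target × outgroup pairs: $z(d) = z_w(d) - z_c(d)$.

Under a bottleneck of diploid size $N_f$ lasting $D_f$ generations and
ending $T_f$ generations before sampling, with equilibrium size $N_o$
otherwise, the expected corrected correlation is

$$ z(d) = I_f \, e^{-(1 + 2 d T_f)}, \qquad I_f = \frac{D_f}{2 N_f}. $$

$I_f$, the *founder intensity*, is the probability of coalescence during
the event; $e^{-1}$ is the equilibrium correlation entering the bottleneck;
and the exponential is the recombination decay accumulated over the $T_f$
post-event generations (the derivation assumes no recombination *during*
the event — see "Interpreting the fitted age" below). The pipeline fits

$$ o(d) = a\,e^{-2 d t} + c $$

by bounded Levenberg–Marquardt least squares and reports
$\hat I_f = e \cdot a$ and $\hat T_f = 100\,t$ when $d$ is measured in cM.
The affine offset $c$ absorbs sampling noise and residual long-range
structure.

## Parameters that matter

* **Distance window and bin width** (`distance_bins()`): default 0.1–30 cM
  in 0.1 cM bins. The lower cut removes the near-zero distances dominated
  by background LD (at equilibrium the within-population correlation decays
  on the $1/(4 N_o d)$ scale, which is negligible beyond 0.1 cM for
  human-sized populations); the upper end must be large enough that the
  curve has visibly flattened, otherwise $c$ and slow decay components are
  confounded and the rate estimate degrades — this is why breeds with
  long-range LD (dogs) use 40 cM, and why fits on very short chromosomes
  should widen the window rather than truncate it.
* **Mesh spacing** (`mesh_cM`, default 0.001 cM = 100 mesh points per bin):
  the FFT engine's discretisation; it bounds the distance distortion by
  half a mesh step.
* **Outgroup** (default a random panel of 15 individuals outside the
  target): only used in correlation mode; the weighted-covariance mode is
  a within-population statistic.
* **Significance thresholds** (`classify_founder_event()`): a founder event
  is called when the CI95 of neither $\hat T_f$ (generations) nor
  $\hat I_f$ includes 0, $\hat T_f < 200$ with SE < 50, $\hat I_f > 0.5\%$,
  and NRMSD < 0.29. The 200-generation horizon is where the decay becomes
  too fast to resolve against the bin width; 300 is sometimes used for
  ancient-sample analyses (`max_age`).

## Two engines, one estimator

The exact ("naive") engine evaluates the estimator definition directly —
a loop over SNP pairs, quadratic in SNP count, practical at array densities
(~100–200 SNPs/cM).

The FFT engine makes sequence-density data tractable. Each SNP's sharing
counts are first *standardised across individual pairs* (centred, scaled by
the maximum-likelihood SD), so that the average over pairs of
$\tilde s_i \tilde s_j$ is exactly the Pearson correlation $r_{ij}$. The
standardised values are rasterised onto mesh cells (nearest cell; co-located
SNPs summed), and one FFT per individual pair yields, at every lag
$\tau$, both $\sum_c a_c a_{c+\tau}$ (cell totals) and
$\sum_c k_c k_{c+\tau}$ (cell counts, i.e. the number of contributing SNP
cross-pairs). Accumulating these two sums over the lags of a bin and over
individual pairs reproduces the exact engine's equal-weight-per-SNP-pair
mean, up to the mesh discretisation of distances. We chose this
construction over the classical masked autocorrelation with per-pair,
per-lag variance normalisation after finding that the latter computes a
materially different statistic: normalising along the genome folds
allele-frequency heterogeneity into the denominator and deflated the
amplitude several-fold in our simulations, whereas the standardised-product
form agrees with the exact engine to ~1e-4 per bin on complete data
(worst bins ~1e-3 at the sparse tails of short chromosomes). Under heavy
missingness the standardisation uses global rather than pairwise-complete
per-SNP moments and the agreement loosens to O(1e-3); at that point the
weighted-covariance mode is the recommended statistic anyway.

In weighted mode the same machinery rasterises the centred sharing
*fractions* $(s/2 - \mu_i)/He_i$ and multiplies by $P/(P-1)$, matching the
exact engine's pairwise-complete covariance with the $He_i He_j$ product
normalisation. The fraction scale (0, ½, 1 — the 0/1 match indicator for
single-allele pseudo-haploid calls) matters only in covariance mode, where
it is what makes the fitted amplitude map to founder intensity through the
same $e \cdot a$ transform as the correlation; the correlation itself is
scale-invariant. (A
$\sqrt{He_i He_j}$ variant is available in
`weighted_cov_profile(normalisation = "sqrt")` for comparison; the product
form is the one whose amplitude maps to founder intensity.)

## Pseudo-haploid data and the weighted covariance

Pseudo-haploid calling (one random allele per site, reported homozygous)
deletes heterozygotes, inflating the spread of sharing counts without
changing their mean. The correlation amplitude — hence $\hat I_f$ — is
biased downward, while the decay rate ($\hat T_f$) is essentially
unaffected. The weighted allele-sharing covariance
$w(i,j) = \mathrm{cov}(A_i, A_j) / (He_i He_j)$, with $He_i = 2p_i(1-p_i)$
estimated from the target samples, removes this bias and needs no outgroup.
`run_ascend()`'s `mode = "auto"` therefore resolves to the weighted
covariance whenever the input is pseudo-haploid or no outgroup is given.
Allele frequencies for $He$ are computed from the target population only:
the statistic is a within-population quantity, and sites monomorphic in the
target are removed by the site filter beforehand so every used $He$ is
positive.

## Uncertainty: weighted block jackknife

Chromosomes are the natural independence blocks. For block $j$ with SNP
count $m_j$ ($M = \sum m_j$, $h_j = M/m_j$, $g$ blocks), the profile is
re-pooled without block $j$ and refitted, giving $\hat\theta_{-j}$. The
reported point estimate is the weighted mean
$\sum_j (m_j/M)\,\hat\theta_{-j}$; the variance uses the pseudovalues
$\tau_j = h_j\hat\theta - (h_j - 1)\hat\theta_{-j}$ around the
bias-corrected combination
$\theta_{bc} = g\hat\theta - \sum_j (1 - m_j/M)\hat\theta_{-j}$:

$$ \widehat{\mathrm{Var}} = \frac{1}{g} \sum_j
   \frac{(\tau_j - \theta_{bc})^2}{h_j - 1}, $$

which reduces to the classical delete-one jackknife under equal weights
(verified in the tests). CI95 is $\pm t_{0.975,\,g-1}\,\mathrm{SE}$: with
the usual 20 chromosome blocks the Student-t quantile (2.09) is close to
the normal 1.96, but on few-block profiles — short validation genomes, or
organisms with few chromosomes — the normal approximation measurably
undercovers (we observed 80% instead of 95% on 5-block replicates), and
the block-count degrees of freedom restore calibration. The paper-style
full-data point estimate is available with
`jackknife_fit(point = "full")`. Leave-one-out fits that
fail to converge are flagged and excluded (weights renormalised); more than
20% failures aborts the jackknife.

## Numerical choices

* Fit bounds: $a \in [0,1]$, $t \in [0, 20]$ per cM ($\hat T_f \le 2000$);
  a rate pinned at the upper bound marks the fit non-converged rather than
  reporting a runaway age. Starting values come from a log-linear
  regression of offset-corrected positive bins (offset initialised at the
  mean of the last decile of bins), with a fixed fallback when fewer than
  three bins are positive.
* Bin abscissa: the bin midpoint (e.g. 0.15 cM for [0.1, 0.2)), unbiased
  under locally uniform SNP-pair density.
* A Pearson $r$ needs at least 2 complete individual-pair observations;
  SNP pairs below that, or with zero variance in either vector, are
  skipped and do not count toward the bin. Bins with no usable pairs are
  *absent* (NA), never zero.
* Distance comparisons carry a 1e-9 cM tolerance so that grid-aligned maps
  do not flip bins on floating-point representation error.
* Cross-chromosome SNP pairs are excluded (no genetic distance is defined
  across chromosomes); per-bin aggregation pools the sums of $r$ values
  and pair counts over chromosomes before dividing, which equals the
  global mean over $S_d$.

## Interpreting the fitted age for extended events

The closed form assumes coalescence happens *at* the event and no
recombination occurs during it. For an extended bottleneck (large $D_f$),
lineages coalesce throughout $[T_f, T_f + D_f]$ and each cohort's
correlation decays from its own coalescence generation; the single
exponential that best fits the resulting mixture estimates approximately
the mean coalescence time within the event, not the event's endpoint. On
the standard validation demography with $N_f = 100$, $D_f = 20$,
$T_f = 10$, that mean is $\approx 19.5$ generations and the pipeline's
estimate lands there, while $\hat I_f$ recovers the nominal 10% almost
exactly. Age estimates for long events should therefore be read as "the
population coalesced around generation $\hat T_f$, within an event whose
span is not separately identifiable"; intensity estimates carry no such
caveat. For a single-generation bottleneck ($D_f = 1$) the age is a point
parameter and the jackknife CI covers it with close to nominal
probability (the replicate study in the test suite measures this).

## What the simulator emulates — and what it does not

`simulate_founder_model()` reproduces the two-population validation
demography: target and outgroup diverging 1,800 generations ago at
$N_o = 12{,}500$ diploids, 20 chromosomes of 50 Mb with uniform
recombination (0.5 Morgans each), mutation $1.2\times10^{-8}$ and
recombination $1\times10^{-8}$ per bp per generation, 30 haploid genomes
per population paired at random without replacement into 15 diploids, and
an optional epoch bottleneck ($N_f$, $D_f$, $T_f$).
`simulate_admixture_founder()` adds a 60/40 pulse admixture 110 generations
ago from two sources that diverged 1,800 generations ago, with the first
source doubling as the outgroup. Degradation operators
(`pseudo_haploidize()`, `inject_missingness()`, `thin_sites()`) emulate
ancient-DNA calling, random missingness, and array ascertainment by
density. The coalescent engine is pluggable by design; the bundled backend
drives msprime through a small Python script, with all demographic
parameters owned by the R configuration object and every random draw keyed
to the config seed.

The simulations are neutral, panmictic within populations, uniform in
recombination and mutation rate, and use random (density-only) site
thinning. Real data add ascertainment bias toward common variants,
recombination hotspots, genotyping error and consanguinity; passing the
validation battery therefore demonstrates correctness of the estimator and
its uncertainty under the stated model, not robustness to those
complications (relatedness filtering in particular is assumed done
upstream).

## Problem sizes used in the validation battery

The test suite runs the full 20 × 50 Mb genome once for the headline
recovery check and for engine equivalence (chromosomes 1–2 of that
genome, thinned to 100 SNPs/cM so the quadratic engine is exact and
affordable). Replicate studies — CI coverage across founder ages
(single-generation bottleneck, $I_f = 10\%$, $T_f \in \{10, 50, 100,
200\}$, five replicates each, on 5 chromosomes × 12 Mb) and
false-discovery control on constant-size populations (20 replicates on
3 chromosomes × 10 Mb) — use reduced genomes at array density, sizes at
which a replicate completes in seconds while leaving over a hundred usable
bins and at least three jackknife blocks. The pseudo-haploid
correction study uses one 5 × 20 Mb genome, comparing the diploid
correlation fit, the degraded (pseudo-haploid, 50% missing) correlation
fit, and the weighted-covariance fit on the same degraded data.

## Known limitations

* Only the ratio $I_f = D_f / 2N_f$ is identifiable, never $D_f$ and $N_f$
  separately; and for extended events the age is the event-interior
  coalescence time discussed above.
* The model does not distinguish a true founder event from other histories
  producing similar decay (e.g. strong recent admixture LD is removed only
  insofar as the outgroup correction captures it).
* Two successive events blend: the intensity tracks the stronger event,
  the age an intensity-weighted compromise unless one event dominates.
* The FFT engine's missing-data standardisation is a documented
  approximation (see above); the exact engine is the reference.
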