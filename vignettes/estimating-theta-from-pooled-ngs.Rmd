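---
title: "Estimating Watterson's theta from error-prone pooled sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating Watterson's theta from error-prone pooled sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualtheta)
```

## The problem

Watterson's $\theta$ — the population-scaled mutation rate per site — is
classically estimated from the number of segregating sites $S$ observed in a
sample of $n$ haploid genomes: $E[S] = a_n \theta l$ over $l$ sites, with
$a_n = \sum_{i=1}^{n-1} 1/i$.  Natural polymorphism is dominated by
low-frequency variants ($P(b \text{ mutant copies}) \propto 1/b$ under the
neutral Ewens spectrum), and next-generation sequencing misreads 0.1–1% of
bases.  At any realistic coverage, a rare true variant and a recurrent
sequencing error look identical in a single dataset, so naive segregating-site
counts overestimate $\theta$ by one to two orders of magnitude.

`dualtheta` implements three estimation schemes for this regime, together with
the forward simulator used to validate them:

1. **Single-line**: each diploid is sequenced separately at low coverage
   (~2X); at every site one read per covered individual is taken to represent
   one haploid genome.  With $n_j$ individuals covered at site $j$,
   $\hat\theta = \frac{1}{l}\sum_j S_j / a'_{n_j}$, where
   $a'_{n_j} = \sum_{i=1+z}^{n_j-1-z} 1/i$ discards the singleton
   ($z = 1$) or singleton-and-doubleton ($z = 2$) frequency classes in which
   errors concentrate.
2. **Pooled, single platform**: DNA from all individuals is pooled in equal
   amounts and sequenced once.  A site with $b$ mutants among $n$ pooled
   haploids covered by $r$ reads is detected as segregating with both alleles
   above $z$ reads with probability
   $q_1(z, b, r) = P(z < X < r - z)$, $X \sim \mathrm{Bin}(r, b/n)$,
   and $\hat\theta = S_{>z} \big/ \sum_j \sum_{b=1}^{n-1} q_1(z, b, r_j)/b$,
   the denominator averaging detection over the $1/b$ spectrum.
3. **Pooled, dual applications**: the same pool is sequenced twice,
   independently (two platforms, or two library preparations on one
   platform).  Sequencing errors of independent runs rarely hit the same site
   with the same wrong nucleotide, so an allele is believed only if it exceeds
   $z$ reads in *both* runs; the detection probability becomes the product of
   the two single-run terms.  This is the estimator of interest: it stays
   calibrated even at a 1% error rate where the other two schemes fail.

## Site classification

A `filter_policy(r_min, z)` drives classification.  Sites below `r_min` reads
(in either application, for the dual scheme) are *missing* and excluded from
both the segregating-site count and the denominator.  Otherwise alleles with
more than `z` reads are retained (for the dual scheme, more than `z` reads in
both applications), and a site is *segregating* when at least two alleles
survive.  `r_min` must be at least $2z + 2$ — a shallower site could never
show two alleles each above $z$ — and defaults to 6, the smallest depth
compatible with $z = 2$.

Two behaviours are offered for sites where more than two alleles survive the
filter.  The default (`multiallelic = "retain"`) counts them as segregating.
The alternative (`multiallelic = "missing"`) excludes them, and for the dual
scheme additionally requires the two applications to retain exactly the same
allele pair.  The strict rule is the more conservative prescription for real
data, where a three-allele site is almost certainly error-contaminated; the
lenient rule is the behaviour under which the reference simulation results
were produced, and is what the validation suite reproduces.  The two differ
materially only at high error rates with $z = 0$, a regime in which neither
variant of the single-platform estimator is usable anyway (estimates there are
tens of times the true value).  Under the infinite-sites assumption a true
site has at most two alleles, so at $\varepsilon = 0$ the options coincide.

Degenerate corner: a covered site at which *no* allele survives the filter
(all counts $\le z$) is treated as missing.  It can only occur at depths
within a read or two of `r_min` and was never observed in the validation
simulations at realistic coverage.

## What the simulator emulates

`simulate_truth()` places segregating sites along a region under the neutral
infinite-sites model: mutant counts follow the Ewens spectrum
$q_n(b) \propto 1/b$, reference alleles are uniform, mutant alleles uniform
over the other three nucleotides.  Two placement modes are available:

* `"bernoulli"` — each site is independently segregating with probability
  $a_n \theta$; the regional polymorphism level varies naturally between
  draws.
* `"fixed_count"` — exactly $S = \mathrm{round}(a_n \theta l)$ sites are
  placed.  This is the default in `run_experiment()`, because the reference
  replicate experiments hold the regional polymorphism level fixed and let
  only sequencing vary: their replicate standard deviations are far below the
  $\sqrt{S}$ noise of a redrawn truth (3% rather than 15% at
  $\theta = 0.1$/kb) and differ between schemes, which is only possible if the
  truth is not resampled.  Consequently, the quantity a replicate experiment
  recovers is the realised diversity of the simulated region,
  $S / (a_n l)$, which differs from the nominal $\theta$ only by the rounding
  of $S$ (at most 0.5% at the sizes used here); the validation suite tests
  recovery against that realised value.

`simulate_pooled_counts()` models sequencing as Poisson depth per site
(mean $n \times$ coverage per haploid), binomial sampling of the mutant
allele with probability $b/n$ (reads sample the pool with replacement), and
independent per-read error with probability $\varepsilon$, the misread
nucleotide uniform over the three alternatives.  Error rates are either
constant or site-specific, $\varepsilon \sim
\mathrm{Beta}(\alpha, \alpha(1-m)/m)$ with mean $m$ — the second shape
parameter is derived from the mean, the only parameterisation consistent with
specifying $(\alpha, m)$.  Small $\alpha$ gives the heavy-tailed,
some-sites-are-error-hotspots landscape seen in real data.

For dual applications the per-site Beta rate is drawn **independently for
each application** by default.  This matches the regime the dual-application
method is designed for — two runs whose error-prone site sets are essentially
uncorrelated (observed cross-run error correlations are of order 0.05–0.15) —
and it is the regime under which the reference Beta-error results were
produced; sharing the draw (`shared_site_error = TRUE`) is available to model
a common site-specific error propensity, and roughly doubles the residual
bias of the dual estimator at $z \le 1$.

`simulate_single_line()` models the truth on $n = 2 \times$
`n_individuals` haploid genomes.  Each individual is covered with probability
$1 - e^{-\lambda}$ (the Poisson zero class; 86% at 2X), and one random
haploid of each covered individual is observed.  Because one-haploid-per-
individual sampling of a random individual subset is, marginally, a uniform
random subset of the $2n$ haploids, the sampled mutant count is
hypergeometric and the truncated-harmonic estimator remains unbiased.  The
two-haploids-per-individual view matters: a singleton among 50 haploids is
sampled with probability $\approx 0.43$, not $0.86$, which is visible in the
replicate variance at $z = 0$.

What the simulator does *not* model: linkage and recombination (sites are
independent), demography and selection, read length and mapping error,
base-quality variation within a run, indels, PCR duplicates, and
substitution-type biases (real errors favour particular substitutions, e.g.
A-to-C, making same-nucleotide doubleton errors more common than the uniform
model predicts — one more reason the truncation filter alone is not a
complete defence on one platform).  Passing validation here therefore shows
the estimators are correct *under the stated generative model*, not that any
particular real dataset satisfies that model.

## Numerical choices

* Detection probabilities use `pbinom` differences,
  $q_1(z,b,r) = F(r - z - 1) - F(z)$, clamped at 0: for $r \le 2z + 1$ the
  subtraction goes negative while the event is simply impossible.  At
  $z = 0$ the closed form $1 - (1-p)^r - p^r$ is used directly, so the
  $z = 0$ reduction is exact to the last bit.
* Denominators are accumulated per distinct depth (or depth pair), computed
  once each — depths at Poisson(100) take a few dozen distinct values over
  100 kb, so this is both faster and free of accumulation-order noise.
* `maf_below_prob()` treats "MAF below cutoff" strictly:
  $P(X \le \lceil c \cdot d\rceil - 1)$.  This convention reproduces the
  reference screening probabilities (0.0375 for a $1/70$ singleton at 2000X
  and a 1% cutoff; $0.0375^2 = 0.0014$ for two applications) exactly at the
  printed precision.  A cutoff $\ge 1$ returns 1, since a minor-allele
  fraction is below 1 by definition.
* Replicate seeds are derived deterministically from the experiment seed
  (affine map modulo $2^{31} - 1$), so experiments are bit-reproducible and
  per-replicate streams do not depend on evaluation order.
* Estimation with zero non-missing sites is an error, not a zero: the
  estimate is undefined, and silently returning 0 would bias downstream
  averaging.
* $\theta$ is carried per site internally; per-kb values are a reporting
  layer ($\times 1000$) only.

## Validation problem sizes

The test suite validates parameter recovery (all three schemes,
$\theta \in \{0.1, 1\}$/kb, $z \in \{0, 1, 2\}$, error-free), the error
regimes at $\varepsilon \in \{0.001, 0.01\}$, the Beta-error regime
($\alpha = 0.8$, mean 0.005), and the small-region precision of the dual
estimator (40 kb, $\theta = 1$/kb).  These use 200 replicates of 100 kb (or
40 kb) regions, which bounds the Monte-Carlo standard error of each reported
mean at roughly a third of a percent of the reference value while keeping the
default test run in the minutes range; `run_experiment()` reproduces the
full 1000-replicate tables unchanged if desired.

## Limitations

* The estimators consume per-site allele counts; alignment, base-quality
  filtering and duplicate handling are upstream concerns.
* The truncation filter discards the information in singletons and
  doubletons; if the scientific question lives in the rare tail of the
  frequency spectrum, no pooled low-coverage design recovers it — deep
  individual sequencing is the only route.
* The dual-application estimator assumes error *independence* between
  applications.  Systematic, sequence-context-driven errors shared by both
  runs (same chemistry, same library) violate this and leak through the
  concordance filter.
* Pool construction assumes equal DNA contributions per individual; unequal
  pooling distorts the effective allele frequencies and is not modelled.
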