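---
title: "Male call timing, female precedence windows, and emergent chorusing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Male call timing, female precedence windows, and emergent chorusing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

In many rhythmically calling insects and anurans, females prefer the
*leading* of two closely timed calls (a precedence effect), and males,
upon hearing a neighbour, momentarily inhibit and phase-reset their
central call rhythm generator, which delays their next call. If the male
adjustment evolved in response to the female preference, two timing
parameters should match across populations:

* **m** — the minimum post-stimulus call delay of males: the shortest
  delay between a heard stimulus and the male's next call;
* **f** — the female preference window: the largest leader–follower onset
  separation at which females still prefer the leading call.

A male whose m is at least the local f (almost) never produces a call
that local females discount as "following". `chorusem` implements the
full analysis chain for testing this coevolution hypothesis across a set
of genetically isolated populations: the resetting chorus model, the
playback estimators of m and f, a microsatellite population phylogeny,
and the phylogenetically corrected correlation between m and f — together
with a synthetic-data generator so every stage is testable end to end
without field data.

## The inhibitory-resetting oscillator

Each male is a free-running oscillator with period `T` (ms). His rhythm
generator rebounds after each call; after an effector delay `t` it
triggers sound. A stimulus heard at post-call delay `d` resets the
generator, and the male's next call follows the stimulus after

$$D(d) = m + (T - t - d)\,\frac{T - m}{T - t}, \qquad 0 \le d \le T - t,$$

with $D(d) = m$ for $d > T - t$. $D$ is continuous, non-increasing, and
bounded in $[m, T]$: a stimulus immediately after the male's own call
leaves his rhythm essentially unperturbed ($D \to T$), while a stimulus
at the generator's peak produces the minimum delay $m$. The published
descriptions of the rebound geometry specify only these endpoints and
monotone steepening; between them the map could be linear, concave or
convex. We adopt the linear form as the minimal assumption and isolate it
behind a single swappable function (`reset_delay()`, the `delay_fun`
argument of `simulate_chorus()`).

`simulate_chorus()` runs an event-driven simulation: every call onset is a
stimulus to every other male whose resetting is enabled, rescheduling his
next onset to `stimulus_time + D(d)`. Ties within $10^{-9}$ ms are
emitted together and do not stimulate each other. Times are continuous
real-valued ms; there is no discretisation grid. Two structural
consequences are worth noting, and are covered by tests:

* with resetting on and no jitter, **no call ever falls within the open
  interval (0, m) after a rival's onset** — the resetting rule makes the
  exclusion zone exact;
* the qualitative regime of a two-male interaction depends on whether the
  effector delay is shorter than the minimum delay. For the realistic
  regime $t < m$ (motor latencies of tens of ms against call periods of
  seconds) a resetter facing a non-resetting rival of equal period
  converges toward the rival's onsets and tends to call just *before*
  him, harvesting the leading role; for $t > m$ the fixed point of
  $D$ instead pins the resetter exactly m after the rival. Only the
  first regime is biologically sensible for the katydids this package
  models, and it reproduces the expectation that resetting males
  broadcast more leading calls and attract more females.

`classify_calls()` labels each call synchronous / following / leading /
solo, with the precedence synchronous > following > leading when a call
qualifies against different rivals, and reports per-pair phase statistics
(mean phase, circular vector strength). The synchrony tolerance and the
follower window are arguments; there are no hidden thresholds.

## Playback estimators

* A male's **m** is the mean of his 3 shortest post-stimulus delays
  (`estimate_male_m()`); the population's m averages the male values.
  Delay histograms use half-open 50-ms bins anchored at the stimulus
  onset, edge values going to the upper bin.
* The **preference index** at a call separation is $(p_L - 0.5)/0.5$,
  where $p_L$ pools leader choices over all trials and females (4 trials
  per female per separation; every complete female contributes equally,
  incomplete females should be excluded rather than reweighted).
* The **sign test** labels each female '+' if she chose the leader in
  more than half her trials and '−' if fewer; ties at exactly one half are
  excluded; the one-tailed p is the upper binomial tail.
* **f** is the largest tested separation whose index is at least 50% of
  the maximum index across separations, with no interpolation. We
  implement the literal maximal-separation reading; a `contiguous`
  flag provides the stricter variant in which the index must stay above
  threshold at every smaller separation as well. Significance of the peak
  index is reported but does not gate f.

## Population genetics and the tree

Allele frequencies are tabulated per population and locus over
non-missing diploid genotypes; individuals with more than 20% missing
loci are removed before clustering-related analyses (`filter_missing()`).
Genetic distance is Nei's allele-sharing distance
$D_A = 1 - \tfrac1L \sum_\ell \sum_a \sqrt{p_a q_a}$, computed over loci
with data in both members of a pair (pairwise deletion maximises data
use). The population tree is neighbor-joining on the $D_A$ matrix;
occasional negative NJ branch lengths are clamped to zero with the
deficit transferred to the adjacent branch (the usual convention), so the
contrast standardisation downstream never sees a negative variance. Node
support is by locus bootstrap: loci resampled with replacement, the tree
rebuilt, and each internal bipartition of the full-data tree scored by
its replicate frequency. Support attaches to bipartitions, so rerooting
preserves it. Between-cluster differentiation uses the multi-allelic
Weir–Cockerham $\theta$ (ratio of sums of variance components over
alleles and loci; the community standard, robust to unequal sample
sizes), with a label-permutation p-value.

Because independent contrasts need a rooted tree and NJ trees are
unrooted, the analysis midpoint-roots the tree by default. The original
analysis does not state its rooting; midpoint rooting is the conventional
neutral choice when no outgroup is available, and support values are
unaffected.

## Phylogenetically corrected correlation

Standardized independent contrasts follow Felsenstein's pruning
algorithm. Polytomies are resolved into zero-length ladders
(deterministically, via `ape::multi2di(random = FALSE)`); each
zero-length internal branch is counted, and the through-origin contrast
correlation

$$r = \frac{\sum x_i y_i}{\sqrt{\sum x_i^2 \sum y_i^2}}, \qquad
  t = r\sqrt{\mathrm{df}}/\sqrt{1 - r^2}$$

uses $\mathrm{df} = (n_{\text{contrasts}} - 1) - n_{\text{zero branches}}$:
one df for the through-origin constraint plus one per soft polytomy, the
standard bookkeeping for polytomy-corrected contrasts (16 contrasts with
two zero-length branches give df = 13). For standardisation only,
zero-length branches are inflated to $10^{-8}\times$ tree height; the df
count still treats them as zero. Contrast pairs are positivized by the
sign of the x-member — this changes neither $|r|$ nor the through-origin
fit, and the identity is verified numerically to $10^{-12}$ in the tests.

Alongside the contrast correlation the package reports ordinary
least-squares regression of m on f, reduced-major-axis lines (slope
$\mathrm{sign}(r)\,s_y/s_x$, or $\mathrm{sign}(\sum xy)\sqrt{\sum y^2/\sum x^2}$
through the origin), Spearman rank correlation on the raw population
values (the published analyses use ρ in both the raw and the contrast
context without defining it, so both are computed), and stepwise linear
regression with partial-F entry/removal thresholds α = 0.15 for the
short-call reanalysis (m on f and mean syllable number). Note a
structural property of α-threshold stepwise selection: a pure-noise
predictor enters with probability ≈ α, so "the informative predictor and
nothing else" is selected in only about $1-\alpha$ of replicates even in
clean data; the tests assert the informative predictor is found and that
noise enters at the designed rate. P-values are two-sided by default;
because the coevolution hypothesis is directional (m tracks f), a
`one_sided` option exists and the end-to-end signal-recovery checks use
it.

## Synthetic study design

The generator (`simulate_study()`) emulates the sampling design of the
field study the package models. Defaults were fixed once and are the
package's study conditions:

| parameter | default | rationale |
|---|---|---|
| populations | 17 | the sampled localities |
| loci | 18 | microsatellite panel size |
| diploids genotyped / population | 12 | inside the reported 7–26 range |
| males / population | 8 | inside the reported 8–18 (one smaller) |
| females / population | 10 | inside the reported 6–18 |
| stimuli / male | 40 | delay records per male |
| separation grid (ms) | 30, 75, 150, 300, 600, 1000, 1500, 2000 | 8 values spanning the stated 30–2000 ms; the per-population grids were not published |
| trials / female / separation | 4 | y-maze protocol |
| root m, f (ms) | 300, 400 | m slightly below f at the root, as observed in most populations |
| BM rate (log scale, per unit height) | 1.0 | reproduces the ~20-fold spread of observed m values across populations |
| trait correlation | 0.9 | the observed cross-population association |
| drift scale | 0.3 | gives between-cluster FST on the reported scale (~0.2) |
| delay noise sd | 10 ms | measurement noise on call onsets |
| preference strength, softness | 0.8, 50 ms | moderate-to-strong graded preference |
| oscillator | T = 4 m, t = 0.02 T | periods of seconds, motor latencies of tens of ms |

Traits evolve as bivariate Brownian motion **on the log scale** (keeping
m and f positive) down a unit-height pure-birth tree, with per-branch
covariance $\begin{pmatrix} \sigma_m^2 & r\sigma_m\sigma_f \\
r\sigma_m\sigma_f & \sigma_f^2\end{pmatrix}$; the 2×2 Cholesky factor is
closed-form, so the degenerate cases (zero rates, |r| = 1) are exact.
Mean syllable number is affine in log m plus noise, floored at 1,
calibrated so that roughly 10 of 17 populations fall in the short-call
band (1.0–2.1 syllables) and the m–syllable rank correlation is ~0.9.

Microsatellite drift uses a Dirichlet approximation: child-node
frequencies are drawn Dirichlet(parent / (drift_scale × branch length)),
which gives the qualitatively correct accumulation of differentiation at
desk-scale speed rather than explicit Wright–Fisher generations. Diploid
genotypes are Hardy–Weinberg draws at the tips with a configurable
missing fraction (default 5%).

Female choice trials are Bernoulli draws with

$$P(\text{leader}) = 0.5 + 0.5\,\text{pref}
  \cdot \operatorname{logit}^{-1}\!\big((f + 2s_\text{soft} - \text{sep})/s_\text{soft}\big).$$

Two design points deserve emphasis. First, the decline is graded (a
smoothed step), because observed preference curves decline gradually and
a hard cutoff would make f-recovery trivially exact. Second, the logistic
midpoint sits two softness scales *beyond* f, so a separation at exactly
f still elicits ≈88% of the full preference. This is the smoothed
analogue of "females prefer the leader when the follower starts within
f": the preference holds throughout the window and decays just beyond
it. Centering the logistic *at* f would put the expected index at f
exactly on the estimator's half-maximum threshold, making the estimate of
an on-grid f a coin flip by construction — the window would be
systematically half-lost. With the offset form, the f estimator recovers
an on-grid true value in ≈98% of replicates at 12 females per population
(≥90% even at the dense low end of the grid).

The generator reproduces the statistical *structure* the analysis
assumes — BM-distributed traits, drifting allele frequencies, graded
preference, delay noise — not features of real data such as
temperature-dependent call rates, within-population trait heterogeneity,
per-population adaptive separation grids, unequal sample sizes, or
linkage between loci. Passing tests therefore validate the machinery and
its calibration, not any empirical claim about real populations.

## Numerical choices and degenerate inputs

* All seeds fan out from one top-level seed through a fixed counter
  scheme (`derive_seed()`), so stages rerun in isolation reproduce the
  pipeline exactly; every derived seed stays below $2^{31}-1$.
* Chorus tie tolerance $10^{-9}$ ms; simultaneous onsets broadcast
  without stimulating each other.
* NJ negative branches: clamp to zero, transfer the deficit to the
  adjacent branch, clamp any residual.
* Contrast standardisation: zero branches inflated to $10^{-8}\times$
  tree height; df still counts them as zero-length.
* The short-call subset regression is skipped (reported as absent) when
  the subset is smaller than 4 populations or degenerate (f is
  grid-valued, so a small subset can have zero variance).
* Empty populations after the missing-data filter, clusters with fewer
  than 2 individuals, all-tied sign tests, and preference curves with no
  positive index all signal explicitly (warning or typed error) rather
  than returning silent values.

## Problem sizes in the test suite

The shipped tests exercise the estimator-recovery loops at 100–200
replicates, the null calibration of the contrast correlation at 1000
replicate trees, the end-to-end signal/null recovery at 100 pipeline runs
each (bootstrap and permutations disabled inside the replication loops),
and the chorus exclusion scan at over $10^5$ simulated calls. These sizes
give Monte-Carlo standard errors comfortably inside the asserted bands
while keeping the default suite in the low minutes on a single core.

## Known limitations

* The linear $D(d)$ is an assumption; only its endpoints and monotonicity
  are empirically grounded. The function is swappable.
* The pipeline's PIC operates on raw m and f values (as in the analysis
  it implements); for strongly lognormal traits, contrasts of logs would
  be better calibrated, and the type-I calibration tests use log traits
  for exactly that reason.
* f estimates are grid-quantized; with tightly clustered true f values,
  many populations collapse onto the same grid value and the contrast
  correlation loses power. This mirrors the real measurement process.
* The Dirichlet drift model has no mutation, so very long branches drift
  toward fixation faster than a mutation-drift process would.
* Cluster assignments in synthetic mode are derived from the generating
  tree (average-linkage cut), standing in for externally supplied
  Bayesian cluster tables; real analyses should supply their own
  cluster map.
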