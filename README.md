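# chorusem

Do male call-timing adjustments coevolve with female preferences for
leading calls? In many chorusing insects and anurans, females prefer the
*leading* of two closely timed calls (a precedence effect), and males
phase-reset their call rhythm when they hear a neighbour, which delays
their next call. `chorusem` implements, end to end, the comparative
analysis that tests whether these two timing parameters match across
genetically isolated populations:

* **m** — the male minimum post-stimulus call delay, estimated per male
  as the mean of his 3 shortest delays in a playback experiment, and per
  population as the mean over males;
* **f** — the female preference window, the largest leader–follower call
  separation at which the preference index
  (p<sub>L</sub> − 0.5)/0.5 stays ≥ 50% of its maximum across tested
  separations.

The package is aimed at behavioural ecologists and evolutionary
biologists working on acoustic communication and comparative methods. It
provides:

* an event-driven **inhibitory-resetting oscillator model** of chorusing
  males — the post-stimulus delay map
  D(d) = m + (T − t − d)(T − m)/(T − t), bounded in [m, T] — with
  call classification (synchronous / following / leading / solo) and a
  precedence-based female choice rule;
* **playback statistics**: delay histograms, m and f estimators, the
  preference index and the one-tailed sign test;
* **population genetics**: GenePop and CSV genotype I/O, the >20%
  missing-data filter, allele frequencies, Nei's D<sub>A</sub> distance,
  neighbor-joining population trees with locus-bootstrap support,
  multi-allelic Weir–Cockerham F<sub>ST</sub> with a permutation test,
  and midpoint rooting;
* **comparative statistics**: Felsenstein's independent contrasts with
  polytomy-adjusted degrees of freedom
  (df = n<sub>contrasts</sub> − 1 − n<sub>zero-length branches</sub>),
  positivized through-origin contrast correlation, OLS and
  reduced-major-axis regression, Spearman correlation, and α-threshold
  stepwise selection;
* a **synthetic-data generator** that emulates the whole study design
  (populations on a tree, correlated Brownian-motion traits on the log
  scale, microsatellite drift, per-male delay records, per-female y-maze
  trials), so the full pipeline is testable and calibrated without field
  data.

See the methods vignette (`vignettes/chorus-coevolution.Rmd`) for the
models, the design decisions and their rationale.

## Worked example

Estimate a male's m from a simulated playback, then run the full
analysis on a synthetic 17-population study:

```r
library(chorusem)

# one male: period 1.2 s, effector delay 24 ms, true m = 300 ms
p <- oscillator_params(free_run_period_T_ms = 1200,
                       effector_delay_t_ms = 24,
                       min_reset_delay_m_ms = 300)
rec <- simulate_male_playback(p, n_stimuli = 40, noise_sd_ms = 10, seed = 42)
estimate_male_m(rec)
#> [1] 306.9724

# the full pipeline: simulate -> estimate m, f -> NJ tree -> contrasts
report <- run_pipeline(seed = 7)
print(report)
#> Analysis report (17 populations, seed 7)
#>   m < f in 11 of 17 populations
#>   raw OLS: m = -107 + 1.51 f (t = 13.85, p = 5.97e-10); Spearman rho = 0.906
#>   PIC (populations): r = 0.902, t = 8.11, df = 15, p = 7.31e-07
#>   PIC (7 clusters): r = 0.990, p = 1.73e-05; mean FST = 0.195 (p = 0.01)
```

Reading the output: across the 17 synthetic populations, m is usually
slightly shorter than f; the raw m–f association is strong (OLS of m on
f, Spearman ρ); and it remains strong after removal of phylogenetic
signal by independent contrasts on the neighbor-joining tree estimated
from the simulated microsatellites, both at the population level and
after averaging populations into 7 genetic clusters, which show
substantial differentiation (mean F<sub>ST</sub>).

`run_pipeline(cfg, seed, out_dir = "...")` also writes `timing.csv`,
`tree.nwk` (with bootstrap supports), `genotypes.gen`, `contrasts.csv`,
`report.json` and `summary.txt`. A thin command-line wrapper is included
at `inst/scripts/chorus-pipeline.R`:

```sh
Rscript inst/scripts/chorus-pipeline.R --config my.yaml --seed 7 --out outdir
```

Configuration is a YAML file whose keys are the fields of
`default_pipeline_config()`.

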