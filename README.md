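# dfspec

Dynamic force spectroscopy (DFS) and binding-probability analysis for
single-molecule AFM experiments on receptor-ligand bonds — the class of
measurement used to rank the stability of cadherin adhesion dimers
(E-cadherin, desmoglein-2, desmocollin-2).

In such an experiment a protein on the AFM tip and its partner on the
substrate are joined through two MW-5000 PEG tethers; the tip is retracted
at constant velocity until the bond ruptures, and the signature non-linear
PEG stretch identifies genuine single-bond events. dfspec implements the
full analysis chain plus a physics-based simulator with ground truth:

- **Bond kinetics.** Bell-Evans slip-bond model,
  `k(F) = k0_off · exp(F·xβ/kBT)`, with the rupture-force density, its
  mode `F* = (kBT/xβ)·ln(r·xβ/(k0_off·kBT))`, exact (truncated) means, and
  an inverse-CDF sampler.
- **Tether mechanics.** Two-state extended freely jointed chain for PEG
  (helical/planar conformer conversion, Kuhn alignment, backbone
  elasticity), with numeric inversion.
- **Simulator.** Retraction curves from the tether + cantilever series
  system with hazard-driven rupture, nonspecific and empty curve classes,
  and Bernoulli contact-trial outcomes — everything reproducible from a
  seed, with per-curve ground truth.
- **Event extraction.** Rupture detection with an explicit, sharp
  censoring point; total-least-squares extended-FJC fits of the stretch
  segment in noise-standardised coordinates (contour length Lc); Gaussian
  contour-length filtering (events within 1 SD of the centre); per-event
  loading rates.
- **Kinetics inference.** k-means grouping of the loading-rate axis,
  per-cluster mean forces, robust (Tukey bisquare) Bell-Evans fits with a
  choice of response curves — including a censored first-passage response
  that accounts for the loading rate varying along each pull — and
  bootstrap confidence intervals.
- **Adhesion frequency.** Binding probabilities with bootstrap standard
  errors, averaged nonspecific baselines, a formal specific-vs-baseline
  comparison, and the Poisson single-bond fraction
  `λe^{-λ}/(1-e^{-λ})`, `λ = -ln(1-p)`.

The methods vignette (`vignettes/dfspec-methods.Rmd`) documents the models,
estimator design decisions, numerical choices and known limitations.

## Worked example

Simulate a Dsc2/Dsg2-like experiment (true `k0_off = 0.20 /s`,
`xβ = 0.3 nm`, six velocities over 100–10,000 nm/s, ~1000 accepted events)
and run the full pipeline (about a minute):

```r
library(dfspec)

kin <- kinetic_params(k0_off = 0.20, x_beta = 0.3)
cfg <- simulation_config(kin, curves_per_velocity = 285,
                         fractions = c(0.9, 0.05, 0.05), seed = 42)
report <- run_pipeline(config = cfg, B = 500, seed = 43)
report
#> Dynamic force spectroscopy report
#>   curves: 1710, detected: 1573, events: 1439, Lc-accepted: 977
#> Lc filter: mu = 80.70 nm, sigma = 5.40 nm; accepted 977 / 1439 events
#> Bell-Evans fit (path response, bisquare): k0_off = 0.1451 1/s, x_beta = 0.3157 nm, 6 clusters
#>   95% CI (bootstrap, B = 500): k0_off [0.09646, 0.249], x_beta [0.2899, 0.3345]
```

The contour-length filter centres on the two-tether contour length
(~80.9 nm) and keeps the one-sigma band; the fitted off-rate for this seed
is 0.145 /s with a 95% bootstrap CI that covers the generating 0.20 /s
(off-rates are exponential-scale parameters — at ~1000 events the interval
is honestly this wide), and the barrier width 0.316 nm sits within 6% of
the generating 0.3 nm.

Adhesion-frequency statistics at a published sample size (5.7% from 2215
contacts):

```r
outcomes <- simulate_binding_outcomes(p = 0.057, n = 2215, seed = 7)
spec <- binding_probability(outcomes, B = 1000, seed = 8)
base <- nonspecific_baseline(simulate_binding_outcomes(0.009, 2000, seed = 9),
                             simulate_binding_outcomes(0.009, 2000, seed = 10),
                             B = 1000, seed = 11)
spec
#> Binding probability: 133 / 2215 trials, p = 6.00% +/- 0.51% (bootstrap s.e., B = 1000)
base
#> Nonspecific baseline: p_ns = 1.05% +/- 0.16% (average of 0.75% and 1.35%)
compare_binding(spec, base)
#> Specific - nonspecific = 4.95% (95% CI [3.94%, 6.00%], z = 9.28): specific
poisson_single_bond_fraction(0.057)
#> [1] 0.9708364
```

So at a ~6% adhesion frequency the bootstrap uncertainty is ±0.5% and more
than 97% of detected events are single-bond ruptures — the operating point
used for single-molecule work.

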