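---
title: "Models and methods behind dfspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dfspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dfspec)
```

dfspec analyses single-molecule AFM dynamic force spectroscopy (DFS)
experiments on receptor-ligand bonds -- the kind of measurement used to
compare the kinetics of cadherin dimers (E-cadherin, desmoglein-2,
desmocollin-2). A bond tethered between an AFM tip and a substrate through
two poly(ethylene glycol) (PEG) spacers is loaded at constant pulling
velocity until it ruptures; rupture forces collected across several
velocities constrain the bond's intrinsic off-rate $k^0_{o\!f\!f}$ and
barrier width $x_\beta$. A second, simpler readout -- the adhesion
frequency, the fraction of tip-surface contacts that produce any bond --
distinguishes specific from nonspecific interactions. This vignette
documents the models, the estimator design, the numerical choices, and what
the simulation-based validation does and does not establish.

## Bond kinetics: the Bell-Evans picture

A tensile force $F$ tilts the dissociation barrier so the off-rate grows
exponentially,
$$k(F) = k^0_{o\!f\!f}\, e^{F x_\beta / k_B T},$$
with `kinetic_params()` holding $(k^0_{o\!f\!f}, x_\beta, k_BT)$. Under a
*constant* loading rate $r$ the rupture-force density is the first-passage
law implemented in `rupture_force_pdf()`; its mode is the classic
most-probable force
$F^*(r) = (k_BT/x_\beta)\,\ln\!\big(r x_\beta/(k^0_{o\!f\!f} k_BT)\big)$
(`most_probable_force()`, clamped at zero below the thermal threshold
$r = k^0_{o\!f\!f} k_BT/x_\beta$, where the unclamped expression turns
negative and loses physical meaning). Three exact auxiliaries matter for
fitting and are worth writing down, with $b = k_BT/x_\beta$ and
$c = k^0_{o\!f\!f} b / r$:

* mean rupture force: $\langle F\rangle = b\, e^{c} E_1(c)$
  (`mean_rupture_force()`; $E_1$ is the exponential integral, via
  `pracma::expint`);
* left-truncated mean: $\mathrm{E}[F \mid F > T] = T + b\, e^{c'}E_1(c')$
  with $c' = c\, e^{T/b}$ -- the observable mean when ruptures below a
  detection limit $T$ are censored;
* inverse-CDF sampling: $F = b \ln\!\big(1 - \ln u /c\big)$ for
  $u \in (0,1]$ (`sample_rupture_force()`).

The mean sits roughly $0.577\,b$ *below* the mode ($e^{c}E_1(c) \to
\ln(1/c) - \gamma$ for small $c$). This is not a pedantic point: cluster
statistics in this pipeline are arithmetic means, and regressing mean forces
on the mode formula inflates $k^0_{o\!f\!f}$ by about $e^\gamma \approx
1.8\times$. `fit_bell_evans()` therefore offers the mean-force curve (and
the path response below) alongside the textbook mode line.

## The tether: two-state extended freely jointed chain

PEG in aqueous buffer stretches in a characteristic way: at rest most
monomers occupy a short helical conformation; force converts them to the
longer planar conformation, while Kuhn-segment alignment and backbone
elasticity add the familiar FJC terms. `tether_model()` implements
$$x(F) = n\left[\frac{l_p}{e^{\Delta G(F)/k_BT}+1} +
\frac{l_h}{e^{-\Delta G(F)/k_BT}+1}\right]
\left(\coth\alpha - \tfrac1\alpha\right) + \frac{nF}{K_s},$$
with $\Delta G(F) = \Delta G_0 k_BT - F (l_p - l_h)$ and
$\alpha = F L_K / k_BT$. The defaults describe *two* MW-5000 PEG spacers in
series (one per surface), the geometry of a specific single-bond rupture:
$n = 226$ monomers, $l_p = 0.358$ nm, $l_h = 0.28$ nm, $\Delta G_0 = 3\,k_BT$,
$L_K = 0.7$ nm, and a per-monomer elasticity giving 150 pN/nm for a single
113-mer. These are literature-typical PEG constants, not quantities measured
by this package, and every one is overridable. The derived contour length
$L_c = n\,l_p \approx 80.9$ nm is the fingerprint that separates specific
events from short nonspecific adhesions. `fjc_force()` inverts $x(F)$ by a
bracketed root-find with Newton polish (round-trip error below $10^{-9}$
relative).

kBT defaults to 4.114 pN nm (25 C) everywhere and is configurable.

## The simulator

`simulate_experiment()` generates retraction curves with full ground truth so
that every downstream stage can be validated without instrument data.
For tethered curves the series system $v t = x_{tether}(F) + F/k_c$ is
solved for $F$ at every sample (dense interpolation table plus vectorised
Newton steps); the bond survives with hazard $k(F(t))$, integrated
trapezoidally, and ruptures where the integral first exceeds a standard
exponential variate. After rupture the force returns to baseline; Gaussian
noise (default SD 5 pN) is added throughout. Empty curves are baseline plus
noise; nonspecific curves use a short tether with $L_c$ uniform on 5-40 nm
and an exponential-tailed detachment force confined below 50 pN.

Defaults define the emulated study conditions: six pulling velocities
log-spaced over 100-10,000 nm/s (the experimental speeds are unpublished;
two decades around 1 um/s is the usual span), a 10 pN/nm cantilever, a
mixture of 6% specific / 2% nonspecific / 92% empty curves (matching ~6%
single-bond adhesion frequency), and 4% relative SD on the per-curve monomer
count. The last emulates PEG polydispersity and attachment geometry and is
what gives the contour-length histogram its finite width; without it the
Gaussian/one-sigma filter stage would be untestable. Two deliberate
departures from naive settings:

* the sampling rate is adaptive, `max(5 kHz, 5 samples per nm x velocity)`:
  a fixed 5 kHz leaves under one sample per nanometre at 10 um/s, which
  quantises rupture forces by >10 pN and biases the fast clusters;
* reproducibility is per curve: one stream drawn from the experiment seed
  assigns classes and per-curve sub-seeds up front, so any curve can be
  regenerated in isolation and reordering cannot change the ensemble.

Simulated rupture ensembles are validated against the *path-hazard law*
(Kolmogorov-Smirnov against the survival computed along the deterministic
noiseless force path) rather than against a fixed-rate Bell-Evans density:
with a compliant tether the loading rate changes severalfold during a pull,
and the fixed-rate density is only an approximation. That distinction drives
much of the estimator design below.

## Event extraction

**Detection** (`detect_rupture()`) locates the largest force discontinuity:
a drop toward baseline exceeding `min_force` within at most three samples of
a lightly smoothed trace (centred 5-sample moving average, used for
detection only), preceded by a rising segment with positive net rise over at
least `min_points` samples or 2% of the trace. The baseline is the median of
the final 10% of the trace. An instantaneous step of height $F$ produces a
maximal 3-sample smoothed drop of only $3F/5$, so the criterion censors
ruptures below about `min_force * 5/3` (~25 pN at the defaults). The
pipeline treats that censoring *explicitly*: `extract_events()` scans for
candidates with a sensitive bar (40% of `min_force`) and then gates events
on a precise force reading at the modelled censor point, which makes the
censoring sharp enough to be carried into the fit as a truncation.

**Rupture force** is read from the near-rupture force-ramp regression line
evaluated at the rupture time, not from the single sample at the detected
index: detection maximises over noisy drops, and the single-sample reading
carries a measured ~+1.6 pN selection offset (at 5 pN noise), while the
ramp-line reading is selection-free with sub-pN noise.

**Tether fitting** (`fit_tether_tls()`) fits the stretch segment with the
extended FJC by total least squares over the monomer count (equivalently
$L_c$) and a distance offset, all other tether parameters held at template
values. Orthogonal distances are measured against a dense model polyline in
compiled code, in *noise-standardised* coordinates: force divided by a
robust per-curve noise estimate from the force-free tail, distance by a
nominal 0.3 nm scanner noise. Raw-coordinate orthogonal regression
implicitly assumes equal noise on both axes; because force is far noisier,
it underweights force residuals on the steep final rise and biases $L_c$
low in a rupture-force-dependent way (up to ~15% for low-force events).
With standardised axes the simulation studies show $L_c$ bias around -1%,
independent of rupture force. Noiseless segments are recovered to 0.1%.

**Contour-length filter** (`filter_by_contour_length()`): the $L_c$
histogram (Freedman-Diaconis bins, at least 8) is fitted with a Gaussian by
least squares on the bin counts -- matching the histogram-based procedure
such experiments report -- and only events within one standard deviation of
the centre are accepted (boundary inclusive). Degenerate inputs (under 10
events, or zero spread) fall back to sample moments with a flag, as does a
failed Gaussian fit.

**Loading rates.** `estimate_loading_rate()` is the windowed
ordinary-least-squares slope of force versus time from `window x` peak force
to rupture. The window defaults to 0.8: with a soft cantilever the series
compliance changes severalfold between 30% and 100% of peak force, so a wide
window badly underestimates the near-rupture rate, while a very narrow one
is noise-dominated; 0.8 keeps the median within ~3% of the instantaneous
rate $v/(1/k_c + \mathrm{d}x/\mathrm{d}F)$ at every velocity. The window
opening is located on a heavily smoothed trace (1% of the trace length);
with light smoothing, noise dips collapse the window to a few samples, and
because non-positive slopes are rejected the surviving estimates are biased
upward. For the pipeline default the per-event *analysis* rate is computed
by that same chain rule ("tether" method), evaluating the tether compliance
from the event's own fitted $L_c$ at its measured rupture force: the slope
estimator is unbiased in the median but has ~25% IQR with a heavy right
tail on single events, and that noise destabilises everything downstream.

## Clustering and the Bell-Evans fit

Events are grouped by one-dimensional k-means (`cluster_loading_rates()`,
50 restarts, deterministic given a seed; verified against exhaustive
enumeration of contiguous 1-D partitions on small instances). The default
pipeline clusters on `log10` *pulling velocity* -- i.e. the six nominal
loading-rate groups -- rather than on the measured per-event rates, which
remains available (`scale = "log10"`). The reason is quantitative: each
event's true near-rupture rate is a function of its own rupture force, so
within a velocity the rate spread is wide whenever rupture happens on the
compliant part of the tether. Clustering on measured rates then (i) sorts
events by force within velocities -- selection on the regressor, inflating
$k^0_{o\!f\!f}$ by up to +50% for fast bonds even with *exact* rates -- and
(ii) under estimator noise stretches the cluster-mean rate span, deflating
it by 15-20% for slow bonds. Grouping on the velocity axis has neither
artefact and coincides with rate k-means whenever the within-velocity spread
is smaller than the group spacing.

Per-cluster statistics are arithmetic means (force, loading rate), the
force SD ($n-1$), and the count. `fit_bell_evans()` fits the cluster points
by iteratively reweighted least squares on $(\log k^0_{o\!f\!f}, \log b)$
with Tukey bisquare weights (tuning constant 4.685, scale $1.4826 \times$
median absolute residual re-estimated per iteration, floored rather than
short-circuited so a gross outlier among otherwise perfectly fitted points
is still rejected), Gauss-Newton steps with step halving, initial values
from the ordinary line of force versus $\ln r$, convergence at $10^{-8}$
relative over at most 100 iterations. Three response curves are available:

* `"mode"` -- the most-probable-force line (for mode-type data);
* `"mean"` -- the exact fixed-rate mean, optionally left-truncated at the
  detection limit;
* `"path"` -- the censored first-passage mean along the reconstructed
  constant-velocity force path: for each cluster the noiseless tether +
  cantilever path $F(t)$ is computed (tether contour length taken from the
  fitted $L_c$ centre), the rupture-time density $S(t)\,k(F(t))$ is
  evaluated on it, and the predicted observable is the hazard-weighted mean
  of the path above the censor.

The pipeline default is `"path"`. The fixed-rate responses are not wrong in
the textbook limit, but under these study conditions (compliant tether,
soft cantilever, censored low forces) fitting cluster means with the
fixed-rate mean curve carries a *deterministic* +30-35% off-rate bias --
measured by fitting the exact censored path means themselves -- because the
loading rate varies along each pull. The path response removes this by
construction and recovers generating parameters exactly in self-consistency
checks.

One observational subtlety remains. The one-sigma contour-length filter
thins low-force events harder than high-force ones (their shorter stretch
segments give noisier $L_c$ estimates), re-weighting each cluster's
observable force distribution upward. The filter's own accept/reject
outcomes make this measurable in-sample, so the pipeline estimates a
logistic acceptance curve $a(F)$ from events in the broad (3-sigma) $L_c$
band and multiplies the path weights by it. Simulation studies show a
residual ~+1 pN excess in the slowest clusters' accepted means that neither
logistic, binned, nor velocity-interaction acceptance models remove; its
consequence is quantified below.

**Bootstrap** (`bootstrap_bell_evans()`): 95% percentile confidence
intervals from `B` (default 1000) replicates that resample events with
replacement *within* their original clusters before recomputing cluster
statistics and refitting; re-clustering each replicate is available
(`mode = "recluster"`) but suffers label-switching instability. `B = 1`
returns a flagged degenerate interval. Coverage of the true off-rate over
200 simulated event-level datasets sits in the nominal 90-99% band.

## Binding statistics

`binding_probability()` estimates the adhesion frequency and its standard
error as the SD of the estimate over bootstrap resamples of the outcome
vector; at the published trial counts (about 1000-2200 contacts at 5-8%
frequency) this reproduces the printed 0.5-0.7% uncertainties and agrees
with the closed-form binomial error within 10%. A zero-event sample is
flagged and accompanied by the rule-of-three bound $3/n$, since the
bootstrap degenerates at $\hat p = 0$. `nonspecific_baseline()` averages the
two standard controls (functionalised tip / bare surface and vice versa)
with errors propagated in quadrature; `compare_binding()` turns the usual
informal bar-plot comparison into a formal two-sided 95% bootstrap test
(labelled an extension of the qualitative published reading).
`poisson_single_bond_fraction()` evaluates
$\lambda e^{-\lambda}/(1-e^{-\lambda})$ with $\lambda = -\ln(1-p)$: at the
5-6% working frequencies used for single-bond work it gives 0.969-0.975,
the quantitative basis for the ">97% single bonds" operating rule (at
exactly 6% the value is 96.9%, marginally below a rounded 97%).

## Problem sizes, accuracy, and limitations

The validation studies simulate at the published scale: ~990, ~725 and ~415
accepted events across six velocities (about 1700, 1600 and 900 curves per
dataset after detection and filtering losses). At that scale, ten-seed
ground-truth studies of the full default pipeline recover:

* $k^0_{o\!f\!f} = 0.20\ \mathrm{s}^{-1}$ at ~990 events: +3% +/- 12%;
* $k^0_{o\!f\!f} = 1.24\ \mathrm{s}^{-1}$ at ~740 events: -10% +/- 6%;
* $k^0_{o\!f\!f} = 1.26\ \mathrm{s}^{-1}$ at ~410 events: -14% +/- 14%.

Two structural limits dominate the fast-bond case: the residual
slow-cluster selection excess noted above (worth roughly -10% on the
off-rate), and the information ceiling of estimating two exponential-scale
parameters from six cluster means of ~70 events each -- the
$k^0_{o\!f\!f}$-$x_\beta$ ridge leaves ~15% estimate SD however the
response is modelled. Individual datasets can therefore miss a 25% recovery
band; the bootstrap intervals, which are wide at 415 events, reflect this
honestly. Barrier widths are recovered within a few percent throughout.

What passing these simulations does *not* show about real data: the
generator draws independent single-bond events with a single tether family,
Gaussian stationary noise, no drift or creep, no multiple simultaneous
tethers, no approach-phase artefacts, and Bell-Evans (single sharp barrier)
kinetics. Catch bonds, heterogeneous barriers (Dudko-Hummer-Szabo
behaviour), worm-like-chain tethers and instrument drift are all outside
the model family, and the pipeline makes no attempt to detect them.

## File formats

Curves travel as one CSV per curve (`time_s, distance_nm, force_pN`) with a
JSON sidecar mapping `curve_id` to velocity, spring constant and condition;
events as a flat CSV; kinetics and binding results as versioned JSON
reports. Units are fixed in the column names; nothing is inferred. Vendor
AFM binary formats are out of scope.
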