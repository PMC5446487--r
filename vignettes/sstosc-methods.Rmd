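---
title: "Modeling trial-by-trial proactive control in the stop-signal task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling trial-by-trial proactive control in the stop-signal task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sstosc)
```

## The problem

In the stop-signal task (SST) a participant responds to frequent go
signals but must withhold the response when an occasional stop signal
follows the go signal after a stop-signal delay (SSD). Although trial
types are drawn independently, people behave as if they track the local
rate of stop signals: reaction time (RT) rises after runs of stop trials
and falls after runs of go trials. `sstosc` packages the machinery
needed to study this *sequential effect* and its electrophysiological
correlates end to end: a dynamic Bayesian observer that turns the
go/stop sequence into a trial-wise stop-signal expectancy, P(stop); a
race-model task simulator whose RTs depend on that expectancy; SSRT
estimation; a single-channel EEG generator with oscillatory bursts tied
to the behavioral variables; Morlet time-frequency decomposition; and a
two-loop permutation framework for trial-by-trial brain-behavior
correlation.

Everything in the package runs on synthetic data; the generators exist
so that each estimator can be exercised against a known ground truth.

## The dynamic Bayesian observer

The observer assumes each trial is a stop trial with probability
$r_k$, and that $r_k$ persists from trial to trial with probability
$\alpha$ or is resampled from a fixed beta prior $\pi(r)$ with
probability $1 - \alpha$:

$$p(r_k \mid s_{k-1}) = \alpha \, p(r_{k-1} \mid s_{k-1})
  + (1 - \alpha)\, \pi(r_k),$$

with $\pi$ a beta density parameterized by its mean $pm = a/(a+b)$ and
concentration $sc = a + b$. After each trial the belief is updated by
Bayes' rule with the Bernoulli likelihood of the observed type, and the
next trial's P(stop) is read out from the predictive distribution
*before* the outcome is seen. On stop trials the Bayesian surprise
(prediction error) is $1 - \mathrm{P(stop)}$.

The transition mixture destroys beta conjugacy, so the belief lives on a
fixed midpoint grid over $(0,1)$ (default 200 cells). Two readouts are
provided: the predictive mean and the maximum a posteriori (MAP) point
(default). MAP ties are broken toward the lowest rate, a deterministic
choice that only matters on degenerate grids. The first trial's P(stop)
is the readout of the generic prior: before any outcome has been seen
the generic prior is the only belief available. The transition is
first-order Markov; higher-order history effects are out of scope.

Numerical guarantees, enforced by tests: the belief mass renormalizes to
1 at every step; at $\alpha = 1$ the mean readout reproduces the
beta-Bernoulli closed form to within $10^{-3}$ at the default grid; a
200-cell grid agrees with a 4000-cell oracle to within $10^{-3}$ for the
mean readout. The MAP readout is quantized at the grid resolution, so
its oracle agreement is bounded by one coarse cell (1/200) rather than
$10^{-3}$ — an intrinsic property of reading out an argmax on a grid.

```{r observer}
p <- observer_params(alpha = 0.78, pm = 0.14, sc = 10)
tr <- run_sequence(c(0, 0, 1, 0, 1, 0, 0), p)
round(tr$pstop, 3)
```

## Fitting the observer to behavior

Per subject, a grid search over $\alpha \in \{0.02, \dots, 0.98\}$
(step 0.02) and $pm \in \{0.01, \dots, 0.49\}$ (step 0.02), with
$sc = 10$ fixed, maximizes the Pearson correlation between the P(stop)
trace and RT. The correlation uses successful go trials only: stop
trials drive the observer's sequence but contribute no RT, and
stop-error RTs are censored by the race, which would bias the
correlation. Exact ties in the argmax are broken toward larger
$\alpha$, then larger $pm$ (deterministic; ties are measure-zero in
practice). Group-level analyses use the arithmetic means of the fitted
$\alpha$ and $pm$ to recompute every subject's trace, so all subjects'
EEG analyses share one observer.

Parameter recovery on the calibrated generator (400 trials) is within
the grid step: the median over 20 replicate fits recovers
$(\alpha, pm) = (0.78, 0.14)$ to within $\pm 0.06$.

## The race-model task simulator

Trial types are i.i.d. Bernoulli (25% stop), foreperiods uniform on
1-3 s. The responder's go process finishes at

$$T_{go} = 345 + 300 \cdot \mathrm{P(stop)}_k + \varepsilon,
  \qquad \varepsilon \sim \mathcal N(0, 60^2) \text{ ms},$$

truncated by the 1 s response window. The slope of 300 ms per unit
P(stop) and the 60 ms noise are the calibration under which the
within-subject sequential correlation lands near 0.29 with the MAP
trace, whose across-trial SD is about 0.06. On stop trials the stop
process finishes at SSD + 216 ms and the earlier process wins; the SSD
follows a one-up-one-down staircase (start 200 ms, steps of 64 ms,
clipped to the response window), whose fixed point is 50% stop success.
A 1.6% attentional-lapse rate sends the go process beyond the window,
producing realistic go omissions; the lapse is realized through the
same window-truncation rule that censors slow finishes, rather than as
a separate outcome label. SSD clipping at 0 and at the window is our
choice for the rare excursions a long error run can produce.

One deliberate asymmetry deserves note. With the MAP readout the
P(stop) trace centers near 0.10, so mean simulated go-RT sits near
375 ms and mean stop-error RT (the truncated lower tail of the go
finishing-time distribution) near 340 ms; with the mean readout the
trace centers near 0.165 and those values move to roughly 395 and
360 ms. No single readout reproduces both the sequential-effect
correlation (which needs the MAP trace's variability) and the absolute
stop-error RT level at this intercept. The package keeps the MAP
readout as the default everywhere because the readout, not the RT
intercept, is the scientifically motivated choice, and reports absolute
RT levels as what they are.

## SSRT via the inhibition function

The critical SSD is estimated by maximum likelihood from all
staircase-generated stop trials: a two-parameter cumulative-Gaussian
inhibition function $P(\text{stop success} \mid \text{SSD})$ fitted as
a probit Bernoulli GLM (success probability decreasing in SSD), whose
50% point is the critical SSD. SSRT is the median successful-go RT
minus the critical SSD. A logistic link is available
(`family = "logistic"`); the two agree within a few ms on the
simulator because the staircase concentrates SSDs near the 50% point,
where the families coincide. On the default cohort the estimator
recovers the generative 216 ms latency to within a few ms.

```{r ssrt}
cohort <- simulate_cohort(6L, seed = 12L)
round(mean(vapply(cohort, function(tb) ssrt(tb), numeric(1))), 1)
```

## The synthetic EEG

Each event-locked epoch (fixation, go, or stop lock; -0.5 to 1 s at
250 Hz by default) is 1/f background noise — white noise shaped in the
spectral domain, exponent 1 — plus one Gaussian-windowed sinusoid whose
amplitude is $\max(0, A_0 + g \, z)$, with $z$ the z-scored behavioral
covariate of that lock: P(stop) at fixation (4 Hz burst near 100 ms),
RT at go (4 Hz, ~200-700 ms, negative gain), prediction error at stop
(16 Hz, ~300-400 ms). Amplitude rather than power is linear in the
covariate so the planted association is a rank (Spearman) relation,
invariant to the monotone amplitude-to-power map. A configurable
fraction of trials (5% by default) receives a square pulse larger than
the 150 uV peak-to-peak rejection threshold, so the artifact-rejection
rule has real work to do; epochs are generated with a 2 s buffer on
each side so that time-frequency decomposition can run on buffered data
and crop, keeping edge ramps out of the analysis window.

The burst gains are pilot-calibrated, and the calibration faces a real
constraint: the behavioral coupling between P(stop) and RT (r ~ 0.29)
leaks every planted effect into the crossed covariate-lock pair at
about 0.29 times its strength. Strong gains make the planted pairs
trivially detectable but push the leaked correlations above the
cluster-forming threshold at the group level, producing significant
clusters in pairs that should stay empty. The defaults (gain 1.1 uV
per covariate SD for the fixation burst and 0.65 uV for the go burst,
against a 10 uV background; gain 3 for the stop-locked burst, which
has no tested crossed pair and only ~100 trials) sit in the window
where the three planted pairs are detected and the two crossed pairs
usually are not. The go gain is lower than the fixation gain because
its leak path (P(stop) against go-locked power) proved the more
sensitive one in pilot cohorts, while the RT effect itself — a
continuous covariate over a broad burst — stays detectable at the
weaker gain.
What passing tests show, therefore, is that the analysis separates
effects whose true correlates are separated in time-frequency given
this leakage level — not that the analysis would null a crossed pair
whose physiological coupling is stronger than behavioral.

The generator is deliberately minimal: one channel (the target
statistics are at a single electrode), no phase-locked evoked
components, no realistic artifact topography, no spatial structure.
Passing tests say nothing about volume conduction, reference choice, or
ICA-based cleaning of real recordings.

## Morlet time-frequency decomposition

59 logarithmically spaced frequencies between 2 and 50 Hz. The temporal
FWHM of the Gaussian amplitude envelope is 1 period at the lowest bin
and 4 periods at the highest, interpolated linearly across bin index
(equivalently log frequency); linear-in-Hz interpolation is available
behind a flag. FWHM converts to the Gaussian SD as
$\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$. Wavelets are normalized so
a unit-amplitude sinusoid yields peak power 1 at every bin, making
power comparable across frequencies. Convolution runs by FFT on the
buffered epoch and is cropped to the analysis window afterwards.

Baseline correction references each trial and frequency to the mean
power in -300 to -100 ms; the default is relative change ($P/B - 1$),
with subtraction behind a flag, and a second application is an error.
Which of the two the original analysis platform used is not stated in
the literature this design follows; relative change is the common
platform default and is what the test suite exercises.

## Two-loop brain-behavior statistics

Loop one, within subject: per time-frequency bin, the Spearman
correlation between single-trial power and the covariate, standardized
into a z-value against a null built from 1000 random trial
permutations (drawn independently; permutations are applied to the
retained, artifact-free trials only). Loop two, across subjects: a
two-tailed one-sample t test per bin on the z-maps; suprathreshold bins
(cluster-forming threshold p < 0.02, 0.005, or 0.001) are clustered by
4-neighbor adjacency (8-neighbor behind a flag), separately per sign;
the cluster statistic is the summed t. The group null records, for each
of 2000 random whole-map sign flips of subjects, the largest absolute
summed t over suprathreshold clusters of either sign — sign flipping is
the standard exchangeability argument for a one-sample test against
zero, and taking the global maximum across both signs controls the
two-tailed family-wise error. `p_perm` is the fraction of null maxima
at or above the observed cluster statistic, floored at 1/2000, so p
values move in steps of 1/2000. Observed power re-runs the null 200
times on fixed data and reports the fraction of repeats with
`p_perm < 0.05`.

Calibration, enforced by tests: on pure-noise z-maps (18 subjects,
40 x 50 bins) the family-wise false-positive rate at nominal 0.05 lies
in [0.02, 0.09] over 200 simulated datasets; the planted fixation
effect at default gains is detected in at least 80% of 20 replicate
cohorts.

Two follow-up statistics mirror the analyses such a study reports: the
trial-wise Pearson correlation between the mean power of two clusters
(e.g. the P(stop) and RT clusters), tested across subjects with a
two-tailed Wilcoxon signed-rank test (with a Kolmogorov-Smirnov
normality check reported alongside, since the signed-rank test is the
fallback for non-normal coefficients); and residualization of
stop-locked power against the stop-success/stop-error condition means,
which removes exactly the outcome-driven component before correlating
with prediction error.

## The full study

`run_study()` chains everything: simulate the cohort, fit the observer
per subject, recompute traces with the group-averaged parameters,
simulate and decompose the three EEG streams, and test the five
covariate-lock pairs — P(stop) x fixation, RT x go, PE x stop (planted)
and P(stop) x go, RT x fixation (expected empty). The default
cluster-forming threshold in the study pipeline is 0.005: the leakage
analysis above showed that 0.02 lets the crossed-pair leak (group
t ~ 2-2.5) form clusters intermittently, while the planted effects
(group t ~ 6 and above) clear the stricter threshold comfortably.
All randomness derives from one master seed: subject $i$ draws its
task sequence from `seed + 1000 i`, its responder noise from the
following stream, and its three EEG streams from fixed per-lock
offsets, so any stage can be reproduced in isolation.

## Problem sizes used by the test suite

Unit and property tests run the generators at reduced size chosen to
keep each property comfortably measurable: cohorts of 6-8 subjects with
150-400 trials for behavioral properties; EEG fixtures at 125 Hz with
15 frequencies to 30 Hz and 5-fold time decimation; 200-1000
permutations where a null distribution is needed. The acceptance-style
checks simulate the full 18 x 400 cohort for behavioral quantities, 200
null cohorts of 18 subjects at 40 x 50 bins for the type-I calibration,
and 20 replicate 18-subject cohorts at reduced spectral resolution for
the detection rate. The vignette and README show outputs from the same
code paths at these sizes.

## Known limitations

* The observer's transition model is first-order; slow drifts in
  strategy or motivation are not modeled.
* The generator produces no post-error slowing beyond what the observer
  induces, and no reward asymmetry between stop-success and stop-error.
* The inhibition-function family the original ML procedure used is not
  documented; the cumulative Gaussian is a choice, and the logistic
  alternative is provided to show the estimate is family-robust on
  staircase data.
* Absolute RT levels under the MAP readout sit below the mean-readout
  levels (see the race-model section); analyses that depend on absolute
  stop-error RT should note the readout.
* The EEG is single-channel and stationary apart from the planted
  bursts; nothing here validates spatial inference.
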