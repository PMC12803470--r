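---
title: "State-space modelling of zebrafish locomotion and ARTR activity"
author: "swimHMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-space modelling of zebrafish locomotion and ARTR activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimHMM)
```

## The scientific problem

Larval zebrafish explore their environment through discrete swim bouts
(~100 ms events triggered at roughly 1–2 Hz). Each bout reorients the
animal by an angle $\delta\theta_n$ (degrees, positive = left turn), and
the distribution of these angles is trimodal: a central mode of small
"forward" reorientations flanked by two turn modes. The classical analysis
thresholds $|\delta\theta_n|$ at $\delta\theta_0 = 10^\circ$ to label each
bout forward (F), left (L) or right (R) and fits a 3-state Markov chain to
the labels. The threshold is arbitrary, and mislabeling near it breaks up
genuine turn streaks, which distorts persistence statistics.

swimHMM instead treats the bout type as a *hidden* state: a three-state
hidden Markov model whose emissions are

$$E(\delta\theta \mid F) = \mathcal{N}(\delta\theta;\, 0, \sigma), \qquad
  E(\delta\theta \mid L) = \Gamma(+\delta\theta;\, \alpha, \theta), \qquad
  E(\delta\theta \mid R) = \Gamma(-\delta\theta;\, \alpha, \theta),$$

with $\alpha > 1$ and $\theta > 0$ (both turn parameters shared between L
and R under the non-handedness hypothesis). Left–right symmetry is also
imposed on the transition matrix:
$P(F\!\to\!L) = P(F\!\to\!R)$, $P(L\!\to\!L) = P(R\!\to\!R)$,
$P(L\!\to\!R) = P(R\!\to\!L)$, $P(L\!\to\!F) = P(R\!\to\!F)$. A symmetric
chain has stationary $P(L) = P(R)$ exactly.

The same machinery is applied to neural data: binarized spike rasters of
the Anterior Rhombencephalic Turning Region (ARTR), the bilateral hindbrain
circuit that selects turn direction. There the emission model is a product
of independent per-neuron Bernoulli laws,
$P(\sigma_1,\dots,\sigma_N \mid s) = \prod_i e^{h_i^s \sigma_i}/(1+e^{h_i^s})$,
with one local field $h_i^s$ per neuron and state. After training, states
are labeled by the lateralized excitability
$\Delta h_s = \langle \ell(h_i^s)\rangle_{i \in \text{left}} -
\langle \ell(h_i^s)\rangle_{i \in \text{right}}$ (logistic $\ell$), ordered
$\Delta h_L > \Delta h_F > \Delta h_R$. No handedness constraint is imposed
on the neural model.

## Training

Both models are trained by Baum–Welch (EM) with an exact forward–backward
E-step, run per trajectory/recording and pooled. Stopping rule: at most 500
iterations, earlier if the total log-likelihood gains less than $10^{-6}$
in one iteration. The log-likelihood trace is checked to be non-decreasing
at every iteration and training aborts if it ever drops beyond numerical
noise — EM's monotonicity is treated as an invariant, not a hope.

M-steps are closed-form except for the turn shape: transitions come from
expected counts (tied entries averaged under the symmetry constraints),
$\sigma$ from the posterior-weighted second moment about zero, and
$(\alpha, \theta)$ from a posterior-weighted Gamma maximum likelihood on
angle magnitudes — Newton iterations on the digamma equation from a
method-of-moments start, with $\alpha$ clamped to $1 + 10^{-6}$ (and
$\theta$ maximized given $\alpha$) if the unconstrained solution falls
below the $\alpha > 1$ constraint. Neural fields are the logit of the
posterior-weighted mean activity, clipped to $[10^{-6}, 1-10^{-6}]$ so
fields stay finite when a neuron is silent or saturated in a state.

Initialization is config-exposed. The first restart starts from a static
(no-dynamics) fit of the three-component Normal + signed-Gamma mixture to
the pooled angles plus symmetrized threshold-label transition counts; this
places EM near the relevant basin. Later restarts use jittered
moment-matching on the $10^\circ$ threshold labels and random
(symmetrized) Dirichlet transitions. Five restarts is the default; the
best final log-likelihood wins, and a restart that starves a state (a
posterior column with essentially zero mass) is discarded. Out-of-support
emission log-densities use a finite floor of $-10^6$ rather than
$-\infty$, keeping the dynamic programming NaN-free; the forward state's
full support guarantees a finite per-frame likelihood.

Viterbi decoding breaks ties toward the fixed state order F < L < R. All
angles (and the Gamma scale $\theta$) are in degrees throughout; degrees
are converted to radians only inside the trigonometric step of trajectory
reconstruction.

## Persistence and the stubbornness factor

Trajectories decompose into streaks (maximal runs) of forward bouts and of
same-direction turns. Streak-length distributions decay exponentially,
$P(\ell) \propto e^{-\ell/\ell_1}$; $\ell_1$ is fitted as $-1/\text{slope}$
of log-counts vs $\ell$ over bins with at least 5 runs. Within a Markov
model $\ell_1(s) = -1/\ln P(s \to s)$, and the memoryless null (transitions
equal to stationary frequencies) gives $\ell_0(s) = -1/\ln P(s)$; the ratio
$\ell_1/\ell_0$ quantifies the memory contribution to persistence. Runs
truncated by trajectory ends are included by default; a flag excludes them
for sensitivity analysis (the difference is a boundary effect that vanishes
with trajectory length).

The stubbornness factor $f_q$ is the ratio of same-direction to
opposite-direction turn pairs separated by exactly $q$ forward bouts,
pooled over trajectories with all overlapping q-plets counted. For any
non-handed 3-state Markov chain the transition-matrix form of $f_q$ equals
1 exactly for every $q \ge 1$ (the $P(F\to F)^q$ factor cancels and the
symmetry ties collapse the ratio), so empirical $f_q > 1$ at $q \ge 1$ is a
direct Markov-violation signal. The reported uncertainty is
$\Delta f_q = f_q\sqrt{\tfrac{1}{N_=+N_\ne}\left(\tfrac{N_=}{N_\ne} +
\tfrac{N_\ne}{N_=}\right)}$; a bootstrap over q-plets shows this is within
a factor $\sqrt 2$ of the resampling standard deviation (they coincide when
one count dominates), which is adequate for the +/- bands it is used for.

## Linking the neural and behavioral clocks

ARTR dynamics under the microscope are slower than free-swimming behavior.
The temporal scaling factor $f_{N/B}$ is found by pooling the sojourn times
of all three states within each modality and minimizing
$\mathrm{RMSE}(Q(\Delta t^b), f \cdot Q(\Delta t^n))$ over $f \in [0,1]$
(grid step 0.001 with local refinement), where $Q$ are matched quantile
vectors on 101 evenly spaced probabilities. A sojourn is the last-minus-
first timestamp of a maximal run, so single-frame runs contribute zero
seconds; they are retained by default. Sojourns are pooled across
recordings before quantile computation. The per-frame neural transition
matrix at frame rate $\nu$ is then mapped onto the bout clock by the
nearest-integer matrix power $P^* = P_n^{\lfloor \nu f_{N/B} \rceil}$
(halves away from zero), which preserves row-stochasticity and the
stationary distribution exactly.

## The synthetic-data generator

Every stage is exercised on generated data with known ground truth. The
defaults are the study conditions this package emulates:

* behavioral emissions $\sigma = 15^\circ$, $\alpha = 2$, $\theta = 10^\circ$;
  symmetric transitions with $P(s \to s) = 0.5$ and equal off-diagonals;
* inter-bout intervals $\delta t_n \sim$ Gamma(mean 1 s, shape 4) and
  travel distances $d_n \sim$ LogNormal(median 1 mm, $\sigma_{\log} = 0.5$)
  — positive, right-skewed stand-ins for the empirical shapes (the
  empirical families are not published quantities, so these are declared
  defaults a config can override, not estimates);
* a lateralized neural population (fields $\pm 2$ in the turn states on the
  ipsi/contralateral side, $-1$ in the balanced forward state) at
  $\nu = 5.9$ Hz, around 300 neurons and ~20 min recordings at dataset
  scale;
* one root seed spawning an independent substream per trajectory and per
  neuron, so enlarging a dataset never perturbs earlier draws.

For the linked behavioral + neural world the generator must realize two
relations at once: neural dwell times equal behavioral dwell times divided
by $f_{N/B}$, and the frame-exponent rescaling with $k = \lfloor \nu f
\rceil$ maps the neural matrix back onto the behavioral one. It therefore
sets $P_n = P_b^{1/k}$ (principal matrix root) and puts the bout clock at a
mean inter-bout interval of $f \cdot k / \nu$, the unique choice consistent
with both. Two further numerical points, both documented design choices:

* The matrix-root construction matches dwell-time *distributions* only in
  the continuous-dwell limit. For weakly persistent chains the geometric
  discreteness biases the quantile-matched $f$ upward (an analytic quantile
  calculation puts the bias at ~0.06–0.18 for $P(s\to s) = 0.5$, under 0.01
  from $P(s \to s) \ge 0.8$). The linked-world default therefore uses a
  persistent behavioral matrix ($P(s\to s) = 0.8$, direct switch 0.05),
  which also matches the slow, seconds-scale ARTR alternation this world
  emulates.
* Interval rescaling direction: behavioral intervals are *divided* by
  $f_{N/B}$ when bouts are placed on the neural clock — neural dynamics are
  slower, so a behavioral second spans $1/f$ seconds of recording.

What passing on synthetic data does *not* show: the generator draws
intervals and distances i.i.d. (no dependence on bout type), neurons are
conditionally independent given the state (no within-state correlations
from recurrent circuitry, so ipsilateral covariances are underestimated by
construction — one test demonstrates exactly this failure mode), there is
no arena geometry, no region-of-interest censoring of stubborn fish, and no
temperature covariate. Real-data quantities that depend on those features
(for example the published streak-length contrast between labeling methods
at 22 °C, or the 14/18 identification count) are reproducible only with the
archived recordings, not from this generator.

## Trajectory synthesis and the MSR

A neural state sequence (decoded or sampled) is converted to a trajectory
by (i) drawing bout times from the empirical inter-bout-interval pool
rescaled to the neural clock, (ii) assigning each bout the neural state of
the last frame at or before it, (iii) drawing $\delta\theta_n$ from the
behavioral emission of that state and $d_n$ from the empirical distance
pool, and (iv) accumulating headings and positions,
$x_k = \sum_{n \le k} d_n \cos\theta_n$ with
$\theta_n = \sum_{n' \le n} \delta\theta_{n'}$ (bout $n$'s reorientation
applies before its displacement).

Orientational diffusion is quantified by the Mean Square Reorientation
$\mathrm{MSR}(q) = \langle(\theta_{n+q} - \theta_n)^2\rangle$, computed on
mean-centered angles (a constant angular bias would otherwise masquerade as
diffusion), averaged over windows within each trajectory and then over
trajectories, never across boundaries. The decomposition
$\mathrm{MSR}(q) = \text{diffusive} + \text{correlation}$ uses the same
window averaging on both terms, so the identity holds to machine precision:
the diffusive term is the window mean square ($\approx q\,\mathrm{Var}$)
and the correlation term twice the summed within-window cross products.
A within-trajectory shuffle control destroys the correlation term while
preserving the angle multiset.

## Individual phenotyping

Long single-fish sessions are split into contiguous equal-duration chunks
(10 chunks of ~12 min for a 2 h session), each trajectory assigned to the
chunk containing its start and never split. Per-fish models (symmetric, as
for pooled data) are compared through the relative likelihood matrix
$rL_{i,j} = L(\text{data}_i \mid \text{model}_j) / L(\text{data}_i \mid
\text{model}_i)$, whose diagonal is 1 by construction; each model
identifies the fish with the highest test likelihood. Likelihoods are
compared as per-dataset totals (the ratio definition), with a per-bout
normalized variant behind a flag since fish differ in bout counts. The
identification curve repeats random 50/50 train/test splits, subsampling a
fraction of test *trajectories* (the unit of likelihood independence).

## Worked example

```{r example, eval = FALSE}
set.seed(1)
gt <- groundTruth()                       # study-condition defaults
sess <- genBehaviorSessions(gt, nTraj = 300, lengthLaw = 60, seed = 1)
angles <- lapply(sess$bouts, `[[`, "dtheta_deg")

fit <- fitBehaviorHMM(angles, hmmConfig(restarts = 3, seed = 1))
fit

labels <- lapply(angles, function(a) viterbiDecode(a, fit))
persistenceReport(labels, transitionMatrix(fit), qMax = 2)
```

## Problem sizes used by the test suite

The suite validates at the scales the analysis is meant for: $10^5$ bouts
(5 restarts) for behavioral parameter recovery, $10^4$ frames by 60
neurons for neural recovery, $10^6$ steps for stationary-distribution
simulation checks, 60 simulated minutes at 5.9 Hz (and 300 trajectories)
for the bridge, and exhaustive-enumeration oracles at $T \le 8$. Sizes
were chosen so Monte-Carlo error sits well inside the asserted tolerances;
one documented exception is the 3%-relative transition-recovery band at
$10^5$ bouts, which the flat likelihood of the overlapping-emission study
conditions does not support (the corresponding assertion fails by a small
margin while the emission parameters recover to ~1%).

## Known limitations

* The symmetric three-state HMM is a model of spontaneous exploration;
  sensory-driven asymmetries (phototaxis, gradients) are out of scope.
* With strongly overlapping emissions (the study-condition defaults), the
  likelihood is flat in some transition directions; transition estimates
  then carry several times the naive binomial standard error. Parameter
  recovery tests at $10^5$ bouts reflect this.
* Bernoulli emissions ignore within-state neuron–neuron coupling; models
  requiring it (e.g. Ising-type emissions) are deliberately not included.
* No continuous-time embedding of transition matrices: rescaling uses
  discrete nearest-integer matrix powers only.
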