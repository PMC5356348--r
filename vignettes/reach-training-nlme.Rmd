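---
title: "Decomposing reach-training movement times into learning and fatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing reach-training movement times into learning and fatigue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachnlme)
```

## The model

During an intensive reach-training session a participant repeats several
hundred point-to-point arm movements. Movement time (MT) — the interval
between the fingertip's speed first exceeding 5% of its peak and falling
back below that threshold inside the target disk — typically improves
quickly at first, then plateaus, and for impaired participants often
*worsens* towards the end of the session. `reachnlme` models the
trial-by-trial MT of subject $i$ on the $t$-th movement to target $k$ as

$$
MT_{i,t,k} = A_i\,e^{-t/\tau_i} + C_i\,t + D_{i,k} + \varepsilon_{i,t,k},
\qquad \varepsilon \sim \mathcal N(0, \sigma^2),
$$

the sum of a decreasing exponential (what is *learned*: amplitude $A_i$
in ms, decay rate $\tau_i$ in trials), an increasing linear term
(activity-dependent fatigue and other learning-unrelated decrements:
slope $C_i$ in ms/trial), and a per-target asymptote $D_{i,k}$ (ms),
because targets at different angles have systematically different MTs.
The trial index $t$ is the **per-target occurrence index** (1..120 in a
600-movement session with five targets), not the global trial number;
this matters because it sets the scale of $\tau$.

Each parameter has a population fixed effect and a per-subject random
effect: $A$ and $\tau$ are log-normal (positive, right-skewed; the
population median is the natural location summary), $C$ and $D_k$ are
normal ($C$ must be free to be zero or negative — unimpaired
participants fatigue little or not at all). The random-effect
covariance is diagonal: with eight structural parameters and cohorts of
10–26 subjects, a full covariance would not be estimable.

The decomposition separates *learning* from *performance*. With
$\bar D_i = \mathrm{mean}_k D_{i,k}$ and $m_i(t) = A_i e^{-t/\tau_i} +
C_i t + \bar D_i$ evaluated over $t = 1..T$:

* initial performance $= m_i(1)$;
* amount of learning $= A_i(e^{-1/\tau_i} - e^{-T/\tau_i})$, the drop of
  the exponential component alone;
* final fatigue $= C_i T$;
* normalized learning $=$ amount of learning / initial performance;
* normalized performance change $= (m_i(1) - m_i(T))/m_i(1)$, the *net*
  modelled change.

The identity
$\text{norm. perf. change} = \text{norm. learning} - C_i(T-1)/m_i(1)$
holds exactly, so the two coincide when $C_i = 0$ and diverge whenever
fatigue is present — the reason a subject can look flat or worsening
during training while having learned a great deal, which resurfaces in
the rested state of a delayed retention test.

## What the synthetic-data generator emulates

No trial-level data accompany the analyses this package operationalises,
so every stage is exercised on synthetic cohorts from
`simulate_cohort()`. The defaults are the study conditions:

| quantity | stroke | control | source of the default |
|---|---|---|---|
| subjects | 16 | 10 | cohort sizes |
| $A$ median (ms) | 279 | 128 | reported group medians |
| $\tau$ median (trials) | 64 | 36 | reported group medians |
| $C$ median (ms/trial) | 1.11 | 0.12 | reported group medians |
| $D_1 \to D_5$ medians (ms) | 328→432 | 227→293 | reported endpoints, interior targets linearly interpolated |
| dispersions | from reported 25–75% IQRs | idem | `iqr_dispersion()` |
| residual SD $\sigma$ (ms) | 76 | 24 | reported group RMSE |

Dispersion calibration uses
$\mathrm{sdlog} = (\ln q_{75} - \ln q_{25})/(2\,z_{0.75})$ for the
log-normal parameters and the analogous identity for the normal ones.
Note that a median-anchored log-normal reproduces the IQR *ratio*
exactly but not both reported quartiles, which are asymmetric about the
median on the log scale; the generator anchors the median (the summary
the analysis compares) and accepts quartiles of, e.g., [190, 411] ms
instead of [210, 455] ms for stroke $A$.

Sessions are 120 trials to each of 5 targets in pseudo-random order with
exact per-target counts and, by default, no immediate target repeats
(the next target is always one of the other four). Observed MTs are the
structural prediction plus Gaussian noise, floored at 50 ms so that
heavy-noise configurations cannot produce non-physical values.

Test phases are a **synthetic-only construct**: no generative link
between training and retention is reported anywhere, so the generator
invents one, parameterized by a single retention fraction $\rho$
(default 0.8). The pre-training mean MT is $\mathrm{mean}_k(A_i +
D_{ik})$ — nothing learned yet, but also no fatigue, because tests are
short and rested — and the 1-month mean is $\mathrm{mean}_k D_{ik} +
(1-\rho)A_i$, each plus noise with SD `retention_noise_sd` (defaults 15
ms stroke / 5 ms control, the order of the standard error of a short
test block's mean at the training residual noise). Long-term change is
therefore driven by the learning amplitude by construction. Real
retention involves consolidation, forgetting and test-specific effects
that this construct does not capture; passing tests show the analysis
chain behaves correctly *given* this link, not that the link is true.

Trajectories for the kinematics module are planar minimum-jerk reaches,
$x(s) = d(10s^3 - 15s^4 + 6s^5)$, with stationary padding and optional
isotropic sensor noise. Their returned ground truth is the exact
5%-of-peak crossing span of the continuous speed profile — the root of
$30 s^2(1-s)^2 = 0.05 \times 1.875$, a span of 0.8811 of the movement
duration. Real reaches are not minimum-jerk (impaired reaches in
particular have multi-peaked speed profiles); the fixture tests the
extractor's threshold logic, not biological realism.

## Movement-time extraction

Position channels are low-pass filtered with a second-order Butterworth
at 5 Hz. Filtering is zero-phase (forward–backward) by default: a causal
pass would delay threshold crossings by a filter-dependent lag and bias
every MT late; `zero_phase = FALSE` restores the causal variant for
sensitivity analysis. The filter is applied over odd-reflection padding
(about 3 cutoff periods) because the underlying routines assume zero
signal outside the record, which produces large transients at a trace
that ends away from the origin. Speed is the Euclidean norm of
componentwise central differences (one-sided at the endpoints; a
forward-difference option exists and differs negligibly at 120 Hz).

Onset is the first sample above 5% of the trace's peak speed. The offset
search is restricted to samples at or after the global peak — otherwise
sub-threshold jitter before movement onset could terminate the segment —
and requires both speed below threshold *and* the fingertip inside the
target disk, so a mid-movement dip outside the target (common in
corrective, multi-peak reaches) does not end the measurement. Movements
longer than 5 s are flagged as timeouts. The sampling rate is
configurable with a 120 Hz default, typical of the magnetic-tracker
class of devices used for this kind of recording.

Left-hemiparesis records are mirrored onto the right-side frame
(`flip_left_hemiparesis()`): target $k \mapsto 6-k$ and trajectory $x$
reflected about the home-position sagittal axis. The flip is an
involution and cannot change any MT value.

## Estimation: SAEM with empirical-Bayes subject estimates

`fit_nlme()` maximizes the marginal likelihood by stochastic
approximation EM on the transformed scale $\phi = (\log A, \log\tau, C,
D_1..D_5)$: per iteration, a Metropolis chain per subject samples the
random effects, then Gaussian sufficient statistics are updated with
step size 1 for 300 burn-in iterations and $1/m^{0.7}$ for 200
averaging iterations. Per-subject estimates are empirical-Bayes
posterior modes under the fitted population distribution, and group
RMSEs are computed from those modes.

This model's likelihood has a hard geometric feature that shaped most
numerical choices: for slow learners ($\tau$ comparable to or larger
than $T$) the exponential is nearly linear over the session, so $A$,
$\tau$, $C$ and $D$ trade off along a long, curved, one-sided-flat
ridge. Individual least-squares solutions scatter enormously along it,
and a sampler with a weak prior drifts into it. Concretely:

* **Proposals follow the ridge.** The random-walk kernel draws from a
  full-covariance Gaussian shaped by the per-subject posterior Hessian
  (likelihood curvature plus prior), refreshed three times during
  burn-in; a diagonal proposal cannot move along the correlated ridge.
  Each iteration also makes one independence proposal from the current
  random-effect distribution, accepted on the likelihood ratio alone.
  Proposal scales adapt towards 30% acceptance during burn-in only.
* **Initialization stays on the data manifold.** Stage one fits each
  subject by profiled least squares ($\tau$ on a log grid then golden
  section, the conditionally linear terms by exact linear solves; $\tau$
  bounded to $[1, 10T]$, amplitude floored at 1 ms for flat learners
  with the linear terms refitted). Stage two anchors the population
  $\tau$ at the cross-subject median and solves the remaining fixed
  effects by a pooled linear fit given that $\tau$: the componentwise
  median of ridge-scattered individual estimates lies *off* the manifold
  of curves the data support and is a poor anchor. Residual noise comes
  from the individual fits' pooled residuals.
* **Random-effect variances are calibrated from restricted fits.** The
  spread of unrestricted individual estimates conflates true
  between-subject dispersion with (ridge-inflated) estimation noise. The
  initializer refits every subject with $\tau$ fixed at the anchor —
  making the model linear and the estimation covariance exact — and
  subtracts that covariance from the robust (MAD²) spread. During
  burn-in the variance update may shrink at most geometrically (5% per
  iteration) and is capped at four times the restricted-estimate spread,
  which is an upper bound on the true dispersion; without the cap the
  variance and the subject samples inflate each other along the ridge.
* **The residual variance is frozen during burn-in** at the two-stage
  estimate (already consistent): a transient excursion of the chain must
  not flatten the likelihood through an inflated noise term.
* Subject states start at their empirical-Bayes modes under the initial
  population, $\tau$ is bounded to $[0.5, 10T]$ throughout (configurable),
  and variances have a tiny proper floor so the prior never degenerates.

Even so, users should treat stroke-scale amplitude/decay/fatigue
estimates as having substantial *common-mode* uncertainty: at $\tau
\approx T/2$ with residual noise near 10% of initial MT, the per-subject
Fisher information along the ridge is weak (local standard errors of
order 1 on $\log A$), and a pooled least-squares fit of a 16-subject
noise-only cohort can land 20% from the generating amplitude. Contrasts,
correlations and normalized quantities are much less affected than the
raw parameter values, because a common-mode shift moves all subjects
together. The package's parameter-recovery simulations report exactly
this: group medians of $D_k$ recover within a few percent, while $A$,
$\tau$ and $C$ recover with 10–30% error at the stroke operating point —
an information limit of the design (600 trials, one session), not of the
fitter.

Fitting all subjects jointly (as one population) is the default
protocol; a per-group fit is a one-line subset of the trial table. The
`error_model = "by_group"` option estimates one residual SD per group
and is the matching likelihood when groups differ several-fold in noise,
as the stroke/control defaults do. Ablation flags (`drop_fatigue`,
`drop_intercepts`) refit the reduced models for RMSE-based model
comparison; on fatigue-bearing data the full model's RMSE beats the
no-fatigue model's, which is the qualitative justification for carrying
the linear term at all.

Determinism: a fit is a pure function of (data, config, seed); the
convergence trace of every fixed effect and the residual SD is returned
for inspection.

## The statistical battery

Group contrasts (`contrast_parameters()`) report per-group medians and
25–75% IQRs with two-sided Mann–Whitney tests for each of the eight
parameters, after a Shapiro–Wilk normality screen whose result is
recorded but does not gate the nonparametric contrast (model parameters
are systematically non-normal, so the nonparametric route is always
reported). No multiple-testing correction is applied by default, and a
Holm option exists. The Mann–Whitney p is exact (tail of the exact U
distribution) for tie-free samples with $n_x n_y \le 400$ — which covers
the 16-vs-10 contrasts — and otherwise uses the tie- and
continuity-corrected normal approximation. That approximation is only
trustworthy once both groups reach about 9 subjects: exhaustively over
all smaller tie-free designs its worst-case disagreement with the exact
p reaches 0.09, which is a property of the approximation itself, not of
this implementation.

The demographics t-test is pooled-variance and two-sided; the
long-term-prediction analysis regresses long-term performance change on
either normalized learning or normalized performance change
(`predict_long_term()`), with a subject-exclusion option for
sensitivity variants. $R^2$ equals the squared Pearson $r$ by
construction in these simple regressions.

One caveat the simulations surface: with $C$ drawn independently of $A$
(the generator's design — no joint dispersion information is available
to calibrate a correlation), in-sample chance correlation between the
two at $n = 16$ flips the learning-vs-performance $R^2$ ordering in
roughly a fifth of cohorts. Real impaired cohorts show strongly
positively correlated $A$ and $C$, which makes the observed ordering
more stable than the independence assumption predicts.

## Problem sizes and runtime choices

The test suite and the acceptance script run cohorts at the study's own
sizes (16 + 10 subjects, 600 trials each; 10 seeded replicates for
recovery and distinction checks; 500 replicates for type-I calibration;
50 for power), with the default SAEM schedule (300 + 200 iterations, 2
Metropolis steps per subject per iteration). A joint 26-subject fit
takes a couple of seconds in this configuration. Reduced schedules
(e.g., 100 + 80) are used in unit tests where only qualitative behavior
is asserted.

## Known limitations

* The retention link is invented; conclusions about long-term
  prediction transfer to real data only insofar as retention is in fact
  driven by the learned amplitude.
* Diagonal random effects cannot express the $A$–$C$ correlation real
  cohorts display.
* Parameter values (as opposed to contrasts and normalized quantities)
  carry large common-mode uncertainty at slow-learner operating points;
  see the estimation section.
* Homoscedastic noise within a group; no heavy-tailed or
  trial-dependent error models.
* Single-session modelling only; no second-session or between-session
  consolidation structure.
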