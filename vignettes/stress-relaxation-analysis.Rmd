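---
title: "Stress-relaxation analysis of soft hydrogels with generalized Maxwell models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-relaxation analysis of soft hydrogels with generalized Maxwell models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelrelax)
```

## The measurement and its model

A low-load compression tester lowers a cylindrical plunger (default
diameter 0.25 cm) onto a hydrogel cast in a ring on a glass slide.  The
plunger approaches at 5 um/s until a small touch load (default 10 mg)
registers contact; the gel thickness is the difference between the slide
position (a calibration input, measured from a blank run) and the plunger
position at contact.  The gel is then compressed to a fixed fraction of its
thickness (default 20%) and the force is recorded while the strain is held
constant (default 100 s).

Force is converted to stress by the plunger cross-section,
$\sigma = F / (\pi (d/2)^2)$, and deformation to engineering strain
$\varepsilon = \Delta h / h$.  Three quantities summarize each measurement:

* **Instantaneous stiffness** $E$: the ordinary least-squares slope of
  stress against strain over the compression ramp (kPa).
* **Relaxing stiffness** $E(t) = \sigma(t) / \varepsilon_0$ over the hold,
  with time zeroed at the hold start.
* **Total relaxation** $TR = 100\,(E(0) - E(t_{end}))/E(0)$.

The hold-phase decay is modelled as a generalized Maxwell (Prony-series)
material:

$$E(t) = E_\infty + \sum_{i=1}^{n} E_i\, e^{-t/\tau_i},$$

a parallel array of spring–dashpot elements with stiffnesses $E_i \ge 0$
and relaxation time constants $\tau_i > 0$, plus an optional equilibrium
spring $E_\infty \ge 0$.  Soft ECM gels typically relax essentially
completely, so $E_\infty \approx 0$ is an expected *outcome*; it is
therefore fitted as a free bounded parameter rather than imposed
(`e_inf = "zero"` switches the term off).  Each element's share of the
instantaneous elastic response is its relative importance
$RI_i = 100\,E_i / \sum_j E_j$ (the equilibrium spring is excluded from the
denominator).

Elements are classified by time constant with left-closed bins:
$(0,1)$ s — interstitial fluid squeezed out of the gel; $[1,10)$ s — the
ECM network; $[10,100]$ s — a slow mode observed in the stiffest, least
relaxing gels; beyond 100 s — out of the instrument's useful range for a
100-s hold.

## Fitting and model-order selection

`fit_fixed_order()` minimizes the chi-squared error function
$\chi^2 = \sum_k (E(t_k) - \hat E(t_k))^2$ — an unweighted sum of squared
residuals, since the instrument supplies no per-sample variances (a weight
vector is accepted but off by default) — by bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) with $E_i \ge 0$, $\tau_i \in [10^{-3}, 10^4]$ s and
$E_\infty \ge 0$.  Multi-exponential least squares is multi-modal, so the
optimizer is multi-started (default 10 starts): time constants start
log-spaced over $[0.1, 100]$ s — the decade range over which these gels
show structure — and are jittered multiplicatively by a seeded RNG;
stiffnesses start at $E(0)/n$.  The best chi-squared among converged starts
wins, and the result is bit-reproducible given the seed.  Elements are
reported sorted by ascending $\tau$, so "the first element" is always the
fastest.

`select_order()` implements the element-addition rule: fit $n = 1$, then
add elements until the chi-squared decrease becomes insignificant —
by default a relative improvement below `epsilon = 0.05`; an
extra-sum-of-squares F test (`criterion = "ftest"`, stop when $p > 0.05$)
is available as an alternative.  No standard quantitative threshold exists
for this rule, so both the 5% default and the F-test variant are exposed as
tunables.  The default `max_n = 4` gives one spare order beyond the 2–3
elements these gels need, which is what lets the stopping rule actually
stop.  Two details make the search well-behaved:

* each $(n{+}1)$-element fit receives a warm start equal to the $n$-element
  solution plus a zero-stiffness element, so the recorded chi-squared
  sequence is non-increasing by construction;
* a numerically perfect fit ($\chi^2 \le 10^{-16} \sum_k E(t_k)^2$) stops
  the search immediately, which keeps the relative-improvement criterion
  away from 0/0.

## Preprocessing choices

* **Contact debounce.** The touch-load crossing must hold for 5 consecutive
  samples (configurable).  A 10-mg threshold alone has no noise rejection;
  with the debounce, noise-only traces trigger a false contact in under 1%
  of simulated runs at a noise SD of 20% of the threshold.
* **Hold-start tolerance.** The compression target is 20% of the *detected*
  thickness.  Under force noise, contact can be detected a few samples
  late, which shrinks the detected thickness and can push the target just
  beyond the plunger's actual travel plateau.  The hold is therefore taken
  to start at the travel plateau whenever the plateau reaches 95% of the
  target; a plunger that genuinely stopped short remains an error.
* **Idealized hold strain.** The hold strain is recorded as exactly the
  configured deformation fraction, matching the constant-strain protocol;
  per-sample ramp strain is travel past contact divided by thickness
  (engineering strain; no large-deformation correction).
* **Stiffness regression.** The stress–strain line includes an intercept so
  the slope is insensitive to the touch-load offset at contact
  (`intercept = FALSE` forces the origin).  $E(0)$ for total relaxation is
  the first hold sample, not an extrapolated peak.
* **Units.** Physics is SI internally (s, m, N, Pa); reported stiffnesses
  are kPa and geometry is um, the units practitioners use.

## The simulator: what it emulates and what it does not

`simulate_trace()` forward-models the protocol: approach at 5 um/s with
zero-mean baseline force noise, contact at (slide position − thickness),
compression to the deformation target, then a hold whose force is exactly
$A\,\varepsilon_0\,E(t)$ for the specified Prony series.  Defaults mirror
the laboratory protocol: 800-um casting rings, 20% deformation, 100-s hold
sampled at 10 Hz (1001 hold samples).  Three idealizations matter when
interpreting test results:

* **Step-strain material response.** The ramp force is a quasi-static
  elastic line ($E(0)$ times strain, plus the touch load); viscoelastic
  relaxation starts at the hold start.  A hereditary-integral ramp
  correction is deliberately out of scope, as only the hold is analysed.
* **Contact step.** At the contact sample the force steps to the touch
  load (with a 5% overshoot so detection is not razor-edge against noise).
  Real contact is a fast but continuous rise; the step is what makes the
  simulated thickness recoverable to one position step, which is the
  property the pipeline is tested against.
* **Noise and collapse.** Measurement noise is additive Gaussian on stress
  with SD expressed as a fraction of $E(0)\,\varepsilon_0$ (default 1%);
  no instrument noise spectrum is modelled.  The collapse failure mode —
  gels that cannot sustain the hold — is a forced exponential force decay
  to baseline (0.2-s time constant) at a specified time into the hold.
  This is a *testing device* for the QC path, not a physical model of gel
  failure, for which no quantitative description exists.

`simulate_cohort()` reproduces the replicate structure of donor-derived
cohorts: donors × pregel solutions × duplicate casts (default 3 × 3 × 2 =
18 traces), with donor-level parameter means, multiplicative pregel-level
deviations (log-SD 0.2, reflecting the large intradonor variation these
gels show), log-normal time constants and zero-truncated normal
stiffnesses.  Default element distributions place a dominant sub-second
element (E ~ 1.2 kPa, tau ~ 0.5 s) and an ECM element in the 1–10 s decade
(E ~ 0.6 kPa, tau ~ 5 s), with a 30% chance of a slow 10–100 s third
element per pregel — the parameter regime reported for nondiabetic
adipose-ECM gels.  "DAM-like" cohorts assign every trace a collapse time
drawn uniformly from 2–8 s into the hold, early enough that the failure is
unambiguous in the recorded window; the real failure times are unknown.

## Quality control and statistics

A measurement is flagged as collapsed (and excluded from summaries) when
the relaxing stiffness turns non-positive before 10% of the hold has
elapsed, when it drops by more than 50% between adjacent samples while
still above 10% of $E(0)$, or when the Maxwell fit fails to converge at
every order.  The 10%-of-$E(0)$ floor on the drop rule exists because a
fully relaxed tail fluctuates around zero under noise, where adjacent-
sample ratios are meaningless.  One consequence worth knowing: a clean but
very fast-relaxing gel (slowest $\tau$ of a few seconds) can reach the
noise floor within the first tenth of the hold and be flagged by the
early-nonpositive rule — such gels are genuinely at the edge of what the
assay can quantify.  The QC thresholds are arguments, not constants.

Cohort summaries report mean, sample SD ($n-1$) and SEM per group;
single-measurement groups carry `dispersion_defined = FALSE` instead of a
fabricated spread.  Group comparisons use a one-tailed two-sample t test,
pooled-variance by default (the common spreadsheet default; Welch is
selectable), and the direction of the alternative must be stated explicitly
by the analyst — the package never guesses a hypothesis.  No
multiple-testing correction is applied by default; `p.adjust` on the
emitted p-values is the recommended route when several metrics are
compared.

## Numerical robustness and limitations

* Fits are deterministic given curve, options and seed; cohort simulation
  is deterministic given the master seed (per-gel seeds are drawn from it).
* Degenerate inputs fail loudly with typed conditions: constant-strain
  ramps, zero hold strain, non-positive $E(0)$, all-zero stiffnesses in the
  RI denominator, time constants $\le 0$.
* Sampling must resolve the fastest element: at 10 Hz, elements with
  $\tau \lesssim 0.2$ s are represented by only a couple of samples and
  their parameters (not the fit quality) become unstable; the drop-rule QC
  can also misread such decays.
* Curves fitted here are relaxing stiffness in kPa.  Fitting stress instead
  rescales $E_i$ by the hold strain and changes nothing else.
* Validation is entirely simulation-based (the generator above defines the
  study conditions).  Passing tests demonstrate correct recovery of
  Prony-series ground truth under additive Gaussian noise and the stated
  protocol; they do not certify behaviour under instrument drift,
  adhesion/pull-off artefacts, substrate compliance, or hydration effects,
  none of which are modelled.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` run at the protocol's nominal
sizes: 1001-sample holds (100 s at 10 Hz); 100 replicate curves for
two-element parameter recovery (median relative errors are well under 10%
and the order search selects $n = 2$ essentially always); 20 curves checked
against an exhaustive 400×400 log-grid single-element search; 50 curves for
chi-squared monotonicity across orders 1–4; 40-curve ensembles for the
dominant-fast-element pattern; and full 18-trace cohorts for the QC
exclusion path.  These sizes give stable pass/fail behaviour for the
stochastic checks while keeping a complete validation run in the
low minutes on a single core.
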