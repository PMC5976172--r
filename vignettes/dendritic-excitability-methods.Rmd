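---
title: "Models and methods for dendritic excitability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for dendritic excitability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendricap)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the constants that matter, and the choices made
where the underlying experimental procedures leave the numerics open.

## The two-compartment capacitance model

A Purkinje neuron in whole-cell voltage clamp is approximated as two RC
compartments: the soma plus main proximal dendrites (capacitance $C_1$,
reached through $R_1$, the pipette access plus somatic internal resistance)
and the distal dendritic arbor ($C_2$, coupled through the dendritic
internal resistance $R_2$). After a voltage step $\Delta V$ the capacitative
current relaxes as a sum of two exponentials,

$$I(t) = A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2},$$

and the circuit parameters follow algebraically:

$$C_1 = \frac{\tau_1 (A_1+A_2)^2}{A_1\,\Delta V},\qquad
  C_2 = \frac{A_2 \tau_2}{\Delta V},\qquad
  R_1 = \frac{\Delta V}{A_1+A_2},\qquad
  R_2 = \frac{\Delta V}{A_2} - \frac{\Delta V}{A_1+A_2}.$$

With pA, ms and mV as the working units, capacitances emerge in pF and
resistances in GΩ (reported as MΩ). The $C_1$ expression is adopted in the
dimensionally consistent form $\tau_1(A_1+A_2)^2/(A_1\Delta V)$ — the only
reading of the source expression under which a capacitance in pF results —
and `compartments_to_biexponential()` is its exact algebraic inverse, which
the test suite exercises as a round-trip identity over random circuits.

The model assumes passive membrane during the step (the protocol steps from
−80 to −90 mV, away from activation ranges), full settling within the 1 s
step, and a transient large relative to noise after ten-sweep averaging.
The fast component is assigned to the somatic compartment ($\tau_1 <
\tau_2$); when the two time constants differ by less than 1.5-fold the fit
is flagged ill-conditioned rather than silently resolved.

### Preprocessing and numerical choices

* **Averaging.** The repeated sweeps (ten in the standard protocol) are
  congruent; their pointwise mean reduces noise by $\sqrt{n}$.
* **Filter realization.** "Low-pass filtered at 5 kHz" fixes only the
  cutoff; the package uses a 4th-order Butterworth applied forward and
  backward (`signal::filtfilt`), i.e. zero phase, so the transient is not
  delayed.
* **Leak correction.** The steady-state current $\Delta V / R_\mathrm{in}$
  is subtracted inside the step. When no independent $R_\mathrm{in}$ is
  supplied, the steady state is estimated from the final 100 ms of the
  step.
* **Fit window.** From the sample after the post-step peak of $|I|$ to step
  end. When the transient was filtered, both ends are further guarded by
  the filter settling time ($1.5/f_c$, 0.3 ms at 5 kHz): the filtered rise
  is shaped by the filter rather than the cell, and zero-phase filtering
  rings backward from the step-off edge. Time is measured from step onset,
  so amplitudes are referred to the onset regardless of where the window
  starts.
* **Initialisation.** Deterministic peel-off: a log-linear fit to the slow
  tail (restricted to samples above $10^{-3}$ of the peak, so the
  fully-decayed tail cannot poison the slope), then a log-linear fit to the
  fast residual. The model includes a constant offset to absorb residual
  leak error; fits whose offset exceeds 10% of the peak are rejected.
* **Degenerate inputs.** A genuinely single-exponential transient makes the
  biexponential Jacobian rank-deficient; the fitter falls back to a
  one-component fit and reports $A_2 = 0$, which propagates to $C_2 = 0$
  with $R_2$ missing and the cell flagged single-compartment. Pure-noise
  input yields either a non-converged flag or an RSS comparable to the
  total variance — never a silently wrong circuit.
* **QC.** Cells with measured input resistance below 100 MΩ are excluded;
  the threshold is strict, so exactly 100 MΩ passes.

The zero-phase filter slightly perturbs the fast component (it overlaps the
filter's settling scale); the test suite bounds this perturbation at 2% on
the recovered circuit, while the unfiltered noiseless round trip recovers
the circuit to 0.1% and far better in practice.

## Spike features

Threshold is the earliest point of the upstroke at which $dV/dt$ reaches 5%
of its maximum within the spike window, with $dV/dt$ by central differences
on the (already 5 kHz-filtered) trace; only the contiguous supra-criterion
run ending at the peak counts, so isolated noise crossings cannot fire the
threshold early. Half-width is the time between the first upward and first
subsequent downward crossing of the midpoint between threshold and peak,
with linear interpolation between samples — at 100 kHz this removes
quantisation bias at negligible cost. Amplitude is peak minus anti-peak,
the anti-peak being the minimum between a peak and the next spike's
threshold (or the window end); the mean over all spikes in a 10 s trace is
the per-cell value, and half-width is averaged over the first five
consecutive spikes. The amplitude and half-width summaries deliberately
take independent inputs, since the underlying recordings need not be the
same trace.

The liquid junction potential correction subtracts 10 mV: for a
K-gluconate internal the true membrane potential is more negative than the
pipette reading. The magnitude is configurable; the direction is a package
decision, documented here, and a corrected flag makes the operation
non-repeatable rather than silently cumulative.

## bAP attenuation and the nested-curve F test

Amplitude versus distance $x$ is modelled as $y = Ae^{-bx}$ (half-width as
$Ae^{bx}$), fitted by unweighted nonlinear least squares on the original
scale — no weighting is assumed because none is given for the reference
analyses; a log-linear regression serves only as the deterministic
initialiser. The length constant is $\lambda = 1/b$ and is rounded to one
decimal in reports. A fit whose decay across the sampled range is below
0.1% is flagged flat instead of reporting a meaningless $\lambda$.

Genotypes are compared with the extra sum-of-squares F test: a pooled
two-parameter curve ($\mathrm{df} = n-2$) against independent per-group
curves ($\mathrm{df} = n-4$),

$$F = \frac{(RSS_p - RSS_s)/2}{RSS_s/(n-4)},$$

with the p-value from the upper tail of $F_{2,\,n-4}$, the standard
orientation for nested curve comparisons. If the separate fits are exact
($RSS_s = 0$) the p-value is taken in the limit and flagged. The test suite
verifies calibration by simulation: under the pooled null (both groups from
one curve, 2 mV noise, 12 cells per group) the rejection rate at
$\alpha = 0.05$ over 1000 replicates must fall in [0.03, 0.07], and power
at the five-week genotype separation ($b = 0.0215$ vs $0.0376$) over 500
replicates must reach 0.9.

## Calcium spikes and cell usability

The somatic signature of a dendritic calcium spike is not defined
quantitatively in the experimental literature this package follows, so
detection is an explicit package criterion: the response must exceed the
passive prediction by at least 20 mV for at least 2 ms of contiguous time.
Both numbers are arguments, and the passive prediction is the smallest
step's response scaled ohmically. The threshold current is the smallest
step whose response contains a spike; a spike pattern that turns off again
at higher currents is reported at the smallest spiking step and flagged
non-monotonic rather than second-guessed.

Input resistance is the slope of steady-state voltage versus injected
current restricted to steady states between −80 and −75 mV, minimising the
influence of active conductances; steady state is the mean over the final
20% of the step (the membrane time constant is an order of magnitude
shorter). Fewer than two in-window points yields a flagged missing value.

Non-firing cells are usable only if the recording began more depolarized
than −45 mV **and** TTX + CdCl₂ hyperpolarized the cell below −55 mV —
evidence of channel-mediated depolarization block rather than slicing
injury. Following the wording of the rules, both inequalities are strict,
and a non-firing cell lacking the post-blocker measurement is *pending*,
never silently classified.

## The channel-gene screen

Expression tables (fold change oriented mutant/wild-type, p, q) are subset
to the 145-member IUPHAR voltage-gated ion channel superfamily, shipped as
a pinned CSV (`extdata/vgic_channel_list.csv`, mouse symbols with
subfamily labels) rather than a live database lookup, because the
classification evolves. Significance is $q \le 0.05$, inclusive, matching
the ≤ in the defining criterion. Heat-map matrices are
$\log_2$(fold change); in significant-only mode an entry is masked at
timepoints where its gene is not significant, so each column shows exactly
that age's significant changes. The persistent set is the intersection of
the significant sets at both ages, with direction. The screen consumes
published differential-expression statistics; it computes none of them.

## What the synthetic data does and does not emulate

Each generator reproduces the *statistical structure the analysis assumes*,
with additive i.i.d. Gaussian noise (the simplest model adequate for
calibration, since no empirical noise magnitudes are available):

* capacitative transients are the exact biexponential-plus-leak current of
  a known circuit, sampled at 100 kHz (the standard digitisation rate);
* bAP cohorts draw one cell per distance with exponentially decaying
  amplitude (clipped at 0 mV — physical non-negativity) and growing
  half-width;
* spike traces are piecewise-linear stereotyped spikes with vertices on
  the sample grid, so every planted feature is exact;
* current-step families superimpose an alpha-function bump (30 mV, ~10 ms)
  on a single-time-constant passive response above a planted threshold —
  all-or-none appearance is the only property the analysis uses, so no
  channel biophysics is modelled;
* gene tables plant an exact number of significant channel genes with
  log-uniform fold changes.

Passing tests therefore show that the estimators recover what they claim
from data satisfying the model assumptions. They do not show robustness to
real-world structure the generators omit: correlated noise, electrode
drift, series-resistance changes, bursting or complex spikes, non-monotonic
attenuation profiles, or per-animal clustering. In particular the
attenuation analysis pools cells across animals — no mixed-effects
nesting — which mirrors the source analyses but is a known limitation.

## Default parameters and problem sizes

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| sampling interval | 0.01 | ms | 100 kHz digitisation |
| filter cutoff | 5 | kHz | standard offline filter |
| sweeps averaged | 10 | – | standard protocol |
| voltage step | −80 → −90 | mV | capacitance protocol |
| QC threshold | 100 | MΩ | exclusion rule, strict |
| dV/dt threshold fraction | 0.05 | – | spike threshold definition |
| LJP correction | 10 | mV | K-gluconate internal |
| transient noise | 5 | pA | calibration condition |
| bAP cohort | 12 cells, 10–120 µm, 2 mV noise | | calibration condition |
| Ca-spike criterion | 20 mV, 2 ms | | package default, configurable |
| Rin window | −80…−75 | mV | active-conductance avoidance |
| steady-state window | final 20% of step | | ≫ membrane time constant |
| q cutoff | 0.05 | – | inclusive |

Simulation-based checks use 200 replicates for capacitance recovery and
1000/500 replicates for F-test calibration/power — sizes at which the
binomial uncertainty of the checked rates is well inside the asserted
bands. The full synthetic study (`run_synthetic_study()`) plants the
published five- and fifteen-week best-fit attenuation parameters, a
wild-type circuit of (112.5 pF, 500 pF, 6.67 MΩ, 13.33 MΩ) with the mutant
distal capacitance reduced to 300 pF, calcium-spike thresholds of 900
(wild-type) vs 600 pA (mutant), and 12/18 significant channel genes at the
two ages with a 6-gene persistent set; every default it uses is logged in
its config and hashed into each output file.

```{r study, eval = FALSE}
study <- run_synthetic_study(list(seed = 1))
study$attenuation
```
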