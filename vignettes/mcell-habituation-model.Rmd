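---
title: "Modeling social-status-dependent habituation of the Mauthner-cell escape circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling social-status-dependent habituation of the Mauthner-cell escape circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcellhab)
```

## The model

The zebrafish startle escape is commanded by the paired Mauthner (M-)
cells.  `mcellhab` models this circuit as two coupled modified
Morris--Lecar neurons.  Each cell carries calcium, potassium, leak and
calcium-dependent potassium currents and obeys

$$C\,\dot v = -I_{Ca} - I_K - I_L - I_{KCa} - I_{syn} + I_{app},$$

with $I_{Ca} = g_{Ca} m_\infty(v)(v - v_{Ca})$,
$I_K = g_K n (v - v_K)$,
$I_{KCa} = g_{KCa}\frac{[Ca]}{[Ca]+k_1}(v - v_K)$,
$I_L = g_L (v - v_L)$, and cross-cell synaptic input
$I_{syn} = g_{syn}(v - v_{syn})\,s_{\mathrm{other}}$ gated by the *other*
cell's synaptic variable.  The gates follow the usual hyperbolic-tangent
activation curves; intracellular calcium integrates the calcium influx,
$\dot{[Ca]} = \varepsilon(-\mu I_{Ca} - k_{Ca}[Ca])$.

The slow variable that carries habituation is the activity-dependent net
excitation $E_{net}$, a lumped stand-in for the balance of excitatory
(VIIIth-nerve) and feed-forward inhibitory drive onto the M-cell.  Calcium
reciprocally sets its target:

$$\dot E_{net} = \frac{1}{\rho}\left(\frac{ag_{max}}{[Ca]+k_2} -
E_{net}\right), \qquad
I_{app} = I_0 + I_i(\tau) + w_M\,E_{net}.$$

The printed form of this relaxation equation is typographically ambiguous
about where $\rho$ sits; we resolve it as a relaxation *time constant*
(divide), because (i) $\rho$ is described as the time constant of
$E_{net}$, and (ii) only this reading places the equilibrium
$E_{net} = ag_{max}/([Ca]+k_2) \approx 41.5/43 \approx 0.96$ inside the
0.9--1.2 band that the slow-plane analysis uses.  With $\rho = 8400$ ms the
adaptation relaxes over $\sim$8.4 s, matching the tens-of-seconds drift
seen in long runs.  Time is in milliseconds throughout; protocol times
quoted in seconds are converted.

`ag_max`, the maximal net excitation, is the social-phenotype control
parameter: 41.5 behaves dominant-like (rapid habituation), 42.2
communal-like, 43.5 subordinate-like (sustained, irregular responding).
The parameter table also prints a constant `s_2 = 0.029` that enters no
equation; we carry it as an inert configuration entry.  It is close to the
circuit's equilibrium synaptic activation
$\alpha s_\infty/(\alpha s_\infty + \beta) \approx 0.023$, which suggests
it was an initial value; we do not guess further.

## Numerical integration

The reference integrator is fixed-step classical RK4 at 0.01 ms, compiled
(Rcpp).  The phrase "adaptive-step RK4 with step size 0.01 ms" in the
source description is self-contradictory, so the package treats fixed-step
RK4 as the reference mode and cross-checks it in the test-suite against an
independent error-controlled integration (`deSolve::ode`, `lsoda`, rtol
1e-10) of the same pure-R vector field.  Pulse edges and all requested
sample times are forced grid points, so no RK4 stage straddles a drive
discontinuity.  Step-halving to 0.005 ms moves the 30 s membrane potential
of the dominant-like 1 Hz run by well under 0.01 mV.

Traces are stored at 1 ms resolution, refined to 0.1 ms within ±50 ms of
each pulse onset so spike latencies and suprathreshold areas are resolved
precisely without storing 0.01 ms samples of multi-minute runs.  Calcium
marginally below zero from round-off is clamped to zero before the
saturating terms are evaluated and the clamp count is reported on the
trace.

Every protocol starts from the quasi-steady state: 20 s of stimulus-free
relaxation from a generic resting start ($v=-30$, $n=n_\infty(-30)$,
$[Ca]=3$, $s=s_\infty(-30)$, $E_{net}=1$).  `quasi_steady_state()` refuses
to return a still-drifting state (max derivative above 0.01 per ms).  The
relaxed membrane potential and potassium gate reproduce the reference rest
points, $(-34.32, 0.00427)$ for `ag_max` 41.5 and $(-34.322, 0.00429)$ for
43.5, to within 0.06 mV and $2\times10^{-5}$.

## The stimulus pulse and its calibration

Stimuli are rectangular depolarizing current pulses of amplitude 4.5
delivered to cell 1 only (cell 2 receives no direct stimulus).  The pulse
*duration* is not part of the model's stated parameter set, and the
circuit's response is remarkably sensitive to it: at amplitude 4.5,
widths at or above about 2.05 ms make even the dominant-like cell fire
faithfully to all 40 stimuli, while widths at or below about 1.95 ms
silence every phenotype.  All the qualitative phenotype structure lives in
a ≈50 µs band around 1.96 ms — which is exactly where one should expect
it: the phenotypes differ only through the small offset that `ag_max`
imparts to $E_{net}$ (equilibria 0.967 vs 1.009), so the stimulus must
place the firing threshold *between* those levels.

`calibrate_pulse_width()` therefore selects the smallest width from a fine
candidate grid (default 1.95--1.99 ms in 0.5 µs steps) such that the
qualitative phenotypes hold:

1. the subordinate-like model fires exactly one action potential to the
   first pulse from quasi-steady state;
2. the dominant-like model responds to at least one of the first ten
   1 Hz stimuli and to none after stimulus 10;
3. the subordinate-like model responds intermittently and aperiodically
   (no exact period ≤ 10) over the stationary 100--300 s window at 1 Hz;
4. at 0.2 Hz the spread of Faithfulness across the three phenotypes is
   smaller than at 1 Hz (the frequency effect seen experimentally).

Conditions 3 and 4 extend the minimal "single spike + dominant stops"
rule: without them a width can pass trivially with an entirely silent
circuit, which is not the phenotype the model is meant to show.  A coarse
candidate set such as {1, 2, 5, 10, 20, 50, 100} ms contains no admissible
width at all.

## Response detection and the return map

Spikes are upward crossings of 0 mV by the cell-1 membrane potential
within each stimulus window; in this regime action potentials overshoot
+30 mV while subthreshold responses stay below about −25 mV, so the
detector is threshold-insensitive over a wide band.  Faithfulness is the
fraction of stimuli in a window that evoke a spike, measured by default
over the initial (20--30 s) and stable (40--70 s) windows of a protocol
starting at 20 s.

The suprathreshold area $A_i$ integrates $\max(v - \theta, 0)$ per
stimulus window (trapezoidal rule on the stored grid) with $\theta = -30$
mV by default, chosen between rest (≈ −34 mV) and the spike peak so that
subthreshold responses leave small nonzero areas; return maps
$(A_i, A_{i+1})$ are log10-scaled because spike and subthreshold areas
differ by orders of magnitude, and classifications are insensitive to
±2 mV changes of $\theta$.  Patterns over the stationary window are
classified by firing fraction $f$ and exact periodicity of the fired
sequence (period ≤ 10 counts as periodic; the deterministic fixed-step
model makes exact repetition meaningful): silent converged ⇒ subthreshold
fixed point, $f=1$ ⇒ suprathreshold fixed point, periodic with
$f \le 0.5$ ⇒ subthreshold periodic, periodic with $f > 0.5$ ⇒
suprathreshold periodic, otherwise irregular.

The jump-up analysis freezes the fast variables at their quasi-steady
values, places the slow pair $([Ca], E_{net})$ on a grid over
$[3, 3.2] \times [0.9, 1.2]$ (increment 0.01), and delivers a single pulse
immediately; the fired set is the jump-up region and its frontier is the
jump-up curve.  Delivering the pulse immediately (rather than after a
further 20 s wait) keeps the slow variables exactly on their grid values;
this is a deliberate, documented deviation that preserves the grid
semantics of the construction.

## Faithfulness scans

`faithfulness_scan()` crosses stimulation frequency
{0.1, 0.2, 0.5, 1, 2, 5} Hz with either `ag_max` (40.5--44.5, step 0.25)
or pulse amplitude (3--6, step 0.25), one full protocol run per cell with
its own quasi-steady initialization, reporting both analysis windows as a
tidy table.  Faithfulness increases with `ag_max` and amplitude, decreases
with frequency, is never higher in the stable window than in the initial
one, and — for the three phenotypes at the default amplitude — converges
to full response at sufficiently low frequency (amplitudes below the
firing threshold of course never reach it).  Two caveats are worth
stating plainly.  First, near the firing boundary the cell sits in a
deterministically irregular regime, and Faithfulness counted over a
finite window is quantized in steps of one response; cell-wise
monotonicity along a fine `ag_max` grid can therefore be broken by
isolated one-count wiggles even though every coarse trend is monotone.
The test-suite asserts the cell-wise property as stated and treats such a
wiggle as a genuine (documented) failure rather than loosening the
assertion.  Second, the scans in the test-suite run the reference
frequency grid against `ag_max` and amplitude sub-grids at 0.5 spacing,
which keeps the full suite within a practical runtime while exercising
the same ranges.

## The synthetic behavioral raster

The behavioral module handles binary animals × stimuli escape-response
rasters.  Because no behavioral recordings ship with the package, a seeded
generator produces synthetic rasters from a status-dependent Bernoulli
habituation model: response probability at (0-based) stimulus $k$ is
$p_k = \text{plateau} + (p_0 - \text{plateau})\,e^{-k/\tau}$.  Defaults
($p_0 = 1$; plateaus 0.05/0.25/0.55 at 1 Hz and 0.45/0.55/0.70 at 0.2 Hz
for dominant/communal/subordinate; $\tau$ = 3/4/5 stimuli) mirror the
empirical orderings: dominants habituate fast and deep, subordinates keep
responding, and slowing the stimulus to 0.2 Hz raises all plateaus and
compresses group differences.  The generator emulates only these
first-order rate structures — independent Bernoulli trials, no
animal-level heterogeneity, no serial correlation within an animal, no
sex/size covariates — so passing its tests validates the summarising
and fitting code, not any claim about real fish.  Latencies, when
requested, are i.i.d. normal (5.7 ± 1 ms, truncated at 0.1 ms) for
responded trials.

Summaries follow the standard presentation: per-bin percent response
(2 stimuli per bin, i.e. 2 s at 1 Hz or 10 s at 0.2 Hz) with per-group
mean ± SEM, and pooled 5-stimulus block rates.  "Cumulative percent
response" in the figure caption this mirrors could denote either per-bin
percentages or a running sum; we implement per-bin percentages, which is
the reading consistent with a y-axis bounded at 100%.  SEM of a single
observation is reported as 0 with an explicit flag rather than NaN.
Recovery of $p_0$ and plateau to ±0.05 by least squares requires about
200 animals per group; the test-suite uses exactly that.

## Problem sizes and numerical choices

The package's reference analyses use: 20 s relaxations; 300 s
(280-stimulus) 1 Hz runs for return maps, slow-plane projections and the
stationary classification window (100--300 s after stimulation onset,
200 stimuli); 70 s runs for Faithfulness windows; and jump-up grids at
increment 0.01 (0.02 in the routine test-suite, which quarters the grid).
Monotonicity checks in the test-suite run the full reference frequency grid
against `ag_max` and amplitude sub-grids at 0.5 spacing with the reference
0.01 ms step.  Degenerate inputs are rejected rather than silently
repaired: non-finite states abort integration, a drifting "steady state"
raises, windows without stimuli raise, and zero areas under a log-scale
request raise with a pointer at the area threshold.

## Known limitations

* The two-cell structure is retained as specified, but cell 2 never
  receives a stimulus and its synaptic feedback onto cell 1 is weak at
  rest; the circuit behaves close to a single driven cell.
* Irregularity is diagnosed by exact-repetition tests on a deterministic
  trajectory, not by Lyapunov exponents; "irregular" means "no exact
  period ≤ 10 over the stationary window".
* The knife-edge sensitivity of the phenotypes to the stimulus pulse
  (≈50 µs in width at amplitude 4.5) is a property of the model, and any
  quantitative statement about spike counts in the irregular regime is
  specific to the integrator step and platform arithmetic; class-level
  statements (silent / periodic / irregular) are the robust objects.
* The behavioral generator is a synthetic stand-in; its defaults encode
  orderings, not fitted animal data.
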