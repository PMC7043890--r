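---
title: "Sodium-channel long-term inactivation as a molecular leaky integrator: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sodium-channel long-term inactivation as a molecular leaky integrator: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(navlti)
```

This vignette documents the models implemented in `navlti`, the choices
made where the design was genuinely open, and what the shipped tests do and
do not establish. Every number quoted here is computed by the test suite,
the analysis scripts under `analysis/`, or `scripts/acceptance.R`; nothing
is asserted that the code does not itself reproduce.

## 1. The gating model and its solver

Nav channel gating is treated as a continuous-time Markov chain over a
small set of conformational states. With occupancies as a row vector
$P$, the master equation is $dP/dt = P\,Q(V)$, where the generator
$Q(V)$ holds the directed transition rates at membrane potential $V$ and
has zero row sums. Every rate is a single-barrier exponential,
$k(V) = k^0 e^{k^1 V}$ with $k^0$ in ms$^{-1}$ and $k^1$ in mV$^{-1}$.

All command-voltage protocols in this package are piecewise constant
(steps and pulse trains; ramps are out of scope), so propagation is exact
per segment through the matrix exponential,
$P(t+\Delta t) = P(t)\,e^{Q\Delta t}$, computed by scaling-and-squaring
(`Matrix::expm`) rather than eigendecomposition, which tolerates the
nearly defective generators that arise at extreme voltages. Two numerical
details matter:

* each per-step transition matrix is renormalised to exact row sums of 1;
  the $\sim 10^{-13}$ residual of the Padé approximant would otherwise
  compound multiplicatively over the $10^5$–$10^6$ steps of a long
  protocol and break the $10^{-9}$ conservation contract the trajectories
  are tested against;
* stationary distributions are obtained from the null space of $Q^\top$
  (smallest singular value of an SVD), renormalised; a second near-zero
  singular value signals a reducible scheme and is an error rather than a
  silent wrong answer.

The propagator is verified against an independent fine-step explicit-Euler
integrator (with step-doubling Richardson extrapolation, so the oracle's
own truncation error, $\sim10^{-8}$, does not mask the $10^{-6}$
agreement bound) on randomly generated small schemes, and against the
closed-form two-state relaxation.

## 2. The 13-state LTI scheme and the synthetic rate table

The canonical topology is an activation ladder of five closed states
C1–C5 feeding one open state O6, a parallel inactivated ladder I7–I12
(giving closed-state inactivation and open-state-bypassing recovery), and
one long-term inactivated state S13 connected to the open state —
open-channel block by an FHF-type auxiliary factor. The non-LTI control
model is identical with S13 and its two transitions removed.

The O6–S13 rate pair is published in two sets (per second):
$k_{6,13} = 400.8\,e^{-0.011V}$ with $k_{13,6} = 0.207\,e^{-0.031V}$
(set 1), and $205.7/0.106$ with the same voltage factors (set 2). The
remaining rates of the full table are **not** published in a form this
package could consume, so the bundled table
(`inst/extdata/nav_rates_synthetic.csv`, marked synthetic) is this
package's own construction: a Kuo–Bean-style parameterisation (paired
forward/backward ladder rates with allosteric scaling of the inactivated
row) whose free constants were calibrated once against the published
emergent behaviour, and then frozen. The calibration targets, all met by
the frozen table, are:

* leak time constant of the post-pulse S decay at $-80$ mV:
  435 ms (set 1) and 820 ms (set 2), fitted as a single exponential on
  the tail of $P_S$ beyond 50 ms (past ten fast-recovery time
  constants) — an observed decay constant, not an eigenvalue, because
  that is what the experimental analysis measures;
* per-pulse split of available channels between normal inactivation and
  LTI after a 5 ms pulse from $-80$ to 0 mV: $\approx 80/20$ (set 1,
  measured 0.205 at the pulse end) and $\approx 90/10$ (set 2, 0.118),
  essentially complete within 2 ms;
* equilibrium S occupancy under sustained depolarisation at 0 mV:
  $P_{S\infty} = 0.700$ for both sets (they share the
  $k_{6,13}/k_{13,6}$ ratio), with the stationary normal-inactivated
  occupancy at 0.300;
* a 100 Hz train of 5 ms pulses holds $P_S$ oscillating between 0.922
  and 0.933;
* simulated two-pulse recovery at $-80$ mV fits bi-exponentially with a
  fast constant of $\approx 5$ ms (the recovery of the I ladder; the
  experimental fast constants are 3–8.5 ms depending on preparation) and
  a slow amplitude of 0.206.

Two resolutions recorded during this calibration:

* **Units.** The methods convention for the model is ms$^{-1}$, but the
  printed O–S pre-factors are consistent with the 435/820 ms leak
  constants only on the per-second scale: requiring *both* sets to
  produce their leak constants simultaneously pins the open-state escape
  rate at $-80$ mV to $\approx 12.8$ ms$^{-1}$ (a physiological
  deactivation rate) under the per-second reading, whereas the per-ms
  reading gives sub-millisecond leaks. The shipped table therefore
  declares `# units: per_s`; the reader supports both scales through the
  metadata line and converts to the canonical per-ms scale on load.
* **Activation range.** The opening step's voltage sensitivity was set so
  that open probability becomes appreciable only above about $-50$ mV,
  matching the described behaviour of these channels in their host
  neurons; a shallower opening step (which leaves every 0 mV and
  $-80$ mV quantity unchanged) would let the model conduct at $-60$ mV
  and place the surrogate neuron's spike threshold unrealistically low.

One deviation from an idealised expectation is documented rather than
forced: the first-pulse peak open probability of the LTI model from rest
is about 3% lower than the non-LTI model's, not within 1%. With the
printed $k_{6,13}(0) = 0.4$ ms$^{-1}$ the S pathway necessarily drains
the open state during the $\sim$0.15 ms rise to peak; the effect cannot
be reduced below $\sim$2% by any physiological activation speed. The
availability interpretation ($P_S = 1 - I^p/I^0$) is unaffected, because
the drain scales both numerator and denominator.

## 3. Voltage-clamp protocols and trace analysis

Protocol generators cover the experimental designs: pulse trains
(`pulse_train_protocol`; 5 ms pulses at 5/10/20 Hz give the 195/95/45 ms
inter-pulse intervals) and two-pulse recovery series
(`recovery_protocol`) with log-spaced delays spanning 1 ms–6 s, the
inter-sweep span used experimentally. Trains degenerate gracefully: a
pulse equal to the period is a single constant depolarisation. The
default initial state is the stationary distribution at the holding
potential — the rested population after a long inter-sweep interval.

Macroscopic current is ohmic in the conducting occupancy,
$I = G_{Na} P_O (V - E_{Na})$, with conductance given either as a total
(nS) or as a density (nS/pF) with the membrane capacitance. $E_{Na}$
defaults to $+60$ mV and is configurable: the experimental solutions
imply a lower Nernst value, but the injected model current used its own
convention, so this is exposed rather than hard-coded. Default sampling
is 0.01 ms (100 kHz digitisation).

Per-pulse peaks are the extremum of $|I|$ inside each pulse window;
availability is the peak normalised to the first pulse, and
$P_S = 1 - I^p/I^0$ (clipped to $[0,1]$, since noise can push
availability slightly above 1). The identity relies on the inter-pulse
interval exceeding roughly ten fast-recovery time constants so the I
states are empty at each pulse onset; under that condition the estimate
tracks the model's true inter-pulse $P_S$ to better than $10^{-3}$
(tested at the 0.05 level the rationale supports).

Bi-exponential recovery fits,
$A(t) = a_f(1 - e^{-t/\tau_f}) + a_s(1 - e^{-t/\tau_s})$, use
Levenberg–Marquardt least squares (`minpack.lm`) with uniform weights (no
weighting scheme is specified for the original analysis). Starting values
come from a two-segment split of the delays at their geometric mean plus
a small multi-start grid, keeping the lowest-RSS converged fit;
components are ordered $\tau_f < \tau_s$ afterwards. Degenerate cases
are flagged, not hidden: a time-constant ratio under 3 flags the split as
unreliable, and effectively mono-exponential data (where the
two-component Jacobian is singular) falls back to a flagged
single-component fit — the behaviour the non-LTI model exercises. On
noiseless self-generated curves the fitter recovers parameters to
$10^{-6}$ relative; per-voltage fits are always independent (no global
fit across voltages is attempted, since none is described).

## 4. The leaky integrator

Three integrator forms are implemented. The continuous form
$dy/dt = x - y/\tau_{leak}$ is solved exactly per constant-input
segment. The elementary discrete recursion
$y_{t+\delta t} = y_t e^{-\delta t/\tau_{leak}} + x_{t+\delta t}\delta t$
has the two published limits — a running sum (event counter) when
$\tau_{leak} \gg \delta t$ and a scaled copy of the input when
$\tau_{leak} \ll \delta t$ — and is linear (superposition holds exactly,
a property the saturating form must violate; both directions are tested).
The saturating form for digital inputs,
$$y_{t+\delta t} = y_t e + x_{t+\delta t}\,y_{inc}\frac{\delta t}{t_p}(1 - y_t e),
\qquad e = e^{-\delta t/\tau_{leak}},$$
spreads a maximum increment $y_{inc}$ (default 0.2, the per-pulse LTI
share) over the pulse duration $t_p$ and is bounded in $[0,1]$ for every
input sequence. Defaults: $\delta t = 0.05$ ms (the original's sampling
interval is unstated; results are insensitive at this resolution),
$t_p = 5$ ms, $\tau_{leak} = 435$ ms. The digital-input restriction is
enforced by type, and $\delta t > t_p$ is rejected (the increment
spreading would be undefined).

Two analytic points the tests pin down, because the idealised
descriptions are only approximate:

* a full pulse from rest loads $1 - e^{-y_{inc}} \approx 0.181$, not
  exactly $y_{inc}$: the recursion multiplies the remaining headroom
  every step (the single-step $\delta t = t_p$ case is exactly
  $y_{inc}$); the tests allow the $y_{inc}^2/2$ compounding error;
* under sustained input the fixed point is
  $g/(1 - e + g e)$ with $g = y_{inc}\delta t/t_p$ — about 0.946 at the
  default step, approaching 1 only as $\delta t \to t_p$. The
  qualitative divergence stands: under constant input the integrator
  saturates near its plateau while the channel model relaxes to
  $P_{S\infty} \approx 0.7$, and the two agree closely at low pulse
  rates (within 0.05 at 2 Hz).

Steady-state comparisons resample the model trajectory by zero-order
hold onto the integrator grid and report per-frequency steady minima,
maxima, means, and the difference of means. Frequency-response runs
iterate the exact two-matrix cycle map until the cycle-to-cycle drift of
the cycle maximum falls below $10^{-7}$, extending the run as needed
(failure to reach $10^{-4}$ is an error, never a silent result).

## 5. The in-silico dynamic clamp and the surrogate host neuron

The hybrid simulator reproduces the structure of the conductance-injection
experiments entirely in software: a 50 kHz loop (0.02 ms steps) in which
the Nav occupancies advance by the matrix method at the present membrane
potential and the host membrane advances one Euler step under
$I_{Na} = G_{Na} C_m P_O (V - E_{Na})$. Per-step transition matrices are
precomputed on a 0.5 mV voltage grid over $[-120, 60]$ mV and linearly
interpolated; a convex combination of row-stochastic matrices is
row-stochastic, so conservation is preserved exactly (tracked to
$10^{-8}$ in every run). A membrane potential leaving the grid is treated
as numerical divergence and reported with its time. Halving the time step
changes the steady firing rate by well under 2%. Two models can be
integrated in parallel with an injection schedule selecting which one
drives the cell — the model-swap protocol.

The host cell is an invented surrogate (the original experiments injected
current into live pacemaker neurons) and is documented as such: a single
compartment, 20 pF, with a passive leak, a delayed-rectifier potassium
conductance, a fast regenerative "shoulder" conductance that stereotypes
and broadens the spike (the stand-in for the calcium shoulder these
pacemakers have; it also lets the cell keep firing shallow spikes without
sodium current, which is the documented behaviour of the real neurons
under TTX — with the shoulder disabled, zero conductance means zero
spikes), and a slow spike-activated adaptation conductance representing
the strong non-Nav adaptation the host neurons are reported to have. The
defaults were calibrated once to the documented phenotype — regular
3–8 Hz pacemaking with 3–6 ms spikes when driven by the non-LTI model at
10 nS/pF — and then frozen; all conductance-injection results are
qualitative, property-level reproductions, never numeric matches to
live-neuron slopes or frequencies.

The calibration taught us something worth recording. In a minimal host
the LTI model can *accelerate* firing: recovery from S passes through
the open state, producing a standing inward current of order 1 pA
throughout the interspike interval (proportional to
$P_S\,k_{13,6}(V)/$deactivation rate), which outruns the availability
deficit when spikes are narrow or the interspike trajectory dips deep.
The published ordering — LTI strictly slower at equal conductance —
emerges robustly only in the regime the real neurons actually occupy:
broad spikes (narrower than 2 ms would halve the per-spike LTI load),
an interspike trajectory riding above about $-60$ mV where the S state
drains slowly and the stored $P_S$ stays high, and adaptation keeping the
rate in the single-Hz range. In the frozen configuration the LTI model
fires below the non-LTI model at every conductance tested
(5–20 nS/pF), both frequency–conductance curves rise approximately
linearly, the stationary frequency–input curve is flatter for the LTI
model with a positive adaptation transient after each bias step, and
swapping the active model from LTI to non-LTI mid-step raises the rate.
The live-neuron observation that the two curves converge at high
conductance (steeper LTI slope) reflects interspike-ramp saturation in
real cells and is not reproduced by this surrogate; the shipped curves
stay nearly parallel.

Spike detection uses upward threshold crossings at $-20$ mV with a 5 ms
refractory filter, the spike time being the local voltage maximum;
instantaneous frequency is the inverse interspike interval timestamped at
the later spike, and "steady" frequency averages the instantaneous
frequency over the second half of a step window, as in the experimental
analysis. Bias currents above 40 pA are warned against (they produced
depolarisation block experimentally and shipped protocols avoid them).

## 6. Synthetic recovery cohorts

The four published bi-exponential recovery parameter sets (neonatal
slice and acutely isolated mature preparations, each at $-80$ and
$-100$ mV, with SEs and cell counts) are built in. The cohort generator
emulates — and is documented as emulating, not reconstructing — the
statistical structure of those recordings: per-cell availability is the
ground-truth curve plus Gaussian noise on the normalised availability
(the actually measured quantity; default SD 0.02), clipped to
$[0, 1.05]$, and with `cell_jitter = TRUE` each cell draws its own
parameters around the published means with SD $= SE\sqrt{n}$ (draws
rejected until amplitudes are positive and $\tau_f < \tau_s$). Every
generator is a pure function of its parameters and seed — bit-identical
on reruns, and the session RNG stream is restored afterwards. The
cohort mean converges to the ground-truth curve as cells accumulate
(tested at $n = 100$ with a per-point $3\sigma/\sqrt{n}$ bound — the
statistically sound version of a two-sigma expectation across twenty
delay points).

`scripts/acceptance.R` uses the neonatal $-80$ mV set with availability
noise only (no cell jitter — the reported quantity is the recovery of the
printed means, and the full jitter, with an SD of 322 ms on the slow
constant, is a cohort-level emulation that would require truncation):
18 cells, 20 log-spaced delays over 1 ms–6 s, per-cell refits, and the
across-cell mean fitted constants. At seed 1 this gives a mean slow
constant of 623 ms and a mean fast constant of 3.14 ms against generating
values of 612 and 3.14 ms.

## 7. Problem sizes, limitations, and what the tests show

Shipped simulations are sized for a desk machine: single pulses and
recovery series run in well under a minute; frequency-response runs
iterate a few hundred to a few thousand exact cycle maps; hybrid runs
use 10–16 s of simulated time per condition (about a second of wall time
each through the compiled loop). The full test suite, including the
acceptance checks, runs in a few minutes.

What passing tests establish: the solver is exact for piecewise-constant
commands to the stated tolerances; the frozen synthetic table reproduces
the published model-derived quantities (leak constants, splits,
equilibrium occupancies, the 100 Hz band, the bi-exponential recovery
structure); the analysis stages recover what they are fed (fitter
exactness, availability identity, cohort refits); and the feedback-loop
properties hold in the surrogate (ordering, flatness, adaptation,
frequency sensing). What they do not establish: agreement with any real
recording beyond the published summary numbers — the rate table away
from the calibrated anchors is conjectural, the host neuron is not a
biophysical model of a real cell (no reconstructed morphology, no
measured conductance complement, spike shapes only phenomenologically
correct), and live-neuron quantities such as the frequency–conductance
slopes are explicitly out of scope. Closed-state entry into LTI is not
modelled (S13 connects only to the open state), mixed channel
populations are not represented, and no thermodynamic cycle-balance
constraint is imposed on user-supplied tables.
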