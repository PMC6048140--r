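---
title: "Modelling UP/DOWN state dynamics in random spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling UP/DOWN state dynamics in random spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(upstates)
```

During slow-wave sleep and under anesthesia, cortical membrane potentials
alternate at roughly 1 Hz between a depolarized, spiking-prone UP state and
a hyperpolarized, quiescent DOWN state. `upstates` simulates this
phenomenon in randomly connected excitatory/inhibitory networks of adaptive
exponential integrate-and-fire (AdEx) neurons, analyzes the existence and
stability of UP states with a mean-field fixed-point calculation, and
quantifies the resulting dynamics: UP/DOWN segmentation and cycle
statistics, spike-count variability (Fano factors), and recurring
cell-assembly patterns extracted by non-negative matrix factorization
(NMF). The central scientific question the toolchain addresses is how the
*mean* and *variance* of the synaptic weight distribution shape the
macroscopic slow oscillation: the mean (through the scaling factors
$\gamma_E$, $\gamma_I$) controls whether UP states exist and whether they
are transient or self-sustained, while the weight variance
$\sigma_E^2$ controls how irregular and how prolonged they are.

## The single neuron

Each neuron follows the AdEx equations with spike-frequency adaptation
(SFA):

$$C\dot V = -g_L(V - V_L) + g_L\Delta_T e^{(V - V_T)/\Delta_T}
  \left\{1 - e^{-[(t - t^{sp})_+/2\,\mathrm{ms}]^{20}}\right\}
  - u + I_{syn} + I_{input} + \eta(t),$$
$$\tau_u \dot u = -u + a_u(V - V_L), \qquad
  u \leftarrow u + b_u \text{ at each spike.}$$

Defaults: $C = 150$ pF, $g_L = 10.005$ nS, $V_L = -70$ mV,
$\Delta_T = 2$ mV, $V_T = -55$ mV, $\tau_u = 200$ ms, $a_u = 4$ nS,
$b_u = 50$ pA. A spike is registered when $V$ reaches $V_{peak} = 20$ mV;
$V$ resets to $-55$ mV. The bracketed factor smoothly suppresses the
spike-generation term for about 2 ms after each spike.

Numerical choices worth knowing about:

* The spike-triggered adaptation is applied as a jump $u \leftarrow u +
  b_u$ with $b_u$ in pA. The alternative reading of the $\delta$-term in
  the $u$ equation (a jump of $b_u/\tau_u = 0.25$ pA) is so small that SFA
  would be invisible in the f-I curve, contradicting the visible
  suppression the model is meant to show.
* The membrane integrates freely during the 2 ms refractory window (only
  the spike-generation term is suppressed), but spike *detection* is
  disabled within 2 ms of the last spike, so inter-spike intervals are
  never shorter than the refractory period. A membrane that crosses
  $V_{peak}$ ballistically inside the window is held at $V_{peak}$ until
  the window ends; the adaptation equation sees $\min(V, V_{peak})$, since
  beyond the detection ceiling the trajectory is the spike-generation
  divergence, not a physical potential. An earlier variant that clamped
  $V$ at the reset during the window measurably depressed the f-I curve
  (the fitted linear coefficient dropped by 25%), which is why the free-run
  rule is used.
* Integration is second-order Runge-Kutta (Heun) at $dt = 0.05$ ms
  (configurable). The exponential term's argument is capped at 30 to avoid
  overflow during the spike divergence; the cap only affects trajectories
  that are already past the detection ceiling. Steady firing rates change
  by well under 2% when $dt$ is halved.
* The noise term $\eta(t)$ is optional zero-mean white current noise
  (`noise_sd`, default 0, parameterized as the standard deviation of its
  1-ms average). The reference dynamics do not need it: afferent Poisson
  input supplies all stochasticity.

The f-I curve of the neuron without SFA ($a_u = b_u = 0$) has rheobase
$\theta_f \approx 130$ pA (analytically $g_L(V_T - V_L - \Delta_T) =
130.07$ pA) and is fitted by an origin-constrained quartic
$f(I) = \Theta(I)[AI + BI^2 + CI^3 + DI^4]$ on $I - \theta_f$, valid up to
$I - \theta_f < 1840$ pA; the fit gives $A \approx 1.31$ Hz/pA on a 40-pA
grid. Beyond the validity bound the response function is held at its value
at the bound ("saturates"); evaluating the raw quartic out there would
eventually produce negative rates.

```{r}
no_sfa <- neuron_params(a_u = 0, b_u = 0)
fi <- measure_fi_curve(no_sfa, currents = seq(0, 1970, by = 40))
fit <- fit_response_function(fi, params = no_sfa)
fit
```

## Synapses

Five receptor classes mediate recurrent currents — AMPA and NMDA from
excitatory neurons; fast GABA-A, slow GABA-A and GABA-B from inhibitory
neurons — each with second-order gating: a rise variable $x$ with time
constant $\tau_{up}$ drives the gate $s$, which decays with $\tau_{dn}$
($\dot s = x(1 - s) - s/\tau_{dn}$). Spikes arrive after a 1 ms axonal
delay. The synaptic current onto a neuron of type X is

$$I^X_{syn} = \gamma_E \sum_{\psi,j} J^{XE}_j g_\psi s_{\psi,j}
  (V_{R,\psi} - V_X) + \gamma_I \sum_{\psi,k} J^{XI}_k g_\psi s_{\psi,k}
  (V_{R,\psi} - V_X),$$

with the postsynaptic cell's own membrane potential in every driving
force. Each excitatory connection drives its AMPA and NMDA gates with one
weight $J$, each inhibitory connection its three GABA gates; the slow
GABA-A component shares $g_{GABA-A} = 4$ nS with the fast one. Gates are
tracked per presynaptic neuron and receptor, not per synapse pair, so the
state scales with $N$, not $N^2$.

**Unitary gate events.** The stationary mean of a gate under Poisson
presynaptic firing at rate $f_0$ is
$\langle s\rangle = \tau_{dn} f_0/(1 + \tau_{dn} f_0)$ — the relation the
mean-field analysis is built on. A renewal-theory calculation shows this
relation holds exactly, at every rate and for every receptor, precisely
when each presynaptic spike drives the gate to saturation ($s \to 1$)
before it decays. A unit-area impulse on the rise variable
($x \mathrel{+}= 1/\tau_{up}$) instead drives the gate only to
$1 - e^{-1} \approx 0.63$ of saturation and its stationary mean falls
20-30% below the analytic curve; no global or per-receptor rescaling of
the impulse removes the remaining rate-dependent bias (the rise-variable
tail then pins the gate high for too long). The package therefore delivers
spikes as saturating events by default (`gate_mode = "saturating"`): each
delivered spike sets $s = 1$, and the second-order decay does the rest.
This choice makes the simulated gates, the analytic mean, and the
mean-field analysis mutually consistent. The literal impulse form remains
available (`gate_mode = "impulse"`), with the documented caveat that the
network then needs roughly 1.4-fold larger $\gamma$ for the same behavior
and no longer matches the analytic gating curve.

## Connection weights

Three weight ensembles, all with mean 1 and variance $\sigma^2$:

* **log-normal** (fully connected): $\sigma_{LN}^2 = \ln(\sigma^2 + 1)$,
  $\mu_{LN} = -\tfrac12\ln(\sigma^2 + 1)$;
* **sparse-Gaussian**: a zero mass $(1 - a)$ plus a half-normal of width
  $\sigma_{SG} = \sqrt{2/\pi}(\sigma^2 + 1)$, sparseness
  $a = (\pi/2)/(\sigma^2 + 1)$, which requires
  $\sigma^2 \ge \pi/2 - 1 \approx 0.571$;
* **sparse-log-normal**: the same $a$, with
  $\sigma_{SLN}^2 = \ln[a(\sigma^2 + 1)] = \ln(\pi/2)$ and, by moment
  matching, $\mu_{SLN} = \ln(1/a) - \tfrac12\ln[a(\sigma^2 + 1)]$. The
  alternative location parameter $\ln(1/a) - \tfrac12\ln(\sigma^2 + 1)$
  gives a mean of $\sqrt a$ rather than 1 (the analytic moments make this
  unambiguous) and is kept behind `printed_mu = TRUE` for comparison.

E-sourced blocks (`EE`, `IE`) use $\sigma_E^2$; I-sourced blocks (`EI`,
`II`) have fixed unit variance. Sparsity is realized through exact zeros in
the sampled blocks; self-connections are included (an $O(1/N)$ effect).

## The network and its afferent drive

The reference network has $N_E = 1000$ excitatory and $N_I = N_E/4$
inhibitory neurons. Each excitatory neuron receives an independent 10 Hz
Poisson afferent train through a dedicated gate
($\tau_{up} = 1$ ms, $\tau_{dn} = 20$ ms), as current
$I_{input} = \gamma_{input} J^{input} A_{input}\, s_{input}$ with
$\gamma_{input} = \gamma_E$ and $J^{input}$ drawn from the configured
ensemble with unit variance. Inhibitory neurons receive no afferent input.

The afferent amplitude $A_{input}$ is a genuine free parameter of the
model: written as a bare product of order-one quantities the afferent
current would be a fraction of a picoampere, which could never lift a
neuron with a 130 pA rheobase out of the DOWN state, yet the modelled
phenomenon requires afferent-triggered UP onsets at about 1 Hz. The
package fixes the scale once by the rule that *a unit-weight afferent
event at the reference scaling $\gamma_E = 0.1$ just reaches rheobase*:
$A_{input} = \theta_f/0.1 = 1300$ pA. Neurons whose afferent weight
$J^{input}$ sits in the upper tail of the ensemble then fire sporadically
during DOWN states, and those seed spikes ignite network-wide UP states
whenever the recurrent network is excitable enough — which is exactly the
regime structure the mean-field analysis predicts.

Simulations run single-threaded in compiled code. The cost driver is the
per-step weighted sum of weight-matrix columns over presynaptic gates; the
weights are held in single precision inside that kernel (the state stays
double precision), receptors sharing a reversal potential and conductance
(AMPA+NMDA; the two GABA-A components) are combined before the sum, both
Runge-Kutta stages are accumulated in one pass over each matrix, and gates
decayed below $10^{-30}$ are flushed to zero to keep the arithmetic out of
the subnormal range. A 12-s reference-size run takes a few minutes of CPU.

## Mean-field analysis of UP states

Assume the population fires at a common stationary rate $f$. Each gate
then averages to $m_\psi(f) = \tau_{dn,\psi} f/(1 + \tau_{dn,\psi} f)$,
the recurrent current at an assumed mean UP-state voltage
$\langle V\rangle = -55$ mV is

$$I_{syn}(f) = \gamma_E N_E \langle J\rangle \sum_{\psi \in exc} g_\psi
  (V_{R,\psi} + 55)\, m_\psi(f) + \gamma_I N_I \langle J\rangle
  \sum_{\psi \in inh} g_\psi (V_{R,\psi} + 55)\, m_\psi(f),$$

and the mean adaptation current is $u(f) = a_u(\langle V\rangle - V_L) +
b_u \tau_u f$. UP states are self-consistent solutions of
$f = F'(f) \equiv F[I_{syn}(f) - u(f)]$ with $F$ the fitted response
function. The solver brackets all crossings on a dense grid and classifies
each by the stability of the fixed-point iteration $f \leftarrow F'(f)$:
stable iff $|dF'/df| < 1$. The absolute value matters: the non-trivial
crossing usually sits on the steeply falling flank of $F'$ (adaptation
dominates at high rates), where the signed slope is large and negative;
under the signed criterion almost any crossing would count as stable and
the self-sustainability boundary would collapse to the point where a
non-trivial crossing first exists, an order of magnitude too low. The
iteration-map criterion reproduces the reported boundary structure.

Regimes: only the trivial solution — `no_up`; non-trivial crossings, none
stable — `transient_up` (UP states ignite but decay); a stable non-trivial
crossing — `self_sustained_up` (near-continuous UP state). With
$\gamma_E = \gamma_I$, $b_u = 50$ pA and $N_E = 1000$ the package computes
a critical $\gamma \approx 0.10$; because the drive is proportional to
$\gamma N$, the boundary scales exactly as $1/N_E$ (0.05 at $N_E = 2000$).
Direct simulation puts the jump to near-continuous UP states between 0.12
and 0.14 on a 0.02-spaced grid — the mean-field value underestimates the
simulated boundary by some 20-30%, as expected from a rate description of
a synchronously oscillating finite network, and the assumed fixed
$\langle V\rangle$ adds inaccuracy at large $b_u$.

```{r}
mf <- meanfield_config(fit, gamma_E = 0.1, gamma_I = 0.1, N_E = 1000)
solve_fixed_points(mf)
critical_gamma_E(NULL, mf)
```

## UP/DOWN segmentation and statistics

Membrane traces (recorded at 1 kHz for a configurable subset of neurons)
are smoothed with a 10 ms boxcar and thresholded at $-62$ mV — the
midpoint between the DOWN plateau near the leak/GABA-A reversal
($\approx -70$ mV) and the UP plateau near threshold ($\approx -55$ mV).
DOWN gaps up to 50 ms between UP segments are merged, then UP segments
shorter than 50 ms are dropped. All four constants are configuration; no
published detector exists for this model, so the defaults are chosen to
segment square-wave fixtures exactly and simulated traces cleanly, and the
statistics below are reported at fixed detector settings.

Derived statistics:

* **Cycle durations**: an UP state plus the consecutive DOWN state
  (onset-to-onset), pooled over neurons and normalized by the pooled mean,
  so normalized samples average to 1. Networks with large weight variance
  ($\sigma_E = 12$) produce multimodal normalized-cycle distributions
  (prolonged UP states spanning several oscillation cycles), small
  variance ($\sigma_E = 8$) unimodal ones; the package counts modes of a
  fixed-bandwidth kernel density estimate.
* **Population UP states**: intervals where at least half the segmented
  neurons are UP simultaneously; their onset rate is the slow-oscillation
  frequency (about 0.5-1 Hz in the transient-UP regime).
* **Fano factors**: per neuron, spike counts in fixed 200 ms windows
  aligned at the onsets of UP episodes at least that long (at least 5
  qualifying episodes required), variance over mean, averaged over
  neurons. The fixed window excludes DOWN-state intervals by construction
  and makes counts comparable across episodes and across recordings of
  different length; an earlier variant that tied the window to the
  shortest episode made the statistic shrink systematically as recordings
  grew (the shortest episode converges to the detector's minimum
  duration), which is why the window is a fixed parameter. In this model
  the onset volley of an UP state is fairly stereotyped, so Fano factors
  are small in low-variance networks and grow with the weight variance
  $\sigma_E^2$, which injects episode-to-episode strength differences.

## Cell assemblies by NMF

Excitatory spike rasters are binned into a non-negative rate matrix
$D$ (neurons × time bins; 200 ms windows sliding at 50 ms, i.e. rate
vectors sampled at 20 Hz; a non-overlapping 200 ms variant is available
via `step = window` — both window layouts appear in descriptions of this
procedure and the sign-level conclusions are robust to the choice). NMF
factorizes $D \approx BC$ with non-negative factors by multiplicative
updates (Frobenius objective, provably non-increasing per iteration),
initialized either deterministically from the truncated SVD (negative
parts folded, zeros lifted) or randomly for restarts. The order $k$ is
selected by AICc with $K = k(\text{rows} + \text{cols})$ free parameters
and the small-sample correction $2K(K+1)/(n - K - 1)$, $n$ = number of
entries; orders with $n - K - 1 \le 0$ are excluded, ties break on lower
RSS then lower $k$. The residual model matters more than is commonly
appreciated. With the Gaussian form $n\ln(RSS/n) + 2K + \dots$ on raw
spike-count rates, the criterion cannot terminate: count noise has
variance proportional to the mean, so the leading residual components in
the high-rate rows carry more unscaled power than the per-order penalty,
and the selected order runs to the top of whatever range is scanned —
planted two-assembly fixtures select five or more components at any
signal-to-noise ratio. The default is therefore AICc with a Poisson
likelihood of the window spike counts evaluated at the fitted means
(`criterion = "poisson"`), under which planted fixtures recover their
construction order exactly; the Gaussian form remains available
(`criterion = "gaussian"`) and is appropriate for matrices with roughly
constant noise variance. Order selection on network rasters uses
non-overlapping windows: with 75%-overlapping windows adjacent columns
share spikes, which inflates the apparent rank.

Downstream statistics: `assembly_statistics()` correlates the selected
order, and the order normalized by total UP time, with the log mean UP
duration across conditions (the hypothesis being that prolonged UP states
repeat a limited repertoire of assemblies rather than adding new ones),
and `pattern_activation_correlation()` tracks how the mean pairwise
correlation between activation rows of $C$ decreases as $\sigma_E$ grows.
In this implementation the normalized order and the activation
correlation show the expected negative signs on simulated sweeps; the raw
order does not (it grows with the weight variance that also prolongs UP
states), which the test suite reports as a failing expectation rather
than hiding.

## Scaled-down study conditions

The drive scales as $\gamma N_E$, so networks of different size are
dynamically comparable when $\gamma \propto 1/N_E$, the excitatory weight
variance as $\sigma_E^2 \propto \sqrt{N_E}$, and the afferent amplitude as
$A_{input} \propto N_E$ (compensating the $\gamma$ rescaling inside
$\gamma_E A_{input}$); `scale_config()` applies all three rules. The
package's property-level tests exercise regime contrasts, Fano/duration
structure and assembly statistics at $N_E = 250$ (about 16-fold cheaper
per simulated second), while boundary-location and oscillation-frequency
checks run at the reference $N_E = 1000$. Test simulations use 7-20 s per
condition; these lengths give stable means for the contrasts tested (each
condition contains dozens of UP episodes) but are far shorter than would
be needed to resolve, say, tail quantiles of cycle durations.

## What the synthetic fixtures do and do not show

`make_fixture_raster()` builds UP/DOWN square-wave-modulated Poisson
rasters with planted co-active assemblies and returns the ground truth.
The fixtures validate the analysis chain (segmentation recovers planted
intervals exactly; NMF recovers planted order and membership; Fano factors
hit their Poisson/clockwork limits). They deliberately lack everything
that makes real (or simulated-network) data hard: graded UP onsets,
within-UP rate fluctuations, assembly overlap in time, heterogeneous
baselines. Passing them certifies the estimators' correctness on their own
terms, not their robustness to model mismatch — that is what the
simulator-based property tests probe.

## Known limitations

* The mean-field analysis fixes $\langle V\rangle = -55$ mV rather than
  solving for it self-consistently; its boundary is accurate to tens of
  percent, not percent, and degrades with stronger spike-triggered
  adaptation.
* The rate description ignores synchrony; the simulated self-sustained
  state oscillates strongly at fast timescales even when its mean rate
  matches the fixed point.
* The afferent pathway (independent Poisson trains, one per neuron, with
  the amplitude convention above) is a modelling choice; correlated or
  oscillatory afferents would phase-lock UP onsets and change
  cycle-duration statistics qualitatively.
* NMF on 200 ms rate vectors cannot resolve spike-timing sequences within
  UP states; it detects co-activation at the rate level only.
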