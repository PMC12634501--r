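---
title: "Neural heterogeneity in spiking networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural heterogeneity in spiking networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`hetsnn` studies how three channels of neural heterogeneity — external
drive, recurrent coupling gain, and the partial post-spike reset — shape
what an all-to-all coupled population of Izhikevich (adaptive quadratic)
neurons can learn. Each neuron obeys

$$C \dot v_i = k (v_i - v_r)(v_i - v_t) - w_i + \eta_i + I_{\rm ext}(t)
  + g_i\, s\, (E - v_i), \qquad
  \tau_w \dot w_i = \beta (v_i - v_r) - w_i,$$

with a spike emitted when $v_i \ge v_{\rm peak}$, after which

$$v_i \leftarrow v_{\rm reset} + \theta_i (v_i - v_{\rm peak}), \qquad
  w_i \leftarrow w_i + w_{\rm jump}.$$

$\theta_i = 0$ is a full reset; $\theta_i > 0$ retains a fraction of the
overshoot above the cutoff. The scalar gating variable $s$ decays with
$\tau_s$ and jumps by $s_{\rm jump}/N$ per spike anywhere in the network,
so $g_i s (E - v_i)$ is the recurrent conductance input.

The three per-neuron parameters $\eta_i$, $g_i$, $\theta_i$ are drawn from
Lorentzian (Cauchy) densities
$p(x) = \Delta / \{\pi[(x - \bar x)^2 + \Delta^2]\}$, each with a center
and a half-width-at-half-maximum. The Lorentzian makes an exact mean-field
reduction possible and has genuinely heavy tails; bounded channels
($\theta \in [0,1]$, $g \ge 0$) are sampled by rejection so the shape on
the support is preserved.

## Default constants

The package ships one preset, `ca3_params()`, a published
pyramidal-cell Izhikevich set: $C = 250$ pF, $k = 2.5$ nS/mV,
$v_r = -60$ mV, $v_t = -20$ mV, $v_{\rm peak} = 30$ mV,
$v_{\rm reset} = -65$ mV, $\tau_w = 100$ ms, $\beta = 0$,
$w_{\rm jump} = 200$ pA, $\tau_s = 20$ ms, $s_{\rm jump} = 1$, and
synaptic reversal $E = 0$ mV (excitatory). The rheobase of the isolated
quadratic model is $k((v_t - v_r)/2)^2 = 1000$ pA, a useful anchor for
all drive values below. With coupling center $\bar g = 15$ nS the preset
is validated by exhibiting the three dynamical regimes of the mean-field
analysis; it makes no claim of quantitative biological calibration.

# Mean-field reduction and regimes

For Lorentzian-distributed drive (width $\Delta_\eta$), homogeneous $g$
and full reset, the infinite-network limit closes exactly in four
variables $(r, \bar v, \bar w, s)$ — the population rate (kHz), mean
voltage, mean adaptation and gating. Writing the voltage equation as
$\dot v = a v^2 + b v + c$, the characteristic
$z = \bar v + i \pi C r / k$ obeys
$\dot z = a z^2 + b z + c + i \Delta_\eta / C$, giving `meanfield_rhs()`:

$$\dot r = \frac{k}{C} r (2\bar v - v_r - v_t) - \frac{\bar g s}{C} r
  + \frac{\Delta_\eta k}{\pi C^2},$$

plus the matching $\dot{\bar v}$ (with a $-\pi^2 C r^2 / k$ pressure
term), $\dot{\bar w}$ including the spike-triggered $w_{\rm jump} r$, and
$\tau_s \dot s = -s + \tau_s s_{\rm jump} r$.

`scan_bifurcation()` continues the fixed point along a drive grid
(predictor-free Newton from the previous solution; central
finite-difference Jacobians, step $10^{-6}$ in scaled units) and locates
Hopf points by bisection on the leading eigenvalue's real part. On the
default preset with $\Delta_\eta = 1$ pA the scan finds exactly two Hopf
points near 1004 and 1171 pA. Below the window the only attractor is a
near-silent fixed point (quiescent); between them a stable limit cycle —
collective ~2–5 Hz bursting whose frequency rises with drive; above it a
stable active fixed point (persistent, tens of Hz). `classify_regime()`
labels these and flags ambiguous/bistable cases instead of resolving them
silently.

The reduction assumes infinite reset/cutoff and a full reset; we use it
with the finite constants above. Validation is therefore empirical: at
$N = 10^4$ the simulated population rate in the persistent regime matches
the fixed-point rate within ~6–10%, and the collective burst frequency in
the oscillatory window matches the mean-field cycle within ~7–15%
(periodogram dominant frequency of the gating variable; burst waveforms
have intra-burst sub-peaks, so peak-interval counting is unreliable).
The residual bias is the known finite-cutoff effect.

# Stage 1: ridge-readout reservoir experiments

A single linear readout is trained on the per-neuron exponentially
filtered spike trains (unit-area kernel, time constant $\tau_s$, sampled
every 1 ms) to reproduce $y_1(t) = \sin(12\pi t)$ or
$y_2(t) = \sin(12\pi t)\sin(24\pi t)$ ($t$ in seconds; both periodic with
a 6 Hz fundamental). The readout is the closed-form ridge solution;
`rls_readout()` implements the classic one-sample recursive form and is
algebraically identical (tested to $10^{-8}$).

**Stimulation protocol.** A single brief pulse leaves the network's
subsequent activity at the mercy of its slow adaptation state: we measured
30–60% trial-to-trial RMS differences in stimulus-locked responses, so a
readout trained on one stretch of autonomous activity does not
generalize. The experiment therefore drives the network with a *periodic
train* of brief pulses (60 ms, 300 pA, one per 1/6 s) that entrains the
collective oscillation to the targets' fundamental. In the entrained
steady state the features are periodic, and a contiguous train/test split
(2 s settle, 5 s train, 2 s test) probes genuine out-of-sample
reproduction. Default network size 2000; ridge scale
$\lambda = 10^{-3}\,\mathrm{tr}(X^\top X)/p$.

**Benchmark conditions.** The heterogeneous benchmark uses
$\bar\eta = 1090$ pA with $\Delta_\eta = 20$ pA — the widest drive
heterogeneity that still leaves a Hopf pair (window $[1043, 1160]$), so
the operating point stays in the oscillatory regime. The quiescent probe
sits far below the window ($\bar\eta = 500$, $\Delta_\eta = 1$); with
wider tails the probe is not meaningful because Cauchy outliers alone can
carry the fit. The homogeneous control zeroes all three widths and the
reset ($\bar\theta = 0$); it synchronizes completely, its feature matrix
collapses to rank one, and the $y_2$ fit saturates near the target
variance. Reintroducing drive or coupling heterogeneity restores the fit
by roughly an order of magnitude.

**What the partial reset can and cannot do here.** The reset rule acts on
the overshoot $v - v_{\rm peak}$ at threshold crossing, which under
forward Euler at $dt = 0.05$ ms is only a few mV — an $O(dt)$ quantity.
In the continuous-time stages the $\theta$ channel is therefore nearly
dynamically inert: it neither desynchronizes the homogeneous network nor
restores the readout, consistent with the observation that the width
$\Delta_\theta$ has no visible effect. Its center $\bar\theta$ matters
where overshoots are large — in the discrete-time classifier below
($dt = 1$ ms), where a strong partial reset visibly raises spike counts.

**Excessive heterogeneity.** Under periodic drive, very wide
$\Delta_\eta$ keeps improving the linear fit (the tail neurons form a
diverse filter bank); degradation appears only at widths far beyond the
regime structure (the Hopf window itself disappears above
$\Delta_\eta \approx 20{-}50$ pA). Excessive *coupling* heterogeneity
does degrade the fit (upturn between $\Delta_g = 10$ and 50 nS).

# Stage 2: FORCE learning

FORCE replaces the gating coupling by two current pathways on the
filtered traces $r$: a sparse static random matrix scaled by $G$
(entries $\mathcal N(0, 1/(p n))$, density $p = 0.1$) and a learned
rank-one feedback $Q\,\mathrm{enc}\,(\phi^\top r)$ whose decoder is
updated online by RLS (every 50 steps, $P_0 = I/\lambda$,
$\lambda = 0.01$; larger $\lambda$ visibly over-regularizes features of
magnitude ~0.05 and the error never contracts). The decoded traces use a
double-exponential filter (rise 2 ms, decay $\tau_s$): with a first-order
filter each spike jumps the feedback discontinuously and the closed loop
cannot stabilize.

Reported performance is $\log_{10}$ of the autonomous test MSE normalized
by the target's mean square, so 0 is exactly the "no better than
silence" boundary. The default target is the 6 Hz sinusoid; the
product-of-sines target's 18 Hz component is not autonomously
reproducible at this scale (no condition reaches the boundary), and a
slowed product variant kills the marginal networks outright, so the
sinusoid is the discriminating benchmark.

The bias current is set just above rheobase ($\bar\eta = 1010$ pA), where
a homogeneous network is marginally active: at the mistuned gain pair
$(G, Q) = (2\times10^3, 9\times10^3)$ its learning fails in most runs,
while drive heterogeneity ($\Delta_\eta = 100$ pA) or coupling-gain
heterogeneity ($\Delta_g = 10$, acting multiplicatively on the static
pathway) restores success in essentially every run. Combined
heterogeneity maximizes the viable count on a $4\times4$ grid of
$(G, Q)$ bracketing that point. In the *combined* condition the drive and
gain supports are clipped at 50 and 10 half-widths: an unbounded Cauchy
tail together with $\theta$ close to 1 produces a runaway reset (the
retained overshoot grows without bound); the integrators additionally
clamp the retained potential at the cutoff. Single-channel conditions
keep unbounded supports — a full reset makes them safe.

# Stage 3: surrogate-gradient classification

A discrete-time ($dt = 1$ ms) feed-forward network of Izhikevich units is
trained by backpropagation through time with a hard-threshold forward
pass and the fast-sigmoid pseudo-derivative
$1/(1 + 0.8\,|v - v_{\rm peak}|)^2$ backward. For the gradient check the
forward pass is replaced by the smoothed spike whose exact derivative is
the surrogate; the analytic gradient then matches central finite
differences to $<10^{-4}$ on toy instances. Optimization is minibatch
Adam (rate $2\times10^{-3}$); class scores are the time-sum of a leaky
integrator (decay 0.9/step) of the last layer's spikes under softmax
cross-entropy.

Inputs are synthetic event streams (64-or-fewer channels): a rate task
(class-dependent Poisson rates, separable from counts alone) and a timing
task in which every channel emits exactly the same number of spikes in
every sample and classes differ only in jittered timing templates —
count-based classifiers are at chance by construction. The benchmark uses
32 channels, 100 ms samples in 50 bins, one spike per channel, 12 ms
jitter, a single hidden layer of 100 units, 15 epochs.

Units are biased near rheobase ($\bar\eta = 900$ pA) so they act as
coincidence detectors. The heterogeneous initialization disperses the
distance to threshold ($\Delta_\eta = 30$ pA on $[650, 980]$), the input
gain ($\Delta_g = 0.15$ around 1), and the partial reset
($\bar\theta = 0.2$, $\Delta_\theta = 0.05$); parameters are sampled once
and frozen (a trainable-bias mode exists behind a flag). On the timing
task the heterogeneous initialization is on average at least as accurate
as the homogeneous control, with gains of a few percent — the same order
as reported for event-stream benchmarks — but with substantial
seed-to-seed variance at this scale.

# What the synthetic data do and do not show

The generators emulate the *temporal statistics* that the analyses
need — Poisson rate codes, count-matched timing codes, jitter noise —
not the content of any real neuromorphic dataset. Passing results show
that the implementation behaves as the theory predicts under controlled
conditions; they do not certify accuracy on real event-camera or speech
data, which involve correlated channels, bursts and far larger scale.

# Numerical choices and limitations

* Forward Euler, default $dt = 0.05$ ms, threshold-then-reset within the
  step (no crossing interpolation); spike-time convergence is first order
  and tested, not assumed. Gating decay uses the exact exponential.
* The gating variable is not clipped at 1: its equation does not enforce
  an upper bound for arbitrary $s_{\rm jump}$ and rates, and clipping
  would silently distort strong-coupling regimes.
* The global drive $I_{\rm ext}(t)$ is added to every neuron on top of
  $\eta_i$.
* Problem sizes (N = 2000 readout networks, N = 10000 validation runs,
  n = 1000 FORCE networks, 5 s training stretches, 3–10 seeds per
  condition) are desk-scale choices that keep a full reproduction run in
  the tens of minutes; all are configurable upward.
* Heavy Cauchy tails are physical poison in two places: they abolish the
  quiescent regime at wide $\Delta_\eta$, and combined with a strong
  partial reset they cause a runaway reset. Bounded supports are used
  where channels are combined.
* The partial-reset channel's near-inertness in continuous time at fine
  $dt$ is a genuine property of the printed reset rule, not an
  implementation accident; treatments that report strong $\theta$ effects
  in continuous-time networks implicitly rely on coarse integration steps
  with large overshoots.
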