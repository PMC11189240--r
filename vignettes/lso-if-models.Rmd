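---
title: "Integrate-and-fire models of the lateral superior olive: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrate-and-fire models of the lateral superior olive: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsoif)
```

## Scope and model family

Neurons of the lateral superior olive (LSO) compare excitation driven by the
ipsilateral ear with inhibition driven by the contralateral ear, and thereby
encode interaural level differences (ILD) and envelope time differences (ITD)
— the binaural cues of sound localization. `lsoif` implements a family of six
single-compartment integrate-and-fire (IF) models of sustained-firing LSO
neurons, a common synthetic synaptic input stage, the monaural and binaural
tuning experiments used to calibrate and compare the models, interspike-
interval statistics, and subthreshold characterization tools.

All six models integrate the same membrane equation,

$$C\,\frac{dV}{dt} = I_{synE} + I_{synI} + I_L + I_K + I_{exp} + I_{spike},$$

with terms switched on or off per variant:

* **Passive membrane** (`PLk`, `PSp`, `PEx`): leak only,
  $I_L = g_L (E_L - V)$, an RC circuit with linear I–V relation.
* **Active membrane** (`ALk`, `ASp`, `AEx`): adds a low-voltage-activated
  potassium current $I_K = g_K\, d(t)\,(E_K - V)$ (KLVA, the Kv1-type
  conductance prevalent in time-coding auditory neurons). The open fraction
  $d$ relaxes with first-order kinetics; the opening/closing rates are
  $\alpha(V) = 0.5\,e^{+(V+50)/16}$ and $\beta(V) = 0.5\,e^{-(V+50)/16}$
  (1/ms), giving a logistic steady state $d_\infty(V)$ with half-activation
  at $-50$ mV and $\tau_d(-50) = 1$ ms.
* **Spike generation**, three mechanisms per membrane group:
  * `Lk` — threshold crossing at $V_{th}$, instant reset to $V_{ref}$, and a
    clamp at $V_{ref}$ for the absolute refractory period $T_{ref}$;
  * `Sp` — threshold crossing triggers a stereotyped biexponential
    spike-mimicking current
    $I_{spike}(t) = A_1 e^{-(t-s)/\tau_1} - A_2 e^{-(t-s)/\tau_2}$ with *no*
    voltage reset; only spike detection pauses for $T_{ref}$;
  * `Ex` — an exponential IF (EIF) spike-generating current
    $I_{exp} = g_T K_T \exp((V - V_T)/K_T)$ produces the upswing
    intrinsically; detection at a high threshold ($-10$ mV), then reset and
    clamp as in `Lk`.

`lso_params()` ships the published parameter set of each variant (capacitance
24 pF; passive $g_L$ 26.4 nS, $E_L$ $-60$ mV; active $g_L$ 14.4 nS, $E_L$
$-56$ mV, $g_K$ 21.6 nS, $E_K$ $-75$ mV; $V_{ref}$ $-60$ mV; $T_{ref}$ 2 ms;
and the variant-specific spike parameters). Units are mV/ms/nS/pF/pA
throughout, which closes dimensionally ($\mathrm{nS \cdot mV = pA}$,
$\mathrm{pF \cdot mV / ms = pA}$); the nA spike-current amplitudes are stored
as pA.

## Synaptic input stage

Each model neuron receives 20 excitatory and 8 inhibitory afferent fibers.
Every fiber is an (in)homogeneous Poisson process. For amplitude-modulated
(AM) tone stimulation, the per-fiber mean rate and the degree of phase
locking depend on the modulation frequency $f_m$:

$$\lambda(f_m) = 180 - 0.03 f_m \ \mathrm{spikes/s}, \qquad
VS(f_m) = 0.65\,\frac{1 - e^{(f_m-2000)/500}}{1 + e^{(f_m-2000)/500}},$$

and for unmodulated tones the rate follows a sigmoidal rate-level function
$\lambda(s) = 30 + 240/(1 + e^{-(s-20)/6})$ spikes/s. Phase locking is
realized by a von Mises intensity profile over the modulation cycle whose
concentration $\kappa$ is solved from $I_1(\kappa)/I_0(\kappa) = VS$ to
$10^{-10}$; sampling uses exact thinning under the peak-intensity envelope.
The cycle-averaged rate always equals the nominal $\lambda$, and the
empirical vector strength of generated trains converges to the requested
value (tested to $\pm 0.01$ over 40 s).

Each input spike contributes an alpha-function conductance
$g(t) = A_{syn} (t/\tau_{syn}) e^{1 - t/\tau_{syn}}$ (excitatory: 3.5 nS,
0.16 ms, reversal 0 mV; inhibitory: 12 nS, 0.32 ms, reversal $-75$ mV);
all fibers sum, and the synaptic current is $g_{tot}(E_{syn} - V)$.

Two implementation notes. First, conductances are not built by kernel
convolution: the integration loop propagates each alpha-function bank with an
exact two-state exponential recursion, which reproduces the kernel sum at
grid points to machine precision at O(1) cost per step (the test suite
cross-checks it against a direct kernel-sum oracle). The spike-mimicking
current uses the analogous two-accumulator recursion. Second, every fiber
draws from its own RNG substream, with substream seeds derived
deterministically from one master seed — so the *identical* input
realization can be replayed into all six models, which is how the
cross-model comparisons are constructed.

### Phase convention

In binaural AM experiments the excitatory fibers lock at phase 0 and the
inhibitory fibers at the phase difference $\Delta\varphi$ (inhibitory minus
excitatory locking phase). The sign convention is anchored to an observable:
at 300 Hz the tuning curve of these models peaks near
$\Delta\varphi = -135^\circ$ and bottoms out near $+45^\circ$. LSO neurons
are *anticoincidence* detectors — firing is maximal when inhibition arrives
out of phase with excitation.

## Experiments and response criteria

Three standard experiments (defaults: 40 s per stimulus condition, forward
Euler at $dt = 2\,\mu s$):

* `phase_tuning()` — binaural AM phase-difference tuning; default grid
  $-180^\circ$ to $+180^\circ$ in $22.5^\circ$ steps at $f_m = 300$ Hz.
* `ild_tuning()` — binaural level-difference tuning with non-phase-locked
  fibers; ILD = contralateral minus ipsilateral level, grid $-45$ to $+50$ dB
  in 5-dB steps at an ipsilateral level of 35 dB.
* `monaural_am_tuning()` — AM-frequency tuning with excitation locked per
  the AM input model and inhibition at its 30 spikes/s spontaneous rate.

Each curve is summarized by its peak, trough, and depth (peak − trough), and
`score_criteria()` checks the nine physiological bands: monaural peak
120–160, trough 0–30, depth > 110; phase peak 110–140 (accepted 90–140),
trough 10–30, depth > 90 (accepted > 70); ILD peak 110–140 (accepted
110–160), trough 10–30, depth > 90. The "accepted" relaxations apply to the
passive models, which lack the KLVA conductance: KLVA closure under
phase-locked inhibition amplifies the voltage response to the subsequent
excitatory volley (raising the phase peak of active models), while KLVA
opening under intense excitation compresses the ILD peak. Active models
therefore score 9/9 targeted bands and passive models 6/9 (failing the phase
peak, phase depth, and ILD peak at the targeted level only).

### Grid choices

The published account does not print the exact abscissa grids. The phase and
ILD grids above follow the figure resolution and the text's anchor points.
For the monaural frequency grid we use
{50, 100, 150, 200, **250**, 300, 450, 600, 800, 1000, 1200} Hz: the 40-s
tuning curves of all variants peak between 200 and 300 Hz (e.g. the active
leaky model gives 145.5 at 200 Hz, 151.0 at 250 Hz, 140.0 at 300 Hz), so a
grid that skips 250 Hz cannot represent the curve's true maximum; the
reported peak values are only reachable when that region is sampled. The
trough lands at the highest frequency (1200 Hz), where locking is weak
(VS ≈ 0.43) and the mean rate is lowest.

### Statistical resolution and reproducibility

A 40-s condition at ~120 spikes/s has a rate standard error of about
1.7 spikes/s; peak/trough values, being maxima/minima over a noisy grid, are
additionally inflated/deflated by up to one standard error. Comparisons with
reference rates therefore use a ±5 spikes/s band (≈3 SE plus
cross-implementation integration differences). Every experiment is fully
determined by its (stimulus, seed) pair — identical seeds give bit-for-bit
identical spike counts. Three of the eighteen score-band checks (the AEx
phase peak vs the targeted edge 110, and the PSp/PEx phase peaks vs the
accepted edge 90) sit within ~1 SE of their band edges; reference values for
those quantities (111.8, 90.3, 90.4) clear the same edges by less than 2
spikes/s, so pass/fail on those three can flip between realizations even
when every rate agrees within the ±5 band.

## Numerical scheme

* **Forward Euler, $dt = 2\,\mu s$** (hard upper bound 10 µs enforced).
  Halving $dt$ changes spike counts by well under 2% (tested). No adaptive
  or implicit integrators: the published scheme is explicit Euler, and the
  exponential-current clipping below depends on the step being fixed.
* **Initial state**: the variant's resting potential (root of the
  steady-state I–V relation, found by `uniroot`), with
  $d_0 = d_\infty(V_0)$. This removes onset transients from 40-s rate
  estimates; the reference account is silent on initialization, and at 40 s
  the choice is worth < 0.1 spikes/s.
* **Refractory clamp**: for the reset variants V is held at $V_{ref}$ while
  $d$ *continues to integrate* at the clamped potential. This matters: the
  transient KLVA closure during the clamp produces the elevated hazard rate
  of active models at 3–4 ms interspike intervals.
* **EIF overflow**: the exponent $(V - V_T)/K_T$ is clipped at +20. One
  Euler step from there moves V far above any detection threshold, so the
  clip changes spike timing by at most one step while keeping the state
  finite. Spike times are recorded at the first *sample* with
  $V \ge V_{th}$, i.e. quantized to the step; the EIF upswing makes PEx/AEx
  spikes emerge ~0.1 ms after the equivalent threshold models', which is
  left uncorrected (it is a property of the mechanism).
* **Ties and degenerate inputs**: multiple input spikes in one grid bin sum
  linearly; empty inputs are valid (quiescence tests rely on this); a
  non-finite membrane potential aborts with the offending time and step.

## Interspike-interval statistics

`isi_histogram()` bins successive intervals at $T_{bin} = 0.2$ ms and
normalizes counts by (bin width × total ISI count), giving a density in 1/s.
`hazard_rate()` computes $H_i = N_i / (T_{bin} S_i)$ with survivor mass
$S_i = \sum_{j \ge i} N_j$, truncated strictly before the first bin with
$S_i < 2\%$ of the total — beyond that point the estimator is dominated by a
handful of long intervals. `conditional_mean()` reports the mean following
interval per preceding-interval bin, only for bins holding more than 0.5% of
the ISI count. For these IF models the conditional mean is flat (renewal
behaviour): reproducing the negative serial ISI correlations seen in some
LSO neurons would require an additional slow (~10 ms) current, which is
deliberately out of scope. The ISI stimulus is the ipsilateral excitatory
input of the ILD experiment at a given level with contralateral inhibition
held at the 30 spikes/s spontaneous floor; run duration defaults to the
40-s standard.

## Subthreshold characterization

`iv_curve()` returns the holding current with spike mechanisms disabled.
`impedance()` linearizes the membrane about an operating point: passive
$|Z| = 1/|g_L + i\omega C|$ (about 37.9 MΩ at DC, corner ≈ 175 Hz); the
active models add the KLVA branch
$g_K\,[d_\infty + (V - E_K)\, d_\infty'(V) / (1 + i\omega\tau_d)]$, whose
phase lag creates a band of *higher* impedance than the passive membrane at
40–400 Hz near $-60$ mV even though both groups share a ~38 MΩ DC
resistance. The reference account does not state how its impedance spectra
were computed; we define the quantity by quasi-active linearization and
validate it against a small-amplitude sinusoidal-current probe simulation
(agreement within 2% over 10–2000 Hz, in the test suite), the two standard
and mutually checkable definitions.

## Calibration utilities

`grid_search()` scans the free parameters of the exponential variants
($V_T \in [-50, -40]$ mV at 0.5 mV, refinable to 0.1 mV; $K_T \in
[1.2, 4.0]$ mV at 0.2 mV; $V_{th} \in [-30, 0]$ mV at 5 mV; $g_T$ fixed at
26.4 nS) against the binaural criteria, returning *all* passing sets —
several combinations pass, and no ranking among them is implied. The
published range statement for $V_T$ carries "ms" units; we read it as mV (a
units typo — $V_T$ is a potential). `refractory_sweep()` recomputes the
binaural metrics across refractory periods (physiological bracket
1.1–2.8 ms): the ILD peak of the reset models falls roughly linearly with
$T_{ref}$ while the spike-current models barely move, because their
post-spike recovery is governed by the spike current rather than the
detection lockout.

## What the generator does and does not emulate

The synthetic input stage reproduces the *rate* and *phase-locking*
statistics of bushy-cell/MNTB afferents as summarized by the three input
functions, with independent Poisson fibers. It does not model cochlear
filtering, actual sound waveforms, input-fiber refractoriness or adaptation,
synaptic depression/facilitation, or across-fiber correlations. Passing
tests therefore demonstrate fidelity to this input model, not to the
auditory periphery: quantities that depend on higher-order input statistics
(e.g. exact trough rates at high modulation frequencies) are more
implementation-sensitive than the headline peaks.

## Problem sizes used by the shipped checks

The acceptance script and the full-scale test file use the study-scale
conditions: 40 s per stimulus condition at $dt = 2\,\mu s$ over the default
grids (17 phase, 20 ILD, 11 frequency conditions per curve). Unit and
property tests use 1–20 s conditions, which resolve the properties they
assert at their stated tolerances.
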