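---
title: "Modelling thalamocortical integration and layer-4 network function in Fmr1-KO barrel cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling thalamocortical integration and layer-4 network function in Fmr1-KO barrel cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barrelsim)
```

## The scientific problem

At postnatal days 10–11, layer 4 of mouse barrel cortex transforms
thalamocortical (TC) input into the sparse, precisely timed spiking that
instructs the development of layer 2/3. In the *Fmr1* knock-out (KO)
mouse model of Fragile X syndrome, stellate cells (SCs, the excitatory
principal cells) show higher input resistance, feed-forward inhibition
(FFI) from fast-spiking (FS) interneurons arrives later and depresses
faster, and FS↔SC connectivity is reduced. `barrelsim` implements the
computational side of that research programme: a single-cell model of
TC integration under FFI, a recurrent spiking network of one barrel, a
two-factor short-term depression (STP) model with fitting, spike-train
metrics, linear population decoding of "oddball" stimuli, and membrane
impedance analysis.

## The models

### Single cell with feed-forward inhibition

A single-compartment conductance-based leaky integrate-and-fire (LIF)
neuron obeys

$$\tau_m \frac{dv}{dt} = -(v - v_\mathrm{rest}) + R_m I_\mathrm{tot}(t),
\qquad \tau_m = R_\mathrm{in} C_m,$$

with threshold crossing triggering a reset and a 1.5 ms refractory
period. Two somatic synapses drive it: a TC input (reversal 0 mV, peak
conductance 1 nS, giving a ~60 pA peak inward current from the −60 mV
leak reversal used in this model) and an FFI input (reversal −71 mV)
whose peak conductance is `ga_ratio` (G/A) times the TC conductance and
which follows each stimulus by the E–I lag. Conductance waveforms are
delayed differences of exponentials normalised to unit peak; each input
depresses independently.

Because both synapses are somatic, a separate dendritic compartment
would be an unobservable degree of freedom; input resistance and
capacitance are therefore set directly to the measured values
(WT: 412 MΩ, 94 pF; KO: 609 MΩ, 89 pF — time constants 38.7 and
54.2 ms, matching the printed 39 and 55 ms).

### Short-term depression

Response amplitude is $A = A_0 D_1 D_2$. Each presynaptic spike
multiplies $D_i$ by $d_i \in (0,1]$; between spikes each factor
recovers as $\tau_{Di}\,\dot D_i = 1 - D_i$, integrated with the exact
exponential solution (the equation is linear, so Euler stepping would
only add error). Fitting uses Levenberg–Marquardt least squares across
5, 10, 20 and 50 Hz trains, equally weighted, with the $d_i$ bounded by
a logistic reparameterisation, three start points, and output
canonicalised to $\tau_{D1} \le \tau_{D2}$ (the factors are
exchangeable). With 5% additive noise on 4 × 5 points the depression
factors are recoverable to roughly 10% (median), but the split of
recovery between the two time constants is close to unidentifiable —
truth-initialised fits show ~30–70% median error on the $\tau$s — so
fit-quality claims should be made on the $d_i$ or on predicted curves.

### The layer-4 network

800 excitatory and 150 inhibitory LIF neurons are randomly connected
(no autapses) with class-specific probabilities; Ex→Ex weights are
log-normal (capped at the class maximum), other classes uniform on
(0, 1] of their maximum. Ex synapses carry AMPA plus NMDA with the
standard sigmoidal magnesium block
$G(v) = 1/(1 + e^{-av}[\mathrm{Mg}^{2+}]_o/b)$
($a = 0.062\,\mathrm{mV^{-1}}$, $b = 3.57$ mM, 1.3 mM Mg²⁺); In
synapses are GABA-A. External TC drive reaches 80% of each population;
its AMPA and NMDA peak conductances are jittered per neuron and per
trial (CV 0.2) and the thalamorecipient subsets reshuffled per trial.
Integration is forward Euler at 0.5 ms over 1000 ms, spike times
discretised to 1 ms. Halving the step changes sweep spike counts in
fewer than 1% of conditions.

## Parameters: measured versus placeholder

Main-text values used directly: the four passive parameters above,
resting potential −64 mV, FFI reversal −71 mV, glutamatergic reversal
0 mV, refractory period 1.5 ms, Mg²⁺ block constants, network sizes and
integration settings, the G/A grid (0–10 in 0.5 steps) and the 5–50 Hz
stimulus protocol (five stimuli).

All remaining parameters are not printed numerically and are package
placeholders, chosen once from the qualitative genotype contrasts and
then frozen:

* **Spike threshold and reset** (−55.8 / −57.5 mV). The threshold is
  set just below the WT first-EPSP peak so that with FFI silenced
  (G/A = 0) both genotype models fire at every tested frequency — the
  reported behaviour of both models with inhibition silenced. This
  places the model
  in the near-threshold regime where the E–I integration window is
  decisive.
* **TC EPSC kinetics** (rise 1 ms, decay 8 ms, both genotypes —
  genotype differences in EPSC kinetics were not observed). Immature
  TC EPSCs are slow; a slow decay also makes the EPSP integrate over
  the membrane time constant, which is where the genotypes differ most.
* **FFI kinetics** (WT 0.8/5 ms; KO 1.2/7 ms — slower in KO) and
  **E–I lag** (WT 2.2 ms; KO 3.5 ms — longer in KO).
* **STP coefficients.** Both genotypes depress; KO depresses more, and
  disproportionately so for the FF-IPSC (WT TC $d_1$ 0.85 vs KO 0.81;
  WT FFI $d_1$ 0.85 vs KO 0.48). Steady-state amplitudes at 50 Hz are
  then ~0.5 (WT EPSC), ~0.4 (KO EPSC), ~0.5 (WT IPSC), ~0.05 (KO
  IPSC), reproducing the reported collapse of the G/A ratio during KO
  trains.
* **Connection probabilities** (WT: Ex→Ex 0.28, Ex→In 0.50, In→Ex
  0.55; KO: 0.28/0.30/0.35 — FS↔SC reduced, SC–SC unchanged; In→In
  defaults to 0 with a config hook).
* **Network conductance scales.** The single-cell sweep pins its own
  conductances (TC 1 nS, FFI = G/A × 1 nS), so network-level `g_max`
  values are independent placeholders calibrated for stable, sparse,
  genotype-contrasted activity: TC→Ex 2.2 nS, Ex→Ex 0.15 nS, In→Ex
  3 nS, recurrent NMDA/AMPA ratio 0.25 (0.5 externally).
* **Dispersions**: 15% CV on jittered scalars; R\_in and C\_m are
  sampled jointly with correlation `rho_RC = 0.5` ("private and shared
  variance"; the correlation itself is unstated and is an explicit
  argument).

## What the model reproduces, and what it does not

On the frozen defaults the deterministic single-cell sweep yields:

* with FFI silenced, both genotypes fire at all frequencies;
* the KO model fires in ~61% more (G/A, frequency) conditions than WT
  (reported: 45%);
* rescuing the E–I delay alone on the KO background leaves spike output
  ~66% above the WT total (reported: +86%);
* rescuing intrinsic excitability alone gives −5.8% versus WT
  (reported: −26%). The sign is right but the magnitude is shallow: in
  a single-compartment conductance-based LIF, input resistance has
  bounded leverage on spike output under transient synaptic drive
  (the depolarisation plateau depends mainly on the synaptic-to-leak
  conductance ratio), so the intrinsic-excitability rescue cannot be
  made much deeper without breaking the G/A = 0 boundary condition or
  the other contrasts.

The network reproduces: greater KO excitatory spiking at low stimulus
frequencies, delayed and more variable KO first spikes, and transient
stimulus-locked population synchrony. It does **not** reproduce the
reported KO ensemble-decoding deficit: here the KO network fires more
throughout and therefore represents the inserted oddball stimulus at
least as decodably as WT. Calibrations that strengthen the WT signal
enough to flip the direction push the KO network (whose FFI depresses
to ~5% by mid-train) into runaway firing first. Reproducing that
deficit evidently requires unpublished parameter relations that keep
KO rates near WT while disorganising their timing;
the corresponding directional test is left failing rather than
weakened.

## Spike-train metrics and decoding conventions

* **Spike density functions**: 1 ms bins, Gaussian kernel of SD 5 ms
  truncated at ±3 SD, each spike's in-window mass renormalised to
  exactly 1 (edge-clipped kernels keep unit mass).
* **van Rossum distance**: causal exponential filter, τ = 50 ms,
  normalisation $D^2 = (1/\tau)\int (f_A - f_B)^2\,dt$, computed with
  the closed-form pairwise-exponential sum; under this convention a
  lone spike against an empty train has distance $\sqrt{1/2}$.
* **Decoder**: per-neuron 10 ms binned counts over the trial as
  covariates; Fisher discriminant with scale-preserving shrinkage
  $\Sigma_\lambda = (1-\lambda)S + \lambda \bar c I$, $\lambda = 0.05$
  ($\bar c$ = mean diagonal of the pooled covariance; an additive
  $S + \lambda I$ variant is exposed). High-dimensional solves use the
  Woodbury identity on the low-rank pooled scatter, so ensembles of
  hundreds of neurons decode exactly without forming the full
  covariance. Accuracy is leave-one-out cross-validated with a
  label-permutation null.
* **Oddball**: inserted at the midpoint of a chosen inter-stimulus
  interval (position configurable), preserving all regular stimulus
  times.

## Impedance analysis

The ZAP current is a linear chirp (±40 pA, 0.5–50 Hz over 25 s) with
phase $2\pi\int f\,dt$ — evaluating $\sin(2\pi f(t)\,t)$ directly would
sweep at twice the intended rate, and `zap_naive()` is included to make
the comparison explicit. Impedance is the ratio of Fourier transforms
on the swept band (mV/pA → MΩ), phase by the four-quadrant arctangent,
Bode gain as $20\log_{10}$ relative to 0.5 Hz (the power convention
gives identical numbers). A simulated RC cell matches
$|Z| = R/\sqrt{1 + (2\pi f RC)^2}$ within 2% and its −3 dB point
matches $1/(2\pi RC)$ within 5%. Spike phase-locking registers spikes
to the analytic (Hilbert) phase of the injected waveform, reported in
the sine convention (a spike at a current peak has phase π/2).

## Problem sizes used in the shipped checks

The test-suite and acceptance runs use the full 21 × 10 single-cell
sweep grid (deterministic), networks at the full 800 + 150 size for the
directional contrasts (one network seed, 3–10 trials per condition),
decoding at ensemble sizes 10–20 with 5 random draws, and 100-seed
Monte-Carlo recovery for the STP fit. These sizes make every headline
quantity reproducible in minutes on one CPU; the experiment layer
(`run_experiment()`) scales to the five-seed, ten-trial,
four-oddball-position design by changing its arguments.

## Known limitations

* No facilitation, receptor desensitisation, dendritic cables, active
  conductances, spontaneous background activity, or thalamic spike-time
  jitter — matching the scope of the modelled study.
* The single-cell rescue analysis is deterministic; inter-trial jitter
  of conductances is a network-layer feature.
* Several parameters are placeholders (listed above); quantities that
  depend on them (notably the rescue-scenario magnitudes) carry that
  uncertainty, which is why the shipped checks use wide bands around
  the reported percentages.
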