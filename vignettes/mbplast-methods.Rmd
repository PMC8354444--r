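---
title: "Modeling heterogeneous dopamine signaling in the mushroom body"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling heterogeneous dopamine signaling in the mushroom body}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbplast)
```

## The model

The *Drosophila* mushroom body learns stimulus-reinforcement associations
through dopamine-gated plasticity of Kenyon-cell (KC) to output-neuron
(MBON) synapses. Recorded dopamine neurons (DANs), however, are tuned to
much more than reward: novelty, internal state, and movement all modulate
them. `mbplast` implements a modeling strategy that *infers* DAN activity
patterns sufficient for behavior instead of assuming them: the output
circuitry (MBONs, DANs and feedback neurons, FBNs) is a recurrent
rate network whose connections are meta-learned by gradient descent through
the plastic dynamics, while within-trial learning happens only through an
experimentally constrained plasticity rule.

Rates follow rectified-linear leaky dynamics,

$$\tau \dot r_i = -r_i + \left[\textstyle\sum_j W^{recur}_{ij} r_j + b_i +
I_i(t)\right]_+,$$

integrated by forward Euler with $\tau = 1$ s and $\Delta t = 0.5$ s. MBONs
receive KC input through the effective weights $W^{KC\to MBON}$, FBNs
receive external input (reinforcement, state pulses, wind) through
$W^{ext}$, and DANs receive no direct input — everything reaching them is
relayed by the recurrent circuit. The DAN$\to$MBON block of $W^{recur}$ is
structurally zero: dopamine acts on plasticity, not on MBON firing. A linear
readout $v(t) = W^{readout} r^{MBON}(t)$ reports valence (optionally a
second row reports stimulus novelty), and for the internal-state task a
softmax readout of DAN rates decodes the current state.

Each KC$\to$MBON synapse carries a latent plastic variable $w_{ij}$ obeying

$$\dot w_{ij} = \bar r^{DAN}_i r^{KC}_j - \bar r^{KC}_j r^{DAN}_i
\; (+\, \beta_i \bar r^{DAN}_i),$$

where bars denote eligibility traces (first-order low-pass filters) and the
DAN index is routed through the compartment map. KC-before-DAN pairings
depress, DAN-before-KC pairings potentiate, and the optional $\beta$ term is
a non-specific potentiation used in continual learning. $w$ is clipped to
$[0, 0.05]$ and the effective weight relaxes toward it with
$\tau_W = 5$ s, capturing the induction timescale of LTD/LTP. All weights
start at the maximum, so first-order conditioning proceeds by depression.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `tau`, `dt` | 1 s, 0.5 s | membrane constant, Euler step (`dt <= tau`) |
| `n_mbon/n_dan/n_fbn/n_kc` | 20/20/60/200 | population sizes |
| `w_max` | 0.05 | weight bound (weights start here) |
| `tau_w` | 5 s | effective-weight relaxation |
| `tau_elig_kc`, `tau_elig_dan` | 1 s | eligibility-trace filters |
| `lambda`, `dan_baseline` | 0.1, 0.1 | DAN activity penalty |
| `learning_rate`, `batch_size` | 0.001, 30 | RMSprop step and batch |
| `omission_prob` | 0.5 | stimulus-omission rate in training trials |
| `beta` init | 0.01 | non-specific potentiation (continual only) |

The eligibility-trace constants are not experimentally pinned down; 1 s for
both filters puts the biphasic pairing window on the seconds-long timescale
reported for this synapse, and both are exposed in `plasticity_config()`.
RMSprop uses the canonical smoothing constant 0.99 and epsilon 1e-8 (also
recorded in every fitted model's `config`).

## Meta-learning

`mb_fit()` draws a batch of 30 fresh random trials per epoch, averages the
trial losses, and takes one RMSprop step (learning rate 0.001) on the
circuit parameters; the gradient is computed by an exact hand-derived
backward pass through the unrolled dynamics — including the plasticity rule,
the weight clipping (subgradient zero on the clamped side), the interval
rate-resets, and, for navigation, the agent kinematics and the smooth part
of the sensory feedback. After fitting, parameters are frozen; evaluation
trials exercise only the dopamine-gated plasticity.

The conditioning loss is the mean squared valence error over all timesteps
plus $\lambda/T \sum_t \sum_i [r^{DAN}_i - 0.1]_+^2$, which discourages
gratuitous dopamine activity. The state task adds the mean squared error of
the decoded state probabilities and drops the DAN penalty (state-tracking
*requires* tonic DAN fluctuations). The navigation loss is the squared final
distance to the rewarded source.

Target conventions for conditioning trials: the target valence equals the
current learned association (scale 1) during every post-pairing CS
presentation and is zero elsewhere. Targets respect the one-step
integration lag of the discretized dynamics: they apply from one timestep
after stimulus onset through stimulus offset, and the onset step is
excluded from the readout loss and from error scoring — a rate network
cannot respond within the step a stimulus arrives, and penalizing that
step would train the readout to hedge against its own rise. An early version that placed targets
only at the final test presentation trained networks to stay silent at
second-interval presentations and consequently fail first-order tests —
the target must be present wherever the association should be expressed.
One unreinforced exposure reduces the extinction test target to 0.5 (the
residual is configurable; the experimental papers only call the
extinction "partial"). With probability 1/2 a stimulus is omitted and the
downstream targets are zeroed, except that omitting the extinction exposure
leaves an intact full-magnitude association; these omission cases are what
prevent overgeneralization and cover first-order behavior inside the
extinction/second-order training mixture.

Continual learning chains trials: the weights starting trial $l$ are
$(1-\chi) w_0 + \chi\, w_{l-1}(T)$ with $\chi$ annealed linearly from 0 to 1
(full carryover) over the first half of optimization, which keeps weights
from saturating early. Gradients are truncated at trial boundaries (the
carried weights enter as constants); within a trial the chain is exact.
The DAN penalty is kept for this task.

Navigation: a 20-s conditioning interval pairs the rewarded odor with a
weak US (amplitude 0.1) at $t = 2$ s, followed by 200 s of navigation in a
two-source plume world (sources at $x_1 = \pm 1$ m, $x_2 \sim U(0,2)$ m with
0.5-m spacing; concentration
$c = \exp(-\Delta x_2^2/(0.1\,\Delta x_1))/(1 + 0.5\,\Delta x_1)$ inside a
0.5-m band downwind). KC drive is the odor pattern scaled by local
concentration; four rectified egocentric projections of the wind vector
(anterior/posterior/left/right, using the wind of the higher-concentration
plume) enter through `W_ext`; forward velocity is a Softplus readout and
angular velocity a linear readout of FBN rates (the movement pathway is
taken from the feedback population, not from MBONs). The initial-heading
jitter $\gamma$ anneals 0 to 0.5. The plume-band edges and the active-plume
switch are non-differentiable and treated as constants in the backward
pass; the in-band concentration and the heading dependence of the wind
input are differentiated exactly.

Closed-loop unrolls of 400 steps through steep near-source concentration
gradients occasionally diverge during optimization, and the resulting loss
spikes (hundreds of m$^2$ against a converged batch loss of ~0.02) wreck an
otherwise good solution; navigation training therefore clips each trial's
gradient and the batch gradient to unit norm before the RMSprop step
(`clip_grad_norm`, recorded in the fitted model's `config`; off for every
other task). Realizations whose mean final position error exceeds 0.4 m
are flagged as non-converged, mirroring the study's discard criterion.

## What the generators emulate — and what they do not

Trial generators are first-class, tested code: sparse 10%-active KC codes,
30-s conditioning intervals with 2-s stimuli at onsets uniform in [5, 15] s
and rate resets at interval starts, 200-s continual sequences (two CS+, two
CS$-$, Poisson mean 2 presentations each, onsets uniform conditioned on
non-overlap), 300-s state trials (three states, 2-s transition pulses, gaps
$10\,(1+\mathrm{Exp}(1))$ s), and fixed-bank probe trials for the
non-plastic comparison (CS+ at 5 s, probe at 15 s, same/different with
probability 1/2). They do not emulate naturalistic odor statistics,
projection-neuron encoding, turbulent plumes, or arena boundaries — so
passing tests show that the *circuit-level* learning mechanisms work under
the idealized protocol, not that they survive realistic sensory noise.

## Numerical choices and degenerate inputs

Forward Euler at `dt = 0.5` is stable for these rectified dynamics whenever
`dt <= tau` (enforced at construction); the test suite checks the coarse
trajectory against a `dt = 0.005` reference integrator. Clipping uses the
closed interval and reports a zero subgradient on the clamped side; exact
ties ($u = 0$ or $u = w_{max}$) take the clamped branch. The plume
concentration at $\Delta x_1 = 0$ is defined as its limit (1 on-axis, 0
off-axis). Softmax readouts subtract the maximum logit. Divergent training
(non-finite loss or gradient) stops the run and flags the record rather
than continuing. Zero-variance response vectors yield flagged `NA`
correlations. Heading angles are wrapped only at the reporting boundary,
never inside the differentiable loop.

## Scale of the shipped experiments

The package's own experiments (tests and the acceptance script) run on one
CPU, so they use the full 20/20/60-neuron, 200-KC circuit with reduced
epoch counts for the headline conditioning comparison (1500–2000 epochs
instead of 5000; at this batch size the loss has reached its plateau by
then, though individual realizations differ in when they escape an
intermediate compromise solution), a 6/6/18-neuron, 60-KC circuit for the
secondary qualitative analyses (novelty, continual, state, non-plastic
comparisons), and, for the in-suite navigation check, the same desk-scale
circuit with up to two 1200-epoch realizations under the discard
protocol — a scale at which agents reliably beat the
plasticity-ablated baseline but plateau short of the 0.4-m convergence
bound that full-size 500-epoch realizations can reach. These sizes are
stated in the helper functions and are deliberate desk-scale choices;
full-scale protocols are a matter of raising `n_epochs` and the
architecture back to the defaults.

## Known limitations

- No direct KC$\to$DAN connections, spiking dynamics, conductance models,
  or direct depolarizing DAN$\to$MBON effects.
- The plasticity rule is shared across compartments except for $\beta$;
  compartment-specific rule shapes are not modeled.
- Continual-learning gradients do not flow across trial boundaries.
- The reversal paradigm is evaluation-only, as in the study design.
- Hierarchical clustering defaults to average linkage (the linkage is not
  specified in the source experiments) and is configurable.
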