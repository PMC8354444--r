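# mbplast

Meta-learned models of dopamine-gated synaptic plasticity in the
*Drosophila* mushroom body.

Dopamine neurons (DANs) in the mushroom body gate plasticity of Kenyon-cell
(KC) to output-neuron (MBON) synapses, but their recorded activity mixes
reward, novelty, internal state and movement — hard to square with models
that assume a single global reward-prediction-error signal. `mbplast`
implements the complementary approach: treat the mushroom-body output
circuitry (20 MBONs, 20 DANs, 60 feedback neurons) as a recurrent
rate network, give the 200 KC→MBON synapses an experimentally constrained
timing-dependent plasticity rule, and *meta-learn* the circuit connections
by backpropagation through the unrolled plastic dynamics so that the
network's own dopamine signals drive successful learning. After this
optimization phase the connections are frozen and all within-trial learning
happens through the biological rule alone.

The package is aimed at computational-neuroscience users who want to
reproduce, probe or extend this class of models from R.

## The model in brief

Rates: rectified-linear leaky dynamics, forward Euler (τ = 1 s,
Δt = 0.5 s),

    τ dr_i/dt = −r_i + [Σ_j W_recur[i,j] r_j + b_i + I_i(t)]_+

with KC input to MBONs, external input (US, state pulses, wind) to feedback
neurons only, no direct input to DANs, and the DAN→MBON block of `W_recur`
structurally zero. Valence is a linear MBON readout. Plasticity of each
KC→MBON synapse:

    dw_ij/dt = r̄_DAN_i r_KC_j − r̄_KC_j r_DAN_i (+ β_i r̄_DAN_i)

(bars = eligibility traces; biphasic timing dependence, depression for
forward pairing), with w clipped to [0, 0.05] and the effective weight
tracking w with τ_W = 5 s. Losses: mean squared readout error plus a
penalty on DAN rates above 0.1 (λ = 0.1); squared final distance to the
rewarded odor source for navigation. Optimizer: RMSprop, learning rate
0.001, batches of 30 random trials.

Task families (`mb_fit(task = ...)`): `"mixture"` (extinction +
second-order conditioning with random stimulus omissions),
`"first_order"`, `"novelty"`, `"continual"` (long association sequences
with meta-learned non-specific potentiation β), `"state"` (three internal
states decoded from DANs), `"navigation"` (2-D odor-plume seeking) and
`"nonplastic"` (ablation with directly optimized, fixed KC→MBON weights).

## Worked example

Train a conditioning network at the study's circuit size (reduced epoch
count; about eight minutes on one CPU) and test it on fresh first-order
trials:

```r
library(mbplast)
model <- mb_fit("mixture", n_epochs = 2000, seed = 301)
print(model)
#> meta-learned mushroom-body model (task: mixture)
#>   circuit: 20 MBON / 20 DAN / 60 FBN, 200 KC, 20 compartments
#>   optimized 2000 epochs (batch 30, RMSprop lr 0.001)
#>   final loss 0.0005 (first epoch 2.2121)

evaluate_error_rate(model, "first_order", n_trials = 50,
                    threshold = 0.2, seed = 42)$error_rate
#> [1] 0
```

The error rate is the fraction of test trials on which the reported valence
deviates from the target by more than 0.2 during the test CS presentation —
0 means the frozen network formed and reported every new association using
only its dopamine-gated plasticity. The timing-dependence of the rule
itself:

```r
pc <- pairing_curve(plasticity_config())
range(pc$delta_w[pc$delta_t_s > 0])   # KC before DAN: depression (< 0)
range(pc$delta_w[pc$delta_t_s < 0])   # DAN before KC: potentiation (> 0)
```

A command-line front end for the same operations (train / evaluate /
simulate-nav / pairing-curve / analyze) ships in `inst/cli/mbtool.R`.

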