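# tiersim

Simulations of the thermodynamic cost of neural information processing, and
of the selective vulnerability it predicts.

The premise: synaptic modification is mechanical work; by the second law,
sustained work generates irreversible entropy in proportion to the work
performed (Δs ∝ W); entropy accumulates locally and a unit fails when its
accumulated entropy reaches its intrinsic fracture fatigue entropy (FFE)
threshold — the same damage law used in engineering fatigue analysis, where
the Thermodynamic State Index TSI = s/FFE tracks degradation from 0
(pristine) toward, but never reaching, 1 (failure). Applied to the brain,
the units that do the most information-processing work per synapse age
fastest. `tiersim` implements the two models that develop this idea:

* **Hierarchical network model.** A 4–4–4 convergent column (primary →
  unimodal → heteromodal; fan-in 4 at the top) learning with the
  exponential-tracking Hebbian rule Δwᵢ = η (xᵢ − wᵢ), η = 0.1, under tanh
  activation. Per representative node, the model tracks per-synapse work
  intensity (the entropy-generation proxy: mean |Δwᵢ|, plus squared / max /
  rate variants), cumulative work W(t), the normalized Shannon entropy of
  activation patterns H = −Σ pᵢ log₂ pᵢ / log₂ n, and a twin-trajectory
  Lyapunov stability series under an ε = 0.001 sustained input
  perturbation — across seeded Monte-Carlo ensembles (2000 trials × 20
  iterations at full scale).
* **Siphon model.** A deterministic coupled pair of populations — 1000
  cortical cells carrying constant cognitive demand W = 3000, and 300
  support cells providing baseline work 500 plus compensation
  2.0 × (fraction lost) × (cortex remaining) — in which per-cell intensity
  (capped at 5.0) accumulates into an entropy index s driving failure rate
  A·exp(s/FFE), with FFE 6.0 (cortex) vs 2.0 (support). The support
  population, shouldering siphoned workload with a lower threshold, reaches
  50% loss first.

A six-part sensitivity suite (work metrics, input regimes, 6×5 FFE grid,
compensation factors, activation functions, 3×3×3 factorial) probes every
headline result. See `vignettes/tier-methods.Rmd` for the full model
account and design rationale.

## Worked example

```r
library(tiersim)

## siphon reference run (deterministic; A calibrated once so support t50 = 5.5)
traj <- run_siphon(reference_siphon_config())
traj
#> <siphon_trajectory> horizon 20 time units
#>   support t50 = 5.499995, cortical t50 = 11.89358, lead = 6.393583
traj$milestones[c("t90_support", "cap_time_support", "cap_time_cortex")]
#> $t90_support   5.9085   $cap_time_support 5.8   $cap_time_cortex 11.7
```

The support population (300 cells) crosses 50% loss at t ≈ 5.5, six time
units before the 1000-cell cortical population it serves, approaches
depletion (90% loss) by t ≈ 5.9, and saturates at the per-cell intensity
cap at t = 5.8 versus t = 11.7 for cortex — accelerated compensatory
failure despite lower absolute workload.

```r
## network ensemble (200-trial smoke run; 2000 for full scale)
es <- run_ensemble(network_config(), stimulus_config("random"),
                   n_trials = 200, base_seed = 42)
es
#> <tier_ensemble> 200 trials, random stimuli (base seed 42)
#>   cumulative-work AUC: L1 2.620, L2 3.320, L3 4.775
#>   Level-3 over Level-1 elevation: 82.3% (paired t = 15.9, p = 2.14e-37)
```

The heteromodal level's cumulative per-synapse work runs ~80–90% above the
primary level under patternless input — workload concentration produced by
the convergent architecture alone. Under fully predictable sinusoidal
input the gradient inverts:

```r
input_regime_sweep(network_config(), n_trials = 200, base_seed = 42)$results
#>                regime   auc_l1   auc_l3 elevation_pct      p_value
#> 1              random 2.619517 4.775408      82.30110 2.136099e-37
#> 2 correlated_gaussian 2.525456 4.775605      89.09873 3.172092e-38
#> 3          sinusoidal 5.116547 4.654432      -9.03178 4.692413e-04
```

Command-line equivalents live in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "tier", package = "tiersim"))')" \
  run-siphon --out siphon-out
```

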