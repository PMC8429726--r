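# chemosched

Deriving and stress-testing daily chemotherapy dosing schedules on a
two-compartment cell-population model — for computational oncology and
mathematical-biology researchers who want to compare *open-loop optimal
control* against *feedback controllers* (a reinforcement-learning agent,
a nearest-neighbour schedule library) when the patient's kinetic
parameters are uncertain.

## The problem

Cycling (proliferative, *P*) and resting (quiescent, *Q*) cells evolve as

    P' = (γ − δ − α − s·f(t))·P + β·Q
    Q' = α·P − (β + λ)·Q ,

with dose fraction f(t) ∈ [0, 1] killing only cycling cells at relative
strength *s*. Nominal rate constants for bone marrow, breast and ovarian
cells ship with the package; simulations start from the untreated
steady-state composition (the proliferative fraction ρ\*, root of a
quadratic in the rates) with total mass normalised to 1.

A schedule delivers one dose per day from {0, 0.1, …, 1} over T = 21
days, maximising

    J_b(f) = ∫₀ᵀ [ P_bm + Q_bm − (b/2)(1 − f)² ] dt ,

i.e. preserve bone marrow while delivering dose, with trade-off weight
*b*. The package provides:

- **exact simulation** (matrix-exponential propagators, the running
  integral carried exactly) and local sensitivity analysis;
- **exact discrete optimal control** per patient via backward dynamic
  programming over affine value pieces with geometric pruning
  (`oc_solve()`, validated against exhaustive enumeration);
- **virtual-patient cohorts** by Latin hypercube perturbation of the
  bone-marrow rates within ±k (`sample_cohort()`);
- a **deep double Q-learning agent** trained only on the nominal patient,
  observing the day index and a 10-day window of relative bone-marrow
  density (`ddqn_train()`, `best_of_runs()`);
- a **nearest-training-neighbour optimal controller** that replays logged
  optimal doses of the closest known-parameter training patient
  (`ntnoc_library()`, `run_ntnoc()`);
- **evaluation statistics**: per-patient scaled scores σ̂ = σ/σ(θ) ≤ 1,
  signed-rank and Kolmogorov–Smirnov comparisons, a random-dosing
  baseline (`evaluate_controller()`, `wilcoxon_one_sided()`, ...).

The drug strength *s* and penalty weight *b* are calibration constants
(defaults 1.0); quantities that depend on them are calibration-dependent
and labelled as such in the documentation.

## Worked example

Train a best-of-5 agent on the nominal patient, then compare it with the
nominal optimal schedule on 50 patients perturbed by up to ±25%:

```r
library(chemosched)
cfg <- objective_config()         # b = 1, T = 21 days, 11 dose levels
bm  <- cell_params("bone_marrow")

steady_state_fraction(bm)
#> [1] 0.1030617

sol <- oc_solve(bm, cfg)
sol
#> Discrete optimal control (affine-piece dynamic programming)
#>   value = 12.994371 (gap 0)
#>   schedule: 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.2 0.4 0.5 0.6 0.7 0.8 0.9 1.0

tc  <- training_config(max_resets = 3000, patience = 400,
                       buffer_capacity = 1e5)
pol <- best_of_runs(bm, cfg, tc, seed = 1)   # ~1 min
ro  <- rollout_policy(pol, bm, cfg)
round(ro$value / sol$value, 3)
#> [1] 0.966

coh <- sample_cohort(50, k = 0.25, seed = 125)
mx  <- oc_max_scores(coh, cfg)               # exact per-patient maxima
rl  <- evaluate_controller(pol, coh, cfg, mx)
oc  <- evaluate_controller(sol$schedule, coh, cfg, mx, tag = "OC-nominal")
summarize_scores(rbind(rl, oc))$by_controller
#>   controller  n    median      mean         sd
#> 1         RL 50 0.9615458 0.9560566 0.03307904
#> 2 OC-nominal 50 0.9470338 0.8897340 0.13437896

wilcoxon_one_sided(rl$sigma_hat, oc$sigma_hat)
#> $statistic
#> [1] 972
#> $p.value
#> [1] 0.0006316366
#> $n
#> [1] 50
```

Reading the output: the exact nominal optimum under the default
calibration is a delayed-ramp schedule worth 12.99; the trained agent's
deterministic rollout recovers 96.6% of it. On the perturbed cohort the
feedback agent keeps a median scaled score of 0.962 with small spread,
while the same-for-everyone nominal schedule degrades (mean 0.890, sd
0.134); the one-sided signed-rank test rejects equality of medians at
p ≈ 6×10⁻⁴. A command-line wrapper over the same functions is installed
at `inst/cli/chemosched.R` (subcommands: `simulate`, `sensitivity`,
`patients`, `oc`, `oc-max`, `train`, `ntnoc-build`, `ntnoc-run`,
`evaluate`).

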