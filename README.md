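# forminproc

Kinetic modelling and survival analysis of **formin processivity** at actin
filament barbed ends.

Formins are homodimeric actin polymerases that track the fast-growing
(barbed) end of an actin filament while it elongates. How long they stay —
their processivity — is quantified by the dissociation rate k_off of the
formin from the barbed end, measured by watching populations of single
filaments lose their formin over time. `forminproc` is for biophysicists
who run or analyse such single-filament experiments (microfluidics,
TIRF-style movies) and want to model, simulate and validate the inference
chain end to end.

## The model

The FH2 dimer at the barbed end flickers between an elongation-competent
*open* state and a *closed* state; pulling force f tilts the equilibrium
open over one monomer size (δ_step = 2.7 nm):

    p_open(f) = 1 / (1 + K_co · exp(−f·δ_step/kBT))

Elongation (subunits/s) is
`v = p_open · k_on · [actin] · (1 + boost(profilin)) · (1 − π_sol)`,
where FH1 domains boost delivery of profilin–actin and solution profilin
on the barbed end (occupancy π_sol) pauses addition. Dissociation is the
sum of two routes with independent Bell (slip-bond) force laws
k(f) = k₀·exp(f·δ/kBT):

* **open route** — `p_open(f) · k_offO(f)`: unbinding from the open state;
* **transition route** — `v · p_T(f) · (1 − π_fh1)`: each subunit addition
  passes through a short-lived dissociation-prone state (per-addition
  probability p_T = k_offT/(k_offT + k_decay)), protected by FH1-held
  profilin (the "ring complex", occupancy π_fh1).

The transition route rides on the elongation rate (hence on actin
concentration); the relative working distances δ_O, δ_T decide whether
k_off(f) curves for different actin concentrations converge under force or
stay separated. The mean filament length grown before dissociation is
`L̄ = (v / k_off) · 2.7 nm`, which collapses roughly ten-fold per 3 pN.

On top of the closed-form model the package provides an exact event-driven
(Gillespie) single-filament simulator (C++ core; zero, constant, or
length-proportional force `f = κ·L`), generators of experiment-shaped
synthetic datasets (frame quantization, censoring, striped alternation
schedules, spurious detachments bounded by a functional fraction), and the
estimation machinery: Kaplan–Meier survival fractions, mono-exponential
fits with Monte-Carlo-calibrated `k₀/√N` confidence intervals, local
hazard estimation under force ramps with force binning and the
`0.74·k_obs < k_off < k_obs` detachment correction, and exact
striped-filament deconvolution.

## Worked example

Predict rates for an mDia1-like construct at 1 µM actin + 5 µM profilin,
then simulate a 40-filament movie and re-estimate k_off from its survival
fraction:

```r
library(forminproc)

params <- formin_params()                      # mDia1-like defaults
cn <- conditions(actin = 1, profilin = 5)
dissociation_rate(cn, f = c(0, 2, 4), params)
#>   f v_elong    k_off k_off_open_route k_off_transition_route p_open pi_solution pi_fh1
#> 1 0      78 0.000123         0.000100               2.32e-05  0.500       0.143   0.99
#> 2 2     123 0.000640         0.000586               5.39e-05  0.788       0.143   0.99
#> 3 4     145 0.002676         0.002582               9.41e-05  0.933       0.143   0.99

des <- experiment_design("seed_anchored", frame_interval = 10,
                         movie_duration = 12000, n_filaments = 40,
                         conds = cn)
tab <- generate_experiment(des, params, seed = 42)
fit_exponential(survival_from_events(tab))
#> <rate_estimate> k = 0.0001442 /s  (65% CI 0.0001214 - 0.000167, N = 40, lsq_survival)
```

Reading the output: at zero force this construct dissociates at
~1.2×10⁻⁴ /s (mean residence ~2.3 h) with the open route dominant because
profilin protects the transition route (π_fh1 ≈ 0.99); 4 pN of tension
accelerates dissociation ~20-fold while elongation barely doubles. The
simulated 40-filament experiment recovers the model rate within its 65%
confidence interval `k·(1 ± 1/√N)`.

Study pipelines: `run_recovery()` (force-ramp parameter recovery through
the full hazard pipeline), `run_regimes()` (converging vs separated
k_off(f) families), `run_mean_length()` (length sweeps),
`run_ci_calibration()` (interval calibration). A thin command-line wrapper
is included:

```sh
Rscript inst/cli/forminproc.R calibrate-ci --n 35 --k0 0.01 --m 2000 \
    --seed 7 --out out_dir
```

## Package layout

* `R/formin_model.R` — closed-form model (rates, occupancies, lengths,
  force-curve families)
* `src/simulate.cpp` + `R/filament_simulator.R` — event-driven simulator
* `R/synthetic_data.R` — experiment designs, event tables, CSV I/O
* `R/survival_analysis.R` — survival curves, fits, calibration, hazards,
  binning, striped deconvolution
* `R/pipeline.R` — studies, config I/O, CLI
* `vignettes/formin-processivity-methods.Rmd` — the methods vignette
  (model assumptions, estimator choices, limitations)
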