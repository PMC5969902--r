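---
title: "Modelling and measuring formin processivity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring formin processivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forminproc)
```

## The problem

Formins are homodimeric actin polymerases that remain attached to the
fast-growing (barbed) end of an actin filament while it elongates. The
duration of this attachment — processivity — is quantified by the formin
dissociation rate $k_{\mathrm{off}}$: populations of formin-bound barbed
ends lose their formin stochastically, and the survival fraction $S(t)$ of
still-bound ends decays with hazard $k_{\mathrm{off}}$. `forminproc`
implements a kinetic model of this dissociation, an exact stochastic
simulator of single filaments, generators of experiment-shaped synthetic
datasets, and the estimation machinery used to infer rates from such data,
so the full inference chain can be exercised and validated end to end.

## The two-route dissociation model

The FH2 dimer at the barbed end flickers in a rapid equilibrium between an
elongation-competent *open* state and an elongation-forbidding *closed*
state. Pulling force $f$ tilts this equilibrium towards the open state over
a working distance of one actin monomer size ($\delta_{step} = 2.7$ nm):

$$p_{\mathrm{open}}(f) = \frac{1}{1 + K_{co}\,e^{-f\delta_{step}/k_BT}}.$$

Subunits add from the open state at rate
$v = p_{\mathrm{open}}\,k_{on}\,[\mathrm{actin}]\,(1 +
\mathrm{boost}(P))\,(1-\pi_{sol})$ (subunits/s), where $P$ is the profilin
concentration. Profilin acts twice on elongation: FH1 domains deliver
profilin–actin to the barbed end, multiplying the rate by
$1 + b_{max}P/(P + K_{boost})$, while profilin binding the barbed end
directly from solution (occupancy $\pi_{sol} = P/(P+K_{PB})$) pauses
elongation. The combination makes $v(P)$ biphasic for FH1-bearing
constructs, and purely inhibitory for FH2-only constructs.

Dissociation proceeds by two routes whose force sensitivities are
independent Bell (slip-bond) laws $k(f) = k_0 e^{f\delta/k_BT}$:

* **open route** — the FH2 dimer unbinds from the open state:
  $k^{O}(f) = p_{\mathrm{open}}(f)\, k^{O}_{0}\,e^{f\delta_O/k_BT}$;
* **transition route** — each subunit addition passes through a
  short-lived, dissociation-prone transition state that either decays back
  (rate $k_{decay}$) or dissociates (rate $k^{T}(f) =
  k^{T}_0 e^{f\delta_T/k_BT}$), so each addition carries a dissociation
  probability $p_T(f) = k^T(f)/(k^T(f) + k_{decay})$ and the route
  contributes $v \cdot p_T(f) \cdot (1 - \pi_{fh1})$.

The observable rate is the sum, $k_{\mathrm{off}} = k^{O} + k^{T}_{route}$.
The transition route rides on the elongation rate, which reproduces the
zero-force dependence of $k_{\mathrm{off}}$ on actin concentration; the
relative placement of $\delta_O$ and $\delta_T$ decides whether the
actin-dependent curves converge under force (open route takes over,
$\delta_O > \delta_T$) or stay separated ($\delta_T > \delta_O$).

```{r regimes}
reg <- run_regimes()
c(open_route = reg$family_open_route$regime,
  transition_route = reg$family_transition_route$regime)
```

### Profilin protection and the ring complex

FH1-held profilin can bridge a polyproline track and the barbed end (the
"ring complex"), hindering FH2 dissociation during subunit addition. We
model this as an occupancy $\pi_{fh1} = P/(P + K_{ring})$ gating only the
transition route, and only for FH1-bearing constructs.

Two genuinely open design points were resolved as follows:

* **Does solution-profilin occupancy also gate the open route?** We decided
  no: barbed-end-bound profilin pauses subunit addition but does not shield
  the FH2 dimer. This choice is forced by the FH2-only observation that
  reaching the same elongation rate with or without profilin gives the
  *same* dissociation rate: with the open route gated by $(1-\pi_{sol})$
  that collapse would only ever be approximate, whereas without gating
  $k_{\mathrm{off}}$ at fixed force is exactly a function of $v$ when
  $\pi_{fh1} = 0$, however $v$ was reached.
* **How strong is ring protection?** Within these functional forms,
  $k_{\mathrm{off}}$ decreases monotonically with profilin (while FH1
  simultaneously accelerates elongation) only if protection saturates
  faster than the delivery boost, roughly $K_{ring} \lesssim
  K_{boost}/b_{max}$. The default $K_{ring} = 0.05\ \mu M$ (with $K_{boost}
  = 0.5\ \mu M$, $b_{max} = 8$) encodes this: FH1 tracks hold profilin at
  high local concentration, so barbed-end protection saturates at
  sub-micromolar bulk profilin.

### Parameters

| parameter | units | default | meaning |
|---|---|---|---|
| `k_on` | /µM/s | 22 | open-state subunit association rate |
| `K_co` | – | 1 | closed:open equilibrium constant at $f=0$ |
| `k_offO0` | /s | 2e-4 | open-route dissociation rate at $f=0$ |
| `k_offT0` | /s | 3 | transition-state dissociation rate |
| `k_decay` | /s | 1e5 | transition-state decay back to equilibrium |
| `delta_O`, `delta_T` | nm | 2.7, 0.8 | Bell working distances of the routes |
| `delta_step` | nm | 2.7 | open/closed working distance (one monomer) |
| `K_PB` | µM | 30 | solution profilin–barbed-end affinity |
| `K_ring` | µM | 0.05 | FH1-mediated protection scale |
| `fh1_boost_max`, `K_boost` | –, µM | 8, 0.5 | FH1 delivery enhancement |
| `salt_multiplier`, `label_multiplier` | – | 1 | phenomenological destabilization by ionic strength / fluorescent labeling |

Defaults are *illustrative calibrations* that reproduce the qualitative
behaviour of mDia1-like constructs at zero force
($k_{\mathrm{off}} \sim 4\times10^{-4}$/s at 1 µM actin, transition route
dominant); they are not fitted constants. Salt and labeling enter only as
multipliers on both zero-force dissociation rates — no mechanistic ion
model is attempted. Thermal energy is exposed as `kBT` in `conditions()`
(default 4.11 pN·nm, 25 °C) rather than hard-coded, since experiments run
at room temperature. All length/velocity conversions use 2.7 nm per
subunit (`SUBUNIT_NM`, ≈370 subunits/µm).

## The event-driven simulator

`simulate_filament()` realizes the model exactly: waiting times are drawn
from the instantaneous total event rate (addition + open-route clock), each
addition lengthens the filament by 2.7 nm and triggers a transition-state
Bernoulli trial with probability $p_T(1-\pi_{fh1})$, and in the
length-proportional force protocol ($f = \kappa L$, the microfluidic drag
geometry) every rate is re-evaluated after every event, so the force is
treated as piecewise constant between events — exact for this event-driven
scheme. Numerical guards reject $f\delta/k_BT > 700$ (overflow) rather than
silently saturating.

The transition state is resolved instantaneously by default because its
decay ($k_{decay}$) is fast compared with additions; a `transition_mode =
"explicit"` variant draws the dwell time in the transition state from its
exit rate $k^T + k_{decay}$ for sensitivity checks at finite $k_{decay}$.
The open/closed flicker itself is never simulated — it is a rapid
equilibrium, entering only through $p_{\mathrm{open}}(f)$.

Reproducibility: populations derive per-filament substreams
deterministically from the population seed (`sample.int` under
`set.seed`), so the same seed always regenerates the same traces; a ramp
protocol with $\kappa = 0$ reproduces zero-force statistics exactly.
Initial lengths in ramp mode are log-normal with mean `L0` and coefficient
of variation `L0_cv` (default 0.2 — the experiments report only mean
initial lengths, and a ~20% spread is typical of flow-aligned filament
populations).

## Synthetic experiments

`generate_experiment()` reshapes exact simulations into the three
observation schemes used in microfluidics assays:

* **seed_anchored** — force-free filaments observed at a fixed frame
  interval; dissociation times are rounded *up* to the next frame and
  records surviving past the last frame are censored there.
* **striped** — solution conditions alternate on a fixed cycle (default
  cadence mirroring the 100 s unlabeled / 20 s labeled protocol, imaged
  once per cycle); measured rates are duration-weighted composites that
  `deconvolve_striped()` inverts exactly.
* **formin_anchored** — surface-anchored formins under flow with
  $f = \kappa L$; a `1 - functional_fraction` subset of filaments detaches
  spuriously (non-formin events), drawn uniformly in time because the
  functionality assay bounds only the fraction (~74% functional), not the
  timing, of spurious events.

Hidden ground-truth columns (`true_time`, `true_route`) ride along for
validation and are written to a separate `_truth` CSV so analysis stages
cannot accidentally consume them.

What the generator does *not* emulate: photobleaching, image noise and
kymograph extraction, the brief formin-capture phase (~10 s) before
observation starts, filament exclusions (crossings, surface sticking), and
any length-dependence of the drag profile beyond the linear $\kappa L$
calibration. Passing tests therefore validate the *inference machinery*
against the model's own stochasticity, frame quantization, censoring and
spurious-detachment structure — not against imaging artefacts.

## Estimators and their numerical choices

**Survival fractions** are product-limit (Kaplan–Meier) estimates computed
via the `survival` package: censored filaments stay in the risk set until
their censoring time without counting as events. (The reference analysis
does not state its censoring treatment; the product-limit construction is
the standard choice.)

**Exponential fits** minimize $\sum_i (S(t_i) - e^{-kt_i})^2$ with the
amplitude pinned at 1, evaluating the empirical step function on a uniform
time grid (100 points spanning the observation window). The grid matters:
movies sample $S(t)$ at regular frames, and it is this time-uniform
weighting that makes the $k_0/\sqrt{N}$ rule calibrate to a ~65%
confidence interval; sampling only at event times over-weights the early,
event-dense part of the curve and inflates the estimator spread. A
maximum-likelihood mode (events divided by total observed filament-time)
is provided as a cross-check; the two agree within $2k/\sqrt{N}$ on
exponential data. The 1-D least-squares problem is solved by golden-section
search on $[0, 20\,k_{init}]$ with tolerance $10^{-7}$ of the bracket,
where $k_{init}$ is the log-linear regression slope.

```{r calibration}
ci_calibration(n = 35, k0 = 0.01, m = 2000, seed = 1)
```

**Local hazards** fit $\ln S$ against $t$ over sliding windows of 10
consecutive survival points (the window is exposed; "local" is not further
specified by the reference protocol) and report minus the slope at the
window's mean time. The printed hazard definition $(dS/dt)/S$ omits the
sign; the implementation uses the magnitude $-d\ln S/dt$, since $S$
decreases and hazards are positive. Adjacent windows share events, so
trend tests on the hazard series must thin to non-overlapping windows.

**Force mapping and binning.** Under a ramp the population force at time
$t$ is $\kappa(L_0 + vt)$ with $v$ the measured elongation speed
(populations are started homogeneous in length; a per-filament force mode
via `force_at()` exists when true lengths are available). Hazard points
pooled across flow rates are grouped into 8 equal-count force bins
(quantile edges; exposed), each reporting mean force ± SD and mean rate.
The detachment-rate correction brackets the true rate as
$[0.74\,k_{obs},\,k_{obs}]$, because only ~74% of anchored formins are
confirmed still functional after an experiment.

**Recovery studies** (`run_recovery()`) generate anchored-formin
populations at the three printed flow conditions (κ = 0.051/0.204/0.501
pN/µm, L0 = 4.9/3.2/2.6 µm, N = 46/49/49), pool local-hazard points over
3 replicate experiments per condition — force–rate points in the reference
assay are likewise averages of 2–3 independent experiments — and compare
each bin's error rectangle (force ± SD horizontally, corrected bounds
vertically) against the generating $k_{\mathrm{off}}(f)$ curve; a
log-linear fit of the binned rates recovers the zero-force rate and the
effective working distance. With ~140 filaments per replicate set the
effective working distance is recovered within 25% and most bins' error
rectangles intersect the truth; both quantities remain stochastic at this
sample size.

**Striped deconvolution** inverts the duration-weighted composition
$v = (\Delta t_1 v_1 + \Delta t_2 v_2)/(\Delta t_1 + \Delta t_2)$ (and the
same for $k$) algebraically; the round trip is exact to floating
precision. Noise can drive recovered rates negative; such values are
flagged with a warning, never clipped.

**Tie-breaks.** The force-regime classifier compares the max/min spread of
$k_{\mathrm{off}}$ across actin concentrations at the lowest and highest
forces of the grid; exactly equal spreads (e.g. a one-point grid) classify
as "separated", the conservative choice.

## Mean filament length

The expected length grown before dissociation is
$\bar L = (v/k_{\mathrm{off}}) \times 2.7\ \mathrm{nm}$, so
$\bar L\,k_{\mathrm{off}}/v \equiv 2.7$ nm identically. Because force
accelerates dissociation far faster than elongation, $\bar L(f)$ collapses
steeply; when the dominant route's working distance equals
$\ln(10)\,k_BT/(3\ \mathrm{pN}) \approx 3.16$ nm the closed form gives
exactly a ten-fold reduction per 3 pN:

```{r tenfold}
p10 <- formin_params(K_co = 1e-9, k_offO0 = 0.003,
                     delta_O = log(10) * 4.11 / 3, k_offT0 = 0)
run_mean_length(params = p10, force_grid = c(0, 3, 6))$vs_force
```

A formin that never dissociates (`k_off = 0`) reports `Inf` rather than an
error, marking the infinite-length condition distinctly.

## Problem sizes and runtimes

The shipped studies use the experimental design sizes: 35–50 filaments per
simulated experiment for calibration (with 2,000–10,000 Monte-Carlo
replicates), 1,000 filaments per parameter set for simulator/model
cross-checks, and the printed three-flow-rate design (×3 replicates) for
ramp recovery. The event-driven core is written in C++ (Rcpp), so the full
test suite and all studies complete in well under a minute each on a
single core.

## Known limitations

* Profilin–actin speciation is not modelled; the delivery boost and
  occupancies use total profilin as a proxy (the model is declared
  effective, and defaults were chosen under that reading).
* Mechanistic ion and labeling effects are phenomenological multipliers,
  calibrated per condition.
* FH2 stepping geometry (stair-stepping vs stepping-second) is not
  resolved — dissociation data cannot distinguish the two — and no
  polyproline-track-resolved FH1 kinetics are attempted.
* No filament buckling or fluctuation mechanics, depolymerization
  tracking, or capping-protein competition.
* Only the estimators described above are implemented; no general
  survival regression (e.g. Cox models) is provided.
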