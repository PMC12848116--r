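---
title: "The glassy motor-clutch model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The glassy motor-clutch model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glassyclutch)
```

# The model

`glassyclutch` simulates the migration of a cell whose traction machinery is
described by the motor-clutch framework: myosin motors drive retrograde
actin flow, and stochastic adhesion "clutches" — Hookean springs that bind
and unbind — transmit that flow as force onto a deformable substrate. Each
migration axis couples two opposing cell ends; a cell is two independent
axes (X, Y).

Per end, three elements interact:

* **Clutches.** Each of the $N_c$ clutches binds at constant rate $r_{on}$
  and, while bound, is stretched by the actin flow. A bound clutch carries
  force $F_c = k_c (x_c - x_s)$ and unbinds by Bell's law,
  $r_{off} = \tau_{off}^{-1} \exp(F_c / F_{bond})$ — a slip bond whose
  dissociation accelerates exponentially with load. Binding occurs at zero
  extension; a slack clutch buckles and carries no force.
* **Glassy off times.** The dissociation time constant $\tau_{off}$ is not a
  single number. Adhesion clusters are supramolecular assemblies whose
  unfolding/unbinding pathways traverse a rugged energy landscape, so their
  relaxation times are broadly distributed. The package models this with a
  power law on $[\tau_{min}, \infty)$,
  $p(\tau) = \frac{\beta - 1}{\tau_{min}} (\tau/\tau_{min})^{-\beta}$,
  whose variance diverges for $\beta \le 3$ (and the mean for
  $\beta \le 2$). Small $\beta$ is the glassy regime: most draws are short,
  but rare draws are enormously long, and those rare events dominate the
  adhesion dynamics. The conventional model (a single constant
  $\tau_{off}$) is available as an exact point mass, not as a large-$\beta$
  approximation.
* **Viscoelastic substrate.** A standard linear solid: spring $k_l$ (the
  long-term stiffness) in parallel with a Maxwell arm (spring $k_a$ in
  series with dashpot $\eta$), governed by
  $(k_a + k_l)\,\eta\,\dot{x}_s + k_a k_l x_s = k_a F_s + \eta \dot{F}_s$.
  Its stress-relaxation timescale is $\tau_s = \eta / k_a$: the substrate
  responds with stiffness $k_a + k_l$ instantly and relaxes to $k_l$ over
  $\tau_s$.

The myosin ensemble follows the linear Hill relation
$V_r = V_u (1 - F_m / F_{stall})$ with $F_{stall} = N_m F_{motor}$, clamped
to $[0, V_u]$.

## Whole-cell force balance

The two ends of an axis are linked through the cell body. The default
(`force_balance = "center"`) treats the body as quasi-static: the tensions
transmitted by the two ends are equal and opposite at every instant, and
the cell velocity $V_m$ is whatever makes that true. Operationally the
semi-implicit update makes each end's post-step tension affine in its
stretch-input velocity, so $V_m$ has a closed form each step; a small
viscous drag $\zeta$ on the body (`body_drag`) regularizes the
adhesion-free limit — a cell with no engaged clutches generates no motion —
and $|V_m|$ is capped at $V_u$, the speed of the actin machinery itself.
Measured relative to the substrate, the end flows are $V_r^L + V_m$ and
$V_r^R - V_m$, so the cell velocity is exactly half the difference of the
substrate-frame retrograde flows.

This coupling is what shapes the trap/step structure. When both ends are
engaged, tension rises to the weaker of grip strength and motor stall;
flows at the two ends match and the cell is trapped. When one end's cluster
fails catastrophically, the surviving end's stored elastic stretch — clutch
extension plus the substrate displacement accumulated by creep — tows the
cell toward it, and on a fast-relaxing substrate that reservoir is up to
$(k_a + k_l)/k_l$ times larger, which is why fast relaxation produces the
larger steps. An uncoupled mode (`force_balance = "per_end"`, each end
loaded by its own clutch force only) is retained for comparison; it
reproduces classic single-end motor-clutch behavior but lets one end stay
persistently weak, which inflates directional persistence.

## The three timescales

The migration phenotype is organized by three timescales, all derived and
logged by `timescales()`:

* $\tau_l = F_{motor} N_m / (V_u k_l)$ — time for the motors to stall
  against the long-term substrate stiffness (10 s at the defaults);
* $\tau_{off}$ — the heavy-tailed dissociation timescale (5th–95th
  percentile roughly 1–100 s at $\beta = 1.5$, $\tau_{min} = 1$ s, in the
  sense that the bulk of draws falls there while the tail extends far
  beyond);
* $\tau_s = \eta / k_a$ — substrate stress relaxation (10 s for the
  fast-relaxing condition, 1000 s for the slow-relaxing one).

# Parameters

| parameter | default | units | role |
|---|---|---|---|
| `n_clutches` | 45 | – | clutches per end |
| `k_c` | 0.8 | pN/nm | clutch spring stiffness |
| `r_on` | 1 | 1/s | clutch association rate |
| `f_bond` | 1.8 | pN | Bell rupture force scale |
| `n_motors` | 50 | – | myosin motors per end |
| `f_motor` | 2 | pN | single-motor stall force |
| `v_u` | 120 | nm/s | unloaded retrograde flow / polymerization speed scale |
| `k_l` | 0.083 | pN/nm | long-term substrate stiffness ($\tau_l$ = 10 s) |
| `k_a` | `9 * k_l` | pN/nm | Maxwell-arm stiffness |
| `tau_s` | 10 | s | stress-relaxation timescale (sets $\eta$) |
| `beta`, `tau_min` | 1.5, 1 | –, s | glassy off-time law |
| `body_drag` | 0.1 | pN s/nm | cell-body drag in the center balance |
| `duration`, `record_interval` | 2000, 10 | s | simulated time, frame interval |
| `burn_in` | 200 | s | discarded equilibration |

The calibration philosophy: the model's observable physics is carried by
the timescales, not by any individual molecular constant, so defaults are
chosen to pin the timescales at their physiological values —
$\tau_l = 10$ s, $\tau_{off}$ spanning ~1–100 s, $\tau_s \in \{10, 1000\}$
s for the fast/slow conditions — and, within that constraint, to place the
kinetics in the regime where the characteristic motor-clutch phenomenology
actually occurs. Two choices deserve comment:

* `n_clutches = 45`, `f_bond = 1.8` pN put the per-clutch load at stall
  ($F_{stall}/N_c \approx 2.2$ pN) slightly above $F_{bond}$. Motors can
  then drive cascading clutch failure, producing the load-and-fail cycling
  of the conventional model and the trap/step alternation of the glassy
  one. With substantially more clutches (or a larger $F_{bond}$) the
  ensemble can never be unbound by the motors: rare long-$\tau_{off}$
  survivors accumulate and every end locks permanently, a regime with no
  migration at all.
* `k_a = 9 * k_l` gives a substrate that relaxes to 10% of its
  instantaneous stiffness, the near-complete stress relaxation
  characteristic of ionically crosslinked alginate-type hydrogels. With
  $k_a = k_l$ the substrate would only soften twofold on relaxation, and
  the fast/slow conditions would differ mechanically by almost nothing.

`modify_params()` rebuilds all derived quantities after any change;
`apply_scenario()` implements the actomyosin-inhibition scenarios (myosin
inhibition scales $N_m$; actin inhibition scales $V_u$ and $N_m$), both of
which lower $\tau_l$ and force generation.

# Numerics

* **Timestep.** Default
  $dt = \min(\tau_{min}/100,\; 1/(100\,r_{on}),\; \tau_s/10)$ — it
  resolves the fastest kinetic scale and always respects the substrate
  bound $dt \le \tau_s / 10$. At the shipped parameters this is 10 ms. For
  very fast-relaxing substrates the bound $\tau_s/10$ governs; resolving
  $\tau_s$ more finely than that buys nothing because the substrate is then
  effectively pre-relaxed relative to every kinetic process.
* **Substrate update.** Backward Euler in $x_s$ with the clutch coupling
  $F_s(x_s)$ resolved inside the linear solve — unconditionally stable for
  the linear part, first-order accurate (relaxation-time error
  $\approx dt/(2\tau_s)$, i.e. 0.5% at $dt = \tau_s/100$). The
  force-bookkeeping invariant $F_s = \sum k_c (x_{c,i} - x_s)$ is
  re-established exactly after every step and its largest violation is
  reported with every run (`force_residual` attribute, typically
  $10^{-13}$ pN).
* **Stochastic kinetics.** Transitions use exact exponential survival:
  binding times are geometric in steps with $p = 1 - e^{-r_{on} dt}$, and
  unbinding accumulates the Bell hazard $\sum r_{off}\,dt$ against a
  pre-drawn Exp(1) budget — identical in law to per-step Bernoulli draws
  with $p = 1 - e^{-r_{off} dt}$, immune to $p > 1$ pathologies under
  force spikes, and cheaper. At most one transition per clutch per step.
* **Off-time sampling.** Default `tau_sampling = "per_binding"`: each
  clutch draws an independent $\tau_{off}$ at each binding event. The
  alternative `"per_episode"` treats the end's whole cluster as occupying
  one glassy configuration with a shared $\tau_{off}$ that renews at rate
  $1/\tau$ (trap-model dynamics).
* **RNG.** The engine uses its own counter-seeded xoshiro256++ streams, so
  trajectories are bit-reproducible from `(params, seed)` regardless of R's
  RNG state, and ensemble members are independent and order-invariant.
* **Burn-in.** Runs start with all clutches unbound; the first `burn_in`
  (200 s) is simulated but not recorded, since the artificial start
  otherwise leaks a super-ballistic transient into the MSD fit window.

# Trajectory statistics

* **MSD.** The default estimator is the ensemble average over cells of the
  squared displacement from each track's origin. This matches the practice
  of averaging displacement curves over many cells and — crucially — it
  preserves anomalous scaling for non-ergodic processes: for heavy-tailed
  waiting times the time-averaged MSD scales linearly in lag regardless of
  the true exponent (weak ergodicity breaking), so a sliding-window
  estimator would report $\alpha \approx 1$ for exactly the trapped
  dynamics this model exists to capture. The time-and-ensemble average
  remains available as `mode = "time"`.
* **Exponent fit.** OLS of $\log MSD$ on $\log \tau$ over one decade of
  lags starting at the first recorded lag (10–100 s at the default frame
  interval): small-lag decades have the most displacement pairs, and the
  early window is where the trap/step competition expresses. At least 8
  positive lags are required; 64 recorded frames is the floor for any MSD
  estimation.
* **Traps and steps.** A trap is a maximal run of frames with frame speed
  below `v_eps` lasting at least `t_min`; steps are the complementary
  segments with their net displacement. Thresholds default to
  $0.05\,V_u$ and three frame intervals and are reported with every
  result, since any speed-threshold segmentation is convention-laden.
  Raising `v_eps` can only grow the trapped fraction (tested property).
* **Kurtosis.** Pearson's $m_4/m_2^2$ (Gaussian = 3), not excess kurtosis,
  so that the tail-weight ratio $K_{trap}/K_{step}$ is always positive and
  well-defined.
* **VAC and straightness** are the standard normalized velocity
  autocorrelation ($C(0) = 1$) and net-over-total path-length ratio.

# Reference walks

`reference_walks()` generates the four canonical mobility classes with
known exponents — ballistic ($\alpha = 2$), Brownian ($\alpha = 1$), CTRW
with Pareto waits ($\alpha = \gamma$, sub-diffusive) and Lévy walks with
Pareto flights ($\alpha = 3 - \gamma$, super-diffusive) — so the statistics
layer is validated against inputs the simulator did not produce. Heavy
tails start at `frame_interval / 20` to keep the recorded lags in the
asymptotic scaling regime. These fixtures emulate the trapping-time and
step-size statistics the analysis assumes; they do not emulate localization
noise, frame dropouts, drift, or finite cell size, so passing them
validates the estimators, not the microscopy pipeline.

# Problem sizes

The packaged experiment drivers default to 100 cells per condition for
headline contrasts and 20 replicates per sweep cell, with 2000 s tracks at
10 s frames; the sweep driver and the acceptance script use 1000 s tracks
(still 100 frames) for the 25-cell grid. These sizes give Monte-Carlo
standard errors of roughly 0.05–0.1 on fitted exponents — the same order as
the biological claims being checked — and are stated here as the package's
study conditions.

# Known limitations

* The two migration axes are fully independent; there is no cell shape,
  polarity memory, or cross-axis force coupling.
* The center force balance treats the cell body as quasi-static with a
  single drag constant; a compliant cell body would low-pass the
  inter-end coupling.
* In this formulation substrate stress relaxation both lengthens steps
  (larger stored-displacement release, delayed motor stall) and, by
  relieving clutch load at stall, stabilizes engaged clusters. The second
  effect partially offsets the first. At the shipped calibration the
  trap-time, step-size and kurtosis-ratio orderings between the fast and
  slow conditions come out as expected (longer traps and smaller steps on
  slow relaxation), and the fast condition is clearly super-diffusive, but
  the slow condition's fitted exponent remains above the diffusive value:
  its rare escape runs are long enough to dominate the fit window. Strong
  sub-diffusion does occur elsewhere in the $(\beta, \tau_s)$ plane (the
  sweep's smallest relaxation times at $\beta = 1.5$). Treat the
  directional trap/step statistics as the robust signatures and
  single-number exponent contrasts as the fragile ones; run
  `scripts/acceptance.R` to recompute the package's own numbers.
* The conventional (constant off-time) model is diffusive to within
  roughly a tenth in the exponent on both substrate conditions; the
  fast-relaxing condition can sit marginally above that band because the
  stored-displacement release mechanism leaves a short persistence time
  comparable to the first fit lags.
* Catch bonds, adhesion reinforcement, substrate plasticity and durotaxis
  are out of scope.

# A worked example

```{r example, eval = FALSE}
p_fast <- clutch_params(tau_s = 10)      # fast-relaxing substrate
p_slow <- clutch_params(tau_s = 1000)    # slow-relaxing substrate
fast <- simulate_ensemble(p_fast, n_cells = 50, seed = 1)
slow <- simulate_ensemble(p_slow, n_cells = 50, seed = 2)
fit_alpha(msd(fast))
fit_alpha(msd(slow))
segment_motion(fast)
relaxation_contrast(reps = 50, seed = 1)
```
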