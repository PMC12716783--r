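---
title: "Models and methods in hepsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in hepsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepsim)
```

`hepsim` couples a statistical habitat-suitability model to an agent-based
demographic and mobility simulator. This vignette records the model, its
assumptions, the tunable parameters, the numerical choices, and what the
synthetic test world does and does not establish.

## 1. The suitability chain

Suitability comes in three layers, each consumed by the next.

**Climate–environment potential Φ_E.** Monthly temperature and precipitation
fields are reduced to the 17 standard bioclimatic variables (the
`compute_bioclim()` conventions: Bio4 is 100× the standard deviation of
monthly means; Bio15 the coefficient of variation of monthly precipitation;
quarters are circular 3-month windows; Bio2/Bio3 require monthly extremes and
are masked without them). Five predictors — Bio1, Bio4, Bio16, Bio15, Bio17 —
are the default selection; `cluster_predictors()` (average-linkage clustering
on 1 − |r|, cut at 0.3, representatives by point-biserial separation) is an
optional override path. After standardization over training cells, a
quadratic score

$$q(\mathbf{P}) = \tfrac12 \mathbf{P}^\top A \mathbf{P} + \mathbf{B}\cdot\mathbf{P} + c_0,
\qquad \Phi_E = \frac{1}{1 + e^{-q}}$$

is fit by maximum-likelihood logistic regression on all linear and unique
quadratic terms; the coefficients are repacked into a symmetric $A$ (diagonal
doubled, off-diagonal split evenly), so the stored form is exactly the
quadratic above. Complete separation triggers a weak L2 ridge refit (IRLS
with penalty $10^{-6}$, intercept unpenalized) and a flag.

**Training labels.** Cells holding at least one site are presences (spatial
blocking: many sites in one cell count once). Cells violating a-priori
bioclimatic bounds are absences; the shipped modern-human bounds are annual
mean temperature in [−2, 16] °C and wettest-month precipitation in
[30, 250] mm. For populations without published bounds the same construction
is applied empirically: central 95% interval of the variable at presence
cells (`thresholds_from_presence()`). The remaining *pseudo-absence* cells
are realized per ensemble member under three options: excluded (1); one third
relabeled presence, one third absence, one third excluded (2); or each cell
independently presence with probability $N_p/(N_p+N_{pa})$ (3, the default
and most conservative). A presence cell that also violates a bound keeps its
presence label — direct evidence beats the prior — with a logged conflict.

**Ensemble.** Each of (by default) 1000 members re-realizes the pseudo-absence
labels, draws a random 80/20 train/validation split, fits, and scores
validation AUC (the metric is our choice; any presence/absence skill score
would do). Degenerate splits are resampled, never skipped. The ensemble mean
⟨Φ_E⟩ is the estimate, the member spread its uncertainty (Welford
accumulation, so identical members give exactly zero spread). Under the
default option 3 the *realized validation labels themselves* are noisy, which
caps attainable AUC well below 1; clean option-1 labels are the right probe
of separability. Tests use each accordingly.

**Accessible potential.** Static landscape factors multiply the mean:
$\Phi_{Ac} = \langle\Phi_E\rangle\, g_1 g_2 g_3 g_x$, where $g_1$ (elevation)
and $g_2$ (roughness) are piecewise-linear ramps from 1 to a 0.8 plateau with
slope $0.2/(x_u - x_l)$ — modern humans: 350/2000 m and 70/400 m;
Neanderthals: 450/2000 m with the roughness factor disabled — and water
($g_3$) and dense forest ($g_x$) zero the cell.

## 2. Demography

Density ρ is measured in PDU (persons per 100 km²; a 20-km cell holding $n$
agents has ρ = n/4). The carrying capacity of a cell is $\rho_c = C\,
\Phi_{Ac}$ with $C$ the cultural carrying capacity (PDU). The attractiveness
of occupied habitat is Weibull-shaped in $u = (\rho/\rho_c)/\varepsilon$:

$$w(u) = \frac{\eta}{\varepsilon} u^{\eta-1} e^{-u^\eta}, \qquad
f_{pa} = w / w_{\max},$$

normalized analytically at the mode $u^* = ((\eta-1)/\eta)^{1/\eta}$
(defaults ε = 0.4, η = 1.6; η > 1 so empty habitat has zero pull). The
*available* potential $\Phi_{Av} = f_{pa}\,\rho_c$ rises from zero, peaks at
intermediate density and falls under crowding — the gregariousness/pressure
trade-off — and is what agents climb. We read the printed Weibull form with
the customary minus sign in the exponential, since it is explicitly a Weibull
density.

Births and deaths are sampled per agent so the expected census obeys
Verhulst growth $d\rho/dt = \rho\, r_B (1 - \rho/\rho_c)$ with the
density-dependent rate

$$r_B(\rho) = r_o\left[\frac{1-\eta_g}{1+e^{-x}} + \eta_g\right],
\qquad x = \epsilon_g \ln(\rho/\rho_d),$$

which tends to $\eta_g r_o < 0$ as ρ → 0 (mating-network collapse), equals
$r_o(1+\eta_g)/2$ at $\rho_d$, and saturates at $r_o$. Defaults:
$\eta_g = -0.1$, $\epsilon_g = 2.5$, $\rho_d = 0.05$ PDU. Numerical choices:
where $\rho_c = 0$ under occupied cells the crowding factor is clamped at −1
(maximal per-capita hazard $r_B\,dt$, avoiding infinite rates); the density
entering demography and attractiveness is smoothed by one 3×3 uniform pass
(default on — it stabilizes gradients at 20-km resolution); a step with
$dt\,|g| > 0.5$ raises a stability error rather than integrating nonsense.
Newborns appear at the parent's position with a random velocity of magnitude
σ (inheritance of parental velocity would be equally defensible; the choice
is inconsequential at τ ≈ years).

## 3. Mobility

Agent velocity follows a damped stochastic process with drift up
$\nabla\Phi_{Av}$:

$$dU = \left(\frac{\alpha}{C}\nabla\Phi_{Av} - \gamma U\right) dt + \beta\, dW,
\qquad dX = U\, dt .$$

Three deliberate readings, each dimensionally forced and verified by
property tests:

* **Drift term (α/C).** Only the ratio reading gives acceleration units and
  closes the published scaling chain: with $\alpha = U_s G_d / D_t$,
  $\tau = D_t$ and a gradient of magnitude $C/G_d$, the steady drift speed is
  exactly $U_s$. The product reading misses by a factor $C^2$.
* **Noise amplitude.** The printed relation between β and σ is dimensionally
  inconsistent with Wiener forcing; we set $\beta^2 = 2\sigma^2\gamma$, the
  unique choice making the stationary per-axis velocity standard deviation
  equal the quantity actually specified, σ = 15 km/yr.
* **Integrator.** The velocity update is the *exact* one-step solution of the
  linear velocity equation (coefficient $e^{-\gamma dt}$, noise std
  $\sigma\sqrt{1-e^{-2\gamma dt}}$, drift equilibrium
  $(\alpha/C)\nabla\Phi_{Av}/\gamma$), not Euler–Maruyama. The defaults have
  $\gamma\,dt = 1$, where Euler–Maruyama inflates the stationary velocity
  variance by a factor of 2; the exact update is unconditionally stable,
  agrees with Euler–Maruyama as $\gamma dt \to 0$, and preserves the
  long-time diffusivity $\sigma^2\tau$ per axis, which is how the Lagrangian
  scheme realizes the macroscopic drift–diffusion picture.

Gradients are central differences with sea cells entered as $\Phi_{Av} = 0$
(so coasts repel) and one-sided stencils at domain edges, bilinearly
interpolated to agent positions. Coastlines and domain walls reflect
symmetrically: the position mirrors across the crossed edge and the normal
velocity component flips; an agent whose mirror also lands on water (e.g. a
one-cell channel) reverts to its pre-move position with fully reversed
velocity, and such fallbacks are counted.

## 4. Admixture

Cells co-occupied by both parent populations are eligible; each NEA–AMH cross
pair independently yields a MIX birth with probability $p_{adm}\,dt$
(default 1%/yr). The event unit is not defined by the source description;
pair-level is the default because it scales with both local densities, and
per-agent or per-cell units are configurable. MIX agents use the arithmetic
mean of the parents' *accessible* potentials (the averaging level is
ambiguous in principle; we average after landscape modification because that
is the field the simulator consumes, and the modification functions are
near-multiplicative anyway) and, by default, never themselves admix.

## 5. Engine, ensembles, diagnostics

A step processes, per population: density → demography fields
(ρ_c, f_pa, Φ_Av) from the period-active Φ_Ac → motion with reflection →
births/deaths → admixture → recording. The order is a convention; a property
test verifies that swapping motion and demography shifts equilibria by < 5%.
Period switches swap Φ_Ac fields discretely at timeline boundaries.
Initialization draws each centre's $N_0$ agents from a Gaussian (standard
deviation in degrees, converted through the grid transform), resampling draws
that land on sea so the census is exact, with initial speeds of magnitude σ.
The first 300 years are excluded from summaries by default (spin-up);
a two-sample test in the suite confirms post-spin-up equilibria forget the
initial placement.

Scenario ensembles multiply every perturbable scalar (C, r_o, η_g, ε_g, ρ_d,
α, σ, D_t, p_adm) by independent uniform draws from [1−p, 1+p] (default
p = 0.1; a Gaussian mode exists). Draws violating a parameter invariant are
clipped into range and logged. Seeding is hierarchical
(master → member → module stream), making every run and ensemble
bit-reproducible. Diagnostics: population means ± sd over members,
ensemble-mean density snapshots, rate-of-change maps
$(\langle\rho(t+\Delta t)\rangle - \langle\rho(t)\rangle)/\Delta t$ with
Δt = 500 yr, and threshold fractions (share of members whose minimum
population falls below given levels, with 0 meaning true extinction).

## 6. The synthetic world, and what a green test establishes

The laboratory (`synth_spec()`) fabricates a coherent coastline (low-pass
filtered noise thresholded at the land-fraction quantile), elevation with
~1200 m relief, roughness as local elevation spread, and a monthly climate
with a latitudinal gradient (0.8 °C/deg), a 6.5 °C/km lapse rate, spatially
varying seasonal amplitude, and smooth spatial noise shared between periods.
The cold period applies ΔT = −4 °C and a precipitation scaling of 0.7. These
two numbers were fixed once, by a stated criterion: together with the default
planted suitability surface (`default_true_hep()`, a concave quadratic on the
five standard predictors) they reduce total accessible capacity under the
cold period to roughly a sixth of the warm value while retaining
high-suitability refugial cells — the "colder and drier stadial with coastal
refugia" structure the simulator is meant to exercise. They were not adjusted
afterwards.

Site records are presence-only draws ∝ Φ_E* with within-cell jitter, so the
full labeling machinery (blocking, a-priori bounds, pseudo-absences) runs on
synthetic data exactly as on real data.

What the green suite establishes: correctness of the formulas and their
stated limits; stationary and transport statistics of the mobility process;
Verhulst agreement of the stochastic demography; parameter and surface
recovery of the suitability model; and the qualitative demographic structure
(equilibrium ordering across presets, cold-period contraction with refugial
persistence). What it does not establish: realism of any particular
paleogeography, absolute population sizes for a real region, or map-level
pattern agreement — those require real reconstructed paleoclimate fields and
site databases, which are out of scope here.

**Known red result.** Under the fragile preset (C = 1 PDU, r_o = 0.01/yr) the
acceptance suite also asserts full member extinctions at desk scale. In the
frozen synthetic world they do not occur: the cold-period refugial
equilibrium (~25–35 individuals) sits above the absorption zone of
demographic stochasticity over 2,500-year horizons, because the two-snapshot
climate lacks the short within-phase oscillations that, over many millennia
on real reconstructed suitability fields, drive rare member extinctions in
full-scale applications. Near-extinction dips
below 30 and 50 individuals do occur in a nonzero fraction of perturbed
members. We left the assertion red rather than hardening the cold period
post hoc, which would have been calibration toward a test.

## 7. Known limitations

* One population's demography step is O(agents) in R; desk-scale ensembles
  (tens of members, thousands of agents, millennia) run in minutes, but the
  full production scale (1000 members) wants a compiled core or a cluster.
* The equirectangular grid transform is adequate for regional domains but is
  not a cartographic projection; distances distort at continental scale.
* Gridded I/O uses a plain-text raster format rather than NetCDF, keeping the
  package dependency-free in this environment; the format is self-describing
  and exact, but not a community standard.
* Forest and inland-water masks are static; no age/sex structure; admixture
  is demographic only (no ancestry tracking).
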