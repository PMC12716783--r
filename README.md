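# hepsim

Constrained agent-based simulation of Paleolithic population dynamics on a
gridded suitability landscape.

## The problem

How resilient were Neanderthal populations to stadial climate shifts, how did
anatomically modern humans disperse into already-occupied landscapes, and how
much admixture does demographic overlap permit? Static archaeological and
genomic records constrain these questions only loosely. `hepsim` implements a
forward-time modelling chain for them, aimed at quantitative archaeologists
and paleo-demographers:

1. **Human Existence Potential (HEP).** From monthly climate fields the
   package derives the 17 standard bioclimatic predictors (Bio1, Bio4, Bio16,
   Bio15 and Bio17 are the default selection) and fits an ensemble of
   quadratic logistic regressions to archaeological presence records,

   *q*(**P**) = ½ **P**ᵀ**A** **P** + **B**·**P** + *c*₀,  Φ_E = 1 / (1 + e^(−q)),

   with per-cell labels built from presence (Φ = 1), a-priori absence
   (bioclimatic bounds violated, Φ = 0) and probabilistically relabeled
   pseudo-absence cells. The ensemble mean ⟨Φ_E⟩ over members (default 1000,
   each trained on a random 80% split) is the suitability estimate;
   topography, roughness, water and dense forest then modify it to the
   accessible potential Φ_Ac = ⟨Φ_E⟩·g₁·g₂·g₃·g_x.

2. **Demography.** A cell's carrying capacity is ρ_c = C·Φ_Ac (C = cultural
   carrying capacity, in PDU = persons/100 km²). Agents reproduce and die so
   the expected census follows dρ/dt = ρ·r_B·(1 − ρ/ρ_c), with a
   density-dependent rate r_B(ρ) = r_o·[(1−η)/(1+e^(−x)) + η],
   x = ε·ln(ρ/ρ_d), that turns negative below the mating-network density ρ_d
   (Allee effect).

3. **Mobility.** Each agent's velocity is a damped stochastic process with a
   deterministic pull up the gradient of the *available* potential
   Φ_Av = f_pa·ρ_c (f_pa is a Weibull-shaped attractiveness in ρ/ρ_c):

   dU = ((α/C)∇Φ_Av − γU)dt + β dW,  dX = U dt,

   with α = U_s·G_d/D_t (default 1250 km²/yr²), γ = 1/τ, τ = D_t, and
   β² = 2σ²γ so the stationary speed scale is exactly σ (default 15 km/yr).
   Coastlines and the domain boundary reflect symmetrically.

4. **Admixture.** Where two populations co-occupy a cell, each cross pair
   yields an admixed (MIX) birth with probability 1%/yr by default; MIX
   agents inherit averaged suitability and never admix again.

5. **Ensembles and diagnostics.** Scenario ensembles perturb every input
   parameter by ±10% per member, and summaries provide population time
   series (mean ± sd), density snapshot means, 500-yr rate-of-change maps
   and extinction/threshold fractions.

A synthetic laboratory (`synth_spec()`, `generate_landscape()`,
`generate_climate()`, `sample_sites_from_hep()`) generates landscapes,
two-period (warm/cold) climates and site records with known ground truth, so
the whole chain is testable without external data. Synthetic and real inputs
are interchangeable: gridded layers use a self-describing text raster format,
site tables are CSV.

## Worked example

```r
library(hepsim)

# 1. synthetic world: landscape, warm-period climate, bioclim predictors
spec <- synth_spec(nx = 30, ny = 30, seed = 7)
world <- generate_landscape(spec)
stack <- compute_bioclim(generate_climate(spec, world, "warm"))

# 2. sites from a known suitability surface, then ensemble HEP training
truth <- true_hep_field(stack, default_true_hep())
sites <- sample_sites_from_hep(truth$field, n_sites = 200, seed = 9)
presence <- sites_to_cells(sites, world$grid, world$landscape$land_mask)$presence
thr <- thresholds_from_presence(stack, presence)
ens <- hep_ensemble(presence, stack, thr, n_members = 100, seed = 4)
print(ens)
land <- world$landscape$land_mask
cat(sprintf("correlation with the planted surface: %.3f\n",
            cor(ens$mean_field$values[land], truth$field$values[land])))

# 3. accessible HEP and a two-period agent-based simulation
sc <- synthetic_scenario(spec, presets = c(NEA = "ExpNEA-C"),
                         t_end = 1200, switch_time = 600,
                         n0 = 1000, n_centers = 4)
out <- run_simulation(sc$scenario, seed = 11)
print(out)
cat(sprintf("warm-period mean population: %.0f\n", mean(out$pop_size[450:600, "NEA"])))
cat(sprintf("cold-period mean population: %.0f\n", mean(out$pop_size[1000:1200, "NEA"])))
```

Output:

```
hep_ensemble: 100 members on Bio1, Bio4, Bio16, Bio15, Bio17; mean AUC 0.649
correlation with the planted surface: 0.858
sim_output: 1200 steps; final sizes: NEA=75
warm-period mean population: 2033
cold-period mean population: 95
```

Reading it: the ensemble-mean suitability recovers the planted surface at
r = 0.86 even though pseudo-absence relabeling caps the per-member
validation AUC (labels themselves are noisy under the default option-3
treatment; training against clean a-priori absences alone scores AUC > 0.9).
In the simulation, a population with the central preset (C = 2 PDU,
r_o = 0.02/yr) equilibrates near two thousand individuals under the warm
climate, then contracts by roughly a factor twenty when the cold period cuts
the accessible potential, persisting in the remaining high-suitability
(refugial) cells.

Named presets `ExpNEA-H/C/L`, `ExpAUR-C` and `ExpMIX-C` (`preset_params()`)
bundle the standard carrying-capacity/growth-rate combinations; 20-member
perturbed ensembles over them reproduce the expected ordering of equilibria
(H > C > L) and the cold-period decline-with-persistence structure (see
`tests/testthat/test-acceptance.R`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, against the installed package, the analytic value of the
elevation modification function at its upper plateau, the carrying capacity
of a fully suitable cell under the high-capacity preset, and the empirical
admixture probability realized by the sampler over at least 10⁵ eligible
pair events, and writes them as JSON.
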