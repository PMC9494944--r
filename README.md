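# pepmem

Quantitative analysis of cationic peptide adsorption onto zwitterionic
lipid bilayers, for researchers studying cell-penetrating peptides (e.g.
nona-arginine R9 vs nona-lysine K9 at POPC membranes) with molecular
dynamics and/or dual-color fluorescence cross-correlation spectroscopy
(FCCS).

The package implements three analysis layers plus the synthetic data that
validates them:

1. **Adsorption free energies from MD density profiles.** The
   leaflet-folded, unit-normalized peptide number density ρ(z) along the
   membrane normal is split at the cutoff z(ρ_min) — the density minimum
   between the interfacial binding peak and the bulk plateau, with a 3.5 nm
   fallback when no specific peak exists — and Boltzmann-inverted:

   ΔG = −k_B T ln(P_bound / P_unbound),  P_bound = ∫₀^z_cut ρ dz.

   Companion observables: per-frame bound-peptide counts, buried
   guanidinium side chains per bound peptide (phosphate-plane criterion),
   area per lipid, and periodic minimum-distance series, all with
   block-averaged errors.

2. **2-D metadynamics free-energy surfaces** over the two
   peptide–membrane distance collective variables: symmetrization along the
   identity line, zeroing at the joint bulk (both peptides beyond 4 nm),
   global minima, and a Boltzmann-sum total adsorption free energy
   ΔG_ads = −k_B T ln(Σ_bound e^{−F/kT} / Σ_bulk e^{−F/kT}) with a
   convergence/drift monitor. Unexplored cells are excluded, never imputed.

3. **FCCS binding analysis.** Multi-tau correlation of two-channel photon
   traces with the fluctuation (−1) convention, single-species 3-D
   diffusion-model amplitude fits, effective detection volumes
   V_eff,x = π^{3/2} S ((ω_b²+ω_r²)/2)^{3/2}, bound peptides per vesicle
   ⟨N_P⟩ = G_x⁰ V_eff,x N_A C_P⁰, free concentration by mass conservation,
   and a Langmuir fit ⟨N_P⟩ = N_max C_free/(K_D + C_free) yielding the
   dissociation constant.

4. **Seeded generators with exact ground truth**: Metropolis/Langevin
   sampling of a membrane-like potential of mean force (analytic ΔG
   oracle), labeled contact toys, noisy symmetric free-energy grids, and a
   Brownian-dynamics confocal photon-trace simulator of vesicle–peptide
   titrations with known K_D and N_max.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` on fits, `autoplot()` on profiles, surfaces, correlation curves
and isotherms.

## Worked example

Sample an equilibrium z-trajectory from a membrane potential with a
12 kJ/mol adsorption well, then recover the adsorption free energy from
its density profile:

```r
library(pepmem)

pmf  <- membrane_pmf(well_depth = 12)   # well at 2.2 nm, barrier at 3.0 nm
traj <- sample_pmf(pmf, 2e5, seed = 42) # Metropolis, seeded
adsorption_free_energy(traj, discard_ns = 0)
#> # A tibble: 1 × 6
#>   delta_g_kj_mol p_bound p_unbound z_cut_nm cutoff_method    n_frames_used
#>            <dbl>   <dbl>     <dbl>    <dbl> <chr>                    <int>
#> 1          -8.12   0.959    0.0410     3.03 detected_minimum        200000

analytic_dg(pmf, 3.0)  # exact quadrature oracle at the same cutoff
#> [1] -8.334307
```

The estimate (−8.12 kJ/mol from 2×10⁵ samples) tracks the exact value
(−8.33 kJ/mol); at the 10⁶-sample validation scale agreement is within
0.3 kJ/mol. The detected cutoff (3.03 nm) is the density minimum at the
potential's desorption barrier; negative ΔG means adsorption is favored.

An FCCS titration end-to-end:

```r
params <- fccs_sim_params(kd = 129e-9, seed = 1)  # 12 points, 0.1-10x Kd
sim    <- simulate_fccs(params)
geom   <- effective_volume(omega_b = 2e-7, omega_r = 2.5e-7, s_param = 5)
res    <- binding_pipeline(sim$traces, geom)
glance(res)       # fitted K_D and N_max with standard errors
autoplot(res$fit) # normalized isotherm
```

A thin command-line wrapper over the same functions ships in
`inst/cli/pepmem` (`dg-scan`, `fes-process`, `fccs-fit`, `simulate`).

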