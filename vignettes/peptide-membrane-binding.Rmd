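---
title: "Quantifying cationic peptide adsorption to zwitterionic bilayers: models, estimators and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cationic peptide adsorption to zwitterionic bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(pepmem)
```

Arginine-rich cell-penetrating peptides such as nona-arginine (R9) adsorb
to zwitterionic phosphatidylcholine membranes far more strongly than their
lysine analogues (K9), a difference that underlies their ability to enter
cells. `pepmem` implements the quantitative analysis layer used to measure
this adsorption from two very different kinds of raw data — particle
trajectories from molecular dynamics, and photon streams from dual-color
fluorescence cross-correlation spectroscopy (FCCS) — together with seeded
synthetic-data generators that provide exact ground truth for every
estimator.

This vignette documents the models, the estimator choices, the generator
design, and the limits of what the synthetic validation can show.

## 1. Adsorption free energy from density profiles

For an unbiased MD simulation of peptides near a bilayer, the membrane
normal is `z` with the membrane center of mass at the origin
(`center_and_fold()` performs the per-frame re-centering and periodic
wrapping). The normalized, leaflet-folded number density `rho(z)` of the
peptide center of mass (`density_profile()`) is partitioned at a cutoff
`z_cut` into a bound region `[0, z_cut]` and an unbound region
`[z_cut, z_max]`, and the adsorption free energy follows by Boltzmann
inversion:

$$
\Delta G \;=\; -k_B T \,\ln\frac{P_\text{bound}}{P_\text{unbound}},
\qquad
P_\text{bound} = \int_0^{z_\text{cut}} \rho\,\mathrm{d}z .
$$

Choices that matter:

* **Folding.** Symmetrization is implemented as folding to `|z|`
  (averaging the two leaflets). For leaflet-symmetric sampling the
  probability ratio is identical whether or not one folds; for asymmetric
  sampling it is not, and the folded convention is the package's default
  (`fold = FALSE` exposes the signed profile for diagnosing asymmetry, but
  such a profile is not accepted by the probability integrals).
* **Normalization.** `rho` integrates to exactly one over the folded
  half-profile, so the probabilities are direct integrals; any common
  normalization would cancel in the ratio anyway.
* **Cutoff detection** (`find_cutoff()`). The cutoff is the density
  minimum between the interfacial binding peak and the bulk plateau. A peak
  counts as interfacial only if it lies below the fallback cutoff and
  exceeds the bulk plateau level (the mean density over the outermost 1 nm)
  by at least 10% — below that prominence the profile is treated as having
  no specific binding peak and the fixed 3.5 nm fallback is used, which is
  the typical situation for the weakly adsorbing K9. Plateaus in the
  minimum are resolved toward the smallest z.
* **Partial bins.** The probability integral splits the bin containing
  `z_cut` by linear interpolation, which removes the bin-width sensitivity
  of `P_bound`. The default bin width is 0.02 nm; the default equilibration
  discard is 500 ns; the default temperature is 310 K.
* **Degenerate inputs.** A profile with all mass on one side of the cutoff
  has a divergent free energy; `adsorption_dg()` raises an error rather
  than returning an infinity, because the correct interpretation is "no
  sampling of one region", not "infinitely strong binding".

The counting observables use the same cutoff for consistency: a peptide is
bound when its center-of-mass `|z|` is at or below `z_cut`
(`count_bound_peptides()`), and an arginine side chain is *buried* when its
guanidinium carbon sits below the proximal-leaflet phosphate plane plus a
0.1 nm margin (`count_buried_gdm()`). The burial rule is a documented
stand-in — the underlying study reports buried side-chain counts without
defining the criterion — and the margin is exposed as an argument.
Uncertainties use block averaging with five equal blocks, which absorbs the
serial correlation a naive standard error would ignore. Area per lipid is
the lateral box area over the lipids per leaflet (100 by default, matching
the bilayer the package models).

## 2. Free-energy-surface post-processing

Well-tempered metadynamics over the two peptide–membrane distance
collective variables yields a two-dimensional free-energy grid (`fes2d`,
read and written in the common whitespace `cv1 cv2 f` dump format with `#`
comments, fastest-varying first column). Post-processing follows three
exact rules:

* `symmetrize()` averages the surface with its transpose — the two
  peptides are exchangeable, so the surface should be invariant under
  exchange of the collective variables. The arithmetic mean of free
  energies was chosen over the Boltzmann average of probabilities as the
  conventional reading of symmetrizing along the identity line; since
  averaging two unbiased noisy estimates of a symmetric truth halves the
  error variance, the symmetrized surface is provably closer to the truth
  (the test suite verifies the √2 error reduction on generated surfaces).
* `shift_to_bulk()` zeroes the surface at the lowest explored free energy
  in the joint bulk (both peptides beyond 4 nm).
* Unexplored cells are `NA` and are excluded from every sum and minimum.
  Imputing them (e.g. as zero, after the bulk shift) would create
  fictitious favorable regions.

The *total adsorption free energy* used for convergence monitoring is not
given a formula in the source study; the package adopts the Boltzmann-sum
definition

$$
\Delta G_\text{ads} = -k_B T \ln
\frac{\sum_\text{bound} w\, e^{-F/k_BT}}
     {\sum_\text{bulk} w\, e^{-F/k_BT}},
$$

with cell-area weights `w`, bound meaning *either* peptide within the
cutoff and bulk meaning both beyond it. On a flat surface this reduces to
the entropic area ratio, which the tests pin exactly.
`convergence_series()` applies this per snapshot and reports the last-half
drift (max minus min over the later half of the series) as a plateau
diagnostic.

## 3. FCCS binding analysis

In the dual-color experiment, vesicles carry a red lipid dye and a fraction
of the peptide carries a blue label. Binding produces co-diffusion and
hence a positive cross-correlation

$$
G_\times(\tau) = \frac{\langle F_1(t)\,F_2(t+\tau)\rangle}
                      {\langle F_1\rangle\langle F_2\rangle} - 1 ,
$$

estimated by `correlate()` with a multi-tau scheme: 16 linearly spaced lags
per octave, with counts *averaged* (not summed) on each factor-two
rebinning, and segment means over the overlapping windows in the
normalization. The `- 1` (fluctuation-normalized) convention is deliberate
and is relied upon throughout: zero amplitude means no co-diffusion, which
is exactly the free-dye control signature. The multi-tau scheme is an
efficiency device only — the test suite verifies it equals a from-scratch
brute-force correlator at every shared lag to within 1e-10.

Amplitudes are extracted by fitting the single-species three-dimensional
diffusion model

$$
G(\tau) = G_0\left(1+\tau/\tau_D\right)^{-1}
          \left(1+\tau/(S^2\tau_D)\right)^{-1/2}
$$

(`fit_amplitude()`, Levenberg–Marquardt with an analytic Jacobian and a
small grid of diffusion-time starts). A model fit was preferred over
shortest-lag extrapolation for robustness to short-lag artifacts; weights
default to none, with inverse-variance weights accepted when replicate
spread is available. Negative fitted amplitudes are reported with a flag
and treated downstream as zero binding.

The amplitudes convert to binding quantities through the effective
detection volumes

$$
V_{\text{eff},\times} = \pi^{3/2} S \left(\tfrac{\omega_b^2+\omega_r^2}{2}\right)^{3/2},
\qquad
V_{\text{eff},r} = \pi^{3/2} S\, \omega_r^3 ,
$$

with focus radii calibrated from reference dyes via
$\omega = \sqrt{4 D \tau_D}$ (`calibrate_radius()`). The mean number of
bound peptides per vesicle and the free peptide concentration follow as

$$
\langle N_P\rangle = G_\times^0\, V_{\text{eff},\times} N_A\, C_P^0,
\qquad
C_V = \frac{1}{G_r^0\, V_{\text{eff},r} N_A},
\qquad
C_P^\text{free} = C_P^0 - \langle N_P\rangle\, C_V ,
$$

so mass conservation holds by construction on every titration point.
These amplitude relations were derived from first principles for 3-D
Gaussian detection profiles (the derivations fix both the cross-volume
formula and the linearity of $\langle N_P\rangle$ in $G_\times^0$), and the
Brownian-dynamics simulator reproduces them without free parameters — that
consistency is what the acceptance suite tests end to end.

Finally `fit_langmuir()` fits the isotherm
$\langle N_P\rangle = N_\text{max} C^\text{free} / (K_D + C^\text{free})$
by nonlinear least squares, reporting $K_D$ and $N_\text{max}$ with
standard errors and flagging titrations that never reach half-saturation as
poorly identified. The unweighted fit in free-concentration space is kept
deliberately: the errors in $\langle N_P\rangle$ and $C^\text{free}$ are
anti-correlated (both descend from the cross amplitude), and in simulation
studies the plain fit recovered $K_D$ with less scatter than
inverse-variance weighting or a depletion-aware total-concentration
parametrization.

`binding_pipeline()` chains the whole analysis. Two robustness rules apply
at strongly depleted titration points (total peptide far below the site
concentration): a negative estimated free concentration — an expected
outcome when $C^\text{free}$ is the small difference of two noisy
estimates — is clamped to zero, and such points are flagged
non-informative and excluded from the isotherm fit, since a zero free
concentration carries no abscissa. If no point shows a cross amplitude
clearly above its uncertainty (five standard errors — the lag-fit errors
are optimistic because multi-tau residuals are correlated), the pipeline
declares no detectable binding instead of fitting, mirroring the free-dye
control. The conversion between
dissociation constants and binding free-energy shifts
(`kd_free_energy_shift()`) defaults to 298 K, as the binding experiments
are performed at room temperature.

## 4. The synthetic generators

Every estimator is validated against data with known ground truth.

**Membrane PMF and sampler.** `membrane_pmf()` is a smooth analytic
potential: a steep exponential wall below 1.5 nm (the bilayer core), a
Gaussian adsorption well at 2.2 nm (where adsorbed-peptide density peaks at
phosphatidylcholine interfaces), a small Gaussian barrier at 3.0 nm, and
zero in the bulk up to the half-box at 4.5 nm. The barrier (2 kJ/mol by
default) is a deliberate addition: the bound/unbound cutoff is defined as a
*density minimum*, and a monotonic well-to-bulk potential has none.
`sample_pmf()` draws equilibrium configurations by Metropolis Monte Carlo
(uniform ±0.6 nm proposals, ~45% acceptance at 310 K) augmented with a 10%
sign-flip move: the potential is even in `z` and the flip is always
accepted, restoring mixing between the two leaflets across the impassable
core. An overdamped-Langevin alternative with reflecting walls is provided
(`method = "overdamped"`). Both samplers burn in internally, so their
output needs no further equilibration discard. `analytic_dg()` is the
matching oracle: adaptive quadrature of the Boltzmann weight on either side
of the cutoff. At $10^6$ samples the sampled estimate tracks the oracle
within 0.3 kJ/mol across well depths 0–20 kJ/mol, and monotonically deeper
wells give monotonically stronger binding.

**Contact toys.** `toy_contact_trajectory()` generates peptides with
per-frame bound labels, nine guanidinium carbons each with a known buried
count, and a phosphate plane whose mean position is exact by construction —
so the counting operators must agree with the generator's bookkeeping
*exactly*, not approximately.

**Noisy surfaces.** `make_fes()` builds `f(a,b) = U(a) + U(b)` from a
membrane PMF plus independent Gaussian noise (which breaks the transpose
symmetry), keeping the exact truth as an attribute.

**Photon traces.** `simulate_fccs()` emulates one titration: vesicles
(slow, red) and labeled peptides (fast, blue) in a periodic box; each
labeled peptide is bound (riding its vesicle) or free by a Bernoulli draw
at the exact Langmuir equilibrium occupancy; Brownian propagation; per-bin
expected counts from 3-D Gaussian detection profiles; Poisson photon
emission. The defaults are the emulated experiment's conditions: 20 nM
vesicles (0.5 mM lipid over ~24,000 lipids per 50-nm vesicle),
$D_\text{ves} = 9.8\times10^{-12}$ m²/s (Stokes–Einstein at 298 K),
$D_\text{pep} = 1.5\times10^{-10}$ m²/s, 10% labeling, ~6 red dyes per
vesicle (4000:1 lipid:dye), focus radii 0.2/0.25 µm with structural
parameter 5, 0.1 ms bins, and 60 s per titration point (the per-point
measurement time of the titration protocol). $N_\text{max}$ defaults to 50
sites per vesicle — the study reports normalized isotherms without printing
$N_\text{max}$, so this is a plausibility choice for a 50-nm vesicle. The
titration default is 12 log-spaced concentrations from $0.1\,K_D$ to
$10\,K_D$.

Generator design notes:

* **Quasi-static binding.** Occupancy is frozen within a trace. The
  amplitude analysis assumes equilibrium occupancy and does not model
  trace-scale exchange kinetics, so the generator does not either; what is
  lost is any exchange-induced relaxation component in the correlation
  functions.
* **One step per bin.** The stated stability rule
  $\Delta t \le \omega_b^2/(20 D)$ is satisfied at the default bin width
  for the species whose correlations the pipeline consumes (vesicles and
  bound peptides). Free peptides traverse the focus faster than one bin;
  for them a single detection-profile evaluation per bin is an unbiased
  estimator of the mean intensity under stationarity, so amplitudes are
  unaffected — only the (unused) shape of the blue autocorrelation at
  sub-bin lags is coarse. A warning fires if the bin width exceeds the
  vesicle-scale limit.
* **Closed-box (canonical) correction.** A periodic box holds a fixed
  particle number, which depresses correlation amplitudes by exactly $1/N$
  relative to the open-volume closed forms. At the default box
  (1.5×1.5×4 µm, chosen with the long axis along the optical axis so that
  periodic images stay dark) this is a percent-level effect that cancels
  almost entirely in the $K_D$ estimate; the single-species model
  validation uses a larger box and adds the exact $1/N$ offset back before
  comparing to the closed form.
* **Point-particle optics.** Bound peptides sit at their vesicle's center;
  the ~25 nm vesicle radius is well below the focus radii, so the intensity
  error is second order.
* **Acquisition times.** The tight-binder titration (sub-micromolar
  concentrations, few labeled molecules per box) uses the full 60 s
  default. For micromolar weak-binder titrations the same default costs
  ~25 CPU-minutes; the packaged validation runs those at 20 s per point,
  which its ~40-fold larger labeled-molecule numbers comfortably absorb.
* **Reproducibility.** All generators are deterministic under an explicit
  integer seed and leave the caller's R RNG state untouched; the
  Brownian/photon core carries its own xoshiro256++/ziggurat generator
  (validated against R's normal distribution), with Poisson emission from
  R's RNG under a derived seed.

## 5. What the synthetic validation does and does not show

The generators validate *estimators*, not *force fields*. Passing tests
show that: the Boltzmann-inversion estimator converges to the exact free
energy of a known potential; the cutoff detector finds the analytic density
minimum; counting operators are exact against labeled data; surface
post-processing obeys its exact guarantees and matches fine-grid Boltzmann
sums; the correlator is exact against brute force; and the full FCCS
chain — simulation, correlation, amplitude fits, occupancy and
free-concentration bookkeeping, isotherm fit — recovers dissociation
constants spanning 129 nM to 4.8 µM within the uncertainties reported for
the corresponding experiments.

They do not show that any particular force field, sampling protocol or
microscope produces accurate inputs. The study-scale MD observables — the
free-energy heat maps over peptide/salt concentration grids, the buried
guanidinium counts of 2.5–5.9 per bound R9, the area-per-lipid trends, and
the −20 kJ/mol metadynamics minimum near 2.2 nm — require microsecond
atomistic trajectories and are out of scope at desk scale; the literature
range 2.5–5.9 should be treated as a plausibility band when applying
`count_buried_gdm()` to real trajectories. Synthetic z-trajectories are
one-dimensional equilibrium samples: they have no lateral structure, no
peptide–peptide interactions, and no slow orientational degrees of
freedom, so they probe estimator correctness, not sampling adequacy.

Problem sizes used by the packaged validation (chosen once as the
package's desk-scale study conditions): $10^6$ Monte-Carlo samples per well
depth for the free-energy loop; 12-point titrations at 60 s (tight binder)
or 20 s (weak binder) per point; ten 20 s replicates for the single-species
model check; $10^4$-bin traces for correlator-oracle equivalence.

## 6. Input formats and interfaces

Trajectories enter as tidy tables (`time_ns`, `particle_id`, `z_nm`; CSV
or TSV via `read_z_table()`) or as multi-model PDB streams via
`read_trajectory()` (bio3d, Ångström→nm). GRO/XTC streams are not read
directly — convert to either supported dialect upstream. Surfaces use the
plain-text three-column grid dump; photon traces use two-column CSV with
`#` metadata headers. Results are tibbles throughout, with `tidy()` and
`glance()` methods on fitted objects, `autoplot()` methods on profiles,
surfaces, correlation curves and isotherm fits, and `heatmap_table()` for
condition-grid exports keyed by peptide and salt concentration (molality
on the simulation side, mol/L on the experiment side; conversions are
never implicit). A thin command-line wrapper over these functions ships in
`inst/cli/pepmem`. Every run can emit its resolved configuration with
`write_run_config()`.

## 7. A worked miniature

```{r example}
pmf <- membrane_pmf(well_depth = 12)
traj <- sample_pmf(pmf, 2e5, seed = 42)
adsorption_free_energy(traj, discard_ns = 0)
analytic_dg(pmf, 3.0)
```

```{r example-plot}
prof <- density_profile(traj, discard_ns = 0)
autoplot(prof, cutoff = find_cutoff(prof))
```
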