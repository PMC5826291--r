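---
title: "Modelling biomimetic nuclear pores: coarse-grained FG-domain brushes, density-based conductance, and selectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling biomimetic nuclear pores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nupore)
```

## The system and the questions

Biomimetic nuclear pore complexes are solid-state nanopores (5-65 nm
diameter, 20 nm membrane thickness) whose inner surface is coated with
intrinsically disordered FG-nucleoporin domains, grafted through a
C-terminal cysteine. Two constructs are built in: the wildtype yeast Nsp1
FG-domain (637-residue purification construct, 65.7 kDa) and its "SG"
mutant Nsp1-S in which the hydrophobic residues F, I, L and V are replaced
by serine. Such pores pose three linked questions that this package's
modules answer computationally:

1. *What spatial structure do the grafted domains adopt inside the pore?*
   (coarse-grained Langevin dynamics; time-averaged density fields)
2. *How does that structure set the ionic conductance?* (a density-based
   local-conductivity relation with access resistance)
3. *Why are wildtype pores selective for transport receptors while the
   mutant pores are not?* (umbrella-sampling free-energy profiles and
   Arrhenius event rates, compared with single-molecule translocation
   statistics)

Because no public deposition accompanies the measurements, the package
ships synthetic-data generators that emulate the two instruments involved
-- a patch-clamp amplifier recording current traces, and the simulation
pipeline producing density fields -- with fully specified statistical
structure, so every analysis stage has a ground-truth recovery test.

## The one-bead-per-amino-acid model

Each residue is one bead centred at its C-alpha position. The energy is

* **Bonds**: stiff harmonic springs, \(r_0 = 0.38\) nm (the C-alpha
  virtual-bond length), \(k_b = 8000\) kJ mol\(^{-1}\) nm\(^{-2}\).
* **Bending/torsion**: the published parameterization derives these terms
  from Ramachandran statistics of coil regions, but the tables themselves
  are not printed in a transcribable form. The shipped default is a
  one-parameter Kratky-Porod bending term,
  \(U = k_{bend}(1 + \cos\theta)\) per bond angle (zero for a straight
  chain), which is the honest calibratable reconstruction: without local
  stiffness a C-alpha chain is far too compact (the freely jointed coil
  Stokes radius of the 172-residue head is ~2.1 nm against the measured
  3.2 nm, a 35% error no cohesion strength can fix). `force_field()` also
  accepts tabulated angle/dihedral potentials (interpolated linearly,
  evaluated by `bonded_energy()`; an angle table replaces the
  Kratky-Porod default) so a published parameterization can be dropped in
  verbatim. Torsion defaults to none.
* **Hydrophobic attraction**: an Ashbaugh-Hatch-type modified
  Lennard-Jones. Below the WCA minimum the potential is the shifted
  repulsive core; beyond it the attraction is scaled by the pair
  hydrophobicity \(\sqrt{\lambda_i\lambda_j}\), so a pair with
  \(\lambda = 0\) is purely repulsive. Per-residue \(\lambda\) values are
  Fauchere-Pliska octanol partition energies renormalized to [0, 1]
  (arginine 0, tryptophan 1) -- a reconstruction of the "normalized
  experimental partition energies" the model family uses; the table is
  config-exposed.
* **Electrostatics**: Debye-screened Coulomb with screening constant
  \(\kappa = 1.27\) nm\(^{-1}\) (150 mM KCl; `debye_constant()` reproduces
  this from first principles) and a Mehler-Solmajer sigmoidal
  distance-dependent dielectric rising to 80 in bulk. D and E carry -1 e,
  K and R +1 e, histidine is neutral at pH 7.4.
* **Cutoffs**: the attraction is switched to zero with a C2 quintic
  switching function over the outer 15% of its 2.5-sigma cutoff;
  electrostatics likewise at 2.5 nm (3.2 Debye lengths; the discarded tail
  is below 0.05 kJ/mol). Energies and analytic forces agree with central
  differences to 1e-5 relative tolerance -- this is a test invariant.

**Calibration.** The model's two free structural parameters -- the
hydrophobic strength \(\varepsilon_0\) and the bending stiffness
\(k_{bend}\) -- were fixed once, jointly, against the two published
single-chain observables the model family itself is calibrated on: the
Stokes radii of the isolated N-terminal head (residues 1-172, measured
3.2 nm) and of the charged stalk (residues 173-603, measured 6.5 nm),
using equilibrated 400,000-step single-chain runs (equilibration was
verified by a late-window plateau check; shorter runs inflate chain
dimensions while collapse is still in progress). The result,
\(k_{bend} = 4\) kJ/mol and \(\varepsilon_0 = 1.25\) kJ/mol, reproduces
the head exactly (Rs = 3.20 nm) and the stalk within 15% (5.52 nm),
inside the model family's stated ~20% accuracy. Neither parameter was
revisited afterwards. The charged/hydrophobic classification behind the composition
ratios uses charged = {D, E, K, R} and hydrophobic = {A, C, F, I, L, M, V,
W, Y}; these sets give 0.91 for Nsp1 against the published 0.9, and 1.73
for Nsp1-S against the published 1.6. No natural set choice reproduces
both printed ratios exactly, and the sets behind the published numbers are
not stated, so the package documents closeness, not equality.

## Pore construction

Pores are cylinders of height 20 nm on the z axis, walls tiled by inert
(purely repulsive, \(\lambda = 0\)) beads of 3 nm diameter on a triangular
shell, centred in a 100 x 100 x 140 nm box by default. Anchors form a
close-packed triangular lattice wrapped on the inner surface at a grafting
distance of 5.7 nm (one chain per 28 nm\(^2\)). Wrapping a triangular
lattice on a cylinder cannot be exact for arbitrary diameter: the number
of circumferential columns is `round(pi d / a)` and of rows
`round(l / (a sqrt(3)/2))`, which preserves the areal density and realizes
the requested spacing within ~5%; `build_anchors()` reports the realized
spacing. For a 48 nm pore this yields 104 sites against the estimate of
~107 from the area count. The top and bottom membrane faces are repulsive
half-spaces outside the pore mouth rather than beads -- chains are free to
spill out axially, as the large-pore simulations show they do.

Chains are grafted C-terminal-bead-first at each site and grown as
non-overlapping random walks biased gently inward, then energy minimized
(adaptive steepest descent with displacement capping) before dynamics.

## Dynamics, units and desk-scale presets

The integrator is BAOAB-split Langevin dynamics, single-threaded and
bit-reproducible for a given seed. Units are nm, kJ/mol, Da and ps-like
reduced time (with these units one time unit is one picosecond of inertial
dynamics; physical diffusion under the implicit solvent is faster than the
nominal mapping, so times are reported as reduced units). The default
timestep 0.01 (0.015 for brush production runs) is ~8x below the stability
bound of the stiffest bond; the friction 0.1-1 ps\(^{-1}\) range trades
thermostat coupling against sampling speed without affecting equilibrium
averages -- the test suite verifies the thermostat (kinetic temperature
within 3%), the Einstein relation for free beads (5%), bond-length
statistics and a noise-free energy-conservation check. Long-range
(hydrophobic + electrostatic) prefactors ramp on linearly over the first
5% of each run, mirroring the gradual switch-on used in the production
protocol; the first 10% (configurable) of steps is discarded, mirroring
the production convention of ignoring the initial tenth of a run.

Full 45-60 nm pores with ~100 full-length chains (60,000+ beads) are
cluster-scale: the headline density maps, the 29.1 nS density-based
conductance of a 45 nm mutant pore, and the 12 / 6 / 6.5 kJ/mol PMF
barriers belong to that regime and are not desk-reproducible. The package
documents them as such and substitutes desk-scale property tests: small
pores (16-22 nm), reduced chain counts and truncated constructs, with
problem sizes stated below.

Umbrella sampling uses the production parameters (1.3 nm window spacing,
spring constant 10 kJ mol\(^{-1}\) nm\(^{-2}\), two starting
configurations per window) with the cargo restrained axially and
laterally, so the reaction coordinate is the central axis. The cargo mass
acts only as a sampling parameter (equilibrium statistics are
mass-independent); light cargos with low friction shorten the position
relaxation time \(\zeta/k\) and are used in tests. WHAM uses 0.1 nm bins
and a 1e-6 kJ/mol convergence tolerance on the window free energies; the
reconstruction is validated against direct Boltzmann sampling of an
analytic quartic potential (<= 0.3 kJ/mol RMS). Barriers are max minus min
of the PMF after fitting sixth-order polynomials to the z < 0 and z > 0
branches separately. The Arrhenius prefactor \(\Gamma_0\) "resembles the
bare-pore event frequency" but is not printed; it is config-exposed and
the validated quantity is the rate *ratio* between barriers, which cancels
it: \(\exp(6/k_BT) \approx 11.2\) at 298 K, matching the published
1.5 Hz / 0.13 Hz receptor-versus-inert contrast.

## Density analysis and the conductance relation

Density fields are accumulated by particle-in-cell counting on (0.5
nm)\(^3\) half-open cells (no kernel smoothing), averaged over frames and
converted with 1 Da/nm\(^3\) = 1.66054 mg/ml. Circumferential averaging
uses the actual cell count per annulus so mass is conserved exactly at
every reduction (grid to (r,z) map to radial profile) -- a test invariant.
The pore window is -10 < z < 10 nm in twenty 1 nm slices; the access
region is 10 < |z| < 40 nm, and shrinking it threefold changes computed
conductances by a bounded amount (the published sensitivity is <= 13%).

Local conductivity falls linearly with protein density,
\(\sigma(\rho) = \sigma_{bare}\max(0, 1 - \rho/\rho_{crit})\) with
defaults \(\sigma_{bare} = 2.2\) nS/nm and \(\rho_{crit} = 85\) mg/ml;
radial integration (trapezoidal on the 0.5 nm grid, exact for the
piecewise-linear test profiles) gives pore and access conductivities, and
the total conductance is the series combination of channel and access
resistance. The access conductivity uses the same radial-integral
construction on the access-window profile -- the published text says only
that "a related expression" is used, so the symmetric choice is a
documented assumption. Sigmoid closed forms are 4-parameter logistics in
diameter bounded by [0, sigma_bare]; the published description says only
"sigmoidal functions". Characteristic in-pore densities are means over the
pore cylinder, another assumption the source leaves open.

## Trace analytics and grafting estimators

Event detection is a two-threshold scheme (entry 5 sigma, exit 2.5 sigma
by default) on a running-median baseline estimated on a decimated copy of
the trace (the baseline varies on the slow 1/f scale, events on the fast
scale, so decimation is principled and fast). Dwell times are
exit-threshold crossing widths; blockades are median event depths over
voltage. Dips closer than the minimum duration merge -- a documented
contract. Log-normal dwell fitting uses the closed-form MLE, cross-checked
in tests against an independent ML fitter, reporting linear-scale mean and
sd to match the "average tau" convention of the experimental analysis.

The grafting estimator converts the conductance drop upon coating into a
protein count via the single-molecule blockade, then area per protein,
triangular spacing and in-pore density; it reproduces all printed values
(107 proteins, 28 nm^2, 5.7 nm, ~320 mg/ml; mutant 105 and 5.9 nm)
exactly, and is pure arithmetic. The Sauerbrey estimator implements both
the multiply-by-overtone convention printed in the source
(\(\Delta m = -C p \Delta f\)) and the standard per-overtone form; with
the printed constant, only the multiply convention combined with a square
lattice approaches the printed 5.6 nm spacing (it gives 5.85 nm), which
the package flags rather than hides: the printed formula and constant are
internally inconsistent under the standard convention.

## Synthetic data: what is and is not emulated

`gen_trace()` produces Axopatch-like traces: Poisson event placement,
log-normal dwells, truncated-Gaussian blockades, trapezoidal dips with
2-sample edges, white noise plus spectrally shaped 1/f noise (exponent
config-exposed; synthesized on a decimated grid since it is low-frequency
by construction). Defaults are tuned to the published bare-pore
transport-receptor statistics (1.7 Hz, tau = 0.29 +/- 0.16 ms, dG = 0.22
+/- 0.07 nS at a 7 nA baseline) with a white-noise floor giving
signal-to-noise ~13, comparable to clearly resolvable recorded spikes.
Not emulated: amplifier Bessel filtering, capacitive transients, or any
physical 1/f mechanism (the generator is phenomenological). Passing
recovery tests therefore demonstrates the analysis pipeline's correctness
on idealized instrument output, not robustness to every artefact of real
recordings.

`gen_density()` realizes three axisymmetric families standing in for the
cluster-scale density maps: uniform (mutant-like), centre-peaked
(wildtype-like) and ring (collapsed-domain-like, with conduction only
through the open central conduit). Generated grids satisfy the
mass-accounting invariants by construction, and the uniform family couples
to the conductance relation in closed form -- used as exact tests.

`gen_test_chain()` produces composition-controlled random sequences for
force-field property tests.

## Desk-scale problem sizes

The test suite and the acceptance script use: single chains of 80-172
residues for observables; 16-22 nm pores with 12-24 truncated chains
(40-120 residues) for brush structure; 9-16 umbrella windows with a light
inert cargo for PMF properties; 20-30 s synthetic traces at 50 kHz over
20 seeds for recovery statistics; and the analytic quartic oracle for
WHAM. These sizes were chosen so each property is measured at several
relaxation times of its slowest mode. The wildtype-versus-mutant structure
contrast compares central mass densities (the experimental unit);
[grafted_pore_density()] also reports bead-number densities, which remove
the ~7% per-residue mass difference introduced by the serine
substitutions, and the desk-scale contrast exceeds that compositional
confound.

## Known limitations

* The bending/torsion tables and the exact hydrophobicity scale of the
  published model family are reconstructions; absolute brush densities
  (and therefore absolute conductances of simulated pores) inherit that
  uncertainty. The conductance relation itself is validated on synthetic
  fields where its inputs are exact.
* Kirkwood's double-sum Stokes radius is a post-hoc estimator;
  hydrodynamic interactions are absent from the dynamics.
* Cargo rotation is off by default (binding spots are homogeneously
  distributed, so translation-only sampling is consistent); cargo-chain
  attraction strength is config-exposed, not calibrated to binding data.
* Desk-scale brush simulations are small and short; they support sign and
  property statements (e.g. denser grafting raises steric barriers), not
  the cluster-scale absolute numbers, which are flagged wherever they
  appear.
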