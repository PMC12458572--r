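# lobehf

Linear-scaling all-electron restricted Hartree–Fock for biomolecular
systems, in R with compiled integral kernels.

The package is aimed at computational chemists and structural
bioinformaticians who want first-principles electronic structure on
systems where conventional quartic-scaling Hartree–Fock is hopeless:
whole peptides and proteins, solvated assemblies, and the molecules
around them. It combines three ingredients:

1. **Gaussian lobe basis functions.** Every basis function is a sum of
   pure s-Gaussians; p orbitals are sign-paired lobes displaced off the
   nucleus instead of Cartesian-prefactor Gaussians. One closed-form
   s-type expression then evaluates every integral; an electron-repulsion
   integral over primitives is

   ```
   (g_a g_b | g_c g_d) = O_ab O_cd √P · ₁F₁(1/2, 3/2, −P d²)
   ```

   with precomputed pair overlaps `O`, reduced exponent
   `P = 1/(1/(α_a+α_b) + 1/(α_c+α_d))` and product-centre distance `d`;
   `₁F₁` reduces to `√π erf(√x)/(2√x)`, evaluated with a six-coefficient
   rational erf approximation saturated at erf argument 4.

2. **Screening.** An orbital pair enters only if the integral of the
   absolute value of its product (its *density relevance*, analytic in
   the lobe representation) exceeds a threshold (default 1e-4); a
   quadruplet only if the distance between pair centres is below a
   Coulomb cut-off with a smooth `1 + 2x³ − 3x²` taper (8→10 Å) and a
   combined-relevance test passes. ERI counts drop by orders of
   magnitude with total energies reproduced to ~1e-4 relative.

3. **Divide and conquer.** Large structures are partitioned into core
   regions (k-means or 3D grid cells) grown by an 8 Å buffer, with
   chemically informed boundary repair: severed double bonds pull both
   partners in, severed single bonds are capped by hydrogen at standard
   X–H lengths. Subsystems are solved independently and their density
   matrices merged (core ownership, averaging where only co-resident).

On top of the solver:

* **RT-TDHF absorption spectra** — a weak Gaussian field pulse, unitary
  exponential-midpoint propagation of the density matrix, and a damped
  Fourier transform of the induced dipole, with the empirical 1.335
  excitation-energy rescaling.
* **Structure assessment** — per-atom energies
  `E_a = (1/Z_a) Σ_{i∈valence(a)} Σ_j P_ij (H_ij + G_ij/2)`,
  Savitzky–Golay smoothed and rescaled onto the pLDDT confidence range
  of predicted models, with a neighbour-count baseline for comparison.

## Worked example

```r
library(lobehf)

## ground state of water with screening disabled
res <- scf_solve(make_molecule("h2o"), screening = no_screening())
print(res)
#> <scf_result> converged after 7 iterations
#>   total energy      -74.952549 Ha (electronic -84.147514 + nuclear 9.194966)
#>   electrons 10 in 7 orbitals; HOMO -0.3862 Ha

## at this size the default screening removes nothing: identical energy
scr <- scf_solve(make_molecule("h2o"))
abs(scr$total_energy - res$total_energy)
#> [1] 0

## absorption spectrum of H2 (2000 steps of 0.25 a.u., damped transform)
h2 <- scf_solve(make_molecule("h2"), screening = no_screening())
trace <- propagate(h2, pulse_params(), propagation_params())
spec <- spectrum_from_dipole(trace, pad = 8L)
print(spectrum_peaks(spec, n = 1))
#>   energy_ev intensity
#> 1  19.06292  123.6228      # = 25.45 eV / 1.335 empirical rescale

## score a predicted-structure fixture against its planted confidence
fx <- make_quality_gradient_peptide(8, disorder_fraction = 0.4, seed = 11)
pep <- scf_solve(fx$structure)
sm <- smooth_energies(atomic_energies(pep)$energies, window = 15)
compare_tracks(sm, fx$quality)
#> <track_comparison> n=64 atoms, Pearson r=-0.29, Spearman rho=-0.138
```

Higher atomic energies mark the disordered tail of the fixture and
anticorrelate with the planted confidence track.  At this desk scale the
anticorrelation is modest: the per-atom energies carry chain-end
environment transients comparable to the disorder signal (the methods
vignette quantifies this and what it implies for protein-scale use).

A command-line front end installs as `exec/lobehf` with subcommands
`scf`, `dnc`, `spectrum`, `score`, `fit-basis` and `fixtures`; every run
writes a log with the configuration echo, screening counters and SCF
trace.

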