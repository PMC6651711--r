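# memperm

Membrane mechanics and water permeability from molecular-simulation
ensembles.

Gel-phase biomimetic bilayers — such as ion-pair-amphiphile (IPA) membranes
with cholesterol — are characterized in simulation studies by a standard
chain of analyses: alkyl-chain ordering, fluctuation-based mechanical
moduli, Helfrich bending energetics, and water permeability through the
inhomogeneous solubility–diffusivity model. `memperm` packages that chain as
tested, reusable R functions for people who run (or re-analyze) bilayer
simulations and want estimator code with parameter-recovery tests instead of
one-off scripts.

## What it computes

**Chain structure**

- deuterium order parameter per carbon, `S_CD = ½⟨3cos²θ − 1⟩` for the C–H
  bond angle θ to the bilayer normal (explicit H, reconstructed united-atom
  H, or the C–C axis approximation);
- gauche-conformer fraction per dihedral position (gauche: |φ| < 120°);
- cavity density `P_cav(z)`: empty-cell fraction of a 0.5 Å grid per slab;
- a gel (S) vs liquid-disordered (Ld) phase call from the thresholds
  plateau |S_CD| > 0.3, gauche < 0.15, with K_A > 700 mN/m and
  χ > 13 k_BT/rad² as corroborating flags.

**Mechanics**

- area compressibility `K_A = k_BT⟨A_mol⟩/(N·var A_mol)`;
- molecular tilt modulus χ by Boltzmann inversion
  `F(α) = −k_BT ln[P(α)/sin α]` and a quadratic fit around its minimum;
- bending modulus K_C from the height-fluctuation spectrum
  `⟨|h(q)|²⟩ = k_BT/(K_C q⁴ + χ_s q²)`;
- Helfrich bending energy `(K_C/2)∫(c₁+c₂)² dA` of truncated-Fourier
  height fields, and bending-energy profiles along a permeation coordinate.

**Permeation (solubility–diffusivity model)**

- `ΔG(z)` by thermodynamic integration of mean constraint forces;
- local diffusivity `D(z) = (RT)²/∫⟨ΔF(t)ΔF(0)⟩dt` from the force
  autocorrelation function;
- partition coefficient `K(z) = exp(−ΔG/k_BT)`, local resistance
  `exp(ΔG/k_BT)/D(z)`, and permeability `P = 1/∫R_local dz`.

A synthetic-membrane generator produces chains, undulating surfaces, area
series and Ornstein–Uhlenbeck constraint-force windows with analytically
known ground truth, so every estimator ships with a recovery test and the
whole pipeline can be exercised end to end without any trajectory data.

## Worked example

```r
library(memperm)

# a gel-like synthetic bilayer: |S_CD| target 0.45, 10% gauche
ch  <- generate_chain_frames(chain_spec(400, 16, order_param_target = 0.45,
                                        gauche_prob = 0.10, seed = 1))
scd <- deuterium_order(ch$frames, ch$topology)
g   <- gauche_fraction(ch$frames, ch$topology)

ka <- area_compressibility(generate_area_series(0.6, 700, N = 64,
                                                n_frames = 10000, seed = 2))
#> KA = 700.5 +/- 10.9 mN/m  (<Amol> = 0.6001 nm^2, N = 64, 10000 frames)

sf <- bending_modulus_spectrum(generate_height_frames(
  surface_spec(25, 25, 16, KC_true = 20, n_frames = 1000, seed = 3)))
#> KC = 19.94 +/- 0.07 kBT; chi_s = 0.00 +/- 0.03 kBT/nm^2 (33 shells < q_cut 4.19, R^2 = 0.999)

classify_phase(scd, g, KA = ka$KA, chi = 13.2)
#> Bilayer phase call: S
#>                 quantity       value threshold comparison points_to
#>            plateau |SCD|   0.4451454      0.30          >         S
#>  plateau gauche fraction   0.1116667      0.15          <         S
#>                KA (mN/m) 700.5495242    700.00          >         S
#>     tilt chi (kBT/rad^2)  13.2000000     13.00          >         S

# permeation: 15 constraint windows every 0.2 nm, 10 replicates each,
# over a 30 kJ/mol Gaussian free-energy barrier
ws <- generate_force_windows(force_spec(
  seq(0, 2.8, 0.2), gaussian_barrier_force(30, 1, 0.4),
  force_variance = 400, correlation_time = 0.5, dt = 0.05,
  n_steps = 10000, n_replicates = 10, seed = 4))
permeation_pipeline(ws)$permeability
#> P = 0.0295 cm/s (R_total = 34 s/cm, bounds [-2.80, 2.80] nm, peak resistance at z = -1.00 nm)
```

The order profile recovers its 0.45 target per carbon, the compressibility
and bending moduli come back at their generator values with honest error
bars, the phase call lands on S (gel) because every indicator clears its
threshold, and the permeability pipeline locates the resistance peak at the
barrier position (|z| = 1 nm). Results are tibbles (or small result objects
with `tidy()`/`glance()` methods and `autoplot()` views), so they drop
straight into dplyr/ggplot2 workflows. `run_pipeline()` drives the same
stages from a YAML config and writes CSV profiles plus a JSON manifest;
`demo_synthetic(seed)` runs every generator–estimator pair and prints a
recovery table.

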