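# claypep

Analysis toolkit for molecular trajectories of amino acids and short
peptides confined in hydrated layered double hydroxide (LDH) interlayers.

Positively charged LDH minerals such as Mg₃Al(OH)₈⁺ can concentrate
deprotonated amino acids from dilute solution, template their arrangement
on the charged surface, and — across repeated wetting–drying cycles —
provide conditions under which peptide bonds can form. Quantifying that
story from molecular-dynamics output requires a chain of specialised
analyses that standard MD tools do not provide in one place. `claypep`
implements them for structural modellers working on mineral–biomolecule
systems:

* **Layer geometry** — DBSCAN assignment of metal atoms to mineral layers,
  global and local (5 × 5 Å sliding-window) *d*-spacing, and layer
  undulation statistics.
* **Adsorption and templating** — per-frame C-terminal (and aspartate
  side-chain) adsorption state at a 2.5 Å surface cutoff, radial
  distribution functions against the Al charge sites, backbone-orientation
  histograms, and counts of "reactive pairs" (adsorbed C- and N-termini
  within 4 Å, a geometric proxy for a bond-forming arrangement).
* **Surface dynamics** — lateral drift velocities of adsorbed species,
  direction histograms with a circular-autocorrelation test for six-fold
  (lattice-templated) diffusion, and post-first-binding residence
  statistics.
* **Hydration energetics** — the per-water hydration energy
  ΔU_H = (⟨U(N)⟩ − ⟨U(0)⟩)/N, classified against the bulk-water reference
  (−33.25 kJ mol⁻¹): interlayers below it are prone to re-swell.
* **Wetting–drying kinetics** — the surface polymerization model
  X₁ + Xₙ → Xₙ₊₁ (all rate constants k = 1), integrated to monomer
  exhaustion per drying phase, with 5 % desorption of every chain and
  monomer repopulation to capacity 100 at each wetting; a stochastic
  (Gillespie) twin validates the deterministic solution.
* **Synthetic trajectory generator** — a bead-level emulation of the
  hydrated interlayer (hexagonal Mg₃Al metal lattice, hydroxyl sheets,
  labelled C/N-terminal and side-chain sites, tunable hydration, two-state
  adsorption kinetics, optional six-fold walk bias, sinusoidal layer
  undulation) so every analysis stage can be exercised against known ground
  truth without external simulation data.

Trajectories are read and written as GRO (nm), multi-model PDB (Å) or XYZ;
atom roles are derived from names through an editable YAML mapping table.

## Worked example

```r
library(claypep)

cfg    <- generator_config(n_layers = 3, nx = 10, ny = 10, hydration = 7, rng_seed = 42)
slab   <- build_ldh_slab(cfg)
frame0 <- populate_interlayer(slab, list(list(residue = "ALA", length = 1, count = 20)))
sim    <- evolve(frame0, 200)

layers <- assign_layers(sim$trajectory, expected = 3)
print(layers)
#> claypep layer assignment: 3 layers, 300 metal atoms, 0 noise
#>   mean z (A): 2.65, 15.25, 27.85

print(d_spacing(layers, sim$trajectory))
#> claypep d-spacing: 12.600 +/- 0.000 A over 2 adjacent pairs (5x5 A windows)

print(undulation(layers, sim$trajectory))
#> claypep undulation: pooled z std 0.3536 A

ads <- adsorption_series(sim$trajectory)
print(adsorption_fraction(sim$trajectory, ads))
#> claypep adsorption: 94.2% backbone (cutoff 2.50 A, 100 equilibrated frames)

print(residence(ads))
#> claypep residence: mean fraction 0.949 (sd 0.051), 0 molecules never adsorbed

vel <- track_velocities(sim$trajectory, ads)
print(vel)
#> claypep diffusion: 3743 steps, mean velocity 9.86 A/ns (sd 9.80)

print(direction_autocorrelation(vel, seed = 1))
#> claypep six-fold test: score -0.0632 (p = 0.964, null 95% band [-0.0682, 0.0724], 3743 steps)

print(run_cycles(20, kinetic_params()))
#> claypep wetting-drying run: 20 cycles (mode 'published', theta = 1)
#>   longest chain >= theta after cycle 20: 12-mer
#>   first cycle reaching theta, by length: 2:1 3:1 4:1 5:1 6:1 7:4 8:7 9:10 10:12 11:15 12:18
```

Reading the output: the three mineral layers sit 12.6 Å apart with a
0.35 Å RMS undulation (the configured 0.5 Å sine amplitude, A/√2). About
94 % of the alanine molecules are adsorbed via their C-terminal
carboxylate, and after a first binding event they stay bound ~95 % of the
time while still drifting laterally at ~10 Å ns⁻¹ with no directional
bias (six-fold score inside the isotropic null band). In the kinetic
model, a single drying phase populates dimers through hexamers at the 1 %
threshold, and a significant 10-mer population first appears at cycle 12.

A thin command-line wrapper ships in `inst/cli/clayped`
(`clayped run --config run.yaml`, `clayped kinetics --cycles 20 --out
ledger.csv`, `clayped energy --hydrated e_N.csv --dry e_0.csv --n-water
100`); `run_pipeline()` is the equivalent R entry point and writes
CSV/JSON reports plus a provenance record.

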