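---
title: "Models and methods behind claypep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind claypep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(claypep)
```

`claypep` analyses trajectories of amino acids and short peptides confined
in hydrated layered double hydroxide (LDH) interlayers and models their
polymerization under wetting--drying cycles. This vignette documents the
models, the parameters that matter, the numerical choices, and what the
synthetic generator does and does not emulate -- the information a user
needs to judge what a passing test suite implies about real simulation
data.

## The physical picture

A brucite-like Mg₃Al(OH)₈ layer carries one positive charge per Al site.
At high pH, amino acids are deprotonated (carboxylate C-terminus) and
exchange into the interlayer, where the C-terminal oxygens hydrogen-bond
to the surface hydroxyls. Adsorbed molecules remain laterally mobile and,
as water is removed, crowd and co-align so that C- and N-termini of
neighbouring molecules approach bonding distance. Repeated
dehydration--rehydration then acts as a ratchet: each dry phase extends
surface-bound chains, each wet phase releases a small fraction of them and
replenishes the monomer pool.

## Layer geometry

**Layer assignment.** Metal atoms are clustered with DBSCAN using
neighbourhood radius `eps = 5` Å on the full 3D distance and
`min_samples = 4` (counting the point itself). The 5 Å linkage is read
literally as "atoms of one layer are at most 5 Å apart"; since the
in-plane metal spacing is ~3 Å and adjacent layers are ≥ 10 Å apart, the
assignment is insensitive to the exact value. `min_samples = 4` keeps thin
layers intact while stray atoms are reported as noise rather than
silently dropped. Clusters are ordered by mean *z*; layers with equal mean
*z* (within 10⁻⁹ Å) are rejected as degenerate input.

**d-spacing.** For every pair of *z*-adjacent layers, a 5 × 5 Å window
slides over the xy plane in 1 Å steps; the local d-spacing is the
difference of the mean metal *z* inside the window in the two layers.
Windows wrap across the periodic box edges by default (the simulated
system is periodic); a non-periodic mode restricts to fully interior
windows. Windows where either layer has no atoms are `NA` and excluded.
The global mean/sd pools all local values; the plain difference of layer
mean-*z* values is reported alongside and coincides with the map mean for
flat layers (a closed form the tests assert).

**Undulation.** Every layer is centred on its per-frame mean *z*, metal
deviations are pooled across frames, and the standard deviation is
reported per layer and overall. A static sinusoid of amplitude *A* gives a
pooled sd of *A*/√2, which the tests recover within 2%.

## Adsorption and templating

**Adsorption state.** A site is adsorbed when either oxygen of its
carboxylate pair (OT1/OT2 for the C-terminus, OD1/OD2 for an aspartate
side chain) lies within `cutoff = 2.5` Å -- the first hydration layer of
the LDH surface -- of a surface atom. "Surface" defaults to the hydroxyl
O *and* H atoms, switchable to either subset, because the underlying
hydrogen-bond criterion does not name the partner atom. Distances use the
minimum image in the periodic xy plane; the slab is treated as open along
*z*. Percentage summaries average over the final half of the frames (the
equilibrated tail; configurable), and side-chain percentages are computed
per site so that di- and hexa-peptides, with 2 and 6 side chains per
C-terminus, are scaled accordingly.

**RDF.** Standard pair-distribution normalisation against the ideal-gas
density of the partner role, with 0.1 Å bins (resolving first-shell
structure at 2--3 Å) and `r_max` validated against half the smallest box
edge. A `lateral = TRUE` mode measures xy-projected distances with area
normalisation -- the natural coordinate for surface templating, where
adsorbed C-termini seated on Al columns reproduce the Al--Al lattice peak
positions regardless of their height above the metal plane.

**Orientation.** The C→N vector of the terminal residue is reduced to its
elevation Θ ∈ [0°, 90°] (0° perpendicular to the surface plane, 90°
parallel; up/down folded), binned at 1°. Angles are rounded at 10⁻⁶ degree
before binning so that exact geometries (45°, 90°) land in their own bin.
Zero-length vectors are skipped with a warning.

**Reactive pairs.** A pair is an adsorbed C-terminus and the N-terminus of
a different molecule that is itself adsorbed (via any site), closer than
4 Å (strict). Candidates are matched greedily in order of increasing
distance with each terminus used at most once, so the count never exceeds
the number of termini available -- a plain double-loop count of close
contacts can. For aspartate, an adsorbed side-chain carboxylate is an
additional donor; such pairs are tallied as β (versus α for the backbone)
and the report sums both. Pairings within one molecule are excluded: at
monomer scale only the intramolecular closure can produce the cyclic
geometry that must not be counted.

## Surface dynamics

**Velocities.** For a molecule adsorbed in two consecutive frames, the
minimum-image xy displacement of its C-terminal carbon over the frame
interval gives a drift velocity in Å ns⁻¹ -- a finite-difference drift,
not a fitted diffusion coefficient, matching how interlayer mobilities are
conventionally reported. Directions are polar angles in [0°, 360°),
rounded at 10⁻⁶ degree so lattice-aligned steps fall in exact bins.

**Six-fold test.** The direction histogram (1° bins) is mean-subtracted
and circularly autocorrelated (FFT, normalised to 1 at lag 0). Diffusion
templated by the hexagonal metal lattice produces peaks at multiples of
60°. The score is the mean autocorrelation at the *uniquely hexagonal*
lags {60°, 120°, 240°, 300°} minus the mean over off-peak lags; lag 180°
is deliberately not scored and 90°/180°/270° are excluded from the
baseline, because any centrosymmetric step distribution -- including a
four-fold lattice walk -- peaks at 180°, and a test that scores it would
mistake square-lattice templating for hexagonal. With this definition a
four-fold control scores ≈ 0 while six-fold walks score strongly positive.
Significance comes from an isotropy randomization test: 1000 seeded
resamples of the same number of uniform directions. (Permuting the
*observed* directions would leave their histogram -- and hence the score
-- unchanged, so a permutation null is vacuous here; the uniform-resample
null is the operative randomization.) The null's central 95% band is
reported alongside the one-sided p-value.

**Residence.** Per molecule, the fraction of frames adsorbed from its
first adsorption event onward; molecules never adsorbed are excluded and
counted separately. An always-adsorbed molecule scores exactly 1.

## Hydration energetics

The per-water hydration energy is
ΔU_H = (⟨U(N)⟩ − ⟨U(0)⟩)/N,
with ⟨U⟩ the mean potential energy of the equilibrated hydrated and dry
systems. If ΔU_H lies strictly below the bulk-water reference
(−33.25 kJ mol⁻¹ by default, configurable) the interlayer is classified as
prone to rehydrate; the boundary itself classifies as *not* rehydrating
("if lower" is read as a strict inequality). Uncertainty is propagated
from block-averaged standard errors (5 blocks) of the two series, a
conventional guard against serial correlation in MD energy traces.

## Wetting--drying kinetics

During a drying phase, adsorbed monomers extend adsorbed chains,
X₁ + Xₙ → Xₙ₊₁, all with rate constant k = 1. The chain equations are

d[Xₙ]/dt = k[X₁]([Xₙ₋₁] − [Xₙ]),  n ≥ 2.

Two monomer balances are implemented:

* `mode = "published"` (default): d[X₁]/dt = −k[X₁] Σₙ≥₂[Xₙ]. The monomer
  loss counts only chain extension; total monomer-unit mass grows during a
  phase. In rescaled time τ (dτ = [X₁]dt) this mode obeys
  X₁² + S² = const (S = Σₙ≥₂Xₙ), so a pure-monomer start converges with
  exactly `capacity` chains on the surface -- a closed form the tests
  assert, along with X₂ = 50(1 − e^(−π/2)) at exhaustion.
* `mode = "conserving"`: d[X₁]/dt = −k[X₁](2[X₁] + Σₙ≥₂[Xₙ]). The factor-2
  dimerization loss makes Σ n[Xₙ] exactly conserved -- the closed-surface
  mass balance. Its cycle-1 closed form is Xₙ = C e⁻¹(n−1)/n!, and it is
  the variant whose ensemble mean the stochastic twin reproduces.

The published form is the default because it is the variant that
reproduces the model's reported outcomes: after a single drying phase the
longest chain at the 1%-of-capacity threshold is the hexamer (the
conserving form stops at the pentamer, X₆ = 100e⁻¹·5/720 ≈ 0.26), and a
significant 10-mer population first appears after strictly more than 10
cycles (cycle 12; the conserving form reaches it at cycle 10). The
conserving form remains available and is used for the mass-conservation
and Gillespie-equivalence checks, which are statements about the
closed-surface system.

**Integration.** The hierarchy is truncated at `n_max = 64` chains with
the mass at the boundary monitored (warning above 10⁻⁹ of capacity);
`deSolve::lsodar` integrates with rtol 10⁻⁹/atol 10⁻¹² and a root-stop at
[X₁] < 10⁻⁶, the practical reading of "reactions stop when [X₁] = 0",
which an ODE only reaches asymptotically. Tiny negative tail values from
the integrator are clamped to zero.

**Wetting.** Each wetting releases `desorb_fraction = 0.05` of every chain
of length ≥ 2 into a cumulative ledger and tops the monomer pool back up
to `capacity = 100` from the infinite solution bath. Desorption applies
only to chains: released monomers would be indistinguishable from the
repopulation and are therefore exchanged implicitly. The ledger balance
(surface mass + released mass = total input) is exact in conserving mode
and unit-tested.

**Significance threshold.** "Observed" chain lengths are those with
converged concentration ≥ θ = 1% of capacity. θ is a reporting threshold,
exposed as a parameter, and the first-reach cycle of every length is
returned so conclusions can be re-read under any other θ.

**Stochastic twin.** `gillespie_dehydration()` simulates the discrete
reaction set exactly, with dimerization propensity k·X₁(X₁−1) (ordered
pairs, matching the conserving ODE's factor-2 convention) and extension
propensities k·X₁·Xₙ. The acceptance test compares the conserving ODE
against the mean of 1000 seeded runs within 3 Monte-Carlo standard errors
per length, floored at 10⁻³ -- one event in one run -- which is the
resolution of a 1000-run ensemble mean.

## The synthetic generator: what it emulates, and what it does not

The generator produces the study conditions every analysis is tested
against:

| parameter | default | rationale |
|---|---|---|
| `n_layers` | 5 | reference slab of five mineral layers |
| `layer_thickness` | 5.3 Å | hydroxyl-to-hydroxyl extent of an LDH layer |
| `interlayer_gap` | 7.3 Å | d-spacing 12.6 Å, hydrated-regime value; leaves a ≥ 3 Å desorbed zone clear of both surfaces at the 2.5 Å cutoff |
| `lattice_a` | 3.05 Å | metal--metal spacing of an Mg₃Al hydroxide sheet |
| `mg_al_ratio` | 3 (fixed) | Mg₃Al stoichiometry; Al dispersed on a periodic sublattice with exactly 1 Al per 3 Mg |
| `hydration` | 20 W/AA | top of the dehydration ladder 20/15/10/7/5/3/2/0 |
| `residence_fraction` | 0.95 | adsorbed species desorb ~5% of the time after first binding |
| `switch_rate` | 0.2 frame⁻¹ | Markov relaxation; mean adsorbed bout 100 frames at the default fraction |
| `step_scale`, `dt` | 1 Å, 0.1 ns | ~10 Å ns⁻¹ lateral drift, the hydrated-regime order of magnitude |
| `hex_bias` | 0 | fraction of steps forced onto the six lattice directions |
| `undulation_amplitude` | 0.5 Å | gentle correlated undulation (equal phases, constant local gap) |
| `energy_profile` | −450 − 40·N kJ/mol | monotone in hydration; ΔU_H = −40 < −33.25, i.e. a re-swelling interlayer |

Adsorption is generated as a two-state Markov chain whose stationary
adsorbed fraction equals `residence_fraction`; the geometry is constructed
so that the chain's state is *exactly* recoverable by the 2.5 Å distance
analysis (adsorbed carboxylates sit 1.5 Å above the hydroxyl sheet,
desorbed ones 3 Å away), which the tests assert bit-for-bit. Waters per
amino acid are counted per residue by default; a per-anion normalisation
(molecules + counterions) is available for charge-diluted mixtures, since
usage varies. Counterion numbers default to charge balance against the Al
count with side-chain charges taken at pH 9.5 (Asp −1, Lys +1, others 0,
C-terminus −1).

The generator is a *statistical* emulation, not physics. Known departures
from real trajectories, hence limits on what passing tests demonstrate:
beads instead of full residues (only the sites the analyses consult
exist); water and counterions are static; no excluded volume or
electrostatics; adsorption kinetics are memoryless, whereas real residence
times are heavy-tailed; layer undulation is a static sinusoid rather than
thermal roughening; generated aspartates never adsorb via their side chain
(side-chain geometry is exercised with hand-built fixtures instead); and
energy series are i.i.d. Gaussian around the profile, so the block-error
machinery is exercised but not stressed by real autocorrelation. Analyses
validated here on known ground truth still need the usual convergence
checks when applied to real MD output.

## Problem sizes and runtime

The test suite runs entirely on synthetic data built at run time: slabs of
4--20 lattice cells per side, 2--100 molecules, trajectories of 2--1000
frames; the largest case (residence recovery, 100 molecules × 1000 frames)
and the 1000-run Gillespie ensemble each complete in well under a minute
on one CPU, and the whole suite in about half a minute. These sizes give
every statistical check comfortable margins (binomial/Monte-Carlo errors
well inside the asserted tolerances) while staying desk-scale.

## Degenerate inputs and error behaviour

Frames without metal atoms, trajectories without surface hydroxyls or
C-termini, d-spacing on fewer than two layers, `r_max` beyond half the box,
empty energy series, a hydrated series with N = 0, and over-packed
interlayers all raise typed errors naming the problem. Molecules lacking
C-terminal oxygens are skipped with a warning; single-frame trajectories
yield an empty velocity table with a warning; an empty direction histogram
yields an explicit all-NA six-fold result rather than a score.
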