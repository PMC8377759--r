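# fdpb — finite-difference Poisson–Boltzmann electrostatics for protein–DNA systems

How does a DNA-repair enzyme find and hold the one damaged base it must
excise? For uracil–DNA glycosylase and its kin, much of the answer is
electrostatic: the enzyme's binding face is positively ringed, the duplex
is uniformly negative, and the flipped-out target base sits in a pocket
whose lone charged residue is *negative*. `fdpb` packages the
continuum-electrostatics workflow used to dissect exactly this kind of
recognition problem — for structural bioinformaticians who want the whole
chain, from charged structure to force curve, reproducible and testable on
one desk-scale machine.

The core is a finite-difference solver for the Poisson–Boltzmann equation

∇·[ε(r)∇φ(r)] = −4πρ(r) + ε_s κ²(r) sinh(φ(r)),

linearized by default, on a regular grid (edge-based dielectric map from
probe-inflated atom spheres, Stern ion-exclusion layer, Debye–Hückel
boundary conditions, SOR iteration; potentials in kT/e). Around it:

* **structures** — whitespace-dialect PQR read/write, PDB coordinates,
  charge templates, residue mutation by template swap, selections, mass
  centers, rigid translations;
* **fields** — trilinear potential/field sampling, per-atom surface
  potentials, RK4 electric-field-line tracing with gradient and
  arc-length filters;
* **forces** — qE net force of a source molecule on a probe group and the
  mass-center separation scan (default 20–40 Å in 4 Å steps) with
  attractive/repulsive classification;
* **titration** — Henderson–Hasselbalch site charges, net-charge curves
  Q(pH), and the Tanford–Wyman relative folding energy
  ΔG(pH) = ln(10)·R·T·∫₀^pH (Q_f − Q_u) d(pH), referenced to 0 kcal/mol
  at pH 0, with stability-plateau detection;
* **synthetic** — deterministic generators for a net-negative double
  helix with a −1 e flipped-out base, a polar enzyme with a positively
  ringed pocket face, their docked complex, and titratable-site sets;
* **pipeline** — `run_scenario()` plus a YAML config and JSON manifest,
  and a thin CLI at `inst/scripts/fdpb.R`.

## Worked example

Two unit charges 10 Å apart in uniform water dielectric — the case with a
pencil-and-paper answer:

```r
library(fdpb)
dimer <- make_dimer(1, -1, 10)
cfg <- pbe_config(spacing = 1, eps_in = 80, eps_out = 80,
                  salt = 0, stern = 0, probe_radius = 0, padding = 12)
fr <- force_on_group(select_group(dimer, "source"),
                     select_group(dimer, "probe"), cfg)
fr
#> force_record: |F| 0.07088 kT/A, axial -0.07088 (attractive)
```

Coulomb's law gives C/(80·10²) = 0.0696 kT/Å with C ≈ 557 kT·Å/e², so the
grid solution is within 2%. The same machinery on the synthetic
enzyme–DNA complex reproduces the recognition pattern the package was
built to probe: scanning the whole enzyme against the DNA gives
`attractive` at all six distances with monotonically decaying magnitude,
while the extracted pocket site against the −1 e flipped base gives
`repulsive` throughout.

pH stability, from a titratable-site set whose folded-state pKa shifts
put the protein's comfort zone in the mid-range:

```r
sites <- make_titration_set(6, 6, "udg_like")
fe <- folding_energy_curve(sites)
stability_range(fe, tolerance = 0.5)
#>  pH_low pH_high
#>       5      10
```

The curve is 0 kcal/mol at pH 0 by construction, falls to its minimum,
stays flat across pH 5–10, and climbs again — lower ΔG meaning higher
stability at that pH. A single acid whose pKa shifts from 4 (unfolded) to
6 (folded) ends at ΔG(14) = 2.745 kcal/mol, matching the closed form
ln(10)·R·T·ΔpKa within the trapezoid error.

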