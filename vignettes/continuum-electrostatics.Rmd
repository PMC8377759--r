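---
title: "Continuum electrostatics of enzyme-DNA recognition with fdpb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuum electrostatics of enzyme-DNA recognition with fdpb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdpb)
```

## The physical model

`fdpb` implements the continuum (implicit-solvent) picture of biomolecular
electrostatics. A solute -- here a base-excision enzyme, a DNA duplex, or
their complex -- is a low-dielectric body carrying fixed partial charges,
embedded in a high-dielectric salt solution. The electrostatic potential
$\phi(\mathbf r)$ obeys the Poisson-Boltzmann equation

$$\nabla \cdot [\epsilon(\mathbf r)\nabla\phi(\mathbf r)]
  = -4\pi\rho(\mathbf r)
  + \epsilon_s\,\kappa^2(\mathbf r)\,\sinh\!\big(\phi(\mathbf r)\big),$$

with $\epsilon(\mathbf r)$ the dielectric map, $\rho$ the fixed charge
density, and $\kappa$ the inverse Debye screening length, which vanishes
inside the solute and in a thin ion-exclusion (Stern) shell around it. The
package works in the field's customary reduced units: lengths in
angstroms, charges in elementary charges, potentials in $kT/e$, energies
in kcal/mol. The electrostatic coupling constant
($\approx 557\;kT\cdot\mathrm{\AA}/e^2$ at 300 K) is derived at run time
from CODATA constants and $R = 1.9872\times10^{-3}$ kcal/(mol K), never
hard-coded.

The **linearized** equation ($\sinh\phi \to \phi$) is the default solver
mode. The analyses this package supports -- surface-potential polarity,
field-line topology, force directions and decay -- rest on potentials of a
few $kT/e$ at and beyond contact distances, where linearization is
accurate, and the linear form admits the closed-form Coulomb/Yukawa
oracles that the test suite exploits. The full $\sinh$ form is available
as `mode = "nonlinear"` (under-relaxed Picard iteration on the
$\sinh$ remainder, relaxation factor 0.5); the suite checks that it damps
high potentials and converges to the linear solution as charges shrink.

## Discretization choices

* **Grid.** Regular cubic lattice, default spacing 0.5 A (2 grid points
  per angstrom), built around the solute with >= 5 A padding (default
  10 A) and odd dimensions so a center node exists.
* **Dielectric map.** Assigned on grid *edges*: an edge midpoint inside
  any probe-inflated atom sphere (radius + 1.4 A probe) takes the solute
  value (2.0), otherwise the solvent value (80.0). This is a
  van-der-Waals-union approximation of the molecular surface; reentrant
  (probe-rolled) surface patches are not modelled. Using edge-centred
  values is equivalent to a harmonic-mean treatment of the dielectric
  jump in the 7-point stencil.
* **Ion map.** $\kappa^2$ lives on nodes: the bulk Debye-Hueckel value
  (0.15 M 1:1 salt gives $1/\kappa \approx 7.95$ A at 300 K) outside, zero
  inside atom spheres inflated by the 2.0 A Stern layer. The Stern
  thickness is standard continuum practice; results at >= 20 A
  separations are insensitive to it.
* **Charge assignment.** Partial charges are spread to nodes with the
  quadratic B-spline (triangular-shaped cloud, 27 nodes) scheme.
  Measured against the point-charge Coulomb oracle on the package's
  65^3 validation grid, TSC roughly halves the near-source
  lattice-anisotropy error relative to trilinear assignment (max error
  over all nodes with $3 \le r \le 10$ A: 3.2% vs 3.8% unsalted, 4.6% vs
  5.4% at 0.15 M). Trilinear remains available as `spreading = "cic"`.
  Self-energy at source nodes is grid-dependent and meaningless; all
  validation therefore measures potentials at $r \ge 3$ A from sources.
* **Boundary conditions.** Default is the per-atom Debye-Hueckel sum on
  the six faces; a dipole-level condition (solute monopole + dipole about
  the mean atom position, screened) and a zero condition are provided.
  For compact solutes the per-atom and dipolar faces agree to a few
  percent at 20+ A, which the suite checks.
* **Solver.** Gauss-Seidel successive over-relaxation with
  $\omega = 2/(1+\sin(\pi/N))$, $N$ the largest grid dimension.
  Convergence is declared when the largest per-sweep change falls below
  `tol` (default $10^{-8}$) times the largest potential magnitude; the
  tight default costs little (SOR at this $\omega$ gains roughly a decade
  of residual per $0.4N$ sweeps) and keeps far-field forces, which can be
  orders of magnitude below the near-field potentials, above the
  iteration noise floor. Non-convergence raises a typed error carrying
  the residual history.

## Forces and the separation scan

The force a source molecule exerts on a probe group is evaluated in the
$qE$ approximation: the equation is solved with the *source charges only*
(by default the probe's cavity is removed too, i.e. the source sits in
pure solvent; `keep_cavity = TRUE` retains the uncharged cavity), and
$\mathbf F = \sum_i q_i \mathbf E(\mathbf r_i)$ is accumulated over probe
atoms with the central-difference field. Dielectric-boundary and ionic
pressure terms are omitted -- at the >= 20 A separations scanned here the
$qE$ term dominates, which is why the dimer fixture reproduces Coulomb's
law within a few percent and scans recover an inverse-square exponent.

The scan protocol displaces the probe rigidly along the unit vector
joining the two mass centers (mass-weighted, element inferred from the
leading letter of the atom name with a 12.0 fallback; a geometric-center
flag exists because the convention is not universal). Scan distances
(default 20-40 A in 4 A steps) are *added displacement from the bound
pose*, not absolute center separations -- the bound pose is distance 0.
A force record is attractive when its projection on that axis points from
the probe back toward the source, with a $10^{-9}$ dead zone mapped to
`"none"`. Pocket-only calculations extract the pocket residues as an
isolated charged group; the alternative (pocket charges in situ in the
otherwise-uncharged enzyme cavity) is reachable via `keep_cavity`.

## Field lines and surface potentials

Field lines are streamlines of $\mathbf E = -\nabla\phi$, integrated with
fixed-step RK4 (0.25 A) on the normalized field, seeded from dots on
probe-inflated atom spheres and kept only where the local gradient
magnitude reaches the filter threshold (default 3.64 $kT/(e\,\mathrm A)$)
and the arc length lies in [4.12, 35.31] A. Those filter numbers are the
display conventions of the rendering tools this workflow descends from;
their units are taken as angstroms in grid coordinates and all four are
configurable. Tracing stops on grid exit, field collapse
($|\mathbf E| < 10^{-6}$), step or length caps, or *stagnation* -- the
normalized-step integrator oscillating across a point sink -- and the
termination reason is recorded per line. Surface potentials are sampled
on deterministic Fibonacci-lattice dots over each atom's probe-inflated
sphere; per-atom means plus a structure summary (mean, fraction positive)
support the face-polarity comparisons.

## pH titration and relative folding energy

Each titratable site carries a sign $y$ (-1 acid, +1 base) and two pKas
(folded, unfolded). The default site charge is the Henderson-Hasselbalch
form

$$q(\mathrm{pH}) = y\,
  \frac{10^{\,y(\mathrm{pK_a}-\mathrm{pH})}}
       {1+10^{\,y(\mathrm{pK_a}-\mathrm{pH})}},$$

i.e. sign times charged fraction: an acid is $-0.5\,e$ at its pKa. A
literal variant occasionally seen in print -- the thermodynamic conversion
factor 2.3 retained *inside* the base-10 exponent, with unsigned per-site
terms -- contradicts the stated sign convention (acids would contribute
positive charge) and doubles the titration steepness; it is deliberately
kept available as `form = "as-printed"` rather than silently corrected,
so both conventions can be compared. All curve-level machinery uses the
standard form by default.

The relative folding energy is the Tanford-Wyman integral

$$\Delta G(\mathrm{pH}) = \ln(10)\,R\,T
  \int_0^{\mathrm{pH}} \big[Q_f(u) - Q_u(u)\big]\,du,$$

evaluated by the trapezoidal rule on the pH grid (default 0-14, step
0.5), referenced to 0 kcal/mol at pH 0; $\ln 10 = 2.303$ is used for the
conversion factor. The grid must start at 0 or the reference is
undefined and the call errors. Halving the step changes the endpoint by
under 1% on random site sets. `stability_range()` reports the widest
contiguous grid interval within `tolerance` (default 0.5 kcal/mol) of the
curve minimum, ties broken toward the wider then lower-pH interval.
Unfolded pKas default to a packaged model-compound table; *computing*
folded pKas from structure is explicitly out of scope -- they are inputs.

## What the synthetic fixtures emulate

The generators produce the electrostatic skeleton of an enzyme-DNA
recognition system, not its chemistry:

* `make_helix()` -- two antiparallel strands of pseudo-nucleotides, one
  $-1\,e$ phosphate each (net $-1\,e$ per residue, like B-DNA at the
  continuum level), with one residue's base atoms flung radially outward
  as the flipped-out target base; that residue is net $-1\,e$ and has a
  same-net-charge cytosine-like template swap available.
* `make_polar_enzyme()` -- a neutral spherical shell with one recessed
  $-1\,e$ pocket site ringed by positive sites on the binding face and
  negative sites on the back face: a polar charge distribution whose
  interface is net positive (+7 e by default) while the back face is net
  negative, and whose whole body is net positive (+3 e) so the negative
  duplex is attracted at long range.
* `make_complex()` -- the helix docked with its flipped base aimed at the
  pocket center at a prescribed closest approach (default 3 A).
* `make_titration_set()` -- sites whose folded-state pKa shifts (acids
  with model pKa <= 5 down 2.5 units, bases >= 10 up 2.5) produce a
  folding-energy curve that falls at acidic pH, stays flat over the
  mid-range, and rises at basic pH.

All randomness (shell jitter, random pKa profiles) comes from an explicit
MINSTD Lehmer generator keyed by an integer seed recorded in provenance,
so every fixture is a pure function of its parameters -- the global R RNG
is never touched and outputs are byte-reproducible.

What passing on these fixtures does *not* show: nothing here validates
force-field-quality charges, base-pairing geometry, reentrant molecular
surfaces, conformational response, or non-electrostatic terms (van der
Waals, hydrogen bonds, salt bridges are all outside the model). The
fixtures establish that the machinery -- solver, field analysis, scans,
titration -- is numerically correct and reproduces the qualitative
pattern it was built to probe: a positively ringed binding face attracts
a negative duplex while the lone negative pocket site repels the negative
flipped base, with magnitudes decaying monotonically over a 20-40 A scan.

## Problem sizes used by the packaged analyses

The validation suite and the pipeline's synthetic scenarios run at sizes
chosen to make every check cheap on a single core while keeping the
oracle comparisons meaningful: a 65^3 node grid at 1.0 A spacing for the
point-charge solver oracles; a 6-residue helix, a 60-atom enzyme shell
and 1.0 A grids for the end-to-end scenarios (generated structures are
guaranteed to fit a 96^3 grid at 1.0 A with 10 A padding); the default
0.5 A production spacing is retained in the default configuration. The
pipeline writes PQR, OpenDX and CSV plus a JSON manifest (inputs, config
and its hash, seed, per-stage outputs) sufficient to re-run any stage.

## Known limitations

Single-grid SOR only (no multigrid, no focusing runs); vdW-union surface
rather than a molecular (reentrant) surface; $qE$ forces without
boundary-pressure terms; relative (not absolute) folding energies; no
pKa prediction, hydrogen building or geometry optimization -- structure
preparation tools own those steps. These bounds are deliberate: within
them every quantity the package reports is covered by an analytic oracle,
a brute-force check, or a construction-known ground truth in the test
suite.
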