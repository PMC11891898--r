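---
title: "Surface-assembled diffusion coefficients: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-assembled diffusion coefficients: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ride)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, how the shipped
hydrodiffusivity scales were generated, what the synthetic-data generators
do and do not emulate, and the numerical choices behind the surface-area
engine and the dynamics toolkit.

## The model

An infinitely dilute solute in a solvent with smooth flow diffuses
according to the Stokes–Einstein relation
$D = k_\mathrm{B} T / (6 \pi \eta R_\mathrm{H})$.
The hydrodynamic radius $R_\mathrm{H}$ of a biomolecule is not its
geometric radius: tightly bound water, ion–dipole interactions and
hydrogen bonding at the surface all add effective drag. The central premise
here is that this drag can be decomposed additively over the solvent-exposed
surface, with a per-residue-type proportionality between exposed area and
squared-radius contribution:

$$R_\mathrm{H,total}^2 = C_\mathrm{term}\,\mathrm{SESA}_\mathrm{term}
 + \sum_{i \in \mathrm{AA}} C_i\,\mathrm{SESA}_i .$$

The working surface is the *solvent-excluded* surface (SES): the boundary
traced by the inward face of a 0.15 nm probe sphere rolling over the van
der Waals envelope, which is the surface the first solvation shell actually
touches. $\mathrm{SESA}_i$ accumulates the SES area of every atom belonging
to residues of type $i$; the assumption of transferability — that a surface
patch of, say, aspartate drags the same way on any protein — is what makes
the scale a scale.

Assumptions worth keeping in view: the solute is treated as rigid (one
conformer in, one prediction out; no ensemble averaging), the flow regime
is laminar Stokes drag, and shape enters only through its effect on exposed
area, not through the anisotropic mobility tensor. Strong specific effects
— ion pairing with charged side chains, for instance — are outside the
model; salt enters purely as a viscosity perturbation.

## Deriving the coefficients

Each coefficient is the excess squared Stokes radius of a capped amino acid
over the N-methylacetamide (NMA) backbone mimic, per unit of excess
surface:

$$C_\mathrm{solute} = \frac{R_\mathrm{H,capped}^2 - R_\mathrm{H,NMA}^2}
 {\mathrm{SESA}_\mathrm{solute}}.$$

The Stokes radii come from simulation diffusion coefficients shipped with
the package (310.15 K, TIP3P water, viscosity 0.275 mPa s); the areas come
from the package's own fixture structures and SES engine. Two scales are
shipped:

* **M** — derived from capped single amino acids in an extended
  (φ = ψ = 180°) conformation;
* **D** — derived from capped homo-decapeptides in an ideal α-helix
  (φ = −57°, ψ = −47°; polyproline-II geometry, φ = −75°/ψ = 145°, for
  proline, whose decapeptide is dominated by that helix). Folding compact
  secondary structure into the derivation hides backbone amides from the
  solvent, which lowers the coefficients and systematically speeds up the
  predictions relative to variant M.

**The denominator choice.** A capped alanine contains exactly the five
heavy atoms of NMA split across its two caps, so two readings of
"excess surface" exist: the capped total minus the area of an *isolated*
NMA molecule, or the capped total minus the area the *cap atoms actually
retain* in the capped structure. The two differ by a few hundredths of a
nm² because the flanking residue buries part of the caps. The package uses
the second (the residue-owned area). The reason is structural: in the
assembly formula the cap/terminus surface is represented by the constant
term $C_\mathrm{term}\mathrm{SESA}_\mathrm{term}$, so if the coefficient is
normalized by the residue-owned area, assembling the derivation structure's
own per-type areas returns the input diffusion coefficient *exactly* — the
scale is self-consistent by construction, and the package's round-trip
tests pin this at machine precision. With the isolated-NMA denominator the
round trip would drift by a few percent per residue type, an error with no
compensating benefit. The derived anchor values are
`r round(ride_scale("M")$coefficients[["ALA"]], 4)` for monopeptide ALA and
`r round(ride_scale("D")$coefficients[["ALA"]], 4)` for decapeptide ALA.

For zwitterionic backbones the terminus coefficient is the mean of the ASP
and LYS coefficients — the two pH-7 formal-charge archetypes, standing in
for the charged NH₃⁺/COO⁻ pair — while $\mathrm{SESA}_\mathrm{term}$
deliberately remains the NMA reference area in both modes, so that the
terminus term is a single constant anchored on one well-defined molecule.

Terminal residues contribute to the per-type sum like any other residue;
the terminus term is purely additive. A single orphan cap (ACE without NME
or vice versa) is treated as zwitterionic with a warning rather than
guessed at.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `probe_radius` | 0.15 | nm | solvent probe defining the SES; all shipped coefficients use it |
| `n_points` | 400 | — | lattice points per probe-expanded atom sphere; probe spheres get `n_points`/4 |
| radius set | Bondi | nm | explicit-atom van der Waals radii (C 0.170, N 0.155, O 0.152, S 0.180) |
| salt slope | 0.095 | (mol/L)⁻¹ | linear NaCl relative-viscosity law, valid to ~1 M |
| MSD window | 30–500 / 30–3000 | ps | small-solute / protein fit windows |
| `alpha` | caller-supplied | — | finite-size correction factor; never guessed (0.86 is the decapeptide average, for reference) |

The radius file behind the original MSMS-derived coefficients is not on
record, so the Bondi set is the shipped default and every scale file
records the radius-set name it was derived with; a scale must be used with
the radius set named in its header. Whether the original derivation
included hydrogens is likewise unrecorded; the fixtures here are heavy-atom
structures, which is one reason re-derived coefficients sit within ~10–15%
of the two published anchor values rather than on top of them. Viscosity
interpolation in the temperature tables is piecewise linear: the tabulated
trend is nearly flat over 5 K steps and a spline would add wiggle, not
information.

## The SES engine

No analytic SES is attempted. The engine samples deterministically
(golden-spiral Fibonacci lattices — no RNG, so repeated runs are
bit-identical) and treats the SES as the inner boundary of the union of all
allowed probe spheres:

1. **Contact patches.** For each atom, probe centers are sampled on its
   probe-expanded sphere; a center is accessible if it overlaps no other
   expanded sphere. The accessible direction fraction times $4\pi r^2$ is
   the contact area — exact for an isolated sphere at any resolution.
2. **Reentrant patches.** Every accessible probe sphere is itself sampled;
   a point survives if no other accessible probe ball covers it (a spatial
   hash over cells of one probe diameter prunes the candidates), and is
   kept if it faces the molecule (lies inside some expanded sphere). Points
   that merely duplicate a contact patch — within a scallop-height
   tolerance of a van der Waals sphere along an accessible radial direction
   — are dropped. Surviving points carry equal area weights and are
   attributed to the nearest atom by surface gap.

The discrete union converges to the rolling-probe surface as the sampling
densifies; *self-convergence under resolution quadrupling* is the
correctness criterion (tested at ±2% on fused-sphere cases), alongside
exact analytic areas for isolated spheres, the van der Waals envelope upper
bound, and agreement with an independent union-of-spheres point-sampling
oracle in the probe→0 limit. When the probe is so small that probe-center
spacing exceeds 0.75 of the probe radius, reentrant seams are below
sampling resolution (their true area vanishes like the probe radius) and
the reentrant stage is skipped. Coincident atoms of equal radius make the
surface ill-defined and are an error. The default resolution keeps a capped
monopeptide area under two seconds while holding rigid-motion variance of
predictions to ~1–2%; totals at this resolution are conserved per-atom sums
to 1e−9 nm².

## Dynamics and finite-size toolkit

The MSD uses multiple-time-origin averaging — the desk-scale analogue of
averaging independent particle traces — and fits
$D = \mathrm{slope}/(2d)$ over a caller-chosen window. Apparent
coefficients in cubic periodic cells follow
$D_\mathrm{app}(L) = D_0 - \alpha\,k_\mathrm{B}T\,\xi_\mathrm{EW}/(6\pi\eta L)$;
extrapolation in $1/L$ uses inverse-variance weighting when uncertainties
are supplied, treating them as *known* standard deviations (parameter
errors from the weight matrix, no residual rescaling — which makes 2-σ
intervals carry their nominal ~95% coverage even for five-point series),
and ordinary least squares otherwise. The empirical factor α is exposed as
an explicit input everywhere: the shipped reference table shows it varying
non-transferably between solutes (0.71–1.07), so the package never fills it
in silently.

The lattice self term $\xi_\mathrm{EW}$ is computed by Ewald summation
(real-space erfc sum, reciprocal sum, self and background terms) with
cutoffs enlarged until stable to the requested tolerance and a built-in
cross-check that two splitting parameters agree; the test suite confirms
the value (≈ 2.837298) against a smoothly tapered direct lattice sum on a
21³ lattice, a purely real-space method. The periodic-perturbation
viscosity estimator projects the velocity profile onto the cos/sin pair at
the box wavenumber — drift-invariant by construction — and inverts
$\eta = A\rho/(V k^2)$.

## Synthetic data: what it does and does not emulate

The generators produce every test input in code: ideal-geometry peptides
(standard bond lengths/angles, one canonical all-trans rotamer per side
chain), sphere clusters with analytic areas, Brownian walks with
per-axis step variance $2D\,\mathrm{d}t$, and finite-size series evaluated
from the relation above with optional seeded Gaussian noise. Test problem
sizes are chosen to resolve each question at desk scale: 100 ns / 3 ps
Brownian walks for MSD recovery, 200-seed ensembles for interval
calibration, five-box series mirroring the reference simulation protocol.

What passing tests therefore show: the pipeline inverts itself exactly, the
estimators recover known inputs at their nominal uncertainties, and the
surface engine converges to the rolling-probe definition. What they cannot
show: that ideal conformers match simulation ensembles (real decapeptides
are mostly *less* ordered than a perfect helix, so real backbone exposure
is higher), that heavy-atom surfaces partition area the same way an
all-atom MSMS run would, or anything about solutes beyond the 20 standard
residues. Simulation-derived inputs (the diffusion/α table, viscosity
tables, the NMA coefficient) are shipped data; reproducing them requires
molecular dynamics and is out of scope by design.

## Known limitations

* Coefficients re-derived with this engine agree with the two published
  per-residue anchors to ~9% (M) and ~5% (D) — the unrecorded radius set,
  hydrogen treatment and conformer choice of the original derivation bound
  the achievable fidelity, which is why scale files carry their full
  provenance header.
* The decapeptide-derived coefficients sit below their monopeptide
  counterparts for 19 of 20 residue types; glycine is the exception (a
  helical GLY₁₀ retains very little residue-owned surface, inflating its
  coefficient), so the "variant D predicts faster" rule is asserted on
  mixed sequences rather than per coefficient.
* Predictions inherit the sampling noise of the surface engine (~1–2% at
  default resolution) — below the scatter of the simulation data the scale
  is built on, but not machine precision.
* The mass-relation state correction $T_\mathrm{ratio}/\eta_\mathrm{ratio}$
  is of limited flexibility, and which experimental viscosity enters the
  ratio is genuinely ambiguous; the function records its ratios as
  attributes and comparisons against state-corrected literature values
  should treat it as indicative.
* No rotational diffusion, no anisotropic mobility tensors, no non-cubic
  box corrections, no PTMs or nucleic acids.
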