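---
title: "Measuring and modelling peptide-bond planarity deviations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling peptide-bond planarity deviations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepgeom)
```

## The problem

The peptide bond has partial double-bond character and is conventionally
treated as planar, with the ω torsion (CAᵢ–Cᵢ–Nᵢ₊₁–CAᵢ₊₁) fixed at 180° for
trans bonds. High-resolution protein crystal structures tell a subtler
story: ω scatters by several degrees around 180°, and the deviation is not
random noise — it depends systematically on the backbone conformation of the
preceding residue. Two local deformation modes matter here:

* **rotation about the C–N bond**, measured by the signed planarity
  deviation Δω (ω − 180° for trans bonds, ω itself for cis), and
* **pyramidalization of the carbonyl carbon**, measured by
  θ_C = (ω − ω₃ + 180°) mod 360°, where ω₃ is the Oᵢ–Cᵢ–Nᵢ₊₁–CAᵢ₊₁ torsion.
  θ_C is zero when the carbonyl carbon is planar; a planar but twisted amide
  changes ω and ω₃ together and leaves θ_C untouched, so the two statistics
  separate twist from pyramidalization.

Surveyed across structures, Δω follows a sinusoid in ψ with a 120° period —
positive and negative deviations alternate every 60° of ψ, with planarity
near ψ ≈ 0°, 60°, 120°, 180° — and θ_C shows the same dependence, coupled to
Δω roughly linearly with a slope near 0.6 in proteins. A nitrogen-side
analogue θ_N exists but needs the amide hydrogen position, which X-ray data
rarely provide; the package computes it only when an H atom is present.

`pepgeom` implements the full chain of analysis: angle measurement, survey
filtering and binning, trend fitting, and a generative backbone model that
makes every stage testable without any external data and supports the
cumulative-distortion experiment described at the end.

## Conventions

Decisions that the literature leaves open are fixed package-wide:

* **Angle interval** (−180°, 180°], boundary assigned to +180°, so an ideal
  trans bond reads +180 rather than −180.
* **Torsion sign** is IUPAC-IUB (clockwise positive viewed from atom 2 to
  atom 3). Survey trends are symmetric under a global sign flip, so
  comparisons against published trend figures should be phase-aware
  (amplitude magnitude and zero positions) rather than raw-signed.
* **cis/trans cut** at |ω − 180°| = 90°, ties to trans. Only near-planar
  bonds survive the survey filters, so the tie rule never influences
  results in practice.
* **Association convention**: the ω-type angles of the bond between
  residues i and i+1 are attributed to residue i, whose ψ shares the Nᵢ₊₁
  atom. This is what makes "Δω versus ψ" well defined.
* **θ_N** is constructed by direct analogy with θ_C as
  (ω_H − ω + 180°) mod 360° with ω_H = CAᵢ–Cᵢ–Nᵢ₊₁–Hᵢ₊₁ — a package
  convention, since no standard formula exists.
* **Degenerate geometry errors**: collinear atom triples raise an error
  naming the atoms instead of returning NaN. A silent NaN entering a
  circular mean would corrupt a whole bin; an error is diagnosable.

## The survey pipeline and its parameters

`extractRecords()` emits one record per residue and never drops rows:
exclusions are recorded as audit reasons so that included + excluded always
equals the total and any count is recoverable. `FilterConfig` holds the
tunable thresholds:

| parameter | default | units | rationale |
|---|---|---|---|
| `bFactorRatio` | 1.3 | – | residue main-chain B above 1.3× the protein's pooled main-chain average marks local disorder |
| `excludeResidues` | GLY, PRO | – | both have unique local chemistry (no Cβ; tertiary amide) |
| `transOnly` | TRUE | – | cis bonds follow a different ideal and are rare |
| `chainBreakDistance` | 1.8 | Å | a bonded C–N is ≈ 1.33 Å; 1.8 Å separates bonds from gaps geometrically, independent of residue numbering |
| `minResolution` / `maxRFactor` | 1.6 Å / 0.20 | | entry-level gates for survey-grade accuracy |

Two readings of "main chain" and "entire protein" had to be fixed: the
main-chain atom set for B-factor statistics is {N, CA, C, O} (the
crystallographic norm; hydrogens are absent from most X-ray entries), and
the B-factor baseline pools all polymer residues of all chains of the
entry, the only well-defined reading for multi-chain entries. Entry-level
resolution/R-factor gates default to off (`gateSource = "none"`) because
database selection is normally performed upstream by a culling server;
`gateSource = "header"` re-checks them from the parsed header instead.

`binRecords()` assigns records to 15°×15° Ramachandran cells whose centers
lie on multiples of the step (half-open on both axes, so assignment is
total and unique), computes per-cell circular means, and flags cells with
fewer than 100 records; flagged cells are excluded from profiles and trend
fits, following the rule that every reported point should average at least
100 independent values. The 15° step matches the grid used in computational
conformer scans, making survey and computed maps directly comparable; both
the step and the count threshold are configurable because the defaults are
unreachable on desk-scale fixtures.

## Trend fitting

`fitHarmonic()` fits y = A·sin(k(ψ − φ₀)) + c by ordinary least squares on
the basis {sin kψ, cos kψ, 1}, with the period fixed at 120° (k = 3): the
observed extrema every 60° of ψ imply the third harmonic, and fixing k
keeps the fit linear and the amplitude unbiased. Treating angular
deviations as plain reals is valid because surveyed Δω and θ_C live within
a few degrees; the fit refuses inputs with |y| ≥ 90°. `fitLinear()` runs
the Δω–θ_C regression the same way. Both default to per-record values, with
a per-bin-means mode available, since published correlation coefficients do
not always state which feeds the regression. `zeroCrossings()` returns the
ψ roots of the fitted curve — the conformations at which the peptide bond
is planar — spaced 60° apart for a centered fit.

## The synthetic backbone generator

`synthesizeEnsemble()` is first-class, tested code, not a fixture factory.
It emulates exactly the statistical structure the survey is designed to
detect:

1. (ϕ, ψ) per residue from a mixture of four Ramachandran basins (β,
   polyproline-II, right- and left-handed α; isotropic Gaussians of 15–25°
   spread, weighted 0.35/0.15/0.40/0.10 roughly as in folded proteins).
   The ψ centers span the 120° period, making amplitude and phase
   identifiable.
2. Δωᵢ = A·sin(3(ψᵢ − phase)) + N(0, σ_ω), defaults A = 2°, phase = 0,
   σ_ω = 1° — deviation and scatter magnitudes typical of high-resolution
   survey data.
3. θ_C,ᵢ = 0.6·Δωᵢ + N(0, 0.5°), mirroring the protein-side regression
   slope of ≈ 0.59.
4. ω = 180° + Δω and ω₃ = ω + 180° − θ_C (wrapped), built into Cartesian
   coordinates with Engh–Huber-style covalent geometry (N–CA 1.458 Å,
   CA–C 1.525 Å, C–N 1.329 Å, C=O 1.231 Å and standard valence angles).

The default ensemble (50 chains × 42 residues) yields exactly 2000 included
survey records, a size at which the amplitude standard error
(σ_ω·√(2/n) ≈ 0.03°) makes recovery within [1.9°, 2.1°] a sharp test.

What the generator does **not** emulate: steric exclusion between distant
residues (chains may self-intersect), side chains, hydrogen bonding,
correlated ϕ/ψ sequences, experimental coordinate error, or real B-factor
and occupancy pathology. Passing recovery tests therefore demonstrates that
the measurement/survey/fit chain is faithful to a known signal, not that
real proteins contain one — that evidence has to come from applying the
survey to real high-resolution entries.

## Internal coordinates, rebuilding and the distortion experiment

`backboneInternalCoords()`/`extractInternal()`/`buildBackbone()` represent
a chain as per-atom (bond length, bond angle, torsion) triplets, anchored
by the Cartesian positions of the first three atoms (N1 at the origin, CA1
on +x, C1 in the xy-plane for synthetic chains). The carbonyl oxygen of
residue i is placed by a torsion about the Cᵢ–Nᵢ₊₁ axis that equals ω₃
itself (by torsion-reversal symmetry), which is what lets the generator
control θ_C directly; the terminal oxygen, which has no following nitrogen,
is oriented by ψ_n + 180°. Extraction and rebuilding are exact inverses,
verified to 10⁻⁶ (degrees and Å) on randomized chains against an
independently coded placement kernel that uses a Gram–Schmidt frame rather
than the package's cross-product frame.

`idealizeOmega()` performs the cumulative-distortion experiment: extract
internal coordinates, set every *trans* ω torsion to exactly 180° (cis
bonds are deliberately untouched — the experiment concerns trans planarity
idealization), keep all other internal coordinates, and rebuild from the
same anchor. Because each ω edit is a hinge rotation about a peptide-bond
axis, residues upstream of a perturbed bond do not move and downstream
displacement grows with the lever arm — a few degrees per bond compound
into Ångström-scale drift over a hundred residues. Since "trace
difference" admits several readings, the `DistortionReport` carries all
candidate metrics: per-residue Cα displacements in the common anchored
frame, their mean and maximum, and the RMSD after optimal (Kabsch)
superposition, which is always a lower bound on the anchored-frame RMS.

The acceptance script's distortion experiment uses a 121-residue
single-chain surrogate drawn from the generator's basin mixture with
ω scatter of 6.8° — the planarity spread reported for an ultra-high-
resolution structure — rather than a repetitive extended chain: a mixed-
basin coil has realistic local geometry and a compact-ish fold, whereas a
uniform extended conformation maximizes lever arms and would overstate the
drift. The drift magnitude still depends on the fold of the particular
chain; the reported numbers characterize the surrogate, not any deposited
structure.

## Numerical choices and degenerate inputs

* Collinearity threshold for dihedrals/placement frames: cross-product norm
  below 10⁻¹⁰ × scale² raises a degenerate-geometry error.
* Circular means with a resultant below 10⁻¹² return NA with a warning
  (undefined mean) instead of an arbitrary angle.
* Altloc resolution keeps the highest-occupancy conformer, ties to
  altloc 'A'; the residue keeps a partial-occupancy flag either way so the
  disorder filter still sees it.
* Multi-model files contribute model 1 only (NMR ensembles are outside the
  X-ray survey scope).
* PDB output carries 3-decimal coordinates; round trips are exact to
  10⁻³ Å, which limits re-measured torsions to ≈ 0.1°.
* Harmonic fits reject rank-deficient designs (all ψ identical) rather
  than returning an arbitrary phase; linear fits with constant y report
  r = 0 with an explicit flag.

## Problem sizes

The test suite and acceptance script run at sizes chosen to make the
statistical checks sharp while staying desk-scale: 2000-record ensembles
for single-seed recovery, 20 seeded replicates for bias checks, 100
randomized chains for the inverse-pair property, and a 121-residue chain
for the distortion experiment.

## Known limitations

* `read.cif` support in the underlying parser is marked beta upstream;
  the package exercises the `_atom_site`/`_refine` categories only.
* θ_N is reported only when an amide hydrogen is deposited; the package
  never constructs hydrogens.
* The survey treats each residue record as independent; no per-chain or
  per-entry random effects are modelled in the fits.
* Harmonic fitting assumes the fixed 120° period rather than searching it;
  a signal at a different period would be mis-fit (by design).
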