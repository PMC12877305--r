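---
title: "Methods: azobenzene switch geometry, burial and host contacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: azobenzene switch geometry, burial and host contacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azogeom)
```

## The problem this package addresses

Azobenzene-based photoswitches such as *p*-(phenylazo)-L-phenylalanine
(Pap, also called AzoF or AzoPhe) interconvert between an extended
*trans* and a bent *cis* configuration about their N=N double bond. In
the *trans* state the side chain threads the cavity of
α-cyclodextrin (α-CD), a torus of six D-glucose units, which is the
basis of light-controlled affinity purification: UV-A illumination
switches the side chain to *cis* and releases the complex. Assessing
how such a switch actually sits in a protein and in its host requires a
small set of reproducible geometric measurements, which this package
implements:

* the conformational descriptor set of the azobenzene moiety,
* optimal rigid-body superpositions and Cα RMSDs over author-numbered
  residue ranges,
* solvent-accessible surface areas (SASA) and the burial of a guest
  side chain upon complexation,
* donor/acceptor hydrogen bonds at the host rim,
* average masses of biosynthetic constructs carrying noncanonical
  residues and a matured GFP-type chromophore.

A synthetic-structure generator produces fully specified fixtures so
that each stage is verifiable without any coordinate download.

## The descriptor set

For an azobenzene moiety ring1–N1=N2–ring2 we report

* `chi_azo = dihedral(ipso1, N1, N2, ipso2)` — the configuration about
  the azo bond (≈180° *trans*, ≈0° *cis*);
* `chi_pre = dihedral(ortho1, ipso1, N1, N2)` and
  `chi_post = dihedral(N1, N2, ipso2, ortho2)` — the twists of each
  phenyl ring out of the azo plane;
* `alpha` — the angle between the least-squares planes of the two
  six-carbon rings.

Torsions follow the standard signed right-hand convention with range
(−180°, 180°]; a trans-planar chain measures exactly 180°.

**Ortho-atom choice.** Each ipso carbon has two ring neighbours, and
the two possible torsions differ by exactly 180°. We take the ortho
carbon giving |χ| ≤ 90°, with an exact 90° tie broken by the
lexicographically lower atom name. This rule makes the descriptor
independent of which way a depositor happened to number the ring and
reproduces the familiar symmetric ±χ pattern of counter-twisted planar
azobenzenes.

**Folded interplanar angle.** A least-squares plane normal has no
intrinsic sign; we fix it by the right-hand rule over the ordered ring
traversal, but the traversal direction itself is a nomenclature
accident. Published interplanar angles for chemically equivalent planar
compounds consequently appear as either ≈0° or ≈180° depending on
convention. We therefore report both `alpha_raw` (in [0°, 180°],
orientation-dependent) and the canonical `alpha_folded = min(raw,
180 − raw)` (in [0°, 90°], orientation-free), and use the folded value
for all comparisons.

**Plane fitting.** Planes are fitted by SVD of the centered ring-carbon
coordinates (the singular direction of least variance), using the six
ring carbons only — substituents do not contribute. Collinear point
sets are rejected (second singular value at relative 1e-9). The arccos
argument in the interplanar angle is clamped to [−1, 1], so exactly
coplanar rings report an interplanar angle of exactly 0.

## Superposition and RMSD

`kabsch()` implements the closed-form least-squares rigid alignment
(SVD of the covariance matrix with the determinant correction that
excludes reflections) and returns the rotation, translation, and
minimal RMSD. The package carries two independent cross-checks in its
test suite: a quaternion-parameterised numeric minimisation and the
fitting route of the bio3d package; both agree with the closed form to
better than 1e-6 Å on seeded noisy instances.

Whole-chain comparisons (`rmsd_ca_ranges()`) pair Cα atoms by identical
author residue number over multi-interval ranges such as 3–74 plus
79–227; residues unmodeled in either structure are dropped silently
and the survivor count is reported. RMSDs are computed *after* optimal
superposition. Pairing is positional (no sequence alignment): the
intended use is comparisons among structures sharing one author
numbering scheme.

Anchored overlays (`superpose_on_substructure()`) fit the transform on
a small anchor set — canonically the six carbons of the first phenyl
ring plus the first azo nitrogen — and apply it to all atoms, so
conformers can be compared ring-to-ring while the rest of the molecule
is free to diverge.

## Accessible surface and burial

`sasa()` is a deterministic Shrake–Rupley-style implementation: each
heavy atom's solvent-extended sphere (van der Waals radius + probe,
probe default 1.4 Å) carries a golden-section (Fibonacci) lattice of
`n_sphere_points` (default 960) points, and the accessible area is the
unburied point fraction times the sphere area. There is no randomness,
so results are bit-reproducible; doubling the lattice density changes
totals by well under 1%, and single- and two-sphere configurations
match the closed-form areas to better than 0.5%. Default radii are
NACCESS-like (C 1.70, N 1.55, O 1.52, S 1.80 Å); unknown elements fall
back to 1.70 Å with a warning. Hydrogens and waters are excluded by
default (toggleable), which matches how areas of ~2 Å-resolution
crystal structures are conventionally computed. Results obtained with
different SASA software can differ by a few percent through radii and
algorithmic choices; comparisons across programs should allow a ±5%
band.

`sidechain_asa_contexts()` evaluates the guest side chain (all residue
atoms except backbone N, CA, C, O — CB is part of the side chain; the
isolated reference keeps the whole free amino acid) in three contexts
at the identical conformation: isolated, protein without host, full
complex. The ordering complex ≤ protein-alone ≤ isolated holds by
construction, and the burial fraction is 1 − complex/isolated.

## Hydrogen bonds at the rim

Without hydrogens, donor/acceptor assignment is not observable from a
crystal structure, so `hydrogen_bonds()` enumerates N/O–N/O heavy-atom
pairs within 3.5 Å (a conventional cutoff) and screens out through-bond
artefacts by requiring every covalently bonded antecedent of either
atom to subtend at least 90° to the partner. Both cutoffs are
parameters; they are defaults of the trade, not values with special
provenance. Bonds are reported sorted by distance with the minimal
antecedent angle attached as evidence.

## Masses of biosynthetic constructs

`average_mass()` sums residue average masses (standard IUPAC atomic
weights) plus one water, with modifications expressed as explicit
deltas: initiator-Met processing subtracts exactly one Met residue
(131.196 Da), and GFP-type chromophore maturation is modeled as a
single net −(H2O + H2) = −20.031 Da (backbone cyclization loses water,
the subsequent oxidation loses H2). Noncanonical residues are
registered by their free-amino-acid elemental formula — for Pap,
C15H15N3O2, which is independently assembled in the test suite from
its fragments (phenyl + azo + phenylene + alanyl backbone). Masses are
averages, matching the scale of ESI deconvolution results.

The package ships `inst/extdata/sfGFP39Pap_reconstructed.fasta`, a
*reconstruction* of a 248-residue superfolder-GFP construct displaying
Pap at position 39 with an SA-linked C-terminal Strep-tag II, assembled
from the published mutation set of superfolder GFP on the avGFP
(P42212) background. It is labelled reconstructed because the exact
expression construct is not bundled with this package; its computed
processed mass (27,965.13 Da) should be read with that caveat, while
the internal Met-retention difference is exact by construction.

## What the synthetic generator emulates — and what it does not

`build_azobenzene_residue()` constructs an idealized residue with fixed
bond geometry (aromatic C–C 1.39 Å, C–N 1.42 Å, N=N 1.25 Å, 120° ring
angles, 113° C–N=N angles) by internal-coordinate (NeRF) placement, so
the three planted torsions are realized *exactly*; the builder is the
inverse of the descriptor and round-trips to ~1e-13°. Planted χ values
outside ±90° are recovered relative to the other ortho carbon (shifted
by 180°), which is the identifiability limit imposed by the ortho rule,
not a defect.

`build_toy_complex()` assembles the guest-through-torus topology: a
poly-Ala helix (rise 1.5 Å, 100°/residue, radius 2.3 Å), the azobenzene
residue aligned on +x, `host_units` (default six, matching an α-CD)
pseudo-sugar occluders at `host_radius` (default 5.5 Å, a cavity-like
distance), and one planted rim contact per unit: a serine-like OG
placed exactly 2.7 Å from the unit's narrow-rim hydroxyl oxygen, with
antecedent atoms placed collinearly so the contact passes any angle
screen. The planted pairs are recorded in the model's `manifest`
attribute. The pseudo-sugars are geometric, not chemical: they exercise
occlusion and contact counting, but carry no glucose stereochemistry,
no realistic tilt of the conical torus, no waters, and no crystal
environment. Passing tests on these fixtures therefore demonstrate the
correctness of the *measurements*, not the realism of any particular
structural model; measurements on real structures additionally face
coordinate error, alternate locations (resolved by highest occupancy,
ties alphabetical) and unmodeled stretches, which the I/O layer handles
explicitly.

Default noise is zero so fixtures are byte-identical across runs;
`perturb_model()` adds seeded i.i.d. Gaussian coordinate noise without
touching the global RNG stream. Under 0.02 Å noise a planar conformer
stays within a few degrees of planarity, which bounds the coordinate
sensitivity of the descriptors.

## Numerical and design choices

* Deposition nomenclature is never hard-coded: ring and azo atom names
  are user-supplied (`ring_spec()`, selector grammar
  `"CHAIN:RES[-RES][,…][/NAME]"`) or derived from coordinates by
  `infer_azo_topology()`, which finds the N=N pair and the two
  six-carbon cycles from a 1.75 Å bond cutoff and labels as ring 1 the
  ring nearer the backbone CA.
* ATOM and HETATM records enter one hierarchy (switch residues and
  carbohydrate ligands are often HETATM); author numbering is
  authoritative; insertion-coded residues sort after the bare number.
* PDB I/O is delegated to bio3d behind the package's interface, with a
  fixed-width pre-scan so malformed records fail with a line number;
  mmCIF is a thin optional reader onto the same model.
* Problem sizes in the test suite (200 descriptor round-trips, 50 noisy
  plane fits, 20 superposition oracle instances, a ~200-atom toy
  complex) were chosen as the smallest sets that exercise every code
  path with comfortable statistical margin while keeping the default
  suite fast.

## Known limitations

* No crystallographic symmetry expansion: only atoms present in the
  file are considered, so contacts to symmetry mates are out of reach.
* Positional (author-numbering) pairing only for RMSD; no alignment.
* Hydrogen-bond detection is heavy-atom geometric; with hydrogens
  present the same distance screen applies (explicit H–A–D angle
  criteria are not implemented).
* SASA is O(n²) in atom count per context, intended for single
  complexes (thousands of atoms), not trajectories.
* The reconstructed construct FASTA is a documented stand-in, not a
  verbatim expression-vector sequence.
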