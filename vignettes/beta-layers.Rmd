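---
title: "Beta-layers in trimeric coiled coils: models, detection and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-layers in trimeric coiled coils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betalayer)
```

## The structural problem

Parallel coiled coils accommodate deviations from their 7-residue repeat
by supercoiling: a straight α-helix turns about 3.63 residues per turn,
and delocalized insertions shift the local periodicity (residues per turn
relative to the bundle axis) within a band of roughly 3.33 (10/3, the
overwinding limit at which helices distort toward 3~10~ geometry) to
about 3.9 (the mirror of that strain on the right-handed side). A repeat
of *r* residues over *t* turns has periodicity *r/t*; below 3.63 the
supercoil is left-handed, above it right-handed. Insertions of 3 (stammer)
or 4 (stutter) residues fall close to one helical turn and delocalize
comfortably (10/3, 11/3, 15/4, 18/5, 19/5). Insertions of 2 (equivalently
9, since 9 ≡ 2 mod 7) have no accessible accommodation: 9/2 = 4.5 and
9/3 = 3.0 are both outside the band, and delocalization over two heptads
only reaches 16/5 = 3.2 or 4.0. `accommodation_report()` reproduces this
algebra and flags such insertions.

The structural escape is the **β-layer**: the three chains of a trimeric
coiled coil each put three consecutive residues into the β region of the
Ramachandran plot, forming a triangular plane perpendicular to the bundle
axis in which the *central* residue of each strand hydrogen-bonds
(backbone N–O) to the central residue of the neighboring chain. The layer
occupies the place of a core *d* position and moves the path of each
chain by ~120° around the bundle axis, so the downstream helix of one
chain continues in the azimuthal slot of its neighbor's upstream helix.
In register terms a 9-residue element reads *a-b-c*-β₁β₂β₃-*e-f-g*; a
6-residue element reads β₁β₂β₃-*e-f-g* preceded by a *g* position whose
Crick angle is biased toward *c* (the hybrid *g/c* position).

## The two-step detector

`detect_beta_layers()` implements the search as a composition of three
operations, each exported on its own:

1. `compute_torsions()` assigns φ/ψ per residue and classifies them into
   two boxes with inclusive boundaries: α is −70° ≤ ψ ≤ −10 with
   −180 ≤ φ ≤ −40; β is 20 ≤ ψ ≤ 180 with the same φ range. The boxes
   are disjoint in ψ, so the classification is a partition.
2. `scan_windows()` slides the seven-residue patterns βββαααα and
   ααααβββ over the classes within continuous chain segments. Both
   patterns are needed: a strand flanked by four α residues on one side
   only is matched by one of them. A triplet matched by both is a single
   candidate. Windows are not matched across chain breaks
   (C–N > 2.5 Å) or at termini shorter than seven residues.
3. `pair_strands()` connects candidates whose central (β₂) residues share
   a backbone N–O contact at or below 3.5 Å — a plain heavy-atom distance
   with no angular term, in either donor/acceptor direction — inside the
   (assembly-expanded) model, and reports connected components of two or
   more strands. Components of exactly three strands are canonical;
   smaller ones are reported rather than hidden (a `strict_trimer` flag
   restricts output to trimeric layers). Strands of one chain may pair,
   admitting monomers with pseudo-threefold symmetry.

Capping is classified from sequence rule rather than re-measured
side-chain geometry: a lysine in β₁ reaches across the trimer core and
C-caps the preceding helices; a hydrophobic β₁ (A, V, L, I, M, F) leaves
the N-capping network of the following helices; anything else is
unclassified. Transition labels (`cc-to-cc`, `cc-to-beta`, `beta-to-cc`,
`Nterm-to-cc`) come from the four flanking torsion classes on each side,
with the flank class rules taking precedence over the near-terminus rule.

## Local periodicity and register

`local_helix_axis()` uses the classic bisector construction: at each
interior residue the bisector of the two Cα–Cα bonds points at the local
helix axis; consecutive bisectors give the axis direction, twist, rise
and radius. `bundle_axis()` averages the per-chain axis points pointwise
(for a C3 bundle this is the symmetry axis) and also fits a line for use
near termini; `bundle_axis_line()` supplies an explicit reference axis
for single straight helices.

The Crick angle of a residue is the signed angle, in the plane normal to
the local axis, between the direction toward the bundle axis and the
direction toward the Cα. Because that reference direction co-rotates
with the superhelix, the per-residue *increment* of the Crick angle is
exactly the rotation of the Cα about the local axis corrected for the
rotation of the local axis about the bundle axis, and

> periodicity(i) = 360° / Δcrick(i).

This formulation was chosen over explicitly subtracting the axis-azimuth
rate from the bisector twist: on generated coils it recovers nominal
periodicities within 0.016 residues/turn over the whole accessible band,
where the explicit subtraction biases the strongly supercoiled 10/3 case
by ~0.05. For helices lying *on* the reference axis (superhelix radius
0) the toward-axis direction is undefined but also non-rotating, and a
fixed perpendicular reference is substituted, which makes the straight
helix measure its own twist (3.63 residues/turn at the canonical value).
Traces are smoothed with a centered three-residue moving average
(`smooth_trace()`, shrinking at the ends), the width used for all
periodicity plots.

`assign_register()` labels helical residues by the nearest of seven
ideal Crick angles spaced 360/3.5 apart and phased so the core positions
*a* and *d* straddle the direction toward the bundle axis (*a* at +25.7°,
*d* at −25.7°). Layer strands are labeled β₁β₂β₃; the residue after β₃
is forced to *e* (layers dictate the downstream register); and a residue
immediately preceding β₁ that is displaced from ideal *g* toward *c* by
at least 10° — but by no more than half the g-to-c span, beyond which it
simply *is* a *c* — is labeled *g/c*. The 10° threshold sits below the
~15° displacement observed in hexad structures, detecting the bias with
margin; a full displacement must stay *c* because the nonad junction
genuinely ends on a *c* position.

## The synthetic generator

`generate_crick_coil()` builds Cα traces from the two-level helix
parameterization: a minor helix of radius 2.28 Å winding at ω₁ = 360/P
degrees per residue (in the frame co-rotating with the superhelix, so
the nominal periodicity relative to the bundle axis is exactly P) about
a superhelical path of radius R₀, with the superhelix frequency set by
the constraint that the helix itself keeps the unperturbed twist of
360/3.63 °/residue. R₀ = 0 reduces to a straight helix with an explicit
twist. Chains are exact n-fold rotational copies. Full backbones are
rebuilt from the Cα path by placing N, C and O in the local frame of
each consecutive Cα triple with offsets calibrated once on an ideal
α-helix grown by internal coordinates (`build_backbone_from_torsions()`,
which round-trips torsions exactly through `compute_torsions()`).

`generate_beta_layer_fixture()` plants detector-positive layers. One
chain is grown from torsions — fourteen-residue ideal helices flanking a
three-residue β-region insert — and the bundle axis is *constructed*
from the two helix-axis lines as the unique axis about which the
downstream helix is the upstream helix rotated 120° at equal radius;
three chains are then placed C3-symmetrically and the radius adjusted by
a deterministic bisection until the cyclic central-residue N–O distances
reach 3.2 Å, inside the 3.5 Å criterion with margin. The strand and
junction torsions are frozen package constants, tuned once (against
axis parallelism, contact closure at zero radial adjustment, and the
register rules above) because the Ramachandran region alone does not
determine the geometry; the tandem fixture's two junctions are tuned
jointly since both layers must close around one shared axis. Fixture
annotations carry the planted ground truth (chains, β₁β₂β₃ residues,
register, achieved radius and contact distance).

What the fixtures emulate: torsion-box geometry, C3 symmetry, cyclic
central hydrogen bonding, the 120° path rotation, and the nonad/hexad
register rules — the features the detector and register machinery test.
What they do not emulate: side chains beyond the sequence letter,
water-mediated or bifurcated hydrogen bonds, lattice disorder,
alternate conformations, and the gradual register conflicts real
fusion constructs resolve by hendecads or stammers. Passing the battery
therefore validates the algorithms' contracts, not their recall on
crystallographic coordinates.

## Numerical choices and degenerate inputs

* Dihedrals follow the IUPAC sign convention (anti = 180°), verified
  against an independent implementation; degenerate geometry (coincident
  or collinear points) yields `NA`, never an error.
* Alternate locations: blank or 'A', highest occupancy on tie — one
  deterministic conformer.
* Chain breaks: C(i)–N(i+1) > 2.5 Å ends a segment; torsions and windows
  never cross breaks or incomplete residues.
* The accessible band [10/3, 3.90] and the 3.63 reference are module
  constants, overridable per call; optimal delocalization ties break
  toward the lower periodicity (the left-handed bias of the heptad
  background).
* A 6-residue insertion delocalized over two heptads lands exactly on
  the inclusive 10/3 limit (it is two consecutive stammers), so the
  periodicity-based flag calls it marginally accessible even though
  structurally such insertions form β-layers; the flag's claim is about
  supercoiling algebra, not about strain accumulation.
* Problem sizes: generated coils use 28 residues per chain and fixtures
  14-residue flanking helices; both are two heptads past the four-residue
  windows every estimator needs, and parameter-recovery errors at these
  sizes are an order of magnitude below the asserted tolerances.

## Robustness and limitations

Coordinate-noise sensitivity (analysis/04_robustness.R) shows detection
of a planted layer is complete under independent per-atom Gaussian noise
up to σ ≈ 0.02 Å and decays steeply past 0.05 Å: 0.1 Å of independent
displacement induces tens of degrees of torsion noise, which flips
residues out of the hard α/β boxes. Real crystallographic coordinate
error is strongly correlated along the backbone and perturbs torsions
far less; the hard-box classifier inherits this cliff from its
definition, and the package asserts full robustness only at σ = 0.02 Å.

mmCIF files are read (first model, polymer chains) but
assembly expansion is implemented for PDB REMARK 350 operators only;
mmCIF input is analyzed as deposited ("asu"). The default assembly for
PDB input is "1" when defined. Residue numbering in all reports is
author numbering. The detector does not attempt layers whose flanks
leave the two window patterns (short chain termini, β-flanked layers
found only by interactive analysis), and no energetic or angular
hydrogen-bond term is applied beyond the 3.5 Å N–O distance.
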