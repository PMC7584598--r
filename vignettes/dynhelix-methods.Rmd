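---
title: "Methods: geometry, interfaces and synthetic assemblies in dynhelix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, interfaces and synthetic assemblies in dynhelix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dynhelix` post-processes coordinate ensembles of dynamin-2 oligomers —
full-atom dimers and coarse-grained 56-monomer helices — and quantifies how
the centronuclear-myopathy mutation R465W reshapes the assembly: the local
interaction network of residue 465, the four monomer–monomer interfaces,
the bending of the bundle signaling element (BSE), and the helical lattice
itself.  This vignette records the concrete definitions, defaults, and
design decisions behind each stage, and what the synthetic-assembly tests
do and do not demonstrate.

## Containers and conventions

A *frame* is a flat particle table (monomer id, residue number and name,
particle name, coordinates in Å, optional mass and radius); a *trajectory*
is an ordered list of frames sharing monomer identities.  Residues use
1-based human dynamin-2 numbering throughout; insertion codes are not
supported.  Monomer identity comes from the chain id (PDB) or
`auth_asym_id` (mmCIF).  Assemblies with more than 62 monomers are written
as mmCIF because classic PDB chain ids cannot index them.  Particles named
`BB`/`SC1`..`SC4` (configurable) mark a frame as coarse-grained; CG bead
masses default to residue mass / bead count, and full-atom masses come from
the element.

Analysis windows mirror common practice for these systems: dimer metrics
are averaged over the trailing nanoseconds of a run and helix metrics over
a trailing window (the `window_spec` modes `last_t_ns`, `last_n_frames`,
`all`).  Because saving intervals vary between studies, a frame-count
fallback is provided when time stamps are absent.

## Inter-domain angles

The **G-BSE angle** is measured at the centroid of residues 291–293 between
arms ending at the centroids of residues 277–285 and 299–306.  The
**BSE-stalk angle** starts at the *pooled* centroid of the hinge
(315–321 ∪ 702–711); one arm ends at the pooled G-domain center
(30–36 ∪ 170–176), the other at the pooled stalk center
(410–422 ∪ 610–626).  Two readings of the hinge wording are possible (one
pooled centroid, or two separate ones); the pooled-union reading is used
because both arms are described as starting from a single point.  All
anchor ranges are overridable through the domain map.

Centroids are mass-weighted on full-atom input and uniform on
coarse-grained input, where bead masses are scheme-dependent and often
absent.  Angles come from the clamped arccos of the normalized dot product,
so numerically (anti)parallel arms return exactly 0°/180° rather than NaN.
Per-monomer angles are averaged over the analysis window *before* group
statistics — the monomer, not the frame, is the statistical unit, which
avoids pseudo-replication across autocorrelated frames.

The **G–G asymmetry** Δ of a cross-rung G–G pair is the absolute difference
of the two monomers' window-mean G-BSE angles, summarized as mean ± SEM
over pairs.  How many pairs a study counts depends on how G–G partners are
identified; here they are defined operationally as cross-rung pairs whose
G-domain particles approach within the contact cutoff, which yields 42
pairs on the generated 4-rung, 14-per-turn helix.

## SASA

Solvent-accessible surface area uses Shrake–Rupley quadrature: each
particle's probe-extended sphere (probe 1.4 Å, full-atom and CG alike) is
sampled on a deterministic generalized-spiral (Fibonacci) point set, and
the fraction of points outside every neighbor's extended sphere scales the
analytic sphere area.  Defaults: 960 points/sphere; van der Waals radii by
element (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Å) and 2.3 Å for CG beads
(a typical 4-to-1 mapping), all table-overridable.  Isolated spheres are
exact by construction; overlap handling is quadrature-accurate (within 2%
of a dense Monte-Carlo reference in the tests).  One consequence worth
knowing: the quadrature is not perfectly rotation-invariant — re-orienting
a heavily overlapped scaffold moves the total by a few tenths of a percent
at the default density, shrinking with more points.

Residue SASA is normalized by empirical Gly-X-Gly maximal accessibilities
(packaged as `inst/extdata/max_sasa.csv`, user-overridable), giving the
dimensionless relative exposure used to compare R465 and W465.  Context
matters: `in_assembly` treats all other monomers as occluders,
`isolated_monomer` does not; assembly context is the default since the
quantity of interest is exposure within the oligomer.

## Interfaces

A residue is a contact residue of a monomer pair when the minimum distance
between any of its particles and any particle of the partner is ≤ 6 Å
(inclusive at the boundary, for determinism).  Contact detection is exact —
the implementation is required by its tests to equal an all-pairs
brute-force oracle, including ties at exactly 6.0 Å.

Classification into the four interface types uses a deterministic
domain-majority rule (threshold 0.5, configurable): cross-rung contacts
dominated by G-domain residues are **G–G**; stalk-majority against
BSE-majority is **interface-1**; stalk–stalk contacts touching the central
αS2–αS4 segments (455–495 or 660–690) are **interface-2**; stalk–stalk
contacts dominated by the L1N^S loop segment (default 390–400,
configurable) are **interface-3**; anything else is `unclassified`.  The
published assignments were made by structural inspection; a reproducible
pipeline needs an explicit rule, hence this one.

The **interface area** is, by default, the summed in-assembly SASA of the
contact residues of both monomers (`exposed_sum` — "the area included by
the amino acids within the cutoff").  Because that phrase could also mean
buried surface, a `buried` mode (isolated-monomer SASA minus in-pair SASA)
is provided and the mode is recorded in outputs.  **Occupancy** of residue
*r* in interface type *t* is the fraction of (instance × frame)
observations of *t* whose contact set contains *r* — the denominator is a
reconstruction, since published occupancy heatmaps are unit-free; counts
are kept alongside the fractions.

Hydrogen bonds (full-atom only) use donor–acceptor distance ≤ 3.5 Å with a
120° minimum angle at the hydrogen when hydrogens exist, or at the donor
against its nearest bonded heavy atom otherwise (hydrogen-free proxy for
stripped structures).  Salt bridges pair basic (Arg NH1/NH2/NE, Lys NZ,
His ND1/NE2) with acidic (Asp OD1/OD2, Glu OE1/OE2) atoms at ≤ 4.0 Å,
collapsed to one bridge per residue pair.  These geometric criteria are
stated explicitly because figure-level bond counts in the literature rarely
are.

The residue-465 analysis restricts contacts to residue 465 of each monomer
against the BSE residues of its within-rung successor (falling back to the
predecessor at rung ends, where the construction leaves no facing
neighbor and the instance is honestly empty).

## Helix geometry

The axis is initialized from whichever principal direction of the monomer
centers of mass minimizes the radial variance (the long axis for extended
helices, the plane normal for flat rings) and refined by Nelder-Mead over
direction and in-plane offset — deterministic, no randomness.  Monomer COMs
are then expressed in cylindrical coordinates; azimuths are unwrapped along
the assembly order (either handedness accepted; mixed azimuthal steps
trigger a warned fallback to axial ordering).  Linear fits of axial
position and unwrapped azimuth against monomer index give the rise per
monomer and azimuthal step Δφ, from which: monomers/turn = 2π/Δφ, pitch =
rise × monomers/turn, and the **helix angle** = arctan(rise/(r·Δφ)) — the
pitch angle between the local helical path and the plane normal to the
axis.  That standard geometric reading is adopted because it is the one
consistent with the small (≈3–6°) values such assemblies show; the COM
diameter is reported alongside an outer (envelope) diameter since figures
often annotate the latter.

## The synthetic-assembly generator

The generator is the package's test substrate: reduced scaffolds
(~230 residues covering every range the analyses select) rather than full
870-residue chains, placed so that every ground-truth label is recoverable.

* Angle targets are hit *exactly*: anchor ranges are laid out as symmetric
  runs about analytically placed centroids (mass-recentered in full-atom
  mode), so `g_bse_angle`/`bse_stalk_angle` reproduce the targets to 1e-6°
  on noiseless monomers.  Defaults: WT 118°, mutant 150° (G-BSE), 109°
  (BSE-stalk) — the bent/extended contrast characteristic of WT vs R465W.
* Helix placement puts each monomer's COM exactly on the lattice (radius
  180 Å, rise 4 Å, 14 monomers/turn by default → 56 monomers, 4 rungs, 14
  tetramers, pitch 56 Å, helix angle 2.83°), so diameter/pitch/angle
  recovery is exact on noiseless frames.
* Contacts are engineered at the default lattice: a vertical G-domain arm
  creates cross-rung G–G contacts; tip (471–495) and tail (660–692) stalk
  segments of azimuthal neighbors interdigitate into interface-2; and a
  BSE "finger" (294–298, 742–745) of each monomer reaches the previous
  monomer's 465 site such that buried R465 touches {P294, V744, S745} and
  the exposed mutant W465 additionally {S298, S742}.  Residue 465's
  exposure flag (buried for WT, exposed for R465W by default) also controls
  its SASA contrast and its loss of the N429/Q433/E466/E468 network.
* Noise is i.i.d. isotropic Gaussian per particle per frame — it emulates
  thermal jitter for estimator testing, not kinetics; there is no force
  field, no membrane mechanics, and no correlated motion.  Everything is a
  deterministic function of the seed, generated under a private RNG state.

What passing tests therefore show: the estimators recover known geometry,
composition and contact structure under coordinate noise at the stated
tolerances.  What they do not show: behavior on real trajectories with
correlated dynamics, partial occupancy of interfaces, disordered loops, or
CG mappings other than the bead-naming convention assumed here.  Two
honesty notes: with exactly 14 monomers per turn, strict WT/mutant
intercalation puts the same genotype on both sides of every vertical G–G
pair, so the generated hetero helix shows near-zero asymmetry — large
hetero-pair Δ values require mixed-genotype pairings that this lattice
cannot produce; and the interface-2 contact engineering holds at the
default lattice, not at arbitrary radii/turn counts (other lattices still
give G–G and stalk contacts, classified by the same rule).

## Statistics

Group comparisons take per-monomer (or per-tetramer, per-frame for helix
parameters) window means.  `anova_tukey` is one-way ANOVA with Tukey HSD;
`kw_dunn` is Kruskal–Wallis with Dunn's rank-based z tests (tie-corrected)
and Holm adjustment — Holm because the multiplicity adjustment inside
published Dunn tests is often unstated and Holm is conservative and
standard.  Mixed-genotype groups are split into `<group>.WT`/`<group>.MUT`
units.  Under the null the ANOVA omnibus p-values are uniform (checked by
simulation in the tests); with two groups the Tukey p equals the
pooled-variance t-test p.

## Problem sizes and determinism

The shipped tests and the acceptance script run entirely on generated
data at desk scale: 56-monomer helices with 50 frames at 0.5 Å noise for
angle-recovery statistics, single frames for lattice recovery (0.1%
noiseless, 2% at 1 Å noise), 200 randomized assemblies for the contact
oracle, and 10^5-point Monte-Carlo sampling for SASA cross-checks.  Interface
areas — the one expensive stage, since each contact residue costs a SASA
evaluation — are evaluated on an evenly spaced frame subsample
(`n_area_frames`, default 5) while contact sets and occupancy use every
frame.  Re-running any pipeline with the same inputs and seed reproduces
the CSV outputs byte-for-byte.

## Known limitations

* No dihedral/torsion or elastic-network analysis; no MM/GBSA-style
  energetics; no lipid-tube deformation analysis.
* The mmCIF reader covers the `atom_site` loop of standard
  coordinate files, not arbitrary CIF dialects.
* SASA is quadrature-based, not analytic; per-atom areas carry the
  orientation sensitivity noted above.
* The interface classification rule is a deterministic surrogate for
  expert assignment; borderline mixed contacts land in `unclassified`
  rather than being forced.
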