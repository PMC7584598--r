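# dynhelix

Structural post-processing of dynamin-2 oligomer ensembles in R.

Dynamin-2 (dyn-2) is a large GTPase that oligomerizes into helices around
membrane necks and catalyzes membrane fission.  The centronuclear-myopathy
mutation R465W, sitting halfway along helix αS3 of the stalk, perturbs the
monomer's local interaction network and propagates allosterically into the
monomer-monomer interfaces and the bending of the bundle signaling element
(BSE).  Quantifying those effects from simulation output requires a stack of
geometric measurements that `dynhelix` implements as a tested, reusable
package:

* **Interfaces** — residue-level contact detection at a 6 Å
  closest-particle cutoff; deterministic classification into the four
  interface types of the dynamin helix (G–G across rungs, interface-1
  stalk/BSE, interface-2 crisscross stalk–stalk, interface-3 L1N^S loop);
  interface areas from solvent-accessible surface area; residue occupancy
  (the fraction of interface observations in which a residue participates);
  hydrogen-bond and salt-bridge counts on full-atom input; and the
  residue-465 ↔ neighbor-BSE interaction.
* **SASA** — Shrake–Rupley quadrature on a deterministic spiral point set
  (probe 1.4 Å, 960 points/sphere by default), normalized per residue by
  empirical Gly-X-Gly maximal accessibilities.
* **Inter-domain angles** — the G-BSE angle (vertex at the centroid of
  residues 291–293, arms to the centroids of 277–285 and 299–306; ~118°
  bent/WT-like vs ~150° extended/mutant-like) and the BSE-stalk angle
  (vertex at the pooled hinge centroid 315–321 ∪ 702–711, arms to the
  G-domain and stalk centers), plus the per-pair G–G asymmetry
  Δ = |θ_a − θ_b| of window-averaged G-BSE angles.
* **Helix geometry** — axis fitting by radial-variance minimization,
  diameter, pitch, helix (pitch) angle θ = arctan(rise / (r·Δφ)),
  monomers per turn, and per-tetramer radius-of-gyration series.
* **Synthetic assemblies** — a deterministic, seedable generator of
  reduced-residue pseudo-dynamin monomers, crisscross dimers, 56-monomer
  helices (4 rungs × 14 monomers, 14 tetramers, engineered G–G,
  interface-2 and 465/BSE contacts) and a 13.7 nm lipid-head nanotube, all
  with ground-truth labels so every estimator is validated by parameter
  recovery.
* **Group statistics** — one-way ANOVA with Tukey HSD and Kruskal–Wallis
  with Dunn's post-hoc (Holm adjustment), operating on per-monomer window
  means.

## Worked example

Generate a WT and a hetero (28 WT + 28 R465W, strictly intercalated) helix,
measure angles, and compare groups:

```r
library(dynhelix)
groups <- list(
  WT = build_helix(genotype_pattern = "all_wt",      n_frames = 10,
                   noise_sigma_A = 0.5, seed = 1),
  HT = build_helix(genotype_pattern = "alternating", n_frames = 10,
                   noise_sigma_A = 0.5, seed = 2))
res <- run_analysis(groups, analyses = c("angles", "helix"))
res$comparisons$g_bse
```

```
Group comparison of 'g_bse' (kw_dunn)
  group  n     mean   median      q25      q75      min      max
     WT 56 117.8165 117.7346 117.4443 118.4290 115.0172 119.8576
 HT.MUT 28 149.6780 149.4039 148.6146 150.9893 148.0115 151.7758
  HT.WT 28 118.0301 117.8460 117.3559 118.4570 115.9732 120.6200
omnibus: statistic = 62.512, p = 2.66e-14
 group1 group2   estimate        p_adj
     WT HT.MUT -7.5380293 1.431380e-13
     WT  HT.WT -0.2637004 7.920108e-01
 HT.MUT  HT.WT  6.2997537 5.962381e-10
```

The mixed-genotype HT group is split into WT and mutant statistical units;
both WT populations recover the bent ~118° G-BSE target while the mutants
sit at the extended ~150° target, and only the mutant-vs-WT pairs are
flagged (Dunn z statistics, Holm-adjusted).  The same bundle carries the
helix lattice parameters:

```r
hp <- res$groups$WT$helix
sprintf("WT helix: diameter %.1f A, pitch %.1f A, helix angle %.2f deg",
        mean(hp$diameter_A), mean(hp$pitch_A), mean(hp$helix_angle_deg))
#> "WT helix: diameter 360.0 A, pitch 56.0 A, helix angle 2.83 deg"
```

Structures round-trip through multi-model mmCIF/PDB (`read_structure`,
`write_structure`); `run_analysis(..., outdir = "out")` writes the angle,
asymmetry, helix, Rg, SASA, interface, occupancy, bond and comparison
tables as CSV together with a run log, and `render_reports()` draws
violin/box, occupancy-heatmap and trace figures.  A thin command-line
front-end lives in `inst/cli/dynhelix.R`
(`analyze --config run.yaml`, `synth helix --out h.cif`, `compare --csv
values.csv`).

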