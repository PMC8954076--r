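# betashape

Shape-theory analysis of betalain antioxidants: Riemannian shape
distances between molecular conformers, thermodynamic-cycle antioxidant
descriptors with mechanism classification, and similarity-invariant
ligand preparation for molecular docking.

## Who this is for

Computational chemists studying radical-scavenging antioxidants
(betanin, betanidin, their C15 epimers, and anything structurally
similar) who already have optimized geometries and species enthalpies
from a quantum-chemistry code and want to:

1. quantify how far each deprotonated anion moves from its parent in
   Kendall shape space, globally and per chemical element;
2. compute BDE / PA / ETE / IP / PDE, rank deprotonation sites, and
   decide between the HAT, SPLET and SET-PT mechanisms;
3. prepare chirality-safe canonical ligand orientations and a
   ten-member rotation ensemble for AutoDock-Vina-style docking.

## The core quantities

A molecule of *k* atoms is a *k* x 3 matrix. Its **preshape** removes
translation and scale; the **Riemannian distance** between two
preshapes Z_A, Z_B is the angle after optimal proper-rotation
alignment: with the SVD Z_A' Z_B = U L V',

    RD = arccos(l1 + l2 ± l3)  in  [0, pi/2],

the smallest singular value negated when det(UV') < 0 (reflections are
excluded by default, so chirality is discriminated; a
reflection-allowing mode is also exposed).

The five descriptors, from species enthalpies in water
(H(H+) = -259.00, H(e-) = -55.61, H(H•) = -314.65 kcal/mol):

    BDE = H(ArO•)  + H(H•) - H(ArOH)        (HAT)
    PA  = H(ArO-)  + H(H+) - H(ArOH)        (SPLET, step 1)
    ETE = H(ArO•)  + H(e-) - H(ArO-)        (SPLET, step 2)
    IP  = H(ArOH•+) + H(e-) - H(ArOH)       (SET-PT, step 1)
    PDE = H(ArO•)  + H(H+) - H(ArOH•+)      (SET-PT, step 2)

Every row must satisfy BDE - PA - ETE = BDE - IP - PDE = -0.04 kcal/mol
exactly; `cycle_residuals()` checks this and flags rows that cannot
have been produced by any enthalpy set.

## Worked example

```r
library(betashape)

# published descriptor values ship with the package as plain text
isobd <- as_descriptor_table(betalain_descriptors("IsoBd"), "IsoBd")
classify_mechanism(isobd)
#> $mechanism
#> [1] "SPLET"
#> $values
#>    HAT  SPLET SET-PT
#>   70.6   10.8   74.8
#> $site
#> [1] "C17"
rank_sites(isobd)         # ascending proton affinity
#> [1] "C17" "C15" "C2"  "C5"  "N16" "C6"
```

SPLET wins because the smallest proton affinity (10.8 kcal/mol, at the
C17 carboxyl) is far below the smallest BDE (70.6) and the IP (74.8):
in water, losing the C17 proton first is the cheapest route. The same
check on betanidin exposes a defect in the published table:

```r
cycle_residuals(as_descriptor_table(betalain_descriptors("Bd"), "Bd"))
#>   site splet_residual setpt_residual splet_ok setpt_ok
#> 1   C2           0.04           0.04     TRUE     TRUE
#> 2  C15           0.04           4.64     TRUE    FALSE
#> 3  C17           0.04          -4.56     TRUE    FALSE
#> ...
```

The C15/C17 PDE cells break the SET-PT cycle by exactly +-4.6 kcal/mol
— the signature of two swapped table cells. They are flagged, never
silently corrected.

Shape distances on a synthetic parent/anion pair (the same calls work
on real XYZ/PDB/SDF/PDBQT files via `read_structure()`):

```r
parent <- random_molecule(12, elements = c("C", "O", "H"), seed = 1)
ap <- make_anion_pair(parent, which(parent$elements == "H")[1],
                      sigma = 0.02, seed = 2)
riemannian_distance(parent, ap$variant, map = ap$map)
#> <shape_distance> rd = 0.008 rad (proper_rotation, 11 atoms, refit subspaces)
#>   by element: C = 0.006, O = 0.006, H = 0.005
```

An rd of 0.008 is the scale real parent-to-anion relaxations show
(published values run 0.007-0.070); 0 means identical shapes, pi/2
maximally different. Docking preparation:

```r
ct <- canonical_template(parent)
ct$frame
#> <template_frame> baseline atoms (6, 12); axis variances 12.895 >= 6.625 >= 4.560 A^2
ens <- rotation_ensemble(ct$template)
emit_docking_job(ens, receptor = "receptor.pdbqt", outdir = "job")
# -> 10 ligand files, 10 Vina configs (box 20x20x20 A at (26,10,118)),
#    manifest.tsv; after docking: collate_scores(...)
```

A command-line wrapper is installed as `exec/betashape` with
subcommands `rd`, `descriptors`, `template`, `dock-prep`, `collate`.

## What this package does not do

Quantum chemistry (geometries and enthalpies are inputs), the docking
search itself (configurations out, scores in), receptor preparation,
and molecular dynamics. See `vignettes/betashape-methods.Rmd` for the
full methods account, tolerances and design decisions.
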