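---
title: "Shape distances, antioxidant descriptors and docking frames: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape distances, antioxidant descriptors and docking frames: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betashape)
```

# The problem

Betalain pigments (betanin, betanidin and their C15 epimers) scavenge
free radicals by giving up a hydrogen from one of several acidic sites
(the C2, C15 and C17 carboxyls, the ring hydroxyls, the N16 amine).
Which site reacts first, and by which mechanism — one-step hydrogen
atom transfer (HAT), deprotonation followed by electron transfer
(SPLET), or electron transfer followed by deprotonation (SET-PT) — is a
thermodynamic question answered by enthalpy differences between the
parent molecule and its radical, anion and cation-radical species.
`betashape` takes those species enthalpies (produced upstream by any
quantum-chemistry code; this package does no electronic-structure
work), computes the standard descriptors, and adds a geometric layer:
the Riemannian shape distance between a parent molecule and each of its
deprotonated anions, which empirically preserves the proton-affinity
ordering of the sites. A third layer prepares ligands for docking in a
similarity-invariant orientation.

# Shape distance

A molecule of $k$ atoms is a $k \times 3$ configuration matrix. Its
*preshape* removes translation (centering at the centroid) and scale
(division by the centroid size $s = \lVert X - \bar{X} \rVert_F$),
leaving a point on a unit hypersphere. The *Riemannian distance* (RD)
between two preshapes $Z_A$, $Z_B$ is the angle between them after
optimal rotation alignment. With the SVD
$Z_A^\top Z_B = U \Lambda V^\top$,
$\lambda_1 \ge \lambda_2 \ge \lambda_3 \ge 0$:

$$\mathrm{RD} = \arccos\left(\lambda_1 + \lambda_2 \pm
\lambda_3\right) \in [0, \pi/2],$$

where the smallest singular value is negated when
$\det(UV^\top) < 0$ in the default `proper_rotation` mode, so that only
proper rotations are searched and a chiral configuration is never
matched onto its mirror image. `allow_reflection` mode uses the plain
sum. Both modes are exposed because either convention appears in the
shape literature; the default is proper rotation, since collapsing
mirror images would blunt exactly the C15-epimer distinctions this
analysis is about.

**Numerical note.** We do not literally evaluate the arccosine. For
nearly identical shapes $\cos(\mathrm{RD}) \to 1$ and arccos loses half
the significant digits (an RD of order $10^{-8}$ appears for bitwise
identical inputs). The implementation computes the chord under the
optimal rotation, $c = \lVert Z_A - Z_B R^\top \rVert_F$, and returns
$2 \arcsin(c/2)$, which is algebraically identical and accurate near
zero. The arccos argument is still monitored: it must never exceed
$1 + 10^{-12}$ on valid input.

**Atom correspondence.** An anion has one hydrogen fewer than its
parent. The package assumes the ordering is shared apart from that one
deletion (`match_atoms()`), optionally disambiguated by the
deprotonation-site label (nearest hydrogen to that heavy atom), and
always overridable by an explicit two-column map file. How the original
study matched atoms is not recorded anywhere we could consult, so the
default here is one documented choice, not a claim about that
procedure.

**Element subspaces.** Per-element RDs (O, C, H) are computed for every
element with at least three matched atoms; smaller subsets are skipped
with a warning (nitrogen, with 2–3 atoms in these compounds, typically
drops out). Two conventions are offered: `refit = TRUE` (default) runs
an independent Procrustes fit per element, `refit = FALSE` inherits the
global rotation and measures the subspace angle under it. The published
per-element values do not say which convention produced them, hence
both are first-class.

**Oracle.** `rd_oracle()` maximizes the preshape inner product over
unit quaternions by multi-start BFGS — no SVD anywhere in the path — and
is held to $|{\rm rd} - {\rm oracle}| \le 10^{-6}$ over hundreds of
random instances in the test suite. It exists purely as an independent
check and should not be used at scale.

# Thermodynamic descriptors

With reference aqueous enthalpies $H(\mathrm{H}^+) = -259.00$,
$H(e^-) = -55.61$, $H(\mathrm{H}^\bullet) = -314.65$ kcal/mol
(overridable in `reference_enthalpies()`):

$$\mathrm{BDE} = H(\mathrm{ArO}^\bullet) + H(\mathrm{H}^\bullet) -
H(\mathrm{ArOH})$$
$$\mathrm{PA} = H(\mathrm{ArO}^-) + H(\mathrm{H}^+) - H(\mathrm{ArOH}),
\quad \mathrm{ETE} = H(\mathrm{ArO}^\bullet) + H(e^-) -
H(\mathrm{ArO}^-)$$
$$\mathrm{IP} = H(\mathrm{ArOH}^{\bullet+}) + H(e^-) -
H(\mathrm{ArOH}), \quad \mathrm{PDE} = H(\mathrm{ArO}^\bullet) +
H(\mathrm{H}^+) - H(\mathrm{ArOH}^{\bullet+})$$

Hartree inputs convert at 627.5095 kcal/mol per hartree (the reference
sources do not state a factor; this is the CODATA-derived constant).
The two-step routes must close onto the one-step route exactly:

$$\mathrm{BDE} - \mathrm{PA} - \mathrm{ETE} = \mathrm{BDE} -
\mathrm{IP} - \mathrm{PDE} = \delta = H(\mathrm{H}^\bullet) -
H(\mathrm{H}^+) - H(e^-) = -0.04\ \mathrm{kcal/mol}.$$

`cycle_residuals()` enforces this at $10^{-10}$ for internally computed
tables and at 0.15 kcal/mol for externally supplied tables rounded to
one decimal (three half-unit roundings cannot exceed that). Flagged
rows are reported, never corrected: in the shipped published table the
betanidin C15/C17 PDE pair fails by $\pm 4.6$ kcal/mol — exactly the
signature of two swapped cells — and the acceptance suite pins that
flag set.

`classify_mechanism()` compares min-site BDE (HAT), min-site PA
(SPLET) and IP (SET-PT) and returns the smallest. Ties resolve in the
order SPLET, HAT, SET-PT — SPLET first because the package's domain is
aqueous-phase chemistry where proton loss is cheapest — and are always
reported. `rank_sites()` orders sites ascending with stable tie
handling. `rd_pa_concordance()` reports the Kendall rank correlation
between PA and global RD with the discordant pairs listed.

# Canonical ligand frame and rotation ensemble

Docking engines are given ligand coordinates in an arbitrary frame; two
runs from two frames of the same ligand are redundant or, worse,
incomparable. The canonical frame makes the input a function of shape
alone. Plain principal axes would do, except that eigenvectors are
defined only up to sign, so a naive PCA can silently reflect the ligand
and destroy its chirality. The construction here:

1. center at the centroid;
2. rotate so coordinate variances decrease along x, y, z (covariance
   eigenstructure defines the axes);
3. fix signs deterministically: the smaller-index atom of the farthest
   pair (the *baseline*) gets non-positive x; the atom of maximal |y|
   gets positive y (ties to the smaller index); the z sign is forced by
   $\det = +1$.

The result is idempotent, invariant under proper rigid motions to
$10^{-8}$ Å, scale-equivariant (physical Å dimensions are never
normalized — docking needs them), and provably reflection-free. When
two coordinate variances tie within $10^{-9}$ (relative) the principal
directions are not unique; the frame then uses the baseline direction
itself as the x axis and warns. The baseline-plus-variability design
resolves the ordering/reflection ambiguity that pure PCA leaves while
using both geometric ideas the method is built on.

`rotation_ensemble()` adds nine rigid copies: quarter-turn rotations
(90/180/270 degrees) in the xy, xz and yz planes, i.e. about the z, y
and x axes, about the template centroid. The rotation center is a
design choice (the construction itself does not dictate one); the
centroid keeps every member inside the same pocket neighborhood,
whereas rotating about the box center would translate the ligand away.
Quarter-turn sines/cosines are exact 0/±1, so ensemble closure
($\mathrm{xy90}^4 = \mathrm{id}$) holds bit-for-bit.
`emit_docking_job()` writes the ten ligands, one engine configuration
each (default grid box 20 x 20 x 20 Å centered at (26, 10, 118) — the
xanthine-oxidase active site around the molybdopterin cofactor — all
overridable) and a manifest; `collate_scores()` reads the engine's
output back. Receptor preparation (chain pruning, polar hydrogens) is
deliberately manual and external.

# Synthetic data

The generator exists so every code path is testable offline; it states
a world and stays there:

- `random_molecule()`: coordinates uniform in a 10 Å cube, elements
  assigned in order, pure function of its seed. A 10 Å cube matches the
  spatial extent of drug-like ligands; uniformity is deliberate — no
  claim of chemical realism (no bonding, no minimum distances).
- `make_anion_pair()`: deletes one named hydrogen and perturbs every
  remaining atom by an isotropic Gaussian (default $\sigma = 0.02$ Å,
  the scale of the relaxation shifts implied by published
  parent-to-anion RDs of 0.007–0.036 on molecules of this size).
  $\sigma = 0$ is exactly rd-null; the mean RD increases with $\sigma$,
  and the suite checks that monotonicity over 100 replicates.
- `synth_enthalpy_table()`: inverse-constructs species enthalpies from
  chosen (BDE, PA, IP) targets, so descriptor recovery is exact to
  $10^{-10}$ by construction — this is the oracle for the descriptor
  equations.

A green synthetic test establishes internal consistency (equations,
invariances, exact inverses); it does not establish anything about
DFT-optimized geometries, which enter only through user-supplied files.

# Degenerate inputs, tolerances, tie breaks

- Preshape requires $k \ge 3$ and positive centroid size; coincident
  atoms are an error, collinear configurations are allowed but flagged.
- Element subspaces need $\ge 3$ matched atoms, else skipped with a
  warning; an explicit global `subset` below 3 atoms is an error.
- Farthest-pair ties: lexicographically smallest index pair.
- Site-ranking ties: input order, with a reported `ties` attribute.
- The arccos-argument guard ($|x| \le 1 + 10^{-12}$), the preshape
  centering/norm tolerances ($10^{-12}$), the frame invariance budget
  ($10^{-8}$ Å over 100 random motions) and the oracle agreement bound
  ($10^{-6}$) are all asserted in the test suite at those values.

# Known limitations

- No quantum chemistry: enthalpies and optimized geometries are inputs.
- No docking engine: configurations are emitted and scores collated,
  the search itself is external. The published affinity comparisons
  therefore cannot be reproduced by this package alone, and the two
  acceptance checks that need the deposited geometries or a docking
  engine fail loudly (not silently skipped) in an offline run.
- Atom correspondence is ordinal, not graph-based; heavily reordered
  conformer files need an explicit map.
- PDB/PDBQT parsing is fixed-column and coordinate-centric; occupancy,
  anisotropy, multi-model files and connectivity are out of scope.
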