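---
title: "Methods: comparing experimental and predicted multi-domain receptor structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing experimental and predicted multi-domain receptor structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrcompare)
```

# The measurement problem

Nuclear receptors are modular: a zinc-finger DNA-binding domain (DBD) and a
helical ligand-binding domain (LBD) joined by a hinge that is flexible in
solution and often unresolved in crystals. Within-domain folds are predicted
almost perfectly by modern structure predictors; the open questions are
relative domain *placement*, the geometry of the ligand-binding pocket, and
whether per-residue confidence tracks behave like experimental quality
metrics. Each package module measures one of these aspects; this vignette
records the models, the tunable parameters, the numerical choices, and what
the synthetic fixtures do and do not establish.

Every analysis is framed by configured **domain spans** — inclusive author
residue number intervals per chain. Spans are deliberately an input, not an
inference: domain boundaries are a curation decision (UniProt-style
annotations are the natural source for real receptors), and making them
explicit is what makes runs reproducible. DBD and LBD spans must be
disjoint; the hinge is never modeled as a path, only summarized by a
derived midpoint (below).

# Superposition and RMSD

`kabsch_superpose()` computes the least-squares rigid transform by the
Kabsch/SVD construction, with the determinant correction that excludes
improper rotations. The three-level analysis (`rmsd_triple()`) fits
all-atom, backbone (N, CA, C, O) and C$\alpha$ selections *independently* —
reusing one level's transform for another would hide exactly the
level-specific deviations the hierarchy diagnostic looks for. The expected
ordering all-atom > backbone > C$\alpha$ is tested strictly, so ties count
as exceptions.

Residue pairing is by author-number correspondence within the span. The
compared chains carry the same protein sequence, which makes
structure-based dynamic-programming alignment redundant; what such aligners
add in practice is outlier trimming, emulated here by iterative rejection:
after each fit, atom pairs farther than `reject_cutoff` (default 2.0 Å) are
removed and the fit repeated, up to `max_cycles` (default 5) or
convergence. The defaults are declared, not derived — published
sequence-independent aligners do not document their exact trimming
schedule, so absolute RMSDs can differ from theirs in the second decimal.
`max_cycles = 0` gives the plain fit. Atoms present in only one structure
(missing density) are simply not paired; the surviving pair count is
reported alongside every RMSD.

# Secondary structure

`assign_sse()` re-implements the electrostatic hydrogen-bond model:
the amide H is placed 1 Å from N opposite the preceding carbonyl, and a
CO(i)→NH(j) bond exists when
$E = 27.888\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN}) < -0.5$ kcal/mol.
The 8-state repertoire is collapsed to three: only 4-turn ($i \to i+4$)
helices count as H; parallel/antiparallel bridge patterns (including
isolated bridges) count as S; $3_{10}$ and $\pi$ helices fall into L. This
matches the coarse H/S/L reporting convention of molecular viewers but can
differ from any particular viewer's assignment by a few percent — the same
order of magnitude as the helix-content differences the comparison is meant
to detect, which is why compositional claims should always be read as
*within-method* contrasts (experimental vs predicted under one assignment),
never absolute percentages. Proline cannot donate; chain breaks (CA–CA
> 4.5 Å) sever all patterns.

# Domain architecture descriptors

Three numbers summarize one chain's architecture: $\varepsilon$ = distance
between the domain centers of mass; $\theta$ = angle at the hinge point;
$DH$ = torsion of (DBD$_{COM}$, DBD$_{C\alpha L}$, LBD$_{C\alpha F}$,
LBD$_{COM}$) about the boundary-C$\alpha$ axis, IUPAC sign convention
(counterclockwise rotations negative), range $(-180, 180]$.

Choices that move the numbers:

* **COM weighting.** Mass-weighted with standard atomic masses (the
  convention of the scripting ecosystems these measurements come from); a
  geometric-centroid option exists because the choice shifts $\varepsilon$
  by fractions of an Å on real domains.
* **Hinge point.** The unweighted midpoint of the last DBD C$\alpha$ and
  first LBD C$\alpha$ — a hinge stand-in that is robust to unresolved hinge
  residues. If a span-boundary residue lacks a C$\alpha$, the nearest
  present residue inside the span is used and reported.
* **Dispersion.** IQR uses Type-7 (linear interpolation) quantiles.
  Circular dispersion reports the mean resultant length $R$ and
  $\sigma_\theta = \sqrt{-2\ln R}$; at $R = 0$ (e.g. two opposite angles)
  $\sigma_\theta$ is reported as `Inf` with a warning rather than an error,
  since downstream tables must not lose the row.
* **Homodimer asymmetry.** Monomers of one receptor are called asymmetric
  when max $|\Delta\varepsilon|$ exceeds 5 Å — a reporting threshold chosen
  to separate the ~14 Å compact/extended splits seen in DNA-bound
  homodimers from sub-Å measurement noise; it is configuration, not
  biology.

# Pocket geometry

The solvent-excluded surface is built on a voxel grid (default 0.4 Å,
probe 1.4 Å): probe centers are admissible where they clear every van der
Waals sphere (Bondi radii); the probe-space component reachable from the
ligand seed points is found by 6-connected flood fill; dilating that
component by the probe radius gives the cavity bounded by the inner SES.
A fill that reaches the padded bounding box means the pocket opens into
bulk solvent — reported with a warning and no capping heuristic, because
any cap is a modeling decision the user should see. No reachable void means
"no pocket found" (the expected result for occluded apo pockets).

Numerical details that matter at this voxel size:

* Binary dilations use FFT convolution with discrete spherical kernels. A
  kernel enlarged by 0.15 voxel centers the quantization bias of the
  discrete ball; the constant was calibrated once against the analytic
  sphere fixtures and frozen.
* Volumes get a sub-voxel correction along the *contact* part of the
  boundary, where the exact signed distance to the vdW surface is known at
  voxel centers: boundary voxels contribute a linear partial volume.
  Reentrant (probe-sphere) boundary parts keep binary counting.
* Areas use the smoothed co-area estimator: Gaussian-smooth the region
  indicator ($\sigma = 1.2$ voxels) and integrate the gradient magnitude.
  This averages out the voxel staircase (a naive face count overestimates a
  sphere's area by ~50%) at a curvature bias of $O((\sigma/r)^2)$.
* On the analytic fixtures these choices give volumes within ~3% and areas
  within ~2%, with sphericity at most ~1% above the isoperimetric bound
  $\Psi \le 1$.

Shape statistics: $\Psi = \pi^{1/3}(6V)^{2/3}/A$ and $r_{eff} = 3V/A$.
Pocket volumes are additionally reported as percent of a designated
reference structure (conventionally the predicted model = 100%) and as
percentage deviations $(v_{pred} - v_{exp})/v_{exp} \times 100$. Absolute
volumes from any cavity detector are method-sensitive — grid placement,
probe handling and capping all move them — so cross-method comparisons
should use the normalized quantities.

# Validation tracks

pLDDT lives on 0–100 and RSCC on $[-1, 1]$; scaling pLDDT by 1/100 puts
both on a common range. The scaling is guarded against double application
(a track whose values are already all $\le 1$ is rejected). Track alignment
applies a constant per-chain numbering offset (identical sequences need no
alignment search) and intersects residue sets; missing residues stay
missing rather than zero-filled, because a zero RSCC is a strong claim
about density, not absence of data. Discrepancy flags use two thresholds:
kind A = RSCC > 0.9 but pLDDT < 0.7 (the experiment sees ordered density
where the model is unsure), kind B the converse. The 0.9/0.7 defaults
bracket the canonical worked example of this discrepancy pattern
(RSCC > 0.90 vs pLDDT 0.68) and are exposed as arguments.

# Torsional comparison

$\phi(i)$ = C(i−1)–N(i)–CA(i)–C(i), $\psi(i)$ = N(i)–CA(i)–C(i)–N(i+1);
termini and chain breaks leave angles undefined. Four agreement metrics per
angle: circular RMSD and MAE on the wrapped difference
$\Delta = ((a-b+180) \bmod 360) - 180$; Pearson correlation on the raw
paired angles (a per-residue reading — the magnitudes this produces match
per-residue, not distribution-level, correlation; a Fisher–Lee circular
correlation option exists because plain Pearson is seam-sensitive near
±180°); and the 1-D Wasserstein distance between the marginal samples,
computed exactly from the merged empirical CDFs. Wasserstein is evaluated
on the *linear* scale $[-180, 180)$: $\phi$ populations sit far from the
seam, $\psi$ only partially, so the linear reading can inflate $\psi$
distances for seam-straddling distributions — a documented divergence
source, not a bug.

## Ramachandran classification

Favored/allowed/outlier calls use contour levels enclosing 98% and 99.8%
of a reference density per residue class (general, glycine, proline,
pre-proline, Ile/Val). The reference here is a **synthetic** periodic
Gaussian-mixture model of the canonical basins, with levels calibrated by
numeric integration on a 2° grid — the empirically-derived high-resolution
survey tables that validation servers use cannot be redistributed with the
package. Consequences: calls agree with survey-based tools in basin cores
but can differ near contour edges, so absolute favored percentages are
model-specific, while *contrasts* between two structures classified under
the same model (the quantity of interest here) are meaningful. The
classes partition classifiable residues exactly:
favored + allowed-only + outliers = residues with both angles defined.

# The synthetic-data generator

The generator exists so that every stage has inputs with known truth:

* `make_ideal_helix()` / `make_ideal_sheet()` build poly-alanine chains by
  NeRF placement with standard bond geometry; the helix recovers its
  construction torsions to 1e-6°, and the sheet's antiparallel register
  (tuned once against the hydrogen-bond criterion, frozen constants) holds
  for 6–10 residue strands before intrinsic twist breaks the rigid-copy
  ladder.
* `make_two_domain_toy()` places two rigid helical domains so the measured
  ($\varepsilon$, $\theta$, $DH$) equal prescribed targets to machine
  precision: the second domain's COM is solved in a hinge-axis frame (the
  dihedral is affine in the azimuth about that axis, so the azimuth is
  obtained by calibration and inversion), and the hinge anchor distance is
  root-found so the rigid body's internal COM-to-anchor length is honored.
  Thirty-residue domains (arm lengths ~22 Å) keep the default target set
  feasible; infeasible targets error rather than approximate.
* `make_spherical_cavity()` places a Fibonacci shell of pseudo-carbons
  whose inner vdW surfaces bound a cavity of analytic volume
  $\tfrac{4}{3}\pi R^3$.
* `make_correlated_tracks()` draws bivariate normals at a target Pearson r
  and maps them affinely into [0,1] (affine maps preserve r; clipping at
  the boundaries is negligible at sd 0.12 around 0.5).
* `perturb_structure()` adds i.i.d. Gaussian noise per coordinate; all
  generators are deterministic given their seed and leave the caller's RNG
  state untouched.

What the toys do **not** emulate: real side-chain packing (only a
$\beta$-carbon is available, placed tetrahedrally), correlated displacement
fields (crystal-vs-prediction differences are locally correlated, not
i.i.d. — i.i.d. noise of matched RMSD therefore *overstates* torsional
disagreement), sequence heterogeneity, ligand chemistry, and crystal-lattice
effects. Passing tests on the toys establishes that the measurement stack
is correct, not that any predictor is accurate on real receptors.

The analysis workflow (`analysis/01...05`) runs the full comparison on a
four-receptor synthetic study set — including a homodimer in compact
(ε = 32 Å) and extended (ε = 46 Å) states whose "prediction" matches only
the extended one, mirroring the single-state behavior of interest. The
per-atom-class noise model (CA 0.06–0.08 Å, peptide atoms 0.10–0.12 Å,
CB 0.22–0.25 Å) yields sub-0.5 Å domain RMSDs with the conventional
all-atom > backbone > C$\alpha$ ordering.

# Problem sizes and determinism

The test and acceptance workloads are sized to run in minutes on one CPU:
1,000 random instances for the Kabsch-vs-quaternion agreement check, 50
seeds for noisy descriptor recovery, 1,000 replicates for the paired-t
null-rejection rate, cavity grids of ~10⁵–10⁶ voxels. Every stochastic
step takes an explicit seed; pipeline reruns with identical configuration
produce byte-identical CSVs (timestamps live only in the JSON manifest).

# Known limitations

* Absolute SSE percentages, pocket volumes and Ramachandran percentages
  are convention-dependent (assignment algorithm, cavity detector, contour
  tables); the package's comparative outputs are designed to be read
  within one convention.
* Residue pairing assumes identical sequences between compared chains; no
  support for homolog comparison or flexible/weighted superposition.
* NMR ensembles: first model only. RSCC is consumed from validation
  reports, never recomputed from density.
* Very open pockets are measured without capping and flagged; their
  volumes are sensitive to the bounding region.
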