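# nrcompare

Quantitative comparison of experimentally determined and AI-predicted
multi-domain protein structures, developed around full-length nuclear
receptors (NRs) — ligand-activated transcription factors built from a
DNA-binding domain (DBD), a flexible hinge, and a ligand-binding domain
(LBD). Structure-prediction models reproduce each domain's fold with
sub-Angstrom accuracy, but whether they capture *domain arrangement*,
*pocket geometry* and *local confidence* the way crystal structures do is a
separate, quantitative question. This package provides the full measurement
stack to answer it, plus a synthetic-structure generator with analytic
ground truth so every stage is testable offline.

## What it measures

For each experimental/predicted chain pair, per configured domain span:

* **Domain-wise RMSD** at three levels — all-atom, backbone (N, CA, C, O)
  and Cα — each independently superposed with the Kabsch algorithm plus
  iterative outlier rejection:
  `RMSD = sqrt( (1/N) Σᵢ ‖xᵢ − yᵢ‖² )` over the N aligned atom pairs.
  Summary statistics: CV = σ/μ × 100, Cohen's
  d = |μ₁ − μ₂| / sqrt((σ₁² + σ₂²)/2), paired t-tests, and the expected
  hierarchy all-atom > backbone > Cα with its exception count.
* **Secondary-structure composition** (α-helix / β-sheet / loop percentages
  per domain) from a Kabsch–Sander-style hydrogen-bond assignment, and the
  helix–loop compensation correlation r(H, L).
* **Domain-architecture descriptors**: inter-domain center-of-mass distance
  ε(DBD,LBD); hinge angle θ at the midpoint of the last DBD Cα and first
  LBD Cα; and the four-point inter-domain dihedral DH about the
  Cα(L)→Cα(F) axis. Dispersion via IQR and circular statistics
  (σθ = sqrt(−2 ln R), R the mean resultant length), plus the
  conformational similarity cos(ΔDH) and a homodimer-asymmetry report.
* **Ligand-binding-pocket geometry**: solvent-excluded (Connolly) volume V
  and area A by a voxelized SES construction (1.4 Å probe), sphericity
  Ψ = π^⅓ (6V)^⅔ / A, effective radius r_eff = 3V/A, percent-of-reference
  normalization and percentage deviations; Kruskal–Wallis tests, OLS
  regression and hierarchical clustering across pockets.
* **Validation tracks**: per-residue RSCC (from wwPDB validation reports),
  B-factors and pLDDT (scaled by 1/100), aligned on common numbering,
  correlated, and scanned for discrepant residues (confident experiment vs
  shaky prediction and the converse).
* **Backbone torsions**: φ/ψ with chain-break handling, circular RMSD/MAE,
  1-D Wasserstein distance, Pearson correlation, and Ramachandran
  favored/allowed/outlier tallies (98% / 99.8% contour levels from a
  synthetic Gaussian-mixture contour model; see the vignette for its
  relation to survey-derived tables).

## Worked example

```r
library(nrcompare)

# a two-domain toy built to a prescribed architecture, with side chains
toy <- make_two_domain_toy(n_residues = 30, target_epsilon = 46,
                           target_theta = 104, target_dihedral = -12,
                           sidechains = TRUE)
geo0 <- domain_geometry(toy$model$chains[["A"]], toy$spans$DBD, toy$spans$LBD)
# epsilon = 46.000 A, theta = 104.000 deg, DH = -12.000 deg   (exact recovery)

# a "predicted" counterpart: 0.12 A Gaussian coordinate noise
pred <- perturb_structure(toy$model$chains[["A"]], 0.12, seed = 42)
geo <- domain_geometry(pred, toy$spans$DBD, toy$spans$LBD)
# epsilon = 46.000 A, theta = 103.592 deg, DH = -10.278 deg

tr <- rmsd_triple(toy$model$chains[["A"]], pred, toy$spans$LBD)
# LBD RMSD: all-atom 0.209, backbone 0.204, CA 0.205 A

# an analytic spherical cavity of radius 5 A measured as a pocket
cav <- make_spherical_cavity(5)
pm <- pocket_metrics(cav, cav$hetero_groups, cutoff = 8)
# V = 538.0 A^3 (analytic 523.6), A = 317.1 A^2, Psi = 1.009, r_eff = 5.09 A
```

The inter-domain distance is insensitive to atomic noise (center-of-mass
averaging), the hinge angle moves by fractions of a degree, and the
dihedral — with the shortest lever arms — is the most noise-sensitive
descriptor; pocket metrics land within a few percent of the analytic sphere
and Ψ stays at its isoperimetric maximum of 1.

## Analysis workflow

`analysis/01_simulate.R` … `05_tracks_torsions.R` run the whole comparison
over a generated study set (four two-domain receptors, including an
asymmetric homodimer pair in compact/extended states) and write the stage
tables under `results/`: `rmsd.csv`, `sse.csv`, `geometry.csv`,
`pockets.csv`, `tracks.csv`, `torsions.csv`. `run_pipeline()` does the same
for any YAML-configured set of real structure files (PDB entries, AlphaFold
Database models, wwPDB validation XML) once those files are on disk.

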