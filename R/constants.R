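# Standard atomic masses (u) and Bondi van der Waals radii (Angstrom) for
# the elements found in protein/ligand structures. Unknown elements fall
# back to carbon values with a warning.

ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, CA = 40.078,
  MN = 54.938, CU = 63.546, "NA" = 22.990, K = 39.098, CL = 35.45,
  F = 18.998, BR = 79.904, I = 126.904
)

# Bondi (1964) vdW radii
VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  ZN = 1.39, FE = 1.40, MG = 1.73, CA = 1.70, MN = 1.40, CU = 1.40,
  "NA" = 2.27, K = 2.75
)

element_masses <- function(elements) {
  el <- toupper(elements)
  m <- ATOMIC_MASSES[el]
  if (anyNA(m)) {
    warning("unknown element(s) ", paste(unique(el[is.na(m)]), collapse = ", "),
            "; using carbon mass")
    m[is.na(m)] <- ATOMIC_MASSES[["C"]]
  }
  unname(m)
}

element_vdw_radii <- function(elements) {
  el <- toupper(elements)
  r <- VDW_RADII[el]
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(el[is.na(r)]), collapse = ", "),
            "; using carbon vdW radius")
    r[is.na(r)] <- VDW_RADII[["C"]]
  }
  unname(r)
}

# Engh & Huber style backbone geometry used by the synthetic builders
BB_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  omega = 180
)
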