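# Independent superposition oracle: Horn's closed-form quaternion method.
# Kept deliberately separate from the package's SVD-based Kabsch path.
horn_rmsd <- function(mobile, target) {
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(target, 2, colMeans(target))
  S <- crossprod(X, Y)
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  sqrt(mean(rowSums((X %*% t(R) - Y)^2)))
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

# apply a rigid transform to every atom of a chain_model
transform_chain <- function(chain, R, t) {
  at <- chain$atoms
  xyz <- cbind(at$x, at$y, at$z) %*% t(R) +
    matrix(t, nrow(at), 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  chain_model(chain$chain_id, at, chain$source_kind)
}

# hand-written 3-residue PDB fixture (one chain, complete backbones)
write_tiny_pdb <- function(path, altloc = FALSE) {
  lines <- c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       2.000   2.500   3.200  1.00 11.00           C",
    "ATOM      3  C   ALA A   1       3.100   1.900   2.800  1.00 12.00           C",
    "ATOM      4  O   ALA A   1       3.500   0.900   3.300  1.00 12.50           O",
    "ATOM      5  N   GLY A   2       3.700   2.500   1.900  1.00 13.00           N",
    "ATOM      6  CA  GLY A   2       4.800   2.000   1.400  1.00 14.00           C",
    "ATOM      7  C   GLY A   2       5.900   2.600   2.000  1.00 15.00           C",
    "ATOM      8  O   GLY A   2       6.000   3.800   2.100  1.00 15.50           O",
    "ATOM      9  N   SER A   3       6.800   1.800   2.400  1.00 16.00           N",
    "ATOM     10  CA  SER A   3       7.900   2.200   3.100  1.00 17.00           C",
    "ATOM     11  C   SER A   3       9.000   1.400   2.700  1.00 18.00           C",
    "ATOM     12  O   SER A   3       9.200   0.300   3.200  1.00 18.50           O")
  if (altloc) {
    lines <- c(lines,
    "ATOM     13  CB ASER A   3       8.100   3.600   3.000  0.70 19.00           C",
    "ATOM     14  CB BSER A   3       8.200   3.700   3.100  0.30 19.50           C")
  }
  writeLines(c(lines, "END"), path)
  path
}

# same three residues as mmCIF
write_tiny_cif <- function(path) {
  hdr <- c("data_test", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  rows <- c(
    "ATOM 1 N N . ALA A 1 1 ? 1.000 2.000 3.000 1.00 10.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 2.000 2.500 3.200 1.00 11.00 ? 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 3.100 1.900 2.800 1.00 12.00 ? 1 ALA A C 1",
    "ATOM 4 O O . ALA A 1 1 ? 3.500 0.900 3.300 1.00 12.50 ? 1 ALA A O 1",
    "ATOM 5 N N . GLY A 1 2 ? 3.700 2.500 1.900 1.00 13.00 ? 2 GLY A N 1",
    "ATOM 6 C CA . GLY A 1 2 ? 4.800 2.000 1.400 1.00 14.00 ? 2 GLY A CA 1",
    "ATOM 7 C C . GLY A 1 2 ? 5.900 2.600 2.000 1.00 15.00 ? 2 GLY A C 1",
    "ATOM 8 O O . GLY A 1 2 ? 6.000 3.800 2.100 1.00 15.50 ? 2 GLY A O 1",
    "ATOM 9 N N . SER A 1 3 ? 6.800 1.800 2.400 1.00 16.00 ? 3 SER A N 1",
    "ATOM 10 C CA . SER A 1 3 ? 7.900 2.200 3.100 1.00 17.00 ? 3 SER A CA 1",
    "ATOM 11 C C . SER A 1 3 ? 9.000 1.400 2.700 1.00 18.00 ? 3 SER A C 1",
    "ATOM 12 O O . SER A 1 3 ? 9.200 0.300 3.200 1.00 18.50 ? 3 SER A O 1")
  writeLines(c(hdr, rows), path)
  path
}

# minimal wwPDB-style validation XML with per-residue rscc entries
write_tiny_validation_xml <- function(path, chains = "A",
                                      resnums = list(c(1, 2, 3)),
                                      rsccs = list(c(0.95, 0.80, -0.10)),
                                      duplicate = FALSE) {
  rows <- character(0)
  for (k in seq_along(chains)) {
    for (i in seq_along(resnums[[k]])) {
      rows <- c(rows, sprintf(
        '  <ModelledSubgroup model="1" chain="%s" resnum="%d" resname="ALA" rscc="%.3f" rsr="0.1"/>',
        chains[k], resnums[[k]][i], rsccs[[k]][i]))
    }
  }
  if (duplicate) rows <- c(rows, rows[1])
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               "<wwPDB_validation_information>", "<Entry>", rows,
               "</Entry>", "</wwPDB_validation_information>"), path)
  path
}
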