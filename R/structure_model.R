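#' Uniform in-memory model for experimental and predicted structures
#'
#' A `ChainModel` stores one polymer chain as a flat atom table (one row per
#' atom) ordered by author residue number and insertion code; a
#' `StructureModel` bundles the chains of one PDB/AFDB entry together with its
#' hetero (ligand) groups. Hydrogens are excluded everywhere; at most one
#' atom per (residue, atom name) is kept after alternate-location resolution.
#'
#' @param chain_id single chain identifier string.
#' @param atoms data.frame with columns `auth_seq` (integer author residue
#'   number), `icode` (insertion code, `""` when absent), `res_name`
#'   (3-letter code), `name` (atom name, e.g. `"CA"`), `element` (element
#'   symbol), `x`, `y`, `z` (Angstrom), `b` (B-factor or raw pLDDT),
#'   `occ` (occupancy), `altloc` (single character, `""` when absent).
#' @param source_kind `"experimental"` or `"predicted"`; predicted models
#'   carry raw pLDDT (0-100) in the `b` column.
#' @return An object of class `chain_model`.
#' @export
chain_model <- function(chain_id, atoms, source_kind = c("experimental", "predicted")) {
  source_kind <- match.arg(source_kind)
  need <- c("auth_seq", "icode", "res_name", "name", "element",
            "x", "y", "z", "b", "occ", "altloc")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols) > 0)
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0) stop("chain '", chain_id, "' has no atoms")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite coordinates in chain '", chain_id, "'")
  if (any(atoms$occ < 0 | atoms$occ > 1, na.rm = TRUE))
    stop("occupancy outside [0,1] in chain '", chain_id, "'")
  atoms <- atoms[order(atoms$auth_seq, atoms$icode), , drop = FALSE]
  key <- paste(atoms$auth_seq, atoms$icode, atoms$name, atoms$altloc)
  if (anyDuplicated(key))
    stop("duplicate atom (auth_seq, icode, name, altloc) in chain '", chain_id, "'")
  rownames(atoms) <- NULL
  structure(list(chain_id = chain_id, atoms = atoms, source_kind = source_kind),
            class = "chain_model")
}

#' @rdname chain_model
#' @param identifier PDB or AlphaFold DB identifier.
#' @param chains list of `chain_model` objects.
#' @param hetero_groups data.frame of ligand atoms (same columns as `atoms`
#'   plus `chain`), or `NULL`.
#' @export
structure_model <- function(identifier, chains, hetero_groups = NULL) {
  ids <- vapply(chains, function(ch) ch$chain_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate chain ids in '", identifier, "'")
  names(chains) <- ids
  structure(list(identifier = identifier, chains = chains,
                 hetero_groups = hetero_groups),
            class = "structure_model")
}

#' @export
print.chain_model <- function(x, ...) {
  cat(sprintf("<chain %s: %d residues, %d atoms, %s>\n", x$chain_id,
              length(unique(paste(x$atoms$auth_seq, x$atoms$icode))),
              nrow(x$atoms), x$source_kind))
  invisible(x)
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure %s: %d chain(s)%s>\n", x$identifier, length(x$chains),
              if (!is.null(x$hetero_groups) && nrow(x$hetero_groups) > 0)
                sprintf(", %d hetero atoms", nrow(x$hetero_groups)) else ""))
  invisible(x)
}

#' Named residue interval used as the coordinate frame of every analysis
#'
#' @param domain_name one of `"DBD"`, `"LBD"`, `"Hinge"`.
#' @param start,end inclusive author residue numbers, `start <= end`.
#' @return An object of class `domain_span`.
#' @export
domain_span <- function(domain_name, start, end) {
  if (!domain_name %in% c("DBD", "LBD", "Hinge"))
    stop("domain_name must be DBD, LBD or Hinge")
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end)
    stop("invalid span: need start <= end")
  structure(list(domain_name = domain_name, start = start, end = end),
            class = "domain_span")
}

#' @export
print.domain_span <- function(x, ...) {
  cat(sprintf("<%s %d-%d>\n", x$domain_name, x$start, x$end))
  invisible(x)
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# residues (auth_seq/icode pairs) whose backbone N, CA, C, O are all present
backbone_complete_keys <- function(atoms) {
  bb <- atoms[atoms$name %in% BACKBONE_ATOMS, , drop = FALSE]
  key <- paste(bb$auth_seq, bb$icode, sep = "\r")
  cnt <- table(key[!duplicated(paste(key, bb$name))])
  names(cnt)[cnt == 4L]
}

#' Select the atoms of a domain from a chain
#'
#' Returns the atoms of residues with `start <= auth_seq <= end` in chain
#' order. In `backbone` and `ca` modes, residues with an incomplete backbone
#' (missing any of N, CA, C, O) are excluded; in `all` mode every atom is
#' kept, so composition counts are unaffected by missing backbone atoms.
#'
#' @param chain a [chain_model()].
#' @param span a [domain_span()].
#' @param atom_mode `"all"`, `"backbone"` (N, CA, C, O) or `"ca"`.
#' @return data.frame of atom rows (subset of `chain$atoms`).
#' @export
select_domain <- function(chain, span, atom_mode = c("all", "backbone", "ca")) {
  atom_mode <- match.arg(atom_mode)
  at <- chain$atoms
  at <- at[at$auth_seq >= span$start & at$auth_seq <= span$end, , drop = FALSE]
  if (atom_mode %in% c("backbone", "ca")) {
    keep <- backbone_complete_keys(at)
    at <- at[paste(at$auth_seq, at$icode, sep = "\r") %in% keep, , drop = FALSE]
    at <- at[at$name %in% (if (atom_mode == "ca") "CA" else BACKBONE_ATOMS), ,
             drop = FALSE]
  }
  if (nrow(at) == 0)
    stop(sprintf("empty selection for %s %d-%d (mode %s) on chain %s",
                 span$domain_name, span$start, span$end, atom_mode,
                 chain$chain_id))
  at
}

# coordinate matrix (n x 3) from an atom table
atoms_xyz <- function(atoms) {
  cbind(x = atoms$x, y = atoms$y, z = atoms$z)
}

#' Per-residue scalar track (RSCC, pLDDT or B-factor)
#'
#' @param metric_name one of `"RSCC"`, `"pLDDT"`, `"b_factor"`.
#' @param values named numeric vector, names = author residue numbers.
#'   Missing residues are simply absent, never zero-filled.
#' @return An object of class `per_residue_track`.
#' @export
per_residue_track <- function(metric_name, values) {
  if (!metric_name %in% c("RSCC", "pLDDT", "b_factor"))
    stop("metric_name must be RSCC, pLDDT or b_factor")
  if (is.null(names(values)) || anyNA(suppressWarnings(as.integer(names(values)))))
    stop("values must be named by integer author residue numbers")
  if (anyDuplicated(names(values)))
    stop("duplicate residue numbers in track")
  if (metric_name == "pLDDT" && any(values < 0 | values > 1))
    stop("scaled pLDDT values must lie in [0,1]")
  if (metric_name == "RSCC" && any(values < -1 | values > 1))
    stop("RSCC values must lie in [-1,1]")
  structure(list(metric_name = metric_name,
                 values = values[order(as.integer(names(values)))]),
            class = "per_residue_track")
}

#' @export
print.per_residue_track <- function(x, ...) {
  cat(sprintf("<%s track: %d residues (%s..%s)>\n", x$metric_name,
              length(x$values), names(x$values)[1],
              names(x$values)[length(x$values)]))
  invisible(x)
}
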