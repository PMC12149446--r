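#' Read a PDB or mmCIF structure file
#'
#' Parses the file (via bio3d) into a [structure_model()]: polymer atoms are
#' split by chain, hydrogens are dropped, alternate locations are resolved by
#' keeping the highest-occupancy altloc (ties broken alphabetically), author
#' numbering is preserved, and HETATM groups (excluding waters) are kept
#' separately as ligand candidates. For multi-model files only the first
#' model is read.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param fmt `"pdb"`, `"mmcif"` or `"auto"` (by file extension).
#' @param source_kind `"experimental"` or `"predicted"`; predicted models are
#'   expected to carry raw pLDDT (0-100) in the B-factor column.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, fmt = c("auto", "pdb", "mmcif"),
                           source_kind = c("experimental", "predicted")) {
  fmt <- match.arg(fmt)
  source_kind <- match.arg(source_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "auto") {
    fmt <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (fmt == "pdb") bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, multi = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse ", path, " as ", fmt, ": ",
                             conditionMessage(e)))
  at <- parsed$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$elesy[is.na(at$elesy) | at$elesy == ""] <-
    guess_element(at$elety[is.na(at$elesy) | at$elesy == ""])
  at <- at[!(toupper(at$elesy) %in% c("H", "D")), , drop = FALSE]

  df <- data.frame(chain = at$chain, auth_seq = as.integer(at$resno),
                   icode = at$insert, res_name = at$resid, name = at$elety,
                   element = toupper(at$elesy), x = at$x, y = at$y, z = at$z,
                   b = at$b, occ = at$o, altloc = at$alt, type = at$type,
                   stringsAsFactors = FALSE)
  df <- resolve_altloc(df)

  poly <- df[df$type == "ATOM", , drop = FALSE]
  het <- df[df$type == "HETATM" & !(df$res_name %in% c("HOH", "WAT", "DOD")), ,
            drop = FALSE]
  if (nrow(poly) == 0) stop("no polymer atoms in ", path)

  chains <- lapply(split(poly, poly$chain), function(sub) {
    chain_model(sub$chain[1],
                sub[, c("auth_seq", "icode", "res_name", "name", "element",
                        "x", "y", "z", "b", "occ", "altloc")],
                source_kind = source_kind)
  })
  hetero <- if (nrow(het) > 0)
    het[, c("chain", "auth_seq", "icode", "res_name", "name", "element",
            "x", "y", "z", "b", "occ", "altloc")] else NULL
  identifier <- sub("\\.(pdb|cif)(\\.gz)?$", "", basename(path),
                    ignore.case = TRUE)
  structure_model(identifier, chains, hetero)
}

# keep highest-occupancy altloc per (chain, residue, atom name); ties go to
# the alphabetically first altloc code
resolve_altloc <- function(df) {
  key <- paste(df$chain, df$auth_seq, df$icode, df$name, df$type, sep = "\r")
  if (!anyDuplicated(key)) return(df)
  ord <- order(key, -df$occ, df$altloc)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(key[ord]), , drop = FALSE]
  df[order(df$chain, df$auth_seq, df$icode), , drop = FALSE]
}

guess_element <- function(atom_names) {
  e <- substr(gsub("[0-9 ]", "", atom_names), 1, 1)
  e[e == ""] <- "C"
  e
}

#' Write a chain or structure to a PDB file
#'
#' Minimal fixed-width PDB writer used for synthetic fixtures; coordinates
#' are written at the PDB precision of 1e-3 Angstrom.
#'
#' @param x a [chain_model()] or [structure_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "chain_model")) x <- structure_model("synthetic", list(x))
  if (!inherits(x, "structure_model")) stop("x must be a chain or structure model")
  lines <- character(0)
  serial <- 0L
  fmt_atom <- function(rec, chain, at, het = FALSE) {
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            if (het) "HETATM" else "ATOM", rec,
            formatC(at$name, width = -4), "", at$res_name, chain,
            at$auth_seq, ifelse(at$icode == "", " ", at$icode),
            at$x, at$y, at$z, at$occ, at$b, at$element)
  }
  for (ch in x$chains) {
    for (i in seq_len(nrow(ch$atoms))) {
      serial <- serial + 1L
      lines <- c(lines, fmt_atom(serial, ch$chain_id, ch$atoms[i, ]))
    }
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d      %-3s %1s", serial,
                              ch$atoms$res_name[nrow(ch$atoms)], ch$chain_id))
  }
  hg <- x$hetero_groups
  if (!is.null(hg) && nrow(hg) > 0) {
    for (i in seq_len(nrow(hg))) {
      serial <- serial + 1L
      lines <- c(lines, fmt_atom(serial, hg$chain[i], hg[i, ], het = TRUE))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Extract the scaled pLDDT track of a predicted model
#'
#' AlphaFold models store the raw per-residue pLDDT (0-100) in the B-factor
#' column of every atom; the track value is the CA-atom value scaled by
#' 1/100 so that it shares the numerical range of RSCC. Applying the scaling
#' to an already-scaled model is rejected (all values <= 1).
#'
#' @param model a predicted [structure_model()].
#' @param chain_id chain to extract.
#' @return A [per_residue_track()] with `metric_name = "pLDDT"`.
#' @export
load_plddt_track <- function(model, chain_id) {
  ch <- model$chains[[chain_id]]
  if (is.null(ch)) stop("chain '", chain_id, "' not found in ", model$identifier)
  if (ch$source_kind != "predicted")
    stop("pLDDT track requires a predicted model (source_kind = 'predicted')")
  ca <- ch$atoms[ch$atoms$name == "CA", , drop = FALSE]
  if (nrow(ca) == 0) stop("no CA atoms in chain '", chain_id, "'")
  if (any(ca$b < 0 | ca$b > 100))
    stop("pLDDT value outside [0,100] in chain '", chain_id, "'")
  if (all(ca$b <= 1))
    stop("values already in [0,1]: pLDDT appears to be scaled already")
  vals <- ca$b / 100
  names(vals) <- ca$auth_seq
  per_residue_track("pLDDT", vals)
}

#' Extract the raw B-factor track of an experimental chain
#'
#' @param model a [structure_model()].
#' @param chain_id chain to extract.
#' @return A [per_residue_track()] with `metric_name = "b_factor"` holding
#'   CA-atom B-factors on author numbering.
#' @export
load_bfactor_track <- function(model, chain_id) {
  ch <- model$chains[[chain_id]]
  if (is.null(ch)) stop("chain '", chain_id, "' not found in ", model$identifier)
  ca <- ch$atoms[ch$atoms$name == "CA", , drop = FALSE]
  if (nrow(ca) == 0) stop("no CA atoms in chain '", chain_id, "'")
  vals <- ca$b
  names(vals) <- ca$auth_seq
  per_residue_track("b_factor", vals)
}

#' Read the per-residue RSCC track from a wwPDB validation report
#'
#' Parses the validation-report XML (`ModelledSubgroup` entries) and returns
#' the real-space correlation coefficient per residue of one chain, keyed by
#' author numbering. Residues without density statistics (no `rscc`
#' attribute) are omitted, never zero-filled.
#'
#' @param path path to the wwPDB validation XML.
#' @param chain_id chain identifier to extract.
#' @return A [per_residue_track()] with `metric_name = "RSCC"`.
#' @export
read_validation_rscc <- function(path, chain_id) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, ".//ModelledSubgroup[@rscc]")
  if (length(nodes) == 0)
    stop("no RSCC data: validation report has no per-residue rscc entries")
  chains <- xml2::xml_attr(nodes, "chain")
  nodes <- nodes[chains == chain_id]
  if (length(nodes) == 0)
    stop("no RSCC data for chain '", chain_id, "' in ", basename(path))
  resnum <- as.integer(xml2::xml_attr(nodes, "resnum"))
  rscc <- as.numeric(xml2::xml_attr(nodes, "rscc"))
  if (anyDuplicated(resnum))
    stop("duplicate RSCC entry for residue(s) ",
         paste(unique(resnum[duplicated(resnum)]), collapse = ", "))
  names(rscc) <- resnum
  per_residue_track("RSCC", rscc)
}
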