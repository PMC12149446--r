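#' Secondary structure content
#'
#' Per-residue H/S/L assignment from backbone hydrogen-bond patterns and
#' domain-wise composition percentages. The assignment is a Kabsch-Sander
#' style electrostatic hydrogen-bond model collapsed to three states:
#' only 4-turn (i -> i+4) alpha-helices count as H, bridge/ladder patterns
#' (parallel or antiparallel) count as S, everything else - including 3-10
#' and pi helices - is L.
#'
#' @name sse
NULL

# Kabsch-Sander H-bond energy constant (kcal/mol * A): 0.42 * 0.20 * 332
KS_Q1Q2F <- 27.888
KS_HBOND_CUTOFF <- -0.5

# Build per-residue backbone coordinate arrays plus a placed amide H:
# H = N + unit(C(i-1) - O(i-1)), the classical approximation when the
# hydrogen is absent from the model. Residues must be backbone-complete.
backbone_frames <- function(chain) {
  at <- chain$atoms
  keys <- unique(paste(at$auth_seq, at$icode, sep = "\r"))
  complete <- backbone_complete_keys(at)
  keys <- keys[keys %in% complete]
  n <- length(keys)
  get_atom <- function(name) {
    sub <- at[at$name == name, , drop = FALSE]
    idx <- match(keys, paste(sub$auth_seq, sub$icode, sep = "\r"))
    atoms_xyz(sub[idx, , drop = FALSE])
  }
  N <- get_atom("N"); CA <- get_atom("CA"); C <- get_atom("C"); O <- get_atom("O")
  auth_seq <- as.integer(sub("\r.*", "", keys))
  res_name <- at$res_name[match(keys, paste(at$auth_seq, at$icode, sep = "\r"))]
  # chain break between consecutive entries when CA-CA distance > 4.5 A
  brk <- c(FALSE, sqrt(rowSums((CA[-1, , drop = FALSE] -
                                CA[-n, , drop = FALSE])^2)) > 4.5)
  H <- N
  for (i in seq_len(n)) {
    if (i == 1 || brk[i]) { H[i, ] <- NA; next }
    co <- C[i - 1, ] - O[i - 1, ]
    H[i, ] <- N[i, ] + co / vec_norm(co)
  }
  list(N = N, CA = CA, C = C, O = O, H = H, auth_seq = auth_seq,
       res_name = res_name, brk = brk, n = n)
}

# n x n logical matrix: hbond[i, j] = CO of residue i accepts from NH of j
ks_hbond_matrix <- function(fr) {
  n <- fr$n
  hb <- matrix(FALSE, n, n)
  donor_ok <- !is.na(fr$H[, 1]) & fr$res_name != "PRO"
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) < 2 || !donor_ok[j]) next
      r_on <- vec_norm(fr$O[i, ] - fr$N[j, ])
      if (r_on > 5.2) next   # distance prefilter, generous vs. the cutoff
      r_ch <- vec_norm(fr$C[i, ] - fr$H[j, ])
      r_oh <- vec_norm(fr$O[i, ] - fr$H[j, ])
      r_cn <- vec_norm(fr$C[i, ] - fr$N[j, ])
      if (min(r_on, r_ch, r_oh, r_cn) < 0.5) { hb[i, j] <- TRUE; next }
      e <- KS_Q1Q2F * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
      hb[i, j] <- e < KS_HBOND_CUTOFF
    }
  }
  hb
}

#' Assign H/S/L secondary structure per residue
#'
#' @param chain a [chain_model()] with at least 5 backbone-complete residues.
#' @return character vector of labels (`"H"`, `"S"`, `"L"`) named by author
#'   residue number; only backbone-complete residues are labeled.
#' @export
assign_sse <- function(chain) {
  fr <- backbone_frames(chain)
  if (fr$n < 5) stop("chain too short: need >= 5 backbone-complete residues")
  hb <- ks_hbond_matrix(fr)
  n <- fr$n
  lab <- rep("L", n)

  # sequence adjacency that respects chain breaks
  adjacent <- function(i, j) j == i + 1 && !fr$brk[j]

  # alpha (4-turn) helices: turn4[i] <- HB(i -> i+4); two consecutive turns
  # make residues i+1..i+4 helical
  turn4 <- rep(FALSE, n)
  for (i in seq_len(n - 4)) {
    if (any(fr$brk[(i + 1):(i + 4)])) next
    turn4[i] <- hb[i, i + 4]
  }
  # the canonical rule marks residues i..i+3 helical when turns start at
  # both i-1 and i
  for (i in seq_len(n)) {
    if (i >= 2 && i <= n - 4 && turn4[i - 1] && turn4[i])
      lab[i:(i + 3)] <- "H"
  }

  # bridges: parallel / antiparallel Kabsch-Sander patterns
  is_bridge <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      if (abs(i - j) < 3) next
      par <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) || (hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (par || anti) { is_bridge[i] <- TRUE; is_bridge[j] <- TRUE }
    }
  }
  lab[is_bridge & lab != "H"] <- "S"
  names(lab) <- fr$auth_seq
  lab
}

#' Domain-wise H/S/L composition
#'
#' @param labels named label vector from [assign_sse()].
#' @param span a [domain_span()].
#' @return list with `helix_pct`, `sheet_pct`, `loop_pct` (each in
#'   \[0, 100\], summing to 100) and `n_residues`.
#' @export
sse_composition <- function(labels, span) {
  res <- as.integer(names(labels))
  sel <- labels[res >= span$start & res <= span$end]
  if (length(sel) == 0) stop("no labeled residues in span ", span$domain_name)
  list(helix_pct = 100 * mean(sel == "H"),
       sheet_pct = 100 * mean(sel == "S"),
       loop_pct = 100 * mean(sel == "L"),
       n_residues = length(sel))
}

#' Pearson correlation between helix and loop percentages
#'
#' The compensatory relation between helix and loop content across a
#' structure set is summarized by the Pearson correlation coefficient.
#'
#' @param h_values,l_values equal-length numeric vectors (percentages),
#'   length >= 3, each with nonzero variance.
#' @return correlation in [-1, 1].
#' @export
sse_pearson <- function(h_values, l_values) {
  if (length(h_values) != length(l_values)) stop("unequal lengths")
  if (length(h_values) < 3) stop("need at least 3 paired values")
  if (stats::sd(h_values) == 0 || stats::sd(l_values) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(h_values, l_values)
}
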