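#' Structure superposition and domain-wise RMSD
#'
#' Least-squares rigid superposition (Kabsch algorithm, SVD-based) with
#' optional iterative outlier rejection, and the three-level RMSD analysis
#' (all-atom, backbone, C-alpha) computed per domain. RMSD is
#' `sqrt(mean(|x_i - y_i|^2))` over the N aligned atom pairs after the
#' optimal rigid transform.
#'
#' @name superpose
NULL

#' Kabsch superposition of two coordinate sets
#'
#' Finds the rigid transform (proper rotation + translation) minimizing the
#' RMSD between paired coordinates, mobile onto target. The transform maps a
#' mobile coordinate row-vector `x` to `x %*% t(rotation) + translation`.
#'
#' @param mobile,target numeric n x 3 matrices, equal n >= 3.
#' @return list with `rotation` (3 x 3, det +1), `translation` (3-vector),
#'   `rmsd` (Angstrom), `n_pairs`, `cycles_run` (always 1 here).
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile)
  target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)))
    stop("coordinate sets differ in size (", nrow(mobile), " vs ",
         nrow(target), " atoms)")
  if (nrow(mobile) < 3) stop("need at least 3 atom pairs")
  cm_m <- colMeans(mobile)
  cm_t <- colMeans(target)
  X <- sweep(mobile, 2, cm_m)
  Y <- sweep(target, 2, cm_t)
  H <- crossprod(X, Y)                     # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) stop("degenerate coordinates: superposition is not unique")
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- X %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  translation <- as.numeric(cm_t - R %*% cm_m)
  list(rotation = R, translation = translation, rmsd = rmsd,
       n_pairs = nrow(mobile), cycles_run = 1L)
}

# apply a superposition result to an n x 3 coordinate matrix
apply_transform <- function(xyz, fit) {
  xyz %*% t(fit$rotation) + matrix(fit$translation, nrow(xyz), 3, byrow = TRUE)
}

#' Superposition with iterative outlier rejection
#'
#' Pairs atoms of two chains by author-number correspondence within a domain
#' span (the compared chains carry the same protein, so sequence alignment
#' is redundant), fits by [kabsch_superpose()], then repeatedly removes atom
#' pairs whose post-fit distance exceeds `reject_cutoff` and re-fits, until
#' convergence or `max_cycles` rejection rounds. This emulates the
#' refinement of sequence-independent structural aligners.
#'
#' @param mobile_chain,target_chain [chain_model()]s covering the span.
#' @param span a [domain_span()].
#' @param atom_mode `"all"`, `"backbone"` or `"ca"`.
#' @param max_cycles maximum rejection rounds (0 = plain Kabsch fit).
#' @param reject_cutoff post-fit distance cutoff in Angstrom.
#' @return As [kabsch_superpose()], with `n_pairs` the surviving pair count
#'   and `cycles_run` the number of fits performed.
#' @export
refined_superpose <- function(mobile_chain, target_chain, span,
                              atom_mode = c("all", "backbone", "ca"),
                              max_cycles = 5, reject_cutoff = 2.0) {
  atom_mode <- match.arg(atom_mode)
  am <- select_domain(mobile_chain, span, atom_mode)
  at <- select_domain(target_chain, span, atom_mode)
  key_m <- paste(am$auth_seq, am$icode, am$name)
  key_t <- paste(at$auth_seq, at$icode, at$name)
  common <- intersect(key_m, key_t)
  if (length(common) < 3)
    stop("fewer than 3 paired atoms in span ", span$domain_name)
  xm <- atoms_xyz(am[match(common, key_m), , drop = FALSE])
  xt <- atoms_xyz(at[match(common, key_t), , drop = FALSE])
  keep <- rep(TRUE, nrow(xm))
  fit <- kabsch_superpose(xm, xt)
  cycles <- 1L
  if (max_cycles > 0) {
    for (cyc in seq_len(max_cycles)) {
      d <- sqrt(rowSums((apply_transform(xm[keep, , drop = FALSE], fit) -
                         xt[keep, , drop = FALSE])^2))
      out <- d > reject_cutoff
      if (!any(out)) break
      keep[keep][out] <- FALSE
      if (sum(keep) < 3)
        stop("over-trimmed: fewer than 3 pairs survive outlier rejection")
      fit <- kabsch_superpose(xm[keep, , drop = FALSE],
                              xt[keep, , drop = FALSE])
      cycles <- cycles + 1L
    }
  }
  fit$n_pairs <- sum(keep)
  fit$n_rejected <- sum(!keep)
  fit$cycles_run <- cycles
  fit
}

#' Three-level RMSD of one domain
#'
#' Runs [refined_superpose()] independently in all-atom, backbone and
#' C-alpha modes over the same span — each level is fitted on its own atom
#' selection, never re-using another level's transform.
#'
#' @param exp_chain,pred_chain [chain_model()]s.
#' @param span a [domain_span()].
#' @param ... passed to [refined_superpose()] (`max_cycles`, `reject_cutoff`).
#' @return list with `all_atom`, `backbone`, `c_alpha` (Angstrom),
#'   `domain_name`, and per-mode pair counts `n_pairs`.
#' @export
rmsd_triple <- function(exp_chain, pred_chain, span, ...) {
  fits <- lapply(c(all = "all", backbone = "backbone", ca = "ca"),
                 function(m) refined_superpose(pred_chain, exp_chain, span,
                                               atom_mode = m, ...))
  list(all_atom = fits$all$rmsd, backbone = fits$backbone$rmsd,
       c_alpha = fits$ca$rmsd, domain_name = span$domain_name,
       n_pairs = vapply(fits, `[[`, integer(1), "n_pairs"))
}

#' Does a triple follow the expected RMSD hierarchy?
#'
#' The expected pattern is strict: all-atom > backbone > C-alpha. Exceptions
#' are counted across a structure set as a diagnostic.
#'
#' @param triple result of [rmsd_triple()] (or a list with `all_atom`,
#'   `backbone`, `c_alpha`).
#' @return `TRUE` iff `all_atom > backbone > c_alpha` strictly.
#' @export
hierarchy_check <- function(triple) {
  v <- c(triple$all_atom, triple$backbone, triple$c_alpha)
  if (!all(is.finite(v))) stop("non-finite RMSD values")
  v[1] > v[2] && v[2] > v[3]
}
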