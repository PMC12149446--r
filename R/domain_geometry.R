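#' Domain-architecture descriptors
#'
#' Multi-domain receptor architecture is summarized by three descriptors
#' computed from centers of mass (COM) and the boundary CA atoms of the two
#' domains: the inter-domain COM distance epsilon (Angstrom), the hinge
#' angle theta at the midpoint of the last DBD CA and the first LBD CA
#' (degrees), and the inter-domain dihedral DH about the axis joining those
#' two CA atoms (degrees, IUPAC sign convention).
#'
#' @name domain-geometry
NULL

#' Center of mass of an atom set
#'
#' @param atoms atom table (rows of a [chain_model()]'s `atoms`).
#' @param mode `"mass"` (standard atomic masses) or `"geometric"` (unweighted
#'   centroid). Mass weighting is the default convention; the geometric
#'   option shifts the result by fractions of an Angstrom on real domains.
#' @return 3-vector in Angstrom.
#' @export
center_of_mass <- function(atoms, mode = c("mass", "geometric")) {
  mode <- match.arg(mode)
  if (is.null(atoms) || nrow(atoms) == 0) stop("empty atom set")
  w <- if (mode == "mass") element_masses(atoms$element) else rep(1, nrow(atoms))
  unname(colSums(atoms_xyz(atoms) * w) / sum(w))
}

#' Inter-domain COM distance epsilon
#'
#' @param dbd_com,lbd_com 3-vectors (COM of each domain).
#' @return Euclidean distance in Angstrom.
#' @export
domain_distance <- function(dbd_com, lbd_com) {
  if (!all(is.finite(c(dbd_com, lbd_com)))) stop("non-finite COM")
  vec_norm(lbd_com - dbd_com)
}

#' Hinge reference point
#'
#' Unweighted midpoint of the last CA atom of the DBD and the first CA atom
#' of the LBD; a standardized hinge stand-in robust to missing hinge
#' residues.
#'
#' @param dbd_last_ca,lbd_first_ca CA coordinates (3-vectors).
#' @return 3-vector.
#' @export
hinge_com <- function(dbd_last_ca, lbd_first_ca) {
  if (!all(is.finite(c(dbd_last_ca, lbd_first_ca)))) stop("missing CA atom")
  (dbd_last_ca + lbd_first_ca) / 2
}

#' Hinge angle theta
#'
#' Angle at the hinge vertex between the two domain COMs, in [0, 180]
#' degrees.
#'
#' @param dbd_com,hinge,lbd_com 3-vectors.
#' @return angle in degrees.
#' @export
domain_angle <- function(dbd_com, hinge, lbd_com) {
  angle3(dbd_com, hinge, lbd_com)
}

#' Inter-domain dihedral DH
#'
#' Signed torsion of (DBD_COM, DBD_CaL, LBD_CaF, LBD_COM) about the
#' DBD_CaL -> LBD_CaF axis, IUPAC convention, in (-180, 180] degrees.
#'
#' @param dbd_com,dbd_ca_last,lbd_ca_first,lbd_com 3-vectors.
#' @return dihedral in degrees.
#' @export
domain_dihedral <- function(dbd_com, dbd_ca_last, lbd_ca_first, lbd_com) {
  torsion4(dbd_com, dbd_ca_last, lbd_ca_first, lbd_com)
}

#' All three descriptors of one chain
#'
#' Resolves the boundary CA atoms against the configured spans on residues
#' actually present: if the span boundary residue lacks a CA, the nearest
#' present residue inside the span is used (and reported).
#'
#' @param chain a [chain_model()].
#' @param dbd_span,lbd_span [domain_span()]s, disjoint.
#' @param com_mode forwarded to [center_of_mass()].
#' @return list with `epsilon`, `theta`, `dihedral`, the COMs and boundary
#'   CA atoms used, and the boundary residue numbers.
#' @export
domain_geometry <- function(chain, dbd_span, lbd_span, com_mode = "mass") {
  if (max(dbd_span$start, lbd_span$start) <= min(dbd_span$end, lbd_span$end))
    stop("DBD and LBD spans overlap")
  dbd_atoms <- select_domain(chain, dbd_span, "all")
  lbd_atoms <- select_domain(chain, lbd_span, "all")
  dbd_com <- center_of_mass(dbd_atoms, com_mode)
  lbd_com <- center_of_mass(lbd_atoms, com_mode)

  ca_last <- boundary_ca(dbd_atoms, "last")
  ca_first <- boundary_ca(lbd_atoms, "first")
  hinge <- hinge_com(ca_last$xyz, ca_first$xyz)
  list(epsilon = domain_distance(dbd_com, lbd_com),
       theta = domain_angle(dbd_com, hinge, lbd_com),
       dihedral = domain_dihedral(dbd_com, ca_last$xyz, ca_first$xyz, lbd_com),
       dbd_com = dbd_com, lbd_com = lbd_com, hinge = hinge,
       dbd_ca_last = ca_last$auth_seq, lbd_ca_first = ca_first$auth_seq)
}

boundary_ca <- function(atoms, which = c("first", "last")) {
  which <- match.arg(which)
  ca <- atoms[atoms$name == "CA", , drop = FALSE]
  if (nrow(ca) == 0) stop("no CA atom inside span")
  row <- if (which == "first") ca[1, ] else ca[nrow(ca), ]
  list(xyz = c(row$x, row$y, row$z), auth_seq = row$auth_seq)
}

#' Circular dispersion of a set of angles
#'
#' Mean resultant length R of the unit vectors and the circular standard
#' deviation sqrt(-2 ln R) in radians. R = 1 gives sd 0; R = 0 (e.g. two
#' opposite angles) gives infinite sd, reported as `Inf` with a warning.
#'
#' @param angles angles in degrees.
#' @return list with `mean_resultant_R`, `circular_sd` (radians), `n`.
#' @export
circular_dispersion <- function(angles) {
  if (length(angles) < 1) stop("need at least one angle")
  rad <- deg2rad(angles)
  R <- vec_norm(c(mean(cos(rad)), mean(sin(rad)), 0))
  if (R < 1e-12) {
    warning("mean resultant length is zero; circular sd is infinite")
    sd <- Inf
  } else {
    sd <- sqrt(-2 * log(min(R, 1)))
  }
  list(mean_resultant_R = R, circular_sd = sd, n = length(angles))
}

#' Conformational similarity of two dihedrals
#'
#' `cos(DH_a - DH_b)`: 1 for identical torsions, -1 for opposite ones.
#'
#' @param dh_a,dh_b dihedrals in degrees.
#' @return value in [-1, 1].
#' @export
conformational_similarity <- function(dh_a, dh_b) {
  if (!all(is.finite(c(dh_a, dh_b)))) stop("non-finite dihedral")
  cos(deg2rad(dh_a - dh_b))
}

#' Homodimer asymmetry report
#'
#' Compares the inter-domain distances of the monomers of one receptor and
#' flags marked asymmetry; optionally reports which experimental state a
#' predicted epsilon is nearest to.
#'
#' @param epsilons named numeric vector of per-monomer epsilon values
#'   (Angstrom), length >= 2.
#' @param predicted_epsilon optional predicted-model epsilon.
#' @param threshold asymmetry threshold on max |delta epsilon| (Angstrom).
#' @return list with `max_delta`, `asymmetric`, pairwise `deltas`, and (when
#'   a prediction is given) `nearest_state`.
#' @export
homodimer_asymmetry <- function(epsilons, predicted_epsilon = NULL,
                                threshold = 5) {
  if (length(epsilons) < 2) stop("need at least 2 monomers")
  if (is.null(names(epsilons))) names(epsilons) <- seq_along(epsilons)
  pairs <- utils::combn(names(epsilons), 2)
  deltas <- abs(epsilons[pairs[1, ]] - epsilons[pairs[2, ]])
  names(deltas) <- paste(pairs[1, ], pairs[2, ], sep = "-")
  out <- list(max_delta = max(deltas), asymmetric = max(deltas) > threshold,
              deltas = deltas, threshold = threshold)
  if (!is.null(predicted_epsilon)) {
    out$nearest_state <- names(epsilons)[which.min(abs(epsilons - predicted_epsilon))]
    out$predicted_epsilon <- predicted_epsilon
  }
  out
}
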