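#' Synthetic structure and track generators
#'
#' Every pipeline stage is testable without downloads through generators
#' that build structures, cavities and confidence tracks with known ground
#' truth. All generators are deterministic given their seed.
#'
#' @name synthetic
NULL

# Build a poly-alanine backbone (N, CA, C, O per residue) from per-residue
# (phi, psi) using NeRF placement with standard bond geometry; omega fixed
# at 180. phi[1] and psi[n] are not used in construction except to place the
# carbonyl O of the last residue.
build_backbone <- function(phi, psi, auth_seq = seq_along(phi),
                           chain_id = "A", res_name = "ALA",
                           sidechains = FALSE) {
  n <- length(phi)
  stopifnot(length(psi) == n, length(auth_seq) == n)
  g <- BB_GEOM
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  # first residue laid out in the xy-plane
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- deg2rad(g$a_n_ca_c)
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_n, g$a_ca_c_n, psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], g$b_n_ca, g$a_c_n_ca,
                              g$omega)
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], g$b_ca_c,
                             g$a_n_ca_c, phi[i + 1])
  }
  for (i in seq_len(n)) O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_o,
                                             g$a_ca_c_o, psi[i] + 180)
  per_res <- 4L
  names_res <- c("N", "CA", "C", "O")
  elems_res <- c("N", "C", "C", "O")
  blocks <- list(N, CA, C, O)
  if (sidechains) {
    # beta carbon at standard tetrahedral geometry off the backbone
    CB <- matrix(NA_real_, n, 3)
    for (i in seq_len(n))
      CB[i, ] <- place_atom(C[i, ], N[i, ], CA[i, ], 1.521, 110.4, -122.6)
    per_res <- 5L
    names_res <- c(names_res, "CB")
    elems_res <- c(elems_res, "C")
    blocks <- c(blocks, list(CB))
  }
  xyz <- do.call(rbind, blocks)
  ord <- as.vector(t(outer(seq_len(n), (seq_len(per_res) - 1) * n, "+")))
  xyz <- xyz[ord, , drop = FALSE]
  atoms <- data.frame(
    auth_seq = rep(as.integer(auth_seq), each = per_res), icode = "",
    res_name = res_name, name = rep(names_res, n),
    element = rep(elems_res, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b = 0, occ = 1, altloc = "", stringsAsFactors = FALSE)
  chain_model(chain_id, atoms, source_kind = "predicted")
}

#' Ideal poly-alanine alpha-helix
#'
#' Backbone built with exact internal (phi, psi, omega = 180) torsions and
#' standard bond lengths/angles, so that torsion recovery and hydrogen-bond
#' based secondary-structure assignment have a constructive ground truth.
#'
#' @param n number of residues (>= 5).
#' @param phi,psi backbone torsions in degrees (defaults: ideal alpha-helix).
#' @param chain_id,start_seq chain id and first author residue number.
#' @param sidechains add a beta carbon per residue (poly-alanine).
#' @return A [chain_model()].
#' @export
make_ideal_helix <- function(n, phi = -57, psi = -47, chain_id = "A",
                             start_seq = 1L, sidechains = FALSE) {
  if (n < 5) stop("need at least 5 residues")
  build_backbone(rep(phi, n), rep(psi, n),
                 auth_seq = seq.int(start_seq, length.out = n),
                 chain_id = chain_id, sidechains = sidechains)
}

#' Ideal two-strand antiparallel beta-sheet
#'
#' Two beta-region strands paired antiparallel: the partner strand is the
#' first strand rotated 180 degrees about the fitted sheet-plane normal
#' (which reverses the strand direction exactly even though the built
#' strand axis drifts slightly out of plane) and offset into
#' hydrogen-bonding register. The register offsets were tuned once against
#' the Kabsch-Sander energy criterion and frozen; they hold for strands of
#' roughly 6-10 residues, beyond which the intrinsic strand twist breaks
#' the rigid-copy ladder.
#'
#' @param n_per_strand residues per strand (4-10; default 8).
#' @return A [chain_model()] with the two strands separated by a numbering
#'   gap (no covalent connection; the gap is a chain break).
#' @export
make_ideal_sheet <- function(n_per_strand = 8) {
  if (n_per_strand < 4) stop("need at least 4 residues per strand")
  n <- n_per_strand
  s1 <- build_backbone(rep(-135, n), rep(135, n))
  a1 <- s1$atoms
  xyz <- atoms_xyz(a1)
  cen <- colMeans(xyz)
  nrm <- svd(sweep(xyz, 2, cen))$v[, 3]      # sheet-plane normal
  ca <- xyz[a1$name == "CA", , drop = FALSE]
  d <- unit_vec(ca[n, ] - ca[1, ])           # strand direction
  side <- cross3(nrm, d)
  R <- rotation_about_axis(nrm, pi)
  x2 <- t(R %*% t(sweep(xyz, 2, cen))) + rep(cen, each = nrow(xyz))
  shift <- SHEET_OFFSET[1] * d + SHEET_OFFSET[2] * side + SHEET_OFFSET[3] * nrm
  x2 <- x2 + rep(shift, each = nrow(xyz))
  a2 <- a1
  a2$x <- x2[, 1]; a2$y <- x2[, 2]; a2$z <- x2[, 3]
  a2$auth_seq <- a2$auth_seq + n + 50L
  chain_model("A", rbind(a1, a2), source_kind = "predicted")
}

# tuned antiparallel-sheet register: (along-strand, inter-strand, normal)
SHEET_OFFSET <- c(-6.3, -5.3, 0.5)

#' Gaussian coordinate perturbation
#'
#' Adds i.i.d. Gaussian displacement (sd per coordinate, Angstrom) to every
#' atom. The caller's RNG state is untouched.
#'
#' @param chain a [chain_model()].
#' @param sd per-coordinate standard deviation in Angstrom (>= 0).
#' @param seed integer seed fixing the perturbation.
#' @return A perturbed [chain_model()].
#' @export
perturb_structure <- function(chain, sd, seed = 1L) {
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) return(chain)
  at <- chain$atoms
  d <- with_seed(seed, matrix(stats::rnorm(3 * nrow(at), sd = sd), ncol = 3))
  at$x <- at$x + d[, 1]
  at$y <- at$y + d[, 2]
  at$z <- at$z + d[, 3]
  chain_model(chain$chain_id, at, chain$source_kind)
}

#' Two-domain toy with prescribed architecture descriptors
#'
#' Builds two rigid helical domains placed so that the measured descriptors
#' (inter-domain COM distance epsilon, hinge angle theta, inter-domain
#' dihedral DH) equal the prescribed targets to high precision before any
#' perturbation. Placement is solved analytically: the second domain's COM
#' is positioned from the (epsilon, theta, DH) constraints in a hinge-axis
#' frame, and the rigid body is rotated so its internal COM-to-anchor vector
#' matches.
#'
#' @param n_residues residues per domain (each an ideal helix).
#' @param target_epsilon COM-COM distance in Angstrom.
#' @param target_theta hinge angle in degrees, strictly inside (0, 180).
#' @param target_dihedral inter-domain dihedral in degrees, (-180, 180].
#' @param perturbation_sd Gaussian coordinate noise (Angstrom) applied after
#'   exact placement; 0 keeps the construction exact.
#' @param seed integer seed for the perturbation.
#' @param com_mode `"mass"` or `"geometric"`, forwarded to the descriptor
#'   convention the toy is built for.
#' @return list with `model` (a [structure_model()]), `spans` (list of DBD
#'   and LBD [domain_span()]s) and `target` (the prescribed descriptors).
#' @export
make_two_domain_toy <- function(n_residues = 30, target_epsilon = 50,
                                target_theta = 120, target_dihedral = -90,
                                perturbation_sd = 0, seed = 1L,
                                com_mode = c("mass", "geometric"),
                                sidechains = FALSE) {
  com_mode <- match.arg(com_mode)
  if (target_theta <= 0 || target_theta >= 180)
    stop("target_theta must lie strictly inside (0, 180)")
  if (target_dihedral <= -180 || target_dihedral > 180)
    stop("target_dihedral must lie in (-180, 180]")
  if (target_epsilon <= 0) stop("target_epsilon must be positive")

  dbd <- make_ideal_helix(n_residues, chain_id = "A", start_seq = 1L,
                          sidechains = sidechains)
  lbd0 <- make_ideal_helix(n_residues, chain_id = "A",
                           start_seq = n_residues + 11L,
                           sidechains = sidechains)

  com_fun <- function(at) center_of_mass(at, mode = com_mode)
  C1 <- com_fun(dbd$atoms)
  L <- ca_coords(dbd, max(dbd$atoms$auth_seq))
  C20 <- com_fun(lbd0$atoms)
  F0 <- ca_coords(lbd0, min(lbd0$atoms$auth_seq))
  v0 <- C20 - F0
  d2 <- vec_norm(v0)

  # hinge anchor direction: away from the DBD COM through its last CA,
  # tilted so that C1, L, F are never collinear (the torsion needs a plane);
  # the tilt is a search parameter alongside the hinge length
  base_dir <- unit_vec(L - C1)
  perp <- unit_vec(cross3(base_dir, if (abs(base_dir[3]) < 0.9) c(0, 0, 1)
                          else c(0, 1, 0)))
  u_dir_at <- function(tilt)
    unit_vec(as.numeric(rotation_about_axis(perp, deg2rad(tilt)) %*% base_dir))

  solve_C2 <- function(t, tilt) {
    Fpt <- L + t * u_dir_at(tilt)
    M <- (L + Fpt) / 2
    zax <- unit_vec(Fpt - L)
    u <- C1 - M
    uz <- sum(u * zax)
    uperp <- u - uz * zax
    r1 <- vec_norm(uperp)
    if (r1 < 1e-9) return(NULL)
    e1 <- uperp / r1
    e2 <- cross3(zax, e1)
    nu <- vec_norm(u)
    th <- deg2rad(target_theta)
    disc <- target_epsilon^2 - (nu * sin(th))^2
    if (disc < 0) return(NULL)
    w_len <- nu * cos(th) + sqrt(disc)
    if (w_len <= 0) return(NULL)
    # the dihedral (C1, L, F, C2) is affine in the azimuth of C2 about the
    # hinge axis; calibrate slope/intercept empirically, then invert
    probe <- function(az) {
      w <- sin(pi / 4) * (cos(az) * e1 + sin(az) * e2) + cos(pi / 4) * zax
      torsion4(C1, L, Fpt, M + w)
    }
    c0 <- probe(0)
    s <- if (abs(wrap180(probe(pi / 2) - (c0 + 90))) < 1e-6) 1 else -1
    az <- deg2rad(wrap180(s * (target_dihedral - c0)))
    A <- r1 * cos(az)
    B <- uz
    C <- nu * cos(th)
    R <- sqrt(A^2 + B^2)
    if (R < abs(C)) return(NULL)
    phi0 <- atan2(A, B)
    for (alpha in c(phi0 + acos(C / R), phi0 - acos(C / R))) {
      if (sin(alpha) < -1e-9) next
      w <- w_len * (sin(alpha) * cos(az) * e1 + sin(alpha) * sin(az) * e2 +
                    cos(alpha) * zax)
      C2 <- M + w
      dh <- torsion4(C1, L, Fpt, C2)
      if (abs(dh - target_dihedral) < 1e-6 ||
          abs(abs(dh - target_dihedral) - 360) < 1e-6)
        return(list(C2 = C2, F = Fpt))
    }
    NULL
  }

  g <- function(t, tilt) {
    sol <- solve_C2(t, tilt)
    if (is.null(sol)) return(NA_real_)
    vec_norm(sol$C2 - sol$F) - d2
  }
  ts <- seq(0.5, 3 * (target_epsilon + d2), length.out = 200)
  sol <- NULL
  for (tilt in seq(5, 175, by = 5)) {
    gs <- vapply(ts, g, numeric(1), tilt = tilt)
    ok <- which(!is.na(gs))
    for (k in seq_along(ok)[-1]) {
      i0 <- ok[k - 1]; i1 <- ok[k]
      if (i1 == i0 + 1 && gs[i0] * gs[i1] <= 0) {
        root <- stats::uniroot(g, c(ts[i0], ts[i1]), tilt = tilt,
                               tol = 1e-13)$root
        sol <- solve_C2(root, tilt)
        break
      }
    }
    if (!is.null(sol)) break
  }
  if (is.null(sol))
    stop("infeasible descriptor targets: no hinge placement satisfies ",
         "(epsilon, theta, DH) with these domain sizes")
  rot <- rotation_between(v0, sol$C2 - sol$F)
  at <- lbd0$atoms
  xyz <- t(rot %*% t(sweep(atoms_xyz(at), 2, F0)) + sol$F)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  lbd <- chain_model("A", at, "predicted")

  chain <- chain_model("A", rbind(dbd$atoms, lbd$atoms), "predicted")
  if (perturbation_sd > 0)
    chain <- perturb_structure(chain, perturbation_sd, seed)
  list(model = structure_model("two_domain_toy", list(chain)),
       spans = list(DBD = domain_span("DBD", 1L, n_residues),
                    LBD = domain_span("LBD", n_residues + 11L,
                                      2L * n_residues + 10L)),
       target = c(epsilon = target_epsilon, theta = target_theta,
                  dihedral = target_dihedral))
}

# CA coordinates of one residue
ca_coords <- function(chain, auth_seq) {
  at <- chain$atoms
  row <- at[at$auth_seq == auth_seq & at$name == "CA", , drop = FALSE]
  if (nrow(row) == 0) stop("no CA atom for residue ", auth_seq)
  c(row$x[1], row$y[1], row$z[1])
}

#' Atom shell enclosing a spherical cavity of known volume
#'
#' Places pseudo-carbon atoms on a Fibonacci sphere of radius
#' `radius + r_vdw(C)` so that their inner van der Waals surfaces enclose an
#' empty cavity of analytic volume `4/3 pi radius^3`. A single seed atom at
#' the center acts as the reference "ligand" for pocket detection.
#'
#' @param radius cavity radius in Angstrom (must exceed the 1.4 A probe).
#' @param shell_atom_count number of shell atoms; too few leaves gaps the
#'   probe can escape through, which pocket extraction reports as a leak.
#' @return A [structure_model()] whose single chain is the shell and whose
#'   hetero group "LIG" is the central seed atom.
#' @export
make_spherical_cavity <- function(radius, shell_atom_count = 500) {
  if (radius <= 1.4) stop("cavity radius must exceed the 1.4 A probe radius")
  n <- shell_atom_count
  rshell <- radius + VDW_RADII[["C"]]
  # Fibonacci lattice on the sphere
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  xyz <- rshell * cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  # spacing check: nearest-neighbour gap must stay below the probe diameter
  spacing <- sqrt(4 * pi * rshell^2 / n)
  if (spacing > 2 * VDW_RADII[["C"]] + 2 * 1.4)
    stop("too few shell atoms: cavity would leak (gap ", round(spacing, 2),
         " A)")
  atoms <- data.frame(
    auth_seq = seq_len(n), icode = "", res_name = "SHL", name = "C",
    element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b = 0, occ = 1, altloc = "", stringsAsFactors = FALSE)
  shell <- chain_model("A", atoms, "experimental")
  seed_atom <- data.frame(
    chain = "A", auth_seq = 9999L, icode = "", res_name = "LIG", name = "C1",
    element = "C", x = 0, y = 0, z = 0, b = 0, occ = 1, altloc = "",
    stringsAsFactors = FALSE)
  structure_model("spherical_cavity", list(shell), seed_atom)
}

#' Paired per-residue tracks with known correlation
#'
#' Draws bivariate normal pairs at the target Pearson correlation and maps
#' them affinely into [0,1] (affine maps preserve the correlation; values
#' are clipped at the boundaries, which at sd 0.12 around 0.5 is negligible).
#'
#' @param n number of residues.
#' @param target_r target Pearson correlation in [-1, 1].
#' @param seed integer seed.
#' @return list of two [per_residue_track()]s (`RSCC` and `pLDDT`) on
#'   residues 1..n.
#' @export
make_correlated_tracks <- function(n, target_r, seed = 1L) {
  if (abs(target_r) > 1) stop("|target_r| must be <= 1")
  z <- with_seed(seed, matrix(stats::rnorm(2 * n), ncol = 2))
  x <- z[, 1]
  y <- target_r * z[, 1] + sqrt(1 - target_r^2) * z[, 2]
  squash <- function(v) pmin(1, pmax(0, 0.5 + 0.12 * v))
  vx <- squash(x); vy <- squash(y)
  names(vx) <- names(vy) <- seq_len(n)
  list(rscc = per_residue_track("RSCC", vx),
       plddt = per_residue_track("pLDDT", vy))
}
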