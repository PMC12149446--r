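#' Ligand-binding-pocket geometry
#'
#' Solvent-excluded (Connolly) volume and area by voxelized construction:
#' the probe-accessible region (probe centers at least `probe` from every
#' van der Waals sphere) is dilated back by the probe radius; its complement
#' is the SES solid. Pocket interiors are the SES-void voxels reachable by
#' flood fill from ligand seed points, so bulk solvent is never counted.
#' Surface area is estimated from the volume of a two-sided boundary shell
#' of half-width delta divided by 2*delta, which cancels the first-order
#' curvature bias of one-sided shells. Dilations use FFT-based binary
#' morphology with spherical structuring elements.
#'
#' Shape statistics: sphericity `Psi = pi^(1/3) (6V)^(2/3) / A` (1 for a
#' sphere, smaller for irregular cavities) and effective radius
#' `r_eff = 3V/A` (radius of the sphere with the same area-to-volume ratio).
#'
#' @name pocket
NULL

DEFAULT_PROBE <- 1.4
DEFAULT_VOXEL <- 0.4

# ---- voxel-grid machinery ---------------------------------------------------

# spherical structuring kernel of radius r (in Angstrom) on a grid of
# spacing h and dims d, centered at [1,1,1] with circular wraparound. The
# sub-voxel enlargement (0.15 voxel) centers the quantization bias of the
# discrete ball, calibrated once on the analytic sphere fixtures.
fft_kernel <- function(d, h, r) {
  rv <- r / h + 0.15
  m <- ceiling(rv)
  off <- expand.grid(x = -m:m, y = -m:m, z = -m:m)
  off <- off[off$x^2 + off$y^2 + off$z^2 <= rv^2 + 1e-9, , drop = FALSE]
  k <- array(0, d)
  ix <- ((off$x %% d[1]) + 1) + ((off$y %% d[2])) * d[1] +
        ((off$z %% d[3])) * d[1] * d[2]
  k[ix] <- 1
  k
}

# binary dilation of a logical array by a spherical element (radius r, A)
dilate <- function(mask, h, r) {
  d <- dim(mask)
  k <- fft_kernel(d, h, r)
  conv <- Re(stats::fft(stats::fft(array(as.numeric(mask), d)) * stats::fft(k),
                        inverse = TRUE)) / prod(d)
  array(conv > 0.5, d)
}

# stamp a union of balls onto the grid: voxel centers with |x - a_i| <= r_i
stamp_union <- function(xyz, radii, origin, h, d) {
  occ <- array(FALSE, d)
  for (i in seq_len(nrow(xyz))) {
    r <- radii[i]
    lo <- pmax(1L, as.integer(floor((xyz[i, ] - r - origin) / h)) + 1L)
    hi <- pmin(d, as.integer(ceiling((xyz[i, ] + r - origin) / h)) + 1L)
    if (any(lo > hi)) next
    gx <- origin[1] + (seq.int(lo[1], hi[1]) - 1) * h - xyz[i, 1]
    gy <- origin[2] + (seq.int(lo[2], hi[2]) - 1) * h - xyz[i, 2]
    gz <- origin[3] + (seq.int(lo[3], hi[3]) - 1) * h - xyz[i, 3]
    sub <- outer(gx^2, gy^2, "+")
    sub <- outer(sub, gz^2, "+") <= r^2
    occ[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      occ[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] | sub
  }
  occ
}

# exact field min_i (|x - a_i| - r_i) evaluated at voxel centers, capped at
# `cap` (distances beyond the cap are irrelevant and not computed)
surface_dist_field <- function(xyz, radii, origin, h, d, cap = 3) {
  fld <- array(cap, d)
  for (i in seq_len(nrow(xyz))) {
    r <- radii[i] + cap
    lo <- pmax(1L, as.integer(floor((xyz[i, ] - r - origin) / h)) + 1L)
    hi <- pmin(d, as.integer(ceiling((xyz[i, ] + r - origin) / h)) + 1L)
    if (any(lo > hi)) next
    gx <- origin[1] + (seq.int(lo[1], hi[1]) - 1) * h - xyz[i, 1]
    gy <- origin[2] + (seq.int(lo[2], hi[2]) - 1) * h - xyz[i, 2]
    gz <- origin[3] + (seq.int(lo[3], hi[3]) - 1) * h - xyz[i, 3]
    sub <- outer(gx^2, gy^2, "+")
    sub <- sqrt(outer(sub, gz^2, "+")) - radii[i]
    blk <- fld[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    fld[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- pmin(blk, sub)
  }
  fld
}

# volume and area of a voxel region. Area by the smoothed co-area formula:
# Gaussian-smooth the indicator (sigma ~ one voxel, FFT) and integrate the
# gradient magnitude; the smoothing averages out the voxel staircase while
# the curvature bias stays O((sigma/r)^2).
region_volume_area <- function(region, h, sigma = 1.2 * h) {
  d <- dim(region)
  V <- sum(region) * h^3
  wavenum <- function(n) c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * h
  K <- outer(outer(exp(-wavenum(d[1])^2 / (2 * sigma^2)),
                   exp(-wavenum(d[2])^2 / (2 * sigma^2))),
             exp(-wavenum(d[3])^2 / (2 * sigma^2)))
  K <- K / sum(K)
  sm <- Re(stats::fft(stats::fft(array(as.numeric(region), d)) *
                      stats::fft(K), inverse = TRUE)) / prod(d)
  shift_axis <- function(a, k, ax) {
    idx <- lapply(d, seq_len)
    idx[[ax]] <- ((idx[[ax]] - 1 - k) %% d[ax]) + 1
    do.call("[", c(list(a), idx))
  }
  gx <- (shift_axis(sm, -1, 1) - shift_axis(sm, 1, 1)) / (2 * h)
  gy <- (shift_axis(sm, -1, 2) - shift_axis(sm, 1, 2)) / (2 * h)
  gz <- (shift_axis(sm, -1, 3) - shift_axis(sm, 1, 3)) / (2 * h)
  A <- sum(sqrt(gx^2 + gy^2 + gz^2)) * h^3
  list(V = V, A = A)
}

# 6-connected flood fill from seed linear indices within `open`;
# returns list(region = logical array, leaked = touched the box boundary)
flood_fill6 <- function(open, seeds) {
  d <- dim(open)
  visited <- array(FALSE, d)
  seeds <- seeds[open[seeds]]
  if (length(seeds) == 0) return(list(region = visited, leaked = FALSE))
  visited[seeds] <- TRUE
  frontier <- arrayInd(seeds, d)
  leaked <- FALSE
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  while (nrow(frontier) > 0) {
    cand <- frontier[rep(seq_len(nrow(frontier)), each = 6), , drop = FALSE] +
            offs[rep(seq_len(6), nrow(frontier)), , drop = FALSE]
    inb <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
           cand[, 2] >= 1 & cand[, 2] <= d[2] &
           cand[, 3] >= 1 & cand[, 3] <= d[3]
    if (any(!inb)) leaked <- leaked || FALSE  # out-of-box neighbours are walls
    cand <- cand[inb, , drop = FALSE]
    lin <- cand[, 1] + (cand[, 2] - 1) * d[1] + (cand[, 3] - 1) * d[1] * d[2]
    keep <- open[lin] & !visited[lin]
    lin <- unique(lin[keep])
    if (length(lin) == 0) break
    visited[lin] <- TRUE
    frontier <- arrayInd(lin, d)
    if (any(frontier[, 1] %in% c(1, d[1]) | frontier[, 2] %in% c(1, d[2]) |
            frontier[, 3] %in% c(1, d[3]))) leaked <- TRUE
  }
  list(region = visited, leaked = leaked)
}

# ---- public operations ------------------------------------------------------

#' Solvent-excluded volume and area of an atom set
#'
#' The SES solid of the whole atom set (atoms plus probe-inaccessible
#' space). For a single atom this is exactly its van der Waals sphere.
#'
#' @param atoms atom table with `element` column (vdW radii from the Bondi
#'   set), or a list with `xyz` (n x 3) and `radii`.
#' @param probe probe radius in Angstrom (1.4 by default).
#' @param voxel grid spacing in Angstrom (must not exceed the probe).
#' @return list with `V` (A^3) and `A` (A^2).
#' @export
ses_volume_area <- function(atoms, probe = DEFAULT_PROBE, voxel = DEFAULT_VOXEL) {
  g <- ses_grid(atoms, probe, voxel)
  region_volume_area(g$ses, voxel)
}

# shared SES grid construction; returns origin/dims plus occupied (vdW
# union), probe-forbidden, and ses (solid) arrays
ses_grid <- function(atoms, probe = DEFAULT_PROBE, voxel = DEFAULT_VOXEL,
                     bounds = NULL) {
  if (voxel > probe) stop("voxel size must not exceed the probe radius")
  if (is.data.frame(atoms)) {
    if (nrow(atoms) == 0) stop("empty atom set")
    xyz <- atoms_xyz(atoms)
    radii <- element_vdw_radii(atoms$element)
  } else {
    xyz <- atoms$xyz
    radii <- atoms$radii
    if (is.null(xyz) || nrow(xyz) == 0) stop("empty atom set")
  }
  rmax <- max(radii)
  pad <- rmax + 2 * probe + 3 * voxel
  if (is.null(bounds)) {
    lo <- apply(xyz, 2, min) - pad
    hi <- apply(xyz, 2, max) + pad
  } else {
    lo <- bounds$lo - pad
    hi <- bounds$hi + pad
    keep <- xyz[, 1] >= lo[1] - rmax & xyz[, 1] <= hi[1] + rmax &
            xyz[, 2] >= lo[2] - rmax & xyz[, 2] <= hi[2] + rmax &
            xyz[, 3] >= lo[3] - rmax & xyz[, 3] <= hi[3] + rmax
    xyz <- xyz[keep, , drop = FALSE]
    radii <- radii[keep]
    if (nrow(xyz) == 0) stop("no atoms inside the pocket bounding box")
  }
  d <- as.integer(ceiling((hi - lo) / voxel)) + 1L
  occupied <- stamp_union(xyz, radii, lo, voxel, d)
  forbidden <- stamp_union(xyz, radii + probe, lo, voxel, d)
  probe_space <- !forbidden
  # bulk solvent = probe-space component connected to the box boundary;
  # enclosed probe-space components are interior cavities, not bulk
  bulk <- flood_fill6(probe_space, boundary_indices(d))$region
  ses <- !dilate(bulk, voxel, probe)
  list(origin = lo, voxel = voxel, dims = d, probe = probe,
       occupied = occupied, probe_space = probe_space, ses = ses)
}

# linear indices of all voxels on the box faces
boundary_indices <- function(d) {
  idx <- array(FALSE, d)
  idx[c(1, d[1]), , ] <- TRUE
  idx[, c(1, d[2]), ] <- TRUE
  idx[, , c(1, d[3])] <- TRUE
  which(idx)
}

#' Define a pocket by a distance cutoff from a reference ligand
#'
#' @param model a [structure_model()].
#' @param ligand_atoms atom table (e.g. rows of `model$hetero_groups`).
#' @param cutoff lining distance in Angstrom (default 5).
#' @return list with `lining_atoms` (protein atom table), `reference_ligand`
#'   and `cutoff`.
#' @export
define_pocket <- function(model, ligand_atoms, cutoff = 5.0) {
  if (is.null(ligand_atoms) || nrow(ligand_atoms) == 0)
    stop("empty ligand atom set")
  prot <- do.call(rbind, lapply(model$chains, function(ch) ch$atoms))
  px <- atoms_xyz(prot)
  lx <- atoms_xyz(ligand_atoms)
  d2min <- rep(Inf, nrow(px))
  for (i in seq_len(nrow(lx)))
    d2min <- pmin(d2min, (px[, 1] - lx[i, 1])^2 + (px[, 2] - lx[i, 2])^2 +
                          (px[, 3] - lx[i, 3])^2)
  lining <- prot[d2min <= cutoff^2, , drop = FALSE]
  if (nrow(lining) == 0)
    stop("empty lining set: no protein atom within ", cutoff,
         " A of the ligand")
  list(lining_atoms = lining, reference_ligand = ligand_atoms,
       cutoff = cutoff)
}

#' Merge holo-structure ligands into an apo frame
#'
#' Each holo chain is superposed onto the apo chain over the LBD span
#' (C-alpha atoms, via [refined_superpose()]) and its ligand atoms are
#' transformed into the apo frame; the merged set is the plain union
#' (ligand copies are retained, never deduplicated). Used to define the
#' pocket of an apo predicted model from the ligand positions of the
#' experimental holo structures.
#'
#' @param apo_chain [chain_model()] of the apo structure.
#' @param holo_chains list of [chain_model()]s.
#' @param ligands list of ligand atom tables, parallel to `holo_chains`.
#' @param span LBD [domain_span()] used for the superposition.
#' @param ... passed to [refined_superpose()].
#' @return merged ligand atom table in the apo frame.
#' @export
merged_ligand_reference <- function(apo_chain, holo_chains, ligands, span, ...) {
  stopifnot(length(holo_chains) == length(ligands))
  merged <- NULL
  for (i in seq_along(holo_chains)) {
    fit <- refined_superpose(holo_chains[[i]], apo_chain, span,
                             atom_mode = "ca", ...)
    lig <- ligands[[i]]
    xyz <- apply_transform(atoms_xyz(lig), fit)
    lig$x <- xyz[, 1]; lig$y <- xyz[, 2]; lig$z <- xyz[, 3]
    merged <- rbind(merged, lig)
  }
  merged
}

#' Pocket metrics from a structure and reference ligand
#'
#' Voxelizes the SES of the protein atoms around the ligand bounding box
#' (padded by the lining cutoff), flood-fills the SES void from the ligand
#' seed points, and measures the cavity. A fill that reaches the box
#' boundary means the pocket opens into bulk solvent; it is reported with a
#' warning and `leaked = TRUE` (no capping is applied). When no void is
#' reachable from the seeds the pocket is reported as not found.
#'
#' @param model a [structure_model()].
#' @param ligand_atoms reference-ligand atom table (seed points).
#' @param cutoff lining cutoff in Angstrom.
#' @param probe,voxel SES parameters.
#' @return list with `found`, `leaked`, `volume`, `area`, `sphericity`,
#'   `effective_radius`, `n_lining`.
#' @export
pocket_metrics <- function(model, ligand_atoms, cutoff = 5.0,
                           probe = DEFAULT_PROBE, voxel = DEFAULT_VOXEL) {
  pocket <- define_pocket(model, ligand_atoms, cutoff)
  prot <- do.call(rbind, lapply(model$chains, function(ch) ch$atoms))
  lx <- atoms_xyz(ligand_atoms)
  bounds <- list(lo = apply(lx, 2, min) - cutoff,
                 hi = apply(lx, 2, max) + cutoff)
  g <- ses_grid(prot, probe, voxel, bounds = bounds)
  # probe positions reachable from the ligand seeds; the cavity is that
  # component dilated back by the probe radius (bounded by the inner SES)
  seeds <- xyz_to_index(lx, g)
  fill <- flood_fill6(g$probe_space, seeds)
  if (!any(fill$region))
    return(list(found = FALSE, leaked = FALSE, volume = NA_real_,
                area = NA_real_, sphericity = NA_real_,
                effective_radius = NA_real_,
                n_lining = nrow(pocket$lining_atoms)))
  if (fill$leaked)
    warning("pocket flood fill reached the bounding box: pocket opens into ",
            "bulk solvent; metrics are method-sensitive")
  cavity <- dilate(fill$region, voxel, probe) & !g$occupied
  # contact-surface refinement: near the vdW surface the exact signed
  # distance at voxel centers is available, so the boundary there is
  # resolved below the voxel size - voxels of the one-voxel rim that lie
  # outside every vdW sphere join the region, and the volume integral uses
  # a linear partial-volume weight across the contact surface. Reentrant
  # (probe-sphere) parts of the boundary keep plain binary counting.
  fld <- surface_dist_field(atoms_xyz(prot), element_vdw_radii(prot$element),
                            g$origin, voxel, g$dims)
  near <- dilate(cavity, voxel, voxel)
  cavity <- cavity | (near & fld >= 0)
  va <- region_volume_area(cavity, voxel)
  contact <- abs(fld) < voxel          # voxels straddling the vdW surface
  frac <- pmin(1, pmax(0, 0.5 + fld / voxel))
  va$V <- (sum(cavity & !contact) + sum(frac[near & contact])) * voxel^3
  list(found = TRUE, leaked = fill$leaked, volume = va$V, area = va$A,
       sphericity = sphericity(va$V, va$A),
       effective_radius = effective_radius(va$V, va$A),
       n_lining = nrow(pocket$lining_atoms))
}

# map coordinates to in-grid linear voxel indices (out-of-grid dropped)
xyz_to_index <- function(xyz, g) {
  ijk <- sweep(xyz, 2, g$origin)
  ijk <- round(ijk / g$voxel) + 1
  d <- g$dims
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] & ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
        ijk[, 3] >= 1 & ijk[, 3] <= d[3]
  ijk <- ijk[ok, , drop = FALSE]
  as.integer(ijk[, 1] + (ijk[, 2] - 1) * d[1] + (ijk[, 3] - 1) * d[1] * d[2])
}

#' Sphericity of a cavity
#'
#' `Psi = pi^(1/3) (6V)^(2/3) / A`; 1 for a perfect sphere (isoperimetric
#' maximum), smaller for irregular shapes.
#'
#' @param V volume (A^3); `A` surface area (A^2); both > 0.
#' @param A surface area (A^2).
#' @return dimensionless sphericity.
#' @export
sphericity <- function(V, A) {
  if (V <= 0 || A <= 0) stop("V and A must be positive")
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}

#' Effective radius of a cavity
#'
#' `r_eff = 3V/A`, the radius of the sphere with the same surface-to-volume
#' ratio.
#'
#' @param V volume (A^3); `A` surface area (A^2); both > 0.
#' @param A surface area (A^2).
#' @return radius in Angstrom.
#' @export
effective_radius <- function(V, A) {
  if (V <= 0 || A <= 0) stop("V and A must be positive")
  3 * V / A
}

#' Pocket volume as percent of a reference
#'
#' The predicted model's pocket is conventionally set to 100% and the
#' experimental pockets expressed relative to it.
#'
#' @param v_structure,v_reference volumes (reference > 0).
#' @return percent of reference.
#' @export
pocket_normalization <- function(v_structure, v_reference) {
  if (any(v_reference <= 0)) stop("reference volume must be positive")
  100 * v_structure / v_reference
}

#' Percentage deviation of a predicted value from an experimental one
#'
#' `(v_pred - v_exp) / v_exp * 100`.
#'
#' @param v_pred,v_exp values (experimental nonzero).
#' @return percent deviation.
#' @export
pocket_deviation <- function(v_pred, v_exp) {
  if (any(v_exp == 0)) stop("experimental value must be nonzero")
  (v_pred - v_exp) / v_exp * 100
}
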