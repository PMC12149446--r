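# Internal 3-D vector helpers shared across modules. All coordinates in
# Angstrom, all user-facing angles in degrees.

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' @noRd
# Signed angle at vertex b (degrees, [0, 180]).
angle3 <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- vec_norm(u)
  nv <- vec_norm(v)
  if (nu < 1e-12 || nv < 1e-12) stop("zero-length arm in angle computation")
  cosang <- sum(u * v) / (nu * nv)
  rad2deg(acos(max(-1, min(1, cosang))))
}

#' @noRd
# Signed torsion of p1-p2-p3-p4 about the p2->p3 axis, IUPAC convention
# (clockwise positive looking from p2 to p3), range (-180, 180].
torsion4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vec_norm(b2) < 1e-12) stop("degenerate torsion: middle bond has zero length")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vec_norm(n1) < 1e-12 || vec_norm(n2) < 1e-12)
    stop("degenerate torsion: collinear points")
  m1 <- cross3(n1, unit_vec(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

# Rotation matrix for angle (radians) about unit axis (Rodrigues).
rotation_about_axis <- function(axis, angle) {
  a <- unit_vec(axis)
  ca <- cos(angle)
  sa <- sin(angle)
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) * ca + sa * K + (1 - ca) * (a %o% a)
}

# Minimal rotation mapping unit vector u onto unit vector v.
rotation_between <- function(u, v) {
  u <- unit_vec(u)
  v <- unit_vec(v)
  c_uv <- sum(u * v)
  if (c_uv > 1 - 1e-12) return(diag(3))
  if (c_uv < -1 + 1e-12) {
    # pick any axis perpendicular to u
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- unit_vec(cross3(u, ref))
    return(rotation_about_axis(axis, pi))
  }
  axis <- cross3(u, v)
  rotation_about_axis(axis, atan2(vec_norm(axis), c_uv))
}

#' @noRd
# NeRF atom placement: position of a new atom at distance `bond` from c,
# bond angle `ang` (degrees, at c between b and the new atom) and torsion
# `tor` (degrees, a-b-c-new).
place_atom <- function(a, b, c, bond, ang, tor) {
  ang <- deg2rad(ang)
  tor <- deg2rad(tor)
  bc <- unit_vec(c - b)
  n <- unit_vec(cross3(b - a, bc))
  m <- cross3(n, bc)
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(tor),
         -bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Run expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Wrap degrees into (-180, 180].
wrap180 <- function(x) {
  y <- ((x + 180) %% 360) - 180
  y[y <= -180] <- y[y <= -180] + 360
  # %% maps exact -180 to -180; ensure 180 stays 180
  y[abs(x %% 360 - 180) < 1e-12] <- 180
  y
}
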