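# Small vector/quaternion helpers shared across modules. All coordinates are
# microns; rows of a matrix are points.

vnorm <- function(v) sqrt(sum(v * v))

vnormalize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# squared cross-distances between two point sets (n x 3, m x 3)
cross_dist2 <- function(A, B) {
  d2 <- matrix(rowSums(A^2), nrow(A), nrow(B)) +
    matrix(rowSums(B^2), nrow(A), nrow(B), byrow = TRUE) -
    2 * A %*% t(B)
  d2[d2 < 0] <- 0
  d2
}

as_point_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    return(unname(x))
  }
  matrix(as.numeric(x), ncol = 3, byrow = TRUE)
}

# --- quaternions: q = c(w, x, y, z), unit norm -----------------------------

quat_identity <- function() c(1, 0, 0, 0)

quat_from_axis_angle <- function(axis, angle) {
  axis <- vnormalize(axis)
  c(cos(angle / 2), sin(angle / 2) * axis)
}

# minimal rotation taking unit vector a onto unit vector b
quat_between <- function(a, b) {
  a <- vnormalize(a); b <- vnormalize(b)
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(quat_identity())
  if (d < -1 + 1e-12) {
    # opposite vectors: pick any perpendicular axis
    ax <- vcross(a, c(1, 0, 0))
    if (vnorm(ax) < 1e-6) ax <- vcross(a, c(0, 1, 0))
    return(quat_from_axis_angle(ax, pi))
  }
  ax <- vcross(a, b)
  q <- c(1 + d, ax)
  q / vnorm(q)
}

quat_conjugate <- function(q) c(q[1], -q[2:4])

quat_multiply <- function(q, r) {
  c(q[1] * r[1] - sum(q[2:4] * r[2:4]),
    q[1] * r[2:4] + r[1] * q[2:4] + vcross(q[2:4], r[2:4]))
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

# rotate points (n x 3) by quaternion
quat_rotate <- function(q, P) {
  P <- as_point_matrix(P)
  P %*% t(quat_to_matrix(q))
}

# an orthonormal basis (u, v) of the plane perpendicular to unit vector n
perp_basis <- function(n) {
  n <- vnormalize(n)
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- vnormalize(vcross(n, ref))
  list(u = u, v = vcross(n, u))
}

# seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_neurofil <- function(msg, class, ...) {
  stop(structure(class = c(class, "neurofil_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}
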