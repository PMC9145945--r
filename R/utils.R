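# Internal helpers shared across modules.

# Polynomial rolling hash of an integer vector into [0, 2^31).
# Base-31 accumulation keeps every intermediate below 2^36 so double
# arithmetic stays exact; not cryptographic, only needs determinism.
hash_ints <- function(v, seed = 5381) {
  h <- seed
  for (x in v) h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  h
}

# MDL ctab charge codes -> formal charge (0=none, 1=+3 ... 7=-3, 4=radical).
mdl_charge <- function(code) {
  map <- c(0L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)
  out <- map[as.integer(code) + 1L]
  out[is.na(out)] <- 0L
  out
}

vec_norm <- function(v) sqrt(sum(v^2))

# Angle (degrees) at vertex b of the triangle a-b-c.
angle_deg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vec_norm(u) * vec_norm(v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# All pairwise distances between two n x 3 coordinate matrices.
cross_dist <- function(a, b) {
  a <- matrix(a, ncol = 3)
  b <- matrix(b, ncol = 3)
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

# Least-squares plane normal of a ring (unit vector), via SVD of the
# centered coordinates.
plane_normal <- function(xyz) {
  xyz <- matrix(xyz, ncol = 3)
  ctr <- colMeans(xyz)
  s <- svd(sweep(xyz, 2, ctr))
  n <- s$v[, 3]
  n / vec_norm(n)
}

# Acute angle between two plane normals, in [0, 90] degrees.
normal_angle <- function(n1, n2) {
  cosang <- abs(sum(n1 * n2) / (vec_norm(n1) * vec_norm(n2)))
  acos(pmin(1, cosang)) * 180 / pi
}

# Kabsch superposition: rotation + translation mapping `mobile` onto `ref`
# (both n x 3) in the least-squares sense. Returns the transform.
kabsch <- function(mobile, ref) {
  cm <- colMeans(mobile)
  cr <- colMeans(ref)
  p <- sweep(mobile, 2, cm)
  q <- sweep(ref, 2, cr)
  s <- svd(t(p) %*% q)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = rot, center_mobile = cm, center_ref = cr)
}

apply_kabsch <- function(xyz, fit) {
  sweep(sweep(xyz, 2, fit$center_mobile) %*% t(fit$rotation), 2,
        fit$center_ref, "+")
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Random rigid motion (rotation matrix + translation), for property tests.
random_rigid_motion <- function() {
  q <- rnorm(4)
  q <- q / vec_norm(q)
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  rot <- matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d),   2 * (b * d + a * c),
    2 * (b * c + a * d),   a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c),   2 * (c * d + a * b),   a^2 - b^2 - c^2 + d^2
  ), 3, 3, byrow = TRUE)
  list(rotation = rot, translation = rnorm(3, sd = 5))
}

apply_rigid <- function(xyz, motion) {
  sweep(matrix(xyz, ncol = 3) %*% t(motion$rotation), 2,
        motion$translation, "+")
}
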