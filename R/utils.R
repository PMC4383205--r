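# Small geometry / numerics helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unit_vector <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalise a zero vector", call. = FALSE)
  v / n
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula.  The axis need not be normalised.
#'
#' @param axis numeric length-3 axis of rotation.
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- unit_vector(as.numeric(axis))
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Deterministic quasi-uniform directions on the unit sphere
#'
#' Spherical Fibonacci lattice; used as the orientation grid for
#' alignment-tensor prediction.
#'
#' @param n number of directions (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# angle (degrees) at vertex b of the triangle a-b-c
angle_at_vertex <- function(a, b, c) {
  v1 <- a - b
  v2 <- c - b
  cosang <- sum(v1 * v2) / (vnorm(v1) * vnorm(v2))
  rad2deg(acos(max(-1, min(1, cosang))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run fn with a local RNG state seeded from `seed`, restoring the caller's
# stream afterwards so package functions never clobber user RNG state
with_local_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  fn()
}
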