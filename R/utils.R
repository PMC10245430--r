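#' Wrap an angle into (-pi, pi]
#'
#' All torsion angles in the package live on the half-open interval
#' \eqn{(-\pi, \pi]}; every comparison between angles goes through
#' [angle_diff()] so that the branch cut never shows up as a spurious
#' \eqn{2\pi} error.
#'
#' @param theta numeric vector of angles in radians.
#' @return numeric vector wrapped into \eqn{(-\pi, \pi]}.
#' @export
wrap_angle <- function(theta) {
  w <- theta - 2 * pi * floor((theta + pi) / (2 * pi))
  # floor() maps pi to -pi; put it back on the closed end
  w[w <= -pi + 1e-15 & cos(theta) < 0 & abs(sin(theta)) < 1e-12] <- pi
  w[w == -pi] <- pi
  w
}

#' Smallest signed difference between two angles
#'
#' @param a,b angles in radians (any branch).
#' @return wrapped difference `a - b` in \eqn{(-\pi, \pi]}.
#' @export
angle_diff <- function(a, b) wrap_angle(a - b)

# Deterministic, platform-independent string hash (polynomial rolling hash
# mod 2^31 - 1, exact in double arithmetic). Used for WL label buckets and
# config hashing; NOT cryptographic.
stable_hash <- function(s, mod = 2147483647) {
  vapply(s, function(x) {
    bytes <- utf8ToInt(enc2utf8(x))
    h <- 0
    for (b in bytes) h <- (h * 31 + b) %% mod
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Rodrigues rotation matrix for unit axis u and angle theta (right-hand rule).
rotation_about_axis <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Kabsch: optimal proper rotation aligning moving onto target (both n x 3,
# already centered). Returns the RMSD after superposition.
kabsch_rmsd <- function(target, moving) {
  ct <- colMeans(target); cm <- colMeans(moving)
  A <- sweep(target, 2, ct); B <- sweep(moving, 2, cm)
  H <- crossprod(B, A)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  BR <- B %*% t(R)
  sqrt(sum((BR - A)^2) / nrow(A))
}

# Random proper rigid motion (rotation + translation) for invariance tests.
random_rigid_motion <- function(coords, rng = NULL) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  R <- rotation_about_axis(ax, stats::runif(1, -pi, pi))
  t <- stats::rnorm(3, sd = 5)
  sweep(coords %*% t(R), 2, t, `+`)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
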