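# Independent brute-force / closed-form oracles used across the suite.
# These deliberately avoid the package's own code paths.

# direct double-loop radius of gyration (mass-weighted)
oracle_rg <- function(coords, masses) {
  com <- colSums(coords * masses) / sum(masses)
  s <- 0
  for (i in seq_len(nrow(coords))) {
    s <- s + masses[i] * sum((coords[i, ] - com)^2)
  }
  sqrt(s / sum(masses))
}

# direct O(N^2) Kirkwood radius
oracle_rh <- function(coords) {
  n <- nrow(coords)
  s <- 0; np <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + 1 / sqrt(sum((coords[i, ] - coords[j, ])^2))
      np <- np + 1
    }
  }
  1 / (s / np)
}

# direct end-group radius
oracle_re <- function(coords, idx, center) {
  sqrt(mean(vapply(idx, function(i) sum((coords[i, ] - center)^2), numeric(1))))
}

# direct-sum scalar ACF (all origins, per-lag n-k normalisation)
oracle_acf_scalar <- function(x, max_lag) {
  n <- length(x)
  mu <- mean(x)
  v <- mean(x^2) - mu^2
  vapply(0:max_lag, function(k) {
    (mean(x[1:(n - k)] * x[(1 + k):n]) - mu^2) / v
  }, numeric(1))
}

# direct-sum orientational ACF for one unit-vector series
oracle_acf_orient <- function(u, order, max_lag) {
  u <- u / sqrt(rowSums(u^2))
  n <- nrow(u)
  vapply(0:max_lag, function(k) {
    dots <- rowSums(u[1:(n - k), , drop = FALSE] * u[(1 + k):n, , drop = FALSE])
    if (order == 1) mean(dots) else mean(1.5 * dots^2 - 0.5)
  }, numeric(1))
}

# double-loop Coulomb energy of a counterion configuration (kBT units)
oracle_mc_energy <- function(coords, Q, R_sphere, lambda_B) {
  n <- nrow(coords)
  e <- 0
  for (i in seq_len(n)) {
    r <- sqrt(sum(coords[i, ]^2))
    e <- e + if (r >= R_sphere) -lambda_B * Q / r
             else -lambda_B * Q * (3 * R_sphere^2 - r^2) / (2 * R_sphere^3)
    if (i < n) {
      for (j in (i + 1):n) {
        e <- e + lambda_B / sqrt(sum((coords[i, ] - coords[j, ])^2))
      }
    }
  }
  e
}

# analytic potential of a charged shell (radius a, charge Q) with the
# compensating charge at D: dimensionless psi(r)
oracle_shell_psi <- function(r, a, Q, D, lambda_B) {
  ifelse(r < a, lambda_B * Q * (1 / a - 1 / D), lambda_B * Q * (1 / r - 1 / D))
}

# dense-scan root of the soft-sphere renormalization relation
oracle_soft_sphere <- function(Q, R, D, lambda_B, nu, n_grid = 400000L) {
  x <- seq(Q * 1e-9, Q * (1 - 1e-9), length.out = n_grid)
  f <- x - (R / lambda_B) * (1 / (2 * nu)) * log((Q / x - 1) * (D^3 / R^3 - 1))
  sgn <- sign(f)
  flips <- which(diff(sgn) != 0)
  list(root = (x[flips] + x[flips + 1L]) / 2, n_roots = length(flips))
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  Rm <- qr.Q(qr_)
  if (det(Rm) < 0) Rm[, 1] <- -Rm[, 1]
  Rm
}

# quick radial-profile builder for solver tests
profile_from_bins <- function(edges, values, kind = "charge") {
  dendritraj:::new_radial_profile(edges, values, kind, 1L)
}
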