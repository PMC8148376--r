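# Independent oracles and small fixtures used across the suite.

# Brute-force sequence Coulomb descriptors: explicit double loop.
brute_coulomb <- function(q) {
  pot <- 0
  frc <- 0
  n <- length(q)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pot <- pot + q[i] * q[j] / (j - i)
    frc <- frc + q[i] * q[j] / (j - i)^2
  }
  c(potential = pot, force = frc)
}

# Brute-force Debye intensity: explicit double loop over all ordered pairs.
brute_debye <- function(coords, f, q) {
  n <- nrow(coords)
  f <- rep_len(f, n)
  sapply(q, function(qk) {
    s <- 0
    for (i in 1:n) for (j in 1:n) {
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      s <- s + f[i] * f[j] * (if (qk * r < 1e-12) 1 else sin(qk * r) / (qk * r))
    }
    s
  })
}

# Brute-force salt-bridge scan.
brute_bridges <- function(coords, q, cutoff) {
  n <- nrow(coords)
  cnt <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (j - i < 2) next
    if (q[i] * q[j] >= 0) next
    if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= cutoff) cnt <- cnt + 1
  }
  cnt
}

# Exact accessible area of two equal overlapping spheres of radius R at
# center distance d < 2R: each loses a cap of height h = R - d/2.
two_sphere_area <- function(R, d) {
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

# Exact uniform-sphere form-factor intensity.
sphere_intensity <- function(q, R, i0 = 100) {
  x <- q * R
  i0 * (3 * (sin(x) - x * cos(x)) / x^3)^2
}

# Direct Rg of a weighted scatterer set (second-moment oracle).
weighted_rg <- function(coords, w) {
  com <- colSums(coords * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(coords, 2, com)^2)) / sum(w))
}

# Random rigid motion (proper rotation + translation).
random_rigid <- function(coords, seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(coords %*% R, 2, rnorm(3, sd = 50), "+")
}

# A small annotated test sequence: 2 phosphosites, mixed charges.
toy_sequence <- function() {
  parse_annotated_sequence("MKKS_AADES_GKRH", name = "toy")
}
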