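# Shared test utilities.

# a reproducible generic Cayley-Klein rotation
random_ck <- function(seed = 1) {
  set.seed(seed)
  a <- complex(real = rnorm(1), imaginary = rnorm(1))
  b <- complex(real = rnorm(1), imaginary = rnorm(1))
  n <- sqrt(Mod(a)^2 + Mod(b)^2)
  ck_rotation(a / n, b / n)
}

# exact moments of a weighted point density (no gridding error); the
# algebraic oracle for all rotation-law tests
point_moments <- function(u, w, order_max) {
  zershape:::moments_from_samples(u, w, order_max)
}

random_point_moments <- function(seed = 1, order_max = 8, npts = 50) {
  set.seed(seed)
  u <- matrix(runif(3 * npts, -0.6, 0.6), ncol = 3)
  w <- runif(npts, 0.5, 2)
  point_moments(u, w, order_max)
}

# analytic Gaussian-mixture density of an atom set evaluated at Angstrom
# points (independent of the rasterizer)
gaussian_mixture_at <- function(atoms, pts) {
  sig <- residue_sigma(atoms$resid)
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(atoms$coords))) {
    d2 <- rowSums(sweep(pts, 2, atoms$coords[i, ])^2)
    out <- out + atoms$mass[i] *
      exp(-d2 / (2 * sig[i]^2)) / ((2 * pi)^(3 / 2) * sig[i]^3)
  }
  out
}

rotation_angle_deg <- function(R1, R2) {
  tr <- sum(diag(t(R1) %*% R2))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

# small deterministic test shape with residue-like masses
test_shape <- function(seed = 5, n = 100, kind = "helix_bundle") {
  make_shape(kind, n_points = n, radius = 13, seed = seed, masses = "residue")
}
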