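# Orthonormal basis functions on the unit ball:
#   Z_nlm(x) = R_nl(|x|) Y_lm(x/|x|)
# with Y_lm the orthonormal complex spherical harmonics (Condon-Shortley
# phase) and R_nl the 3D Zernike radial polynomials normalised so that
# integral_0^1 R_nl(r) R_n'l(r) r^2 dr = delta_nn'.

# Normalised associated Legendre functions Pbar_lm(cos theta) such that
# Y_lm = Pbar_lm(cos theta) * exp(i m phi).  Standard stable recurrence;
# values stay O(1) up to l ~ 2000, far beyond the orders used here.
# Returns a list indexed by l+1, each element a matrix [npts x (l+1)]
# for m = 0..l.
legendre_bar <- function(costh, lmax) {
  npts <- length(costh)
  sinth <- sqrt(pmax(0, 1 - costh^2))
  out <- vector("list", lmax + 1L)
  # P[[m]] slots reused across l; build diagonal then upward recurrence
  Pmm <- rep(sqrt(1 / (4 * pi)), npts)           # Pbar_00
  Pdiag <- vector("list", lmax + 1L)
  Pdiag[[1L]] <- Pmm
  if (lmax >= 1) {
    for (m in 1:lmax) {
      Pmm <- -sqrt((2 * m + 1) / (2 * m)) * sinth * Pmm  # Condon-Shortley sign
      Pdiag[[m + 1L]] <- Pmm
    }
  }
  cols <- vector("list", lmax + 1L)  # cols[[m+1]] = list of Pbar_lm for l = m..lmax
  for (m in 0:lmax) {
    vals <- vector("list", lmax - m + 1L)
    vals[[1L]] <- Pdiag[[m + 1L]]
    if (lmax > m) {
      vals[[2L]] <- sqrt(2 * m + 3) * costh * Pdiag[[m + 1L]]
      if (lmax > m + 1) {
        for (l in (m + 2):lmax) {
          a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
          b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
          vals[[l - m + 1L]] <- a * (costh * vals[[l - m]] - b * vals[[l - m - 1L]])
        }
      }
    }
    cols[[m + 1L]] <- vals
  }
  for (l in 0:lmax) {
    mat <- matrix(0, npts, l + 1L)
    for (m in 0:l) mat[, m + 1L] <- cols[[m + 1L]][[l - m + 1L]]
    out[[l + 1L]] <- mat
  }
  out
}

# Spherical harmonics Y_lm for m = 0..l at unit-ball points.
# Returns list indexed by l+1 of complex matrices [npts x (l+1)].
# At the origin (r = 0) only Y_00 is non-zero, handled by costh := 1.
ylm_tables <- function(ux, uy, uz, lmax) {
  r <- sqrt(ux^2 + uy^2 + uz^2)
  costh <- ifelse(r > 0, uz / r, 1)
  phi <- atan2(uy, ux)
  P <- legendre_bar(costh, lmax)
  out <- vector("list", lmax + 1L)
  for (l in 0:lmax) {
    mat <- matrix(0i, length(r), l + 1L)
    # azimuthal phase twist (-i)^m: an orthonormal-basis gauge that keeps
    # conjugation symmetry and makes the Cayley-Klein zeta-coding rotation
    # law hold with the rotation matrix R(a, b) acting by substitution
    # f -> f(R x); pinned by the moment-rotation oracle in the tests
    for (m in 0:l) mat[, m + 1L] <-
      P[[l + 1L]][, m + 1L] * exp(1i * m * phi) * (-1i)^m
    out[[l + 1L]] <- mat
  }
  out
}

# Radial polynomials.  R_nl(r) = sqrt(2n+3) r^l P_k^{(0, l+1/2)}(2 r^2 - 1)
# with k = (n-l)/2 (Jacobi polynomials); this choice makes Z_nlm orthonormal
# on the unit ball.  Returns, for fixed l, a list over k = 0..kmax of
# vectors R_{l+2k, l}(r).
radial_table <- function(r, l, kmax) {
  x <- 2 * r^2 - 1
  rl <- r^l
  alpha <- 0
  beta <- l + 1 / 2
  P <- vector("list", kmax + 1L)
  P[[1L]] <- rep(1, length(r))
  if (kmax >= 1) {
    P[[2L]] <- (alpha + 1) + (alpha + beta + 2) * (x - 1) / 2
    if (kmax >= 2) {
      for (k in 2:kmax) {
        n2 <- k
        c1 <- 2 * n2 * (n2 + alpha + beta) * (2 * n2 + alpha + beta - 2)
        c2 <- (2 * n2 + alpha + beta - 1) *
          ((2 * n2 + alpha + beta) * (2 * n2 + alpha + beta - 2) * x + alpha^2 - beta^2)
        c3 <- 2 * (n2 + alpha - 1) * (n2 + beta - 1) * (2 * n2 + alpha + beta)
        P[[k + 1L]] <- (c2 * P[[k]] - c3 * P[[k - 1L]]) / c1
      }
    }
  }
  out <- vector("list", kmax + 1L)
  for (k in 0:kmax) {
    n <- l + 2L * k
    out[[k + 1L]] <- sqrt(2 * n + 3) * rl * P[[k + 1L]]
  }
  out
}

# Evaluate a single basis function Z_nlm at points (used by tests and
# reconstruction checks; the bulk paths use the table builders above).
zernike_basis <- function(ux, uy, uz, n, l, m) {
  stopifnot(l <= n, (n - l) %% 2 == 0, abs(m) <= l)
  r <- sqrt(ux^2 + uy^2 + uz^2)
  Y <- ylm_tables(ux, uy, uz, l)[[l + 1L]]
  ylm <- if (m >= 0) Y[, m + 1L] else (-1)^m * Conj(Y[, -m + 1L])
  R <- radial_table(r, l, (n - l) %/% 2L)[[(n - l) %/% 2L + 1L]]
  R * ylm
}
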