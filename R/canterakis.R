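#' Cayley-Klein rotation parameters
#'
#' A 3D rotation encoded by two complex numbers (a, b) with
#' \eqn{|a|^2 + |b|^2 = 1} (the SU(2) double cover of SO(3); (a, b) and
#' (-a, -b) encode the same rotation).
#'
#' @param a,b complex scalars.
#' @param tol tolerance on the unit-norm constraint.
#' @return object of class \code{zs_ck}.
#' @export
ck_rotation <- function(a, b, tol = 1e-9) {
  a <- as.complex(a); b <- as.complex(b)
  nrm <- Mod(a)^2 + Mod(b)^2
  if (abs(nrm - 1) > tol) stop("|a|^2 + |b|^2 must equal 1 (got ", nrm, ")")
  structure(list(a = a / sqrt(nrm), b = b / sqrt(nrm)), class = "zs_ck")
}

#' @export
print.zs_ck <- function(x, ...) {
  cat("Cayley-Klein rotation: a =", format(x$a), ", b =", format(x$b), "\n")
  invisible(x)
}

#' Rotation matrix of a Cayley-Klein pair
#'
#' The 3x3 proper orthogonal matrix R(a, b).  Package convention:
#' \code{rotate_moments(M, rot)} produces the moments of the substituted
#' density \eqn{x \mapsto f(R x)}, equivalently of the point cloud moved by
#' the transpose of this matrix (see \code{\link{ck_point_matrix}}).
#'
#' @param rot a \code{zs_ck} object.
#' @return 3x3 orthogonal matrix with determinant +1.
#' @export
rotation_matrix <- function(rot) {
  stopifnot(inherits(rot, "zs_ck"))
  a <- rot$a; b <- rot$b
  matrix(c(
    Re(a^2 + b^2), -Im(a^2 - b^2),  2 * Im(a * b),
    Im(a^2 + b^2),  Re(a^2 - b^2), -2 * Re(a * b),
    2 * Im(a * Conj(b)), 2 * Re(a * Conj(b)), Mod(a)^2 - Mod(b)^2
  ), nrow = 3, byrow = TRUE)
}

#' Point-motion matrix of a Cayley-Klein pair
#'
#' The matrix Q such that moving every point p -> Q p and recomputing
#' moments agrees with \code{rotate_moments(M, rot)} (up to grid error when
#' moments come from a rasterized volume; exactly for point densities).
#' It is the transpose (= inverse) of \code{\link{rotation_matrix}}.
#'
#' @param rot a \code{zs_ck} object.
#' @return 3x3 proper orthogonal matrix.
#' @export
ck_point_matrix <- function(rot) t(rotation_matrix(rot))

# Wigner-type transformation matrix for degree l in the zeta-coding
# parameterisation: row m (= -l..l), column mu (= -l..l) with
#   T[m, mu] = coefficient of zeta^(l+m) in (a zeta + b)^(l+mu) (a* - b* zeta)^(l-mu).
# Acting on modified moments: (rotated)_m = sum_mu T[m, mu] modified_mu.
ck_transform_matrix <- function(a, b, l) {
  dim <- 2L * l + 1L
  T <- matrix(0i, dim, dim)
  for (j in 0:(dim - 1L)) {       # j = l + mu
    p1 <- choose(j, 0:j) * a^(0:j) * b^(j - (0:j))            # (a z + b)^j
    q <- dim - 1L - j             # l - mu
    p2 <- choose(q, 0:q) * (-Conj(b))^(0:q) * Conj(a)^(q - (0:q))  # (a* - b* z)^q
    conv <- complex(dim)
    for (i1 in 0:j) for (i2 in 0:q)
      conv[i1 + i2 + 1L] <- conv[i1 + i2 + 1L] + p1[i1 + 1L] * p2[i2 + 1L]
    T[, j + 1L] <- conv
  }
  T
}

#' Rotate a moment set in moment space
#'
#' Applies the degree-l zeta-coding transformation to every (n, l) moment
#' vector, equivalent to rotating the underlying density by
#' \code{rotation_matrix(rot)} and recomputing its moments, but exact (no
#' regridding).  Per-(n, l) norms are preserved (the transformation is
#' unitary on the orthonormal-basis coefficients), which is why the 3DZD
#' invariants carry no orientation information while the Canterakis
#' normalisation does.
#'
#' @param moments a \code{zs_moments} object.
#' @param rot a \code{zs_ck} rotation.
#' @return rotated \code{zs_moments}.
#' @export
rotate_moments <- function(moments, rot) {
  stopifnot(inherits(moments, "zs_moments"), inherits(rot, "zs_ck"))
  was_modified <- inherits(moments, "zs_modified_moments")
  mod <- if (was_modified) moments else modify_moments(moments)
  out <- mod
  N <- mod$order_max
  for (l in 0:N) {
    ks <- seq(l, N, by = 2)
    if (!length(ks)) next
    T <- ck_transform_matrix(rot$a, rot$b, l)
    for (n in ks) {
      v <- moment_full_m(mod, n, l)          # m = -l..l
      w <- (T %*% v)[, 1]
      pos <- moment_block(mod, n, l)
      out$values[pos] <- w[(l + 1L):(2L * l + 1L)]   # keep m = 0..l
    }
  }
  if (was_modified) out else unmodify_moments(out)
}

# Value of the constrained modified moment (n, l, m = l) after rotation,
# as a function of t = a / conj(b):  proportional to
#   sum_mu (-1)^(l - mu) modified_{n, l, mu} t^(l + mu).
# Returns the polynomial coefficients in ascending powers of t.
normalization_polynomial <- function(modified, n, l) {
  v <- moment_full_m(modified, n, l)         # mu = -l..l
  mu <- (-l):l
  (-1)^(l - mu) * v                          # coefficient of t^(l + mu)
}

#' Solve the Canterakis normalization system
#'
#' Finds all Cayley-Klein rotations that drive the modified moment
#' \eqn{(\hat\Omega^R)_{n,l,l}} to zero (constraint (l, m) = (2, 2) for even
#' orders, (3, 3) for odd).  Substituting \eqn{t = a/\bar b} gives a
#' degree-2l complex polynomial whose roots fix two rotational degrees of
#' freedom; the third is fixed by requiring the imaginary part of a second
#' moment (default \eqn{\hat\Omega_{311}}) to vanish, a real quadratic in
#' \eqn{s = \Im b / \Re b}.  Generic moments yield 2l x 2 solutions (8 for
#' the (2,2) system).  The gauge \eqn{\Re b > 0} is built into the (a, b)
#' recovery.
#'
#' @param modified a \code{zs_modified_moments} object.
#' @param n order whose moments are constrained.
#' @param constraint integer pair (l, m) with m = l; default chosen by the
#'   parity of \code{n}.
#' @param second_constraint (n, l, m) of the moment whose imaginary part
#'   fixes the residual in-plane angle; \code{NULL} picks (3, 1, 1) when
#'   available, else falls back to s = 0.
#' @param tol relative tolerance classifying degenerate systems.
#' @return list of class \code{zs_normalization}: \code{rotations} (list of
#'   \code{zs_ck}), \code{residuals} (post-rotation magnitudes of the
#'   constrained moment), \code{constrained_index}, \code{degenerate} flag.
#' @export
solve_normalization <- function(modified, n,
                                constraint = NULL,
                                second_constraint = NULL,
                                tol = 1e-12) {
  stopifnot(inherits(modified, "zs_modified_moments"))
  if (is.null(constraint)) constraint <- if (n %% 2 == 0) c(2L, 2L) else c(3L, 3L)
  l <- constraint[1]
  if (constraint[2] != l) stop("only m = l constraints are supported")
  if (l > n || (n - l) %% 2 != 0) stop("constraint degree incompatible with order n")
  coefs <- normalization_polynomial(modified, n, l)
  scale <- sqrt(sum(Mod(coefs)^2))
  degenerate <- scale == 0 || all(Mod(coefs) < tol * max(scale, 1))
  if (degenerate) {
    return(structure(list(rotations = list(), residuals = numeric(),
                          constrained_index = c(n, l, l),
                          degenerate = TRUE), class = "zs_normalization"))
  }
  # deflate near-zero leading coefficients (root at t = infinity corresponds
  # to b = 0, a z-axis rotation that already satisfies the constraint when
  # the top coefficient vanishes)
  cc <- coefs
  while (length(cc) > 1 && Mod(cc[length(cc)]) < tol * scale)
    cc <- cc[-length(cc)]
  if (length(cc) <= 1) {
    return(structure(list(rotations = list(), residuals = numeric(),
                          constrained_index = c(n, l, l),
                          degenerate = TRUE), class = "zs_normalization"))
  }
  ts <- polyroot(cc)
  if (is.null(second_constraint)) {
    has311 <- modified$order_max >= 3
    second_constraint <- if (has311) c(3L, 1L, 1L) else NULL
  }
  rotations <- list()
  for (t in ts) {
    ss <- solve_second_constraint(modified, t, second_constraint)
    for (s in ss) {
      den <- sqrt((1 + Mod(t)^2) * (1 + s^2))
      b <- complex(real = 1, imaginary = s) / den
      a <- complex(real = 1, imaginary = -s) / den * t
      rotations[[length(rotations) + 1L]] <- ck_rotation(a, b)
    }
  }
  residuals <- vapply(rotations, function(rot) {
    T <- ck_transform_matrix(rot$a, rot$b, l)
    v <- moment_full_m(modified, n, l)
    Mod((T %*% v)[2L * l + 1L, 1])
  }, numeric(1))
  structure(list(rotations = rotations, residuals = residuals,
                 constrained_index = c(n, l, l), degenerate = FALSE),
            class = "zs_normalization")
}

# Roots s of Im{(rotated modified moment at sc)} = 0 given t.  The rotated
# value times (1 + s^2)(1 + |t|^2) is a real-coefficient quadratic in s,
# recovered by interpolation at s = -1, 0, 1.  Falls back to s = 0 when the
# quadratic is degenerate or has no real roots (symmetric shapes).
solve_second_constraint <- function(modified, t, sc) {
  if (is.null(sc)) return(0)
  n2 <- sc[1]; l2 <- sc[2]; m2 <- sc[3]
  v <- moment_full_m(modified, n2, l2)
  val_at <- function(s) {
    den <- sqrt((1 + Mod(t)^2) * (1 + s^2))
    b <- complex(real = 1, imaginary = s) / den
    a <- complex(real = 1, imaginary = -s) / den * t
    T <- ck_transform_matrix(a, b, l2)
    Im((T %*% v)[l2 + m2 + 1L, 1]) * (1 + s^2) * (1 + Mod(t)^2)
  }
  g0 <- val_at(0); gp <- val_at(1); gm <- val_at(-1)
  qa <- (gp + gm) / 2 - g0
  qb <- (gp - gm) / 2
  qc <- g0
  sc_mag <- max(abs(c(qa, qb, qc)))
  if (sc_mag == 0) return(0)
  if (abs(qa) < 1e-12 * sc_mag) {
    if (abs(qb) < 1e-12 * sc_mag) return(0)
    return(-qc / qb)
  }
  disc <- qb^2 - 4 * qa * qc
  if (disc < 0) return(0)
  c((-qb + sqrt(disc)) / (2 * qa), (-qb - sqrt(disc)) / (2 * qa))
}

#' Canterakis-norm invariant vector
#'
#' Normalizes the moment set by driving \eqn{(\hat\Omega^R)_{n22}} (even n)
#' or \eqn{(\hat\Omega^R)_{n33}} (odd n) to zero, rotates the full moment
#' set by every solution, and averages the complex magnitudes per
#' (n, l, m >= 0) index.  Averaging magnitudes makes the result independent
#' of the residual in-plane angle (the third degree of freedom) and of the
#' solution multiplicity, and rotation-invariant up to grid error.
#'
#' @param moments a \code{zs_moments} object with \code{order_max >= n}.
#' @param n normalization order (2..5 in the composite descriptor).
#' @return object of class \code{zs_cn}: numeric vector of length
#'   \code{count_indices(order_max, TRUE)} with attributes \code{order} and
#'   \code{degenerate}.
#' @export
cn_invariant <- function(moments, n) {
  stopifnot(inherits(moments, "zs_moments"), moments$order_max >= n)
  mod <- modify_moments(moments)
  sol <- solve_normalization(mod, n)
  if (sol$degenerate || !length(sol$rotations)) {
    vals <- Mod(moments$values)
    return(structure(vals, order = n, degenerate = TRUE, class = "zs_cn"))
  }
  acc <- numeric(length(moments$values))
  for (rot in sol$rotations) {
    rotated <- rotate_moments(moments, rot)
    acc <- acc + Mod(rotated$values)
  }
  structure(acc / length(sol$rotations), order = n, degenerate = FALSE,
            class = "zs_cn")
}

#' Composite Canterakis-norm descriptor
#'
#' Concatenation of \code{\link{cn_invariant}} vectors for the requested
#' normalization orders (ascending).  With the defaults (orders 2..5 at
#' N = 20) the result has 4 x 946 = 3784 components.
#'
#' @param moments a \code{zs_moments} object.
#' @param orders normalization orders, default \code{2:5}.
#' @return numeric vector.
#' @export
composite_cn <- function(moments, orders = 2:5) {
  orders <- sort(orders)
  unlist(lapply(orders, function(n) as.numeric(cn_invariant(moments, n))),
         use.names = FALSE)
}
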