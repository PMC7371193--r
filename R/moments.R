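#' 3D Zernike moment set
#'
#' Container for the complex expansion coefficients \eqn{\Omega_{nlm}} of a
#' density over the orthonormal Zernike basis on the unit ball.  Only
#' \code{m >= 0} coefficients are stored; negative-m values follow from the
#' conjugation symmetry of real densities.
#'
#' @param values complex vector in canonical index order
#'   (see \code{\link{zernike_indices}}).
#' @param order_max maximum order N.
#' @param frame the \code{zs_frame} used to scale coordinates into the unit
#'   ball (may be \code{NULL} for synthetic moment sets).
#' @return object of class \code{zs_moments}.
#' @export
new_moments <- function(values, order_max, frame = NULL) {
  idx <- zernike_indices(order_max, with_m = TRUE)
  stopifnot(length(values) == nrow(idx))
  structure(
    list(order_max = as.integer(order_max), idx = idx,
         values = as.complex(values), frame = frame),
    class = "zs_moments")
}

#' @export
print.zs_moments <- function(x, ...) {
  cat("3D Zernike moments, order_max =", x$order_max,
      "(", length(x$values), "coefficients, m >= 0 )\n")
  cat("  |Omega_000| =", format(Mod(x$values[1])), "\n")
  invisible(x)
}

# positions of the (n, l, m = 0..l) block within the canonical vector
moment_block <- function(moments, n, l) {
  which(moments$idx$n == n & moments$idx$l == l)
}

# full m = -l..l coefficient vector for one (n, l), negative m via
# conjugation symmetry
moment_full_m <- function(moments, n, l) {
  pos <- moment_block(moments, n, l)
  stopifnot(length(pos) == l + 1L)
  vpos <- moments$values[pos]            # m = 0..l
  if (l == 0) return(vpos)
  m <- 1:l
  vneg <- (-1)^m * Conj(vpos[m + 1L])    # m = -1..-l
  c(rev(vneg), vpos)                     # ordered m = -l..l
}

#' Compute 3D Zernike moments of a density volume
#'
#' Projects the volume onto the orthonormal Zernike basis by midpoint
#' (voxel-centre) summation after mapping coordinates into the unit ball
#' with \code{frame}.  Voxels whose centre falls outside the unit sphere are
#' ignored.
#'
#' @param volume a \code{zs_volume} (see \code{\link{rasterize}}).
#' @param frame a \code{zs_frame} (see \code{\link{unit_sphere_frame}}).
#' @param order_max maximum expansion order (the descriptor pipeline uses 20).
#' @return a \code{zs_moments} object.
#' @export
compute_moments <- function(volume, frame, order_max) {
  stopifnot(inherits(volume, "zs_volume"), inherits(frame, "zs_frame"))
  if (order_max < 0) stop("order_max must be >= 0")
  ctr <- voxel_centers(volume)
  u <- sweep(ctr, 2, frame$center) * frame$scale
  f <- as.vector(volume$values)
  keep <- rowSums(u^2) <= 1
  u <- u[keep, , drop = FALSE]
  f <- f[keep]
  dV <- (volume$grid_width * frame$scale)^3
  moments_from_samples(u, f * dV, order_max, frame = frame)
}

# Shared projection core: Omega_nlm = sum_i w_i * conj(Z_nlm(u_i)).
# With w = f * dV this is grid quadrature; with w = point masses it gives
# the exact moments of a sum of delta functions (used as an algebraic
# oracle in tests, free of gridding error).
moments_from_samples <- function(u, w, order_max, frame = NULL) {
  N <- as.integer(order_max)
  r <- sqrt(rowSums(u^2))
  Y <- ylm_tables(u[, 1], u[, 2], u[, 3], N)
  vals <- vector("list", 0L)
  out <- complex(count_indices(N, TRUE))
  idx <- zernike_indices(N, TRUE)
  for (l in 0:N) {
    kmax <- (N - l) %/% 2L
    R <- radial_table(r, l, kmax)
    Yl <- Y[[l + 1L]]
    # stack radial-weighted densities for all n sharing this l
    W <- vapply(0:kmax, function(k) w * R[[k + 1L]], numeric(length(w)))
    # (l+1) x (kmax+1) block of moments
    blk <- crossprod(Conj(Yl), W)
    for (k in 0:kmax) {
      n <- l + 2L * k
      pos <- which(idx$n == n & idx$l == l)
      out[pos] <- blk[, k + 1L]
    }
  }
  new_moments(out, N, frame = frame)
}

#' Reconstruct a density from its Zernike moments
#'
#' Evaluates the partial sum \eqn{\sum \Omega_{nlm} Z_{nlm}(x)} (all m,
#' negative indices via conjugation symmetry) on a regular grid covering
#' \eqn{[-1, 1]^3} in the unit-ball frame.  The summand is complex; for a
#' real input density the imaginary part cancels analytically, and its
#' residual magnitude is reported in the \code{max_imag} attribute.
#'
#' @param moments a \code{zs_moments} object.
#' @param grid_shape voxel dimensions of the reconstruction grid (length 1
#'   or 3).
#' @param order_max optionally truncate the expansion below
#'   \code{moments$order_max}.
#' @return a \code{zs_volume} in unit-ball coordinates (grid width
#'   \code{2/dim}), with attribute \code{max_imag}.
#' @export
reconstruct <- function(moments, grid_shape, order_max = moments$order_max) {
  stopifnot(inherits(moments, "zs_moments"), order_max <= moments$order_max)
  dims <- as.integer(rep(grid_shape, length.out = 3))
  w <- 2 / dims[1]
  ax <- lapply(dims, function(d) -1 + (seq_len(d) - 0.5) * (2 / d))
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  r <- sqrt(g$x^2 + g$y^2 + g$z^2)
  inside <- r <= 1
  u <- as.matrix(g)[inside, , drop = FALSE]
  rr <- r[inside]
  N <- as.integer(order_max)
  Y <- ylm_tables(u[, 1], u[, 2], u[, 3], N)
  acc <- complex(nrow(u))
  for (l in 0:N) {
    kmax <- (N - l) %/% 2L
    R <- radial_table(rr, l, kmax)
    Yl <- Y[[l + 1L]]                     # m = 0..l
    Yfull <- if (l == 0) Yl else {
      m <- 1:l
      cbind(Conj(Yl[, rev(m) + 1L, drop = FALSE]) %*% diag((-1)^rev(m), l, l), Yl)
    }                                     # m = -l..l
    for (k in 0:kmax) {
      n <- l + 2L * k
      om <- moment_full_m(moments, n, l)
      acc <- acc + (Yfull %*% om)[, 1] * R[[k + 1L]]
    }
  }
  vol <- array(0, dims)
  vol[inside] <- Re(acc)
  out <- new_volume(vol, grid_width = w, origin = c(-1, -1, -1),
                    center_of_mass = c(0, 0, 0), gyration_radius = NA_real_)
  attr(out, "max_imag") <- if (length(acc)) max(abs(Im(acc))) else 0
  out
}

#' Classical 3DZD rotation invariants
#'
#' The per-(n, l) Euclidean norms \eqn{F_{nl} = \lVert\Omega_{nl}\rVert} of
#' the (2l+1)-dimensional moment vectors (negative m reconstructed by
#' conjugation symmetry).  Length 121 at N = 20.  These invariants discard
#' all intra-(n, l) phase information, which is what the Canterakis-norm
#' descriptors recover.
#'
#' @param moments a \code{zs_moments} object.
#' @return named numeric vector, one entry per (n, l) pair.
#' @export
descriptor_3dzd <- function(moments) {
  idx <- zernike_indices(moments$order_max, with_m = FALSE)
  out <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    v <- moment_full_m(moments, idx$n[i], idx$l[i])
    out[i] <- sqrt(sum(Mod(v)^2))
  }
  names(out) <- paste0("F", idx$n, "_", idx$l)
  out
}

# m-dependent part of the Cayley-Klein scaling factor c_lm.  Only the ratio
# c_lm / c_lm' within one l affects the normalisation algebra; the
# l-dependent prefactor cancels identically.  The m-dependence must be
# sqrt((l+m)! (l-m)!) for the zeta-coding transformation law to agree with
# real-space rotation under orthonormal (Condon-Shortley) harmonics; this
# is pinned by the rotation oracle in the test suite.
clm_factor <- function(l, m) {
  m <- abs(m)
  (2 * l + 1) / factorial(l) *
    exp(0.5 * (lfactorial(l + m) + lfactorial(l - m)))
}

#' Modified Zernike moments
#'
#' Elementwise rescaling \eqn{\hat\Omega_{nlm} = \Omega_{nlm} / c_{lm}} that
#' turns the rotation of moment vectors into the polynomial
#' (zeta-coding) transformation law used by the Canterakis normalisation.
#' \code{unmodify_moments} inverts the scaling exactly.
#'
#' @param moments a \code{zs_moments} object.
#' @return object of class \code{zs_modified_moments} (same index layout).
#' @export
modify_moments <- function(moments) {
  stopifnot(inherits(moments, "zs_moments"))
  cf <- clm_factor(moments$idx$l, moments$idx$m)
  out <- moments
  out$values <- moments$values / cf
  class(out) <- c("zs_modified_moments", "zs_moments")
  out
}

#' @rdname modify_moments
#' @param modified a \code{zs_modified_moments} object.
#' @export
unmodify_moments <- function(modified) {
  stopifnot(inherits(modified, "zs_modified_moments"))
  cf <- clm_factor(modified$idx$l, modified$idx$m)
  out <- modified
  out$values <- modified$values * cf
  class(out) <- "zs_moments"
  out
}

#' Serialize moments to a plain-text table
#'
#' Writes one row per stored (n, l, m >= 0) coefficient with real and
#' imaginary parts; \code{read_moments} restores the object.  Output is
#' bit-stable for identical inputs.
#'
#' @param moments a \code{zs_moments} object.
#' @param path file path (CSV).
#' @export
write_moments <- function(moments, path) {
  df <- data.frame(moments$idx,
                   re = Re(moments$values),
                   im = Im(moments$values))
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_moments
#' @export
read_moments <- function(path) {
  df <- utils::read.csv(path)
  N <- max(df$n)
  idx <- zernike_indices(N, TRUE)
  stopifnot(nrow(df) == nrow(idx), all(df$n == idx$n),
            all(df$l == idx$l), all(df$m == idx$m))
  new_moments(complex(real = df$re, imaginary = df$im), N)
}
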