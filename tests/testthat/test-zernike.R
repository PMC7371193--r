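# a manual unit-ball frame for volumes built directly in unit coordinates
unit_frame <- function() structure(list(center = c(0, 0, 0), scale = 1),
                                   class = "zs_frame")

unit_grid_volume <- function(fill, dims = 48) {
  ax <- -1 + (seq_len(dims) - 0.5) * (2 / dims)
  g <- as.matrix(expand.grid(ax, ax, ax))
  vals <- array(fill(g), rep(dims, 3))
  new_volume(vals, grid_width = 2 / dims, origin = c(-1, -1, -1),
             center_of_mass = c(0, 0, 0), gyration_radius = NA_real_)
}

test_that("grid-sampled basis functions are orthonormal on the unit ball", {
  dims <- 40
  ax <- -1 + (seq_len(dims) - 0.5) * (2 / dims)
  g <- as.matrix(expand.grid(ax, ax, ax))
  inside <- rowSums(g^2) <= 1
  u <- g[inside, , drop = FALSE]
  dV <- (2 / dims)^3
  idx <- zernike_indices(4, with_m = TRUE)
  B <- sapply(seq_len(nrow(idx)), function(r)
    zershape:::zernike_basis(u[, 1], u[, 2], u[, 3],
                             idx$n[r], idx$l[r], idx$m[r]))
  Gm <- crossprod(Conj(B), B) * dV
  expect_lt(max(Mod(Gm - diag(nrow(idx)))), 0.02)
})

test_that("spherically symmetric densities excite only (l, m) = (0, 0)", {
  vol <- unit_grid_volume(function(g) exp(-rowSums(g^2) / (2 * 0.3^2)))
  mom <- compute_moments(vol, unit_frame(), 8)
  nl0 <- mom$idx$l == 0
  expect_gt(Mod(mom$values[1]), 0.1)
  expect_lt(max(Mod(mom$values[!nl0])), 1e-3 * Mod(mom$values[1]))
  # realness: m = 0 coefficients are real, Omega_000 >= 0
  m0 <- mom$idx$m == 0
  expect_lt(max(abs(Im(mom$values[m0]))), 1e-10)
  expect_gt(Re(mom$values[1]), 0)
})

test_that("uniform unit-ball density projects onto the constant basis function", {
  vol <- unit_grid_volume(function(g) rep(1, nrow(g)), dims = 64)
  mom <- compute_moments(vol, unit_frame(), 4)
  # closed form: Z_000 = sqrt(3) * sqrt(1/(4 pi)); integral over the ball
  # gives sqrt(3/(4 pi)) * 4 pi / 3 = sqrt(4 pi / 3)
  expect_equal(Re(mom$values[1]), sqrt(4 * pi / 3), tolerance = 0.01)
})

test_that("moments satisfy conjugation symmetry bookkeeping and Parseval bound", {
  sh <- test_shape(seed = 3, n = 80)
  vol <- rasterize(sh, 1.0)
  fr <- unit_sphere_frame(sh)
  mom <- compute_moments(vol, fr, 10)
  m0 <- mom$idx$m == 0
  expect_lt(max(abs(Im(mom$values[m0]))), 1e-12 * max(Mod(mom$values)))
  # Parseval: sum over the full lattice of |Omega|^2 bounded by ||f||^2
  idx2 <- zernike_indices(10, with_m = FALSE)
  total <- sum(vapply(seq_len(nrow(idx2)), function(r)
    sum(Mod(zershape:::moment_full_m(mom, idx2$n[r], idx2$l[r]))^2),
    numeric(1)))
  ctr <- zershape:::voxel_centers(vol)
  u <- sweep(ctr, 2, fr$center) * fr$scale
  f2 <- sum(as.vector(vol$values)[rowSums(u^2) <= 1]^2) *
    (vol$grid_width * fr$scale)^3
  expect_lte(total, f2 * (1 + 1e-9))
})

test_that("3DZD invariants have length 121, per-order locality and rotation invariance", {
  mom <- random_point_moments(seed = 21, order_max = 20, npts = 40)
  f <- descriptor_3dzd(mom)
  expect_length(f, 121)
  # zeroing all moments of one order changes only that order's entries
  # (guards against the cumulative-invariant bug)
  mom2 <- mom
  mom2$values[mom2$idx$n == 6] <- 0
  f2 <- descriptor_3dzd(mom2)
  changed <- which(f != f2)
  expect_true(all(grepl("^F6_", names(f)[changed])))
  # rotation invariance via the exact point oracle
  set.seed(22)
  u <- matrix(runif(120, -0.6, 0.6), ncol = 3)
  w <- runif(40, 0.5, 2)
  rot <- random_ck(23)
  f_a <- descriptor_3dzd(point_moments(u, w, 12))
  f_b <- descriptor_3dzd(point_moments(u %*% rotation_matrix(rot), w, 12))
  expect_equal(f_a, f_b, tolerance = 1e-12)
})

test_that("moment modification is invertible and uses the printed scaling", {
  # c_lm for (0,0) is 1; for (2,2) the m-dependent part is
  # sqrt((l+m)!(l-m)!) with prefactor (2l+1)/l!
  expect_equal(zershape:::clm_factor(0, 0), 1)
  expect_equal(zershape:::clm_factor(2, 2),
               (2 * 2 + 1) / factorial(2) * sqrt(factorial(4) * factorial(0)))
  mom <- random_point_moments(seed = 5, order_max = 6)
  round <- unmodify_moments(modify_moments(mom))
  expect_equal(round$values, mom$values, tolerance = 1e-14)
  # (0,0,0) unchanged by modification
  expect_equal(modify_moments(mom)$values[1], mom$values[1])
})

test_that("reconstruction is self-consistent and improves with order", {
  sh <- test_shape(seed = 4, n = 70)
  fr <- unit_sphere_frame(sh)
  vol <- rasterize(sh, 1.2)
  mom <- compute_moments(vol, fr, 20)
  dims <- 32
  rec20 <- reconstruct(mom, dims)
  expect_lt(attr(rec20, "max_imag"), 1e-9)
  # analytic input density on the reconstruction grid
  ctr <- zershape:::voxel_centers(rec20)           # unit coordinates
  inside <- rowSums(ctr^2) <= 1
  pts <- sweep(ctr[inside, , drop = FALSE] / fr$scale, 2, fr$center, "+")
  truth <- gaussian_mixture_at(sh, pts)
  expect_gt(stats::cor(as.vector(rec20$values)[inside], truth), 0.9)
  errs <- vapply(seq(0, 20, 4), function(N) {
    rec <- reconstruct(mom, dims, order_max = N)
    sqrt(sum((as.vector(rec$values)[inside] - truth)^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8 * errs[1]))
  # all-zero moments reconstruct to the zero volume
  z <- new_moments(complex(count_indices(4, TRUE)), 4)
  expect_true(all(reconstruct(z, 16)$values == 0))
})

test_that("moment serialization round trips bit-stably", {
  mom <- random_point_moments(seed = 8, order_max = 5)
  f <- tempfile(fileext = ".csv")
  write_moments(mom, f)
  back <- read_moments(f)
  expect_identical(back$values, mom$values)
  expect_identical(readLines(f), {write_moments(mom, f); readLines(f)})
})
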