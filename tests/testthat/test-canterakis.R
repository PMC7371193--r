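test_that("Cayley-Klein matrices are proper rotations with the stated special cases", {
  expect_equal(rotation_matrix(ck_rotation(1 + 0i, 0i)), diag(3))
  # (a, b) = (0, 1): direct substitution gives diag(1, -1, -1), trace -1
  R01 <- rotation_matrix(ck_rotation(0i, 1 + 0i))
  expect_equal(R01, diag(c(1, -1, -1)))
  expect_equal(sum(diag(R01)), -1)
  for (s in 1:5) {
    R <- rotation_matrix(random_ck(s))
    expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
  expect_error(ck_rotation(1 + 0i, 1 + 0i), "must equal 1")
})

test_that("moment rotation matches the printed five-term expansion at (2,2,2)", {
  mom <- random_point_moments(seed = 41, order_max = 4)
  hat <- modify_moments(mom)
  for (s in 1:4) {
    rot <- random_ck(100 + s)
    a <- rot$a; b <- rot$b
    out <- modify_moments(rotate_moments(mom, rot))
    v <- function(n, l, m) {
      pos <- which(hat$idx$n == n & hat$idx$l == l & hat$idx$m == m)
      hat$values[pos]
    }
    expected <- a^4 * v(2, 2, 2) - a^3 * Conj(b) * v(2, 2, 1) +
      a^2 * Conj(b)^2 * v(2, 2, 0) + a * Conj(b)^3 * Conj(v(2, 2, 1)) +
      Conj(b)^4 * Conj(v(2, 2, 2))
    got <- out$values[which(out$idx$n == 2 & out$idx$l == 2 & out$idx$m == 2)]
    expect_equal(got, expected, tolerance = 1e-13)
  }
})

test_that("moment-space rotation equals real-space rotation of the density", {
  # exact for point densities: no gridding error in the oracle
  set.seed(51)
  u <- matrix(runif(150, -0.65, 0.65), ncol = 3)
  w <- runif(50, 0.5, 2)
  mom <- point_moments(u, w, 10)
  for (s in 1:3) {
    rot <- random_ck(200 + s)
    moved <- u %*% t(ck_point_matrix(rot))      # p -> Q p
    mom_moved <- point_moments(moved, w, 10)
    pred <- rotate_moments(mom, rot)
    relerr <- sqrt(sum(Mod(pred$values - mom_moved$values)^2)) /
      sqrt(sum(Mod(mom$values)^2))
    expect_lt(relerr, 1e-12)
  }
})

test_that("rotation preserves per-(n,l) norms and composes correctly", {
  mom <- random_point_moments(seed = 61, order_max = 8)
  r1 <- random_ck(62); r2 <- random_ck(63)
  rot1 <- rotate_moments(mom, r1)
  expect_equal(descriptor_3dzd(rot1), descriptor_3dzd(mom), tolerance = 1e-12)
  # composition: the composed Cayley-Klein pair comes from SU(2) products
  su2 <- function(r) matrix(c(r$a, -Conj(r$b), r$b, Conj(r$a)), 2)
  m12 <- su2(r1) %*% su2(r2)
  r12 <- ck_rotation(m12[1, 1], m12[1, 2])
  lhs <- rotate_moments(rotate_moments(mom, r1), r2)
  rhs1 <- rotate_moments(mom, r12)
  m21 <- su2(r2) %*% su2(r1)
  rhs2 <- rotate_moments(mom, ck_rotation(m21[1, 1], m21[1, 2]))
  errs <- c(sqrt(sum(Mod(lhs$values - rhs1$values)^2)),
            sqrt(sum(Mod(lhs$values - rhs2$values)^2))) /
    sqrt(sum(Mod(mom$values)^2))
  expect_lt(min(errs), 1e-12)
  # identity rotation is exact
  id <- rotate_moments(mom, ck_rotation(1 + 0i, 0i))
  expect_equal(id$values, mom$values, tolerance = 1e-14)
})

test_that("the order-2 normalization system yields 8 verified solutions", {
  mom <- random_point_moments(seed = 71, order_max = 8)
  hat <- modify_moments(mom)
  sol <- solve_normalization(hat, 2)
  expect_false(sol$degenerate)
  expect_length(sol$rotations, 8)
  scale <- sqrt(sum(Mod(zershape:::moment_full_m(hat, 2, 2))^2))
  expect_lt(max(sol$residuals), 1e-8 * scale)
  # every solution respects the gauge Re{b} > 0 and back-substitutes
  for (r in sol$rotations) {
    expect_gt(Re(r$b), 0)
    rotated <- modify_moments(rotate_moments(mom, r))
    v222 <- rotated$values[which(rotated$idx$n == 2 & rotated$idx$l == 2 &
                                   rotated$idx$m == 2)]
    expect_lt(Mod(v222), 1e-8 * scale)
  }
  # odd-order constraint (3,3): degree-6 polynomial, up to 12 solutions
  sol3 <- solve_normalization(hat, 3)
  expect_false(sol3$degenerate)
  expect_gte(length(sol3$rotations), 8)
  scale3 <- sqrt(sum(Mod(zershape:::moment_full_m(hat, 3, 3))^2))
  expect_lt(max(sol3$residuals), 1e-8 * scale3)
})

test_that("a vanishing constrained moment puts t = 0 among the roots", {
  mom <- random_point_moments(seed = 81, order_max = 4)
  hat <- modify_moments(mom)
  i222 <- which(hat$idx$n == 2 & hat$idx$l == 2 & hat$idx$m == 2)
  hat$values[i222] <- 0
  coefs <- zershape:::normalization_polynomial(hat, 2, 2)
  # constant term is the conjugate of the constrained moment: zero
  expect_equal(Mod(coefs[1]), 0)
  roots <- polyroot(coefs[-length(coefs)])   # leading coefficient also 0
  expect_true(any(Mod(roots) < 1e-10))
})

test_that("CN invariants are rotation invariant with the documented bookkeeping", {
  set.seed(91)
  u <- matrix(runif(150, -0.6, 0.6), ncol = 3)
  w <- runif(50, 0.5, 2)
  mom <- point_moments(u, w, 20)
  cn <- cn_invariant(mom, 2)
  expect_length(cn, 946)
  expect_true(all(cn >= 0))
  rot <- random_ck(92)
  mom_r <- point_moments(u %*% rotation_matrix(rot), w, 20)
  cn_r <- cn_invariant(mom_r, 2)
  expect_equal(as.numeric(cn), as.numeric(cn_r), tolerance = 1e-10)
  comp <- composite_cn(mom)
  expect_length(comp, 3784)
  expect_length(composite_cn(mom, 2), 946)
  comp_r <- composite_cn(mom_r)
  expect_equal(comp, comp_r, tolerance = 1e-9)
})

test_that("rotation-inert moment sets fall back to raw magnitudes", {
  vals <- complex(count_indices(6, TRUE))
  vals[1] <- 2.5 + 0i                          # only Omega_000 non-zero
  mom <- new_moments(vals, 6)
  cn <- cn_invariant(mom, 2)
  expect_true(attr(cn, "degenerate"))
  expect_equal(as.numeric(cn[1]), 2.5)
  expect_true(all(cn[-1] == 0))
})

test_that("normalizing an already-normalized moment set is a fixed point", {
  mom <- random_point_moments(seed = 95, order_max = 8)
  sol <- solve_normalization(modify_moments(mom), 2)
  std <- rotate_moments(mom, sol$rotations[[1]])
  cn1 <- cn_invariant(std, 2)
  sol2 <- solve_normalization(modify_moments(std), 2)
  # the standard position satisfies the constraint; rotating by the new
  # solutions changes the averaged magnitudes negligibly
  cn2 <- cn_invariant(rotate_moments(std, sol2$rotations[[1]]), 2)
  expect_equal(as.numeric(cn1), as.numeric(cn2), tolerance = 1e-8)
})
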