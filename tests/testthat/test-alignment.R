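test_that("alignment descriptor carries order-6 moments and the centre of mass", {
  sh <- test_shape(seed = 23, n = 60)
  cfg <- zs_config(grid_width = 1.2)
  ad <- alignment_descriptor(sh, cfg)
  expect_identical(ad$moments$order_max, 6L)
  expect_true(all(is.finite(ad$center_of_mass)))
  # translated copy: identical moments, shifted centre
  sh2 <- sh; sh2$coords <- sweep(sh$coords, 2, c(4, 8, -2), "+")
  ad2 <- alignment_descriptor(sh2, cfg)
  expect_equal(ad2$center_of_mass, ad$center_of_mass + c(4, 8, -2))
  expect_lt(sqrt(sum(Mod(ad2$moments$values - ad$moments$values)^2)) /
              sqrt(sum(Mod(ad$moments$values)^2)), 1e-8)
  # rotated copy: moments related by the moment-space rotation law
  rot <- random_ck(24)
  sh3 <- sh; sh3$coords <- sh$coords %*% t(ck_point_matrix(rot))
  ad3 <- alignment_descriptor(sh3, cfg)
  pred <- rotate_moments(ad$moments, rot)
  expect_lt(sqrt(sum(Mod(ad3$moments$values - pred$values)^2)) /
              sqrt(sum(Mod(ad$moments$values)^2)), 0.02)
})

test_that("the relative moment distance follows the printed form", {
  m1 <- random_point_moments(seed = 25, order_max = 4)
  m2 <- random_point_moments(seed = 26, order_max = 4)
  expect_equal(moment_pair_distance(m1, m1), 0)
  expect_equal(moment_pair_distance(m1, m2), moment_pair_distance(m2, m1))
  # toy moments evaluated by hand over the full lattice
  t1 <- new_moments(c(2 + 0i), 0)
  t2 <- new_moments(c(0.5 + 0i), 0)
  expect_equal(moment_pair_distance(t1, t2), 1.5 / (2 + 0.5 + 1))
  # order-1 toy: full lattice includes the conjugate negative-m entries
  v1 <- complex(3); v2 <- complex(3)
  v1[2] <- 1 + 0i; v1[3] <- 1i; v2[2] <- 1 + 0i; v2[3] <- 0.5i
  o1 <- new_moments(v1, 1); o2 <- new_moments(v2, 1)
  # (n,l,m)=(1,1,0) equal; (1,1,1) differs by 0.5; (1,1,-1) likewise
  expect_equal(moment_pair_distance(o1, o2), 2 * 0.5 / (1 + 0.5 + 1))
  expect_error(moment_pair_distance(m1, random_point_moments(order_max = 6)),
               "mismatch")
})

test_that("optimal normalization aligns a rotated copy and the identity case", {
  sh <- test_shape(seed = 27, n = 70)
  cfg <- zs_config(grid_width = 0.8)
  rot <- random_ck(28)
  Q <- ck_point_matrix(rot)
  sh2 <- sh; sh2$coords <- sh$coords %*% t(Q)
  a1 <- alignment_descriptor(sh, cfg)
  a2 <- alignment_descriptor(sh2, cfg)
  res <- optimal_normalization(a1, a2)
  expect_false(res$degenerate)
  # distance in standard position is much smaller than unaligned
  expect_lt(res$distance, 0.05 * moment_pair_distance(a1$moments, a2$moments))
  # recovered relative rotation maps s2 points onto s1: p1 = R p2
  expect_lt(rotation_angle_deg(res$rotation, t(Q)), 2)
  # s1 vs itself: zero distance, identity up to the symmetry of the solution set
  self <- optimal_normalization(a1, a1)
  expect_equal(self$distance, 0, tolerance = 1e-9)
  expect_lt(rotation_angle_deg(self$rotation, diag(3)), 1e-6)
})

test_that("order-2 normalization of an elongated shape aligns principal axes", {
  base <- make_shape("random_blob", n_points = 130, radius = 16, seed = 29)
  base$coords[, 1] <- base$coords[, 1] * 2.2       # strongly elongated
  conf <- make_conformer(base, amplitude = 0.8, seed = 30)
  rot <- random_ck(31)
  conf$coords <- conf$coords %*% t(ck_point_matrix(rot))
  cfg <- zs_config(grid_width = 1.0)
  a1 <- alignment_descriptor(base, cfg)
  a2 <- alignment_descriptor(conf, cfg)
  res <- optimal_normalization(a1, a2, orders = 2)
  pax <- function(x) eigen(stats::cov(x), symmetric = TRUE)$vectors[, 1]
  v1 <- pax(base$coords)
  v2 <- res$rotation %*% pax(conf$coords)
  ang <- acos(min(1, abs(sum(v1 * v2)))) * 180 / pi
  expect_lt(ang, 5)
})

test_that("superposition recovers rigid transforms for multiple copies", {
  sh <- test_shape(seed = 32, n = 60)
  cfg <- zs_config(grid_width = 0.8)
  set.seed(33)
  copies <- list(sh)
  truths <- list(rigid_transform(diag(3)))
  for (k in 2:4) {
    tf <- rigid_transform(rotation_matrix(random_ck(330 + k)),
                          rnorm(3, sd = 8))
    copies[[k]] <- apply_transform(sh, tf)
    truths[[k]] <- tf
  }
  res <- cmd_align(copies, config = cfg)
  expect_false(res$degenerate)
  expect_true(all(res$rmsd < 1.5))
  # identical pair gives identity transforms
  res2 <- superpose(list(alignment_descriptor(sh, cfg),
                         alignment_descriptor(sh, cfg)))
  expect_equal(res2$transforms[[2]]$rotation, diag(3), tolerance = 1e-6)
  expect_equal(res2$transforms[[2]]$translation, c(0, 0, 0), tolerance = 1e-6)
  expect_error(cmd_align(list(sh)), "at least 2")
})

test_that("alignment quality degrades gracefully with perturbation amplitude", {
  sh <- test_shape(seed = 35, n = 60)
  cfg <- zs_config(grid_width = 1.0)
  rmsds <- vapply(c(0.5, 4), function(amp) {
    conf <- make_conformer(sh, amp, seed = 36)
    rot <- random_ck(37)
    conf$coords <- conf$coords %*% t(ck_point_matrix(rot))
    res <- cmd_align(list(sh, conf), config = cfg)
    res$rmsd[2]
  }, numeric(1))
  expect_lt(rmsds[1], rmsds[2])
})

test_that("transforms serialize as homogeneous matrices", {
  tf <- rigid_transform(rotation_matrix(random_ck(38)), c(1, 2, 3))
  hom <- transforms_to_json(list(tf))
  expect_equal(dim(hom[[1]]), c(4, 4))
  expect_equal(hom[[1]][1:3, 4], c(1, 2, 3))
  expect_equal(hom[[1]][4, ], c(0, 0, 0, 1))
  f <- tempfile(fileext = ".json")
  transforms_to_json(list(tf), f)
  expect_true(file.exists(f))
})
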