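#' Alignment descriptor
#'
#' Complete 3D Zernike moments to order 6 in the structure's unit-sphere
#' frame, together with the centre of mass (lost by the scaling and needed
#' to superpose in real space).
#'
#' @param atoms a \code{zs_atoms} set.
#' @param config a \code{zs_config}; \code{align_order_max} and
#'   \code{grid_width} are used.
#' @return object of class \code{zs_align}: \code{moments},
#'   \code{center_of_mass}, \code{frame}.
#' @export
alignment_descriptor <- function(atoms, config = zs_config()) {
  stopifnot(inherits(atoms, "zs_atoms"))
  frame <- unit_sphere_frame(atoms)
  vol <- rasterize(atoms, grid_width = config$grid_width)
  mom <- compute_moments(vol, frame, config$align_order_max)
  structure(list(moments = mom, center_of_mass = frame$center,
                 frame = frame), class = "zs_align")
}

#' Relative moment distance (alignment score)
#'
#' The sum over the full index lattice (negative m via conjugation
#' symmetry) of \eqn{|\Omega_{nlm}(s_1)-\Omega_{nlm}(s_2)| /
#' (|\Omega_{nlm}(s_1)|+|\Omega_{nlm}(s_2)|+1)}, evaluated on moment sets
#' already rotated to a candidate standard position.  Symmetric,
#' non-negative, zero for identical moments.
#'
#' @param m1,m2 \code{zs_moments} of equal order.
#' @return non-negative scalar.
#' @export
moment_pair_distance <- function(m1, m2) {
  stopifnot(inherits(m1, "zs_moments"), inherits(m2, "zs_moments"))
  if (m1$order_max != m2$order_max) stop("moment order mismatch")
  idx <- zernike_indices(m1$order_max, with_m = FALSE)
  total <- 0
  for (r in seq_len(nrow(idx))) {
    v1 <- moment_full_m(m1, idx$n[r], idx$l[r])
    v2 <- moment_full_m(m2, idx$n[r], idx$l[r])
    total <- total + sum(Mod(v1 - v2) / (Mod(v1) + Mod(v2) + 1))
  }
  total
}

# All candidate normalization rotations of a moment set: every solution of
# every requested order, labelled by order and solution index.
candidate_normalizations <- function(moments, orders = 2:5) {
  mod <- modify_moments(moments)
  out <- list()
  for (n in orders) {
    if (n > moments$order_max) next
    sol <- solve_normalization(mod, n)
    if (sol$degenerate || !length(sol$rotations)) next
    for (i in seq_along(sol$rotations))
      out[[length(out) + 1L]] <- list(order = n, index = i,
                                      rot = sol$rotations[[i]])
  }
  out
}

#' Optimal pairwise normalization
#'
#' Enumerates candidate Canterakis normalizations of both structures
#' (orders 2-5, all polynomial solutions) and selects the pair of
#' rotations, constrained to the same normalization order, that minimizes
#' the relative moment distance in standard position.  Ties are broken by
#' the enumeration order (lowest order, then first solution).  When every
#' normalization is degenerate for either structure (highly symmetric
#' shapes) the identity rotation is used and flagged.
#'
#' @param s1,s2 \code{zs_align} descriptors.
#' @param orders candidate normalization orders.
#' @return list: \code{rot1}, \code{rot2} (\code{zs_ck}), \code{order},
#'   \code{distance}, \code{rotation} (3x3 matrix mapping s2 coordinates
#'   into s1's orientation), \code{degenerate}.
#' @export
optimal_normalization <- function(s1, s2, orders = 2:5) {
  stopifnot(inherits(s1, "zs_align"), inherits(s2, "zs_align"))
  c1 <- candidate_normalizations(s1$moments, orders)
  c2 <- candidate_normalizations(s2$moments, orders)
  best <- NULL
  for (o in sort(unique(vapply(c1, `[[`, numeric(1), "order")))) {
    k1 <- Filter(function(x) x$order == o, c1)
    k2 <- Filter(function(x) x$order == o, c2)
    if (!length(k1) || !length(k2)) next
    r1 <- lapply(k1, function(x) rotate_moments(s1$moments, x$rot))
    r2 <- lapply(k2, function(x) rotate_moments(s2$moments, x$rot))
    for (i in seq_along(k1)) for (j in seq_along(k2)) {
      d <- moment_pair_distance(r1[[i]], r2[[j]])
      if (is.null(best) || d < best$distance)
        best <- list(rot1 = k1[[i]]$rot, rot2 = k2[[j]]$rot, order = o,
                     distance = d, degenerate = FALSE)
    }
  }
  if (is.null(best)) {
    id <- ck_rotation(1 + 0i, 0i)
    best <- list(rot1 = id, rot2 = id, order = NA_integer_,
                 distance = moment_pair_distance(s1$moments, s2$moments),
                 degenerate = TRUE)
  }
  # points of structure k move to standard position by Q_k = t(R(a,b));
  # matching standard positions gives p1 = Q1^T Q2 p2
  Q1 <- ck_point_matrix(best$rot1)
  Q2 <- ck_point_matrix(best$rot2)
  best$rotation <- t(Q1) %*% Q2
  best
}

#' Rigid transform
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation length-3 vector (Angstrom).
#' @return object of class \code{zs_transform}.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)),
            max(abs(crossprod(rotation) - diag(3))) < 1e-6,
            abs(det(rotation) - 1) < 1e-6)
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "zs_transform")
}

#' Apply a rigid transform to representative atoms
#'
#' @param atoms a \code{zs_atoms} set.
#' @param tf a \code{zs_transform}; points map as \code{R x + t}.
#' @return transformed \code{zs_atoms}.
#' @export
apply_transform <- function(atoms, tf) {
  stopifnot(inherits(atoms, "zs_atoms"), inherits(tf, "zs_transform"))
  out <- atoms
  out$coords <- sweep(atoms$coords %*% t(tf$rotation), 2, tf$translation, "+")
  out
}

#' Superpose structures via their standard positions
#'
#' Aligns every structure onto the target (default the first) by selecting,
#' per normalization order, the target's candidate rotation that minimizes
#' the summed relative moment distance of all other structures' best
#' candidates; translation matches centres of mass.  Cost is linear in the
#' number of structures: each is aligned to the shared standard position
#' independently.
#'
#' @param structures list of \code{zs_align} descriptors (length >= 2).
#' @param target index of the reference structure.
#' @param orders candidate normalization orders.
#' @return list with \code{transforms} (list of \code{zs_transform}, the
#'   target receiving the identity), \code{order}, \code{distances}.
#' @export
superpose <- function(structures, target = 1, orders = 2:5) {
  stopifnot(length(structures) >= 2,
            all(vapply(structures, inherits, logical(1), "zs_align")))
  ref <- structures[[target]]
  others <- setdiff(seq_along(structures), target)
  cref <- candidate_normalizations(ref$moments, orders)
  cand_by_order <- function(cands, o) Filter(function(x) x$order == o, cands)
  cothers <- lapply(structures[others], function(s)
    candidate_normalizations(s$moments, orders))
  best <- NULL
  ref_orders <- sort(unique(vapply(cref, `[[`, numeric(1), "order")))
  for (o in ref_orders) {
    kr <- cand_by_order(cref, o)
    ko <- lapply(cothers, cand_by_order, o)
    if (any(!vapply(ko, length, integer(1)))) next
    rot_oth <- lapply(seq_along(others), function(t1)
      lapply(ko[[t1]], function(x)
        rotate_moments(structures[[others[t1]]]$moments, x$rot)))
    for (i in seq_along(kr)) {
      rref <- rotate_moments(ref$moments, kr[[i]]$rot)
      picks <- integer(length(others)); dsum <- 0
      for (t1 in seq_along(others)) {
        ds <- vapply(rot_oth[[t1]], moment_pair_distance, numeric(1), m1 = rref)
        picks[t1] <- which.min(ds)
        dsum <- dsum + min(ds)
      }
      if (is.null(best) || dsum < best$total)
        best <- list(order = o, ref_rot = kr[[i]]$rot,
                     rots = lapply(seq_along(others), function(t1)
                       ko[[t1]][[picks[t1]]]$rot),
                     dists = vapply(seq_along(others), function(t1)
                       moment_pair_distance(
                         rotate_moments(structures[[others[t1]]]$moments,
                                        ko[[t1]][[picks[t1]]]$rot),
                         rref), numeric(1)),
                     total = dsum)
    }
  }
  transforms <- vector("list", length(structures))
  if (is.null(best)) {
    # all candidate normalizations degenerate: centre-of-mass superposition
    for (k in seq_along(structures))
      transforms[[k]] <- rigid_transform(diag(3),
        ref$center_of_mass - structures[[k]]$center_of_mass)
    return(list(transforms = transforms, order = NA_integer_,
                distances = rep(NA_real_, length(others)), degenerate = TRUE))
  }
  Qr <- ck_point_matrix(best$ref_rot)
  transforms[[target]] <- rigid_transform(diag(3), c(0, 0, 0))
  for (t1 in seq_along(others)) {
    Qk <- ck_point_matrix(best$rots[[t1]])
    R <- t(Qr) %*% Qk
    com_k <- structures[[others[t1]]]$center_of_mass
    transforms[[others[t1]]] <-
      rigid_transform(R, ref$center_of_mass - as.vector(R %*% com_k))
  }
  list(transforms = transforms, order = best$order, distances = best$dists,
       degenerate = FALSE)
}

#' Transforms as homogeneous matrices / JSON
#'
#' @param transforms list of \code{zs_transform}.
#' @param path optional JSON output file.
#' @return list of 4x4 homogeneous matrices (invisibly when writing).
#' @export
transforms_to_json <- function(transforms, path = NULL) {
  hom <- lapply(transforms, function(tf) {
    m <- diag(4)
    m[1:3, 1:3] <- tf$rotation
    m[1:3, 4] <- tf$translation
    m
  })
  if (!is.null(path)) {
    jsonlite::write_json(hom, path, digits = NA)
    return(invisible(hom))
  }
  hom
}

#' Representative-atom RMSD
#'
#' Root-mean-square deviation between two equally sized point sets in
#' corresponding order.  Used only as an alignment quality metric; the
#' alignment itself never uses point correspondences.
#'
#' @param a,b \code{zs_atoms} with equal point counts.
#' @return RMSD in Angstrom.
#' @export
rmsd_atoms <- function(a, b) {
  stopifnot(nrow(a$coords) == nrow(b$coords))
  sqrt(mean(rowSums((a$coords - b$coords)^2)))
}
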