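# Deterministic synthetic shape, conformer and benchmark generation.  The
# generators emulate the statistical design of an assemblies benchmark:
# classes of distinct base shapes, each populated with smoothly deformed
# conformers, so every pipeline stage is testable without external data.

with_seed <- function(seed, code) {
  rng <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(rng)) assign(".Random.seed", rng, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Deterministic synthetic point-cloud shapes
#'
#' Generates a representative-atom set of the requested kind.  The same
#' arguments and seed always give a bitwise-identical point set.
#' Kinds:
#' \describe{
#'   \item{helix_bundle}{a chiral, asymmetric bundle of helical strands;}
#'   \item{ring_cn}{a ring of small blobs with exact Cn symmetry
#'     (\code{symmetry} copies);}
#'   \item{dumbbell}{two dense lobes joined by a thin bar, giving a bimodal
#'     centre-of-mass distance distribution;}
#'   \item{slab}{a flat rectangular plate;}
#'   \item{random_blob}{points in a random anisotropic ellipsoid.}
#' }
#'
#' @param kind shape family (see above).
#' @param n_points approximate point count (exact for most kinds).
#' @param radius overall size scale in Angstrom.
#' @param symmetry rotational symmetry order for \code{ring_cn}.
#' @param seed integer seed.
#' @param masses "unit" for unit point masses or "residue" for masses (and
#'   Gaussian widths) drawn from the standard amino-acid table.
#' @return a \code{zs_atoms} set.
#' @export
make_shape <- function(kind = c("helix_bundle", "ring_cn", "dumbbell",
                                "slab", "random_blob"),
                       n_points = 150, radius = 15, symmetry = 6, seed = 1,
                       masses = c("unit", "residue")) {
  kind <- match.arg(kind)
  masses <- match.arg(masses)
  xyz <- with_seed(seed, switch(
    kind,
    helix_bundle = {
      n_hel <- 3
      per <- ceiling(n_points / n_hel)
      offs <- matrix(rnorm(2 * n_hel, sd = radius / 3), ncol = 2)
      jit <- rnorm(3) * radius / 10     # break all symmetry
      do.call(rbind, lapply(seq_len(n_hel), function(h) {
        t <- seq(0, 4 * pi, length.out = per) + h
        r_h <- radius / 4
        cbind(offs[h, 1] + r_h * cos(t),
              offs[h, 2] + r_h * sin(t),
              seq(-radius, radius, length.out = per) + jit[min(h, 3)] * (h - 2))
      }))[seq_len(min(n_points, per * n_hel)), , drop = FALSE]
    },
    ring_cn = {
      per <- max(3L, floor(n_points / symmetry))
      # compact subunit blobs: keep inter-subunit gaps resolvable so the
      # symmetry order is encoded in high-azimuthal-order moments
      blob <- matrix(rnorm(3 * per, sd = radius / 12), ncol = 3)
      blob[, 1] <- blob[, 1] + radius
      do.call(rbind, lapply(0:(symmetry - 1), function(k) {
        th <- 2 * pi * k / symmetry
        Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
        blob %*% t(Rz)
      }))
    },
    dumbbell = {
      # two dense lobes plus a long thin bar holding half the points, so
      # the centre-of-mass distance distribution is strongly bimodal
      n_lobe <- floor(0.25 * n_points)
      n_bar <- n_points - 2 * n_lobe
      l1 <- matrix(rnorm(3 * n_lobe, sd = radius / 4), ncol = 3)
      l2 <- matrix(rnorm(3 * n_lobe, sd = radius / 4), ncol = 3)
      l1[, 3] <- l1[, 3] - radius
      l2[, 3] <- l2[, 3] + radius
      bar <- cbind(rnorm(n_bar, sd = radius / 12),
                   rnorm(n_bar, sd = radius / 12),
                   seq(-radius, radius, length.out = n_bar))
      rbind(l1, l2, bar)
    },
    slab = {
      k <- ceiling(sqrt(n_points))
      g <- expand.grid(x = seq(-radius, radius, length.out = k),
                       y = seq(-radius, radius, length.out = k))
      cbind(g$x, g$y, rnorm(nrow(g), sd = radius / 20))[seq_len(min(n_points, k * k)), ,
                                                        drop = FALSE]
    },
    random_blob = {
      ax <- sort(runif(3, 0.4, 1), decreasing = TRUE) * radius
      u <- matrix(rnorm(3 * n_points), ncol = 3)
      u <- u / sqrt(rowSums(u^2)) * runif(n_points)^(1 / 3)
      sweep(u, 2, ax, "*")
    }))
  res <- if (masses == "residue")
    with_seed(seed + 1L, sample(names(.aa_mass), nrow(xyz), replace = TRUE))
  else "UNK"
  representative_atoms(
    xyz,
    mass = if (masses == "unit") rep(1, nrow(xyz)) else NULL,
    resid = res,
    source_id = sprintf("%s_n%d_r%g_s%d", kind, nrow(xyz), radius, seed))
}

#' Smoothly deformed conformer of a base shape
#'
#' Applies a low-frequency displacement field, the sum of three random
#' long-wavelength sinusoidal modes, scaled so the RMS displacement equals
#' \code{amplitude}; this emulates slow collective (normal-mode-like)
#' motions.  Amplitude 0 returns the base unchanged; for a fixed seed the
#' field scales linearly with amplitude, so the RMSD from the base grows
#' monotonically.  The per-point displacement never exceeds 3x the RMS
#' mode amplitude sum (a bound used by the tests).
#'
#' @param base a \code{zs_atoms} set.
#' @param amplitude RMS displacement in Angstrom (>= 0).
#' @param seed integer seed for the mode directions and phases.
#' @return a deformed \code{zs_atoms} set.
#' @export
make_conformer <- function(base, amplitude, seed = 1) {
  stopifnot(inherits(base, "zs_atoms"), amplitude >= 0)
  if (amplitude == 0) return(base)
  xyz <- base$coords
  L <- max(apply(xyz, 2, function(v) diff(range(v))), 1e-6)
  disp <- with_seed(seed, {
    d <- matrix(0, nrow(xyz), 3)
    for (mode in 1:3) {
      kvec <- rnorm(3); kvec <- kvec / sqrt(sum(kvec^2)) * (2 * pi / (1.5 * L))
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      ph <- runif(1, 0, 2 * pi)
      d <- d + outer(sin(xyz %*% kvec + ph)[, 1], dir)
    }
    d
  })
  rms <- sqrt(mean(rowSums(disp^2)))
  out <- base
  out$coords <- xyz + disp * (amplitude / max(rms, 1e-12))
  out$source_id <- sprintf("%s_conf_a%g_s%d", base$source_id, amplitude, seed)
  out
}

#' Labeled benchmark of shape classes with conformers
#'
#' Generates \code{n_classes} distinct base shapes (cycling over
#' \code{base_kinds} with varied size/symmetry parameters) and
#' \code{n_members} conformers of each at the given deformation amplitude.
#' Base shapes closer than \code{distinct_floor} in uniform-weight GEO
#' distance to an already accepted shape are resampled, enforcing distinct
#' classes.
#'
#' @param n_classes number of classes (>= 2).
#' @param n_members conformers per class (>= 2; the base is member 1).
#' @param base_kinds shape kinds to cycle over.
#' @param amplitude conformer RMS displacement (Angstrom).
#' @param seed integer seed.
#' @param distinct_floor minimum between-class GEO distance.
#' @return list with \code{atoms} (list of \code{zs_atoms}) and
#'   \code{labels} (class of each entry).
#' @export
make_benchmark <- function(n_classes = 20, n_members = 5,
                           base_kinds = c("helix_bundle", "ring_cn",
                                          "dumbbell", "slab", "random_blob"),
                           amplitude = 1, seed = 1, distinct_floor = 0.5) {
  stopifnot(n_classes >= 2, n_members >= 2)
  bases <- list()
  geo_ref <- list()
  wu <- uniform_weights(1)   # only the GEO block is used for the floor
  geo_dist <- function(g1, g2)
    sum(abs(g1 - g2) / (1 + abs(g1) + abs(g2)))
  tries <- 0L
  cls <- 0L
  while (cls < n_classes) {
    tries <- tries + 1L
    if (tries > 50L * n_classes)
      stop("cannot satisfy distinctness floor; use fewer classes or a lower floor")
    kind <- base_kinds[(cls %% length(base_kinds)) + 1L]
    cand <- make_shape(kind,
                       n_points = 120 + 20 * ((tries + cls) %% 4),
                       radius = 12 + 3 * ((tries + 2 * cls) %% 5),
                       symmetry = 3 + (cls %% 7),
                       seed = seed * 1000L + tries)
    g <- as.numeric(geo_descriptor(cand))
    ok <- all(vapply(geo_ref, function(gr) geo_dist(g, gr) >= distinct_floor,
                     logical(1)))
    if (!ok) next
    cls <- cls + 1L
    bases[[cls]] <- cand
    geo_ref[[cls]] <- g
  }
  atoms <- list(); labels <- character(0)
  for (c1 in seq_len(n_classes)) {
    for (k in seq_len(n_members)) {
      a <- if (k == 1) bases[[c1]]
      else make_conformer(bases[[c1]], amplitude,
                          seed = seed * 10000L + c1 * 100L + k)
      a$source_id <- sprintf("class%02d_m%d", c1, k)
      atoms[[length(atoms) + 1L]] <- a
      labels <- c(labels, sprintf("class%02d", c1))
    }
  }
  list(atoms = atoms, labels = labels)
}
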