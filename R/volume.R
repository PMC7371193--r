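#' Density volume on a regular grid
#'
#' @param values non-negative 3D numeric array.
#' @param grid_width voxel edge length in Angstrom.
#' @param origin Angstrom position of the corner of voxel (1,1,1).
#' @param center_of_mass mass-weighted centroid of the generating atoms
#'   (original coordinates, Angstrom).
#' @param gyration_radius mass-weighted RMS distance to the centroid
#'   (Angstrom).
#' @return object of class \code{zs_volume}.
#' @export
new_volume <- function(values, grid_width, origin, center_of_mass,
                       gyration_radius) {
  stopifnot(length(dim(values)) == 3, grid_width > 0, all(is.finite(values)))
  structure(list(values = values, grid_width = grid_width, origin = origin,
                 center_of_mass = center_of_mass,
                 gyration_radius = gyration_radius),
            class = "zs_volume")
}

#' @export
print.zs_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density volume %d x %d x %d, grid width %.3g A, mass %.4g\n",
              d[1], d[2], d[3], x$grid_width,
              sum(x$values) * x$grid_width^3))
  invisible(x)
}

# Angstrom coordinates of all voxel centres, as an (nvox x 3) matrix in
# array order (first index fastest).
voxel_centers <- function(volume) {
  d <- dim(volume$values)
  ax <- lapply(1:3, function(i)
    volume$origin[i] + (seq_len(d[i]) - 0.5) * volume$grid_width)
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
}

#' Choose the rasterization grid width
#'
#' Picks a width in 0.25-16 Angstrom so that the mean grid dimension
#' (extent / width, in voxels) falls in [50, 200] when possible; otherwise
#' the nearest bound of the width range is returned.  The search runs over
#' the power-of-two ladder 0.25 * 2^k, preferring the finest admissible
#' grid; because the admissible width interval spans a factor of 4 while
#' the ladder steps by 2, an in-range width always exists when the interval
#' overlaps [0.25, 16].
#'
#' @param bounding_extents three positive lengths (Angstrom).
#' @return grid width in Angstrom.
#' @export
choose_grid_width <- function(bounding_extents) {
  if (length(bounding_extents) != 3 || any(!is.finite(bounding_extents)) ||
      any(bounding_extents <= 0))
    stop("bounding_extents must be 3 positive lengths")
  ladder <- 0.25 * 2^(0:6)                # 0.25 .. 16
  mean_ext <- mean(bounding_extents)
  dims <- mean_ext / ladder
  ok <- dims >= 50 & dims <= 200
  if (any(ok)) return(ladder[which(ok)[1]])
  # no admissible width: clamp toward the nearest feasible bound
  if (mean_ext / 0.25 < 50) 0.25 else 16
}

#' Rasterize representative atoms into a Gaussian density volume
#'
#' Each point contributes an isotropic Gaussian with integral equal to its
#' mass and a per-residue-type width from the embedded table (see
#' \code{\link{residue_sigma}}).  Gaussians are truncated at +-3 sigma along
#' each axis (mass loss below 1 percent) and the grid is padded so no
#' truncated Gaussian is clipped.
#'
#' @param atoms a \code{zs_atoms} set (see
#'   \code{\link{representative_atoms}}).
#' @param grid_width voxel edge in Angstrom; \code{NULL} invokes
#'   \code{\link{choose_grid_width}} on the padded bounding box.
#' @return a \code{zs_volume}.
#' @export
rasterize <- function(atoms, grid_width = NULL) {
  stopifnot(inherits(atoms, "zs_atoms"))
  xyz <- atoms$coords
  if (nrow(xyz) < 1) stop("empty atom set")
  sig <- residue_sigma(atoms$resid)
  pad <- 3 * max(sig)
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  if (is.null(grid_width)) grid_width <- choose_grid_width(hi - lo)
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / grid_width)))
  vol <- array(0, dims)
  axes <- lapply(1:3, function(i) lo[i] + (seq_len(dims[i]) - 0.5) * grid_width)
  for (i in seq_len(nrow(xyz))) {
    s <- sig[i]
    m <- atoms$mass[i]
    g1 <- list()
    rng <- list()
    for (d in 1:3) {
      sel <- which(abs(axes[[d]] - xyz[i, d]) <= 3 * s)
      if (!length(sel)) { g1 <- NULL; break }
      rng[[d]] <- sel
      g1[[d]] <- exp(-(axes[[d]][sel] - xyz[i, d])^2 / (2 * s^2)) /
        (sqrt(2 * pi) * s)
    }
    if (is.null(g1)) next
    patch <- outer(outer(g1[[1]], g1[[2]]), g1[[3]]) * m
    vol[rng[[1]], rng[[2]], rng[[3]]] <-
      vol[rng[[1]], rng[[2]], rng[[3]]] + patch
  }
  vol <- vol * grid_width^0  # density units: mass / A^3 (integral via * w^3)
  com <- mass_center(atoms)
  new_volume(vol, grid_width = grid_width, origin = lo,
             center_of_mass = com,
             gyration_radius = gyration_radius(atoms))
}

mass_center <- function(atoms) {
  colSums(atoms$coords * atoms$mass) / sum(atoms$mass)
}

#' Mass-weighted radius of gyration
#'
#' @param atoms a \code{zs_atoms} set.
#' @return RMS mass-weighted distance to the centroid, in Angstrom.
#' @export
gyration_radius <- function(atoms) {
  com <- mass_center(atoms)
  d2 <- rowSums(sweep(atoms$coords, 2, com)^2)
  sqrt(sum(atoms$mass * d2) / sum(atoms$mass))
}

#' Unit-sphere scaling frame
#'
#' The mapping \code{u = scale * (x - center)} with \code{center} the
#' mass-weighted centroid and \code{scale = 1 / (1.8 * Rg)} sends the
#' structure into the unit ball (all but a small mass fraction for very
#' elongated shapes).
#'
#' @param atoms a \code{zs_atoms} set with at least 2 non-coincident points.
#' @return object of class \code{zs_frame} with fields \code{center} and
#'   \code{scale}.
#' @export
unit_sphere_frame <- function(atoms) {
  stopifnot(inherits(atoms, "zs_atoms"))
  rg <- gyration_radius(atoms)
  if (!is.finite(rg) || rg <= 0)
    stop("degenerate geometry: gyration radius is zero (coincident points)")
  structure(list(center = mass_center(atoms), scale = 1 / (1.8 * rg)),
            class = "zs_frame")
}

#' @export
print.zs_frame <- function(x, ...) {
  cat(sprintf("unit-sphere frame: center (%.2f, %.2f, %.2f) A, scale %.4g 1/A\n",
              x$center[1], x$center[2], x$center[3], x$scale))
  invisible(x)
}
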