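#' GEO geometric feature vector
#'
#' 17 fast rotation- and translation-invariant features of a representative
#' atom set, in this fixed order:
#' \enumerate{
#'   \item \code{dist_sd}, \code{dist_skew}, \code{dist_kurt}: standard
#'     deviation, skewness and excess kurtosis of the distances from the
#'     (mass-weighted) centre of mass to all points (unweighted statistics);
#'   \item \code{dist_p10} .. \code{dist_p90}: the 10th..90th percentiles of
#'     that distance distribution (linear interpolation between order
#'     statistics);
#'   \item \code{rg}: mass-weighted radius of gyration (Angstrom);
#'   \item \code{mw}: nominal molecular weight (sum of residue masses, Da);
#'   \item \code{ax_sd1} .. \code{ax_sd3}: standard deviation of the
#'     coordinates along the three principal axes (from the unweighted
#'     coordinate covariance; descending), the dimensions of the structure.
#' }
#'
#' @param atoms a \code{zs_atoms} set with at least 2 points.
#' @return named numeric vector of length 17, class \code{zs_geo}.
#' @export
geo_descriptor <- function(atoms) {
  stopifnot(inherits(atoms, "zs_atoms"))
  xyz <- atoms$coords
  if (nrow(xyz) < 2) stop("degenerate geometry: need at least 2 points")
  com <- mass_center(atoms)
  d <- sqrt(rowSums(sweep(xyz, 2, com)^2))
  pct <- stats::quantile(d, probs = seq(0.1, 0.9, by = 0.1), names = FALSE,
                         type = 7)
  ev <- eigen(stats::cov(xyz), symmetric = TRUE, only.values = TRUE)$values
  sdd <- stats::sd(d)
  # degenerate distance distribution (e.g. points on a sphere shell):
  # shape statistics are defined as 0
  skw <- if (sdd > 0) e1071::skewness(d) else 0
  krt <- if (sdd > 0) e1071::kurtosis(d) else 0
  out <- c(sdd, skw, krt,
           pct, gyration_radius(atoms), sum(atoms$mass),
           sqrt(pmax(0, ev)))
  names(out) <- c("dist_sd", "dist_skew", "dist_kurt",
                  paste0("dist_p", seq(10, 90, 10)),
                  "rg", "mw", paste0("ax_sd", 1:3))
  class(out) <- "zs_geo"
  out
}

#' @export
print.zs_geo <- function(x, ...) {
  cat("GEO descriptor (17 components):\n")
  print(round(unclass(x), 4))
  invisible(x)
}
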