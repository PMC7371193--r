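#' Descriptor pipeline configuration
#'
#' @param order_max Zernike expansion order for the shape descriptor
#'   (default 20, giving 946 CN components per order).
#' @param cn_orders normalization orders entering the composite CN
#'   descriptor (default 2:5, composite length 3784).
#' @param grid_width rasterization voxel width in Angstrom; \code{NULL}
#'   selects it automatically (see \code{\link{choose_grid_width}}).
#' @param align_order_max expansion order of the alignment descriptor
#'   (default 6).
#' @param include_dzd also store the 121-component 3DZD invariants.
#' @return a \code{zs_config} list with a canonical \code{id} string used
#'   to guard descriptor compatibility.
#' @export
zs_config <- function(order_max = 20, cn_orders = 2:5, grid_width = NULL,
                      align_order_max = 6, include_dzd = TRUE) {
  cfg <- list(order_max = as.integer(order_max),
              cn_orders = as.integer(sort(cn_orders)),
              grid_width = grid_width,
              align_order_max = as.integer(align_order_max),
              include_dzd = isTRUE(include_dzd))
  cfg$id <- paste0("N", cfg$order_max,
                   "|cn", paste(cfg$cn_orders, collapse = ","),
                   "|w", if (is.null(grid_width)) "auto" else format(grid_width),
                   "|a", cfg$align_order_max)
  class(cfg) <- "zs_config"
  cfg
}

#' Composite BioZernike-style shape descriptor
#'
#' Runs the full pipeline: representative atoms -> Gaussian density volume
#' -> 3D Zernike moments (order \code{order_max}) -> Canterakis-norm
#' invariants of the configured orders, plus the 17 GEO features and
#' (optionally) the classical 3DZD invariants.  Deterministic given the
#' configuration.
#'
#' @param atoms a \code{zs_atoms} set.
#' @param config a \code{zs_config}.
#' @return object of class \code{zs_descriptor} with fields \code{geo},
#'   \code{cn}, \code{dzd} (or NULL), \code{id}, \code{config_id}.
#' @export
biozernike_descriptor <- function(atoms, config = zs_config()) {
  stopifnot(inherits(atoms, "zs_atoms"), inherits(config, "zs_config"))
  frame <- unit_sphere_frame(atoms)
  vol <- rasterize(atoms, grid_width = config$grid_width)
  mom <- compute_moments(vol, frame, config$order_max)
  structure(list(
    geo = geo_descriptor(atoms),
    cn = composite_cn(mom, config$cn_orders),
    dzd = if (config$include_dzd) descriptor_3dzd(mom) else NULL,
    id = atoms$source_id,
    config_id = config$id), class = "zs_descriptor")
}

#' @export
print.zs_descriptor <- function(x, ...) {
  cat(sprintf("shape descriptor%s: GEO %d + CN %d%s components\n",
              if (nzchar(x$id)) paste0(" [", x$id, "]") else "",
              length(x$geo), length(x$cn),
              if (!is.null(x$dzd)) paste0(" + 3DZD ", length(x$dzd)) else ""))
  invisible(x)
}

#' Distance weights for descriptor comparison
#'
#' Non-negative weights of the composite distance: \code{wg} enters the GEO
#' term squared, \code{wm} the CN term linearly.
#'
#' @param wg 17 non-negative reals.
#' @param wm non-negative reals matching the composite CN length.
#' @param meta optional metadata (fit provenance, thresholds).
#' @return object of class \code{zs_weights}.
#' @export
distance_weights <- function(wg, wm, meta = list()) {
  wg <- as.numeric(wg); wm <- as.numeric(wm)
  if (length(wg) != 17) stop("wg must have 17 components")
  if (any(wg < 0) || any(wm < 0)) stop("weights must be non-negative")
  structure(list(wg = wg, wm = wm, meta = meta), class = "zs_weights")
}

#' Uniform default weights
#'
#' @param n_cn composite CN length (default 3784).
#' @param geo_scale,cn_scale common scale of the two blocks.  The defaults
#'   weight each GEO term as one unit and each CN term by the inverse
#'   composite length, so neither block dominates a priori.
#' @return a \code{zs_weights} object.
#' @export
uniform_weights <- function(n_cn = 4 * 946, geo_scale = 1,
                            cn_scale = 17 / n_cn) {
  distance_weights(rep(sqrt(geo_scale), 17), rep(cn_scale, n_cn),
                   meta = list(kind = "uniform"))
}

#' Weighted descriptor distance
#'
#' The composite dissimilarity
#' \deqn{D = \sum_i w_g(i)^2 \frac{|g_1(i)-g_2(i)|}{1+|g_1(i)|+|g_2(i)|}
#'   + \sum_i w_m(i) |m_1(i)-m_2(i)|}
#' (GEO differences relativized, CN differences absolute).  Symmetric and
#' non-negative; zero when the weighted components coincide.  It is not
#' claimed to satisfy the triangle inequality.
#'
#' @param d1,d2 \code{zs_descriptor} objects with matching lengths.
#' @param w a \code{zs_weights}; default uniform.
#' @return non-negative scalar.
#' @export
descriptor_distance <- function(d1, d2, w = NULL) {
  stopifnot(inherits(d1, "zs_descriptor"), inherits(d2, "zs_descriptor"))
  if (length(d1$cn) != length(d2$cn) || length(d1$geo) != length(d2$geo))
    stop("descriptor length mismatch")
  if (is.null(w)) w <- uniform_weights(length(d1$cn))
  if (length(w$wm) != length(d1$cn)) stop("weight length mismatch")
  g1 <- as.numeric(d1$geo); g2 <- as.numeric(d2$geo)
  sum(w$wg^2 * abs(g1 - g2) / (1 + abs(g1) + abs(g2))) +
    sum(w$wm * abs(d1$cn - d2$cn))
}

#' Serialize descriptors to a data frame / CSV
#'
#' One row per descriptor: id, 17 GEO columns, CN columns (and 3DZD columns
#' when present), plus the config id as a comment-style column.
#'
#' @param descriptors list of \code{zs_descriptor}.
#' @return data.frame.
#' @export
descriptors_to_df <- function(descriptors) {
  stopifnot(length(descriptors) >= 1)
  cfg <- unique(vapply(descriptors, function(d) d$config_id, character(1)))
  if (length(cfg) != 1) stop("descriptors come from different configurations")
  rows <- lapply(descriptors, function(d) {
    v <- c(unclass(d$geo), stats::setNames(d$cn, paste0("cn", seq_along(d$cn))))
    if (!is.null(d$dzd)) v <- c(v, stats::setNames(d$dzd, paste0("dzd", seq_along(d$dzd))))
    as.data.frame(as.list(v), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(id = vapply(descriptors, function(d) d$id, character(1)),
                          config_id = cfg, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Save / load distance weights as JSON
#'
#' @param w a \code{zs_weights} object.
#' @param path JSON file path.
#' @export
write_weights <- function(w, path) {
  stopifnot(inherits(w, "zs_weights"))
  jsonlite::write_json(list(wg = w$wg, wm = w$wm, meta = w$meta), path,
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  distance_weights(x$wg, x$wm, meta = as.list(x$meta))
}
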