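# Retrieval surface: batch description, linear-scan index, search with
# calibrated strict/relaxed thresholds, alignment and benchmark commands.
# Search is deliberately exhaustive: speed comes from the descriptor, not
# from pre-clustering or caching.

#' Batch descriptor computation
#'
#' Computes a shape descriptor (and optionally an alignment descriptor) for
#' every input.  Inputs may be structure file paths or \code{zs_atoms}
#' objects.  Per-input failures are collected and reported; the call fails
#' only if every input fails.
#'
#' @param inputs character vector of file paths or list of \code{zs_atoms}.
#' @param config a \code{zs_config}.
#' @param with_alignment also compute \code{\link{alignment_descriptor}}s.
#' @return object of class \code{zs_index}: lists \code{descriptors},
#'   \code{alignment}, \code{ids}, the \code{config}, and \code{failures}.
#' @export
cmd_describe <- function(inputs, config = zs_config(), with_alignment = FALSE) {
  if (length(inputs) == 0) stop("no inputs given")
  if (is.character(inputs)) inputs <- as.list(inputs)
  descriptors <- list(); alignment <- list(); ids <- character(0)
  failures <- character(0)
  for (k in seq_along(inputs)) {
    res <- tryCatch({
      atoms <- if (inherits(inputs[[k]], "zs_atoms")) inputs[[k]]
      else load_representative_atoms(inputs[[k]])
      list(d = biozernike_descriptor(atoms, config),
           a = if (with_alignment) alignment_descriptor(atoms, config))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0(if (is.character(inputs[[k]]))
        inputs[[k]] else paste0("input ", k), ": ", conditionMessage(res)))
      next
    }
    descriptors[[length(descriptors) + 1L]] <- res$d
    if (with_alignment) alignment[[length(alignment) + 1L]] <- res$a
    ids <- c(ids, res$d$id)
  }
  if (!length(descriptors))
    stop("all inputs failed:\n", paste(failures, collapse = "\n"))
  if (length(failures))
    warning(length(failures), " input(s) failed:\n",
            paste(failures, collapse = "\n"))
  structure(list(descriptors = descriptors, alignment = alignment,
                 ids = ids, config = config, failures = failures),
            class = "zs_index")
}

#' @export
print.zs_index <- function(x, ...) {
  cat(sprintf("descriptor index: %d entries [%s]\n",
              length(x$descriptors), x$config$id))
  invisible(x)
}

#' Calibrate strict / relaxed search thresholds
#'
#' Given labeled benchmark distances, returns the distance at the maximal
#' Matthews correlation coefficient ("strict") and the distance achieving
#' 99.9 percent recall of positives ("relaxed").
#'
#' @param scores distances of labeled pairs.
#' @param labels logical same-class flags.
#' @return named numeric vector \code{c(strict = , relaxed = )}.
#' @export
calibrate_thresholds <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(any(labels), any(!labels))
  ord <- order(scores)
  s <- scores[ord]; lab <- labels[ord]
  np <- sum(lab); nn <- sum(!lab)
  tp <- cumsum(lab); fp <- cumsum(!lab)
  fn <- np - tp; tn <- nn - fp
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- ifelse(den == 0, 0, (tp * tn - fp * fn) / den)
  strict <- s[which.max(mcc)]
  relaxed <- s[which(tp / np >= 0.999)[1]]
  c(strict = strict, relaxed = relaxed)
}

#' Search a descriptor index
#'
#' Exhaustive linear scan: distances from the query to every index entry,
#' ascending, filtered by a threshold.  \code{mode} may be a number or one
#' of "strict"/"relaxed" (thresholds stored in \code{weights$meta} or
#' supplied).
#'
#' @param query a \code{zs_descriptor} (its \code{config_id} must match the
#'   index).
#' @param index a \code{zs_index}.
#' @param weights a \code{zs_weights}; default uniform.
#' @param mode numeric distance threshold, "strict", "relaxed", or
#'   \code{Inf} for no filtering.
#' @param thresholds named vector from \code{\link{calibrate_thresholds}}
#'   used for the named modes.
#' @return data.frame \code{id}, \code{distance}, ascending.
#' @export
cmd_search <- function(query, index, weights = NULL, mode = Inf,
                       thresholds = NULL) {
  stopifnot(inherits(query, "zs_descriptor"), inherits(index, "zs_index"))
  if (query$config_id != index$config$id)
    stop("query and index were computed with different configurations")
  if (is.null(weights)) weights <- uniform_weights(length(query$cn))
  thr <- if (is.numeric(mode)) mode else {
    if (is.null(thresholds)) thresholds <- weights$meta$thresholds
    if (is.null(thresholds)) stop("no calibrated thresholds available")
    unname(thresholds[[match.arg(mode, c("strict", "relaxed"))]])
  }
  d <- vapply(index$descriptors, descriptor_distance, numeric(1),
              d1 = query, w = weights)
  out <- data.frame(id = index$ids, distance = d)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out[out$distance <= thr, , drop = FALSE]
}

#' Align structures and report transforms
#'
#' Thin wrapper over \code{\link{superpose}} accepting files or atom sets;
#' optionally writes transforms as homogeneous matrices in JSON.
#'
#' @param inputs >= 2 file paths or \code{zs_atoms}.
#' @param config a \code{zs_config}.
#' @param target reference structure index.
#' @param json optional output path for the transforms.
#' @return the \code{\link{superpose}} result plus \code{atoms} and,
#'   when point counts match, pairwise RMSD to the target.
#' @export
cmd_align <- function(inputs, config = zs_config(), target = 1, json = NULL) {
  if (length(inputs) < 2) stop("need at least 2 inputs to align")
  atoms <- lapply(inputs, function(x)
    if (inherits(x, "zs_atoms")) x else load_representative_atoms(x))
  descs <- lapply(atoms, alignment_descriptor, config = config)
  res <- superpose(descs, target = target)
  res$atoms <- atoms
  n_ref <- nrow(atoms[[target]]$coords)
  res$rmsd <- vapply(seq_along(atoms), function(k) {
    if (nrow(atoms[[k]]$coords) != n_ref) return(NA_real_)
    rmsd_atoms(apply_transform(atoms[[k]], res$transforms[[k]]),
               apply_transform(atoms[[target]], res$transforms[[target]]))
  }, numeric(1))
  if (!is.null(json)) transforms_to_json(res$transforms, json)
  res
}

#' Fixtures benchmark of retrieval back-ends
#'
#' Generates a labeled benchmark (see \code{\link{make_benchmark}}),
#' computes descriptors, forms all-versus-all pairs and reports ROC AUC,
#' PR AUC and max MCC for each back-end: GEO only, composite CN only,
#' CN+GEO, and 3DZD with Euclidean distance.
#'
#' @param n_classes,n_members,amplitude,seed benchmark parameters.
#' @param config a \code{zs_config}.
#' @param weights optional \code{zs_weights} for the weighted back-ends;
#'   default uniform.
#' @param backends subset of \code{c("geo", "cn", "cn_geo", "dzd")}.
#' @return list with \code{metrics} (data.frame backend x metric),
#'   \code{distances} (matrix pair x backend), \code{pairs}, \code{index}.
#' @export
cmd_benchmark <- function(n_classes = 20, n_members = 5, amplitude = 1,
                          seed = 1, config = zs_config(grid_width = 1.5),
                          weights = NULL,
                          backends = c("geo", "cn", "cn_geo", "dzd")) {
  bench <- make_benchmark(n_classes = n_classes, n_members = n_members,
                          amplitude = amplitude, seed = seed)
  index <- cmd_describe(bench$atoms, config)
  pairs <- make_pairs(bench$labels)
  feats <- pair_features(index$descriptors, pairs)
  n_cn <- length(index$descriptors[[1]]$cn)
  if (is.null(weights)) weights <- uniform_weights(n_cn)
  geo_term <- as.vector(feats[, 1:17, drop = FALSE] %*% weights$wg^2)
  cn_term <- as.vector(feats[, -(1:17), drop = FALSE] %*% weights$wm)
  dist_tab <- list(geo = geo_term, cn = cn_term, cn_geo = geo_term + cn_term)
  if ("dzd" %in% backends) {
    Z <- t(vapply(index$descriptors, function(d) d$dzd,
                  numeric(length(index$descriptors[[1]]$dzd))))
    dist_tab$dzd <- sqrt(rowSums((Z[pairs$i, , drop = FALSE] -
                                  Z[pairs$j, , drop = FALSE])^2))
  }
  dist_tab <- dist_tab[intersect(c("geo", "cn", "cn_geo", "dzd"), backends)]
  metrics <- do.call(rbind, lapply(names(dist_tab), function(b) {
    m <- retrieval_metrics(dist_tab[[b]], pairs$positive)
    data.frame(backend = b, roc_auc = m$roc_auc, pr_auc = m$pr_auc,
               max_mcc = m$max_mcc)
  }))
  list(metrics = metrics, distances = do.call(cbind, dist_tab),
       pairs = pairs, index = index, labels = bench$labels)
}

#' Fit distance weights on a fixtures benchmark
#'
#' Generates a benchmark, computes descriptors and pair features, and runs
#' the grouped-CV non-negative logistic fit.
#'
#' @inheritParams cmd_benchmark
#' @param nfolds CV folds.
#' @return a \code{zs_weights}.
#' @export
cmd_fit_weights <- function(n_classes = 10, n_members = 4, amplitude = 1.5,
                            seed = 2, config = zs_config(grid_width = 1.5),
                            nfolds = 10) {
  bench <- make_benchmark(n_classes = n_classes, n_members = n_members,
                          amplitude = amplitude, seed = seed)
  index <- cmd_describe(bench$atoms, config)
  pairs <- make_pairs(bench$labels)
  feats <- pair_features(index$descriptors, pairs)
  fit_weights(feats, pairs$positive, groups = bench$labels[pairs$i],
              nfolds = nfolds, seed = seed)
}
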