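#' All-versus-all labeled pairs
#'
#' Builds every unordered pair of items; a pair is positive when both items
#' carry the same class label.  For c balanced classes of size k this gives
#' \code{c * choose(k, 2)} positives (the benchmark construction: 500
#' classes of 5 conformers yield 5000 positives and 3118750 negatives).
#'
#' @param labels class labels, one per item (length >= 2).
#' @return data.frame with integer columns \code{i}, \code{j} (i < j) and
#'   logical \code{positive}.
#' @export
make_pairs <- function(labels) {
  n <- length(labels)
  if (n < 2) stop("need at least 2 items")
  j <- rep.int(2:n, 1:(n - 1))
  i <- sequence(1:(n - 1))
  data.frame(i = i, j = j, positive = labels[i] == labels[j])
}

#' Per-pair feature columns of the descriptor distance
#'
#' One column per distance term: 17 relativized GEO differences
#' \code{|g1-g2| / (1+|g1|+|g2|)} followed by the absolute CN differences.
#' A non-negative weight vector applied to these columns reproduces the
#' composite distance, so fitted coefficients map directly onto
#' \code{wg^2} and \code{wm}.
#'
#' @param descriptors list of \code{zs_descriptor}.
#' @param pairs data.frame from \code{\link{make_pairs}}.
#' @return numeric matrix (npairs x (17 + n_cn)).
#' @export
pair_features <- function(descriptors, pairs) {
  G <- t(vapply(descriptors, function(d) as.numeric(d$geo), numeric(17)))
  M <- t(vapply(descriptors, function(d) d$cn,
                numeric(length(descriptors[[1]]$cn))))
  g1 <- G[pairs$i, , drop = FALSE]; g2 <- G[pairs$j, , drop = FALSE]
  geo_part <- abs(g1 - g2) / (1 + abs(g1) + abs(g2))
  cn_part <- abs(M[pairs$i, , drop = FALSE] - M[pairs$j, , drop = FALSE])
  out <- cbind(geo_part, cn_part)
  colnames(out) <- c(names(descriptors[[1]]$geo),
                     paste0("cn", seq_len(ncol(cn_part))))
  out
}

#' Fit non-negative distance weights by regularized logistic regression
#'
#' Models the probability that a pair is same-class as a logistic function
#' of minus the weighted distance, i.e. logistic regression of the pair
#' label on the distance feature columns with coefficients constrained to
#' be non-positive (L1 penalty); weights are the negated coefficients, so
#' the fitted linear score is exactly the composite distance.  The penalty
#' strength is chosen by grouped cross-validation at the class level,
#' maximizing the Matthews correlation coefficient of held-out hard
#' classifications; together with the sign constraint this yields sparse
#' weight vectors (most components exactly zero).
#'
#' @param features matrix from \code{\link{pair_features}}.
#' @param positive logical pair labels.
#' @param groups class label of each pair used for fold construction
#'   (e.g. the class of the pair's first member).
#' @param nfolds number of grouped CV folds (default 10).
#' @param seed integer seed making fold assignment deterministic.
#' @param n_geo number of leading columns belonging to the GEO block
#'   (default 17); their fitted coefficients are returned as \code{wg}
#'   via a square root.
#' @return a \code{zs_weights} with fit metadata (chosen lambda, CV MCC).
#' @export
fit_weights <- function(features, positive, groups, nfolds = 10, seed = 1,
                        n_geo = 17) {
  features <- as.matrix(features)
  positive <- as.logical(positive)
  if (length(unique(positive)) < 2)
    stop("need both positive and negative pairs to fit weights")
  classes <- sort(unique(as.character(groups)))
  if (length(classes) < 2) stop("need at least 2 classes")
  nfolds <- min(nfolds, length(classes))
  rng <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(rng)) assign(".Random.seed", rng, envir = globalenv()))
  set.seed(seed)
  class_fold <- sample(rep_len(seq_len(nfolds), length(classes)))
  fold <- class_fold[match(as.character(groups), classes)]
  y <- as.numeric(positive)
  fit_full <- glmnet::glmnet(features, y, family = "binomial", alpha = 1,
                             upper.limits = 0, standardize = FALSE,
                             lambda.min.ratio = 1e-4, nlambda = 60)
  lambdas <- fit_full$lambda
  mcc_sum <- matrix(NA_real_, nfolds, length(lambdas))
  for (k in seq_len(nfolds)) {
    tr <- fold != k
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
    fk <- glmnet::glmnet(features[tr, , drop = FALSE], y[tr],
                         family = "binomial", alpha = 1, upper.limits = 0,
                         standardize = FALSE, lambda = lambdas)
    pr <- stats::predict(fk, features[!tr, , drop = FALSE], type = "response")
    # MCC of the held-out hard classifications (same-class iff p >= 0.5)
    mcc_sum[k, seq_len(ncol(pr))] <- apply(pr >= 0.5, 2, binary_mcc,
                                           truth = positive[!tr])
  }
  mean_mcc <- colMeans(mcc_sum, na.rm = TRUE)
  best <- which.max(mean_mcc)
  coefs <- as.numeric(stats::coef(fit_full)[-1, best])
  w <- pmax(0, -coefs)
  distance_weights(sqrt(w[seq_len(n_geo)]), w[-seq_len(n_geo)],
                   meta = list(kind = "fitted",
                               lambda = lambdas[best],
                               cv_mcc = mean_mcc[best],
                               nfolds = nfolds, seed = seed))
}

binary_mcc <- function(pred, truth) {
  tp <- sum(pred & truth); tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# max MCC over thresholds for distance-like scores (smaller = positive)
max_mcc_sweep <- function(scores, labels) {
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) return(0)
  ord <- order(scores)
  lab <- labels[ord]; so <- scores[ord]
  tp <- cumsum(lab); fp <- cumsum(!lab)
  last <- c(so[-1] != so[-length(so)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  fn <- np - tp; tn <- nn - fp
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  max(ifelse(den == 0, 0, (tp * tn - fp * fn) / den))
}

#' Retrieval quality metrics
#'
#' ROC AUC, precision-recall AUC and the maximal Matthews correlation
#' coefficient over all score thresholds, for distances where smaller
#' means more likely positive.  ROC AUC uses the rank (Mann-Whitney)
#' statistic with tie correction; PR AUC is the step-interpolated average
#' precision; max MCC sweeps every distinct threshold.
#'
#' @param scores numeric distances.
#' @param labels logical; TRUE for same-class (positive) pairs.
#' @return named list \code{roc_auc}, \code{pr_auc}, \code{max_mcc}.
#' @export
retrieval_metrics <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) stop("need at least one positive and one negative")
  s <- -as.numeric(scores)                      # larger = more positive
  r <- rank(s)
  roc_auc <- (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(s, decreasing = TRUE)
  lab <- labels[ord]; so <- s[ord]
  tp <- cumsum(lab); fp <- cumsum(!lab)
  last <- c(so[-1] != so[-length(so)], TRUE)    # threshold group ends
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp); rec <- tp / np
  pr_auc <- sum(diff(c(0, rec)) * prec)
  list(roc_auc = roc_auc, pr_auc = pr_auc,
       max_mcc = max_mcc_sweep(as.numeric(scores), labels))
}
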