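# class labels (classA/classB factor) for the samples of a feature matrix
.case_labels <- function(features, labels) {
  ann <- labels[match(rownames(features), labels$sample_id), ]
  keep <- !is.na(ann$phenotype) & ann$phenotype %in% c("classA", "classB")
  y <- factor(as.character(ann$phenotype[keep]), levels = c("classA", "classB"))
  list(x = features[keep, , drop = FALSE], y = y)
}

#' Area under the ROC curve (Mann-Whitney convention)
#'
#' AUC computed from rank statistics with the Mann-Whitney tie convention:
#' tied positive/negative pairs count one half. The positive class is classA
#' (the Crohn's-disease analogue in the disease application).
#'
#' @param scores Numeric vector of classifier scores (higher = more classA).
#' @param is_positive Logical vector, TRUE for classA samples.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, is_positive) {
  n_pos <- sum(is_positive); n_neg <- sum(!is_positive)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[is_positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Train a random-forest ensemble
#'
#' Trains `n_models` random forests that differ only in their random seed
#' (`seed + 0 ... seed + n_models - 1`); with `resample = TRUE` each model is
#' additionally trained on a bootstrap resample of the training samples.
#' Forest hyperparameters are the randomForest classification defaults with
#' `ntree` trees and are recorded on the ensemble.
#'
#' @param train A `feature_matrix` of training samples.
#' @param labels A [sample_annotation()]; only classA/classB samples are
#'   used.
#' @param n_models Number of forests (>= 1).
#' @param seed Base integer seed.
#' @param ntree Trees per forest (default 500).
#' @param resample Bootstrap-resample training samples per model.
#' @return An object of class `rf_ensemble`.
#' @export
train_ensemble <- function(train, labels, n_models = 100L, seed = 0L,
                           ntree = 500L, resample = FALSE) {
  if (n_models < 1L) stop("n_models must be at least 1")
  d <- .case_labels(train, labels)
  if (nlevels(droplevels(d$y)) < 2L) stop("training labels contain a single class")
  if (min(table(d$y)) < 2L) stop("need at least 2 training samples per class")
  models <- vector("list", n_models)
  for (i in seq_len(n_models)) {
    models[[i]] <- with_local_seed(seed + i - 1L, {
      if (resample) {
        idx <- sample.int(nrow(d$x), replace = TRUE)
        randomForest::randomForest(d$x[idx, , drop = FALSE], d$y[idx], ntree = ntree)
      } else {
        randomForest::randomForest(d$x, d$y, ntree = ntree)
      }
    })
  }
  structure(list(models = models, n_models = as.integer(n_models),
                 feature_ids = colnames(train),
                 classes = levels(d$y),
                 seeds = seed + seq_len(n_models) - 1L,
                 hyperparameters = list(ntree = ntree,
                                        mtry = floor(sqrt(ncol(train))),
                                        resample = resample)),
            class = "rf_ensemble")
}

#' @export
print.rf_ensemble <- function(x, ...) {
  cat(sprintf("Random-forest ensemble: %d models x %d trees on %d features\n",
              x$n_models, x$hyperparameters$ntree, length(x$feature_ids)))
  invisible(x)
}

#' Score test samples and compute per-model AUCs
#'
#' Every model scores the test samples (class-probability of classA); each
#' model's AUC is computed with classA positive and ties at one half, and the
#' ensemble is summarized by the median AUC. Per-sample median probabilities
#' across models are returned for aggregate ROC analysis.
#'
#' @param ensemble An `rf_ensemble`.
#' @param test A `feature_matrix` with the training feature columns.
#' @param labels A [sample_annotation()] covering the test samples.
#' @return A list: `per_model_auc`, `median_auc`, `median_prob` (named
#'   per-sample vector), `is_positive`.
#' @export
score_and_auc <- function(ensemble, test, labels) {
  if (!identical(colnames(test), ensemble$feature_ids)) {
    if (!setequal(colnames(test), ensemble$feature_ids))
      stop("test features do not match the training features")
    test <- test[, ensemble$feature_ids, drop = FALSE]
  }
  d <- .case_labels(test, labels)
  if (nlevels(droplevels(d$y)) < 2L) stop("test labels contain a single class")
  probs <- vapply(ensemble$models, function(m)
    stats::predict(m, d$x, type = "prob")[, "classA"], numeric(nrow(d$x)))
  probs <- matrix(probs, nrow = nrow(d$x),
                  dimnames = list(rownames(d$x), NULL))
  is_pos <- d$y == "classA"
  per_model <- apply(probs, 2L, auc_mw, is_positive = is_pos)
  list(per_model_auc = per_model,
       median_auc = stats::median(per_model),
       median_prob = apply(probs, 1L, stats::median),
       is_positive = stats::setNames(is_pos, rownames(d$x)))
}

#' Area under the precision-recall curve
#'
#' Step-wise interpolation over the distinct score thresholds, with classA as
#' the positive class: AUPRC = sum over threshold steps of
#' (recall gain) x (precision at that threshold). With constant scores the
#' curve has a single point and the area equals the positive prevalence.
#'
#' @param scores Numeric vector of scores (higher = more classA).
#' @param is_positive Logical vector, TRUE for classA samples.
#' @return AUPRC in `[0, 1]`.
#' @export
pr_auc <- function(scores, is_positive) {
  if (!any(is_positive)) stop("no positive samples")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- is_positive[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- c(s[-1] != s[-length(s)], TRUE)   # last index of each distinct score
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / sum(is_positive)
  sum(diff(c(0, recall)) * precision)
}

#' DeLong's test for two correlated ROC curves
#'
#' Paired comparison of two score vectors on the same samples using DeLong's
#' structural-component covariance estimate, with a two-sided p-value from
#' the normal approximation. Identical score vectors have a zero-variance
#' AUC difference, reported as z = 0, p = 1.
#'
#' @param scores1,scores2 Numeric score vectors on the same samples.
#' @param is_positive Logical vector, TRUE for classA samples.
#' @return A list with `auc1`, `auc2`, `z`, `p`.
#' @export
delong_test <- function(scores1, scores2, is_positive) {
  if (length(scores1) != length(scores2) ||
      length(scores1) != length(is_positive))
    stop("scores1, scores2 and is_positive must have equal length")
  m <- sum(is_positive); n <- sum(!is_positive)
  if (m < 2L || n < 2L) stop("need at least 2 samples in each class")
  psi <- function(x, y) outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v <- lapply(list(scores1, scores2), function(s) {
    P <- psi(s[is_positive], s[!is_positive])
    list(v10 = rowMeans(P), v01 = colMeans(P), auc = mean(P))
  })
  auc1 <- v[[1]]$auc; auc2 <- v[[2]]$auc
  s10 <- stats::cov(cbind(v[[1]]$v10, v[[2]]$v10))
  s01 <- stats::cov(cbind(v[[1]]$v01, v[[2]]$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  z <- if (var_diff <= 0) 0 else (auc1 - auc2) / sqrt(var_diff)
  list(auc1 = auc1, auc2 = auc2, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Mean decrease in Gini importance, averaged over an ensemble
#'
#' @param ensemble An `rf_ensemble`.
#' @return Data frame (`feature`, `mean_decrease_gini`) sorted descending.
#' @export
gini_importance <- function(ensemble) {
  imp <- vapply(ensemble$models, function(m)
    randomForest::importance(m)[, "MeanDecreaseGini"],
    numeric(length(ensemble$feature_ids)))
  imp <- matrix(imp, nrow = length(ensemble$feature_ids),
                dimnames = list(ensemble$feature_ids, NULL))
  out <- data.frame(feature = rownames(imp),
                    mean_decrease_gini = rowMeans(imp),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$mean_decrease_gini), , drop = FALSE]
}

#' Classical MDS embedding under cosine distance
#'
#' Pairwise cosine distances (1 - cosine similarity) between sample feature
#' vectors, embedded into `n_dims` dimensions by classical (metric)
#' multidimensional scaling. Classical MDS is an eigendecomposition, hence
#' fully deterministic.
#'
#' @param features A samples x features numeric matrix (>= 3 samples).
#' @param n_dims Embedding dimension (default 2).
#' @return A samples x n_dims coordinate matrix.
#' @export
mds_embedding <- function(features, n_dims = 2L) {
  if (nrow(features) < 3L) stop("need at least 3 samples")
  norms <- sqrt(rowSums(features^2))
  zero <- norms == 0
  if (any(zero))
    stop("cosine distance undefined for zero-vector sample(s): ",
         paste(rownames(features)[zero], collapse = ", "))
  sim <- (features / norms) %*% t(features / norms)
  dmat <- 1 - sim
  dmat[dmat < 0] <- 0   # guard tiny negative round-off
  d <- stats::as.dist(dmat)
  coords <- stats::cmdscale(d, k = n_dims)
  rownames(coords) <- rownames(features)
  coords
}

#' Pathway differences behind misclassified samples
#'
#' Within each true class, compares every feature between the misclassified
#' and correctly classified samples of that class with a two-sided
#' pooled-variance Student t-test, ranking features by ascending p-value.
#' Classes without misclassified samples contribute no rows; with no
#' misclassifications at all the table is empty.
#'
#' @param features A samples x features `feature_matrix`.
#' @param labels A [sample_annotation()] with the true classes.
#' @param predictions Named character vector of predicted classes
#'   (classA/classB) per sample.
#' @return Data frame (`class`, `feature`, `t`, `p`) sorted by p within
#'   class.
#' @export
misclassification_pathway_report <- function(features, labels, predictions) {
  out <- list()
  for (cls in c("classA", "classB")) {
    ids <- intersect(samples_of(labels, cls), rownames(features))
    ids <- intersect(ids, names(predictions))
    mis <- ids[predictions[ids] != cls]
    cor <- ids[predictions[ids] == cls]
    if (length(mis) < 1L || length(cor) < 2L) next
    res <- apply(features[ids, , drop = FALSE], 2L, function(v) {
      x <- v[match(mis, ids)]; y <- v[match(cor, ids)]
      n1 <- length(x); n2 <- length(y)
      ss1 <- if (n1 > 1L) (n1 - 1) * stats::var(x) else 0
      sp2 <- (ss1 + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      if (se == 0) {
        if (mean(x) == mean(y)) return(c(t = 0, p = 1))
        return(c(t = sign(mean(x) - mean(y)) * Inf, p = 0))
      }
      t <- (mean(x) - mean(y)) / se
      c(t = t, p = 2 * stats::pt(-abs(t), n1 + n2 - 2))
    })
    tab <- data.frame(class = cls, feature = colnames(features),
                      t = res["t", ], p = res["p", ],
                      stringsAsFactors = FALSE, row.names = NULL)
    out[[cls]] <- tab[order(tab$p), , drop = FALSE]
  }
  if (length(out) == 0L)
    return(data.frame(class = character(0), feature = character(0),
                      t = numeric(0), p = numeric(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
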