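# vectorized two-sided Welch t-test per gene (rows) between two sample sets
.welch_t_rows <- function(mat, cols1, cols2) {
  x <- mat[, cols1, drop = FALSE]; y <- mat[, cols2, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1L, stats::var); v2 <- apply(y, 1L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  t[se2 == 0] <- 0
  df[se2 == 0] <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(t), df)
  data.frame(gene = rownames(mat), t = t, df = df, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

# training case samples present in the matrix, by class
.train_cols <- function(matrix, labels, phenotype, min_n = 2L) {
  cols <- intersect(samples_of(labels, phenotype), colnames(matrix))
  if (length(cols) < min_n)
    stop(sprintf("need at least %d %s training sample(s); found %d",
                 min_n, phenotype, length(cols)))
  cols
}

# restrict gene sets to measured genes, dropping emptied sets with a warning
.measured_sets <- function(gene_sets, measured) {
  out <- lapply(gene_sets, intersect, y = measured)
  empty <- vapply(out, length, integer(1)) == 0L
  if (any(empty)) {
    warning(sum(empty), " gene set(s) with no measured genes dropped: ",
            paste(utils::head(names(out)[empty], 5), collapse = ", "))
    out <- out[!empty]
  }
  if (length(out) == 0L) stop("no gene set has measured genes")
  out
}

#' Gene-level baseline features
#'
#' Four gene-level feature sets used as classification baselines: all
#' measured genes; genes belonging to at least one pathway; an explicit gene
#' panel; or the top `k` genes ranked by two-sided Welch t-test between the
#' two case classes on training samples only.
#'
#' @param matrix Expression matrix (genes x samples); all its samples are
#'   scored.
#' @param mode One of `"all"`, `"pathway_genes"`, `"panel"`, `"top_k"`.
#' @param labels A [sample_annotation()]; used only by `top_k` (training
#'   classA/classB samples).
#' @param k Number of genes for `top_k`.
#' @param panel Character vector of gene ids for `panel`.
#' @param pathway_genes Character vector of pathway-member gene ids for
#'   `pathway_genes`.
#' @return A `feature_matrix` (samples x genes), method tag `genes`.
#' @export
gene_features <- function(matrix, mode = c("all", "pathway_genes", "panel", "top_k"),
                          labels = NULL, k = NULL, panel = NULL,
                          pathway_genes = NULL) {
  mode <- match.arg(mode)
  validate_expression_matrix(matrix)
  sel <- switch(mode,
    all = rownames(matrix),
    pathway_genes = {
      if (is.null(pathway_genes)) stop("mode 'pathway_genes' needs pathway_genes")
      sel <- intersect(rownames(matrix), pathway_genes)
      if (length(sel) == 0L) stop("no pathway gene is measured")
      sel
    },
    panel = {
      if (is.null(panel)) stop("mode 'panel' needs an explicit gene panel")
      miss <- setdiff(panel, rownames(matrix))
      if (length(miss) > 0L)
        stop("panel gene(s) absent from the matrix: ", paste(miss, collapse = ", "))
      panel
    },
    top_k = {
      if (is.null(k)) stop("mode 'top_k' needs k")
      if (k > nrow(matrix)) stop("k exceeds the number of measured genes")
      a <- .train_cols(matrix, labels, "classA")
      b <- .train_cols(matrix, labels, "classB")
      tt <- .welch_t_rows(matrix, a, b)
      tt$gene[order(tt$p, -abs(tt$t))][seq_len(k)]
    })
  feature_matrix(t(matrix[sel, , drop = FALSE]), method = "genes", mode = mode)
}

#' Log-likelihood-ratio pathway features
#'
#' Per gene, class-conditional Gaussians are fitted (maximum-likelihood mean
#' and variance) to the classA and classB training samples; each sample's raw
#' LLR for a gene is the difference of the two log-densities at its observed
#' value. Raw LLRs are z-normalized per gene (by default frozen on the
#' training case samples' statistics; `pool_normalization = TRUE` normalizes
#' across all scored samples instead) and summed over each pathway's genes.
#'
#' @param gene_sets Named list of gene-id vectors.
#' @param matrix Expression matrix (genes x samples); all samples scored.
#' @param labels A [sample_annotation()] marking training classA/classB
#'   samples (at least 2 each).
#' @param pool_normalization Normalize across all scored samples instead of
#'   freezing on training statistics.
#' @return A `feature_matrix` (samples x pathways), method tag `llr`.
#' @export
llr_features <- function(gene_sets, matrix, labels, pool_normalization = FALSE) {
  validate_expression_matrix(matrix)
  a <- .train_cols(matrix, labels, "classA")
  b <- .train_cols(matrix, labels, "classB")
  sets <- .measured_sets(gene_sets, rownames(matrix))
  genes <- sort(unique(unlist(sets)))
  sub <- matrix[genes, , drop = FALSE]
  mle_var <- function(m) rowSums((m - rowMeans(m))^2) / ncol(m)
  floor_var <- function(v) {
    if (any(v < VARIANCE_FLOOR))
      warning("zero-variance gene(s) in a class; variance floored")
    pmax(v, VARIANCE_FLOOR)
  }
  mA <- rowMeans(sub[, a, drop = FALSE]); vA <- floor_var(mle_var(sub[, a, drop = FALSE]))
  mB <- rowMeans(sub[, b, drop = FALSE]); vB <- floor_var(mle_var(sub[, b, drop = FALSE]))
  # log N(x; mA, vA) - log N(x; mB, vB), per gene (row) and sample (column)
  raw <- -0.5 * log(2 * pi * vA) - (sub - mA)^2 / (2 * vA) +
          0.5 * log(2 * pi * vB) + (sub - mB)^2 / (2 * vB)
  norm_cols <- if (pool_normalization) colnames(sub) else c(a, b)
  mu <- rowMeans(raw[, norm_cols, drop = FALSE])
  sd <- apply(raw[, norm_cols, drop = FALSE], 1L, stats::sd)
  z <- (raw - mu) / sd
  z[sd == 0, ] <- 0   # identical class-conditional fits carry no signal
  values <- vapply(sets, function(g) colSums(z[g, , drop = FALSE]),
                   numeric(ncol(sub)))
  feature_matrix(matrix(values, ncol = length(sets),
                        dimnames = list(colnames(sub), names(sets))),
                 method = "llr", pooled = pool_normalization)
}

#' Condition-responsive-genes (CORG) pathway features
#'
#' Per pathway, member genes are z-scored across all scored samples and
#' ranked by the absolute Welch t-statistic between the classA and classB
#' training samples. Genes are added greedily to the responsive subset S; the
#' pathway activity is `a(s) = sum_{g in S} z_gs / sqrt(|S|)`, and a
#' candidate gene is accepted only while the activity's |t| strictly
#' improves. The feature is the final subset's activity; selected genes are
#' recorded in the `selected` attribute.
#'
#' @inheritParams llr_features
#' @return A `feature_matrix` (samples x pathways), method tag `corg`.
#' @export
corg_features <- function(gene_sets, matrix, labels) {
  validate_expression_matrix(matrix)
  a <- .train_cols(matrix, labels, "classA")
  b <- .train_cols(matrix, labels, "classB")
  sets <- .measured_sets(gene_sets, rownames(matrix))
  genes <- sort(unique(unlist(sets)))
  sub <- matrix[genes, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  sds[sds == 0] <- 1   # constant gene: z-score identically 0
  z <- (sub - rowMeans(sub)) / sds
  act_t <- function(act) {
    t <- stats::t.test(act[a], act[b])$statistic
    if (is.finite(t)) abs(unname(t)) else 0
  }
  values <- matrix(NA_real_, nrow = ncol(sub), ncol = length(sets),
                   dimnames = list(colnames(sub), names(sets)))
  selected <- vector("list", length(sets))
  names(selected) <- names(sets)
  for (pw in names(sets)) {
    g <- sets[[pw]]
    tt <- .welch_t_rows(sub[g, , drop = FALSE], a, b)
    ranked <- tt$gene[order(-abs(tt$t))]
    S <- ranked[1L]
    act <- z[S, ]
    best <- act_t(act)
    for (cand in ranked[-1L]) {
      S2 <- c(S, cand)
      act2 <- colSums(z[S2, , drop = FALSE]) / sqrt(length(S2))
      t2 <- act_t(act2)
      if (t2 > best) { S <- S2; act <- act2; best <- t2 } else break
    }
    values[, pw] <- act
    selected[[pw]] <- S
  }
  feature_matrix(values, method = "corg", selected = selected)
}

#' Normal-tissue-centroid (NTC) pathway features
#'
#' Per pathway, the reference centroid is the per-gene mean over REFERENCE
#' samples restricted to the pathway's measured genes; each sample's feature
#' is its Euclidean distance to that centroid.
#'
#' @inheritParams llr_features
#' @return A `feature_matrix` (samples x pathways), method tag `ntc`.
#' @export
ntc_features <- function(gene_sets, matrix, labels) {
  validate_expression_matrix(matrix)
  ref <- intersect(samples_of(labels, "reference"), colnames(matrix))
  if (length(ref) == 0L) stop("need at least 1 reference sample")
  sets <- .measured_sets(gene_sets, rownames(matrix))
  values <- vapply(sets, function(g) {
    sub <- matrix[g, , drop = FALSE]
    centroid <- rowMeans(sub[, ref, drop = FALSE])
    sqrt(colSums((sub - centroid)^2))
  }, numeric(ncol(matrix)))
  feature_matrix(matrix(values, ncol = length(sets),
                        dimnames = list(colnames(matrix), names(sets))),
                 method = "ntc")
}

#' Gene-expression-deviation (GED) pathway features
#'
#' Two features per pathway, one aggregating over-expressed genes and one
#' under-expressed genes. A gene participates when the two-sample
#' Kolmogorov-Smirnov test between a case class's training distribution and
#' the REFERENCE distribution is significant at `alpha`. Each participating
#' gene contributes a per-sample score — by default the absolute
#' reference-standardized deviation `|x - mean_ref| / sd_ref`, injectable via
#' `score_fn` — to the over or under feature according to the sign of its
#' training-sample mean deviation from reference. Gene inclusion and sign are
#' decided on training samples only. No promiscuous-gene or silhouette
#' pruning is applied: all genes and pathways are kept.
#'
#' @inheritParams llr_features
#' @param alpha KS significance level in (0,1); default 0.05.
#' @param score_fn Function `(x, ref_mean, ref_sd) -> score` giving each
#'   included gene's per-sample (nonnegative) contribution.
#' @return A `feature_matrix` (samples x 2*pathways, columns
#'   `<pathway>_over` / `<pathway>_under`), method tag `ged`.
#' @export
ged_features <- function(gene_sets, matrix, labels, alpha = 0.05,
                         score_fn = function(x, ref_mean, ref_sd)
                           abs((x - ref_mean) / ref_sd)) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0,1)")
  validate_expression_matrix(matrix)
  ref <- .train_cols(matrix, labels, "reference")
  a <- .train_cols(matrix, labels, "classA")
  b <- .train_cols(matrix, labels, "classB")
  sets <- .measured_sets(gene_sets, rownames(matrix))
  genes <- sort(unique(unlist(sets)))
  sub <- matrix[genes, , drop = FALSE]
  ref_mean <- rowMeans(sub[, ref, drop = FALSE])
  ref_sd <- apply(sub[, ref, drop = FALSE], 1L, stats::sd)
  if (any(ref_sd < sqrt(VARIANCE_FLOOR))) {
    warning("zero reference variance gene(s); sd floored")
    ref_sd <- pmax(ref_sd, sqrt(VARIANCE_FLOOR))
  }
  ks_p <- function(g, cols) suppressWarnings(
    stats::ks.test(sub[g, cols], sub[g, ref])$p.value)
  sig <- vapply(genes, function(g)
    ks_p(g, a) < alpha || ks_p(g, b) < alpha, logical(1))
  # direction from the training case samples' mean deviation from reference
  dir_up <- rowMeans(sub[, c(a, b), drop = FALSE]) - ref_mean > 0
  score <- score_fn(sub, ref_mean, ref_sd)
  score[!sig, ] <- 0
  values <- matrix(0, nrow = ncol(sub), ncol = 2L * length(sets),
                   dimnames = list(colnames(sub),
                                   paste0(rep(names(sets), each = 2L),
                                          c("_over", "_under"))))
  for (pw in names(sets)) {
    g <- sets[[pw]]
    up <- g[sig[g] & dir_up[g]]
    dn <- g[sig[g] & !dir_up[g]]
    values[, paste0(pw, "_over")] <- colSums(score[up, , drop = FALSE])
    values[, paste0(pw, "_under")] <- colSums(score[dn, , drop = FALSE])
  }
  feature_matrix(values, method = "ged", alpha = alpha)
}
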