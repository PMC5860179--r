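# residual-variance floor: a perfect linear fit would otherwise give an
# unusable zero-variance Gaussian
VARIANCE_FLOOR <- 1e-8
# ridge strength for underdetermined / rank-deficient node regressions
RIDGE_LAMBDA <- 1e-6

#' Fit one node of a linear-Gaussian Bayesian network
#'
#' Each node (gene) is normal with mean linear in its parents' expression:
#' `x ~ N(beta0 + sum(beta_i * parent_i), sigma2)`. `beta` is the
#' ordinary-least-squares solution (which is the maximum-likelihood estimate
#' under the Gaussian model) and `sigma2` the maximum-likelihood residual
#' variance, i.e. the residual sum of squares divided by the sample count
#' `n` — not `n - p - 1`. Parentless nodes reduce to the sample mean and the
#' MLE variance.
#'
#' When the regression is underdetermined (fewer samples than parents + 1) or
#' rank-deficient, a ridge penalty `lambda = 1e-6` on the parent coefficients
#' (never the intercept) keeps the fit defined; the returned object flags
#' this. A residual variance below the floor `1e-8` is raised to the floor
#' with a warning.
#'
#' @param node Gene id of the node to fit.
#' @param parents Character vector of parent gene ids (possibly empty).
#' @param reference Expression matrix (genes x samples) of reference samples.
#' @return A list of class `node_params`: `node`, `parents`, `beta0`,
#'   `betas` (aligned with `parents`), `sigma2`, `ridged` (logical).
#' @export
fit_node <- function(node, parents, reference) {
  if (!node %in% rownames(reference)) stop("node gene not measured: ", node)
  miss <- setdiff(parents, rownames(reference))
  if (length(miss) > 0L) stop("parent gene(s) not measured: ", paste(miss, collapse = ", "))
  n <- ncol(reference)
  if (n < 2L) stop("need at least 2 reference samples to fit a node")
  y <- reference[node, ]
  p <- length(parents)
  ridged <- FALSE
  if (p == 0L) {
    beta0 <- mean(y)
    betas <- numeric(0)
    rss <- sum((y - beta0)^2)
  } else {
    Z <- cbind(1, t(reference[parents, , drop = FALSE]))
    qrz <- qr(Z)
    if (n >= p + 1L && qrz$rank == p + 1L) {
      beta <- qr.coef(qrz, y)
    } else {
      ridged <- TRUE
      D <- diag(c(0, rep(RIDGE_LAMBDA, p)), p + 1L)
      beta <- solve(crossprod(Z) + D, crossprod(Z, y))[, 1L]
    }
    beta0 <- unname(beta[1L])
    betas <- unname(beta[-1L])
    rss <- sum((y - Z %*% beta)^2)
  }
  sigma2 <- rss / n
  if (sigma2 < VARIANCE_FLOOR) {
    warning(sprintf("node '%s': residual variance %.3g below floor; using %g",
                    node, sigma2, VARIANCE_FLOOR))
    sigma2 <- VARIANCE_FLOOR
  }
  structure(list(node = node, parents = as.character(parents),
                 beta0 = beta0, betas = betas, sigma2 = sigma2,
                 ridged = ridged),
            class = "node_params")
}

#' Gaussian log-density of one node given its parents
#'
#' Natural-log density of the node's observed value under its fitted
#' conditional Gaussian, `log N(x; beta0 + sum(betas * parent_values),
#' sigma2)`.
#'
#' @param params A `node_params` object from [fit_node()].
#' @param x Observed expression of the node.
#' @param parent_values Observed expression of the parents, aligned with
#'   `params$parents`.
#' @return The log-density (natural log), a single finite number.
#' @export
node_loglik <- function(params, x, parent_values = numeric(0)) {
  if (length(parent_values) != length(params$parents))
    stop("parent_values must align with params$parents")
  if (!all(is.finite(c(x, parent_values)))) stop("non-finite inputs")
  mu <- params$beta0 + sum(params$betas * parent_values)
  stats::dnorm(x, mean = mu, sd = sqrt(params$sigma2), log = TRUE)
}

#' Fit a linear-Gaussian Bayesian network on a pathway DAG
#'
#' Fits every node's conditional Gaussian by maximum likelihood on the
#' reference samples (the healthy/non-lesional pool in the disease
#' application).
#'
#' @param dag A `pathway_dag` from [dagify()].
#' @param reference Expression matrix (genes x samples) of reference samples;
#'   must contain every DAG node.
#' @return A list of class `pathway_gbn`: `dag`, `node_params` (named list,
#'   one per node), `n_reference`.
#' @export
fit_pathway_gbn <- function(dag, reference) {
  validate_expression_matrix(reference)
  if (ncol(reference) < 2L) stop("need at least 2 reference samples")
  miss <- setdiff(dag$nodes, rownames(reference))
  if (length(miss) > 0L)
    stop("DAG node(s) not in reference matrix: ", paste(miss, collapse = ", "))
  parents <- dag_parents(dag)
  node_params <- lapply(dag$nodes, function(v) fit_node(v, parents[[v]], reference))
  names(node_params) <- dag$nodes
  structure(list(dag = dag, node_params = node_params,
                 n_reference = ncol(reference)),
            class = "pathway_gbn")
}

#' Pathway log-likelihood of one sample
#'
#' The pathway score of a sample is the joint log-likelihood of its
#' expression under the reference-fitted network: the sum over nodes of each
#' node's conditional Gaussian log-density given its parents' observed
#' values. No normalization by node count is applied, so pathways of
#' different sizes live on different scales (downstream random forests are
#' scale-tolerant).
#'
#' @param gbn A `pathway_gbn` from [fit_pathway_gbn()].
#' @param sample Named numeric vector of expression containing every pathway
#'   gene.
#' @return The pathway log-likelihood (natural log).
#' @export
pathway_loglik <- function(gbn, sample) {
  miss <- setdiff(gbn$dag$nodes, names(sample))
  if (length(miss) > 0L)
    stop("sample missing gene value(s): ", paste(miss, collapse = ", "))
  sum(vapply(gbn$node_params, function(np) {
    node_loglik(np, sample[[np$node]],
                unlist(sample[np$parents], use.names = FALSE))
  }, numeric(1)))
}

# vectorized pathway log-likelihood over the columns of an expression matrix
.pathway_loglik_all <- function(gbn, mat) {
  ll <- numeric(ncol(mat))
  for (np in gbn$node_params) {
    mu <- rep(np$beta0, ncol(mat))
    if (length(np$parents) > 0L)
      mu <- mu + drop(np$betas %*% mat[np$parents, , drop = FALSE])
    ll <- ll + stats::dnorm(mat[np$node, ], mean = mu,
                            sd = sqrt(np$sigma2), log = TRUE)
  }
  stats::setNames(ll, colnames(mat))
}

#' Fit probabilistic pathway score models
#'
#' The model-fitting entry point. Each pathway graph is restricted to the
#' genes measured in `reference`, pathways left with no edge are excluded,
#' the survivors are converted to DAGs by seed-determined random edge
#' insertion ([dagify()]), and a linear-Gaussian Bayesian network is fitted
#' per pathway by maximum likelihood on the reference samples. Scoring new
#' samples ([predict.props_model()]) yields one log-likelihood feature per
#' pathway per sample.
#'
#' @param pathways A list of [pathway_graph()] objects (or a single one).
#' @param reference Expression matrix (genes x samples) of reference samples
#'   (at least 2).
#' @param seed Integer seed shared by all pathways' DAG randomization.
#' @return An object of class `props_model` with components `fits` (named
#'   list of `pathway_gbn`), `genes` (the measured gene space), `seed`,
#'   `n_reference`, and `train_scores` (reference samples x pathways
#'   log-likelihood matrix).
#' @export
props <- function(pathways, reference, seed = 0L) {
  if (inherits(pathways, "pathway_graph")) pathways <- list(pathways)
  validate_expression_matrix(reference)
  if (ncol(reference) < 2L) stop("need at least 2 reference samples")
  measured <- rownames(reference)
  restricted <- lapply(pathways, restrict_to_measured, measured = measured)
  scorable <- filter_scorable(restricted)
  if (length(scorable) == 0L)
    stop("no scorable pathways: every pathway lost all its edges after restriction")
  dags <- lapply(scorable, dagify, seed = seed)
  fits <- lapply(dags, fit_pathway_gbn, reference = reference)
  names(fits) <- vapply(dags, function(d) d$name, character(1))
  model <- structure(list(fits = fits, genes = measured,
                          seed = as.integer(seed),
                          n_reference = ncol(reference)),
                     class = "props_model")
  model$train_scores <- predict(model, reference)
  model
}

#' Score samples with a fitted pathway model
#'
#' @param object A `props_model` from [props()].
#' @param newdata Expression matrix (genes x samples) sharing the model's
#'   gene space.
#' @param ... Unused.
#' @return A `feature_matrix` (samples x pathways) of log-likelihood scores.
#' @export
predict.props_model <- function(object, newdata, ...) {
  validate_expression_matrix(newdata)
  miss <- setdiff(unique(unlist(lapply(object$fits, function(f) f$dag$nodes))),
                  rownames(newdata))
  if (length(miss) > 0L)
    stop("newdata missing pathway gene(s): ", paste(miss[seq_len(min(5, length(miss)))], collapse = ", "))
  values <- vapply(object$fits, .pathway_loglik_all, numeric(ncol(newdata)),
                   mat = newdata)
  if (ncol(newdata) == 1L)
    values <- matrix(values, nrow = 1L, dimnames = list(colnames(newdata), names(object$fits)))
  feature_matrix(values, method = "props", seed = object$seed,
                 dropped_edges = vapply(object$fits, function(f)
                   nrow(f$dag$dropped_edges), integer(1)))
}

#' Convenience wrapper: pathway features for case samples
#'
#' Fits [props()] on the reference samples and scores the case samples,
#' matching the end-to-end feature-engineering step.
#'
#' @param pathways List of [pathway_graph()] objects.
#' @param reference Reference expression matrix (genes x samples).
#' @param cases Case expression matrix sharing the gene space.
#' @return A `feature_matrix` (cases x pathways).
#' @param seed Integer seed for DAG randomization.
#' @export
props_features <- function(pathways, reference, cases, seed = 0L) {
  predict(props(pathways, reference, seed = seed), cases)
}

#' @export
print.props_model <- function(x, ...) {
  cat(sprintf("Probabilistic pathway score model: %d pathway(s), fitted on %d reference samples (seed %d)\n",
              length(x$fits), x$n_reference, x$seed))
  invisible(x)
}

#' @export
summary.props_model <- function(object, ...) {
  tab <- data.frame(
    pathway = names(object$fits),
    nodes = vapply(object$fits, function(f) length(f$dag$nodes), integer(1)),
    edges_kept = vapply(object$fits, function(f) nrow(f$dag$kept_edges), integer(1)),
    edges_dropped = vapply(object$fits, function(f) nrow(f$dag$dropped_edges), integer(1)),
    ridged_nodes = vapply(object$fits, function(f)
      sum(vapply(f$node_params, function(np) np$ridged, logical(1))), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  tab$prop_edges_kept <- ifelse(tab$edges_kept + tab$edges_dropped > 0,
                                tab$edges_kept / (tab$edges_kept + tab$edges_dropped), NA)
  structure(list(table = tab, n_reference = object$n_reference,
                 seed = object$seed), class = "summary.props_model")
}

#' @export
print.summary.props_model <- function(x, ...) {
  cat(sprintf("Pathway model summary (%d reference samples, seed %d)\n",
              x$n_reference, x$seed))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.props_model <- function(object, ...) {
  rows <- lapply(names(object$fits), function(pw) {
    do.call(rbind, lapply(object$fits[[pw]]$node_params, function(np) {
      data.frame(pathway = pw, node = np$node,
                 term = c("(Intercept)", np$parents),
                 estimate = c(np$beta0, np$betas),
                 sigma2 = np$sigma2, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate expression from a fitted pathway model
#'
#' Ancestral sampling from every fitted pathway network: nodes are visited in
#' topological order and drawn from their conditional Gaussians. A gene that
#' belongs to several pathways is drawn from the first pathway containing it.
#'
#' @param object A `props_model`.
#' @param nsim Number of samples to draw.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return An expression matrix (genes x nsim) over the model's pathway
#'   genes.
#' @export
simulate.props_model <- function(object, nsim = 1, seed = 0L, ...) {
  mats <- list()
  for (i in seq_along(object$fits)) {
    mats[[i]] <- sample_from_gbn(object$fits[[i]], n = nsim,
                                 seed = seed + i - 1L)
  }
  genes_seen <- character(0)
  rows <- list()
  for (m in mats) {
    new <- setdiff(rownames(m), genes_seen)
    rows[[length(rows) + 1L]] <- m[new, , drop = FALSE]
    genes_seen <- c(genes_seen, new)
  }
  out <- do.call(rbind, rows)
  colnames(out) <- sprintf("sim%d", seq_len(nsim))
  out
}

#' Construct a feature matrix
#'
#' Samples x features real-valued matrix with provenance metadata (`method`
#' tag plus any extra attributes such as the DAG seed).
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param method Provenance tag: one of props, llr, corg, ntc, ged, genes.
#' @param ... Further metadata stored as attributes.
#' @return The matrix with class `feature_matrix`.
#' @export
feature_matrix <- function(values, method, ...) {
  if (!is.matrix(values) || !is.numeric(values)) stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("feature matrix needs sample row names and feature column names")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("duplicate sample or feature ids")
  if (any(!is.finite(values))) stop("non-finite feature values")
  meta <- list(...)
  attr(values, "method") <- method
  for (nm in names(meta)) attr(values, nm) <- meta[[nm]]
  class(values) <- c("feature_matrix", class(values))
  values
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix [%s]: %d samples x %d features\n",
              attr(x, "method"), nrow(x), ncol(x)))
  invisible(x)
}
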