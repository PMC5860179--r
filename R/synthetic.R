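#' Random pathway DAG
#'
#' Draws a directed acyclic graph by sampling a random node order and
#' including each forward (lower-triangular) edge independently with
#' probability `edge_prob` — acyclic by construction.
#'
#' @param n_nodes Number of nodes (>= 1).
#' @param edge_prob Edge inclusion probability in (0,1); 1 is allowed and
#'   yields the complete DAG.
#' @param seed Integer seed.
#' @param name Pathway name.
#' @param genes Optional character vector of `n_nodes` gene ids.
#' @return A `pathway_dag` (all edges kept, none dropped).
#' @export
random_dag <- function(n_nodes, edge_prob, seed = 0L, name = "synthetic",
                       genes = NULL) {
  if (n_nodes < 1L) stop("n_nodes must be at least 1")
  if (!is.numeric(edge_prob) || edge_prob <= 0 || edge_prob > 1)
    stop("edge_prob must lie in (0, 1]")
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(n_nodes))
  if (length(genes) != n_nodes) stop("genes must have length n_nodes")
  edges <- with_local_seed(seed, {
    ord <- sample(genes)
    src <- character(0); tgt <- character(0)
    if (n_nodes > 1L) {
      for (j in 2:n_nodes) {
        take <- stats::runif(j - 1L) < edge_prob
        src <- c(src, ord[seq_len(j - 1L)][take])
        tgt <- c(tgt, rep(ord[j], sum(take)))
      }
    }
    cbind(src, tgt)
  })
  g <- pathway_graph(name, genes, edges)
  dag <- dagify_order(g, seq_len(nrow(unique(g$edges))))
  dag$seed <- as.integer(seed)
  stopifnot(nrow(dag$dropped_edges) == 0L)
  dag
}

#' Random linear-Gaussian network parameters on a DAG
#'
#' Draws plausible log-scale expression parameters: intercepts uniform on
#' `intercept_range` (log2 microarray intensities are typically 6-10), parent
#' coefficients with magnitude uniform on `beta_range` and random sign, and
#' residual variances uniform on `sigma2_range`.
#'
#' @param dag A `pathway_dag`.
#' @param seed Integer seed.
#' @param intercept_range,beta_range,sigma2_range Length-2 numeric ranges.
#' @return A `pathway_gbn` (with `n_reference = NA`).
#' @export
random_gbn <- function(dag, seed = 0L, intercept_range = c(6, 10),
                       beta_range = c(0.3, 0.9), sigma2_range = c(0.25, 1)) {
  parents <- dag_parents(dag)
  node_params <- with_local_seed(seed, {
    lapply(dag$nodes, function(v) {
      p <- length(parents[[v]])
      structure(list(node = v, parents = parents[[v]],
                     beta0 = stats::runif(1, intercept_range[1], intercept_range[2]),
                     betas = sample(c(-1, 1), p, replace = TRUE) *
                       stats::runif(p, beta_range[1], beta_range[2]),
                     sigma2 = stats::runif(1, sigma2_range[1], sigma2_range[2]),
                     ridged = FALSE),
                class = "node_params")
    })
  })
  names(node_params) <- dag$nodes
  structure(list(dag = dag, node_params = node_params,
                 n_reference = NA_integer_),
            class = "pathway_gbn")
}

#' Simulate expression from a pathway network
#'
#' Ancestral sampling: nodes are visited in topological order and each is
#' drawn from its conditional Gaussian given its parents' sampled values.
#'
#' @param gbn A `pathway_gbn`.
#' @param n Number of samples (>= 1).
#' @param seed Integer seed.
#' @param sample_ids Optional character vector of `n` sample ids.
#' @return An expression matrix (pathway genes x n samples).
#' @export
sample_from_gbn <- function(gbn, n, seed = 0L, sample_ids = NULL) {
  if (n < 1L) stop("n must be at least 1")
  ord <- topological_order(gbn$dag)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_len(n))
  out <- matrix(NA_real_, nrow = length(gbn$dag$nodes), ncol = n,
                dimnames = list(gbn$dag$nodes, sample_ids))
  with_local_seed(seed, {
    for (v in ord) {
      np <- gbn$node_params[[v]]
      mu <- rep(np$beta0, n)
      if (length(np$parents) > 0L)
        mu <- mu + drop(np$betas %*% out[np$parents, , drop = FALSE])
      out[v, ] <- stats::rnorm(n, mean = mu, sd = sqrt(np$sigma2))
    }
  })
  out
}

#' Specify a ground-truth pathway perturbation
#'
#' Perturbations act on the generative model, not post hoc on the data, so a
#' perturbed pathway is by construction less likely under the reference
#' model. `coefficient_rescale` multiplies every parent coefficient of the
#' pathway by `magnitude`; `mean_shift` adds `magnitude * sqrt(sigma2)` to
#' every node's intercept (a shift expressed in residual standard
#' deviations).
#'
#' @param pathway Pathway name.
#' @param mode `"coefficient_rescale"` or `"mean_shift"`.
#' @param magnitude Finite real.
#' @param target_class `"classA"` or `"classB"`.
#' @return A list of class `perturbation_spec`.
#' @export
perturbation_spec <- function(pathway, mode = c("mean_shift", "coefficient_rescale"),
                              magnitude, target_class = c("classA", "classB")) {
  mode <- match.arg(mode)
  target_class <- match.arg(target_class)
  if (!is.numeric(magnitude) || !is.finite(magnitude))
    stop("magnitude must be finite")
  structure(list(pathway = pathway, mode = mode, magnitude = magnitude,
                 target_class = target_class),
            class = "perturbation_spec")
}

# apply a perturbation to a fitted/synthetic network
.perturb_gbn <- function(gbn, spec) {
  for (v in names(gbn$node_params)) {
    np <- gbn$node_params[[v]]
    if (spec$mode == "coefficient_rescale") {
      np$betas <- np$betas * spec$magnitude
    } else {
      np$beta0 <- np$beta0 + spec$magnitude * sqrt(np$sigma2)
    }
    gbn$node_params[[v]] <- np
  }
  gbn
}

#' Generate a synthetic classification scenario
#'
#' Emulates the multi-study reference/case layout of a two-disease
#' transcriptomic comparison: reference samples are drawn from unperturbed
#' per-pathway linear-Gaussian networks over disjoint gene sets; each case
#' class is drawn from the same networks except that pathways named in
#' `perturbations` are perturbed for their target class. Optional per-study
#' additive offsets emulate batch structure (recorded in the annotation,
#' never corrected). Defaults mirror the study's scale loosely: 20 pathways
#' of 15 genes, 80 reference samples, 25 + 60 case samples.
#'
#' @param n_pathways,nodes_per_pathway Pathway count and size.
#' @param n_reference Number of reference samples.
#' @param n_class_a,n_class_b Case sample counts per class.
#' @param perturbations List of [perturbation_spec()] objects (may be empty
#'   for a null scenario).
#' @param batch_offsets Optional named numeric vector of per-study additive
#'   offsets; samples are assigned to studies round-robin.
#' @param edge_prob Edge probability of the random DAGs.
#' @param seed Integer seed; the scenario is bit-reproducible given it.
#' @return A list: `pathways` (list of [pathway_graph()]), `reference` and
#'   `cases` (expression matrices), `labels` ([sample_annotation()] covering
#'   all samples), `truth` (the perturbation list), `gbns` (the generating
#'   networks), `seed`.
#' @export
make_scenario <- function(n_pathways = 20L, nodes_per_pathway = 15L,
                          n_reference = 80L, n_class_a = 25L, n_class_b = 60L,
                          perturbations = list(), batch_offsets = NULL,
                          edge_prob = 0.25, seed = 0L) {
  if (inherits(perturbations, "perturbation_spec"))
    perturbations <- list(perturbations)
  pw_names <- sprintf("PW%02d", seq_len(n_pathways))
  bad <- setdiff(vapply(perturbations, function(p) p$pathway, character(1)),
                 pw_names)
  if (length(bad) > 0L)
    stop("perturbation targets unknown pathway(s): ", paste(bad, collapse = ", "))
  dags <- lapply(seq_len(n_pathways), function(i)
    random_dag(nodes_per_pathway, edge_prob, seed = seed + i,
               name = pw_names[i],
               genes = sprintf("%sG%02d", pw_names[i], seq_len(nodes_per_pathway))))
  gbns <- lapply(seq_len(n_pathways), function(i)
    random_gbn(dags[[i]], seed = seed + 1000L + i))
  names(gbns) <- pw_names

  draw <- function(gbn_list, n, ids, seed0) {
    do.call(rbind, lapply(seq_along(gbn_list), function(i)
      sample_from_gbn(gbn_list[[i]], n, seed = seed0 + i, sample_ids = ids)))
  }
  perturbed_for <- function(cls) {
    out <- gbns
    for (p in perturbations) {
      if (p$target_class == cls) out[[p$pathway]] <- .perturb_gbn(out[[p$pathway]], p)
    }
    out
  }
  ref_ids <- sprintf("REF%03d", seq_len(n_reference))
  a_ids <- sprintf("A%03d", seq_len(n_class_a))
  b_ids <- sprintf("B%03d", seq_len(n_class_b))
  reference <- draw(gbns, n_reference, ref_ids, seed + 2000L)
  cases <- cbind(draw(perturbed_for("classA"), n_class_a, a_ids, seed + 3000L),
                 draw(perturbed_for("classB"), n_class_b, b_ids, seed + 4000L))
  labels <- sample_annotation(
    c(ref_ids, a_ids, b_ids),
    c(rep("reference", n_reference), rep("classA", n_class_a),
      rep("classB", n_class_b)))
  if (!is.null(batch_offsets)) {
    if (is.null(names(batch_offsets))) stop("batch_offsets must be named by study")
    all_ids <- labels$sample_id
    batch <- rep(names(batch_offsets), length.out = length(all_ids))
    labels$batch <- batch
    for (j in seq_along(all_ids)) {
      off <- batch_offsets[[batch[j]]]
      if (all_ids[j] %in% colnames(reference)) {
        reference[, all_ids[j]] <- reference[, all_ids[j]] + off
      } else {
        cases[, all_ids[j]] <- cases[, all_ids[j]] + off
      }
    }
  }
  pathways <- lapply(dags, function(d)
    pathway_graph(d$name, d$nodes, d$kept_edges))
  validate_expression_matrix(reference)
  validate_expression_matrix(cases)
  list(pathways = pathways, reference = reference, cases = cases,
       labels = labels, truth = perturbations, gbns = gbns,
       seed = as.integer(seed))
}

#' Write a scenario to the package's TSV dialects
#'
#' Emits `expression.tsv` (reference and case samples combined),
#' `annotation.tsv` and `pathways.tsv` (edge list) so synthetic data can
#' exercise the full file-based pipeline.
#'
#' @param scenario Output of [make_scenario()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  expr <- cbind(scenario$reference, scenario$cases)
  write_expression_tsv(expr, file.path(dir, "expression.tsv"))
  utils::write.table(
    data.frame(sample_id = scenario$labels$sample_id,
               phenotype = as.character(scenario$labels$phenotype),
               batch = scenario$labels$batch),
    file.path(dir, "annotation.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_edge_list_tsv(scenario$pathways, file.path(dir, "pathways.tsv"))
  invisible(dir)
}

#' Write an expression matrix as TSV
#' @param matrix Genes x samples numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(matrix, path) {
  validate_expression_matrix(matrix)
  tab <- data.frame(gene_id = rownames(matrix), matrix,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
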