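#' Read a gene expression matrix from TSV
#'
#' Reads a tab-separated expression table with a header row of sample
#' identifiers and gene (or probe) identifiers in the first column (header
#' `gene_id`). Values are continuous, log-scale intensities as produced by
#' upstream normalization (e.g. RMA); this package validates but never
#' transforms intensities.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix, genes in rows and samples in columns, with
#'   unique row and column names and all values finite.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L) stop("empty expression matrix in ", path)
  gene_ids <- tab[[1L]]
  sample_ids <- colnames(tab)[-1L]
  values <- suppressWarnings(
    vapply(tab[-1L], as.numeric, numeric(nrow(tab)))
  )
  values <- matrix(values, nrow = nrow(tab),
                   dimnames = list(gene_ids, sample_ids))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric or non-finite expression value at gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  }
  validate_expression_matrix(values)
}

#' Validate an expression matrix
#'
#' Checks the invariants every expression matrix in this package must hold:
#' a numeric matrix with unique, non-empty gene row names and sample column
#' names, and all values finite.
#'
#' @param x A numeric matrix (genes x samples).
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs gene row names and sample column names")
  dup_g <- rownames(x)[duplicated(rownames(x))]
  if (length(dup_g) > 0L)
    stop("duplicate gene id(s): ", paste(unique(dup_g), collapse = ", "))
  dup_s <- colnames(x)[duplicated(colnames(x))]
  if (length(dup_s) > 0L)
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
  }
  invisible(x)
}

#' Read sample annotations from TSV
#'
#' The annotation table assigns each sample a phenotype: `reference`
#' (healthy/non-lesional samples used to parameterize baseline pathway
#' models), `classA`, or `classB` (the two case classes to discriminate,
#' e.g. Crohn's disease vs ulcerative colitis). An optional `batch` column
#' records the study of origin; batches are recorded, never corrected here.
#'
#' @param path Path to a TSV with columns `sample_id`, `phenotype`
#'   (`reference|classA|classB`) and optionally `batch`.
#' @return A data frame with columns `sample_id`, `phenotype` (factor with
#'   levels reference, classA, classB) and `batch` (character or NA).
#' @export
read_annotation_tsv <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("sample_id", "phenotype") %in% colnames(tab)))
    stop("annotation TSV must have columns sample_id and phenotype")
  sample_annotation(tab$sample_id, tab$phenotype,
                    if ("batch" %in% colnames(tab)) tab$batch else NULL)
}

#' Construct a sample annotation table
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param phenotype Character vector, each one of `reference`, `classA`,
#'   `classB`.
#' @param batch Optional character vector of batch/study labels.
#' @return A data frame of class `sample_annotation`.
#' @export
sample_annotation <- function(sample_id, phenotype, batch = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample id(s) in annotation: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  levs <- c("reference", "classA", "classB")
  phenotype <- as.character(phenotype)
  bad <- setdiff(unique(phenotype), levs)
  if (length(bad) > 0L)
    stop("unknown phenotype label(s): ", paste(bad, collapse = ", "),
         " (expected reference|classA|classB)")
  ann <- data.frame(sample_id = sample_id,
                    phenotype = factor(phenotype, levels = levs),
                    batch = if (is.null(batch)) NA_character_ else as.character(batch),
                    stringsAsFactors = FALSE)
  class(ann) <- c("sample_annotation", "data.frame")
  ann
}

#' Samples annotated with a given phenotype
#' @param annotation A `sample_annotation` data frame.
#' @param phenotype One of `"reference"`, `"classA"`, `"classB"`.
#' @return Character vector of sample ids.
#' @export
samples_of <- function(annotation, phenotype) {
  annotation$sample_id[annotation$phenotype == phenotype]
}

#' Read a probe-to-gene map from TSV
#'
#' One row per probe-gene pair (columns `probe_id`, `gene_id`); probes
#' mapping to several genes appear on several rows.
#'
#' @param path Path to the TSV.
#' @return A data frame with character columns `probe_id` and `gene_id`.
#' @export
read_probe_map_tsv <- function(path) {
  if (!file.exists(path)) stop("probe map file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("probe_id", "gene_id") %in% colnames(tab)))
    stop("probe map TSV must have columns probe_id and gene_id")
  tab <- unique(tab[, c("probe_id", "gene_id")])
  if (nrow(tab) == 0L) stop("empty probe map")
  tab
}

#' Collapse probe-level values to gene level
#'
#' Each gene's value per sample is the arithmetic mean of all probe values
#' mapped to it: genes measured by multiple probes are averaged, and a probe
#' mapped to multiple genes contributes its value to every one of them.
#' Probes absent from the map are dropped (their count is reported via a
#' message and the `n_dropped_probes` attribute), never imputed.
#'
#' @param probe_matrix Numeric matrix, probes x samples.
#' @param probe_map Data frame with columns `probe_id`, `gene_id`.
#' @return Numeric gene x sample matrix with attribute `n_dropped_probes`.
#' @export
collapse_probes_to_genes <- function(probe_matrix, probe_map) {
  validate_expression_matrix(probe_matrix)
  if (nrow(probe_map) == 0L) stop("empty probe map")
  keep <- probe_map$probe_id %in% rownames(probe_matrix)
  if (!any(keep)) stop("probe map references no probe present in the matrix")
  map <- probe_map[keep, , drop = FALSE]
  dropped <- setdiff(rownames(probe_matrix), unique(map$probe_id))
  if (length(dropped) > 0L)
    message(length(dropped), " probe(s) without gene mapping dropped")
  genes <- sort(unique(map$gene_id))
  # group-mean via one pass of rowsum over the (probe, gene) pair expansion
  expanded <- probe_matrix[map$probe_id, , drop = FALSE]
  sums <- rowsum(expanded, group = map$gene_id, reorder = TRUE)
  counts <- as.vector(table(map$gene_id)[rownames(sums)])
  out <- sums / counts
  out <- out[genes, , drop = FALSE]
  attr(out, "n_dropped_probes") <- length(dropped)
  validate_expression_matrix(out)
  out
}

#' Restrict matrices to their common gene space
#'
#' Only genes measured in every study can contribute to cross-study models;
#' this restricts each matrix to the (sorted) intersection of all gene sets.
#'
#' @param matrices A list of gene x sample numeric matrices.
#' @return A list of matrices sharing one identical, sorted gene set.
#' @export
intersect_gene_space <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0L)
    stop("need at least one expression matrix")
  for (m in matrices) validate_expression_matrix(m)
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (length(common) == 0L) stop("gene sets have empty intersection")
  common <- sort(common)
  lapply(matrices, function(m) m[common, , drop = FALSE])
}
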