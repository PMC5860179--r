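#' Write a feature matrix with its JSON sidecar
#'
#' TSV with samples in rows (first column `sample_id`, then one column per
#' feature), plus a sidecar JSON recording provenance metadata (method tag,
#' DAG seed, per-pathway dropped-edge counts, ...).
#'
#' @param features A `feature_matrix`.
#' @param path Output TSV path.
#' @param sidecar Sidecar JSON path (default `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path,
                                 sidecar = paste0(path, ".json")) {
  tab <- data.frame(sample_id = rownames(features),
                    unclass(features),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  keep <- setdiff(names(attributes(features)),
                  c("dim", "dimnames", "class"))
  meta <- attributes(features)[keep]
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path Feature TSV path.
#' @param sidecar Sidecar JSON path (default `<path>.json`; optional).
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path, sidecar = paste0(path, ".json")) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- tab[[1L]]
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
          else list(method = "genes")
  do.call(feature_matrix,
          c(list(values = values), meta[unique(c("method", names(meta)))]))
}

#' Serialize fitted pathway networks to JSON
#'
#' Audit/re-scoring format: per pathway, the node set, kept and dropped
#' edges, the DAG seed, and per node its parents, intercept, coefficients and
#' residual variance.
#'
#' @param model A `props_model` from [props()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_gbn_json <- function(model, path) {
  as_edge_df <- function(e) if (nrow(e) == 0L) list() else
    lapply(seq_len(nrow(e)), function(i) list(source = e[i, 1L], target = e[i, 2L]))
  payload <- list(
    seed = model$seed,
    n_reference = model$n_reference,
    pathways = lapply(model$fits, function(f) list(
      name = f$dag$name,
      nodes = f$dag$nodes,
      kept_edges = as_edge_df(f$dag$kept_edges),
      dropped_edges = as_edge_df(f$dag$dropped_edges),
      dag_seed = f$dag$seed,
      nodes_params = lapply(f$node_params, function(np) list(
        parents = as.list(np$parents), beta0 = np$beta0,
        betas = as.list(np$betas), sigma2 = np$sigma2, ridged = np$ridged))
    )))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load fitted pathway networks from JSON
#'
#' Inverse of [write_gbn_json()]; the returned model can score new samples
#' with [predict.props_model()] (training scores are not restored).
#'
#' @param path JSON path.
#' @return A `props_model`.
#' @export
read_gbn_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  fits <- lapply(payload$pathways, function(pw) {
    edge_mat <- function(lst) {
      if (length(lst) == 0L) return(matrix(character(0), ncol = 2L,
                                           dimnames = list(NULL, c("source", "target"))))
      m <- cbind(vapply(lst, function(e) e$source, character(1)),
                 vapply(lst, function(e) e$target, character(1)))
      colnames(m) <- c("source", "target")
      m
    }
    nodes <- unlist(pw$nodes)
    dag <- structure(list(name = pw$name, nodes = nodes,
                          kept_edges = edge_mat(pw$kept_edges),
                          dropped_edges = edge_mat(pw$dropped_edges),
                          seed = pw$dag_seed,
                          insertion_order = NA_integer_),
                     class = "pathway_dag")
    node_params <- lapply(pw$nodes_params, function(np)
      structure(list(node = NA_character_,
                     parents = as.character(unlist(np$parents)),
                     beta0 = np$beta0,
                     betas = as.numeric(unlist(np$betas)),
                     sigma2 = np$sigma2, ridged = isTRUE(np$ridged)),
                class = "node_params"))
    names(node_params) <- nodes
    for (v in nodes) node_params[[v]]$node <- v
    structure(list(dag = dag, node_params = node_params,
                   n_reference = payload$n_reference),
              class = "pathway_gbn")
  })
  names(fits) <- vapply(payload$pathways, function(pw) pw$name, character(1))
  structure(list(fits = fits,
                 genes = unique(unlist(lapply(fits, function(f) f$dag$nodes))),
                 seed = payload$seed,
                 n_reference = payload$n_reference),
            class = "props_model")
}
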