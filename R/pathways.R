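#' Construct a directed pathway graph
#'
#' A pathway is a named directed graph over gene identifiers. The edge list
#' may contain cycles, self-loops and parallel duplicates exactly as drawn
#' from the source database; acyclicity is only enforced later by
#' [dagify()].
#'
#' @param name Non-empty pathway name.
#' @param nodes Character vector of gene identifiers (deduplicated).
#' @param edges Two-column character matrix (source, target); may be empty.
#' @return An object of class `pathway_graph`.
#' @export
pathway_graph <- function(name, nodes, edges = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("pathway name must be a non-empty string")
  nodes <- unique(as.character(nodes))
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  } else {
    edges <- matrix(as.character(edges), ncol = 2L)
  }
  colnames(edges) <- c("source", "target")
  missing <- setdiff(unique(as.vector(edges)), nodes)
  if (length(missing) > 0L)
    stop("edge endpoint(s) not in node set: ", paste(missing, collapse = ", "))
  structure(list(name = name, nodes = nodes, edges = edges),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("Pathway graph '%s': %d nodes, %d edges\n",
              x$name, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# gene ids listed by a KGML entry node ("hsa:1234 hsa:5678" -> both tokens)
.kgml_entry_genes <- function(entry) {
  strsplit(trimws(xml2::xml_attr(entry, "name")), "\\s+")[[1L]]
}

#' Parse a KEGG KGML pathway file into a directed graph
#'
#' Gene-type entries become nodes (entries naming several genes expand to
#' several nodes); each relation between gene entries becomes directed edges
#' over all implied gene-id pairs; group entries expand to their component
#' members with relations duplicated to each member. Relations whose subtype
#' is an undirected interaction (binding/association) are emitted in both
#' directions; the randomized DAG construction later decides which direction
#' survives when a cycle would arise.
#'
#' @param path Path to a KGML XML file.
#' @return A [pathway_graph()].
#' @export
parse_kgml <- function(path) {
  if (!file.exists(path)) stop("KGML file not found: ", path)
  doc <- xml2::read_xml(path)
  name <- xml2::xml_attr(doc, "title")
  if (is.na(name) || !nzchar(name)) name <- xml2::xml_attr(doc, "name")
  if (is.na(name) || !nzchar(name)) name <- basename(path)

  entries <- xml2::xml_find_all(doc, ".//entry")
  entry_id <- xml2::xml_attr(entries, "id")
  entry_type <- xml2::xml_attr(entries, "type")

  genes_by_entry <- stats::setNames(vector("list", length(entries)), entry_id)
  for (i in seq_along(entries)) {
    if (identical(entry_type[i], "gene")) {
      genes_by_entry[[i]] <- .kgml_entry_genes(entries[[i]])
    }
  }
  # group entries expand to the genes of their component entries
  for (i in seq_along(entries)) {
    if (identical(entry_type[i], "group")) {
      comp <- xml2::xml_attr(xml2::xml_find_all(entries[[i]], ".//component"), "id")
      genes_by_entry[[i]] <- unique(unlist(genes_by_entry[comp]))
    }
  }
  nodes <- unique(unlist(genes_by_entry))
  if (length(nodes) == 0L) stop("no gene nodes in KGML file ", path)

  undirected_subtypes <- c("binding/association")
  rels <- xml2::xml_find_all(doc, ".//relation")
  src <- character(0); tgt <- character(0)
  for (rel in rels) {
    g1 <- genes_by_entry[[xml2::xml_attr(rel, "entry1")]]
    g2 <- genes_by_entry[[xml2::xml_attr(rel, "entry2")]]
    if (length(g1) == 0L || length(g2) == 0L) next
    pairs <- expand.grid(from = g1, to = g2, stringsAsFactors = FALSE)
    src <- c(src, pairs$from); tgt <- c(tgt, pairs$to)
    subtypes <- xml2::xml_attr(xml2::xml_find_all(rel, ".//subtype"), "name")
    if (any(subtypes %in% undirected_subtypes)) {
      src <- c(src, pairs$to); tgt <- c(tgt, pairs$from)
    }
  }
  pathway_graph(name, nodes, cbind(src, tgt))
}

#' Read pathway graphs from an edge-list TSV
#'
#' Simple exchange dialect for non-KEGG pathway sets and fixtures: columns
#' `pathway`, `source_gene`, `target_gene`, one directed edge per row.
#' Isolated nodes cannot be expressed in this dialect; every node named here
#' has at least one incident edge.
#'
#' @param path Path to the TSV.
#' @return A named list of [pathway_graph()] objects.
#' @export
read_edge_list_tsv <- function(path) {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("pathway", "source_gene", "target_gene")
  if (!all(need %in% colnames(tab)))
    stop("edge list TSV must have columns ", paste(need, collapse = ", "))
  out <- lapply(split(tab, tab$pathway), function(d) {
    pathway_graph(d$pathway[1L],
                  unique(c(d$source_gene, d$target_gene)),
                  cbind(d$source_gene, d$target_gene))
  })
  out[order(names(out))]
}

#' Write pathway graphs to an edge-list TSV
#' @param graphs A list of [pathway_graph()] objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list_tsv <- function(graphs, path) {
  rows <- do.call(rbind, lapply(graphs, function(g) {
    if (nrow(g$edges) == 0L) return(NULL)
    data.frame(pathway = g$name, source_gene = g$edges[, 1L],
               target_gene = g$edges[, 2L], stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a two-column TSV
#'
#' Columns `pathway`, `gene`; used for set-based scoring methods (LLR, CORG,
#' NTC, GED) with MSigDB-style canonical pathway collections.
#'
#' @param path Path to the TSV.
#' @return A named list of character vectors (gene ids per set).
#' @export
read_gene_sets_tsv <- function(path) {
  if (!file.exists(path)) stop("gene set file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("pathway", "gene") %in% colnames(tab)))
    stop("gene set TSV must have columns pathway and gene")
  sets <- lapply(split(tab$gene, tab$pathway), unique)
  sets[order(names(sets))]
}

#' Read gene sets in GMT format
#'
#' GMT is the MSigDB exchange format: one set per line, tab-separated as
#' `name`, `description`, then member genes.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file")
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(ln, 1, 60))
    sets[[parts[1L]]] <- unique(parts[-(1:2)])
  }
  sets
}

#' Gene sets implied by pathway graphs
#' @param graphs List of [pathway_graph()] objects.
#' @return Named list of character vectors (each pathway's node set).
#' @export
graphs_to_gene_sets <- function(graphs) {
  stats::setNames(lapply(graphs, function(g) g$nodes),
                  vapply(graphs, function(g) g$name, character(1)))
}

#' Restrict a pathway graph to measured genes
#'
#' Genes not measured in every study, and their incident edges, cannot enter
#' the model and are removed.
#'
#' @param graph A [pathway_graph()].
#' @param measured Character vector of measured gene ids.
#' @return A [pathway_graph()] over `nodes` intersected with `measured`.
#' @export
restrict_to_measured <- function(graph, measured) {
  keep_nodes <- intersect(graph$nodes, measured)
  keep <- graph$edges[, 1L] %in% keep_nodes & graph$edges[, 2L] %in% keep_nodes
  pathway_graph(graph$name, keep_nodes, graph$edges[keep, , drop = FALSE])
}

#' Keep only scorable pathways
#'
#' A pathway is scorable when at least one edge survives restriction and
#' deduplication; edgeless pathways carry no topology and are excluded.
#'
#' @param graphs A list of [pathway_graph()] objects.
#' @return The sublist of graphs with at least one deduplicated edge.
#' @export
filter_scorable <- function(graphs) {
  Filter(function(g) nrow(unique(g$edges)) >= 1L, graphs)
}
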