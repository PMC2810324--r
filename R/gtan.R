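#' Build a gene-term association network
#'
#' A strictly bipartite graph linking each gene of a deregulated gene list
#' to every selected functional term annotating it. Typical use: the four
#' disease-relevant GO-BP terms (oxidative phosphorylation, apoptosis,
#' synaptic transmission, transmission of nerve impulse) against the
#' male-PD list pre-intersected with the all-samples lists.
#'
#' @param gene_list A `gene_list`/data.frame with a `gene` column, or a
#'   character vector of gene symbols.
#' @param sets A [gene_set_collection()].
#' @param selected_terms Character vector of set ids to include as term
#'   nodes.
#' @return List of class `gene_term_network`: `edges` (data.frame gene,
#'   term, ordered by term then gene), `genes`, `terms`, and per-node
#'   degree tables.
#' @export
build_gtan <- function(gene_list, sets, selected_terms) {
  stopifnot(inherits(sets, "gene_set_collection"))
  genes <- if (is.data.frame(gene_list)) unique(gene_list$gene)
           else unique(as.character(gene_list))
  unknown <- setdiff(selected_terms, names(sets$sets))
  if (length(unknown))
    stop("unknown term id(s): ", paste(unknown, collapse = ", "))
  edges <- do.call(rbind, lapply(sort(selected_terms), function(t) {
    hit <- sort(intersect(sets$sets[[t]], genes))
    if (length(hit) == 0) return(NULL)
    data.frame(gene = hit, term = t, stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(gene = character(), term = character(),
                        stringsAsFactors = FALSE)
  gene_degree <- table(factor(edges$gene, levels = sort(unique(edges$gene))))
  structure(list(edges = edges,
                 genes = sort(unique(edges$gene)),
                 terms = sort(selected_terms),
                 gene_degree = gene_degree,
                 term_degree = table(factor(edges$term,
                                            levels = sort(selected_terms)))),
            class = "gene_term_network")
}

#' @export
print.gene_term_network <- function(x, ...) {
  cat(sprintf("gene_term_network: %d genes, %d terms, %d edges\n",
              length(x$genes), length(x$terms), nrow(x$edges)))
  invisible(x)
}

#' Genes associated with at least `min_terms` selected terms
#'
#' Extracts the multi-term genes of a gene-term network — the transcripts
#' common to two or more of the selected pathways.
#'
#' @param net A `gene_term_network`.
#' @param min_terms Minimum degree (default 2).
#' @return Character vector of gene symbols, sorted lexicographically.
#' @export
select_multiterm_genes <- function(net, min_terms = 2) {
  stopifnot(inherits(net, "gene_term_network"))
  if (min_terms < 1) stop("min_terms must be >= 1")
  sort(names(net$gene_degree)[net$gene_degree >= min_terms])
}

#' Write a gene-term network as a TSV edge list
#' @param net A `gene_term_network`.
#' @param path Output path.
#' @export
write_gtan_tsv <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a gene-term network to GraphML (requires igraph)
#'
#' Node attribute `role` distinguishes gene from term nodes; term nodes
#' carry their member count.
#'
#' @param net A `gene_term_network`.
#' @param path Output .graphml path.
#' @export
write_gtan_graphml <- function(net, path) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("GraphML export requires the igraph package")
  nodes <- data.frame(name = c(net$genes, net$terms),
                      role = rep(c("gene", "term"),
                                 c(length(net$genes), length(net$terms))),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
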