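#' Construct an evidence annotation table
#'
#' Key-gene selection combines four externally curated evidence criteria
#' per gene: (1) membership in the pathway-level comparative enrichment,
#' (2) association with disease pathogenesis, (3) support from previously
#' published expression studies, and (4) genetic-association/GWAS support.
#' The package treats these as opaque boolean flags with provenance; no
#' live database mining is attempted.
#'
#' @param gene Character vector of gene symbols.
#' @param pathway_enrichment,pd_pathway,microarray_support,genetic_support
#'   Logical vectors, one per gene.
#' @param source Optional character provenance label per gene.
#' @return A data.frame of class `evidence_annotation`.
#' @export
evidence_annotation <- function(gene, pathway_enrichment, pd_pathway,
                                microarray_support, genetic_support,
                                source = NA_character_) {
  out <- data.frame(gene = as.character(gene),
                    pathway_enrichment = as.logical(pathway_enrichment),
                    pd_pathway = as.logical(pd_pathway),
                    microarray_support = as.logical(microarray_support),
                    genetic_support = as.logical(genetic_support),
                    source = source, stringsAsFactors = FALSE)
  if (anyNA(out[2:5])) stop("evidence flags must be TRUE/FALSE")
  if (anyDuplicated(out$gene)) stop("duplicate genes in evidence table")
  class(out) <- c("evidence_annotation", "data.frame")
  out
}

#' Compose the key-gene table from merged matrices and evidence flags
#'
#' Retains the genes that satisfy all four evidence criteria AND appear in
#' at least one contrast list at either stringency; attaches the five
#' fold-change columns (all-samples stringent; male stringent/relaxed;
#' female stringent/relaxed; 0 = absent) and the cross-stringency gender
#' status from [classify_gender_status()].
#'
#' @param matrix_stringent,matrix_relaxed `merged_matrix` objects carrying
#'   at least the all-samples and the two gender contrast columns.
#' @param evidence An [evidence_annotation()].
#' @param all_col,male_col,female_col Contrast column names (defaults
#'   "allN_allPD", "mN_mPD", "fN_fPD").
#' @return A data.frame of class `key_gene_table` with columns gene,
#'   fc_all_stringent, fc_male_stringent, fc_male_relaxed,
#'   fc_female_stringent, fc_female_relaxed, status.
#' @export
compose_key_gene_list <- function(matrix_stringent, matrix_relaxed,
                                  evidence,
                                  all_col = "allN_allPD",
                                  male_col = "mN_mPD",
                                  female_col = "fN_fPD") {
  if (missing(evidence) || !inherits(evidence, "evidence_annotation"))
    stop("an evidence_annotation table is required")
  flags <- evidence$pathway_enrichment & evidence$pd_pathway &
    evidence$microarray_support & evidence$genetic_support
  candidates <- evidence$gene[flags]
  in_lists <- union(rownames(matrix_stringent), rownames(matrix_relaxed))
  retained <- sort(intersect(candidates, in_lists))
  cell <- function(m, g, col) {
    out <- numeric(length(g))
    hit <- g %in% rownames(m)
    if (col %in% colnames(m))
      out[hit] <- m[g[hit], col]
    out
  }
  status <- classify_gender_status(matrix_stringent, matrix_relaxed,
                                   male_col = male_col,
                                   female_col = female_col)
  out <- data.frame(
    gene = retained,
    fc_all_stringent = cell(matrix_stringent, retained, all_col),
    fc_male_stringent = cell(matrix_stringent, retained, male_col),
    fc_male_relaxed = cell(matrix_relaxed, retained, male_col),
    fc_female_stringent = cell(matrix_stringent, retained, female_col),
    fc_female_relaxed = cell(matrix_relaxed, retained, female_col),
    status = status$status[match(retained, status$gene)],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("key_gene_table", "data.frame")
  out
}

#' Read an evidence annotation from TSV
#' @param path TSV with columns gene, pathway_enrichment, pd_pathway,
#'   microarray_support, genetic_support and optionally source; flags as
#'   TRUE/FALSE or 0/1.
#' @return An [evidence_annotation()].
#' @export
read_evidence_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  evidence_annotation(df$gene,
                      as.logical(df$pathway_enrichment),
                      as.logical(df$pd_pathway),
                      as.logical(df$microarray_support),
                      as.logical(df$genetic_support),
                      source = if ("source" %in% names(df)) df$source
                               else NA_character_)
}
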