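#' Construct an expression matrix container
#'
#' Bundles a log2 intensity matrix (probes x samples) with its probe-to-gene
#' map. All downstream analyses (batch removal, SAM, ANOVA, fold changes)
#' operate on this container.
#'
#' @param values Numeric matrix of log2 intensities, probes in rows, samples
#'   in columns. Row names are probe ids, column names sample ids.
#' @param probe_to_gene Named character vector mapping probe id to gene
#'   symbol. Names must cover all row names of `values`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` and `probe_to_gene`.
#' @export
expression_matrix <- function(values, probe_to_gene) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have probe row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe ids in `values`")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in `values`")
  if (!all(is.finite(values)))
    stop("all expression values must be finite")
  probe_to_gene <- probe_to_gene[rownames(values)]
  if (anyNA(probe_to_gene) || is.null(names(probe_to_gene)))
    stop("`probe_to_gene` must name a gene for every probe")
  structure(list(values = values, probe_to_gene = probe_to_gene),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probes x %d samples (%d genes)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$probe_to_gene))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Construct sample metadata
#'
#' @param sample_id Character vector of sample ids.
#' @param gender Factor or character, each "male" or "female".
#' @param disease Factor or character, each "control" or "PD".
#' @param batch Batch labels (any atomic type; coerced to character).
#' @return A data.frame of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_id, gender, disease, batch) {
  gender <- as.character(gender)
  disease <- as.character(disease)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  if (!all(gender %in% c("male", "female")))
    stop("gender must be 'male' or 'female'")
  if (!all(disease %in% c("control", "PD")))
    stop("disease must be 'control' or 'PD'")
  out <- data.frame(sample_id = as.character(sample_id),
                    gender = gender, disease = disease,
                    batch = as.character(batch),
                    stringsAsFactors = FALSE)
  if (anyNA(out)) stop("metadata must be complete (no NA)")
  class(out) <- c("sample_metadata", "data.frame")
  out
}

check_samples_match <- function(x, meta) {
  if (!setequal(colnames(x$values), meta$sample_id))
    stop("metadata sample ids do not match expression columns")
  invisible(TRUE)
}

#' Names of the six standard contrasts
#'
#' The disease-by-gender design is interrogated through six gene lists:
#' an all-control vs all-PD comparison computed twice (once by SAM, once as
#' the disease factor of the multi-factor ANOVA), the within-gender disease
#' contrasts (mN_mPD, fN_fPD), and the cross-gender contrasts among controls
#' (mN_fN) and among patients (mPD_fPD).
#'
#' @return Character vector of contrast names.
#' @export
contrast_names <- function() {
  c("allN_allPD", "allN_allPD_anova", "mN_mPD", "fN_fPD", "mN_fN", "mPD_fPD")
}

#' Resolve the two sample groups of a named contrast
#'
#' @param meta A `sample_metadata`.
#' @param contrast One of `contrast_names()` (the ANOVA variant resolves the
#'   same groups as `allN_allPD`).
#' @return List with character vectors `group_a` and `group_b` of sample ids;
#'   fold changes and SAM d are reported as B relative to A.
#' @export
contrast_groups <- function(meta, contrast) {
  pick <- function(g, d) {
    keep <- rep(TRUE, nrow(meta))
    if (!is.null(g)) keep <- keep & meta$gender == g
    if (!is.null(d)) keep <- keep & meta$disease == d
    meta$sample_id[keep]
  }
  res <- switch(contrast,
    allN_allPD = ,
    allN_allPD_anova = list(group_a = pick(NULL, "control"),
                            group_b = pick(NULL, "PD")),
    mN_mPD = list(group_a = pick("male", "control"),
                  group_b = pick("male", "PD")),
    fN_fPD = list(group_a = pick("female", "control"),
                  group_b = pick("female", "PD")),
    mN_fN  = list(group_a = pick("male", "control"),
                  group_b = pick("female", "control")),
    mPD_fPD = list(group_a = pick("male", "PD"),
                   group_b = pick("female", "PD")),
    stop("unknown contrast: ", contrast))
  if (length(res$group_a) == 0 || length(res$group_b) == 0)
    stop("contrast ", contrast, " has an empty group")
  res
}

#' Write an expression matrix and its probe map to TSV
#'
#' @param x An `expression_matrix`.
#' @param path Output TSV path; first column `probe_id`, second `gene`,
#'   remaining columns one per sample.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(probe_id = rownames(x$values),
                   gene = unname(x$probe_to_gene),
                   x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression_tsv()]
#'
#' @param path TSV path.
#' @return An `expression_matrix`.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(vals) <- df$probe_id
  expression_matrix(vals, stats::setNames(df$gene, df$probe_id))
}

#' Write sample metadata to TSV
#' @param meta A `sample_metadata`.
#' @param path Output path.
#' @export
write_metadata_tsv <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#' @param path TSV with columns sample_id, gender, disease, batch.
#' @return A `sample_metadata`.
#' @export
read_metadata_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  sample_metadata(df$sample_id, df$gender, df$disease, df$batch)
}
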