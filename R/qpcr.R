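#' Construct a qPCR Ct table
#'
#' Long-format cycle-threshold data: one row per (gene, sample, replicate),
#' with a designated endogenous-control (reference) gene used for
#' within-sample normalization.
#'
#' @param data Data.frame with columns `gene`, `sample`, `replicate`, `ct`.
#' @param reference_gene Gene symbol of the endogenous control (e.g. GUSB).
#' @param n_replicates Declared replicates per (gene, sample); default 3.
#' @return A data.frame of class `ct_table` with attributes
#'   `reference_gene` and `n_replicates`.
#' @export
ct_table <- function(data, reference_gene, n_replicates = 3) {
  stopifnot(is.data.frame(data),
            all(c("gene", "sample", "replicate", "ct") %in% names(data)))
  if (any(!is.finite(data$ct)) || any(data$ct <= 0))
    stop("Ct values must be finite and positive")
  if (!reference_gene %in% data$gene)
    stop("reference gene ", reference_gene, " absent from Ct table")
  counts <- table(data$gene, data$sample)
  if (any(counts > 0 & counts != n_replicates))
    warning("some (gene, sample) cells deviate from the declared ",
            n_replicates, " replicates")
  out <- data
  attr(out, "reference_gene") <- reference_gene
  attr(out, "n_replicates") <- n_replicates
  class(out) <- c("ct_table", "data.frame")
  out
}

#' Relative expression by the 2^-DeltaCt method
#'
#' Replicate Ct values are aggregated by their mean per (gene, sample);
#' cells whose replicate SD exceeds `sd_flag` cycles are flagged (and the
#' furthest replicate dropped when `drop_outliers = TRUE`). DeltaCt is the
#' gene's mean Ct minus the same-sample reference-gene mean Ct, and
#' relative expression is 2^-DeltaCt, so the reference gene itself is 1 in
#' every sample.
#'
#' @param ct A [ct_table()].
#' @param sd_flag Replicate-SD flag threshold in cycles (default 0.5).
#' @param drop_outliers Remove the replicate furthest from the cell median
#'   in flagged cells before aggregating (default FALSE: flag only).
#' @return A data.frame of class `relative_expression` with columns gene,
#'   sample, mean_ct, sd_ct, flagged, delta_ct, rel_expr, plus a per-gene
#'   `tier` column (high/medium/low by tertiles of mean rel_expr over
#'   samples, reference gene excluded from tiering).
#' @export
relative_expression_2dct <- function(ct, sd_flag = 0.5,
                                     drop_outliers = FALSE) {
  stopifnot(inherits(ct, "ct_table"))
  ref <- attr(ct, "reference_gene")
  agg <- do.call(rbind, lapply(split(ct, list(ct$gene, ct$sample),
                                     drop = TRUE), function(cell) {
    ctv <- cell$ct
    sdv <- if (length(ctv) > 1) stats::sd(ctv) else 0
    flagged <- sdv > sd_flag
    if (flagged && drop_outliers && length(ctv) > 2) {
      ctv <- ctv[-which.max(abs(ctv - stats::median(ctv)))]
      sdv <- stats::sd(ctv)
    }
    data.frame(gene = cell$gene[1], sample = cell$sample[1],
               mean_ct = mean(ctv), sd_ct = sdv, flagged = flagged,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  samples <- unique(ct$sample)
  ref_rows <- agg[agg$gene == ref, ]
  missing_ref <- setdiff(samples, ref_rows$sample)
  if (length(missing_ref))
    stop("reference gene ", ref, " not measured in sample(s): ",
         paste(missing_ref, collapse = ", "))
  ref_ct <- stats::setNames(ref_rows$mean_ct, ref_rows$sample)
  agg$delta_ct <- agg$mean_ct - ref_ct[agg$sample]
  agg$rel_expr <- 2^(-agg$delta_ct)
  # expression tiers over the assayed (non-reference) genes
  gene_means <- tapply(agg$rel_expr[agg$gene != ref],
                       agg$gene[agg$gene != ref], mean)
  tier <- rep(NA_character_, length(gene_means))
  if (length(gene_means) >= 3) {
    cuts <- stats::quantile(gene_means, c(1 / 3, 2 / 3), names = FALSE)
    tier <- ifelse(gene_means <= cuts[1], "low",
                   ifelse(gene_means <= cuts[2], "medium", "high"))
  }
  tiers <- stats::setNames(tier, names(gene_means))
  agg$tier <- tiers[agg$gene]
  agg <- agg[order(agg$gene, agg$sample), ]
  rownames(agg) <- NULL
  attr(agg, "reference_gene") <- ref
  class(agg) <- c("relative_expression", "data.frame")
  agg
}

#' Cross-platform concordance of qPCR and array measurements
#'
#' For each assayed gene present on the array, pairs the per-sample
#' 2^-DeltaCt values with array z-scores (the gene's log2 values
#' standardized across the shared samples) and reports their Spearman
#' correlation plus direction-of-change agreement between PD and control
#' group means (when metadata is supplied). Genes with constant array
#' expression are skipped with a notice.
#'
#' @param rel A `relative_expression`.
#' @param x An [expression_matrix()]; multi-probe genes are averaged on the
#'   log2 scale before standardization.
#' @param meta Optional [sample_metadata()] enabling the direction check.
#' @return A data.frame of class `concordance_report`: gene, n_samples,
#'   spearman, direction_agree (NA without metadata), tier.
#' @export
compare_with_zscores <- function(rel, x, meta = NULL) {
  stopifnot(inherits(rel, "relative_expression"),
            inherits(x, "expression_matrix"))
  ref <- attr(rel, "reference_gene")
  shared_samples <- intersect(unique(rel$sample), colnames(x$values))
  if (length(shared_samples) < 3)
    stop("need >= 3 shared samples between qPCR and array data")
  genes <- setdiff(intersect(unique(rel$gene), x$probe_to_gene), ref)
  if (length(genes) == 0) stop("no shared genes")
  rows <- lapply(genes, function(g) {
    probes <- names(x$probe_to_gene)[x$probe_to_gene == g]
    arr <- colMeans(x$values[probes, shared_samples, drop = FALSE])
    if (stats::sd(arr) == 0) {
      message("gene ", g, " has constant array expression; skipped")
      return(NULL)
    }
    z <- (arr - mean(arr)) / stats::sd(arr)
    rq <- rel[rel$gene == g, ]
    q <- stats::setNames(rq$rel_expr, rq$sample)[shared_samples]
    rho <- stats::cor(z, q, method = "spearman")
    dir_agree <- NA
    if (!is.null(meta)) {
      md <- meta[match(shared_samples, meta$sample_id), ]
      if (all(c("control", "PD") %in% md$disease)) {
        d_arr <- mean(arr[md$disease == "PD"]) -
          mean(arr[md$disease == "control"])
        d_q <- mean(q[md$disease == "PD"]) -
          mean(q[md$disease == "control"])
        dir_agree <- sign(d_arr) == sign(d_q)
      }
    }
    data.frame(gene = g, n_samples = length(shared_samples),
               spearman = rho, direction_agree = dir_agree,
               tier = rq$tier[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("all shared genes had constant array expression")
  rownames(out) <- NULL
  class(out) <- c("concordance_report", "data.frame")
  out
}

#' Read a long-format Ct TSV
#' @param path TSV with columns gene, sample, replicate, ct.
#' @param reference_gene Endogenous-control gene symbol.
#' @param n_replicates Declared replicate count (default 3).
#' @return A [ct_table()].
#' @export
read_ct_tsv <- function(path, reference_gene, n_replicates = 3) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  ct_table(df, reference_gene, n_replicates)
}

#' Write a Ct table to TSV
#' @param ct A `ct_table`.
#' @param path Output path.
#' @export
write_ct_tsv <- function(ct, path) {
  utils::write.table(as.data.frame(ct), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
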