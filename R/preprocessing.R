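#' Remove an additive batch effect by a per-gene fixed-effects ANOVA model
#'
#' Fits, per probe, the additive model
#' `log2 expression ~ disease + gender + batch` by least squares and
#' subtracts the fitted batch component, re-centred so the per-probe grand
#' mean is preserved. With a single batch the input is returned unchanged.
#' The operation is idempotent and exact for a truly additive batch shift.
#'
#' @param x An [expression_matrix()].
#' @param meta A [sample_metadata()] covering the columns of `x`.
#' @return A corrected `expression_matrix` of the same shape.
#' @export
remove_batch_effect <- function(x, meta) {
  stopifnot(inherits(x, "expression_matrix"))
  check_samples_match(x, meta)
  meta <- meta[match(colnames(x$values), meta$sample_id), ]
  batches <- unique(meta$batch)
  if (length(batches) == 1) return(x)
  counts <- table(meta$batch)
  if (any(counts < 2))
    stop("batch ", names(counts)[which(counts < 2)[1]],
         " has a single sample; batch effect not estimable")
  if (length(unique(paste(meta$disease, meta$batch))) ==
      length(unique(meta$batch)))
    warning("batch is perfectly confounded with disease; ",
            "correction removes disease signal")
  # disease + gender main effects first, batch dummies last so pivoting
  # drops aliased batch terms under confounding instead of class terms
  design <- stats::model.matrix(~ disease + gender + batch,
                                data = data.frame(
                                  disease = factor(meta$disease),
                                  gender = factor(meta$gender),
                                  batch = factor(meta$batch)))
  fit <- stats::lm.fit(design, t(x$values))
  coefs <- t(fit$coefficients)  # probes x p
  if (anyNA(coefs)) {
    warning("batch aliased with class terms; the aliased component is ",
            "left uncorrected")
    coefs[is.na(coefs)] <- 0
  }
  bcols <- grep("^batch", colnames(design))
  batch_fit <- coefs[, bcols, drop = FALSE] %*%
    t(design[, bcols, drop = FALSE])
  # re-centre so per-probe grand means are untouched
  batch_fit <- batch_fit - rowMeans(batch_fit)
  corrected <- x$values - batch_fit
  expression_matrix(corrected, x$probe_to_gene)
}

#' Principal component scores for QC of class and batch separation
#'
#' PCA of samples in probe space, by default on per-probe z-scores
#' (each probe centred and scaled across samples), which puts all probes on
#' a comparable footing; `standardize = FALSE` analyses raw log2 values
#' (centred only).
#'
#' @param x An [expression_matrix()].
#' @param n_components Number of components to keep.
#' @param standardize Standardize probes before PCA (default TRUE).
#' @return List with `scores` (samples x components), `variance_fraction`
#'   (length `n_components`, non-increasing) and `loadings` (probes x
#'   components, orthonormal).
#' @export
pca_scores <- function(x, n_components = 2, standardize = TRUE) {
  stopifnot(inherits(x, "expression_matrix"))
  if (n_components > min(dim(x$values)))
    stop("n_components exceeds min(#probes, #samples)")
  v <- x$values
  sds <- apply(v, 1, stats::sd)
  if (all(sds == 0)) stop("constant expression matrix: no variance for PCA")
  if (standardize) {
    keep <- sds > 0
    v <- (v[keep, , drop = FALSE] - rowMeans(v[keep, , drop = FALSE])) /
      sds[keep]
  }
  p <- stats::prcomp(t(v), center = !standardize, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  vf <- (p$sdev^2 / sum(p$sdev^2))[seq_len(k)]
  list(scores = p$x[, seq_len(k), drop = FALSE],
       variance_fraction = vf,
       loadings = p$rotation[, seq_len(k), drop = FALSE])
}

#' Mean silhouette width of a labelling in a score space
#'
#' Small helper for QC: average silhouette of samples grouped by a label
#' (e.g. batch) using Euclidean distance in PC space. Values near 0 or
#' below indicate no separation. Computed from the definition.
#'
#' @param scores Numeric matrix, samples x dimensions.
#' @param labels Grouping labels, one per row of `scores`.
#' @return Mean silhouette width (scalar in [-1, 1]).
#' @export
mean_silhouette <- function(scores, labels) {
  labels <- as.character(labels)
  d <- as.matrix(stats::dist(scores))
  n <- nrow(d)
  sil <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) < 2) return(0)
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}
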