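#' Collapse several probe-level signed fold changes to one gene-level value
#'
#' Each signed fold change is mapped to a linear ratio (a 2.1-fold drop
#' becomes 1/2.1), the ratios are averaged arithmetically, and the mean is
#' converted back to the signed convention. Averaging in ratio space (not
#' log space) matches how multi-probe genes are summarised in this
#' pipeline: probes at -2.1 and +1.3 collapse to -1.13.
#'
#' @param fold_changes Numeric vector of signed fold changes (|FC| >= 1).
#' @return A single signed fold change.
#' @export
collapse_probes <- function(fold_changes) {
  if (length(fold_changes) == 0) stop("no probe fold changes to collapse")
  if (any(!is.finite(fold_changes)) || any(abs(fold_changes) < 1))
    stop("signed fold changes must be finite with |FC| >= 1")
  ratios <- ifelse(fold_changes >= 0, fold_changes, -1 / fold_changes)
  r <- mean(ratios)
  if (r >= 1) r else -1 / r
}

#' Collapse a probe-level gene list to gene level
#'
#' @param gl A `gene_list` (probe-level).
#' @return A data.frame with one row per gene: gene, fold_change (collapsed
#'   via [collapse_probes()]), n_probes, min q and min p across the gene's
#'   probes. Keeps the `contrast`/`stringency` attributes.
#' @export
collapse_gene_list <- function(gl) {
  stopifnot(is.data.frame(gl))
  if (nrow(gl) == 0) {
    out <- data.frame(gene = character(), fold_change = numeric(),
                      n_probes = integer(), q = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    sp <- split(gl, gl$gene)
    out <- data.frame(
      gene = names(sp),
      fold_change = vapply(sp, function(d)
        collapse_probes(d$fold_change), numeric(1)),
      n_probes = vapply(sp, nrow, integer(1)),
      q = vapply(sp, function(d) min(d$q), numeric(1)),
      p = vapply(sp, function(d) min(d$p), numeric(1)),
      stringsAsFactors = FALSE)
    out <- out[order(out$gene), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "contrast") <- attr(gl, "contrast")
  attr(out, "stringency") <- attr(gl, "stringency")
  out
}

#' Build the merged genes-by-contrasts fold-change matrix
#'
#' One row per gene appearing in at least one list; cells carry the
#' collapsed signed fold change, with 0 reserved as the "absent from that
#' list" sentinel (list entries always have |FC| >= 1, so 0 cannot collide
#' with a real value).
#'
#' @param lists Named list of gene-level data.frames (columns `gene`,
#'   `fold_change`), e.g. from [collapse_gene_list()]; names become the
#'   matrix columns.
#' @return A numeric matrix of class `merged_matrix` (genes x contrasts).
#' @export
build_merged_matrix <- function(lists) {
  stopifnot(is.list(lists), length(lists) >= 1, !is.null(names(lists)))
  for (nm in names(lists)) {
    l <- lists[[nm]]
    if (anyDuplicated(l$gene))
      stop("list ", nm, " has conflicting duplicate gene rows; ",
           "collapse probes first")
  }
  genes <- sort(unique(unlist(lapply(lists, `[[`, "gene"))))
  m <- matrix(0, length(genes), length(lists),
              dimnames = list(genes, names(lists)))
  for (nm in names(lists)) {
    l <- lists[[nm]]
    m[l$gene, nm] <- l$fold_change
  }
  class(m) <- c("merged_matrix", class(m))
  m
}

#' Recover per-contrast gene lists from a merged matrix
#'
#' Inverse of [build_merged_matrix()]: non-zero cells define membership.
#'
#' @param m A `merged_matrix`.
#' @return Named list of data.frames (gene, fold_change).
#' @export
merged_matrix_to_lists <- function(m) {
  stats::setNames(lapply(colnames(m), function(nm) {
    keep <- m[, nm] != 0
    data.frame(gene = rownames(m)[keep], fold_change = unname(m[keep, nm]),
               stringsAsFactors = FALSE)
  }), colnames(m))
}

#' Partition a family of gene lists into membership regions
#'
#' Computes, Venn-style, every non-empty membership signature over the
#' lists with its gene set and count, plus per-list up/down counts and
#' counts above a fold-change magnitude cut-off (default 1.5). When
#' `reference_total` is given (e.g. the size of the full deregulated list),
#' each region is also reported as a percentage of it, rounded to one
#' decimal.
#'
#' @param lists Named list of gene-level data.frames (columns `gene`,
#'   `fold_change`).
#' @param fold_cutoff Magnitude threshold for the "strong" counts.
#' @param reference_total Optional denominator for region percentages.
#' @return List of class `overlap_partition` with `regions` (data.frame:
#'   signature, count, percent, genes) and `per_list` (data.frame: list,
#'   size, n_up, n_down, n_up_strong, n_down_strong).
#' @export
partition_overlaps <- function(lists, fold_cutoff = 1.5,
                               reference_total = NULL) {
  stopifnot(is.list(lists), length(lists) >= 2, !is.null(names(lists)))
  nms <- names(lists)
  membership <- lapply(lists, function(l) unique(l$gene))
  genes <- sort(unique(unlist(membership)))
  sig_mat <- vapply(membership, function(s) genes %in% s,
                    logical(length(genes)))
  if (length(genes) == 1) sig_mat <- matrix(sig_mat, nrow = 1,
                                            dimnames = list(genes, nms))
  signature <- apply(sig_mat, 1, function(r)
    paste(nms[r], collapse = "&"))
  sp <- split(genes, signature)
  regions <- data.frame(
    signature = names(sp),
    count = vapply(sp, length, integer(1)),
    genes = vapply(sp, function(g) paste(g, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(reference_total))
    regions$percent <- round(100 * regions$count / reference_total, 1)
  regions <- regions[order(-regions$count, regions$signature), ]
  rownames(regions) <- NULL
  per_list <- do.call(rbind, lapply(nms, function(nm) {
    fc <- lists[[nm]]$fold_change
    data.frame(list = nm, size = length(fc),
               n_up = sum(fc > 0), n_down = sum(fc < 0),
               n_up_strong = sum(fc > fold_cutoff),
               n_down_strong = sum(fc < -fold_cutoff),
               stringsAsFactors = FALSE)
  }))
  structure(list(regions = regions, per_list = per_list,
                 n_union = length(genes),
                 fold_cutoff = fold_cutoff,
                 reference_total = reference_total),
            class = "overlap_partition")
}

#' Count genes present in every one of a set of lists
#'
#' Convenience accessor over an [partition_overlaps()] result: total genes
#' whose membership includes all the named lists (summing all matching
#' regions).
#'
#' @param part An `overlap_partition`.
#' @param which_lists Character vector of list names.
#' @return Integer count; with attribute `percent` when the partition was
#'   built with a `reference_total`.
#' @export
overlap_count <- function(part, which_lists) {
  stopifnot(inherits(part, "overlap_partition"))
  in_all <- vapply(strsplit(part$regions$signature, "&", fixed = TRUE),
                   function(s) all(which_lists %in% s), logical(1))
  n <- sum(part$regions$count[in_all])
  if (!is.null(part$reference_total))
    attr(n, "percent") <- round(100 * n / part$reference_total, 1)
  n
}

#' @export
print.overlap_partition <- function(x, ...) {
  cat(sprintf("overlap_partition: %d lists, union %d genes, %d regions\n",
              nrow(x$per_list), x$n_union, nrow(x$regions)))
  print(utils::head(x$regions[, setdiff(names(x$regions), "genes")], 10))
  invisible(x)
}

#' Classify per-gene gender status across two stringencies
#'
#' At each stringency a gene is labelled M if present (non-zero) in the
#' male disease contrast and absent from the female one, F for the
#' converse, MF if present in both; the final label is "male-specific" when
#' M at both stringencies, "female-specific" when F at both, "shared" when
#' MF at both, and "stringency-dependent" otherwise. Genes absent from both
#' gender contrasts at both stringencies are excluded with a notice.
#'
#' @param matrix_stringent,matrix_relaxed `merged_matrix` objects carrying
#'   the male and female contrast columns at each stringency.
#' @param male_col,female_col Column names of the gender contrasts
#'   (defaults "mN_mPD", "fN_fPD").
#' @return A data.frame (gene, status_stringent, status_relaxed, status)
#'   of class `gender_status`.
#' @export
classify_gender_status <- function(matrix_stringent, matrix_relaxed,
                                   male_col = "mN_mPD",
                                   female_col = "fN_fPD") {
  for (m in list(matrix_stringent, matrix_relaxed))
    if (!all(c(male_col, female_col) %in% colnames(m)))
      stop("matrices must carry columns ", male_col, " and ", female_col)
  genes <- sort(union(rownames(matrix_stringent), rownames(matrix_relaxed)))
  cell <- function(m, g, col)
    ifelse(g %in% rownames(m), m[match(g, rownames(m)), col], 0)
  per_str <- function(m) {
    male <- vapply(genes, cell, numeric(1), m = m, col = male_col) != 0
    female <- vapply(genes, cell, numeric(1), m = m, col = female_col) != 0
    ifelse(male & female, "MF",
           ifelse(male, "M", ifelse(female, "F", "absent")))
  }
  s1 <- per_str(matrix_stringent)
  s2 <- per_str(matrix_relaxed)
  drop <- s1 == "absent" & s2 == "absent"
  if (any(drop))
    message(sum(drop), " gene(s) absent from both gender contrasts at ",
            "both stringencies; excluded")
  status <- ifelse(s1 == "M" & s2 == "M", "male-specific",
            ifelse(s1 == "F" & s2 == "F", "female-specific",
            ifelse(s1 == "MF" & s2 == "MF", "shared",
                   "stringency-dependent")))
  out <- data.frame(gene = genes, status_stringent = s1,
                    status_relaxed = s2, status = status,
                    stringsAsFactors = FALSE)[!drop, ]
  rownames(out) <- NULL
  class(out) <- c("gender_status", "data.frame")
  out
}

#' Write a merged matrix to TSV
#' @param m A `merged_matrix`.
#' @param path Output path.
#' @export
write_merged_matrix_tsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a merged matrix from TSV
#' @param path TSV with a `gene` column then one column per contrast.
#' @return A `merged_matrix`.
#' @export
read_merged_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  class(m) <- c("merged_matrix", class(m))
  m
}
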