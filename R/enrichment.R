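#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (member gene symbols).
#' @param descriptions Optional named character vector of set descriptions.
#' @param universe Character vector of background gene symbols (all genes
#'   measured on the platform after probe collapsing). Set members outside
#'   the universe are dropped with a message.
#' @return List of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (anyDuplicated(names(sets))) stop("duplicate set ids")
  if (length(universe) == 0) stop("empty universe")
  universe <- sort(unique(universe))
  n_dropped <- 0L
  sets <- lapply(sets, function(s) {
    s2 <- intersect(unique(s), universe)
    n_dropped <<- n_dropped + (length(unique(s)) - length(s2))
    sort(s2)
  })
  if (n_dropped > 0)
    message(n_dropped, " set member(s) outside the universe dropped")
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)],
                 universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets over %d universe genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' One-sided Fisher exact over-representation p-value
#'
#' Upper-tail hypergeometric probability P(X >= k) of observing at least k
#' members of a size-K gene set in a size-n gene list drawn from a size-N
#' universe. Equivalent to the one-sided Fisher exact test on the 2x2
#' membership table.
#'
#' @param k Observed overlap.
#' @param K Gene-set size.
#' @param n Gene-list size.
#' @param N Universe size.
#' @return p in (0, 1].
#' @export
fisher_enrichment_p <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N)
    stop("inconsistent counts: need 0 <= k <= min(K, n) and K, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fisher over-representation of every set in every gene list
#'
#' @param lists Named list of gene-level data.frames (column `gene`) or
#'   character vectors of gene symbols.
#' @param sets A [gene_set_collection()]; its universe is the background.
#' @return List of class `enrichment_matrix`: `p` and `neg_log10_p`
#'   (sets x lists), and count matrices `k`, plus vectors `K`, `n` and
#'   scalar `N`.
#' @export
enrich_lists <- function(lists, sets) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (length(sets$universe) == 0) stop("empty universe")
  lists <- lapply(lists, function(l)
    if (is.data.frame(l)) unique(l$gene) else unique(as.character(l)))
  lists <- lapply(lists, intersect, y = sets$universe)
  N <- length(sets$universe)
  Ks <- vapply(sets$sets, length, integer(1))
  ns <- vapply(lists, length, integer(1))
  k_mat <- vapply(lists, function(l)
    vapply(sets$sets, function(s) length(intersect(s, l)), integer(1)),
    integer(length(sets$sets)))
  if (length(sets$sets) == 1)
    k_mat <- matrix(k_mat, nrow = 1,
                    dimnames = list(names(sets$sets), names(lists)))
  p_mat <- k_mat
  for (j in seq_along(lists))
    p_mat[, j] <- stats::phyper(k_mat[, j] - 1, Ks, N - Ks, ns[j],
                                lower.tail = FALSE)
  structure(list(p = p_mat, neg_log10_p = -log10(p_mat), k = k_mat,
                 K = Ks, n = ns, N = N,
                 descriptions = sets$descriptions),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("enrichment_matrix: %d sets x %d lists (universe %d)\n",
              nrow(x$p), ncol(x$p), x$N))
  invisible(x)
}

#' Anchor-restricted comparative enrichment
#'
#' Returns the gene sets significantly enriched in BOTH the anchor column
#' (typically the all-samples disease contrast) and a target column
#' (typically one gender's disease contrast) — the comparative
#' pattern-extraction step that pins gender-specific pathways to the
#' overall disease signal.
#'
#' @param em An `enrichment_matrix`.
#' @param anchor,target Column (gene-list) names; must differ.
#' @param alpha Significance threshold on the raw one-sided p (default
#'   0.05).
#' @param adjust Optionally "BH"-adjust p-values per column before
#'   thresholding (default "none").
#' @return Character vector of set ids, sorted by target-column p.
#' @export
restrict_to_anchor <- function(em, anchor, target, alpha = 0.05,
                               adjust = c("none", "BH")) {
  stopifnot(inherits(em, "enrichment_matrix"))
  adjust <- match.arg(adjust)
  if (!all(c(anchor, target) %in% colnames(em$p)))
    stop("unknown column(s): ",
         paste(setdiff(c(anchor, target), colnames(em$p)), collapse = ", "))
  if (anchor == target) stop("anchor and target must differ")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  pa <- em$p[, anchor]
  pt <- em$p[, target]
  if (adjust == "BH") {
    pa <- stats::p.adjust(pa, "BH")
    pt <- stats::p.adjust(pt, "BH")
  }
  hits <- rownames(em$p)[pa < alpha & pt < alpha]
  hits[order(pt[match(hits, rownames(em$p))])]
}

#' Read a gene-set collection from a GMT file
#'
#' GMT: one set per line, tab-separated: id, description, members...
#'
#' @param path GMT path.
#' @param universe Background genes; defaults to the union of all members.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1)
  desc <- vapply(parts, `[`, character(1), 2)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- ids
  if (is.null(universe)) universe <- unique(unlist(sets))
  gene_set_collection(sets, stats::setNames(desc, ids), universe)
}

#' Write a gene-set collection to a GMT file
#' @param sets A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  lines <- vapply(names(sets$sets), function(id)
    paste(c(id, sets$descriptions[[id]], sets$sets[[id]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write an enrichment matrix to TSV
#' @param em An `enrichment_matrix`.
#' @param path Output path. One row per set: id, description, K, then per
#'   list k, p and -log10 p.
#' @export
write_enrichment_tsv <- function(em, path) {
  df <- data.frame(set_id = rownames(em$p),
                   description = unname(em$descriptions[rownames(em$p)]),
                   K = unname(em$K), stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (nm in colnames(em$p)) {
    df[[paste0("k_", nm)]] <- em$k[, nm]
    df[[paste0("p_", nm)]] <- em$p[, nm]
    df[[paste0("neglog10p_", nm)]] <- em$neg_log10_p[, nm]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
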