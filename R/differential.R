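#' SAM moderated difference statistic
#'
#' Computes, per probe, the two-class unpaired SAM statistic
#' d = (mean_B - mean_A) / (s + s0), where s is the pooled standard error
#' sqrt((1/n_A + 1/n_B) * pooled within-group variance). With s0 = 0, d is
#' the classical pooled-variance two-sample t statistic. A probe with zero
#' variance in both groups and s0 = 0 gets d = 0 and is flagged.
#'
#' @param x An [expression_matrix()] or plain numeric matrix (probes x
#'   samples).
#' @param group_a,group_b Character vectors of sample (column) ids.
#' @param s0 Non-negative fudge factor added to the denominator.
#' @return A data.frame with columns `d`, `s` and logical `zero_variance`,
#'   one row per probe, in input probe order.
#' @export
sam_d_statistics <- function(x, group_a, group_b, s0 = 0) {
  v <- if (inherits(x, "expression_matrix")) x$values else x
  stopifnot(s0 >= 0, length(group_a) >= 2, length(group_b) >= 2)
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  a <- v[, group_a, drop = FALSE]
  b <- v[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  ssw <- rowSums((a - ma)^2) + rowSums((b - mb)^2)
  s <- sqrt((1 / na + 1 / nb) * ssw / (na + nb - 2))
  denom <- s + s0
  d <- ifelse(denom > 0, (mb - ma) / denom, 0)
  data.frame(d = d, s = s, zero_variance = denom == 0,
             row.names = rownames(v))
}

#' Select the SAM fudge factor s0
#'
#' Standard SAM recipe: candidate s0 values are percentiles of the pooled
#' standard errors s; for each candidate, probes are binned into 100
#' quantile windows of s, the median absolute deviation of d is computed per
#' window, and the candidate minimising the coefficient of variation of
#' these MADs across windows is chosen. Deterministic for fixed input and
#' invariant to probe order.
#'
#' @param x Expression matrix (container or plain matrix).
#' @param group_a,group_b Sample id vectors as in [sam_d_statistics()].
#' @param alphas Candidate percentiles of s (fractions in [0, 1]).
#' @return The selected s0 (scalar >= 0) with attribute `alpha`.
#' @export
select_s0 <- function(x, group_a, group_b,
                      alphas = seq(0, 1, by = 0.05)) {
  base <- sam_d_statistics(x, group_a, group_b, s0 = 0)
  s <- base$s
  m <- length(s)
  if (m < 100)
    warning("fewer than 100 probes; s0 selection is unstable")
  if (stats::sd(s) == 0) {
    out <- stats::quantile(s, alphas[1], names = FALSE)
    attr(out, "alpha") <- alphas[1]
    return(out)
  }
  diff_means <- base$d * s  # numerator, reused for every candidate
  n_windows <- min(100, max(2, floor(m / 10)))
  win <- cut(rank(s, ties.method = "first"),
             breaks = n_windows, labels = FALSE)
  cv <- vapply(alphas, function(a) {
    s0 <- stats::quantile(s, a, names = FALSE)
    d <- diff_means / (s + s0)
    v <- tapply(d, win, stats::mad)
    v <- v[is.finite(v) & v > 0]
    if (length(v) < 2) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  a_hat <- alphas[which.min(cv)]
  out <- stats::quantile(s, a_hat, names = FALSE)
  attr(out, "alpha") <- a_hat
  attr(out, "cv") <- cv
  out
}

# All or a seeded sample of two-group label assignments. Returns a logical
# matrix (n_samples x n_perms): TRUE marks membership of permuted group B.
# The first column is always the observed labelling.
permutation_assignments <- function(na, nb, n_permutations, seed) {
  n <- na + nb
  n_distinct <- choose(n, nb)
  obs <- c(rep(FALSE, na), rep(TRUE, nb))
  if (n_distinct <= n_permutations) {
    idx <- utils::combn(n, nb)
    perms <- matrix(FALSE, n, ncol(idx))
    perms[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = nb))] <- TRUE
    # put the observed labelling first
    obs_col <- which(colSums(perms == obs) == n)[1]
    perms <- perms[, c(obs_col, setdiff(seq_len(ncol(perms)), obs_col))]
    attr(perms, "exhaustive") <- TRUE
    return(perms)
  }
  set.seed(seed)
  perms <- matrix(FALSE, n, n_permutations)
  perms[, 1] <- obs
  for (j in 2:n_permutations)
    perms[sample.int(n, nb), j] <- TRUE
  attr(perms, "exhaustive") <- FALSE
  perms
}

# d statistics for every column of an assignment matrix, vectorised:
# group means and pooled SS via two matrix products.
permutation_d <- function(v, perms, s0) {
  nb <- colSums(perms)
  na <- nrow(perms) - nb
  pb <- perms * 1
  pa <- (!perms) * 1
  sum_b <- v %*% pb
  sum_a <- v %*% pa
  mb <- sweep(sum_b, 2, nb, "/")
  ma <- sweep(sum_a, 2, na, "/")
  tot_ss <- rowSums(v^2)
  ssw <- tot_ss - sweep(mb^2, 2, nb, "*") - sweep(ma^2, 2, na, "*")
  ssw[ssw < 0] <- 0  # guard against negative rounding residue
  fac <- (1 / na + 1 / nb) / (na + nb - 2)
  s <- sqrt(sweep(ssw, 2, fac, "*"))
  denom <- s + s0
  out <- (mb - ma)
  out[denom > 0] <- out[denom > 0] / denom[denom > 0]
  out[denom <= 0] <- 0  # zero-variance probes: d defined as 0
  out
}

#' Run the SAM two-class procedure with permutation FDR
#'
#' Full SAM pipeline for one contrast: fudge factor selection, observed d,
#' permutation null (exhaustive over all distinct label assignments when
#' fewer than `n_permutations` exist, otherwise a seeded random sample),
#' pooled permutation p-values (add-one smoothed), and per-probe q-values by
#' delta-thresholding of observed against expected null order statistics.
#' The false discovery rate at a delta is pi0 times the median (or 90th
#' percentile) permutation call count over the observed call count.
#'
#' @param x An [expression_matrix()].
#' @param group_a,group_b Sample id vectors; d and fold change are B vs A.
#' @param n_permutations Requested permutations (default 1000).
#' @param seed Integer seed (mandatory).
#' @param fdr_method "median" (default) or "p90" null call summary.
#' @param s0 Optional fixed fudge factor; by default chosen by
#'   [select_s0()].
#' @param n_deltas Size of the delta grid for q-value computation.
#' @param contrast Optional contrast label carried into results.
#' @return An object of class `sam_result`: data.frame `table` (probe, gene,
#'   d, s, fold_change, p, q), plus s0, permutation count, exhaustive flag,
#'   pi0 and seed.
#' @export
run_sam <- function(x, group_a, group_b, n_permutations = 1000, seed,
                    fdr_method = c("median", "p90"), s0 = NULL,
                    n_deltas = 100, contrast = NA_character_) {
  stopifnot(inherits(x, "expression_matrix"))
  if (missing(seed)) stop("`seed` is mandatory")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  fdr_method <- match.arg(fdr_method)
  v <- x$values[, c(group_a, group_b), drop = FALSE]
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("need >= 2 samples per group")
  if (choose(na + nb, nb) < 10)
    message("fewer than 10 distinct permutations; enumerating all of them")

  if (is.null(s0)) s0 <- as.numeric(select_s0(x, group_a, group_b))
  obs <- sam_d_statistics(x, group_a, group_b, s0 = s0)
  d_obs <- obs$d
  m <- length(d_obs)

  perms <- permutation_assignments(na, nb, n_permutations, seed)
  d_null <- permutation_d(v, perms[, -1, drop = FALSE], s0)
  n_perm <- ncol(d_null)

  # pooled permutation p, add-one smoothed
  null_abs_sorted <- sort(abs(as.vector(d_null)))
  n_null <- length(null_abs_sorted)
  ge <- n_null - findInterval(abs(d_obs) - 1e-12, null_abs_sorted)
  p <- (1 + ge) / (1 + n_null)

  # expected null order statistics
  d_sorted <- sort(d_obs)
  ord <- order(d_obs)
  null_sorted_cols <- apply(d_null, 2, sort)
  dbar <- rowMeans(null_sorted_cols)

  # pi0 from the central null quartiles (1 when the null is degenerate)
  qn <- stats::quantile(as.vector(d_null), c(0.25, 0.75), names = FALSE)
  pi0 <- if (qn[2] > qn[1])
    min(1, sum(d_obs > qn[1] & d_obs < qn[2]) / (0.5 * m)) else 1

  # delta grid over the observed deviations from the null expectation:
  # quantiles give resolution in the bulk, the uniform component in the
  # tail where the interesting cutoffs live
  dev <- abs(d_sorted - dbar)
  deltas <- if (any(dev > 0)) sort(unique(c(
    stats::quantile(dev[dev > 0],
                    probs = seq(0, 1, length.out = n_deltas),
                    names = FALSE),
    seq(0, max(dev), length.out = n_deltas)))) else 0

  origin <- which.min(abs(dbar))  # index where the null expectation ~ 0
  cutup <- vapply(deltas, function(delta) {
    i <- which(d_sorted[origin:m] - dbar[origin:m] >= delta)
    if (length(i)) d_sorted[origin + i[1] - 1] else Inf
  }, numeric(1))
  cutlow <- vapply(deltas, function(delta) {
    i <- which(dbar[1:origin] - d_sorted[1:origin] >= delta)
    if (length(i)) d_sorted[max(i)] else -Inf
  }, numeric(1))
  # enforce monotone cutoffs (feasible sets shrink as delta grows)
  cutup <- cummax(cutup)
  cutlow <- cummin(cutlow)

  n_called <- vapply(seq_along(deltas), function(k)
    sum(d_obs >= cutup[k]) + sum(d_obs <= cutlow[k]), numeric(1))
  # per-permutation null call counts via binary search on sorted columns
  null_counts <- matrix(0, length(deltas), n_perm)
  for (j in seq_len(n_perm)) {
    colj <- null_sorted_cols[, j]
    up <- m - findInterval(cutup - 1e-12, colj)
    lo <- findInterval(cutlow + 1e-12, colj)
    null_counts[, j] <- up + lo
  }
  null_summary <- if (fdr_method == "median")
    apply(null_counts, 1, stats::median)
  else apply(null_counts, 1, stats::quantile, probs = 0.9, names = FALSE)
  # add-one smoothing (as for the permutation p) keeps the estimate away
  # from a degenerate 0 when the median null count vanishes in the far tail
  fdr <- pmin(1, pi0 * (1 + null_summary) / (1 + n_called))
  cm_fdr <- cummin(fdr)  # best FDR achievable within a delta prefix

  # q per probe: min FDR over deltas at which the probe is called; the
  # called deltas form a prefix of the ascending grid
  q <- rep(1, m)
  pos <- d_obs > 0
  # probe called at delta k iff d >= cutup[k]; cutup ascending, so the
  # largest such k is the count of cutoffs <= d
  kmax_pos <- findInterval(d_obs[pos], cutup)
  q[pos][kmax_pos > 0] <- cm_fdr[kmax_pos[kmax_pos > 0]]
  neg <- d_obs < 0
  kmax_neg <- findInterval(-d_obs[neg], sort(-cutlow))  # cutlow descending
  q[neg][kmax_neg > 0] <- cm_fdr[kmax_neg[kmax_neg > 0]]

  fc <- signed_fold_change(x, group_a, group_b)
  tab <- data.frame(probe = rownames(x$values),
                    gene = unname(x$probe_to_gene),
                    d = d_obs, s = obs$s, fold_change = fc,
                    p = p, q = q, stringsAsFactors = FALSE)
  structure(list(table = tab, s0 = s0, n_permutations = n_perm,
                 exhaustive = attr(perms, "exhaustive"), pi0 = pi0,
                 seed = seed, contrast = contrast,
                 deltas = deltas, fdr_at_delta = fdr,
                 cutup = cutup, cutlow = cutlow),
            class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf(paste0("sam_result (%s): %d probes, s0 = %.4g, %d %s",
                     " permutations, pi0 = %.3f\n"),
              ifelse(is.na(x$contrast), "unnamed", x$contrast),
              nrow(x$table), x$s0, x$n_permutations,
              if (isTRUE(x$exhaustive)) "exhaustive" else "sampled",
              x$pi0))
  cat(sprintf("  q < 0.05: %d probes; q < 0.05 & p < 0.01: %d probes\n",
              sum(x$table$q < 0.05),
              sum(x$table$q < 0.05 & x$table$p < 0.01)))
  invisible(x)
}

#' Per-probe multi-factor fixed-effects ANOVA
#'
#' Fits, per probe, the additive linear model over the requested metadata
#' factors and reports a marginal (drop-one) F-test p-value per factor.
#' Benjamini-Hochberg adjusted q-values per factor are included; gating the
#' disease factor at q < 0.10 reproduces an "ANOVA FDR10"-style gene list.
#'
#' @param x An [expression_matrix()].
#' @param meta A [sample_metadata()].
#' @param factors Character subset of c("disease", "gender", "batch").
#' @return List with matrices `p` and `q` (probes x factors).
#' @export
anova_per_gene <- function(x, meta,
                           factors = c("disease", "gender", "batch")) {
  stopifnot(inherits(x, "expression_matrix"))
  check_samples_match(x, meta)
  meta <- meta[match(colnames(x$values), meta$sample_id), ]
  factors <- match.arg(factors, c("disease", "gender", "batch"),
                       several.ok = TRUE)
  df <- data.frame(lapply(meta[factors], factor))
  keep <- vapply(df, function(f) nlevels(f) > 1, logical(1))
  if (!all(keep))
    stop("factor(s) with a single level: ",
         paste(factors[!keep], collapse = ", "))
  full <- stats::model.matrix(
    stats::as.formula(paste("~", paste(factors, collapse = " + "))), df)
  qr_full <- qr(full)
  if (qr_full$rank < ncol(full)) {
    ali <- colnames(full)[qr_full$pivot[-seq_len(qr_full$rank)]]
    stop("aliased model terms (rank-deficient design): ",
         paste(ali, collapse = ", "))
  }
  y <- t(x$values)  # samples x probes
  rss_full <- colSums(qr.resid(qr_full, y)^2)
  df_res <- nrow(full) - qr_full$rank
  if (df_res < 1) stop("no residual degrees of freedom")
  p_mat <- q_mat <- matrix(NA_real_, nrow(x$values), length(factors),
                           dimnames = list(rownames(x$values), factors))
  assign_idx <- attr(full, "assign")
  for (k in seq_along(factors)) {
    red <- full[, assign_idx != k, drop = FALSE]
    qr_red <- qr(red)
    df_f <- qr_full$rank - qr_red$rank
    rss_red <- colSums(qr.resid(qr_red, y)^2)
    fstat <- ((rss_red - rss_full) / df_f) / (rss_full / df_res)
    p_mat[, k] <- stats::pf(fstat, df_f, df_res, lower.tail = FALSE)
    q_mat[, k] <- stats::p.adjust(p_mat[, k], method = "BH")
  }
  list(p = p_mat, q = q_mat, df_residual = df_res)
}

#' Signed fold change between two groups
#'
#' Group means are taken on the linear scale (2^log2 values); the ratio
#' r = mean_B / mean_A is reported as +r when r >= 1 and as -1/r when
#' r < 1, so |FC| >= 1 always and a 2-fold drop prints as -2. Antisymmetric
#' under group swap.
#'
#' @param x An [expression_matrix()] or plain log2 matrix.
#' @param group_a,group_b Sample id vectors.
#' @return Named numeric vector of signed fold changes, one per probe.
#' @export
signed_fold_change <- function(x, group_a, group_b) {
  v <- if (inherits(x, "expression_matrix")) x$values else x
  ma <- rowMeans(2^v[, group_a, drop = FALSE])
  mb <- rowMeans(2^v[, group_b, drop = FALSE])
  if (any(ma <= 0) || any(mb <= 0))
    stop("internal error: nonpositive linear group mean")
  r <- mb / ma
  ifelse(r >= 1, r, -1 / r)
}

#' Filter a SAM result into a significance-gated gene list
#'
#' The stringent gate keeps probes with q < 0.05 (FDR < 5%) and permutation
#' p < 0.01; the relaxed gate uses p < 0.05 with the same q gate. Entries
#' are sorted by gene symbol then probe id.
#'
#' @param sam A `sam_result` from [run_sam()].
#' @param stringency "stringent" or "relaxed".
#' @param q_threshold FDR gate (default 0.05).
#' @return A data.frame of class `gene_list` with columns probe, gene,
#'   fold_change, q, p and attributes `contrast` and `stringency`. May be
#'   empty.
#' @export
build_contrast_list <- function(sam, stringency = c("stringent", "relaxed"),
                                q_threshold = 0.05) {
  stopifnot(inherits(sam, "sam_result"))
  stringency <- match.arg(stringency)
  p_threshold <- if (stringency == "stringent") 0.01 else 0.05
  tab <- sam$table
  keep <- tab$q < q_threshold & tab$p < p_threshold
  out <- tab[keep, c("probe", "gene", "fold_change", "q", "p")]
  out <- out[order(out$gene, out$probe), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "contrast") <- sam$contrast
  attr(out, "stringency") <- stringency
  class(out) <- c("gene_list", "data.frame")
  out
}

#' Write a gene list to TSV
#' @param gl A `gene_list`.
#' @param path Output path.
#' @export
write_gene_list_tsv <- function(gl, path) {
  out <- as.data.frame(gl)
  out$contrast <- rep(attr(gl, "contrast"), nrow(out))
  out$stringency <- rep(attr(gl, "stringency"), nrow(out))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene list written by [write_gene_list_tsv()]
#' @param path TSV path.
#' @return A `gene_list`.
#' @export
read_gene_list_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  out <- df[, c("probe", "gene", "fold_change", "q", "p")]
  attr(out, "contrast") <- df$contrast[1]
  attr(out, "stringency") <- df$stringency[1]
  class(out) <- c("gene_list", "data.frame")
  out
}
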