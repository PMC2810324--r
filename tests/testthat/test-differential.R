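two_group_x <- function(a, b, n_extra = 0, seed = 1) {
  # one probe with prescribed group values, plus optional random filler
  set.seed(seed)
  v <- rbind(c(a, b),
             if (n_extra > 0)
               matrix(rnorm(n_extra * (length(a) + length(b)), 7, 1),
                      n_extra))
  rownames(v) <- sprintf("p%03d", seq_len(nrow(v)))
  colnames(v) <- c(sprintf("a%d", seq_along(a)),
                   sprintf("b%d", seq_along(b)))
  expression_matrix(v, stats::setNames(sprintf("g%03d", seq_len(nrow(v))),
                                       rownames(v)))
}

test_that("d equals the pooled t statistic at s0 = 0", {
  x <- two_group_x(c(1, 2, 3), c(3, 4, 5))
  ds <- sam_d_statistics(x, paste0("a", 1:3), paste0("b", 1:3), s0 = 0)
  # hand calculation: diff 2, pooled var 1, s = sqrt(1/3 + 1/3)
  expect_equal(ds$d[1], 2 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(ds$d[1], 3), 2.449)
  # agreement with t.test's pooled-variance statistic
  tt <- t.test(c(3, 4, 5), c(1, 2, 3), var.equal = TRUE)
  expect_equal(ds$d[1], unname(tt$statistic), tolerance = 1e-12)
})

test_that("d is antisymmetric, shift-invariant and s0-monotone", {
  x <- tiny_expression(80, 10, seed = 2)
  a <- sprintf("s%02d", 1:5); b <- sprintf("s%02d", 6:10)
  d1 <- sam_d_statistics(x, a, b, s0 = 0.1)
  d2 <- sam_d_statistics(x, b, a, s0 = 0.1)
  expect_equal(d1$d, -d2$d, tolerance = 1e-12)
  # adding one constant to every value leaves d unchanged
  xc <- expression_matrix(x$values + 3.21, x$probe_to_gene)
  expect_equal(sam_d_statistics(xc, a, b, s0 = 0.1)$d, d1$d,
               tolerance = 1e-10)
  # increasing s0 weakly shrinks |d|
  d3 <- sam_d_statistics(x, a, b, s0 = 0.5)
  expect_true(all(abs(d3$d) <= abs(d1$d) + 1e-12))
  # zero-variance probe with s0 = 0 is defined and flagged
  v <- x$values; v[1, ] <- 5
  x0 <- expression_matrix(v, x$probe_to_gene)
  ds0 <- sam_d_statistics(x0, a, b, s0 = 0)
  expect_equal(ds0$d[1], 0)
  expect_true(ds0$zero_variance[1])
})

test_that("identical group means give d = 0", {
  x <- two_group_x(c(1, 2, 3), c(3, 2, 1))
  expect_equal(sam_d_statistics(x, paste0("a", 1:3), paste0("b", 1:3),
                                s0 = 0)$d[1], 0)
})

test_that("select_s0 is order-invariant and sane on degenerate input", {
  x <- tiny_expression(300, 10, seed = 3)
  a <- sprintf("s%02d", 1:5); b <- sprintf("s%02d", 6:10)
  s0 <- select_s0(x, a, b)
  expect_gte(as.numeric(s0), 0)
  perm <- sample(nrow(x$values))
  xp <- expression_matrix(x$values[perm, ], x$probe_to_gene[perm])
  expect_equal(as.numeric(select_s0(xp, a, b)), as.numeric(s0))
  # all s equal: any percentile returns that s
  v <- matrix(rep(c(0, 1), 50), 25, 4, byrow = TRUE)
  dimnames(v) <- list(sprintf("p%02d", 1:25), sprintf("s%02d", 1:4))
  xe <- expression_matrix(v, stats::setNames(sprintf("g%02d", 1:25),
                                             rownames(v)))
  suppressWarnings(s0e <- select_s0(xe, c("s01", "s03"), c("s02", "s04")))
  expect_equal(as.numeric(s0e),
               sam_d_statistics(xe, c("s01", "s03"),
                                c("s02", "s04"), 0)$s[1])
  # CV criterion at the chosen percentile beats the extremes
  cv <- attr(select_s0(x, a, b, alphas = c(0, 0.5, 1)), "cv")
  cv_all <- attr(s0, "cv")
  expect_lte(min(cv_all), min(cv) + 1e-12)
})

test_that("signed fold change follows the +r / -1/r convention", {
  v <- matrix(log2(c(2, 2, 4, 4,    # ratio 2 -> +2
                     4, 4, 2, 2,    # ratio 0.5 -> -2
                     3, 3, 3, 3)),  # equal -> 1
              3, 4, byrow = TRUE)
  dimnames(v) <- list(paste0("p", 1:3), paste0("s", 1:4))
  x <- expression_matrix(v, stats::setNames(paste0("g", 1:3), rownames(v)))
  fc <- signed_fold_change(x, c("s1", "s2"), c("s3", "s4"))
  expect_equal(unname(fc), c(2, -2, 1), tolerance = 1e-12)
  swapped <- signed_fold_change(x, c("s3", "s4"), c("s1", "s2"))
  expect_equal(unname(swapped), c(-2, 2, 1), tolerance = 1e-12)
  expect_true(all(abs(fc) >= 1))
})

test_that("run_sam is deterministic, gated lists nest, empty list is valid", {
  x <- tiny_expression(200, 10, seed = 5)
  a <- sprintf("s%02d", 1:5); b <- sprintf("s%02d", 6:10)
  r1 <- run_sam(x, a, b, n_permutations = 100, seed = 42)
  r2 <- run_sam(x, a, b, n_permutations = 100, seed = 42)
  expect_identical(r1$table, r2$table)
  expect_true(all(r1$table$p >= 0 & r1$table$p <= 1))
  expect_true(all(r1$table$q >= 0 & r1$table$q <= 1))
  stringent <- build_contrast_list(r1, "stringent")
  relaxed <- build_contrast_list(r1, "relaxed")
  expect_true(all(stringent$probe %in% relaxed$probe))
  # constant matrix: nothing called
  v <- matrix(5, 50, 10, dimnames = list(sprintf("p%02d", 1:50),
                                         sprintf("s%02d", 1:10)))
  xc <- expression_matrix(v, stats::setNames(sprintf("g%02d", 1:50),
                                             rownames(v)))
  rc <- run_sam(xc, a, b, n_permutations = 50, seed = 1)
  gl <- build_contrast_list(rc, "stringent")
  expect_equal(nrow(gl), 0)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  expect_no_error(write_gene_list_tsv(gl, tmp))
  expect_error(run_sam(x, a, b, n_permutations = 0, seed = 1),
               "n_permutations")
})

test_that("fold-change filter on a gene list matches a brute-force filter", {
  x <- tiny_expression(200, 12, seed = 6)
  # plant some strong effects so the list is non-empty
  x$values[1:30, 7:12] <- x$values[1:30, 7:12] + 2
  a <- sprintf("s%02d", 1:6); b <- sprintf("s%02d", 7:12)
  r <- run_sam(x, a, b, n_permutations = 200, seed = 9)
  gl <- build_contrast_list(r, "relaxed")
  expect_gt(nrow(gl), 0)
  n_strong <- sum(abs(gl$fold_change) > 1.5)
  expect_equal(n_strong, nrow(gl[abs(gl$fold_change) > 1.5, ]))
  # entries sorted by gene then probe
  expect_false(is.unsorted(gl$gene))
})

test_that("per-gene ANOVA matches the F = t^2 identity and null is uniform", {
  x <- tiny_expression(400, 12, seed = 7)
  meta <- sample_metadata(sprintf("s%02d", 1:12),
                          gender = rep(c("male", "female"), 6),
                          disease = rep(c("control", "PD"), each = 6),
                          batch = rep("b1", 12))
  res <- anova_per_gene(x, meta, factors = "disease")
  ds <- sam_d_statistics(x, sprintf("s%02d", 1:6), sprintf("s%02d", 7:12),
                         s0 = 0)
  f_from_t <- ds$d^2
  f_p <- stats::pf(f_from_t, 1, 10, lower.tail = FALSE)
  expect_equal(unname(res$p[, "disease"]), f_p, tolerance = 1e-8)
  # disease-only signal leaves the gender factor null
  x2 <- tiny_expression(2000, 12, seed = 8)
  x2$values[1:100, 7:12] <- x2$values[1:100, 7:12] + 2
  res2 <- anova_per_gene(x2, meta, factors = c("disease", "gender"))
  expect_gt(stats::ks.test(res2$p[, "gender"], "punif")$p.value, 0.01)
  expect_lt(stats::ks.test(res2$p[, "disease"], "punif")$p.value, 0.01)
  # rank deficiency reported
  meta_conf <- sample_metadata(sprintf("s%02d", 1:12),
                               gender = rep(c("male", "female"), 6),
                               disease = rep(c("control", "PD"), each = 6),
                               batch = rep(c("b1", "b2"), each = 6))
  expect_error(anova_per_gene(x, meta_conf,
                              factors = c("disease", "batch")),
               "aliased")
})

test_that("permutation machinery is exhaustive for small groups", {
  x <- tiny_expression(50, 6, seed = 10)
  a <- sprintf("s%02d", 1:3); b <- sprintf("s%02d", 4:6)
  r <- run_sam(x, a, b, n_permutations = 1000, seed = 1)
  expect_true(r$exhaustive)
  expect_equal(r$n_permutations, choose(6, 3) - 1)
  # below 10 distinct permutations a notice is logged
  x4 <- tiny_expression(50, 4, seed = 10)
  expect_message(
    r4 <- run_sam(x4, sprintf("s%02d", 1:2), sprintf("s%02d", 3:4),
                  n_permutations = 1000, seed = 1),
    "enumerating")
  expect_equal(r4$n_permutations, choose(4, 2) - 1)
})
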