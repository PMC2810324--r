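test_that("probe collapsing averages in ratio space", {
  # the multi-probe worked example: 2.1-fold down + 1.3-fold up -> -1.13
  expect_equal(round(collapse_probes(c(-2.1, 1.3)), 2), -1.13)
  # hand arithmetic: ratios (2, 0.5), mean 1.25 -> +1.25
  expect_equal(collapse_probes(c(2, -2)), 1.25, tolerance = 1e-12)
  # singleton identity, permutation invariance, errors
  expect_equal(collapse_probes(-3.7), -3.7)
  expect_equal(collapse_probes(c(1.3, -2.1)), collapse_probes(c(-2.1, 1.3)))
  expect_error(collapse_probes(numeric(0)), "no probe")
  expect_error(collapse_probes(c(0.5, 2)), "FC")
})

test_that("merged matrix round-trips membership exactly", {
  lists <- lapply(random_gene_lists(4, pool_size = 50, seed = 2),
                  function(l) l[!duplicated(l$gene), ])
  m <- build_merged_matrix(lists)
  expect_true(all(rowSums(m != 0) >= 1))   # no all-zero rows
  expect_true(all(abs(m[m != 0]) >= 1))
  back <- merged_matrix_to_lists(m)
  for (nm in names(lists)) {
    orig <- lists[[nm]][order(lists[[nm]]$gene), ]
    rec <- back[[nm]][order(back[[nm]]$gene), ]
    expect_equal(rec$gene, orig$gene)
    expect_equal(rec$fold_change, orig$fold_change)
  }
  m2 <- build_merged_matrix(back)
  expect_equal(m2[rownames(m), colnames(m)], m[, ],
               ignore_attr = TRUE)
  # duplicate gene rows in one list are rejected
  bad <- lists
  bad$L1 <- rbind(bad$L1, bad$L1[1, ])
  expect_error(build_merged_matrix(bad), "duplicate")
})

test_that("a gene present in one list only gets zeros elsewhere", {
  lists <- list(fN_fPD = data.frame(gene = "ATP5G3", fold_change = -2.17),
                mN_mPD = data.frame(gene = "ATP5G3", fold_change = -2.94),
                mN_fN = data.frame(gene = "OTHER", fold_change = 2))
  m <- build_merged_matrix(lists)
  expect_equal(unname(m["ATP5G3", ]), c(-2.17, -2.94, 0))
  expect_false("ABSENT" %in% rownames(m))
})

test_that("overlap partition matches brute-force set algebra", {
  lists <- random_gene_lists(4, pool_size = 40, seed = 3)
  lists <- lapply(lists, function(l) l[!duplicated(l$gene), ])
  part <- partition_overlaps(lists)
  sets <- lapply(lists, `[[`, "gene")
  union_all <- unique(unlist(sets))
  # regions disjoint, counts sum to union
  expect_equal(sum(part$regions$count), length(union_all))
  all_genes <- unlist(strsplit(part$regions$genes, ",", fixed = TRUE))
  expect_equal(anyDuplicated(all_genes), 0)
  # every region equals the brute-force membership intersection
  for (i in seq_len(nrow(part$regions))) {
    members <- strsplit(part$regions$signature[i], "&", fixed = TRUE)[[1]]
    expected <- union_all
    for (nm in names(sets))
      expected <- if (nm %in% members) intersect(expected, sets[[nm]])
                  else setdiff(expected, sets[[nm]])
    expect_setequal(strsplit(part$regions$genes[i], ",")[[1]], expected)
  }
  # per-list identity: up + down = size
  expect_equal(part$per_list$n_up + part$per_list$n_down,
               part$per_list$size)
  # disjoint lists have no multi-list regions
  disj <- list(A = data.frame(gene = c("g1", "g2"), fold_change = c(2, -2)),
               B = data.frame(gene = c("g3", "g4"), fold_change = c(3, 2)))
  pd <- partition_overlaps(disj)
  expect_false(any(grepl("&", pd$regions$signature, fixed = TRUE)))
})

test_that("gender-status classification follows the two-stringency rule", {
  ms <- build_merged_matrix(list(
    mN_mPD = data.frame(gene = c("m1", "b1"), fold_change = c(2, 1.5)),
    fN_fPD = data.frame(gene = c("f1", "b1"), fold_change = c(-2, 1.2))))
  mr <- build_merged_matrix(list(
    mN_mPD = data.frame(gene = c("m1", "b1", "x1"),
                        fold_change = c(2, 1.5, 1.3)),
    fN_fPD = data.frame(gene = c("f1", "b1"), fold_change = c(-2, 1.2))))
  st <- classify_gender_status(ms, mr)
  get <- function(g) st$status[st$gene == g]
  expect_equal(get("m1"), "male-specific")
  expect_equal(get("f1"), "female-specific")
  expect_equal(get("b1"), "shared")
  expect_equal(get("x1"), "stringency-dependent")  # absent at stringent
  # partition property: counts sum to classified genes
  expect_equal(sum(table(st$status)), nrow(st))
})

test_that("merged matrix TSV round-trips", {
  lists <- random_gene_lists(3, seed = 4)
  lists <- lapply(lists, function(l) l[!duplicated(l$gene), ])
  m <- build_merged_matrix(lists)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_merged_matrix_tsv(m, tmp)
  back <- read_merged_matrix_tsv(tmp)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(m))
})
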