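test_that("default config reproduces the stratified study design", {
  st <- generate_expression_study(simulation_config(n_probes = 100,
                                                    n_genes = 90,
                                                    seed = 1))
  tab <- table(st$metadata$gender, st$metadata$disease)
  expect_equal(tab["female", "control"], 3)
  expect_equal(tab["female", "PD"], 3)
  expect_equal(tab["male", "control"], 6)
  expect_equal(tab["male", "PD"], 7)
  expect_setequal(st$metadata$sample_id, colnames(st$expression$values))
})

test_that("generation is deterministic given config + seed", {
  cfg <- simulation_config(n_probes = 200, n_genes = 150, seed = 99,
                           de_spec = data.frame(gene = "G00010",
                                                contrast = "shared",
                                                log2fc = 1))
  s1 <- generate_expression_study(cfg)
  s2 <- generate_expression_study(cfg)
  expect_identical(s1$expression$values, s2$expression$values)
  expect_identical(s1$truth_de, s2$truth_de)
})

test_that("config validation rejects bad worlds", {
  expect_error(simulation_config(n_probes = 100, n_genes = 90),
               "seed")
  expect_error(simulation_config(n_probes = 100, n_genes = 200, seed = 1))
  expect_error(
    generate_expression_study(simulation_config(
      n_probes = 50, n_genes = 50,
      group_sizes = c(female_control = 1, female_PD = 3,
                      male_control = 6, male_PD = 7), seed = 1)),
    "female_control")
  expect_error(simulation_config(
    n_probes = 50, n_genes = 50, seed = 1,
    de_spec = data.frame(gene = "G00001", contrast = "shared",
                         log2fc = Inf)), "finite")
})

test_that("planted effect is recovered by direct sample means", {
  # +1 log2 in male PD only: empirical mean difference within 3 SE of 1,
  # and within 4*s*sqrt(2/n) across most seeds (effect-recovery property)
  hits <- vapply(1:20, function(s) {
    cfg <- simulation_config(
      n_probes = 60, n_genes = 60, n_batches = 1, batch_shift_sd = 0,
      noise_sd = 0.35,
      de_spec = data.frame(gene = "G00005", contrast = "male-only",
                           log2fc = 1),
      seed = 1000 + s)
    st <- generate_expression_study(cfg)
    m <- st$metadata
    v <- st$expression$values["P00005_G00005", ]
    d <- mean(v[m$sample_id[m$gender == "male" & m$disease == "PD"]]) -
      mean(v[m$sample_id[m$gender == "male" & m$disease == "control"]])
    abs(d - 1) <= 4 * 0.35 * sqrt(2 / 6)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # female samples untouched
  cfg <- simulation_config(
    n_probes = 60, n_genes = 60, n_batches = 1, batch_shift_sd = 0,
    noise_sd = 0, de_spec = data.frame(gene = "G00005",
                                       contrast = "male-only", log2fc = 1),
    seed = 5)
  st <- generate_expression_study(cfg)
  m <- st$metadata
  v <- st$expression$values["P00005_G00005", ]
  expect_equal(mean(v[m$sample_id[m$gender == "female" & m$disease == "PD"]]),
               mean(v[m$sample_id[m$gender == "female" &
                                    m$disease == "control"]]))
})

test_that("null studies give uniform per-gene t p-values", {
  cfg <- simulation_config(n_probes = 5000, n_genes = 5000, n_batches = 1,
                           batch_shift_sd = 0, seed = 11)
  st <- generate_expression_study(cfg)
  gr <- contrast_groups(st$metadata, "mN_mPD")
  ds <- sam_d_statistics(st$expression, gr$group_a, gr$group_b, s0 = 0)
  df <- length(gr$group_a) + length(gr$group_b) - 2
  pvals <- 2 * stats::pt(-abs(ds$d), df)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("gene sets round-trip through GMT and respect size bounds", {
  cfg <- simulation_config(
    n_probes = 300, n_genes = 300, seed = 3,
    de_spec = data.frame(gene = sprintf("G%05d", 1:30),
                         contrast = "male-only", log2fc = 1.5),
    enriched_sets = data.frame(set_id = "MALE_PATHWAY",
                               de_fraction = 0.5))
  st <- generate_expression_study(cfg)
  coll <- generate_gene_sets(cfg, st, n_background = 10,
                             size_range = c(10, 25))
  sizes <- lengths(coll$sets)
  expect_true(all(sizes >= 10 & sizes <= 25))
  expect_equal(attr(coll, "truth_enriched"), "MALE_PATHWAY")
  # planted fraction realised
  expect_gte(length(intersect(coll$sets$MALE_PATHWAY, st$truth_de$gene)),
             round(0.5 * length(coll$sets$MALE_PATHWAY)))
  tmp <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, tmp)
  back <- read_gmt(tmp, universe = coll$universe)
  expect_identical(back$sets, coll$sets)
  # impossible enrichment request errors
  cfg2 <- simulation_config(
    n_probes = 300, n_genes = 300, seed = 3,
    de_spec = data.frame(gene = "G00001", contrast = "male-only",
                         log2fc = 1.5),
    enriched_sets = data.frame(set_id = "MALE_BIG", de_fraction = 1))
  st2 <- generate_expression_study(cfg2)
  expect_error(generate_gene_sets(cfg2, st2, size_range = c(20, 20)),
               "DE")
})

test_that("Ct tables follow the analytic Ct model", {
  cfg <- simulation_config(n_probes = 40, n_genes = 40, n_batches = 1,
                           batch_shift_sd = 0, noise_sd = 0,
                           de_spec = data.frame(gene = "G00002",
                                                contrast = "shared",
                                                log2fc = -1),
                           seed = 7)
  st <- generate_expression_study(cfg)
  ct <- generate_ct_table(st, genes = c("G00002", "G00003"),
                          reference_gene = "G00001", replicate_sd = 0,
                          seed = 8)
  # exactly 3 identical replicates per (gene, sample) at zero noise
  counts <- table(ct$gene, ct$sample)
  expect_true(all(counts == 3))
  spread <- tapply(ct$ct, list(ct$gene, ct$sample),
                   function(v) diff(range(v)))
  expect_true(all(spread == 0))
  # gene planted 2-fold lower in PD: mean Ct rises by 1 cycle
  m <- st$metadata
  ct2 <- ct[ct$gene == "G00002", ]
  mean_ct <- tapply(ct2$ct, ct2$sample, mean)
  d <- mean(mean_ct[m$sample_id[m$disease == "PD"]]) -
    mean(mean_ct[m$sample_id[m$disease == "control"]])
  expect_equal(d, 1, tolerance = 1e-10)
  expect_error(generate_ct_table(st, genes = "G00002",
                                 reference_gene = "NOPE", seed = 1),
               "reference gene")
})
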