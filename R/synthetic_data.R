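#' Configuration for the synthetic study generator
#'
#' The defaults emulate the stratified postmortem design that motivates this
#' package: 3 female controls, 3 female PD, 6 male controls and 7 male PD
#' samples of laser-microdissected nigral dopamine neurons, profiled on a
#' single-channel array on the log2 scale, with an additive processing-batch
#' effect. Differential expression is planted per gene as a log2 shift in the
#' PD samples of the targeted gender(s).
#'
#' @param n_probes Number of probes on the simulated array.
#' @param n_genes Number of distinct genes (<= n_probes; the surplus probes
#'   are assigned as extra probes of randomly chosen genes, sharing the gene
#'   effect plus an independent probe-level offset).
#' @param group_sizes Named integer vector with entries `female_control`,
#'   `female_PD`, `male_control`, `male_PD`.
#' @param n_batches Number of processing batches; samples are dealt to
#'   batches round-robin within each group so batch is not confounded with
#'   disease or gender.
#' @param batch_shift_sd SD (log2 units) of the per-batch, per-gene additive
#'   shift. 0 disables the batch effect.
#' @param noise_sd SD (log2 units) of i.i.d. Gaussian measurement noise.
#' @param baseline_mean,baseline_sd Per-gene baseline log2 expression is
#'   drawn from Normal(baseline_mean, baseline_sd); defaults 7 and 2 mimic
#'   the intensity spread of expression arrays.
#' @param probe_offset_sd SD of the fixed per-probe offset for multi-probe
#'   genes.
#' @param de_spec Data frame describing planted effects with columns `gene`
#'   (gene id), `contrast` (one of "male-only", "female-only", "shared"),
#'   `log2fc` (signed log2 effect applied to PD samples of the targeted
#'   gender(s)). NULL plants nothing.
#' @param enriched_sets Data frame with columns `set_id` and `de_fraction`
#'   describing gene sets that [generate_gene_sets()] should plant as
#'   enriched (that fraction of members drawn from planted DE genes). NULL
#'   plants none.
#' @param seed Integer seed; mandatory, there is no implicit randomness.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_probes = 2000,
                              n_genes = 1800,
                              group_sizes = c(female_control = 3,
                                              female_PD = 3,
                                              male_control = 6,
                                              male_PD = 7),
                              n_batches = 2,
                              batch_shift_sd = 0.5,
                              noise_sd = 0.35,
                              baseline_mean = 7,
                              baseline_sd = 2,
                              probe_offset_sd = 0.25,
                              de_spec = NULL,
                              enriched_sets = NULL,
                              seed) {
  if (missing(seed) || length(seed) != 1 || is.na(seed))
    stop("a scalar `seed` is mandatory")
  stopifnot(n_probes >= 1, n_genes >= 1, n_genes <= n_probes,
            n_batches >= 1, batch_shift_sd >= 0, noise_sd >= 0,
            baseline_sd >= 0, probe_offset_sd >= 0)
  required <- c("female_control", "female_PD", "male_control", "male_PD")
  if (!all(required %in% names(group_sizes)))
    stop("group_sizes must name: ", paste(required, collapse = ", "))
  group_sizes <- group_sizes[required]
  if (any(group_sizes < 1)) stop("all group sizes must be positive")
  if (!is.null(de_spec)) {
    stopifnot(is.data.frame(de_spec),
              all(c("gene", "contrast", "log2fc") %in% names(de_spec)))
    if (!all(de_spec$contrast %in% c("male-only", "female-only", "shared")))
      stop("de_spec contrast must be male-only, female-only or shared")
    if (!all(is.finite(de_spec$log2fc))) stop("effect sizes must be finite")
    if (anyDuplicated(de_spec$gene)) stop("duplicate genes in de_spec")
  }
  if (!is.null(enriched_sets)) {
    stopifnot(is.data.frame(enriched_sets),
              all(c("set_id", "de_fraction") %in% names(enriched_sets)),
              all(enriched_sets$de_fraction >= 0),
              all(enriched_sets$de_fraction <= 1))
  }
  structure(list(n_probes = as.integer(n_probes),
                 n_genes = as.integer(n_genes),
                 group_sizes = group_sizes,
                 n_batches = as.integer(n_batches),
                 batch_shift_sd = batch_shift_sd,
                 noise_sd = noise_sd,
                 baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 probe_offset_sd = probe_offset_sd,
                 de_spec = de_spec,
                 enriched_sets = enriched_sets,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic stratified expression study with known ground truth
#'
#' Log2 values are baseline + batch shift + planted effect + Gaussian noise.
#' The truth tables record exactly what was planted, so downstream SAM,
#' overlap-partition and gender-classification stages can be scored.
#'
#' @param config A [simulation_config()].
#' @return List of class `synthetic_study` with elements `expression`
#'   (an [expression_matrix()]), `metadata` (a [sample_metadata()]),
#'   `truth_de` (data frame gene/contrast/log2fc/direction) and
#'   `truth_enriched` (filled by [generate_gene_sets()]).
#' @export
generate_expression_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  gs <- config$group_sizes
  # any within-gender disease contrast needs >= 2 per cell
  for (cell in names(gs))
    if (gs[[cell]] < 2)
      stop("group ", cell, " has fewer than 2 samples; contrasts over it ",
           "are not estimable")
  set.seed(config$seed)

  grp <- data.frame(
    gender = rep(c("female", "female", "male", "male"), gs),
    disease = rep(c("control", "PD", "control", "PD"), gs),
    stringsAsFactors = FALSE)
  n_samples <- nrow(grp)
  sample_id <- sprintf("%s%s%02d",
                       ifelse(grp$gender == "male", "m", "f"),
                       ifelse(grp$disease == "PD", "PD", "C"),
                       stats::ave(seq_len(n_samples),
                                  paste(grp$gender, grp$disease),
                                  FUN = seq_along))
  # round-robin batches within each group: batch never confounded with class
  batch <- stats::ave(seq_len(n_samples), paste(grp$gender, grp$disease),
                      FUN = function(i)
                        ((seq_along(i) - 1) %% config$n_batches) + 1)
  meta <- sample_metadata(sample_id, grp$gender, grp$disease,
                          paste0("batch", batch))

  genes <- sprintf("G%05d", seq_len(config$n_genes))
  # first probe of every gene, then surplus probes on random genes
  probe_gene_idx <- c(seq_len(config$n_genes),
                      sample.int(config$n_genes,
                                 config$n_probes - config$n_genes,
                                 replace = TRUE))
  probe_ids <- sprintf("P%05d_%s", seq_len(config$n_probes),
                       genes[probe_gene_idx])
  probe_to_gene <- stats::setNames(genes[probe_gene_idx], probe_ids)

  baseline_gene <- stats::rnorm(config$n_genes, config$baseline_mean,
                                config$baseline_sd)
  probe_offset <- c(rep(0, config$n_genes),
                    stats::rnorm(config$n_probes - config$n_genes,
                                 0, config$probe_offset_sd))
  mu <- baseline_gene[probe_gene_idx] + probe_offset

  x <- matrix(mu, nrow = config$n_probes, ncol = n_samples)
  dimnames(x) <- list(probe_ids, sample_id)

  if (config$batch_shift_sd > 0 && config$n_batches > 1) {
    shift <- matrix(stats::rnorm(config$n_probes * config$n_batches,
                                 0, config$batch_shift_sd),
                    config$n_probes, config$n_batches)
    x <- x + shift[, batch]
  }

  truth <- data.frame(gene = character(), contrast = character(),
                      log2fc = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  if (!is.null(config$de_spec)) {
    bad <- setdiff(config$de_spec$gene, genes)
    if (length(bad))
      stop("de_spec genes absent from study: ", paste(bad, collapse = ", "))
    for (i in seq_len(nrow(config$de_spec))) {
      g <- config$de_spec$gene[i]
      eff <- config$de_spec$log2fc[i]
      tgt <- config$de_spec$contrast[i]
      rows <- which(probe_to_gene == g)
      cols <- switch(tgt,
        "male-only" = meta$gender == "male" & meta$disease == "PD",
        "female-only" = meta$gender == "female" & meta$disease == "PD",
        "shared" = meta$disease == "PD")
      x[rows, cols] <- x[rows, cols] + eff
    }
    truth <- data.frame(gene = config$de_spec$gene,
                        contrast = config$de_spec$contrast,
                        log2fc = config$de_spec$log2fc,
                        direction = ifelse(config$de_spec$log2fc >= 0,
                                           "up", "down"),
                        stringsAsFactors = FALSE)
  }

  if (config$noise_sd > 0)
    x <- x + matrix(stats::rnorm(length(x), 0, config$noise_sd),
                    nrow(x), ncol(x))

  structure(list(expression = expression_matrix(x, probe_to_gene),
                 metadata = meta,
                 truth_de = truth,
                 truth_enriched = character(),
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("synthetic_study: %d probes x %d samples, ",
                     "%d planted DE genes, seed %d\n"),
              nrow(x$expression$values), ncol(x$expression$values),
              nrow(x$truth_de), x$config$seed))
  invisible(x)
}

#' Generate a gene-set collection with planted enrichment
#'
#' Emulates the GO-BP/KEGG/BioCarta collections used for over-representation
#' testing. Sets named in `config$enriched_sets` draw the configured fraction
#' of their members from the planted DE genes of the study (per target
#' contrast when the set id carries a `male`/`female`/`shared` hint, else
#' from all DE genes); remaining members and background sets are uniform
#' draws from the study universe.
#'
#' @param config The [simulation_config()] used for the study.
#' @param study The matching `synthetic_study`.
#' @param n_background Number of unenriched background sets.
#' @param size_range Length-2 integer vector of allowed set sizes.
#' @return A `gene_set_collection` (see [gene_set_collection()]); the
#'   enriched set ids are also recorded in the return's `truth_enriched`
#'   attribute and should be copied into the study by the caller.
#' @export
generate_gene_sets <- function(config, study, n_background = 20,
                               size_range = c(15, 40)) {
  stopifnot(inherits(study, "synthetic_study"))
  set.seed(config$seed + 1L)
  universe <- sort(unique(study$expression$probe_to_gene))
  de_by_contrast <- split(study$truth_de$gene, study$truth_de$contrast)
  sets <- list()
  enriched_ids <- character()
  if (!is.null(config$enriched_sets)) {
    for (i in seq_len(nrow(config$enriched_sets))) {
      sid <- config$enriched_sets$set_id[i]
      frac <- config$enriched_sets$de_fraction[i]
      pool <- study$truth_de$gene
      sid_lc <- tolower(sid)
      hint <- if (grepl("female", sid_lc)) "female-only"
              else if (grepl("male", sid_lc)) "male-only"
              else if (grepl("shared", sid_lc)) "shared"
              else NA_character_
      if (!is.na(hint) && !is.null(de_by_contrast[[hint]]))
        pool <- de_by_contrast[[hint]]
      size <- sample(size_range[1]:size_range[2], 1)
      n_de <- round(frac * size)
      if (n_de > length(pool))
        stop("set ", sid, " requests ", n_de, " DE members but only ",
             length(pool), " planted DE genes are available")
      members <- c(sample(pool, n_de),
                   sample(setdiff(universe, pool), size - n_de))
      sets[[sid]] <- sort(members)
      enriched_ids <- c(enriched_ids, sid)
    }
  }
  for (j in seq_len(n_background)) {
    size <- sample(size_range[1]:size_range[2], 1)
    sets[[sprintf("BG_SET_%03d", j)]] <- sort(sample(universe, size))
  }
  coll <- gene_set_collection(sets,
                              descriptions = stats::setNames(
                                paste("synthetic set", names(sets)),
                                names(sets)),
                              universe = universe)
  attr(coll, "truth_enriched") <- enriched_ids
  coll
}

#' Generate a qPCR Ct table matching a synthetic study
#'
#' Models the cycle-threshold readout as Ct = c0 - log2(expression) + noise,
#' i.e. one cycle per 2-fold expression change, so that downstream 2^-DeltaCt
#' quantification recovers true expression ratios exactly in expectation.
#' Three replicates are emitted per gene per sample.
#'
#' @param study A `synthetic_study`.
#' @param genes Gene ids to assay.
#' @param reference_gene Endogenous-control gene id (assayed too).
#' @param replicate_sd Replicate noise SD in cycles.
#' @param seed Integer seed.
#' @param c0 Ct intercept (cycles at unit expression); default 30.
#' @param n_replicates Replicates per (gene, sample); default 3.
#' @return A `ct_table` (see [ct_table()]).
#' @export
generate_ct_table <- function(study, genes, reference_gene,
                              replicate_sd = 0.15, seed, c0 = 30,
                              n_replicates = 3) {
  stopifnot(inherits(study, "synthetic_study"))
  if (missing(seed)) stop("`seed` is mandatory")
  all_genes <- unique(study$expression$probe_to_gene)
  if (!reference_gene %in% all_genes)
    stop("reference gene ", reference_gene, " absent from study")
  missing_g <- setdiff(genes, all_genes)
  if (length(missing_g))
    stop("genes absent from study: ", paste(missing_g, collapse = ", "))
  set.seed(seed)
  assay <- unique(c(genes, reference_gene))
  samples <- colnames(study$expression$values)
  # gene-level log2 expression: mean over the gene's probes
  gmap <- study$expression$probe_to_gene
  rows <- lapply(assay, function(g) which(gmap == g))
  long <- do.call(rbind, lapply(seq_along(assay), function(i) {
    log2e <- colMeans(study$expression$values[rows[[i]], , drop = FALSE])
    data.frame(gene = assay[i],
               sample = rep(samples, each = n_replicates),
               replicate = rep(seq_len(n_replicates), length(samples)),
               ct = c0 - rep(log2e, each = n_replicates) +
                 stats::rnorm(length(samples) * n_replicates,
                              0, replicate_sd),
               stringsAsFactors = FALSE)
  }))
  ct_table(long, reference_gene = reference_gene,
           n_replicates = n_replicates)
}

#' Write a synthetic study to a directory of plain-text files
#'
#' Emits expression TSV, metadata TSV and the DE truth table; [write_gmt()]
#' covers the gene sets and [write_ct_tsv()] the Ct tables.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(study$expression, file.path(dir, "expression.tsv"))
  write_metadata_tsv(study$metadata, file.path(dir, "metadata.tsv"))
  utils::write.table(study$truth_de, file.path(dir, "truth_de.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
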