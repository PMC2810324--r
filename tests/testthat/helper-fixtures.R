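# Shared fixture builders. Everything is generated in code or read from the
# small plain-text tables under inst/extdata.

extdata <- function(name) system.file("extdata", name, package = "stratade")

# Curated key-gene table: gene + five signed fold-change columns
# (all/male/female at stringent p<0.01 and relaxed p<0.05; 0 = absent).
read_key_gene_fixture <- function() {
  utils::read.table(extdata("pd_key_genes.tsv"), sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

# Merged matrices (stringent, relaxed) from the key-gene fixture columns.
key_gene_matrices <- function() {
  kg <- read_key_gene_fixture()
  as_list <- function(col) {
    keep <- kg[[col]] != 0
    data.frame(gene = kg$gene[keep], fold_change = kg[[col]][keep],
               stringsAsFactors = FALSE)
  }
  list(
    stringent = build_merged_matrix(list(
      allN_allPD = as_list("fc_all_p01"),
      mN_mPD = as_list("fc_male_p01"),
      fN_fPD = as_list("fc_female_p01"))),
    relaxed = build_merged_matrix(list(
      allN_allPD = as_list("fc_all_p01"),
      mN_mPD = as_list("fc_male_p05"),
      fN_fPD = as_list("fc_female_p05"))))
}

# Small deterministic expression container for unit tests.
tiny_expression <- function(n_probes = 50, n_samples = 8, seed = 1,
                            genes_per_probe = NULL) {
  set.seed(seed)
  v <- matrix(stats::rnorm(n_probes * n_samples, 7, 1), n_probes, n_samples)
  rownames(v) <- sprintf("p%03d", seq_len(n_probes))
  colnames(v) <- sprintf("s%02d", seq_len(n_samples))
  genes <- if (is.null(genes_per_probe)) sprintf("g%03d", seq_len(n_probes))
           else genes_per_probe
  expression_matrix(v, stats::setNames(genes, rownames(v)))
}

# Random gene-level lists (gene + fold_change) for set-algebra oracles.
random_gene_lists <- function(n_lists = 4, pool_size = 60, seed = 1) {
  set.seed(seed)
  pool <- sprintf("g%03d", seq_len(pool_size))
  out <- lapply(seq_len(n_lists), function(i) {
    genes <- sample(pool, sample(10:30, 1))
    fc <- sample(c(-1, 1), length(genes), replace = TRUE) *
      stats::runif(length(genes), 1, 5)
    data.frame(gene = genes, fold_change = fc, stringsAsFactors = FALSE)
  })
  stats::setNames(out, paste0("L", seq_len(n_lists)))
}

# Exhaustive hypergeometric upper tail by enumerating every size-n draw
# from an N-element universe (independent oracle for fisher_enrichment_p).
enumerate_upper_tail <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  in_set <- seq_len(K)  # wlog the set is the first K elements
  hits <- apply(draws, 2, function(d) sum(d %in% in_set))
  mean(hits >= k)
}
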