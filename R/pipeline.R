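#' Run the gender-stratified differential-expression pipeline
#'
#' Orchestrates the core path: optional batch removal, SAM over the
#' requested contrasts, gating at both stringencies, probe collapsing,
#' merged matrices and cross-stringency gender classification.
#'
#' @param x An [expression_matrix()].
#' @param meta A [sample_metadata()].
#' @param contrasts Contrast names to run (default the SAM-estimable four:
#'   allN_allPD, mN_mPD, fN_fPD, mN_fN, mPD_fPD minus any with groups of
#'   size < 2).
#' @param n_permutations,seed Passed to [run_sam()].
#' @param remove_batch Remove batch effects first (default TRUE when more
#'   than one batch is present).
#' @return List of class `gender_analysis`: `sam` (per contrast),
#'   `lists` (per contrast and stringency, probe level), `merged`
#'   (per stringency, gene level) and `gender_status`.
#' @export
run_gender_analysis <- function(x, meta,
                                contrasts = c("allN_allPD", "mN_mPD",
                                              "fN_fPD", "mN_fN",
                                              "mPD_fPD"),
                                n_permutations = 1000, seed,
                                remove_batch = NULL) {
  if (missing(seed)) stop("`seed` is mandatory")
  check_samples_match(x, meta)
  if (is.null(remove_batch))
    remove_batch <- length(unique(meta$batch)) > 1
  if (remove_batch) x <- remove_batch_effect(x, meta)

  sams <- list()
  for (ct in contrasts) {
    gr <- contrast_groups(meta, ct)
    if (length(gr$group_a) < 2 || length(gr$group_b) < 2) {
      message("skipping ", ct, ": a group has fewer than 2 samples")
      next
    }
    sams[[ct]] <- run_sam(x, gr$group_a, gr$group_b,
                          n_permutations = n_permutations,
                          seed = seed + match(ct, contrasts),
                          contrast = ct)
  }
  lists <- list()
  merged <- list()
  for (st in c("stringent", "relaxed")) {
    per_contrast <- lapply(sams, build_contrast_list, stringency = st)
    lists[[st]] <- per_contrast
    merged[[st]] <- build_merged_matrix(
      lapply(per_contrast, collapse_gene_list))
  }
  status <- NULL
  if (all(c("mN_mPD", "fN_fPD") %in% names(sams)))
    status <- classify_gender_status(merged$stringent, merged$relaxed)
  structure(list(sam = sams, lists = lists, merged = merged,
                 gender_status = status, seed = seed),
            class = "gender_analysis")
}

#' @export
print.gender_analysis <- function(x, ...) {
  cat("gender_analysis over contrasts:",
      paste(names(x$sam), collapse = ", "), "\n")
  for (st in names(x$lists))
    cat(sprintf("  %s: %s\n", st,
                paste(sprintf("%s=%d", names(x$lists[[st]]),
                              vapply(x$lists[[st]], nrow, integer(1))),
                      collapse = " ")))
  if (!is.null(x$gender_status))
    print(table(x$gender_status$status))
  invisible(x)
}
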