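#' Run the full dysregulation-network pipeline
#'
#' Chains the stages end to end: sample alignment, pairwise subtype
#' dysregulation analyses, cosine-similarity network construction,
#' hard-threshold pruning (fixed threshold from the config when given,
#' otherwise scale-free grid selection), Louvain module extraction, and a
#' one-vs-rest SGL logistic classifier of the stage labels using the
#' extracted modules as group structure (miRNAs outside any module enter as
#' singleton groups). A pure-L1 baseline (`alpha = 1`, no group structure)
#' is fitted on the same split for comparison. All randomness derives from
#' `config$seed`, so two runs with the same inputs and config are
#' identical.
#'
#' @param mirna,mrna [expr_matrix()] objects (processed scale).
#' @param design a `group_design`.
#' @param subtypes subtype labels for the dysregulation analyses (default
#'   all labeled subtypes with >= 4 samples).
#' @param config configuration list from [read_config()].
#' @param fit_l1_baseline also fit the `alpha = 1` ungrouped baseline
#'   (default `TRUE`).
#' @param known_set optional character vector of known marker miRNAs for
#'   precision/recall evaluation of the ranked candidates.
#' @param k_list top-k sizes for the biomarker evaluation.
#' @param test_fraction held-out fraction for the AUROC evaluation
#'   (default 0.2, stratified by stage).
#' @return an `mdsn_result` list: `assoc`, `network` (pruned), `threshold`,
#'   `partition`, `model`, `model_l1`, `auroc` (tibble with per-class
#'   AUROC by method), `biomarkers` (or `NULL`), `config`.
#' @export
mdsn_pipeline <- function(mirna, mrna, design, subtypes = NULL,
                          config = read_config(), fit_l1_baseline = TRUE,
                          known_set = NULL, k_list = c(10, 25, 50, 100),
                          test_fraction = 0.2) {
  al <- align_samples(mirna, mrna, design)
  assoc <- run_pairwise_analyses(al$mirna, al$mrna, al$design, subtypes,
                                 p_threshold = config$p_threshold,
                                 require_negative = config$require_negative)
  net <- build_similarity_network(assoc, beta = config$beta)
  if (!is.null(config$threshold)) {
    net$r2_by_threshold <- threshold_curve(net, config$threshold_grid)
    net$threshold <- config$threshold
  } else {
    net <- select_threshold(net, grid = config$threshold_grid, r2_min = config$r2_min)
  }
  threshold <- net$threshold
  pruned <- prune(net, threshold)
  partition <- louvain_modules(pruned, seed = config$seed)

  keep <- !is.na(al$design$stage)
  X <- t(al$mirna$values[, keep, drop = FALSE])
  labels <- droplevels(factor(al$design$stage[keep], ordered = FALSE))
  n_folds <- max(2L, as.integer(round(1 / test_fraction)))
  fold <- .stratified_folds(labels, n_folds, config$seed)
  test <- fold == 1L
  groups <- group_structure(colnames(X), partition)
  model <- fit_sgl_logistic(X[!test, , drop = FALSE], labels[!test], groups,
                            lambda = config$sgl_lambda, alpha = config$sgl_alpha)
  auroc_tbl <- roc_auc_per_class(model, X[test, , drop = FALSE], labels[test]) |>
    dplyr::mutate(method = "sgl_modules", .before = 1)
  model_l1 <- NULL
  if (fit_l1_baseline) {
    model_l1 <- fit_sgl_logistic(X[!test, , drop = FALSE], labels[!test],
                                 group_structure(colnames(X)),
                                 lambda = config$sgl_lambda, alpha = 1)
    auroc_tbl <- dplyr::bind_rows(
      auroc_tbl,
      roc_auc_per_class(model_l1, X[test, , drop = FALSE], labels[test]) |>
        dplyr::mutate(method = "l1", .before = 1)
    )
  }
  biomarkers <- if (!is.null(known_set)) {
    rank_and_evaluate_biomarkers(model, known_set, k_list)
  }
  structure(
    list(assoc = assoc, network = pruned, threshold = threshold,
         partition = partition, model = model, model_l1 = model_l1,
         auroc = auroc_tbl, biomarkers = biomarkers, config = config),
    class = "mdsn_result"
  )
}

#' @export
print.mdsn_result <- function(x, ...) {
  cat("<mdsn_result>\n")
  cat(sprintf("  dysregulations: %d across %d analyses\n",
              n_dysregulations(x$assoc), length(x$assoc$analysis_ids)))
  cat(sprintf("  network: threshold %g, %d non-isolated nodes\n",
              x$threshold, x$network$n_nonisolated))
  cat(sprintf("  modules: %d (modularity %.4f)\n",
              length(unique(x$partition$assignment)), x$partition$modularity))
  sgl <- x$auroc[x$auroc$method == "sgl_modules", ]
  cat(sprintf("  SGL macro-AUROC: %.3f\n", mean(sgl$auroc, na.rm = TRUE)))
  invisible(x)
}

#' Write the pipeline outputs to a directory
#'
#' Writes `modules.tsv`, `model.json`, `auroc.tsv`,
#' `threshold_curve.tsv` and, when present, `biomarkers.tsv`, all with
#' fixed numeric formatting (two runs of the same configuration produce
#' byte-identical files).
#'
#' @param result an `mdsn_result`.
#' @param dir output directory (created if missing).
#' @return character vector of the files written, invisibly.
#' @export
write_mdsn_results <- function(result, dir) {
  stopifnot(inherits(result, "mdsn_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    modules = file.path(dir, "modules.tsv"),
    model = file.path(dir, "model.json"),
    auroc = file.path(dir, "auroc.tsv"),
    curve = file.path(dir, "threshold_curve.tsv")
  )
  write_modules(result$partition, files["modules"])
  write_model_json(result$model, files["model"])
  readr::write_tsv(
    dplyr::mutate(result$auroc,
                  auroc = sprintf("%.10f", .data$auroc)),
    files["auroc"], progress = FALSE)
  curve <- result$network$r2_by_threshold
  if (!is.null(curve)) {
    readr::write_tsv(
      dplyr::mutate(curve, dplyr::across(dplyr::where(is.numeric),
                                         ~ sprintf("%.10g", .x))),
      files["curve"], progress = FALSE)
  }
  if (!is.null(result$biomarkers)) {
    files <- c(files, biomarkers = file.path(dir, "biomarkers.tsv"))
    readr::write_tsv(
      dplyr::mutate(result$biomarkers,
                    precision = sprintf("%.10f", .data$precision),
                    recall = sprintf("%.10f", .data$recall)),
      files["biomarkers"], progress = FALSE)
  }
  invisible(files)
}
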