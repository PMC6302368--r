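#' Simulate a sample-matched miRNA/mRNA cohort with planted dysregulation
#'
#' Generates paired miRNA and mRNA expression matrices on the standardized
#' (post-preprocessing) scale, a sample design with subtype and stage labels,
#' and the planted ground truth. Each planted module consists of a block of
#' miRNAs and a disjoint block of target mRNAs; within a subtype, every
#' (module miRNA, module target) pair has population Pearson correlation
#' `corr_scheme[module, subtype]`, realised through a shared latent Gaussian
#' factor per (module, sample): with loading `a = sqrt(|rho|)` on the miRNA
#' side and `sign(rho) * a` on the target side, the pair correlation is
#' exactly `rho` (this also induces within-module miRNA-miRNA correlation
#' `|rho|`, which the pipeline never uses). Background features are
#' independent standard normals, so background miRNA-target pairs have
#' population correlation 0.
#'
#' Stage labels come from an ordinal model on the per-sample mean expression
#' of the miRNAs in `relevant_modules`: a latent score
#' `effect_size * mean + logistic noise (scale noise_sd)` is cut at its
#' empirical quantiles into `stage_classes` ordered classes. With
#' `effect_size = 0` stages are independent of expression.
#'
#' @param n_mirna,n_mrna total numbers of miRNA and mRNA features (planted
#'   blocks included).
#' @param n_modules number of planted modules.
#' @param mirnas_per_module,targets_per_module sizes of each module's miRNA
#'   and target blocks; module target sets are disjoint.
#' @param subtype_sizes named integer vector of samples per subtype
#'   (each >= 4; the Fisher variance term needs n - 3 > 0).
#' @param corr_scheme numeric matrix (`n_modules` x number of subtypes) of
#'   target correlations in (-1, 1). Default: -0.8 for every module in the
#'   first subtype, 0 elsewhere — a repression pattern present in one
#'   subtype and absent in the others.
#' @param stage_classes number of ordered stage classes (default 5:
#'   normal, I-IV).
#' @param relevant_modules integer indices of modules whose miRNAs carry the
#'   stage signal.
#' @param effect_size coefficient of the relevant-module mean in the stage
#'   model (per standardized-expression unit).
#' @param noise_sd scale of the logistic noise in the stage model.
#' @param seed integer seed; output is bit-reproducible given the seed.
#' @return list with elements `mirna`, `mrna` ([expr_matrix()], processed
#'   scale), `design` (`group_design`), `truth` (`planted_structure`).
#' @export
simulate_cohort <- function(n_mirna = 100, n_mrna = 300, n_modules = 4,
                            mirnas_per_module = 10, targets_per_module = 15,
                            subtype_sizes = c(A = 60, B = 60),
                            corr_scheme = NULL,
                            stage_classes = 5, relevant_modules = 1L,
                            effect_size = 1, noise_sd = 1, seed = 1L) {
  stopifnot(n_mirna >= n_modules * mirnas_per_module,
            n_mrna >= n_modules * targets_per_module,
            all(subtype_sizes >= 4), length(subtype_sizes) >= 1,
            stage_classes >= 2)
  n_sub <- length(subtype_sizes)
  if (is.null(names(subtype_sizes))) names(subtype_sizes) <- LETTERS[seq_len(n_sub)]
  if (is.null(corr_scheme)) {
    corr_scheme <- matrix(0, n_modules, n_sub)
    corr_scheme[, 1] <- -0.8
  }
  corr_scheme <- as.matrix(corr_scheme)
  if (!all(dim(corr_scheme) == c(n_modules, n_sub))) {
    stop("`corr_scheme` must be n_modules x n_subtypes", call. = FALSE)
  }
  if (any(abs(corr_scheme) >= 1)) stop("correlations must satisfy |rho| < 1", call. = FALSE)
  dimnames(corr_scheme) <- list(paste0("M", seq_len(n_modules)), names(subtype_sizes))

  n <- sum(subtype_sizes)
  samp <- sprintf("S%03d", seq_len(n))
  subtype <- rep(names(subtype_sizes), subtype_sizes)
  mir_ids <- sprintf("mir_%03d", seq_len(n_mirna))
  mrna_ids <- sprintf("gene_%04d", seq_len(n_mrna))

  module_of <- rep(NA_integer_, n_mirna)
  names(module_of) <- mir_ids
  targets_of_module <- vector("list", n_modules)
  for (m in seq_len(n_modules)) {
    module_of[(m - 1) * mirnas_per_module + seq_len(mirnas_per_module)] <- m
    targets_of_module[[m]] <- mrna_ids[(m - 1) * targets_per_module +
                                         seq_len(targets_per_module)]
  }
  names(targets_of_module) <- rownames(corr_scheme)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  X <- matrix(stats::rnorm(n_mirna * n), n_mirna, n, dimnames = list(mir_ids, samp))
  Y <- matrix(stats::rnorm(n_mrna * n), n_mrna, n, dimnames = list(mrna_ids, samp))
  col0 <- 0L
  for (s in seq_len(n_sub)) {
    cols <- col0 + seq_len(subtype_sizes[s])
    for (m in seq_len(n_modules)) {
      rho <- corr_scheme[m, s]
      if (rho == 0) next
      a <- sqrt(abs(rho))
      f <- stats::rnorm(length(cols))
      mi <- which(module_of == m)
      tj <- match(targets_of_module[[m]], mrna_ids)
      # replace the independent draws with factor + residual, unit variance
      X[mi, cols] <- a * rep(f, each = length(mi)) +
        sqrt(1 - a^2) * stats::rnorm(length(mi) * length(cols))
      Y[tj, cols] <- sign(rho) * a * rep(f, each = length(tj)) +
        sqrt(1 - a^2) * stats::rnorm(length(tj) * length(cols))
    }
    col0 <- col0 + subtype_sizes[s]
  }

  rel_mirnas <- names(module_of)[module_of %in% relevant_modules]
  score <- if (length(rel_mirnas)) colMeans(X[rel_mirnas, , drop = FALSE]) else numeric(n)
  latent <- effect_size * score + stats::rlogis(n, scale = noise_sd)
  cuts <- stats::quantile(latent, probs = seq_len(stage_classes - 1) / stage_classes)
  stage_idx <- findInterval(latent, cuts) + 1L
  labels <- c("normal", "I", "II", "III", "IV", as.character(utils::as.roman(5:20)))
  label_order <- labels[seq_len(stage_classes)]
  design <- group_design(samp, subtype, label_order[stage_idx], label_order)

  truth <- structure(
    list(module_of = module_of,
         targets_of_module = targets_of_module,
         corr_by_subtype = corr_scheme,
         relevant_modules = as.integer(relevant_modules),
         effect_size = effect_size),
    class = "planted_structure"
  )
  list(mirna = expr_matrix(X, processed = TRUE),
       mrna = expr_matrix(Y, processed = TRUE),
       design = design,
       truth = truth)
}

#' @export
print.planted_structure <- function(x, ...) {
  cat(sprintf("<planted_structure> %d modules, %d planted miRNAs, effect size %.3g\n",
              length(x$targets_of_module), sum(!is.na(x$module_of)), x$effect_size))
  invisible(x)
}

#' Planted miRNA-target pairs
#'
#' Enumerates every (module miRNA, module target) pair of a planted
#' structure, one row per pair per subtype, with the planted correlation.
#'
#' @param truth a `planted_structure`.
#' @return tibble with columns `mirna_id`, `mrna_id`, `module`, `subtype`,
#'   `rho`.
#' @export
planted_pairs <- function(truth) {
  stopifnot(inherits(truth, "planted_structure"))
  mods <- seq_along(truth$targets_of_module)
  purrr::map_dfr(mods, function(m) {
    mir <- names(truth$module_of)[!is.na(truth$module_of) & truth$module_of == m]
    tidyr::expand_grid(mirna_id = mir, mrna_id = truth$targets_of_module[[m]]) |>
      tidyr::expand_grid(subtype = colnames(truth$corr_by_subtype)) |>
      dplyr::mutate(module = m, rho = truth$corr_by_subtype[m, .data$subtype]) |>
      dplyr::select("mirna_id", "mrna_id", "module", "subtype", "rho")
  })
}

#' Reference partition of the planted module miRNAs
#'
#' Restates the planted structure as a `module_partition` over the miRNAs
#' that belong to a module (background miRNAs are excluded), for use as the
#' ground truth in recovery comparisons.
#'
#' @param truth a `planted_structure`.
#' @return a `module_partition`.
#' @export
ground_truth_partition <- function(truth) {
  stopifnot(inherits(truth, "planted_structure"))
  keep <- !is.na(truth$module_of)
  new_module_partition(truth$module_of[keep], modularity = NA_real_,
                       levels = list(), seed = NA_integer_)
}

#' Map standardized expression back to a raw abundance scale
#'
#' Inverse of the preprocessing transform, `2^x - pseudocount` clipped at 0,
#' for producing raw-scale fixtures that exercise [preprocess_expression()].
#' The round trip is approximate: clipping and re-standardization of finite
#' samples do not reproduce the input exactly.
#'
#' @param m a processed [expr_matrix()].
#' @param pseudocount offset used by the forward transform.
#' @return an unprocessed [expr_matrix()] of non-negative values.
#' @export
as_raw_scale <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  expr_matrix(pmax(2^m$values - pseudocount, 0), processed = FALSE)
}
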