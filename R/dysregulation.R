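#' Fisher z-transformation of a correlation coefficient
#'
#' `z = 0.5 * log((1 + r) / (1 - r))`, an odd function of `r`. Correlations
#' are clipped to `|r| <= 1 - 1e-15` first so that numerically perfect
#' correlations do not map to infinity.
#'
#' @param r numeric vector of correlations in `[-1, 1]`.
#' @return numeric vector of z-values.
#' @export
fisher_z <- function(r) {
  r <- pmin(pmax(r, -(1 - 1e-15)), 1 - 1e-15)
  0.5 * log((1 + r) / (1 - r))
}

#' Sample Pearson correlation
#'
#' Thin validated wrapper around [stats::cor()]: equal lengths of at least
#' 2 are required and a constant vector raises a classed
#' `mdsn_constant_vector` error (in the pairwise scan such pairs are skipped
#' and counted rather than raised).
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop(structure(class = c("mdsn_constant_vector", "error", "condition"),
                   list(message = "correlation undefined for a constant vector",
                        call = sys.call(-1))))
  }
  stats::cor(x, y)
}

#' Test the difference of two correlations between sample groups
#'
#' Computes the Pearson correlations `r_A`, `r_B` of a miRNA-target pair in
#' two sample groups, Fisher-transforms them and forms
#' `z_AB = (z_A - z_B) / sqrt(1/(n_A - 3) + 1/(n_B - 3))`; the two-tailed
#' p-value is `2 * (1 - Phi(|z_AB|))`. The dysregulation score `dys` is the
#' raw correlation difference `r_A - r_B`.
#'
#' @param x_A,y_A expression of the miRNA and target in group A.
#' @param x_B,y_B expression of the miRNA and target in group B.
#' @return one-row tibble with `r_A`, `r_B`, `dys`, `z_AB`, `p_value`,
#'   `eligible` (negative correlation in at least one group).
#' @export
correlation_difference_test <- function(x_A, y_A, x_B, y_B) {
  n_A <- length(x_A); n_B <- length(x_B)
  if (n_A < 4 || n_B < 4) {
    stop("each group needs >= 4 samples (Fisher variance term uses n - 3)",
         call. = FALSE)
  }
  r_A <- pearson_correlation(x_A, y_A)
  r_B <- pearson_correlation(x_B, y_B)
  z <- (fisher_z(r_A) - fisher_z(r_B)) / sqrt(1 / (n_A - 3) + 1 / (n_B - 3))
  tibble::tibble(
    r_A = r_A, r_B = r_B, dys = r_A - r_B, z_AB = z,
    p_value = 2 * stats::pnorm(-abs(z)),
    eligible = r_A < 0 | r_B < 0
  )
}

#' Permutation test for a correlation difference
#'
#' Nonparametric oracle for [correlation_difference_test()]: pools the two
#' groups, re-splits them uniformly at random into groups of the original
#' sizes `n_perm` times and recomputes the absolute correlation difference
#' `|Dys| = |r_A - r_B|` each time. The p-value uses the add-one estimator
#' `p = (1 + #{|Dys_perm| >= |Dys_obs|}) / (1 + n_perm)`, which never
#' returns exactly zero.
#'
#' @inheritParams correlation_difference_test
#' @param n_perm number of random re-splits (>= 1).
#' @param seed integer seed; the returned p-value is reproducible.
#' @return permutation p-value in `(0, 1]`.
#' @export
permutation_difference_test <- function(x_A, y_A, x_B, y_B,
                                        n_perm = 10000, seed = 1L) {
  stopifnot(n_perm >= 1)
  n_A <- length(x_A); n_B <- length(x_B); n <- n_A + n_B
  x <- c(x_A, x_B); y <- c(y_A, y_B)
  obs <- abs(stats::cor(x_A, y_A) - stats::cor(x_B, y_B))

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  exceed <- 0L
  chunk <- 2000L
  done <- 0L
  while (done < n_perm) {
    b <- min(chunk, n_perm - done)
    idx <- replicate(b, sample.int(n))
    iA <- idx[seq_len(n_A), , drop = FALSE]
    iB <- idx[n_A + seq_len(n_B), , drop = FALSE]
    rA <- .col_cor(matrix(x[iA], n_A), matrix(y[iA], n_A))
    rB <- .col_cor(matrix(x[iB], n_B), matrix(y[iB], n_B))
    exceed <- exceed + sum(abs(rA - rB) >= obs, na.rm = TRUE)
    done <- done + b
  }
  (1 + exceed) / (1 + n_perm)
}

# column-wise Pearson correlation of two conformable matrices
.col_cor <- function(A, B) {
  n <- nrow(A)
  mA <- colMeans(A); mB <- colMeans(B)
  cov <- colMeans(A * B) - mA * mB
  vA <- colMeans(A * A) - mA^2
  vB <- colMeans(B * B) - mB^2
  cov / sqrt(vA * vB)
}

# correlation of every row of X (features x samples) with every row of Y,
# restricted to sample columns idx; returns list(r = feature_x x feature_y,
# const_x, const_y logical masks for zero-variance rows within the group)
.group_cor <- function(X, Y, idx) {
  Xs <- t(X[, idx, drop = FALSE])
  Ys <- t(Y[, idx, drop = FALSE])
  const_x <- apply(Xs, 2, stats::sd) == 0
  const_y <- apply(Ys, 2, stats::sd) == 0
  r <- suppressWarnings(stats::cor(Xs, Ys))
  list(r = r, const_x = const_x, const_y = const_y)
}

#' Per-pair dysregulation statistics for one subtype pair
#'
#' Full record table of the Fisher-z dysregulation analysis between two
#' sample groups: one row per (miRNA, mRNA) pair with both correlations,
#' the correlation difference, the z-statistic, the two-tailed p-value and
#' the inverse-correlation eligibility flag. Pairs involving a feature that
#' is constant within either group get `NA` statistics and are excluded
#' from significance.
#'
#' @param mirna,mrna processed, sample-aligned [expr_matrix()] objects.
#' @param design a `group_design` aligned with the matrices.
#' @param group_a,group_b subtype labels of the two groups.
#' @return tibble with columns `mirna_id`, `mrna_id`, `analysis_id`, `r_A`,
#'   `r_B`, `dys`, `z_AB`, `p_value`, `eligible`.
#' @export
dysregulation_table <- function(mirna, mrna, design, group_a, group_b) {
  idx_a <- which(design$subtype %in% group_a)
  idx_b <- which(design$subtype %in% group_b)
  if (length(idx_a) < 4 || length(idx_b) < 4) {
    stop("each subtype group needs >= 4 samples", call. = FALSE)
  }
  st <- .analysis_stats(mirna$values, mrna$values, idx_a, idx_b)
  aid <- paste(sort(c(group_a, group_b))[1], "vs", sort(c(group_a, group_b))[2], sep = "_")
  tibble::tibble(
    mirna_id = rep(rownames(mirna$values), times = nrow(mrna$values)),
    mrna_id = rep(rownames(mrna$values), each = nrow(mirna$values)),
    analysis_id = aid,
    r_A = as.vector(st$rA), r_B = as.vector(st$rB),
    dys = as.vector(st$rA - st$rB),
    z_AB = as.vector(st$z), p_value = as.vector(st$p),
    eligible = as.vector(st$eligible)
  )
}

# z / p / eligibility matrices for one pair of sample index sets
.analysis_stats <- function(X, Y, idx_a, idx_b) {
  ga <- .group_cor(X, Y, idx_a)
  gb <- .group_cor(X, Y, idx_b)
  n_a <- length(idx_a); n_b <- length(idx_b)
  z <- (fisher_z(ga$r) - fisher_z(gb$r)) / sqrt(1 / (n_a - 3) + 1 / (n_b - 3))
  p <- 2 * stats::pnorm(-abs(z))
  skip <- outer(ga$const_x | gb$const_x, ga$const_y | gb$const_y, `|`)
  z[skip] <- NA_real_; p[skip] <- NA_real_
  rA <- ga$r; rB <- gb$r
  rA[skip] <- NA_real_; rB[skip] <- NA_real_
  list(rA = rA, rB = rB, z = z, p = p,
       eligible = !skip & (rA < 0 | rB < 0), n_skipped = sum(skip))
}

#' Run all pairwise subtype dysregulation analyses
#'
#' For every unordered pair of the listed subtypes, tests every
#' (miRNA, mRNA) pair for a significant correlation change with the Fisher
#' z-test and assembles the binary association matrix `A`: entry 1 when the
#' p-value passes `p_threshold` and — when `require_negative` — the pair is
#' negatively correlated in at least one of the two groups (miRNAs repress
#' their targets, so inverse correlation is the prerequisite for a genuine
#' regulatory pair). Analysis blocks are concatenated column-wise in
#' lexicographic analysis order. Subtypes with fewer than 4 samples are
#' skipped with a warning and recorded.
#'
#' @param mirna,mrna processed, sample-aligned [expr_matrix()] objects.
#' @param design a `group_design` aligned with the matrices.
#' @param subtypes subtype labels to analyse; default all labeled subtypes.
#' @param p_threshold significance cut-off (default 0.001).
#' @param require_negative apply the inverse-correlation prerequisite
#'   (default `TRUE`).
#' @param p_adjust `"none"` (default, fixed threshold on raw p-values) or
#'   `"BH"` for Benjamini-Hochberg adjustment within each analysis.
#' @return an `assoc_matrix` object: binary matrix `A` (miRNAs x
#'   (target, analysis) columns), the column key, per-analysis counts and
#'   the excluded subtypes.
#' @export
run_pairwise_analyses <- function(mirna, mrna, design, subtypes = NULL,
                                  p_threshold = 0.001, require_negative = TRUE,
                                  p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(mirna, "expr_matrix"), inherits(mrna, "expr_matrix"))
  if (!identical(colnames(mirna$values), colnames(mrna$values)) ||
      !identical(colnames(mirna$values), design$sample_id)) {
    stop("matrices and design are not sample-aligned; call align_samples() first",
         call. = FALSE)
  }
  sizes <- subtype_sizes(design)
  if (is.null(subtypes)) subtypes <- sizes$subtype
  small <- subtypes[subtypes %in% sizes$subtype[sizes$n < 4] |
                      !(subtypes %in% sizes$subtype)]
  if (length(small)) {
    warning("excluding subtype(s) with < 4 samples: ", paste(small, collapse = ", "))
    subtypes <- setdiff(subtypes, small)
  }
  if (length(subtypes) < 2) stop("need >= 2 usable subtypes", call. = FALSE)
  subtypes <- sort(subtypes)
  pairs <- utils::combn(subtypes, 2, simplify = FALSE)
  aids <- vapply(pairs, function(p) paste(p[1], "vs", p[2], sep = "_"), "")
  ord <- order(aids)
  pairs <- pairs[ord]; aids <- aids[ord]

  # features flagged constant at preprocessing never enter the tests
  keep_mir <- setdiff(rownames(mirna$values), mirna$constant_features)
  keep_rna <- setdiff(rownames(mrna$values), mrna$constant_features)
  X <- mirna$values[keep_mir, , drop = FALSE]
  Y <- mrna$values[keep_rna, , drop = FALSE]

  blocks <- vector("list", length(pairs))
  counts <- vector("list", length(pairs))
  for (k in seq_along(pairs)) {
    idx_a <- which(design$subtype == pairs[[k]][1])
    idx_b <- which(design$subtype == pairs[[k]][2])
    st <- .analysis_stats(X, Y, idx_a, idx_b)
    p <- st$p
    if (p_adjust == "BH") p[] <- stats::p.adjust(as.vector(p), method = "BH")
    sig <- !is.na(p) & p < p_threshold
    if (require_negative) sig <- sig & st$eligible
    storage.mode(sig) <- "integer"
    blocks[[k]] <- sig
    counts[[k]] <- tibble::tibble(
      analysis_id = aids[k], n_A = length(idx_a), n_B = length(idx_b),
      n_tested = sum(!is.na(p)), n_skipped = st$n_skipped,
      n_significant = sum(sig)
    )
  }
  A <- do.call(cbind, blocks)
  rownames(A) <- keep_mir
  columns <- tibble::tibble(
    mrna_id = rep(rep(keep_rna, each = 1), times = length(pairs)),
    analysis_id = rep(aids, each = length(keep_rna))
  )
  structure(
    list(A = A, mirna_ids = keep_mir, columns = columns,
         p_threshold = p_threshold, require_negative = require_negative,
         analysis_ids = aids, counts = dplyr::bind_rows(counts),
         excluded_subtypes = small),
    class = "assoc_matrix"
  )
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("<assoc_matrix> %d miRNAs x %d (target, analysis) columns; %d analyses\n",
              nrow(x$A), ncol(x$A), length(x$analysis_ids)))
  cat(sprintf("  %d dysregulations at p < %g%s\n", sum(x$A), x$p_threshold,
              if (x$require_negative) " (inverse-correlation prerequisite)" else ""))
  invisible(x)
}

#' Total dysregulation count of an association matrix
#' @param assoc an `assoc_matrix`.
#' @return integer count of 1-entries across all analysis blocks.
#' @export
n_dysregulations <- function(assoc) {
  stopifnot(inherits(assoc, "assoc_matrix"))
  sum(assoc$A)
}

#' Write an association matrix as a sparse triplet TSV
#'
#' One row per 1-entry: `mirna_id`, `mrna_id`, `analysis_id`.
#'
#' @param assoc an `assoc_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_association <- function(assoc, path) {
  stopifnot(inherits(assoc, "assoc_matrix"))
  hits <- which(assoc$A == 1L, arr.ind = TRUE)
  out <- tibble::tibble(
    mirna_id = assoc$mirna_ids[hits[, 1]],
    mrna_id = assoc$columns$mrna_id[hits[, 2]],
    analysis_id = assoc$columns$analysis_id[hits[, 2]]
  ) |> dplyr::arrange(.data$analysis_id, .data$mirna_id, .data$mrna_id)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
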