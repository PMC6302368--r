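#' Cosine similarity of two binary profiles
#'
#' `s(a, b) = (a . b) / (||a|| ||b||)`, the number of shared dysregulated
#' targets normalized by the geometric mean of the two connection counts.
#' Defined as 0 when either vector has zero norm.
#'
#' @param a,b numeric (typically 0/1) vectors of equal length.
#' @return similarity in `[0, 1]` for non-negative inputs.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Build the miRNA-miRNA synergism network
#'
#' Computes the cosine similarity of every pair of association-matrix rows
#' (a miRNA's dysregulated-target profile concatenated across analyses) and
#' raises it to the power `beta`. miRNAs with an all-zero row — never found
#' dysregulated — are excluded from the network.
#'
#' @param assoc an `assoc_matrix` from [run_pairwise_analyses()], or a
#'   plain binary matrix with miRNA rownames.
#' @param beta positive power applied to the similarities (default 1, i.e.
#'   the raw cosine similarity).
#' @return a `similarity_network`: symmetric weight matrix `M` with zero
#'   diagonal, node IDs, `beta`, and empty threshold state.
#' @export
build_similarity_network <- function(assoc, beta = 1) {
  A <- if (inherits(assoc, "assoc_matrix")) assoc$A else as.matrix(assoc)
  stopifnot(beta > 0)
  norms <- sqrt(rowSums(A^2))
  keep <- norms > 0
  if (sum(keep) < 2) stop("fewer than 2 miRNAs with any dysregulation; network is degenerate",
                          call. = FALSE)
  A <- A[keep, , drop = FALSE]
  An <- A / norms[keep]
  M <- tcrossprod(An)
  M <- (M + t(M)) / 2                 # enforce exact symmetry
  M[M < 0] <- 0; M[M > 1] <- 1
  diag(M) <- 0
  M <- M^beta
  structure(
    list(node_ids = rownames(A), M = M, beta = beta,
         threshold = NULL, r2_by_threshold = NULL,
         dropped_nodes = character(),
         n_nonisolated = sum(rowSums(M > 0) > 0)),
    class = "similarity_network"
  )
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network> %d nodes, %d positive edges, beta = %g\n",
              length(x$node_ids), sum(x$M > 0) / 2, x$beta))
  if (!is.null(x$threshold)) {
    cat(sprintf("  pruned at threshold %g; %d non-isolated nodes\n",
                x$threshold, x$n_nonisolated))
  }
  invisible(x)
}

#' Edge list of a similarity network
#' @param network a `similarity_network`.
#' @return tibble with columns `node_a`, `node_b`, `weight` (upper triangle,
#'   positive weights only).
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "similarity_network"))
  up <- which(upper.tri(network$M) & network$M > 0, arr.ind = TRUE)
  tibble::tibble(
    node_a = network$node_ids[up[, 1]],
    node_b = network$node_ids[up[, 2]],
    weight = network$M[up]
  ) |> dplyr::arrange(.data$node_a, .data$node_b)
}

# log10-binned histogram fit: squared correlation of log10(bin center
# frequency) against the bin center position in log10 space
.powerlaw_fit <- function(values, n_bins) {
  values <- values[values > 0]
  if (length(values) < 2) return(NA_real_)
  lv <- log10(values)
  lo <- min(lv); hi <- max(lv)
  if (hi - lo < .Machine$double.eps) return(NA_real_)
  edges <- seq(lo, hi, length.out = n_bins + 1)
  bin <- findInterval(lv, edges, rightmost.closed = TRUE)
  bin[bin == 0] <- 1L
  freq <- tabulate(bin, nbins = n_bins)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  keep <- freq > 0
  if (sum(keep) < 3) return(NA_real_)
  stats::cor(centers[keep], log10(freq[keep]))^2
}

#' Scale-free topology fit score
#'
#' Quantifies how well the thresholded network follows a power law as the
#' squared Pearson correlation between `log10` bin position and `log10` bin
#' frequency of a histogram with `n_bins` equal-width bins in log space
#' (empty bins dropped, centers at the arithmetic midpoints of the log bin
#' edges). In `mode = "degree"` the binned quantity is the node degree of
#' the unweighted thresholded network (degree-0 nodes excluded); in
#' `mode = "score"` it is the surviving similarity scores themselves.
#' Returns `NA` when fewer than 3 non-empty bins remain (fit undefined).
#'
#' Note the score is the squared correlation exactly; a positive log-log
#' slope also yields a high score, so inspect the curve when in doubt.
#'
#' @param network a `similarity_network`.
#' @param threshold hard threshold in `[0, 1]` applied before measuring.
#' @param n_bins number of histogram bins (>= 3, default 10).
#' @param mode `"degree"` (default) or `"score"`.
#' @return fit score in `[0, 1]`, or `NA` when undefined.
#' @export
scale_free_fit <- function(network, threshold, n_bins = 10,
                           mode = c("degree", "score")) {
  mode <- match.arg(mode)
  stopifnot(inherits(network, "similarity_network"), n_bins >= 3,
            threshold >= 0, threshold <= 1)
  keepE <- network$M >= threshold & network$M > 0
  if (mode == "degree") {
    deg <- rowSums(keepE)
    .powerlaw_fit(deg[deg > 0], n_bins)
  } else {
    s <- network$M[upper.tri(network$M)]
    .powerlaw_fit(s[s >= threshold & s > 0], n_bins)
  }
}

#' Select the hard threshold by the scale-free criterion
#'
#' Evaluates the fit score over a threshold grid and returns the smallest
#' (least stringent) threshold whose score reaches `r2_min`, so that as
#' many edges as possible survive while the degree distribution keeps a
#' power-law shape. The full curve is recorded on the returned network.
#'
#' @param network a `similarity_network`.
#' @param grid ascending numeric vector of candidate thresholds.
#' @param r2_min required fit score in `(0, 1)` (default 0.8).
#' @param n_bins histogram bins for the fit.
#' @param mode fit mode passed to [scale_free_fit()].
#' @return the network with `threshold` set and `r2_by_threshold` holding a
#'   tibble `(threshold, r2_degree, r2_score, n_edges, n_nonisolated)`.
#' @export
select_threshold <- function(network, grid = seq(0.05, 0.95, by = 0.05),
                             r2_min = 0.8, n_bins = 10,
                             mode = c("degree", "score")) {
  mode <- match.arg(mode)
  stopifnot(is.unsorted(grid) == FALSE, r2_min > 0, r2_min < 1)
  curve <- threshold_curve(network, grid, n_bins)
  fit <- if (mode == "degree") curve$r2_degree else curve$r2_score
  ok <- which(!is.na(fit) & fit >= r2_min)
  network$r2_by_threshold <- curve
  if (length(ok) == 0) {
    best <- if (all(is.na(fit))) NA_real_ else max(fit, na.rm = TRUE)
    stop(sprintf("no grid threshold reaches fit score %g (best achieved: %s)",
                 r2_min, format(best, digits = 4)), call. = FALSE)
  }
  network$threshold <- grid[min(ok)]
  network
}

#' Fit-versus-threshold diagnostic curve
#'
#' @param network a `similarity_network`.
#' @param grid candidate thresholds.
#' @param n_bins histogram bins for the fit.
#' @return tibble `(threshold, r2_degree, r2_score, n_edges, n_nonisolated)`.
#' @export
threshold_curve <- function(network, grid = seq(0.05, 0.95, by = 0.05), n_bins = 10) {
  stopifnot(inherits(network, "similarity_network"))
  purrr::map_dfr(grid, function(th) {
    keepE <- network$M >= th & network$M > 0
    deg <- rowSums(keepE)
    tibble::tibble(
      threshold = th,
      r2_degree = scale_free_fit(network, th, n_bins, "degree"),
      r2_score = scale_free_fit(network, th, n_bins, "score"),
      n_edges = sum(keepE) / 2,
      n_nonisolated = sum(deg > 0)
    )
  })
}

#' Prune a similarity network at a hard threshold
#'
#' Removes every edge with weight below `threshold` and drops nodes left
#' without any edge (their IDs are recorded in `dropped_nodes`).
#'
#' @param network a `similarity_network`.
#' @param threshold edge-weight cutoff in `[0, 1]`; defaults to the
#'   threshold stored by [select_threshold()].
#' @return the pruned `similarity_network`.
#' @export
prune <- function(network, threshold = network$threshold) {
  stopifnot(inherits(network, "similarity_network"))
  if (is.null(threshold)) stop("no threshold given or stored on the network", call. = FALSE)
  if (threshold < 0 || threshold > 1) stop("`threshold` must be in [0, 1]", call. = FALSE)
  M <- network$M
  M[M < threshold] <- 0
  iso <- rowSums(M > 0) == 0
  network$dropped_nodes <- c(network$dropped_nodes, network$node_ids[iso])
  network$M <- M[!iso, !iso, drop = FALSE]
  network$node_ids <- network$node_ids[!iso]
  network$threshold <- threshold
  network$n_nonisolated <- sum(!iso)
  network
}

#' Convert a similarity network to an igraph graph
#' @param network a `similarity_network`.
#' @return an undirected weighted [igraph::graph] object.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "similarity_network"))
  igraph::graph_from_adjacency_matrix(network$M, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Write a network edge list as TSV
#' @param network a `similarity_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  edges <- network_edges(network) |>
    dplyr::mutate(weight = formatC(.data$weight, format = "f", digits = 10))
  readr::write_tsv(edges, path, progress = FALSE)
  invisible(path)
}
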