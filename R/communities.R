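new_module_partition <- function(assignment, modularity, levels, seed) {
  structure(
    list(assignment = assignment, modularity = modularity,
         levels = levels, seed = seed),
    class = "module_partition"
  )
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d nodes in %d modules",
              length(x$assignment), length(unique(x$assignment))))
  if (!is.na(x$modularity)) cat(sprintf(", modularity %.4f", x$modularity))
  cat("\n")
  invisible(x)
}

#' Weighted modularity of a partition
#'
#' `Q = (1 / 2m) * sum_pq [M_pq - k_p k_q / 2m] delta(c_p, c_q)` with `k`
#' the weighted degree and `m` the total edge weight: the density of edge
#' weight inside communities relative to a degree-preserving random null.
#'
#' @param network a `similarity_network` (edge weights = similarities).
#' @param membership named vector assigning every network node to a module,
#'   or a `module_partition`.
#' @return modularity in `[-0.5, 1]`.
#' @export
modularity_score <- function(network, membership) {
  stopifnot(inherits(network, "similarity_network"))
  if (inherits(membership, "module_partition")) membership <- membership$assignment
  if (!all(network$node_ids %in% names(membership))) {
    stop("membership does not cover all network nodes", call. = FALSE)
  }
  mu <- membership[network$node_ids]
  M <- network$M
  two_m <- sum(M)
  if (two_m == 0) return(0)
  k <- rowSums(M)
  same <- outer(mu, mu, `==`)
  sum((M - outer(k, k) / two_m) * same) / two_m
}

#' Extract miRNA modules by Louvain community detection
#'
#' Runs the two-phase greedy Louvain optimization of weighted modularity on
#' the pruned network (phase 1: move each node to the neighboring community
#' with maximal modularity gain until no move improves; phase 2: aggregate
#' communities into super-nodes and repeat) and returns the hierarchy level
#' with the highest modularity. The node visit order is randomized, so the
#' result is deterministic only for a fixed `seed`.
#'
# one phase-1 sweep set: greedy node moves to the neighbor community with
# maximal modularity gain, repeated until a full pass moves nothing.
# A may carry self-loops on the diagonal (aggregated internal weight x 2).
.louvain_phase1 <- function(A, gamma) {
  n <- nrow(A)
  comm <- seq_len(n)
  k <- rowSums(A)
  two_m <- sum(A)
  if (two_m == 0) return(comm)
  sig <- k                              # total strength per community
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      ci <- comm[i]
      sig[ci] <- sig[ci] - k[i]
      nbr <- which(A[i, ] > 0)
      nbr <- nbr[nbr != i]
      cand <- unique(c(ci, comm[nbr]))
      # gain (up to a constant factor) of placing i into community c
      gain <- vapply(cand, function(cc) {
        members <- which(comm == cc)
        members <- members[members != i]
        sum(A[i, members]) - gamma * sig[cc] * k[i] / two_m
      }, 0)
      best <- cand[which.max(gain)]
      stay <- gain[cand == ci]
      if (best != ci && max(gain) > stay + 1e-12) {
        comm[i] <- best
        moved <- TRUE
      }
      sig[comm[i]] <- sig[comm[i]] + k[i]
    }
    if (!moved) break
  }
  match(comm, unique(comm))             # renumber 1..K
}

# full two-phase hierarchy for one randomized visit order; returns the list
# of partitions of the original nodes, finest first
.louvain_once <- function(M, gamma) {
  n <- nrow(M)
  levels <- list()
  A <- M
  map <- seq_len(n)                     # original node -> current super node
  repeat {
    comm <- .louvain_phase1(A, gamma)
    if (length(unique(comm)) == nrow(A)) break   # no merge: converged
    map <- comm[map]
    levels[[length(levels) + 1]] <- map
    K <- max(comm)
    S <- matrix(0, nrow(A), K)
    S[cbind(seq_len(nrow(A)), comm)] <- 1
    A <- t(S) %*% A %*% S               # aggregate; diagonal = 2 x internal
    if (K == 1) break
  }
  if (length(levels) == 0) levels <- list(seq_len(n))
  levels
}

#' Extract miRNA modules by Louvain community detection
#'
#' Two-phase greedy Louvain optimization of weighted modularity on the
#' pruned network. Phase 1 visits nodes in a random order and moves each to
#' the neighboring community with the largest positive modularity gain
#' (ties keep the current community) until a full pass changes nothing;
#' phase 2 aggregates communities into super-nodes (internal weight becomes
#' a self-loop) and the phases alternate until no further merging occurs.
#' All recorded hierarchy levels are scored and the partition with the
#' highest modularity is returned. Because the greedy optimization is visit
#' -order dependent, `n_restarts` independent randomized runs are performed
#' and the best kept; all randomness derives from `seed`.
#'
#' @param network a `similarity_network`.
#' @param seed integer seed.
#' @param resolution resolution parameter of the modularity objective
#'   (1 = classic modularity).
#' @param n_restarts number of randomized restarts (default 10).
#' @return a `module_partition` with the assignment, its modularity, the
#'   recorded hierarchy levels of the winning run, and the seed.
#' @export
louvain_modules <- function(network, seed = 1L, resolution = 1, n_restarts = 10) {
  stopifnot(inherits(network, "similarity_network"), n_restarts >= 1)
  ids <- network$node_ids
  if (length(ids) == 0) {
    return(new_module_partition(stats::setNames(integer(0), character(0)),
                                NA_real_, list(), as.integer(seed)))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  best_part <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(as.integer(seed) + r - 1L)
    raw_levels <- .louvain_once(network$M, resolution)
    levels <- lapply(raw_levels, function(mu) stats::setNames(as.integer(mu), ids))
    q <- vapply(levels, function(mu) modularity_score(network, mu), 0)
    top <- which.max(q)
    if (is.null(best_part) || q[top] > best_part$modularity + 1e-12) {
      best_part <- new_module_partition(levels[[top]], q[top], levels,
                                        as.integer(seed))
    }
  }
  best_part
}

# entropy (nats) of a count vector
.entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Normalized mutual information between two partitions
#'
#' `NMI = I(P1; P2) / mean(H(P1), H(P2))` from the contingency table of
#' co-assignments on the shared node set. Label-invariant, symmetric, in
#' `[0, 1]`; 1 for identical partitions (including two identical one-block
#' partitions), 0 when either partition is a single block and they are
#' otherwise independent.
#'
#' @param p1,p2 `module_partition` objects (or named assignment vectors)
#'   with a non-empty node intersection.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(p1, p2) {
  a1 <- if (inherits(p1, "module_partition")) p1$assignment else p1
  a2 <- if (inherits(p2, "module_partition")) p2$assignment else p2
  shared <- intersect(names(a1), names(a2))
  if (length(shared) == 0) stop("partitions share no nodes", call. = FALSE)
  t12 <- table(a1[shared], a2[shared])
  n <- sum(t12)
  h1 <- .entropy(rowSums(t12)); h2 <- .entropy(colSums(t12))
  if (h1 == 0 && h2 == 0) return(1)
  pij <- t12 / n
  pi_ <- rowSums(pij); p_j <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, p_j)[nz]))
  val <- mi / mean(c(h1, h2))
  min(max(val, 0), 1)
}

#' Pairwise module-consistency matrix
#'
#' NMI between every pair of module assignments obtained from independent
#' dysregulation analyses, computed on the node intersection of each pair.
#' Pairs with an empty intersection get `NA`.
#'
#' @param partitions named list of `module_partition` objects, one per
#'   analysis.
#' @return symmetric numeric matrix with unit diagonal and analysis labels.
#' @export
module_consistency_matrix <- function(partitions) {
  stopifnot(length(partitions) >= 2)
  ids <- names(partitions)
  if (is.null(ids)) ids <- paste0("analysis_", seq_along(partitions))
  k <- length(partitions)
  out <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  diag(out) <- 1
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      val <- tryCatch(nmi(partitions[[i]], partitions[[j]]), error = function(e) NA_real_)
      out[i, j] <- out[j, i] <- val
    }
  }
  out
}

#' Write module assignments as TSV
#' @param partition a `module_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_modules <- function(partition, path) {
  stopifnot(inherits(partition, "module_partition"))
  out <- tibble::tibble(
    mirna_id = names(partition$assignment),
    module = as.integer(partition$assignment)
  ) |> dplyr::arrange(.data$mirna_id)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read module assignments from TSV
#' @param path TSV with columns `mirna_id`, `module`.
#' @return a `module_partition` (modularity unknown).
#' @export
read_modules <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    mirna_id = readr::col_character(), module = readr::col_integer()
  ), progress = FALSE)
  new_module_partition(stats::setNames(df$module, df$mirna_id),
                       NA_real_, list(), NA_integer_)
}
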