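#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an SGL model's coefficients
#'
#' @param x an `sgl_model`.
#' @param all_terms include zero coefficients (default `FALSE`).
#' @param ... unused.
#' @return tibble `(class, term, estimate, group)`.
#' @exportS3Method generics::tidy
tidy.sgl_model <- function(x, all_terms = FALSE, ...) {
  group_of <- integer(length(x$groups$feature_ids))
  for (i in seq_along(x$groups$groups)) group_of[x$groups$groups[[i]]] <- i
  out <- tidyr::expand_grid(class = x$class_labels, term = rownames(x$W)) |>
    dplyr::mutate(
      estimate = purrr::map2_dbl(.data$term, .data$class, ~ x$W[.x, .y]),
      group = group_of[match(.data$term, x$groups$feature_ids)]
    )
  if (!all_terms) out <- dplyr::filter(out, .data$estimate != 0)
  out
}

#' One-row summary of an SGL model
#' @param x an `sgl_model`.
#' @param ... unused.
#' @return tibble with penalty parameters, sparsity and convergence info.
#' @exportS3Method generics::glance
glance.sgl_model <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, alpha = x$alpha,
    n_classes = length(x$class_labels),
    n_features = nrow(x$W),
    n_nonzero = sum(rowSums(abs(x$W)) > 0),
    n_groups = length(x$groups$groups),
    iterations = sum(x$convergence$iterations),
    converged = all(x$convergence$converged)
  )
}

#' Tidy a module partition
#' @param x a `module_partition`.
#' @param ... unused.
#' @return tibble `(mirna_id, module)`.
#' @exportS3Method generics::tidy
tidy.module_partition <- function(x, ...) {
  tibble::tibble(mirna_id = names(x$assignment),
                 module = as.integer(x$assignment))
}

#' One-row summary of a module partition
#' @param x a `module_partition`.
#' @param ... unused.
#' @return tibble `(n_nodes, n_modules, modularity, seed)`.
#' @exportS3Method generics::glance
glance.module_partition <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$assignment),
                 n_modules = length(unique(x$assignment)),
                 modularity = x$modularity, seed = x$seed)
}

#' Per-analysis dysregulation counts
#' @param x an `assoc_matrix`.
#' @param ... unused.
#' @return tibble of per-analysis sample sizes and counts.
#' @exportS3Method generics::tidy
tidy.assoc_matrix <- function(x, ...) x$counts

#' One-row summary of an association matrix
#' @param x an `assoc_matrix`.
#' @param ... unused.
#' @return tibble with dimensions and the total dysregulation count.
#' @exportS3Method generics::glance
glance.assoc_matrix <- function(x, ...) {
  tibble::tibble(n_mirnas = nrow(x$A), n_columns = ncol(x$A),
                 n_analyses = length(x$analysis_ids),
                 n_dysregulations = sum(x$A),
                 p_threshold = x$p_threshold,
                 require_negative = x$require_negative)
}

#' Edge list of a similarity network (tidy form)
#' @param x a `similarity_network`.
#' @param ... unused.
#' @return tibble `(node_a, node_b, weight)`.
#' @exportS3Method generics::tidy
tidy.similarity_network <- function(x, ...) network_edges(x)

#' One-row summary of a similarity network
#' @param x a `similarity_network`.
#' @param ... unused.
#' @return tibble with node/edge counts and threshold state.
#' @exportS3Method generics::glance
glance.similarity_network <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$node_ids),
                 n_edges = sum(x$M > 0) / 2,
                 beta = x$beta,
                 threshold = if (is.null(x$threshold)) NA_real_ else x$threshold,
                 n_nonisolated = x$n_nonisolated)
}
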