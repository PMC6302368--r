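#' Group structure for the sparse group lasso
#'
#' Builds disjoint feature groups from a module partition; features not
#' assigned to any module (background or pruned miRNAs) become singleton
#' groups so every feature stays in the model. Each group's penalty weight
#' is `sqrt(|g|)`.
#'
#' @param feature_ids character vector of model feature IDs (order defines
#'   the design-matrix columns).
#' @param partition optional `module_partition` (or named module vector)
#'   mapping a subset of the features to modules.
#' @return a `group_structure`: list of integer index vectors `groups`,
#'   weights `sqrt(|g|)` and the feature IDs.
#' @export
group_structure <- function(feature_ids, partition = NULL) {
  stopifnot(!anyDuplicated(feature_ids))
  assign <- if (inherits(partition, "module_partition")) partition$assignment else partition
  groups <- list()
  if (!is.null(assign)) {
    assign <- assign[names(assign) %in% feature_ids]
    for (m in sort(unique(assign))) {
      groups <- c(groups, list(match(names(assign)[assign == m], feature_ids)))
    }
  }
  covered <- unlist(groups)
  if (anyDuplicated(covered)) stop("groups must be disjoint", call. = FALSE)
  singles <- setdiff(seq_along(feature_ids), covered)
  groups <- c(groups, lapply(singles, identity))
  structure(
    list(groups = groups,
         weights = sqrt(lengths(groups)),
         feature_ids = feature_ids),
    class = "group_structure"
  )
}

#' @export
print.group_structure <- function(x, ...) {
  sz <- lengths(x$groups)
  cat(sprintf("<group_structure> %d features in %d groups (%d non-singleton)\n",
              length(x$feature_ids), length(x$groups), sum(sz > 1)))
  invisible(x)
}

# lambda * (alpha * l1 + (1 - alpha) * sum_g sqrt(|g|) ||w_g||_2)
sgl_penalty <- function(w, lambda, alpha, groups) {
  gl <- sum(vapply(seq_along(groups$groups), function(i) {
    groups$weights[i] * sqrt(sum(w[groups$groups[[i]]]^2))
  }, 0))
  lambda * alpha * sum(abs(w)) + lambda * (1 - alpha) * gl
}

# numerically stable mean logistic loss over margins m = y * (Xw + b)
.logistic_loss <- function(m) {
  mean(ifelse(m > 0, log1p(exp(-m)), -m + log1p(exp(m))))
}

#' Sparse group lasso logistic objective
#'
#' Mean logistic loss over `+/-1` labels plus the SGL penalty
#' `lambda * alpha * ||w||_1 + lambda * (1 - alpha) * sum_g sqrt(|g|) ||w_g||_2`.
#' The intercept is unpenalized.
#'
#' @param w numeric weight vector (one per feature).
#' @param intercept scalar intercept.
#' @param X samples-by-features design matrix (standardized features).
#' @param y labels in `{-1, +1}`.
#' @param lambda sparsity coefficient (>= 0).
#' @param alpha mixing coefficient in `[0, 1]` (1 = pure lasso).
#' @param groups a [group_structure()].
#' @return scalar objective value.
#' @export
sgl_objective <- function(w, intercept, X, y, lambda, alpha, groups) {
  if (length(w) != ncol(X)) stop("length(w) must equal ncol(X)", call. = FALSE)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (!all(y %in% c(-1, 1))) stop("labels must be -1/+1", call. = FALSE)
  m <- y * (as.vector(X %*% w) + intercept)
  .logistic_loss(m) + sgl_penalty(w, lambda, alpha, groups)
}

#' Proximal operator of the sparse group lasso penalty
#'
#' Exact prox of `step * lambda * (alpha ||.||_1 + (1 - alpha) GL(.))`:
#' coordinate-wise soft-thresholding at `step * lambda * alpha` followed by
#' per-group block soft-thresholding at `step * lambda * (1 - alpha) *
#' sqrt(|g|)` (the composition is the exact prox of the composite penalty).
#'
#' @param v numeric input vector.
#' @param step positive step size.
#' @param lambda,alpha penalty parameters.
#' @param groups a [group_structure()].
#' @return the proximal point, same length as `v`.
#' @export
sgl_prox <- function(v, step, lambda, alpha, groups) {
  stopifnot(step > 0)
  u <- sign(v) * pmax(abs(v) - step * lambda * alpha, 0)
  thr <- step * lambda * (1 - alpha)
  if (thr > 0) {
    for (i in seq_along(groups$groups)) {
      g <- groups$groups[[i]]
      nrm <- sqrt(sum(u[g]^2))
      u[g] <- if (nrm <= thr * groups$weights[i]) 0 else {
        u[g] * (1 - thr * groups$weights[i] / nrm)
      }
    }
  }
  u
}

# monotone FISTA for one binary SGL-logistic problem; returns list(w, b,
# objective path, iterations, converged)
.fit_sgl_binary <- function(X, y, groups, lambda, alpha, max_iter, tol,
                            intercept = TRUE) {
  n <- nrow(X); d <- ncol(X)
  w <- numeric(d); b <- 0
  obj <- function(w, b) sgl_objective(w, b, X, y, lambda, alpha, groups)
  gradient <- function(w, b) {
    m <- y * (as.vector(X %*% w) + b)
    r <- -y * stats::plogis(-m) / n
    list(gw = as.vector(crossprod(X, r)), gb = if (intercept) sum(r) else 0,
         loss = .logistic_loss(m))
  }
  # Lipschitz bound of the logistic gradient: ||[1 X]||_2^2 / (4n)
  step <- 4 * n / (sum(X^2) + n)
  wx <- w; bx <- b                      # accepted (monotone) iterate
  wy <- w; by <- b                      # extrapolated point
  w_prev <- w; b_prev <- b
  t_k <- 1
  f_x <- obj(wx, bx)
  path <- f_x
  converged <- FALSE
  flat <- 0L
  for (it in seq_len(max_iter)) {
    g <- gradient(wy, by)
    repeat {                            # backtracking on the smooth part
      wz <- sgl_prox(wy - step * g$gw, step, lambda, alpha, groups)
      bz <- by - step * g$gb
      m <- y * (as.vector(X %*% wz) + bz)
      lhs <- .logistic_loss(m)
      dq <- sum((wz - wy) * g$gw) + (bz - by) * g$gb +
        (sum((wz - wy)^2) + (bz - by)^2) / (2 * step)
      if (lhs <= g$loss + dq + 1e-12) break
      step <- step / 2
    }
    f_z <- lhs + sgl_penalty(wz, lambda, alpha, groups)
    if (f_z > f_x) {
      # momentum overshoot: adaptive restart from the accepted iterate;
      # the next (plain proximal-gradient) step cannot increase the objective
      t_k <- 1
      wy <- wx; by <- bx
      w_prev <- wx; b_prev <- bx
      path <- c(path, f_x)
      next
    }
    t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    wy <- wz + ((t_k - 1) / t_next) * (wz - wx)
    by <- bz + ((t_k - 1) / t_next) * (bz - bx)
    rel <- (f_x - f_z) / max(1, abs(f_x))
    w_prev <- wx; b_prev <- bx
    wx <- wz; bx <- bz
    f_x <- f_z
    t_k <- t_next
    path <- c(path, f_x)
    flat <- if (rel < tol) flat + 1L else 0L
    if (flat >= 3L) { converged <- TRUE; break }
  }
  list(w = wx, b = bx, objective = path, iterations = length(path) - 1,
       converged = converged)
}

#' Fit a one-vs-rest sparse group lasso logistic classifier
#'
#' Fits one binary (`+1` = class, `-1` = rest) logistic model with the SGL
#' penalty per class label via monotone accelerated proximal gradient
#' (FISTA with backtracking; the recorded objective is non-increasing).
#' Prediction assigns the class with the highest linear score.
#'
#' @param X samples-by-features numeric matrix with column names;
#'   features should be standardized.
#' @param labels factor (or coercible) of class labels, length `nrow(X)`.
#' @param groups a [group_structure()] over `colnames(X)`; default all
#'   singletons (plain sparse logistic regression).
#' @param lambda sparsity coefficient (default 1).
#' @param alpha mixing coefficient (default 0.5).
#' @param max_iter iteration cap (default 10000).
#' @param tol relative objective-change tolerance (default 1e-6).
#' @param intercept include an unpenalized intercept (default `TRUE`).
#' @return an `sgl_model`: weight matrix `W` (features x classes),
#'   intercepts, penalty parameters, group structure, class labels and
#'   convergence diagnostics.
#' @export
fit_sgl_logistic <- function(X, labels, groups = NULL, lambda = 1, alpha = 0.5,
                             max_iter = 10000, tol = 1e-6, intercept = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("need >= 2 classes present in `labels`", call. = FALSE)
  if (is.null(groups)) groups <- group_structure(colnames(X))
  if (!identical(groups$feature_ids, colnames(X))) {
    stop("group structure feature IDs must match colnames(X)", call. = FALSE)
  }
  classes <- levels(labels)
  W <- matrix(0, ncol(X), length(classes), dimnames = list(colnames(X), classes))
  b <- stats::setNames(numeric(length(classes)), classes)
  conv <- vector("list", length(classes))
  for (k in seq_along(classes)) {
    y <- ifelse(labels == classes[k], 1, -1)
    fit <- .fit_sgl_binary(X, y, groups, lambda, alpha, max_iter, tol, intercept)
    if (!fit$converged) {
      warning(sprintf("class '%s': not converged after %d iterations (objective %.6g)",
                      classes[k], fit$iterations, utils::tail(fit$objective, 1)))
    }
    W[, k] <- fit$w
    b[k] <- fit$b
    conv[[k]] <- tibble::tibble(class = classes[k], iterations = fit$iterations,
                                objective = utils::tail(fit$objective, 1),
                                converged = fit$converged)
    attr(conv[[k]], "path") <- fit$objective
  }
  structure(
    list(W = W, intercepts = b, lambda = lambda, alpha = alpha,
         groups = groups, class_labels = classes,
         convergence = dplyr::bind_rows(conv),
         objective_paths = lapply(conv, attr, "path")),
    class = "sgl_model"
  )
}

#' @export
print.sgl_model <- function(x, ...) {
  cat(sprintf("<sgl_model> %d classes x %d features; lambda = %g, alpha = %g\n",
              length(x$class_labels), nrow(x$W), x$lambda, x$alpha))
  cat(sprintf("  %d features with a nonzero coefficient\n",
              sum(rowSums(abs(x$W)) > 0)))
  invisible(x)
}

#' Predict from a fitted SGL model
#'
#' @param object an `sgl_model`.
#' @param newdata samples-by-features matrix with the model's features.
#' @param type `"class"` (default) or `"score"` (per-class linear decision
#'   values).
#' @param ... unused.
#' @return factor of predicted classes, or a samples-by-classes score
#'   matrix.
#' @export
predict.sgl_model <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)[, rownames(object$W), drop = FALSE]
  scores <- sweep(X %*% object$W, 2, object$intercepts, `+`)
  if (type == "score") return(scores)
  factor(object$class_labels[max.col(scores, ties.method = "first")],
         levels = object$class_labels)
}

#' Rank-based AUROC
#'
#' Area under the ROC curve from the Wilcoxon rank statistic; tied scores
#' contribute 1/2 per discordant-tie pair.
#'
#' @param scores numeric decision values.
#' @param positive logical vector marking positive cases.
#' @return AUROC in `[0, 1]`, or `NA` if either class is absent.
#' @export
auroc <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-class one-vs-rest AUROC on a test set
#'
#' @param model an `sgl_model`.
#' @param X_test,labels_test held-out data.
#' @return tibble with columns `class`, `auroc` (`NA` when the class is
#'   absent from the test set).
#' @export
roc_auc_per_class <- function(model, X_test, labels_test) {
  scores <- predict(model, X_test, type = "score")
  labels_test <- factor(labels_test, levels = model$class_labels)
  purrr::map_dfr(seq_along(model$class_labels), function(k) {
    tibble::tibble(class = model$class_labels[k],
                   auroc = auroc(scores[, k], labels_test == model$class_labels[k]))
  })
}

#' Macro-averaged one-vs-rest AUROC
#' @inheritParams roc_auc_per_class
#' @return mean per-class AUROC over classes present in the test set.
#' @export
macro_auroc <- function(model, X_test, labels_test) {
  mean(roc_auc_per_class(model, X_test, labels_test)$auroc, na.rm = TRUE)
}

# stratified fold ids, deterministic given seed
.stratified_folds <- function(labels, n_folds, seed) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Cross-validate SGL regularization parameters
#'
#' Stratified k-fold cross-validation over a `(lambda, alpha)` grid,
#' scored by mean one-vs-rest macro-AUROC on the held-out folds.
#'
#' @param X,labels training data (labels factor-coercible).
#' @param groups a [group_structure()].
#' @param lambda_grid,alpha_grid candidate values.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed controlling the fold split.
#' @param ... passed to [fit_sgl_logistic()] (e.g. `max_iter`, `tol`).
#' @return list with `best_lambda`, `best_alpha` and `table`, a tibble
#'   `(lambda, alpha, fold, macro_auroc)`.
#' @export
cross_validate_sgl <- function(X, labels, groups = NULL,
                               lambda_grid = c(0.1, 0.5, 1),
                               alpha_grid = c(0.5), n_folds = 5, seed = 1L, ...) {
  stopifnot(n_folds >= 2)
  X <- as.matrix(X)
  labels <- droplevels(as.factor(labels))
  if (any(table(labels) < n_folds)) {
    stop("every class needs >= n_folds samples for stratified folds", call. = FALSE)
  }
  fold <- .stratified_folds(labels, n_folds, seed)
  grid <- tidyr::expand_grid(lambda = lambda_grid, alpha = alpha_grid)
  table <- purrr::pmap_dfr(grid, function(lambda, alpha) {
    purrr::map_dfr(seq_len(n_folds), function(f) {
      fit <- fit_sgl_logistic(X[fold != f, , drop = FALSE], labels[fold != f],
                              groups, lambda = lambda, alpha = alpha, ...)
      tibble::tibble(lambda = lambda, alpha = alpha, fold = f,
                     macro_auroc = macro_auroc(fit, X[fold == f, , drop = FALSE],
                                               labels[fold == f]))
    })
  })
  means <- table |>
    dplyr::group_by(.data$lambda, .data$alpha) |>
    dplyr::summarise(mean_auroc = mean(.data$macro_auroc), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_auroc))
  list(best_lambda = means$lambda[1], best_alpha = means$alpha[1], table = table)
}

#' Rank model features as biomarker candidates
#'
#' Candidates are features with a nonzero coefficient; the ranking score is
#' the maximum absolute coefficient across classes (for a binary
#' tumor-vs-normal model the two columns coincide up to sign, so this is
#' the natural binary ranking too).
#'
#' @param model an `sgl_model`.
#' @return tibble `(rank, feature_id, coefficient)` sorted by decreasing
#'   absolute coefficient (feature ID breaks ties).
#' @export
rank_biomarkers <- function(model) {
  stopifnot(inherits(model, "sgl_model"))
  score <- apply(abs(model$W), 1, max)
  keep <- score > 0
  out <- tibble::tibble(feature_id = rownames(model$W)[keep],
                        coefficient = score[keep]) |>
    dplyr::arrange(dplyr::desc(.data$coefficient), .data$feature_id) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  out
}

#' Precision and recall of top-ranked biomarkers against a known set
#'
#' For each `k`, precision is the fraction of the top-k ranked candidates
#' that belong to `known_set` and recall the fraction of `known_set`
#' recovered in the top k. `k` values beyond the candidate count are
#' truncated with a warning.
#'
#' @param model an `sgl_model`.
#' @param known_set character vector of known marker feature IDs.
#' @param k_list integer vector of list sizes.
#' @return tibble `(k, n_hits, precision, recall)`.
#' @export
rank_and_evaluate_biomarkers <- function(model, known_set, k_list = c(10, 25, 50, 100)) {
  if (length(known_set) == 0) stop("`known_set` is empty", call. = FALSE)
  ranked <- rank_biomarkers(model)
  n_cand <- nrow(ranked)
  if (any(k_list > n_cand)) {
    warning(sprintf("k truncated to the %d available candidates", n_cand))
    k_list <- pmin(k_list, n_cand)
  }
  purrr::map_dfr(unique(k_list), function(k) {
    top <- ranked$feature_id[seq_len(k)]
    hits <- length(intersect(top, known_set))
    tibble::tibble(k = k, n_hits = hits,
                   precision = hits / k,
                   recall = hits / length(known_set))
  })
}

#' Write a fitted SGL model as JSON
#'
#' Serializes class labels, penalty parameters, the group map and the
#' per-class sparse coefficients with a fixed numeric format, so identical
#' models produce byte-identical files.
#'
#' @param model an `sgl_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "sgl_model"))
  nz <- which(abs(model$W) > 0, arr.ind = TRUE)
  coefs <- tibble::tibble(
    feature_id = rownames(model$W)[nz[, 1]],
    class = model$class_labels[nz[, 2]],
    coefficient = sprintf("%.12g", model$W[nz])
  ) |> dplyr::arrange(.data$class, .data$feature_id)
  obj <- list(
    class_labels = model$class_labels,
    lambda = model$lambda, alpha = model$alpha,
    intercepts = sprintf("%.12g", model$intercepts),
    groups = lapply(model$groups$groups, function(g) model$groups$feature_ids[g]),
    coefficients = coefs
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
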