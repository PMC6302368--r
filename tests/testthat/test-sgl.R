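test_that("the SGL objective matches closed-form special cases", {
  set.seed(1)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c(-1, 1), 5)
  gs <- group_structure(colnames(X))
  # at the origin the loss is log(2) regardless of the data
  expect_equal(sgl_objective(numeric(4), 0, X, y, 1, 0.5, gs), log(2))

  # one group of 4 features with unit l2 norm, alpha = 0: penalty sqrt(4) = 2
  gs1 <- raw_groups(4)
  w <- c(0.5, 0.5, 0.5, 0.5)
  expect_equal(sgl_objective(w, 0, X, y, 1, 0, gs1) -
                 mean(log1p(exp(-y * as.vector(X %*% w)))), 2)

  # alpha = 1 reduces to the plain lasso objective
  expect_equal(sgl_objective(w, 0.3, X, y, 2, 1, gs1),
               mean(log1p(exp(-y * (as.vector(X %*% w) + 0.3)))) + 2 * sum(abs(w)))
  expect_error(sgl_objective(numeric(3), 0, X, y, 1, 0.5, gs), "ncol")
})

test_that("sgl_prox reproduces the two-stage closed form", {
  gs <- raw_groups(2)
  expect_identical(sgl_prox(c(3, -1), 1, 0, 0.5, gs), c(3, -1))   # no penalty

  # block-kill: group norm below the block threshold maps to zero
  gsA <- raw_groups(3)
  v <- c(0.1, -0.1, 0.05)
  expect_equal(sgl_prox(v, 1, 1, 0, gsA), c(0, 0, 0))

  # hand-evaluated two-stage prox on one group of two
  gs2 <- raw_groups(2)
  u <- c(2.5, -0.5)                      # soft-threshold of (3, -1) at 0.5
  shrink <- 1 - (0.5 * sqrt(2)) / sqrt(sum(u^2))
  expect_equal(sgl_prox(c(3, -1), 1, 1, 0.5, gs2), u * shrink)
})

test_that("sgl_prox minimizes the prox objective (numerical oracle)", {
  set.seed(4)
  for (i in 1:20) {
    gs <- raw_groups(c(3, 2, 1))
    v <- rnorm(6) * 2
    step <- runif(1, 0.1, 2); lambda <- runif(1, 0, 1.5); alpha <- runif(1)
    w <- sgl_prox(v, step, lambda, alpha, gs)
    f_prox <- prox_objective(w, v, step, lambda, alpha, gs)
    nm <- numeric_prox(v, step, lambda, alpha, gs)
    expect_lte(f_prox, nm$value + 1e-9)
    expect_lt(abs(f_prox - nm$value), 1e-6)
  }
})

test_that("lambda = 0 reproduces the unpenalized logistic fit", {
  set.seed(42)
  n <- 50; d <- 10
  X <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("f", 1:d)))
  beta <- c(rep(1, 3), rep(0, 7))
  y <- ifelse(runif(n) < plogis(X %*% beta), "a", "b")
  fit <- fit_sgl_logistic(X, y, lambda = 0, tol = 1e-13, max_iter = 1e5)
  ref <- glm(I(y == "a") ~ X, family = binomial)
  dec <- predict(fit, X, type = "score")[, "a"]
  dec_ref <- as.vector(cbind(1, X) %*% coef(ref))
  expect_lt(max(abs(dec - dec_ref)), 1e-4)
})

test_that("the recorded objective is monotone and large lambda kills the model", {
  set.seed(7)
  X <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- sample(c("u", "v"), 40, TRUE)
  fit <- fit_sgl_logistic(X, y, lambda = 0.05, alpha = 0.5)
  for (p in fit$objective_paths) expect_true(all(diff(p) <= 1e-10))

  dead <- fit_sgl_logistic(X, y, lambda = 1000)
  expect_true(all(dead$W == 0))
  pred <- predict(dead, X)
  expect_length(unique(pred), 1)      # majority/constant class
  expect_error(fit_sgl_logistic(X, rep("u", 40)), "2 classes")
})

test_that("alpha = 0 yields all-or-none groups", {
  set.seed(8)
  n <- 120
  X <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, paste0("f", 1:12)))
  eta <- rowMeans(X[, 1:6]) * 3
  y <- ifelse(runif(n) < plogis(eta), "a", "b")
  gs <- group_structure(colnames(X),
                        stats::setNames(rep(1:2, each = 6), colnames(X)))
  fit <- fit_sgl_logistic(X, y, gs, lambda = 0.05, alpha = 0)
  w <- fit$W[, 1]
  for (g in gs$groups) {
    expect_true(all(abs(w[g]) < 1e-10) || all(abs(w[g]) > 1e-10))
  }
  # the signal-carrying group survives
  expect_gt(sqrt(sum(w[1:6]^2)), 0)
})

test_that("group-aligned signal concentrates the selected weight in the module", {
  set.seed(10)
  n <- 150; d <- 50
  X <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("f", 1:d)))
  eta <- rowMeans(X[, 1:10]) * 6
  y <- ifelse(runif(n) < plogis(eta), "case", "ctrl")
  gs <- group_structure(colnames(X),
                        stats::setNames(rep(1:5, each = 10), colnames(X)))
  fit <- fit_sgl_logistic(X, y, gs, lambda = 0.1, alpha = 0.1)
  mass <- rowSums(abs(fit$W))
  expect_gte(sum(mass[1:10]) / sum(mass), 0.8)
})

test_that("rank-based AUROC matches pair counting and the pROC reference", {
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.1)
  pos <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(auroc(scores, pos), 8 / 9)      # 8 concordant of 9 pairs
  expect_equal(auroc(rep(1, 6), pos), 0.5)     # all tied
  expect_equal(auroc(as.numeric(pos), pos), 1)
  expect_true(is.na(auroc(scores, rep(TRUE, 6))))

  set.seed(11)
  for (i in 1:5) {
    s <- rnorm(40); lab <- rbinom(40, 1, 0.4)
    expect_equal(auroc(s, lab == 1),
                 as.numeric(pROC::auc(pROC::roc(lab, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("cross-validation is stratified, deterministic, and handles a singleton grid", {
  set.seed(12)
  n <- 100
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- ifelse(runif(n) < plogis(X[, 1] * 2), "a", "b")
  cv1 <- cross_validate_sgl(X, y, lambda_grid = 0.05, alpha_grid = 0.5,
                            n_folds = 4, seed = 3, max_iter = 500, tol = 1e-5)
  expect_equal(cv1$best_lambda, 0.05)
  expect_equal(cv1$best_alpha, 0.5)
  expect_equal(nrow(cv1$table), 4)
  cv2 <- cross_validate_sgl(X, y, lambda_grid = 0.05, alpha_grid = 0.5,
                            n_folds = 4, seed = 3, max_iter = 500, tol = 1e-5)
  expect_identical(cv1$table, cv2$table)
  expect_error(cross_validate_sgl(X, c("z", rep(c("a", "b"), len = n - 1)),
                                  n_folds = 5, seed = 1),
               "n_folds")
})

test_that("shuffled labels give chance-level cross-validation AUROC", {
  set.seed(15)
  n <- 120
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- sample(rep(c("a", "b"), each = n / 2))   # labels independent of X
  cv <- cross_validate_sgl(X, y, lambda_grid = c(0.01, 0.05), alpha_grid = 0.5,
                           n_folds = 4, seed = 2, max_iter = 500, tol = 1e-5)
  means <- tapply(cv$table$macro_auroc, paste(cv$table$lambda), mean)
  expect_true(all(abs(means - 0.5) < 0.15))
})

test_that("biomarker ranking and evaluation follow the top-k definitions", {
  # constructed model: 10 candidates with hand-set coefficients
  W <- matrix(0, 12, 2, dimnames = list(paste0("mir", sprintf("%02d", 1:12)),
                                        c("tumor", "normal")))
  W[1:10, 1] <- seq(1, 0.1, length.out = 10)
  model <- structure(
    list(W = W, intercepts = c(tumor = 0, normal = 0), lambda = 1, alpha = 0.5,
         groups = group_structure(rownames(W)), class_labels = c("tumor", "normal"),
         convergence = tibble::tibble()),
    class = "sgl_model"
  )
  ranked <- rank_biomarkers(model)
  expect_equal(nrow(ranked), 10)
  expect_identical(ranked$feature_id[1], "mir01")

  known <- c(paste0("mir", sprintf("%02d", c(1, 3, 4, 5))),
             paste0("other", 1:4))                 # 4 of top-5, |known| = 8
  ev <- rank_and_evaluate_biomarkers(model, known, k_list = 5)
  expect_equal(ev$precision, 0.8)
  expect_equal(ev$recall, 0.5)

  # saturation and disjoint edge cases
  expect_equal(rank_and_evaluate_biomarkers(model, ranked$feature_id,
                                            k_list = c(2, 10))$precision,
               c(1, 1))
  ev0 <- rank_and_evaluate_biomarkers(model, "absent", k_list = 5)
  expect_equal(ev0$precision, 0)
  expect_equal(ev0$recall, 0)
  expect_warning(rank_and_evaluate_biomarkers(model, known, k_list = 50),
                 "truncated")
})
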