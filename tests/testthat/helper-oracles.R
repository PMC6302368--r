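# Independent oracles and fixture builders shared across tests.

# naive counting oracle for the cosine similarity of binary vectors
brute_cosine_binary <- function(a, b) {
  shared <- 0L
  for (i in seq_along(a)) if (a[i] == 1 && b[i] == 1) shared <- shared + 1L
  na <- sum(a == 1); nb <- sum(b == 1)
  if (na == 0 || nb == 0) return(0)
  shared / (sqrt(na) * sqrt(nb))
}

# all set partitions of n elements (restricted growth strings)
all_partitions <- function(n) {
  out <- vector("list", 0)
  rec <- function(a, k, i) {
    if (i > n) {
      out[[length(out) + 1]] <<- a
      return(invisible(NULL))
    }
    for (j in seq_len(k + 1)) {
      a[i] <- j
      rec(a, max(k, j), i + 1)
    }
  }
  rec(integer(n), 0L, 1L)
  out
}

# exhaustive-search modularity optimum of a small similarity network
exhaustive_modularity_opt <- function(net) {
  ids <- net$node_ids
  qs <- vapply(all_partitions(length(ids)), function(p) {
    modularity_score(net, stats::setNames(p, ids))
  }, 0)
  max(qs)
}

# wrap a symmetric weight matrix as a similarity_network fixture
make_network <- function(M, ids = paste0("n", seq_len(nrow(M)))) {
  dimnames(M) <- list(ids, ids)
  structure(
    list(node_ids = ids, M = M, beta = 1, threshold = NULL,
         r2_by_threshold = NULL, dropped_nodes = character(),
         n_nonisolated = sum(rowSums(M > 0) > 0)),
    class = "similarity_network"
  )
}

# random weighted graph fixture with at least one edge
random_network <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  repeat {
    M <- matrix(0, n, n)
    up <- upper.tri(M)
    w <- ifelse(stats::runif(sum(up)) < p, stats::runif(sum(up), 0.1, 1), 0)
    M[up] <- w
    M <- M + t(M)
    if (any(M > 0)) return(make_network(M))
  }
}

# graph with an exact k^(-2) degree sequence (edge weight `w`) flooded by
# Erdos-Renyi noise edges at a lower weight; fit crosses r2 = 0.8 between
# thresholds 0.30 and 0.35
powerlaw_noise_network <- function(seed = 7, C = 400, kmax = 30,
                                   w_pl = 0.6, w_noise = 0.3, p_noise = 0.5) {
  set.seed(seed)
  deg <- unlist(lapply(seq_len(kmax), function(k) rep(k, round(C * k^-2))))
  deg <- deg[deg > 0]
  if (sum(deg) %% 2 == 1) deg <- c(deg, 1)
  g <- igraph::sample_degseq(deg, method = "fast.heur.simple")
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE) * w_pl
  n <- length(deg)
  noise <- matrix(0, n, n)
  up <- upper.tri(noise)
  noise[up] <- ifelse(stats::runif(sum(up)) < p_noise, w_noise, 0)
  noise <- noise + t(noise)
  make_network(pmax(A, noise))
}

# objective of the prox subproblem: (1/2)||w - v||^2 + step * penalty(w)
prox_objective <- function(w, v, step, lambda, alpha, groups) {
  gl <- sum(vapply(seq_along(groups$groups), function(i) {
    groups$weights[i] * sqrt(sum(w[groups$groups[[i]]]^2))
  }, 0))
  sum((w - v)^2) / 2 +
    step * (lambda * alpha * sum(abs(w)) + lambda * (1 - alpha) * gl)
}

# numerical prox minimization; the objective separates over groups, so each
# low-dimensional group subproblem is minimized on its own (restarted
# Nelder-Mead, golden-section for singleton groups)
numeric_prox <- function(v, step, lambda, alpha, groups) {
  w_out <- numeric(length(v))
  total <- 0
  for (i in seq_along(groups$groups)) {
    g <- groups$groups[[i]]
    sub_obj <- function(w) {
      sum((w - v[g])^2) / 2 +
        step * lambda * alpha * sum(abs(w)) +
        step * lambda * (1 - alpha) * groups$weights[i] * sqrt(sum(w^2))
    }
    if (length(g) == 1) {
      r <- stats::optimize(sub_obj, lower = -abs(v[g]) - 1, upper = abs(v[g]) + 1,
                           tol = 1e-12)
      # the kink at zero can defeat golden section; compare with 0 explicitly
      if (sub_obj(0) < r$objective) r <- list(minimum = 0, objective = sub_obj(0))
      w_out[g] <- r$minimum
      total <- total + r$objective
    } else {
      best <- Inf; wb <- v[g]
      for (start in list(v[g], numeric(length(g)))) {
        w <- start
        for (rep in 1:6) {
          r <- stats::optim(w, sub_obj, method = "Nelder-Mead",
                            control = list(maxit = 20000, reltol = 1e-16))
          w <- r$par
        }
        val <- sub_obj(w)
        if (val < best) { best <- val; wb <- w }
      }
      w_out[g] <- wb
      total <- total + best
    }
  }
  list(value = total, par = w_out)
}

# ad-hoc group structure over feature indices (bypasses the constructor's
# ID plumbing for penalty-level tests)
raw_groups <- function(sizes) {
  idx <- split(seq_len(sum(sizes)), rep(seq_along(sizes), sizes))
  structure(
    list(groups = unname(idx), weights = sqrt(sizes),
         feature_ids = paste0("x", seq_len(sum(sizes)))),
    class = "group_structure"
  )
}

# bivariate normal sample with population correlation rho
rbvn <- function(n, rho) {
  x <- stats::rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(x, y)
}

# study conditions of the module-structured stage-signal experiment
stage_signal_cohort <- function(seed) {
  simulate_cohort(
    n_mirna = 60, n_mrna = 60, n_modules = 4, mirnas_per_module = 10,
    targets_per_module = 10, subtype_sizes = c(A = 150),
    corr_scheme = matrix(-0.3, 4, 1), stage_classes = 5,
    relevant_modules = 1, effect_size = 8, noise_sd = 0.5, seed = seed
  )
}
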