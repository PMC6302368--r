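test_that("modularity matches its closed forms", {
  # any graph, single community: the two terms cancel exactly
  net <- random_network(12, p = 0.5, seed = 2)
  one <- stats::setNames(rep(1L, 12), net$node_ids)
  expect_equal(modularity_score(net, one), 0)

  # two disconnected equal cliques split as the cliques: Q = 1/2
  K <- matrix(1, 5, 5); diag(K) <- 0
  M <- rbind(cbind(K, matrix(0, 5, 5)), cbind(matrix(0, 5, 5), K))
  cliq <- make_network(M)
  split2 <- stats::setNames(rep(1:2, each = 5), cliq$node_ids)
  expect_equal(modularity_score(cliq, split2), 0.5)

  # all singletons: Q = -sum (k_p / 2m)^2
  singletons <- stats::setNames(seq_len(12), net$node_ids)
  k <- rowSums(net$M); two_m <- sum(net$M)
  expect_equal(modularity_score(net, singletons), -sum((k / two_m)^2))
})

test_that("modularity agrees with the igraph implementation", {
  for (s in 1:10) {
    net <- random_network(15, p = 0.4, seed = s)
    set.seed(s)
    mu <- stats::setNames(sample(1:4, 15, replace = TRUE), net$node_ids)
    g <- as_igraph(net)
    expect_equal(modularity_score(net, mu),
                 igraph::modularity(g, mu[net$node_ids],
                                    weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("louvain recovers obvious community structure", {
  K <- matrix(1, 5, 5); diag(K) <- 0
  M <- rbind(cbind(K, matrix(0, 5, 5)), cbind(matrix(0, 5, 5), K))
  cliq <- make_network(M)
  part <- louvain_modules(cliq, seed = 1)
  expect_length(unique(part$assignment), 2)
  expect_equal(part$modularity, 0.5)
  # the exhaustive optimum over all partitions of the 10 nodes is also 0.5
  expect_equal(part$modularity, exhaustive_modularity_opt(cliq))

  # a single triangle cannot be improved by splitting
  tri <- make_network(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3) * 0.8)
  expect_length(unique(louvain_modules(tri, seed = 1)$assignment), 1)
})

test_that("louvain is deterministic given a seed and reports a coherent hierarchy", {
  net <- random_network(40, p = 0.2, seed = 8)
  p1 <- louvain_modules(net, seed = 5)
  p2 <- louvain_modules(net, seed = 5)
  expect_identical(p1$assignment, p2$assignment)
  # stored modularity equals the functional on (graph, assignment)
  expect_equal(p1$modularity, modularity_score(net, p1$assignment),
               tolerance = 1e-9)
  q <- vapply(p1$levels, function(mu) modularity_score(net, mu), 0)
  best <- which.max(q)
  expect_equal(p1$modularity, max(q))
  expect_true(all(diff(q[seq_len(best)]) >= -1e-12))
  # every node appears exactly once
  expect_setequal(names(p1$assignment), net$node_ids)
})

test_that("nmi matches hand-computed contingency cases and its invariances", {
  p1 <- stats::setNames(c(1, 1, 2, 2), letters[1:4])
  expect_equal(nmi(p1, p1), 1)
  relabeled <- stats::setNames(c(9, 9, 4, 4), letters[1:4])
  expect_equal(nmi(p1, relabeled), 1)
  crossed <- stats::setNames(c(1, 2, 1, 2), letters[1:4])  # {ac | bd}
  expect_equal(nmi(p1, crossed), 0)
  single <- stats::setNames(rep(1, 4), letters[1:4])
  expect_equal(nmi(single, crossed), 0)
  expect_equal(nmi(single, single), 1)
  expect_error(nmi(p1, stats::setNames(1:2, c("x", "y"))), "no nodes")

  set.seed(23)
  for (i in 1:10) {
    a <- stats::setNames(sample(1:3, 20, TRUE), paste0("n", 1:20))
    b <- stats::setNames(sample(1:4, 20, TRUE), paste0("n", 1:20))
    expect_equal(nmi(a, b), nmi(b, a))
    expect_gte(nmi(a, b), 0); expect_lte(nmi(a, b), 1)
    perm <- stats::setNames(c(7, 5, 9)[a], names(a))
    expect_equal(nmi(a, b), nmi(perm, b))
  }
})

test_that("nmi cross-checks against igraph's implementation", {
  set.seed(14)
  for (i in 1:10) {
    a <- stats::setNames(sample(1:4, 30, TRUE), paste0("n", 1:30))
    b <- stats::setNames(sample(1:3, 30, TRUE), paste0("n", 1:30))
    expect_equal(nmi(a, b), igraph::compare(a, b, method = "nmi"),
                 tolerance = 1e-12)
  }
})

test_that("the consistency matrix is symmetric with unit diagonal", {
  net1 <- random_network(20, p = 0.3, seed = 1)
  part <- louvain_modules(net1, seed = 1)
  cm <- module_consistency_matrix(list(x = part, y = part))
  expect_equal(cm["x", "y"], 1)

  # partitions of independent random graphs agree only weakly
  parts <- lapply(1:4, function(s) louvain_modules(random_network(30, 0.25, s),
                                                   seed = s))
  names(parts) <- paste0("a", 1:4)
  cm2 <- module_consistency_matrix(parts)
  expect_identical(cm2, t(cm2))
  expect_equal(unname(diag(cm2)), rep(1, 4))
  off <- cm2[upper.tri(cm2)]
  expect_lt(mean(off), 0.5)

  # disjoint node sets are flagged missing
  p_other <- stats::setNames(c(1, 2), c("zz1", "zz2"))
  cm3 <- module_consistency_matrix(list(a = part,
                                        b = new_partition <- structure(
                                          list(assignment = p_other,
                                               modularity = NA_real_,
                                               levels = list(), seed = 1L),
                                          class = "module_partition")))
  expect_true(is.na(cm3["a", "b"]))
})

test_that("module assignments round-trip through TSV", {
  net <- random_network(15, p = 0.4, seed = 6)
  part <- louvain_modules(net, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_modules(part, path)
  back <- read_modules(path)
  expect_equal(nmi(part, back), 1)
  expect_identical(sort(names(back$assignment)), sort(names(part$assignment)))
})
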