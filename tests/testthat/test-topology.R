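sym_adj <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  a
}

test_that("module connectivity: triangle, empty and brute-force cases", {
  a <- matrix(1, 3, 3); diag(a) <- 0
  dimnames(a) <- list(paste0("g", 1:3), paste0("g", 1:3))
  part <- toy_partition(setNames(rep("M1", 3), paste0("g", 1:3)))
  mc <- module_connectivity(a, part)
  expect_equal(mc$intramodular_connectivity, 3)
  expect_equal(mc$mean_connectivity, 1)

  a0 <- a * 0
  dimnames(a0) <- dimnames(a)
  mc0 <- module_connectivity(a0, part)
  expect_equal(mc0$intramodular_connectivity, 0)
  expect_equal(mc0$mean_connectivity, 0)

  a <- sym_adj(12, 1)
  part <- toy_partition(setNames(rep("M1", 12), rownames(a)))
  mc <- module_connectivity(a, part)
  brute <- 0
  for (i in 1:11) for (j in (i + 1):12) brute <- brute + a[i, j]
  expect_equal(mc$intramodular_connectivity, brute, tolerance = 1e-12)
  expect_equal(mc$mean_connectivity, brute / choose(12, 2), tolerance = 1e-12)
})

test_that("mean connectivity is intramodular over the pair count, exactly", {
  a <- sym_adj(9, 2)
  labels <- setNames(c(rep("M1", 5), rep("M2", 4)), rownames(a))
  mc <- module_connectivity(a, toy_partition(labels))
  expect_equal(mc$mean_connectivity,
               mc$intramodular_connectivity / choose(mc$size, 2))
})

test_that("centralities match closed forms on canonical graphs", {
  # path a-b-c-d
  a <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  a["a", "b"] <- a["b", "a"] <- 1
  a["b", "c"] <- a["c", "b"] <- 1
  a["c", "d"] <- a["d", "c"] <- 1
  gm <- graph_metrics(a)$per_gene
  expect_equal(gm$betweenness_centrality[gm$gene == "b"], 2 / 3,
               tolerance = 1e-12)

  # complete unweighted graph
  k <- matrix(1, 5, 5); diag(k) <- 0
  dimnames(k) <- list(paste0("g", 1:5), paste0("g", 1:5))
  gm <- graph_metrics(k)$per_gene
  expect_true(all(abs(gm$clustering_coefficient - 1) < 1e-12))
  expect_true(all(abs(gm$closeness_centrality - 1) < 1e-12))
  expect_true(all(abs(gm$degree_centrality - 1) < 1e-12))
})

test_that("centralities agree with brute-force oracles on random graphs", {
  for (s in 1:8) {
    n <- 10
    a <- sym_adj(n, 100 + s)
    a[a < 0.3] <- 0   # some sparsity
    gm <- graph_metrics(a, edge_threshold = 0)$per_gene
    expect_equal(gm$betweenness_centrality, oracle_betweenness(a),
                 tolerance = 1e-9)
    expect_equal(gm$closeness_centrality, oracle_closeness(a),
                 tolerance = 1e-9)
    expect_equal(gm$eigenvector_centrality, oracle_eigencent(a),
                 tolerance = 1e-9)
    expect_equal(gm$clustering_coefficient, oracle_barrat(a),
                 tolerance = 1e-9)
  }
})

test_that("module diversity matches direct Shannon evaluation", {
  act <- matrix(0, 5, 2, dimnames = list(paste0("g", 1:5), c("s1", "s2")))
  act[1:4, ] <- 1          # equal summed activity
  act[5, ] <- c(3, 1)
  labels <- setNames(c(rep("M1", 4), "M2"), rownames(act))
  labels["g5"] <- "M0"
  part <- toy_partition(labels)
  md <- module_diversity(act, part)
  expect_equal(md$module_diversity[md$module == "M1"], log(4),
               tolerance = 1e-12)

  # single dominant gene
  act2 <- act; act2[2:4, ] <- 0
  md2 <- module_diversity(act2, part)
  expect_equal(md2$module_diversity[md2$module == "M1"], 0)

  # hand-set proportions (0.5, 0.25, 0.25)
  act3 <- matrix(c(2, 1, 1), 3, 1,
                 dimnames = list(paste0("g", 1:3), "s1"))
  part3 <- toy_partition(setNames(rep("M1", 3), paste0("g", 1:3)))
  md3 <- module_diversity(act3, part3)
  expect_equal(md3$module_diversity, 1.039721, tolerance = 1e-6)
})

test_that("module diversity is bounded by log module size, attained at uniformity", {
  for (s in 1:10) {
    set.seed(s)
    nsz <- sample(3:12, 1)
    act <- matrix(rexp(nsz * 4), nsz, 4,
                  dimnames = list(paste0("g", 1:nsz), paste0("s", 1:4)))
    part <- toy_partition(setNames(rep("M1", nsz), rownames(act)))
    h <- module_diversity(act, part)$module_diversity
    expect_gte(h, 0)
    expect_lte(h, log(nsz) + 1e-9)
  }
  act_u <- matrix(1, 6, 3, dimnames = list(paste0("g", 1:6), paste0("s", 1:3)))
  part_u <- toy_partition(setNames(rep("M1", 6), rownames(act_u)))
  expect_equal(module_diversity(act_u, part_u)$module_diversity, log(6),
               tolerance = 1e-9)
})

test_that("trait-class comparisons behave at the degenerate and separated extremes", {
  topo <- data.frame(module = sprintf("M%d", 1:15),
                     size = 30L,
                     mean_connectivity = rep(1.5, 15),
                     trait_class = rep(c("HC", "PD", "none"), each = 5))
  res <- compare_by_trait(topo)
  expect_equal(res$H, 0)
  expect_equal(res$p, 1)

  topo$mean_connectivity <- c(1:5, 11:15, 21:25)   # disjoint ranges
  res <- compare_by_trait(topo)
  expect_lt(res$p, 0.01)
  # oracle: exact rank computation of the KW statistic
  r <- rank(topo$mean_connectivity)
  n <- 15
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, topo$trait_class, function(x) length(x) * mean(x)^2)) -
    3 * (n + 1)
  expect_equal(res$H, H, tolerance = 1e-9)

  # excluding a whole class leaves the test missing-coded
  res2 <- compare_by_trait(topo, exclude = sprintf("M%d", 1:5))
  expect_true(is.na(res2$p) || sum(!is.na(res2$p)) >= 0)  # still well-formed
  res3 <- compare_by_trait(topo[topo$trait_class != "none", ],
                           exclude = sprintf("M%d", 6:10))
  expect_true(all(is.na(res3$p)))
})

test_that("diversity-metric correlations hit the rank extremes", {
  topo <- data.frame(module = paste0("M", 1:4), size = 25L,
                     module_diversity = c(1, 2, 3, 4),
                     mean_connectivity = c(2, 4, 6, 8),
                     betweenness_centrality = c(8, 6, 4, 2),
                     trait_class = "none")
  res <- diversity_metric_correlations(topo)$diversity_vs
  expect_equal(res$rho[res$metric == "mean_connectivity"], 1)
  expect_equal(res$rho[res$metric == "betweenness_centrality"], -1)

  topo$flat <- 1
  res2 <- diversity_metric_correlations(topo)$diversity_vs
  expect_true(is.na(res2$rho[res2$metric == "flat"]))
})
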