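# deterministic correlated expression: two planted blocks plus noise genes
block_expr <- function(n_per_block = 30, n_noise = 0, n_samples = 40,
                       r = 0.9, seed = 1) {
  set.seed(seed)
  blocks <- list()
  for (b in 1:2) {
    f <- rnorm(n_samples)
    blocks[[b]] <- t(sapply(seq_len(n_per_block), function(i)
      sqrt(r) * f + sqrt(1 - r) * rnorm(n_samples)))
  }
  x <- do.call(rbind, blocks)
  if (n_noise > 0) x <- rbind(x, matrix(rnorm(n_noise * n_samples), n_noise))
  rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%02d", seq_len(n_samples))
  x
}

test_that("signed adjacency hits its closed-form anchor points", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),          # cor +1
             c = c(4, 3, 2, 1),                             # cor -1 with a
             d = c(1, -1, -1, 1))                           # cor 0 with a
  colnames(x) <- paste0("s", 1:4)
  net <- signed_adjacency(x, beta = 17)
  a <- net$adjacency
  expect_equal(a["a", "b"], 1, tolerance = 1e-12)
  expect_equal(a["a", "c"], 0, tolerance = 1e-12)
  expect_equal(a["a", "d"], 0.5^17, tolerance = 1e-12)

  x <- rbind(x, flat = c(1, 1, 1, 1))
  expect_error(signed_adjacency(x, 6), "zero-variance")
})

test_that("scale-free fit recognizes a power-law degree distribution", {
  set.seed(4)
  # continuous power-law sample: p(k) ~ k^-2
  k <- (1 - runif(2000))^(-1 / 1.0)
  sf <- scale_free_fit(log10(k) * 0 + k)
  expect_gt(sf$fit, 0.95)
  expect_lt(sf$slope, 0)

  # a distribution concentrated at high k must score negatively
  sf_bad <- scale_free_fit(sqrt(runif(2000)))
  expect_lt(sf_bad$fit, 0)
})

test_that("power selection takes the first crossing and honours edge cases", {
  sft <- data.frame(power = c(5L, 10L, 14L, 17L, 20L),
                    fit = c(0.2, 0.55, 0.84, 0.918, 0.95))
  expect_identical(pick_soft_power(sft, 0.9), 17L)
  expect_identical(pick_soft_power(sft, 0), 5L)
  expect_warning(b <- pick_soft_power(sft, 0.99), "maximum fit")
  expect_identical(b, 20L)
})

test_that("soft threshold scan wires the rule to computed fits", {
  x <- block_expr(20, 20, seed = 2)
  scan <- suppressWarnings(soft_threshold_scan(x, powers = c(2L, 6L, 12L),
                                               r2_cut = 0))
  ok <- which(scan$sft_table$fit >= 0)
  expected <- if (length(ok)) scan$sft_table$power[min(ok)] else
    scan$sft_table$power[which.max(scan$sft_table$fit)]
  expect_identical(scan$beta, expected)
  expect_equal(nrow(scan$sft_table), 3L)
  expect_true(all(diff(scan$sft_table$mean_k) < 0))
})

test_that("topological overlap matches closed forms and a brute-force oracle", {
  ones <- matrix(1, 3, 3); diag(ones) <- 0
  tom <- topological_overlap(ones)
  expect_equal(tom, matrix(1, 3, 3), ignore_attr = TRUE)

  zeros <- matrix(0, 4, 4)
  tom <- topological_overlap(zeros)
  expect_equal(tom, diag(4), ignore_attr = TRUE)

  for (s in 1:20) {
    set.seed(s)
    a <- matrix(runif(15 * 15), 15)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    expect_equal(topological_overlap(a), oracle_tom(a), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("module eigengene matches an independent eigendecomposition", {
  x <- block_expr(20, 0, seed = 3)[1:20, ]
  me <- module_eigengene(x, rownames(x))
  xs <- t(scale(t(x)))
  ev <- eigen(crossprod(xs))           # sample-space covariance
  expect_equal(attr(me, "var_explained"),
               ev$values[1] / sum(ev$values), tolerance = 1e-10)
  expect_equal(sum(me^2), 1, tolerance = 1e-12)

  # identical standardized profiles: eigengene correlates 1 with each member
  y <- matrix(rep(rnorm(30), each = 4), 4, byrow = FALSE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:30)))
  me_y <- module_eigengene(y, rownames(y))
  expect_equal(unname(cor(me_y, y[1, ])), 1, tolerance = 1e-9)

  # global sign flip is undone by the orientation rule
  me_flip <- module_eigengene(-x, rownames(x))
  expect_gt(mean(cor(me_flip, t(t(scale(t(-x)))))), 0)
})

test_that("module cutting recovers planted blocks and enforces minimum size", {
  x <- block_expr(30, 30, seed = 5)
  net <- topological_overlap(signed_adjacency(x, 6))
  part <- cut_modules(net$tom, x, min_module_size = 20)
  lab <- part$labels
  b1 <- lab[sprintf("g%03d", 1:30)]
  b2 <- lab[sprintf("g%03d", 31:60)]
  expect_length(unique(b1), 1L)
  expect_length(unique(b2), 1L)
  expect_false(unique(b1) == unique(b2))
  expect_true(all(unique(b1) != "M0"))

  # fewer genes than the minimum: everything unassigned
  y <- block_expr(5, 0, seed = 6)
  net_y <- topological_overlap(signed_adjacency(y, 6))
  expect_warning(part_y <- cut_modules(net_y$tom, y, min_module_size = 20),
                 "unassigned")
  expect_true(all(part_y$labels == "M0"))
})

test_that("modules with near-identical eigengenes are merged", {
  # topology says two blocks, expression says one driver: the eigengene
  # dissimilarity (~0 < 0.18) must fuse the topological clusters
  set.seed(7)
  tom <- matrix(0.05, 60, 60)
  tom[1:30, 1:30] <- 0.9
  tom[31:60, 31:60] <- 0.9
  diag(tom) <- 1
  dimnames(tom) <- list(sprintf("g%03d", 1:60), sprintf("g%03d", 1:60))
  f <- rnorm(40)
  x <- t(sapply(1:60, function(i) sqrt(.9) * f + sqrt(.1) * rnorm(40)))
  dimnames(x) <- list(rownames(tom), sprintf("s%02d", 1:40))
  part <- cut_modules(tom, x, min_module_size = 20, merge_dissim = 0.18)
  mods <- setdiff(unique(part$labels), "M0")
  expect_length(mods, 1L)
  expect_gt(length(part$merge_log), 0L)
})

test_that("partition is stable under gene order permutation", {
  x <- block_expr(25, 20, seed = 8)
  net1 <- topological_overlap(signed_adjacency(x, 6))
  part1 <- cut_modules(net1$tom, x)
  perm <- sample(nrow(x))
  net2 <- topological_overlap(signed_adjacency(x[perm, ], 6))
  part2 <- cut_modules(net2$tom, x[perm, ])
  l1 <- part1$labels[rownames(x)]
  l2 <- part2$labels[rownames(x)]
  expect_equal(unname(l1 == "M0"), unname(l2 == "M0"))
  tab <- table(l1, l2)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("module-trait association reproduces the t-distribution p-value", {
  n <- 95
  ind <- c(rep(0, 48), rep(1, 47))
  z <- (ind - mean(ind)) / sd(ind)
  set.seed(9)
  e <- residuals(lm(rnorm(n) ~ z))
  e <- e / sd(e)
  me <- 0.3 * z + sqrt(1 - 0.09) * e
  eig <- matrix(me, ncol = 1, dimnames = list(paste0("s", 1:n), "M1"))
  part <- toy_partition(setNames(rep("M1", 2), c("g1", "g2")),
                        eigengenes = eig)
  meta <- data.frame(sample_id = paste0("s", 1:n),
                     group = ifelse(ind == 1, "PD", "HC"))
  part <- module_trait(part, meta)
  expect_equal(part$trait_stats$r, 0.3, tolerance = 1e-9)
  expect_equal(part$trait_stats$p, 0.003140077, tolerance = 1e-6)
  expect_equal(part$trait_stats$trait_class, "PD")

  # eigengene equal to the (standardized) indicator: r = 1, p ~ 0
  eig2 <- matrix(z, ncol = 1, dimnames = list(paste0("s", 1:n), "M1"))
  part2 <- toy_partition(part$labels, eigengenes = eig2)
  part2 <- module_trait(part2, meta)
  expect_gt(part2$trait_stats$r, 0.999)
  expect_lt(part2$trait_stats$p, 1e-12)
})

test_that("null eigengenes are flagged at the nominal rate", {
  set.seed(10)
  n <- 60
  meta <- data.frame(sample_id = paste0("s", 1:n),
                     group = rep(c("HC", "PD"), each = n / 2))
  hits <- replicate(100, {
    eig <- matrix(rnorm(n), ncol = 1,
                  dimnames = list(paste0("s", 1:n), "M1"))
    part <- toy_partition(c(g1 = "M1", g2 = "M1"), eigengenes = eig)
    module_trait(part, meta)$trait_stats$p < 0.05
  })
  expect_lt(abs(mean(hits) - 0.05), 2.576 * sqrt(0.05 * 0.95 / 100) + 0.01)
})
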