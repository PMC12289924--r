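# Independent oracle implementations used to check the package's fast paths.
# These are deliberately naive (loops, enumeration, grid search) and share no
# code with the implementation.

# O(n^3) topological overlap by explicit triple loop
oracle_tom <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# all-pairs shortest paths with path counting (Floyd-Warshall style) on
# distance = 1/weight; returns normalized betweenness
oracle_betweenness <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  cnt <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && a[i, j] > 0) { d[i, j] <- 1 / a[i, j]; cnt[i, j] <- 1 }
  }
  diag(d) <- 0; diag(cnt) <- 1
  # path counts via repeated relaxation through intermediates
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || i == k || j == k) next
    alt <- d[i, k] + d[k, j]
    if (alt < d[i, j] - 1e-12) { d[i, j] <- alt; cnt[i, j] <- cnt[i, k] * cnt[k, j] }
    else if (is.finite(alt) && abs(alt - d[i, j]) <= 1e-12)
      cnt[i, j] <- cnt[i, j] + cnt[i, k] * cnt[k, j]
  }
  # dependency accumulation by enumerating intermediates
  btw <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(d[s, t])) next
      through <- abs(d[s, v] + d[v, t] - d[s, t]) <= 1e-12
      if (through && cnt[s, t] > 0)
        tot <- tot + cnt[s, v] * cnt[v, t] / cnt[s, t]
    }
    btw[v] <- tot
  }
  btw / ((n - 1) * (n - 2) / 2)
}

oracle_closeness <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && a[i, j] > 0) d[i, j] <- 1 / a[i, j]
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  vapply(seq_len(n), function(i) {
    di <- d[i, -i]; r <- sum(is.finite(di))
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(di[is.finite(di)]))
  }, numeric(1))
}

# power-iteration-free eigenvector centrality via dense eigendecomposition
oracle_eigencent <- function(a) {
  ev <- eigen(a, symmetric = TRUE)$vectors[, 1]
  if (sum(ev) < 0) ev <- -ev
  abs(ev) / sqrt(sum(ev^2))
}

# Barrat weighted clustering coefficient by explicit loops
oracle_barrat <- function(a) {
  n <- nrow(a)
  deg <- rowSums(a > 0)
  s <- rowSums(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (deg[i] < 2) { out[i] <- 0; next }
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      if (a[i, j] > 0 && a[i, h] > 0 && a[j, h] > 0)
        acc <- acc + (a[i, j] + a[i, h]) / 2
    }
    out[i] <- acc / (s[i] * (deg[i] - 1))
  }
  out
}

# two-sided Fisher exact p by full enumeration of the margin-fixed family
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- dhyper(xs, r1, n - r1, c1)
  p_obs <- dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Yeo-Johnson lambda by grid search over the profile log-likelihood
oracle_yj_lambda <- function(x, grid = seq(-5, 5, by = 0.01)) {
  ll <- vapply(grid, function(l) {
    y <- if (abs(l) > 1e-10) ((x + 1)^l - 1) / l else log1p(x)
    n <- length(y)
    s2 <- var(y) * (n - 1) / n
    -n / 2 * log(s2) + (l - 1) * sum(log1p(abs(x)) * sign(x))
  }, numeric(1))
  grid[which.max(ll)]
}

# GSEA running sum walked step by step
oracle_es <- function(stat, in_set, weight = 1) {
  stat <- unname(stat)
  nr <- sum(abs(stat[in_set])^weight)
  n_miss <- sum(!in_set)
  run <- 0; best <- 0
  for (i in seq_along(stat)) {
    if (in_set[i]) run <- run + abs(stat[i])^weight / nr
    else run <- run - 1 / n_miss
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# type-7 quantile by explicit sorted interpolation
oracle_quantile7 <- function(x, p) {
  xs <- sort(unname(x)); n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[min(lo + 1, n)] - xs[lo])
}

# small deterministic gene feature tables for IO tests
toy_counts <- function(layer = "MG") {
  cm <- matrix(c(10L, 0L, 5L, 3L, 7L, 1L), nrow = 3, byrow = TRUE,
               dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  gene_feature_table(cm, c(g1 = 100L, g2 = 200L, g3 = 150L), layer)
}

# minimal module partition object for unit tests
toy_partition <- function(labels, eigengenes = NULL, trait_stats = NULL) {
  structure(list(labels = labels, eigengenes = eigengenes,
                 trait_stats = trait_stats, merge_log = list(),
                 dendrogram = NULL),
            class = "module_partition")
}

# long-format tensor from a (taxon, ko, sample) value array
toy_tensor <- function(df, rank = "species") {
  structure(df, rank = rank, class = c("taxon_gene_tensor", "data.frame"))
}

small_sim <- function(seed = 1, ...) {
  synth_generate(synthetic_config(
    n_hc = 12, n_pd = 12, n_taxa = 12, n_ko = 80,
    module_sizes = c(20L, 20L), affected_modules = 1L,
    module_taxa = 6L, dropout_taxa = 3L,
    depth_mg = 4e5, depth_mt = 4e5, seed = seed, ...))
}

activity_from_sim <- function(sim) {
  ko <- sim$annotation$ko_id[match(rownames(sim$mg$counts),
                                   sim$annotation$feature_id)]
  mta_ratio(tpm_by_key(sim$mt, ko), tpm_by_key(sim$mg, ko))
}
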