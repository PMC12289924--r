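#' Intramodular and mean connectivity per module
#'
#' Intramodular connectivity is the sum of the module's adjacency submatrix
#' divided by two (each unordered pair once, diagonal excluded); mean
#' connectivity is that sum divided by the number of within-module pairs.
#'
#' @param net A `coexpression_network` (or adjacency matrix).
#' @param part A `module_partition`.
#' @return data.frame: module, size, intramodular_connectivity,
#'   mean_connectivity.
#' @export
module_connectivity <- function(net, part) {
  a <- if (inherits(net, "coexpression_network")) net$adjacency else net
  mods <- setdiff(unique(part$labels), "M0")
  mods <- mods[order(as.integer(sub("^M", "", mods)))]
  rows <- lapply(mods, function(m) {
    g <- names(part$labels)[part$labels == m]
    size <- length(g)
    if (size < 2L) {
      warn_fmt("module %s has a single gene: connectivity 0", m)
      return(data.frame(module = m, size = size,
                        intramodular_connectivity = 0, mean_connectivity = 0))
    }
    sub <- a[g, g]
    diag(sub) <- 0
    intr <- sum(sub) / 2
    data.frame(module = m, size = size, intramodular_connectivity = intr,
               mean_connectivity = intr / (size * (size - 1) / 2))
  })
  do.call(rbind, rows)
}

#' Per-gene graph centralities, averaged per module
#'
#' The adjacency is pruned at `edge_threshold` (edges below it dropped for
#' tractability) and treated as a weighted graph; path-based metrics use
#' distance = 1/weight. Per gene: weighted clustering coefficient (Barrat),
#' degree centrality (strength / (n-1)), closeness on the reachable set with
#' the size correction C(u) = ((r-1)/(n-1)) * ((r-1)/sum d), eigenvector
#' centrality (principal eigenvector of the weighted adjacency, L2
#' normalized), and betweenness normalized by (n-1)(n-2)/2. Isolated or
#' disconnected nodes are handled by the reachable-set correction and logged.
#'
#' @param net A `coexpression_network` (or adjacency matrix).
#' @param part Optional `module_partition`; when given, module means are
#'   returned in addition to the per-gene table.
#' @param edge_threshold Minimum adjacency weight retained as an edge.
#' @return list(per_gene, per_module) of data.frames.
#' @export
graph_metrics <- function(net, part = NULL, edge_threshold = 0.01) {
  a <- if (inherits(net, "coexpression_network")) net$adjacency else net
  diag(a) <- 0
  n <- nrow(a)
  genes <- rownames(a) %||% as.character(seq_len(n))
  a_thr <- a
  a_thr[a_thr < edge_threshold] <- 0
  g <- igraph::graph_from_adjacency_matrix(a_thr, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  w <- igraph::E(g)$weight
  clus <- igraph::transitivity(g, type = "barrat", isolates = "zero")
  if (length(clus) != n) clus <- rep(0, n)
  degree_c <- igraph::strength(g) / (n - 1)
  dmat <- igraph::distances(g, weights = 1 / w)
  closeness_c <- vapply(seq_len(n), function(i) {
    d <- dmat[i, -i]
    reach <- is.finite(d)
    r <- sum(reach)
    if (r == 0L) return(0)
    (r / (n - 1)) * (r / sum(d[reach]))
  }, numeric(1))
  if (any(!is.finite(dmat)))
    log_msg("graph is disconnected at threshold %.3g: closeness used the reachable-set correction",
            edge_threshold)
  ev <- eigen(a_thr, symmetric = TRUE)
  v <- ev$vectors[, 1L]
  if (sum(v) < 0) v <- -v
  eigen_c <- abs(v) / sqrt(sum(v^2))
  btw <- igraph::betweenness(g, weights = 1 / w, directed = FALSE)
  btw <- btw / ((n - 1) * (n - 2) / 2)
  per_gene <- data.frame(gene = genes,
                         clustering_coefficient = clus,
                         degree_centrality = unname(degree_c),
                         closeness_centrality = closeness_c,
                         eigenvector_centrality = eigen_c,
                         betweenness_centrality = unname(btw),
                         stringsAsFactors = FALSE)
  per_module <- NULL
  if (!is.null(part)) {
    per_gene$module <- unname(part$labels[per_gene$gene])
    mods <- setdiff(unique(per_gene$module), "M0")
    mods <- mods[order(as.integer(sub("^M", "", mods)))]
    per_module <- do.call(rbind, lapply(mods, function(m) {
      sub <- per_gene[per_gene$module == m, ]
      data.frame(module = m,
                 clustering_coefficient = mean(sub$clustering_coefficient),
                 degree_centrality = mean(sub$degree_centrality),
                 closeness_centrality = mean(sub$closeness_centrality),
                 eigenvector_centrality = mean(sub$eigenvector_centrality),
                 betweenness_centrality = mean(sub$betweenness_centrality))
    }))
  }
  list(per_gene = per_gene, per_module = per_module)
}

#' Module diversity (mH')
#'
#' Shannon entropy (nats) of the module members' summed activity:
#' mH' = -sum g_i log g_i where g_i is gene i's share of the module's total
#' MT/MG ratio summed over samples. Computed on the untransformed ratio, not
#' the power-transformed matrix used for the network.
#'
#' @param act Activity matrix in raw-ratio state.
#' @param part A `module_partition`.
#' @return data.frame: module, size, module_diversity (NA when the module has
#'   no activity at all).
#' @export
module_diversity <- function(act, part) {
  mods <- setdiff(unique(part$labels), "M0")
  mods <- mods[order(as.integer(sub("^M", "", mods)))]
  rows <- lapply(mods, function(m) {
    genes <- intersect(names(part$labels)[part$labels == m], rownames(act))
    tot <- rowSums(act[genes, , drop = FALSE], na.rm = TRUE)
    h <- if (sum(tot) == 0) NA_real_ else
      as.numeric(vegan::diversity(tot, index = "shannon"))
    data.frame(module = m, size = length(genes), module_diversity = h)
  })
  do.call(rbind, rows)
}

#' Assemble the per-module topology table
#'
#' @param net `coexpression_network`.
#' @param part `module_partition` with trait_stats.
#' @param act Raw-ratio activity matrix (for module diversity).
#' @param edge_threshold Passed to [graph_metrics()].
#' @return data.frame with one row per module: size, connectivity, diversity,
#'   module-averaged centralities and trait_class.
#' @export
module_topology_table <- function(net, part, act, edge_threshold = 0.01) {
  conn <- module_connectivity(net, part)
  gm <- graph_metrics(net, part, edge_threshold)$per_module
  dv <- module_diversity(act, part)
  out <- merge(merge(conn, dv[, c("module", "module_diversity")], by = "module"),
               gm, by = "module")
  if (!is.null(part$trait_stats))
    out <- merge(out, part$trait_stats[, c("module", "trait_class")],
                 by = "module")
  out[order(as.integer(sub("^M", "", out$module))), , drop = FALSE]
}

#' Compare topology metrics across trait-association classes
#'
#' Kruskal-Wallis test of each metric across the HC / PD / none classes,
#' optionally excluding listed modules (e.g. an outlier default module)
#' before testing. Metrics with fewer than two classes of >= 2 modules are
#' missing-coded.
#'
#' @param topo Output of [module_topology_table()].
#' @param exclude Modules to drop before testing.
#' @return data.frame: metric, H, p (NA when not testable).
#' @export
compare_by_trait <- function(topo, exclude = character(0)) {
  topo <- topo[!topo$module %in% exclude, , drop = FALSE]
  metrics <- setdiff(names(topo), c("module", "size", "trait_class"))
  cls <- factor(topo$trait_class)
  rows <- lapply(metrics, function(m) {
    ok <- !is.na(topo[[m]])
    tab <- table(cls[ok])
    if (sum(tab >= 2L) < 2L)
      return(data.frame(metric = m, H = NA_real_, p = NA_real_))
    if (stats::sd(topo[[m]][ok]) == 0)   # all tied: no evidence of difference
      return(data.frame(metric = m, H = 0, p = 1))
    kt <- stats::kruskal.test(topo[[m]][ok], droplevels(cls[ok]))
    data.frame(metric = m, H = unname(kt$statistic), p = kt$p.value)
  })
  do.call(rbind, rows)
}

#' Spearman correlations of module diversity with topology metrics
#'
#' Spearman rho and p for module diversity against every other metric, plus
#' the full metric-vs-metric matrix; BH correction across all tested pairs.
#' Constant metrics are missing-coded.
#'
#' @param topo Output of [module_topology_table()].
#' @return list(diversity_vs = data.frame(metric, rho, p, q),
#'   matrix = data.frame(metric_a, metric_b, rho, p, q)).
#' @export
diversity_metric_correlations <- function(topo) {
  metrics <- setdiff(names(topo), c("module", "trait_class"))
  if (nrow(topo) < 4L) stop_fmt("need >= 4 modules for metric correlations")
  pair_test <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 4L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                           exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  }
  pairs <- utils::combn(metrics, 2L)
  mat <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    res <- pair_test(topo[[pairs[1L, j]]], topo[[pairs[2L, j]]])
    data.frame(metric_a = pairs[1L, j], metric_b = pairs[2L, j],
               rho = res[1L], p = res[2L], stringsAsFactors = FALSE)
  }))
  mat$q <- stats::p.adjust(mat$p, "BH")
  dv <- mat[mat$metric_a == "module_diversity" | mat$metric_b == "module_diversity", ]
  dv$metric <- ifelse(dv$metric_a == "module_diversity", dv$metric_b, dv$metric_a)
  list(diversity_vs = dv[, c("metric", "rho", "p", "q")], matrix = mat)
}
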