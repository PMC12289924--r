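#' Select network-wide hub genes (95th-percentile connectivity)
#'
#' The hub pool is the union of genes in all trait-associated (HC or PD)
#' modules. The threshold is the empirical 95th percentile of their
#' whole-network connectivity (type-7 linear-interpolation quantile); hubs
#' are the pool genes with connectivity >= threshold.
#'
#' @param net A `coexpression_network` (or adjacency matrix).
#' @param part A `module_partition` with trait_stats.
#' @param probs Quantile of the connectivity distribution (default 0.95).
#' @return data.frame: gene, hub_type ("p95"), module, trait_class,
#'   connectivity (kTotal basis); attribute `threshold`.
#' @export
select_hubs_p95 <- function(net, part, probs = 0.95) {
  if (is.null(part$trait_stats)) stop_fmt("partition has no trait_stats")
  assoc <- part$trait_stats$module[part$trait_stats$trait_class != "none"]
  pool <- names(part$labels)[part$labels %in% assoc]
  if (length(pool) == 0L) {
    warn_fmt("no trait-associated module: empty hub set")
    out <- data.frame(gene = character(0), hub_type = character(0),
                      module = character(0), trait_class = character(0),
                      connectivity = numeric(0))
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  k <- connectivity(net)[pool]
  thr <- stats::quantile(k, probs, type = 7, names = FALSE)
  if (length(k) > 1L && stats::sd(k) == 0)
    warn_fmt("all pool connectivities equal: every pool gene selected")
  sel <- names(k)[k >= thr]
  cls <- stats::setNames(part$trait_stats$trait_class, part$trait_stats$module)
  out <- data.frame(gene = sel, hub_type = "p95",
                    module = unname(part$labels[sel]),
                    trait_class = unname(cls[part$labels[sel]]),
                    connectivity = unname(k[sel]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Select intramodular hub genes (top fraction per module)
#'
#' Within each trait-associated module, genes are ranked by intramodular
#' connectivity (within-module adjacency row sum, kWithin) and the top
#' `ceiling(fraction * size)` selected. Ties at the cut are broken by gene id
#' order, so reruns are identical.
#'
#' @param net A `coexpression_network` (or adjacency matrix).
#' @param part A `module_partition` with trait_stats.
#' @param fraction Fraction of each module selected (default 0.10).
#' @return data.frame: gene, hub_type ("imodule"), module, trait_class,
#'   connectivity (kWithin basis).
#' @export
select_hubs_intramodular <- function(net, part, fraction = 0.10) {
  if (fraction <= 0 || fraction >= 1) stop_fmt("fraction must be in (0, 1)")
  if (is.null(part$trait_stats)) stop_fmt("partition has no trait_stats")
  a <- if (inherits(net, "coexpression_network")) net$adjacency else net
  assoc <- part$trait_stats[part$trait_stats$trait_class != "none", ]
  rows <- lapply(assoc$module, function(m) {
    g <- names(part$labels)[part$labels == m]
    sub <- a[g, g, drop = FALSE]
    diag(sub) <- 0
    kw <- rowSums(sub)
    n_take <- ceiling(fraction * length(g))
    ord <- order(-kw, names(kw))
    sel <- names(kw)[ord][seq_len(n_take)]
    data.frame(gene = sel, hub_type = "imodule", module = m,
               trait_class = assoc$trait_class[assoc$module == m],
               connectivity = unname(kw[sel]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(gene = character(0), hub_type = character(0),
                                      module = character(0),
                                      trait_class = character(0),
                                      connectivity = numeric(0))
  rownames(out) <- NULL
  out
}

#' Pathway composition of a hub set
#'
#' Counts hub genes per (module, pathway); genes in several pathways count
#' once per pathway, genes in none fall into an `"unannotated"` bin. The
#' proportion is relative to the module's hub count.
#'
#' @param hubs Hub table from [select_hubs_p95()] or
#'   [select_hubs_intramodular()].
#' @param sets Gene sets from [read_gene_sets()] (may be an empty list).
#' @return data.frame: module, pathway, n_genes, proportion.
#' @export
hub_pathway_profile <- function(hubs, sets) {
  if (nrow(hubs) == 0L)
    return(data.frame(module = character(0), pathway = character(0),
                      n_genes = integer(0), proportion = numeric(0)))
  rows <- list()
  for (m in unique(hubs$module)) {
    genes <- hubs$gene[hubs$module == m]
    n_m <- length(genes)
    hit_any <- rep(FALSE, n_m)
    for (s in names(sets)) {
      hit <- genes %in% sets[[s]]
      if (any(hit))
        rows[[length(rows) + 1L]] <- data.frame(
          module = m, pathway = s, n_genes = sum(hit),
          proportion = sum(hit) / n_m, stringsAsFactors = FALSE)
      hit_any <- hit_any | hit
    }
    if (any(!hit_any))
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, pathway = "unannotated", n_genes = sum(!hit_any),
        proportion = sum(!hit_any) / n_m, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
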