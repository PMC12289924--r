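#' Taxonomic diversity of gene expression (tDGE) for all genes and samples
#'
#' For each (gene, sample), gH' = -sum s_i log s_i (nats) over the taxa
#' expressing the gene, where s_i is the taxon's share of the gene's total
#' normalized expression in that sample. Genes unexpressed in a sample are
#' missing-coded.
#'
#' @param tensor A `taxon_gene_tensor` from [build_tensor()].
#' @param drop_unclassified Exclude the `"unclassified"` taxon bin.
#' @return Matrix genes x samples of tDGE values (NA when unexpressed or the
#'   gene's activity is missing-coded in that sample).
#' @export
tdge_matrix <- function(tensor, drop_unclassified = TRUE) {
  df <- tensor
  if (drop_unclassified) df <- df[df$taxon != "unclassified", , drop = FALSE]
  kos <- sort(unique(df$ko)); samples <- unique(df$sample)
  lin <- match(df$ko, kos) + (match(df$sample, samples) - 1L) * length(kos)
  v <- df$value
  bad <- is.na(v)
  v[bad] <- 0
  vlogv <- ifelse(v > 0, v * log(v), 0)
  tot <- rowsum(v, lin); sumvl <- rowsum(vlogv, lin)
  any_na <- rowsum(as.numeric(bad), lin) > 0
  out <- matrix(NA_real_, length(kos), length(samples),
                dimnames = list(kos, samples))
  pos <- as.integer(rownames(tot))
  h <- ifelse(tot[, 1L] > 0, log(tot[, 1L]) - sumvl[, 1L] / tot[, 1L], NA_real_)
  h[h < 0 & h > -1e-12] <- 0   # clamp numerical negatives
  h[any_na[, 1L]] <- NA_real_
  out[pos] <- h
  out
}

#' tDGE of one gene in one sample
#'
#' @inheritParams tdge_matrix
#' @param gene KO id.
#' @param sample Sample id.
#' @return Shannon entropy in nats (NA when the gene is unexpressed).
#' @export
tdge <- function(tensor, gene, sample, drop_unclassified = TRUE) {
  df <- tensor[tensor$ko == gene & tensor$sample == sample, , drop = FALSE]
  if (nrow(df) == 0L) stop_fmt("gene '%s' not present in the tensor", gene)
  if (drop_unclassified) df <- df[df$taxon != "unclassified", , drop = FALSE]
  if (any(is.na(df$value))) return(NA_real_)
  shannon(df$value)
}

#' Compare tDGE between groups and by hub membership
#'
#' Per gene: mean tDGE per group and the log2 fold change (PD over HC) with
#' pseudocount epsilon = half the minimum positive tDGE, plus a per-gene
#' Mann-Whitney test of the per-sample tDGE values (BH-corrected across
#' genes). Genes with fewer than `min_n` expressed samples in either group
#' are excluded and logged. Distribution-level Mann-Whitney comparisons are
#' run on the per-gene group means: HC vs PD overall, within hub genes,
#' within non-hub genes, and hub vs non-hub.
#'
#' @param tensor A `taxon_gene_tensor`.
#' @param meta Metadata with `sample_id` and `group`.
#' @param hub_genes Character vector of hub (e.g. intramodular hub) gene ids.
#' @param min_n Minimum expressed samples per group for the per-gene test.
#' @return list(per_gene, tests, excluded).
#' @export
tdge_group_compare <- function(tensor, meta, hub_genes = character(0),
                               min_n = 3L) {
  td <- tdge_matrix(tensor)
  meta <- meta[match(colnames(td), meta$sample_id), , drop = FALSE]
  hc <- meta$group == "HC"; pd <- meta$group == "PD"
  n_ok_hc <- rowSums(!is.na(td[, hc, drop = FALSE]))
  n_ok_pd <- rowSums(!is.na(td[, pd, drop = FALSE]))
  keep <- n_ok_hc >= min_n & n_ok_pd >= min_n
  excluded <- rownames(td)[!keep]
  if (length(excluded) > 0L)
    log_msg("%d gene(s) excluded from tDGE comparison (< %d expressed samples per group)",
            length(excluded), min_n)
  td <- td[keep, , drop = FALSE]
  mean_hc <- rowMeans(td[, hc, drop = FALSE], na.rm = TRUE)
  mean_pd <- rowMeans(td[, pd, drop = FALSE], na.rm = TRUE)
  eps <- half_min_positive(td)
  p <- vapply(seq_len(nrow(td)), function(i) {
    x <- td[i, hc]; y <- td[i, pd]
    suppressWarnings(stats::wilcox.test(y[!is.na(y)], x[!is.na(x)],
                                        exact = FALSE)$p.value)
  }, numeric(1))
  per_gene <- data.frame(
    gene = rownames(td), mean_tdge_hc = mean_hc, mean_tdge_pd = mean_pd,
    log2fc_tdge = log2((mean_pd + eps) / (mean_hc + eps)),
    p = p, q = stats::p.adjust(p, "BH"),
    hub = rownames(td) %in% hub_genes,
    stringsAsFactors = FALSE, row.names = NULL)

  mw <- function(x, y) {
    if (length(x) < 2L || length(y) < 2L) return(NA_real_)
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
  }
  overall <- c(per_gene$mean_tdge_hc, per_gene$mean_tdge_pd)
  is_hub <- per_gene$hub
  gene_mean <- rowMeans(cbind(per_gene$mean_tdge_hc, per_gene$mean_tdge_pd))
  tests <- data.frame(
    comparison = c("HC_vs_PD_all", "HC_vs_PD_hub", "HC_vs_PD_nonhub",
                   "hub_vs_nonhub"),
    p = c(mw(per_gene$mean_tdge_hc, per_gene$mean_tdge_pd),
          mw(per_gene$mean_tdge_hc[is_hub], per_gene$mean_tdge_pd[is_hub]),
          mw(per_gene$mean_tdge_hc[!is_hub], per_gene$mean_tdge_pd[!is_hub]),
          mw(gene_mean[is_hub], gene_mean[!is_hub])),
    stringsAsFactors = FALSE)
  list(per_gene = per_gene, tests = tests, excluded = excluded)
}

#' Functional redundancy per sample
#'
#' Species diversity D = 1 - sum p_i^2 (Simpson) over the species' shares of
#' total normalized expression; functional diversity Q = Rao quadratic
#' entropy sum_i sum_j p_i p_j d_ij with d_ij the Gower distance between the
#' species' binary expressed-gene profiles (for binary traits this is the
#' fraction of mismatching genes among genes expressed by either species);
#' functional redundancy FR = D - Q, in [0, D]. Samples with a single active
#' species get FR = 0 by convention (logged).
#'
#' @param tensor A `taxon_gene_tensor` (species rank recommended).
#' @param drop_unclassified Exclude the `"unclassified"` bin.
#' @return data.frame: sample, n_species, species_diversity, rao_q,
#'   functional_redundancy.
#' @export
functional_redundancy <- function(tensor, drop_unclassified = TRUE) {
  df <- tensor
  if (drop_unclassified) df <- df[df$taxon != "unclassified", , drop = FALSE]
  samples <- unique(df$sample)
  rows <- lapply(samples, function(s) {
    sub <- df[df$sample == s & !is.na(df$value) & df$value > 0, , drop = FALSE]
    taxa <- unique(sub$taxon)
    if (length(taxa) < 2L) {
      log_msg("sample %s has %d active species: FR = 0 by convention",
              s, length(taxa))
      return(data.frame(sample = s, n_species = length(taxa),
                        species_diversity = 0, rao_q = 0,
                        functional_redundancy = 0, stringsAsFactors = FALSE))
    }
    ab <- rowsum(sub$value, sub$taxon)[, 1L]
    p <- ab / sum(ab)
    kos <- unique(sub$ko)
    traits <- matrix(FALSE, length(taxa), length(kos),
                     dimnames = list(names(ab), kos))
    traits[cbind(match(sub$taxon, rownames(traits)), match(sub$ko, kos))] <- TRUE
    d <- matrix(0, length(p), length(p))
    for (i in seq_along(p)) for (j in seq_len(i - 1L)) {
      either <- traits[i, ] | traits[j, ]
      d[i, j] <- d[j, i] <- sum(xor(traits[i, ], traits[j, ])) / sum(either)
    }
    D <- 1 - sum(p^2)
    Q <- as.numeric(t(p) %*% d %*% p)
    data.frame(sample = s, n_species = length(p), species_diversity = D,
               rao_q = Q, functional_redundancy = D - Q,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expressed-gene diversity per genus
#'
#' Sums normalized expression per (genus, KO, sample) and computes, per genus
#' and sample: richness (number of genes with expression > 0), Shannon index
#' and inverse Simpson index over the gene-expression proportions. Each
#' (genus, index) pair is compared HC vs PD with a Mann-Whitney test,
#' BH-corrected across genera x indices. Genera absent from the tensor are
#' missing-coded.
#'
#' @param tensor A `taxon_gene_tensor` at genus rank.
#' @param meta Metadata with `sample_id` and `group`.
#' @param genera Character vector of genera of interest.
#' @return list(per_sample, tests).
#' @export
genus_expression_diversity <- function(tensor, meta, genera) {
  samples <- unique(tensor$sample)
  per_sample <- list(); tests <- list()
  for (g in genera) {
    sub <- tensor[tensor$taxon == g, , drop = FALSE]
    if (nrow(sub) == 0L) {
      per_sample[[g]] <- data.frame(genus = g, sample = NA_character_,
                                    richness = NA_integer_,
                                    shannon = NA_real_,
                                    inv_simpson = NA_real_)
      next
    }
    rows <- lapply(samples, function(s) {
      v <- sub$value[sub$sample == s]
      v <- v[!is.na(v) & v > 0]
      if (length(v) == 0L)
        return(data.frame(genus = g, sample = s, richness = 0L,
                          shannon = NA_real_, inv_simpson = NA_real_))
      data.frame(genus = g, sample = s, richness = length(v),
                 shannon = as.numeric(vegan::diversity(v, "shannon")),
                 inv_simpson = as.numeric(vegan::diversity(v, "invsimpson")),
                 stringsAsFactors = FALSE)
    })
    per_sample[[g]] <- do.call(rbind, rows)
  }
  per_sample <- do.call(rbind, per_sample)
  rownames(per_sample) <- NULL
  meta_g <- stats::setNames(meta$group, meta$sample_id)
  present <- per_sample[!is.na(per_sample$sample), , drop = FALSE]
  if (nrow(present) > 0L) {
    present$group <- unname(meta_g[present$sample])
    for (g in unique(present$genus)) for (idx in c("richness", "shannon",
                                                   "inv_simpson")) {
      x <- present[present$genus == g & present$group == "HC", idx]
      y <- present[present$genus == g & present$group == "PD", idx]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      p <- if (length(x) >= 3L && length(y) >= 3L)
        suppressWarnings(stats::wilcox.test(y, x, exact = FALSE)$p.value)
      else NA_real_
      tests[[paste(g, idx)]] <- data.frame(
        genus = g, index = idx,
        mean_hc = if (length(x)) mean(x) else NA_real_,
        mean_pd = if (length(y)) mean(y) else NA_real_,
        p = p, stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, tests)
  if (!is.null(tests)) {
    tests$q <- stats::p.adjust(tests$p, "BH")
    rownames(tests) <- NULL
  }
  list(per_sample = per_sample, tests = tests)
}
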