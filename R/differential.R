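#' Per-gene differential normalized expression
#'
#' Rank-based differential analysis of the MT/MG activity ratio:
#' log2fc = log2((mean_PD + eps) / (mean_HC + eps)) with eps = half the
#' minimum positive group mean, a two-sided Mann-Whitney p per gene, BH q
#' across tested genes, and significance tiers at 0.05 (`q_sig` for q < 0.05,
#' `p_sig` for p < 0.05 only, `ns` otherwise). Genes zero in every sample are
#' excluded. The effect size is a ratio of means because the input is itself
#' a ratio, for which count-model likelihoods are not defined.
#'
#' @param act Activity matrix in raw-ratio state (genes x samples).
#' @param meta Metadata with `sample_id` and `group`.
#' @param alpha Tier threshold.
#' @return data.frame: gene, mean_hc, mean_pd, log2fc_expression, p, q,
#'   group_label (PD iff log2fc > 0), significance_tier.
#' @export
differential_expression <- function(act, meta, alpha = 0.05) {
  meta <- meta[match(colnames(act), meta$sample_id), , drop = FALSE]
  hc <- meta$group == "HC"; pd <- meta$group == "PD"
  if (sum(hc) < 3L || sum(pd) < 3L) stop_fmt("each group needs >= 3 samples")
  nonzero <- rowSums(act > 0 & !is.na(act)) > 0
  act <- act[nonzero, , drop = FALSE]
  mean_hc <- rowMeans(act[, hc, drop = FALSE], na.rm = TRUE)
  mean_pd <- rowMeans(act[, pd, drop = FALSE], na.rm = TRUE)
  eps <- half_min_positive(c(mean_hc, mean_pd))
  p <- vapply(seq_len(nrow(act)), function(i) {
    x <- act[i, hc]; y <- act[i, pd]
    suppressWarnings(stats::wilcox.test(y[!is.na(y)], x[!is.na(x)],
                                        exact = FALSE)$p.value)
  }, numeric(1))
  q <- stats::p.adjust(p, "BH")
  lfc <- log2((mean_pd + eps) / (mean_hc + eps))
  data.frame(
    gene = rownames(act), mean_hc = mean_hc, mean_pd = mean_pd,
    log2fc_expression = lfc, p = p, q = q,
    group_label = ifelse(lfc > 0, "PD", ifelse(lfc < 0, "HC", NA)),
    significance_tier = ifelse(q < alpha, "q_sig",
                               ifelse(p < alpha, "p_sig", "ns")),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Joint classification of expression change and tDGE change
#'
#' Bins each gene by the sign of its expression log2FC (PD vs HC group
#' label), the sign of its tDGE log2FC (up/down), hub membership, and the
#' differential-expression significance tier. Genes with a missing tDGE or a
#' zero log2FC are collected in an `"unclassifiable"` bin; bins plus
#' unclassifiable partition the gene set exactly.
#'
#' @param de Output of [differential_expression()].
#' @param tdge_per_gene Per-gene table from [tdge_group_compare()] (columns
#'   gene, log2fc_tdge).
#' @param hub_genes Character vector of hub gene ids.
#' @return list(genes = per-gene classified table, counts = stacked counts
#'   per (group_label, tdge_direction, hub, significance_tier),
#'   n_unclassifiable).
#' @export
joint_classification <- function(de, tdge_per_gene, hub_genes = character(0)) {
  df <- merge(de, tdge_per_gene[, c("gene", "log2fc_tdge")],
              by = "gene", all.x = TRUE)
  df$hub <- df$gene %in% hub_genes
  df$tdge_direction <- ifelse(is.na(df$log2fc_tdge), NA,
                              ifelse(df$log2fc_tdge > 0, "up",
                                     ifelse(df$log2fc_tdge < 0, "down", NA)))
  unclass <- is.na(df$tdge_direction) | is.na(df$group_label)
  if (any(unclass))
    log_msg("%d gene(s) unclassifiable (missing tDGE or zero fold change)",
            sum(unclass))
  ok <- df[!unclass, , drop = FALSE]
  counts <- as.data.frame(table(group_label = ok$group_label,
                                tdge_direction = ok$tdge_direction,
                                hub = ok$hub,
                                significance_tier = ok$significance_tier),
                          stringsAsFactors = FALSE)
  names(counts)[names(counts) == "Freq"] <- "n"
  list(genes = df, counts = counts, n_unclassifiable = sum(unclass))
}

#' Fisher exact and chi-square tests on a 2x2 table
#'
#' Two-sided Fisher exact p (sum of conditional hypergeometric probabilities
#' of tables at most as probable as the observed one), Pearson chi-square p
#' without continuity correction by default, and the sample odds ratio
#' ad/bc. When a margin is zero the chi-square is missing-coded while the
#' Fisher p remains defined.
#'
#' @param tab 2x2 integer matrix.
#' @param correct Continuity-correct the chi-square test.
#' @return data.frame: odds_ratio, fisher_p, chisq_p.
#' @export
proportion_tests <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop_fmt("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop_fmt("table must hold counts")
  fisher_p <- stats::fisher.test(tab)$p.value
  chisq_p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) NA_real_
  else suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
  num <- tab[1, 1] * tab[2, 2]
  den <- tab[1, 2] * tab[2, 1]
  or <- if (num == 0 && den == 0) NA_real_
  else if (den == 0) Inf
  else num / den
  data.frame(odds_ratio = or, fisher_p = fisher_p, chisq_p = chisq_p)
}
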