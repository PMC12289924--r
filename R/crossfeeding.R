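#' All-pairs Spearman correlations between two gene blocks
#'
#' Every (row of A, row of B) pair is tested with a Spearman correlation
#' (two-sided); BH correction is applied over all pairs of the call.
#' Constant vectors give missing-coded pairs. Counts of positive significant
#' correlations before (p < alpha) and after (q < alpha) FDR correction are
#' attached, matching the convention of counting positive-rho pairs only.
#'
#' @param a,b Numeric matrices, genes x samples, sharing sample columns.
#' @param alpha Significance level for the counts.
#' @return data.frame (gene_a, gene_b, rho, p, q) with attribute `counts`
#'   (n_pairs, positive_p_sig, positive_q_sig).
#' @export
block_correlations <- function(a, b, alpha = 0.05) {
  shared <- intersect(colnames(a), colnames(b))
  if (length(shared) < 4L) stop_fmt("need >= 4 shared samples")
  a <- a[, shared, drop = FALSE]; b <- b[, shared, drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    x <- a[i, ]; y <- b[j, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 4L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      rho <- NA_real_; p <- NA_real_
    } else {
      ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                             exact = FALSE))
      rho <- unname(ct$estimate); p <- ct$p.value
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = rownames(a)[i] %||% as.character(i),
      gene_b = rownames(b)[j] %||% as.character(j),
      rho = rho, p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  attr(out, "counts") <- c(
    n_pairs = nrow(out),
    positive_p_sig = sum(out$rho > 0 & out$p < alpha, na.rm = TRUE),
    positive_q_sig = sum(out$rho > 0 & out$q < alpha, na.rm = TRUE))
  out
}

#' Restrict a tensor to selected genera and aggregate per KO
#'
#' Rows from genera outside the list are dropped (absent genera produce a
#' warning, the rest are retained) and values are summed per (KO, sample).
#'
#' @param tensor A `taxon_gene_tensor` at genus rank.
#' @param genera Non-empty character vector of genus names.
#' @return Matrix KO x sample of summed normalized expression.
#' @export
filter_by_taxa <- function(tensor, genera) {
  if (length(genera) == 0L) stop_fmt("genera list must be non-empty")
  missing <- setdiff(genera, unique(tensor$taxon))
  if (length(missing) > 0L)
    warn_fmt("genera absent from the tensor dropped: %s",
             paste(missing, collapse = ", "))
  df <- tensor[tensor$taxon %in% genera, , drop = FALSE]
  if (nrow(df) == 0L) stop_fmt("no rows retained for the given genera")
  tensor_marginalize(structure(df, class = c("taxon_gene_tensor", "data.frame")))
}

#' Process-level expression sums per genus and sample
#'
#' Sums normalized expression over the member KOs of each process (e.g.
#' microcompartment, flagellar assembly, chemotaxis, transporter gene lists)
#' per genus per sample; long dot-plot-ready table.
#'
#' @param tensor A `taxon_gene_tensor` at genus rank.
#' @param process_lists Named list of KO id vectors.
#' @return data.frame: genus, process, sample, total_expression.
#' @export
process_sums <- function(tensor, process_lists) {
  if (length(process_lists) == 0L) stop_fmt("no process lists given")
  genera <- setdiff(unique(tensor$taxon), "unclassified")
  samples <- unique(tensor$sample)
  rows <- list()
  for (g in genera) {
    sub <- tensor[tensor$taxon == g, , drop = FALSE]
    for (pr in names(process_lists)) {
      prsub <- sub[sub$ko %in% process_lists[[pr]], , drop = FALSE]
      tot <- if (nrow(prsub) > 0L)
        rowsum(ifelse(is.na(prsub$value), 0, prsub$value), prsub$sample)
      else NULL
      vals <- stats::setNames(rep(0, length(samples)), samples)
      if (!is.null(tot)) vals[rownames(tot)] <- tot[, 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        genus = g, process = pr, sample = samples,
        total_expression = unname(vals), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
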