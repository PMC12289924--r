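#' Build the taxon-resolved activity tensor
#'
#' Feature counts are collapsed to (taxon at `rank`, KO) read rates, TPM is
#' computed per sample on each layer, and the tensor value is defined as
#' `MT_TPM[taxon, KO] / MG_TPM[KO]`: the taxon's transcription of a gene over
#' the gene's total DNA-normalized potential. With this construction the
#' tensor marginalizes exactly: summing values over taxa reproduces the
#' KO-level MT/MG activity matrix. Features without a taxon at `rank` are
#' pooled into an `"unclassified"` bin (kept in the tensor, excluded from
#' diversity statistics by default); entries with MT > 0 but MG potential 0
#' are missing-coded as in [mta_ratio()].
#'
#' @param mg,mt `gene_feature_table` objects on identical features/samples.
#' @param annotation Annotation data.frame (feature_id, ko_id, genus, species).
#' @param rank `"genus"` or `"species"`.
#' @return A `taxon_gene_tensor`: long data.frame (taxon, ko, sample, value)
#'   with attributes `rank` and `ko_mg_tpm` (KO-level MG TPM used as the
#'   denominator).
#' @export
build_tensor <- function(mg, mt, annotation, rank = c("species", "genus")) {
  rank <- match.arg(rank)
  if (!identical(rownames(mg$counts), rownames(mt$counts)))
    stop_fmt("MG and MT tables must share identical features")
  ann <- annotation[match(rownames(mg$counts), annotation$feature_id), ]
  if (all(is.na(ann$ko_id))) stop_fmt("no KO annotations cover the features")
  taxon <- ann[[rank]]
  if (all(is.na(taxon))) stop_fmt("rank '%s' absent from all lineages", rank)
  taxon[is.na(taxon)] <- "unclassified"
  ko <- ann$ko_id
  keep <- !is.na(ko)
  key <- paste(taxon, ko, sep = "\r")

  mt_tk <- tpm_by_key(mt, ifelse(keep, key, NA))
  mg_k <- tpm_by_key(mg, ifelse(keep, ko, NA))
  mt_k_of_row <- sub("^.*\r", "", rownames(mt_tk))
  tax_of_row <- sub("\r.*$", "", rownames(mt_tk))
  denom <- mg_k[mt_k_of_row, , drop = FALSE]
  val <- mt_tk / denom
  val[mt_tk == 0 & denom == 0] <- 0
  n_missing <- sum(mt_tk > 0 & denom == 0)
  val[mt_tk > 0 & denom == 0] <- NA_real_
  if (n_missing > 0L)
    log_msg("%d tensor entries with MT > 0 but MG = 0 missing-coded", n_missing)

  long <- data.frame(
    taxon = rep(tax_of_row, ncol(val)),
    ko = rep(mt_k_of_row, ncol(val)),
    sample = rep(colnames(val), each = nrow(val)),
    value = as.vector(val), stringsAsFactors = FALSE)
  structure(long, rank = rank, ko_mg_tpm = mg_k,
            class = c("taxon_gene_tensor", "data.frame"))
}

#' Marginalize a tensor over taxa to the KO-level activity matrix
#'
#' @param tensor A `taxon_gene_tensor`.
#' @param drop_unclassified Exclude the `"unclassified"` taxon bin.
#' @return Matrix KO x sample of summed values (NA if any contributing entry
#'   is missing).
#' @export
tensor_marginalize <- function(tensor, drop_unclassified = FALSE) {
  df <- tensor
  if (drop_unclassified) df <- df[df$taxon != "unclassified", , drop = FALSE]
  kos <- sort(unique(df$ko)); samples <- unique(df$sample)
  out <- matrix(0, length(kos), length(samples), dimnames = list(kos, samples))
  has_na <- matrix(FALSE, length(kos), length(samples),
                   dimnames = list(kos, samples))
  lin <- match(df$ko, kos) + (match(df$sample, samples) - 1L) * length(kos)
  v <- df$value
  na <- is.na(v)
  if (any(na)) has_na[unique(lin[na])] <- TRUE
  v[na] <- 0
  agg <- rowsum(v, group = lin)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out[has_na] <- NA_real_
  out
}

#' Taxon-level microbial transcriptional activity
#'
#' Collapses counts per taxon at `rank` (summed read rates over all the
#' taxon's features) and forms the per-taxon MT/MG TPM ratio — the input of
#' differential-activity analysis at genus or species level.
#'
#' @inheritParams build_tensor
#' @param pseudocount Passed to [mta_ratio()].
#' @return Activity matrix taxa x samples.
#' @export
taxon_mta <- function(mg, mt, annotation, rank = c("species", "genus"),
                      pseudocount = 0) {
  rank <- match.arg(rank)
  ann <- annotation[match(rownames(mg$counts), annotation$feature_id), ]
  taxon <- ann[[rank]]
  if (all(is.na(taxon))) stop_fmt("rank '%s' absent from all lineages", rank)
  mta_ratio(tpm_by_key(mt, taxon), tpm_by_key(mg, taxon), pseudocount)
}

#' Differential activity between HC and PD
#'
#' Units (taxa, genes, or taxon x gene pairs) below the prevalence cut are
#' excluded before testing and before FDR correction. Each remaining unit is
#' tested with a two-sided Mann-Whitney rank-sum test; BH correction is
#' applied across the tested units of the call.
#'
#' @param mat Numeric matrix, units x samples.
#' @param meta Metadata with `sample_id` and `group` covering the columns.
#' @param min_prevalence Detection fraction required to test a unit.
#' @param pseudocount Added to group means for the log2 fold change; default
#'   half the minimum positive group mean.
#' @return data.frame: unit, n_hc, n_pd, median_hc, median_pd, log2fc
#'   (PD over HC), p, q.
#' @export
differential_mta <- function(mat, meta, min_prevalence = 0.5,
                             pseudocount = NULL) {
  meta <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
  hc <- meta$group == "HC"; pd <- meta$group == "PD"
  if (sum(hc) < 3L || sum(pd) < 3L)
    stop_fmt("each group needs at least 3 samples (HC=%d, PD=%d)",
             sum(hc), sum(pd))
  det <- rowMeans(mat > 0 & !is.na(mat))
  keep <- det >= min_prevalence
  if (!any(keep)) stop_fmt("no unit passes the prevalence cut")
  mat <- mat[keep, , drop = FALSE]
  mean_hc <- rowMeans(mat[, hc, drop = FALSE], na.rm = TRUE)
  mean_pd <- rowMeans(mat[, pd, drop = FALSE], na.rm = TRUE)
  if (is.null(pseudocount)) pseudocount <- half_min_positive(c(mean_hc, mean_pd))
  p <- vapply(seq_len(nrow(mat)), function(i) {
    x <- mat[i, hc]; y <- mat[i, pd]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 3L || length(y) < 3L) return(NA_real_)
    suppressWarnings(stats::wilcox.test(y, x, exact = FALSE)$p.value)
  }, numeric(1))
  data.frame(
    unit = rownames(mat),
    n_hc = sum(hc), n_pd = sum(pd),
    median_hc = apply(mat[, hc, drop = FALSE], 1L, stats::median, na.rm = TRUE),
    median_pd = apply(mat[, pd, drop = FALSE], 1L, stats::median, na.rm = TRUE),
    log2fc = log2((mean_pd + pseudocount) / (mean_hc + pseudocount)),
    p = p, q = stats::p.adjust(p, "BH"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' PCA ordination with permutation-tested group fit
#'
#' Samples are ordinated by centered PCA of the CLR-transformed activity
#' matrix. The group factor's goodness of fit on the first `n_axes` score
#' axes is r^2 = 1 - SS_within / SS_total (centroid fit), with a permutation
#' p-value from `n_perm` label shuffles:
#' p = (1 + #\{r2_perm >= r2_obs\}) / (1 + n_perm).
#'
#' @param act CLR-transformed activity matrix (features x samples).
#' @param meta Metadata with `sample_id` and `group`.
#' @param n_perm Number of label permutations (>= 99).
#' @param n_axes Number of ordination axes for the fit.
#' @param seed Seed for the permutations.
#' @return list(scores, r2, p, n_perm, var_explained).
#' @export
ordinate_and_fit <- function(act, meta, n_perm = 999, n_axes = 2, seed = 1L) {
  meta <- meta[match(colnames(act), meta$sample_id), , drop = FALSE]
  groups <- factor(meta$group)
  if (nlevels(groups) < 2L) stop_fmt("need at least two groups for factor fitting")
  if (n_perm < 99L) stop_fmt("n_perm must be >= 99")
  pc <- stats::prcomp(t(act), center = TRUE, scale. = FALSE)
  n_axes <- min(n_axes, ncol(pc$x))
  scores <- pc$x[, seq_len(n_axes), drop = FALSE]
  r2_of <- function(g) {
    tot <- sum(sweep(scores, 2L, colMeans(scores), "-")^2)
    if (tot == 0) return(0)
    within <- 0
    for (lev in levels(g)) {
      s <- scores[g == lev, , drop = FALSE]
      within <- within + sum(sweep(s, 2L, colMeans(s), "-")^2)
    }
    1 - within / tot
  }
  r2 <- r2_of(groups)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) r2_of(sample(groups)), numeric(1))
  p <- (1 + sum(perm >= r2)) / (1 + n_perm)
  list(scores = scores, r2 = r2, p = p, n_perm = n_perm,
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}
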