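#' Transcripts-per-million normalization
#'
#' TPM_i = (R_i / L_i) / sum_j (R_j / L_j) * 1e6 per sample, where R is the
#' read count and L the feature length in bp. Column sums are 1e6 by
#' construction; zero counts give zero TPM.
#'
#' @param table A `gene_feature_table`, or a numeric counts matrix (features x
#'   samples) if `length_bp` is supplied.
#' @param length_bp Feature lengths named by feature (only when `table` is a
#'   bare matrix).
#' @return Numeric matrix of TPM values, features x samples.
#' @export
tpm <- function(table, length_bp = NULL) {
  if (inherits(table, "gene_feature_table")) {
    counts <- table$counts
    length_bp <- table$length_bp
  } else {
    counts <- table
    if (is.null(length_bp)) stop_fmt("length_bp required for a bare matrix")
    length_bp <- length_bp[rownames(counts)]
  }
  if (any(length_bp < 1)) stop_fmt("lengths must be >= 1")
  rate <- counts / as.numeric(length_bp)
  denom <- colSums(rate)
  zero <- colnames(counts)[denom == 0]
  if (length(zero) > 0L)
    stop_fmt("sample(s) with all-zero counts: %s", paste(zero, collapse = ", "))
  sweep(rate, 2L, denom, "/") * 1e6
}

#' Collapse feature-level counts to a higher-level TPM matrix
#'
#' Computes per-feature read rates R/L, sums them within each group given by
#' `key`, and applies the per-sample TPM normalization to the summed rates.
#' Because the TPM denominator is the total rate of the sample, TPM is
#' additive over features and this equals summing feature-level TPMs per key.
#'
#' @param table A `gene_feature_table`.
#' @param key Character vector, one group id per feature (NA features are
#'   dropped); typically the KO id, or a taxon|KO pair.
#' @return TPM matrix with one row per unique key.
#' @export
tpm_by_key <- function(table, key) {
  stopifnot(length(key) == nrow(table$counts))
  keep <- !is.na(key)
  rate <- table$counts[keep, , drop = FALSE] / as.numeric(table$length_bp[keep])
  denom <- colSums(table$counts / as.numeric(table$length_bp))
  zero <- colnames(table$counts)[denom == 0]
  if (length(zero) > 0L)
    stop_fmt("sample(s) with all-zero counts: %s", paste(zero, collapse = ", "))
  agg <- rowsum(rate, group = key[keep])
  sweep(agg, 2L, denom, "/") * 1e6
}

#' Microbial transcriptional activity: the MT/MG TPM ratio
#'
#' MTA = MT_TPM / (MG_TPM + pseudocount). With pseudocount 0, entries with
#' MG = 0 and MT > 0 (activity without detected potential, typically mapping
#' artifacts) are set to NA and counted in a report; 0/0 entries are 0.
#'
#' @param mt_tpm,mg_tpm TPM matrices with identical feature and sample
#'   indices.
#' @param pseudocount Non-negative value added to the MG denominator.
#' @return Activity matrix (features x samples) with attributes
#'   `transform_state = "raw_ratio"` and `mta_report` (count of missing-coded
#'   entries).
#' @export
mta_ratio <- function(mt_tpm, mg_tpm, pseudocount = 0) {
  assert_matrix_aligned(mt_tpm, mg_tpm, "MT and MG TPM matrices")
  if (pseudocount < 0) stop_fmt("pseudocount must be >= 0")
  denom <- mg_tpm + pseudocount
  ratio <- mt_tpm / denom
  ratio[mt_tpm == 0 & denom == 0] <- 0
  n_missing <- sum(mt_tpm > 0 & denom == 0)
  ratio[mt_tpm > 0 & denom == 0] <- NA_real_
  if (n_missing > 0L)
    log_msg("%d entries with MT > 0 but MG = 0 were missing-coded", n_missing)
  attr(ratio, "transform_state") <- "raw_ratio"
  attr(ratio, "mta_report") <- c(n_missing = n_missing)
  ratio
}

#' Filter features on detection prevalence
#'
#' Keeps features detected (value > 0 and not missing) in at least
#' `ceiling(min_fraction * n_samples)` samples.
#'
#' @param act Activity matrix.
#' @param min_fraction Required detection fraction in (0, 1].
#' @return Filtered matrix with attributes `kept` and `dropped` (feature ids).
#' @export
prevalence_filter <- function(act, min_fraction = 0.5) {
  if (min_fraction <= 0 || min_fraction > 1)
    stop_fmt("min_fraction must be in (0, 1]")
  need <- ceiling(min_fraction * ncol(act))
  det <- rowSums(act > 0 & !is.na(act))
  keep <- det >= need
  if (!any(keep)) stop_fmt("prevalence filter at %.2f removed every feature",
                           min_fraction)
  out <- act[keep, , drop = FALSE]
  attr(out, "transform_state") <- attr(act, "transform_state")
  attr(out, "kept") <- rownames(act)[keep]
  attr(out, "dropped") <- rownames(act)[!keep]
  out
}

# Yeo-Johnson transform of a vector at a given lambda.
yeo_johnson <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  neg <- !is.na(x) & x < 0
  if (abs(lambda) > 1e-10) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else out[pos] <- log1p(x[pos])
  if (abs(lambda - 2) > 1e-10) {
    out[neg] <- -((-x[neg] + 1)^(2 - lambda) - 1) / (2 - lambda)
  } else out[neg] <- -log1p(-x[neg])
  out[is.na(x)] <- NA_real_
  out
}

# Profile log-likelihood of the Yeo-Johnson model at lambda.
yj_loglik <- function(x, lambda) {
  y <- yeo_johnson(x, lambda)
  n <- length(y)
  s2 <- stats::var(y) * (n - 1) / n
  if (!is.finite(s2) || s2 <= 0) return(-Inf)
  -n / 2 * log(s2) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
}

#' Per-feature Yeo-Johnson power transform with standardization
#'
#' For each feature, the Yeo-Johnson lambda is fit by maximum likelihood
#' (1-D optimization over `lambda_range`), the transform applied, and the
#' result standardized to mean 0, SD 1 — the shape co-expression analysis
#' expects. Constant features are dropped with a warning rather than emitting
#' NaN.
#'
#' @param act Activity matrix in `raw_ratio` state.
#' @param lambda_range Search interval for lambda.
#' @return Transformed matrix, `transform_state = "power_transformed"`, with
#'   a `lambda` attribute (per-feature fitted values).
#' @export
power_transform <- function(act, lambda_range = c(-5, 5)) {
  sds <- apply(act, 1L, stats::sd, na.rm = TRUE)
  const <- !is.finite(sds) | sds == 0
  if (any(const)) {
    warn_fmt("%d constant feature(s) dropped before power transform", sum(const))
    act <- act[!const, , drop = FALSE]
  }
  if (nrow(act) == 0L) stop_fmt("no non-constant features to transform")
  lambdas <- numeric(nrow(act))
  out <- act
  for (i in seq_len(nrow(act))) {
    x <- act[i, ]
    ok <- !is.na(x)
    lam <- stats::optimize(function(l) yj_loglik(x[ok], l),
                           interval = lambda_range, maximum = TRUE)$maximum
    lambdas[i] <- lam
    y <- yeo_johnson(x, lam)
    out[i, ] <- (y - mean(y, na.rm = TRUE)) / stats::sd(y, na.rm = TRUE)
  }
  attr(out, "transform_state") <- "power_transformed"
  attr(out, "lambda") <- stats::setNames(lambdas, rownames(act))
  out
}

#' Centered log-ratio transform
#'
#' Per sample (column): x -> log(x + pseudocount) - mean(log(x + pseudocount)).
#' Each transformed column sums to zero.
#'
#' @param mat Non-negative matrix, features x samples.
#' @param pseudocount Value added before the log. The default, half the
#'   smallest non-zero entry of the matrix, is the standard multiplicative
#'   zero replacement; a zero pseudocount is only valid when the matrix has
#'   no zeros.
#' @return CLR-transformed matrix, `transform_state = "clr"`.
#' @export
clr_transform <- function(mat, pseudocount = NULL) {
  if (any(mat < 0, na.rm = TRUE)) stop_fmt("CLR input must be non-negative")
  if (is.null(pseudocount)) pseudocount <- half_min_positive(mat)
  if (pseudocount <= 0 && any(mat == 0, na.rm = TRUE))
    stop_fmt("zeros present: CLR needs a positive pseudocount")
  lx <- log(mat + pseudocount)
  out <- sweep(lx, 2L, colMeans(lx, na.rm = TRUE), "-")
  attr(out, "transform_state") <- "clr"
  out
}

#' Per-feature prevalence and activity summary
#'
#' @param act Activity matrix (raw ratio).
#' @param meta Sample metadata with `sample_id` and `group`.
#' @return list with `per_feature` (prevalence overall/per group, mean,
#'   median and variance of the non-zero activity; missing-coded for all-zero
#'   features) and `shared_counts` (features above 50% and 100% prevalence).
#' @export
prevalence_summary <- function(act, meta) {
  meta <- meta[match(colnames(act), meta$sample_id), , drop = FALSE]
  det <- act > 0 & !is.na(act)
  prev <- rowMeans(det)
  per_group <- sapply(c("HC", "PD"), function(g) {
    cols <- meta$group == g
    if (!any(cols)) return(rep(NA_real_, nrow(act)))
    rowMeans(det[, cols, drop = FALSE])
  })
  stat_nonzero <- function(f) apply(act, 1L, function(x) {
    x <- x[!is.na(x) & x > 0]
    if (length(x) == 0L) NA_real_ else f(x)
  })
  per_feature <- data.frame(
    feature = rownames(act),
    prevalence = prev,
    prevalence_hc = per_group[, "HC"],
    prevalence_pd = per_group[, "PD"],
    mean_nonzero = stat_nonzero(mean),
    median_nonzero = stat_nonzero(stats::median),
    var_nonzero = stat_nonzero(stats::var),
    stringsAsFactors = FALSE, row.names = NULL)
  list(per_feature = per_feature,
       shared_counts = c(ge_50pct = sum(prev >= 0.5), all_samples = sum(prev == 1)))
}
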