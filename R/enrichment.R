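#' Rank all network genes by module membership (kME)
#'
#' kME is the Pearson correlation of each gene's expression profile with the
#' module eigengene; genes are returned in descending kME order with a
#' deterministic tie-break on gene id. Because the eigengene is sign-oriented
#' toward its members, the ranking is invariant to eigengene sign flips.
#'
#' @param part A `module_partition` with eigengenes.
#' @param expr Power-transformed expression, genes x samples.
#' @param module Module label to rank against.
#' @return Named numeric vector of kME values, sorted descending.
#' @export
rank_genes <- function(part, expr, module) {
  if (is.null(part$eigengenes) || !module %in% colnames(part$eigengenes))
    stop_fmt("module '%s' has no eigengene", module)
  me <- part$eigengenes[, module]
  kme <- as.numeric(stats::cor(t(expr), me))
  names(kme) <- rownames(expr)
  kme[order(-kme, names(kme))]
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score.
# stat must be sorted descending; returns the maximum-deviation ES.
gsea_es <- function(stat, in_set, weight = 1) {
  hit_w <- abs(stat)^weight * in_set
  denom_hit <- sum(hit_w)
  n_miss <- sum(!in_set)
  if (denom_hit == 0 || n_miss == 0) return(0)
  run <- cumsum(hit_w / denom_hit - (!in_set) / n_miss)
  unname(run[which.max(abs(run))])
}

#' Preranked gene-set enrichment with a permutation null
#'
#' Classic weighted running-sum statistic: walking down the ranking, hits
#' increment proportionally to |stat|^weight (normalized over set hits) and
#' misses decrement by 1/(N - N_hit); the enrichment score ES is the maximum
#' deviation of the running sum. The null is built from `n_perm` random gene
#' sets of the same size (gene-label permutation). The p-value is
#' sign-stratified: among permutations whose ES has the observed sign,
#' p = (1 + #\{|ES_perm| >= |ES|\}) / (1 + #same-sign perms), which respects
#' the 1/(n_perm + 1) floor and is uniform under the null. NES is
#' ES / mean(|ES_perm|) over same-sign permutations.
#'
#' @param ranked Named statistic vector sorted descending (e.g. from
#'   [rank_genes()]).
#' @param set Character vector of member gene ids.
#' @param n_perm Number of permutations (>= 99).
#' @param weight Exponent on |stat| for hit increments (1 = classic
#'   weighted; 0 = unweighted Kolmogorov-Smirnov).
#' @param min_size Minimum overlap between set and ranking.
#' @param seed Seed for the permutations.
#' @return data.frame: es, nes, p, size; or NULL (logged) when the overlap is
#'   below `min_size`.
#' @export
gsea_preranked <- function(ranked, set, n_perm = 999, weight = 1,
                           min_size = 5, seed = 1L) {
  if (n_perm < 99L) stop_fmt("n_perm must be >= 99")
  in_set <- names(ranked) %in% set
  size <- sum(in_set)
  if (size < min_size) {
    log_msg("set overlap %d below min_size %d: skipped", size, min_size)
    return(NULL)
  }
  es <- gsea_es(ranked, in_set, weight)
  set.seed(seed)
  n <- length(ranked)
  perm_es <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, size)
    memb <- logical(n); memb[idx] <- TRUE
    gsea_es(ranked, memb, weight)
  }, numeric(1))
  same <- sign(perm_es) == sign(es)
  n_same <- sum(same)
  p <- if (n_same == 0) 1 / (n_perm + 1)
  else (1 + sum(abs(perm_es[same]) >= abs(es))) / (1 + n_same)
  nes <- if (n_same == 0) NA_real_ else es / mean(abs(perm_es[same]))
  data.frame(es = es, nes = nes, p = p, size = size)
}

#' GSEA of every module against a gene-set collection
#'
#' Each module's genes are ranked by kME and tested against every set;
#' BH correction is applied across the whole (module x pathway) family.
#'
#' @param part `module_partition` with eigengenes.
#' @param expr Power-transformed expression.
#' @param sets Named list of gene sets ([read_gene_sets()]).
#' @param n_perm,weight,min_size,seed Passed to [gsea_preranked()].
#' @return data.frame: module, pathway, es, nes, p, q, size.
#' @export
gsea_modules <- function(part, expr, sets, n_perm = 999, weight = 1,
                         min_size = 5, seed = 1L) {
  mods <- colnames(part$eigengenes)
  rows <- list()
  for (m in mods) {
    ranked <- rank_genes(part, expr, m)
    for (s in names(sets)) {
      res <- gsea_preranked(ranked, sets[[s]], n_perm = n_perm,
                            weight = weight, min_size = min_size,
                            seed = seed + match(s, names(sets)))
      if (!is.null(res))
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(module = m, pathway = s, stringsAsFactors = FALSE), res)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(module = character(0), pathway = character(0),
                      es = numeric(0), nes = numeric(0), p = numeric(0),
                      q = numeric(0), size = integer(0)))
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out[, c("module", "pathway", "es", "nes", "p", "q", "size")]
}

#' Count module genes covered by no pathway set
#'
#' @param part A `module_partition`.
#' @param sets Named list of gene sets.
#' @return list(per_module = data.frame(module, size, n_unannotated,
#'   fraction_unannotated), summary = mean/min/max fraction across modules).
#' @export
unannotated_accounting <- function(part, sets) {
  covered <- unique(unlist(sets, use.names = FALSE))
  mods <- setdiff(unique(part$labels), "M0")
  mods <- mods[order(as.integer(sub("^M", "", mods)))]
  per <- do.call(rbind, lapply(mods, function(m) {
    g <- names(part$labels)[part$labels == m]
    n_un <- sum(!g %in% covered)
    data.frame(module = m, size = length(g), n_unannotated = n_un,
               fraction_unannotated = n_un / length(g))
  }))
  list(per_module = per,
       summary = c(mean = mean(per$fraction_unannotated),
                   min = min(per$fraction_unannotated),
                   max = max(per$fraction_unannotated)))
}
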