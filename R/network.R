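#' Signed co-expression adjacency
#'
#' a_ij = ((1 + cor(x_i, x_j)) / 2) ^ beta with Pearson correlation across
#' samples. Signed adjacency keeps anti-correlated genes apart (cor = -1 gives
#' a = 0). The diagonal is set to zero so connectivity sums exclude self-edges.
#'
#' @param expr Power-transformed expression matrix, genes x samples.
#' @param beta Soft-thresholding power.
#' @return A `coexpression_network` list: genes, adjacency, beta
#'   (tom/sft_table slots filled by [topological_overlap()] /
#'   [soft_threshold_scan()]).
#' @export
signed_adjacency <- function(expr, beta) {
  sds <- apply(expr, 1L, stats::sd)
  if (any(!is.finite(sds) | sds == 0))
    stop_fmt("zero-variance gene(s) present: %s",
             paste(utils::head(rownames(expr)[!is.finite(sds) | sds == 0], 5L),
                   collapse = ", "))
  a <- ((1 + stats::cor(t(expr))) / 2)^beta
  diag(a) <- 0
  structure(list(genes = rownames(expr), adjacency = a, tom = NULL,
                 beta = beta, sft_table = NULL),
            class = "coexpression_network")
}

#' Whole-network connectivity
#' @param net A `coexpression_network` (or adjacency matrix).
#' @return Named vector k_i = sum_j a_ij (diagonal excluded).
#' @export
connectivity <- function(net) {
  a <- if (inherits(net, "coexpression_network")) net$adjacency else net
  rowSums(a) - diag(a)
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins k into `nbreaks` equal-width bins and regresses log10(freq) on
#' log10(mean k) per occupied bin. The fit index follows the usual
#' convention for scale-free topology: -sign(slope) * R^2, so only
#' decreasing degree distributions score positively.
#'
#' @param k Connectivity vector.
#' @param nbreaks Number of bins of the connectivity histogram.
#' @return list(fit, slope, r_squared).
#' @export
scale_free_fit <- function(k, nbreaks = 10) {
  if (stats::sd(k) == 0) return(list(fit = NA_real_, slope = NA_real_,
                                     r_squared = NA_real_))
  bins <- cut(k, nbreaks, include.lowest = TRUE)
  freq <- tapply(k, bins, length) / length(k)
  mean_k <- tapply(k, bins, mean)
  ok <- !is.na(freq) & freq > 0 & !is.na(mean_k) & mean_k > 0
  if (sum(ok) < 3L) return(list(fit = NA_real_, slope = NA_real_,
                                r_squared = NA_real_))
  fitlm <- stats::lm(log10(freq[ok]) ~ log10(mean_k[ok]))
  slope <- unname(stats::coef(fitlm)[2L])
  r2 <- summary(fitlm)$r.squared
  list(fit = -sign(slope) * r2, slope = slope, r_squared = r2)
}

#' Scan soft-thresholding powers for scale-free topology
#'
#' For each candidate power the signed adjacency is formed, connectivities
#' k_i computed, and the scale-free fit index evaluated. The chosen beta is
#' the smallest power whose fit reaches `r2_cut`; if none does, the power
#' with the maximum fit is returned with a warning.
#'
#' @param expr Power-transformed expression, genes x samples.
#' @param powers Ascending integer powers to scan.
#' @param r2_cut Required fit index (0.9 is the customary criterion).
#' @return list(beta, sft_table) where sft_table has one row per power:
#'   power, fit, slope, mean_k, median_k, max_k.
#' @export
soft_threshold_scan <- function(expr, powers = 1:20, r2_cut = 0.9) {
  if (nrow(expr) < 20L) stop_fmt("need >= 20 genes for a soft-threshold scan")
  if (ncol(expr) < 10L) stop_fmt("need >= 10 samples for a soft-threshold scan")
  if (is.unsorted(powers, strictly = TRUE)) stop_fmt("powers must be ascending")
  sds <- apply(expr, 1L, stats::sd)
  if (all(sds == 0)) stop_fmt("all-constant expression")
  cm <- stats::cor(t(expr))
  base <- (1 + cm) / 2
  diag(base) <- 0
  rows <- lapply(powers, function(b) {
    a <- base^b
    diag(a) <- 0
    k <- rowSums(a)
    sf <- scale_free_fit(k)
    data.frame(power = b, fit = sf$fit, slope = sf$slope,
               mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  })
  sft <- do.call(rbind, rows)
  list(beta = pick_soft_power(sft, r2_cut), sft_table = sft)
}

#' Select the soft power from a scan table
#'
#' @param sft_table data.frame with columns `power` and `fit`.
#' @param r2_cut Fit threshold.
#' @return The smallest power with fit >= r2_cut, else the power at maximum
#'   fit (with a warning).
#' @export
pick_soft_power <- function(sft_table, r2_cut = 0.9) {
  ok <- which(!is.na(sft_table$fit) & sft_table$fit >= r2_cut)
  if (length(ok) > 0L) return(sft_table$power[min(ok)])
  warn_fmt("no power reaches fit %.2f; using power %d at maximum fit %.3f",
           r2_cut, sft_table$power[which.max(sft_table$fit)],
           max(sft_table$fit, na.rm = TRUE))
  sft_table$power[which.max(sft_table$fit)]
}

#' Topological overlap matrix
#'
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' l_ij = sum_u a_iu a_uj (u != i, j via the zero diagonal); TOM_ii = 1.
#'
#' @param net A `coexpression_network` (or adjacency matrix).
#' @return The network with the `tom` slot filled (or the TOM matrix when a
#'   bare adjacency was given).
#' @export
topological_overlap <- function(net) {
  a <- if (inherits(net, "coexpression_network")) net$adjacency else net
  if (!isSymmetric(unname(a), tol = 1e-12)) stop_fmt("adjacency must be symmetric")
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  if (inherits(net, "coexpression_network")) {
    net$tom <- tom
    net
  } else tom
}

#' Module eigengene
#'
#' First right-singular vector (sample dimension) of the per-gene
#' standardized module submatrix, sign-oriented so its mean correlation with
#' the member genes is positive; unit L2 norm.
#'
#' @param expr Expression matrix, genes x samples.
#' @param genes Character vector of module member genes (>= 2).
#' @return Numeric vector over samples with attribute `var_explained`.
#' @export
module_eigengene <- function(expr, genes) {
  x <- expr[genes, , drop = FALSE]
  if (nrow(x) < 2L) stop_fmt("a module eigengene needs >= 2 genes")
  x <- t(scale(t(x)))
  if (any(!is.finite(x))) stop_fmt("degenerate module submatrix")
  sv <- svd(x, nu = 0, nv = 1)
  if (sv$d[1L] == 0) stop_fmt("rank-0 module submatrix")
  me <- sv$v[, 1L]
  if (mean(stats::cor(me, t(x))) < 0) me <- -me
  attr(me, "var_explained") <- sv$d[1L]^2 / sum(sv$d^2)
  stats::setNames(me, colnames(expr))
}

# --- dendrogram utilities for the adaptive tree cut ----------------------

# parent[i] = internal node whose merge includes internal node i; 0 for root
.hc_parents <- function(merge) {
  n1 <- nrow(merge)
  parent <- integer(n1)
  for (j in seq_len(n1)) for (s in 1:2) {
    v <- merge[j, s]
    if (v > 0) parent[v] <- j
  }
  parent
}

# leaves under internal node i (iterative; merge uses hclust conventions)
.hc_leaves <- function(merge, i) {
  out <- integer(0)
  stack <- i
  while (length(stack) > 0L) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (s in 1:2) {
      v <- merge[nd, s]
      if (v < 0) out <- c(out, -v) else stack <- c(stack, v)
    }
  }
  out
}

#' Cut a TOM dendrogram into modules
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM,
#' followed by an adaptive branch cut: an internal branch is a module
#' candidate when it holds at least `min_module_size` genes, completes below
#' `cut_height_frac` of the dendrogram height range, and is separated from
#' its merge environment: the gap between the branch's completion height and
#' the height at which it attaches to the rest of the tree must be at least
#' `gap_frac` of the attachment height minus the dendrogram floor. Among
#' nested candidates the outermost are kept (deeper structure inside an
#' accepted branch is left to the eigengene merge step); genes under no
#' accepted branch are unassigned (module `"M0"`). Module eigengenes are then computed and
#' modules whose eigengene dissimilarity (1 - cor) falls below `merge_dissim`
#' are iteratively merged, closest pair first, until no pair qualifies.
#' Labels are ordered by size (M1 largest).
#'
#' @param tom TOM matrix (or a `coexpression_network` with a filled tom).
#' @param expr Power-transformed expression (genes x samples) used for
#'   eigengenes.
#' @param min_module_size Minimum genes per module.
#' @param merge_dissim Eigengene dissimilarity threshold below which two
#'   modules merge (0.18 corresponds to eigengene correlation 0.82).
#' @param cut_height_frac Branches completing above this fraction of the
#'   dendrogram height range are never modules.
#' @param gap_frac Minimum relative branch separation (see above).
#' @return A `module_partition`: labels (gene -> module), eigengenes
#'   (samples x modules), merge_log, dendrogram, trait_stats slot (filled by
#'   [module_trait()]).
#' @export
cut_modules <- function(tom, expr, min_module_size = 20, merge_dissim = 0.18,
                        cut_height_frac = 0.99, gap_frac = 0.02) {
  if (inherits(tom, "coexpression_network")) tom <- tom$tom
  if (min_module_size < 2L) stop_fmt("min_module_size must be >= 2")
  genes <- rownames(tom)
  n <- length(genes)
  labels <- stats::setNames(rep("M0", n), genes)
  if (n < min_module_size) {
    warn_fmt("fewer genes (%d) than min_module_size (%d): all unassigned",
             n, min_module_size)
    return(structure(list(labels = labels, eigengenes = NULL,
                          trait_stats = NULL, merge_log = list(),
                          dendrogram = NULL),
                     class = "module_partition"))
  }
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  merge <- hc$merge; height <- hc$height
  parent <- .hc_parents(merge)
  sizes <- integer(nrow(merge))
  for (j in seq_len(nrow(merge)))
    sizes[j] <- sum(ifelse(merge[j, ] < 0, 1L, sizes[pmax(merge[j, ], 1L)]))
  parent_h <- ifelse(parent == 0L, Inf, height[pmax(parent, 1L)])
  h_cut <- min(height) + cut_height_frac * (max(height) - min(height))
  # branch separation relative to its merge environment: a module branch
  # completes well below the height at which it attaches to the rest
  rel_gap <- (parent_h - height) / pmax(parent_h - min(height),
                                        .Machine$double.eps)
  candidate <- sizes >= min_module_size & height <= h_cut & rel_gap >= gap_frac
  # outermost candidates: reject any candidate with an accepted ancestor
  accepted <- logical(nrow(merge))
  for (j in rev(seq_len(nrow(merge)))) {
    if (!candidate[j]) next
    anc <- parent[j]
    ok <- TRUE
    while (anc != 0L) {
      if (accepted[anc]) { ok <- FALSE; break }
      anc <- parent[anc]
    }
    accepted[j] <- ok
  }
  accepted <- which(accepted)
  for (i in seq_along(accepted))
    labels[genes[.hc_leaves(merge, accepted[i])]] <- sprintf("C%d", i)

  part <- structure(list(labels = labels, eigengenes = NULL,
                         trait_stats = NULL, merge_log = list(),
                         dendrogram = hc),
                    class = "module_partition")
  part <- .merge_close_modules(part, expr, merge_dissim)
  .relabel_by_size(part)
}

# iterative eigengene merging, closest pair first
.merge_close_modules <- function(part, expr, merge_dissim) {
  repeat {
    mods <- setdiff(unique(part$labels), "M0")
    if (length(mods) < 2L) break
    me <- sapply(mods, function(m)
      module_eigengene(expr, names(part$labels)[part$labels == m]))
    diss <- 1 - stats::cor(me)
    diag(diss) <- Inf
    mn <- min(diss)
    if (mn >= merge_dissim) break
    ij <- which(diss == mn, arr.ind = TRUE)[1L, ]
    a <- mods[min(ij)]; b <- mods[max(ij)]
    part$labels[part$labels == b] <- a
    part$merge_log <- c(part$merge_log,
                        list(list(kept = a, absorbed = b, dissim = mn)))
  }
  part
}

.relabel_by_size <- function(part) {
  mods <- setdiff(unique(part$labels), "M0")
  if (length(mods) == 0L) return(part)
  sz <- sort(table(part$labels[part$labels != "M0"]), decreasing = TRUE)
  map <- stats::setNames(sprintf("M%d", seq_along(sz)), names(sz))
  part$labels[part$labels != "M0"] <- map[part$labels[part$labels != "M0"]]
  part
}

#' Attach eigengenes for every named module
#'
#' @param part A `module_partition`.
#' @param expr Power-transformed expression, genes x samples.
#' @return The partition with the `eigengenes` slot filled
#'   (samples x modules, columns ordered M1, M2, ...).
#' @export
compute_eigengenes <- function(part, expr) {
  mods <- setdiff(unique(part$labels), "M0")
  mods <- mods[order(as.integer(sub("^M", "", mods)))]
  if (length(mods) == 0L) { part$eigengenes <- NULL; return(part) }
  me <- sapply(mods, function(m)
    module_eigengene(expr, names(part$labels)[part$labels == m]))
  rownames(me) <- colnames(expr)
  part$eigengenes <- me
  part
}

#' Module-trait association
#'
#' Pearson correlation of each module eigengene with the binary group
#' indicator (HC = 0, PD = 1), Student t p-value on n - 2 df, BH q across
#' modules. A module is classified HC-associated (r < 0, p <= alpha),
#' PD-associated (r > 0, p <= alpha), or unassociated.
#'
#' @param part A `module_partition` with eigengenes (see
#'   [compute_eigengenes()]).
#' @param meta Metadata with `sample_id` and `group`.
#' @param alpha Significance level for trait classification.
#' @return The partition with `trait_stats` filled: module, size, r, p, q,
#'   trait_class.
#' @export
module_trait <- function(part, meta, alpha = 0.05) {
  if (is.null(part$eigengenes)) stop_fmt("partition has no eigengenes")
  meta <- meta[match(rownames(part$eigengenes), meta$sample_id), , drop = FALSE]
  if (!all(c("HC", "PD") %in% meta$group)) stop_fmt("both groups must be present")
  ind <- as.numeric(meta$group == "PD")
  n <- length(ind)
  r <- as.numeric(stats::cor(part$eigengenes, ind))
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  q <- stats::p.adjust(p, "BH")
  cls <- ifelse(p <= alpha & r < 0, "HC", ifelse(p <= alpha & r > 0, "PD", "none"))
  part$trait_stats <- data.frame(
    module = colnames(part$eigengenes),
    size = as.integer(table(part$labels)[colnames(part$eigengenes)]),
    r = r, p = p, q = q, trait_class = cls,
    stringsAsFactors = FALSE, row.names = NULL)
  part
}
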