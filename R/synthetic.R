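#' Configuration for the synthetic paired MG/MT generator
#'
#' The generator emulates the data structure the analysis assumes: taxa with
#' log-normal abundance profiles carrying KO genes, planted co-expression
#' modules driven by per-sample latent factors, a multiplicative disease
#' (PD) depletion of selected module genes, and taxon expression dropout that
#' lowers the taxonomic diversity of gene expression (tDGE) in PD only.
#'
#' Defaults encode the benchmark study conditions: 40 + 40 samples, 5 planted
#' modules of 40 genes, within-module Pearson correlation of the MT/MG
#' activity around 0.7, a 0.5x PD depletion of the first three modules, and
#' silencing of 8 of 30 taxa in PD. The variance parameters follow from the
#' one-factor log-normal model: on the log-activity scale the within-module
#' correlation is sd_f^2 / (sd_f^2 + sd_noise^2), where sd_noise^2 collects
#' gene noise, residual taxon noise and the negative-binomial counting noise
#' of both layers; see the methods vignette for the decomposition.
#'
#' @param n_hc,n_pd Number of healthy-control and PD samples.
#' @param n_taxa Number of taxa (each one genus/species in the taxonomy).
#' @param n_ko Number of KO genes.
#' @param carriage_prob Probability a background (taxon, KO) pair is carried.
#' @param module_sizes Integer vector of planted module sizes.
#' @param affected_modules Indices of modules whose member-gene expression is
#'   multiplied by `group_effect` in PD samples.
#' @param group_effect Multiplicative PD effect on affected module expression
#'   rates (0.5 = 2-fold depletion; 1 = null).
#' @param module_taxa Number of taxa carrying each planted module (overlapping
#'   subsets drawn from the non-dropout taxa).
#' @param module_carriage_prob Carriage probability of a module gene within
#'   its module's taxon subset (one carrier is always guaranteed).
#' @param latent_factor_sd SD of the per-(module, sample) latent activity
#'   factor on the log scale.
#' @param gene_noise_sd SD of per-(gene, sample) log-normal expression noise.
#' @param taxon_noise_sd SD of per-(taxon, gene, sample) residual noise.
#' @param baseline_sd SD of per-gene baseline log expression level.
#' @param taxon_abund_sd SD of taxon mean log abundances.
#' @param sample_abund_sd SD of per-sample log abundance fluctuation.
#' @param nb_size Negative-binomial size (dispersion) shared by all genes and
#'   both layers; larger = closer to Poisson.
#' @param dropout_taxa Character vector of taxa silenced in PD (expression
#'   zeroed, carriage untouched), or an integer count (last taxa used).
#' @param p_drop Per-(taxon, sample) probability that a dropout taxon is
#'   silent in a PD sample.
#' @param depth_mg,depth_mt Mean library sizes of the two layers.
#' @param length_range Interval gene lengths are drawn from (bp, uniform).
#' @param seed Integer seed; the whole draw is deterministic given the config.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_hc = 40, n_pd = 40, n_taxa = 30, n_ko = 400,
                             carriage_prob = 0.25,
                             module_sizes = rep(40L, 5L),
                             affected_modules = c(1L, 2L, 3L),
                             group_effect = 0.5,
                             module_taxa = 8L, module_carriage_prob = 0.8,
                             latent_factor_sd = 0.35, gene_noise_sd = 0.16,
                             taxon_noise_sd = 0.3, baseline_sd = 0.5,
                             taxon_abund_sd = 1.0, sample_abund_sd = 0.4,
                             nb_size = 30,
                             dropout_taxa = 8L, p_drop = 0.9,
                             depth_mg = 2e6, depth_mt = 2e6,
                             length_range = c(300L, 3000L), seed = 1L) {
  taxa <- sprintf("T%02d", seq_len(n_taxa))
  if (is.numeric(dropout_taxa) && length(dropout_taxa) == 1L) {
    ndrop <- as.integer(dropout_taxa)
    if (ndrop > n_taxa) stop_fmt("more dropout taxa than taxa")
    dropout_taxa <- if (ndrop > 0L) utils::tail(taxa, ndrop) else character(0)
  }
  cfg <- list(n_hc = n_hc, n_pd = n_pd, n_taxa = n_taxa, n_ko = n_ko,
              carriage_prob = carriage_prob,
              module_sizes = as.integer(module_sizes),
              affected_modules = as.integer(affected_modules),
              group_effect = group_effect,
              module_taxa = as.integer(module_taxa),
              module_carriage_prob = module_carriage_prob,
              latent_factor_sd = latent_factor_sd,
              gene_noise_sd = gene_noise_sd, taxon_noise_sd = taxon_noise_sd,
              baseline_sd = baseline_sd, taxon_abund_sd = taxon_abund_sd,
              sample_abund_sd = sample_abund_sd, nb_size = nb_size,
              dropout_taxa = dropout_taxa, p_drop = p_drop,
              depth_mg = depth_mg, depth_mt = depth_mt,
              length_range = as.integer(length_range), seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (sum(cfg$module_sizes) > cfg$n_ko)
    stop_fmt("infeasible config: module sizes sum (%d) exceeds KO pool (%d)",
             sum(cfg$module_sizes), cfg$n_ko)
  if (any(cfg$affected_modules > length(cfg$module_sizes)))
    stop_fmt("affected_modules index exceeds module count")
  probs <- c(cfg$carriage_prob, cfg$module_carriage_prob, cfg$p_drop)
  if (any(probs < 0 | probs > 1)) stop_fmt("probabilities must be in [0, 1]")
  if (cfg$depth_mg <= 0 || cfg$depth_mt <= 0) stop_fmt("depths must be > 0")
  if (cfg$group_effect <= 0) stop_fmt("group_effect must be > 0")
  if (cfg$module_taxa > cfg$n_taxa - length(cfg$dropout_taxa))
    stop_fmt("module_taxa exceeds the non-dropout taxon pool")
  invisible(cfg)
}

#' Generate a paired synthetic MG/MT dataset
#'
#' @param cfg A [synthetic_config()].
#' @return list with elements `mg`, `mt` (gene_feature_table, identical
#'   feature ids), `annotation` (feature -> KO, lineage), `meta` (sample
#'   metadata) and `truth` (a `synthetic_truth` recording every planted draw:
#'   module map, per-gene true log2 effect, tDGE-down flags, carriage,
#'   abundances, latent factors and silencing indicators).
#' @export
synth_generate <- function(cfg) {
  validate_synthetic_config(cfg)
  set.seed(cfg$seed)
  n_s <- cfg$n_hc + cfg$n_pd
  samples <- sprintf("S%03d", seq_len(n_s))
  group <- c(rep("HC", cfg$n_hc), rep("PD", cfg$n_pd))
  taxa <- sprintf("T%02d", seq_len(cfg$n_taxa))
  kos <- sprintf("K%05d", seq_len(cfg$n_ko))
  modules <- rep("M0", cfg$n_ko)
  pos <- 1L
  for (m in seq_along(cfg$module_sizes)) {
    modules[pos:(pos + cfg$module_sizes[m] - 1L)] <- sprintf("P%d", m)
    pos <- pos + cfg$module_sizes[m]
  }
  names(modules) <- kos

  ## taxon abundances: per-taxon mean, per-sample log-normal wobble
  mu_tax <- stats::rnorm(cfg$n_taxa, 0, cfg$taxon_abund_sd)
  log_ab <- matrix(stats::rnorm(cfg$n_taxa * n_s, 0, cfg$sample_abund_sd),
                   cfg$n_taxa, n_s) + mu_tax
  abund <- exp(log_ab)
  abund <- sweep(abund, 2L, colSums(abund), "/")
  dimnames(abund) <- list(taxa, samples)

  ## carriage: background Bernoulli; module genes on overlapping subsets of
  ## the non-dropout taxa so planted DE and planted dropout stay separable
  carry <- matrix(stats::rbinom(cfg$n_taxa * cfg$n_ko, 1L, cfg$carriage_prob),
                  cfg$n_taxa, cfg$n_ko, dimnames = list(taxa, kos))
  nondrop <- setdiff(taxa, cfg$dropout_taxa)
  module_taxon_sets <- list()
  for (m in seq_along(cfg$module_sizes)) {
    sub <- sample(nondrop, cfg$module_taxa)
    module_taxon_sets[[sprintf("P%d", m)]] <- sub
    gm <- kos[modules == sprintf("P%d", m)]
    carry[, gm] <- 0L
    carry[sub, gm] <- matrix(
      stats::rbinom(length(sub) * length(gm), 1L, cfg$module_carriage_prob),
      length(sub), length(gm))
    # guarantee a carrier
    none <- gm[colSums(carry[sub, gm, drop = FALSE]) == 0L]
    for (g in none) carry[sub[1L], g] <- 1L
  }
  # background genes also need at least one carrier
  none <- kos[modules == "M0" & colSums(carry) == 0L]
  for (g in none) carry[sample(cfg$n_taxa, 1L), g] <- 1L

  ## latent module factors and expression rates (log link)
  n_mod <- length(cfg$module_sizes)
  fac <- matrix(stats::rnorm(n_mod * n_s, 0, cfg$latent_factor_sd), n_mod, n_s,
                dimnames = list(sprintf("P%d", seq_len(n_mod)), samples))
  baseline <- stats::setNames(stats::rnorm(cfg$n_ko, 0, cfg$baseline_sd), kos)
  gene_noise <- matrix(stats::rnorm(cfg$n_ko * n_s, 0, cfg$gene_noise_sd),
                       cfg$n_ko, n_s, dimnames = list(kos, samples))
  log_rate <- gene_noise + baseline
  for (m in seq_len(n_mod)) {
    gm <- modules == sprintf("P%d", m)
    log_rate[gm, ] <- sweep(log_rate[gm, , drop = FALSE], 2L, fac[m, ], "+")
    if (m %in% cfg$affected_modules)
      log_rate[gm, group == "PD"] <- log_rate[gm, group == "PD"] +
        log(cfg$group_effect)
  }

  ## dropout: PD-only silencing indicator per (dropout taxon, sample)
  silenced <- matrix(0L, cfg$n_taxa, n_s, dimnames = list(taxa, samples))
  if (length(cfg$dropout_taxa) > 0L && cfg$p_drop > 0) {
    pd_idx <- which(group == "PD")
    silenced[cfg$dropout_taxa, pd_idx] <-
      matrix(stats::rbinom(length(cfg$dropout_taxa) * length(pd_idx), 1L,
                           cfg$p_drop),
             length(cfg$dropout_taxa), length(pd_idx))
  }

  ## features: one per carried (taxon, KO) pair
  idx <- which(carry == 1L, arr.ind = TRUE)
  ord <- order(idx[, 2L], idx[, 1L])
  idx <- idx[ord, , drop = FALSE]
  f_taxon <- taxa[idx[, 1L]]
  f_ko <- kos[idx[, 2L]]
  fid <- paste(f_taxon, f_ko, sep = "|")
  n_f <- length(fid)
  lens <- stats::setNames(
    sample(seq(cfg$length_range[1L], cfg$length_range[2L]), n_f, replace = TRUE),
    fid)

  ## taxon-level residual noise per (feature, sample)
  tax_noise <- matrix(stats::rnorm(n_f * n_s, 0, cfg$taxon_noise_sd), n_f, n_s)

  ## expected count rates (arbitrary scale, normalized to depth per sample)
  ab_f <- abund[f_taxon, , drop = FALSE]           # n_f x n_s
  mg_rate <- ab_f * lens
  expr <- exp(log_rate[f_ko, , drop = FALSE] + tax_noise)
  expr <- expr * (1 - silenced[f_taxon, , drop = FALSE])
  mt_rate <- ab_f * expr * lens

  draw_counts <- function(rate, depth) {
    mu <- sweep(rate, 2L, colSums(rate), "/") * depth
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu, size = cfg$nb_size),
                  nrow(mu), ncol(mu))
    dimnames(cnt) <- list(fid, samples)
    storage.mode(cnt) <- "integer"
    cnt
  }
  mg_counts <- draw_counts(mg_rate, cfg$depth_mg)
  mt_counts <- draw_counts(mt_rate, cfg$depth_mt)

  lineage <- sprintf(
    "d__Bacteria;p__Phy%02d;c__Cla%02d;o__Ord%02d;f__Fam%02d;g__Genus%s;s__Genus%s sp%s",
    (match(f_taxon, taxa) - 1L) %% 5L + 1L, (match(f_taxon, taxa) - 1L) %% 5L + 1L,
    (match(f_taxon, taxa) - 1L) %% 8L + 1L, (match(f_taxon, taxa) - 1L) %% 10L + 1L,
    f_taxon, f_taxon, f_taxon)
  annotation <- data.frame(feature_id = fid, ko_id = f_ko, lineage = lineage,
                           genus = paste0("Genus", f_taxon),
                           species = paste0("Genus", f_taxon, " sp", f_taxon),
                           stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = samples, group = group,
                     stringsAsFactors = FALSE)

  ## truth bookkeeping
  n_drop_carrier <- colSums(carry[cfg$dropout_taxa, , drop = FALSE])
  n_other_carrier <- colSums(carry) - n_drop_carrier
  tdge_down <- cfg$p_drop > 0 & n_drop_carrier > 0 & n_other_carrier > 0
  true_lfc <- ifelse(modules %in% sprintf("P%d", cfg$affected_modules),
                     log2(cfg$group_effect), 0)
  if (cfg$group_effect == 1) true_lfc[] <- 0
  truth <- structure(list(
    modules = modules,
    affected_modules = if (cfg$group_effect != 1)
      sprintf("P%d", cfg$affected_modules) else character(0),
    true_log2_effect = stats::setNames(true_lfc, kos),
    tdge_down = stats::setNames(as.logical(tdge_down), kos),
    carriage = carry, abundance = abund, factors = fac,
    silenced = silenced, module_taxon_sets = module_taxon_sets,
    dropout_taxa = cfg$dropout_taxa, config = cfg), class = "synthetic_truth")

  list(mg = gene_feature_table(mg_counts, lens, "MG"),
       mt = gene_feature_table(mt_counts, lens, "MT"),
       annotation = annotation, meta = meta, truth = truth)
}

#' Summarize the planted truth per gene
#'
#' @param truth A `synthetic_truth` from [synth_generate()].
#' @return data.frame with one row per KO: planted module, true log2 effect of
#'   the disease group on expression, its sign, and whether the gene's tDGE is
#'   planted to decrease in PD (carried by at least one dropout taxon and one
#'   surviving taxon).
#' @export
truth_report <- function(truth) {
  kos <- names(truth$modules)
  data.frame(ko = kos,
             module = unname(truth$modules),
             true_log2_effect = unname(truth$true_log2_effect[kos]),
             effect_sign = sign(unname(truth$true_log2_effect[kos])),
             tdge_down = unname(truth$tdge_down[kos]),
             stringsAsFactors = FALSE)
}

#' Write a synthetic dataset to a directory in the pipeline's TSV dialects
#'
#' @param sim Output of [synth_generate()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$mg, file.path(dir, "mg_counts.tsv"))
  write_counts(sim$mt, file.path(dir, "mt_counts.tsv"))
  utils::write.table(sim$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$meta, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth_report(sim$truth), file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
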