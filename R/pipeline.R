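#' Pipeline configuration
#'
#' Assembles and validates the configuration of [run_pipeline()]. Defaults
#' follow the analysis conventions: 50% prevalence, soft power chosen as the
#' smallest with scale-free fit >= 0.9, minimum module size 20, eigengene
#' merge threshold 0.18, 95th-percentile and top-10% hub rules, alpha 0.05.
#' Unknown keys are rejected before any stage runs.
#'
#' @param ... Overrides of the defaults; `synthetic` takes a list of
#'   [synthetic_config()] overrides, `stages` a subset of the stage names in
#'   execution order.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    stages = c("simulate", "quantify", "taxa", "network", "topology",
               "hubs", "diversity", "differential", "enrichment",
               "crossfeeding"),
    synthetic = list(),
    mg_path = NULL, mt_path = NULL, annotation_path = NULL, meta_path = NULL,
    gene_sets_path = NULL,
    min_prevalence = 0.5, ratio_pseudocount = 0,
    powers = 1:20, r2_cut = 0.9,
    min_module_size = 20L, merge_dissim = 0.18, cut_height_frac = 0.99,
    alpha = 0.05,
    hub_quantile = 0.95, hub_fraction = 0.10,
    edge_threshold = 0.01,
    n_perm_fit = 999L, n_perm_gsea = 499L, gsea_min_size = 5L,
    tensor_rank = "species",
    process_lists = NULL, selected_genera = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0L)
    stop_fmt("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  bad <- setdiff(cfg$stages, defaults$stages)
  if (length(bad) > 0L) stop_fmt("unknown stage(s): %s", paste(bad, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Synthetic pathway annotation for a KO universe
#'
#' Partitions a fraction of the KO pool into disjoint gene sets of roughly
#' equal size, leaving the rest unannotated — a stand-in collection for
#' exercising enrichment and annotation accounting on synthetic data.
#'
#' @param kos Character vector of KO ids.
#' @param n_sets Number of sets.
#' @param coverage Fraction of KOs assigned to a set.
#' @param seed Seed for the assignment.
#' @return Named list of KO id vectors.
#' @export
synth_gene_sets <- function(kos, n_sets = 16, coverage = 0.6, seed = 1L) {
  set.seed(seed)
  n_cov <- round(coverage * length(kos))
  covered <- sample(kos, n_cov)
  idx <- rep(seq_len(n_sets), length.out = n_cov)
  sets <- split(covered, sprintf("path%02d", idx))
  sets[order(names(sets))]
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulate (or load), quantify,
#' taxa, network, topology, hubs, diversity, differential, enrichment,
#' crossfeeding — with per-stage random streams derived from a single seed,
#' and optionally writes every result table plus a manifest to `out_dir`.
#' Identical config and seed produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return Named list of stage results (see the methods vignette for the
#'   table inventory).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stages <- config$stages
  res <- list(config = config)

  ## ---- inputs ----
  if ("simulate" %in% stages) {
    syn_args <- utils::modifyList(list(seed = stage_seed(config$seed, "simulate")),
                                  config$synthetic)
    scfg <- do.call(synthetic_config, syn_args)
    sim <- synth_generate(scfg)
    res$truth <- sim$truth
  } else {
    if (is.null(config$mg_path)) stop_fmt("no inputs: enable simulate or give paths")
    sim <- list(mg = read_counts(config$mg_path, "MG"),
                mt = read_counts(config$mt_path, "MT"),
                annotation = read_annotations(config$annotation_path),
                meta = read_metadata(config$meta_path))
  }
  al <- align_samples(sim$mg, sim$mt, sim$meta)
  mg <- al$mg; mt <- al$mt; meta <- al$meta
  ann <- sim$annotation
  res$meta <- meta

  ## ---- quantify: KO-level activity ----
  ko_of <- ann$ko_id[match(rownames(mg$counts), ann$feature_id)]
  mg_tpm <- tpm_by_key(mg, ko_of)
  mt_tpm <- tpm_by_key(mt, ko_of)
  act <- mta_ratio(mt_tpm, mg_tpm, config$ratio_pseudocount)
  res$activity <- act
  act_f <- prevalence_filter(act, config$min_prevalence)
  res$activity_filtered <- act_f
  expr <- power_transform(act_f)
  res$expression <- expr
  res$prevalence <- prevalence_summary(act, meta)

  ## ---- taxa ----
  if ("taxa" %in% stages) {
    res$tensor <- build_tensor(mg, mt, ann, rank = config$tensor_rank)
    res$tensor_genus <- build_tensor(mg, mt, ann, rank = "genus")
    tax_act <- taxon_mta(mg, mt, ann, rank = config$tensor_rank)
    res$taxa_differential <- differential_mta(tax_act, meta,
                                              config$min_prevalence)
    clr <- clr_transform(act_f)
    res$ordination <- ordinate_and_fit(clr, meta, n_perm = config$n_perm_fit,
                                       seed = stage_seed(config$seed, "taxa"))
  }

  ## ---- network ----
  if ("network" %in% stages) {
    scan <- soft_threshold_scan(expr, config$powers, config$r2_cut)
    net <- signed_adjacency(expr, scan$beta)
    net$sft_table <- scan$sft_table
    net <- topological_overlap(net)
    part <- cut_modules(net$tom, expr,
                        min_module_size = config$min_module_size,
                        merge_dissim = config$merge_dissim,
                        cut_height_frac = config$cut_height_frac)
    part <- compute_eigengenes(part, expr)
    if (!is.null(part$eigengenes))
      part <- module_trait(part, meta, config$alpha)
    res$network <- net
    res$partition <- part
  }

  ## ---- topology ----
  if ("topology" %in% stages && !is.null(res$partition$eigengenes)) {
    topo <- module_topology_table(res$network, res$partition, act_f,
                                  config$edge_threshold)
    res$topology <- topo
    res$topology_tests <- compare_by_trait(topo)
    if (nrow(topo) >= 4L)
      res$topology_correlations <- diversity_metric_correlations(topo)
  }

  ## ---- hubs ----
  if ("hubs" %in% stages && !is.null(res$partition$trait_stats)) {
    res$hubs_p95 <- select_hubs_p95(res$network, res$partition,
                                    config$hub_quantile)
    res$hubs_imodule <- select_hubs_intramodular(res$network, res$partition,
                                                 config$hub_fraction)
  }

  ## ---- diversity ----
  if ("diversity" %in% stages && !is.null(res$tensor)) {
    hubs <- if (!is.null(res$hubs_imodule)) res$hubs_imodule$gene else character(0)
    res$tdge <- tdge_group_compare(res$tensor, meta, hub_genes = hubs)
    res$functional_redundancy <- functional_redundancy(res$tensor)
    genera <- config$selected_genera %||%
      utils::head(sort(unique(res$tensor_genus$taxon)), 5L)
    res$genus_diversity <- genus_expression_diversity(res$tensor_genus, meta,
                                                      genera)
  }

  ## ---- differential ----
  if ("differential" %in% stages) {
    res$differential <- differential_expression(act_f, meta, config$alpha)
    if (!is.null(res$tdge)) {
      hubs <- if (!is.null(res$hubs_imodule)) res$hubs_imodule$gene else character(0)
      res$joint <- joint_classification(res$differential, res$tdge$per_gene,
                                        hubs)
    }
  }

  ## ---- enrichment ----
  if ("enrichment" %in% stages && !is.null(res$partition$eigengenes)) {
    sets <- if (!is.null(config$gene_sets_path))
      read_gene_sets(config$gene_sets_path)
    else synth_gene_sets(rownames(expr),
                         seed = stage_seed(config$seed, "enrichment"))
    res$gene_sets <- sets
    res$gsea <- gsea_modules(res$partition, expr, sets,
                             n_perm = config$n_perm_gsea,
                             min_size = config$gsea_min_size,
                             seed = stage_seed(config$seed, "enrichment"))
    res$unannotated <- unannotated_accounting(res$partition, sets)
  }

  ## ---- crossfeeding ----
  if ("crossfeeding" %in% stages) {
    pl <- config$process_lists
    if (is.null(pl) && !is.null(res$truth)) {
      mods <- res$truth$modules
      pl <- list(BMC = names(mods)[mods == "P1"],
                 FA = names(mods)[mods == "P2"])
    }
    if (!is.null(pl) && length(pl) >= 2L) {
      g1 <- intersect(pl[[1L]], rownames(act_f))
      g2 <- intersect(pl[[2L]], rownames(act_f))
      if (length(g1) > 0L && length(g2) > 0L) {
        bc <- block_correlations(act_f[g1, , drop = FALSE],
                                 act_f[g2, , drop = FALSE], config$alpha)
        res$crossfeeding <- list(correlations = bc,
                                 counts = attr(bc, "counts"))
      }
      if (!is.null(res$tensor_genus))
        res$process_sums <- process_sums(res$tensor_genus, pl)
    }
  }

  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# Serialize result tables and a manifest; deterministic for a fixed config.
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  counts <- list()
  tables <- list(
    metadata.tsv = res$meta,
    sft_table.tsv = res$network$sft_table,
    trait_stats.tsv = res$partition$trait_stats,
    topology.tsv = res$topology,
    topology_tests.tsv = res$topology_tests,
    taxa_differential.tsv = res$taxa_differential,
    hubs_p95.tsv = res$hubs_p95,
    hubs_imodule.tsv = res$hubs_imodule,
    tdge_per_gene.tsv = res$tdge$per_gene,
    functional_redundancy.tsv = res$functional_redundancy,
    genus_diversity_tests.tsv = res$genus_diversity$tests,
    differential.tsv = res$differential,
    joint_counts.tsv = res$joint$counts,
    gsea.tsv = res$gsea,
    unannotated.tsv = res$unannotated$per_module,
    crossfeeding.tsv = res$crossfeeding$correlations,
    process_sums.tsv = res$process_sums)
  for (nm in names(tables)) {
    wt(tables[[nm]], nm)
    if (!is.null(tables[[nm]])) counts[[sub(".tsv", "", nm, fixed = TRUE)]] <-
      nrow(tables[[nm]])
  }
  if (!is.null(res$partition))
    write_module_assignments(res$partition, file.path(out_dir, "modules.tsv"))
  cfg <- res$config
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- file.path(out_dir, "config.json")
  writeLines(cfg_json, tmp)
  manifest <- list(config_hash = unname(tools::md5sum(tmp)),
                   seed = cfg$seed,
                   beta = res$network$beta,
                   n_modules = if (!is.null(res$partition$eigengenes))
                     ncol(res$partition$eigengenes) else 0L,
                   row_counts = counts)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' Benchmark pipeline results against the planted truth
#'
#' Matches found modules to planted ones by best overlap and reports: the
#' adjusted Rand index between found and planted gene partitions (unassigned
#' genes form their own class), the fraction of truly affected modules whose
#' best-matching found module is trait-associated at q < alpha, the fraction
#' of planted differentially-active genes recovered at q < alpha, and the
#' fraction of planted tDGE-down genes with Mann-Whitney p < alpha in the
#' right direction.
#'
#' @param res Result list from [run_pipeline()] (run with `simulate`).
#' @param alpha Significance level.
#' @return list(ari, trait_recall, de_recall, tdge_recall, n_modules).
#' @export
benchmark_recovery <- function(res, alpha = 0.05) {
  truth <- res$truth
  if (is.null(truth)) stop_fmt("result has no synthetic truth")
  found <- res$partition$labels
  genes <- intersect(names(truth$modules), names(found))
  ari <- if (requireNamespace("mclust", quietly = TRUE))
    mclust::adjustedRandIndex(truth$modules[genes], found[genes])
  else NA_real_

  trait_recall <- NA_real_
  if (length(truth$affected_modules) > 0L && !is.null(res$partition$trait_stats)) {
    ts <- res$partition$trait_stats
    hit <- vapply(truth$affected_modules, function(pm) {
      members <- names(truth$modules)[truth$modules == pm]
      members <- intersect(members, names(found))
      if (length(members) == 0L) return(FALSE)
      best <- names(sort(table(found[members]), decreasing = TRUE))
      best <- setdiff(best, "M0")[1L]
      if (is.na(best)) return(FALSE)
      row <- ts[ts$module == best, ]
      nrow(row) == 1L && !is.na(row$q) && row$q < alpha
    }, logical(1))
    trait_recall <- mean(hit)
  }

  de_recall <- NA_real_
  if (!is.null(res$differential)) {
    planted <- names(truth$true_log2_effect)[truth$true_log2_effect != 0]
    de <- res$differential
    tested <- intersect(planted, de$gene)
    if (length(tested) > 0L) {
      qv <- de$q[match(tested, de$gene)]
      sgn <- sign(de$log2fc_expression[match(tested, de$gene)])
      de_recall <- mean(qv < alpha &
                          sgn == sign(truth$true_log2_effect[tested]))
    }
  }

  tdge_recall <- NA_real_
  if (!is.null(res$tdge)) {
    targets <- names(truth$tdge_down)[truth$tdge_down]
    pg <- res$tdge$per_gene
    tested <- intersect(targets, pg$gene)
    if (length(tested) > 0L) {
      i <- match(tested, pg$gene)
      tdge_recall <- mean(pg$p[i] < alpha & pg$log2fc_tdge[i] < 0)
    }
  }

  list(ari = ari, trait_recall = trait_recall, de_recall = de_recall,
       tdge_recall = tdge_recall,
       n_modules = if (!is.null(res$partition$eigengenes))
         ncol(res$partition$eigengenes) else 0L)
}
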