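make_paired_tables <- function(counts_mg, counts_mt, lens) {
  list(mg = gene_feature_table(counts_mg, lens, "MG"),
       mt = gene_feature_table(counts_mt, lens, "MT"))
}

test_that("tensor construction sums features per (taxon, KO) before TPM", {
  # two ORFs of the same KO and genus collapse to one tensor row;
  # the same KO in two genera stays resolved
  cm_mg <- matrix(c(10L, 20L, 30L, 40L), 4, 1,
                  dimnames = list(paste0("f", 1:4), "s1"))
  cm_mt <- matrix(c(5L, 10L, 15L, 20L), 4, 1,
                  dimnames = list(paste0("f", 1:4), "s1"))
  lens <- setNames(rep(1000L, 4), paste0("f", 1:4))
  tb <- make_paired_tables(cm_mg, cm_mt, lens)
  ann <- data.frame(
    feature_id = paste0("f", 1:4),
    ko_id = c("K1", "K1", "K1", "K2"),
    lineage = NA, genus = c("GA", "GA", "GB", "GA"),
    species = c("GA s", "GA s", "GB s", "GA s"))
  tens <- build_tensor(tb$mg, tb$mt, ann, rank = "genus")
  expect_equal(sort(unique(paste(tens$taxon, tens$ko))),
               c("GA K1", "GA K2", "GB K1"))
  # GA K1 pools f1+f2
  mg_rate_total <- sum(cm_mg[, 1] / 1000)
  mt_rate_total <- sum(cm_mt[, 1] / 1000)
  mt_tpm_ga_k1 <- (15 / 1000) / mt_rate_total * 1e6
  mg_tpm_k1 <- (60 / 1000) / mg_rate_total * 1e6
  got <- tens$value[tens$taxon == "GA" & tens$ko == "K1"]
  expect_equal(got, mt_tpm_ga_k1 / mg_tpm_k1, tolerance = 1e-12)
})

test_that("tensor marginalizes to the KO-level activity matrix", {
  sim <- small_sim(21)
  ko <- sim$annotation$ko_id[match(rownames(sim$mg$counts),
                                   sim$annotation$feature_id)]
  act <- mta_ratio(tpm_by_key(sim$mt, ko), tpm_by_key(sim$mg, ko))
  tens <- build_tensor(sim$mg, sim$mt, sim$annotation, "species")
  marg <- tensor_marginalize(tens)
  common <- intersect(rownames(act), rownames(marg))
  expect_equal(marg[common, colnames(act)], act[common, ],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("rank missing from all lineages is an error", {
  sim <- small_sim(22)
  ann <- sim$annotation
  ann$species <- NA
  expect_error(build_tensor(sim$mg, sim$mt, ann, "species"), "species")
})

test_that("differential activity: BH with one unit keeps q equal to p", {
  set.seed(2)
  mat <- matrix(rnorm(20, 5), 1, 20,
                dimnames = list("t1", paste0("s", 1:20)))
  meta <- data.frame(sample_id = paste0("s", 1:20),
                     group = rep(c("HC", "PD"), each = 10))
  res <- differential_mta(mat, meta, min_prevalence = 0.5)
  expect_equal(res$q, res$p)
})

test_that("differential activity refuses tiny groups and is calibrated under the null", {
  mat <- matrix(rnorm(40, 5), 2, 20,
                dimnames = list(c("a", "b"), paste0("s", 1:20)))
  meta <- data.frame(sample_id = paste0("s", 1:20),
                     group = c(rep("HC", 2), rep("PD", 18)))
  expect_error(differential_mta(mat, meta), "3 samples")

  set.seed(31)
  fp <- mean(replicate(100, {
    m <- matrix(rlnorm(30), 1, 30, dimnames = list("u", paste0("s", 1:30)))
    meta <- data.frame(sample_id = paste0("s", 1:30),
                       group = sample(rep(c("HC", "PD"), 15)))
    differential_mta(m, meta)$p < 0.05
  }))
  expect_lt(abs(fp - 0.05), 2.576 * sqrt(0.05 * 0.95 / 100) + 0.01)
})

test_that("a taxon silenced in PD is recovered as HC-associated", {
  sim <- synth_generate(synthetic_config(
    n_hc = 40, n_pd = 40, n_taxa = 12, n_ko = 80,
    module_sizes = c(20L, 20L), affected_modules = integer(0),
    group_effect = 1, dropout_taxa = 2L, p_drop = 1,
    depth_mg = 8e5, depth_mt = 8e5, seed = 55))
  tax <- taxon_mta(sim$mg, sim$mt, sim$annotation, "species")
  res <- differential_mta(tax, sim$meta, min_prevalence = 0.4)
  silenced_species <- paste0("Genus", sim$truth$dropout_taxa, " sp",
                             sim$truth$dropout_taxa)
  hit <- res[res$unit %in% silenced_species, ]
  expect_gt(nrow(hit), 0)
  expect_true(all(hit$q < 0.05))
  expect_true(all(hit$log2fc < 0))
})

test_that("ordination factor fit is exact for separated point clouds", {
  # two mirrored clouds with zero within-group variance
  act <- matrix(0, 5, 20, dimnames = list(paste0("g", 1:5), paste0("s", 1:20)))
  act[1, 1:10] <- 1; act[1, 11:20] <- -1
  act[2, ] <- rep(c(2, -2), each = 10)
  meta <- data.frame(sample_id = paste0("s", 1:20),
                     group = rep(c("HC", "PD"), each = 10))
  fit <- ordinate_and_fit(act, meta, n_perm = 99, seed = 3)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$p, 1 / 100)
})

test_that("ordination r2 is invariant to duplicating every sample", {
  set.seed(11)
  act <- matrix(rnorm(100), 5, 20,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:20)))
  meta <- data.frame(sample_id = paste0("s", 1:20),
                     group = rep(c("HC", "PD"), 10))
  f1 <- ordinate_and_fit(act, meta, n_perm = 99, seed = 1)
  act2 <- cbind(act, act)
  colnames(act2) <- paste0("s", 1:40)
  meta2 <- data.frame(sample_id = paste0("s", 1:40),
                      group = rep(meta$group, 2))
  f2 <- ordinate_and_fit(act2, meta2, n_perm = 99, seed = 1)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-9)
})

test_that("PCA scores are stable under feature permutation up to sign", {
  set.seed(12)
  act <- matrix(rnorm(200), 10, 20,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  meta <- data.frame(sample_id = paste0("s", 1:20),
                     group = rep(c("HC", "PD"), 10))
  f1 <- ordinate_and_fit(act, meta, n_perm = 99, seed = 1)
  f2 <- ordinate_and_fit(act[sample(10), ], meta, n_perm = 99, seed = 1)
  for (j in 1:2)
    expect_equal(abs(f1$scores[, j]), abs(f2$scores[, j]), tolerance = 1e-9)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-12)
})
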