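tensor_from_values <- function(vals) {
  # vals: named list sample -> named list ko -> named numeric (taxon shares)
  rows <- list()
  for (s in names(vals)) for (k in names(vals[[s]])) {
    v <- vals[[s]][[k]]
    rows[[length(rows) + 1L]] <- data.frame(
      taxon = names(v), ko = k, sample = s, value = unname(v),
      stringsAsFactors = FALSE)
  }
  toy_tensor(do.call(rbind, rows))
}

test_that("tDGE matches direct Shannon evaluation", {
  tens <- tensor_from_values(list(
    s1 = list(K1 = c(t1 = 1, t2 = 1, t3 = 1),
              K2 = c(t1 = 2),
              K3 = c(t1 = 0.7, t2 = 0.2, t3 = 0.1),
              K4 = c(t1 = 0, t2 = 0))))
  expect_equal(tdge(tens, "K1", "s1"), log(3), tolerance = 1e-12)
  expect_equal(tdge(tens, "K2", "s1"), 0)
  expect_equal(tdge(tens, "K3", "s1"), 0.8018186, tolerance = 1e-6)
  expect_true(is.na(tdge(tens, "K4", "s1")))

  td <- tdge_matrix(tens)
  expect_equal(unname(td["K1", "s1"]), log(3), tolerance = 1e-12)
  expect_equal(unname(td["K3", "s1"]), 0.8018186, tolerance = 1e-6)
  expect_true(is.na(td["K4", "s1"]))
})

test_that("tDGE is zero iff one taxon expresses, bounded by log of the count", {
  set.seed(1)
  for (i in 1:20) {
    k <- sample(1:6, 1)
    v <- setNames(rexp(k), paste0("t", 1:k))
    tens <- tensor_from_values(list(s1 = list(K = v)))
    h <- tdge(tens, "K", "s1")
    if (k == 1) expect_equal(h, 0) else expect_gt(h, 0)
    expect_lte(h, log(k) + 1e-9)
  }
  v <- setNames(rep(2.5, 4), paste0("t", 1:4))
  tens <- tensor_from_values(list(s1 = list(K = v)))
  expect_equal(tdge(tens, "K", "s1"), log(4), tolerance = 1e-9)
})

test_that("group comparison recovers planted dropout and nulls are flat", {
  sim <- synth_generate(synthetic_config(
    n_hc = 40, n_pd = 40, seed = 42))
  tens <- build_tensor(sim$mg, sim$mt, sim$annotation, "species")
  res <- tdge_group_compare(tens, sim$meta)
  targets <- names(sim$truth$tdge_down)[sim$truth$tdge_down]
  pg <- res$per_gene[res$per_gene$gene %in% targets, ]
  expect_gt(mean(pg$log2fc_tdge < 0), 0.9)
  expect_gt(mean(pg$p < 0.05 & pg$log2fc_tdge < 0), 0.8)

  # identical tensors for both groups give log2fc exactly 0
  tens_id <- tensor_from_values(list(
    s1 = list(K1 = c(t1 = 1, t2 = 2)), s2 = list(K1 = c(t1 = 1, t2 = 2)),
    s3 = list(K1 = c(t1 = 1, t2 = 2)), s4 = list(K1 = c(t1 = 1, t2 = 2)),
    s5 = list(K1 = c(t1 = 1, t2 = 2)), s6 = list(K1 = c(t1 = 1, t2 = 2))))
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     group = rep(c("HC", "PD"), 3))
  res_id <- tdge_group_compare(tens_id, meta)
  expect_equal(res_id$per_gene$log2fc_tdge, 0)
})

test_that("functional redundancy hits the Rao limits", {
  # two species, equal shares, disjoint gene sets: FR = 0
  tens <- tensor_from_values(list(
    s1 = list(K1 = c(sp1 = 1), K2 = c(sp2 = 1))))
  fr <- functional_redundancy(tens)
  expect_equal(fr$species_diversity, 0.5)
  expect_equal(fr$rao_q, 0.5)
  expect_equal(fr$functional_redundancy, 0)

  # identical trait profiles: Q = 0, FR = D
  tens2 <- tensor_from_values(list(
    s1 = list(K1 = c(sp1 = 1, sp2 = 1), K2 = c(sp1 = 1, sp2 = 1))))
  fr2 <- functional_redundancy(tens2)
  expect_equal(fr2$rao_q, 0)
  expect_equal(fr2$functional_redundancy, fr2$species_diversity)

  # single species: FR = 0 by convention, logged
  tens1 <- tensor_from_values(list(s1 = list(K1 = c(sp1 = 2))))
  expect_message(fr1 <- functional_redundancy(tens1), "convention")
  expect_equal(fr1$functional_redundancy, 0)
})

test_that("Rao Q matches the explicit double sum on a hand-set instance", {
  # three species with abundances (0.5, 0.3, 0.2) and binary profiles
  tens <- tensor_from_values(list(s1 = list(
    K1 = c(a = 0.5, b = 0.3), K2 = c(a = 0.5, c = 0.2),
    K3 = c(b = 0.3, c = 0.2), K4 = c(a = 0.5))))
  fr <- functional_redundancy(tens)
  ab <- c(a = 1.5, b = 0.6, c = 0.4)
  p <- ab / sum(ab)
  prof <- rbind(a = c(1, 1, 0, 1), b = c(1, 0, 1, 0), c = c(0, 1, 1, 0))
  d <- matrix(0, 3, 3, dimnames = list(names(p), names(p)))
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    either <- prof[i, ] | prof[j, ]
    d[i, j] <- sum(xor(prof[i, ], prof[j, ])) / sum(either)
  }
  q_oracle <- 0
  for (i in 1:3) for (j in 1:3) q_oracle <- q_oracle + p[i] * p[j] * d[i, j]
  expect_equal(fr$rao_q, unname(q_oracle), tolerance = 1e-12)
  expect_equal(fr$species_diversity, unname(1 - sum(p^2)), tolerance = 1e-12)
})

test_that("FR is invariant to species order and bounded by D", {
  set.seed(3)
  for (rep in 1:10) {
    n_sp <- sample(3:6, 1)
    n_ko <- 8
    rows <- list()
    for (sp in paste0("sp", 1:n_sp)) {
      expressed <- sample(n_ko, sample(2:n_ko, 1))
      for (k in expressed)
        rows[[length(rows) + 1L]] <- data.frame(
          taxon = sp, ko = paste0("K", k), sample = "s1",
          value = rexp(1), stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    fr1 <- functional_redundancy(toy_tensor(df))
    fr2 <- functional_redundancy(toy_tensor(df[sample(nrow(df)), ]))
    expect_equal(fr1$functional_redundancy, fr2$functional_redundancy,
                 tolerance = 1e-12)
    expect_gte(fr1$functional_redundancy, -1e-12)
    expect_lte(fr1$rao_q, fr1$species_diversity + 1e-12)
  }
})

test_that("genus diversity indices hit closed forms and flag planted silencing", {
  tens <- tensor_from_values(list(
    s1 = list(K1 = c(GA = 1), K2 = c(GA = 1), K3 = c(GA = 1),
              K4 = c(GA = 1), K5 = c(GA = 1)),
    s2 = list(K1 = c(GB = 2))))
  meta <- data.frame(sample_id = c("s1", "s2"), group = c("HC", "PD"))
  gd <- genus_expression_diversity(tens, meta, c("GA", "GB", "GZ"))
  ga_s1 <- gd$per_sample[gd$per_sample$genus == "GA" &
                           gd$per_sample$sample == "s1", ]
  expect_equal(ga_s1$richness, 5L)
  expect_equal(ga_s1$inv_simpson, 5, tolerance = 1e-9)
  expect_equal(ga_s1$shannon, log(5), tolerance = 1e-9)
  ga_s2 <- gd$per_sample[gd$per_sample$genus == "GA" &
                           gd$per_sample$sample == "s2", ]
  expect_equal(ga_s2$richness, 0L)
  expect_true(is.na(ga_s2$shannon))
  expect_true(is.na(gd$per_sample$richness[gd$per_sample$genus == "GZ"][1]))

  # planted PD silencing of a genus lowers richness significantly
  sim <- synth_generate(synthetic_config(n_hc = 40, n_pd = 40, seed = 5))
  tg <- build_tensor(sim$mg, sim$mt, sim$annotation, "genus")
  dropped_genus <- paste0("Genus", sim$truth$dropout_taxa[1])
  gd2 <- genus_expression_diversity(tg, sim$meta, dropped_genus)
  rich <- gd2$tests[gd2$tests$index == "richness", ]
  expect_lt(rich$mean_pd, rich$mean_hc)
  expect_lt(rich$p, 0.05)
})

test_that("inverse Simpson of a uniform distribution equals the count", {
  expect_equal(as.numeric(vegan::diversity(rep(3, 7), "invsimpson")), 7,
               tolerance = 1e-12)
})
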