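test_that("Shannon diversity matches closed forms", {
  expect_equal(shannon_diversity(c(5, 0, 0)), 0)
  expect_equal(shannon_diversity(rep(1, 4)), 2)
  expect_equal(shannon_diversity(c(0.5, 0.25, 0.25)), 1.5)
  expect_equal(shannon_diversity(rep(1, 4), base = exp(1)), log(4))
  expect_error(shannon_diversity(c(0, 0)), "all-zero")
})

test_that("Mann-Whitney volcano p-values match exact enumeration", {
  mk_md <- function(n1, n2) data.frame(
    sample_id = paste0("s", seq_len(n1 + n2)),
    group = rep(c("a", "b"), c(n1, n2)))
  # canonical fully separated case
  prof <- matrix(c(1, 2, 3, 4, 5, 6), 6, 1,
                 dimnames = list(paste0("s", 1:6), "f1"))
  res <- volcano_group_test(prof, mk_md(3, 3), "group")
  expect_equal(res$p_raw, 0.1)
  expect_equal(res$p_raw, mw_exact_p(1:3, 4:6))

  # random small-sample cases against the enumeration oracle
  set.seed(31)
  for (i in 1:8) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    vals <- sample(1:100, n1 + n2)  # distinct values: exact test applies
    prof_i <- matrix(vals, ncol = 1,
                     dimnames = list(paste0("s", seq_len(n1 + n2)), "f"))
    res_i <- volcano_group_test(prof_i, mk_md(n1, n2), "group")
    expect_equal(res_i$p_raw, mw_exact_p(vals[1:n1], vals[-(1:n1)]),
                 info = paste("case", i))
  }
})

test_that("volcano test reports near-null results for identical groups and valid adjustment", {
  set.seed(5)
  prof <- matrix(rep(rnorm(10, 50, 1), 4), 8, 5, byrow = TRUE,
                 dimnames = list(paste0("s", 1:8), paste0("f", 1:5)))
  md <- data.frame(sample_id = paste0("s", 1:8),
                   group = rep(c("a", "b"), each = 4))
  res <- volcano_group_test(prof, md, "group")
  expect_true(all(res$p_raw > 0.9))
  expect_true(all(abs(res$log2_fold_change) < 1e-6))
  expect_true(all(res$p_adjusted >= res$p_raw))
  md3 <- md; md3$group[1] <- "c"
  expect_error(volcano_group_test(prof, md3, "group"), "pairwise")
})

test_that("the planted fiber shift is the only volcano discovery on the cohort fixture", {
  fx <- make_toy_fixture("two_group_cohort", seed = 3)
  ifdp_m <- compute_ifdp(fx$ffp, fx$M)
  res <- volcano_group_test(ifdp_m, fx$metadata, "group")
  flagged <- res$feature[res$p_adjusted < 0.05]
  expect_identical(flagged, fx$planted_fiber)
  # shift planted in group B: capacity higher in B, so A-vs-B fold change < 0
  expect_lt(res$log2_fold_change[res$feature == fx$planted_fiber], 0)
})

test_that("unstratified PERMANOVA reproduces the reference implementation", {
  set.seed(17)
  prof <- matrix(rnorm(20 * 6), 20, 6,
                 dimnames = list(sprintf("s%02d", 1:20), paste0("f", 1:6)))
  prof[11:20, 1:2] <- prof[11:20, 1:2] + 1.5
  md <- data.frame(sample_id = rownames(prof),
                   group = rep(c("a", "b"), each = 10))
  ours <- permanova_stratified(prof, md, "group", "none", n_perm = 999,
                               seed = 3)
  ref <- vegan::adonis2(dist(prof) ~ group, data = md, permutations = 999)
  expect_equal(ours$F, ref$F[1], tolerance = 1e-10)
  expect_lt(abs(ours$p - ref$`Pr(>F)`[1]), 0.02)
})

test_that("PERMANOVA separates distinct point clouds but not species-confounded labels", {
  set.seed(23)
  prof <- matrix(rnorm(20 * 4), 20, 4,
                 dimnames = list(sprintf("s%02d", 1:20), paste0("f", 1:4)))
  prof[11:20, ] <- prof[11:20, ] + 4
  md <- data.frame(sample_id = rownames(prof),
                   group = rep(c("a", "b"), each = 10),
                   species = rep(paste0("sp", 1:10), each = 2),
                   phylo_class = rep(c("c1", "c2"), 10))
  well_sep <- permanova_stratified(prof, md, "group", "none",
                                   n_perm = 999, seed = 1)
  expect_lte(well_sep$p, 0.01)

  # labels perfectly confounded with one species cluster: cluster-level
  # permutation sees the separation as a species effect, p not small
  md2 <- md
  md2$species <- rep(c("spA", "spB"), each = 10)
  conf <- permanova_stratified(prof, md2, "group", "cluster_by_species",
                               n_perm = 199, seed = 1)
  expect_gt(conf$p, 0.4)
})

test_that("restricted permutation schemes hold their nominal type-I error", {
  # quick calibration check (the full 200-simulation version runs in the
  # acceptance suite); 60 null datasets per scheme
  n_sim <- 60
  rej <- matrix(FALSE, n_sim, 2,
                dimnames = list(NULL, c("cluster_by_species", "within_class")))
  for (s in seq_len(n_sim)) {
    set.seed(1000 + s)
    prof <- matrix(rnorm(20 * 6), 20, 6,
                   dimnames = list(sprintf("s%02d", 1:20), paste0("f", 1:6)))
    species <- rep(paste0("sp", 1:10), each = 2)
    cls <- rep(c("c1", "c2"), each = 10)
    sp_lab <- setNames(sample(rep(c("a", "b"), 5)), paste0("sp", 1:10))
    md_cl <- data.frame(sample_id = rownames(prof), species = species,
                        phylo_class = cls, group = sp_lab[species])
    rej[s, 1] <- permanova_stratified(prof, md_cl, "group",
                                      "cluster_by_species", n_perm = 199,
                                      seed = s)$p <= 0.05
    grp <- unlist(lapply(split(seq_len(20), cls),
                         function(i) sample(rep(c("a", "b"), length(i) / 2))))
    md_wc <- md_cl
    md_wc$group[unlist(split(seq_len(20), cls))] <- grp
    rej[s, 2] <- permanova_stratified(prof, md_wc, "group", "within_class",
                                      n_perm = 199, seed = s)$p <= 0.05
  }
  # loose sanity bounds at this simulation size; the acceptance suite uses
  # the binomial CI at 200 simulations
  expect_lt(mean(rej[, 1]), 0.15)
  expect_lt(mean(rej[, 2]), 0.15)
})

test_that("agreement permutation test matches exhaustive enumeration on small instances", {
  # 4 clades, 1 fiber, single no-growth case at the lowest clade: exact 0.5
  ifdp1 <- matrix(c(1, 2, 3, 4), 4, 1,
                  dimnames = list(LETTERS[1:4], "F1"))
  growth1 <- matrix("untested", 4, 1, dimnames = dimnames(ifdp1))
  growth1["A", "F1"] <- "no_growth"
  res1 <- agreement_permutation_test(ifdp1, growth1, n_shuffles = 2000,
                                     seed = 4)
  expect_equal(res1$n_agree_nogrow, 1)
  exact1 <- agreement_exact_p(ifdp1, growth1)
  expect_equal(unname(exact1["p_nogrow"]), 0.5)
  expect_lt(abs(res1$p_nogrow - 0.5), 0.05)

  # 4 clades x 2 fibers with growth and no-growth cases
  set.seed(41)
  ifdp2 <- matrix(sample(1:8), 4, 2, dimnames = list(LETTERS[1:4],
                                                     c("F1", "F2")))
  growth2 <- matrix("untested", 4, 2, dimnames = dimnames(ifdp2))
  growth2[which.min(ifdp2[, 1]), 1] <- "no_growth"
  growth2[which.max(ifdp2[, 2]), 2] <- "grows"
  growth2[which.min(ifdp2[, 2]), 2] <- "no_growth"
  res2 <- agreement_permutation_test(ifdp2, growth2, n_shuffles = 4000,
                                     seed = 8)
  exact2 <- agreement_exact_p(ifdp2, growth2)
  expect_lt(abs(res2$p_nogrow - exact2["p_nogrow"]), 0.05)
  expect_lt(abs(res2$p_grow - exact2["p_grow"]), 0.05)

  all_untested <- matrix("untested", 4, 1, dimnames = dimnames(ifdp1))
  expect_error(agreement_permutation_test(ifdp1, all_untested), "untested")
})

test_that("k independently agreeing fibers give p near 0.5^k and ties are flagged", {
  fx <- make_toy_fixture("clades_growth", seed = 2)
  res <- agreement_permutation_test(fx$clade_ifdp, fx$growth,
                                    n_shuffles = 4000, seed = 6)
  expect_equal(res$n_agree_nogrow, 6)
  expect_lt(abs(res$p_nogrow - 0.5^6), 0.01)
  expect_lt(abs(res$p_grow - 0.5^6), 0.01)

  tied <- fx$clade_ifdp
  tied[, 1] <- 1
  expect_warning(
    agreement_permutation_test(tied, fx$growth, n_shuffles = 10, seed = 1),
    "tied")
})

test_that("country-versus-rest t-statistics flag only planted shifts", {
  set.seed(51)
  countries <- rep(c("AT", "NL", "ES", "CN"), each = 30)
  prof <- matrix(rnorm(120 * 6, mean = 10), 120, 6,
                 dimnames = list(sprintf("s%03d", 1:120), paste0("f", 1:6)))
  prof[countries == "AT", "f1"] <- prof[countries == "AT", "f1"] + 5
  md <- data.frame(sample_id = rownames(prof), country = countries)
  res <- country_tstat_matrix(prof, md, "country")
  expect_identical(dim(res$t), c(4L, 6L))
  expect_true(res$significant["AT", "f1"])
  expect_gt(res$t["AT", "f1"], 0)
  expect_false(any(res$significant[, setdiff(colnames(prof), "f1")]))

  # a country with one sample is excluded with a warning
  md2 <- md; md2$country[1] <- "XX"
  expect_warning(res2 <- country_tstat_matrix(prof[-(2:30), ], md2[-(2:30), ],
                                              "country"),
                 "XX")
  expect_identical(res2$excluded, "XX")
})

test_that("ordination exposes rank structure and clustering separates blocks", {
  base <- matrix(rnorm(6 * 5, sd = 1e-8), 6, 5)
  rank1 <- outer(seq_len(6), seq_len(5)) + base
  rownames(rank1) <- paste0("s", 1:6); colnames(rank1) <- paste0("f", 1:5)
  pc <- ordination_and_clustering(rank1, "pca", n_components = 2)
  expect_gt(pc$explained_var[1], 0.999)
  expect_error(ordination_and_clustering(rank1, "pca", n_components = 10),
               "components")

  set.seed(61)
  blocks <- rbind(matrix(rnorm(4 * 5), 4, 5),
                  matrix(rnorm(4 * 5, mean = 8), 4, 5))
  rownames(blocks) <- c(paste0("x", 1:4), paste0("y", 1:4))
  hc <- ordination_and_clustering(blocks, "hclust")
  split2 <- cutree(hc, k = 2)
  expect_equal(length(unique(split2[1:4])), 1)
  expect_equal(length(unique(split2[5:8])), 1)
  expect_false(split2[1] == split2[5])
})

test_that("random-forest harness returns one AUC per iteration and separates separable data", {
  set.seed(71)
  prof <- matrix(rnorm(30 * 8), 30, 8,
                 dimnames = list(sprintf("s%02d", 1:30), paste0("f", 1:8)))
  prof[16:30, 1:3] <- prof[16:30, 1:3] + 6
  md <- data.frame(sample_id = rownames(prof),
                   group = rep(c("a", "b"), each = 15))
  res <- rf_group_prediction(prof, md, "group", n_iter = 25, seed_base = 100)
  expect_length(res$auc, 25)
  expect_gte(res$mean_auc, 0.99)
  expect_equal(nrow(res$mean_roc), 101)

  # bit-for-bit reproducibility for a fixed seed base
  res2 <- rf_group_prediction(prof, md, "group", n_iter = 5, seed_base = 100)
  expect_identical(res$auc[1:5], res2$auc)

  md_bad <- md; md_bad$group <- c("a", rep("b", 29))
  expect_error(rf_group_prediction(prof, md_bad, "group", n_iter = 2),
               "class")
})
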