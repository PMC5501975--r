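test_that("degenerate and hand-enumerated permutation tests are exact", {
  res <- permutation_de_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(res$p_tn, 1)
  expect_equal(res$log2fold, 0)

  res <- permutation_de_test(c(3, 4), c(1, 2))
  expect_true(res$exhaustive)
  expect_equal(res$p_tn, 1 / 3)
  expect_equal(res$log2fold, 2)

  res <- permutation_de_test(c(10, 11, 12), c(1, 2, 3))
  expect_equal(res$p_tn, 0.1)
  expect_equal(res$log2fold, 9)
})

test_that("exhaustive permutation p matches the enumeration oracle", {
  set.seed(11)
  for (i in 1:60) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    tum <- round(rnorm(n1, 1), 3)
    nor <- round(rnorm(n2), 3)
    res <- permutation_de_test(tum, nor)
    expect_true(res$exhaustive)
    expect_equal(res$p_tn, oracle_perm_p(tum, nor))
  }
})

test_that("Monte-Carlo permutation p converges to the exhaustive value", {
  tum <- c(2.1, 3.3, 1.8, 2.9)
  nor <- c(0.4, 1.1, 0.2, 1.6)
  exact <- permutation_de_test(tum, nor)$p_tn
  mc <- permutation_de_test(tum, nor, n_perm = 100000L, seed = 3L,
                            exhaustive_limit = 1L)$p_tn
  expect_false(permutation_de_test(tum, nor, exhaustive_limit = 1L)$exhaustive)
  expect_lt(abs(mc - exact), 0.01)
})

test_that("permutation test rejects insufficient or non-finite input", {
  expect_error(permutation_de_test(1, c(1, 2)), "insufficient")
  expect_error(permutation_de_test(c(1, NA), c(1, 2)), "finite")
})

test_that("BH adjustment equals the brute-force step-up on random vectors", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(5)
  for (i in 1:200) {
    p <- runif(sample(1:60, 1))
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
  expect_error(bh_fdr(c(0.5, 0)), "outside")
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
})

test_that("BH output is order-invariant and stays in (0, 1]", {
  set.seed(9)
  p <- runif(30)
  q <- bh_fdr(p)
  o <- sample(30)
  expect_equal(bh_fdr(p[o]), q[o])
  expect_true(all(q > 0 & q <= 1))
})

test_that("Pearson correlation matches its closed forms", {
  expect_equal(mirna_mrna_correlation(c(1, 2, 3), c(-1, -2, -3),
                                      min_matched = 3)$r, -1)
  res <- mirna_mrna_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3),
                                min_matched = 4)
  expect_equal(res$r, 0.6)
  # df = 2 closed-form t CDF: F(t) = 1/2 + t / (2 sqrt(t^2 + 2))
  tval <- 0.6 * sqrt(2) / sqrt(1 - 0.36)
  expect_equal(res$p_r, 2 * (1 - (0.5 + tval / (2 * sqrt(tval^2 + 2)))))
  expect_equal(round(res$p_r, 3), 0.4)
})

test_that("correlation handles absence, perfection and degeneracy", {
  res <- mirna_mrna_correlation(1:4, c(3, 1, 2, 4), min_matched = 5)
  expect_true(is.na(res$r) && is.na(res$p_r))
  expect_equal(res$n_matched, 4L)
  perfect <- mirna_mrna_correlation(1:6, -(1:6))
  expect_equal(perfect$r, -1)
  expect_gt(perfect$p_r, 0)  # floored, never exactly 0
  expect_error(mirna_mrna_correlation(rep(1, 6), 1:6), "zero variance")
})

test_that("correlation p-values are calibrated under the null", {
  set.seed(21)
  n <- 12
  p <- replicate(4000, {
    mirna_mrna_correlation(rnorm(n), rnorm(n), min_matched = n)$p_r
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort_gene_stats fills the full table and flags planted effects", {
  cfgs <- study_configs(101L)
  sim <- simulate_cohorts(cfgs[1])
  ch <- sim$cohorts[[1]]
  st <- cohort_gene_stats(ch, n_perm = 2000L, seed = 7L)
  expect_equal(nrow(st), 500L)
  expect_true(all(st$p_tn > 0 & st$p_tn <= 1))
  planted <- sim$truth$planted_target_ids
  # strong planted effect dominates the FDR ranking
  expect_lte(max(st$fdr[st$gene_id %in% planted]), min(st$fdr) + 1e-12)
  expect_true(all(st$log2fold[st$gene_id %in% planted] < -1))
  expect_true(all(st$r[st$gene_id %in% planted] < 0))
})

test_that("a cohort without matched samples leaves correlations absent", {
  cfg <- cohort_sim_config(n_genes = 40L, n_planted_targets = 2L,
                           n_tumor = 8L, n_normal = 8L, n_matched = 0L,
                           seed = 5L, name = "nomatch")
  ch <- simulate_cohorts(cfg)$cohorts[[1]]
  st <- cohort_gene_stats(ch, n_perm = 500L)
  expect_true(all(is.na(st$r)))
  expect_true(all(is.na(st$p_r)))
  expect_true(all(is.finite(st$p_tn)))
  expect_true(all(is.finite(st$log2fold)))
})

test_that("single-gene and cohort-level permutation paths agree", {
  cfg <- cohort_sim_config(n_genes = 10L, n_planted_targets = 1L,
                           n_tumor = 4L, n_normal = 4L, n_matched = 4L,
                           seed = 3L, name = "tiny")
  ch <- simulate_cohorts(cfg)$cohorts[[1]]
  st <- cohort_gene_stats(ch)  # choose(8,4)=70 -> exhaustive
  tum <- names(ch$sample_class)[ch$sample_class == "tumor"]
  nor <- names(ch$sample_class)[ch$sample_class == "normal"]
  for (g in rownames(ch$mrna)[c(1, 5, 10)]) {
    single <- permutation_de_test(ch$mrna[g, tum], ch$mrna[g, nor])
    expect_equal(st$p_tn[st$gene_id == g], single$p_tn)
    expect_equal(st$log2fold[st$gene_id == g], single$log2fold)
  }
})

test_that("genes with missing values are dropped with a warning", {
  cfg <- cohort_sim_config(n_genes = 20L, n_planted_targets = 0L,
                           n_tumor = 5L, n_normal = 5L, n_matched = 5L,
                           seed = 2L, name = "na")
  ch <- simulate_cohorts(cfg)$cohorts[[1]]
  ch$mrna[3, 2] <- NA
  expect_warning(st <- cohort_gene_stats(ch, n_perm = 200L), "missing")
  expect_equal(nrow(st), 19L)
})
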