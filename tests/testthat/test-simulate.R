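test_that("cohort configs validate their invariants", {
  expect_error(cohort_sim_config(n_genes = 10, n_planted_targets = 11),
               "invalid config")
  expect_error(cohort_sim_config(n_matched = 31), "invalid config")
  expect_error(cohort_sim_config(noise_sd = 0), "positive")
  expect_error(cohort_sim_config(frac_decoy_down = 1.2), "\\[0, 1\\]")
})

test_that("identical config and seed reproduce identical cohorts", {
  cfg <- cohort_sim_config(n_genes = 30L, n_planted_targets = 3L,
                           n_tumor = 6L, n_normal = 6L, n_matched = 5L,
                           seed = 7L, name = "det")
  a <- simulate_cohorts(cfg)
  b <- simulate_cohorts(cfg)
  expect_identical(a$cohorts[[1]]$mrna, b$cohorts[[1]]$mrna)
  expect_identical(a$cohorts[[1]]$mirna, b$cohorts[[1]]$mirna)
  expect_identical(a$truth$planted_target_ids, b$truth$planted_target_ids)
})

test_that("truth classes are disjoint and match the generated structure", {
  cfg <- cohort_sim_config(n_genes = 200L, n_planted_targets = 10L,
                           frac_decoy_down = 0.1, frac_decoy_corr = 0.1,
                           n_tumor = 10L, n_normal = 10L, n_matched = 8L,
                           seed = 9L)
  tr <- simulate_cohorts(cfg)$truth
  expect_length(intersect(tr$planted_target_ids, tr$decoy_down_ids), 0)
  expect_length(intersect(tr$planted_target_ids, tr$decoy_corr_ids), 0)
  expect_length(intersect(tr$decoy_down_ids, tr$decoy_corr_ids), 0)
  expect_length(tr$planted_target_ids, 10)
  expect_equal(unname(tr$slope[tr$planted_target_ids]), rep(-1, 10))
  expect_true(all(tr$shift[tr$decoy_down_ids] == -2))
  expect_true(all(tr$shift[tr$decoy_corr_ids] == 0))
})

test_that("null generator has zero expected log2 fold change", {
  folds <- vapply(1:200, function(s) {
    cfg <- cohort_sim_config(n_genes = 4L, n_planted_targets = 1L,
                             n_tumor = 5L, n_normal = 5L, n_matched = 5L,
                             mirna_tumor_shift = 0, target_slope = 0,
                             frac_decoy_down = 0, frac_decoy_corr = 0,
                             seed = s)
    ch <- simulate_cohorts(cfg)$cohorts[[1]]
    tum <- ch$sample_class == "tumor"
    mean(rowMeans(ch$mrna[, tum]) - rowMeans(ch$mrna[, !tum]))
  }, numeric(1))
  se <- sd(folds) / sqrt(length(folds))
  expect_lt(abs(mean(folds)), 3 * se + 1e-12)
})

test_that("near-noiseless planted target is almost perfectly anticorrelated", {
  # pooled matched samples: the miRNA's tumor shift dominates its tiny
  # noise, so the coupling is near-deterministic across the matched set
  cfg <- cohort_sim_config(n_genes = 5L, n_planted_targets = 1L,
                           n_tumor = 10L, n_normal = 10L, n_matched = 10L,
                           mirna_tumor_shift = 2, target_slope = -1,
                           noise_sd = 0.01, frac_decoy_down = 0,
                           frac_decoy_corr = 0, seed = 12L,
                           matched_mode = "pooled")
  sim <- simulate_cohorts(cfg)
  ch <- sim$cohorts[[1]]
  g <- sim$truth$planted_target_ids
  r <- cor(ch$mrna[g, ch$matched], ch$mirna[ch$matched])
  expect_lt(r, -0.99)
})

test_that("matched samples respect the configured mode", {
  cfg_t <- cohort_sim_config(n_genes = 10L, n_tumor = 6L, n_normal = 6L,
                             n_matched = 4L, seed = 1L,
                             matched_mode = "tumor")
  ch <- simulate_cohorts(cfg_t)$cohorts[[1]]
  expect_true(all(ch$sample_class[ch$matched] == "tumor"))
  cfg_p <- cohort_sim_config(n_genes = 10L, n_tumor = 6L, n_normal = 6L,
                             n_matched = 4L, seed = 1L,
                             matched_mode = "pooled")
  chp <- simulate_cohorts(cfg_p)$cohorts[[1]]
  expect_setequal(unique(unname(chp$sample_class[chp$matched])),
                  c("tumor", "normal"))
})

test_that("UTR generator plants sites exactly where the truth says", {
  genes <- sprintf("g%02d", 1:6)
  plan <- list(g01 = "8mer", g02 = c("7mer-m8", "6mer"), g03 = "offset-6mer")
  sim <- simulate_utrs(genes, MIR21, site_plan = plan, length = 120L,
                       seed = 3L)
  expect_equal(length(sim$utrs), 6L)
  expect_true(all(nchar(as.character(sim$utrs)) == 120L))
  for (k in seq_len(nrow(sim$truth))) {
    row <- sim$truth[k, ]
    found <- find_seed_sites(as.character(sim$utrs[[row$gene_id]]), MIR21,
                             site_types = row$site_type)
    expect_true(any(found$start == row$start & found$end == row$end))
  }
  # planting created no stray site at equal-or-higher stringency
  s1 <- find_seed_sites(as.character(sim$utrs[["g01"]]), MIR21, "8mer")
  expect_equal(nrow(s1), 1L)
})

test_that("UTR generation is byte-deterministic and validates its config", {
  a <- simulate_utrs(c("x", "y"), MIR21, site_plan = list(x = "8mer"),
                     length = 60L, seed = 5L)
  b <- simulate_utrs(c("x", "y"), MIR21, site_plan = list(x = "8mer"),
                     length = 60L, seed = 5L)
  expect_identical(as.character(a$utrs), as.character(b$utrs))
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(a$utrs, f1)
  Biostrings::writeXStringSet(b$utrs, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_error(simulate_utrs("g", MIR21, site_plan = list(g = "8mer"),
                             length = 9L), "length")
  expect_error(simulate_utrs("g", MIR21, site_plan = list(g = "9mer")),
               "unsupported")
})

test_that("background 8mer rate matches the expected occurrence probability", {
  # brute-force expectation: per-window match probability is the product
  # of the background base probabilities of the 8mer pattern; for a
  # 200-nt UTR the chance of >= 1 match is ~ 1 - (1 - p)^193
  n_utr <- 4000L
  gc <- 0.5
  sim <- simulate_utrs(sprintf("u%04d", 1:n_utr), MIR21, length = 200L,
                       gc_fraction = gc, seed = 17L)
  hits <- vapply(as.character(sim$utrs), function(s) {
    nrow(find_seed_sites(s, MIR21, "8mer")) > 0
  }, logical(1))
  p_window <- 0.25^8  # uniform composition at gc = 0.5
  expected <- 1 - (1 - p_window)^(200 - 8 + 1)
  se <- sqrt(expected * (1 - expected) / n_utr)
  expect_lt(abs(mean(hits) - expected), 3 * se + 1e-4)
})

test_that("dose-response generator honours its closed form and determinism", {
  expect_equal(simulate_dose_response(2, 10, 10)$fa, 0.5)
  expect_equal(simulate_dose_response(1, 10, 100)$fa, 10 / 11)
  a <- simulate_dose_response(1.5, 20, c(1, 10, 50), noise_sd = 0.05,
                              seed = 2L)
  b <- simulate_dose_response(1.5, 20, c(1, 10, 50), noise_sd = 0.05,
                              seed = 2L)
  expect_identical(a, b)
  expect_true(all(a$fa > 0 & a$fa < 1))
  expect_error(simulate_dose_response(-1, 10, 1), "invalid config")
  expect_error(simulate_dose_response(1, 10, c(1, -2)), "positive")
  expect_error(simulate_additive_combination(list(m = 1, Dm = 1),
                                             list(m = 1, Dm = 1),
                                             numeric(0), 1),
               "invalid config")
})
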