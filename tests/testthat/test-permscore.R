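# Permutation scoring against the closed-form hypergeometric null.

test_that("eligibility drops blocklisted and zero-overlap compounds", {
  prof <- list(hit = c("1", "2"), miss = c("8", "9"), ion = c("1"))
  gs <- gene_set("g", c("1", "2", "3"))
  kept <- eligible_profiles(prof, gs, blocklist = "ion")
  expect_identical(names(kept), "hit")
})

test_that("permutation p-value and Z-score on explicit null samples", {
  null <- c(0, 1, 1, 2, 3)
  expect_equal(permutation_pvalue(2, null), 1 / 5)   # strict tail
  expect_equal(permutation_pvalue(3, null), 0)       # may be exactly 0
  expect_equal(permutation_pvalue(-1, null), 1)
  expect_equal(permutation_zscore(mean(null), null), 0)
  expect_gt(permutation_zscore(4, null), permutation_zscore(3, null))
  expect_error(permutation_zscore(1, rep(2, 10)), "zero spread")
})

test_that("analytic p-value equals the strict hypergeometric tail", {
  expect_equal(analytic_pvalue(2, 3, 4, 10), enum_hyper_tail(10, 4, 3, 2,
                                                             strict = TRUE),
               tolerance = 1e-12)
  # strict vs non-strict differ by the point mass at the observed count
  expect_equal(hypergeom_tail(10, 4, 3, 2) - analytic_pvalue(2, 3, 4, 10),
               dhyper(2, 4, 6, 3), tolerance = 1e-12)
  # impossible exceedance
  expect_identical(analytic_pvalue(3, 3, 4, 10), 0)
})

test_that("null sampler reproduces the hypergeometric overlap law", {
  sampler <- sample_null(4, universe_size = 10, n_permutations = 20000,
                         seed = 5)
  ov <- null_overlaps(sampler, targets_idx = c(2, 5, 9))  # m = 3
  expect_length(ov, 20000)
  for (k in 0:3) {
    p_exact <- dhyper(k, 3, 7, 4)
    se <- sqrt(p_exact * (1 - p_exact) / 20000)
    expect_lt(abs(mean(ov == k) - p_exact), 4 * se + 1e-9)
  }
  # degenerate draws
  expect_true(all(null_overlaps(sample_null(10, 10, 50, 1), 1:3) == 3))
  expect_true(all(null_overlaps(sample_null(0, 10, 50, 1), 1:3) == 0))
})

test_that("Monte-Carlo p converges to the analytic tail", {
  set.seed(17)
  ok <- 0
  for (rep in 1:15) {
    U <- sample(8:20, 1)
    x <- sample(1:(U - 1), 1)
    m <- sample(1:(U - 1), 1)
    obs <- sample(0:min(m, x), 1)
    sampler <- sample_null(x, U, 10000, seed = rep)
    ov <- null_overlaps(sampler, seq_len(m))
    p_hat <- permutation_pvalue(obs, ov)
    p <- analytic_pvalue(obs, m, x, U)
    se <- sqrt(p * (1 - p) / 10000)
    if (abs(p_hat - p) <= 3 * se + 1e-12) ok <- ok + 1
  }
  expect_gte(ok / 15, 0.95 - 1e-9)
})

test_that("score_model is deterministic given the seed", {
  cfg <- synth_config(seed = 2, n_compounds = 30)
  cir <- make_cir_sets(cfg)
  hct <- make_hct(cfg, cir, herbs = "h1")
  prof <- compound_profiles(dedupe_ct(classify_direct(hct$ct_edges)))
  gs <- union_sets(cir)
  a <- score_model(prof, gs, n_permutations = 2000, seed = 99)
  b <- score_model(prof, gs, n_permutations = 2000, seed = 99)
  expect_identical(a$results, b$results)
  c <- score_model(prof, gs, n_permutations = 2000, seed = 100)
  expect_false(identical(a$results$pvalue, c$results$pvalue))
  # recorded settings
  expect_identical(a$results$seed[1], 99L)
  expect_identical(a$settings$method, "permutation")
})

test_that("identical profiles share a p-value; positives antitone in q", {
  prof <- list(a = c("1", "2", "3"), b = c("1", "2", "3"),
               c = c("1", "9", "10"))
  gs <- gene_set("g", as.character(1:5))
  md <- score_model(prof, gs, universe_size = 50, n_permutations = 2000,
                    seed = 1)
  res <- md$results
  expect_equal(res$pvalue[res$compound_id == "a"],
               res$pvalue[res$compound_id == "b"])
  loose <- score_model(prof, gs, universe_size = 50,
                       n_permutations = 2000, seed = 1, q_threshold = 0.5)
  expect_true(all(md$positives %in% loose$positives))
})

test_that("planted compounds are recovered under a strong target bias", {
  # mechanism check at lambda = 40 (see methods vignette: at the
  # default gene-set sizes a 5x bias is far below the detection limit)
  sens <- fp <- numeric(0)
  for (s in 1:5) {
    cfg <- synth_config(seed = s, planted_cir_bias = 40)
    cir <- make_cir_sets(cfg)
    hct <- make_hct(cfg, cir, herbs = "h1")
    prof <- compound_profiles(dedupe_ct(classify_direct(hct$ct_edges)))
    md <- score_model(prof, union_sets(cir), n_permutations = 2000,
                      seed = s)
    sens <- c(sens, mean(hct$planted %in% md$positives))
    fp <- c(fp, sum(!md$positives %in% hct$planted))
  }
  expect_gte(mean(sens), 0.90)
  expect_lte(mean(fp), 5)
})

test_that("analytic fast path agrees with permutation scoring", {
  cfg <- synth_config(seed = 6, n_compounds = 40, planted_cir_bias = 40)
  cir <- make_cir_sets(cfg)
  hct <- make_hct(cfg, cir, herbs = "h1")
  prof <- compound_profiles(dedupe_ct(classify_direct(hct$ct_edges)))
  gs <- union_sets(cir)
  perm <- score_model(prof, gs, n_permutations = 20000, seed = 3)
  ana <- score_model(prof, gs, method = "analytic")
  pr <- perm$results[order(perm$results$compound_id)]
  ar <- ana$results[order(ana$results$compound_id)]
  expect_identical(pr$observed, ar$observed)
  expect_equal(pr$null_mean, ar$null_mean, tolerance = 0.05)
  expect_equal(pr$zscore, ar$zscore, tolerance = 0.15)
  se <- sqrt(ar$pvalue * (1 - ar$pvalue) / 20000)
  expect_true(all(abs(pr$pvalue - ar$pvalue) <= 4 * se + 5e-4))
})

test_that("consensus combines normalized Z across models", {
  cfg <- synth_config(seed = 8, planted_cir_bias = 40)
  cir <- make_cir_sets(cfg)
  hct <- make_hct(cfg, cir, herbs = "h1")
  prof <- compound_profiles(dedupe_ct(classify_direct(hct$ct_edges)))
  five <- cir_model_sets(cir)
  models <- lapply(five$sets, function(gs)
    score_model(prof, gs, method = "analytic"))
  cons <- combine_models(models)
  expect_true(all(cons$all_model_positives %in% cons$union_positives))
  expect_true(all(diff(cons$table$combined_z) <= 1e-12))
  # planted compounds dominate the top decile of the ranking
  top <- head(cons$table$compound_id, ceiling(nrow(cons$table) / 10))
  expect_gte(mean(top %in% hct$planted), 0.9)
  # single model: intersection equals that model's positives
  one <- combine_models(models[3])
  expect_setequal(one$all_model_positives, models[[3]]$positives)
  expect_setequal(one$union_positives, models[[3]]$positives)
  # min-max option bounded in [0, 1] per model
  mm <- combine_models(models, normalization = "minmax")
  expect_true(all(mm$table$combined_z >= -1e-9 &
                    mm$table$combined_z <= 1 + 1e-9))
})
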