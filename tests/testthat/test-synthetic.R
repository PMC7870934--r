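# Synthetic-data generators: determinism, invariants, round-trips.

test_that("generators are byte-identical under a fixed seed", {
  cfg <- synth_config(seed = 123, n_herbs = 40, n_enriched_herbs = 6,
                      n_compounds = 30)
  expect_identical(make_literature_table(cfg), make_literature_table(cfg))
  cir <- make_cir_sets(cfg)
  expect_identical(cir, make_cir_sets(cfg))
  expect_identical(make_hct(cfg, cir), make_hct(cfg, cir))
  expect_identical(make_fingerprints(cfg), make_fingerprints(cfg))
  cfg2 <- synth_config(seed = 124, n_herbs = 40, n_enriched_herbs = 6,
                       n_compounds = 30)
  expect_false(identical(make_literature_table(cfg2)$records,
                         make_literature_table(cfg)$records))
})

test_that("literature counts respect k <= n and the planted multiplier", {
  cfg <- synth_config(seed = 5, n_herbs = 60, n_enriched_herbs = 8)
  lit <- make_literature_table(cfg)
  expect_true(all(lit$records$cooccurrence_papers <=
                    lit$records$herb_papers))
  expect_length(lit$enriched, 8)
  rec <- lit$records
  r <- rec$cooccurrence_papers / rec$herb_papers
  expect_gt(mean(r[rec$herb_id %in% lit$enriched]),
            mean(r[!rec$herb_id %in% lit$enriched]))
})

test_that("immune gene sets hit the requested sizes and overlap", {
  cfg <- synth_config(seed = 9)
  cir <- make_cir_sets(cfg)
  expect_identical(unname(vapply(cir$sets, length, 1L)),
                   unname(as.integer(cfg$cir_sizes)))
  rep <- pairwise_overlap_report(cir)
  expect_true(all(abs(rep$jaccard - cfg$cir_jaccard) <= 0.02))
  # extremes: disjoint and identical
  disj <- make_cir_sets(synth_config(seed = 1, cir_jaccard = 0))
  expect_true(all(pairwise_overlap_report(disj)$overlap == 0))
  same <- make_cir_sets(synth_config(
    seed = 1, cir_jaccard = 1, cir_sizes = c(A = 50, B = 50, C = 50)))
  expect_true(all(pairwise_overlap_report(same)$jaccard == 1))
})

test_that("network tables attach every compound and straddle 10 uM", {
  cfg <- synth_config(seed = 11, n_compounds = 80)
  cir <- make_cir_sets(cfg)
  hct <- make_hct(cfg, cir, herbs = sprintf("h%02d", 1:12))
  expect_setequal(unique(hct$hc_pairs$compound_id),
                  sprintf("cmp%04d", 1:80))
  m <- table(hct$ct_edges$compound_id)
  expect_true(all(m >= cfg$targets_per_compound[1] &
                    m <= cfg$targets_per_compound[2]))
  cls <- classify_direct(hct$ct_edges)
  expect_gt(sum(cls$evidence == "direct"), 0)
  expect_gt(sum(!is.na(cls$affinity_um) & cls$evidence == "indirect"), 0)
  expect_length(hct$planted, round(0.2 * 80))
})

test_that("planted compounds are biased toward immune genes", {
  cfg <- synth_config(seed = 13, n_compounds = 200, planted_cir_bias = 10)
  cir <- make_cir_sets(cfg)
  hct <- make_hct(cfg, cir, herbs = "h1")
  cirg <- union_sets(cir)$genes
  ct <- hct$ct_edges
  planted_rate <- mean(ct$target[ct$compound_id %in% hct$planted] %in% cirg)
  bg_rate <- mean(ct$target[!ct$compound_id %in% hct$planted] %in% cirg)
  expect_gt(planted_rate, 3 * bg_rate)
})

test_that("zero flip probability collapses clusters to prototypes", {
  cfg <- synth_config(seed = 2, fp_prototypes = 3, fp_per_prototype = 5,
                      fp_length = 128, fp_flip_prob = 0)
  fpz <- make_fingerprints(cfg)
  d <- tanimoto_dist_matrix(fpz$fingerprints)
  for (j in 1:3) {
    members <- names(fpz$labels)[fpz$labels == j]
    expect_true(all(d[members, members] == 0))
  }
  expect_identical(sort(unname(unique(fpz$labels))), 1:3)
  expect_length(fpz$labels, nrow(fpz$fingerprints))
})

test_that("the full bundle writes and reads back losslessly", {
  cfg <- synth_config(seed = 21, n_herbs = 30, n_enriched_herbs = 5,
                      n_compounds = 25)
  dir <- file.path(tempdir(), "synthbundle")
  paths <- synth_write_all(cfg, dir)
  expect_true(all(file.exists(unlist(paths))))
  lit <- make_literature_table(cfg)
  expect_equal(as.data.frame(read_literature_table(paths$literature)),
               as.data.frame(lit$records))
  cir <- make_cir_sets(cfg)
  back <- read_gmt(paths$genesets, universe_size = cfg$universe_size)
  for (nm in names(cir$sets))
    expect_setequal(back$sets[[nm]]$genes, cir$sets[[nm]]$genes)
  hct <- make_hct(cfg, cir, herbs = lit$enriched)
  expect_equal(as.data.frame(read_hc_pairs(paths$hc_pairs)),
               as.data.frame(hct$hc_pairs))
  ct_back <- read_ct_table(paths$ct_edges)
  expect_identical(nrow(ct_back), nrow(hct$ct_edges))
  gt <- jsonlite::read_json(paths$ground_truth, simplifyVector = TRUE)
  expect_identical(gt$planted_compounds, hct$planted)
  expect_identical(gt$enriched_herbs, lit$enriched)
})
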