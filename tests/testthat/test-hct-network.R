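# Tripartite network assembly, classification and degree analysis.

toy_ct <- function() data.frame(
  compound_id = c("c1", "c1", "c2", "c2"),
  target = c("t1", "t2", "t1", "t3"),
  affinity_value = c(500, NA, 10, 2),
  affinity_unit = c("nM", NA, "uM", "uM"),
  affinity_kind = c("Ki", NA, "IC50", "Kd"))

test_that("direct/indirect classification applies the strict 10 uM rule", {
  ct <- classify_direct(toy_ct())
  expect_identical(ct$evidence, c("direct", "indirect", "indirect",
                                  "direct"))
  expect_equal(ct$affinity_um, c(0.5, NA, 10, 2))
  expect_error(classify_direct(
    data.frame(compound_id = "c", target = "t", affinity_value = 1,
               affinity_unit = "mM", affinity_kind = "Ki")),
    "unknown affinity unit")
  expect_error(classify_direct(
    data.frame(compound_id = "c", target = "t", affinity_value = 1,
               affinity_unit = "uM", affinity_kind = "Kx")),
    "unknown affinity_kind")
  # micro sign accepted as uM
  mu <- classify_direct(data.frame(compound_id = "c", target = "t",
                                   affinity_value = 9.9,
                                   affinity_unit = "µM",
                                   affinity_kind = "EC50"))
  expect_identical(mu$evidence, "direct")
})

test_that("dedupe keeps direct over indirect, lowest affinity, kind order", {
  e <- classify_direct(data.frame(
    compound_id = "c", target = "t",
    affinity_value = c(NA, 1, 0.2), affinity_unit = c(NA, "uM", "uM"),
    affinity_kind = c(NA, "Ki", "IC50")))
  kept <- dedupe_ct(e)
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$affinity_um, 0.2)   # min affinity beats kind rank
  # kind preference breaks exact affinity ties: Ki > Kd > IC50 > EC50
  tie <- classify_direct(data.frame(
    compound_id = "c", target = "t", affinity_value = c(1, 1),
    affinity_unit = c("uM", "uM"), affinity_kind = c("EC50", "Kd")))
  expect_identical(dedupe_ct(tie)$affinity_kind, "Kd")
  # direct outranks indirect regardless of order; exact dups collapse
  pair <- classify_direct(data.frame(
    compound_id = c("c", "c"), target = c("t", "t"),
    affinity_value = c(NA, 3), affinity_unit = c(NA, "uM"),
    affinity_kind = c(NA, "Ki")))
  expect_identical(dedupe_ct(pair)$evidence, "direct")
  expect_identical(nrow(dedupe_ct(rbind(e, e))), 1L)
})

test_that("dedupe is idempotent and order-independent", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    raw <- data.frame(
      compound_id = sample(sprintf("c%d", 1:6), n, replace = TRUE),
      target = sample(sprintf("t%d", 1:6), n, replace = TRUE),
      affinity_value = ifelse(runif(n) < 0.5, NA, round(runif(n, 1, 20000))),
      affinity_unit = sample(c("nM", "uM"), n, replace = TRUE),
      affinity_kind = sample(c("Ki", "Kd", "IC50", "EC50"), n,
                             replace = TRUE))
    raw$affinity_unit[is.na(raw$affinity_value)] <- NA
    raw$affinity_kind[is.na(raw$affinity_value)] <- NA
    e <- classify_direct(raw)
    d1 <- dedupe_ct(e)
    expect_equal(dedupe_ct(d1), d1)
    d2 <- dedupe_ct(e[sample(nrow(e)), ])
    expect_equal(d1, d2)
  }
})

test_that("assembly restricts to retained herbs and reports rejects", {
  hc <- data.frame(herb_id = c("h1", "h1", "h2"),
                   compound_id = c("c1", "c2", "c9"))
  net <- assemble_hct(hc, toy_ct(), herb_filter = c("h1"))
  expect_identical(net$herbs, "h1")
  expect_setequal(net$compounds, c("c1", "c2"))
  expect_identical(nrow(net$ct_edges), 4L)
  expect_identical(nrow(attr(net, "rejects")), 0L)
  # compound c2 dropped with its herb -> its edges land in rejects
  net2 <- assemble_hct(data.frame(herb_id = c("h1", "h2"),
                                  compound_id = c("c1", "c2")),
                       toy_ct(), herb_filter = "h1")
  expect_setequal(attr(net2, "rejects")$compound_id, "c2")
  expect_identical(nrow(net2$ct_edges), 2L)
  # empty filter -> empty network
  net3 <- assemble_hct(hc, toy_ct(), herb_filter = character(0))
  expect_length(net3$herbs, 0)
  expect_identical(nrow(net3$ct_edges), 0L)
})

test_that("gene-set restriction prunes compounds and herbs transitively", {
  hc <- data.frame(herb_id = c("h1", "h2"), compound_id = c("c1", "c2"))
  net <- assemble_hct(hc, toy_ct())
  all_genes <- gene_set("all", net$targets)
  expect_equal(restrict_to_geneset(net, all_genes)$ct_edges,
               net$ct_edges)
  empty <- restrict_to_geneset(net, gene_set("none", character(0)))
  expect_length(empty$compounds, 0)
  expect_length(empty$herbs, 0)
  only_t3 <- restrict_to_geneset(net, gene_set("t3", "t3"))
  expect_identical(only_t3$compounds, "c2")
  expect_identical(only_t3$herbs, "h2")
})

test_that("degrees count CT edges only, with the handshake identity", {
  # complete bipartite 3 compounds x 2 targets
  cb <- hct_network(
    data.frame(herb_id = "h", compound_id = c("c1", "c2", "c3")),
    classify_direct(expand.grid(compound_id = c("c1", "c2", "c3"),
                                target = c("t1", "t2"))))
  rep <- degree_report(cb)
  expect_true(all(rep$compound_degree == 2))
  expect_true(all(rep$target_degree == 3))
  expect_equal(rep$mean_compound_degree, 2)
  expect_equal(rep$mean_target_degree, 3)
  expect_identical(sum(rep$compound_degree), rep$n_ct_edges)
  expect_identical(sum(rep$target_degree), rep$n_ct_edges)
  single <- hct_network(data.frame(herb_id = "h", compound_id = "c"),
                        classify_direct(data.frame(compound_id = "c",
                                                   target = "t")))
  expect_identical(unname(degree_report(single)$compound_degree), 1L)
  expect_error(degree_report(hct_network(
    data.frame(herb_id = "h", compound_id = "c"), toy_ct()[0, ])),
    "no compound-target edges")
})

test_that("restriction + degree report equals brute-force recomputation", {
  set.seed(33)
  for (rep in 1:30) {
    n <- sample(20:80, 1)
    raw <- data.frame(
      compound_id = sample(sprintf("c%d", 1:8), n, replace = TRUE),
      target = sample(sprintf("t%d", 1:10), n, replace = TRUE))
    hc <- data.frame(herb_id = sample(c("h1", "h2"), 8, replace = TRUE),
                     compound_id = sprintf("c%d", 1:8))
    net <- assemble_hct(hc, raw)
    keep <- sample(sprintf("t%d", 1:10), 5)
    sub <- restrict_to_geneset(net, gene_set("k", keep))
    if (nrow(sub$ct_edges) == 0) next
    dr <- degree_report(sub)
    edges <- unique(raw[raw$target %in% keep, ])
    byhand_D <- table(edges$target)
    expect_equal(dr$target_degree,
                 setNames(as.integer(byhand_D), names(byhand_D)))
    expect_identical(sum(dr$compound_degree), nrow(sub$ct_edges))
  }
})

test_that("high-degree selection is inclusive at the boundary", {
  rep <- structure(list(target_degree = c(a = 10L, b = 9L),
                        compound_degree = c(x = 19L),
                        mean_compound_degree = 19,
                        mean_target_degree = 9.5, n_ct_edges = 19L),
                   class = "degree_report")
  expect_identical(select_high_degree_genes(rep)$genes, "a")
  expect_setequal(select_high_degree_genes(rep, 0)$genes, c("a", "b"))
})

test_that("herb subnetworks and shared targets", {
  hc <- data.frame(herb_id = c("h1", "h1", "h2"),
                   compound_id = c("c1", "c2", "c2"))
  net <- assemble_hct(hc, toy_ct())
  sub <- herb_subnetwork(net, "h1")
  expect_setequal(sub$compounds, c("c1", "c2"))
  expect_identical(nrow(sub$ct_edges), 4L)
  foc <- herb_subnetwork(net, "h1", compounds_filter = "c1")
  expect_identical(foc$compounds, "c1")
  expect_error(herb_subnetwork(net, "nope"), "unknown herb")
  # c1 and c2 share only t1
  expect_identical(shared_targets(net, c("c1", "c2"))$genes, "t1")
  expect_error(shared_targets(net, "c1"), "at least two")
  disj <- assemble_hct(hc, data.frame(compound_id = c("c1", "c2"),
                                      target = c("t1", "t2")))
  expect_length(shared_targets(disj, c("c1", "c2")), 0)
})

test_that("positive proportions use a strict threshold", {
  hc <- data.frame(herb_id = rep("h", 10),
                   compound_id = sprintf("c%02d", 1:10))
  net <- assemble_hct(hc, data.frame(compound_id = sprintf("c%02d", 1:10),
                                     target = "t1"))
  one <- positive_proportion_by_herb(net, "c01")
  expect_equal(one$proportion, 0.10)
  expect_false(one$flagged)   # strictly greater than 10% required
  all_pos <- positive_proportion_by_herb(net, sprintf("c%02d", 1:10))
  expect_equal(all_pos$proportion, 1)
  expect_true(all_pos$flagged)
})

test_that("network exports produce parseable GraphML and edge lists", {
  hc <- data.frame(herb_id = c("h1", "h2"), compound_id = c("c1", "c2"))
  net <- assemble_hct(hc, toy_ct())
  stem <- file.path(tempdir(), "nettest")
  paths <- write_network_exports(net, stem, meta = list(seed = 1))
  g <- igraph::read_graph(paste0(stem, ".graphml"), format = "graphml")
  expect_equal(igraph::vcount(g),
               length(net$herbs) + length(net$compounds) +
                 length(net$targets))
  expect_equal(igraph::ecount(g),
               nrow(net$hc_edges) + nrow(net$ct_edges))
  back <- read_ct_table(paste0(stem, "_ct_edges.tsv"))
  expect_identical(nrow(back), nrow(net$ct_edges))
})
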