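# End-to-end orchestration: screen herbs -> assemble network ->
# restrict to immune genes -> degree analysis -> five gene-set models
# -> consensus -> clustering -> per-herb case studies. Stages
# communicate via files under the run directory so any stage can be
# audited or rerun in isolation.

#' Pipeline run configuration
#'
#' Paths to the five input tables plus every threshold of the screen.
#' Thresholds default to the study design: herb screen q < 0.01 and
#' R > 0.05, direct-affinity cutoff 10 uM, compound q < 0.01,
#' high-degree cutoff D >= 10, positive-ingredient flag > 10%,
#' 100,000 permutations over a 20,462-gene universe.
#'
#' @param literature,genesets,hc_pairs,ct_edges,smiles input paths
#'   (`smiles` may be NA to skip clustering).
#' @param out_dir run directory for artifacts.
#' @param corpus_N,corpus_K corpus constants for the screen.
#' @param q_herb,r_herb herb-screen thresholds.
#' @param affinity_um direct-interaction threshold (uM).
#' @param q_compound model positive-call threshold.
#' @param min_degree high-degree gene cutoff (inclusive).
#' @param proportion positive-ingredient flag threshold (strict).
#' @param n_permutations permutations per model.
#' @param universe_size gene universe.
#' @param seed RNG seed.
#' @param method `"permutation"` or `"analytic"` (exact fast path).
#' @param k_clusters scaffold cluster count.
#' @param blocklist optional path to a one-compound-per-line blocklist
#'   (ions, solvents).
#' @param normalization consensus Z normalisation.
#' @return an object of class `run_config`.
#' @export
run_config <- function(literature, genesets, hc_pairs, ct_edges,
                       smiles = NA, out_dir = "run",
                       corpus_N = 29.0e6, corpus_K = 3874763,
                       q_herb = 0.01, r_herb = 0.05, affinity_um = 10,
                       q_compound = 0.01, min_degree = 10,
                       proportion = 0.10, n_permutations = 100000,
                       universe_size = 20462, seed = 1L,
                       method = c("permutation", "analytic"),
                       k_clusters = 5, blocklist = NA,
                       normalization = c("zstandardize", "minmax")) {
  cfg <- list(literature = literature, genesets = genesets,
              hc_pairs = hc_pairs, ct_edges = ct_edges, smiles = smiles,
              out_dir = out_dir, corpus_N = corpus_N, corpus_K = corpus_K,
              q_herb = q_herb, r_herb = r_herb, affinity_um = affinity_um,
              q_compound = q_compound, min_degree = min_degree,
              proportion = proportion, n_permutations = n_permutations,
              universe_size = universe_size, seed = as.integer(seed),
              method = match.arg(method), k_clusters = k_clusters,
              blocklist = blocklist,
              normalization = match.arg(normalization))
  thr <- c(cfg$q_herb, cfg$r_herb, cfg$affinity_um, cfg$q_compound,
           cfg$min_degree, cfg$proportion)
  if (any(thr <= 0)) stop("thresholds must be positive")
  structure(cfg, class = "run_config")
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full screening pipeline
#'
#' Executes the stages in study order: (A) literature screen of herbs,
#' (B) network assembly restricted to the significant herbs, (C) gene
#' set integration, immune-restricted network and degree analysis,
#' (D) the five gene-set models and their consensus, (E) scaffold
#' clustering of the union positives (when SMILES and a Python RDKit
#' are available) and per-herb positive proportions. Every output TSV
#' carries `# config=<md5> seed=<seed>` header lines and a
#' `manifest.json` records the counts at every stage.
#'
#' @param config a [run_config].
#' @return invisibly, the manifest list (also written to
#'   `out_dir/manifest.json`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$literature, config$genesets, config$hc_pairs,
              config$ct_edges))
    if (!file.exists(p)) stop("input does not exist: ", p)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(config = .config_hash(config), seed = config$seed)
  manifest <- list(config_hash = meta$config, seed = config$seed)

  # A: literature screen
  lit <- read_literature_table(config$literature)
  corpus <- corpus_stats(config$corpus_N, config$corpus_K)
  screen <- screen_herbs(lit, corpus, q_threshold = config$q_herb,
                         r_threshold = config$r_herb)
  write_screen_results(screen, file.path(config$out_dir, "herb_screen.tsv"),
                       meta)
  sig_herbs <- screen$herb_id[screen$significant]
  manifest$screen <- list(n_herbs = nrow(screen),
                          n_significant = length(sig_herbs))
  .stage_log("screen", "%d of %d herbs significant (q < %g, R > %g)",
             length(sig_herbs), nrow(screen), config$q_herb, config$r_herb)
  if (length(sig_herbs) == 0) stop("stage screen: no significant herbs")

  # B: assemble the full network over significant herbs
  hc <- read_hc_pairs(config$hc_pairs)
  ct <- read_ct_table(config$ct_edges)
  net <- assemble_hct(hc, ct, herb_filter = sig_herbs,
                      threshold_um = config$affinity_um)
  write_network_exports(net, file.path(config$out_dir, "network_full"),
                        meta)
  manifest$network <- list(
    herbs = length(net$herbs), compounds = length(net$compounds),
    targets = length(net$targets), hc_edges = nrow(net$hc_edges),
    ct_edges = nrow(net$ct_edges),
    direct = sum(net$ct_edges$evidence == "direct"),
    indirect = sum(net$ct_edges$evidence == "indirect"),
    rejected_ct = nrow(attr(net, "rejects")))
  .stage_log("network", "%d herbs / %d compounds / %d targets, %d CTIs (%d direct)",
             length(net$herbs), length(net$compounds), length(net$targets),
             nrow(net$ct_edges), manifest$network$direct)

  # C: gene sets, immune-restricted network, degree analysis
  base_sets <- read_gmt(config$genesets,
                        universe_size = config$universe_size)
  models_sets <- cir_model_sets(base_sets)
  write_gmt(models_sets, file.path(config$out_dir, "genesets_model.gmt"))
  overlaps <- pairwise_overlap_report(base_sets)
  .write_tsv(overlaps, file.path(config$out_dir, "geneset_overlaps.tsv"),
             meta)
  ig2 <- models_sets$sets[["IG-2"]]
  cir_net <- restrict_to_geneset(net, ig2)
  write_network_exports(cir_net, file.path(config$out_dir, "network_cir"),
                        meta)
  deg <- degree_report(cir_net)
  .write_tsv(data.table::data.table(target = names(deg$target_degree),
                                    degree = deg$target_degree),
             file.path(config$out_dir, "target_degrees.tsv"), meta)
  high <- select_high_degree_genes(deg, config$min_degree)
  write_gmt(high, file.path(config$out_dir, "high_degree_genes.gmt"))
  manifest$genesets <- stats::setNames(
    lapply(models_sets$sets, length), names(models_sets$sets))
  manifest$cir_network <- list(
    herbs = length(cir_net$herbs), compounds = length(cir_net$compounds),
    targets = length(cir_net$targets), hc_edges = nrow(cir_net$hc_edges),
    ct_edges = nrow(cir_net$ct_edges),
    nodes = length(cir_net$herbs) + length(cir_net$compounds) +
      length(cir_net$targets),
    edges = nrow(cir_net$hc_edges) + nrow(cir_net$ct_edges),
    mean_compound_degree = deg$mean_compound_degree,
    mean_target_degree = deg$mean_target_degree,
    n_high_degree = length(high))
  .stage_log("cir", "restricted network: %d nodes / %d edges; %d genes with D >= %d",
             manifest$cir_network$nodes, manifest$cir_network$edges,
             length(high), config$min_degree)

  # D: five gene-set models + consensus
  blocklist <- if (!is.na(config$blocklist) && nzchar(config$blocklist))
    readLines(config$blocklist, warn = FALSE) else character(0)
  profiles <- compound_profiles(net)
  models <- lapply(models_sets$sets, function(gs)
    score_model(profiles, gs, universe_size = config$universe_size,
                n_permutations = config$n_permutations,
                seed = config$seed, q_threshold = config$q_compound,
                method = config$method, blocklist = blocklist))
  for (mdl in models)
    .write_tsv(mdl$results,
               file.path(config$out_dir,
                         sprintf("model_%s.tsv",
                                 gsub("[^A-Za-z0-9]+", "_",
                                      mdl$geneset_name))), meta)
  consensus <- combine_models(models, normalization = config$normalization)
  .write_tsv(consensus$table,
             file.path(config$out_dir, "consensus.tsv"), meta)
  manifest$models <- lapply(models, function(mdl)
    list(scored = nrow(mdl$results), positives = length(mdl$positives)))
  manifest$consensus <- list(
    union_positives = length(consensus$union_positives),
    all_model_positives = length(consensus$all_model_positives),
    normalization = config$normalization)
  .stage_log("models", "positives per model: %s; union %d, all-model %d",
             paste(vapply(models, function(m) length(m$positives), 1L),
                   collapse = "/"),
             length(consensus$union_positives),
             length(consensus$all_model_positives))

  # E: positive-ingredient proportions and scaffold clustering
  prop_cir <- positive_proportion_by_herb(cir_net,
                                          consensus$union_positives,
                                          threshold = config$proportion)
  prop_full <- positive_proportion_by_herb(net,
                                           consensus$union_positives,
                                           threshold = config$proportion)
  .write_tsv(prop_cir, file.path(config$out_dir,
                                 "positive_proportions_cir.tsv"), meta)
  .write_tsv(prop_full, file.path(config$out_dir,
                                  "positive_proportions_full.tsv"), meta)
  manifest$positive_proportions <- list(
    flagged_cir = sum(prop_cir$flagged),
    flagged_full = sum(prop_full$flagged))
  manifest$clustering <- .run_cluster_stage(config, consensus, meta)

  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.run_cluster_stage <- function(config, consensus, meta) {
  pos <- consensus$union_positives
  if (is.na(config$smiles) || !nzchar(config$smiles))
    return(list(skipped = "no SMILES input"))
  if (length(pos) < config$k_clusters)
    return(list(skipped = sprintf("only %d positives for k = %d",
                                  length(pos), config$k_clusters)))
  if (!nzchar(Sys.which("python")))
    return(list(skipped = "no python/RDKit available"))
  smi <- read_smiles_table(config$smiles)
  smi <- smi[smi$compound_id %in% pos]
  if (nrow(smi) < config$k_clusters)
    return(list(skipped = "too few positives with structures"))
  fps <- fingerprints_from_smiles(smi$smiles, ids = smi$compound_id)
  cl <- cluster_fingerprints(fps, k = config$k_clusters,
                             seed = config$seed)
  .write_tsv(data.table::data.table(compound_id = names(cl$cluster),
                                    cluster = as.integer(cl$cluster),
                                    medoid = cl$medoids[cl$cluster]),
             file.path(config$out_dir, "clusters.tsv"), meta)
  .stage_log("cluster", "k = %d over %d positives, objective %.3f",
             cl$k, length(cl$cluster), cl$objective)
  list(k = cl$k, n = length(cl$cluster), medoids = cl$medoids,
       objective = cl$objective)
}

#' Per-herb case-study exports
#'
#' Extracts one herb's compound-target subnetwork (optionally focused
#' on a few named compounds), writes its edge lists plus the
#' shared-target report across the focus compounds.
#'
#' @param network an `hct_network` (typically the immune-restricted
#'   network of a run).
#' @param herb_id the herb to profile.
#' @param focus_compounds optional compound subset for the focused
#'   subnetwork and shared-target report.
#' @param out_dir output directory.
#' @return invisibly, a list with the two subnetworks and the shared
#'   target set (NULL when no focus given).
#' @export
case_study <- function(network, herb_id, focus_compounds = NULL,
                       out_dir = "case_study") {
  sub_all <- herb_subnetwork(network, herb_id)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_network_exports(sub_all,
                        file.path(out_dir, paste0(herb_id, "_all")))
  sub_focus <- NULL
  shared <- NULL
  if (!is.null(focus_compounds)) {
    sub_focus <- herb_subnetwork(network, herb_id, focus_compounds)
    write_network_exports(sub_focus,
                          file.path(out_dir, paste0(herb_id, "_focus")))
    if (length(intersect(focus_compounds, sub_focus$compounds)) >= 2) {
      shared <- shared_targets(sub_focus,
                               intersect(focus_compounds,
                                         sub_focus$compounds))
      write_gmt(shared, file.path(out_dir,
                                  paste0(herb_id, "_shared_targets.gmt")))
    }
  }
  invisible(list(subnetwork = sub_all, focus = sub_focus,
                 shared_targets = shared))
}
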