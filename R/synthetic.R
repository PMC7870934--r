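# Seeded generators emulating every input table of the screening
# pipeline, with planted ground truth, so all stages are testable
# without any external database.

#' Configuration for the synthetic-data generators
#'
#' Defaults state the emulated world: a 525-herb pharmacopoeia screened
#' against a 29-million-paper corpus with 3.87 million disease papers,
#' 66 planted disease-associated herbs with a 10x co-occurrence
#' enrichment, a 20,462-gene protein-coding universe carrying three
#' curated immune gene sets of sizes 138/78/226 with pairwise Jaccard
#' ~0.1, and a compound library (default 100 compounds at desk scale)
#' in which a planted fraction of compounds draws targets with a
#' lambda-fold preference for immune genes. Co-occurrence counts use a
#' binomial approximation to the corpus hypergeometric (exact at
#' N ~ 1e7 scale).
#'
#' @param seed integer master seed; all generators derive from it.
#' @param n_herbs herbs in the literature table.
#' @param n_enriched_herbs planted disease-associated herbs.
#' @param corpus_N,corpus_K corpus totals (papers, disease papers).
#' @param herb_paper_range inclusive range for per-herb paper counts.
#' @param enrichment_multiplier fold-increase of the co-occurrence rate
#'   for planted herbs.
#' @param universe_size protein-coding gene universe.
#' @param cir_sizes sizes of the three base immune gene sets.
#' @param cir_jaccard requested pairwise Jaccard between base sets.
#' @param n_compounds compounds in the network.
#' @param targets_per_compound inclusive range of targets per compound.
#' @param planted_positive_fraction fraction of compounds planted as
#'   immuno-active.
#' @param planted_cir_bias lambda >= 1: sampling weight of immune genes
#'   for planted compounds (1 = null).
#' @param compounds_per_herb inclusive range of constituents per herb.
#' @param affinity_fraction fraction of CT edges carrying a measured
#'   binding affinity (log-normal around the 10 uM threshold, so the
#'   direct/indirect classifier is exercised on both sides).
#' @param fp_prototypes,fp_per_prototype,fp_length,fp_flip_prob,fp_density
#'   fingerprint generator: number of prototype scaffolds, copies per
#'   prototype, folded length, per-bit flip probability, prototype
#'   on-bit density.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_herbs = 525, n_enriched_herbs = 66,
                         corpus_N = 29.0e6, corpus_K = 3874763,
                         herb_paper_range = c(200, 3000),
                         enrichment_multiplier = 10,
                         universe_size = 20462,
                         cir_sizes = c(IO = 138, IM = 78, IN = 226),
                         cir_jaccard = 0.10,
                         n_compounds = 100,
                         targets_per_compound = c(8, 25),
                         planted_positive_fraction = 0.20,
                         planted_cir_bias = 5,
                         compounds_per_herb = c(10, 25),
                         affinity_fraction = 0.30,
                         fp_prototypes = 5, fp_per_prototype = 10,
                         fp_length = 2048, fp_flip_prob = 0.02,
                         fp_density = 0.10) {
  cfg <- list(seed = as.integer(seed), n_herbs = n_herbs,
              n_enriched_herbs = n_enriched_herbs, corpus_N = corpus_N,
              corpus_K = corpus_K, herb_paper_range = herb_paper_range,
              enrichment_multiplier = enrichment_multiplier,
              universe_size = universe_size, cir_sizes = cir_sizes,
              cir_jaccard = cir_jaccard, n_compounds = n_compounds,
              targets_per_compound = targets_per_compound,
              planted_positive_fraction = planted_positive_fraction,
              planted_cir_bias = planted_cir_bias,
              compounds_per_herb = compounds_per_herb,
              affinity_fraction = affinity_fraction,
              fp_prototypes = fp_prototypes,
              fp_per_prototype = fp_per_prototype,
              fp_length = fp_length, fp_flip_prob = fp_flip_prob,
              fp_density = fp_density)
  with(cfg, {
    stopifnot(n_herbs > 0, n_enriched_herbs >= 0,
              n_enriched_herbs <= n_herbs,
              corpus_K > 0, corpus_K <= corpus_N,
              all(cir_sizes <= universe_size),
              cir_jaccard >= 0, cir_jaccard <= 1,
              planted_positive_fraction >= 0,
              planted_positive_fraction <= 1,
              planted_cir_bias >= 1, affinity_fraction >= 0,
              affinity_fraction <= 1, fp_prototypes >= 1)
  })
  structure(cfg, class = "synth_config")
}

#' Synthetic per-herb literature counts with planted associations
#'
#' Background herbs draw their disease co-occurrence count k from
#' Binomial(n, K/N); planted herbs from
#' Binomial(n, min(1, multiplier * K/N)). Ground truth is returned
#' alongside the table.
#'
#' @param config a [synth_config].
#' @return list with `records` (herb_id, herb_papers,
#'   cooccurrence_papers), `enriched` (planted herb IDs), `corpus`.
#' @export
make_literature_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  ids <- sprintf("herb%03d", seq_len(config$n_herbs))
  n <- sample(config$herb_paper_range[1]:config$herb_paper_range[2],
              config$n_herbs, replace = TRUE)
  enriched <- sort(sample(ids, config$n_enriched_herbs))
  base_rate <- config$corpus_K / config$corpus_N
  rate <- ifelse(ids %in% enriched,
                 min(1, config$enrichment_multiplier * base_rate),
                 base_rate)
  k <- stats::rbinom(config$n_herbs, n, rate)
  list(records = data.table::data.table(
         herb_id = ids, herb_papers = n, cooccurrence_papers = k),
       enriched = enriched,
       corpus = corpus_stats(config$corpus_N, config$corpus_K))
}

#' Three synthetic immune gene sets with controlled pairwise overlap
#'
#' Builds sets of the configured sizes over the universe `1..U`
#' (IDs as Entrez-style integer strings) with pairwise Jaccard within
#' +-0.02 of `cir_jaccard`. Overlap is realised as pairwise-shared
#' blocks; when the request is so high that pairwise blocks alone are
#' infeasible (e.g. Jaccard 1), the excess is moved into a block shared
#' by all three sets. Errors if the requested overlap cannot be
#' realised.
#'
#' @param config a [synth_config].
#' @return a [gene_set_collection] with the three base sets.
#' @export
make_cir_sets <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  s <- as.integer(config$cir_sizes)
  nm <- names(config$cir_sizes)
  if (is.null(nm)) nm <- c("IO", "IM", "IN")
  j <- config$cir_jaccard
  ov <- function(a, b) as.integer(round(j * (a + b) / (1 + j)))
  o12 <- ov(s[1], s[2]); o13 <- ov(s[1], s[3]); o23 <- ov(s[2], s[3])
  # core shared by all three sets absorbs whatever pairwise blocks
  # cannot accommodate
  core <- max(0L, o12 + o13 - s[1], o12 + o23 - s[2], o13 + o23 - s[3])
  core <- min(core, o12, o13, o23)
  e12 <- o12 - core; e13 <- o13 - core; e23 <- o23 - core
  uniq <- c(s[1] - e12 - e13 - core, s[2] - e12 - e23 - core,
            s[3] - e13 - e23 - core)
  if (any(uniq < 0)) stop("requested cir_jaccard is infeasible")
  need <- core + e12 + e13 + e23 + sum(uniq)
  if (need > config$universe_size)
    stop("sets exceed the universe")
  pool <- sample.int(config$universe_size, need)
  take <- function(n) {
    if (n == 0) return(integer(0))
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  g_core <- take(core); g12 <- take(e12); g13 <- take(e13)
  g23 <- take(e23)
  gA <- c(g_core, g12, g13, take(uniq[1]))
  gB <- c(g_core, g12, g23, take(uniq[2]))
  gC <- c(g_core, g13, g23, take(uniq[3]))
  coll <- gene_set_collection(
    list(gene_set(nm[1], gA), gene_set(nm[2], gB), gene_set(nm[3], gC)),
    universe_size = config$universe_size)
  achieved <- pairwise_overlap_report(coll)$jaccard
  if (any(abs(achieved - j) > 0.02))
    stop("achieved Jaccard deviates more than 0.02 from request (",
         paste(round(achieved, 3), collapse = ", "), ")")
  coll
}

#' Synthetic herb-compound-target tables with planted positives
#'
#' Every compound is attached to at least one herb; planted positives
#' draw their targets from the universe with weight `planted_cir_bias`
#' on the union of the immune gene sets (weight 1 elsewhere,
#' sequential weighted sampling without replacement), background
#' compounds draw uniformly. A configured fraction of CT edges carries
#' a binding affinity log-normally distributed around the 10 uM
#' threshold, in mixed units and assay kinds.
#'
#' @param config a [synth_config].
#' @param cir a [gene_set_collection] from [make_cir_sets()].
#' @param herbs herb IDs owning the compounds; defaults to the planted
#'   disease-associated herbs of [make_literature_table()] under the
#'   same config, so the screen and the network agree end to end.
#' @return list with `hc_pairs`, `ct_edges` (raw, unclassified),
#'   `planted` (compound IDs), `herbs`.
#' @export
make_hct <- function(config, cir, herbs = NULL) {
  stopifnot(inherits(config, "synth_config"),
            inherits(cir, "gene_set_collection"))
  if (is.null(herbs)) herbs <- make_literature_table(config)$enriched
  set.seed(config$seed + 2L)
  n_c <- config$n_compounds
  compounds <- sprintf("cmp%04d", seq_len(n_c))
  # herb membership: each herb draws a constituent list, then leftover
  # compounds are attached to random herbs so none is orphaned
  rng <- config$compounds_per_herb
  hc <- data.table::rbindlist(lapply(herbs, function(h) {
    sz <- min(n_c, sample(rng[1]:rng[2], 1))
    data.table::data.table(herb_id = h,
                           compound_id = sample(compounds, sz))
  }))
  missing <- setdiff(compounds, hc$compound_id)
  if (length(missing))
    hc <- rbind(hc, data.table::data.table(
      herb_id = sample(herbs, length(missing), replace = TRUE),
      compound_id = missing))
  hc <- unique(hc)

  planted <- sort(sample(compounds,
                         round(config$planted_positive_fraction * n_c)))
  cir_union <- union_sets(cir)$genes
  w <- rep(1, config$universe_size)
  w[as.integer(cir_union)] <- config$planted_cir_bias
  trng <- config$targets_per_compound
  ct <- data.table::rbindlist(lapply(compounds, function(cm) {
    m <- sample(trng[1]:trng[2], 1)
    tg <- if (cm %in% planted)
      sample.int(config$universe_size, m, prob = w)
    else sample.int(config$universe_size, m)
    data.table::data.table(compound_id = cm, target = as.character(tg))
  }))
  # affinities straddling the direct threshold on a subset of edges
  n_e <- nrow(ct)
  has_aff <- stats::runif(n_e) < config$affinity_fraction
  val_um <- exp(stats::rnorm(n_e, mean = log(8), sd = 1.5))
  unit <- sample(c("nM", "uM"), n_e, replace = TRUE)
  ct[, affinity_value := ifelse(has_aff,
                                ifelse(unit == "nM", val_um * 1000, val_um),
                                NA_real_)]
  ct[, affinity_unit := ifelse(has_aff, unit, NA_character_)]
  ct[, affinity_kind := ifelse(has_aff,
                               sample(c("Ki", "Kd", "IC50", "EC50"), n_e,
                                      replace = TRUE), NA_character_)]
  list(hc_pairs = hc, ct_edges = ct, planted = planted, herbs = herbs)
}

#' Synthetic fingerprints with planted cluster structure
#'
#' Prototype bit patterns (Bernoulli on-bits at `fp_density`) copied
#' with independent per-bit flips at `fp_flip_prob`; ground-truth
#' labels returned.
#'
#' @param config a [synth_config].
#' @return list with `fingerprints` (logical matrix) and `labels`
#'   (integer prototype assignment, named by compound).
#' @export
make_fingerprints <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 3L)
  L <- config$fp_length
  protos <- matrix(stats::runif(config$fp_prototypes * L) <
                     config$fp_density,
                   nrow = config$fp_prototypes)
  n <- config$fp_prototypes * config$fp_per_prototype
  labels <- rep(seq_len(config$fp_prototypes),
                each = config$fp_per_prototype)
  flips <- matrix(stats::runif(n * L) < config$fp_flip_prob, nrow = n)
  fp <- protos[labels, , drop = FALSE] != flips   # XOR
  rownames(fp) <- sprintf("cmp%04d", seq_len(n))
  list(fingerprints = fp, labels = stats::setNames(labels, rownames(fp)))
}

#' Assign vocabulary SMILES to synthetic compounds
#'
#' Synthetic compounds get structures from a small packaged vocabulary
#' of natural-product SMILES (cyclically); chemistry is illustrative,
#' not curated.
#'
#' @param compound_ids character vector of compound IDs.
#' @return data.table with columns `compound_id`, `smiles`,
#'   `vocabulary_name`.
#' @export
make_smiles_table <- function(compound_ids) {
  vocab <- .read_tsv(system.file("extdata", "smiles_vocabulary.tsv",
                                 package = "tcmimmuno"))
  i <- ((seq_along(compound_ids) - 1L) %% nrow(vocab)) + 1L
  data.table::data.table(compound_id = as.character(compound_ids),
                         smiles = vocab$smiles[i],
                         vocabulary_name = vocab$compound_name[i])
}

#' Write a full synthetic input bundle to a directory
#'
#' Emits every table the pipeline reads — literature counts, the three
#' base gene sets (GMT), herb-compound pairs, compound-target
#' interactions, SMILES — plus a `ground_truth.json` sidecar with the
#' planted herb and compound sets.
#'
#' @param config a [synth_config].
#' @param dir output directory (created).
#' @return invisibly, a named list of the paths written.
#' @export
synth_write_all <- function(config, dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lit <- make_literature_table(config)
  cir <- make_cir_sets(config)
  hct <- make_hct(config, cir, herbs = lit$enriched)
  smi <- make_smiles_table(sort(unique(hct$hc_pairs$compound_id)))
  meta <- list(seed = config$seed, generator = "tcmimmuno::synth_write_all")
  paths <- list(
    literature = file.path(dir, "literature_counts.tsv"),
    genesets = file.path(dir, "cir_genesets.gmt"),
    hc_pairs = file.path(dir, "herb_compound.tsv"),
    ct_edges = file.path(dir, "compound_target.tsv"),
    smiles = file.path(dir, "compound_smiles.tsv"),
    ground_truth = file.path(dir, "ground_truth.json"))
  .write_tsv(lit$records, paths$literature, meta)
  write_gmt(cir, paths$genesets)
  .write_tsv(hct$hc_pairs, paths$hc_pairs, meta)
  .write_tsv(hct$ct_edges, paths$ct_edges, meta)
  .write_tsv(smi, paths$smiles, meta)
  jsonlite::write_json(
    list(seed = config$seed,
         enriched_herbs = lit$enriched,
         planted_compounds = hct$planted,
         corpus = list(total_papers = config$corpus_N,
                       disease_papers = config$corpus_K),
         universe_size = config$universe_size),
    paths$ground_truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
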