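#' Classify compound-target interactions as direct or indirect
#'
#' An interaction is *direct* when it carries a binding-affinity
#' measurement (Ki, Kd, IC50 or EC50) strictly below 10 uM after unit
#' conversion; everything else — including functional or
#' literature-derived evidence without an affinity — is *indirect*.
#'
#' @param interactions data.frame with columns `compound_id`, `target`
#'   and optional `affinity_value`, `affinity_unit` ("nM" or "uM";
#'   micro sign accepted), `affinity_kind` (Ki/Kd/IC50/EC50).
#' @param threshold_um direct threshold in micromolar (default 10,
#'   strict `<`).
#' @return data.table with an `evidence` column ("direct"/"indirect")
#'   and a normalised `affinity_um` column (NA when no affinity).
#' @export
classify_direct <- function(interactions, threshold_um = 10) {
  stopifnot(is.data.frame(interactions),
            all(c("compound_id", "target") %in% names(interactions)))
  dt <- data.table::copy(data.table::as.data.table(interactions))
  for (col in c("affinity_value", "affinity_unit", "affinity_kind"))
    if (!col %in% names(dt)) data.table::set(dt, j = col, value = NA)
  dt[, affinity_value := as.numeric(affinity_value)]
  dt[, affinity_unit := as.character(affinity_unit)]
  dt[, affinity_kind := as.character(affinity_kind)]
  has_aff <- !is.na(dt$affinity_value)
  if (any(has_aff & dt$affinity_value <= 0))
    stop("affinity_value must be positive")
  kinds <- toupper(dt$affinity_kind[has_aff])
  bad_kind <- !is.na(kinds) & !kinds %in% c("KI", "KD", "IC50", "EC50")
  if (any(bad_kind))
    stop("unknown affinity_kind: ",
         paste(unique(dt$affinity_kind[has_aff][bad_kind]), collapse = ", "))
  fac <- .unit_to_um(dt$affinity_unit[has_aff])
  dt[, affinity_um := NA_real_]
  if (any(has_aff))
    data.table::set(dt, i = which(has_aff), j = "affinity_um",
                    value = dt$affinity_value[has_aff] * fac)
  dt[, evidence := ifelse(!is.na(affinity_um) & affinity_um < threshold_um,
                          "direct", "indirect")]
  dt[]
}

.unit_to_um <- function(unit) {
  u <- tolower(trimws(unit))
  u <- gsub("µ|μ", "u", u)   # micro sign / mu -> "u"
  fac <- c(nm = 1e-3, um = 1)[u]
  if (anyNA(fac))
    stop("unknown affinity unit: ",
         paste(unique(unit[is.na(fac)]), collapse = ", "),
         " (expected nM or uM)")
  unname(fac)
}

#' Deduplicate compound-target edges
#'
#' Collapses the edge list to one row per (compound, target). Direct
#' evidence outranks indirect; among several direct rows the lowest
#' micromolar affinity wins, ties broken by assay-kind preference
#' Ki > Kd > IC50 > EC50, then original row order. Idempotent and
#' independent of input order.
#'
#' @param edges data.table as produced by [classify_direct()].
#' @return deduplicated data.table.
#' @export
dedupe_ct <- function(edges) {
  dt <- data.table::copy(data.table::as.data.table(edges))
  if (nrow(dt) == 0) return(dt)
  stopifnot(all(c("compound_id", "target", "evidence") %in% names(dt)))
  if (!"affinity_um" %in% names(dt)) dt[, affinity_um := NA_real_]
  kind_rank <- c(KI = 1L, KD = 2L, IC50 = 3L, EC50 = 4L)
  dt[, .direct_first := evidence != "direct"]
  dt[, .kind_rank := kind_rank[toupper(as.character(affinity_kind))]]
  dt[is.na(.kind_rank), .kind_rank := 5L]
  data.table::setorder(dt, compound_id, target, .direct_first,
                       affinity_um, .kind_rank, na.last = TRUE)
  dt <- unique(dt, by = c("compound_id", "target"))
  dt[, c(".direct_first", ".kind_rank") := NULL]
  dt[]
}

#' Tripartite herb-compound-target network
#'
#' Container validated for bipartite structure: herb-compound
#' membership edges and deduplicated compound-target interaction edges,
#' with node sets derived from the edges.
#'
#' @param hc_edges data.frame of unique (`herb_id`, `compound_id`) pairs.
#' @param ct_edges data.frame of compound-target interactions (one row
#'   per pair; see [dedupe_ct()]).
#' @return an object of class `hct_network`.
#' @export
hct_network <- function(hc_edges, ct_edges) {
  hc <- unique(data.table::as.data.table(hc_edges)[
    , .(herb_id = as.character(herb_id),
        compound_id = as.character(compound_id))])
  ct <- data.table::as.data.table(ct_edges)
  if (nrow(ct) > 0) {
    ct[, compound_id := as.character(compound_id)]
    ct[, target := as.character(target)]
    if (anyDuplicated(ct, by = c("compound_id", "target")))
      stop("duplicate compound-target pair; run dedupe_ct() first")
  }
  structure(list(
    herbs = sort(unique(hc$herb_id)),
    compounds = sort(unique(c(hc$compound_id,
                              if (nrow(ct)) ct$compound_id))),
    targets = sort(unique(if (nrow(ct)) ct$target else character(0))),
    hc_edges = hc, ct_edges = ct), class = "hct_network")
}

#' @export
print.hct_network <- function(x, ...) {
  nd <- if (nrow(x$ct_edges)) sum(x$ct_edges$evidence == "direct") else 0L
  cat(sprintf(
    "herb-compound-target network: %d herbs, %d compounds, %d targets\n",
    length(x$herbs), length(x$compounds), length(x$targets)))
  cat(sprintf("  %d herb-compound pairs, %d CT interactions (%d direct, %d indirect)\n",
              nrow(x$hc_edges), nrow(x$ct_edges), nd, nrow(x$ct_edges) - nd))
  invisible(x)
}

#' Assemble a herb-compound-target network
#'
#' Restricts to herbs in `herb_filter` (all herbs when `NULL`), keeps
#' compounds linked to at least one retained herb, classifies and
#' deduplicates compound-target edges, and prunes orphan targets.
#' CT edges whose compound is not attached to any retained herb are
#' not fatal: they are returned in the `rejects` attribute.
#'
#' @param hc_pairs data.frame of (`herb_id`, `compound_id`) pairs.
#' @param ct_edges data.frame of compound-target interactions (raw;
#'   classified and deduplicated internally).
#' @param herb_filter optional character vector of herbs to retain.
#' @param threshold_um direct-affinity threshold in uM.
#' @return an `hct_network`; dropped CT rows in `attr(, "rejects")`.
#' @export
assemble_hct <- function(hc_pairs, ct_edges, herb_filter = NULL,
                         threshold_um = 10) {
  hc <- unique(data.table::as.data.table(hc_pairs)[
    , .(herb_id = as.character(herb_id),
        compound_id = as.character(compound_id))])
  if (!is.null(herb_filter)) hc <- hc[herb_id %in% as.character(herb_filter)]
  ct <- dedupe_ct(classify_direct(ct_edges, threshold_um = threshold_um))
  keep <- ct$compound_id %in% hc$compound_id
  net <- hct_network(hc, ct[keep])
  attr(net, "rejects") <- ct[!keep]
  net
}

#' Restrict a network's interactions to a gene set
#'
#' Keeps compound-target edges whose target lies in `genes`, then
#' prunes compounds left without targets and herbs left without
#' compounds.
#'
#' @param network an `hct_network`.
#' @param genes a [gene_set] or character vector of gene IDs.
#' @return a pruned `hct_network`.
#' @export
restrict_to_geneset <- function(network, genes) {
  stopifnot(inherits(network, "hct_network"))
  g <- .genes_of(genes)
  ct <- network$ct_edges[target %in% g]
  hc <- network$hc_edges[compound_id %in% unique(ct$compound_id)]
  hct_network(hc, ct)
}

#' Degree report over compound-target edges
#'
#' Compound degree K and target degree D are counted over
#' compound-target edges only; herb membership edges do not contribute.
#'
#' @param network an `hct_network` with at least one CT edge.
#' @return an object of class `degree_report` with per-node degrees and
#'   their means.
#' @export
degree_report <- function(network) {
  stopifnot(inherits(network, "hct_network"))
  ct <- network$ct_edges
  if (nrow(ct) == 0) stop("network has no compound-target edges")
  K <- table(ct$compound_id)
  D <- table(ct$target)
  structure(list(
    compound_degree = stats::setNames(as.integer(K), names(K)),
    target_degree = stats::setNames(as.integer(D), names(D)),
    mean_compound_degree = mean(as.integer(K)),
    mean_target_degree = mean(as.integer(D)),
    n_ct_edges = nrow(ct)), class = "degree_report")
}

#' @export
print.degree_report <- function(x, ...) {
  cat(sprintf("degrees over %d CT edges: mean K = %.1f (%d compounds), mean D = %.1f (%d targets)\n",
              x$n_ct_edges, x$mean_compound_degree,
              length(x$compound_degree), x$mean_target_degree,
              length(x$target_degree)))
  top <- sort(x$target_degree, decreasing = TRUE)
  top <- utils::head(top, 3)
  cat("  top targets:",
      paste(sprintf("%s (D = %d)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Select highly connected target genes
#'
#' @param report a [degree_report].
#' @param min_degree inclusive degree threshold (default 10).
#' @param name name of the resulting set.
#' @return a [gene_set] of targets with `D >= min_degree`.
#' @export
select_high_degree_genes <- function(report, min_degree = 10,
                                     name = "high-degree") {
  stopifnot(inherits(report, "degree_report"))
  D <- report$target_degree
  gene_set(name, names(D)[D >= min_degree])
}

#' Extract one herb's compound-target subnetwork
#'
#' @param network an `hct_network`.
#' @param herb_id the herb.
#' @param compounds_filter optional compound set to intersect with the
#'   herb's constituents.
#' @return an `hct_network` restricted to the herb.
#' @export
herb_subnetwork <- function(network, herb_id, compounds_filter = NULL) {
  stopifnot(inherits(network, "hct_network"))
  hid <- as.character(herb_id)
  if (!hid %in% network$herbs) stop("unknown herb: ", hid)
  hc <- network$hc_edges[network$hc_edges$herb_id == hid]
  cmp <- hc$compound_id
  if (!is.null(compounds_filter))
    cmp <- intersect(cmp, as.character(compounds_filter))
  hct_network(hc[compound_id %in% cmp],
              network$ct_edges[compound_id %in% cmp])
}

#' Targets shared by every listed compound
#'
#' @param network an `hct_network`.
#' @param compounds character vector of at least two compound IDs.
#' @param name name of the resulting set.
#' @return a [gene_set] of targets adjacent to all the compounds.
#' @export
shared_targets <- function(network, compounds, name = "shared") {
  stopifnot(inherits(network, "hct_network"))
  compounds <- unique(as.character(compounds))
  if (length(compounds) < 2) stop("need at least two compounds")
  per <- lapply(compounds, function(cm)
    unique(network$ct_edges[compound_id == cm]$target))
  gene_set(name, Reduce(intersect, per))
}

#' Per-herb proportion of positive ingredients
#'
#' For every herb in the network, the fraction of its compounds (in
#' this network's roster — pass a CIR-restricted network for the
#' restricted denominator) that are in `positives`. Herbs are flagged
#' when the proportion strictly exceeds `threshold`.
#'
#' @param network an `hct_network`.
#' @param positives character vector of positive compound IDs.
#' @param threshold flag threshold (default 0.10, strict `>`).
#' @return data.table with columns `herb_id`, `n_compounds`,
#'   `n_positive`, `proportion`, `flagged`.
#' @export
positive_proportion_by_herb <- function(network, positives,
                                        threshold = 0.10) {
  stopifnot(inherits(network, "hct_network"))
  positives <- as.character(positives)
  out <- network$hc_edges[, .(
    n_compounds = data.table::uniqueN(compound_id),
    n_positive = sum(unique(compound_id) %in% positives)), by = herb_id]
  out[, proportion := ifelse(n_compounds > 0, n_positive / n_compounds, 0)]
  out[, flagged := proportion > threshold]
  data.table::setorder(out, -proportion, herb_id)
  out[]
}

#' Per-compound target profiles from a network
#'
#' @param network an `hct_network` (or a data.frame of CT edges).
#' @return named list mapping compound_id to its character vector of
#'   targets.
#' @export
compound_profiles <- function(network) {
  ct <- if (inherits(network, "hct_network")) network$ct_edges
        else data.table::as.data.table(network)
  if (nrow(ct) == 0) return(list())
  split(as.character(ct$target), as.character(ct$compound_id))
}
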