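#' A named gene set
#'
#' Gene identity is the trimmed Entrez ID string; duplicates and empty
#' IDs are dropped. No symbol-to-Entrez mapping is bundled: inputs must
#' be pre-mapped.
#'
#' @param name set name (e.g. "IO", "IM", "IN", "IG-1", "IG-2").
#' @param genes character (or coercible) vector of Entrez gene IDs.
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(name, genes) {
  genes <- trimws(as.character(genes))
  genes <- unique(genes[nzchar(genes) & !is.na(genes)])
  structure(list(name = as.character(name)[1], genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene set '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' A collection of gene sets over a common universe
#'
#' @param sets list of [gene_set] objects with unique names.
#' @param universe_size size of the gene universe (default 20,462
#'   protein-coding genes).
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe_size = 20462) {
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, TRUE, "gene_set")))
  nm <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("gene set names must be unique")
  if (any(vapply(sets, length, 1L) > universe_size))
    stop("a set is larger than the universe")
  names(sets) <- nm
  structure(list(sets = sets, universe_size = universe_size),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene set collection (universe %d):\n", x$universe_size))
  for (s in x$sets) cat(sprintf("  %-6s %d genes\n", s$name, length(s$genes)))
  invisible(x)
}

#' Keep targets supported by a minimum number of agents
#'
#' Curation filter for pipeline-derived target lists: targets with
#' fewer than `min_agents` distinct agents are removed (the boundary
#' count is kept).
#'
#' @param target_agents data.frame with columns `target`, `n_agents`,
#'   or a named numeric vector of agent counts.
#' @param min_agents minimum agent count (default 3).
#' @param name name for the resulting set (default "IO").
#' @return a [gene_set].
#' @export
filter_by_agent_count <- function(target_agents, min_agents = 3, name = "IO") {
  if (is.data.frame(target_agents)) {
    stopifnot(all(c("target", "n_agents") %in% names(target_agents)))
    tg <- as.character(target_agents$target)
    ct <- target_agents$n_agents
  } else {
    tg <- names(target_agents)
    ct <- as.numeric(target_agents)
  }
  if (any(ct < 0)) stop("agent counts must be >= 0")
  gene_set(name, tg[ct >= min_agents])
}

#' Genes belonging to a minimum number of sets
#'
#' Integrates a collection into the set of genes present in at least
#' `min_sets` member sets (the "IG-1" construction at the default of 2).
#'
#' @param collection a [gene_set_collection].
#' @param min_sets minimum number of sets a gene must appear in.
#' @param name name for the resulting set.
#' @return a [gene_set].
#' @export
integrate_min_membership <- function(collection, min_sets = 2,
                                     name = "IG-1") {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (min_sets > length(collection$sets))
    stop("min_sets exceeds the number of sets in the collection")
  tab <- table(unlist(lapply(collection$sets, function(s) s$genes)))
  gene_set(name, names(tab)[tab >= min_sets])
}

#' Union of all sets in a collection
#'
#' The "IG-2" construction: every gene appearing in any member set.
#'
#' @inheritParams integrate_min_membership
#' @return a [gene_set].
#' @export
union_sets <- function(collection, name = "IG-2") {
  stopifnot(inherits(collection, "gene_set_collection"))
  gene_set(name, unlist(lapply(collection$sets, function(s) s$genes)))
}

#' Build the five model gene sets from the three base sets
#'
#' Given the three curated cancer-immune-response sets, derives the two
#' integrated sets (membership >= 2, and the union) and returns all
#' five in one collection.
#'
#' @param collection a [gene_set_collection] holding the base sets.
#' @return a [gene_set_collection] with the base sets plus IG-1, IG-2.
#' @export
cir_model_sets <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  ig1 <- integrate_min_membership(collection, 2, "IG-1")
  ig2 <- union_sets(collection, "IG-2")
  gene_set_collection(c(collection$sets, list(ig1, ig2)),
                      universe_size = collection$universe_size)
}

#' Pairwise overlap significance within a collection
#'
#' One row per unordered pair of sets, with the overlap count and the
#' one-sided hypergeometric enrichment p-value in the collection's
#' universe.
#'
#' @param collection a [gene_set_collection].
#' @return data.table with columns `set_i`, `set_j`, `size_i`, `size_j`,
#'   `overlap`, `jaccard`, `p`.
#' @export
pairwise_overlap_report <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  sets <- collection$sets
  if (length(sets) < 2) stop("need at least two sets")
  pairs <- utils::combn(names(sets), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- sets[[pairs[1, j]]]$genes
    b <- sets[[pairs[2, j]]]$genes
    ov <- length(intersect(a, b))
    data.table::data.table(
      set_i = pairs[1, j], set_j = pairs[2, j],
      size_i = length(a), size_j = length(b), overlap = ov,
      jaccard = if (length(union(a, b)) > 0) ov / length(union(a, b)) else 0,
      p = set_overlap_test(a, b, collection$universe_size))
  })
  data.table::rbindlist(rows)
}
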