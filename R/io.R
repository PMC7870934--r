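# File formats: tab-separated tables with a header row and optional
# leading "#" metadata lines, GMT gene sets, id<TAB>SMILES tables,
# GraphML / plain edge-list network exports.

.read_tsv <- function(path) {
  first <- readLines(path, n = 50L, warn = FALSE)
  n_skip <- sum(cumprod(startsWith(first, "#")))
  data.table::fread(path, sep = "\t", header = TRUE, skip = n_skip,
                    colClasses = NULL, data.table = TRUE)
}

.write_tsv <- function(dt, path, meta = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (!is.null(meta)) {
    writeLines(paste0("# ", names(meta), "=", unlist(meta)), path)
    data.table::fwrite(dt, path, sep = "\t", append = TRUE,
                       col.names = TRUE)
  } else {
    data.table::fwrite(dt, path, sep = "\t")
  }
  invisible(path)
}

#' Read a per-herb literature count table
#'
#' Expects columns `herb_id`, `herb_papers`, `cooccurrence_papers`
#' (tab-separated, header row, leading `#` lines ignored).
#'
#' @param path file path.
#' @return data.table.
#' @export
read_literature_table <- function(path) {
  dt <- .read_tsv(path)
  req <- c("herb_id", "herb_papers", "cooccurrence_papers")
  if (!all(req %in% names(dt)))
    stop(path, " lacks columns: ",
         paste(setdiff(req, names(dt)), collapse = ", "))
  dt
}

#' Write a screen result (or any table) as annotated TSV
#'
#' @param dt table to write.
#' @param path output path.
#' @param meta optional named list written as leading `# key=value` lines.
#' @export
write_screen_results <- function(dt, path, meta = NULL)
  .write_tsv(data.table::as.data.table(dt), path, meta)

#' Read herb-compound membership pairs
#'
#' Expects columns `herb_id`, `compound_id`.
#' @param path file path.
#' @return data.table.
#' @export
read_hc_pairs <- function(path) {
  dt <- .read_tsv(path)
  if (!all(c("herb_id", "compound_id") %in% names(dt)))
    stop(path, " needs columns herb_id, compound_id")
  dt
}

#' Read a compound-target interaction table
#'
#' Expects columns `compound_id`, `target` and optionally
#' `affinity_value`, `affinity_unit`, `affinity_kind`.
#' @param path file path.
#' @return data.table.
#' @export
read_ct_table <- function(path) {
  dt <- .read_tsv(path)
  if (!all(c("compound_id", "target") %in% names(dt)))
    stop(path, " needs columns compound_id, target")
  dt
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then gene IDs, tab-separated.
#'
#' @param path file path.
#' @param universe_size universe for the resulting collection.
#' @return a [gene_set_collection].
#' @export
read_gmt <- function(path, universe_size = 20462) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(ln, 1, 60))
    gene_set(f[1], f[-(1:2)])
  })
  gene_set_collection(sets, universe_size = universe_size)
}

#' Write a collection (or single set) in GMT format
#'
#' @param collection a [gene_set_collection] or [gene_set].
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  sets <- if (inherits(collection, "gene_set")) list(collection)
          else collection$sets
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(vapply(sets, function(s)
    paste(c(s$name, "na", s$genes), collapse = "\t"), ""), path)
  invisible(path)
}

#' Read a compound SMILES table
#'
#' Expects columns `compound_id`, `smiles`.
#' @param path file path.
#' @return data.table.
#' @export
read_smiles_table <- function(path) {
  dt <- .read_tsv(path)
  if (!all(c("compound_id", "smiles") %in% names(dt)))
    stop(path, " needs columns compound_id, smiles")
  dt
}

#' Convert a network to an igraph object
#'
#' Nodes carry a `type` attribute (herb/compound/target); edges carry
#' `relation` ("herb-compound" or "compound-target") and, for CT edges,
#' `evidence` and `affinity_um`.
#'
#' @param network an `hct_network`.
#' @return an igraph graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "hct_network"))
  nodes <- data.frame(
    name = c(network$herbs, network$compounds, network$targets),
    type = rep(c("herb", "compound", "target"),
               c(length(network$herbs), length(network$compounds),
                 length(network$targets))))
  hc <- network$hc_edges
  ct <- network$ct_edges
  edges <- rbind(
    data.frame(from = hc$herb_id, to = hc$compound_id,
               relation = "herb-compound",
               evidence = NA_character_, affinity_um = NA_real_),
    if (nrow(ct)) data.frame(from = ct$compound_id, to = ct$target,
                             relation = "compound-target",
                             evidence = ct$evidence,
                             affinity_um = ct$affinity_um))
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Export a network as GraphML plus plain edge lists
#'
#' Writes `<stem>.graphml` and two TSV edge lists
#' (`<stem>_hc_edges.tsv`, `<stem>_ct_edges.tsv`) suitable for
#' Gephi/Cytoscape import.
#'
#' @param network an `hct_network`.
#' @param stem output path stem.
#' @param meta optional metadata for the TSV headers.
#' @return paths written, invisibly.
#' @export
write_network_exports <- function(network, stem, meta = NULL) {
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  gml <- paste0(stem, ".graphml")
  igraph::write_graph(as_igraph(network), gml, format = "graphml")
  hc <- paste0(stem, "_hc_edges.tsv")
  ct <- paste0(stem, "_ct_edges.tsv")
  .write_tsv(network$hc_edges, hc, meta)
  keep <- intersect(c("compound_id", "target", "evidence", "affinity_value",
                      "affinity_unit", "affinity_kind", "affinity_um"),
                    names(network$ct_edges))
  .write_tsv(network$ct_edges[, keep, with = FALSE], ct, meta)
  invisible(c(gml, hc, ct))
}
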