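#' Corpus-level literature counts
#'
#' Constants of the literature screen: the total number of indexed
#' papers (N) and the number mentioning the disease (K). Defaults are
#' the corpus snapshot used throughout the package's examples
#' (N = 29.0 million, K = 3,874,763 cancer papers).
#'
#' @param total_papers total papers in the corpus (N).
#' @param disease_papers papers co-occurring with the disease (K).
#' @return an object of class `corpus_stats`.
#' @export
corpus_stats <- function(total_papers = 29.0e6, disease_papers = 3874763) {
  if (disease_papers <= 0 || disease_papers > total_papers)
    stop("need 0 < disease_papers <= total_papers")
  structure(list(total_papers = total_papers,
                 disease_papers = disease_papers),
            class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf("corpus: N = %s papers, K = %s disease papers (K/N = %.4f)\n",
              format(x$total_papers, big.mark = ","),
              format(x$disease_papers, big.mark = ","),
              x$disease_papers / x$total_papers))
  invisible(x)
}

#' Chance probability of an herb-disease literature co-occurrence
#'
#' Probability of seeing at least `cooccurrence_papers` disease papers
#' among an herb's `herb_papers` by chance, under hypergeometric
#' sampling from the corpus. Herbs with no papers get p = 1 (no
#' evidence can never be significant).
#'
#' @param herb_papers number of papers mentioning the herb (n).
#' @param cooccurrence_papers papers mentioning both herb and disease (k).
#' @param corpus a [corpus_stats] object.
#' @return a p-value. Vectorised over the two count arguments.
#' @export
herb_pvalue <- function(herb_papers, cooccurrence_papers, corpus) {
  stopifnot(inherits(corpus, "corpus_stats"))
  if (any(cooccurrence_papers > herb_papers))
    stop("cooccurrence_papers exceeds herb_papers")
  if (any(herb_papers > corpus$total_papers))
    stop("herb_papers exceeds corpus size")
  n <- length(herb_papers)
  p <- numeric(n)
  for (i in seq_len(n)) {
    p[i] <- if (herb_papers[i] == 0) 1 else
      hypergeom_tail(pop_size = corpus$total_papers,
                     successes_in_pop = corpus$disease_papers,
                     draws = herb_papers[i],
                     observed = cooccurrence_papers[i],
                     strict = FALSE)
  }
  p
}

#' Negative base-10 log of a q-value with display floor
#'
#' `-log10(q)` with zeros replaced by a small positive floor, so that a
#' q of exactly zero displays as a capped finite value (200.00 at the
#' default floor of 1e-200).
#'
#' @param qvalue q-values in \[0, 1\].
#' @param floor replacement for zero (default 1e-200).
#' @return non-negative values, capped at `-log10(floor)`.
#' @export
neg_log_q <- function(qvalue, floor = 1e-200) {
  if (any(qvalue < 0 | qvalue > 1, na.rm = TRUE))
    stop("qvalue must lie in [0, 1]")
  pmin(-log10(pmax(qvalue, floor)), -log10(floor))
}

#' Screen herbs for disease association from literature counts
#'
#' Computes the co-occurrence p-value for every herb, applies
#' Benjamini-Hochberg across the full submitted list, and flags herbs
#' passing both filters: adjusted q strictly below `q_threshold` and
#' co-occurrence ratio R = k/n strictly above `r_threshold`. Output is
#' ordered by descending `-lg(q)`, ties broken by descending ratio then
#' herb_id, so the ranking is invariant to input order.
#'
#' @param records data.frame with columns `herb_id`, `herb_papers`,
#'   `cooccurrence_papers`.
#' @param corpus a [corpus_stats] object.
#' @param q_threshold significance threshold on q (default 0.01, strict `<`).
#' @param r_threshold threshold on the ratio R (default 0.05, strict `>`).
#' @return data.table with added columns `ratio`, `pvalue`, `qvalue`,
#'   `neg_log_q`, `significant`.
#' @export
screen_herbs <- function(records, corpus, q_threshold = 0.01,
                         r_threshold = 0.05) {
  req <- c("herb_id", "herb_papers", "cooccurrence_papers")
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("records must be a non-empty data.frame")
  if (!all(req %in% names(records)))
    stop("records needs columns: ", paste(req, collapse = ", "))
  dt <- data.table::as.data.table(records)[, req, with = FALSE]
  if (anyDuplicated(dt$herb_id)) stop("duplicate herb_id in records")
  dt[, ratio := ifelse(herb_papers > 0,
                       cooccurrence_papers / herb_papers, 0)]
  dt[, pvalue := herb_pvalue(herb_papers, cooccurrence_papers, corpus)]
  dt[, qvalue := bh_adjust(pvalue)]
  dt[, neg_log_q := neg_log_q(qvalue)]
  dt[, significant := qvalue < q_threshold & ratio > r_threshold]
  data.table::setorder(dt, -neg_log_q, -ratio, herb_id)
  dt[]
}
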