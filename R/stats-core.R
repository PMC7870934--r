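#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least (or strictly more than) `observed`
#' successes when `draws` items are taken without replacement from a
#' population of `pop_size` containing `successes_in_pop` successes.
#' This is the chance probability behind literature co-occurrence
#' screening (population = corpus, successes = disease papers, draws =
#' papers mentioning the herb) and the exact null of the target-set
#' permutation models (population = protein-coding genome, successes =
#' gene-set size, draws = a compound's targets).
#'
#' Computed through the log-space survival function of the
#' hypergeometric distribution, so corpus-scale populations
#' (N ~ 2.9e7) do not overflow; the literal finite sum of binomial
#' coefficients is only used as an oracle in the test suite.
#'
#' @param pop_size population size (N).
#' @param successes_in_pop number of successes in the population (K).
#' @param draws number of draws (n).
#' @param observed observed successes among the draws (k).
#' @param strict if `FALSE` (default) return P(X >= observed) ("at least
#'   k"); if `TRUE` return P(X > observed) (the permutation-model tail).
#' @return a probability in \[0, 1\]. Vectorised over `observed`.
#' @examples
#' hypergeom_tail(10, 4, 3, 2)          # 1/3
#' hypergeom_tail(10, 3, 4, 2, strict = TRUE)  # 7/210
#' @export
hypergeom_tail <- function(pop_size, successes_in_pop, draws, observed,
                           strict = FALSE) {
  .check_count(pop_size, "pop_size")
  .check_count(successes_in_pop, "successes_in_pop")
  .check_count(draws, "draws")
  .check_count(observed, "observed")
  if (successes_in_pop > pop_size)
    stop("successes_in_pop (", successes_in_pop, ") exceeds pop_size (",
         pop_size, ")")
  if (draws > pop_size)
    stop("draws (", draws, ") exceeds pop_size (", pop_size, ")")
  if (any(observed > pmin(draws, successes_in_pop)))
    stop("observed exceeds min(draws, successes_in_pop)")
  q <- if (strict) observed else observed - 1
  stats::phyper(q, m = successes_in_pop, n = pop_size - successes_in_pop,
                k = draws, lower.tail = FALSE)
}

.check_count <- function(x, what) {
  if (length(x) < 1 || anyNA(x) || any(x < 0) || any(x != floor(x)))
    stop(what, " must be a non-negative integer count")
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control; output keeps the order and
#' length of the input.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return vector of q-values, `q >= p` elementwise.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' One-sided gene-set overlap enrichment test
#'
#' Fisher-style enrichment p-value for the overlap of two gene sets in a
#' finite universe: the hypergeometric probability of an overlap at
#' least as large as observed.
#'
#' @param set_a,set_b character vectors of gene IDs, or [gene_set]
#'   objects.
#' @param universe_size size of the gene universe both sets were drawn
#'   from.
#' @return enrichment p-value.
#' @export
set_overlap_test <- function(set_a, set_b, universe_size) {
  a <- unique(.genes_of(set_a))
  b <- unique(.genes_of(set_b))
  .check_count(universe_size, "universe_size")
  if (length(a) > universe_size || length(b) > universe_size)
    stop("universe_size smaller than one of the sets")
  hypergeom_tail(pop_size = universe_size, successes_in_pop = length(a),
                 draws = length(b), observed = length(intersect(a, b)),
                 strict = FALSE)
}

.genes_of <- function(x) {
  if (inherits(x, "gene_set")) x$genes else as.character(x)
}
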