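#' Drop compounds that cannot be scored
#'
#' Removes blocklisted compounds (ions, organic solvents, ...) and
#' compounds whose target set has zero overlap with the gene set under
#' test.
#'
#' @param profiles named list of compound target vectors (see
#'   [compound_profiles()]).
#' @param genes a [gene_set] or character vector.
#' @param blocklist compound IDs to remove unconditionally.
#' @return the filtered profile list.
#' @export
eligible_profiles <- function(profiles, genes, blocklist = character(0)) {
  g <- .genes_of(genes)
  profiles <- profiles[!names(profiles) %in% as.character(blocklist)]
  keep <- vapply(profiles, function(tg) length(intersect(tg, g)) > 0, TRUE)
  profiles[keep]
}

#' Define a shared permutation null
#'
#' Describes the null used by the network models: `n_permutations`
#' draws of `geneset_size` distinct genes, uniformly without
#' replacement from a universe of `universe_size` protein-coding genes.
#' One null is shared by every compound scored against the same gene
#' set; draws are generated deterministically from `seed` in fixed-size
#' chunks, so results are bit-reproducible.
#'
#' @param geneset_size number of genes drawn per permutation (x).
#' @param universe_size genome-wide gene count (default 20,462).
#' @param n_permutations number of draws (default 100,000).
#' @param seed integer RNG seed.
#' @return an object of class `null_sampler`.
#' @export
sample_null <- function(geneset_size, universe_size = 20462,
                        n_permutations = 100000, seed = 1L) {
  .check_count(geneset_size, "geneset_size")
  .check_count(universe_size, "universe_size")
  .check_count(n_permutations, "n_permutations")
  if (geneset_size > universe_size)
    stop("geneset_size exceeds universe_size")
  if (n_permutations < 1) stop("need at least one permutation")
  structure(list(geneset_size = as.integer(geneset_size),
                 universe_size = as.integer(universe_size),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), chunk_size = 1000L),
            class = "null_sampler")
}

#' @export
print.null_sampler <- function(x, ...) {
  cat(sprintf("permutation null: %d draws of %d genes from %d (seed %d)\n",
              x$n_permutations, x$geneset_size, x$universe_size, x$seed))
  invisible(x)
}

# Stream the null draws chunk by chunk as a sparse indicator matrix
# (universe x chunk). f(S, n_done) is called once per chunk.
.with_null_chunks <- function(sampler, f) {
  set.seed(sampler$seed)
  U <- sampler$universe_size
  x <- sampler$geneset_size
  done <- 0L
  while (done < sampler$n_permutations) {
    B <- min(sampler$chunk_size, sampler$n_permutations - done)
    if (x == 0) {
      S <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                dims = c(U, B))
    } else {
      draws <- vapply(seq_len(B), function(i) sample.int(U, x), integer(x))
      S <- Matrix::sparseMatrix(i = as.vector(draws),
                                j = rep(seq_len(B), each = x),
                                x = 1, dims = c(U, B))
    }
    f(S, done)
    done <- done + B
  }
  invisible(NULL)
}

#' Null overlap counts for one target set
#'
#' Materialises, for a single compound, the overlap between its targets
#' and every permutation draw of the sampler. Intended for diagnostics
#' and small problems; model scoring streams the same draws without
#' storing them.
#'
#' @param sampler a [sample_null()] object.
#' @param targets_idx integer indices of the compound's targets in
#'   `1..universe_size` (any injection of target genes into the
#'   universe is valid by exchangeability).
#' @return integer vector of length `n_permutations`.
#' @export
null_overlaps <- function(sampler, targets_idx) {
  stopifnot(inherits(sampler, "null_sampler"))
  targets_idx <- as.integer(targets_idx)
  if (any(targets_idx < 1 | targets_idx > sampler$universe_size))
    stop("target indices outside the universe")
  out <- integer(sampler$n_permutations)
  .with_null_chunks(sampler, function(S, done) {
    ov <- if (length(targets_idx) == 0) integer(ncol(S)) else
      as.integer(round(Matrix::colSums(S[targets_idx, , drop = FALSE])))
    out[done + seq_len(ncol(S))] <<- ov
  })
  out
}

#' Permutation p-value (strict tail)
#'
#' Fraction of null samples strictly greater than the observed count.
#' Ties do not count against the observation, and the value may be an
#' exact zero.
#'
#' @param observed observed overlap count.
#' @param null_samples vector of null overlap counts.
#' @return a probability.
#' @export
permutation_pvalue <- function(observed, null_samples) {
  if (length(null_samples) < 1) stop("need at least one permutation")
  sum(null_samples > observed) / length(null_samples)
}

#' Permutation Z-score
#'
#' `(observed - mean(null)) / sd(null)`; errors when the null has zero
#' spread, since the score is then undefined.
#'
#' @inheritParams permutation_pvalue
#' @return a real Z-score.
#' @export
permutation_zscore <- function(observed, null_samples) {
  if (length(null_samples) < 2) stop("need at least two permutations")
  s <- stats::sd(null_samples)
  if (!is.finite(s) || s == 0)
    stop("null distribution has zero spread (all samples = ",
         null_samples[1], "); Z undefined")
  (observed - mean(null_samples)) / s
}

#' Exact p-value for the permutation null
#'
#' Closed-form equivalent of the permutation p-value: the strict upper
#' tail of the hypergeometric distribution of the overlap between a
#' fixed m-target set and a random x-gene draw from the universe. Used
#' to validate the Monte-Carlo machinery and as a fast scoring path.
#'
#' @param observed observed overlap.
#' @param m number of targets of the compound.
#' @param geneset_size genes drawn per permutation (x).
#' @param universe_size universe size.
#' @return P(X > observed) under the hypergeometric null.
#' @export
analytic_pvalue <- function(observed, m, geneset_size,
                            universe_size = 20462) {
  hypergeom_tail(pop_size = universe_size, successes_in_pop = geneset_size,
                 draws = m, observed = observed, strict = TRUE)
}

#' Score compounds against one gene-set model
#'
#' For every eligible compound, computes the observed number of
#' gene-set targets (Sm), a p-value from the shared permutation null
#' (or the exact hypergeometric fast path), the null mean/SD and the
#' Z-score, then applies Benjamini-Hochberg across all compounds scored
#' in this model. Positives are compounds with q strictly below
#' `q_threshold`.
#'
#' @param profiles named list of compound target vectors.
#' @param genes a [gene_set].
#' @param universe_size genome-wide gene count.
#' @param n_permutations permutation count (ignored for
#'   `method = "analytic"`).
#' @param seed RNG seed; recorded in every result row.
#' @param q_threshold positive-call threshold on q (default 0.01).
#' @param method `"permutation"` (Monte-Carlo null) or `"analytic"`
#'   (exact hypergeometric tail and moments; bit-stable, no RNG).
#' @param blocklist compounds to drop before scoring.
#' @return an object of class `model_prediction` with elements
#'   `geneset_name`, `results` (one row per scored compound),
#'   `positives`, and `settings`.
#' @export
score_model <- function(profiles, genes, universe_size = 20462,
                        n_permutations = 100000, seed = 1L,
                        q_threshold = 0.01,
                        method = c("permutation", "analytic"),
                        blocklist = character(0)) {
  method <- match.arg(method)
  stopifnot(inherits(genes, "gene_set"))
  profiles <- eligible_profiles(profiles, genes, blocklist)
  if (length(profiles) == 0)
    stop("no eligible compounds (all blocklisted or zero overlap)")
  profiles <- lapply(profiles, unique)
  g <- genes$genes
  x <- length(g)
  catalog <- sort(unique(c(unlist(profiles, use.names = FALSE), g)))
  if (length(catalog) > universe_size)
    stop("more distinct genes (", length(catalog),
         ") than the universe (", universe_size, ")")
  m <- lengths(profiles)
  observed <- vapply(profiles, function(tg) length(intersect(tg, g)), 1L)

  if (method == "analytic") {
    U <- universe_size
    pvals <- mapply(analytic_pvalue, observed, m,
                    MoreArgs = list(geneset_size = x, universe_size = U))
    mu <- m * x / U
    sig <- sqrt(m * (x / U) * (1 - x / U) * (U - m) / (U - 1))
    z <- (observed - mu) / sig
    p_analytic <- pvals
    nperm_used <- 0L
  } else {
    sampler <- sample_null(x, universe_size, n_permutations, seed)
    idx <- lapply(profiles, function(tg) match(tg, catalog))
    Tm <- Matrix::sparseMatrix(
      i = rep(seq_along(idx), times = lengths(idx)),
      j = unlist(idx), x = 1,
      dims = c(length(idx), universe_size))
    cnt_gt <- numeric(length(idx))
    s1 <- numeric(length(idx))
    s2 <- numeric(length(idx))
    .with_null_chunks(sampler, function(S, done) {
      M <- as.matrix(Tm %*% S)
      cnt_gt <<- cnt_gt + rowSums(M > observed)
      s1 <<- s1 + rowSums(M)
      s2 <<- s2 + rowSums(M * M)
    })
    np <- sampler$n_permutations
    pvals <- cnt_gt / np
    mu <- s1 / np
    sig <- sqrt(pmax(0, (s2 - np * mu^2) / (np - 1)))
    if (any(sig == 0))
      stop("permutation null has zero spread for some compounds; ",
           "increase n_permutations")
    z <- (observed - mu) / sig
    p_analytic <- mapply(analytic_pvalue, observed, m,
                         MoreArgs = list(geneset_size = x,
                                         universe_size = universe_size))
    nperm_used <- np
  }

  res <- data.table::data.table(
    compound_id = names(profiles), m = as.integer(m),
    observed = as.integer(observed), null_mean = mu, null_sd = sig,
    pvalue = pvals, pvalue_analytic = p_analytic,
    qvalue = bh_adjust(pvals), zscore = z,
    n_permutations = nperm_used, seed = as.integer(seed))
  data.table::setorder(res, pvalue, -zscore, compound_id)
  structure(list(
    geneset_name = genes$name, results = res,
    positives = res$compound_id[res$qvalue < q_threshold],
    settings = list(universe_size = universe_size, method = method,
                    n_permutations = nperm_used, seed = seed,
                    q_threshold = q_threshold)),
    class = "model_prediction")
}

#' @export
print.model_prediction <- function(x, ...) {
  cat(sprintf("model '%s' (%s, universe %d): %d compounds scored, %d positive at q < %g\n",
              x$geneset_name, x$settings$method, x$settings$universe_size,
              nrow(x$results), length(x$positives), x$settings$q_threshold))
  invisible(x)
}

#' Combine gene-set models into a consensus ranking
#'
#' Union and intersection of per-model positive calls, plus a combined
#' Z-score per compound: the mean over models of the per-model
#' normalised Z. Normalisation is across compounds within each model,
#' by default z-standardisation (min-max rescaling offered as an
#' alternative); the intersection is over the models in which the
#' compound was scored.
#'
#' @param models list of `model_prediction` objects.
#' @param normalization `"zstandardize"` (default) or `"minmax"`.
#' @return an object of class `consensus_ranking` with a ranked `table`
#'   (compound, models scored/positive, combined_z), `union_positives`
#'   and `all_model_positives`.
#' @export
combine_models <- function(models,
                           normalization = c("zstandardize", "minmax")) {
  normalization <- match.arg(normalization)
  stopifnot(length(models) >= 1,
            all(vapply(models, inherits, TRUE, "model_prediction")))
  norm1 <- function(z) {
    if (length(z) < 2) return(rep(0, length(z)))
    if (normalization == "zstandardize") {
      s <- stats::sd(z)
      if (s == 0) rep(0, length(z)) else (z - mean(z)) / s
    } else {
      r <- range(z)
      if (diff(r) == 0) rep(0, length(z)) else (z - r[1]) / diff(r)
    }
  }
  per <- data.table::rbindlist(lapply(models, function(mdl) {
    data.table::data.table(
      geneset_name = mdl$geneset_name,
      compound_id = mdl$results$compound_id,
      norm_z = norm1(mdl$results$zscore),
      positive = mdl$results$compound_id %in% mdl$positives)
  }))
  tab <- per[, .(n_models_scored = .N, n_models_positive = sum(positive),
                 combined_z = mean(norm_z)), by = compound_id]
  data.table::setorder(tab, -combined_z, compound_id)
  structure(list(
    table = tab[],
    union_positives = sort(unique(per$compound_id[per$positive])),
    all_model_positives = sort(
      tab$compound_id[tab$n_models_positive == tab$n_models_scored &
                        tab$n_models_positive > 0]),
    normalization = normalization,
    geneset_names = vapply(models, `[[`, "", "geneset_name")),
    class = "consensus_ranking")
}

#' @export
print.consensus_ranking <- function(x, ...) {
  cat(sprintf("consensus over %d models (%s): %d compounds ranked, %d union positives, %d positive in every model scored\n",
              length(x$geneset_names), x$normalization, nrow(x$table),
              length(x$union_positives), length(x$all_model_positives)))
  invisible(x)
}
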