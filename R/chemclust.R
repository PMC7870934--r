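#' Circular feature-class fingerprints from SMILES
#'
#' Computes folded binary feature-class circular fingerprints
#' (diameter 6 at the default radius 3, i.e. the FCFP_6 family) for a
#' vector of structures, by delegating to the Python RDKit toolkit
#' found on the PATH (Morgan fingerprint with feature invariants).
#' Identical canonical structures give identical fingerprints;
#' tautomer-insensitive canonicalisation is *not* promised.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids compound IDs (defaults to names of `smiles` or an index).
#' @param radius circular radius (default 3).
#' @param n_bits folded length (default 2048).
#' @param python path to a Python interpreter with RDKit.
#' @return logical matrix, one row per compound (rownames = ids).
#' @export
fingerprints_from_smiles <- function(smiles, ids = NULL, radius = 3,
                                     n_bits = 2048,
                                     python = Sys.which("python")) {
  if (is.null(ids))
    ids <- if (!is.null(names(smiles))) names(smiles)
           else sprintf("cmp%04d", seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  if (!nzchar(python))
    stop("no python interpreter found; RDKit is required for SMILES ",
         "fingerprints (fingerprint matrices can be supplied directly)")
  script <- system.file("python", "fcfp_bits.py", package = "tcmimmuno")
  if (!nzchar(script)) stop("bundled fingerprint script not found")
  input <- paste(ids, smiles, sep = "\t")
  out <- suppressWarnings(system2(python, c(shQuote(script), radius, n_bits),
                                  input = input, stdout = TRUE,
                                  stderr = FALSE))
  parts <- strsplit(out, "\t", fixed = TRUE)
  got_id <- vapply(parts, `[`, "", 1)
  payload <- vapply(parts, function(p) if (length(p) > 1) p[2] else "", "")
  bad <- got_id[payload == "ERROR"]
  if (length(bad))
    stop("unparseable SMILES for: ", paste(bad, collapse = ", "))
  if (!setequal(got_id, ids))
    stop("fingerprint backend failed (python/RDKit error)")
  fp <- matrix(FALSE, nrow = length(ids), ncol = n_bits,
               dimnames = list(ids, NULL))
  for (i in seq_along(parts)) {
    on <- payload[match(ids[i], got_id)]
    if (nzchar(on))
      fp[i, as.integer(strsplit(on, ",", fixed = TRUE)[[1]]) + 1L] <- TRUE
  }
  fp
}

#' @rdname fingerprints_from_smiles
#' @export
fingerprint_from_smiles <- function(smiles, radius = 3, n_bits = 2048,
                                    python = Sys.which("python")) {
  fingerprints_from_smiles(smiles[1], ids = "fp", radius = radius,
                           n_bits = n_bits, python = python)[1, ]
}

#' Tanimoto distance between two fingerprints
#'
#' `1 - |a AND b| / |a OR b|`; 0 for identical bit sets, 1 for disjoint
#' ones. Two empty fingerprints have distance 0 by convention.
#'
#' @param a,b logical (or 0/1) vectors of equal length.
#' @return a distance in \[0, 1\].
#' @export
tanimoto_distance <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint lengths differ")
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0) return(0)
  1 - sum(a & b) / un
}

#' Pairwise Tanimoto distance matrix
#'
#' @param fps logical (or 0/1) matrix, one fingerprint per row.
#' @return symmetric numeric matrix of Tanimoto distances.
#' @export
tanimoto_dist_matrix <- function(fps) {
  fps <- as.matrix(fps) * 1
  inter <- tcrossprod(fps)
  n_on <- rowSums(fps)
  un <- outer(n_on, n_on, `+`) - inter
  d <- 1 - inter / un
  d[un == 0] <- 0   # two empty fingerprints
  diag(d) <- 0
  dimnames(d) <- list(rownames(fps), rownames(fps))
  d
}

#' k-medoids scaffold clustering under Tanimoto distance
#'
#' Partitions fingerprints into `k` groups, each represented by a
#' medoid compound minimising the root-mean-square Tanimoto distance
#' to its members (equivalently the within-cluster sum of squared
#' distances). Alternates assignment to the nearest medoid with exact
#' medoid updates until the objective stops improving; the objective is
#' non-increasing across iterations and the result is deterministic
#' given the seed.
#'
#' @param fps logical matrix of fingerprints (one per row, rownames =
#'   compound IDs), or a precomputed symmetric distance matrix when
#'   `is_distance = TRUE`.
#' @param k number of clusters (default 5).
#' @param seed RNG seed for medoid initialisation.
#' @param max_iter iteration cap.
#' @param is_distance interpret `fps` as a distance matrix.
#' @return an object of class `fp_clusters`: `cluster` (named integer
#'   assignment), `medoids` (compound IDs), `within_rms` (per-cluster
#'   RMS distance to the medoid), `objective` (total sum of squared
#'   distances), `objective_trace`.
#' @export
cluster_fingerprints <- function(fps, k = 5, seed = 1L, max_iter = 100,
                                 is_distance = FALSE) {
  d <- if (is_distance) as.matrix(fps) else tanimoto_dist_matrix(fps)
  n <- nrow(d)
  if (k > n) stop("k (", k, ") exceeds the number of compounds (", n, ")")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- sprintf("c%04d", 1:n)
  ids <- rownames(d)
  d2 <- d * d
  set.seed(seed)
  # k-means++-style seeding on squared distances, then exact alternation
  med <- sample.int(n, 1)
  while (length(med) < k) {
    w <- apply(d2[, med, drop = FALSE], 1, min)
    w[med] <- 0
    med <- c(med, if (sum(w) > 0) sample.int(n, 1, prob = w)
                  else sample(setdiff(seq_len(n), med), 1))
  }
  obj_of <- function(assign, med)
    sum(d2[cbind(seq_len(n), med[assign])])
  trace <- numeric(0)
  assign <- max.col(-d2[, med, drop = FALSE], ties.method = "first")
  obj <- obj_of(assign, med)
  for (it in seq_len(max_iter)) {
    trace <- c(trace, obj)
    new_med <- med
    for (j in seq_len(k)) {
      members <- which(assign == j)
      if (length(members) == 0) {           # revive on the worst-fit point
        far <- which.max(d2[cbind(seq_len(n), med[assign])])
        new_med[j] <- far
        next
      }
      ss <- colSums(d2[members, members, drop = FALSE])
      new_med[j] <- members[which.min(ss)]
    }
    new_assign <- max.col(-d2[, new_med, drop = FALSE],
                          ties.method = "first")
    new_obj <- obj_of(new_assign, new_med)
    if (new_obj >= obj - 1e-12 && identical(new_med, med)) break
    if (new_obj <= obj) {
      med <- new_med; assign <- new_assign; obj <- new_obj
    } else break
  }
  within_rms <- vapply(seq_len(k), function(j) {
    members <- which(assign == j)
    if (length(members) == 0) return(NA_real_)
    sqrt(mean(d2[members, med[j]]))
  }, 1.0)
  structure(list(
    cluster = stats::setNames(assign, ids),
    medoids = ids[med],
    within_rms = stats::setNames(within_rms, ids[med]),
    objective = obj, objective_trace = c(trace, obj),
    k = k, seed = seed), class = "fp_clusters")
}

#' @export
print.fp_clusters <- function(x, ...) {
  cat(sprintf("k-medoids Tanimoto clustering: k = %d, %d compounds, objective (sum sq dist) = %.4f\n",
              x$k, length(x$cluster), x$objective))
  for (j in seq_len(x$k))
    cat(sprintf("  cluster %d: %d members, medoid %s, within RMS %.3f\n",
                j, sum(x$cluster == j), x$medoids[j], x$within_rms[j]))
  invisible(x)
}
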