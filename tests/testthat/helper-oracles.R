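# Independent oracles, kept deliberately naive.

# Exhaustive hypergeometric tail by enumerating every draw (pop <= 12).
enum_hyper_tail <- function(pop, succ, draws, obs, strict = FALSE) {
  if (draws == 0) return(as.numeric(if (strict) obs < 0 else obs <= 0))
  combos <- utils::combn(pop, draws)
  hits <- colSums(combos <= succ)   # items 1..succ are the successes
  if (strict) mean(hits > obs) else mean(hits >= obs)
}

# Literal Benjamini-Hochberg step-up rule.
bh_by_hand <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Pair-counting partition agreement (Rand index), label-permutation
# invariant.
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, `==`)[upper.tri(diag(n))]
  same_b <- outer(b, b, `==`)[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# Small valid structures for fingerprint tests.
test_smiles <- c(methane = "C", benzene = "c1ccccc1",
                 ethanol = "CCO", phenol = "Oc1ccccc1")
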