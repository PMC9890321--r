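# Independent oracles used by the tests. These deliberately avoid the
# package's own counting / testing code paths: counting is done by explicit
# loops, null distributions by exhaustive enumeration of multiset
# permutations, and the Kruskal-Wallis statistic by the rank formula.

# all distinct arrangements of a token multiset
multiset_perms <- function(tokens) {
  out <- list()
  rec <- function(prefix, rest) {
    if (!length(rest)) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (u in unique(rest)) rec(c(prefix, u), rest[-match(u, rest)])
  }
  rec(character(0), sort(tokens))
  out
}

# forward transition probability from -> to of one arrangement cut into
# sequences of the given lengths (NA if `from` never precedes anything)
oracle_trans_prob <- function(arrangement, lens, from, to) {
  n_from <- 0L
  n_pair <- 0L
  pos <- 0L
  for (L in lens) {
    seqk <- arrangement[pos + seq_len(L)]
    pos <- pos + L
    if (L < 2) next
    for (i in seq_len(L - 1)) {
      if (seqk[i] == from) {
        n_from <- n_from + 1L
        if (seqk[i + 1] == to) n_pair <- n_pair + 1L
      }
    }
  }
  if (n_from == 0L) NA_real_ else n_pair / n_from
}

# exhaustive null distribution and exact two-tailed p for one cell, using the
# same tail rule as the Monte-Carlo test (ties into both tails, p = 2*min)
oracle_exact_test <- function(tokens, lens, from, to, observed) {
  vals <- vapply(multiset_perms(tokens), oracle_trans_prob, numeric(1),
                 lens = lens, from = from, to = to)
  vals <- vals[!is.na(vals)]
  pl <- mean(vals <= observed)
  pg <- mean(vals >= observed)
  list(null = vals, p = min(1, 2 * min(pl, pg)))
}

# Kruskal-Wallis H by the rank formula with tie correction
oracle_kw_H <- function(g1, g2) {
  x <- c(g1, g2)
  n <- length(x)
  r <- rank(x)
  R1 <- sum(r[seq_along(g1)])
  R2 <- sum(r[-seq_along(g1)])
  H <- 12 / (n * (n + 1)) *
    (R1^2 / length(g1) + R2^2 / length(g2)) - 3 * (n + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}
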