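# Independent oracles: brute-force or closed-form reference computations that
# never share code with the implementation paths they check.

# Exact maximum of sum_{communities} sum(B[c, c]) over all set partitions of
# the nodes, via a subset dynamic program: OPT(S) = max over subsets T of S
# containing S's lowest element of w(T) + OPT(S \ T). O(3^n); n <= ~12.
exhaustive_best_weight <- function(B) {
  n <- nrow(B)
  stopifnot(n <= 14)
  full <- bitwShiftL(1L, n) - 1L
  # subset weights, built incrementally from the subset without its lowest bit
  w <- numeric(full + 1L)
  members <- vector("list", full + 1L)
  members[[1L]] <- integer(0)
  for (m in seq_len(full)) {
    low <- bitwAnd(m, -m)
    k <- as.integer(log2(low)) + 1L
    rest <- bitwAnd(m, bitwNot(low))
    mem <- members[[rest + 1L]]
    w[m + 1L] <- w[rest + 1L] + 2 * sum(B[k, mem]) + B[k, k]
    members[[m + 1L]] <- c(mem, k)
  }
  best <- numeric(full + 1L)
  for (m in seq_len(full)) {
    low <- bitwAnd(m, -m)
    rest <- bitwAnd(m, bitwNot(low))
    # iterate submasks of rest; T = sub | low always contains the lowest bit
    opt <- w[low + 1L] + best[rest + 1L]
    sub <- rest
    while (sub > 0L) {
      T <- bitwOr(sub, low)
      cand <- w[T + 1L] + best[bitwAnd(m, bitwNot(T)) + 1L]
      if (cand > opt) opt <- cand
      sub <- bitwAnd(sub - 1L, rest)
    }
    best[m + 1L] <- opt
  }
  best[full + 1L]
}

# Literal quadruple-sum evaluation of multilayer modularity from its
# definition, looping over every ordered node pair.
naive_modularity <- function(Bobj, p) {
  n <- length(p$labels)
  q <- 0
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (p$labels[u] == p$labels[v]) q <- q + Bobj$B[u, v]
  }
  q / Bobj$c_norm
}

# Two-pass textbook Pearson correlation of log1p-transformed TPM vectors.
naive_pearson_log1p <- function(x, y) {
  lx <- log(x + 1); ly <- log(y + 1)
  mx <- sum(lx) / length(lx); my <- sum(ly) / length(ly)
  num <- sum((lx - mx) * (ly - my))
  num / sqrt(sum((lx - mx)^2) * sum((ly - my)^2))
}

# Enumerate all k-subsets of the universe to get the exact shuffle-null moments
# of the same-chromosome pair fraction for a group of size k.
exhaustive_xc_null <- function(universe_chrom, k) {
  n <- length(universe_chrom)
  combos <- utils::combn(n, k)
  vals <- apply(combos, 2, function(idx) {
    tab <- table(universe_chrom[idx])
    sum(tab * (tab - 1) / 2) / (k * (k - 1) / 2)
  })
  list(mean = mean(vals), sd = stats::sd(vals), values = vals)
}
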