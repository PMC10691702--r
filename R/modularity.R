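# Supra-modularity matrices and their maximization: build the NL x NL matrix B
# whose normalized within-community sum is the multilayer modularity, maximize
# it with a generalized Louvain engine, iterate to a fixed point, and combine
# stochastic runs by consensus clustering.

#' Build the supra-modularity matrix for a multilayer correlation matrix
#'
#' Intralayer blocks hold `rho_ij - gamma * <rho_ij>` (null expectation from
#' the configuration model, diagonal included), and interlayer blocks are
#' diagonal with the empirical couplings `omega`. The normalization constant is
#' `c_norm = sum_(i,alpha) (sum_j rho_ij + sum_beta omega_i,alpha,beta)`.
#'
#' @param mlc a `multilayer_corr` from [build_multilayer()].
#' @param nulls list of `null_model_layer` fitted to `mlc$rho`, one per layer.
#' @param gamma resolution parameter(s): scalar or per-layer vector, > 0.
#' @return An object of class `supra_modularity` with fields `B`, `c_norm`,
#'   `gamma`, `mode = "correlation"`, `gene_ids`, `layer_labels`, `N`, `L`.
#' @export
build_supra_corr <- function(mlc, nulls, gamma = 1) {
  stopifnot(inherits(mlc, "multilayer_corr"))
  N <- length(mlc$gene_ids); L <- length(mlc$layer_labels)
  if (length(nulls) != L) stop_mlc("need one null model per layer")
  gamma <- rep_len(gamma, L)
  if (any(gamma <= 0)) stop_mlc("gamma must be positive")
  B <- matrix(0, N * L, N * L)
  for (a in seq_len(L)) {
    idx <- (a - 1L) * N + seq_len(N)
    B[idx, idx] <- mlc$rho[[a]] - gamma[a] * nulls[[a]]$null_corr
  }
  for (a in seq_len(L)) for (b in seq_len(L)) {
    if (a == b) next
    ia <- (a - 1L) * N + seq_len(N)
    ib <- (b - 1L) * N + seq_len(N)
    B[cbind(ia, ib)] <- mlc$omega[, a, b]
  }
  c_norm <- sum(vapply(seq_len(L), function(a)
    sum(mlc$rho[[a]]), numeric(1))) + sum(mlc$omega)
  if (c_norm <= 0) stop_mlc("normalization constant c_norm = %.3g <= 0", c_norm)
  structure(
    list(B = B, c_norm = c_norm, gamma = gamma, mode = "correlation",
         gene_ids = mlc$gene_ids, layer_labels = mlc$layer_labels,
         N = N, L = L),
    class = "supra_modularity"
  )
}

#' Build the supra-modularity matrix for a conventional multilayer network
#'
#' Intralayer blocks hold the Newman-Girvan form
#' `A_ij - gamma * k_i k_j / (2 m)` per layer; interlayer blocks are diagonal
#' with `omega`; the normalization constant is `2 mu`, twice the total edge
#' weight including couplings. With one layer and zero couplings this reduces
#' to single-layer modularity.
#'
#' @param net a [multilayer_network()].
#' @param gamma resolution parameter(s), scalar or per-layer.
#' @return A `supra_modularity` with `mode = "network"`.
#' @export
build_supra_network <- function(net, gamma = 1) {
  stopifnot(inherits(net, "multilayer_network"))
  N <- length(net$gene_ids); L <- length(net$layer_labels)
  gamma <- rep_len(gamma, L)
  B <- matrix(0, N * L, N * L)
  two_mu <- 0
  for (a in seq_len(L)) {
    A <- net$adjacency[[a]]
    k <- rowSums(A)
    two_m <- sum(k)
    if (two_m <= 0) stop_mlc("layer %d ('%s') has no edges", a,
                             net$layer_labels[a])
    idx <- (a - 1L) * N + seq_len(N)
    B[idx, idx] <- A - gamma[a] * outer(k, k) / two_m
    two_mu <- two_mu + two_m
  }
  for (a in seq_len(L)) for (b in seq_len(L)) {
    if (a == b) next
    ia <- (a - 1L) * N + seq_len(N)
    ib <- (b - 1L) * N + seq_len(N)
    B[cbind(ia, ib)] <- net$omega[, a, b]
  }
  two_mu <- two_mu + sum(net$omega)
  structure(
    list(B = B, c_norm = two_mu, gamma = gamma, mode = "network",
         gene_ids = net$gene_ids, layer_labels = net$layer_labels,
         N = N, L = L),
    class = "supra_modularity"
  )
}

#' @export
print.supra_modularity <- function(x, ...) {
  cat(sprintf("Supra-modularity matrix (%s mode): %d x %d, gamma = %s, c_norm = %.4g\n",
              x$mode, nrow(x$B), ncol(x$B),
              paste(signif(x$gamma, 4), collapse = "/"), x$c_norm))
  invisible(x)
}

#' Multilayer modularity of a partition
#'
#' `Q = (1/c_norm) * sum over ordered node pairs (including i = j) of
#' B[node1, node2]` restricted to pairs sharing a community: the exact double
#' sum, double-counting (i, j) and (j, i).
#'
#' @param B a `supra_modularity`.
#' @param p a [supra_partition()] covering all N*L nodes.
#' @return numeric Q.
#' @export
modularity_value <- function(B, p) {
  stopifnot(inherits(B, "supra_modularity"), inherits(p, "supra_partition"))
  if (length(p$labels) != nrow(B$B))
    stop_mlc("partition covers %d nodes; B has %d", length(p$labels), nrow(B$B))
  q <- 0
  for (c in unique(p$labels)) {
    idx <- which(p$labels == c)
    q <- q + sum(B$B[idx, idx])
  }
  q / B$c_norm
}

# ---- Louvain engine ---------------------------------------------------------

# One local-moving phase over a (possibly aggregated) modularity matrix.
# Moves a node to the neighboring (or fresh) community with the largest
# strictly positive gain; ties go to the smallest community label. Negative
# entries are first-class, so moving out to a singleton can be a gain.
louvain_phase <- function(B, labels, tol = 1e-12) {
  n <- nrow(B)
  repeat {
    moved <- FALSE
    for (v in sample.int(n)) {
      lv <- labels[v]
      strengths <- rowsum(B[v, ], labels)          # community -> sum of B[v, .]
      comms <- as.integer(rownames(strengths))
      s <- strengths[, 1]
      cur <- s[match(lv, comms)] - B[v, v]         # exclude self
      # candidate gains: join community c (c != lv) or a fresh singleton (0)
      fresh <- if (sum(labels == lv) > 1L)
        min(setdiff(seq_len(n + 1L), comms)) else NA
      cand_comms <- comms[comms != lv]
      cand_gain <- s[match(cand_comms, comms)] - cur
      if (!is.na(fresh)) {
        cand_comms <- c(cand_comms, fresh)
        cand_gain <- c(cand_gain, 0 - cur)
      }
      if (length(cand_comms) == 0L) next
      best <- max(cand_gain)
      if (best > tol) {
        pick <- min(cand_comms[cand_gain >= best - tol / 2])
        labels[v] <- pick
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  labels
}

# Collapse communities into super-nodes, summing B entries (self-loops kept).
# Labels must be 1..k; row/column c of the result corresponds to community c.
aggregate_matrix <- function(B, labels) {
  f <- factor(labels, levels = sort(unique(labels)))
  t(rowsum(t(rowsum(B, f)), f))
}

louvain_engine <- function(B, init = NULL, tol = 1e-12) {
  mapping <- if (is.null(init)) seq_len(nrow(B))
             else canonical_labels(as.integer(init))
  # full multilevel passes, restarted from the refined partition until the
  # node-level sweep is itself a fixed point
  repeat {
    prev <- canonical_labels(mapping)
    mapping <- canonical_labels(louvain_phase(B, mapping, tol))
    Bcur <- aggregate_matrix(B, mapping)
    repeat {
      k <- nrow(Bcur)
      if (k <= 1L) break
      agg <- canonical_labels(louvain_phase(Bcur, seq_len(k), tol))
      if (length(unique(agg)) == k) break  # no merges at this level
      mapping <- agg[mapping]
      Bcur <- aggregate_matrix(Bcur, agg)
    }
    if (identical(canonical_labels(mapping), prev)) break
  }
  canonical_labels(mapping)
}

#' Generalized Louvain maximization of a supra-modularity matrix
#'
#' Greedy local moving with aggregation, applied directly to the (possibly
#' negative-valued) modularity matrix. Stochastic through the random node
#' sweep order; reproducible under `seed`. The returned partition is locally
#' optimal: no single-node move increases Q.
#'
#' @param B a `supra_modularity`.
#' @param seed RNG seed.
#' @param init optional initial labels (length N*L).
#' @return A [supra_partition()].
#' @export
genlouvain <- function(B, seed = NULL, init = NULL) {
  stopifnot(inherits(B, "supra_modularity"))
  labels <- with_seed(seed, louvain_engine(B$B, init = init))
  supra_partition(labels, B$gene_ids, B$layer_labels)
}

#' Iterated generalized Louvain
#'
#' Reruns [genlouvain()] initialized from the previous output until the
#' partition no longer changes between successive rounds (a fixed point) or
#' `max_rounds` is hit. Because local moving only accepts improving moves, the
#' modularity sequence across rounds is non-decreasing.
#'
#' @param B a `supra_modularity`.
#' @param seed RNG seed (fans out per round).
#' @param max_rounds round cap; exceeding it warns and returns the best found.
#' @param init `"singleton"` starts the first round from singletons;
#'   `"random"` from a random label assignment, which diversifies multi-start
#'   searches past local optima that greedy merging from singletons cannot
#'   escape.
#' @return A [supra_partition()] with attributes `Q` (final modularity) and
#'   `rounds`.
#' @export
iterated_genlouvain <- function(B, seed = NULL, max_rounds = 100,
                                init = c("singleton", "random")) {
  init <- match.arg(init)
  first <- if (init == "random") {
    n <- nrow(B$B)
    with_seed(if (is.null(seed)) NULL else derive_seed(seed, "louvain", 0L),
              sample.int(n, n, replace = TRUE))
  } else NULL
  p <- genlouvain(B, seed = seed, init = first)
  q <- modularity_value(B, p)
  rounds <- 1L
  repeat {
    s2 <- if (is.null(seed)) NULL else derive_seed(seed, "louvain", rounds)
    p2 <- genlouvain(B, seed = s2, init = p$labels)
    q2 <- modularity_value(B, p2)
    rounds <- rounds + 1L
    same <- identical(canonical_labels(p2$labels), canonical_labels(p$labels))
    if (q2 >= q) { p <- p2; q <- q2 }
    if (same) break
    if (rounds >= max_rounds) {
      warn_mlc("iterated GenLouvain hit max_rounds = %d before a fixed point",
               max_rounds)
      break
    }
  }
  attr(p, "Q") <- q
  attr(p, "rounds") <- rounds
  p
}

# ---- Consensus clustering ---------------------------------------------------

co_classification <- function(labels) {
  outer(labels, labels, `==`) * 1
}

# Expected co-classification of two distinct nodes under the permutation null
# for one partition: sum_c n_c (n_c - 1) / (n (n - 1)).
permutation_null_agreement <- function(labels) {
  n <- length(labels)
  tab <- table(labels)
  sum(tab * (tab - 1)) / (n * (n - 1))
}

#' Consensus partition of stochastic Louvain runs
#'
#' Builds the co-classification (agreement) matrix of the input partitions,
#' subtracts the permutation-model expected agreement, reclusters the null-
#' adjusted matrix with the Louvain engine, and repeats until the agreement
#' matrix is block-deterministic (all entries 0 or 1).
#'
#' @param partitions list of >= 2 [supra_partition()] over the same node set.
#' @param seed RNG seed.
#' @param n_runs Louvain runs per consensus round (default: number of input
#'   partitions, capped at 100).
#' @param max_rounds convergence cap; exceeded -> error.
#' @return A [supra_partition()].
#' @export
consensus_partition <- function(partitions, seed = NULL, n_runs = NULL,
                                max_rounds = 100) {
  stopifnot(length(partitions) >= 2)
  p1 <- partitions[[1]]
  n <- length(p1$labels)
  if (!all(vapply(partitions, function(p) length(p$labels) == n, logical(1))))
    stop_mlc("all partitions must cover the same node set")
  if (is.null(n_runs)) n_runs <- min(length(partitions), 100L)
  lab_list <- lapply(partitions, `[[`, "labels")
  for (round in seq_len(max_rounds)) {
    A <- Reduce(`+`, lapply(lab_list, co_classification)) / length(lab_list)
    if (all(abs(A) < 1e-9 | abs(A - 1) < 1e-9)) {
      # block-deterministic: read communities off the agreement blocks
      labels <- integer(n)
      next_lab <- 0L
      for (v in seq_len(n)) {
        if (labels[v] == 0L) {
          next_lab <- next_lab + 1L
          labels[A[v, ] > 0.5] <- next_lab
        }
      }
      return(supra_partition(labels, p1$gene_ids, p1$layer_labels))
    }
    enull <- mean(vapply(lab_list, permutation_null_agreement, numeric(1)))
    Bc <- A - enull
    diag(Bc) <- 0
    lab_list <- lapply(seq_len(n_runs), function(r) {
      s <- if (is.null(seed)) NULL else derive_seed(seed, "consensus",
                                                    round * 1000L + r)
      with_seed(s, louvain_engine(Bc))
    })
  }
  stop_mlc("consensus clustering did not converge in %d rounds", max_rounds)
}
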