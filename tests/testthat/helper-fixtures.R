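# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk except files the tests write themselves.

# A supra_modularity object wrapped around an explicit matrix.
make_supra <- function(B, N, L, c_norm = NULL, mode = "network") {
  if (is.null(c_norm)) c_norm <- max(sum(abs(B)), 1)
  structure(
    list(B = B, c_norm = c_norm, gamma = 1, mode = mode,
         gene_ids = paste0("g", seq_len(N)),
         layer_labels = paste0("L", seq_len(L)), N = N, L = L),
    class = "supra_modularity"
  )
}

make_partition <- function(labels, N, L, renumber = FALSE) {
  supra_partition(labels, paste0("g", seq_len(N)), paste0("L", seq_len(L)),
                  renumber = renumber)
}

# Random expression layer with the given dimensions (no planted structure).
random_layer <- function(N = 6, S = 20, tissue = "t1", seed = 1,
                         donors = NULL) {
  set.seed(seed)
  vals <- matrix(stats::rexp(N * S, rate = 0.1), N, S)
  rownames(vals) <- sprintf("G%03d", seq_len(N))
  colnames(vals) <- sprintf("SYN-%04d-%s", seq_len(S), tissue)
  if (is.null(donors)) donors <- sprintf("SYN-%04d", seq_len(S))
  names(donors) <- colnames(vals)
  expression_layer(tissue, vals, donors)
}

# Random valid correlation matrix via a latent factor sample.
random_corr <- function(N, S = 60, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(S * N), S, N) + rnorm(S) %o% runif(N, 0, 1.2)
  r <- stats::cor(X)
  dimnames(r) <- list(paste0("g", seq_len(N)), paste0("g", seq_len(N)))
  r
}

# Small random multilayer correlation object (valid rho + omega) for
# modularity tests.
random_mlc <- function(N = 3, L = 2, S = 40, seed = 1) {
  set.seed(seed)
  rho <- lapply(seq_len(L), function(a) random_corr(N, S, seed = seed + a))
  omega <- array(0, dim = c(N, L, L))
  if (L > 1) {
    for (a in seq_len(L - 1)) for (b in (a + 1):L) {
      w <- runif(N, 0, 0.8)
      omega[, a, b] <- w
      omega[, b, a] <- w
    }
  }
  Ssz <- rep(S, L)
  structure(
    list(layer_labels = paste0("L", seq_len(L)),
         gene_ids = paste0("g", seq_len(N)), rho = rho, omega = omega,
         sample_counts = list(per_layer = stats::setNames(Ssz,
                                paste0("L", seq_len(L))),
                              common_donors = matrix(S, L, L))),
    class = "multilayer_corr"
  )
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Simple annotation covering a set of genes deterministically.
grid_annotation <- function(genes, chroms, starts, width = 1e4) {
  gene_annotation(data.frame(
    gene_id = genes, chrom = as.character(chroms),
    start = starts, end = starts + width - 1, stringsAsFactors = FALSE))
}
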