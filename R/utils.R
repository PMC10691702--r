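# Internal helpers shared across modules.

#' Evaluate code with a temporarily fixed RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the generator, runs `code`, and
#' restores the previous state so library calls never clobber user randomness.
#' A `NULL` seed runs the code with the ambient RNG untouched.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic fan-out of one user seed into per-stage seeds, so stages can be
# rerun independently with identical results. Kept below 2^31.
derive_seed <- function(seed, stage, i = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- (as.double(seed) * 48271 + match(stage, c(
    "sweep", "consensus", "louvain", "null", "sample", "localize", "synth",
    "run", "misc"
  ), nomatch = 9L) * 2654435 + as.double(i) * 97561) %% 2147483629
  as.integer(h) + 1L
}

# FNV-1a hash of a character scalar; used only to fingerprint configs in run
# manifests.
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

stop_mlc <- function(...) stop(sprintf(...), call. = FALSE)
warn_mlc <- function(...) warning(sprintf(...), call. = FALSE)

# Renumber arbitrary community labels to consecutive integers 1..K, ordered by
# decreasing community size; ties broken by first appearance.
renumber_labels <- function(labels) {
  tab <- table(labels)
  first <- tapply(seq_along(labels), labels, min)
  ord <- order(-as.vector(tab), as.vector(first[names(tab)]))
  map <- integer(length(tab))
  map[ord] <- seq_along(ord)
  names(map) <- names(tab)
  unname(map[as.character(labels)])
}

#' Supra-partition constructor
#'
#' A supra partition assigns every (gene, layer) node of a multilayer object to
#' one community. Node order is gene-major within layer blocks: node
#' `(i, alpha)` sits at index `(alpha - 1) * N + i`.
#'
#' @param labels integer vector of length `N * L` of community labels.
#' @param gene_ids character vector of N gene identifiers.
#' @param layer_labels character vector of L layer (tissue) labels.
#' @param renumber renumber labels to 1..K by decreasing community size.
#' @return An object of class `supra_partition`.
#' @export
supra_partition <- function(labels, gene_ids, layer_labels, renumber = TRUE) {
  N <- length(gene_ids)
  L <- length(layer_labels)
  if (length(labels) != N * L)
    stop_mlc("labels has length %d; expected N*L = %d", length(labels), N * L)
  if (anyNA(labels)) stop_mlc("partition labels must not contain NA")
  lab <- if (renumber) renumber_labels(labels) else as.integer(labels)
  structure(
    list(labels = lab, gene_ids = gene_ids, layer_labels = layer_labels,
         N = N, L = L),
    class = "supra_partition"
  )
}

#' @export
as.data.frame.supra_partition <- function(x, ...) {
  data.frame(
    gene_id = rep(x$gene_ids, times = x$L),
    layer_label = rep(x$layer_labels, each = x$N),
    community_label = x$labels,
    stringsAsFactors = FALSE
  )
}

#' @export
print.supra_partition <- function(x, ...) {
  k <- length(unique(x$labels))
  cat(sprintf("Supra partition: %d genes x %d layers, %d communities\n",
              x$N, x$L, k))
  print(utils::head(sort(table(Community = x$labels), decreasing = TRUE), 10))
  invisible(x)
}

# Node indices (into the N*L supra ordering) of one community.
community_nodes <- function(p, community) {
  idx <- which(p$labels == community)
  if (length(idx) == 0L) stop_mlc("community %s not present in partition",
                                  as.character(community))
  idx
}

node_gene <- function(p, idx) ((idx - 1L) %% p$N) + 1L
node_layer <- function(p, idx) ((idx - 1L) %/% p$N) + 1L

# Canonical form for comparing partitions up to relabeling.
canonical_labels <- function(labels) as.integer(factor(labels, levels = unique(labels)))
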