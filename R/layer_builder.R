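# Gene selection, log transform, per-layer Pearson correlation, and empirical
# interlayer couplings over shared donors: assembly of the multilayer
# correlation object.

#' Select the most variable genes across layers
#'
#' For each layer, ranks genes by the variance of raw TPM across that layer's
#' samples and keeps the top `k`; returns the union over layers, sorted by gene
#' ID. Ties are broken by gene ID (stable), so selection is deterministic.
#'
#' @param layers list of [expression_layer()] objects sharing one gene universe.
#' @param k number of top-variance genes per layer.
#' @return Character vector of selected gene IDs (sorted); the per-layer top-k
#'   sets are attached as attribute `"per_layer"`.
#' @export
select_genes <- function(layers, k) {
  stopifnot(length(layers) >= 1, k >= 1)
  universe <- layers[[1]]$gene_ids
  for (ly in layers) {
    if (!setequal(ly$gene_ids, universe))
      stop_mlc("layer '%s' does not contain the full gene universe",
               ly$tissue_label)
  }
  if (k > length(universe))
    stop_mlc("k = %d exceeds the %d-gene universe", k, length(universe))
  per_layer <- lapply(layers, function(ly) {
    v <- apply(ly$values, 1, stats::var)
    ord <- order(-v, ly$gene_ids)
    ly$gene_ids[ord[seq_len(k)]]
  })
  names(per_layer) <- vapply(layers, `[[`, character(1), "tissue_label")
  sel <- sort(unique(unlist(per_layer)))
  attr(sel, "per_layer") <- per_layer
  sel
}

#' Overlap statistics between two top-gene sets
#'
#' Jaccard index of the two sets and the average 1-based rank (by mean
#' expression) of the variance-selected genes, the two descriptors used to
#' check that highly variable genes are also highly expressed.
#'
#' @param top_by_mean,top_by_var character vectors (non-empty gene sets).
#' @param ranks_by_mean named numeric vector of 1-based ranks by mean TPM
#'   covering `top_by_var`.
#' @return list with `jaccard` and `average_rank`.
#' @export
overlap_stats <- function(top_by_mean, top_by_var, ranks_by_mean) {
  if (length(top_by_mean) == 0 || length(top_by_var) == 0)
    stop_mlc("gene sets must be non-empty")
  missing <- setdiff(top_by_var, names(ranks_by_mean))
  if (length(missing) > 0)
    stop_mlc("gene '%s' absent from rank mapping", missing[1])
  jac <- length(intersect(top_by_mean, top_by_var)) /
    length(union(top_by_mean, top_by_var))
  list(jaccard = jac,
       average_rank = mean(ranks_by_mean[top_by_var]))
}

#' Log-transform TPM values
#'
#' Elementwise natural `log(x + 1)`, so a TPM of 0 maps to 0. The base is
#' irrelevant downstream: Pearson correlation is invariant under positive
#' affine rescaling.
#'
#' @param values non-negative numeric matrix or vector.
#' @return transformed values of the same shape.
#' @export
log_transform <- function(values) {
  if (any(values < 0)) stop_mlc("log_transform requires non-negative input")
  log1p(values)
}

#' Within-layer co-expression matrix
#'
#' Pearson correlation of `log(TPM + 1)` between every gene pair across the
#' layer's samples.
#'
#' @param layer an [expression_layer()].
#' @param genes ordered gene IDs to include.
#' @return N x N symmetric correlation matrix with unit diagonal.
#' @export
layer_correlation <- function(layer, genes) {
  stopifnot(inherits(layer, "expression_layer"))
  missing <- setdiff(genes, layer$gene_ids)
  if (length(missing) > 0)
    stop_mlc("gene '%s' not present in layer '%s'", missing[1],
             layer$tissue_label)
  if (length(layer$sample_ids) < 3)
    stop_mlc("layer '%s' has fewer than 3 samples", layer$tissue_label)
  lx <- log_transform(layer$values[genes, , drop = FALSE])
  v <- apply(lx, 1, stats::var)
  if (any(v == 0))
    stop_mlc("gene '%s' has zero variance of log(TPM + 1) in layer '%s'",
             genes[which(v == 0)[1]], layer$tissue_label)
  r <- stats::cor(t(lx))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(genes, genes)
  r
}

# Per-donor log1p expression for the selected genes: averages log1p(TPM) over
# a donor's samples when a donor contributed more than one sample to a layer.
donor_log_expression <- function(layer, genes) {
  lx <- log_transform(layer$values[genes, , drop = FALSE])
  donors <- layer$donor_ids
  if (anyDuplicated(donors)) {
    sums <- rowsum(t(lx), group = donors)   # donors x genes, sorted by donor
    counts <- as.vector(table(donors))      # table() sorts identically
    lx <- t(sums / counts)
  } else {
    colnames(lx) <- donors
  }
  lx
}

#' Empirical interlayer couplings
#'
#' For every gene i and layer pair (alpha, beta), the Pearson correlation of
#' the gene's `log(TPM + 1)` across the donors common to the two layers,
#' clipped below at zero (modularity maximization assumes non-negative
#' interlayer weights). Pairs with fewer than `min_common_donors` shared donors
#' get coupling 0 with a warning.
#'
#' @param layers list of [expression_layer()].
#' @param genes ordered gene IDs.
#' @param min_common_donors floor below which the pair's couplings are zeroed.
#' @return N x L x L array, symmetric in the layer pair, zero on the diagonal.
#' @export
interlayer_couplings <- function(layers, genes, min_common_donors = 3) {
  N <- length(genes); L <- length(layers)
  omega <- array(0, dim = c(N, L, L),
                 dimnames = list(genes, NULL, NULL))
  if (L < 2) return(omega)
  expr <- lapply(layers, donor_log_expression, genes = genes)
  for (a in seq_len(L - 1)) {
    for (b in (a + 1):L) {
      common <- intersect(colnames(expr[[a]]), colnames(expr[[b]]))
      if (length(common) < min_common_donors) {
        warn_mlc(
          "layers '%s' and '%s' share %d donor(s) (< %d); couplings set to 0",
          layers[[a]]$tissue_label, layers[[b]]$tissue_label,
          length(common), min_common_donors)
        next
      }
      xa <- expr[[a]][, common, drop = FALSE]
      xb <- expr[[b]][, common, drop = FALSE]
      for (i in seq_len(N)) {
        sa <- stats::sd(xa[i, ]); sb <- stats::sd(xb[i, ])
        w <- if (sa == 0 || sb == 0) 0 else stats::cor(xa[i, ], xb[i, ])
        w <- max(w, 0)
        omega[i, a, b] <- w
        omega[i, b, a] <- w
      }
    }
  }
  omega
}

#' Assemble a multilayer correlation object
#'
#' Composes gene selection, the log transform, per-layer Pearson correlation
#' and the empirical interlayer couplings into the central input object of the
#' method.
#'
#' @param layers list of [expression_layer()] (one per tissue).
#' @param k per-layer top-variance gene count (ignored when `genes` given).
#' @param genes explicit ordered gene list overriding selection.
#' @param drop_constant drop genes with zero log-expression variance in any
#'   layer instead of erroring.
#' @param min_common_donors see [interlayer_couplings()].
#' @return An object of class `multilayer_corr` with fields `layer_labels`,
#'   `gene_ids`, `rho` (list of L correlation matrices), `omega`
#'   (N x L x L coupling array) and `sample_counts`.
#' @export
build_multilayer <- function(layers, k = 75, genes = NULL,
                             drop_constant = FALSE, min_common_donors = 3) {
  stopifnot(length(layers) >= 1)
  labels <- vapply(layers, `[[`, character(1), "tissue_label")
  if (anyDuplicated(labels)) stop_mlc("duplicate tissue labels")
  if (is.null(genes)) genes <- select_genes(layers, k)
  genes <- as.character(genes)
  if (drop_constant) {
    keep <- genes
    for (ly in layers) {
      lx <- log_transform(ly$values[genes, , drop = FALSE])
      v <- apply(lx, 1, stats::var)
      keep <- setdiff(keep, genes[v == 0])
    }
    if (length(keep) < length(genes))
      warn_mlc("dropped %d constant gene(s)", length(genes) - length(keep))
    genes <- keep
  }
  rho <- lapply(layers, layer_correlation, genes = genes)
  names(rho) <- labels
  omega <- interlayer_couplings(layers, genes,
                                min_common_donors = min_common_donors)
  S <- vapply(layers, function(ly) length(ly$sample_ids), integer(1))
  names(S) <- labels
  donors <- lapply(layers, function(ly) unique(ly$donor_ids))
  common <- matrix(0L, length(layers), length(layers),
                   dimnames = list(labels, labels))
  for (a in seq_along(layers)) for (b in seq_along(layers))
    common[a, b] <- length(intersect(donors[[a]], donors[[b]]))
  structure(
    list(layer_labels = labels, gene_ids = genes, rho = rho, omega = omega,
         sample_counts = list(per_layer = S, common_donors = common)),
    class = "multilayer_corr"
  )
}

#' @export
print.multilayer_corr <- function(x, ...) {
  cat(sprintf("Multilayer correlation: %d genes x %d layers (%s)\n",
              length(x$gene_ids), length(x$layer_labels),
              paste(x$layer_labels, collapse = ", ")))
  cat(sprintf("samples per layer: %s\n",
              paste(x$sample_counts$per_layer, collapse = ", ")))
  invisible(x)
}

#' Multilayer network constructor (conventional-adjacency mode)
#'
#' Container for precomputed multilayer adjacency matrices (for example
#' graphical-lasso networks) with the same interlayer coupling tensor as the
#' correlation mode. Intralayer diagonals must be zero and all weights
#' non-negative.
#'
#' @param adjacency list of L symmetric N x N matrices with zero diagonal.
#' @param omega N x L x L coupling array (or NULL for no couplings).
#' @param gene_ids,layer_labels identifiers.
#' @return An object of class `multilayer_network`.
#' @export
multilayer_network <- function(adjacency, omega = NULL, gene_ids = NULL,
                               layer_labels = NULL) {
  L <- length(adjacency)
  N <- nrow(adjacency[[1]])
  if (is.null(gene_ids)) gene_ids <- rownames(adjacency[[1]])
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(N))
  if (is.null(layer_labels)) layer_labels <- paste0("layer", seq_len(L))
  if (is.null(omega)) omega <- array(0, dim = c(N, L, L))
  for (a in seq_len(L)) {
    A <- adjacency[[a]]
    if (nrow(A) != N || ncol(A) != N) stop_mlc("layer %d has wrong size", a)
    if (max(abs(A - t(A))) > 1e-12) stop_mlc("layer %d is not symmetric", a)
    if (any(diag(A) != 0)) stop_mlc("layer %d has nonzero diagonal", a)
    if (any(A < 0)) stop_mlc("layer %d has negative weights", a)
  }
  if (any(omega < 0)) stop_mlc("interlayer couplings must be non-negative")
  structure(
    list(layer_labels = layer_labels, gene_ids = gene_ids,
         adjacency = adjacency, omega = omega),
    class = "multilayer_network"
  )
}
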