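# Specialist fraction and specialist/generalist classification of multilayer
# communities, plus the generalist gene filter used by the genomic analyses.

#' Specialist profile of a community
#'
#' A gene is unique to tissue alpha within a community when node (gene, alpha)
#' is in the community and no other layer's copy of the gene is. The specialist
#' tissue is the tissue with the most unique genes, and the specialist fraction
#' is that count divided by the total number of nodes in the community. A
#' community lying within one layer has fraction 1; a community in which every
#' gene appears in at least two tissues has fraction 0 (specialist tissue
#' "N/A").
#'
#' @param p a [supra_partition()].
#' @param community community label.
#' @return list of class `specialist_profile` with fields `community`,
#'   `n_nodes`, `n_genes`, `unique_counts` (per tissue), `specialist_tissue`,
#'   `specialist_fraction`, `tie`.
#' @export
specialist_profile <- function(p, community) {
  idx <- community_nodes(p, community)
  genes <- node_gene(p, idx)
  layers <- node_layer(p, idx)
  n_nodes <- length(idx)
  layers_per_gene <- split(layers, genes)
  uniq_layer <- vapply(layers_per_gene, function(ls)
    if (length(ls) == 1L) ls[1] else NA_integer_, integer(1))
  counts <- integer(p$L)
  for (al in seq_len(p$L)) counts[al] <- sum(uniq_layer == al, na.rm = TRUE)
  names(counts) <- p$layer_labels
  best <- max(counts)
  if (best == 0L) {
    tissue <- "N/A"; tie <- FALSE
  } else {
    hits <- which(counts == best)
    # tie: lexicographically first tissue, flagged
    tissue <- p$layer_labels[hits[order(p$layer_labels[hits])][1]]
    tie <- length(hits) > 1L
  }
  structure(
    list(community = community, n_nodes = n_nodes,
         n_genes = length(layers_per_gene), unique_counts = counts,
         specialist_tissue = tissue,
         specialist_fraction = best / n_nodes, tie = tie),
    class = "specialist_profile"
  )
}

#' @export
print.specialist_profile <- function(x, ...) {
  cat(sprintf(
    "Community %s: %d nodes, %d genes, specialist fraction %.3f (%s)%s\n",
    as.character(x$community), x$n_nodes, x$n_genes, x$specialist_fraction,
    x$specialist_tissue, if (x$tie) " [tie]" else ""))
  invisible(x)
}

#' Specialist profiles for every community of a partition
#'
#' @param p a [supra_partition()].
#' @return data frame with one row per community: community, n_nodes, n_genes,
#'   n_specialist_genes, specialist_fraction, specialist_tissue, tie.
#' @export
specialist_table <- function(p) {
  comms <- sort(unique(p$labels))
  do.call(rbind, lapply(comms, function(cc) {
    pr <- specialist_profile(p, cc)
    data.frame(community = cc, n_nodes = pr$n_nodes, n_genes = pr$n_genes,
               n_specialist_genes = max(pr$unique_counts),
               specialist_fraction = pr$specialist_fraction,
               specialist_tissue = pr$specialist_tissue, tie = pr$tie,
               stringsAsFactors = FALSE)
  }))
}

#' Classify communities as specialist or generalist
#'
#' Strictly above the threshold is specialist; at or below is generalist.
#'
#' @param profiles data frame from [specialist_table()] or a list of
#'   [specialist_profile()] objects.
#' @param threshold classification threshold (default 0.5).
#' @return character vector of labels, one per profile.
#' @export
classify_communities <- function(profiles, threshold = 0.5) {
  frac <- if (is.data.frame(profiles)) profiles$specialist_fraction
          else vapply(profiles, `[[`, numeric(1), "specialist_fraction")
  ifelse(frac > threshold, "specialist", "generalist")
}

#' Genes of a generalist community present in several tissues
#'
#' Restricts a (generalist) community to the genes whose node appears in at
#' least `min_layers` distinct layers of that community — the gene set the
#' downstream genomic analyses use, so that each gene belongs to at most one
#' generalist community.
#'
#' @param p a [supra_partition()].
#' @param community community label.
#' @param min_layers minimum number of layers (default 3).
#' @return character vector of gene IDs.
#' @export
generalist_gene_filter <- function(p, community, min_layers = 3) {
  idx <- community_nodes(p, community)
  genes <- node_gene(p, idx)
  layers <- node_layer(p, idx)
  n_layers <- vapply(split(layers, genes), function(ls)
    length(unique(ls)), integer(1))
  p$gene_ids[as.integer(names(n_layers)[n_layers >= min_layers])]
}
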