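# Shared-eQTL screen: gene pairs whose co-expression exceeds a threshold and
# whose associated SNP sets intersect.

#' Co-expressed gene pairs sharing an associated eQTL SNP
#'
#' Scans a layer's correlation matrix for unordered gene pairs with
#' `rho > threshold` (strict) and reports those whose eQTL SNP sets intersect,
#' with the shared SNPs. Genes absent from the eQTL table simply have no
#' associated SNPs. The p-value column of the table is carried along in SNP
#' sets but never filtered here (the input is expected to be pre-filtered for
#' significance).
#'
#' @param rho_layer N x N correlation matrix with gene IDs as dimnames.
#' @param eqtl an `eqtl_table` from [read_eqtl()] (columns snp_id, gene_id,
#'   p_value).
#' @param threshold co-expression threshold, strict (default 0.5).
#' @return data frame with columns gene_i, gene_j (gene_i < gene_j), rho,
#'   n_shared_snps, shared_snps (comma-joined).
#' @export
shared_eqtl_pairs <- function(rho_layer, eqtl, threshold = 0.5) {
  genes <- rownames(rho_layer)
  if (is.null(genes)) stop_mlc("rho_layer needs gene IDs as dimnames")
  snp_sets <- split(eqtl$snp_id, eqtl$gene_id)
  hits <- which(upper.tri(rho_layer) & rho_layer > threshold, arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(hits)), function(h) {
    gi <- genes[hits[h, 1]]; gj <- genes[hits[h, 2]]
    shared <- intersect(snp_sets[[gi]], snp_sets[[gj]])
    if (length(shared) == 0) return(NULL)
    ord <- sort(c(gi, gj))
    data.frame(gene_i = ord[1], gene_j = ord[2],
               rho = rho_layer[hits[h, 1], hits[h, 2]],
               n_shared_snps = length(shared),
               shared_snps = paste(sort(shared), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(gene_i = character(0), gene_j = character(0),
                      rho = numeric(0), n_shared_snps = integer(0),
                      shared_snps = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(-out$rho), , drop = FALSE]
}
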