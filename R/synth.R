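# Synthetic multilayer expression generator with planted community structure.
# Every other module is testable against the known ground truth this module
# produces: block-factor co-expression within layers, donor-linked factors
# across layers (which create interlayer couplings), clustered gene
# coordinates, and planted shared-eQTL pairs.
#
# Factor model in log space: for gene g of block b, donor d, layer a,
#   log(TPM + 1) = mu_g + loading * f[b, d] + noise_sd * eps,
# so the within-block (and, for shared donors, cross-layer) correlation is
# loading^2 / (loading^2 + noise_sd^2).

#' Planted multilayer design
#'
#' Describes the study conditions of a synthetic data set: layer/gene/sample
#' counts, donor sharing, per-(gene, layer) block assignment (0 = background
#' noise), factor loading and noise scale, the expression marginal, and the
#' annotation plan. The default is a two-layer design with one generalist
#' block (present in both layers, factors linked through shared donors) and
#' one specialist block (one layer only), 500 samples per layer.
#'
#' @param L layers; @param N genes; @param S samples per layer (scalar or
#'   length-L).
#' @param donor_shared_frac fraction of donors present in every layer.
#' @param blocks N x L integer matrix of block assignments (0 = background);
#'   `NULL` builds the default generalist + specialist layout from
#'   `n_generalist`/`n_specialist`.
#' @param n_generalist,n_specialist sizes of the default blocks.
#' @param target_rho within-block correlation the loading is solved for.
#' @param noise_sd noise scale in log space.
#' @param marginal `"lognormal"` (default) or `"negative-binomial"`.
#' @param nb_size negative-binomial dispersion (size) when that marginal is
#'   used.
#' @param baseline_range range of per-gene baseline log1p expression.
#' @param chrom_size chromosome length in bp for the annotation plan.
#' @param gene_length_range range of gene lengths in bp.
#' @param clusters list of planted coordinate clusters, each
#'   `list(genes=, chrom=, start=, width=)`.
#' @param seed default seed the generators fall back to.
#' @return An object of class `planted_design`.
#' @export
planted_design <- function(L = 2, N = 80, S = 500, donor_shared_frac = 0.8,
                           blocks = NULL, n_generalist = 6,
                           n_specialist = 6, target_rho = 0.85,
                           noise_sd = 1, marginal = c("lognormal",
                                                      "negative-binomial"),
                           nb_size = 10, baseline_range = c(2, 6),
                           chrom_size = 1e8,
                           gene_length_range = c(1e4, 1e5),
                           clusters = list(), seed = 1L) {
  marginal <- match.arg(marginal)
  S <- rep_len(S, L)
  if (is.null(blocks)) {
    if (n_generalist + n_specialist > N)
      stop_mlc("blocks need %d genes but N = %d",
               n_generalist + n_specialist, N)
    blocks <- matrix(0L, N, L)
    if (n_generalist > 0) blocks[seq_len(n_generalist), ] <- 1L
    if (n_specialist > 0)
      blocks[n_generalist + seq_len(n_specialist), 1] <- 2L
  }
  if (nrow(blocks) != N || ncol(blocks) != L)
    stop_mlc("blocks must be an N x L matrix")
  if (target_rho < 0 || target_rho >= 1)
    stop_mlc("target_rho must lie in [0, 1)")
  loading <- sqrt(target_rho / (1 - target_rho)) * noise_sd
  structure(
    list(L = L, N = N, S = S, donor_shared_frac = donor_shared_frac,
         blocks = blocks, loading = loading, target_rho = target_rho,
         noise_sd = noise_sd, marginal = marginal, nb_size = nb_size,
         baseline_range = baseline_range,
         gene_ids = sprintf("G%03d", seq_len(N)),
         layer_labels = paste0("tissue", seq_len(L)),
         chrom_size = chrom_size, gene_length_range = gene_length_range,
         clusters = clusters, seed = seed),
    class = "planted_design"
  )
}

#' Ground-truth node labels of a planted design
#'
#' Community labels for the (gene, layer) nodes carrying planted blocks;
#' background nodes get label 0.
#'
#' @param design a [planted_design()].
#' @return integer vector of length N*L (gene-major within layer blocks).
#' @export
planted_truth <- function(design) {
  as.integer(design$blocks)
}

#' Generate expression layers from a planted design
#'
#' @param design a [planted_design()].
#' @param seed RNG seed; defaults to the design's.
#' @return list of [expression_layer()], one per layer.
#' @export
generate_expression <- function(design, seed = NULL) {
  if (is.null(seed)) seed <- design$seed
  d <- design
  with_seed(seed, {
    n_shared <- round(d$donor_shared_frac * min(d$S))
    shared <- sprintf("SYN-S%04d", seq_len(n_shared))
    donors <- lapply(seq_len(d$L), function(a) {
      own <- d$S[a] - n_shared
      c(shared, if (own > 0) sprintf("SYN-P%d%04d", a, seq_len(own)))
    })
    all_donors <- unique(unlist(donors))
    n_blocks <- max(d$blocks)
    mu <- stats::runif(d$N, d$baseline_range[1], d$baseline_range[2])
    f <- if (n_blocks > 0)
      matrix(stats::rnorm(n_blocks * length(all_donors)),
             nrow = n_blocks, ncol = length(all_donors),
             dimnames = list(NULL, all_donors)) else NULL
    lapply(seq_len(d$L), function(a) {
      dn <- donors[[a]]
      z <- matrix(mu, d$N, d$S[a]) +
        d$noise_sd * matrix(stats::rnorm(d$N * d$S[a]), d$N)
      for (g in seq_len(d$N)) {
        b <- d$blocks[g, a]
        if (b > 0) z[g, ] <- z[g, ] + d$loading * f[b, dn]
      }
      z <- pmax(z, 0)
      tpm <- expm1(z)
      if (d$marginal == "negative-binomial") {
        tpm <- matrix(stats::rnbinom(length(tpm), mu = tpm, size = d$nb_size),
                      nrow = d$N)
      }
      rownames(tpm) <- d$gene_ids
      colnames(tpm) <- paste0(dn, sprintf("-%02d", a))
      names(dn) <- colnames(tpm)
      expression_layer(d$layer_labels[a], tpm, dn)
    })
  })
}

#' Generate a gene annotation from a planted design
#'
#' Genes named in a planted cluster are placed within the stated bp window on
#' the stated chromosome; all other genes are placed uniformly at random
#' across chromosomes 1-22. Gene lengths are uniform on the design's
#' `gene_length_range` (default 10-100 kb).
#'
#' @param design a [planted_design()].
#' @param seed RNG seed; defaults to the design's.
#' @return a `gene_annotation`.
#' @export
generate_annotation <- function(design, seed = NULL) {
  if (is.null(seed)) seed <- design$seed
  d <- design
  with_seed(seed, {
    chrom <- sample(as.character(1:22), d$N, replace = TRUE)
    len <- round(stats::runif(d$N, d$gene_length_range[1],
                               d$gene_length_range[2]))
    start <- round(stats::runif(d$N, 1, d$chrom_size - max(len)))
    names(chrom) <- names(start) <- names(len) <- d$gene_ids
    for (cl in d$clusters) {
      g <- cl$genes
      if (!all(g %in% d$gene_ids)) stop_mlc("cluster names unknown gene(s)")
      glen <- len[g]
      if (cl$width < sum(glen))
        stop_mlc("cluster window (%g bp) smaller than its genes (%g bp)",
                 cl$width, sum(glen))
      chrom[g] <- as.character(cl$chrom)
      # non-overlapping placement inside the window
      slack <- cl$width - sum(glen)
      gaps <- diff(c(0, sort(stats::runif(length(g), 0, slack))))
      pos <- cl$start
      for (t in seq_along(g)) {
        pos <- pos + gaps[t]
        start[g[t]] <- round(pos)
        pos <- pos + glen[g[t]]
      }
    }
    gene_annotation(data.frame(
      gene_id = d$gene_ids, chrom = unname(chrom),
      start = unname(start), end = unname(start + len - 1),
      stringsAsFactors = FALSE))
  })
}

#' Generate an eQTL table from a planted design
#'
#' Every gene receives a few background SNPs of its own; each designated pair
#' additionally shares planted SNPs.
#'
#' @param design a [planted_design()].
#' @param shared_pairs data frame with columns `gene_i`, `gene_j` and
#'   optionally `n_shared` (default 1 planted shared SNP per pair).
#' @param mean_private_snps Poisson mean of per-gene private SNPs.
#' @param seed RNG seed; defaults to the design's.
#' @return an `eqtl_table`.
#' @export
generate_eqtl <- function(design, shared_pairs = NULL, mean_private_snps = 2,
                          seed = NULL) {
  if (is.null(seed)) seed <- design$seed
  d <- design
  with_seed(seed, {
    rows <- list()
    snp_counter <- 0L
    new_snp <- function() {
      snp_counter <<- snp_counter + 1L
      sprintf("rs%06d", snp_counter)
    }
    for (g in d$gene_ids) {
      k <- stats::rpois(1, mean_private_snps)
      for (t in seq_len(k))
        rows[[length(rows) + 1L]] <- data.frame(
          snp_id = new_snp(), gene_id = g,
          p_value = stats::runif(1, 1e-8, 1e-4))
    }
    if (!is.null(shared_pairs)) {
      for (r in seq_len(nrow(shared_pairs))) {
        ns <- if ("n_shared" %in% names(shared_pairs))
          shared_pairs$n_shared[r] else 1L
        for (t in seq_len(ns)) {
          s <- new_snp()
          for (g in c(shared_pairs$gene_i[r], shared_pairs$gene_j[r]))
            rows[[length(rows) + 1L]] <- data.frame(
              snp_id = s, gene_id = g,
              p_value = stats::runif(1, 1e-8, 1e-4))
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("eqtl_table", "data.frame")
    out
  })
}
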