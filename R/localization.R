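# Tests of physical clustering of a gene group on chromosomes: same-chromosome
# pair fraction, average base-pair distance between same-chromosome pairs, and
# per-chromosome average distances, each compared with label-shuffling nulls
# drawn from the analyzed gene universe, with Bonferroni correction across
# chromosomes within a group.

#' Fraction of gene pairs on the same chromosome
#'
#' @param genes character vector (n >= 2), all annotated.
#' @param annot a `gene_annotation`.
#' @return exact fraction in [0, 1]: same-chromosome pairs / (n(n-1)/2).
#' @export
same_chrom_fraction <- function(genes, annot) {
  genes <- unique(genes)
  n <- length(genes)
  if (n < 2) stop_mlc("need at least two genes")
  chrom <- annot_chrom(annot, genes)
  tab <- table(chrom)
  sum(tab * (tab - 1) / 2) / (n * (n - 1) / 2)
}

annot_chrom <- function(annot, genes) {
  hit <- match(genes, annot$gene_id)
  if (anyNA(hit)) stop_mlc("gene '%s' is not annotated", genes[which(is.na(hit))[1]])
  annot$chrom[hit]
}

#' Base-pair distance between two genes on the same chromosome
#'
#' The gap from the earlier gene's end to the later gene's start. Overlapping
#' genes get distance 0 with attribute `overlap = TRUE` (the gap would be
#' negative and a physical distance must be non-negative).
#'
#' @param i,j gene IDs.
#' @param annot a `gene_annotation`.
#' @return non-negative distance in bp.
#' @export
gene_distance <- function(i, j, annot) {
  a <- annot[match(i, annot$gene_id), ]
  b <- annot[match(j, annot$gene_id), ]
  if (anyNA(a$gene_id) || anyNA(b$gene_id))
    stop_mlc("gene '%s' is not annotated", if (anyNA(a$gene_id)) i else j)
  if (a$chrom != b$chrom)
    stop_mlc("genes '%s' and '%s' are on different chromosomes", i, j)
  if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
  d <- b$start - a$end
  if (d < 0) structure(0, overlap = TRUE) else structure(d, overlap = FALSE)
}

# Vectorized pairwise distances of genes on one chromosome (clamped at 0).
chrom_pair_distances <- function(genes, annot) {
  hit <- match(genes, annot$gene_id)
  st <- annot$start[hit]; en <- annot$end[hit]
  n <- length(genes)
  pr <- utils::combn(n, 2)
  a <- pr[1, ]; b <- pr[2, ]
  swap <- st[a] > st[b]
  lo_end <- ifelse(swap, en[b], en[a])
  hi_start <- ifelse(swap, st[a], st[b])
  pmax(hi_start - lo_end, 0)
}

# Average distance over all same-chromosome pairs of a gene group; NA when no
# chromosome holds two group genes.
average_pair_distance <- function(genes, annot) {
  chrom <- annot_chrom(annot, genes)
  tot <- 0; npairs <- 0
  for (k in unique(chrom)) {
    g <- genes[chrom == k]
    if (length(g) < 2) next
    d <- chrom_pair_distances(g, annot)
    tot <- tot + sum(d)
    npairs <- npairs + length(d)
  }
  if (npairs == 0) return(NA_real_)
  tot / npairs
}

zscore_from_null <- function(obs, nulls) {
  mu <- mean(nulls); sdev <- stats::sd(nulls)
  if (!is.finite(sdev) || sdev == 0) return(NA_real_)
  (obs - mu) / sdev
}

emp_pvalue <- function(obs, nulls, side) {
  n <- length(nulls)
  hits <- if (side == "greater") sum(nulls >= obs) else sum(nulls <= obs)
  (1 + hits) / (1 + n)
}

#' Randomization tests of chromosomal localization for a gene group
#'
#' Three statistics against shuffling nulls drawn from the analyzed gene
#' universe:
#' * `x_c`, the same-chromosome pair fraction, against uniformly reshuffled
#'   gene-to-chromosome assignments of the universe (clustering gives z > 0);
#' * `d_c`, the average bp distance over same-chromosome pairs, against groups
#'   resampled per chromosome (`n_k` genes drawn uniformly from the universe's
#'   genes on chromosome k, for every k with `n_k >= 2`; clustering gives
#'   z < 0);
#' * per-chromosome average distances with the same resampling control,
#'   Bonferroni-corrected within the group over chromosomes carrying at least
#'   `min_family_genes` group genes.
#'
#' Empirical one-sided p-values (toward clustering) accompany each Z score.
#'
#' @param genes gene group (subset of `universe`).
#' @param annot a `gene_annotation` covering the universe.
#' @param universe the analyzed gene universe the controls are drawn from.
#' @param n_rand number of randomizations (default 100).
#' @param seed RNG seed.
#' @param alpha significance level for the Bonferroni flags.
#' @param min_family_genes minimum group genes on a chromosome for membership
#'   in the multiple-testing family (default 3).
#' @return An object of class `localization_result`.
#' @export
localization_test <- function(genes, annot, universe, n_rand = 100,
                              seed = NULL, alpha = 0.05,
                              min_family_genes = 3) {
  genes <- unique(genes)
  if (!all(genes %in% universe))
    stop_mlc("gene group must be a subset of the universe")
  n <- length(genes)
  if (n < 2) stop_mlc("need at least two genes")
  uni_chrom <- annot_chrom(annot, universe)
  grp_chrom <- annot_chrom(annot, genes)
  nk <- table(grp_chrom)
  chroms2 <- names(nk)[nk >= 2]

  x_obs <- same_chrom_fraction(genes, annot)
  d_obs <- average_pair_distance(genes, annot)
  dk_obs <- vapply(chroms2, function(k)
    mean(chrom_pair_distances(genes[grp_chrom == k], annot)), numeric(1))

  res <- with_seed(seed, {
    x_null <- numeric(n_rand)
    d_null <- rep(NA_real_, n_rand)
    dk_null <- matrix(NA_real_, n_rand, length(chroms2),
                      dimnames = list(NULL, chroms2))
    pos <- match(genes, universe)
    for (r in seq_len(n_rand)) {
      # x_c control: shuffle the universe's gene -> chromosome association
      shuf <- sample(uni_chrom)
      tab <- table(shuf[pos])
      stopifnot(sum(tab) == n)  # shuffling preserves the assignment multiset
      x_null[r] <- sum(tab * (tab - 1) / 2) / (n * (n - 1) / 2)
      # d_c / per-chromosome controls: resample n_k genes per chromosome
      tot <- 0; npairs <- 0
      for (k in chroms2) {
        pool <- universe[uni_chrom == k]
        draw <- sample(pool, nk[[k]])
        d <- chrom_pair_distances(draw, annot)
        dk_null[r, k] <- mean(d)
        tot <- tot + sum(d)
        npairs <- npairs + length(d)
      }
      if (npairs > 0) d_null[r] <- tot / npairs
    }
    list(x_null = x_null, d_null = d_null, dk_null = dk_null)
  })

  z_x <- zscore_from_null(x_obs, res$x_null)
  if (is.na(z_x)) warn_mlc("degenerate null for x_c (zero variance)")
  p_x <- emp_pvalue(x_obs, res$x_null, "greater")
  z_d <- if (is.na(d_obs)) NA_real_ else zscore_from_null(d_obs, res$d_null)
  p_d <- if (is.na(d_obs)) NA_real_ else emp_pvalue(d_obs, res$d_null, "less")

  per_chrom <- if (length(chroms2) > 0) {
    fam <- names(nk)[nk >= min_family_genes]
    family_size <- length(intersect(chroms2, fam))
    rows <- lapply(chroms2, function(k) {
      z <- zscore_from_null(dk_obs[[k]], res$dk_null[, k])
      pv <- emp_pvalue(dk_obs[[k]], res$dk_null[, k], "less")
      in_fam <- k %in% fam
      data.frame(chrom = k, n_k = as.integer(nk[[k]]), d_ck = dk_obs[[k]],
                 z = z, p_emp = pv, in_family = in_fam,
                 bonferroni_significant = in_fam && family_size > 0 &&
                   !is.na(pv) && pv * family_size < alpha,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    attr(df, "family_size") <- family_size
    df
  } else {
    df <- data.frame(chrom = character(0), n_k = integer(0),
                     d_ck = numeric(0), z = numeric(0), p_emp = numeric(0),
                     in_family = logical(0),
                     bonferroni_significant = logical(0))
    attr(df, "family_size") <- 0L
    df
  }

  structure(
    list(genes = genes, n = n, x_c = x_obs, z_x = z_x, p_x = p_x,
         d_c = d_obs, z_d = z_d, p_d = p_d, per_chromosome = per_chrom,
         n_randomizations = n_rand, seed = seed, alpha = alpha),
    class = "localization_result"
  )
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf("Localization of %d genes (%d randomizations)\n", x$n,
              x$n_randomizations))
  cat(sprintf("  x_c = %.4f  z = %s  p = %.3g\n", x$x_c,
              formatC(x$z_x, digits = 3, format = "f"), x$p_x))
  if (!is.na(x$d_c))
    cat(sprintf("  d_c = %.0f bp  z = %s  p = %.3g\n", x$d_c,
                formatC(x$z_d, digits = 3, format = "f"), x$p_d))
  if (nrow(x$per_chromosome) > 0) {
    cat("  per-chromosome:\n")
    print(x$per_chromosome, row.names = FALSE)
  }
  invisible(x)
}
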