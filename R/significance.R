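# Analytic community significance under the configuration model: the observed
# total intralayer weight of a community is compared with its expectation and
# variance over sample covariance matrices drawn from the fitted null, giving
# a Z score per community. Correlation matrices pass through unchanged (a
# correlation matrix is a covariance matrix).

# Intralayer unordered index pairs (i > j) of a community, per layer.
community_layer_pairs <- function(p, community) {
  idx <- community_nodes(p, community)
  genes <- node_gene(p, idx)
  layers <- node_layer(p, idx)
  lapply(seq_len(p$L), function(al) {
    g <- sort(genes[layers == al])
    if (length(g) < 2) return(NULL)
    pairs <- utils::combn(g, 2)
    list(i = pairs[2, ], j = pairs[1, ])  # i > j
  })
}

#' Total intralayer weight of a community
#'
#' Sums the empirical correlations over all unordered within-layer gene pairs
#' of the community (each pair once; diagonal excluded).
#'
#' @param mlc a `multilayer_corr`.
#' @param p a [supra_partition()].
#' @param community community label.
#' @return numeric W.
#' @export
community_weight <- function(mlc, p, community) {
  pairs <- community_layer_pairs(p, community)
  w <- 0
  for (al in seq_along(pairs)) {
    pr <- pairs[[al]]
    if (is.null(pr)) next
    w <- w + sum(mlc$rho[[al]][cbind(pr$i, pr$j)])
  }
  w
}

#' Analytic null moments of a community's intralayer weight
#'
#' Expectation and variance of the total intralayer weight over sample
#' covariance matrices drawn from the configuration model. The expectation is
#' the same pair sum taken over the fitted null covariance. The variance sums,
#' per layer, the Wishart covariance of every ordered pair of pairs
#' `(C_ik C_jr + C_ir C_jk)`, divided by the number of observations used to
#' form that layer's sample covariance.
#'
#' @param nulls per-layer `null_model_layer` list.
#' @param p a [supra_partition()].
#' @param community community label.
#' @param n_samples_per_layer divisor per layer; default the `sample_size`
#'   stored on each null model.
#' @return list with `expected_W` and `var_W`.
#' @export
analytic_moments <- function(nulls, p, community, n_samples_per_layer = NULL) {
  pairs <- community_layer_pairs(p, community)
  if (all(vapply(pairs, is.null, logical(1))))
    stop_mlc("community %s has no intralayer pairs; moments are undefined",
             as.character(community))
  if (is.null(n_samples_per_layer))
    n_samples_per_layer <- vapply(nulls, `[[`, numeric(1), "sample_size")
  n_samples_per_layer <- rep_len(n_samples_per_layer, length(nulls))
  if (anyNA(n_samples_per_layer) || any(n_samples_per_layer < 2))
    stop_mlc("valid per-layer sample sizes are required for the variance")
  ew <- 0; vw <- 0
  for (al in seq_along(pairs)) {
    pr <- pairs[[al]]
    if (is.null(pr)) next
    C <- nulls[[al]]$null_cov
    ew <- ew + sum(C[cbind(pr$i, pr$j)])
    m <- length(pr$i)
    # pair-of-pairs sum, chunked over the second pair index to bound memory
    acc <- 0
    for (chunk in split(seq_len(m), ceiling(seq_len(m) / 1000))) {
      acc <- acc + sum(
        C[pr$i, pr$i[chunk], drop = FALSE] * C[pr$j, pr$j[chunk], drop = FALSE] +
        C[pr$i, pr$j[chunk], drop = FALSE] * C[pr$j, pr$i[chunk], drop = FALSE])
    }
    vw <- vw + acc / n_samples_per_layer[al]
  }
  list(expected_W = ew, var_W = vw)
}

#' Z scores for all communities of a partition
#'
#' `z = (W - E[W]) / sqrt(Var[W])` per community; communities without
#' intralayer pairs (single nodes, or one gene spread over layers) get a null
#' (NA) Z score, as do degenerate zero-variance cases (with a warning).
#'
#' @param mlc a `multilayer_corr`.
#' @param nulls per-layer null models.
#' @param p a [supra_partition()].
#' @param n_samples_per_layer see [analytic_moments()]; defaults to the
#'   per-layer empirical sample counts recorded on `mlc`.
#' @return data frame of class `community_significance` with columns
#'   community, n_nodes, n_pairs, W, expected_W, var_W, z.
#' @export
community_zscore <- function(mlc, nulls, p, n_samples_per_layer = NULL) {
  if (is.null(n_samples_per_layer)) {
    stored <- vapply(nulls, `[[`, numeric(1), "sample_size")
    n_samples_per_layer <- if (anyNA(stored))
      as.numeric(mlc$sample_counts$per_layer) else stored
  }
  comms <- sort(unique(p$labels))
  rows <- lapply(comms, function(cc) {
    idx <- community_nodes(p, cc)
    pairs <- community_layer_pairs(p, cc)
    n_pairs <- sum(vapply(pairs, function(pr)
      if (is.null(pr)) 0L else length(pr$i), integer(1)))
    if (n_pairs == 0L) {
      return(data.frame(community = cc, n_nodes = length(idx),
                        n_pairs = 0L, W = 0, expected_W = NA_real_,
                        var_W = NA_real_, z = NA_real_))
    }
    W <- community_weight(mlc, p, cc)
    mom <- analytic_moments(nulls, p, cc, n_samples_per_layer)
    z <- if (mom$var_W <= 0) {
      warn_mlc("community %d has zero null variance; Z set to NA", cc)
      NA_real_
    } else (W - mom$expected_W) / sqrt(mom$var_W)
    data.frame(community = cc, n_nodes = length(idx), n_pairs = n_pairs,
               W = W, expected_W = mom$expected_W, var_W = mom$var_W, z = z)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("community_significance", "data.frame")
  out
}
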