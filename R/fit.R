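# Top-level estimator: from expression layers to significant, classified
# multilayer communities in one call, following the modelling-function idiom.

#' Detect communities in a multilayer gene co-expression correlation matrix
#'
#' The full estimation pipeline: select high-variance genes, build per-tissue
#' correlation layers with empirical interlayer couplings, fit the
#' configuration-model null per layer, sweep the resolution parameter and pick
#' robust values with CHAMP, form a consensus partition from stochastic
#' GenLouvain runs at each selected resolution, and attach significance Z
#' scores and specialist profiles.
#'
#' @param layers list of [expression_layer()] objects, or an existing
#'   `multilayer_corr`.
#' @param k top-variance genes per layer (default 75).
#' @param genes explicit gene list overriding selection.
#' @param gamma_grid resolution sweep grid (default 15 values on [1, 4]).
#' @param n_consensus stochastic runs entering the consensus (default 200).
#' @param seed RNG seed; all stages derive their seeds from it.
#' @param specialist_threshold classification threshold (default 0.5).
#' @param drop_constant drop zero-variance genes instead of erroring.
#' @param null_tol strength tolerance of the configuration-model fit.
#' @return An object of class `mlc_fit` with components `mlc`, `nulls`,
#'   `sweep` (CHAMP result and sweep partitions), `selected_gammas`, and per
#'   selected gamma `partitions`, `significance`, `profiles`, `classification`.
#' @export
multilayer_communities <- function(layers, k = 75, genes = NULL,
                                   gamma_grid = seq(1, 4, length.out = 15),
                                   n_consensus = 200, seed = 1,
                                   specialist_threshold = 0.5,
                                   drop_constant = FALSE, null_tol = 1e-8) {
  mlc <- if (inherits(layers, "multilayer_corr")) layers
         else build_multilayer(layers, k = k, genes = genes,
                               drop_constant = drop_constant)
  nulls <- lapply(seq_along(mlc$layer_labels), function(a)
    fit_config_model(mlc$rho[[a]], tol = null_tol,
                     sample_size = mlc$sample_counts$per_layer[a]))
  sw <- sweep_and_select(mlc, nulls, gamma_grid = gamma_grid, seed = seed)
  per_gamma <- lapply(seq_along(sw$selected_gammas), function(si) {
    gam <- sw$selected_gammas[si]
    Bg <- build_supra_corr(mlc, nulls, gamma = gam)
    runs <- lapply(seq_len(n_consensus), function(r)
      iterated_genlouvain(Bg, seed = derive_seed(seed, "louvain",
                                                 si * 100000L + r)))
    cons <- consensus_partition(runs, seed = derive_seed(seed, "consensus",
                                                         si))
    sig <- community_zscore(mlc, nulls, cons)
    prof <- specialist_table(cons)
    prof$class <- classify_communities(prof, specialist_threshold)
    list(gamma = gam, partition = cons, Q = modularity_value(Bg, cons),
         significance = sig, profiles = prof)
  })
  structure(
    list(mlc = mlc, nulls = nulls, sweep = sw,
         selected_gammas = sw$selected_gammas, results = per_gamma,
         call = match.call(), seed = seed,
         settings = list(k = k, gamma_grid = gamma_grid,
                         n_consensus = n_consensus,
                         specialist_threshold = specialist_threshold)),
    class = "mlc_fit"
  )
}

#' @export
print.mlc_fit <- function(x, ...) {
  cat("Multilayer co-expression community fit\n")
  cat(sprintf("  %d genes x %d layers (%s)\n", length(x$mlc$gene_ids),
              length(x$mlc$layer_labels),
              paste(x$mlc$layer_labels, collapse = ", ")))
  cat(sprintf("  CHAMP domains on [%.3g, %.3g]: %d; selected gamma: %s\n",
              x$sweep$champ$gamma_range[1], x$sweep$champ$gamma_range[2],
              nrow(x$sweep$champ$domains),
              paste(signif(x$selected_gammas, 3), collapse = ", ")))
  for (res in x$results)
    cat(sprintf("  gamma = %.3g: %d communities, Q = %.4f\n", res$gamma,
                length(unique(res$partition$labels)), res$Q))
  invisible(x)
}

#' @export
summary.mlc_fit <- function(object, ...) {
  out <- lapply(object$results, function(res) {
    tab <- merge(res$significance,
                 res$profiles[, c("community", "specialist_fraction",
                                  "specialist_tissue", "class")],
                 by = "community")
    tab$gamma <- res$gamma
    tab
  })
  out <- do.call(rbind, out)
  class(out) <- c("summary.mlc_fit", "data.frame")
  out
}

#' @export
print.summary.mlc_fit <- function(x, ...) {
  cat("Communities by selected resolution:\n")
  df <- as.data.frame(x)
  for (col in intersect(c("W", "expected_W", "var_W", "z"), names(df)))
    df[[col]] <- signif(df[[col]], 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Plot the CHAMP envelope of a fit
#'
#' Draws each sweep partition's modularity line Q(gamma) = a - gamma b over
#' the sweep range and highlights the upper envelope with its domain
#' boundaries.
#'
#' @param x an `mlc_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mlc_fit <- function(x, ...) {
  ch <- x$sweep$champ
  rng <- ch$gamma_range
  gg <- seq(rng[1], rng[2], length.out = 200)
  qs <- sapply(seq_len(nrow(ch$lines)), function(i)
    ch$lines$a[i] - gg * ch$lines$b[i])
  graphics::matplot(gg, qs, type = "l", lty = 3, col = "grey60",
                    xlab = expression(gamma), ylab = "Q",
                    main = "CHAMP envelope", ...)
  env <- apply(qs, 1, max)
  graphics::lines(gg, env, lwd = 2)
  graphics::abline(v = ch$domains$lo[-1], lty = 2, col = "grey40")
  graphics::points(x$selected_gammas,
                   vapply(x$selected_gammas, function(g)
                     max(ch$lines$a - g * ch$lines$b), numeric(1)),
                   pch = 19, col = "red3")
  invisible(x)
}
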