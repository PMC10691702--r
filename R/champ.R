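# One-dimensional CHAMP: every candidate partition's modularity is linear in
# the resolution parameter, Q(gamma) = a - gamma * b, because the null term is
# the only gamma-dependent part and c_norm does not depend on gamma. The upper
# envelope of the candidate lines over a gamma range identifies, for each
# sub-interval, the partition that attains maximal modularity; the widest
# sub-intervals mark robust resolutions.

#' Modularity line of a partition
#'
#' Decomposes `Q(gamma) = a - gamma * b` for one partition of a multilayer
#' correlation matrix: `a` collects the within-community empirical correlation
#' and coupling terms, `b` the within-community null-model terms.
#'
#' @param mlc a `multilayer_corr`.
#' @param nulls per-layer `null_model_layer` list.
#' @param p a [supra_partition()].
#' @param id optional identifier stored on the line.
#' @return list with `id`, `a`, `b` and the partition.
#' @export
partition_line <- function(mlc, nulls, p, id = NULL) {
  stopifnot(inherits(mlc, "multilayer_corr"), inherits(p, "supra_partition"))
  N <- length(mlc$gene_ids); L <- length(mlc$layer_labels)
  a_sum <- 0; b_sum <- 0
  for (al in seq_len(L)) {
    idx <- (al - 1L) * N + seq_len(N)
    lab <- p$labels[idx]
    for (c in unique(lab)) {
      members <- which(lab == c)
      a_sum <- a_sum + sum(mlc$rho[[al]][members, members])
      b_sum <- b_sum + sum(nulls[[al]]$null_corr[members, members])
    }
  }
  for (al in seq_len(L)) for (be in seq_len(L)) {
    if (al == be) next
    same <- p$labels[(al - 1L) * N + seq_len(N)] ==
      p$labels[(be - 1L) * N + seq_len(N)]
    a_sum <- a_sum + sum(mlc$omega[same, al, be])
  }
  c_norm <- sum(vapply(seq_len(L), function(a) sum(mlc$rho[[a]]), numeric(1))) +
    sum(mlc$omega)
  list(id = id, a = a_sum / c_norm, b = b_sum / c_norm, partition = p)
}

#' Upper envelope of modularity lines over a resolution range
#'
#' @param lines list of lines from [partition_line()] (fields `id`, `a`, `b`).
#' @param gamma_range numeric length-2 range (half-open domains `[lo, hi)`).
#' @return An object of class `champ_result`: data frame `domains` (lo, hi,
#'   id, width) tiling the range, `admissible` ids, and `widest_two` ids
#'   ordered by decreasing width.
#' @export
champ_1d <- function(lines, gamma_range = c(1, 4)) {
  if (length(lines) == 0) stop_mlc("champ_1d needs at least one line")
  lo <- gamma_range[1]; hi <- gamma_range[2]
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    stop_mlc("gamma_range must be a finite increasing interval")
  ids <- vapply(seq_along(lines), function(i) {
    if (is.null(lines[[i]]$id)) i else lines[[i]]$id
  }, numeric(1))
  a <- vapply(lines, `[[`, numeric(1), "a")
  b <- vapply(lines, `[[`, numeric(1), "b")
  # breakpoints: all pairwise intersections inside the range
  cuts <- c(lo, hi)
  n <- length(lines)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (abs(b[i] - b[j]) > 1e-14) {
        g <- (a[i] - a[j]) / (b[i] - b[j])
        if (g > lo && g < hi) cuts <- c(cuts, g)
      }
    }
  }
  cuts <- sort(unique(cuts))
  seg_winner <- integer(length(cuts) - 1L)
  for (s in seq_len(length(cuts) - 1L)) {
    mid <- (cuts[s] + cuts[s + 1L]) / 2
    q <- a - mid * b
    w <- which(q >= max(q) - 1e-12)
    seg_winner[s] <- w[which.min(b[w])]  # tie: flatter line (stable)
  }
  keep <- c(TRUE, seg_winner[-1] != seg_winner[-length(seg_winner)])
  starts <- cuts[-length(cuts)][keep]
  ends <- c(starts[-1], hi)
  winners <- seg_winner[keep]
  domains <- data.frame(lo = starts, hi = ends, id = ids[winners],
                        width = ends - starts)
  ord <- order(-domains$width, domains$lo)
  structure(
    list(domains = domains,
         admissible = unique(ids[winners]),
         widest_two = domains$id[ord][seq_len(min(2L, nrow(domains)))],
         lines = data.frame(id = ids, a = a, b = b),
         gamma_range = c(lo, hi)),
    class = "champ_result"
  )
}

#' @export
print.champ_result <- function(x, ...) {
  cat(sprintf("CHAMP envelope on [%.3g, %.3g): %d domain(s)\n",
              x$gamma_range[1], x$gamma_range[2], nrow(x$domains)))
  print(x$domains, row.names = FALSE)
  invisible(x)
}

#' Resolution sweep with CHAMP selection
#'
#' Runs one iterated GenLouvain maximization per grid value of gamma, computes
#' each partition's modularity line, forms the CHAMP upper envelope over the
#' grid range, and returns representative gamma values (domain midpoints) for
#' the two widest domains.
#'
#' @param mlc a `multilayer_corr`.
#' @param nulls per-layer null models.
#' @param gamma_grid sweep grid; default 15 evenly spaced values on [1, 4].
#' @param seed RNG seed (fans out per grid point).
#' @return list with `champ` (a `champ_result`), `selected_gammas` (midpoints
#'   of the two widest domains, widest first), `partitions` (per grid gamma)
#'   and `lines`.
#' @export
sweep_and_select <- function(mlc, nulls, gamma_grid = seq(1, 4,
                                                          length.out = 15),
                             seed = NULL) {
  if (is.unsorted(gamma_grid)) stop_mlc("gamma_grid must be sorted ascending")
  partitions <- vector("list", length(gamma_grid))
  lines <- vector("list", length(gamma_grid))
  for (g in seq_along(gamma_grid)) {
    Bg <- build_supra_corr(mlc, nulls, gamma = gamma_grid[g])
    s <- if (is.null(seed)) NULL else derive_seed(seed, "sweep", g)
    partitions[[g]] <- iterated_genlouvain(Bg, seed = s)
    lines[[g]] <- partition_line(mlc, nulls, partitions[[g]], id = g)
  }
  ch <- champ_1d(lines, gamma_range = range(gamma_grid))
  sel <- vapply(ch$widest_two, function(id) {
    d <- ch$domains[ch$domains$id == id, , drop = FALSE]
    d <- d[which.max(d$width), ]
    (d$lo + d$hi) / 2
  }, numeric(1))
  list(champ = ch, selected_gammas = sel, partitions = partitions,
       lines = lines, gamma_grid = gamma_grid)
}
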