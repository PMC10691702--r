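test_that("correlation-mode supra matrix matches hand arithmetic on a 2x2x2 fixture", {
  rho1 <- matrix(c(1, 0.6, 0.6, 1), 2)
  rho2 <- matrix(c(1, -0.2, -0.2, 1), 2)
  null1 <- matrix(c(1, 0.4, 0.4, 1), 2)
  null2 <- matrix(c(1, 0.1, 0.1, 1), 2)
  omega <- array(0, c(2, 2, 2))
  omega[1, 1, 2] <- omega[1, 2, 1] <- 0.5
  omega[2, 1, 2] <- omega[2, 2, 1] <- 0.3
  mlc <- structure(list(layer_labels = c("a", "b"), gene_ids = c("g1", "g2"),
                        rho = list(rho1, rho2), omega = omega,
                        sample_counts = list(per_layer = c(a = 10, b = 10))),
                   class = "multilayer_corr")
  nulls <- list(list(null_corr = null1, null_cov = null1, sample_size = 10),
                list(null_corr = null2, null_cov = null2, sample_size = 10))
  gam <- 2
  sm <- build_supra_corr(mlc, nulls, gamma = gam)
  # hand substitution, node order (g1,a),(g2,a),(g1,b),(g2,b)
  expect_equal(sm$B[1, 2], 0.6 - gam * 0.4)
  expect_equal(sm$B[1, 1], 1 - gam * 1)
  expect_equal(sm$B[3, 4], -0.2 - gam * 0.1)
  expect_equal(sm$B[1, 3], 0.5)   # omega for g1
  expect_equal(sm$B[2, 4], 0.3)
  expect_equal(sm$B[1, 4], 0)     # off-diagonal interlayer block is zero
  expect_equal(sm$B, t(sm$B))
  # c_norm = sum of all rho entries + all omega entries
  expect_equal(sm$c_norm, sum(rho1) + sum(rho2) + sum(omega))
})

test_that("gamma = 1 with null equal to rho leaves only couplings; omega = 0 is block-diagonal", {
  mlc <- random_mlc(N = 3, L = 2, seed = 5)
  nulls <- lapply(mlc$rho, function(r)
    list(null_corr = r, null_cov = r, sample_size = 40))
  sm <- build_supra_corr(mlc, nulls, gamma = 1)
  intra <- sm$B
  intra[1:3, 4:6] <- 0; intra[4:6, 1:3] <- 0
  expect_equal(max(abs(intra)), 0)
  mlc0 <- mlc; mlc0$omega[] <- 0
  nulls0 <- lapply(mlc0$rho, fit_config_model)
  sm0 <- build_supra_corr(mlc0, nulls0, gamma = 1.5)
  expect_equal(max(abs(sm0$B[1:3, 4:6])), 0)
})

test_that("network-mode supra recovers single-layer modularity closed forms", {
  # complete graph, gamma = 1: all-in-one gives Q = 0 exactly (the full double
  # sum of A equals the full double sum of the null term), and singletons give
  # only the diagonal null terms, Q = -sum(k^2)/(4 M^2)
  A <- matrix(1, 4, 4) - diag(4)
  net <- multilayer_network(list(A))
  sm <- build_supra_network(net, gamma = 1)
  p <- make_partition(rep(1L, 4), 4, 1)
  k <- rowSums(A); M <- sum(A) / 2
  expect_equal(modularity_value(sm, p), 0, tolerance = 1e-12)
  psing <- make_partition(1:4, 4, 1)
  expect_equal(modularity_value(sm, psing), -sum(k^2) / (4 * M^2),
               tolerance = 1e-12)

  # two disconnected triangles: the two-clique partition is the enumerated optimum
  B2 <- matrix(0, 6, 6)
  B2[1:3, 1:3] <- 1; B2[4:6, 4:6] <- 1; diag(B2) <- 0
  net2 <- multilayer_network(list(B2))
  sm2 <- build_supra_network(net2, gamma = 1)
  best <- exhaustive_best_weight(sm2$B) / sm2$c_norm
  ptwo <- make_partition(rep(1:2, each = 3), 6, 1)
  expect_equal(modularity_value(sm2, ptwo), best, tolerance = 1e-12)
  expect_error(build_supra_network(
    multilayer_network(list(matrix(0, 3, 3))), 1), "no edges")
})

test_that("modularity value matches the naive double-sum and is label/order invariant", {
  set.seed(8)
  for (rep in 1:5) {
    N <- 3; L <- 2
    B <- matrix(rnorm(36), 6); B <- (B + t(B)) / 2
    sm <- make_supra(B, N, L, c_norm = 4.2)
    labs <- sample.int(3, 6, replace = TRUE)
    p <- make_partition(labs, N, L)
    expect_equal(modularity_value(sm, p), naive_modularity(sm, p),
                 tolerance = 1e-12)
    # relabeling invariance
    relab <- make_partition(c(9L, 4L, 7L)[labs], N, L)
    expect_equal(modularity_value(sm, relab), modularity_value(sm, p))
  }
})

test_that("singleton partition on a zero-diagonal B gives Q = 0", {
  B <- matrix(rnorm(25), 5); B <- (B + t(B)) / 2; diag(B) <- 0
  sm <- make_supra(B, 5, 1)
  p <- make_partition(1:5, 5, 1)
  expect_equal(modularity_value(sm, p), 0)
})

test_that("genlouvain recovers planted diagonal blocks and leaves zero matrices atomized", {
  B <- matrix(0, 9, 9)
  B[1:4, 1:4] <- 0.5; B[5:9, 5:9] <- 0.7; diag(B) <- 0
  sm <- make_supra(B, 9, 1)
  p <- genlouvain(sm, seed = 1)
  expect_equal(ari(p$labels, rep(1:2, c(4, 5))), 1)
  # enumeration confirms this is the unique maximizer
  expect_equal(modularity_value(sm, p),
               exhaustive_best_weight(B) / sm$c_norm, tolerance = 1e-12)
  z <- genlouvain(make_supra(matrix(0, 6, 6), 6, 1), seed = 2)
  expect_equal(length(unique(z$labels)), 6L)
})

test_that("single-pass genlouvain reaches the enumerated optimum on most seeds", {
  # 8-node instances of the kind the package actually maximizes: supra
  # matrices built from random correlation fixtures at random resolutions
  hits <- 0L; total <- 0L
  for (inst in 1:6) {
    mlc <- random_mlc(N = 4, L = 2, S = 30, seed = 9000 + inst)
    nulls <- lapply(mlc$rho, fit_config_model, sample_size = 30)
    set.seed(inst)
    sm <- build_supra_corr(mlc, nulls, gamma = runif(1, 0.5, 3))
    best <- exhaustive_best_weight(sm$B) / sm$c_norm
    qs <- vapply(1:50, function(s)
      modularity_value(sm, genlouvain(sm, seed = s)), numeric(1))
    expect_true(all(qs <= best + 1e-10))
    hits <- hits + sum(abs(qs - best) < 1e-10)
    total <- total + 50L
  }
  expect_gte(hits / total, 0.9)
})

test_that("iterated genlouvain is a fixed point with non-decreasing Q", {
  set.seed(17)
  B <- matrix(rnorm(100, sd = 0.4), 10); B <- (B + t(B)) / 2
  sm <- make_supra(B, 5, 2)
  p <- iterated_genlouvain(sm, seed = 3)
  # running one more round from the converged labels changes nothing
  again <- genlouvain(sm, seed = 99, init = p$labels)
  expect_equal(mlcoexp:::canonical_labels(again$labels),
               mlcoexp:::canonical_labels(p$labels))
  expect_gte(attr(p, "Q"), modularity_value(sm, genlouvain(sm, seed = 3)))
})

test_that("iterated genlouvain never loses to the single pass on planted fixtures", {
  d <- planted_design(N = 10, S = 80, n_generalist = 4, n_specialist = 3)
  layers <- generate_expression(d, seed = 12)
  mlc <- build_multilayer(layers, genes = d$gene_ids)
  nulls <- lapply(mlc$rho, fit_config_model, sample_size = 80)
  sm <- build_supra_corr(mlc, nulls, gamma = 1)
  for (s in 1:20) {
    qi <- attr(iterated_genlouvain(sm, seed = s), "Q")
    q1 <- modularity_value(sm, genlouvain(sm, seed = s))
    expect_gte(qi, q1 - 1e-12)
  }
})

test_that("Q is non-decreasing in an interlayer coupling joining co-assigned copies", {
  mlc <- random_mlc(N = 3, L = 2, seed = 14)
  nulls <- lapply(mlc$rho, fit_config_model)
  p <- make_partition(c(1L, 2L, 2L, 1L, 2L, 3L), 3, 2)  # gene 1 co-assigned
  qs <- vapply(c(0.1, 0.3, 0.7), function(w) {
    m2 <- mlc
    m2$omega[1, 1, 2] <- m2$omega[1, 2, 1] <- w
    modularity_value(build_supra_corr(m2, nulls, 1), p)
  }, numeric(1))
  expect_true(all(diff(qs) >= 0))
})

test_that("with zero couplings the multilayer optimum is the union of per-layer optima", {
  set.seed(23)
  for (rep in 1:3) {
    N <- 4
    B1 <- matrix(rnorm(16, sd = 0.6), 4); B1 <- (B1 + t(B1)) / 2
    B2 <- matrix(rnorm(16, sd = 0.6), 4); B2 <- (B2 + t(B2)) / 2
    Bfull <- matrix(0, 8, 8)
    Bfull[1:4, 1:4] <- B1; Bfull[5:8, 5:8] <- B2
    expect_equal(exhaustive_best_weight(Bfull),
                 exhaustive_best_weight(B1) + exhaustive_best_weight(B2),
                 tolerance = 1e-12)
    sm <- make_supra(Bfull, 4, 2)
    qs <- vapply(1:20, function(s)
      modularity_value(sm, iterated_genlouvain(sm, seed = s)), numeric(1))
    expect_equal(max(qs), exhaustive_best_weight(Bfull) / sm$c_norm,
                 tolerance = 1e-10)
  }
})

test_that("consensus of identical or relabeled partitions returns them unchanged", {
  p <- make_partition(c(1L, 1L, 2L, 2L, 3L, 3L), 3, 2)
  same <- consensus_partition(list(p, p, p), seed = 1)
  expect_equal(ari(same$labels, p$labels), 1)
  relab <- make_partition(c(5L, 5L, 9L, 9L, 1L, 1L), 3, 2)
  mix <- consensus_partition(list(p, relab, p), seed = 2)
  expect_equal(ari(mix$labels, p$labels), 1)
})

test_that("consensus recovers a planted partition from noisy corruptions", {
  set.seed(77)
  truth <- rep(1:3, each = 6)
  N <- 9; L <- 2
  noisy <- lapply(1:200, function(r) {
    lab <- truth
    flip <- sample(length(lab), max(1, round(0.1 * length(lab))))
    lab[flip] <- sample.int(3, length(flip), replace = TRUE)
    make_partition(lab, N, L)
  })
  cons <- consensus_partition(noisy, seed = 5)
  expect_gte(ari(cons$labels, truth), 0.95)
})
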