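test_that("top-k variance selection matches a definitional variance oracle", {
  set.seed(7)
  vals1 <- matrix(rexp(5 * 10, 0.2), 5, 10,
                  dimnames = list(paste0("G", 1:5), paste0("SYN-%04d-a", 1:10)))
  colnames(vals1) <- sprintf("SYN-A%03d-x", 1:10)
  vals2 <- vals1[, ]; vals2[] <- rexp(50, 0.05)
  colnames(vals2) <- sprintf("SYN-B%03d-x", 1:10)
  l1 <- expression_layer("t1", vals1,
                         setNames(sprintf("SYN-A%03d", 1:10), colnames(vals1)))
  l2 <- expression_layer("t2", vals2,
                         setNames(sprintf("SYN-B%03d", 1:10), colnames(vals2)))
  sel <- select_genes(list(l1, l2), k = 2)
  per <- attr(sel, "per_layer")
  # oracle: definitional variance over samples, per layer
  for (ly in list(l1, l2)) {
    v <- apply(ly$values, 1, function(x) sum((x - mean(x))^2) / (length(x) - 1))
    expect_setequal(per[[ly$tissue_label]],
                    names(sort(v, decreasing = TRUE))[1:2])
  }
  expect_setequal(sel, union(per[[1]], per[[2]]))
  expect_equal(as.vector(sel), sort(as.vector(sel)))
})

test_that("disjoint and identical per-layer top-k sets give union sizes 2k and k", {
  mk <- function(vars, tissue, tag) {
    S <- 12
    vals <- t(sapply(vars, function(v) rnorm(S, mean = 50, sd = sqrt(v))))
    vals <- pmax(vals, 0)
    rownames(vals) <- paste0("G", seq_along(vars))
    colnames(vals) <- sprintf("SYN-%s%02d-s", tag, 1:S)
    expression_layer(tissue, vals,
                     setNames(sprintf("SYN-%s%02d", tag, 1:S), colnames(vals)))
  }
  set.seed(11)
  # layer A: genes 1-3 most variable; layer B: genes 4-6
  lA <- mk(c(900, 800, 700, 1, 1, 1), "A", "a")
  lB <- mk(c(1, 1, 1, 900, 800, 700), "B", "b")
  expect_length(select_genes(list(lA, lB), k = 3), 6L)
  lC <- mk(c(900, 800, 700, 1, 1, 1), "C", "c")
  expect_length(select_genes(list(lA, lC), k = 3), 3L)
  expect_error(select_genes(list(lA), k = 7), "universe")
})

test_that("overlap stats match set enumeration", {
  ranks <- setNames(1:4, paste0("g", 1:4))
  expect_equal(overlap_stats(c("g1", "g2"), c("g1", "g2"), ranks)$jaccard, 1)
  expect_equal(overlap_stats(paste0("a", 1:75), paste0("b", 1:75),
                             setNames(1:75, paste0("b", 1:75)))$jaccard, 0)
  st <- overlap_stats(c("g1", "g2", "g3"), c("g2", "g3", "g4"), ranks)
  expect_equal(st$jaccard, 0.5)
  expect_equal(st$average_rank, mean(c(2, 3, 4)))
  expect_error(overlap_stats("g1", "g9", ranks), "absent")
})

test_that("log transform maps 0 to 0 and e-1 to 1, and rejects negatives", {
  expect_equal(log_transform(0), 0)
  expect_equal(log_transform(exp(1) - 1), 1)
  expect_error(log_transform(-0.1), "non-negative")
})

test_that("layer correlation equals a literal two-pass Pearson evaluation", {
  vals <- rbind(c(0, 1, 3), c(1, 2, 5))
  rownames(vals) <- c("gi", "gj"); colnames(vals) <- paste0("SYN-C0", 1:3, "-s")
  ly <- expression_layer("t", vals,
                         setNames(paste0("SYN-C0", 1:3), colnames(vals)))
  r <- layer_correlation(ly, c("gi", "gj"))
  expect_equal(r["gi", "gj"], naive_pearson_log1p(vals[1, ], vals[2, ]),
               tolerance = 1e-12)
  expect_equal(diag(r), c(gi = 1, gj = 1))
})

test_that("duplicated and anti-correlated genes give r = 1 and r = -1", {
  set.seed(3)
  x <- rexp(10, 0.1)
  dup <- rbind(x, x)
  rownames(dup) <- c("a", "b"); colnames(dup) <- sprintf("SYN-D%02d-s", 1:10)
  donors <- setNames(sprintf("SYN-D%02d", 1:10), colnames(dup))
  expect_equal(layer_correlation(expression_layer("t", dup, donors),
                                 c("a", "b"))["a", "b"], 1)
  anti <- rbind(x, expm1(5 - log1p(x)))  # log1p(y) = 5 - log1p(x)
  rownames(anti) <- c("a", "b"); colnames(anti) <- colnames(dup)
  expect_equal(layer_correlation(expression_layer("t", anti, donors),
                                 c("a", "b"))["a", "b"], -1, tolerance = 1e-10)
})

test_that("Pearson correlation is invariant to the log base", {
  set.seed(9)
  x <- rexp(30, 0.1); y <- x * 2 + rexp(30, 0.5)
  r_nat <- cor(log(x + 1), log(y + 1))
  r_b10 <- cor(log10(x + 1), log10(y + 1))
  expect_equal(r_nat, r_b10, tolerance = 1e-12)
})

test_that("zero-variance genes raise an error naming the gene, or are dropped", {
  vals <- rbind(c(5, 5, 5, 5), rexp(4, 0.1), rexp(4, 0.1))
  rownames(vals) <- c("flat", "a", "b")
  colnames(vals) <- sprintf("SYN-E%02d-s", 1:4)
  donors <- setNames(sprintf("SYN-E%02d", 1:4), colnames(vals))
  ly <- expression_layer("t", vals, donors)
  expect_error(layer_correlation(ly, rownames(vals)), "flat")
  expect_warning(
    mlc <- build_multilayer(list(ly), genes = rownames(vals),
                            drop_constant = TRUE),
    "dropped")
  expect_equal(mlc$gene_ids, c("a", "b"))
})

test_that("interlayer couplings match definitional Pearson on shared donors and clip at 0", {
  # 4 shared donors, deterministic values
  v1 <- rbind(g1 = c(1, 2, 3, 4), g2 = c(10, 0, 5, 2))
  v2 <- rbind(g1 = c(2, 4, 6, 9), g2 = c(0, 11, 1, 6))
  colnames(v1) <- sprintf("SYN-F%02d-t1", 1:4)
  colnames(v2) <- sprintf("SYN-F%02d-t2", 1:4)
  d1 <- setNames(sprintf("SYN-F%02d", 1:4), colnames(v1))
  d2 <- setNames(sprintf("SYN-F%02d", 1:4), colnames(v2))
  l1 <- expression_layer("t1", v1, d1)
  l2 <- expression_layer("t2", v2, d2)
  om <- interlayer_couplings(list(l1, l2), c("g1", "g2"))
  r1 <- naive_pearson_log1p(v1["g1", ], v2["g1", ])
  r2 <- naive_pearson_log1p(v1["g2", ], v2["g2", ])
  expect_equal(unname(om["g1", 1, 2]), max(r1, 0), tolerance = 1e-12)
  expect_equal(unname(om["g2", 1, 2]), max(r2, 0), tolerance = 1e-12)
  expect_true(r2 < 0)          # the fixture really exercises clipping
  expect_equal(unname(om["g2", 1, 2]), 0)
  expect_equal(om[, 1, 1], c(g1 = 0, g2 = 0))
  expect_equal(om[, 1, 2], om[, 2, 1])
})

test_that("identical cross-layer profiles give omega = 1; donor order is irrelevant", {
  set.seed(5)
  x <- matrix(rexp(2 * 6, 0.1), 2, 6, dimnames = list(c("g1", "g2"), NULL))
  colnames(x) <- sprintf("SYN-G%02d-t1", 1:6)
  dA <- setNames(sprintf("SYN-G%02d", 1:6), colnames(x))
  l1 <- expression_layer("t1", x, dA)
  perm <- sample(6)
  y <- x[, perm]; colnames(y) <- sprintf("SYN-G%02d-t2", (1:6)[perm])
  dB <- setNames(sprintf("SYN-G%02d", (1:6)[perm]), colnames(y))
  l2 <- expression_layer("t2", y, dB)
  om <- interlayer_couplings(list(l1, l2), c("g1", "g2"))
  expect_equal(unname(om[, 1, 2]), c(1, 1), tolerance = 1e-12)
})

test_that("too few common donors zeroes the pair's couplings with a warning", {
  l1 <- random_layer(N = 3, S = 5, tissue = "t1", seed = 1,
                     donors = sprintf("SYN-A%02d", 1:5))
  l2 <- random_layer(N = 3, S = 5, tissue = "t2", seed = 2,
                     donors = sprintf("SYN-B%02d", 1:5))
  expect_warning(om <- interlayer_couplings(list(l1, l2), l1$gene_ids),
                 "couplings set to 0")
  expect_true(all(om == 0))
})

test_that("built multilayer object satisfies its invariants", {
  d <- planted_design(N = 12, S = 60, n_generalist = 4, n_specialist = 4)
  layers <- generate_expression(d, seed = 21)
  mlc <- build_multilayer(layers, genes = d$gene_ids)
  for (r in mlc$rho) {
    expect_equal(r, t(r))
    expect_equal(unname(diag(r)), rep(1, nrow(r)))
    expect_true(all(abs(r) <= 1 + 1e-12))
    ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
    expect_true(min(ev) > -1e-8)  # valid correlation matrix (PSD)
  }
  expect_true(all(mlc$omega >= 0 & mlc$omega <= 1))
  expect_true(all(mlc$omega[, 1, 1] == 0) && all(mlc$omega[, 2, 2] == 0))
  # single layer: omega all zero
  m1 <- build_multilayer(layers[1], genes = d$gene_ids)
  expect_true(all(m1$omega == 0))
})

test_that("planted blocks show higher within-block than between-block correlation", {
  d <- planted_design(N = 20, S = 300, n_generalist = 6, n_specialist = 6)
  layers <- generate_expression(d, seed = 33)
  mlc <- build_multilayer(layers, genes = d$gene_ids)
  r <- mlc$rho[[1]]
  within <- r[1:6, 1:6][upper.tri(diag(6))]
  between <- r[1:6, 13:20]
  expect_gt(mean(within), mean(between) + 0.5)
})
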