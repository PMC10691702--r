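test_that("same-chromosome fraction is the exact pair count ratio", {
  ann <- grid_annotation(paste0("g", 1:6), c(1, 1, 1, 2, 3, 4),
                         seq(1e5, 6e5, by = 1e5))
  expect_equal(same_chrom_fraction(paste0("g", 1:3), ann), 1)
  expect_equal(same_chrom_fraction(c("g3", "g4", "g5", "g6"), ann), 0)
  # 4 genes split 3 + 1: 3 same-chromosome pairs of 6
  expect_equal(same_chrom_fraction(c("g1", "g2", "g3", "g4"), ann), 0.5)
  expect_error(same_chrom_fraction(c("g1", "nope"), ann), "not annotated")
})

test_that("gene distance is the gap between end and start, clamped at overlap", {
  ann <- gene_annotation(data.frame(
    gene_id = c("a", "b", "c", "d"), chrom = "1",
    start = c(500, 1500, 1001, 900), end = c(1000, 2000, 1600, 1200)))
  expect_equal(as.numeric(gene_distance("a", "b", ann)), 500)
  expect_equal(as.numeric(gene_distance("a", "c", ann)), 1)   # adjacent
  d <- gene_distance("a", "d", ann)                           # overlapping
  expect_equal(as.numeric(d), 0)
  expect_true(attr(d, "overlap"))
  ann2 <- gene_annotation(data.frame(gene_id = c("a", "b"),
                                     chrom = c("1", "2"),
                                     start = c(1, 1), end = c(10, 10)))
  expect_error(gene_distance("a", "b", ann2), "different chromosomes")
})

test_that("shuffle z for the chromosome fraction matches the exhaustive oracle", {
  # 10-gene universe on two chromosomes (6 + 4), group of 3 on chromosome 1
  uni <- paste0("g", 1:10)
  ann <- grid_annotation(uni, rep(c("1", "2"), c(6, 4)),
                         seq(2e5, 2e6, by = 2e5))
  grp <- paste0("g", 1:3)
  x_obs <- same_chrom_fraction(grp, ann)
  oracle <- exhaustive_xc_null(rep(c("1", "2"), c(6, 4)), 3)
  z_exact <- (x_obs - oracle$mean) / oracle$sd
  res <- localization_test(grp, ann, uni, n_rand = 100, seed = 7)
  # Monte-Carlo standard error of a z from 100 draws
  expect_lt(abs(res$z_x - z_exact), 3 * sqrt(1 / 100) * 3)
  # and with many draws the agreement tightens
  res2 <- localization_test(grp, ann, uni, n_rand = 5000, seed = 8)
  expect_lt(abs(res2$z_x - z_exact), 0.15)
})

test_that("whole-universe group yields a degenerate x_c null", {
  uni <- paste0("g", 1:6)
  ann <- grid_annotation(uni, rep(c("1", "2"), each = 3),
                         seq(1e5, 6e5, by = 1e5))
  expect_warning(res <- localization_test(uni, ann, uni, n_rand = 50,
                                          seed = 1),
                 "degenerate")
  expect_true(is.na(res$z_x))
})

test_that("a planted tight cluster is detected as z_d strongly negative", {
  d <- planted_design(N = 40, clusters = list(
    list(genes = c("G001", "G002", "G003"), chrom = "11", start = 5e6,
         width = 5e5)))
  ann <- generate_annotation(d, seed = 2)
  res <- localization_test(c("G001", "G002", "G003"), ann, d$gene_ids,
                           n_rand = 1000, seed = 3)
  expect_lt(res$z_d, -2)
})

test_that("null groups calibrate to mean z near zero", {
  set.seed(6)
  d <- planted_design(N = 40)
  ann <- generate_annotation(d, seed = 10)
  zx <- numeric(0); zd <- numeric(0)
  for (r in 1:120) {
    grp <- sample(d$gene_ids, 6)
    res <- localization_test(grp, ann, d$gene_ids, n_rand = 60,
                             seed = 1000 + r)
    zx <- c(zx, res$z_x); zd <- c(zd, res$z_d)
  }
  expect_lt(abs(mean(zx, na.rm = TRUE)), 0.15)
  expect_lt(abs(mean(zd, na.rm = TRUE)), 0.25)
})

test_that("per-chromosome rows exist only for n_k >= 2 and respect the family rule", {
  uni <- paste0("g", 1:12)
  ann <- grid_annotation(uni, rep(c("1", "2", "3"), each = 4),
                         rep(seq(1e6, 4e6, by = 1e6), 3))
  grp <- c("g1", "g2", "g3", "g5", "g6", "g9")  # chrom1: 3, chrom2: 2, chrom3: 1
  res <- localization_test(grp, ann, uni, n_rand = 50, seed = 4)
  expect_setequal(res$per_chromosome$chrom, c("1", "2"))
  expect_equal(attr(res$per_chromosome, "family_size"), 1L)  # only chrom 1 has >= 3
  expect_true(res$per_chromosome$in_family[res$per_chromosome$chrom == "1"])
  expect_false(res$per_chromosome$in_family[res$per_chromosome$chrom == "2"])
})

test_that("Bonferroni flags are monotone in alpha", {
  d <- planted_design(N = 30, clusters = list(
    list(genes = c("G001", "G002", "G003", "G004"), chrom = "7",
         start = 1e6, width = 6e5)))
  ann <- generate_annotation(d, seed = 5)
  res_lo <- localization_test(paste0("G00", 1:4), ann, d$gene_ids,
                              n_rand = 200, seed = 6, alpha = 0.01)
  res_hi <- localization_test(paste0("G00", 1:4), ann, d$gene_ids,
                              n_rand = 200, seed = 6, alpha = 0.2)
  flagged_lo <- res_lo$per_chromosome$bonferroni_significant
  flagged_hi <- res_hi$per_chromosome$bonferroni_significant
  expect_true(all(!flagged_lo | flagged_hi))  # raising alpha never unflags
})

test_that("z_x and z_d from 100 vs 10000 randomizations agree within Monte-Carlo error", {
  d <- planted_design(N = 30)
  ann <- generate_annotation(d, seed = 9)
  grp <- d$gene_ids[c(1, 4, 7, 10, 13, 16)]
  a <- localization_test(grp, ann, d$gene_ids, n_rand = 100, seed = 11)
  b <- localization_test(grp, ann, d$gene_ids, n_rand = 10000, seed = 12)
  expect_lt(abs(a$z_x - b$z_x), 0.6)
  expect_lt(abs(a$z_d - b$z_d), 0.6)
})
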