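# a minimal hand-built map: one chromosome, six 1-Mb bins
manual_binmap <- function(n_bins = 6, chrom = "chr01", size = 1e6) {
  bm <- data.frame(bin = sprintf("Bin%04d", seq_len(n_bins)), chrom = chrom,
                   start = (seq_len(n_bins) - 1) * size,
                   end = seq_len(n_bins) * size, size_bp = size)
  class(bm) <- c("bin_map", "data.frame")
  bm
}

test_that("the scan LOD matches a least-squares oracle and is affine invariant", {
  codes <- c(rep("AA", 4), rep("aa", 4))
  geno <- matrix(codes, 8, 1, dimnames = list(NULL, "Bin0001"))
  design <- genotype_design(geno)
  set.seed(6)
  y <- c(2, 2, 2, 2, 0, 0, 0, 0) + rnorm(8, sd = 0.01)
  bm <- manual_binmap(1)
  lod <- scan_trait(y, design, integer(0), bm)
  expect_equal(unname(lod), bf_lod(y, codes), tolerance = 1e-6)
  # affine transform leaves the profile unchanged
  lod2 <- scan_trait(3 * y + 100, design, integer(0), bm)
  expect_equal(lod, lod2, tolerance = 1e-9)
  # constant trait scans flat at zero
  expect_true(all(scan_trait(rep(5, 8), design, integer(0), bm) == 0))
})

test_that("scan handles monomorphic and two-class bins", {
  geno <- cbind(Bin0001 = rep("Aa", 10),
                Bin0002 = c(rep("AA", 5), rep("Aa", 5)),
                Bin0003 = c(rep("AA", 4), rep("Aa", 3), rep("aa", 3)))
  design <- genotype_design(geno)
  set.seed(2)
  y <- rnorm(10)
  lod <- scan_trait(y, design, integer(0), manual_binmap(3))
  expect_equal(unname(lod[1]), 0)          # single class: flagged flat
  expect_gte(lod[2], 0)
  expect_gte(lod[3], 0)
  expect_equal(unname(lod[3]), bf_lod(y, geno[, 3]), tolerance = 1e-8)
})

test_that("LOD profiles match the oracle on a simulated population", {
  study <- recovery_study(n_traits = 5, a = 1, d = 0, seed = 1)
  design <- genotype_design(study$geno)
  bm <- study$binmap
  for (i in 1:3) {
    y <- study$expr$values[i, ]
    lod <- scan_trait(y, design, integer(0), bm)
    for (b in c(1, 10, nrow(bm))) {
      expect_equal(unname(lod[b]), bf_lod(y, study$geno[, b]),
                   tolerance = 1e-8)
    }
    expect_true(all(lod >= 0))
  }
})

test_that("cofactor selection finds determinants and resists pure noise", {
  study <- null_study(n_traits = 100, seed = 31)
  design <- genotype_design(study$geno)
  # a trait exactly determined by one bin: that bin is picked first
  b <- 25
  y_det <- design$x[, b] * 2 + 10
  cof <- select_cofactors(y_det, design, 3)
  expect_equal(cof[1], b)
  # pure-noise traits select an empty set >= 90% of the time
  n_empty <- sum(vapply(1:100, function(i)
    length(select_cofactors(study$expr$values[i, ], design, 3)) == 0,
    logical(1)))
  expect_gte(n_empty, 90)
  # max_cofactors = 0 degenerates to simple interval mapping
  expect_length(select_cofactors(y_det, design, 0), 0)
  expect_length(select_cofactors(rep(1, design$n), design, 3), 0)
})

test_that("permutation thresholds are deterministic with quantile edge cases", {
  study <- recovery_study(n_traits = 5, a = 1, d = 0, seed = 1)
  design <- genotype_design(study$geno)
  y <- study$expr$values[1, ]
  p1 <- permutation_threshold(y, design, integer(0), study$binmap,
                              n_perm = 50, seed = 42)
  p2 <- permutation_threshold(y, design, integer(0), study$binmap,
                              n_perm = 50, seed = 42)
  expect_identical(p1$threshold, p2$threshold)
  expect_identical(p1$p_value, p2$p_value)
  # alpha = 1 -> the smallest permuted maximum
  pa <- permutation_threshold(y, design, integer(0), study$binmap,
                              n_perm = 50, alpha = 1, seed = 42)
  expect_equal(pa$threshold, min(pa$perm_max))
  expect_error(permutation_threshold(y, design, integer(0), study$binmap,
                                     n_perm = 0), "n_perm")
})

test_that("BH selection reproduces the hand-stepped procedure", {
  expect_equal(fdr_across_traits(c(0.001, 0.02, 0.04, 0.6), q = 0.05),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(fdr_across_traits(rep(1, 5)), rep(FALSE, 5))
  expect_equal(fdr_across_traits(rep(1e-6, 5)), rep(TRUE, 5))
})

test_that("peak calling separates maxima and resolves plateaus to lower coordinates", {
  bm <- manual_binmap(6)
  pk <- call_peaks(c(0, 6, 0, 0, 7, 0), threshold = 5, bm, min_sep = 2)
  expect_equal(pk$bin_index, c(2, 5))
  expect_equal(nrow(call_peaks(rep(4, 6), threshold = 5, bm)), 0)
  # plateau of equal maxima -> single peak at the lowest coordinate
  pk2 <- call_peaks(c(0, 6, 6, 6, 0, 0), threshold = 5, bm)
  expect_equal(pk2$bin_index, 2)
  # close maxima without a deep valley collapse onto the higher one
  pk3 <- call_peaks(c(0, 6, 5.5, 7, 0, 0), threshold = 5, bm, min_sep = 5)
  expect_equal(pk3$bin_index, 4)
  # a 1.5-LOD valley splits even close maxima
  pk4 <- call_peaks(c(0, 6, 3, 7, 0, 0), threshold = 5, bm, min_sep = 5)
  expect_equal(pk4$bin_index, c(2, 4))
})

test_that("support intervals follow the LOD-drop rule with one-bin extension", {
  bm <- manual_binmap(5)
  ci <- support_interval(c(1, 3, 5, 3, 1), 3, bm, drop = 1.5)
  expect_equal(c(ci$bin_lo, ci$bin_hi), c(2, 4))   # core {3} extended by 1
  expect_equal(ci$start_bp, bm$start[2])
  expect_equal(ci$end_bp, bm$end[4])
  # peak at the chromosome end clips there
  ci2 <- support_interval(c(1, 2, 3, 4, 5), 5, bm, drop = 1.5)
  expect_equal(ci2$bin_hi, 5)
  expect_equal(ci2$bin_lo, 3)
  # a drop exceeding the peak spans everything plus flanks
  ci3 <- support_interval(c(1, 3, 5, 3, 1), 3, bm, drop = 10)
  expect_equal(c(ci3$bin_lo, ci3$bin_hi), c(1, 5))
  # widening the drop never shrinks the interval; peak always inside
  for (drop in c(0.5, 1.5, 3)) {
    ci_d <- support_interval(c(1, 3, 5, 3, 1), 3, bm, drop)
    expect_lte(ci_d$bin_lo, 3); expect_gte(ci_d$bin_hi, 3)
  }
})

test_that("variance explained matches the least-squares oracle", {
  codes <- c(rep("AA", 30), rep("Aa", 40), rep("aa", 28))
  x <- (codes == "AA") - (codes == "aa"); z <- (codes == "Aa") * 1
  # noise-free planted effect explains everything
  expect_equal(variance_explained(10 + 2 * x - z, codes), 1)
  set.seed(7)
  y <- 10 + x + rnorm(98)
  fit <- lm(y ~ x + z)
  r2_oracle <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  expect_equal(variance_explained(y, codes), r2_oracle, tolerance = 1e-10)
  expect_warning(variance_explained(y, rep("AA", 98)), "genotype classes")
  expect_warning(variance_explained(rep(3, 98), codes), "zero-variance")
})

test_that("local and distant QTLs are classified by interval and distance", {
  bm <- manual_binmap(6)       # 1-Mb bins on chr01
  ci <- list(bin_lo = 2, bin_hi = 3, start_bp = 1e6, end_bp = 3e6)
  expect_equal(classify_local_distant(2, ci, "chr01", 1.5e6, bm), "local")
  expect_equal(classify_local_distant(2, ci, "chr02", 1.5e6, bm), "distant")
  # 240 kb beyond the peak bin boundary is still local; 260 kb is not
  expect_equal(classify_local_distant(2, list(bin_lo = 2, bin_hi = 2,
                                              start_bp = 1e6, end_bp = 2e6),
                                      "chr01", 2e6 + 240e3, bm), "local")
  expect_equal(classify_local_distant(2, list(bin_lo = 2, bin_hi = 2,
                                              start_bp = 1e6, end_bp = 2e6),
                                      "chr01", 2e6 + 260e3, bm), "distant")
})

test_that("scan_population maps planted QTLs end to end", {
  study <- recovery_study(n_traits = 12, a = 1.5, d = 0, seed = 5)
  tm <- study_trait_matrix(study)
  res <- scan_population(tm, study$geno, study$binmap,
                         scan_config(n_perm = 100, seed = 2))
  expect_true(all(res$traits$p_value > 0) & all(res$traits$p_value <= 1))
  expect_gte(sum(res$traits$significant), 10)
  expect_true(all(res$qtl$r2 >= 0 & res$qtl$r2 <= 1))
  expect_true(all(res$qtl$ci_lo_bin <= res$qtl$bin_index &
                    res$qtl$ci_hi_bin >= res$qtl$bin_index))
  # rerunning with the same config reproduces the table exactly
  res2 <- scan_population(tm, study$geno, study$binmap,
                          scan_config(n_perm = 100, seed = 2))
  expect_identical(res$qtl, res2$qtl)
})
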