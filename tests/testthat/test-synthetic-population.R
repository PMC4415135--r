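test_that("zero recombination yields single-founder RILs and determinism holds", {
  layout <- genome_layout(data.frame(name = "chr01", length = 1e6))
  cfg0 <- sim_config(seed = 3, n_rils = 10, n_imf2 = 5,
                     rec_rate_cM_per_Mb = 0)
  rils <- simulate_ril_genomes(layout, 10, cfg0)
  for (r in rils) {
    expect_equal(nrow(r$chr01), 1)
    expect_true(r$chr01$founder %in% c("ZS", "MH"))
  }
  # same seed twice -> identical breakpoint lists
  again <- simulate_ril_genomes(layout, 10, cfg0)
  expect_identical(rils, again)
})

test_that("founder allele frequency is near one half across many RILs", {
  layout <- genome_layout(data.frame(name = "chr01", length = 1e6))
  cfg <- sim_config(seed = 11, n_rils = 1000, n_imf2 = 2,
                    rec_rate_cM_per_Mb = 2)
  rils <- simulate_ril_genomes(layout, 1000, cfg)
  for (pos in c(1e5, 5e5, 9e5)) {
    frac_zs <- mean(vapply(rils, function(r)
      founder_at(r, "chr01", pos) == "ZS", logical(1)))
    expect_gt(frac_zs, 0.45)
    expect_lt(frac_zs, 0.55)
  }
  # RILs are fully homozygous mosaics by construction: segments tile [0, L)
  for (r in rils[1:50]) {
    seg <- r$chr01
    expect_equal(seg$start[1], 0)
    expect_equal(seg$end[nrow(seg)], 1e6)
    if (nrow(seg) > 1) {
      expect_equal(seg$start[-1], seg$end[-nrow(seg)])
      # merged representation: consecutive segments alternate founder
      expect_true(all(seg$founder[-1] != seg$founder[-nrow(seg)]))
    }
  }
})

test_that("IMF2 genotypes follow the paired-cross definition", {
  zs <- manual_ril("ZS", numeric(0))
  mh <- manual_ril("MH", numeric(0))
  mix <- manual_ril(c("ZS", "MH"), 5e5)
  binmap <- derive_bin_map(list(zs, mh, mix),
                           genome_layout(data.frame(name = "chr01",
                                                    length = 1e6)))
  g <- imf2_genotypes(list(zs, mh, mix), rbind(c(1, 1 + 2), c(1, 2), c(2, 3)),
                      binmap)
  # pair (zs, mix): AA left of the breakpoint, Aa right of it
  expect_equal(unname(g[1, ]), c("AA", "Aa"))
  # pair (zs, mh): Aa everywhere
  expect_equal(unname(g[2, ]), c("Aa", "Aa"))
  # pair (mh, mix): Aa then aa
  expect_equal(unname(g[3, ]), c("Aa", "aa"))
  expect_error(imf2_genotypes(list(zs, mh), rbind(c(1, 3)), binmap),
               "missing RIL")
  expect_error(imf2_genotypes(list(zs, mh), rbind(c(2, 2)), binmap),
               "distinct")
})

test_that("random pairings give Mendelian genotype frequencies", {
  layout <- genome_layout(data.frame(name = "chr01", length = 1e6))
  cfg <- sim_config(seed = 11, n_rils = 1000, n_imf2 = 2,
                    rec_rate_cM_per_Mb = 2)
  rils <- simulate_ril_genomes(layout, 1000, cfg)
  binmap <- derive_bin_map(rils, layout)
  set.seed(21)
  pairing <- draw_pairing(1000, 500)
  g <- imf2_genotypes(rils, pairing, binmap)
  freq <- c(mean(g == "AA"), mean(g == "Aa"), mean(g == "aa"))
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 0.07))
  # heterozygosity converges to one half across many pairings
  expect_lt(abs(mean(g == "Aa") - 0.5), 0.05)
})

test_that("bin maps tile the genome and genotypes never change inside a bin", {
  layout <- genome_layout(data.frame(name = "chr01", length = 4e7))
  # single shared breakpoint at 10 Mb
  rils <- list(manual_ril(c("ZS", "MH"), 1e7, 4e7),
               manual_ril(c("MH", "ZS"), 1e7, 4e7))
  bm <- derive_bin_map(rils, layout)
  expect_equal(bm$start, c(0, 1e7))
  expect_equal(bm$end, c(1e7, 4e7))
  # no breakpoints -> one bin per chromosome
  bm1 <- derive_bin_map(list(manual_ril("ZS", numeric(0), 4e7)), layout)
  expect_equal(nrow(bm1), 1)
  # random panel: brute-force check that no segment boundary is inside a bin
  layout2 <- genome_layout(data.frame(name = c("chr01", "chr02"),
                                      length = c(5e6, 3e6)))
  cfg <- sim_config(seed = 4, n_rils = 15, n_imf2 = 5,
                    rec_rate_cM_per_Mb = 10)
  rils2 <- simulate_ril_genomes(layout2, 15, cfg)
  bm2 <- derive_bin_map(rils2, layout2)
  for (r in rils2) {
    for (nm in names(r)) {
      internal <- r[[nm]]$start[-1]
      bins <- bm2[bm2$chrom == nm, ]
      # every founder switch must sit exactly on a bin boundary
      expect_true(all(internal %in% bins$start))
    }
  }
})

test_that("planted effects force the genotype group means", {
  study <- recovery_study(n_traits = 4, a = 3, d = 0, seed = 77)
  geno <- study$geno
  arch <- study$arch
  arch$noise_sd <- 1e-9
  noiseless <- simulate_expression(arch, geno, study$config)
  for (i in seq_len(4)) {
    b <- arch$effects$bin[arch$effects$trait_id == arch$traits$trait_id[i]]
    y <- noiseless$values[i, ]
    codes <- geno[, b]
    expect_equal(mean(y[codes == "AA"]), 13, tolerance = 1e-6)
    expect_equal(mean(y[codes == "Aa"]), 10, tolerance = 1e-6)
    expect_equal(mean(y[codes == "aa"]), 7, tolerance = 1e-6)
  }
  # negative dominance pushes the heterozygote below both homozygotes
  arch$effects$a <- 3
  arch$effects$d <- -4
  over <- simulate_expression(arch, geno, study$config)
  b <- arch$effects$bin[1]
  y <- over$values[1, ]
  codes <- geno[, b]
  expect_equal(mean(y[codes == "Aa"]), 6, tolerance = 1e-6)
  expect_lt(mean(y[codes == "Aa"]), mean(y[codes == "AA"]))
  expect_lt(mean(y[codes == "Aa"]), mean(y[codes == "aa"]))
})

test_that("null architectures show no genotype effect for most traits", {
  study <- null_study(n_traits = 100, seed = 31)
  geno <- study$geno
  set.seed(1)
  bins <- sample(colnames(geno), 100, replace = TRUE)
  p <- vapply(seq_len(100), function(i) {
    anova(lm(study$expr$values[i, ] ~ factor(geno[, bins[i]])))$`Pr(>F)`[1]
  }, numeric(1))
  expect_gte(mean(p > 0.01), 0.95)
})

test_that("regression on true genotypes recovers planted additive and dominance effects", {
  study <- recovery_study(n_traits = 200, a = 1, d = -0.5, seed = 13)
  geno <- study$geno
  ok <- vapply(seq_len(200), function(i) {
    b <- study$arch$effects$bin[i]
    y <- study$expr$values[i, ]
    x <- (geno[, b] == "AA") - (geno[, b] == "aa")
    z <- (geno[, b] == "Aa") * 1
    fit <- summary(lm(y ~ x + z))$coefficients
    abs(fit["x", 1] - 1) <= 3 * fit["x", 2] &&
      abs(fit["z", 1] - (-0.5)) <= 3 * fit["z", 2]
  }, logical(1))
  expect_gte(mean(ok), 0.9)   # joint 3-se coverage of both effects
  # estimator consistency: bias well under 0.05 on average
  est <- vapply(seq_len(200), function(i) {
    b <- study$arch$effects$bin[i]
    y <- study$expr$values[i, ]
    e <- estimate_effects(y, geno[, b])
    c(e$a, e$d)
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - 1), 0.05)
  expect_lt(abs(mean(est[2, ]) - (-0.5)), 0.05)
})
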