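hot_binmap <- function() {
  bm <- data.frame(bin = sprintf("Bin%04d", 1:5),
                   chrom = c("chr01", "chr01", "chr01", "chr02", "chr02"),
                   start = c(0, 1e5, 2e6, 0, 1e6),
                   end = c(1e5, 2e6, 3e6, 1e6, 2e6))
  bm$size_bp <- bm$end - bm$start
  class(bm) <- c("bin_map", "data.frame")
  bm
}

test_that("per-bin densities count anchors and divide by Mb", {
  bm <- hot_binmap()
  anchors <- data.frame(chrom = c(rep("chr01", 5), "chr02"),
                        pos = c(rep(5e4, 5), 1.5e6))
  track <- density_per_bin(anchors, bm)
  expect_equal(track$count, c(5, 0, 0, 0, 1))
  expect_equal(track$density[1], 50)             # 5 anchors in a 0.1-Mb bin
  expect_equal(track$density[2], 0)
  expect_error(density_per_bin(data.frame(chrom = "chr09", pos = 1), bm),
               "unknown chromosome")
  # counting oracle under random placement
  set.seed(18)
  rnd <- data.frame(chrom = sample(c("chr01", "chr02"), 300, TRUE),
                    pos = sample.int(2e6, 300))
  rnd$pos[rnd$chrom == "chr01"] <- sample.int(3e6,
                                              sum(rnd$chrom == "chr01"))
  tr <- density_per_bin(rnd, bm)
  for (k in 1:5) {
    expect_equal(tr$count[k],
                 sum(rnd$chrom == bm$chrom[k] & rnd$pos >= bm$start[k] &
                       rnd$pos < bm$end[k]))
  }
})

test_that("hotspot flags use a strict multiple of the genome average", {
  bm <- hot_binmap()
  track <- structure(data.frame(bm, count = c(31, 10, 10, 10, 10),
                                size_mb = bm$size_bp / 1e6),
                     class = c("density_track", "data.frame"))
  track$density <- track$count / track$size_mb
  attr(track, "genome_avg") <- 10
  track$density <- c(31, 10, 10, 10, 10)         # densities per Mb directly
  flags <- call_hotspots(track, 3)
  expect_true(flags[1])                          # 31 > 30
  track$density[1] <- 30
  expect_false(call_hotspots(track, 3)[1])       # exactly 30 is not a hotspot
  # raising the multiplier never adds hotspots; rescaling counts changes nothing
  set.seed(6)
  rnd <- structure(data.frame(bm, count = rpois(5, 20),
                              size_mb = bm$size_bp / 1e6),
                   class = c("density_track", "data.frame"))
  rnd$density <- rnd$count / rnd$size_mb
  attr(rnd, "genome_avg") <- sum(rnd$count) / sum(rnd$size_mb)
  f2 <- call_hotspots(rnd, 2); f3 <- call_hotspots(rnd, 3)
  expect_true(all(f2 | !f3))
  scaled <- rnd
  scaled$density <- rnd$density * 7
  attr(scaled, "genome_avg") <- attr(rnd, "genome_avg") * 7
  expect_equal(call_hotspots(scaled, 2), f2)
})

test_that("consecutive hotspot runs never cross chromosome boundaries", {
  bm <- hot_binmap()
  runs <- consecutive_hotspots(c(TRUE, TRUE, FALSE, TRUE, TRUE), bm)
  expect_equal(nrow(runs), 2)
  expect_equal(runs$bin_lo, c(1, 4))
  expect_equal(runs$bin_hi, c(2, 5))
  expect_equal(runs$chrom, c("chr01", "chr02"))
  # a run that would span chr01|chr02 splits at the boundary
  runs2 <- consecutive_hotspots(c(FALSE, TRUE, TRUE, TRUE, FALSE), bm)
  expect_equal(nrow(runs2), 2)
  expect_equal(runs2$n_bins, c(2, 1))
  expect_equal(nrow(consecutive_hotspots(rep(FALSE, 5), bm)), 0)
})

test_that("within-group correlations behave at the exact and null limits", {
  set.seed(10)
  base <- rnorm(98)
  vals <- rbind(t1 = base, t2 = base, t3 = -base, t4 = rnorm(98))
  cors <- pairwise_correlations(vals, rep("g1", 4))
  r <- function(i, j) cors$r[cors$trait_i == i & cors$trait_j == j]
  expect_equal(r("t1", "t2"), 1)
  expect_equal(r("t1", "t3"), -1)
  expect_equal(nrow(cors), 6)
  # zero-variance traits are skipped with a message
  vals2 <- rbind(vals, t5 = rep(1, 98))
  expect_message(c2 <- pairwise_correlations(vals2, rep("g1", 5)),
                 "zero-variance")
  expect_equal(nrow(c2), 6)
  # independent traits: mean r near zero over many pairs
  set.seed(11)
  nv <- matrix(rnorm(98 * 128), 128, 98,
               dimnames = list(paste0("n", 1:128), NULL))
  nc <- pairwise_correlations(nv, rep(paste0("grp", 1:8), each = 16))
  expect_gt(nrow(nc), 900)
  expect_lt(abs(mean(nc$r)), 0.01)
})

test_that("the simulated |r| threshold approaches the analytic critical value", {
  r98 <- simulation_threshold(98, n_sims = 4e4, seed = 3)
  expect_lt(abs(r98 - analytic_r_crit(98)), 0.01)
  # monotone decreasing in the sample count; deterministic under a seed
  r26 <- simulation_threshold(26, n_sims = 2e4, seed = 3)
  r50 <- simulation_threshold(50, n_sims = 2e4, seed = 3)
  expect_true(r26 > r50 && r50 > r98)
  expect_identical(simulation_threshold(50, n_sims = 5e3, seed = 4),
                   simulation_threshold(50, n_sims = 5e3, seed = 4))
})

test_that("correlation classes split at +/-0.3 inclusively", {
  expect_equal(classify_correlations(c(0.31, -0.29, -0.30, 0.30, 0)),
               c("strong-positive", "none", "strong-negative",
                 "strong-positive", "none"))
})

test_that("co-regulation classes combine QTL classes and peak distance", {
  q <- function(class, chrom, mid) list(class = class, chrom = chrom,
                                        peak_start = mid - 5e4,
                                        peak_end = mid + 5e4)
  expect_equal(coregulation_classify(q("distant", "chr01", 1e6),
                                     q("distant", "chr01", 2.5e6)),
               "nearby-distant")                     # 1.5 Mb apart
  expect_equal(coregulation_classify(q("distant", "chr01", 1e6),
                                     q("distant", "chr01", 3.5e6)),
               "far-distant")                        # 2.5 Mb apart
  expect_equal(coregulation_classify(q("distant", "chr01", 1e6),
                                     q("distant", "chr02", 1e6)),
               "far-distant")
  expect_equal(coregulation_classify(q("local", "chr03", 1e6),
                                     q("local", "chr03", 1.2e6)),
               "shared-local")
  expect_equal(coregulation_classify(q("local", "chr03", 1e6),
                                     q("distant", "chr05", 1e6)),
               "mixed")
})
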