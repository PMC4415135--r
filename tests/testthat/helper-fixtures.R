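# Shared fixtures and independent brute-force oracles. Fixtures are built
# once per test run and memoised, so the expensive simulations are shared
# across test files.

tiny_layout <- function() {
  genome_layout(
    data.frame(name = c("chr01", "chr02"), length = c(1e6, 8e5)),
    genes = data.frame(gene_id = c("gA", "gB"),
                       chrom = c("chr01", "chr01"),
                       strand = c("+", "-"),
                       start = c(5000, 40000), end = c(7000, 43000),
                       te = c(FALSE, TRUE)),
    exons = data.frame(gene_id = c("gA", "gA", "gB"),
                       start = c(5000, 6500, 40000),
                       end = c(5500, 7000, 43000)))
}

# manual two-RIL genomes for definition-level genotype tests
manual_ril <- function(founders, breaks, length_bp = 1e6) {
  # founders: labels per segment; breaks: internal breakpoints
  bounds <- c(0, breaks, length_bp)
  list(chr01 = data.frame(start = bounds[-length(bounds)],
                          end = bounds[-1], founder = founders))
}

scan_layout <- function() {
  set.seed(5)
  simulate_genome_layout(n_chrom = 4, chrom_length_bp = 25e6,
                         genes_per_chrom = 20)
}

# coarse-map population used for planted-QTL recovery tests (~33 bins)
recovery_study <- local({
  cache <- new.env(parent = emptyenv())
  function(prop_local = 1, a = 1, d = 0, n_traits = 100, seed = 1L) {
    key <- paste(prop_local, a, d, n_traits, seed, sep = "|")
    if (is.null(cache[[key]])) {
      cfg <- sim_config(seed = seed, n_rils = 24L, n_imf2 = 98L,
                        rec_rate_cM_per_Mb = 0.6, n_generations = 8L)
      cache[[key]] <- simulate_imf2_study(
        scan_layout(), cfg,
        arch_fn = function(bm, ly)
          random_architecture(bm, ly, n_traits = n_traits,
                              prop_local = prop_local, a = a, d = d,
                              mu = 10, noise = "normal", noise_sd = 1))
    }
    cache[[key]]
  }
})

# dense-map population (~200 bins) used for null-calibration tests
null_study <- local({
  cache <- new.env(parent = emptyenv())
  function(n_traits = 200, seed = 1L) {
    key <- paste(n_traits, seed, sep = "|")
    if (is.null(cache[[key]])) {
      cfg <- sim_config(seed = seed, n_rils = 24L, n_imf2 = 98L,
                        rec_rate_cM_per_Mb = 3.5, n_generations = 8L)
      cache[[key]] <- simulate_imf2_study(
        scan_layout(), cfg,
        arch_fn = function(bm, ly)
          random_architecture(bm, ly, n_traits = n_traits, prop_local = 1,
                              a = 0, d = 0, mu = 10, noise = "normal",
                              noise_sd = 1))
    }
    cache[[key]]
  }
})

study_trait_matrix <- function(study) {
  trait_matrix(study$expr$values,
               study$arch$traits[, c("trait_id", "chrom", "pos", "length")],
               "sRNA-RPM")
}

toy_srna <- function(starts = c(100, 150, 5000), lengths = c(21, 24, 24),
                     counts = NULL, chrom = "chr01", totals = NULL) {
  n <- length(starts)
  if (is.null(counts))
    counts <- matrix(c(5, 3, 2, 1, 8, 4), nrow = n)[seq_len(n), , drop = FALSE]
  if (is.null(totals)) totals <- rep(2e6, ncol(counts))
  names(totals) <- colnames(counts) <- paste0("lib", seq_len(ncol(counts)))
  srna_table(records = data.frame(srna_id = paste0("s", seq_len(n)),
                                  chrom = chrom, start = starts,
                                  strand = "+", length = lengths,
                                  category = "shared"),
             counts = counts, library_totals = totals)
}

small_pipeline_config <- function(seed = 5L) {
  pipeline_config(
    seed = seed,
    layout = list(n_chrom = 2, chrom_length_bp = 15e6, genes_per_chrom = 15),
    population = list(n_rils = 16L, n_imf2 = 40L, rec_rate_cM_per_Mb = 3),
    architecture = list(n_traits = 16L, prop_local = 0.75, a = 4, d = -1.5,
                        mu = 20, noise = "negbin", dispersion = 0.02),
    scan = list(n_perm = 60L, max_cofactors = 2L))
}

# ---- independent brute-force oracles ------------------------------------

bf_coverage <- function(table, chrom, len) {
  cov <- numeric(len)
  rec <- table$records
  tot <- rowSums(table$counts)
  for (i in which(rec$chrom == chrom)) {
    span <- (rec$start[i] + 1):(rec$start[i] + rec$length[i])
    cov[span] <- cov[span] + tot[i]
  }
  cov
}

bf_islands <- function(cov, min_cov) {
  # per-position run scan on a plain numeric vector (1-based positions)
  above <- cov >= min_cov
  out <- NULL
  i <- 1
  while (i <= length(above)) {
    if (above[i]) {
      j <- i
      while (j < length(above) && above[j + 1]) j <- j + 1
      out <- rbind(out, c(i - 1, j))   # 0-based half-open
      i <- j + 1
    } else i <- i + 1
  }
  out
}

bf_merge <- function(islands, max_gap) {
  # islands: matrix (start, end) sorted; transitive union by pairwise pass
  n <- nrow(islands)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        gap <- max(islands[j, 1] - islands[i, 2],
                   islands[i, 1] - islands[j, 2])
        if (gap <= max_gap && grp[i] != grp[j]) {
          grp[grp == grp[j]] <- grp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed || n < 2) break
  }
  t(vapply(unique(grp), function(g) {
    c(min(islands[grp == g, 1]), max(islands[grp == g, 2]))
  }, numeric(2)))
}

# closed-form single-marker regression LOD on additive+dominance codes
bf_lod <- function(y, codes) {
  n <- length(y)
  x <- (codes == "AA") - (codes == "aa")
  z <- (codes == "Aa") * 1
  rss_red <- sum((y - mean(y))^2)
  fit <- lm(y ~ x + z)
  rss_full <- sum(residuals(fit)^2)
  (n / 2) * log10(rss_red / rss_full)
}

analytic_r_crit <- function(n, alpha = 0.05) {
  t <- qt(1 - alpha / 2, df = n - 2)
  t / sqrt(t^2 + n - 2)
}
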