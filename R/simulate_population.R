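#' Simulation configuration for the IMF2 population generator
#'
#' Bundles every knob of the population and expression simulator. The
#' defaults describe the study design the package targets: 98 hybrids from
#' paired crosses of 196 homozygous recombinant inbred lines (RILs), with a
#' recombination rate calibrated so that the union-of-breakpoints bin map
#' has on the order of 1500 bins genome-wide.
#'
#' @param seed master RNG seed; every random draw derives from it.
#' @param n_rils number of RILs to simulate.
#' @param n_imf2 number of hybrids made by pairing RILs.
#' @param rec_rate_cM_per_Mb recombination rate; crossovers per meiosis are
#'   Poisson with mean `length_Mb * rate / 100` (Haldane, no interference).
#' @param n_generations selfing generations of single-seed descent before
#'   the line is fixed (residual heterozygosity is resolved to zero).
#' @param library_size_range range (min, max) of simulated total
#'   genome-mapped reads per library.
#' @param thresholds a [threshold_bundle()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_rils = 196L, n_imf2 = 98L,
                       rec_rate_cM_per_Mb = 1.3, n_generations = 8L,
                       library_size_range = c(15e6, 28e6),
                       thresholds = threshold_bundle()) {
  assert_that(n_rils >= 2, "need at least two RILs")
  assert_that(n_imf2 <= choose(n_rils, 2),
              "n_imf2 exceeds the number of distinct RIL pairs")
  assert_that(rec_rate_cM_per_Mb >= 0, "recombination rate must be >= 0")
  structure(list(seed = as.integer(seed), n_rils = as.integer(n_rils),
                 n_imf2 = as.integer(n_imf2),
                 rec_rate_cM_per_Mb = rec_rate_cM_per_Mb,
                 n_generations = as.integer(n_generations),
                 library_size_range = library_size_range,
                 thresholds = thresholds),
            class = "sim_config")
}

# One meiotic product of a pair of haplotypes on one chromosome.
# Haplotypes are data.frames (start, end, founder) tiling [0, L).
# Crossover count ~ Poisson(L_Mb * rate / 100); positions uniform (Haldane).
.gamete <- function(h1, h2, length_bp, rate_cM_per_Mb) {
  n_xo <- stats::rpois(1, length_bp / 1e6 * rate_cM_per_Mb / 100)
  phase <- sample.int(2, 1)
  if (n_xo == 0) return(if (phase == 1) h1 else h2)
  cuts <- sort(unique(round(stats::runif(n_xo, 1, length_bp - 1))))
  bounds <- c(0, cuts, length_bp)
  segs <- vector("list", length(bounds) - 1)
  for (k in seq_along(segs)) {
    src <- if ((phase + k) %% 2 == 0) h1 else h2
    s <- bounds[k]; e <- bounds[k + 1]
    keep <- src$end > s & src$start < e
    piece <- src[keep, , drop = FALSE]
    piece$start <- pmax(piece$start, s)
    piece$end <- pmin(piece$end, e)
    segs[[k]] <- piece
  }
  .merge_segments(do.call(rbind, segs))
}

.merge_segments <- function(seg) {
  if (nrow(seg) <= 1) {
    rownames(seg) <- NULL
    return(seg)
  }
  keep <- c(TRUE, seg$founder[-1] != seg$founder[-nrow(seg)])
  grp <- cumsum(keep)
  out <- data.frame(start = tapply(seg$start, grp, min),
                    end = tapply(seg$end, grp, max),
                    founder = seg$founder[keep])
  rownames(out) <- NULL
  out
}

#' Simulate homozygous RIL genomes by single seed descent
#'
#' Starting from the F1 of the two founders (labelled `ZS` and `MH`), each
#' line is selfed for `config$n_generations` generations with Haldane
#' crossovers at each meiosis, then fixed to full homozygosity (residual
#' heterozygous segments are resolved to one haplotype). Each RIL genome is
#' a founder mosaic: per chromosome a table of segments `(start, end,
#' founder)`.
#'
#' @param layout a [genome_layout()].
#' @param n number of RILs (>= 2).
#' @param config a [sim_config()]; only the recombination rate, generation
#'   count and seed are used.
#' @return A list of `n` RIL genomes; each is a named list of per-chromosome
#'   segment data.frames.
#' @export
simulate_ril_genomes <- function(layout, n, config = sim_config()) {
  assert_that(n >= 2, "need n >= 2 RILs")
  assert_that(all(layout$chromosomes$length > 0),
              "zero-length chromosome in layout")
  chroms <- layout$chromosomes
  with_seed(config$seed, {
    lapply(seq_len(n), function(i) {
      genome <- lapply(seq_len(nrow(chroms)), function(c) {
        L <- chroms$length[c]
        h1 <- data.frame(start = 0, end = L, founder = "ZS")
        h2 <- data.frame(start = 0, end = L, founder = "MH")
        for (g in seq_len(config$n_generations)) {
          n1 <- .gamete(h1, h2, L, config$rec_rate_cM_per_Mb)
          n2 <- .gamete(h1, h2, L, config$rec_rate_cM_per_Mb)
          h1 <- n1; h2 <- n2
        }
        h1   # fix the line: take one haplotype, fully homozygous
      })
      names(genome) <- chroms$name
      genome
    })
  })
}

# Founder label of one RIL at (chrom, pos); pos is 0-based.
founder_at <- function(ril, chrom, pos) {
  seg <- ril[[chrom]]
  i <- findInterval(pos, seg$start)
  assert_that(all(i >= 1) && all(pos < seg$end[i]), "position outside chromosome")
  seg$founder[i]
}

#' Derive the bin map from a panel of RIL genomes
#'
#' Bins are the intervals between the union of all RIL breakpoints on each
#' chromosome: within a bin no sampled recombination occurred, so every RIL
#' (and therefore every IMF2 hybrid) has a constant genotype across the bin.
#' Bin ids are assigned genome-wide in genomic order (`Bin0001`, ...).
#'
#' @param rils list of RIL genomes from [simulate_ril_genomes()].
#' @param layout the [genome_layout()] the RILs were simulated on.
#' @return data.frame of class `bin_map` with columns `bin`, `chrom`,
#'   `start`, `end` (0-based half-open), `size_bp`.
#' @export
derive_bin_map <- function(rils, layout) {
  assert_that(length(rils) >= 1, "need at least one RIL")
  chroms <- layout$chromosomes
  out <- lapply(seq_len(nrow(chroms)), function(c) {
    nm <- chroms$name[c]; L <- chroms$length[c]
    cuts <- sort(unique(unlist(lapply(rils, function(r) {
      s <- r[[nm]]$start
      s[s > 0]
    }))))
    bounds <- c(0, cuts, L)
    data.frame(chrom = nm, start = bounds[-length(bounds)], end = bounds[-1])
  })
  bins <- do.call(rbind, out)
  bins <- data.frame(bin = sprintf("Bin%04d", seq_len(nrow(bins))), bins)
  bins$size_bp <- bins$end - bins$start
  class(bins) <- c("bin_map", "data.frame")
  bins
}

#' Draw RIL pairings for an IMF2 population
#'
#' Pairs are sampled without replacement from the set of unordered distinct
#' RIL pairs; individual RILs may appear in several pairs (as in real paired
#' crossing designs when hybrids outnumber lines / 2).
#'
#' @param n_rils number of available RILs.
#' @param n_imf2 number of hybrids.
#' @return two-column integer matrix of RIL indices, one row per hybrid.
#' @export
draw_pairing <- function(n_rils, n_imf2) {
  assert_that(n_imf2 <= choose(n_rils, 2),
              "more hybrids requested than distinct RIL pairs")
  if (2L * n_imf2 <= n_rils) {
    idx <- sample.int(n_rils, 2L * n_imf2)
    return(matrix(idx, ncol = 2))
  }
  all_pairs <- t(utils::combn(n_rils, 2))
  all_pairs[sample.int(nrow(all_pairs), n_imf2), , drop = FALSE]
}

#' IMF2 genotypes at bin-map resolution
#'
#' Crosses the paired RILs in silico: the hybrid genotype at a locus is `AA`
#' when both parental RILs carry the Zhenshan 97 (`ZS`) founder allele, `aa`
#' when both carry Minghui 63 (`MH`), and `Aa` otherwise. The `A` allele is
#' by convention the Zhenshan 97 allele, so effect signs downstream are
#' relative to the ZS genotype.
#'
#' @param rils list of RIL genomes.
#' @param pairing integer matrix from [draw_pairing()] (or supplied
#'   explicitly), one row `(i, j)` per hybrid, `i != j`.
#' @param binmap a [derive_bin_map()] result.
#' @return character matrix hybrids x bins with values `AA`/`Aa`/`aa`;
#'   rownames `IMF2_###`, colnames the bin ids.
#' @export
imf2_genotypes <- function(rils, pairing, binmap) {
  pairing <- as.matrix(pairing)
  assert_that(all(pairing >= 1 & pairing <= length(rils)),
              "pairing references a missing RIL")
  assert_that(all(pairing[, 1] != pairing[, 2]),
              "a pair must consist of two distinct RILs")
  mid <- (binmap$start + binmap$end) / 2
  # founder of every RIL at every bin (bin genotype is constant within bins)
  fo <- vapply(rils, function(r) {
    out <- character(nrow(binmap))
    for (nm in unique(binmap$chrom)) {
      ix <- which(binmap$chrom == nm)
      out[ix] <- founder_at(r, nm, mid[ix])
    }
    out
  }, character(nrow(binmap)))
  g1 <- t(fo[, pairing[, 1], drop = FALSE])
  g2 <- t(fo[, pairing[, 2], drop = FALSE])
  geno <- matrix("Aa", nrow(pairing), nrow(binmap))
  geno[g1 == "ZS" & g2 == "ZS"] <- "AA"
  geno[g1 == "MH" & g2 == "MH"] <- "aa"
  dimnames(geno) <- list(sprintf("IMF2_%03d", seq_len(nrow(pairing))),
                         binmap$bin)
  geno
}

#' Point genotype of an IMF2 hybrid
#'
#' @param rils list of RIL genomes.
#' @param pairing pairing matrix.
#' @param individual hybrid index (row of `pairing`).
#' @param chrom,pos genomic position (0-based).
#' @return `"AA"`, `"Aa"` or `"aa"`.
#' @export
imf2_genotype_at <- function(rils, pairing, individual, chrom, pos) {
  p <- pairing[individual, ]
  f1 <- founder_at(rils[[p[1]]], chrom, pos)
  f2 <- founder_at(rils[[p[2]]], chrom, pos)
  ifelse(f1 == "ZS" & f2 == "ZS", "AA",
         ifelse(f1 == "MH" & f2 == "MH", "aa", "Aa"))
}
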