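#' Additive/dominance design codes from a genotype matrix
#'
#' Codes each bin genotype as an additive score `x` (+1 for `AA`, 0 for
#' `Aa`, -1 for `aa`; `A` = Zhenshan 97 allele) and a dominance indicator
#' `z` (1 for `Aa`, else 0). Because IMF2 genotypes are fully observed at
#' bin resolution, interval mapping reduces to marker regression on these
#' two codes.
#'
#' @param geno character matrix individuals x bins of `AA`/`Aa`/`aa`.
#' @return An object of class `genotype_design` with elements `x`, `z`
#'   (numeric matrices), `codes`, `bins`, `n`.
#' @export
genotype_design <- function(geno) {
  assert_that(all(geno %in% c("AA", "Aa", "aa")), "invalid genotype code")
  x <- (geno == "AA") - (geno == "aa")
  z <- (geno == "Aa") * 1
  structure(list(x = x, z = z, codes = geno, bins = colnames(geno),
                 n = nrow(geno)),
            class = "genotype_design")
}

#' Genome-scan settings
#'
#' @param alpha genome-wide significance level of the per-trait permutation
#'   threshold.
#' @param q Benjamini-Hochberg FDR level across traits.
#' @param n_perm permutations per trait.
#' @param max_cofactors maximum forward-selected marker cofactors.
#' @param window_bp cofactors within this distance of the test bin are
#'   dropped from the model at that bin.
#' @param min_peak_sep peaks closer than this many bins merge unless a
#'   valley of at least `valley_lod` separates them.
#' @param valley_lod LOD drop between maxima that forces a split.
#' @param lod_drop support-interval LOD drop.
#' @param local_max_dist_bp local-QTL fallback distance from the peak bin.
#' @param h_test_perm permutations of the dominance (h) test.
#' @param seed master seed; per-trait streams are derived from it.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(alpha = 0.05, q = 0.05, n_perm = 1000L,
                        max_cofactors = 3L, window_bp = 10e6,
                        min_peak_sep = 5L, valley_lod = 1.5,
                        lod_drop = 1.5, local_max_dist_bp = 250e3,
                        h_test_perm = 1000L, seed = 1L) {
  assert_that(n_perm >= 1, "need at least one permutation")
  structure(list(alpha = alpha, q = q, n_perm = as.integer(n_perm),
                 max_cofactors = as.integer(max_cofactors),
                 window_bp = window_bp,
                 min_peak_sep = as.integer(min_peak_sep),
                 valley_lod = valley_lod, lod_drop = lod_drop,
                 local_max_dist_bp = local_max_dist_bp,
                 h_test_perm = as.integer(h_test_perm),
                 seed = as.integer(seed)),
            class = "scan_config")
}

#' Forward stepwise cofactor selection by modified BIC
#'
#' Selects marker cofactors on the additive codes only: at each step the
#' bin giving the largest residual-sum-of-squares reduction enters if it
#' lowers the selection criterion, up to `max_cofactors` bins. Because the
#' best bin is chosen among hundreds of candidates, the plain BIC penalty
#' `log(n)` would admit spurious markers for most null traits; the
#' modified BIC used in marker selection adds `2 log(B)` per term (`B` =
#' number of bins) to account for that multiplicity, leaving pure-noise
#' traits with an empty cofactor set with high probability. A
#' (near-)constant trait yields an empty set.
#'
#' @param y trait values (length n).
#' @param design a [genotype_design()].
#' @param max_cofactors maximum number of cofactor bins.
#' @return Integer vector of selected bin indices (possibly empty).
#' @export
select_cofactors <- function(y, design, max_cofactors = 3L) {
  n <- length(y)
  assert_that(max_cofactors < n / 10,
              "max_cofactors must be < n/10")
  if (stats::var(y) < 1e-12 || max_cofactors == 0) return(integer(0))
  X <- design$x
  B <- ncol(X)
  penalty <- log(n) + 2 * log(B)        # modified BIC per selected marker
  chosen <- integer(0)
  W <- matrix(1, n, 1)
  qrW <- qr(W)
  ry <- qr.resid(qrW, y)
  rss <- sum(ry^2)
  crit <- n * log(rss / n)
  while (length(chosen) < max_cofactors) {
    rX <- qr.resid(qrW, X)
    sxx <- colSums(rX^2)
    sxy <- as.vector(crossprod(rX, ry))
    red <- ifelse(sxx > 1e-10 * n, sxy^2 / sxx, 0)
    best <- unname(which.max(red))
    new_rss <- max(rss - red[best], rss * 1e-12, .Machine$double.xmin)
    new_crit <- n * log(new_rss / n) + (length(chosen) + 1) * penalty
    if (new_crit >= crit - 1e-8) break
    chosen <- c(chosen, best)
    W <- cbind(W, X[, best])
    qrW <- qr(W)
    ry <- qr.resid(qrW, y)
    rss <- sum(ry^2)
    crit <- new_crit
  }
  chosen
}

# Group test bins by the subset of cofactors retained at each bin:
# a cofactor is dropped at bins on its own chromosome within window_bp
# (midpoint distance). Returns list of (bins, cofactors) groups.
.cofactor_groups <- function(cofactors, binmap, window_bp) {
  B <- nrow(binmap)
  if (!length(cofactors)) {
    return(list(list(bins = seq_len(B), cofactors = integer(0))))
  }
  mid <- (binmap$start + binmap$end) / 2
  keep <- vapply(seq_len(B), function(b) {
    retained <- cofactors[!(binmap$chrom[cofactors] == binmap$chrom[b] &
                              abs(mid[cofactors] - mid[b]) <= window_bp)]
    paste(retained, collapse = ",")
  }, character(1))
  lapply(split(seq_len(B), keep), function(bins) {
    key <- keep[bins[1]]
    cf <- if (nzchar(key)) as.integer(strsplit(key, ",")[[1]]) else integer(0)
    list(bins = bins, cofactors = cf)
  })
}

# Vectorized composite-interval-mapping scan.
# Y: n x P matrix of trait vectors (columns can be permutations of one
# trait). Returns B x P LOD matrix, LOD = (n/2) log10(RSS_red / RSS_full),
# reduced model = intercept + retained cofactors, full model additionally
# has the additive and dominance codes of the test bin.
.scan_core <- function(Y, design, cofactors, binmap, window_bp) {
  n <- nrow(Y); P <- ncol(Y); B <- nrow(binmap)
  lod <- matrix(0, B, P)
  eps <- 1e-10 * n
  for (grp in .cofactor_groups(cofactors, binmap, window_bp)) {
    W <- cbind(rep(1, n),
               design$x[, grp$cofactors, drop = FALSE])
    qrW <- qr(W)
    Yr <- qr.resid(qrW, Y)
    rss_red <- colSums(Yr^2)
    Xr <- qr.resid(qrW, design$x[, grp$bins, drop = FALSE])
    Zr <- qr.resid(qrW, design$z[, grp$bins, drop = FALSE])
    a11 <- colSums(Xr^2); a22 <- colSums(Zr^2); a12 <- colSums(Xr * Zr)
    B1 <- crossprod(Xr, Yr)          # bins x P
    B2 <- crossprod(Zr, Yr)
    det <- a11 * a22 - a12^2
    two_df <- det > eps * pmax(a11, 1) * pmax(a22, 1)
    drop <- matrix(0, length(grp$bins), P)
    if (any(two_df)) {
      i <- which(two_df)
      drop[i, ] <- (a22[i] * B1[i, , drop = FALSE]^2 -
                      2 * a12[i] * B1[i, , drop = FALSE] *
                        B2[i, , drop = FALSE] +
                      a11[i] * B2[i, , drop = FALSE]^2) / det[i]
    }
    one_x <- !two_df & a11 > eps
    if (any(one_x)) {
      i <- which(one_x)
      drop[i, ] <- B1[i, , drop = FALSE]^2 / a11[i]
    }
    one_z <- !two_df & !one_x & a22 > eps
    if (any(one_z)) {
      i <- which(one_z)
      drop[i, ] <- B2[i, , drop = FALSE]^2 / a22[i]
    }
    rr <- matrix(rss_red, length(grp$bins), P, byrow = TRUE)
    drop <- pmin(drop, rr)
    full <- pmax(rr - drop, rr * 1e-12)
    l <- (n / 2) * log10(rr / full)
    l[rr < 1e-12] <- 0
    lod[grp$bins, ] <- l
  }
  lod
}

#' Composite interval mapping LOD profile for one trait
#'
#' Marker-regression CIM at bin resolution: at each bin the trait is
#' regressed on the additive and dominance codes of that bin plus the
#' selected cofactors, with cofactors within `window_bp` of the test bin
#' dropped. `LOD = (n/2) log10(RSS_reduced / RSS_full)`; the profile is
#' invariant to affine transforms of the trait.
#'
#' @param y trait values.
#' @param design a [genotype_design()].
#' @param cofactors integer bin indices from [select_cofactors()].
#' @param binmap the bin map.
#' @param window_bp cofactor exclusion window (bp).
#' @return Numeric LOD vector named by bin id.
#' @export
scan_trait <- function(y, design, cofactors = integer(0), binmap,
                       window_bp = 10e6) {
  assert_that(length(y) == design$n, "trait length != number of individuals")
  lod <- .scan_core(matrix(y, ncol = 1), design, cofactors, binmap,
                    window_bp)[, 1]
  names(lod) <- binmap$bin
  lod
}

#' Genome-wide permutation threshold and trait p-value
#'
#' Permutes the trait values across individuals, rescans (same cofactors),
#' and records the genome-wide maximum LOD of every permutation. The
#' threshold is the `1 - alpha` empirical quantile of the permuted maxima
#' and the trait-level p-value is `(1 + #{perm max >= observed max}) /
#' (1 + n_perm)`.
#'
#' @inheritParams scan_trait
#' @param n_perm number of permutations (>= 1).
#' @param alpha genome-wide significance level.
#' @param seed seed of this trait's permutation stream.
#' @return list with `threshold`, `p_value`, `obs_max`, `perm_max`.
#' @export
permutation_threshold <- function(y, design, cofactors = integer(0), binmap,
                                  n_perm = 1000L, alpha = 0.05,
                                  window_bp = 10e6, seed = 1L) {
  assert_that(n_perm >= 1, "n_perm must be >= 1")
  n <- length(y)
  obs <- max(.scan_core(matrix(y, ncol = 1), design, cofactors, binmap,
                        window_bp))
  perm_max <- with_seed(seed, {
    Y <- vapply(seq_len(n_perm), function(i) y[sample.int(n)], numeric(n))
    apply(.scan_core(Y, design, cofactors, binmap, window_bp), 2, max)
  })
  list(threshold = stats::quantile(perm_max, 1 - alpha, type = 1,
                                   names = FALSE),
       p_value = (1 + sum(perm_max >= obs)) / (1 + n_perm),
       obs_max = obs, perm_max = perm_max)
}

#' Benjamini-Hochberg significant trait set
#'
#' @param p_values per-trait permutation p-values.
#' @param q FDR level.
#' @return Logical vector: trait declared significant.
#' @export
fdr_across_traits <- function(p_values, q = 0.05) {
  assert_that(all(p_values > 0 & p_values <= 1), "p-values must be in (0, 1]")
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Call QTL peaks on a LOD profile
#'
#' Peaks are local maxima at or above the threshold, per chromosome.
#' Maxima closer than `min_sep` bins collapse onto the higher one (ties to
#' the lower coordinate) unless the profile dips at least `valley_lod`
#' below the lower of the two maxima between them.
#'
#' @param lod LOD vector over the bins of `binmap`.
#' @param threshold genome-wide threshold from [permutation_threshold()].
#' @param binmap the bin map.
#' @param min_sep minimum peak separation (bins).
#' @param valley_lod valley depth that always splits two maxima.
#' @return data.frame `bin_index`, `bin`, `lod`.
#' @export
call_peaks <- function(lod, threshold, binmap, min_sep = 5L,
                       valley_lod = 1.5) {
  out <- list()
  for (nm in unique(binmap$chrom)) {
    ix <- which(binmap$chrom == nm)
    l <- lod[ix]
    r <- rle(l)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    k <- length(r$values)
    is_max <- vapply(seq_len(k), function(j) {
      left <- if (j > 1) r$values[j - 1] else -Inf
      right <- if (j < k) r$values[j + 1] else -Inf
      r$values[j] >= threshold & r$values[j] > left & r$values[j] > right
    }, logical(1))
    cand <- starts[is_max]              # plateau -> lowest coordinate
    if (!length(cand)) next
    merged <- cand[1]
    for (c in cand[-1]) {
      last <- merged[length(merged)]
      between <- min(l[last:c])
      lower <- min(l[last], l[c])
      if ((c - last) < min_sep && between > lower - valley_lod) {
        # collapse: keep the higher (tie -> lower coordinate)
        if (l[c] > l[last]) merged[length(merged)] <- c
      } else {
        merged <- c(merged, c)
      }
    }
    out[[nm]] <- data.frame(bin_index = ix[merged],
                            bin = binmap$bin[ix[merged]],
                            lod = l[merged])
  }
  if (!length(out)) {
    return(data.frame(bin_index = integer(), bin = character(),
                      lod = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' LOD-drop support interval around a peak
#'
#' The contiguous run of bins around the peak whose LOD stays within
#' `drop` of the peak LOD, extended by one bin on each side and clipped at
#' the chromosome ends.
#'
#' @param lod LOD vector over the bins of `binmap`.
#' @param peak_index bin index of a called peak.
#' @param binmap the bin map.
#' @param drop LOD drop (default 1.5).
#' @return list `bin_lo`, `bin_hi` (bin indices), `start_bp`, `end_bp`.
#' @export
support_interval <- function(lod, peak_index, binmap, drop = 1.5) {
  ix <- which(binmap$chrom == binmap$chrom[peak_index])
  lo <- peak_index
  while (lo > min(ix) && lod[lo - 1] >= lod[peak_index] - drop) lo <- lo - 1
  hi <- peak_index
  while (hi < max(ix) && lod[hi + 1] >= lod[peak_index] - drop) hi <- hi + 1
  lo <- max(min(ix), lo - 1)            # one-bin extension, clipped
  hi <- min(max(ix), hi + 1)
  list(bin_lo = lo, bin_hi = hi,
       start_bp = binmap$start[lo], end_bp = binmap$end[hi])
}

#' Variance explained by the QTL at a bin
#'
#' `R^2 = 1 - RSS(mu + a x + d z) / TSS`; with all three genotype classes
#' the fit equals the genotype class means.
#'
#' @param y trait values.
#' @param codes genotype codes (`AA`/`Aa`/`aa`) at the peak bin.
#' @return R-squared in `[0, 1]`, or `NA` for a zero-variance trait or a
#'   monomorphic bin (with a warning).
#' @export
variance_explained <- function(y, codes) {
  if (length(unique(codes)) < 2) {
    warning("fewer than two genotype classes; R^2 undefined")
    return(NA_real_)
  }
  tss <- sum((y - mean(y))^2)
  if (tss < 1e-12) {
    warning("zero-variance trait; R^2 undefined")
    return(NA_real_)
  }
  fit <- stats::ave(y, codes)
  r2 <- 1 - sum((y - fit)^2) / tss
  min(max(r2, 0), 1)
}

#' Classify a QTL as local or distant
#'
#' Local means the trait's genomic anchor falls inside the support
#' interval, or lies no more than `max_dist` bp from the peak bin's nearest
#' boundary on the same chromosome; anything else — including any peak on
#' another chromosome — is distant.
#'
#' @param peak_index peak bin index.
#' @param interval a [support_interval()] result.
#' @param anchor_chrom,anchor_pos trait anchor.
#' @param binmap the bin map.
#' @param max_dist local fallback distance (default 250 kb).
#' @return `"local"` or `"distant"`.
#' @export
classify_local_distant <- function(peak_index, interval, anchor_chrom,
                                   anchor_pos, binmap, max_dist = 250e3) {
  if (anchor_chrom != binmap$chrom[peak_index]) return("distant")
  in_ci <- anchor_pos >= interval$start_bp & anchor_pos < interval$end_bp
  gap <- max(0, binmap$start[peak_index] - anchor_pos,
             anchor_pos - binmap$end[peak_index])
  if (in_ci || gap <= max_dist) "local" else "distant"
}

#' Map QTLs for every trait of an expression matrix
#'
#' The full per-trait pipeline: cofactor selection, CIM scan, permutation
#' threshold and p-value (per-trait RNG substream derived from the master
#' seed), BH FDR across traits, then — within significant traits — peak
#' calling at the trait's own threshold, support intervals, variance
#' explained, additive/dominance effects with the permutation h-test, and
#' local/distant plus dominance classification per QTL.
#'
#' @param tm a [trait_matrix()] of called traits.
#' @param geno genotype matrix individuals x bins (samples must match the
#'   columns of `tm`).
#' @param binmap the bin map.
#' @param config a [scan_config()].
#' @return list with `qtl` (one row per QTL) and `traits` (per-trait scan
#'   summary: `max_lod`, `threshold`, `p_value`, `significant`).
#' @export
scan_population <- function(tm, geno, binmap, config = scan_config()) {
  assert_that(ncol(tm$values) == nrow(geno),
              "samples of trait matrix and genotype matrix differ")
  design <- genotype_design(geno)
  m <- nrow(tm$values)
  traits <- data.frame(trait_id = tm$anchors$trait_id,
                       max_lod = NA_real_, threshold = NA_real_,
                       p_value = NA_real_, significant = FALSE)
  scans <- vector("list", m)
  cofs <- vector("list", m)
  for (i in seq_len(m)) {
    y <- tm$values[i, ]
    cofs[[i]] <- select_cofactors(y, design, config$max_cofactors)
    pt <- permutation_threshold(y, design, cofs[[i]], binmap,
                                n_perm = config$n_perm,
                                alpha = config$alpha,
                                window_bp = config$window_bp,
                                seed = derive_seed(config$seed, i))
    traits$max_lod[i] <- pt$obs_max
    traits$threshold[i] <- pt$threshold
    traits$p_value[i] <- pt$p_value
    scans[[i]] <- scan_trait(y, design, cofs[[i]], binmap,
                             config$window_bp)
  }
  traits$significant <- fdr_across_traits(traits$p_value, config$q)
  qtl <- list()
  for (i in which(traits$significant)) {
    y <- tm$values[i, ]
    lod <- scans[[i]]
    peaks <- call_peaks(lod, traits$threshold[i], binmap,
                        config$min_peak_sep, config$valley_lod)
    for (k in seq_len(nrow(peaks))) {
      b <- peaks$bin_index[k]
      ci <- support_interval(lod, b, binmap, config$lod_drop)
      codes <- geno[, b]
      eff <- estimate_effects(y, codes)
      p_dom <- if (is.na(eff$d)) NA_real_ else {
        h_test(y, codes, n_perm = config$h_test_perm,
               seed = derive_seed(config$seed + 7L, i * 1000L + k))
      }
      cls <- classify_local_distant(b, ci, tm$anchors$chrom[i],
                                    tm$anchors$pos[i], binmap,
                                    config$local_max_dist_bp)
      dom <- classify_dominance(eff, !is.na(p_dom) && p_dom < 0.05)
      qtl[[length(qtl) + 1]] <- data.frame(
        trait_id = tm$anchors$trait_id[i],
        trait_chrom = tm$anchors$chrom[i],
        trait_pos = tm$anchors$pos[i],
        bin_index = b, bin = binmap$bin[b],
        chrom = binmap$chrom[b],
        peak_start = binmap$start[b], peak_end = binmap$end[b],
        lod = peaks$lod[k],
        ci_lo_bin = ci$bin_lo, ci_hi_bin = ci$bin_hi,
        ci_start = ci$start_bp, ci_end = ci$end_bp,
        r2 = variance_explained(y, codes),
        a = eff$a, d = eff$d, p_dominance = p_dom,
        class = cls, dominance_class = dom)
    }
  }
  qtl <- if (length(qtl)) do.call(rbind, qtl) else data.frame(
    trait_id = character(), trait_chrom = character(),
    trait_pos = numeric(), bin_index = integer(), bin = character(),
    chrom = character(), peak_start = numeric(), peak_end = numeric(),
    lod = numeric(), ci_lo_bin = integer(), ci_hi_bin = integer(),
    ci_start = numeric(), ci_end = numeric(), r2 = numeric(),
    a = numeric(), d = numeric(), p_dominance = numeric(),
    class = character(), dominance_class = character())
  rownames(qtl) <- NULL
  list(qtl = qtl, traits = traits)
}
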