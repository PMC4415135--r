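#' Pairwise Pearson correlations within trait groups
#'
#' Computes the correlation between every pair of traits sharing a group
#' key — the same mother gene, the same sRNA cluster, or a trait paired
#' with its mother gene's e-trait. Zero-variance traits are skipped with a
#' message.
#'
#' @param values numeric matrix traits x samples.
#' @param groups grouping key per trait (character/factor); `NA` traits are
#'   ignored.
#' @return data.frame `group`, `trait_i`, `trait_j`, `n`, `r`.
#' @export
pairwise_correlations <- function(values, groups) {
  assert_that(nrow(values) == length(groups),
              "one group key per trait required")
  keep <- !is.na(groups)
  out <- list()
  for (g in unique(groups[keep])) {
    ix <- which(groups == g & keep)
    if (length(ix) < 2) next
    v <- apply(values[ix, , drop = FALSE], 1, stats::var)
    if (any(v < 1e-14)) {
      message(sprintf("group %s: skipping %d zero-variance trait(s)",
                      g, sum(v < 1e-14)))
      ix <- ix[v >= 1e-14]
      if (length(ix) < 2) next
    }
    cm <- stats::cor(t(values[ix, , drop = FALSE]))
    pr <- which(upper.tri(cm), arr.ind = TRUE)
    out[[length(out) + 1]] <- data.frame(
      group = g,
      trait_i = rownames(values)[ix[pr[, 1]]],
      trait_j = rownames(values)[ix[pr[, 2]]],
      n = ncol(values), r = cm[pr])
  }
  if (!length(out)) {
    return(data.frame(group = character(), trait_i = character(),
                      trait_j = character(), n = integer(), r = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlations between traits and their mother-gene e-traits
#'
#' @param trait_values traits x samples matrix (e.g. s-trait RPM).
#' @param gene_values e-traits x samples matrix (FPKM), rownames = gene
#'   ids.
#' @param mother_gene gene id per trait (`NA` = no mother gene).
#' @return data.frame `trait_id`, `gene_id`, `n`, `r`.
#' @export
mother_gene_correlations <- function(trait_values, gene_values,
                                     mother_gene) {
  keep <- which(!is.na(mother_gene) & mother_gene %in% rownames(gene_values))
  out <- lapply(keep, function(i) {
    y1 <- trait_values[i, ]
    y2 <- gene_values[mother_gene[i], ]
    if (stats::var(y1) < 1e-14 || stats::var(y2) < 1e-14) return(NULL)
    data.frame(trait_id = rownames(trait_values)[i],
               gene_id = mother_gene[i], n = length(y1),
               r = stats::cor(y1, y2))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(trait_id = character(), gene_id = character(),
                      n = integer(), r = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulation-based significance threshold for |r|
#'
#' The `1 - alpha` empirical quantile of `|r|` between independent
#' standard-normal vectors of the shared sample length — the null against
#' which observed expression correlations are judged. For large
#' simulation counts this converges to the analytic two-sided critical
#' Pearson correlation `t / sqrt(t^2 + n - 2)` with
#' `t = t_{1 - alpha/2, n - 2}`.
#'
#' @param n_samples shared sample count (>= 4).
#' @param n_sims number of simulated null pairs.
#' @param alpha significance level.
#' @param seed RNG seed.
#' @return The threshold `r*`.
#' @export
simulation_threshold <- function(n_samples, n_sims = 1e5, alpha = 0.05,
                                 seed = 1L) {
  assert_that(n_samples >= 4, "need at least 4 shared samples")
  with_seed(seed, {
    r <- abs(.null_correlations(n_samples, n_sims))
    stats::quantile(r, 1 - alpha, names = FALSE)
  })
}

# |r| under independence, computed in chunks to bound memory
.null_correlations <- function(n, n_sims, chunk = 20000L) {
  out <- numeric(0)
  left <- n_sims
  while (left > 0) {
    k <- min(chunk, left)
    X <- matrix(stats::rnorm(n * k), n, k)
    Y <- matrix(stats::rnorm(n * k), n, k)
    Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
    r <- colSums(Xc * Yc) /
      sqrt(colSums(Xc^2) * colSums(Yc^2))
    out <- c(out, r)
    left <- left - k
  }
  out
}

#' Classify correlations into strength classes
#'
#' `r >= strong_cut` is a strong positive correlation, `r <= -strong_cut`
#' strong negative, anything strictly inside the band is `none`. The
#' boundary itself counts as strong (inclusive).
#'
#' @param r correlation coefficients.
#' @param strong_cut dividing point (default 0.3).
#' @return Character vector in `{strong-negative, none, strong-positive}`.
#' @export
classify_correlations <- function(r, strong_cut = 0.3) {
  ifelse(r >= strong_cut, "strong-positive",
         ifelse(r <= -strong_cut, "strong-negative", "none"))
}

#' Co-regulation class of two mapped traits
#'
#' Two traits are `shared-local` when both their QTLs are local,
#' `nearby-distant` when both are distant on the same chromosome with peak
#' midpoints within `max_dist` (2 Mb), `far-distant` when both are distant
#' otherwise, and `mixed` when one is local and the other distant.
#'
#' @param qtl1,qtl2 one QTL record each (a list/row with `class`, `chrom`,
#'   `peak_start`, `peak_end`).
#' @param max_dist distance defining nearby distant-QTL pairs (bp).
#' @return The co-regulation class.
#' @export
coregulation_classify <- function(qtl1, qtl2, max_dist = 2e6) {
  loc1 <- qtl1$class == "local"; loc2 <- qtl2$class == "local"
  if (loc1 && loc2) return("shared-local")
  if (xor(loc1, loc2)) return("mixed")
  if (qtl1$chrom == qtl2$chrom) {
    m1 <- (qtl1$peak_start + qtl1$peak_end) / 2
    m2 <- (qtl2$peak_start + qtl2$peak_end) / 2
    if (abs(m1 - m2) <= max_dist) return("nearby-distant")
  }
  "far-distant"
}
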