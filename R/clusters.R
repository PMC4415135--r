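#' Pooled per-position sRNA coverage
#'
#' Coverage at a position is the sum, over all records overlapping it, of
#' that record's counts summed across every library — parents, F1 and
#' hybrids pooled together. Returned as one run-length-encoded track per
#' chromosome.
#'
#' @param table an [srna_table()].
#' @param chromosomes optional data.frame `name`,`length` fixing track
#'   lengths; defaults to the span of the records.
#' @return Named list of [S4Vectors::Rle] coverage vectors (1-based
#'   positions), one per chromosome.
#' @export
pooled_coverage <- function(table, chromosomes = NULL) {
  rec <- table$records
  tot <- rowSums(table$counts)
  chroms <- if (!is.null(chromosomes)) chromosomes$name else unique(rec$chrom)
  out <- lapply(chroms, function(nm) {
    i <- which(rec$chrom == nm)
    width <- if (!is.null(chromosomes))
      chromosomes$length[match(nm, chromosomes$name)]
    else if (length(i)) max(rec$start[i] + rec$length[i]) else 0
    if (!length(i)) return(S4Vectors::Rle(0L, width))
    ir <- IRanges::IRanges(start = rec$start[i] + 1,
                           width = rec$length[i])
    IRanges::coverage(ir, weight = tot[i], width = width)
  })
  names(out) <- chroms
  out
}

#' Find sRNA islands in a coverage track
#'
#' Islands are the maximal runs of consecutive positions whose pooled
#' coverage is at least `min_cov` (30x under the study defaults).
#'
#' @param cov named list of per-chromosome `Rle` tracks from
#'   [pooled_coverage()].
#' @param min_cov minimum per-position coverage (>= 1).
#' @return data.frame of class `island_set`: `chrom`, `start`, `end`
#'   (0-based half-open), sorted and disjoint.
#' @export
find_islands <- function(cov, min_cov = 30L) {
  assert_that(min_cov >= 1, "min_cov must be >= 1")
  out <- lapply(names(cov), function(nm) {
    ir <- IRanges::ranges(IRanges::slice(cov[[nm]], lower = min_cov,
                                         rangesOnly = FALSE))
    if (length(ir) == 0) {
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric()))
    }
    data.frame(chrom = nm, start = BiocGenerics::start(ir) - 1,
               end = BiocGenerics::end(ir))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("island_set", "data.frame")
  res
}

#' Merge nearby islands into sRNA clusters
#'
#' Islands on the same chromosome whose gap (next start minus previous end,
#' half-open coordinates) is at most `max_gap` are merged transitively; the
#' cluster span runs from the first member's start to the last member's
#' end. Cluster ids follow the `chrNN-start-end` convention using the
#' 0-based half-open span.
#'
#' @param islands an `island_set` from [find_islands()] (sorted, disjoint).
#' @param max_gap maximum merged gap in nt (default 1000).
#' @param min_span optional minimum cluster span filter (bp); no filter by
#'   default.
#' @return data.frame of class `cluster_set`: `cluster_id`, `chrom`,
#'   `start`, `end`, `n_islands`.
#' @export
merge_islands <- function(islands, max_gap = 1000L, min_span = 0L) {
  if (nrow(islands) == 0) {
    out <- data.frame(cluster_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_islands = integer())
    class(out) <- c("cluster_set", "data.frame")
    return(out)
  }
  by_chr <- split(islands, islands$chrom)
  ok <- vapply(by_chr, function(d) {
    !is.unsorted(d$start, strictly = TRUE) &&
      all(d$start[-1] >= d$end[-nrow(d)] | nrow(d) < 2)
  }, logical(1))
  assert_that(all(ok), "islands must be sorted and disjoint per chromosome")
  out <- lapply(by_chr, function(d) {
    gap <- c(Inf, d$start[-1] - d$end[-nrow(d)])
    grp <- cumsum(gap > max_gap)
    data.frame(chrom = d$chrom[1],
               start = tapply(d$start, grp, min),
               end = tapply(d$end, grp, max),
               n_islands = as.integer(table(grp)))
  })
  res <- do.call(rbind, out)
  res <- res[res$end - res$start >= min_span, , drop = FALSE]
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res <- data.frame(cluster_id = sprintf("%s-%d-%d", res$chrom,
                                         as.integer(res$start),
                                         as.integer(res$end)),
                    res)
  rownames(res) <- NULL
  class(res) <- c("cluster_set", "data.frame")
  res
}

#' Per-cluster, per-library read counts
#'
#' A record belongs to the cluster containing its anchor (5' start);
#' records outside every cluster contribute nothing.
#'
#' @param table an [srna_table()].
#' @param clusters a `cluster_set`.
#' @return Integer matrix clusters x libraries.
#' @export
quantify_clusters <- function(table, clusters) {
  counts <- matrix(0L, nrow(clusters), ncol(table$counts),
                   dimnames = list(clusters$cluster_id,
                                   colnames(table$counts)))
  rec <- table$records
  for (nm in unique(clusters$chrom)) {
    cl <- which(clusters$chrom == nm)
    ri <- which(rec$chrom == nm)
    if (!length(ri)) next
    hit <- findInterval(rec$start[ri], clusters$start[cl])
    inside <- hit >= 1 & rec$start[ri] < clusters$end[cl][pmax(hit, 1)]
    ri <- ri[inside]; hit <- hit[inside]
    if (!length(ri)) next
    add <- rowsum(table$counts[ri, , drop = FALSE], group = hit)
    counts[cl[as.integer(rownames(add))], ] <-
      counts[cl[as.integer(rownames(add))], , drop = FALSE] + add
  }
  counts
}

#' Median-of-ratios size factors and normalization
#'
#' The size factor of a library is the median, across clusters with
#' positive counts in every library, of the ratio between the library's
#' count and the cluster's geometric mean count. Normalized values are
#' counts divided by their library's factor. This is the effective-library-
#' size estimator of the DESeq family.
#'
#' @param counts integer matrix clusters x libraries.
#' @return `size_factors_median_of_ratios`: numeric vector of per-library
#'   factors.
#' @export
size_factors_median_of_ratios <- function(counts) {
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  assert_that(any(use),
    "no cluster has positive counts in every library; build more clusters")
  f <- apply(counts[use, , drop = FALSE], 2, function(cnt) {
    exp(stats::median(log(cnt) - log_geo[use]))
  })
  assert_that(all(f > 0), "non-positive size factor")
  f
}

#' @rdname size_factors_median_of_ratios
#' @param factors per-library size factors.
#' @return `normalize_counts`: the normalized matrix.
#' @export
normalize_counts <- function(counts, factors) {
  assert_that(length(factors) == ncol(counts), "one factor per library")
  sweep(counts, 2, factors, `/`)
}

#' Build, quantify and normalize sRNA clusters in one step
#'
#' Runs [pooled_coverage()], [find_islands()], [merge_islands()],
#' [quantify_clusters()] and median-of-ratios normalization with the
#' thresholds bundle, returning the cluster-normalized [trait_matrix()]
#' (pre-filter; apply [call_traits()] to obtain sc-traits).
#'
#' @param table an [srna_table()].
#' @param thresholds a [threshold_bundle()].
#' @param chromosomes optional chromosome table for the coverage tracks.
#' @return list with `islands`, `clusters`, `counts`, `size_factors`,
#'   `matrix` (a `trait_matrix` of kind `cluster-normalized`).
#' @export
build_clusters <- function(table, thresholds = threshold_bundle(),
                           chromosomes = NULL) {
  cov <- pooled_coverage(table, chromosomes)
  islands <- find_islands(cov, thresholds$island_coverage)
  clusters <- merge_islands(islands, thresholds$island_merge_gap_nt)
  counts <- quantify_clusters(table, clusters)
  sf <- size_factors_median_of_ratios(counts)
  norm <- normalize_counts(counts, sf)
  anchors <- data.frame(trait_id = clusters$cluster_id,
                        chrom = clusters$chrom, pos = clusters$start,
                        length = NA_integer_)
  list(islands = islands, clusters = clusters, counts = counts,
       size_factors = sf,
       matrix = trait_matrix(norm, anchors, "cluster-normalized"))
}
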