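#' Per-bin density of traits or QTLs
#'
#' Counts items whose anchor falls inside each bin and divides by the bin
#' size in Mb. QTLs are anchored at their peak bin, traits at their
#' genomic anchor. The genome-average density is the total item count over
#' the total genome size (Mb).
#'
#' @param anchors data.frame with `chrom`, `pos` (0-based anchor per item).
#' @param binmap the bin map (bins tile the genome).
#' @return data.frame of class `density_track`: the bin map columns plus
#'   `count`, `size_mb`, `density`, with the genome average in
#'   `attr(, "genome_avg")`.
#' @export
density_per_bin <- function(anchors, binmap) {
  count <- integer(nrow(binmap))
  for (nm in unique(anchors$chrom)) {
    bi <- which(binmap$chrom == nm)
    assert_that(length(bi) > 0, "anchor on unknown chromosome '%s'", nm)
    pos <- anchors$pos[anchors$chrom == nm]
    assert_that(all(pos >= binmap$start[bi[1]]) &&
                  all(pos < binmap$end[bi[length(bi)]]),
                "anchor outside the bin map on %s", nm)
    hit <- findInterval(pos, binmap$start[bi])
    count[bi] <- count[bi] + tabulate(hit, nbins = length(bi))
  }
  out <- data.frame(binmap, count = count,
                    size_mb = binmap$size_bp / 1e6)
  out$density <- out$count / out$size_mb
  attr(out, "genome_avg") <- sum(count) / sum(out$size_mb)
  class(out) <- c("density_track", "data.frame")
  out
}

#' Flag hotspot bins
#'
#' A bin is a hotspot when its density is strictly greater than
#' `multiplier` times the genome-average density. The study multipliers
#' are 3x for s-trait/e-trait hotspots, 6x for QTL hotspots and 2x for
#' sc-trait hotspots.
#'
#' @param track a [density_per_bin()] result.
#' @param multiplier positive density multiplier.
#' @return Logical vector of hotspot flags, one per bin.
#' @export
call_hotspots <- function(track, multiplier) {
  assert_that(multiplier > 0, "multiplier must be positive")
  track$density > multiplier * attr(track, "genome_avg")
}

#' Runs of consecutive hotspot bins
#'
#' Maximal runs of adjacent flagged bins on the same chromosome, reported
#' with their bp spans.
#'
#' @param flags logical vector from [call_hotspots()].
#' @param binmap the bin map.
#' @return data.frame `run_id`, `chrom`, `bin_lo`, `bin_hi`, `n_bins`,
#'   `start_bp`, `end_bp`.
#' @export
consecutive_hotspots <- function(flags, binmap) {
  runs <- list()
  for (nm in unique(binmap$chrom)) {
    ix <- which(binmap$chrom == nm)
    r <- rle(flags[ix])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      lo <- ix[starts[j]]; hi <- ix[ends[j]]
      runs[[length(runs) + 1]] <- data.frame(
        chrom = nm, bin_lo = lo, bin_hi = hi, n_bins = hi - lo + 1L,
        start_bp = binmap$start[lo], end_bp = binmap$end[hi])
    }
  }
  if (!length(runs)) {
    return(data.frame(run_id = integer(), chrom = character(),
                      bin_lo = integer(), bin_hi = integer(),
                      n_bins = integer(), start_bp = numeric(),
                      end_bp = numeric()))
  }
  out <- do.call(rbind, runs)
  data.frame(run_id = seq_len(nrow(out)), out)
}
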