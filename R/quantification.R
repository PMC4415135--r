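#' Expression-calling thresholds
#'
#' The inclusive expression thresholds and window sizes used throughout the
#' pipeline. An sRNA is expressed in a library at RPM >= 0.6, a cluster at
#' median-of-ratios normalized count >= 6, an mRNA at FPKM >= 1; an entity
#' expressed in more than `min_expressing_gt` hybrids (i.e. >= 26 of 98
#' under the defaults) becomes an expression trait. Islands require 30x
#' pooled coverage; islands within 1000 nt merge into one cluster; gene
#' context windows are 2 kb upstream of the TSS and 500 bp downstream.
#'
#' @param rpm_expressed,cluster_expressed,fpkm_expressed inclusive
#'   expression thresholds per kind.
#' @param min_expressing_gt a trait must be expressed in strictly more than
#'   this many samples.
#' @param island_coverage minimum pooled per-position coverage of an island.
#' @param island_merge_gap_nt maximum inter-island gap merged into one
#'   cluster.
#' @param upstream_bp,downstream_bp gene context window sizes.
#' @return A list of class `threshold_bundle`.
#' @export
threshold_bundle <- function(rpm_expressed = 0.6, cluster_expressed = 6,
                             fpkm_expressed = 1, min_expressing_gt = 25L,
                             island_coverage = 30L,
                             island_merge_gap_nt = 1000L,
                             upstream_bp = 2000L, downstream_bp = 500L) {
  vals <- c(rpm_expressed, cluster_expressed, fpkm_expressed,
            island_coverage, island_merge_gap_nt, upstream_bp, downstream_bp)
  assert_that(all(vals > 0), "all thresholds must be positive")
  structure(list(rpm_expressed = rpm_expressed,
                 cluster_expressed = cluster_expressed,
                 fpkm_expressed = fpkm_expressed,
                 min_expressing_gt = as.integer(min_expressing_gt),
                 island_coverage = as.integer(island_coverage),
                 island_merge_gap_nt = as.integer(island_merge_gap_nt),
                 upstream_bp = as.integer(upstream_bp),
                 downstream_bp = as.integer(downstream_bp)),
            class = "threshold_bundle")
}

# counts / (totals in millions), vectorized over the whole matrix
rpm_values <- function(counts, totals) {
  sweep(counts, 2, totals / 1e6, `/`)
}

#' Expression trait matrix
#'
#' Normalized trait-by-sample values of one kind (`sRNA-RPM`,
#' `cluster-normalized` or `mRNA-FPKM`) together with each trait's genomic
#' anchor.
#'
#' @param values non-negative numeric matrix traits x samples.
#' @param anchors data.frame with `trait_id`, `chrom`, `pos` (0-based
#'   anchor = forward-strand 5'-most coordinate), `length` (nt; NA for
#'   clusters/mRNAs).
#' @param kind one of `"sRNA-RPM"`, `"cluster-normalized"`, `"mRNA-FPKM"`.
#' @return An object of class `trait_matrix`.
#' @export
trait_matrix <- function(values, anchors,
                         kind = c("sRNA-RPM", "cluster-normalized",
                                  "mRNA-FPKM")) {
  kind <- match.arg(kind)
  assert_that(all(values >= 0), "expression values must be >= 0")
  assert_that(nrow(values) == nrow(anchors),
              "one anchor per trait required")
  rownames(values) <- anchors$trait_id
  structure(list(values = values, anchors = anchors, kind = kind),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix [%s]: %d traits x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Normalize an sRNA count table to RPM
#'
#' RPM of a record in a library is its count divided by the library's total
#' genome-mapped reads in millions. This is the pre-filter abundance matrix
#' from which s-traits are called.
#'
#' @param table an [srna_table()].
#' @return A [trait_matrix()] of kind `sRNA-RPM` covering every record.
#' @export
rpm_normalize <- function(table) {
  bad <- which(table$library_totals <= 0)
  assert_that(length(bad) == 0, "library '%s' has zero total reads",
              paste(names(table$library_totals)[bad], collapse = ","))
  vals <- rpm_values(table$counts, table$library_totals)
  anchors <- data.frame(trait_id = table$records$srna_id,
                        chrom = table$records$chrom,
                        pos = table$records$start,
                        length = table$records$length)
  trait_matrix(vals, anchors, "sRNA-RPM")
}

#' Which samples express an entity
#'
#' Expression is called at an inclusive threshold: `value >= threshold`.
#'
#' @param values numeric vector or matrix of normalized values.
#' @param threshold positive expression threshold.
#' @return Logical vector/matrix of the same shape.
#' @export
call_expressed <- function(values, threshold) {
  assert_that(threshold > 0, "threshold must be positive")
  values >= threshold
}

#' Call expression traits from a pre-filter matrix
#'
#' An entity becomes an expression trait when it is expressed (inclusive
#' threshold) in strictly more than `min_expressing_gt` samples — i.e. in
#' at least 26 of 98 hybrids under the study defaults. The same rule yields
#' s-traits, sc-traits and e-traits from their respective kinds.
#'
#' @param tm a [trait_matrix()] (pre-filter).
#' @param thresholds a [threshold_bundle()]; the threshold matching
#'   `tm$kind` is applied.
#' @return The filtered `trait_matrix` containing only retained traits.
#' @export
call_traits <- function(tm, thresholds = threshold_bundle()) {
  thr <- switch(tm$kind,
                "sRNA-RPM" = thresholds$rpm_expressed,
                "cluster-normalized" = thresholds$cluster_expressed,
                "mRNA-FPKM" = thresholds$fpkm_expressed)
  n_expr <- rowSums(call_expressed(tm$values, thr))
  keep <- n_expr > thresholds$min_expressing_gt
  trait_matrix(tm$values[keep, , drop = FALSE],
               tm$anchors[keep, , drop = FALSE], tm$kind)
}

#' Assign genomic region classes to trait anchors
#'
#' Each anchor receives exactly one primary class out of `exon`, `UTR`
#' (exonic but non-coding, only when CDS intervals are annotated),
#' `intron`, `upstream2kb`, `downstream500bp` or `intergenic`, with
#' precedence genic > upstream > downstream > intergenic and ties within a
#' level broken by distance to the nearest TSS. Upstream/downstream windows
#' are strand-aware (upstream = 5' of the TSS). Genic and flanking classes
#' additionally carry the gene's transposon flag.
#'
#' @param anchors data.frame with `trait_id`, `chrom`, `pos`.
#' @param layout a [genome_layout()].
#' @param thresholds a [threshold_bundle()] (window sizes).
#' @return data.frame `trait_id`, `region`, `te`, `gene_id`.
#' @export
annotate_trait_regions <- function(anchors, layout,
                                   thresholds = threshold_bundle()) {
  lens <- chrom_length(layout, anchors$chrom)
  assert_that(all(anchors$pos >= 0 & anchors$pos < lens),
              "anchor beyond chromosome end")
  g <- layout$genes
  n <- nrow(anchors)
  region <- rep("intergenic", n)
  te <- rep(NA, n)
  gene <- rep(NA_character_, n)
  if (nrow(g) == 0) {
    return(data.frame(trait_id = anchors$trait_id, region = region,
                      te = te, gene_id = gene))
  }
  tss <- ifelse(g$strand == "+", g$start, g$end - 1)
  up_s <- ifelse(g$strand == "+", g$start - thresholds$upstream_bp, g$end)
  up_e <- ifelse(g$strand == "+", g$start, g$end + thresholds$upstream_bp)
  dn_s <- ifelse(g$strand == "+", g$end, g$start - thresholds$downstream_bp)
  dn_e <- ifelse(g$strand == "+", g$end + thresholds$downstream_bp, g$start)
  pick <- function(pos, chrom, s, e) {
    hits <- which(g$chrom == chrom & pos >= s & pos < e)
    if (!length(hits)) return(NA_integer_)
    hits[which.min(abs(pos - tss[hits]))]
  }
  for (i in seq_len(n)) {
    p <- anchors$pos[i]; cm <- anchors$chrom[i]
    j <- pick(p, cm, g$start, g$end)
    if (!is.na(j)) {
      e <- layout$exons[layout$exons$gene_id == g$gene_id[j], , drop = FALSE]
      in_exon <- any(p >= e$start & p < e$end)
      if (in_exon && !is.null(layout$cds)) {
        cd <- layout$cds[layout$cds$gene_id == g$gene_id[j], , drop = FALSE]
        region[i] <- if (any(p >= cd$start & p < cd$end)) "exon" else "UTR"
      } else {
        region[i] <- if (in_exon) "exon" else "intron"
      }
    } else {
      j <- pick(p, cm, up_s, up_e)
      if (!is.na(j)) {
        region[i] <- "upstream2kb"
      } else {
        j <- pick(p, cm, dn_s, dn_e)
        if (!is.na(j)) region[i] <- "downstream500bp"
      }
    }
    if (!is.na(j)) {
      te[i] <- g$te[j]
      gene[i] <- g$gene_id[j]
    }
  }
  data.frame(trait_id = anchors$trait_id, region = region, te = te,
             gene_id = gene)
}

#' Size-class summary of retained sRNA traits
#'
#' @param tm a [trait_matrix()] whose anchors carry `length`.
#' @return data.frame `length`, `n`, `fraction` (fractions sum to 1).
#' @export
size_class_summary <- function(tm) {
  len <- tm$anchors$length
  tab <- table(factor(len, levels = sort(unique(len))))
  data.frame(length = as.integer(names(tab)), n = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab))
}
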