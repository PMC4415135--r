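#' Genome layout: chromosomes and gene annotation
#'
#' A `genome_layout` holds the coordinate frame for everything downstream:
#' chromosome names and lengths, plus a gene annotation table with exon (and
#' optionally CDS) structure and a transposon flag. All coordinates are
#' internal 0-based half-open; GFF3 conversion happens at the I/O boundary.
#'
#' @param chromosomes data.frame with columns `name`, `length` (bp > 0).
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (0-based half-open transcript span) and
#'   logical `te` (transposon-related). May have zero rows.
#' @param exons data.frame with columns `gene_id`, `start`, `end`; exons of a
#'   gene must be non-overlapping, ordered and within the gene span.
#' @param cds optional data.frame like `exons` giving coding intervals; used
#'   to split exonic anchors into CDS vs UTR.
#' @return An object of class `genome_layout`.
#' @export
genome_layout <- function(chromosomes, genes = empty_genes(), exons = empty_exons(),
                          cds = NULL) {
  chromosomes$name <- as.character(chromosomes$name)
  assert_that(nrow(chromosomes) >= 1, "need at least one chromosome")
  assert_that(all(chromosomes$length > 0),
              "chromosome lengths must be positive")
  assert_that(!anyDuplicated(chromosomes$name),
              "duplicated chromosome names")
  if (nrow(genes)) {
    genes$chrom <- as.character(genes$chrom)
    assert_that(all(genes$chrom %in% chromosomes$name),
                "gene on unknown chromosome")
    len <- chromosomes$length[match(genes$chrom, chromosomes$name)]
    assert_that(all(genes$start >= 0 & genes$end <= len & genes$start < genes$end),
                "gene interval outside chromosome bounds")
    assert_that(all(genes$strand %in% c("+", "-")), "bad strand")
    if (nrow(exons)) {
      assert_that(all(exons$gene_id %in% genes$gene_id),
                  "exon for unknown gene")
      sp <- split(exons, exons$gene_id)
      ok <- vapply(sp, function(e) {
        e <- e[order(e$start), , drop = FALSE]
        g <- genes[genes$gene_id == e$gene_id[1], ]
        all(e$start >= g$start) && all(e$end <= g$end) &&
          all(e$start < e$end) &&
          (nrow(e) < 2 || all(e$start[-1] >= e$end[-nrow(e)]))
      }, logical(1))
      assert_that(all(ok), "exons overlap, are unordered, or exceed gene span")
    }
  }
  structure(list(chromosomes = chromosomes, genes = genes,
                 exons = exons, cds = cds),
            class = "genome_layout")
}

empty_genes <- function() {
  data.frame(gene_id = character(), chrom = character(), strand = character(),
              start = numeric(), end = numeric(), te = logical())
}

empty_exons <- function() {
  data.frame(gene_id = character(), start = numeric(), end = numeric())
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosome(s), %.1f Mb, %d gene(s)\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
              nrow(x$genes)))
  invisible(x)
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chromosomes$name)
  assert_that(!anyNA(i), "unknown chromosome: %s",
              paste(chrom[is.na(i)], collapse = ", "))
  layout$chromosomes$length[i]
}

#' Simulate a compact genome layout with random gene models
#'
#' Draws non-overlapping two-exon gene models of the given span uniformly
#' along each chromosome. Intended for building test populations; the gene
#' density and structure are deliberately simple.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp length of every chromosome (bp).
#' @param genes_per_chrom gene models per chromosome.
#' @param gene_span_bp transcript span of each gene.
#' @param te_fraction fraction of genes flagged transposon-related.
#' @return A [genome_layout()].
#' @export
simulate_genome_layout <- function(n_chrom = 4, chrom_length_bp = 25e6,
                                   genes_per_chrom = 40, gene_span_bp = 4000,
                                   te_fraction = 0.25) {
  chroms <- data.frame(name = sprintf("chr%02d", seq_len(n_chrom)),
                       length = rep(chrom_length_bp, n_chrom))
  genes <- list(); exons <- list()
  for (c in seq_len(n_chrom)) {
    # lay genes on a jittered grid so they never overlap
    slot <- floor(chrom_length_bp / (genes_per_chrom + 1))
    start <- vapply(seq_len(genes_per_chrom), function(g) {
      (g - 1) * slot + 3000 +
        floor(stats::runif(1, 0, max(1, slot - gene_span_bp - 6000)))
    }, numeric(1))
    id <- sprintf("gene_%s_%03d", chroms$name[c], seq_len(genes_per_chrom))
    strand <- sample(c("+", "-"), genes_per_chrom, replace = TRUE)
    genes[[c]] <- data.frame(gene_id = id, chrom = chroms$name[c],
                             strand = strand, start = start,
                             end = start + gene_span_bp,
                             te = stats::runif(genes_per_chrom) < te_fraction)
    # two exons separated by an intron occupying the middle half of the span
    e1 <- data.frame(gene_id = id, start = start,
                     end = start + floor(gene_span_bp / 4))
    e2 <- data.frame(gene_id = id,
                     start = start + floor(3 * gene_span_bp / 4),
                     end = start + gene_span_bp)
    exons[[c]] <- rbind(e1, e2)
  }
  genome_layout(chroms, do.call(rbind, genes), do.call(rbind, exons))
}
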