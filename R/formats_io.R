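#' Position-resolved sRNA count table
#'
#' Container for aligned, size-filtered sRNA records and their per-library
#' counts. Each record carries its genomic anchor (0-based start of the
#' alignment, forward-strand minimum), length in nt, and an origin category
#' reflecting how the read mapped to the two parental SNP-replaced genomes:
#' `shared` (identical sequence in both parents, one count), `SNP-bearing`
#' (polymorphic site; the two allele-specific counts have been summed),
#' `ZS-only` or `MH-only` (parent-specific mapping).
#'
#' @param records data.frame with columns `srna_id`, `chrom`, `start`
#'   (0-based), `strand`, `length` (nt), `category`; an optional `sequence`
#'   column is kept when present (needed only for blocklist filtering).
#' @param counts integer matrix records x libraries, non-negative.
#' @param library_totals named numeric vector of total genome-mapped reads
#'   per library; must be >= the column sums of `counts`.
#' @return An object of class `srna_table`.
#' @export
srna_table <- function(records, counts, library_totals) {
  counts <- as.matrix(counts)
  assert_that(nrow(records) == nrow(counts),
              "records and count matrix disagree in length")
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "counts must be non-negative integers")
  assert_that(all(records$category %in%
                    c("shared", "SNP-bearing", "ZS-only", "MH-only")),
              "unknown origin category")
  if (is.null(colnames(counts)))
    colnames(counts) <- names(library_totals)
  assert_that(length(library_totals) == ncol(counts),
              "one library total per count column required")
  assert_that(all(colSums(counts) <= library_totals + 1e-8),
              "library totals smaller than column sums")
  rownames(counts) <- records$srna_id
  structure(list(records = records, counts = counts,
                 library_totals = library_totals),
            class = "srna_table")
}

#' @export
print.srna_table <- function(x, ...) {
  cat(sprintf("srna_table: %d records x %d libraries\n",
              nrow(x$records), ncol(x$counts)))
  invisible(x)
}

#' Filter sRNA records by size and sequence blocklist
#'
#' Retains records with `min_len <= length <= max_len` whose sequence (when
#' available) is not on the blocklist; reads shorter than 18 nt or longer
#' than 26 nt are excluded under the defaults. The blocklist is a generic
#' stand-in for removal of tRNA/rRNA/snRNA/snoRNA matches. Record order is
#' preserved and counts are never altered, only dropped with their record.
#'
#' @param table an [srna_table()].
#' @param min_len,max_len inclusive length bounds (nt).
#' @param blocklist character vector of sequences to exclude.
#' @return A filtered `srna_table` (possibly empty, with a warning).
#' @export
filter_srna_records <- function(table, min_len = 18L, max_len = 26L,
                                blocklist = character()) {
  assert_that(min_len <= max_len, "min_len must be <= max_len")
  keep <- table$records$length >= min_len & table$records$length <= max_len
  if (length(blocklist) && !is.null(table$records$sequence))
    keep <- keep & !(table$records$sequence %in% blocklist)
  if (!any(keep)) warning("no sRNA records left after filtering")
  srna_table(table$records[keep, , drop = FALSE],
             table$counts[keep, , drop = FALSE],
             table$library_totals)
}

#' Merge allele-specific counts by origin category
#'
#' At a polymorphic (SNP-bearing) site the reads carrying either parental
#' allele are the same sRNA, so the two allele-specific counts are summed;
#' at a monomorphic (shared) site there is a single indistinguishable count;
#' at a parent-specific site only that parent's count exists and the other
#' must be zero.
#'
#' @param zs_counts,mh_counts non-negative integer vectors of allele counts.
#' @param category per-locus origin category.
#' @return Combined count vector.
#' @export
merge_allelic_counts <- function(zs_counts, mh_counts, category) {
  assert_that(all(zs_counts >= 0) && all(mh_counts >= 0),
              "counts must be non-negative")
  n <- length(category)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- switch(category[i],
      "SNP-bearing" = zs_counts[i] + mh_counts[i],
      "shared" = {
        assert_that(zs_counts[i] == mh_counts[i],
                    "shared site %d carries two different counts", i)
        zs_counts[i]
      },
      "ZS-only" = {
        assert_that(mh_counts[i] == 0,
                    "ZS-only site %d has a Minghui 63 count", i)
        zs_counts[i]
      },
      "MH-only" = {
        assert_that(zs_counts[i] == 0,
                    "MH-only site %d has a Zhenshan 97 count", i)
        mh_counts[i]
      },
      stopf("unknown category '%s'", category[i]))
  }
  out
}

#' Build a SNP-replaced parental genome
#'
#' Substitutes the given parent's allele at every SNP position of the
#' reference, after verifying that the reference base at each site matches
#' the SNP table. Sequence lengths are preserved.
#'
#' @param reference a [Biostrings::DNAStringSet] (names = chromosomes).
#' @param snps data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `zs`, `mh`; bases in `A/C/G/T`.
#' @param parent `"ZS"` or `"MH"`.
#' @return A `DNAStringSet` with the parental bases substituted.
#' @export
build_snp_replaced_genome <- function(reference, snps, parent = c("ZS", "MH")) {
  parent <- match.arg(parent)
  assert_that(!anyDuplicated(paste(snps$chrom, snps$pos)),
              "duplicated SNP positions")
  out <- reference
  alt_col <- if (parent == "ZS") "zs" else "mh"
  for (nm in unique(snps$chrom)) {
    assert_that(nm %in% names(reference), "SNP on unknown sequence '%s'", nm)
    s <- snps[snps$chrom == nm, , drop = FALSE]
    assert_that(all(s$pos >= 1 & s$pos <= length(reference[[nm]])),
                "SNP position out of range on %s", nm)
    have <- as.character(Biostrings::extractAt(
      reference[[nm]], IRanges::IRanges(s$pos, s$pos)))
    bad <- which(have != s$ref)
    assert_that(length(bad) == 0,
                "reference base mismatch at %s:%d (have %s, SNP table says %s)",
                nm, s$pos[bad[1]], have[bad[1]], s$ref[bad[1]])
    out[[nm]] <- Biostrings::replaceLetterAt(
      reference[[nm]], s$pos, s[[alt_col]])
  }
  out
}

# ---- TSV / GFF3 / JSON round-trip helpers -------------------------------

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#", ...)
}

#' Read / write a genotype matrix (rows = individuals, columns = bins)
#' @param geno character matrix of `AA`/`Aa`/`aa` codes.
#' @param path file path.
#' @return `read_genotype_matrix` returns the character matrix.
#' @export
write_genotype_matrix <- function(geno, path) {
  df <- data.frame(individual = rownames(geno), geno, check.names = FALSE)
  .write_tsv(df, path)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$individual
  m
}

#' Read / write an sRNA count table
#'
#' Single TSV holding the record metadata columns followed by one count
#' column per library; library totals travel in a `# library_totals:`
#' comment line so the file round-trips losslessly.
#'
#' @param table an [srna_table()].
#' @param path file path.
#' @return `read_srna_table` returns the `srna_table`.
#' @export
write_srna_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# library_totals: ",
                    paste(sprintf("%s=%s", names(table$library_totals),
                                  format(table$library_totals, scientific = FALSE,
                                         trim = TRUE)),
                          collapse = ",")), con)
  df <- cbind(table$records, as.data.frame(table$counts, check.names = FALSE))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_srna_table
#' @export
read_srna_table <- function(path) {
  hdr <- readLines(path, n = 1)
  assert_that(startsWith(hdr, "# library_totals:"),
              "missing library_totals header in %s", path)
  kv <- strsplit(sub("^# library_totals: *", "", hdr), ",")[[1]]
  parts <- strsplit(kv, "=")
  totals <- as.numeric(vapply(parts, `[`, "", 2))
  names(totals) <- vapply(parts, `[`, "", 1)
  df <- .read_tsv(path)
  meta_cols <- intersect(c("srna_id", "chrom", "start", "strand", "length",
                           "category", "sequence"), colnames(df))
  counts <- as.matrix(df[, setdiff(colnames(df), meta_cols), drop = FALSE])
  srna_table(df[, meta_cols, drop = FALSE], counts, totals)
}

#' Read / write a numeric expression matrix as TSV
#' @param mat numeric matrix (traits x samples).
#' @param path file path.
#' @return `read_expression_matrix` returns the matrix.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(trait_id = rownames(mat), mat, check.names = FALSE)
  .write_tsv(df, path)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$trait_id
  m
}

#' Export / import a genome layout as GFF3
#'
#' Internal 0-based half-open coordinates are converted to GFF3's 1-based
#' closed convention at this boundary (start + 1, end unchanged).
#'
#' @param layout a [genome_layout()].
#' @param path GFF3 path.
#' @return `read_layout_gff3` returns a `genome_layout` (requires
#'   `chromosomes` because GFF3 does not carry sequence lengths).
#' @param chromosomes data.frame `name`,`length` for the reader.
#' @export
write_layout_gff3 <- function(layout, path) {
  g <- layout$genes
  feats <- list()
  if (nrow(g)) {
    feats$gene <- GenomicRanges::GRanges(
      g$chrom, IRanges::IRanges(g$start + 1, g$end), strand = g$strand,
      type = "gene", ID = g$gene_id, te = ifelse(g$te, "TRUE", "FALSE"))
    if (nrow(layout$exons)) {
      e <- layout$exons
      ec <- g$chrom[match(e$gene_id, g$gene_id)]
      es <- g$strand[match(e$gene_id, g$gene_id)]
      feats$exon <- GenomicRanges::GRanges(
        ec, IRanges::IRanges(e$start + 1, e$end), strand = es,
        type = "exon", Parent = e$gene_id)
    }
  }
  gr <- if (length(feats)) suppressWarnings(do.call(c, unname(feats)))
        else GenomicRanges::GRanges()
  GenomeInfoDb::seqlevels(gr) <- layout$chromosomes$name
  GenomeInfoDb::seqlengths(gr) <- layout$chromosomes$length
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_layout_gff3
#' @export
read_layout_gff3 <- function(path, chromosomes) {
  gr <- rtracklayer::import(path, format = "gff3")
  gg <- gr[gr$type == "gene"]
  genes <- data.frame(gene_id = as.character(gg$ID),
                      chrom = as.character(GenomeInfoDb::seqnames(gg)),
                      strand = as.character(BiocGenerics::strand(gg)),
                      start = BiocGenerics::start(gg) - 1,
                      end = BiocGenerics::end(gg),
                      te = as.character(gg$te) == "TRUE")
  ee <- gr[gr$type == "exon"]
  exons <- data.frame(gene_id = vapply(ee$Parent, `[`, "", 1),
                      start = BiocGenerics::start(ee) - 1,
                      end = BiocGenerics::end(ee))
  if (nrow(genes) == 0) genes <- empty_genes()
  if (nrow(exons) == 0) exons <- empty_exons()
  genome_layout(chromosomes, genes, exons)
}

#' Write the synthetic-study fixture bundle
#'
#' Emits the full set of on-disk artifacts for one simulated study:
#' genotype TSV, bin map TSV, sRNA count TSV (or expression matrix for
#' normal-noise simulations), FPKM TSV when mother genes were simulated,
#' GFF3 annotation, ground-truth JSON (every planted QTL) and the YAML
#' config. All files are plain text and re-readable losslessly.
#'
#' @param study result of [simulate_imf2_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture_bundle <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             binmap = file.path(dir, "binmap.tsv"),
             annotation = file.path(dir, "annotation.gff3"),
             truth = file.path(dir, "truth.json"),
             config = file.path(dir, "config.yaml"))
  write_genotype_matrix(study$geno, paths["genotypes"])
  .write_tsv(as.data.frame(study$binmap), paths["binmap"])
  write_layout_gff3(study$layout, paths["annotation"])
  if (!is.null(study$expr)) {
    if (!is.null(study$expr$srna)) {
      paths["srna"] <- file.path(dir, "srna_counts.tsv")
      write_srna_table(study$expr$srna, paths["srna"])
    } else {
      paths["values"] <- file.path(dir, "trait_values.tsv")
      write_expression_matrix(study$expr$values, paths["values"])
    }
    if (!is.null(study$expr$fpkm)) {
      paths["fpkm"] <- file.path(dir, "fpkm.tsv")
      write_expression_matrix(study$expr$fpkm, paths["fpkm"])
    }
  }
  truth <- list(seed = study$config$seed,
                traits = study$arch$traits %||% data.frame(),
                effects = study$arch$effects %||% data.frame(),
                noise = study$arch$noise %||% "none")
  jsonlite::write_json(truth, paths["truth"], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- unclass(study$config)
  cfg$thresholds <- unclass(cfg$thresholds)
  yaml::write_yaml(cfg, paths["config"])
  invisible(paths)
}

#' Read back a fixture bundle written by [write_fixture_bundle()]
#' @param dir the bundle directory.
#' @return list with `geno`, `binmap`, `layout`, `truth`, `config`, and
#'   whichever of `srna`, `values`, `fpkm` were written.
#' @export
read_fixture_bundle <- function(dir) {
  binmap <- .read_tsv(file.path(dir, "binmap.tsv"))
  class(binmap) <- c("bin_map", "data.frame")
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  chroms <- stats::aggregate(end ~ chrom, data = binmap, FUN = max)
  names(chroms) <- c("name", "length")
  out <- list(
    geno = read_genotype_matrix(file.path(dir, "genotypes.tsv")),
    binmap = binmap,
    layout = read_layout_gff3(file.path(dir, "annotation.gff3"), chroms),
    truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE),
    config = cfg)
  f <- file.path(dir, "srna_counts.tsv")
  if (file.exists(f)) out$srna <- read_srna_table(f)
  f <- file.path(dir, "trait_values.tsv")
  if (file.exists(f)) out$values <- read_expression_matrix(f)
  f <- file.path(dir, "fpkm.tsv")
  if (file.exists(f)) out$fpkm <- read_expression_matrix(f)
  out
}
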