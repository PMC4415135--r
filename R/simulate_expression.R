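#' QTL architecture: the simulator's ground truth
#'
#' Describes, per simulated trait, its genomic anchor, baseline level and
#' the loci acting on it. Each effect locus contributes
#' `a * x + d * z` to the expected trait value of an individual, where
#' `x = +1/0/-1` for genotypes `AA/Aa/aa` (A = Zhenshan 97 allele) and
#' `z = 1` for heterozygotes: `a` is the additive effect (half the
#' difference between homozygote means) and `d` the dominance effect
#' (heterozygote mean minus the homozygote midpoint).
#'
#' @param traits data.frame with columns `trait_id`, `chrom`, `pos`
#'   (0-based anchor), `length` (nt, sRNA size class), `mu` (baseline
#'   expected value on the expression scale).
#' @param effects data.frame with columns `trait_id`, `bin` (bin id in the
#'   bin map), `a`, `d`.
#' @param noise `"normal"` or `"negbin"`.
#' @param noise_sd residual standard deviation (normal noise).
#' @param dispersion negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); must be > 0.
#' @param coupling mother-gene coupling coefficient: the expected mRNA level
#'   of a trait's mother gene is `coupling` times the trait's genetic
#'   expectation plus an independent baseline.
#' @return A list of class `qtl_architecture`.
#' @export
qtl_architecture <- function(traits, effects, noise = c("normal", "negbin"),
                             noise_sd = 1, dispersion = 0.2, coupling = 0) {
  noise <- match.arg(noise)
  assert_that(dispersion > 0, "dispersion must be > 0")
  assert_that(all(effects$trait_id %in% traits$trait_id),
              "effect for unknown trait")
  structure(list(traits = traits, effects = effects, noise = noise,
                 noise_sd = noise_sd, dispersion = dispersion,
                 coupling = coupling),
            class = "qtl_architecture")
}

#' Draw a random QTL architecture over a bin map
#'
#' Plants one QTL per trait. Local traits are anchored inside their effect
#' bin; distant traits are anchored on a different chromosome than the
#' effect locus. Effect sizes are expressed in units of the residual
#' standard deviation.
#'
#' @param binmap a bin map.
#' @param layout the genome layout (anchors are placed within chromosome
#'   bounds).
#' @param n_traits number of traits.
#' @param prop_local fraction of traits whose QTL is local.
#' @param a,d additive and dominance effect (recycled across traits).
#' @param mu baseline expected value.
#' @param noise,noise_sd,dispersion,coupling passed to [qtl_architecture()].
#' @return A `qtl_architecture`.
#' @export
random_architecture <- function(binmap, layout, n_traits, prop_local = 1,
                                a = 1, d = 0, mu = 10,
                                noise = "normal", noise_sd = 1,
                                dispersion = 0.2, coupling = 0) {
  n_local <- round(n_traits * prop_local)
  is_local <- seq_len(n_traits) <= n_local
  bins <- sample.int(nrow(binmap), n_traits, replace = TRUE)
  a <- rep_len(a, n_traits); d <- rep_len(d, n_traits)
  chrom <- character(n_traits); pos <- numeric(n_traits)
  for (i in seq_len(n_traits)) {
    b <- bins[i]
    if (is_local[i]) {
      chrom[i] <- binmap$chrom[b]
      pos[i] <- floor(stats::runif(1, binmap$start[b], binmap$end[b] - 30))
    } else {
      other <- setdiff(unique(binmap$chrom), binmap$chrom[b])
      assert_that(length(other) > 0,
                  "distant traits need at least two chromosomes")
      chrom[i] <- sample(other, 1)
      pos[i] <- floor(stats::runif(1, 0, chrom_length(layout, chrom[i]) - 30))
    }
  }
  traits <- data.frame(trait_id = sprintf("trait_%04d", seq_len(n_traits)),
                       chrom = chrom, pos = pos,
                       length = sample(c(21L, 22L, 24L), n_traits, TRUE,
                                       prob = c(0.15, 0.1, 0.75)),
                       mu = rep_len(mu, n_traits))
  effects <- data.frame(trait_id = traits$trait_id,
                        bin = binmap$bin[bins], a = a, d = d)
  effects <- effects[effects$a != 0 | effects$d != 0, , drop = FALSE]
  qtl_architecture(traits, effects, noise = noise, noise_sd = noise_sd,
                   dispersion = dispersion, coupling = coupling)
}

# Expected trait values per individual: mu + sum over loci of a*x + d*z.
# Returns traits x individuals matrix.
expected_trait_values <- function(arch, geno) {
  tr <- arch$traits
  n <- nrow(geno)
  ev <- matrix(rep(tr$mu, each = n), nrow = nrow(tr), ncol = n, byrow = TRUE)
  rownames(ev) <- tr$trait_id
  if (nrow(arch$effects)) {
    x <- (geno == "AA") - (geno == "aa")
    z <- (geno == "Aa") * 1
    for (k in seq_len(nrow(arch$effects))) {
      e <- arch$effects[k, ]
      i <- match(e$trait_id, tr$trait_id)
      ev[i, ] <- ev[i, ] + e$a * x[, e$bin] + e$d * z[, e$bin]
    }
  }
  ev
}

#' Simulate expression data for an IMF2 population
#'
#' Draws trait values around the genetic expectation
#' `mu + sum(a * x + d * z)`. With `noise = "normal"` the values are
#' continuous on the expression scale (the model under which the genome
#' scan operates); with `noise = "negbin"` integer sRNA counts are drawn
#' per library with overdispersion, scaled by simulated library sizes, and
#' returned as an [srna_table()] alongside RPM-scale expectations.
#' Negative genetic expectations are clipped at zero with a warning.
#' Mother-gene mRNA (FPKM) levels are generated when the architecture's
#' `coupling` is non-zero, as `coupling * expectation + baseline + noise`.
#'
#' @param arch a [qtl_architecture()].
#' @param geno genotype matrix from [imf2_genotypes()].
#' @param config a [sim_config()] (library sizes, seed).
#' @param layout optional genome layout used to attach mother genes.
#' @return list with `values` (traits x individuals matrix on the
#'   expression scale), `expected` (the noise-free expectations), `counts`
#'   and `library_totals` (negbin noise only), `srna` (an `srna_table`,
#'   negbin only), `fpkm` (mother-gene matrix or NULL) and `arch`.
#' @export
simulate_expression <- function(arch, geno, config = sim_config(),
                                layout = NULL) {
  missing_bins <- setdiff(arch$effects$bin, colnames(geno))
  assert_that(length(missing_bins) == 0,
              "architecture references unknown bins: %s",
              paste(missing_bins, collapse = ", "))
  ev <- expected_trait_values(arch, geno)
  if (any(ev < 0)) {
    warning(sprintf("%d expected values < 0 clipped at 0", sum(ev < 0)))
    ev[ev < 0] <- 0
  }
  n <- ncol(ev); m <- nrow(ev)
  with_seed(config$seed + 1L, {
    if (arch$noise == "normal") {
      vals <- ev + matrix(stats::rnorm(m * n, sd = arch$noise_sd), m, n)
      counts <- NULL; totals <- NULL; srna <- NULL
    } else {
      totals <- round(stats::runif(n, config$library_size_range[1],
                                   config$library_size_range[2]))
      names(totals) <- rownames(geno)
      # ev is on the RPM scale; expected count = RPM * total / 1e6
      mu_cnt <- sweep(ev, 2, totals / 1e6, `*`)
      counts <- matrix(stats::rnbinom(m * n, mu = as.vector(mu_cnt),
                                      size = 1 / arch$dispersion), m, n)
      dimnames(counts) <- dimnames(ev)
      srna <- srna_table(records = data.frame(
                           srna_id = arch$traits$trait_id,
                           chrom = arch$traits$chrom,
                           start = arch$traits$pos,
                           strand = "+",
                           length = arch$traits$length,
                           category = "shared"),
                         counts = counts, library_totals = totals)
      vals <- rpm_values(counts, totals)
    }
    fpkm <- NULL
    if (arch$coupling != 0) {
      fpkm <- arch$coupling * ev +
        matrix(stats::rnorm(m * n, mean = 5, sd = arch$noise_sd), m, n)
      fpkm[fpkm < 0] <- 0
      rownames(fpkm) <- paste0("mother_", arch$traits$trait_id)
    }
    dimnames(vals) <- list(arch$traits$trait_id, rownames(geno))
    list(values = vals, expected = ev, counts = counts,
         library_totals = totals, srna = srna, fpkm = fpkm, arch = arch)
  })
}

#' Simulate a complete IMF2 study
#'
#' Convenience wrapper running the whole generator: RIL genomes, pairing,
#' bin map, IMF2 genotypes and expression data with the given architecture
#' builder. Everything derives from `config$seed`.
#'
#' @param layout genome layout.
#' @param config a [sim_config()].
#' @param arch_fn function `(binmap, layout) -> qtl_architecture`; called
#'   inside the seeded stream.
#' @return list with `rils`, `pairing`, `binmap`, `geno`, `expr`
#'   (see [simulate_expression()]) and `arch`.
#' @export
simulate_imf2_study <- function(layout, config = sim_config(),
                                arch_fn = NULL) {
  rils <- simulate_ril_genomes(layout, config$n_rils, config)
  binmap <- derive_bin_map(rils, layout)
  pairing <- with_seed(config$seed + 2L,
                       draw_pairing(config$n_rils, config$n_imf2))
  geno <- imf2_genotypes(rils, pairing, binmap)
  arch <- NULL; expr <- NULL
  if (!is.null(arch_fn)) {
    arch <- with_seed(config$seed + 3L, arch_fn(binmap, layout))
    expr <- simulate_expression(arch, geno, config, layout)
  }
  list(rils = rils, pairing = pairing, binmap = binmap, geno = geno,
       expr = expr, arch = arch, config = config, layout = layout)
}
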