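#' Additive and dominance effects at a QTL
#'
#' From the unweighted genotype-class means, the additive effect is half
#' the difference between the two homozygote means,
#' `a = (m_AA - m_aa) / 2` (positive when the Zhenshan 97 homozygote is
#' higher), and the dominance effect is the heterozygote mean minus the
#' homozygote midpoint, `d = m_Aa - (m_AA + m_aa) / 2`.
#'
#' @param y trait values.
#' @param codes genotype codes (`AA`/`Aa`/`aa`) at the peak bin.
#' @return list of class `effect_estimate`: `m_AA`, `m_Aa`, `m_aa`, `a`,
#'   `d` (`d = NA`, flagged via `complete = FALSE`, when a genotype class
#'   is absent; `a` additionally requires both homozygote classes).
#' @export
estimate_effects <- function(y, codes) {
  m_AA <- if (any(codes == "AA")) mean(y[codes == "AA"]) else NA_real_
  m_Aa <- if (any(codes == "Aa")) mean(y[codes == "Aa"]) else NA_real_
  m_aa <- if (any(codes == "aa")) mean(y[codes == "aa"]) else NA_real_
  complete <- !anyNA(c(m_AA, m_Aa, m_aa))
  a <- if (!is.na(m_AA) && !is.na(m_aa)) (m_AA - m_aa) / 2 else NA_real_
  d <- if (complete) m_Aa - (m_AA + m_aa) / 2 else NA_real_
  structure(list(m_AA = m_AA, m_Aa = m_Aa, m_aa = m_aa, a = a, d = d,
                 complete = complete),
            class = "effect_estimate")
}

#' Permutation test of the dominance effect (h-test)
#'
#' Tests `d = 0` while leaving the additive signal intact: the statistic
#' is the observed dominance effect; the null distribution is generated by
#' permuting the residuals of the additive-only fit (`y ~ x`), adding them
#' back to the additive fitted values, and recomputing `d`. Two-sided
#' p-value `(1 + #{|d_perm| >= |d_obs|}) / (1 + n_perm)`.
#'
#' @param y trait values.
#' @param codes genotype codes at the peak bin; all three classes required.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed of this test's stream.
#' @return The permutation p-value.
#' @export
h_test <- function(y, codes, n_perm = 1000L, seed = 1L) {
  assert_that(n_perm >= 1, "n_perm must be >= 1")
  assert_that(all(c("AA", "Aa", "aa") %in% codes),
              "h-test requires all three genotype classes")
  n <- length(y)
  x <- (codes == "AA") - (codes == "aa")
  fit <- stats::lm.fit(cbind(1, x), y)
  e <- fit$residuals
  f <- fit$fitted.values
  d_of <- function(Y) {
    # column-wise d = m_Aa - (m_AA + m_aa)/2 for a matrix of trait vectors
    iAA <- codes == "AA"; iAa <- codes == "Aa"; iaa <- codes == "aa"
    colMeans(Y[iAa, , drop = FALSE]) -
      (colMeans(Y[iAA, , drop = FALSE]) + colMeans(Y[iaa, , drop = FALSE])) / 2
  }
  d_obs <- d_of(matrix(y, ncol = 1))
  d_perm <- with_seed(seed, {
    E <- vapply(seq_len(n_perm), function(i) e[sample.int(n)], numeric(n))
    d_of(f + E)
  })
  (1 + sum(abs(d_perm) >= abs(d_obs))) / (1 + n_perm)
}

#' Classify the mode of dominance at a QTL
#'
#' Non-significant dominance is `none`. Significant negative `d` means the
#' heterozygote lies below the mid-homozygote value (`negative`); when it
#' lies below both homozygotes (`d < -|a|`) the QTL is
#' `negative-overdominant`. The positive classes mirror this.
#'
#' @param estimate an [estimate_effects()] result.
#' @param significant logical: did the h-test reject at the chosen level?
#' @return One of `none`, `positive`, `negative`, `positive-overdominant`,
#'   `negative-overdominant`.
#' @export
classify_dominance <- function(estimate, significant) {
  d <- estimate$d; a <- estimate$a
  assert_that(!is.na(d), "dominance effect undefined")
  if (!isTRUE(significant) || d == 0) return("none")
  if (d < 0) {
    if (d < -abs(a)) "negative-overdominant" else "negative"
  } else {
    if (d > abs(a)) "positive-overdominant" else "positive"
  }
}
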