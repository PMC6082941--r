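#' Exact Hardy-Weinberg test for a diallelic locus
#'
#' Levene-Haldane exact conditional test: holding the observed allele counts
#' fixed, every heterozygote count of matching parity is enumerated, the
#' conditional probability of each configuration is computed, and the p-value
#' is the total probability of configurations no more probable than the one
#' observed (the standard two-sided convention). Monomorphic samples return 1.
#'
#' @param c a [locus_counts()] object
#' @return p-value in \[0, 1\]
#' @export
hwe_exact <- function(c) {
  check_counts(c)
  n <- c$n
  nA <- 2 * c$n_II + c$n_ID
  nB <- 2 * n - nA
  if (nA == 0 || nB == 0) return(1)
  het <- seq(nA %% 2, min(nA, nB), by = 2)
  # conditional log-probabilities P(het | n, nA), normalised below
  lp <- het * log(2) +
    lgamma(n + 1) - lgamma((nA - het) / 2 + 1) - lgamma(het + 1) -
    lgamma((nB - het) / 2 + 1)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(c$n_ID, het)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Chi-square Hardy-Weinberg test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the `p^2, 2pq, q^2` expectations at the sample allele frequency;
#' the asymptotic companion to [hwe_exact()]. Monomorphic samples return
#' `chi2 = 0, p = 1`.
#'
#' @param c a [locus_counts()] object
#' @return list with `chi2` and `p`
#' @export
hwe_chi2 <- function(c) {
  check_counts(c)
  p <- insertion_freq(c)
  if (p == 0 || p == 1) return(list(chi2 = 0, p = 1))
  expected <- c$n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  observed <- c(c$n_II, c$n_ID, c$n_DD)
  chi2 <- sum((observed - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m` for `m` simultaneous tests (0.05/30 = 0.00167 for a 30-locus
#' panel).
#'
#' @param alpha nominal family-wise level in (0, 1)
#' @param m number of tests (>= 1)
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Hardy-Weinberg test table for a panel
#'
#' Exact and chi-square tests for every locus, flagged against the
#' Bonferroni-corrected threshold `alpha / n_loci`.
#'
#' @param gm a [genotype_matrix()]
#' @param alpha nominal family-wise significance level
#' @return data frame with columns `locus`, `p_exact`, `chi2`, `p_chi2`,
#'   `significant_after_bonferroni`; the threshold used is carried as an
#'   attribute
#' @export
hwe_table <- function(gm, alpha = 0.05) {
  thr <- bonferroni_threshold(alpha, n_loci(gm))
  rows <- lapply(locus_ids(gm), function(l) {
    cnt <- locus_counts(gm, l)
    chi <- hwe_chi2(cnt)
    pe <- hwe_exact(cnt)
    data.frame(locus = l, p_exact = pe, chi2 = chi$chi2, p_chi2 = chi$p,
               significant_after_bonferroni = pe < thr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "bonferroni_threshold") <- thr
  out
}
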