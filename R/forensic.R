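#' Genotype counts at one locus
#'
#' Counts of the three genotype classes over non-missing calls; the atom from
#' which every per-locus forensic statistic is computed.
#'
#' @param gm a [genotype_matrix()]
#' @param locus locus id
#' @return an object of class `locus_counts`: list with `n_II`, `n_ID`,
#'   `n_DD` and `n = n_II + n_ID + n_DD`
#' @export
locus_counts <- function(gm, locus) {
  if (!(locus %in% locus_ids(gm))) stop("unknown locus id: ", locus)
  calls <- gm$calls[, locus]
  make_locus_counts(sum(calls == "II", na.rm = TRUE),
                    sum(calls == "ID", na.rm = TRUE),
                    sum(calls == "DD", na.rm = TRUE))
}

#' @rdname locus_counts
#' @param n_II,n_ID,n_DD non-negative genotype counts
#' @export
make_locus_counts <- function(n_II, n_ID, n_DD) {
  if (any(c(n_II, n_ID, n_DD) < 0)) stop("genotype counts must be >= 0")
  structure(list(n_II = as.integer(n_II), n_ID = as.integer(n_ID),
                 n_DD = as.integer(n_DD),
                 n = as.integer(n_II + n_ID + n_DD)),
            class = "locus_counts")
}

check_counts <- function(c) {
  if (!inherits(c, "locus_counts")) stop("expected a locus_counts object")
  if (c$n < 1) stop("no non-missing genotypes at this locus")
  c
}

#' Insertion-allele frequency from genotype counts
#'
#' `p = (2 n_II + n_ID) / (2 n)`.
#'
#' @param c a [locus_counts()] object with `n >= 1`
#' @return frequency in \[0, 1\]
#' @export
insertion_freq <- function(c) {
  check_counts(c)
  (2 * c$n_II + c$n_ID) / (2 * c$n)
}

#' Observed heterozygosity
#'
#' The heterozygote proportion `Ho = n_ID / n`.
#'
#' @inheritParams insertion_freq
#' @export
observed_het <- function(c) {
  check_counts(c)
  c$n_ID / c$n
}

#' Unbiased expected heterozygosity
#'
#' Nei's small-sample estimator for a diallelic locus:
#' `He = 2n/(2n - 1) * (1 - p^2 - q^2)`.
#'
#' @param p insertion-allele frequency in \[0, 1\]
#' @param n number of genotyped individuals (>= 1)
#' @export
expected_het_unbiased <- function(p, n) {
  stopifnot(p >= 0, p <= 1, n >= 1)
  (2 * n / (2 * n - 1)) * (1 - p^2 - (1 - p)^2)
}

#' Polymorphism information content
#'
#' For a diallelic locus: `PIC = 1 - (p^2 + q^2) - 2 p^2 q^2`.
#'
#' @param p insertion-allele frequency in \[0, 1\]
#' @export
pic <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' Match probability
#'
#' Probability that two individuals drawn at random from the sample share a
#' genotype, using the observed genotype class frequencies (not their
#' Hardy-Weinberg expectations): `MP = sum_g (count_g / n)^2`.
#' The discrimination power is its complement, `DP = 1 - MP`.
#'
#' @inheritParams insertion_freq
#' @export
match_probability <- function(c) {
  check_counts(c)
  sum((c(c$n_II, c$n_ID, c$n_DD) / c$n)^2)
}

#' Power of exclusion
#'
#' Single-parent exclusion probability from observed heterozygosity
#' (Brenner's formula): `PE = Ho^2 * (1 - 2 Ho (1 - Ho)^2)`.
#'
#' @param Ho observed heterozygosity in \[0, 1\]
#' @export
power_exclusion <- function(Ho) {
  stopifnot(all(Ho >= 0 & Ho <= 1))
  Ho^2 * (1 - 2 * Ho * (1 - Ho)^2)
}

#' Typing paternity index
#'
#' `TPI = 1 / (2 (1 - Ho))`, the average paternity index of a locus as a
#' function of its homozygosity.
#'
#' @param Ho observed heterozygosity in \[0, 1)
#' @export
typing_paternity_index <- function(Ho) {
  stopifnot(all(Ho >= 0 & Ho <= 1))
  if (any(Ho == 1))
    stop("TPI is infinite at Ho = 1 (no observed homozygotes)")
  1 / (2 * (1 - Ho))
}

#' Reconstruct genotype counts from published summary statistics
#'
#' Inverts a published (allele frequency, TPI, n) triple to the integer
#' genotype counts that produced it: the heterozygote count from TPI, the
#' insertion-allele copy count from p, homozygotes by closure. Errors if the
#' implied counts are not consistent integers.
#'
#' @param p insertion-allele frequency (0 < p < 1)
#' @param tpi typing paternity index (>= 0.5)
#' @param n genotyped individuals
#' @return a [locus_counts()] object
#' @export
reconstruct_counts <- function(p, tpi, n) {
  stopifnot(p > 0, p < 1, tpi >= 0.5, n >= 1)
  n_ID <- round(n * (1 - 1 / (2 * tpi)))
  n_I <- round(2 * n * p)
  if ((n_I - n_ID) %% 2 != 0)
    stop("inconsistent inputs: insertion copies minus heterozygotes is odd")
  n_II <- (n_I - n_ID) / 2
  n_DD <- n - n_II - n_ID
  if (n_II < 0 || n_DD < 0 || n_ID < 0)
    stop("inconsistent inputs: negative genotype count implied")
  make_locus_counts(n_II, n_ID, n_DD)
}

#' Panel-wide combination of per-locus statistics
#'
#' Cumulative match probability `CMP = prod(MP_l)` and combined power of
#' exclusion `CPE = 1 - prod(1 - PE_l)`, both computed in log space; valid
#' under locus independence. Also returns `log10(CMP)` and `log10(1 - CPE)`
#' so very small products remain inspectable.
#'
#' @param profile a data frame with numeric columns `MP` and `PE` (one row
#'   per locus), e.g. from [profile_table()]
#' @return list with `CMP`, `CPE`, `log10_CMP`, `log10_one_minus_CPE`
#' @export
combined_panel_stats <- function(profile) {
  mp <- profile$MP
  pe <- profile$PE
  if (is.null(mp) || is.null(pe)) stop("profile needs MP and PE columns")
  bad <- which(!is.finite(mp) | !is.finite(pe))
  if (length(bad))
    stop("missing per-locus statistic at: ",
         paste(profile$locus[bad], collapse = ", "))
  if (length(mp) < 1) stop("need at least one locus")
  log_cmp <- sum(log(mp))
  log_not_excl <- sum(log1p(-pe))
  list(CMP = exp(log_cmp),
       CPE = -expm1(log_not_excl),
       log10_CMP = log_cmp / log(10),
       log10_one_minus_CPE = log_not_excl / log(10))
}

#' Forensic efficiency profile of a panel
#'
#' One row per locus with the full set of forensic efficiency parameters
#' (allele frequencies, MP, DP, PIC, PE, TPI, Ho, He and the exact
#' Hardy-Weinberg p-value), plus the panel-wide CMP/CPE as attributes.
#'
#' @param gm a [genotype_matrix()]
#' @return a data frame of class `forensic_profile`; attributes `CMP`,
#'   `CPE`, `log10_CMP` carry the panel combination
#' @examples
#' gm <- simulate_hwe_population(n = 100, p = rep(0.5, 5), seed = 1)
#' prof <- profile_table(gm)
#' attr(prof, "CMP")
#' @export
profile_table <- function(gm) {
  rows <- lapply(locus_ids(gm), function(l) {
    cnt <- tryCatch(check_counts(locus_counts(gm, l)),
                    error = function(e)
                      stop("locus ", l, ": ", conditionMessage(e),
                           call. = FALSE))
    p <- insertion_freq(cnt)
    ho <- observed_het(cnt)
    data.frame(
      locus = l, n = cnt$n, p_ins = p, p_del = 1 - p,
      MP = match_probability(cnt), DP = 1 - match_probability(cnt),
      PIC = pic(p), PE = power_exclusion(ho),
      TPI = if (ho < 1) typing_paternity_index(ho) else Inf,
      Ho = ho, He = expected_het_unbiased(p, cnt$n),
      hwe_p = hwe_exact(cnt),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(gm$rs)) out <- cbind(out[1], rs = gm$rs, out[-1])
  rownames(out) <- NULL
  comb <- combined_panel_stats(out)
  attr(out, "CMP") <- comb$CMP
  attr(out, "CPE") <- comb$CPE
  attr(out, "log10_CMP") <- comb$log10_CMP
  class(out) <- c("forensic_profile", "data.frame")
  out
}

#' @export
print.forensic_profile <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 4)
  print(df, ...)
  cat(sprintf("CMP = %.4g   CPE = %.4f\n",
              attr(x, "CMP"), attr(x, "CPE")))
  invisible(x)
}
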