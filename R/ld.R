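#' Two-locus genotype-pair table
#'
#' 3x3 table of joint genotype counts for a locus pair, indexed by the
#' insertion-allele dosage (0, 1, 2) at each locus; complete cases only.
#'
#' @param gm a [genotype_matrix()]
#' @param locus_a,locus_b locus ids
#' @return 3x3 integer matrix; rows = dosage at `locus_a`, columns at
#'   `locus_b`
#' @export
pair_genotype_table <- function(gm, locus_a, locus_b) {
  dos <- dosage_matrix(gm)
  a <- dos[, locus_a]; b <- dos[, locus_b]
  keep <- !is.na(a) & !is.na(b)
  tab <- table(factor(a[keep], levels = 0:2), factor(b[keep], levels = 0:2))
  m <- matrix(as.integer(tab), 3, 3, dimnames = list(0:2, 0:2))
  m
}

# fixed haplotype contributions of the eight unambiguous genotype-pair
# cells, order (II, ID, DI, DD) meaning (allele at A, allele at B)
hap_base_counts <- function(tab) {
  c(II = 2 * tab["2", "2"] + tab["2", "1"] + tab["1", "2"],
    ID = 2 * tab["2", "0"] + tab["2", "1"] + tab["1", "0"],
    DI = 2 * tab["0", "2"] + tab["0", "1"] + tab["1", "2"],
    DD = 2 * tab["0", "0"] + tab["0", "1"] + tab["1", "0"])
}

# observed-data log-likelihood of a 3x3 genotype-pair table under
# haplotype frequencies f = (II, ID, DI, DD)
pair_loglik <- function(f, tab) {
  f <- pmax(f, 0)
  cellp <- matrix(c(
    f["DD"]^2,            2 * f["DI"] * f["DD"],            f["DI"]^2,
    2 * f["ID"] * f["DD"], 2 * (f["II"] * f["DD"] + f["ID"] * f["DI"]),
    2 * f["II"] * f["DI"],
    f["ID"]^2,            2 * f["II"] * f["ID"],            f["II"]^2),
    3, 3, byrow = TRUE, dimnames = list(0:2, 0:2))
  keep <- tab > 0
  if (any(cellp[keep] <= 0)) return(-Inf)
  sum(tab[keep] * log(cellp[keep]))
}

#' EM estimation of two-locus haplotype frequencies
#'
#' Maximum-likelihood haplotype frequencies from unphased diallelic
#' genotype-pair counts. Only the double-heterozygote cell is phase
#' ambiguous; the E-step splits it between the coupling (II/DD) and
#' repulsion (ID/DI) phases in proportion to the current haplotype
#' frequencies. Initialisation is the linkage-equilibrium product of the
#' observed allele frequencies; the diallelic problem has a single free
#' parameter, so no restarts are needed.
#'
#' @param tab 3x3 genotype-pair table from [pair_genotype_table()]
#' @param tol convergence threshold on the largest frequency change
#' @param max_iter iteration cap
#' @return named numeric vector `(II, ID, DI, DD)` summing to 1, with
#'   attributes `iterations` and `loglik`
#' @export
em_haplotype_freqs <- function(tab, tol = 1e-10, max_iter = 1000) {
  tab <- as.matrix(tab)
  storage.mode(tab) <- "double"
  dimnames(tab) <- list(0:2, 0:2)
  n_hap <- 2 * sum(tab)
  if (n_hap == 0) stop("empty genotype-pair table")
  base <- hap_base_counts(tab)
  n_dh <- tab["1", "1"]
  p1 <- unname(base["II"] + base["ID"] + n_dh) / n_hap
  p2 <- unname(base["II"] + base["DI"] + n_dh) / n_hap
  f <- c(II = p1 * p2, ID = p1 * (1 - p2), DI = (1 - p1) * p2,
         DD = (1 - p1) * (1 - p2))
  it <- 0L
  repeat {
    it <- it + 1L
    denom <- f["II"] * f["DD"] + f["ID"] * f["DI"]
    w <- if (denom > 0) f["II"] * f["DD"] / denom else 0.5
    new_f <- (base + n_dh * c(w, 1 - w, 1 - w, w)) / n_hap
    names(new_f) <- names(f)
    delta <- max(abs(new_f - f))
    f <- new_f
    if (delta < tol || it >= max_iter) break
  }
  structure(f, iterations = it, loglik = pair_loglik(f, tab))
}

#' Linkage-disequilibrium coefficients from haplotype frequencies
#'
#' `D = f_II - p1 p2`; `D' = |D| / Dmax` with the sign-dependent feasible
#' maximum; `r2 = D^2 / (p1 q1 p2 q2)`. When either locus is monomorphic the
#' normalised coefficients are undefined and returned as `NA` with
#' `defined = FALSE` (D itself is still reported; it is 0 in that case).
#'
#' @param hap_freqs named vector `(II, ID, DI, DD)` summing to 1
#' @return list with `D`, `D_prime`, `r2`, `p1`, `p2`, `defined`
#' @export
ld_stats <- function(hap_freqs) {
  f <- hap_freqs
  if (abs(sum(f) - 1) > 1e-9) stop("haplotype frequencies must sum to 1")
  p1 <- f[["II"]] + f[["ID"]]
  p2 <- f[["II"]] + f[["DI"]]
  D <- f[["II"]] - p1 * p2
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1))
    return(list(D = D, D_prime = NA_real_, r2 = NA_real_,
                p1 = p1, p2 = p2, defined = FALSE))
  d_max <- if (D >= 0) min(p1 * (1 - p2), (1 - p1) * p2)
           else min(p1 * p2, (1 - p1) * (1 - p2))
  list(D = D,
       D_prime = if (d_max > 0) abs(D) / d_max else 0,
       r2 = D^2 / (p1 * (1 - p1) * p2 * (1 - p2)),
       p1 = p1, p2 = p2, defined = TRUE)
}

#' Pairwise linkage-disequilibrium screen
#'
#' EM haplotype frequencies and LD coefficients for every unordered locus
#' pair (`L (L-1) / 2` pairs; 435 for a 30-locus panel), flagged against an
#' `r2` cutoff. Pairs with a monomorphic locus have undefined `r2` and are
#' excluded from threshold counting (`above_threshold = NA`).
#'
#' @param gm a [genotype_matrix()] with at least two loci
#' @param r2_threshold cutoff applied to `r2` (default 0.8)
#' @return data frame with one row per pair: haplotype frequencies, `D`,
#'   `D_prime`, `r2`, `above_threshold`
#' @export
ld_screen <- function(gm, r2_threshold = 0.8) {
  loci <- locus_ids(gm)
  if (length(loci) < 2) stop("need at least two loci")
  pairs <- utils::combn(loci, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    la <- pairs[1, k]; lb <- pairs[2, k]
    f <- em_haplotype_freqs(pair_genotype_table(gm, la, lb))
    s <- ld_stats(f)
    data.frame(locus_a = la, locus_b = lb,
               f_II = f[["II"]], f_ID = f[["ID"]],
               f_DI = f[["DI"]], f_DD = f[["DD"]],
               D = s$D, D_prime = s$D_prime, r2 = s$r2,
               above_threshold = if (s$defined) s$r2 >= r2_threshold else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "r2_threshold") <- r2_threshold
  out
}
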