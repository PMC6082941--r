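#' Allele count table for a population pair at one locus
#'
#' 2x2 integer table (rows = populations, columns = insertion/deletion allele
#' counts) used by the exact differentiation test. Works from genotype data
#' (complete cases, 2 alleles per genotyped individual) or from a frequency
#' table plus per-population sample sizes.
#'
#' @param x a [genotype_matrix()] or a [freq_table()] (the latter must carry
#'   `sample_size`)
#' @param pop_a,pop_b population ids
#' @param locus locus id
#' @return 2x2 integer matrix with dimnames
#' @export
allele_count_2x2 <- function(x, pop_a, pop_b, locus) {
  if (inherits(x, "genotype_matrix")) {
    counts <- function(pop) {
      cnt <- locus_counts(subset_populations(x, pop), locus)
      c(ins = 2 * cnt$n_II + cnt$n_ID, del = 2 * cnt$n_DD + cnt$n_ID)
    }
    tab <- rbind(counts(pop_a), counts(pop_b))
  } else if (inherits(x, "freq_table")) {
    if (is.null(x$sample_size))
      stop("freq_table needs sample_size to reconstruct allele counts")
    counts <- function(pop) {
      two_n <- 2 * x$sample_size[[pop]]
      ins <- round(two_n * x$freq[pop, locus])
      c(ins = ins, del = two_n - ins)
    }
    tab <- rbind(counts(pop_a), counts(pop_b))
  } else stop("x must be a genotype_matrix or freq_table")
  rownames(tab) <- c(pop_a, pop_b)
  storage.mode(tab) <- "integer"
  tab
}

#' Two-sided Fisher exact test on a 2x2 allele-count table
#'
#' Hypergeometric enumeration summing the probabilities of all tables no
#' more probable than the observed one; the default locus-by-locus
#' differentiation test for diallelic loci.
#'
#' @param tab 2x2 non-negative integer matrix
#' @return p-value
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  if (sum(tab) == 0) stop("all-zero table")
  stats::fisher.test(tab)$p.value
}

# Weir-Cockerham (1984) variance components for one diallelic locus over
# r populations: n_i genotyped individuals, p_i insertion frequencies,
# h_i observed heterozygote proportions. Returns c(a, b, c).
wc_components <- function(n_i, p_i, h_i) {
  keep <- n_i > 0
  n_i <- n_i[keep]; p_i <- p_i[keep]; h_i <- h_i[keep]
  r <- length(n_i)
  if (r < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  n_bar <- mean(n_i)
  if (n_bar <= 1) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n_i * p_i) / (r * n_bar)
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n_i * h_i) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
       (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  c(a = a, b = b, c = cc)
}

# per-population (n_i, p_i, h_i) arrays for the loci of gm
pop_locus_summaries <- function(gm, pops) {
  dos <- dosage_matrix(gm)
  L <- n_loci(gm)
  n <- p <- h <- matrix(0, length(pops), L,
                        dimnames = list(pops, locus_ids(gm)))
  for (i in seq_along(pops)) {
    d <- dos[gm$populations == pops[i], , drop = FALSE]
    ni <- colSums(!is.na(d))
    n[i, ] <- ni
    p[i, ] <- ifelse(ni > 0, colSums(d, na.rm = TRUE) / (2 * ni), NA)
    h[i, ] <- ifelse(ni > 0, colSums(d == 1, na.rm = TRUE) / ni, NA)
  }
  list(n = n, p = p, h = h)
}

#' Weir-Cockerham F_st
#'
#' The 1984 theta estimator of population differentiation: per-locus
#' variance components `a` (among populations), `b` (among individuals
#' within populations) and `c` (within individuals) are summed over loci and
#' theta is the ratio `sum(a) / sum(a + b + c)`. Slightly negative estimates
#' for undifferentiated populations are legitimate and not clamped.
#'
#' @param gm a [genotype_matrix()]
#' @param pops populations to include (default: all, must be >= 2); every
#'   included population needs at least 2 genotyped individuals
#' @return theta (scalar); per-locus components are attached as attribute
#'   `components`
#' @export
wc_fst <- function(gm, pops = NULL) {
  if (is.null(pops)) pops <- unique(gm$populations)
  if (length(pops) < 2) stop("need at least two populations")
  sizes <- table(factor(gm$populations, levels = pops))
  if (any(sizes < 2))
    stop("population(s) with fewer than 2 individuals: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  gm <- subset_populations(gm, pops)
  s <- pop_locus_summaries(gm, pops)
  comp <- sapply(seq_len(n_loci(gm)), function(l)
    wc_components(s$n[, l], s$p[, l], s$h[, l]))
  ok <- colSums(is.na(comp)) == 0
  total <- sum(comp[, ok, drop = FALSE])
  theta <- if (total == 0) NaN else sum(comp["a", ok]) / total
  attr(theta, "components") <- comp
  theta
}

#' Permutation test on locus-wise theta
#'
#' Null distribution of the single-locus Weir-Cockerham theta obtained by
#' permuting individuals between two populations;
#' `p = (1 + #permuted >= observed) / (n_perm + 1)`. A locus monomorphic
#' across both populations carries no differentiation signal and returns 1.
#'
#' @param gm a [genotype_matrix()]
#' @param pop_a,pop_b population ids
#' @param locus locus id
#' @param n_perm number of permutations (>= 100)
#' @param seed RNG seed (required, recorded in the result)
#' @return p-value with attributes `observed_theta`, `seed`, `n_perm`
#' @export
permutation_fst_test <- function(gm, pop_a, pop_b, locus, n_perm = 1000,
                                 seed) {
  stopifnot(n_perm >= 100)
  sub <- subset_populations(gm, c(pop_a, pop_b))
  dos <- dosage_matrix(sub)[, locus]
  labels <- sub$populations
  keep <- !is.na(dos)
  dos <- dos[keep]; labels <- labels[keep]
  theta_of <- function(lab) {
    ni <- c(sum(lab == pop_a), sum(lab == pop_b))
    pi_ <- c(sum(dos[lab == pop_a]) / (2 * ni[1]),
             sum(dos[lab == pop_b]) / (2 * ni[2]))
    hi <- c(mean(dos[lab == pop_a] == 1), mean(dos[lab == pop_b] == 1))
    comp <- wc_components(ni, pi_, hi)
    tot <- sum(comp)
    if (is.na(tot) || tot == 0) NA_real_ else comp[["a"]] / tot
  }
  obs <- theta_of(labels)
  if (is.na(obs)) {
    p <- 1
  } else {
    exceed <- withr::with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        th <- theta_of(sample(labels))
        !is.na(th) && th >= obs - 1e-12
      }, logical(1)))
    })
    p <- (1 + exceed) / (n_perm + 1)
  }
  structure(p, observed_theta = obs, seed = seed, n_perm = n_perm)
}

#' Locus-by-locus differentiation profile for a population pair
#'
#' Per-locus p-values of allele-frequency differentiation between two
#' populations, with the count of loci significant after Bonferroni
#' correction (`alpha / L`). Fisher's exact test on allele counts is the
#' default; a permutation test on locus-wise theta is the alternative.
#'
#' @param gm a [genotype_matrix()]
#' @param pop_a,pop_b population ids
#' @param alpha family-wise level before correction
#' @param method `"fisher"` or `"permutation"`
#' @param n_perm,seed passed to [permutation_fst_test()] when
#'   `method = "permutation"`
#' @return list of class `differentiation_profile`: data frame `loci`
#'   (locus, p_value), `n_significant`, `threshold`
#' @export
differentiation_profile <- function(gm, pop_a, pop_b, alpha = 0.05,
                                    method = c("fisher", "permutation"),
                                    n_perm = 1000, seed = NULL) {
  method <- match.arg(method)
  loci <- locus_ids(gm)
  if (!length(loci)) stop("no shared loci")
  pv <- vapply(loci, function(l) {
    if (method == "fisher")
      fisher_exact_2x2(allele_count_2x2(gm, pop_a, pop_b, l))
    else {
      if (is.null(seed)) stop("permutation method requires a seed")
      as.numeric(permutation_fst_test(gm, pop_a, pop_b, l, n_perm, seed))
    }
  }, numeric(1))
  thr <- bonferroni_threshold(alpha, length(loci))
  structure(list(population_pair = c(pop_a, pop_b),
                 loci = data.frame(locus = loci, p_value = unname(pv),
                                   stringsAsFactors = FALSE),
                 n_significant = sum(pv < thr),
                 threshold = thr, method = method),
            class = "differentiation_profile")
}

#' @export
print.differentiation_profile <- function(x, ...) {
  cat(sprintf("Differentiation %s vs %s (%s test): %d of %d loci below %.5f\n",
              x$population_pair[1], x$population_pair[2], x$method,
              x$n_significant, nrow(x$loci), x$threshold))
  invisible(x)
}

#' Nei's D_A genetic distance
#'
#' `D_A = 1 - (1/L) * sum_l sum_alleles sqrt(x_la * y_la)`, a drift-oriented
#' distance between allele-frequency vectors. For the diallelic panels here
#' each locus contributes `sqrt(px py) + sqrt((1-px)(1-py))`.
#'
#' @param freqs_x,freqs_y numeric vectors of insertion-allele frequencies
#'   over the same locus set (aligned by names when both are named)
#' @return distance in \[0, 1\]
#' @export
nei_da <- function(freqs_x, freqs_y) {
  if (!is.null(names(freqs_x)) && !is.null(names(freqs_y))) {
    if (!setequal(names(freqs_x), names(freqs_y)))
      stop("mismatched locus sets")
    freqs_y <- freqs_y[names(freqs_x)]
  } else if (length(freqs_x) != length(freqs_y))
    stop("frequency vectors differ in length")
  stopifnot(all(freqs_x >= 0 & freqs_x <= 1),
            all(freqs_y >= 0 & freqs_y <= 1))
  1 - mean(sqrt(freqs_x * freqs_y) +
             sqrt((1 - freqs_x) * (1 - freqs_y)))
}

#' Pairwise distance matrix over populations
#'
#' Assembles a labelled symmetric matrix of Nei's D_A (from allele
#' frequencies) or pairwise Weir-Cockerham F_st (from genotypes). Negative
#' F_st estimates are floored at 0 in the matrix; the raw values are kept in
#' the `raw` attribute.
#'
#' @param x a [freq_table()] (for `metric = "da"`) or a [genotype_matrix()]
#'   (either metric; converted through [population_freqs()] for `"da"`)
#' @param metric `"da"` or `"fst"`
#' @return a [as_distance_matrix()] object
#' @export
distance_matrix <- function(x, metric = c("da", "fst")) {
  metric <- match.arg(metric)
  if (metric == "da") {
    ft <- if (inherits(x, "genotype_matrix")) population_freqs(x)
          else if (inherits(x, "freq_table")) x
          else stop("x must be a genotype_matrix or freq_table")
    pops <- rownames(ft$freq)
    if (length(pops) < 2) stop("need at least two populations")
    m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
    for (i in seq_along(pops)) for (j in seq_len(i - 1)) {
      m[i, j] <- m[j, i] <- nei_da(ft$freq[pops[i], ], ft$freq[pops[j], ])
    }
    return(as_distance_matrix(m))
  }
  if (!inherits(x, "genotype_matrix"))
    stop("metric 'fst' requires genotype data")
  pops <- unique(x$populations)
  if (length(pops) < 2) stop("need at least two populations")
  raw <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1)) {
    th <- as.numeric(wc_fst(x, c(pops[i], pops[j])))
    raw[i, j] <- raw[j, i] <- th
  }
  dm <- as_distance_matrix(pmax(raw, 0))
  attr(dm, "raw") <- raw
  dm
}
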