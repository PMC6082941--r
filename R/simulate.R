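#' Simulate a single population of diallelic genotypes
#'
#' Genotypes are drawn per locus with class probabilities
#' `(p^2 + Fpq, 2pq(1 - F), q^2 + Fpq)`; `F = 0` gives Hardy-Weinberg
#' proportions and `F = 1` eliminates heterozygotes. All simulators in the
#' package require an explicit seed and are bit-reproducible given it.
#'
#' @param n individuals
#' @param p insertion-allele frequency: a vector of length `L`, or a single
#'   value recycled when `L` is given
#' @param F_inbreeding inbreeding coefficient in \[0, 1\]
#' @param seed RNG seed (required)
#' @param L number of loci (defaults to `length(p)`)
#' @param population population label for all samples
#' @param locus_ids optional locus ids
#' @return a [genotype_matrix()]
#' @export
simulate_hwe_population <- function(n, p, F_inbreeding = 0, seed,
                                    L = length(p), population = "pop1",
                                    locus_ids = NULL) {
  if (missing(seed)) stop("seed is required")
  stopifnot(F_inbreeding >= 0, F_inbreeding <= 1,
            all(p >= 0 & p <= 1), n >= 1)
  p <- rep_len(p, L)
  if (is.null(locus_ids)) locus_ids <- paste0("locus", seq_len(L))
  calls <- withr::with_seed(seed, {
    m <- matrix(NA_character_, n, L)
    for (l in seq_len(L)) {
      q <- 1 - p[l]
      pr <- c(p[l]^2 + F_inbreeding * p[l] * q,
              2 * p[l] * q * (1 - F_inbreeding),
              q^2 + F_inbreeding * p[l] * q)
      m[, l] <- sample(c("II", "ID", "DD"), n, replace = TRUE, prob = pr)
    }
    m
  })
  dimnames(calls) <- list(paste0(population, "_", seq_len(n)), locus_ids)
  genotype_matrix(calls, populations = rep(population, n))
}

#' Simulate structured populations under the Balding-Nichols model
#'
#' For each locus an ancestral insertion frequency `p` is drawn (or given);
#' each population's frequency is then drawn from
#' `Beta(p (1 - c) / c, (1 - p)(1 - c) / c)` with `c = fst_target`, and
#' genotypes are in Hardy-Weinberg proportions within populations. This is
#' the standard ground-truth generator for F_st estimation: the expected
#' Weir-Cockerham theta equals `c`.
#'
#' @param n integer vector of individuals per population (named or not;
#'   length >= 2)
#' @param L number of loci
#' @param fst_target Balding-Nichols `c` in (0, 1)
#' @param seed RNG seed (required)
#' @param ancestral_p optional length-`L` vector; default draws from
#'   `Uniform(0.1, 0.9)` so loci stay informative
#' @param pop_names population labels (default `pop1`, `pop2`, ...)
#' @return a [genotype_matrix()]; the per-population frequencies used are
#'   attached as attribute `true_freqs` (populations x loci)
#' @export
simulate_balding_nichols <- function(n, L, fst_target, seed,
                                     ancestral_p = NULL, pop_names = NULL) {
  if (missing(seed)) stop("seed is required")
  stopifnot(fst_target > 0, fst_target < 1, length(n) >= 2)
  if (is.null(pop_names))
    pop_names <- if (!is.null(names(n))) names(n)
                 else paste0("pop", seq_along(n))
  withr::with_seed(seed, {
    if (is.null(ancestral_p)) ancestral_p <- stats::runif(L, 0.1, 0.9)
    stopifnot(length(ancestral_p) == L,
              all(ancestral_p > 0 & ancestral_p < 1))
    c_ <- fst_target
    freqs <- matrix(0, length(n), L, dimnames = list(pop_names, NULL))
    for (l in seq_len(L)) {
      a <- ancestral_p[l] * (1 - c_) / c_
      b <- (1 - ancestral_p[l]) * (1 - c_) / c_
      repeat {
        fr <- stats::rbeta(length(n), a, b)
        if (all(fr > 0 & fr < 1)) break
        message("degenerate population frequency at locus ", l,
                "; redrawing")
      }
      freqs[, l] <- fr
    }
    gms <- lapply(seq_along(n), function(i) {
      calls <- matrix(NA_character_, n[i], L)
      for (l in seq_len(L)) {
        pl <- freqs[i, l]
        calls[, l] <- sample(c("II", "ID", "DD"), n[i], replace = TRUE,
                             prob = c(pl^2, 2 * pl * (1 - pl), (1 - pl)^2))
      }
      dimnames(calls) <- list(paste0(pop_names[i], "_", seq_len(n[i])),
                              paste0("locus", seq_len(L)))
      genotype_matrix(calls, populations = rep(pop_names[i], n[i]))
    })
    gm <- do.call(bind_genotypes, gms)
    colnames(freqs) <- locus_ids(gm)
    attr(gm, "true_freqs") <- freqs
    gm
  })
}

#' Simulate admixed individuals
#'
#' Each allele copy independently picks a cluster of origin from the
#' individual's ancestry vector, then an allele from that cluster's
#' insertion frequency — exactly the generative model fitted by
#' [structure_fit()].
#'
#' @param Q n x K matrix of ancestry proportions (rows sum to 1)
#' @param cluster_freqs K x L matrix of cluster insertion frequencies
#' @param seed RNG seed (required)
#' @param population label(s) for the samples (length 1 or n)
#' @return a [genotype_matrix()]
#' @export
simulate_admixed <- function(Q, cluster_freqs, seed, population = "admixed") {
  if (missing(seed)) stop("seed is required")
  Q <- as.matrix(Q); cluster_freqs <- as.matrix(cluster_freqs)
  if (ncol(Q) != nrow(cluster_freqs))
    stop("ncol(Q) must equal nrow(cluster_freqs)")
  if (max(abs(rowSums(Q) - 1)) > 1e-9) stop("Q rows must sum to 1")
  n <- nrow(Q); L <- ncol(cluster_freqs); K <- ncol(Q)
  calls <- withr::with_seed(seed, {
    m <- matrix(NA_character_, n, L)
    for (i in seq_len(n)) {
      k1 <- sample.int(K, L, replace = TRUE, prob = Q[i, ])
      k2 <- sample.int(K, L, replace = TRUE, prob = Q[i, ])
      a1 <- stats::rbinom(L, 1, cluster_freqs[cbind(k1, seq_len(L))])
      a2 <- stats::rbinom(L, 1, cluster_freqs[cbind(k2, seq_len(L))])
      m[i, ] <- c("DD", "ID", "II")[a1 + a2 + 1]
    }
    m
  })
  dimnames(calls) <- list(paste0("adm_", seq_len(n)),
                          paste0("locus", seq_len(L)))
  genotype_matrix(calls, populations = rep_len(population, n))
}

#' Simulate a two-locus sample with known linkage disequilibrium
#'
#' Draws `2n` haplotypes i.i.d. from the four haplotype frequencies
#' `(II, ID, DI, DD)` and pairs them randomly into `n` unphased two-locus
#' genotypes — the ground truth for the EM haplotype-frequency machinery.
#'
#' @param hap_freqs numeric vector of 4 haplotype frequencies summing to 1,
#'   in the order (I-I, I-D, D-I, D-D)
#' @param n individuals
#' @param seed RNG seed (required)
#' @return a [genotype_matrix()] with loci `locusA`, `locusB`
#' @export
simulate_ld_pair <- function(hap_freqs, n, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(length(hap_freqs) == 4, all(hap_freqs >= 0),
            abs(sum(hap_freqs) - 1) < 1e-9)
  # haplotype h codes (allele at A, allele at B): 1=II, 2=ID, 3=DI, 4=DD
  a_of <- c(1L, 1L, 0L, 0L); b_of <- c(1L, 0L, 1L, 0L)
  calls <- withr::with_seed(seed, {
    h <- sample.int(4, 2 * n, replace = TRUE, prob = hap_freqs)
    h1 <- h[seq_len(n)]; h2 <- h[n + seq_len(n)]
    dos_a <- a_of[h1] + a_of[h2]
    dos_b <- b_of[h1] + b_of[h2]
    cbind(c("DD", "ID", "II")[dos_a + 1], c("DD", "ID", "II")[dos_b + 1])
  })
  dimnames(calls) <- list(paste0("s", seq_len(n)), c("locusA", "locusB"))
  genotype_matrix(calls, populations = rep("pop1", n))
}

#' Reference insertion-allele frequencies of the 30-locus DIPplex panel
#'
#' The per-locus insertion-allele frequencies (with rs annotations and the
#' published TPI values) observed in a sample of 169 Dongxiang individuals
#' genotyped on the Investigator DIPplex 30-InDel panel. These drive the
#' bundled "Dongxiang-like" simulator used throughout the test suite as a
#' stand-in for the deposited genotype data.
#'
#' @return data frame with columns `locus`, `rs`, `p_ins`, `tpi`
#' @export
dipplex_panel_freqs <- function() {
  data.frame(
    locus = c("HLD 77", "HLD 45", "HLD 131", "HLD 70", "HLD 6", "HLD 111",
              "HLD 58", "HLD 56", "HLD 118", "HLD 92", "HLD 93", "HLD 99",
              "HLD 88", "HLD 101", "HLD 67", "HLD 83", "HLD 114", "HLD 48",
              "HLD 124", "HLD 122", "HLD 125", "HLD 64", "HLD 81",
              "HLD 136", "HLD 133", "HLD 97", "HLD 40", "HLD 128",
              "HLD 39", "HLD 84"),
    rs = c("1611048", "2307959", "1611001", "2307652", "1610905",
           "1305047", "1610937", "2308292", "16438", "17174476", "2307570",
           "2308163", "8190570", "2307433", "1305056", "2308072", "2307581",
           "28369942", "6481", "8178524", "16388", "1610935", "17879936",
           "16363", "2067235", "17238892", "2307924", "17878444", "2307956",
           "3081400"),
    p_ins = c(0.4586, 0.6746, 0.4320, 0.5680, 0.4911, 0.1598, 0.3905,
              0.5799, 0.8550, 0.3669, 0.5473, 0.8462, 0.5266, 0.4734,
              0.5651, 0.3905, 0.3077, 0.3994, 0.5947, 0.3254, 0.4527,
              0.7988, 0.7633, 0.5148, 0.3432, 0.3669, 0.6272, 0.3728,
              0.2041, 0.6746),
    tpi = c(0.8622, 0.8711, 0.9286, 0.9941, 0.9713, 0.6870, 0.8895,
            0.9286, 0.6213, 0.8895, 1.0563, 0.6983, 0.9941, 0.9713,
            0.9602, 0.9286, 0.9713, 0.9185, 1.0563, 0.8535, 1.2071,
            0.7478, 0.7348, 1.0432, 1.0696, 0.9494, 0.9713, 0.9086,
            0.7824, 0.9286),
    stringsAsFactors = FALSE)
}

#' Simulate a Dongxiang-like 30-locus panel sample
#'
#' Hardy-Weinberg genotypes for `n` individuals at the
#' [dipplex_panel_freqs()] insertion frequencies — the bundled stand-in for
#' the study-scale dataset (n = 169, L = 30).
#'
#' @param n individuals (default 169)
#' @param seed RNG seed (required)
#' @param population population label
#' @return a [genotype_matrix()] with the panel's locus ids and rs numbers
#' @export
simulate_panel_like <- function(n = 169, seed, population = "dongxiang") {
  ref <- dipplex_panel_freqs()
  gm <- simulate_hwe_population(n = n, p = ref$p_ins, seed = seed,
                                population = population,
                                locus_ids = ref$locus)
  gm$rs <- ref$rs
  gm
}
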