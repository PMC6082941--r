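test_that("exact HWE test matches enumeration on small closed forms", {
  expect_equal(hwe_exact(make_locus_counts(0, 2, 0)), 1)
  expect_equal(hwe_exact(make_locus_counts(1, 0, 1)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(hwe_exact(make_locus_counts(12, 0, 0)), 1)
})

test_that("exact HWE test equals the enumeration oracle for all n <= 25", {
  for (n in 1:25) {
    for (n_II in 0:n) for (n_ID in 0:(n - n_II)) {
      n_DD <- n - n_II - n_ID
      expect_equal(hwe_exact(make_locus_counts(n_II, n_ID, n_DD)),
                   oracle_hwe_exact(n_II, n_ID, n_DD),
                   tolerance = 1e-9,
                   info = paste(n_II, n_ID, n_DD))
    }
  }
})

test_that("chi-square HWE test matches hand computation and closed forms", {
  res <- hwe_chi2(make_locus_counts(42, 71, 56))
  expect_equal(res$chi2, 4.0058, tolerance = 1e-4)
  # all-heterozygote sample at p = 0.5: chi2 equals n
  for (n in c(10, 25)) {
    expect_equal(hwe_chi2(make_locus_counts(0, n, 0))$chi2, n)
  }
  # exact HWE proportions give chi2 = 0
  expect_equal(hwe_chi2(make_locus_counts(25, 50, 25))$chi2, 0)
  expect_equal(hwe_chi2(make_locus_counts(30, 0, 0)),
               list(chi2 = 0, p = 1))
})

test_that("exact and chi-square p-values agree in the decision regime", {
  set.seed(53)
  res <- t(sapply(1:200, function(i) {
    p <- runif(1, 0.15, 0.85)
    cnt <- as.vector(rmultinom(1, 169, c(p^2, 2 * p * (1 - p), (1 - p)^2)))
    c_ <- make_locus_counts(cnt[1], cnt[2], cnt[3])
    c(hwe_exact(c_), hwe_chi2(c_)$p)
  }))
  small <- res[, 1] < 0.1 | res[, 2] < 0.1
  expect_lt(max(abs(res[small, 1] - res[small, 2])), 0.05)
  expect_gt(cor(res[, 1], res[, 2]), 0.95)
})

test_that("Bonferroni threshold reproduces the panel-wide level", {
  expect_equal(signif(bonferroni_threshold(0.05, 30), 3), 0.00167)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 435), 0.05 / 435)
  expect_error(bonferroni_threshold(1.2, 3))
})

test_that("HWE table flags loci against the corrected threshold", {
  gm <- simulate_panel_like(n = 80, seed = 5)
  tab <- hwe_table(gm, alpha = 0.05)
  expect_equal(nrow(tab), 30)
  expect_equal(attr(tab, "bonferroni_threshold"), 0.05 / 30)
  expect_identical(tab$significant_after_bonferroni,
                   tab$p_exact < 0.05 / 30)
})

test_that("EM equals closed-form counting when no phase ambiguity exists", {
  tab <- matrix(c(5, 2, 0, 3, 0, 0, 0, 0, 1), 3, 3)  # no double hets
  f <- em_haplotype_freqs(tab)
  base <- indelpanel:::hap_base_counts(
    matrix(as.double(tab), 3, 3, dimnames = list(0:2, 0:2)))
  expect_equal(unname(unclass(f)[1:4]), unname(base / sum(base)),
               tolerance = 1e-12)
  expect_error(em_haplotype_freqs(matrix(0, 3, 3)), "empty")
})

test_that("EM recovers simulating haplotype frequencies and is monotone", {
  truth <- c(0.4, 0.1, 0.1, 0.4)
  gm <- simulate_ld_pair(truth, n = 500, seed = 41)
  tab <- pair_genotype_table(gm, "locusA", "locusB")
  f <- em_haplotype_freqs(tab)
  se <- sqrt(truth * (1 - truth) / 1000)
  expect_true(all(abs(unclass(f)[1:4] - truth) < 3 * se + 0.02))

  # per-iteration monotonicity of the observed-data log-likelihood
  tabs <- list(tab, pair_genotype_table(
    simulate_ld_pair(c(0.7, 0.05, 0.2, 0.05), 120, seed = 42),
    "locusA", "locusB"))
  for (tb in tabs) {
    tb <- matrix(as.double(tb), 3, 3, dimnames = list(0:2, 0:2))
    base <- indelpanel:::hap_base_counts(tb)
    n_dh <- tb["1", "1"]; n_hap <- 2 * sum(tb)
    p1 <- unname(base["II"] + base["ID"] + n_dh) / n_hap
    p2 <- unname(base["II"] + base["DI"] + n_dh) / n_hap
    f_it <- c(II = p1 * p2, ID = p1 * (1 - p2), DI = (1 - p1) * p2,
              DD = (1 - p1) * (1 - p2))
    ll_prev <- indelpanel:::pair_loglik(f_it, tb)
    for (it in 1:50) {
      denom <- f_it["II"] * f_it["DD"] + f_it["ID"] * f_it["DI"]
      w <- if (denom > 0) unname(f_it["II"] * f_it["DD"] / denom) else 0.5
      f_it <- stats::setNames(
        (base + n_dh * c(w, 1 - w, 1 - w, w)) / n_hap, names(f_it))
      ll <- indelpanel:::pair_loglik(f_it, tb)
      expect_gte(ll, ll_prev - 1e-9)
      ll_prev <- ll
    }
  }
})

test_that("EM log-likelihood is not beaten by a fine grid search", {
  set.seed(61)
  for (i in 1:10) {
    truth <- as.vector(rmultinom(1, 40, runif(4, 0.05, 1)))
    truth <- truth / sum(truth)
    gm <- simulate_ld_pair(truth, n = 150, seed = 6000 + i)
    tab <- pair_genotype_table(gm, "locusA", "locusB")
    f <- em_haplotype_freqs(tab)
    grid <- oracle_ld_grid(tab)
    expect_gte(attr(f, "loglik"), grid$loglik - 1e-6)
    expect_lt(abs(f[["II"]] - grid$f_II), 0.0015)
  }
})

test_that("LD coefficients match closed forms and are label-swap invariant", {
  ind <- ld_stats(c(II = 0.25, ID = 0.25, DI = 0.25, DD = 0.25))
  expect_equal(ind$D, 0)
  expect_equal(ind$r2, 0)
  full <- ld_stats(c(II = 0.5, ID = 0, DI = 0, DD = 0.5))
  expect_equal(full$D_prime, 1)
  expect_equal(full$r2, 1)
  mid <- ld_stats(c(II = 0.4, ID = 0.1, DI = 0.1, DD = 0.4))
  expect_equal(mid$D, 0.15)
  expect_equal(mid$r2, 0.36)

  set.seed(71)
  for (i in 1:20) {
    f <- as.vector(rmultinom(1, 100, runif(4, 0.05, 1))) / 100
    if (any(c(f[1] + f[2], f[1] + f[3]) %in% c(0, 1))) next
    f <- stats::setNames(f, c("II", "ID", "DI", "DD"))
    swapped_a <- stats::setNames(f[c("DI", "DD", "II", "ID")],
                                 c("II", "ID", "DI", "DD"))
    expect_equal(ld_stats(swapped_a)$r2, ld_stats(f)$r2,
                 tolerance = 1e-12)
  }

  mono <- ld_stats(c(II = 0.5, ID = 0.5, DI = 0, DD = 0))
  expect_false(mono$defined)
  expect_true(is.na(mono$r2))
})

test_that("the pair screen enumerates unordered pairs and flags thresholds", {
  gm <- simulate_hwe_population(40, runif(5, 0.3, 0.7), seed = 81)
  sc <- ld_screen(gm)
  expect_equal(nrow(sc), 10)
  two <- ld_screen(simulate_hwe_population(30, c(0.5, 0.5), seed = 82))
  expect_equal(nrow(two), 1)
  # hap freqs rows sum to one
  expect_rows_sum_to_one(as.matrix(sc[, c("f_II", "f_ID", "f_DI", "f_DD")]))
  # independent loci at study-like n: nothing above the 0.8 cutoff
  big <- simulate_hwe_population(169, runif(8, 0.2, 0.8), seed = 83)
  sb <- ld_screen(big, r2_threshold = 0.8)
  expect_equal(sum(sb$above_threshold, na.rm = TRUE), 0)
  # a monomorphic locus yields undefined r2, excluded from counting
  gm$calls[, 2] <- "II"
  sm <- ld_screen(gm)
  expect_true(anyNA(sm$above_threshold))
})
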