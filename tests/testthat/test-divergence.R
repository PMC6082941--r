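test_that("allele count tables conserve allele numbers", {
  calls <- matrix(c("II", "II", "DD", "DD"), 4, 1,
                  dimnames = list(paste0("s", 1:4), "L1"))
  gm <- genotype_matrix(calls, populations = c("a", "a", "b", "b"))
  tab <- allele_count_2x2(gm, "a", "b", "L1")
  expect_equal(unname(tab), matrix(c(4L, 0L, 0L, 4L), 2, 2))
  expect_equal(sum(tab), 2 * 4)

  ft <- freq_table(matrix(c(0.25, 0.5), 2, 1,
                          dimnames = list(c("a", "b"), "L1")),
                   sample_size = c(a = 10L, b = 20L))
  tab2 <- allele_count_2x2(ft, "a", "b", "L1")
  expect_equal(unname(tab2), matrix(c(5L, 20L, 15L, 20L), 2, 2))
  ft$sample_size <- NULL
  expect_error(allele_count_2x2(ft, "a", "b", "L1"), "sample_size")
})

test_that("Fisher exact test matches exhaustive enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(4, 0, 0, 4), 2, 2)), 2 / 70,
               tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2)), 1)
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "all-zero")

  # tables with total <= 16, sampled densely per total
  set.seed(19)
  for (n in 1:16) {
    parts <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    parts <- parts[rowSums(parts) <= n, ]
    for (r in sample(nrow(parts), min(nrow(parts), 60))) {
      tab <- matrix(c(parts$a[r], parts$b[r], parts$c[r],
                      n - parts$a[r] - parts$b[r] - parts$c[r]), 2, 2)
      expect_equal(fisher_exact_2x2(tab), oracle_fisher_2x2(tab),
                   tolerance = 1e-7, info = paste(tab, collapse = ","))
    }
  }
  # invariance under row and column swaps
  set.seed(91)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 6) + 1, 2, 2)
    p <- fisher_exact_2x2(tab)
    expect_equal(fisher_exact_2x2(tab[2:1, ]), p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[, 2:1]), p, tolerance = 1e-12)
  }
})

test_that("permutation theta test calibrates on null and saturates on fixed differences", {
  gm <- simulate_hwe_population(60, runif(9, 0.3, 0.7), seed = 101)
  gm$populations <- rep(c("a", "b"), each = 30)
  ps <- vapply(locus_ids(gm), function(l)
    as.numeric(permutation_fst_test(gm, "a", "b", l, n_perm = 199,
                                    seed = 77)), numeric(1))
  expect_gt(median(ps), 0.2)
  expect_lt(median(ps), 0.8)

  calls <- matrix(c(rep("II", 20), rep("DD", 20)), 40, 1,
                  dimnames = list(paste0("s", 1:40), "L1"))
  fixed <- genotype_matrix(calls, populations = rep(c("a", "b"), each = 20))
  pf <- permutation_fst_test(fixed, "a", "b", "L1", n_perm = 199, seed = 5)
  expect_equal(as.numeric(pf), 1 / 200)
  pf2 <- permutation_fst_test(fixed, "b", "a", "L1", n_perm = 199, seed = 5)
  expect_equal(as.numeric(pf), as.numeric(pf2))
})

test_that("differentiation profiles count Bonferroni-significant loci", {
  gm <- simulate_balding_nichols(c(169, 169), L = 30, fst_target = 0.15,
                                 seed = 111)
  prof <- differentiation_profile(gm, "pop1", "pop2")
  expect_equal(nrow(prof$loci), 30)
  expect_equal(prof$threshold, 0.05 / 30)
  expect_gt(prof$n_significant, 0)
  # monotone in alpha
  looser <- differentiation_profile(gm, "pop1", "pop2", alpha = 0.2)
  expect_gte(looser$n_significant, prof$n_significant)
  # a population against itself shows nothing
  half <- gm
  half$calls <- rbind(gm$calls[1:169, ], gm$calls[1:169, ])
  rownames(half$calls) <- paste0("s", 1:338)
  half$populations <- rep(c("x", "y"), each = 169)
  self_prof <- differentiation_profile(half, "x", "y")
  expect_equal(self_prof$n_significant, 0)
})

test_that("Nei's D_A matches closed forms and is a bounded semimetric", {
  expect_equal(nei_da(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(nei_da(1, 0), 1)
  expect_equal(nei_da(0.8, 0.2), 0.2, tolerance = 1e-12)
  set.seed(121)
  for (i in 1:30) {
    x <- runif(10); y <- runif(10)
    expect_equal(nei_da(x, y), nei_da(y, x))
    expect_gte(nei_da(x, y), 0)
    expect_lte(nei_da(x, y), 1)
    expect_equal(nei_da(x, x), 0, tolerance = 1e-12)
    if (max(abs(x - y)) > 1e-3) expect_gt(nei_da(x, y), 0)
  }
  expect_error(nei_da(c(a = 0.5), c(b = 0.5)), "mismatched")
})

test_that("Weir-Cockerham theta is near zero on a random split and near one on fixed differences", {
  gm <- simulate_hwe_population(500, runif(100, 0.2, 0.8), seed = 131)
  gm$populations <- rep(c("a", "b"), 250)
  th <- as.numeric(wc_fst(gm))
  expect_lt(abs(th), 0.01)

  calls <- cbind(c(rep("II", 25), rep("DD", 25)),
                 c(rep("DD", 25), rep("II", 25)))
  dimnames(calls) <- list(paste0("s", 1:50), c("L1", "L2"))
  fixed <- genotype_matrix(calls, populations = rep(c("a", "b"), each = 25))
  expect_gt(as.numeric(wc_fst(fixed)), 0.95)

  expect_error(wc_fst(subset_populations(gm, "a")), "two populations")
  tiny <- genotype_matrix(matrix("II", 3, 1,
                                 dimnames = list(paste0("s", 1:3), "L")),
                          c("a", "a", "b"))
  expect_error(wc_fst(tiny), "fewer than 2")
})

test_that("theta is invariant to allele-label swaps and population order", {
  gm <- simulate_balding_nichols(c(60, 60), L = 40, fst_target = 0.08,
                                 seed = 141)
  th <- as.numeric(wc_fst(gm, c("pop1", "pop2")))
  expect_equal(as.numeric(wc_fst(gm, c("pop2", "pop1"))), th,
               tolerance = 1e-12)
  flip <- gm
  flip$calls[flip$calls == "II"] <- "tmp"
  flip$calls[flip$calls == "DD"] <- "II"
  flip$calls[flip$calls == "tmp"] <- "DD"
  expect_equal(as.numeric(wc_fst(flip)), th, tolerance = 1e-12)
})

test_that("distance matrices are symmetric, floored and rank-concordant", {
  gm <- simulate_balding_nichols(c(50, 50, 50, 50), L = 60,
                                 fst_target = 0.08, seed = 151)
  dm_da <- distance_matrix(gm, "da")
  dm_fst <- distance_matrix(gm, "fst")
  for (dm in list(dm_da, dm_fst)) {
    expect_equal(unclass(dm), t(unclass(dm)))
    expect_equal(unname(diag(dm)), rep(0, 4))
    expect_true(all(dm >= 0))
  }
  lower <- lower.tri(dm_da)
  expect_gt(cor(dm_da[lower], attr(dm_fst, "raw")[lower],
                method = "spearman"), 0)

  # identical frequency rows give zero D_A off-diagonal
  ft <- freq_table(matrix(0.4, 2, 5,
                          dimnames = list(c("x", "y"), paste0("L", 1:5))))
  expect_equal(unname(unclass(distance_matrix(ft, "da"))),
               matrix(0, 2, 2))
})
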