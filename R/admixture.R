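#' Admixture-model Gibbs sampler (STRUCTURE-style clustering)
#'
#' Bayesian clustering of diallelic genotypes under the admixture model:
#' each of an individual's two allele copies at every locus carries a latent
#' cluster-of-origin. The Gibbs sweep (i) samples every allele-copy
#' assignment conditional on the individual's ancestry vector and the
#' cluster allele frequencies, (ii) updates cluster insertion frequencies
#' from conjugate `Beta(1 + n_I, 1 + n_D)` posteriors, and (iii) updates
#' each ancestry vector from `Dirichlet(alpha + assignment counts)`. By
#' default the symmetric Dirichlet hyperparameter `alpha` is itself inferred
#' with a Metropolis random-walk step under a uniform prior on (0, 10) —
#' the scheme STRUCTURE uses — which lets the posterior concentrate
#' ancestry vectors when individuals are in fact unadmixed; pass a numeric
#' `alpha` to fix it instead. Posterior means over the post-burn-in sweeps
#' are returned. The run is fully reproducible given `seed`; the
#' observed-data log-likelihood is recorded along the chain for convergence
#' inspection.
#'
#' No within-chain label-switching correction is applied; for well-separated
#' clusters (the intended desk scale) chains do not switch in practice, and
#' [align_runs()] reconciles labels across independent runs.
#'
#' @param gm a [genotype_matrix()] (all loci diallelic by construction)
#' @param K number of clusters (>= 1)
#' @param burn_in discarded initial sweeps (default 10000)
#' @param reps retained sweeps after burn-in (default 10000)
#' @param seed RNG seed (required)
#' @param alpha `"infer"` (default) or a fixed positive numeric value of
#'   the Dirichlet ancestry hyperparameter
#' @param record_every record the log-likelihood every this many sweeps
#' @return object of class `admixture_fit`: `K`, `Q` (posterior-mean
#'   ancestry matrix, rows sum to 1), `cluster_allele_freqs` (K x L
#'   posterior-mean insertion frequencies), `alpha` (posterior mean, or the
#'   fixed value), `loglik_trace` (data frame `iter`, `loglik`, `alpha`),
#'   `burn_in`, `reps`, `seed`, `sample_ids`, `populations`
#' @examples
#' gm <- simulate_hwe_population(n = 30, p = rep(0.5, 10), seed = 7)
#' fit <- structure_fit(gm, K = 1, burn_in = 50, reps = 50, seed = 7)
#' stopifnot(all(fit$Q == 1))
#' @export
structure_fit <- function(gm, K, burn_in = 10000, reps = 10000, seed,
                          alpha = "infer", record_every = 10) {
  stopifnot(K >= 1, burn_in >= 0, reps >= 1)
  if (missing(seed)) stop("seed is required")
  infer_alpha <- identical(alpha, "infer")
  if (!infer_alpha) stopifnot(is.numeric(alpha), alpha > 0)
  alpha0 <- if (infer_alpha) 1 else alpha
  alpha_max <- 10; alpha_sd <- 0.05
  X <- dosage_matrix(gm)
  n <- nrow(X); L <- ncol(X)
  A1 <- 1 * (X >= 1)        # first allele copy: carries I iff dosage >= 1
  A2 <- 1 * (X == 2)        # second copy: carries I iff homozygous II
  obs1 <- !is.na(A1); obs2 <- !is.na(A2)
  phat <- colSums(X, na.rm = TRUE) / (2 * colSums(!is.na(X)))

  sample_z <- function(A, obs, Q, P) {
    w <- matrix(0, n * L, K)
    for (k in seq_len(K)) {
      pk <- matrix(P[k, ], n, L, byrow = TRUE)
      w[, k] <- as.vector(Q[, k] * (A * pk + (1 - A) * (1 - pk)))
    }
    u <- stats::runif(n * L) * rowSums(w)
    z <- integer(n * L)
    acc <- 0
    for (k in seq_len(K)) {
      acc <- acc + w[, k]
      z[z == 0L & u <= acc] <- k
    }
    z[z == 0L] <- K  # numerical guard for u landing on the total
    z <- matrix(z, n, L)
    z[!obs] <- NA_integer_
    z
  }

  # log-density of the ancestry matrix under a symmetric Dirichlet(a)
  lp_alpha <- function(a, Q) {
    n * (lgamma(K * a) - K * lgamma(a)) + (a - 1) * sum(log(Q))
  }
  res <- withr::with_seed(seed, {
    Q <- matrix(1 / K, n, K)
    P <- matrix(pmin(pmax(rep(phat, each = K) +
                            stats::runif(K * L, -0.05, 0.05), 0.01), 0.99),
                K, L)
    if (K == 1) { Q[] <- 1 }
    a_cur <- alpha0
    Qsum <- matrix(0, n, K); Psum <- matrix(0, K, L); a_sum <- 0
    trace_iter <- integer(); trace_ll <- numeric(); trace_a <- numeric()
    total <- burn_in + reps
    for (it in seq_len(total)) {
      z1 <- sample_z(A1, obs1, Q, P)
      z2 <- sample_z(A2, obs2, Q, P)
      r <- matrix(0, n, K)
      for (k in seq_len(K)) {
        m1 <- z1 == k; m2 <- z2 == k
        cI <- colSums(A1 * m1, na.rm = TRUE) + colSums(A2 * m2, na.rm = TRUE)
        cT <- colSums(m1, na.rm = TRUE) + colSums(m2, na.rm = TRUE)
        P[k, ] <- stats::rbeta(L, 1 + cI, 1 + (cT - cI))
        r[, k] <- rowSums(m1, na.rm = TRUE) + rowSums(m2, na.rm = TRUE)
      }
      G <- matrix(stats::rgamma(n * K, shape = a_cur + r), n, K)
      Q <- G / rowSums(G)
      Q <- pmax(Q, 1e-12); Q <- Q / rowSums(Q)
      if (infer_alpha && K > 1) {
        a_prop <- a_cur + stats::rnorm(1, 0, alpha_sd)
        if (a_prop > 0 && a_prop < alpha_max &&
            log(stats::runif(1)) < lp_alpha(a_prop, Q) - lp_alpha(a_cur, Q))
          a_cur <- a_prop
      }
      if (it > burn_in) {
        Qsum <- Qsum + Q
        Psum <- Psum + P
        a_sum <- a_sum + a_cur
      }
      if (it %% record_every == 0 || it == total) {
        trace_iter <- c(trace_iter, it)
        trace_ll <- c(trace_ll, admix_loglik(X, Q, P))
        trace_a <- c(trace_a, a_cur)
      }
    }
    list(Q = Qsum / reps, P = Psum / reps, alpha = a_sum / reps,
         trace = data.frame(iter = trace_iter, loglik = trace_ll,
                            alpha = trace_a))
  })
  Qm <- res$Q / rowSums(res$Q)
  dimnames(Qm) <- list(sample_ids(gm), paste0("cluster", seq_len(K)))
  Pm <- res$P
  dimnames(Pm) <- list(paste0("cluster", seq_len(K)), locus_ids(gm))
  structure(list(K = K, Q = Qm, cluster_allele_freqs = Pm,
                 alpha = res$alpha, loglik_trace = res$trace,
                 burn_in = burn_in, reps = reps, seed = seed,
                 sample_ids = sample_ids(gm),
                 populations = gm$populations),
            class = "admixture_fit")
}

#' Observed-data log-likelihood under the admixture model
#'
#' Marginalises the latent per-copy cluster assignments: the insertion
#' probability of each copy of individual `i` at locus `l` is
#' `theta_il = sum_k Q_ik P_kl`, and the two copies are independent.
#'
#' @param X dosage matrix (0/1/2, `NA` missing)
#' @param Q n x K ancestry matrix
#' @param P K x L cluster insertion frequencies
#' @return scalar log-likelihood
#' @export
admix_loglik <- function(X, Q, P) {
  theta <- Q %*% P
  eps <- 1e-300
  ll <- ifelse(X == 2, 2 * log(theta + eps),
        ifelse(X == 0, 2 * log(1 - theta + eps),
               log(2) + log(theta + eps) + log(1 - theta + eps)))
  sum(ll[!is.na(X)])
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("Admixture fit: K =", x$K, ",", nrow(x$Q), "individuals,",
      ncol(x$cluster_allele_freqs), "loci\n")
  cat("burn-in", x$burn_in, "+", x$reps, "sweeps, seed", x$seed, "\n")
  cat("final log-likelihood",
      round(utils::tail(x$loglik_trace$loglik, 1), 2), "\n")
  invisible(x)
}

#' Align cluster labels across admixture runs
#'
#' Cluster labels are only identified up to permutation; this matches every
#' run's columns to the first run by greedy assignment minimising the
#' root-mean-square difference between ancestry columns (deterministic:
#' ties resolve to the lowest index).
#'
#' @param fits list of `admixture_fit` objects with identical `K`
#' @return the list with `Q` columns and `cluster_allele_freqs` rows
#'   permuted; each fit carries its permutation as attribute `permutation`
#' @export
align_runs <- function(fits) {
  stopifnot(length(fits) >= 1)
  K <- fits[[1]]$K
  if (!all(vapply(fits, function(f) f$K, numeric(1)) == K))
    stop("all fits must share the same K")
  ref <- fits[[1]]$Q
  out <- fits
  attr(out[[1]], "permutation") <- seq_len(K)
  for (f in seq_along(fits)[-1]) {
    Q <- fits[[f]]$Q
    sim <- -sqrt(outer(seq_len(K), seq_len(K), Vectorize(function(a, b)
      mean((ref[, a] - Q[, b])^2))))
    perm <- integer(K)
    free_r <- rep(TRUE, K); free_c <- rep(TRUE, K)
    for (step in seq_len(K)) {
      s <- sim
      s[!free_r, ] <- -Inf; s[, !free_c] <- -Inf
      best <- which(s == max(s), arr.ind = TRUE)[1, ]
      perm[best[1]] <- best[2]
      free_r[best[1]] <- FALSE; free_c[best[2]] <- FALSE
    }
    fit <- fits[[f]]
    fit$Q <- fit$Q[, perm, drop = FALSE]
    colnames(fit$Q) <- colnames(ref)
    fit$cluster_allele_freqs <- fit$cluster_allele_freqs[perm, , drop = FALSE]
    rownames(fit$cluster_allele_freqs) <- rownames(fits[[1]]$cluster_allele_freqs)
    attr(fit, "permutation") <- perm
    out[[f]] <- fit
  }
  out
}

#' Per-population mean ancestry for stacked bar charts
#'
#' Population-ordered mean ancestry vectors plus sample sizes, the numbers
#' behind a STRUCTURE-style stacked bar chart whose bar widths are
#' proportional to population sample size.
#'
#' @param fit an `admixture_fit`
#' @param population_labels label per individual (default: the labels stored
#'   in the fit)
#' @return data frame: `population`, `n`, one column per cluster
#' @export
membership_barchart_data <- function(fit, population_labels = NULL) {
  if (is.null(population_labels)) population_labels <- fit$populations
  stopifnot(length(population_labels) == nrow(fit$Q))
  pops <- unique(population_labels)
  rows <- lapply(pops, function(p) {
    sel <- population_labels == p
    cbind(data.frame(population = p, n = sum(sel),
                     stringsAsFactors = FALSE),
          as.data.frame(t(colMeans(fit$Q[sel, , drop = FALSE]))))
  })
  do.call(rbind, rows)
}
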