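#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q-criterion and the
#' standard branch-length formulas. Ties in the Q minimisation are broken
#' deterministically on the lexicographically smallest (sorted) label pair,
#' so the result is identical across platforms and input orderings. The
#' returned tree is unrooted with all input taxa as leaves. Negative branch
#' lengths (possible on non-additive input) are kept by default, matching
#' common NJ software; `negative_branches = "zero"` clamps them to 0 and
#' moves the length onto the sister branch so pairwise path lengths through
#' the joined node are preserved.
#'
#' @param dm a matrix accepted by [as_distance_matrix()] with >= 3 taxa
#' @param negative_branches `"keep"` or `"zero"`
#' @return an `ape` `phylo` object
#' @examples
#' d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' tr <- neighbor_joining(d)
#' @export
neighbor_joining <- function(dm, negative_branches = c("keep", "zero")) {
  negative_branches <- match.arg(negative_branches)
  dm <- as_distance_matrix(dm)
  m <- nrow(dm)
  if (m < 3) stop("neighbor joining needs at least 3 taxa")
  labs <- rownames(dm)
  safe <- gsub("[,;:()\\[\\]'\"[:space:]]+", "_", labs)
  if (!identical(safe, labs))
    warning("tree labels sanitised for Newick (spaces/punctuation -> '_')")
  if (anyDuplicated(safe)) stop("labels collide after Newick sanitising")
  d <- unclass(dm)
  frag <- safe            # Newick fragment per active node
  key <- safe             # tie-break key: smallest leaf label in subtree
  fix_neg <- function(vi, vj, dij) {
    if (negative_branches == "zero") {
      if (vi < 0) { vi <- 0; vj <- dij }
      if (vj < 0) { vj <- dij; vi <- 0 }
    }
    c(vi, vj)
  }
  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_key <- apply(cand, 1, function(ij) {
      k <- sort(c(key[ij[1]], key[ij[2]]))
      paste(k, collapse = "\r")
    })
    pick <- cand[order(pair_key)[1], ]
    i <- pick[[1]]; j <- pick[[2]]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    v <- fix_neg(vi, vj, d[i, j])
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt_bl(v[1]),
                        frag[j], fmt_bl(v[2]))
    new_key <- min(key[i], key[j])
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
    key <- c(key[keep], new_key)
    rownames(d) <- colnames(d) <- NULL
  }
  # final unrooted join of the last three nodes
  a <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  cc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (negative_branches == "zero") { a <- max(a, 0); b <- max(b, 0); cc <- max(cc, 0) }
  ord <- order(key)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[ord[1]], fmt_bl(c(a, b, cc)[ord[1]]),
                 frag[ord[2]], fmt_bl(c(a, b, cc)[ord[2]]),
                 frag[ord[3]], fmt_bl(c(a, b, cc)[ord[3]]))
  ape::read.tree(text = nwk)
}

fmt_bl <- function(x) formatC(x, digits = 12, format = "g", flag = "")

#' Classical (Torgerson) multidimensional scaling
#'
#' Metric MDS: double-centering of the squared distance matrix and
#' eigendecomposition, with coordinates taken from the leading non-negative
#' eigenvalues (via [stats::cmdscale()]). If fewer positive eigenvalues than
#' requested dimensions exist, the embedding is reduced with a warning;
#' negative eigenvalues (non-Euclidean input) are dropped with a warning.
#'
#' @param dm a matrix accepted by [as_distance_matrix()] with >= 2 labels
#' @param n_dims target dimensionality (default 2)
#' @return list with `coords` (labels x dims matrix) and `eigenvalues`
#'   (all `n` eigenvalues of the centred matrix)
#' @export
classical_mds <- function(dm, n_dims = 2) {
  dm <- as_distance_matrix(dm)
  n <- nrow(dm)
  if (n < 2) stop("need at least 2 labels")
  stopifnot(n_dims >= 1)
  if (n_dims > n - 1) stop("n_dims must be <= matrix size - 1")
  fit <- suppressWarnings(stats::cmdscale(dm, k = n - 1, eig = TRUE))
  eig <- fit$eig
  tol <- 1e-9 * max(abs(eig), 1)
  n_pos <- sum(eig > tol)
  if (any(eig < -tol))
    warning("input is not Euclidean-embeddable: ",
            sum(eig < -tol), " negative eigenvalue(s) dropped")
  k <- min(n_dims, max(n_pos, 1))
  if (k < n_dims)
    warning("only ", n_pos, " positive eigenvalue(s): embedding reduced to ",
            k, " dimension(s)")
  coords <- fit$points[, seq_len(min(k, ncol(fit$points))), drop = FALSE]
  if (ncol(coords) < k)  # degenerate all-zero matrix: cmdscale returns none
    coords <- matrix(0, n, k, dimnames = list(rownames(dm), NULL))
  rownames(coords) <- rownames(dm)
  list(coords = coords, eigenvalues = eig)
}

#' Centroid-silhouette group-separation score
#'
#' For each point: `a` = distance to its own group centroid, `b` = smallest
#' distance to any other group centroid, score `(b - a) / max(a, b)` (0 when
#' both are 0); the mean over points summarises how well the ordination
#' separates the groups. Singleton groups contribute with `a = 0`.
#'
#' @param coords numeric matrix of point coordinates (rows = points)
#' @param group_labels group label per point (>= 2 distinct groups)
#' @return scalar in \[-1, 1\]
#' @export
group_separation_score <- function(coords, group_labels) {
  coords <- as.matrix(coords)
  group_labels <- as.character(group_labels)
  groups <- unique(group_labels)
  if (length(groups) < 2) stop("need at least 2 groups")
  centroids <- t(sapply(groups, function(g)
    colMeans(coords[group_labels == g, , drop = FALSE])))
  scores <- vapply(seq_len(nrow(coords)), function(i) {
    dc <- sqrt(rowSums(sweep(centroids, 2, coords[i, ])^2))
    own <- match(group_labels[i], groups)
    a <- dc[own]
    b <- min(dc[-own])
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(scores)
}
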