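#' Clustering evaluation metrics
#'
#' Partition-agreement metrics (NMI, ARI, pair-counting Jaccard),
#' internal quality metrics (silhouette coefficient, Dunn index),
#' diversity wrappers, and the seeded k-means protocol used for single
#' clustering on the co-embedding.
#'
#' @param a,b integer/factor label vectors of equal length.
#' @name metrics
NULL

check_partitions <- function(a, b) {
  if (length(a) != length(b))
    stop("argument error: partitions must have equal length")
  invisible(TRUE)
}

contingency <- function(a, b) table(a, b)

#' @describeIn metrics Normalized mutual information; mutual information
#'   of the contingency table normalized by the arithmetic mean of the
#'   two label entropies. In `[0, 1]`; 1 for identical partitions.
#' @export
nmi <- function(a, b) {
  check_partitions(a, b)
  n <- length(a)
  ct <- contingency(a, b)
  pij <- ct / n
  pa <- rowSums(pij)
  pb <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pa, pb)[nz]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha + hb == 0) return(1)      # both partitions trivial, hence identical
  max(0, min(1, mi / ((ha + hb) / 2)))
}

#' @describeIn metrics Adjusted Rand index from pair counts,
#'   `(RI - E[RI]) / (max RI - E[RI])`; 1 for identical partitions, ~0
#'   for independent ones.
#' @export
ari <- function(a, b) {
  check_partitions(a, b)
  ct <- contingency(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(ct))
  sa <- sum(ch2(rowSums(ct)))
  sb <- sum(ch2(colSums(ct)))
  tot <- ch2(n)
  expected <- sa * sb / tot
  mx <- (sa + sb) / 2
  if (mx == expected) return(0)
  (sij - expected) / (mx - expected)
}

#' @describeIn metrics Pair-counting Jaccard index
#'   `n11 / (n11 + n10 + n01)` over co-clustered cell pairs; compares
#'   two full clusterings (not set-matching).
#' @export
jaccard_index <- function(a, b) {
  check_partitions(a, b)
  ct <- contingency(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  n11 <- sum(ch2(ct))
  pa <- sum(ch2(rowSums(ct)))
  pb <- sum(ch2(colSums(ct)))
  denom <- pa + pb - n11       # n11 + n10 + n01
  if (denom == 0) return(1)    # no co-clustered pairs in either partition
  n11 / denom
}

#' @describeIn metrics Diversity between two clusterings: `1 - NMI` and
#'   `1 - JI`, both in `[0, 1]` (larger = less redundant).
#' @export
diversity <- function(a, b) {
  c(one_minus_nmi = 1 - nmi(a, b), one_minus_ji = 1 - jaccard_index(a, b))
}

#' @describeIn metrics Mean silhouette width over all points,
#'   `(b_i - a_i) / max(a_i, b_i)` with Euclidean distances (`a_i` mean
#'   within-cluster distance excluding self, `b_i` smallest mean
#'   distance to another cluster); points with `max(a_i, b_i) = 0` or in
#'   singleton clusters score 0.
#' @param points numeric matrix, rows = cells, for `silhouette_score`
#'   and `dunn_index`.
#' @param labels cluster labels for the rows of `points`.
#' @export
silhouette_score <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  n <- nrow(points)
  if (k < 2) stop("metric error: need at least 2 clusters")
  if (k == n) stop("metric error: all clusters are singletons")
  dm <- as.matrix(stats::dist(points))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a_i <- sum(dm[i, own]) / (sum(own) - 1)
    b_i <- min(vapply(setdiff(seq_len(k), labels[i]),
                      function(j) mean(dm[i, labels == j]), numeric(1)))
    m <- max(a_i, b_i)
    s[i] <- if (m == 0) 0 else (b_i - a_i) / m
  }
  mean(s)
}

#' @describeIn metrics Dunn index: minimum single-linkage inter-cluster
#'   distance divided by maximum intra-cluster diameter (Euclidean).
#' @export
dunn_index <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("metric error: need at least 2 clusters")
  dm <- as.matrix(stats::dist(points))
  diam <- max(vapply(seq_len(k), function(j) {
    idx <- which(labels == j)
    if (length(idx) < 2) 0 else max(dm[idx, idx])
  }, numeric(1)))
  if (diam == 0) stop("metric error: zero maximum intra-cluster diameter")
  sep <- min(vapply(seq_len(k - 1), function(j) {
    min(vapply((j + 1):k, function(j2) min(dm[labels == j, labels == j2]),
               numeric(1)))
  }, numeric(1)))
  sep / diam
}

#' Seeded k-means single clustering on a co-embedding
#'
#' The single-clustering protocol: Lloyd k-means with seeded
#' multi-restart on the fused co-embedding; deterministic given `seed`.
#' Columns are standardized first by default, so latent dimensions with
#' inflated scale do not dominate the Euclidean geometry (the same
#' convention the subspace-clustering stage uses).
#'
#' @param ZI numeric matrix, cells x latent dimensions.
#' @param k number of clusters (`2 <= k <= N`).
#' @param seed RNG seed.
#' @param nstart number of random restarts.
#' @param standardize standardize columns to zero mean, unit variance
#'   before clustering.
#' @return Integer label vector of length `nrow(ZI)`.
#' @export
kmeans_single_clustering <- function(ZI, k, seed = 1, nstart = 10,
                                     standardize = TRUE) {
  ZI <- as.matrix(ZI)
  if (standardize && nrow(ZI) > 1) {
    sds <- apply(ZI, 2, stats::sd)
    ZI <- sweep(sweep(ZI, 2, colMeans(ZI)), 2, pmax(sds, 1e-12), "/")
  }
  if (k > nrow(ZI)) stop("argument error: k exceeds the number of cells")
  if (k < 1) stop("argument error: k must be positive")
  if (k == nrow(ZI)) return(seq_len(k))   # every cell its own cluster
  set.seed(seed)
  stats::kmeans(ZI, centers = k, nstart = nstart, iter.max = 100)$cluster
}
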