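# Brute-force oracles, independent of the package implementations.

# central finite-difference gradient of scalar f at matrix x
num_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# O(N^2) pair-counting over all cell pairs
pair_counts <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa) n10 <- n10 + 1
    else if (sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
}

oracle_jaccard <- function(a, b) {
  pc <- pair_counts(a, b)
  unname(pc["n11"] / (pc["n11"] + pc["n10"] + pc["n01"]))
}

oracle_ari <- function(a, b) {
  pc <- pair_counts(a, b)
  n <- length(a)
  tot <- n * (n - 1) / 2
  sa <- pc["n11"] + pc["n10"]
  sb <- pc["n11"] + pc["n01"]
  expected <- sa * sb / tot
  unname((pc["n11"] - expected) / ((sa + sb) / 2 - expected))
}

oracle_nmi <- function(a, b) {
  n <- length(a)
  mi <- 0
  for (u in unique(a)) for (v in unique(b)) {
    pij <- sum(a == u & b == v) / n
    if (pij > 0) mi <- mi + pij * log(pij / (mean(a == u) * mean(b == v)))
  }
  ent <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log(p))
  }
  mi / ((ent(a) + ent(b)) / 2)
}

oracle_silhouette <- function(pts, lab) {
  n <- nrow(pts)
  d <- function(i, j) sqrt(sum((pts[i, ] - pts[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(lab == lab[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a_i <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b_i <- min(vapply(setdiff(unique(lab), lab[i]), function(cl) {
      mean(vapply(which(lab == cl), function(j) d(i, j), numeric(1)))
    }, numeric(1)))
    s[i] <- if (max(a_i, b_i) == 0) 0 else (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}

oracle_dunn <- function(pts, lab) {
  d <- function(i, j) sqrt(sum((pts[i, ] - pts[j, ])^2))
  cl <- unique(lab)
  diam <- 0
  for (c1 in cl) {
    idx <- which(lab == c1)
    if (length(idx) > 1)
      for (i in idx) for (j in idx) if (i < j) diam <- max(diam, d(i, j))
  }
  sep <- Inf
  for (i in seq_along(lab)) for (j in seq_along(lab))
    if (lab[i] != lab[j]) sep <- min(sep, d(i, j))
  sep / diam
}

# naive HSIC: explicit Gram, centering, double-loop trace
oracle_hsic <- function(O1, O2) {
  m <- ncol(O1)
  H <- diag(m) - matrix(1 / m, m, m)
  A <- t(O1) %*% O1 %*% H
  B <- t(O2) %*% O2 %*% H
  tr <- 0
  M <- A %*% B
  for (i in seq_len(m)) tr <- tr + M[i, i]
  tr / (m - 1)^2
}
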