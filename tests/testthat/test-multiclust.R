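# Stage-2 operations: HSIC algebra, DEC-style assignment/target math,
# attention-head projections, and a miniature end-to-end run.

rand_state <- function(d, cfg, seed = 1) {
  set.seed(seed)
  structure(list(params = scMultiClust:::init_stage2_params(d, cfg), cfg = cfg),
            class = "multiclust_state")
}

test_that("multi-head projection: singleton, symmetry, hand evaluation", {
  cfg <- multiclust_config(L = 2, m = 3, cluster_counts = c(2, 2), epochs = 2,
                           warmup_epochs = 1, center_stagger = 0)
  st <- rand_state(4, cfg)
  # one cell: attention weight is 1, so O = V + V (skip connection)
  Z1 <- matrix(rnorm(4), 1, 4)
  hs1 <- multihead_project(Z1, cfg, st)
  expect_equal(hs1$heads[[1]], 2 * (Z1 %*% st$params$wv1), tolerance = 1e-12)
  # all-equal rows stay all-equal
  Zeq <- matrix(1, 5, 4)
  hseq <- multihead_project(Zeq, cfg, st)
  expect_equal(hseq$heads[[2]], matrix(hseq$heads[[2]][1, ], 5, 3, byrow = TRUE),
               tolerance = 1e-12)
  # hand-evaluated head: Q = K = V = ZI (identity-like projections),
  # O = softmax(ZI ZI^T / m) ZI + ZI with the skip connection
  cfg1 <- multiclust_config(L = 1, m = 2, cluster_counts = 2, epochs = 2,
                            warmup_epochs = 1)  # L = 1: stagger is irrelevant
  st1 <- rand_state(2, cfg1)
  st1$params$wq1 <- st1$params$wk1 <- st1$params$wv1 <- diag(2)
  ZI <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE)
  O <- multihead_project(ZI, cfg1, st1)$heads[[1]]
  A <- scMultiClust:::row_softmax(ZI %*% t(ZI) / 2)
  expect_equal(O, A %*% ZI + ZI, tolerance = 1e-12)
  # and the printed attention form without the skip
  cfg0 <- multiclust_config(L = 1, m = 2, cluster_counts = 2, epochs = 2,
                            warmup_epochs = 1, head_skip = FALSE)
  O0 <- multihead_project(ZI, cfg0, st1)$heads[[1]]
  expect_equal(O0, A %*% ZI, tolerance = 1e-12)
})

test_that("reconstruction loss: zero, unit-offset and elementwise identities", {
  cfg <- multiclust_config(L = 1, m = 2, cluster_counts = 2, epochs = 2,
                           warmup_epochs = 1)
  ZI <- matrix(rnorm(12), 6, 2)
  expect_equal(reconstruction_loss(ZI, list(Zbar_I = ZI)), 0)
  expect_equal(reconstruction_loss(ZI, list(Zbar_I = ZI + 1)), 1)
  off <- matrix(rnorm(12), 6, 2)
  expect_equal(reconstruction_loss(ZI, list(Zbar_I = ZI + off)), mean(off^2),
               tolerance = 1e-12)
})

test_that("HSIC: constant head, self-similarity, brute-force agreement", {
  expect_equal(hsic(matrix(3, 5, 4), matrix(rnorm(20), 5, 4)), 0,
               tolerance = 1e-9)
  set.seed(41)
  O <- matrix(rnorm(15), 5, 3)
  expect_gte(hsic(O, O), 0)
  O1 <- matrix(sample(-3:3, 12, replace = TRUE), 4, 3)
  O2 <- matrix(sample(-3:3, 12, replace = TRUE), 4, 3)
  expect_equal(hsic(O1, O2), oracle_hsic(O1, O2), tolerance = 1e-10)
  expect_error(hsic(matrix(1, 3, 1), matrix(1, 3, 1)), "argument error")
})

test_that("redundancy loss matches the per-head trace identity", {
  expect_equal(redundancy_loss(list(heads = list(matrix(rnorm(12), 4, 3)))), 0)
  set.seed(42)
  O <- matrix(rnorm(20), 5, 4)
  expect_equal(redundancy_loss(list(heads = list(O, O))), 2 * hsic(O, O),
               tolerance = 1e-10)
  heads <- lapply(1:3, function(i) matrix(rnorm(24), 6, 4))
  m <- 4
  H <- diag(m) - matrix(1 / m, m, m)
  U <- lapply(heads, crossprod)
  trace_form <- 0
  for (l in 1:3) {
    Ut <- Reduce(`+`, lapply(setdiff(1:3, l), function(l2) H %*% U[[l2]] %*% H)) /
      (m - 1)^2
    trace_form <- trace_form + sum(diag(heads[[l]] %*% Ut %*% t(heads[[l]])))
  }
  expect_equal(redundancy_loss(list(heads = heads)), trace_form,
               tolerance = 1e-8 * abs(trace_form))
})

test_that("soft assignment: symmetry, monotonicity, 1-D closed form", {
  centers <- rbind(c(1, 0), c(-1, 0))
  equid <- soft_assign(matrix(c(0, 5), 1, 2), centers)
  expect_equal(as.vector(equid), c(0.5, 0.5))
  at_c1 <- soft_assign(rbind(c(1, 0)), centers)
  expect_gt(at_c1[1, 1], at_c1[1, 2])
  one_d <- soft_assign(matrix(0, 1, 1), matrix(c(0, 1), 2, 1))
  expect_equal(as.vector(one_d), c(2 / 3, 1 / 3), tolerance = 1e-12)
  set.seed(43)
  P <- soft_assign(matrix(rnorm(30), 10, 3), matrix(rnorm(12), 4, 3))
  expect_equal(rowSums(P), rep(1, 10), tolerance = 1e-12)
})

test_that("target distribution: fixed points, symmetry, hand example", {
  P_hot <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(target_distribution(P_hot), P_hot, ignore_attr = TRUE)
  P_unif <- matrix(1 / 2, 4, 2)
  expect_equal(target_distribution(P_unif), P_unif, ignore_attr = TRUE)
  P <- rbind(c(0.8, 0.2), c(0.4, 0.6))
  R <- target_distribution(P)
  # f = (1.2, 0.8); row 1 ~ (0.9143, 0.0857), row 2 ~ (0.2286, 0.7714)
  expect_equal(R[1, ], c(16 / 17.5, 1.5 / 17.5), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(R[2, ], c(4 / 17.5, 13.5 / 17.5), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(rowSums(R), c(1, 1), ignore_attr = TRUE)
  expect_warning(target_distribution(cbind(c(1, 1), c(0, 0))), "empty cluster")
})

test_that("target distribution preserves the row argmax at equal frequencies", {
  # balanced design: rows are cyclic shifts of one probability vector,
  # so cluster frequencies f_j are exactly equal
  base <- c(0.5, 0.3, 0.15, 0.05)
  Pbal <- t(vapply(0:7, function(k) base[(seq(0, 3) + k) %% 4 + 1], numeric(4)))
  stopifnot(max(abs(colSums(Pbal) - 2)) < 1e-12)
  R <- target_distribution(Pbal)
  expect_equal(max.col(R), max.col(Pbal))
  expect_true(all(apply(R, 1, max) >= apply(Pbal, 1, max) - 1e-12))
})

test_that("clustering loss: KL identities and brute-force agreement", {
  P <- rbind(c(0.7, 0.3), c(0.2, 0.8))
  expect_equal(clustering_loss(P, P), 0)
  expect_equal(clustering_loss(matrix(c(1, 0), 1, 2), matrix(0.5, 1, 2)), log(2),
               tolerance = 1e-12)
  set.seed(45)
  P <- scMultiClust:::row_softmax(matrix(rnorm(24), 8, 3))
  R <- target_distribution(P)
  brute <- 0
  for (i in 1:8) for (j in 1:3) brute <- brute + P[i, j] * log(P[i, j] / R[i, j])
  expect_equal(clustering_loss(P, R), brute, tolerance = 1e-12)
  expect_gte(clustering_loss(P, R), 0)
  # list form sums over heads
  expect_equal(clustering_loss(list(P, P), list(R, R)), 2 * brute,
               tolerance = 1e-12)
})

test_that("stage-2 on separable data: loss decreases, labels recover structure, determinism", {
  set.seed(46)
  centers <- rbind(c(4, 0, 0, 0), c(0, 4, 0, 0), c(0, 0, 4, 0))
  truth <- rep(1:3, each = 20)
  ZI <- centers[truth, ] + matrix(rnorm(240, 0, 0.3), 60, 4)
  cfg <- multiclust_config(L = 1, m = 4, cluster_counts = 3, epochs = 80,
                           warmup_epochs = 30, seed = 2)
  st <- train_stage2(ZI, cfg)
  h <- st$loss_history
  expect_true(all(is.finite(h$total)))
  expect_lt(h$rec[length(h$rec)], h$rec[1])
  expect_gt(ari(st$clusters$labels[[1]], truth), 0.9)
  # redundancy column is absent for L = 1
  expect_true(all(is.na(h$red)))
  st_b <- train_stage2(ZI, cfg)
  expect_identical(st$clusters$labels, st_b$clusters$labels)
  # cluster-state invariants
  expect_equal(rowSums(st$clusters$soft[[1]]), rep(1, 60), tolerance = 1e-12)
  expect_equal(rowSums(st$clusters$target[[1]]), rep(1, 60), tolerance = 1e-12)
  expect_identical(st$clusters$labels[[1]],
                   max.col(st$clusters$target[[1]], ties.method = "first"))
})
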