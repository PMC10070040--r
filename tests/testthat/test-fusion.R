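# Stage-1 operations with closed-form or hand-evaluated expectations.
# Training-dependent behaviour is exercised on a miniature dataset here;
# the full fixture lives in test-acceptance.R.

mini_sim <- function(seed = 1) {
  simulate_pair(sim_config(n_cells = 40, n_genes = 25, n_peaks = 30,
                           n_types = 2, n_states = 2, seed = seed))
}

mini_cfg <- function(...) {
  args <- utils::modifyList(list(d = 8, hidden = c(32, 16), epochs = 15,
                                 learning_rate = 3e-3), list(...))
  do.call(fusion_config, args)
}

test_that("self-attention: uniform rows, singleton, and hand-evaluated case", {
  Z <- matrix(1, 4, 3)                 # all-equal rows
  att <- self_attention(Z)
  expect_equal(att$A, matrix(0.25, 4, 4), ignore_attr = TRUE)
  expect_equal(att$Zg, Z, ignore_attr = TRUE)
  one <- self_attention(matrix(c(2, -1), 1, 2))
  expect_equal(one$A, matrix(1, 1, 1))
  expect_equal(one$Zg, matrix(c(2, -1), 1, 2))
  # Z = I_2, d = 2: scores row 1 = (0.5, 0)
  att2 <- self_attention(diag(2), d = 2)
  w <- exp(c(0.5, 0)) / sum(exp(c(0.5, 0)))
  expect_equal(att2$A[1, ], w, ignore_attr = TRUE)
  expect_equal(att2$Zg[1, ], w, ignore_attr = TRUE)   # A %*% I rows = weights
  expect_equal(rowSums(att2$A), c(1, 1), ignore_attr = TRUE)
})

test_that("contrastive loss: aligned one-hot views, uniform case, zero case", {
  d <- 4; n <- 40
  set.seed(31)
  # strongly one-hot rows, identical across views, spread over coordinates
  hot <- 50 * diag(d)[sample(rep(1:d, each = n / d)), ]
  aligned <- contrastive_loss(hot, hot, epsilon_cl = 1)
  # maximal dependence: I ~ H ~ log d, so loss ~ -(log d + 2 log d)
  expect_lt(aligned, -(3 * log(d)) + 0.05)
  # constant rows -> uniform softmax -> uniform joint: I = 0, H = log d
  const <- matrix(1, 10, d)
  expect_equal(contrastive_loss(const, const, epsilon_cl = 1), -2 * log(d),
               tolerance = 1e-12)
  expect_equal(contrastive_loss(const, const, epsilon_cl = 0), 0,
               tolerance = 1e-12)
})

test_that("ZINB NLL: degenerate mixtures, clipping, NB(0) closed form", {
  g <- function(pi, mu, th) list(Pi = matrix(pi, 1, 1), MeanX = matrix(mu, 1, 1),
                                 Theta = matrix(th, 1, 1))
  expect_equal(zinb_nll(matrix(0L, 1, 1), g(1 - 1e-12, 1, 1)), 0, tolerance = 1e-9)
  # impossible observation under pi = 1: clipped to -log(1e-10)
  expect_equal(zinb_nll(matrix(3L, 1, 1), g(1, 1, 1)), -log(1e-10))
  # x = 0, pi = 0.5, mu = theta = 1: pmf = 0.5 + 0.5 * 0.5 = 0.75
  expect_equal(zinb_nll(matrix(0L, 1, 1), g(0.5, 1, 1)), -log(0.75),
               tolerance = 1e-12)
  expect_error(zinb_nll(matrix(1.5, 1, 1), g(0.5, 1, 1)), "format error")
  # pi = 0 degenerates to the NB negative log-likelihood
  set.seed(32)
  x <- matrix(rpois(12, 3), 3, 4)
  mu <- matrix(runif(12, 0.5, 4), 3, 4)
  th <- matrix(runif(12, 0.5, 4), 3, 4)
  expect_equal(zinb_nll(x, list(Pi = mu * 0, MeanX = mu, Theta = th)),
               mean(-dnbinom(x, size = th, mu = mu, log = TRUE)),
               tolerance = 1e-9)
})

test_that("Bernoulli cross-entropy closed forms", {
  expect_lt(bernoulli_ce(matrix(1, 1, 1), matrix(1, 1, 1)), 1e-5)
  expect_equal(bernoulli_ce(matrix(1, 1, 1), matrix(0.5, 1, 1)), log(2))
  expect_equal(bernoulli_ce(matrix(c(1, 0), 1, 2), matrix(c(0.8, 0.2), 1, 2)),
               -(log(0.8) + log(0.8)) / 2, tolerance = 1e-12)
})

test_that("encoders: shapes, equal-input consistency, determinism, shape errors", {
  sim <- mini_sim()
  pair <- sim$omics
  cfg <- mini_cfg(seed = 3)
  st <- train_stage1(pair, cfg)
  enc <- encode(pair, st)
  expect_equal(dim(enc$ZX), c(40, 8))
  expect_equal(dim(enc$ZY), c(40, 8))
  # identical input rows give identical latent rows
  rna2 <- pair$rna_counts; rna2[2, ] <- rna2[1, ]
  atac2 <- pair$atac_bin; atac2[2, ] <- atac2[1, ]
  pair2 <- omics_pair(rna2, atac2)
  enc2 <- encode(pair2, st)
  expect_equal(enc2$ZX[1, ], enc2$ZX[2, ])
  expect_equal(enc2$ZY[1, ], enc2$ZY[2, ])
  expect_identical(encode(pair, st), encode(pair, st))
  bad <- omics_pair(pair$rna_counts[, 1:10], pair$atac_bin)
  expect_error(encode(bad, st), "shape error")
})

test_that("training is seed-deterministic and the fused identity holds exactly", {
  sim <- mini_sim()
  a <- train_stage1(sim$omics, mini_cfg(seed = 7))
  b <- train_stage1(sim$omics, mini_cfg(seed = 7))
  expect_identical(a$loss_history, b$loss_history)
  expect_identical(a$latents$ZI, b$latents$ZI)
  L <- a$latents
  expect_equal(L$ZI, L$ZXY + 0.1 * L$ZgX + 0.1 * L$ZgY, tolerance = 1e-12)
  # attention rows are probability vectors
  expect_equal(rowSums(L$AX), rep(1, 40), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(L$AX >= 0 & L$AX <= 1))
  # fuse_embeddings reproduces the trained forward pass
  fz <- fuse_embeddings(L$QX, L$QY, L$ZgX, L$ZgY, a$cfg, a)
  expect_equal(fz$ZXY, L$ZXY, tolerance = 1e-12)
  expect_equal(fz$ZI, L$ZI, tolerance = 1e-12)
  expect_error(fuse_embeddings(L$QX[1:3, ], L$QY, L$ZgX, L$ZgY, a$cfg, a),
               "shape error")
})

test_that("lambda weights act as stated in the fused sum", {
  sim <- mini_sim()
  st0 <- train_stage1(sim$omics, mini_cfg(seed = 5, lambda_x = 0, lambda_y = 0,
                                          epochs = 5))
  expect_equal(st0$latents$ZI, st0$latents$ZXY, tolerance = 1e-12)
  fz <- fuse_embeddings(st0$latents$QX, st0$latents$QY,
                        st0$latents$ZgX, st0$latents$ZgY,
                        fusion_config(d = 8, lambda_x = 1, lambda_y = 0), st0)
  expect_equal(fz$ZI - fz$ZXY, st0$latents$ZgX, tolerance = 1e-12)
})

test_that("discriminator loss: perfect and uniform predictors, near-chance at init", {
  sim <- mini_sim()
  st <- train_stage1(sim$omics, mini_cfg(seed = 11, epochs = 1))
  lab <- make_omics_labels(50)
  # hand-built logits: exact one-hot prediction gives ~0; uniform gives log 2
  S_perfect <- pmin(pmax(lab, 1e-12), 1)
  expect_equal(-sum(lab * log(S_perfect)) / nrow(lab), 0, tolerance = 1e-9)
  S_unif <- matrix(0.5, nrow(lab), 2)
  expect_equal(-sum(lab * log(S_unif)) / nrow(lab), log(2), tolerance = 1e-12)
  # untrained discriminator on N(0,1) embeddings is near chance
  set.seed(33)
  ZgX <- matrix(rnorm(50 * 8), 50, 8)
  ZgY <- matrix(rnorm(50 * 8), 50, 8)
  expect_lt(abs(discriminator_loss(ZgX, ZgY, lab, st) - log(2)), 0.2)
})

test_that("ablation switches zero terms and bypass sub-networks", {
  sim <- mini_sim()
  # alpha weights zero: total equals the ZINB history
  st <- train_stage1(sim$omics, mini_cfg(seed = 2, alpha1 = 0, alpha2 = 0,
                                         alpha3 = 0, epochs = 8))
  expect_equal(st$loss_history$total, st$loss_history$zinb, tolerance = 1e-12)
  # attention off: Zg = Z exactly, no attention matrices
  st_noatt <- train_stage1(sim$omics, mini_cfg(seed = 2, use_attention = FALSE,
                                               epochs = 5))
  expect_identical(st_noatt$latents$ZgX, st_noatt$latents$ZX)
  expect_null(st_noatt$latents$AX)
  # generative path off: no ZINB/Bernoulli components in the history
  st_nozb <- train_stage1(sim$omics, mini_cfg(seed = 2, use_generative = FALSE,
                                              epochs = 5))
  expect_true(all(is.na(st_nozb$loss_history$zinb)))
  expect_true(all(is.na(st_nozb$loss_history$ber)))
  expect_true(all(is.finite(st_nozb$loss_history$total)))
})

test_that("impute returns decoder means with the right shapes and ranges", {
  sim <- mini_sim()
  st <- train_stage1(sim$omics, mini_cfg(seed = 4, epochs = 10))
  imp <- impute(st)
  expect_equal(dim(imp$imputed_rna), dim(sim$omics$rna_counts))
  expect_equal(dim(imp$imputed_atac), dim(sim$omics$atac_bin))
  expect_true(all(imp$imputed_atac > 0 & imp$imputed_atac < 1))
  expect_true(all(imp$imputed_rna > 0))
  expect_error(impute(structure(list(trained = FALSE), class = "fusion_state")),
               "state error")
  expect_error(impute(list()), "state error")
})

test_that("loss history is finite and the smoothed total is non-increasing", {
  sim <- mini_sim()
  st <- train_stage1(sim$omics, mini_cfg(seed = 6, epochs = 40))
  h <- st$loss_history
  expect_true(all(is.finite(h$total)))
  sm <- stats::filter(h$total, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= abs(sm[-length(sm)]) * 0.02 + 1e-6))
})
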