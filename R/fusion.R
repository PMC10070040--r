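#' Stage-1 configuration: fusion network and losses
#'
#' Hyperparameters of the fusion stage: omics-specific encoders with
#' self-attention individuality extraction, an omics-label
#' discriminator, a contrastive commonality path, co-embedding fusion
#' `ZI = ZXY + lambda_x * ZgX + lambda_y * ZgY`, and ZINB (RNA) /
#' Bernoulli (ATAC) generative decoders trained jointly as
#' `L1 = L_ZINB + alpha1 * L_Ber + alpha2 * L_dis + alpha3 * L_cl`.
#'
#' @param d latent dimension of all stage-1 embeddings (>= 2).
#' @param lambda_x,lambda_y scale parameters weighting the RNA / ATAC
#'   individuality embeddings in the co-embedding sum.
#' @param alpha1,alpha2,alpha3 non-negative weights of the Bernoulli,
#'   discriminator and contrastive loss terms.
#' @param epsilon_cl entropy weight inside the contrastive loss.
#' @param hidden encoder hidden widths (decoders mirror them).
#' @param epochs,learning_rate full-batch Adam schedule.
#' @param weight_decay decoupled L2 weight decay applied by the
#'   optimizer; counteracts the outward pressure of the contrastive
#'   term on latent norms.
#' @param seed RNG seed covering initialization (training itself is
#'   deterministic).
#' @param use_attention,use_discriminator,use_contrastive,use_generative
#'   ablation switches; disabling attention sets `Zg = Z`, the others
#'   drop the corresponding loss term.
#' @param learn_lambda if `TRUE`, `lambda_x`/`lambda_y` become trainable
#'   parameters initialized at the given values.
#' @param norm_latent standardize the columns of the encoder outputs
#'   (full-batch normalization without learnable affine) before the
#'   attention and contrastive paths; off by default (it constrains the
#'   latent geometry noticeably and reduced recovery in practice).
#' @param pretrain_epochs initial epochs trained with the generative
#'   (ZINB + Bernoulli) losses only, before the discriminator and
#'   contrastive terms switch on; autoencoder pretraining before
#'   auxiliary objectives stabilizes the latent structure. Counted as
#'   part of `epochs`. Ignored when `use_generative = FALSE`.
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(d = 32, lambda_x = 0.1, lambda_y = 0.1,
                          alpha1 = 1, alpha2 = 1, alpha3 = 1,
                          epsilon_cl = 1, hidden = c(256, 64),
                          epochs = 500, learning_rate = 1e-3,
                          weight_decay = 1e-3, seed = 1,
                          use_attention = TRUE, use_discriminator = TRUE,
                          use_contrastive = TRUE, use_generative = TRUE,
                          learn_lambda = FALSE, norm_latent = FALSE,
                          pretrain_epochs = 100) {
  cfg <- as.list(environment())
  stopifnot(cfg$d >= 2, cfg$alpha1 >= 0, cfg$alpha2 >= 0, cfg$alpha3 >= 0,
            cfg$epsilon_cl >= 0, cfg$epochs >= 1, cfg$learning_rate > 0,
            all(is.finite(c(cfg$lambda_x, cfg$lambda_y))))
  class(cfg) <- "fusion_config"
  cfg
}

# value clipping conventions shared by decoders and likelihoods
.EXP_LO <- log(1e-5)
.EXP_HI <- log(1e6)
.P_EPS <- 1e-6
.PMF_EPS <- 1e-10

# ---- pure numeric operations -----------------------------------------

#' Self-attention individuality reorganization
#'
#' Cell-by-cell attention over a latent matrix: `A = softmax(Z Z^T / d)`
#' row-wise, `Zg = A Z`. Each attention row is a probability vector over
#' cells, so `Zg` reorganizes each cell's embedding as a similarity-
#' weighted average over all cells.
#'
#' @param Z numeric matrix, cells x d.
#' @param d scaling divisor; defaults to `ncol(Z)`.
#' @return List with `A` (N x N, row-stochastic) and `Zg` (N x d).
#' @export
self_attention <- function(Z, d = ncol(Z)) {
  Z <- as.matrix(Z)
  A <- row_softmax(Z %*% t(Z) / d)
  list(A = A, Zg = A %*% Z)
}

#' Contrastive commonality loss
#'
#' Mutual-information--based contrastive loss between the two
#' semantically aligned views: rows of `QX` and `QY` are softmax-
#' normalized into d-way distributions, their average outer product
#' forms a d x d joint `J` (symmetrized and renormalized), and the loss
#' is `-(I(J) + epsilon * (H_X + H_Y))` with `I` the mutual information
#' of `J` and `H` the marginal entropies. Minimizing it maximizes
#' cross-omics consistency while the entropy terms avoid the collapse
#' of all cells onto one coordinate.
#'
#' @param QX,QY numeric matrices, cells x d, from the shared MLP.
#' @param epsilon_cl entropy weight.
#' @return Scalar loss value.
#' @export
contrastive_loss <- function(QX, QY, epsilon_cl = 1) {
  stopifnot(all(dim(QX) == dim(QY)))
  N <- nrow(QX)
  J <- crossprod(row_softmax(as.matrix(QX)), row_softmax(as.matrix(QY))) / N
  J <- (J + t(J)) / 2
  J <- J / sum(J)
  r <- rowSums(J)
  cc <- colSums(J)
  pos <- J > 0
  I <- sum(J[pos] * log(J[pos] / outer(r, cc)[pos]))
  H <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  -(I + epsilon_cl * (H(r) + H(cc)))
}

# log NB pmf with full normalization (mean/dispersion parameterization)
log_nb_pmf <- function(x, mu, theta) {
  lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    theta * (log(theta) - log(theta + mu)) + x * (log(mu) - log(theta + mu))
}

#' Zero-inflated negative binomial negative log-likelihood
#'
#' Mean over all matrix entries of `-log(pi * 1[x=0] + (1 - pi) *
#' NB(x; mu, theta))`, with the fully normalized NB pmf
#' `Gamma(x + theta) / (Gamma(theta) x!) (theta/(theta+mu))^theta
#' (mu/(theta+mu))^x` so the distribution sums to one. Mixture
#' probabilities are clipped below at `1e-10` before the log, so
#' impossible observations give a large finite penalty.
#'
#' @param x_counts non-negative integer matrix (raw RNA counts).
#' @param gen list with matrices `Pi` (dropout probability in (0,1)),
#'   `MeanX` (NB mean > 0) and `Theta` (dispersion > 0), each shaped
#'   like `x_counts`.
#' @return Scalar mean NLL.
#' @export
zinb_nll <- function(x_counts, gen) {
  x <- as.matrix(x_counts)
  check_counts(x)
  pi <- as.matrix(gen$Pi); mu <- as.matrix(gen$MeanX); th <- as.matrix(gen$Theta)
  nb <- exp(log_nb_pmf(x, mu, th))
  mix <- pi * (x == 0) + (1 - pi) * nb
  mean(-log(pmax(mix, .PMF_EPS)))
}

#' ZINB probability mass function
#'
#' @param x non-negative integer vector.
#' @param pi,mu,theta scalar ZINB parameters.
#' @return `P(X = x)` under ZINB(pi, mu, theta).
#' @export
zinb_pmf <- function(x, pi, mu, theta) {
  pi * (x == 0) + (1 - pi) * exp(log_nb_pmf(x, mu, theta))
}

#' Bernoulli cross-entropy for the accessibility decoder
#'
#' Mean over entries of `-(y log mu_y + (1 - y) log(1 - mu_y))` with
#' `mu_y` clipped to `(1e-6, 1 - 1e-6)`.
#'
#' @param y_bin binary matrix.
#' @param MeanY decoded accessibility probabilities, same shape.
#' @return Scalar mean cross-entropy.
#' @export
bernoulli_ce <- function(y_bin, MeanY) {
  y <- as.matrix(y_bin)
  stopifnot(all(y %in% c(0, 1)))
  mu <- pmin(pmax(as.matrix(MeanY), .P_EPS), 1 - .P_EPS)
  mean(-(y * log(mu) + (1 - y) * log(1 - mu)))
}

# ---- parameter initialization ----------------------------------------

init_stage1_params <- function(DX, DY, d, hidden, learn_lambda, lambda_x, lambda_y) {
  h1 <- hidden[1]; h2 <- hidden[2]
  p <- list()
  p <- add_dense(p, "encX1", DX, h1); p <- add_dense(p, "encX2", h1, h2)
  p <- add_dense(p, "encX3", h2, d)
  p <- add_dense(p, "encY1", DY, h1); p <- add_dense(p, "encY2", h1, h2)
  p <- add_dense(p, "encY3", h2, d)
  p <- add_dense(p, "mlp1", d, h2); p <- add_dense(p, "mlp2", h2, d)
  p <- add_dense(p, "fxy1", 2 * d, h2); p <- add_dense(p, "fxy2", h2, d)
  p <- add_dense(p, "dis1", d, 32); p <- add_dense(p, "dis2", 32, 2)
  p <- add_dense(p, "decX1", d, h2); p <- add_dense(p, "decX2", h2, h1)
  p <- add_dense(p, "headPi", h1, DX); p <- add_dense(p, "headMu", h1, DX)
  p <- add_dense(p, "headTheta", h1, DX)
  p <- add_dense(p, "decY1", d, h2); p <- add_dense(p, "decY2", h2, h1)
  p <- add_dense(p, "headMuY", h1, DY)
  if (learn_lambda) {
    p[["lambda_x"]] <- matrix(lambda_x, 1, 1)
    p[["lambda_y"]] <- matrix(lambda_y, 1, 1)
  }
  p
}

# ---- autodiff forward pass -------------------------------------------

ad_self_attention <- function(Z, d) {
  A <- ad_rowsoftmax(ad_scale(ad_matmul(Z, ad_t(Z)), 1 / d))
  list(A = A, Zg = ad_matmul(A, Z))
}

ad_contrastive <- function(QX, QY, epsilon_cl) {
  N <- nrow(QX$value)
  SX <- ad_rowsoftmax(QX); SY <- ad_rowsoftmax(QY)
  J <- ad_scale(ad_matmul(ad_t(SX), SY), 1 / N)
  J <- ad_scale(ad_add(J, ad_t(J)), 0.5)
  J <- ad_normalize_sum(J)
  r <- ad_rowsums(J); cc <- ad_colsums(J)
  Jc <- ad_clip(J, 1e-12, Inf)
  rc <- ad_clip(ad_matmul(r, cc), 1e-12, Inf)
  I <- ad_sum(ad_mul(J, ad_sub(ad_log(Jc), ad_log(rc))))
  ent <- function(p) ad_neg(ad_sum(ad_mul(p, ad_log(ad_clip(p, 1e-12, Inf)))))
  ad_neg(ad_add(I, ad_scale(ad_add(ent(r), ent(cc)), epsilon_cl)))
}

ad_zinb_nll <- function(Xc, Z0c, Pi, Mu, Th) {
  lognb <- ad_add(
    ad_sub(ad_lgamma(ad_add(Xc, Th)),
           ad_add(ad_lgamma(Th), ad_const(lgamma(Xc$value + 1)))),
    ad_add(ad_mul(Th, ad_sub(ad_log(Th), ad_log(ad_add(Th, Mu)))),
           ad_mul(Xc, ad_sub(ad_log(Mu), ad_log(ad_add(Th, Mu))))))
  mix <- ad_add(ad_mul(Pi, Z0c),
                ad_mul(ad_shift(ad_neg(Pi), 1), ad_exp(lognb)))
  ad_neg(ad_mean(ad_log(ad_clip(mix, .PMF_EPS, Inf))))
}

ad_bernoulli_ce <- function(Yc, MuY) {
  mu <- ad_clip(MuY, .P_EPS, 1 - .P_EPS)
  ad_neg(ad_mean(ad_add(ad_mul(Yc, ad_log(mu)),
                        ad_mul(ad_shift(ad_neg(Yc), 1),
                               ad_log(ad_shift(ad_neg(mu), 1))))))
}

# Full stage-1 forward; returns ad nodes for latents, generative heads
# and loss components. `data` carries const nodes for X (norm + raw),
# Y and the omics-label matrix.
forward_stage1 <- function(nodes, data, cfg) {
  d <- cfg$d
  ZX <- ad_mlp(data$Xn, nodes, c("encX1", "encX2", "encX3"))
  ZY <- ad_mlp(data$Y, nodes, c("encY1", "encY2", "encY3"))
  if (isTRUE(cfg$norm_latent)) {
    ZX <- ad_colstd(ZX)
    ZY <- ad_colstd(ZY)
  }
  if (cfg$use_attention) {
    attX <- ad_self_attention(ZX, d); attY <- ad_self_attention(ZY, d)
    AX <- attX$A; ZgX <- attX$Zg; AY <- attY$A; ZgY <- attY$Zg
  } else {
    AX <- AY <- NULL; ZgX <- ZX; ZgY <- ZY
  }
  QX <- ad_mlp(ZX, nodes, c("mlp1", "mlp2"))
  QY <- ad_mlp(ZY, nodes, c("mlp1", "mlp2"))
  ZXY <- ad_mlp(ad_cbind(QX, QY), nodes, c("fxy1", "fxy2"))
  if (cfg$learn_lambda) {
    ZI <- ad_add(ZXY, ad_add(ad_smul(ZgX, nodes$lambda_x),
                             ad_smul(ZgY, nodes$lambda_y)))
  } else {
    ZI <- ad_add(ZXY, ad_add(ad_scale(ZgX, cfg$lambda_x),
                             ad_scale(ZgY, cfg$lambda_y)))
  }

  HX <- ad_relu(ad_dense(ad_relu(ad_dense(ZI, nodes, "decX1")), nodes, "decX2"))
  Pi <- ad_clip(ad_sigmoid(ad_dense(HX, nodes, "headPi")), .P_EPS, 1 - .P_EPS)
  Mu <- ad_exp(ad_clip(ad_dense(HX, nodes, "headMu"), .EXP_LO, .EXP_HI))
  Th <- ad_exp(ad_clip(ad_dense(HX, nodes, "headTheta"), .EXP_LO, .EXP_HI))
  HY <- ad_relu(ad_dense(ad_relu(ad_dense(ZI, nodes, "decY1")), nodes, "decY2"))
  MuY <- ad_sigmoid(ad_dense(HY, nodes, "headMuY"))

  loss <- NULL
  comp <- list(zinb = NA_real_, ber = NA_real_, dis = NA_real_, cl = NA_real_)
  wadd <- function(acc, term, w) {
    if (w == 0) return(acc)
    term <- ad_scale(term, w)
    if (is.null(acc)) term else ad_add(acc, term)
  }
  if (cfg$use_generative) {
    lz <- ad_zinb_nll(data$Xraw, data$Z0, Pi, Mu, Th)
    lb <- ad_bernoulli_ce(data$Y, MuY)
    comp$zinb <- as.numeric(lz$value); comp$ber <- as.numeric(lb$value)
    loss <- wadd(loss, lz, 1)
    loss <- wadd(loss, lb, cfg$alpha1)
  }
  if (cfg$use_discriminator) {
    Zg_all <- ad_rbind(ZgX, ZgY)
    logits <- ad_dense(ad_relu(ad_dense(Zg_all, nodes, "dis1")), nodes, "dis2")
    S <- ad_clip(ad_rowsoftmax(logits), 1e-12, Inf)
    ld <- ad_scale(ad_neg(ad_sum(ad_mul(data$P, ad_log(S)))),
                   1 / nrow(data$P$value))
    comp$dis <- as.numeric(ld$value)
    loss <- wadd(loss, ld, cfg$alpha2)
  }
  if (cfg$use_contrastive) {
    lc <- ad_contrastive(QX, QY, cfg$epsilon_cl)
    comp$cl <- as.numeric(lc$value)
    loss <- wadd(loss, lc, cfg$alpha3)
  }
  if (is.null(loss)) loss <- ad_scale(ad_mean(ZI), 0) # no active term
  list(ZX = ZX, ZY = ZY, AX = AX, AY = AY, ZgX = ZgX, ZgY = ZgY,
       QX = QX, QY = QY, ZXY = ZXY, ZI = ZI,
       Pi = Pi, Mu = Mu, Th = Th, MuY = MuY,
       loss = loss, comp = comp)
}

stage1_data_nodes <- function(pair) {
  N <- nrow(pair$rna_counts)
  list(Xn = ad_const(pair$rna_norm), Xraw = ad_const(pair$rna_counts),
       Z0 = ad_const((pair$rna_counts == 0) * 1),
       Y = ad_const(pair$atac_bin),
       P = ad_const(make_omics_labels(N)))
}

# ---- training ---------------------------------------------------------

#' Train the stage-1 fusion network
#'
#' Jointly minimizes the ZINB reconstruction NLL of the raw RNA counts,
#' the Bernoulli cross-entropy of the binary ATAC matrix, the
#' (cooperative) omics-label discriminator cross-entropy, and the
#' contrastive commonality loss with full-batch Adam. Ablation switches
#' in the config drop terms / bypass the attention sub-network.
#'
#' @param pair an [omics_pair].
#' @param cfg a [fusion_config].
#' @param verbose print the loss every 50 epochs.
#' @return A `fusion_state` with `params`, final `latents` (`ZX`, `ZY`,
#'   `AX`, `AY`, `ZgX`, `ZgY`, `QX`, `QY`, `ZXY`, `ZI`), generative
#'   parameters `gen` (`Pi`, `MeanX`, `Theta`, `MeanY`) and a
#'   per-epoch `loss_history` data frame.
#' @export
train_stage1 <- function(pair, cfg = fusion_config(), verbose = FALSE) {
  stopifnot(inherits(pair, "omics_pair"), inherits(cfg, "fusion_config"))
  set.seed(cfg$seed)
  DX <- ncol(pair$rna_counts); DY <- ncol(pair$atac_bin)
  params <- init_stage1_params(DX, DY, cfg$d, cfg$hidden, cfg$learn_lambda,
                               cfg$lambda_x, cfg$lambda_y)
  opt <- adam_init(params)
  hist <- vector("list", cfg$epochs)
  pre <- if (cfg$use_generative) min(cfg$pretrain_epochs, cfg$epochs - 1L) else 0L
  for (ep in seq_len(cfg$epochs)) {
    ecfg <- cfg
    if (ep <= pre) {
      ecfg$use_discriminator <- FALSE
      ecfg$use_contrastive <- FALSE
    }
    ad_tape_reset()
    nodes <- ad_wrap(params)
    data <- stage1_data_nodes(pair)
    fw <- forward_stage1(nodes, data, ecfg)
    tot <- as.numeric(fw$loss$value)
    if (!is.finite(tot))
      stop(sprintf("training error: non-finite loss at epoch %d", ep))
    hist[[ep]] <- data.frame(epoch = ep, zinb = fw$comp$zinb, ber = fw$comp$ber,
                             dis = fw$comp$dis, cl = fw$comp$cl, total = tot)
    ad_backward(fw$loss)
    st <- adam_step(params, ad_grads(nodes), opt, cfg$learning_rate,
                    weight_decay = cfg$weight_decay)
    params <- st$params; opt <- st$opt
    if (verbose && (ep %% 50 == 0 || ep == 1))
      message(sprintf("epoch %d: L1 = %.4f", ep, tot))
  }
  # final inference pass with trained parameters
  ad_tape_reset()
  nodes <- ad_wrap(params)
  fw <- forward_stage1(nodes, stage1_data_nodes(pair), cfg)
  val <- function(x) if (is.null(x)) NULL else x$value
  structure(list(
    params = params, cfg = cfg,
    dims = list(N = nrow(pair$rna_counts), DX = DX, DY = DY, d = cfg$d),
    latents = list(ZX = val(fw$ZX), ZY = val(fw$ZY), AX = val(fw$AX),
                   AY = val(fw$AY), ZgX = val(fw$ZgX), ZgY = val(fw$ZgY),
                   QX = val(fw$QX), QY = val(fw$QY), ZXY = val(fw$ZXY),
                   ZI = val(fw$ZI)),
    gen = list(Pi = val(fw$Pi), MeanX = val(fw$Mu), Theta = val(fw$Th),
               MeanY = val(fw$MuY)),
    loss_history = do.call(rbind, hist),
    trained = TRUE), class = "fusion_state")
}

#' @export
print.fusion_state <- function(x, ...) {
  cat(sprintf("fusion_state: N=%d, d=%d, %d epochs, final L1 = %.4f\n",
              x$dims$N, x$dims$d, nrow(x$loss_history),
              utils::tail(x$loss_history$total, 1)))
  invisible(x)
}

#' Encode a paired dataset with trained (or freshly initialized) encoders
#'
#' @param pair an [omics_pair] with the feature dimensions the state was
#'   built for.
#' @param state a `fusion_state`.
#' @return List with matrices `ZX`, `ZY` (cells x d); deterministic.
#' @export
encode <- function(pair, state) {
  stopifnot(inherits(state, "fusion_state"))
  if (ncol(pair$rna_counts) != state$dims$DX ||
      ncol(pair$atac_bin) != state$dims$DY)
    stop("shape error: feature dimensions do not match the model state")
  ad_tape_reset()
  nodes <- ad_wrap(state$params)
  list(ZX = ad_mlp(ad_const(pair$rna_norm), nodes, c("encX1", "encX2", "encX3"))$value,
       ZY = ad_mlp(ad_const(pair$atac_bin), nodes, c("encY1", "encY2", "encY3"))$value)
}

#' Omics-label discriminator loss
#'
#' Mean cross-entropy of the two-layer discriminator's omics prediction
#' over the `2N` stacked individuality embeddings; minimized jointly
#' (cooperatively) so that `ZgX` and `ZgY` stay omics-distinguishable.
#'
#' @param ZgX,ZgY individuality embeddings (cells x d).
#' @param labels one-hot matrix from [make_omics_labels].
#' @param state a `fusion_state` holding the discriminator parameters.
#' @return Scalar loss.
#' @export
discriminator_loss <- function(ZgX, ZgY, labels, state) {
  ad_tape_reset()
  nodes <- ad_wrap(state$params)
  Zg_all <- ad_rbind(ad_const(as.matrix(ZgX)), ad_const(as.matrix(ZgY)))
  logits <- ad_dense(ad_relu(ad_dense(Zg_all, nodes, "dis1")), nodes, "dis2")
  S <- pmin(pmax(row_softmax(logits$value), 1e-12), 1)
  -sum(labels * log(S)) / nrow(labels)
}

#' Fuse commonality and individuality into the co-embedding
#'
#' `ZXY = f_XY(concat(QX, QY))` through the trained two-layer fusion
#' network, then `ZI = ZXY + lambda_x * ZgX + lambda_y * ZgY`.
#'
#' @param QX,QY commonality embeddings from the shared MLP.
#' @param ZgX,ZgY individuality embeddings.
#' @param cfg the `fusion_config` (for the lambda weights).
#' @param state a `fusion_state` (for the fusion-network parameters).
#' @return List with `ZXY` and `ZI`.
#' @export
fuse_embeddings <- function(QX, QY, ZgX, ZgY, cfg, state) {
  if (!all(dim(QX) == dim(QY)) || !all(dim(QX) == dim(ZgX)) ||
      !all(dim(QX) == dim(ZgY)))
    stop("shape error: embedding shapes differ")
  ad_tape_reset()
  nodes <- ad_wrap(state$params)
  ZXY <- ad_mlp(ad_cbind(ad_const(as.matrix(QX)), ad_const(as.matrix(QY))),
                nodes, c("fxy1", "fxy2"))$value
  lx <- if (cfg$learn_lambda) as.numeric(state$params$lambda_x) else cfg$lambda_x
  ly <- if (cfg$learn_lambda) as.numeric(state$params$lambda_y) else cfg$lambda_y
  list(ZXY = ZXY, ZI = ZXY + lx * as.matrix(ZgX) + ly * as.matrix(ZgY))
}

#' Impute RNA and ATAC matrices from the trained generative decoders
#'
#' The ZINB mean matrix imputes the RNA counts (dropout-free expected
#' expression) and the Bernoulli mean matrix imputes accessibility.
#'
#' @param state a trained `fusion_state`.
#' @return List with `imputed_rna` (N x D_X, positive) and
#'   `imputed_atac` (N x D_Y in (0,1)).
#' @export
impute <- function(state) {
  if (!inherits(state, "fusion_state") || !isTRUE(state$trained))
    stop("state error: impute() needs a trained fusion_state")
  list(imputed_rna = state$gen$MeanX, imputed_atac = state$gen$MeanY)
}
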