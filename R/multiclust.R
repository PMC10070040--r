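#' Stage-2 configuration: multiple clusterings from the co-embedding
#'
#' The co-embedding is projected into `L` salient subspaces by
#' multi-head attention; a reconstruction loss keeps the heads faithful
#' to the co-embedding, an HSIC penalty reduces redundancy between
#' heads, and a KL target-distribution loss sharpens the clustering in
#' each head: `L2 = L_rec + beta1 * L_red + beta2 * L_clu`. `L = 1`
#' drops the redundancy term exactly and gives the single-clustering
#' mode.
#'
#' @param L number of clusterings (>= 1).
#' @param m head dimension.
#' @param cluster_counts integer vector of length `L`; clusters per
#'   head, each >= 2.
#' @param beta1,beta2 non-negative diversity / quality weights.
#' @param epochs total training epochs, including `warmup_epochs`
#'   without the clustering term before centers are initialized.
#' @param warmup_epochs epochs of reconstruction-only training before
#'   the first center initialization.
#' @param center_stagger epochs between the center initializations of
#'   consecutive heads: head `l` gets its seeded k-means centers at
#'   epoch `warmup_epochs + (l-1)*center_stagger + 1` and its
#'   clustering loss from then on. Anchoring the first head before the
#'   later ones lets the redundancy penalty reshape the remaining heads
#'   around the structure already claimed, instead of freezing every
#'   head onto near-identical k-means partitions of the co-embedding.
#' @param center_init center initialization method (only `"kmeans"`:
#'   seeded 10-restart k-means on each head).
#' @param target_update_interval epochs between refreshes of the
#'   auxiliary target distribution after a head's centers are
#'   initialized. The default `Inf` computes each head's target once at
#'   its center initialization and keeps it fixed: frequent refreshes
#'   let the self-training loop drift away from the anchored partition,
#'   while a fixed target sharpens it in place.
#' @param learning_rate,seed Adam step size and RNG seed.
#' @param standardize standardize the columns of the input embedding to
#'   zero mean and unit variance before projecting; keeps head
#'   attention logits well-scaled whatever the scale of the stage-1
#'   co-embedding.
#' @param normalize_hsic if `TRUE` the training objective uses the
#'   normalized HSIC (each pair divided by the geometric mean of the
#'   self-HSIC terms, a CKA-style dependence in `[0, 1]`), so the
#'   redundancy term is scale-invariant and `beta1 = 1` weights it
#'   comparably to the other losses; [redundancy_loss] itself always
#'   reports the raw sum.
#' @param head_skip add a residual (skip) connection around the
#'   attention mixing in each head, `O_l = (A_l + I) V_l`; without it
#'   the row-stochastic attention average can erase within-neighborhood
#'   contrasts (fine-grained structure) from every head.
#' @param hsic_space Gram matrix used by the training-time redundancy
#'   penalty: `"sample"` (default) centers the N x N sample-similarity
#'   Gram `O O^T`, which measures whether two heads organize the cells
#'   the same way and is what drives clustering diversity; `"feature"`
#'   centers the m x m feature Gram `O^T O` (the form [hsic] reports).
#' @return A `multiclust_config` list.
#' @export
multiclust_config <- function(L = 2, m = 16, cluster_counts = c(4, 2),
                              beta1 = 1, beta2 = 1, epochs = 300,
                              warmup_epochs = 100, center_stagger = 100,
                              center_init = c("kmeans"),
                              target_update_interval = Inf,
                              learning_rate = 1e-3, seed = 1,
                              standardize = TRUE, normalize_hsic = TRUE,
                              head_skip = TRUE,
                              hsic_space = c("sample", "feature")) {
  center_init <- match.arg(center_init)
  hsic_space <- match.arg(hsic_space)
  cfg <- as.list(environment())
  stopifnot(cfg$L >= 1, length(cfg$cluster_counts) == cfg$L,
            all(cfg$cluster_counts >= 2), cfg$m >= 2,
            cfg$beta1 >= 0, cfg$beta2 >= 0, cfg$center_stagger >= 0,
            cfg$epochs > cfg$warmup_epochs + (cfg$L - 1) * cfg$center_stagger,
            cfg$target_update_interval >= 1)
  class(cfg) <- "multiclust_config"
  cfg
}

# ---- pure numeric operations -----------------------------------------

#' Project a co-embedding into the L attention-head subspaces
#'
#' For head `l`: `Q_l = ZI W^Q_l`, `K_l = ZI W^K_l`, `V_l = ZI W^V_l`,
#' `O_l = rowsoftmax(Q_l K_l^T / m) V_l`.
#'
#' @param ZI numeric matrix, cells x d.
#' @param cfg a [multiclust_config].
#' @param state a `multiclust_state` (holds the projection triplets).
#' @return List with `heads` (list of `L` N x m matrices),
#'   `projections` and the reconstruction `Zbar_I`.
#' @export
multihead_project <- function(ZI, cfg, state) {
  ZI <- as.matrix(ZI)
  heads <- lapply(seq_len(cfg$L), function(l) {
    Q <- ZI %*% state$params[[paste0("wq", l)]]
    K <- ZI %*% state$params[[paste0("wk", l)]]
    V <- ZI %*% state$params[[paste0("wv", l)]]
    O <- row_softmax(Q %*% t(K) / cfg$m) %*% V
    if (isTRUE(cfg$head_skip)) O + V else O
  })
  Zbar <- do.call(cbind, heads)
  ad_tape_reset()
  nodes <- ad_wrap(state$params)
  ZbarI <- ad_mlp(ad_const(Zbar), nodes, c("dec1", "dec2"))$value
  list(heads = heads,
       projections = lapply(seq_len(cfg$L), function(l)
         list(WQ = state$params[[paste0("wq", l)]],
              WK = state$params[[paste0("wk", l)]],
              WV = state$params[[paste0("wv", l)]])),
       Zbar_I = ZbarI)
}

#' Subspace reconstruction loss
#'
#' Mean squared difference between the co-embedding and its
#' reconstruction from the concatenated heads.
#'
#' @param ZI the co-embedding.
#' @param headset output of [multihead_project].
#' @return Scalar mean squared error.
#' @export
reconstruction_loss <- function(ZI, headset) {
  mean((as.matrix(ZI) - headset$Zbar_I)^2)
}

#' Feature-space HSIC between two heads
#'
#' `HSIC(O_l, O_l') = Tr(U_l H U_l' H) / (m - 1)^2` with feature Gram
#' matrices `U = O^T O` (m x m) and the centering matrix
#' `H = I_m - (1/m) 1 1^T`. Quantifies (and, as a penalty, reduces)
#' dependence between subspaces.
#'
#' @param Ol,Ol2 N x m head matrices sharing `m >= 2`.
#' @return Scalar HSIC value.
#' @export
hsic <- function(Ol, Ol2) {
  Ol <- as.matrix(Ol); Ol2 <- as.matrix(Ol2)
  m <- ncol(Ol)
  if (m < 2 || ncol(Ol2) != m)
    stop("argument error: heads must share a common dimension m >= 2")
  H <- diag(m) - matrix(1 / m, m, m)
  U1 <- crossprod(Ol); U2 <- crossprod(Ol2)
  sum(diag(U1 %*% H %*% U2 %*% H)) / (m - 1)^2
}

#' Redundancy loss over all head pairs
#'
#' Sum of [hsic] over ordered pairs `l != l'`; zero when `L = 1`.
#' Equals `sum_l Tr(O_l Utilde_l O_l^T)` with
#' `Utilde_l = (m-1)^-2 sum_{l' != l} H U_l' H`.
#'
#' @param headset output of [multihead_project] (or any list with a
#'   `heads` field).
#' @return Scalar redundancy.
#' @export
redundancy_loss <- function(headset) {
  heads <- headset$heads
  L <- length(heads)
  if (L < 2) return(0)
  tot <- 0
  for (l in seq_len(L)) for (l2 in seq_len(L)) if (l != l2)
    tot <- tot + hsic(heads[[l]], heads[[l2]])
  tot
}

#' Student-t soft cluster assignment
#'
#' `p_ij = (1 + ||o_i - omega_j||^2)^-1`, normalized over clusters `j`.
#'
#' @param Ol N x m head matrix.
#' @param centers J x m matrix of cluster centers.
#' @return N x J row-stochastic matrix.
#' @export
soft_assign <- function(Ol, centers) {
  Ol <- as.matrix(Ol); centers <- as.matrix(centers)
  stopifnot(all(is.finite(centers)), nrow(centers) >= 2)
  d2 <- outer(rowSums(Ol^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(Ol)), rowSums(centers^2)) - 2 * Ol %*% t(centers)
  k <- 1 / (1 + pmax(d2, 0))
  k / rowSums(k)
}

#' Auxiliary target distribution
#'
#' `r_ij = (p_ij^2 / f_j) / sum_j' (p_ij'^2 / f_j')` with soft cluster
#' frequencies `f_j = sum_i p_ij`; squares sharpen high-confidence
#' assignments, the frequency division balances cluster sizes. Empty
#' clusters (`f_j = 0`) are handled with an additive epsilon and a
#' warning.
#'
#' @param P N x J row-stochastic soft assignment.
#' @return N x J row-stochastic target.
#' @export
target_distribution <- function(P) {
  P <- as.matrix(P)
  f <- colSums(P)
  if (any(f == 0)) {
    warning("empty cluster in target_distribution; using additive epsilon")
    f <- f + 1e-12
  }
  R <- sweep(P^2, 2, f, "/")
  R / rowSums(R)
}

#' KL clustering loss
#'
#' `sum_l KL(P_l || R_l) = sum_l sum_ij p_ij log(p_ij / r_ij)`;
#' non-negative and zero iff `P_l = R_l` for every head. The targets
#' are treated as constants during training.
#'
#' @param soft a soft-assignment matrix or list of them.
#' @param target matching target matrix or list.
#' @return Scalar loss.
#' @export
clustering_loss <- function(soft, target) {
  if (is.matrix(soft)) { soft <- list(soft); target <- list(target) }
  tot <- 0
  for (l in seq_along(soft)) {
    P <- soft[[l]]; R <- target[[l]]
    stopifnot(all(dim(P) == dim(R)))
    pos <- P > 0
    tot <- tot + sum(P[pos] * log(P[pos] / pmax(R[pos], 1e-300)))
  }
  tot
}

# ---- autodiff pieces --------------------------------------------------

ad_head <- function(ZI, nodes, l, cfg) {
  Q <- ad_matmul(ZI, nodes[[paste0("wq", l)]])
  K <- ad_matmul(ZI, nodes[[paste0("wk", l)]])
  V <- ad_matmul(ZI, nodes[[paste0("wv", l)]])
  O <- ad_matmul(ad_rowsoftmax(ad_scale(ad_matmul(Q, ad_t(K)), 1 / cfg$m)), V)
  if (isTRUE(cfg$head_skip)) ad_add(O, V) else O
}

ad_soft_assign <- function(O, W, ones_1J, ones_N1) {
  d2 <- ad_add(ad_matmul(ad_rowsums(ad_mul(O, O)), ones_1J),
               ad_add(ad_matmul(ones_N1, ad_t(ad_rowsums(ad_mul(W, W)))),
                      ad_scale(ad_matmul(O, ad_t(W)), -2)))
  kern <- ad_div(ad_const(matrix(1, nrow(ones_N1$value), ncol(ones_1J$value))),
                 ad_shift(ad_clip(d2, 0, Inf), 1))
  ad_div(kern, ad_matmul(ad_rowsums(kern), ones_1J))
}

# KL(P || R) with constant target R, summed over entries
ad_kl_const_target <- function(P, Rconst) {
  Pc <- ad_clip(P, 1e-12, Inf)
  ad_sum(ad_mul(P, ad_sub(ad_log(Pc), ad_const(log(pmax(Rconst, 1e-300))))))
}

forward_stage2 <- function(nodes, ZIc, cfg, targets = NULL, use_red = TRUE) {
  N <- nrow(ZIc$value)
  heads <- lapply(seq_len(cfg$L), function(l) ad_head(ZIc, nodes, l, cfg))
  Zbar <- heads[[1]]
  if (cfg$L > 1) for (l in 2:cfg$L) Zbar <- ad_cbind(Zbar, heads[[l]])
  ZbarI <- ad_mlp(Zbar, nodes, c("dec1", "dec2"))
  diff <- ad_sub(ZIc, ZbarI)
  lrec <- ad_mean(ad_mul(diff, diff))

  comp <- list(rec = as.numeric(lrec$value), red = NA_real_, clu = NA_real_)
  loss <- lrec
  if (use_red && cfg$L > 1 && cfg$beta1 > 0) {
    if (cfg$hsic_space == "sample") {
      # Tr(K_l H K_l' H) with K = O O^T equals ||Oc_l^T Oc_l'||_F^2 for
      # column-centered heads Oc = H O, so only m x m products are needed
      Oc <- lapply(heads, function(O)
        ad_addbias(O, ad_scale(ad_colsums(O), -1 / N)))
      pair_hsic <- function(l, l2) {
        Cr <- ad_matmul(ad_t(Oc[[l]]), Oc[[l2]])
        ad_scale(ad_sum(ad_mul(Cr, Cr)), 1 / (N - 1)^2)
      }
    } else {
      Hc <- ad_const(diag(cfg$m) - matrix(1 / cfg$m, cfg$m, cfg$m))
      U <- lapply(heads, function(O) ad_matmul(ad_t(O), O))
      CU <- lapply(U, function(Ul) ad_matmul(ad_matmul(Hc, Ul), Hc))
      pair_hsic <- function(l, l2) ad_scale(ad_sum(ad_mul(CU[[l]], U[[l2]])),
                                            1 / (cfg$m - 1)^2)
    }
    lred <- NULL
    for (l in seq_len(cfg$L)) for (l2 in seq_len(cfg$L)) if (l2 != l) {
      term <- pair_hsic(l, l2)
      if (cfg$normalize_hsic) # CKA-style: scale-invariant dependence in [0,1]
        term <- ad_div(term, ad_shift(ad_sqrt(ad_mul(pair_hsic(l, l),
                                                     pair_hsic(l2, l2))), 1e-12))
      lred <- if (is.null(lred)) term else ad_add(lred, term)
    }
    comp$red <- as.numeric(lred$value)
    loss <- ad_add(loss, ad_scale(lred, cfg$beta1))
  }
  soft <- NULL
  live <- if (is.null(targets)) integer(0) else
    which(!vapply(targets, is.null, logical(1)))
  if (length(live)) {
    ones_N1 <- ad_const(matrix(1, N, 1))
    soft <- vector("list", cfg$L)
    lclu <- NULL
    for (l in live) {
      ones_1J <- ad_const(matrix(1, 1, cfg$cluster_counts[l]))
      soft[[l]] <- ad_soft_assign(heads[[l]], nodes[[paste0("cent", l)]],
                                  ones_1J, ones_N1)
      term <- ad_kl_const_target(soft[[l]], targets[[l]])
      lclu <- if (is.null(lclu)) term else ad_add(lclu, term)
    }
    lclu <- ad_scale(lclu, 1 / N)                      # N-stable scaling
    comp$clu <- as.numeric(lclu$value)
    loss <- ad_add(loss, ad_scale(lclu, cfg$beta2))
  }
  list(heads = heads, ZbarI = ZbarI, soft = soft, loss = loss, comp = comp)
}

init_stage2_params <- function(d, cfg) {
  p <- list()
  lim <- sqrt(6 / (d + cfg$m))
  for (l in seq_len(cfg$L)) {
    for (w in c("wq", "wk", "wv"))
      p[[paste0(w, l)]] <- matrix(stats::runif(d * cfg$m, -lim, lim), d, cfg$m)
  }
  p <- add_dense(p, "dec1", cfg$L * cfg$m, 64)
  p <- add_dense(p, "dec2", 64, d)
  p
}

# ---- training ---------------------------------------------------------

#' Train the stage-2 multiple-clusterings model
#'
#' Warm-up epochs optimize reconstruction (plus the redundancy penalty,
#' so the heads decorrelate before clustering starts); k-means then
#' initializes the cluster centers in each head; the remaining epochs
#' optimize the full objective with the auxiliary targets refreshed
#' every `target_update_interval` epochs and treated as constants in
#' between. Hard labels are the row argmax of the final targets, ties
#' broken toward the lowest cluster index.
#'
#' @param ZI numeric matrix, cells x d (typically `state$latents$ZI`
#'   from [train_stage1]); stage-1 parameters are frozen.
#' @param cfg a [multiclust_config].
#' @param verbose print the loss every 50 epochs.
#' @return A `multiclust_state` with `headset` (`heads`, `projections`,
#'   `Zbar_I`), `clusters` (`centers`, `soft`, `target`, `labels`),
#'   `params` and `loss_history`.
#' @export
train_stage2 <- function(ZI, cfg = multiclust_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "multiclust_config"))
  ZI <- as.matrix(ZI)
  if (cfg$standardize) {
    sds <- apply(ZI, 2, stats::sd)
    ZI <- sweep(sweep(ZI, 2, colMeans(ZI)), 2, pmax(sds, 1e-12), "/")
  }
  set.seed(cfg$seed)
  d <- ncol(ZI)
  params <- init_stage2_params(d, cfg)
  opt <- adam_init(params)
  hist <- vector("list", cfg$epochs)
  targets <- NULL

  N <- nrow(ZI)
  init_epoch <- cfg$warmup_epochs + (seq_len(cfg$L) - 1L) * cfg$center_stagger
  targets <- vector("list", cfg$L)
  for (ep in seq_len(cfg$epochs)) {
    newly <- which(init_epoch + 1L == ep)
    if (length(newly)) {
      # Center initialization by seeded multi-restart k-means. The first
      # head anchors the primary clustering, so its initial partition
      # comes from k-means on the full co-embedding (the single-
      # clustering protocol) and is mapped into head space as label
      # means; later heads are initialized on their own (by then
      # redundancy-reshaped) geometry.
      hv <- head_values(params, ZI, cfg)
      for (l in newly) {
        set.seed(cfg$seed + 1000L + l)
        # remove the cluster-mean structure already claimed by earlier
        # heads, so this head's initial partition is an alternative one
        Zres <- ZI
        for (l2 in seq_len(l - 1L)) {
          lab2 <- max.col(targets[[l2]], ties.method = "first")
          for (j in unique(lab2)) {
            idx <- lab2 == j
            Zres[idx, ] <- sweep(Zres[idx, , drop = FALSE], 2,
                                 colMeans(Zres[idx, , drop = FALSE]))
          }
        }
        if (l > 1L) {
          # re-seat this head's value projection on the residual view:
          # ridge-fit W_V so that ZI W_V approximates the leading
          # principal components of the residualized co-embedding
          pcs <- stats::prcomp(Zres, center = FALSE)
          S <- pcs$x[, seq_len(min(cfg$m, ncol(pcs$x))), drop = FALSE]
          S <- sweep(S, 2, pmax(apply(S, 2, stats::sd), 1e-8), "/")
          if (ncol(S) < cfg$m) S <- cbind(S, matrix(0, N, cfg$m - ncol(S)))
          G <- crossprod(ZI) + diag(1e-6, ncol(ZI))
          params[[paste0("wv", l)]] <- solve(G, crossprod(ZI, S))
          opt$m[[paste0("wv", l)]] <- params[[paste0("wv", l)]] * 0
          opt$v[[paste0("wv", l)]] <- params[[paste0("wv", l)]] * 0
          hv <- head_values(params, ZI, cfg)
        }
        lab <- stats::kmeans(Zres, centers = cfg$cluster_counts[l],
                             nstart = 10, iter.max = 100)$cluster
        cent <- t(vapply(seq_len(cfg$cluster_counts[l]), function(j)
          colMeans(hv[[l]][lab == j, , drop = FALSE]), numeric(cfg$m)))
        params[[paste0("cent", l)]] <- cent
        opt$m[[paste0("cent", l)]] <- cent * 0
        opt$v[[paste0("cent", l)]] <- cent * 0
      }
    }
    live <- which(init_epoch < ep)
    if (length(live) &&
        (length(newly) || (ep - cfg$warmup_epochs - 1) %% cfg$target_update_interval == 0)) {
      hv <- head_values(params, ZI, cfg)
      for (l in live)
        targets[[l]] <- target_distribution(
          soft_assign(hv[[l]], params[[paste0("cent", l)]]))
    }
    ad_tape_reset()
    nodes <- ad_wrap(params)
    fw <- forward_stage2(nodes, ad_const(ZI), cfg,
                         targets = targets,
                         use_red = ep > cfg$warmup_epochs)
    tot <- as.numeric(fw$loss$value)
    if (!is.finite(tot))
      stop(sprintf("training error: non-finite loss at epoch %d", ep))
    hist[[ep]] <- data.frame(epoch = ep, rec = fw$comp$rec, red = fw$comp$red,
                             clu = fw$comp$clu, total = tot)
    ad_backward(fw$loss)
    st <- adam_step(params, ad_grads(nodes), opt, cfg$learning_rate)
    params <- st$params; opt <- st$opt
    if (verbose && (ep %% 50 == 0 || ep == 1))
      message(sprintf("epoch %d: L2 = %.4f", ep, tot))
  }

  heads <- head_values(params, ZI, cfg)
  soft <- lapply(seq_len(cfg$L), function(l)
    soft_assign(heads[[l]], params[[paste0("cent", l)]]))
  target <- lapply(soft, target_distribution)
  labels <- lapply(target, function(R) max.col(R, ties.method = "first"))
  state <- structure(list(params = params, cfg = cfg), class = "multiclust_state")
  hs <- multihead_project(ZI, cfg, state)
  state$headset <- hs
  state$clusters <- list(
    centers = lapply(seq_len(cfg$L), function(l) params[[paste0("cent", l)]]),
    soft = soft, target = target, labels = labels)
  state$loss_history <- do.call(rbind, hist)
  state$trained <- TRUE
  state
}

head_values <- function(params, ZI, cfg) {
  lapply(seq_len(cfg$L), function(l) {
    Q <- ZI %*% params[[paste0("wq", l)]]
    K <- ZI %*% params[[paste0("wk", l)]]
    V <- ZI %*% params[[paste0("wv", l)]]
    O <- row_softmax(Q %*% t(K) / cfg$m) %*% V
    if (isTRUE(cfg$head_skip)) O + V else O
  })
}

#' @export
print.multiclust_state <- function(x, ...) {
  cat(sprintf("multiclust_state: L=%d clusterings (%s clusters), final L2 = %.4f\n",
              x$cfg$L, paste(x$cfg$cluster_counts, collapse = "/"),
              utils::tail(x$loss_history$total, 1)))
  invisible(x)
}
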