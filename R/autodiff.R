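# Reverse-mode automatic differentiation over dense matrices.
#
# Minimal tape-based engine used by both training stages. A forward pass
# builds the graph eagerly (values computed immediately); ad_backward()
# walks the tape in reverse, accumulating gradients into the leaves
# created with ad_param(). Parameters live as plain matrices in model
# state lists and are re-wrapped at every forward pass, so no tape state
# survives between epochs.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL
.ad$n <- 0L

ad_tape_reset <- function() {
  .ad$tape <- vector("list", 256L)
  .ad$n <- 0L
  invisible(NULL)
}

ad_node <- function(value, parents = list(), backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  class(node) <- "ad_node"
  n <- .ad$n + 1L
  if (n > length(.ad$tape)) .ad$tape <- c(.ad$tape, vector("list", length(.ad$tape)))
  .ad$tape[[n]] <- node
  .ad$n <- n
  node$id <- n
  node
}

ad_param <- function(x) ad_node(x)
ad_const <- function(x) {
  node <- ad_node(x)
  node$is_const <- TRUE
  node
}

ad_value <- function(x) if (inherits(x, "ad_node")) x$value else x

.accum <- function(node, g) {
  if (isTRUE(node$is_const)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' @noRd
ad_backward <- function(loss) {
  stopifnot(inherits(loss, "ad_node"), length(loss$value) == 1L)
  loss$grad <- 1
  for (i in seq(loss$id, 1L)) {
    node <- .ad$tape[[i]]
    if (is.null(node) || is.null(node$grad) || is.null(node$backward)) next
    gs <- node$backward(node$grad)
    for (k in seq_along(gs)) .accum(node$parents[[k]], gs[[k]])
  }
  invisible(NULL)
}

# ---- elementwise / structural ops -------------------------------------

ad_add <- function(a, b) ad_node(a$value + b$value, list(a, b),
  function(g) list(g, g))

ad_sub <- function(a, b) ad_node(a$value - b$value, list(a, b),
  function(g) list(g, -g))

ad_mul <- function(a, b) ad_node(a$value * b$value, list(a, b),
  function(g) list(g * b$value, g * a$value))

ad_div <- function(a, b) ad_node(a$value / b$value, list(a, b),
  function(g) list(g / b$value, -g * a$value / (b$value^2)))

ad_scale <- function(a, s) ad_node(a$value * s, list(a),
  function(g) list(g * s))

ad_shift <- function(a, s) ad_node(a$value + s, list(a),
  function(g) list(g))

ad_neg <- function(a) ad_scale(a, -1)

ad_matmul <- function(a, b) ad_node(a$value %*% b$value, list(a, b),
  function(g) list(tcrossprod(g, b$value), crossprod(a$value, g)))

ad_t <- function(a) ad_node(t(a$value), list(a), function(g) list(t(g)))

# bias broadcast: A [n x k] + b [1 x k]
ad_addbias <- function(a, b) {
  ad_node(sweep(a$value, 2, as.vector(b$value), "+"), list(a, b),
    function(g) list(g, matrix(colSums(g), nrow = 1)))
}

ad_rbind <- function(a, b) {
  na <- nrow(a$value)
  ad_node(rbind(a$value, b$value), list(a, b),
    function(g) list(g[seq_len(na), , drop = FALSE],
                     g[-seq_len(na), , drop = FALSE]))
}

ad_cbind <- function(a, b) {
  ka <- ncol(a$value)
  ad_node(cbind(a$value, b$value), list(a, b),
    function(g) list(g[, seq_len(ka), drop = FALSE],
                     g[, -seq_len(ka), drop = FALSE]))
}

# ---- nonlinearities ---------------------------------------------------

ad_relu <- function(a) ad_node(pmax(a$value, 0), list(a),
  function(g) list(g * (a$value > 0)))

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(s, list(a), function(g) list(g * s * (1 - s)))
}

ad_exp <- function(a) {
  e <- exp(a$value)
  ad_node(e, list(a), function(g) list(g * e))
}

ad_log <- function(a) ad_node(log(a$value), list(a),
  function(g) list(g / a$value))

ad_lgamma <- function(a) ad_node(lgamma(a$value), list(a),
  function(g) list(g * digamma(a$value)))

ad_sqrt <- function(a) {
  s <- sqrt(a$value)
  ad_node(s, list(a), function(g) list(g / (2 * s)))
}

# clip: gradient passes only where the value was inside [lo, hi]
ad_clip <- function(a, lo, hi) {
  v <- pmin(pmax(a$value, lo), hi)
  ad_node(v, list(a), function(g) list(g * (a$value >= lo & a$value <= hi)))
}

# row-wise softmax of a matrix
ad_rowsoftmax <- function(a) {
  s <- row_softmax(a$value)
  ad_node(s, list(a),
    function(g) list((g - rowSums(g * s)) * s))
}

# normalize a (positive) matrix to sum 1
ad_normalize_sum <- function(a) {
  s <- sum(a$value)
  v <- a$value / s
  ad_node(v, list(a), function(g) list(g / s - sum(g * v) / s))
}

# matrix node times scalar node (1x1)
ad_smul <- function(a, s) {
  sv <- as.numeric(s$value)
  ad_node(a$value * sv, list(a, s),
    function(g) list(g * sv, matrix(sum(g * a$value), 1, 1)))
}

# column standardization (full-batch norm, no learnable affine):
# z_col <- (z_col - mean) / sqrt(var + eps)
ad_colstd <- function(a, eps = 1e-5) {
  n <- nrow(a$value)
  ones <- ad_const(matrix(1, n, 1))
  mu <- ad_scale(ad_colsums(a), 1 / n)
  cent <- ad_sub(a, ad_matmul(ones, mu))
  v <- ad_shift(ad_scale(ad_colsums(ad_mul(cent, cent)), 1 / n), eps)
  ad_div(cent, ad_matmul(ones, ad_sqrt(v)))
}

# ---- reductions -------------------------------------------------------

ad_sum <- function(a) ad_node(sum(a$value), list(a),
  function(g) list(array(g, dim = dim(a$value))))

ad_mean <- function(a) {
  n <- length(a$value)
  ad_node(mean(a$value), list(a),
    function(g) list(array(g / n, dim = dim(a$value))))
}

# row sums -> [n x 1]; column sums -> [1 x k]
ad_rowsums <- function(a) {
  k <- ncol(a$value)
  ad_node(matrix(rowSums(a$value), ncol = 1), list(a),
    function(g) list(matrix(g, nrow = nrow(a$value), ncol = k)))
}

ad_colsums <- function(a) {
  n <- nrow(a$value)
  ad_node(matrix(colSums(a$value), nrow = 1), list(a),
    function(g) list(matrix(g, nrow = n, ncol = ncol(a$value), byrow = TRUE)))
}

# ---- shared numeric helpers ------------------------------------------

row_softmax <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

# ---- layers and optimizer --------------------------------------------

# Glorot-uniform dense layer parameters
init_dense <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  list(W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = matrix(0, 1, n_out))
}

# Parameters are kept as a FLAT named list of matrices; layer "foo" owns
# entries "foo.W" and "foo.b". add_dense() appends a layer, ad_wrap()
# turns every matrix into a fresh ad_param node for one forward pass,
# ad_grads() reads the accumulated gradients back out.

add_dense <- function(params, name, n_in, n_out) {
  d <- init_dense(n_in, n_out)
  params[[paste0(name, ".W")]] <- d$W
  params[[paste0(name, ".b")]] <- d$b
  params
}

ad_wrap <- function(params) lapply(params, ad_param)

ad_grads <- function(nodes) {
  lapply(nodes, function(nd) if (is.null(nd$grad)) nd$value * 0 else nd$grad)
}

# x through dense layer `name`; then through an MLP given layer names
ad_dense <- function(x, nodes, name) {
  ad_addbias(ad_matmul(x, nodes[[paste0(name, ".W")]]),
             nodes[[paste0(name, ".b")]])
}

ad_mlp <- function(x, nodes, layer_names) {
  h <- x
  nl <- length(layer_names)
  for (i in seq_len(nl)) {
    h <- ad_dense(h, nodes, layer_names[i])
    if (i < nl) h <- ad_relu(h)
  }
  h
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

adam_step <- function(flat, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip_norm = 5, weight_decay = 0) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(gn) && gn > clip_norm) grads <- lapply(grads, function(g) g * (clip_norm / gn))
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (key in names(flat)) {
    g <- grads[[key]]
    if (is.null(g)) next
    opt$m[[key]] <- beta1 * opt$m[[key]] + (1 - beta1) * g
    opt$v[[key]] <- beta2 * opt$v[[key]] + (1 - beta2) * g^2
    flat[[key]] <- flat[[key]] -
      lr * (opt$m[[key]] / bc1) / (sqrt(opt$v[[key]] / bc2) + eps) -
      lr * weight_decay * flat[[key]]
  }
  list(params = flat, opt = opt)
}
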