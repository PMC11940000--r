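# Minimal neural-network engine for the three grasp-prediction architectures.
#
# Layers operate on batches: EMG input is an array (batch, frames, channels),
# context input a (batch, features) matrix. Convolutions use valid padding and
# are computed as BLAS matrix products through an im2col expansion whose
# column order is (kernel position major, input channel minor); conv weights
# are stored as (kernel_size * in_channels) x filters matrices with matching
# row order. All parameters are initialized Glorot-uniform with zero biases,
# drawn from the caller's RNG stream in a fixed order (EMG branch, context
# branch, head) so that hybrid variants sharing a seed share EMG-branch
# initial weights exactly.

.glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

#' Instantiate a network from a model spec
#'
#' Draws Glorot-uniform weights (zero biases) from the current RNG stream in
#' the fixed order EMG branch, context branch, head.
#'
#' @param spec A [build_model()] result.
#' @return A list of parameter tensors (class `nn_params`).
#' @export
nn_init <- function(spec) {
  params <- list()
  if (!is.null(spec$emg)) {
    c1 <- spec$emg[[1]]; c2 <- spec$emg[[3]]
    params$conv1 <- list(
      W = .glorot(c1$in_dim * c1$kernel_size, c1$units_or_filters * c1$kernel_size,
                  c(c1$kernel_size * c1$in_dim, c1$units_or_filters)),
      b = rep(0, c1$units_or_filters))
    params$conv2 <- list(
      W = .glorot(c2$in_dim * c2$kernel_size, c2$units_or_filters * c2$kernel_size,
                  c(c2$kernel_size * c2$in_dim, c2$units_or_filters)),
      b = rep(0, c2$units_or_filters))
  }
  if (!is.null(spec$context)) {
    f1 <- spec$context[[1]]; f2 <- spec$context[[2]]
    params$fc1 <- list(W = .glorot(f1$in_dim, f1$units_or_filters,
                                   c(f1$in_dim, f1$units_or_filters)),
                       b = rep(0, f1$units_or_filters))
    params$fc2 <- list(W = .glorot(f2$in_dim, f2$units_or_filters,
                                   c(f2$in_dim, f2$units_or_filters)),
                       b = rep(0, f2$units_or_filters))
  }
  params$head <- lapply(Filter(function(l) l$kind == "dense", spec$head), function(l) {
    list(W = .glorot(l$in_dim, l$units_or_filters, c(l$in_dim, l$units_or_filters)),
         b = rep(0, l$units_or_filters))
  })
  structure(params, class = "nn_params")
}

#' Trainable-parameter count of an instantiated network
#'
#' The backend's own report, used to cross-check the spec-level closed-form
#' accounting of [count_params()].
#'
#' @param params An [nn_init()] result.
#' @return Integer count of trainable scalars.
#' @export
nn_param_count <- function(params) {
  count <- function(x) {
    if (is.numeric(x)) length(x) else sum(vapply(x, count, numeric(1)))
  }
  as.integer(count(unclass(params)))
}

# ---- layer primitives -------------------------------------------------------
#
# The convolution and pooling kernels run in C++ (src/kernels.cpp). The plain
# R implementations below are retained as independent references; the test
# suite asserts kernel equivalence against them on random batches.

.im2col <- function(X, K) {
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  Lout <- L - K + 1L
  Xc <- matrix(0, B * Lout, K * C)
  for (k in seq_len(K)) {
    Xc[, ((k - 1L) * C + 1L):(k * C)] <-
      matrix(X[, k:(k + Lout - 1L), , drop = FALSE], B * Lout, C)
  }
  Xc
}

.conv_fwd_ref <- function(X, W, b, K) {
  d <- dim(X); B <- d[1]
  Lout <- d[2] - K + 1L
  Xc <- .im2col(X, K)
  Y <- Xc %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = array(Y, c(B, Lout, ncol(W))), Xc = Xc)
}

.conv_bwd_ref <- function(dY, Xc, W, K, L, C) {
  d <- dim(dY); B <- d[1]; Lout <- d[2]; F_ <- d[3]
  dYm <- matrix(dY, B * Lout, F_)
  dW <- crossprod(Xc, dYm)
  db <- colSums(dYm)
  dXc <- dYm %*% t(W)
  dX <- array(0, c(B, L, C))
  for (k in seq_len(K)) {
    dX[, k:(k + Lout - 1L), ] <- dX[, k:(k + Lout - 1L), , drop = FALSE] +
      array(dXc[, ((k - 1L) * C + 1L):(k * C)], c(B, Lout, C))
  }
  list(dX = dX, dW = dW, db = db)
}

.maxpool_fwd_ref <- function(X, size = 4L) {
  d <- dim(X); B <- d[1]; L <- d[2]; F_ <- d[3]
  Lp <- L %/% size
  A <- array(X[, seq_len(size * Lp), , drop = FALSE], c(B, size, Lp, F_))
  slices <- lapply(seq_len(size), function(i) array(A[, i, , , drop = FALSE], c(B, Lp, F_)))
  M <- slices[[1]]
  for (i in 2:size) M <- pmax(M, slices[[i]])
  list(Y = M, slices = slices, L = L, size = size)
}

.maxpool_bwd_ref <- function(pool, dY) {
  d <- dim(dY); B <- d[1]; Lp <- d[2]; F_ <- d[3]
  size <- pool$size
  dA <- array(0, c(B, size, Lp, F_))
  taken <- array(FALSE, c(B, Lp, F_))
  for (i in seq_len(size)) {
    mask <- (pool$slices[[i]] == pool$Y) & !taken
    taken <- taken | mask
    dA[, i, , ] <- dY * mask
  }
  dX <- array(0, c(B, pool$L, F_))
  dX[, seq_len(size * Lp), ] <- array(dA, c(B, size * Lp, F_))
  dX
}

.gap_fwd <- function(X) {
  d <- dim(X); B <- d[1]; Lt <- d[2]; F_ <- d[3]
  Y <- matrix(0, B, F_)
  for (f in seq_len(F_)) Y[, f] <- rowMeans(matrix(X[, , f, drop = FALSE], B, Lt))
  Y
}

.gap_bwd <- function(dY, Lt) {
  B <- nrow(dY); F_ <- ncol(dY)
  aperm(array(rep(as.numeric(dY) / Lt, times = Lt), c(B, F_, Lt)), c(1, 3, 2))
}

.softmax_rows <- function(Z) {
  E <- exp(Z - apply(Z, 1, max))
  E / rowSums(E)
}

# ---- full network forward / backward ---------------------------------------

# X: (B, L, C) array or NULL; Cx: (B, d) matrix or NULL.
.nn_forward <- function(params, spec, X = NULL, Cx = NULL, keep_cache = FALSE) {
  cache <- list()
  emg_emb <- ctx_emb <- NULL
  if (!is.null(spec$emg)) {
    K1 <- spec$emg[[1]]$kernel_size
    K2 <- spec$emg[[3]]$kernel_size
    A1 <- .conv_relu_fwd_cpp(X, params$conv1$W, params$conv1$b, K1, TRUE)
    pool <- .maxpool_fwd_cpp(A1, spec$emg[[2]]$units_or_filters)
    A2 <- .conv_relu_fwd_cpp(pool$Y, params$conv2$W, params$conv2$b, K2, TRUE)
    emg_emb <- .gap_fwd(A2)
    if (keep_cache) {
      cache$emg <- list(X = X, A1 = A1, pool = pool, A2 = A2,
                        Lt2 = dim(A2)[2], pool_size = spec$emg[[2]]$units_or_filters)
    }
  }
  if (!is.null(spec$context)) {
    Z1 <- Cx %*% params$fc1$W + rep(params$fc1$b, each = nrow(Cx))
    A1c <- pmax(Z1, 0)
    Z2 <- A1c %*% params$fc2$W + rep(params$fc2$b, each = nrow(A1c))
    ctx_emb <- pmax(Z2, 0)
    if (keep_cache) cache$ctx <- list(Cx = Cx, Z1pos = Z1 > 0, A1c = A1c, Z2pos = Z2 > 0)
  }
  H <- if (!is.null(emg_emb) && !is.null(ctx_emb)) {
    cbind(emg_emb, ctx_emb)
  } else if (!is.null(emg_emb)) emg_emb else ctx_emb
  n_head <- length(params$head)
  Hs <- vector("list", n_head + 1L)
  Zpos <- vector("list", n_head)
  Hs[[1]] <- H
  for (i in seq_len(n_head)) {
    Z <- Hs[[i]] %*% params$head[[i]]$W + rep(params$head[[i]]$b, each = nrow(Hs[[i]]))
    if (i < n_head) {
      Zpos[[i]] <- Z > 0
      Hs[[i + 1L]] <- pmax(Z, 0)
    } else {
      Hs[[i + 1L]] <- Z  # logits
    }
  }
  probs <- .softmax_rows(Hs[[n_head + 1L]])
  if (keep_cache) cache$head <- list(Hs = Hs, Zpos = Zpos, emg_dim = ncol(emg_emb %||% matrix(0, 1, 0)))
  list(probs = probs, logits = Hs[[n_head + 1L]], cache = cache)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# dZ: gradient of the loss w.r.t. the logits, (B, 2).
.nn_backward <- function(params, spec, cache, dZ) {
  grads <- list()
  n_head <- length(params$head)
  Hs <- cache$head$Hs
  d_up <- dZ
  grads$head <- vector("list", n_head)
  for (i in rev(seq_len(n_head))) {
    grads$head[[i]] <- list(W = crossprod(Hs[[i]], d_up), b = colSums(d_up))
    d_up <- d_up %*% t(params$head[[i]]$W)
    if (i > 1L) d_up <- d_up * cache$head$Zpos[[i - 1L]]
  }
  d_emg_emb <- d_ctx_emb <- NULL
  if (!is.null(spec$emg) && !is.null(spec$context)) {
    ed <- cache$head$emg_dim
    d_emg_emb <- d_up[, seq_len(ed), drop = FALSE]
    d_ctx_emb <- d_up[, (ed + 1L):ncol(d_up), drop = FALSE]
  } else if (!is.null(spec$emg)) {
    d_emg_emb <- d_up
  } else {
    d_ctx_emb <- d_up
  }
  if (!is.null(spec$context)) {
    cc <- cache$ctx
    dZ2 <- d_ctx_emb * cc$Z2pos
    grads$fc2 <- list(W = crossprod(cc$A1c, dZ2), b = colSums(dZ2))
    dA1c <- dZ2 %*% t(params$fc2$W)
    dZ1 <- dA1c * cc$Z1pos
    grads$fc1 <- list(W = crossprod(cc$Cx, dZ1), b = colSums(dZ1))
  }
  if (!is.null(spec$emg)) {
    ce <- cache$emg
    dA2 <- .gap_bwd(d_emg_emb, ce$Lt2)
    bw2 <- .conv_relu_bwd_cpp(ce$pool$Y, ce$A2, dA2, params$conv2$W,
                              spec$emg[[3]]$kernel_size, TRUE, TRUE)
    grads$conv2 <- list(W = bw2$dW, b = as.numeric(bw2$db))
    dA1 <- .maxpool_bwd_cpp(ce$pool$idx, bw2$dX, dim(ce$A1)[2], ce$pool_size)
    # dX at the input layer is never needed
    bw1 <- .conv_relu_bwd_cpp(ce$X, ce$A1, dA1, params$conv1$W,
                              spec$emg[[1]]$kernel_size, TRUE, FALSE)
    grads$conv1 <- list(W = bw1$dW, b = as.numeric(bw1$db))
  }
  grads
}

# Cross-entropy of 2-class softmax against one-hot targets; y in {0,1}.
.ce_loss <- function(probs, y) {
  p <- pmax(probs[cbind(seq_along(y), y + 1L)], 1e-12)
  -mean(log(p))
}

.ce_grad_logits <- function(probs, y) {
  B <- length(y)
  T_ <- matrix(0, B, 2)
  T_[cbind(seq_len(B), y + 1L)] <- 1
  (probs - T_) / B
}

# ---- Adam -------------------------------------------------------------------

.zeros_like <- function(x) {
  if (is.numeric(x)) x * 0 else lapply(x, .zeros_like)
}

.adam_init <- function(params) {
  list(m = .zeros_like(unclass(params)), v = .zeros_like(unclass(params)), t = 0L)
}

.adam_leaf <- function(p, g, m, v, lr, t, beta1, beta2, eps) {
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g * g
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

.adam_recurse <- function(p, g, m, v, lr, t, beta1, beta2, eps) {
  if (is.numeric(p)) return(.adam_leaf(p, g, m, v, lr, t, beta1, beta2, eps))
  out_p <- p; out_m <- m; out_v <- v
  # index by name where available: gradient lists are not built in
  # parameter-list order
  keys <- if (!is.null(names(p))) names(p) else seq_along(p)
  for (nm in keys) {
    r <- .adam_recurse(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t, beta1, beta2, eps)
    out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
  }
  list(p = out_p, m = out_m, v = out_v)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-7) {
  state$t <- state$t + 1L
  r <- .adam_recurse(unclass(params), grads, state$m, state$v, lr, state$t,
                     beta1, beta2, eps)
  state$m <- r$m; state$v <- r$v
  list(params = structure(r$p, class = "nn_params"), state = state)
}
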