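# Internal 1-D convolutional network engine.
#
# Activations for a batch of N sequences of length L with C channels are
# stored as an (N*L) x C matrix in position-major row order (row
# (t-1)*N + n holds position t of sequence n). With kernel width 3 and
# same-padding, the im2col matrix is then just cbind(shift, A, shift),
# so every convolution is a single BLAS matrix product. Gradients are
# exact backpropagation; the optimizer is Adam. The layout and the
# backward pass are covered by a finite-difference gradient test.

.shift_down <- function(A, N) {  # position t receives position t-1; t=1 gets 0
  rbind(matrix(0, N, ncol(A)), A[seq_len(nrow(A) - N), , drop = FALSE])
}

.shift_up <- function(A, N) {    # position t receives position t+1; t=L gets 0
  rbind(A[(N + 1):nrow(A), , drop = FALSE], matrix(0, N, ncol(A)))
}

.im2col3 <- function(A, N) {
  cbind(.shift_down(A, N), A, .shift_up(A, N))
}

.cnn_init <- function(in_channels, channels, kernel = 3L) {
  layers <- list()
  cin <- in_channels
  for (i in seq_along(channels)) {
    fan_in <- kernel * cin
    layers[[i]] <- list(
      W = matrix(stats::rnorm(fan_in * channels[i], sd = sqrt(2 / fan_in)),
                 fan_in, channels[i]),
      b = numeric(channels[i]))
    cin <- channels[i]
  }
  dense <- list(
    W = matrix(stats::rnorm(cin, sd = sqrt(1 / cin)), cin, 1),
    b = 0)
  list(conv = layers, dense = dense)
}

# Forward pass. X: (N*L) x in_channels position-major one-hot matrix.
# Returns probabilities and, if keep = TRUE, the caches needed for backprop.
.cnn_forward <- function(params, X, N, L, keep = FALSE) {
  A <- X
  caches <- list()
  for (i in seq_along(params$conv)) {
    Xc <- .im2col3(A, N)
    Z <- Xc %*% params$conv[[i]]$W
    Z <- sweep(Z, 2, params$conv[[i]]$b, "+")
    A <- Z * (Z > 0)
    if (keep) caches[[i]] <- list(Xc = Xc, relu = Z > 0)
  }
  # global max pool over positions
  C <- ncol(A)
  P <- A[seq_len(N), , drop = FALSE]
  tmax <- matrix(1L, N, C)
  if (L > 1L) {
    for (t in 2:L) {
      At <- A[((t - 1) * N + 1):(t * N), , drop = FALSE]
      upd <- At > P
      tmax[upd] <- t
      P[upd] <- At[upd]
    }
  }
  z <- drop(P %*% params$dense$W) + params$dense$b
  p <- 1 / (1 + exp(-z))
  if (!keep) return(list(p = p))
  list(p = p, P = P, tmax = tmax, caches = caches, n_pool_rows = nrow(A),
       C_last = C)
}

# Backward pass for mean binary cross-entropy. Returns gradients with the
# same structure as params.
.cnn_backward <- function(params, fwd, y, N, L) {
  dlogit <- matrix((fwd$p - y) / N, ncol = 1)
  g <- list(conv = vector("list", length(params$conv)), dense = NULL)
  g$dense <- list(W = crossprod(fwd$P, dlogit), b = sum(dlogit))
  dP <- dlogit %*% t(params$dense$W)          # N x C_last
  # scatter pooled gradient back to the argmax positions
  C <- fwd$C_last
  dA <- matrix(0, fwd$n_pool_rows, C)
  li <- (fwd$tmax - 1) * N + seq_len(N) +
    (rep(seq_len(C) - 1L, each = N)) * fwd$n_pool_rows
  dA[li] <- dP
  for (i in rev(seq_along(params$conv))) {
    cache <- fwd$caches[[i]]
    dZ <- dA * cache$relu
    g$conv[[i]] <- list(W = crossprod(cache$Xc, dZ), b = colSums(dZ))
    if (i > 1L) {
      dXc <- dZ %*% t(params$conv[[i]]$W)
      Cin <- ncol(dXc) / 3L
      dA <- dXc[, (Cin + 1):(2 * Cin), drop = FALSE] +
        .shift_up(dXc[, seq_len(Cin), drop = FALSE], N) +
        .shift_down(dXc[, (2 * Cin + 1):(3 * Cin), drop = FALSE], N)
    }
  }
  g
}

.adam_state <- function(params) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(m = rapply(params, function(x) x * 0, how = "replace"),
       v = rapply(params, function(x) x * 0, how = "replace"),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  walk <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^state$t)
    vhat <- v / (1 - beta2^state$t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  for (i in seq_along(params$conv)) {
    for (nm in c("W", "b")) {
      u <- walk(params$conv[[i]][[nm]], grads$conv[[i]][[nm]],
                state$m$conv[[i]][[nm]], state$v$conv[[i]][[nm]])
      params$conv[[i]][[nm]] <- u$p
      state$m$conv[[i]][[nm]] <- u$m
      state$v$conv[[i]][[nm]] <- u$v
    }
  }
  for (nm in c("W", "b")) {
    u <- walk(params$dense[[nm]], grads$dense[[nm]],
              state$m$dense[[nm]], state$v$dense[[nm]])
    params$dense[[nm]] <- u$p
    state$m$dense[[nm]] <- u$m
    state$v$dense[[nm]] <- u$v
  }
  list(params = params, state = state)
}

.bce_loss <- function(p, y, eps = 1e-12) {
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}
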