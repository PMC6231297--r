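# CNN layer primitives.
#
# Internal representation: a batch of feature maps is a dense matrix of
# shape (H*W*B) x C — spatial index fastest (column-major within each
# sample), then sample, with one column per channel. The memory-bound
# im2col/col2im and pooling kernels live in src/kernels.cpp; matrix
# products go through BLAS. All layers return a `cache` for
# backpropagation.

# ---- convolution: kernel k x k, same-padding (k odd), stride 1 ----
#
# im2col layout (built in C++): Cols is (H*W*B) x (Cin*k*k), channel
# fastest within each kernel-offset block, offsets ordered row-offset
# fastest. The reshaped weight matrix aperm(weights, c(3,1,2,4)) matches
# that order, so the convolution is one BLAS product Cols %*% Wmat.

conv_weight_matrix <- function(weights) {
  k <- dim(weights)[1]; Cin <- dim(weights)[3]; Cout <- dim(weights)[4]
  Wm <- aperm(weights, c(3, 1, 2, 4))
  dim(Wm) <- c(Cin * k * k, Cout)
  Wm
}

conv_forward <- function(A, H, W, B, weights, bias) {
  k <- dim(weights)[1]
  pad <- (k - 1L) %/% 2L
  Cols <- cpp_im2col(A, H, W, B, k, pad)
  Out <- Cols %*% conv_weight_matrix(weights)
  for (cc in seq_along(bias)) Out[, cc] <- Out[, cc] + bias[cc]
  list(out = Out, cache = list(Cols = Cols, H = H, W = W, B = B,
                               k = k, pad = pad, Cin = dim(weights)[3],
                               Cout = dim(weights)[4]))
}

conv_backward <- function(dOut, weights, cache) {
  k <- cache$k; Cin <- cache$Cin
  dWmat <- crossprod(cache$Cols, dOut)          # (Cin*k*k) x Cout
  dim(dWmat) <- c(Cin, k, k, cache$Cout)
  dW <- aperm(dWmat, c(2, 3, 1, 4))
  dCols <- dOut %*% t(conv_weight_matrix(weights))
  dA <- cpp_col2im(dCols, cache$H, cache$W, cache$B, Cin, k, cache$pad)
  list(dA = dA, dW = dW, db = colSums(dOut))
}

# ---- ReLU ----

relu_forward <- function(A) { m <- A > 0; list(out = A * m, cache = m) }
relu_backward <- function(dOut, cache) dOut * cache

# ---- pooling: k x k window, stride s, ceil mode (windows clipped at the
#      border; averages divide by the clipped window size) ----

pool_out_size <- function(H, k = 3L, s = 2L) as.integer(ceiling((H - k) / s) + 1L)

pool_forward <- function(A, H, W, B, type = c("max", "avg"), k = 3L, s = 2L) {
  type <- match.arg(type)
  if (type == "max") {
    r <- cpp_pool_max_forward(A, H, W, B, k, s)
    list(out = r$out, cache = list(type = type, argmax = r$argmax,
                                   H = H, W = W, B = B, k = k, s = s))
  } else {
    r <- cpp_pool_avg_forward(A, H, W, B, k, s)
    list(out = r$out, cache = list(type = type, H = H, W = W, B = B,
                                   k = k, s = s))
  }
}

pool_backward <- function(dOut, cache) {
  if (cache$type == "max") {
    cpp_pool_max_backward(dOut, cache$argmax, cache$H, cache$W, cache$B)
  } else {
    cpp_pool_avg_backward(dOut, cache$H, cache$W, cache$B, cache$k, cache$s)
  }
}

# ---- local response normalization across channels ----
# b_c = a_c / (k0 + (alpha/n) * sum_{c' in window(c)} a_{c'}^2)^beta

lrn_channel_window_sum <- function(M, half) {
  C <- ncol(M)
  S <- matrix(0, nrow(M), C)
  for (cc in seq_len(C)) {
    lo <- max(1L, cc - half); hi <- min(C, cc + half)
    S[, cc] <- rowSums(M[, lo:hi, drop = FALSE])
  }
  S
}

lrn_forward <- function(A, n = 3L, alpha = 5e-5, beta = 0.75, k0 = 1) {
  half <- n %/% 2L
  d <- k0 + (alpha / n) * lrn_channel_window_sum(A * A, half)
  list(out = A * d^(-beta),
       cache = list(A = A, d = d, n = n, alpha = alpha, beta = beta, half = half))
}

lrn_backward <- function(dOut, cache) {
  A <- cache$A; d <- cache$d; beta <- cache$beta
  U <- dOut * A * d^(-beta - 1)
  V <- lrn_channel_window_sum(U, cache$half)
  dOut * d^(-beta) - (2 * cache$alpha * beta / cache$n) * A * V
}

# ---- flatten (H*W*B) x C  ->  B x (H*W*C), feature = spatial-major ----

flatten_forward <- function(A, S, B, C) {
  dim(A) <- c(S, B, C)
  A <- aperm(A, c(1, 3, 2))
  dim(A) <- c(S * C, B)
  t(A)
}

flatten_backward <- function(dF, S, B, C) {
  dA <- t(dF)
  dim(dA) <- c(S, C, B)
  dA <- aperm(dA, c(1, 3, 2))
  dim(dA) <- c(S * B, C)
  dA
}

# ---- fully connected + softmax cross-entropy ----

fc_forward <- function(Fmat, W, b) {
  list(out = sweep(Fmat %*% W, 2, b, "+"), cache = Fmat)
}

fc_backward <- function(dOut, W, cache) {
  list(dF = dOut %*% t(W), dW = crossprod(cache, dOut), db = colSums(dOut))
}

softmax_probs <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# labels01: vector in {0,1}; column 1 = class 0, column 2 = class 1
softmax_xent <- function(logits, labels01) {
  B <- nrow(logits)
  P <- softmax_probs(logits)
  Y <- cbind(1 - labels01, labels01)
  eps <- 1e-12
  loss <- -mean(log(pmax(rowSums(P * Y), eps)))
  list(loss = loss, probs = P, dLogits = (P - Y) / B)
}
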