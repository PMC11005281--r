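# Internal convolutional-network primitives.
#
# Tensors are (C, H, W, N) double arrays; convolutions are computed as one
# BLAS matmul per kernel offset, which keeps a desk-scale model trainable on
# a single CPU without any compiled code. All layers expose a forward pass
# returning (out, cache) and a backward pass returning (dx, dW, db).

conv_fwd <- function(x, layer, stride = 1L, pad = NULL) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  k <- dim(layer$W)[3]; O <- dim(layer$W)[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  if (pad > 0) {
    xp <- array(0, c(C, H + 2L * pad, W + 2L * pad, N))
    xp[, pad + seq_len(H), pad + seq_len(W), ] <- x
  } else xp <- x
  M <- Ho * Wo * N
  out <- matrix(layer$b, O, M)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    xs <- xp[, i + stride * (seq_len(Ho) - 1L),
             j + stride * (seq_len(Wo) - 1L), , drop = FALSE]
    dim(xs) <- c(C, M)
    out <- out + matrix(layer$W[, , i, j], O, C) %*% xs
  }
  dim(out) <- c(O, Ho, Wo, N)
  list(out = out,
       cache = list(xp = xp, dims = c(C, H, W, N), k = k, stride = stride,
                    pad = pad, Ho = Ho, Wo = Wo))
}

conv_bwd <- function(dout, layer, cache) {
  cc <- cache; C <- cc$dims[1]; H <- cc$dims[2]; W <- cc$dims[3]; N <- cc$dims[4]
  k <- cc$k; stride <- cc$stride; pad <- cc$pad; Ho <- cc$Ho; Wo <- cc$Wo
  O <- dim(layer$W)[1]; M <- Ho * Wo * N
  dm <- dout; dim(dm) <- c(O, M)
  dW <- array(0, dim(layer$W))
  dxp <- array(0, dim(cc$xp))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    rows <- i + stride * (seq_len(Ho) - 1L)
    cols <- j + stride * (seq_len(Wo) - 1L)
    xs <- cc$xp[, rows, cols, , drop = FALSE]
    dim(xs) <- c(C, M)
    dW[, , i, j] <- dm %*% t(xs)
    dxs <- crossprod(matrix(layer$W[, , i, j], O, C), dm)
    dim(dxs) <- c(C, Ho, Wo, N)
    dxp[, rows, cols, ] <- dxp[, rows, cols, , drop = FALSE] + dxs
  }
  dx <- if (pad > 0)
    dxp[, pad + seq_len(H), pad + seq_len(W), , drop = FALSE] else dxp
  list(dx = dx, dW = dW, db = rowSums(dm))
}

relu_fwd <- function(x) {
  out <- x
  out[out < 0] <- 0
  out
}
relu_bwd <- function(dout, x) dout * (x > 0)

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[, rep(seq_len(d[2]), each = 2L), rep(seq_len(d[3]), each = 2L), ,
    drop = FALSE]
}
upsample2_bwd <- function(dout) {
  d <- dim(dout)
  r1 <- seq(1L, d[2], 2L); r2 <- seq(2L, d[2], 2L)
  c1 <- seq(1L, d[3], 2L); c2 <- seq(2L, d[3], 2L)
  dout[, r1, c1, , drop = FALSE] + dout[, r2, c1, , drop = FALSE] +
    dout[, r1, c2, , drop = FALSE] + dout[, r2, c2, , drop = FALSE]
}

gap_fwd <- function(x) {
  d <- dim(x)
  m <- x; dim(m) <- c(d[1], d[2] * d[3], d[4])
  apply(m, c(1, 3), mean)
}
gap_bwd <- function(dout, dims) {
  C <- dims[1]; H <- dims[2]; W <- dims[3]; N <- dims[4]
  aperm(array(dout / (H * W), c(C, N, H, W)), c(1, 3, 4, 2))
}

dense_fwd <- function(x, layer) layer$W %*% x + layer$b
dense_bwd <- function(dout, layer, x) {
  list(dx = crossprod(layer$W, dout), dW = dout %*% t(x), db = rowSums(dout))
}

he_conv <- function(O, C, k) {
  list(W = array(stats::rnorm(O * C * k * k, 0, sqrt(2 / (C * k * k))),
                 c(O, C, k, k)),
       b = rep(0, O))
}
he_dense <- function(O, C) {
  list(W = matrix(stats::rnorm(O * C, 0, sqrt(2 / C)), O, C), b = rep(0, O))
}

adam_init <- function(params) {
  zero_like <- function(p) lapply(p, function(a)
    if (is.null(dim(a))) numeric(length(a)) else array(0, dim(a)))
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) for (f in names(params[[nm]])) {
    g <- grads[[nm]][[f]]
    state$m[[nm]][[f]] <- beta1 * state$m[[nm]][[f]] + (1 - beta1) * g
    state$v[[nm]][[f]] <- beta2 * state$v[[nm]][[f]] + (1 - beta2) * g^2
    params[[nm]][[f]] <- params[[nm]][[f]] -
      lr * (state$m[[nm]][[f]] / bc1) /
      (sqrt(state$v[[nm]][[f]] / bc2) + eps)
  }
  list(params = params, state = state)
}

n_params <- function(params)
  sum(vapply(params, function(p) sum(vapply(p, length, 1L)), 1))
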