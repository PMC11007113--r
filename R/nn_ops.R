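# Low-level differentiable operations. Tensor layout is (C, H, W, N),
# channels fastest, so a convolution is one BLAS matmul on im2col patches.
# Every *F() returns list(y, cache); every *B() consumes (dout, cache) and
# returns dx plus parameter gradients. Weights for (possibly grouped) convs
# and linears are 3-D arrays (outPerGroup, inPerGroup * kh * kw, groups).

# Slice group g of a (out, in, groups) weight array without dim dropping.
wSlice <- function(W, g) {
  m <- W[, , g, drop = FALSE]
  dim(m) <- dim(W)[1:2]
  m
}

initConvW <- function(cin, cout, kh, kw, groups = 1L) {
  fanin <- (cin %/% groups) * kh * kw
  array(rnorm(cout * fanin, sd = sqrt(2 / fanin)),
        dim = c(cout %/% groups, fanin, groups))
}

initLinearW <- function(fin, fout, groups = 1L) {
  array(rnorm(fout * (fin %/% groups), sd = sqrt(2 / fin)),
        dim = c(fout %/% groups, fin %/% groups, groups))
}

convF <- function(x, W, b = NULL, stride = 1L, pad = 0L) {
  d <- dim(x)
  G <- dim(W)[3L]
  kwh <- dim(W)[2L] %/% (d[1L] %/% G)   # kh * kw
  kh <- as.integer(round(sqrt(kwh)))    # square kernels only
  kw <- kwh %/% kh
  Ho <- (d[2L] + 2L * pad - kh) %/% stride + 1L
  Wo <- (d[3L] + 2L * pad - kw) %/% stride + 1L
  cinG <- d[1L] %/% G
  coutG <- dim(W)[1L]
  y <- array(0, dim = c(coutG * G, Ho, Wo, d[4L]))
  cols <- vector("list", G)
  for (g in seq_len(G)) {
    xg <- if (G == 1L) x else x[((g - 1L) * cinG + 1L):(g * cinG), , , ,
                                drop = FALSE]
    cols[[g]] <- im2col_cpp(xg, cinG, d[2L], d[3L], d[4L],
                            kh, kw, stride, pad)
    ym <- wSlice(W, g) %*% cols[[g]]
    if (!is.null(b)) ym <- ym + b[((g - 1L) * coutG + 1L):(g * coutG)]
    y[((g - 1L) * coutG + 1L):(g * coutG), , , ] <- ym
  }
  list(y = y,
       cache = list(cols = cols, dimIn = d, W = W, kh = kh, kw = kw,
                    stride = stride, pad = pad, hasBias = !is.null(b)))
}

convB <- function(dout, cache) {
  d <- cache$dimIn
  G <- dim(cache$W)[3L]
  cinG <- d[1L] %/% G
  coutG <- dim(cache$W)[1L]
  dW <- array(0, dim = dim(cache$W))
  db <- if (cache$hasBias) numeric(coutG * G) else NULL
  dx <- array(0, dim = d)
  for (g in seq_len(G)) {
    rows <- ((g - 1L) * coutG + 1L):(g * coutG)
    dm <- matrix(dout[rows, , , ], nrow = coutG)
    dW[, , g] <- dm %*% t(cache$cols[[g]])
    if (cache$hasBias) db[rows] <- rowSums(dm)
    dcols <- crossprod(wSlice(cache$W, g), dm)
    dxg <- col2im_cpp(dcols, cinG, d[2L], d[3L], d[4L],
                      cache$kh, cache$kw, cache$stride, cache$pad)
    dx[((g - 1L) * cinG + 1L):(g * cinG), , , ] <- dxg
  }
  list(dx = dx, dW = dW, db = db)
}

# Batch norm over channels; x may be a (C,H,W,N) array or a (C,N) matrix.
bnF <- function(x, gamma, beta, rmean, rvar, training, momentum = 0.1,
                eps = 1e-5) {
  d <- dim(x)
  C <- d[1L]
  xm <- matrix(x, nrow = C)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    newR <- list(rmean = (1 - momentum) * rmean + momentum * mu,
                 rvar = (1 - momentum) * rvar + momentum * v)
  } else {
    mu <- rmean; v <- rvar; newR <- NULL
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * invstd
  y <- gamma * xhat + beta
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                           dims = d, training = training),
       newR = newR)
}

bnB <- function(dout, cache) {
  d <- cache$dims
  dm <- matrix(dout, nrow = d[1L])
  xhat <- cache$xhat
  dgamma <- rowSums(dm * xhat)
  dbeta <- rowSums(dm)
  dxhat <- dm * cache$gamma
  M <- ncol(dm)
  if (cache$training) {
    dx <- (cache$invstd / M) *
      (M * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  } else {
    dx <- dxhat * cache$invstd
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

reluF <- function(x) {
  y <- x
  y[y < 0] <- 0
  list(y = y, cache = x >= 0)
}

reluB <- function(dout, cache) {
  dx <- dout
  dx[!cache] <- 0
  dx
}

maxpoolF <- function(x, k = 2L, stride = k) {
  d <- dim(x)
  r <- maxpool_cpp(x, d[1L], d[2L], d[3L], d[4L], k, k, stride)
  list(y = r$y, cache = list(argmax = r$argmax, dimIn = d))
}

maxpoolB <- function(dout, cache) {
  dx <- numeric(prod(cache$dimIn))
  agg <- rowsum(as.numeric(dout), group = cache$argmax)
  dx[as.integer(rownames(agg))] <- agg
  dim(dx) <- cache$dimIn
  dx
}

# Global average pooling (C,H,W,N) -> (C,N); view x as (C, H*W, N) and
# average over the middle dim.
gapF <- function(x) {
  d <- dim(x)
  M <- d[2L] * d[3L]
  x3 <- x
  dim(x3) <- c(d[1L], M, d[4L])
  y <- vapply(seq_len(d[4L]), function(n) rowMeans(x3[, , n, drop = FALSE]),
              numeric(d[1L]))
  y <- matrix(y, nrow = d[1L])
  list(y = y, cache = d)
}

gapB <- function(dout, cache) {
  d <- cache
  M <- d[2L] * d[3L]
  dx <- array(0, dim = d)
  for (n in seq_len(d[4L])) {
    dx[, , , n] <- array(rep(dout[, n] / M, times = M), dim = d[1:3])
  }
  dx
}

linF <- function(x, W, b = NULL, groups = 1L) {
  G <- dim(W)[3L]
  finG <- dim(W)[2L]
  foutG <- dim(W)[1L]
  y <- matrix(0, nrow = foutG * G, ncol = ncol(x))
  for (g in seq_len(G)) {
    xg <- x[((g - 1L) * finG + 1L):(g * finG), , drop = FALSE]
    ym <- wSlice(W, g) %*% xg
    if (!is.null(b)) ym <- ym + b[((g - 1L) * foutG + 1L):(g * foutG)]
    y[((g - 1L) * foutG + 1L):(g * foutG), ] <- ym
  }
  list(y = y, cache = list(x = x, W = W, hasBias = !is.null(b)))
}

linB <- function(dout, cache) {
  W <- cache$W
  G <- dim(W)[3L]
  finG <- dim(W)[2L]
  foutG <- dim(W)[1L]
  dW <- array(0, dim = dim(W))
  db <- if (cache$hasBias) numeric(foutG * G) else NULL
  dx <- matrix(0, nrow = finG * G, ncol = ncol(dout))
  for (g in seq_len(G)) {
    rows <- ((g - 1L) * foutG + 1L):(g * foutG)
    xrows <- ((g - 1L) * finG + 1L):(g * finG)
    dm <- dout[rows, , drop = FALSE]
    dW[, , g] <- dm %*% t(cache$x[xrows, , drop = FALSE])
    if (cache$hasBias) db[rows] <- rowSums(dm)
    dx[xrows, ] <- crossprod(wSlice(W, g), dm)
  }
  list(dx = dx, dW = dW, db = db)
}

# Softmax cross-entropy; logits (C,N), target 1-based integer labels.
softmaxXent <- function(logits, target) {
  z <- sweep(logits, 2L, apply(logits, 2L, max))
  ez <- exp(z)
  p <- sweep(ez, 2L, colSums(ez), "/")
  n <- ncol(logits)
  idx <- cbind(target, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = p)
}

# r-softmax: normalize attention logits across the radix dimension for every
# channel (degenerates to a sigmoid gate at radix 1). z is (C*R, N) with R
# contiguous blocks of C channels.
rSoftmaxF <- function(z, C, R) {
  if (R == 1L) {
    a <- 1 / (1 + exp(-z))
    return(list(y = a, cache = list(a = a, C = C, R = R)))
  }
  arr <- array(z, dim = c(C, R, ncol(z)))
  mx <- apply(arr, c(1L, 3L), max)
  ea <- array(0, dim = dim(arr))
  for (r in seq_len(R)) ea[, r, ] <- exp(arr[, r, ] - mx)
  tot <- apply(ea, c(1L, 3L), sum)
  a <- array(0, dim = dim(arr))
  for (r in seq_len(R)) a[, r, ] <- ea[, r, ] / tot
  y <- matrix(a, nrow = C * R)
  list(y = y, cache = list(a = a, C = C, R = R))
}

rSoftmaxB <- function(dout, cache) {
  C <- cache$C; R <- cache$R
  if (R == 1L) {
    a <- cache$a
    return(dout * a * (1 - a))
  }
  a <- cache$a
  darr <- array(dout, dim = dim(a))
  dot <- array(0, dim = c(C, dim(a)[3L]))
  for (r in seq_len(R)) dot <- dot + darr[, r, ] * a[, r, ]
  dz <- array(0, dim = dim(a))
  for (r in seq_len(R)) dz[, r, ] <- a[, r, ] * (darr[, r, ] - dot)
  matrix(dz, nrow = C * R)
}

# ---- Adam optimizer over a flat named list of numeric arrays ----

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

addGrad <- function(grads, name, g) {
  if (is.null(grads[[name]])) grads[[name]] <- g
  else grads[[name]] <- grads[[name]] + g
  grads
}
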