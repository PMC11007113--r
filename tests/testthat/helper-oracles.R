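# Independent naive oracles: everything here is computed with explicit
# scalar loops and direct formulas, never through the package's vectorized
# layer code.

# Naive 2-D convolution on one sample. x (Cin,H,W); W in the package layout
# (coutPerG, cinPerG*kh*kw, G) with rows ordered (ci fastest, then dh, then
# dw).
naiveConv <- function(x, W, b = NULL, stride = 1L, pad = 0L, kh = NULL) {
  G <- dim(W)[3]
  Cin <- dim(x)[1]
  cinG <- Cin %/% G
  coutG <- dim(W)[1]
  if (is.null(kh)) kh <- as.integer(round(sqrt(dim(W)[2] %/% cinG)))
  kw <- dim(W)[2] %/% (cinG * kh)
  H <- dim(x)[2]; Wd <- dim(x)[3]
  xp <- array(0, dim = c(Cin, H + 2 * pad, Wd + 2 * pad))
  xp[, pad + seq_len(H), pad + seq_len(Wd)] <- x
  Ho <- (H + 2 * pad - kh) %/% stride + 1L
  Wo <- (Wd + 2 * pad - kw) %/% stride + 1L
  y <- array(0, dim = c(coutG * G, Ho, Wo))
  for (g in seq_len(G)) {
    for (co in seq_len(coutG)) {
      for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
        acc <- if (is.null(b)) 0 else b[(g - 1) * coutG + co]
        for (ci in seq_len(cinG)) for (dh in seq_len(kh)) for (dw in seq_len(kw)) {
          row <- ci + cinG * ((dh - 1) + kh * (dw - 1))
          acc <- acc + W[co, row, g] *
            xp[(g - 1) * cinG + ci, (ho - 1) * stride + dh,
               (wo - 1) * stride + dw]
        }
        y[(g - 1) * coutG + co, ho, wo] <- acc
      }
    }
  }
  y
}

# Naive batch norm in training mode over a list of per-sample (C,H,W) arrays.
naiveBN <- function(xs, gamma, beta, eps = 1e-5) {
  C <- dim(xs[[1]])[1]
  out <- lapply(xs, function(x) array(0, dim = dim(x)))
  for (c in seq_len(C)) {
    vals <- unlist(lapply(xs, function(x) as.numeric(x[c, , ])))
    mu <- mean(vals)
    v <- mean((vals - mu)^2)
    for (n in seq_along(xs)) {
      out[[n]][c, , ] <- gamma[c] * (xs[[n]][c, , ] - mu) / sqrt(v + eps) +
        beta[c]
    }
  }
  out
}

naiveBNVec <- function(vs, gamma, beta, eps = 1e-5) {
  # vs: list of per-sample numeric vectors (features)
  C <- length(vs[[1]])
  out <- lapply(vs, function(v) numeric(C))
  for (c in seq_len(C)) {
    vals <- vapply(vs, `[`, numeric(1), c)
    mu <- mean(vals)
    v <- mean((vals - mu)^2)
    for (n in seq_along(vs)) {
      out[[n]][c] <- gamma[c] * (vs[[n]][c] - mu) / sqrt(v + eps) + beta[c]
    }
  }
  out
}

naiveGroupedLinear <- function(v, W, b) {
  G <- dim(W)[3]
  finG <- dim(W)[2]; foutG <- dim(W)[1]
  out <- numeric(foutG * G)
  for (g in seq_len(G)) for (o in seq_len(foutG)) {
    acc <- b[(g - 1) * foutG + o]
    for (i in seq_len(finG)) {
      acc <- acc + W[o, i, g] * v[(g - 1) * finG + i]
    }
    out[(g - 1) * foutG + o] <- acc
  }
  out
}

# Naive Split-Attention block (training-mode batch norm), computed per group
# and per radix with explicit loops. xs: list of per-sample (Cin,H,W) arrays.
# params/spec as produced by the package, but every op here is hand-rolled.
naiveSplitAttention <- function(spec, params, xs) {
  P <- function(s) params[[paste0(spec$name, ".", s)]]
  C <- spec$width; R <- spec$radix; K <- spec$cardinality
  N <- length(xs)
  r1 <- naiveBN(lapply(xs, naiveConv, W = P("conv1.W")),
                P("bn1.gamma"), P("bn1.beta"))
  r1 <- lapply(r1, function(x) { x[x < 0] <- 0; x })
  r2 <- naiveBN(lapply(r1, naiveConv, W = P("conv2.W"),
                       stride = spec$stride, pad = 1L, kh = 3L),
                P("bn2.gamma"), P("bn2.beta"))
  r2 <- lapply(r2, function(x) { x[x < 0] <- 0; x })
  outs <- vector("list", N)
  # attention logits need batch-normed fc features, so collect per sample
  Usum <- lapply(r2, function(x) {
    u <- array(0, dim = c(C, dim(x)[2], dim(x)[3]))
    for (r in seq_len(R)) u <- u + x[(r - 1) * C + seq_len(C), , , drop = FALSE]
    u
  })
  svec <- lapply(Usum, function(u) {
    vapply(seq_len(C), function(c) mean(u[c, , ]), numeric(1))
  })
  z1 <- lapply(svec, naiveGroupedLinear, W = P("fc1.W"), b = P("fc1.b"))
  z1 <- naiveBNVec(z1, P("bnfc.gamma"), P("bnfc.beta"))
  z1 <- lapply(z1, function(v) pmax(v, 0))
  logit <- lapply(z1, naiveGroupedLinear, W = P("fc2.W"), b = P("fc2.b"))
  for (n in seq_len(N)) {
    a <- numeric(C * R)
    for (c in seq_len(C)) {
      zs <- logit[[n]][c + (seq_len(R) - 1) * C]
      if (R == 1L) {
        a[c] <- 1 / (1 + exp(-zs))
      } else {
        e <- exp(zs - max(zs))
        a[c + (seq_len(R) - 1) * C] <- e / sum(e)
      }
    }
    V <- array(0, dim = dim(Usum[[n]]))
    for (r in seq_len(R)) for (c in seq_len(C)) {
      V[c, , ] <- V[c, , ] + a[(r - 1) * C + c] *
        r2[[n]][(r - 1) * C + c, , ]
    }
    outs[[n]] <- V
  }
  o3 <- naiveBN(lapply(outs, naiveConv, W = P("conv3.W")),
                P("bn3.gamma"), P("bn3.beta"))
  sc <- if (spec$hasSC) {
    naiveBN(lapply(xs, naiveConv, W = P("sc.W"), stride = spec$stride),
            P("bnsc.gamma"), P("bnsc.beta"))
  } else xs
  lapply(seq_len(N), function(n) {
    y <- o3[[n]] + sc[[n]]
    y[y < 0] <- 0
    y
  })
}

# Independent squeeze-excitation block with a sigmoid channel gate; the
# radix-1 Split-Attention block must reduce to this.
naiveSEBlock <- function(spec, params, xs) {
  stopifnot(spec$radix == 1L)
  P <- function(s) params[[paste0(spec$name, ".", s)]]
  C <- spec$width
  r1 <- naiveBN(lapply(xs, naiveConv, W = P("conv1.W")),
                P("bn1.gamma"), P("bn1.beta"))
  r1 <- lapply(r1, function(x) pmax(x, 0))
  U <- naiveBN(lapply(r1, naiveConv, W = P("conv2.W"), stride = spec$stride,
                      pad = 1L, kh = 3L),
               P("bn2.gamma"), P("bn2.beta"))
  U <- lapply(U, function(x) pmax(x, 0))
  s <- lapply(U, function(u) vapply(seq_len(C), function(c) mean(u[c, , ]),
                                    numeric(1)))
  z <- lapply(s, naiveGroupedLinear, W = P("fc1.W"), b = P("fc1.b"))
  z <- naiveBNVec(z, P("bnfc.gamma"), P("bnfc.beta"))
  z <- lapply(z, pmax, 0)
  gate <- lapply(z, function(v) {
    1 / (1 + exp(-naiveGroupedLinear(v, P("fc2.W"), P("fc2.b"))))
  })
  V <- lapply(seq_along(xs), function(n) {
    v <- U[[n]]
    for (c in seq_len(C)) v[c, , ] <- gate[[n]][c] * v[c, , ]
    v
  })
  o3 <- naiveBN(lapply(V, naiveConv, W = P("conv3.W")),
                P("bn3.gamma"), P("bn3.beta"))
  sc <- if (spec$hasSC) {
    naiveBN(lapply(xs, naiveConv, W = P("sc.W"), stride = spec$stride),
            P("bnsc.gamma"), P("bnsc.beta"))
  } else xs
  lapply(seq_along(xs), function(n) pmax(o3[[n]] + sc[[n]], 0))
}

# Run the package's vectorized Split-Attention block on a list of samples.
packageSplitAttention <- function(spec, params, xs) {
  x <- array(0, dim = c(dim(xs[[1]]), length(xs)))
  for (n in seq_along(xs)) x[, , , n] <- xs[[n]]
  y <- DSNetax:::saF(spec, params, x, training = TRUE)$y
  lapply(seq_along(xs), function(n) y[, , , n])
}

makeBlock <- function(cin, width, stride, radix, cardinality, seed,
                      hasSC = NULL) {
  if (is.null(hasSC)) hasSC <- (stride > 1L || cin != width)
  interG <- max(1L, width %/% (cardinality * 4L))
  spec <- list(type = "splitattn", name = "blk", cin = cin, width = width,
               stride = stride, radix = radix, cardinality = cardinality,
               inter = interG * cardinality, hasSC = hasSC)
  params <- DSNetax:::withSeed(seed, {
    p <- DSNetax:::initBlockParams(list(), spec, "splitattn")
    # non-trivial scales/shifts so batch norm is genuinely exercised
    for (nm in names(p)) {
      if (grepl("gamma$", nm)) p[[nm]] <- runif(length(p[[nm]]), 0.5, 1.5)
      if (grepl("beta$", nm)) p[[nm]] <- rnorm(length(p[[nm]]), sd = 0.2)
    }
    p
  })
  list(spec = spec, params = params)
}
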