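# Deep-shallow parallel classifier. A model is its DSNetaxConfig plus a flat
# named list of weight arrays; the layer graph is rebuilt deterministically
# from the config, so checkpoints are just (config, params, labelIndex).

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Construct a classifier configuration
#'
#' Defaults follow the published architecture where stated (four deep stages
#' of 2, 3, 2, 2 Split-Attention blocks; a 3-layer Conv+ReLU shallow branch)
#' and common ResNeSt-style conventions where not (stem 3x3 stride-2 conv +
#' max-pool; cardinality 1, radix 2, reduction 4; fusion by concatenating
#' the two globally pooled branch vectors). \code{stageWidths} defaults to
#' 64,128,256,512 scaled by \code{widthScale} so desk-scale tests can run
#' the identical topology with small widths.
#'
#' @param nClasses number of species labels.
#' @param variant \code{"dsnetax"} (default), \code{"resnest"},
#'   \code{"resnet34"} or \code{"cnn3"}.
#' @param stageBlocks integer(4) deep-stage block counts. Defaults: 2,3,2,2
#'   for Split-Attention variants; 3,4,6,3 for \code{resnet34}.
#' @param widthScale multiplier applied to the reference widths 64,128,256,512.
#' @param stageWidths integer(4) channel widths (overrides widthScale).
#' @param stemWidth stem channels (default first stage width).
#' @param shallowLayers 3, 4 or 5 Conv+ReLU pairs.
#' @param shallowWidth shallow branch channels.
#' @param radix,cardinality,reduction Split-Attention hyperparameters.
#' @param fusion \code{"concat"}, \code{"sum"} or \code{"gated"}.
#' @return a \linkS4class{DSNetaxConfig}.
#' @export
dsnetaxConfig <- function(nClasses,
                          variant = c("dsnetax", "resnest", "resnet34", "cnn3"),
                          stageBlocks = NULL,
                          widthScale = 1,
                          stageWidths = NULL,
                          stemWidth = NULL,
                          shallowLayers = 3L,
                          shallowWidth = NULL,
                          radix = 2L,
                          cardinality = 1L,
                          reduction = 4L,
                          fusion = "concat") {
  variant <- match.arg(variant)
  if (is.null(stageBlocks)) {
    stageBlocks <- if (variant == "resnet34") c(3L, 4L, 6L, 3L) else
      c(2L, 3L, 2L, 2L)
  }
  if (is.null(stageWidths)) {
    stageWidths <- as.integer(round(c(64, 128, 256, 512) * widthScale))
    gran <- radix * cardinality
    stageWidths <- pmax(gran, (stageWidths %/% gran) * gran)
  }
  if (is.null(stemWidth)) stemWidth <- stageWidths[1L]
  if (is.null(shallowWidth)) shallowWidth <- stageWidths[1L]
  new("DSNetaxConfig",
      variant = variant,
      stageBlocks = as.integer(stageBlocks),
      stageWidths = as.integer(stageWidths),
      stemWidth = as.integer(stemWidth),
      shallowLayers = as.integer(shallowLayers),
      shallowWidth = as.integer(shallowWidth),
      radix = as.integer(radix),
      cardinality = as.integer(cardinality),
      reduction = as.integer(reduction),
      nClasses = as.integer(nClasses),
      fusion = fusion)
}

hasDeepBranch <- function(cfg) cfg@variant %in% c("dsnetax", "resnest", "resnet34")
hasShallowBranch <- function(cfg) cfg@variant %in% c("dsnetax", "cnn3")

# ---- layer specs (pure function of the config) ----

buildLayerSpecs <- function(cfg) {
  specs <- list(deep = NULL, shallow = NULL)
  if (hasDeepBranch(cfg)) {
    blockType <- if (cfg@variant == "resnet34") "basicblock" else "splitattn"
    layers <- list(
      list(type = "conv", name = "deep.stem.conv", stride = 2L, pad = 1L,
           cin = 1L, cout = cfg@stemWidth, k = 3L, bias = FALSE, groups = 1L),
      list(type = "bn", name = "deep.stem.bn", C = cfg@stemWidth),
      list(type = "relu"),
      list(type = "maxpool", k = 2L)
    )
    cin <- cfg@stemWidth
    for (i in seq_len(4L)) {
      w <- cfg@stageWidths[i]
      for (j in seq_len(cfg@stageBlocks[i])) {
        stride <- if (j == 1L && i > 1L) 2L else 1L
        name <- sprintf("deep.s%d.b%d", i, j)
        if (blockType == "splitattn") {
          interG <- max(1L, w %/% (cfg@cardinality * cfg@reduction))
          layers[[length(layers) + 1L]] <- list(
            type = "splitattn", name = name, cin = cin, width = w,
            stride = stride, radix = cfg@radix, cardinality = cfg@cardinality,
            inter = interG * cfg@cardinality,
            hasSC = (stride > 1L || cin != w))
        } else {
          layers[[length(layers) + 1L]] <- list(
            type = "basicblock", name = name, cin = cin, width = w,
            stride = stride, hasSC = (stride > 1L || cin != w))
        }
        cin <- w
      }
    }
    layers[[length(layers) + 1L]] <- list(type = "gap")
    specs$deep <- layers
  }
  if (hasShallowBranch(cfg)) {
    layers <- list()
    cin <- 1L
    for (i in seq_len(cfg@shallowLayers)) {
      stride <- if (i <= 2L) 2L else 1L   # at most 4x total downsampling
      layers[[length(layers) + 1L]] <- list(
        type = "conv", name = sprintf("shallow.c%d", i), stride = stride,
        pad = 1L, cin = cin, cout = cfg@shallowWidth, k = 3L, bias = TRUE,
        groups = 1L)
      layers[[length(layers) + 1L]] <- list(type = "relu")
      cin <- cfg@shallowWidth
    }
    layers[[length(layers) + 1L]] <- list(type = "gap")
    specs$shallow <- layers
  }
  specs
}

featureDim <- function(cfg) {
  dD <- if (hasDeepBranch(cfg)) cfg@stageWidths[4L] else 0L
  dS <- if (hasShallowBranch(cfg)) cfg@shallowWidth else 0L
  if (cfg@variant == "dsnetax") {
    switch(cfg@fusion, concat = dD + dS, sum = dD, gated = dD)
  } else {
    max(dD, dS)
  }
}

# ---- parameter initialization ----

initBNParams <- function(params, name, C) {
  params[[paste0(name, ".gamma")]] <- rep(1, C)
  params[[paste0(name, ".beta")]] <- rep(0, C)
  params[[paste0(name, ".rmean")]] <- rep(0, C)
  params[[paste0(name, ".rvar")]] <- rep(1, C)
  params
}

initBlockParams <- function(params, sp, kind) {
  nm <- sp$name
  if (kind == "splitattn") {
    C <- sp$width; R <- sp$radix; K <- sp$cardinality
    params[[paste0(nm, ".conv1.W")]] <- initConvW(sp$cin, C, 1L, 1L)
    params <- initBNParams(params, paste0(nm, ".bn1"), C)
    params[[paste0(nm, ".conv2.W")]] <- initConvW(C, C * R, 3L, 3L,
                                                  groups = K * R)
    params <- initBNParams(params, paste0(nm, ".bn2"), C * R)
    params[[paste0(nm, ".fc1.W")]] <- initLinearW(C, sp$inter, groups = K)
    params[[paste0(nm, ".fc1.b")]] <- rep(0, sp$inter)
    params <- initBNParams(params, paste0(nm, ".bnfc"), sp$inter)
    params[[paste0(nm, ".fc2.W")]] <- initLinearW(sp$inter, C * R, groups = K)
    params[[paste0(nm, ".fc2.b")]] <- rep(0, C * R)
    params[[paste0(nm, ".conv3.W")]] <- initConvW(C, C, 1L, 1L)
    params <- initBNParams(params, paste0(nm, ".bn3"), C)
    if (sp$hasSC) {
      params[[paste0(nm, ".sc.W")]] <- initConvW(sp$cin, C, 1L, 1L)
      params <- initBNParams(params, paste0(nm, ".bnsc"), C)
    }
  } else {
    C <- sp$width
    params[[paste0(nm, ".conv1.W")]] <- initConvW(sp$cin, C, 3L, 3L)
    params <- initBNParams(params, paste0(nm, ".bn1"), C)
    params[[paste0(nm, ".conv2.W")]] <- initConvW(C, C, 3L, 3L)
    params <- initBNParams(params, paste0(nm, ".bn2"), C)
    if (sp$hasSC) {
      params[[paste0(nm, ".sc.W")]] <- initConvW(sp$cin, C, 1L, 1L)
      params <- initBNParams(params, paste0(nm, ".bnsc"), C)
    }
  }
  params
}

#' Build an untrained classifier
#'
#' @param config a \linkS4class{DSNetaxConfig}.
#' @param labelIndex character vector of species names in label-id order.
#' @param embedderFingerprint fingerprint string of the embedding provider
#'   (see \code{\link{embedderFingerprint}}); stored so prediction can refuse
#'   a mismatched provider.
#' @param seed integer seed for weight initialization.
#' @return a \linkS4class{DSNetaxModel}.
#' @export
buildModel <- function(config, labelIndex = NULL, embedderFingerprint = "",
                       seed = 1L) {
  if (is.null(labelIndex)) {
    labelIndex <- sprintf("label%d", seq_len(config@nClasses))
  }
  if (length(labelIndex) != config@nClasses) {
    stop("labelIndex length must equal nClasses")
  }
  specs <- buildLayerSpecs(config)
  params <- withSeed(seed, {
    p <- list()
    for (branch in specs) {
      for (sp in branch %||% list()) {
        if (is.null(sp$type)) next
        if (sp$type == "conv") {
          p[[paste0(sp$name, ".W")]] <- initConvW(sp$cin, sp$cout, sp$k, sp$k,
                                                  groups = sp$groups)
          if (isTRUE(sp$bias)) p[[paste0(sp$name, ".b")]] <- rep(0, sp$cout)
        } else if (sp$type == "bn") {
          p <- initBNParams(p, sp$name, sp$C)
        } else if (sp$type %in% c("splitattn", "basicblock")) {
          p <- initBlockParams(p, sp, sp$type)
        }
      }
    }
    if (config@variant == "dsnetax" && config@fusion == "gated") {
      dD <- config@stageWidths[4L]
      p[["fusion.proj.W"]] <- initLinearW(config@shallowWidth, dD)
      p[["fusion.proj.b"]] <- rep(0, dD)
      p[["fusion.gate.W"]] <- initLinearW(2L * dD, dD)
      p[["fusion.gate.b"]] <- rep(0, dD)
    }
    if (config@variant == "dsnetax" && config@fusion == "sum" &&
        config@stageWidths[4L] != config@shallowWidth) {
      stop("sum fusion requires shallowWidth == final stage width")
    }
    p[["head.W"]] <- initLinearW(featureDim(config), config@nClasses)
    p[["head.b"]] <- rep(0, config@nClasses)
    p
  })
  new("DSNetaxModel", config = config, params = params,
      labelIndex = labelIndex, embedderFingerprint = embedderFingerprint)
}

# ---- Split-Attention block ----

# Broadcast a (C,N) matrix over the spatial dims of a (C,H,W,N) array.
bcastCN <- function(a, dims) {
  array(a[, rep(seq_len(dims[4L]), each = dims[2L] * dims[3L]), drop = FALSE],
        dim = dims)
}

saF <- function(sp, params, x, training) {
  P <- function(s) params[[paste0(sp$name, ".", s)]]
  C <- sp$width; R <- sp$radix
  bnUp <- list()
  c1 <- convF(x, P("conv1.W"))
  b1 <- bnF(c1$y, P("bn1.gamma"), P("bn1.beta"), P("bn1.rmean"),
            P("bn1.rvar"), training)
  if (!is.null(b1$newR)) bnUp[[paste0(sp$name, ".bn1")]] <- b1$newR
  r1 <- reluF(b1$y)
  c2 <- convF(r1$y, P("conv2.W"), stride = sp$stride, pad = 1L)
  b2 <- bnF(c2$y, P("bn2.gamma"), P("bn2.beta"), P("bn2.rmean"),
            P("bn2.rvar"), training)
  if (!is.null(b2$newR)) bnUp[[paste0(sp$name, ".bn2")]] <- b2$newR
  r2 <- reluF(b2$y)
  dims <- dim(r2$y)
  udims <- c(C, dims[2L], dims[3L], dims[4L])
  Usum <- array(0, dim = udims)
  for (r in seq_len(R)) {
    Usum <- Usum + r2$y[((r - 1L) * C + 1L):(r * C), , , , drop = FALSE]
  }
  gp <- gapF(Usum)
  f1 <- linF(gp$y, P("fc1.W"), P("fc1.b"))
  bf <- bnF(f1$y, P("bnfc.gamma"), P("bnfc.beta"), P("bnfc.rmean"),
            P("bnfc.rvar"), training)
  if (!is.null(bf$newR)) bnUp[[paste0(sp$name, ".bnfc")]] <- bf$newR
  rf <- reluF(bf$y)
  f2 <- linF(rf$y, P("fc2.W"), P("fc2.b"))
  at <- rSoftmaxF(f2$y, C, R)
  V <- array(0, dim = udims)
  for (r in seq_len(R)) {
    ar <- at$y[((r - 1L) * C + 1L):(r * C), , drop = FALSE]
    V <- V + bcastCN(ar, udims) *
      r2$y[((r - 1L) * C + 1L):(r * C), , , , drop = FALSE]
  }
  c3 <- convF(V, P("conv3.W"))
  b3 <- bnF(c3$y, P("bn3.gamma"), P("bn3.beta"), P("bn3.rmean"),
            P("bn3.rvar"), training)
  if (!is.null(b3$newR)) bnUp[[paste0(sp$name, ".bn3")]] <- b3$newR
  if (sp$hasSC) {
    sc <- convF(x, P("sc.W"), stride = sp$stride)
    bsc <- bnF(sc$y, P("bnsc.gamma"), P("bnsc.beta"), P("bnsc.rmean"),
               P("bnsc.rvar"), training)
    if (!is.null(bsc$newR)) bnUp[[paste0(sp$name, ".bnsc")]] <- bsc$newR
    scOut <- bsc$y
  } else {
    sc <- NULL; bsc <- NULL
    scOut <- x
  }
  ro <- reluF(b3$y + scOut)
  list(y = ro$y, bnUp = bnUp,
       cache = list(c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2, r2 = r2,
                    Usum = Usum, gp = gp, f1 = f1, bf = bf, rf = rf, f2 = f2,
                    at = at, sc = sc, bsc = bsc, c3 = c3, b3 = b3, ro = ro,
                    udims = udims, r2y = r2$y))
}

saB <- function(sp, params, cache, dout) {
  P <- function(s) params[[paste0(sp$name, ".", s)]]
  C <- sp$width; R <- sp$radix
  g <- list()
  nm <- function(s) paste0(sp$name, ".", s)
  dsum <- reluB(dout, cache$ro$cache)
  bb3 <- bnB(dsum, cache$b3$cache)
  g[[nm("bn3.gamma")]] <- bb3$dgamma
  g[[nm("bn3.beta")]] <- bb3$dbeta
  cb3 <- convB(bb3$dx, cache$c3$cache)
  g[[nm("conv3.W")]] <- cb3$dW
  dV <- cb3$dx
  if (sp$hasSC) {
    bbs <- bnB(dsum, cache$bsc$cache)
    g[[nm("bnsc.gamma")]] <- bbs$dgamma
    g[[nm("bnsc.beta")]] <- bbs$dbeta
    cbs <- convB(bbs$dx, cache$sc$cache)
    g[[nm("sc.W")]] <- cbs$dW
    dxSC <- cbs$dx
  } else {
    dxSC <- dsum
  }
  udims <- cache$udims
  M <- udims[2L] * udims[3L]
  # attention weights gradient: da_r[c,n] = sum_hw dV * U_r
  da <- matrix(0, nrow = C * R, ncol = udims[4L])
  for (r in seq_len(R)) {
    Ur <- cache$r2y[((r - 1L) * C + 1L):(r * C), , , , drop = FALSE]
    pr <- dV * Ur
    dim(pr) <- c(C, M, udims[4L])
    da[((r - 1L) * C + 1L):(r * C), ] <-
      vapply(seq_len(udims[4L]), function(n) rowSums(pr[, , n, drop = FALSE]),
             numeric(C))
  }
  df2 <- rSoftmaxB(da, cache$at$cache)
  lb2 <- linB(df2, cache$f2$cache)
  g[[nm("fc2.W")]] <- lb2$dW
  g[[nm("fc2.b")]] <- lb2$db
  drf <- reluB(lb2$dx, cache$rf$cache)
  bbf <- bnB(drf, cache$bf$cache)
  g[[nm("bnfc.gamma")]] <- bbf$dgamma
  g[[nm("bnfc.beta")]] <- bbf$dbeta
  lb1 <- linB(bbf$dx, cache$f1$cache)
  g[[nm("fc1.W")]] <- lb1$dW
  g[[nm("fc1.b")]] <- lb1$db
  dUsum <- gapB(lb1$dx, cache$gp$cache)
  dr2 <- array(0, dim = dim(cache$r2y))
  for (r in seq_len(R)) {
    ar <- cache$at$y[((r - 1L) * C + 1L):(r * C), , drop = FALSE]
    dr2[((r - 1L) * C + 1L):(r * C), , , ] <-
      bcastCN(ar, udims) * dV + dUsum
  }
  dr2 <- reluB(dr2, cache$r2$cache)
  bb2 <- bnB(dr2, cache$b2$cache)
  g[[nm("bn2.gamma")]] <- bb2$dgamma
  g[[nm("bn2.beta")]] <- bb2$dbeta
  cb2 <- convB(bb2$dx, cache$c2$cache)
  g[[nm("conv2.W")]] <- cb2$dW
  dr1 <- reluB(cb2$dx, cache$r1$cache)
  bb1 <- bnB(dr1, cache$b1$cache)
  g[[nm("bn1.gamma")]] <- bb1$dgamma
  g[[nm("bn1.beta")]] <- bb1$dbeta
  cb1 <- convB(bb1$dx, cache$c1$cache)
  g[[nm("conv1.W")]] <- cb1$dW
  list(dx = cb1$dx + dxSC, grads = g)
}

# ---- plain residual (ResNet-34 style) block ----

bbF <- function(sp, params, x, training) {
  P <- function(s) params[[paste0(sp$name, ".", s)]]
  bnUp <- list()
  c1 <- convF(x, P("conv1.W"), stride = sp$stride, pad = 1L)
  b1 <- bnF(c1$y, P("bn1.gamma"), P("bn1.beta"), P("bn1.rmean"),
            P("bn1.rvar"), training)
  if (!is.null(b1$newR)) bnUp[[paste0(sp$name, ".bn1")]] <- b1$newR
  r1 <- reluF(b1$y)
  c2 <- convF(r1$y, P("conv2.W"), stride = 1L, pad = 1L)
  b2 <- bnF(c2$y, P("bn2.gamma"), P("bn2.beta"), P("bn2.rmean"),
            P("bn2.rvar"), training)
  if (!is.null(b2$newR)) bnUp[[paste0(sp$name, ".bn2")]] <- b2$newR
  if (sp$hasSC) {
    sc <- convF(x, P("sc.W"), stride = sp$stride)
    bsc <- bnF(sc$y, P("bnsc.gamma"), P("bnsc.beta"), P("bnsc.rmean"),
               P("bnsc.rvar"), training)
    if (!is.null(bsc$newR)) bnUp[[paste0(sp$name, ".bnsc")]] <- bsc$newR
    scOut <- bsc$y
  } else {
    sc <- NULL; bsc <- NULL; scOut <- x
  }
  ro <- reluF(b2$y + scOut)
  list(y = ro$y, bnUp = bnUp,
       cache = list(c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2, sc = sc,
                    bsc = bsc, ro = ro))
}

bbB <- function(sp, params, cache, dout) {
  g <- list()
  nm <- function(s) paste0(sp$name, ".", s)
  dsum <- reluB(dout, cache$ro$cache)
  bb2 <- bnB(dsum, cache$b2$cache)
  g[[nm("bn2.gamma")]] <- bb2$dgamma
  g[[nm("bn2.beta")]] <- bb2$dbeta
  cb2 <- convB(bb2$dx, cache$c2$cache)
  g[[nm("conv2.W")]] <- cb2$dW
  dr1 <- reluB(cb2$dx, cache$r1$cache)
  bb1 <- bnB(dr1, cache$b1$cache)
  g[[nm("bn1.gamma")]] <- bb1$dgamma
  g[[nm("bn1.beta")]] <- bb1$dbeta
  cb1 <- convB(bb1$dx, cache$c1$cache)
  g[[nm("conv1.W")]] <- cb1$dW
  if (sp$hasSC) {
    bbs <- bnB(dsum, cache$bsc$cache)
    g[[nm("bnsc.gamma")]] <- bbs$dgamma
    g[[nm("bnsc.beta")]] <- bbs$dbeta
    cbs <- convB(bbs$dx, cache$sc$cache)
    g[[nm("sc.W")]] <- cbs$dW
    dxSC <- cbs$dx
  } else {
    dxSC <- dsum
  }
  list(dx = cb1$dx + dxSC, grads = g)
}

# ---- branch execution ----

branchF <- function(layers, params, x, training) {
  caches <- vector("list", length(layers))
  bnUp <- list()
  for (i in seq_along(layers)) {
    sp <- layers[[i]]
    r <- switch(sp$type,
      conv = convF(x, params[[paste0(sp$name, ".W")]],
                   b = params[[paste0(sp$name, ".b")]],
                   stride = sp$stride, pad = sp$pad),
      bn = {
        o <- bnF(x, params[[paste0(sp$name, ".gamma")]],
                 params[[paste0(sp$name, ".beta")]],
                 params[[paste0(sp$name, ".rmean")]],
                 params[[paste0(sp$name, ".rvar")]], training)
        if (!is.null(o$newR)) bnUp[[sp$name]] <- o$newR
        o
      },
      relu = reluF(x),
      maxpool = maxpoolF(x, k = sp$k),
      gap = gapF(x),
      splitattn = {
        o <- saF(sp, params, x, training)
        bnUp <- c(bnUp, o$bnUp)
        o
      },
      basicblock = {
        o <- bbF(sp, params, x, training)
        bnUp <- c(bnUp, o$bnUp)
        o
      },
      stop("unknown layer type ", sp$type))
    caches[[i]] <- r$cache
    x <- r$y
  }
  list(y = x, caches = caches, bnUp = bnUp)
}

branchB <- function(layers, params, caches, dout) {
  grads <- list()
  for (i in rev(seq_along(layers))) {
    sp <- layers[[i]]
    if (sp$type == "conv") {
      r <- convB(dout, caches[[i]])
      grads[[paste0(sp$name, ".W")]] <- r$dW
      if (!is.null(r$db)) grads[[paste0(sp$name, ".b")]] <- r$db
      dout <- r$dx
    } else if (sp$type == "bn") {
      r <- bnB(dout, caches[[i]])
      grads[[paste0(sp$name, ".gamma")]] <- r$dgamma
      grads[[paste0(sp$name, ".beta")]] <- r$dbeta
      dout <- r$dx
    } else if (sp$type == "relu") {
      dout <- reluB(dout, caches[[i]])
    } else if (sp$type == "maxpool") {
      dout <- maxpoolB(dout, caches[[i]])
    } else if (sp$type == "gap") {
      dout <- gapB(dout, caches[[i]])
    } else if (sp$type == "splitattn") {
      r <- saB(sp, params, caches[[i]], dout)
      grads[names(r$grads)] <- r$grads
      dout <- r$dx
    } else if (sp$type == "basicblock") {
      r <- bbB(sp, params, caches[[i]], dout)
      grads[names(r$grads)] <- r$grads
      dout <- r$dx
    }
  }
  list(dx = dout, grads = grads)
}

# ---- whole-model forward/backward ----

# x: array (1, L', d, N) of stacked embedding matrices.
modelForward <- function(model, x, training = FALSE) {
  cfg <- model@config
  specs <- buildLayerSpecs(cfg)
  params <- model@params
  bnUp <- list()
  gd <- NULL; gs <- NULL; dCache <- NULL; sCache <- NULL
  if (hasDeepBranch(cfg)) {
    r <- branchF(specs$deep, params, x, training)
    gd <- r$y; dCache <- r$caches; bnUp <- c(bnUp, r$bnUp)
  }
  if (hasShallowBranch(cfg)) {
    r <- branchF(specs$shallow, params, x, training)
    gs <- r$y; sCache <- r$caches; bnUp <- c(bnUp, r$bnUp)
  }
  fCache <- NULL
  if (cfg@variant == "dsnetax") {
    if (cfg@fusion == "concat") {
      f <- rbind(gd, gs)
    } else if (cfg@fusion == "sum") {
      f <- gd + gs
    } else {
      pj <- linF(gs, params[["fusion.proj.W"]], params[["fusion.proj.b"]])
      gt <- linF(rbind(gd, pj$y), params[["fusion.gate.W"]],
                 params[["fusion.gate.b"]])
      a <- sigmoid(gt$y)
      f <- a * gd + (1 - a) * pj$y
      fCache <- list(pj = pj, gt = gt, a = a, gd = gd)
    }
  } else {
    f <- if (hasDeepBranch(cfg)) gd else gs
  }
  hd <- linF(f, params[["head.W"]], params[["head.b"]])
  list(logits = hd$y,
       caches = list(deep = dCache, shallow = sCache, fusion = fCache,
                     head = hd$cache, gdim = nrow(gd %||% gs)),
       bnUp = bnUp)
}

modelBackward <- function(model, fw, dlogits) {
  cfg <- model@config
  specs <- buildLayerSpecs(cfg)
  params <- model@params
  grads <- list()
  hb <- linB(dlogits, fw$caches$head)
  grads[["head.W"]] <- hb$dW
  grads[["head.b"]] <- hb$db
  df <- hb$dx
  dgd <- NULL; dgs <- NULL
  if (cfg@variant == "dsnetax") {
    if (cfg@fusion == "concat") {
      nD <- fw$caches$gdim
      dgd <- df[seq_len(nD), , drop = FALSE]
      dgs <- df[-seq_len(nD), , drop = FALSE]
    } else if (cfg@fusion == "sum") {
      dgd <- df; dgs <- df
    } else {
      fc <- fw$caches$fusion
      a <- fc$a
      dgd <- df * a
      dpj <- df * (1 - a)
      dA <- df * (fc$gd - fc$pj$y) * a * (1 - a)
      gb <- linB(dA, fc$gt$cache)
      grads[["fusion.gate.W"]] <- gb$dW
      grads[["fusion.gate.b"]] <- gb$db
      nD <- fw$caches$gdim
      dgd <- dgd + gb$dx[seq_len(nD), , drop = FALSE]
      dpj <- dpj + gb$dx[-seq_len(nD), , drop = FALSE]
      pb <- linB(dpj, fc$pj$cache)
      grads[["fusion.proj.W"]] <- pb$dW
      grads[["fusion.proj.b"]] <- pb$db
      dgs <- pb$dx
    }
  } else if (hasDeepBranch(cfg)) {
    dgd <- df
  } else {
    dgs <- df
  }
  if (!is.null(dgd)) {
    r <- branchB(specs$deep, params, fw$caches$deep, dgd)
    grads[names(r$grads)] <- r$grads
  }
  if (!is.null(dgs)) {
    r <- branchB(specs$shallow, params, fw$caches$shallow, dgs)
    grads[names(r$grads)] <- r$grads
  }
  grads
}

# Stack a list of equal-shape (L' x d) embedding matrices into (1, L', d, N).
embedBatch <- function(embs) {
  L <- nrow(embs[[1L]]); d <- ncol(embs[[1L]])
  x <- array(0, dim = c(1L, L, d, length(embs)))
  for (n in seq_along(embs)) x[1L, , , n] <- embs[[n]]
  x
}

#' Run the deep (Split-Attention) branch on an embedding matrix
#'
#' @param model a \linkS4class{DSNetaxModel} whose variant has a deep branch.
#' @param emb an (L' x d) embedding matrix, or a list of equal-shape
#'   matrices for a batch.
#' @param training use batch statistics in batch norm (default FALSE).
#' @return pooled feature matrix (channels x batch).
#' @export
deepForward <- function(model, emb, training = FALSE) {
  if (!hasDeepBranch(model@config)) stop("variant has no deep branch")
  if (is.matrix(emb)) emb <- list(emb)
  specs <- buildLayerSpecs(model@config)
  branchF(specs$deep, model@params, embedBatch(emb), training)$y
}

#' Run the shallow (Conv+ReLU) branch on an embedding matrix
#' @inheritParams deepForward
#' @return pooled feature matrix (channels x batch).
#' @export
shallowForward <- function(model, emb, training = FALSE) {
  if (!hasShallowBranch(model@config)) stop("variant has no shallow branch")
  if (is.matrix(emb)) emb <- list(emb)
  specs <- buildLayerSpecs(model@config)
  branchF(specs$shallow, model@params, embedBatch(emb), training)$y
}

#' Fuse pooled branch features and classify
#'
#' @param model a \linkS4class{DSNetaxModel}.
#' @param g deep-branch feature matrix (channels x batch), or NULL for
#'   shallow-only variants.
#' @param l shallow-branch feature matrix, or NULL for deep-only variants.
#' @return logits matrix (nClasses x batch).
#' @export
fuseClassify <- function(model, g, l = NULL) {
  cfg <- model@config
  params <- model@params
  f <- if (cfg@variant == "dsnetax") {
    if (is.null(g) || is.null(l)) stop("dsnetax fusion needs both branches")
    switch(cfg@fusion,
      concat = rbind(g, l),
      sum = g + l,
      gated = {
        pj <- linF(l, params[["fusion.proj.W"]], params[["fusion.proj.b"]])$y
        a <- sigmoid(linF(rbind(g, pj), params[["fusion.gate.W"]],
                          params[["fusion.gate.b"]])$y)
        a * g + (1 - a) * pj
      })
  } else if (hasDeepBranch(cfg)) g else l
  if (nrow(f) != dim(params[["head.W"]])[2L]) {
    stop("feature dimension does not match the classifier head")
  }
  linF(f, params[["head.W"]], params[["head.b"]])$y
}

#' Top-k label prediction from logits
#'
#' Returns the 0-based label ids of the \code{ktop} largest logits in
#' descending order; ties are broken by ascending label id so predictions
#' are deterministic.
#'
#' @param z numeric vector of logits (length nClasses).
#' @param ktop number of labels to return (1..nClasses).
#' @return integer vector of 0-based label ids.
#' @examples
#' predictTopk(c(0.1, 0.9, 0.5), 2)  # 1 2
#' @export
predictTopk <- function(z, ktop) {
  if (ktop < 1L || ktop > length(z)) stop("ktop out of range")
  order(-z, seq_along(z))[seq_len(ktop)] - 1L
}

#' Summarize a model's topology and size
#'
#' @param model a \linkS4class{DSNetaxModel}.
#' @return list with \code{convLayers} (every convolution in the graph,
#'   including those inside blocks), \code{splitAttentionBlocks},
#'   \code{residualBlocks}, \code{shallowConvLayers}, \code{stageBlocks} and
#'   \code{nParameters} (trainable weights; batch-norm running stats
#'   excluded).
#' @export
describeModel <- function(model) {
  specs <- buildLayerSpecs(model@config)
  nConv <- 0L; nSA <- 0L; nBB <- 0L; nShallow <- 0L
  for (branch in c("deep", "shallow")) {
    for (sp in specs[[branch]] %||% list()) {
      t <- sp$type %||% ""
      if (t == "conv") {
        nConv <- nConv + 1L
        if (branch == "shallow") nShallow <- nShallow + 1L
      } else if (t == "splitattn") {
        nSA <- nSA + 1L
        nConv <- nConv + 3L + as.integer(sp$hasSC)
      } else if (t == "basicblock") {
        nBB <- nBB + 1L
        nConv <- nConv + 2L + as.integer(sp$hasSC)
      }
    }
  }
  trainable <- !grepl("\\.(rmean|rvar)$", names(model@params))
  list(convLayers = nConv,
       splitAttentionBlocks = nSA,
       residualBlocks = nBB,
       shallowConvLayers = nShallow,
       stageBlocks = if (hasDeepBranch(model@config))
         model@config@stageBlocks else integer(0),
       nParameters = sum(vapply(model@params[trainable], length, integer(1))))
}
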