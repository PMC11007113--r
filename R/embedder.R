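# Embedding providers. All three map 0-based content token ids to an
# (L' x d) matrix of per-token word vectors; the MLM provider is a small
# BERT-style transformer encoder trained here with the masked-language-model
# objective only (no next-sentence prediction).

#' Deterministic hash-table embedding stub
#'
#' Assigns every vocabulary token an independent Gaussian vector drawn once
#' from the seed: the same k-mer always maps to the same vector and distinct
#' k-mers collide with negligible probability. Used as a fast deterministic
#' provider in tests and desk-scale benchmarks.
#'
#' @param vocab a \linkS4class{KmerVocabulary}.
#' @param dModel embedding width.
#' @param seed integer seed.
#' @return a \code{HashEmbedder}.
#' @export
hashEmbedder <- function(vocab, dModel = 32L, seed = 1L) {
  tab <- withSeed(seed, matrix(rnorm(length(vocab) * dModel, sd = 1),
                               nrow = length(vocab)))
  new("HashEmbedder", vocab = vocab, dModel = as.integer(dModel),
      table = tab, seed = as.integer(seed))
}

#' Embedding provider backed by an imported token-to-vector table
#'
#' Lets users export per-token vectors from any external DNA language model
#' checkpoint and use them here without a framework dependency.
#'
#' @param vocab a \linkS4class{KmerVocabulary}.
#' @param table numeric matrix with one row per vocabulary token (rows in
#'   vocabulary id order) or with rownames naming the tokens.
#' @return a \code{TableEmbedder}.
#' @export
tableEmbedder <- function(vocab, table) {
  if (!is.null(rownames(table))) {
    miss <- setdiff(vocab@tokens, rownames(table))
    if (length(miss)) {
      stop("embedding table is missing tokens: ",
           paste(head(miss, 5L), collapse = ", "))
    }
    table <- table[vocab@tokens, , drop = FALSE]
  }
  if (nrow(table) != length(vocab)) {
    stop("embedding table must have one row per vocabulary token")
  }
  new("TableEmbedder", vocab = vocab, dModel = ncol(table),
      table = unname(as.matrix(table)))
}

#' Read a token-to-vector table from a TSV file
#'
#' First column is the token, remaining columns its vector.
#'
#' @param path TSV path.
#' @param vocab the vocabulary the table must cover.
#' @return a \code{TableEmbedder}.
#' @export
readEmbeddingTable <- function(path, vocab) {
  tab <- read.delim(path, header = FALSE, row.names = 1L,
                    colClasses = c("character"), check.names = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  tableEmbedder(vocab, m)
}

lookupEmbed <- function(provider, ids) {
  if (any(ids < 0L | ids >= length(provider@vocab))) {
    stop("token id outside the provider's vocabulary")
  }
  provider@table[ids + 1L, , drop = FALSE]
}

#' @rdname embedIds
#' @export
setMethod("embedIds", "HashEmbedder", function(provider, ids, ...) {
  lookupEmbed(provider, ids)
})

#' @rdname embedIds
#' @export
setMethod("embedIds", "TableEmbedder", function(provider, ids, ...) {
  lookupEmbed(provider, ids)
})

#' @rdname embedIds
#' @param maxTokens,overlap window controls for sequences longer than the
#'   encoder capacity; see \code{\link{chunkWindows}}.
#' @export
setMethod("embedIds", "MLMEmbedder",
          function(provider, ids, maxTokens = provider@config$maxTokens,
                   overlap = provider@config$overlap, ...) {
  if (any(ids < 0L | ids >= length(provider@vocab))) {
    stop("token id outside the provider's vocabulary")
  }
  windows <- chunkWindows(ids, maxTokens = maxTokens, overlap = overlap)
  embWins <- lapply(windows, function(w) {
    idx <- c(2L, w, 3L) + 1L  # [CLS] ... [SEP], 1-based
    X <- encoderForward(provider@params, provider@config, idx)$X
    X[2L:(nrow(X) - 1L), , drop = FALSE]  # drop special-token rows
  })
  reassembleWindows(embWins, overlap = overlap)
})

#' Embed every record of a dataset
#'
#' Tokenizes, encodes and embeds each sequence with the provider's
#' vocabulary; the row count of each matrix equals the sequence's k-mer
#' token count.
#'
#' @param ds an \linkS4class{AmpliconDataset}.
#' @param provider a \linkS4class{KmerEmbedder}.
#' @return named list of (L' x dModel) matrices, one per record.
#' @export
embedDataset <- function(ds, provider) {
  seqs <- as.character(sequences(ds))
  out <- lapply(seqs, function(s) {
    embedIds(provider, encodeSequence(s, provider@vocab))
  })
  names(out) <- names(ds)
  out
}

# ---- masking ----

#' Sample masked positions for the MLM objective
#'
#' Replaces roughly \code{maskRate} of the content tokens with \code{[MASK]}.
#' With \code{spanLen > 1}, masked positions come in contiguous spans of
#' that length (k contiguous k-mer tokens cover one genomic locus, so span
#' masking stops the model from trivially copying overlapping neighbours).
#' Special tokens are never masked; at least one position is always masked.
#'
#' @param ids encoded id vector (specials allowed; only content ids >= 5 are
#'   maskable).
#' @param maskRate target masked fraction of content tokens.
#' @param spanLen span length per pick (1 = independent single tokens).
#' @return list with \code{ids} (masked input), \code{pos} (masked
#'   positions) and \code{targets} (original ids at those positions).
#' @export
maskTokenIds <- function(ids, maskRate = 0.15, spanLen = 1L) {
  stopifnot(maskRate > 0, maskRate < 1)
  maskable <- which(ids >= 5L)
  if (!length(maskable)) stop("no maskable content tokens")
  target <- max(1L, as.integer(round(maskRate * length(maskable))))
  picked <- integer(0)
  for (s in sample(maskable)) {
    if (length(picked) >= target) break
    span <- intersect(s:min(s + spanLen - 1L, max(maskable)), maskable)
    span <- setdiff(span, picked)
    picked <- c(picked, head(span, target - length(picked)))
  }
  out <- ids
  out[picked] <- 4L  # [MASK]
  list(ids = out, pos = picked, targets = ids[picked])
}

# ---- transformer encoder (per-sequence forward/backward) ----

lnF <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+")
  list(y = y, cache = list(xhat = xhat, inv = inv, g = g))
}

lnB <- function(dy, cache) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2L, cache$g, "*")
  dx <- cache$inv * (dxhat - rowMeans(dxhat) -
                     xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

rowSoftmax <- function(S) {
  e <- exp(S - apply(S, 1L, max))
  e / rowSums(e)
}

encoderForward <- function(params, cfg, idx) {
  T <- length(idx)
  if (T > nrow(params$P)) stop("sequence exceeds the encoder's position table")
  X <- params$E[idx, , drop = FALSE] + params$P[seq_len(T), , drop = FALSE]
  caches <- vector("list", cfg$nLayers)
  d <- cfg$dModel
  H <- cfg$nHeads
  dh <- d %/% H
  for (l in seq_len(cfg$nLayers)) {
    p <- function(s) params[[sprintf("L%d.%s", l, s)]]
    Q <- X %*% p("Wq") + rep(1, T) %o% p("bq")
    K <- X %*% p("Wk") + rep(1, T) %o% p("bk")
    V <- X %*% p("Wv") + rep(1, T) %o% p("bv")
    Cc <- matrix(0, T, d)
    As <- vector("list", H)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) /
        sqrt(dh)
      A <- rowSoftmax(S)
      As[[h]] <- A
      Cc[, cols] <- A %*% V[, cols, drop = FALSE]
    }
    O <- Cc %*% p("Wo") + rep(1, T) %o% p("bo")
    l1 <- lnF(X + O, p("ln1.g"), p("ln1.b"))
    Hf <- l1$y %*% p("W1") + rep(1, T) %o% p("b1")
    Hr <- reluF(Hf)
    Ff <- Hr$y %*% p("W2") + rep(1, T) %o% p("b2")
    l2 <- lnF(l1$y + Ff, p("ln2.g"), p("ln2.b"))
    caches[[l]] <- list(X = X, Q = Q, K = K, V = V, As = As, Cc = Cc,
                        l1 = l1, Xa = l1$y, Hr = Hr, l2 = l2)
    X <- l2$y
  }
  list(X = X, caches = caches, idx = idx)
}

encoderBackward <- function(params, cfg, fw, dX) {
  g <- list()
  d <- cfg$dModel
  H <- cfg$nHeads
  dh <- d %/% H
  for (l in rev(seq_len(cfg$nLayers))) {
    cc <- fw$caches[[l]]
    nm <- function(s) sprintf("L%d.%s", l, s)
    p <- function(s) params[[nm(s)]]
    b2 <- lnB(dX, cc$l2$cache)
    g[[nm("ln2.g")]] <- b2$dg
    g[[nm("ln2.b")]] <- b2$db
    dXa <- b2$dx                         # residual into l1 output
    dFf <- b2$dx
    g[[nm("W2")]] <- crossprod(cc$Hr$y, dFf)
    g[[nm("b2")]] <- colSums(dFf)
    dHr <- dFf %*% t(p("W2"))
    dHf <- reluB(dHr, cc$Hr$cache)
    g[[nm("W1")]] <- crossprod(cc$Xa, dHf)
    g[[nm("b1")]] <- colSums(dHf)
    dXa <- dXa + dHf %*% t(p("W1"))
    b1 <- lnB(dXa, cc$l1$cache)
    g[[nm("ln1.g")]] <- b1$dg
    g[[nm("ln1.b")]] <- b1$db
    dXin <- b1$dx                        # residual into layer input
    dO <- b1$dx
    g[[nm("Wo")]] <- crossprod(cc$Cc, dO)
    g[[nm("bo")]] <- colSums(dO)
    dCc <- dO %*% t(p("Wo"))
    dQ <- matrix(0, nrow(dX), d)
    dK <- matrix(0, nrow(dX), d)
    dV <- matrix(0, nrow(dX), d)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cc$As[[h]]
      dOh <- dCc[, cols, drop = FALSE]
      Vh <- cc$V[, cols, drop = FALSE]
      dA <- tcrossprod(dOh, Vh)
      dV[, cols] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- dS %*% cc$K[, cols, drop = FALSE] / sqrt(dh)
      dK[, cols] <- crossprod(dS, cc$Q[, cols, drop = FALSE]) / sqrt(dh)
    }
    g[[nm("Wq")]] <- crossprod(cc$X, dQ)
    g[[nm("bq")]] <- colSums(dQ)
    g[[nm("Wk")]] <- crossprod(cc$X, dK)
    g[[nm("bk")]] <- colSums(dK)
    g[[nm("Wv")]] <- crossprod(cc$X, dV)
    g[[nm("bv")]] <- colSums(dV)
    dX <- dXin + dQ %*% t(p("Wq")) + dK %*% t(p("Wk")) + dV %*% t(p("Wv"))
  }
  # embedding gradients: scatter-add rows by token index
  dE <- matrix(0, nrow(params$E), ncol(params$E))
  agg <- rowsum(dX, group = fw$idx)
  dE[as.integer(rownames(agg)), ] <- agg
  g[["E"]] <- dE
  dP <- matrix(0, nrow(params$P), ncol(params$P))
  dP[seq_len(nrow(dX)), ] <- dX
  g[["P"]] <- dP
  g
}

initEmbedderParams <- function(cfg, vocabSize) {
  d <- cfg$dModel
  f <- cfg$ffnDim
  sd0 <- 0.02
  p <- list(E = matrix(rnorm(vocabSize * d, sd = sd0), vocabSize, d),
            P = matrix(rnorm(cfg$maxTokens * d, sd = sd0), cfg$maxTokens, d))
  for (l in seq_len(cfg$nLayers)) {
    nm <- function(s) sprintf("L%d.%s", l, s)
    for (w in c("Wq", "Wk", "Wv", "Wo")) {
      p[[nm(w)]] <- matrix(rnorm(d * d, sd = sd0), d, d)
    }
    for (b in c("bq", "bk", "bv", "bo")) p[[nm(b)]] <- rep(0, d)
    p[[nm("ln1.g")]] <- rep(1, d); p[[nm("ln1.b")]] <- rep(0, d)
    p[[nm("W1")]] <- matrix(rnorm(d * f, sd = sd0), d, f)
    p[[nm("b1")]] <- rep(0, f)
    p[[nm("W2")]] <- matrix(rnorm(f * d, sd = sd0), f, d)
    p[[nm("b2")]] <- rep(0, d)
    p[[nm("ln2.g")]] <- rep(1, d); p[[nm("ln2.b")]] <- rep(0, d)
  }
  p[["out.W"]] <- matrix(rnorm(vocabSize * d, sd = sd0), vocabSize, d)
  p[["out.b"]] <- rep(0, vocabSize)
  p
}

# Loss + grads for one masked sequence; idx is the 1-based masked input.
mlmStep <- function(params, cfg, idx, pos, targets) {
  fw <- encoderForward(params, cfg, idx)
  Xm <- fw$X[pos, , drop = FALSE]
  logits <- Xm %*% t(params$out.W) + rep(1, length(pos)) %o% params$out.b
  sm <- softmaxXent(t(logits), targets + 1L)
  dlog <- t(sm$dlogits)                 # (nMask x V)
  g <- list()
  g[["out.W"]] <- crossprod(dlog, Xm)
  g[["out.b"]] <- colSums(dlog)
  dX <- matrix(0, nrow(fw$X), cfg$dModel)
  dX[pos, ] <- dlog %*% params$out.W
  g2 <- encoderBackward(params, cfg, fw, dX)
  for (n in names(g2)) g <- addGrad(g, n, g2[[n]])
  nhit <- sum(max.col(logits) == targets + 1L)
  list(loss = sm$loss, grads = g, nMask = length(pos), nHit = nhit)
}

#' Train a masked-language-model embedder on a k-mer corpus
#'
#' BERT-style transformer encoder trained with the MLM objective only (the
#' next-sentence-prediction task is removed). Sequences longer than
#' \code{maxTokens - 2} content tokens are windowed with
#' \code{\link{chunkWindows}} and each window is a training sentence.
#'
#' @param corpus list of character sequences, or list of 0-based content id
#'   vectors already encoded under \code{vocab}.
#' @param vocab a \linkS4class{KmerVocabulary}.
#' @param dModel embedding width (default 32 at desk scale; 768 reproduces
#'   the BERT-base geometry).
#' @param nLayers,nHeads encoder size.
#' @param ffnMult feed-forward width multiplier (ffn dim = ffnMult * dModel).
#' @param maxTokens window capacity including \code{[CLS]}/\code{[SEP]}.
#' @param overlap window overlap, see \code{\link{chunkWindows}}.
#' @param maskRate fraction of content tokens masked per sentence.
#' @param spanMask mask k contiguous tokens per pick (DNABERT convention);
#'   FALSE masks independent single tokens.
#' @param epochs,batch,lr,seed training settings (Adam optimizer).
#' @return an \linkS4class{MLMEmbedder} with per-epoch loss in
#'   \code{@history}.
#' @export
trainEmbedder <- function(corpus, vocab, dModel = 32L, nLayers = 1L,
                          nHeads = 2L, ffnMult = 2L, maxTokens = 512L,
                          overlap = 64L, maskRate = 0.15, spanMask = TRUE,
                          epochs = 5L, batch = 8L, lr = 1e-3, seed = 1L) {
  if (!length(corpus)) stop("corpus is empty")
  if (dModel %% nHeads != 0L) stop("dModel must be divisible by nHeads")
  ids <- lapply(corpus, function(s) {
    if (is.character(s)) encodeSequence(s, vocab) else as.integer(s)
  })
  windows <- unlist(lapply(ids, chunkWindows, maxTokens = maxTokens,
                           overlap = overlap), recursive = FALSE)
  cfg <- list(dModel = as.integer(dModel), nLayers = as.integer(nLayers),
              nHeads = as.integer(nHeads),
              ffnDim = as.integer(ffnMult * dModel),
              maxTokens = as.integer(maxTokens), overlap = as.integer(overlap),
              maskRate = maskRate, spanMask = spanMask,
              spanLen = if (spanMask) vocab@k else 1L,
              lr = lr, seed = as.integer(seed))
  history <- numeric(epochs)
  params <- withSeed(seed, {
    params <- initEmbedderParams(cfg, length(vocab))
    state <- adamInit(params)
    for (ep in seq_len(epochs)) {
      ord <- sample(seq_along(windows))
      epLoss <- 0
      nb <- 0L
      for (bStart in seq(1L, length(ord), by = batch)) {
        sel <- ord[bStart:min(bStart + batch - 1L, length(ord))]
        grads <- list()
        bLoss <- 0
        for (i in sel) {
          enc <- c(2L, windows[[i]], 3L)  # [CLS] ... [SEP]
          mk <- maskTokenIds(enc, maskRate = maskRate, spanLen = cfg$spanLen)
          st <- mlmStep(params, cfg, mk$ids + 1L, mk$pos, mk$targets)
          for (n in names(st$grads)) grads <- addGrad(grads, n, st$grads[[n]])
          bLoss <- bLoss + st$loss
        }
        grads <- lapply(grads, function(gv) gv / length(sel))
        upd <- adamStep(params, grads, state, lr = lr)
        params <- upd$params
        state <- upd$state
        epLoss <- epLoss + bLoss / length(sel)
        nb <- nb + 1L
      }
      history[ep] <- epLoss / nb
    }
    params
  })
  new("MLMEmbedder", vocab = vocab, dModel = as.integer(dModel),
      params = params, config = cfg, history = history)
}

#' Masked-token prediction accuracy of an MLM embedder
#'
#' Masks each corpus sequence with the embedder's own masking settings and
#' reports the fraction of masked tokens whose identity the model predicts
#' correctly.
#'
#' @param embedder an \linkS4class{MLMEmbedder}.
#' @param corpus list of character sequences or 0-based id vectors.
#' @param seed seed for the mask draws.
#' @return fraction in [0, 1].
#' @export
mlmMaskedAccuracy <- function(embedder, corpus, seed = 1L) {
  vocab <- embedder@vocab
  cfg <- embedder@config
  ids <- lapply(corpus, function(s) {
    if (is.character(s)) encodeSequence(s, vocab) else as.integer(s)
  })
  windows <- unlist(lapply(ids, chunkWindows, maxTokens = cfg$maxTokens,
                           overlap = cfg$overlap), recursive = FALSE)
  withSeed(seed, {
    hit <- 0L; tot <- 0L
    for (w in windows) {
      enc <- c(2L, w, 3L)
      mk <- maskTokenIds(enc, maskRate = cfg$maskRate, spanLen = cfg$spanLen)
      fw <- encoderForward(embedder@params, cfg, mk$ids + 1L)
      logits <- fw$X[mk$pos, , drop = FALSE] %*% t(embedder@params$out.W) +
        rep(1, length(mk$pos)) %o% embedder@params$out.b
      hit <- hit + sum(max.col(logits) == mk$targets + 1L)
      tot <- tot + length(mk$pos)
    }
    hit / tot
  })
}
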