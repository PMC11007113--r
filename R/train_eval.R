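# Training loop, top-k evaluation, long-tail head/tail reporting and the
# ablation harness.

# Group record indices into batches of records with identical embedding
# shape (global pooling makes the model length-agnostic, but a batch tensor
# needs one L').
shapeBatches <- function(embs, idxs, batch) {
  keys <- vapply(embs[idxs], function(m) paste(dim(m), collapse = "x"),
                 character(1))
  unlist(lapply(split(idxs, keys), function(ii) {
    split(ii, ceiling(seq_along(ii) / batch))
  }), recursive = FALSE, use.names = FALSE)
}

#' Map species to genus for genus-level scoring
#' @param ds an \linkS4class{AmpliconDataset}.
#' @return named character vector, species name -> genus name.
#' @export
speciesToGenus <- function(ds) {
  tx <- taxonomy(ds)
  sp <- tx$species
  keep <- !duplicated(sp) & sp != ""
  setNames(tx$genus[keep], sp[keep])
}

#' Train a classifier with cross-entropy
#'
#' Minibatch Adam training. Per-epoch train loss/accuracy (and test
#' loss/accuracy when a test set is supplied) are recorded; the returned
#' model carries the weights of the best test top-1 epoch when
#' \code{keepBest} and a test set are given, otherwise the final weights.
#' Training aborts with diagnostics if the loss turns non-finite.
#'
#' @param model an untrained \linkS4class{DSNetaxModel} from
#'   \code{\link{buildModel}}.
#' @param embs named list of embedding matrices (training records).
#' @param labels integer vector of 0-based species label ids, aligned with
#'   \code{embs}.
#' @param epochs training epochs (the reference setting is 60; desk-scale
#'   runs use fewer).
#' @param batch minibatch size.
#' @param lr Adam learning rate.
#' @param seed shuffling seed.
#' @param testEmbs,testLabels optional held-out set scored every epoch.
#' @param keepBest keep the best-test-top-1 checkpoint.
#' @param verbose print per-epoch progress.
#' @return list with \code{model} (trained \code{DSNetaxModel}) and
#'   \code{history} (data.frame epoch, trainLoss, trainAcc, testLoss,
#'   testAcc).
#' @export
trainModel <- function(model, embs, labels, epochs = 60L, batch = 32L,
                       lr = 1e-3, seed = 1L, testEmbs = NULL,
                       testLabels = NULL, keepBest = TRUE, verbose = FALSE) {
  nC <- model@config@nClasses
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= nC)) {
    stop("label id outside the model's nClasses")
  }
  params <- model@params
  state <- adamInit(params)
  hist <- data.frame(epoch = seq_len(epochs), trainLoss = NA_real_,
                     trainAcc = NA_real_, testLoss = NA_real_,
                     testAcc = NA_real_)
  best <- list(acc = -1, params = NULL)
  withSeed(deriveSeed(seed, "train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample(seq_along(embs))
      batches <- shapeBatches(embs, ord, batch)
      epLoss <- 0; epHit <- 0L
      for (bi in batches) {
        x <- embedBatch(embs[bi])
        model@params <- params
        fw <- modelForward(model, x, training = TRUE)
        sm <- softmaxXent(fw$logits, labels[bi] + 1L)
        if (!is.finite(sm$loss)) {
          stop(sprintf("non-finite training loss at epoch %d (|logits| max %.3g)",
                       ep, max(abs(fw$logits))))
        }
        grads <- modelBackward(model, fw, sm$dlogits)
        upd <- adamStep(params, grads, state, lr = lr)
        params <- upd$params
        state <- upd$state
        for (nmbn in names(fw$bnUp)) {
          params[[paste0(nmbn, ".rmean")]] <- fw$bnUp[[nmbn]]$rmean
          params[[paste0(nmbn, ".rvar")]] <- fw$bnUp[[nmbn]]$rvar
        }
        epLoss <- epLoss + sm$loss * length(bi)
        epHit <- epHit + sum(max.col(t(fw$logits)) == labels[bi] + 1L)
      }
      hist$trainLoss[ep] <- epLoss / length(embs)
      hist$trainAcc[ep] <- 100 * epHit / length(embs)
      if (!is.null(testEmbs)) {
        model@params <- params
        te <- scoreSet(model, testEmbs, testLabels, ks = 1L)
        hist$testLoss[ep] <- te$loss
        hist$testAcc[ep] <- te$topk[["1"]]
        if (keepBest && te$topk[["1"]] > best$acc) {
          best$acc <- te$topk[["1"]]
          best$params <- params
        }
      }
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  acc %5.1f%%%s", ep,
                        hist$trainLoss[ep], hist$trainAcc[ep],
                        if (!is.null(testEmbs))
                          sprintf("  test %5.1f%%", hist$testAcc[ep]) else ""))
      }
    }
  })
  model@params <- if (keepBest && !is.null(best$params)) best$params else params
  list(model = model, history = hist)
}

# Forward a whole set in eval mode; returns loss, topk percentages and the
# per-record 0/1 hit matrix.
scoreSet <- function(model, embs, labels, ks = c(1L, 5L), batch = 64L) {
  ks <- sort(as.integer(ks))
  kmax <- min(max(ks), model@config@nClasses)
  n <- length(embs)
  hits <- matrix(0L, n, length(ks), dimnames = list(NULL, as.character(ks)))
  loss <- 0
  batches <- shapeBatches(embs, seq_len(n), batch)
  predTop <- matrix(NA_integer_, n, kmax)
  for (bi in batches) {
    fw <- modelForward(model, embedBatch(embs[bi]), training = FALSE)
    sm <- softmaxXent(fw$logits, labels[bi] + 1L)
    loss <- loss + sm$loss * length(bi)
    for (j in seq_along(bi)) {
      top <- predictTopk(fw$logits[, j], kmax)
      predTop[bi[j], ] <- top
      for (ki in seq_along(ks)) {
        hits[bi[j], ki] <- as.integer(labels[bi[j]] %in%
                                        top[seq_len(min(ks[ki], kmax))])
      }
    }
  }
  list(loss = loss / n,
       topk = setNames(100 * colMeans(hits), as.character(ks)),
       hits = hits, predTop = predTop)
}

#' Evaluate top-k accuracy of a trained model
#'
#' Accuracy at k is the percentage of records whose true species label is
#' among the k highest-scoring predictions. Genus-level accuracy maps each
#' predicted species to its genus; genus top-k counts a hit when any of the
#' top-k predicted species belongs to the true genus.
#'
#' @param model a trained \linkS4class{DSNetaxModel}.
#' @param embs named list of test embedding matrices.
#' @param labels 0-based true species label ids.
#' @param ks the k values to report (default 1 and 5).
#' @param genusMap optional species-to-genus map from
#'   \code{\link{speciesToGenus}}; enables genus-level scoring.
#' @return an \linkS4class{EvalReport}.
#' @export
evaluateTopk <- function(model, embs, labels, ks = c(1L, 5L),
                         genusMap = NULL) {
  if (!length(embs)) stop("test set is empty")
  ks <- sort(as.integer(ks))
  sc <- scoreSet(model, embs, labels, ks = ks)
  genus <- numeric(0)
  if (!is.null(genusMap)) {
    trueGenus <- unname(genusMap[model@labelIndex[labels + 1L]])
    predGenus <- matrix(genusMap[model@labelIndex[sc$predTop + 1L]],
                        nrow = nrow(sc$predTop))
    genus <- vapply(ks, function(k) {
      kk <- min(k, ncol(predGenus))
      100 * mean(vapply(seq_along(labels), function(i) {
        trueGenus[i] %in% predGenus[i, seq_len(kk)]
      }, logical(1)))
    }, numeric(1))
    names(genus) <- as.character(ks)
  }
  new("EvalReport", topk = sc$topk, genusTopk = genus,
      n = length(embs), hits = sc$hits)
}

#' Long-tail head/tail evaluation
#'
#' Partitions the test records at each cutpoint c into HEAD (species whose
#' TRAINING read count is >= c) and TAIL (< c) and reports per-part top-k
#' accuracy. The abundance must come from the training set (the long-tail
#' profile the model actually saw); species absent from it count 0. Empty
#' parts are marked not-reported (NA) rather than scored.
#'
#' @param report an \linkS4class{EvalReport} from \code{\link{evaluateTopk}}.
#' @param testSpecies character vector of true species names, aligned with
#'   the report's records.
#' @param trainAbundance named integer vector from
#'   \code{\link{countPerSpecies}} on the training set.
#' @param cutpoints positive integer cutpoints (default 50, 100, 500).
#' @return a \linkS4class{HeadTailReport}.
#' @export
headTailEval <- function(report, testSpecies, trainAbundance,
                         cutpoints = c(50L, 100L, 500L)) {
  if (any(cutpoints <= 0L)) stop("cutpoints must be positive")
  if (length(testSpecies) != report@n) {
    stop("testSpecies must align with the report's records")
  }
  counts <- trainAbundance[testSpecies]
  counts[is.na(counts)] <- 0L
  ks <- colnames(report@hits)
  rows <- list()
  for (cut in as.integer(cutpoints)) {
    isHead <- counts >= cut
    for (part in c("head", "tail")) {
      sel <- if (part == "head") isHead else !isHead
      acc <- if (any(sel)) {
        100 * colMeans(report@hits[sel, , drop = FALSE])
      } else {
        setNames(rep(NA_real_, length(ks)), ks)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cutpoint = cut, part = part, n = sum(sel),
        as.list(setNames(acc, paste0("top", ks))),
        reported = any(sel))
    }
  }
  new("HeadTailReport", cutpoints = as.integer(cutpoints),
      table = do.call(rbind, rows))
}

#' Stratified subsampling of a training set
#'
#' Keeps \code{round(n * fraction)} records per species, clamped to at least
#' one, so every species stays represented. Deterministic given the seed.
#'
#' @param ds an \linkS4class{AmpliconDataset}.
#' @param fraction fraction in (0, 1].
#' @param seed integer seed.
#' @return an \linkS4class{AmpliconDataset}.
#' @export
subsampleTraining <- function(ds, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(ds)
  sp <- speciesLabels(ds)
  keep <- logical(length(ds))
  for (s in unique(sp)) {
    idx <- sort(which(sp == s))
    nKeep <- min(max(as.integer(round(length(idx) * fraction)), 1L),
                 length(idx))
    keep[idx[withSeed(deriveSeed(seed, s), sample.int(length(idx), nKeep))]] <- TRUE
  }
  ds[keep]
}

#' Run a grid of training/evaluation experiments
#'
#' Desk-scale ablation harness mirroring the published experimental designs:
#' k-mer size, model variant, shallow depth and training-set fraction vary
#' over a grid; each grid point trains from scratch with a logged seed and
#' is scored on the common test set.
#'
#' @param train,test \linkS4class{AmpliconDataset} parts from
#'   \code{\link{stratifiedSplit}}.
#' @param grid data.frame with any of the columns \code{k}, \code{variant},
#'   \code{shallowLayers}, \code{fraction} (missing columns take defaults
#'   3, "dsnetax", 3, 1.0).
#' @param dModel embedding width of the per-k hash providers.
#' @param widthScale classifier width multiplier (see
#'   \code{\link{dsnetaxConfig}}).
#' @param epochs,batch,lr training settings per grid point.
#' @param seed base seed; each row logs its own derived seed.
#' @return data.frame: one row per grid point with top-1/top-5 accuracy and
#'   the seed used.
#' @export
runAblation <- function(train, test, grid, dModel = 16L, widthScale = 1 / 8,
                        epochs = 10L, batch = 32L, lr = 1e-3, seed = 1L) {
  if (!nrow(grid)) return(data.frame())
  if (is.null(grid$k)) grid$k <- 3L
  if (is.null(grid$variant)) grid$variant <- "dsnetax"
  if (is.null(grid$shallowLayers)) grid$shallowLayers <- 3L
  if (is.null(grid$fraction)) grid$fraction <- 1.0
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rowSeed <- deriveSeed(seed, sprintf("ablation-%d-%s-%d-%g", grid$k[i],
                                        grid$variant[i],
                                        grid$shallowLayers[i],
                                        grid$fraction[i]))
    vocab <- buildVocab(grid$k[i])
    provider <- hashEmbedder(vocab, dModel = dModel, seed = rowSeed)
    tr <- subsampleTraining(train, grid$fraction[i], seed = rowSeed)
    trEmb <- embedDataset(tr, provider)
    teEmb <- embedDataset(test, provider)
    cfg <- dsnetaxConfig(nClasses = length(train@labelIndex),
                         variant = grid$variant[i],
                         widthScale = widthScale,
                         shallowLayers = grid$shallowLayers[i])
    mdl <- buildModel(cfg, labelIndex = train@labelIndex,
                      embedderFingerprint = embedderFingerprint(provider),
                      seed = rowSeed)
    fit <- trainModel(mdl, trEmb, labelIds(tr), epochs = epochs,
                      batch = batch, lr = lr, seed = rowSeed,
                      keepBest = FALSE)
    rep <- evaluateTopk(fit$model, teEmb, labelIds(test),
                        ks = c(1L, min(5L, cfg@nClasses)))
    ksNames <- names(rep@topk)
    out[[i]] <- data.frame(k = grid$k[i], variant = grid$variant[i],
                           shallowLayers = grid$shallowLayers[i],
                           fraction = grid$fraction[i],
                           top1 = rep@topk[[1L]],
                           top5 = rep@topk[[length(ksNames)]],
                           seed = rowSeed)
  }
  do.call(rbind, out)
}
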