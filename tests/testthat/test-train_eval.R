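test_that("training reduces the loss and records a full history", {
  cm <- benchCommunity(nSpecies = 4L, reads = 6L, len = 80L, seed = 31L)
  v <- buildVocab(3)
  pe <- hashEmbedder(v, 8L, seed = 31L)
  emb <- embedDataset(cm$dataset, pe)
  m <- buildModel(dsnetaxConfig(nClasses = 4L, widthScale = 1 / 16),
                  labelIndex = cm$dataset@labelIndex,
                  embedderFingerprint = embedderFingerprint(pe), seed = 31L)
  fit <- trainModel(m, emb, labelIds(cm$dataset), epochs = 3L, batch = 12L,
                    lr = 2e-3, seed = 31L)
  expect_identical(nrow(fit$history), 3L)
  expect_lt(fit$history$trainLoss[3], fit$history$trainLoss[1])
  expect_true(all(is.finite(fit$history$trainLoss)))
  expect_error(trainModel(m, emb, rep(9L, length(emb)), epochs = 1L),
               "nClasses")
  # evaluation: nesting and shape contracts
  rep1 <- evaluateTopk(fit$model, emb, labelIds(cm$dataset), ks = c(1L, 3L),
                       genusMap = speciesToGenus(cm$dataset))
  expect_lte(rep1@topk[["1"]], rep1@topk[["3"]])
  expect_true(all(rep1@hits[, 1] <= rep1@hits[, 2]))
  expect_gte(rep1@genusTopk[["1"]], rep1@topk[["1"]])
  expect_identical(rep1@n, length(emb))
  expect_error(evaluateTopk(fit$model, list(), integer(0)), "empty")
})

test_that("training is reproducible under a fixed seed", {
  cm <- benchCommunity(nSpecies = 3L, reads = 5L, len = 60L, seed = 37L)
  v <- buildVocab(3)
  pe <- hashEmbedder(v, 8L, seed = 37L)
  emb <- embedDataset(cm$dataset, pe)
  m <- buildModel(dsnetaxConfig(nClasses = 3L, widthScale = 1 / 16),
                  labelIndex = cm$dataset@labelIndex, seed = 37L)
  f1 <- trainModel(m, emb, labelIds(cm$dataset), epochs = 2L, seed = 5L)
  f2 <- trainModel(m, emb, labelIds(cm$dataset), epochs = 2L, seed = 5L)
  expect_identical(f1$history, f2$history)
  expect_equal(f1$model@params, f2$model@params)
})

test_that("top-k accuracy of uniform-random logits matches the binomial expectation", {
  set.seed(61)
  C <- 20L; n <- 2000L
  hits1 <- 0L; hits5 <- 0L
  truth <- sample(0:(C - 1L), n, replace = TRUE)
  for (i in seq_len(n)) {
    top <- predictTopk(runif(C), 5L)
    hits1 <- hits1 + (truth[i] == top[1L])
    hits5 <- hits5 + (truth[i] %in% top)
  }
  sd1 <- sqrt(0.05 * 0.95 / n)
  sd5 <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(hits1 / n - 0.05), 3 * sd1)
  expect_lt(abs(hits5 / n - 0.25), 3 * sd5)
})

test_that("head/tail partitions are exact and recombine to the overall accuracy", {
  set.seed(71)
  n <- 300L
  hits <- cbind(`1` = rbinom(n, 1L, 0.7), `5` = 0L)
  hits[, 2] <- pmax(hits[, 1], rbinom(n, 1L, 0.5))
  rep1 <- new("EvalReport", topk = setNames(100 * colMeans(hits), c("1", "5")),
              genusTopk = numeric(0), n = n, hits = hits)
  species <- sample(sprintf("sp%d", 1:30), n, replace = TRUE)
  abundance <- setNames(as.integer(round(600 * (1:30)^-1.3)),
                        sprintf("sp%d", 1:30))
  ht <- headTailEval(rep1, species, abundance, cutpoints = c(50L, 100L, 500L))
  tab <- ht@table
  for (cut in c(50L, 100L, 500L)) {
    part <- tab[tab$cutpoint == cut, ]
    expect_identical(sum(part$n), n)
    # weighted recombination is exact
    for (col in c("top1", "top5")) {
      w <- sum(part$n * ifelse(is.na(part[[col]]), 0, part[[col]])) / n
      expect_equal(w, rep1@topk[[sub("top", "", col)]])
    }
  }
  # a species with train count exactly at the cut is HEAD
  one <- new("EvalReport", topk = c(`1` = 100), genusTopk = numeric(0),
             n = 1L, hits = matrix(1L, 1, 1, dimnames = list(NULL, "1")))
  ht50 <- headTailEval(one, "spX", c(spX = 50L), cutpoints = 50L)
  expect_identical(ht50@table$n[ht50@table$part == "head"], 1L)
  # empty tail is flagged not-reported, not scored zero
  expect_false(ht50@table$reported[ht50@table$part == "tail"])
  expect_true(is.na(ht50@table$top1[ht50@table$part == "tail"]))
  expect_error(headTailEval(one, "spX", c(spX = 50L), cutpoints = 0L),
               "positive")
})

test_that("stratified subsampling keeps every species represented", {
  ds <- toyBandDataset(sizes = c(10L, 4L, 1L), withAmbiguity = FALSE)
  expect_identical(names(subsampleTraining(ds, 1.0)), names(ds))
  half <- subsampleTraining(ds, 0.5, seed = 2L)
  expect_identical(unname(countPerSpecies(half)[c("Genus1_sp1", "Genus2_sp1",
                                                  "Genus3_sp1")]),
                   c(5L, 2L, 1L))
  expect_identical(names(subsampleTraining(ds, 0.5, seed = 2L)), names(half))
  set.seed(83)
  for (i in 1:10) {
    sizes <- sample(1:12, 4L)
    dsr <- toyBandDataset(sizes = sizes, withAmbiguity = FALSE)
    f <- runif(1, 0.05, 0.95)
    sub <- subsampleTraining(dsr, f, seed = i)
    cnt <- countPerSpecies(sub)
    expect_identical(sort(names(cnt)), sort(names(countPerSpecies(dsr))))
    expect_true(all(cnt >= 1L))
  }
})

test_that("the ablation harness runs every variant to completion, deterministically", {
  cm <- benchCommunity(nSpecies = 6L, reads = 5L, len = 60L, seed = 41L)
  sp <- stratifiedSplit(cm$dataset, 0.2, seed = 41L)
  grid <- data.frame(variant = c("cnn3", "resnet34", "dsnetax"),
                     k = c(3L, 3L, 4L))
  tab <- runAblation(sp$train, sp$test, grid, dModel = 8L, widthScale = 1 / 16,
                     epochs = 2L, batch = 16L, seed = 13L)
  expect_identical(nrow(tab), 3L)
  expect_true(all(is.finite(tab$top1)))
  expect_true(all(tab$top1 >= 0 & tab$top1 <= 100))
  expect_true(all(tab$top1 <= tab$top5))
  tab2 <- runAblation(sp$train, sp$test, grid, dModel = 8L, widthScale = 1 / 16,
                      epochs = 2L, batch = 16L, seed = 13L)
  expect_identical(tab, tab2)
  expect_identical(nrow(runAblation(sp$train, sp$test, grid[0, , drop = FALSE])),
                   0L)
})
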