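test_that("configuration validity guards the architecture contract", {
  expect_error(dsnetaxConfig(nClasses = 1L), "nClasses")
  expect_error(dsnetaxConfig(nClasses = 5L, shallowLayers = 6L), "3, 4 or 5")
  expect_error(dsnetaxConfig(nClasses = 5L, stageWidths = c(6L, 6L, 6L, 6L),
                             radix = 4L), "divisible")
  cfg <- dsnetaxConfig(nClasses = 5L)
  expect_identical(cfg@stageBlocks, c(2L, 3L, 2L, 2L))
  expect_identical(sum(cfg@stageBlocks), 9L)
})

test_that("variants instantiate the published topologies", {
  li <- sprintf("sp%d", 1:6)
  small <- function(variant, shallowLayers = 3L) {
    buildModel(dsnetaxConfig(nClasses = 6L, variant = variant,
                             widthScale = 1 / 16, shallowLayers = shallowLayers),
               labelIndex = li, seed = 1L)
  }
  d <- describeModel(small("dsnetax"))
  expect_identical(d$splitAttentionBlocks, 9L)
  expect_identical(d$stageBlocks, c(2L, 3L, 2L, 2L))
  expect_identical(d$shallowConvLayers, 3L)
  r <- describeModel(small("resnet34"))
  expect_identical(r$stageBlocks, c(3L, 4L, 6L, 3L))
  expect_identical(r$residualBlocks, 16L)
  expect_identical(r$splitAttentionBlocks, 0L)
  c3 <- describeModel(small("cnn3"))
  expect_identical(c3$convLayers, 3L)
  expect_identical(c3$splitAttentionBlocks, 0L)
  for (sl in 4:5) {
    expect_identical(describeModel(small("dsnetax", sl))$shallowConvLayers, sl)
  }
})

test_that("r-softmax weights sum to one across the radix", {
  set.seed(33)
  for (R in 2:3) {
    C <- 6L
    z <- matrix(rnorm(C * R * 5, sd = 3), C * R, 5)
    a <- DSNetax:::rSoftmaxF(z, C, R)$y
    sums <- matrix(0, C, 5)
    for (r in seq_len(R)) sums <- sums + a[(r - 1) * C + seq_len(C), ]
    expect_lt(max(abs(sums - 1)), 1e-6)
  }
})

test_that("the vectorized Split-Attention block matches the naive loop oracle", {
  set.seed(44)
  cases <- list(
    list(cin = 4L, width = 4L, stride = 1L, radix = 2L, cardinality = 1L),
    list(cin = 4L, width = 8L, stride = 2L, radix = 2L, cardinality = 2L),
    list(cin = 8L, width = 8L, stride = 1L, radix = 3L, cardinality = 1L))
  for (cs in cases) {
    blk <- makeBlock(cs$cin, cs$width, cs$stride, cs$radix, cs$cardinality,
                     seed = cs$width + cs$radix)
    xs <- lapply(1:2, function(n) array(rnorm(cs$cin * 8 * 8), c(cs$cin, 8, 8)))
    fast <- packageSplitAttention(blk$spec, blk$params, xs)
    slow <- naiveSplitAttention(blk$spec, blk$params, xs)
    for (n in 1:2) {
      expect_lt(max(abs(fast[[n]] - slow[[n]])), 1e-5)
    }
  }
})

test_that("radix 1 degenerates to a squeeze-excitation block with sigmoid gate", {
  blk <- makeBlock(4L, 4L, 1L, radix = 1L, cardinality = 1L, seed = 10L)
  xs <- lapply(1:2, function(n) array(rnorm(4 * 8 * 8), c(4, 8, 8)))
  fast <- packageSplitAttention(blk$spec, blk$params, xs)
  se <- naiveSEBlock(blk$spec, blk$params, xs)
  for (n in 1:2) expect_lt(max(abs(fast[[n]] - se[[n]])), 1e-5)
})

test_that("deep branch pools to a fixed-length vector for any sequence length", {
  cfg <- dsnetaxConfig(nClasses = 4L, widthScale = 1 / 16)
  m <- buildModel(cfg, seed = 6L)
  for (L in c(64L, 128L, 1498L)) {
    g <- deepForward(m, matrix(rnorm(L * 16), L, 16))
    expect_identical(dim(g), c(cfg@stageWidths[4], 1L))
    expect_true(all(is.finite(g)))
  }
  # batch size only scales the batch dimension
  embs <- lapply(1:4, function(i) matrix(rnorm(64 * 16), 64, 16))
  expect_identical(dim(deepForward(m, embs)), c(cfg@stageWidths[4], 4L))
})

test_that("shallow branch is nonnegative and zero maps to zero at init", {
  cfg <- dsnetaxConfig(nClasses = 4L, widthScale = 1 / 16)
  m <- buildModel(cfg, seed = 2L)
  x <- matrix(rnorm(100 * 16), 100, 16)
  s <- shallowForward(m, x)
  expect_true(all(s >= 0))
  expect_identical(dim(s), c(cfg@shallowWidth, 1L))
  # conv biases start at zero, so a zero map stays zero through Conv+ReLU
  expect_true(all(shallowForward(m, matrix(0, 100, 16)) == 0))
})

test_that("fusion concatenates pooled features into class logits", {
  li <- sprintf("sp%d", 1:5)
  m <- buildModel(dsnetaxConfig(nClasses = 5L, widthScale = 1 / 16),
                  labelIndex = li, seed = 3L)
  embs <- lapply(1:3, function(i) matrix(rnorm(80 * 12), 80, 12))
  g <- deepForward(m, embs)
  l <- shallowForward(m, embs)
  z <- fuseClassify(m, g, l)
  expect_identical(dim(z), c(5L, 3L))
  # permuting the batch permutes logits identically
  z2 <- fuseClassify(m, g[, c(3, 1, 2)], l[, c(3, 1, 2)])
  expect_equal(z2, z[, c(3, 1, 2)])
  expect_error(fuseClassify(m, g[1:3, , drop = FALSE], l), "dimension")
  # consistency with the training-path forward in eval mode
  fw <- DSNetax:::modelForward(m, DSNetax:::embedBatch(embs), training = FALSE)
  expect_equal(fw$logits, z, tolerance = 1e-12)
})

test_that("gradients flow through both branches", {
  m <- buildModel(dsnetaxConfig(nClasses = 4L, widthScale = 1 / 16), seed = 9L)
  x <- DSNetax:::embedBatch(lapply(1:4, function(i) matrix(rnorm(60 * 12), 60, 12)))
  fw <- DSNetax:::modelForward(m, x, training = TRUE)
  sm <- DSNetax:::softmaxXent(fw$logits, c(1L, 2L, 3L, 4L))
  gr <- DSNetax:::modelBackward(m, fw, sm$dlogits)
  expect_gt(sum(abs(gr[["deep.stem.conv.W"]])), 0)
  expect_gt(sum(abs(gr[["shallow.c1.W"]])), 0)
  expect_gt(sum(abs(gr[["deep.s1.b1.fc2.W"]])), 0)
})

test_that("alternative fusion modes produce finite logits and gradients", {
  for (fus in c("sum", "gated")) {
    m <- buildModel(dsnetaxConfig(nClasses = 3L, widthScale = 1 / 16,
                                  shallowWidth = 32L, fusion = fus), seed = 4L)
    x <- DSNetax:::embedBatch(lapply(1:2, function(i) matrix(rnorm(50 * 8), 50, 8)))
    fw <- DSNetax:::modelForward(m, x, training = TRUE)
    expect_true(all(is.finite(fw$logits)))
    gr <- DSNetax:::modelBackward(m, fw,
                                  DSNetax:::softmaxXent(fw$logits, c(1L, 2L))$dlogits)
    expect_gt(sum(abs(gr[["shallow.c1.W"]])), 0)
  }
})

test_that("predictTopk ranks labels with deterministic tie-breaking", {
  expect_identical(predictTopk(c(0.1, 0.9, 0.5), 2L), c(1L, 2L))
  expect_identical(sort(predictTopk(rnorm(7), 7L)), 0:6)
  expect_identical(predictTopk(rep(1, 5), 3L), 0:2)
  expect_error(predictTopk(c(1, 2), 3L), "out of range")
})
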